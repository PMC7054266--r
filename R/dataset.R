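#' Behavioral dataset of conflict-task trials
#'
#' A light container for one subject's trials: per trial a conflict
#' indicator (0 = congruent/non-conflict, 1 = incongruent/conflict), a
#' response time in seconds measured from stimulus onset, and an
#' accuracy-coded choice (`correct` logical; the upper decision bound is the
#' correct response). Fitting requires at least one trial of each condition.
#'
#' @param trials data frame with columns `condition`, `rt`, `correct`
#'   (optionally `session_id`).
#' @param subject_id subject label.
#' @return An object of class `behavioral_dataset`.
#' @export
behavioral_dataset <- function(trials, subject_id = "subject") {
  trials <- as.data.frame(trials)
  req <- c("condition", "rt", "correct")
  miss <- setdiff(req, names(trials))
  if (length(miss))
    stop("trials is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(trials) == 0L) stop("dataset must contain at least one trial")
  if (!all(trials$condition %in% c(0, 1)))
    stop("condition must be 0 (non-conflict) or 1 (conflict)")
  if (any(!is.finite(trials$rt)) || any(trials$rt <= 0))
    stop("all response times must be finite and > 0")
  trials$condition <- as.integer(trials$condition)
  trials$correct <- as.logical(trials$correct)
  structure(list(subject_id = subject_id, trials = trials),
            class = "behavioral_dataset")
}

#' @export
print.behavioral_dataset <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("behavioral_dataset '%s': %d trials (%d conflict, %d non-conflict)\n",
              x$subject_id, nrow(tr), sum(tr$condition == 1),
              sum(tr$condition == 0)))
  invisible(x)
}

# Accept either a behavioral_dataset or a bare trial data frame.
as_trial_df <- function(dataset) {
  if (inherits(dataset, "behavioral_dataset")) return(dataset$trials)
  if (is.data.frame(dataset)) {
    req <- c("condition", "rt", "correct")
    miss <- setdiff(req, names(dataset))
    if (length(miss))
      stop("trial data frame is missing column(s): ",
           paste(miss, collapse = ", "))
    return(dataset)
  }
  stop("dataset must be a behavioral_dataset or a trial data frame")
}
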