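#' Simulated trace pool for expected-decision-variable reconstruction
#'
#' Simulates a large pool of SE-SSM trials with full decision-variable
#' traces under a subject's fitted parameters, half per condition. Observed
#' trials are later matched to pool trials with the same choice and nearly
#' the same response time (see [match_and_average()]).
#'
#' @param params the subject's fitted [se_params].
#' @param n_sim total number of simulated trials (default 7.5e5, at least
#'   1e4).
#' @param dt simulation step (s).
#' @param match_resolution RT matching resolution (s); a trial matches pool
#'   trials within `+/- match_resolution/2` of its RT (a 25 ms bin centered
#'   on the observed RT by default).
#' @param seed optional integer seed.
#' @return An object of class `dv_pool`: per condition the simulated trial
#'   table with trace attributes.
#' @export
dv_pool <- function(params, n_sim = 7.5e5, dt = 0.001,
                    match_resolution = 0.025, seed = NULL) {
  validate_se_params(params)
  if (n_sim < 1e4) stop("n_sim must be >= 1e4 for stable matching")
  if (!is.null(seed)) set.seed(seed)
  half <- ceiling(n_sim / 2)
  pools <- lapply(c(0L, 1L), function(cc)
    simulate_trials(params, cc, half, dt = dt, keep_traces = TRUE))
  names(pools) <- c("c0", "c1")
  structure(list(pools = pools, params = params, dt = dt,
                 match_resolution = match_resolution, n_sim = 2 * half),
            class = "dv_pool")
}

#' Expected decision-variable trace for one observed trial
#'
#' Selects pool trials with the same condition and correctness whose
#' simulated RT lies within `match_resolution/2` of the observed RT, aligns
#' their traces at the threshold-crossing sample (aligned time 0) and
#' averages backwards in time over samples covered by at least half of the
#' matched traces (earlier samples, carried only by the longest traces, are
#' dropped).
#'
#' @param pool a [dv_pool].
#' @param trial a one-row trial data frame (columns `condition`, `rt`,
#'   `correct`) or a list with those fields.
#' @param min_matches minimum number of matched traces; below it the trial
#'   is excluded (`NULL` return) with a warning rather than the tolerance
#'   widened.
#' @return An object of class `expected_dv`: `aligned_time` (s, <= 0, step
#'   `dt`, 0 at threshold crossing), `mean_dv`, `n_matched`, `condition`,
#'   `rt`, `correct`; or `NULL` if too few matches.
#' @export
match_and_average <- function(pool, trial, min_matches = 10) {
  stopifnot(inherits(pool, "dv_pool"))
  cc <- as_conflict(trial$condition)
  sims <- pool$pools[[if (cc == 0) "c0" else "c1"]]
  tol <- pool$match_resolution / 2
  sel <- which(!sims$censored & sims$correct == as.logical(trial$correct) &
                 abs(sims$rt - trial$rt) <= tol)
  if (length(sel) < min_matches) {
    warning(sprintf(
      "trial (c=%d, rt=%.3f, correct=%s): only %d matched simulations (< %d); excluded",
      cc, trial$rt, trial$correct, length(sel), min_matches))
    return(NULL)
  }
  agg <- .aligned_sums_cpp(attr(sims, "trace_values"),
                           attr(sims, "trace_offsets"), sel)
  keep <- agg$counts >= length(sel) / 2
  mean_rev <- (agg$sums / agg$counts)[keep]
  L <- length(mean_rev)
  structure(list(aligned_time = -(seq_len(L) - 1L) * pool$dt,
                 mean_dv = mean_rev, n_matched = length(sel),
                 condition = cc, rt = trial$rt,
                 correct = as.logical(trial$correct)),
            class = "expected_dv")
}

#' Expected decision-variable traces for a whole dataset
#'
#' @param pool a [dv_pool].
#' @param trials trial data frame or `behavioral_dataset`.
#' @param min_matches see [match_and_average()].
#' @return A list of `expected_dv` (or `NULL` for excluded trials), one per
#'   row of `trials`.
#' @export
expected_dv_traces <- function(pool, trials, min_matches = 10) {
  tr <- as_trial_df(trials)
  lapply(seq_len(nrow(tr)), function(i) match_and_average(pool, tr[i, ],
                                                          min_matches))
}

#' Response-locked window averages of expected-decision-variable traces
#'
#' Window `k` (k = 0, 1, ...) covers
#' `[center_k - width/2, center_k + width/2]` with
#' `center_k = first_center - width*k`: 50 ms windows stepping back from
#' the response, the first centered at -25 ms. A window not fully covered
#' by a trial's trace yields `NA`.
#'
#' @param traces list of `expected_dv` objects (`NULL` entries allowed;
#'   they yield all-`NA` rows).
#' @param window_width window width (s).
#' @param first_center center of the first (latest) window (s, negative).
#' @param n_windows number of windows.
#' @return A numeric matrix, trials x windows; column names give window
#'   centers in seconds.
#' @export
extract_windows <- function(traces, window_width = 0.050,
                            first_center = -0.025, n_windows = 8) {
  centers <- first_center - window_width * (seq_len(n_windows) - 1L)
  amp <- matrix(NA_real_, nrow = length(traces), ncol = n_windows,
                dimnames = list(NULL, sprintf("%.3f", centers)))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    if (is.null(tr)) next
    t0 <- min(tr$aligned_time)
    for (k in seq_len(n_windows)) {
      lo <- centers[k] - window_width / 2
      hi <- centers[k] + window_width / 2
      if (lo < t0 - 1e-12 || hi > 1e-9) next
      inw <- tr$aligned_time >= lo - 1e-12 & tr$aligned_time <= hi + 1e-12
      amp[i, k] <- mean(tr$mean_dv[inw])
    }
  }
  attr(amp, "centers") <- centers
  amp
}

#' Z-score window amplitudes into GLM regressor amplitudes
#'
#' Z-scores each window's amplitudes over non-missing trials (population
#' standard deviation), then imputes missing values as 0 — the post-z-score
#' mean — so the event count stays constant across windows. With
#' `condition` supplied, trials are split by condition and each subset is
#' z-scored separately (the condition-split decision-variable regressors).
#'
#' @param amplitudes trials x windows matrix from [extract_windows()].
#' @param condition optional vector of 0/1 condition codes per trial.
#' @return A matrix of the same shape (or, with `condition`, a list with
#'   one matrix per condition holding that condition's rows and `NA`
#'   elsewhere replaced by 0 after split z-scoring).
#' @export
zscore_amplitudes <- function(amplitudes, condition = NULL) {
  zs_one <- function(mat) {
    out <- mat
    for (k in seq_len(ncol(mat))) {
      x <- mat[, k]
      ok <- !is.na(x)
      if (sum(ok) == 0L) {
        warning("window ", colnames(mat)[k],
                " has no covered trials; regressor set to all zeros")
        out[, k] <- 0
        next
      }
      if (sum(ok) < 3L)
        stop("window ", colnames(mat)[k], " has fewer than 3 covered trials")
      mu <- mean(x[ok])
      sdp <- sqrt(mean((x[ok] - mu)^2))
      if (sdp == 0) stop("window ", colnames(mat)[k], " has zero variance")
      out[ok, k] <- (x[ok] - mu) / sdp
      out[!ok, k] <- 0
    }
    out
  }
  if (is.null(condition)) return(zs_one(amplitudes))
  stopifnot(length(condition) == nrow(amplitudes))
  lapply(stats::setNames(c(0, 1), c("c0", "c1")), function(cc) {
    out <- matrix(0, nrow(amplitudes), ncol(amplitudes),
                  dimnames = dimnames(amplitudes))
    idx <- condition == cc
    out[idx, ] <- zs_one(amplitudes[idx, , drop = FALSE])
    out
  })
}

#' Export per-trial window amplitudes as CSV
#'
#' @param amplitudes matrix from [extract_windows()].
#' @param trials the matching trial data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dv_amplitudes <- function(amplitudes, trials, path) {
  tr <- as_trial_df(trials)
  centers <- attr(amplitudes, "centers")
  long <- do.call(rbind, lapply(seq_len(ncol(amplitudes)), function(k)
    data.frame(trial_id = seq_len(nrow(tr)), condition = tr$condition,
               rt = tr$rt, correct = tr$correct,
               window_center = centers[k], amplitude = amplitudes[, k])))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
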