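#' Cohort specification for the synthetic Simon-task study
#'
#' Defaults mirror the structure of the two-session Simon-task study the
#' package is designed around: 21 subjects, 2 sessions each, every session
#' holding 48 congruent, 48 incongruent and 24 null trials of 2.5 s on a
#' regular onset grid (TR 2 s, 151 volumes per session). Subject-level
#' parameters are drawn from the same distributions used to initialize
#' model fitting.
#'
#' @param n_subjects number of subjects.
#' @param sessions_per_subject sessions per subject.
#' @param n_congruent,n_incongruent,n_null trial counts per session.
#' @param trial_duration trial slot length (s).
#' @param tr repetition time (s).
#' @param n_volumes volumes per session.
#' @param seed integer seed for the whole cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 21, sessions_per_subject = 2,
                        n_congruent = 48, n_incongruent = 48, n_null = 24,
                        trial_duration = 2.5, tr = 2.0, n_volumes = 151,
                        seed = 1L) {
  stopifnot(n_subjects >= 1, sessions_per_subject >= 1, n_congruent > 0,
            n_incongruent > 0, n_null >= 0, trial_duration > 0)
  structure(list(n_subjects = n_subjects,
                 sessions_per_subject = sessions_per_subject,
                 n_congruent = n_congruent, n_incongruent = n_incongruent,
                 n_null = n_null, trial_duration = trial_duration,
                 tr = tr, n_volumes = n_volumes, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic behavioral cohort
#'
#' Draws one SE-SSM parameter set per subject (from the fitting
#' initialization distributions, full M4 model) and simulates every
#' session's trials. Trial order is randomized per session with null trials
#' at uniformly random positions; onsets sit on the 2.5 s trial grid.
#' Reproducible: the same spec (including seed) yields identical cohorts.
#'
#' @param spec a [cohort_spec].
#' @return A list of class `synthetic_cohort`: per subject `params`, a
#'   `behavioral_dataset`, and `events` (BIDS-style events data frame with
#'   columns onset, duration, trial_type, response_time, correct,
#'   session_id).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  subjects <- lapply(seq_len(spec$n_subjects), function(si) {
    params <- sample_initial_params(model_spec("M4"))
    events <- list()
    trials <- list()
    for (ss in seq_len(spec$sessions_per_subject)) {
      tt <- c(rep("congruent", spec$n_congruent),
              rep("incongruent", spec$n_incongruent),
              rep("null", spec$n_null))
      tt <- sample(tt)
      onsets <- (seq_along(tt) - 1L) * spec$trial_duration
      sim0 <- simulate_trials(params, 0L, spec$n_congruent)
      sim1 <- simulate_trials(params, 1L, spec$n_incongruent)
      rt <- correct <- rep(NA, length(tt))
      rt[tt == "congruent"] <- sim0$rt
      correct[tt == "congruent"] <- sim0$correct
      rt[tt == "incongruent"] <- sim1$rt
      correct[tt == "incongruent"] <- sim1$correct
      events[[ss]] <- data.frame(
        onset = onsets, duration = 1, trial_type = tt,
        response_time = rt, correct = as.integer(correct),
        session_id = ss)
      resp <- tt != "null"
      trials[[ss]] <- data.frame(
        condition = as.integer(tt[resp] == "incongruent"),
        rt = rt[resp], correct = as.logical(correct[resp]),
        session_id = ss)
    }
    list(params = params,
         dataset = behavioral_dataset(do.call(rbind, trials),
                                      subject_id = sprintf("sub-%02d", si)),
         events = do.call(rbind, events))
  })
  names(subjects) <- sprintf("sub-%02d", seq_len(spec$n_subjects))
  structure(list(subjects = subjects, spec = spec),
            class = "synthetic_cohort")
}

#' Write cohort events as BIDS-style TSV files
#'
#' One `events.tsv` per subject and session with columns onset, duration,
#' trial_type, response_time, correct. Null trials carry `n/a` in the
#' response columns.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
write_cohort_events <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (id in names(cohort$subjects)) {
    ev <- cohort$subjects[[id]]$events
    for (ss in unique(ev$session_id)) {
      path <- file.path(dir, sprintf("%s_ses-%02d_events.tsv", id, ss))
      write_events(ev[ev$session_id == ss,
                      c("onset", "duration", "trial_type",
                        "response_time", "correct")], path)
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

#' Generate synthetic group maps with a planted covariate-linked region
#'
#' Voxels in `region` get `beta = slope * covariate + N(0, noise_sd)`
#' across subjects; all other voxels are pure `N(0, noise_sd)` noise.
#'
#' @param dim 3D grid dimensions.
#' @param covariate numeric vector (one value per subject).
#' @param region integer voxel indices (into the flattened grid) of the
#'   planted region; may be empty.
#' @param slope linear effect size (0 gives a global null).
#' @param noise_sd noise standard deviation, > 0.
#' @param seed optional integer seed.
#' @return A list of per-subject 3D arrays (pass to [group_maps()]).
#' @export
generate_group_maps <- function(dim = c(10, 10, 10), covariate,
                                region = integer(0), slope = 0,
                                noise_sd = 1, seed = NULL) {
  stopifnot(noise_sd > 0, all(region >= 1), all(region <= prod(dim)))
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_along(covariate), function(si) {
    m <- array(stats::rnorm(prod(dim), 0, noise_sd), dim)
    m[region] <- m[region] + slope * covariate[si]
    m
  })
}

#' Cubic region of voxel indices
#'
#' Convenience for planting effects: the flattened indices of an axis-
#' aligned cube `start + 0:(size-1)` in each dimension.
#'
#' @param dim 3D grid dimensions.
#' @param start 3-vector of 1-based corner coordinates.
#' @param size cube edge length.
#' @return Integer vector of flattened voxel indices.
#' @export
cube_region <- function(dim, start = c(4, 4, 4), size = 3) {
  idx <- expand.grid(x = start[1] + 0:(size - 1),
                     y = start[2] + 0:(size - 1),
                     z = start[3] + 0:(size - 1))
  as.integer(idx$x + dim[1] * (idx$y - 1) + dim[1] * dim[2] * (idx$z - 1))
}

#' Generate a synthetic 4D BOLD series with planted regressors
#'
#' Each voxel's time course is `baseline + X_signal beta + N(0, noise_sd)`,
#' where `X_signal` holds the HRF-convolved planted regressors (built with
#' [build_design()] conventions from the supplied event regressors).
#'
#' @param events named list of [event_regressor] objects to plant.
#' @param betas matrix voxels x regressors of planted effect sizes (0 for
#'   null voxels).
#' @param n_volumes,tr scan geometry.
#' @param noise_sd white-noise standard deviation (>= 0; 0 gives a
#'   noise-free series for exact-recovery checks).
#' @param baseline constant baseline level.
#' @param seed optional integer seed.
#' @return A list: `data` (matrix n_volumes x voxels), `design_signal`
#'   (the noiseless planted regressor matrix).
#' @export
generate_bold <- function(events, betas, n_volumes = 151, tr = 2.0,
                          noise_sd = 1, baseline = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- build_design(events, n_volumes = n_volumes, tr = tr,
                    hp_cutoff = NULL)
  Xs <- X[, attr(X, "event_cols"), drop = FALSE]
  betas <- as.matrix(betas)
  stopifnot(ncol(betas) == ncol(Xs))
  signal <- Xs %*% t(betas)
  noise <- if (noise_sd > 0)
    matrix(stats::rnorm(length(signal), 0, noise_sd), nrow(signal))
  else 0
  list(data = baseline + signal + noise, design_signal = Xs)
}
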