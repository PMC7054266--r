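#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peak delay 6 s, undershoot
#' delay 16 s, unit dispersions, undershoot ratio 1/6), peak-normalized to
#' 1. This is the canonical kernel used to convolve event regressors.
#'
#' @param time non-negative time grid (s), step <= 0.1 s.
#' @return Numeric kernel values on `time`.
#' @export
double_gamma_hrf <- function(time) {
  if (length(time) > 1 && max(diff(time)) > 0.1 + 1e-9)
    stop("HRF must be evaluated on a grid with step <= 0.1 s")
  h <- stats::dgamma(time, shape = 6, rate = 1) -
    stats::dgamma(time, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Event regressor
#'
#' @param onsets event onsets (s, scan time; volume 0 acquired at t = 0).
#' @param durations event durations (s), recycled; stimulus events default
#'   to 1 s step functions.
#' @param amplitudes unitless modulations, recycled (default 1).
#' @return An object of class `event_regressor`.
#' @export
event_regressor <- function(onsets, durations = 1, amplitudes = 1) {
  n <- length(onsets)
  durations <- rep_len(durations, n)
  amplitudes <- rep_len(amplitudes, n)
  if (any(durations <= 0)) stop("durations must be > 0")
  if (any(onsets < 0)) stop("onsets must be >= 0")
  structure(list(onsets = onsets, durations = durations,
                 amplitudes = amplitudes), class = "event_regressor")
}

# Discrete-cosine drift basis up to a cutoff period (high-pass filtering as
# design columns rather than pre-filtering the data).
dct_drift_basis <- function(n_volumes, tr, cutoff = 100) {
  T_total <- n_volumes * tr
  K <- floor(2 * T_total / cutoff)
  if (K < 1) return(NULL)
  v <- seq_len(n_volumes) - 1L
  basis <- vapply(seq_len(K), function(k)
    cos(pi * k * (2 * v + 1) / (2 * n_volumes)), numeric(n_volumes))
  colnames(basis) <- paste0("drift", seq_len(K))
  basis
}

#' Build a first-level GLM design matrix
#'
#' Each event regressor is rendered as an amplitude-scaled boxcar at 0.1 s
#' microtime resolution, convolved with the canonical double-gamma HRF, and
#' sampled at the volume acquisition times (volume `i` at `i*TR`). An
#' intercept, discrete-cosine drift columns implementing the high-pass
#' cutoff, and any confound columns are appended unconvolved.
#'
#' The three standard designs are expressible directly: the simple GLM
#' (all-stimulus events + incongruent-only events), the RT GLM
#' (all-stimulus events + events with log-transformed, z-scored RT
#' amplitudes; see [log_rt_amplitudes()]), and the DV-GLM (correct-trial
#' stimulus events + 100 ms decision-variable events; see
#' [dv_event_regressor()]).
#'
#' @param events named list of [event_regressor] objects.
#' @param n_volumes number of volumes.
#' @param tr repetition time (s).
#' @param confounds optional numeric matrix/data frame of confound columns
#'   (never convolved).
#' @param hp_cutoff high-pass cutoff period (s); `NULL` disables drift
#'   columns.
#' @param microtime microtime resolution (s) for boxcar rendering.
#' @return A design matrix (`n_volumes` rows) with named columns; event
#'   columns first, then `(Intercept)`, drift and confound columns.
#'   Attribute `event_cols` names the convolved columns.
#' @export
build_design <- function(events, n_volumes, tr = 2.0, confounds = NULL,
                         hp_cutoff = 100, microtime = 0.1) {
  stopifnot(is.list(events), length(events) > 0)
  if (is.null(names(events)) || any(names(events) == ""))
    stop("events must be a named list")
  scan_end <- n_volumes * tr
  tgrid <- seq(0, scan_end, by = microtime)
  hrf <- double_gamma_hrf(seq(0, 32, by = microtime))
  cols <- vapply(events, function(ev) {
    stopifnot(inherits(ev, "event_regressor"))
    if (any(ev$onsets + ev$durations > scan_end + 1e-9))
      stop("event extends beyond the end of the scan (",
           scan_end, " s)")
    box <- numeric(length(tgrid))
    for (i in seq_along(ev$onsets)) {
      idx <- which(tgrid >= ev$onsets[i] - 1e-9 &
                     tgrid < ev$onsets[i] + ev$durations[i] - 1e-9)
      box[idx] <- box[idx] + ev$amplitudes[i]
    }
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(tgrid)] *
      microtime
    stats::approx(tgrid, conv, xout = (seq_len(n_volumes) - 1L) * tr,
                  rule = 2)$y
  }, numeric(n_volumes))
  colnames(cols) <- names(events)
  X <- cbind(cols, `(Intercept)` = 1)
  if (!is.null(hp_cutoff)) {
    drift <- dct_drift_basis(n_volumes, tr, hp_cutoff)
    if (!is.null(drift)) X <- cbind(X, drift)
  }
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (is.null(colnames(confounds)))
      colnames(confounds) <- paste0("confound", seq_len(ncol(confounds)))
    X <- cbind(X, confounds)
  }
  zero <- colnames(cols)[apply(cols, 2, function(x) all(x == 0))]
  if (length(zero))
    stop("all-zero event regressor column(s): ", paste(zero, collapse = ", "))
  attr(X, "event_cols") <- names(events)
  X
}

#' Log-transformed, z-scored RT amplitudes
#'
#' The RT-GLM's parametric modulator: `z(log(rt))` across the supplied
#' trials (sample standard deviation), mean 0 and sd 1 by construction.
#'
#' @param rt response times (s), > 0.
#' @return Numeric amplitude vector.
#' @export
log_rt_amplitudes <- function(rt) {
  stopifnot(all(rt > 0))
  x <- log(rt)
  (x - mean(x)) / stats::sd(x)
}

#' Decision-variable event regressor for the DV-GLM
#'
#' Each correct trial contributes one 100 ms event centered on the
#' extraction time of its decision-variable window: the window center is
#' measured backwards from the response, so the event onset is
#' `onset + rt + window_center - duration/2`.
#'
#' @param onsets stimulus onsets (s).
#' @param rt response times (s).
#' @param amplitudes z-scored window amplitudes (one per trial).
#' @param window_center window center relative to the response (s,
#'   negative, e.g. -0.025).
#' @param duration event duration (s), 100 ms by default.
#' @return An [event_regressor].
#' @export
dv_event_regressor <- function(onsets, rt, amplitudes, window_center,
                               duration = 0.1) {
  stopifnot(length(onsets) == length(rt), length(rt) == length(amplitudes))
  event_regressor(onsets = onsets + rt + window_center - duration / 2,
                  durations = duration, amplitudes = amplitudes)
}

#' Ordinary-least-squares GLM fit with contrasts
#'
#' Fits `Y = X beta + e` by OLS for each data series and evaluates the
#' requested contrasts: `t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)` with
#' `sigma2` the residual variance at `n - rank(X)` degrees of freedom, and
#' `z` the standard-normal quantile matching the t tail probability.
#'
#' @param data numeric vector or matrix (`n_volumes` x series).
#' @param design design matrix from [build_design()].
#' @param contrasts named list of numeric contrast weight vectors; short
#'   vectors are zero-padded on the right (weights over the leading,
#'   event, columns).
#' @return An object of class `glm_result`: `betas` (columns x series),
#'   `sigma2`, `dof`, and per contrast `estimate`, `se`, `t`, `z`
#'   (matrices contrast x series).
#' @export
fit_glm <- function(data, design, contrasts = list()) {
  Y <- as.matrix(data)
  X <- as.matrix(design)
  if (nrow(Y) != nrow(X)) stop("data and design have different row counts")
  if (any(!is.finite(Y))) stop("data contains non-finite values")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  betas <- qr.coef(qrx, Y)
  res <- Y - X %*% betas
  dof <- nrow(X) - qrx$rank
  if (dof <= 0) stop("no residual degrees of freedom")
  sigma2 <- colSums(res^2) / dof
  xtx_inv <- chol2inv(qr.R(qrx))[order(qrx$pivot), order(qrx$pivot)]
  con <- lapply(contrasts, function(w) {
    cw <- numeric(ncol(X))
    cw[seq_along(w)] <- w
    est <- drop(crossprod(cw, betas))
    se <- sqrt(sigma2 * drop(crossprod(cw, xtx_inv %*% cw)))
    tval <- est / se
    zval <- t_to_z(tval, dof)
    list(estimate = est, se = se, t = tval, z = zval)
  })
  structure(list(betas = betas, sigma2 = sigma2, dof = dof,
                 contrasts = con, design_cols = colnames(X)),
            class = "glm_result")
}

# Convert t statistics to z scores through matched tail probabilities,
# using log tail probabilities so large statistics stay finite.
t_to_z <- function(tval, dof) {
  sign(tval) * stats::qnorm(stats::pt(abs(tval), dof, lower.tail = FALSE,
                                      log.p = TRUE),
                            lower.tail = FALSE, log.p = TRUE)
}

#' Combine GLM estimates across sessions and subjects
#'
#' Session (second) level: fixed-effects combination of per-session betas,
#' weighted by inverse variance. Subject (third) level: a one-sample
#' t-test across subjects per voxel, returned as t and z maps, with
#' suprathreshold clusters (`|z| > z_thresh`, 26-connectivity) extracted
#' for reporting.
#'
#' @param session_estimates list (sessions) of lists with `estimate` and
#'   `var` numeric vectors (aligned voxels), or a single such list.
#' @return `combine_sessions`: list with `estimate` and `var` (fixed
#'   effects).
#' @export
combine_sessions <- function(session_estimates) {
  if (!is.null(session_estimates$estimate))
    session_estimates <- list(session_estimates)
  if (length(session_estimates) == 1L)
    return(session_estimates[[1]])
  w <- lapply(session_estimates, function(s) 1 / s$var)
  wsum <- Reduce(`+`, w)
  est <- Reduce(`+`, Map(function(s, wi) s$estimate * wi,
                         session_estimates, w)) / wsum
  list(estimate = est, var = 1 / wsum)
}

#' @rdname combine_sessions
#' @param subject_estimates matrix subjects x voxels of combined
#'   session-level estimates.
#' @param dim 3D array dimensions of the voxel grid (for cluster
#'   extraction); `NULL` skips clustering.
#' @param z_thresh cluster-forming threshold on |z|.
#' @param connectivity 6 or 26.
#' @return `group_onesample`: list with `t`, `z`, `dof`, and `clusters` (a
#'   data frame: label, size, sign, peak_z) when `dim` is given.
#' @export
group_onesample <- function(subject_estimates, dim = NULL, z_thresh = 2.5,
                            connectivity = 26) {
  M <- as.matrix(subject_estimates)
  n <- nrow(M)
  if (n < 2) stop("need >= 2 subjects")
  mu <- colMeans(M)
  se <- apply(M, 2, stats::sd) / sqrt(n)
  tval <- mu / se
  zval <- t_to_z(tval, n - 1)
  clusters <- NULL
  labels <- NULL
  if (!is.null(dim)) {
    stopifnot(prod(dim) == length(zval))
    labels <- array(0L, dim)
    rows <- list()
    nxt <- 0L
    for (sgn in c(1, -1)) {
      mask <- array(sgn * zval > z_thresh, dim)
      lab <- .label_components_cpp(as.logical(mask), as.integer(dim),
                                  as.integer(connectivity))
      ncomp <- attr(lab, "n_components")
      if (is.null(ncomp) || ncomp == 0L) next
      for (k in seq_len(ncomp)) {
        idx <- which(lab == k)
        nxt <- nxt + 1L
        labels[idx] <- nxt
        rows[[nxt]] <- data.frame(label = nxt, size = length(idx),
                                  sign = sgn,
                                  peak_z = sgn * max(sgn * zval[idx]))
      }
    }
    clusters <- if (length(rows)) do.call(rbind, rows) else
      data.frame(label = integer(), size = integer(), sign = integer(),
                 peak_z = numeric())
  }
  list(t = tval, z = zval, dof = n - 1, clusters = clusters,
       cluster_labels = labels)
}
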