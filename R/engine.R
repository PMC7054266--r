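#' First-passage engine configuration
#'
#' Controls the discretization used by the transition-matrix first-passage
#' engine: the decision-variable grid resolution `dx` (0.01 for the coarse
#' fitting pass, 0.005 for the refinement pass), the time step `dt`, the
#' decision-time horizon `t_max`, the grid extension beyond the bounds in
#' multiples of `s*sqrt(dt)`, and the density floor used when evaluating
#' log-likelihoods.
#'
#' @param dx decision-variable grid spacing (evidence units).
#' @param dt time step (s).
#' @param t_max maximum decision-time horizon (s).
#' @param boundary_pad grid extension beyond `+/- x_th` in multiples of
#'   `s*sqrt(dt)`; at least 5 so a single Gaussian step practically never
#'   leaves the grid.
#' @param density_floor minimum defective density substituted in the
#'   log-likelihood so outlier response times cannot produce `-Inf`.
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(dx = 0.01, dt = 0.001, t_max = 5,
                          boundary_pad = 5, density_floor = 1e-10) {
  stopifnot(dx > 0, dt > 0, t_max > 0, density_floor > 0)
  if (boundary_pad < 5)
    stop("boundary_pad must be >= 5 (single-step Gaussian containment)")
  structure(list(dx = dx, dt = dt, t_max = t_max,
                 boundary_pad = boundary_pad,
                 density_floor = density_floor),
            class = "engine_config")
}

#' Decision-variable grid of the transition-matrix engine
#'
#' A uniform grid with spacing `dx` spanning
#' `+/- (x_th + boundary_pad * s * sqrt(dt))`. Grid states at or beyond the
#' bounds (`|x| >= x_th`) are absorbing: their transition-matrix columns are
#' zero except for a unit diagonal. The initial distribution places all mass
#' on the grid point nearest the starting point `x_b * (1 - 2c)`.
#'
#' @param params an [se_params] object.
#' @param config an [engine_config] object.
#' @return A list with `x` (grid points), `absorbing` (logical), and the
#'   index `i0_nonconflict`/`i0_conflict` of the initial-mass grid point per
#'   condition.
#' @export
build_grid <- function(params, config) {
  validate_se_params(params)
  K <- ceiling((params$x_th + config$boundary_pad * params$s *
                  sqrt(config$dt)) / config$dx - 1e-9)
  K_th <- ceiling(params$x_th / config$dx - 1e-9)
  if (K_th < 2)
    stop("degenerate grid: dx (", config$dx,
         ") too coarse to host interior states for x_th (", params$x_th, ")")
  x <- seq.int(-K, K) * config$dx
  i0 <- function(c) {
    g <- round(params$x_b * (1 - 2 * c) / config$dx)
    if (abs(g) >= K_th)
      stop("starting bias x_b falls outside the grid interior")
    g + K + 1L
  }
  list(x = x, absorbing = abs(x) >= params$x_th - 1e-12,
       i0_nonconflict = i0(0), i0_conflict = i0(1), K = K, K_th = K_th)
}

#' Defective first-passage densities by transition-matrix propagation
#'
#' Propagates the discretized decision-variable distribution through
#' one-step Gaussian transition kernels with absorbing decision bounds.
#' Each step applies a kernel with mean shift `v*(1 + c*b*d)*dt` (constant
#' on non-conflict trials, time-varying under conflict because of the `b*d`
#' gain) and standard deviation `s*sqrt(dt)`, renormalized over the grid.
#' Mass landing at or beyond `+x_th` / `-x_th` accumulates into the
#' defective CDFs of correct and error responses; the defective densities
#' are obtained by numerically differentiating the cumulative absorbed
#' mass.
#'
#' @param params an [se_params] object.
#' @param c conflict indicator, 0 or 1.
#' @param config an [engine_config] object.
#' @return An object of class `fp_density`: list with `time` (decision-time
#'   grid), `pdf_correct`, `pdf_error`, `cdf_correct`, `cdf_error`,
#'   `condition`, and the config used.
#' @export
fp_propagate <- function(params, c, config = engine_config()) {
  validate_se_params(params)
  c <- as_conflict(c)
  res <- .fp_propagate_cpp(params$v, params$b, c, params$x_th, params$x_b,
                           params$s, config$dx, config$dt, config$t_max,
                           config$boundary_pad, 1e-9)
  if (any(!is.finite(res$cdf_up)) || any(!is.finite(res$cdf_lo)))
    stop("non-finite mass encountered during propagation")
  if (res$interior_mass > 1e-3)
    warning(sprintf(
      "first-passage mass leakage %.2e at t_max = %g s; increase t_max",
      res$interior_mass, config$t_max))
  time <- seq_len(res$n_steps) * config$dt
  structure(list(
    time = time,
    steps_used = res$steps_used,
    pdf_correct = diff(c(0, res$cdf_up)) / config$dt,
    pdf_error = diff(c(0, res$cdf_lo)) / config$dt,
    cdf_correct = res$cdf_up,
    cdf_error = res$cdf_lo,
    condition = c,
    config = config,
    params = params
  ), class = "fp_density")
}

#' @export
as.data.frame.fp_density <- function(x, ...) {
  data.frame(time = x$time, pdf_correct = x$pdf_correct,
             pdf_error = x$pdf_error, cdf_correct = x$cdf_correct,
             cdf_error = x$cdf_error)
}

#' Export a first-passage density as tidy CSV
#'
#' @param fpd an `fp_density` object from [fp_propagate()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fp_density <- function(fpd, path) {
  stopifnot(inherits(fpd, "fp_density"))
  utils::write.csv(as.data.frame(fpd), path, row.names = FALSE)
  invisible(path)
}

# Discretized uniform kernel of total width s_t on a dt grid: cell j covers
# [j*dt - dt/2, j*dt + dt/2]; its weight is the overlap with
# [-s_t/2, s_t/2] divided by s_t. Exact box integration keeps total mass 1.
uniform_kernel <- function(s_t, dt) {
  if (s_t <= 0) return(list(w = 1, j = 0L))
  m <- ceiling((s_t / 2 + dt / 2) / dt)
  j <- seq.int(-m, m)
  lo <- pmax(j * dt - dt / 2, -s_t / 2)
  hi <- pmin(j * dt + dt / 2, s_t / 2)
  w <- pmax(hi - lo, 0) / s_t
  keep <- w > 0
  list(w = w[keep], j = j[keep])
}

#' Map first-passage densities to the observed response-time domain
#'
#' Shifts the defective decision-time densities by the base non-decision
#' time `t` and convolves them with the uniform non-decision-time jitter
#' kernel of width `s_t`. Total defective mass is preserved.
#'
#' @param fpd an `fp_density` object.
#' @param params an [se_params] object (supplies `t` and `s_t`).
#' @return An object of class `rt_density`: list with `rt` (observed
#'   response-time grid), `pdf_correct`, `pdf_error`, `cdf_correct`,
#'   `cdf_error`, `condition`.
#' @export
apply_nondecision <- function(fpd, params = fpd$params) {
  stopifnot(inherits(fpd, "fp_density"))
  validate_se_params(params)
  dt <- fpd$config$dt
  n_used <- min(fpd$steps_used %||% length(fpd$time), length(fpd$time))
  ker <- uniform_kernel(params$s_t, dt)
  conv1 <- function(p) {
    p <- p[seq_len(n_used)]
    if (length(ker$w) == 1L) return(p)
    .conv_open_cpp(p, ker$w)
  }
  pdf_c <- conv1(fpd$pdf_correct)
  pdf_e <- conv1(fpd$pdf_error)
  rt0 <- fpd$time[1] + params$t + ker$j[1] * dt
  rt <- rt0 + (seq_along(pdf_c) - 1L) * dt
  structure(list(rt = rt, pdf_correct = pdf_c, pdf_error = pdf_e,
                 cdf_correct = cumsum(pdf_c) * dt,
                 cdf_error = cumsum(pdf_e) * dt,
                 condition = fpd$condition, dt = dt),
            class = "rt_density")
}

# Interpolate a defective RT-domain density at observed RTs (0 outside the
# grid support).
interp_density <- function(rtd, rts, correct) {
  pdf <- if (correct) rtd$pdf_correct else rtd$pdf_error
  stats::approx(rtd$rt, pdf, xout = rts, rule = 1)$y
}

#' Negative log-likelihood of a behavioral dataset under the SE-SSM
#'
#' Computes one pair of defective RT densities per condition present in the
#' data (both conditions share the propagation) and sums
#' `-log(max(density_floor, f(rt)))` over trials, interpolating each trial's
#' response time linearly on the RT grid. Trials whose RT falls outside the
#' representable support contribute the density floor with a warning.
#'
#' @param dataset a `behavioral_dataset` (see [behavioral_dataset()]) or a
#'   data frame with columns `condition` (0/1), `rt` (s), `correct`
#'   (logical).
#' @param params an [se_params] object.
#' @param config an [engine_config] object.
#' @return The negative log-likelihood in nats (single finite number).
#' @export
trial_loglik <- function(dataset, params, config = engine_config()) {
  trials <- as_trial_df(dataset)
  if (nrow(trials) == 0L) stop("dataset contains no trials")
  validate_se_params(params)
  nll <- 0
  n_out <- 0L
  for (cc in sort(unique(trials$condition))) {
    rtd <- apply_nondecision(fp_propagate(params, cc, config), params)
    for (corr in c(TRUE, FALSE)) {
      idx <- trials$condition == cc & trials$correct == corr
      if (!any(idx)) next
      dens <- interp_density(rtd, trials$rt[idx], corr)
      bad <- is.na(dens)
      n_out <- n_out + sum(bad)
      dens[bad] <- 0
      nll <- nll - sum(log(pmax(dens, config$density_floor)))
    }
  }
  if (n_out > 0L)
    warning(n_out, " trial(s) with RT outside the representable support ",
            "contributed the density floor")
  as.numeric(nll)
}
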