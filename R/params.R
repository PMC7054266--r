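#' SE-SSM parameter set
#'
#' Constructs and validates the full parameterization of the Simon-effect
#' sequential sampling model (SE-SSM): a drift-diffusion accumulator with
#' symmetric decision bounds at `+/- x_th`, a conflict-induced starting-point
#' bias `x_b`, and a conflict-counteraction gain `b` that ramps the drift up
#' linearly within a conflict trial. Choices are accuracy coded: the upper
#' bound `+x_th` is the correct response.
#'
#' The per-step evidence update is
#' `dx = v * (1 + c*b*d) * dt + s * xi1 * sqrt(dt)`, where `c` is the trial's
#' conflict indicator (0/1) and `d` the elapsed decision time in seconds.
#' The starting point is `x0 = x_b * (1 - 2c)`, i.e. toward the correct bound
#' on non-conflict trials and toward the error bound under conflict. Observed
#' response time is decision time plus an effective non-decision time
#' `t_eff = t + xi2 * s_t` with `xi2 ~ U(-1/2, 1/2)`, so `s_t` is the full
#' range of the uniform non-decision-time jitter.
#'
#' @param v drift rate (evidence units/s), > 0.
#' @param x_th decision threshold (evidence units), > 0; bounds at `+/- x_th`.
#' @param t base non-decision time (s), > 0.
#' @param s_t non-decision-time jitter range (s), >= 0 and `t - s_t/2 > 0`.
#' @param b conflict-counteraction gain (1/s), >= 0.
#' @param x_b starting-point bias magnitude (evidence units), in `[0, x_th)`.
#' @param s diffusion noise scale (evidence units/sqrt(s)); fixed at 1 in all
#'   fitting contexts.
#' @return An object of class `se_params` (a named list).
#' @examples
#' p <- se_params(v = 2, x_th = 0.6, t = 0.3, s_t = 0.1, b = 2.5, x_b = 0.1)
#' starting_point(p, c = 1)
#' @export
se_params <- function(v, x_th, t, s_t = 0, b = 0, x_b = 0, s = 1) {
  p <- list(v = as.numeric(v), x_th = as.numeric(x_th), t = as.numeric(t),
            s_t = as.numeric(s_t), b = as.numeric(b), x_b = as.numeric(x_b),
            s = as.numeric(s))
  validate_se_params(p)
  structure(p, class = "se_params")
}

validate_se_params <- function(p) {
  for (nm in c("v", "x_th", "t", "s_t", "b", "x_b", "s")) {
    val <- p[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (p$v <= 0) stop("drift rate v must be > 0")
  if (p$x_th <= 0) stop("threshold x_th must be > 0")
  if (p$t <= 0) stop("non-decision time t must be > 0")
  if (p$s_t < 0) stop("non-decision jitter range s_t must be >= 0")
  if (p$b < 0) stop("conflict-counteraction gain b must be >= 0")
  if (p$x_b < 0) stop("starting bias x_b must be >= 0")
  if (p$s <= 0) stop("noise scale s must be > 0")
  if (p$x_b >= p$x_th)
    stop("starting bias x_b must lie strictly inside the bounds (x_b < x_th)")
  if (p$t - p$s_t / 2 <= 0)
    stop("effective non-decision time can become non-positive (need t - s_t/2 > 0)")
  invisible(p)
}

#' @export
print.se_params <- function(x, ...) {
  cat("SE-SSM parameters\n")
  cat(sprintf("  v = %.4g  x_th = %.4g  t = %.4g  s_t = %.4g\n",
              x$v, x$x_th, x$t, x$s_t))
  cat(sprintf("  b = %.4g  x_b = %.4g  s = %.4g (fixed in fitting)\n",
              x$b, x$x_b, x$s))
  invisible(x)
}

as_conflict <- function(c) {
  if (length(c) != 1L || !(c %in% c(0, 1)))
    stop("conflict indicator c must be exactly 0 (non-conflict) or 1 (conflict)")
  as.integer(c)
}

#' Instantaneous drift of the SE-SSM
#'
#' On conflict trials the effective drift grows linearly with the elapsed
#' decision time `d`, `v * (1 + c*b*d)`; on non-conflict trials it is the
#' constant `v`.
#'
#' @param params an [se_params] object.
#' @param c conflict indicator, 0 or 1.
#' @param d elapsed decision time (s), >= 0; may be a vector.
#' @return Drift in evidence units/s, same length as `d`.
#' @export
instantaneous_drift <- function(params, c, d) {
  validate_se_params(params)
  c <- as_conflict(c)
  if (any(!is.finite(d)) || any(d < 0))
    stop("elapsed decision time d must be finite and >= 0")
  params$v * (1 + c * params$b * d)
}

#' Starting point of the decision variable
#'
#' `x0 = x_b * (1 - 2c)`: the bias points toward the correct bound (`+x_b`)
#' when there is no conflict and toward the error bound (`-x_b`) under
#' conflict.
#'
#' @inheritParams instantaneous_drift
#' @return Initial decision-variable value (evidence units).
#' @export
starting_point <- function(params, c) {
  validate_se_params(params)
  c <- as_conflict(c)
  params$x_b * (1 - 2 * c)
}

#' Draw effective non-decision times
#'
#' `t_eff = t + xi2 * s_t` with `xi2 ~ U(-1/2, 1/2)`, so draws are uniform on
#' `[t - s_t/2, t + s_t/2]` with mean `t`.
#'
#' @param params an [se_params] object.
#' @param n number of draws.
#' @return Numeric vector of `n` effective non-decision times (s).
#' @export
sample_nondecision_time <- function(params, n = 1) {
  validate_se_params(params)
  params$t + (stats::runif(n) - 0.5) * params$s_t
}

#' Read/write SE-SSM parameters as JSON
#'
#' Parameters are serialized as a flat JSON object with keys
#' `v, x_th, t, s_t, b, x_b, s`; a missing `s` defaults to 1 on read.
#'
#' @param params an [se_params] object.
#' @param path file path.
#' @return `read_se_params` returns an [se_params] object;
#'   `write_se_params` returns `path` invisibly.
#' @export
write_se_params <- function(params, path) {
  validate_se_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_se_params
#' @export
read_se_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  s_val <- if (is.null(x[["s"]])) 1 else x[["s"]]
  se_params(v = x[["v"]], x_th = x[["x_th"]], t = x[["t"]],
            s_t = x[["s_t"]], b = x[["b"]], x_b = x[["x_b"]], s = s_val)
}
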