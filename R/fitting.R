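#' Fitting configuration
#'
#' Controls maximum-likelihood estimation: the number of random restarts at
#' the coarse decision-variable resolution, the coarse and refinement grid
#' resolutions, per-parameter box bounds, and the optimizer's stopping
#' tolerance on the negative log-likelihood.
#'
#' Bounds default to wide boxes enclosing the initialization distributions:
#' `v in (0, 20]`, `x_th in (0.05, 5]`, `t in (0.05, 1.5]`,
#' `s_t in [0, min(0.5, 2t - 0.01)]`, `b in [0, 20]`,
#' `x_b in [0, 0.95*x_th]`. The last two upper bounds are joint constraints
#' enforced by projection during the search.
#'
#' @param n_restarts independent random restarts at the coarse resolution.
#' @param coarse_dx,fine_dx decision-variable resolutions of the two fitting
#'   passes.
#' @param nll_tol stopping tolerance (nats): the search stops once a full
#'   poll at the minimum step size fails to improve the NLL by more than
#'   this.
#' @param max_evals cap on NLL evaluations per search.
#' @param t_max decision-time horizon passed to the engine.
#' @param rng_seed integer seed making restarts reproducible.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_restarts = 5, coarse_dx = 0.01, fine_dx = 0.005,
                       nll_tol = 1e-3, max_evals = 600, t_max = 3.5,
                       rng_seed = 1L) {
  stopifnot(n_restarts >= 1, coarse_dx > 0, fine_dx > 0, nll_tol > 0)
  structure(list(n_restarts = as.integer(n_restarts), coarse_dx = coarse_dx,
                 fine_dx = fine_dx, nll_tol = nll_tol,
                 max_evals = as.integer(max_evals), t_max = t_max,
                 rng_seed = as.integer(rng_seed),
                 bounds = list(v = c(1e-3, 20), x_th = c(0.05, 5),
                               t = c(0.05, 1.5), s_t = c(0, 0.5),
                               b = c(0, 20), x_b = c(0, 4.75))),
            class = "fit_config")
}

#' Draw random starting parameters
#'
#' Starting points for the multi-restart search are drawn from
#' `v ~ G(3, 1)`, `x_th ~ G(0.6, 0.15)`, `t ~ G(0.3, 0.075)`,
#' `b ~ HN(2.5)`, `x_b ~ G(0.1, 0.06)`, `s_t ~ U(0, 0.15)`, where `G(m, s)`
#' is the Gamma distribution parameterized by mean and standard deviation
#' (moment matching: shape `(m/s)^2`, scale `s^2/m`), `HN(s)` the
#' half-normal with scale `s`, and `U` uniform. Parameters fixed by the
#' model specification (`b` and/or `x_b`) are forced to zero; `s` is fixed
#' at 1. Draws violating the joint parameter invariants are resampled.
#'
#' @param spec a [model_spec] object.
#' @param seed optional integer seed.
#' @return An [se_params] object.
#' @export
sample_initial_params <- function(spec = model_spec("M4"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rgamma_ms <- function(m, s) stats::rgamma(1, shape = (m / s)^2,
                                            scale = s^2 / m)
  for (i in 1:100) {
    p <- list(v = rgamma_ms(3, 1), x_th = rgamma_ms(0.6, 0.15),
              t = rgamma_ms(0.3, 0.075),
              b = if (spec$free_b) abs(stats::rnorm(1, 0, 2.5)) else 0,
              x_b = if (spec$free_xb) rgamma_ms(0.1, 0.06) else 0,
              s_t = stats::runif(1, 0, 0.15), s = 1)
    ok <- p$x_b < p$x_th && p$t - p$s_t / 2 > 0 && p$v > 0
    if (ok) return(se_params(v = p$v, x_th = p$x_th, t = p$t, s_t = p$s_t,
                             b = p$b, x_b = p$x_b, s = p$s))
  }
  stop("could not draw valid starting parameters")  # nocov
}

# --- bounded generalized pattern search -------------------------------------

free_param_names <- function(spec) {
  c("v", "x_th", "t", "s_t", if (spec$free_b) "b", if (spec$free_xb) "x_b")
}

params_to_vec <- function(params, spec) {
  vapply(free_param_names(spec), function(nm) params[[nm]], 0)
}

vec_to_params <- function(theta, spec) {
  p <- list(v = 0, x_th = 0, t = 0, s_t = 0, b = 0, x_b = 0, s = 1)
  for (nm in names(theta)) p[[nm]] <- unname(theta[[nm]])
  se_params(v = p$v, x_th = p$x_th, t = p$t, s_t = p$s_t, b = p$b,
            x_b = p$x_b, s = 1)
}

# Project a free-parameter vector into the feasible box, including the joint
# constraints s_t <= 2t - 0.01 and x_b <= 0.95 x_th.
project_theta <- function(theta, bounds) {
  for (nm in names(theta))
    theta[nm] <- min(max(theta[[nm]], bounds[[nm]][1]), bounds[[nm]][2])
  theta["s_t"] <- min(theta[["s_t"]], 2 * theta[["t"]] - 0.01)
  theta["s_t"] <- max(theta[["s_t"]], 0)
  if ("x_b" %in% names(theta))
    theta["x_b"] <- min(theta[["x_b"]], 0.95 * theta[["x_th"]])
  theta
}

# Generalized pattern search of the Hooke-Jeeves family: an opportunistic
# coordinate poll (exploratory move) followed by pattern (extrapolation)
# moves that let the search track curved ridges such as the v--x_th valley
# of near-ceiling-accuracy data. Steps halve after a failed poll; the
# search stops once a poll fails at the minimum step size. Deterministic.
# step0_frac scales the initial step sizes (refinement passes start small).
pattern_search <- function(theta0, fn, bounds, nll_tol, max_evals,
                           step0_frac = 1) {
  scale <- c(v = 0.5, x_th = 0.1, t = 0.05, s_t = 0.05, b = 1, x_b = 0.05)
  scale <- scale[names(theta0)]
  step <- scale * step0_frac
  min_step <- scale / 128
  evals <- 0L
  f_of <- function(th) {
    evals <<- evals + 1L
    fn(th)
  }
  explore <- function(th, f0) {
    for (nm in names(th)) {
      for (sgn in c(1, -1)) {
        if (evals >= max_evals) return(list(theta = th, f = f0))
        cand <- th
        cand[nm] <- cand[[nm]] + sgn * step[[nm]]
        cand <- project_theta(cand, bounds)
        if (all(cand == th)) next
        fc <- f_of(cand)
        if (is.finite(fc) && fc < f0 - 1e-12) {
          th <- cand
          f0 <- fc
          break
        }
      }
    }
    list(theta = th, f = f0)
  }
  base <- project_theta(theta0, bounds)
  fb <- f_of(base)
  repeat {
    ex <- explore(base, fb)
    if (ex$f < fb - 1e-12) {
      prev <- base
      base <- ex$theta
      fb <- ex$f
      # pattern moves: extrapolate along the last successful displacement
      # and poll around the extrapolated point
      while (evals < max_evals) {
        pat <- project_theta(base + (base - prev), bounds)
        fp <- if (all(pat == base)) Inf else f_of(pat)
        ex2 <- explore(pat, fp)
        if (is.finite(ex2$f) && ex2$f < fb - 1e-12) {
          prev <- base
          base <- ex2$theta
          fb <- ex2$f
        } else break
      }
    } else {
      if (all(step <= min_step + 1e-15)) break
      step <- pmax(step / 2, min_step)
    }
    if (evals >= max_evals) break
  }
  list(theta = base, nll = fb, evals = evals)
}

#' Maximum-likelihood fit of one subject
#'
#' Runs `n_restarts` independent generalized-pattern-search minimizations
#' of the negative log-likelihood at the coarse decision-variable
#' resolution, each from a fresh draw of [sample_initial_params()], then a
#' single refinement pass from the best coarse solution at the fine
#' resolution. The result is deterministic given `fit_config$rng_seed`.
#'
#' @param dataset a `behavioral_dataset` (or trial data frame) containing
#'   both conditions.
#' @param spec a [model_spec] object.
#' @param config a [fit_config] object.
#' @param extra_starts optional list of [se_params] used as additional
#'   starting points of the refinement pass (e.g. optima of nested models,
#'   which is how [compare_subject()] guarantees the nesting inequalities).
#' @return An object of class `fit_result`: `params` (the ML estimate),
#'   `nll` (at the fine resolution), `n_free`, `spec`, `restart_nlls`,
#'   `converged`.
#' @export
fit_subject <- function(dataset, spec = model_spec("M4"),
                        config = fit_config(), extra_starts = NULL) {
  trials <- as_trial_df(dataset)
  if (length(unique(trials$condition)) < 2L)
    stop("fitting requires at least one trial of each condition")
  set.seed(config$rng_seed)
  bounds <- config$bounds
  # single-slot propagation cache per condition: the non-conflict density
  # depends only on (v, x_th, x_b, dx), the conflict density also on b, so
  # polls over t/s_t (and, for c = 0, over b) reuse the propagated mass
  cache <- new.env(parent = emptyenv())
  nll_at <- function(theta, dx) {
    p <- tryCatch(vec_to_params(theta, spec), error = function(e) NULL)
    if (is.null(p)) return(Inf)
    cfg <- engine_config(dx = dx, t_max = config$t_max)
    nll <- 0
    for (cc in conds) {
      key <- paste(p$v, p$x_th, p$x_b, if (cc == 1) p$b, dx)
      slot <- paste0("c", cc)
      if (!identical(cache[[paste0(slot, "_key")]], key)) {
        # candidate parameters explored by the search may leak mass at the
        # horizon; the density floor accounts for it, so keep the search quiet
        cache[[slot]] <- suppressWarnings(fp_propagate(p, cc, cfg))
        cache[[paste0(slot, "_key")]] <- key
      }
      rtd <- apply_nondecision(cache[[slot]], p)
      for (corr in c(TRUE, FALSE)) {
        idx <- trials$condition == cc & trials$correct == corr
        if (!any(idx)) next
        dens <- interp_density(rtd, trials$rt[idx], corr)
        dens[is.na(dens)] <- 0
        nll <- nll - sum(log(pmax(dens, cfg$density_floor)))
      }
    }
    nll
  }
  conds <- sort(unique(trials$condition))
  starts <- lapply(seq_len(config$n_restarts),
                   function(i) sample_initial_params(spec))
  coarse <- lapply(starts, function(p0) {
    pattern_search(params_to_vec(p0, spec),
                   function(th) nll_at(th, config$coarse_dx),
                   bounds, config$nll_tol, config$max_evals)
  })
  restart_nlls <- vapply(coarse, `[[`, 0, "nll")
  if (all(!is.finite(restart_nlls)))
    stop("all restarts failed to produce a finite likelihood; check the data")
  best <- coarse[[which.min(restart_nlls)]]
  # the refinement pass starts from the best coarse solution and from any
  # warm starts (nested-model optima), so nesting inequalities hold at the
  # reported resolution
  fine_starts <- c(list(best$theta),
                   lapply(extra_starts, params_to_vec, spec = spec))
  fine_runs <- lapply(fine_starts, function(th0)
    pattern_search(th0, function(th) nll_at(th, config$fine_dx),
                   bounds, config$nll_tol,
                   min(config$max_evals, 250L),
                   step0_frac = 1 / 8))
  fine <- fine_runs[[which.min(vapply(fine_runs, `[[`, 0, "nll"))]]
  structure(list(params = vec_to_params(fine$theta, spec), nll = fine$nll,
                 n_free = spec$n_free, spec = spec,
                 restart_nlls = restart_nlls,
                 converged = fine$evals < config$max_evals),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("SE-SSM fit (%s): NLL = %.3f, %d free parameters%s\n",
              x$spec$name, x$nll, x$n_free,
              if (x$converged) "" else " [eval cap reached]"))
  print(x$params)
  invisible(x)
}

#' Write a fit result to JSON
#'
#' @param fit a `fit_result` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  jsonlite::write_json(list(model = fit$spec$name,
                            params = unclass(fit$params), nll = fit$nll,
                            n_free = fit$n_free,
                            restart_nlls = fit$restart_nlls,
                            converged = fit$converged),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
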