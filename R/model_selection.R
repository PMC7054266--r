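#' Candidate model family M1-M4
#'
#' The nested candidate set used for model comparison: M1 is the basic
#' sequential sampling model (conflict parameters fixed at zero, 4 free
#' parameters: `v`, `x_th`, `t`, `s_t`); M2 frees the conflict-counteraction
#' gain `b` (5); M3 frees the starting bias `x_b` (5); M4, the full SE-SSM,
#' frees both (6). The diffusion scale `s` is fixed at 1 throughout.
#'
#' @param name one of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @return An object of class `model_spec` with fields `name`, `free_b`,
#'   `free_xb`, `n_free`.
#' @export
model_spec <- function(name = c("M1", "M2", "M3", "M4")) {
  name <- match.arg(name)
  free_b <- name %in% c("M2", "M4")
  free_xb <- name %in% c("M3", "M4")
  structure(list(name = name, free_b = free_b, free_xb = free_xb,
                 n_free = 4L + free_b + free_xb),
            class = "model_spec")
}

#' Akaike information criterion from a negative log-likelihood
#'
#' `AIC = 2*n_free + 2*nll`.
#'
#' @param nll negative log-likelihood (nats), finite.
#' @param n_free number of free parameters.
#' @return The AIC value.
#' @export
aic <- function(nll, n_free) {
  if (!is.numeric(nll) || any(!is.finite(nll)))
    stop("nll must be finite")
  2 * n_free + 2 * nll
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)` with
#' `Delta_i = AIC_i - min(AIC)`; the weight of a model is read as the
#' probability of it being the best model in the candidate set. The
#' subtraction of the minimum makes the computation stable for large AIC
#' differences.
#'
#' @param aics numeric vector of AIC values (>= 2 candidates), optionally
#'   named.
#' @return Numeric vector of weights summing to 1.
#' @export
waic <- function(aics) {
  if (length(aics) < 2L || any(!is.finite(aics)))
    stop("need >= 2 finite AIC values")
  d <- aics - min(aics)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fit and compare the M1-M4 family on one subject
#'
#' Fits all four candidate models to the same dataset and returns their
#' AICs and Akaike weights. Searches are warm-start chained along the
#' nesting structure (M2 and M3 start also from M1's optimum, M4 from M2's
#' and M3's), which enforces the nesting inequality
#' `NLL(M4) <= min(NLL(M2), NLL(M3)) <= NLL(M1)` up to optimizer tolerance.
#' Ties in the winner are broken toward the model with fewer free
#' parameters.
#'
#' @param dataset a `behavioral_dataset` with both conditions present.
#' @param fit_config a [fit_config] object.
#' @return A list of class `comparison_row`: `fits` (named list of
#'   `fit_result`), `aic`, `waic` (named vectors), `winner`.
#' @export
compare_subject <- function(dataset, fit_config = fit_config()) {
  specs <- lapply(c("M1", "M2", "M3", "M4"), model_spec)
  names(specs) <- vapply(specs, `[[`, "", "name")
  fits <- list()
  warm <- function(models) lapply(fits[models], function(f) f$params)
  fits$M1 <- fit_subject(dataset, specs$M1, fit_config)
  fits$M2 <- fit_subject(dataset, specs$M2, fit_config,
                         extra_starts = warm("M1"))
  fits$M3 <- fit_subject(dataset, specs$M3, fit_config,
                         extra_starts = warm("M1"))
  fits$M4 <- fit_subject(dataset, specs$M4, fit_config,
                         extra_starts = warm(c("M2", "M3")))
  aics <- vapply(fits, function(f) aic(f$nll, f$n_free), 0)
  w <- waic(aics)
  n_free <- vapply(fits, `[[`, 0L, "n_free")
  best <- which(w >= max(w) - 1e-12)
  winner <- names(fits)[best[which.min(n_free[best])]]
  structure(list(fits = fits, aic = aics, waic = w, winner = winner),
            class = "comparison_row")
}

#' @export
print.comparison_row <- function(x, ...) {
  cat("Model comparison (winner:", x$winner, ")\n")
  print(data.frame(model = names(x$aic), aic = round(x$aic, 2),
                   waic = round(x$waic, 4), row.names = NULL))
  invisible(x)
}

#' Comparison table across subjects
#'
#' @param rows named list of `comparison_row` objects (one per subject).
#' @return A data frame with one row per subject: wAIC per model and the
#'   winning model label. Weight rows sum to 1.
#' @export
comparison_table <- function(rows) {
  do.call(rbind, lapply(names(rows), function(id) {
    r <- rows[[id]]
    data.frame(subject_id = id, wAIC_M1 = r$waic[["M1"]],
               wAIC_M2 = r$waic[["M2"]], wAIC_M3 = r$waic[["M3"]],
               wAIC_M4 = r$waic[["M4"]], winner = r$winner)
  }))
}
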