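#' Euler-Maruyama simulation of SE-SSM trials
#'
#' Simulates individual decision-variable traces: starting from
#' `x0 = x_b*(1-2c)`, each step adds `v*(1 + c*b*d)*dt + s*xi1*sqrt(dt)`
#' with standard-normal `xi1`, until the first sample with `|x| >= x_th`.
#' The observed response time adds a uniform effective non-decision time
#' (see [sample_nondecision_time()]). Threshold crossing is recorded at the
#' first suprathreshold sample (no within-step bridge correction); trials
#' not absorbed by `t_max` are flagged censored.
#'
#' Reproducibility follows R's RNG: call `set.seed()` (or pass `seed`)
#' before simulating.
#'
#' @param params an [se_params] object.
#' @param c conflict indicator, 0 or 1.
#' @param n number of trials, >= 1.
#' @param dt simulation time step (s).
#' @param t_max censoring horizon (s).
#' @param seed optional integer seed (calls `set.seed`).
#' @param keep_traces if `TRUE`, stores every trace (concatenated in
#'   attributes `trace_values` / `trace_offsets`; trace `i` runs from
#'   `trace_offsets[i]+1` to `trace_offsets[i+1]`, begins at `x0`, ends at
#'   the first suprathreshold sample).
#' @return A data frame with columns `condition`, `rt`, `correct`,
#'   `decision_time`, `t_eff`, `censored`, with trace attributes when
#'   requested.
#' @export
simulate_trials <- function(params, c, n, dt = 0.001, t_max = 5,
                            seed = NULL, keep_traces = FALSE) {
  validate_se_params(params)
  c <- as_conflict(c)
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  res <- .simulate_cpp(params$v, params$b, c, params$x_th, params$x_b,
                       params$s, params$t, params$s_t, as.integer(n), dt,
                       t_max, isTRUE(keep_traces))
  out <- data.frame(condition = rep.int(c, n), rt = res$rt,
                    correct = res$correct, decision_time = res$decision_time,
                    t_eff = res$t_eff, censored = res$censored)
  if (any(out$censored))
    warning(sum(out$censored),
            " trial(s) exceeded t_max and are censored; exclude them from RT summaries")
  if (isTRUE(keep_traces)) {
    attr(out, "trace_values") <- res$trace_values
    attr(out, "trace_offsets") <- res$trace_offsets
    attr(out, "dt") <- dt
  }
  out
}

#' Behavioral summary with RT-percentile-bin accuracy
#'
#' Per condition: mean RT, RT standard deviation, and accuracy; plus the
#' conditional accuracy function, i.e. accuracy within RT-percentile bins
#' at edges \[0, 20, 40, 60, 80, 100\]% (percentiles of all responded
#' trials in that condition). For error responses, whose counts are small,
#' a single 50% split is summarized by the median error RT.
#'
#' @param trials a trial data frame (e.g. from [simulate_trials()]) or a
#'   `behavioral_dataset`. Censored trials are dropped.
#' @return A list with elements `by_condition` (data frame: condition,
#'   n, mean_rt, sd_rt, accuracy), `bin_accuracy` (data frame: condition,
#'   bin, rt_center, accuracy, n) and `errors` (data frame: condition,
#'   n_errors, median_error_rt).
#' @export
behavioral_summary <- function(trials) {
  tr <- as_trial_df(trials)
  if (!is.null(tr$censored)) tr <- tr[!tr$censored, , drop = FALSE]
  conds <- sort(unique(tr$condition))
  for (cc in conds)
    if (sum(tr$condition == cc) < 5L)
      stop("condition ", cc, " has fewer than 5 trials")
  edges <- c(0, 20, 40, 60, 80, 100) / 100
  by_condition <- do.call(rbind, lapply(conds, function(cc) {
    x <- tr[tr$condition == cc, ]
    data.frame(condition = cc, n = nrow(x), mean_rt = mean(x$rt),
               sd_rt = stats::sd(x$rt), accuracy = mean(x$correct))
  }))
  bin_accuracy <- do.call(rbind, lapply(conds, function(cc) {
    x <- tr[tr$condition == cc, ]
    q <- stats::quantile(x$rt, edges, names = FALSE, type = 7)
    bin <- cut(x$rt, q, include.lowest = TRUE, labels = FALSE)
    centers <- stats::quantile(x$rt, (edges[-1] + edges[-length(edges)]) / 2,
                               names = FALSE)
    do.call(rbind, lapply(seq_len(length(edges) - 1L), function(k) {
      inb <- bin == k
      data.frame(condition = cc, bin = k, rt_center = centers[k],
                 accuracy = if (any(inb)) mean(x$correct[inb]) else NA_real_,
                 n = sum(inb))
    }))
  }))
  errors <- do.call(rbind, lapply(conds, function(cc) {
    e <- tr[tr$condition == cc & !tr$correct, ]
    data.frame(condition = cc, n_errors = nrow(e),
               median_error_rt = if (nrow(e)) stats::median(e$rt) else NA_real_)
  }))
  list(by_condition = by_condition, bin_accuracy = bin_accuracy,
       errors = errors)
}
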