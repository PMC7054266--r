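# hand-built dv_pool with known traces (structure documented in dv_pool())
fake_pool <- function(rts, traces, correct = TRUE, condition = 1L,
                      dt = 0.01, match_resolution = 0.025) {
  sims <- data.frame(condition = condition, rt = rts,
                     correct = rep_len(correct, length(rts)),
                     decision_time = rts, t_eff = 0,
                     censored = FALSE)
  attr(sims, "trace_values") <- unlist(traces)
  attr(sims, "trace_offsets") <- c(0L, cumsum(lengths(traces)))
  pools <- list(c0 = sims, c1 = sims)
  structure(list(pools = pools, params = p_ref(), dt = dt,
                 match_resolution = match_resolution,
                 n_sim = length(rts)),
            class = "dv_pool")
}

test_that("RT matching uses a 25 ms bin centered on the observed RT", {
  pool <- fake_pool(rts = c(0.490, 0.510, 0.540),
                    traces = list(1:5 / 10, 1:6 / 10, 1:7 / 10))
  trial <- list(condition = 1, rt = 0.500, correct = TRUE)
  tr <- match_and_average(pool, trial, min_matches = 2)
  expect_equal(tr$n_matched, 2L)  # 0.540 is outside +/- 12.5 ms

  expect_warning(
    excl <- match_and_average(pool, trial, min_matches = 10),
    "excluded")
  expect_null(excl)
})

test_that("aligned averaging is response-locked with majority coverage", {
  # two traces of length 3, one of length 5: samples earlier than 3 steps
  # before crossing are carried by <50% of traces and must be dropped
  pool <- fake_pool(rts = c(0.50, 0.50, 0.50),
                    traces = list(c(0.1, 0.3, 0.6), c(0.0, 0.2, 0.5),
                                  c(0, 0.1, 0.2, 0.4, 0.6)))
  tr <- match_and_average(pool, list(condition = 1, rt = 0.5, correct = TRUE),
                          min_matches = 3)
  expect_equal(tr$aligned_time, -(0:2) * 0.01)
  expect_equal(tr$mean_dv, c(0.6 + 0.5 + 0.6, 0.3 + 0.2 + 0.4,
                             0.1 + 0 + 0.2) / 3)
})

test_that("expected DV reaches the threshold at the crossing sample", {
  p <- se_params(v = 2.5, x_th = 0.6, t = 0.3, s_t = 0.05, b = 2, x_b = 0.15)
  pool <- dv_pool(p, n_sim = 2e4, seed = 61)
  set.seed(62)
  obs <- simulate_trials(p, 1, 30)
  traces <- expected_dv_traces(pool, obs)
  kept <- Filter(Negate(is.null), traces)
  expect_gt(length(kept), 10)
  for (tr in kept[1:5]) {
    at0 <- tr$mean_dv[1]
    if (tr$correct) {
      expect_gte(at0, p$x_th)
      expect_lt(at0, p$x_th + 5 * sqrt(pool$dt))
    }
  }
  # conflict trials start biased toward the error bound
  long <- kept[[which.max(vapply(kept, function(t) length(t$mean_dv), 0))]]
  expect_lt(tail(long$mean_dv, 1), 0.1)
})

test_that("windows step back 50 ms from -25 ms and respect coverage", {
  # constant trace 0.3, 300 ms long at 1 ms steps
  tr <- structure(list(aligned_time = -(0:299) / 1000,
                       mean_dv = rep(0.3, 300), n_matched = 50,
                       condition = 1L, rt = 0.5, correct = TRUE),
                  class = "expected_dv")
  amp <- extract_windows(list(tr), n_windows = 4)
  expect_equal(attr(amp, "centers"), c(-0.025, -0.075, -0.125, -0.175))
  expect_equal(unname(amp[1, ]), rep(0.3, 4))

  short <- structure(list(aligned_time = -(0:59) / 1000,
                          mean_dv = rep(0.2, 60), n_matched = 50,
                          condition = 1L, rt = 0.5, correct = TRUE),
                     class = "expected_dv")
  amp2 <- extract_windows(list(short), n_windows = 2)
  expect_equal(unname(amp2[1, 1]), 0.2)   # [-0.05, 0] covered
  expect_true(is.na(amp2[1, 2]))          # [-0.1, -0.05] not covered
})

test_that("z-scoring centers windows and imputes missing trials at 0", {
  m <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "-0.025"))
  z <- zscore_amplitudes(m)
  expect_equal(unname(z[, 1]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  m2 <- matrix(c(1, 2, 3, NA), ncol = 1, dimnames = list(NULL, "-0.025"))
  z2 <- zscore_amplitudes(m2)
  expect_equal(unname(z2[4, 1]), 0)
  expect_equal(mean(z2[1:3, 1]), 0)

  m3 <- matrix(NA_real_, 4, 1, dimnames = list(NULL, "-0.025"))
  expect_warning(z3 <- zscore_amplitudes(m3), "all zeros")
  expect_equal(unname(z3[, 1]), rep(0, 4))
  expect_error(zscore_amplitudes(matrix(rep(1, 4), ncol = 1,
                                        dimnames = list(NULL, "w"))),
               "zero variance")

  # condition split z-scores each condition separately
  m4 <- matrix(c(1, 2, 3, 10, 20, 30), ncol = 1,
               dimnames = list(NULL, "-0.025"))
  sp <- zscore_amplitudes(m4, condition = c(0, 0, 0, 1, 1, 1))
  expect_equal(mean(sp$c0[1:3, 1]), 0)
  expect_equal(mean(sp$c1[4:6, 1]), 0)
  expect_equal(sp$c0[4:6, 1], rep(0, 3))
})

test_that("the pre-response expected DV separates fast from slow trials", {
  # self-consistency: among same-condition trials the expected DV 25 ms
  # before the response carries strong RT information -- slow trials have
  # lingered near the bound and sit closer to threshold, fast trials shot
  # through it, so the window amplitude increases with RT rank
  p <- se_params(v = 2.5, x_th = 0.6, t = 0.3, s_t = 0.05, b = 2, x_b = 0.15)
  pool <- dv_pool(p, n_sim = 4e4, seed = 63)
  set.seed(64)
  obs <- simulate_trials(p, 1, 220)
  obs <- obs[obs$correct & !obs$censored, ][1:150, ]
  amp <- extract_windows(expected_dv_traces(pool, obs), n_windows = 1)
  ok <- !is.na(amp[, 1])
  expect_gt(sum(ok), 100)
  r <- cor(amp[ok, 1], rank(obs$rt[ok]))
  expect_gt(r, 0.5)
})
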