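test_that("the double-gamma kernel peaks near 5 s with a single undershoot", {
  tg <- seq(0, 32, by = 0.1)
  h <- double_gamma_hrf(tg)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  expect_lt(abs(tg[which.max(h)] - 5.0), 0.2)
  sgn <- sign(h[h != 0])
  expect_equal(sum(diff(sgn) != 0), 1)  # positive lobe then undershoot only
  expect_error(double_gamma_hrf(seq(0, 32, by = 0.5)), "step")
})

test_that("design construction is linear in event amplitudes", {
  on <- c(10, 30, 50, 80)
  a <- c(1, -0.5, 2, 0.3)
  b <- c(0.2, 1, -1, 0.5)
  d_a <- build_design(list(ev = event_regressor(on, 1, a)), 60, tr = 2)
  d_b <- build_design(list(ev = event_regressor(on, 1, b)), 60, tr = 2)
  d_ab <- build_design(list(ev = event_regressor(on, 1, a + b)), 60, tr = 2)
  expect_equal(d_ab[, "ev"], d_a[, "ev"] + d_b[, "ev"], tolerance = 1e-10)
  d_2a <- build_design(list(ev = event_regressor(on, 1, 2 * a)), 60, tr = 2)
  expect_equal(d_2a[, "ev"], 2 * d_a[, "ev"], tolerance = 1e-10)

  expect_error(build_design(list(ev = event_regressor(200, 1)), 60, tr = 2),
               "beyond the end")
})

test_that("RT amplitudes are log-transformed and z-scored", {
  rt <- c(0.4, 0.5, 0.55, 0.7, 1.1)
  amp <- log_rt_amplitudes(rt)
  expect_equal(mean(amp), 0, tolerance = 1e-12)
  expect_equal(sd(amp), 1, tolerance = 1e-12)
  expect_equal(order(amp), order(rt))
})

test_that("DV events are 100 ms long, centered on their extraction time", {
  ev <- dv_event_regressor(onsets = 10, rt = 0.5, amplitudes = 1.3,
                           window_center = -0.025)
  expect_equal(ev$onsets, 10.425)
  expect_equal(ev$durations, 0.1)
  expect_equal(ev$amplitudes, 1.3)
})

test_that("OLS recovers exact coefficients and flags rank deficiency", {
  X <- build_design(list(stim = event_regressor(c(10, 40, 70, 100, 130), 1)),
                    80, tr = 2)
  beta <- c(2.5, 100, rep(0, ncol(X) - 2))
  y <- drop(X %*% beta)
  res <- fit_glm(y, X, contrasts = list(stim = 1))
  expect_equal(unname(res$betas[1:2, 1]), c(2.5, 100), tolerance = 1e-8)
  expect_equal(unname(res$contrasts$stim$estimate), 2.5, tolerance = 1e-8)

  Xbad <- cbind(X, dup = X[, "stim"])
  expect_error(fit_glm(y, Xbad, list(stim = 1)), "dup")
})

test_that("contrast p-values are uniform under pure noise", {
  X <- build_design(list(stim = event_regressor(seq(10, 280, by = 20), 1)),
                    150, tr = 2)
  set.seed(71)
  Y <- matrix(rnorm(150 * 1000), 150)
  res <- fit_glm(Y, X, contrasts = list(stim = 1))
  pvals <- 2 * pt(-abs(res$contrasts$stim$t), df = res$dof)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  # z and t agree in the bulk
  expect_lt(max(abs(res$contrasts$stim$z - res$contrasts$stim$t)), 0.15)
})

test_that("a sum contrast over split DV regressors adds their effects", {
  on <- seq(10, 280, by = 20)
  set.seed(72)
  ev <- list(stim = event_regressor(on, 1),
             dv_c0 = event_regressor(on + 0.4, 0.1, rnorm(length(on))),
             dv_c1 = event_regressor(on + 0.45, 0.1, rnorm(length(on))))
  X <- build_design(ev, 150, tr = 2)
  y <- drop(X[, "dv_c0"] * 1.5 + X[, "dv_c1"] * 0.5) + 0.01 * rnorm(150)
  res <- fit_glm(y, X, contrasts = list(sum = c(0, 1, 1)))
  expect_equal(unname(res$contrasts$sum$estimate), 2.0, tolerance = 0.05)
})

test_that("session and group combination behave as fixed/random effects", {
  s1 <- list(estimate = c(1, 2, 3), var = c(1, 1, 1))
  expect_equal(combine_sessions(list(s1, s1))$estimate, s1$estimate)
  expect_equal(combine_sessions(s1)$estimate, s1$estimate)  # pass-through
  s2 <- list(estimate = c(3, 4, 5), var = c(1, 1, 1))
  expect_equal(combine_sessions(list(s1, s2))$estimate, c(2, 3, 4))
  # inverse-variance weighting favors the precise session
  s3 <- list(estimate = c(10, 10, 10), var = c(100, 100, 100))
  expect_lt(max(abs(combine_sessions(list(s1, s3))$estimate -
                      c(1.089, 2.079, 3.069))), 0.01)

  dims <- c(10, 10, 10)
  set.seed(73)
  M <- matrix(rnorm(21 * prod(dims)), 21)
  planted <- cube_region(dims, c(4, 4, 4), 3)
  M[, planted] <- M[, planted] + 1.2
  g <- group_onesample(M, dim = dims, z_thresh = 2.5)
  expect_gt(nrow(g$clusters), 0)
  sig <- which(g$cluster_labels > 0 & array(g$z, dims) > 2.5)
  expect_gt(length(intersect(sig, planted)) / length(planted), 0.8)

  g0 <- group_onesample(matrix(rnorm(21 * 27, 0, 1e-3) +
                                 rep(rnorm(27), each = 21), 21),
                        dim = c(3, 3, 3), z_thresh = 1e6)
  expect_equal(nrow(g0$clusters), 0)
})
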