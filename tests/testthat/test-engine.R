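test_that("grid spans the bounds plus the boundary pad and locates x_b", {
  p <- se_params(v = 1, x_th = 0.6, t = 0.3, x_b = 0.1)
  cfg <- engine_config(dx = 0.01, dt = 0.001)
  g <- build_grid(p, cfg)
  expect_lt(abs(max(g$x) - (0.6 + 5 * sqrt(0.001))), cfg$dx)
  expect_equal(min(g$x), -max(g$x))
  expect_true(all(abs(g$x[g$absorbing]) >= p$x_th - 1e-12))
  expect_equal(g$x[g$i0_nonconflict], 0.1)
  expect_equal(g$x[g$i0_conflict], -0.1)

  expect_error(build_grid(se_params(v = 1, x_th = 0.05, t = 0.3),
                          engine_config(dx = 0.2)), "degenerate grid")
})

test_that("absorption probability matches the closed form for constant drift", {
  cfg <- engine_config(dx = 0.005, dt = 2.5e-4)
  for (case in list(c(v = 1, x_th = 0.5), c(v = 2, x_th = 0.4))) {
    p <- se_params(v = case[["v"]], x_th = case[["x_th"]], t = 0.3)
    fp <- fp_propagate(p, 0, cfg)
    expect_lt(abs(tail(fp$cdf_correct, 1) -
                    absorb_prob(p$v, p$x_th, 2 * p$x_th)), 0.005)
  }
  # near-zero drift: symmetry gives P(correct) = 1/2
  p0 <- se_params(v = 1e-6, x_th = 0.4, t = 0.3)
  fp0 <- fp_propagate(p0, 0, cfg)
  expect_lt(abs(tail(fp0$cdf_correct, 1) - 0.5), 0.005)
})

test_that("defective densities are valid and grid-converged", {
  p <- p_ref()
  for (cc in 0:1) {
    fp <- fp_propagate(p, cc, engine_config())
    expect_true(all(fp$pdf_correct >= 0) && all(fp$pdf_error >= 0))
    expect_true(all(diff(fp$cdf_correct) >= -1e-12))
    expect_true(all(diff(fp$cdf_error) >= -1e-12))
    total <- tail(fp$cdf_correct, 1) + tail(fp$cdf_error, 1)
    expect_gte(total, 0.999)
    expect_lte(total, 1 + 1e-9)
  }
  # halving dx barely moves the absorption split
  pc1 <- tail(fp_propagate(p, 0, engine_config(dx = 0.01))$cdf_correct, 1)
  pc2 <- tail(fp_propagate(p, 0, engine_config(dx = 0.005))$cdf_correct, 1)
  expect_lt(abs(pc1 - pc2), 0.002)
})

test_that("conflict counteraction shrinks the conflict RT spread", {
  base <- list(v = 2, x_th = 0.5, t = 0.3, x_b = 0.1)
  with_b <- se_params(v = base$v, x_th = base$x_th, t = base$t,
                      b = 4, x_b = base$x_b)
  no_b <- se_params(v = base$v, x_th = base$x_th, t = base$t,
                    b = 0, x_b = base$x_b)
  rt_sd <- function(p) {
    fp <- fp_propagate(p, 1, engine_config())
    w <- fp$pdf_correct / sum(fp$pdf_correct)
    mu <- sum(w * fp$time)
    sqrt(sum(w * (fp$time - mu)^2))
  }
  expect_lt(rt_sd(with_b), rt_sd(no_b))
})

test_that("mirroring the start point swaps correct and error densities", {
  # drift +v from +x_b reflected through 0 equals drift -v from -x_b;
  # with b = 0 the conflict flag only flips the start point, so comparing
  # (v, c=0) against (-v, c=1) must swap the defective CDFs exactly
  a <- sessm:::.fp_propagate_cpp(1.5, 0, 0L, 0.5, 0.1, 1, 0.01, 0.001, 3, 5,
                                 1e-9)
  b <- sessm:::.fp_propagate_cpp(-1.5, 0, 1L, 0.5, 0.1, 1, 0.01, 0.001, 3, 5,
                                 1e-9)
  expect_equal(a$cdf_up, b$cdf_lo, tolerance = 1e-12)
  expect_equal(a$cdf_lo, b$cdf_up, tolerance = 1e-12)
})

test_that("non-decision convolution shifts, spreads and conserves mass", {
  p <- se_params(v = 2, x_th = 0.5, t = 0.25, s_t = 0)
  fp <- fp_propagate(p, 0, engine_config())
  rtd <- apply_nondecision(fp)
  n <- length(rtd$rt)
  expect_equal(rtd$rt, fp$time[seq_len(n)] + 0.25)
  expect_equal(rtd$pdf_correct, fp$pdf_correct[seq_len(n)])

  pj <- se_params(v = 2, x_th = 0.5, t = 0.25, s_t = 0.1)
  rtj <- apply_nondecision(fp_propagate(pj, 0, engine_config()), pj)
  mass_in <- tail(fp$cdf_correct, 1) + tail(fp$cdf_error, 1)
  mass_out <- tail(rtj$cdf_correct, 1) + tail(rtj$cdf_error, 1)
  expect_lt(abs(mass_in - mass_out), 1e-6)

  # a delta-like decision-time density spreads to the kernel width
  ker <- sessm:::uniform_kernel(0.1, 0.001)
  expect_equal(sum(ker$w), 1)
  expect_lt(abs(diff(range(ker$j)) * 0.001 - 0.1), 0.002)
})

test_that("trial likelihood interpolates densities and floors outliers", {
  p <- p_ref()
  cfg <- engine_config()
  rtd <- apply_nondecision(fp_propagate(p, 0, cfg), p)
  mode_rt <- rtd$rt[which.max(rtd$pdf_correct)]
  one <- data.frame(condition = 0, rt = mode_rt, correct = TRUE)
  expect_equal(trial_loglik(one, p, cfg), -log(max(rtd$pdf_correct)),
               tolerance = 1e-8)

  # an RT far outside the support contributes the density floor
  far <- data.frame(condition = 0, rt = 20, correct = TRUE)
  expect_warning(nll_far <- trial_loglik(far, p, cfg), "outside")
  expect_equal(nll_far, -log(cfg$density_floor))

  # generating parameters beat grossly wrong ones on simulated data
  set.seed(21)
  d <- rbind(simulate_trials(p, 0, 250), simulate_trials(p, 1, 250))
  wrong <- se_params(v = 4 * p$v, x_th = p$x_th, t = p$t, s_t = p$s_t,
                     b = p$b, x_b = p$x_b)
  nll_wrong <- suppressWarnings(trial_loglik(d, wrong, cfg))
  expect_lt(trial_loglik(d, p, cfg), nll_wrong)
})

test_that("first-passage densities export as tidy CSV", {
  fp <- fp_propagate(p_basic(), 0, engine_config(t_max = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fp_density(fp, path)
  df <- read.csv(path)
  expect_named(df, c("time", "pdf_correct", "pdf_error", "cdf_correct",
                     "cdf_error"))
  expect_equal(nrow(df), length(fp$time))
})
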