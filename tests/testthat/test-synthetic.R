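test_that("cohorts have the study's trial structure and are seed-stable", {
  spec <- cohort_spec(n_subjects = 3, seed = 101)
  cohort <- generate_cohort(spec)
  expect_length(cohort$subjects, 3)
  for (sub in cohort$subjects) {
    tr <- sub$dataset$trials
    expect_equal(nrow(tr), 192L)  # 2 sessions x (48 + 48) responded trials
    expect_equal(sum(tr$condition == 0), 96L)
    expect_equal(sum(tr$condition == 1), 96L)
    ev <- sub$events
    expect_equal(nrow(ev), 240L)
    expect_equal(sum(ev$trial_type == "null"), 48L)
    expect_true(all(is.na(ev$response_time[ev$trial_type == "null"])))
    # onsets on the 2.5 s grid within each session
    expect_equal(unique(diff(ev$onset[ev$session_id == 1])), 2.5)
  }

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_cohort_events(generate_cohort(spec), dir1)
  write_cohort_events(generate_cohort(spec), dir2)
  f1 <- list.files(dir1, full.names = TRUE)
  f2 <- list.files(dir2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("a subject with positive bias shows the Simon RT effect", {
  cohort <- generate_cohort(cohort_spec(n_subjects = 8, seed = 102))
  xbs <- vapply(cohort$subjects, function(s) s$params$x_b, 0)
  sub <- cohort$subjects[[which(xbs > 0.08)[1]]]
  set.seed(103)
  s0 <- simulate_trials(sub$params, 0, 2000)
  s1 <- simulate_trials(sub$params, 1, 2000)
  expect_gt(mean(s1$rt), mean(s0$rt))
})

test_that("planted group maps have the requested correlation structure", {
  dims <- c(8, 8, 8)
  region <- cube_region(dims, c(3, 3, 3), 3)
  set.seed(104)
  cov <- rnorm(21)
  maps <- generate_group_maps(dims, cov, region = region, slope = 5,
                              noise_sd = 0.2, seed = 105)
  M <- t(vapply(maps, as.numeric, numeric(prod(dims))))
  r_region <- apply(M[, region], 2, cor, y = cov)
  expect_true(all(r_region > 0.9))
  r_null <- apply(M[, setdiff(seq_len(prod(dims)), region)][, 1:50], 2,
                  cor, y = cov)
  expect_lt(mean(abs(r_null)), 0.3)

  # a mask excluding the planted region hides the effect entirely
  mask <- array(TRUE, dims)
  mask[region] <- FALSE
  gm <- group_maps(maps, cov, mask = mask)
  res <- max_stat_permutation(gm, n_perm = 200, seed = 106)
  expect_gt(min(pmin(res$p_pos, res$p_neg)), 0.05)
})

test_that("noise-free planted BOLD is recovered exactly by the GLM", {
  on <- seq(10, 280, by = 15)
  bold <- generate_bold(list(stim = event_regressor(on, 1)),
                        betas = matrix(c(3.2, 0, 0), ncol = 1),
                        n_volumes = 151, tr = 2, noise_sd = 0)
  X <- build_design(list(stim = event_regressor(on, 1)), 151, tr = 2)
  res <- fit_glm(bold$data, X, contrasts = list(stim = 1))
  expect_equal(unname(res$contrasts$stim$estimate),
               c(3.2, 0, 0), tolerance = 1e-6)

  # null voxels give approximately standard-normal z statistics
  set.seed(107)
  noisy <- generate_bold(list(stim = event_regressor(on, 1)),
                         betas = matrix(0, 1000, 1), n_volumes = 151,
                         tr = 2, noise_sd = 1)
  resn <- fit_glm(noisy$data, X, contrasts = list(stim = 1))
  expect_lt(abs(mean(resn$contrasts$stim$z)), 0.1)
  expect_lt(abs(sd(resn$contrasts$stim$z) - 1), 0.1)
})
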