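make_maps <- function(n_subj, dims, f = function(i) array(rnorm(prod(dims)),
                                                          dims)) {
  lapply(seq_len(n_subj), f)
}

test_that("voxelwise correlations are Fisher z-transformed and capped", {
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  dims <- c(4, 4, 2)
  cov <- c(0.2, 0.5, 0.9, 1.4, 2.0, 2.2, 3.1)
  set.seed(81)
  gm <- group_maps(make_maps(7, dims), cov)
  z <- voxelwise_fisher_z(gm)
  r <- tanh(z)
  # cross-check one voxel against cor()
  expect_equal(r[1, 1, 1], cor(cov, gm$data[, 1]), tolerance = 1e-9)

  # maps proportional to the covariate: r = 1 capped to finite z
  prop <- lapply(cov, function(v) array(v * seq_len(prod(dims)), dims))
  gp <- group_maps(prop, cov)
  zp <- voxelwise_fisher_z(gp)
  expect_true(all(is.finite(zp)))
  expect_true(all(zp > 10))

  expect_error(group_maps(make_maps(7, dims), rep(1, 7)), "zero variance")
  expect_error(group_maps(make_maps(4, dims), cov[1:4]), "at least 5")
})

test_that("TFCE matches the analytic integral on flat clusters", {
  # flat cluster, extent 4, height 1: integral of n^E h^H dh = sqrt(4)/3
  m <- array(0, c(10, 1, 1))
  m[3:6, 1, 1] <- 1
  e <- tfce(m, dh = 0.01)
  expect_lt(max(abs(e[3:6, 1, 1] - sqrt(4) / 3)), 0.01)
  expect_lt(max(abs(e[3:6, 1, 1] - sqrt(4) / 3)) / (sqrt(4) / 3), 0.015)

  # single voxel of height 2: integral h^2 dh from 0 to 2 = 8/3
  m2 <- array(0, c(5, 5, 5))
  m2[3, 3, 3] <- 2
  e2 <- tfce(m2, dh = 0.02)
  expect_lt(abs(e2[3, 3, 3] - 8 / 3), 0.03)

  expect_equal(tfce(array(0, c(3, 3, 3))), array(0, c(3, 3, 3)))

  # negative part is enhanced symmetrically and recombined with sign
  expect_equal(tfce(-m, dh = 0.01), -e)
})

test_that("scaling a map strictly increases every nonzero TFCE value", {
  set.seed(82)
  m <- array(rnorm(5 * 5 * 5), c(5, 5, 5))
  e1 <- abs(tfce(m))
  e2 <- abs(tfce(1.7 * m))
  nz <- e1 > 0
  expect_true(all(e2[nz] > e1[nz]))
})

test_that("exact enumeration agrees with an independent permutation oracle", {
  dims <- c(4, 4, 1)
  n <- 6
  set.seed(83)
  maps <- make_maps(n, dims)
  cov <- rnorm(n)
  gm <- group_maps(maps, cov)
  res <- max_stat_permutation(gm, n_perm = 720, seed = 84)
  expect_true(res$exact)
  expect_equal(res$n_permutations, 720)

  # oracle: recursive permutation generation + direct max-statistic loop,
  # independent of the package's enumeration path
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  stat <- function(cv) {
    z <- vapply(seq_len(ncol(gm$data)), function(j) {
      r <- cor(cv, gm$data[, j])
      atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
    }, 0)
    max(abs(tfce(array(z, dims))))
  }
  null_max <- vapply(perms(cov), stat, 0)
  obs <- abs(res$tfce_obs)
  p_oracle <- array(vapply(as.numeric(obs),
                           function(o) mean(null_max >= o - 1e-12), 0),
                    dims)
  p_pkg <- pmin(res$p_pos, res$p_neg)
  expect_equal(array(p_pkg, dims), p_oracle, tolerance = 1e-12)

  # relabeling subjects leaves the exact p-values unchanged
  rel <- c(3, 1, 6, 2, 5, 4)
  gm2 <- group_maps(maps[rel], cov[rel])
  res2 <- max_stat_permutation(gm2, n_perm = 720, seed = 85)
  expect_equal(res2$p_pos, res$p_pos, tolerance = 1e-12)
  expect_equal(res2$p_neg, res$p_neg, tolerance = 1e-12)
})

test_that("permutation p-values respect bounds and tail complements", {
  dims <- c(5, 5, 2)
  set.seed(86)
  cov <- rnorm(8)
  gm <- group_maps(make_maps(8, dims), cov)
  res <- max_stat_permutation(gm, n_perm = 120, seed = 87)
  expect_true(all(res$p_pos > 0 & res$p_pos <= 1))
  expect_true(all(res$p_neg > 0 & res$p_neg <= 1))
  expect_gte(min(c(res$p_pos, res$p_neg)), 1 / (120 + 1))
  # each voxel is assigned to exactly one tail (the other is set to 1)
  expect_true(all(res$p_pos == 1 | res$p_neg == 1))

  # masked-out voxels carry p = 1
  mask <- array(TRUE, dims)
  mask[1, , ] <- FALSE
  gmm <- group_maps(make_maps(8, dims), cov, mask = mask)
  resm <- max_stat_permutation(gmm, n_perm = 120, seed = 88)
  expect_true(all(resm$p_pos[1, , ] == 1 & resm$p_neg[1, , ] == 1))
})

test_that("a planted covariate-linked region is detected", {
  dims <- c(10, 10, 10)
  region <- cube_region(dims, c(4, 4, 4), 3)
  set.seed(89)
  cov <- rnorm(21)
  maps <- generate_group_maps(dims, cov, region = region, slope = 1,
                              noise_sd = 0.5, seed = 90)
  gm <- group_maps(maps, cov)
  res <- max_stat_permutation(gm, n_perm = 500, seed = 91)
  expect_lt(min(res$p_pos[region]), 0.05)
})
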