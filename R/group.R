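#' Group maps container
#'
#' Per-subject 3D statistic maps plus one scalar covariate per subject
#' (a fitted model parameter, mean RT, or RT difference), and an optional
#' analysis mask (e.g. excluding brain stem and white matter).
#'
#' @param maps list of 3D arrays (same dimensions) or a subjects x voxels
#'   matrix with attribute `dim3`.
#' @param covariate numeric vector, one value per subject, nonzero
#'   variance.
#' @param mask optional logical 3D array; `NULL` means all voxels.
#' @return An object of class `group_maps`: `data` (subjects x voxels,
#'   masked voxels only), `mask`, `dim`, `covariate`.
#' @export
group_maps <- function(maps, covariate, mask = NULL) {
  if (is.list(maps)) {
    dims <- dim(maps[[1]])
    if (length(dims) != 3) stop("maps must be 3D arrays")
    if (!all(vapply(maps, function(m) identical(dim(m), dims), TRUE)))
      stop("all subject maps must share dimensions")
    M <- t(vapply(maps, as.numeric, numeric(prod(dims))))
  } else {
    M <- as.matrix(maps)
    dims <- attr(maps, "dim3")
    if (is.null(dims)) stop("matrix input needs a 'dim3' attribute")
  }
  if (nrow(M) < 5) stop("need at least 5 subjects")
  if (length(covariate) != nrow(M))
    stop("covariate length must equal the number of subjects")
  if (stats::sd(covariate) == 0) stop("covariate has zero variance")
  if (is.null(mask)) mask <- array(TRUE, dims)
  stopifnot(identical(dim(mask), dims))
  keep <- which(as.logical(mask))
  if (any(!is.finite(M[, keep])))
    stop("maps contain non-finite values inside the mask")
  structure(list(data = M[, keep, drop = FALSE], mask = as.logical(mask),
                 dim = dims, covariate = as.numeric(covariate)),
            class = "group_maps")
}

# Vectorized per-voxel Pearson correlation of a covariate with the columns
# of a subjects x voxels matrix.
col_pearson <- function(M, covariate) {
  xc <- covariate - mean(covariate)
  Mc <- sweep(M, 2, colMeans(M))
  num <- drop(crossprod(xc, Mc))
  den <- sqrt(sum(xc^2) * colSums(Mc^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)  # keep atanh finite at |r| = 1
}

#' Voxelwise Fisher-z correlation map
#'
#' Pearson correlation between the covariate and each masked voxel's values
#' across subjects, Fisher z-transformed (`z = atanh(r)`; `|r| = 1` is
#' capped just below 1 so z stays finite). Voxels with constant maps get
#' z = 0 with a warning; voxels outside the mask are `NA`.
#'
#' @param gm a [group_maps] object.
#' @return A 3D array of Fisher z values (NA outside the mask).
#' @export
voxelwise_fisher_z <- function(gm) {
  stopifnot(inherits(gm, "group_maps"))
  r <- col_pearson(gm$data, gm$covariate)
  if (any(is.na(r))) {
    warning(sum(is.na(r)), " constant voxel(s): z set to 0")
    r[is.na(r)] <- 0
  }
  out <- array(NA_real_, gm$dim)
  out[gm$mask] <- atanh(r)
  out
}

#' Threshold-free cluster enhancement
#'
#' For every voxel, integrates `extent(h)^E * h^H` over thresholds `h`,
#' where `extent(h)` is the size of the suprathreshold connected component
#' containing the voxel. Applied separately to the positive part and the
#' negated negative part, recombined with sign. The integral is evaluated
#' as a midpoint Riemann sum at thresholds `(k - 1/2)*dh`.
#'
#' @param map 3D array (NA treated as 0).
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh threshold step; `NULL` uses `max(|map|)/100`.
#' @param connectivity 6 or 26 (default 26).
#' @return A 3D array of signed enhanced values.
#' @export
tfce <- function(map, E = 0.5, H = 2, dh = NULL, connectivity = 26) {
  stopifnot(length(dim(map)) == 3)
  m <- map
  m[is.na(m)] <- 0
  if (is.null(dh)) {
    mx <- max(abs(m))
    if (mx == 0) return(array(0, dim(map)))
    dh <- mx / 100
  }
  out <- .tfce_cpp(as.numeric(m), as.integer(dim(map)), E, H, dh,
                   as.integer(connectivity))
  array(out, dim(map))
}

#' Max-statistic permutation test of TFCE-enhanced correlation maps
#'
#' The observed statistic per voxel is `|TFCE(fisher-z map)|`. The null
#' distribution is the image-wide maximum of the same statistic with the
#' covariate randomly permuted across subjects. Voxelwise family-wise
#' error corrected p-values are
#' `p = (1 + #(null max >= observed)) / (1 + n_perm)` (add-one smoothing);
#' when `n_perm` reaches the number of distinct permutations the test
#' enumerates all of them exactly and `p = #(null >= observed)/n!` with
#' the identity included. The two-tailed p map is split by the observed
#' sign into a positive-tail and a negative-tail map, with the
#' complementary voxels set to p = 1.
#'
#' @param gm a [group_maps] object.
#' @param n_perm number of permutations (>= 100).
#' @param E,H,connectivity TFCE settings (see [tfce()]).
#' @param seed optional integer seed.
#' @return An object of class `tfce_result`: `tfce_obs` (signed 3D array),
#'   `p_pos`, `p_neg` (3D arrays, 1 outside mask/complementary tail),
#'   `null_max`, `n_permutations`, `exact`.
#' @export
max_stat_permutation <- function(gm, n_perm = 1000, E = 0.5, H = 2,
                                 connectivity = 26, seed = NULL) {
  stopifnot(inherits(gm, "group_maps"))
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  n <- length(gm$covariate)
  zmap <- voxelwise_fisher_z(gm)
  obs_signed <- tfce(zmap, E = E, H = H, connectivity = connectivity)
  obs_signed[is.na(obs_signed)] <- 0
  obs <- abs(obs_signed)

  stat_for <- function(cv) {
    r <- col_pearson(gm$data, cv)
    r[is.na(r)] <- 0
    z <- array(0, gm$dim)
    z[gm$mask] <- atanh(r)
    max(abs(tfce(z, E = E, H = H, connectivity = connectivity)))
  }

  nfact <- factorial(n)
  exact <- is.finite(nfact) && nfact <= n_perm
  if (exact) {
    perms <- all_permutations(n)
    null_max <- vapply(perms, function(pr) stat_for(gm$covariate[pr]),
                       numeric(1))
    counts <- vapply(as.numeric(obs),
                     function(o) sum(null_max >= o - 1e-12), 0)
    p <- counts / length(null_max)
    n_used <- length(null_max)
  } else {
    null_max <- vapply(seq_len(n_perm), function(i)
      stat_for(gm$covariate[sample.int(n)]), numeric(1))
    counts <- vapply(as.numeric(obs),
                     function(o) sum(null_max >= o - 1e-12), 0)
    p <- (1 + counts) / (1 + n_perm)
    n_used <- n_perm
  }
  p <- array(pmin(p, 1), gm$dim)
  p[!gm$mask] <- 1
  p_pos <- ifelse(obs_signed > 0, p, 1)
  p_neg <- ifelse(obs_signed < 0, p, 1)
  structure(list(tfce_obs = obs_signed, p_pos = array(p_pos, gm$dim),
                 p_neg = array(p_neg, gm$dim), null_max = null_max,
                 n_permutations = n_used, exact = exact),
            class = "tfce_result")
}

# All permutations of 1..n (used for exact enumeration at small n):
# insert n into every slot of each permutation of 1..n-1.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub)
    for (k in 0:(n - 1L)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = k)
    }
  out
}

#' Write group-statistics outputs as NIfTI and CSV
#'
#' @param result a `tfce_result`.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @param alpha significance level for the summary CSV.
#' @return Invisibly, the paths written.
#' @export
write_tfce_result <- function(result, dir, prefix = "group", alpha = 0.05) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    tfce = file.path(dir, paste0(prefix, "_tfce.nii.gz")),
    p_pos = file.path(dir, paste0(prefix, "_p_pos.nii.gz")),
    p_neg = file.path(dir, paste0(prefix, "_p_neg.nii.gz")),
    summary = file.path(dir, paste0(prefix, "_summary.csv")))
  RNifti::writeNifti(RNifti::asNifti(result$tfce_obs), paths["tfce"])
  RNifti::writeNifti(RNifti::asNifti(result$p_pos), paths["p_pos"])
  RNifti::writeNifti(RNifti::asNifti(result$p_neg), paths["p_neg"])
  utils::write.csv(data.frame(
    tail = c("positive", "negative"),
    n_significant = c(sum(result$p_pos <= alpha),
                      sum(result$p_neg <= alpha)),
    min_p = c(min(result$p_pos), min(result$p_neg)),
    n_permutations = result$n_permutations),
    paths["summary"], row.names = FALSE)
  invisible(paths)
}
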