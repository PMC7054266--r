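#' Read a BIDS-style events TSV into a behavioral dataset
#'
#' Expects columns `onset`, `duration`, `trial_type`
#' (congruent/incongruent/null), `response_time` (s) and `correct`. Null
#' trials are dropped from the behavioral dataset but kept in the returned
#' event table for scan timing; `trial_type` maps to the conflict code
#' (congruent = 0, incongruent = 1). Rows with non-positive response times
#' are rejected with a warning.
#'
#' @param path events TSV path.
#' @param subject_id subject label for the dataset.
#' @return A `behavioral_dataset` with the full event table (including
#'   null trials) in attribute `events`.
#' @export
read_events <- function(path, subject_id = basename(path)) {
  ev <- utils::read.delim(path, sep = "\t", na.strings = c("n/a", "NA"),
                          stringsAsFactors = FALSE)
  req <- c("onset", "duration", "trial_type", "response_time", "correct")
  for (nm in req)
    if (!nm %in% names(ev)) stop("events file is missing column '", nm, "'")
  resp <- ev$trial_type != "null"
  bad_rt <- which(resp & !is.na(ev$response_time) &
                    !is.numeric(ev$response_time))
  if (!is.numeric(ev$response_time)) {
    suppressWarnings(rt_num <- as.numeric(ev$response_time))
    bad <- which(resp & is.na(rt_num) & !is.na(ev$response_time))
    if (length(bad))
      stop("non-numeric response_time on responded trial(s), row(s): ",
           paste(bad, collapse = ", "))
    ev$response_time <- rt_num
  }
  rows <- which(resp)
  nonpos <- rows[!is.na(ev$response_time[rows]) & ev$response_time[rows] <= 0]
  if (length(nonpos)) {
    warning("rejecting ", length(nonpos), " row(s) with RT <= 0")
    rows <- setdiff(rows, nonpos)
  }
  rows <- rows[!is.na(ev$response_time[rows])]
  trials <- data.frame(
    condition = as.integer(ev$trial_type[rows] == "incongruent"),
    rt = ev$response_time[rows],
    correct = as.logical(as.integer(ev$correct[rows])))
  ds <- behavioral_dataset(trials, subject_id = subject_id)
  attr(ds, "events") <- ev
  ds
}

#' Write events as BIDS-style TSV
#'
#' Missing values are written as `n/a` per the BIDS convention.
#'
#' @param events data frame with columns onset, duration, trial_type,
#'   response_time, correct.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  ev <- events
  for (nm in names(ev))
    if (is.numeric(ev[[nm]])) ev[[nm]] <- ifelse(is.na(ev[[nm]]), "n/a",
                                                 format(ev[[nm]], digits = 15))
  ev[is.na(ev)] <- "n/a"
  utils::write.table(ev, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write 3D or 4D NIfTI images
#'
#' Thin wrappers around RNifti with an error naming the offending file.
#'
#' @param path NIfTI file path.
#' @return `read_nifti_array` returns a plain numeric array.
#' @export
read_nifti_array <- function(path) {
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop("cannot read NIfTI file '", path, "': ", conditionMessage(e)))
  array(as.numeric(img), dim(img))
}

#' @rdname read_nifti_array
#' @param x numeric array to write.
#' @export
write_nifti_array <- function(x, path) {
  RNifti::writeNifti(RNifti::asNifti(x), path)
  invisible(path)
}

# Manifest describing one pipeline stage: inputs, seed, parameter hash,
# output files with md5 checksums. Wall-clock time is deliberately omitted
# so identical runs produce identical manifests.
write_manifest <- function(dir, stage, seed, config, outputs) {
  # hash the config by serializing it to canonical JSON
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(stage = stage, seed = seed,
                   config_hash = unname(tools::md5sum(tmp)),
                   outputs = lapply(outputs, function(p)
                     list(file = basename(p),
                          md5 = unname(tools::md5sum(p)))))
  unlink(tmp)
  path <- file.path(dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run a reproducible pipeline stage
#'
#' Drives the package's stages from one declarative configuration:
#' `synth` materializes a synthetic cohort (events TSVs + parameter JSONs),
#' `fit` fits one subject's events TSV and writes a fit-result JSON,
#' `compare` writes the per-subject M1-M4 wAIC table, `dv` writes per-trial
#' decision-variable window amplitudes, `group` runs the TFCE permutation
#' test on NIfTI maps + a covariate CSV. Every stochastic stage derives its
#' seed from `seed`; rerunning with the same config reproduces outputs
#' bit for bit. On failure, partial outputs are quarantined in
#' `<out_dir>/.quarantine` rather than left in place.
#'
#' @param command one of `"synth"`, `"fit"`, `"compare"`, `"dv"`,
#'   `"group"`.
#' @param config named list of stage options (see Details of the individual
#'   functions; recognized keys per stage: synth: `n_subjects`, `seed`;
#'   fit/compare: `events`, `model`, `n_restarts`, `seed`; dv: `events`,
#'   `params`, `n_sim`, `n_windows`, `seed`; group: `maps` (vector of
#'   NIfTI paths), `covariate_csv`, `mask`, `n_perm`, `seed`).
#' @param out_dir output directory (created).
#' @return Invisibly, a character vector of written files.
#' @export
run_pipeline <- function(command = c("synth", "fit", "compare", "dv",
                                     "group"),
                         config = list(), out_dir = "sessm-out") {
  command <- match.arg(command)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  work <- file.path(out_dir, paste0(".tmp-", command))
  unlink(work, recursive = TRUE)
  dir.create(work, recursive = TRUE)
  outputs <- tryCatch(
    switch(command,
      synth = stage_synth(config, work, seed),
      fit = stage_fit(config, work, seed),
      compare = stage_compare(config, work, seed),
      dv = stage_dv(config, work, seed),
      group = stage_group(config, work, seed)),
    error = function(e) {
      qdir <- file.path(out_dir, ".quarantine", command)
      unlink(qdir, recursive = TRUE)
      dir.create(qdir, recursive = TRUE, showWarnings = FALSE)
      file.copy(list.files(work, full.names = TRUE), qdir,
                recursive = TRUE)
      unlink(work, recursive = TRUE)
      stop("stage '", command, "' failed (partial outputs quarantined in ",
           qdir, "): ", conditionMessage(e), call. = FALSE)
    })
  write_manifest(work, command, seed, config, outputs)
  final <- list.files(work, full.names = TRUE)
  moved <- file.path(out_dir, basename(final))
  file.copy(final, out_dir, overwrite = TRUE, recursive = TRUE)
  unlink(work, recursive = TRUE)
  invisible(moved)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_synth <- function(config, dir, seed) {
  spec <- cohort_spec(n_subjects = config$n_subjects %||% 21, seed = seed)
  cohort <- generate_cohort(spec)
  paths <- write_cohort_events(cohort, dir)
  for (id in names(cohort$subjects)) {
    p <- file.path(dir, paste0(id, "_params.json"))
    write_se_params(cohort$subjects[[id]]$params, p)
    paths <- c(paths, p)
  }
  paths
}

stage_fit <- function(config, dir, seed) {
  if (is.null(config$events)) stop("fit stage needs config$events")
  ds <- read_events(config$events)
  spec <- model_spec(config$model %||% "M4")
  fc <- fit_config(n_restarts = config$n_restarts %||% 5, rng_seed = seed)
  fit <- fit_subject(ds, spec, fc)
  path <- file.path(dir, "fit_result.json")
  write_fit_result(fit, path)
  path
}

stage_compare <- function(config, dir, seed) {
  if (is.null(config$events)) stop("compare stage needs config$events")
  paths <- config$events
  rows <- lapply(paths, function(p) {
    ds <- read_events(p)
    compare_subject(ds, fit_config(n_restarts = config$n_restarts %||% 5,
                                   rng_seed = seed))
  })
  names(rows) <- basename(paths)
  out <- file.path(dir, "comparison_table.csv")
  utils::write.csv(comparison_table(rows), out, row.names = FALSE)
  out
}

stage_dv <- function(config, dir, seed) {
  if (is.null(config$events) || is.null(config$params))
    stop("dv stage needs config$events and config$params")
  ds <- read_events(config$events)
  params <- read_se_params(config$params)
  pool <- dv_pool(params, n_sim = config$n_sim %||% 7.5e5, seed = seed)
  traces <- expected_dv_traces(pool, ds)
  amp <- extract_windows(traces,
                         n_windows = config$n_windows %||% 8)
  out <- file.path(dir, "dv_amplitudes.csv")
  write_dv_amplitudes(amp, ds, out)
  out
}

stage_group <- function(config, dir, seed) {
  for (nm in c("maps", "covariate_csv"))
    if (is.null(config[[nm]])) stop("group stage needs config$", nm)
  maps <- lapply(config$maps, read_nifti_array)
  cov <- utils::read.csv(config$covariate_csv)
  if (!all(c("subject_id", "value") %in% names(cov)))
    stop("covariate CSV needs columns subject_id, value")
  mask <- if (!is.null(config$mask))
    read_nifti_array(config$mask) > 0 else NULL
  gm <- group_maps(maps, cov$value, mask = mask)
  res <- max_stat_permutation(gm, n_perm = config$n_perm %||% 1000,
                              seed = seed)
  write_tfce_result(res, dir, prefix = "group")
}
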