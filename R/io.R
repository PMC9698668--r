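fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[!is.finite(x)] <- ""
  out
}

#' Write a labelled square matrix as CSV
#'
#' Delimited text with a header row and a leading label column; absent
#' entries (`NA`) are written as empty fields. Values are written with 17
#' significant digits so a write/read round trip is bit-identical.
#'
#' @param x numeric (or logical) matrix with row/column names.
#' @param path output file.
#' @export
write_matrix <- function(x, path) {
  if (is.logical(x)) { x <- x * 1L; storage.mode(x) <- "double" }
  lab <- rownames(x)
  if (is.null(lab)) lab <- paste0("R", seq_len(nrow(x)))
  lines <- c(paste(c("region", lab), collapse = ","),
             vapply(seq_len(nrow(x)), function(i)
               paste(c(lab[i], fmt_num(x[i, ])), collapse = ","), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read and validate a square matrix from CSV
#'
#' Strict reader for the delimited matrix dialect of [write_matrix()]:
#' header row and leading label column, empty/`NA`/`NaN` fields meaning
#' "absent". Validation depends on `kind`:
#' * `lengths`: symmetric (tolerance 1e-9), strictly positive, diagonal
#'   treated as absent;
#' * `lesions`: symmetric, entries 0/1 only (returned as logical);
#' * `delays`: strictly positive where present, diagonal absent.
#'
#' @param path CSV file.
#' @param kind `"lengths"`, `"lesions"` or `"delays"`.
#' @param labels optional expected region labels (error on mismatch).
#' @return numeric matrix (`NA` = absent), or logical matrix for lesions.
#' @export
read_matrix <- function(path, kind = c("lengths", "lesions", "delays"),
                        labels = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  lab <- as.character(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(lab, colnames(raw)[-1L])
  if (!identical(rownames(m), colnames(m)))
    stop(path, ": row and column labels differ", call. = FALSE)
  if (!is.null(labels) && !identical(rownames(m), as.character(labels)))
    stop(path, ": region labels do not match the configured parcellation",
         call. = FALSE)
  m[is.nan(m)] <- NA_real_
  pres <- which(!is.na(m), arr.ind = TRUE)
  if (kind %in% c("lengths", "lesions")) {
    gap <- abs(m - t(m))
    gap[is.na(gap)] <- 0                       # both-absent pairs are fine
    asym <- gap > 1e-9 | (is.na(m) != is.na(t(m)))
    if (any(asym)) {
      cell <- which(asym, arr.ind = TRUE)[1L, ]
      stop(sprintf("%s: asymmetric at (%s, %s)", path,
                   rownames(m)[cell[1L]], colnames(m)[cell[2L]]), call. = FALSE)
    }
  }
  if (kind == "lengths") {
    diag(m) <- NA_real_
    bad <- !is.na(m) & m <= 0
    if (any(bad)) {
      cell <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf("%s: non-positive length at (%s, %s)", path,
                   rownames(m)[cell[1L]], colnames(m)[cell[2L]]), call. = FALSE)
    }
    m[!is.na(m) & m == 0] <- NA_real_
    return(m)
  }
  if (kind == "lesions") {
    m[is.na(m)] <- 0
    bad <- !(m %in% c(0, 1))
    if (any(bad)) {
      cell <- which(matrix(bad, nrow(m)), arr.ind = TRUE)[1L, ]
      stop(sprintf("%s: lesion flag not 0/1 at (%s, %s)", path,
                   rownames(m)[cell[1L]], colnames(m)[cell[2L]]), call. = FALSE)
    }
    return(matrix(m == 1, nrow(m), dimnames = dimnames(m)))
  }
  bad <- !is.na(m) & m <= 0
  if (any(bad)) {
    cell <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: non-positive delay at (%s, %s)", path,
                 rownames(m)[cell[1L]], colnames(m)[cell[2L]]), call. = FALSE)
  }
  diag(m) <- NA_real_
  m
}

#' Write a regional time series as CSV
#'
#' First column = region label, remaining columns = samples.
#' @param ts a [source_ts()].
#' @param path output file.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "source_ts"))
  lines <- c(paste(c("region", paste0("s", seq_len(ncol(ts$data)))), collapse = ","),
             vapply(seq_len(nrow(ts$data)), function(i)
               paste(c(rownames(ts$data)[i], fmt_num(ts$data[i, ])),
                     collapse = ","), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a regional time series from CSV
#'
#' @param path CSV file (first column region labels, then samples).
#' @param fs sampling rate in Hz.
#' @return A [source_ts()].
#' @export
read_timeseries <- function(path, fs) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)[-1L]            # header carries only sample ids
  parts <- strsplit(lines, ",", fixed = TRUE)
  lab <- vapply(parts, `[[`, character(1), 1L)
  m <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
  rownames(m) <- lab
  source_ts(m, fs)
}

#' Write avalanches as JSON lines
#'
#' One JSON record per avalanche: `{subject, start_bin, frames}` where
#' frames is a list of region-label lists.
#'
#' @param avalanches list of `avalanche` objects.
#' @param path output file.
#' @param subject subject id stored in each record.
#' @export
write_avalanches_jsonl <- function(avalanches, path, subject = "S1") {
  lines <- vapply(avalanches, function(a) {
    jsonlite::toJSON(list(subject = subject, start_bin = a$start_bin,
                          frames = lapply(a$frames, function(f)
                            as.list(a$labels[f]))),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Analysis run configuration
#'
#' Collects every analysis setting; defaults are the headline settings of
#' the method (|z| > 3, bin width 3, no avalanche-size filter, onset
#' events, bin-resolution delays, 1000 permutations), and every published
#' variation (thresholds 2.5/3.5, bins 1-5, size filters, sample-resolution
#' delays) is reachable here without code changes.
#'
#' @param fs sampling rate of the input time series (Hz).
#' @param target_fs decimate to this rate before analysis (`NULL` = keep).
#' @param threshold z magnitude (default 3; alternates 2.5, 3.5).
#' @param bin_width samples per bin (default 3; tested range 1-5).
#' @param min_avalanche_size keep only avalanches with more than this many
#'   bins (0 = keep all; alternates 10, 15). Interpreted in bins.
#' @param events `"onset"` or `"occupancy"` event semantics.
#' @param delay_resolution `"bin"` or `"sample"` recruitment-time
#'   resolution.
#' @param n_perm surrogate/permutation count (default 1000).
#' @param percentile_bins bins for percentile profiles (default 100).
#' @param seed master seed.
#' @param region_labels optional parcellation label set for validation.
#' @return list of class `run_config`.
#' @export
run_config <- function(fs, target_fs = NULL, threshold = 3, bin_width = 3,
                       min_avalanche_size = 0, events = "onset",
                       delay_resolution = "bin", n_perm = 1000,
                       percentile_bins = 100, seed = 1,
                       region_labels = NULL) {
  stopifnot(fs > 0, threshold > 0, bin_width >= 1, min_avalanche_size >= 0,
            n_perm >= 0, percentile_bins >= 1)
  structure(list(fs = fs, target_fs = target_fs, threshold = threshold,
                 bin_width = as.integer(bin_width),
                 min_avalanche_size = as.integer(min_avalanche_size),
                 events = match.arg(events, c("onset", "occupancy")),
                 delay_resolution = match.arg(delay_resolution,
                                              c("bin", "sample")),
                 n_perm = as.integer(n_perm),
                 percentile_bins = as.integer(percentile_bins),
                 seed = as.integer(seed),
                 region_labels = region_labels),
            class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file with [run_config()] fields (`fs` required).
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Write a synthetic cohort bundle to disk
#'
#' Layout consumed by [run_pipeline()]: `manifest.csv` (id, group, seed and
#' relative paths), `lengths.csv`, `ts_<id>.csv`, `lesions_<id>.csv` for
#' patients, and `ground_truth.json` (generator parameters, velocity law,
#' lesioned edge lists).
#'
#' @param cohort a `synthetic_cohort` built with `timeseries = TRUE`.
#' @param dir output directory (created if needed).
#' @export
write_cohort_bundle <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(cohort$ground_truth$lengths, file.path(dir, "lengths.csv"))
  man <- cohort$manifest
  man$ts <- paste0("ts_", man$id, ".csv")
  man$lengths <- "lengths.csv"
  man$lesions <- ifelse(man$group == "patient",
                        paste0("lesions_", man$id, ".csv"), "")
  for (s in cohort$subjects) {
    if (is.null(s$ts))
      stop("cohort was built without time series; rerun make_cohort(timeseries = TRUE)",
           call. = FALSE)
    write_timeseries(s$ts, file.path(dir, paste0("ts_", s$id, ".csv")))
    if (!is.null(s$lesion_mask))
      write_matrix(s$lesion_mask, file.path(dir, paste0("lesions_", s$id, ".csv")))
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  p <- cohort$params
  gtj <- list(params = unclass(p),
              velocity_law = list(a = p$a, b = p$b),
              labels = cohort$ground_truth$labels,
              hemisphere_map = as.list(cohort$ground_truth$hemisphere_map))
  jsonlite::write_json(gtj, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the full topochronic pipeline over a cohort directory
#'
#' Per subject: read the time series, z-score, threshold, bin, segment
#' avalanches (applying the size filter), estimate the branching parameter,
#' the delay matrix and, with the structural lengths, the velocity matrix.
#' Per group: group delay matrices, complete-coverage edges, length-delay
#' correlation with its time-shuffle surrogate null, percentile profiles,
#' control-vs-patient KS comparison, edge-wise differences with the
#' lesioned-edge permutation test, and the convergence curve. A subject
#' whose processing fails is dropped with a logged reason rather than
#' aborting the run.
#'
#' @param dir cohort directory containing `manifest.csv` (columns `id`,
#'   `group`, `ts`, `lengths`, optional `lesions`) and the referenced files.
#' @param config a [run_config()].
#' @param surrogates compute the per-subject surrogate correlation null for
#'   `"first"` control (default), `"all"` controls, or `"none"`.
#' @return list of class `topochron_run`.
#' @export
run_pipeline <- function(dir, config,
                         surrogates = c("first", "all", "none")) {
  surrogates <- match.arg(surrogates)
  stopifnot(inherits(config, "run_config"))
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  fits <- list(); failures <- list()
  lengths_cache <- list()
  for (k in seq_len(nrow(man))) {
    id <- man$id[k]
    res <- tryCatch({
      lp <- man$lengths[k]
      if (is.null(lengths_cache[[lp]]))
        lengths_cache[[lp]] <- read_matrix(file.path(dir, lp), "lengths",
                                           labels = config$region_labels)
      L <- lengths_cache[[lp]]
      ts <- read_timeseries(file.path(dir, man$ts[k]), config$fs)
      fit <- topochron(ts, lengths = L, config = config)
      fit$id <- id
      fit$group <- man$group[k]
      if (!is.na(man$lesions[k]) && nzchar(man$lesions[k]))
        fit$lesion_mask <- read_matrix(file.path(dir, man$lesions[k]),
                                       "lesions")
      fit
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
      message("subject ", id, " failed: ", conditionMessage(res))
    } else fits[[id]] <- res
  }
  if (length(fits) == 0L) stop("no subject survived the pipeline", call. = FALSE)
  groups <- vapply(fits, function(f) f$group, character(1))
  controls <- fits[groups == "control"]
  patients <- fits[groups == "patient"]
  L <- fits[[1L]]$lengths
  out <- list(fits = fits, failures = failures, config = config,
              lengths = L)
  if (length(controls)) {
    cd <- lapply(controls, function(f) f$delay)
    out$control_group_delay <- group_delay_matrix(cd)
    out$control_group_velocity <- velocity_matrix(out$control_group_delay, L)
    out$coverage <- complete_coverage_edges(cd)
    out$correlation <- length_delay_correlation(out$control_group_delay, L)
    ne <- nrow(paired_edges(out$control_group_delay, L))
    if (ne >= config$percentile_bins) {
      out$delay_profile <- percentile_profile(out$control_group_delay, L,
                                              config$percentile_bins)
      out$velocity_profile <- percentile_profile(out$control_group_velocity, L,
                                                 config$percentile_bins)
    }
    if (surrogates != "none" && config$n_perm > 0) {
      which_ctrl <- if (surrogates == "first") 1L else seq_along(controls)
      out$surrogate_tests <- lapply(which_ctrl, function(i) {
        f <- controls[[i]]
        obs <- length_delay_correlation(f$delay, L)
        ens <- surrogate_delay_ensemble(
          f$avalanches, n_perm = config$n_perm, seed = config$seed,
          bin_width = f$settings$bin_width, fs = f$settings$fs)
        c(list(id = f$id, observed_r = obs$r),
          correlation_null_test(obs$r, ens, L)["p"])
      })
    }
    if (length(cd) >= 2L)
      out$convergence <- convergence_curve(cd, n_orders = 10,
                                           seed = config$seed)
  }
  if (length(controls) && length(patients)) {
    pd <- lapply(patients, function(f) f$delay)
    out$patient_group_delay <- group_delay_matrix(pd)
    ctrl_sym <- symmetrize_delays(out$control_group_delay)
    pat_sym <- symmetrize_delays(out$patient_group_delay)
    cov <- out$coverage
    out$ks <- ks_compare_groups(ctrl_sym$mean[cov], pat_sym$mean[cov])
    masks <- lapply(patients, function(f) f$lesion_mask)
    if (!any(vapply(masks, is.null, logical(1)))) {
      out$edgewise <- edgewise_differences(pd, out$control_group_delay,
                                           cov, masks)
      if (any(out$edgewise$lesioned) && any(!out$edgewise$lesioned))
        out$lesion_test <- lesion_permutation_test(out$edgewise,
                                                   n_perm = max(config$n_perm, 1L),
                                                   seed = config$seed)
    }
  }
  class(out) <- "topochron_run"
  out
}

#' @export
print.topochron_run <- function(x, ...) {
  cat(sprintf("<topochron_run> %d subjects analysed (%d failed)\n",
              length(x$fits), length(x$failures)))
  if (!is.null(x$correlation))
    cat(sprintf("  length-delay Spearman r = %.3f (n = %d edges)\n",
                x$correlation$r, x$correlation$n))
  if (!is.null(x$ks))
    cat(sprintf("  KS patients vs controls: D = %.3f, p = %.3g\n",
                x$ks$D, x$ks$p))
  if (!is.null(x$lesion_test))
    cat(sprintf("  lesion permutation test: p = %.3g\n", x$lesion_test$p))
  invisible(x)
}

#' Write a machine- and human-readable run report
#'
#' Writes `report.json` (settings echo, per-subject avalanche counts and
#' branching parameters, group statistics with p-values, sections marked
#' "skipped" when a group is absent) plus figure-ready CSVs: group
#' matrices, percentile profiles, group CDFs, edge-wise differences and the
#' lesion-test null distribution, and the convergence curve.
#'
#' @param results a `topochron_run`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
report <- function(results, dir) {
  stopifnot(inherits(results, "topochron_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  per_subject <- lapply(results$fits, function(f) list(
    id = f$id, group = f$group,
    n_avalanches = length(f$avalanches),
    n_discarded_boundary = f$n_discarded_boundary,
    n_excluded_single_bin = f$n_excluded_single_bin,
    sigma = if (is.null(f$sigma)) NULL else f$sigma$sigma))
  js <- list(settings = unclass(results$config)[
               !vapply(unclass(results$config), is.null, logical(1))],
             subjects = per_subject,
             failures = results$failures)
  quant <- function(m) as.list(stats::quantile(m[is.finite(m)],
                                               c(.05, .25, .5, .75, .95)))
  if (!is.null(results$correlation)) {
    js$length_delay_correlation <- results$correlation
    js$delay_quantiles_s <- quant(symmetrize_delays(results$control_group_delay)$mean)
    js$velocity_quantiles_ms <- quant(results$control_group_velocity$velocity)
    js$n_complete_coverage_edges <- nrow(results$coverage)
    write_matrix(symmetrize_delays(results$control_group_delay)$mean,
                 file.path(dir, "control_group_delay.csv"))
    write_matrix(results$control_group_velocity$velocity,
                 file.path(dir, "control_group_velocity.csv"))
  }
  if (!is.null(results$surrogate_tests))
    js$surrogate_tests <- lapply(results$surrogate_tests, function(s)
      list(id = s$id, observed_r = s$observed_r, p = s$p))
  if (!is.null(results$delay_profile)) {
    utils::write.csv(data.frame(
      percentile = seq_len(results$delay_profile$n_bins),
      mean_length_mm = results$delay_profile$mean_length_per_bin,
      mean_delay_s = results$delay_profile$mean_value_per_bin,
      mean_velocity_ms = results$velocity_profile$mean_value_per_bin),
      file.path(dir, "percentile_profiles.csv"), row.names = FALSE)
  }
  if (is.null(results$ks)) {
    js$group_comparison <- "skipped"
  } else {
    js$group_comparison <- list(ks_D = results$ks$D, ks_p = results$ks$p)
    utils::write.csv(results$ks$cdf, file.path(dir, "group_cdfs.csv"),
                     row.names = FALSE)
  }
  if (is.null(results$lesion_test)) {
    js$lesion_test <- "skipped"
  } else {
    js$lesion_test <- list(observed_mean = results$lesion_test$observed_mean,
                           p = results$lesion_test$p,
                           n_lesioned = results$lesion_test$n_lesioned)
    utils::write.csv(results$edgewise, file.path(dir, "edgewise_differences.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(null_mean = results$lesion_test$null_distribution),
                     file.path(dir, "lesion_null_distribution.csv"),
                     row.names = FALSE)
  }
  if (!is.null(results$convergence))
    utils::write.csv(data.frame(n_subjects = results$convergence$sizes,
                                median_abs_change_s = results$convergence$median_curve),
                     file.path(dir, "convergence.csv"), row.names = FALSE)
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
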