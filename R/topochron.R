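#' Fit a subject-level topochronic map
#'
#' The main per-subject estimator. Runs the avalanche pipeline on a
#' source-reconstructed regional time series: optional integer decimation,
#' z-scoring, thresholding at `|z| > threshold`, time-binning, avalanche
#' segmentation (with boundary and size exclusions), branching-parameter
#' estimation, recruitment-delay extraction, and — when a structural
#' tract-length matrix is supplied — per-edge conduction velocities.
#'
#' @param ts a [source_ts()], or a regions x samples numeric matrix
#'   (then `fs` is required).
#' @param lengths optional symmetric tract-length matrix (mm, `NA` = no
#'   tract) aligned with the regions.
#' @param fs sampling rate when `ts` is a bare matrix.
#' @param threshold z magnitude (default 3).
#' @param bin_width samples per bin (default 3).
#' @param target_fs decimate to this rate first (`NULL` = keep).
#' @param min_avalanche_size keep only avalanches with more than this many
#'   bins (default 0 = all).
#' @param events `"onset"` (one event per excursion, default) or
#'   `"occupancy"`.
#' @param delay_resolution `"bin"` (recruitment at bin resolution, default)
#'   or `"sample"` (first suprathreshold sample within the avalanche).
#' @param config optionally a [run_config()]; overrides the individual
#'   arguments above.
#' @return An object of class `topochron`: list with `delay`
#'   (directed `delay_matrix`, seconds), `velocity` (`velocity_matrix` or
#'   `NULL`), `sigma` (`branching_result` or `NULL` if undefined),
#'   `avalanches`, exclusion counts, `lengths`, and `settings`.
#' @seealso [coef.topochron()], [plot.topochron()], [simulate.topochron()]
#' @export
topochron <- function(ts, lengths = NULL, fs = NULL, threshold = 3,
                      bin_width = 3, target_fs = NULL,
                      min_avalanche_size = 0, events = "onset",
                      delay_resolution = c("bin", "sample"),
                      config = NULL) {
  if (!is.null(config)) {
    stopifnot(inherits(config, "run_config"))
    threshold <- config$threshold; bin_width <- config$bin_width
    target_fs <- config$target_fs
    min_avalanche_size <- config$min_avalanche_size
    events <- config$events; delay_resolution <- config$delay_resolution
  }
  delay_resolution <- match.arg(delay_resolution)
  if (!inherits(ts, "source_ts")) {
    if (is.null(fs)) stop("'fs' is required for a bare matrix", call. = FALSE)
    ts <- source_ts(ts, fs)
  }
  if (!is.null(lengths)) {
    if (!identical(rownames(lengths), rownames(ts$data)))
      stop("tract-length labels do not match the time-series regions",
           call. = FALSE)
  }
  if (!is.null(target_fs) && target_fs != ts$fs) ts <- downsample(ts, target_fs)
  z <- zscore_timeseries(ts)
  r1 <- binarize(z, threshold)
  r <- bin_raster(r1, bin_width)
  av <- segment_avalanches(r, events = events)
  n_boundary <- attr(av, "n_discarded_boundary")
  if (min_avalanche_size > 0)
    av <- av[vapply(av, function(a) a$n_bins, integer(1)) > min_avalanche_size]
  sigma <- tryCatch(cohort_branching(av), error = function(e) NULL)
  n_single <- sum(vapply(av, function(a) a$n_bins, integer(1)) == 1L)
  delay <- if (length(av)) {
    if (delay_resolution == "bin")
      subject_delay_matrix(av, bin_width = r$bin_width, fs = r$fs)
    else
      sample_delay_matrix(av, r1, r$bin_width)
  } else NULL
  vel <- if (!is.null(delay) && !is.null(lengths))
    velocity_matrix(delay, lengths) else NULL
  structure(list(delay = delay, velocity = vel, sigma = sigma,
                 avalanches = av,
                 n_avalanches = length(av),
                 n_discarded_boundary = n_boundary,
                 n_excluded_single_bin = n_single,
                 lengths = lengths,
                 labels = rownames(ts$data),
                 settings = list(fs = r$fs, threshold = threshold,
                                 bin_width = r$bin_width,
                                 min_avalanche_size = min_avalanche_size,
                                 events = events,
                                 delay_resolution = delay_resolution)),
            class = "topochron")
}

# Delay matrix at raw-sample resolution: recruitment time = first
# suprathreshold sample per region within the avalanche's sample window.
sample_delay_matrix <- function(avalanches, r1, bin_width) {
  labels <- rownames(r1$onsets)
  n <- length(labels)
  times <- lapply(avalanches, function(a) {
    ws <- (a$start_bin - 1L) * bin_width + 1L
    we <- min((a$start_bin + a$n_bins - 1L) * bin_width, ncol(r1$onsets))
    sub <- r1$onsets[, ws:we, drop = FALSE]
    t <- rep(NA_integer_, n)
    hit <- which(sub, arr.ind = TRUE)
    if (nrow(hit)) {
      first <- tapply(hit[, 2L], hit[, 1L], min)
      t[as.integer(names(first))] <- as.integer(first) - 1L
    }
    t
  })
  acc <- accumulate_times(times, n, 1 / r1$fs)
  m <- acc$sum / ifelse(acc$counts > 0L, acc$counts, NA_real_)
  diag(m) <- NA_real_
  cnt <- acc$counts; diag(cnt) <- 0L
  dimnames(m) <- dimnames(cnt) <- list(labels, labels)
  new_delay_matrix(m, cnt)
}

#' @export
print.topochron <- function(x, ...) {
  cat(sprintf("<topochron> %d regions, %d avalanches (bin width %d, |z| > %g)\n",
              length(x$labels), x$n_avalanches,
              x$settings$bin_width, x$settings$threshold))
  if (!is.null(x$sigma))
    cat(sprintf("  branching parameter sigma = %.3f (%d avalanches)\n",
                x$sigma$sigma, x$sigma$n_avalanches_used))
  if (!is.null(x$delay))
    cat(sprintf("  delay estimates on %d ordered pairs\n",
                sum(x$delay$counts > 0L)))
  if (!is.null(x$velocity)) print(x$velocity)
  invisible(x)
}

#' Summarise a topochron fit
#'
#' @param object a `topochron` fit.
#' @param ... unused.
#' @return list of class `summary.topochron` with avalanche counts, sigma,
#'   delay/velocity quantiles, and the length-delay Spearman correlation
#'   when structural lengths are available.
#' @export
summary.topochron <- function(object, ...) {
  q <- function(v) if (length(v)) stats::quantile(v, c(.05, .5, .95)) else NULL
  dsym <- if (!is.null(object$delay)) symmetrize_delays(object$delay) else NULL
  out <- list(
    n_avalanches = object$n_avalanches,
    n_discarded_boundary = object$n_discarded_boundary,
    n_excluded_single_bin = object$n_excluded_single_bin,
    sigma = if (is.null(object$sigma)) NA_real_ else object$sigma$sigma,
    delay_quantiles = if (!is.null(dsym)) q(dsym$mean[is.finite(dsym$mean)]),
    velocity_quantiles = if (!is.null(object$velocity))
      q(object$velocity$velocity[is.finite(object$velocity$velocity)]),
    correlation = if (!is.null(object$delay) && !is.null(object$lengths) &&
                      nrow(paired_edges(object$delay, object$lengths)) >= 3L)
      length_delay_correlation(object$delay, object$lengths),
    settings = object$settings)
  class(out) <- "summary.topochron"
  out
}

#' @export
print.summary.topochron <- function(x, ...) {
  cat(sprintf("Avalanches: %d (boundary-discarded %d, single-bin %d)\n",
              x$n_avalanches, x$n_discarded_boundary, x$n_excluded_single_bin))
  cat(sprintf("Branching parameter sigma: %.3f\n", x$sigma))
  if (!is.null(x$delay_quantiles)) {
    cat("Delay quantiles (s):\n"); print(signif(x$delay_quantiles, 3))
  }
  if (!is.null(x$velocity_quantiles)) {
    cat("Velocity quantiles (m/s):\n"); print(signif(x$velocity_quantiles, 3))
  }
  if (!is.null(x$correlation))
    cat(sprintf("Length-delay Spearman r = %.3f (p = %.3g, n = %d edges)\n",
                x$correlation$r, x$correlation$p, x$correlation$n))
  invisible(x)
}

#' Edge-level estimates of a topochron fit
#'
#' @param object a `topochron` fit.
#' @param ... unused.
#' @return data.frame of undirected edges with `from`, `to`, `delay` (s),
#'   `count` (contributing avalanches), and, when lengths were supplied,
#'   `length` (mm) and `velocity` (m/s).
#' @export
coef.topochron <- function(object, ...) {
  if (is.null(object$delay)) return(data.frame())
  d <- symmetrize_delays(object$delay)
  keep <- is.finite(d$mean)
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(from = object$labels[idx[, 1L]],
                    to = object$labels[idx[, 2L]],
                    delay = d$mean[idx], count = d$counts[idx])
  if (!is.null(object$lengths)) {
    out$length <- object$lengths[idx]
    out$velocity <- if (!is.null(object$velocity))
      object$velocity$velocity[idx] else NA_real_
  }
  out[order(out$from, out$to), , drop = FALSE]
}

#' Plot delay against tract length for a topochron fit
#'
#' Scatter of per-edge delays over tract lengths with the percentile-
#' profile trend and constant-velocity reference curves.
#'
#' @param x a `topochron` fit with structural lengths.
#' @param n_bins percentile bins for the trend line.
#' @param ref_velocities constant velocities (m/s) for reference lines.
#' @param ... passed to [graphics::plot()].
#' @export
plot.topochron <- function(x, n_bins = 20, ref_velocities = c(5, 10, 20),
                           ...) {
  if (is.null(x$delay) || is.null(x$lengths))
    stop("plotting needs both delays and tract lengths", call. = FALSE)
  pe <- paired_edges(x$delay, x$lengths)
  graphics::plot(pe$length, pe$value * 1000, pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.5),
                 xlab = "tract length (mm)", ylab = "delay (ms)", ...)
  if (nrow(pe) >= n_bins) {
    pp <- percentile_profile(x$delay, x$lengths, n_bins)
    graphics::lines(pp$mean_length_per_bin, pp$mean_value_per_bin * 1000,
                    lwd = 2, col = "firebrick")
  }
  lg <- seq(min(pe$length), max(pe$length), length.out = 50)
  for (v in ref_velocities)
    graphics::lines(lg, lg / v, lty = 3, col = "grey40")
  invisible(x)
}

#' Surrogate delay matrices for a topochron fit
#'
#' Time-shuffle surrogates of the fitted subject: permutes the frames of
#' every avalanche and recomputes the delay matrix, `nsim` times.
#'
#' @param object a `topochron` fit.
#' @param nsim number of surrogates (default 100).
#' @param seed integer seed.
#' @param ... unused.
#' @return A `surrogate_ensemble` (see [surrogate_delay_ensemble()]).
#' @export
simulate.topochron <- function(object, nsim = 100, seed = 1, ...) {
  if (object$n_avalanches == 0L) stop("fit has no avalanches", call. = FALSE)
  surrogate_delay_ensemble(object$avalanches, n_perm = nsim, seed = seed,
                           bin_width = object$settings$bin_width,
                           fs = object$settings$fs)
}
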