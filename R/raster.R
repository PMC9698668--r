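#' Construct a regional source time-series object
#'
#' Container for source-reconstructed regional time series: a regions x
#' samples numeric matrix plus its sampling rate. Region labels are taken
#' from the matrix row names (or generated as `R1..Rn`) and must be unique;
#' they are used to align the raster with structural tract-length and lesion
#' matrices downstream.
#'
#' @param data numeric matrix, regions x samples. All values must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param region_labels optional character vector of unique region labels;
#'   defaults to `rownames(data)` or `R1..Rn`.
#' @return An object of class `source_ts`: a list with elements `data`
#'   (labelled matrix) and `fs`.
#' @export
source_ts <- function(data, fs, region_labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L)
    stop("a source time series needs at least 2 regions", call. = FALSE)
  if (!all(is.finite(data)))
    stop("non-finite values in time series; clean or reject upstream", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive sampling rate in Hz", call. = FALSE)
  if (is.null(region_labels)) region_labels <- rownames(data)
  if (is.null(region_labels)) region_labels <- paste0("R", seq_len(nrow(data)))
  region_labels <- as.character(region_labels)
  if (length(region_labels) != nrow(data) || anyDuplicated(region_labels))
    stop("region labels must be unique and match the number of rows", call. = FALSE)
  rownames(data) <- region_labels
  structure(list(data = data, fs = as.numeric(fs)), class = "source_ts")
}

#' @export
print.source_ts <- function(x, ...) {
  cat(sprintf("<source_ts> %d regions x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Z-score each region over the full recording
#'
#' Normalises every regional series to mean 0 and unit standard deviation,
#' computed over the whole segment with the population (n) denominator.
#' Regions with zero variance (flat or dead channels) are an error.
#'
#' @param ts a [source_ts()] object.
#' @return A `source_ts` with z-scored data.
#' @export
zscore_timeseries <- function(ts) {
  stopifnot(inherits(ts, "source_ts"))
  x <- ts$data
  m <- rowMeans(x)
  s <- sqrt(rowMeans((x - m)^2))
  bad <- s == 0 | !is.finite(s)
  if (any(bad))
    stop("zero variance region(s): ", paste(rownames(x)[bad], collapse = ", "),
         " (flat/dead channel)", call. = FALSE)
  ts$data <- (x - m) / s
  ts
}

#' Downsample by integer decimation
#'
#' Keeps every k-th sample where `k = fs / target_fs` must be an integer.
#' Anti-alias filtering is assumed to have happened upstream (acquisition
#' pipelines low-pass well below the decimated Nyquist before this stage).
#'
#' @param ts a [source_ts()] object.
#' @param target_fs desired sampling rate; `fs` must be an integer multiple.
#' @return A `source_ts` at `target_fs` with `floor(n * target_fs / fs)` samples.
#' @export
downsample <- function(ts, target_fs) {
  stopifnot(inherits(ts, "source_ts"))
  if (target_fs > ts$fs)
    stop("target_fs must not exceed the current sampling rate", call. = FALSE)
  k <- ts$fs / target_fs
  if (abs(k - round(k)) > 1e-9)
    stop("fs/target_fs = ", format(k), " is not an integer; ",
         "resample upstream before decimating", call. = FALSE)
  k <- as.integer(round(k))
  if (k == 1L) return(ts)
  n_out <- floor(ncol(ts$data) / k)
  idx <- seq(1L, by = k, length.out = n_out)
  ts$data <- ts$data[, idx, drop = FALSE]
  ts$fs <- as.numeric(target_fs)
  ts
}

new_binned_raster <- function(occupancy, onsets, bin_width, fs, threshold) {
  structure(list(occupancy = occupancy, onsets = onsets,
                 bin_width = as.integer(bin_width), fs = as.numeric(fs),
                 threshold = as.numeric(threshold)),
            class = "binned_raster")
}

#' @export
print.binned_raster <- function(x, ...) {
  cat(sprintf("<binned_raster> %d regions x %d bins (bin_width %d samples @ %g Hz, |z| > %g)\n",
              nrow(x$occupancy), ncol(x$occupancy), x$bin_width, x$fs, x$threshold))
  invisible(x)
}

onsets_from_occupancy <- function(occ) {
  if (ncol(occ) == 0L) return(occ)
  occ & !cbind(FALSE, occ[, -ncol(occ), drop = FALSE])
}

#' Threshold a z-scored series into an activation raster
#'
#' Marks occupancy wherever the z score strictly exceeds the threshold in
#' magnitude (both positive and negative excursions count) and onsets at the
#' first sample of each contiguous suprathreshold run per region. The result
#' is a sample-resolution raster (`bin_width = 1`); see [bin_raster()].
#'
#' @param ts a z-scored [source_ts()].
#' @param threshold z-score magnitude (> 0); default 3.
#' @return A `binned_raster` with `bin_width = 1`.
#' @export
binarize <- function(ts, threshold = 3) {
  stopifnot(inherits(ts, "source_ts"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("'threshold' must be a single positive z magnitude", call. = FALSE)
  occ <- abs(ts$data) > threshold
  new_binned_raster(occ, onsets_from_occupancy(occ), 1L, ts$fs, threshold)
}

#' Re-bin an activation raster
#'
#' Aggregates a sample-resolution raster into bins of `bin_width` samples:
#' a bin is occupied if any of its samples is occupied (logical OR), and the
#' onset raster is recomputed on the binned occupancy (first bin of each
#' contiguous binned run). A trailing partial bin is dropped.
#'
#' @param r a `binned_raster` with `bin_width = 1`.
#' @param bin_width number of samples per bin (>= 1).
#' @return A `binned_raster` with the requested `bin_width`.
#' @export
bin_raster <- function(r, bin_width = 3) {
  stopifnot(inherits(r, "binned_raster"))
  if (bin_width < 1) stop("'bin_width' must be >= 1", call. = FALSE)
  bin_width <- as.integer(bin_width)
  if (r$bin_width != 1L)
    stop("input raster must be at sample resolution (bin_width = 1)", call. = FALSE)
  if (bin_width == 1L) return(r)
  n_bins <- ncol(r$occupancy) %/% bin_width
  occ <- matrix(FALSE, nrow(r$occupancy), n_bins,
                dimnames = list(rownames(r$occupancy), NULL))
  for (b in seq_len(n_bins)) {
    cols <- ((b - 1L) * bin_width + 1L):(b * bin_width)
    occ[, b] <- rowSums(r$occupancy[, cols, drop = FALSE]) > 0L
  }
  new_binned_raster(occ, onsets_from_occupancy(occ), bin_width, r$fs, r$threshold)
}

new_avalanche <- function(start_bin, frames, labels) {
  structure(list(start_bin = as.integer(start_bin),
                 frames = frames,
                 n_events_per_bin = vapply(frames, length, integer(1)),
                 n_bins = length(frames),
                 labels = labels),
            class = "avalanche")
}

#' @export
print.avalanche <- function(x, ...) {
  cat(sprintf("<avalanche> start bin %d, %d bins, %d events, %d regions\n",
              x$start_bin, x$n_bins, sum(x$n_events_per_bin),
              length(unique(unlist(x$frames)))))
  invisible(x)
}

#' Segment neuronal avalanches from a binned raster
#'
#' A neuronal avalanche is a maximal run of consecutive bins in which at
#' least one region is suprathreshold, bounded by empty bins. Avalanches
#' touching the first or last bin of the recording are discarded because
#' their start/end are unobservable. Each avalanche records, per bin, the
#' set of regions whose activation falls in that bin: with
#' `events = "onset"` (default) a region counts once per excursion, at the
#' bin containing the excursion's first suprathreshold sample; with
#' `events = "occupancy"` every suprathreshold bin counts.
#'
#' @param r a `binned_raster`.
#' @param events `"onset"` or `"occupancy"` event semantics.
#' @return A list of `avalanche` objects. The number of boundary-touching
#'   runs that were discarded is attached as attribute `n_discarded_boundary`.
#' @export
segment_avalanches <- function(r, events = c("onset", "occupancy")) {
  stopifnot(inherits(r, "binned_raster"))
  events <- match.arg(events)
  occ <- r$occupancy
  labels <- rownames(occ)
  n_bins_total <- ncol(occ)
  if (n_bins_total == 0L) {
    out <- list()
    attr(out, "n_discarded_boundary") <- 0L
    return(out)
  }
  active <- colSums(occ) > 0L
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  ev <- if (events == "onset") r$onsets else occ
  out <- list()
  discarded <- 0L
  for (k in which(keep)) {
    if (starts[k] == 1L || ends[k] == n_bins_total) {
      discarded <- discarded + 1L
      next
    }
    bins <- starts[k]:ends[k]
    frames <- lapply(bins, function(b) which(ev[, b]))
    out[[length(out) + 1L]] <- new_avalanche(starts[k], frames, labels)
  }
  attr(out, "n_discarded_boundary") <- discarded
  out
}

#' Branching parameter of a single avalanche
#'
#' Geometric mean, over consecutive bin pairs, of the ratio of event counts
#' in the next bin (descendants) to the current bin (ancestors):
#' `sigma_i = prod_j (n[j+1]/n[j]) ^ (1/(Nbin-1))`. Undefined for
#' single-bin avalanches (returns `NA` with class "undefined"); also `NA`
#' when an intermediate bin has zero events (possible under onset-event
#' semantics when a bin only continues existing excursions).
#'
#' @param a an `avalanche`, or an integer vector of events per bin.
#' @return The branching parameter, a positive real, or `NA_real_`.
#' @export
branching_parameter <- function(a) {
  n <- if (inherits(a, "avalanche")) a$n_events_per_bin else as.numeric(a)
  if (length(n) < 2L) return(NA_real_)
  if (any(n <= 0)) return(NA_real_)
  exp(mean(diff(log(n))))
}

#' Cohort branching parameter
#'
#' Geometric mean of per-avalanche branching parameters over all avalanches
#' for which sigma_i is defined (at least two bins, no zero-event bin).
#' Values near 1 indicate near-critical dynamics.
#'
#' @param avalanches list of `avalanche` objects (or numeric sigma values).
#' @return A list of class `branching_result` with `sigma`,
#'   `sigma_per_avalanche` and `n_avalanches_used`.
#' @export
cohort_branching <- function(avalanches) {
  sig <- if (is.numeric(avalanches)) as.numeric(avalanches)
         else vapply(avalanches, branching_parameter, numeric(1))
  sig <- sig[is.finite(sig)]
  if (length(sig) == 0L)
    stop("no avalanche with >= 2 bins: branching parameter undefined", call. = FALSE)
  structure(list(sigma = exp(mean(log(sig))),
                 sigma_per_avalanche = sig,
                 n_avalanches_used = length(sig)),
            class = "branching_result")
}

#' @export
print.branching_result <- function(x, ...) {
  cat(sprintf("<branching_result> sigma = %.4f over %d avalanches\n",
              x$sigma, x$n_avalanches_used))
  invisible(x)
}

#' Select the time-bin width by criticality
#'
#' Evaluates the cohort branching parameter at every candidate bin width and
#' returns the candidate whose sigma is closest to 1 (critical branching),
#' breaking ties toward the smaller width.
#'
#' @param ts a z-scored [source_ts()].
#' @param candidates integer vector of candidate bin widths (default 1:5).
#' @param threshold z magnitude for [binarize()].
#' @param events event semantics passed to [segment_avalanches()].
#' @return A list with `bin_width` (the selection) and `sigma_table`
#'   (data.frame of candidate, sigma, n_avalanches_used).
#' @export
select_bin_width <- function(ts, candidates = 1:5, threshold = 3,
                             events = "onset") {
  if (length(candidates) == 0L) stop("no candidate bin widths", call. = FALSE)
  candidates <- sort(unique(as.integer(candidates)))
  r1 <- binarize(ts, threshold)
  tab <- data.frame(bin_width = candidates, sigma = NA_real_,
                    n_avalanches_used = NA_integer_)
  for (i in seq_along(candidates)) {
    av <- segment_avalanches(bin_raster(r1, candidates[i]), events = events)
    br <- cohort_branching(av)
    tab$sigma[i] <- br$sigma
    tab$n_avalanches_used[i] <- br$n_avalanches_used
  }
  best <- which.min(abs(tab$sigma - 1))   # ties: first = smallest width
  list(bin_width = candidates[best], sigma_table = tab)
}
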