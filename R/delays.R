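MM_PER_M <- 1000  # all tract lengths in mm, delays in s, velocities in m/s

new_delay_matrix <- function(mean, counts) {
  stopifnot(identical(dim(mean), dim(counts)))
  mean[counts == 0L] <- NA_real_
  structure(list(mean = mean, counts = counts), class = "delay_matrix")
}

#' @export
print.delay_matrix <- function(x, ...) {
  pres <- sum(x$counts > 0L)
  cat(sprintf("<delay_matrix> %d regions, %d present entries, mean delay %.3g s\n",
              nrow(x$mean), pres,
              if (pres) mean(x$mean[x$counts > 0L]) else NA_real_))
  invisible(x)
}

region_labels_of <- function(x) {
  if (inherits(x, "delay_matrix")) rownames(x$mean)
  else if (inherits(x, "velocity_matrix")) rownames(x$velocity)
  else rownames(x)
}

check_aligned <- function(a, b) {
  la <- region_labels_of(a); lb <- region_labels_of(b)
  if (!identical(la, lb))
    stop("region labels are not aligned between operands", call. = FALSE)
  invisible(la)
}

recruitment_times <- function(a) {
  # first activation bin of each region, 0-based relative to avalanche start
  n <- length(a$labels)
  t <- rep(NA_integer_, n)
  for (f in seq_along(a$frames)) {
    regs <- a$frames[[f]]
    fresh <- regs[is.na(t[regs])]
    if (length(fresh)) t[fresh] <- f - 1L
  }
  t
}

#' Recruitment delays within one avalanche
#'
#' From the moment region i first activates in an avalanche, records how
#' long region j takes to activate: for every ordered pair with
#' `t_j > t_i` the delay `(t_j - t_i) * bin_width / fs` seconds is emitted.
#' Simultaneous recruitments emit nothing and each region contributes only
#' its first activation.
#'
#' @param a an `avalanche`.
#' @param bin_width samples per bin of the parent raster.
#' @param fs sampling rate in Hz.
#' @return data.frame with columns `from`, `to` (region labels) and
#'   `delay` (seconds).
#' @export
avalanche_delays <- function(a, bin_width = 1, fs = 1) {
  stopifnot(inherits(a, "avalanche"))
  t <- recruitment_times(a)
  rec <- which(!is.na(t))
  scale <- bin_width / fs
  if (length(rec) < 2L)
    return(data.frame(from = character(0), to = character(0),
                      delay = numeric(0)))
  tr <- t[rec]
  d <- outer(tr, tr, function(x, y) y - x)   # d[i, j] = t_j - t_i
  pos <- which(d > 0, arr.ind = TRUE)
  data.frame(from = a$labels[rec[pos[, 1L]]],
             to = a$labels[rec[pos[, 2L]]],
             delay = d[pos] * scale)
}

# Accumulate per-avalanche recruitment-time vectors into sum/count matrices.
accumulate_times <- function(times_list, n, scale) {
  s <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  for (t in times_list) {
    rec <- which(!is.na(t))
    if (length(rec) < 2L) next
    tr <- t[rec]
    d <- outer(tr, tr, function(x, y) y - x)
    pos <- d > 0
    s[rec, rec] <- s[rec, rec] + ifelse(pos, d, 0)
    cnt[rec, rec] <- cnt[rec, rec] + pos
  }
  list(sum = s * scale, counts = cnt)
}

#' Subject-level delay matrix
#'
#' Entrywise arithmetic mean of per-avalanche delays over the avalanches in
#' which each ordered region pair was observed. Unobserved pairs are absent
#' (`NA`), never zero; `counts` records the number of contributing
#' avalanches per entry.
#'
#' @param avalanches list of `avalanche` objects (all sharing one region
#'   set), or a list of data.frames as returned by [avalanche_delays()]
#'   together with `region_labels`.
#' @param bin_width,fs raster bin width (samples) and sampling rate (Hz);
#'   used only when `avalanches` are avalanche objects.
#' @param region_labels required when passing precomputed delay entries.
#' @return A `delay_matrix` (directed: entry i,j is the mean delay from i's
#'   activation to j's activation).
#' @export
subject_delay_matrix <- function(avalanches, bin_width = 1, fs = 1,
                                 region_labels = NULL) {
  if (length(avalanches) == 0L) stop("need at least one avalanche", call. = FALSE)
  if (inherits(avalanches[[1L]], "avalanche")) {
    labels <- avalanches[[1L]]$labels
    times <- lapply(avalanches, recruitment_times)
    acc <- accumulate_times(times, length(labels), bin_width / fs)
  } else {
    if (is.null(region_labels))
      stop("'region_labels' required for precomputed delay entries", call. = FALSE)
    labels <- region_labels
    n <- length(labels)
    acc <- list(sum = matrix(0, n, n), counts = matrix(0L, n, n))
    for (df in avalanches) {
      if (nrow(df) == 0L) next
      i <- match(df$from, labels); j <- match(df$to, labels)
      if (anyNA(i) || anyNA(j)) stop("unknown region label in delay entries", call. = FALSE)
      for (k in seq_len(nrow(df))) {
        acc$sum[i[k], j[k]] <- acc$sum[i[k], j[k]] + df$delay[k]
        acc$counts[i[k], j[k]] <- acc$counts[i[k], j[k]] + 1L
      }
    }
  }
  m <- acc$sum / ifelse(acc$counts > 0L, acc$counts, NA_real_)
  diag(m) <- NA_real_
  cnt <- acc$counts; diag(cnt) <- 0L
  dimnames(m) <- dimnames(cnt) <- list(labels, labels)
  new_delay_matrix(m, cnt)
}

#' Group-level delay matrix
#'
#' Entrywise mean over subjects with a present estimate for that entry,
#' discarding missing entries (an edge absent in some subjects is averaged
#' over the subjects that do have it). `counts` becomes the number of
#' contributing subjects.
#'
#' @param subjects list of `delay_matrix` objects with aligned labels.
#' @return A `delay_matrix`.
#' @export
group_delay_matrix <- function(subjects) {
  if (length(subjects) == 0L) stop("need at least one subject", call. = FALSE)
  for (s in subjects) check_aligned(subjects[[1L]], s)
  n <- nrow(subjects[[1L]]$mean)
  s <- matrix(0, n, n); cnt <- matrix(0L, n, n)
  for (d in subjects) {
    pres <- d$counts > 0L
    s[pres] <- s[pres] + d$mean[pres]
    cnt <- cnt + pres
  }
  m <- s / ifelse(cnt > 0L, cnt, NA_real_)
  dimnames(m) <- dimnames(cnt) <- dimnames(subjects[[1L]]$mean)
  new_delay_matrix(m, cnt)
}

#' Symmetrise a directed delay matrix
#'
#' Count-weighted mean of the two directions wherever at least one is
#' present; used before velocity computation since tract lengths are
#' undirected.
#'
#' @param d a `delay_matrix`.
#' @return A symmetric `delay_matrix` (counts are summed over directions).
#' @export
symmetrize_delays <- function(d) {
  stopifnot(inherits(d, "delay_matrix"))
  s <- ifelse(d$counts > 0L, d$mean * d$counts, 0)
  s <- s + t(s)
  cnt <- d$counts + t(d$counts)
  m <- s / ifelse(cnt > 0L, cnt, NA_real_)
  dimnames(m) <- dimnames(cnt) <- dimnames(d$mean)
  new_delay_matrix(m, cnt)
}

#' Edges with complete coverage across controls
#'
#' Returns the edges for which a delay estimate is present in every control
#' subject; group statistics restricted to these edges are based on all
#' subjects at every edge.
#'
#' @param controls list of `delay_matrix` objects with aligned labels.
#' @param symmetrize if `TRUE` (default) work on symmetrised matrices and
#'   return undirected edges (i < j); otherwise ordered pairs.
#' @return Two-column integer matrix of region index pairs, with region
#'   labels as attribute `labels`.
#' @export
complete_coverage_edges <- function(controls, symmetrize = TRUE) {
  if (length(controls) == 0L) stop("need at least one control", call. = FALSE)
  for (s in controls) check_aligned(controls[[1L]], s)
  if (symmetrize) controls <- lapply(controls, symmetrize_delays)
  pres <- Reduce(`&`, lapply(controls, function(d) d$counts > 0L))
  if (symmetrize) pres[lower.tri(pres, diag = TRUE)] <- FALSE else diag(pres) <- FALSE
  idx <- which(pres, arr.ind = TRUE)
  edges <- cbind(from = as.integer(idx[, 1L]), to = as.integer(idx[, 2L]))
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  attr(edges, "labels") <- region_labels_of(controls[[1L]])
  edges
}

#' Per-edge conduction velocities
#'
#' Divides tract lengths (mm) by the corresponding functional delays (s) to
#' obtain velocities in m/s. Velocities exist only where BOTH a direct
#' structural tract and a delay estimate are present. The directed delay
#' matrix is symmetrised first unless `directed = TRUE`.
#'
#' @param d a `delay_matrix`.
#' @param L symmetric tract-length matrix in mm with `NA` where no direct
#'   tract exists (see [read_matrix()]).
#' @param directed keep delays directed (velocity then inherits direction).
#' @return An object of class `velocity_matrix`: list with `velocity`
#'   (matrix, m/s, `NA` absent).
#' @export
velocity_matrix <- function(d, L, directed = FALSE) {
  stopifnot(inherits(d, "delay_matrix"))
  check_aligned(d, L)
  if (!directed) d <- symmetrize_delays(d)
  v <- (L / MM_PER_M) / d$mean
  v[!(is.finite(L) & L > 0) | d$counts == 0L] <- NA_real_
  diag(v) <- NA_real_
  structure(list(velocity = v), class = "velocity_matrix")
}

#' @export
print.velocity_matrix <- function(x, ...) {
  v <- x$velocity[is.finite(x$velocity)]
  cat(sprintf("<velocity_matrix> %d regions, %d present edges, range %.3g-%.3g m/s\n",
              nrow(x$velocity), length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

# Upper-triangle edges present in both a value matrix and the length matrix.
paired_edges <- function(values, L) {
  if (inherits(values, "delay_matrix")) values <- symmetrize_delays(values)$mean
  else if (inherits(values, "velocity_matrix")) values <- values$velocity
  check_aligned(values, L)
  keep <- is.finite(values) & is.finite(L) & L > 0
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  data.frame(from = idx[, 1L], to = idx[, 2L],
             length = L[idx], value = values[idx])
}

#' Percentile profile of delays or velocities against tract length
#'
#' Ranks the present edges by tract length, partitions them into
#' `n_bins` equal-count percentile bins (sorted order, near-equal chunk
#' sizes) and returns the mean value per bin; the profile behind the
#' length-percentile plots of delay/velocity growth.
#'
#' @param values a `delay_matrix` (symmetrised) or `velocity_matrix`.
#' @param L tract-length matrix (mm).
#' @param n_bins number of percentile bins (default 100).
#' @return A list of class `percentile_profile` with `percentile_edges`
#'   (upper length boundary per bin), `mean_value_per_bin`, `mean_length_per_bin`
#'   and `n_bins`.
#' @export
percentile_profile <- function(values, L, n_bins = 100) {
  pe <- paired_edges(values, L)
  n <- nrow(pe)
  if (n < n_bins)
    stop(sprintf("only %d edges for %d bins; use a smaller n_bins", n, n_bins),
         call. = FALSE)
  o <- order(pe$length)
  bin <- ceiling(seq_len(n) * n_bins / n)
  structure(list(
    percentile_edges = as.numeric(tapply(pe$length[o], bin, max)),
    mean_value_per_bin = as.numeric(tapply(pe$value[o], bin, mean)),
    mean_length_per_bin = as.numeric(tapply(pe$length[o], bin, mean)),
    n_bins = as.integer(n_bins)), class = "percentile_profile")
}

#' Expected delays under homogeneous velocity
#'
#' The delay each tract would show if signals travelled at one constant
#' velocity everywhere: `delay = (L/1000) / v` seconds wherever a tract is
#' present. Used as the reference curves against observed delay profiles.
#'
#' @param L tract-length matrix (mm).
#' @param v constant velocity in m/s (> 0).
#' @return A `delay_matrix` of expected delays (counts 1 where present).
#' @export
constant_velocity_expectation <- function(L, v) {
  if (!is.numeric(v) || length(v) != 1L || v <= 0)
    stop("'v' must be a single positive velocity in m/s", call. = FALSE)
  pres <- is.finite(L) & L > 0
  m <- ifelse(pres, (L / MM_PER_M) / v, NA_real_)
  diag(m) <- NA_real_
  cnt <- matrix(0L, nrow(L), ncol(L)); cnt[pres] <- 1L; diag(cnt) <- 0L
  dimnames(m) <- dimnames(cnt) <- dimnames(L)
  new_delay_matrix(m, cnt)
}

#' Fast-edge subgraph
#'
#' Edges whose conduction velocity strictly exceeds a threshold (default
#' 15 m/s), each tagged iso- vs. cross-hemispheric when a region-to-
#' hemisphere map is supplied.
#'
#' @param V a `velocity_matrix`.
#' @param threshold velocity threshold in m/s (> 0).
#' @param hemisphere_map named character vector mapping region label to
#'   `"L"`/`"R"`; if `NULL` edges are returned untagged with a warning.
#' @return data.frame with `region_a`, `region_b`, `velocity`,
#'   `hemisphere_tag` (`"iso"`, `"cross"` or `NA`).
#' @export
fast_edge_subgraph <- function(V, threshold = 15, hemisphere_map = NULL) {
  stopifnot(inherits(V, "velocity_matrix"))
  if (threshold <= 0) stop("'threshold' must be > 0", call. = FALSE)
  v <- V$velocity
  keep <- is.finite(v) & v > threshold
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  labels <- rownames(v)
  out <- data.frame(region_a = labels[idx[, 1L]], region_b = labels[idx[, 2L]],
                    velocity = v[idx],
                    hemisphere_tag = rep(NA_character_, nrow(idx)))
  if (is.null(hemisphere_map)) {
    if (nrow(out)) warning("no hemisphere map supplied; edges returned untagged")
  } else {
    ha <- hemisphere_map[out$region_a]; hb <- hemisphere_map[out$region_b]
    out$hemisphere_tag <- ifelse(ha == hb, "iso", "cross")
  }
  out[order(-out$velocity), , drop = FALSE]
}
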