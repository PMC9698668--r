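# Independent brute-force oracles and fixture builders. Everything here is
# deliberately written as plain loops, separate from the package's
# vectorised implementations.

# Build a bin_width-1 raster with a prescribed occupancy pattern by feeding
# binarize() a series that is +/-4 where occupied and 0 elsewhere.
raster_from_occupancy <- function(occ, fs = 100) {
  ts <- source_ts(ifelse(occ, 4, 0), fs)
  binarize(ts, threshold = 3)
}

random_occupancy <- function(n_regions, n_bins, p = 0.2) {
  matrix(stats::runif(n_regions * n_bins) < p, n_regions, n_bins,
         dimnames = list(paste0("R", seq_len(n_regions)), NULL))
}

# Build an avalanche object directly from a list of integer frames.
make_avalanche <- function(frames, n_regions, start_bin = 2L) {
  topochron:::new_avalanche(start_bin, frames, paste0("R", seq_len(n_regions)))
}

# Brute-force avalanche segmentation: walk the bin axis, collect maximal
# non-empty runs, drop runs touching either recording boundary.
oracle_segment <- function(occ, onsets) {
  n_bins <- ncol(occ)
  active <- apply(occ, 2, any)
  runs <- list()
  b <- 1
  while (b <= n_bins) {
    if (active[b]) {
      e <- b
      while (e < n_bins && active[e + 1]) e <- e + 1
      if (b > 1 && e < n_bins) {
        frames <- lapply(b:e, function(j) which(onsets[, j]))
        runs[[length(runs) + 1]] <- list(start = b, frames = frames)
      }
      b <- e + 1
    } else b <- b + 1
  }
  runs
}

# Brute-force recruitment delays from a frame list (first activation only).
oracle_delays <- function(frames, n_regions) {
  first <- rep(NA_integer_, n_regions)
  for (j in seq_along(frames))
    for (r in frames[[j]])
      if (is.na(first[r])) first[r] <- j - 1L
  out <- NULL
  for (i in seq_len(n_regions))
    for (j in seq_len(n_regions))
      if (!is.na(first[i]) && !is.na(first[j]) && first[j] > first[i])
        out <- rbind(out, c(i, j, first[j] - first[i]))
  out
}

# Brute-force accumulate-and-divide subject averaging over delay entries.
oracle_subject_mean <- function(entry_list, n_regions) {
  s <- matrix(0, n_regions, n_regions)
  cnt <- matrix(0, n_regions, n_regions)
  for (e in entry_list) {
    if (is.null(e)) next
    for (k in seq_len(nrow(e))) {
      s[e[k, 1], e[k, 2]] <- s[e[k, 1], e[k, 2]] + e[k, 3]
      cnt[e[k, 1], e[k, 2]] <- cnt[e[k, 1], e[k, 2]] + 1
    }
  }
  list(mean = ifelse(cnt > 0, s / cnt, NA_real_), counts = cnt)
}

# Hand-built ground truth on explicit per-edge delays (seconds).
manual_ground_truth <- function(delay_s) {
  labels <- paste0("R", seq_len(nrow(delay_s)))
  dimnames(delay_s) <- list(labels, labels)
  L <- ifelse(is.na(delay_s), NA_real_, 100)
  dimnames(L) <- dimnames(delay_s)
  structure(list(lengths = L, velocity_gt = (L / 1000) / delay_s,
                 delay_gt = delay_s,
                 hemisphere_map = stats::setNames(
                   rep(c("L", "R"), length.out = length(labels)), labels),
                 labels = labels, lesion_mask = NULL, slowdown = 1),
            class = "ground_truth")
}

# Shortest-arrival (first-arrival) bin lags from a seed region, via igraph's
# Dijkstra on the rounded per-edge bin delays.
dijkstra_lags <- function(delay_bins, seed_region) {
  g <- igraph::graph_from_adjacency_matrix(!is.na(delay_bins),
                                           mode = "undirected")
  el <- igraph::as_edgelist(g, names = FALSE)
  igraph::distances(g, v = seed_region, weights = delay_bins[el])[1, ]
}
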