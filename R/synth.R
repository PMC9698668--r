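#' Parameters for the synthetic cascade cohort
#'
#' Bundles every knob of the synthetic ground-truthed cohort generator.
#' Defaults describe the emulated study conditions: a 1024 Hz native
#' sampling rate, a moderately sparse connectome with log-normal
#' (fat-tailed) tract lengths around 70 mm, a velocity law `v = a * L^b`
#' with exponent `b = 0.8` (longer tracts conduct faster, between the
#' constant-velocity null `b = 0` and the homogeneous-delay regime
#' `b = 1`), and a near-critical transmission probability.
#'
#' @param n_regions number of regions (>= 4).
#' @param edge_density probability that a region pair has a direct tract.
#' @param meanlog,sdlog log-normal tract-length parameters (mm).
#' @param a,b velocity-law coefficients, `v = a * L^b` (m/s with L in mm).
#' @param p_t per-edge transmission probability in (0, 1].
#' @param n_avalanches cascades simulated per subject.
#' @param fs sampling rate (Hz) of synthesised time series.
#' @param bin_width samples per bin used for cascade scheduling.
#' @param threshold z magnitude the synthesised pulses must exceed.
#' @param noise_sd background noise standard deviation (> 0).
#' @param horizon_bins cascades lasting longer than this are discarded.
#' @param seed master integer seed.
#' @return list of class `cascade_params`.
#' @export
cascade_params <- function(n_regions = 60, edge_density = 0.1,
                           meanlog = log(70), sdlog = 0.55,
                           a = 0.18, b = 0.8, p_t = 0.12,
                           n_avalanches = 500, fs = 1024, bin_width = 1,
                           threshold = 3, noise_sd = 1,
                           horizon_bins = 500, seed = 1) {
  stopifnot(n_regions >= 4, edge_density > 0, edge_density <= 1,
            a > 0, b >= 0, p_t > 0, p_t <= 1, n_avalanches >= 1,
            fs > 0, bin_width >= 1, noise_sd > 0, horizon_bins >= 1)
  structure(as.list(environment()), class = "cascade_params")
}

#' Generate a synthetic structural connectome
#'
#' Draws a symmetric, connected tract-length matrix: each region pair gets
#' a direct tract with probability `edge_density`, with log-normally
#' distributed (fat-tailed) lengths in mm. Hemisphere labels are assigned
#' half/half. Disconnected draws are retried with an incremented sub-seed.
#'
#' @param params a [cascade_params()] object.
#' @param max_retries retries before giving up on a connected draw.
#' @return list of class `ground_truth` with `lengths` (mm, `NA` = no
#'   tract), `hemisphere_map`, `labels`, empty lesion fields, and
#'   `velocity_gt`/`delay_gt` unset until [assign_velocities()].
#' @export
synth_connectome <- function(params, max_retries = 20) {
  stopifnot(inherits(params, "cascade_params"))
  n <- params$n_regions
  labels <- paste0("R", seq_len(n))
  for (r in 0:max_retries) {
    set.seed(params$seed + 100000 * r)
    up <- upper.tri(matrix(0, n, n))
    present <- matrix(FALSE, n, n)
    present[up] <- stats::runif(sum(up)) < params$edge_density
    L <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
    L[present] <- stats::rlnorm(sum(present), params$meanlog, params$sdlog)
    L[lower.tri(L)] <- t(L)[lower.tri(L)]
    adj <- !is.na(L)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::is_connected(g)) {
      hemi <- stats::setNames(rep(c("L", "R"), c(ceiling(n / 2), floor(n / 2))),
                              labels)
      return(structure(list(lengths = L, velocity_gt = NULL, delay_gt = NULL,
                            hemisphere_map = hemi, labels = labels,
                            lesion_mask = NULL, slowdown = 1),
                       class = "ground_truth"))
    }
  }
  stop("could not draw a connected connectome; raise edge_density", call. = FALSE)
}

#' @export
print.ground_truth <- function(x, ...) {
  ne <- sum(!is.na(x$lengths[upper.tri(x$lengths)]))
  cat(sprintf("<ground_truth> %d regions, %d tracts%s%s\n",
              length(x$labels), ne,
              if (!is.null(x$velocity_gt)) sprintf(", v = %.3g-%.3g m/s",
                min(x$velocity_gt, na.rm = TRUE), max(x$velocity_gt, na.rm = TRUE))
              else "",
              if (!is.null(x$lesion_mask))
                sprintf(", %d lesioned (x%.2g slowdown)",
                        sum(x$lesion_mask[upper.tri(x$lesion_mask)]), x$slowdown)
              else ""))
  invisible(x)
}

#' Assign ground-truth velocities and delays by a length power law
#'
#' Sets `v = a * L^b` m/s on every tract (L in mm) and the implied delay
#' `delay = (L/1000) / v` seconds. `b = 0` gives the constant-velocity
#' null; `b = 1` gives identical delays on all tracts (homogeneous-delay
#' regime).
#'
#' @param gt a `ground_truth` from [synth_connectome()].
#' @param a,b velocity-law coefficients (`a > 0`, `b >= 0`).
#' @return The `ground_truth` with `velocity_gt` and `delay_gt` filled in.
#' @export
assign_velocities <- function(gt, a, b) {
  stopifnot(inherits(gt, "ground_truth"), a > 0, b >= 0)
  v <- a * gt$lengths^b
  gt$velocity_gt <- v
  gt$delay_gt <- (gt$lengths / MM_PER_M) / v
  gt
}

#' Flag random edges as lesioned and slow them down
#'
#' Marks a random fraction of the structural edges as lesioned and
#' multiplies their ground-truth delay by `slowdown` (the delay is slowed,
#' not the length, so the structural matrix stays intact); ground-truth
#' velocities are updated to keep `delay * velocity = length/1000`.
#'
#' @param gt a `ground_truth` with delays assigned.
#' @param fraction fraction of edges to lesion, in (0, 1).
#' @param slowdown multiplicative delay factor (> 1).
#' @param seed integer seed.
#' @return The lesioned `ground_truth` (`lesion_mask`, `slowdown` set).
#' @export
apply_lesions <- function(gt, fraction, slowdown, seed = 1) {
  stopifnot(inherits(gt, "ground_truth"))
  if (is.null(gt$delay_gt)) stop("assign velocities first", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0,1)", call. = FALSE)
  if (slowdown <= 1) stop("'slowdown' must be > 1", call. = FALSE)
  up <- which(upper.tri(gt$lengths) & !is.na(gt$lengths))
  k <- max(1L, round(fraction * length(up)))
  set.seed(seed)
  hit <- sample(up, k)
  mask <- matrix(FALSE, nrow(gt$lengths), ncol(gt$lengths),
                 dimnames = dimnames(gt$lengths))
  mask[hit] <- TRUE
  mask <- mask | t(mask)
  gt$delay_gt[mask] <- gt$delay_gt[mask] * slowdown
  gt$velocity_gt <- (gt$lengths / MM_PER_M) / gt$delay_gt
  gt$lesion_mask <- mask
  gt$slowdown <- slowdown
  gt
}

# Ground-truth per-edge delays in integer bins; errors on zero-bin edges.
delay_bins_of <- function(gt, params) {
  db <- round(gt$delay_gt * params$fs / params$bin_width)
  bad <- !is.na(db) & db < 1
  if (any(bad))
    stop("some edges round to a zero-bin delay; use a finer fs/bin_width ",
         "or longer delays", call. = FALSE)
  db
}

#' Simulate avalanche cascades on the delayed connectome
#'
#' Each cascade starts at a uniformly random seed region at bin 0. When a
#' region activates at bin t it attempts, independently with probability
#' `p_t` per edge, to recruit each structural neighbour w at bin
#' `t + round(delay_gt_uw * fs / bin_width)`; a region is recruited at most
#' once, by whichever attempt arrives first. The cascade ends when the
#' event queue empties; cascades outlasting `horizon_bins` are discarded.
#'
#' @param gt a `ground_truth` with delays (possibly lesion-slowed).
#' @param params a [cascade_params()]; `seed` governs the whole batch.
#' @return list of `avalanche` objects (frames = regions recruited per
#'   bin), each carrying attributes `seed_region` and `arrival_bins`.
#'   The number of horizon-discarded cascades is attached as attribute
#'   `n_discarded_horizon`.
#' @export
simulate_cascades <- function(gt, params) {
  stopifnot(inherits(gt, "ground_truth"), inherits(params, "cascade_params"))
  if (is.null(gt$delay_gt)) stop("assign velocities first", call. = FALSE)
  db <- delay_bins_of(gt, params)
  n <- length(gt$labels)
  nbrs <- lapply(seq_len(n), function(i) which(!is.na(db[i, ])))
  set.seed(params$seed)
  seeds <- sample.int(n, params$n_avalanches, replace = TRUE)
  out <- vector("list", params$n_avalanches)
  discarded <- 0L
  for (c in seq_len(params$n_avalanches)) {
    arrival <- rep(NA_integer_, n)
    qt <- 0L; qr <- seeds[c]          # pending arrivals (times, regions)
    while (length(qt)) {
      k <- which.min(qt)
      t <- qt[k]; u <- qr[k]
      qt <- qt[-k]; qr <- qr[-k]
      if (!is.na(arrival[u])) next
      arrival[u] <- t
      cand <- nbrs[[u]]
      cand <- cand[is.na(arrival[cand])]
      if (length(cand)) {
        fire <- cand[stats::runif(length(cand)) < params$p_t]
        if (length(fire)) {
          qt <- c(qt, t + db[u, fire])
          qr <- c(qr, fire)
        }
      }
    }
    Tmax <- max(arrival, na.rm = TRUE)
    if (Tmax > params$horizon_bins) { discarded <- discarded + 1L; next }
    frames <- lapply(0:Tmax, function(b) which(arrival == b))
    av <- new_avalanche(0L, frames, gt$labels)
    attr(av, "seed_region") <- seeds[c]
    attr(av, "arrival_bins") <- arrival
    out[[c]] <- av
  }
  out <- out[!vapply(out, is.null, logical(1))]
  attr(out, "n_discarded_horizon") <- discarded
  attr(out, "delay_bins") <- db
  out
}

#' Synthesise continuous time series from simulated cascades
#'
#' Embeds the cascades in background Gaussian noise so that the full
#' detection pipeline (z-score, threshold, bin, segment) recovers them
#' exactly: each recruited region holds a suprathreshold excursion from its
#' recruitment bin to the cascade's last recruitment bin (one onset per
#' recruitment), with a random sign. Inter-cascade gaps (>= 4 empty bins,
#' also padding both recording ends) are stretched so that no region's duty
#' cycle exceeds `1 / (1 + (threshold + 2.5)^2)`, and excursion amplitudes
#' are scaled per region so that after z-scoring pulses exceed the
#' threshold while background noise stays far below it.
#'
#' @param avalanches cascades from [simulate_cascades()].
#' @param params the matching [cascade_params()].
#' @return A [source_ts()] at `params$fs`, with attribute `cascade_starts`
#'   (1-based start bin of each cascade on the width-`bin_width` bin axis).
#' @export
synthesize_timeseries <- function(avalanches, params) {
  stopifnot(inherits(params, "cascade_params"))
  if (length(avalanches) == 0L) stop("no cascades to embed", call. = FALSE)
  labels <- avalanches[[1L]]$labels
  n <- length(labels)
  w <- as.integer(params$bin_width)
  ncasc <- length(avalanches)
  times <- lapply(avalanches, recruitment_times)
  Tc <- vapply(avalanches, function(a) a$n_bins, integer(1))
  # active bins per region per cascade (recruitment..cascade end)
  active <- matrix(0L, n, ncasc)
  for (c in seq_len(ncasc)) {
    rec <- which(!is.na(times[[c]]))
    active[rec, c] <- Tc[c] - times[[c]][rec]
  }
  duty_cap <- 1 / (1 + (params$threshold + 2.5)^2)
  busiest <- max(rowSums(active))
  g0 <- 4L
  natural <- sum(Tc) + g0 * (ncasc + 1L)
  total_bins <- max(natural, ceiling(busiest / duty_cap))
  gap <- g0 + ceiling(max(0, total_bins - natural) / (ncasc + 1L))
  starts <- cumsum(c(gap, Tc[-ncasc] + gap))          # 0-based start bins
  total_bins <- starts[ncasc] + Tc[ncasc] + gap
  n_samples <- total_bins * w
  set.seed(params$seed + 777)
  x <- matrix(stats::rnorm(n * n_samples, sd = params$noise_sd), n, n_samples)
  duty <- rowSums(active) / total_bins
  amp <- ifelse(duty > 0,
                10 * params$noise_sd / sqrt(duty * (1 - duty)), 0)
  for (c in seq_len(ncasc)) {
    rec <- which(!is.na(times[[c]]))
    sgn <- sample(c(-1, 1), length(rec), replace = TRUE)
    for (m in seq_along(rec)) {
      r <- rec[m]
      b0 <- starts[c] + times[[c]][r]                 # 0-based global bin
      smp <- (b0 * w + 1L):((starts[c] + Tc[c]) * w)
      x[r, smp] <- x[r, smp] + sgn[m] * amp[r]
    }
  }
  rownames(x) <- labels
  ts <- source_ts(x, params$fs)
  attr(ts, "cascade_starts") <- starts + 1L
  ts
}

#' Generate a full synthetic cohort with known ground truth
#'
#' Builds one shared connectome with a length-dependent velocity law, then
#' simulates independent cascade sets per subject. Patients receive a
#' per-subject lesion mask whose edges have their ground-truth delays
#' multiplied by `slowdown`. Optionally writes the on-disk bundle consumed
#' by [run_pipeline()] (manifest, lengths, per-subject time series and
#' lesion masks, ground-truth JSON).
#'
#' @param params a [cascade_params()].
#' @param n_controls,n_patients subject counts (study design: 20 and 18).
#' @param lesion list with `fraction` and `slowdown` for patients.
#' @param timeseries also synthesise continuous time series per subject
#'   (needed for the on-disk bundle; the in-memory cascades are always
#'   returned).
#' @param dir if non-`NULL`, write the bundle under this directory.
#' @return list of class `synthetic_cohort`: `ground_truth`, `subjects`
#'   (per subject: `id`, `group`, `avalanches`, optional `ts`, patients also
#'   `lesion_mask` and lesioned `ground_truth`), `manifest` (data.frame),
#'   `params`.
#' @export
make_cohort <- function(params = cascade_params(), n_controls = 20,
                        n_patients = 18,
                        lesion = list(fraction = 0.2, slowdown = 1.5),
                        timeseries = FALSE, dir = NULL) {
  stopifnot(n_controls >= 1, n_patients >= 0)
  gt <- assign_velocities(synth_connectome(params), params$a, params$b)
  ids <- c(paste0("C", seq_len(n_controls)),
           if (n_patients > 0) paste0("P", seq_len(n_patients)))
  groups <- rep(c("control", "patient"), c(n_controls, n_patients))
  subjects <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    sp <- params
    sp$seed <- params$seed + 1000L + s
    gt_s <- gt
    if (groups[s] == "patient") {
      gt_s <- apply_lesions(gt, lesion$fraction, lesion$slowdown,
                            seed = params$seed + 5000L + s)
    }
    av <- simulate_cascades(gt_s, sp)
    rec <- list(id = ids[s], group = groups[s], avalanches = av,
                seed = sp$seed)
    if (groups[s] == "patient") {
      rec$lesion_mask <- gt_s$lesion_mask
      rec$ground_truth <- gt_s
    }
    if (timeseries) rec$ts <- synthesize_timeseries(av, sp)
    subjects[[s]] <- rec
  }
  names(subjects) <- ids
  manifest <- data.frame(id = ids, group = groups,
                         seed = params$seed + 1000L + seq_along(ids))
  cohort <- structure(list(ground_truth = gt, subjects = subjects,
                           manifest = manifest, params = params),
                      class = "synthetic_cohort")
  if (!is.null(dir)) write_cohort_bundle(cohort, dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d controls + %d patients, %d regions, %d cascades/subject\n",
              sum(x$manifest$group == "control"),
              sum(x$manifest$group == "patient"),
              x$params$n_regions, x$params$n_avalanches))
  invisible(x)
}
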