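#' Time-shuffle an avalanche
#'
#' Draws a uniformly random permutation of the avalanche's time frames while
#' leaving the regions recruited at each frame untouched: temporal structure
#' is destroyed, spatial structure (size, duration, per-frame region sets)
#' is preserved.
#'
#' @param a an `avalanche`.
#' @param seed optional integer seed for reproducibility.
#' @return An `avalanche` with permuted frames.
#' @export
shuffle_avalanche <- function(a, seed = NULL) {
  stopifnot(inherits(a, "avalanche"))
  if (!is.null(seed)) set.seed(seed)
  if (a$n_bins > 1L) {
    perm <- sample.int(a$n_bins)
    a$frames <- a$frames[perm]
    a$n_events_per_bin <- a$n_events_per_bin[perm]
  }
  a
}

#' Surrogate delay ensemble from time-shuffled avalanches
#'
#' For each of `n_perm` permutations every avalanche is independently
#' time-shuffled and the subject delay matrix recomputed, yielding a null
#' distribution of mean delays per edge under destroyed temporal (but
#' preserved spatial) structure. Permutation k uses the derived seed
#' `seed + k`, making the ensemble fully reproducible.
#'
#' @param avalanches list of `avalanche` objects.
#' @param n_perm number of permutations (default 1000).
#' @param seed root integer seed.
#' @param bin_width,fs time-base of the parent raster.
#' @param symmetrize store undirected (i < j) edge delays (default) or
#'   directed pairs.
#' @return Object of class `surrogate_ensemble`: list with `edges`
#'   (two-column index matrix over the union of edges observed in any
#'   permutation), `delays` (edges x n_perm matrix, `NA` where an edge was
#'   unobserved in that permutation), `labels`, `n_perm`, `seed`.
#' @export
surrogate_delay_ensemble <- function(avalanches, n_perm = 1000, seed = 1,
                                     bin_width = 1, fs = 1, symmetrize = TRUE) {
  if (n_perm < 1) stop("'n_perm' must be >= 1", call. = FALSE)
  if (length(avalanches) == 0L) stop("no avalanches", call. = FALSE)
  labels <- avalanches[[1L]]$labels
  n <- length(labels)
  scale <- bin_width / fs
  # per avalanche: frame index of each event occurrence (region, frame)
  ev <- lapply(avalanches, function(a) {
    reg <- unlist(a$frames, use.names = FALSE)
    frame <- rep.int(seq_along(a$frames), a$n_events_per_bin)
    list(reg = reg, frame = frame, n_bins = a$n_bins)
  })
  mats <- vector("list", n_perm)
  for (k in seq_len(n_perm)) {
    set.seed(seed + k)
    times <- lapply(ev, function(e) {
      perm <- if (e$n_bins > 1L) sample.int(e$n_bins) else 1L
      t <- rep(NA_integer_, n)
      pos <- perm[e$frame]            # new frame position of each event
      o <- order(pos)
      first <- !duplicated(e$reg[o])  # earliest occurrence per region
      t[e$reg[o][first]] <- pos[o][first] - 1L
      t
    })
    acc <- accumulate_times(times, n, scale)
    m <- acc$sum / ifelse(acc$counts > 0L, acc$counts, NA_real_)
    if (symmetrize) {
      s <- ifelse(acc$counts > 0L, m * acc$counts, 0); s <- s + t(s)
      cnt <- acc$counts + t(acc$counts)
      m <- s / ifelse(cnt > 0L, cnt, NA_real_)
      m[lower.tri(m, diag = TRUE)] <- NA_real_
    } else diag(m) <- NA_real_
    mats[[k]] <- m
  }
  union_pres <- Reduce(`|`, lapply(mats, is.finite))
  idx <- which(union_pres, arr.ind = TRUE)
  o <- order(idx[, 1L], idx[, 2L])
  idx <- idx[o, , drop = FALSE]
  delays <- vapply(mats, function(m) m[idx], numeric(nrow(idx)))
  delays <- matrix(delays, nrow = nrow(idx), ncol = n_perm)
  structure(list(edges = cbind(from = as.integer(idx[, 1L]),
                               to = as.integer(idx[, 2L])),
                 delays = delays, labels = labels,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 symmetrized = symmetrize),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("<surrogate_ensemble> %d edges x %d permutations (seed %d)\n",
              nrow(x$edges), x$n_perm, x$seed))
  invisible(x)
}

#' Correlation between tract length and delay (or velocity)
#'
#' Rank (Spearman, default) or linear (Pearson) correlation over the edges
#' present in both the value matrix and the structural length matrix.
#'
#' @param d a `delay_matrix` or `velocity_matrix`.
#' @param L tract-length matrix (mm).
#' @param method `"spearman"` or `"pearson"`.
#' @return list with `r`, `p`, `n` (number of paired edges), `method`.
#' @export
length_delay_correlation <- function(d, L, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  pe <- paired_edges(d, L)
  if (nrow(pe) < 3L) stop("fewer than 3 paired edges", call. = FALSE)
  if (stats::sd(pe$value) == 0 || stats::sd(pe$length) == 0)
    return(list(r = 0, p = 1, n = nrow(pe), method = method))
  ct <- suppressWarnings(
    stats::cor.test(pe$length, pe$value, method = method, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(pe), method = method)
}

#' Empirical p-value of a correlation against the surrogate null
#'
#' Recomputes the length-value correlation for every surrogate delay matrix
#' in the ensemble and locates the observed correlation in that null with
#' the add-one (permutation-inclusive) estimator
#' `p = (1 + #more-extreme) / (1 + n_perm)`.
#'
#' @param observed_r the observed correlation.
#' @param ensemble a `surrogate_ensemble`.
#' @param L tract-length matrix (mm), aligned with the ensemble's labels.
#' @param side `"greater"`: surrogates at least as large as observed count
#'   as extreme; `"less"`: at most as large.
#' @param method correlation method (default Spearman, as for the observed).
#' @return list with `p`, `surrogate_r` (length `n_perm`), `side`.
#' @export
correlation_null_test <- function(observed_r, ensemble, L,
                                  side = c("greater", "less"),
                                  method = "spearman") {
  side <- match.arg(side)
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  if (!identical(rownames(L), ensemble$labels))
    stop("length matrix labels do not match the ensemble", call. = FALSE)
  len <- L[ensemble$edges]
  ok_len <- is.finite(len) & len > 0
  rs <- apply(ensemble$delays, 2L, function(dl) {
    use <- ok_len & is.finite(dl)
    if (sum(use) < 3L) return(NA_real_)
    stats::cor(len[use], dl[use], method = method)
  })
  rs <- rs[is.finite(rs)]
  n <- length(rs)
  if (n == 0L) stop("no surrogate correlation could be computed", call. = FALSE)
  extreme <- if (side == "greater") sum(rs >= observed_r) else sum(rs <= observed_r)
  list(p = (1 + extreme) / (1 + n), surrogate_r = rs, side = side, n_perm = n)
}

#' Kolmogorov-Smirnov comparison of two delay distributions
#'
#' Two-sample KS test between per-edge (or per-percentile) mean delays of
#' two groups, plus both empirical CDFs for plotting/export.
#'
#' @param control_delays,patient_delays numeric vectors of delays (s).
#' @return list with `D`, `p`, and `cdf` (data.frame `value`, `ecdf_control`,
#'   `ecdf_patient` evaluated on the pooled sorted values).
#' @export
ks_compare_groups <- function(control_delays, patient_delays) {
  x <- control_delays[is.finite(control_delays)]
  y <- patient_delays[is.finite(patient_delays)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(x, y))
  grid <- sort(unique(c(x, y)))
  cdf <- data.frame(value = grid,
                    ecdf_control = stats::ecdf(x)(grid),
                    ecdf_patient = stats::ecdf(y)(grid))
  list(D = unname(kt$statistic), p = kt$p.value, cdf = cdf)
}

#' Edge-wise patient-minus-control delay differences
#'
#' For each patient and each complete-coverage edge where the patient has a
#' delay estimate, the difference between the patient's delay and the
#' control-group mean delay at that edge, flagged lesioned/healthy from the
#' patient's lesion mask.
#'
#' @param patients list of (symmetrised or directed) `delay_matrix`, one per
#'   patient; names are used as patient ids.
#' @param controls_mean group-level `delay_matrix` of the controls.
#' @param coverage edge matrix from [complete_coverage_edges()].
#' @param masks list of symmetric logical/0-1 lesion matrices aligned with
#'   `patients` (same order), or `NULL` for no lesion information.
#' @return data.frame of class `edgewise_differences` with columns
#'   `patient`, `from`, `to`, `difference` (s), `lesioned`.
#' @export
edgewise_differences <- function(patients, controls_mean, coverage,
                                 masks = NULL) {
  if (nrow(coverage) == 0L) stop("empty coverage edge set", call. = FALSE)
  if (!is.null(masks) && length(masks) != length(patients))
    stop("'masks' must align one-to-one with 'patients'", call. = FALSE)
  labels <- region_labels_of(controls_mean)
  ids <- names(patients)
  if (is.null(ids)) ids <- paste0("P", seq_along(patients))
  out <- vector("list", length(patients))
  for (k in seq_along(patients)) {
    d <- patients[[k]]
    check_aligned(d, controls_mean)
    dsym <- symmetrize_delays(d)
    pd <- dsym$mean[coverage]
    cd <- symmetrize_delays(controls_mean)$mean[coverage]
    les <- if (is.null(masks)) rep(FALSE, nrow(coverage))
           else masks[[k]][coverage] > 0
    keep <- is.finite(pd) & is.finite(cd)
    out[[k]] <- data.frame(patient = ids[k],
                           from = labels[coverage[keep, 1L]],
                           to = labels[coverage[keep, 2L]],
                           difference = pd[keep] - cd[keep],
                           lesioned = les[keep])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("edgewise_differences", "data.frame")
  res
}

#' Lesioned-edge permutation test
#'
#' Tests whether delays on structurally lesioned edges slowed more than
#' expected: the observed statistic is the mean patient-minus-control delay
#' difference over lesioned records; the null draws `n_perm` random subsets
#' of the same size from the pooled differences and takes their means.
#' One-sided p (lesioned slower) with the add-one estimator.
#'
#' @param diffs an `edgewise_differences` data.frame.
#' @param n_perm number of random subsets (default 1000).
#' @param seed integer seed.
#' @param null_pool `"all"` (default; subsets drawn from all records, as the
#'   ignore-structure null) or `"nonlesioned"` (stricter).
#' @param side `"greater"` (default: lesioned edges slowed more) or
#'   `"two.sided"`.
#' @return list with `observed_mean`, `null_distribution`, `p`,
#'   `n_lesioned`, `n_records`.
#' @export
lesion_permutation_test <- function(diffs, n_perm = 1000, seed = 1,
                                    null_pool = c("all", "nonlesioned"),
                                    side = c("greater", "two.sided")) {
  null_pool <- match.arg(null_pool)
  side <- match.arg(side)
  les <- diffs$difference[diffs$lesioned]
  if (length(les) == 0L) stop("no lesioned records", call. = FALSE)
  if (!any(!diffs$lesioned)) stop("no non-lesioned records", call. = FALSE)
  pool <- if (null_pool == "all") diffs$difference
          else diffs$difference[!diffs$lesioned]
  observed <- mean(les)
  m <- length(les)
  set.seed(seed)
  null_dist <- vapply(seq_len(n_perm),
                      function(i) mean(pool[sample.int(length(pool), m)]),
                      numeric(1))
  extreme <- if (side == "greater") sum(null_dist >= observed)
             else sum(abs(null_dist - mean(pool)) >= abs(observed - mean(pool)))
  list(observed_mean = observed, null_distribution = null_dist,
       p = (1 + extreme) / (1 + n_perm),
       n_lesioned = m, n_records = nrow(diffs), side = side,
       null_pool = null_pool)
}

#' Convergence of the group delay matrix with sample size
#'
#' For random orderings of the subjects, computes for each cumulative
#' sample size x = 2..N the mean over edges of the absolute change of the
#' group-mean delay when the x-th subject is added, i.e.
#' `mean |groupmean(x subjects) - groupmean(x-1 subjects)|` over the edges
#' present in both aggregates. The curve shrinking toward zero indicates
#' that the group delay matrix has converged.
#'
#' @param subjects list of `delay_matrix` objects.
#' @param n_orders number of random subject orderings to average over.
#' @param seed integer seed.
#' @return list of class `convergence_curve` with `sizes` (2..N), `curves`
#'   (`n_orders` x length(sizes) matrix) and `median_curve`.
#' @export
convergence_curve <- function(subjects, n_orders = 10, seed = 1) {
  N <- length(subjects)
  if (N < 2L) stop("need at least 2 subjects", call. = FALSE)
  for (s in subjects) check_aligned(subjects[[1L]], s)
  n <- nrow(subjects[[1L]]$mean)
  set.seed(seed)
  sizes <- 2:N
  curves <- matrix(NA_real_, n_orders, length(sizes))
  for (o in seq_len(n_orders)) {
    ord <- sample.int(N)
    s <- matrix(0, n, n); cnt <- matrix(0L, n, n)
    prev <- NULL
    for (x in seq_len(N)) {
      d <- subjects[[ord[x]]]
      pres <- d$counts > 0L
      s[pres] <- s[pres] + d$mean[pres]
      cnt <- cnt + pres
      cur <- s / ifelse(cnt > 0L, cnt, NA_real_)
      if (x >= 2L) {
        both <- is.finite(cur) & is.finite(prev)
        curves[o, x - 1L] <- mean(abs(cur[both] - prev[both]))
      }
      prev <- cur
    }
  }
  structure(list(sizes = sizes, curves = curves,
                 median_curve = apply(curves, 2L, stats::median)),
            class = "convergence_curve")
}

#' @export
print.convergence_curve <- function(x, ...) {
  cat(sprintf("<convergence_curve> N = %d subjects, median |delta|: %.3g (x=2) -> %.3g (x=%d)\n",
              max(x$sizes), x$median_curve[1L],
              x$median_curve[length(x$median_curve)], max(x$sizes)))
  invisible(x)
}
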