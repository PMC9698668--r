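test_that("the three-region worked example yields recruitment delays of 3 and 5 timesteps", {
  # region i starts the avalanche, j follows 3 timesteps later, z after 5
  av <- topochron:::new_avalanche(
    2L, list(1L, integer(0), integer(0), 2L, integer(0), 3L),
    c("i", "j", "z"))
  d <- avalanche_delays(av, bin_width = 1, fs = 1)
  get <- function(f, t) d$delay[d$from == f & d$to == t]
  expect_equal(get("i", "j"), 3)
  expect_equal(get("i", "z"), 5)
  expect_equal(get("j", "z"), 2)   # all ordered pairs are recorded
  expect_equal(nrow(d), 3)

  # delays are converted to seconds by bin_width / fs
  d2 <- avalanche_delays(av, bin_width = 3, fs = 512)
  expect_equal(d2$delay[d2$from == "i" & d2$to == "j"], 3 * 3 / 512)

  # simultaneous recruitment emits nothing
  sim <- make_avalanche(list(c(1L, 2L, 3L)), 3)
  expect_equal(nrow(avalanche_delays(sim)), 0)
})

test_that("subject averaging disregards missing entries and matches the brute-force oracle", {
  # pair observed at 2 ms and 4 ms plus one avalanche without the pair
  a1 <- make_avalanche(list(1L, integer(0), 2L), 3)      # delay 2 bins
  a2 <- make_avalanche(list(1L, integer(0), integer(0), integer(0), 2L), 3)
  a3 <- make_avalanche(list(3L), 3)
  dm <- subject_delay_matrix(list(a1, a2, a3), bin_width = 1, fs = 1000)
  expect_equal(dm$mean[1, 2], 0.003)                      # (2 + 4)/2 ms
  expect_equal(dm$counts[1, 2], 2)
  expect_true(is.na(dm$mean[1, 3]))                       # never observed
  expect_equal(dm$counts[1, 3], 0)

  # 50 random avalanches against independent accumulation
  set.seed(21)
  n <- 6
  avs <- lapply(1:50, function(i) {
    nb <- sample(1:6, 1)
    frames <- lapply(seq_len(nb), function(j)
      which(runif(n) < 0.3))
    make_avalanche(frames, n)
  })
  dm2 <- subject_delay_matrix(avs, bin_width = 2, fs = 100)
  oracle <- oracle_subject_mean(
    lapply(avs, function(a) oracle_delays(a$frames, n)), n)
  expect_equal(unname(dm2$mean), oracle$mean * 2 / 100)
  expect_equal(unname(dm2$counts), oracle$counts, ignore_attr = TRUE)

  # precomputed-entries path agrees with the avalanche path
  dm3 <- subject_delay_matrix(lapply(avs, avalanche_delays,
                                     bin_width = 2, fs = 100),
                              region_labels = paste0("R", 1:n))
  expect_equal(dm3$mean, dm2$mean)
  expect_equal(dm3$counts, dm2$counts)

  # permutation invariance
  dm4 <- subject_delay_matrix(rev(avs), bin_width = 2, fs = 100)
  expect_equal(dm4$mean, dm2$mean)
})

test_that("group averaging discards absent subject entries", {
  lab <- c("a", "b", "c")
  mk <- function(v12) {
    m <- matrix(NA_real_, 3, 3, dimnames = list(lab, lab))
    cnt <- matrix(0L, 3, 3, dimnames = list(lab, lab))
    if (!is.na(v12)) { m[1, 2] <- v12; cnt[1, 2] <- 1L }
    topochron:::new_delay_matrix(m, cnt)
  }
  g <- group_delay_matrix(list(mk(0.003), mk(NA), mk(0.005)))
  expect_equal(g$mean[1, 2], 0.004)
  expect_equal(g$counts[1, 2], 2)

  single <- mk(0.007)
  expect_equal(group_delay_matrix(list(single))$mean, single$mean)

  set.seed(8)
  subs <- lapply(1:10, function(i) {
    m <- matrix(runif(16, 0.001, 0.02), 4, 4)
    m[runif(16) < 0.4] <- NA
    diag(m) <- NA
    cnt <- matrix(as.integer(!is.na(m)), 4, 4)
    dimnames(m) <- dimnames(cnt) <- list(paste0("R", 1:4), paste0("R", 1:4))
    topochron:::new_delay_matrix(m, cnt)
  })
  g2 <- group_delay_matrix(subs)
  for (i in 1:4) for (j in 1:4) {
    vals <- sapply(subs, function(s) s$mean[i, j])
    vals <- vals[!is.na(vals)]
    if (length(vals)) expect_equal(g2$mean[i, j], mean(vals))
    else expect_true(is.na(g2$mean[i, j]))
  }
  expect_equal(group_delay_matrix(rev(subs))$mean, g2$mean)
  expect_error(group_delay_matrix(list(subs[[1]], mk(0.1))), "aligned")
})

test_that("complete-coverage edges are present in every control", {
  lab <- paste0("R", 1:5)
  mk <- function(pairs) {
    m <- matrix(NA_real_, 5, 5, dimnames = list(lab, lab))
    cnt <- matrix(0L, 5, 5, dimnames = list(lab, lab))
    for (p in pairs) { m[p[1], p[2]] <- 0.01; cnt[p[1], p[2]] <- 1L }
    topochron:::new_delay_matrix(m, cnt)
  }
  c1 <- mk(list(c(1, 2), c(1, 3), c(2, 4), c(3, 5)))
  c2 <- mk(list(c(2, 1), c(3, 1), c(4, 2)))   # same 3 edges, other direction
  cov <- complete_coverage_edges(list(c1, c2))
  expect_equal(nrow(cov), 3)
  expect_equal(cov[, "from"], c(1L, 1L, 2L), ignore_attr = TRUE)
  expect_equal(cov[, "to"], c(2L, 3L, 4L), ignore_attr = TRUE)

  expect_equal(nrow(complete_coverage_edges(list(c1, mk(list())))), 0)

  # random sparse matrices against a set-intersection oracle
  set.seed(13)
  ctrls <- lapply(1:6, function(i)
    mk(apply(which(upper.tri(diag(5)) &
                   matrix(runif(25) < 0.5, 5), arr.ind = TRUE), 1, identity,
             simplify = FALSE)))
  cov2 <- complete_coverage_edges(ctrls)
  oracle <- Reduce(intersect, lapply(ctrls, function(d) {
    s <- topochron:::symmetrize_delays(d)
    which(s$counts > 0 & upper.tri(s$counts))
  }))
  expect_setequal(cov2[, 1] + (cov2[, 2] - 1L) * 5L, oracle)
})

test_that("velocities are length/delay on structurally connected pairs only", {
  lab <- c("a", "b", "c")
  L <- matrix(NA_real_, 3, 3, dimnames = list(lab, lab))
  L[1, 2] <- L[2, 1] <- 150
  m <- matrix(NA_real_, 3, 3, dimnames = list(lab, lab))
  cnt <- matrix(0L, 3, 3, dimnames = list(lab, lab))
  m[1, 2] <- 0.010; cnt[1, 2] <- 1L      # 10 ms on the tract
  m[1, 3] <- 0.005; cnt[1, 3] <- 1L      # delay without a tract
  d <- topochron:::new_delay_matrix(m, cnt)
  V <- velocity_matrix(d, L)
  expect_equal(V$velocity[1, 2], 15)     # 150 mm / 10 ms = 15 m/s
  expect_equal(V$velocity[2, 1], 15)
  expect_true(is.na(V$velocity[1, 3]))   # no structural tract -> absent

  # random elementwise oracle, symmetrised delays
  set.seed(17)
  n <- 6; lab2 <- paste0("R", 1:n)
  L2 <- matrix(runif(n * n, 20, 200), n, n, dimnames = list(lab2, lab2))
  L2[lower.tri(L2)] <- t(L2)[lower.tri(L2)]; diag(L2) <- NA
  m2 <- matrix(runif(n * n, 0.002, 0.03), n, n, dimnames = list(lab2, lab2))
  diag(m2) <- NA
  cnt2 <- matrix(rpois(n * n, 3), n, n, dimnames = list(lab2, lab2))
  cnt2[is.na(m2)] <- 0L
  m2[cnt2 == 0] <- NA
  d2 <- topochron:::new_delay_matrix(m2, cnt2)
  V2 <- velocity_matrix(d2, L2)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    num <- sum(m2[i, j] * cnt2[i, j], m2[j, i] * cnt2[j, i], na.rm = TRUE)
    den <- cnt2[i, j] + cnt2[j, i]
    if (den > 0) expect_equal(V2$velocity[i, j], (L2[i, j] / 1000) / (num / den),
                              tolerance = 1e-12)
  }

  # round trip: constant-velocity delays recover the constant everywhere
  exp_d <- constant_velocity_expectation(L2, 7.5)
  Vc <- velocity_matrix(exp_d, L2)
  expect_equal(unique(round(Vc$velocity[is.finite(Vc$velocity)], 12)), 7.5)
})

test_that("constant-velocity expected delays are linear in length", {
  L <- matrix(c(NA, 60, 60, NA), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  d <- constant_velocity_expectation(L, 6)
  expect_equal(d$mean[1, 2], 0.010)                     # 60 mm at 6 m/s
  expect_equal(constant_velocity_expectation(L * 2, 6)$mean[1, 2], 0.020)
  set.seed(2)
  n <- 5
  L2 <- matrix(runif(25, 10, 300), n, n); diag(L2) <- NA
  L2[lower.tri(L2)] <- t(L2)[lower.tri(L2)]
  dimnames(L2) <- list(paste0("R", 1:n), paste0("R", 1:n))
  for (v in c(2, 5, 10)) {
    dv <- constant_velocity_expectation(L2, v)
    expect_equal(dv$mean[1, 2], (L2[1, 2] / 1000) / v, tolerance = 1e-12)
    expect_equal(dv$mean, t(dv$mean))
  }
})

test_that("percentile profiles average values within equal-count length bins", {
  lab <- paste0("R", 1:5)
  L <- matrix(NA_real_, 5, 5, dimnames = list(lab, lab))
  m <- matrix(NA_real_, 5, 5, dimnames = list(lab, lab))
  cnt <- matrix(0L, 5, 5, dimnames = list(lab, lab))
  lens <- c(10, 20, 30, 40); dels <- c(0.001, 0.001, 0.003, 0.003)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3), c(4, 5))
  for (k in 1:4) {
    p <- pairs[[k]]
    L[p[1], p[2]] <- L[p[2], p[1]] <- lens[k]
    m[p[1], p[2]] <- dels[k]; cnt[p[1], p[2]] <- 1L
  }
  d <- topochron:::new_delay_matrix(m, cnt)
  pp <- percentile_profile(d, L, 2)
  expect_equal(pp$mean_value_per_bin, c(0.001, 0.003))
  expect_equal(percentile_profile(d, L, 1)$mean_value_per_bin, 0.002)
  expect_error(percentile_profile(d, L, 10), "smaller n_bins")

  # 500 random edges, 100 bins, against an independent sort-and-chunk oracle
  set.seed(23)
  n <- 40; lab2 <- paste0("R", 1:n)
  L2 <- matrix(NA_real_, n, n, dimnames = list(lab2, lab2))
  m2 <- matrix(NA_real_, n, n, dimnames = list(lab2, lab2))
  cnt2 <- matrix(0L, n, n, dimnames = list(lab2, lab2))
  up <- which(upper.tri(L2))
  sel <- sample(up, 500)
  L2[sel] <- runif(500, 10, 250)
  m2[sel] <- runif(500, 0.002, 0.03)
  cnt2[sel] <- 1L
  L2[lower.tri(L2)] <- t(L2)[lower.tri(L2)]
  pp2 <- percentile_profile(topochron:::new_delay_matrix(m2, cnt2), L2, 100)
  o <- order(L2[sel])
  chunk <- split(m2[sel][o], ceiling(seq_len(500) * 100 / 500))
  expect_equal(pp2$mean_value_per_bin, unname(sapply(chunk, mean)),
               tolerance = 1e-12)
})

test_that("the fast-edge subgraph keeps velocities above threshold with hemisphere tags", {
  lab <- paste0("R", 1:4)
  v <- matrix(NA_real_, 4, 4, dimnames = list(lab, lab))
  v[1, 2] <- v[2, 1] <- 10
  v[1, 3] <- v[3, 1] <- 16
  v[2, 4] <- v[4, 2] <- 20
  V <- structure(list(velocity = v), class = "velocity_matrix")
  hemi <- setNames(c("L", "L", "R", "R"), lab)
  fe <- fast_edge_subgraph(V, 15, hemi)
  expect_equal(nrow(fe), 2)
  expect_equal(fe$velocity, c(20, 16))
  expect_equal(fe$hemisphere_tag, c("cross", "cross"))
  expect_equal(nrow(fast_edge_subgraph(V, 25, hemi)), 0)
  expect_warning(fast_edge_subgraph(V, 15), "hemisphere")
})

test_that("missingness propagates and no present delay or velocity is non-positive", {
  # all-single-frame avalanches produce an entirely absent delay matrix
  avs <- lapply(1:5, function(i) make_avalanche(list(c(1L, 2L)), 3))
  dm <- subject_delay_matrix(avs, bin_width = 1, fs = 100)
  expect_true(all(is.na(dm$mean)))
  expect_true(all(dm$counts == 0))

  set.seed(31)
  avs2 <- lapply(1:30, function(i)
    make_avalanche(lapply(1:sample(1:5, 1), function(j) which(runif(5) < 0.4)), 5))
  dm2 <- subject_delay_matrix(avs2, bin_width = 3, fs = 512)
  pres <- dm2$counts > 0
  expect_true(all(dm2$mean[pres] > 0))
  expect_true(all(is.na(dm2$mean[!pres])))
})
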