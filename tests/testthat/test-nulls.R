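test_that("time-shuffling permutes frames uniformly while conserving their contents", {
  a1 <- make_avalanche(list(1L), 3)
  expect_identical(shuffle_avalanche(a1, seed = 1)$frames, a1$frames)

  a2 <- make_avalanche(list(1L, c(2L, 3L)), 3)
  swapped <- 0L
  for (s in 1:1000)
    if (identical(shuffle_avalanche(a2, seed = s)$frames[[1]], c(2L, 3L)))
      swapped <- swapped + 1L
  expect_gt(swapped, 437)   # within 4 sd of Binomial(1000, 1/2)
  expect_lt(swapped, 563)

  set.seed(41)
  a3 <- make_avalanche(lapply(1:6, function(j) which(runif(5) < 0.5)), 5)
  sh <- shuffle_avalanche(a3, seed = 9)
  expect_equal(sh$n_bins, a3$n_bins)
  expect_equal(sort(sh$n_events_per_bin), sort(a3$n_events_per_bin))
  expect_setequal(lapply(sh$frames, sort), lapply(a3$frames, sort))
})

test_that("the surrogate delay ensemble is reproducible and matches a reference run", {
  set.seed(43)
  avs <- lapply(1:3, function(i)
    make_avalanche(lapply(1:4, function(j) which(runif(4) < 0.5)), 4))
  ens <- surrogate_delay_ensemble(avs, n_perm = 10, seed = 7,
                                  bin_width = 2, fs = 100,
                                  symmetrize = FALSE)
  # independently coded reference with the same per-permutation seed protocol
  for (k in 1:10) {
    set.seed(7 + k)
    ref <- oracle_subject_mean(lapply(avs, function(a) {
      perm <- if (a$n_bins > 1) sample.int(a$n_bins) else 1L
      oracle_delays(a$frames[order(perm)], 4)
    }), 4)
    got <- matrix(NA_real_, 4, 4)
    got[ens$edges] <- ens$delays[, k]
    expect_equal(got, ref$mean * 2 / 100, tolerance = 1e-12)
  }
  ens2 <- surrogate_delay_ensemble(avs, n_perm = 10, seed = 7,
                                   bin_width = 2, fs = 100,
                                   symmetrize = FALSE)
  expect_identical(ens$delays, ens2$delays)

  # degenerate inputs: single-frame or single-region avalanches give nothing
  empty1 <- surrogate_delay_ensemble(lapply(1:3, function(i)
    make_avalanche(list(c(1L, 2L)), 3)), n_perm = 5, seed = 1)
  expect_equal(nrow(empty1$edges), 0)
  empty2 <- surrogate_delay_ensemble(lapply(1:3, function(i)
    make_avalanche(list(1L, 1L, 1L), 3)), n_perm = 5, seed = 1)
  expect_equal(nrow(empty2$edges), 0)
})

test_that("length-delay correlations behave on exact and random inputs", {
  lab <- paste0("R", 1:6)
  L <- matrix(NA_real_, 6, 6, dimnames = list(lab, lab))
  up <- which(upper.tri(L))
  set.seed(47)
  L[up] <- runif(length(up), 20, 200)
  L[lower.tri(L)] <- t(L)[lower.tri(L)]
  mk <- function(vals) {
    m <- matrix(NA_real_, 6, 6, dimnames = list(lab, lab))
    m[up] <- vals
    cnt <- matrix(0L, 6, 6, dimnames = list(lab, lab)); cnt[up] <- 1L
    topochron:::new_delay_matrix(m, cnt)
  }
  prop <- mk(L[up] / 5000)
  expect_equal(length_delay_correlation(prop, L)$r, 1)
  expect_equal(length_delay_correlation(mk(rep(0.01, length(up))),
                                        L, "pearson")$r, 0)

  vals <- runif(length(up), 0.001, 0.02)
  r_sp <- length_delay_correlation(mk(vals), L)$r
  expect_equal(r_sp, cor(rank(L[up]), rank(vals)), tolerance = 1e-10)
  r_pe <- length_delay_correlation(mk(vals), L, "pearson")$r
  expect_equal(r_pe, cor(L[up], vals), tolerance = 1e-12)
})

test_that("the surrogate correlation null uses the add-one empirical p", {
  set.seed(53)
  avs <- lapply(1:40, function(i)
    make_avalanche(lapply(1:5, function(j) which(runif(8) < 0.4)), 8))
  ens <- surrogate_delay_ensemble(avs, n_perm = 99, seed = 3)
  lab <- paste0("R", 1:8)
  L <- matrix(runif(64, 20, 200), 8, 8, dimnames = list(lab, lab))
  L[lower.tri(L)] <- t(L)[lower.tri(L)]; diag(L) <- NA
  nt <- correlation_null_test(1, ens, L)     # r = 1 beats every surrogate
  expect_equal(nt$p, 1 / 100)
  nt_all <- correlation_null_test(-1, ens, L)  # everything is >= -1
  expect_equal(nt_all$p, 1)
  expect_length(nt$surrogate_r, 99)
})

test_that("the KS comparison matches a brute-force ECDF scan", {
  same <- ks_compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(ks_compare_groups(1:5, 6:10)$D, 1)

  set.seed(59)
  x <- rnorm(20, 0.01, 0.002); y <- rnorm(20, 0.012, 0.002)
  ks <- ks_compare_groups(x, y)
  grid <- sort(c(x, y))
  brute <- max(abs(sapply(grid, function(g) mean(x <= g) - mean(y <= g))))
  expect_equal(ks$D, brute, tolerance = 1e-12)
  expect_equal(ks$cdf$ecdf_control, ecdf(x)(ks$cdf$value))
})

test_that("edge-wise differences attach lesion flags over coverage edges only", {
  lab <- paste0("R", 1:4)
  mk <- function(vals) {
    m <- matrix(NA_real_, 4, 4, dimnames = list(lab, lab))
    cnt <- matrix(0L, 4, 4, dimnames = list(lab, lab))
    for (k in seq_along(vals)) if (!is.na(vals[k])) {
      idx <- which(upper.tri(m))[k]
      m[idx] <- vals[k]; cnt[idx] <- 1L
    }
    topochron:::new_delay_matrix(m, cnt)
  }
  ctrl <- mk(c(0.010, 0.010, 0.010, NA, NA, NA))
  pat <- mk(c(0.012, NA, 0.011, NA, NA, NA))
  cov <- complete_coverage_edges(list(ctrl))
  mask <- matrix(FALSE, 4, 4, dimnames = list(lab, lab))
  mask[1, 2] <- mask[2, 1] <- TRUE
  d <- edgewise_differences(list(P1 = pat), ctrl, cov, list(mask))
  expect_equal(nrow(d), 2)           # patient lacks the third coverage edge
  expect_equal(d$difference[d$from == "R1" & d$to == "R2"], 0.002)
  expect_true(d$lesioned[d$from == "R1" & d$to == "R2"])
  expect_false(any(d$lesioned[d$from == "R1" & d$to == "R3"]))

  # record count = sum over patients of |present-in-patient ∩ coverage|
  set.seed(61)
  pats <- lapply(1:5, function(i) mk(ifelse(runif(6) < 0.6, runif(6, 0.005, 0.02), NA)))
  d2 <- edgewise_differences(pats, ctrl, cov,
                             lapply(1:5, function(i) mask))
  expected_n <- sum(sapply(pats, function(p) {
    s <- topochron:::symmetrize_delays(p)
    sum(is.finite(s$mean[cov]))
  }))
  expect_equal(nrow(d2), expected_n)
})

test_that("the lesion permutation test matches exhaustive enumeration on a tiny case", {
  diffs <- data.frame(patient = "P1",
                      from = paste0("R", 1:5), to = paste0("S", 1:5),
                      difference = c(5, 1, 4, 2, 3) / 1000,
                      lesioned = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  class(diffs) <- c("edgewise_differences", "data.frame")
  lt <- lesion_permutation_test(diffs, n_perm = 2000, seed = 5)
  expect_equal(lt$observed_mean, 0.0045)
  enum <- combn(diffs$difference, 2, mean)          # all C(5,2) subsets
  expect_true(all(lt$null_distribution %in% enum))
  expect_setequal(round(unique(lt$null_distribution), 12), round(unique(enum), 12))
  # exact p: (1 + #{enumerated mean >= 4.5 ms drawn}) matches the draw tally
  expect_equal(lt$p, (1 + sum(lt$null_distribution >= 0.0045)) / 2001)

  # all differences equal -> p = 1
  flat <- diffs; flat$difference <- rep(0.002, 5)
  expect_equal(lesion_permutation_test(flat, n_perm = 100, seed = 1)$p, 1)

  # strongly shifted lesioned records beat every null subset drawn from the
  # non-lesioned pool: smallest attainable p under the add-one rule
  shift <- diffs
  shift$difference[shift$lesioned] <- shift$difference[shift$lesioned] + 1
  lt2 <- lesion_permutation_test(shift, n_perm = 1000, seed = 2,
                                 null_pool = "nonlesioned")
  expect_equal(lt2$p, 1 / 1001)

  expect_error(lesion_permutation_test(
    within(diffs, lesioned <- rep(FALSE, 5)), 10, 1), "lesioned")
})

test_that("convergence curves are zero for identical subjects and correct for two", {
  lab <- paste0("R", 1:4)
  m <- matrix(runif(16, 0.005, 0.02), 4, 4, dimnames = list(lab, lab))
  diag(m) <- NA
  cnt <- matrix(1L, 4, 4, dimnames = list(lab, lab)); diag(cnt) <- 0L
  d <- topochron:::new_delay_matrix(m, cnt)
  cc <- convergence_curve(list(d, d, d, d), n_orders = 3, seed = 1)
  expect_equal(max(cc$median_curve), 0)

  m2 <- m * 2
  d2 <- topochron:::new_delay_matrix(m2, cnt)
  cc2 <- convergence_curve(list(d, d2), n_orders = 2, seed = 1)
  both <- is.finite(m) & is.finite(m2)
  expect_equal(unique(cc2$curves[, 1]),
               mean(abs((m[both] + m2[both]) / 2 - m[both])))
})
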