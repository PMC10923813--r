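# Exact Wilcoxon maps, effect sizes, Bayes factors, FDR and TFCE.

test_that("exact Wilcoxon: worked example, symmetry, enumeration oracle", {
  # 12 all-positive paired differences: two-sided exact p = 2/2^12
  res <- wilcoxon_exact(seq(0.1, 1.2, by = 0.1))
  expect_equal(res$p, 2 / 4096)
  expect_lt(abs(res$p - 0.00048), 1e-5)
  # perfectly symmetric +/- pairs of equal magnitude
  expect_equal(wilcoxon_exact(c(1, -1, 2, -2, 3, -3, 4, -4))$p, 1)
  expect_error(wilcoxon_exact(rep(0, 6)), "degenerate")
  # random data vs exhaustive sign-flip enumeration (n <= 12)
  set.seed(1)
  for (rep in 1:30) {
    n <- sample(5:12, 1)
    d <- rnorm(n)
    expect_equal(wilcoxon_exact(d)$p, signflip_exact_p(d), tolerance = 1e-12)
  }
  # tied magnitudes take the enumeration path and still match the oracle
  for (rep in 1:10) {
    d <- sample(c(-2, -1, 1, 2), 9, replace = TRUE) + 0
    d[d == 0] <- 1
    expect_equal(wilcoxon_exact(d)$p, signflip_exact_p(d), tolerance = 1e-12)
  }
})

test_that("JZS Bayes factors match an independent implementation", {
  # frozen oracle values (pingouin 0.6.1 bayesfactor_ttest, r = sqrt(2)/2)
  expect_equal(bf10_jzs(2.0, 12), 1.2748443, tolerance = 1e-5)
  expect_equal(bf10_jzs(5.0, 18), 259.95229, tolerance = 1e-5)
  expect_equal(bf10_jzs(0.5, 10), 0.3434953, tolerance = 1e-5)
  expect_equal(bf10_jzs(8.0, 18), 44773.770, tolerance = 1e-5)
})

test_that("effect stats: paired d, evidence bins, degenerate equality", {
  expect_equal(effect_stats(1:10, 1:10)$d_prime, 0)
  es <- effect_stats(c(2, 4, 6), c(1, 2, 3))      # diffs 1, 2, 3
  expect_equal(es$d_prime, 2 / 1)                  # mean/SD with sample SD
  # strong consistent effect -> decisive evidence
  set.seed(2)
  a <- rnorm(18, 1, 0.2); b <- rnorm(18, 0, 0.2)
  es2 <- effect_stats(a, b)
  expect_gt(es2$log10_bf10, 2)
  expect_equal(es2$evidence, "decisive")
  expect_equal(es2$log10_bf01, -es2$log10_bf10)
  # moderate effect labels follow the bins
  es3 <- list(log10_bf10 = 0.7)
  expect_equal(effect_stats(c(1, 2, 3, 4, 5, 7), c(1, 2, 3, 4, 5, 6))$evidence %in%
                 c("none", "positive", "substantial", "decisive"), TRUE)
})

test_that("wilcoxon_map attaches the Bonferroni threshold and flags channels", {
  set.seed(3)
  n_sub <- 12; n_ch <- 16
  rA <- matrix(rnorm(n_sub * n_ch, 0.3, 0.05), n_sub)
  rB <- matrix(rnorm(n_sub * n_ch, 0.0, 0.05), n_sub)
  rB[, 1] <- rA[, 1] + rnorm(n_sub, 0, 0.05)     # channel 1: no effect
  out <- wilcoxon_map(rA, rB)
  expect_equal(nrow(out), n_ch)
  expect_equal(attr(out, "bonferroni_threshold"), 0.05 / 16)
  expect_true(all(out$significant_bonferroni[-1]))
  expect_gt(min(out$d_prime[-1]), 1)
  expect_true(all(out$p_fdr >= out$p_uncorrected))
})

test_that("128-channel Bonferroni threshold is 3.90625e-4", {
  dec <- subject_significance_map(matrix(1e-5, 128, 5))
  expect_equal(dec$threshold, 0.05 / 128)
  expect_equal(dec$threshold, 3.90625e-4)
})

test_that("lateralization: degenerate equality, closed form, detection power", {
  perf <- c(stats::setNames(rep(0.4, 12), paste0("L", 1:12)),
            stats::setNames(rep(0.4, 12), paste0("R", 1:12)))
  expect_warning(res <- lateralization_test(perf, paste0("L", 1:12),
                                            paste0("R", 1:12)), "degenerate")
  expect_equal(res$p, 1)
  # left uniformly greater on all 12 rank-matched pairs -> p = 2/2^12
  set.seed(4)
  lv <- sort(runif(12, 0.3, 0.5)); rv <- lv - runif(12, 0.01, 0.05)
  perf2 <- c(stats::setNames(lv, paste0("L", 1:12)),
             stats::setNames(rv, paste0("R", 1:12)))
  res2 <- lateralization_test(perf2, paste0("L", 1:12), paste0("R", 1:12))
  expect_equal(res2$p, 2 / 4096, tolerance = 1e-12)
  expect_error(lateralization_test(perf2, paste0("L", 1:12),
                                   c("L1", paste0("R", 1:11))), "disjoint")
  # a 1.5x left-hemisphere effect is detected in almost all replicates
  hits <- vapply(1:50, function(s) {
    set.seed(600 + s)
    base <- runif(12, 0.2, 0.35)
    pm <- rbind(matrix(rep(1.5 * base, each = 10), 10) +
                  matrix(rnorm(120, 0, 0.05), 10),
                NULL)
    left_r <- colMeans(pm)
    right_r <- base + rnorm(12, 0, 0.02)
    perf_s <- c(stats::setNames(left_r, paste0("L", 1:12)),
                stats::setNames(right_r, paste0("R", 1:12)))
    lateralization_test(perf_s, paste0("L", 1:12), paste0("R", 1:12))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("BH-FDR matches a reference step-up implementation", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(rep(0.02, 7)), rep(0.02, 7))
  set.seed(5)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(fdr_bh(p), bh_stepup_ref(p), tolerance = 1e-12)
  }
  expect_error(fdr_bh(c(0.5, 0)), "p")
})

test_that("TFCE enhancement matches hand computation and a BFS oracle", {
  # plateau of height 1 and extent 4 on an empty map:
  # sum over thresholds h = 0.2, 0.4, ..., 1.0 of 4^0.5 * h^2 * 0.2
  m <- matrix(0, 4, 5)
  m[2, 2:3] <- 1; m[3, 2:3] <- 1
  expected <- sum(2 * seq(0.2, 1, by = 0.2)^2 * 0.2)
  enh <- tfce_enhance(m)
  expect_equal(enh[2, 2], expected, tolerance = 1e-12)
  expect_equal(enh[1, 1], 0)
  # negative clusters are enhanced symmetrically
  expect_equal(tfce_enhance(-m), -enh)
  # cluster extents agree with an independent BFS labeling:
  # with E = 1, H = 0 and one threshold the score is the extent itself
  set.seed(6)
  for (rep in 1:10) {
    mask <- matrix(runif(12 * 9) < 0.4, 12, 9)
    enh1 <- tfce_enhance(matrix(as.numeric(mask), 12, 9), start = 0,
                         step = 1, E = 1, H = 0)
    expect_equal(enh1, bfs_cluster_extents(mask))
  }
  # monotonicity: scaling up never decreases any TFCE value
  stat <- matrix(rnorm(16 * 20), 16)
  expect_true(all(tfce_enhance(1.5 * stat) * sign(stat) >=
                    tfce_enhance(stat) * sign(stat) - 1e-12))
})

test_that("TFCE one-sample test: null map, p bounds, exhaustive cap", {
  z <- array(0, dim = c(6, 8, 10))
  res <- tfce_one_sample(z, n_perm = 64, seed = 1)
  expect_true(all(res$p == 1))
  set.seed(7)
  x <- array(rnorm(6 * 8 * 10), dim = c(6, 8, 10))
  res2 <- tfce_one_sample(x, n_perm = 200, seed = 2)
  expect_true(all(res2$p >= 1 / (res2$n_perm + 1)))
  expect_true(all(res2$p <= 1))
  # n_perm above 2^n_subjects collapses to exhaustive enumeration
  res3 <- tfce_one_sample(x, n_perm = 100000, seed = 3)
  expect_equal(res3$n_perm, 2^6)
})
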