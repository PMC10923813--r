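# Group-level comparisons of encoding performance between conditions and
# hemispheres: exact Wilcoxon signed-rank maps with Bonferroni thresholds,
# paired Cohen's d, JZS Bayes factors, Benjamini-Hochberg FDR, and a
# threshold-free cluster enhancement (TFCE) one-sample test over the
# feature x lag plane of the mTRF.

#' Exact Wilcoxon signed-rank test for paired differences
#'
#' Two-sided signed-rank test on a vector of paired differences. Zeros are
#' dropped (standard convention). Without ties the p-value is exact (from
#' the signed-rank distribution); with ties it is exact by exhaustive
#' sign-flip enumeration for `n <= 16`, otherwise a tie-corrected normal
#' approximation is used. All-zero differences are a degenerate-test error.
#'
#' @param d numeric vector of paired differences.
#' @return list with `statistic` (V, sum of positive midranks), `p`,
#'   `n` (non-zero pairs), `method`.
#' @export
wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate test: all paired differences are zero")
  rk <- rank(abs(d))
  v <- sum(rk[d > 0])
  ties <- anyDuplicated(rk) > 0
  if (!ties && n <= 1023) {
    p_le <- stats::psignrank(v, n)
    p_ge <- 1 - stats::psignrank(v - 1, n)  # v is integer when untied
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact signed-rank distribution"
  } else if (n <= 16) {
    # exhaustive enumeration of all 2^n sign assignments on the midranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vall <- as.numeric(signs %*% rk)
    p_le <- mean(vall <= v + 1e-9)
    p_ge <- mean(vall >= v - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exhaustive sign-flip enumeration"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "tie-corrected normal approximation"
  }
  list(statistic = v, p = p, n = n, method = method)
}

#' JZS Bayes factor for a one-sample (paired) t-test
#'
#' Bayes factor BF10 for the paired comparison, with a Cauchy prior of
#' scale `rscale` on the standardized effect (default `sqrt(2)/2`),
#' computed by numerical integration over the JZS prior on the variance
#' scale.
#'
#' @param t t statistic of the paired test.
#' @param n number of pairs.
#' @param rscale Cauchy prior scale.
#' @return BF10 (evidence for a difference over the null).
#' @export
bf10_jzs <- function(t, n, rscale = sqrt(2) / 2) {
  stopifnot(n >= 2, is.finite(t))
  v <- n - 1
  null_lik <- (1 + t^2 / v)^(-(v + 1) / 2)
  integrand <- function(g) {
    q <- 1 + n * g * rscale^2
    q^(-1 / 2) * (1 + t^2 / (q * v))^(-(v + 1) / 2) *
      (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g))
  }
  alt_lik <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-9)$value
  alt_lik / null_lik
}

#' Effect size and Bayesian evidence for a paired comparison
#'
#' Paired Cohen's d (mean of the differences over their sample SD), the
#' JZS Bayes factor on the log10 scale, and the qualitative evidence label
#' (log10 BF10 > 0: positive, > 0.5: substantial, > 2: decisive).
#'
#' @param rA,rB paired numeric vectors (e.g. per-subject correlations under
#'   two conditions).
#' @return list with `d_prime`, `log10_bf10`, `log10_bf01`, `evidence`.
#' @export
effect_stats <- function(rA, rB) {
  stopifnot(length(rA) == length(rB))
  d <- rA - rB
  n <- length(d)
  sdd <- stats::sd(d)
  d_prime <- if (sdd == 0) 0 else mean(d) / sdd
  if (sdd == 0) {
    lbf <- 0
  } else {
    t <- mean(d) / (sdd / sqrt(n))
    lbf <- log10(bf10_jzs(t, n))
  }
  evidence <- if (lbf > 2) "decisive" else if (lbf > 0.5) "substantial"
              else if (lbf > 0) "positive" else "none"
  list(d_prime = d_prime, log10_bf10 = lbf, log10_bf01 = -lbf,
       evidence = evidence)
}

#' Per-channel Wilcoxon comparison of two condition performance maps
#'
#' For every channel, a two-sided exact Wilcoxon signed-rank test on the
#' per-subject correlation values of condition A vs condition B, plus the
#' paired Cohen's d and log10 Bayes factor. The Bonferroni threshold
#' `alpha_fw / n_channels` is attached.
#'
#' @param rA,rB `n_subjects x n_channels` matrices of fold-averaged
#'   correlations.
#' @param alpha_fw family-wise level for the Bonferroni threshold.
#' @return data frame with one row per channel: `channel`, `p_uncorrected`,
#'   `p_fdr`, `d_prime`, `log10_bf10`, `significant_bonferroni`; attribute
#'   `"bonferroni_threshold"`.
#' @export
wilcoxon_map <- function(rA, rB, alpha_fw = 0.05) {
  rA <- as.matrix(rA); rB <- as.matrix(rB)
  stopifnot(all(dim(rA) == dim(rB)), nrow(rA) >= 5)
  C <- ncol(rA)
  p <- d_prime <- lbf <- numeric(C)
  for (c in seq_len(C)) {
    p[c] <- wilcoxon_exact(rA[, c] - rB[, c])$p
    es <- effect_stats(rA[, c], rB[, c])
    d_prime[c] <- es$d_prime
    lbf[c] <- es$log10_bf10
  }
  thr <- alpha_fw / C
  out <- data.frame(
    channel = if (is.null(colnames(rA))) paste0("ch", seq_len(C)) else colnames(rA),
    p_uncorrected = p, p_fdr = fdr_bh(p), d_prime = d_prime,
    log10_bf10 = lbf, significant_bonferroni = p < thr)
  attr(out, "bonferroni_threshold") <- thr
  out
}

#' Hemispheric lateralization test
#'
#' Compares the encoding performance of matched frontal electrode sets of
#' the two hemispheres: within each hemisphere's selection the channel mean
#' correlations are sorted and paired by rank, and the paired differences
#' go into a two-sided exact Wilcoxon signed-rank test (n = 12 electrode
#' pairs in the standard montage). Identical left and right values are a
#' degenerate comparison, reported as p = 1 with a warning.
#'
#' @param perf `n_subjects x n_channels` matrix of fold-averaged
#'   correlations with channel names, or a named per-channel vector.
#' @param left,right disjoint channel-label sets of equal size (12 each in
#'   the standard analysis).
#' @return list with `p`, `statistic`, `d_prime`, `left_mean`,
#'   `right_mean`, `n`.
#' @export
lateralization_test <- function(perf, left, right) {
  if (length(intersect(left, right)) > 0)
    stop("left and right channel sets must be disjoint")
  stopifnot(length(left) == length(right))
  if (is.matrix(perf)) perf <- colMeans(perf)
  stopifnot(!is.null(names(perf)), all(c(left, right) %in% names(perf)))
  lv <- sort(perf[left], decreasing = TRUE)
  rv <- sort(perf[right], decreasing = TRUE)
  d <- as.numeric(lv - rv)
  es <- effect_stats(as.numeric(lv), as.numeric(rv))
  if (all(d == 0)) {
    warning("degenerate lateralization comparison: identical hemispheres; p = 1")
    return(list(p = 1, statistic = NA_real_, d_prime = 0,
                left_mean = mean(lv), right_mean = mean(rv), n = length(d)))
  }
  wt <- wilcoxon_exact(d)
  list(p = wt$p, statistic = wt$statistic, d_prime = es$d_prime,
       left_mean = mean(lv), right_mean = mean(rv), n = length(d))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone non-decreasing in rank.
#'
#' @param pvals p-values in `(0, 1]`.
#' @return adjusted p-values.
#' @export
fdr_bh <- function(pvals) {
  stopifnot(all(pvals > 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

# 4-connected cluster extents of a logical matrix; returns per-cell extent
# (0 outside clusters)
.cluster_extent <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  if (max(lab) == 0) return(matrix(0, nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0])
  ext <- matrix(0, nrow(mask), ncol(mask))
  ext[lab > 0] <- sizes[lab[lab > 0]]
  ext
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' Integrates, over thresholds `start + step, start + 2*step, ...` up to
#' the map maximum, the cluster-extent term `extent^E * h^H * step` for the
#' 4-connected supra-threshold clusters. Positive and negative parts are
#' enhanced separately and combined with their signs.
#'
#' @param stat_map numeric matrix (e.g. the t map over features x lags).
#' @param start,step threshold start and step (defaults 0 and 0.2).
#' @param E,H extent and height exponents (defaults 0.5 and 2).
#' @return enhanced map, same shape, signed.
#' @export
tfce_enhance <- function(stat_map, start = 0, step = 0.2, E = 0.5, H = 2) {
  enhance_pos <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    top <- max(m)
    if (top <= start) return(out)
    for (h in seq(start + step, top, by = step)) {
      mask <- m >= h
      ext <- .cluster_extent(mask)
      out[mask] <- out[mask] + ext[mask]^E * h^H * step
    }
    out
  }
  enhance_pos(stat_map) - enhance_pos(-stat_map)
}

#' One-sample TFCE permutation test over the mTRF plane
#'
#' Tests, across subjects, which feature x lag points of the mTRF differ
#' from zero: the one-sample t map is TFCE-enhanced and scored against the
#' sign-flip permutation distribution of the maximum absolute enhanced
#' value (family-wise error controlled). If `n_perm` meets or exceeds
#' `2^n_subjects` the enumeration is exhaustive.
#'
#' @param trf_stack array `n_subjects x n_features x n_lags`.
#' @param n_perm number of sign-flip permutations (default 4096).
#' @param start,step,E,H TFCE parameters (see [tfce_enhance()]).
#' @param seed optional integer seed.
#' @return list with `p` (matrix `n_features x n_lags`), `tfce`, `t`,
#'   `mask05` (p < 0.05), `neg_log10_p`, `n_perm`.
#' @export
tfce_one_sample <- function(trf_stack, n_perm = 4096, start = 0, step = 0.2,
                            E = 0.5, H = 2, seed = NULL) {
  stopifnot(length(dim(trf_stack)) == 3, dim(trf_stack)[1] >= 2)
  ns <- dim(trf_stack)[1]
  nf <- dim(trf_stack)[2]; nl <- dim(trf_stack)[3]
  flat <- matrix(trf_stack, ns, nf * nl)
  t_of <- function(M) {
    mu <- colMeans(M)
    sdv <- sqrt(colSums(sweep(M, 2, mu)^2) / (ns - 1))
    t <- mu / (sdv / sqrt(ns))
    t[!is.finite(t)] <- 0
    matrix(t, nf, nl)
  }
  t_map <- t_of(flat)
  tfce_map <- tfce_enhance(t_map, start, step, E, H)
  exhaustive <- n_perm >= 2^ns
  if (exhaustive) n_perm <- 2^ns
  if (!is.null(seed)) {
    rs <- .session_rng(seed, "tfce")
    on.exit(rs())
  }
  max_null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    signs <- if (exhaustive) 2 * (bitwAnd(b - 1, 2^(seq_len(ns) - 1)) > 0) - 1
             else sample(c(-1, 1), ns, replace = TRUE)
    tb <- t_of(flat * signs)
    max_null[b] <- max(abs(tfce_enhance(tb, start, step, E, H)))
  }
  p <- matrix((vapply(abs(tfce_map), function(v) sum(max_null >= v),
                      numeric(1)) + 1) / (n_perm + 1), nf, nl)
  list(p = p, tfce = tfce_map, t = t_map, mask05 = p < 0.05,
       neg_log10_p = -log10(p), n_perm = n_perm)
}
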