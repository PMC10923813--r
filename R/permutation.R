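# Permutation null for encoding-model performance. Whole rows (samples) of
# the training design matrix are shuffled — each row keeps its internal lag
# structure, so column means and the within-sample correlation structure
# are preserved — the model is refit with the original ridge strength, and
# the original held-out set is predicted. The p-value uses the add-one
# rule, p = (N_exceed + 1) / (N_perm + 1), so it can never be zero.

#' Permutation-test p-value for one channel's encoding model
#'
#' Builds the null distribution of the held-out correlation by refitting
#' the model `n_perm` times on row-shuffled training data (with the alpha
#' of the original model) and predicting the original, unpermuted
#' evaluation set. Exceedances are strict (`rho_rand > rho_true`).
#'
#' @param design a [build_design_matrix()] result or a bare matrix.
#' @param y channel signal at the design's rows.
#' @param alpha ridge strength of the original model.
#' @param n_perm number of permutations (default 3000; reduce for
#'   desk-scale runs).
#' @param train_idx,test_idx row indices of the training and evaluation
#'   split; default: first 80% / last 20% (contiguous).
#' @param seed optional integer seed for the permutations.
#' @return object of class `permutation_null`: `rho_true`, `rho_rand`
#'   (length `n_perm`), `n_perm`, `n_exceed`, `p`.
#' @export
permutation_null_pvalue <- function(design, y, alpha, n_perm = 3000,
                                    train_idx = NULL, test_idx = NULL,
                                    seed = NULL) {
  X <- if (inherits(design, "lagged_design")) design$X else as.matrix(design)
  if (n_perm < 1) stop("n_perm must be >= 1")
  n <- nrow(X)
  if (is.null(train_idx)) train_idx <- seq_len(floor(0.8 * n))
  if (is.null(test_idx)) test_idx <- setdiff(seq_len(n), train_idx)
  if (!is.null(seed)) {
    rs <- .session_rng(seed, "perm-null")
    on.exit(rs())
  }
  res <- .perm_null_multi(X, matrix(y, ncol = 1), alpha, n_perm,
                          train_idx, test_idx)
  rho_true <- res$rho_true[1]
  rho_rand <- res$rho_rand[, 1]
  n_exceed <- sum(rho_rand > rho_true)
  structure(
    list(rho_true = rho_true, rho_rand = rho_rand, n_perm = n_perm,
         n_exceed = n_exceed, p = (n_exceed + 1) / (n_perm + 1)),
    class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> rho_true = %.4f, %d/%d exceedances, p = %.4g\n",
              x$rho_true, x$n_exceed, x$n_perm, x$p))
  invisible(x)
}

# shared machinery: null correlations for all channels at once.
# Y is N x C; alpha may be scalar or per-channel. Row permutations are
# shared across channels (one surrogate dataset per permutation). Exploits
# the fact that crossprod(X) is invariant under row permutation: only the
# X'y alignment changes, so the Cholesky factor per alpha is reused.
.perm_null_multi <- function(X, Y, alpha, n_perm, train_idx, test_idx) {
  alpha <- rep_len(alpha, ncol(Y))
  Xtr <- X[train_idx, , drop = FALSE]
  Ytr <- Y[train_idx, , drop = FALSE]
  Xte <- X[test_idx, , drop = FALSE]
  Yte <- Y[test_idx, , drop = FALSE]
  xm <- colMeans(Xtr); ym <- colMeans(Ytr)
  Xtr <- sweep(Xtr, 2, xm)
  Ytr <- sweep(Ytr, 2, ym)
  Xte <- sweep(Xte, 2, xm)
  XtX <- crossprod(Xtr)
  p <- ncol(X)
  chols <- lapply(unique(alpha), function(a) chol(XtX + diag(a, p)))
  names(chols) <- as.character(unique(alpha))
  solve_w <- function(XtY) {
    W <- matrix(0, p, ncol(Y))
    for (a in unique(alpha)) {
      R <- chols[[as.character(a)]]
      ch <- which(alpha == a)
      W[, ch] <- backsolve(R, backsolve(R, XtY[, ch, drop = FALSE],
                                        transpose = TRUE))
    }
    W
  }
  r_of <- function(W) {
    P <- sweep(Xte %*% W, 2, ym, "+")
    .col_cor(P, Yte)
  }
  rho_true <- r_of(solve_w(crossprod(Xtr, Ytr)))
  ntr <- length(train_idx)
  rho_rand <- matrix(NA_real_, n_perm, ncol(Y))
  for (b in seq_len(n_perm)) {
    s <- sample.int(ntr)
    # rows of Xtr permuted by s  <=>  X' y with y at the inverse alignment
    XtY_perm <- crossprod(Xtr, Ytr[order(s), , drop = FALSE])
    rho_rand[b, ] <- r_of(solve_w(XtY_perm))
  }
  list(rho_true = rho_true, rho_rand = rho_rand)
}

#' Per-channel, per-fold permutation significance of an encoding model
#'
#' Reruns the permutation test of [permutation_null_pvalue()] for every
#' channel and every outer fold of a fitted [crossval_encode()] model,
#' reusing each fold's train/test split and selected alpha.
#'
#' @param features,eeg,model the inputs and fitted model of
#'   [crossval_encode()].
#' @param n_perm permutations per fold (default 3000).
#' @param seed optional integer seed.
#' @return list with matrices `p` and `rho_true` (`n_channels x n_folds`)
#'   and `n_perm`.
#' @export
permutation_significance <- function(features, eeg, model, n_perm = 3000,
                                     seed = NULL) {
  stopifnot(inherits(model, "trf_model"))
  meta <- model$design_meta
  design <- build_design_matrix(features, meta$sample_index,
                                meta$window_ms, meta$discard_ms)
  Y <- t(eeg$data[, design$sample_index, drop = FALSE])
  fid <- model$fold_id
  K <- ncol(model$alpha)
  C <- nrow(model$alpha)
  if (!is.null(seed)) {
    rs <- .session_rng(seed, "perm-significance")
    on.exit(rs())
  }
  p_mat <- rho_mat <- matrix(NA_real_, C, K)
  for (k in seq_len(K)) {
    tr <- which(fid != k); te <- which(fid == k)
    res <- .perm_null_multi(design$X, Y, model$alpha[, k], n_perm, tr, te)
    n_exceed <- colSums(sweep(res$rho_rand, 2, res$rho_true, ">"))
    p_mat[, k] <- (n_exceed + 1) / (n_perm + 1)
    rho_mat[, k] <- res$rho_true
  }
  list(p = p_mat, rho_true = rho_mat, n_perm = n_perm)
}

#' Channel significance decision and significant-subject counts
#'
#' A channel is significant for a subject when its permutation p-value is
#' below `alpha_fw / n_channels` (Bonferroni over channels) in every fold.
#' Given several subjects, the per-channel decisions are summed into
#' significant-subject counts.
#'
#' @param pvals a `n_channels x n_folds` p-value matrix (one subject) or a
#'   list of such matrices (one per subject).
#' @param alpha_fw family-wise level (default 0.05).
#' @param n_channels Bonferroni divisor; defaults to the number of channels
#'   in the input (128 in the full montage).
#' @return list with `significant` (logical matrix `n_channels x
#'   n_subjects`), `counts` (per-channel significant-subject counts) and
#'   `threshold`.
#' @export
subject_significance_map <- function(pvals, alpha_fw = 0.05,
                                     n_channels = NULL) {
  if (is.matrix(pvals)) pvals <- list(pvals)
  stopifnot(all(vapply(pvals, is.matrix, logical(1))))
  if (is.null(n_channels)) n_channels <- nrow(pvals[[1]])
  if (any(vapply(pvals, function(m) any(m <= 0 | m > 1), logical(1))))
    stop("p-values must lie in (0, 1]")
  thr <- alpha_fw / n_channels
  sig <- vapply(pvals, function(m) apply(m < thr, 1, all),
                logical(nrow(pvals[[1]])))
  sig <- matrix(sig, nrow = nrow(pvals[[1]]))
  list(significant = sig, counts = rowSums(sig), threshold = thr)
}
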