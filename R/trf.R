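# Lagged ridge encoding models. Each EEG sample at frame t is predicted
# from the previous 600 ms of the stimulus features: lags 1..77 frames at
# 128 Hz (the contemporaneous frame is excluded by the 3 ms discard, the
# sound's travel time over ~1 m). The model weights, reshaped to
# feature x lag, are the multivariate temporal response function (mTRF).

#' Default regularization grid
#'
#' Logarithmically spaced ridge strengths, `1e-2 .. 1e6` in 13 steps.
#'
#' @return numeric vector.
#' @export
default_alpha_grid <- function() 10^seq(-2, 6, length.out = 13)

#' Build the lagged design matrix
#'
#' Row `i` stacks, for each feature, the feature frames at lags
#' `1..n_lags` before sample index `t_i` (columns grouped feature-major:
#' feature 1 lags 1..77, feature 2 lags 1..77, ...). With the defaults
#' (600 ms at 128 Hz, first 3 ms discarded) `n_lags = 77`, so the envelope
#' gives 77 columns and the 16-band spectrogram 77 * 16 = 1232. Row `t`
#' only contains feature frames at times strictly before `t`: no future
#' leakage. Indices too early for the full lag window are dropped.
#'
#' @param features a [feature_series()].
#' @param sample_indices frame indices of the samples (rows).
#' @param window_ms lag window in ms (default 600).
#' @param discard_ms initial portion of the window to discard, in ms
#'   (default 3; removes the contemporaneous frame, lag 0).
#' @return object of class `lagged_design`: list with `X`
#'   (`N x n_features*n_lags`), `n_lags`, `n_features`, `lag_ms`,
#'   `sample_index`, `fs`.
#' @export
build_design_matrix <- function(features, sample_indices, window_ms = 600,
                                discard_ms = 3) {
  stopifnot(inherits(features, "feature_series"))
  fs <- features$fs
  n_lags <- as.integer(round(window_ms / 1000 * fs))
  first_lag <- if (discard_ms > 0) 1L else 0L
  lags <- seq.int(first_lag, length.out = n_lags)
  sample_indices <- sort(unique(as.integer(sample_indices)))
  sample_indices <- sample_indices[sample_indices > max(lags) &
                                     sample_indices <= features$n_frames]
  nf <- features$n_features
  X <- matrix(0, length(sample_indices), nf * n_lags)
  for (j in seq_along(lags)) {
    block <- t(features$values[, sample_indices - lags[j], drop = FALSE])
    X[, (seq_len(nf) - 1L) * n_lags + j] <- block
  }
  structure(
    list(X = X, n_lags = n_lags, n_features = nf,
         lag_ms = lags / fs * 1000, sample_index = sample_indices, fs = fs),
    class = "lagged_design")
}

#' @export
print.lagged_design <- function(x, ...) {
  cat(sprintf("<lagged_design> %d samples x %d columns (%d features x %d lags, %.1f-%.1f ms)\n",
              nrow(x$X), ncol(x$X), x$n_features, x$n_lags,
              min(x$lag_ms), max(x$lag_ms)))
  invisible(x)
}

# ridge solution on centered data via the normal equations
# (X'X + alpha I) w = X'y, Cholesky-factored
.ridge_solve <- function(XtX, Xty, alpha) {
  p <- nrow(XtX)
  R <- chol(XtX + diag(alpha, p))
  backsolve(R, backsolve(R, Xty, transpose = TRUE))
}

#' Fit a ridge regression for one channel
#'
#' Minimizes `||y - Xw||^2 + alpha ||w||^2` after centering `y` and the
#' columns of `X` (the intercept is carried by the stored means).
#' Deterministic; non-finite inputs are an error.
#'
#' @param design a [build_design_matrix()] result (or a bare matrix).
#' @param y channel signal at the design's sample indices.
#' @param alpha ridge strength.
#' @return object of class `ridge_fit`: `w` (coefficients), `x_mean`,
#'   `y_mean`, `alpha`.
#' @export
fit_ridge <- function(design, y, alpha) {
  X <- if (inherits(design, "lagged_design")) design$X else as.matrix(design)
  stopifnot(nrow(X) == length(y), alpha >= 0)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in ridge inputs")
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  w <- .ridge_solve(crossprod(Xc), crossprod(Xc, y - ym), alpha)
  structure(list(w = drop(w), x_mean = xm, y_mean = ym, alpha = alpha),
            class = "ridge_fit")
}

#' @export
predict.ridge_fit <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "lagged_design")) newdata$X else as.matrix(newdata)
  drop(sweep(X, 2, object$x_mean) %*% object$w) + object$y_mean
}

# Pearson r per column between predictions P and targets Y (both N x C);
# a constant column yields NA
.col_cor <- function(P, Y) {
  vapply(seq_len(ncol(Y)), function(c) {
    if (stats::sd(P[, c]) == 0 || stats::sd(Y[, c]) == 0) return(NA_real_)
    stats::cor(P[, c], Y[, c])
  }, numeric(1))
}

# Per-channel alpha selection by inner k-fold CV, sharing Cholesky factors
# across channels. X (N x p), Y (N x C). One-SE parsimony rule: the largest
# alpha whose mean held-out r lies within one standard error (across inner
# folds) of the best mean r — on informative data the SE is tiny and the
# argmax wins; on uninformative data the rule prefers strong
# regularization instead of chasing noise. Returns list(alpha = C-vector,
# mean_r = grid x C matrix).
.select_alpha_multi <- function(X, Y, grid, inner_folds = 3) {
  n <- nrow(X)
  fid <- fold_id_contiguous(n, inner_folds)
  r_fold <- array(NA_real_, c(length(grid), inner_folds, ncol(Y)))
  for (k in seq_len(inner_folds)) {
    tr <- fid != k; te <- !tr
    xm <- colMeans(X[tr, , drop = FALSE])
    ym <- colMeans(Y[tr, , drop = FALSE])
    Xtr <- sweep(X[tr, , drop = FALSE], 2, xm)
    Ytr <- sweep(Y[tr, , drop = FALSE], 2, ym)
    Xte <- sweep(X[te, , drop = FALSE], 2, xm)
    XtX <- crossprod(Xtr)
    XtY <- crossprod(Xtr, Ytr)
    for (a in seq_along(grid)) {
      W <- .ridge_solve(XtX, XtY, grid[a])
      P <- Xte %*% W
      r_fold[a, k, ] <- .col_cor(P, Y[te, , drop = FALSE])
    }
  }
  mean_r <- apply(r_fold, c(1, 3), mean)
  alpha <- vapply(seq_len(ncol(Y)), function(c) {
    mr <- mean_r[, c]
    if (all(is.na(mr))) stop("undefined correlation: degenerate channel")
    i_best <- which.max(mr)
    se <- stats::sd(r_fold[i_best, , c]) / sqrt(inner_folds)
    if (!is.finite(se)) se <- 0
    grid[max(which(mr >= mr[i_best] - se))]
  }, numeric(1))
  list(alpha = alpha, mean_r = mean_r)
}

#' Select the ridge strength by inner cross-validation
#'
#' Returns the grid value maximizing the mean held-out Pearson correlation
#' over an inner contiguous k-fold cross-validation on the provided data;
#' ties go to the strongest regularization.
#'
#' @param design a [build_design_matrix()] result or matrix.
#' @param y channel signal.
#' @param grid candidate alphas (non-empty, positive).
#' @param inner_folds number of inner folds (default 3).
#' @return selected alpha (attribute `"mean_r"` carries the CV curve).
#' @export
select_alpha <- function(design, y, grid = default_alpha_grid(),
                         inner_folds = 3) {
  X <- if (inherits(design, "lagged_design")) design$X else as.matrix(design)
  stopifnot(length(grid) >= 1, all(grid > 0))
  if (stats::sd(y) == 0)
    stop("undefined correlation: y is constant")
  if (length(grid) == 1L) return(grid)
  sel <- .select_alpha_multi(X, matrix(y, ncol = 1), grid, inner_folds)
  structure(sel$alpha, mean_r = drop(sel$mean_r))
}

#' Cross-validated encoding model (mTRF + performance map)
#'
#' Fits, per EEG channel, a lagged ridge model under an unshuffled
#' contiguous `n_folds`-fold cross-validation: per fold, the ridge strength
#' is selected on the training split by inner cross-validation, the model
#' is fit on the training split and evaluated as the Pearson correlation
#' between predicted and recorded EEG on the held-out fold. Weights and
#' correlations are averaged over folds first (per channel), the standard
#' order before any across-participant averaging.
#'
#' @param features a [feature_series()] (the stimulus side).
#' @param eeg an [eeg_recording()] at the same rate.
#' @param samples valid frame indices (see [extract_training_samples()]).
#' @param n_folds outer folds (default 5).
#' @param alpha_grid ridge grid (default [default_alpha_grid()]).
#' @param inner_folds inner folds for alpha selection (default 3).
#' @param window_ms,discard_ms design-matrix parameters.
#' @return object of class `trf_model`: `weights` (fold-averaged array
#'   `n_channels x n_features x n_lags`), `r` (fold-averaged per-channel
#'   Pearson correlation), `r_folds` (`n_channels x n_folds`), `alpha`
#'   (`n_channels x n_folds`), `lag_ms`, `fold_id`, `design_meta`.
#' @export
crossval_encode <- function(features, eeg, samples, n_folds = 5,
                            alpha_grid = default_alpha_grid(),
                            inner_folds = 3, window_ms = 600,
                            discard_ms = 3) {
  stopifnot(inherits(eeg, "eeg_recording"))
  design <- build_design_matrix(features, samples, window_ms, discard_ms)
  X <- design$X
  n <- nrow(X)
  if (n < n_folds * inner_folds)
    stop("fewer samples than folds: ", n, " samples for ",
         n_folds, "x", inner_folds, " folds")
  Y <- t(eeg$data[, design$sample_index, drop = FALSE])
  C <- ncol(Y)
  fid <- fold_id_contiguous(n, n_folds)
  L <- design$n_lags; Fk <- design$n_features
  w_sum <- matrix(0, Fk * L, C)
  r_folds <- alpha_mat <- matrix(NA_real_, C, n_folds)
  for (k in seq_len(n_folds)) {
    tr <- fid != k; te <- !tr
    sel <- .select_alpha_multi(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                               alpha_grid, inner_folds)
    xm <- colMeans(X[tr, , drop = FALSE])
    ym <- colMeans(Y[tr, , drop = FALSE])
    Xtr <- sweep(X[tr, , drop = FALSE], 2, xm)
    XtX <- crossprod(Xtr)
    XtY <- crossprod(Xtr, sweep(Y[tr, , drop = FALSE], 2, ym))
    Xte <- sweep(X[te, , drop = FALSE], 2, xm)
    W <- matrix(0, Fk * L, C)
    for (a in unique(sel$alpha)) {
      ch <- which(sel$alpha == a)
      W[, ch] <- .ridge_solve(XtX, XtY[, ch, drop = FALSE], a)
    }
    P <- sweep(Xte %*% W, 2, ym, "+")
    r_folds[, k] <- .col_cor(P, Y[te, , drop = FALSE])
    alpha_mat[, k] <- sel$alpha
    w_sum <- w_sum + W
  }
  w_mean <- w_sum / n_folds
  weights <- array(0, dim = c(C, Fk, L))
  for (c in seq_len(C)) weights[c, , ] <- matrix(w_mean[, c], L, Fk,
                                                 byrow = FALSE) |> t()
  structure(
    list(weights = weights, r = rowMeans(r_folds), r_folds = r_folds,
         alpha = alpha_mat, lag_ms = design$lag_ms, fold_id = fid,
         channel_names = eeg$channel_names,
         design_meta = list(window_ms = window_ms, discard_ms = discard_ms,
                            n_lags = L, n_features = Fk,
                            sample_index = design$sample_index)),
    class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf("<trf_model> %d channels, %d features x %d lags; mean r = %.3f\n",
              dim(x$weights)[1], dim(x$weights)[2], dim(x$weights)[3],
              mean(x$r, na.rm = TRUE)))
  invisible(x)
}

#' Cosine similarity between an estimated mTRF and reference kernels
#'
#' Scale-free agreement between the fold-averaged weights of a
#' [crossval_encode()] model and ground-truth kernels, per channel.
#'
#' @param model a `trf_model`.
#' @param kernels reference array `n_channels x n_features x n_lags`.
#' @return numeric vector of per-channel cosine similarities.
#' @export
trf_kernel_cosine <- function(model, kernels) {
  stopifnot(all(dim(model$weights) == dim(kernels)))
  vapply(seq_len(dim(kernels)[1]), function(c) {
    a <- as.numeric(model$weights[c, , ])
    b <- as.numeric(kernels[c, , ])
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
}

#' Write a performance map as CSV
#'
#' One row per channel and fold: participant, band, condition, channel,
#' fold, r, alpha.
#'
#' @param model a `trf_model`.
#' @param path output CSV path.
#' @param participant,band,condition labels recorded in the table.
#' @return `path`, invisibly.
#' @export
write_performance_csv <- function(model, path, participant = "p1",
                                  band = "raw", condition = "E") {
  C <- nrow(model$r_folds); K <- ncol(model$r_folds)
  df <- data.frame(
    participant = participant, band = band, condition = condition,
    channel = rep(model$channel_names, K),
    fold = rep(seq_len(K), each = C),
    r = as.numeric(model$r_folds),
    alpha = as.numeric(model$alpha))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
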