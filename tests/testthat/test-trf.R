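# Lagged design matrix, ridge solver, alpha selection and the
# cross-validated encoder.

test_that("design-matrix shape: 77 lags per feature, 1232 for 16 bands", {
  env <- feature_series(matrix(rnorm(1000), 1), 128, "envelope")
  d <- build_design_matrix(env, 100:900)
  expect_equal(d$n_lags, 77)
  expect_equal(ncol(d$X), 77)
  spec16 <- feature_series(matrix(rnorm(16 * 1000), 16), 128)
  d16 <- build_design_matrix(spec16, 100:900)
  expect_equal(ncol(d16$X), 77 * 16)
  expect_equal(ncol(d16$X), 1232)
  # lag axis excludes lag 0 and spans ~7.8..601.6 ms
  expect_equal(d$lag_ms[1], 1000 / 128)
  expect_equal(d$lag_ms[77], 77 * 1000 / 128)
})

test_that("design rows carry exactly the lagged frames", {
  set.seed(1)
  f <- feature_series(matrix(rnorm(2 * 300), 2), 128)
  d <- build_design_matrix(f, c(100, 200))
  for (j in c(1, 20, 77)) {
    expect_equal(d$X[1, j], f$values[1, 100 - j])
    expect_equal(d$X[1, 77 + j], f$values[2, 100 - j])
    expect_equal(d$X[2, j], f$values[1, 200 - j])
  }
  # a one-lag window is just the previous frame
  d1 <- build_design_matrix(feature_series(matrix(1:100, 1), 128),
                            10:20, window_ms = 1000 / 128)
  expect_equal(ncol(d1$X), 1)
  expect_equal(drop(d1$X), 9:19)
  # indices too early for the lag window are dropped
  dd <- build_design_matrix(f, c(5, 50, 100))
  expect_equal(dd$sample_index, 100L)
})

test_that("no future leakage: later frames never affect earlier rows", {
  set.seed(2)
  vals <- matrix(rnorm(3 * 500), 3)
  f <- feature_series(vals, 128)
  idx <- 90:200
  d <- build_design_matrix(f, idx)
  vals2 <- vals
  vals2[, 201:500] <- rnorm(3 * 300)
  d2 <- build_design_matrix(feature_series(vals2, 128), idx)
  expect_identical(d$X, d2$X)
})

test_that("ridge matches the normal-equations oracle and obeys limits", {
  set.seed(3)
  X <- matrix(rnorm(50 * 8), 50)
  y <- rnorm(50)
  fit <- fit_ridge(X, y, 0.5)
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  w_oracle <- solve(crossprod(Xc) + 0.5 * diag(8), crossprod(Xc, yc))
  expect_lt(max(abs(fit$w - w_oracle)), 1e-8)
  # alpha -> 0 with y equal to one (orthogonalized) column
  Q <- qr.Q(qr(matrix(rnorm(60 * 5), 60)))
  fit0 <- fit_ridge(Q, Q[, 3], 1e-10)
  expect_equal(unname(fit0$w[3]), 1, tolerance = 1e-6)
  expect_lt(max(abs(fit0$w[-3])), 1e-6)
  # alpha -> Inf shrinks to zero
  fitI <- fit_ridge(X, y, 1e12)
  expect_lt(max(abs(fitI$w)), 1e-6)
  expect_error(fit_ridge(X, c(y[-1], NA), 1), "non-finite")
  # predictions are centered-consistent
  expect_equal(predict(fit, X), drop(Xc %*% fit$w) + mean(y))
})

test_that("alpha selection: singleton grid, noiseless argmin, noise parsimony", {
  set.seed(4)
  X <- matrix(rnorm(300 * 20), 300)
  w <- rnorm(20)
  expect_equal(select_alpha(X, drop(X %*% w), grid = 3.14), 3.14)
  grid <- default_alpha_grid()
  a <- select_alpha(X, drop(X %*% w), grid = grid)
  expect_equal(as.numeric(a), min(grid))
  expect_gt(max(attr(a, "mean_r"), na.rm = TRUE), 0.99)
  expect_error(select_alpha(X, rep(1, 300), grid = grid), "constant")
  # pure-noise y: strong regularization preferred in most replicates
  hits <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    Xn <- matrix(rnorm(200 * 15), 200)
    as.numeric(select_alpha(Xn, rnorm(200), grid = grid)) >= median(grid)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("cross-validated encoder: folds partition, noiseless recovery", {
  ses <- make_session(duration_s = 90, n_channels = 2, seed = 31, snr = Inf)
  m <- crossval_encode(ses$tracks[[2]]$features, ses$eeg, ses$samples_E,
                       alpha_grid = 10^seq(-4, 0, length.out = 5))
  # contiguous disjoint folds covering all samples
  expect_equal(length(m$fold_id), length(ses$samples_E))
  expect_equal(sort(unique(m$fold_id)), 1:5)
  expect_true(all(diff(m$fold_id) >= 0))
  # noiseless identifiability
  expect_true(all(m$r > 0.99))
  expect_true(all(trf_kernel_cosine(m, ses$gt$kernels) > 0.99))
  expect_error(crossval_encode(ses$tracks[[2]]$features, ses$eeg,
                               ses$samples_E[1:10]), "fewer samples")
})

test_that("mTRF of a noiseless delta-kernel simulation reproduces the kernel", {
  tr <- sample_dialogue(dialogue_spec(duration_s = 90, seed = 33))
  nf <- tr[[1]]$features$n_features
  k <- array(0, dim = c(2, nf, 77))
  k[1, , 5] <- 1
  k[2, , 30] <- -1
  gt <- ground_truth(k, gain_other = 1, gain_self = 0, noise_sd = 0, seed = 1)
  eeg <- synthesize_eeg(tr[[1]], tr[[2]], gt)
  mask <- label_conditions(tr[[1]]$activity, tr[[2]]$activity,
                           tr[[1]]$features$n_frames, 128)
  m <- crossval_encode(tr[[2]]$features, eeg,
                       extract_training_samples(mask, "E"),
                       alpha_grid = 10^seq(-3, 1, length.out = 5))
  expect_true(all(trf_kernel_cosine(m, k) > 0.999))
})

test_that("independent-noise EEG gives mean r consistent with zero", {
  rs <- vapply(1:50, function(s) {
    set.seed(5000 + s)
    f <- feature_series(matrix(pmax(0, rnorm(600, 0.5, 0.3)), 1), 128,
                        "envelope")
    eeg <- eeg_recording(matrix(rnorm(600), 1), 128)
    m <- crossval_encode(f, eeg, 100:550, alpha_grid = c(1, 100))
    m$r[1]
  }, numeric(1))
  se <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs)), 2 * se + 0.02)
})

test_that("performance CSV carries one row per channel and fold", {
  ses <- make_session(duration_s = 30, n_channels = 2, seed = 35, snr = 5)
  m <- crossval_encode(ses$tracks[[2]]$features, ses$eeg, ses$samples_E,
                       alpha_grid = c(1, 100))
  path <- tempfile(fileext = ".csv")
  write_performance_csv(m, path, participant = "p1", band = "raw",
                        condition = "E")
  df <- read.csv(path)
  expect_equal(nrow(df), 2 * 5)
  expect_equal(mean(df$r), mean(m$r_folds))
  unlink(path)
})
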