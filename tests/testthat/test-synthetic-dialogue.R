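# The dialogue generator is the ground-truth testbed: its turn-taking,
# feature and EEG contracts must hold exactly for downstream recovery
# claims to mean anything.

test_that("invalid dialogue specs are rejected", {
  expect_error(dialogue_spec(duration_s = 0), "duration")
  expect_error(dialogue_spec(duration_s = -5), "duration")
  expect_error(dialogue_spec(overlap_prob = 1.2), "overlap_prob")
  expect_error(dialogue_spec(turn_mean_s = 0), "non-positive")
  expect_error(dialogue_spec(fs_audio = 16001), "integer multiple")
})

test_that("overlap_prob = 0 yields no frame where both speakers are active", {
  for (seed in 1:3) {
    tr <- sample_dialogue(dialogue_spec(duration_s = 120, overlap_prob = 0,
                                        seed = seed))
    a1 <- colSums(tr[[1]]$features$values) > 0
    a2 <- colSums(tr[[2]]$features$values) > 0
    expect_equal(sum(a1 & a2), 0)
  }
})

test_that("identical seeds give identical sessions, different seeds differ", {
  s <- dialogue_spec(duration_s = 60, seed = 11)
  t1 <- sample_dialogue(s)
  t2 <- sample_dialogue(s)
  expect_identical(t1, t2)
  t3 <- sample_dialogue(dialogue_spec(duration_s = 60, seed = 12))
  expect_false(identical(t1[[1]]$activity, t3[[1]]$activity))
})

test_that("condition durations from either perspective sum to the session", {
  for (seed in c(2, 5)) {
    tr <- sample_dialogue(dialogue_spec(duration_s = 90, seed = seed))
    n <- tr[[1]]$features$n_frames
    m12 <- label_conditions(tr[[1]]$activity, tr[[2]]$activity, n, 128)
    m21 <- label_conditions(tr[[2]]$activity, tr[[1]]$activity, n, 128)
    expect_equal(length(m12$labels), n)
    expect_equal(sum(table(m12$labels)), n)
    expect_equal(sum(table(m21$labels)), n)
    # perspectives agree up to swapping E and S
    expect_equal(sum(m12$labels == "E"), sum(m21$labels == "S"))
    expect_equal(sum(m12$labels == "B"), sum(m21$labels == "B"))
  }
})

test_that("features are zero outside activity intervals and positive inside", {
  tr <- sample_dialogue(dialogue_spec(duration_s = 60, seed = 4))
  for (sp in 1:2) {
    mid <- (seq_len(tr[[sp]]$features$n_frames) - 0.5) / 128
    iv <- tr[[sp]]$activity
    inside <- rep(FALSE, length(mid))
    for (i in seq_len(nrow(iv)))
      inside <- inside | (mid >= iv[i, 1] & mid < iv[i, 2])
    expect_true(all(tr[[sp]]$features$values[, !inside] == 0))
    expect_true(all(tr[[sp]]$features$values[, inside] > 0))
  }
})

test_that("empirical overlap fraction matches a turn-level Monte-Carlo oracle", {
  # oracle: same generative rules (alternating exponential turns/pauses,
  # overlap with prob p), rasterized at turn level over many replicates
  oracle_overlap_frac <- function(p_ov, turn_mean, pause_mean, dur, n_rep) {
    fracs <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      grid <- seq(0, dur, by = 1 / 64)
      occ1 <- rep(FALSE, length(grid)); occ2 <- rep(FALSE, length(grid))
      t_cur <- rexp(1, 1 / pause_mean); sp <- 1
      while (t_cur < dur) {
        d <- rexp(1, 1 / turn_mean)
        e <- min(t_cur + d, dur)
        sel <- grid >= t_cur & grid < e
        if (sp == 1) occ1[sel] <- TRUE else occ2[sel] <- TRUE
        if (runif(1) < p_ov) t_cur <- e - min(rexp(1, 1 / pause_mean), e - t_cur)
        else t_cur <- e + rexp(1, 1 / pause_mean)
        sp <- 3 - sp
      }
      fracs[r] <- mean(occ1 & occ2)
    }
    fracs
  }
  set.seed(404)
  oracle <- oracle_overlap_frac(0.2, 1.5, 0.5, 150, 400)
  pkg <- vapply(1:40, function(seed) {
    tr <- sample_dialogue(dialogue_spec(duration_s = 150, overlap_prob = 0.2,
                                        seed = seed))
    a1 <- colSums(tr[[1]]$features$values) > 0
    a2 <- colSums(tr[[2]]$features$values) > 0
    mean(a1 & a2)
  }, numeric(1))
  se <- sqrt(var(oracle) / length(oracle) + var(pkg) / length(pkg))
  expect_lt(abs(mean(pkg) - mean(oracle)), 3 * se + 1e-12)
})

test_that("make_kernel honors construction: zeros, peak index, default length", {
  expect_equal(make_kernel(amplitudes = c(0, 0, 0)), rep(0, 77))
  k <- make_kernel(peak_lag_s = 0.125, widths = 0.02, amplitudes = 1,
                   n_lags = 77, fs = 128)
  expect_equal(which.max(k), round(0.125 * 128))
  expect_length(make_kernel(), 77)
})

test_that("synthesize_eeg: delta kernel is a pure delay, and the model is linear", {
  tr <- sample_dialogue(dialogue_spec(duration_s = 30, seed = 9))
  nf <- tr[[1]]$features$n_features
  k <- array(0, dim = c(2, nf, 77))
  k[, , 5] <- 1  # unit impulse at lag 5 for every channel and feature
  gt <- ground_truth(k, gain_other = 1, gain_self = 0, noise_sd = 0, seed = 1)
  eeg <- synthesize_eeg(tr[[1]], tr[[2]], gt)
  summed <- colSums(tr[[2]]$features$values)
  n <- length(summed)
  expect_equal(eeg$data[1, 6:n], summed[1:(n - 5)], tolerance = 1e-10)
  expect_equal(eeg$data[1, 1:5], rep(0, 5), tolerance = 1e-12)
  # linearity: doubling features doubles the EEG exactly
  tr2 <- tr
  for (sp in 1:2) tr2[[sp]]$features$values <- 2 * tr[[sp]]$features$values
  eeg2 <- synthesize_eeg(tr2[[1]], tr2[[2]], gt)
  expect_equal(eeg2$data, 2 * eeg$data, tolerance = 1e-10)
})

test_that("with gain_self = 0 the EEG carries no self-speech information", {
  ses <- make_session(duration_s = 90, n_channels = 2, seed = 21, snr = 4)
  sS <- ses$samples_S
  expect_gt(length(sS), 500)  # seed chosen so the S condition is well populated
  x <- ses$tracks[[1]]$features$values[8, ]
  lagged_self <- x[sS - 10]
  r_obs <- abs(cor(ses$eeg$data[1, sS], lagged_self))
  # circular-shift surrogate null for the same statistic
  set.seed(77)
  null <- replicate(200, {
    sh <- sample(100:(length(x) - 100), 1)
    abs(cor(ses$eeg$data[1, sS], x[((sS - 10 + sh - 1) %% length(x)) + 1]))
  })
  expect_lt(r_obs, quantile(null, 0.99))
})

test_that("EEG noise is seed-deterministic and mismatched tracks error", {
  tr <- sample_dialogue(dialogue_spec(duration_s = 20, seed = 3))
  gt <- ground_truth(default_kernels(2, seed = 3), noise_sd = 1, seed = 42)
  e1 <- synthesize_eeg(tr[[1]], tr[[2]], gt)
  e2 <- synthesize_eeg(tr[[1]], tr[[2]], gt)
  expect_identical(e1$data, e2$data)
  tr_bad <- tr
  tr_bad[[2]]$features$values <- tr[[2]]$features$values[, 1:100]
  expect_error(synthesize_eeg(tr_bad[[1]], tr_bad[[2]], gt), "shape")
})

test_that("crosstalk mixes the other's features into the own microphone", {
  tr <- sample_dialogue(dialogue_spec(duration_s = 20, seed = 6))
  mixed <- apply_crosstalk(tr[[1]]$features, tr[[2]]$features, 0.3)
  expect_equal(mixed, tr[[1]]$features$values + 0.3 * tr[[2]]$features$values)
  expect_error(apply_crosstalk(tr[[1]]$features, tr[[2]]$features, 1), "crosstalk")
})

test_that("a session round-trips through the plain-text store", {
  ses <- make_session(duration_s = 20, n_channels = 2, seed = 13, snr = 10)
  dir <- file.path(tempdir(), "sistrf-session-test")
  write_session(ses$tracks, ses$eeg, ses$gt, dir)
  back <- read_session(dir)
  expect_equal(back$tracks[[1]]$features$values,
               ses$tracks[[1]]$features$values, tolerance = 1e-8)
  expect_equal(back$tracks[[2]]$activity, ses$tracks[[2]]$activity,
               tolerance = 1e-8)
  expect_equal(back$eeg$data, ses$eeg$data, tolerance = 1e-8)
  expect_equal(back$gt$kernels, ses$gt$kernels, tolerance = 1e-8)
  expect_equal(back$gt$gain_self, ses$gt$gain_self)
  unlink(dir, recursive = TRUE)
})
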