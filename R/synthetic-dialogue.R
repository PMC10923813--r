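#' Specification of a synthetic dyadic dialogue session
#'
#' Parameters of the two-speaker turn-taking generator. Turn (inter-pausal
#' unit) lengths and pauses are drawn from exponential distributions with
#' the stated means — the simplest memoryless turn-taking model — and with
#' probability `overlap_prob` a turn onset overlaps the end of the other
#' speaker's ongoing turn, so that all four dialogue conditions (only self,
#' only other, both, silence) occur.
#'
#' @param duration_s session length in seconds.
#' @param turn_mean_s mean turn (IPU) length in seconds.
#' @param pause_mean_s mean pause between turns in seconds.
#' @param overlap_prob probability in `[0, 1]` that a turn onset overlaps
#'   the other speaker's turn.
#' @param n_channels number of EEG channels to synthesize.
#' @param fs_feature feature/EEG frame rate in Hz (default 128).
#' @param fs_audio audio rate in Hz (default 16000); must be an integer
#'   multiple of `fs_feature`.
#' @param seed integer seed; identical seeds give byte-identical sessions.
#' @return An object of class `dialogue_spec`.
#' @export
dialogue_spec <- function(duration_s = 300, turn_mean_s = 1.5,
                          pause_mean_s = 0.5, overlap_prob = 0.2,
                          n_channels = 8, fs_feature = 128,
                          fs_audio = 16000, seed = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("invalid dialogue spec: duration_s must be positive")
  if (overlap_prob < 0 || overlap_prob > 1)
    stop("invalid dialogue spec: overlap_prob must be in [0, 1]")
  if (turn_mean_s <= 0 || pause_mean_s <= 0 || fs_feature <= 0 ||
      fs_audio <= 0 || n_channels < 1)
    stop("invalid dialogue spec: non-positive rate, mean, or channel count")
  if (fs_audio %% fs_feature != 0)
    stop("invalid dialogue spec: fs_audio must be an integer multiple of fs_feature")
  structure(
    list(duration_s = duration_s, turn_mean_s = turn_mean_s,
         pause_mean_s = pause_mean_s, overlap_prob = overlap_prob,
         n_channels = n_channels, fs_feature = fs_feature,
         fs_audio = fs_audio, seed = as.integer(seed)),
    class = "dialogue_spec")
}

#' Ground truth of a synthetic session
#'
#' The known quantities the analysis should recover: per-channel response
#' kernels, the gain of the brain response to the other's speech
#' (`gain_other`), the gain of the response to one's own speech
#' (`gain_self`; 0 encodes full speech-induced suppression), the
#' microphone crosstalk (attenuated leak of the other's speech into one's
#' own microphone features), and the 1/f background noise level.
#'
#' @param kernels array `n_channels x n_features x n_lags`; lag `j` is the
#'   response `j` frames after the feature frame (lags `1..n_lags`).
#' @param gain_other,gain_self non-negative unitless gains.
#' @param crosstalk microphone crosstalk in `[0, 1)`.
#' @param noise_sd standard deviation of the 1/f background noise.
#' @param seed integer seed for the noise.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(kernels, gain_other = 1, gain_self = 0,
                         crosstalk = 0, noise_sd = 1, seed = 1L) {
  stopifnot(is.array(kernels), length(dim(kernels)) == 3)
  if (gain_other < 0 || gain_self < 0) stop("gains must be non-negative")
  if (crosstalk < 0 || crosstalk >= 1) stop("crosstalk must be in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(
    list(kernels = kernels, gain_other = gain_other, gain_self = gain_self,
         crosstalk = crosstalk, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "ground_truth")
}

#' Build a smooth multi-peak response kernel
#'
#' Deterministic sum of Gaussian bumps on the lag axis, emulating the
#' multi-peaked shape of auditory temporal response functions. Lag `j` of
#' the returned vector is the response `j` samples (frames) after the
#' stimulus frame, i.e. the lag axis runs `1/fs .. n_lags/fs` seconds.
#'
#' @param peak_lag_s peak latencies in seconds (vector).
#' @param widths Gaussian SDs in seconds (recycled against peaks).
#' @param amplitudes signed peak amplitudes (recycled).
#' @param n_lags kernel length in lags; default 77 (600 ms at 128 Hz with
#'   the contemporaneous sample excluded).
#' @param fs frame rate in Hz.
#' @return numeric vector of length `n_lags`.
#' @export
make_kernel <- function(peak_lag_s = c(0.05, 0.125, 0.25),
                        widths = c(0.02, 0.03, 0.06),
                        amplitudes = c(0.6, 1, -0.4),
                        n_lags = 77, fs = 128) {
  stopifnot(n_lags >= 1)
  m <- max(length(peak_lag_s), length(widths), length(amplitudes))
  peak_lag_s <- rep_len(peak_lag_s, m)
  widths <- rep_len(widths, m)
  amplitudes <- rep_len(amplitudes, m)
  lag_s <- seq_len(n_lags) / fs
  k <- numeric(n_lags)
  for (i in seq_len(m))
    k <- k + amplitudes[i] * exp(-0.5 * ((lag_s - peak_lag_s[i]) / widths[i])^2)
  k
}

#' Default ground-truth kernel bank for a session
#'
#' One smooth kernel per channel and mel band, with channel-specific peak
#' amplitudes and a mild band profile, so channels are distinguishable and
#' recovery can be scored per channel.
#'
#' @param n_channels,n_features,n_lags,fs dimensions and frame rate.
#' @param seed integer seed for the per-channel amplitude jitter.
#' @return array `n_channels x n_features x n_lags`.
#' @export
default_kernels <- function(n_channels, n_features = 16, n_lags = 77,
                            fs = 128, seed = 1L) {
  rs <- .session_rng(seed, "kernels")
  on.exit(rs())
  band_profile <- exp(-0.5 * ((seq_len(n_features) - n_features / 2) /
                                (n_features / 3))^2)
  k <- array(0, dim = c(n_channels, n_features, n_lags))
  for (c in seq_len(n_channels)) {
    amp <- c(0.6, 1, -0.4) * stats::runif(3, 0.7, 1.3) *
      sample(c(-1, 1), 1)  # polarity varies over the scalp
    base <- make_kernel(amplitudes = amp, n_lags = n_lags, fs = fs)
    for (f in seq_len(n_features)) k[c, f, ] <- band_profile[f] * base
  }
  k
}

# Run expr under a deterministic RNG derived from (seed, tag), restoring the
# caller's RNG state afterwards. Returns the restore function for on.exit.
.session_rng <- function(seed, tag) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  seed <- (as.numeric(seed) + strtoi(substr(fnv1a32(tag), 1, 7), 16L)) %% 2147483647
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

# draw alternating-speaker turn onsets/offsets for one session
.draw_turns <- function(spec) {
  turns <- list()
  t_cursor <- stats::rexp(1, 1 / spec$pause_mean_s)  # initial silence
  speaker <- 1L
  prev_end <- 0
  while (t_cursor < spec$duration_s) {
    dur <- stats::rexp(1, 1 / spec$turn_mean_s)
    start <- t_cursor
    end <- min(start + dur, spec$duration_s)
    turns[[length(turns) + 1L]] <- c(speaker, start, end)
    # next speaker's onset: overlap with prob overlap_prob, else a pause
    if (spec$overlap_prob > 0 && stats::runif(1) < spec$overlap_prob) {
      ov <- min(stats::rexp(1, 1 / spec$pause_mean_s), end - start)
      t_cursor <- end - ov
    } else {
      t_cursor <- end + stats::rexp(1, 1 / spec$pause_mean_s)
    }
    prev_end <- end
    speaker <- 3L - speaker
  }
  if (length(turns) == 0L)
    return(matrix(numeric(0), ncol = 3))
  do.call(rbind, turns)
}

# merge overlapping intervals of one speaker (an overlapped next-next turn
# can collide with the same speaker's previous turn in rare cases)
.merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= out[nrow(out), 2])
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    else out <- rbind(out, iv[i, ])
  }
  out
}

# Band-correlated amplitude-modulated feature streams inside speech.
# Per-band modulators are low-passed noise (~16 Hz), mixed across adjacent
# bands (tridiagonal 1/4-1/2-1/4) plus a slow global syllabic-rate (~4 Hz)
# component, giving the distance-decaying band correlation of real mel
# spectra (adjacent bands ~0.7, distant bands near 0). A 0.1 floor keeps
# speech energy positive; features are exactly zero outside speech.
.speech_features <- function(active, n_features, fs) {
  n <- length(active)
  smooth <- function(x, cut) {
    L <- max(3L, round(fs / cut))
    stats::filter(c(rep(x[1], L), x, rep(x[n], L)),
                  rep(1 / L, L), sides = 2)[(L + 1):(L + n)]
  }
  U <- vapply(seq_len(n_features + 2), function(i) {
    u <- smooth(stats::rnorm(n), 16)
    (u - min(u)) / diff(range(u))
  }, numeric(n))
  glob <- smooth(stats::rnorm(n), 4)
  glob <- (glob - min(glob)) / diff(range(glob))
  vals <- matrix(0, n_features, n)
  for (f in seq_len(n_features))
    vals[f, ] <- 0.25 * U[, f] + 0.5 * U[, f + 1] + 0.25 * U[, f + 2] +
      0.2 * glob + 0.1
  vals * rep(as.numeric(active), each = n_features)
}

#' Sample a synthetic two-speaker dialogue
#'
#' Draws alternating turns with exponential lengths and pauses, optional
#' onset overlap, and 16-band amplitude-modulated feature streams at the
#' frame rate (zero outside speech). Identical seeds give identical output.
#'
#' @param spec a [dialogue_spec()].
#' @param n_features number of mel-like feature bands per speaker.
#' @return list of two `speech_track` objects (fields `activity`: matrix of
#'   `[start_s, end_s)` rows; `features`: a [feature_series()]; `fs_audio`),
#'   one per speaker.
#' @export
sample_dialogue <- function(spec, n_features = 16) {
  stopifnot(inherits(spec, "dialogue_spec"))
  rs <- .session_rng(spec$seed, "dialogue")
  on.exit(rs())
  turns <- .draw_turns(spec)
  n_frames <- floor(spec$duration_s * spec$fs_feature)
  mid_s <- (seq_len(n_frames) - 0.5) / spec$fs_feature
  tracks <- vector("list", 2)
  for (sp in 1:2) {
    iv <- .merge_intervals(turns[turns[, 1] == sp, 2:3, drop = FALSE])
    active <- rep(FALSE, n_frames)
    for (i in seq_len(nrow(iv)))
      active <- active | (mid_s >= iv[i, 1] & mid_s < iv[i, 2])
    feats <- .speech_features(active, n_features, spec$fs_feature)
    tracks[[sp]] <- structure(
      list(activity = iv,
           features = feature_series(feats, spec$fs_feature, "spectrogram"),
           fs_audio = spec$fs_audio, speaker = sp),
      class = "speech_track")
  }
  tracks
}

#' @export
print.speech_track <- function(x, ...) {
  cat(sprintf("<speech_track speaker %d> %d intervals, %.1f s of speech\n",
              x$speaker, nrow(x$activity),
              sum(x$activity[, 2] - x$activity[, 1])))
  invisible(x)
}

#' Observed own-microphone features under crosstalk
#'
#' The directional microphone of a speaker mostly captures their own voice,
#' plus an attenuated leak of the other speaker's voice. Returns the
#' feature stream a feature extractor would observe on the own microphone.
#'
#' @param own,other `n_features x n_frames` matrices (or [feature_series()]).
#' @param crosstalk attenuation in `[0, 1)` of the other's features.
#' @return matrix of the same shape as `own`.
#' @export
apply_crosstalk <- function(own, other, crosstalk) {
  if (inherits(own, "feature_series")) own <- own$values
  if (inherits(other, "feature_series")) other <- other$values
  stopifnot(all(dim(own) == dim(other)), crosstalk >= 0, crosstalk < 1)
  own + crosstalk * other
}

#' Synthesize EEG from a dialogue and a ground truth
#'
#' Per channel `c`: `y_c(t) = gain_other * sum_f (k_cf (*) x^other_f)(t) +
#' gain_self * sum_f (k_cf (*) x^self_f)(t) + noise`, where `(*)` is causal
#' convolution over lags `1..n_lags` (the kernel applies to past feature
#' frames only) and the noise is 1/f with SD `noise_sd`. Identical seeds
#' give identical noise.
#'
#' @param self_track,other_track `speech_track`s from [sample_dialogue()],
#'   from the perspective of the participant whose EEG is generated
#'   (`self_track` is their own speech).
#' @param gt a [ground_truth()].
#' @return an [eeg_recording()] at the feature rate, band `"raw"`.
#' @export
synthesize_eeg <- function(self_track, other_track, gt) {
  xs <- self_track$features$values
  xo <- other_track$features$values
  if (!all(dim(xs) == dim(xo)))
    stop("shape error: tracks must share feature count and length")
  d <- dim(gt$kernels)
  if (d[2] != nrow(xs))
    stop("shape error: kernel feature count does not match tracks")
  n <- ncol(xs)
  fs <- self_track$features$fs
  rs <- .session_rng(gt$seed, "eeg-noise")
  on.exit(rs())
  y <- matrix(0, d[1], n)
  for (c in seq_len(d[1])) {
    acc <- numeric(n)
    for (f in seq_len(d[2])) {
      k <- c(0, gt$kernels[c, f, ])  # lag 0 coefficient is zero: strictly past
      if (gt$gain_other > 0) acc <- acc + gt$gain_other * fft_fir(xo[f, ], k)
      if (gt$gain_self > 0) acc <- acc + gt$gain_self * fft_fir(xs[f, ], k)
    }
    y[c, ] <- acc
  }
  if (gt$noise_sd > 0)
    for (c in seq_len(d[1])) y[c, ] <- y[c, ] + gt$noise_sd * pink_noise(n)
  eeg_recording(y, fs, band = "raw")
}

#' Noise SD giving a target signal-to-noise ratio
#'
#' Computes the SD of the noiseless synthetic EEG (averaged over channels)
#' and returns the noise SD such that `var(signal)/var(noise) = snr`.
#' Because the session alternates speech and silence, the session-wide
#' signal variance is dominated by the block structure; `samples` restricts
#' the variance computation to the frames actually analyzed (e.g. the
#' listening-condition samples), which is the SNR that governs encoding
#' performance there.
#'
#' @inheritParams synthesize_eeg
#' @param snr target power SNR.
#' @param samples optional frame indices over which the signal variance is
#'   measured; default all frames.
#' @return numeric noise SD.
#' @export
calibrate_noise_sd <- function(self_track, other_track, gt, snr,
                               samples = NULL) {
  stopifnot(snr > 0)
  gt0 <- gt
  gt0$noise_sd <- 0
  clean <- synthesize_eeg(self_track, other_track, gt0)$data
  if (!is.null(samples)) clean <- clean[, samples, drop = FALSE]
  sig_sd <- sqrt(mean(apply(clean, 1, stats::var)))
  sig_sd / sqrt(snr)
}

#' Write / read a synthetic session as plain text
#'
#' Stores features, activity intervals, EEG, and the ground truth of one
#' session in a directory of CSV and JSON files, plus the standard interval
#' table `intervals.csv` (`speaker,start_s,end_s`).
#'
#' @param tracks list of two `speech_track`s.
#' @param eeg an [eeg_recording()].
#' @param gt a [ground_truth()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(tracks, eeg, gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iv <- do.call(rbind, lapply(1:2, function(sp) {
    a <- tracks[[sp]]$activity
    if (nrow(a) == 0L) return(NULL)
    data.frame(speaker = sp, start_s = a[, 1], end_s = a[, 2])
  }))
  utils::write.csv(iv, file.path(dir, "intervals.csv"), row.names = FALSE)
  for (sp in 1:2)
    utils::write.csv(tracks[[sp]]$features$values,
                     file.path(dir, sprintf("features_speaker%d.csv", sp)),
                     row.names = FALSE)
  utils::write.csv(eeg$data, file.path(dir, "eeg.csv"), row.names = FALSE)
  meta <- list(fs_feature = tracks[[1]]$features$fs,
               fs_audio = tracks[[1]]$fs_audio,
               eeg_fs = eeg$fs, eeg_band = eeg$band,
               gain_other = gt$gain_other, gain_self = gt$gain_self,
               crosstalk = gt$crosstalk, noise_sd = gt$noise_sd,
               seed = gt$seed, kernel_dim = dim(gt$kernels),
               kernels = as.numeric(gt$kernels))
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  iv <- utils::read.csv(file.path(dir, "intervals.csv"))
  tracks <- lapply(1:2, function(sp) {
    vals <- as.matrix(utils::read.csv(
      file.path(dir, sprintf("features_speaker%d.csv", sp))))
    dimnames(vals) <- NULL
    a <- as.matrix(iv[iv$speaker == sp, c("start_s", "end_s")])
    dimnames(a) <- NULL
    structure(list(activity = a,
                   features = feature_series(vals, meta$fs_feature, "spectrogram"),
                   fs_audio = meta$fs_audio, speaker = sp),
              class = "speech_track")
  })
  ed <- as.matrix(utils::read.csv(file.path(dir, "eeg.csv")))
  dimnames(ed) <- NULL
  eeg <- eeg_recording(ed, meta$eeg_fs, band = meta$eeg_band)
  gt <- ground_truth(array(meta$kernels, dim = meta$kernel_dim),
                     gain_other = meta$gain_other, gain_self = meta$gain_self,
                     crosstalk = meta$crosstalk, noise_sd = meta$noise_sd,
                     seed = meta$seed)
  list(tracks = tracks, eeg = eeg, gt = gt)
}
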