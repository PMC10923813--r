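# Stimulus feature extraction at the EEG frame rate. Frames are
# non-overlapping 125-sample windows of 16 kHz audio, so no feature frame
# uses audio from later windows and the frame rate is exactly 128 Hz.

.frame_len <- 125L
.audio_fs <- 16000L

# Slaney-style mel scale: linear below 1 kHz, logarithmic above
hz_to_mel <- function(f) {
  ifelse(f < 1000, f / (200 / 3),
         15 + log(pmax(f, 1000) / 1000) / (log(6.4) / 27))
}

mel_to_hz <- function(m) {
  ifelse(m < 15, m * 200 / 3, 1000 * exp((m - 15) * log(6.4) / 27))
}

#' Mel triangular filterbank
#'
#' `n_mels` triangular filters between `fmin` and `fmax`, area-normalized
#' (Slaney style), evaluated at the FFT bin frequencies for an `n_fft`-point
#' transform at rate `fs`.
#'
#' @param n_mels number of filters (16 for the standard analysis).
#' @param fs audio sampling rate in Hz.
#' @param n_fft FFT length.
#' @param fmin,fmax filterbank frequency range in Hz.
#' @return matrix `n_mels x (n_fft/2 + 1)` of filter weights; attribute
#'   `"center_hz"` holds the filter center frequencies.
#' @export
mel_filterbank <- function(n_mels = 16, fs = 16000, n_fft = 128,
                           fmin = 0, fmax = 8000) {
  n_bins <- n_fft %/% 2 + 1L
  bin_hz <- (seq_len(n_bins) - 1) * fs / n_fft
  edges <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax),
                         length.out = n_mels + 2))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (bin_hz - lo) / (ce - lo)
    down <- (hi - bin_hz) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down)) * 2 / (hi - lo)  # area normalization
  }
  attr(fb, "center_hz") <- edges[2:(n_mels + 1)]
  fb
}

# split audio into the standard non-overlapping 125-sample frames (columns);
# trailing partial frame discarded
.frame_audio <- function(audio) {
  n_frames <- floor(length(audio) / .frame_len)
  if (n_frames == 0L) return(matrix(numeric(0), .frame_len, 0))
  matrix(audio[seq_len(n_frames * .frame_len)], .frame_len, n_frames)
}

#' Mel spectrogram of speech audio at the EEG frame rate
#'
#' Power spectrum per non-overlapping 125-sample window (zero-padded to a
#' 128-point FFT), projected on a 16-band mel filterbank up to 8 kHz, then
#' per-band min-max normalized to `[0, 1]`. One frame per window gives a
#' 128 Hz feature rate, and no frame uses audio samples from later windows.
#'
#' @param audio mono waveform at 16 kHz.
#' @param fs audio sampling rate; must be 16000 (resample beforehand).
#' @param n_mels number of mel bands.
#' @param normalize per-band min-max normalization to `[0, 1]` (default
#'   `TRUE`, matching the envelope contract).
#' @return a [feature_series()] with `n_mels` rows at 128 Hz.
#' @export
compute_mel_spectrogram <- function(audio, fs = 16000, n_mels = 16,
                                    normalize = TRUE) {
  if (fs != .audio_fs)
    stop("rate error: audio must be at 16 kHz (resample before calling)")
  frames <- .frame_audio(audio)
  n_fft <- 128L
  if (ncol(frames) == 0L)
    return(feature_series(matrix(numeric(0), n_mels, 0), 128, "spectrogram"))
  padded <- rbind(frames, matrix(0, n_fft - .frame_len, ncol(frames)))
  spec <- stats::mvfft(padded)[seq_len(n_fft %/% 2 + 1L), , drop = FALSE]
  power <- Mod(spec)^2
  fb <- mel_filterbank(n_mels, fs, n_fft)
  vals <- fb %*% power
  if (normalize) {
    rmin <- apply(vals, 1, min)
    rng <- apply(vals, 1, max) - rmin
    rng[rng <= 0] <- 1           # constant bands map to all zeros
    vals <- (vals - rmin) / rng  # row-wise via column-major recycling
  }
  feature_series(vals, 128, "spectrogram")
}

#' Speech envelope at the EEG frame rate
#'
#' Magnitude of the analytic signal (Hilbert transform), averaged over
#' non-overlapping 125-sample windows and min-max normalized to `[0, 1]`.
#' All-zero audio yields an all-zero envelope (the normalization is guarded
#' against divide-by-zero).
#'
#' @param audio mono waveform at 16 kHz.
#' @param fs audio sampling rate; must be 16000.
#' @return a [feature_series()] with one row at 128 Hz, values in `[0, 1]`.
#' @export
compute_envelope <- function(audio, fs = 16000) {
  if (fs != .audio_fs)
    stop("rate error: audio must be at 16 kHz (resample before calling)")
  if (length(audio) < .frame_len)
    return(feature_series(matrix(numeric(0), 1, 0), 128, "envelope"))
  env <- Mod(analytic_signal(audio))
  frames <- .frame_audio(env)
  vals <- minmax01(colMeans(frames))
  feature_series(matrix(vals, 1), 128, "envelope")
}

#' Alignment lag between two recordings by cross-correlation
#'
#' Integer lag (in samples) maximizing the cross-correlation between a
#' reference signal and a delayed copy; a positive lag means the copy lags
#' the reference, and shifting the copy forward by `-lag` aligns them.
#'
#' @param reference,delayed_copy numeric vectors (non-constant).
#' @param max_lag optional search bound in samples.
#' @return integer lag in samples.
#' @export
sync_by_crosscorr <- function(reference, delayed_copy, max_lag = NULL) {
  if (stats::sd(reference) == 0 || stats::sd(delayed_copy) == 0)
    stop("undefined lag: constant input signal")
  a <- reference - mean(reference)
  b <- delayed_copy - mean(delayed_copy)
  na <- length(a); nb <- length(b)
  m <- stats::nextn(na + nb, 2)
  # cc[k] = sum_t a(t) b(t + shift) at shift = -(k-1) mod m (circular);
  # zero-padding to na+nb makes it a full linear cross-correlation
  cc <- Re(stats::fft(stats::fft(c(b, numeric(m - nb))) *
                      Conj(stats::fft(c(a, numeric(m - na)))), inverse = TRUE)) / m
  shifts <- c(0:(m %/% 2), -(m - (m %/% 2 + 1)):-1)  # index -> signed shift
  keep <- if (is.null(max_lag)) rep(TRUE, m) else abs(shifts) <= max_lag
  best <- which(keep)[which.max(cc[keep])]
  as.integer(shifts[best])
}

#' Read and write mono PCM-16 WAV files
#'
#' Minimal RIFF/WAVE reader and writer for 16-bit mono PCM, the format of
#' the per-speaker speech recordings. Samples are scaled to `[-1, 1]`.
#'
#' @param path file path.
#' @return `read_wav`: list with `audio` (numeric vector in `[-1, 1]`) and
#'   `fs` (Hz). `write_wav`: `path`, invisibly.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, "raw", 4)) != "RIFF") stop("not a RIFF file")
  readBin(con, "integer", 1, 4, endian = "little")
  if (rawToChar(readBin(con, "raw", 4)) != "WAVE") stop("not a WAVE file")
  fs <- NULL; bits <- NULL; n_chan <- NULL; audio <- NULL
  repeat {
    tag <- readBin(con, "raw", 4)
    if (length(tag) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    id <- rawToChar(tag)
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", size %/% 2, 2, endian = "little",
                     signed = FALSE)
      n_chan <- fmt[2]; fs <- fmt[3] + 65536 * fmt[4]; bits <- fmt[8]
    } else if (id == "data") {
      audio <- readBin(con, "integer", size %/% 2, 2, endian = "little",
                       signed = TRUE)
      break
    } else {
      readBin(con, "raw", size + size %% 2)
    }
  }
  if (is.null(audio) || is.null(fs)) stop("malformed WAV file")
  if (is.null(bits) || bits != 16 || n_chan != 1)
    stop("only 16-bit mono PCM WAV is supported")
  list(audio = audio / 32768, fs = fs)
}

#' @rdname read_wav
#' @param audio numeric vector in `[-1, 1]`.
#' @param fs sampling rate in Hz.
#' @export
write_wav <- function(audio, fs, path) {
  pcm <- as.integer(pmax(-32768, pmin(32767, round(audio * 32767))))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")            # PCM, mono
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, 4, endian = "little")  # byte rate
  writeBin(c(2L, 16L), con, 2, endian = "little")           # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
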