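# Band filtering, standardization, decimation and re-referencing of EEG.
# The filter phase is an explicit choice: zero-phase (linear-phase FIR with
# group-delay compensation) preserves latencies; causal minimum-phase
# guarantees no output before input onset, at the price of a small positive
# delay that propagates into TRF latencies.

# window-method FIR band-pass; transition bandwidth follows the automatic
# rule min(max(0.25*edge, 2), edge) Hz on the lower edge
.design_bandpass <- function(low, high, fs) {
  stopifnot(fs > 2 * high)
  tb <- min(max(0.25 * low, 2), low)
  n_taps <- ceiling(3.3 / (tb / fs))      # hamming window design rule
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1L  # odd -> integer group delay
  signal::fir1(n_taps - 1L, c(low, high) / (fs / 2), type = "pass",
               window = signal::hamming(n_taps))
}

# convert a linear-phase FIR to its minimum-phase counterpart
# (homomorphic/cepstral method)
.minimum_phase <- function(h) {
  L <- length(h)
  n <- stats::nextn(8L * L, 2)
  H <- stats::fft(c(h, numeric(n - L)))
  mag <- pmax(Mod(H), max(Mod(H)) * 1e-8)
  cep <- Re(stats::fft(log(mag), inverse = TRUE)) / n
  fold <- cep
  fold[2:(n / 2)] <- 2 * cep[2:(n / 2)]
  fold[(n / 2 + 2):n] <- 0
  hm <- Re(stats::fft(exp(stats::fft(fold)), inverse = TRUE)) / n
  hm[seq_len(L)]
}

# apply FIR taps to one channel with edge-value padding;
# zero-phase variant compensates the (L-1)/2 group delay
.apply_fir <- function(x, h, zero_phase) {
  n <- length(x); L <- length(h)
  pad <- c(rep(x[1], L), x, rep(x[n], L))
  y <- fft_fir(pad, h)
  gd <- if (zero_phase) (L - 1L) %/% 2L else 0L
  y[(L + 1L + gd):(L + n + gd)]
}

#' Band-pass filter an EEG recording
#'
#' Window-method (hamming) FIR band-pass at the canonical band edges of
#' [eeg_bands()], with edge-value padding. `phase = "zero_phase"` applies
#' the linear-phase filter and compensates its group delay;
#' `phase = "causal_minimum_phase"` converts the filter to minimum phase
#' and applies it causally, so no output precedes its input.
#'
#' @param rec an [eeg_recording()].
#' @param band band name in `names(eeg_bands())`.
#' @param phase `"zero_phase"` or `"causal_minimum_phase"`.
#' @return a band-labeled [eeg_recording()].
#' @export
bandpass_band <- function(rec, band,
                          phase = c("zero_phase", "causal_minimum_phase")) {
  stopifnot(inherits(rec, "eeg_recording"))
  phase <- match.arg(phase)
  bands <- eeg_bands()
  if (!band %in% names(bands))
    stop("unknown band name: ", band)
  edges <- bands[[band]]
  h <- .design_bandpass(edges[1], edges[2], rec$fs)
  if (phase == "causal_minimum_phase") h <- .minimum_phase(h)
  out <- t(apply(rec$data, 1, .apply_fir, h = h,
                 zero_phase = phase == "zero_phase"))
  eeg_recording(out, rec$fs, band = band, channel_names = rec$channel_names)
}

#' Z-score and decimate an EEG recording
#'
#' Anti-alias low-pass (FIR, zero-phase), integer sub-sampling to
#' `target_fs`, then per-channel z-scoring, so every returned channel has
#' mean 0 and SD 1.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs target rate in Hz; `rec$fs` must be an integer multiple.
#' @return an [eeg_recording()] at `target_fs`.
#' @export
standardize_and_downsample <- function(rec, target_fs = 128) {
  stopifnot(inherits(rec, "eeg_recording"))
  ratio <- rec$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("rec$fs must be an integer multiple of target_fs")
  ratio <- as.integer(round(ratio))
  data <- rec$data
  if (ratio > 1L) {
    cutoff <- 0.8 * (target_fs / 2)
    n_taps <- 257L
    h <- signal::fir1(n_taps - 1L, cutoff / (rec$fs / 2), type = "low",
                      window = signal::hamming(n_taps))
    data <- t(apply(data, 1, .apply_fir, h = h, zero_phase = TRUE))
    n_out <- floor(ncol(data) * target_fs / rec$fs)
    data <- data[, seq(1L, by = ratio, length.out = n_out), drop = FALSE]
  }
  data <- t(apply(data, 1, function(x) as.numeric(scale(x))))
  eeg_recording(data, target_fs, band = rec$band,
                channel_names = rec$channel_names)
}

#' Re-reference to the average of all electrodes
#'
#' Subtracts, at every sample, the mean across channels, so the channel
#' mean is zero at every time point.
#'
#' @param rec an [eeg_recording()] with at least 2 channels.
#' @return an [eeg_recording()].
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2L) stop("average reference needs >= 2 channels")
  out <- sweep(rec$data, 2, colMeans(rec$data))
  eeg_recording(out, rec$fs, band = rec$band,
                channel_names = rec$channel_names)
}

#' Identity hook for externally cleaned data
#'
#' Artifact removal by ICA (ocular/muscle components) is performed with
#' external, expert-supervised tools on real recordings; this pass-through
#' hook marks the stage in pipelines without re-implementing it.
#'
#' @param rec an [eeg_recording()].
#' @return `rec`, unchanged.
#' @export
ica_passthrough <- function(rec) rec
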