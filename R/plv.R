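# Lagged phase-locking between the speech envelope and the EEG. Phases
# come from the analytic signal of the band-passed series; the PLV at lag
# tau is the modulus of the mean complex unit vector of the phase
# differences, with the envelope shifted back by tau so that positive lags
# mean the brain activity follows the auditory signal (a causally delayed
# EEG copy peaks at its positive delay).

#' Phase-locking value of two phase series
#'
#' Modulus of the mean phase-difference unit vector,
#' `|1/n sum exp(i (theta_a - theta_b))|`: 1 for perfect synchrony, 0 for
#' none. Invariant to a constant phase offset of either series.
#'
#' @param theta_env,theta_eeg equal-length phase series in radians.
#' @return PLV in `[0, 1]`.
#' @export
compute_plv <- function(theta_env, theta_eeg) {
  if (length(theta_env) == 0L || length(theta_eeg) == 0L)
    stop("empty phase series")
  stopifnot(length(theta_env) == length(theta_eeg))
  Mod(mean(exp(1i * (theta_env - theta_eeg))))
}

# zero-phase FIR band-pass of a single series, same design as the EEG
# band filters
.bandpass_series <- function(x, low, high, fs) {
  h <- .design_bandpass(low, high, fs)
  .apply_fir(x, h, zero_phase = TRUE)
}

#' Lagged PLV scan between the envelope and every EEG channel
#'
#' The envelope is band-passed 4-8 Hz (zero-phase, so latencies are not
#' filter-shifted); the EEG is used as provided (typically the Theta band).
#' Phases are extracted from the analytic signal of the full continuous
#' series, then the PLV at each integer-sample lag covering `lag_range_ms`
#' is computed over the condition samples only, concatenated across
#' segments as one trial; samples within `edge_frames` of a segment
#' boundary are dropped to limit filter-edge artifacts.
#'
#' @param env a [feature_series()] with one row (the envelope), or any
#'   single-row stream to treat as the envelope.
#' @param eeg an [eeg_recording()] at the same rate (band-filtered by the
#'   caller, typically Theta).
#' @param condition_samples frame indices belonging to the dialogue
#'   condition; default all frames.
#' @param lag_range_ms lag range to cover, default `c(-200, 400)`; the
#'   grid is every integer sample lag spanning it. Negative lags mean the
#'   EEG precedes the envelope.
#' @param env_band envelope band-pass edges in Hz (default `c(4, 8)`).
#' @param edge_frames segment-boundary guard in frames; default one period
#'   of the band's low edge.
#' @return object of class `plv_result`: `lags_ms`, `plv`
#'   (`n_channels x n_lags`), `mean_plv` (channel average per lag),
#'   `peak_lag_ms`, `n` (samples used per lag at the peak).
#' @export
plv_lag_scan <- function(env, eeg, condition_samples = NULL,
                         lag_range_ms = c(-200, 400), env_band = c(4, 8),
                         edge_frames = NULL) {
  stopifnot(inherits(eeg, "eeg_recording"))
  ev <- if (inherits(env, "feature_series")) drop(env$values) else as.numeric(env)
  stopifnot(is.numeric(ev))
  fs <- eeg$fs
  n <- ncol(eeg$data)
  stopifnot(length(ev) == n)
  if (is.null(condition_samples)) condition_samples <- seq_len(n)
  if (is.null(edge_frames)) edge_frames <- ceiling(fs / env_band[1])
  if (length(condition_samples) < fs / env_band[1])
    warning("fewer condition samples than one cycle of the band's low edge")
  theta_env <- Arg(analytic_signal(.bandpass_series(ev, env_band[1],
                                                    env_band[2], fs)))
  E_eeg <- exp(1i * t(apply(eeg$data, 1, function(x)
    Arg(analytic_signal(x)))))          # C x n unit phasors
  if (nrow(eeg$data) == 1L) E_eeg <- matrix(E_eeg, 1, n)
  # drop condition samples close to segment edges
  cs <- sort(unique(as.integer(condition_samples)))
  keep <- cs
  if (edge_frames > 0 && length(cs) > 0) {
    brk <- which(diff(cs) > 1)
    seg_start <- cs[c(1, brk + 1)]
    seg_end <- cs[c(brk, length(cs))]
    ok <- rep(FALSE, length(cs))
    for (i in seq_along(seg_start)) {
      lo <- seg_start[i] + edge_frames
      hi <- seg_end[i] - edge_frames
      ok <- ok | (cs >= lo & cs <= hi)
    }
    keep <- cs[ok]
  }
  if (length(keep) == 0L)
    stop("no condition samples left after edge trimming")
  lags <- seq.int(floor(lag_range_ms[1] / 1000 * fs),
                  ceiling(lag_range_ms[2] / 1000 * fs))
  Eenv <- exp(1i * theta_env)
  plv <- matrix(NA_real_, nrow(eeg$data), length(lags))
  n_used <- integer(length(lags))
  for (j in seq_along(lags)) {
    tau <- lags[j]
    t_ok <- keep[keep - tau >= 1 & keep - tau <= n]
    n_used[j] <- length(t_ok)
    if (length(t_ok) == 0L) next
    # exp(i(theta_env(t - tau) - theta_eeg(t)))
    z <- Conj(E_eeg[, t_ok, drop = FALSE]) *
      rep(Eenv[t_ok - tau], each = nrow(eeg$data))
    plv[, j] <- Mod(rowMeans(matrix(z, nrow(eeg$data))))
  }
  mean_plv <- colMeans(plv)
  peak <- which.max(mean_plv)
  structure(
    list(lags_ms = lags / fs * 1000, plv = plv, mean_plv = mean_plv,
         peak_lag_ms = lags[peak] / fs * 1000, n = n_used[peak]),
    class = "plv_result")
}

#' @export
print.plv_result <- function(x, ...) {
  cat(sprintf("<plv_result> %d channels x %d lags (%.1f..%.1f ms); peak %.1f ms (mean PLV %.3f)\n",
              nrow(x$plv), length(x$lags_ms), min(x$lags_ms), max(x$lags_ms),
              x$peak_lag_ms, max(x$mean_plv)))
  invisible(x)
}

#' Write a PLV scan as CSV
#'
#' One row per channel and lag: channel, lag_ms, plv, condition.
#'
#' @param res a [plv_lag_scan()] result.
#' @param path output CSV path.
#' @param condition condition label recorded in the table.
#' @param channel_names optional channel labels.
#' @return `path`, invisibly.
#' @export
write_plv_csv <- function(res, path, condition = "E", channel_names = NULL) {
  C <- nrow(res$plv); L <- length(res$lags_ms)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(C))
  df <- data.frame(channel = rep(channel_names, L),
                   lag_ms = rep(res$lags_ms, each = C),
                   plv = as.numeric(res$plv), condition = condition)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
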