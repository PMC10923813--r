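# Internal numerical helpers shared across modules.

#' Analytic signal via frequency-domain Hilbert transform
#'
#' Returns the complex analytic signal `x + i*H(x)`; its modulus is the
#' instantaneous amplitude and its argument the instantaneous phase.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty signal")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# linear convolution of x with FIR taps h via FFT; returns the causal
# output y[t] = sum_j h[j] x[t - j + 1], length(x)
fft_fir <- function(x, h) {
  n <- length(x); L <- length(h)
  m <- stats::nextn(n + L - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(m - n))) *
                     stats::fft(c(h, numeric(m - L))), inverse = TRUE)) / m
  y[seq_len(n)]
}

# min-max normalization to [0, 1]; constant input maps to all zeros
minmax01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

#' 1/f ("pink") background noise
#'
#' Gaussian noise spectrally shaped so that power falls as `1/f^exponent`,
#' scaled to unit standard deviation. Used as the EEG-like background of the
#' synthetic dialogue generator.
#'
#' @param n number of samples.
#' @param exponent spectral exponent of the power spectrum (default 1).
#' @return numeric vector of length `n` with SD 1.
#' @export
pink_noise <- function(n, exponent = 1) {
  stopifnot(n >= 2)
  w <- stats::rnorm(n)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)              # two-sided frequency index
  f[1] <- f[2]                     # keep DC finite
  scale <- f^(-exponent / 2)
  x <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# FNV-1a 32-bit hash of a character scalar, as hex; used to stamp outputs
# with a config fingerprint without external dependencies
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # modular multiply in 16-bit halves to stay inside double precision
    h_lo <- h %% 65536
    h_hi <- (h - h_lo) / 65536
    h <- (h_lo * m + ((h_hi * m) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", (h - h %% 65536) / 65536), sprintf("%04x", h %% 65536))
}

# contiguous, unshuffled fold assignment: fold i gets a contiguous run
fold_id_contiguous <- function(n, k) {
  stopifnot(n >= k, k >= 1)
  cuts <- floor(seq(0, n, length.out = k + 1))
  rep(seq_len(k), times = diff(cuts))
}
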