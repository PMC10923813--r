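# Shared fixtures, built in code at test time.

# small synthetic session with ground truth; SNR calibrated on the
# E-condition samples
make_session <- function(duration_s = 60, n_channels = 4, seed = 1,
                         gain_other = 1, gain_self = 0, crosstalk = 0,
                         snr = 10, overlap_prob = 0.2) {
  spec <- dialogue_spec(duration_s = duration_s, n_channels = n_channels,
                        overlap_prob = overlap_prob, seed = seed)
  tracks <- sample_dialogue(spec)
  mask <- label_conditions(tracks[[1]]$activity, tracks[[2]]$activity,
                           tracks[[1]]$features$n_frames, spec$fs_feature)
  kernels <- default_kernels(n_channels, seed = seed)
  gt <- ground_truth(kernels, gain_other = gain_other,
                     gain_self = gain_self, crosstalk = crosstalk,
                     seed = seed)
  sE <- extract_training_samples(mask, "E")
  if (is.finite(snr))
    gt$noise_sd <- calibrate_noise_sd(tracks[[1]], tracks[[2]], gt, snr,
                                      samples = if (length(sE)) sE else NULL)
  else gt$noise_sd <- 0
  eeg <- synthesize_eeg(tracks[[1]], tracks[[2]], gt)
  list(spec = spec, tracks = tracks, mask = mask, gt = gt, eeg = eeg,
       samples_E = sE, samples_S = extract_training_samples(mask, "S"))
}

# amplitude-modulated tone at 16 kHz
am_tone <- function(dur_s = 2, carrier_hz = 2000, mod_hz = 5,
                    fs = 16000, depth = 1) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  mod <- 1 + depth * sin(2 * pi * mod_hz * t)
  list(audio = mod * sin(2 * pi * carrier_hz * t), modulator = mod, t = t)
}

# independent BFS 4-connected labeling used as the clustering oracle
bfs_cluster_extents <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  ext <- matrix(0, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    members <- list()
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      members[[length(members) + 1L]] <- p
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
    for (p in members) ext[p[1], p[2]] <- length(members)
  }
  ext
}

# exhaustive two-sided signed-rank p over all 2^n sign assignments
# (independent oracle; midranks for ties)
signflip_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vall <- as.numeric(signs %*% rk)
  min(1, 2 * min(mean(vall <= v + 1e-9), mean(vall >= v - 1e-9)))
}

# reference BH step-up implementation (independent of stats::p.adjust)
bh_stepup_ref <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
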