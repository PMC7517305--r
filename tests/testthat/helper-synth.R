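# Shared fixtures: deterministic synthetic records, beat matching against
# ground truth, and brute-force oracles kept independent of the package
# implementations they check.

# a clean (noise-free by default) synthetic record with 10 s pre-ROSC lead-in
synth_record <- function(seed, duration = 75, rr = rr_model_params(),
                         morph = morphology_params(),
                         noise = noise_params(white_sd = 0, baseline_amp = 0,
                                              spike_rate = 0),
                         rosc = 10) {
  rrs <- generate_rr_series(rr, rosc + duration + 2, seed = seed)
  rec <- synthesize_ecg(rrs, morph, noise, fs = 250, seed = seed + 1000L)
  rec$rosc_time <- rosc
  rec
}

# ground-truth peaks inside the analysis window, in segment-local indices;
# a margin keeps edge-truncated complexes out of sensitivity scoring
gt_in_segment <- function(rec, tw, margin = 0.2) {
  fs <- rec$fs
  i0 <- floor(rec$rosc_time * fs)
  n <- round(tw * 60 * fs)
  gt <- rec$ground_truth_peaks - i0
  gt[gt >= 1 + margin * fs & gt <= n - margin * fs]
}

# sensitivity over interior truth beats, PPV over all truth beats
beat_stats <- function(det, truth_interior, truth_all, tol = 12L) {
  c(sens = mean(vapply(truth_interior,
                       function(t) any(abs(det - t) <= tol), logical(1))),
    ppv = mean(vapply(det,
                      function(d) any(abs(truth_all - d) <= tol), logical(1))))
}

# clean record plus a twin carrying a burst of large Gaussian spikes
spiked_pair <- function(seed, spike_times, spike_amp = 10000) {
  rrs <- generate_rr_series(rr_model_params(), 62, seed = seed)
  rec <- synthesize_ecg(rrs, morphology_params(),
                        noise_params(white_sd = 10, baseline_amp = 50,
                                     spike_rate = 0),
                        fs = 250, seed = seed + 1L)
  x <- rec$samples
  tt <- (seq_along(x) - 1) / 250
  for (tc in spike_times) {
    x <- x + spike_amp * exp(-(tt - tc)^2 / (2 * 0.01^2))
  }
  spiked <- rec
  spiked$samples <- x
  list(clean = rec, spiked = spiked)
}

# brute-force double-loop sample entropy (template counting), the oracle
# for the vectorized implementation
brute_sampen <- function(y, m, r) {
  n <- length(y)
  a <- 0L
  b <- 0L
  for (i in seq_len(n - m)) {
    for (j in seq_len(n - m)) {
      if (j <= i) next
      if (max(abs(y[i:(i + m - 1L)] - y[j:(j + m - 1L)])) <= r) {
        b <- b + 1L
        if (i + m <= n && j + m <= n && abs(y[i + m] - y[j + m]) <= r) {
          a <- a + 1L
        }
      }
    }
  }
  if (a == 0L || b == 0L) return(NA_real_)
  -log(a / b)
}

# random RR series (plain rr_series object) for formula oracles
rand_rr <- function(seed, n = 60, mean_rr = 0.8, sd = 0.05) {
  set.seed(seed)
  rr <- pmax(0.25, rnorm(n, mean_rr, sd))
  rr_series(c(0, cumsum(rr)))
}
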