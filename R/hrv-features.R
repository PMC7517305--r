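# Heart rate variability features v1-v17 computed from an RR series:
# time domain (v1-v6), Lomb-Scargle spectral (v7-v13), Poincare (v14-v16)
# and sample entropy (v17). Features that cannot be computed are returned
# as NA (the per-feature missing flag).

# interval times helper: time of the closing beat of each retained interval
rr_times_of <- function(rr) {
  if (!is.null(rr$rr_times)) rr$rr_times else rr$beat_times[-1L]
}

#' Time-domain HRV features (v1-v6)
#'
#' @param rr An `rr_series`.
#' @return Named numeric vector: `v1` mean RR (s), `v2` SDNN (sample SD,
#'   s), `v3` RMSSD (s), `v4` coefficient of variation `v2/v1`, `v5` NN50
#'   (count of successive differences over 50 ms), `v6` interquartile
#'   range of RR (s, linear-interpolation quantiles).
#' @export
compute_time_domain <- function(rr) {
  out <- c(v1 = NA_real_, v2 = NA_real_, v3 = NA_real_,
           v4 = NA_real_, v5 = NA_real_, v6 = NA_real_)
  x <- rr$rr
  n <- length(x)
  if (n < 2L) return(out)
  out["v1"] <- mean(x)
  out["v2"] <- stats::sd(x)
  out["v4"] <- out["v2"] / out["v1"]
  out["v6"] <- unname(diff(stats::quantile(x, c(0.25, 0.75), names = FALSE)))
  if (n >= 3L) {
    d <- diff(x)
    out["v3"] <- sqrt(mean(d^2))
    out["v5"] <- sum(abs(d) > 0.05)
  }
  out
}

#' Lomb-Scargle periodogram of the RR series
#'
#' Classical Lomb-Scargle periodogram of the mean-subtracted RR values at
#' their (unevenly spaced) beat times, evaluated on a fixed grid from
#' 0.005 to 0.5 Hz in steps of 0.0025 Hz. The power is scaled to a
#' one-sided density (s^2/Hz) such that the grid-integrated power
#' approximates the series variance.
#'
#' @param rr An `rr_series` with at least 8 intervals.
#' @param f_grid Frequency grid in Hz.
#' @return A list of class `psd_spectrum` with `freqs` and `psd`, or
#'   `NULL` when too few intervals are available.
#' @export
compute_lomb_psd <- function(rr, f_grid = seq(0.005, 0.5, by = 0.0025)) {
  x <- rr$rr
  if (length(x) < 8L) return(NULL)
  t <- rr_times_of(rr)
  x <- x - mean(x)
  n <- length(x)
  fs_mean <- (n - 1) / (t[n] - t[1L])
  omega <- 2 * pi * f_grid
  psd <- vapply(omega, function(w) {
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau))
    st <- sin(w * (t - tau))
    p <- 0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
    p
  }, numeric(1))
  structure(list(freqs = f_grid, psd = 2 * psd / fs_mean),
            class = "psd_spectrum")
}

#' Frequency-domain HRV features (v7-v13)
#'
#' Band powers by trapezoidal integration of the RR spectrum over the LF
#' (0.04-0.15 Hz) and HF (0.15-0.4 Hz) bands.
#'
#' @param spec A `psd_spectrum` covering `[0.04, 0.4]` Hz (e.g. from
#'   [compute_lomb_psd()]).
#' @return Named numeric vector: `v7`/`v9` absolute LF/HF power (s^2),
#'   `v8`/`v10` relative LF/HF power (normalized by LF+HF), `v11` LF/HF
#'   ratio, `v12`/`v13` LF/HF peak frequency (Hz). Ratios are `NA` when
#'   LF+HF power is zero.
#' @export
compute_freq_domain <- function(spec) {
  out <- c(v7 = NA_real_, v8 = NA_real_, v9 = NA_real_, v10 = NA_real_,
           v11 = NA_real_, v12 = NA_real_, v13 = NA_real_)
  if (is.null(spec)) return(out)
  f <- spec$freqs
  p <- spec$psd
  assert_that(min(f) <= 0.04 && max(f) >= 0.4,
              "spectrum must cover [0.04, 0.4] Hz")
  lf <- f >= 0.04 & f <= 0.15
  hf <- f >= 0.15 & f <= 0.4
  out["v7"] <- trapz(f[lf], p[lf])
  out["v9"] <- trapz(f[hf], p[hf])
  tot <- out["v7"] + out["v9"]
  if (tot > 0) {
    out["v8"] <- out["v7"] / tot
    out["v10"] <- out["v9"] / tot
    if (out["v9"] > 0) out["v11"] <- out["v7"] / out["v9"]
  }
  out["v12"] <- f[lf][which.max(p[lf])]
  out["v13"] <- f[hf][which.max(p[hf])]
  out
}

#' Poincare features (v14-v16)
#'
#' From consecutive interval pairs `(RR_k, RR_{k+1})`: `v14` = SD1^2, the
#' sample variance of `(RR_{k+1} - RR_k)/sqrt(2)` (dispersion across the
#' identity line); `v15` = SD2^2, the sample variance of
#' `(RR_{k+1} + RR_k)/sqrt(2)` (dispersion along it); `v16 = v14/v15`.
#'
#' @param rr An `rr_series` with at least 3 intervals.
#' @return Named numeric vector `v14`, `v15`, `v16` (s^2, s^2, ratio).
#' @export
compute_poincare <- function(rr) {
  out <- c(v14 = NA_real_, v15 = NA_real_, v16 = NA_real_)
  x <- rr$rr
  n <- length(x)
  if (n < 3L) return(out)
  d <- (x[-1L] - x[-n]) / sqrt(2)
  s <- (x[-1L] + x[-n]) / sqrt(2)
  out["v14"] <- stats::var(d)
  out["v15"] <- stats::var(s)
  if (out["v15"] > 0) out["v16"] <- out["v14"] / out["v15"]
  out
}

#' Sample entropy of the RR series (v17)
#'
#' The RR series is cubically interpolated onto a uniform 10 Hz grid over
#' its time span, then SampEn(m = 1, r = 0.2 * SD of the interpolated
#' series, Chebyshev distance, self-matches excluded) is computed as
#' `-ln(A/B)`, where `B` counts matching template pairs of length `m` and
#' `A` of length `m + 1`.
#'
#' @param rr An `rr_series` with at least 4 beats spanning at least 10 s.
#' @param m Embedding dimension.
#' @param r_frac Tolerance as a fraction of the interpolated series SD.
#' @param interp_fs Interpolation rate in Hz.
#' @return SampEn value, or `NA` when undefined (no matches).
#' @export
compute_sample_entropy <- function(rr, m = 1L, r_frac = 0.2, interp_fs = 10) {
  x <- rr$rr
  t <- rr_times_of(rr)
  if (length(x) < 3L || (t[length(t)] - t[1L]) < 10) return(NA_real_)
  grid <- seq(t[1L], t[length(t)], by = 1 / interp_fs)
  y <- stats::spline(t, x, xout = grid, method = "fmm")$y
  sampen(y, m = m, r = r_frac * stats::sd(y))
}

#' Sample entropy of a numeric series
#'
#' @param y Uniformly sampled numeric series.
#' @param m Embedding dimension (only `m = 1` is vectorized; larger `m`
#'   falls back to a direct implementation).
#' @param r Absolute tolerance (Chebyshev distance).
#' @return `-ln(A/B)`; `NA` when `A` or `B` is zero.
#' @export
sampen <- function(y, m = 1L, r) {
  n <- length(y)
  if (n < m + 2L) return(NA_real_)
  if (m == 1L) {
    h <- y[seq_len(n - 1L)]
    dm <- abs(outer(h, h, "-")) <= r
    b <- (sum(dm) - (n - 1L)) / 2
    tl <- y[2:n]
    dm1 <- dm & (abs(outer(tl, tl, "-")) <= r)
    a <- (sum(dm1) - (n - 1L)) / 2
  } else {
    nt <- n - m
    b <- 0
    a <- 0
    for (i in seq_len(nt - 1L)) {
      for (j in seq(i + 1L, nt)) {
        if (max(abs(y[i:(i + m - 1L)] - y[j:(j + m - 1L)])) <= r) {
          b <- b + 1
          if (abs(y[i + m] - y[j + m]) <= r) a <- a + 1
        }
      }
    }
  }
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}
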