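# ECG waveform features v18-v21 computed directly from the filtered
# analysis segment: Welch spectral centroid (v18), mean absolute
# amplitude (v19), relative QRS-band power (v20) and the SD of
# wavelet-delineated QRS widths (v21).

#' Welch power spectral density of an ECG segment
#'
#' Averaged modified periodogram: 12 s Hann-tapered windows, 50% overlap,
#' 4096-point FFT. At 250 Hz this gives a frequency step of
#' `fs/4096 ~ 0.061` Hz.
#'
#' @param segment An [analysis_segment()] at least `win_s` seconds long.
#' @param win_s Window length in seconds.
#' @param overlap Fractional overlap between windows.
#' @param nfft FFT length (windows are zero-padded to this length).
#' @return A `psd_spectrum` (one-sided, uV^2/Hz) with `n_windows` attached.
#' @export
compute_welch_psd <- function(segment, win_s = 12, overlap = 0.5, nfft = 4096) {
  stopifnot(inherits(segment, "analysis_segment"))
  x <- segment$samples
  fs <- segment$fs
  L <- round(win_s * fs)
  assert_that(length(x) >= L, "segment must be at least one window long")
  hop <- round(L * (1 - overlap))
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1L)) / (L - 1L))  # Hann
  u <- sum(w^2)
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  half <- nfft %/% 2L + 1L
  acc <- numeric(half)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    X <- stats::fft(c(seg, numeric(nfft - L)))
    acc <- acc + Mod(X[seq_len(half)])^2
  }
  p <- acc / length(starts) / (fs * u)
  p[2:(half - 1L)] <- 2 * p[2:(half - 1L)]  # one-sided
  structure(list(freqs = (seq_len(half) - 1L) * fs / nfft, psd = p,
                 n_windows = length(starts)),
            class = "psd_spectrum")
}

#' Spectral centroid frequency (v18)
#'
#' Power-weighted mean frequency of the estimated spectrum,
#' `sum(PSD(fi) * fi) / sum(PSD(fi))` over the full grid.
#'
#' @param spec A `psd_spectrum`.
#' @return Centroid frequency in Hz, `NA` when total power is zero.
#' @export
compute_centroid_frequency <- function(spec) {
  tot <- sum(spec$psd)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  sum(spec$psd * spec$freqs) / tot
}

#' Mean absolute ECG amplitude (v19)
#'
#' @param segment An [analysis_segment()] (or numeric vector).
#' @return Mean of the absolute sample values, in microvolts.
#' @export
compute_mean_abs_amplitude <- function(segment) {
  x <- if (inherits(segment, "analysis_segment")) segment$samples else segment
  mean(abs(x))
}

#' Relative QRS-band power (v20)
#'
#' Fraction of spectral power in the QRS-complex band (5-14 Hz, band
#' edges inclusive), with the denominator taken over the full grid.
#'
#' @param spec A `psd_spectrum` covering the QRS band.
#' @param band QRS band in Hz.
#' @return Fraction in `[0, 1]`, `NA` when total power is zero.
#' @export
compute_relative_qrs_power <- function(spec, band = c(5, 14)) {
  tot <- sum(spec$psd)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  inb <- spec$freqs >= band[1L] & spec$freqs <= band[2L]
  sum(spec$psd[inb]) / tot
}

# Dyadic stationary (a trous) wavelet transform with the quadratic-spline
# mother wavelet (Mallat-Zhong filter bank): lowpass h = [1,3,3,1]/8,
# highpass g = [2,-2]. Returns the detail signal at the requested scale,
# shifted to compensate the filter-bank group delay.
mz_wavelet_detail <- function(x, scale_exp = 2L) {
  h0 <- c(1, 3, 3, 1) / 8
  g0 <- c(2, -2)
  s <- x
  n <- length(x)
  conv_same <- function(v, k) {
    out <- stats::convolve(v, rev(k), type = "open")
    out[seq_len(length(v))]
  }
  upsample <- function(k, j) {
    if (j == 1L) return(k)
    kk <- numeric((length(k) - 1L) * 2^(j - 1L) + 1L)
    kk[seq(1L, length(kk), by = 2^(j - 1L))] <- k
    kk
  }
  delay <- 0
  w <- NULL
  for (j in seq_len(scale_exp)) {
    gj <- upsample(g0, j)
    if (j == scale_exp) {
      w <- conv_same(s, gj)
      delay <- delay + 0.5 * 2^(j - 1L)
    } else {
      hj <- upsample(h0, j)
      s <- conv_same(s, hj)
      delay <- delay + 1.5 * 2^(j - 1L)
    }
  }
  shift <- round(delay)
  out <- numeric(n)
  if (shift < n) out[seq_len(n - shift)] <- w[(shift + 1L):n]
  out
}

#' Wavelet QRS delineation and width variability (v21)
#'
#' Each QRS is delineated on the dyadic quadratic-spline wavelet detail at
#' scale 2^2: the modulus-maxima pair bracketing the R peak (positive
#' maximum before, negative minimum after, search windows +-120 ms) marks
#' the complex; onset/offset are placed where `|W|` first falls below
#' 0.1 times the corresponding local modulus maximum.
#'
#' @param segment A filtered [analysis_segment()].
#' @param beats [beat_annotations()] for the segment (>= 3 beats).
#' @param search_win Search half-window around the R peak, seconds.
#' @param thr_frac Threshold as a fraction of the local modulus maximum.
#' @return A data.frame with one row per delineated beat:
#'   `peak_index`, `onset_time`, `offset_time`, `width` (seconds).
#' @export
delineate_qrs <- function(segment, beats, search_win = 0.12, thr_frac = 0.1) {
  stopifnot(inherits(segment, "analysis_segment"),
            inherits(beats, "beat_annotations"))
  x <- segment$samples
  fs <- segment$fs
  w2 <- mz_wavelet_detail(x, 2L)
  win <- round(search_win * fs)
  n <- length(x)
  rows <- lapply(beats$peak_indices, function(p) {
    lo <- max(1L, p - win)
    hi <- min(n, p + win)
    if (p - lo < 3L || hi - p < 3L) return(NULL)
    pre <- w2[lo:p]
    post <- w2[p:hi]
    i_max <- lo + which.max(pre) - 1L
    i_min <- p + which.min(post) - 1L
    if (w2[i_max] <= 0 || w2[i_min] >= 0) return(NULL)
    thr_on <- thr_frac * abs(w2[i_max])
    thr_off <- thr_frac * abs(w2[i_min])
    onset <- NA_integer_
    for (i in seq(i_max, lo)) {
      if (abs(w2[i]) < thr_on) { onset <- i; break }
    }
    offset <- NA_integer_
    for (i in seq(i_min, hi)) {
      if (abs(w2[i]) < thr_off) { offset <- i; break }
    }
    if (is.na(onset) || is.na(offset)) return(NULL)
    width <- (offset - onset) / fs
    if (width <= 0 || width > 0.3) return(NULL)
    data.frame(peak_index = p, onset_time = (onset - 1L) / fs,
               offset_time = (offset - 1L) / fs, width = width)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(peak_index = integer(0), onset_time = numeric(0),
                      offset_time = numeric(0), width = numeric(0)))
  }
  do.call(rbind, rows)
}

#' QRS width variability (v21)
#'
#' Sample SD of the delineated QRS widths. Requires at least 3 delineated
#' beats covering at least half of the detected beats.
#'
#' @param delin Output of [delineate_qrs()].
#' @param n_beats Number of detected beats the delineation was run on.
#' @return SD of QRS width in seconds, or `NA`.
#' @export
qrs_width_sd <- function(delin, n_beats) {
  if (nrow(delin) < 3L || nrow(delin) < 0.5 * n_beats) return(NA_real_)
  stats::sd(delin$width)
}
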