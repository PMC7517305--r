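# QRS detection and RR-series construction.
#
# Primary detector: Hamilton-Tompkins (band-pass emphasis, differentiation,
# rectification, 80 ms moving-window integration, adaptive peak/noise
# thresholds with a 200 ms refractory period and searchback). A
# variance-based correction rescues beats suppressed by spike-inflated
# thresholds. Secondary detector: curve-length transform (Zong-style),
# more sensitive at low SNR. Agreement between the two yields the
# beat-agreement signal quality index (bSQI).

#' Construct beat annotations
#'
#' @param peak_indices Strictly increasing R-peak sample indices.
#' @param detector_id `"primary"` or `"secondary"`.
#' @return An object of class `beat_annotations`.
#' @export
beat_annotations <- function(peak_indices, detector_id = "primary") {
  peak_indices <- as.integer(peak_indices)
  if (length(peak_indices) >= 2L) {
    assert_that(all(diff(peak_indices) > 0),
                "peak_indices must be strictly increasing")
  }
  structure(list(peak_indices = peak_indices, detector_id = detector_id),
            class = "beat_annotations")
}

# local maxima of a numeric vector (strict rise, non-strict fall)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

# refine detections to the local ECG extremum within +-win seconds
refine_peaks <- function(x, idx, fs, win = 0.04) {
  w <- round(win * fs)
  n <- length(x)
  out <- integer(length(idx))
  for (k in seq_along(idx)) {
    lo <- max(1L, idx[k] - w)
    hi <- min(n, idx[k] + w)
    out[k] <- lo + which.max(abs(x[lo:hi])) - 1L
  }
  out
}

# drop detections too close to the segment edges: a complex cut by the
# boundary cannot be located reliably, and the two detectors would
# disagree arbitrarily there
trim_edge_beats <- function(idx, n, fs, guard = 0.1) {
  g <- round(guard * fs)
  idx[idx > g & idx <= n - g]
}

# enforce minimum separation, keeping the earlier detection on collision
dedup_peaks <- function(idx, min_sep) {
  idx <- sort(unique(idx))
  if (length(idx) < 2L) return(idx)
  keep <- idx[1L]
  for (i in idx[-1L]) {
    if (i - keep[length(keep)] >= min_sep) keep <- c(keep, i)
  }
  keep
}

# adaptive-threshold peak selection shared by both detectors: walk the
# candidate peaks of a detection function in time order, maintaining signal
# and noise level estimates, a refractory period and mean-RR searchback.
adaptive_select <- function(det, fs, cand = local_maxima(det),
                            thr_coef = 0.3125, refractory = 0.2,
                            searchback_factor = 1.5, sb_coef = 0.5) {
  if (length(cand) == 0L) return(integer(0))
  # keep only candidates dominant within +-refractory (one per complex)
  w <- round(refractory * fs)
  n_det <- length(det)
  dominant <- vapply(cand, function(i) {
    det[i] >= max(det[max(1L, i - w):min(n_det, i + w)])
  }, logical(1))
  cand <- cand[dominant]
  if (length(cand) == 0L) return(integer(0))
  heights <- det[cand]
  # initialize level estimates from the first two seconds of candidates
  init <- heights[cand <= 2 * fs]
  if (length(init) == 0L) init <- heights[seq_len(min(5L, length(heights)))]
  spk <- max(init)
  npk <- stats::median(init) * 0.5
  thr <- function() npk + thr_coef * (spk - npk)
  qrs <- integer(0)
  rr_hist <- numeric(0)
  rej_idx <- integer(0)
  rej_h <- numeric(0)
  for (k in seq_along(cand)) {
    i <- cand[k]
    h <- heights[k]
    if (length(qrs) > 0L && (i - qrs[length(qrs)]) < refractory * fs) next
    if (h > thr()) {
      # searchback before accepting: was a beat missed in a long gap?
      if (length(qrs) > 0L && length(rr_hist) >= 2L) {
        gap <- i - qrs[length(qrs)]
        if (gap > searchback_factor * mean(rr_hist) * fs && length(rej_idx)) {
          inwin <- rej_idx > qrs[length(qrs)] + refractory * fs &
            rej_idx < i - refractory * fs
          if (any(inwin)) {
            hh <- rej_h[inwin]
            ii <- rej_idx[inwin]
            best <- which.max(hh)
            if (hh[best] > sb_coef * thr()) {
              rr_hist <- c(rr_hist, (ii[best] - qrs[length(qrs)]) / fs)
              qrs <- c(qrs, ii[best])
              spk <- 0.75 * spk + 0.25 * hh[best]
            }
          }
        }
      }
      if (length(qrs) > 0L) {
        rr_hist <- c(rr_hist, (i - qrs[length(qrs)]) / fs)
        if (length(rr_hist) > 8L) rr_hist <- utils::tail(rr_hist, 8L)
      }
      qrs <- c(qrs, i)
      spk <- 0.875 * spk + 0.125 * h
    } else {
      npk <- 0.875 * npk + 0.125 * h
      rej_idx <- c(rej_idx, i)
      rej_h <- c(rej_h, h)
      if (length(rej_idx) > 32L) {
        rej_idx <- utils::tail(rej_idx, 32L)
        rej_h <- utils::tail(rej_h, 32L)
      }
    }
  }
  qrs
}

#' Hamilton-Tompkins QRS detection
#'
#' Band-pass emphasis around 8-16 Hz, differentiation, rectification,
#' 80 ms moving-window integration, then adaptive peak/noise thresholding
#' with a 200 ms refractory period and searchback when the current gap
#' exceeds 1.5 times the running mean RR. Detections are refined to the
#' local ECG extremum within +-40 ms.
#'
#' @param segment A filtered [analysis_segment()], at least 5 s long.
#' @return A [beat_annotations()] object (possibly with zero beats).
#' @export
detect_qrs_primary <- function(segment) {
  stopifnot(inherits(segment, "analysis_segment"))
  x <- segment$samples
  fs <- segment$fs
  assert_that(length(x) >= 5 * fs, "segment must be at least 5 s long")
  if (stats::sd(x) == 0) return(beat_annotations(integer(0), "primary"))
  bf <- signal::butter(3, c(8, 16) / (fs / 2), type = "pass")
  xe <- signal::filtfilt(bf, x)
  det <- moving_average(abs(c(diff(xe), 0)), round(0.08 * fs))
  qrs <- adaptive_select(det, fs)
  if (length(qrs) < 2L) return(beat_annotations(integer(0), "primary"))
  qrs <- refine_peaks(x, qrs, fs)
  qrs <- trim_edge_beats(qrs, length(x), fs)
  beat_annotations(dedup_peaks(qrs, round(0.2 * fs)), "primary")
}

#' Curve-length-transform QRS detection
#'
#' Secondary detector: the curve length of the ECG over a sliding 130 ms
#' window (computed on the millivolt-scaled signal), detrended by a 2 s
#' moving average, then passed through the same adaptive thresholding as
#' the primary detector. More sensitive than the primary detector at low
#' signal-to-noise ratios.
#'
#' @param segment A filtered [analysis_segment()].
#' @return A [beat_annotations()] object.
#' @export
detect_qrs_secondary <- function(segment) {
  stopifnot(inherits(segment, "analysis_segment"))
  x <- segment$samples
  fs <- segment$fs
  assert_that(length(x) >= 5 * fs, "segment must be at least 5 s long")
  if (stats::sd(x) == 0) return(beat_annotations(integer(0), "secondary"))
  # low-pass at 16 Hz before the transform (the length transform itself
  # has no spectral selectivity; unsmoothed broadband noise would swamp
  # the QRS slope contribution)
  lp <- signal::butter(3, 16 / (fs / 2), type = "low")
  xl <- signal::filtfilt(lp, x)
  dy <- diff(xl / 1000) * fs           # mV per second
  len_el <- sqrt(1 + dy^2) / fs        # curve-length element per sample
  lt <- moving_average(c(len_el, 0), round(0.13 * fs)) * round(0.13 * fs)
  det <- lt - moving_average(lt, round(2 * fs))
  det[det < 0] <- 0
  qrs <- adaptive_select(det, fs)
  if (length(qrs) < 2L) return(beat_annotations(integer(0), "secondary"))
  qrs <- refine_peaks(x, qrs, fs)
  qrs <- trim_edge_beats(qrs, length(x), fs)
  beat_annotations(dedup_peaks(qrs, round(0.2 * fs)), "secondary")
}

#' Variance-based correction of QRS detections
#'
#' Large transient artifacts inflate the adaptive thresholds of the
#' primary detector and can suppress subsequent true beats. The correction
#' computes a sliding 1 s variance; samples inside windows whose variance
#' exceeds 5 times the median window variance are amplitude-clipped to the
#' 99th percentile of the remaining signal, the detector is re-run on the
#' clipped signal, and the two annotation sets are merged (union with
#' 200 ms de-duplication, keeping the original index on collision). On
#' clean signals the correction is the identity.
#'
#' @param segment The filtered [analysis_segment()] the beats came from.
#' @param beats [beat_annotations()] from [detect_qrs_primary()].
#' @return Corrected [beat_annotations()]; never removes an input beat.
#' @export
apply_variance_correction <- function(segment, beats) {
  stopifnot(inherits(segment, "analysis_segment"),
            inherits(beats, "beat_annotations"))
  x <- segment$samples
  fs <- segment$fs
  n <- length(x)
  w <- round(fs)            # 1 s windows
  hop <- round(fs / 4)      # sliding by 250 ms
  starts <- seq(1L, max(1L, n - w + 1L), by = hop)
  v <- vapply(starts, function(s) stats::var(x[s:min(n, s + w - 1L)]), numeric(1))
  med_v <- stats::median(v, na.rm = TRUE)
  bad_win <- which(v > 5 * med_v)
  if (length(bad_win) == 0L || med_v == 0) return(beats)
  bad_mask <- rep(FALSE, n)
  for (s in starts[bad_win]) bad_mask[s:min(n, s + w - 1L)] <- TRUE
  if (all(bad_mask)) return(beats)
  clip <- stats::quantile(abs(x[!bad_mask]), 0.99, names = FALSE)
  xc <- pmin(pmax(x, -clip), clip)
  seg_c <- segment
  seg_c$samples <- xc
  beats2 <- detect_qrs_primary(seg_c)
  merged <- beats$peak_indices
  for (i in beats2$peak_indices) {
    if (length(merged) == 0L || min(abs(merged - i)) >= 0.2 * fs) {
      merged <- c(merged, i)
    }
  }
  beat_annotations(sort(merged), beats$detector_id)
}

#' Beat-agreement signal quality index (bSQI)
#'
#' Greedy nearest-neighbour one-to-one matching of two detectors' beats
#' within a tolerance; bSQI is the number of matched beats over the union
#' of all detected beats, `matched / (|a| + |b| - matched)`.
#'
#' @param a,b [beat_annotations()] from the same segment.
#' @param fs Sampling frequency in Hz.
#' @param tol Matching tolerance in seconds.
#' @return A list with `bsqi` (fraction, `NA` when both sets are empty),
#'   `n_matched` and `n_union`.
#' @export
compute_sqi <- function(a, b, fs, tol = 0.15) {
  ta <- a$peak_indices / fs
  tb <- b$peak_indices / fs
  na_ <- length(ta)
  nb <- length(tb)
  if (na_ + nb == 0L) {
    return(list(bsqi = NA_real_, n_matched = 0L, n_union = 0L))
  }
  pairs <- NULL
  if (na_ > 0L && nb > 0L) {
    d <- abs(outer(ta, tb, "-"))
    cand <- which(d <= tol, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(d[cand])
      cand <- cand[ord, , drop = FALSE]
      used_a <- logical(na_)
      used_b <- logical(nb)
      m <- 0L
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1L]
        j <- cand[r, 2L]
        if (!used_a[i] && !used_b[j]) {
          used_a[i] <- TRUE
          used_b[j] <- TRUE
          m <- m + 1L
        }
      }
      pairs <- m
    }
  }
  matched <- if (is.null(pairs)) 0L else pairs
  n_union <- na_ + nb - matched
  list(bsqi = matched / n_union, n_matched = matched, n_union = n_union)
}

#' Build an RR series from beat annotations
#'
#' Beat times are `peak_indices / fs`; successive differences outside the
#' physiological range `[0.2, 3.0]` s (artifact gaps, missed beats) are
#' dropped from the interval series, keeping the neighbouring intervals.
#'
#' @param beats A [beat_annotations()] object with at least 2 beats.
#' @param fs Sampling frequency in Hz.
#' @param rr_range Valid RR range in seconds.
#' @return An `rr_series` whose `rr` holds the retained intervals and
#'   `rr_times` the time of each interval's closing beat, or `NULL` when
#'   fewer than 2 beats are available.
#' @export
build_rr_series <- function(beats, fs, rr_range = c(0.2, 3.0)) {
  stopifnot(inherits(beats, "beat_annotations"))
  if (length(beats$peak_indices) < 2L) return(NULL)
  bt <- beats$peak_indices / fs
  rr <- diff(bt)
  keep <- rr >= rr_range[1L] & rr <= rr_range[2L]
  out <- rr_series(bt)
  out$rr <- rr[keep]
  out$rr_times <- bt[-1L][keep]
  if (length(out$rr) < 1L) return(NULL)
  out
}
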