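# ECG conditioning: record/segment containers, segment extraction at the
# ROSC annotation, and zero-phase band-pass filtering.

#' Construct an ECG record
#'
#' One patient's single-channel ECG plus the clinical annotations needed by
#' the pipeline: the ROSC onset time and (for training data) the binary
#' rearrest label.
#'
#' @param patient_id Identifier string.
#' @param samples ECG samples in microvolts.
#' @param fs Sampling frequency in Hz.
#' @param rosc_time ROSC onset, seconds from record start.
#' @param rearrest_time Rearrest time in seconds, or `NA`.
#' @param label 1 = rearrest (RA), 0 = sustained ROSC (NoRA), `NA` unknown.
#' @param ground_truth_peaks Optional true R-peak sample indices
#'   (synthetic records only).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(patient_id, samples, fs, rosc_time = 0,
                       rearrest_time = NA_real_, label = NA_integer_,
                       ground_truth_peaks = NULL) {
  assert_that(fs > 0, "fs must be positive")
  assert_that(length(samples) > 0, "samples must be non-empty")
  assert_that(rosc_time >= 0, "rosc_time must be non-negative")
  assert_that(is.na(label) || label %in% c(0L, 1L), "label must be 0, 1 or NA")
  structure(list(patient_id = as.character(patient_id),
                 samples = as.numeric(samples), fs = fs,
                 rosc_time = rosc_time, rearrest_time = rearrest_time,
                 label = as.integer(label),
                 ground_truth_peaks = ground_truth_peaks),
            class = "ecg_record")
}

#' Construct an analysis segment
#'
#' @param samples ECG samples in microvolts.
#' @param fs Sampling frequency in Hz.
#' @param tw Segment length in minutes.
#' @param origin Patient id the segment was cut from.
#' @return An object of class `analysis_segment`.
#' @export
analysis_segment <- function(samples, fs, tw = length(samples) / fs / 60,
                             origin = NA_character_) {
  assert_that(fs > 0, "fs must be positive")
  structure(list(samples = as.numeric(samples), fs = fs, tw = tw,
                 origin = origin),
            class = "analysis_segment")
}

#' Extract the post-ROSC analysis segment
#'
#' Cuts `tw` minutes of signal starting at the ROSC annotation, using the
#' half-open window `[rosc_time, rosc_time + 60 * tw)`.
#'
#' @param record An [ecg_record()].
#' @param tw Window length in minutes.
#' @return An [analysis_segment()], or `NULL` (with a warning) when the
#'   record holds less than `tw` minutes after `rosc_time`.
#' @export
extract_segment <- function(record, tw) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  i0 <- floor(record$rosc_time * fs) + 1L
  n_seg <- round(tw * 60 * fs)
  i1 <- i0 + n_seg - 1L
  if (i1 > length(record$samples)) {
    warning(sprintf("record %s skipped: less than %g min of signal after ROSC",
                    record$patient_id, tw))
    return(NULL)
  }
  analysis_segment(record$samples[i0:i1], fs, tw = tw, origin = record$patient_id)
}

#' Zero-phase band-pass filter (0.5-40 Hz, order-4 Butterworth)
#'
#' Applies an order-4 Butterworth band-pass forward and backward
#' (zero net phase; effective order 8 in magnitude). The segment is
#' reflect-padded by one settling length before filtering to suppress end
#' transients, then trimmed back to its original length.
#'
#' @param segment An [analysis_segment()] (or a numeric vector, with `fs`).
#' @param low,high Band edges in Hz.
#' @param order Filter order of the one-pass design.
#' @param fs Sampling frequency, required when `segment` is a bare vector.
#' @return Filtered segment of the same class and length as the input.
#' @export
bandpass_filter <- function(segment, low = 0.5, high = 40, order = 4, fs = NULL) {
  if (inherits(segment, "analysis_segment")) {
    x <- segment$samples
    fs <- segment$fs
  } else {
    assert_that(!is.null(fs), "fs is required for a bare numeric vector")
    x <- as.numeric(segment)
  }
  assert_that(fs > 2 * high, "sampling rate too low for the requested passband")
  n <- length(x)
  pad <- min(n - 1L, ceiling(3 * fs / low))  # settling length ~ 3 periods of the low edge
  assert_that(n > 3L, "segment too short to filter")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  y <- signal::filtfilt(bf, xp)
  y <- y[(pad + 1L):(pad + n)]
  if (inherits(segment, "analysis_segment")) {
    segment$samples <- y
    segment
  } else {
    y
  }
}
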