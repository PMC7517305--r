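# Synthetic post-ROSC ECG cohort simulator.
#
# Generates labeled single-channel ECG records with known beat-to-beat (RR)
# dynamics and known R-peak positions, so that every downstream stage of the
# rearrest-prediction pipeline (QRS detection, HRV features, waveform
# features, classification) can be validated against ground truth.

#' RR-interval model parameters
#'
#' Parameters of the generative RR model: a mean interval modulated by one
#' low-frequency (LF) and one high-frequency (HF) sinusoid — emulating the
#' classical LF (0.04–0.15 Hz) and HF (0.15–0.4 Hz) structure of heart rate
#' variability — plus white beat-to-beat jitter and occasional ectopic
#' beats (a shortened interval followed by a compensatory lengthening).
#'
#' @param mean_rr Mean RR interval in seconds (> 0.25).
#' @param sdnn_target Optional target SDNN in seconds. When given, the
#'   LF/HF amplitudes and the jitter SD are rescaled by a common factor so
#'   that the model's theoretical RR standard deviation
#'   `sqrt(lf_amp^2/2 + hf_amp^2/2 + jitter_sd^2)` equals this value.
#' @param lf_amp,lf_freq LF modulation amplitude (s) and frequency (Hz,
#'   in `[0.04, 0.15)`).
#' @param hf_amp,hf_freq HF modulation amplitude (s) and frequency (Hz,
#'   in `[0.15, 0.4]`).
#' @param jitter_sd SD of white RR noise in seconds.
#' @param ectopic_rate Probability per beat of an ectopic perturbation
#'   (RR shortened by 30%, next RR lengthened by 30%).
#' @return An object of class `rr_model_params`.
#' @export
rr_model_params <- function(mean_rr = 0.6, sdnn_target = NULL,
                            lf_amp = 0.04, lf_freq = 0.10,
                            hf_amp = 0.04, hf_freq = 0.30,
                            jitter_sd = 0.06, ectopic_rate = 0.02) {
  assert_that(mean_rr > 0.25, "mean_rr must exceed 0.25 s")
  assert_that(all(c(lf_amp, hf_amp, jitter_sd, ectopic_rate) >= 0),
              "amplitudes, jitter_sd and ectopic_rate must be non-negative")
  assert_that(lf_freq >= 0.04 && lf_freq < 0.15, "lf_freq must lie in [0.04, 0.15)")
  assert_that(hf_freq >= 0.15 && hf_freq <= 0.4, "hf_freq must lie in [0.15, 0.4]")
  if (!is.null(sdnn_target)) {
    assert_that(sdnn_target >= 0, "sdnn_target must be non-negative")
    sd0 <- sqrt(lf_amp^2 / 2 + hf_amp^2 / 2 + jitter_sd^2)
    if (sd0 > 0) {
      k <- sdnn_target / sd0
      lf_amp <- lf_amp * k
      hf_amp <- hf_amp * k
      jitter_sd <- jitter_sd * k
    }
  }
  structure(list(mean_rr = mean_rr, lf_amp = lf_amp, lf_freq = lf_freq,
                 hf_amp = hf_amp, hf_freq = hf_freq,
                 jitter_sd = jitter_sd, ectopic_rate = ectopic_rate),
            class = "rr_model_params")
}

#' ECG beat morphology parameters
#'
#' The beat template is a sum of Gaussian bumps: a narrow positive QRS bump
#' whose nominal duration is `qrs_width` (the template is scaled so that a
#' derivative-based delineator recovers approximately this width) and a
#' broader, lower T bump 250 ms after the R peak. `qrs_width_sd` adds
#' beat-to-beat jitter to the QRS duration, the ground truth for the QRS
#' width-variability feature.
#'
#' @param qrs_width Nominal QRS duration in seconds (`[0.02, 0.2]`).
#' @param qrs_amp R-peak amplitude in microvolts.
#' @param t_amp T-wave amplitude in microvolts.
#' @param qrs_width_sd SD of beat-to-beat QRS width jitter in seconds.
#' @return An object of class `morphology_params`.
#' @export
morphology_params <- function(qrs_width = 0.08, qrs_amp = 1000,
                              t_amp = 200, qrs_width_sd = 0.005) {
  assert_that(qrs_width >= 0.02 && qrs_width <= 0.2,
              "qrs_width must lie in [0.02, 0.2] s")
  assert_that(all(c(qrs_amp, t_amp, qrs_width_sd) >= 0),
              "amplitudes and qrs_width_sd must be non-negative")
  structure(list(qrs_width = qrs_width, qrs_amp = qrs_amp,
                 t_amp = t_amp, qrs_width_sd = qrs_width_sd),
            class = "morphology_params")
}

#' Additive ECG noise parameters
#'
#' @param baseline_amp Baseline-wander sinusoid amplitude in microvolts.
#' @param baseline_freq Baseline-wander frequency in Hz (< 0.5).
#' @param white_sd SD of broadband white noise in microvolts.
#' @param spike_rate Transient spike artifacts per minute.
#' @param spike_amp Spike amplitude in microvolts.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(baseline_amp = 100, baseline_freq = 0.25,
                         white_sd = 15, spike_rate = 0.3, spike_amp = 2000) {
  assert_that(all(c(baseline_amp, baseline_freq, white_sd,
                    spike_rate, spike_amp) >= 0),
              "all noise parameters must be non-negative")
  assert_that(baseline_freq < 0.5, "baseline_freq must be below 0.5 Hz")
  structure(list(baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 white_sd = white_sd, spike_rate = spike_rate,
                 spike_amp = spike_amp),
            class = "noise_params")
}

#' Synthetic cohort configuration
#'
#' @param n_patients Number of patients (>= 2).
#' @param prevalence Fraction of rearrest (RA) patients, strictly in (0, 1).
#'   The realized number of RA records is `round(n_patients * prevalence)`.
#' @param tw Analysis-window length in minutes (1, 2 or 5).
#' @param fs Sampling frequency in Hz.
#' @param class_effect Named numeric vector of multipliers applied to the RA
#'   patients' generative parameters (names among `mean_rr`, `lf_amp`,
#'   `hf_amp`, `jitter_sd`, `ectopic_rate`, `qrs_width`, `qrs_amp`, `t_amp`,
#'   `qrs_width_sd`). The default makes RA records more RR-variable
#'   (larger SDNN and Poincare dispersion) and relatively more sinusoidal
#'   (lower sample entropy), with more variable QRS widths.
#' @param base_rr,base_morph,base_noise Baseline generative parameters
#'   shared by all patients before per-patient heterogeneity and class
#'   effects are applied.
#' @param rosc_lead Seconds of signal simulated before the ROSC annotation.
#' @param seed Master seed; per-patient sub-seeds are spawned from it so a
#'   cohort is reproducible independent of patient order.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 162, prevalence = 55 / 162,
                          tw = 2, fs = 250,
                          class_effect = c(lf_amp = 2.5, hf_amp = 2.5,
                                           jitter_sd = 1.5, qrs_width_sd = 2),
                          base_rr = rr_model_params(),
                          base_morph = morphology_params(),
                          base_noise = noise_params(),
                          rosc_lead = 10, seed = 1L) {
  assert_that(n_patients >= 2, "n_patients must be at least 2")
  assert_that(prevalence > 0 && prevalence < 1,
              "prevalence must lie strictly in (0, 1)")
  assert_that(tw %in% c(1, 2, 5), "tw must be 1, 2 or 5 minutes")
  assert_that(fs > 0, "fs must be positive")
  n_ra <- round(n_patients * prevalence)
  assert_that(n_ra >= 1 && n_ra <= n_patients - 1,
              "prevalence must yield at least one record of each class")
  structure(list(n_patients = as.integer(n_patients), prevalence = prevalence,
                 tw = tw, fs = fs, class_effect = class_effect,
                 base_rr = base_rr, base_morph = base_morph,
                 base_noise = base_noise, rosc_lead = rosc_lead,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Construct an RR series
#'
#' @param beat_times Strictly increasing beat times in seconds.
#' @return An object of class `rr_series` with fields `beat_times` and
#'   `rr` (successive differences).
#' @export
rr_series <- function(beat_times) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) >= 2L) {
    assert_that(all(diff(beat_times) > 0), "beat_times must be strictly increasing")
  }
  structure(list(beat_times = beat_times, rr = diff(beat_times)),
            class = "rr_series")
}

#' Generate a synthetic RR series
#'
#' Beat times are built cumulatively (integral-pulse style): the interval
#' started at beat time `t_k` is
#' `RR_k = mean_rr + lf_amp*sin(2*pi*lf_freq*t_k) + hf_amp*sin(2*pi*hf_freq*t_k) + jitter`,
#' with jitter redrawn whenever an interval would fall at or below 0.2 s.
#' Ectopic perturbations (30% shortening with compensatory lengthening) are
#' applied afterwards.
#'
#' @param params An [rr_model_params()] object.
#' @param duration Duration to cover in seconds (>= 10).
#' @param seed Integer seed; identical seeds give identical series.
#' @return An [rr_series()] whose beat times span `[0, duration]`.
#' @export
generate_rr_series <- function(params, duration, seed = NULL) {
  stopifnot(inherits(params, "rr_model_params"))
  assert_that(is.numeric(duration) && length(duration) == 1L && duration > 0,
              "duration must be a positive scalar")
  assert_that(duration >= 10 || params$jitter_sd == 0,
              "duration must be at least 10 s")
  with_seed(seed, {
    n_max <- ceiling(duration / 0.2) + 2L
    times <- numeric(n_max)
    t <- 0
    n <- 1L
    repeat {
      mod <- params$mean_rr +
        params$lf_amp * sin(2 * pi * params$lf_freq * t) +
        params$hf_amp * sin(2 * pi * params$hf_freq * t)
      rr <- mod + if (params$jitter_sd > 0) stats::rnorm(1L, 0, params$jitter_sd) else 0
      tries <- 0L
      while (rr <= 0.2 && tries < 100L) {
        rr <- mod + stats::rnorm(1L, 0, params$jitter_sd)
        tries <- tries + 1L
      }
      if (rr <= 0.2) rr <- 0.201  # pathological parameters: clamp
      t <- t + rr
      if (t > duration + 1e-9) break
      n <- n + 1L
      times[n] <- t
    }
    times <- times[seq_len(n)]
    rr <- diff(times)
    if (params$ectopic_rate > 0 && length(rr) >= 2L) {
      hit <- which(stats::runif(length(rr) - 1L) < params$ectopic_rate)
      for (k in hit) {
        if (rr[k] * 0.7 > 0.2) {
          rr[k] <- rr[k] * 0.7
          rr[k + 1L] <- rr[k + 1L] * 1.3
        }
      }
      times <- c(times[1L], times[1L] + cumsum(rr))
    }
    rr_series(times)
  })
}

# Gaussian bump scale: a symmetric Gaussian QRS of sd sigma crosses 10% of
# its maximum slope at ~2.76*sigma either side of the peak, so a
# derivative-threshold delineator reports a width of ~5.5*sigma.
.QRS_SIGMA_FACTOR <- 5.5

#' Synthesize an ECG record from an RR series
#'
#' Places one beat template (narrow Gaussian QRS bump plus a broad low
#' T bump 250 ms later) at every beat time, then adds a baseline-wander
#' sinusoid, white noise and transient spike artifacts. Ground-truth R-peak
#' sample indices are stored on the record.
#'
#' @param rr An [rr_series()].
#' @param morph A [morphology_params()] object.
#' @param noise A [noise_params()] object.
#' @param fs Sampling frequency in Hz.
#' @param seed Integer seed.
#' @param patient_id Identifier stored on the record.
#' @return An [ecg_record()] with `ground_truth_peaks` filled in.
#' @export
synthesize_ecg <- function(rr, morph = morphology_params(),
                           noise = noise_params(), fs = 250, seed = NULL,
                           patient_id = "synthetic") {
  stopifnot(inherits(rr, "rr_series"), inherits(morph, "morphology_params"),
            inherits(noise, "noise_params"))
  assert_that(fs > 0, "fs must be positive")
  assert_that(length(rr$beat_times) >= 1L, "rr must contain at least one beat")
  duration <- max(rr$beat_times)
  n <- ceiling(duration * fs)
  if (n < 1L) n <- 1L
  with_seed(seed, {
    x <- numeric(n)
    tb <- rr$beat_times
    widths <- rep(morph$qrs_width, length(tb)) +
      if (morph$qrs_width_sd > 0) stats::rnorm(length(tb), 0, morph$qrs_width_sd) else 0
    widths <- pmax(widths, 0.02)
    sig_t <- 0.08
    for (i in seq_along(tb)) {
      sig_q <- widths[i] / .QRS_SIGMA_FACTOR
      # QRS bump over +-5 sigma
      i0 <- max(1L, floor((tb[i] - 5 * sig_q) * fs) + 1L)
      i1 <- min(n, ceiling((tb[i] + 5 * sig_q) * fs) + 1L)
      if (i0 <= i1) {
        tt <- (seq(i0, i1) - 1L) / fs
        x[i0:i1] <- x[i0:i1] + morph$qrs_amp * exp(-(tt - tb[i])^2 / (2 * sig_q^2))
      }
      if (morph$t_amp > 0) {
        tc <- tb[i] + 0.25
        j0 <- max(1L, floor((tc - 4 * sig_t) * fs) + 1L)
        j1 <- min(n, ceiling((tc + 4 * sig_t) * fs) + 1L)
        if (j0 <= j1) {
          tt <- (seq(j0, j1) - 1L) / fs
          x[j0:j1] <- x[j0:j1] + morph$t_amp * exp(-(tt - tc)^2 / (2 * sig_t^2))
        }
      }
    }
    tt_all <- (seq_len(n) - 1L) / fs
    if (noise$baseline_amp > 0) {
      phi <- stats::runif(1L, 0, 2 * pi)
      x <- x + noise$baseline_amp * sin(2 * pi * noise$baseline_freq * tt_all + phi)
    }
    if (noise$white_sd > 0) x <- x + stats::rnorm(n, 0, noise$white_sd)
    if (noise$spike_rate > 0 && noise$spike_amp > 0) {
      n_spikes <- stats::rpois(1L, noise$spike_rate * duration / 60)
      if (n_spikes > 0L) {
        centers <- stats::runif(n_spikes, 0, duration)
        signs <- sample(c(-1, 1), n_spikes, replace = TRUE)
        for (k in seq_len(n_spikes)) {
          sig_s <- 0.01  # ~30 ms wide transient
          i0 <- max(1L, floor((centers[k] - 3 * sig_s) * fs) + 1L)
          i1 <- min(n, ceiling((centers[k] + 3 * sig_s) * fs) + 1L)
          tt <- (seq(i0, i1) - 1L) / fs
          x[i0:i1] <- x[i0:i1] +
            signs[k] * noise$spike_amp * exp(-(tt - centers[k])^2 / (2 * sig_s^2))
        }
      }
    }
    peaks <- pmin(pmax(round(tb * fs) + 1L, 1L), n)
    ecg_record(patient_id = patient_id, samples = x, fs = fs,
               rosc_time = 0, label = NA_integer_,
               ground_truth_peaks = as.integer(peaks))
  })
}

# apply named multipliers to a parameter list, keeping its class
apply_multipliers <- function(params, mult) {
  for (nm in names(mult)) {
    if (!is.null(params[[nm]])) params[[nm]] <- params[[nm]] * mult[[nm]]
  }
  params
}

#' Generate a labeled synthetic cohort
#'
#' Produces `round(n_patients * prevalence)` rearrest (RA) records and the
#' remainder no-rearrest (NoRA) records. Per-patient heterogeneity is drawn
#' log-normally around the baseline parameters; RA patients additionally
#' receive the configured `class_effect` multipliers. Each record carries
#' `rosc_lead` seconds of pre-ROSC signal plus `tw` minutes (and a 2 s
#' tail) after the ROSC annotation.
#'
#' @param config A [cohort_config()] object.
#' @return A list of [ecg_record()] objects with `label` set (1 = RA,
#'   0 = NoRA) and attribute `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  n_ra <- round(n * config$prevalence)
  labels <- c(rep(1L, n_ra), rep(0L, n - n_ra))
  seeds <- spawn_seeds(config$seed, 3L * n)
  duration <- config$rosc_lead + config$tw * 60 + 2
  records <- vector("list", n)
  for (i in seq_len(n)) {
    het <- with_seed(seeds[i], {
      list(mean_rr = exp(stats::rnorm(1L, 0, 0.15)),
           lf_amp = exp(stats::rnorm(1L, 0, 0.3)),
           hf_amp = exp(stats::rnorm(1L, 0, 0.3)),
           jitter_sd = exp(stats::rnorm(1L, 0, 0.3)),
           qrs_amp = exp(stats::rnorm(1L, 0, 0.2)),
           qrs_width = exp(stats::rnorm(1L, 0, 0.1)),
           rearrest_lag = exp(stats::rnorm(1L, log(300), 0.5)))
    })
    rr_p <- apply_multipliers(config$base_rr, het[c("mean_rr", "lf_amp",
                                                    "hf_amp", "jitter_sd")])
    morph_p <- apply_multipliers(config$base_morph, het[c("qrs_amp", "qrs_width")])
    noise_p <- config$base_noise
    if (labels[i] == 1L) {
      rr_p <- apply_multipliers(rr_p, config$class_effect)
      morph_p <- apply_multipliers(morph_p, config$class_effect)
    }
    rr_p$mean_rr <- max(rr_p$mean_rr, 0.3)
    morph_p$qrs_width <- min(max(morph_p$qrs_width, 0.02), 0.2)
    rrs <- generate_rr_series(rr_p, duration, seed = seeds[n + i])
    rec <- synthesize_ecg(rrs, morph_p, noise_p, fs = config$fs,
                          seed = seeds[2L * n + i],
                          patient_id = sprintf("pt%03d", i))
    rec$rosc_time <- config$rosc_lead
    rec$label <- labels[i]
    rec$rearrest_time <- if (labels[i] == 1L) config$rosc_lead + het$rearrest_lag else NA_real_
    records[[i]] <- rec
  }
  structure(records, config = config, class = "ecg_cohort")
}

#' Write a cohort to per-patient CSV files plus a manifest
#'
#' Each record is written as a two-column CSV `(time_s, ecg_uV)`; the
#' manifest CSV lists `patient_id, label, tw_min, fs_hz, path, rosc_time_s`.
#'
#' @param cohort A list of [ecg_record()]s, e.g. from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param tw Analysis-window length recorded in the manifest, in minutes.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir, tw = NULL) {
  if (is.null(tw)) {
    cfg <- attr(cohort, "config")
    tw <- if (!is.null(cfg)) cfg$tw else NA_real_
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(rec) {
    path <- file.path(dir, paste0(rec$patient_id, ".csv"))
    utils::write.csv(
      data.frame(time_s = (seq_along(rec$samples) - 1L) / rec$fs,
                 ecg_uV = rec$samples),
      path, row.names = FALSE)
    data.frame(patient_id = rec$patient_id, label = rec$label, tw_min = tw,
               fs_hz = rec$fs, path = basename(path),
               rosc_time_s = rec$rosc_time)
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}
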