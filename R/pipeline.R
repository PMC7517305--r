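# End-to-end pipeline: configuration, cohort reading, per-record feature
# extraction (label-blind), feature-table assembly and the full
# extract -> filter -> detect -> featurize -> evaluate run.

#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one auditable place.
#' Defaults: 2 min windows at 250 Hz, 0.5-40 Hz order-4 zero-phase
#' band-pass, SampEn with m = 1, r = 0.2 x SD at 10 Hz interpolation,
#' Welch 12 s / 50% / 4096 points, forest of 300 trees on 5% bootstraps,
#' 5-fold cross-validation repeated 100 times.
#'
#' @param tw Analysis-window length in minutes.
#' @param fs Sampling frequency in Hz.
#' @param filter_band Band-pass edges in Hz.
#' @param filter_order Butterworth order (one pass).
#' @param sampen_m,sampen_r,sampen_fs Sample-entropy parameters.
#' @param lomb_grid Lomb-Scargle frequency grid in Hz.
#' @param welch_win,welch_overlap,welch_nfft Welch parameters.
#' @param rf An [rf_config()].
#' @param cv_k,cv_reps Cross-validation folds and repetitions.
#' @param feature_mode `"all"` (21 features) or `"hrv_only"` (17).
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(tw = 2, fs = 250, filter_band = c(0.5, 40),
                            filter_order = 4, sampen_m = 1L, sampen_r = 0.2,
                            sampen_fs = 10,
                            lomb_grid = seq(0.005, 0.5, by = 0.0025),
                            welch_win = 12, welch_overlap = 0.5,
                            welch_nfft = 4096, rf = rf_config(),
                            cv_k = 5L, cv_reps = 100L,
                            feature_mode = c("all", "hrv_only"), seed = 1L) {
  feature_mode <- match.arg(feature_mode)
  structure(list(tw = tw, fs = fs, filter_band = filter_band,
                 filter_order = filter_order, sampen_m = sampen_m,
                 sampen_r = sampen_r, sampen_fs = sampen_fs,
                 lomb_grid = lomb_grid, welch_win = welch_win,
                 welch_overlap = welch_overlap, welch_nfft = welch_nfft,
                 rf = rf, cv_k = cv_k, cv_reps = cv_reps,
                 feature_mode = feature_mode, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Feature columns for a feature-subset mode
#'
#' @param mode `"all"` (v1-v21) or `"hrv_only"` (v1-v17).
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(mode = c("all", "hrv_only")) {
  mode <- match.arg(mode)
  paste0("v", seq_len(if (mode == "all") 21L else 17L))
}

#' Read a cohort from a manifest CSV
#'
#' The manifest has columns `patient_id, label, tw_min, fs_hz, path,
#' rosc_time_s`; each `path` (relative to the manifest) is a two-column
#' CSV `(time_s, ecg_uV)`.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return A list of [ecg_record()]s. Unreadable records are skipped with
#'   a warning.
#' @export
read_cohort <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  dir <- dirname(manifest_path)
  records <- list()
  for (i in seq_len(nrow(man))) {
    path <- file.path(dir, man$path[i])
    rec <- tryCatch({
      sig <- utils::read.csv(path)
      ecg_record(patient_id = man$patient_id[i], samples = sig$ecg_uV,
                 fs = man$fs_hz[i], rosc_time = man$rosc_time_s[i],
                 label = man$label[i])
    }, error = function(e) {
      warning(sprintf("record %s skipped: %s", man$patient_id[i],
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  records
}

#' Extract the 21-feature vector from one record
#'
#' Label-blind feature extraction for a single patient: cut the post-ROSC
#' segment, band-pass filter, detect beats (primary detector plus
#' variance correction), run the secondary detector for the bSQI, build
#' the RR series and compute v1-v21.
#'
#' @param record An [ecg_record()].
#' @param config A [pipeline_config()].
#' @return A named list with `v1`...`v21`, `bsqi`, `n_beats`, or `NULL`
#'   when the record is too short.
#' @export
extract_features <- function(record, config = pipeline_config()) {
  seg <- extract_segment(record, config$tw)
  if (is.null(seg)) return(NULL)
  seg <- bandpass_filter(seg, low = config$filter_band[1L],
                         high = config$filter_band[2L],
                         order = config$filter_order)
  beats <- detect_qrs_primary(seg)
  beats <- apply_variance_correction(seg, beats)
  sec <- detect_qrs_secondary(seg)
  sqi <- compute_sqi(beats, sec, seg$fs)
  feats <- stats::setNames(rep(NA_real_, 21L), paste0("v", 1:21))
  rr <- build_rr_series(beats, seg$fs)
  if (!is.null(rr)) {
    feats[1:6] <- compute_time_domain(rr)
    spec_rr <- compute_lomb_psd(rr, f_grid = config$lomb_grid)
    feats[7:13] <- compute_freq_domain(spec_rr)
    feats[14:16] <- compute_poincare(rr)
    feats["v17"] <- compute_sample_entropy(rr, m = config$sampen_m,
                                           r_frac = config$sampen_r,
                                           interp_fs = config$sampen_fs)
  }
  spec_ecg <- compute_welch_psd(seg, win_s = config$welch_win,
                                overlap = config$welch_overlap,
                                nfft = config$welch_nfft)
  feats["v18"] <- compute_centroid_frequency(spec_ecg)
  feats["v19"] <- compute_mean_abs_amplitude(seg)
  feats["v20"] <- compute_relative_qrs_power(spec_ecg)
  if (length(beats$peak_indices) >= 3L) {
    delin <- delineate_qrs(seg, beats)
    feats["v21"] <- qrs_width_sd(delin, length(beats$peak_indices))
  }
  c(as.list(feats), list(bsqi = sqi$bsqi,
                         n_beats = length(beats$peak_indices)))
}

#' Build the feature table for a cohort
#'
#' Runs [extract_features()] on every record (feature extraction never
#' looks at labels; the label column is joined afterwards for the
#' evaluation stage) and logs one line per patient with the beat count,
#' bSQI and any missing features.
#'
#' @param records List of [ecg_record()]s.
#' @param config A [pipeline_config()].
#' @param verbose Emit one log line per record.
#' @return A data.frame `patient_id, label, tw_min, v1..v21, bsqi,
#'   n_beats, missing_mask` (records skipped for length are omitted).
#' @export
extract_feature_table <- function(records, config = pipeline_config(),
                                  verbose = FALSE) {
  rows <- list()
  for (rec in records) {
    fv <- extract_features(rec, config)
    if (is.null(fv)) next
    vnames <- paste0("v", 1:21)
    miss <- vnames[!vapply(fv[vnames], is.finite, logical(1))]
    if (verbose) {
      message(sprintf("%s: %d beats, bsqi=%.3f, missing=[%s]",
                      rec$patient_id, fv$n_beats,
                      ifelse(is.na(fv$bsqi), NaN, fv$bsqi),
                      paste(miss, collapse = ",")))
    }
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(patient_id = rec$patient_id, label = rec$label,
                       tw_min = config$tw),
            as.data.frame(fv[vnames]),
            data.frame(bsqi = fv$bsqi, n_beats = fv$n_beats,
                       missing_mask = paste(miss, collapse = ";")))
  }
  assert_that(length(rows) > 0L, "no usable records in the cohort")
  do.call(rbind, rows)
}

#' Run the full rearrest-prediction pipeline
#'
#' Extract -> filter -> detect -> featurize -> repeated cross-validated
#' classification, from a cohort (list of records or a manifest path) to
#' a feature table and a `cv_report`.
#'
#' @param cohort A list of [ecg_record()]s or a manifest CSV path.
#' @param config A [pipeline_config()].
#' @param verbose Log per-record lines during feature extraction.
#' @return A list with `features` (data.frame) and `report`
#'   ([run_repeated_cv()] output), plus the `config` echo.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), verbose = FALSE) {
  records <- if (is.character(cohort)) read_cohort(cohort) else cohort
  features <- extract_feature_table(records, config, verbose = verbose)
  report <- run_repeated_cv(features,
                            feature_cols = feature_columns(config$feature_mode),
                            k = config$cv_k, n_reps = config$cv_reps,
                            rf = config$rf, seed = config$seed)
  list(features = features, report = report, config = config)
}

#' Write a feature table to CSV
#'
#' @param features Output of [extract_feature_table()].
#' @param path Destination CSV path.
#' @return Invisibly, `path`.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Write a cross-validation report to JSON
#'
#' Serializes the per-repetition metrics, the median(IQR) aggregates, the
#' median-repetition curves and the configuration echo.
#'
#' @param report A `cv_report` from [run_repeated_cv()].
#' @param path Destination JSON path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  out <- list(per_rep = report$per_rep,
              aggregate = cbind(stat = rownames(report$aggregate),
                                report$aggregate),
              median_rep = report$median_rep,
              curves = report$curves,
              config = list(k = report$config$k,
                            n_reps = report$config$n_reps,
                            feature_cols = report$config$feature_cols,
                            seed = report$config$seed,
                            rf = unclass(report$config$rf)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
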