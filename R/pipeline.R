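#' Analysis pipeline configuration
#'
#' All tunables of the end-to-end analysis, defaulting to the values the
#' method prescribes: respiratory conditioning band 0.05–2 Hz, cardiac
#' carrier band 0.7–20 Hz, envelope band 0.7–5 Hz, RR search band
#' 0.1–1.5 Hz, HR search band 0.7–4 Hz, RMS amplitude fractions 0.50
#' (wearable) / 0.40 (reference), and 30 s windows with 50 % overlap for
#' short-time HR tracking.
#'
#' @param resp_band respiratory conditioning band, Hz.
#' @param carrier_band seismo/gyrocardiographic carrier band, Hz.
#' @param envelope_band final heart-beat envelope band, Hz.
#' @param rr_band RR spectral search band, Hz.
#' @param hr_band HR spectral search band, Hz.
#' @param filter_order Butterworth design order (zero-phase applied).
#' @param welch_segment_s,welch_overlap whole-trial Welch parameters.
#' @param rr_freq_res,hr_freq_res spectral grid spacings, Hz (0.005 Hz =
#'   0.3 breaths/min for whole-trial spectra; 0.1 beats/min for the
#'   windowed HR spectra).
#' @param amp_fraction_ws,amp_fraction_ref inspiratory-peak height
#'   thresholds as fractions of the trace RMS.
#' @param hr_window_s,hr_window_overlap short-time HR window length and
#'   overlap.
#' @param max_plausible_rr automated plausibility ceiling for detected
#'   breaths, breaths/min; `Inf` disables the filter.
#' @param ref_hr_envelope if `TRUE`, envelope-process the reference ECG
#'   like the IMU channels (default uses its band-passed form).
#' @param invert_strain negate the fused strain-channel voltage before
#'   peak detection. The strain-to-voltage calibration has negative slope
#'   (inspiration lowers the voltage), so negation makes end-inspiration
#'   appear as maxima.
#' @param pair_tol_fraction breath-pairing tolerance as a fraction of the
#'   median reference interval.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(resp_band = c(0.05, 2),
                            carrier_band = c(0.7, 20),
                            envelope_band = c(0.7, 5),
                            rr_band = c(0.1, 1.5),
                            hr_band = c(0.7, 4),
                            filter_order = 3,
                            welch_segment_s = 60, welch_overlap = 0.5,
                            rr_freq_res = 0.005, hr_freq_res = 0.1 / 60,
                            amp_fraction_ws = 0.5,
                            amp_fraction_ref = 0.4,
                            hr_window_s = 30, hr_window_overlap = 0.5,
                            max_plausible_rr = 90,
                            ref_hr_envelope = FALSE,
                            invert_strain = TRUE,
                            pair_tol_fraction = 0.5) {
  structure(list(
    resp_band = resp_band, carrier_band = carrier_band,
    envelope_band = envelope_band, rr_band = rr_band, hr_band = hr_band,
    filter_order = filter_order,
    welch_segment_s = welch_segment_s, welch_overlap = welch_overlap,
    rr_freq_res = rr_freq_res, hr_freq_res = hr_freq_res,
    amp_fraction_ws = amp_fraction_ws,
    amp_fraction_ref = amp_fraction_ref,
    hr_window_s = hr_window_s, hr_window_overlap = hr_window_overlap,
    max_plausible_rr = max_plausible_rr,
    ref_hr_envelope = ref_hr_envelope,
    invert_strain = invert_strain,
    pair_tol_fraction = pair_tol_fraction
  ), class = "pipeline_config")
}

#' Full cardio-respiratory analysis of one trial
#'
#' Runs the complete estimation chain on a trial's analysis segment and
#' compares wearable against reference:
#' * RR, frequency domain — fused strain channels, band-pass 0.05–2 Hz,
#'   Welch PSD, highest peak in 0.1–1.5 Hz; likewise for the reference
#'   respiratory waveform.
#' * RR, time domain — inspiratory-peak detection (temporal threshold
#'   `60 / RR`, amplitude threshold 0.50/0.40 RMS), breath-by-breath
#'   rates, breath pairing, MAE and Bland-Altman statistics.
#' * HR, whole trial — heart-beat envelopes of the accelerometer and
#'   gyroscope x-axes vs the band-passed reference ECG, Welch PSD,
#'   highest peak in 0.7–4 Hz.
#' * HR, short-time — 30 s windows (50 % overlap) on the gyroscope
#'   envelope and the reference ECG, one HR and one error per window.
#'
#' @param rec a [trial_recording()].
#' @param config a [pipeline_config()].
#' @return An object of class `"trial_analysis"`; see
#'   [summary.trial_analysis()]. Main components: `rr_freq` (wearable /
#'   reference whole-trial RR and errors), `breaths` (breath series,
#'   pairs, `mae`, `bland_altman`), `hr` (per-source whole-trial HR and
#'   errors), `hr_windowed` (per-window series and errors).
#' @examples
#' trial <- make_trial(sim_config(scenario = "supine", seed = 5))
#' fit <- analyze_trial(trial$recording)
#' fit
#' @export
analyze_trial <- function(rec, config = pipeline_config()) {
  stopifnot(inherits(rec, "trial_recording"))
  ord <- config$filter_order
  resp_spec <- filter_spec(config$resp_band[1], config$resp_band[2], ord)

  # condition the full recording, then cut the breathing segment, so
  # filter edge transients decay inside the apnea holds
  r_ws <- bandpass_zero_phase(fuse_strain_channels(rec$strain),
                              rec$fs_ws, resp_spec)
  if (config$invert_strain) r_ws <- -r_ws
  r_ref <- bandpass_zero_phase(rec$ref_resp, rec$fs_ref_resp, resp_spec)
  r_ws <- r_ws[segment_idx(rec, rec$fs_ws)]
  r_ref <- r_ref[segment_idx(rec, rec$fs_ref_resp)]
  seg <- rec

  ws_spec <- welch_psd(r_ws, seg$fs_ws,
                       segment_s = config$welch_segment_s,
                       overlap = config$welch_overlap,
                       freq_res = config$rr_freq_res)
  ref_spec <- welch_psd(r_ref, seg$fs_ref_resp,
                        segment_s = config$welch_segment_s,
                        overlap = config$welch_overlap,
                        freq_res = config$rr_freq_res)
  rr_ws <- rr_from_spectrum(ws_spec, config$rr_band)
  rr_ref <- rr_from_spectrum(ref_spec, config$rr_band)

  detect <- function(x, fs, avg_rr, frac) {
    pk <- detect_breath_peaks(x, fs, avg_rr, frac)
    if (is.finite(config$max_plausible_rr))
      pk <- filter_implausible_peaks(pk, x, fs, config$max_plausible_rr)
    pk
  }
  pk_ws <- detect(r_ws, seg$fs_ws, rr_ws, config$amp_fraction_ws)
  pk_ref <- detect(r_ref, seg$fs_ref_resp, rr_ref,
                   config$amp_fraction_ref)
  bs_ws <- breath_series(pk_ws)
  bs_ref <- breath_series(pk_ref)
  pairs <- pair_breaths(bs_ref, bs_ws, config$pair_tol_fraction)
  breath_mae <- mae(pairs)
  ba <- bland_altman(pairs)

  hr_est <- function(source) {
    whole_trial_hr(seg, source, hr_band = config$hr_band,
                   segment_s = config$welch_segment_s,
                   overlap = config$welch_overlap,
                   freq_res = config$rr_freq_res,
                   ref_envelope = config$ref_hr_envelope, order = ord)
  }
  hr_ref <- hr_est("ref"); hr_gx <- hr_est("gx"); hr_ax <- hr_est("ax")

  win <- function(source) {
    windowed_hr(seg, source, window_s = config$hr_window_s,
                overlap = config$hr_window_overlap,
                hr_band = config$hr_band,
                freq_res = config$hr_freq_res,
                ref_envelope = config$ref_hr_envelope, order = ord)
  }
  w_gx <- win("gx"); w_ref <- win("ref")
  nw <- min(length(w_gx$hr), length(w_ref$hr))

  structure(list(
    scenario = rec$scenario,
    rr_freq = list(
      ws = rr_ws, ref = rr_ref,
      error = absolute_error(rr_ref, rr_ws),
      error_pct = percentage_error(rr_ref, rr_ws),
      ws_spectrum = ws_spec, ref_spectrum = ref_spec
    ),
    breaths = list(
      ws = bs_ws, ref = bs_ref, pairs = pairs,
      mae = breath_mae$mae, mae_pct = breath_mae$mae_pct,
      bland_altman = ba
    ),
    hr = list(
      ref = hr_ref, gx = hr_gx, ax = hr_ax,
      gx_error = absolute_error(hr_ref, hr_gx),
      gx_error_pct = percentage_error(hr_ref, hr_gx),
      ax_error = absolute_error(hr_ref, hr_ax),
      ax_error_pct = percentage_error(hr_ref, hr_ax)
    ),
    hr_windowed = list(
      gx = w_gx, ref = w_ref,
      errors = absolute_error(w_ref$hr[seq_len(nw)], w_gx$hr[seq_len(nw)]),
      errors_pct = percentage_error(w_ref$hr[seq_len(nw)],
                                    w_gx$hr[seq_len(nw)]),
      mean_error = mean(absolute_error(w_ref$hr[seq_len(nw)],
                                       w_gx$hr[seq_len(nw)])),
      mean_error_pct = mean(percentage_error(w_ref$hr[seq_len(nw)],
                                             w_gx$hr[seq_len(nw)]))
    ),
    config = config
  ), class = "trial_analysis")
}

#' @export
print.trial_analysis <- function(x, ...) {
  cat("Cardio-respiratory trial analysis (", x$scenario, ")\n", sep = "")
  cat(sprintf(
    "  RR (freq):  WS %.2f vs ref %.2f breaths/min (err %.2f, %.2f%%)\n",
    x$rr_freq$ws, x$rr_freq$ref, x$rr_freq$error, x$rr_freq$error_pct))
  cat(sprintf(
    "  RR (time):  %d paired breaths, MAE %.2f breaths/min (%.2f%%)\n",
    length(x$breaths$pairs$ref_rates), x$breaths$mae, x$breaths$mae_pct))
  cat(sprintf(
    "  HR (trial): gx %.2f / ax %.2f vs ref %.2f beats/min (err %.2f / %.2f)\n",
    x$hr$gx, x$hr$ax, x$hr$ref, x$hr$gx_error, x$hr$ax_error))
  cat(sprintf(
    "  HR (30 s):  %d windows, mean gx error %.2f beats/min (%.2f%%)\n",
    length(x$hr_windowed$errors), x$hr_windowed$mean_error,
    x$hr_windowed$mean_error_pct))
  invisible(x)
}

#' Summarise a trial analysis as one row of metrics
#'
#' @param object a [analyze_trial()] result.
#' @param ... unused.
#' @return A one-row data frame with the trial's error metrics (RR
#'   frequency- and time-domain, HR per source, windowed HR) suitable for
#'   [aggregate_report()].
#' @export
summary.trial_analysis <- function(object, ...) {
  data.frame(
    scenario = object$scenario,
    rr_ws = object$rr_freq$ws, rr_ref = object$rr_freq$ref,
    rr_error = object$rr_freq$error,
    rr_error_pct = object$rr_freq$error_pct,
    rr_mae = object$breaths$mae, rr_mae_pct = object$breaths$mae_pct,
    ba_mod = object$breaths$bland_altman$mod,
    hr_gx = object$hr$gx, hr_ax = object$hr$ax, hr_ref = object$hr$ref,
    hr_gx_error = object$hr$gx_error, hr_ax_error = object$hr$ax_error,
    hr_gx_error_pct = object$hr$gx_error_pct,
    hr_ax_error_pct = object$hr$ax_error_pct,
    hr_win_error = object$hr_windowed$mean_error,
    hr_win_error_pct = object$hr_windowed$mean_error_pct
  )
}

#' Generate a synthetic cohort of trials
#'
#' One trial per subject and scenario. Subject-level mean rates are drawn
#' once per subject (RR uniform on 12–18 breaths/min, HR uniform on
#' 60–85 beats/min, the self-paced resting ranges the generator targets);
#' every trial gets its own deterministic seed derived from `seed`.
#'
#' @param n_subjects number of subjects (default 8).
#' @param scenarios character vector of postures.
#' @param seed master seed for the cohort.
#' @param ... overrides passed on to every [sim_config()] call.
#' @return A list of `make_trial()` results with elements named
#'   `S<subject>_<scenario>`, each also carrying `subject` and `scenario`.
#' @export
synth_cohort <- function(n_subjects = 8,
                         scenarios = c("sitting", "standing", "supine"),
                         seed = 1L, ...) {
  set.seed(seed)
  subj_rr <- runif(n_subjects, 12, 18)
  subj_hr <- runif(n_subjects, 60, 85)
  out <- list()
  k <- 0L
  for (i in seq_len(n_subjects)) {
    for (sc in scenarios) {
      k <- k + 1L
      cfg <- sim_config(scenario = sc, mean_rr = subj_rr[i],
                        mean_hr = subj_hr[i],
                        seed = (seed %% 100003L) * 101L + k, ...)
      trial <- make_trial(cfg)
      trial$subject <- i
      trial$scenario <- sc
      out[[paste0("S", i, "_", sc)]] <- trial
    }
  }
  out
}

#' Run the full pipeline over a set of trials
#'
#' Analyses every trial, collects per-trial error metrics, aggregates
#' them per scenario ([aggregate_report()] layout) and pools the
#' breath-by-breath pairs per scenario for Bland-Altman analysis. A trial
#' whose analysis fails is reported and skipped; the run only errors if
#' every trial fails.
#'
#' @param trials either a list as returned by [synth_cohort()] (elements
#'   with `recording`, `subject`, `scenario`), a list of bare
#'   [trial_recording()] objects, or a directory containing one trial
#'   sub-directory per recording ([load_trial()] format, subject taken
#'   from the directory name).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory: writes one CSV per
#'   aggregated error table, a `bland_altman_<scenario>.csv` scatter per
#'   scenario and a `summary.json`.
#' @return An object of class `"agreement_report"`: list with `per_trial`
#'   (data frame), `tables` (named list of [aggregate_report()] tables),
#'   `bland_altman` (per-scenario), and `failures`.
#' @export
run_pipeline <- function(trials, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(trials)) {
    dirs <- list.dirs(trials, recursive = FALSE)
    if (!length(dirs)) stop("no trial directories found in ", trials)
    trials <- lapply(dirs, function(d) {
      rec <- load_trial(d)
      list(recording = rec, subject = basename(d),
           scenario = rec$scenario)
    })
  }
  trials <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    if (inherits(tr, "trial_recording"))
      tr <- list(recording = tr, subject = i, scenario = tr$scenario)
    tr
  })

  rows <- list(); pair_pool <- list(); failures <- list()
  for (tr in trials) {
    res <- tryCatch(analyze_trial(tr$recording, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(subject = as.character(tr$subject),
                   scenario = tr$scenario,
                   message = conditionMessage(res))
      next
    }
    row <- summary(res)
    row$subject <- as.character(tr$subject)
    rows[[length(rows) + 1L]] <- row
    sc <- tr$scenario
    pair_pool[[sc]] <- list(
      ref_rates = c(pair_pool[[sc]]$ref_rates,
                    res$breaths$pairs$ref_rates),
      ws_rates = c(pair_pool[[sc]]$ws_rates,
                   res$breaths$pairs$ws_rates))
  }
  if (!length(rows))
    stop("all trials failed; first error: ",
         if (length(failures)) failures[[1]]$message else "none")

  per_trial <- do.call(rbind, rows)
  metrics <- c(rr_error = "rr_error", rr_error_pct = "rr_error_pct",
               rr_mae = "rr_mae", rr_mae_pct = "rr_mae_pct",
               hr_gx_error = "hr_gx_error", hr_ax_error = "hr_ax_error",
               hr_gx_error_pct = "hr_gx_error_pct",
               hr_ax_error_pct = "hr_ax_error_pct",
               hr_win_error = "hr_win_error",
               hr_win_error_pct = "hr_win_error_pct")
  scenarios <- unique(per_trial$scenario)
  tables <- lapply(metrics, function(m) {
    aggregate_report(data.frame(subject = per_trial$subject,
                                scenario = per_trial$scenario,
                                value = per_trial[[m]]),
                     scenarios = scenarios)
  })
  ba <- lapply(pair_pool, bland_altman)

  report <- structure(list(per_trial = per_trial, tables = tables,
                           bland_altman = ba,
                           failures = if (length(failures))
                             do.call(rbind, failures) else NULL),
                      class = "agreement_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report:", nrow(x$per_trial), "trials analysed")
  if (!is.null(x$failures)) cat(",", nrow(x$failures), "failed")
  cat("\n\nWhole-trial RR absolute error [breaths/min]:\n")
  print(x$tables$rr_error)
  cat("\nBreath-by-breath RR MAE [breaths/min]:\n")
  print(x$tables$rr_mae)
  cat("\nWhole-trial HR absolute error, gyroscope x [beats/min]:\n")
  print(x$tables$hr_gx_error)
  for (sc in names(x$bland_altman)) {
    cat("\nBland-Altman (", sc, "): ", sep = "")
    b <- x$bland_altman[[sc]]
    cat(sprintf("MOD %.4f, LOA [%.4f, %.4f]\n",
                b$mod, b$loa_lower, b$loa_upper))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (nm in names(report$tables)) {
    tab <- as.data.frame(report$tables[[nm]])
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], round, digits = 2)
    write.csv(tab, file.path(out_dir, paste0(nm, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  for (sc in names(report$bland_altman)) {
    b <- report$bland_altman[[sc]]
    write.csv(data.frame(mean = b$means, diff = b$differences),
              file.path(out_dir, paste0("bland_altman_", sc, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  summary <- list(
    n_trials = nrow(report$per_trial),
    averages = lapply(report$tables, function(tab) {
      avg <- as.data.frame(tab)
      as.list(avg[avg$Subject == "Average", -1, drop = FALSE])
    }),
    bland_altman = lapply(report$bland_altman, function(b)
      list(mod = b$mod, loa_upper = b$loa_upper,
           loa_lower = b$loa_lower, n = b$n))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(out_dir)
}
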