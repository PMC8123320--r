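#' Construct a trial recording
#'
#' Container for one subject-by-scenario session: four strain-channel
#' voltages and nine IMU channels on the wearable-system clock, plus the
#' reference respiratory waveform and single-lead ECG on their own
#' clocks. All streams are timestamped from a shared t = 0 (synchronized
#' starts are assumed; real data must be pre-aligned).
#'
#' @param scenario posture label.
#' @param strain `n x 4` matrix of strain-channel voltages at `fs_ws`.
#' @param imu `n x 9` matrix (`ax, ay, az, gx, gy, gz, mx, my, mz`) at
#'   `fs_ws`.
#' @param ref_resp reference respiratory trace at `fs_ref_resp`.
#' @param ref_ecg reference ECG trace at `fs_ecg`.
#' @param fs_ws,fs_ref_resp,fs_ecg sampling rates, Hz.
#' @param analysis_segment `(start_s, end_s)` of the breathing segment the
#'   rate analyses run on (apneas excluded).
#' @param seed generator seed, if the trial is synthetic (else `NA`).
#' @return An object of class `"trial_recording"`.
#' @export
trial_recording <- function(scenario, strain, imu, ref_resp, ref_ecg,
                            fs_ws, fs_ref_resp, fs_ecg,
                            analysis_segment = NULL, seed = NA_integer_) {
  strain <- as.matrix(strain); imu <- as.matrix(imu)
  if (ncol(strain) != 4) stop("strain must have 4 channels")
  if (ncol(imu) != 9) stop("imu must have 9 channels")
  if (nrow(strain) != nrow(imu))
    stop("strain and imu streams share the WS clock and must have ",
         "equal length")
  duration <- nrow(strain) / fs_ws
  check_stream <- function(x, fs, name) {
    if (any(!is.finite(x)))
      stop("non-finite samples in stream '", name, "'")
    if (abs(length_or_rows(x) - round(duration * fs)) > 1)
      stop("stream '", name, "' length inconsistent with its declared ",
           "sampling rate (", fs, " Hz) and the trial duration")
    invisible(x)
  }
  check_stream(strain, fs_ws, "strain")
  check_stream(imu, fs_ws, "imu")
  check_stream(ref_resp, fs_ref_resp, "resp")
  check_stream(ref_ecg, fs_ecg, "ecg")
  if (is.null(analysis_segment)) analysis_segment <- c(0, duration)
  structure(list(
    scenario = scenario, strain = strain, imu = imu,
    ref_resp = as.numeric(ref_resp), ref_ecg = as.numeric(ref_ecg),
    fs_ws = fs_ws, fs_ref_resp = fs_ref_resp, fs_ecg = fs_ecg,
    duration_s = duration, analysis_segment = analysis_segment,
    seed = seed
  ), class = "trial_recording")
}

length_or_rows <- function(x) if (is.matrix(x)) nrow(x) else length(x)

#' @export
print.trial_recording <- function(x, ...) {
  cat("Trial recording (", x$scenario, ")\n", sep = "")
  cat(sprintf("  duration %.1f s; analysis segment [%g, %g] s\n",
              x$duration_s, x$analysis_segment[1], x$analysis_segment[2]))
  cat(sprintf("  strain: 4 ch @ %g Hz (%d samples)\n",
              x$fs_ws, nrow(x$strain)))
  cat(sprintf("  IMU: 9 ch @ %g Hz; resp @ %g Hz (%d); ECG @ %g Hz (%d)\n",
              x$fs_ws, x$fs_ref_resp, length(x$ref_resp),
              x$fs_ecg, length(x$ref_ecg)))
  invisible(x)
}

#' Write a trial to a directory of CSV files
#'
#' One CSV per stream group (`strain.csv`: `t, ch1..ch4`; `imu.csv`:
#' `t, ax..mz`; `resp.csv`: `t, resp`; `ecg.csv`: `t, ecg`) plus a
#' key-value `metadata.txt` recording sampling rates, scenario, analysis
#' segment and seed. Times in seconds with 6 decimal places; values with
#' 6 decimals, so a round trip is lossless to 1e-6.
#'
#' @param rec a [trial_recording()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @seealso [load_trial()]
#' @export
write_trial <- function(rec, dir) {
  stopifnot(inherits(rec, "trial_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(v) sprintf("%.6f", v)
  write_stream <- function(df, file) {
    df[] <- lapply(df, fmt)
    write.csv(df, file.path(dir, file), row.names = FALSE, quote = FALSE)
  }
  n <- nrow(rec$strain)
  t_ws <- (seq_len(n) - 1) / rec$fs_ws
  write_stream(data.frame(t = t_ws, rec$strain), "strain.csv")
  write_stream(data.frame(t = t_ws, rec$imu), "imu.csv")
  t_r <- (seq_along(rec$ref_resp) - 1) / rec$fs_ref_resp
  write_stream(data.frame(t = t_r, resp = rec$ref_resp), "resp.csv")
  t_e <- (seq_along(rec$ref_ecg) - 1) / rec$fs_ecg
  write_stream(data.frame(t = t_e, ecg = rec$ref_ecg), "ecg.csv")
  meta <- c(
    scenario = rec$scenario, fs_ws = rec$fs_ws,
    fs_ref_resp = rec$fs_ref_resp, fs_ecg = rec$fs_ecg,
    duration_s = rec$duration_s,
    analysis_start_s = rec$analysis_segment[1],
    analysis_end_s = rec$analysis_segment[2],
    seed = rec$seed
  )
  writeLines(paste(names(meta), meta, sep = ": "),
             file.path(dir, "metadata.txt"))
  invisible(dir)
}

#' Load a trial from a directory of CSV files
#'
#' Reads the stream CSVs written by [write_trial()], validates them
#' against the declared metadata (missing streams, length/rate mismatch
#' beyond one sample, and non-finite samples are errors naming the
#' offending stream) and returns a [trial_recording()].
#'
#' @param dir directory containing `strain.csv`, `imu.csv`, `resp.csv`,
#'   `ecg.csv` and `metadata.txt`.
#' @return A [trial_recording()].
#' @export
load_trial <- function(dir) {
  meta_path <- file.path(dir, "metadata.txt")
  if (!file.exists(meta_path)) stop("missing metadata.txt in ", dir)
  kv <- read_metadata(meta_path)
  need <- c("strain", "imu", "resp", "ecg")
  for (s in need)
    if (!file.exists(file.path(dir, paste0(s, ".csv"))))
      stop("missing stream '", s, "' in ", dir)
  read_stream <- function(name) {
    df <- read.csv(file.path(dir, paste0(name, ".csv")))
    m <- as.matrix(df[, -1, drop = FALSE])
    if (any(!is.finite(m)))
      stop("non-finite samples in stream '", name, "'")
    m
  }
  strain <- read_stream("strain")
  imu <- read_stream("imu")
  resp <- read_stream("resp")[, 1]
  ecg <- read_stream("ecg")[, 1]
  duration <- as.numeric(kv[["duration_s"]])
  check_rate <- function(len, fs, name) {
    if (abs(len - round(duration * fs)) > 1)
      stop("stream '", name, "': ", len, " samples inconsistent with ",
           "declared rate ", fs, " Hz over ", duration, " s")
  }
  check_rate(nrow(strain), as.numeric(kv[["fs_ws"]]), "strain")
  check_rate(nrow(imu), as.numeric(kv[["fs_ws"]]), "imu")
  check_rate(length(resp), as.numeric(kv[["fs_ref_resp"]]), "resp")
  check_rate(length(ecg), as.numeric(kv[["fs_ecg"]]), "ecg")
  trial_recording(
    scenario = kv[["scenario"]], strain = strain, imu = imu,
    ref_resp = resp, ref_ecg = ecg,
    fs_ws = as.numeric(kv[["fs_ws"]]),
    fs_ref_resp = as.numeric(kv[["fs_ref_resp"]]),
    fs_ecg = as.numeric(kv[["fs_ecg"]]),
    analysis_segment = c(as.numeric(kv[["analysis_start_s"]]),
                         as.numeric(kv[["analysis_end_s"]])),
    seed = suppressWarnings(as.integer(kv[["seed"]]))
  )
}

read_metadata <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  kv <- vapply(parts, function(p) trimws(p[2]), character(1))
  names(kv) <- vapply(parts, function(p) trimws(p[1]), character(1))
  kv
}

#' Extract a time segment from a trial
#'
#' Cuts every stream on its own clock; segment boundaries are rounded to
#' the nearest sample per stream. Extracting the full range is the
#' identity.
#'
#' @param rec a [trial_recording()].
#' @param start_s,end_s segment bounds in seconds,
#'   `0 <= start_s < end_s <= duration`.
#' @return A [trial_recording()] covering the segment (its
#'   `analysis_segment` re-expressed relative to the new origin).
#' @export
extract_segment <- function(rec, start_s, end_s) {
  stopifnot(inherits(rec, "trial_recording"))
  if (!(start_s >= 0 && start_s < end_s && end_s <= rec$duration_s + 1e-9))
    stop("require 0 <= start_s < end_s <= duration")
  cut <- function(x, fs) {
    i0 <- round(start_s * fs) + 1
    i1 <- round(end_s * fs)
    if (i1 < i0) stop("empty segment for stream at ", fs, " Hz")
    if (is.matrix(x)) x[i0:i1, , drop = FALSE] else x[i0:i1]
  }
  new_seg <- c(max(rec$analysis_segment[1], start_s) - start_s,
               min(rec$analysis_segment[2], end_s) - start_s)
  if (new_seg[2] <= new_seg[1]) new_seg <- c(0, end_s - start_s)
  trial_recording(
    scenario = rec$scenario,
    strain = cut(rec$strain, rec$fs_ws),
    imu = cut(rec$imu, rec$fs_ws),
    ref_resp = cut(rec$ref_resp, rec$fs_ref_resp),
    ref_ecg = cut(rec$ref_ecg, rec$fs_ecg),
    fs_ws = rec$fs_ws, fs_ref_resp = rec$fs_ref_resp,
    fs_ecg = rec$fs_ecg,
    analysis_segment = new_seg, seed = rec$seed
  )
}
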