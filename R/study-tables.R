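#' Per-subject agreement errors reported by the validation study
#'
#' The per-subject, per-scenario error values published in the validation
#' study of the wearable system (eight healthy volunteers, three
#' postures), as printed. They serve as fixed inputs for reproducing the
#' study's scenario averages with [aggregate_report()] and for checking
#' the Bland-Altman identities; they are data, not outputs of this
#' package.
#'
#' Available tables (all `data.frame(subject, scenario, value)` in long
#' form, scenarios `sitting`, `standing`, `supine`):
#' * `rr_abs` — whole-trial RR absolute error, breaths/min
#' * `rr_pct` — whole-trial RR percentage error, %
#' * `rr_mae` — breath-by-breath RR mean absolute error, breaths/min
#' * `rr_mae_pct` — breath-by-breath RR percentage MAE, %
#' * `hr_gx`, `hr_ax` — whole-trial HR absolute error (gyroscope /
#'   accelerometer x-axis), beats/min
#' * `hr_gx_pct`, `hr_ax_pct` — percentage forms, %
#' * `hr_win`, `hr_win_pct` — 30-s windowed HR error (gyroscope x-axis),
#'   beats/min and %
#'
#' @return Named list of long-form data frames.
#' @seealso [study_bland_altman()]
#' @export
study_error_tables <- function() {
  long <- function(sitting, standing, supine) {
    data.frame(
      subject = rep(1:8, 3),
      scenario = rep(c("sitting", "standing", "supine"), each = 8),
      value = c(sitting, standing, supine)
    )
  }
  list(
    rr_abs = long(
      c(0.99, 0.06, 0.07, 0.02, 0.04, 0.01, 0.11, 0.04),
      c(0.01, 2.39, 0.06, 0.01, 0.00, 0.01, 0.27, 0.01),
      c(0.01, 0.36, 0.01, 0.03, 0.13, 0.01, 0.34, 22.57)),
    rr_pct = long(
      c(6.78, 0.40, 0.95, 0.09, 0.33, 0.06, 0.72, 0.32),
      c(0.05, 25.43, 0.72, 0.10, 0.01, 0.08, 1.47, 0.07),
      c(0.87, 2.16, 0.08, 0.13, 1.19, 0.04, 2.58, 66.94)),
    rr_mae = long(
      c(0.24, 0.30, 0.22, 0.24, 0.11, 0.18, 0.36, 0.05),
      c(0.61, 0.28, 0.39, 0.33, 0.11, 0.25, 0.23, 0.23),
      c(1.16, 1.08, 1.11, 3.14, 1.92, 0.87, 1.78, 0.07)),
    rr_mae_pct = long(
      c(1.52, 1.44, 2.56, 1.36, 0.91, 1.15, 2.25, 0.37),
      c(3.17, 2.25, 3.59, 1.89, 0.81, 1.64, 1.29, 1.93),
      c(7.72, 7.41, 9.08, 15.00, 18.09, 5.65, 12.57, 0.57)),
    hr_gx = long(
      c(0.56, 3.83, 5.19, 0.28, 0.13, 0.30, 0.18, 0.25),
      c(2.92, 0.05, 5.97, 13.07, 1.98, 0.23, 6.20, 0.08),
      c(0.89, 0.18, 0.03, 0.09, 0.06, 0.28, 0.02, 0.80)),
    hr_ax = long(
      c(0.41, 3.83, 8.45, 6.29, 0.13, 3.04, 0.16, 0.25),
      c(32.80, 0.05, 24.55, 0.73, 0.02, 9.93, 36.21, 6.24),
      c(0.06, 0.18, 0.03, 2.23, 0.06, 0.28, 0.02, 0.12)),
    hr_gx_pct = long(
      c(0.83, 5.54, 7.96, 0.41, 0.21, 0.35, 0.31, 0.30),
      c(6.44, 0.06, 7.37, 17.98, 2.69, 0.23, 11.21, 0.09),
      c(1.53, 0.28, 0.06, 0.14, 0.10, 0.37, 0.04, 1.14)),
    hr_ax_pct = long(
      c(0.61, 5.54, 12.96, 9.16, 0.21, 3.53, 0.28, 0.30),
      c(72.34, 0.06, 30.31, 1.00, 0.03, 9.85, 65.49, 7.01),
      c(0.11, 0.28, 0.06, 3.59, 0.10, 0.37, 0.04, 0.17)),
    hr_win = long(
      c(5.45, 0.00, 13.45, 8.60, 0.20, 0.20, 0.80, 0.20),
      c(27.27, 27.45, 16.18, 4.60, 0.00, 35.60, 15.20, 0.20),
      c(0.18, 0.67, 1.00, 5.20, 0.00, 28.73, 0.00, 0.40)),
    hr_win_pct = long(
      c(8.02, 0.00, 20.96, 13.03, 0.31, 0.23, 1.30, 0.29),
      c(53.99, 16.99, 20.91, 6.33, 0.00, 30.01, 22.56, 0.24),
      c(0.29, 1.08, 1.98, 8.01, 0.00, 13.42, 0.00, 0.58))
  )
}

#' Printed scenario averages of the validation study
#'
#' The `Average`-row values as printed in the study's error tables, keyed
#' by the same table names as [study_error_tables()]. Useful for
#' verifying that [aggregate_report()] reproduces the printed
#' aggregation from the printed per-subject entries.
#'
#' @return Named list; each element is a named numeric vector
#'   (`sitting`, `standing`, `supine`).
#' @export
study_printed_averages <- function() {
  avg <- function(si, st, su) c(sitting = si, standing = st, supine = su)
  list(
    rr_abs = avg(0.17, 0.35, 2.95),
    rr_pct = avg(1.21, 3.49, 9.25),
    rr_mae = avg(0.21, 0.30, 1.39),
    rr_mae_pct = avg(1.45, 2.07, 9.51),
    hr_gx = avg(1.34, 3.81, 0.29),
    hr_ax = avg(2.82, 13.82, 0.37),
    hr_gx_pct = avg(1.99, 5.75, 0.46),
    hr_ax_pct = avg(4.07, 23.26, 0.59),
    hr_win = avg(3.61, 15.81, 4.52),
    hr_win_pct = avg(5.52, 18.88, 3.17)
  )
}

#' Bland-Altman summary reported by the validation study
#'
#' Mean of differences (MOD) and limits of agreement (LOA) of the pooled
#' breath-by-breath RR comparison, per scenario, as printed.
#'
#' @return Data frame with columns `scenario`, `mod`, `loa_upper`,
#'   `loa_lower` (breaths/min).
#' @export
study_bland_altman <- function() {
  data.frame(
    scenario = c("sitting", "standing", "supine"),
    mod = c(-0.0039, 0.0186, -0.2948),
    loa_upper = c(0.9391, 1.6753, 4.9264),
    loa_lower = c(-0.9470, -1.6392, -5.5160)
  )
}
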