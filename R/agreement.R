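#' Absolute error between reference and wearable estimates
#'
#' `|ref - ws|`, in the units of the inputs (breaths/min or beats/min).
#' Vectorised.
#'
#' @param ref_value,ws_value finite numeric values.
#' @return Non-negative error(s).
#' @export
absolute_error <- function(ref_value, ws_value) {
  if (any(!is.finite(ref_value)) || any(!is.finite(ws_value)))
    stop("inputs must be finite")
  abs(ref_value - ws_value)
}

#' Percentage error between reference and wearable estimates
#'
#' `100 * |ref - ws| / ref`; the reference value must be positive. Scale
#' invariant: doubling both inputs leaves the percentage unchanged.
#'
#' @param ref_value,ws_value finite numeric values, `ref_value > 0`.
#' @return Percentage error(s).
#' @export
percentage_error <- function(ref_value, ws_value) {
  if (any(!is.finite(ref_value)) || any(!is.finite(ws_value)))
    stop("inputs must be finite")
  if (any(ref_value <= 0))
    stop("percentage error undefined for non-positive reference values")
  100 * abs(ref_value - ws_value) / ref_value
}

#' Pair wearable and reference breath-by-breath rates
#'
#' Matches wearable inspiratory peaks to reference peaks by greedy
#' nearest-neighbour assignment (closest pairs first) within a tolerance
#' of half the median reference inter-breath interval; each peak is used
#' at most once, and unmatched peaks on either side are dropped but
#' counted. A rate pair is formed for every pair of *consecutive* matched
#' reference peaks, so a spurious extra wearable peak mid-interval does
#' not distort the paired rates.
#'
#' @param ref,ws [breath_series()] objects (reference and wearable).
#' @param tol_fraction matching tolerance as a fraction of the median
#'   reference interval (default 0.5).
#' @return An object of class `"paired_rates"`: list with `ref_rates`,
#'   `ws_rates` (breaths/min, element-wise paired), and a pairing record
#'   (`n_ref_peaks`, `n_ws_peaks`, `n_matched_peaks`, `n_unmatched_ref`,
#'   `n_unmatched_ws`, `tolerance_s`).
#' @export
pair_breaths <- function(ref, ws, tol_fraction = 0.5) {
  stopifnot(inherits(ref, "breath_series"), inherits(ws, "breath_series"))
  rp <- ref$peak_times; wp <- ws$peak_times
  tol <- tol_fraction * median(ref$intervals)
  d <- abs(outer(rp, wp, "-"))
  d[d > tol] <- NA
  match_ws <- rep(NA_integer_, length(rp))
  used_ws <- logical(length(wp))
  ord <- order(d, na.last = NA)  # candidate pairs, closest first
  for (k in ord) {
    i <- (k - 1) %% length(rp) + 1
    j <- (k - 1) %/% length(rp) + 1
    if (is.na(match_ws[i]) && !used_ws[j] && !is.na(d[i, j])) {
      match_ws[i] <- j
      used_ws[j] <- TRUE
    }
  }
  matched <- which(!is.na(match_ws))
  ref_rates <- ws_rates <- numeric(0)
  for (m in seq_along(matched)[-1]) {
    i1 <- matched[m - 1]; i2 <- matched[m]
    if (i2 != i1 + 1) next  # a reference breath went undetected: drop it
    dt_ref <- rp[i2] - rp[i1]
    dt_ws <- wp[match_ws[i2]] - wp[match_ws[i1]]
    if (dt_ws <= 0) next
    ref_rates <- c(ref_rates, 60 / dt_ref)
    ws_rates <- c(ws_rates, 60 / dt_ws)
  }
  if (!length(ref_rates))
    stop("no matched breath pairs within the pairing tolerance")
  structure(list(
    ref_rates = ref_rates, ws_rates = ws_rates,
    n_ref_peaks = length(rp), n_ws_peaks = length(wp),
    n_matched_peaks = length(matched),
    n_unmatched_ref = sum(is.na(match_ws)),
    n_unmatched_ws = sum(!used_ws),
    tolerance_s = tol
  ), class = "paired_rates")
}

#' @export
print.paired_rates <- function(x, ...) {
  cat(sprintf(
    "Paired rates: %d pairs (%d/%d ref peaks matched, %d WS unmatched)\n",
    length(x$ref_rates), x$n_matched_peaks, x$n_ref_peaks,
    x$n_unmatched_ws))
  invisible(x)
}

#' Mean absolute error of paired breath-by-breath rates
#'
#' The mean over breaths of `|ref - ws|`, plus the percentage form in
#' which each term is divided by its own reference rate before averaging
#' (the mean of per-breath ratios, not the ratio of means).
#'
#' @param pairs a [pair_breaths()] result, or a list with `ref_rates` and
#'   `ws_rates`.
#' @return List with `mae` (same units as the rates) and `mae_pct` (%).
#' @examples
#' mae(list(ref_rates = c(10, 20), ws_rates = c(11, 18)))  # 1.5, 10 %
#' @export
mae <- function(pairs) {
  r <- pairs$ref_rates; w <- pairs$ws_rates
  if (!length(r) || length(r) != length(w))
    stop("need equal-length, non-empty paired rates")
  list(mae = mean(abs(r - w)),
       mae_pct = mean(100 * abs(r - w) / r))
}

#' Bland-Altman agreement analysis
#'
#' For each pair the mean `(ref + ws) / 2` and the difference
#' `ref - ws`; the mean of differences (MOD), the sample standard
#' deviation of the differences (n - 1 denominator), and the limits of
#' agreement `MOD +/- 1.96 * sd`. By construction the LOAs are symmetric
#' about the MOD.
#'
#' @param pairs a [pair_breaths()] result or list with `ref_rates`,
#'   `ws_rates` (>= 2 pairs), or a numeric vector of reference values if
#'   `ws` is supplied.
#' @param ws optional numeric vector of wearable values (with `pairs` the
#'   reference vector).
#' @return An object of class `"bland_altman"`: list with `means`,
#'   `differences`, `mod`, `sd_differences`, `loa_upper`, `loa_lower`,
#'   `n`.
#' @export
bland_altman <- function(pairs, ws = NULL) {
  if (!is.null(ws)) pairs <- list(ref_rates = pairs, ws_rates = ws)
  r <- pairs$ref_rates; w <- pairs$ws_rates
  if (length(r) != length(w)) stop("paired series must have equal length")
  if (length(r) < 2) stop("Bland-Altman analysis needs at least 2 pairs")
  diffs <- r - w
  mod <- mean(diffs)
  s <- sd(diffs)
  structure(list(
    means = (r + w) / 2, differences = diffs,
    mod = mod, sd_differences = s,
    loa_upper = mod + 1.96 * s, loa_lower = mod - 1.96 * s,
    n = length(r)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): MOD %.4f, LOA [%.4f, %.4f], sd %.4f\n",
    x$n, x$mod, x$loa_lower, x$loa_upper, x$sd_differences))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "Mean of methods",
                              ylab = "Difference (ref - WS)", ...) {
  plot(x$means, x$differences, xlab = xlab, ylab = ylab, ...)
  abline(h = x$mod, col = "blue")
  abline(h = c(x$loa_lower, x$loa_upper), col = "red", lty = 2)
  invisible(x)
}

#' Aggregate per-subject errors into a subjects-by-scenarios table
#'
#' Arranges per-subject error values into the standard report layout —
#' one row per subject, one column per scenario, plus an `Average` row
#' holding the arithmetic mean of the per-subject entries in each
#' scenario column.
#'
#' @param errors data frame with columns `subject`, `scenario`, `value`
#'   (one value per subject-scenario combination).
#' @param scenarios column order (default: order of first appearance).
#' @return An object of class `"agreement_table"`: a data frame with a
#'   `Subject` column, one numeric column per scenario, and a final
#'   `Average` row.
#' @examples
#' df <- data.frame(subject = rep(1:2, each = 2),
#'                  scenario = rep(c("sitting", "supine"), 2),
#'                  value = c(0.1, 0.3, 0.2, 0.5))
#' aggregate_report(df)
#' @export
aggregate_report <- function(errors, scenarios = NULL) {
  stopifnot(all(c("subject", "scenario", "value") %in% names(errors)))
  if (is.null(scenarios)) scenarios <- unique(as.character(errors$scenario))
  subjects <- unique(errors$subject)
  tab <- sapply(scenarios, function(sc) {
    vapply(subjects, function(su) {
      v <- errors$value[errors$subject == su & errors$scenario == sc]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  })
  tab <- matrix(tab, nrow = length(subjects),
                dimnames = list(NULL, scenarios))
  avg <- colMeans(tab, na.rm = TRUE)
  out <- data.frame(Subject = c(as.character(subjects), "Average"),
                    rbind(tab, avg), check.names = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("agreement_table", "data.frame"))
}

#' @export
print.agreement_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE, ...)
  invisible(x)
}
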