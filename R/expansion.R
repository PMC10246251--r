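#' Serial-scan comparison and haematoma-expansion classification
#'
#' Compares baseline and follow-up haemorrhage volumes. The absolute
#' difference is `followup_cc - baseline_cc` (growth positive), the percent
#' difference is that difference relative to baseline, and haematoma
#' expansion (HE) is called when *both* criteria are met — an absolute
#' increase of at least `abs_threshold_cc` (default 6 cc) *and* a relative
#' increase of at least `pct_threshold` percent (default 33) — the
#' conjunction rule, chosen over either/or to increase specificity. Both
#' comparisons are non-strict (`>=`). Negative differences ("negative
#' expansion", typically partial-volume effects on follow-up) are valid and
#' reported as-is.
#'
#' @param baseline_cc baseline haemorrhage volume in cc; must be at least
#'   `min_baseline_cc` (percent change is undefined below the detection
#'   floor, matching a 1 ml inclusion bound).
#' @param followup_cc follow-up volume in cc, `>= 0`.
#' @param abs_threshold_cc absolute growth criterion in cc (default 6).
#' @param pct_threshold relative growth criterion in percent (default 33).
#' @param min_baseline_cc smallest admissible baseline volume (default 1).
#' @return An object of class `serial_comparison` with fields
#'   `baseline_cc`, `followup_cc`, `abs_diff_cc`, `pct_diff`, `he_positive`
#'   and the criteria used.
#' @examples
#' compare_serial(10, 16.5)   # +6.5 cc, +65% -> HE positive
#' compare_serial(100, 107)   # +7 cc but only +7% -> negative
#' compare_serial(3, 5)       # +66.7% but only +2 cc -> negative
#' compare_serial(20, 18)     # negative expansion, reported as-is
#' @export
compare_serial <- function(baseline_cc, followup_cc,
                           abs_threshold_cc = 6.0, pct_threshold = 33.0,
                           min_baseline_cc = 1.0) {
  if (!is.finite(baseline_cc) || !is.finite(followup_cc))
    stop("volumes must be finite")
  if (followup_cc < 0) stop("followup_cc must be >= 0")
  if (baseline_cc < min_baseline_cc)
    stop(sprintf("baseline volume %.3g cc is below the %.3g cc floor; percent change undefined",
                 baseline_cc, min_baseline_cc))
  abs_diff <- followup_cc - baseline_cc
  pct_diff <- 100 * abs_diff / baseline_cc
  structure(list(
    baseline_cc = baseline_cc, followup_cc = followup_cc,
    abs_diff_cc = abs_diff, pct_diff = pct_diff,
    he_positive = (abs_diff >= abs_threshold_cc) && (pct_diff >= pct_threshold),
    criteria = c(abs_threshold_cc = abs_threshold_cc,
                 pct_threshold = pct_threshold)
  ), class = "serial_comparison")
}

#' @export
print.serial_comparison <- function(x, ...) {
  cat(sprintf("Serial comparison: %.2f cc -> %.2f cc\n", x$baseline_cc, x$followup_cc))
  cat(sprintf("  absolute change: %+.2f cc   relative change: %+.2f%%\n",
              x$abs_diff_cc, x$pct_diff))
  cat(sprintf("  hematoma expansion (>= %g cc AND >= %g%%): %s\n",
              x$criteria["abs_threshold_cc"], x$criteria["pct_threshold"],
              if (x$he_positive) "POSITIVE" else "negative"))
  invisible(x)
}

#' Classify a cohort of serial volume pairs
#'
#' Applies [compare_serial()] to every row of a cohort table and reports
#' per-row HE calls plus summary counts.
#'
#' @param rows a data frame with columns `id`, `baseline_cc`, `followup_cc`
#'   (extra columns are carried through).
#' @inheritParams compare_serial
#' @return An object of class `he_cohort`: the input data frame augmented
#'   with `abs_diff_cc`, `pct_diff` and `he_positive`, with attributes
#'   `n_positive` / `n_negative`.
#' @export
classify_cohort <- function(rows, abs_threshold_cc = 6.0, pct_threshold = 33.0,
                            min_baseline_cc = 1.0) {
  rows <- as.data.frame(rows)
  need <- c("id", "baseline_cc", "followup_cc")
  if (!all(need %in% names(rows)))
    stop("cohort table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(rows$id))
    stop("duplicate ids: ", paste(unique(rows$id[duplicated(rows$id)]), collapse = ", "))
  n <- nrow(rows)
  abs_diff <- pct_diff <- numeric(n)
  pos <- logical(n)
  for (i in seq_len(n)) {
    cmp <- tryCatch(
      compare_serial(rows$baseline_cc[i], rows$followup_cc[i],
                     abs_threshold_cc, pct_threshold, min_baseline_cc),
      error = function(e) stop(sprintf("row %d (id %s): %s", i, rows$id[i],
                                       conditionMessage(e)), call. = FALSE))
    abs_diff[i] <- cmp$abs_diff_cc
    pct_diff[i] <- cmp$pct_diff
    pos[i] <- cmp$he_positive
  }
  rows$abs_diff_cc <- abs_diff
  rows$pct_diff <- pct_diff
  rows$he_positive <- pos
  structure(rows, n_positive = sum(pos), n_negative = n - sum(pos),
            class = c("he_cohort", "data.frame"))
}

#' @export
print.he_cohort <- function(x, ...) {
  cat(sprintf("HE cohort classification: %d scans, %d positive, %d negative\n",
              nrow(x), attr(x, "n_positive"), attr(x, "n_negative")))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}
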