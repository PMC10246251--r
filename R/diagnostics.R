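#' 2x2 confusion table for expansion detection
#'
#' Tabulates automated HE calls against the reference (reader) calls.
#' The reference is treated as ground truth: `tp` counts pairs both call
#' growth, `fp` pairs only the automated test calls growth, `fn` pairs only
#' the reference calls growth, `tn` pairs both call non-growth.
#'
#' @param reference logical (or 0/1) reference labels, growth = TRUE.
#' @param test logical (or 0/1) automated labels, same length.
#' @return An object of class `confusion_table` with integer fields
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
build_confusion <- function(reference, test) {
  as_bin <- function(x, what) {
    if (is.logical(x)) return(x)
    if (is.numeric(x) && all(x %in% c(0, 1))) return(x == 1)
    stop(sprintf("%s labels must be logical or 0/1", what))
  }
  reference <- as_bin(reference, "reference")
  test <- as_bin(test, "test")
  if (length(reference) != length(test)) stop("label vectors differ in length")
  if (anyNA(reference) || anyNA(test)) stop("labels contain NA")
  confusion_table(tp = sum(reference & test), fp = sum(!reference & test),
                  fn = sum(reference & !test), tn = sum(!reference & !test))
}

#' @rdname build_confusion
#' @param tp,fp,fn,tn non-negative integer counts.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) < 1) stop("empty table")
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(`Automated` = c("Growth", "Non-growth"),
                              `Reference` = c("Growth", "Non-growth")))
  print(m)
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Point estimate and exact two-sided interval for a binomial proportion,
#' on the percent scale, from the beta-quantile form:
#' lower = `qbeta(alpha/2, k, n-k+1)`, upper = `qbeta(1-alpha/2, k+1, n-k)`,
#' with the conventional boundary values 0 at `k = 0` and 100 at `k = n`.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `>= 1`.
#' @param alpha two-sided error rate (default 0.05 for a 95\% interval).
#' @return An object of class `estimate_ci`: `point`, `ci_low`, `ci_high`
#'   (percent), `method = "clopper_pearson"`.
#' @examples
#' clopper_pearson(16, 17)    # 94.12% (71.31, 99.85)
#' clopper_pearson(107, 110)  # 97.27% (92.24, 99.43)
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must be in [0, n]")
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  estimate_ci(100 * k / n, 100 * lo, 100 * hi, "clopper_pearson")
}

estimate_ci <- function(point, ci_low, ci_high, method) {
  structure(list(point = point, ci_low = ci_low, ci_high = ci_high,
                 method = method), class = "estimate_ci")
}

#' @export
print.estimate_ci <- function(x, digits = 2, ...) {
  cat(sprintf("%.*f (95%% CI: %.*f-%.*f) [%s]\n", digits, x$point,
              digits, x$ci_low, digits, x$ci_high, x$method))
  invisible(x)
}

#' Likelihood ratios with log-method confidence intervals
#'
#' LR+ = sensitivity / (1 - specificity), LR- = (1 - sensitivity) /
#' specificity. 95\% intervals use the standard log method,
#' `exp(log(LR) +/- z * SE)` with
#' `SE(log LR+) = sqrt(1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn))` and the
#' analogous expression (fn, tn in place of tp, fp) for LR-. A zero cell
#' that makes a ratio undefined is an error — no continuity correction is
#' applied silently.
#'
#' @param table a [confusion_table()].
#' @param alpha two-sided error rate (default 0.05).
#' @return List with `lr_pos` and `lr_neg`, each an `estimate_ci`
#'   (`method = "log_lr"`).
#' @export
likelihood_ratios <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "confusion_table"))
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  if (tp + fn == 0) stop("tp+fn = 0: sensitivity undefined")
  if (fp + tn == 0) stop("fp+tn = 0: false-positive rate undefined")
  if (fp == 0) stop("fp = 0: LR+ undefined (division by zero false-positive rate)")
  if (tn == 0) stop("tn = 0: LR- undefined (division by zero specificity)")
  z <- stats::qnorm(1 - alpha / 2)
  sens <- tp / (tp + fn)
  fpr <- fp / (fp + tn)
  lr_pos <- sens / fpr
  lr_neg <- (fn / (tp + fn)) / (tn / (fp + tn))
  ci <- function(lr, a, A, b, B) {
    # a/A and b/B are the two proportions entering the ratio
    se <- sqrt(1 / a - 1 / A + 1 / b - 1 / B)
    exp(log(lr) + c(-1, 1) * z * se)
  }
  pos <- ci(lr_pos, tp, tp + fn, fp, fp + tn)
  neg <- ci(lr_neg, fn, tp + fn, tn, fp + tn)
  list(lr_pos = estimate_ci(lr_pos, pos[1], pos[2], "log_lr"),
       lr_neg = estimate_ci(lr_neg, neg[1], neg[2], "log_lr"))
}

#' Diagnostic-accuracy summary of a 2x2 table
#'
#' Sensitivity, specificity, PPV, NPV and accuracy (percent, with exact
#' Clopper-Pearson 95\% intervals) and the positive/negative likelihood
#' ratios (log-method intervals). A likelihood ratio made undefined by a
#' zero cell is reported as `NA` with the explanatory message in
#' `lr_errors`; the proportion metrics are always reported.
#'
#' @param table a [confusion_table()].
#' @param alpha two-sided error rate (default 0.05).
#' @return An object of class `diagnostic_summary`.
#' @examples
#' summarize_diagnostics(confusion_table(16, 3, 1, 107))
#' @export
summarize_diagnostics <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "confusion_table"))
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  n <- tp + fp + fn + tn
  out <- list(
    table = table,
    sensitivity = clopper_pearson(tp, tp + fn, alpha),
    specificity = clopper_pearson(tn, tn + fp, alpha),
    ppv = clopper_pearson(tp, tp + fp, alpha),
    npv = clopper_pearson(tn, tn + fn, alpha),
    accuracy = clopper_pearson(tp + tn, n, alpha),
    lr_pos = NULL, lr_neg = NULL, lr_errors = character()
  )
  lr <- tryCatch(likelihood_ratios(table, alpha), error = function(e) e)
  if (inherits(lr, "error")) {
    out$lr_errors <- conditionMessage(lr)
    out$lr_pos <- estimate_ci(NA_real_, NA_real_, NA_real_, "log_lr")
    out$lr_neg <- estimate_ci(NA_real_, NA_real_, NA_real_, "log_lr")
  } else {
    out$lr_pos <- lr$lr_pos
    out$lr_neg <- lr$lr_neg
  }
  structure(out, class = "diagnostic_summary")
}

#' @export
summary.confusion_table <- function(object, alpha = 0.05, ...)
  summarize_diagnostics(object, alpha)

#' @export
print.diagnostic_summary <- function(x, digits = 2, ...) {
  cat("Diagnostic accuracy (reference = reader calls)\n")
  print(x$table)
  fmt <- function(name, e, pct = TRUE) {
    if (is.na(e$point)) cat(sprintf("  %-12s NA (%s)\n", name, x$lr_errors))
    else cat(sprintf("  %-12s %.*f%s (95%% CI: %.*f-%.*f)\n", name,
                     digits, e$point, if (pct) "%" else "",
                     digits, e$ci_low, digits, e$ci_high))
  }
  fmt("sensitivity", x$sensitivity)
  fmt("specificity", x$specificity)
  fmt("PPV", x$ppv)
  fmt("NPV", x$npv)
  fmt("accuracy", x$accuracy)
  fmt("LR+", x$lr_pos, pct = FALSE)
  fmt("LR-", x$lr_neg, pct = FALSE)
  invisible(x)
}

#' @export
as.data.frame.diagnostic_summary <- function(x, ...) {
  met <- c("sensitivity", "specificity", "ppv", "npv", "accuracy",
           "lr_pos", "lr_neg")
  do.call(rbind, lapply(met, function(m) {
    e <- x[[m]]
    data.frame(metric = m, point = e$point, ci_low = e$ci_low,
               ci_high = e$ci_high, method = e$method)
  }))
}
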