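## Evaluation of triage calls against H&E pathology labels.

TRIAGE_LEVELS <- c("++", "+", "-")

check_labeled <- function(records) {
  if (!is.data.frame(records))
    stopf("`records` must be a data frame")
  need <- c("call", "he_label")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stopf("records are missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(records)) {
    bad <- which(is.na(records$call) | is.na(records$he_label) |
                   !records$call %in% TRIAGE_LEVELS |
                   !records$he_label %in% c("P", "N"))
    if (length(bad)) {
      id <- if ("sample_id" %in% names(records))
        records$sample_id[bad[1]] else sprintf("row %d", bad[1])
      stopf("record %s has a missing or invalid call/label", id)
    }
  }
  invisible(records)
}

rate_or_na <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s is undefined (zero denominator); reported as NA", what),
            call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Confusion summary of triage calls versus pathology
#'
#' Screen-positive is `{++, +}` (any strong channel flags the specimen),
#' screen-negative is `-`; H&E label `P` is condition-positive.
#' Specificity = TN/(TN+FP), sensitivity = TP/(TP+FN), PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN). NPV matters clinically: it is the fraction of
#' screen-negative margins that are truly tumor-free, the quantity that
#' justifies closing on a negative pre-screen. Rates with a zero
#' denominator are reported as `NA` with a warning, never silently as 0
#' or 1.
#'
#' @param records data frame with columns `call` (in `++`/`+`/`-`) and
#'   `he_label` (in `P`/`N`); every row must have both.
#' @return A list of class `"confusion_summary"` with counts `tp`, `fp`,
#'   `tn`, `fn` and rates `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
confusion_summary <- function(records) {
  check_labeled(records)
  pred_pos <- records$call %in% c("++", "+")
  cond_pos <- records$he_label == "P"
  tp <- sum(pred_pos & cond_pos)
  fp <- sum(pred_pos & !cond_pos)
  fn <- sum(!pred_pos & cond_pos)
  tn <- sum(!pred_pos & !cond_pos)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = rate_or_na(tp, tp + fn, "sensitivity"),
    specificity = rate_or_na(tn, tn + fp, "specificity"),
    ppv = rate_or_na(tp, tp + fp, "PPV"),
    npv = rate_or_na(tn, tn + fn, "NPV")),
    class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("Confusion vs H&E: TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %s  specificity %s  PPV %s  NPV %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv)))
  invisible(x)
}

#' Triage-by-pathology crosstab
#'
#' The 3 x 2 count table of triage group (`++`, `+`, `-`) against H&E
#' label (`P`, `N`) -- the correlation table relating fluorescence
#' pre-screening to permanent-section pathology.
#'
#' @inheritParams confusion_summary
#' @return A 3 x 2 integer `table` with rows `++`, `+`, `-` and columns
#'   `P`, `N` (all cells present, zero-filled).
#' @export
group_crosstab <- function(records) {
  check_labeled(records)
  table(call = factor(records$call, levels = TRIAGE_LEVELS),
        he_label = factor(records$he_label, levels = c("P", "N")))
}

#' Write a crosstab as CSV
#'
#' @param ct a table from [group_crosstab()].
#' @param path output path.
#' @export
write_crosstab_csv <- function(ct, path) {
  df <- as.data.frame.matrix(ct)
  df <- cbind(call = rownames(df), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
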