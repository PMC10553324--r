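as_counts <- function(c) {
  if (inherits(c, "confusion_counts")) return(c)
  if (is.list(c) && all(c("tp", "fp", "tn", "fn") %in% names(c)))
    return(new_confusion_counts(c$tp, c$fp, c$tn, c$fn,
                                c$mode %||% "pooled"))
  stop("need a confusion_counts object or a list with tp/fp/tn/fn",
       call. = FALSE)
}

#' Sensitivity, specificity and accuracy of confusion counts
#'
#' The usual rates: sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`.  A zero denominator is an error
#' (the rate is undefined, not zero).
#'
#' @param c a `"confusion_counts"` object (or list with `tp`,`fp`,`tn`,`fn`).
#' @return The rate in [0, 1].
#' @export
sensitivity <- function(c) {
  c <- as_counts(c)
  if (c$tp + c$fn == 0) stop("sensitivity undefined: TP + FN = 0",
                             call. = FALSE)
  c$tp / (c$tp + c$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(c) {
  c <- as_counts(c)
  if (c$tn + c$fp == 0) stop("specificity undefined: TN + FP = 0",
                             call. = FALSE)
  c$tn / (c$tn + c$fp)
}

#' @rdname sensitivity
#' @export
accuracy <- function(c) {
  c <- as_counts(c)
  tot <- c$tp + c$fp + c$tn + c$fn
  if (tot == 0) stop("accuracy undefined: no counts", call. = FALSE)
  (c$tp + c$tn) / tot
}

#' Cohen's kappa for a 2x2 confusion table
#'
#' Chance-corrected agreement, evaluated as
#' `2 (TP*TN - FN*FP) / ((TP+FP)(FP+TN) + (TP+FN)(FN+TN))`,
#' which is algebraically the classical `(p_o - p_e) / (1 - p_e)` for two
#' raters on a binary outcome.
#'
#' @inheritParams sensitivity
#' @return Kappa in [-1, 1].
#' @export
cohen_kappa <- function(c) {
  c <- as_counts(c)
  den <- (c$tp + c$fp) * (c$fp + c$tn) + (c$tp + c$fn) * (c$fn + c$tn)
  if (den == 0) stop("kappa undefined: zero denominator", call. = FALSE)
  2 * (c$tp * c$tn - c$fn * c$fp) / den
}

#' Round half away from zero
#'
#' Presentation rounding used for agreement tables (`0.845 -> 0.85`),
#' unlike base R's round-half-to-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-acquisition agreement summary
#'
#' Computes sensitivity, specificity, accuracy and Cohen's kappa for each
#' acquisition's confusion counts, plus unweighted means across
#' acquisitions and the standard deviation of kappa (sample, n-1
#' convention).  Full precision is retained in the returned columns;
#' rounding half-up to two decimals happens only in the print method.
#' Rows with an undefined rate are kept but flagged and excluded from the
#' means with a warning.
#'
#' @param counts a data frame with columns `tn`, `tp`, `fn`, `fp` (one row
#'   per acquisition), or a list of `"confusion_counts"`.
#' @param labels optional acquisition labels.
#' @return An `"acquisition_summary"` data frame with attributes
#'   `mean_sensitivity`, `mean_specificity`, `mean_accuracy`,
#'   `mean_kappa`, `sd_kappa`.
#' @export
acquisition_summary <- function(counts, labels = NULL) {
  if (is.data.frame(counts)) {
    df <- counts
    stopifnot(all(c("tn", "tp", "fn", "fp") %in% names(df)))
  } else {
    cl <- lapply(counts, as_counts)
    df <- data.frame(tn = vapply(cl, `[[`, 0, "tn"),
                     tp = vapply(cl, `[[`, 0, "tp"),
                     fn = vapply(cl, `[[`, 0, "fn"),
                     fp = vapply(cl, `[[`, 0, "fp"))
  }
  stopifnot(nrow(df) >= 1)
  n <- nrow(df)
  safe <- function(fun, i) tryCatch(
    fun(new_confusion_counts(df$tp[i], df$fp[i], df$tn[i], df$fn[i])),
    error = function(e) NA_real_)
  df$sensitivity <- vapply(seq_len(n), function(i) safe(sensitivity, i), 0)
  df$specificity <- vapply(seq_len(n), function(i) safe(specificity, i), 0)
  df$accuracy    <- vapply(seq_len(n), function(i) safe(accuracy, i), 0)
  df$kappa       <- vapply(seq_len(n), function(i) safe(cohen_kappa, i), 0)
  df <- cbind(acquisition = labels %||% seq_len(n), df)
  if (anyNA(df[c("sensitivity", "specificity", "accuracy", "kappa")]))
    warning("undefined rate(s) excluded from the mean row", call. = FALSE)
  attr(df, "mean_sensitivity") <- mean(df$sensitivity, na.rm = TRUE)
  attr(df, "mean_specificity") <- mean(df$specificity, na.rm = TRUE)
  attr(df, "mean_accuracy") <- mean(df$accuracy, na.rm = TRUE)
  attr(df, "mean_kappa") <- mean(df$kappa, na.rm = TRUE)
  attr(df, "sd_kappa") <- stats::sd(df$kappa[!is.na(df$kappa)])
  class(df) <- c("acquisition_summary", "data.frame")
  df
}

#' @export
print.acquisition_summary <- function(x, decimal_comma = FALSE, ...) {
  fmt <- function(v) {
    s <- sprintf("%.2f", round_half_up(v, 2))
    if (decimal_comma) s <- sub("\\.", ",", s)
    s
  }
  df <- as.data.frame(x)
  for (nm in c("sensitivity", "specificity", "accuracy", "kappa"))
    df[[nm]] <- fmt(df[[nm]])
  print(df, row.names = FALSE)
  cat(sprintf("MEAN VALUE  sensitivity %s  specificity %s  accuracy %s  kappa %s (sd %s)\n",
              fmt(attr(x, "mean_sensitivity")),
              fmt(attr(x, "mean_specificity")),
              fmt(attr(x, "mean_accuracy")),
              fmt(attr(x, "mean_kappa")),
              fmt(attr(x, "sd_kappa"))))
  invisible(x)
}

#' Write an acquisition summary table to CSV
#'
#' Mirrors the printed table including a `MEAN VALUE` row; with
#' `decimal_comma = TRUE` rates are rendered with a decimal comma.
#'
#' @param x an `"acquisition_summary"`.
#' @param path output path.
#' @param decimal_comma render rates with a comma decimal separator.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(x, path, decimal_comma = FALSE) {
  fmt <- function(v) {
    s <- sprintf("%.2f", round_half_up(v, 2))
    if (decimal_comma) sub("\\.", ",", s) else s
  }
  df <- as.data.frame(x)
  out <- data.frame(acquisition = as.character(df$acquisition),
                    tn = df$tn, tp = df$tp, fn = df$fn, fp = df$fp,
                    sensitivity = fmt(df$sensitivity),
                    specificity = fmt(df$specificity),
                    accuracy = fmt(df$accuracy),
                    kappa = fmt(df$kappa))
  out[nrow(out) + 1, ] <- c("MEAN VALUE", NA, NA, NA, NA,
                            fmt(attr(x, "mean_sensitivity")),
                            fmt(attr(x, "mean_specificity")),
                            fmt(attr(x, "mean_accuracy")),
                            fmt(attr(x, "mean_kappa")))
  utils::write.csv(out, path, row.names = FALSE,
                   quote = decimal_comma)
  invisible(path)
}

#' Confusion counts from a published clinical validation study
#'
#' Per-acquisition pooled confusion counts (22 complete 24-hour
#' acquisitions from twelve patients, 528 recording hours) from a
#' published clinical validation of this wrist-worn monitoring method
#' against patient motor diaries, together with the per-row rates and the
#' diary hours as published.  Shipped as plain-text CSVs under
#' `inst/extdata/`; used by the acceptance checks to verify the agreement
#' statistics against their published values.
#'
#' Note: one acquisition (#16) is internally inconsistent in the published
#' table -- the rates printed alongside its counts do not follow from
#' those counts.  The counts are kept as published.
#'
#' @return Data frame with columns `acquisition`, `tn`, `tp`, `fn`, `fp`,
#'   published rates `sens_pub`, `spec_pub`, `acc_pub`, and diary hours
#'   `diary_off_h`, `diary_on_h`, `diary_on_td_h`, `diary_sleep_h`.
#' @export
clinical_validation_table <- function() {
  counts <- utils::read.csv(system.file("extdata",
                                        "clinical_validation_counts.csv",
                                        package = "wristpd"))
  hours <- utils::read.csv(system.file("extdata",
                                       "clinical_validation_diary_hours.csv",
                                       package = "wristpd"))
  merge(counts, hours, by = "acquisition", sort = TRUE)
}
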