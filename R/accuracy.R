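# Region-level diagnostic accuracy: confusion counts over adequacy calls,
# sensitivity / specificity / PPV / NPV with exact (Clopper-Pearson) 95%
# binomial confidence intervals, and the enumeration utility that recovers
# integer confusion matrices from rounded published metrics.

#' Diagnostic accuracy of region-level adequacy calls
#'
#' An inadequate margin (< threshold) is the positive class. Ratios with a
#' zero denominator are reported as NA (not defined), never as 0/0 = 0.
#' Confidence intervals are exact binomial (Clopper-Pearson).
#'
#' @param test_calls,ref_calls Character or factor vectors of paired calls
#'   (`"inadequate"` / `"adequate"`), or logical vectors (TRUE = inadequate),
#'   over the same ordered (specimen, region) slots.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `accuracy_report`: `counts` (TP, FN, FP, TN, n)
#'   and `metrics` (data frame: metric, estimate, lower, upper as
#'   proportions).
#' @export
diagnostic_accuracy <- function(test_calls, ref_calls, conf_level = 0.95) {
  as_pos <- function(x) {
    if (is.logical(x)) return(x)
    x <- as.character(x)
    bad <- setdiff(unique(x), c("inadequate", "adequate"))
    if (length(bad)) {
      sm_error(sprintf("calls must be binary inadequate/adequate (got %s)",
                       paste(bad, collapse = ", ")),
               "specimargin_error_non_binary")
    }
    x == "inadequate"
  }
  test <- as_pos(test_calls); ref <- as_pos(ref_calls)
  if (length(test) != length(ref)) {
    sm_error("call vectors differ in length", "specimargin_error_length_mismatch")
  }
  tp <- sum(test & ref); fn <- sum(!test & ref)
  fp <- sum(test & !ref); tn <- sum(!test & !ref)
  counts <- c(TP = tp, FN = fn, FP = fp, TN = tn, n = length(test))
  one <- function(name, x, n) {
    if (n == 0) {
      data.frame(metric = name, estimate = NA_real_,
                 lower = NA_real_, upper = NA_real_)
    } else {
      ci <- binom.test(x, n, conf.level = conf_level)$conf.int
      data.frame(metric = name, estimate = x / n,
                 lower = ci[1], upper = ci[2])
    }
  }
  metrics <- rbind(one("sensitivity", tp, tp + fn),
                   one("specificity", tn, tn + fp),
                   one("ppv", tp, tp + fp),
                   one("npv", tn, tn + fn))
  structure(list(counts = counts, metrics = metrics,
                 conf_level = conf_level),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> TP=%d FN=%d FP=%d TN=%d (n=%d)\n",
              x$counts["TP"], x$counts["FN"], x$counts["FP"], x$counts["TN"],
              x$counts["n"]))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (is.na(m$estimate[i])) {
      cat(sprintf("  %-11s not defined (zero denominator)\n", m$metric[i]))
    } else {
      cat(sprintf("  %-11s %3.0f%% (%.0f%% - %.0f%%)\n", m$metric[i],
                  100 * m$estimate[i], 100 * m$lower[i], 100 * m$upper[i]))
    }
  }
  invisible(x)
}

# round-half-up to integer percent, the convention of published tables
pct_round <- function(x) floor(100 * x + 0.5)

#' Recover integer confusion matrices from rounded percent metrics
#'
#' Exhaustively enumerates all nonnegative integer confusion matrices
#' (TP, FN, FP, TN) summing to `n` whose sensitivity, specificity, PPV and
#' NPV round (half-up) to the given integer percents. Useful for validating
#' published accuracy tables that print metrics but not counts.
#'
#' @param metrics_pct Numeric length-4: sensitivity, specificity, PPV, NPV in
#'   integer percent.
#' @param n Total number of slots.
#' @return Data frame with columns TP, FN, FP, TN (possibly zero rows).
#' @export
reconstruct_confusion_matrices <- function(metrics_pct, n) {
  stopifnot(length(metrics_pct) == 4, n >= 1,
            all(metrics_pct >= 0 & metrics_pct <= 100))
  n <- as.integer(n)
  res <- list(); k <- 1
  for (tp in 0:n) for (fn in 0:(n - tp)) for (fp in 0:(n - tp - fn)) {
    tn <- n - tp - fn - fp
    mets <- c(if (tp + fn > 0) pct_round(tp / (tp + fn)) else NA,
              if (tn + fp > 0) pct_round(tn / (tn + fp)) else NA,
              if (tp + fp > 0) pct_round(tp / (tp + fp)) else NA,
              if (tn + fn > 0) pct_round(tn / (tn + fn)) else NA)
    if (!anyNA(mets) && all(mets == metrics_pct)) {
      res[[k]] <- c(TP = tp, FN = fn, FP = fp, TN = tn); k <- k + 1
    }
  }
  as.data.frame(do.call(rbind, res) %||% matrix(integer(0), 0, 4,
    dimnames = list(NULL, c("TP", "FN", "FP", "TN"))))
}
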