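# evaluation statistics: confusion matrices, overall and per-class metrics,
# Wilson score intervals, McNemar tests, and table rendering.

#' Confusion matrix
#'
#' Rows are the true class, columns the predicted class;
#' `counts[i, j]` = number of samples of true class i predicted as class j.
#'
#' @param y_true,y_pred label vectors (factors or coercible).
#' @param class_names class names; defaults to the union of factor levels.
#' @return a K x K integer matrix of class `gptnext_confusion` with dimnames
#'   `true` / `predicted`.
#' @export
confusion_matrix <- function(y_true, y_pred, class_names = NULL) {
  if (length(y_true) != length(y_pred))
    stop_input("y_true and y_pred lengths differ")
  if (is.null(class_names))
    class_names <- union(levels(factor(y_true)), levels(factor(y_pred)))
  if (!all(as.character(y_true) %in% class_names) ||
      !all(as.character(y_pred) %in% class_names))
    stop_input("labels outside class_names")
  yt <- factor(y_true, levels = class_names)
  yp <- factor(y_pred, levels = class_names)
  cm <- unclass(table(true = yt, predicted = yp))
  class(cm) <- c("gptnext_confusion", class(cm))
  cm
}

#' Overall classification metrics
#'
#' Accuracy = 100 * trace/total; UAR (unweighted average recall) = mean
#' per-class recall; UAP = mean per-class precision; F1 = harmonic mean of
#' UAR and UAP. Classes absent from the truth (zero row) are excluded from
#' UAR with a warning; classes never predicted are excluded from UAP.
#'
#' @param cm a [confusion_matrix()] (or plain K x K count matrix).
#' @return list with `accuracy`, `uar`, `uap`, `f1` (percentages, unrounded)
#'   and `n` (total count).
#' @export
overall_metrics <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop_input("empty confusion matrix")
  rs <- rowSums(cm); cs <- colSums(cm)
  if (any(rs == 0))
    warning("classes absent from the truth excluded from UAR: ",
            paste(rownames(cm)[rs == 0], collapse = ", "), call. = FALSE)
  recall <- diag(cm)[rs > 0] / rs[rs > 0]
  precision <- diag(cm)[cs > 0] / cs[cs > 0]
  acc <- 100 * sum(diag(cm)) / total
  uar <- 100 * mean(recall)
  uap <- 100 * mean(precision)
  f1 <- if (uar + uap > 0) 2 * uar * uap / (uar + uap) else 0
  list(accuracy = acc, uar = uar, uap = uap, f1 = f1, n = total)
}

#' Per-class metrics
#'
#' One-vs-rest sensitivity (recall), specificity, precision and F1 per class,
#' plus unweighted macro averages. Cells with zero denominators are reported
#' as `NA` and excluded from the macro averages with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @return data.frame with one row per class plus a final "macro" row;
#'   percentage columns `sensitivity`, `specificity`, `precision`, `f1`.
#' @export
per_class_metrics <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop_input("empty confusion matrix")
  K <- nrow(cm)
  out <- data.frame(class = rownames(cm) %||% as.character(seq_len(K)),
                    sensitivity = NA_real_, specificity = NA_real_,
                    precision = NA_real_, f1 = NA_real_)
  for (k in seq_len(K)) {
    tp <- cm[k, k]; fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp; tn <- total - tp - fn - fp
    out$sensitivity[k] <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    out$specificity[k] <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
    out$precision[k]   <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
    p <- out$precision[k]; r <- out$sensitivity[k]
    out$f1[k] <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r)
                 else NA_real_
  }
  if (anyNA(out[, -1]))
    warning("undefined (zero-denominator) cells excluded from macro averages",
            call. = FALSE)
  macro <- data.frame(class = "macro",
                      sensitivity = mean(out$sensitivity, na.rm = TRUE),
                      specificity = mean(out$specificity, na.rm = TRUE),
                      precision = mean(out$precision, na.rm = TRUE),
                      f1 = mean(out$f1, na.rm = TRUE))
  rbind(out, macro)
}

#' Wilson score confidence interval
#'
#' Binomial proportion interval with accurate coverage near 0% and 100%,
#' using the standard-normal quantile at `(1 + confidence)/2`.
#'
#' @param successes,n number of successes and trials.
#' @param confidence confidence level (default 0.95).
#' @return named numeric `c(lower, upper)` in percent, rounded half-up to two
#'   decimals.
#' @export
wilson_interval <- function(successes, n, confidence = 0.95) {
  if (n <= 0) stop_input("n must be positive")
  if (successes < 0 || successes > n)
    stop_input("successes must lie in [0, n]")
  z <- stats::qnorm((1 + confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = round_half_up(100 * max(0, center - half), 2),
    upper = round_half_up(100 * min(1, center + half), 2))
}

#' McNemar test for paired classifier comparison
#'
#' Counts the discordant pairs between two prediction sets on the same
#' samples (`b` = A right / B wrong, `c` = A wrong / B right) and computes
#' the chi-squared statistic with 1 df: `(|b-c|-1)^2/(b+c)` with continuity
#' correction (default) or `(b-c)^2/(b+c)` without.
#'
#' @param predsA,predsB `gptnext_predictions` with identical `y_true`.
#' @param correction apply the continuity correction.
#' @return an object of class `gptnext_mcnemar`: list with `b`, `c`, `chi2`,
#'   `p`, `corrected`, `degenerate` (TRUE when `b + c == 0`, where `p = 1`).
#' @export
mcnemar <- function(predsA, predsB, correction = TRUE) {
  if (is.null(predsA$y_true) || is.null(predsB$y_true))
    stop_input("both prediction sets need y_true")
  if (length(predsA$y_true) != length(predsB$y_true) ||
      any(as.character(predsA$y_true) != as.character(predsB$y_true)))
    stop_input("prediction sets are not paired on the same samples")
  rightA <- predsA$y_pred == predsA$y_true
  rightB <- predsB$y_pred == predsB$y_true
  b <- sum(rightA & !rightB)
  c_ <- sum(!rightA & rightB)
  if (b + c_ == 0) {
    res <- list(b = b, c = c_, chi2 = 0, p = 1, corrected = correction,
                degenerate = TRUE)
  } else {
    num <- if (correction) (abs(b - c_) - 1)^2 else (b - c_)^2
    chi2 <- max(0, num) / (b + c_)
    res <- list(b = b, c = c_, chi2 = chi2,
                p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                corrected = correction, degenerate = FALSE)
  }
  class(res) <- "gptnext_mcnemar"
  res
}

#' @export
print.gptnext_mcnemar <- function(x, ...) {
  cat(sprintf("McNemar: b = %d, c = %d, chi2 = %.4f, p = %.4g%s%s\n",
              x$b, x$c, x$chi2, x$p,
              if (x$corrected) " (continuity-corrected)" else "",
              if (x$degenerate) " [degenerate: no discordant pairs]" else ""))
  invisible(x)
}

#' Full metrics report for a prediction set
#'
#' Confusion matrix, overall metrics with the Wilson 95% CI on accuracy, and
#' the per-class table.
#'
#' @param preds a `gptnext_predictions` with `y_true` set.
#' @param class_names optional class names.
#' @return an object of class `gptnext_report`.
#' @export
metrics_report <- function(preds, class_names = NULL) {
  if (is.null(preds$y_true)) stop_input("predictions carry no y_true")
  cm <- confusion_matrix(preds$y_true, preds$y_pred, class_names)
  ov <- overall_metrics(cm)
  ci <- wilson_interval(sum(diag(unclass(cm))), ov$n)
  structure(list(source = preds$source, confusion = cm, overall = ov,
                 ci = ci, per_class = per_class_metrics(cm)),
            class = "gptnext_report")
}

#' @export
print.gptnext_report <- function(x, ...) {
  cat("== evaluation:", x$source, "==\n\nconfusion matrix (rows = true):\n")
  print(unclass(x$confusion))
  cat(sprintf("\naccuracy %s%%  [%.2f, %.2f] 95%% CI (Wilson), n = %d\n",
              format(round_half_up(x$overall$accuracy, 2), nsmall = 2),
              x$ci["lower"], x$ci["upper"], x$overall$n))
  cat(sprintf("UAR %.2f%%  UAP %.2f%%  F1 %.2f%%\n",
              round_half_up(x$overall$uar, 2), round_half_up(x$overall$uap, 2),
              round_half_up(x$overall$f1, 2)))
  cat("\nper-class (%):\n")
  pc <- x$per_class
  pc[, -1] <- lapply(pc[, -1], function(v) round_half_up(v, 2))
  print(pc, row.names = FALSE)
  invisible(x)
}

# write a report as CSV tables (overall + per-class + confusion)
write_report_csv <- function(report, prefix) {
  ov <- report$overall
  utils::write.csv(data.frame(
    source = report$source,
    accuracy = round_half_up(ov$accuracy, 2), uar = round_half_up(ov$uar, 2),
    uap = round_half_up(ov$uap, 2), f1 = round_half_up(ov$f1, 2),
    ci_lower = report$ci["lower"], ci_upper = report$ci["upper"], n = ov$n),
    paste0(prefix, "_overall.csv"), row.names = FALSE)
  pc <- report$per_class
  pc[, -1] <- lapply(pc[, -1], function(v) round_half_up(v, 2))
  utils::write.csv(pc, paste0(prefix, "_per_class.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(report$confusion)),
                   paste0(prefix, "_confusion.csv"))
  invisible(prefix)
}
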