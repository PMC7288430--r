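#' Confusion counts with class-size normalization
#'
#' Benchmarks with many more non-viral than viral test sequences are made
#' comparable by scaling the negative class down to the size of the
#' positive class: `FP` and `TN` are multiplied by
#' `n_virus / n_nonvirus`, leaving `TP` and `FN` (hence recall) unchanged.
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN` and optionally
#'   `n_virus`, `n_nonvirus` (defaulting to `TP+FN` and `FP+TN`).
#' @return the counts list with scaled `FP`/`TN` and `norm_factor` set.
#' @export
normalizeCounts <- function(counts) {
  nV <- if (!is.null(counts$n_virus)) counts$n_virus else
    counts$TP + counts$FN
  nN <- if (!is.null(counts$n_nonvirus)) counts$n_nonvirus else
    counts$FP + counts$TN
  if (nN == 0) stop("no non-virus examples to normalize against")
  if (nN < nV) stop("normalization expects n_nonvirus >= n_virus")
  f <- nV / nN
  counts$FP <- counts$FP * f
  counts$TN <- counts$TN * f
  counts$n_virus <- nV
  counts$n_nonvirus <- nN
  counts$norm_factor <- f
  counts
}

#' Binary-classification performance metrics
#'
#' Standard definitions: recall = TP/(TP+FN); precision = TP/(TP+FP);
#' specificity = TN/(TN+FP); accuracy = (TP+TN)/total; F1 = 2PR/(P+R);
#' MCC by its usual product-moment formula. A metric whose denominator is
#' zero is reported as `NA` (undefined).
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN` (possibly normalized,
#'   see [normalizeCounts()]).
#' @return named list: `recall`, `precision`, `accuracy`, `specificity`,
#'   `F1`, `MCC`.
#' @export
computeMetrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  recall <- div(TP, TP + FN)
  precision <- div(TP, TP + FP)
  specificity <- div(TN, TN + FP)
  accuracy <- div(TP + TN, TP + TN + FP + FN)
  f1 <- if (is.na(recall) || is.na(precision) || recall + precision == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  mccDen <- sqrt((TP + FP)) * sqrt((TP + FN)) * sqrt((TN + FP)) *
    sqrt((TN + FN))
  mcc <- if (mccDen == 0) NA_real_ else (TP * TN - FP * FN) / mccDen
  list(recall = recall, precision = precision, accuracy = accuracy,
       specificity = specificity, F1 = f1, MCC = mcc)
}

#' F1 from a printed recall/precision pair
#'
#' Convenience for recomputing reported F1 values from reported recall and
#' precision percentages.
#'
#' @param recallPct,precisionPct recall and precision in percent.
#' @param digits rounding for the reported value (default 3).
#' @return numeric F1.
#' @export
f1FromPercent <- function(recallPct, precisionPct, digits = 3) {
  r <- recallPct / 100
  p <- precisionPct / 100
  round(2 * p * r / (p + r), digits)
}

#' Pairwise comparison ratios and cross-dataset means
#'
#' Given per-dataset totals for two methods, reports the per-dataset ratio
#' `A / B` (rounded to `digits` decimal places) and the arithmetic mean of
#' the ratios across datasets.
#'
#' @param a,b numeric vectors of totals, aligned by dataset.
#' @param digits rounding for per-dataset ratios (default 2).
#' @return list with `ratios` (per dataset) and `mean` (mean of the
#'   rounded ratios, rounded to `digits`).
#' @export
ratioReport <- function(a, b, digits = 2) {
  ratios <- ifelse(b == 0, NA_real_, round(a / b, digits))
  list(ratios = ratios,
       mean = round(mean(ratios, na.rm = TRUE), digits))
}

#' Confusion counts from labeled prediction vectors
#'
#' @param truth,predicted vectors of `"virus"`/`"nonvirus"` labels.
#' @return counts list suitable for [computeMetrics()].
#' @export
confusionCounts <- function(truth, predicted) {
  list(TP = sum(truth == "virus" & predicted == "virus"),
       FP = sum(truth == "nonvirus" & predicted == "virus"),
       TN = sum(truth == "nonvirus" & predicted == "nonvirus"),
       FN = sum(truth == "virus" & predicted == "nonvirus"),
       n_virus = sum(truth == "virus"),
       n_nonvirus = sum(truth == "nonvirus"))
}
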