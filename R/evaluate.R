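# Performance metrics and statistics: balanced accuracy, Matthews
# correlation coefficient, ROC-AUC (midrank convention), quartile-based
# performance grouping and paired Wilcoxon signed-rank testing with
# Holm-Bonferroni adjustment.

#' Confusion counts from true and predicted labels
#'
#' @param truth,pred 0/1 vectors of equal length.
#' @return list with fields `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  list(tp = sum(truth == 1 & pred == 1),
       fn = sum(truth == 1 & pred == 0),
       tn = sum(truth == 0 & pred == 0),
       fp = sum(truth == 0 & pred == 1))
}

#' Balanced accuracy
#'
#' `BA = (sensitivity + specificity) / 2 =
#' (TP/(TP+FN) + TN/(TN+FP)) / 2`. Undefined (error) when a class is absent.
#'
#' @param c confusion counts ([confusion_counts()]).
#' @return balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(c) {
  if (c$tp + c$fn == 0 || c$tn + c$fp == 0) {
    stop_input("balanced accuracy undefined: a class is absent")
  }
  0.5 * (c$tp / (c$tp + c$fn) + c$tn / (c$tn + c$fp))
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; when any
#' factor of the denominator is zero the coefficient is defined as 0
#' (standard convention).
#'
#' @param c confusion counts ([confusion_counts()]).
#' @return MCC in `[-1, 1]`.
#' @export
mcc_score <- function(c) {
  den <- (c$tp + c$fp) * (c$tp + c$fn) * (c$tn + c$fp) * (c$tn + c$fn)
  if (den == 0) return(0)
  (c$tp * c$tn - c$fp * c$fn) / sqrt(den)
}

#' Area under the ROC curve
#'
#' Threshold-free: the probability that a randomly drawn positive receives a
#' higher score than a randomly drawn negative, with ties counted half
#' (midrank convention).
#'
#' @param scores real-valued scores, higher = more active.
#' @param labels 0/1 labels (both classes required).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop_input("ROC-AUC undefined: a class is absent")
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Group assay results into performance tiers by MCC quartiles
#'
#' Within one experiment cell, test assays with MCC strictly above the third
#' quartile are labeled `"positive"` (best predictions), those strictly
#' below the first quartile `"negative"`, and the closed interval in between
#' `"interquartile"`. Quartiles use linear interpolation (default quantile
#' convention).
#'
#' @param results a `data.frame` with (at least) an `mcc` column; needs
#'   >= 4 rows.
#' @return `results` with an added `group` factor column.
#' @export
group_by_mcc <- function(results) {
  stopifnot(is.data.frame(results), "mcc" %in% names(results))
  if (nrow(results) < 4) stop_input("MCC grouping needs at least 4 results")
  q <- quantile(results$mcc, c(0.25, 0.75), names = FALSE, type = 7)
  grp <- ifelse(results$mcc > q[2], "positive",
                ifelse(results$mcc < q[1], "negative", "interquartile"))
  results$group <- factor(grp, levels = c("positive", "interquartile",
                                          "negative"))
  results
}

#' Paired Wilcoxon signed-rank tests with Holm-Bonferroni adjustment
#'
#' Compares a per-assay metric between all pairs of representations (or any
#' other conditions) over the same set of test assays. For each pair a
#' two-sided signed-rank test is computed (exact distribution for <= 25
#' non-zero differences without ties, normal approximation otherwise);
#' p-values are then Holm-adjusted across the family of pairs. Pairs with
#' all-zero differences cannot be tested and are reported with `NA` p-values
#' and a `zero_differences` flag.
#'
#' @param metric_by_condition named list of numeric vectors, one per
#'   condition, each named by test assay; all vectors must cover the same
#'   assays.
#' @param alpha significance level for the adjusted p-values (default 0.05).
#' @return a `data.frame` with columns `condition_a`, `condition_b`,
#'   `raw_p`, `adjusted_p`, `significant`, `zero_differences`.
#' @export
paired_wilcoxon_holm <- function(metric_by_condition, alpha = 0.05) {
  stopifnot(is.list(metric_by_condition), length(metric_by_condition) >= 2)
  nm <- names(metric_by_condition)
  ref <- sort(names(metric_by_condition[[1]]))
  if (is.null(ref) || !length(ref)) {
    stop_input("metric vectors must be named by test assay")
  }
  for (k in nm) {
    if (!identical(sort(names(metric_by_condition[[k]])), ref)) {
      stop_input("condition '%s' does not cover the same test assays", k)
    }
  }
  pairs <- combn(nm, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    x <- metric_by_condition[[a]][ref]
    y <- metric_by_condition[[b]][ref]
    d <- x - y
    nz <- d[d != 0]
    if (!length(nz)) {
      return(data.frame(condition_a = a, condition_b = b, raw_p = NA_real_,
                        zero_differences = TRUE, stringsAsFactors = FALSE))
    }
    exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
    p <- suppressWarnings(
      wilcox.test(x, y, paired = TRUE, exact = exact)$p.value)
    data.frame(condition_a = a, condition_b = b, raw_p = p,
               zero_differences = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- NA_real_
  testable <- !is.na(out$raw_p)
  out$adjusted_p[testable] <- p.adjust(out$raw_p[testable], method = "holm")
  out$significant <- !is.na(out$adjusted_p) & out$adjusted_p < alpha
  out[, c("condition_a", "condition_b", "raw_p", "adjusted_p",
          "significant", "zero_differences")]
}
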