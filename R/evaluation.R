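#' Per-tissue accuracy report
#'
#' Tallies predictions against ground-truth tissue labels: one row per true
#' tissue with sample count, correct count and accuracy fraction, plus an
#' overall row whose counts are the exact column sums. "Correct" means the
#' predicted label string-equals the true label after `label_map` (a named
#' character vector, applied to truth labels) has been applied.
#'
#' @param preds list of `get_prediction`.
#' @param meta sample metadata holding the truth tissue labels.
#' @param label_map optional named character vector harmonizing truth labels
#'   (names = raw labels, values = template labels).
#' @param digits decimal places for the rendered percent column (default 2).
#' @return data.frame with columns `tissue`, `n_samples`, `n_correct`,
#'   `accuracy` (fraction) and `percent` (rendered string); last row
#'   `tissue == "overall"`.
#' @export
accuracy_report <- function(preds, meta, label_map = NULL, digits = 2) {
  stopifnot(all(vapply(preds, inherits, logical(1), "get_prediction")))
  validate_metadata(meta)
  ids <- vapply(preds, `[[`, "", "sample_id")
  truth <- meta$tissue[match(ids, meta$sample_id)]
  if (anyNA(truth))
    stop("predictions without metadata: ",
         paste(ids[is.na(truth)], collapse = ", "))
  if (!is.null(label_map)) {
    mapped <- label_map[truth]
    truth <- ifelse(is.na(mapped), truth, mapped)
  }
  predicted <- vapply(preds, `[[`, "", "predicted_tissue")
  correct <- predicted == truth

  tissues <- sort(unique(truth))
  n <- vapply(tissues, function(t) sum(truth == t), integer(1))
  k <- vapply(tissues, function(t) sum(correct[truth == t]), integer(1))
  out <- data.frame(tissue = c(tissues, "overall"),
                    n_samples = c(n, sum(n)),
                    n_correct = c(k, sum(k)),
                    stringsAsFactors = FALSE)
  out$accuracy <- out$n_correct / out$n_samples
  out$percent <- format_percent(out$accuracy, digits)
  rownames(out) <- NULL
  out
}

#' Sensitivity and specificity from a 2x2 confusion table
#'
#' sensitivity = TP / (TP + FN), specificity = TN / (TN + FP), reported as
#' exact fractions plus integer-percent renderings (half away from zero, so
#' 40/45 renders as 89%).
#'
#' @param tp,fp,fn,tn nonnegative counts; `positive_label` names the class
#'   counted as positive (kept explicit so either orientation of the table
#'   is reproducible).
#' @param positive_label label of the positive class.
#' @return list with `sensitivity`, `specificity` (fractions),
#'   `sensitivity_pct`, `specificity_pct` (integers) and `positive_label`.
#' @export
confusion_stats <- function(tp, fp, fn, tn, positive_label = "positive") {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("confusion counts must be nonnegative integers")
  if (sum(counts) == 0) stop("empty confusion table")
  if (tp + fn == 0) stop("zero denominator: tp + fn == 0 (sensitivity undefined)")
  if (tn + fp == 0) stop("zero denominator: tn + fp == 0 (specificity undefined)")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(sensitivity = sens, specificity = spec,
       sensitivity_pct = round_half_away(100 * sens),
       specificity_pct = round_half_away(100 * spec),
       positive_label = positive_label)
}

#' Mean and SD of correlations to a target tissue
#'
#' Summary statistic used for "correlation coefficient mean +/- sd" style
#' reporting of how tightly a sample group tracks its expected template.
#'
#' @param preds list of at least two `get_prediction`.
#' @param target_tissue template tissue whose correlations to summarize.
#' @return list with `mean`, `sd` (sample sd, n-1 denominator) and `n`.
#' @export
correlation_summary <- function(preds, target_tissue) {
  stopifnot(all(vapply(preds, inherits, logical(1), "get_prediction")))
  if (length(preds) < 2) stop("need at least 2 predictions (sd undefined)")
  r <- vapply(preds, function(p) {
    if (!target_tissue %in% names(p$correlations))
      stop("unknown tissue label: ", target_tissue)
    unname(p$correlations[target_tissue])
  }, numeric(1))
  list(mean = mean(r), sd = stats::sd(r), n = length(r))
}
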