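#' Nearest-template tissue prediction
#'
#' A sample is classified to the tissue whose template it correlates with
#' most (1-nearest-neighbour over templates). Pearson correlation is the
#' default; Spearman (average ranks for ties) probes robustness to monotone
#' distortions. Ties at equal correlation break lexicographically by tissue
#' label, and the tie is logged.
#'
#' @param x numeric vector of signature-gene expression, aligned to
#'   `ts$signature` (same genes, same order), or a named vector covering it.
#' @param ts `get_templates`.
#' @param method `"pearson"` or `"spearman"`.
#' @param sample_id identifier recorded in the result.
#' @return object of class `get_prediction`: fields `sample_id`,
#'   `correlations` (named, one per tissue), `predicted_tissue`, `method`.
#' @export
predict_sample <- function(x, ts, method = c("pearson", "spearman"),
                           sample_id = "sample") {
  method <- match.arg(method)
  stopifnot(inherits(ts, "get_templates"))
  genes <- ts$signature$gene_ids
  if (!is.null(names(x))) {
    absent <- setdiff(genes, names(x))
    if (length(absent))
      stop("sample vector missing signature genes: ",
           paste(absent, collapse = ", "))
    x <- x[genes]
  } else if (length(x) != length(genes)) {
    stop(sprintf("sample vector length %d != signature length %d",
                 length(x), length(genes)))
  }
  if (!all(is.finite(x))) stop("sample vector contains non-finite values")
  if (stats::sd(x) == 0) stop("constant sample vector: correlation undefined")
  tsd <- apply(ts$vectors, 1, stats::sd)
  if (any(tsd == 0))
    stop("constant template for tissue: ",
         paste(ts$tissues[tsd == 0], collapse = ", "))

  cors <- drop(stats::cor(x, t(ts$vectors), method = method))
  names(cors) <- ts$tissues
  best <- max(cors)
  winners <- sort(names(cors)[cors == best])
  if (length(winners) > 1)
    log_msg("tie at correlation ", formatC(best), " among ",
            paste(winners, collapse = ", "), "; keeping ", winners[1])
  structure(list(sample_id = sample_id,
                 correlations = cors,
                 predicted_tissue = winners[1],
                 method = method),
            class = "get_prediction")
}

#' @export
print.get_prediction <- function(x, ...) {
  cat(sprintf("%s -> %s (%s r = %.4f)\n", x$sample_id, x$predicted_tissue,
              x$method, max(x$correlations)))
  invisible(x)
}

#' Batch nearest-template prediction
#'
#' One prediction per sample column, order preserved. If some signature
#' genes are absent from the test matrix the prediction runs on the present
#' subset provided at least `min_gene_frac` of the signature is covered
#' (warning logs the missing genes); below that it is an error.
#'
#' @param m test expression matrix (genes x samples).
#' @param ts `get_templates`.
#' @param method `"pearson"` or `"spearman"`.
#' @param min_gene_frac minimum fraction of signature genes that must be
#'   present (default 0.9).
#' @return list of `get_prediction`, one per column of `m`.
#' @export
predict_matrix <- function(m, ts, method = c("pearson", "spearman"),
                           min_gene_frac = 0.9) {
  method <- match.arg(method)
  stopifnot(inherits(ts, "get_templates"))
  if (ncol(m) == 0) return(list())
  validate_matrix(m)
  genes <- ts$signature$gene_ids
  present <- intersect(genes, rownames(m))
  if (length(present) < min_gene_frac * length(genes))
    stop(sprintf("only %d of %d signature genes present (< %.0f%%)",
                 length(present), length(genes), 100 * min_gene_frac))
  if (length(present) < length(genes)) {
    missing <- setdiff(genes, present)
    warning("predicting on ", length(present), "/", length(genes),
            " signature genes; missing: ", paste(missing, collapse = ", "))
    keep <- genes %in% present
    ts <- new_templates(ts$vectors[, keep, drop = FALSE],
                        new_signature(genes[keep]), ts$provenance)
    genes <- present <- genes[keep]
  }
  lapply(colnames(m), function(s)
    predict_sample(m[genes, s], ts, method = method, sample_id = s))
}

#' Deviation score: correlation to a named tissue's template
#'
#' The quantity used to measure how far a cancerous, engineered or
#' developing sample has drifted from its expected normal tissue state; low
#' values flag departure from normal physiology.
#'
#' @inheritParams predict_sample
#' @param target_tissue tissue label present in `ts`.
#' @return correlation in `[-1, 1]`.
#' @export
deviation_score <- function(x, ts, target_tissue,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(ts, "get_templates"))
  if (!target_tissue %in% ts$tissues)
    stop("unknown tissue label: ", target_tissue)
  pred <- predict_sample(x, ts, method = method)
  unname(pred$correlations[target_tissue])
}

#' Tabulate predictions as a report data.frame
#'
#' Columns: `sample_id`, `predicted_tissue`, `best_correlation`, then one
#' correlation column per template tissue.
#'
#' @param preds list of `get_prediction`.
#' @return data.frame, one row per prediction.
#' @export
prediction_report <- function(preds) {
  if (length(preds) == 0)
    return(data.frame(sample_id = character(0),
                      predicted_tissue = character(0),
                      best_correlation = numeric(0)))
  stopifnot(all(vapply(preds, inherits, logical(1), "get_prediction")))
  cors <- t(vapply(preds, `[[`, preds[[1]]$correlations, "correlations"))
  data.frame(sample_id = vapply(preds, `[[`, "", "sample_id"),
             predicted_tissue = vapply(preds, `[[`, "", "predicted_tissue"),
             best_correlation = apply(cors, 1, max),
             cors, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname prediction_report
#' @param path output TSV path.
#' @export
write_predictions <- function(preds, path) {
  utils::write.table(prediction_report(preds), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
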