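#' Tissue template sets (GETs)
#'
#' A template set holds one expected signature-gene expression vector per
#' tissue: rows = tissues (lexicographic), cols = signature genes, log2
#' units, plus provenance (training dataset ids and averaging mode).
#'
#' @param vectors numeric matrix, rows = tissues, cols = signature genes.
#' @param signature `get_signature` (or character vector) defining columns.
#' @param provenance free-text record.
#' @return object of class `get_templates`.
#' @export
new_templates <- function(vectors, signature, provenance = "") {
  if (is.character(signature)) signature <- new_signature(signature)
  stopifnot(inherits(signature, "get_signature"))
  if (!is.matrix(vectors) || !is.numeric(vectors))
    stop("template vectors must form a numeric matrix")
  if (!identical(colnames(vectors), signature$gene_ids))
    stop("template columns must match the signature gene order")
  if (is.null(rownames(vectors)) || anyDuplicated(rownames(vectors)))
    stop("tissue labels must be present and unique")
  if (!all(is.finite(vectors))) stop("template vectors contain non-finite values")
  structure(list(signature = signature, tissues = rownames(vectors),
                 vectors = vectors, provenance = provenance),
            class = "get_templates")
}

#' @export
print.get_templates <- function(x, ...) {
  cat(sprintf("Template set: %d tissues x %d signature genes\n",
              length(x$tissues), length(x$signature$gene_ids)))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Build tissue templates from training compendia
#'
#' For each tissue and signature gene the template entry is, by default, the
#' equal-weight two-level mean: first average within (dataset, tissue) over
#' that dataset's samples, then average the per-dataset means. This keeps a
#' large compendium from dominating the template. `mode = "pooled"` averages
#' all samples of a tissue across datasets in one pass instead.
#'
#' Tissues missing from any dataset are dropped with a logged warning
#' (every retained tissue is represented in every dataset). Signature genes
#' absent from a matrix are an error.
#'
#' @param matrices list of training expression matrices.
#' @param meta sample metadata covering every training sample.
#' @param sig `get_signature` (or character vector of gene ids).
#' @param mode `"two_level"` (default) or `"pooled"`.
#' @return `get_templates`, tissues in lexicographic order.
#' @export
build_templates <- function(matrices, meta, sig,
                            mode = c("two_level", "pooled")) {
  mode <- match.arg(mode)
  if (is.character(sig)) sig <- new_signature(sig)
  stopifnot(inherits(sig, "get_signature"))
  if (!is.list(matrices)) matrices <- list(matrices)
  validate_metadata(meta)
  genes <- sig$gene_ids

  subs <- lapply(seq_along(matrices), function(k) {
    m <- matrices[[k]]
    validate_matrix(m)
    absent <- setdiff(genes, rownames(m))
    if (length(absent))
      stop("signature genes absent from dataset ", k, ": ",
           paste(absent, collapse = ", "))
    m[genes, , drop = FALSE]
  })

  tissue_of <- function(m) {
    tt <- meta$tissue[match(colnames(m), meta$sample_id)]
    if (anyNA(tt)) stop("training samples without metadata: ",
                        paste(colnames(m)[is.na(tt)], collapse = ", "))
    tt
  }
  per_ds_tissues <- lapply(subs, function(m) unique(tissue_of(m)))
  tissues <- sort(Reduce(intersect, per_ds_tissues))
  dropped <- setdiff(sort(unique(unlist(per_ds_tissues))), tissues)
  if (length(dropped)) {
    warning("tissues absent from some dataset, dropped: ",
            paste(dropped, collapse = ", "))
    log_msg("build_templates: dropped tissues ", paste(dropped, collapse = ", "))
  }
  if (length(tissues) == 0) stop("no tissue present in every dataset")

  if (mode == "two_level") {
    per_ds <- lapply(subs, function(m) {
      tt <- tissue_of(m)
      vapply(tissues, function(x)
        rowMeans(m[, tt == x, drop = FALSE]), numeric(length(genes)))
    })
    vec <- Reduce(`+`, per_ds) / length(per_ds)  # genes x tissues
  } else {
    all_m <- do.call(cbind, subs)
    tt <- tissue_of(all_m)
    vec <- vapply(tissues, function(x)
      rowMeans(all_m[, tt == x, drop = FALSE]), numeric(length(genes)))
  }
  vectors <- t(vec)
  dimnames(vectors) <- list(tissues, genes)
  prov <- sprintf("build_templates: mode=%s, %d datasets, tissues=%d",
                  mode, length(subs), length(tissues))
  new_templates(vectors, sig, provenance = prov)
}

#' Pairwise Pearson similarity between tissue templates
#'
#' Diagnostic for near-duplicate tissues. Symmetric, unit diagonal, entries
#' in `[-1, 1]`.
#'
#' @param ts `get_templates` with at least two tissues.
#' @return tissue x tissue correlation matrix.
#' @export
template_similarity <- function(ts) {
  stopifnot(inherits(ts, "get_templates"))
  if (length(ts$tissues) < 2) stop("need at least 2 tissues")
  sds <- apply(ts$vectors, 1, stats::sd)
  if (any(sds == 0))
    stop("constant template vector for tissue: ",
         paste(ts$tissues[sds == 0], collapse = ", "))
  stats::cor(t(ts$vectors))
}

#' Read / write template sets
#'
#' TSV: first column `tissue`, remaining columns the signature genes (header
#' row); a JSON sidecar `<path>.json` carries provenance and gene order.
#'
#' @param path TSV path.
#' @return `get_templates` for the reader; `path` invisibly for the writer.
#' @export
read_templates <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "tissue") stop("template TSV must start with a 'tissue' column")
  vectors <- as.matrix(df[, -1, drop = FALSE])
  rownames(vectors) <- df$tissue
  prov <- ""
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    prov <- meta$provenance %||% ""
  }
  new_templates(vectors, new_signature(colnames(vectors)), provenance = prov)
}

#' @rdname read_templates
#' @param ts `get_templates` to serialize.
#' @export
write_templates <- function(ts, path) {
  stopifnot(inherits(ts, "get_templates"))
  df <- data.frame(tissue = ts$tissues,
                   formatC(ts$vectors, format = "g", digits = 17),
                   check.names = FALSE)
  colnames(df) <- c("tissue", ts$signature$gene_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(provenance = ts$provenance,
                            signature = ts$signature$gene_ids,
                            tissues = ts$tissues),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
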