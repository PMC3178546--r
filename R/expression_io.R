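#' Expression matrices and sample metadata
#'
#' An expression matrix in this package is a plain numeric matrix with unique
#' rownames (gene identifiers) and unique colnames (sample identifiers), on
#' log2-intensity scale once [ensure_log2()] has been applied. Gene
#' identifiers are opaque, case-sensitive strings. Sample metadata is a
#' data.frame with columns `sample_id`, `tissue`, `dataset_id` and optional
#' `time` (finite, nonnegative) and `condition`.
#'
#' @name expression-io
NULL

#' Validate an expression matrix
#'
#' Checks the container invariants: numeric matrix, unique gene and sample
#' identifiers, all values finite.
#'
#' @param m numeric matrix, rows = genes, cols = samples.
#' @param allow_na allow missing values (only during loading, before the
#'   reject/impute policy is applied).
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_matrix <- function(m, allow_na = FALSE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (!allow_na && !all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  invisible(m)
}

#' Validate sample metadata against an expression matrix
#'
#' @param meta data.frame with columns `sample_id`, `tissue`, `dataset_id`,
#'   optional `time` and `condition`.
#' @param m optional expression matrix whose samples must all be covered.
#' @return `meta`, invisibly.
#' @export
validate_metadata <- function(meta, m = NULL) {
  need <- c("sample_id", "tissue", "dataset_id")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  if ("time" %in% names(meta)) {
    t <- meta$time[!is.na(meta$time)]
    if (length(t) && (!all(is.finite(t)) || any(t < 0)))
      stop("metadata time values must be finite and nonnegative")
  }
  if (!is.null(m)) {
    absent <- setdiff(colnames(m), meta$sample_id)
    if (length(absent))
      stop("samples without metadata: ", paste(absent, collapse = ", "))
  }
  invisible(meta)
}

#' Read an expression matrix from TSV or GEO series-matrix text
#'
#' The plain `tsv` format is UTF-8, tab-separated, first header cell
#' `gene_id`, remaining header cells sample identifiers, one gene per row.
#' The `series_matrix` dialect ignores `!`-prefixed metadata lines and parses
#' the data table between the `!series_matrix_table_begin` and
#' `!series_matrix_table_end` markers; identifiers may be double-quoted.
#'
#' Duplicate gene rows (multiple probes mapping to one gene) are collapsed by
#' `collapse`: `"max-mean-row"` keeps the probe row with the highest mean
#' expression (common microarray convention), `"mean"` takes the elementwise
#' mean. Missing cells are an error unless `impute = TRUE`, which substitutes
#' the per-gene mean (and errors on all-missing genes).
#'
#' @param path file path.
#' @param format `"tsv"` or `"series_matrix"`.
#' @param collapse duplicate-gene collapse policy.
#' @param impute impute missing values with the per-gene mean instead of
#'   rejecting them.
#' @return numeric expression matrix (genes x samples).
#' @export
read_matrix <- function(path, format = c("tsv", "series_matrix"),
                        collapse = c("max-mean-row", "mean"),
                        impute = FALSE) {
  format <- match.arg(format)
  collapse <- match.arg(collapse)
  if (!file.exists(path)) stop("no such file: ", path)

  lines <- readLines(path, warn = FALSE)
  if (format == "series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) == 1 && length(end) == 1 && begin < end) {
      lines <- lines[(begin + 1):(end - 1)]
    } else {
      # tolerate marker-less dumps: drop all '!' metadata lines
      lines <- lines[!startsWith(lines, "!")]
    }
    lines <- gsub('"', "", lines, fixed = TRUE)
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("parse error: no data rows in ", path)

  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  if (length(header) < 2)
    stop("parse error at line 1: header must hold gene id column plus sample ids")
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))

  body <- cells[-1]
  nfield <- lengths(body)
  if (any(nfield != length(header))) {
    bad <- which(nfield != length(header))[1]
    stop(sprintf("parse error at line %d: expected %d fields, found %d",
                 bad + 1L, length(header), nfield[bad]))
  }
  gene_ids <- vapply(body, `[[`, "", 1L)
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1]), numeric(length(sample_ids))))
  vals <- if (length(sample_ids) == 1L) matrix(vals, nrow = 1L) else vals
  m <- t(vals)
  dimnames(m) <- list(gene_ids, sample_ids)

  na_from_text <- is.na(m) & !vapply(body, function(r)
    any(r[-1] %in% c("NA", "", "null", "NaN")), logical(1))
  if (any(na_from_text)) {
    bad <- which(na_from_text, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }

  if (anyDuplicated(gene_ids)) m <- collapse_duplicates(m, collapse)

  if (anyNA(m)) {
    if (!impute) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("missing value at gene '%s', sample '%s' (set impute=TRUE to impute)",
                   rownames(m)[bad[1]], colnames(m)[bad[2]]))
    }
    m <- impute_gene_means(m)
  }
  validate_matrix(m)
  m
}

collapse_duplicates <- function(m, collapse) {
  ids <- rownames(m)
  if (collapse == "mean") {
    out <- rowsum(m, group = ids, reorder = FALSE) /
      as.vector(table(ids)[unique(ids)])
    rownames(out) <- unique(ids)
    out
  } else { # max-mean-row
    keep <- tapply(seq_len(nrow(m)), ids, function(i) {
      mu <- rowMeans(m[i, , drop = FALSE], na.rm = TRUE)
      i[order(-mu, i)][1]  # ties: first occurrence
    })
    out <- m[sort(unname(keep)), , drop = FALSE]
    out
  }
}

impute_gene_means <- function(m) {
  mu <- rowMeans(m, na.rm = TRUE)
  if (any(!is.finite(mu)))
    stop("cannot impute genes with no observed values: ",
         paste(rownames(m)[!is.finite(mu)], collapse = ", "))
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- mu[idx[, 1]]
  m
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_matrix()] for the `tsv` format (round-trip identity up to
#' numeric printing; full precision is kept with 17 significant digits).
#'
#' @param m expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  validate_matrix(m)
  df <- data.frame(gene_id = rownames(m),
                   formatC(m, format = "g", digits = 17),
                   check.names = FALSE)
  colnames(df) <- c("gene_id", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonize a matrix to log2 scale
#'
#' Microarray compendia mix normalization schemes: RMA emits log2-scale
#' values (essentially never exceeding ~20) while MAS5-style output is
#' linear-scale intensity in the thousands. `mode = "auto"` applies
#' `log2(v + epsilon)` iff the matrix maximum exceeds `linear_threshold`;
#' `"force"` always transforms; `"skip"` never does. The decision taken is
#' logged to stderr.
#'
#' @param m expression matrix.
#' @param mode `"auto"`, `"force"` or `"skip"`.
#' @param epsilon offset added before the log (default 1, avoids log2(0)).
#' @param linear_threshold maximum value above which `auto` fires (default 50).
#' @return transformed (or untouched) matrix.
#' @export
ensure_log2 <- function(m, mode = c("auto", "force", "skip"),
                        epsilon = 1.0, linear_threshold = 50) {
  mode <- match.arg(mode)
  validate_matrix(m)
  fire <- switch(mode,
                 force = TRUE,
                 skip = FALSE,
                 auto = max(m) > linear_threshold)
  if (!fire) {
    log_msg("ensure_log2: mode=", mode, ", no transform applied (max=",
            formatC(max(m), format = "g"), ")")
    return(m)
  }
  if (any(m < 0))
    stop("negative values under log2 transform: data already log-scale or corrupt")
  log_msg("ensure_log2: applying log2(v + ", epsilon, ") (mode=", mode, ")")
  log2(m + epsilon)
}

#' Intersect gene sets across matrices
#'
#' Restricts every matrix to the common genes, in sorted order; needed when
#' compendia come from different chips. Sample columns are untouched.
#'
#' @param matrices list of at least two expression matrices.
#' @return list of matrices over the identical, sorted gene intersection.
#' @export
align_genes <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2)
    stop("align_genes needs a list of at least two matrices")
  lapply(matrices, validate_matrix)
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (length(common) == 0) stop("empty gene intersection across matrices")
  common <- sort(common)
  lapply(matrices, function(m) m[common, , drop = FALSE])
}
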