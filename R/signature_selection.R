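#' Signature objects
#'
#' A signature is the ordered set of gene identifiers that defines the
#' template dimension (56 genes in the original application), together with a
#' free-text provenance record of the selection parameters.
#'
#' @param gene_ids character vector, nonempty, no duplicates.
#' @param provenance character scalar describing how the set was derived.
#' @return object of class `get_signature`.
#' @export
new_signature <- function(gene_ids, provenance = "") {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) == 0) stop("signature must be nonempty")
  if (anyDuplicated(gene_ids)) stop("signature contains duplicate gene ids")
  structure(list(gene_ids = gene_ids, provenance = provenance),
            class = "get_signature")
}

#' @export
print.get_signature <- function(x, ...) {
  cat(sprintf("Gene signature: %d genes\n", length(x$gene_ids)))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  cat(paste(utils::head(x$gene_ids, 10), collapse = ", "),
      if (length(x$gene_ids) > 10) "..." else "", "\n")
  invisible(x)
}

#' @export
length.get_signature <- function(x) length(x$gene_ids)

#' Per-gene coefficient of variation
#'
#' CV = sample standard deviation (n-1 denominator) divided by mean, computed
#' for each gene across all samples of one dataset. CV is undefined when the
#' mean is zero or negative, which can happen on log2 data that crosses zero;
#' such genes are reported as an error and the caller must shift or filter.
#'
#' @param m expression matrix for a single dataset.
#' @param dataset_id optional dataset label recorded in the result.
#' @return data.frame with columns `gene_id`, `cv` and (if given)
#'   `dataset_id`, one row per gene in matrix order.
#' @export
compute_cv <- function(m, dataset_id = NULL) {
  validate_matrix(m)
  if (ncol(m) < 2) stop("compute_cv needs at least 2 samples per gene")
  mu <- rowMeans(m)
  if (any(mu <= 0))
    stop("CV undefined for genes with nonpositive mean: ",
         paste(rownames(m)[mu <= 0], collapse = ", "))
  n <- ncol(m)
  sd_ <- sqrt(rowSums((m - mu)^2) / (n - 1))
  out <- data.frame(gene_id = rownames(m), cv = sd_ / mu,
                    stringsAsFactors = FALSE)
  if (!is.null(dataset_id)) out$dataset_id <- dataset_id
  out
}

#' Top CV fraction
#'
#' Returns the `ceiling(q * G)` genes with largest CV. Ties at the cut are
#' broken by lexicographic gene id (the smaller id is kept), making the
#' selection deterministic.
#'
#' @param cv_table data.frame from [compute_cv()].
#' @param q fraction in (0, 1]; the original pipeline uses 0.025 (top 2.5%).
#' @return character vector of selected gene ids (sorted by descending CV,
#'   ties lexicographic).
#' @export
top_cv_fraction <- function(cv_table, q = 0.025) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q > 1)
    stop("q must lie in (0, 1]")
  if (nrow(cv_table) == 0) stop("empty CV table")
  k <- ceiling(q * nrow(cv_table))
  ord <- order(-cv_table$cv, cv_table$gene_id)
  cv_table$gene_id[ord][seq_len(k)]
}

#' Intersect candidate gene sets across datasets
#'
#' @param sets list of at least two character vectors of gene ids.
#' @return sorted character vector, the exact intersection.
#' @export
intersect_candidates <- function(sets) {
  if (!is.list(sets) || length(sets) < 2)
    stop("intersect_candidates needs at least two sets")
  out <- sort(Reduce(intersect, sets))
  if (length(out) == 0)
    stop("empty candidate intersection; increase the CV fraction q")
  out
}

#' Redundancy removal by correlation clustering
#'
#' Candidate genes with highly similar expression profiles are collapsed:
#' average-linkage hierarchical clustering under the correlation distance
#' d = 1 - Pearson(gene_i, gene_j), tree cut at height `1 - corr_cut`, and
#' one representative kept per cluster. The representative is the member
#' with the highest mean CV across training datasets when `cv` is supplied
#' (keeps the most variable exemplar), otherwise the cluster medoid
#' (smallest summed correlation distance to the other members). All ties
#' break lexicographically by gene id.
#'
#' @param m expression matrix whose columns are the profiles to cluster on
#'   (tissue-averaged or raw samples, the caller's choice).
#' @param candidates character vector of candidate gene ids, subset of
#'   `rownames(m)`.
#' @param corr_cut correlation threshold in (0, 1); genes correlated above it
#'   end up in one cluster. Default 0.85.
#' @param cv optional named numeric vector of mean CVs used to pick cluster
#'   representatives.
#' @return `get_signature` with lexicographically ordered gene ids.
#' @export
remove_redundancy <- function(m, candidates, corr_cut = 0.85, cv = NULL) {
  validate_matrix(m)
  if (!is.numeric(corr_cut) || corr_cut <= 0 || corr_cut >= 1)
    stop("corr_cut must lie in (0, 1)")
  candidates <- as.character(candidates)
  absent <- setdiff(candidates, rownames(m))
  if (length(absent))
    stop("candidates absent from matrix: ", paste(absent, collapse = ", "))
  sub <- m[candidates, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0))
    stop("Pearson undefined for constant candidate genes: ",
         paste(candidates[sds == 0], collapse = ", "))

  if (length(candidates) == 1) {
    cl <- stats::setNames(1L, candidates)
  } else {
    d <- stats::as.dist(1 - stats::cor(t(sub)))
    hc <- stats::hclust(d, method = "average")
    cl <- stats::cutree(hc, h = 1 - corr_cut)
  }

  reps <- vapply(split(names(cl), cl), function(members) {
    members <- sort(members)
    if (length(members) == 1) return(members)
    if (!is.null(cv)) {
      score <- cv[members]
      if (anyNA(score)) stop("cv vector missing entries for: ",
                             paste(members[is.na(score)], collapse = ", "))
      members[order(-score, members)][1]
    } else {
      dm <- 1 - stats::cor(t(sub[members, , drop = FALSE]))
      tot <- rowSums(dm)
      members[order(tot, members)][1]
    }
  }, character(1))

  prov <- sprintf("remove_redundancy: corr_cut=%g, %d candidates -> %d representatives (%s)",
                  corr_cut, length(candidates), length(reps),
                  if (is.null(cv)) "medoid rule" else "max mean-CV rule")
  log_msg(prov)
  new_signature(sort(unname(reps)), provenance = prov)
}

#' Full signature-selection pipeline
#'
#' Chains per-dataset CV ranking, cross-dataset intersection and redundancy
#' removal: the derivation route for a compact tissue-classifying signature
#' when no externally supplied gene list is available.
#'
#' Clustering for redundancy removal runs on tissue-averaged profiles of the
#' concatenated training data by default (`profile = "tissue_mean"`), or on
#' all raw sample columns (`profile = "samples"`).
#'
#' @param matrices list of training expression matrices (one per dataset).
#' @param meta sample metadata covering every training sample.
#' @param q top-CV fraction per dataset (default 0.025).
#' @param corr_cut redundancy correlation threshold (default 0.85).
#' @param profile clustering profile type.
#' @return `get_signature`.
#' @export
select_signature <- function(matrices, meta, q = 0.025, corr_cut = 0.85,
                             profile = c("tissue_mean", "samples")) {
  profile <- match.arg(profile)
  validate_metadata(meta)
  matrices <- align_genes(matrices)
  ids <- names(matrices) %||% paste0("dataset", seq_along(matrices))
  cvs <- Map(compute_cv, matrices, ids)
  sets <- lapply(cvs, top_cv_fraction, q = q)
  candidates <- intersect_candidates(sets)
  log_msg("select_signature: ", length(candidates),
          " candidates after intersecting ", length(sets), " datasets")

  combined <- do.call(cbind, matrices)
  cluster_input <- if (profile == "tissue_mean") {
    tiss <- meta$tissue[match(colnames(combined), meta$sample_id)]
    if (anyNA(tiss)) stop("training samples without metadata tissue label")
    prof <- vapply(sort(unique(tiss)), function(tt)
      rowMeans(combined[, tiss == tt, drop = FALSE]), numeric(nrow(combined)))
    prof
  } else combined

  cv_all <- do.call(rbind, cvs)
  mean_cv <- tapply(cv_all$cv, cv_all$gene_id, mean)
  sig <- remove_redundancy(cluster_input, candidates, corr_cut = corr_cut,
                           cv = mean_cv)
  sig$provenance <- sprintf(
    "select_signature: q=%g, corr_cut=%g, profile=%s, datasets=%s; %s",
    q, corr_cut, profile, paste(ids, collapse = ","), sig$provenance)
  sig
}

#' Read / write signature files
#'
#' One gene id per line; `#`-prefixed lines carry the provenance header.
#'
#' @param path file path.
#' @return `get_signature` for the reader; `path` invisibly for the writer.
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  prov <- sub("^#\\s*", "", lines[startsWith(lines, "#")])
  genes <- trimws(lines[!startsWith(lines, "#")])
  genes <- genes[nzchar(genes)]
  new_signature(genes, provenance = paste(prov, collapse = "; "))
}

#' @rdname read_signature
#' @param sig `get_signature` to serialize.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "get_signature"))
  writeLines(c(paste0("# ", sig$provenance), sig$gene_ids), path)
  invisible(path)
}
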