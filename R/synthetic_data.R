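#' Simulation configuration
#'
#' The stated world for synthetic compendia: multiple datasets sharing
#' tissue-specific mean profiles for a minority of high-variance signature
#' genes amid a low-variance background, with per-(gene, dataset) batch
#' offsets and per-cell Gaussian noise, all on log2 scale.
#'
#' Defaults mirror the training design the method was built for: 24 tissues
#' in 3 datasets with one sample per (tissue, dataset) — a 24 x 3 = 72
#' column compendium — 5000 genes of which 60 are planted signature-like,
#' a tissue-effect sd of 2 log2 units (strong tissue specificity), batch
#' offsets of 0.5 and residual noise of 0.5 (= tissue effect / 4), around a
#' baseline mean of 8 (typical RMA mid-range intensity).
#'
#' @param n_tissues,n_genes,n_signature,n_datasets,samples_per_tissue_per_dataset
#'   design counts, all >= 1, `n_signature <= n_genes`.
#' @param tissue_effect_sd,batch_sd,noise_sd,baseline_mean model parameters
#'   in log2 units; sds >= 0.
#' @param seed master integer seed; every draw flows from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_tissues = 24, n_genes = 5000, n_signature = 60,
                       n_datasets = 3, samples_per_tissue_per_dataset = 1,
                       tissue_effect_sd = 2, batch_sd = 0.5, noise_sd = 0.5,
                       baseline_mean = 8, seed = 1) {
  cfg <- list(n_tissues = n_tissues, n_genes = n_genes,
              n_signature = n_signature, n_datasets = n_datasets,
              samples_per_tissue_per_dataset = samples_per_tissue_per_dataset,
              tissue_effect_sd = tissue_effect_sd, batch_sd = batch_sd,
              noise_sd = noise_sd, baseline_mean = baseline_mean,
              seed = seed)
  counts <- cfg[c("n_tissues", "n_genes", "n_signature", "n_datasets",
                  "samples_per_tissue_per_dataset")]
  if (any(unlist(counts) < 1) || any(unlist(counts) != floor(unlist(counts))))
    stop("all design counts must be integers >= 1")
  if (cfg$n_signature > cfg$n_genes) stop("n_signature must be <= n_genes")
  sds <- unlist(cfg[c("tissue_effect_sd", "batch_sd", "noise_sd")])
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single finite number")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic multi-dataset compendium
#'
#' Planted model, per cell of dataset k, tissue t, gene g:
#' \deqn{y = b_g + e_{g,t} \cdot [g \in signature] + d_{g,k} + \epsilon}
#' with baseline `b_g ~ N(baseline_mean, 1)`, tissue effect
#' `e_{g,t} ~ N(0, tissue_effect_sd)` fixed across datasets (the shared
#' biology), batch offset `d_{g,k} ~ N(0, batch_sd)` per (gene, dataset),
#' and cell noise `~ N(0, noise_sd)`. Fully reproducible from `cfg$seed`;
#' each stage draws from its own derived stream.
#'
#' @param cfg `sim_config`.
#' @return list with `matrices` (one expression matrix per dataset, named
#'   `ds1..dsK`), `meta` (sample metadata), and `truth` (planted signature
#'   gene ids, tissue labels, and the `expected` tissue-profile matrix
#'   `b_g + e_{g,t}` over signature genes, tissues x genes).
#' @export
generate_compendium <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  tissues <- sprintf("tissue%02d", seq_len(cfg$n_tissues))
  sig_genes <- genes[seq_len(cfg$n_signature)]

  with_seed(derive_seed(cfg$seed, "baseline"), {
    b <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, 1)
  })
  with_seed(derive_seed(cfg$seed, "tissue_effect"), {
    e <- matrix(stats::rnorm(cfg$n_signature * cfg$n_tissues,
                             0, cfg$tissue_effect_sd),
                nrow = cfg$n_signature,
                dimnames = list(sig_genes, tissues))
  })
  with_seed(derive_seed(cfg$seed, "batch"), {
    d <- array(stats::rnorm(cfg$n_genes * cfg$n_datasets, 0, cfg$batch_sd),
               dim = c(cfg$n_genes, cfg$n_datasets))
  })

  spt <- cfg$samples_per_tissue_per_dataset
  matrices <- lapply(seq_len(cfg$n_datasets), function(k) {
    ncols <- cfg$n_tissues * spt
    mean_mat <- matrix(b + d[, k], nrow = cfg$n_genes, ncol = ncols)
    tiss_idx <- rep(seq_len(cfg$n_tissues), each = spt)
    mean_mat[match(sig_genes, genes), ] <-
      mean_mat[match(sig_genes, genes), ] + e[, tiss_idx]
    with_seed(derive_seed(cfg$seed, paste0("noise_ds", k)), {
      noise <- matrix(stats::rnorm(cfg$n_genes * ncols, 0, cfg$noise_sd),
                      nrow = cfg$n_genes)
    })
    m <- mean_mat + noise
    dimnames(m) <- list(genes,
                        sprintf("ds%d_%s_r%d", k, tissues[tiss_idx],
                                rep(seq_len(spt), times = cfg$n_tissues)))
    m
  })
  names(matrices) <- paste0("ds", seq_len(cfg$n_datasets))

  meta <- do.call(rbind, lapply(seq_len(cfg$n_datasets), function(k) {
    data.frame(sample_id = colnames(matrices[[k]]),
               tissue = rep(tissues, each = spt),
               dataset_id = paste0("ds", k),
               stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL

  expected <- t(e) + matrix(b[match(sig_genes, genes)],
                            nrow = cfg$n_tissues, ncol = cfg$n_signature,
                            byrow = TRUE)
  dimnames(expected) <- list(tissues, sig_genes)

  list(matrices = matrices, meta = meta,
       truth = list(signature_genes = sig_genes, tissues = tissues,
                    expected = expected, config = cfg))
}

#' Synthetic developmental trajectory
#'
#' Samples interpolate from a progenitor profile toward the target tissue's
#' adult template: at time t the mean is
#' `(1 - w(t)) * progenitor + w(t) * template(target)` with Gaussian noise
#' added per gene. `w(t) = t / max(times)` (linear mixing) by default;
#' `mixing = "logistic"` uses a sigmoid in t centred at `max(times)/2`.
#'
#' @param ts `get_templates`.
#' @param target_tissue tissue whose template is the adult endpoint.
#' @param progenitor numeric vector aligned to `ts$signature` (same length
#'   and order, or named covering it).
#' @param times nonnegative sampling times.
#' @param noise_sd per-gene Gaussian noise sd (log2 units).
#' @param seed integer seed.
#' @param mixing `"linear"` or `"logistic"`.
#' @return list with `matrix` (signature genes x samples) and `meta`
#'   (sample metadata including `time`).
#' @export
generate_trajectory <- function(ts, target_tissue, progenitor, times,
                                noise_sd = 0, seed = 1,
                                mixing = c("linear", "logistic")) {
  mixing <- match.arg(mixing)
  stopifnot(inherits(ts, "get_templates"))
  if (!target_tissue %in% ts$tissues)
    stop("unknown tissue label: ", target_tissue)
  if (length(times) == 0) stop("times must be nonempty")
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and nonnegative")
  genes <- ts$signature$gene_ids
  if (!is.null(names(progenitor))) {
    absent <- setdiff(genes, names(progenitor))
    if (length(absent))
      stop("progenitor missing signature genes: ",
           paste(absent, collapse = ", "))
    progenitor <- progenitor[genes]
  } else if (length(progenitor) != length(genes)) {
    stop("progenitor vector not aligned to the signature")
  }
  adult <- ts$vectors[target_tissue, ]
  tmax <- max(times)
  w <- if (tmax == 0) rep(0, length(times))
       else if (mixing == "linear") times / tmax
       else stats::plogis((times - tmax / 2) / (tmax / 8))

  mean_mat <- outer(progenitor, 1 - w) + outer(adult, w)
  with_seed(derive_seed(seed, "trajectory"), {
    noise <- matrix(stats::rnorm(length(mean_mat), 0, noise_sd),
                    nrow = length(genes))
  })
  m <- mean_mat + noise
  dimnames(m) <- list(genes, sprintf("t%03d_s%02d", round(times),
                                     seq_along(times)))
  meta <- data.frame(sample_id = colnames(m),
                     tissue = target_tissue,
                     dataset_id = "trajectory",
                     time = times,
                     stringsAsFactors = FALSE)
  list(matrix = m, meta = meta)
}

#' Synthetic cancer-like perturbation of a tissue template
#'
#' Each sample is the tissue template with a random subset of
#' `ceiling(fraction * |signature|)` genes shifted by `N(0, shift_sd)`, plus
#' per-gene baseline noise: a stand-in for the multi-gene expression
#' derangement that pulls a tumour's deviation score below normal.
#'
#' @param ts `get_templates`.
#' @param tissue template tissue to perturb.
#' @param fraction fraction of signature genes perturbed, in (0, 1].
#' @param shift_sd sd of the per-gene shifts (log2 units).
#' @param n number of samples.
#' @param seed integer seed.
#' @param noise_sd baseline per-cell noise sd (default 0.1).
#' @return expression matrix (signature genes x n samples).
#' @export
generate_perturbed <- function(ts, tissue, fraction, shift_sd, n, seed = 1,
                               noise_sd = 0.1) {
  stopifnot(inherits(ts, "get_templates"))
  if (!tissue %in% ts$tissues) stop("unknown tissue label: ", tissue)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  if (shift_sd < 0 || noise_sd < 0) stop("sds must be >= 0")
  if (n < 1) stop("n must be >= 1")
  genes <- ts$signature$gene_ids
  template <- ts$vectors[tissue, ]
  k <- ceiling(fraction * length(genes))
  with_seed(derive_seed(seed, "perturb"), {
    m <- vapply(seq_len(n), function(i) {
      hit <- sample.int(length(genes), k)
      x <- template + stats::rnorm(length(genes), 0, noise_sd)
      x[hit] <- x[hit] + stats::rnorm(k, 0, shift_sd)
      x
    }, numeric(length(genes)))
  })
  dimnames(m) <- list(genes, sprintf("%s_pert%03d", tissue, seq_len(n)))
  m
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
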