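test_that("compute_cv matches the n-1 definition", {
  m <- rbind(g1 = c(5, 5, 5, 5), g2 = c(1, 3, 1, 3))
  colnames(m) <- paste0("s", 1:4)
  cv <- compute_cv(m)
  expect_equal(cv$cv[cv$gene_id == "g1"], 0)          # constant gene
  two <- rbind(gA = c(1, 3)); colnames(two) <- c("s1", "s2")
  cv2 <- compute_cv(two)
  expect_equal(cv2$cv, sqrt(2) / 2)                   # sd sqrt(2), mean 2
  # scale invariance
  expect_equal(compute_cv(two * 10)$cv, cv2$cv)
  # dataset label recorded
  expect_identical(compute_cv(two, dataset_id = "ds1")$dataset_id, "ds1")
  # nonpositive mean is an error naming the gene
  neg <- rbind(gBad = c(-2, 2)); colnames(neg) <- c("s1", "s2")
  expect_error(compute_cv(neg), "gBad")
})

test_that("top_cv_fraction takes ceil(q*G) genes with deterministic ties", {
  set.seed(2)
  tab <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    cv = runif(200), stringsAsFactors = FALSE)
  top <- top_cv_fraction(tab, 0.025)
  expect_length(top, 5)                               # ceil(0.025*200)
  expect_setequal(top, tab$gene_id[order(-tab$cv)][1:5])
  expect_length(top_cv_fraction(tab, 1), 200)         # q=1 keeps all
  # boundary tie: lexicographically smaller id kept
  tie <- data.frame(gene_id = c("gB", "gA", "gC", "gD"),
                    cv = c(0.5, 0.5, 0.9, 0.1))
  expect_identical(top_cv_fraction(tie, 0.5), c("gC", "gA"))
  expect_error(top_cv_fraction(tab, 0), "q must")
  expect_error(top_cv_fraction(tab, 1.2), "q must")
})

test_that("intersect_candidates is an exact intersection", {
  expect_identical(intersect_candidates(list(c("A", "B", "C"),
                                             c("B", "C", "D"),
                                             c("B", "C", "E"))),
                   c("B", "C"))
  s <- c("X", "Y")
  expect_identical(intersect_candidates(list(s, s)), sort(s))
  expect_error(intersect_candidates(list(c("A"), c("B"))), "empty")
  expect_error(intersect_candidates(list(c("A"))), "at least two")
})

test_that("remove_redundancy collapses correlated genes at the cut", {
  # two perfect duplicates -> one representative
  m <- rbind(gA = c(1, 2, 3, 4), gB = c(2, 4, 6, 8), gC = c(4, 1, 5, 2))
  colnames(m) <- paste0("t", 1:4)
  sig <- suppressMessages(remove_redundancy(m, rownames(m), corr_cut = 0.9))
  expect_length(sig$gene_ids, 2)
  expect_true("gC" %in% sig$gene_ids)
  expect_length(intersect(c("gA", "gB"), sig$gene_ids), 1)

  # all pairwise correlations below the cut -> everything retained
  set.seed(9)
  mlow <- matrix(rnorm(5 * 40), 5, 40,
                 dimnames = list(paste0("g", 1:5), paste0("t", 1:40)))
  stopifnot(max(abs(cor(t(mlow))[upper.tri(diag(5))])) < 0.6)
  sig2 <- suppressMessages(remove_redundancy(mlow, rownames(mlow), 0.85))
  expect_setequal(sig2$gene_ids, rownames(mlow))

  # constant candidate -> error naming it
  mc <- rbind(gA = c(1, 2, 3), gFlat = c(7, 7, 7))
  colnames(mc) <- paste0("t", 1:3)
  expect_error(suppressMessages(remove_redundancy(mc, rownames(mc), 0.8)),
               "gFlat")
})

test_that("planted correlated pairs reduce to one representative each", {
  # 3 pairs: within-pair r ~ 1, between-pair r ~ 0
  set.seed(21)
  base <- matrix(rnorm(3 * 30), 3, 30)
  m <- rbind(base[1, ], base[1, ] + rnorm(30, 0, 0.01),
             base[2, ], base[2, ] + rnorm(30, 0, 0.01),
             base[3, ], base[3, ] + rnorm(30, 0, 0.01))
  dimnames(m) <- list(paste0("g", 1:6), paste0("t", 1:30))

  # brute-force oracle: connected components of the r >= corr_cut graph
  adj <- abs(cor(t(m))) >= 0.85
  comp <- rep(NA_integer_, 6)
  cid <- 0L
  for (i in 1:6) if (is.na(comp[i])) {
    cid <- cid + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      stack <- c(stack, which(adj[v, ] & is.na(comp)))
    }
  }
  expect_identical(max(comp), 3L)  # the construction really makes 3 clusters

  sig <- suppressMessages(remove_redundancy(m, rownames(m), corr_cut = 0.85))
  expect_length(sig$gene_ids, 3)
  for (k in 1:3)  # exactly one representative per planted pair
    expect_length(intersect(sig$gene_ids, paste0("g", c(2 * k - 1, 2 * k))), 1)
})

test_that("cv-based representative choice keeps the most variable member", {
  m <- rbind(gA = c(1, 2, 3, 4), gB = c(2, 4, 6, 8))
  colnames(m) <- paste0("t", 1:4)
  cv <- c(gA = 0.2, gB = 0.9)
  sig <- suppressMessages(remove_redundancy(m, rownames(m), 0.9, cv = cv))
  expect_identical(sig$gene_ids, "gB")
})

test_that("representative count is non-increasing as corr_cut is lowered", {
  set.seed(33)
  m <- matrix(rnorm(12 * 20), 12, 20,
              dimnames = list(sprintf("g%02d", 1:12), paste0("t", 1:20)))
  cuts <- c(0.95, 0.8, 0.6, 0.4, 0.2)
  sizes <- vapply(cuts, function(cc)
    length(suppressMessages(remove_redundancy(m, rownames(m), cc))$gene_ids),
    0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("selection is invariant to sample and dataset order", {
  sim <- generate_compendium(sim_config(n_tissues = 6, n_genes = 300,
                                        n_signature = 15, seed = 14))
  sig1 <- suppressMessages(select_signature(sim$matrices, sim$meta))
  # permute datasets
  sig2 <- suppressMessages(select_signature(rev(sim$matrices), sim$meta))
  expect_identical(sig1$gene_ids, sig2$gene_ids)
  # permute sample columns within each dataset
  set.seed(1)
  shuf <- lapply(sim$matrices, function(m) m[, sample(ncol(m)), drop = FALSE])
  sig3 <- suppressMessages(select_signature(shuf, sim$meta))
  expect_identical(sig1$gene_ids, sig3$gene_ids)
})

test_that("signature files round-trip with provenance", {
  sig <- new_signature(c("gB", "gA"), provenance = "q=0.025, corr_cut=0.85")
  p <- tempfile(fileext = ".txt")
  write_signature(sig, p)
  back <- read_signature(p)
  expect_identical(back$gene_ids, sig$gene_ids)
  expect_match(back$provenance, "corr_cut=0.85")
  expect_error(new_signature(character(0)), "nonempty")
  expect_error(new_signature(c("a", "a")), "duplicate")
})
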