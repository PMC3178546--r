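test_that("read_matrix parses plain TSV and round-trips through write_matrix", {
  p <- write_tsv_fixture(c("gene_id\ts1\ts2",
                           "gA\t1.5\t2.5",
                           "gB\t3\t4",
                           "gC\t5.25\t6"))
  m <- read_matrix(p)
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(rownames(m), c("gA", "gB", "gC"))
  expect_identical(colnames(m), c("s1", "s2"))
  expect_equal(m["gC", "s1"], 5.25)

  # round-trip identity
  p2 <- tempfile(fileext = ".tsv")
  write_matrix(m, p2)
  expect_equal(read_matrix(p2), m)

  # full-precision round trip on irrational values
  set.seed(3)
  m2 <- make_matrix(4, 3, rnorm(12, 8, 2))
  write_matrix(m2, p2)
  expect_equal(read_matrix(p2), m2, tolerance = 1e-15)
})

test_that("duplicate gene rows are collapsed per policy", {
  p <- write_tsv_fixture(c("gene_id\ts1\ts2",
                           "gA\t1\t2",
                           "gA\t3\t4",
                           "gB\t10\t10"))
  # mean policy: elementwise mean, hand-checked
  m_mean <- read_matrix(p, collapse = "mean")
  expect_equal(unname(m_mean["gA", ]), c(2, 3))
  # max-mean-row keeps the probe with the higher mean (row [3,4])
  m_max <- read_matrix(p, collapse = "max-mean-row")
  expect_equal(unname(m_max["gA", ]), c(3, 4))
  expect_identical(nrow(m_max), 2L)
})

test_that("series_matrix dialect skips metadata lines and strips quotes", {
  p <- write_tsv_fixture(c(
    "!Series_title\t\"toy\"",
    "!Series_platform\t\"GPL96\"",
    "!Sample_source\t\"a\"\t\"b\"\t\"c\"",
    "!extra\tx",
    "!another\ty",
    "!series_matrix_table_begin",
    "\"ID_REF\"\t\"s1\"\t\"s2\"\t\"s3\"",
    "\"gA\"\t1\t2\t3",
    "\"gB\"\t4\t5\t6",
    "\"gC\"\t7\t8\t9",
    "\"gD\"\t10\t11\t12",
    "!series_matrix_table_end"))
  m <- read_matrix(p, format = "series_matrix")
  expect_identical(dim(m), c(4L, 3L))
  expect_identical(rownames(m), c("gA", "gB", "gC", "gD"))
  expect_equal(unname(m["gD", ]), c(10, 11, 12))
})

test_that("read_matrix rejects malformed input with located errors", {
  expect_error(read_matrix(tempfile()), "no such file")
  p <- write_tsv_fixture(c("gene_id\ts1\ts1", "gA\t1\t2"))
  expect_error(read_matrix(p), "duplicate sample ids")
  p <- write_tsv_fixture(c("gene_id\ts1\ts2", "gA\t1\tabc"))
  expect_error(read_matrix(p), "non-numeric cell.*gA.*s2")
  p <- write_tsv_fixture(c("gene_id\ts1\ts2", "gA\t1"))
  expect_error(read_matrix(p), "parse error at line 2")
})

test_that("missing values are rejected by default, imputed on request", {
  p <- write_tsv_fixture(c("gene_id\ts1\ts2\ts3",
                           "gA\t1\tNA\t3",
                           "gB\t4\t5\t6"))
  expect_error(read_matrix(p), "missing value.*gA")
  m <- read_matrix(p, impute = TRUE)
  expect_equal(unname(m["gA", "s2"]), 2)  # per-gene mean of 1, 3
})

test_that("ensure_log2 applies the linear-scale heuristic", {
  m <- make_matrix(3, 2, c(2, 4, 8, 16, 18, 20))
  # all values <= 20: auto does not fire
  expect_identical(suppressMessages(ensure_log2(m, "auto")), m)
  # force with epsilon 0: log2 identity
  expect_equal(unname(suppressMessages(
    ensure_log2(m, "force", epsilon = 0))["g01", "s01"]), 1)
  m1024 <- make_matrix(1, 2, c(1024, 1024))
  expect_equal(unname(suppressMessages(
    ensure_log2(m1024, "force", epsilon = 0))[1, 1]), 10)
  # auto fires on MAS5-like scale; recomputation oracle per cell
  big <- make_matrix(3, 2, c(10, 200, 3000, 20000, 50, 7))
  out <- suppressMessages(ensure_log2(big, "auto"))
  expect_equal(out, log2(big + 1))
  expect_equal(max(out), log2(20000 + 1))
  # negatives under force are an error
  neg <- make_matrix(2, 2, c(-1, 2, 3, 4))
  expect_error(suppressMessages(ensure_log2(neg, "force")), "negative")
})

test_that("ensure_log2 force is monotone over cells", {
  set.seed(11)
  for (i in 1:25) {
    m <- make_matrix(6, 4, runif(24, 0, 5000))
    out <- suppressMessages(ensure_log2(m, "force"))
    expect_identical(order(m), order(out))
  }
})

test_that("align_genes intersects and sorts gene sets", {
  a <- make_matrix(3, 2); rownames(a) <- c("A", "B", "C")
  b <- make_matrix(3, 2); rownames(b) <- c("B", "C", "D")
  out <- align_genes(list(a, b))
  expect_identical(rownames(out[[1]]), c("B", "C"))
  expect_identical(rownames(out[[2]]), c("B", "C"))
  expect_identical(colnames(out[[1]]), colnames(a))

  # idempotence on identical inputs (up to row sort)
  out2 <- align_genes(list(a, a))
  expect_equal(out2[[1]], a[sort(rownames(a)), ])

  # three inputs sharing exactly one gene -> 1-row matrices; brute-force
  # intersection oracle
  cset <- make_matrix(3, 2); rownames(cset) <- c("C", "X", "Y")
  oracle <- Reduce(intersect, list(rownames(a), rownames(b), rownames(cset)))
  expect_identical(oracle, "C")
  out3 <- align_genes(list(a, b, cset))
  expect_true(all(vapply(out3, nrow, 0L) == 1L))
  expect_true(all(vapply(out3, rownames, "") == "C"))

  # disjoint -> error
  d <- make_matrix(2, 2); rownames(d) <- c("Z1", "Z2")
  expect_error(align_genes(list(a, d)), "empty gene intersection")
  expect_error(align_genes(list(a)), "at least two")
})

test_that("align_genes outputs are always a subset of every input (property)", {
  set.seed(5)
  for (i in 1:30) {
    pool <- sprintf("g%02d", 1:15)
    ms <- lapply(1:3, function(k) {
      g <- sort(sample(pool, sample(8:14, 1)))
      m <- matrix(rnorm(length(g) * 3), length(g), 3,
                  dimnames = list(g, paste0("s", 1:3)))
      m
    })
    common <- Reduce(intersect, lapply(ms, rownames))
    if (length(common) == 0) next
    out <- align_genes(ms)
    glists <- lapply(out, rownames)
    expect_true(all(vapply(glists[-1], identical, TRUE, glists[[1]])))
    for (k in 1:3) expect_true(all(glists[[1]] %in% rownames(ms[[k]])))
  }
})
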