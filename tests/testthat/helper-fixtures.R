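# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# genes x samples matrix with deterministic dimnames
make_matrix <- function(nr, nc, values = NULL, prefix = "g") {
  m <- matrix(if (is.null(values)) seq_len(nr * nc) else values, nr, nc)
  dimnames(m) <- list(sprintf("%s%02d", prefix, seq_len(nr)),
                      sprintf("s%02d", seq_len(nc)))
  m
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# A small deterministic template set: `nt` tissues over `ng` genes.
make_templates <- function(nt = 3, ng = 5, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(nt * ng, 8, 2), nt, ng)
  dimnames(v) <- list(sprintf("tissue%02d", seq_len(nt)),
                      sprintf("g%02d", seq_len(ng)))
  new_templates(v, new_signature(colnames(v)))
}

# Independent Pearson oracle, textbook formula
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `expr` under a fixed seed without disturbing the caller's stream
with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
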