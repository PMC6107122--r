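# Small builders shared across tests. All synthetic data is generated in
# code; nothing is read from disk except the packaged case-study fixture.

# geno_matrix from a list of "a/b" strings per sample: list(S1 = c("150/154", ...))
geno_from_strings <- function(calls, loci = NULL, pop = NULL) {
  n <- length(calls)
  L <- length(calls[[1]])
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  a1 <- a2 <- matrix(NA_integer_, n, L, dimnames = list(names(calls), loci))
  for (i in seq_len(n)) {
    for (j in seq_len(L)) {
      cell <- calls[[i]][j]
      if (!is.na(cell) && nzchar(cell)) {
        ab <- as.integer(strsplit(cell, "/")[[1]])
        a1[i, j] <- ab[1]; a2[i, j] <- ab[2]
      }
    }
  }
  geno_matrix(a1, a2, pop = pop)
}

# allele_freq_table from explicit per-locus count matrices (pops x alleles)
freq_table_from_counts <- function(counts) {
  pops <- rownames(counts[[1]])
  loci <- names(counts)
  freq <- lapply(counts, function(cnt) {
    n <- rowSums(cnt)
    fr <- cnt / n
    fr[n == 0, ] <- NA_real_
    fr
  })
  n <- vapply(counts, rowSums, numeric(length(pops)))
  if (length(pops) == 1) n <- matrix(n, 1, dimnames = list(pops, loci))
  colnames(n) <- loci
  structure(list(pops = pops, loci = loci, freq = freq,
                 counts = lapply(counts, function(x) {
                   storage.mode(x) <- "integer"; x
                 }), n = n), class = "allele_freq_table")
}

# random geno_matrix for round-trip property tests
random_geno <- function(n, L, seed, miss_rate = 0.1, with_pop = TRUE) {
  set.seed(seed)
  a1 <- matrix(sample(seq(100L, 140L, 2L), n * L, TRUE), n, L)
  a2 <- matrix(sample(seq(100L, 140L, 2L), n * L, TRUE), n, L)
  miss <- matrix(runif(n * L) < miss_rate, n, L)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  rownames(a1) <- rownames(a2) <- paste0("ind", seq_len(n))
  colnames(a1) <- colnames(a2) <- paste0("loc", seq_len(L))
  pop <- if (with_pop) sample(c("north", "south"), n, TRUE) else NULL
  geno_matrix(a1, a2, pop = pop)
}

expect_geno_equal <- function(x, y) {
  expect_identical(unname(x$a1), unname(y$a1))
  expect_identical(unname(x$a2), unname(y$a2))
  expect_identical(sample_ids(x), sample_ids(y))
  expect_identical(locus_names(x), locus_names(y))
}
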