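test_that("frequency assignment reproduces the one-locus hand computation", {
  # query AA; p_A = 0.5 in pop1, 0.9 in pop2 -> scores 0.25/1.06, 0.81/1.06
  tab <- freq_table_from_counts(list(
    l1 = matrix(c(50, 50, 90, 10), 2, 2, byrow = TRUE,
                dimnames = list(c("pop1", "pop2"), c("100", "102")))))
  q <- geno_from_strings(list(q1 = "100/100"), loci = "l1")
  sc <- assign_frequency(q, tab)
  expect_equal(unname(sc$scores[1, "pop1"]), 0.25 / 1.06, tolerance = 1e-9)
  expect_equal(unname(sc$scores[1, "pop2"]), 0.81 / 1.06, tolerance = 1e-9)
  expect_equal(unname(sum(sc$scores)), 1)
  expect_equal(unname(sc$loglik[1, "pop1"]), log(0.25))
})

test_that("unobserved alleles are floored and keep likelihoods finite", {
  tab <- freq_table_from_counts(list(
    l1 = matrix(c(100, 0, 50, 50), 2, 2, byrow = TRUE,
                dimnames = list(c("pop1", "pop2"), c("100", "102")))))
  q <- geno_from_strings(list(q1 = "102/102"), loci = "l1")
  sc <- assign_frequency(q, tab, missing_allele_freq = 0.01)
  expect_true(all(is.finite(sc$loglik)))
  # pop1: p(102) floored to 0.01 then renormalized over {0.99..., 0.01}
  expect_equal(unname(sc$loglik[1, "pop1"]), log((0.01 / 1.01)^2))
  # a single candidate population normalizes to 1
  tab1 <- freq_table_from_counts(list(
    l1 = matrix(c(50, 50), 1, 2, dimnames = list("only", c("100", "102")))))
  expect_equal(unname(assign_frequency(q, tab1)$scores[1, 1]), 1)
  # fully missing query errors
  qna <- geno_matrix(matrix(NA_integer_, 1, 1, dimnames = list("q", "l1")),
                     matrix(NA_integer_, 1, 1))
  expect_error(assign_frequency(qna, tab), "no genotyped locus")
})

test_that("Bayesian assignment matches the Dirichlet closed forms", {
  # pop1 holds one AA individual, pop2 one BB: k = 2 alleles dataset-wide
  tab <- freq_table_from_counts(list(
    l1 = matrix(c(2, 0, 0, 2), 2, 2, byrow = TRUE,
                dimnames = list(c("pop1", "pop2"), c("100", "102")))))
  q <- geno_from_strings(list(q1 = "100/100"), loci = "l1")
  sc <- assign_bayesian(q, tab)
  expect_equal(unname(exp(sc$loglik[1, "pop1"])), 2.5 * 3.5 / 12,
               tolerance = 1e-12)
  expect_equal(unname(exp(sc$loglik[1, "pop2"])), 0.5 * 1.5 / 12,
               tolerance = 1e-12)
  expect_equal(unname(sum(sc$scores[1, ])), 1)

  # empty reference population: prior predictive for a heterozygote is 1/4
  tab0 <- freq_table_from_counts(list(
    l1 = matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE,
                dimnames = list(c("empty", "seen"), c("100", "102")))))
  qh <- geno_from_strings(list(q1 = "100/102"), loci = "l1")
  sc0 <- assign_bayesian(qh, tab0)
  expect_equal(unname(exp(sc0$loglik[1, "empty"])),
               2 * 0.5 * 0.5 / 2, tolerance = 1e-12)
})

test_that("Bayesian closed form agrees with Monte-Carlo Dirichlet integration", {
  # P(query AA | counts) = E_p[p_A^2], p ~ Dirichlet(1/k + counts)
  cnt <- matrix(c(7, 3), 1, 2, dimnames = list("p1", c("100", "102")))
  tab <- freq_table_from_counts(list(l1 = cnt))
  q <- geno_from_strings(list(q1 = "100/100"), loci = "l1")
  sc <- assign_bayesian(q, tab)
  set.seed(99)
  draws <- matrix(rgamma(2e5, rep(c(7.5, 3.5), each = 1e5)), ncol = 2)
  pa <- draws[, 1] / rowSums(draws)
  expect_equal(unname(exp(sc$loglik[1, 1])), mean(pa^2), tolerance = 0.002)
})

test_that("frequency and Bayesian scores converge with deep reference data", {
  cfg <- sim_config(seed = 3, fst = 0.2, n_per_pop = 5000, n_queries = 9)
  ref <- simulate_reference(cfg)
  qs <- simulate_queries(cfg, ref)
  tab <- allele_frequencies(ref$genotypes)
  f <- assign_frequency(qs$genotypes, tab)
  b <- assign_bayesian(qs$genotypes, tab)
  expect_lt(max(abs(f$scores - b$scores)), 0.01)
})

test_that("DAPC separates fixed populations and flags zero within-group variance", {
  calls <- c(lapply(1:6, function(i) rep("100/100", 4)),
             lapply(1:6, function(i) rep("200/200", 4)))
  names(calls) <- paste0("i", 1:12)
  g <- geno_from_strings(calls, pop = rep(c("east", "west"), each = 6))
  m <- dapc_fit(g, n_pca = 1)   # two distinct profiles span a single axis
  expect_true(m$perfect_separation)
  sc <- dapc_predict(m, g[c(1, 12), ])
  expect_gt(sc$scores[1, "east"], 0.999)
  expect_gt(sc$scores[2, "west"], 0.999)
  expect_error(dapc_fit(g, n_pca = 0), "at least 1")
  expect_error(dapc_fit(g, n_pca = 50), "exceeds")
})

test_that("DAPC group separation matches an independent PCA+LDA fit", {
  skip_if_not_installed("MASS")
  cfg <- sim_config(seed = 19, fst = 0.2, n_per_pop = 25, n_queries = 0)
  ref <- simulate_reference(cfg)
  m <- dapc_fit(ref$genotypes)
  # rebuild the dummy matrix independently and fit MASS::lda on PCA scores
  g <- ref$genotypes
  tab <- allele_frequencies(g, by_pop = FALSE)
  X <- NULL
  for (l in tab$loci) {
    for (a in as.integer(colnames(tab$freq[[l]]))) {
      jl <- match(l, locus_names(g))
      X <- cbind(X, ((g$a1[, jl] == a) + (g$a2[, jl] == a)) / 2)
    }
  }
  pca <- stats::prcomp(scale(X, scale = FALSE))
  Y <- pca$x[, seq_len(m$n_pca)]
  ld <- MASS::lda(Y, grouping = factor(g$pop))
  my_means <- m$group_means
  ld_means <- ld$means %*% ld$scaling
  # discriminant bases differ by rotation/sign: compare pairwise distances
  expect_equal(unname(as.matrix(dist(my_means))),
               unname(as.matrix(dist(ld_means))), tolerance = 1e-6)
  # and posterior argmax agrees with MASS prediction on the references
  sc <- dapc_predict(m, g)
  mine <- colnames(sc$scores)[apply(sc$scores, 1, which.max)]
  theirs <- as.character(stats::predict(ld, Y)$class)
  expect_gte(mean(mine == theirs), 0.97)
})

test_that("a query at a group mean profile is assigned there; symmetry halves", {
  g <- geno_from_strings(list(
    a1 = c("100/100", "200/200"), a2 = c("100/100", "200/200"),
    a3 = c("100/102", "200/200"),
    b1 = c("104/104", "200/202"), b2 = c("104/104", "200/202"),
    b3 = c("104/106", "200/202")),
    pop = rep(c("A", "B"), each = 3))
  m <- dapc_fit(g, n_pca = 2)
  qa <- g[1, ]
  expect_equal(unname(which.max(dapc_predict(m, qa)$scores[1, ])),
               match("A", m$groups))
  # perfectly symmetric two-group design: the grand-mean query splits 50/50
  gs <- geno_from_strings(list(
    a1 = "100/100", a2 = "100/102", b1 = "104/104", b2 = "104/106"),
    pop = c("A", "A", "B", "B"))
  ms <- dapc_fit(gs, n_pca = 2)
  mid <- geno_from_strings(list(q = "100/104"))
  scm <- dapc_predict(ms, mid)
  expect_equal(unname(scm$scores[1, ]), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("score rows are normalized and invariant to population order", {
  cfg <- sim_config(seed = 29, fst = 0.15, n_per_pop = 20, n_queries = 6)
  ref <- simulate_reference(cfg)
  qs <- simulate_queries(cfg, ref)
  tab <- allele_frequencies(ref$genotypes)
  for (sc in list(assign_frequency(qs$genotypes, tab),
                  assign_bayesian(qs$genotypes, tab),
                  dapc_predict(dapc_fit(ref$genotypes), qs$genotypes))) {
    expect_equal(unname(rowSums(sc$scores)), rep(1, 6), tolerance = 1e-9)
  }
  # reversing population order permutes but does not change scores
  rev_idx <- rev(seq_len(nrow(ref$genotypes$a1)))
  tab_rev <- allele_frequencies(ref$genotypes[rev_idx, ])
  f1 <- assign_frequency(qs$genotypes, tab)
  f2 <- assign_frequency(qs$genotypes, tab_rev)
  expect_equal(f1$scores[, colnames(f2$scores)], f2$scores, tolerance = 1e-12)
})
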