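test_that("exact matching finds duplicates and respects the mismatch cap", {
  refs <- geno_from_strings(list(
    r1 = c("150/154", "200/200", "118/120", "300/302", "150/150", "160/162",
           "170/170", "180/184"),
    r2 = c("150/150", "200/202", "118/118", "300/300", "152/152", "160/160",
           "172/174", "180/180")))
  q_same <- refs[1, ]
  rownames(q_same$a1) <- rownames(q_same$a2) <- "query"
  hits <- match_genotypes(q_same, refs)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$ref, "r1")
  expect_equal(hits$mismatches, 0L)
  expect_equal(hits$loci_compared, 8L)

  # one differing locus is excluded at max_mismatch 0, reported at 1
  q_off <- q_same
  q_off$a1[1, 1] <- 152L; q_off$a2[1, 1] <- 152L
  expect_equal(nrow(match_genotypes(q_off, refs)), 0L)
  expect_equal(match_genotypes(q_off, refs, max_mismatch = 1)$mismatches, 1L)

  # missing loci shrink the comparable set; min_loci gates the pair
  q_miss <- q_same
  q_miss$a1[1, 1:3] <- NA_integer_; q_miss$a2[1, 1:3] <- NA_integer_
  expect_equal(nrow(match_genotypes(q_miss, refs, min_loci = 6)), 0L)
  expect_equal(match_genotypes(q_miss, refs, min_loci = 5)$loci_compared, 5L)

  expect_error(match_genotypes(geno_from_strings(list(q = "1/2"), loci = "zz"),
                               refs), "no shared loci")
})

test_that("a planted duplicate in a simulated database is the unique hit", {
  cfg <- sim_config(seed = 5, n_pops = 3, n_per_pop = 40, n_queries = 4,
                    duplicate_fraction = 0.25)
  ref <- simulate_reference(cfg)
  qs <- simulate_queries(cfg, ref)
  dup <- qs$truth$queries[qs$truth$queries$type == "duplicate", ]
  hits <- match_genotypes(qs$genotypes, ref$genotypes)
  hits0 <- hits[hits$mismatches == 0L, ]
  expect_equal(sort(unique(hits0$query)), sort(dup$sample))
  expect_equal(hits0$ref[match(dup$sample, hits0$query)], dup$duplicate_of)
})

test_that("probability of identity matches closed forms and enumeration", {
  # two equifrequent alleles
  tab <- freq_table_from_counts(list(
    l1 = matrix(c(50, 50), 1, 2, dimnames = list("p", c("100", "102")))))
  ids <- probability_of_identity(tab)
  expect_equal(ids$pid, 0.375)
  expect_equal(ids$pid_sibs, 0.59375)

  # monomorphic locus is 1 and flagged uninformative
  mono <- freq_table_from_counts(list(
    l1 = matrix(100, 1, 1, dimnames = list("p", "100"))))
  idm <- probability_of_identity(mono)
  expect_equal(idm$pid, 1)
  expect_equal(idm$pid_sibs, 1)
  expect_true(idm$per_locus$uninformative[1])

  # exhaustive enumeration oracle: PID = sum over genotypes of P(g)^2
  set.seed(9)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    p <- as.numeric(rmultinom(1, 500, rep(1, k))) / 500
    p <- p[p > 0]; k <- length(p)
    cnt <- matrix(round(p * 1e6), 1, k,
                  dimnames = list("p", as.character(seq(100, by = 2,
                                                        length.out = k))))
    tab <- freq_table_from_counts(list(lx = cnt))
    pid <- probability_of_identity(tab)$pid
    enum <- 0
    for (i in seq_len(k)) for (j in i:k) {
      pg <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
      enum <- enum + pg^2
    }
    expect_equal(pid, enum, tolerance = 1e-9)
  }
})

test_that("PID is multiplicative, monotone in loci, and below PID(sibs)", {
  cfg <- sim_config(seed = 9, n_pops = 1, n_per_pop = 40, n_queries = 0)
  sim <- simulate_reference(cfg)
  tab <- allele_frequencies(sim$genotypes, by_pop = FALSE)
  ids <- probability_of_identity(tab)
  expect_equal(ids$pid, prod(ids$per_locus$pid))
  expect_true(all(ids$per_locus$pid <= ids$per_locus$pid_sibs))
  expect_true(ids$pid <= ids$pid_sibs)
  running <- cumprod(ids$per_locus$pid)
  expect_true(all(diff(running) <= 0))
})

test_that("Weir-Cockerham theta behaves at the degenerate extremes", {
  # a population duplicated into two "populations" shows no differentiation
  g1 <- simulate_reference(sim_config(seed = 6, n_pops = 1, n_per_pop = 50,
                                      n_queries = 0))$genotypes
  a1 <- rbind(g1$a1, g1$a1); a2 <- rbind(g1$a2, g1$a2)
  rownames(a1) <- rownames(a2) <- paste0("i", seq_len(100))
  g_same <- geno_matrix(a1, a2, pop = rep(c("p1", "p2"), each = 50))
  expect_lt(abs(fst_weir_cockerham(g_same)$theta), 0.02)

  g_fixed <- geno_from_strings(list(
    a = c("150/150", "200/200"), b = c("150/150", "200/200"),
    c = c("154/154", "204/204"), d = c("154/154", "204/204")),
    pop = c("p1", "p1", "p2", "p2"))
  expect_equal(fst_weir_cockerham(g_fixed)$theta, 1)

  g_mono <- geno_from_strings(list(a = "150/150", b = "150/150",
                                   c = "150/150", d = "150/150"),
                              pop = c("p1", "p1", "p2", "p2"))
  expect_warning(res <- fst_weir_cockerham(g_mono), "no allele-frequency")
  expect_equal(res$theta, 0)
})

test_that("theta recovers the Balding-Nichols F around 0.15", {
  thetas <- vapply(c(13, 14, 15), function(s) {
    cfg <- sim_config(seed = s, n_per_pop = 100, fst = 0.15, n_queries = 0)
    sim <- simulate_reference(cfg)
    fst_weir_cockerham(sim$genotypes)$theta
  }, 1)
  # central interval for an 8-locus estimate at F = 0.15 is wide
  expect_true(all(thetas > 0.05 & thetas < 0.30))
  expect_lt(abs(mean(thetas) - 0.15), 0.07)
})

test_that("individual Nei distance matches hand-computed J sums", {
  g <- geno_from_strings(list(i1 = "100/100", i2 = "100/102", i3 = "102/102"))
  D <- nei_distance_individuals(g)
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_equal(D, t(D))
  # J1 = 1, J2 = 0.5, J12 = 0.5 -> D = -ln(0.5 / sqrt(0.5))
  expect_equal(D["i1", "i2"], -log(0.5 / sqrt(0.5)))
  expect_equal(D["i1", "i3"], Inf)      # no shared alleles

  g2 <- geno_from_strings(list(i1 = c("100/102", "200/200"),
                               i2 = c("100/102", "200/200")))
  expect_equal(nei_distance_individuals(g2)["i1", "i2"], 0)
})

test_that("UPGMA matches closed forms and a naive reimplementation", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- upgma(d2)
  expect_equal(sort(tr$tip.label), c("a", "b"))
  expect_equal(unname(tr$edge.length), c(0.2, 0.2))

  d3 <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d3["A", "B"] <- d3["B", "A"] <- 0.2
  d3["A", "C"] <- d3["C", "A"] <- 0.8
  d3["B", "C"] <- d3["C", "B"] <- 0.6
  tr3 <- upgma(d3)
  # A and B join first: their pairwise cophenetic distance is the smallest
  coph <- ape::cophenetic.phylo(tr3)
  expect_equal(coph["A", "B"], 0.2)
  expect_equal(coph["A", "C"], coph["B", "C"])

  # naive average-linkage oracle for root height on a random matrix
  set.seed(2)
  n <- 8
  m <- matrix(runif(n * n, 0.1, 1), n, n)
  m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(letters[1:n], letters[1:n])
  naive_root <- function(d) {
    act <- as.list(rownames(d)); h <- 0
    while (length(act) > 1) {
      best <- c(1, 2); bv <- Inf
      for (i in seq_along(act)) for (j in seq_along(act)) if (i < j) {
        v <- mean(d[act[[i]], act[[j]]])
        if (v < bv) { bv <- v; best <- c(i, j) }
      }
      h <- bv / 2
      merged <- c(act[[best[1]]], act[[best[2]]])
      act <- c(act[-best], list(merged))
    }
    h
  }
  tr8 <- upgma(m)
  depth <- max(ape::node.depth.edgelength(tr8))
  expect_equal(depth, naive_root(m), tolerance = 1e-9)
})

test_that("UPGMA trees are ultrametric and infinite distances are capped", {
  set.seed(4)
  n <- 10
  m <- matrix(runif(n * n, 0.2, 2), n, n); m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  tr <- upgma(m)
  depths <- ape::node.depth.edgelength(tr)[seq_len(n)]
  expect_lt(max(depths) - min(depths), 1e-9)

  m2 <- m; m2[1, 2] <- m2[2, 1] <- Inf
  expect_warning(tr2 <- upgma(m2), "infinite")
  expect_true(ape::is.ultrametric(tr2, tol = 1e-8))
})
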