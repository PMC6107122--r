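#' Match query genotypes against a reference database
#'
#' Pairwise profile comparison in the style of database matching tools:
#' for every (query, reference) pair, loci non-missing in both profiles are
#' compared as unordered allele pairs, and the pair is reported as a hit when
#' the number of mismatching loci is at most \code{max_mismatch} over at
#' least \code{min_loci} comparable loci. The defaults (exact match over at
#' least 6 loci) suit forensic re-identification with partial profiles.
#'
#' @param queries,refs \code{geno_matrix} objects; their shared locus set is
#'   used and must be non-empty
#' @param max_mismatch maximum mismatching loci for a hit (default 0)
#' @param min_loci minimum comparable loci for a pair to be evaluated
#'   (default 6)
#' @return data.frame with columns \code{query}, \code{ref},
#'   \code{loci_compared}, \code{mismatches}
#' @export
match_genotypes <- function(queries, refs, max_mismatch = 0L, min_loci = 6L) {
  shared <- intersect(locus_names(queries), locus_names(refs))
  if (!length(shared)) stop("no shared loci between queries and references")
  q <- queries[, shared]; r <- refs[, shared]
  out <- data.frame(query = character(), ref = character(),
                    loci_compared = integer(), mismatches = integer(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(q$a1))) {
    for (j in seq_len(nrow(r$a1))) {
      comp <- !is.na(q$a1[i, ]) & !is.na(r$a1[j, ])
      nc <- sum(comp)
      if (nc < min_loci) next
      mm <- sum(q$a1[i, comp] != r$a1[j, comp] |
                q$a2[i, comp] != r$a2[j, comp])
      if (mm <= max_mismatch)
        out[nrow(out) + 1L, ] <- list(rownames(q$a1)[i], rownames(r$a1)[j],
                                      nc, mm)
    }
  }
  out
}

#' Probability of identity for a locus panel
#'
#' Gauges the individual-identification power of a microsatellite panel.
#' For a locus with allele frequencies \eqn{a_i}:
#' \deqn{PID = 2 (\sum a_i^2)^2 - \sum a_i^4}
#' \deqn{PID_{sibs} = 0.25 + 0.5 \sum a_i^2 + 0.5 (\sum a_i^2)^2
#'       - 0.25 \sum a_i^4}
#' Multi-locus values are products over loci (independence across loci
#' assumed). A monomorphic locus contributes 1 and is flagged uninformative.
#'
#' @param freqs an \code{\link{allele_frequencies}} table; frequencies are
#'   pooled over its populations (weighted by gene-copy counts)
#' @param loci optional subset of locus names (default: all)
#' @return list with \code{pid}, \code{pid_sibs} (multi-locus products),
#'   \code{per_locus} data.frame (columns \code{locus}, \code{pid},
#'   \code{pid_sibs}, \code{uninformative})
#' @export
probability_of_identity <- function(freqs, loci = NULL) {
  if (is.null(loci)) loci <- freqs$loci
  missing_loci <- setdiff(loci, freqs$loci)
  if (length(missing_loci))
    stop("no frequencies for loci: ", paste(missing_loci, collapse = ", "))
  per <- data.frame(locus = loci, pid = NA_real_, pid_sibs = NA_real_,
                    uninformative = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(loci)) {
    l <- loci[k]
    cnt <- colSums(freqs$counts[[l]])
    if (sum(cnt) == 0) stop("no observed gene copies at locus ", l)
    p <- cnt / sum(cnt)
    s2 <- sum(p^2); s4 <- sum(p^4)
    per$pid[k] <- 2 * s2^2 - s4
    per$pid_sibs[k] <- 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
    per$uninformative[k] <- sum(p > 0) < 2
  }
  list(pid = prod(per$pid), pid_sibs = prod(per$pid_sibs), per_locus = per)
}

#' Weir-Cockerham F_ST for multi-allelic loci
#'
#' Variance-components estimator theta of Weir & Cockerham (1984) extended to
#' multiple alleles: for every (locus, allele) the among-population (a),
#' among-individual (b) and within-individual (c) components are computed
#' from sample sizes, allele frequencies and observed heterozygosities, and
#' theta is the ratio of summed a over summed a + b + c across all alleles
#' and loci.
#'
#' @param g a \code{geno_matrix} with population labels
#' @param pops optional subset of population labels (default: all labeled)
#' @return list with \code{theta} (global), \code{per_locus} data.frame
#' @export
fst_weir_cockerham <- function(g, pops = NULL) {
  if (is.null(pops)) pops <- sort(unique(g$pop[g$pop_known]))
  if (length(pops) < 2) stop("need at least two populations")
  keep <- g$pop_known & g$pop %in% pops
  a1 <- g$a1[keep, , drop = FALSE]; a2 <- g$a2[keep, , drop = FALSE]
  popv <- g$pop[keep]
  r <- length(pops)
  loci <- colnames(a1)
  per <- data.frame(locus = loci, a = 0, abc = 0)
  for (l in seq_along(loci)) {
    x1 <- a1[, l]; x2 <- a2[, l]
    ok <- !is.na(x1)
    if (!sum(ok)) next
    ni <- vapply(pops, function(p) sum(ok & popv == p), 1)
    if (any(ni < 1)) next
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    alle <- sort(unique(c(x1[ok], x2[ok])))
    for (A in alle) {
      pi <- vapply(pops, function(p) {
        sel <- ok & popv == p
        (sum(x1[sel] == A) + sum(x2[sel] == A)) / (2 * sum(sel))
      }, 1)
      hi <- vapply(pops, function(p) {
        sel <- ok & popv == p
        sum((x1[sel] == A) != (x2[sel] == A)) / sum(sel)
      }, 1)
      pbar <- sum(ni * pi) / (r * nbar)
      s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * hi) / (r * nbar)
      if (nbar <= 1) next
      a_ <- nbar / nc * (s2 - 1 / (nbar - 1) *
              (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      b_ <- nbar / (nbar - 1) *
              (pbar * (1 - pbar) - (r - 1) / r * s2 -
               (2 * nbar - 1) / (4 * nbar) * hbar)
      c_ <- hbar / 2
      per$a[l] <- per$a[l] + a_
      per$abc[l] <- per$abc[l] + a_ + b_ + c_
    }
  }
  per$theta <- ifelse(per$abc != 0, per$a / per$abc, NA_real_)
  denom <- sum(per$abc)
  theta <- if (denom == 0) {
    warning("no allele-frequency variation; theta reported as 0")
    0
  } else sum(per$a) / denom
  list(theta = theta, per_locus = per)
}

#' Nei standard genetic distance between individuals
#'
#' Treats each individual as a "population" whose allele frequency vector at
#' a locus has entries 0, 0.5 or 1, and computes Nei's (1972) standard
#' distance \eqn{D = -\ln(J_{xy} / \sqrt{J_x J_y})} with the J identity terms
#' summed over loci and alleles. Loci missing in either member of a pair are
#' dropped pairwise. Pairs sharing no alleles anywhere (\eqn{J_{xy} = 0})
#' receive an infinite-distance sentinel (\code{Inf}).
#'
#' @param g a \code{geno_matrix} with at least two individuals
#' @return symmetric numeric matrix of distances with zero diagonal, labels
#'   from \code{sample_ids(g)}
#' @export
nei_distance_individuals <- function(g) {
  n <- nrow(g$a1)
  if (n < 2) stop("need at least two individuals")
  ids <- sample_ids(g)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- which(!is.na(g$a1[i, ]) & !is.na(g$a1[j, ]))
      jx <- jy <- jxy <- 0
      for (l in comp) {
        gi <- c(g$a1[i, l], g$a2[i, l]); gj <- c(g$a1[j, l], g$a2[j, l])
        alle <- unique(c(gi, gj))
        pi_ <- vapply(alle, function(a) mean(gi == a), 1)
        pj_ <- vapply(alle, function(a) mean(gj == a), 1)
        jx <- jx + sum(pi_^2); jy <- jy + sum(pj_^2)
        jxy <- jxy + sum(pi_ * pj_)
      }
      D[i, j] <- D[j, i] <-
        if (!length(comp) || jxy == 0) Inf else -log(jxy / sqrt(jx * jy))
    }
  }
  D
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering returning a rooted ultrametric
#' tree, used here to screen for outlier samples that fall outside the main
#' population clusters. Infinite distances (the \code{Inf} sentinel from
#' \code{\link{nei_distance_individuals}}) are replaced by 1.5 times the
#' largest finite distance, with a warning.
#'
#' @param d symmetric distance matrix with labels
#' @return a rooted \code{phylo} tree (see \pkg{ape}); leaf labels are the
#'   matrix labels
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2) stop("need at least two leaves")
  if (any(!is.finite(d[upper.tri(d)]))) {
    mx <- max(d[is.finite(d)])
    warning("infinite distances replaced by ", format(1.5 * mx))
    d[!is.finite(d)] <- 1.5 * mx
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(hc)
}
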