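pop_scores <- function(scores, loglik, method) {
  structure(list(scores = scores, loglik = loglik, method = method),
            class = "pop_scores")
}

#' @export
print.pop_scores <- function(x, ...) {
  cat("pop_scores (", x$method, "):\n", sep = "")
  print(round(x$scores, 4))
  invisible(x)
}

check_query_loci <- function(queries) {
  all_missing <- rowSums(!is.na(queries$a1)) == 0
  if (any(all_missing))
    stop("query with no genotyped locus: ",
         paste(sample_ids(queries)[all_missing], collapse = ", "))
}

#' Frequency-based population assignment
#'
#' The classic frequency assignment likelihood: for each candidate
#' population the query's multi-locus Hardy-Weinberg genotype probability is
#' computed from the population's allele frequencies (2 p_a p_b for a
#' heterozygote, p_a^2 for a homozygote), taking the product over the query's
#' non-missing loci. Any allele unobserved in a population is floored at
#' \code{missing_allele_freq} and the frequency vector renormalized, so
#' likelihoods stay finite. Scores are the per-population likelihoods
#' normalized to sum to 1 across the candidates.
#'
#' @param queries a \code{geno_matrix} of query samples
#' @param freqs an \code{\link{allele_frequencies}} table for the reference
#'   populations
#' @param missing_allele_freq floor for unobserved alleles (default 0.01)
#' @return a \code{pop_scores}: \code{scores} (samples x populations,
#'   rows sum to 1), \code{loglik} (raw log-likelihoods), \code{method}
#' @export
assign_frequency <- function(queries, freqs, missing_allele_freq = 0.01) {
  check_query_loci(queries)
  pops <- freqs$pops
  shared <- intersect(locus_names(queries), freqs$loci)
  if (!length(shared)) stop("no locus shared with the frequency table")
  ll <- matrix(0, nrow(queries$a1), length(pops),
               dimnames = list(sample_ids(queries), pops))
  for (l in shared) {
    jq <- match(l, locus_names(queries))
    tab_alle <- as.integer(colnames(freqs$freq[[l]]))
    for (i in seq_len(nrow(queries$a1))) {
      a <- queries$a1[i, jq]; b <- queries$a2[i, jq]
      if (is.na(a)) next
      alle <- union(tab_alle, c(a, b))
      for (p in seq_along(pops)) {
        f <- stats::setNames(rep(0, length(alle)), alle)
        fr <- freqs$freq[[l]][p, ]
        if (!anyNA(fr)) f[as.character(tab_alle)] <- fr
        f[f <= 0] <- missing_allele_freq
        f <- f / sum(f)
        pa <- f[as.character(a)]; pb <- f[as.character(b)]
        ll[i, p] <- ll[i, p] + if (a == b) log(pa^2) else log(2 * pa * pb)
      }
    }
  }
  scores <- t(apply(ll, 1, function(x) { e <- exp(x - max(x)); e / sum(e) }))
  pop_scores(scores, ll, "frequency")
}

#' Bayesian population assignment (Dirichlet posterior-predictive)
#'
#' For each candidate population and locus, the posterior-predictive
#' probability of the query genotype after updating a symmetric
#' Dirichlet(1/k) prior (k = distinct alleles observed at the locus across
#' the whole dataset) with the population's observed allele counts n_i
#' (total n): a heterozygote \{a, b\} has probability
#' 2 (n_a + 1/k)(n_b + 1/k) / ((n + 1)(n + 2)) and a homozygote \{a, a\}
#' has (n_a + 1/k)(n_a + 1/k + 1) / ((n + 1)(n + 2)). The per-locus terms
#' multiply over the query's non-missing loci and are normalized across
#' candidate populations.
#'
#' @inheritParams assign_frequency
#' @return a \code{pop_scores} with method \code{"bayesian"}
#' @export
assign_bayesian <- function(queries, freqs) {
  check_query_loci(queries)
  pops <- freqs$pops
  shared <- intersect(locus_names(queries), freqs$loci)
  if (!length(shared)) stop("no locus shared with the frequency table")
  ll <- matrix(0, nrow(queries$a1), length(pops),
               dimnames = list(sample_ids(queries), pops))
  for (l in shared) {
    jq <- match(l, locus_names(queries))
    cnts <- freqs$counts[[l]]
    tab_alle <- as.integer(colnames(cnts))
    q_alle <- unique(c(queries$a1[, jq], queries$a2[, jq]))
    k <- length(union(tab_alle[colSums(cnts) > 0], q_alle[!is.na(q_alle)]))
    for (i in seq_len(nrow(queries$a1))) {
      a <- queries$a1[i, jq]; b <- queries$a2[i, jq]
      if (is.na(a)) next
      for (p in seq_along(pops)) {
        n <- sum(cnts[p, ])
        na_ <- if (as.character(a) %in% colnames(cnts)) cnts[p, as.character(a)] else 0
        nb_ <- if (as.character(b) %in% colnames(cnts)) cnts[p, as.character(b)] else 0
        pr <- if (a == b) {
          (na_ + 1 / k) * (na_ + 1 / k + 1) / ((n + 1) * (n + 2))
        } else {
          2 * (na_ + 1 / k) * (nb_ + 1 / k) / ((n + 1) * (n + 2))
        }
        ll[i, p] <- ll[i, p] + log(pr)
      }
    }
  }
  scores <- t(apply(ll, 1, function(x) { e <- exp(x - max(x)); e / sum(e) }))
  pop_scores(scores, ll, "bayesian")
}

geno_dummy <- function(g, col_locus, col_allele) {
  X <- matrix(0, nrow(g$a1), length(col_locus),
              dimnames = list(sample_ids(g), paste0(col_locus, ".", col_allele)))
  miss <- matrix(FALSE, nrow(g$a1), length(col_locus))
  for (j in seq_along(col_locus)) {
    jl <- match(col_locus[j], locus_names(g))
    if (is.na(jl)) { miss[, j] <- TRUE; next }
    a1 <- g$a1[, jl]; a2 <- g$a2[, jl]
    X[, j] <- (ifelse(is.na(a1), 0, a1 == col_allele[j]) +
               ifelse(is.na(a2), 0, a2 == col_allele[j])) / 2
    miss[, j] <- is.na(a1)
  }
  list(X = X, miss = miss)
}

#' Fit a DAPC model to reference populations
#'
#' Discriminant analysis of principal components: individuals are encoded as
#' allele relative-frequency dummy vectors (0 / 0.5 / 1 per allele; a missing
#' locus is imputed with the individual's population mean), centered, reduced
#' by PCA, and the retained principal-component scores are fed to a linear
#' discriminant analysis (at most one fewer discriminant axes than groups).
#' The discriminant scaling whitens the pooled within-group covariance, so
#' group membership reduces to Euclidean distance in discriminant space.
#' Perfectly separated groups (zero pooled within-group variance) are
#' handled with a small ridge and flagged.
#'
#' @param refs a \code{geno_matrix} with at least 2 labeled populations of
#'   at least 2 individuals each
#' @param n_pca number of principal axes to retain (default: smallest number
#'   reaching 90\% cumulative variance, capped at n/3)
#' @param n_da number of discriminant axes (default: groups - 1)
#' @return object of class \code{dapc_model}
#' @export
dapc_fit <- function(refs, n_pca = NULL, n_da = NULL) {
  keep <- refs$pop_known
  g <- refs[keep, ]
  groups <- factor(g$pop)
  if (nlevels(groups) < 2) stop("need at least two labeled populations")
  if (any(table(groups) < 2)) stop("each population needs at least 2 individuals")
  freqs <- allele_frequencies(g, by_pop = FALSE)
  col_locus <- col_allele <- c()
  for (l in freqs$loci) {
    alle <- as.integer(colnames(freqs$freq[[l]]))
    col_locus <- c(col_locus, rep(l, length(alle)))
    col_allele <- c(col_allele, alle)
  }
  dd <- geno_dummy(g, col_locus, col_allele)
  X <- dd$X
  for (k in levels(groups)) {       # population-mean imputation, refs only
    sel <- groups == k
    if (any(dd$miss[sel, ])) {
      pm <- colSums(X[sel, , drop = FALSE] * !dd$miss[sel, , drop = FALSE]) /
        pmax(colSums(!dd$miss[sel, , drop = FALSE]), 1)
      for (j in which(colSums(dd$miss[sel, , drop = FALSE]) > 0))
        X[sel & dd$miss[, j], j] <- pm[j]
    }
  }
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  pca <- stats::prcomp(Xc, center = FALSE)
  pvar <- pca$sdev^2
  pos <- pvar > 1e-12
  cumvar <- cumsum(pvar[pos]) / sum(pvar[pos])
  if (is.null(n_pca))
    n_pca <- min(which(cumvar >= 0.90)[1], max(1L, floor(nrow(X) / 3)))
  if (n_pca < 1) stop("n_pca must be at least 1")
  if (n_pca > sum(pos)) stop("n_pca exceeds the available principal axes")
  K <- nlevels(groups)
  if (is.null(n_da)) n_da <- K - 1L
  n_da <- min(n_da, K - 1L, n_pca)
  Y <- pca$x[, seq_len(n_pca), drop = FALSE]
  M <- apply(Y, 2, function(col) tapply(col, groups, mean))
  if (K == 2) M <- matrix(M, nrow = K, dimnames = list(levels(groups), colnames(Y)))
  nk <- as.vector(table(groups))
  W <- matrix(0, n_pca, n_pca)
  for (k in seq_len(K)) {
    sel <- which(as.integer(groups) == k)
    D <- sweep(Y[sel, , drop = FALSE], 2, M[k, ])
    W <- W + crossprod(D)
  }
  W <- W / (nrow(Y) - K)
  perfect <- sum(diag(W)) < 1e-10
  eps <- if (perfect) 1e-8 else 1e-8 * sum(diag(W)) / n_pca
  W <- W + diag(eps, n_pca)
  ew <- eigen(W, symmetric = TRUE)
  Wih <- ew$vectors %*% diag(1 / sqrt(pmax(ew$values, 1e-300)), n_pca) %*%
    t(ew$vectors)
  gm <- colSums(M * nk) / sum(nk)
  B <- crossprod(sweep(M, 2, gm) * sqrt(nk)) / (K - 1)
  eb <- eigen(Wih %*% B %*% Wih, symmetric = TRUE)
  scaling <- Wih %*% eb$vectors[, seq_len(n_da), drop = FALSE]
  proj <- pca$rotation[, seq_len(n_pca), drop = FALSE] %*% scaling
  structure(list(center = center, scale = rep(1, length(center)),
                 col_locus = col_locus, col_allele = col_allele,
                 proj = proj, group_means = M %*% scaling,
                 groups = levels(groups), n_pca = n_pca, n_da = n_da,
                 eig = eb$values[seq_len(n_da)],
                 pca_rotation = pca$rotation[, seq_len(n_pca), drop = FALSE],
                 lda_scaling = scaling,
                 perfect_separation = perfect,
                 cum_var = cumvar[n_pca]), class = "dapc_model")
}

#' @export
print.dapc_model <- function(x, ...) {
  cat("dapc_model:", length(x$groups), "groups,", x$n_pca, "PCs (",
      round(100 * x$cum_var, 1), "% variance ),", x$n_da, "discriminant axes",
      if (x$perfect_separation) "[perfect separation]" else "", "\n")
  invisible(x)
}

#' Posterior group membership of queries under a DAPC model
#'
#' Queries are encoded on the model's allele dummy columns (missing loci fall
#' back to the stored global centering, i.e. the overall mean profile),
#' projected through the stored principal-axis and discriminant loadings,
#' and assigned posterior memberships proportional to
#' \eqn{\exp(-d_k^2 / 2)} where \eqn{d_k} is the Mahalanobis distance to
#' group k's mean under the pooled within-group covariance (identity in the
#' whitened discriminant space), with equal priors.
#'
#' @param model a \code{dapc_model}
#' @param queries a \code{geno_matrix}
#' @return a \code{pop_scores} with method \code{"dapc"}
#' @export
dapc_predict <- function(model, queries) {
  check_query_loci(queries)
  if (!length(intersect(locus_names(queries), unique(model$col_locus))))
    stop("queries share no locus with the fitted model")
  dd <- geno_dummy(queries, model$col_locus, model$col_allele)
  X <- dd$X
  for (j in seq_len(ncol(X)))       # missing locus -> global mean
    X[dd$miss[, j], j] <- model$center[j]
  Z <- sweep(X, 2, model$center) %*% model$proj
  d2 <- outer(rep(1, nrow(Z)), rep(0, nrow(model$group_means)))
  for (k in seq_len(nrow(model$group_means)))
    d2[, k] <- rowSums(sweep(Z, 2, model$group_means[k, ])^2)
  dimnames(d2) <- list(sample_ids(queries), model$groups)
  ll <- -d2 / 2
  scores <- t(apply(ll, 1, function(x) { e <- exp(x - max(x)); e / sum(e) }))
  pop_scores(scores, ll, "dapc")
}
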