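#' Options for the admixture-model Gibbs sampler
#'
#' Desk-scale defaults (5,000 burn-in, 20,000 retained-phase sweeps, 10
#' independent chains) keep a full K-grid analysis of a ~100-individual,
#' 8-locus panel to minutes on one CPU; the full-scale settings used with
#' external clustering tools (hundreds of thousands of sweeps) remain
#' configurable.
#'
#' @param K number of clusters (>= 1)
#' @param burn_in burn-in sweeps (default 5000)
#' @param reps post-burn-in sweeps (default 20000)
#' @param n_runs independent chains for multi-run workflows (default 10)
#' @param seed integer random seed (mandatory)
#' @param alpha_init,alpha_max,alpha_proposal_sd controls for the admixture
#'   hyperparameter alpha: initial value, upper bound of its uniform prior,
#'   and the Metropolis proposal standard deviation
#' @param lambda Dirichlet prior parameter for cluster allele frequencies
#'   (default 1, the flat prior of the independent-frequencies model)
#' @param supervised if \code{TRUE}, individuals with a known population
#'   anchor their labeled cluster's allele frequencies (their allele-origin
#'   indicators are fixed); unknowns are updated freely
#' @param alpha_from which individuals inform the alpha update:
#'   \code{"unknown"} (default; only freely updated individuals, the
#'   convention matching the anchored supervised scheme) or \code{"all"}
#' @param thin record every \code{thin}-th post-burn-in sweep (default 10)
#' @return list of class \code{mcmc_options}
#' @export
mcmc_options <- function(K, burn_in = 5000L, reps = 20000L, n_runs = 10L,
                         seed, alpha_init = 1, alpha_max = 10,
                         alpha_proposal_sd = 0.05, lambda = 1,
                         supervised = FALSE, alpha_from = c("unknown", "all"),
                         thin = 10L) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(K >= 1, burn_in > 0, reps > 0, lambda > 0, thin >= 1)
  alpha_from <- match.arg(alpha_from)
  structure(list(K = as.integer(K), burn_in = as.integer(burn_in),
                 reps = as.integer(reps), n_runs = as.integer(n_runs),
                 seed = as.integer(seed), alpha_init = alpha_init,
                 alpha_max = alpha_max, alpha_proposal_sd = alpha_proposal_sd,
                 lambda = lambda, supervised = isTRUE(supervised),
                 alpha_from = alpha_from,
                 thin = as.integer(thin)), class = "mcmc_options")
}

encode_geno <- function(g) {
  L <- ncol(g$a1)
  n_alleles <- integer(L)
  idx <- matrix(0L, nrow(g$a1), 2L * L)
  for (l in seq_len(L)) {
    alle <- sort(unique(c(g$a1[, l], g$a2[, l])))
    alle <- alle[!is.na(alle)]
    if (!length(alle)) stop("locus ", colnames(g$a1)[l], " has no observed allele")
    n_alleles[l] <- length(alle)
    idx[, 2L * l - 1L] <- match(g$a1[, l], alle)
    idx[, 2L * l] <- match(g$a2[, l], alle)
  }
  idx[is.na(idx)] <- 0L
  list(idx = idx, n_alleles = n_alleles)
}

#' Run one chain of the admixture-model Gibbs sampler
#'
#' Bayesian clustering of multi-allelic genotypes: each individual holds a
#' vector Q of admixture proportions over K clusters, each gene copy an
#' origin indicator Z, and each cluster a set of allele frequencies P with
#' independent Dirichlet(lambda) priors. Q has a symmetric Dirichlet(alpha)
#' prior whose alpha is itself sampled by a Metropolis step under a uniform
#' prior on (0, alpha_max]. Missing genotypes contribute nothing. In
#' supervised mode, reference individuals (known population) have Z fixed to
#' their labeled cluster, anchoring cluster frequencies, while query
#' individuals are updated freely.
#'
#' @param g a \code{geno_matrix}; in supervised mode its known population
#'   labels (at most K distinct) define the leading clusters
#' @param opts an \code{\link{mcmc_options}}
#' @return object of class \code{q_matrix}: \code{Q} (individuals x K
#'   posterior-mean admixture, rows summing to 1), \code{lnl_trace},
#'   \code{mean_lnl}, \code{var_lnl}, \code{model_score}
#'   (= mean - variance/2), \code{K}, \code{cluster_names}, \code{alpha}
#' @export
run_admixture <- function(g, opts) {
  if (!nrow(g$a1)) stop("empty genotype matrix")
  enc <- encode_geno(g)
  labels <- rep(0L, nrow(g$a1))
  cluster_names <- paste0("C", seq_len(opts$K))
  if (opts$supervised) {
    known_pops <- sort(unique(g$pop[g$pop_known]))
    if (length(known_pops) > opts$K)
      stop("more labeled populations than clusters")
    labels[g$pop_known] <- match(g$pop[g$pop_known], known_pops)
    cluster_names[seq_along(known_pops)] <- known_pops
  }
  set.seed(opts$seed)
  res <- .admixture_gibbs(enc$idx, enc$n_alleles, opts$K, opts$burn_in,
                          opts$reps, opts$thin, opts$lambda, opts$alpha_init,
                          opts$alpha_max, opts$alpha_proposal_sd, labels,
                          as.integer(identical(opts$alpha_from, "all")))
  Q <- res$Q
  dimnames(Q) <- list(sample_ids(g), cluster_names)
  lnl <- res$lnl_trace
  structure(list(Q = Q, lnl_trace = lnl, mean_lnl = mean(lnl),
                 var_lnl = stats::var(lnl),
                 model_score = mean(lnl) - stats::var(lnl) / 2,
                 K = opts$K, cluster_names = cluster_names,
                 alpha = res$alpha, opts = opts), class = "q_matrix")
}

#' @export
print.q_matrix <- function(x, ...) {
  cat("q_matrix: K =", x$K, ",", nrow(x$Q), "individuals, L(K) =",
      format(x$model_score, digits = 6), "\n")
  invisible(x)
}

#' Model score L(K) of one admixture run
#'
#' The standard model-evidence approximation reported per run:
#' mean of the log-likelihood trace minus half its variance.
#'
#' @param run a \code{q_matrix} (or any list with \code{lnl_trace})
#' @return numeric L(K)
#' @export
model_score <- function(run) {
  lnl <- run$lnl_trace
  v <- if (length(lnl) > 1) stats::var(lnl) else 0
  mean(lnl) - v / 2
}

#' Evanno delta-K table from per-K, per-run model scores
#'
#' For each interior K, DeltaK(K) is the mean over runs of the absolute
#' second difference |L(K+1) - 2 L(K) + L(K-1)|, divided by the standard
#' deviation of L(K) over runs. DeltaK is undefined at the grid edges and
#' wherever the run standard deviation is zero (reported \code{NA}, never
#' infinity).
#'
#' @param scores numeric matrix of model scores, runs x K values, with
#'   column names giving consecutive integer K values
#' @return data.frame with columns \code{K}, \code{mean_l}, \code{sd_l},
#'   \code{delta_k}
#' @export
evanno_delta_k <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2) stop("need at least 2 runs per K for a standard deviation")
  ks <- as.integer(colnames(scores))
  if (any(is.na(ks)) || !all(diff(ks) == 1L))
    stop("columns must be consecutive K values")
  if (length(ks) < 3) stop("need at least 3 consecutive K values")
  out <- data.frame(K = ks, mean_l = colMeans(scores),
                    sd_l = apply(scores, 2, stats::sd), delta_k = NA_real_)
  for (j in 2:(length(ks) - 1)) {
    sdl <- out$sd_l[j]
    if (sdl > 0) {
      second <- abs(scores[, j + 1] - 2 * scores[, j] + scores[, j - 1])
      out$delta_k[j] <- mean(second) / sdl
    }
  }
  rownames(out) <- NULL
  out
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

#' Align and average Q matrices across independent runs
#'
#' Cluster labels are arbitrary per chain (label switching). For each run
#' after the first, the column permutation maximizing the summed per-row
#' dot-product similarity with the first run is found by exhaustive search
#' over the K! permutations (K <= 8), applied, and the aligned runs are
#' averaged element-wise with rows renormalized to sum to 1.
#'
#' @param runs list of \code{q_matrix} objects (or plain Q matrices) with
#'   identical individuals and K
#' @return the averaged Q matrix (individuals x K), dimnames from run 1
#' @export
align_runs <- function(runs) {
  mats <- lapply(runs, function(r) if (inherits(r, "q_matrix")) r$Q else as.matrix(r))
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1) stop("runs have mismatched shapes")
  K <- ncol(mats[[1]])
  if (K > 8) stop("exhaustive permutation alignment limited to K <= 8")
  ref <- mats[[1]]
  acc <- ref
  if (length(mats) > 1) {
    perms <- all_permutations(K)
    for (m in mats[-1]) {
      best <- NULL; best_sim <- -Inf
      for (p in perms) {
        sim <- sum(ref * m[, p, drop = FALSE])
        if (sim > best_sim) { best_sim <- sim; best <- p }
      }
      acc <- acc + m[, best, drop = FALSE]
    }
  }
  avg <- acc / length(mats)
  avg / rowSums(avg)
}

#' Run the admixture sampler over a K grid with independent chains
#'
#' Convenience driver for model selection: runs \code{n_runs} chains at each
#' K in \code{k_range}, collects the per-run model scores for
#' \code{\link{evanno_delta_k}}, and the aligned average Q per K.
#'
#' @param g a \code{geno_matrix}
#' @param k_range integer vector of consecutive K values
#' @param opts an \code{\link{mcmc_options}} whose K is overridden per grid
#'   point; chain seeds are derived as \code{seed + 1000 * K + run}
#' @return list with \code{scores} (runs x K matrix), \code{runs} (list of
#'   lists of \code{q_matrix}), \code{q_avg} (per K, aligned average Q)
#' @export
run_k_grid <- function(g, k_range, opts) {
  scores <- matrix(NA_real_, opts$n_runs, length(k_range),
                   dimnames = list(NULL, k_range))
  all_runs <- q_avg <- stats::setNames(vector("list", length(k_range)),
                                       paste0("K", k_range))
  for (j in seq_along(k_range)) {
    runs_k <- vector("list", opts$n_runs)
    for (r in seq_len(opts$n_runs)) {
      o <- opts
      o$K <- as.integer(k_range[j])
      o$seed <- as.integer(opts$seed + 1000L * k_range[j] + r)
      runs_k[[r]] <- run_admixture(g, o)
      scores[r, j] <- runs_k[[r]]$model_score
    }
    all_runs[[j]] <- runs_k
    q_avg[[j]] <- align_runs(runs_k)
  }
  list(scores = scores, runs = all_runs, q_avg = q_avg)
}
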