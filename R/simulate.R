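#' Configuration for the microsatellite study simulator
#'
#' Defaults emulate the operating conditions of a three-park forensic
#' reference panel: 3 source populations differentiated at a Balding-Nichols
#' F of 0.15, 8 polymorphic loci with 6-10 alleles each, tens of individuals
#' per population, and replicate PCR noise at an allelic-dropout rate of
#' 2.5\% and a false-allele rate of 16\% with 4 replicates per locus.
#'
#' @param n_pops number of source populations (default 3)
#' @param n_per_pop individuals per population (default 30)
#' @param n_loci number of loci (default 8)
#' @param alleles_per_locus range (length-2) or scalar count of alleles per
#'   locus (default 6 to 10)
#' @param fst Balding-Nichols differentiation F in [0, 1) (default 0.15)
#' @param n_queries number of forensic query samples (default 10)
#' @param admixed_fraction fraction of queries that are 50/50 admixed between
#'   the first two populations (default 0)
#' @param mixing mixture vector for admixed queries (default 0.5/0.5 between
#'   populations 1 and 2)
#' @param duplicate_fraction fraction of queries copied verbatim from a
#'   reference individual (default 0)
#' @param mixed_sample_fraction fraction of queries whose replicate sets are
#'   two-individual template mixtures (default 0)
#' @param ado_rate per-replicate allelic dropout probability at heterozygous
#'   loci (default 0.025)
#' @param fa_rate per-replicate false-allele probability (default 0.16)
#' @param n_replicates PCR replicates per (sample, locus) (default 4)
#' @param seed integer random seed (mandatory)
#' @return a list of class \code{sim_config}
#' @export
sim_config <- function(n_pops = 3L, n_per_pop = 30L, n_loci = 8L,
                       alleles_per_locus = c(6L, 10L), fst = 0.15,
                       n_queries = 10L, admixed_fraction = 0,
                       mixing = NULL, duplicate_fraction = 0,
                       mixed_sample_fraction = 0, ado_rate = 0.025,
                       fa_rate = 0.16, n_replicates = 4L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(fst >= 0, fst < 1, n_pops >= 1, n_loci >= 1,
            ado_rate >= 0, ado_rate <= 1, fa_rate >= 0, fa_rate <= 1)
  if (is.null(mixing)) {
    mixing <- rep(0, n_pops); mixing[seq_len(min(2L, n_pops))] <- 0.5
    if (n_pops == 1L) mixing <- 1
  }
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop, n_loci = n_loci,
                 alleles_per_locus = alleles_per_locus, fst = fst,
                 n_queries = n_queries, admixed_fraction = admixed_fraction,
                 mixing = mixing / sum(mixing),
                 duplicate_fraction = duplicate_fraction,
                 mixed_sample_fraction = mixed_sample_fraction,
                 ado_rate = ado_rate, fa_rate = fa_rate,
                 n_replicates = n_replicates, seed = as.integer(seed)),
            class = "sim_config")
}

# sample() treats a length-1 x as 1:x; guard allele ladders of one position
sample_alleles <- function(ladder, n, prob) {
  if (length(ladder) == 1L) return(rep(ladder, n))
  sample(ladder, n, replace = TRUE, prob = prob)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) { x <- rep(0, length(alpha)); x[which.max(alpha)] <- 1; return(x) }
  x / sum(x)
}

#' Simulate reference populations under the Balding-Nichols model
#'
#' Per locus, ancestral allele frequencies p are drawn from a flat Dirichlet;
#' each population's frequencies are drawn from Dirichlet(p (1 - F) / F),
#' so that the expected Weir-Cockerham differentiation among populations is
#' approximately F. F = 0 is handled as its limit (population frequencies
#' equal the ancestral ones). Diploid genotypes are drawn under
#' Hardy-Weinberg equilibrium within populations. Allele labels are
#' dinucleotide-ladder fragment sizes in base pairs.
#'
#' @param cfg a \code{\link{sim_config}}
#' @return list with \code{genotypes} (a \code{geno_matrix} with population
#'   labels \code{pop1..popK}) and \code{truth} (ancestral and population
#'   allele frequencies, allele ladders, the config)
#' @export
simulate_reference <- function(cfg) {
  set.seed(cfg$seed)
  apl <- cfg$alleles_per_locus
  loci <- paste0("L", seq_len(cfg$n_loci))
  pops <- paste0("pop", seq_len(cfg$n_pops))
  ladders <- anc <- pfreq <- vector("list", cfg$n_loci)
  names(ladders) <- names(anc) <- names(pfreq) <- loci
  for (l in seq_len(cfg$n_loci)) {
    A <- if (length(apl) == 2) sample(apl[1]:apl[2], 1) else apl
    start <- sample(seq(100L, 280L, by = 2L), 1)
    ladders[[l]] <- start + 2L * (seq_len(A) - 1L)
    p <- rdirichlet1(rep(1, A))
    anc[[l]] <- stats::setNames(p, ladders[[l]])
    pf <- matrix(NA_real_, cfg$n_pops, A, dimnames = list(pops, ladders[[l]]))
    for (k in seq_len(cfg$n_pops)) {
      pf[k, ] <- if (cfg$fst == 0) p else
        rdirichlet1(p * (1 - cfg$fst) / cfg$fst)
    }
    pfreq[[l]] <- pf
  }
  n <- cfg$n_pops * cfg$n_per_pop
  a1 <- a2 <- matrix(NA_integer_, n, cfg$n_loci,
                     dimnames = list(paste0("R", formatC(seq_len(n), width = 3,
                                                         flag = "0")), loci))
  popv <- rep(pops, each = cfg$n_per_pop)
  for (l in seq_len(cfg$n_loci)) {
    for (k in seq_len(cfg$n_pops)) {
      sel <- which(popv == pops[k])
      draws <- sample_alleles(ladders[[l]], 2 * length(sel),
                              prob = pfreq[[l]][k, ])
      a1[sel, l] <- draws[seq_along(sel)]
      a2[sel, l] <- draws[length(sel) + seq_along(sel)]
    }
  }
  g <- geno_matrix(a1, a2, pop = popv)
  list(genotypes = g,
       truth = list(ancestral = anc, pop_freq = pfreq, ladders = ladders,
                    origin = stats::setNames(popv, rownames(a1)), cfg = cfg))
}

#' Simulate forensic query samples
#'
#' Draws query genotypes against a simulated reference: pure queries come
#' from a single population (cycled over populations), admixed queries draw
#' each gene copy from a population chosen by the mixing vector, duplicates
#' are verbatim copies of randomly chosen reference individuals, and a
#' configured fraction is earmarked as two-template mixtures (realized later
#' at the replicate stage). Ground truth records each query's origin,
#' admixture vector, source duplicate and mixture partners.
#'
#' @param cfg a \code{\link{sim_config}}
#' @param ref output of \code{\link{simulate_reference}}
#' @return list with \code{genotypes} (query \code{geno_matrix}, populations
#'   unknown) and \code{truth} (data.frame \code{queries} plus the reference
#'   truth carried through)
#' @export
simulate_queries <- function(cfg, ref) {
  set.seed(cfg$seed + 1L)
  nq <- cfg$n_queries
  n_dup <- round(cfg$duplicate_fraction * nq)
  n_adm <- round(cfg$admixed_fraction * nq)
  n_mix <- round(cfg$mixed_sample_fraction * nq)
  if (n_adm > 0 && cfg$n_pops < 2) stop("admixed queries need >= 2 populations")
  n_pure <- nq - n_dup - n_adm
  if (n_pure < 0) stop("duplicate and admixed fractions exceed 1")
  pops <- rownames(ref$truth$pop_freq[[1]])
  loci <- names(ref$truth$pop_freq)
  ids <- paste0("Q", formatC(seq_len(nq), width = 3, flag = "0"))
  a1 <- a2 <- matrix(NA_integer_, nq, length(loci), dimnames = list(ids, loci))
  qt <- data.frame(sample = ids, type = "pure", origin = NA_character_,
                   duplicate_of = NA_character_, mix_with = NA_character_,
                   stringsAsFactors = FALSE)
  # realized per-gene-copy ancestry (differs from the nominal mixture by
  # binomial sampling); one row per query, one column per population
  realized <- matrix(0, nq, length(ref$truth$pop_freq[[1]][, 1]),
                     dimnames = list(ids, rownames(ref$truth$pop_freq[[1]])))
  draw_copy <- function(k, l) sample_alleles(ref$truth$ladders[[l]], 1,
                                             prob = ref$truth$pop_freq[[l]][k, ])
  i <- 0L
  for (q in seq_len(n_pure)) {
    i <- i + 1L
    k <- ((q - 1L) %% length(pops)) + 1L
    qt$origin[i] <- pops[k]
    realized[i, k] <- 1
    for (l in seq_along(loci)) {
      a1[i, l] <- draw_copy(k, l); a2[i, l] <- draw_copy(k, l)
    }
  }
  for (q in seq_len(n_adm)) {
    i <- i + 1L
    qt$type[i] <- "admixed"
    qt$origin[i] <- paste(pops[cfg$mixing > 0], collapse = "/")
    for (l in seq_along(loci)) {
      k1 <- sample(length(pops), 1, prob = cfg$mixing)
      k2 <- sample(length(pops), 1, prob = cfg$mixing)
      a1[i, l] <- draw_copy(k1, l); a2[i, l] <- draw_copy(k2, l)
      realized[i, k1] <- realized[i, k1] + 1 / (2 * length(loci))
      realized[i, k2] <- realized[i, k2] + 1 / (2 * length(loci))
    }
  }
  if (n_dup > 0) {
    src <- sample(sample_ids(ref$genotypes), n_dup)
    for (q in seq_len(n_dup)) {
      i <- i + 1L
      qt$type[i] <- "duplicate"
      qt$duplicate_of[i] <- src[q]
      qt$origin[i] <- ref$truth$origin[src[q]]
      realized[i, qt$origin[i]] <- 1
      a1[i, ] <- ref$genotypes$a1[src[q], ]
      a2[i, ] <- ref$genotypes$a2[src[q], ]
    }
  }
  if (n_mix > 0) {            # earmark the first n_mix non-duplicate queries
    cand <- which(qt$type != "duplicate")[seq_len(n_mix)]
    partners <- sample(sample_ids(ref$genotypes), n_mix)
    qt$type[cand] <- ifelse(qt$type[cand] == "admixed", "admixed_mixed", "mixed")
    qt$mix_with[cand] <- partners
  }
  truth <- ref$truth
  truth$queries <- qt
  truth$realized_admixture <- realized
  list(genotypes = geno_matrix(a1, a2), truth = truth)
}

#' Simulate replicate-level PCR outcomes
#'
#' Per (sample, locus, replicate): heterozygous loci suffer an allelic
#' dropout event with probability \code{ado_rate} (one randomly chosen
#' allele vanishes, leaving an apparent homozygote); with probability
#' \code{fa_rate} a false allele replaces one true allele (heterozygotes) or
#' appears beside the true allele (homozygotes), its size drawn uniformly
#' from the locus's allele ladder augmented with the one-repeat stutter
#' neighbors of the true alleles (true alleles excluded). Samples
#' earmarked as mixtures emit the union of two individuals' alleles per
#' replicate, each allele subject to dropout independently.
#'
#' @param genotypes a \code{geno_matrix} of true genotypes
#' @param cfg a \code{\link{sim_config}}
#' @param truth optional truth list (from \code{\link{simulate_queries}});
#'   supplies allele ladders and mixture partners, and receives the injected
#'   error events
#' @param ref_genotypes reference \code{geno_matrix}, required when mixtures
#'   are earmarked in \code{truth}
#' @return list with \code{reps} (data.frame: sample, locus, rep, a1..a4)
#'   and \code{truth} (with an \code{error_events} data.frame appended)
#' @export
simulate_replicates <- function(genotypes, cfg, truth = NULL,
                                ref_genotypes = NULL) {
  set.seed(cfg$seed + 2L)
  loci <- locus_names(genotypes)
  ids <- sample_ids(genotypes)
  ladders <- if (!is.null(truth)) truth$ladders else
    stats::setNames(lapply(seq_along(loci), function(l)
      sort(unique(c(genotypes$a1[, l], genotypes$a2[, l])))), loci)
  mix_with <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(truth) && !is.null(truth$queries)) {
    qd <- truth$queries
    mix_with[qd$sample] <- qd$mix_with
  }
  rows <- vector("list", length(ids) * length(loci) * cfg$n_replicates)
  ev <- list()
  ri <- 0L
  for (i in seq_along(ids)) {
    partner <- mix_with[ids[i]]
    for (l in seq_along(loci)) {
      true_set <- unique(c(genotypes$a1[i, l], genotypes$a2[i, l]))
      true_set <- true_set[!is.na(true_set)]
      if (!is.na(partner)) {
        pa <- c(ref_genotypes$a1[partner, l], ref_genotypes$a2[partner, l])
        true_set <- unique(c(true_set, pa[!is.na(pa)]))
      }
      ladder <- ladders[[loci[l]]]
      fa_pool <- setdiff(unique(c(ladder, true_set - 2L, true_set + 2L)),
                         true_set)
      for (r in seq_len(cfg$n_replicates)) {
        ri <- ri + 1L
        obs <- true_set
        ado <- fa <- FALSE
        if (length(obs) == 0) {
          rows[[ri]] <- list(ids[i], loci[l], r, NA_integer_, NA_integer_,
                             NA_integer_, NA_integer_)
          next
        }
        if (length(obs) == 2L) {              # ordinary heterozygote
          if (stats::runif(1) < cfg$ado_rate) {
            obs <- obs[-sample.int(2L, 1L)]; ado <- TRUE
          }
        } else if (length(obs) > 2L) {        # mixture template
          drop <- stats::runif(length(obs)) < cfg$ado_rate / 2
          if (all(drop)) drop[sample.int(length(obs), 1L)] <- FALSE
          ado <- any(drop)
          obs <- obs[!drop]
        }
        if (length(fa_pool) && stats::runif(1) < cfg$fa_rate) {
          wrong <- if (length(fa_pool) == 1L) fa_pool else sample(fa_pool, 1L)
          if (length(obs) >= 2L) {
            obs[sample.int(length(obs), 1L)] <- wrong
          } else {
            obs <- c(obs, wrong)              # homozygote gains a spurious peak
          }
          fa <- TRUE
        }
        obs <- sort(unique(obs))
        obs4 <- c(obs, rep(NA_integer_, 4L - length(obs)))[1:4]
        rows[[ri]] <- list(ids[i], loci[l], r, obs4[1], obs4[2], obs4[3], obs4[4])
        if (ado || fa)
          ev[[length(ev) + 1L]] <- list(ids[i], loci[l], r, ado, fa)
      }
    }
  }
  reps <- do.call(rbind, lapply(rows, function(x)
    data.frame(sample = x[[1]], locus = x[[2]], rep = x[[3]], a1 = x[[4]],
               a2 = x[[5]], a3 = x[[6]], a4 = x[[7]],
               stringsAsFactors = FALSE)))
  events <- if (length(ev)) do.call(rbind, lapply(ev, function(x)
    data.frame(sample = x[[1]], locus = x[[2]], rep = x[[3]], ado = x[[4]],
               fa = x[[5]], stringsAsFactors = FALSE))) else
    data.frame(sample = character(), locus = character(), rep = integer(),
               ado = logical(), fa = logical())
  if (is.null(truth)) truth <- list()
  truth$error_events <- events
  list(reps = reps, truth = truth)
}

#' Simulate triplicate amelogenin sex-typing replicates
#'
#' True males emit an X and Y band pattern with the Y band dropping out with
#' probability \code{ado_rate}; females emit X only.
#'
#' @param sexes named character vector (\code{"male"}/\code{"female"})
#' @param cfg a \code{\link{sim_config}}
#' @param n_replicates replicates per sample (default 3)
#' @return named list of band-pattern replicate lists per sample, as accepted
#'   by \code{\link{call_sex}}
#' @export
simulate_sex_replicates <- function(sexes, cfg, n_replicates = 3L) {
  set.seed(cfg$seed + 3L)
  out <- lapply(sexes, function(s) {
    lapply(seq_len(n_replicates), function(r) {
      if (s == "male") {
        if (stats::runif(1) < cfg$ado_rate) "X" else c("X", "Y")
      } else "X"
    })
  })
  names(out) <- names(sexes)
  out
}
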