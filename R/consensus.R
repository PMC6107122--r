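#' Consensus genotype call for one (sample, locus) from replicate PCRs
#'
#' Implements the multi-tube rules used for low-template forensic samples:
#' an allele is *confirmed* when it is observed in at least two independent
#' replicates; a heterozygote \{a, b\} is called when a and b are both
#' confirmed and no third allele is confirmed; a homozygote a is called when
#' at least three replicates are exactly a/a and no second allele is
#' confirmed. Three or more confirmed alleles indicate a mixed template and
#' yield \code{no_call} with \code{extra_alleles} populated. Anything else is
#' \code{no_call}.
#'
#' @param reps list of replicate outcomes: each an integer vector of the
#'   alleles observed in that PCR (length 1 = single-allele observation,
#'   length 2 = allele pair, length 0 or \code{NULL} = failed reaction).
#' @return list with \code{status} (\code{"homozygote"}, \code{"heterozygote"}
#'   or \code{"no_call"}), \code{alleles}, \code{support} (named per-allele
#'   replicate counts), \code{extra_alleles}.
#' @export
call_consensus_locus <- function(reps) {
  reps <- lapply(reps, function(r) unique(as.integer(r[!is.na(r)])))
  reps <- reps[vapply(reps, length, 1L) > 0]
  out <- list(status = "no_call", alleles = integer(0),
              support = integer(0), extra_alleles = integer(0))
  if (!length(reps)) return(out)
  alle <- sort(unique(unlist(reps)))
  support <- vapply(alle, function(a)
    sum(vapply(reps, function(r) a %in% r, TRUE)), 1L)
  names(support) <- as.character(alle)
  out$support <- support
  confirmed <- alle[support >= 2L]
  if (length(confirmed) >= 3L) {
    out$extra_alleles <- confirmed
    return(out)
  }
  if (length(confirmed) == 2L) {
    out$status <- "heterozygote"
    out$alleles <- confirmed
    return(out)
  }
  if (length(confirmed) == 1L) {
    a <- confirmed
    n_exact_hom <- sum(vapply(reps, function(r) identical(r, a), TRUE))
    if (n_exact_hom >= 3L) {
      out$status <- "homozygote"
      out$alleles <- a
    }
  }
  out
}

#' Consensus genotypes and QC flags for one sample
#'
#' Applies \code{\link{call_consensus_locus}} across loci, then two
#' sample-level screens: a mixed-template flag when the number of loci with
#' three or more confirmed alleles reaches \code{mixed_locus_threshold}, and
#' a low-success flag when the fraction of loci yielding a call falls below
#' \code{completeness}.
#'
#' @param reps_by_locus named list (per locus) of replicate outcome lists, as
#'   accepted by \code{\link{call_consensus_locus}}
#' @param mixed_locus_threshold loci with >= 3 confirmed alleles needed to
#'   flag the sample as a mixture (default 1)
#' @param completeness minimum fraction of called loci (default 0.5)
#' @return list with \code{calls} (per-locus consensus list), \code{a1},
#'   \code{a2} (named allele vectors, \code{NA} for no_call), \code{flags}
#'   (subset of \code{"excluded_mixed"}, \code{"low_success"})
#' @export
call_consensus_sample <- function(reps_by_locus, mixed_locus_threshold = 1L,
                                  completeness = 0.5) {
  calls <- lapply(reps_by_locus, call_consensus_locus)
  loci <- names(reps_by_locus)
  a1 <- a2 <- stats::setNames(rep(NA_integer_, length(loci)), loci)
  for (l in seq_along(calls)) {
    cl <- calls[[l]]
    if (cl$status == "homozygote") a1[l] <- a2[l] <- cl$alleles
    if (cl$status == "heterozygote") { a1[l] <- cl$alleles[1]; a2[l] <- cl$alleles[2] }
  }
  n_mixed <- sum(vapply(calls, function(cl) length(cl$extra_alleles) >= 3L, TRUE))
  called_frac <- mean(!is.na(a1))
  flags <- character(0)
  if (n_mixed >= mixed_locus_threshold) flags <- c(flags, "excluded_mixed")
  if (called_frac <= completeness + 1e-12) flags <- c(flags, "low_success")
  list(calls = calls, a1 = a1, a2 = a2, flags = flags,
       n_mixed_loci = n_mixed, called_fraction = called_frac)
}

#' Sex call from replicated amelogenin band patterns
#'
#' The X-linked amelogenin fragment amplifies in both sexes; the shorter
#' Y fragment marks males. A sample is called male when X and Y bands appear
#' together in at least two of three replicates, female when exactly three
#' replicates amplified and every one shows the X band only; anything else is
#' inconclusive.
#'
#' @param reps list of band patterns, each a character vector drawn from
#'   \code{c("X", "Y")} (length 0 / \code{NULL} = failed reaction)
#' @return one of \code{"male"}, \code{"female"}, \code{"inconclusive"}
#' @export
call_sex <- function(reps) {
  pat <- lapply(reps, function(r) unique(as.character(r[!is.na(r)])))
  nonfailed <- pat[vapply(pat, length, 1L) > 0]
  xy <- sum(vapply(nonfailed, function(r) all(c("X", "Y") %in% r), TRUE))
  if (xy >= 2L) return("male")
  x_only <- vapply(nonfailed, function(r) identical(sort(r), "X"), TRUE)
  any_y <- any(vapply(nonfailed, function(r) "Y" %in% r, TRUE))
  if (!any_y && length(nonfailed) == 3L && all(x_only)) return("female")
  "inconclusive"
}

#' Estimate allelic dropout and false allele rates from replicates
#'
#' Scores replicates against their consensus calls. Allelic dropout (ADO):
#' among non-failed replicates of loci with a heterozygous consensus, the
#' fraction appearing as a clean homozygote for exactly one of the two
#' consensus alleles. False alleles (FA): among non-failed replicates of all
#' called loci, the fraction containing at least one allele absent from the
#' consensus genotype. Both the per-replicate pooled rates and a per-locus
#' breakdown are returned; zero-denominator rates are \code{NA}, never 0.
#'
#' @param reps data.frame with columns \code{sample}, \code{locus},
#'   \code{rep} and allele columns \code{a1}, \code{a2}, ... (all \code{NA}
#'   = failed reaction; a single non-\code{NA} allele = single-allele
#'   observation; more than two record multi-peak patterns from mixed
#'   templates)
#' @param consensus a \code{geno_matrix} of consensus genotypes for the same
#'   samples and loci (uncalled loci \code{NA})
#' @return list of class \code{error_rates}: \code{ado_rate}, \code{fa_rate},
#'   \code{per_locus} data.frame, denominator counts
#' @export
estimate_error_rates <- function(reps, consensus) {
  loci <- locus_names(consensus)
  ids <- sample_ids(consensus)
  tab <- data.frame(locus = loci, ado_num = 0L, ado_den = 0L,
                    fa_num = 0L, fa_den = 0L)
  sidx <- match(reps$sample, ids)
  lidx <- match(reps$locus, loci)
  keep <- !is.na(sidx) & !is.na(lidx)
  reps <- reps[keep, ]; sidx <- sidx[keep]; lidx <- lidx[keep]
  acols <- grep("^a[0-9]+$", names(reps))
  amat <- as.matrix(reps[, acols, drop = FALSE])
  for (r in seq_len(nrow(reps))) {
    obs <- unique(amat[r, ])
    obs <- obs[!is.na(obs)]
    if (!length(obs)) next                      # failed reaction
    c1 <- consensus$a1[sidx[r], lidx[r]]; c2 <- consensus$a2[sidx[r], lidx[r]]
    if (is.na(c1)) next                         # locus not called
    cons <- unique(c(c1, c2))
    l <- lidx[r]
    tab$fa_den[l] <- tab$fa_den[l] + 1L
    if (any(!obs %in% cons)) tab$fa_num[l] <- tab$fa_num[l] + 1L
    if (c1 != c2) {                             # heterozygous consensus
      tab$ado_den[l] <- tab$ado_den[l] + 1L
      if (length(obs) == 1L && obs %in% cons)
        tab$ado_num[l] <- tab$ado_num[l] + 1L
    }
  }
  rate <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tab$ado_rate <- rate(tab$ado_num, tab$ado_den)
  tab$fa_rate <- rate(tab$fa_num, tab$fa_den)
  structure(list(
    ado_rate = rate(sum(tab$ado_num), sum(tab$ado_den)),
    fa_rate = rate(sum(tab$fa_num), sum(tab$fa_den)),
    ado_rate_locus_mean = mean(tab$ado_rate, na.rm = TRUE),
    fa_rate_locus_mean = mean(tab$fa_rate, na.rm = TRUE),
    per_locus = tab,
    n_ado_replicates = sum(tab$ado_den),
    n_fa_replicates = sum(tab$fa_den)), class = "error_rates")
}

#' @export
print.error_rates <- function(x, ...) {
  cat(sprintf("error_rates: ADO %.3f (n=%d), FA %.3f (n=%d)\n",
              x$ado_rate, x$n_ado_replicates, x$fa_rate, x$n_fa_replicates))
  invisible(x)
}

#' Consensus-call a whole replicate table
#'
#' Convenience wrapper: groups a long replicate table by sample, applies
#' \code{\link{call_consensus_sample}}, and assembles the calls into a
#' \code{geno_matrix} plus a QC table.
#'
#' @inheritParams estimate_error_rates
#' @param loci locus order for the output (default: order of appearance)
#' @param ... passed to \code{\link{call_consensus_sample}}
#' @return list with \code{genotypes} (a \code{geno_matrix}) and \code{qc}
#'   (data.frame: sample, flags, n_mixed_loci, called_fraction)
#' @export
consensus_genotypes <- function(reps, loci = NULL, ...) {
  if (is.null(loci)) loci <- unique(reps$locus)
  samples <- unique(reps$sample)
  a1 <- a2 <- matrix(NA_integer_, length(samples), length(loci),
                     dimnames = list(samples, loci))
  qc <- data.frame(sample = samples,
                   flags = character(length(samples)),
                   n_mixed_loci = integer(length(samples)),
                   called_fraction = rep(NA_real_, length(samples)),
                   stringsAsFactors = FALSE)
  acols <- grep("^a[0-9]+$", names(reps))
  for (i in seq_along(samples)) {
    sub <- reps[reps$sample == samples[i], ]
    rbl <- lapply(loci, function(l) {
      s2 <- sub[sub$locus == l, ]
      lapply(seq_len(nrow(s2)), function(r) {
        v <- unlist(s2[r, acols], use.names = FALSE); v[!is.na(v)]
      })
    })
    names(rbl) <- loci
    res <- call_consensus_sample(rbl, ...)
    a1[i, ] <- res$a1; a2[i, ] <- res$a2
    qc$flags[i] <- paste(res$flags, collapse = ";")
    qc$n_mixed_loci[i] <- res$n_mixed_loci
    qc$called_fraction[i] <- res$called_fraction
  }
  list(genotypes = geno_matrix(a1, a2), qc = qc)
}
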