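#' Per-method assignment thresholds and the agreement rule
#'
#' Defaults encode the conservative forensic criteria: admixture Q-score at
#' least 0.70 (values below mark a sample as admixed), each of the two
#' GeneClass-style likelihoods strictly above 0.99, DAPC posterior at least
#' 0.90, and agreement of at least 3 of the 4 methods on the same population.
#' The comparison operators differ deliberately: the Q-score rule is
#' inclusive and the likelihood rule strict.
#'
#' @param structure_q_min minimum admixture Q (inclusive, default 0.70)
#' @param geneclass_min likelihood threshold, applied strictly (\code{>}) to
#'   each of the frequency and Bayesian methods separately (default 0.99)
#' @param dapc_min minimum DAPC posterior (inclusive, default 0.90)
#' @param methods_required methods that must agree (default 3)
#' @return list of class \code{method_thresholds}
#' @export
method_thresholds <- function(structure_q_min = 0.70, geneclass_min = 0.99,
                              dapc_min = 0.90, methods_required = 3L) {
  stopifnot(structure_q_min > 0, structure_q_min <= 1,
            geneclass_min > 0, geneclass_min <= 1,
            dapc_min > 0, dapc_min <= 1,
            methods_required %in% 1:4)
  structure(list(structure_q_min = structure_q_min,
                 geneclass_min = geneclass_min, dapc_min = dapc_min,
                 methods_required = as.integer(methods_required)),
            class = "method_thresholds")
}

#' Final forensic assignment for one sample from four method score rows
#'
#' Applies the per-method thresholds and the agreement rule: a method
#' "passes" for population p when its score for p meets its threshold
#' (admixture Q >= \code{structure_q_min}; each GeneClass-style method
#' > \code{geneclass_min}; DAPC >= \code{dapc_min}). The sample is assigned
#' to p when at least \code{methods_required} methods pass for the same p;
#' otherwise it is reported unassigned/admixed.
#'
#' @param scores named list with numeric score vectors (named by candidate
#'   population) for methods \code{structure_q}, \code{geneclass_freq},
#'   \code{geneclass_bayes}, \code{dapc}
#' @param t a \code{\link{method_thresholds}}
#' @return list with \code{status} (\code{"assigned"} or
#'   \code{"unassigned_admixed"}), \code{population} (\code{NA} when
#'   unassigned), \code{n_support}, and \code{method_pass} (named character
#'   vector: passing population per method or \code{NA})
#' @export
consensus_assign <- function(scores, t = method_thresholds()) {
  methods <- c("structure_q", "geneclass_freq", "geneclass_bayes", "dapc")
  if (!all(methods %in% names(scores)))
    stop("missing method score row(s): ",
         paste(setdiff(methods, names(scores)), collapse = ", "))
  passing <- function(v, thr, strict) {
    ok <- if (strict) v > thr else v >= thr
    if (any(ok)) names(v)[which.max(v)] else NA_character_
  }
  mp <- c(structure_q = passing(scores$structure_q, t$structure_q_min, FALSE),
          geneclass_freq = passing(scores$geneclass_freq, t$geneclass_min, TRUE),
          geneclass_bayes = passing(scores$geneclass_bayes, t$geneclass_min, TRUE),
          dapc = passing(scores$dapc, t$dapc_min, FALSE))
  votes <- table(mp[!is.na(mp)])
  if (length(votes) && max(votes) >= t$methods_required) {
    pop <- names(votes)[which.max(votes)]
    list(status = "assigned", population = pop,
         n_support = as.integer(max(votes)), method_pass = mp)
  } else {
    list(status = "unassigned_admixed", population = NA_character_,
         n_support = if (length(votes)) as.integer(max(votes)) else 0L,
         method_pass = mp)
  }
}

#' Load the packaged per-sample method scores of the seizure case study
#'
#' The packaged fixture transcribes the printed per-method, per-population
#' scores (admixture Q, two GeneClass-style likelihoods, DAPC posterior) of
#' the 15 confiscated tiger samples, 14 of them scored and one failed at
#' genotyping QC.
#'
#' @return data.frame, one row per sample
#' @export
table1_scores <- function() {
  path <- system.file("extdata", "table1_scores.csv", package = "forensat")
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Re-derive the case study's forensic assignments from its printed scores
#'
#' Applies \code{\link{consensus_assign}} to every scored sample of the
#' packaged fixture and tallies the outcome per population. The sample whose
#' genotyping failed QC is carried through with status \code{failed_qc}.
#'
#' @param t a \code{\link{method_thresholds}}
#' @return list with \code{calls} (data.frame: sample, status, population,
#'   n_support) and \code{counts} (named integer vector: per-population
#'   assigned counts, \code{unassigned}, \code{failed_qc}, \code{assigned})
#' @export
run_table1_fixture <- function(t = method_thresholds()) {
  df <- table1_scores()
  pops <- c("BNP", "SWR", "CNP")
  calls <- data.frame(sample = df$sample, status = NA_character_,
                      population = NA_character_, n_support = NA_integer_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    if (is.na(df$structure_q_BNP[i])) {
      calls$status[i] <- "failed_qc"
      next
    }
    sc <- list(
      structure_q = stats::setNames(as.numeric(df[i, paste0("structure_q_", pops)]), pops),
      geneclass_freq = stats::setNames(as.numeric(df[i, paste0("geneclass_freq_", pops)]), pops),
      geneclass_bayes = stats::setNames(as.numeric(df[i, paste0("geneclass_bayes_", pops)]), pops),
      dapc = stats::setNames(as.numeric(df[i, paste0("dapc_", pops)]), pops))
    res <- consensus_assign(sc, t)
    calls$status[i] <- res$status
    calls$population[i] <- res$population
    calls$n_support[i] <- res$n_support
  }
  counts <- c(vapply(pops, function(p)
                sum(calls$population == p, na.rm = TRUE), 1L),
              unassigned = sum(calls$status == "unassigned_admixed"),
              failed_qc = sum(calls$status == "failed_qc"),
              assigned = sum(calls$status == "assigned"))
  list(calls = calls, counts = counts)
}

#' End-to-end forensic pipeline on replicate-level query data
#'
#' Orchestrates the full inference chain: replicate consensus calling with
#' QC (mixed-template and low-success screens), exact-profile matching
#' against the reference database, the four assignment methods (supervised
#' admixture Q averaged over aligned chains, frequency and Bayesian
#' assignment, DAPC), and the thresholded agreement rule. A sample failing
#' QC is reported \code{failed_qc} and skipped by the assignment stages;
#' a failure in one sample never aborts the batch.
#'
#' @param refs reference \code{geno_matrix} with known population labels
#' @param query_reps replicate table for the query samples (see
#'   \code{\link{estimate_error_rates}} for the layout)
#' @param thresholds a \code{\link{method_thresholds}}
#' @param mcmc an \code{\link{mcmc_options}} for the supervised admixture
#'   stage; its K is set to the number of reference populations
#' @param max_mismatch,min_loci matching parameters (see
#'   \code{\link{match_genotypes}})
#' @param n_struct_runs aligned chains averaged for the Q-scores (default 3)
#' @return list with \code{report} (per-sample data.frame), \code{qc},
#'   \code{matches}, \code{scores} (per-method \code{pop_scores}),
#'   \code{consensus} (the called query \code{geno_matrix})
#' @export
full_pipeline <- function(refs, query_reps, thresholds = method_thresholds(),
                          mcmc = NULL, max_mismatch = 0L, min_loci = 6L,
                          n_struct_runs = 3L) {
  pops <- sort(unique(refs$pop[refs$pop_known]))
  cons <- consensus_genotypes(query_reps, loci = locus_names(refs))
  qc <- cons$qc
  nq <- nrow(qc)
  report <- data.frame(sample = qc$sample, qc_flags = qc$flags,
                       matched_ref = rep(NA_character_, nq),
                       status = rep(NA_character_, nq),
                       population = rep(NA_character_, nq),
                       n_support = rep(NA_integer_, nq),
                       stringsAsFactors = FALSE)
  if (!nrow(report))
    return(list(report = report, qc = qc, matches = NULL, scores = NULL,
                consensus = cons$genotypes))
  ok <- !grepl("excluded_mixed|low_success", qc$flags)
  report$status[!ok] <- "failed_qc"
  scores <- list()
  matches <- NULL
  if (any(ok)) {
    q <- cons$genotypes[ok, ]
    matches <- tryCatch(
      match_genotypes(q, refs, max_mismatch = max_mismatch,
                      min_loci = min_loci),
      error = function(e) NULL)
    if (!is.null(matches) && nrow(matches)) {
      first <- matches[!duplicated(matches$query), ]
      report$matched_ref[match(first$query, report$sample)] <- first$ref
    }
    if (is.null(mcmc))
      mcmc <- mcmc_options(K = length(pops), seed = 1L, supervised = TRUE,
                           n_runs = n_struct_runs)
    mcmc$K <- length(pops); mcmc$supervised <- TRUE
    combined <- rbind_geno(refs, q)
    runs <- lapply(seq_len(n_struct_runs), function(r) {
      o <- mcmc; o$seed <- as.integer(mcmc$seed + r)
      run_admixture(combined, o)
    })
    q_avg <- align_runs(runs)
    q_rows <- q_avg[sample_ids(q), pops, drop = FALSE]
    freqs <- allele_frequencies(refs)
    sc_freq <- assign_frequency(q, freqs)
    sc_bayes <- assign_bayesian(q, freqs)
    model <- dapc_fit(refs)
    sc_dapc <- dapc_predict(model, q)
    scores <- list(structure_q = q_rows, geneclass_freq = sc_freq,
                   geneclass_bayes = sc_bayes, dapc = sc_dapc)
    for (s in sample_ids(q)) {
      res <- tryCatch(consensus_assign(list(
        structure_q = q_rows[s, ],
        geneclass_freq = sc_freq$scores[s, pops],
        geneclass_bayes = sc_bayes$scores[s, pops],
        dapc = sc_dapc$scores[s, pops]), thresholds),
        error = function(e) list(status = "error", population = NA_character_,
                                 n_support = NA_integer_))
      i <- match(s, report$sample)
      report$status[i] <- res$status
      report$population[i] <- res$population
      report$n_support[i] <- res$n_support
    }
  }
  list(report = report, qc = qc, matches = matches, scores = scores,
       consensus = cons$genotypes)
}
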