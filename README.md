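# forensat

Forensic microsatellite genotyping and population assignment for wildlife
casework. The package implements the full inference chain used to identify
individuals and the geographic source of confiscated animal parts from
short-tandem-repeat (STR) profiles: replicate-based consensus
genotype and sex calling, identity statistics, Bayesian admixture-model
clustering, three independent population-assignment engines, and a
thresholded multi-method agreement rule that produces the final forensic
call. A Balding–Nichols simulator generates reference populations, query
samples and replicate-level PCR data with complete ground truth, so every
stage can be exercised and audited without access to a real (and typically
confidential) reference database.

Who it is for: molecular ecologists and wildlife-forensics labs that type
degraded samples (skin, bone, scat, blood swabs) at a small panel of
multi-allelic microsatellite loci against a geo-referenced reference
database, and need reproducible, defensible assignment calls.

## Methods at the core

* **Multi-tube consensus calling.** Low-template DNA is typed in several
  independent PCRs. A homozygote *a/a* is called only after ≥ 3 identical
  homozygous replicates; a heterozygote \{a, b\} only after each allele is
  seen in ≥ 2 independent replicates; three or more confirmed alleles flag a
  mixed template. Allelic dropout (ADO) and false allele (FA) rates are
  estimated per replicate against the consensus.
* **Probability of identity.** For allele frequencies *aᵢ* at a locus,
  `PID = 2(Σaᵢ²)² − Σaᵢ⁴` and
  `PID_sibs = 0.25 + 0.5Σaᵢ² + 0.5(Σaᵢ²)² − 0.25Σaᵢ⁴`,
  multiplied across loci — the panel's power to distinguish individuals
  (unrelated, or full siblings).
* **Admixture-model MCMC.** A Gibbs sampler (Rcpp) over cluster allele
  frequencies *P* (Dirichlet(λ) priors), per-individual admixture
  proportions *Q* (symmetric Dirichlet(α), α learned by a Metropolis step)
  and latent allele origins *Z*; supervised mode anchors each reference
  individual's gene copies to its known population. Model selection by mean
  model score `L(K) = mean(lnL) − var(lnL)/2` and by the Evanno ΔK second
  difference; label switching across chains resolved by exhaustive
  permutation alignment and averaging (CLUMPP-style).
* **Assignment engines.** (i) frequency-based assignment likelihood (HWE
  genotype probability under each population's frequencies, unseen alleles
  floored at 0.01); (ii) Bayesian Dirichlet posterior-predictive assignment
  (prior 1/k per allele); (iii) DAPC — PCA of allele dummy vectors followed
  by linear discriminant analysis, with posterior membership from
  Mahalanobis distances in discriminant space.
* **Forensic consensus rule.** A sample is assigned to a population only
  when ≥ 3 of the 4 methods pass their thresholds for the *same* population
  (admixture Q ≥ 0.70, each likelihood method > 0.99, DAPC ≥ 0.90);
  otherwise it is reported unassigned/admixed. Exact-profile matching
  against the reference database (GenAlEx-style) runs first and can
  identify a known individual outright.
* **Supporting statistics.** Multi-allelic Weir–Cockerham F_ST,
  individual-level Nei standard distance, and UPGMA trees (via
  `hclust`/`ape`) for outlier screening.

Genotypes are read and written in GenePop, STRUCTURE and CSV dialects.

## Worked example

The packaged case study ships the printed per-method scores of 15 seized
tiger samples scored against three Nepalese source populations (Bardia,
BNP; Shuklaphanta, SWR; Chitwan, CNP). Re-deriving the final calls:

```r
library(forensat)
res <- run_table1_fixture()
res$counts
#>        BNP        SWR        CNP unassigned  failed_qc   assigned
#>          6          2          1          5          1          9
```

Six samples assign to BNP, two to SWR, one to CNP; five samples fail the
3-of-4 agreement rule and are reported admixed/unassigned; one sample
failed genotyping QC. `res$calls` holds the per-sample verdicts, e.g.
sample F-NP-0010 is assigned BNP on 3 supporting methods (its Bayesian
likelihood, 0.984, misses the strict > 0.99 bar).

The same chain runs end-to-end on synthetic data with known truth:

```r
cfg <- sim_config(seed = 11, fst = 0.2, n_per_pop = 30, n_queries = 8,
                  duplicate_fraction = 0.25, mixed_sample_fraction = 0.125)
ref <- simulate_reference(cfg)
qs  <- simulate_queries(cfg, ref)
rr  <- simulate_replicates(qs$genotypes, cfg, truth = qs$truth,
                           ref_genotypes = ref$genotypes)
out <- full_pipeline(ref$genotypes, rr$reps,
                     mcmc = mcmc_options(K = 3, seed = 11, supervised = TRUE))
out$report
#>   sample                   qc_flags matched_ref    status population n_support
#> 1   Q001 excluded_mixed;low_success        <NA> failed_qc       <NA>        NA
#> 2   Q002                                   <NA>  assigned       pop2         4
#> ...
#> 7   Q007                                   R012  assigned       pop1         4
#> 8   Q008                                   R042  assigned       pop2         4
```

The planted two-template mixture (Q001) is excluded at QC; the two planted
re-samples of reference individuals (Q007, Q008) are matched back to their
source profiles (R012, R042) at zero mismatches; pure queries are assigned
to their true populations with all four methods agreeing. On this
reference panel the identity statistics print
`PID = 1.35e-08 ; PID(sibs) = 0.000827` — comfortably below the 0.01
operational bar for individual identification.

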