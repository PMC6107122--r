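---
title: "Forensic microsatellite assignment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forensic microsatellite assignment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forensat)
```

forensat implements the inference chain of wildlife molecular forensics on
multi-allelic microsatellite (STR) panels: from replicate-level PCR
outcomes to a final, thresholded geographic assignment of samples of
unknown origin. This vignette explains each model, the parameters that
matter, what the bundled simulator does and does not emulate, and the
design decisions taken where the methodology is genuinely open.

## The genotype container

A `geno_matrix` stores unordered diploid allele pairs (integer fragment
sizes in base pairs) per sample and locus, with an optional population
label per sample. Missingness is all-or-nothing per call: half-calls are
normalized to fully missing with a warning, because every downstream
statistic (identity probabilities, assignment likelihoods, the admixture
model) is defined on complete diploid genotypes. Sample and population
identifiers are opaque, case-sensitive strings — forensic IDs are never
normalized. GenePop (2- and 3-digit codes auto-detected, all-zero codes
missing), STRUCTURE (one- and two-row dialects, `-9` missing) and a simple
`a/b`-cell CSV are supported, with bit-exact read/write round-trips; the
GenePop writer groups samples into population blocks, which reorders rows.

## Multi-tube consensus calling

Degraded samples are typed in `n_replicates` independent PCRs (default 4,
configurable). The calling rules, applied per (sample, locus):

* an allele is **confirmed** when observed in at least 2 replicates;
* **heterozygote** \{a, b\}: both alleles confirmed and no third allele
  confirmed (the two alleles need not co-occur in one replicate);
* **homozygote** a: at least 3 replicates that are exactly a/a, and no
  second allele confirmed; discordant extra replicates do not veto unless
  they confirm another allele;
* ≥ 3 confirmed alleles: no call, and the locus is recorded as
  multi-allelic — `mixed_locus_threshold` such loci (default 1) flag the
  sample as a probable two-animal mixture (`excluded_mixed`);
* a sample whose fraction of called loci is at or below `completeness`
  (default 0.5) is flagged `low_success`. The at-threshold case flags
  deliberately: a profile with only half its loci is not safely matchable.

Sex is called from triplicate amelogenin band patterns: male when X and Y
co-amplify in ≥ 2 of 3 replicates, female only when exactly three
replicates amplified and all show X alone. Note the asymmetry: systematic
Y dropout can in principle produce a false female; the rule mirrors
standard bench practice and the simulator lets you quantify that risk.

### Error-rate estimation

Rates are scored per replicate against the consensus. ADO: among non-failed
replicates of heterozygous-consensus loci, the fraction appearing as a
clean apparent homozygote for exactly one consensus allele. FA: among
non-failed replicates of called loci, the fraction containing any allele
absent from the consensus. Two conventions deserve a note:

* a replicate showing one consensus allele *plus* a spurious allele scores
  as FA only, not ADO — otherwise a high FA rate would contaminate the ADO
  estimate;
* the simulator injects dropout as a per-replicate *event* (one randomly
  chosen allele of a heterozygote vanishes with probability `ado_rate`), so
  the injected rate and the per-replicate estimator are on the same scale
  and round-trip within binomial noise. The alternative per-allele
  parameterization would make the estimator read roughly twice the nominal
  rate.

Zero-denominator rates are reported `NA`, never 0.

An inherent limit of the confirm-at-2 rule is worth knowing: at a high FA
rate (the regime simulated below is 16% per replicate), two false-allele
events at the same locus collide on the same spurious size with
probability roughly one over the size-ladder pool, fabricating a confirmed
heterozygote from a true homozygote. With 4 replicates this puts the
expected consensus accuracy among called loci near 99%, not above it; the
acceptance suite measures exactly this.

## Identity statistics

Per locus with allele frequencies $a_i$:
$PID = 2(\sum a_i^2)^2 - \sum a_i^4$ and
$PID_{sibs} = 0.25 + 0.5\sum a_i^2 + 0.5(\sum a_i^2)^2 - 0.25\sum a_i^4$;
multi-locus values are products (loci assumed independent). Monomorphic
loci contribute 1 and are flagged uninformative. The test suite proves the
PID form against exhaustive enumeration of genotype pairs under
Hardy–Weinberg equilibrium. Profile matching compares unordered allele
pairs over loci non-missing in both profiles, with `max_mismatch`
(default 0) and `min_loci` (default 6, tolerating partial 8-locus
profiles). Weir–Cockerham $\theta$ is computed from per-allele variance
components summed over alleles and loci; individual-level Nei distance
treats each individual as a two-copy population (frequencies 0/0.5/1),
drops missing loci pairwise, and reports an infinite-distance sentinel
when two profiles share no alleles (UPGMA then caps it at 1.5 times the
largest finite distance, with a warning). UPGMA itself is average-linkage
`hclust` converted to an ultrametric `ape` tree.

## The admixture model

The Gibbs sampler (compiled, Rcpp) targets the classic admixture model
with independent allele frequencies: cluster frequencies
$P_{k,l} \sim \mathrm{Dirichlet}(\lambda)$ (default $\lambda = 1$),
admixture vectors $Q_i \sim \mathrm{Dirichlet}(\alpha, \ldots, \alpha)$,
latent origins $Z$ per gene copy, and a Metropolis random walk on $\alpha$
(uniform prior on $(0, \alpha_{max}]$, default $\alpha_{max} = 10$,
proposal sd 0.05). The correlated-frequencies F-model is not implemented;
at the differentiation levels simulated here the independent model assigns
essentially identically and is fully verifiable against its primary
literature. Missing genotypes contribute nothing to any update.

**Supervised mode.** Reference individuals (known population) have their
gene copies' $Z$ fixed to their labeled cluster, anchoring that cluster's
frequencies; queries are updated freely. This is a deliberate
simplification of location-prior machinery: it is transparent, and its one
behavioral subtlety is documented here — because anchored individuals are
exactly pure by construction, they must not inform $\alpha$, or the
hyperparameter collapses toward zero and forces genuinely admixed queries
into spurious purity. The default `alpha_from = "unknown"` therefore
learns $\alpha$ from the free individuals only; the flip side is that
$\alpha$ is weakly identified when very few queries are present, so
supervised runs are best made on a batch of queries (the realistic
forensic situation). `alpha_from = "all"` is available for unsupervised
workflows.

**Model selection.** Each run reports
$L(K) = \mathrm{mean}(\ln L) - \mathrm{var}(\ln L)/2$ over the retained
trace. `evanno_delta_k` computes, per interior $K$, the mean absolute
per-run second difference of $L$ divided by the between-run standard
deviation; it is undefined (reported `NA`, never infinite) at the grid
edges and wherever the run spread is zero. Both criteria are reported and
neither is privileged: on simulated three-population data at moderate
differentiation ($F_{ST} = 0.2$) ΔK tends to select $K = 2$ while the mean
model score peaks at the true $K = 3$ — the same disagreement the
forensic literature reports on real reference panels, usually resolved in
favor of the mean-likelihood/Q-plot reading. At strong differentiation
($F_{ST} = 0.35$) both criteria agree on $K = 3$; the acceptance suite
fixes exactly these two regimes.

**Label switching.** `align_runs` exhaustively searches the $K!$ column
permutations (capped at $K \le 8$) maximizing dot-product similarity with
the first run, then averages and renormalizes — small-K exact alignment
in the CLUMPP spirit.

**Chain lengths.** Desk-scale defaults are 5,000 burn-in and 20,000
retained sweeps, thinned by 10, with 10 independent chains; on an
8-locus, ~100-individual panel one chain runs in roughly a second, so a
full $K = 1..6$ grid with 10 chains per $K$ stays within a couple of
minutes. The K-grid analyses in the test suite use 2,000/8,000 sweeps,
which already reproduce the full-length selection behavior on these
panel sizes. Production settings of external tools (hundreds of thousands
of sweeps) remain configurable but are unnecessary at this problem size.

## Assignment engines and the consensus rule

* **Frequency method**: per population, the product over non-missing loci
  of the HWE genotype probability; alleles unobserved in a population are
  floored at `missing_allele_freq = 0.01` and the vector renormalized —
  the floor keeps log-likelihoods finite and is applied symmetrically to
  both likelihood methods' inputs.
* **Bayesian method**: Dirichlet(1/k) prior per locus (k = alleles observed
  dataset-wide) updated by the population's allele counts; the query
  genotype's posterior-predictive probability has the closed forms tested
  against Monte-Carlo Dirichlet integration in the suite.
* **DAPC**: individuals become allele relative-frequency dummy vectors
  (0/0.5/1; missing reference loci imputed by population means, missing
  query loci by the global center), centered, reduced by PCA (`n_pca`
  defaults to the smallest axis count reaching 90% cumulative variance,
  capped at n/3), then canonical discriminant analysis with a whitening
  scaling, so posterior membership is
  $\propto \exp(-d^2/2)$ on Euclidean distances to group means in
  discriminant space with equal priors. A vanishing pooled within-group
  covariance (perfectly separated groups) is ridge-regularized and
  flagged. The suite cross-checks group separation against an independent
  `MASS::lda` fit.

Every engine returns per-population scores normalized to sum to 1.

**Decision layer.** Thresholds follow the conservative forensic
convention: admixture Q ≥ 0.70 (inclusive), each likelihood method > 0.99
(strict), DAPC ≥ 0.90, and at least 3 of the 4 methods must pass for the
*same* population. The two likelihood engines count as independent votes.
The DAPC cutoff is the least standardized of the four in practice, so the
packaged case study is asserted to be invariant over `dapc_min` in
[0.90, 0.99]. The rule is monotone: raising any threshold or the vote
count never converts an unassigned sample into an assigned one.

## What the simulator emulates — and what it does not

`sim_config` defaults encode the study conditions the package targets:
3 source populations under the Balding–Nichols model (population
frequencies Dirichlet-drawn around flat-Dirichlet ancestral frequencies
with concentration $(1-F)/F$, default $F = 0.15$, HWE within populations),
8 loci with 6–10 alleles on contiguous dinucleotide ladders, tens of
individuals per population, and replicate noise at `ado_rate = 0.025`,
`fa_rate = 0.16`, 4 replicates — error rates of the magnitude reported
for noninvasive and forensic STR work. Queries can be pure, 50/50 admixed
(gene-copy-wise, so the realized ancestry fraction is itself binomially
distributed around 0.5 — recorded in `truth$realized_admixture`),
verbatim duplicates of reference individuals, or two-template mixtures
realized at the replicate stage as the union of two individuals' alleles.
False-allele sizes are drawn from the locus ladder plus one-repeat stutter
neighbors of the true alleles; dropout is a per-replicate event as
described above. Everything is deterministic given the seed, and every
generated datum is traceable to `SimTruth`.

Not emulated: per-locus error-rate heterogeneity, null alleles, linkage,
peak-height/stutter electropherogram structure, mutation or coalescent
history, and spatial landscape effects. Passing recovery tests on this
generator therefore demonstrates correctness of the *inference chain*
under its stated statistical assumptions — not robustness to every
pathology of real degraded-sample data.

## Numerical choices and degenerate inputs

Likelihood normalizations use log-sum-exp; allele-frequency cells with
zero observed gene copies are `NA` (unavailable), never 0; Dirichlet draws
are clamped away from exact zero; the UPGMA infinite-distance cap and the
DAPC ridge are described above; `evanno_delta_k` requires ≥ 2 runs and ≥ 3
consecutive K. Consensus calling treats any degenerate replicate input as
`no_call` rather than an error. One failing sample never aborts a
`full_pipeline` batch.

## Known limitations

* Supervised admixture Q-scores are soft at 8 loci and moderate
  differentiation: a pure-origin query typically lands near, and
  sometimes just below, Q = 0.9, and strongly lopsided realized admixture
  is amplified by the corner-favoring small-$\alpha$ prior. The
  likelihood and DAPC engines are the sharp instruments at this
  information level; the Q-score is one vote of four by design.
* The confirm-at-2 consensus rule's false-heterozygote ceiling at high FA
  rates, discussed above.
* No exclusion-test Monte-Carlo (significance-level) machinery for the
  frequency method: only normalized scores and thresholds are
  implemented; the conventional 0.05 exclusion level is recorded in
  configuration for provenance but unused.
* No likelihood-ratio kinship testing, no bootstrap support on UPGMA
  trees, no sequence-level formats.
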