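---
title: "From tagged amplicon reads to functional-allele fitness effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tagged amplicon reads to functional-allele fitness effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcnest)
```

## The problem

In many passerines the major histocompatibility complex (MHC) class I region
is multi-locus and hyper-polymorphic: an individual house sparrow can carry
up to eight distinguishable class I exon 3 alleles, and the alleles that
matter functionally are those whose peptide-binding region (PBR) residues
differ. This package implements a complete analysis path for asking whether
MHC functional diversity predicts early survival and growth in a pedigreed
aviary population:

1. call per-individual MHC genotypes from tagged amplicon reads through a
   multi-step artifact-filter cascade;
2. collapse DNA alleles into *functional alleles* (FAs) by their PBR
   physicochemistry;
3. quantify parental MHC similarity (proportion of FAs shared; tree-based
   UniFrac distances) and neutral heterozygosity;
4. relate survival and growth to these covariates with an iterative
   AICc/relative-variable-importance (RVI) model-selection procedure.

A synthetic-data module generates pedigreed populations with planted allele
effects and noisy reads so that every stage — and the pipeline end to end —
is testable without access to any field data.

## Genotype calling

### The coverage model

A sample with too few reads cannot be genotyped confidently: with `m` alleles
amplifying equally, the probability that all of them are sequenced at least
`t` times out of `T` total reads follows a multinomial coverage model. We
compute it exactly by conditioning one allele's binomial count at a time
(`genotyping_score()`), which is numerically stabler than inclusion–exclusion
but identical in value; the unit tests verify it against exhaustive
multinomial enumeration for all small cases. With the species maximum of
`m = 8` alleles, `t = 3` reads per allele and a 99.9 % confidence target, the
smallest adequate total is

```{r}
min_reads_for_score(m = 8, t = 3, confidence = 0.999)
```

reads per sample — samples below this threshold are excluded rather than
miscalled.

### The filter cascade

`call_genotypes()` applies, per sequencing run and in a fixed order:

| step | rule | default |
|------|------|---------|
| merge | identical sequences within a sample are summed | — |
| low abundance | per-sample cells with < `min_reads` reads deleted | 3 |
| coverage | samples under the score threshold fail | 104 |
| within-sample frequency | cells under `min_frac` of the sample total deleted (single pass on pre-deletion totals) | 2 % |
| occurrence | variants must appear in ≥ `min_samples` independent PCRs (technical replicates count) | 2 |
| length/frame | lengths outside 222–225 bp, or deviations from the 222-bp frame not ≡ 0 (mod 3), deleted | — |
| artifacts | chimeras and 1-bp substitution variants removed | ratio 10 |

Runs are filtered separately and an individual's calls are merged across
runs and replicates by union (the occurrence filter has already demanded two
independent PCRs; an intersection mode exists for sensitivity analysis).

The artifact detector automates what is often done by eye. A candidate
parent must dominate the variant it explains *within every sample where the
variant occurs* (≥ 10× its reads, sample by sample): a polymerase
substitution or PCR recombinant can only arise in a sample containing its
source template(s), and it arises at a small per-read rate, so it is always
a minor fraction of its parent there. Without this condition, rare *true*
alleles sitting 1 bp from common alleles (a real feature of MHC allele
series, including synonymous variants) are wrongly removed whenever their
carriers co-inherit the neighbour; with it, our end-to-end
simulations at the default noise level (10⁻³ per-base substitution rate, 2 %
chimera rate, 300× coverage) reach per-sample allele sensitivity above 0.99
with a false-allele rate below 0.01. Variants carried by ≥ 2 % of samples
are treated as true alleles and never flagged.

We apply both the length-range rule and the frame rule as written, although
they interact: lengths 223 and 224 fall inside the accepted range but
violate the mod-3 rule and are therefore removed by default. Both rules are
independently configurable.

## Functional alleles

Filtered DNA alleles are translated (standard code, frame anchored on the
222-bp reference; internal stops are rejected), synonymous alleles are
merged, and the 16 PBR residues — positions homologous to the
antigen-contacting residues of the chicken class I structure — are extracted
and encoded with the five published z-descriptors per residue (z1
hydrophobicity, z2 steric bulk, z3 polarity, z4/z5 electronic effects).

Functional-allele identity is **exact equality of the 16-residue PBR
string** (equivalently of the 16×5 z-matrix, since descriptor rows are
distinct). We chose exact equality over clustering of z-vectors because it
is deterministic and parameter-free: it reproduces a fixed DNA → AA → FA
collapse without an arbitrary clustering radius. The 16 default positions
ship as data (`default_pbr_positions()`), not code; users with a different
amplicon or reference structure should substitute their own ordered list.
Because published studies rarely print these positions, the synthetic allele
panel (below) is *constructed* so that its collapse structure (85 DNA → 78
AA → 59 FA) matches the deposited panel it emulates; the tests therefore
validate the collapse machinery, not any particular position list.

Common FAs are those carried by more than 10 % of genotyped offspring —
below that, per-allele sample sizes lose statistical value — and enter the
models as presence/absence indicators (multi-locus data cannot distinguish
homo- from heterozygotes).

## Parental similarity

* **Proportion of FAs shared** = 100 / (n male + n female) × number of
  shared FAs, computed on sets. Shared alleles are counted once — the
  literal reading of the formula — so identical parents score 50, not 100;
  `count_both = TRUE` gives the doubled variant. The denominator sums the
  two set sizes without cross-parent deduplication.
* **Tree distances**: unweighted UniFrac on externally inferred rooted
  trees (Newick input) — the fraction of branch length leading to either
  parent's leaves that is unique to one parent. Presence/absence (not
  abundance) is the natural weighting for allele sets. Zero-length branches
  contribute nothing; multifurcations are allowed. Tree *inference* is out
  of scope; `fixture_trees()` builds simple average-linkage distance trees
  for tests and demonstrations only.
* **Neutral heterozygosity**: proportion of heterozygous typed
  microsatellite loci, missing loci excluded from both numerator and
  denominator.

## Model selection

With 15–20 candidate variables and a few hundred observations, all-subsets
selection over the full list is both infeasible (2²⁰ models) and an
overfitting risk. The procedure used here:

1. take the first 10 variables in the configured order (default: clutch
   size, clutch order, sex, heterozygosity, FA count, the ten common FA
   indicators, then — for survival — sharing and the two tree distances);
2. fit **all subsets** (2¹⁰ including the intercept-only model), compute
   AICc = −2 logLik + 2k + 2k(k+1)/(n−k−1), Akaike weights and each
   variable's RVI (summed weight of models containing it);
3. keep variables with RVI > 0.5, refill the pool with the next unused
   variables, and repeat until every variable has entered a pool (at most
   three rounds in practice);
4. refit all subsets of the final kept set and report **full
   model-averaged** estimates: absent variables contribute zero to the
   average, and the adjusted SE is the revised unconditional estimator
   √Σwᵢ(varᵢ + (βᵢ − β̄)²) (an older summation-of-roots variant is available);
   p-values come from the normal z = β̄/SE. Variables with RVI > 0.7 are
   flagged relevant.

The final interpretation model refits and re-averages over the final pool
rather than reusing round-wise values; this makes the reported table a
function of one coherent candidate set.

**Grouping and the aggregation fallback.** Continuous responses use nested
random intercepts (clutch within female within aviary) via the `lmer`
backend under maximum likelihood, with k counting fixed effects, variance
components and the residual variance, and the random structure held fixed
within a pool so AICc is comparable across subsets. Binary survival
responses default to clutch-level aggregation — every variable replaced by
its clutch mean, so survival becomes a clutch proportion and sex a sex
ratio — because per-individual logistic mixed models with this nesting
routinely fail to converge at these sample sizes; aggregation yields
well-behaved Gaussian models (and absorbs the clutch-level random effect by
construction). Aggregated fits are weighted by clutch size: the mean of n
binary outcomes has residual variance proportional to 1/n, and leaving that
heteroscedasticity unmodelled measurably inflates the evidence assigned to
clutch size itself in null data. A per-individual logistic mode remains
available (`aggregate = FALSE`). The fitting backend is a contract (log-likelihood, k,
coefficients, variances); the fast fixed-effects `lm` backend is the default
for aggregated data and for simulation studies, where refitting thousands
of mixed models would dominate runtime without changing the selection
behaviour being tested.

Day-of-season is deliberately absent from the default variable list: clutch
order carries the same information (the two are strongly correlated in
seasonal breeders) and only one of a collinear pair belongs in an
information-theoretic comparison.

**Survival bookkeeping.** The day-1 analysis contrasts hatched chicks with
embryonated unhatched eggs; the day-6 analysis uses hatched nestlings,
excluding individuals whose death was flagged non-natural (e.g. killed by
neighbouring adults — their later survival cannot be prospected); the
day-12 analysis uses nestlings alive at day 6. Growth responses use
nestlings alive and measured on the focal day.

## The synthetic-data generator

`simulate_population()` emulates the aviary study design: 14 aviaries of
4–5 breeding pairs, 1–4 clutches per female, truncated-Poisson clutch sizes
(mean 5), Bernoulli(0.5) offspring sex. Each parent carries two haplotypes
of 1–4 panel alleles and transmits one per meiosis, reproducing the
observed 1–8 alleles per individual without asserting a locus structure —
the true locus architecture behind multi-locus amplicon genotypes is
unknown, and this haplotype model is a stand-in, not an inference. Survival
at days 1/6/12 is generated sequentially from logistic models; mass and
tarsus from Gaussian models; all effect coefficients (per-FA, clutch order
and size, sex, parental sharing) are configurable and default to zero with
intercepts set to the study's observed survival rates (logits 2.13 / 1.72 /
2.02). A configurable fraction of mid-window deaths (default 11/49) is
flagged non-natural to exercise the exclusion rule.

`simulate_reads()` draws per-sample totals from a negative binomial around
300× (dispersion 10), allocates reads to alleles with log-normal
amplification weights (σ = 0.5 — deliberately skewed so that the 2 %
within-sample filter is stressed), converts reads into 1-bp substitution
variants at 10⁻³ per base, and emits single-breakpoint chimeras at a 2 %
per-read rate. Individuals are split across two runs with ~13 % technical
replicates, and runs are filtered separately downstream.

What the generator does **not** emulate: homopolymer-specific 454 error
profiles, quality scores, extra-pair paternity (rare in the emulated study
and ignored there), and any environmental covariate structure. Passing
tests therefore demonstrate that the algorithms behave correctly under a
clean generative model, not that any particular field dataset would yield
identical tables.

The deterministic `study_template_population()` is a labelled synthetic
stand-in for a deposited genotype–phenotype table: it plants the published
bookkeeping exactly (293 offspring; 31 unhatched; 49 deaths before day 6 of
which 11 non-natural; 25 deaths before day 12; clutch-order counts
140/75/66/12) and carrier counts for two focal FAs of 42/290 (14.48 %) and
44/290 (15.17 % — the closest integer count to the emulated 15.15 %; no
integer denominator ≤ 293 reproduces both printed frequencies
simultaneously). It validates the table-building and frequency machinery,
not the deposited data themselves.

## Numerical choices and degenerate inputs

* The threshold scan in `min_reads_for_score()` compares against
  `confidence − 10⁻⁹` to absorb floating-point error in exact-boundary
  cases (e.g. two reads, two alleles, 50 % target); the margin is far below
  any meaningful confidence gap.
* Within-sample frequency decisions are made in a single pass on
  pre-deletion totals, making them order-independent.
* A sample whose every variant is filtered simply has no call; an empty
  keep-set in the RVI rotation replaces the pool with the next unused
  variables; if a round keeps a full pool while variables remain, the
  lowest-RVI kept variable is released so rotation always terminates.
* Candidate models with n ≤ k + 1 (AICc undefined) or failed convergence
  are excluded from weighting and counted.
* UniFrac on sets with no observed branch length returns 0.

## Problem sizes used in the tests

The simulation studies in the test suite use 24 aviaries (~230 clutch-level
rows, matching the scale at which the selection procedure is meant to
operate) with 50 replicates for planted-effect recovery and 100 for the
null calibration; end-to-end genotyping checks run two simulated runs of
~250 samples each at default noise. These sizes were chosen to give stable
pass/fail behaviour at study-like scale while keeping the default test run
fast.

## Known limitations

* The default PBR position list is a documented package default, not a
  published constant; analyses of real data should supply the positions
  appropriate to their amplicon.
* Functional-allele identity by exact PBR equality is conservative;
  supertype-style clustering of z-vectors is out of scope.
* The artifact detector is a reproducible automation of a manual practice;
  on real data its flags should be audited (`detect_artifacts(...,
  audit = TRUE)` examines even common variants and the full flag table is
  returned for inspection).
* The statistical tables produced on synthetic data are not expected to
  reproduce any published study's coefficients numerically: they depend on
  backend, convergence behaviour and variable ordering; the package's
  claims are the property-based ones its tests compute.
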