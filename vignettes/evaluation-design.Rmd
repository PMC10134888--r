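---
title: "Evaluating metagenome inference accuracy: model, design and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating metagenome inference accuracy: model, design and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgInferEval)
```

## The problem

Metagenome inference tools predict a community's gene-family (KO) content
from a 16S rRNA taxonomic profile and a reference-genome database. Their
error is not uniform: taxa poorly represented in the reference are
predicted badly, and when such taxa dominate particular community types,
inference accuracy becomes a function of community type. In case/control
studies where community type is itself associated with the outcome — the
situation in vaginal microbiome research, where *Lactobacillus*
dominance relates to birth outcomes — this is differential measurement
error, and it can bias associations toward or away from the null.

This package implements the evaluation framework for that problem: two
concordance statistics between observed (shotgun) and predicted KO tables,
stratified by community cluster and by KO functional category, each with a
permutation-null robustness check, plus a synthetic generator that
reproduces the statistical structure under which differential error
arises, so the whole pipeline is testable end to end without sequence
data.

## Evaluation statistics

**Abundance concordance.** All tables are first restricted to KOs with
relative abundance above zero in at least one sample of *every* table
(observed and each prediction). Restricted values are deliberately **not**
renormalized — the statistics should see the abundances as produced — so
restricted tables carry the unconstrained (`"counts"`) scale; a
`renormalize` flag provides the other convention. For each shared KO and
each stratum (overall, then each community cluster), the Spearman
correlation between observed and predicted values across that stratum's
samples is computed. KOs constant in either table within a stratum are
reported as *undefined* and excluded from medians with their count
surfaced, never silently coerced to zero, which would bias summaries.
Functional-category stratification groups the overall per-KO correlations
by level-1 category: categories partition KOs, not samples, so nothing is
recomputed.

**Signed log-P concordance.** Within each stratum, a two-sided Wilcoxon
rank-sum test per KO compares cases against controls, separately on
observed and predicted values; each P value becomes
`Pt = log10(P) * sign(mean_case - mean_control)`, and one Spearman
correlation across KOs between the observed-data and predicted-data `Pt`
vectors summarizes whether inference preserves differential-abundance
conclusions. Conventions: `sign(0)` gives `Pt = 0`; P is floored at 1e-300
so the transform stays finite; no multiple-testing correction is applied
anywhere because raw P values enter the transform.

**Wilcoxon variant.** Exact P values are used wherever feasible: when both
groups have at most 10 values, a tie-aware exhaustive enumeration of group
assignments of the pooled mid-ranks (two-sided tail count of the rank
sum); for tie-free data with both groups below 50, the classical exact
rank-sum distribution; otherwise the normal approximation with tie and
continuity corrections. The enumeration path exists because no standard
routine provides exact P under ties, and the test suite pins it against an
independent brute-force oracle. Completely tied data return P = 1.
Calibration was checked directly: one KO's within-cluster P value across
500 independently generated null datasets is uniform (KS ≈ 0.04–0.07).
Two caveats worth knowing, both properties of the statistics rather than
of this implementation: (i) within a single dataset the per-KO P values
are correlated through shared compositional factors, so one dataset's P
ensemble can sit far from uniform even under the null; (ii) the study
design assigns cases within clusters (stratified), which makes the
unstratified rank-sum conservative in the overall stratum.

**Permutation null.** Each KO's values are permuted across samples
independently in every table, with one seeded child stream per
(table, replicate, KO) so any replicate is exactly replayable; each
column's multiset of values is preserved exactly. The evaluator is rerun
on each of the (default 100) permuted replicates; the unpermuted
evaluation is never part of the null. Because columnwise shuffles break
row-stochasticity, permuted tables carry the unconstrained scale.

## Community structure

Samples are clustered on pairwise Jensen–Shannon divergence
(natural-log units, used directly as the distance, no square root) with
Ward linkage in the Ward.D2 variant — the squared-distance Lance–Williams
update applied to the supplied distances. Tie-breaking among equal-height
merge candidates follows `stats::hclust`'s deterministic internal order.
The number of clusters is deliberately a user decision: internal
validation statistics (connectivity with a default neighbourhood of 10,
ties in neighbour ranking broken by sample order; mean silhouette width;
Dunn index) are reported for a range of k, but nothing selects k
automatically — on vaginal data the two-cluster statistical optimum merges
iners-dominated and mixed communities, and domain knowledge argues for
three. Richness on relative data counts features with value > 0; Shannon
uses natural logs; Simpson is 1 − Σp², inverse Simpson its reciprocal.

## The generative model

`generatorConfig()` holds every parameter. The defaults *are* the study
conditions the framework was designed around; they were fixed once, and
the calibration-sensitive ones are justified below.

**Design.** 72 samples: 17 crispatus-dominated (11 cases), 31
iners-dominated (13 cases), 24 mixed (11 cases). Eight taxa: the two
*Lactobacillus* species, a Gardnerella-like mixed-cluster taxon, five
background anaerobes.

**Composition.** Dominated clusters use a hierarchical model: dominant
abundance ~ Beta(mean = 0.87 or 0.86, concentration 12), minors = the
remaining mass split by a Dirichlet (concentration 60) around the
template's conditional minor profile. This gives broad, realistic
dominance spread (≈ ±0.09) with a comparatively stable minor profile —
the single-concentration Dirichlet alternative ties minor-profile
volatility to dominance volatility at every concentration and therefore
cannot make the dominance axis the main within-cluster signal, which is
what the differential-error mechanism requires. The mixed cluster is a
plain Dirichlet (concentration 25). Cases' dominance odds are shifted by
`outcomeOddsRatio` (default 0.6, split symmetrically so cluster means stay
at 0.87/0.86): the case-control design this emulates presumes a real
composition–outcome association, and without one the `Pt` vectors carry
only chance imbalance.

**Genome content.** 500 KOs partitioned over eight level-1 categories
(metabolism 30%, genetic information processing 16%, …, uncharacterized
10%). Each taxon carries a Bernoulli subset of each category's KOs
(carriage 0.50 crispatus, 0.55 iners, 0.45 background) with
within-category Dirichlet weights scaled to the taxon's category-weight
profile. The iners-like taxon is enriched for genetic information
processing (0.36 vs 0.16 background) and the crispatus-like taxon for
uncharacterized genes (0.18 vs 0.10), with metabolism compensating —
the genome-composition asymmetry that couples community state to
metagenome composition and gives the coupling regressions their
orientations. Sparsity matters: with dense genomes, removing a taxon
merely rescales KO values, which rank correlations ignore.

**Observation.** Observed KO tables are composition × genome content,
optionally shifted in cases for configured effect KOs (none by default),
perturbed by log-normal noise (sd 0.25), renormalized, then resampled as
20,000 multinomial reads per sample. The counting step makes low-abundance
KOs unreliable exactly as finite sequencing depth does, and is as
essential to the differential mechanism as sparsity; `noiseSD = 0` with
`depth = Inf` gives the exact noise-free projection used by the
perfect-prediction checks.

**Reference error.** A per-taxon ANI-like similarity (defaults: crispatus
0.995, iners 0.93, others 0.94–0.99) drives two modes sharing one map:
*discard* removes taxa under the 0.97 threshold and renormalizes the
remainder (reporting each sample's discarded fraction — ≈0.86 in
iners-dominated samples under defaults); *blend* replaces each taxon's
genome row by `ani^25` of the true row plus the complement of a fixed
seeded log-normal corruption (sd 1). The exponent is large because ANI
lives in a compressed range: 0.93^25 ≈ 0.16 means a taxon 7 points below
perfect keeps only ~16% of its true genome signal. With all ANI = 1, both
modes return the noise-free observed table exactly.

**Seeding.** Every draw flows from the single config seed through named
child streams (`.childSeed(seed, stage, ...)`, a polynomial hash into
32-bit range), so datasets, perturbation rows and permutations are
individually replayable; generated outputs are byte-identical across runs.

## What the generator does and does not establish

Passing tests on this generator show that the evaluation statistics
behave correctly *given* the mechanisms the generator encodes: they reach
their maxima under perfect prediction, collapse under permutation, and
expose differential error when a dominant taxon's reference is poor. Real
data differ in ways the generator deliberately omits: many more taxa and
KOs with long-tailed abundance distributions; 16S-vs-shotgun measurement
disagreement in the taxon table itself (here predictions see the true
composition); copy-number and primer bias; strain-level genome variation
within a taxon; multi-category KO annotations (the framework requires one
level-1 category per KO and leaves the collapse to upstream annotation).
Absolute concordance values on synthetic data therefore do not forecast
absolute values on real data; the orderings and null behaviours are the
transferable results.

## Numerical and degenerate-case choices

* Relative tables must row-sum to 1 within 1e-9; all-zero rows are errors
  naming the sample. Feature subsets of relative tables drop to the
  unconstrained scale rather than silently renormalizing.
* Spearman correlations of identical vectors return exactly 1 (no
  floating-point shortfall); constant vectors are `NA`, never 0.
* JSD uses `0·log(0/x) = 0`, and matrix entries are clamped at 0 against
  epsilon-negative entropy differences; inputs must sum to 1 within 1e-9.
* `cutClusters` requires 1 ≤ k ≤ n; validation requires 2 ≤ k ≤ n−1 and a
  neighbourhood smaller than n; an all-singleton clustering has Dunn = ∞.
* The coupling ratio predictor is `(crispatus + 1e-6)/(iners + 1e-6)`;
  the pseudocount guards empty denominators and is configurable. A
  constant response gives R² = 0 by convention; a constant predictor is
  an error. Fits are untransformed linear models.
* Problem sizes in the test suite (20-seed orderings, 100-replicate
  nulls, 500-dataset calibration, 10,000 JSD property pairs) were chosen
  to make the checked orderings and bounds stable across reruns at the
  package's default dimensions.

## Known limitations

The category stratification requires a strict partition of KOs; the
framework does not model wNSTI (reference proximity enters only through
the ANI fidelity map); sample-wise (across-KO) correlation modes and
alternative distances (Bray–Curtis, UniFrac) are out of scope; and the
cluster-count decision is intentionally manual.
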