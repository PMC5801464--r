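---
title: "Models and methods behind MetExpand"
author: "MetExpand authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind MetExpand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetExpand)
```

MetExpand analyses gene family expansion in multi-genome annotation censuses
and the downstream divergence of duplicated metabolic enzymes. This vignette
explains each model, its assumptions, the tunable parameters, and the design
choices made where the underlying analysis conventions were genuinely open.

## The expansion-event rule

The census is a roles × genomes matrix of copy numbers (a
`FunctionalCensus`, backed by `SummarizedExperiment`, taxonomy in
`colData`). For each role the per-group mean copy number is computed at the
genus level by default — means are taken **per genus**, and suborder-level
aggregation is used for pathway reporting; both levels are exposed via
`level=` because the rule is meaningful at either. A group is a *gene
expansion event* for a role when its mean is greater than or equal to the
phylum-wide mean of the group means plus `sdMultiplier` (default 1) times
their standard deviation.

Three conventions needed fixing:

- **SD type.** The sample (n−1) standard deviation over group means is the
  default, as the conservative small-n choice; `sdType = "population"` is
  available.
- **Level of the phylum statistics.** Mean and SD are computed over *group
  means*, not over raw genome counts: group means are the quantities the
  rule compares, so pooling raw counts would mix within- and between-group
  variance. This is configurable only through the grouping level.
- **Inclusive threshold.** "Equal to or higher" is honoured literally; when
  all groups are identical the SD is 0 and every group is flagged. This
  degenerate boundary case is deliberate and tested.

The rule is a one-sided exceedance rule, not a significance test: under a
pure Poisson null it flags a stable background fraction of (group, role)
pairs (roughly the probability that one of n group means exceeds mean + SD,
about 10–16 % for 20 groups of 5 genomes). The test suite calibrates this
empirically by resampling the same generative null rather than asserting a
parametric value. Interpreting the flags therefore always requires the null
rate alongside, which is why the synthetic census exists.

**Pathway matrix.** The percentage in each (suborder, pathway) cell is
100 × flagged (genus, role) pairs / (genera in suborder × enzymes in the
minimum pathway). This denominator is a reconstruction: it reproduces
spot-checked published cells (e.g. 7 flags over 3 genera × 10 glycolytic
enzymes = 23.3 %, and 5 over 2 × 10 = 25.0 %) but is an interpretation, not
a stated formula. Cells with zero flags print as `"NE"`; percentages are
reported at one decimal.

## Duplication versus horizontal transfer

Published analyses of this question typically read tree topology by eye. We
encode the minimal defensible rule, deliberately without a
duplication-transfer-loss reconciliation model, and label everything the
rule cannot decide as `ambiguous` rather than guessing:

1. Focal-lineage gene copies are partitioned into maximal clades whose tip
   species all belong to the focal lineage.
2. A clade containing multiple copies per species whose children each carry
   exactly one copy of every focal species present (the bifurcating
   duplicated pattern) marks its copies as **duplication**.
3. A focal copy whose smallest enclosing clade of ≥ 2 tips contains only
   foreign species is **hgt** — the nearest relatives of the copy are the
   donor lineage.
4. Species with one congruent copy yield no call: there is no expansion to
   classify.

"Phylogenetically distant" has no operational definition in the visual
analyses this mirrors; the smallest-enclosing-foreign-clade rule is one
formalization, and branch-length-outlier alternatives were considered and
not implemented (branch lengths are not required of the input trees). Trees
are used as rooted as written, with no midpoint rerooting. Polytomies are
conservative: an unresolved arrangement that merely *could* be the
duplicated pattern does not satisfy rule 2, so its copies fall through to
`ambiguous`.

Congruence between species and gene trees is a normalized Robinson–Foulds
distance over non-trivial rooted clades (0 identical, 1 no shared clade).
RF needs a tip bijection, so multi-copy species are collapsed to one copy
chosen under a fixed seed, with the number collapsed reported — a random
choice, made reproducible, rather than a hidden deterministic bias toward
one paralog.

The alignment-coverage filter retains records with
aligned columns / query length ≥ 0.25, the inclusive reading of "at least
25 % coverage".

## Nei–Gojobori dN/dS

Site counting: for each codon position the three single-nucleotide mutants
are classified against the genetic code; mutations to stop codons are
removed from the denominator and the position renormalized to one site, so
every codon contributes exactly 3 sites. This is the convention of the
standard distance-based implementations; nothing in the upstream literature
this follows pins it down, so it is stated here and enforced by an invariant
(N + S = 3 × codons) in the tests.

Difference counting averages synonymous/nonsynonymous step counts over all
orderings of the differing positions, excluding pathways through stop codons
and renormalizing over the survivors; when nothing is excluded nd + sd
equals the number of differing positions. Both primitives are verified
against an exhaustive-enumeration oracle over the entire code table.

Distances are Jukes–Cantor corrected, d = −(3/4)·ln(1 − 4p/3), defined for
p < 0.75 (saturation raises an error rather than returning a complex
number). ω = dN/dS; dS = 0 yields an explicit undefined flag, never
infinity. Uncertainty comes from resampling codon columns with replacement
(default 1000 replicates, seed-reproducible). Codons containing non-ACGT
symbols are dropped pairwise with a message, matching common
pairwise-deletion practice. The genetic code defaults to the standard table;
the bacterial table 11 is identical for coding changes, and the table is an
argument for other cases.

The published 0.407–0.500 ω range for pyruvate kinase paralog pairs would
require the original 20-sequence alignment (deposited externally); it is
treated as optional validation, not a build input. The package's own
evidence is recovery on synthetic pairs: ω estimates are median-monotone in
the generating ω across 0.1 / 0.5 / 1.0.

## Enzyme kinetics

Saturation data are fitted by bounded Levenberg–Marquardt least squares
(`minpack.lm`) of v = Vmax·Sⁿ/(S₀.₅ⁿ + Sⁿ), with n ≡ 1 for the hyperbolic
model. The original analyses used a GUI tool, so the optimizer contract is
ours: multi-start over S₀.₅ at the 10/25/50/75/90 % quantiles of the
observed substrate range and n ∈ {1, 2, 4, 8}, Vmax started at the maximum
observed rate; lowest residual sum of squares wins with first-found
tie-break; convergence tolerances 1e-15 so that noiseless data is recovered
to ≤ 1e-6 relative error (asserted for every characterised parameter set).
The Hill coefficient is bounded in [0.5, 12]. Replicates are fitted pooled,
not averaged, so the fit weighs every measurement; a failure of every start
returns a flagged non-converged fit, never a silent fallback. Standard
errors come from the curvature of the least-squares surface at the optimum.

Model choice ("Michaelis–Menten or Hill where appropriate") is by
small-sample AICc with a configurable evidence margin (default 2) in favour
of the simpler hyperbolic model; designs with fewer than 8 observations are
flagged low-confidence.

Derived quantities: kcat = Vmax·M/60000/sites (U = µmol·min⁻¹, M the
subunit molar mass in g/mol) and efficiency kcat/S₀.₅. The published
turnover numbers for these enzymes (e.g. 4703 s⁻¹ alongside 73.3 U/mg) are
not reproducible from any ~50 kDa subunit mass under this standard
conversion, which gives ≈ 61 s⁻¹; the mass/site convention behind the
printed values is unstated. The package therefore reports recomputed values
from its own conversion, carries the printed values as data
(`pykKineticParameters()`) for ratio reporting — the > 20-fold Pyk1/Pyk2
turnover contrast holds for the printed values (4703/215 ≈ 21.9) — and
`consistencyCheck()` compares printed versus recomputed with rounding-aware
tolerance at the printed precision (which also absorbs the 65.45 vs 65.5
one-decimal discrepancy between text and table).

Activator dose-responses (AMP for these type II enzymes) reuse the Hill
machinery on rate versus activator concentration, subtracting a
zero-activator baseline when present. The activation Hill coefficient of
the characterised AMP responses is not published, so simulations of that
response use n = 1; the fit itself leaves n free.

## Fitness, expression, yields

Malthusian rate m = ln(Nf/N0)/t per competitor; relative fitness W = m₁/m₂
per replicate; summary mean, SD, and a two-sided one-sample t test of W
against 1 (the publication never names its test, so Welch/Student t with
the usual 0.05/0.01/0.001 display thresholds is our choice, with a
two-sample Welch test between experiments available as `compareFitness()`).
Each replicate is one assay yielding one W, matching triplicate assay
practice. Identical counts give W = 1 exactly, and reciprocal orientations
multiply to 1 — both asserted.

qPCR fold changes use the comparative Ct model: ΔCt = Ct_target − Ct_ref
per sample, ΔΔCt between condition means, fold = E^−ΔΔCt with E = 2 (100 %
efficiency) by default and E exposed. The published 3-fold / 8-fold shifts
cannot be recomputed without the raw Ct values, which were not deposited;
they are illustrative only. Specific yields are guarded ratios (AU/mg), with
negative absorbances from blank over-subtraction clamped to zero with a
warning.

## What the synthetic data does and does not emulate

The generators define the study conditions for all tests:

- **Census**: Poisson copy counts at a base rate of 1 copy/genome/role, the
  regime of single-copy core metabolic genes; planted expansions add a fixed
  shift (+3 in the acceptance suite) to a group's Poisson mean. Real
  censuses have over-dispersion, correlated roles and annotation error, none
  of which is modelled — so passing recovery tests demonstrates the rule's
  arithmetic and calibration, not robustness to annotation noise.
- **Trees**: duplication events copy a clade in place (species-congruent
  paralog clades); transfers graft an extra recipient copy beside the donor
  tip. No gene loss, no rate heterogeneity, no inference error: these trees
  test the classification rule, not tree estimation.
- **Codon pairs**: per-codon Poisson substitution events with
  ω-proportional acceptance of nonsynonymous proposals and stop rejection —
  an approximation to a full codon-model CTMC that controls the realised
  dN/dS without simulating likelihoods. At ω = 0 accepted changes are
  additionally required to keep the ancestor–derived codon pair
  pathway-synonymous, because chains of synonymous steps can otherwise leave
  a pair whose direct mutational pathways contain nonsynonymous steps, which
  difference counting would rightly score as Nd > 0.
- **Kinetics**: multiplicative Gaussian noise at constant CV (default 5 %),
  truncated at zero, triplicate — the error structure of specific-activity
  assays. Substrate grids: 8 points over 0.05–5 mM for hyperbolic ADP
  kinetics, 10 points over 1–20 mM for cooperative PEP kinetics, 8 points
  over 0.001–1 mM for the AMP response; each spans its S₀.₅ with points on
  both limbs.
- **Competition**: exponential growth from ~1e5 CFU per strain over 68 h
  with multiplicative plating noise on final counts, triplicate.

All generators are bit-reproducible under a fixed seed, and every
user-facing seed is applied locally without disturbing the caller's RNG
state.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for quick desk-scale runs while
keeping estimator behaviour visible: 20-genera censuses with 5 genomes per
genus and 30–40 roles, 2000 null resamples for the exceedance-rate
calibration, 300–2000-codon alignments, 200 simulated experiments per
kinetic recovery target, and 1000 null competitions for the type-I-error
check. The full-scale published analysis (612 genomes, 80 genera) is not
reproduced because its database lives in an external repository; the
pipeline consumes such data unchanged through the same TSV/Newick/FASTA/CSV
interfaces.

Seeds fan out from a single global seed through a named-substream scheme
(`runPipeline`), so disabling one stage never shifts another stage's random
draws — stage isolation is asserted in the orchestrator tests, and rerunning
with the same seed reproduces `summary.json` byte for byte.

## Known limitations

- The expansion rule inherits the published definition's lack of a
  multiplicity correction; the resampled null is the honest companion.
- Mechanism classification is topology-only; transfers between closely
  related lineages, overlapping events, or losses can land in `ambiguous`.
- The dN/dS estimator is the pairwise counting method; it is not a
  maximum-likelihood codon model and makes no attempt at site-wise tests.
- The kcat unit convention of the published table cannot be reconciled with
  the standard conversion; both views are reported, neither is asserted.
- The qPCR and coverage-filter stages are thin by design: they encode the
  published procedures' arithmetic, not instrument error models.
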