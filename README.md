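# MetExpand

Gene families in specialized-metabolite-producing actinobacteria are often
expanded: a genome carries more copies of a central metabolic enzyme than is
typical for the phylum. MetExpand is an R package for detecting such
expansions in multi-genome functional-annotation censuses and for
characterising what happens after them — whether the extra copies arose by
duplication or horizontal gene transfer (HGT), how strongly the paralogs are
constrained by purifying selection, how their enzyme kinetics have diverged,
and what the copies are worth in competitive fitness. The motivating system
is the duplicated type II pyruvate kinase pair (Pyk1/Pyk2) of
*Streptomyces coelicolor*, but every stage is generic.

It is aimed at comparative genomicists and molecular microbiologists who
have: RAST-style annotation tables plus a taxonomy, species and gene trees in
Newick, in-frame codon alignments, enzyme rate measurements, and two-strain
competition counts. A synthetic-data module generates all of these with known
ground truth, so the whole pipeline is testable without any external data.

## What it computes

**Expansion events** (census module). With per-genus mean copy numbers
x̄_g of a functional role and the phylum-wide mean μ and standard deviation
σ of those group means, a group is flagged as a *gene expansion event* when

    x̄_g ≥ μ + σ

(inclusive). Pathway-level reporting gives, per suborder and pathway, the
percentage of possible (genus, role) expansion events realised:
100 · flags / (n_genera × pathway size), with "NE" marking empty cells.

**Duplication vs HGT** (phylo module). Extra gene copies of a focal lineage
are classified from the gene-tree topology: two or more species-congruent
paralog clades → *duplication*; a copy nested inside a foreign lineage's
clade → *hgt*; anything else → *ambiguous*. Congruence is quantified as a
normalized Robinson–Foulds distance over rooted clades. A 25 %
alignment-coverage filter screens inputs.

**Selection** (selection module). Pairwise dN/dS by the Nei–Gojobori method:
fractional synonymous/nonsynonymous site counts per codon (stop mutations
excluded, positions normalized so each codon contributes 3 sites), difference
counts averaged over all mutational pathways (stop-traversing pathways
dropped with renormalization), Jukes–Cantor correction
d = −(3/4)·ln(1 − 4p/3), ω = dN/dS, and a codon-resampling bootstrap SE.

**Kinetics** (kinetics module). Michaelis–Menten and Hill fits
(v = Vmax·Sⁿ/(S₀.₅ⁿ + Sⁿ)) by bounded multi-start Levenberg–Marquardt least
squares; AICc-based model choice; activator dose-response fits; turnover
number kcat = Vmax·M/60000 per catalytic site; catalytic efficiency
kcat/S₀.₅; parameter fold changes.

**Fitness and expression** (phenotype module). Malthusian rates
m = ln(Nf/N0)/t, Lenski-style relative fitness W = m₁/m₂ with replicate
statistics and a test of W against 1, 2^−ΔΔCt expression fold changes
normalized to a reference gene (hrdB by default), and specific metabolite
yields.

## Worked example

```r
library(MetExpand)

# a census of 15 genera in 3 suborders, one planted +3-copy expansion
cen <- simulateCensus(nSuborders = 3, generaPerSuborder = 5,
                      genomesPerGenus = 5,
                      roles = list(GLY = paste0("gly", 1:10)),
                      baseCopyRate = 1,
                      plantedExpansions = data.frame(group = "so1_genus1",
                                                     role = "gly1",
                                                     added_mean = 3),
                      seed = 101)
calls <- callExpansions(cen, level = "genus")
head(subset(calls, flagged)[, c("group", "role", "group_mean", "threshold")])
#>          group role group_mean threshold
#> 1   so1_genus1 gly1        4.2  2.059213
#> 17  so1_genus2 gly2        2.0  1.763087
#> ...
```

The planted genus is flagged far above threshold (mean 4.2 vs 2.06); the
remaining flags are the expected exceedance rate of the mean + SD rule under
the Poisson null (see the vignette on calibrating this against a resampled
null).

```r
pair <- simulateCodonPair(nCodons = 300, targetOmega = 0.45,
                          subsPerCodon = 0.4, seed = 2)
dnds(pair[[1]], pair[[2]], nBootstrap = 500, seed = 1)
#> DnDsResult (300 codons):
#>   N = 670.417, S = 229.583, Nd = 36.000, Sd = 25.000
#>   pN = 0.05370, pS = 0.10889, dN = 0.05572, dS = 0.11766
#>   dN/dS = 0.4736 (bootstrap SE 0.1477, 500 replicates)  [purifying]
```

A pair generated at ω = 0.45 is estimated at 0.47 ± 0.15 — purifying
selection, in the range reported for *Streptomyces* pyruvate kinase paralog
pairs.

```r
d <- simulateRateData("Hill", vmax = 9.1, s50 = 8.6, hillN = 7.1,
                      substrate = seq(1, 20, length.out = 10),
                      noiseCv = 0.05, replicates = 3, seed = 3)
fitHill(d)
#> KineticFit [Hill]: Vmax = 8.999 U/mg (SE 0.096), S0.5 = 8.602 mM (SE 0.0819), n = 6.99 (SE 0.408)
#>   RSS = 2.145 on 30 observations
```

Triplicate data at 5 % assay noise recovers the generating parameters
(Vmax 9.1 U/mg, S₀.₅ 8.6 mM, Hill n 7.1) within the reported standard errors.

```r
assay <- simulateCompetition(m1 = 0.095, m2 = 0.101, countNoiseCv = 0.05,
                             seed = 4)
relativeFitness(assay, numerator = "strain1")
#> FitnessResult: W(strain1 / strain2) = 0.9454 (SD 0.0023, 3 replicates)
#>   one-sample t vs W = 1: t = -41.528, p = 0.0005793
```

A mutant growing 6 % slower than its competitor shows W ≈ 0.95,
significantly below 1: reduced fitness.

`runPipeline()` (or `pipelineDemo()`, or
`Rscript inst/scripts/run_pipeline.R --demo`) wires all stages together and
writes `summary.json`, `report.md` and per-stage CSVs; reruns with the same
seed are byte-identical.

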