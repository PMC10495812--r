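---
title: "Delimiting conservation units from microsatellite and chloroplast data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting conservation units from microsatellite and chloroplast data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalunits)
```

# The problem

Threatened species with very small ranges can still harbour internal
genetic structure worth protecting separately. The canonical example this
package is built around is a relict conifer whose entire wild population
(a few hundred trees in two adjacent valleys) was genotyped at eight
unlinked nuclear microsatellites and sequenced for six chloroplast
fragments. The analysis question is two-staged:

1. **Pattern** — how is diversity distributed? Are there differentiated
   nuclear clusters, and do plastid haplotype clades track geography?
2. **Process and decision** — what demographic history (stable size vs.
   growth vs. decline; divergence time; migration) explains the nuclear
   pattern, and do the groups qualify as separate management units (MUs)
   or evolutionarily significant units (ESUs)?

`coalunits` implements the statistics for stage 1, a coalescent
simulator and ABC machinery for stage 2, and the explicit decision rule
that turns both into unit counts.

# Data model and conventions

Genotypes live in an `msat_table` (individuals × loci × 2 integer allele
sizes, `NA` for missing, population and optional group labels). Sizes are
stored on the scale of the input file; `repeat_unit` declares how many
base pairs one repeat spans, and `to_repeat_scale()` converts before any
allele-size-based statistic (R_ST, GSM work). GenePop (2/3-digit) and
two-row STRUCTURE files are parsed and written natively; the
population-to-group assignment is deliberately an *input* (YAML sidecar
or named vector), because cluster membership typically comes from an
upstream Bayesian assignment analysis that is out of scope here.

Alignments live in a `seq_alignment` (character matrix over
`A,C,G,T,-,N`). Sites containing a gap or `N` are excluded
alignment-wide (complete deletion, the common default in sequence
software) before nucleotide statistics; haplotype collapse masks `N`
columns but keeps gap characters, so indel variants remain distinct
haplotypes while neutrality tests see substitutions only.

# Nuclear statistics

Per stratum and locus: `Na`, `Ne = 1/Σp²`, `Ho`, `He = 1 − Σp²`, and
`FIS = (He − Ho)/He` (undefined-flagged when `He = 0`; negative values
legitimate and common). `He` is uncorrected by default with an
`unbiased` switch for the `2n/(2n−1)` factor — published tables rarely
state which was used, so both are available.

**Two F_ST scales coexist, intentionally.** The AMOVA on individuals
with the squared codominant genotype distance (Smouse–Peakall: 0 for
identical genotypes, 1 for one allele substituted, 4 for opposite
homozygotes, summed over loci, pairwise deletion of missing loci) yields
a φ-type among-group fraction whose expectation under an F-model is
`2F/(1+F)` — this is what the "percent variance among groups" of a
genotype AMOVA reports, and it runs nearly twice F_ST at moderate
differentiation. Wright's F_ST itself (`fst_amova()`, `wright_fst()`) is
computed at the gene-copy level (allele-identity distance, or the
Weir–Cockerham moment estimator as an independent route). Reports should
quote both deliberately, as published tables do.

**Standardized F'_ST.** `fst_prime()` divides F_ST by `F_ST(max)`,
obtained by recoding every group's alleles to be private to it
(frequencies preserved) and re-running the same AMOVA — the recoding
approach to maximal differentiation. `F'_ST ≥ F_ST` always; with all
loci monomorphic the ratio is undefined-flagged rather than zero.

**R_ST vs. pR_ST.** R_ST is the among-group fraction of allele-size
variance (one-way components on gene copies, components summed over
loci). The null permutes, within each locus, the size values assigned to
the allelic states: allele identities and their distribution over groups
are untouched, only the stepwise (memory) content of sizes is destroyed,
so the permuted mean pR_ST sits at the F_ST level. A significantly larger
R_ST indicates phylogeographic structure. Monomorphic loci are excluded
with a warning. p-values throughout use the `(#{perm ≥ obs}+1)/(n+1)`
estimator, so no permutation p is ever exactly zero.

**Hardy–Weinberg.** The classical exact test is replaced by a
Monte-Carlo shuffle of the `2n` gene copies into random diploids; the
statistic is the absolute deviation of the heterozygote count from its
random-pairing expectation (computed in closed form), making the test
two-sided. `sequential_bonferroni()` provides the Holm/Rice ordering for
loci × population batteries.

**PCoA** is classical metric scaling (`cmdscale`) behind a validated
surface; pass `sqrt(genotype_dist(x))` to ordinate genotypes.

# Chloroplast statistics

Haplotype diversity uses Nei's unbiased `h = n/(n−1)(1 − Σ(f/n)²)`;
nucleotide diversity is the mean pairwise proportion of differing sites.
Tajima's `D` uses the mean pairwise difference count (not per-site) and
the standard constants; Fu & Li's `D*`/`F*` (no outgroup) use total
mutations η, singletons η_s and the corrected variance constants adopted
by the mainstream sequence software. All are undefined-flagged at
`S = 0`; sign behaviour at spectrum extremes (all-singleton vs.
no-singleton alignments) is covered by tests.

φ_ST between clades is the two-level AMOVA on pairwise
nucleotide-difference distances. φ_ST(max) recodes haplotypes shared
between groups to be group-private (between-group distance at least one
mutation) while preserving within-group distances and frequencies, so
φ'_ST = 1 exactly when groups share no haplotypes. "Clades spatially
segregated" — judged visually in typical studies — is operationalized as
a permutation test: φ of clade membership across spatial labels must
exceed 0.2 with p < α. The 0.2 threshold is a package design choice
(clade membership should explain at least a fifth of spatial variance to
count as geographic structure); it is configurable.

# The coalescent simulator

The Rcpp core runs an event-driven structured Kingman coalescent
backwards in time, in continuous generations: `k` lineages in a deme of
diploid size `N` coalesce at rate `k(k−1)/2` per `2N` generations;
lineages migrate individually at their backward per-copy rates (active
only between the present and the divergence time `T`, after which the
demes merge into the ancestral deme); instantaneous size changes are
phase events; the exponential trajectory of the size-change model is
sampled by closed-form hazard inversion.

Model families: `snm_model(N)` (constant), `pgm_model(N, G, t)`,
`srm_model(N, Nb, t1)` (`N < Nb`), `dvm_model(N1, N2, Nanc, T, m12,
m21)` (`max(N1, N2) < Nanc`). The size-change reconstruction follows the
printed form `Na = N·exp(G·t)` literally; with that backward-time
parameterization a forward *expansion* corresponds to `G < 0`, and the
default priors use negative `G`. Migration rates are backward lineage
rates per gene copy per generation; `m12` (deme 1 → deme 2 backwards)
corresponds to forward gene flow from deme 2 into deme 1.

GSM mutation: Poisson on branches at the per-locus rate; each mutation
steps the repeat count by ±k with k geometric
(`P(k) = (1−p)p^(k−1)`); `p_gsm = 0` is the strict SMM. No allele-size
boundaries are imposed (sizes may drift; a whole locus is shifted
positive on output only if needed). Per-locus rates are
gamma(shape, shape) multiples of `mu_mean` (default 5×10⁻⁴ per
generation); `normalize_mu` (default on) rescales draws so the
across-locus mean is exact — the alternative (off) leaves pure gamma
draws.

Validation anchors (tested): `E[T2] = 2N`, `E[TMRCA] = 4N(1−1/n)`,
strict-SMM equilibrium `He = 1 − 1/√(1+8Nμ)` at θ ∈ {0.4, 4}, structural
impossibility of cross-deme coalescence before `T` at `m = 0`, and
monotone loss of differentiation with increasing migration.

# ABC inference

Summary statistics follow the ARLSUMSTAT convention: mean and SD across
loci of allele count, expected heterozygosity and allele-size range;
pair mode adds the per-group blocks, the mean pooled size range, and
Nei's G_ST between the two groups (14 statistics).

Reference tables allocate rows round-robin over the candidate models
with equal prior weight. Default priors (all config-exposed): sizes
log-uniform 10²..10⁴; event times uniform 1..10⁴; divergence-model
`T ~ U(1, 10⁴)`, `Nanc ~ U(10², 10⁴)`, `m ~ U(10⁻⁵, 0.3)`; GSM
nuisance `shape ~ U(0.5, 5)`, `p_gsm ~ U(0, 0.99)`. The exact published
priors for the size-change comparison live in an unavailable supplement,
so two structural constraints make the comparison well-posed a priori:
the growth and reduction alternatives must describe at least a two-fold
size change, and the change must fall within ~4N generations — without
these, a near-zero or invisible change makes the alternative
observationally identical to the constant-size null and the
classification error is dominated by an artefact of prior overlap rather
than by data informativeness. Reported error rates remain sensitive to
these choices.

Model choice is a 1000-tree classification forest on the statistics;
the prior error rate is the out-of-bag misclassification rate, and the
posterior probability of the selected model is a regression forest
trained on the OOB success indicator, evaluated at the observed
statistics. Posterior estimation retains the `tolerance` fraction of
rows nearest in SD-normalized Euclidean statistic space and adjusts
parameters by weighted local-linear regression (Epanechnikov weights;
single-hidden-layer neural network optional), with strictly positive
parameters log-transformed before adjustment (switchable). As with any
linear adjustment, adjusted draws can spill slightly beyond the prior
bounds on weakly informed tables; clamping them to the bounds was
evaluated and rejected because the boundary mass it creates distorts the
HPD (a logit transform over the prior range would be the principled
remedy and is left as an extension). The mode is
the Gaussian-KDE maximizer (Silverman bandwidth); the 95% HPD is the
narrowest contiguous window of sorted draws. Posterior-predictive
goodness of fit simulates from resampled posterior draws and doubles the
one-sided tail fraction per statistic.

# Synthetic data: what it does and does not emulate

`balding_nichols_table()` draws group allele frequencies from a
Dirichlet with parameters `p·(1−F)/F`, giving `Var(p) = F·p(1−p)` and
hence direct control of the expected F_ST — the generator of choice for
calibrating differentiation statistics, independent of the coalescent
code path. Defaults emulate the study design: 467 diploids in two
groups, 8 loci, F = 0.11, skewed ("geometric-k") ancestral frequencies
whose gene diversity (~0.45) matches the observed overall He ≈ 0.44.
It has **no** temporal or stepwise structure: R_ST ≈ F_ST on its output,
and parameter-recovery work must use `coalescent_table()` instead.

`two_clade_cpdna()` builds two star-like haplotype clusters separated by
a few fixed differences, with clade labels independent of the random,
balanced spatial labels — emulating "two clades admixed in space"
(defaults: 172 sequences, 2827 sites, 22 derived haplotypes per clade,
3 between-clade mutations; haplotype count and diversities land near the
motivating dataset's H = 47, h ≈ 0.93, π ≈ 0.9×10⁻³). Being star-like,
its site-frequency spectrum is singleton-rich, so Tajima's D on this
synthetic data is negative even though the motivating data's was ~0;
tests therefore check D's sign behaviour on constructed extremes, not on
this generator. Neither generator simulates genotyping error, null
alleles or linkage.

# The decision rule

`delimit_units()`: two groups are distinct MUs iff the nuclear
divergence p-value is below α (default 0.05) **and** the dispersal rate
is below 0.10 per generation in *each* direction (the threshold is
applied per direction, which is the stricter of the readings of the
"<10% dispersal" criterion). Distinct ESUs additionally require
monophyletic, spatially segregated plastid clades; missing plastid
evidence leaves one ESU with an explicit indeterminate flag. The rule is
monotone: lowering p or m never decreases the MU count (tested).
Migration rates are inputs — typically assignment-based or
coalescent-based published estimates — because their estimation is out
of scope. Generation length (default 25 years) is used only for
year conversions in reports.

# Problem sizes and numerical choices

The test suite runs the heavy checks at deliberately scaled sizes chosen
as a package design point: simulator closed forms at 2000 replicates;
permutation-null calibration at 200 datasets × 99 permutations
(Kolmogorov–Smirnov at α = 0.01); ABC recovery with a 20,000-row
reference table over two 15-diploid demes and 20 repeated observations
(95% HPD coverage within 10 percentage points of nominal; rejection and
regression modes agreeing within an HPD width); model-choice endpoints
with 400–1500-row tables. Degenerate inputs are flagged, not silently
zeroed: all-missing strata, monomorphic loci in R_ST and HWE, `S = 0`
neutrality tests, constant summary statistics in ABC (adjustment no-op
with a warning), and tolerance settings that would retain fewer than 50
draws (error).

# Known limitations

* The HWE test is Monte-Carlo, not the exact enumeration; extremely
  small p-values are bounded by `1/(n_perm+1)`.
* φ'_ST uses the shared-haplotype recoding described above; other
  software's standardizations can differ when groups share many similar
  haplotypes.
* The simulator supports exponential trajectories only in the
  single-deme growth model; divergence-model demes are piecewise
  constant, matching the model families compared.
* Plastid "reciprocal monophyly" is consumed as a flag (from an upstream
  phylogenetic analysis); the package tests spatial segregation, not
  monophyly itself.
* ABC error rates and posterior widths depend on the priors; with the
  published prior supplement unavailable, the defaults here are
  documented package choices.
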