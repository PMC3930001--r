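---
title: "Designing low-density SNP panels and evaluating imputation accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing low-density SNP panels and evaluating imputation accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-density SNP genotyping remains a limiting cost in equine genomics. A
practical alternative is to genotype most animals on a small, cheap
low-density panel (LDP) and to *impute* the remaining chip genotypes from a
reference population genotyped at full density. `ldpanel` implements the
whole design-and-evaluation loop for this strategy in a population with a
strong recent founder effect, of which the Thoroughbred horse is the
motivating case: an effective population size near 150, descent from
roughly 28 effective founders about 30 generations ago, and chip-style
ascertainment of common variants.

The package covers: simulation of such populations with truth haplotypes;
SNP quality control; construction of linkage-disequilibrium-unit (LDU) maps
from unphased genotypes; three tag-SNP selection strategies; a
haplotype-copying imputation engine with a closed-form random baseline; and
per-SNP / per-individual accuracy metrics. Everything is driven end-to-end
by the scripts under `analysis/`.

## Data model

Genotypes are biallelic allele counts: homozygotes for allele A are coded
0, heterozygotes 1, homozygotes for allele B 2. Allele orientation is
recorded per SNP (by default allele A is the major allele in the data
read), so coding is stable across datasets; orientation affects the sign of
a genotype correlation but never its square. PLINK text (`.ped`/`.map`)
with a small `.ref` companion file is the interchange format, and
round-trips are lossless for coding, missingness and marker order.

The experimental data flow splits a cohort into three sets: a panel-design
set **A** (MAFs, QC, LDU maps and panel selection use only A), a reference
set **B** (the imputation templates), and a test set **C**, which is masked
down to the panel and imputed. QC on A removes SNPs genotyped in less than
95% of samples or with minor allele frequency below 0.01, both strict
inequalities.

## LD-unit maps

Under the Malecot model, pairwise association declines with distance $d$ as

$$\rho(d) = (1 - L)\,M\,e^{-\varepsilon d} + L,$$

with intercept $M$, asymptote $L$ and decline rate $\varepsilon$. An LDU
map re-expresses position so that one LD unit corresponds to an $e$-fold
decay of association: the LDU length of a marker interval is
$\varepsilon_i d_i$, and cumulative LDU positions are additive.

`build_ldu_map()` works from unphased genotypes:

1. Pairwise $|D'|$ (Lewontin-normalised) for all SNP pairs within 500 kb,
   with two-locus haplotype frequencies estimated by EM over the
   double-heterozygote phase ambiguity. Pairs with undefined $D'$
   (boundary marginals) are skipped and counted.
2. $M$ is fixed at 1 (a single-origin founder assumption). $L$ is the mean
   $|D'|$ of the most distant pairs on the chromosome (about 70% of the
   map apart). This matters: $L$ is the *unlinked background* association,
   which with a few hundred samples sits well above zero purely from
   sampling; estimating it inside the short pair window would confound it
   with genuine linkage and flatten the map.
3. Per-interval rates $\varepsilon_i \ge 0$ are fitted by coordinate
   descent on the summed squared difference between predicted and observed
   $|D'|$, where a pair's prediction uses the summed LDU length of the
   intervals it spans. Each 1-D update optimises the interval's LDU length
   directly (not $\varepsilon$), so the search tolerance is scale-free and
   the total LDU span is invariant to a uniform rescaling of bp
   coordinates. Intervals are capped at 10 LDU; initialisation inverts the
   Malecot formula on adjacent pairs.

Two caveats shape what a "good" map looks like. On a population with
uniform recombination and a large, stable effective size the map is close
to a straight line against bp (the package's tests check $R^2 > 0.9$ at
$N_e = 400$, 500 samples). Under the breed demography itself ($N_e = 150$,
28 founders) the realized LD landscape is genuinely lumpy — windowed mean
$r_g^2$ can vary two-fold along one chromosome in a single realization —
and the fitted map tracks those lumps, as it should; linearity is then not
a valid diagnostic.

## Panel selection

The number of panel SNPs per chromosome is proportional to physical
chromosome length (largest-remainder rounding, at least 2 per chromosome).
Panel sizes are reported as Ne-scaled densities, `size / (morgans * ne)`,
so that results can be compared across species; 36 SNPs on a 1-Morgan
chromosome at $N_e=150$ is 0.24 Ne/Morgan, the density equivalent of a
genome-wide 1K panel on 27.72 Morgan.

* **bpEQ** divides the span between the first and last SNP into
  $n_{chr}-1$ equal segments and takes the SNP nearest each boundary,
  irrespective of MAF. Distance ties go to the lower bp position;
  duplicate hits take the next-nearest unused SNP. Boundaries are anchored
  at the first/last SNP (not bp 0) so the ends are always representable.
* **bpMAF** minimises, by a genetic algorithm,
  $$\sum_i (0.5 - \mathrm{MAF}_i)^2 \;+\;
    \lambda \sum_i \left(\frac{S_{i+1}-S_i}{d} - 1\right)^2,$$
  with $d = \mathrm{len}/(n_{chr}-1)$ the ideal spacing. The spacing
  deviation is divided by $d$ before squaring: a raw squared bp deviation
  would be of order $10^{12}$ against a MAF term bounded by $0.25$,
  making the MAF objective irrelevant; the normalisation makes the two
  stated goals commensurate and scale-free ($\lambda = 1$ by default).
  The outermost SNPs are always included (chromosome ends recombine more,
  so coverage there protects imputation). GA defaults: population 60, 300
  generations, tournament size 3, crossover 0.9, per-gene mutation 0.1,
  early stop after 50 stagnant generations; the equidistant solution seeds
  the population and elitism guarantees the returned cost never exceeds
  the equidistant panel's cost.
* **lduMAF** is the same optimisation with SNP locations in LDU. SNPs
  mapped to identical LDU positions get $k \cdot 10^{-6}$ offsets (and any
  residual non-increase is pushed up by the same increment) so panel order
  stays consistent with the physical map.

## Imputation

Two engines, sharing one result contract (posterior genotype triples, the
most likely genotype per cell with ties broken toward the genotype more
frequent in the reference, and the mask of imputed cells):

**Random baseline.** Each masked genotype is drawn from Hardy–Weinberg
proportions $(q^2, 2pq, p^2)$ of the reference allele frequency. Its
expected proportion of correct calls has the closed form
$p^4 + 4p^2q^2 + q^4$, which is also the chance floor used by the adjusted
accuracy below.

**Haplotype-copying HMM.** A diploid Li–Stephens-style model: the hidden
state is an ordered pair of template haplotypes from a subsampled
reference panel of size $K$ (default 60, seeded). Between adjacent
informative sites separated by $\Delta$ Morgan each chromosome switches
templates independently with probability $1 - e^{-\rho\Delta}$,
$\rho = 4N_e/K$ per Morgan, landing uniformly on the $K$ templates.
Emissions compare the implied genotype with the observed panel genotype
under a per-allele error rate $e = 0.002$. Distances come from the marker
map's Morgan coordinates when available (simulated truth maps are), else
bp at 1 cM/Mb. Forward–backward messages are computed at the informative
sites only; at a masked site the flanking messages are transported to its
map position through the same transition kernel (the kernel composes
exactly, so this interpolation is the correct marginal under the model).
The kernel factorises per haplotype, giving $O(K^2)$ updates; the heavy
loops are compiled (Rcpp).

The engine consumes phased references (truth phase in simulations);
statistical phasing of real unphased references is delegated to the
external-tool adapter (`run_external_imputer()`), which writes PLINK text,
invokes a configured executable and parses its output. The engine is a
controllable stand-in for production imputation software, not a
re-implementation of any particular tool: with a finite template subsample
its absolute accuracy is bounded by $K$, which is why comparisons across
panel designs (its purpose here) are more meaningful than absolute levels.

## Accuracy metrics

Per SNP and per individual: (i) the proportion of exactly correct imputed
genotypes over evaluated cells, and (ii) the Pearson correlation of true
and imputed allele counts, with constant vectors excluded (returned as
`NA`) on both axes. Per SNP the report also carries the expected random
accuracy at the reference frequency and the adjusted accuracy
$(\mathrm{acc} - \mathrm{rand})/(1 - \mathrm{rand})$, which removes the
chance-concordance floor that flatters low-MAF SNPs; under the random
engine it centres on zero. Summaries are mean (min, max). An overall
correct-cell count is identical whether aggregated by SNP or by
individual, which the tests assert as a consistency check.

## The synthetic-data generator

`simulate_population()` is a forward Wright–Fisher simulation designed
around the features the analysis is sensitive to:

* **Ancestral equilibration.** The source population is first burned in
  for $2N_e$ generations (default 300) at $N_e$ so that haplotypes carry
  drift–recombination equilibrium LD; binned $r^2$ against distance then
  matches the Sved expectation $1/(1 + 4N_e c)$ over 0.01–0.1 Morgan,
  which the tests check. Starting founders from independent sites instead
  would leave mid-range LD far below equilibrium.
* **Founder bottleneck and breed history.** 28 diploid founders are drawn
  from the equilibrated pool, then 30 generations at $N_e = 150$ with
  Poisson crossovers; the sampled cohort (853 by default) is bred from the
  final parental generation.
* **Chip-style ascertainment.** Candidate sites are over-generated with a
  flat common-variant founder spectrum, then filtered to MAF $\ge 0.05$
  in the sampled cohort and thinned evenly to the target density
  (1300/Morgan by default); the resulting MAF spectrum has mean ≈ 0.25,
  matching a commercial chip's common-variant profile.
* **Recombination heterogeneity** via a piecewise relative-rate profile
  (`centromere_profile()` suppresses the central region, emulating the
  high-LD centromeric pattern), **population splits** with migration, and
  **half-sib families** grafted onto a finished population
  (`add_half_sib_structure()`), for the between-population and
  relatedness experiments.

What it does *not* emulate: new mutation after founding (negligible over
30 generations), selection, sex chromosomes, genotyping error or
platform-specific cluster artefacts, and cross-breed ascertainment bias.
Passing tests therefore demonstrate correctness of the pipeline under a
neutral, autosomal, error-free caricature of the breed — not performance
on any real dataset.

## Numerical choices and degenerate inputs

* Two-locus EM initialises at linkage equilibrium and preserves allele
  marginals exactly; monomorphic input is an error, as is $D'$ at boundary
  marginals.
* `optimize()` is used for all 1-D fits with the boundary re-checked
  explicitly (golden-section never evaluates endpoints).
* Equidistant selection resolves distance ties to the lower bp position;
  the GA repairs offspring by sort/deduplicate/refill-nearest.
* Posterior ties in genotype calls go to the genotype with the higher
  reference Hardy–Weinberg probability.
* A test sample with no observed panel SNP on a chromosome falls back to
  reference Hardy–Weinberg posteriors with a warning; requesting more
  templates than available haplotypes caps $K$ with a warning.
* All randomness (splits, GA, template subsampling, random engine,
  simulation) is seeded per call, and seeded helpers restore the caller's
  RNG state.

## Problem sizes

The test suite simulates one 0.5-Morgan chromosome with ~300 SNPs and 500
samples for module-level checks, and the full study conditions (1 Morgan,
~1300 SNPs, 853 samples split 200/490/163) for the end-to-end suite; the
density trend is evaluated on a 60-sample test subset, the headline cell
on the full 163. The analysis scripts use the full conditions with three
densities by default; the complete six-density sweep is a one-line edit in
`analysis/04_impute_and_evaluate.R`.

## Known limitations

The copying engine's absolute accuracy at a given panel density depends on
the template subsample size $K$ and on reference phase quality, so
absolute levels should be read as lower bounds for what a production
imputation tool with richer haplotype modelling can reach; relative
comparisons across selection methods and densities are the robust output.
The LDU map is fitted from $|D'|$, which saturates in regions of complete
LD; map resolution there is limited to marker intervals, and the Malecot
asymptote estimate requires a chromosome long enough to contain
near-unlinked pairs. Per-chromosome panel allocation uses physical length
only; allocating by LDU span genome-wide is a plausible refinement that is
deliberately out of scope.
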