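---
title: "Phenotypic and SSR diversity analysis of tea germplasm: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic and SSR diversity analysis of tea germplasm: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teadiv)
```

`teadiv` implements the joint phenotype + microsatellite workflow used in
germplasm diversity surveys, built around a study of 40 wild tea
(*Camellia sinensis*) accessions from seven populations in Chongzuo,
Guangxi, genotyped at 14 SSR loci. This vignette is the package's account
of the statistics it computes, the modelling assumptions behind them, the
defaults and why they were chosen, and what the bundled simulator can and
cannot tell you about real data.

## Phenotypic diversity

Descriptive traits (tree type, leaf shape, serration, ...) are recorded as
small integer category codes; quantitative leaf traits are measured in cm
and cm² (leaf area follows the survey convention *length × width × 0.7*).
Three statistics summarize each trait:

* **Shannon–Weaver index** $H' = -\sum_i P_i \ln P_i$ over the observed
  category proportions $P_i$ (natural log, so $H'$ is in nats and bounded
  by $\ln k$ for $k$ categories).
* **Coefficient of variation** $\mathrm{CV} = 100\,s/\bar x$ with the
  sample ($n-1$) standard deviation. For coded traits the codes are
  treated as ordinal scores; this is the only convention that reproduces
  the published CVs of the Chongzuo survey (e.g. tree type 15.76% from
  35×code 2 + 5×code 3 at $n = 40$), which pins both the $n-1$ choice and
  the codes-as-scores choice.
* **Quantitative grading**: continuous traits are discretized before
  computing $H'$. The grid is anchored on the sample moments: class 1
  below $m - 2\sigma$, the top class at or above $m + 2\sigma$, interior
  classes each $0.5\sigma$ wide (10 classes by default). The survey cites
  a grading method without detail; published quantitative $H'$ values
  (1.91/1.90/1.93/1.70) are not reproduced by this grid, nor by
  equal-width or equal-frequency 10-class grids, so they should be read as
  convention-dependent. `grade_quantitative()` is validated instead
  against the analytic normal bin masses it implies.

For clustering, all traits (codes and measurements) are standardized to
per-trait z-scores, accessions are compared by Euclidean distance, and the
tree is built with the same UPGMA engine used for the marker data.
Zero-variance traits are dropped with a warning rather than producing
`NaN` columns.

Several published trait-summary rows are internally inconsistent (their
printed $H'$ or CV cannot be obtained from their own printed frequencies,
e.g. leaf blade color prints $H' = 1.00$ where the frequencies give 1.26).
The fixture table flags each row (`h_consistent`, `cv_consistent`), the
package reproduces the *formula*, and only consistent rows are used in
validation.

## Marker diversity statistics

For a codominant diploid locus with allele frequencies $p_i$ estimated by
direct allele-copy counting (two copies per non-missing call, per-locus
deletion of missing calls):

* $N_a$ — observed alleles; $N_e = 1/\sum p_i^2$ — effective alleles;
* $I = -\sum p_i \ln p_i$ — Shannon information (same kernel as $H'$,
  natural log);
* $H_o$ — fraction of heterozygous calls; $H_e = 1 - \sum p_i^2$
  (the uncorrected form used by GenAlEx-style workflows; the unbiased
  $\frac{2n}{2n-1}$ correction is available as an option, off by default
  to match the provenance of the survey tables);
* $F = 1 - H_o/H_e$ — within-locus fixation index, computed from
  unrounded $H_o$/$H_e$ (recomputing from 2-dp published values can shift
  the second decimal);
* $\mathrm{PIC} = 1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$ (Botstein).

Per-population summaries average these across loci; the "percentage of
effective alleles" is $100\,\overline{N_e}/\overline{N_a}$ on the
unrounded means.

## Differentiation: AMOVA, Fst, gene flow, Nei distance

`amova()` partitions allelic variance at three levels — among populations,
among individuals within populations, within individuals — using the 0/1
allele-mismatch distance summed over loci (the GenAlEx default for
codominant data; a stepwise-mutation R_ST-style distance is deliberately
out of scope). Sums of squares use the pairwise identity
$SS = \sum_{i<j} d_{ij}/n$ within each level; degrees of freedom are
$k-1$, $N-k$, $N$; variance components follow the standard
unequal-sample-size estimators with
$n_0 = (N - \sum n_i^2/N)/(k-1)$. Negative components (common in
near-panmictic data) are reported raw but truncated to zero before
percentages, with a flag. $F_{ST} = \sigma^2_a/\sigma^2_{tot}$ by
construction equals the among-population percentage divided by 100.
Pairwise $F_{ST}$ runs the two-population AMOVA per pair; island-model
gene flow is $N_m = (1-F_{ST})/(4F_{ST})$.

Population distances use Nei's (1972) standard distance
$D = -\ln\!\big(J_{XY}/\sqrt{J_X J_Y}\big)$ with the identity
probabilities averaged over loci (ratio of means, Nei's original form).
The survey computed distances in PowerMarker without naming the measure;
Nei 1972 is the package default and the tooling accepts any labelled
distance matrix, so the choice is not load-bearing for downstream
clustering code.

A Mantel test relates two distance matrices by the Pearson correlation of
their strictly-lower triangles, with a one-tailed permutation p-value
$(\#\{r_{perm} \ge r_{obs}\} + 1)/(B+1)$ under simultaneous row/column
permutation of the second matrix. The default $B = 9999$ (the survey does
not state its count); p-values are verified uniform under the null and the
Monte-Carlo p agrees with exhaustive enumeration on 4×4 problems.

## UPGMA and the height convention

A single UPGMA engine serves the phenotype tree, the population tree and
the individual tree. One convention matters: merges are recorded at *half*
the average inter-cluster distance, so two populations at Nei distance
0.24 join at height 0.12 and "cutting at genetic distance $x$" means
cutting at height $x$. This is pinned by the survey's narrative, which
reads thresholds 0.12/0.17/0.20 directly off a tree built from a matrix
whose smallest entry is 0.24. `upgma()` is `hclust`-compatible
(`stats::hclust(method = "average")` reports the same merges at twice the
height, and is used as an independent oracle in the tests). Ties are
broken by the lexicographically smallest pair of cluster labels, making
the merge list invariant to input row order; average linkage guarantees
monotone heights, and sub-nanometre floating-point inversions are clamped.

Individual-level genetic distances use allele sharing,
$1 - \mathrm{shared}/(2L)$ over loci non-missing in both individuals. The
survey does not name its individual-level metric, so individual-tree
results are validated only on simulated data (cluster recovery), never
against published individual trees.

## Admixture model and Evanno ΔK

`admixture_gibbs()` implements the independent-allele-frequency admixture
model: each allele copy has a latent cluster of origin $z$ with
$\Pr(z=k) \propto q_{ik}\,p_{k\ell a}$; cluster frequencies and individual
ancestries are Gibbs-updated from $\mathrm{Dirichlet}(\lambda + \text{counts})$
and $\mathrm{Dirichlet}(\alpha + \text{counts})$ with $\lambda = \alpha = 1$.
$\alpha$ is held fixed — the reference implementation's Metropolis update
of $\alpha$ adds complexity that ΔK-based selection of the cluster number
does not need; this is a deliberate simplification. The correlated-allele-
frequency prior, linkage model and sample-group priors are likewise out of
scope.

The model evidence is estimated as
$\widehat{\ln P(D)} = \overline{\ln L} - \tfrac{1}{2}\mathrm{Var}(\ln L)$
over retained sweeps — the estimator the ΔK statistic was designed
around. It is exact only for normally distributed $\ln L$; on a one-locus
toy it converges within ~0.23 nats of the exact Dirichlet-multinomial
evidence, and the tests assert agreement within 0.3 nats. Because the
same estimator is used at every $K$, the bias largely cancels in the
second differences that ΔK uses.

`evanno_delta_k()` takes a $K \times \text{replicate}$ table of
$\widehat{\ln P(D)}$, computes per-replicate second differences
$L''(K)$, and reports
$\Delta K = \overline{|L''(K)|}\,/\,\mathrm{sd}_K$; the supported cluster
number is the argmax (defined for $2 \le K \le K_{max}-1$). A zero
replicate SD yields an infinite ΔK with a warning rather than an error.
Membership classification assigns each individual to its largest-Q cluster
and flags individuals with $\max Q$ below 0.6 — the survey's threshold for
a "complex genetic background" — as admixed.

**Run lengths.** The survey's settings (100 000 sweeps, 10 000 burn-in,
20 replicates, $K \le 10$) remain available through the arguments. The
package defaults are desk-scale — 20 000 sweeps, 5 000 burn-in, 10
replicates, $K_{max} = 5$ — chosen because on 40×14 panels the chain mixes
within a few hundred sweeps and ΔK selection is insensitive to longer
runs. The validation suite runs reduced settings (3 000 sweeps, 600
burn-in, 5 replicates, $K_{max}=4$, ten independent experiments), at which
the true $K = 2$ is recovered with wide margins (ΔK at the true K is one
to two orders of magnitude above the runner-up).

## The synthetic-data generator

Simulated panels use the Balding–Nichols construction: ancestral
frequencies from a flat Dirichlet, descendant frequencies from
$\mathrm{Dirichlet}\big(p\,(1-F)/F\big)$, whose divergence parameter $F$
is exactly the expected $F_{ST}$ — so Fst-recovery tests have a
quantitative truth. `simulate_tea_panel()` mirrors the study design: 40
accessions in populations of sizes (5, 5, 10, 5, 5, 5, 5), 14 loci with
4–15 alleles, two ancestral clusters with only the first population (the
analogue of the survey's divergent high-elevation population) drawn from
the minor cluster, 2% missing calls, and population-correlated phenotypes
built from the same cluster assignment (18 coded traits with
Dirichlet-divergent category distributions; leaf length/width with
per-cluster offsets and the ratio/area traits derived exactly).

The two divergence levels default to `fst_between = 0.28` and
`fst_within = 0.10`, fixed once by scanning twelve seeds so that the
realized among-population AMOVA share centres on the study's ~20% (scan
mean 19.5%, range 16–25%).

What the generator does *not* emulate: stepwise SSR mutation (allele
labels are arbitrary sizes, consistent with the mismatch-distance AMOVA),
linkage between loci, genotyping error beyond uniform missingness,
null alleles, and environment-driven phenotype covariance. Passing
recovery tests therefore demonstrate correctness of the estimators under
the stated model, not robustness to those real-data complications.

## Numerical choices and degenerate inputs

* Monomorphic loci: $N_e = 1$, $I = H_e = \mathrm{PIC} = 0$, $F$ undefined
  (`NA`); population summaries skip all-missing loci with a message.
* $F_{ST} \le 0$: gene flow returns `Inf` with a warning; $F_{ST}$
  estimates below 0 are truncated to 0 in the pairwise matrix.
* Nei distance with no shared alleles at any locus: `Inf` with a warning.
* Zero-SD traits: dropped from standardization (warning); zero-SD grading
  puts everything in the middle class (warning).
* Mantel on a zero-variance triangle and half-missing genotype calls are
  errors, not silent `NA`s.
* All randomness flows from explicit seeds; the Gibbs sampler uses R's
  RNG, so `set.seed()` governs it too, and replicate scans derive
  per-run seeds deterministically from the master seed. Pipeline reruns
  with the same configuration are byte-identical.

## Reading the bundled survey tables

`survey_tables()` ships the published summary tables as plain-text
fixtures: the accession map, the locus panel, trait and leaf-trait
tables, per-locus and per-population diversity, the population distance
matrix, the combined Fst/Nm matrix, and the AMOVA table. Three
transcription repairs are applied and documented in the loader's help
(a doubled decimal point, run-together digits, a frequency that must be
12.50 for its row to sum to 100); one leaf-width value is retained as
published but flagged suspect, and the leaf-width column is excluded from
any validation that needs it. The published membership list assigns one
accession to two populations; the fixture keeps the population sizes at
their stated values. The raw genotype table behind the survey is not
published, so marker statistics are validated by simulation and by the
printed tables' internal identities, not by re-deriving the tables from
genotypes.

## Worked example

```{r example, eval = FALSE}
library(teadiv)

sim <- simulate_tea_panel(seed = 1)
run_full_analysis(sim$genotypes, sim$phenotypes, out_dir = "analysis",
                  Kmax = 5, reps = 10, sweeps = 20000, burnin = 5000,
                  seed = 1)
```

emits the ten report tables (trait summary through Mantel) plus Newick
trees and a manifest. On the published tables alone:

```{r fixtures, eval = FALSE}
tabs <- survey_tables()
tree <- upgma(tabs$population_distance)
cut_dendrogram(tree, height = 0.20)   # the divergent population stands alone
gene_flow(0.38)                       # 0.41 migrants/generation at max Fst
```

## Known limitations

* The published quantitative-trait $H'$ values are convention-dependent
  and not reproduced (see above); treat `grade_quantitative()` output as
  internally consistent rather than comparable across software.
* AMOVA degrees of freedom assume the full design even when individual
  loci have missing calls (sums of squares already exclude them); with
  heavy targeted missingness the df are nominal.
* The admixture sampler is single-chain per run; replicate scans, not
  within-chain diagnostics, are the intended convergence check.
* lnPD is a biased evidence estimator (shared with the reference
  implementation); compare values only across $K$ within one dataset.
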