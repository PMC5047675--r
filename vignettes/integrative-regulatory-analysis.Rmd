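---
title: "Integrative analysis of ChIP-seq reproducibility, enhancer annotation, expression and AP-MS stoichiometry"
author: "chromflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative regulatory analysis with chromflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromflow)
```

## What this package computes

chromflow is a testable re-implementation of the analysis pattern behind a
common question in stem-cell regulatory genomics: a zinc-finger
transcription factor (here called by its mouse name, Sall4) binds thousands
of genomic sites and co-purifies with a chromatin-remodelling co-repressor
(the NuRD complex) — does it *recruit* that complex to chromatin, and does
it act *through* it? Answering this requires stitching together four data
types:

* replicated ChIP-seq peak calls, filtered for reproducibility;
* histone-mark signal, to classify binding sites as promoters, gene bodies,
  intergenic sites, poised enhancers or active enhancers;
* RNA-seq differential expression in factor-knockout lines, joined to peaks
  through nearest-gene assignment; and
* quantitative AP-MS, to measure what fraction of the factor is physically
  in the complex at all.

Every stage is driven by a synthetic-data generator that plants known
ground truth, so the pipeline's statistical behaviour (error rates, power,
parameter recovery) is itself under test.

## The IDR copula mixture model

Two ChIP-seq replicates are paired peak-by-peak (greedy one-to-one matching
by overlap, visiting replicate-1 peaks in descending score order). The
paired scores $(x_i, y_i)$ enter only through their ranks,
$u_i = (\mathrm{rank}_i - 0.5)/n$. On normal scores $z = \Phi^{-1}(u)$ the
model is a two-component bivariate Gaussian mixture:

* component 0 (irreproducible): standard bivariate normal, independent
  coordinates;
* component 1 (reproducible): mean $(\mu, \mu)$, common variance
  $\sigma^2$, correlation $\rho$; mixing weight $\pi_1$.

The *local IDR* of a pair is its posterior probability of component 0; the
*global IDR* at rank $i$ is the mean of the $i$ smallest local IDR values,
an FDR-like quantity that is non-decreasing along the ranking. Peaks with
global IDR at or below a threshold (default 0.05, a user-facing argument —
the analysis this models does not publish its threshold) are exported with
the two replicate intervals merged and scores summed.

**Why the pseudo-data iteration.** A tempting simplification is to fit the
mixture once on plain rank normal scores. We implemented and measured that
variant: because the *marginal* of the mixture is itself a mixture, the
one-pass transform maps the irreproducible mass away from the standard
normal that component 0 assumes, and EM compensates by absorbing everything
into the flexible component ($\hat\pi_1 \approx 0.94$ when the truth is
0.7). `fit_idr()` therefore re-derives the normal scores between EM passes
by inverting the current fitted marginal CDF
$H(z) = \pi_1 N(z;\mu,\sigma^2) + (1-\pi_1)N(z;0,1)$ at the rank quantiles
— the standard pseudo-data step of semiparametric Gaussian-copula
estimation. With it, mean absolute error of $\hat\pi_1$ is 0.02–0.09 across
$\pi_1 \in \{0.3, 0.5, 0.7, 0.9\}$ (n = 2000 pairs), which the acceptance
suite asserts.

Numerical choices: EM starts at $\pi_1 = 0.5, \mu = 1, \sigma^2 = 1,
\rho = 0.5$; inner convergence at $|\Delta \ell| < 10^{-6}$ (cap 500
iterations, warning on non-convergence); outer pseudo-data loop stops when
no parameter moves by more than $10^{-4}$ (cap 30). $\rho$ is clamped to
$[0, 0.999]$ and $\pi_1$ to $[10^{-4}, 1-10^{-4}]$. Ties in scores are
rank-averaged; a replicate whose scores are all tied is rejected rather
than fitted. Unpaired peaks never reach the model and are never called
reproducible. The lenient alternative, `merge_replicates()`, is the plain
union of both replicates collapsed by overlap; its loci are a superset of
any IDR-passing set by construction.

```{r idr-example}
cfg <- sim_config(seed = 7, pi1 = 0.7, n_peaks = 1000, factors = "Sall4")
ann <- make_genome(cfg)
pk <- simulate_peak_replicates(ann, cfg)
pp <- pair_replicates(pk$Sall4$rep1, pk$Sall4$rep2)
fit <- fit_idr(pp)
fit
reproducible <- call_reproducible(assign_idr(fit, pp), pp, alpha = 0.05)
nrow(reproducible)
```

## Five-class peak annotation

Peaks are scored against binned mark tracks as mean per-base signal within
the peak divided by the genome-wide median bin value, then classified by a
fixed cascade:

1. centre within 1 kb of a TSS, *or* H3K4me3 enrichment $\ge$ 4 →
   **promoter**;
2. otherwise H3K4me1 $\ge$ 2 → **active enhancer** if H3K27ac $\ge$ 2,
   else **poised enhancer**;
3. otherwise centre inside a gene → **gene body**; else **intergenic**.

The promoter rule deliberately precedes the enhancer rule: a
H3K4me3-high TSS peak is a promoter even when H3K4me1-high, which matches
the observation that enhancer-binding factors correlate with
H3K4me1/H3K27ac but not H3K4me3. The source analysis defines its five
classes in a supplement we treat as unavailable, so this cascade is the
package's own declared rule set; every window and threshold is a
`classification_thresholds()` field, so an alternative definition is one
argument away. Raising a threshold can only demote (e.g. active → poised),
never promote — a monotonicity the tests assert.

## Profiles and occupancy correlation

`profile_matrix()` averages track bins in 80 × 50 bp windows spanning
±2 kb around each peak centre (rows sorted by total signal, the heat-map
convention; windows clipped at a chromosome edge are padded with the
genome median and flagged). `occupancy_correlation()` reduces each dataset
to a binary occupancy vector over the merged universe of all peaks and
reports pairwise Pearson r with average-linkage clustering on 1 − r. We
correlate *peak occupancy* rather than binned signal because it is
scale-free and matches how such heat maps are usually labelled
("correlation between ChIP peaks"); `signal_correlation()` provides the
binned-signal alternative since published figures do not always say which
was used.

## Differential expression

The DE stage is self-contained rather than a wrapper, so its statistical
behaviour is fully specified here:

* **Size factors** are classic median-of-ratios to the per-gene geometric
  mean (log-space median, rescaled to median 1), with an upper-quartile
  fallback when no gene has all-positive counts.
* **Dispersion** $\phi$ ($\mathrm{Var} = \mu + \phi\mu^2$) is estimated per
  gene by method of moments on normalised counts, then shrunk 50/50 toward
  a lowess trend on the log mean, and finally floored at the trend. The
  floor matters: with three replicates per group the MoM estimate is often
  zero by chance, and a gene granted near-Poisson dispersion produces false
  positives. With the floor, 20-seed null simulations (2000 genes) yield a
  realised false-discovery proportion of 0.05 at nominal 0.05, and planted
  $|\log_2 \mathrm{FC}| = 2$ genes at mean ≥ 100 are detected with
  essentially full power at 3 vs 3 — both asserted by the acceptance suite.
* **The test** conditions on the per-gene total: condition sums of
  normalised counts are modelled as NB, and the p-value is the probability
  mass of all splits of the observed total no more likely than the observed
  one (the classic exact-style two-group NB test). Enumeration is windowed
  to the region holding all but $10^{-12}$ of the mass, so large counts stay
  cheap. BH correction gives the FDR; the default gene-level threshold is
  0.05.

FPKM is `count / (length_kb × mapped_millions)`; PCA embeds samples by SVD
of gene-centred `log2(FPKM + 1)` over the 500 most variable genes (both
transform and gene count are arguments; the modelled analysis does not
state its choices), with component signs fixed so the first retained gene
loads non-negatively.

Single-cell qPCR: per cell, $-\Delta C_t = -(C_t^{\mathrm{gene}} -
\overline{C_t^{\mathrm{housekeeping}}})$ with defaults Atp5a1, Ppia and
Gapdh as the housekeeping panel. Missing wells stay missing — no
limit-of-detection imputation — matching how such heat maps grey out
unavailable cells; cells with no housekeeping measurement are dropped with
a warning. Clustering is average linkage on Euclidean distance with
pairwise-complete missing-value handling; bulk comparisons use
$2^{-\Delta\Delta C_t}$.

## AP-MS: interactors and stoichiometry

Missing LFQ intensities are left-censored, so `impute_missing()` draws
them per run from a normal down-shifted by 1.8 observed s.d. with 0.3 of
the observed spread (the standard treatment for missing-at-low-abundance
data), deterministically under a seed. `volcano_test()` compares bait and
control runs with a moderated statistic $d = \Delta / (s + s_0)$
($s_0 = 0.1$ guards small variances), builds a pooled null from all
distinct balanced label permutations (the observed partition is excluded
in *both* orientations — its sign-flipped twin would otherwise plant every
true effect inside its own null), and calls interactors at BH-FDR ≤ 0.01
with positive enrichment. With 3 vs 3 runs there are 18 usable
relabellings; the permutation cap, $s_0$ and the FDR threshold are all
arguments because the modelled analysis leaves them in an unavailable
supplement.

Stoichiometry follows the iBAQ convention: background-corrected mean bait
intensity (control mean subtracted, clamped at zero) divided by the
theoretical tryptic peptide count approximates molar abundance; each
protein is reported relative to the summed abundance of the anchor
subunits (Mbd2 and Mbd3 share one complex slot, hence the sum). Peptide
counts default to 1 when unknown, degrading gracefully to plain intensity
ratios. Under one bait copy and one anchor slot per complex, a bait at
$S$-fold molar excess has $100/S$ percent of its molecules in the complex:

```{r stoich-example}
cfg <- sim_config(seed = 1, noise_cv = 0, censor_q = 0, n_background = 0)
st <- stoichiometry(simulate_lfq(cfg),
                    anchor_proteins = c("Mbd2", "Mbd3"), bait = "Sall4")
attr(st, "S_bait")
fraction_in_complex(st)
```

## Cross-dataset integration

Peaks map to genes by nearest TSS from the peak centre (strand ignored for
the distance; ties broken toward the lexicographically smaller gene id —
the published analysis does not state its assignment rule, so this
reproducible convention is ours and is documented on `nearest_gene()`).
`overlap_report()` and `dependency_analysis()` reproduce the worked
arithmetic of recruitment analyses — e.g. a fixture with 4422 cofactor
peaks lost in a knockout, 1073 of them bound by the candidate recruiter,
reports 24% — with percentages rounded half away from zero to integers and
fold gains to one decimal, the granularity such results are printed at.
`direction_correlation()` regresses shared DE genes' fold changes and
reports $R^2$; on independently planted effects mean $R^2 \le 0.05$ (the
"no correlation" signature that argues *against* joint regulation), on
correlated effects $R^2 \ge 0.9$. Both tallies of ambiguous universes
(gene-level after deduplication, and peak-level) are available from the
primitives, since published percentages do not always say which was used.

## The synthetic-data generator

All generators are pure functions of a `sim_config()` (identical seed ⇒
byte-identical output, caller's RNG untouched), and every latent truth —
reproducibility labels, planted fold changes, complex composition,
population labels — is returned alongside the data but never consumed by
an analysis stage.

Default study conditions, chosen once as a compact but realistic desk-scale
stand-in for a mouse ESC dataset: 2 × 1 Mb chromosomes, 200 genes (2–8 kb),
150 enhancer loci of 500 bp (half active); 1000 latent peak loci per
factor at 400 bp width; replicate scores log-normal with the reproducible
component shifted 2 log-units and correlated at 0.8; signal tracks binned
at 50 bp over a Poisson(5) background with 8-fold enrichment at marked
loci; NB counts with dispersion 0.05 (typical for laboratory RNA-seq) and
log-normal baseline means; a 14-subunit complex with the bait at 14-fold
excess, 20% LFQ noise CV, left-censoring below the 0.15 intensity quantile,
100 background binders; 40 + 35 cells separated by 6 Ct on opposing marker
panels, 10% dropout. DE simulations in the test and acceptance suites use
2000 genes on a 2 × 20 Mb genome so that baseline means span a realistic
range — sizes picked so the whole suite runs in well under a minute of
simulation time per criterion.

One generator decision deserves its rationale here: in
`simulate_peak_replicates()`, every latent locus appears in *both*
replicates — reproducible loci (probability `pi1`) get correlated scores,
irreproducible loci get independent scores from the background marginal —
and per-replicate-only noise peaks are an optional extra (`n_unpaired`,
default 0). This is the structure the IDR mixture actually models
(paired observations from two score-coupling regimes); making
irreproducible peaks replicate-private instead would leave the model
nothing to fit and would break the limit case `pi1 = 1` (every replicate-1
peak then has a replicate-2 partner). Factor co-occupancy is generated
relative to the first (reference) factor; mutual overlap among
non-reference factors arises only by chance, because arbitrary pairwise
constraints are not jointly satisfiable.

What the generator does *not* emulate — and hence what green tests do not
show about real data: read-level artefacts (mappability, GC bias, fragment
size), peak-width and peak-shape heterogeneity, dispersion trends that
vary by biotype, batch effects, ratio compression in LFQ, and
amplification-efficiency differences between qPCR assays. Conclusions
about those failure modes need real data.

## Known limitations

* IDR handles exactly two replicates (the standard pairwise practice);
  more replicates mean more pairwise runs.
* Nearest-TSS assignment ignores topological domains and enhancer-promoter
  loops; it is the field's default, not a claim about contact maps.
* The DE test is two-group only — no covariates, no batch terms.
* `fraction_in_complex()` is exactly the one-bait-one-anchor inversion; a
  complex admitting several bait copies would need a different model.
* Genome-scale counts from the modelled study (peak numbers, DE gene
  counts) depend on raw sequencing data and are out of desk-scale reach;
  the package reproduces the *arithmetic and statistical machinery*, and
  its worked examples use the published counts as fixtures.
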