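---
title: "Modelling TP53-dependent Cas9 cut toxicity in pooled screens"
author: "dsbtox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling TP53-dependent Cas9 cut toxicity in pooled screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbtox)
library(SummarizedExperiment)
```

## The problem

Cas9 knockout screening works by cutting DNA. The double-strand break (DSB)
itself, independently of the gene it disrupts, costs fitness -- and in cells
with intact p53 the cost is larger, because p53 responds to DSBs with arrest
or apoptosis. The penalty is not uniform across the genome: cuts in open,
actively transcribed chromatin provoke a stronger p53 response than cuts in
lamina-associated heterochromatin, and the DNA sequence around the cut
(microhomologies that enable MMEJ repair, the base directly upstream of the
NGG PAM, G/C-rich motifs) modulates it further. In a screen comparing
conditions this guide-level toxicity behaves as structured noise: it depletes
guides in both arms, attenuates effect sizes, and differs between sgRNAs
targeting the same gene, which reduces the power to detect conditional
essentiality in TP53 wild-type cells.

`dsbtox` implements the analysis chain for quantifying this effect from an
isogenic-pair screen (TP53 wild type versus knockout), and a synthetic screen
generator so the whole chain is testable without any external data.

## The screen container and normalization

Counts live in a `SummarizedExperiment`: assay `counts` (raw integers,
sgRNA x sample), `rowData` the guide library, `colData` the sample sheet
with `genotype` (factor, knockout first = model reference),
`pseudo_replicate` (treatment arm used as a near-replicate), `time_point`,
and `offset` -- the natural log of the sample's total non-targeting counts,
which is the exposure term of every count regression.

`medianNormalize()` computes median-of-ratios size factors on a reference
set (all guides, the non-targeting controls, or a non-essential gene list):
with `g_i` the geometric mean of reference guide `i` across samples,
`s_j = median_i(c_ij / g_i)`. The arithmetic median of ratios is used
(for an odd reference count it coincides with the log-scale median).
`computeLFC()` then forms `log2((treated + pc) / (control + pc))` per guide
for matched wild-type/knockout sample pairs. The pseudocount defaults to 1
(configurable); it only matters for dropouts, and keeps every LFC finite. A
`drop_zero_baseline` option removes guides absent from the baseline sample.
Technical batches can be summed with `mergeBatches()` before normalization;
merging across genotypes is refused.

## Locus classes

With three pseudo-replicates and three later time points there are nine
wild-type-versus-knockout comparisons. `callTargetLoci()` labels a guide a
*target* (p53-toxic) locus when its LFC is below -0.5 in **all** nine;
`callNonSelected()` takes `|LFC| < 0.5` in all nine; *background* loci are
the remaining guides of genes that contain a target, i.e. same-gene controls
for gene-function effects. Two points were genuinely open and are decided
here: background guides are **not** additionally required to be
non-selected (they are defined purely by gene membership), and consistently
positively selected guides are kept in the background by default
(`exclude_positive` flips this).

Target guides in TP53-interactor genes, genes from enriched GO terms, or
OR*/USP*/FAM* family genes (symbol-prefix rule with an override list) are
removed with per-filter provenance. The off-target filter removes targets
with any exact-match off-target or a total CFD (sum over the top-5
off-targets; scores are inputs, not computed here) above the 95th percentile
of the non-selected loci, using type-7 (linearly interpolated) quantiles.

## Sequence features at the cut

* **Microhomology.** `findMHPairs()` enumerates identical arm pairs of
  5-15 bp flanking the cut with each arm's cut-proximal end within 15 bp of
  it. The window rule is applied to *both* arms' proximal ends, arms must not
  span the cut, and arms containing `N` never match. A locus with at least
  one pair is an MMEJ candidate. All three geometry parameters are exposed.
* **PAM context.** `extractPAMContext()` reduces the 4-mer (1 bp upstream +
  NGG) to its upstream-base class (`CNGG`, `GNGG`, ...), reverse-complementing
  genome-oriented minus-strand records first.
* **CpG.** Overlap-free `CG` dimer count over the context window.
* **Motifs.** `scanMotif()` counts exact IUPAC-consensus matches on both
  strands whose span intersects a window centred on the cut (half-widths 8,
  25, 50 give 16/50/100 bp search lengths), capped at 5 occurrences per
  locus; covariates present in under 10% of the locus universe are dropped
  (inclusive threshold: exactly 10% is kept). Both the capped count and a
  binary presence encoding are available, defaulting to the count;
  `scanPWM()` offers PWM matching at 80% of the maximal score as the
  alternative mode.

## Covariate binning

Chromatin-mark abundances are binned 0 (absence) / 1 / 2, splitting the
positive territory at a weighted median chosen to balance the two bins'
total genome weight to within one unit; ties at the split go to the lower
bin, and bin-1 guides are masked out of single-feature regressions to
sharpen the absence-versus-abundance contrast. With no genome-territory
weights available (all synthetic data), equal weights over the guide
universe preserve the 50/50 semantics. Copy-number bins 1-7 binarize to
high = 5-7; replication timing 0-6 to early = 6, with bin-0 guides dropped;
genes longer than 200 kb are removed before the short/long median split;
cut-to-5'-end distance is scaled to [0, 1]. All split points are returned
for reproducibility.

## The toxicity regressions

The central model, fit with `MASS::glm.nb` (log link, single ML-estimated
dispersion theta, IRLS tolerance 1e-8, 100 iterations max, Poisson fallback
flagged on failure), is

```
counts ~ feature * TP53_status + D2 + offset(log total non-targeting counts)
```

with reference levels *feature absent* and *knockout*. The interaction
coefficient is the quantity of interest: the extra log-count change per
feature unit in the wild type, i.e. p53-dependent cut toxicity associated
with the feature. D2 (RNAi-based gene essentiality) absorbs gene-function
fitness effects, so what remains is attributable to the break, not the
knockout. Unordered factors use treatment coding, ordered ones polynomial
contrasts (R defaults). Supporting variants: the wild-type-only model
(`counts ~ feature + D2 + offset`), pairwise-conditioned models adding one
co-feature (with its own status interaction by default -- both readings of
the open "interacting or not" question are exposed via
`interaction_mode`), status-only and D2-only baselines, and the cell-line
panel models `counts ~ TP53 * HR + D2 + tissue + offset` and
`counts ~ feature * HR + D2 + tissue + offset` with breast as tissue
reference and per-line offsets over a supplied non-essential gene set.

**Time-course exposure.** The simulator scales effects with the time index
(see below), so a fit pooling several later time points estimates a
count-weighted average effect. Passing `effect_exposure` (the per-sample
time index) scales the effect covariates so the coefficient becomes a
per-time-unit effect. Scaled covariates acquire a sample-level mean
component proportional to the exposure, which would let per-sample
offset-measurement noise leak into the feature terms; the fit therefore
adds exposure and exposure-by-genotype terms whenever the exposure varies,
keeping the interaction identified by within-sample contrasts. With the
default exposure (1 everywhere) the formula is exactly the cross-sectional
model above. Type-I error of the interaction test was verified at ~5%
under the null in simulation.

FDR control is Benjamini-Hochberg by default; `method = "qvalue"` gives a
Storey q-value (pi0 from a lambda grid 0.05-0.95 with a cubic smoothing
spline evaluated at lambda = 0.95, q = pi0 x BH) that falls back to BH when
fewer than 100 p-values are supplied or pi0 is unstable.

## Copy-number calibration and the example score

Copy-number amplification gives the one covariate whose toxicity has a
natural physical unit. The binarized CN contrast spans mean CN scores 0.7
(reference) versus 2.0 (high), a 2.9-fold ploidy difference, so a feature
coefficient converts to ploidy units by rule-of-three:
`fold_ploidy = 2.9 * beta_feature / beta_cn`. Summaries round ploidy
equivalents to 1 decimal and count fold changes (`exp(beta)`) to 2, always
retaining full precision. `scoreSgRNA()` provides an *example* linear
p53-toxicity score -- a weighted sum of locus covariates with weights
defaulting to the negated interaction coefficients averaged across
pseudo-replicates, plus a library-wide percentile rank. Its exact
functional form was an open question; the linear form is this package's
documented reconstruction, and deliberately not a trained classifier.

## Screen-level statistics

`essentialityAUROC()` is the normalized Mann-Whitney statistic (ties 1/2)
for separating essential from non-essential benchmark genes ranked by mean
normalized counts. `zScore()` standardizes per-condition gene scores with
the population (1/n) SD. `emTwoCluster()` fits 2-D Gaussian mixtures with
1-4 components (mclust, BIC selection, seeded initialization) and labels
the component with the lower mean treatment z-score "selected" when two
components win. `conditionalHitCall()` implements the 2-SD rule: control
z within the threshold, treatment z below its negative, and the
treatment-control difference below -2 SD of the difference distribution
(its own SD by default; a pooled SD can be supplied -- whether the study
pooled across genotypes is not stated). `residualCompare()` contrasts
per-genotype OLS residuals of treatment-versus-control z-scores.
`permutationNull()` reshuffles hit labels independently within each of the
12 comparison columns (6 knockout, 6 wild type), preserving column sums
(asserted every iteration), and counts iterations with at least 2 genes hit
in at least 4 of 6 knockout and at most 0 of 6 wild-type comparisons.

`panelEffectSizes()` reconstructs the panel effect size as Cohen's d with
pooled SD (wild type minus mutant; negative = worse fitness with intact
p53) with pooled-variance t-tests -- a documented reconstruction of the
named ANOVA tool's statistic, without its MSI/medium covariates. Panel
target loci take d < -0.4, the low-toxicity control set -0.04 < d < 0.04,
both strict.

## The synthetic screen generator

`simulateScreen()` emulates the isogenic-pair design: 2 genotypes x 3
pseudo-replicates x 4 time points (t0 baseline), 4 guides per gene plus
non-targeting controls, counts drawn independently per guide and sample
from NB(mean, theta) with

```
log mean = baseline + log depth_j
         + s_j * (beta_D2 * D2 + sum_f beta_f x_f + 1[wt] sum_f beta_fxTP53 x_f)
```

where `s_j` is the time index (0, 1, 2, 3) -- effects accumulate over the
time course, mimicking cumulative dropout, and baseline counts predate any
effect. Defaults are the study-like conditions used throughout the tests:
baseline log-mean log(500) (~400-500x coverage), theta = 10, per-sample
depth factors lognormal(0, 0.1), a 50% carrier feature with interaction
-0.3, essentiality slope 0.5 on D2 ~ N(-0.3, 0.4). Non-targeting guides
receive only depth and baseline. Chromatin abundances come from a latent
Gaussian with configurable cross-mark correlation, hinged at the
zero-inflation quantile (default 50%, so bin 0 and bins 1/2 are both
populated); the configured correlation applies to the latent scale and the
induced abundance correlation is mildly attenuated (~0.63 for 0.7).
Context sequences embed the protospacer and PAM around the cut; with
`mh_fraction` set, that fraction of guides gets a planted microhomology arm
pair and the rest are rejection-sampled microhomology-free, making the
planted fraction exactly recoverable by the scanner.

What the generator does **not** emulate -- and hence what green tests do
not certify about real screens: off-target cutting, lentiviral MOI and
infection bottlenecks, PCR jackpotting, batch effects beyond a scalar depth
factor, guide-efficiency variation, and any mean-variance relationship
beyond a single shared theta. Passing recovery tests show the estimators
are correct under the stated generative model, not that real data satisfy
that model.

## Numerical and reproducibility choices

* Integer counts throughout; simulated log-means above 21 are rejected
  (they would leave integer range) naming the offending parameter.
* Quantiles are type 7 everywhere a percentile is taken.
* Ties at binning splits go to the lower bin; the prevalence threshold is
  inclusive.
* Replicate simulations draw their seeds from one master RNG stream
  (`sample.int` after `set.seed(master)`) rather than `master + r`:
  consecutive Mersenne-Twister seeds produce measurably correlated
  replicates, which we observed as an inflated empirical test size before
  switching.
* Every generator is deterministic given (config, seed); the pipeline
  stamps outputs with the seed and a config hash, and reruns are
  byte-identical.
* Problem sizes used by the test-suite recovery studies: 5,000 sgRNAs for
  coverage and dispersion recovery (100 count replicates over a fixed
  library), 800 sgRNAs for the 500-replicate null-size study, 4,000 sgRNAs
  for locus-calling recall, 1,000 random 201-nt sequences for the scanner
  oracles.

## Known limitations

The per-feature regressions follow a marginal design:
conditioning is pairwise only, never joint over all covariates. Gene-level
scores are proxied by median sgRNA LFC when no external beta scores are
supplied. CFD profiles, TP53/HR status labels and tissue assignments are
inputs; the package neither computes off-target scores nor classifies
variants. Under the generator's own stated noise conditions (theta = 10,
500x depth, effect -1 at the first later time point) the all-nine-
comparisons target rule has an irreducible per-guide miss probability at
t9, so recall plateaus near 0.78 -- a property of the rule under these
conditions, discussed alongside the acceptance checks.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- defaultRunConfig()
cfg$n_genes <- 250L
res <- runPipeline(cfg, "dsbtox_run")
head(subset(res$fit_table, role == "interaction"))
```
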