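---
title: "Methods: median-effect synergy analysis, candidate scoring, and pan-cancer meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: median-effect synergy analysis, candidate scoring, and pan-cancer meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicombi)
```

`epicombi` implements the computational core of a two-drug combination
screening study: median-effect dose-response analysis, Chou-Talalay
combination-index (CI) profiling with synergy classification, weighted
multi-feature prioritization of screen hits, a formula-defined impact score
for knockdown screens, and pan-cancer differential-expression and survival
meta-analysis. This vignette records the models, the tunable parameters, and
the design decisions, in the package's own terms.

## The median-effect model

A single drug's dose-response is described by the median-effect equation

$$\frac{f_a}{1 - f_a} = \left(\frac{D}{D_m}\right)^m,$$

where $f_a$ is the fraction affected (one minus relative viability), $D_m$
is the dose producing half-maximal effect (the IC50 on this scale), and $m$
is the sigmoidicity slope. `compute_fa()` converts raw plate signal to
$f_a = 1 - \bar{s}(D)/\bar{s}_\text{control}$; `fit_median_effect()` fits
the log-linearization $\log_{10}(f_a/(1-f_a)) = m\log_{10}D - m\log_{10}D_m$
by ordinary least squares and reports the linear correlation $r$ as the fit
quality statistic.

Numerical choices worth noting:

* **Fa clamping.** $f_a$ values outside $(0,1)$ cannot be log-linearized.
  They are clamped to $[10^{-3}, 1-10^{-3}]$ (configurable) and flagged;
  doses at which the mean signal is at or above control ($f_a \le 0$, e.g.
  growth stimulation) are excluded by default rather than clamped, since a
  clamped zero would otherwise act as an influential pseudo-observation.
* **Replicate handling.** Replicates are averaged before linearization (one
  Fa per dose), matching the convention of the standard desktop CI software;
  fitting replicates as separate points would change the leverage of noisy
  wells.
* **Failure modes.** Fewer than three usable points refuses the fit; a
  non-positive slope returns a fit flagged `non-monotone`, and downstream CI
  computation refuses flagged fits instead of producing doses from an
  inverted curve. CI computation warns when either single-agent $r < 0.90$
  (configurable); no hard cut is applied because screens legitimately
  contain borderline curves whose CI values are still reported, just with a
  caveat.
* **Log base.** Base 10 throughout; the fitted $m$ and $D_m$ are
  base-invariant.

## Combination index

For a constant-ratio series of a drug pair, at each combination point with
observed effect $f_a$ and component doses $(d_A, d_B)$,

$$\mathrm{CI}(f_a) = \frac{d_A}{D_{x,A}(f_a)} + \frac{d_B}{D_{x,B}(f_a)},$$

with $D_x$ the single-agent dose producing the same effect, obtained by
inverting each drug's median-effect fit. CI $= 1$ is Loewe additivity;
below 1, synergy; above 1, antagonism. The mutually exclusive form (no
cross term) is the default, as in the standard workflow this reproduces;
the nonexclusive form (adding $d_A d_B / (D_{x,A} D_{x,B})$) is available
via `form = "nonexclusive"`.

Profiles are summarized by the **median** CI across the tested Fa points
(which drives hit calling) and also by the arithmetic mean (used by
heatmap-style summaries). We read the screening literature's "medium CI" as
the median; the CI at the middle dose point is computable from the stored
profile if a user prefers that reading. Classification uses the closed
interval convention: synergism for CI $< 0.83$, additive for
$0.83 \le \mathrm{CI} \le 1.2$, antagonism for CI $> 1.2$; boundary values
are additive, and hit calling is the strict `median CI < 0.83`.
`screen_rollup()` produces per-line synergistic hit sets and their
intersection across lines.

Combination series are *not* refit with their own median-effect model for
CI computation: CI uses the observed per-point effect, which is the
constant-ratio convention; a total-dose fit is available only as a
diagnostic.

## Priority score

Screen hits are prioritized on five features: summarized CI, single-agent
efficacy, cancer-dependency effect, expression dysregulation, and genomic
alteration. Each feature is min-max normalized with its "good" direction
mapped toward 1 (CI and dependency: lower/more negative is good; the
others: higher is good), then combined as a weighted sum with weights
renormalized to 1. The published figure this emulates shows weighted
features but prints no weights, so the default is equal weights (0.2 each),
exposed as configuration rather than baked in. Candidates with missing
features are scored on renormalized remaining weights and flagged
(`complete = FALSE`); imputation is deliberately avoided so a missing
feature can never push a candidate above fully observed ones on invented
evidence. A constant feature makes min-max scaling degenerate; it maps to
0.5 everywhere with a warning, contributing equally to every candidate.

## Impact score

For a knockdown screen, the score is exactly the four printed formulas:
per-treatment expression fold change
$F_\text{exp}^{t,g} = \log_2 \text{exp}_{t,g} - \log_2 \text{exp}_{C,g}$;
IC50 fold change $F_{IC50}^{kg} = IC50_{kg}/IC50_C$; min-max scaling
$F' = (F - F_\min)/(F_\max - F_\min)$; and
$\mathrm{Score}_g = F'_{IC50,kg} \cdot \sum_t F_\text{exp}^{t,g}$, the sum
running over the provided treatments (two in the emulated design).

The literal product has a sign subtlety: the most-sensitizing gene
($F' = 0$) scores exactly 0, which is the *maximum* whenever all expression
sums are negative — so "highest score" identifies the strongest sensitizer
among repressed genes, but the value itself carries no magnitude. The
default mode (`"literal"`) implements the formula as printed. An
alternative `"magnitude"` mode, $\mathrm{Score} = (1-F')\cdot\left|\sum
F_\text{exp}\right|$, rewards joint sensitization and repression with large
positive scores and ranks a designed strongest-sensitizer/strongest-
repression gene first; it exists because the literal formula's degenerate
zero is an awkward summary of that gene. The mode used is echoed in every
output (attribute `mode`). Ranking is a stable descending sort with
lexicographic tie-breaking on the gene identifier, so re-ordering input
rows can never change a reported rank.

## Pan-cancer meta-analysis

**Sample deduplication.** When a participant has several tumor samples, one
is selected by lexicographic priority: sample type (primary `01` >
recurrent `02` > metastatic `06`), then higher portion number, then higher
plate. "Higher plate" is interpreted as ordered string comparison, which is
how plate identifiers of the emulated cohort sort. Unknown type codes are
excluded with a warning rather than guessed at.

**Differential expression.** Per cancer type with at least three normal
adjacent samples (types below that are excluded and recorded), one-sided
two-sample t-tests on $\log_2(\text{FPKM}+1)$ test up- and down-regulation
separately. Welch's unequal-variance test is the default; the
pooled-variance variant (for which $p_\text{up} + p_\text{down} = 1$ holds
exactly) is available. The log transform with pseudocount 1 is a standard
variance stabilization for FPKM-scale data; the emulated study does not
state its transform.

**Fisher combination and direction.** Each direction's per-type p-values
are combined as $X^2 = -2\sum\ln p_i \sim \chi^2_{2k}$. The direction with
the smaller meta-p is reported, with
$\text{meta-}z = \Phi^{-1}(1-\text{meta-}p)$ signed positive for
up-regulation/risky and negative for down-regulation/protective (computed
via the upper-tail quantile to avoid overflow at extreme significance).
Note a calibration subtlety: the *direction-selected* meta-p is the minimum
of two strongly anti-correlated tests and therefore exceeds its nominal
level by about a factor of two under the null (about 10% of null genes fall
below 0.05). Each single direction's Fisher meta-p is calibrated at its
nominal level, and that is the quantity the package's type-I-control checks
assert; consumers comparing direction-selected meta-p values across genes
are ranking, not testing.

**Survival.** Per cancer type, a Cox proportional-hazards model
`Surv(time, event) ~ expression` (via the `survival` package) yields a Wald
$z$; one-sided p-values for the risky ($P(Z>z)$) and protective ($P(Z<z)$)
arms are Fisher-combined separately and the more significant arm reported
with a signed meta-z. Types with fewer than 10 events (configurable) or
non-convergent fits are dropped and recorded.

**Signatures.** Per-sample signature scores are the mean of per-gene
standardized $\log_2$ expression over set members present in the matrix — a
declared stand-in for heavier single-sample enrichment scoring, echoed in
the output metadata, chosen because it is transparent, fast, and monotone
in coordinated shifts of the set. `correlation_rank()` correlates a gene
with each signature score (Pearson on log expression by default) and maps
p-values linearly to $[0,1]$ with 1 the most significant signature.

**Gene sets and enrichment.** `build_brcaness_set()` implements the
two-arm construction: pathway genes annotated by at least two of exactly
three databases, unioned with a curated sensitivity list, provenance
retained per gene. Over-representation uses the one-sided hypergeometric
(Fisher's exact) test with Benjamini-Hochberg correction across the tested
sets (per-analysis scope; the emulated study does not state its correction
scope). Down-regulated fractions default to $|\log_2\mathrm{FC}| \ge
0.585$ (1.5-fold) and BH $q < 0.05$, both configurable, since the emulated
figures print no cutoffs.

## The synthetic-data generators

Every pipeline input can be generated with known ground truth:
median-effect viability plates, constant-ratio combination series with a
prescribed CI profile (component doses solved from
$d_A/D_{x,A} + d_B/D_{x,B} = \mathrm{CI}(f_a)$ under the ratio
constraint), log-normal tumor/normal expression with per-type planted log2
effects, exponential-baseline proportional-hazards survival cohorts,
knockdown screens with exact prescribed fold changes, barcode cohorts with
recorded dedup winners, and annotation tables with recorded expected gene
sets.

Choices and what they imply:

* **Noise model.** Multiplicative Gaussian on viability, truncated to
  $(0, 1.2]$, default SD 5% of signal — a convention for plate-reader
  error, not a measured value; no assay noise magnitudes were available.
  Dose designs place five points on an equally spaced $f_a$ grid from 0.2
  to 0.8, the informative range of a five-point constant-ratio design.
* **Determinism.** Each generator draws from its own RNG stream (seed plus
  a hash of the generator name and identifiers), so adding one generator
  call never shifts another's draws, and the caller's RNG state is
  restored. Identical seed and configuration give bit-identical tables.
* **What passing tests do and do not show.** The generators draw exactly
  from the fitted model family (median-effect curves, log-normal
  expression, exponential hazards), so closed-loop recovery tests verify
  the estimators and the algebra, not robustness to model misspecification.
  Real plates have edge effects, dispensing error and non-monotone
  artifacts; real expression has heavier tails, batch structure and
  correlated genes; none of these are simulated. Headline count checks
  (the 73/223/247 gene-set construction; the 33/21/10 screen rollup) run on
  synthetic reconstructions that plant the documented marginal structure —
  they demonstrate that the pipeline's rules reproduce those counts from
  inputs with that structure, not that we possess the original tables.
* **Problem sizes.** Monte-Carlo checks use 100 seeds for IC50 recovery,
  500 genes across 5 types for null calibration, 50 seeds for survival
  direction calls, and 1000 random tables for the impact-score oracle —
  sizes at which the binomial error of each estimated rate is well inside
  the asserted band.

## Known limitations

* Only the median-effect/Loewe CI framework is implemented: no Bliss, HSA
  or ZIP models, no dose-reduction index, no checkerboard designs.
* The median-effect form fixes response endpoints at 0 and 1 (no variable
  floor/ceiling 4PL fits).
* No portal clients: dependency/dysregulation/alteration features and real
  cohort matrices must arrive as prepared tables.
* Proteomics matrices are treated as pre-normalized inputs to the same
  meta-analysis path; paired-sample protein tests use the same t-test
  machinery with pairing handled upstream.

## A worked example

```{r example}
cfg <- sim_config(seed = 1, noise_model = "none")
pa <- drug_params(m = 1.3, Dm = 2, label = "olaparib")
pb <- drug_params(m = 0.8, Dm = 0.5, label = "epi01")
plateA <- gen_monotherapy_plate(pa, c(0.5, 1, 2, 4, 8), cfg)
plateB <- gen_monotherapy_plate(pb, c(0.125, 0.25, 0.5, 1, 2), cfg)
fitA <- fit_median_effect(plateA)
fitB <- fit_median_effect(plateB)
series <- gen_combination_series(pa, pb, ratio = 4,
                                 ci_profile = function(fa) 0.6, cfg = cfg)
prof <- combination_index(series, fitA, fitB)
prof
classify_ci(summarize_ci(prof))
```
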