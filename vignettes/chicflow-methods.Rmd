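---
title: "Calling chromatin interactions from Capture Hi-C: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling chromatin interactions from Capture Hi-C: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chicflow)
library(dplyr)
```

## The problem

Capture Hi-C (CHi-C) enriches a Hi-C library for ligation products that
involve a designed set of restriction fragments (*baits*), giving
fragment-resolution contact maps around loci of interest — here, a *Region
Capture* design tiling disease-associated LD regions and a *Promoter
Capture* design targeting fragments around transcription start sites within
500 kb of the lead SNPs. The statistical task is to decide, for every
bait–prey fragment pair, whether its di-tag count exceeds what generic
polymer contact and technical bias explain. chicflow implements that
pipeline end to end: HindIII digestion and bait design, di-tag filtering and
ligation classification, a trans-count background model, a negative binomial
(NB) regression background with FDR-controlled calling, reciprocal
co-validation between the two capture designs, and a synthetic generator
with ground truth.

## Coordinate system and filtering

All coordinates are 0-based half-open (BED convention). The HindIII map is
produced by scanning each sequence for `AAGCTT` and cutting after the first
base (`A^AGCTT`); matching is case-insensitive and `N` never matches, so
unresolved sequence is treated as uncuttable. Before analysis, di-tags are
dropped when (i) neither end is baited (off-target), (ii) both ends are the
same fragment (self-ligation), or (iii) the ends are cis with midpoint
separation below 20 kb, where contact frequency is dominated by linear
proximity. Distance is always midpoint-to-midpoint; the convention is
configurable but midpoints are symmetric and standard. Retained di-tags fall
into exactly one of four ligation categories: single-baited cis within 5 Mb,
single-baited cis beyond 5 Mb, double-baited cis, and trans. Only cis pairs
within 5 Mb are ever tested; the 5 Mb boundary case goes to the near class.

## Interactability and the truncated negative binomial

Each baited fragment has a generic propensity to form ligation products —
capture efficiency, mappability, local chromatin state. Trans contacts are
assumed to be random background, so a fragment's total trans di-tag count
measures that propensity (*interactability*). Across fragments the trans
totals are bimodal: a low mode of stochastic noise and a high mode of
genuinely interacting fragments. The signal mode is modelled by maximum
likelihood with a *left-truncated* NB fitted to counts at or above 3,000
(the truncation for interacting fragments; diagnostic truncations of 1,500
and 600 describe the noise mode of promoter and region libraries and are
exposed in the configuration). The likelihood renormalises the NB pmf by its
mass above the truncation, so the fitted mean and size describe the
underlying non-truncated distribution; optimisation is over log-parameters
for positivity, started from moment estimates. The *noise threshold* is the
5% quantile of that non-truncated fit — the smallest count whose CDF reaches
0.05 — and fragments with fewer trans di-tags are discarded as noise, both
as baits and as preys (the symmetric reading of "filtered out").
Interactability is the trans count divided by its mean over retained
fragments; the scale is arbitrary and cancels into the regression intercept.

Replicates are pooled before the trans fit (stability; the assay's two
replicates measure the same propensity).

## The regression background and interaction tests

For testable pairs the expected count is modelled log-linearly,

$$\log E[y] = \beta_0 + \beta_1 \log d + \beta_2 \log \iota_{\mathrm{bait}}
\;[+\; \beta_3 \log \iota_{\mathrm{other}}],$$

with NB errors and maximum-likelihood dispersion (`MASS::glm.nb`). The
other-end term exists only for double-baited pairs — trans totals, hence
interactability, are observable only for baited fragments — so single- and
double-baited pairs get separate models. Replicate counts are summed per
pair before fitting. Each pair's p-value is the upper tail
$P(X \ge y_{\mathrm{obs}})$ under the NB at its fitted expectation (an
observed zero has p-value 1). All p-values of one experiment (cell line ×
capture design) form one Benjamini–Hochberg family; a pair is called at
$q \le 0.05$, inclusive.

The log-linear form is the standard choice consistent with correcting for
distance and interactability; the link and covariates are not uniquely
dictated by the assay, and the model matrix is assembled in one place
(`fit_background_glm()`) should a polynomial-in-log-distance variant be
needed.

## Reciprocal co-validation and the enrichment statistic

A region-capture call whose prey fragment is targeted in the promoter design
could in principle be re-observed from the other side; such calls are
*validatable*, and *matched* when the promoter experiment calls the same
fragment pair with roles swapped. Concordance as thresholds tighten is
summarised by the conditional enrichment
$$X[i,j] = \frac{P(\text{region } q \le i \wedge \text{promoter match } q
\le j \mid \text{region } q \le 0.20)}{P(\text{region } q \le i \mid
\text{region } q \le 0.20)},$$
estimated by empirical proportions over the validatable region calls at the
20% reference FDR. Under independent validation at rate $r$ the grid is flat
near $r$; shared true interactions make $X$ rise as $i$ tightens. Matching
is exact at the fragment level (calls are made at fragment resolution); a
±1-fragment slack exists but is off by default. No smoothing is applied to
the proportions.

## The synthetic generator

`simulate_design()` and `simulate_counts()` generate the study conditions
the package is tested under, with a single seed driving everything:

* **Genome**: 4 chromosomes × 1,250 fragments, fragment lengths from a
  shifted exponential with mean 3.5 kb (the assay's average HindIII fragment
  size), tiled without gaps.
* **Designs**: 2,000 region baits and 1,000 promoter baits, disjoint, so
  loops spiked between them are reciprocally observable.
* **Interactability**: lognormal per fragment (log-scale SD 0.35). A
  fragment's *capture efficiency* scales its cis and trans propensity
  consistently; noise-class fragments (30%) have their efficiency scaled by
  the noise/signal trans ratio, which is exactly why their trans totals sit
  in the low mode. Signal trans totals are conditionally Poisson around
  efficiency × 5,000 (deep-sequencing regime: relative Poisson noise on
  thousands of reads is small), noise totals are overdispersed around
  efficiency × 100 — giving the bimodal marginal the threshold must split.
* **Cis counts**: each bait receives 25 preys at log-uniform distances in
  [20 kb, 5 Mb]; a pair's per-replicate expectation is
  $\mu = s\,\iota_b\,\iota_p^{[\text{baited}]}(d/20\,\text{kb})^{-\alpha}\phi$
  with $s = 1000$, $\alpha = 1$, spiked fold $\phi$ (1 for non-loops), and
  the prey factor applied only when the prey is itself baited — mirroring
  what the downstream model can observe. Counts are NB with size 5,
  independent per replicate; only non-zero counts become di-tags, and the
  deep-capture scale keeps zero dropout negligible. A double-baited pair can
  be drawn from either side but is kept once (it is one physical pair).
* **Loops** are placed between signal-class region and promoter baits: a
  loop at a pure-noise fragment would be unobservable by the assay's own
  filtering, so spiking one would measure the filter, not the caller.

What the generator does **not** emulate: ligation artefacts (dangling ends,
re-ligations — removed upstream by read-level pipelines), duplicate reads,
copy-number and mappability structure along the genome, under-sequenced
libraries with heavy zero-inflation, and spatially correlated biology such
as domains. Passing tests therefore demonstrate the statistical machinery —
calibration, FDR control, power, reciprocal enrichment — under the model's
own assumptions, not robustness to every artefact of real libraries.

## Numerical choices and degenerate inputs

* Truncated-NB optimisation: BFGS on $(\log\mu, \log\,\text{size})$, moment
  starts, non-finite likelihood mapped to a large penalty; non-convergence
  is an error, and fewer than 25 counts above the truncation is an error
  naming the truncation point.
* `noise_threshold()` uses the exact quantile function (`qnbinom`), i.e.
  the smallest integer whose CDF reaches the quantile; tests verify it
  against direct pmf summation.
* Boundary conventions, all inclusive on the retained side: distance 20 kb
  retained, 5 Mb in the near class, trans count equal to the threshold
  retained, $q = 0.05$ called.
* Bait design scans 120-bp windows inward in 1-bp steps and takes the first
  window satisfying GC ∈ [25%, 65%] (inclusive) and fewer than 3 `N`s whose
  proximal edge lies within 400 bp of the fragment end; fragments shorter
  than 120 bp fail, and overlapping left/right picks on fragments under
  240 bp collapse to the left oligo (one-end capture).
* All-zero trans totals (degenerate library) and empty conditioning sets in
  the enrichment grid are errors, not silent zeros.

## Problem sizes used by the checks

The packaged checks run at desk scale, chosen to finish in minutes while
leaving Monte-Carlo noise well below the asserted margins: 20 libraries of
20,000 draws for truncated-NB recovery; 300 null libraries of 2,000 baited
fragments for calibration (pooled KS on 100,000 p-values; the mean
false-discovery proportion over null libraries is compared against 0.075 —
under a global null that mean is essentially the per-library probability of
any call, so several hundred libraries are needed for a stable estimate);
one 120-loop scenario across folds 2–16 for sensitivity and power
monotonicity; and a 150-loop fold-mixture scenario for the enrichment grid.

## Known limitations

* The regression conditions on estimated interactability; measurement error
  in very shallow libraries would attenuate $\beta_2$ and inflate the
  dispersion, a regime the deep-capture defaults deliberately avoid.
* One noise threshold per experiment is derived from the pooled trans fit;
  per-chromosome or per-batch thresholds are not modelled.
* The caller tests observed pairs only. In very sparse libraries the
  missing zero-count pairs would make the background fit slightly
  conservative.
* Matching in co-validation is exact at fragment resolution; designs on
  different fragment maps cannot be compared.
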