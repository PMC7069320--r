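---
title: "Quantifying background matching from calibrated photographs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying background matching from calibrated photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camoquant)
```

camoquant measures how well an animal's coloration matches its visual
background from standardized field photographs, and tests how that matching
varies along an environmental gradient and with population structure. The
motivating system is a polymorphic ground-dwelling lizard on a coastal dune
whose substrate runs continuously from bare pale sand to full vegetation
cover; the same machinery applies to any animal photographed against its
background with an in-frame gray standard.

This vignette explains each model in the pipeline, the tunable parameters and
their defaults, what the synthetic-data generator does and does not emulate,
and the numerical conventions that make results reproducible bit for bit.

## Photograph calibration

Cameras apply a nonlinear tone curve and channel-dependent gains, so raw RGB
values are not comparable across photographs. Calibration proceeds in two
steps on each photo's mean region values:

1. **Linearization.** `linearize()` inverts the tone curve with a fixed
   exponent, $v_{\mathrm{lin}} = v_{\mathrm{raw}}^{\gamma}$, default
   $\gamma = 2.2$ (the sRGB-class approximation). A single gray card cannot
   identify the full camera response, so the exponent is a model choice, not
   an estimate; it is configurable per camera.
2. **Equalization.** `equalize()` scales each channel so the in-frame 18%
   gray standard reads exactly its known reflectance:
   $c_{\mathrm{out}} = t \, c_{\mathrm{in}} / g_c$ with $t = 0.18$. The gray
   card is an exact fixed point of the calibration by construction, and
   per-channel gains cancel exactly.

Region colors are *means first, calibration second*: the 400 sampled raw
values are averaged, and the mean is calibrated. On heterogeneous regions
(e.g. a speckled dorsum) the tone-curve nonlinearity makes the calibrated
mean differ slightly from the mean of calibrated pixels (a Jensen-gap effect
of order 1–3% in brightness for strongly patterned regions). This matches the
field protocol; because the gap is channel-uniform for pattern elements that
are darkened or lightened versions of the base color, chromatic quantities
are unaffected.

## Color space

All color metrics live in a 2-D chromaticity space of standardized channel
differences computed from calibrated RGB:

$$x = \frac{R - G}{R + G + B}, \qquad y = \frac{G - B}{R + G + B},$$

with saturation $S = \sqrt{x^2 + y^2}$, hue $H = \operatorname{atan2}(y, x)$,
and brightness $V = (R + G + B)/3$. Two conventions deserve flagging:

* **Hue is a full-quadrant angle** in $(-\pi, \pi]$. A one-argument
  $\tan^{-1}(y/x)$ is quadrant-ambiguous, and gray-green animal colors do
  reach negative $x$, so the two-argument form is required for consistency.
* **Achromatic colors have no hue.** `hue(0, 0)` is an error, not 0; mapping
  gray to hue 0 would silently bias circular summaries toward "red".

## Contrast indices

Background matching is quantified by two indices between a body region
(subscript $s$) and its background (subscript $b$), both from calibrated RGB:

$$\mathrm{achromatic} = \frac{\sum RGB_s - \sum RGB_b}{\sum RGB_s + \sum RGB_b},
\qquad
\mathrm{chromatic} = \lVert p_s - p_b \rVert_2,$$

where $p$ are the RGB proportions (each channel over the channel sum). The
achromatic index is kept *signed* — the sign says whether the animal is
darker or lighter than its background, which is itself informative along the
gradient — with `abs_achromatic` provided for magnitude analyses. The
chromatic index is brightness-invariant, symmetric, and a true metric on the
simplex with range $[0, \sqrt 2]$. Lower values mean better matching.

## Pattern classification

Dorsal morphs are assigned by a deterministic 2×2 rule on a binary pattern
map (body, speckle, and mid-dorsal-line masks, body axis aligned to raster
columns):

|              | midline ≤ 50% of axis | midline > 50% of axis |
|--------------|----------------------|----------------------|
| speckle < 10% | plain                | midplain             |
| speckle ≥ 10% | spot                 | midspot              |

The midline boundary is strict (`> 0.5`, "more than half the body length");
the speckle boundary is inclusive (`>= dense_threshold`). The 10% dense
threshold operationalizes a by-eye judgment of "distinctive dense speckling";
it is configurable, and every generator default stays at least 10% away from
both boundaries so that classification accuracy statements are about the
rule, not about borderline cases. Segmenting masks out of raw photographs is
out of scope; the package consumes masks.

## Vegetation cover score

The quadrat photograph is partitioned into 2×2 quadrant sections. Each
section scores its vegetation area as a percentage of the *whole* image,
rounded to the nearest multiple of 5 and capped at 25 (a full quadrant is a
quarter of the image); the four scores sum to a total out of 100. The
protocol's "minimum 5%" is read as scoring granularity: any nonzero
vegetation below 2.5% still scores 5. Rounding contributes at most 2.5 points
per section, so totals are within ±10 of the true pixel percentage for masks
whose nonempty sections hold at least the 2.5% floor — and within ±5 on
masks aligned to the 5% grid, which is how the generator lays vegetation
down. A section holding only a trace of vegetation can carry up to 5 points
of excess by design of the floor rule. Ties at the rounding midpoint follow
R's round-half-to-even.

## ROI sampling

Region colors are estimated from `points_per_region = 400` random points
inside each polygon ROI, drawn uniformly **with replacement** over the pixel
centers contained in the polygon by the even-odd rule. Coordinates are
0-based `(col, row)` with pixel centers at integers. These conventions are
arbitrary but fixed, which makes every sampled mean reproducible from
`(inputs, config, seed)` alone; each ROI draws from a sub-seed derived from
the pipeline seed and the image/region labels, so adding or removing one
image never shifts another image's draws. The exhaustive region mean
(`full_region_mean()`) is retained as the oracle the sampler converges to.

## Synthetic scenes and populations

The generator exists so that every stage can be tested against known ground
truth without any field data. It emulates, with explicit switch-offable
parameters:

* a background whose brightness declines steeply with vegetation cover while
  its chromaticity slides from sand toward vegetation;
* a dorsum that tracks background brightness more weakly — so animals are
  darker than bare sand and lighter than dense vegetation;
* a skink-versus-background chromaticity offset whose magnitude is *linear in
  cover* with Gaussian noise — the generating slope (default
  $8\times10^{-4}$ per percent cover from an intercept of 0.05) that
  regression should recover;
* elevated ventral chroma in adults (+35%) and additionally in adult males
  (+15%), capped at a total factor of 1.5 so colors stay inside the camera's
  range;
* seasonal rotation of the dorsal offset direction (hue shifts of +0.18,
  +0.05, −0.12 rad for the nonbreeding, mating, and birthing seasons);
* between-year random intercepts (sd 0.01 on brightness, 0.006 on the offset
  magnitude) so the survey-year grouping the mixed models fit has real
  variance behind it;
* pattern-type frequencies tilted along the cover gradient around
  population-level weights of 6/19/9/66% for plain/midplain/spot/midspot;
* mass–length allometry $m = a\,L^3 e^{\varepsilon}$ for the scaled mass
  index.

The default population size is 352 across survey years 2006–2008 weighted
19/271/62. The camera model is per-channel gain (default 1.2/1.0/0.8), gamma
compression ($1/\gamma$), additive Gaussian sensor noise (sd 0.005, applied
before quantization so it dithers the quantizer), and 8-bit quantization.
Scene `dorsal_rgb` is defined as the *mean* color of the dorsal sampling
region — dark speckles and light midline included — matching what the
photographic protocol measures; the painter rescales the base coat
accordingly.

What the generator does **not** emulate: spatial texture statistics of real
sand and plants, specular highlights and shadows, segmentation error in the
masks, non-power-law camera response, spatially correlated sensor noise, and
any covariance between pattern type and color beyond the cover gradient.
Passing tests therefore validate the *computational chain*, not the field
protocol's ecological assumptions.

## Inferential layer

* **Scaled mass index.** $SMI_i = m_i (L_0/L_i)^{b_{SMA}}$ with
  $b_{SMA} = b_{OLS}/r$ estimated from $\ln m$ on $\ln L$ and $L_0$ the mean
  length by default. Authored here because its SMA slope convention is the
  substance of the index.
* **AICc and model ranking.** $AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with
  Akaike weights $e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$. Candidate sets are
  ranked *exhaustively* over a declared list rather than by greedy stepwise
  search: the result is order-independent and reproducible. `k` counts fixed
  coefficients plus two variance components (random-intercept and residual),
  stated explicitly because AICc comparability depends on it.
* **Mixed models.** Random intercept per survey year only, fitted by
  unrestricted maximum likelihood (lme4) so likelihoods are comparable across
  fixed-effect structures. With a single group the fit degenerates to OLS
  with the same `k` convention. Collinear fixed-effect sets are an error
  naming the terms, never a silent drop.
* **Rank tests.** Signed-rank and rank-sum tests use the exact enumeration
  null for small tie-free samples (at most 25 nonzero differences; combined
  n at most 20) and the tie-corrected normal approximation with continuity
  correction otherwise; the method used is recorded in the result.
  Kruskal–Wallis uses the standard tie-corrected H against chi-square; a
  fully tied sample reports H = 0, p = 1 by convention rather than 0/0.
* **Pairwise contrasts.** Tukey-style single-step adjustment over the
  multivariate-t distribution (multcomp); Holm-adjusted pairwise t-tests are
  the recorded fallback if the single-step computation fails. Groups with
  fewer than two observations are reported as skipped pairs.

## Problem sizes and tolerances used by the test suite

Formula identities are checked at $10^{-12}$ relative tolerance. The
calibration round-trip uses 100 rendered scenes; the sampler-versus-oracle
comparison 1000 seeded draws pooled over channels; pattern recovery 200 maps;
slope recovery 100 populations of n = 352; the type-I-error check 2000 null
populations of n = 40. These sizes keep the full suite and the acceptance
script to a few minutes on one CPU while leaving the binomial sampling error
of each empirical rate well below the margin it is compared against — with
one deliberate exception: the slope-recovery check asks for ≥95% of
replicates inside ±2 standard errors, which is the *nominal* coverage of a
2-SE interval, so that check sits at its theoretical pass rate by
construction and can fall short by sampling noise alone. The measured
coverage diagnosis is part of the test design record.

## Known limitations

* A single gray standard identifies gains but not the response curve; if the
  true camera response is not a power law, linearization bias propagates to
  brightness (not to proportions-based chromatic quantities).
* Mean-then-calibrate on patterned regions slightly underestimates
  brightness relative to per-pixel calibration (1–3% for the default pattern
  contrasts).
* The binomial-family mixed model for a four-level pattern response is not
  identifiable from the protocol description and is deliberately replaced by
  multinomial summaries plus the rank tests the analyses actually report.
* The vegetation-score floor rule makes the ±10 worst-case bound formally
  conditional (see above); field quadrats with nonzero sections below 2.5%
  cover inherit the floor's excess.
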