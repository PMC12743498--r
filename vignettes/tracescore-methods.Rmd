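---
title: "tracescore: models, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tracescore: models, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracescore)
```

This vignette is the package's own account of its science: what each stage
computes, which knobs matter, where the design was genuinely open and what
we chose, and what a green test does — and does not — establish.

## 1. The measurement model

An edge-tracing experiment produces binary **trace maps**: 1-pixel-wide
drawings of the edges an observer perceived in a grayscale scene. The
observer's trace of the noise-free, high-contrast image (RMS contrast
0.16) is their personal **ground truth**; their traces of the same image
at lower contrast under a noise mask are **responses**. Scoring treats
every pixel as a trial:

* a response pixel within a Euclidean disk of radius $r$ (the error
  margin) of any ground-truth pixel is a **hit**; other response pixels
  are **false alarms**;
* a ground-truth pixel with no response pixel within $r$ is a **miss**;
* everything else is a **correct rejection**.

The four categories partition the grid by construction, so
$H + M + FA + CR = N$ always holds — this is enforced in the
`contingency_counts` constructor and tested as an invariant. Pixels are
of course not independent trials (a stroke is drawn as a unit); the
framework is used descriptively, and the psychometric stage accounts for
the dependence through effective counts (Section 3).

**Error margin.** Human tracing is not pixel-accurate, so the margin
absorbs placement error. It defaults to `round(0.025 * size_px)` — 13 px
on a 512 px image — expressed either as a fraction or in pixels. Hits are
monotone non-decreasing and FAs non-increasing in $r$ (tested), so the
margin scales performance curves without reordering them.

**The miss rule (open design point).** Whether a ground-truth pixel is
"explained" should be judged against the dilated response map (a response
stroke nearby explains it) or only against the response pixels themselves.
Counts in published figures cannot disambiguate the two. We default to
the dilated-response rule — it is the symmetric counterpart of the hit
rule and keeps the identity case exact — and expose `miss_rule = "strict"`
as the alternative. Both are validated against a brute-force
pairwise-distance oracle on small maps.

**Rates of 0 or 1.** $d' = z(\text{hit rate}) - z(\text{FA rate})$ and
$c = -\tfrac12[z(\text{hit rate}) + z(\text{FA rate})]$ need finite
quantiles. The default log-linear correction adds 0.5 to each cell of the
affected pair *only when that rate is exactly 0 or 1*, so interior rates
are transformed untouched (this keeps the $d' = 2$ anchor at rates
$(\Phi(1), \Phi(-1))$ exact to machine precision); a hard clamp to
$1/(2N)$ is the alternative.

## 2. Stimuli

Stimuli live in physical units: luminance in cd/m², spatial frequency in
cycles per degree via the display's pixels-per-degree (44 ppd in the
reference apparatus; a 512 px stimulus spans 11.6°). RMS contrast is the
population standard deviation over the mean.

Noise masks are made by spectrally filtering a seeded Gaussian field.
The family names refer to the **power** spectrum — white $f^0$, pink
$f^{-1}$, brown $f^{-2}$ — so the amplitude weights are their square
roots; stating this explicitly avoids the classic factor-of-two error,
and the radially averaged power-spectrum slopes (0 / −1 / −2 ± 0.2) are
acceptance-tested on 1024² grids. Narrowband masks use an isotropic
log-Gaussian amplitude envelope with a default bandwidth of 1 octave
(full width at half height). The exact filter used for the original
stimuli is not public; ours is the common practice for SF-selective
masking noise, is configurable, and is *not* claimed to be identical —
the acceptance test only pins the radial peak to within ¼ octave of the
center frequency.

Scene and mask combine additively in the contrast domain,
$L = \bar L\,(1 + c_\text{scene}\, s + n)$, so the mask's contrast energy
(fixed at RMS 0.1) is independent of the image contrast — this is what
"superimposed noise at fixed RMS" implies. Negative luminances after
compositing are clamped to zero; the clipped fraction is attached to the
result and a warning fires above 1%. At the contrasts in use, clipping is
rare and the mean is preserved to a very good approximation.

A deliberately unresolved inconsistency: the reference apparatus's monitor
geometry (523 mm / 1920 px at 100 cm) does not reproduce its stated
44 ppd exactly. The package trusts the stated ppd and leaves the geometry
alone.

## 3. Psychometric fitting

Maximum performance in this paradigm stays well below 1 even at the
highest contrasts — an observer's noisy trace never perfectly matches
their own ground truth — so proportion correct is first scaled by the
observed maximum `pmax` and the cumulative Gaussian
$$\hat p(x) = \gamma + (1 - \gamma - \lambda)\,\Phi\!\left(\frac{x - \mu}{\sigma}\right)$$
is fitted to the scaled data. Defaults: guess rate $\gamma = 0$
(appropriate for the CR-free proportion correct, which starts near 0),
lapse rate $\lambda$ free in $[0, 0.05]$ with a mild quadratic penalty
toward 0.

The original analysis used an external Bayesian fitting tool; we replace
it with an in-package penalized-MLE fitter because (a) the toolkit must be
self-contained and (b) pixel counts are not Bernoulli trials, so the
"number of trials" entering any likelihood is a modeling choice anyway.
The likelihood is binomial on **effective counts**: the weights are
normalized, so only relative weights matter and the fit is exactly
invariant to uniform weight rescaling (tested). The effective count per
aggregated point is a configuration knob (`effective_n`, default 50).
Optimization is L-BFGS-B restarted from a deterministic grid (quantile
midpoints × three slope scales), making the fit a deterministic function
of the data; degenerate (non-increasing) data yield a flagged fit, never a
crash.

Thresholds are read off at a criterion expressed as a fraction of the
scaled range; 0.5 gives the midpoint $\mu$ (the conventional threshold of
the original tool), and $\Phi(1)$ gives $\mu + \sigma$. Confidence
intervals use a nonparametric bootstrap over observers (default 1000
resamples, seeded), standing in for the original's 68% credible
intervals. The parameter-recovery acceptance test fixes the generating
curve at $\mu = 0.05$, $\sigma = 0.02$, 5 levels, 200 effective trials
per level, and requires median $|\hat\mu - \mu|/\mu < 5\%$ over 200
simulated datasets.

## 4. Patch analysis

Stacking all observers' ground-truth maps gives a consensus heatmap.
Patch categories follow the consensus fractions: **salient** centers were
traced by at least $\lceil 0.95\,n\rceil$ observers (19 of 20 — the
operational rule from the reference figure caption, generalized from "all
observers" in the text), **some** by 25–75% (5–15 of 20), **none** by
nobody; the three sets are disjoint by construction. Patches are 51×51,
fully interior, with centers at least one patch width apart (the source
description says only "avoid selecting neighboring regions"; one patch
width is the weakest rule that prevents overlap).

Features are mean luminance and RMS contrast. Directional spectra use the
mean-subtracted 2D FFT power aggregated in one-pixel-wide frequency
annuli restricted to a 30° wedge around the chosen frequency axis —
"vertical direction" means energy along the vertical *frequency* axis,
i.e. produced by horizontally oriented structure. A Hann window limits
leakage by default; with the window off, total power equals the patch
variance exactly (Parseval, tested at 1e−8). Wedge width, window, and
normalization are configurable because the original figure does not state
them.

## 5. The synthetic world

The synthetic module exists so every stage can be verified end to end
with a known answer. Its defaults are a *stated world*, fixed a priori:

* **Scenes**: a horizon step plus ~6 rotated ellipses on a mid-gray
  ground, amplitudes 0.25–0.6 in contrast units, mean luminance exactly
  100 cd/m² (the contrast field is mean-centered, which also makes scene
  RMS contrast exactly linear in the amplitude scale). The exact 1-px
  boundary map is returned with the scene.
* **Observer**: each boundary segment is traced with probability
  $\Phi((c_\text{eff} - \mu_o)/\sigma_o)$, where
  $c_\text{eff} = c_\text{image}\,|a| / (1 + m)$ — a cumulative-Gaussian
  visibility link, chosen deliberately to match the analysis model so
  recovery is well-posed. Defaults $\mu_o = 0.02$, $\sigma_o = 0.01$ put
  ground-truth-session visibility near ceiling, mirroring the ~2/3
  within-observer consistency regime rather than perfect tracing.
  Jitter is a smooth random displacement field with sd 1.5 px (drawing
  inaccuracy of a pen, well inside the 13 px margin). False traces are
  bounded-turning random-walk strokes totaling ~100 px per image —
  spatially extended curves, like real mistaken-noise traces, not
  salt-and-pepper.
* **Masking** is one multiplicative attenuation $m$ per noise family
  (defaults 1 < 2 < 3). The simulator validates the *measurement
  pipeline*, not the visual system: no channel model is implied.
* **Design**: per observer every image identity appears exactly once and
  conditions are drawn uniformly from the 5-contrast × family grid; the
  per-family contrast levels emulate the piloting step by bracketing each
  family's predicted midpoint from 0.4× to 2.4×.

`end_to_end_recovery()` runs the full loop (default 20 observers × 30
images) and checks that fitted thresholds reproduce the injected masking
ordering. It runs at 128 px / 11 ppd rather than 512 px / 44 ppd: the
margin still resolves to 2.5% of the side, the field of view stays
~11.6°, and the whole experiment fits in about a minute — full-size runs
only change the constant in front.

**What a green test does not establish.** The generator produces
unambiguous, closed object boundaries with piecewise-constant interiors.
Natural images have textures, shadows (which real observers
systematically decline to trace), edges of graded sharpness, and
1/f-correlated backgrounds; none of these are emulated, so passing tests
validate the *pipeline's arithmetic and recovery properties*, not any
claim about natural-scene statistics. The published headline values of
the paradigm (between/within-observer consistency 0.63/0.66, the 74%
ceiling, the bias–performance correlation, the threshold-pattern
correlations against Cornsweet-edge data) depend on the real raw data
and are deliberately not reproduction targets of this package.

## 6. File formats and determinism

Images travel as 16-bit grayscale PNG plus a JSON sidecar
(`mean_luminance`, `ppd`, `cdm2_per_level`); 8-bit files are accepted on
read with a warning, color files are rejected. Because the available PNG
binding writes only 8-bit files, the package assembles the 16-bit
container itself (zlib stream from base R's `memCompress`, CRC32 from
`digest`) and verifies it by bit-exact round trips. Trace maps are 8-bit
PNGs thresholded at nonzero. All tabular outputs are CSV with fixed
float formatting and ordering, so identical inputs re-produce
byte-identical files; every output row carries the config hash and the
package version. Every source of randomness — noise fields, scenes,
observers, designs, bootstraps — is seeded, and identical seeds give
bit-identical results.

## 7. Known limitations

* The narrowband filter and the per-condition contrast levels of the
  original experiment are not public; ours are sensible, configurable
  stand-ins, and threshold values obtained with them are not comparable
  in absolute terms to the original study's.
* The pixelwise SDT treatment ignores stroke-level dependence; d′ and c
  should be read as descriptive indices, and the effective-count knob is
  an acknowledgment, not a solution.
* Jittered simulated observers cannot produce pixel-exact 19-of-20
  consensus, so "salient" patch sampling on jittered synthetic data
  requires either zero jitter or a margin-aware consensus definition; the
  package implements the plain per-pixel stack used in the field.
* `simulate_observer` draws whole shape boundaries; partial tracing of a
  single contour (common in humans) is only approximated through the
  per-shape detail level.
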