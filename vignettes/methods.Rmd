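---
title: "Average image contrast from the zero-lag autocorrelation: model, estimator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Average image contrast from the zero-lag autocorrelation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imagecontrast)
```

## The model

A digitized painting is reduced to a luminance field
$L_{ij} = (0.299\,R + 0.587\,G + 0.114\,B)/255 \in [0,1]$ and treated as a
realization of a wide-sense-stationary (WSS) 2D random process, fully
characterized by its mean and its autocorrelation function (ACF). The
statistic of interest is the ACF of the *mean-centered* field at lag
$(0,0)$ — the mean normalized power, i.e. the plug-in variance — and its
square root, the RMS contrast:

$$\hat C_{\mathrm{var}} = \frac{1}{N}\sum_{i,j}(L_{ij}-\bar L)^2,
  \qquad \hat C_{\mathrm{rms}} = \sqrt{\hat C_{\mathrm{var}}}.$$

Estimation goes through the power spectrum (Wiener–Khinchin): the circular
autocovariance is the inverse 2D FFT of $|\mathrm{FFT}(L - \bar L)|^2$,
divided by the pixel count. At the origin this equals the direct sum
exactly (Parseval), which the test suite asserts to $10^{-12}$; away from
the origin a brute-force double-summation estimator
(`autocorrelation_direct`) provides an independent oracle to $10^{-10}$.

Two readings of "the value at the origin produced the contrast" are
possible — with or without mean removal, with or without a square root. We
resolve this transparently rather than by fiat:

* **Mean-centering is not optional.** Without it the lag-0 value is
  $\bar L^2 + \hat C_{\mathrm{var}}$, dominated by the DC term, and cannot
  represent contrast. The WSS framing itself separates the mean from the
  ACF.
* **Both scales are always computed.** For $L \in [0,1]$,
  $\hat C_{\mathrm{rms}} \le 0.5$ (equality only for balanced binary
  fields) while $\hat C_{\mathrm{var}} \le 0.25$. The empirical ceiling of
  $\sim 0.5$ observed in the motivating timeline matches the RMS scale, so
  RMS is the headline default; the variance scale is reported alongside.
  The two orderings are identical, so the rank-based group test is
  unaffected by the choice.

## Estimator details and numerical choices

* **Normalization.** Circular (FFT-native) mode divides every lag by $N$
  (biased estimate): this is what makes lag 0 equal the plug-in variance
  exactly. A `linear_unbiased` mode (zero-padding to $\ge (2H-1)(2W-1)$,
  each lag divided by its overlap count) is available because the *shape*
  of the ACF — used by `radial_acf_profile` — differs between the two; the
  lag-0 statistic does not.
* **Luminance normalization.** Dividing by 255 makes contrast comparable
  across bit depths and gives the analytic 0.5 RMS ceiling. 16-bit PNG
  sources are first mapped to 0–255 by integer division (÷257).
* **No gamma linearization by default.** The luma weights are
  conventionally applied to gamma-encoded values; a `linearize_srgb` flag
  exists for sensitivity analyses only.
* **Cropping and downsampling are off by default** (`crop_fraction = 0`,
  `max_dim = Inf`): the original analysis mentions neither. Both knobs are
  stamped into `config_digest`, which every output row carries, so results
  computed under different settings can never be silently mixed. For
  band-limited images, lag-0 contrast is insensitive to modest
  box-downsampling (asserted at 5e-3 in the suite).
* **Degenerate inputs.** A single-pixel image has no defined contrast and
  errors; an all-constant image returns exactly 0; tiny negative FFT
  round-off at lag 0 is clamped to 0 before the square root.

## The two-condition comparison

Cohorts are ordered by a 1-based chronological `order_index` and carry one
of two exposure conditions (`low` / `high`; in the motivating study, 19 low
vs 9 high with the high condition at chronological positions
9–12, 21–23, 27–28). The comparison is a Mann–Whitney U test implemented
in-package:

* $U_a = R_a - n_a(n_a+1)/2$ from mid-ranks; reported $U$ is
  $\min(U_a, U_b)$ for the two-sided test.
* **Exact p-values** whenever the pooled data are tie-free and
  $n_a + n_b \le 28$: the null distribution of $U$ is built by the standard
  count recursion $N(u;n,m) = N(u-m;n-1,m) + N(u;n,m-1)$ (the Gaussian
  binomial coefficients), not by naive enumeration, and cached per size
  pair. The threshold 28 is chosen so the motivating 19-vs-9 design is
  handled exactly. Two-sided exact $p = \min(1,\, 2P(U \le \min(U_a,U_b)))$.
* **Otherwise** a normal approximation with tie correction and continuity
  correction; fully tied data degenerate to $p = 1$.
* **Sidedness** defaults to two-sided (conservative); the directional
  alternative (`high` stochastically greater) is exposed as
  `one_sided_greater` because the scientific hypothesis is directional.
* No multiple-testing machinery: the design is a single test.

The suite verifies the exact path against two independent oracles
(brute-force enumeration of all rank splits for totals ≤ 12 — exact
equality — and `pwilcox`), checks label-swap symmetry, rank invariance
under strictly increasing transforms (hence metric invariance), and
sub-uniformity of null p-values.

## What the synthetic generator emulates — and what it does not

`synthetic_image_spec` produces fields of *analytically known* contrast:
uniform (0), balanced checkerboard ($((l_2-l_1)/2)^2$), sinusoidal grating
($A^2/2$), random two-tone fields ($p(1-p)(l_2-l_1)^2$), and stationary
Gaussian random fields (spectral synthesis with a Gaussian kernel of
correlation length $\ell$, realized plug-in SD pinned to $\sigma$, mean
0.5, clipped to $[0,1]$). The $\sigma \le 0.15$ bound keeps the expected
clipped fraction below $10^{-3}$ (3.3 SDs from either bound) — enforced
rather than corrected, favoring transparency over exactness at extreme
$\sigma$. All generation is deterministic per seed, and images are
quantized to 8 bits before saving, matching real plate depth; truth tables
record pre-quantization targets with a stated 1e-3 calibration tolerance.

`synthetic_cohort_spec` emulates the 28-image two-condition design:
per-image target RMS contrasts drawn per condition
(Normal(mean, `within_sd`), truncated to the realizing kind's attainable
range). Defaults state the world of the motivating study: 19 low / 9 high,
24×25-pixel images, `within_sd = 0.05`, and condition means of 0.10 with a
0.30 high-condition mean for effect cohorts — values on the scale of the
observed timeline (near 0 to ~0.5 RMS). Cohort images are realized as
**oblique gratings** (random seeded phase, orientation, and integer
frequencies) because (a) the realized RMS equals the drawn target up to
8-bit quantization, supporting targets up to $0.5/\sqrt2 \approx 0.354$ —
the Gaussian-field kind caps at 0.15 — and (b) quantized contrast estimates
are effectively tie-free, so the exact test path is exercised. The default
24×25 (coprime) dimensions matter: with $H = W$ an integer-frequency
grating only samples $W$ distinct phases and 8-bit round-off can push the
RMS calibration error past 1e-3; coprime dimensions spread round-off over
all $HW$ phase samples (measured worst case ≈ 8.5e-4 over 3000 draws).

What a green test does **not** establish: synthetic cohorts contain no
brushwork, no pigment aging, no JPEG artifacts, no frame/mat borders, and
no spatial nonstationarity — so passing the suite validates the estimator
and the test, not the art-historical claim. Reproducing the published
museum-plate p-value is explicitly out of scope (plates are not
redistributable; an optional script documents the manual route and reports,
without asserting, its p-value).

## Simulation-based acceptance checks

Type-I error (null cohorts, 19 vs 9, 2000 replicates) and power
(effect cohorts, 500 replicates, compared against the same rank test run
directly on the drawn truth targets) run the pipeline end to end *in
memory*: generate → quantize to 8 bits → luminance → FFT contrast → exact
test. The PNG disk round-trip is verified bit-lossless once in the unit
suite, so skipping it in the replicate loop changes nothing but run time.
At this design the discrete exact test's largest attainable two-sided level
at $\alpha = 0.05$ is 0.0477 (computed from the null distribution of $U$),
comfortably inside the acceptance band [0.041, 0.060].

## Known limitations

* TIFF input is not supported (no decoder in the dependency set); PNG,
  JPEG, and ASCII PGM/PPM are.
* The contrast statistic is second-order only: it ignores the ACF's shape
  away from the origin except through the optional radial profile, and says
  nothing about higher-order structure (fractal dimension, turbulence-like
  scaling), which is deliberately out of scope.
* Pigment fading over a century alters measured contrast in ways the
  pipeline cannot correct; results on aged plates are associations between
  *current* digital reproductions and the historical timeline.
* JPEG sources are analyzed as-is; lossy block artifacts slightly inflate
  high-frequency power.
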