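---
title: "Models and methods behind pawsway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pawsway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pawsway)
```

`pawsway` analyses centre-of-pressure (CoP) sway of a quadruped standing
still on two synchronized instruments: a force platform sampling six
force/moment channels at 100 Hz, and a pressure mat sampling a sensel grid
at 60 Hz. This vignette is the package's own account of the models it
implements, the parameters that matter, and the choices made where the
design was genuinely open.

## The sway model

Quiet-stance CoP dynamics are simulated as an independent stationary AR(1)
process per body axis — the exact discretisation of an Ornstein–Uhlenbeck
process. With sampling rate $f$ and correlation time $\tau$ the lag-1
coefficient is $\rho = e^{-1/(f\tau)}$, innovations have sd
$\sigma\sqrt{1-\rho^2}$, and the first sample is a stationary draw, so the
marginal sd is exactly $\sigma$ throughout the trial. A trial holds
$n = \mathrm{round}(Tf)$ samples at times $0, 1/f, \dots, (n-1)/f$.

This is deliberately the simplest stationary process with tunable
amplitude and path length; it makes no claim about neuromuscular control.
The defaults — $\tau = 0.02$ s, $\sigma_{AP} = 0.38$ cm,
$\sigma_{ML} = 0.54$ cm, 10 s at 100 Hz — were calibrated once so that the
plate-side expected maximum AP and ML ranges sit at the normative
magnitudes for healthy small dogs (about 2.45 and 3.45 cm; see
`normative_reference()`). A short correlation time is what the normative
numbers themselves imply: with ranges near $6\sigma$ and a sway path of
several hundred cm per 10 s, the measured signal is close to white at
100 Hz.

Two deterministic approximations support the cohort generator's target
inversion:

* the expected-range ratio $\kappa(\rho) = E[\mathrm{range}]/\sigma$ for a
  10 s, 100 Hz trial, fitted once against direct simulation as a cubic in
  $\rho$ (coefficients `6.5606, -1.4498, 4.8076, -4.4973`; max error
  ≈ 1.5% over $\rho \in [0.05, 0.95]$);
* the expected sway path $(n-1)\,E\|\Delta\|$, where the planar AR(1)
  increment has per-axis sd $s = \sqrt{2\sigma^2(1-\rho) + 2\nu^2}$
  ($\nu$ = plate CoP noise sd) and
  $E\|\Delta\| = \sqrt{2/\pi}\, s_{\max} E(m)$ with $E$ the complete
  elliptic integral of the second kind, $m = 1 - (s_{\min}/s_{\max})^2$.

## Device models

**Force platform.** The stream carries `time, fx, fy, fz, mx, my, mz`
(N, N·cm) with the surface convention $x = -M_y/F_z$, $y = M_x/F_z$;
$x$ points cranially, $y$ to the animal's left, origin at the plate
centre. Any consistent convention gives identical measures (ranges, path
and area are translation-invariant and the axes are fixed by
construction), so the convention is simply stated in every file header.
Measurement error is parameterised as CoP-equivalent white noise
(default sd 0.05 cm, i.e. sub-half-millimetre CoP accuracy) added before
the moments are formed; the channel noise on `fx, fy, fz, mz` is tied to
the same scale (4 N per cm of CoP noise) purely so that a zero-noise
specification renders an exactly invertible stream. Vertical force is
body weight times $g = 9.81$ m/s².

**Pressure mat.** A 44 × 52 sensel grid at pitch $1/\sqrt{1.4} \approx
0.845$ cm (1.4 sensel/cm²). Each paw is an isotropic Gaussian pressure
blob (sd 0.8 cm — a paw pad a few sensels wide) centred on its paw,
normalised on the grid so the sensel loads sum exactly to the body weight
in every frame. Per-frame paw load fractions come from `solve_paw_shares()`:
the three equality constraints (sum to one, centroid at the CoP) leave one
degree of freedom, and the returned solution is the exact closed-form
projection of the nominal front-heavy split (0.3/0.3/0.2/0.2) onto the
feasible segment of the simplex. Pressures are quantized linearly over
$[0, 86.2]$ N/cm² into 256 counts; the implied N-per-count factor is the
calibration scale. Static calibration against a known mass follows
`scale = m g / \overline{\text{total raw load}}`.

Because the blob is Gaussian and well inside the grid, the rasterised
centroid coincides with the paw centre to ~1e-8 cm (the discrepancy decays
like $e^{-2\pi^2 s^2/p^2}$ for blob sd $s$ and pitch $p$), so the
quantization-free mat pipeline reproduces the ground-truth CoP essentially
exactly, and quantized recovery stays well inside one sensel pitch.

## Quality control

The generator can inject the two behaviours that force a trial to be
discarded in practice: a limb unload (one paw's share ramps to zero over
0.5 s) and a whole-body shift (a ramped CoP drift). `qc_trial()`
mechanises the visual discard rules: reject when a paw region's share of
the mat load stays below 0.05 for more than 0.2 s, when the plate CoP
strays more than 5 cm from the trial median, or when the recording is
shorter than 9 s. Paw regions are found by 4-connectivity labelling of the
time-averaged sensel image (four largest components). The unload rule is
evaluated before the excursion rule: a full unload also drags the CoP
toward the remaining paws, and the more specific reason should win.
Thresholds are deliberately permissive relative to normal sway (ranges of
2–4 cm, shares fluctuating around 0.1–0.3), which is why clean synthetic
trials are never rejected at the defaults.

## The cohort generator

`simulate_cohort()` samples demographics from truncated normals matching a
small-breed clinical population (age 4.3 ± 3.2 y on [0.6, 13], weight
5.4 ± 1.4 kg on [3.2, 9], height 19.2 ± 1.9 cm, length-to-height ratio
1.40 ± 0.11, BCS 3.4 ± 0.9 on a 1–5 scale; 30/42 female,
16/16/10 smooth/long/wire-haired).

Effects enter through per-dog measure targets:

* **age** acts on amplitude, decreasing logarithmically:
  `ap_target = 3.00 − 0.38 log(age)`,
  `ml_target = 4.08 − 0.43 log(age)`. The ellipse-area target is implied
  ($\pi\,\chi^2_{0.95,2}\,\sigma_{AP}\sigma_{ML}$) and therefore also
  decreases with age, while the sway path is left untouched by age;
* **weight** acts on the plate sway-path target through a quadratic,
  `1100 − 110 w + 5.5 w²` (decreasing over the cohort range), with a
  power-law reference `312 w^{-0.3}` recorded for the mat.

Between-dog Gaussian noise (defaults ap 0.60, ml 0.70, path 17) sets how
much of the variance the maps explain; with these defaults the age maps
account for up to roughly a third of the amplitude variance and the weight
map for roughly half to three quarters of the plate path variance, with
substantial cohort-to-cohort fluctuation at n = 42. Targets are inverted into
$(\sigma_{AP}, \sigma_{ML}, \rho)$ per dog with the two approximations
above ($\rho$ solved by `uniroot`, $\kappa$ iterated to a fixed point).
When a drawn path target is unreachable at the drawn amplitudes — an old,
light dog — $\rho$ is clamped to $[0.05, 0.95]$ and the realised
expectation recorded in the ground-truth manifest. A sizeable minority of
dogs (typically 15–30% under the defaults) sit on this boundary, which
flattens the realised weight effect at the light end and is the main
reason the realised weight–path $R^2$ falls short of the map's nominal
share of variance.

One trajectory cannot satisfy a plate path target and an independent mat
path target simultaneously (the mat sees the same dynamics at 60 Hz), so
the plate target is binding and the mat map is reference metadata. The
within-dog trial-to-trial variance is not a separate dial: it is whatever
ordinary sampling variability of a 10 s AR(1) trial produces. Real
quiet-stance data have slow drifts, intermittent control and
weight-shifting that this generator does not emulate; passing tests
demonstrate the correctness of the measures, statistics and plumbing, not
biological realism.

## Agreement and reliability statistics

Bland–Altman bias is `mean(A − B)` on per-dog means (one point per dog;
per-trial pairing is available behind a flag), with limits of agreement at
±1.96 sd (multiplier stated, configurable) and a proportional-bias trend
from the OLS slope of differences on pair means, computed directly from
the normal equations so exact fits stay warning-free. Pearson correlations
use the t transform on $n-2$ degrees of freedom, two-sided (sidedness is a
declared convention).

`icc_a_k()` implements the two-way mixed-effects, absolute-agreement,
average-of-k intraclass correlation from the mean squares of the complete
$n \times k$ table:
$$\mathrm{ICC}(A,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n}.$$
The 95% interval is the F-based absolute-agreement interval for the
single-rating form with Satterthwaite degrees of freedom, mapped to the
averaged form by the Spearman–Brown relation; the implementation is
cross-checked in the test suite against an independent reference
implementation on a frozen fixture. Conventions worth stating: boundary
values fall in the upper reliability band (0.75 is "good"); negative
estimates are reported as computed, with a warning, because flooring them
hides near-null data; a zero within-subject-variance table returns a
degenerate interval at the estimate. Because the raters (trials) are fixed
effects in the mixed model, simulation oracles in the tests condition on
the realised trial effects rather than on their nominal variance. Dogs
missing trials on a device are excluded from that device's reliability
matrix — the absolute-agreement decomposition needs complete rows, and
imputation is out of scope.

## Regression and ANOVA conventions

The five demographic families (linear, logarithmic, quadratic,
exponential, power) are all scored by original-scale least squares:
$R^2 = 1 - RSS/TSS$ on untransformed residuals, so values are comparable
across families (a log-scale $R^2$ for the power family would not be).
The exponential and power families are refined with `minpack.lm::nlsLM`
from log-scale closed-form starts. The overall p-value is the F test
against the intercept-only model on $(p-1, n-p)$ degrees of freedom.
`select_family()` keeps every candidate fit and picks the highest $R^2$,
breaking ties within 1e-9 toward fewer coefficients, so exactly linear
data select "linear" rather than the equally perfect quadratic. $R^2$ is
floored at zero for non-linear fits that underperform the mean. One-way
ANOVA uses the classical equal-variance between/within decomposition; no
multiple-testing correction is applied, and reports say so. Factorial
covariate-adjusted ANOVA is deliberately out of scope.

## Numerical and interface choices

* The ellipse uses the large-sample $\chi^2$ constant 5.991 rather than an
  F-based small-sample correction; trials contain ≥ 600 samples, where the
  two differ by well under 1%. Sample covariance uses $n-1$. Degenerate
  (collinear/coincident) point sets give area 0 with a warning.
* Resampling is linear interpolation on the trajectory polyline at
  `t0 + k/rate`; interpolated vertices lie on the polyline, so the sway
  path can only shrink and ranges can only contract — both asserted as
  properties. The default analysis keeps each device at its native rate;
  resampling the mat to 100 Hz sits behind a flag because it degrades
  cross-device correlations of rate-dependent measures.
* Division guards: plate samples need `Fz > 1` N; mat frames need a total
  load above 0.1 × the trial median. Excluded samples are counted on the
  returned trajectory.
* Everything is cm and cm²; seconds from trial start; mat frames at
  nominal $k/60$ s. All file formats are documented ASCII with `# key:
  value` provenance headers (the mat dialect is a simplified stand-in for
  proprietary binary exports, preserving their timestamped frame-block
  structure).
* Determinism: every stochastic entry point takes a seed; identical seeds
  give identical trials, cohorts and on-disk sessions.

## Problem sizes used in the checks

The shipped verification suite exercises: metric-oracle equivalence on
1 000 random ≤ 20-point paths (agreement asserted at 1e-12 on the
well-conditioned covariance scale, since the determinant cancels
catastrophically for near-collinear sets); the Gaussian ellipse limit at
$n = 10^5$; device round trips over full 10 s trials; ICC null/closed-form
checks at 200–500 subjects and CI coverage over 500 replicates of the
42 × 5 design; regression recovery at $n = 200$ with a bootstrap-SE
oracle; ANOVA type-I calibration over 1 000 replicates; QC on a labelled
50/50 clean-vs-unload set; and end-to-end disk sessions of 2–4 dogs.
`scripts/acceptance.R` re-runs the headline pipeline on a full 42-dog
cohort.

## Known limitations

The generator's AR(1) sway has no slow postural drift, no
intermittency, and no coupling between axes; the mat model has no sensel
noise, hysteresis or edge effects beyond quantization; plate sway-path
magnitudes depend on the chosen CoP noise floor and correlation time, and
the generator matches normative range/area magnitudes rather than every
published path value. Reliability of the synthetic cohort is higher than
typical live-animal ICCs because the generator has no day effects or
behavioural variability beyond the injected artifacts.
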