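---
title: "Force spectroscopy of protein-drug interfaces with afmforce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force spectroscopy of protein-drug interfaces with afmforce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmforce)
```

## Scope

`afmforce` analyses AFM force-spectroscopy measurements of soft (protein)
layers, of the kind used to probe how a treatment — here, an applied DC
electric field in the presence of small-molecule drugs — modulates
protein–protein and protein–drug interactions. The pipeline covers five
measurement channels: adhesion from force–distance curves, their
decomposition into specific and non-specific force components, friction
from lateral-signal loops (free and constant-load), and surface topography
metrics from height maps. A synthetic-data generator with known ground
truth backs every stage, so the entire pipeline is testable without
instrument data.

## Force-distance curves and adhesion

An AFM force measurement records the photodetector deflection signal
against the piezo position during approach to and retraction from the
surface. With deflection sensitivity $s$ (nm per signal unit) and normal
spring constant $k$ (N/m), Hooke's law converts signal to force,
$F = k\,(s \cdot \text{signal})$, reported in pN (`signal_to_force()`).
The default $k$ of 0.2 N/m corresponds to a typical soft contact-mode
cantilever.

The *adhesion force* is the maximum attractive force needed to separate
tip and sample: the magnitude of the most negative force on the retraction
segment after baseline correction. `correct_baseline()` fits a straight
line to the farthest 30% of the retract positions (where the tip is out of
contact) and subtracts it from both segments, removing offset and linear
drift. Two numerical choices matter in `extract_adhesion()`:

* **Noise estimate.** The robust noise SD is the MAD of the corrected
  forces over the farthest 50% of the retract. The noise window is wider
  than the baseline-fit window because the threshold quality is limited by
  the variance of the MAD itself, and the MAD tolerates partial overlap
  with real curve structure. With a ~400-point curve, a 5×MAD threshold
  on a 50% window holds the false-positive event rate near 0.2%
  (measured over 1000 pure-noise curves in the test suite); the narrower
  30% window roughly sextuples it.
* **Event threshold.** An unbinding event is declared when the attractive
  magnitude reaches `threshold_mads` (default 5) times the robust noise
  SD, with a 1 pN absolute floor so that an exactly flat noiseless retract
  never reports an event. The boundary is closed: a magnitude exactly at
  threshold counts. A curve with no event reports the adhesion as `NA`,
  never as a zero measurement.

Attractive forces are negative internally; reported adhesion is the
positive magnitude, matching the convention in which adhesion peaks are
quoted as positive pN values.

## Poisson step analysis

If each tip–sample contact ruptures a discrete number $n$ of identical
bonds, each contributing a fixed *specific force* $F_i$, and $n$ is
Poisson distributed with mean $\lambda$, then on top of a *non-specific
offset* $F_0$ an ensemble of adhesion forces has

$$\mu = F_0 + \lambda F_i, \qquad \sigma^2 = \lambda F_i^2,$$

so that across ensembles differing only in $\lambda$,

$$\sigma^2_m = \mu_m F_i - F_i F_0 .$$

The variance of grouped adhesion measurements is therefore linear in the
group mean; `fit_poisson_decomposition()` fits this line by ordinary least
squares and reports $F_i$ (slope), $F_0$ ($-$intercept/slope), their
standard errors (the $F_0$ SE by first-order delta-method propagation from
the slope–intercept covariance), and $R^2$. A weighted variant (weights =
group sizes) is available behind a flag; the default is unweighted,
matching the plain straight-line fit conventionally shown for such data.
A negative fitted slope violates the model's sign structure and is
returned flagged invalid, never silently corrected.

Three statistical properties of this estimator are worth knowing:

* **Measurement-noise bias.** Additive Gaussian measurement noise of SD
  $s$ inflates every group variance by $s^2$, shifting the intercept to
  $-F_i F_0 + s^2$ and biasing the recovered $F_0$ low by $s^2/F_i$
  (about 3 pN at $F_i \approx 33$ pN and $s = 10$ pN). The noise variance
  is deliberately *not* subtracted — the conventional analysis fits raw
  variances — so this is a documented bias source rather than a hidden
  correction.
* **Attenuation.** Group means are themselves estimated with sampling
  error, which attenuates the slope exactly as in errors-in-variables
  regression; the attenuation shrinks as curves-per-group grow. The test
  suite checks this consistency on a ramp of increasing ensemble sizes.
* **Few-group inference.** With $k$ groups the $\pm 2\,\mathrm{SE}$ band
  on the slope has roughly $t_{k-2}$ coverage, i.e. clearly below 95%
  for 6 groups. The parameter-recovery test therefore simulates 18 groups
  (three replicates of bond-count means 1–6) of 300 curves each at 5 pN
  noise, a design whose measured operating characteristics (~92% 2-SE
  coverage, median $R^2 \approx 0.97$) match what the check asserts.

`group_curves()` builds the $(\mu_m, \sigma^2_m)$ pairs by partitioning
curves into disjoint groups (default 30 per group, so 300 curves per
condition yield 10 groups). Grouping schemes: `sequential` (acquisition
order), `random` (seeded permutation), and `spatial`, which orders curves
by a caller-supplied index such as a scan-position rank — the measurement
files carry no tip coordinates, so spatial structure must be supplied by
the caller. Leftover curves that do not fill a group are dropped and
reported.

## Ensemble statistics

Force ensembles are summarized the standard way: a histogram with a
Gaussian peak fit, and box statistics.

* `fit_gaussian_peak()` fits $A \exp(-(x-\mu)^2 / 2\sigma^2)$ to the bin
  counts by Levenberg–Marquardt nonlinear least squares. Default bin
  width is Freedman–Diaconis; breaks are anchored at the data minimum so
  the fit is exactly translation-equivariant. Initialisation: $\mu_0$ at
  the modal bin centre, $\sigma_0$ at the sample SD, $A_0$ at the maximum
  count, with $\sigma$ bounded away from zero. Degenerate inputs (all
  values equal, fewer than three occupied bins, a fitted centre escaping
  the data range) yield an honest `converged = FALSE`, not an error.
  Both the fit SE of the centre and the fitted width are reported, since
  peak uncertainties are quoted inconsistently across instruments and
  labs.
* `box_stats()` uses linear-interpolation quartiles (R type 7) and Tukey
  1.5×IQR whiskers with an outlier count.
* `percent_reduction()` is $100 (i - f)/i$ rounded half-away-from-zero to
  an integer — the rounding under which published force pairs such as
  372→228 pN and 202→126 pN reproduce their printed ~39% and 38%
  reductions exactly.
* `welch_t_test()` is the unequal-variance two-sided t-test with
  Welch–Satterthwaite degrees of freedom. Star annotations follow the
  methods-section thresholds 0.05/0.01/0.001/0.0001 by default; a
  `captions` table (with the ** threshold at 0.005, as some figure
  captions print) is selectable, since the two conventions coexist in the
  literature. Two zero-variance groups with equal means give $p = 1$ by
  convention, flagged as degenerate.

## Friction loops

A friction loop pairs the lateral signal of the forward (trace) and
backward (retrace) scan over the same line. The friction signal is half
the trace–retrace difference,

$$V_f = \tfrac{1}{2}(V_\text{trace} - V_\text{retrace}),$$

averaged over the central 80% of the line (turnaround artifacts live at
the ends) with the absolute value taken, so the result is independent of
scan orientation and of any common offset. The lateral force calibration

$$F_f = \tfrac{3}{2}\, K_f\, \frac{h}{l}\, \frac{V_f}{S}$$

uses the lateral spring coefficient $K_f$, tip height $h$, cantilever
length $l$, and lateral detector sensitivity $S$. $S$ is treated as
signal-units-per-nm so that $V_f/S$ is a length and $F_f$ a force (pN);
this unit convention is exposed in the calibration object rather than
hidden. With the defaults ($K_f = 80$ N/m, $h = 17$ µm, $l = 450$ µm,
$S = 0.02$ per nm), $V_f = 0.001$ gives $F_f \approx 226.7$ pN.
`friction_ensemble()` applies this per loop; in constant-load mode every
loop must carry the same load tag (the constant-load protocol fixes the
normal load, typically 1 nN), and mixed or missing tags are an error.

## Topography

Height maps are leveled by least-squares plane subtraction
(`level_plane()`, order 1) before roughness analysis; average height is
reported relative to a caller-chosen reference (for synthetic maps, the
generator's substrate baseline). `surface_stats()` reports the mean
height, the average roughness $S_a = \overline{|z - \bar z|}$ and the RMS
roughness $S_q = \sqrt{\overline{(z-\bar z)^2}}$ over the full scanned
area, with $S_q \ge S_a$ guaranteed by Cauchy–Schwarz.

## The synthetic-data generator

The generator reproduces the statistical structure the analysis assumes —
no more:

* **Rupture forces** are $F_0 + n F_i + \varepsilon$ with
  $n \sim \text{Poisson}(\lambda)$ and Gaussian noise $\varepsilon$.
  Negative draws (possible at high noise) are clipped to zero and
  flagged, since physical rupture forces are non-negative and the flag
  preserves auditability.
* **Force curves** are piecewise linear: a contact ramp, an adhesion well
  descending to the rupture force at a grid point, a single jump-off, and
  a flat baseline, plus optional linear drift and Gaussian signal noise.
  Because the well bottom lies exactly on the sample grid, extraction
  recovers the input force to machine precision at zero noise, and to
  within one sample step otherwise.
* **Friction loops** are `offset ± true_vf` plus independent noise per
  direction, so the half-width estimator converges to `true_vf`.
* **Height maps** are a flat baseline plus Gaussian bumps with random
  centres and truncated-normal heights; a multiplicative compaction
  factor in (0, 1] scales the bump field, so mean height above baseline,
  $S_a$ and $S_q$ scale exactly linearly with it. The defaults (128 px,
  1 µm scan, ~2400 bumps of ~1.45 nm mean height and 20 nm width on a
  6.9 nm substrate) were tuned once so a full-compaction map resembles a
  serum-albumin monolayer: ≈8.4 nm mean height above the substrate and
  $S_q \approx 2.6$ nm.

All randomness flows from one explicit integer seed per call
(`withr::with_seed`), leaving the caller's RNG state untouched; identical
seeds give bit-identical output.

What the generator does **not** emulate: viscoelastic contact mechanics,
polymer-stretch (worm-like-chain) unbinding shapes, multiple rupture
steps per curve, tip convolution in imaging, scanner drift and creep, or
any physics of the electric field itself — field effects enter only as
phenomenological parameter scalings (per-condition force levels, a
compaction factor). Passing tests therefore demonstrate that the analysis
recovers known ground truth under the model's assumptions, not that those
assumptions hold for any particular instrument or sample.

## The drug-by-field sweep

`run_sweep()` composes all stages over a list of (drug, field-strength)
conditions, each backed either by simulation parameters or by directories
of measurement files, and emits one report row per condition (adhesion
peak and box stats, $F_i$, $F_0$, loop and constant-load friction peaks,
surface metrics, and Welch-test stars against the baseline field).
Missing inputs skip the condition with a warning; nothing is imputed.
`reduction_summary()` derives per-drug integer percent reductions between
two fields plus the min/max across drugs. The baseline defaults to
0 mV/mm; published percent ranges for the non-specific force are
reproduced from the bundled reference table only under the 0→100 baseline
(the running-text ranges are consistent with a 20→100 baseline instead,
so both are supported).

`demo_sweep_config()` builds a six-drug × six-field scenario whose
ground truth follows the bundled published force table
(`tki_reference_forces()`) and monotone attenuation ramps for friction
and compaction. One sizing note: with 50-curve groups the slope SE of the
variance–mean regression (~6 pN) is far wider than adjacent published
$F_i$ gaps (1–2 pN), so monotone *estimates* across all six fields cannot
be expected from ensembles of realistic size. The monotonicity check in
the test suite therefore uses a coarser field grid (0/60/100 mV/mm) and
1600 curves per bond-count level, sized so every adjacent ground-truth
gap is at least ~2.5 estimator SEs.

## Problem sizes used in the checks

The test suite and acceptance script use: 100-replicate parameter
recovery at 18 × 300 curves (recovery design above) and at the published
operating point's prescribed 6 × 50 curves with 10 pN noise; 200-curve
extraction round trips; 1000 pure-noise curves for the false-positive
rate; 500-loop and 500-map property sweeps; and 20-seed moment checks at
$n = 10^4$. These sizes were chosen so each check's statistical power
matches what it asserts.

## Worked example

```{r example}
# decompose a synthetic ensemble at a published operating point
forces <- unlist(lapply(1:6, function(lambda) {
  draw_rupture_forces(adhesion_model_params(
    f_i = 33.4, f_0 = 90, lambda_mean = lambda,
    noise_sd = 5, n_curves = 300, seed = 100 + lambda))
}))
groups <- group_curves(forces, group_size = 300)
fit_poisson_decomposition(groups)
```

## Known limitations

* Single-event extraction only: one adhesion value per curve, no
  multi-peak decomposition.
* The Poisson decomposition inherits the biases above (noise variance in
  the intercept, attenuation from finite groups); both shrink with
  ensemble size but are not corrected for.
* Lateral calibration takes $K_f$ as given; no torsional calibration is
  performed.
* Quartile and binning conventions are fixed (type-7, Freedman–Diaconis)
  rather than auto-selected; both are exposed as arguments.
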