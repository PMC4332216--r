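---
title: "Methods: linescan velocimetry, FWHM diametry and shear-driven remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linescan velocimetry, FWHM diametry and shear-driven remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pialflow)
```

pialflow quantifies blood flow in the surface (pial) vessels of the
neonatal mouse cortex from two-photon linescan data and relates the
mechanical forces of flow to day-to-day vessel remodeling. This vignette
explains each model in the chain, the assumptions behind it, the tunable
parameters, and the numerical choices made where the design was open.

## The kymograph model

A linescan repeatedly samples a line placed along a vessel's axis at a
line rate $f$ (Hz). Stacking the scans gives a space–time image — a
kymograph — with rows as time and columns as space (pixel size $p$,
µm/pixel). The plasma is fluorescently labelled; red blood cells exclude
the dye and appear as dark streaks. A cell moving at velocity $v$ (mm/s)
advances

$$ m = \frac{1000\,v}{f\,p} \quad \text{pixels per line}, $$

so its streak makes an angle $\theta$ with the time axis with
$\tan\theta = m$. Velocimetry is therefore angle estimation.

The synthetic generator (`generate_kymograph()`) renders exactly this
scene: cells enter the upstream edge of the field as a Poisson process,
carry a Gaussian dark cross-profile (FWHM `streak_width`, default 6 µm —
the scale of a mouse erythrocyte), attenuate the background
multiplicatively (overlapping cells darken more, saturating naturally),
and advance $m$ pixels per line. Additive Gaussian noise and line-wise
motion artifacts (each corrupted line displaced sideways by a uniform
jitter of up to a quarter of the field width, which locally decorrelates
the streak pattern) complete the model. Defaults follow the acquisition
settings of the underlying study design: 2 kHz line rate, 0.5 µm pixels,
128-pixel fields. The cell arrival rate is auto-set so ~4 cells occupy
the field at once; contrast (0.6) and noise are free parameters, since
streak contrast and hematocrit are not constrained by desk-scale
information. A commanded shift of $|m| \ge n_\text{pixels}/2$ is refused:
such streaks are unrecoverably aliased and the caller must raise the line
rate.

What the generator does **not** emulate: optics (no PSF, so streak edges
are sharper than real data), photobleaching, flow pulsatility, hematocrit
packing statistics, or scanner distortions. Passing the recovery tests
therefore shows the estimators are correct for ideal streak geometry plus
noise and gross motion — not that they are robust to every real-world
degradation.

## Radon streak-angle velocimetry

For a candidate angle $\theta$, each pixel $(i, j)$ (row $i$ = time,
column $j$ = space) is projected onto the axis perpendicular to the
streak direction,

$$ u = j\cos\theta - i\sin\theta, $$

and accumulated into unit-width bins. When the projection runs along the
streaks, bin means separate into dark and bright; the objective is the
count-weighted variance of the bin means,
$\sum_b n_b (\bar x_b - \bar x)^2 / \sum_b n_b$. The weighting matters:
with raw bin *sums*, lattice-resonant angles (45°, 63.4°, …) produce
uneven bin occupancy and spurious variance even for pure noise, whereas
for the weighted form the expected objective of mean-subtracted white
noise is occupancy-independent. The angle search runs a coarse 1° grid
over (−89°, 89°), then refines by bracketed grid subdivision
(±span at a tenth of the step, repeated) down to 0.001°;
`radon_angle_scan()` exposes the raw objective so the refinement can be
checked against exhaustive sweeps. An optimum at $|\theta| \ge 89^\circ$
— within a degree of horizontal streaks — is declared unresolvable: the
flow is too fast for the line rate.

Quality is summarized by the *separability*, the maximum coarse-grid
variance over its mean. Coherent streaks give values well above the
default acceptance threshold of 3.0; white noise and jittered artifact
lines give values near 1–2. The threshold is configurable; 3.0 cleanly
split signal from artifact across the generator's noise range.

Two numerical caveats are documented rather than hidden. First,
nearest-bin accumulation leaves a sub-degree lattice bias near 0°, so a
noise-free stalled-cell block optimizes a fraction of a degree off
vertical; the suite bounds the effect below 0.01 mm/s at default
calibration — negligible at physiological scales. Second,
`estimate_velocity()` suppresses static stripes (vessel-wall shadows) by
subtracting the *record-wide* column mean from each window, not the
per-window column mean: a static stripe is constant over the whole scan,
so the record mean removes it exactly, whereas a per-window column mean
acts as a temporal high-pass that biases slow flow (at 0.2 mm/s a
streak dwells ~85 of 128 window lines on one column, so much of the
streak itself is subtracted); with record-wide subtraction the recovery
sweep holds its 5% tolerance down to 0.2 mm/s.

## Cross-correlation fallback for fast flow

Near-horizontal streaks defeat angle estimation, so when the Radon
result is unresolvable the window falls back to
`correlation_window_velocity()`: every pair of lines `line_lag` apart is
cross-correlated (mean product per overlapping sample, so the taper of
partial overlap does not bias the peak), correlograms are averaged
across pairs, and the peak lag is refined with a three-point parabolic
fit, giving velocity $\hat s\,p\,f/(1000\,\text{lag})$. A peak on the
search boundary means the shift exceeded the search range; a normalized
peak below `min_peak_corr` (default 0.25) rejects the window as
incoherent.

## Windowed processing and the 40 s quality standard

`estimate_velocity()` slides a 128-line window at a 64-line hop
(defaults), yielding one velocity and separability per 32 ms of data at
2 kHz. The aggregate is the **median** over accepted windows — robust to
residual artifact windows that pass the separability gate; the mean is
available by option. The accepted duration,
`accepted windows × hop / line rate`, is compared to the 40 s
representative-flow standard used when screening linescans, and
estimates based on less accepted time carry a `below_standard` flag. The
flag marks, rather than blocks: short clean records still yield accurate
velocities, and the synthetic studies in the test suite (seconds of data,
chosen to keep runtimes at desk scale) run with the flag set.
"Representative flow" has no operational definition beyond this duration
rule here; the separability gate is this package's proxy for the manual
artifact screening an experimenter would do.

## FWHM diametry

With labelled plasma, the lumen is a bright band in a cross-section
intensity profile. `fwhm_diameter()` smooths the profile (Gaussian,
sd 1 sample by default), takes the baseline as the median of the pooled
raw outer 10% of samples on each side (raw rather than smoothed: the
smoothed tail samples are correlated and their median is noisier), the
peak as the vertex of a quadratic fitted over the smoothed top band
(samples above 75% contrast), and measures the distance between the two
linearly interpolated crossings of $(peak + baseline)/2$ that bound the
contiguous above-half-max run containing the peak. The quadratic vertex
replaces the raw smoothed maximum because a maximum over noisy samples
is selection-biased upward, which raises the half level and coherently
narrows the measured width.
Anchoring on the peak's run resolves multi-peak profiles (a second
vessel in the chord) deterministically. Degenerate inputs raise typed
errors: contrast below `min_contrast` (no vessel), or a run touching the
profile end (chord too short). The half-max fraction is configurable. A
profile is "one measurement per vessel per session"; no session
averaging is assumed.

Smoothing with sd 1 sample widens a Gaussian lumen of sd $\sigma$ to
$\sqrt{\sigma^2 + 1}$ samples — a 0.2% overestimate for a 20 µm vessel
at 0.5 µm sampling, far below the one-pixel accuracy target. Heavier
smoothing was rejected: its widening bias on Gaussian-shaped lumens
grows quadratically and breaks the 1% noise-free accuracy of the
analytic-FWHM check.

Noise performance differs sharply by edge shape. At 10% contrast noise a
20 µm *tophat* (sharp-walled) profile is recovered well within a pixel,
but a *Gaussian*-shaped lumen of the same width is not: its half-max
slope is gentle (0.06 intensity/µm for 20 µm at unit contrast), so
intensity noise converts to crossing jitter, and the half level itself
(peak and baseline estimates) shifts both crossings coherently. This is
an information limit, not an implementation gap — the suite verifies on
the same benchmark that even a full 4-parameter Gaussian
maximum-likelihood fit, the optimal estimator under the true model,
exceeds half a pixel of median error, and that the FWHM estimator stays
within a factor of two of that floor. Sub-pixel single-profile diametry
of soft-edged structures at this noise level is not achievable by any
method; averaging repeated profiles is the practical remedy on real
data.

## Shear rate, not shear stress

For Poiseuille (parabolic, laminar) flow the wall shear rate is
$\dot\gamma = 4 v_\text{centerline} / D$; with $v$ in mm/s and $D$ in µm,
`shear_rate()` returns $4|v| \cdot 1000 / D$ per second. Only the
magnitude is kept — shear rate is direction-free. Shear *stress* is
deliberately not computed and no viscosity parameter exists anywhere in
the package: blood viscosity varies with hematocrit and is unknown in
this setting, and exposing a default would invite a misleading output.
The centerline velocity enters uncorrected for profile blunting, which
is the stated estimator of the analysis this package reproduces.

## The remodeling regression

`pair_sessions()` forms one point per vessel per *consecutive-day* pair:
$x = \log_{10}\dot\gamma$ at day $t$, $y$ = percent diameter change from
day $t$ to $t+1$. The log transform reflects that shear spans orders of
magnitude across the venous plexus. Pairs at longer lags are not formed
— the integration time of the vessel's mechanotransduction is an open
question, and lag-1 is the study design. Vessels missing an ingredient
are skipped with a logged reason. When one vessel contributes several
consecutive-day pairs, all of them enter the regression as separate
points; the fit is a plain OLS (`stats::lm`), not a mixed model, so
repeated-vessel correlation is not modelled — both choices mirror the
analysis being reproduced and are stated here rather than silently made.

`fit_remodeling()` returns the fit twice: excluding points with
$y > 100\%$ (the single documented outlier rule — upper tail only; no
symmetric lower-tail rule is invented) and including them. The p-value
is the conventional two-sided t-test of zero slope; sidedness was an
open choice and two-sided is the conservative default. When the total
sum of squares is zero (all $y$ equal) the fit reports slope 0 and
$R^2 = 0$ with an undefined p-value.

`age_bin_velocity_diameter()` computes the Pearson velocity–diameter
correlation within inclusive postnatal-age bins, default P2–6 and
P8–12. (The early bin is described elsewhere as both "P2–6" and "P3–6";
the bins here follow the P2–P6 convention and are configurable.) Bins
with fewer than 3 usable observations report `NA` rather than erroring.

## The cohort generator and what the tests show

`generate_cohort()` draws day-1 diameters and velocities log-uniformly
(so $x = \log_{10}(4000 v/D)$ has variance
$(w_v^2 + w_d^2)/12$ for decade-widths $w$ — used to tune noise to a
target population $R^2$), applies
$\%\Delta D/D = 15.4\,\log_{10}\dot\gamma - 40.9 + \varepsilon$ per
transition, and emits per-day observation rows. The default law is the
fitted remodeling relation for pial venules; with `noise_sd = 0` every
point lies exactly on it, so the whole pipeline
(pair → fit) must return slope 15.4 and intercept −40.9 to numerical
precision — the package's primary self-check. A vessel whose diameter
would become nonpositive is recorded as pruned (`NA` onward), the
synthetic analogue of pruning to invisibility; under heavy noise this
truncates the extreme lower tail and is the one way generated cohorts
deviate from the pure law. An optional Gaussian copula (`vd_rho`)
rank-correlates day-1 velocity with diameter to emulate the age-dependent
tightening of the velocity–diameter relationship; `n_days > 2` iterates
the law with freshly drawn velocities.

Problem sizes in the test suite are chosen for desk-scale runs: 5–50 s
synthetic records for velocimetry recovery (0.2–10 mm/s, noise to 20% of
contrast, both signs), 20 blocks for the exhaustive-sweep angle oracle,
100 seeds per shape for diametry, 200 replicate cohorts of 50 vessels
for the $R^2$ calibration, and a 20-vessel × 3-day fully synthetic
study for the end-to-end slope-recovery check.

## Known limitations

- The velocimeters assume a single dominant velocity per window; two
  populations of streaks (e.g. a crossing vessel in the scan path) will
  resolve to whichever projects more coherently.
- Separability thresholding is a proxy for manual artifact screening; a
  slow drift that preserves streak coherence passes it.
- FWHM diametry measures the dye column, i.e. the lumen, not the wall;
  it requires the lumen to be the brightest structure in the chord.
- The remodeling fit inherits OLS assumptions; with measurement noise in
  $x$ (velocimetry + diametry errors propagate into shear) the slope is
  attenuated, though at the tested noise levels the bias is well inside
  the confidence interval.
- No image registration across days: vessel identity is an input label,
  as in landmark-based relocation during acquisition.
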