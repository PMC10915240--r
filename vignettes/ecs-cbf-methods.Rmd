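---
title: "Methods: simulating and classifying pulsatile cerebral blood flow from resonant-frequency traces"
author: "ecscbf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying pulsatile cerebral blood flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecscbf)
```

## The measurement model

Electromagnetic-coupling sensing places a coil-on-electrode sensor in the
near field of the head. The sensor, together with the tissue under it, forms
a resonant circuit: a fixed no-load inductance $L$ and capacitance $C$, a
coupling capacitance $C_{cap}$ that tracks the tissue dielectric constant,
and an induced resistance $R_{ind}$ that tracks tissue conductivity. The
measured signal is the circuit's resonant frequency

$$
f_{osc} \;=\; \frac{1}{2\pi}\sqrt{\frac{1}{L\,(C+C_{cap})}-\frac{R_{ind}^2}{L^2}},
$$

which is strictly decreasing in both $C_{cap}$ and $R_{ind}$. Pulsatile
cerebral blood flow — the cyclic intracranial blood-volume change over the
cardiac cycle — perturbs both tissue properties, so the RF trace pulses at
the cardiac (or, on a pump-driven phantom, the pump) rate. The printed
form of the radicand is typographically ambiguous about grouping; the
package adopts $1/(L(C+C_{cap})) - R_{ind}^2/L^2$, the grouping consistent
with the underlying coupled-resonator derivation, and isolates it in the
single function `resonant_frequency()` so an alternative grouping would be
a one-line change.

## The forward simulator

`generate_rf_trace()` composes four pieces:

1. **Vessel waveform.** Each pulse period carries a broad systolic lobe
   (raised half-sine occupying 0.6 of the period) and a narrower dicrotic
   rebound lobe (0.3 of the period, height `dicrotic_ratio` times the
   primary, default 0.3, delayed by `dicrotic_delay` of the period, default
   0.65). The broad primary lobe keeps the spectral fundamental about twice
   as strong as any harmonic, which is what real pulse spectra look like
   and what makes the dominant-frequency readout meaningful. A
   narrow-lobed geometry (e.g. two equal 0.4-width lobes around
   mid-period) hands the spectrum to the second harmonic and was rejected
   for that reason.
2. **Coupling.** Relative volume $v(t) \in [0, 1]$ perturbs the circuit as
   $C_{cap}(t) = C_{cap}(1 + k_c\,a\,v(t))$ and
   $R_{ind}(t) = R_{ind}(1 + k_r\,a\,v(t))$ with phenomenological gains
   $k_c = k_r = 10^{-3}$. The attenuation
   $a = e^{-d/\lambda_d} e^{-r/\lambda_r}$ (depth $d$, lateral offset $r$,
   $\lambda_d = 3$ cm, $\lambda_r = 2$ cm) reproduces the qualitative
   fall-off of pulsation amplitude with sensor-to-vessel distance; the
   constants are not calibrated to any physical sensor.
3. **Circuit defaults.** $L = 1\,\mu H$, $C = 1\,nF$, $C_{cap} = 0.1\,nF$,
   $R_{ind} = 1\,\Omega$ put the carrier near 4.8 MHz with pulse-induced
   excursions of order $10^{-4}$ MHz at 2 cm depth and $10^{-5}$ MHz at
   8 cm — the regime reported for this class of sensor.
4. **Noise.** White Gaussian noise (`noise_sd`, default $10^{-5}$ MHz,
   about 10% of the pulsation amplitude at 2 cm) plus a random-walk
   baseline drift growing at `drift_sd` MHz per $\sqrt{s}$ (default
   $2\times 10^{-6}$). Both are reproducible under a seed and are the only
   stochastic components of a trace.

The two-state cohort generator `generate_cohort()` draws per-subject heart
rates from $N(1.17, 0.1)$ Hz truncated to $[0.8, 1.6]$ (roughly 50–95 bpm)
and pulse strengths from a lognormal with 20% coefficient of variation,
then emits one baseline recording plus post-caffeine recordings whose pulse
amplitude is multiplied by $e^{-r\,m}$ at minute mark $m$. The decay rate
$r$ (default 0.02/min, i.e. a 45% amplitude loss at 30 min) is a
phenomenological stand-in for the vascular-stiffness effect of caffeine:
only the monotone decline over 30 minutes is asserted, not a
pharmacokinetic time course.

**What the generator does not emulate:** motion and contact artifacts,
heart-rate variability within a recording, respiratory modulation,
inter-device calibration differences, and the non-uniform caffeine
response seen in real volunteers (where a minority show amplitude
*increases*). Classification results on this synthetic cohort therefore
demonstrate that the pipeline is correct and sensitive to
amplitude-coded flow differences, not that any particular accuracy will
transfer to human recordings.

## Preprocessing

**Wavelet denoising.** `wavelet_denoise()` runs a periodized orthogonal
DWT (Daubechies-4 by default, level 4 on 20 Hz data, so detail bands cover
0.625–10 Hz) and thresholds detail coefficients with the universal rule
$t = \hat\sigma\sqrt{2\ln N}$, $\hat\sigma = \mathrm{MAD}(d_1)/0.6745$.
Both soft and hard thresholding are provided. Soft shrinkage subtracts $t$
from every retained coefficient, which biases the reconstructed pulse
amplitude downward — by different relative amounts for large (baseline)
and small (post-caffeine) pulses — so the amplitude/CRA pipeline uses
**hard** thresholding, which leaves above-threshold coefficients untouched.
The generic operation defaults to soft, the conventional choice when
amplitude fidelity is not the target. Signals whose length is not a
multiple of $2^{level}$ are reflection-padded at the tail and truncated
after reconstruction; with a zero threshold the round trip is the identity
to numerical precision.

**Pulse detection and amplitude.** Because $f_{osc}$ falls when blood
volume rises, the pulse event is a downward dip in the RF trace.
`detect_pulses()` auto-detects this polarity (the trace spends most of its
time near the upper plateau, so its mean falls below its median) and finds
pulse extrema with a refractory constraint of `min_period` seconds,
default 0.6. The default rejects the dicrotic bump — which trails the
primary event by 0.65 of a period — for pulse rates up to about 1.6 Hz; a
shorter refractory window would double-count it. The per-trace amplitude
is the mean over interior pulses of (peak value − mean of the two flanking
troughs), in MHz.

**CRA.** The change ratio of amplitude is the signed percent change
relative to the pre-intervention baseline,
$\mathrm{CRA} = 100\,(A_{state}-A_{base})/A_{base}$; it is scale-invariant
and zero at baseline. Under the programmed exponential decay,
$\log(1+\mathrm{CRA}/100) = -r\,m$, so `estimate_decay_rate()` recovers
$r$ by a through-the-origin least-squares fit pooled over subjects; on a
13-subject cohort at the default noise the estimate lands within a few
percent of the programmed rate.

**Spectra and correlation.** `dominant_frequency()` reports the maximal
magnitude-spectrum bin excluding DC (resolution $f_s/N$ attached as an
attribute). `spearman_rho()` uses average ranks for ties, a
$t$-approximation for $n \ge 10$ and the exact permutation distribution
below that — with only six or seven trajectory points the asymptotic
approximation would be untrustworthy.

## From traces to images

Traces are cut into fixed windows of 300 samples with a step of 60
(16 windows per minute at 20 Hz), always inside one-minute blocks so no
window spans a state boundary. Each window is drawn as a 1-pixel black
polyline on a white 300×300 canvas — one abscissa column per sample, no
axes or margins — then resized to 100×100 with a separable
Catmull-Rom-class bicubic kernel ($a=-0.5$, replicate borders, output
clipped to $[0,255]$). The resize is what introduces the gray transitions
along the line that the texture features consume.

The vertical scale matters: with per-window min–max scaling every window
fills the canvas and amplitude information is erased, making the two-state
classification ill-posed. The default is therefore a **global** scale per
recording (the subject's min–max across both states, with 5% headroom),
so post-caffeine windows draw visibly flatter traces. Per-window scaling
is retained as an ablation option.

## Feature families

On each 100×100 image the package extracts a fixed 14,379-dimension
vector: 7 Hu invariant moments and 16 GLCM statistics (the 23 "global"
dimensions), plus 4,356 HOG and 10,000 LBP values (the 14,356 "local"
dimensions). Conventions that pin these counts down:

* **GLCM** — 8 gray levels (equal-width bins over 0–255), distance 1,
  symmetric matrices in the four directions 0°, 45°, 90°, 135°; four
  statistics per direction (contrast, entropy, energy, inverse difference
  moment), statistic-major ordering. Four directions × four statistics is
  the unique decomposition of the 16-dimension count given the four named
  statistics.
* **HOG** — centered-difference gradients with replicate borders, signed
  orientations over 0–360° in 9 bins, 8×8-pixel cells tiled from the
  top-left (12×12 full cells, the 4-pixel remainder dropped), 2×2-cell
  blocks at one-cell stride (11×11 blocks), per-block L2 normalization:
  $11 \cdot 11 \cdot 4 \cdot 9 = 4356$. The one-cell stride and dropped
  remainder are the unique standard configuration reproducing that count
  on a 100×100 image.
* **LBP** — 3×3 neighborhood, neighbors read clockwise from the top-left
  with the first neighbor as the most significant bit, bit set when the
  neighbor is *at least* the center (ties set the bit), replicate-padded
  borders so the code map stays 100×100 and flattens row-major to 10,000
  codes in 0–255.
* **Hu** — computed on raw intensities without a log transform; they are
  routinely discarded by the importance filter anyway.

All four extractors are validated against brute-force double-loop oracles
implemented independently in the test suite.

## Selection and classification

`importance_selection()` scores every non-GLCM feature with the
impurity-decrease importance of a 500-tree random forest (fixed seed),
normalizes importances to fractions summing to one over the scored
features, and keeps features at or above 0.5% — a tie at exactly the
threshold is retained. The GLCM family bypasses scoring and is always
kept, reflecting its directly interpretable per-state trends.

`split_and_standardize()` performs a stratified 4:1 split and z-scores
with training-set statistics only. Stratification is an assumption, not a
documented fact of the original analysis; per-subject grouping (no subject
in both train and test) is deliberately **not** the default — windows from
one recording are strongly correlated, so the default split measures
within-cohort discrimination, not subject-level generalization. This is a
stated limitation.

`grid_search_train()` runs an exhaustive 5-fold stratified CV over the
reference grids (KNN: 28 neighbor counts × uniform/distance weights = 56;
SVM: 101 C × 101 gamma × linear/rbf = 20,402; random forest:
152 × 2 × 7 × 4 = 8,512), scoring by accuracy with ties broken by grid
order. A reduced grid covering the same ranges is provided for routine
runs. The random-forest grid follows scikit-learn-style names and is
mapped onto `ranger`: `max_depth = None` becomes unlimited depth, and
`min_samples_split` $s$ maps to `min.node.size` $= \max(1, s-1)$ — an
approximation, since `ranger` bounds terminal- rather than internal-node
size. The distance-weighted KNN variant is computed by an exact small
distance voter inside the package (weights $1/d$; ties at a 0.5 vote
share resolve to the nearest neighbor's class); the uniform-vote route is
cross-checked against an independent implementation in the tests.

`evaluate()` reports accuracy, recall, precision and F1 with the
post-intervention state as the positive class, ROC and PR curves by
threshold sweep, trapezoid AUC, the confusion matrix (rows = truth), and
a learning curve obtained by refitting the selected hyperparameters on
stratified subsets of the training data.

## Numerical choices and degenerate inputs

* A non-positive radicand in the resonance formula (over-damped circuit)
  raises an error naming the parameter set; it is never clamped.
* Flat traces yield empty peak lists (not an error); amplitude on a flat
  trace errors, as does the CRA with a non-positive baseline.
* A constant trace has no dominant frequency and errors; the spectral
  resolution is always attached so bin-exactness claims are checkable.
* Rendering maps values to rows with `floor(x + 0.5)` so equal inputs give
  identical pixels across platforms; a constant window draws a mid-height
  line.
* Constant feature columns get unit scale in the z-scorer (centered only).
* All randomness flows from explicit seeds; the pipeline derives one seed
  per stage from the single run seed (`(seed * 7919 + stage * 104729) mod
  2147483629`) so stages re-run independently yet reproducibly.

## Problem sizes

The bundled end-to-end analyses run at a deliberate desk scale chosen once:
13 subjects × 2 states × 1 minute per state → 416 images of 14,379
features, reduced hyperparameter grids, 20–25 simulated phantom traces for
spectral checks, and a 13 × 6-minute-mark cohort for the CRA decay
recovery. At this scale the full pipeline completes in well under a minute
of CPU time while keeping every statistical check comfortably powered.
The label-permutation control reports the mean test accuracy over three
independent permutations, which keeps the sampling standard deviation of
the estimate near 0.03 at the ~84-image test-set size — small against the
±0.1 chance band it is compared to.

## Known limitations

* The coupling gains, attenuation lengths and caffeine decay are
  phenomenological; none are calibrated to hardware or physiology.
* The image total of any real recording session depends on how many
  minutes per state are used; this is a parameter, not a constant.
* Accuracy on the synthetic cohort does not transfer to human data; the
  generator's separation between states is programmed, and the default
  split does not test subject-level generalization.
* Only the 8-bit, radius-1 LBP and signed-gradient HOG variants are
  implemented — the configurations fixed by the dimensional contract.
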