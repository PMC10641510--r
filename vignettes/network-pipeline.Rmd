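---
title: "From raw fNIRS intensity to language-network topology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw fNIRS intensity to language-network topology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsnet)
```

# What the package computes

`nirsnet` implements a complete analysis chain for continuous-wave fNIRS
functional-connectivity studies of the cerebral language network, of the kind
used to compare children with frontal or temporal lobe epilepsy against
healthy controls during a passive story-listening task. The chain is:

1. **Preprocessing** — raw two-wavelength light intensity (760/850 nm, 50
   channels, 7.8 Hz) is quality-controlled, artifact-corrected, converted to
   oxy-/deoxyhemoglobin concentration changes, filtered, and cleaned of
   systemic physiology.
2. **Connectivity** — subject-level functional-connectivity (FC) matrices are
   estimated by circular bootstrap over 60-s windows, Fisher-transformed,
   corrected for age, and reduced to task-minus-rest residual matrices.
3. **Network metrics** — residual-free stage-B task matrices are thresholded
   over a sparsity range into weighted graphs; segregation (clustering
   coefficient, local efficiency) and integration (characteristic path
   length, global efficiency) metrics are normalized by degree-preserving
   random references and integrated into per-subject AUCs.
4. **Cohort statistics** — edgewise permutation tests, z-score subgroup maps,
   effect sizes, and moderation regression linking network AUCs to cognitive
   scores.

Because clinical recordings of this kind are not publicly deposited, the
package ships a first-class synthetic cohort generator with exact ground
truth; every pipeline stage is validated against quantities the generator
plants.

# The synthetic cohort generator

## Signal model

Clean oxyhemoglobin for one subject is a latent-factor process
`HbO = s · L F`, where `L` is the symmetric square root of the planted
channel-by-channel correlation matrix, the rows of `F` are independent
zero-mean unit-variance processes, and `s` (default 0.5 µM) sets the
physiological scale. This construction guarantees that the population
correlation of the clean signal equals the planted matrix exactly — the
property every connectivity test relies on.

Each stochastic factor mixes two spectral components in equal variance:
white noise convolved with the canonical double-gamma hemodynamic response
function (peak ~6 s, undershoot ~16 s, undershoot ratio 1/6), and a lightly
smoothed broadband component. The slow part gives the factors realistic
hemodynamic autocorrelation; the broadband part reflects the fact that real
fNIRS low-frequency fluctuations are not band-limited to the HRF passband,
and keeps the effective sample size of a 60-s window large enough that
windowed Pearson estimates are close to unbiased. With purely HRF-smoothed
factors, a 60-s window would hold only ~15 independent samples and the
bootstrap estimator would be visibly biased; we regard that regime as
unrepresentative of real recordings.

During the task condition the leading factor carries the stimulus-locked
response: the 18-block design (20-s stimuli, inter-stimulus intervals drawn
uniformly from 15–20 s) convolved with the HRF, standardized, and mixed into
factor 1 with weight `evoked_weight` (default 0.6). Because the factor is
standardized, planting the evoked response does not change the correlation
structure — it only makes the shared variance stimulus-locked, as in a real
block-design recording.

Deoxyhemoglobin is sign-flipped, scaled oxyhemoglobin (ratio 0.3); modelling
HbR-specific physiology is out of scope since all analyses run on HbO.

## From concentrations to raw intensity

Concentrations are projected to optical density through the modified
Beer–Lambert forward model (extinction coefficients below), after which the
generator adds, per channel and wavelength: a shared cardiac sinusoid
(frequency drawn from 0.9–1.5 Hz per subject, per-channel amplitude jitter
and phase lag), a 1/f-like random-walk drift, white measurement noise, and
injected artifacts. Raw intensity is `I0 · 10^(−ΔOD)` with an arbitrary
baseline `I0 = 1`; only intensity ratios carry information.

Poorly coupled channels (fraction `bad_channel_frac`) carry 5% of the
cardiac amplitude and 10× the noise — the signature the cardiac-coherence QC
is designed to catch.

Artifacts are specified as (kind, amplitude, duration, channel fraction,
count). Amplitudes are expressed in robust standard deviations of the
*detail* signal (intensity minus its trailing 6-s moving average), i.e. on
the exact scale the detector thresholds, so a "5 SD" artifact is 5 SD by the
detector's own measure. The default spike is a flat-enveloped oscillatory
burst (1.6 Hz), the canonical appearance of a pediatric motion artifact;
step and ramp ("drift") kinds are also available.

## Cohort structure

Ages are uniform on 6–18 years (group summaries alone do not constrain the
shape, and uniform gives the age regression maximal leverage). Patients
receive connectivity offsets — by default a left intra-hemispheric decrement
(−0.06), right intra-hemispheric increment (+0.06) and inter-hemispheric
decrement (−0.04) on the correlation scale — and every subject's
within-hemisphere coupling drifts with age (+0.004/year). For patients the
left-hemisphere coupling is additionally modulated by centered IQ, planting
a group-moderated association between topology and cognition. Cognitive
scores give the patient group a 20-point IQ deficit, consistent with a large
standardized group difference (d ≈ 1.3).

For statistical calibration work a separate table-level generator
(`simulate_moderation_cohort()`) draws IQ exogenously and constructs the
network AUC as `b0 + slope_g · IQ_c + b_group · group + ε` with
group-specific slopes (defaults −1.4 for patients, 0 for controls, per-SD
IQ units). This is the generative direction matched by the fitted moderation
model, so planted and recovered coefficients are directly comparable.

## What the generator does not emulate

No optode geometry or photon transport; no EEG waveforms (seizure intervals
enter as annotations); no condition-specific physiological confounds such as
task-correlated breathing; no heteroscedastic noise over time. Consequently,
passing tests demonstrate the *pipeline's* correctness and calibration under
a realistic stationary signal model — they do not certify performance on
recordings whose artifacts or physiology depart strongly from that model.

# Preprocessing decisions

The stage order is fixed: channel QC → artifact detection → PARAFAC
correction or exclusion → ΔOD → band-pass → Beer–Lambert → global signal
regression, each stage consuming the previous stage's validity mask.

**Cardiac-coherence QC.** Magnitude-squared coherence is computed by Welch
averaging (256-sample Hann segments, 50% overlap); the cardiac peak is the
largest average-spectrum peak in 0.8–2.3 Hz. A channel is retained when its
median coherence with all other channels at that peak reaches 0.1. The
threshold is deliberately low: the point is to catch decoupled optodes
(coherence near the independence floor, roughly 1/#segments), not to rank
good channels. For recordings much shorter than ~8 minutes the independence
floor approaches 0.1 and the threshold should be raised via the config.

**Artifact detection.** A sample is a candidate when the deviation of
intensity from its trailing 6-s moving average exceeds 3 robust standard
deviations (1.4826·MAD of the deviation signal over the whole recording —
the robust estimator keeps artifacts from inflating their own threshold).
Candidate runs per channel are fused across gaps shorter than 2 s, runs
shorter than 3 s are dropped, events must affect at least 5% of channels,
channels correlating above 0.8 with a flagged channel within the event are
added, and events closer than 2 s merge. The trailing (causal) moving
average matters: a centered average absorbs half of a sustained step, so
steps of moderate amplitude would never cross the threshold; with the causal
form both onset and offset of a step are detected and fuse into one event
covering it.

**PARAFAC correction.** Isolated artifact intervals (shorter than
`long_noise_s`, default 10 s) are corrected by a rank-3 trilinear
(time × channel × wavelength) canonical-polyadic decomposition of the
interval plus 6 s of context, fitted by alternating least squares with
singular-vector initialization (tolerance 1e-8 on the fit, up to 500
sweeps). Components whose time-course variance inside the interval exceeds
twice their context variance are deemed artifact and subtracted inside the
interval only, linearly detrended through short context averages on either
side so the corrected signal is continuous at the boundaries. Intervals
where ALS fails to converge, and long intervals, are excluded via the mask
instead; excised data are never interpolated.

**ΔOD and filtering.** ΔOD uses the per-segment mean of valid samples as
reference (stable against initial transients). The band-pass is a
Butterworth design (4th-order low-pass prototype, 0.001–0.5 Hz) applied
forward–backward, giving zero phase and an effective 8th-order magnitude
response. Contiguous valid segments are filtered independently; segments too
short for the filter's padding are dropped from the mask with a warning.

**Beer–Lambert.** The built-in extinction table uses standard compiled
base-10 molar extinction coefficients (cm⁻¹ M⁻¹): 586.0/1548.52 (HbO/HbR) at
760 nm and 1058.0/691.32 at 850 nm; any table can be supplied instead.
Differential pathlength factors come from the general age- and
wavelength-dependent equation
`DPF = 223.3 + 0.05624·A^0.8493 − 5.723e-7·λ³ + 1.245e-3·λ² − 0.9025·λ`
(age `A` in years, `λ` in nm), overridable per call. Missing source–detector
distances default to 30 mm. The 2×2 inversion is exact; the round trip is
tested to 1e-10 relative error.

**Global signal regression** projects out the mean time course of retained
channels (with intercept), fitted on valid samples.

# Connectivity decisions

"Cross-correlation" is zero-lag Pearson correlation — no lagged maxima. Two
hundred 60-s windows are drawn uniformly on the circularized recording;
wrapping windows are allowed, overlapping draws are allowed, and a window is
valid only when it contains *no* masked sample (strict exclusion guarantees
that seizure-contaminated samples can never leak into an FC estimate). Stage
A is the element-wise mean over windows; pairs involving a zero-variance
window channel are averaged over the remaining windows.

Fisher z-transformation precedes the age regression, which is an
edgewise OLS on age pooled over patients and controls of a condition —
pooling uses all 39 subjects of the cohort and assumes a shared
developmental slope; fitting per group is a config away but halves the
regression's n. Stage B subtracts `β̂1·(age − mean age)` rather than taking
raw residuals: downstream absolute-value thresholds need the FC *level*, not
zero-mean residuals. The task−rest subtraction is element-wise.

# Network-metric decisions

Thresholds run over τ = 0.01…0.17 in steps of 0.01 and are applied directly
to stage-B values (Fisher-z scale), with `|b| ≥ τ` keeping its absolute
value. Path lengths use the standard 1/weight mapping. Weighted clustering
is the geometric-mean triangle-intensity form (weights scaled by the graph
maximum; nodes of degree < 2 contribute 0). Local efficiency of a node is
the global efficiency of its neighbors' induced subgraph. Characteristic
path length averages finite shortest paths over ordered pairs; disconnected
pairs contribute efficiency 0 and are excluded from the path-length mean.
Global efficiency is reported as the mean of inverse distances (the
Latora–Marchiori form), which equals the reciprocal of the harmonic-mean
path length rather than 1/λ exactly; the two agree on the canonical
closed-form test graphs.

Hemispheric summaries average nodal values over each hemisphere's channels
*on the full graph*, preserving cross-hemispheric neighborhoods; a
hemisphere-subgraph mode would discard them.

Random references are Maslov–Sneppen degree-preserving rewirings (10 swap
attempts per edge) of the binary skeleton with the original weight multiset
randomly reassigned to the rewired edges. The normalization constant
`M_rand` is pooled over all random graphs of all subjects of a group — a
group-level normalization; per-subject normalization is available but the
pooled form is the default. The small-world index is
σ = γ_norm/λ_norm with whole-graph clustering.

The validated sparsity range requires group-mean minimal degree ≥ 1 and mean
normalized γ > 1, with normalized λ > 1 additionally required unless the
small-network fallback (γ exceeding its random reference) is accepted — the
default, appropriate for 50-node networks. AUCs are trapezoidal integrals
over the grid.

Shortest-path and local-efficiency kernels are compiled (Rcpp): local
efficiency requires all-pairs paths on ~50 induced subgraphs per graph, and
the metric stage evaluates tens of thousands of graphs once random
references are included.

# Statistical decisions

Edgewise inference uses 2000 unpaired permutations of a pooled-variance
two-sample t statistic, the *same* permutation sequence for all 1,225 edges
(preserving the cross-edge dependence of the null), and the add-one p-value
convention `p = (#{|t*| ≥ |t|} + 1)/(B + 1)`, making 1/2001 the smallest
attainable p. Edges are tested at uncorrected α = 0.05; an FDR option exists
but is off by default, mirroring exploratory edgewise practice. An
exhaustive mode enumerates all group splits for small cohorts and is tested
against direct enumeration.

Subgroup maps standardize patient residual matrices by the control-group
edgewise mean and SD; ±2 SD masks are disjoint by construction.

The moderation model is `AUC ~ IQ_c * group` with IQ centered on the pooled
mean and scaled by 15 (one IQ SD), group coded control = 0 / epilepsy = 1.
Partial η² uses the single-coefficient form t²/(t² + df). Simple slopes come
from the coefficient covariance: the control slope is the IQ coefficient;
the patient slope adds the interaction, with its standard error from the
full covariance. Clinical correlations use Pearson for continuous factors
and Spearman for coded categorical factors (FLE = 0/TLE = 1; left = 0/
right = 1/bilateral = 2; seizure control yes = 1/no = 0).

# Numerical choices and degenerate inputs

* Fisher transform clips |ρ| = 1 to 1 − 1e-7 with a warning.
* Zero age variance or fewer than 3 subjects: stage B = stage A, warned.
* Zero-variance edges are skipped in permutation tests (p = NA) and flagged
  undefined in z maps.
* Empty graphs at a threshold mark all metrics invalid at that τ; AUCs
  integrate the contiguous finite part of the profile and need at least two
  valid grid points.
* `M_rand = 0` invalidates the corresponding normalized metric.
* All stochastic stages derive their seed from a master seed and a stage
  label; equal seeds give bit-identical outputs end to end.

# Problem sizes used in validation

The test-suite and acceptance computations run at the study's native signal
scale (50 channels, 7.8 Hz, 720-s conditions, 200 × 60-s bootstrap windows,
2000 permutations) for the stages where those numbers are the point, and at
reduced cohort sizes elsewhere: parameter-recovery and calibration loops use
20 generator seeds, 200 simulated cohorts for the moderation analyses, two
50-node subjects with 30–50 random references per threshold for the
small-world checks, and a 6-subject cohort for the end-to-end pipeline
smoke test. These sizes give Monte-Carlo error comfortably inside the
asserted bounds while keeping the whole suite fast enough to run routinely.

# Known limitations

* The PARAFAC rank is fixed (default 3) rather than selected per interval;
  rank selection by explained-variance gain is straightforward but the
  correction already leaves residuals far below the artifact scale.
* The cardiac-coherence threshold is absolute (0.1); an adaptive threshold
  tied to the independence floor would behave better on very short records.
* Group-level `M_rand` pooling means a subject's normalized metrics depend
  on their group's other members; per-subject normalization is available as
  a config choice where independence matters.
* The generator's artifacts are archetypes (bursts, steps, ramps); detector
  sensitivity on real pediatric motion artifacts will depend on their
  spectral content.
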