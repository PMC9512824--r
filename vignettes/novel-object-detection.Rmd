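---
title: "Center-surround receptive fields as novel-object detectors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Center-surround receptive fields as novel-object detectors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinovel)
```

`retinovel` studies one computation from several angles: a stimulus moving
continuously through the visual scene enters a neuron's antagonistic
surround long before it reaches the excitatory center, so by the time the
center is driven, surround inhibition is already developed; a stimulus that
appears abruptly — flashed, or emerging from behind an occluder — engages
center and surround together and is answered with a larger, faster response.
This vignette documents the models, the choices behind every tunable
parameter, what the synthetic data emulate (and do not), and the numerical
conventions, so that results produced with the package can be interpreted
and reproduced.

## 1. The outer-retina circuit model

`run_opl_simulation()` integrates a one-dimensional array (default 150
cells at 10 µm, i.e. 1500 µm) of four interacting populations at a fixed
1-ms step. The temporal update constants (60, 400, 300, 50, 80 ms) are
per-millisecond divisors of literal difference equations; we deliberately do
not offer dt rescaling, because the model is defined by those difference
equations rather than by an underlying ODE.

*Photoreceptors* respond to the combined light/feedback drive with a
difference of two first-order activation functions (decay 60 and 400 ms,
weight 0.8 on the slow one), producing the characteristic biphasic
waveform: a fast trough, relaxation to a sustained level of 20 % of the
drive, and a rebound of opposite sign when the stimulus leaves.

*The drive* combines the visual input (`E_VS = −10` mV per unit stimulus;
light hyperpolarizes) with horizontal-cell feedback divisively:

```
drive_i = gain · (E_HC · h̄_i + E_VS · VS_i) / (|h̄|_i + VS_i + 1)
```

where `h̄` is the HC signal averaged under the 300-µm HC kernel and
normalised by the kernel sum. The distance normalisation matters: with raw
kernel sums the feedback term is amplified by the kernel mass (≈ 32 on
this lattice), and HC activity then recruits neighbouring photoreceptors
into a self-sustaining wave that sweeps the whole array within a second and
erases every stimulus-condition asymmetry. We ship the raw form
(`photoreceptor_drive(..., normalize = FALSE)`) for comparison, but the
normalised form is the model.

*Horizontal cells* average photoreceptor output under the same normalised
kernel and relax (τ = 300 ms) toward a saturating target
`E_Ph·x/(x + E_Ph)`. Because HCs pool over ±~150 µm, they begin to respond
to an approaching bar hundreds of milliseconds before the bar reaches the
cell — the anticipatory inhibition that differentiates established from
novel motion. `hc_lead_time()` quantifies this as the interval between the
bar first covering a cell and the cell's |HC| first crossing a threshold
fraction of its eventual peak. The threshold is a free parameter (no
physiological definition of "initiation" exists); at the default 10 % the
maximal lead at default parameters is 266 ms, at 20 % about 130 ms, at
25–30 % about 100 ms. We report the 10 % value and expose
`threshold_frac`.

*Bipolar cells* receive the photoreceptor signal through a sigmoidal
synapse, baseline-subtracted so rest maps to zero. The sigmoid operates on
the light-response amplitude `−Ph` (photoreceptors hyperpolarize to light;
ON bipolar cells depolarize). This sign convention is a deliberate design
decision: applied to the signed, light-negative `Ph`, the transient
parameterisation (`V_½ = 4 mV`, slope 1.1 mV⁻¹) sits in the sigmoid's
saturated tail, every light response is capped at `σ(0)`×kernel mass, and
transient cells come out *less* transient than sustained ones — the
opposite of the physiology the parameters encode. With the inverted input,
`V_½` lies just above the peak photoreceptor light response, the transient
population operates in the sigmoid's exponential regime, and small
differences in peak photoreceptor output (exactly what surround priming
modulates) are amplified into large response differences. The signed form
remains available (`form = "as_printed"`). Synaptic activation relaxes with
τ = 50 ms and is converted to membrane potential by a resistive-divider
expression in which amacrine input (reversal 0 mV) acts as pure shunt.

*Amacrine cells* (optional, off by default) are driven by a separate
"driver" BC population (slope 2 mV⁻¹, `V_½` 4 mV) through a second sigmoid
(gain 1, slope 1.5 mV⁻¹, `V_½` 7 mV), relax with τ = 80 ms, and feed a
distance-normalised shunt back onto the transient/sustained BCs. Setting
the gain to zero is bit-identical to disabling the circuit.

At the defaults, the battery built by `opl_battery()` (2-s full-field
flash, 1-mm bars at 0.5 mm/s, 300-µm masks at both array ends) yields at a
near-edge transient BC: emerging ≈ 24 % larger than exiting motion,
emerging > continuous, exiting ≈ continuous, flash > continuous, and a
larger enhancement in transient than sustained cells. Silencing HCs
(`hc_enabled = FALSE`) flattens photoreceptor peaks across all conditions
to within 1 %.

## 2. The linear center-surround population

Each unit has Gaussian center and surround weighting functions with half
widths 50 and 200 µm. "Half width" is read as half-width at half-maximum
(the weight is exactly 0.5 at the stated distance); a `halfwidth_mode`
switch provides the FWHM reading. Both kernels are normalised to unit mass
on the pixel lattice, each component low-pass filters its own illumination
(τ = 20 ms center, 100 ms surround, 1-ms steps), and the output is

```
RF_full = RF_center − factor_surround · ρ · RF_surround
```

with `ρ = surround_weight_ratio = 2` the integrated surround:center weight.
The ratio is the one genuinely open structural convention in the model, and
we fix it by behaviour: with `ρ = 1` (equal integrated weights) the
difference of Gaussians retains at least a fraction `1 − f` of any
extended scene at every surround factor `f < 1`, so continuous scene motion
is never cancelled, novel objects gain no relative salience at any factor,
and none of the novelty phenomenology appears. With `ρ = 2` the DoG
balances (zero DC gain) exactly at the operating factor 0.5, extended
scenes and established motion are nulled while object-scale features pass,
and the full phenomenology — novelty information, its interior maximum in
the surround-strength sweep, the ~100-µm spatial focus — follows. Responses
are linear and unrectified; peak extraction uses the signed maximum, and
only the information-theoretic readout rectifies at zero (peak amplitudes
are defined on a 0–255-derived scale).

Population simulation uses a separable-convolution fast path plus a small
compiled kernel for the temporal recursion and windowed peak extraction;
`rf_illumination()`/`step_rf()` are the reference single-unit forms and the
test suite checks the fast path against brute-force double loops.

## 3. Naturalistic movies and the novelty ensemble

`novelty_ensemble()` renders, per trial, three conditions of one scene
(100 × 100 pixels at 10 µm, 20-ms frames, 1.6 s):

- **masked** — the background streams horizontally at 0.5 mm/s behind a
  static occluder covering the left half of the scene; a textured object
  emerges from behind the occluder's silhouette and crosses the scene at
  1 mm/s;
- **flow** — the identical streaming background with no occluder and no
  object (the input generated by continuous motion of the entire scene);
- **unmasked** — the identical object trajectory with the occluder removed,
  so the object arrives at each cell as established motion.

The mutual-information analysis asks how well a single cell's peak response
(500-ms window from the moment the visible object first reaches the cell;
the same windows applied to the object-free flow trial) discriminates
"novel object appeared" (masked) from "the scene is simply moving" (flow).
The enhancement-versus-distance profile instead contrasts masked with
unmasked — the same object seen as novel versus established — which
isolates the surround-priming transient and decays over roughly the
distance the object travels in one surround time constant plus a center
width (~100 µm).

Generator choices, fixed once (the stated 8-bit statistics — background and
occluder scaled to mean 128, SD 30; object pixel mean 2 SD above — are
constraints, not choices):

- *Texture family*: sums of Gaussian-smoothed noise at octave scales (SD 2,
  5, 12, 30 px) with amplitude proportional to scale — a red, roughly 1/f²
  spectrum, the canonical natural-image statistic. Most luminance variance
  therefore lives in large structures, which the center passes (so a +2 SD
  object is not an amplitude outlier for a center-only unit) and a balanced
  DoG cancels.
- *Marginal*: a lognormal-like transform (skew 0.8) plus 0–255 clipping
  reproduces the bright heavy tail of natural 8-bit frames.
- *Object*: a 300-µm disc envelope with a patchy silhouette (50 % fill at
  30-µm grain) and its own multi-scale texture; each trial draws a new
  instance ("different predator frames"), while `fixed_stimulus = TRUE`
  reuses one. Object speed 1 mm/s — predators move relative to the flow;
  the value also sets the emergence abruptness and, through `v·τ_surround`,
  the width of the novelty zone.
- *Occluder*: silhouette boundary at x = 500 µm with smooth ±30 µm per-row
  jitter, flattened across the object's trajectory rows so the emergence
  time and site are analytically exact.
- *Pairing*: all three conditions of a trial share one wide background
  field; across trials the background and silhouette are redrawn ("
  permutations of the background"). Each trial's center and surround
  activations are computed once and reused for every surround factor.

What the generator does **not** emulate: real scenes' object semantics and
occlusion depth ordering, luminance clipping correlations, eye/head
kinematics beyond uniform translation, and — important for interpreting the
information numbers — the full heavy-tailed local-contrast statistics of
natural footage. In our texture family a +2 SD object retains some residual
amplitude information that a center-only unit can read (≈ 0.4 bits at 1000
paired trials), where real movies make it amplitude-confusable (reported
≈ 0.08); correspondingly the center-surround MI here is ≈ 0.53 bits rather
than ≈ 0.7. The *structure* of the result — information carried by the
center-surround configuration, rising with surround factor to a maximum at
0.4–0.6 and collapsing beyond balance; enhancement confined to ~100 µm
around the emergence site; flat center-only profiles — reproduces at the
stated study conditions, and those are the claims the test suite asserts.

Problem sizes: the acceptance analyses use 1000 paired background
permutations (the stated ensemble size) with factors {0, 0.5}; the
surround sweep reuses one ensemble evaluated on an 11-point factor grid.
A 1000-trial, 11-factor ensemble takes roughly 7–8 minutes on one CPU.

## 4. Response metrics

The transiency index is `TI = 1 − mean/peak` within the stimulation
window. The verbal definition of TI as a peak-to-mean *ratio* conflicts
with the convention that sustained plateaus score near 0 and sharp
transients near 1; `1 − mean/peak` satisfies that convention, and the raw
ratio is available via `form = "peak_over_mean"`. Edge enhancement and
emerging-object enhancement are the peak ratios minus one; the
direction-selectivity index is the normalised vector sum of
direction-tagged peaks. RF position comes from half the difference of the
50 % rise times of opposed motion trials times speed; the 50 % rise time is
measured model-free by linear interpolation (robust), with the 4-parameter
logistic fit of the rising phase and the single-exponential decay fit
(`minpack.lm`) reported separately. Responses are classified full-field
(nearest edge ≥ 100 µm), near-edge (< 50 µm) or intermediate (excluded).

## 5. The imaging pipeline and its ground truth

Preprocessing averages protocol repeats, bins 2 × 2, low-pass filters at
20 Hz (2nd-order Butterworth, zero-phase; fluctuations are filtered about
each pixel's mean to avoid zero-state edge transients on the large DC
offset) and converts to dF/F against each condition segment's pre-stimulus
baseline. Pixels with maximal dF/F > 20 % enter primary clustering:
feature vectors are the concatenated 1-s windows around stimulus entrance
(one per condition), distances are 1 − Pearson correlation (amplitude-
robust; Euclidean optional), groups come from maximin-seeded farthest-point
clustering with a distance-threshold stopping rule, and spatially
4-connected components become ROIs. ROIs whose member-pixel coefficient of
variation (mean over in-window timepoints of across-pixel SD over |mean|,
over timepoints with non-negligible mean) exceeds 1 are discarded — the
threshold is strict, so a ROI at exactly 1 is kept.

Secondary clustering pools curated ROIs and groups their 1-s full-field
flash waveforms by average-linkage hierarchical clustering; the cluster
count minimises the c-index within plausibility bounds (default 3–15,
encoding the rejection of implausibly small or large counts). One numerical
subtlety is handled explicitly: once clusters are pure, every further cut
of the tree also consists of the globally smallest distances, so the
c-index curve falls to an exactly flat plateau and cannot distinguish cuts
within it. Ties within 5 % (of the curve's range) of the minimum are
therefore resolved by mean silhouette width, which penalises both merged
and over-split solutions.

The synthetic generator gives this pipeline a complete ground truth:
kinetic templates (sigmoid rise × exponential relaxation to a plateau,
exponential decay after offset) spread over rise 40–320 ms, latency
0–150 ms, slope 8–55 ms, decay 80–700 ms, plateau 2–90 % and amplitude
0.5–1.5 dF/F. Because functional types must be distinguishable within the
1-s analysis window for "k types" to be a well-posed ground truth, the
template generator keeps the most separated of up to 60 seeded draws
(target: maximum pairwise waveform correlation ≤ 0.85). Rendered movies add
per-ROI kinetic heterogeneity (2 % SD — types are families of similar, not
identical, cells) and white pixel noise in dF/F units; motion conditions
shift onsets by RF position over bar speed and apply per-template motion
modifiers, so motion-versus-stationary kinetics differences are a
controlled ground truth rather than an emergent artifact. Under these
conditions the full pipeline recovered the true cluster count and
membership (ARI ≥ 0.9) in 17 of 18 seeded runs across k ∈ {3, 5, 8}.

## 6. Numerical conventions and degenerate inputs

Bar movies use background 0 with bar amplitude equal to the contrast value
(the amplitude actually fed to the models is a modelling unit; the display
contrast ±60 % does not translate into model units, and the circuit's
divisive drive makes its outputs nearly amplitude-invariant). Naturalistic
movies use the 8-bit 0–255 scale. Spatial coordinates are 0-based sample
positions in µm; mask extents are half-open `[start, end)`. Movies include
a 200-ms pre-stimulus baseline by default; the linear-RF fast path starts
each component at its first-frame illumination (adapted to the initial
scene), while `simulate_rf_population()` defaults to zero initial state.
Leftward bars are exact lattice mirrors of rightward bars, so mirrored
stimuli produce bit-mirrored simulations. Degenerate inputs are flagged
rather than silently handled: zero peaks make TI/DSI undefined (`NA` with a
warning), flat or monotone traces set `fit_ok = FALSE`, empty emergence-cell
sets and empty grids are errors, and an empty mask region is a warning
no-op.

## 7. Known limitations

The circuit model is one-dimensional, noise-free and has a single HC type
with fixed kernels; it is a mechanism demonstrator, not a fitted retina.
The HC-lead magnitude depends on the initiation threshold, which has no
physiological definition. The linear population has no output nonlinearity
or noise, so its information numbers are upper bounds for a linear readout
of noiseless responses, and their absolute values depend on the synthetic
scene statistics as discussed in §3. The imaging generator produces
additive white noise (no shot-noise scaling by default, no motion
artifacts, no neuropil contamination), and the c-index plateau tie-break,
while principled, is a convention; both are recorded in the outputs.
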