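---
title: "Methods: simulating and evaluating single-position ECG detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating single-position ECG detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Conventional electrocardiography needs at least two body-surface contacts:
a detection electrode and a reference, separated by centimetres to tens of
centimetres. A charge-induction sensor can instead read a signal at a
*single* position, with no distant reference — at the price of a waveform
that no longer looks like a textbook ECG. This package asks, on simulated
data, whether such a single-position trace still carries the information
that matters for ambulatory monitoring: the beat-to-beat rhythm. It does so
with two instruments: a forward simulation of a heart–torso phantom that
produces both kinds of surface trace, and a synthetic measurement campaign
(paired recordings plus a posture protocol) evaluated with a heart-rate
correlation pipeline.

# The cardiac phantom

## Dynamics

Tissue electrophysiology is modelled with the two-variable FitzHugh–Nagumo
reaction–diffusion system on a 2-D grid. In active cardiac tissue,

$$
\frac{\partial u_1}{\partial t} = \nabla \cdot (D \nabla u_1)
  + u_1\,(u_1 - \theta)\,(\alpha - u_1) - u_2, \qquad
\frac{\partial u_2}{\partial t} = \epsilon\,(\beta u_1 - \gamma u_2 - \delta),
$$

where $u_1$ is the action potential, $u_2$ the gate (recovery) variable,
$\alpha = 1$ the excited root of the cubic, $\theta$ the threshold root,
and $\epsilon$ the region excitability. Passive regions (torso, lungs,
blood chambers, electrode layer) carry no source: $u_1$ only diffuses
through them. The fibrous barrier does not conduct at all ($D = 0$).
All quantities are dimensionless.

The reference parameter set is $\beta = 0.5$, $\gamma = 1$, $\delta = 0$,
with per-region excitabilities (sinoatrial node 0.003; atria and
atrioventricular node 0.015; His bundle and bundle branches 0.01; Purkinje
fibers and ventricles 0.005) and diffusion coefficients (torso and lung
0.2; nodes, His bundle, branches and ventricles 0.1; atria 0.15; Purkinje
0.3; blood chambers 0.7; electrode layer 0.2). These are the defaults of
`dynamic_params()` and appear literally in
`inst/extdata/default_config.yaml`.

**Threshold root.** The default is $\theta = 0.1$. A cubic with roots
$\{0, \theta, 1\}$ and these excitabilities produces a reaction force of at
most $\approx 0.12$; at $\theta = 0.15$ that force leaves essentially no
ignition margin where the conduction tree changes calibre (His bundle into
the branches, branches into the Purkinje layer): the wave stalls at the
junction while the recovery variable accumulates, and conduction dies.
$\theta = 0.1$ — a conventional choice for this model family — restores a
robust, grid-independent margin at every junction while leaving the resting
state and the excited state unchanged. The threshold remains configurable
globally and per region.

## Geometry

The phantom is drawn in *physical units* on a fixed $50 \times 50$-unit
square, so refining the grid refines the discretisation without changing
the tissue ($h = 50/\mathrm{rows}$; the default grid is $150 \times 150$,
the test suite mostly uses $100 \times 100$). The torso fills the domain —
its rectangle corners are the "vertices" used for electrode placement —
with two elliptical lungs, and a heart ellipse whose upper half is atrial
and lower half ventricular tissue. A 1-unit fibrous band separates the two;
the only bridge is a $2\times2$-unit atrioventricular node. From the node a
His bundle (2 units wide) descends into a horizontal band of bundle
branches, wrapped in a one-cell insulating sheath so the tree does not leak
into the working myocardium; the sheath opens at a thin Purkinje layer in
full contact with the ventricles below. Each half-heart contains a passive
blood chamber, and an optional ~1-unit electrode layer wraps the torso.
`validate_phantom()` enforces the topology: every region present, no direct
atria–ventricle adjacency, and a contiguous conduction chain
SA → atria → AV → His → branches → Purkinje → ventricles.

Junction calibres matter: in prototype sweeps, bands one cell thinner (or a
Purkinje layer contacting the branches over a small patch rather than their
full length) failed to ignite at fine grids even though they worked at
coarse ones — a reminder that source–sink balance at calibre changes, not
plane-wave propagation, is the fragile part of conduction-system models.

## Discretisation and time mapping

Explicit Euler with a 5-point Laplacian; face diffusivities are harmonic
means of the two adjacent cells, so any face touching non-conducting tissue
carries no flux, and the outer boundary is zero-flux. The scheme is stable
for $\Delta t \le h^2 / (4 D_{\max})$; `step_field()` and
`run_simulation()` refuse larger steps by name. By default the step is the
largest value that divides the recording interval while staying under 90%
of the bound. The zero-flux Laplacian conserves the total $u_1$ of a
source-free sheet to rounding error, which the tests verify.

The model time unit is mapped to seconds by the stimulation protocol: one
stimulus period (default 1000 time units) corresponds to one cardiac cycle
(default 0.8 s, i.e. 75 beats per minute, inside the normal sinus range of
60–100). The sinoatrial node is driven by a periodic suprathreshold pulse
(amplitude 0.5, width 5 time units) because the reference parameters are
not self-oscillatory. Output traces are sampled at 500 Hz of mapped time.
Activation times are read as the first upward crossing of 0.5 by the
region-mean $u_1$, linearly interpolated between samples; a mid-amplitude
crossing is insensitive to the discretisation.

## Surface traces: two probe models

The two detection modes are modelled by two different functionals of the
same field, reflecting the physics of the sensors:

* **Conventional differential lead.** A distant amplifier referenced to a
  second electrode responds to the instantaneous volume currents of the
  heart. Each probe point therefore records a quasi-static volume-conductor
  potential: the sum over cardiac cells of the impressed current
  $\nabla\cdot(D\nabla u_1)$ weighted by the 2-D logarithmic kernel
  $-\ln(r)/2\pi$ (regularised at one cell). The lead is the detection-point
  trace minus the reference-point trace, mean-removed. This produces the
  familiar separated P, QRS and T deflections.
* **Single-position trace.** A charge sensor with no reference integrates
  the charge induced at its contact; this is modelled as the raw diffused
  $u_1$ at the electrode-layer cell touching the torso, mean-removed. The
  passive medium acts as a strong spatio-temporal low-pass
  ($\tau \sim L^2/4D \approx 10^2$ time units at torso distances), so the
  trace is a smooth wave-like oscillation per cycle with little
  high-frequency content — the qualitative signature of single-position
  detection.

A point-potential model for the *differential* lead was tried first and
rejected: at any feasible probe distance the diffusive smearing merges P,
QRS and T into one slow hump, because the event separations are bounded by
conduction times and the ventricular action-potential duration while the
smearing grows with distance squared.

# The synthetic measurement campaign

The volunteer recordings that a device study would analyse are emulated by
`synthetic_data` generators; every generator is a pure function of its
arguments including the seed.

* **Rhythm.** Beat-to-beat intervals are i.i.d. normal, truncated to
  (0.2 s, 3 s), with defaults of 70 bpm mean and SDNN 0.03 s — an ordinary
  resting sinus rhythm with mild variability. No autocorrelation structure
  (respiratory sinus arrhythmia, trends) is modelled.
* **Morphology.** Each beat is a sum of Gaussians. The conventional channel
  uses five components (P 0.12 at −180 ms, Q −0.10 at −35 ms, R 1.00 at 0
  (σ 12 ms), S −0.25 at +35 ms, T 0.30 at +280 ms); the single-position
  channel uses two broad lobes (0.35 at −20 ms, σ 35 ms; −0.22 at +120 ms,
  σ 70 ms), giving the smooth, visibly smaller waveform of the
  single-electrode sensor. Morphology is identical across beats.
* **Noise.** Output = clean + drift + powerline + white noise. Drift is a
  sum of eight random sinusoids in 0.02–0.45 Hz scaled to a preset standard
  deviation; powerline is a 50 Hz sinusoid; the white-noise vector is
  rescaled so the ratio of clean power to white power hits the preset SNR
  exactly, making the ground truth exact by construction. Posture presets:
  sitting 20 dB (drift sd 0.15), office/turning/stepping 12 dB (drift 0.30
  / 0.50 / 0.70), `low_drift` 20 dB with drift 0.03 (the modified electrode
  whose on-board reference point removes drift), `clean` disables
  everything. The dynamic four-posture protocol is performed with the
  modified electrode, so `synthesize_dynamic_recording()` scales the preset
  drift by 0.2 by default (set `drift_scale = 1` for the raw sensor).

What is *not* emulated: beat-shape variability and ectopy, impulsive
motion artifacts and electrode contact loss, muscle noise, and
autocorrelated heart-rate variability. Passing the synthetic evaluation
therefore shows that the pipeline recovers rhythm information from a
wave-like, drift-prone, noisy channel under stationary interference — not
that it survives every artifact class of real ambulatory data.

# The evaluation pipeline

**Filtering.** Two arms, matching the measurement protocol: 0.5 Hz
high-pass for the raw one-electrode signal (strongly drift-prone) and
0.25 Hz for the modified electrode, both followed by 50 Hz and 100 Hz
notches and a 100 Hz low-pass. Stages are order-4 Butterworth (notches:
biquads with Q = 30) applied forward–backward, so the chain is zero-phase
and R-peak timing is untouched; the single-pass magnitude is queryable
with `chain_response()`. Signals must exceed three transients of the
slowest stage.

**Beat detection.** Pan–Tompkins-style: 30 ms moving-average conditioning,
differentiate, square, 150 ms moving-window integration, adaptive threshold
(2 s running median plus 3 MAD, with a relative amplitude gate), local-max
refinement on the conditioned trace with a 3-point parabolic vertex, and a
200 ms refractory period. Differentiating the *conditioned* trace matters:
the smooth single-position lobe has a slope of only a few units per second,
which wideband noise at 12 dB would otherwise bury. All decision statistics
are ratios, so detection is invariant to gain and DC offset. Sub-sample
peak times matter too — at 500 Hz, integer sampling alone contributes
~0.2 bpm of quantisation error to instantaneous rate.

**Heart-rate graphs.** With inter-peak distance $n$ samples and sampling
interval $T$, the instantaneous rate is $F_{HR} = 60/(nT)$ bpm, stamped at
the interval's end peak; values outside (20, 300) bpm are discarded as
detection artifacts. Two curves are compared after linear resampling onto a
shared uniform 1 s grid over their overlap: Pearson correlation, and the
absolute deviations of the curve maxima and minima.

**SNR estimation.** Beats are windowed from 35% of the median inter-peak
distance before each peak to 45% after it (neighbouring beats stay outside
the window under rhythm variability), linearly detrended (residual drift),
and ensemble-averaged. Signal power is the template power; noise power is
the residual power after projecting out each beat's component along the
template derivative — first-order alignment error, which would otherwise
masquerade as noise — with degrees-of-freedom corrections for the template,
the detrend and the projection. On white-noise-only corruption at 20 dB the
estimator is unbiased to within a fraction of a decibel; on filtered
recordings it reads the in-band SNR, which exceeds the broadband ground
truth because the chain removes out-of-band noise.

**Signal-quality screening.** Non-overlapping 10 s windows are flagged as
unrecognizable when the detected beat count implies a rate outside
20–300 bpm, when the inter-peak intervals do not show a coherent rhythm
(fewer than five intervals, or a coefficient of variation of 0.5 or more —
a handful of stray detections is not rhythm evidence), or when the window
RMS departs from the median window RMS by more than a factor of ten.

# Problem sizes, determinism, degenerate inputs

The shipped analyses use 5-minute paired recordings at 500 Hz (≈350
beats), an 8-minute four-posture recording, and phantom runs of 2.4–60 s
of mapped time at $100\times100$ to $150\times150$; a 60 s run of the
default phantom takes a few minutes on one core via the compiled kernel.
Every stochastic step takes an explicit integer seed and restores the RNG
state afterwards, so identical configurations give byte-identical CSV
outputs and reports. Degenerate inputs fail loudly and descriptively:
grids under $100\times100$, missing or disconnected regions, steps beyond
the stability bound, probes off their tissue, empty RR sequences,
too-short signals for a filter transient, cutoffs at or beyond Nyquist,
zero-variance heart-rate curves. An all-zero signal yields an empty peak
train with a warning flag rather than an error, and a run whose ventricles
never activate returns a flagged recording rather than throwing.

# Known limitations

The phantom is a 2-D qualitative analogue: amplitudes and absolute timings
are not calibrated to millivolts or milliseconds, repolarisation gradients
(hence concordant T waves) are not modelled, and only sinus rhythm is
produced — no arrhythmias. The synthetic campaign omits the artifact
classes listed above, and the SNR presets treat interference as stationary
within a posture. The correlation evaluation assumes both channels observe
the same heart; it quantifies rhythm agreement, not diagnostic morphology
fidelity, which single-position detection by design does not preserve.
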