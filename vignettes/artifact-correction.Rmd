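---
title: "Model-based stimulation-artifact correction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based stimulation-artifact correction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccepclean)
```

## The physical model

Direct electrical stimulation injects a square current pulse between two
intracranial contacts. What the recording amplifier sees is shaped by the
electrode–tissue interface, which `ccepclean` approximates as a series RC
circuit: the capacitance summarizes interfacial (double-layer) capacitive
effects, the resistance the passive resistivity of brain tissue. The
recorded artifact is the resistor voltage,

$$\frac{du_c}{dt} = \frac{u_i - u_c}{RC}, \qquad u_R = u_i - u_c,$$

with $u_i$ the pulse (monophasic, or biphasic split into two equal
opposite phases over the stated total duration) and $u_c(0) = 0$. Because
the input is piecewise constant, the solution is available in closed form
per segment, $u_c(t) = A + (v_0 - A)e^{-t/RC}$, which `ccep_artifact()`
evaluates exactly at the sample points with $u_c$ continuous across
segment boundaries. A numerical integrator exists in the test suite purely
as an independent oracle; the shipped solver has no step-size parameter.

This is deliberately a minimal interface model. Constant-phase elements
and Faradaic impedances describe real interfaces more faithfully, but at
clinical sampling rates (256–2048 Hz) the recorded artifact is so heavily
under-sampled that the extra structure is not resolvable; the RC family
already spans the observed shapes when $RC$ sweeps $10^{-6}$–$10^{-2}$ s.

Physical amplitude is deliberately dimensionless (template amplitude 1):
the mapping from injected current to recorded microvolts depends on
geometry and hardware and is absorbed by the per-stimulation regression
coefficient.

## The template bank

Recording and stimulation clocks are generally unsynchronized, so each
pulse lands at an arbitrary sub-sample phase of the acquisition grid and
the sampled artifact differs from pulse to pulse. `ccep_bank()` makes this
degeneracy explicit: each template, simulated at a 50 kHz master rate, is
decimated to the recording rate at every integer master-sample offset
within one recording sample (`round(fs_high / fs_target)` shifts; for
non-integer rate ratios the source index of output sample $j$ is
`round(shift + j * fs_high / fs_target)`, bounding the accumulated phase
error by half a master sample). Decimation is pure sample selection — no
anti-alias filter — because the bank must reproduce exactly the aliased
shapes the acquisition produces, not a smoothed version of them. The
default RC grid is log-spaced at 10 points per decade (41 values); the
grid range is physically motivated, the density a resolution/cost
compromise exposed as a parameter.

## The correction

Per stimulation and channel, every bank variant is compared to the
recording by ordinary least squares (slope plus intercept) over a window
of 1.2 pulse durations, at least 3 samples. The window is kept this short
on purpose: the pulse portion of the signal is far less likely to contain
physiological response energy than the slow capacitive decay, which is
exactly what an early response looks like. The intercept absorbs local
baseline offset; only the scaled template is subtracted, never the
intercept.

Three nested selections follow, and their design deserves explanation:

* **Alignment (shift and onset offset) per stimulation** is chosen by the
  in-window residual. Event onsets are nominal; because of clock phase,
  the first artifact-bearing sample can sit one sample off, so offsets
  $\{-1, 0, +1\}$ around each onset are searched (`onset_search`).
* **The RC value per channel** is chosen by the residual power of the
  scaled template over its *full* support (pulse plus tail), summed over
  the stimulation run. A 3-sample window fitted with 2 parameters retains
  a single residual degree of freedom and is compared across hundreds of
  candidate alignments; its minimum is pure selection noise and cannot
  discriminate time constants. A wrong time constant, however, mispredicts
  the capacitive tail, which the full-support residual measures directly.
  In pilot simulations, in-window-only selection mis-assigned long-tail
  channels badly enough to triple the latency-bias spread at 512 Hz.
* **A parsimony margin** (`rc_margin`, default 5 %): among RC values whose
  summed residual lies within the margin of the minimum, the smallest is
  selected. For channels whose true artifact has no appreciable tail, all
  small-RC templates explain the data equally well while a long-tail
  template can shave a few percent off the residual by absorbing part of
  the response — a classic overfitting trade that the margin resolves
  toward least intervention. Exact ties (affinely equivalent variants, an
  inherent degeneracy of decimated exponentials) are resolved the same
  way at the alignment level, using the full-support residual only within
  float-level ties.

Both methods end with a zero-phase (forward–backward) 4th-order
Butterworth low-pass at 90 Hz. Zero-phase filtering is essential here: a
causal filter would delay every corrected peak and corrupt the latency
estimates. The filter input is reflection-padded so that the zero initial
state of each pass does not produce edge transients. Below 180 Hz
sampling the cutoff is clipped to 0.45 fs with a warning.

The average-subtraction baseline follows common practice: per channel, the
windows of length pulse duration + 1 ms after each onset are referenced to
their first sample and averaged; the average is subtracted at each onset.
It is exact when the artifact repeats identically and fails in proportion
to pulse-to-pulse phase variability — which is the regime clinical
recordings live in.

## The simulator

`ccep_simulate()` builds data sets with known ground truth, per channel
$i$ and stimulation $s$:

$$Da_{i,s} = D_{i,s} + \mathrm{artifact}, \qquad D_{i,s} = \mathrm{response} + \mathrm{noise}.$$

Defaults describe the reference protocol: 30 channels, 5 s baseline, 40
pulses at 1 Hz, master rate 50 kHz, decimation to 256–4096 Hz, response
probability 0.5, Gaussian noise with per-channel SD uniform on 1–50 µV
(read as an SD — a variance in microvolts is dimensionally inconsistent).
Artifacts take a per-channel log-uniform RC in $[10^{-6}, 10^{-2}]$ s,
random polarity, and a log-uniform amplitude in 200–5000 µV; clinical
stimulation artifacts are of millivolt order, and the correction is
scale-equivariant, so this choice affects realism of signal-to-artifact
ratios rather than the method itself. Responses are
single raised-cosine deflections: fast channels at 50–70 Hz with peak
latencies 1–20 ms (truncated so the deflection never precedes the pulse),
slow channels at 20–50 Hz with peaks at 20–40 ms; within a channel the
cosine period jitters by less than 10 % across stimulations, across
channels period and amplitude vary widely with random polarity. Response
amplitude is partially proportional to the artifact amplitude
($\max(3\sigma_{\mathrm{noise}},\ 0.05\,A_{\mathrm{artifact}}\,u)$,
$u \sim U(0.5, 1.5)$), keeping every response detectable at three times
the background level.

Two timing choices matter:

* **Per-stimulation onset phase.** The stimulator clock is modeled as
  unsynchronized with the ADC: each pulse receives a random sub-sample
  phase on the recording grid, in addition to the per-channel decimation
  shift. Without this, pulses at an exact 1 Hz spacing would alias
  identically every time, average subtraction would be artificially
  perfect, and fitting a shift per stimulation would be pointless; the
  pulse-to-pulse irreproducibility is the phenomenon the method exists
  for.
* **Snapped reference latencies.** The expected first-peak latency of a
  channel is the true (continuous) latency snapped to that channel's
  actual post-decimation sample grid, including its random shift. A
  grid-agnostic rounding would inject a spurious half-sample bias into
  LBias that reflects bookkeeping, not correction quality.

The fraction of responding channels carrying fast responses
(`fast_fraction = 0.6`) fixes the prevalence of the early fast channels
the evaluation focuses on: with fast peaks uniform on 1–20 ms, a 20-set
study of 600 channels then contains
$600 \times 0.5 \times 0.6 \times 9/19 \approx 85$ qualifying channels
(true peak ≤ 10 ms), the mid-80s prevalence the benchmark is designed
around.

Deterministic components (artifact, response) are built at the master rate
and decimated, preserving sub-sample phase effects; the white noise is
added at the recording rate, which is statistically identical because pure
decimation leaves white Gaussian noise white with the same SD. What the
simulator does **not** model: 1/f background spectra, line noise,
epileptiform transients, amplifier saturation (common in ECoG for 5–10
ms), and response-shape families beyond windowed cosines. Passing the
benchmark therefore demonstrates correct behavior under idealized
backgrounds; on real data, saturation episodes in particular must be
flagged and excluded upstream.

## Metrics

RPower compares corrected to true signal over onset to onset + 10 ms: the
mean square of the difference divided by the mean square of the truth,
averaged over stimulations. Both signals must pass the same 90 Hz
low-pass; in-band components then cancel exactly and the numerator
isolates the artifact residual (otherwise the filtered-out part of the
noise would be charged to the correction). Stimulations with zero truth
power are excluded with a warning.

First-peak latency is the first local maximum of the absolute deflection
after onset whose amplitude reaches twice the signal SD, searched up to
100 ms (responses end by 40 ms; the margin absorbs filter ringing).
Absolute deflection, because responses may have either polarity. The SD is
estimated robustly (MAD) from the pre-stimulus baseline of the corrected
signal *before* the final low-pass: the band-limited filtered noise has a
~40 % smaller SD, and thresholding on it lets filtered noise ripples
qualify as peaks, producing spurious detections that a threshold on the
signal's own scale rejects. Channels with no detectable corrected peak on
any stimulation are flagged and excluded from summaries.

LBias is the mean over stimulations of corrected minus expected latency.
Summaries (`summarize_performance()`) report median and SD per (sampling
rate, pulse duration, method) cell over early fast-response channels (true
peak ≤ 10 ms) pooled across sets — the channels for which artifact overlap
actually threatens the latency estimate.

## Identifiability and the RC-recovery check

A time constant far below the sample period collapses the decimated
template to a one-sample spike; all such templates are affinely equivalent
within any fit window, and RC is structurally unidentifiable — no
estimator can recover it. This is the same under-sampling limit that
degrades all correction at 256 Hz (a 256 Hz recording cannot even
represent a biphasic pulse shorter than 2 ms). The parameter-recovery
check therefore draws true RC values on-grid from the identifiable regime
$RC \ge 1/f_s$ at 2048 Hz and requires 95 % of 50 noiseless channels to be
recovered within one grid step. Recovery degrades gracefully, not
catastrophically, below that regime: unidentifiable channels select some
small RC whose spike-like template is interchangeable with the truth, so
the *correction* remains accurate even where the *parameter* is not.

## Problem sizes and numerical conventions

The shipped benchmark (`run_benchmark()`, also driven by
`scripts/acceptance.R`) uses 5 simulated sets per parameter cell over
sampling rates 256–2048 Hz and pulse durations 1–3 ms with biphasic
pulses — a grid a single CPU core completes in a few minutes; the
full-scale protocol uses 20 sets per cell, and `n_sets` scales the run when
more precision is wanted. Other conventions: sample indices are 1-based
inside R and 0-based in exported JSON/event files (event files are in
seconds); decimation rounding is half-up, applied identically in the
simulator and the bank so that the bank's completeness is exact; degenerate
(constant-in-window) template variants are skipped, and a channel errors
only if every variant is degenerate; residual powers are mean squares, so
windows of unequal length compare fairly.

## Known limitations

Selection between near-equivalent sub-sample shifts is arbitrary by
nature (the variants are numerically interchangeable); consumers should
rely on the reconstructed artifact and corrected signal, not on the shift
label. At 256 Hz, early-response latencies carry a bias of roughly one
sample (~4–5 ms median in simulation) — a recording-rate limit, not a
correctable defect, and the reason for recommending ≥ 512 Hz acquisition.
Channels whose true peak falls within the fit window (1–2 samples after
onset at low rates) mix response and artifact irreducibly; they dominate
the residual spread of the latency bias. The average-subtraction method is
included for comparison, not recommendation.
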