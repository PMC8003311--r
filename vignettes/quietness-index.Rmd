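---
title: "Assessing urban quietness from spectral indices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing urban quietness from spectral indices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quietscape)
```

## The problem and the model

Quietness in a city is not the absence of sound. An urban park at dawn can
be loud with birdsong and still be exactly what noise policy means by a
"quiet area", while a sparsely used square with a steady traffic drone at
modest level is not. `quietscape` operationalizes this view with purely
spectral metrics: no sound-level-meter calibration, no perceptual survey.

A candidate area is sampled at eight edge points and one core point, one
recording per point. Two per-recording indices feed the composite:

* the **acoustic complexity index (ACI)** measures frame-to-frame intensity
  variability per frequency bin, normalized within temporal clusters. For
  cluster $j$ and bin $k$,
  $$ d_{jk} = \frac{\sum_t |I_{t+1,k} - I_{t,k}|}{\sum_t I_{t,k}}, \qquad
     \mathrm{ACI} = \sum_j \sum_k d_{jk}. $$
  Biotic sound (chirps, song) fluctuates strongly between 23-ms frames;
  traffic drone barely does. The within-bin normalization makes ACI
  invariant to global gain — a recorder-friendly property — but the total
  grows with frame count, so recordings are comparable only at equal
  duration and identical spectrogram settings. The package enforces both.

* the **normalized difference soundscape index (NDSI)** compares energy in
  an anthropophony band $\alpha$ (1–2 kHz, where traffic and machinery
  concentrate) with a biophony band $\beta$ (2–8 kHz, most songbirds):
  $(\beta-\alpha)/(\beta+\alpha) \in [-1, +1]$.

The area-level composite is
$$ \mathrm{CUQI} = \mathrm{AD} \times (\mathrm{RG}_{ACI} \times
   \mathrm{CB}), $$
with $\mathrm{CB} = \bar e / c$ the ratio of mean edge ACI to core ACI,
$\mathrm{RG}_{ACI}$ the range of ACI over all nine points, and
$\mathrm{AD} = \mathrm{sign}(\overline{\mathrm{NDSI}})$ over the nine
points. CB near 1 indicates spatially balanced complexity; CB below 1,
edges degraded by masking noise; AD keeps the sign of the dominant sound
class without affecting magnitude. Areas are ranked by descending CUQI.

### Interpreting the composite

The formula rewards a *large* complexity range scaled by the edge/core
balance. Note an inherent tension: CUQI grows monotonically with CB even
though CB far *above* 1 is itself a symptom (a complexity-poor core), and
a heavily degraded area whose biophony has collapsed entirely can have a
*small* |CUQI| because its complexity range collapses too. The package
implements the formula exactly as defined and treats the sign (AD) as the
primary qualitative statement; magnitude comparisons are most meaningful
among areas on the same side of the sign boundary and near CB ≈ 1.

## Analysis parameters

All tunables live in one `analysis_params()` object that is attached to
every survey and serialized into every output file.

| parameter | default | why |
|---|---|---|
| `analysis_rate` | 22050 Hz | Nyquist 11.025 kHz comfortably covers the 2–8 kHz biophony band; clips under 16 kHz are rejected because that band would be truncated. |
| `window_len`, `hop` | 512, 512 samples | non-overlapping ~23 ms frames, the convention of the classic R ecoacoustics toolchain, keeping values comparable with it. |
| `window` | Hamming (periodic) | see *Numerical choices*. |
| `cluster_s` | 5 s | conventional ACI temporal cluster; at least two frames per cluster are required. |
| `anthro_band`, `bio_band` | 1–2, 2–8 kHz | the operative NDSI bands for urban anthropophony vs songbird biophony (narrower than the 2–11 kHz of some NDSI variants; configurable). |
| `adi_n_bands` × `adi_band_width` | 10 × 1000 Hz | ADI/AEI occupancy grid spanning 0–10 kHz. |
| `adi_db_threshold` | −50 dB | occupancy threshold relative to the spectrogram maximum (amplitude dB). |

## Numerical choices

* **Periodic ("DFT-even") tapers.** Windows use $w[n] = f(2\pi n/N)$,
  the spectral-analysis convention, rather than the symmetric filter-design
  form. For a sinusoid centred on a DFT bin the periodic Hamming window
  confines leakage to exactly the two neighbouring bins, which makes band
  partitions clean and lets the synthetic generator place energy in a band
  *exactly* (see below).
* **Half-open bands.** `band_power()` sums squared magnitudes over
  $[f_{lo}, f_{hi})$, so any partition of $[0,$ Nyquist$)$ is additive
  with no double counting.
* **Magnitude vs power.** ACI consumes amplitude magnitudes; NDSI band
  powers square them — matching each index's source definition.
* **ACI silence floor.** Bin-clusters whose summed magnitude falls below
  $10^{-9}\times$ the spectrogram maximum count as silent ($d = 0$).
  Without this, double-precision FFT round-off (order $10^{-16}$) in
  empty bins fluctuates randomly and registers as substantial fake
  complexity on noiseless synthetic signals.
* **Degenerate inputs.** NDSI of total silence is defined as 0 (neutral)
  and flagged, keeping AD well defined; a core recording with ACI = 0 is a
  *silent-core error*, not an infinite CUQI — zero complexity signals a
  broken measurement, not perfect quietness; AD at a mean NDSI of exactly
  0 is defined as 0 (the defining ratio is undefined there, and neutrality
  avoids an arbitrary sign).
* **Unequal durations.** Clips within one survey are truncated to the
  shortest before extraction, because ACI totals scale with frame count.
* **Ties in ranking** break lexicographically by area name, making the
  ranking a deterministic function of its inputs.

## The synthetic soundscape generator

The generator exists so that every index and the composite itself can be
validated end-to-end without field recordings. It emulates three source
classes:

* **biophony** — Poisson-arriving chirp events (default 2 events/s) with
  linear frequency sweeps inside 2–8 kHz, raised-cosine envelopes of
  0.1–0.5 s and random per-event amplitude (peaks up to −20 dBFS):
  maximal frame-to-frame intensity variability, which is what ACI rewards;
* **anthropophony** — a comb of 7 constant-amplitude partials inside
  1–2 kHz (default −35 dBFS RMS, +6 dB at edge points): the
  constant-intensity drone that ACI is blind to and NDSI penalizes;
* **geophony** — white Gaussian background at −55 dBFS: the ambient floor
  every real recorder captures.

### Grid-aligned synthesis

Event frequencies are quantized to the analysis grid (bin centres of the
512-sample frame) and envelopes are stepped per analysis frame, with
frames aligned to the synthesis grid. Two consequences:

1. under the default spectrogram every tone's leakage lands in its two
   neighbouring bins, so biophony and anthropophony are band-separated
   *exactly* — the NDSI endpoints +1 and −1 are attained to machine
   precision rather than approximated; and
2. the drone's partials are spaced at least three bins apart, which makes
   every analysis frame's energy identical: a constant envelope in
   exactly the sense ACI measures (its ACI is ~0 up to the silence
   floor).

The cost is realism at the sample level (a frequency-stepped tone pulse is
a discretized chirp, with inaudible-in-analysis discontinuities at frame
boundaries). This is a deliberate trade: the generator's purpose is
controlled, exactly analysable structure, not perceptual fidelity.

### Why the ambient floor matters

Masking is what reduces *measured* complexity at noisy edges: a loud
constant drone takes over its frequency bins, replacing the fluctuating
ambient background whose variability would otherwise contribute to ACI.
In a mathematically silent background there is nothing to mask and a
band-limited drone cannot move ACI at all (the index is gain-invariant
per bin). The geophony floor is therefore on by default; the edge-masking
behaviour (CB < 1 under a strong perimeter drone) emerges exactly when
the drone is inaudible at the core (level at or below the floor) and
dominant at the edges — which is the field situation the edge/core
protocol is designed to detect.

### Scenario ladders

`scenario_ladder()` builds sequences of scenarios sharing one seed and
event pattern in which the drone level rises while chirp levels fall
(common random numbers). Along such a ladder the anthropophony band power
is strictly increasing and the biophony band power strictly decreasing,
so the mean NDSI is strictly decreasing and its sign flips exactly once —
the property the monotonicity tests assert. The rank-recovery test spans
the biophony-dominated regime through the disturbance transition; the
deep-noise regime is deliberately left to the sign/monotonicity checks,
because there the composite's magnitude is non-monotone in disturbance
(see *Interpreting the composite*).

### What passing tests do and do not show

The generator produces tonal, grid-aligned, stationary-background
soundscapes. Real recordings add broadband biotic sound (insects), wind
and rain transients, reverberation, overlapping broadband anthropophony
(which leaks *into* the biophony band), and recorder self-noise. Passing
the synthetic suite demonstrates that the indices and the composite are
implemented correctly and respond to planted structure in the designed
direction; it does not validate the ecological interpretation of CUQI on
field data, which requires ground truth the package cannot synthesize.

## Problem sizes used by the test suite

Simulation tests run at sizes chosen to give stable statistics at desk
scale: 60 s clips (the full default) for the edge-masking check, where the
effect is a few percent of CB and needs twelve ACI clusters per clip to
stand clear of sampling noise; 10–20 s clips for ladder and identity
checks; 2–5 s clips for per-clip properties. The clip duration is a
scenario field, and all defaults are stated above.

## Known limitations

* Only the fixed nine-point shape (8 edges + 1 core) is supported; other
  area geometries would need a spatially generalized CB.
* Absolute calibration is out of scope: Leq is reported relative to full
  scale (dBFS) unless the user supplies a calibration offset; linking
  recordings to sound-level-meter readings is not recoverable from files
  alone.
* The anthropophony model is strictly band-limited; real traffic noise has
  broadband skirts that depress NDSI further than the model does.
* CUQI magnitudes are comparable only between surveys analysed with
  identical parameters and equal recording durations — the package
  enforces this within a survey and records parameters in every output so
  cross-survey comparisons can be audited.
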