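---
title: "A passive-membrane model of direction selectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A passive-membrane model of direction selectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t4sim)
```

## The model

Fly T4 neurons are the first cells of the ON motion pathway that respond
to visual motion in a direction-selective way. `t4sim` simulates a
biophysically minimal account of how that selectivity can arise in a
*purely passive* dendrite: no voltage-gated channels, only synaptic
conductances acting on an isopotential membrane patch,

$$V_m \;=\; \frac{E_{exc}\,g_{exc} + E_{inh}\,g_{inh}}
                 {g_{exc} + g_{inh} + g_{leak}},$$

with all conductances expressed relative to the leak and all voltages
relative to the leak reversal. Two algebraic facts drive everything
else:

* **Two excitatory inputs always sum sublinearly.** Each added
  conductance also loads the membrane, so the response to both inputs
  together is smaller than the sum of the individual responses
  (`response_exc_exc()`).
* **Excitation paired with *release from inhibition* sums
  supralinearly.** If the second input does not excite but *withdraws*
  a tonic inhibitory conductance ($g_{inh} = 1 - y$), the withdrawal
  raises the input resistance and thereby amplifies concurrent
  excitation. For drives $0 \le x \le 1$ and $|E_{exc}| > |E_{inh}|$
  the nonlinear response component is strictly positive
  (`response_exc_inh()`).

The motion detector wires this mechanism retinotopically. Each
rightward-preferring unit reads three horizontally adjacent points of
visual space, 4.5 degrees apart:

* **left / preferred side** — an OFF-centre, slow cell (Mi9 role): the
  low-pass filtered (50 ms) signal of *one minus* luminance, driving an
  inhibitory conductance. A bright edge arriving from the left
  *releases* this inhibition just before the central excitation
  arrives: preferred direction enhancement (PDE).
* **centre** — a fast, transient ON cell (Mi1/Tm3 role): the high-pass
  filtered (250 ms) luminance plus a 10% DC fraction, rectified at 0,
  driving the excitatory conductance.
* **right / null side** — a slow ON cell (Mi4 role): the low-pass
  filtered (50 ms) luminance, driving an inhibitory conductance. For
  null-direction motion its delayed inhibition coincides with the
  central excitation and shunts it: null direction suppression (NDS).

Blocking the left arm leaves an NDS-only detector, blocking the right
arm a PDE-only detector (`detector_variants`); comparing the three
variants is the point of the experiment battery. The population readout
mimics a lobula plate tangential cell: every unit's voltage is
rectified at 0 mV and averaged across the 38 x 40 array.

## Parameters and study conditions

All defaults are the constants of the modelled study and are not meant
to be tuned:

| parameter | value | meaning |
|---|---|---|
| movie geometry | 200 x 200 px, 1000 frames | 180 x 180 deg, 10 s (0.9 deg/px, 10 ms/frame) |
| receptor grid | 40 x 40 | one receptor per 4.5 x 4.5 deg (5 x 5 px block mean) |
| detector array | 38 x 40 | horizontal triples of adjacent receptors |
| `E_exc`, `E_inh`, `g_leak` | +50 mV, -20 mV, 1 | detector membrane batteries and leak |
| Fig-2-style circuit demos | `E_inh = -10 mV` | the equivalent-circuit sweeps use the weaker battery |
| `tau_hp`, `tau_lp`, DC | 250 ms, 50 ms, 10% | peripheral filters |
| grating | 36 deg wavelength, mean 0.5, contrast 1 | `make_grating()` |
| photon noise | factors 1, 2, 4, 8, 16, 32 | Poisson mean = factor x pixel value, then renormalised |
| dots | 500 single-pixel dots, re-randomised every 50 ms, 4.5 deg blur | `make_dots()` |
| noise-experiment schedule | still 0-0.5 s, PD 0.5-4.5 s, still 4.5-5.5 s, ND 5.5-9.5 s | `pd_nd_schedule()` |

Dot speed is not fixed by the study conditions; the default of
36 deg/s (one grating wavelength per second) places the coherent
motion in the detector's sensitive range and is exposed as an argument.

## Numerical choices

* **Steady-state membrane.** The membrane time constant is assumed
  small against the stimulus dynamics, so the voltage is solved
  algebraically per frame; there is no capacitive state.
* **Filters.** The first-order recursions use the exact exponential
  update coefficient $1 - e^{-\Delta t/\tau}$ (exact for
  piecewise-constant input), and their state is initialised to the
  first input sample so a static scene starts settled and onset
  transients do not contaminate tuning averages.
* **Filtered drives are used as wired.** The OFF low-pass drive is the
  low-pass of $1 - I$; under strong luminance noise $I$ can exceed 1
  and the drive transiently dips below zero. The detector evaluates
  the membrane equation on these signals exactly as the wiring
  prescribes rather than clipping them; the circuit-level operations,
  by contrast, enforce non-negative conductances as part of their
  domain.
* **Blur conventions.** `gaussian_blur()` interprets "half-width" as
  full width at half maximum ($\sigma = FWHM/(2\sqrt{2\ln 2}) \approx
  1.91$ deg) and uses periodic boundaries via FFT convolution. Its
  default kernel is normalised to unit mass (uniform fields pass
  through unchanged). The dot generator instead uses a *unit-peak*
  kernel: its purpose there is to dilate single-pixel dots to receptor
  scale before down-sampling, and a unit-mass kernel would dilute a
  dot roughly 30-fold — far below anything the 0 mV rectification of
  the population readout could register, leaving the dot experiments
  without any signal. Overlapping dot halos are clamped at luminance 1.
* **Photon-noise normalisation.** After the Poisson draw the whole
  movie is rescaled affinely to restore the clean movie's mean and
  standard deviation (the "same mean luminance and contrast"
  constraint), then clamped at 0. For Poisson draws the affine offset
  is always positive, so the clamp is a safety net rather than an
  active nonlinearity.
* **Response scalar.** Tuning curves use the time-mean of the
  rectified population output from 1 s onward, excluding the onset
  second.
* **SNR.** `snr()` uses the windows of the noise schedule
  (PD 0.5-4.5 s, ND 5.5-9.5 s) and, by default, the variance pooled
  within both windows after removing each window's mean;
  PD-only and ND-only variance modes are available.
* **Sub-pixel dot motion.** Dot positions are continuous and rendered
  to the nearest pixel per frame, so slow dots do not stall; positions
  and the blur wrap periodically, keeping dot density constant.
* **Random-direction dots** draw continuous directions, uniformly on
  the circle, independently per dot every 50 ms; the coherent subset
  has fixed membership of size `round(coherence * n_dots)` and moves
  only during scheduled motion epochs.

## What the synthetic stimuli do and do not emulate

The generators reproduce the three stimulus classes of the modelled
experiments — drifting sine gratings, Poisson shot noise on gratings,
and random-dot kinematograms — on a flat, square pixel raster. They do
not emulate natural scenes, the fly eye's hexagonal sampling lattice,
photoreceptor adaptation, or apparent-motion bar protocols. Passing
tests therefore certify the model's behaviour under these idealised
conditions, not its performance on real imagery.

## Known limitations and honest discrepancies

Replication of the published headline numbers is deliberately computed,
never asserted by fiat, and three of them do not reproduce under the
stated operationalisations; the package reports what it measures.

* **Photon-noise SNR extremes.** The published signal-to-noise curve
  spans roughly 1 (factor 1) to 100 (factor 32). Here the curve is
  monotone but compressed (about 4.5 to 8). The within-window variance
  of the population response is floored by *deterministic* structure:
  the onset transient after motion begins at 0.5 s, and a steady
  phase-sampling ripple that exists because the 38 detector columns
  span 4.75 grating wavelengths, so rectified harmonics do not cancel
  exactly. At high luminance factors this floor, not photon noise,
  sets the variance; at factor 1 the 1520-detector average suppresses
  pixel-independent noise too effectively to reach SNR ~1. Mid-range
  factors agree well with the published curve (about 6 at factor 4).
  Wrap-around (40-column) wiring, subsample-style down-sampling and
  settling-excluded windows were each evaluated and narrow but do not
  close the gap; none is adopted, since each contradicts an explicit
  part of the stated methods.
* **100%-coherence SNR.** The published value of almost 1000 implies a
  population trace fluctuating by ~0.1% within windows; residual
  pixel-rendering ripple of the drifting dot pattern leaves a few
  percent here, giving an SNR near 10 (still far above the 20%
  coherence value, and far below the published ceiling, which the
  experiment treats as an upper bound).
* **Null-direction leak at high temporal frequency.** The full model's
  ND response is essentially zero up to 2 Hz (< 2.5% of the PD peak)
  but reaches ~7% at 5 Hz and ~16% at 10 Hz: the 50 ms inhibitory
  arms attenuate (gain 0.30 at 10 Hz) and no longer shunt the
  high-pass excitatory transients. This is not a time-step artefact
  (halving dt leaves it unchanged).
* **Direction tuning at 60 degrees** lands at 51% of the peak —
  marginally above the published "less than 50%".

## Problem sizes used in the test suite

Unit tests run on a reduced 50 x 50 px / 45 x 45 deg patch with the
same pixel pitch, receptor spacing and time step as the full geometry,
so every local mechanism is unchanged and a complete run takes
milliseconds. The replication checks and `scripts/acceptance.R` use
the full 200 x 200 x 1000 geometry, with 10 replicate seeds per
stochastic condition.
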