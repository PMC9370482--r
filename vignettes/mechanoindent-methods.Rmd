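---
title: "Methods: microindentation mechanosensitivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microindentation mechanosensitivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanoindent)
```

## The assay

Mechanosensitive ion channels such as Piezo1 convert mechanical stimuli into
ionic currents; their opening admits extracellular Ca^2+^. A practical
single-cell assay for this is progressive microindentation under ratiometric
calcium imaging: a fine glass probe on a motorised stage pokes one adherent
cell with increasing depth while fura-2 fluorescence reports cytosolic
calcium. A cell that responds shows a transient rise of the normalized
fluorescence ratio before its membrane finally ruptures under the deepest
indentations; a cell that never does is unresponsive. The fraction of
responsive cells — the activation rate AR — summarises the
mechanosensitivity of a cell population, and binning it by the indentation
depth that elicited each response (AR~δ~) adds a dose dimension.

`mechanoindent` implements the complete analysis chain for such an assay:

1. **Stage calibration** — metrology of a screw-driven stepper stage
   (bidirectional systematic error, backlash, positioning accuracy, total
   uncertainty) and its correction by integer-step overshooting.
2. **Holographic morphometry** — cell thickness from quantitative phase
   maps, giving the mean maximal thickness ⟨T~max~⟩ that anchors the depth
   scale.
3. **Indentation protocol** — the train of progressive indentations, its
   timing, the depth map δ = ⟨T~max~⟩ − Z, and a G-code motion program.
4. **Trace classification** — normalization of F340/F380 to R, detection of
   activation transients and membrane rupture, per-cell classification.
5. **Cohort statistics** — AR, AR~δ~, threshold sweeps and threshold
   selection.
6. **Synthetic data** — seeded generators for every input, so the whole
   chain is testable without laboratory recordings.

## Ratiometric model and trace classification

Fura-2 is a dual-excitation dye: calcium binding raises emission under
340 nm excitation and lowers it under 380 nm. The ratio `FR = F340/F380`
is therefore monotone in cytosolic calcium and independent of dye
concentration and illumination (any joint rescaling of the channels
cancels). We normalize FR to its resting baseline, `R = FR/FR0`, with FR~0~
the mean of FR over the pre-stimulus window (default the first 10 s;
configurable, and it must precede the first indentation and contain at
least five samples).

An **activation event** is a transient peak of R that (i) exceeds the
classification threshold R~T~, (ii) has a width at baseline of at least
w = 30 s, and (iii) coincides with a peak in F340 *and* a dip in F380 —
the ratiometric signature that excludes single-channel artefacts.
**Rupture** is the opposite signature: both channels collapse together as
the dye diffuses out, so R stays flat while the raw signals fall.

Detection choices that the assay description leaves open were fixed as
follows:

* *Structural detection, then thresholding.* Candidate transients are found
  once, independently of R~T~: local maxima of lightly smoothed R (moving
  average, 4 s window — a tenth of the nominal transient width) with
  topographic prominence ≥ 0.2 above the surrounding signal. A cell is then
  responsive at a given R~T~ iff some candidate's smoothed peak exceeds it.
  This mirrors the find-peaks-then-threshold flow of standard practice and
  makes the sweep curve AR(R~T~) non-increasing *by construction*, which is
  the invariant the statistics rely on.
* *Width at baseline* is measured at `R = 1 + 0.1 (peak − 1)`, a 10% guard
  above baseline that keeps frame noise from truncating the measured width.
* *Peak/dip coincidence* uses intensity-weighted centroid times of the
  smoothed R peak, F340 peak and F380 dip over the event window, compared
  within a 2 s tolerance (4–5 frames at the 0.44 s ratio sampling interval).
  Centroids average the whole excursion and are far more stable against
  frame noise than single-sample argmax positions.
* *Rupture* requires both smoothed channels to drop by ≥ 50% within a 5 s
  window, with R flat (SD < 0.05) over the trailing 20 s of the record.
  Flatness is judged at the record's tail rather than immediately after the
  drop: when rupture truncates an ongoing transient, R needs a few tens of
  seconds to finish relaxing, but once the dye is gone the tail is flat.
* *Pre-rupture clipping.* Event analysis runs on the record before the
  detected rupture (with a 2.5 s guard): the dual-channel collapse would
  otherwise bias the centroid-based peak/dip localisation of transients
  elicited by the penultimate indentations.
* *Event assignment.* The first qualifying event is assigned to the most
  recent indentation whose window contains its peak time. The window is the
  step's full duration — down travel, up travel, and the 40 s dwell — since
  the observation time for late events starts when the probe returns. An
  event outside every window leaves the cell responsive with an unassigned
  depth (reported, with a warning, in a separate histogram bin so AR~δ~
  still sums to AR).

## Stage metrology

A screw-driven stage loses motion at every direction reversal (backlash).
From a saw-tooth calibration trajectory — m repeats of P forward steps then
the same backward, with interferometric position readout — the package
computes, per position i and approach direction ±, the mean deviation
z̄~i~^±^ and its standard uncertainty σ~i~^±^, and from them:

* the bidirectional systematic error `E = max(z̄) − min(z̄)`;
* the bidirectional positioning accuracy
  `A = max(z̄ + kσ) − min(z̄ − kσ)` with coverage factor k = 2 (so A ≥ E
  always, and A = E when all σ = 0);
* backlash estimators: within a repeat the + approach precedes the −
  approach with the +→− reversal between them, so `Δz_i(+−) = z_i(+) −
  z_i(−)` estimates the +→− backlash; the −→+ reversal lies between the −
  leg of repeat r and the + leg of repeat r + 1, so those pairs estimate the
  −→+ backlash. Averaging over positions and repeats and taking magnitudes
  recovers both injected values exactly on a noiseless simulation — the
  pairing is what makes the two directions separable at all;
* the total positioning uncertainty `Δz = E_residual + E_R`, with E~R~
  operationalised as the mean absolute deviation of a corrected trajectory
  (the description of the random error as a "cumulative mean deviation"
  fixes no formula; the mean absolute residual is the conservative choice).

Correction is by **integer-step overshooting**: the backlash magnitudes are
rounded to motor steps (21.1 nm nominal in +, 18.9 nm in −) and the first
move after each reversal is extended by that many steps; the screw's play
absorbs the extension. On the simulator this reduces E from ≈ the injected
backlash to below one nominal step (plus noise). The simulator itself uses
the physical sign convention — the stage lags behind the commanded motion —
because only then does the corrected command sequence preserve move
directions at reversals.

## Holographic morphometry

Digital holography yields a phase map Φ (radians). After background
calibration (subtracting the mean phase of the cell-free medium region),
thickness follows from the refractive-index contrast:

> T = (λ / 2π) · Φ / (n~c~ − n~m~),  with defaults λ = 635 nm,
> n~c~ = 1.38, n~m~ = 1.34.

Per cell, T~max~ converts the *maximum* phase within the ROI (a
configurable percentile is provided for noisy maps but defaults to 100, the
plain maximum). The cohort summary reports the mean and standard error of
the per-cell T~max~; the mean enters the depth map as ⟨T~max~⟩. No phase
unwrapping is attempted: with Δn = 0.04 and λ = 635 nm the phase stays
below 2π for T ≲ 15.9 μm, comfortably above realistic cell thicknesses;
maps whose phase exceeds 2π trigger a warning instead.

## Indentation protocol

The default train indents by D = 8, 10, …, 18 μm from a rest height
h~0~ = 20 μm at v = 3 μm/s with a 40 s dwell: six steps, tip heights
Z = h~0~ − D from 12 μm down to 2 μm above the coverslip (never below it),
travel times D/v (4 s at D = 12 μm). Step start times chain the previous
step's down-and-up travel plus the dwell; the whole train takes about
5 minutes per cell, so a ten-cell session fits a 50-minute viability
budget. Depths δ = ⟨T~max~⟩ − Z may be negative for the shallow steps
(no contact with a ~9 μm cell); such steps stay in the train but are
excluded from the AR~δ~ bins. The G-code emitter produces relative moves
(G91) in millimetres with the feed rate in mm/min (0.18 at 3 μm/s) and G4
dwells, optionally with the overshoot extension at each reversal.

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated; they are first-class, tested code.

* **Traces.** Baselines of 800/1000 a.u. with multiplicative Gaussian frame
  noise (CV 0.02 by default; realistic for ratio imaging and unstated in
  assay descriptions). An activation transient is a Gaussian kernel (FWHM
  40 s) applied anti-correlated to the channels — F340 scaled by √A, F380
  by 1/√A — so R peaks exactly at the configured amplitude A (3.0 by
  default) and the anti-correlation is exact in the noiseless limit. The
  onset is uniform within 0–10 s after the activating step's travel ends,
  the peak half an FWHM later, which keeps every peak inside its step's
  window. Rupture multiplies both channels by a common exponential decay
  (τ = 3 s) to a 10% floor, so R is flat after rupture by construction.
  An optional low-amplitude "artifact" excursion (same kernel, labelled
  non-responsive) emulates the spurious sub-threshold responses that real
  control groups show below the usable threshold range.
* **Cohorts.** Exactly `round(n × responsive_fraction)` cells are
  responsive; the calcium-free group is forced to zero (no extracellular
  calcium, no influx). Activation steps default to the deeper half of the
  train excluding the terminal step (steps 3–5 of the default train — the
  first contact-making depths for ~9 μm cells); the terminal step ruptures
  every cell, as in practice.
* **Stage.** Measured = commanded + hysteresis offset (full backlash
  traversed at each reversal) + optional per-step random-walk noise +
  white positioning noise. Recovery tests use 0.05 μm white noise.
* **Phase maps.** Cells are raised-cosine-squared domes centred on pixels,
  so each peak phase equals the forward model exactly; ROI labels are the
  dome footprints and per-cell ground truth is returned alongside.

What the generators do **not** emulate — photobleaching, focus and motion
drift, cell-to-cell baseline heterogeneity, partial ruptures, overlapping
or migrating cells, asymmetric transient shapes — bounds what the green
tests show: they validate the algorithms against the stated signal model,
not the pipeline's robustness to every artefact of real recordings.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 20-position × 3-repeat
saw-tooth calibrations (plus 100-position runs for estimator precision),
100-cell cohorts for classifier fidelity, 20 seeded replicates of 28–33
cell cohorts for AR recovery, 65-cell phase maps for the thickness cohort,
and a 0.1-step threshold grid over [0, 4.5] — sizes chosen to match the
scale of a real study while keeping a full run in seconds. Ties and
degenerate inputs are fixed throughout: σ = 0 for a single repeat; the
−/+ backlash is NA for a single-repeat trajectory; equal-height smoothed
maxima resolve to the earlier sample; empty groups, empty masks and empty
command sequences raise errors rather than returning silent zeros.

For threshold selection, the usable interval is bounded below by the
smallest grid threshold at which the control group's AR reaches zero *and
stays* zero (guarding against non-monotone blips) and above by the largest
threshold at which any group still responds; the selected R~T~ is the
interval's midpoint. The toxin-treated group participates in sweeps but not
in threshold selection — only the calcium-free control defines the noise
floor. One consequence of structural detection is that a degenerate
threshold of zero does not mark every cell responsive: the width,
prominence and coincidence rules still apply, which is exactly why the
control curve falls to zero at a finite threshold.

## Limitations

* ROI extraction and cell segmentation are out of scope; per-cell traces
  and label masks are inputs.
* No absolute calcium calibration is attempted; R is used as a
  dimensionless classifier signal only.
* The rupture detector keys on the dual-channel drop plus trailing
  flatness; the post-rupture plateau *level* of R is deliberately not used
  (it depends on background subtraction in the recording system).
* Descriptive statistics only: AR and AR~δ~ with no inter-group inference.
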