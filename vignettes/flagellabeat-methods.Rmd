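---
title: "Quantifying the flagellar beat of tethered sperm: methods and design"
author: "flagellabeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the flagellar beat of tethered sperm: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

A sperm cell tethered by its head to a glass surface beats its flagellum
freely, typically at 5–20 Hz. Dark-field microscopy renders the cell as a
bright, thin, curvilinear structure on a dark background, recorded at
200 frames/s. Two quantities are of interest:

* the **instantaneous beat frequency**, frame by frame, including its
  response to an experimental event such as a brief light flash that raises
  intracellular cAMP and accelerates the beat; and
* the **waveform envelope**, a "stop-motion" image superimposing all frames
  after rotational alignment, which shows the spatial extent of one beating
  cycle.

Alongside the video pipeline, the package normalizes fluorescence traces
from Ca²⁺ indicator experiments as percent ΔF/F0 under the two baseline
conventions used by plate-reader and stopped-flow instruments.

Because raw microscopy recordings are large and instrument-specific, the
package ships a synthetic recording generator with complete ground truth;
every analysis stage is validated against that ground truth rather than
against downloaded data.

## The synthetic recording model

The flagellum is modelled as a traveling wave of the tangent angle, the
standard low-amplitude description of flagellar kinematics:

$$\psi(s, t) = \psi_0 + A \sin\!\big(\varphi(t) - 2\pi s/\lambda\big),
\qquad \varphi(t) = 2\pi \int_0^t f(\tau)\,d\tau,$$

where $s \in [0, L]$ is arc length from the head attachment point, $\psi_0$
the orientation of the cell's symmetry axis, $A$ the tangent-angle
amplitude, $\lambda$ the wavelength and $f(t)$ the programmable frequency
time course (constant, a step at an event time emulating a light flash, or
an arbitrary function). The curve is obtained by integrating the tangent
with midpoint-rule steps of 0.25 µm, so consecutive spacing is exact and
total arc length is exact by construction. The head is tethered: it moves
only through explicit drift and rigid-rotation parameters.

Defaults: $L = 60$ µm and $\lambda = 120$ µm (typical mouse sperm flagellum
length and a wavelength that puts roughly half a wave on the flagellum),
$A = 0.35$ rad (gives head-to-midpoint angle excursions of about ±0.31 rad,
a visibly beating but low-amplitude waveform), 256×256 px frames at
11/16 µm/px (an 11-µm camera pixel behind 16× total magnification). The
published observations do not report amplitude or wavelength, so these are
free parameters of the generator, chosen once; all validation treats them
as such.

Rendering emulates dark-field contrast only: a Gaussian-profile ridge
(σ = 1 px) along the curve, the head as a filled antialiased disk (radius
4 µm), additive Gaussian noise clipped to the intensity range. One seed
governs all stochastic draws, and identical protocols render bit-identical
videos. What the generator does **not** emulate: diffraction side lobes
and the instrument PSF, intensity falloff along the flagellum, debris and
neighbouring cells, focus drift, and 3-D components of the beat. Passing
tests therefore demonstrate correctness of the algorithms on an idealized
dark-field scene, not robustness to every artefact of real recordings.

Fluorescence traces are a baseline plus an optional step or saturating
exponential response starting at the event sample, plus Gaussian noise.

## Segmentation

Each frame is thresholded globally and restricted to the largest connected
component; pinholes are filled (a noise dip inside the cell would otherwise
skeletonize into a loop). The threshold criterion is the **triangle
method** (Zack et al. 1977): on these images more than 99% of pixels are
background, and Otsu's between-class-variance criterion — the other
standard parameter-free choice, available via `method = "otsu"` — places
the threshold roughly at half the ridge peak, clipping the dim flanks of
the flagellum (overlap with the ground-truth mask drops to ~0.73 Jaccard).
The triangle criterion is designed for exactly this skewed histogram shape
(a dominant background mode with a long sparse bright tail) and keeps the
segmented flagellum at its full rendered width.

## Flagellum tracing

The component is thinned to a 1-px, 8-connected skeleton (Zhang–Suen).
Side branches are pruned by walking inward from each endpoint to the first
junction and deleting leaves shorter than `prune_len` (default 5 px) —
but only while more than two endpoints remain, so the two genuine ends of
the flagellar path can never be pruned away. Exactly two endpoints must
survive; zero or one indicates a closed loop and more than two an
unresolvable branching, both reported as per-frame tracing errors. The
ordered path is the breadth-first shortest path between the endpoint
nearest the head center (ties broken by distance, then index) and the far
endpoint.

Two corrections address known biases of grid skeletons:

* **Tip regrowth** — thinning erodes line ends by up to half the line
  width; the tip is regrown along its local direction while the binary
  foreground continues. The head end is left alone, since the attachment
  point lies inside the head blob, not at its rim.
* **Staircase smoothing** — an 8-connected grid path overestimates the
  length of an oblique smooth curve by up to ~8%. Arc length and the
  midflagellar point are computed on a 5-point moving-average copy of the
  path (`points_smooth`); the raw grid path is kept in `points`.

The head position is the intensity-weighted centroid of the locally widest
part of the component (the distance-transform maximum and its surroundings),
searched inside a window around the previous frame's estimate.

## Angle series and symmetry axis

For each frame the signed angle (positive counter-clockwise, measured in a
y-up mathematical frame) between the cell's symmetry axis and the line from
the head center to the midflagellar point is recorded. The symmetry axis is
not directly observable; it is estimated as the **circular mean of the
head-to-midpoint directions over the frame's analysis window** — the beat
oscillates symmetrically about the cell axis, so the mean direction over
whole cycles is the axis. For the traveling-wave model this estimator is
exact to numerical precision at the default amplitude, and windowing makes
it follow slow rigid rotation of the cell. Frames whose segmentation or
tracing fails carry gap markers; gaps are never interpolated, and more than
10% failures aborts with per-frame diagnostics.

## Sliding-window frequency estimation

The angle series oscillates sinusoidally at the beat frequency. For each
frame a window of exactly $N = 2\,\mathrm{round}(w\,\mathrm{fps}) + 1$
frames is placed around it (default half-window $w = 0.5$ s, so 201 frames
at 200 fps: 0.5 s before and after the frame). At the video boundaries, or
next to an event frame, the window is **shifted, not truncated**: it keeps
exactly $N$ frames, stays inside the event-free run containing its center
frame, and never mixes frames from both sides of an event. The event frame
index marks the first post-flash frame and belongs to the post-event
regime. A window that cannot be placed (run shorter than $N$) yields a gap
for that frame, never a global failure.

Within each window, $a \sin(2\pi f t + \phi) + c$ is fitted by variable
projection: for fixed $f$ the remaining parameters solve a linear least
squares problem, and the profiled residual sum of squares is minimized over
$f$ by bounded Brent search seeded at the zero-padded FFT peak of the
detrended samples, followed by two parabolic polish steps (Brent alone
stalls near the square root of machine precision; the polish brings exact
sinusoids to ~1e-12 Hz reproducibility, and makes the estimate invariant to
the time origin). The search is bounded to $[0.5, \mathrm{fps}/4]$ Hz to
exclude DC drift and aliasing artefacts. Fits are flagged failed — and
carry no frequency — when samples are constant, span less than one period,
or the fitted amplitude falls below the noise floor, taken as $\sqrt{2}$
times the residual standard deviation (the point where the coherent signal
power equals the residual power). Amplitude is reported non-negative, phase
normalized to $(-\pi, \pi]$.

A plain centered moving average is provided for plotting frequency traces;
it is not equivalent to the display smoothing of commercial graphing
software and is never used in any quantitative step.

## Head registration and the waveform envelope

For envelope construction the head is registered by normalized
cross-correlation of a head template over integer shifts with parabolic
sub-pixel refinement, the search window following the previous frame's
estimate. The template is taken **once, from the first frame** inside the
user-defined ROI, rather than re-extracted every frame: sequential
frame-to-frame matching accumulates sub-pixel interpolation bias as a
random walk over hundreds of frames, while a fixed reference keeps each
frame's error independent (well under half a pixel RMS). Match scores below
0.5 raise a tracking-lost error.

The direction at which the flagellum leaves the head (the neck azimuth) is
measured inside an annulus centred on the head — internal diameter 16 µm to
cover the head, external diameter 4 µm larger, enough to resolve the first
pixels of the neck. The azimuth is the direction of the centroid of the
foreground pixels inside the annulus, intensity-weighted when the raw frame
is available: dim rim pixels flicker across the threshold from frame to
frame, and weighting roughly halves the resulting angular noise. Foreground
mass in opposite sectors (a flagellar loop re-entering the annulus) is
reported as an ambiguous-neck error.

Every frame is then translated so its head sits at the reference center and
rotated by (reference azimuth − frame azimuth) with bilinear interpolation;
the reference azimuth is that of the first usable frame. Superposition uses
a maximum projection by default — bright dark-field structures on a black
background superimpose naturally under max; a mean projection is available,
as the original superposition operator is not documented. Gap frames are
skipped and counted, never interpolated.

## ΔF/F0 normalization

Two baseline conventions, matching the two instruments:

* **plate reader** — F0 is the mean of all samples before the
  compound-addition event; requires at least two pre-event samples. In the
  alternating-excitation protocol (indicator read at 520 nm, photo-activation
  pulses at 485 nm) the 485-nm samples are bookkept but excluded from
  ΔF/F0 — they exist to activate the photo-enzyme, not to measure.
* **stopped flow** — F0 is the mean of the first three data points recorded
  immediately after mixing.

In both cases ΔF/F0(%) = 100·(F − F0)/F0, which is invariant under positive
gain and averages exactly zero over the samples that define F0. A buffer
control trace, normalized under the same convention, can be subtracted
pointwise; the operation is anti-symmetric and requires matching length and
time base. No detrending or photobleaching correction is applied. Whether
samples recorded during the physical injection should be excluded from F0
is not specified by the protocol; all pre-event samples are used.

## Numerical conventions and determinism

Pixel centers sit at integer coordinates, origin top-left, x right, y down
in storage; every angle is computed after mapping to a y-up frame so
mathematical conventions (positive = counter-clockwise) hold throughout.
Videos travel as multi-page 16-bit TIFF with a YAML sidecar (fps, µm/px,
event frames); tables as CSV; summaries as JSON. All randomness flows from
protocol seeds: identical configuration and seed give byte-identical
outputs, which the test suite asserts.

## Validation scale

The test suite and the acceptance script validate the pipeline on
recordings at the acquisition conditions described above: 200 frames/s,
noise at 5% of the flagellar peak intensity, beat frequencies spanning
5–18 Hz on 2-s recordings, a 7→18 Hz step with the event at 2 s on a 4-s
recording, and 0.5-s recordings for tracking and envelope checks —
durations chosen so each property is measured over many beat cycles while
a full run stays comfortable on a laptop. Unit tests use shorter clips
(0.3–0.5 s) of the same geometry.

## Known limitations

* The tracer assumes a single cell whose skeleton is a simple path; beats
  so deep that the flagellum touches itself (enclosing background) are
  rejected per frame rather than resolved.
* The symmetry axis estimator assumes the beat is symmetric about the cell
  axis within each analysis window; strongly asymmetric beating would bias
  the axis and hence the angle offset, though not the fitted frequency.
* The registration template is planar and fixed; large in-plane rotation of
  the head itself (beyond what a round head shows) would lower match
  scores.
* Sub-pixel accuracy figures are established on synthetic scenes; real
  dark-field recordings add structured artefacts the generator does not
  model.
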