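---
title: "Simulating cardiac-motion effects on radioablation dose distributions"
author: "cardioblur"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cardiac-motion effects on radioablation dose distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioblur)
```

## The problem

Stereotactic arrhythmia radioablation delivers a single high dose (here
420 cGy prescribed at the 70% isodose line of a 600 cGy maximum) to an
arrhythmogenic cardiac substrate with a robotic radiosurgery system.
Respiratory motion is compensated by a tracking system that predicts the
target position from an external surrogate through a periodically refitted
correlation model — but the heart also beats, and cardiac motion is not
compensated.  This package is a fully synthetic, desk-scale model of that
delivery chain, built to ask one question: *how much does uncompensated
cardiac motion blur and displace the delivered dose distribution?*

Every input is generated in code; there is no external data.  The pipeline
mirrors a phantom experiment: a motion stage carrying a film-loaded ballcube
phantom, a fluoroscopic QA of the stage, correlation-model tracking, film
irradiation, scanning, and three standard film analyses.

## Motion models

**Cardiac motion** is a sine: \(x(t) = (pv/2)\sin(2\pi t/T + \phi)\), with
peak-to-valley \(pv = 5\) mm and period \(T = 1\) s by default (population
mean target / ICD-lead excursions).  In the 1D layout it acts along SI; in
the 2D layout the platform axis is inclined 35° from SI toward the patient
right, so an SI peak-to-valley of 5 mm carries an LR peak-to-valley of
\(5\tan 35^\circ = 3.5\) mm.

**Respiratory motion** is the Lujan-type waveform
\[
P(t) = P_0 - A\cos^6(\pi t/\tau - \phi),
\]
with \(A = 20\) mm, \(\tau = 5\) s, \(\phi = 0\): the target rests near
exhale (\(P_0\)) with brief excursions to inhale (\(P_0 - A\)).  Note that
\(A\) is the full waveform depth — throughout the package "amplitude" means
**peak-to-valley**, consistent with how measured platform waveforms are
reported (peak-to-valley distances matched against set amplitudes).

AP motion of the phantom stage is fixed at zero (the platforms move in the
horizontal plane); AP appears only in the centroid bookkeeping.  The cardiac
phase relative to respiration is a free, seedable parameter — the two are
never synchronized, and the delivery driver draws the phase from its seed.

Trajectories are sampled at `dt = 1/150` s, ten times the 15 fps
fluoroscopy rate, which keeps peak-to-valley discretization error below
0.1%.

## Tracking simulator

The correlation model is the **linear** one: a per-axis least-squares line
from the surrogate signal to the imaged target position, fitted over a
sliding window of the latest 15 paired acquisitions, with 3 points replaced
at each refit (every 60 s).  The surrogate is taken as the respiratory SI
waveform itself — a perfect respiratory surrogate that is blind to cardiac
motion, which is exactly the mechanism under study: cardiac motion enters
the model window as noise and the per-event *correlation error* (actual
minus predicted position) inherits the cardiac term.

Two regimes matter and the tests cover both:

* Against an **uncontaminated** respiratory map, the error at an imaging
  event is exactly the cardiac displacement: extremes converge to
  \(\pm pv/2\) per projected axis with zero mean.
* In the **full pipeline** the model windows are themselves contaminated,
  and ordinary-least-squares extrapolation inflates the extremes beyond
  \(\pm pv/2\) (the mean stays at zero and axes orthogonal to the motion are
  untouched).  The simulation reproduces the experimental pattern: cardiac
  motion leaves mean correlation errors unchanged and inflates the extremes
  in the direction of motion.

**Imaging cadence.**  The cadence of the imaging events is not a published
quantity.  The package default is 3.7 s with 0.5 s Gaussian jitter,
deliberately *incommensurate* with the 5 s respiratory period: a cadence
equal to the period resamples a single breathing phase, the surrogate range
inside the window collapses, and the linear fit becomes rank-deficient.
Between refits the model parameters are held piecewise-constant.

## Synthetic plan

The treatment planning system is out of scope; the plan is an analytic
spherical distribution with an error-function penumbra,
\[
D(r) = D_{max}\,\Phi\!\left(\frac{r_{50} - r}{\sigma}\right),\qquad
r_{50} = r_{Rx} + \sigma\,\Phi^{-1}(f_{Rx}),
\]
so that the prescription surface carries the prescription dose *exactly*:
\(D(12.875\,\mathrm{mm}) = 420\) cGy at the 70% line of
\(D_{max} = 600\) cGy (the PTV sphere sits 3 mm inside the 31.75 mm
ballcube insert, hence \(r_{Rx} = 31.75/2 - 3\)).  The penumbra scale
\(\sigma = 2.5\) mm is a typical 6 MV MLC penumbra and is a configuration
knob: the reference profile is not parameterized in print, so absolute
isodose distances from the synthetic plan are model-dependent — only the
prescription-surface diameter (25.75 mm) is geometry-anchored.  Isodose
percentages are defined relative to \(D_{max}\) (so the 70% line carries
420 cGy); percent-of-prescription is available by passing a different
reference dose.

Both film planes pass through the sphere centre (axial = LR × AP,
sagittal = SI × AP), with the film centre as coordinate origin and a 1 mm
slit through the centre parallel to the in-plane x axis.

## Blur simulator

Delivery is modelled as **trajectory-occupancy averaging** at constant dose
rate: \(D_{del}(x) = \frac{1}{N}\sum_t D_{plan}(x - m(t))\) with \(m(t)\)
the in-plane projection of the uncompensated (residual) displacement.
Off-grid shifts use bilinear interpolation; edges use nearest-pixel
(constant) extension, which only biases the outer low-dose region where the
plan is already at background.  Beam-by-beam sequencing and interplay
effects are not modelled — this is the standard first-order blurring model.

For pure sinusoidal motion the infinite-sample limit is closed-form: the
occupancy density of \(u = (pv/2)\sin\theta\) under uniform phase is the
arcsine law \(p(u) = 1/\pi\sqrt{(pv/2)^2 - u^2}\).  `arcsineKernel()`
discretises it by exact integration over pixel bins (so it sums to one and
handles the integrable edge singularities), and the test suite checks that
`blurWithTrajectory()` converges to the kernel convolution and that the
kernel matches the Monte-Carlo occupancy histogram (total variation < 0.01
at \(10^6\) samples).

Symmetric zero-mean blur predicts two signatures, both asserted in the
acceptance suite: isodose distances *shrink* at high levels (90%, 80%) and
*grow* at low levels (20%), and the thresholded-mask centroid stays put
(< 0.05 mm) — consistent with measured centroid displacements remaining
below the ~0.3 mm analysis accuracy of the film test.

## Film dosimetry

The film response is a rational net-optical-density curve
\(D(od) = a + b\,od/(1 - c\,od)\), the standard saturating shape for
radiochromic film, fitted by Levenberg–Marquardt least squares to 15
(od, dose) pairs spanning 0–1000 cGy.  The forward scanner model converts
dose → od (closed-form inverse of the rational response — exact, so no
root-finding tolerance enters the round trip) → 16-bit red-channel pixel
value \(U\cdot 10^{-od}\) (unexposed value \(U = 40000\), a knob), adds
Gaussian granularity noise, quantizes to integers, and sets slit pixels to
unexposed film.  The inverse model is
\(od = \log_{10}(U/\mathrm{pixel})\), then the calibration curve; the
noiseless round trip is exact to < 0.1 cGy (16-bit quantization only).
Net OD (rather than raw OD) is the dosimetric signal.  24 h development
kinetics, lateral scanner response, and triple-channel correction are
deliberately not modelled.

Scans serialize as 16-bit grayscale TIFF with a JSON sidecar (dpi,
unexposed value); 16-bit depth is required to keep quantization below the
film noise floor.

## Marker-tracking QA

Platform QA mirrors the fluoroscopic procedure: 100 frames at 15 fps of a
1.5 mm bright marker at 0.096 mm/pixel, anti-aliased with a one-pixel
linear edge ramp.  Spatial calibration thresholds a rendered 41.30 mm
sphere (Otsu), keeps the largest connected component, and divides the known
diameter by the major-axis pixel extent.  Tracking binarizes each frame the
same way and takes the *unweighted* centroid of the mask ("centre of mass
through binarization"); RMSE against the ideal sine fixes amplitude and
period at their nominal values and fits only phase and offset — the phase
is obtained in closed form from a sine/cosine basis regression, and an
unfitted-phase mode is exposed for comparison.

## Dose analysis

* **Centroid error**: per film, binary mask at 50% of the film maximum
  (slit excluded), unweighted centroid minus film centre; SI from the
  sagittal film, LR from the axial film, AP averaged over both.  The 50%
  threshold and the unweighted mode are package choices (the vendor values
  are unpublished); dose-weighted centroids and other thresholds are
  exposed.  Cardiac displacement is the with-cardiac minus without-cardiac
  difference.
* **Isodose distances**: profiles parallel to the slit at 3 mm offset
  (clear of the slit and the interlocking film edge), crossings located by
  linear interpolation between the two bracketing samples at 90/80/70/50/20%
  of the plan maximum; profiles that do not cross a level exactly twice are
  an error, not a guess.
* **Gamma**: global normalization to the reference maximum, 10% low-dose
  threshold, 25 mm central ROI, 2 mm slit exclusion.  The search disc has
  radius \(3\cdot\)DTA and lattice step DTA/10, chosen to keep the
  discretization error below 0.5 pass-rate points against an exhaustive
  DTA/100 brute-force evaluator (the test oracle, written independently in
  plain R; the implementation is compiled and uses a radius-ordered early
  exit).

## Problem sizes and determinism

The test and acceptance suites run at desk scale: 63.5 mm films at 75 dpi
(188 × 188), 2000 blur time samples (quadrature error < 0.1 cGy, verified
by doubling), 10 s cardiac residuals (10 whole cycles), 600 s tracking
simulations pooled over three repetitions, 21 × 21 grids for the
gamma-oracle comparison, and 100 seeds for calibration recovery.  Every
stochastic element (cardiac phase, imaging jitter, film noise) is drawn
through an explicit seed, and deliveries are bit-reproducible given the
seed.

## What the generator does and does not emulate

The synthetic data reproduce the *study conditions*: sine cardiac motion
(5 / 3.5 mm via the 35° layout, 1 s cycle), the cos⁶ respiratory waveform
(20 mm, 5 s), film granularity noise, scanner resolutions (300 / 75 dpi),
and fluoroscopy geometry (0.096 mm/pixel, 15 fps).  They do **not** emulate
irregular patient heartbeats, 3D cardiac rotation/deformation, beam-by-beam
delivery interplay, CT/metal-artifact effects, real film development or
scanner lateral response, or the vendor's model-quality gating.  Passing
tests therefore validate the blurring *mechanism* and the analysis chain,
not absolute agreement with any specific experimental film — experimental
pass-rate tables depend on a physical linac and real films and are
reproduced qualitatively (direction and ordering of effects), not
numerically.

## A worked pass through the pipeline

```{r pipeline, eval = FALSE}
plan <- planModel()                       # 420 cGy at 70%, 600 cGy max
sag  <- renderPlanImage(plan, "sagittal", dpiToSpacing(75))

# uncompensated 1D cardiac motion, 10 whole cycles
res <- sampleTrajectory("cardiac_1d", cardiac = waveformParams(5, 1),
                        duration = 10)
del <- blurWithTrajectory(sag, res, 2000, cyclePeriod = 1)

# film chain: scan and reconstruct
cal  <- fitCalibration(defaultCalibrationSamples())
film <- scanToDose(doseToScan(del, cal, noiseSd = 100, seed = 1), cal)

# the three analyses
centroidError(renderPlanImage(plan, "axial", dpiToSpacing(75)), film)
isodoseDistance(extractProfile(film, "SI", 3), plan@dMax, 80)
passRate(gammaPassRate(sag, film, dta = 1, ddPct = 3))
```

## Known limitations

The blur/tracking decomposition (residual trajectory → occupancy blur) is a
model choice; a film measurement cannot separate tracking lag from blur.
Absolute isodose distances inherit the penumbra knob.  The linear
correlation model is the only one implemented (quadratic and zero-quadratic
variants exist in the clinical system).  Whether in-between imaging events
also log errors without refitting is unspecified in the clinical system; the
package logs at every event and refits on schedule.
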