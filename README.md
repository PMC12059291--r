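# cardioblur

A fully synthetic, desk-scale R model of how **uncompensated cardiac
motion** degrades the dose distribution delivered during stereotactic
arrhythmia radioablation with a robotic, respiratory-tracked radiosurgery
system — for medical physicists and methodologists who want the blurring
mechanism, the tracking behaviour, and the standard film analyses in one
reproducible, data-free pipeline.

## What it models

* **Motion.** Cardiac motion is a sine, `x(t) = (pv/2)·sin(2πt/T + φ)`
  (defaults: 5 mm peak-to-valley SI, 1 s cycle; a 35° inclined layout adds
  a 3.5 mm LR component).  Respiration is the Lujan-type waveform
  `P(t) = P0 − A·cos⁶(πt/τ − φ)` (A = 20 mm, τ = 5 s): long rests near
  exhale, brief excursions to inhale.
* **Tracking.** A linear correlation model maps the respiratory surrogate
  to the target position, fitted over a sliding 15-point window of paired
  imaging events with 3 points refitted every 60 s.  The surrogate never
  sees cardiac motion, so the per-event *correlation error*
  (actual − predicted) inherits the cardiac term: extremes inflate toward
  ±pv/2 per projected axis while the mean stays at zero.
* **Dose.** An analytic spherical plan with an error-function penumbra,
  `D(r) = D_max·Φ((r50 − r)/σ)`, calibrated so the 70% isodose surface
  (radius 12.875 mm) carries exactly 420 cGy of a 600 cGy maximum.
  Delivery under motion is trajectory-occupancy averaging,
  `D_del(x) = (1/N)·Σ_t D_plan(x − m(t))`; for sine motion the
  infinite-sample limit is convolution with the closed-form arcsine
  occupancy kernel `p(u) = 1/(π√((pv/2)² − u²))`.
* **Film.** A rational net-optical-density calibration
  `D(od) = a + b·od/(1 − c·od)` fitted to 15 points over 0–1000 cGy, a
  forward 16-bit red-channel scanner model with granularity noise, and the
  inverse reconstruction.
* **Analyses.** Centroid error of the thresholded distribution on an
  orthogonal film pair, isodose-distance profiles (linear interpolation at
  90/80/70/50/20% of the plan maximum, 3 mm off the film slit), and gamma
  pass rates (2 mm/3%, 2 mm/2%, 1 mm/3%; global normalization, 10%
  threshold, 25 mm ROI, 2 mm slit exclusion), plus mean ± SD summaries
  across repetitions.  A fluoroscopic marker-tracking QA module (Otsu
  binarization, centre-of-mass, RMSE against the ideal sine) closes the
  loop on platform accuracy.

## Worked example

Blur the sagittal plan film with ten cycles of 5 mm cardiac motion and run
the analyses:

```r
library(cardioblur)

plan <- planModel()                                  # 600 cGy max
sag  <- renderPlanImage(plan, "sagittal", dpiToSpacing(75))
res  <- sampleTrajectory("cardiac_1d", cardiac = waveformParams(5, 1),
                         duration = 10)
del  <- blurWithTrajectory(sag, res, 2000, cyclePeriod = 1)

prPlan <- extractProfile(sag, "SI", 3)
prDel  <- extractProfile(del, "SI", 3)
for (pct in c(90, 80, 20))
  cat(sprintf("%d%%: plan %.2f mm, delivered %.2f mm\n", pct,
              isodoseDistance(prPlan, plan@dMax, pct),
              isodoseDistance(prDel,  plan@dMax, pct)))
#> 90%: plan 21.19 mm, delivered 19.70 mm
#> 80%: plan 23.46 mm, delivered 22.42 mm
#> 20%: plan 32.07 mm, delivered 33.11 mm

passRate(gammaPassRate(sag, del, dta = 2, ddPct = 3))
#> [1] 100
```

Reading: symmetric cardiac blur pulls the high isodose lines inward (the
90% distance shrinks by 1.5 mm, the 80% by 1.0 mm) and pushes the low ones
outward (the 20% distance grows by 1.0 mm) — the classic blurring
signature — while the centroid of the thresholded distribution stays put
and the 2 mm/3% gamma still passes everywhere.  The tracked-delivery
driver (`deliveredForCondition()`) runs the same analysis for any
respiratory / tracking / cardiac arm and attaches the residual trajectory
and correlation-error log to the result.

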