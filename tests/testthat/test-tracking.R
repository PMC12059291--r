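# Correlation-model tracking simulator: acquisition, linear fits, sliding
# 15-point window updates, error logs, and the residual trajectory.

resp20 <- waveformParams(20, 5)
dtFine <- 1 / 150

makeTrajs <- function(duration, cardiacPv = 5, phase = 0, angleDeg = 0) {
  resp <- sampleTrajectory("respiratory", resp = resp20, duration = duration,
                           dt = dtFine)
  card <- if (cardiacPv > 0) {
    kind <- if (angleDeg != 0) "cardiac_2d" else "cardiac_1d"
    sampleTrajectory(kind, cardiac = waveformParams(cardiacPv, 1, phase),
                     angleDeg = angleDeg, duration = duration, dt = dtFine)
  } else motionTrajectory(resp@times)
  target <- motionTrajectory(resp@times, resp@si + card@si, card@lr, 0)
  list(target = target, marker = resp)
}

test_that("model points are interpolated exactly at sample instants", {
  tj <- makeTrajs(20)
  t <- tj$target@times[c(10, 100, 500)]
  pts <- acquireModelPoints(tj$target, tj$marker, t)
  expect_equal(pts$si, tj$target@si[c(10, 100, 500)])
  expect_equal(pts$marker, tj$marker@si[c(10, 100, 500)])
  expect_error(acquireModelPoints(tj$target, tj$marker, c(-1, 5)), "outside")
})

test_that("without cardiac motion marker and target are perfectly collinear", {
  tj <- makeTrajs(20, cardiacPv = 0)
  pts <- acquireModelPoints(tj$target, tj$marker, seq(0.5, 19, length.out = 15))
  expect_equal(pts$si, pts$marker, tolerance = 1e-12)
  # and with cardiac on, the target is the closed-form sum at those instants
  tj2 <- makeTrajs(20, cardiacPv = 5, phase = 0.7)
  t <- seq(0.5, 19, length.out = 15)
  # snap to the sampling grid so interpolation is exact
  t <- round(t / dtFine) * dtFine
  pts2 <- acquireModelPoints(tj2$target, tj2$marker, t)
  expected <- respiratoryPosition(t, resp20) +
    cardiacPosition(t, waveformParams(5, 1, 0.7))
  expect_equal(pts2$si, expected, tolerance = 1e-9)
})

test_that("linear fit recovers a known line and rejects degenerate input", {
  marker <- seq(-10, 10, length.out = 15)
  pts <- data.frame(time = 1:15, marker = marker, si = 2 * marker + 1,
                    lr = 0, ap = 0)
  m <- fitCorrelationModel(pts)
  cf <- modelCoefficients(m)
  expect_equal(unname(cf["slope", "si"]), 2, tolerance = 1e-12)
  expect_equal(unname(cf["intercept", "si"]), 1, tolerance = 1e-12)
  # agrees with the explicit covariance-formula line fit
  oracle <- lineFitR(pts$marker, pts$si)
  expect_equal(unname(cf[, "si"]), unname(oracle), tolerance = 1e-10)
  pts$marker <- 3
  expect_error(fitCorrelationModel(pts), "degenerate")
})

test_that("noiseless respiratory-only fits predict exactly; cardiac residuals stay near +/- pv/2", {
  tj <- makeTrajs(80, cardiacPv = 0)
  t <- seq(2, 76, length.out = 15)
  m <- fitCorrelationModel(acquireModelPoints(tj$target, tj$marker, t))
  log <- correlationErrors(m, acquireModelPoints(tj$target, tj$marker,
                                                 seq(1, 79, by = 0.5)))
  expect_lt(max(abs(log$err_si_mm)), 1e-9)
  # cardiac on: in-window residuals are the cardiac term minus a small
  # fitted projection, confined near +/- 2.5 mm
  tj2 <- makeTrajs(80, cardiacPv = 5, phase = 1.3)
  pts2 <- acquireModelPoints(tj2$target, tj2$marker, t)
  m2 <- fitCorrelationModel(pts2)
  resid <- correlationErrors(m2, pts2)$err_si_mm
  expect_lt(max(resid), 2.9)
  expect_gt(min(resid), -2.9)
  expect_lt(abs(mean(resid)), 1e-9)     # OLS residuals have zero mean
})

test_that("3-point updates slide the 15-point window", {
  marker <- seq(-10, 10, length.out = 15)
  pts <- data.frame(time = 1:15, marker = marker, si = 2 * marker + 1,
                    lr = 0, ap = 0)
  m <- fitCorrelationModel(pts)
  # updating with points on the same trend leaves the fit unchanged
  newPts <- data.frame(time = 16:18, marker = c(-3, 0.5, 4),
                       si = 2 * c(-3, 0.5, 4) + 1, lr = 0, ap = 0)
  m2 <- updateCorrelationModel(m, newPts)
  expect_equal(modelCoefficients(m2), modelCoefficients(m), tolerance = 1e-10)
  expect_equal(nrow(modelWindow(m2)), 15L)
  expect_error(updateCorrelationModel(m, newPts[1:2, ]), "3 points")
  # five successive updates replace the entire window
  set.seed(5)
  cur <- m
  for (k in 1:5) {
    batch <- data.frame(time = 100 + 3 * k + (1:3),
                        marker = rnorm(3), si = 0, lr = 0, ap = 0)
    batch$si <- 5 * batch$marker - 2
    cur <- updateCorrelationModel(cur, batch)
  }
  expect_true(all(modelWindow(cur)$time > 100))
  expect_equal(unname(modelCoefficients(cur)["slope", "si"]), 5,
               tolerance = 1e-9)
  # a drifting baseline is tracked by the refit intercept
  drift <- data.frame(time = 1:15, marker = marker, si = 2 * marker + 1,
                      lr = 0, ap = 0)
  mD <- fitCorrelationModel(drift)
  shifted <- data.frame(time = 16:18, marker = c(-5, 0, 5),
                        si = 2 * c(-5, 0, 5) + 4, lr = 0, ap = 0)
  mD2 <- updateCorrelationModel(mD, shifted)
  win <- modelWindow(mD2)
  oracle <- lineFitR(win$marker, win$si)
  expect_equal(unname(modelCoefficients(mD2)[, "si"]), unname(oracle),
               tolerance = 1e-10)
  expect_gt(modelCoefficients(mD2)["intercept", "si"],
            modelCoefficients(mD)["intercept", "si"])
})

test_that("against an ideal respiratory model, error extremes converge to +/- pv/2", {
  # the model is fitted on cardiac-free points (exact respiratory map); the
  # imaged events then carry cardiac motion at effectively uniform phases, so
  # the per-event error IS the cardiac term: bounded by pv/2, zero mean
  tj0 <- makeTrajs(80, cardiacPv = 0)
  t <- round(seq(2, 76, length.out = 15) / dtFine) * dtFine
  m <- fitCorrelationModel(acquireModelPoints(tj0$target, tj0$marker, t))
  eventsFor <- function(pv, angleDeg = 0) {
    tj <- makeTrajs(80, cardiacPv = pv, phase = 0.9, angleDeg = angleDeg)
    et <- round(seq(0.5, 79, by = 0.173) / dtFine) * dtFine
    acquireModelPoints(tj$target, tj$marker, et)
  }
  log5 <- correlationErrors(m, eventsFor(5))
  expect_equal(max(log5$err_si_mm), 2.5, tolerance = 0.01)
  expect_equal(min(log5$err_si_mm), -2.5, tolerance = 0.01)
  expect_lt(abs(mean(log5$err_si_mm)), 0.05)
  expect_lt(max(abs(log5$err_lr_mm)), 1e-9)
  # extremes grow monotonically with the cardiac peak-to-valley
  log2 <- correlationErrors(m, eventsFor(2))
  expect_lt(max(log2$err_si_mm), max(log5$err_si_mm))
  expect_gt(min(log2$err_si_mm), min(log5$err_si_mm))
  expect_equal(max(log2$err_si_mm), 1.0, tolerance = 0.01)
  # 2D layout: LR errors approach +/- 1.75 mm (the 3.5 mm LR component)
  log2d <- correlationErrors(m, eventsFor(5, angleDeg = 35))
  expect_equal(max(log2d$err_lr_mm), 1.75, tolerance = 0.01)
  expect_equal(min(log2d$err_lr_mm), -1.75, tolerance = 0.01)
})

test_that("the full tracking pipeline inflates extremes in the motion direction, mean unchanged", {
  # with the model windows themselves contaminated by cardiac motion, the
  # extremes exceed +/- pv/2 by the fitted-extrapolation term, while the
  # mean error stays near zero and LR is untouched by 1D motion
  pool <- function(pv) {
    logs <- lapply(1:3, function(rep) {
      tj <- makeTrajs(600, cardiacPv = pv, phase = rep * 2.1)
      ev <- imagingEventTimes(600, seed = 100 + rep)
      buildModelSchedule(tj$target, tj$marker, ev)$log
    })
    do.call(rbind, logs)
  }
  log5 <- pool(5)
  expect_lt(abs(mean(log5$err_si_mm)), 0.15)
  expect_gt(max(log5$err_si_mm), 2.2)
  expect_lt(min(log5$err_si_mm), -2.2)
  expect_lt(max(abs(log5$err_lr_mm)), 1e-9)
  # extremes grow with the cardiac peak-to-valley
  log2 <- pool(2)
  expect_lt(max(log2$err_si_mm), max(log5$err_si_mm))
  expect_gt(min(log2$err_si_mm), min(log5$err_si_mm))
})

test_that("residual trajectory matches direct target-minus-prediction subtraction", {
  tj <- makeTrajs(200, cardiacPv = 5, phase = 0.4)
  ev <- imagingEventTimes(200, seed = 11)
  sched <- buildModelSchedule(tj$target, tj$marker, ev)
  r <- residualTrajectory(tj$target, tj$marker, sched)
  # oracle: apply each active model's coefficients by hand
  mods <- sched$models
  idx <- findInterval(r@times, mods$tStart)
  cfList <- lapply(sched$fits, modelCoefficients)
  markerAt <- approx(tj$marker@times, tj$marker@si, r@times)$y
  targetAt <- approx(tj$target@times, tj$target@si, r@times)$y
  pred <- vapply(seq_along(idx), function(k) {
    cf <- cfList[[idx[k]]]
    cf["intercept", "si"] + cf["slope", "si"] * markerAt[k]
  }, 0)
  expect_equal(r@si, targetAt - pred, tolerance = 1e-9)
  # residual peak-to-valley: cardiac pv plus a bounded model perturbation
  expect_gte(peakToValley(r@si), 5 - 1e-6)
  expect_lt(peakToValley(r@si), 7)
  # tracking off reproduces the target; perfect tracking kills respiration
  off <- residualTrajectory(tj$target)
  expect_equal(off@si, tj$target@si)
  tj0 <- makeTrajs(200, cardiacPv = 0)
  sched0 <- buildModelSchedule(tj0$target, tj0$marker, ev)
  r0 <- residualTrajectory(tj0$target, tj0$marker, sched0)
  expect_lt(max(abs(r0@si)), 1e-9)
  expect_error(residualTrajectory(tj0$target, tj0$marker, sched0,
                                  from = 0, to = 10), "covered")
})

test_that("error-log summary and CSV writer round-trip", {
  log <- data.frame(t_s = 1:4, err_si_mm = c(-1, 0, 1, 2),
                    err_lr_mm = 0, err_ap_mm = c(0.5, -0.5, 0, 0))
  s <- correlationErrorSummary(log)
  expect_equal(s$mean[s$axis == "si"], 0.5)
  expect_equal(s$max[s$axis == "si"], 2)
  expect_equal(s$min[s$axis == "ap"], -0.5)
  f <- tempfile(fileext = ".csv")
  writeCorrelationLog(log, f)
  expect_equal(read.csv(f), log)
})
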