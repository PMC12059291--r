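# Motion-blurred delivery: trajectory-occupancy averaging of the planned
# dose, the closed-form arcsine occupancy kernel of sinusoidal motion, and
# the per-condition delivery driver.

#' Blur a planned dose image with a residual motion trajectory
#'
#' First-order motion model for a constant dose rate: the delivered dose is
#' the time average of the plan shifted by the in-plane projection of the
#' residual displacement,
#' \deqn{D_{del}(x) = \frac{1}{N}\sum_t D_{plan}(x - m(t)).}
#' The residual is resampled at `nTimeSamples` uniform instants across its
#' span (half-open, so whole periodic cycles are covered without double
#' counting); fractional shifts use bilinear interpolation with nearest-edge
#' extension.  The film sees its two in-plane axes: (LR, AP) for an axial
#' film, (SI, AP) for a sagittal film.
#'
#' @param planImg planned [DoseImage-class]
#' @param residual residual `MotionTrajectory` (uncompensated displacement);
#'   should span an integer number of cardiac cycles when cardiac motion is
#'   present (pass `cyclePeriod` to check)
#' @param nTimeSamples number of quadrature time samples, >= 100
#' @param cyclePeriod optional cardiac period (s); a warning is raised when
#'   the residual span is not an integer multiple
#' @return the delivered `DoseImage`
#' @export
blurWithTrajectory <- function(planImg, residual, nTimeSamples = 2000,
                               cyclePeriod = NULL) {
  stopifnot(is(planImg, "DoseImage"), is(residual, "MotionTrajectory"))
  if (nTimeSamples < 100) stop("nTimeSamples must be >= 100")
  span <- diff(range(residual@times))
  if (span <= 0) stop("residual trajectory must span a positive duration")
  if (!is.null(cyclePeriod)) {
    frac <- (span / cyclePeriod) %% 1
    if (min(frac, 1 - frac) > 1e-6)
      warning("residual span (", signif(span, 6),
              " s) is not an integer number of cardiac cycles")
  }
  t <- residual@times[1] + (seq_len(nTimeSamples) - 1) * span / nTimeSamples
  m <- interpTraj(residual, t)
  inPlane <- switch(planImg@plane,
    axial = list(x = m$lr, y = m$ap),
    sagittal = list(x = m$si, y = m$ap))
  extent <- dim(planImg@dose) * planImg@spacing
  if (max(abs(inPlane$x)) >= extent[2] || max(abs(inPlane$y)) >= extent[1])
    stop("motion shift exceeds the dose-grid extent")
  out <- .blurAccumulate(planImg@dose, inPlane$x / planImg@spacing,
                         inPlane$y / planImg@spacing)
  doseImage(out, planImg@spacing, planImg@plane, planImg@slitWidth)
}

#' Arcsine occupancy kernel of sinusoidal motion
#'
#' A point oscillating as \eqn{u(t) = (pv/2)\sin\theta} with uniform phase
#' occupies position u with density \eqn{p(u) = 1/(\pi\sqrt{(pv/2)^2 - u^2})}
#' on \eqn{|u| < pv/2}.  The kernel discretises this density by exact
#' integration over pixel bins (\eqn{\int p = (\arcsin(b/h)-\arcsin(a/h))/\pi}),
#' so it sums to 1 and is symmetric; blurring a profile with it is the
#' infinite-sample limit of [blurWithTrajectory()] for pure sine motion.
#'
#' @param pv peak-to-valley displacement (mm), >= 0
#' @param spacing pixel spacing (mm)
#' @return numeric vector of odd length with unit sum, centred on zero shift;
#'   the identity kernel (`1`) when `pv < spacing`
#' @export
arcsineKernel <- function(pv, spacing) {
  if (pv < 0) stop("pv must be >= 0")
  if (pv < spacing) return(1)
  h <- pv / 2
  m <- ceiling(h / spacing + 0.5)
  centers <- (-m:m) * spacing
  lo <- pmax(pmin(centers - spacing / 2, h), -h)
  hi <- pmax(pmin(centers + spacing / 2, h), -h)
  k <- (asin(hi / h) - asin(lo / h)) / pi
  k <- k[k > 0 | rev(k) > 0]          # trim empty tails, keep symmetry
  k / sum(k)
}

#' Delivered dose for a named motion/tracking condition
#'
#' Reproduces the experimental arms: with tracking off the residual is the
#' full target motion; with tracking on, a surrogate trajectory and a
#' periodically refitted linear correlation model are simulated first
#' ([buildModelSchedule()]) and the residual is target minus prediction.
#' Tracking requires respiratory motion.  The cardiac phase and the
#' imaging-event jitter are drawn from `seed`, making the delivery
#' deterministic given the seed.
#'
#' @param planImg planned [DoseImage-class]
#' @param resp logical: respiratory motion on?
#' @param tracking logical: respiratory motion tracking on?
#' @param cardiac `"off"`, `"1d"` (SI) or `"2d"` (SI + LR via the 35-degree
#'   layout)
#' @param seed RNG seed for the cardiac phase and imaging jitter
#' @param duration delivery duration (s), integer seconds keep whole cardiac
#'   cycles
#' @param nTimeSamples quadrature samples for the blur
#' @param cardiacPv,cardiacPeriod cardiac peak-to-valley SI component (mm)
#'   and period (s)
#' @param angleDeg 2D-layout inclination (degrees)
#' @param respParams respiratory [waveformParams()]
#' @return the delivered `DoseImage`; the residual trajectory and (when
#'   tracking) the correlation-error log are attached as attributes
#'   `"residual"` and `"trackingLog"`
#' @export
deliveredForCondition <- function(planImg, resp = FALSE, tracking = FALSE,
                                  cardiac = c("off", "1d", "2d"), seed = 1,
                                  duration = 60, nTimeSamples = 2000,
                                  cardiacPv = 5, cardiacPeriod = 1,
                                  angleDeg = 35,
                                  respParams = waveformParams(20, 5)) {
  cardiac <- match.arg(cardiac)
  if (tracking && !resp)
    stop("inconsistent condition: tracking requires respiratory motion")
  dt <- 1 / 150
  phase <- withSeed(seed, runif(1, 0, 2 * pi))
  cardP <- waveformParams(cardiacPv, cardiacPeriod, phase)
  lead <- if (tracking) 80 else 0   # room for the initial 15-point model
  total <- lead + duration
  zero <- motionTrajectory(seq(0, total, by = dt))
  cardTraj <- switch(cardiac,
    off = zero,
    "1d" = sampleTrajectory("cardiac_1d", cardiac = cardP, duration = total,
                            dt = dt),
    "2d" = sampleTrajectory("cardiac_2d", cardiac = cardP,
                            angleDeg = angleDeg, duration = total, dt = dt))
  respTraj <- if (resp)
    sampleTrajectory("respiratory", resp = respParams, duration = total,
                     dt = dt)
  else zero
  target <- motionTrajectory(cardTraj@times, cardTraj@si + respTraj@si,
                             cardTraj@lr + respTraj@lr,
                             cardTraj@ap + respTraj@ap)
  log <- NULL
  if (tracking) {
    events <- imagingEventTimes(total, seed = seed + 1L)
    sched <- buildModelSchedule(target, respTraj, events)
    # snap the delivery window to the sampling grid so it spans exactly
    # `duration` seconds (whole cardiac cycles for integer durations)
    t0 <- ceiling((sched$models$tStart[1] + 1e-9) / dt) * dt
    residual <- residualTrajectory(target, respTraj, sched, from = t0,
                                   to = t0 + duration)
    log <- sched$log
  } else {
    residual <- residualTrajectory(target, from = 0, to = duration)
  }
  out <- blurWithTrajectory(planImg, residual, nTimeSamples,
                            cyclePeriod = if (cardiac != "off") cardiacPeriod)
  attr(out, "residual") <- residual
  attr(out, "trackingLog") <- log
  out
}
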