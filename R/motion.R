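# Motion models: cos^6 respiratory waveform, sinusoidal cardiac waveform,
# inclined-platform projection, and trajectory sampling.

#' Respiratory position at time t (Lujan-type cos^6 waveform)
#'
#' \deqn{P(t) = P_0 - A \cos^6(\pi t / \tau - \phi)}
#' where \eqn{P_0} is the exhale (baseline) position, \eqn{A} the waveform
#' depth (peak-to-valley), \eqn{\tau} the period and \eqn{\phi} the initial
#' phase.  The waveform is bounded in \eqn{[P_0 - A, P_0]}: the target rests
#' near exhale and makes brief excursions towards inhale, the standard
#' asymmetric breathing model.  Study defaults: A = 20 mm, tau = 5 s, phi = 0.
#'
#' @param t time (s), vectorised
#' @param p a [waveformParams()] object: `amplitudePv` = A, `period` = tau,
#'   `phase` = phi, `baseline` = P0
#' @return position (mm), positive = superior
#' @export
#' @examples
#' p <- waveformParams(20, 5)
#' respiratoryPosition(0, p)     # -20, inhale extreme
#' respiratoryPosition(2.5, p)   # 0, exhale
respiratoryPosition <- function(t, p) {
  stopifnot(is(p, "WaveformParams"))
  if (!all(is.finite(t))) stop("t must be finite")
  p@baseline - p@amplitudePv * cos(pi * t / p@period - p@phase)^6
}

#' Cardiac position at time t (sine waveform)
#'
#' \deqn{x(t) = (pv/2) \sin(2\pi t / T + \phi)}
#' Displacement along the cardiac platform axis, symmetric about the middle
#' position (0).  Study defaults: 5 mm peak-to-valley, 1 s cycle.
#'
#' @inheritParams respiratoryPosition
#' @return displacement along the platform axis (mm)
#' @export
#' @examples
#' cardiacPosition(0.25, waveformParams(5, 1))   # +2.5 mm, sine peak
cardiacPosition <- function(t, p) {
  stopifnot(is(p, "WaveformParams"))
  if (!all(is.finite(t))) stop("t must be finite")
  p@baseline + (p@amplitudePv / 2) * sin(2 * pi * t / p@period + p@phase)
}

#' Project an inclined-axis displacement onto the SI/LR axes
#'
#' The 2D cardiac layout inclines the platform axis by `angleDeg` from the SI
#' axis towards the patient right/left, so a displacement d along the axis
#' contributes `d cos(angle)` SI and `d sin(angle)` LR.  The Euclidean norm is
#' preserved.
#'
#' @param axisDisplacement displacement along the platform axis (mm),
#'   vectorised
#' @param angleDeg inclination angle (degrees), in (-90, 90)
#' @return list with components `si` and `lr` (mm)
#' @export
#' @examples
#' # a 5 mm SI component at 35 degrees carries a 3.5 mm LR component
#' projectToSiLr(5 / cos(35 * pi / 180), 35)
projectToSiLr <- function(axisDisplacement, angleDeg) {
  if (!is.finite(angleDeg) || angleDeg <= -90 || angleDeg >= 90)
    stop("angleDeg must lie in (-90, 90)")
  a <- angleDeg * pi / 180
  list(si = axisDisplacement * cos(a), lr = axisDisplacement * sin(a))
}

#' Sample a motion trajectory on a uniform time grid
#'
#' Builds the discretised trajectories used throughout the pipeline.
#' Respiratory motion acts on SI only; cardiac motion acts on SI (1D layout)
#' or on SI and LR via the inclined platform axis (2D layout); AP is 0 for
#' the phantom stage.  `combined` is the componentwise sum of the cardiac and
#' respiratory parts.
#'
#' @param kind one of `"cardiac_1d"`, `"cardiac_2d"`, `"respiratory"`,
#'   `"combined"`
#' @param cardiac [waveformParams()] for the cardiac sine; `amplitudePv` is
#'   the SI peak-to-valley component (the along-axis excursion in the 2D
#'   layout is `amplitudePv / cos(angle)`)
#' @param resp [waveformParams()] for the respiratory waveform
#' @param angleDeg platform inclination (degrees) used by `cardiac_2d` (and
#'   by `combined` when non-zero)
#' @param duration trajectory length (s), > 0
#' @param dt sample interval (s), > 0; default 1/150 s (10x the 15 fps
#'   fluoroscopy rate)
#' @return a [MotionTrajectory-class] sampled at `seq(0, duration, by = dt)`
#' @export
#' @examples
#' tr <- sampleTrajectory("cardiac_2d", cardiac = waveformParams(5, 1),
#'                        angleDeg = 35, duration = 2)
#' peakToValley(tr@si)  # 5 mm
#' peakToValley(tr@lr)  # 3.5 mm
sampleTrajectory <- function(kind, cardiac = waveformParams(5, 1),
                             resp = waveformParams(20, 5), angleDeg = 35,
                             duration, dt = 1 / 150) {
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  t <- seq(0, duration, by = dt)
  zero <- numeric(length(t))
  comp <- switch(kind,
    cardiac_1d = {
      list(si = cardiacPosition(t, cardiac), lr = zero)
    },
    cardiac_2d = {
      axisPv <- cardiac@amplitudePv / cos(angleDeg * pi / 180)
      axisP <- waveformParams(axisPv, cardiac@period, cardiac@phase,
                              cardiac@baseline)
      projectToSiLr(cardiacPosition(t, axisP), angleDeg)
    },
    respiratory = list(si = respiratoryPosition(t, resp), lr = zero),
    combined = {
      card <- if (angleDeg != 0) {
        axisPv <- cardiac@amplitudePv / cos(angleDeg * pi / 180)
        axisP <- waveformParams(axisPv, cardiac@period, cardiac@phase,
                                cardiac@baseline)
        projectToSiLr(cardiacPosition(t, axisP), angleDeg)
      } else {
        list(si = cardiacPosition(t, cardiac), lr = zero)
      }
      list(si = card$si + respiratoryPosition(t, resp), lr = card$lr)
    },
    stop("unknown trajectory kind: ", kind)
  )
  motionTrajectory(t, si = comp$si, lr = comp$lr, ap = 0)
}

#' Peak-to-valley distance of a displacement series
#'
#' @param values displacement samples (mm), non-empty
#' @return `max(values) - min(values)` (mm)
#' @export
peakToValley <- function(values) {
  if (length(values) == 0) stop("peakToValley: empty input")
  if (!all(is.finite(values))) stop("peakToValley: non-finite values")
  max(values) - min(values)
}

#' Read or write a trajectory as CSV
#'
#' Dialect: header `t_s,si_mm,lr_mm,ap_mm`, one row per sample.
#'
#' @param traj a `MotionTrajectory`
#' @param path file path
#' @return `readTrajectory` returns a `MotionTrajectory`; `writeTrajectory`
#'   returns `path` invisibly
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(is(traj, "MotionTrajectory"))
  write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  d <- read.csv(path)
  motionTrajectory(d$t_s, si = d$si_mm, lr = d$lr_mm, ap = d$ap_mm)
}

#' Read a motion configuration file (YAML or JSON)
#'
#' Recognised keys: `cardiac.pv_mm`, `cardiac.period_s`, `layout.angle_deg`,
#' `resp.A_mm`, `resp.tau_s`, `resp.phi_rad`.  Missing keys fall back to the
#' study defaults (5 mm / 1 s cardiac, 35 degrees, 20 mm / 5 s / 0 rad
#' respiratory).
#'
#' @param path path to a YAML or JSON file
#' @return list with components `cardiac` and `resp` ([waveformParams()]
#'   objects) and `angleDeg`
#' @export
readMotionConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  pick <- function(x, key, default) if (!is.null(x[[key]])) x[[key]] else default
  list(
    cardiac = waveformParams(pick(cfg$cardiac, "pv_mm", 5),
                             pick(cfg$cardiac, "period_s", 1)),
    resp = waveformParams(pick(cfg$resp, "A_mm", 20),
                          pick(cfg$resp, "tau_s", 5),
                          pick(cfg$resp, "phi_rad", 0)),
    angleDeg = pick(cfg$layout, "angle_deg", 35)
  )
}
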