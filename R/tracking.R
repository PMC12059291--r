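# Respiratory-tracking correlation-model simulator: paired marker/target
# acquisitions, per-axis linear fits over a sliding 15-point window, periodic
# 3-point refits, correlation-error logging, and the residual (uncompensated)
# trajectory fed to the blur simulator.

interpTraj <- function(traj, times) {
  rng <- range(traj@times)
  if (any(times < rng[1] - 1e-9) || any(times > rng[2] + 1e-9))
    stop("requested times fall outside the trajectory span")
  data.frame(
    time = times,
    si = approx(traj@times, traj@si, times, rule = 2)$y,
    lr = approx(traj@times, traj@lr, times, rule = 2)$y,
    ap = approx(traj@times, traj@ap, times, rule = 2)$y
  )
}

#' Acquire paired model points from target and marker trajectories
#'
#' Emulates simultaneous kV imaging of the target and optical acquisition of
#' the surrogate marker: both trajectories are linearly interpolated at the
#' requested instants.  The surrogate signal is the marker trajectory's SI
#' component (the marker is a perfect respiratory surrogate; it does not see
#' cardiac motion).
#'
#' @param trajTarget target `MotionTrajectory` (respiratory + cardiac)
#' @param trajMarker surrogate-marker `MotionTrajectory` (respiratory only)
#' @param times acquisition instants (s), within both trajectory spans
#' @return data.frame of model points: `time`, `marker`, `si`, `lr`, `ap`
#' @export
acquireModelPoints <- function(trajTarget, trajMarker, times) {
  stopifnot(is(trajTarget, "MotionTrajectory"), is(trajMarker, "MotionTrajectory"))
  tg <- interpTraj(trajTarget, times)
  mk <- interpTraj(trajMarker, times)
  data.frame(time = times, marker = mk$si, si = tg$si, lr = tg$lr, ap = tg$ap)
}

#' Fit the linear correlation model
#'
#' Ordinary least-squares line per axis (target component versus marker
#' signal) over the supplied model points; at most the latest 15 points are
#' retained as the model window.
#'
#' @param points data.frame as returned by [acquireModelPoints()]
#' @return a [CorrelationModel-class]
#' @export
fitCorrelationModel <- function(points) {
  points <- tail(points, 15L)
  if (nrow(points) < 2L || length(unique(points$marker)) < 2L)
    stop("degenerate model points: need >= 2 distinct marker values")
  cf <- vapply(c("si", "lr", "ap"), function(ax) {
    coef(lm(points[[ax]] ~ points$marker))
  }, numeric(2))
  dimnames(cf) <- list(c("intercept", "slope"), c("si", "lr", "ap"))
  new("CorrelationModel", coefficients = cf, window = points)
}

#' Update the correlation model with a new 3-point batch
#'
#' Drops the oldest 3 points of the window, appends the 3 new points and
#' refits, keeping the window at 15 points (the periodic update performed
#' every 60 s during tracking).
#'
#' @param model a `CorrelationModel`
#' @param newPoints data.frame of exactly 3 model points
#' @return the refitted `CorrelationModel`
#' @export
updateCorrelationModel <- function(model, newPoints) {
  stopifnot(is(model, "CorrelationModel"))
  if (nrow(newPoints) != 3L)
    stop("model updates replace exactly 3 points, got ", nrow(newPoints))
  win <- rbind(model@window[-(1:3), , drop = FALSE], newPoints)
  fitCorrelationModel(win)
}

#' Predict the target position from a marker signal
#'
#' @param model a `CorrelationModel`
#' @param marker surrogate signal values (mm), vectorised
#' @return data.frame with columns `si`, `lr`, `ap` (mm)
#' @export
predictTarget <- function(model, marker) {
  stopifnot(is(model, "CorrelationModel"))
  cf <- model@coefficients
  data.frame(si = cf["intercept", "si"] + cf["slope", "si"] * marker,
             lr = cf["intercept", "lr"] + cf["slope", "lr"] * marker,
             ap = cf["intercept", "ap"] + cf["slope", "ap"] * marker)
}

#' Correlation errors at imaging events
#'
#' Error = actual target position minus model prediction, per axis per event.
#' A positive SI error means the imaged target lies further superior than the
#' model predicts.
#'
#' @param model a fitted `CorrelationModel`
#' @param events data.frame of model points (the imaged events)
#' @return data.frame: `t_s`, `err_si_mm`, `err_lr_mm`, `err_ap_mm`
#' @export
correlationErrors <- function(model, events) {
  pred <- predictTarget(model, events$marker)
  data.frame(t_s = events$time,
             err_si_mm = events$si - pred$si,
             err_lr_mm = events$lr - pred$lr,
             err_ap_mm = events$ap - pred$ap)
}

#' Summarise a correlation-error log
#'
#' @param log data.frame as returned by [correlationErrors()]
#' @return data.frame with one row per axis and columns `axis`, `mean`,
#'   `max`, `min` (mm)
#' @export
correlationErrorSummary <- function(log) {
  ax <- c(si = "err_si_mm", lr = "err_lr_mm", ap = "err_ap_mm")
  data.frame(axis = names(ax),
             mean = vapply(ax, function(a) mean(log[[a]]), 0),
             max = vapply(ax, function(a) max(log[[a]]), 0),
             min = vapply(ax, function(a) min(log[[a]]), 0),
             row.names = NULL)
}

#' Write a correlation-error log as CSV
#'
#' Dialect: header `t_s,err_si_mm,err_lr_mm,err_ap_mm`.
#' @param log data.frame as returned by [correlationErrors()]
#' @param path file path
#' @export
writeCorrelationLog <- function(log, path) {
  write.csv(log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Imaging-event times over a treatment interval
#'
#' Uniform spacing with optional Gaussian jitter.  The imaging cadence of the
#' tracking system is a free parameter; the default of 3.7 s is deliberately
#' incommensurate with the 5 s respiratory period, so successive events sweep
#' the breathing cycle instead of resampling one phase (a cadence equal to
#' the respiratory period makes the surrogate signal nearly constant across
#' the model window and the linear fit rank-deficient).
#'
#' @param duration total interval (s)
#' @param interval nominal spacing (s)
#' @param jitterSd jitter standard deviation (s)
#' @param seed optional RNG seed
#' @return increasing event times in (0, duration)
#' @export
imagingEventTimes <- function(duration, interval = 3.7, jitterSd = 0.5,
                              seed = NULL) {
  nominal <- seq(interval, duration - 1e-9, by = interval)
  withSeed(seed, {
    t <- nominal + rnorm(length(nominal), 0, jitterSd)
    sort(pmin(pmax(t, 1e-3), duration - 1e-3))
  })
}

#' Build the model schedule over a treatment course
#'
#' The initial model is fitted to the first 15 imaging events; thereafter the
#' model is refitted every `updateEvery` seconds using the latest 3 events
#' (dropping the oldest 3 of the 15-point window).  Correlation errors are
#' logged at every imaging event under the model active at that instant.
#'
#' @param trajTarget,trajMarker target and surrogate trajectories
#' @param eventTimes imaging-event times (s), e.g. [imagingEventTimes()]
#' @param updateEvery refit cadence (s), default 60
#' @return list with `models` (data.frame `tStart`, `tEnd` plus a parallel
#'   list of `CorrelationModel`s in attribute-free form: component `fits`),
#'   and `log`, the pooled correlation-error log
#' @export
buildModelSchedule <- function(trajTarget, trajMarker, eventTimes,
                               updateEvery = 60) {
  if (length(eventTimes) < 15L)
    stop("need at least 15 imaging events to build the initial model")
  ev <- acquireModelPoints(trajTarget, trajMarker, eventTimes)
  model <- fitCorrelationModel(ev[1:15, ])
  tReady <- eventTimes[15]
  fits <- list(model)
  starts <- tReady
  log <- correlationErrors(model, ev[1:15, ])
  nextUpdate <- tReady + updateEvery
  pending <- NULL
  for (k in seq(16, length.out = max(0, length(eventTimes) - 15))) {
    log <- rbind(log, correlationErrors(model, ev[k, , drop = FALSE]))
    pending <- rbind(pending, ev[k, , drop = FALSE])
    if (eventTimes[k] >= nextUpdate && nrow(pending) >= 3L) {
      model <- updateCorrelationModel(model, tail(pending, 3L))
      fits <- c(fits, model)
      starts <- c(starts, eventTimes[k])
      pending <- NULL
      nextUpdate <- nextUpdate + updateEvery
    }
  }
  ends <- c(starts[-1], max(max(eventTimes), tail(trajTarget@times, 1)))
  list(models = data.frame(tStart = starts, tEnd = ends), fits = fits,
       log = log)
}

#' Residual (uncompensated) motion under a tracking schedule
#'
#' The robot follows the correlation-model prediction, so the displacement
#' that blurs the dose is the target position minus the prediction under the
#' model active at each instant.  With tracking off, pass `schedule = NULL`:
#' the residual is then the full target motion.  With perfect tracking and no
#' cardiac motion the residual is identically 0.
#'
#' @param trajTarget target `MotionTrajectory`
#' @param trajMarker surrogate `MotionTrajectory` (ignored when
#'   `schedule = NULL`)
#' @param schedule a model schedule from [buildModelSchedule()], or `NULL`
#' @param from,to time window (s); defaults to the schedule coverage (or the
#'   full target span when `schedule = NULL`)
#' @return a `MotionTrajectory` of residual displacements
#' @export
residualTrajectory <- function(trajTarget, trajMarker = NULL, schedule = NULL,
                               from = NULL, to = NULL) {
  stopifnot(is(trajTarget, "MotionTrajectory"))
  if (is.null(schedule)) {
    keep <- rep(TRUE, length(trajTarget@times))
    if (!is.null(from)) keep <- keep & trajTarget@times >= from - 1e-9
    if (!is.null(to)) keep <- keep & trajTarget@times <= to + 1e-9
    return(motionTrajectory(trajTarget@times[keep], trajTarget@si[keep],
                            trajTarget@lr[keep], trajTarget@ap[keep]))
  }
  stopifnot(is(trajMarker, "MotionTrajectory"))
  mods <- schedule$models
  if (is.null(from)) from <- mods$tStart[1]
  if (is.null(to)) to <- tail(mods$tEnd, 1)
  if (from < mods$tStart[1] - 1e-9 || to > tail(mods$tEnd, 1) + 1e-9)
    stop("requested window is not covered by the model schedule")
  keep <- trajTarget@times >= from - 1e-9 & trajTarget@times <= to + 1e-9
  t <- trajTarget@times[keep]
  mk <- interpTraj(trajMarker, t)
  # piecewise-constant model parameters: model i active on [tStart_i, tEnd_i)
  idx <- findInterval(t, mods$tStart, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  si <- lr <- ap <- numeric(length(t))
  for (i in unique(idx)) {
    sel <- idx == i
    pred <- predictTarget(schedule$fits[[i]], mk$si[sel])
    si[sel] <- trajTarget@si[keep][sel] - pred$si
    lr[sel] <- trajTarget@lr[keep][sel] - pred$lr
    ap[sel] <- trajTarget@ap[keep][sel] - pred$ap
  }
  motionTrajectory(t, si, lr, ap)
}
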