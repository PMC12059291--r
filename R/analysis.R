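# The three film analyses: centroid error of the thresholded dose
# distribution, isodose-distance profiles, and global-normalization gamma
# pass rates, plus mean +/- SD summaries across repetitions.

#' Centroid error of an orthogonal film pair
#'
#' Per film, the dose distribution is thresholded at `thresholdFrac` of its
#' maximum (slit band excluded), and the unweighted centroid of the binary
#' mask is compared with the film centre (which coincides with the planned
#' centroid).  The SI component is read from the sagittal film, LR from the
#' axial film, and AP (present on both films) is averaged.
#'
#' @param axial,sagittal the two [DoseImage-class] films, sharing the phantom
#'   centre as origin
#' @param thresholdFrac mask threshold as a fraction of the film maximum
#'   (default 0.5)
#' @param weighted use a dose-weighted centroid instead of the unweighted
#'   mask centroid
#' @return list with components `si`, `lr`, `ap` (mm)
#' @export
centroidError <- function(axial, sagittal, thresholdFrac = 0.5,
                          weighted = FALSE) {
  stopifnot(is(axial, "DoseImage"), is(sagittal, "DoseImage"))
  if (axial@plane != "axial" || sagittal@plane != "sagittal")
    stop("pass the axial film first and the sagittal film second")
  one <- function(img) {
    d <- img@dose
    keep <- d >= thresholdFrac * max(d) & !slitMask(img, img@slitWidth)
    if (!any(keep)) stop("empty centroid mask")
    x <- pixelCoords(ncol(d), img@spacing)
    y <- pixelCoords(nrow(d), img@spacing)
    w <- if (weighted) d * keep else keep * 1
    sw <- sum(w)
    c(x = sum(t(w) * x) / sw, y = sum(w * y) / sw)
  }
  ax <- one(axial)      # x = LR, y = AP
  sg <- one(sagittal)   # x = SI, y = AP
  list(si = unname(sg["x"]), lr = unname(ax["x"]),
       ap = unname((ax["y"] + sg["y"]) / 2))
}

#' Centroid displacement attributable to cardiac motion
#'
#' Componentwise difference of the centroid error with cardiac motion minus
#' the centroid error without, isolating the cardiac effect from the shared
#' systematic errors of the delivery chain.
#'
#' @param withCardiac,without centroid errors (lists with `si`, `lr`, `ap`)
#' @return list with components `si`, `lr`, `ap` (mm)
#' @export
centroidDisplacement <- function(withCardiac, without) {
  list(si = withCardiac$si - without$si,
       lr = withCardiac$lr - without$lr,
       ap = withCardiac$ap - without$ap)
}

#' Extract a dose profile parallel to the slit
#'
#' Returns the dose row nearest the line parallel to the requested direction
#' at `offset` mm from the film centre slit (3 mm by default, clear of the
#' slit and the interlocking film edge).  SI profiles live on the sagittal
#' film, LR profiles on the axial film.
#'
#' @param img a [DoseImage-class]
#' @param direction `"SI"` or `"LR"`
#' @param offset perpendicular offset from the slit centre line (mm)
#' @return data.frame with columns `pos` (mm along the profile) and `dose`
#'   (cGy); the realised offset is attached as attribute `"offset"`
#' @export
extractProfile <- function(img, direction = c("SI", "LR"), offset = 3) {
  direction <- match.arg(direction)
  stopifnot(is(img, "DoseImage"))
  needed <- if (direction == "SI") "sagittal" else "axial"
  if (img@plane != needed)
    stop(direction, " profiles require the ", needed, " film")
  y <- pixelCoords(nrow(img@dose), img@spacing)
  if (offset < min(y) || offset > max(y))
    stop("offset line lies outside the image")
  row <- which.min(abs(y - offset))
  out <- data.frame(pos = pixelCoords(ncol(img@dose), img@spacing),
                    dose = img@dose[row, ])
  attr(out, "offset") <- y[row]
  out
}

#' Distance between isodose crossings on a profile
#'
#' The isodose level is `pct` percent of `reference` (conventionally the
#' plan maximum dose).  The two crossings of a single-peaked profile are
#' located by linear interpolation between the two samples bracketing the
#' level on each side; the returned distance is right crossing minus left
#' crossing.
#'
#' @param profile data.frame with columns `pos`, `dose` (from
#'   [extractProfile()])
#' @param reference reference dose (cGy) that `pct` refers to
#' @param pct isodose level (% of `reference`)
#' @return isodose distance (mm)
#' @export
isodoseDistance <- function(profile, reference, pct) {
  level <- pct / 100 * reference
  dose <- profile$dose
  pos <- profile$pos
  above <- dose >= level
  cross <- which(diff(above) != 0)
  if (length(cross) != 2L)
    stop("profile crosses the ", pct, "% level ", length(cross),
         " times (need exactly 2)")
  interp <- function(i) {
    pos[i] + (level - dose[i]) * (pos[i + 1] - pos[i]) / (dose[i + 1] - dose[i])
  }
  interp(cross[2]) - interp(cross[1])
}

#' Gamma analysis with global normalization
#'
#' For every evaluable reference point, \eqn{\gamma} is the minimum over a
#' search disc of \eqn{\sqrt{(\Delta r/\mathrm{DTA})^2 +
#' (\Delta D/(\mathrm{DD}\cdot D_{norm}))^2}}, where the evaluated
#' distribution is bilinearly interpolated on a lattice of step
#' `dta / 10` (bounding the discretization error well below half a pass-rate
#' point) with search radius `3 * dta`.  The normalization is the reference
#' (plan) maximum.  Points below `thresholdPct` of the normalization, outside
#' the central `roiMm` box, or within `slitExclusionMm` of the film slit are
#' excluded.  Study criteria: 2 mm/3%, 2 mm/2%, 1 mm/3%, threshold 10%,
#' 25 mm ROI, 2 mm slit exclusion.
#'
#' @param ref reference (planned) [DoseImage-class]
#' @param eval evaluated (delivered) `DoseImage`, co-registered with `ref`
#' @param dta distance-to-agreement (mm)
#' @param ddPct dose-difference criterion (% of the normalization)
#' @param thresholdPct low-dose threshold (% of the normalization)
#' @param roiMm edge length of the central square ROI (mm)
#' @param slitExclusionMm half-width of the slit exclusion band (mm)
#' @param step search lattice step (mm); default `dta / 10`
#' @param searchRadius search radius (mm); default `3 * dta`
#' @return a [GammaResult-class]
#' @export
gammaPassRate <- function(ref, eval, dta, ddPct, thresholdPct = 10,
                          roiMm = 25, slitExclusionMm = 2,
                          step = dta / 10, searchRadius = 3 * dta) {
  stopifnot(is(ref, "DoseImage"), is(eval, "DoseImage"))
  if (!identical(dim(ref@dose), dim(eval@dose)) ||
      abs(ref@spacing - eval@spacing) > 1e-9)
    stop("reference and evaluated images must share grid and spacing")
  norm <- max(ref@dose)
  x <- pixelCoords(ncol(ref@dose), ref@spacing)
  y <- pixelCoords(nrow(ref@dose), ref@spacing)
  inRoi <- outer(abs(y) <= roiMm / 2, abs(x) <= roiMm / 2, "&")
  nearSlit <- matrix(abs(y) <= slitExclusionMm, length(y), length(x))
  evaluate <- inRoi & !nearSlit & ref@dose >= thresholdPct / 100 * norm
  if (!any(evaluate)) stop("no evaluable points")
  g <- .gammaCore(ref@dose, eval@dose, ref@spacing, dta, ddPct / 100 * norm,
                  evaluate, step, searchRadius)
  vals <- g[evaluate]
  new("GammaResult", passRate = 100 * mean(vals <= 1 + 1e-9), gammaMap = g,
      dta = dta, ddPct = ddPct, thresholdPct = thresholdPct,
      normalization = norm, nEvaluated = length(vals))
}

#' Summarise metrics across repetitions
#'
#' Mean and standard deviation per condition and metric, the layout of the
#' study's result tables.  A single repetition reports SD = 0.
#'
#' @param results long data.frame with columns `condition`, `metric`,
#'   `value` (one row per repetition)
#' @return data.frame with columns `condition`, `metric`, `n`, `mean`, `sd`
#' @export
summarizeConditions <- function(results) {
  stopifnot(all(c("condition", "metric", "value") %in% names(results)))
  agg <- stats::aggregate(value ~ condition + metric, results,
                          function(v) c(n = length(v), mean = mean(v),
                                        sd = if (length(v) > 1) sd(v) else 0))
  out <- data.frame(condition = agg$condition, metric = agg$metric,
                    n = agg$value[, "n"], mean = agg$value[, "mean"],
                    sd = agg$value[, "sd"])
  out[order(out$condition, out$metric), , drop = FALSE]
}
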