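# Analytic spherical plan: error-function penumbra around a spherical target,
# calibrated so the prescription isodose surface carries the prescription
# dose exactly, rendered onto axial/sagittal film planes.

#' Construct the analytic spherical plan model
#'
#' Emulates a ballcube E2E plan prescribing `rxDose` to the sphere surface at
#' the `rxFraction` isodose of the maximum dose.  The radial dose is
#' \eqn{D(r) = D_{max}\,\Phi((r_{50} - r)/\sigma)} with \eqn{\Phi} the
#' standard normal CDF; \eqn{r_{50} = r_{Rx} + \sigma\,\Phi^{-1}(f_{Rx})} so
#' that \eqn{D(r_{Rx}) = D_{Rx}} exactly.
#'
#' Defaults reproduce the study plan: 420 cGy at the 70% isodose line of a
#' 600 cGy maximum, on a PTV sphere of radius 31.75/2 - 3 = 12.875 mm.
#'
#' @param rxDose prescription dose (cGy)
#' @param rxFraction isodose fraction at prescription, in (0, 1)
#' @param rRx radius of the prescription isodose surface (mm)
#' @param penumbraSigma penumbra width parameter (mm); 2.5 mm is a typical
#'   6 MV MLC penumbra scale
#' @return a [PlanModel-class]
#' @export
#' @examples
#' plan <- planModel()
#' plan@dMax              # 600
#' radialDose(12.875, plan)  # 420
planModel <- function(rxDose = 420, rxFraction = 0.70,
                      rRx = 31.75 / 2 - 3, penumbraSigma = 2.5) {
  new("PlanModel", dMax = rxDose / rxFraction, rxDose = rxDose,
      rxFraction = rxFraction, rRx = rRx, penumbraSigma = penumbraSigma,
      r50 = rRx + penumbraSigma * qnorm(rxFraction))
}

#' Radial dose of the spherical plan
#'
#' @param r radius from the sphere centre (mm), >= 0, vectorised
#' @param plan a [planModel()]
#' @return dose (cGy); continuous and monotone non-increasing in r
#' @export
radialDose <- function(r, plan) {
  stopifnot(is(plan, "PlanModel"))
  if (any(r < 0)) stop("r must be >= 0")
  plan@dMax * pnorm((plan@r50 - r) / plan@penumbraSigma)
}

#' Render the planned dose onto a film plane
#'
#' Both film planes pass through the sphere centre, so the in-plane distance
#' from the film centre equals the 3D radius and the rendered grid is
#' `radialDose` evaluated at pixel-centre distances.
#'
#' @param plan a [planModel()]
#' @param plane `"axial"` (LR x AP) or `"sagittal"` (SI x AP)
#' @param spacing pixel spacing (mm); `dpiToSpacing(300)` and
#'   `dpiToSpacing(75)` are the scanner-matched choices
#' @param sizeMm film edge length (mm), default 63.5; must cover the
#'   prescription isodose surface
#' @param slitWidth film slit width (mm)
#' @return a [DoseImage-class]
#' @export
renderPlanImage <- function(plan, plane = c("axial", "sagittal"),
                            spacing = dpiToSpacing(75), sizeMm = 63.5,
                            slitWidth = 1) {
  plane <- match.arg(plane)
  stopifnot(is(plan, "PlanModel"), spacing > 0)
  if (sizeMm < 2 * plan@rRx)
    stop("film size ", sizeMm, " mm does not cover the prescription surface")
  n <- max(3L, as.integer(round(sizeMm / spacing)))
  x <- pixelCoords(n, spacing)
  r <- sqrt(outer(x^2, x^2, "+"))   # [y, x]
  doseImage(radialDose(r, plan), spacing, plane, slitWidth)
}

#' Ground-truth isodose diameter of the plan
#'
#' Diameter of the isodose surface at `pct` percent of the maximum dose,
#' located by bisection on [radialDose()] to 1e-6 mm.
#'
#' @param plan a [planModel()]
#' @param pct isodose level, % of the maximum dose, in (0, 100)
#' @return diameter (mm)
#' @export
#' @examples
#' isodoseDiameterTruth(planModel(), 70)  # 25.75
isodoseDiameterTruth <- function(plan, pct) {
  stopifnot(is(plan, "PlanModel"))
  if (pct <= 0 || pct >= 100) stop("pct must lie in (0, 100)")
  level <- pct / 100 * plan@dMax
  if (level >= radialDose(0, plan))
    stop("isodose level exceeds the central dose")
  lo <- 0
  hi <- plan@r50 + 20 * plan@penumbraSigma
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (radialDose(mid, plan) > level) lo <- mid else hi <- mid
  }
  2 * (lo + hi) / 2
}

#' Read or write a `DoseImage` as CSV matrix + JSON sidecar
#'
#' `pathBase` is extended to `<pathBase>.csv` (the dose grid, no header) and
#' `<pathBase>.json` (spacing, plane, slit width, dimensions, and optional
#' free-form metadata such as the delivery condition).
#'
#' @param img a `DoseImage`
#' @param pathBase path without extension
#' @param meta optional named list stored in the sidecar
#' @return `readDoseImage` returns a `DoseImage` (sidecar metadata attached
#'   as attribute `"meta"`); `writeDoseImage` returns `pathBase` invisibly
#' @export
writeDoseImage <- function(img, pathBase, meta = list()) {
  stopifnot(is(img, "DoseImage"))
  utils::write.table(img@dose, paste0(pathBase, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  side <- c(list(spacing_mm = img@spacing, plane = img@plane,
                 slit_width_mm = img@slitWidth,
                 ny = nrow(img@dose), nx = ncol(img@dose)), meta)
  jsonlite::write_json(side, paste0(pathBase, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(pathBase)
}

#' @rdname writeDoseImage
#' @export
readDoseImage <- function(pathBase) {
  side <- jsonlite::read_json(paste0(pathBase, ".json"), simplifyVector = TRUE)
  m <- as.matrix(read.csv(paste0(pathBase, ".csv"), header = FALSE))
  dimnames(m) <- NULL
  img <- doseImage(m, side$spacing_mm, side$plane, side$slit_width_mm)
  attr(img, "meta") <- side[setdiff(names(side),
    c("spacing_mm", "plane", "slit_width_mm", "ny", "nx"))]
  img
}
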