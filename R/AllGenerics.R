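# Accessor generics, coercions and show methods.

#' @export
setGeneric("doseGrid", function(x) standardGeneric("doseGrid"))
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @export
setGeneric("filmPlane", function(x) standardGeneric("filmPlane"))
#' @export
setGeneric("slitMask", function(x, widthMm) standardGeneric("slitMask"))
#' @export
setGeneric("passRate", function(x) standardGeneric("passRate"))
#' @export
setGeneric("gammaMap", function(x) standardGeneric("gammaMap"))
#' @export
setGeneric("modelCoefficients", function(x) standardGeneric("modelCoefficients"))
#' @export
setGeneric("modelWindow", function(x) standardGeneric("modelWindow"))

#' Dose grid of a `DoseImage`
#' @param x a `DoseImage`
#' @return numeric matrix of doses (cGy), indexed `[y, x]`
#' @rdname DoseImage-class
#' @aliases doseGrid doseGrid,DoseImage-method
#' @export
setMethod("doseGrid", "DoseImage", function(x) x@dose)

#' @rdname DoseImage-class
#' @aliases gridSpacing gridSpacing,DoseImage-method
#' @export
setMethod("gridSpacing", "DoseImage", function(x) x@spacing)

#' @rdname DoseImage-class
#' @aliases filmPlane filmPlane,DoseImage-method
#' @export
setMethod("filmPlane", "DoseImage", function(x) x@plane)

#' Slit / exclusion-band mask of a film image
#'
#' The slit runs through the film centre parallel to the in-plane x axis.
#' `widthMm` defaults to the physical slit width (1 mm); pass a larger value
#' (e.g. 4 mm for a 2 mm exclusion band either side of the slit centre line)
#' to build the gamma-analysis exclusion region.
#'
#' @param x a `DoseImage` or `ScanImage`
#' @param widthMm full band width (mm) centred on the slit line
#' @return logical matrix, `TRUE` inside the band
#' @rdname slitMask
#' @export
setMethod("slitMask", "DoseImage", function(x, widthMm) {
  if (missing(widthMm)) widthMm <- x@slitWidth
  y <- pixelCoords(nrow(x@dose), x@spacing)
  matrix(abs(y) <= widthMm / 2, nrow(x@dose), ncol(x@dose))
})

#' @rdname slitMask
#' @export
setMethod("slitMask", "ScanImage", function(x, widthMm) {
  if (missing(widthMm)) widthMm <- x@slitWidth
  sp <- dpiToSpacing(x@dpi)
  y <- pixelCoords(nrow(x@pixels), sp)
  matrix(abs(y) <= widthMm / 2, nrow(x@pixels), ncol(x@pixels))
})

#' @rdname GammaResult-class
#' @aliases passRate passRate,GammaResult-method
#' @export
setMethod("passRate", "GammaResult", function(x) x@passRate)

#' @rdname GammaResult-class
#' @aliases gammaMap gammaMap,GammaResult-method
#' @export
setMethod("gammaMap", "GammaResult", function(x) x@gammaMap)

#' @rdname CorrelationModel-class
#' @aliases modelCoefficients modelCoefficients,CorrelationModel-method
#' @export
setMethod("modelCoefficients", "CorrelationModel", function(x) x@coefficients)

#' @rdname CorrelationModel-class
#' @aliases modelWindow modelWindow,CorrelationModel-method
#' @export
setMethod("modelWindow", "CorrelationModel", function(x) x@window)

#' @export
setMethod("length", "MotionTrajectory", function(x) length(x@times))

#' Coerce a trajectory to a data.frame
#' @param x a `MotionTrajectory`
#' @param ... ignored
#' @return data.frame with columns `t_s`, `si_mm`, `lr_mm`, `ap_mm`
#' @export
setMethod("as.data.frame", "MotionTrajectory", function(x, ...) {
  data.frame(t_s = x@times, si_mm = x@si, lr_mm = x@lr, ap_mm = x@ap)
})

setMethod("show", "WaveformParams", function(object) {
  cat(sprintf("WaveformParams: peak-to-valley %.3g mm, period %.3g s, phase %.3g rad, baseline %.3g mm\n",
              object@amplitudePv, object@period, object@phase, object@baseline))
})

setMethod("show", "MotionTrajectory", function(object) {
  n <- length(object@times)
  cat(sprintf("MotionTrajectory: %d samples", n))
  if (n) {
    cat(sprintf(" over %.3g s; peak-to-valley SI %.3g, LR %.3g, AP %.3g mm",
                diff(range(object@times)),
                diff(range(object@si)), diff(range(object@lr)),
                diff(range(object@ap))))
  }
  cat("\n")
})

setMethod("show", "DoseImage", function(object) {
  cat(sprintf("DoseImage (%s plane): %d x %d pixels at %.4g mm, max %.4g cGy\n",
              object@plane, nrow(object@dose), ncol(object@dose),
              object@spacing, max(object@dose)))
})

setMethod("show", "ScanImage", function(object) {
  cat(sprintf("ScanImage (%s plane): %d x %d pixels at %g dpi, unexposed value %g\n",
              object@plane, nrow(object@pixels), ncol(object@pixels),
              object@dpi, object@unexposedValue))
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve: dose(od) = %.4g + %.4g od / (1 - %.4g od); %d samples, max residual %.3g cGy\n",
              object@a, object@b, object@c, nrow(object@samples),
              object@maxResidual))
})

setMethod("show", "CorrelationModel", function(object) {
  cat("CorrelationModel (linear), window of", nrow(object@window), "points\n")
  print(round(object@coefficients, 4))
})

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameSequence: %d frames of %d x %d pixels, %g fps, %.4g mm/pixel\n",
              d[3], d[1], d[2], object@fps, object@mmPerPixel))
})

setMethod("show", "GammaResult", function(object) {
  cat(sprintf("GammaResult %g mm / %g%% (threshold %g%%, norm %.4g cGy): pass rate %.2f%% over %d points\n",
              object@dta, object@ddPct, object@thresholdPct,
              object@normalization, object@passRate, object@nEvaluated))
})

setMethod("show", "PlanModel", function(object) {
  cat(sprintf("PlanModel: %.4g cGy max, %.4g cGy prescribed at the %.0f%% isodose (r = %.4g mm); penumbra sigma %.3g mm, r50 %.4g mm\n",
              object@dMax, object@rxDose, 100 * object@rxFraction,
              object@rRx, object@penumbraSigma, object@r50))
})

# pixel-centre coordinates of an n-pixel axis with the grid centre at 0 (mm)
pixelCoords <- function(n, spacing) ((seq_len(n) - 0.5) - n / 2) * spacing
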