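# Central S4 containers.  Image matrices are indexed [y, x]; pixel centres sit
# at (i - 0.5) * spacing - extent / 2 so the film (or frame) centre is the
# coordinate origin.  Positive SI = superior, positive LR = patient left,
# positive AP = anterior.

#' Parameters of a periodic motion waveform
#'
#' Amplitude is stored as the full peak-to-valley displacement throughout the
#' package: for the respiratory \eqn{\cos^6} waveform the depth parameter
#' \eqn{A} already equals the peak-to-valley excursion (the waveform runs over
#' \eqn{[P_0 - A, P_0]}), and measured platform amplitudes are conventionally
#' reported as peak-to-valley distances.
#'
#' @slot amplitudePv peak-to-valley displacement (mm), \eqn{\ge 0}
#' @slot period motion period (s), \eqn{> 0}
#' @slot phase initial phase (radians)
#' @slot baseline baseline position (mm); for the respiratory waveform this is
#'   the exhale position \eqn{P_0}
#' @exportClass WaveformParams
setClass("WaveformParams",
  representation(amplitudePv = "numeric", period = "numeric",
                 phase = "numeric", baseline = "numeric"),
  validity = function(object) {
    v <- c(object@amplitudePv, object@period, object@phase, object@baseline)
    if (length(v) != 4L || !all(is.finite(v)))
      return("all waveform parameters must be finite scalars")
    if (object@amplitudePv < 0) return("amplitudePv must be >= 0")
    if (object@period <= 0) return("period must be > 0")
    TRUE
  })

#' @param amplitudePv peak-to-valley displacement (mm)
#' @param period motion period (s)
#' @param phase initial phase (radians)
#' @param baseline baseline position (mm)
#' @return a `WaveformParams` object
#' @rdname WaveformParams-class
#' @export
#' @examples
#' respDefault <- waveformParams(20, 5)    # A = 20 mm, tau = 5 s
#' cardDefault <- waveformParams(5, 1)     # 5 mm peak-to-valley, 1 s cycle
waveformParams <- function(amplitudePv, period, phase = 0, baseline = 0) {
  new("WaveformParams", amplitudePv = as.numeric(amplitudePv),
      period = as.numeric(period), phase = as.numeric(phase),
      baseline = as.numeric(baseline))
}

#' Time-stamped 3D motion trajectory
#'
#' @slot times sample times (s), strictly increasing
#' @slot si,lr,ap displacement components (mm)
#' @exportClass MotionTrajectory
setClass("MotionTrajectory",
  representation(times = "numeric", si = "numeric", lr = "numeric",
                 ap = "numeric"),
  validity = function(object) {
    n <- length(object@times)
    if (length(object@si) != n || length(object@lr) != n ||
        length(object@ap) != n)
      return("times, si, lr, ap must have equal lengths")
    if (n && !all(is.finite(c(object@times, object@si, object@lr, object@ap))))
      return("trajectory values must be finite")
    if (n > 1 && any(diff(object@times) <= 0))
      return("times must be strictly increasing")
    TRUE
  })

#' @param times sample times (s), strictly increasing
#' @param si,lr,ap displacement components (mm); scalars are recycled
#' @return a `MotionTrajectory`
#' @rdname MotionTrajectory-class
#' @export
motionTrajectory <- function(times, si = 0, lr = 0, ap = 0) {
  n <- length(times)
  new("MotionTrajectory", times = as.numeric(times),
      si = rep_len(as.numeric(si), n), lr = rep_len(as.numeric(lr), n),
      ap = rep_len(as.numeric(ap), n))
}

#' Planar dose distribution on a film plane
#'
#' The grid is indexed `[y, x]`.  For an axial film the in-plane axes are
#' (x = LR, y = AP); for a sagittal film (x = SI, y = AP).  The physical film
#' carries a 1 mm wide slit running through the film centre along the x axis;
#' [slitMask()] materialises the slit (or a wider exclusion band) as a logical
#' mask.
#'
#' @slot dose dose grid (cGy), matrix `[y, x]`
#' @slot spacing pixel spacing (mm)
#' @slot plane `"axial"` or `"sagittal"`
#' @slot slitWidth slit width (mm)
#' @exportClass DoseImage
setClass("DoseImage",
  representation(dose = "matrix", spacing = "numeric", plane = "character",
                 slitWidth = "numeric"),
  validity = function(object) {
    if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
        object@spacing <= 0)
      return("spacing must be a positive scalar (mm)")
    if (!object@plane %in% c("axial", "sagittal"))
      return("plane must be 'axial' or 'sagittal'")
    if (any(!is.finite(object@dose)) || any(object@dose < -1e-9))
      return("doses must be finite and non-negative")
    if (object@slitWidth < 0) return("slitWidth must be >= 0")
    TRUE
  })

#' @param dose dose matrix (cGy), indexed `[y, x]`
#' @param spacing pixel spacing (mm)
#' @param plane `"axial"` or `"sagittal"`
#' @param slitWidth film slit width (mm)
#' @return a `DoseImage`
#' @rdname DoseImage-class
#' @export
doseImage <- function(dose, spacing, plane = c("axial", "sagittal"),
                      slitWidth = 1) {
  plane <- match.arg(plane)
  dose[dose < 0] <- 0
  new("DoseImage", dose = dose, spacing = as.numeric(spacing), plane = plane,
      slitWidth = as.numeric(slitWidth))
}

#' Simulated film scan (red-channel pixel values)
#'
#' @slot pixels pixel-value matrix on the 16-bit scale `[0, 65535]`
#' @slot dpi scan resolution (dots per inch)
#' @slot unexposedValue pixel value of unexposed film
#' @slot plane film plane label
#' @slot slitWidth film slit width (mm)
#' @exportClass ScanImage
setClass("ScanImage",
  representation(pixels = "matrix", dpi = "numeric",
                 unexposedValue = "numeric", plane = "character",
                 slitWidth = "numeric"),
  validity = function(object) {
    if (any(!is.finite(object@pixels)) || any(object@pixels < 0) ||
        any(object@pixels > 65535))
      return("pixel values must lie in [0, 65535]")
    if (object@dpi <= 0) return("dpi must be > 0")
    if (object@unexposedValue <= 0 || object@unexposedValue > 65535)
      return("unexposedValue must lie in (0, 65535]")
    TRUE
  })

#' Radiochromic-film calibration curve
#'
#' Rational response model \eqn{D(od) = a + b\,od / (1 - c\,od)} fitted by
#' least squares to paired (net optical density, dose) samples.
#'
#' @slot a,b,c fitted coefficients (cGy intercept, cGy slope, od^-1 curvature)
#' @slot samples data.frame with columns `od`, `dose` used for the fit
#' @slot odRange calibrated net-OD range
#' @slot maxResidual maximum absolute fit residual (cGy)
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 samples = "data.frame", odRange = "numeric",
                 maxResidual = "numeric"),
  validity = function(object) {
    if (!all(is.finite(c(object@a, object@b, object@c))))
      return("coefficients must be finite")
    if (object@b <= 0)
      return("b must be > 0 for an increasing dose response")
    hi <- max(object@odRange)
    if (object@c > 0 && object@c * hi >= 1)
      return("pole of the rational response lies inside the calibrated range")
    TRUE
  })

#' Linear surrogate-to-target correlation model
#'
#' Per-axis linear maps from the surrogate marker signal to the target
#' position, fitted to a sliding window of at most 15 paired model points.
#'
#' @slot coefficients 2 x 3 matrix (rows `intercept`, `slope`; columns `si`,
#'   `lr`, `ap`)
#' @slot window data.frame of the model points backing the current fit
#'   (columns `time`, `marker`, `si`, `lr`, `ap`)
#' @exportClass CorrelationModel
setClass("CorrelationModel",
  representation(coefficients = "matrix", window = "data.frame"),
  validity = function(object) {
    if (!identical(dim(object@coefficients), c(2L, 3L)))
      return("coefficients must be a 2 x 3 matrix")
    if (nrow(object@window) > 15L)
      return("model window holds at most 15 points")
    TRUE
  })

#' Fluoroscopic frame sequence
#'
#' @slot frames numeric array `[y, x, frame]`, intensities on a [0, 1] scale
#' @slot fps frame rate (frames per second)
#' @slot mmPerPixel spatial resolution (mm/pixel)
#' @exportClass FrameSequence
setClass("FrameSequence",
  representation(frames = "array", fps = "numeric", mmPerPixel = "numeric"),
  validity = function(object) {
    if (length(dim(object@frames)) != 3L)
      return("frames must be a 3D array [y, x, frame]")
    if (object@fps <= 0) return("fps must be > 0")
    if (object@mmPerPixel <= 0) return("mmPerPixel must be > 0")
    TRUE
  })

#' Gamma-analysis result
#'
#' @slot passRate percentage of evaluated points with \eqn{\gamma \le 1}
#' @slot gammaMap gamma values (NA outside the evaluated set)
#' @slot dta distance-to-agreement criterion (mm)
#' @slot ddPct dose-difference criterion (% of the global normalization)
#' @slot thresholdPct low-dose threshold (% of the global normalization)
#' @slot normalization global normalization dose (cGy, reference maximum)
#' @slot nEvaluated number of evaluated reference points
#' @exportClass GammaResult
setClass("GammaResult",
  representation(passRate = "numeric", gammaMap = "matrix", dta = "numeric",
                 ddPct = "numeric", thresholdPct = "numeric",
                 normalization = "numeric", nEvaluated = "integer"),
  validity = function(object) {
    if (object@passRate < 0 || object@passRate > 100)
      return("passRate must lie in [0, 100]")
    if (object@dta <= 0 || object@ddPct <= 0)
      return("dta and ddPct must be > 0")
    TRUE
  })

#' Analytic spherical plan model
#'
#' Radially symmetric dose with an error-function penumbra:
#' \eqn{D(r) = D_{max}\,\Phi((r_{50} - r)/\sigma)}, with \eqn{r_{50}} chosen
#' so that the prescription isodose surface (fraction `rxFraction` of
#' \eqn{D_{max}}) sits exactly at radius `rRx`.
#'
#' @slot dMax maximum dose (cGy), `rxDose / rxFraction`
#' @slot rxDose prescription dose (cGy)
#' @slot rxFraction isodose fraction at prescription (0, 1)
#' @slot rRx radius of the prescription isodose surface (mm)
#' @slot penumbraSigma penumbra width parameter (mm)
#' @slot r50 radius of the 50% isodose surface (mm, derived)
#' @exportClass PlanModel
setClass("PlanModel",
  representation(dMax = "numeric", rxDose = "numeric", rxFraction = "numeric",
                 rRx = "numeric", penumbraSigma = "numeric", r50 = "numeric"),
  validity = function(object) {
    if (object@rxFraction <= 0 || object@rxFraction >= 1)
      return("rxFraction must lie in (0, 1)")
    if (object@rxDose <= 0 || object@rRx <= 0 || object@penumbraSigma <= 0)
      return("rxDose, rRx, penumbraSigma must be > 0")
    if (abs(object@dMax - object@rxDose / object@rxFraction) > 1e-9)
      return("dMax must equal rxDose / rxFraction")
    TRUE
  })
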