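# Radiochromic-film dosimetry: rational net-OD calibration curve, forward
# scanner model (dose -> pixel values) and its inverse.

#' Scanner resolution to pixel spacing
#'
#' @param dpi scan resolution (dots per inch), > 0
#' @return pixel spacing in mm (`25.4 / dpi`); 75 dpi gives 0.34 mm at 2-dp
#'   rounding
#' @export
dpiToSpacing <- function(dpi) {
  if (any(dpi <= 0)) stop("dpi must be > 0")
  25.4 / dpi
}

#' Fit the rational dose calibration curve
#'
#' Least-squares fit of \eqn{D(od) = a + b\,od/(1 - c\,od)} to paired (net
#' optical density, dose) samples — the standard saturating response shape of
#' radiochromic film.  The study protocol uses 15 samples spanning
#' 0–1000 cGy.
#'
#' @param samples data.frame with columns `od` (net optical density) and
#'   `dose` (cGy); at least 4 distinct od values, doses in `[0, 1000]`
#' @return a [CalibrationCurve-class]
#' @export
fitCalibration <- function(samples) {
  stopifnot(all(c("od", "dose") %in% names(samples)))
  if (length(unique(samples$od)) < 4L)
    stop("need at least 4 distinct od values")
  if (any(samples$dose < 0 | samples$dose > 1000))
    stop("calibration doses must lie in [0, 1000] cGy")
  ord <- order(samples$od)
  rho <- stats::cor(samples$od, samples$dose, method = "spearman")
  if (!is.finite(rho) || rho < 0.8)
    stop("calibration data are not monotone beyond noise ",
         sprintf("(Spearman rho = %.2f); check the od/dose pairing", rho))
  # linear start values: D ~ a + b od for small c
  start <- unname(coef(lm(dose ~ od, samples)))
  fit <- minpack.lm::nlsLM(dose ~ a + b * od / (1 - c * od), data = samples,
                           start = list(a = start[1], b = max(start[2], 1),
                                        c = 0.1),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  res <- stats::residuals(fit)
  curve <- new("CalibrationCurve", a = unname(cf["a"]), b = unname(cf["b"]),
               c = unname(cf["c"]), samples = samples[ord, ],
               odRange = range(samples$od), maxResidual = max(abs(res)))
  # the rational form is monotone when b > 0 and the pole is outside the
  # range (checked by the class validity); report a failed fit clearly
  validObject(curve)
  curve
}

#' Evaluate or invert a calibration curve
#'
#' `predictDose` maps net OD to dose; `invertCalibration` maps dose back to
#' net OD via the closed-form inverse of the rational response,
#' \eqn{od = (D - a) / (b + c (D - a))}, exact on the calibrated range.
#'
#' @param cal a [CalibrationCurve-class]
#' @param od,dose values to convert (vectorised)
#' @return dose (cGy) or net optical density
#' @export
predictDose <- function(cal, od) {
  stopifnot(is(cal, "CalibrationCurve"))
  cal@a + cal@b * od / (1 - cal@c * od)
}

#' @rdname predictDose
#' @export
invertCalibration <- function(cal, dose) {
  stopifnot(is(cal, "CalibrationCurve"))
  (dose - cal@a) / (cal@b + cal@c * (dose - cal@a))
}

#' Reference 15-point calibration samples
#'
#' Generates the (net OD, dose) pairs of a known rational response on 15
#' doses spanning 0–1000 cGy, optionally with multiplicative OD noise —
#' the synthetic stand-in for the film calibration strips.
#'
#' @param a,b,c true response coefficients; defaults give net OD about 0.38
#'   at the 600 cGy maximum plan dose
#' @param noiseSd multiplicative OD noise (relative SD), e.g. 0.02 for 2%
#' @param seed optional RNG seed
#' @return data.frame with columns `od`, `dose`
#' @export
defaultCalibrationSamples <- function(a = 0, b = 1200, c = 0.6,
                                      noiseSd = 0, seed = NULL) {
  dose <- seq(0, 1000, length.out = 15)
  od <- (dose - a) / (b + c * (dose - a))
  od <- withSeed(seed, od * (1 + rnorm(length(od), 0, noiseSd)))
  data.frame(od = pmax(od, 0), dose = dose)
}

#' Forward scanner model: dose image to film scan
#'
#' Each pixel's dose is converted to net optical density through the inverse
#' calibration curve, then to a transmission pixel value
#' `unexposedValue * 10^(-od)` on the 16-bit red-channel scale, plus Gaussian
#' granularity noise.  Slit pixels read as unexposed film.
#'
#' @param doseImg a [DoseImage-class]; doses must lie within the calibrated
#'   range
#' @param cal a [CalibrationCurve-class]
#' @param dpi scan resolution; must match the dose-image spacing
#' @param noiseSd granularity noise SD in pixel-value units (16-bit scale)
#' @param unexposedValue pixel value of unexposed film
#' @param seed optional RNG seed
#' @return a [ScanImage-class]
#' @export
doseToScan <- function(doseImg, cal, dpi = NULL, noiseSd = 0,
                       unexposedValue = 40000, seed = NULL) {
  stopifnot(is(doseImg, "DoseImage"), is(cal, "CalibrationCurve"))
  maxCal <- max(cal@samples$dose)
  if (max(doseImg@dose) > maxCal + 1e-6)
    stop("dose ", round(max(doseImg@dose), 1),
         " cGy exceeds the calibrated range (", round(maxCal, 1), " cGy)")
  if (is.null(dpi)) dpi <- 25.4 / doseImg@spacing
  od <- invertCalibration(cal, doseImg@dose)
  px <- unexposedValue * 10^(-od)
  px[slitMask(doseImg, doseImg@slitWidth)] <- unexposedValue
  px <- withSeed(seed, px + rnorm(length(px), 0, noiseSd))
  px <- matrix(round(pmin(pmax(px, 1), 65535)), nrow(px), ncol(px))
  new("ScanImage", pixels = px, dpi = dpi, unexposedValue = unexposedValue,
      plane = doseImg@plane, slitWidth = doseImg@slitWidth)
}

#' Inverse scanner model: film scan to dose image
#'
#' Net optical density `log10(unexposedValue / pixel)` is mapped to dose
#' through the calibration curve; negative reconstructed doses (noise around
#' the unexposed level) are clamped to 0.
#'
#' @param scan a [ScanImage-class]
#' @param cal a [CalibrationCurve-class]
#' @return a [DoseImage-class]
#' @export
scanToDose <- function(scan, cal) {
  stopifnot(is(scan, "ScanImage"), is(cal, "CalibrationCurve"))
  if (any(scan@pixels <= 0)) stop("non-positive pixel values")
  od <- log10(scan@unexposedValue / scan@pixels)
  dose <- predictDose(cal, od)
  doseImage(matrix(pmax(dose, 0), nrow(od), ncol(od)),
            dpiToSpacing(scan@dpi), scan@plane, scan@slitWidth)
}

#' Read or write a film scan as 16-bit grayscale TIFF + JSON sidecar
#'
#' `pathBase` is extended to `<pathBase>.tif` and `<pathBase>.json` (dpi,
#' unexposed value, plane, slit width).
#'
#' @param scan a `ScanImage`
#' @param pathBase path without extension
#' @return `readScanImage` returns a `ScanImage`; `writeScanImage` returns
#'   `pathBase` invisibly
#' @export
writeScanImage <- function(scan, pathBase) {
  stopifnot(is(scan, "ScanImage"))
  tiff::writeTIFF(scan@pixels / 65535, paste0(pathBase, ".tif"),
                  bits.per.sample = 16)
  jsonlite::write_json(list(dpi = scan@dpi,
                            unexposed_value = scan@unexposedValue,
                            plane = scan@plane,
                            slit_width_mm = scan@slitWidth),
                       paste0(pathBase, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(pathBase)
}

#' @rdname writeScanImage
#' @export
readScanImage <- function(pathBase) {
  side <- jsonlite::read_json(paste0(pathBase, ".json"), simplifyVector = TRUE)
  px <- tiff::readTIFF(paste0(pathBase, ".tif")) * 65535
  new("ScanImage", pixels = px, dpi = side$dpi,
      unexposedValue = side$unexposed_value, plane = side$plane,
      slitWidth = side$slit_width_mm)
}

#' Read calibration samples from CSV
#'
#' Dialect: header `net_od,dose_cGy`.
#' @param path CSV file path
#' @return data.frame with columns `od`, `dose`
#' @export
readCalibrationSamples <- function(path) {
  d <- read.csv(path)
  data.frame(od = d$net_od, dose = d$dose_cGy)
}
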