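# Fluoroscopic platform QA: frame synthesis of a bright marker disc,
# spatial calibration from a known-size sphere, centre-of-mass tracking
# through binarization, and RMSE against the ideal sine motion.

# anti-aliased bright disc on a dark background; centre in mm relative to
# the frame centre, matrix [y, x], intensities in [0, 1] before noise
renderDisc <- function(ny, nx, mmPerPixel, centerX = 0, centerY = 0,
                       diameter = 1.5) {
  x <- pixelCoords(nx, mmPerPixel)
  y <- pixelCoords(ny, mmPerPixel)
  d <- sqrt(outer((y - centerY)^2, (x - centerX)^2, "+"))
  # linear edge ramp one pixel wide approximates pixel-area coverage
  pmin(pmax((diameter / 2 - d) / mmPerPixel + 0.5, 0), 1)
}

#' Render fluoroscopic frames of a moving marker
#'
#' Each frame contains an anti-aliased bright disc at the in-plane projection
#' of the trajectory (x = SI, y = LR for the horizontal platform plane), plus
#' optional Gaussian background noise.  Study defaults: a 1.5 mm marker
#' imaged at 0.096 mm/pixel, 15 frames per second, 100 frames.
#'
#' @param traj marker `MotionTrajectory`; must cover `nFrames / fps` seconds
#' @param markerDiameter marker diameter (mm)
#' @param mmPerPixel spatial resolution (mm/pixel)
#' @param nFrames,fps number of frames and cine rate
#' @param noiseSd Gaussian noise SD on the [0, 1] intensity scale
#' @param seed optional RNG seed
#' @param marginMm frame margin beyond the motion extent (mm); ignored when
#'   `frameSizeMm` is given
#' @param frameSizeMm optional fixed frame edge length (mm); an error is
#'   raised if the marker leaves this field of view
#' @return a [FrameSequence-class]
#' @export
renderMarkerFrames <- function(traj, markerDiameter = 1.5,
                               mmPerPixel = 0.096, nFrames = 100, fps = 15,
                               noiseSd = 0, seed = NULL, marginMm = 3,
                               frameSizeMm = NULL) {
  stopifnot(is(traj, "MotionTrajectory"))
  t <- (seq_len(nFrames) - 1) / fps
  if (max(t) > max(traj@times) + 1e-9)
    stop("trajectory does not cover ", nFrames, " frames at ", fps, " fps")
  pos <- interpTraj(traj, t)
  half <- if (is.null(frameSizeMm))
    max(abs(c(pos$si, pos$lr))) + markerDiameter / 2 + marginMm
  else frameSizeMm / 2
  n <- 2L * ceiling(half / mmPerPixel)
  if (max(abs(c(pos$si, pos$lr))) + markerDiameter / 2 > n / 2 * mmPerPixel)
    stop("marker leaves the field of view")
  frames <- array(0, c(n, n, nFrames))
  for (k in seq_len(nFrames))
    frames[, , k] <- renderDisc(n, n, mmPerPixel, pos$si[k], pos$lr[k],
                                markerDiameter)
  if (noiseSd > 0)
    frames <- withSeed(seed,
      frames + array(rnorm(length(frames), 0, noiseSd), dim(frames)))
  new("FrameSequence", frames = frames, fps = fps, mmPerPixel = mmPerPixel)
}

#' Render a calibration sphere image
#'
#' @param diameter sphere diameter (mm); 41.30 mm is the study's reference
#'   sphere
#' @param mmPerPixel nominal resolution (mm/pixel)
#' @param noiseSd Gaussian noise SD on the [0, 1] scale
#' @param seed optional RNG seed
#' @return intensity matrix `[y, x]`
#' @export
renderSphereImage <- function(diameter = 41.30, mmPerPixel = 0.096,
                              noiseSd = 0, seed = NULL) {
  n <- 2L * ceiling((diameter / 2 + 3) / mmPerPixel) + 1L
  img <- renderDisc(n, n, mmPerPixel, 0, 0, diameter)
  if (noiseSd > 0)
    img <- withSeed(seed,
      img + matrix(rnorm(length(img), 0, noiseSd), n, n))
  img
}

# Otsu binarization + largest connected component (EBImage)
binarizeLargest <- function(img) {
  clipped <- pmin(pmax(img, 0), 1)
  th <- EBImage::otsu(EBImage::Image(clipped), range = c(0, 1))
  mask <- clipped > th
  if (!any(mask)) stop("binarization produced an empty mask")
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Spatial calibration from a known-size sphere
#'
#' Binarizes the image (Otsu threshold), keeps the largest connected
#' component, measures its extent in pixels along the major axis, and returns
#' `knownDiameter / extent` — the verification procedure for the fluoroscopy
#' pixel scale.
#'
#' @param sphereImage intensity matrix containing a single bright sphere
#' @param knownDiameter true sphere diameter (mm)
#' @return recovered resolution (mm/pixel)
#' @export
#' @examples
#' img <- renderSphereImage(41.30, 0.096)
#' round(calibrateSpatial(img, 41.30), 3)  # 0.096
calibrateSpatial <- function(sphereImage, knownDiameter) {
  mask <- binarizeLargest(sphereImage)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no object found")
  extent <- max(diff(range(idx[, 1])), diff(range(idx[, 2]))) + 1
  knownDiameter / extent
}

#' Track the marker centre of mass across frames
#'
#' Per frame: global Otsu threshold, largest connected component, unweighted
#' centroid of the binary mask, converted to mm relative to the frame centre.
#'
#' @param frames a [FrameSequence-class]
#' @return in-plane `MotionTrajectory` (`si` = x, `lr` = y, `ap` = 0) sampled
#'   at the frame times
#' @export
trackCom <- function(frames) {
  stopifnot(is(frames, "FrameSequence"))
  n <- dim(frames@frames)[3]
  si <- lr <- numeric(n)
  ny <- dim(frames@frames)[1]
  nx <- dim(frames@frames)[2]
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  for (k in seq_len(n)) {
    mask <- binarizeLargest(frames@frames[, , k])
    idx <- which(mask, arr.ind = TRUE)
    si[k] <- (mean(idx[, 2]) - cx) * frames@mmPerPixel
    lr[k] <- (mean(idx[, 1]) - cy) * frames@mmPerPixel
  }
  motionTrajectory((seq_len(n) - 1) / frames@fps, si = si, lr = lr, ap = 0)
}

#' RMSE of measured motion against the ideal sine
#'
#' Fits the phase and offset of a sine with the *nominal* amplitude and
#' period to the measured positions by least squares, then reports the RMSE
#' over all frames.  Amplitude and period stay fixed at their nominal values;
#' fitting phase and offset is the conservative alignment (an unfitted phase
#' would dominate the error).  Set `fitPhase = FALSE` to score against the
#' nominal phase instead.
#'
#' @param measured in-plane `MotionTrajectory` (from [trackCom()])
#' @param nominal [waveformParams()] of the ideal sine
#' @param axis which measured component to score (`"si"` or `"lr"`)
#' @param fitPhase fit the phase (default) or use `nominal@phase`
#' @return RMSE (mm)
#' @export
rmseVsIdeal <- function(measured, nominal, axis = c("si", "lr"),
                        fitPhase = TRUE) {
  axis <- match.arg(axis)
  stopifnot(is(measured, "MotionTrajectory"), is(nominal, "WaveformParams"))
  x <- slot(measured, axis)
  t <- measured@times
  if (length(x) < 10) stop("need at least 10 samples")
  amp <- nominal@amplitudePv / 2
  w <- 2 * pi / nominal@period
  rmseAt <- function(phi) {
    ideal <- amp * sin(w * t + phi)
    off <- mean(x - ideal)
    sqrt(mean((x - off - ideal)^2))
  }
  if (amp == 0) return(rmseAt(0))
  if (!fitPhase) return(rmseAt(nominal@phase))
  # closed-form phase: regress on the sine/cosine basis; the coefficient
  # pair (A cos phi, A sin phi) yields the aligned phase directly
  basis <- lm(x ~ sin(w * t) + cos(w * t))
  rmseAt(atan2(coef(basis)[3], coef(basis)[2]))
}

#' Read or write a frame sequence as multi-page 16-bit TIFF + JSON sidecar
#'
#' @param frames a `FrameSequence`
#' @param pathBase path without extension (`.tif` and `.json` are appended)
#' @return `readFrameSequence` returns a `FrameSequence`;
#'   `writeFrameSequence` returns `pathBase` invisibly
#' @export
writeFrameSequence <- function(frames, pathBase) {
  stopifnot(is(frames, "FrameSequence"))
  pages <- lapply(seq_len(dim(frames@frames)[3]),
                  function(k) pmin(pmax(frames@frames[, , k], 0), 1))
  tiff::writeTIFF(pages, paste0(pathBase, ".tif"), bits.per.sample = 16)
  jsonlite::write_json(list(fps = frames@fps,
                            mm_per_pixel = frames@mmPerPixel),
                       paste0(pathBase, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(pathBase)
}

#' @rdname writeFrameSequence
#' @export
readFrameSequence <- function(pathBase) {
  side <- jsonlite::read_json(paste0(pathBase, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(pathBase, ".tif"), all = TRUE)
  frames <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- pages[[k]]
  new("FrameSequence", frames = frames, fps = side$fps,
      mmPerPixel = side$mm_per_pixel)
}
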