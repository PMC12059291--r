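# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately written without reference to the package's
# internal code paths (plain R, brute force).

# pixel-centre coordinates with the grid centre at 0 (mirrors the package's
# convention; trivial arithmetic, restated here so oracles stand alone)
coordsOf <- function(n, spacing) ((seq_len(n) - 0.5) - n / 2) * spacing

# plain bilinear interpolation at continuous pixel indices (1-based), no
# boundary extension: caller guarantees the point lies inside the grid
bilinearAtR <- function(m, iy, ix) {
  y0 <- floor(iy); x0 <- floor(ix)
  y1 <- pmin(y0 + 1, nrow(m)); x1 <- pmin(x0 + 1, ncol(m))
  fy <- iy - y0; fx <- ix - x0
  m[cbind(y0, x0)] * (1 - fy) * (1 - fx) + m[cbind(y0, x1)] * (1 - fy) * fx +
    m[cbind(y1, x0)] * fy * (1 - fx) + m[cbind(y1, x1)] * fy * fx
}

# Exhaustive brute-force gamma pass rate: for every evaluable reference
# pixel, minimise over ALL lattice offsets (step mm, no early exit, no
# sorting) of the combined distance/dose term.  Global normalization to the
# reference maximum; same exclusion rules as the study analysis.
gammaBruteR <- function(refImg, evalImg, dta, ddPct, thresholdPct = 10,
                        roiMm = 25, slitExclusionMm = 2, step = dta / 100,
                        radius = 3 * dta) {
  ref <- refImg@dose; ev <- evalImg@dose; sp <- refImg@spacing
  norm <- max(ref)
  x <- coordsOf(ncol(ref), sp); y <- coordsOf(nrow(ref), sp)
  use <- outer(abs(y) <= roiMm / 2, abs(x) <= roiMm / 2, "&") &
    !matrix(abs(y) <= slitExclusionMm, length(y), length(x)) &
    ref >= thresholdPct / 100 * norm
  m <- floor(radius / step + 1e-9)
  off <- expand.grid(ox = (-m:m) * step, oy = (-m:m) * step)
  off <- off[off$ox^2 + off$oy^2 <= radius^2 + 1e-12, ]
  distTerm <- (off$ox^2 + off$oy^2) / dta^2
  ddAbs <- ddPct / 100 * norm
  idx <- which(use, arr.ind = TRUE)
  g <- numeric(nrow(idx))
  for (p in seq_len(nrow(idx))) {
    i <- idx[p, 1]; j <- idx[p, 2]
    ix <- j + off$ox / sp
    iy <- i + off$oy / sp
    ok <- ix >= 1 & ix <= ncol(ev) & iy >= 1 & iy <= nrow(ev)
    dd <- bilinearAtR(ev, iy[ok], ix[ok]) - ref[i, j]
    g[p] <- sqrt(min(distTerm[ok] + dd^2 / ddAbs^2))
  }
  list(passRate = 100 * mean(g <= 1 + 1e-9), gamma = g)
}

# 1D convolution of each matrix row with a centred kernel, edge-replicated
# padding: the infinite-sample limit of sinusoidal blur along x
convolveRowsR <- function(m, kernel) {
  h <- (length(kernel) - 1) / 2
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    padded <- c(rep(m[i, 1], h), m[i, ], rep(m[i, ncol(m)], h))
    out[i, ] <- stats::filter(padded, rev(kernel), sides = 2)[(h + 1):(h + ncol(m))]
  }
  out
}

# a smooth random multiplicative perturbation field (low-order Fourier)
smoothFieldR <- function(n, spacing, seed, scale = 0.02) {
  set.seed(seed)
  x <- coordsOf(n, spacing)
  f <- matrix(0, n, n)
  for (k in 1:3) {
    kx <- runif(1, 0.05, 0.2); ky <- runif(1, 0.05, 0.2)
    ph <- runif(2, 0, 2 * pi); a <- rnorm(1)
    f <- f + a * outer(sin(ky * x + ph[1]), cos(kx * x + ph[2]))
  }
  1 + scale * f / max(abs(f))
}

# small Gaussian-blob reference image for gamma tests (21 x 21, 1 mm)
blobImage <- function(n = 21, spacing = 1, sigma = 6, dmax = 100,
                      shiftX = 0, plane = "axial") {
  x <- coordsOf(n, spacing)
  d <- dmax * exp(-outer(x^2, (x - shiftX)^2, "+") / (2 * sigma^2))
  doseImage(d, spacing, plane)
}

# least-squares line by the explicit covariance formula (oracle for the
# correlation-model fits, which use lm internally)
lineFitR <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# closed-form isodose radius of the error-function plan (oracle for the
# bisection in isodoseDiameterTruth)
isodoseRadiusClosedForm <- function(plan, pct) {
  plan@r50 - plan@penumbraSigma * qnorm(pct / 100)
}
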