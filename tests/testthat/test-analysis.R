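# Film analyses: centroid error, isodose-distance profiles, gamma pass
# rates, and repetition summaries.

filmPair <- function(spacing = dpiToSpacing(75)) {
  plan <- planModel()
  list(axial = renderPlanImage(plan, "axial", spacing),
       sagittal = renderPlanImage(plan, "sagittal", spacing))
}

test_that("centroid error vanishes for the symmetric plan and tracks known shifts", {
  fp <- filmPair()
  ce <- centroidError(fp$axial, fp$sagittal)
  expect_lt(max(abs(unlist(ce))), 0.02)
  # a +1 mm SI shift of the sagittal film moves the SI centroid by 1 mm
  shifted <- blurWithTrajectory(fp$sagittal,
    motionTrajectory(seq(0, 1, by = 0.01), si = 1), 100)
  ce1 <- centroidError(fp$axial, shifted)
  expect_equal(ce1$si, 1, tolerance = 0.05)
  expect_error(centroidError(fp$sagittal, fp$axial), "axial")
  # dose-weighted mode agrees for the symmetric plan
  cw <- centroidError(fp$axial, fp$sagittal, weighted = TRUE)
  expect_lt(max(abs(unlist(cw))), 0.02)
})

test_that("centroid displacement is the componentwise difference and is antisymmetric", {
  a <- list(si = 0.19, lr = 0.09, ap = 0.12)
  b <- list(si = -0.04, lr = 0.00, ap = 0.09)
  d <- centroidDisplacement(a, b)
  expect_equal(unlist(d), c(si = 0.23, lr = 0.09, ap = 0.03))
  expect_equal(unlist(centroidDisplacement(b, a)), -unlist(d))
  expect_equal(unlist(centroidDisplacement(a, a)), c(si = 0, lr = 0, ap = 0))
})

test_that("profiles come off the right film, at the right offset and spacing", {
  fp <- filmPair()
  pr <- extractProfile(fp$sagittal, "SI", offset = 3)
  expect_equal(diff(pr$pos)[1], dpiToSpacing(75), tolerance = 1e-12)
  expect_equal(attr(pr, "offset"), 3, tolerance = dpiToSpacing(75))
  # symmetric plan -> symmetric profile
  expect_lt(max(abs(pr$dose - rev(pr$dose))), 1)
  # the off-centre line never reaches the true maximum
  expect_lt(max(pr$dose), 600)
  expect_error(extractProfile(fp$axial, "SI"), "sagittal")
  expect_error(extractProfile(fp$sagittal, "SI", offset = 50), "outside")
})

test_that("isodose distances interpolate linearly and order by level", {
  # triangle profile, peak 100 at x = 0 over [-10, 10]: closed form
  pos <- seq(-12, 12, by = 0.5)
  tri <- data.frame(pos = pos, dose = pmax(0, 100 * (1 - abs(pos) / 10)))
  expect_equal(isodoseDistance(tri, 100, 50), 10)
  expect_error(isodoseDistance(tri, 100, 150), "0 times")
  twoPeaks <- data.frame(pos = pos, dose = 50 + 40 * cos(pos))
  expect_error(isodoseDistance(twoPeaks, 100, 60), "times")
  # unblurred plan at the centre line reproduces the analytic diameters
  plan <- planModel()
  img <- renderPlanImage(plan, "sagittal", dpiToSpacing(75))
  ctr <- extractProfile(img, "SI", offset = 0)
  expect_equal(isodoseDistance(ctr, plan@dMax, 70), 25.75, tolerance = 0.05)
  d <- vapply(c(90, 80, 70, 50, 20), function(p)
    isodoseDistance(ctr, plan@dMax, p), 0)
  expect_true(all(diff(d) > 0))
  # ... and each matches the bisection ground truth
  for (i in seq_along(d))
    expect_equal(d[i], isodoseDiameterTruth(plan, c(90, 80, 70, 50, 20)[i]),
                 tolerance = 0.05)
})

test_that("gamma is exact on identical inputs and tolerant of pure dose offsets", {
  ref <- blobImage()
  for (cr in list(c(2, 3), c(2, 2), c(1, 3)))
    expect_equal(passRate(gammaPassRate(ref, ref, cr[1], cr[2],
                                        roiMm = 16, slitExclusionMm = 1)),
                 100)
  # a uniform offset of half the dose criterion passes everywhere
  up <- doseImage(doseGrid(ref) + 0.5 * 0.03 * max(doseGrid(ref)), 1, "axial")
  expect_equal(passRate(gammaPassRate(ref, up, 2, 3, roiMm = 16,
                                      slitExclusionMm = 1)), 100)
  expect_error(gammaPassRate(ref, blobImage(n = 11), 2, 3), "co-registered|share")
})

test_that("gamma pass rate is monotone in the criteria and matches the brute-force oracle", {
  ref <- blobImage(sigma = 5)
  pert <- doseImage(doseGrid(blobImage(sigma = 5, shiftX = 0.6)) *
                      smoothFieldR(21, 1, seed = 8, scale = 0.03), 1, "axial")
  prs <- vapply(list(c(2, 3), c(2, 2), c(1, 3)), function(cr)
    passRate(gammaPassRate(ref, pert, cr[1], cr[2], roiMm = 16,
                           slitExclusionMm = 1)), 0)
  expect_lte(prs[2], prs[1] + 1e-9)   # 2/2 no looser than 2/3
  expect_lte(prs[3], prs[1] + 1e-9)   # 1/3 no looser than 2/3
  oracle <- gammaBruteR(ref, pert, 2, 3, roiMm = 16, slitExclusionMm = 1,
                        step = 0.02)
  expect_lt(abs(prs[1] - oracle$passRate), 0.5)
})

test_that("repetition summaries report mean and SD per condition", {
  res <- data.frame(condition = rep("trk_1d", 3), metric = "gamma_2_3",
                    value = c(99, 100, 101))
  s <- summarizeConditions(res)
  expect_equal(s$mean, 100)
  expect_equal(s$sd, 1)
  one <- summarizeConditions(data.frame(condition = "a", metric = "m",
                                        value = 5))
  expect_identical(one$sd, 0)
  expect_equal(one$n, 1)
})
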