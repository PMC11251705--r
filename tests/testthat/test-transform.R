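test_that("two-segment mapping hits both line equations and extrapolates", {
  lm <- LandmarkSet(0, 0, 2, 4, 8, alpha = 0, beta = 95)
  sc <- StandardScale(0, 5, 10, beta = 95, invScaleFactor = 1,
                      modality = "AC")
  # segment 1 slope 2.5, segment 2 slope 2.5; 6 > pBeta is extrapolated
  expect_equal(mapIntensities(c(1, 3, 6), lm, sc), c(2.5, 7.5, 15))
  expect_equal(mapIntensities(2, lm, sc), 5)                 # pM -> sM exact
  expect_equal(mapIntensities(c(0, 4), lm, sc), c(0, 10))    # ends exact
  # landmarks already on the standard scale: identity
  lmId <- LandmarkSet(0, 0, 5, 10, 20, alpha = 0, beta = 95)
  x <- c(0, 1.3, 5, 7.7, 10, 18)
  expect_equal(mapIntensities(x, lmId, sc), x)
  bad <- LandmarkSet(0, 0, 2, 4, 8, alpha = 0, beta = 95)
  bad@pM <- 0  # degenerate on purpose, bypassing the constructor
  expect_error(mapIntensities(1, bad, sc), "degenerate")
})

test_that("intermediate image records realized extremes, never clipped", {
  img <- blockImage(1000, insertLevel = 9000)
  lm <- extractLandmarks(img, beta = 95)
  sc <- StandardScale(0, 30000, 50000, beta = 95, invScaleFactor = 1,
                      modality = "AC")
  inter <- mapToStandardScale(img, lm, sc)
  expect_gte(inter@sMaxReal, sc@sMax)
  expect_equal(max(voxels(inter)), inter@sMaxReal)
  expect_equal(inter@sMinReal, sc@sMin)  # pAlpha = min(I) case
})

test_that("standardization composes the landmark map with the inverse scale", {
  cfg <- phantomConfig(seed = 40)
  coh <- generateCohort(cfg, 6)
  imgs <- subjectImages(coh)
  msks <- subjectMasks(coh, "liver")
  scale <- calibrate(imgs, msks, step = 0.5)

  std <- standardize(imgs[[1]], scale)
  lm <- extractLandmarks(imgs[[1]], beta = scale@beta)
  inter <- mapToStandardScale(imgs[[1]], lm, scale)
  expect_equal(voxels(std), invScaleFactor(scale) * voxels(inter))

  # landmark exactness of the composed mapping
  psi <- function(x) invScaleFactor(scale) * mapIntensities(x, lm, scale)
  expect_equal(psi(lm@pAlpha), invScaleFactor(scale) * scale@sMin,
               tolerance = 1e-12)
  expect_equal(psi(lm@pM), invScaleFactor(scale) * scale@sM,
               tolerance = 1e-12)
  expect_equal(psi(lm@pBeta), invScaleFactor(scale) * scale@sMax,
               tolerance = 1e-12)

  # provenance carries the applied step
  prov <- provenance(std)
  expect_length(prov, 1)
  expect_equal(prov[[1]]$op, "s-AC")
  expect_equal(prov[[1]]$beta, scale@beta)

  # modality guard
  suv <- toSUV(imgs[[1]], doseMBq = 500, weightKg = 70)
  expect_error(standardize(suv, scale), "modality mismatch")
})

test_that("standardization is invariant to a global intensity gain", {
  cfg <- phantomConfig(seed = 41)
  coh <- generateCohort(cfg, 6)
  imgs <- subjectImages(coh)
  scale <- calibrate(imgs, subjectMasks(coh, "liver"), step = 0.5)
  img <- imgs[[2]]
  a <- voxels(standardize(img, scale))
  b <- voxels(standardize(PetImage(3 * voxels(img), "AC"), scale))
  expect_lt(max(abs(a - b)), 1e-8 * max(abs(a)))
})

test_that("SUV conversion follows dose-per-weight with unit body density", {
  img <- constImage(5000)
  suv <- toSUV(img, doseMBq = 555, weightKg = 74)
  # 5000 Bq/ml = 0.005 MBq/ml; dose/weight = 555/74000 MBq/g
  expect_equal(voxels(suv)[1], 0.005 / (555 / 74000), tolerance = 1e-12)
  expect_equal(modality(suv), "SUV")
  expect_equal(voxels(toSUV(constImage(0), doseMBq = 555,
                            weightKg = 74))[1], 0)
  # ratio invariance
  expect_equal(voxels(toSUV(img, doseMBq = 1110, weightKg = 148)),
               voxels(suv))
  expect_error(toSUV(img, doseMBq = -1, weightKg = 74), "positive")
  expect_error(toSUV(suv, doseMBq = 555, weightKg = 74), "AC-modality")
  # metadata fallback
  img2 <- PetImage(voxels(img), "AC",
                   metadata = list(doseMBq = 555, weightKg = 74))
  expect_equal(voxels(toSUV(img2)), voxels(suv))
})

test_that("operation chains recalibrate on the transformed calibration set", {
  cfg <- phantomConfig(seed = 43)
  coh <- generateCohort(cfg, 8)
  cal <- generateCohort(phantomConfig(seed = 1043), 6)
  imgs <- subjectImages(coh)
  msks <- subjectMasks(coh, "liver")
  ci <- subjectImages(cal)
  cm <- subjectMasks(cal, "liver")

  # a one-step chain equals plain standardization with the same scale
  r1 <- applySequence(imgs, "s-AC", ci, cm, step = 0.5)
  sc <- calibrate(ci, cm, step = 0.5)
  expect_equal(voxels(r1$images[[1]]), voxels(standardize(imgs[[1]], sc)))

  # second application changes organ means by < 10%
  r2 <- applySequence(imgs, c("s-AC", "s-AC"), ci, cm, step = 0.5)
  mu1 <- mapply(organMean, r1$images, msks)
  mu2 <- mapply(organMean, r2$images, msks)
  expect_true(all(abs(mu2 - mu1) / mu1 < 0.10))
  expect_length(r2$scales, 2)

  # chain typing is enforced
  expect_error(applySequence(imgs, c("SUV", "SUV"), ci, cm, step = 0.5),
               "inconsistent chain")
  expect_error(applySequence(imgs, "s-SUV", ci, cm, step = 0.5),
               "inconsistent chain")
})

test_that("direct SUV standardization beats standardize-then-convert", {
  cfg <- phantomConfig(seed = 44)
  coh <- generateCohort(cfg, 12)
  cal <- generateCohort(phantomConfig(seed = 1044), 8)
  imgs <- subjectImages(coh)
  msks <- subjectMasks(coh, "liver")
  ci <- subjectImages(cal)
  cm <- subjectMasks(cal, "liver")
  viaAC <- applySequence(imgs, c("s-AC", "SUV"), ci, cm, step = 0.5)
  direct <- applySequence(imgs, c("SUV", "s-SUV"), ci, cm, step = 0.5)
  cvA <- cvMetric(viaAC$images, msks)@CV
  cvB <- cvMetric(direct$images, msks)@CV
  expect_lt(cvB, cvA)
})
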