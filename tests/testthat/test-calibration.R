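mkLandmarks <- function(pM, pBeta, maxVal = 10 * pBeta)
  LandmarkSet(minVal = 0, pAlpha = 0, pM = pM, pBeta = pBeta,
              maxVal = maxVal, alpha = 0, beta = 95)

test_that("linear scale factor is (sMax - sMin) / (pBeta - pAlpha)", {
  expect_equal(linearScaleFactor(mkLandmarks(1000, 10000), 0, 50000), 5)
  expect_equal(linearScaleFactor(mkLandmarks(2, 5), 0, 5), 1)
  expect_equal(linearScaleFactor(mkLandmarks(1, 2), 0, 5), 2.5)
})

test_that("standard median is the mean of per-image mapped body medians", {
  # lambda(pM) = sMax * pM / pBeta when alpha = 0 = sMin
  lms <- list(mkLandmarks(1, 4), mkLandmarks(2, 4))
  expect_equal(estimateStandardMedian(lms, 0, 8), 3)        # (2 + 4) / 2
  lms3 <- list(mkLandmarks(1, 4), mkLandmarks(2, 4), mkLandmarks(1, 2))
  expect_equal(estimateStandardMedian(lms3, 0, 8), 10 / 3)  # (2 + 4 + 4) / 3
  # identical images: sM is the common mapped median
  expect_equal(estimateStandardMedian(list(mkLandmarks(3, 6),
                                           mkLandmarks(3, 6)), 0, 12), 6)
  expect_error(estimateStandardMedian(list(), 0, 8), "empty")
})

test_that("reference-organ CV matches an independent brute-force path", {
  cfg <- phantomConfig(seed = 21)
  coh <- generateCohort(cfg, 5)
  imgs <- subjectImages(coh)
  msks <- subjectMasks(coh, "liver")
  b <- 96
  res <- deltaForPercentile(b, imgs, msks, sMin = 0, sMax = 50000)

  # brute force: explicit per-image landmark mapping, then CV by hand
  # (pAlpha = min(I) is near, but not exactly, zero on noisy phantoms)
  lms <- lapply(imgs, extractLandmarks, beta = b)
  sM <- mean(vapply(lms, function(l)
    50000 / (l@pBeta - l@pAlpha) * (l@pM - l@pAlpha), numeric(1)))
  mus <- mapply(function(img, msk, l) {
    scale <- StandardScale(0, sM, 50000, beta = b, invScaleFactor = 1,
                           modality = "AC")
    mean(mapIntensities(voxels(img), l, scale)[voxels(msk)])
  }, imgs, msks, lms)
  expect_equal(res$m, mean(mus), tolerance = 1e-10)
  expect_equal(res$sigma, stats::sd(mus), tolerance = 1e-10)
  expect_equal(res$delta, stats::sd(mus) / mean(mus), tolerance = 1e-10)

  # identical images give zero CV
  same <- rep(imgs[1], 4)
  res0 <- deltaForPercentile(b, same, rep(msks[1], 4), 0, 50000)
  expect_equal(res0$sigma, 0)
  expect_equal(res0$delta, 0)

  # CV is invariant under a global intensity rescaling of the cohort
  scaled <- lapply(imgs, function(i) PetImage(3.7 * voxels(i), "AC"))
  res2 <- deltaForPercentile(b, scaled, msks, 0, 50000)
  expect_equal(res2$delta, res$delta, tolerance = 1e-10)
})

test_that("upper-percentile search returns the grid argmin, ties to largest b", {
  pl <- plantedCutoffCohort(8, seed = 42)
  res <- optimizeBeta(pl$images, pl$liver, sMin = 0, sMax = 50000)
  # internal consistency: betaOpt attains the minimum of the trace
  ok <- is.finite(res@deltaValues)
  expect_equal(min(res@deltaValues[ok]),
               res@deltaValues[res@bGrid == res@betaOpt])
  # below the planted cutoff all candidates tie at delta = 0; the largest wins
  expect_equal(res@deltaValues[res@bGrid == 90], 0)
  expect_equal(res@betaOpt, 94.9)

  single <- optimizeBeta(pl$images, pl$liver, sMin = 0, sMax = 50000,
                         bLow = 96, bHigh = 96)
  expect_equal(single@betaOpt, 96)
  expect_error(optimizeBeta(pl$images[1:2], pl$liver[1:2], sMin = 0,
                            sMax = 50000), "at least 3")
})

test_that("inverse scale factor excludes factors beyond one sample SD", {
  # retained mean 6.00 -> reciprocal 0.167 to three decimals
  expect_equal(round(estimateInvScaleFactor(c(5, 6, 7, 100)), 3), 0.167)
  expect_equal(estimateInvScaleFactor(c(2, 2, 2)), 0.5)
  # {1,2,3,100}: mean 26.5, sample SD 49.0 -> 100 excluded, mean 2
  expect_equal(estimateInvScaleFactor(c(1, 2, 3, 100)), 0.5)
  expect_equal(estimateInvScaleFactor(5), 0.2)  # single factor kept
  expect_error(estimateInvScaleFactor(numeric(0)), "no scale factors")
  expect_error(estimateInvScaleFactor(c(1, -2)), "positive")
})

test_that("sMax choice enforces unit slope of the composed mapping", {
  # zero background so pAlpha = 0; single image: both segment slopes equal
  # sMax / pBeta, so the binding candidate is the first one >= pBeta
  v <- array(0, c(12L, 12L, 12L))
  v[3:10, 3:10, 3:10] <- 3           # body block
  v[3:6, 3:6, 3:6] <- 4.5            # hot insert, 12.5% of the body
  img <- PetImage(v, "AC")
  lm <- extractLandmarks(img, beta = 95)
  pB <- lm@pBeta
  grid <- seq(0.5, 3 * pB, by = 0.25)
  chosen <- chooseSMax(list(img), beta = 95, candidates = grid)
  expect_equal(chosen, grid[which(grid >= pB)[1]])
  # exact-threshold candidate is accepted
  expect_equal(chooseSMax(list(img), beta = 95,
                          candidates = c(pB / 2, pB, 2 * pB)), pB)
  # dx does not enter the slope criterion
  expect_equal(chooseSMax(list(img), beta = 95, candidates = grid,
                          dx = 0.02), chosen)
  # a fixed inverse-scale multiplier shifts the requirement proportionally
  expect_equal(chooseSMax(list(img), beta = 95, candidates = grid,
                          lambdaInv = 2),
               grid[which(grid >= pB / 2)[1]])
  expect_error(chooseSMax(list(img), beta = 95, candidates = pB / 10),
               "minimum slope")
})

test_that("calibration on identical images inverts its own scale factor", {
  cfg <- phantomConfig(seed = 30, noiseCV = 0, gainRange = c(1, 1))
  img <- subjectImage(generateSubject(cfg, 1))
  msk <- subjectMask(generateSubject(cfg, 1), "liver")
  imgs <- rep(list(img), 4)
  scale <- calibrate(imgs, rep(list(msk), 4))
  lm <- extractLandmarks(img, beta = scale@beta)
  f <- 50000 / (lm@pBeta - lm@pAlpha)
  expect_equal(invScaleFactor(scale), 1 / f, tolerance = 1e-12)
  expect_equal(scale@sM, f * (lm@pM - lm@pAlpha), tolerance = 1e-12)
})

test_that("two-gain noise-free cohort yields the closed-form scale factors", {
  cfg <- phantomConfig(seed = 31, noiseCV = 0, gainRange = c(1, 1))
  s <- generateSubject(cfg, 1)
  img1 <- subjectImage(s)
  img2 <- PetImage(2 * voxels(img1), "AC")
  msk <- subjectMask(s, "liver")
  scale <- calibrate(list(img1, img1, img2, img2), rep(list(msk), 4))
  lm <- extractLandmarks(img1, beta = scale@beta)
  f <- 50000 / (lm@pBeta - lm@pAlpha)
  expect_equal(sort(unique(round(scale@search$scaleFactors, 9))),
               sort(round(c(f / 2, f), 9)))
  # all four factors lie within one SD of their mean, so none are excluded
  expect_equal(invScaleFactor(scale), 1 / (0.75 * f), tolerance = 1e-12)
})

test_that("calibration is scale-equivariant", {
  cfg <- phantomConfig(seed = 33)
  coh <- generateCohort(cfg, 6)
  imgs <- subjectImages(coh)
  msks <- subjectMasks(coh, "liver")
  s1 <- calibrate(imgs, msks, step = 0.5)
  c <- 4.2
  s2 <- calibrate(lapply(imgs, function(i) PetImage(c * voxels(i), "AC")),
                  msks, step = 0.5)
  expect_equal(s2@beta, s1@beta)
  expect_equal(s2@sM, s1@sM, tolerance = 1e-9)
  expect_equal(invScaleFactor(s2), c * invScaleFactor(s1),
               tolerance = 1e-9)
})
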