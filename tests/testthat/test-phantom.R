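test_that("subject generation is deterministic and seed-sensitive", {
  cfg <- phantomConfig(seed = 70)
  a <- generateSubject(cfg, 3)
  b <- generateSubject(cfg, 3)
  expect_identical(voxels(subjectImage(a)), voxels(subjectImage(b)))
  expect_identical(petMetadata(a)$planted$gain, petMetadata(b)$planted$gain)

  other <- generateSubject(phantomConfig(seed = 71), 3)
  expect_false(identical(voxels(subjectImage(a)),
                         voxels(subjectImage(other))))
  expect_false(organMean(subjectImage(a), subjectMask(a, "liver")) ==
                 organMean(subjectImage(other), subjectMask(other, "liver")))
})

test_that("noise-free generation plants organ means exactly", {
  liverSpec <- list(name = "liver", center = c(0.64, 0.50, 0.53) * 32,
                    radii = c(0.19, 0.155, 0.155) * 32,
                    meanRange = c(5000, 5000))
  spleenSpec <- list(name = "spleen", center = c(0.33, 0.53, 0.47) * 32,
                     radii = c(0.125, 0.09, 0.09) * 32,
                     meanRange = c(4000, 4000))
  cfg <- phantomConfig(seed = 72, noiseCV = 0, gainRange = c(1, 1),
                       organSpecs = list(liverSpec, spleenSpec))
  s <- generateSubject(cfg, 1)
  expect_equal(organMean(subjectImage(s), subjectMask(s, "liver")), 5000)
  expect_equal(organMean(subjectImage(s), subjectMask(s, "spleen")), 4000)
})

test_that("voxels are non-negative and the histogram is bimodal", {
  cfg <- phantomConfig(seed = 73)
  coh <- generateCohort(cfg, 5)
  for (s in coh) {
    v <- voxels(subjectImage(s))
    expect_gte(min(v), 0)
    # valley below mean(I): the fraction of voxels under the mean matches
    # the configured background fraction within 5% relative
    frac <- mean(v < mean(v))
    expect_lt(abs(frac - cfg@backgroundFraction),
              0.05 * cfg@backgroundFraction)
    # hot spots push the maximum well above the body's 99th percentile
    body <- voxels(subjectMask(s, "body_truth"))
    expect_gt(max(v[body]), percentileOf(v[body], 99))
  }
})

test_that("planted organ means are recovered within sampling error", {
  cfg <- phantomConfig(seed = 74)
  coh <- generateCohort(cfg, 8)
  for (s in coh) {
    planted <- petMetadata(s)$planted
    for (org in c("liver", "spleen")) {
      msk <- subjectMask(s, org)
      mu <- organMean(subjectImage(s), msk)
      n <- sum(voxels(msk))
      relTol <- 3 * cfg@noiseCV * max(cfg@organHetRange) / sqrt(n)
      expect_lt(abs(mu - planted$organMeans[[org]]) /
                  planted$organMeans[[org]], relTol)
    }
  }
})

test_that("cohorts have unique ids, non-empty masks and real gain spread", {
  cfg <- phantomConfig(seed = 75)
  coh <- generateCohort(cfg, 5)
  expect_length(coh, 5)
  ids <- vapply(coh, function(s) petMetadata(s)$subjectId, character(1))
  expect_equal(anyDuplicated(ids), 0L)
  for (s in coh)
    for (nm in c("liver", "spleen", "body_truth"))
      expect_true(any(voxels(subjectMask(s, nm))))
  expect_error(generateCohort(cfg, 1), "at least 2")

  big <- generateCohort(phantomConfig(seed = 76, gainRange = c(0.5, 2)), 30)
  cv <- cvMetric(subjectImages(big), subjectMasks(big, "liver"))@CV
  expect_gte(cv, 0.20)
})

test_that("repeat pairs share biology and perturb organ means as configured", {
  # no repeat change, no noise: paired liver means identical
  cfg0 <- phantomConfig(seed = 77, noiseCV = 0, repeatDeltaCV = 0)
  p0 <- generateRepeatPairs(cfg0, 2)
  for (p in p0)
    expect_equal(organMean(subjectImage(p[[1]]), subjectMask(p[[1]], "liver")),
                 organMean(subjectImage(p[[2]]), subjectMask(p[[2]], "liver")))

  expect_length(generateRepeatPairs(phantomConfig(seed = 78), 3), 3)

  # default 5% repeat change: mean normalized difference in a sane band
  cfg <- phantomConfig(seed = 79)
  pairs <- generateRepeatPairs(cfg, 20)
  md <- mdMetric(pairImages(pairs), pairMasks(pairs, "liver"))@MD
  expect_gt(md, 0.01)
  expect_lt(md, 0.15)
  # pairing is recorded
  expect_equal(petMetadata(pairs[[1]][[1]])$pairId,
               petMetadata(pairs[[1]][[2]])$pairId)
})

test_that("two-scanner cohorts realize a pure gain contrast", {
  base <- function(gain, id) phantomConfig(seed = 80, noiseCV = 0,
                                           gainRange = gain, scannerId = id)
  tc <- generateTwoScannerCohorts(base(c(1, 1), "A"), base(c(3, 3), "B"), 3)
  expect_length(tc$A, 3)
  expect_length(tc$B, 3)
  for (i in 1:3) {
    muA <- organMean(subjectImage(tc$A[[i]]), subjectMask(tc$A[[i]], "liver"))
    muB <- organMean(subjectImage(tc$B[[i]]), subjectMask(tc$B[[i]], "liver"))
    expect_equal(muB, 3 * muA, tolerance = 1e-12)
    expect_equal(petMetadata(tc$A[[i]])$scannerId, "A")
    expect_equal(petMetadata(tc$B[[i]])$scannerId, "B")
  }

  # noisy version: raw liver means differ by a factor near 3
  cfgA <- phantomConfig(seed = 81, gainRange = c(0.8, 1.2), scannerId = "A")
  cfgB <- phantomConfig(seed = 82, gainRange = c(2.4, 3.6), scannerId = "B")
  tc2 <- generateTwoScannerCohorts(cfgA, cfgB, 10)
  mA <- mean(mapply(organMean, subjectImages(tc2$A),
                    subjectMasks(tc2$A, "liver")))
  mB <- mean(mapply(organMean, subjectImages(tc2$B),
                    subjectMasks(tc2$B, "liver")))
  expect_gt(mB / mA, 2.2)
  expect_lt(mB / mA, 3.8)
})

test_that("configuration invariants are enforced", {
  expect_error(phantomConfig(gridShape = c(8, 32, 32)), ">= 16")
  expect_error(phantomConfig(backgroundFraction = 1.2), "\\(0, 1\\)")
  expect_error(phantomConfig(gainRange = c(2, 1)), "low <= high")
  badOrgan <- list(name = "liver", center = c(2, 2, 2),
                   radii = c(8, 8, 8), meanRange = c(5000, 6000))
  expect_error(phantomConfig(organSpecs = list(badOrgan)),
               "does not fit inside the body")
})
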