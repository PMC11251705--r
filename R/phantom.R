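#' @include evaluation.R
NULL

## semi-axes of the body ellipsoid realizing (approximately) the requested
## body volume fraction inside the grid
.bodySemiAxes <- function(gridShape, backgroundFraction) {
  f <- (6 * (1 - backgroundFraction) / pi)^(1 / 3)
  f * gridShape / 2
}

.ellipsoidMask <- function(dims, center, radii) {
  dx <- ((seq_len(dims[1]) - center[1]) / radii[1])^2
  dy <- ((seq_len(dims[2]) - center[2]) / radii[2])^2
  dz <- ((seq_len(dims[3]) - center[3]) / radii[3])^2
  outer(outer(dx, dy, "+"), dz, "+") <= 1
}

## evaluate code with a temporary RNG state, restoring the caller's stream
.withSeed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

.subjectSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %%
               2147483629)
}

.defaultOrganSpecs <- function(gridShape) {
  d <- gridShape
  list(
    list(name = "liver",
         center = c(0.64, 0.50, 0.53) * d,
         radii = c(0.190, 0.155, 0.155) * d,
         meanRange = c(7600, 8600)),
    list(name = "spleen",
         center = c(0.33, 0.53, 0.47) * d,
         radii = c(0.125, 0.090, 0.090) * d,
         meanRange = c(7000, 7900))
  )
}

#' Configure the synthetic PET phantom
#'
#' Builds a validated \linkS4class{PhantomConfig}. The defaults emulate a
#' torso FDG-PET acquisition: a bimodal whole-volume histogram (near-zero
#' background plus a body mode), reference organs (liver, spleen) with
#' uptake above the surrounding body tissue, a handful of bright, highly
#' variable hot spots in the upper intensity tail, and a per-subject
#' multiplicative scanner/dose gain. Organ mean ranges times the default
#' gain range span the population range of normal liver/spleen activity
#' concentration (roughly 3,000 to 18,700 Bq/ml).
#'
#' @param gridShape voxels per axis (each at least 16).
#' @param backgroundFraction fraction of voxels outside the body, in
#'   (0, 1); values much above 0.52 cannot be realized by an ellipsoidal
#'   body inside the grid and saturate.
#' @param bodyLevel central body-tissue intensity (Bq/ml).
#' @param organSpecs list of organ specifications, each a list with
#'   \code{name}, ellipsoid \code{center} and \code{radii} (voxel units),
#'   and \code{meanRange} (low, high) for the subject-level mean uptake
#'   draw. Defaults place a liver and a spleen inside the body.
#' @param hotspotCountRange integer (low, high) for the number of hot
#'   spots per subject.
#' @param hotspotMultRange intensity multiplier range relative to
#'   \code{bodyLevel}.
#' @param hotspotRadiusRange hot-spot sphere radius range (voxels).
#' @param gainRange per-subject multiplicative gain interval.
#' @param noiseCV within-tissue coefficient of variation of voxel noise
#'   (noise SD is \code{noiseCV} times the local mean, truncated at 0).
#' @param organHetRange per-subject multiplier range applied to the organ
#'   noise CV, emulating subject-specific tissue texture so that
#'   within-organ dispersion is not a fixed fraction of the organ mean.
#' @param repeatDeltaCV between-repeat relative change of organ means.
#' @param doseRange injected dose range (MBq).
#' @param weightRange body weight range (kg).
#' @param scannerId scanner label stamped into subject metadata.
#' @param seed integer master seed; every subject derives its own
#'   substream from (seed, subject index).
#' @return a \linkS4class{PhantomConfig}.
#' @examples
#' cfg <- phantomConfig(seed = 1)
#' sub <- generateSubject(cfg, 1)
#' organMean(subjectImage(sub), subjectMask(sub, "liver"))
#' @export
phantomConfig <- function(gridShape = c(32L, 32L, 32L),
                          backgroundFraction = 0.5,
                          bodyLevel = 6000,
                          organSpecs = .defaultOrganSpecs(gridShape),
                          hotspotCountRange = c(2L, 5L),
                          hotspotMultRange = c(3, 10),
                          hotspotRadiusRange = c(1.5, 2.5),
                          gainRange = c(0.5, 2.0),
                          noiseCV = 0.12,
                          organHetRange = c(0.5, 2.5),
                          repeatDeltaCV = 0.05,
                          doseRange = c(450, 650),
                          weightRange = c(49, 98),
                          scannerId = "scanner1",
                          seed = 1234L) {
  new("PhantomConfig",
      gridShape = as.integer(gridShape),
      backgroundFraction = backgroundFraction,
      bodyLevel = bodyLevel, organSpecs = organSpecs,
      hotspotCountRange = as.integer(hotspotCountRange),
      hotspotMultRange = hotspotMultRange,
      hotspotRadiusRange = hotspotRadiusRange,
      gainRange = gainRange, noiseCV = noiseCV,
      organHetRange = organHetRange, repeatDeltaCV = repeatDeltaCV,
      doseRange = doseRange, weightRange = weightRange,
      scannerId = scannerId, seed = as.integer(seed))
}

.runif1 <- function(range) stats::runif(1, range[1], range[2])

## Core generator. `shared` may pre-set gain, organMeansBase, het, doseMBq,
## weightKg (used by repeat pairs); draws it provides are skipped.
.generateSubjectImpl <- function(config, index, shared = list()) {
  dims <- config@gridShape
  ctr <- (dims + 1) / 2
  semi <- .bodySemiAxes(dims, config@backgroundFraction)
  body <- .ellipsoidMask(dims, ctr, semi)
  if (!any(body))
    stop("degenerate configuration: empty body region")
  organMasks <- lapply(config@organSpecs, function(sp)
    .ellipsoidMask(dims, sp$center, sp$radii))
  names(organMasks) <- vapply(config@organSpecs, `[[`, character(1), "name")
  for (om in organMasks)
    if (!any(om)) stop("degenerate configuration: empty organ mask")
  anyOrgan <- Reduce(`|`, organMasks)

  .withSeed(.subjectSeed(config@seed, index), {
    gain <- if (!is.null(shared$gain)) shared$gain
            else .runif1(config@gainRange)
    organMeansBase <- if (!is.null(shared$organMeansBase))
      shared$organMeansBase
    else vapply(config@organSpecs, function(sp)
      .runif1(sp$meanRange), numeric(1))
    names(organMeansBase) <- names(organMasks)
    het <- if (!is.null(shared$het)) shared$het
           else vapply(names(organMasks),
                       function(nm) .runif1(config@organHetRange),
                       numeric(1))
    doseMBq <- if (!is.null(shared$doseMBq)) shared$doseMBq
               else .runif1(config@doseRange)
    weightKg <- if (!is.null(shared$weightKg)) shared$weightKg
                else .runif1(config@weightRange)

    ## hot spots: bright spheres inside the body, outside named organs
    nHot <- if (config@hotspotCountRange[2] > config@hotspotCountRange[1])
      sample(config@hotspotCountRange[1]:config@hotspotCountRange[2], 1)
    else config@hotspotCountRange[1]
    hotMask <- array(FALSE, dims)
    hotLevels <- numeric(0)
    hotLocal <- array(0, dims)
    placed <- 0L
    tries <- 0L
    while (placed < nHot && tries < 200L) {
      tries <- tries + 1L
      cand <- ctr + (stats::runif(3, -1, 1) * 0.70) * semi
      r <- .runif1(config@hotspotRadiusRange)
      mult <- .runif1(config@hotspotMultRange)
      sph <- .ellipsoidMask(dims, cand, rep(r, 3))
      if (!any(sph)) next
      if (any(sph & !body) || any(sph & anyOrgan) || any(sph & hotMask))
        next
      hotMask <- hotMask | sph
      hotLocal[sph] <- config@bodyLevel * mult * gain
      hotLevels <- c(hotLevels, mult)
      placed <- placed + 1L
    }

    localMean <- array(0, dims)
    localMean[body] <- config@bodyLevel * gain
    sdArr <- config@noiseCV * localMean
    for (nm in names(organMasks)) {
      mu <- organMeansBase[[nm]] * gain
      om <- organMasks[[nm]]
      localMean[om] <- mu
      sdArr[om] <- config@noiseCV * het[[nm]] * mu
    }
    localMean[hotMask] <- hotLocal[hotMask]
    sdArr[hotMask] <- config@noiseCV * hotLocal[hotMask]

    vox <- array(pmax(stats::rnorm(length(localMean), localMean, sdArr), 0),
                 dims)
    nbg <- sum(!body)
    vox[!body] <- abs(stats::rnorm(nbg, 0, 0.01 * config@bodyLevel * gain))

    subjectId <- sprintf("%s-S%03d", config@scannerId, index)
    masks <- c(lapply(names(organMasks), function(nm)
      OrganMask(organMasks[[nm]], nm)),
      list(OrganMask(body, "body_truth")))
    names(masks) <- c(names(organMasks), "body_truth")
    md <- list(subjectId = subjectId, scannerId = config@scannerId,
               doseMBq = doseMBq, weightKg = weightKg, modality = "AC",
               planted = list(gain = gain,
                              organMeansBase = organMeansBase,
                              organMeans = organMeansBase * gain,
                              het = het, hotspotMults = hotLevels))
    img <- PetImage(vox, "AC", metadata = md)
    new("PhantomSubject", image = img, masks = masks, metadata = md)
  })
}

#' Generate one synthetic subject
#'
#' Deterministic given (config seed, subject index): background voxels are
#' drawn near zero, body voxels around gain times \code{bodyLevel}, each
#' organ around a subject-specific mean drawn from its range times the
#' gain, and hot spots well above the body's upper tail.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @param subjectIndex positive integer.
#' @return a \linkS4class{PhantomSubject}.
#' @export
generateSubject <- function(config, subjectIndex) {
  stopifnot(is(config, "PhantomConfig"), subjectIndex >= 1)
  .generateSubjectImpl(config, subjectIndex)
}

#' Generate a cohort of independent subjects
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @param n number of subjects (at least 2).
#' @return list of \linkS4class{PhantomSubject} objects with unique ids.
#' @export
generateCohort <- function(config, n) {
  if (n < 2) stop("a cohort needs at least 2 subjects")
  lapply(seq_len(n), function(i) .generateSubjectImpl(config, i))
}

#' Generate repeat-scan pairs
#'
#' Each pair shares the subject's biology: the second scan perturbs the
#' organ means by a relative change with SD \code{repeatDeltaCV} and
#' redraws the voxel noise (and hot spots). By default the two scans also
#' share the subject gain; with \code{shareGain = FALSE} each scan draws
#' its own gain, emulating repeat scans acquired under different
#' scanner/dose conditions.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @param nPairs number of pairs (at least 1).
#' @param shareGain share the multiplicative gain within a pair.
#' @return list of two-element lists of \linkS4class{PhantomSubject}
#'   objects; pairing is recorded in the metadata \code{pairId}.
#' @export
generateRepeatPairs <- function(config, nPairs, shareGain = TRUE) {
  stopifnot(is(config, "PhantomConfig"), nPairs >= 1)
  lapply(seq_len(nPairs), function(i) {
    s1 <- .generateSubjectImpl(config, 2L * i - 1L)
    p <- s1@metadata$planted
    shared <- .withSeed(.subjectSeed(config@seed, 1000000L + i), {
      gain2 <- if (shareGain) p$gain else .runif1(config@gainRange)
      z <- stats::rnorm(length(p$organMeansBase))
      base2 <- pmax(p$organMeansBase * (1 + config@repeatDeltaCV * z),
                    0.05 * p$organMeansBase)
      list(gain = gain2, organMeansBase = base2, het = p$het,
           doseMBq = s1@metadata$doseMBq, weightKg = s1@metadata$weightKg)
    })
    s2 <- .generateSubjectImpl(config, 2L * i, shared = shared)
    pairId <- sprintf("P%03d", i)
    for (nm in c("a", "b")) {
      s <- if (nm == "a") s1 else s2
      s@metadata$pairId <- pairId
      s@metadata$subjectId <- sprintf("%s-%s", pairId, nm)
      s@image@metadata <- s@metadata
      if (nm == "a") s1 <- s else s2 <- s
    }
    list(s1, s2)
  })
}

#' Generate two single-scanner cohorts
#'
#' Emulates cohorts acquired on two scanner brands; typically the two
#' configurations differ only in \code{gainRange} (and
#' \code{scannerId}). Matching subject indices share their biological
#' draws when the two configurations share a seed, so pure gain contrasts
#' are exact.
#'
#' @param configA,configB \linkS4class{PhantomConfig} for each scanner.
#' @param nEach subjects per cohort.
#' @return list with cohorts \code{A} and \code{B}.
#' @export
generateTwoScannerCohorts <- function(configA, configB, nEach) {
  stopifnot(nEach >= 2)
  if (identical(configA@scannerId, configB@scannerId)) {
    configA@scannerId <- paste0(configA@scannerId, "-A")
    configB@scannerId <- paste0(configB@scannerId, "-B")
  }
  list(A = lapply(seq_len(nEach),
                  function(i) .generateSubjectImpl(configA, i)),
       B = lapply(seq_len(nEach),
                  function(i) .generateSubjectImpl(configB, i)))
}

#' Images of a phantom cohort
#'
#' @param cohort list of \linkS4class{PhantomSubject} objects.
#' @return list of \linkS4class{PetImage} objects.
#' @export
subjectImages <- function(cohort) lapply(cohort, subjectImage)

#' Organ masks of a phantom cohort
#'
#' @param cohort list of \linkS4class{PhantomSubject} objects.
#' @param organ mask name.
#' @return list of \linkS4class{OrganMask} objects.
#' @export
subjectMasks <- function(cohort, organ)
  lapply(cohort, subjectMask, organ = organ)
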