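#' @include AllGenerics.R
NULL

.MODALITIES <- c("AC", "SUV")

#' PetImage: a 3D scalar PET volume
#'
#' The central data object: a 3D array of non-negative, finite voxel
#' intensities, tagged with a modality (\code{"AC"} for activity
#' concentration in Bq/ml, or unitless \code{"SUV"}) and optional
#' acquisition metadata used for SUV conversion.
#'
#' @slot voxels numeric 3D array, all values finite and \eqn{\ge 0}.
#' @slot modality \code{"AC"} or \code{"SUV"}.
#' @slot metadata named list; recognised entries are \code{doseMBq},
#'   \code{weightKg}, \code{scannerId}, \code{subjectId}.
#'
#' @seealso \code{\link{PetImage}} for the constructor.
#' @export
setClass("PetImage",
         representation(voxels = "array", modality = "character",
                        metadata = "list"))

setValidity("PetImage", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L)
    return("'voxels' must be a 3D array")
  if (length(v) < 1L)
    return("image must contain at least one voxel")
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
    return("all voxel values must be finite numbers")
  if (min(v) < 0)
    return("negative voxel values are not allowed in a PET image")
  if (length(object@modality) != 1L || !(object@modality %in% .MODALITIES))
    return("'modality' must be \"AC\" or \"SUV\"")
  TRUE
})

#' Construct a PetImage
#'
#' @param voxels numeric 3D array of non-negative intensities.
#' @param modality \code{"AC"} (Bq/ml) or \code{"SUV"}.
#' @param metadata optional named list (\code{doseMBq}, \code{weightKg},
#'   \code{scannerId}, \code{subjectId}).
#' @return a \linkS4class{PetImage}.
#' @examples
#' img <- PetImage(array(runif(8 * 8 * 8, 0, 100), c(8, 8, 8)), "AC")
#' modality(img)
#' @export
PetImage <- function(voxels, modality = c("AC", "SUV"), metadata = list()) {
  modality <- match.arg(modality)
  storage.mode(voxels) <- "double"
  new("PetImage", voxels = voxels, modality = modality, metadata = metadata)
}

#' OrganMask: a binary volume naming an organ
#'
#' @slot voxels logical 3D array on the image grid.
#' @slot organ organ name, e.g. \code{"liver"}.
#' @export
setClass("OrganMask",
         representation(voxels = "array", organ = "character"))

setValidity("OrganMask", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L) return("mask must be a 3D array")
  if (!is.logical(v)) return("mask voxels must be logical")
  if (!any(v)) return("mask must be non-empty")
  if (length(object@organ) != 1L || !nzchar(object@organ))
    return("'organ' must be a non-empty name")
  TRUE
})

#' Construct an OrganMask
#'
#' @param voxels logical (or numeric; nonzero means inside) 3D array.
#' @param organ organ name.
#' @return an \linkS4class{OrganMask}.
#' @export
OrganMask <- function(voxels, organ) {
  if (!is.logical(voxels)) {
    stopifnot(is.numeric(voxels))
    voxels <- array(voxels != 0, dim(voxels))
  }
  new("OrganMask", voxels = voxels, organ = organ)
}

#' BodyMask: body-region segmentation by mean thresholding
#'
#' Voxels at or above the whole-volume mean intensity, separating the
#' patient's body from the near-zero background.
#'
#' @slot voxels logical 3D array.
#' @slot threshold the whole-volume mean used as threshold.
#' @export
setClass("BodyMask",
         representation(voxels = "array", threshold = "numeric"))

setValidity("BodyMask", function(object) {
  if (!is.logical(object@voxels)) return("mask voxels must be logical")
  if (!any(object@voxels)) return("body mask must be non-empty")
  TRUE
})

#' LandmarkSet: per-image intensity landmarks
#'
#' The five intensity landmarks anchoring the piecewise-linear mapping:
#' whole-volume minimum and maximum, the lower-percentile value (equal to
#' the minimum when \code{alpha = 0}), the body-region median, and the
#' body-region upper-percentile value.
#'
#' @slot minVal,maxVal whole-volume extrema.
#' @slot pAlpha lower-percentile landmark.
#' @slot pM body-region median.
#' @slot pBeta body-region upper-percentile landmark.
#' @slot alpha,beta the percentiles (in \eqn{[0, 100]}) that produced
#'   \code{pAlpha} and \code{pBeta}.
#' @export
setClass("LandmarkSet",
         representation(minVal = "numeric", pAlpha = "numeric",
                        pM = "numeric", pBeta = "numeric",
                        maxVal = "numeric", alpha = "numeric",
                        beta = "numeric"))

setValidity("LandmarkSet", function(object) {
  o <- object
  if (!(o@minVal <= o@pAlpha && o@pAlpha <= o@pM && o@pM < o@pBeta &&
        o@pBeta <= o@maxVal))
    return("landmark ordering min <= pAlpha <= pM < pBeta <= max violated")
  if (o@alpha < 0 || o@alpha > 100 || o@beta < 0 || o@beta > 100)
    return("percentiles must lie in [0, 100]")
  TRUE
})

#' Construct a LandmarkSet
#'
#' @param minVal,pAlpha,pM,pBeta,maxVal landmark intensities.
#' @param alpha,beta the generating percentiles.
#' @return a \linkS4class{LandmarkSet}.
#' @export
LandmarkSet <- function(minVal, pAlpha, pM, pBeta, maxVal, alpha, beta) {
  new("LandmarkSet", minVal = minVal, pAlpha = pAlpha, pM = pM,
      pBeta = pBeta, maxVal = maxVal, alpha = alpha, beta = beta)
}

#' StandardScale: the calibrated standardization parameters
#'
#' Output of \code{\link{calibrate}}; everything needed to standardize any
#' image of the matching modality.
#'
#' @slot sMin,sM,sMax landmarks on the standard scale.
#' @slot beta optimized upper percentile.
#' @slot alpha lower percentile (0 in the standard setting).
#' @slot invScaleFactor positive multiplier restoring physical magnitude
#'   after the landmark mapping.
#' @slot modality \code{"AC"} or \code{"SUV"}.
#' @slot dx discriminability step used when choosing \code{sMax}.
#' @slot search list with the upper-percentile search trace
#'   (\code{bGrid}, \code{deltaValues}) when produced by
#'   \code{\link{calibrate}}.
#' @export
setClass("StandardScale",
         representation(sMin = "numeric", sM = "numeric", sMax = "numeric",
                        beta = "numeric", alpha = "numeric",
                        invScaleFactor = "numeric", modality = "character",
                        dx = "numeric", search = "list"))

setValidity("StandardScale", function(object) {
  o <- object
  if (!(o@sMin < o@sM && o@sM < o@sMax))
    return("standard-scale landmarks must satisfy sMin < sM < sMax")
  if (o@invScaleFactor <= 0) return("invScaleFactor must be positive")
  if (o@beta < 90 || o@beta > 100) return("beta must lie in [90, 100]")
  if (!(o@modality %in% .MODALITIES)) return("unknown modality")
  if (o@dx <= 0) return("dx must be positive")
  TRUE
})

#' Construct a StandardScale
#'
#' Usually produced by \code{\link{calibrate}}; the constructor is exposed
#' for programmatic scales.
#'
#' @param sMin,sM,sMax standard-scale landmarks.
#' @param beta upper percentile in [90, 100].
#' @param invScaleFactor positive inverse scale multiplier.
#' @param modality \code{"AC"} or \code{"SUV"}.
#' @param alpha lower percentile.
#' @param dx discriminability step.
#' @param search optional calibration trace.
#' @return a \linkS4class{StandardScale}.
#' @export
StandardScale <- function(sMin, sM, sMax, beta, invScaleFactor,
                          modality, alpha = 0, dx = 0.01, search = list()) {
  new("StandardScale", sMin = sMin, sM = sM, sMax = sMax, beta = beta,
      alpha = alpha, invScaleFactor = invScaleFactor, modality = modality,
      dx = dx, search = search)
}

#' BetaSearchResult: trace of the upper-percentile optimization
#'
#' @slot bGrid candidate percentiles.
#' @slot deltaValues reference-organ coefficient of variation per candidate.
#' @slot mValues,sigmaValues cohort mean and sample SD of the standardized
#'   organ means per candidate.
#' @slot betaOpt the selected percentile (grid argmin, ties broken toward
#'   the largest candidate).
#' @export
setClass("BetaSearchResult",
         representation(bGrid = "numeric", deltaValues = "numeric",
                        mValues = "numeric", sigmaValues = "numeric",
                        betaOpt = "numeric"))

setValidity("BetaSearchResult", function(object) {
  o <- object
  n <- length(o@bGrid)
  if (length(o@deltaValues) != n || length(o@mValues) != n ||
      length(o@sigmaValues) != n)
    return("grid and value vectors must have equal length")
  ok <- is.finite(o@deltaValues)
  if (!any(ok)) return("all candidates degenerate")
  if (abs(min(o@deltaValues[ok]) - o@deltaValues[o@bGrid == o@betaOpt]) > 1e-12)
    return("betaOpt must attain the minimum delta")
  TRUE
})

#' IntermediateImage: image on the intermediate standardized scale
#'
#' Result of the two-segment landmark mapping before multiplication by the
#' inverse scale factor.
#'
#' @slot voxels mapped 3D array.
#' @slot sMinReal,sMaxReal realized extremes after end-segment
#'   extrapolation; \code{sMaxReal} varies from image to image and is never
#'   clipped.
#' @export
setClass("IntermediateImage",
         representation(voxels = "array", sMinReal = "numeric",
                        sMaxReal = "numeric"))

#' StandardizedImage: a fully standardized PET volume
#'
#' A \linkS4class{PetImage} with the scale that produced it and the ordered
#' provenance of operations applied.
#'
#' @slot scaleUsed the \linkS4class{StandardScale} applied last.
#' @slot provenance list of per-step records (operation, upper percentile,
#'   landmarks, inverse scale factor, realized extremes).
#' @export
setClass("StandardizedImage", contains = "PetImage",
         representation(scaleUsed = "StandardScale", provenance = "list"))

#' NormalizedImage: output of a baseline normalization method
#'
#' Baseline methods (Gaussian, z-score, histogram-landmark) can produce
#' negative intensities, so their output is kept separate from
#' \linkS4class{PetImage}.
#'
#' @slot voxels numeric 3D array (may contain negatives).
#' @slot method which baseline produced it.
#' @export
setClass("NormalizedImage",
         representation(voxels = "array", method = "character"))

#' CohortMetrics: cross-subject consistency of organ uptake
#'
#' @slot organ organ name.
#' @slot n number of images.
#' @slot M mean of per-image organ means.
#' @slot S sample SD (n-1 denominator) of per-image organ means.
#' @slot CV coefficient of variation \code{S/M}.
#' @slot perImageMeans the per-image organ means.
#' @export
setClass("CohortMetrics",
         representation(organ = "character", n = "integer", M = "numeric",
                        S = "numeric", CV = "numeric",
                        perImageMeans = "numeric"))

setValidity("CohortMetrics", function(object) {
  if (object@n != length(object@perImageMeans))
    return("n must equal the number of per-image means")
  if (abs(object@CV - object@S / object@M) > 1e-12 * max(1, abs(object@CV)))
    return("CV must equal S/M")
  TRUE
})

#' RepeatMetrics: test-retest reproducibility of organ uptake
#'
#' @slot organ organ name.
#' @slot nPairs number of repeat-scan pairs.
#' @slot MD mean normalized absolute difference of organ means.
#' @slot perPairTerms the per-pair normalized differences, each in [0, 2].
#' @export
setClass("RepeatMetrics",
         representation(organ = "character", nPairs = "integer",
                        MD = "numeric", perPairTerms = "numeric"))

#' ScannerComparison: two-cohort comparison of organ means
#'
#' @slot groupMeans,groupSDs per-cohort mean and sample SD of organ means.
#' @slot pValue two-sided t-test probability.
#' @slot welch whether the unequal-variance (Welch) test was used.
#' @export
setClass("ScannerComparison",
         representation(groupMeans = "numeric", groupSDs = "numeric",
                        pValue = "numeric", welch = "logical"))

#' PhantomConfig: parameters of the synthetic PET phantom
#'
#' See \code{\link{phantomConfig}} for field meanings and defaults.
#'
#' @slot gridShape,backgroundFraction,bodyLevel,organSpecs,hotspotCountRange,hotspotMultRange,hotspotRadiusRange,gainRange,noiseCV,organHetRange,repeatDeltaCV,doseRange,weightRange,scannerId,seed see constructor.
#' @export
setClass("PhantomConfig",
         representation(gridShape = "integer", backgroundFraction = "numeric",
                        bodyLevel = "numeric", organSpecs = "list",
                        hotspotCountRange = "integer",
                        hotspotMultRange = "numeric",
                        hotspotRadiusRange = "numeric",
                        gainRange = "numeric", noiseCV = "numeric",
                        organHetRange = "numeric", repeatDeltaCV = "numeric",
                        doseRange = "numeric", weightRange = "numeric",
                        scannerId = "character", seed = "integer"))

.rangeOK <- function(r) length(r) == 2L && all(is.finite(r)) && r[1] <= r[2]

setValidity("PhantomConfig", function(object) {
  o <- object
  if (length(o@gridShape) != 3L || any(o@gridShape < 16L))
    return("gridShape must be three integers, each >= 16")
  if (o@backgroundFraction <= 0 || o@backgroundFraction >= 1)
    return("backgroundFraction must lie in (0, 1)")
  if (o@bodyLevel <= 0) return("bodyLevel must be positive")
  if (!.rangeOK(o@gainRange) || o@gainRange[1] <= 0)
    return("gainRange must be a positive low <= high pair")
  for (r in list(o@hotspotMultRange, o@hotspotRadiusRange, o@organHetRange,
                 o@doseRange, o@weightRange))
    if (!.rangeOK(r)) return("all ranges must satisfy low <= high")
  if (length(o@hotspotCountRange) != 2L ||
      o@hotspotCountRange[1] > o@hotspotCountRange[2] ||
      o@hotspotCountRange[1] < 0L)
    return("hotspotCountRange must be a non-negative low <= high pair")
  if (o@noiseCV < 0) return("noiseCV must be >= 0")
  if (o@repeatDeltaCV < 0) return("repeatDeltaCV must be >= 0")
  semi <- .bodySemiAxes(o@gridShape, o@backgroundFraction)
  ctr <- (o@gridShape + 1) / 2
  for (sp in o@organSpecs) {
    if (!all(c("name", "center", "radii", "meanRange") %in% names(sp)))
      return("each organ spec needs name, center, radii, meanRange")
    if (!.rangeOK(sp$meanRange) || sp$meanRange[1] <= 0)
      return("organ meanRange must be a positive low <= high pair")
    # conservative containment: organ bounding offsets inside body ellipsoid
    if (sum(((abs(sp$center - ctr) + sp$radii) / semi)^2) > 1)
      return(sprintf("organ '%s' does not fit inside the body region",
                     sp$name))
  }
  TRUE
})

#' PhantomSubject: one synthetic subject
#'
#' @slot image the generated \linkS4class{PetImage} (AC modality).
#' @slot masks named list of \linkS4class{OrganMask} objects, including
#'   \code{"body_truth"}.
#' @slot metadata subject metadata, including the planted ground-truth
#'   parameters under \code{$planted}.
#' @export
setClass("PhantomSubject",
         representation(image = "PetImage", masks = "list",
                        metadata = "list"))

setValidity("PhantomSubject", function(object) {
  dims <- dim(object@image@voxels)
  nms <- names(object@masks)
  if (!all(c("liver", "spleen", "body_truth") %in% nms))
    return("masks must include liver, spleen and body_truth")
  for (m in object@masks) {
    if (!is(m, "OrganMask")) return("masks must be OrganMask objects")
    if (!identical(dim(m@voxels), dims))
      return("masks must share the image grid")
  }
  body <- object@masks[["body_truth"]]@voxels
  acc <- array(FALSE, dims)
  for (nm in setdiff(nms, "body_truth")) {
    v <- object@masks[[nm]]@voxels
    if (any(v & !body)) return("organ masks must be subsets of body_truth")
    if (any(v & acc)) return("organ masks must be disjoint")
    acc <- acc | v
  }
  TRUE
})

## ---- accessors ----

#' @rdname voxels
#' @export
setMethod("voxels", "PetImage", function(x) x@voxels)

#' @rdname voxels
#' @export
setMethod("voxels", "OrganMask", function(x) x@voxels)

#' @rdname voxels
#' @export
setMethod("voxels", "BodyMask", function(x) x@voxels)

#' @rdname voxels
#' @export
setMethod("voxels", "IntermediateImage", function(x) x@voxels)

#' @rdname voxels
#' @export
setMethod("voxels", "NormalizedImage", function(x) x@voxels)

#' @rdname modality
#' @export
setMethod("modality", "PetImage", function(x) x@modality)

#' @rdname petMetadata
#' @export
setMethod("petMetadata", "PetImage", function(x) x@metadata)

#' @rdname petMetadata
#' @export
setMethod("petMetadata", "PhantomSubject", function(x) x@metadata)

#' @rdname organ
#' @export
setMethod("organ", "OrganMask", function(x) x@organ)

#' Landmark values as a named vector
#'
#' @param x a \linkS4class{LandmarkSet}.
#' @return named numeric vector \code{(min, pAlpha, pM, pBeta, max, alpha,
#'   beta)}.
#' @export
landmarkValues <- function(x) {
  stopifnot(is(x, "LandmarkSet"))
  c(min = x@minVal, pAlpha = x@pAlpha, pM = x@pM, pBeta = x@pBeta,
    max = x@maxVal, alpha = x@alpha, beta = x@beta)
}

#' Standard-scale landmarks
#'
#' @param x a \linkS4class{StandardScale}.
#' @return named numeric vector \code{(sMin, sM, sMax)}.
#' @export
scaleLandmarks <- function(x) {
  stopifnot(is(x, "StandardScale"))
  c(sMin = x@sMin, sM = x@sM, sMax = x@sMax)
}

#' Inverse scale factor of a calibrated scale
#'
#' @param x a \linkS4class{StandardScale}.
#' @return positive scalar.
#' @export
invScaleFactor <- function(x) {
  stopifnot(is(x, "StandardScale"))
  x@invScaleFactor
}

#' Optimized upper percentile of a search or scale
#'
#' @param x a \linkS4class{BetaSearchResult} or \linkS4class{StandardScale}.
#' @return the percentile.
#' @export
betaOpt <- function(x) {
  if (is(x, "BetaSearchResult")) return(x@betaOpt)
  if (is(x, "StandardScale")) return(x@beta)
  stop("no upper percentile stored in this object")
}

#' Provenance of a standardized image
#'
#' @param x a \linkS4class{StandardizedImage}.
#' @return list of per-step records.
#' @export
provenance <- function(x) {
  stopifnot(is(x, "StandardizedImage"))
  x@provenance
}

#' Image of a phantom subject
#'
#' @param x a \linkS4class{PhantomSubject}.
#' @return the subject's \linkS4class{PetImage}.
#' @export
subjectImage <- function(x) {
  stopifnot(is(x, "PhantomSubject"))
  x@image
}

#' Organ mask of a phantom subject
#'
#' @param x a \linkS4class{PhantomSubject}.
#' @param organ mask name (\code{"liver"}, \code{"spleen"},
#'   \code{"body_truth"}, ...).
#' @return an \linkS4class{OrganMask}.
#' @export
subjectMask <- function(x, organ) {
  stopifnot(is(x, "PhantomSubject"))
  m <- x@masks[[organ]]
  if (is.null(m)) stop("no mask named '", organ, "'")
  m
}

## ---- show methods ----

setMethod("show", "PetImage", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("%s image (%s): %d x %d x %d voxels, range [%.4g, %.4g]\n",
              class(object), object@modality, d[1], d[2], d[3],
              min(object@voxels), max(object@voxels)))
  sid <- object@metadata$subjectId
  if (!is.null(sid)) cat("  subject:", sid, "\n")
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf(paste0("LandmarkSet (alpha = %g, beta = %g):\n",
                     "  min %.4g | pAlpha %.4g | pM %.4g | pBeta %.4g | max %.4g\n"),
              object@alpha, object@beta, object@minVal, object@pAlpha,
              object@pM, object@pBeta, object@maxVal))
})

setMethod("show", "StandardScale", function(object) {
  cat(sprintf(paste0("StandardScale (%s): sMin = %.4g, sM = %.4g, ",
                     "sMax = %.4g\n  beta = %.1f, invScaleFactor = %.4g, ",
                     "dx = %g\n"),
              object@modality, object@sMin, object@sM, object@sMax,
              object@beta, object@invScaleFactor, object@dx))
})

setMethod("show", "BetaSearchResult", function(object) {
  cat(sprintf("BetaSearchResult: %d candidates in [%g, %g], betaOpt = %g\n",
              length(object@bGrid), min(object@bGrid), max(object@bGrid),
              object@betaOpt))
})

setMethod("show", "CohortMetrics", function(object) {
  cat(sprintf("CohortMetrics [%s, n = %d]: M = %.4g, S = %.4g, CV = %.2f%%\n",
              object@organ, object@n, object@M, object@S, 100 * object@CV))
})

setMethod("show", "RepeatMetrics", function(object) {
  cat(sprintf("RepeatMetrics [%s, %d pairs]: MD = %.2f%%\n",
              object@organ, object@nPairs, 100 * object@MD))
})

setMethod("show", "ScannerComparison", function(object) {
  cat(sprintf(paste0("ScannerComparison (%s t-test): means %.4g vs %.4g, ",
                     "p = %.4g\n"),
              if (object@welch) "Welch" else "pooled",
              object@groupMeans[1], object@groupMeans[2], object@pValue))
})

setMethod("show", "PhantomSubject", function(object) {
  cat(sprintf("PhantomSubject %s (scanner %s): ",
              object@metadata$subjectId, object@metadata$scannerId))
  show(object@image)
})
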