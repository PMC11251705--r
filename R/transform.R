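#' @include calibration.R
NULL

#' Map raw intensities through the two-segment landmark mapping
#'
#' The first segment sends \code{[pAlpha, pM]} linearly onto
#' \code{[sMin, sM]} and is extended over \code{[min, pAlpha)}; the
#' second sends \code{[pM, pBeta]} onto \code{[sM, sMax]} and is extended
#' over \code{(pBeta, max]}. The map is continuous at \code{pM}, strictly
#' increasing, and exact at all three landmarks. Intensities above
#' \code{pBeta} are retained (extrapolated), never clipped.
#'
#' @param x numeric vector or array of intensities.
#' @param landmarks the image's \linkS4class{LandmarkSet}.
#' @param scale a \linkS4class{StandardScale} (only its \code{sMin},
#'   \code{sM}, \code{sMax} are used; multiply by
#'   \code{\link{invScaleFactor}} for the full composed mapping).
#' @return mapped values, same shape as \code{x}.
#' @export
mapIntensities <- function(x, landmarks, scale) {
  stopifnot(is(landmarks, "LandmarkSet"), is(scale, "StandardScale"))
  if (!(landmarks@pAlpha < landmarks@pM && landmarks@pM < landmarks@pBeta))
    stop("degenerate landmarks: need pAlpha < pM < pBeta")
  out <- .pwlMap(x, landmarks@pAlpha, landmarks@pM, landmarks@pBeta,
                 scale@sMin, scale@sM, scale@sMax)
  if (is.array(x)) out <- array(out, dim(x))
  out
}

#' Map an image onto the intermediate standardized scale
#'
#' @param image a \linkS4class{PetImage}.
#' @param landmarks its \linkS4class{LandmarkSet}.
#' @param scale a \linkS4class{StandardScale}.
#' @return an \linkS4class{IntermediateImage}; its realized extremes
#'   record where the whole-volume minimum and maximum landed.
#' @export
mapToStandardScale <- function(image, landmarks, scale) {
  stopifnot(is(image, "PetImage"))
  v <- mapIntensities(image@voxels, landmarks, scale)
  new("IntermediateImage", voxels = v,
      sMinReal = .pwlMap(landmarks@minVal, landmarks@pAlpha, landmarks@pM,
                         landmarks@pBeta, scale@sMin, scale@sM, scale@sMax),
      sMaxReal = .pwlMap(landmarks@maxVal, landmarks@pAlpha, landmarks@pM,
                         landmarks@pBeta, scale@sMin, scale@sM, scale@sMax))
}

#' @rdname standardize
#' @export
setMethod("standardize", "PetImage", function(x, scale, ...) {
  stopifnot(is(scale, "StandardScale"))
  if (modality(x) != scale@modality)
    stop(sprintf("modality mismatch: image is %s but scale was calibrated on %s",
                 modality(x), scale@modality))
  lm <- extractLandmarks(x, beta = scale@beta, alpha = scale@alpha)
  inter <- mapToStandardScale(x, lm, scale)
  out <- scale@invScaleFactor * inter@voxels
  step <- list(op = paste0("s-", modality(x)), beta = scale@beta,
               landmarks = landmarkValues(lm),
               invScaleFactor = scale@invScaleFactor,
               sMinReal = inter@sMinReal, sMaxReal = inter@sMaxReal)
  prov <- if (is(x, "StandardizedImage")) x@provenance else list()
  new("StandardizedImage", voxels = out, modality = modality(x),
      metadata = petMetadata(x), scaleUsed = scale,
      provenance = c(prov, list(step)))
})

#' @rdname toSUV
#' @param doseMBq injected radiotracer dose in MBq.
#' @param weightKg body weight in kg.
#' @export
setMethod("toSUV", "PetImage", function(x, doseMBq = NULL, weightKg = NULL,
                                        ...) {
  if (modality(x) != "AC")
    stop("SUV conversion requires an AC-modality image")
  md <- petMetadata(x)
  if (is.null(doseMBq)) doseMBq <- md$doseMBq
  if (is.null(weightKg)) weightKg <- md$weightKg
  if (is.null(doseMBq) || is.null(weightKg))
    stop("doseMBq and weightKg are required (argument or image metadata)")
  if (doseMBq <= 0 || weightKg <= 0)
    stop("dose and weight must be positive")
  ## AC is in Bq/ml; SUV = (AC / 1e6 MBq/ml) / (dose_MBq / weight_g),
  ## assuming average body density 1 g/ml.
  suv <- x@voxels * weightKg / (doseMBq * 1000)
  md$modality <- "SUV"
  PetImage(suv, "SUV", metadata = md)
})

#' Run a chain of standardization / SUV-conversion steps
#'
#' Executes an ordered sequence of operations from
#' \{\code{"s-AC"}, \code{"s-SUV"}, \code{"SUV"}\} on a set of test
#' images. Each standardization step calibrates a fresh scale on the
#' current state of the calibration set (which is carried through the
#' chain alongside the test set, so re-standardization re-estimates the
#' calibration parameters on already-standardized images). The SUV step
#' converts every image using its own metadata.
#'
#' @param images list of test \linkS4class{PetImage} objects.
#' @param chain character vector of steps, e.g.
#'   \code{c("s-AC", "SUV", "s-SUV")}.
#' @param calibImages list of calibration images (same starting modality
#'   as \code{images}).
#' @param calibMasks reference-organ masks for the calibration images.
#' @param ... passed to \code{\link{calibrate}} (e.g. \code{step},
#'   \code{sMax}).
#' @return list with the transformed \code{images}, the transformed
#'   \code{calibImages}, and \code{scales}, one per standardization step.
#' @export
applySequence <- function(images, chain, calibImages, calibMasks, ...) {
  stopifnot(length(chain) >= 1L,
            all(chain %in% c("s-AC", "s-SUV", "SUV")))
  curMod <- unique(c(vapply(images, modality, character(1)),
                     vapply(calibImages, modality, character(1))))
  if (length(curMod) != 1L)
    stop("test and calibration images must share one modality")
  scales <- list()
  for (st in chain) {
    if (st == "SUV") {
      if (curMod != "AC")
        stop("inconsistent chain: SUV conversion requires AC-modality state")
      images <- lapply(images, toSUV)
      calibImages <- lapply(calibImages, toSUV)
      curMod <- "SUV"
    } else {
      need <- if (st == "s-AC") "AC" else "SUV"
      if (curMod != need)
        stop(sprintf("inconsistent chain: step %s on %s-modality state",
                     st, curMod))
      scale <- calibrate(calibImages, calibMasks, ...)
      images <- lapply(images, standardize, scale = scale)
      calibImages <- lapply(calibImages, standardize, scale = scale)
      scales[[length(scales) + 1L]] <- scale
    }
  }
  list(images = images, calibImages = calibImages, scales = scales)
}
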