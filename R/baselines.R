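#' @include transform.R
NULL

.organSD <- function(image, organMask) {
  mv <- voxels(organMask)
  if (!identical(dim(mv), dim(image@voxels)))
    stop("organ mask grid does not match the image grid")
  vals <- image@voxels[mv]
  s <- stats::sd(vals)
  if (is.na(s) || s == 0)
    stop("degenerate organ: zero intensity variance within the mask")
  s
}

#' Gaussian reference-organ normalization
#'
#' Divides every voxel by the per-image standard deviation of intensities
#' within the reference organ. The formula is applied to the whole
#' volume; evaluation metrics are computed within the organ, matching how
#' such methods are assessed.
#'
#' @param image a \linkS4class{PetImage}.
#' @param organMask the reference-organ \linkS4class{OrganMask}.
#' @return a \linkS4class{NormalizedImage}.
#' @export
gaussianNormalize <- function(image, organMask) {
  stopifnot(is(image, "PetImage"))
  s <- .organSD(image, organMask)
  new("NormalizedImage", voxels = image@voxels / s, method = "gaussian")
}

#' Z-score reference-organ normalization
#'
#' Shifts by the calibration-set organ mean, then divides by the
#' per-image organ standard deviation.
#'
#' @param image a \linkS4class{PetImage}.
#' @param organMask the reference-organ mask.
#' @param calibMean mean organ intensity over the calibration set, e.g.
#'   from \code{\link{organCalibMean}}.
#' @return a \linkS4class{NormalizedImage} (may contain negatives).
#' @export
zscoreNormalize <- function(image, organMask, calibMean) {
  stopifnot(is(image, "PetImage"), is.numeric(calibMean))
  s <- .organSD(image, organMask)
  new("NormalizedImage", voxels = (image@voxels - calibMean) / s,
      method = "zscore")
}

#' Calibration-set organ mean for z-score normalization
#'
#' @param images calibration images.
#' @param organMasks matching organ masks.
#' @return mean over images of the per-image organ mean.
#' @export
organCalibMean <- function(images, organMasks) {
  mean(mapply(organMean, images, organMasks))
}

.nyulLandmarks <- function(image, percentiles) {
  body <- computeBodyMask(image)
  vals <- sort(image@voxels[body@voxels])
  L <- vapply(percentiles, function(q) .quantileSorted(vals, q), numeric(1))
  if (any(diff(L) <= 0))
    stop("non-monotone histogram landmarks; image histogram too coarse ",
         "for the landmark method")
  L
}

#' Calibrate the classic histogram-landmark model
#'
#' The two-step landmark standardization of the MRI literature, adapted
#' verbatim to PET: foreground is the mean-thresholded body region;
#' landmarks are the 0th percentile, the deciles 10..90, and the 99.8th
#' percentile of the foreground. Training maps each image's landmark span
#' linearly onto a fixed scale and averages the mapped landmark
#' positions.
#'
#' @param images list of training \linkS4class{PetImage} objects
#'   (at least 2).
#' @param pc1,pc2 outer percentiles (defaults 0 and 99.8).
#' @param deciles interior percentiles (defaults 10..90 by 10).
#' @param sLow,sHigh fixed standard scale (defaults 0 and 100).
#' @return a model list with the averaged standard landmark positions,
#'   consumed by \code{\link{nyulTransform}}.
#' @export
nyulCalibrate <- function(images, pc1 = 0, pc2 = 99.8,
                          deciles = seq(10, 90, by = 10),
                          sLow = 0, sHigh = 100) {
  if (length(images) < 2L)
    stop("landmark-model training needs at least 2 images")
  percs <- c(pc1, deciles, pc2)
  mapped <- vapply(images, function(img) {
    L <- .nyulLandmarks(img, percs)
    sLow + (L - L[1]) * (sHigh - sLow) / (L[length(L)] - L[1])
  }, numeric(length(percs)))
  standard <- rowMeans(mapped)
  if (any(diff(standard) <= 0))
    stop("averaged standard landmarks are not strictly increasing")
  list(percentiles = percs, standard = standard, sLow = sLow, sHigh = sHigh)
}

#' Apply the histogram-landmark standardization
#'
#' Piecewise-linear mapping of the image's own landmarks onto the model's
#' averaged standard landmarks, continuous and non-decreasing, with
#' end-segment extrapolation below the first and above the last landmark.
#'
#' @param image a \linkS4class{PetImage}.
#' @param model output of \code{\link{nyulCalibrate}}.
#' @return a \linkS4class{NormalizedImage}.
#' @export
nyulTransform <- function(image, model) {
  stopifnot(is(image, "PetImage"),
            all(c("percentiles", "standard") %in% names(model)))
  L <- .nyulLandmarks(image, model$percentiles)
  mu <- model$standard
  x <- as.numeric(image@voxels)
  k <- findInterval(x, L)
  k <- pmin(pmax(k, 1L), length(L) - 1L)
  y <- mu[k] + (x - L[k]) * (mu[k + 1L] - mu[k]) / (L[k + 1L] - L[k])
  new("NormalizedImage", voxels = array(y, dim(image@voxels)),
      method = "nyul")
}
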