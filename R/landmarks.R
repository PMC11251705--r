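#' @include AllClasses.R
NULL

## Percentile with the rank = 1 + (n-1) q / 100 linear-interpolation
## convention, on an already-sorted vector. Used by the hot paths so the
## sort is paid once per image.
.quantileSorted <- function(sorted, q) {
  n <- length(sorted)
  if (n == 1L) return(sorted)
  h <- 1 + (n - 1) * q / 100
  lo <- floor(h)
  hi <- ceiling(h)
  sorted[lo] + (h - lo) * (sorted[hi] - sorted[lo])
}

#' @rdname percentileOf
#' @export
setMethod("percentileOf", "numeric", function(x, q, ...) {
  if (length(x) == 0L) stop("cannot take a percentile of an empty set")
  if (anyNA(q) || any(q < 0) || any(q > 100))
    stop("'q' must lie in [0, 100]")
  stats::quantile(x, probs = q / 100, type = 7, names = FALSE)
})

#' @rdname percentileOf
#' @param mask an \linkS4class{OrganMask} or \linkS4class{BodyMask}
#'   restricting the voxels used.
#' @export
setMethod("percentileOf", "PetImage", function(x, q, mask = NULL, ...) {
  v <- x@voxels
  if (!is.null(mask)) {
    mv <- voxels(mask)
    if (!identical(dim(mv), dim(v)))
      stop("mask grid does not match the image grid")
    v <- v[mv]
    if (length(v) == 0L) stop("mask selects no voxels")
  }
  percentileOf(as.numeric(v), q)
})

#' Segment the body region by mean thresholding
#'
#' The whole-volume histogram of a PET image is typically bimodal: a
#' near-zero background mode and a body mode. Thresholding at the
#' whole-volume mean separates the two; voxels equal to the mean are
#' included, which keeps constant images non-degenerate at this stage.
#'
#' @param image a \linkS4class{PetImage}.
#' @return a \linkS4class{BodyMask} with the threshold used.
#' @examples
#' v <- array(0, c(16, 16, 16)); v[5:12, 5:12, 5:12] <- 1000
#' mask <- computeBodyMask(PetImage(v, "AC"))
#' mask@threshold
#' @export
computeBodyMask <- function(image) {
  stopifnot(is(image, "PetImage"))
  m <- mean(image@voxels)
  if (m <= 0)
    stop("degenerate image: whole-volume mean is zero")
  new("BodyMask", voxels = image@voxels >= m, threshold = m)
}

#' Extract the intensity landmarks of a PET image
#'
#' Computes the five landmarks used by the standardization mapping:
#' whole-volume minimum and maximum, the lower-percentile value
#' \code{pAlpha} (the minimum when \code{alpha = 0}, the standard choice),
#' the median of the body region, and the upper \code{beta}-percentile of
#' the body region. The body region is found with
#' \code{\link{computeBodyMask}}.
#'
#' @param image a \linkS4class{PetImage}.
#' @param beta upper percentile in \eqn{[90, 100]}.
#' @param alpha lower percentile; the default 0 makes \code{pAlpha} the
#'   whole-volume minimum.
#' @return a \linkS4class{LandmarkSet}.
#' @examples
#' v <- array(0, c(16, 16, 16)); v[5:12, 5:12, 5:12] <- 1000
#' v[6:7, 6:7, 6:7] <- 5000
#' extractLandmarks(PetImage(v, "AC"), beta = 96)
#' @export
extractLandmarks <- function(image, beta, alpha = 0) {
  stopifnot(is(image, "PetImage"))
  if (beta < 90 || beta > 100)
    stop("'beta' must lie in [90, 100]")
  if (alpha < 0 || alpha >= beta)
    stop("'alpha' must satisfy 0 <= alpha < beta")
  v <- as.numeric(image@voxels)
  body <- computeBodyMask(image)
  sortedBody <- sort(v[body@voxels])
  .landmarksFromSorted(v, sortedBody, beta, alpha)
}

## core landmark computation from precomputed pieces; shared with the
## calibration fast path
.landmarksFromSorted <- function(allVals, sortedBody, beta, alpha,
                                 minVal = min(allVals),
                                 maxVal = max(allVals)) {
  pA <- if (alpha <= 0) minVal else percentileOf(allVals, alpha)
  pM <- .quantileSorted(sortedBody, 50)
  pB <- .quantileSorted(sortedBody, beta)
  if (pM >= pB)
    stop("landmark degeneracy: body median is not below the upper ",
         "percentile value (pM >= pBeta)")
  LandmarkSet(minVal = minVal, pAlpha = pA, pM = pM, pBeta = pB,
              maxVal = maxVal, alpha = alpha, beta = beta)
}

#' Serialize a landmark set to JSON
#'
#' @param x a \linkS4class{LandmarkSet}.
#' @param path optional file; when omitted the JSON string is returned.
#' @return the JSON string, invisibly when written to file.
#' @export
landmarksToJson <- function(x, path = NULL) {
  stopifnot(is(x, "LandmarkSet"))
  obj <- list(min = x@minVal, p_alpha = x@pAlpha, p_m = x@pM,
              p_beta = x@pBeta, max = x@maxVal, alpha = x@alpha,
              beta = x@beta)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
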