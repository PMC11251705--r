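#' @include landmarks.R
NULL

## Two-segment piecewise-linear landmark map: [pAlpha, pM] -> [sMin, sM],
## [pM, pBeta] -> [sM, sMax], each segment extended beyond its interval.
## Vectorized over x; shared by the transform module and the calibration
## fast path.
.pwlMap <- function(x, pA, pM, pB, sMin, sM, sMax) {
  slope1 <- (sM - sMin) / (pM - pA)
  slope2 <- (sMax - sM) / (pB - pM)
  ifelse(x <= pM, sMin + slope1 * (x - pA), sM + slope2 * (x - pM))
}

#' Linear scale factor of an image onto the standard scale
#'
#' The slope of the linear map sending \code{[pAlpha, pBeta]} onto
#' \code{[sMin, sMax]}. In the standard setting \code{pAlpha = 0 = sMin},
#' so this is the pure multiplier \code{sMax / pBeta}.
#'
#' @param landmarks a \linkS4class{LandmarkSet}.
#' @param sMin,sMax standard-scale endpoints.
#' @return positive scalar.
#' @export
linearScaleFactor <- function(landmarks, sMin, sMax) {
  stopifnot(is(landmarks, "LandmarkSet"))
  span <- landmarks@pBeta - landmarks@pAlpha
  if (span <= 0)
    stop("degenerate landmarks: pBeta equals pAlpha")
  (sMax - sMin) / span
}

## value of the linear map at x (lambda(x) in the field's notation)
.scaleMapValue <- function(x, landmarks, sMin, sMax) {
  sMin + linearScaleFactor(landmarks, sMin, sMax) * (x - landmarks@pAlpha)
}

#' Estimate the standard-scale median landmark
#'
#' Each calibration image's body median is sent through that image's
#' linear map onto \code{[sMin, sMax]}; the standard median \code{sM} is
#' the mean of the mapped values over the calibration set.
#'
#' @param landmarkList list of \linkS4class{LandmarkSet} objects, one per
#'   calibration image.
#' @param sMin,sMax standard-scale endpoints.
#' @return the estimated \code{sM}, strictly between \code{sMin} and
#'   \code{sMax}.
#' @export
estimateStandardMedian <- function(landmarkList, sMin, sMax) {
  if (length(landmarkList) < 1L)
    stop("empty calibration set")
  mapped <- vapply(landmarkList, function(lm)
    .scaleMapValue(lm@pM, lm, sMin, sMax), numeric(1))
  sM <- mean(mapped)
  if (sM <= sMin || sM >= sMax)
    stop("degenerate calibration: standard median fell outside (sMin, sMax)")
  sM
}

## Precompute the per-image quantities the upper-percentile search reuses:
## sorted body-region intensities, whole-volume extrema, organ voxel values.
.prepCalibration <- function(images, organMasks) {
  stopifnot(length(images) == length(organMasks), length(images) >= 1L)
  mapply(function(img, msk) {
    stopifnot(is(img, "PetImage"), is(msk, "OrganMask"))
    v <- as.numeric(img@voxels)
    body <- computeBodyMask(img)
    mv <- voxels(msk)
    if (!identical(dim(mv), dim(img@voxels)))
      stop("organ mask grid does not match its image")
    list(sortedBody = sort(v[body@voxels]),
         minVal = min(v), maxVal = max(v),
         organVals = v[mv])
  }, images, organMasks, SIMPLIFY = FALSE)
}

## One evaluation of the reference-organ coefficient of variation for a
## candidate upper percentile, on precomputed per-image data.
.deltaAt <- function(b, prep, sMin, sMax, alpha = 0) {
  lms <- lapply(prep, function(p)
    .landmarksFromSorted(NULL, p$sortedBody, b, alpha,
                         minVal = p$minVal, maxVal = p$maxVal))
  sM <- estimateStandardMedian(lms, sMin, sMax)
  mus <- mapply(function(p, lm)
    mean(.pwlMap(p$organVals, lm@pAlpha, lm@pM, lm@pBeta, sMin, sM, sMax)),
    prep, lms)
  m <- mean(mus)
  if (m == 0)
    stop("degenerate cohort: mean standardized organ uptake is zero")
  sigma <- stats::sd(mus)
  list(delta = sigma / m, m = m, sigma = sigma)
}

#' Reference-organ coefficient of variation for one upper percentile
#'
#' For a candidate upper percentile \code{b}, every calibration image is
#' standardized onto the intermediate scale using its landmarks at
#' \code{b} (the standard median being re-estimated for that \code{b});
#' the value returned is the cross-subject coefficient of variation
#' (sample SD over mean) of the mean standardized intensity within the
#' reference organ.
#'
#' @param b candidate upper percentile in \eqn{[90, 100]}.
#' @param images list of calibration \linkS4class{PetImage} objects.
#' @param organMasks list of matching reference-organ
#'   \linkS4class{OrganMask} objects.
#' @param sMin,sMax standard-scale endpoints.
#' @param alpha lower percentile (default 0).
#' @return list with \code{delta} (the CV), \code{m} (cohort mean) and
#'   \code{sigma} (cohort sample SD).
#' @export
deltaForPercentile <- function(b, images, organMasks, sMin, sMax,
                               alpha = 0) {
  prep <- .prepCalibration(images, organMasks)
  .deltaAt(b, prep, sMin, sMax, alpha)
}

#' Optimize the upper percentile against a reference organ
#'
#' Grid search for the upper percentile minimizing the reference-organ
#' coefficient of variation across the calibration set. Ties are broken
#' toward the largest candidate, i.e. the largest percentile whose CV is
#' the smallest. Candidates where the landmark extraction degenerates are
#' skipped.
#'
#' @param images list of calibration \linkS4class{PetImage} objects
#'   (at least 3).
#' @param organMasks matching reference-organ masks.
#' @param bLow,bHigh,step search grid (defaults 90 to 100 by 0.1).
#' @param sMin,sMax standard-scale endpoints.
#' @param alpha lower percentile (default 0).
#' @return a \linkS4class{BetaSearchResult}.
#' @export
optimizeBeta <- function(images, organMasks, sMin, sMax,
                         bLow = 90, bHigh = 100, step = 0.1, alpha = 0) {
  if (length(images) < 3L)
    stop("upper-percentile optimization needs at least 3 calibration images")
  if (bHigh > 100 || bLow < 90 || bLow > bHigh)
    stop("search interval must lie inside [90, 100]")
  grid <- seq(bLow, bHigh, by = step)
  prep <- .prepCalibration(images, organMasks)
  delta <- m <- sigma <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    res <- tryCatch(.deltaAt(grid[i], prep, sMin, sMax, alpha),
                    error = function(e) NULL)
    if (!is.null(res)) {
      delta[i] <- res$delta; m[i] <- res$m; sigma[i] <- res$sigma
    }
  }
  if (all(is.na(delta)))
    stop("calibration failure: all upper-percentile candidates degenerate")
  best <- min(delta, na.rm = TRUE)
  betaOpt <- max(grid[!is.na(delta) & delta == best])
  new("BetaSearchResult", bGrid = grid, deltaValues = delta,
      mValues = m, sigmaValues = sigma, betaOpt = betaOpt)
}

#' Estimate the inverse scale factor
#'
#' Scale factors more than one sample SD away from their mean are
#' removed; the inverse scale factor is the reciprocal of the mean of the
#' remaining factors. If the exclusion empties the set (or a single
#' factor is supplied), all factors are retained.
#'
#' @param scaleFactors positive per-image linear scale factors.
#' @return positive scalar, the reciprocal of the trimmed mean.
#' @examples
#' estimateInvScaleFactor(c(5, 6, 7, 100))  # outlier 100 removed -> 1/6
#' @export
estimateInvScaleFactor <- function(scaleFactors) {
  if (length(scaleFactors) < 1L) stop("no scale factors supplied")
  if (any(scaleFactors <= 0)) stop("scale factors must be positive")
  m <- mean(scaleFactors)
  s <- stats::sd(scaleFactors)
  keep <- if (is.na(s)) rep(TRUE, length(scaleFactors))
          else abs(scaleFactors - m) <= s
  if (!any(keep)) keep <- rep(TRUE, length(scaleFactors))
  1 / mean(scaleFactors[keep])
}

#' Choose the standard-scale maximum for a target discriminability
#'
#' Any two input intensities \code{dx} apart should remain at least
#' \code{dx} apart after standardization, which holds exactly when both
#' linear-segment slopes of the composed mapping are at least 1 for every
#' calibration image. The smallest candidate satisfying this for the
#' whole calibration set is returned. The inverse scale factor entering
#' the composition is supplied as a fixed multiplier (default 1, i.e. the
#' criterion is applied on the intermediate standardized scale).
#'
#' @param images calibration images.
#' @param beta upper percentile at which landmarks are taken.
#' @param candidates increasing grid of candidate \code{sMax} values.
#' @param dx discriminability step (recorded; the slope criterion itself
#'   does not depend on it).
#' @param lambdaInv fixed inverse-scale multiplier entering the composed
#'   mapping.
#' @param sMin standard-scale minimum (default 0).
#' @param alpha lower percentile (default 0).
#' @return the chosen \code{sMax}.
#' @export
chooseSMax <- function(images, beta, candidates, dx = 0.01,
                       lambdaInv = 1, sMin = 0, alpha = 0) {
  if (dx <= 0) stop("'dx' must be positive")
  if (length(candidates) < 1L) stop("empty candidate grid")
  candidates <- sort(candidates)
  lms <- lapply(images, extractLandmarks, beta = beta, alpha = alpha)
  bestSlope <- -Inf
  for (cand in candidates) {
    sM <- estimateStandardMedian(lms, sMin, cand)
    slopes <- vapply(lms, function(lm) {
      s1 <- (sM - sMin) / (lm@pM - lm@pAlpha)
      s2 <- (cand - sM) / (lm@pBeta - lm@pM)
      min(s1, s2) * lambdaInv
    }, numeric(1))
    worst <- min(slopes)
    bestSlope <- max(bestSlope, worst)
    if (worst >= 1 - 1e-12) return(cand)
  }
  stop(sprintf(paste0("no candidate sMax guarantees unit slope; maximum ",
                      "achievable minimum slope was %.4g"), bestSlope))
}

#' Calibrate the standard scale on a set of normal images
#'
#' The one-time calibration: optimizes the upper percentile against the
#' reference organ, extracts landmarks at the optimum, computes per-image
#' linear scale factors, estimates the standard median landmark and the
#' inverse scale factor, and assembles the reusable
#' \linkS4class{StandardScale}.
#'
#' @param images list of calibration \linkS4class{PetImage} objects of a
#'   common modality (normal subjects).
#' @param organMasks matching reference-organ masks (calibration only;
#'   transformation of new images needs no masks).
#' @param sMax standard-scale maximum; defaults to 50000 for AC (Bq/ml)
#'   and 5 for SUV.
#' @param sMin standard-scale minimum (default 0).
#' @param bLow,bHigh,step upper-percentile search grid.
#' @param dx discriminability step recorded in the scale.
#' @param alpha lower percentile (default 0).
#' @return a \linkS4class{StandardScale}; the search trace is kept in its
#'   \code{search} slot.
#' @export
calibrate <- function(images, organMasks, sMax = NULL, sMin = 0,
                      bLow = 90, bHigh = 100, step = 0.1, dx = 0.01,
                      alpha = 0) {
  mods <- unique(vapply(images, modality, character(1)))
  if (length(mods) != 1L)
    stop("all calibration images must share one modality")
  if (is.null(sMax)) sMax <- if (mods == "AC") 50000 else 5
  search <- optimizeBeta(images, organMasks, sMin = sMin, sMax = sMax,
                         bLow = bLow, bHigh = bHigh, step = step,
                         alpha = alpha)
  beta <- search@betaOpt
  lms <- lapply(images, extractLandmarks, beta = beta, alpha = alpha)
  factors <- vapply(lms, linearScaleFactor, numeric(1),
                    sMin = sMin, sMax = sMax)
  sM <- estimateStandardMedian(lms, sMin, sMax)
  StandardScale(sMin = sMin, sM = sM, sMax = sMax, beta = beta,
                invScaleFactor = estimateInvScaleFactor(factors),
                modality = mods, alpha = alpha, dx = dx,
                search = list(bGrid = search@bGrid,
                              deltaValues = search@deltaValues,
                              scaleFactors = factors,
                              nCalibration = length(images)))
}
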