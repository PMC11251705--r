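#' @include baselines.R
NULL

## voxel array of anything image-like
.vox <- function(x) {
  if (is.array(x)) return(x)
  voxels(x)
}

#' Mean intensity within an organ mask
#'
#' @param image a \linkS4class{PetImage}, \linkS4class{NormalizedImage},
#'   or bare 3D array.
#' @param mask an \linkS4class{OrganMask}.
#' @return scalar mean.
#' @export
organMean <- function(image, mask) {
  v <- .vox(image)
  mv <- voxels(mask)
  if (!identical(dim(mv), dim(v)))
    stop("organ mask grid does not match the image grid")
  mean(v[mv])
}

#' Cross-subject coefficient of variation of organ uptake
#'
#' Per-image organ means are summarized by their cohort mean \code{M},
#' sample SD \code{S} (n-1 denominator) and coefficient of variation
#' \code{CV = S/M}.
#'
#' @param images list of images (any mix of \linkS4class{PetImage},
#'   \linkS4class{StandardizedImage}, \linkS4class{NormalizedImage}).
#' @param masks list of matching \linkS4class{OrganMask} objects.
#' @return a \linkS4class{CohortMetrics}.
#' @export
cvMetric <- function(images, masks) {
  stopifnot(length(images) >= 2L, length(images) == length(masks))
  mus <- mapply(organMean, images, masks)
  M <- mean(mus)
  if (M == 0)
    stop("degenerate cohort: mean organ uptake is zero, CV undefined")
  S <- stats::sd(mus)
  new("CohortMetrics", organ = organ(masks[[1]]),
      n = length(images), M = M, S = S, CV = S / M,
      perImageMeans = as.numeric(mus))
}

#' Test-retest mean normalized absolute difference of organ uptake
#'
#' For each repeat pair, the absolute difference of organ means is
#' normalized by the pair average; the metric is the mean of these terms.
#'
#' @param pairs list of two-element lists of images (scan 1, scan 2).
#' @param masks list of two-element lists of matching organ masks.
#' @return a \linkS4class{RepeatMetrics}.
#' @export
mdMetric <- function(pairs, masks) {
  stopifnot(length(pairs) >= 1L, length(pairs) == length(masks))
  terms <- vapply(seq_along(pairs), function(i) {
    mu1 <- organMean(pairs[[i]][[1]], masks[[i]][[1]])
    mu2 <- organMean(pairs[[i]][[2]], masks[[i]][[2]])
    if (mu1 + mu2 == 0)
      stop("degenerate pair: organ means sum to zero")
    abs(mu1 - mu2) / ((mu1 + mu2) / 2)
  }, numeric(1))
  new("RepeatMetrics", organ = organ(masks[[1]][[1]]),
      nPairs = length(pairs), MD = mean(terms), perPairTerms = terms)
}

#' Compare organ uptake between two scanner cohorts
#'
#' Two-sided two-sample t-test on per-image organ means, Welch
#' (unequal-variance) by default. If both cohorts have zero variance the
#' p-value is 1 when the means agree and 0 otherwise.
#'
#' @param imagesA,imagesB the two cohorts.
#' @param masksA,masksB matching organ masks.
#' @param varEqual use the pooled-variance test instead of Welch.
#' @return a \linkS4class{ScannerComparison}.
#' @export
interscannerCompare <- function(imagesA, imagesB, masksA, masksB,
                                varEqual = FALSE) {
  stopifnot(length(imagesA) >= 2L, length(imagesB) >= 2L)
  muA <- mapply(organMean, imagesA, masksA)
  muB <- mapply(organMean, imagesB, masksB)
  sdA <- stats::sd(muA); sdB <- stats::sd(muB)
  if (sdA == 0 && sdB == 0) {
    p <- if (isTRUE(all.equal(mean(muA), mean(muB)))) 1 else 0
  } else {
    p <- stats::t.test(muA, muB, var.equal = varEqual)$p.value
  }
  new("ScannerComparison", groupMeans = c(mean(muA), mean(muB)),
      groupSDs = c(sdA, sdB), pValue = p, welch = !varEqual)
}
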