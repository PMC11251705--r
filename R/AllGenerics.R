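#' @import methods
NULL

#' Extract the voxel array of an image-like object
#'
#' @param x a \linkS4class{PetImage}, mask, or related object.
#' @return For images, a numeric 3D array; for masks, a logical 3D array.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Modality of a PET image
#'
#' @param x a \linkS4class{PetImage}.
#' @return \code{"AC"} (activity concentration, Bq/ml) or \code{"SUV"}.
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' Acquisition metadata of a PET image
#'
#' @param x a \linkS4class{PetImage} or \linkS4class{PhantomSubject}.
#' @return a named list (typically \code{doseMBq}, \code{weightKg},
#'   \code{scannerId}, \code{subjectId}).
#' @export
setGeneric("petMetadata", function(x) standardGeneric("petMetadata"))

#' Organ name attached to a mask
#'
#' @param x an \linkS4class{OrganMask}.
#' @return character scalar.
#' @export
setGeneric("organ", function(x) standardGeneric("organ"))

#' Percentile of intensities with the linear-interpolation convention
#'
#' For \eqn{n} sorted values, percentile \eqn{q} corresponds to rank
#' \eqn{1 + (n-1)q/100}, interpolating linearly between the two neighbouring
#' order statistics; \eqn{q = 0} gives the minimum and \eqn{q = 100} the
#' maximum.
#'
#' @param x a numeric vector, or a \linkS4class{PetImage} (then \code{mask}
#'   selects the voxels).
#' @param q percentile in \eqn{[0, 100]}.
#' @param ... further arguments (\code{mask} for the image method).
#' @return the interpolated intensity value.
#' @export
setGeneric("percentileOf", function(x, q, ...) standardGeneric("percentileOf"))

#' Apply the full standardization mapping to an image
#'
#' @param x a \linkS4class{PetImage}.
#' @param scale a \linkS4class{StandardScale} from \code{\link{calibrate}}.
#' @param ... further arguments.
#' @return a \linkS4class{StandardizedImage}.
#' @export
setGeneric("standardize", function(x, scale, ...) standardGeneric("standardize"))

#' Convert an activity-concentration image to SUV
#'
#' @param x a \linkS4class{PetImage} with modality \code{"AC"} (Bq/ml).
#' @param ... \code{doseMBq} and \code{weightKg}; taken from the image
#'   metadata when omitted.
#' @return a \linkS4class{PetImage} with modality \code{"SUV"}.
#' @export
setGeneric("toSUV", function(x, ...) standardGeneric("toSUV"))
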