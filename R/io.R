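#' @include phantom.R
NULL

#' Read a 3D PET volume from NIfTI
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file holding a 3D
#'   scalar volume.
#' @param modality \code{"AC"} or \code{"SUV"}.
#' @param metadata optional metadata list (see \code{\link{readMetadata}}).
#' @return a \linkS4class{PetImage}. Negative voxels are rejected, as are
#'   4D/vector inputs.
#' @export
readPetImage <- function(path, modality = c("AC", "SUV"),
                         metadata = list()) {
  modality <- match.arg(modality)
  nim <- RNifti::readNifti(path)
  arr <- array(as.numeric(nim), dim(nim))
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) {
    arr <- array(arr, d[1:3])
  } else if (length(d) != 3L) {
    stop("unsupported NIfTI: expected a 3D scalar volume, got ",
         length(d), " dimensions")
  }
  if (min(arr) < 0)
    stop("file contains negative voxel values; not a valid PET volume: ",
         path)
  PetImage(arr, modality, metadata)
}

#' Write a PET volume to NIfTI
#'
#' Intensities are stored as 32-bit floating point; standardized values
#' are never rounded or quantized.
#'
#' @param image a \linkS4class{PetImage} or \linkS4class{NormalizedImage}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return the path, invisibly.
#' @export
writePetImage <- function(image, path) {
  RNifti::writeNifti(RNifti::asNifti(.vox(image)), path,
                     datatype = "float")
  invisible(path)
}

#' Read a binary organ mask from NIfTI
#'
#' Any nonzero voxel is inside the mask.
#'
#' @param path NIfTI file.
#' @param organ organ name to attach.
#' @return an \linkS4class{OrganMask}.
#' @export
readOrganMask <- function(path, organ) {
  nim <- RNifti::readNifti(path)
  arr <- array(as.numeric(nim), dim(nim))
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) arr <- array(arr, d[1:3])
  if (length(dim(arr)) != 3L)
    stop("unsupported NIfTI mask: expected a 3D volume")
  OrganMask(arr != 0, organ)
}

#' Write a binary mask to NIfTI (uint8)
#'
#' @param mask an \linkS4class{OrganMask}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeOrganMask <- function(mask, path) {
  arr <- array(as.integer(voxels(mask)), dim(voxels(mask)))
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "uint8")
  invisible(path)
}

.KNOWN_META <- c("dose_MBq", "weight_kg", "scanner_id", "subject_id",
                 "modality", "pair_id")

#' Read an image metadata sidecar
#'
#' JSON with fields \code{dose_MBq}, \code{weight_kg}, \code{scanner_id},
#' \code{subject_id}, \code{modality} (and optionally \code{pair_id}).
#' Unknown fields are ignored with a warning.
#'
#' @param path JSON file.
#' @param requireDoseWeight demand positive dose and weight (needed for
#'   SUV conversion of AC images).
#' @return metadata list with elements \code{doseMBq}, \code{weightKg},
#'   \code{scannerId}, \code{subjectId}, \code{modality}.
#' @export
readMetadata <- function(path, requireDoseWeight = FALSE) {
  md <- jsonlite::fromJSON(path)
  extra <- setdiff(names(md), .KNOWN_META)
  if (length(extra))
    warning("ignoring unknown metadata fields: ",
            paste(extra, collapse = ", "))
  if (requireDoseWeight) {
    for (f in c("dose_MBq", "weight_kg")) {
      if (is.null(md[[f]]))
        stop("metadata field '", f, "' is required for SUV conversion ",
             "but missing in ", path)
      if (md[[f]] <= 0)
        stop("metadata field '", f, "' must be positive")
    }
  }
  list(doseMBq = md$dose_MBq, weightKg = md$weight_kg,
       scannerId = md$scanner_id, subjectId = md$subject_id,
       modality = if (is.null(md$modality)) "AC" else md$modality,
       pairId = md$pair_id)
}

#' Write a subject to disk
#'
#' Writes the image, one NIfTI mask per organ, and a JSON metadata
#' sidecar into \code{dir/<subjectId>/}.
#'
#' @param subject a \linkS4class{PhantomSubject}.
#' @param dir output directory (created if needed).
#' @return the subject directory, invisibly.
#' @export
writeSubject <- function(subject, dir) {
  stopifnot(is(subject, "PhantomSubject"))
  md <- subject@metadata
  sdir <- file.path(dir, md$subjectId)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  writePetImage(subject@image, file.path(sdir, "image.nii.gz"))
  for (nm in names(subject@masks))
    writeOrganMask(subject@masks[[nm]],
                   file.path(sdir, sprintf("mask_%s.nii.gz", nm)))
  side <- list(subject_id = md$subjectId, scanner_id = md$scannerId,
               dose_MBq = md$doseMBq, weight_kg = md$weightKg,
               modality = md$modality)
  if (!is.null(md$pairId)) side$pair_id <- md$pairId
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA),
             file.path(sdir, "meta.json"))
  invisible(sdir)
}

#' Read a directory of subjects written by \code{\link{writeSubject}}
#'
#' @param dir directory containing one sub-directory per subject.
#' @param organ which organ masks to load alongside the images.
#' @return list with \code{images}, \code{masks} and \code{metadata}.
#' @export
readSubjectDir <- function(dir, organ = "liver") {
  subdirs <- list.dirs(dir, recursive = FALSE)
  if (!length(subdirs)) stop("no subject directories found in ", dir)
  images <- list(); masks <- list(); metas <- list()
  for (sd in subdirs) {
    md <- readMetadata(file.path(sd, "meta.json"))
    img <- readPetImage(file.path(sd, "image.nii.gz"),
                        modality = md$modality, metadata = md)
    mp <- file.path(sd, sprintf("mask_%s.nii.gz", organ))
    images[[length(images) + 1L]] <- img
    masks[[length(masks) + 1L]] <-
      if (file.exists(mp)) readOrganMask(mp, organ) else NULL
    metas[[length(metas) + 1L]] <- md
  }
  list(images = images, masks = masks, metadata = metas)
}

#' Write a calibrated standard scale to JSON
#'
#' @param scale a \linkS4class{StandardScale}.
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
writeStandardScale <- function(scale, path) {
  stopifnot(is(scale, "StandardScale"))
  obj <- list(modality = scale@modality, alpha = scale@alpha,
              beta = scale@beta, s_min = scale@sMin, s_m = scale@sM,
              s_max = scale@sMax, lambda_inv = scale@invScaleFactor,
              dx = scale@dx)
  if (length(scale@search)) {
    obj$n_calibration <- scale@search$nCalibration
    obj$b_grid <- scale@search$bGrid
    obj$delta_values <- scale@search$deltaValues
  }
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"),
             path)
  invisible(path)
}

#' Read a standard scale from JSON
#'
#' @param path JSON file written by \code{\link{writeStandardScale}}.
#' @return a \linkS4class{StandardScale}.
#' @export
readStandardScale <- function(path) {
  o <- jsonlite::fromJSON(path)
  search <- if (!is.null(o$b_grid))
    list(bGrid = o$b_grid, deltaValues = o$delta_values,
         nCalibration = o$n_calibration)
  else list()
  StandardScale(sMin = o$s_min, sM = o$s_m, sMax = o$s_max, beta = o$beta,
                invScaleFactor = o$lambda_inv, modality = o$modality,
                alpha = o$alpha, dx = o$dx, search = search)
}
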