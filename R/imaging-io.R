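#' Image volumes and ROI masks
#'
#' An `image_volume` carries a 3-D array of intensities plus the voxel
#' spacing in millimetres (one value per array axis, in array index order)
#' and a sequence label (`"T1CE"` or `"T2"`). An `roi_mask` carries a logical
#' 3-D array aligned voxel-for-voxel with its volume and a structure label
#' (`"tumor"` or `"node"`). Volumes and masks are required to be pre-aligned
#' on the same grid; no world-coordinate resampling is performed.
#'
#' @param intensities 3-D numeric array of finite values.
#' @param spacing_mm positive numeric triple, millimetres per voxel along
#'   each array axis.
#' @param sequence sequence label, `"T1CE"` or `"T2"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(intensities, spacing_mm, sequence = c("T1CE", "T2")) {
  sequence <- match.arg(sequence)
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("'intensities' must be a 3-D array")
  if (!all(is.finite(intensities)))
    stop("'intensities' must be finite")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("'spacing_mm' must be three positive numbers")
  structure(
    list(intensities = intensities, spacing_mm = spacing_mm,
         sequence = sequence),
    class = "image_volume"
  )
}

#' @rdname image_volume
#' @param voxels 3-D logical (or 0/1) array.
#' @param structure structure label, `"tumor"` or `"node"`.
#' @export
roi_mask <- function(voxels, structure = c("tumor", "node")) {
  structure <- match.arg(structure)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3-D array")
  vox <- array(voxels > 0.5, dim = dim(voxels))
  structure(list(voxels = vox, structure = structure), class = "roi_mask")
}

check_geometry <- function(volume, mask, what = "mask") {
  if (!identical(dim(volume$intensities), dim(mask$voxels)))
    stop(sprintf(
      "geometry error: %s shape (%s) does not match volume shape (%s)",
      what, paste(dim(mask$voxels), collapse = "x"),
      paste(dim(volume$intensities), collapse = "x")))
  invisible(TRUE)
}

check_nonempty <- function(mask) {
  if (!any(mask$voxels))
    stop("empty-ROI error: mask '", mask$structure,
         "' contains no foreground voxel")
  invisible(TRUE)
}

#' Read and write NIfTI volumes and masks
#'
#' Thin wrappers around RNifti. Spacing is taken from the NIfTI header
#' (`pixdim`); masks are binarized at 0.5 on read.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param sequence,structure labels attached to the object read.
#' @return `read_volume()` an `image_volume`; `read_mask()` an `roi_mask`.
#' @export
read_volume <- function(path, sequence = c("T1CE", "T2")) {
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim = dim(img)),
               RNifti::pixdim(img)[seq_len(3)], match.arg(sequence))
}

#' @rdname read_volume
#' @export
read_mask <- function(path, structure = c("tumor", "node")) {
  img <- RNifti::readNifti(path)
  roi_mask(array(as.numeric(img), dim = dim(img)), match.arg(structure))
}

#' @rdname read_volume
#' @param volume an `image_volume` to write.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$intensities)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @param mask an `roi_mask` to write.
#' @param spacing_mm spacing recorded in the mask header.
#' @export
write_mask <- function(mask, path, spacing_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.numeric(mask$voxels), dim = dim(mask$voxels)))
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Feature table CSV round trip
#'
#' A feature table is a data frame with a `patient_id` column and one column
#' per feature, named `<structure>_<sequence>_<family>_<feature>`. Values are
#' matched by column name, never by position; missing feature values are
#' serialized as empty cells and read back as `NA`.
#'
#' @param table feature table data frame.
#' @param path CSV path.
#' @return `read_feature_table()` returns the table with `patient_id` as
#'   character and feature columns numeric.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table), "patient_id" %in% names(table))
  if (anyDuplicated(table$patient_id))
    stop("duplicate patient_id in feature table")
  write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, check.names = FALSE, colClasses = c(patient_id = "character"))
  if (anyDuplicated(tab$patient_id))
    stop("duplicate patient_id in feature table")
  feat <- setdiff(names(tab), "patient_id")
  tab[feat] <- lapply(tab[feat], as.numeric)
  tab
}

#' @rdname write_feature_table
#' @param outcomes long outcome table with columns `patient_id`, `endpoint`,
#'   `time_months`, `event`.
#' @export
write_outcomes <- function(outcomes, path) {
  stopifnot(all(c("patient_id", "endpoint", "time_months", "event") %in%
                  names(outcomes)))
  write.csv(outcomes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_outcomes <- function(path) {
  out <- read.csv(path, check.names = FALSE,
                  colClasses = c(patient_id = "character"))
  stopifnot(all(c("patient_id", "endpoint", "time_months", "event") %in%
                  names(out)))
  out
}
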