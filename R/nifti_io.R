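#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file into a [scan_volume()]. Geometry (spacing, origin,
#' orientation) is taken from the sform/qform affine. A gantry-tilt angle
#' is read from a YAML sidecar `<path>.yaml` (key `gantry_tilt_deg`) when
#' present, since the NIfTI header has no field for it.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A `scan_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("volume file does not exist: ", path)
  img <- tryCatch(
    withCallingHandlers(
      RNifti::readNifti(path),
      warning = function(w) stop(conditionMessage(w))),
    error = function(e) stop("malformed NIfTI file '", path, "': ",
                             conditionMessage(e)))
  arr <- array(as.vector(img), dim(img))   # strip RNifti attributes
  if (length(dim(arr)) != 3)
    stop("malformed NIfTI header: expected 3 dimensions (field dim), got ",
         length(dim(arr)))
  m <- RNifti::xform(img)
  sp <- sqrt(colSums(m[1:3, 1:3]^2))
  if (any(sp <= 0) || any(!is.finite(sp)))
    stop("malformed NIfTI header: non-positive voxel spacing (field pixdim)")
  orient <- sweep(m[1:3, 1:3], 2, sp, "/")
  tilt <- 0
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    if (!is.null(meta$gantry_tilt_deg)) tilt <- as.numeric(meta$gantry_tilt_deg)
  }
  scan_volume(arr, spacing = sp, origin = m[1:3, 4], orientation = orient,
              gantry_tilt_deg = tilt)
}

#' Write a NIfTI volume
#'
#' Writes a [scan_volume()] as NIfTI-1 with a float64 data block so the
#' write/read round trip preserves intensities exactly. A nonzero gantry
#' tilt is recorded in a YAML sidecar `<path>.yaml`.
#'
#' @param v a `scan_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "scan_volume"))
  arr <- v$data
  storage.mode(arr) <- "double"
  attr(arr, "pixdim") <- v$spacing
  img <- RNifti::asNifti(arr, datatype = "double")
  m <- diag(4)
  m[1:3, 1:3] <- sweep(v$orientation, 2, v$spacing, "*")
  m[1:3, 4] <- v$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  sidecar <- paste0(path, ".yaml")
  if (v$gantry_tilt_deg != 0) {
    yaml::write_yaml(list(gantry_tilt_deg = v$gantry_tilt_deg), sidecar)
  } else if (file.exists(sidecar)) {
    unlink(sidecar)
  }
  invisible(path)
}

#' Write a binary mask as a NIfTI label volume
#'
#' Background is 0, the labelled structure 1.
#' @param mask a `binary_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  v <- scan_volume(array(as.numeric(mask$values), dim(mask$values)),
                   mask$spacing, mask$origin, mask$orientation)
  write_volume(v, path)
}

#' Read a NIfTI label volume as a binary mask
#' @param path path to a label volume (nonzero = labelled).
#' @param role mask role, `"brain"` or `"skull"`.
#' @return A `binary_mask`.
#' @export
read_mask <- function(path, role = "brain") {
  v <- read_volume(path)
  binary_mask(v$data > 0.5, v, role = role)
}
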