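#' CT-like volume in Hounsfield units
#'
#' A light container for a 3D scalar grid in Hounsfield units (HU) together
#' with the geometric metadata the projection code needs: the voxel size, the
#' room-frame position of the first voxel center, and the machine isocenter.
#' The room frame is the fixed couch frame with axes (lateral, longitudinal,
#' vertical) in mm; by convention the isocenter sits at the room origin.
#'
#' @param values 3D numeric array of HU values.
#' @param spacing Numeric length-3, voxel size in mm per axis (must be > 0).
#' @param origin Numeric length-3, room coordinates (mm) of the center of
#'   voxel `[1, 1, 1]`.
#' @param isocenter Numeric length-3, room coordinates (mm) of the machine
#'   isocenter. Must lie inside the volume bounds.
#' @param bb Optional list describing an embedded ball-bearing fiducial,
#'   with elements `center` (room mm) and `diameter` (mm). Used by
#'   [sample_fill_hu()] to refuse regions that overlap the BB.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(values, spacing, origin, isocenter = c(0, 0, 0),
                      bb = NULL) {
  if (length(dim(values)) != 3L) abort("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("`spacing` must be three strictly positive voxel sizes (mm)")
  if (any(!is.finite(values))) abort("HU values must be finite")
  origin <- as.numeric(origin)
  isocenter <- as.numeric(isocenter)
  vol <- structure(
    list(values = values, spacing = spacing, origin = origin,
         isocenter = isocenter, bb = bb),
    class = "ct_volume"
  )
  upper <- origin + (dim(values) - 1) * spacing
  if (any(isocenter < origin - spacing / 2) ||
      any(isocenter > upper + spacing / 2))
    abort("`isocenter` lies outside the volume bounds")
  vol
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  HU range [%.1f, %.1f], isocenter (%s) mm\n",
              min(x$values), max(x$values),
              paste(signif(x$isocenter, 4), collapse = ", ")))
  if (!is.null(x$bb))
    cat(sprintf("  BB: %.1f mm diameter at (%s) mm\n", x$bb$diameter,
                paste(signif(x$bb$center, 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$values)

# voxel index (1-based) of the room point nearest to `point`
voxel_index <- function(volume, point) {
  i <- round((point - volume$origin) / volume$spacing) + 1
  pmin(pmax(as.integer(i), 1L), dim(volume$values))
}

# room coordinates of voxel centers along one axis
axis_coords <- function(volume, axis) {
  volume$origin[axis] + (seq_len(dim(volume$values)[axis]) - 1) *
    volume$spacing[axis]
}

#' Read and write CT volumes as NIfTI
#'
#' Volumes are stored as NIfTI-1 with the voxel size in `pixdim` and the
#' room-frame origin in the sform. Isocenter and BB metadata, which NIfTI has
#' no slot for, travel in a JSON sidecar (`<file>.json`) written next to the
#' image; `read_ct_volume()` falls back to an isocenter at the room origin
#' when no sidecar is present.
#'
#' @param volume A [ct_volume()].
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return `write_ct_volume()` returns `path` invisibly; `read_ct_volume()`
#'   returns a [ct_volume()].
#' @export
write_ct_volume <- function(volume, path) {
  mat <- diag(4)
  mat[1, 1] <- volume$spacing[1]
  mat[2, 2] <- volume$spacing[2]
  mat[3, 3] <- volume$spacing[3]
  mat[1:3, 4] <- volume$origin
  img <- RNifti::asNifti(volume$values)
  img <- RNifti::`pixdim<-`(img, volume$spacing)
  img <- RNifti::`sform<-`(img, structure(mat, code = 2L))
  RNifti::writeNifti(img, path)
  side <- list(isocenter = volume$isocenter, bb = volume$bb)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ct_volume
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  spacing <- hdr$pixdim[2:4]
  mat <- RNifti::xform(img)
  origin <- as.numeric(mat[1:3, 4])
  iso <- c(0, 0, 0)
  bb <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$isocenter)) iso <- as.numeric(side$isocenter)
    if (!is.null(side$bb) && length(side$bb)) {
      bb <- list(center = as.numeric(side$bb$center),
                 diameter = as.numeric(side$bb$diameter))
    }
  }
  ct_volume(array(as.numeric(img), dim = dim(img)), spacing, origin, iso, bb)
}

# translate a volume rigidly in the room frame (anatomy moves by +offset)
translate_volume <- function(volume, offset) {
  volume$origin <- volume$origin + as.numeric(offset)
  if (!is.null(volume$bb)) volume$bb$center <- volume$bb$center + offset
  volume
}
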