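#' CT volume container
#'
#' A `ct_volume` holds a 3D grid of Hounsfield-unit (HU) values together with
#' its voxel spacing and free-form provenance metadata. Axial slice index
#' increases inferior to superior; readers normalise input data to this
#' convention. Voxels are stored as double even when the source data are
#' integral, because downstream medians and slice averages are fractional.
#'
#' @param voxels 3D numeric array of HU values (rows x columns x slices).
#' @param spacing numeric length-3: (row_mm, col_mm, slice_mm), all > 0.
#' @param meta named list of provenance (source path, original thickness,
#'   rescale applied, ...). Free-form.
#'
#' @details HU values outside the plausible scanner range (-1024 to 4000) do
#'   not invalidate the volume: a warning is raised and a record is appended
#'   to `meta$warnings`, since clipped or padded exports are common in
#'   practice. Non-finite voxels or non-positive spacing are hard errors.
#'
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, meta = list()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite values (row_mm, col_mm, slice_mm)")
  storage.mode(voxels) <- "double"
  if (!all(is.finite(voxels)))
    stop("voxels contain non-finite HU values")
  rng <- range(voxels)
  if (rng[1] < -1024 || rng[2] > 4000) {
    msg <- sprintf("HU values outside plausible range [-1024, 4000]: observed [%.1f, %.1f]",
                   rng[1], rng[2])
    meta$warnings <- c(meta$warnings, msg)
    warning(msg, call. = FALSE)
  }
  structure(list(voxels = voxels, spacing = as.numeric(spacing), meta = meta),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$voxels), max(x$voxels)))
  if (!is.null(x$meta$source)) cat("  source:", x$meta$source, "\n")
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Binary segmentation mask on a CT grid
#'
#' A `seg_mask` is a voxelwise logical labelling sharing the grid (shape and
#' spacing) of a parent [ct_volume()]. The same class serves every mask role:
#' intracranial mask, lesion mask, exclusion zone, phantom ground truth.
#'
#' @param voxels 3D logical array.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param parent optional `ct_volume`; if given, shape and spacing must match.
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(voxels, spacing, parent = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("mask voxels must be a 3D array")
  if (!is.logical(voxels)) {
    if (!all(voxels %in% c(0, 1)))
      stop("mask voxels must be logical or 0/1")
    voxels <- array(voxels != 0, dim(voxels))
  }
  if (!is.null(parent)) {
    if (!identical(dim(voxels), dim(parent$voxels)))
      stop(sprintf("mask shape (%s) does not match volume shape (%s)",
                   paste(dim(voxels), collapse = "x"),
                   paste(dim(parent$voxels), collapse = "x")))
    spacing <- parent$spacing
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite values")
  structure(list(voxels = voxels, spacing = as.numeric(spacing)),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<seg_mask> %d x %d x %d, %d voxels set (%.2f cc)\n",
              d[1], d[2], d[3], sum(x$voxels), volume_cc(x)))
  invisible(x)
}

#' @export
dim.seg_mask <- function(x) dim(x$voxels)

#' Mask volume in cubic centimetres
#'
#' Volume is the in-plane pixel area times the slice thickness, summed over
#' voxels: `count * row_mm * col_mm * slice_mm / 1000`.
#'
#' @param mask a `seg_mask`, a logical array, or a voxel count.
#' @param spacing voxel spacing in mm; taken from `mask` when it is a
#'   `seg_mask`.
#' @return Volume in cc (ml).
#' @export
volume_cc <- function(mask, spacing = NULL) {
  if (inherits(mask, "seg_mask")) {
    count <- sum(mask$voxels)
    spacing <- mask$spacing
  } else if (is.array(mask) || is.logical(mask)) {
    count <- sum(mask != 0)
  } else if (is.numeric(mask) && length(mask) == 1L) {
    count <- mask
  } else stop("mask must be a seg_mask, a logical array, or a voxel count")
  if (is.null(spacing)) stop("spacing required when mask carries none")
  count * prod(spacing) / 1000
}

# grid-compatibility check used wherever a mask is paired with a volume
check_same_grid <- function(a, b) {
  da <- if (inherits(a, c("ct_volume", "seg_mask"))) dim(a$voxels) else dim(a)
  db <- if (inherits(b, c("ct_volume", "seg_mask"))) dim(b$voxels) else dim(b)
  if (!identical(da, db))
    stop(sprintf("grid mismatch: %s vs %s",
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  invisible(TRUE)
}
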