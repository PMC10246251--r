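#' Read a non-contrast head CT volume
#'
#' Reads a CT volume from a NIfTI-1 file or a DICOM series directory into a
#' [ct_volume()]. DICOM rescale slope/intercept are applied so voxels are in
#' Hounsfield units, slices are sorted by table position so the axial index
#' always increases inferior to superior, and provenance (source path,
#' original slice thickness, rescale, gantry tilt) is recorded in `meta`.
#' Gantry tilt is recorded but never corrected.
#'
#' @param path a NIfTI file (`.nii` / `.nii.gz`) or a directory of DICOM
#'   Part-10 files.
#' @param format `"auto"` (directory = DICOM series, file = NIfTI),
#'   `"dicom_series"` or `"nifti"`.
#' @param spacing_tolerance maximum relative variation tolerated in DICOM
#'   slice spacing (default 0.05); larger gaps (missing slices) are an error.
#' @return A [ct_volume()].
#' @seealso [resample_thickness()], [read_mask()]
#' @export
read_ct <- function(path, format = c("auto", "dicom_series", "nifti"),
                    spacing_tolerance = 0.05) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  if (!file.exists(path)) stop(sprintf("path does not exist: %s", path))
  if (format == "dicom_series") {
    read_dicom_series(path, spacing_tolerance = spacing_tolerance)
  } else {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    arr <- array(as.vector(arr), dim(arr))  # drop RNifti attributes
    if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
    if (length(dim(arr)) != 3L)
      stop(sprintf("expected a 3D NIfTI volume, got %dD", length(dim(arr))))
    pd <- RNifti::pixdim(img)[seq_len(3)]
    # normalise to inferior -> superior: flip if the xform sends +k to -z
    xf <- try(RNifti::xform(img), silent = TRUE)
    flipped <- FALSE
    if (!inherits(xf, "try-error") && is.matrix(xf) && nrow(xf) >= 3 && xf[3, 3] < 0) {
      arr <- arr[, , rev(seq_len(dim(arr)[3])), drop = FALSE]
      flipped <- TRUE
    }
    ct_volume(arr, spacing = pd,
              meta = list(source = path, format = "nifti",
                          original_thickness_mm = pd[3], flipped_z = flipped))
  }
}

#' Write a CT volume to NIfTI-1
#'
#' @param vol a [ct_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_ct <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Merge-and-average a CT volume to the analysis slice thickness
#'
#' Serial head CT protocols acquire 1-5 mm axial slices; analysis is
#' performed on a uniform 5 mm grid, with thinner source slices merged and
#' averaged. Each output slice is the thickness-weighted mean of the input
#' slices it spans, with fractional weights for input slices straddling an
#' output boundary, so the HU "mass" `sum(voxels) * slice_mm` is conserved
#' when the target is an integer multiple of the source thickness. The
#' in-plane grid is never touched, and a volume already at the target
#' thickness is returned unchanged.
#'
#' @param vol a [ct_volume()].
#' @param target_mm analysis slice thickness in mm (default 5). Must be at
#'   least the source thickness: slices are only ever merged, never
#'   interpolated thinner.
#' @return A [ct_volume()] with `slice_mm == target_mm`.
#' @export
resample_thickness <- function(vol, target_mm = 5.0) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!is.finite(target_mm) || target_mm <= 0) stop("target_mm must be > 0")
  src <- vol$spacing[3]
  if (abs(src - target_mm) < 1e-9) return(vol)
  if (src > target_mm)
    stop(sprintf("source slices (%.3g mm) are thicker than target (%.3g mm); merging only, no interpolation",
                 src, target_mm))
  d <- dim(vol$voxels)
  nz_in <- d[3]
  depth <- nz_in * src
  nz_out <- ceiling(depth / target_mm - 1e-9)
  # overlap in mm between input slice i (spans [(i-1)s, is]) and output slice j
  W <- matrix(0, nz_in, nz_out)
  for (j in seq_len(nz_out)) {
    lo <- (j - 1) * target_mm
    hi <- min(j * target_mm, depth)
    i0 <- floor(lo / src) + 1
    i1 <- min(ceiling(hi / src - 1e-9), nz_in)
    for (i in i0:i1)
      W[i, j] <- max(0, min(i * src, hi) - max((i - 1) * src, lo))
    W[, j] <- W[, j] / sum(W[, j])
  }
  flat <- matrix(vol$voxels, nrow = d[1] * d[2], ncol = nz_in)
  out <- array(flat %*% W, c(d[1], d[2], nz_out))
  meta <- vol$meta
  meta$resampled_from_mm <- src
  ct_volume(out, spacing = c(vol$spacing[1:2], target_mm), meta = meta)
}

#' Read / write a binary mask as NIfTI
#'
#' Masks round-trip losslessly as uint8 \{0,1\} NIfTI-1 volumes. When a
#' companion volume is supplied the mask grid must match it exactly.
#'
#' @param path NIfTI file path.
#' @param companion optional [ct_volume()] the mask must share a grid with.
#' @return A [seg_mask()].
#' @export
read_mask <- function(path, companion = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim(arr))
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  pd <- RNifti::pixdim(img)[seq_len(3)]
  m <- seg_mask(arr != 0, spacing = pd)
  if (!is.null(companion)) check_same_grid(m, companion)
  m
}

#' @rdname read_mask
#' @param mask a [seg_mask()] to write.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "seg_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$voxels), dim(mask$voxels)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
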