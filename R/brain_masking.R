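#' Parameters for intracranial masking and anatomical exclusion
#'
#' Hyperdensity detection needs two geometric ingredients besides the HU
#' threshold: the intracranial (brain) mask over which the reference median
#' is taken, and an exclusion zone marking where hyperdense voxels are
#' presumed dural or falcine rather than haemorrhagic — the dural venous
#' sinuses (torcular Herophili, straight, sagittal and transverse sinuses)
#' hug the inner skull table, and the falx cerebri sits in the posterior
#' interhemispheric midline. Both are realised geometrically: a peripheral
#' shell of `dural_margin_mm` inside the cranial vault, plus a posterior
#' mid-sagittal band of half-width `midline_band_mm`.
#'
#' @param bone_hu HU threshold above which a voxel is skull (default 300).
#' @param brain_hu_window `(low, high)` HU window for parenchyma candidates
#'   (default `c(0, 100)`). Cavity voxels from `low` up to `bone_hu` are kept
#'   in the intracranial mask so hyperdense blood is never excluded from it.
#' @param dural_margin_mm thickness of the peripheral dural shell (default 3).
#' @param midline_band_mm half-width of the posterior midline (falx) band
#'   (default 2). Zero disables the band.
#' @return An object of class `masking_params`.
#' @export
masking_params <- function(bone_hu = 300, brain_hu_window = c(0, 100),
                           dural_margin_mm = 3.0, midline_band_mm = 2.0) {
  stopifnot(length(brain_hu_window) == 2, brain_hu_window[1] < brain_hu_window[2])
  if (bone_hu <= brain_hu_window[2])
    stop("bone_hu must exceed the upper brain HU window")
  if (dural_margin_mm < 0 || midline_band_mm < 0)
    stop("margins must be >= 0")
  structure(list(bone_hu = bone_hu, brain_hu_window = as.numeric(brain_hu_window),
                 dural_margin_mm = dural_margin_mm,
                 midline_band_mm = midline_band_mm),
            class = "masking_params")
}

# per-slice cavity: non-bone regions fully enclosed by skull in that slice.
# A non-bone component touching the slice border is outside the head.
.slice_cavities <- function(bone) {
  d <- dim(bone)
  cav <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    sl <- !bone[, , k]
    lab <- .cc_label3d(as.logical(sl), c(d[1], d[2], 1L), 6L)  # 4-connectivity in-plane
    n <- attr(lab, "n")
    if (n == 0) next
    lab <- matrix(lab, d[1], d[2])
    border <- unique(c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]]))
    border <- border[border > 0]
    keep <- setdiff(seq_len(n), border)
    if (length(keep)) cav[, , k] <- lab %in% keep
  }
  cav
}

#' Intracranial mask
#'
#' Segments the space inside the skull: voxels above `bone_hu` are skull,
#' each axial slice's skull-enclosed cavity is filled, the largest 3D
#' connected cavity component is kept (discarding enclosed pockets outside
#' the cranial vault), and the result is intersected with the HU range
#' `[brain_hu_window[1], bone_hu)` so air and bone are excluded but
#' hyperdense blood is retained.
#'
#' @param vol a [ct_volume()] head NCCT, normally already resampled to the
#'   analysis thickness.
#' @param params a [masking_params()].
#' @return A [seg_mask()] of intracranial tissue. Contains no bone voxels.
#' @export
intracranial_mask <- function(vol, params = masking_params()) {
  stopifnot(inherits(vol, "ct_volume"))
  bone <- vol$voxels > params$bone_hu
  if (!any(bone)) stop("not a head CT: no voxels above the skull HU threshold")
  cav <- .slice_cavities(bone)
  if (!any(cav)) stop("empty cavity: skull encloses no interior on any slice")
  lab <- .cc_label3d(as.logical(cav), dim(cav), 26L)
  counts <- tabulate(lab[lab > 0], nbins = attr(lab, "n"))
  cav <- array(lab == which.max(counts), dim(cav))
  keep <- cav & vol$voxels >= params$brain_hu_window[1] & vol$voxels < params$bone_hu
  if (!any(keep)) stop("empty cavity after HU filtering")
  seg_mask(keep, spacing = vol$spacing)
}

#' Restrict a cavity mask to the analysed slice range
#'
#' Slices below the brain stem and above the vertex are excluded from
#' analysis. The skull base is located as the lowest slice whose cavity
#' cross-section reaches 25\% of the maximum cross-section — a reproducible
#' proxy for an anatomically fuzzy boundary — and the top is the highest
#' slice containing any cavity voxel. Everything outside that slice interval
#' is zeroed. Idempotent.
#'
#' @param mask a [seg_mask()] from [intracranial_mask()].
#' @param min_fraction cross-section fraction defining the lowest slice
#'   (default 0.25).
#' @return A [seg_mask()].
#' @export
slice_range_filter <- function(mask, min_fraction = 0.25) {
  stopifnot(inherits(mask, "seg_mask"))
  area <- apply(mask$voxels, 3, sum)
  if (all(area == 0)) stop("empty mask")
  lo <- which(area >= min_fraction * max(area))[1]
  hi <- max(which(area > 0))
  out <- mask$voxels
  if (lo > 1) out[, , seq_len(lo - 1)] <- FALSE
  if (hi < dim(out)[3]) out[, , seq(hi + 1, dim(out)[3])] <- FALSE
  seg_mask(out, spacing = mask$spacing)
}

# binary erosion by a Euclidean ball of radius margin_mm, anisotropic spacing.
# Implemented as shift-and-AND over the in-ball offsets; voxels outside the
# array count as background, so the mask is also eroded at the array edge.
.erode_mm <- function(mask, spacing, margin_mm) {
  if (margin_mm <= 0) return(mask)
  d <- dim(mask)
  rng <- function(mm) seq(-floor(margin_mm / mm), floor(margin_mm / mm))
  out <- mask
  for (dz in rng(spacing[3])) for (dy in rng(spacing[2])) for (dx in rng(spacing[1])) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if ((dx * spacing[1])^2 + (dy * spacing[2])^2 + (dz * spacing[3])^2 > margin_mm^2) next
    sh <- array(FALSE, d)
    src_i <- seq_len(d[1]) + dx; src_j <- seq_len(d[2]) + dy; src_k <- seq_len(d[3]) + dz
    ok_i <- src_i >= 1 & src_i <= d[1]
    ok_j <- src_j >= 1 & src_j <= d[2]
    ok_k <- src_k >= 1 & src_k <= d[3]
    sh[ok_i, ok_j, ok_k] <- mask[src_i[ok_i], src_j[ok_j], src_k[ok_k]]
    out <- out & sh
    if (!any(out)) break
  }
  out
}

#' Anatomical exclusion zone for dural and falcine hyperdensities
#'
#' Marks where a hyperdense voxel is presumed to be a normal dense structure
#' rather than haemorrhage: the union of a peripheral shell (the mask minus
#' its 3D erosion by `dural_margin_mm`, where the dural venous sinuses run)
#' and a posterior mid-sagittal band of half-width `midline_band_mm` (the
#' falx cerebri and the straight/inferior sagittal sinuses). The
#' mid-sagittal plane is estimated per slice as the cavity's in-plane
#' centre-of-mass column; the posterior half is rows beyond the
#' centre-of-mass row. Components of detected hyperdensity falling mostly
#' inside this zone are rejected by [filter_false_positives()].
#'
#' An empty zone is valid (both margins zero).
#'
#' @param mask a [seg_mask()] from [slice_range_filter()].
#' @param params a [masking_params()].
#' @return A [seg_mask()], a subset of `mask`.
#' @export
exclusion_zone <- function(mask, params = masking_params()) {
  stopifnot(inherits(mask, "seg_mask"))
  m <- mask$voxels
  d <- dim(m)
  shell <- m & !.erode_mm(m, mask$spacing, params$dural_margin_mm)
  band <- array(FALSE, d)
  if (params$midline_band_mm > 0) {
    for (k in seq_len(d[3])) {
      sl <- m[, , k]
      if (!any(sl)) next
      idx <- which(sl, arr.ind = TRUE)
      com_row <- mean(idx[, 1]); com_col <- mean(idx[, 2])
      cols_in <- abs(seq_len(d[2]) - com_col) * mask$spacing[2] <= params$midline_band_mm
      rows_in <- seq_len(d[1]) > com_row
      band[rows_in, cols_in, k] <- sl[rows_in, cols_in]
    }
  }
  seg_mask(shell | band, spacing = mask$spacing)
}
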