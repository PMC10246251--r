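#' Hyperdensity detection parameters
#'
#' @param hu_offset HU margin above the brain-tissue median defining
#'   hyperdensity (default 15; inclusion is strictly greater than
#'   `median + hu_offset`).
#' @param min_component_cc detection floor per connected component in cc
#'   (default 1): smaller components are rejected, mirroring a 1 ml
#'   detection limit.
#' @param connectivity 3D neighbourhood for component labelling: 6, 18 or
#'   26 (default 26, the standard choice for lesion blobs).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(hu_offset = 15.0, min_component_cc = 1.0,
                             connectivity = 26L) {
  if (!is.finite(hu_offset) || hu_offset <= 0) stop("hu_offset must be > 0")
  if (min_component_cc < 0) stop("min_component_cc must be >= 0")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  structure(list(hu_offset = hu_offset, min_component_cc = min_component_cc,
                 connectivity = as.integer(connectivity)),
            class = "detection_params")
}

#' Median HU of brain tissue
#'
#' The detection threshold is relative to the median HU over the
#' intracranial mask. The median is taken over all masked voxels, including
#' any hyperdense lesion voxels; with an even voxel count the midpoint of
#' the two central order statistics is returned. For a very large ICH the
#' included lesion biases the median (hence the threshold) slightly upward
#' — see the package vignette.
#'
#' @param vol a [ct_volume()].
#' @param brain_mask a non-empty [seg_mask()] on the same grid.
#' @return Median HU (scalar).
#' @export
brain_median <- function(vol, brain_mask) {
  stopifnot(inherits(vol, "ct_volume"), inherits(brain_mask, "seg_mask"))
  check_same_grid(vol, brain_mask)
  if (!any(brain_mask$voxels)) stop("empty brain mask: median undefined")
  stats::median(vol$voxels[brain_mask$voxels])
}

#' Threshold hyperdense voxels relative to the brain median
#'
#' A voxel is hyperdense when it lies in the brain mask and its HU is
#' strictly greater than `median_hu + hu_offset` (the "> 15 HU above the
#' brain tissue median" rule; ties at the threshold are excluded).
#'
#' @param vol a [ct_volume()].
#' @param brain_mask intracranial [seg_mask()].
#' @param median_hu brain median from [brain_median()].
#' @param params a [detection_params()].
#' @return A [seg_mask()] of hyperdense candidate voxels.
#' @export
threshold_hyperdense <- function(vol, brain_mask, median_hu,
                                 params = detection_params()) {
  stopifnot(is.finite(median_hu))
  check_same_grid(vol, brain_mask)
  seg_mask(brain_mask$voxels & vol$voxels > median_hu + params$hu_offset,
           spacing = vol$spacing)
}

#' Label 3D connected components
#'
#' Assigns every mask voxel to exactly one maximal connected component under
#' the chosen 3D connectivity (6 = faces, 18 = faces+edges, 26 = all
#' neighbours). An empty mask yields zero components.
#'
#' @param mask a [seg_mask()].
#' @param connectivity 6, 18 or 26.
#' @return An object of class `cc_labels`: list with `labels` (integer 3D
#'   array, 0 = background), `n` (component count), `spacing`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "seg_mask"))
  lab <- .cc_label3d(as.logical(mask$voxels), dim(mask$voxels),
                     as.integer(connectivity))
  n <- attr(lab, "n")
  structure(list(labels = array(as.integer(lab), dim(mask$voxels)),
                 n = n, spacing = mask$spacing, connectivity = connectivity),
            class = "cc_labels")
}

#' Reject false-positive components
#'
#' Applies the false-positive correction to labelled hyperdense components:
#' a component is rejected when its volume is below the detection floor
#' (`reason = "below_detection_floor"`) or when more than half of its voxels
#' lie inside the anatomical exclusion zone (`reason = "dural_structure"`,
#' the fate of falx and sinus hyperdensities). All other components are
#' kept.
#'
#' @param components a `cc_labels` from [label_components()].
#' @param zone exclusion [seg_mask()] from [exclusion_zone()], or `NULL`.
#' @param params a [detection_params()].
#' @param max_zone_fraction rejection cutoff on the fraction of component
#'   voxels inside the zone (default 0.5).
#' @return A data frame with one row per component: `id`, `voxels`,
#'   `volume_cc`, centroid (mm), `zone_fraction`, `kept`, `reason`.
#' @export
filter_false_positives <- function(components, zone = NULL,
                                   params = detection_params(),
                                   max_zone_fraction = 0.5) {
  stopifnot(inherits(components, "cc_labels"))
  n <- components$n
  sp <- components$spacing
  if (n == 0)
    return(data.frame(id = integer(), voxels = integer(), volume_cc = numeric(),
                      centroid_row_mm = numeric(), centroid_col_mm = numeric(),
                      centroid_slice_mm = numeric(), zone_fraction = numeric(),
                      kept = logical(), reason = character()))
  lab <- components$labels
  idx <- which(lab > 0)
  comp <- lab[idx]
  counts <- tabulate(comp, nbins = n)
  d <- dim(lab)
  ai <- arrayInd(idx, d)
  cen <- vapply(1:3, function(a)
    (vapply(split(ai[, a], comp), mean, 0) - 0.5) * sp[a], numeric(n))
  cen <- matrix(cen, nrow = n)
  zone_frac <- if (is.null(zone)) rep(0, n) else {
    inz <- zone$voxels[idx]
    vapply(split(inz, comp), mean, 0)
  }
  vol <- counts * prod(sp) / 1000
  reason <- rep(NA_character_, n)
  reason[vol < params$min_component_cc] <- "below_detection_floor"
  reason[is.na(reason) & zone_frac > max_zone_fraction] <- "dural_structure"
  data.frame(id = seq_len(n), voxels = counts, volume_cc = vol,
             centroid_row_mm = cen[, 1], centroid_col_mm = cen[, 2],
             centroid_slice_mm = cen[, 3],
             zone_fraction = zone_frac,
             kept = is.na(reason),
             reason = ifelse(is.na(reason), "", reason))
}

#' Detect intracerebral haemorrhage on a head NCCT
#'
#' Runs the full automated volumetry pipeline: resample to the analysis
#' slice thickness, intracranial masking, slice-range restriction,
#' anatomical exclusion zone, brain-median-relative HU thresholding,
#' 3D component labelling, false-positive rejection, and volumetry. The
#' result is deterministic for a fixed input.
#'
#' @param vol a [ct_volume()] head NCCT (slice thickness at most
#'   `analysis_thickness_mm`).
#' @param masking a [masking_params()].
#' @param detection a [detection_params()].
#' @param analysis_thickness_mm slice thickness the analysis runs at
#'   (default 5 mm; thinner acquisitions are merged and averaged).
#' @return An object of class `lesion_report`: total detected volume
#'   (`total_volume_cc`, the sum of kept component volumes), the per-
#'   component table, `brain_median_hu`, `threshold_hu`, the kept-lesion
#'   [seg_mask()] (`lesion_mask`, on the analysis grid) and the parameters
#'   used.
#' @export
detect_ich <- function(vol, masking = masking_params(),
                       detection = detection_params(),
                       analysis_thickness_mm = 5.0) {
  stopifnot(inherits(vol, "ct_volume"))
  vol5 <- resample_thickness(vol, analysis_thickness_mm)
  brain <- intracranial_mask(vol5, masking)
  brain <- slice_range_filter(brain)
  zone <- exclusion_zone(brain, masking)
  med <- brain_median(vol5, brain)
  hyper <- threshold_hyperdense(vol5, brain, med, detection)
  comps <- label_components(hyper, detection$connectivity)
  tab <- filter_false_positives(comps, zone, detection)
  kept_ids <- tab$id[tab$kept]
  lesion <- seg_mask(array(comps$labels %in% kept_ids, dim(comps$labels)),
                     spacing = vol5$spacing)
  structure(list(
    total_volume_cc = sum(tab$volume_cc[tab$kept]),
    components = tab,
    brain_median_hu = med,
    threshold_hu = med + detection$hu_offset,
    lesion_mask = lesion,
    params = list(masking = masking, detection = detection,
                  analysis_thickness_mm = analysis_thickness_mm),
    provenance = vol$meta
  ), class = "lesion_report")
}

#' @export
print.lesion_report <- function(x, digits = 2, ...) {
  cat("Automated hyperdensity detection\n")
  cat(sprintf("  brain median: %.1f HU   threshold: > %.1f HU\n",
              x$brain_median_hu, x$threshold_hu))
  k <- sum(x$components$kept)
  r <- nrow(x$components) - k
  cat(sprintf("  components: %d kept, %d rejected\n", k, r))
  if (r > 0) {
    rej <- x$components[!x$components$kept, ]
    for (i in seq_len(nrow(rej)))
      cat(sprintf("    - rejected #%d (%.2f cc): %s\n",
                  rej$id[i], rej$volume_cc[i], rej$reason[i]))
  }
  cat(sprintf("  total ICH volume: %.*f cc\n", digits, x$total_volume_cc))
  invisible(x)
}

#' @export
as.data.frame.lesion_report <- function(x, ...) x$components
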