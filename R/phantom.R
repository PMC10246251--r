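# Synthetic head NCCT phantom: ellipsoidal skull shell around a brain
# cavity, ellipsoidal hyperdense lesions with analytic ground-truth
# volumes, and optional falx/sinus distractors whose HU is deliberately
# inside the hyperdense range so only the anatomical rejection path can
# remove them.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Describe a phantom lesion
#'
#' An ellipsoidal hyperdense lesion, positioned relative to the head
#' centre. Either explicit semi-axes or a target volume (sphere) may be
#' given; the analytic volume `4/3 * pi * a * b * c` is the ground truth
#' recorded for the lesion.
#'
#' @param center_mm offset of the lesion centre from the head centre, in mm
#'   (row = anterior->posterior, col = left->right, slice =
#'   inferior->superior).
#' @param semiaxes_mm ellipsoid semi-axes in mm; or
#' @param volume_cc target volume in cc of a spherical lesion (ignored when
#'   `semiaxes_mm` is given).
#' @param hu lesion attenuation (default 70, acute blood).
#' @return A list describing the lesion, for [phantom_spec()].
#' @export
phantom_lesion <- function(center_mm = c(-18, 14, 0), semiaxes_mm = NULL,
                           volume_cc = NULL, hu = 70) {
  if (is.null(semiaxes_mm)) {
    if (is.null(volume_cc)) stop("give semiaxes_mm or volume_cc")
    r <- (3 * volume_cc * 1000 / (4 * pi))^(1 / 3)
    semiaxes_mm <- c(r, r, r)
  }
  stopifnot(length(center_mm) == 3, length(semiaxes_mm) == 3, all(semiaxes_mm > 0))
  list(center_mm = as.numeric(center_mm), semiaxes_mm = as.numeric(semiaxes_mm),
       hu = hu)
}

#' Phantom specification
#'
#' Defines the synthetic head: grid, HU palette, skull geometry, lesions,
#' distractors, noise and seed. The default HU palette (air -1000, brain
#' 35, lesion 70, distractor 60, skull 1200) sits inside clinically typical
#' ranges and is chosen so that a 15 HU offset above the brain median
#' separates both lesion *and* distractor from parenchyma — distractors are
#' only removable anatomically, exercising the false-positive correction.
#'
#' @param shape head grid (rows, cols, slices), default 192 x 192 x 40.
#' @param spacing_mm voxel spacing, default 1 x 1 x 2.5 mm (a thin-slice
#'   acquisition that the pipeline merges to 5 mm).
#' @param skull_outer_mm outer semi-axes of the skull ellipsoid.
#' @param skull_thickness_mm shell thickness; the brain cavity is the
#'   interior of the inner ellipsoid.
#' @param brain_hu,skull_hu,air_hu,distractor_hu,neck_hu HU palette.
#' @param noise_sigma i.i.d. Gaussian HU noise added inside the head
#'   (default 4; 0 gives a noiseless phantom).
#' @param lesions list of [phantom_lesion()]s; may be empty.
#' @param falx_plate,sinus_blob enable the posterior mid-sagittal falx
#'   plate / posterior dural sinus blob distractors.
#' @param neck_slices sub-cranial soft-tissue slices appended below the
#'   skull base (no enclosing bone), default 0.
#' @param seed RNG seed for the noise field.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(192L, 192L, 40L), spacing_mm = c(1, 1, 2.5),
                         skull_outer_mm = c(85, 70, 46), skull_thickness_mm = 6,
                         brain_hu = 35, skull_hu = 1200, air_hu = -1000,
                         distractor_hu = 60, neck_hu = 40,
                         noise_sigma = 4, lesions = list(),
                         falx_plate = FALSE, sinus_blob = FALSE,
                         neck_slices = 0L, seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 4), length(spacing_mm) == 3,
            all(spacing_mm > 0), skull_thickness_mm > 0, noise_sigma >= 0,
            neck_slices >= 0)
  if (length(lesions) && is.numeric(lesions[[1]])) lesions <- list(lesions)
  for (l in lesions) if (l$hu <= brain_hu) stop("lesion HU must exceed brain HU")
  structure(list(shape = as.integer(shape), spacing_mm = as.numeric(spacing_mm),
                 skull_outer_mm = skull_outer_mm,
                 skull_thickness_mm = skull_thickness_mm,
                 brain_hu = brain_hu, skull_hu = skull_hu, air_hu = air_hu,
                 distractor_hu = distractor_hu, neck_hu = neck_hu,
                 noise_sigma = noise_sigma, lesions = lesions,
                 falx_plate = falx_plate, sinus_blob = sinus_blob,
                 neck_slices = as.integer(neck_slices), seed = as.integer(seed)),
            class = "phantom_spec")
}

# squared ellipsoid norm over the grid: ((r-c1)/a1)^2 + ... as a 3D array
.ell_norm2 <- function(coords, center, semi) {
  rr <- ((coords$r - center[1]) / semi[1])^2
  cc <- ((coords$c - center[2]) / semi[2])^2
  zz <- ((coords$z - center[3]) / semi[3])^2
  outer(outer(rr, cc, "+"), zz, "+")
}

#' Generate a synthetic head NCCT with ground truth
#'
#' Builds the phantom volume described by a [phantom_spec()] together with
#' its ground truth: per-lesion binary masks and analytic volumes, the
#' distractor mask, and the brain-cavity mask. Deterministic for a fixed
#' seed; noiseless when `noise_sigma = 0`.
#'
#' @param spec a [phantom_spec()].
#' @return List with `volume` (a [ct_volume()]) and `truth` (class
#'   `phantom_truth`: `lesion_masks`, `lesion_analytic_cc`,
#'   `lesion_voxel_cc`, `distractor_mask`, `cavity_mask`, `brain_hu`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing_mm
  nz <- spec$shape[3] + spec$neck_slices
  d <- c(spec$shape[1:2], nz)
  coords <- list(r = (seq_len(d[1]) - 0.5) * sp[1],
                 c = (seq_len(d[2]) - 0.5) * sp[2],
                 z = (seq_len(nz) - 0.5) * sp[3])
  center <- c(d[1] * sp[1] / 2, d[2] * sp[2] / 2,
              (spec$neck_slices + spec$shape[3] / 2) * sp[3])
  outer_semi <- spec$skull_outer_mm
  inner_semi <- outer_semi - spec$skull_thickness_mm

  e_out <- .ell_norm2(coords, center, outer_semi)
  e_in <- .ell_norm2(coords, center, inner_semi)
  head <- e_out <= 1
  cavity <- e_in <= 1

  vox <- array(spec$air_hu, d)
  vox[head] <- spec$skull_hu
  vox[cavity] <- spec$brain_hu

  if (spec$neck_slices > 0) {
    rr <- ((coords$r - center[1]) / 60)^2
    cc <- ((coords$c - center[2]) / 50)^2
    disk <- outer(rr, cc, "+") <= 1
    for (k in seq_len(spec$neck_slices)) {
      sl <- vox[, , k]
      sl[disk & sl == spec$air_hu] <- spec$neck_hu
      vox[, , k] <- sl
    }
  }

  distract <- array(FALSE, d)
  roff <- outer(outer(coords$r - center[1], rep(1, d[2])), rep(1, nz))
  coff <- outer(outer(rep(1, d[1]), coords$c - center[2]), rep(1, nz))
  zoff <- outer(outer(rep(1, d[1]), rep(1, d[2])), coords$z - center[3])
  if (spec$falx_plate)
    distract <- distract | (cavity & e_in <= 0.97 &
                              abs(coff) <= max(0.75, 0.55 * sp[2]) &
                              roff >= 8 & zoff >= -12)
  if (spec$sinus_blob)
    distract <- distract | (cavity & e_in >= 0.925 &
                              roff >= 0.6 * inner_semi[1] &
                              abs(coff) <= 9 & abs(zoff) <= 8)
  vox[distract] <- spec$distractor_hu

  lesion_masks <- list()
  analytic <- voxelcc <- numeric(length(spec$lesions))
  occupied <- distract
  for (i in seq_along(spec$lesions)) {
    l <- spec$lesions[[i]]
    el <- .ell_norm2(coords, center + l$center_mm, l$semiaxes_mm)
    m <- el <= 1
    if (any(m & !cavity))
      stop(sprintf("lesion %d protrudes outside the brain interior", i))
    if (any(m & occupied))
      stop(sprintf("lesion %d overlaps another lesion or a distractor", i))
    occupied <- occupied | m
    vox[m] <- l$hu
    lesion_masks[[i]] <- seg_mask(m, spacing = sp)
    analytic[i] <- 4 / 3 * pi * prod(l$semiaxes_mm) / 1000
    voxelcc[i] <- volume_cc(lesion_masks[[i]])
  }

  if (spec$noise_sigma > 0) {
    idx <- which(head | cavity)
    noise <- with_seed(spec$seed, stats::rnorm(length(idx), 0, spec$noise_sigma))
    vox[idx] <- vox[idx] + noise
  }

  truth <- structure(list(
    lesion_masks = lesion_masks,
    lesion_analytic_cc = analytic,
    lesion_voxel_cc = voxelcc,
    distractor_mask = seg_mask(distract, spacing = sp),
    cavity_mask = seg_mask(cavity, spacing = sp),
    brain_hu = spec$brain_hu
  ), class = "phantom_truth")

  list(volume = ct_volume(vox, spacing = sp,
                          meta = list(source = "synthetic head phantom",
                                      seed = spec$seed,
                                      original_thickness_mm = sp[3])),
       truth = truth)
}

#' Generate a baseline / follow-up phantom pair
#'
#' Same head geometry and noise model in both members (independent noise
#' draws); the single lesion is rescaled isotropically so its analytic
#' volume hits `followup_volume_cc`. The ground-truth expansion call is
#' computed from the analytic volumes with [compare_serial()].
#'
#' @param spec a [phantom_spec()] with exactly one lesion (the baseline).
#' @param followup_volume_cc analytic lesion volume of the follow-up, cc.
#' @param seed seed for the follow-up noise field (baseline uses
#'   `spec$seed`).
#' @return List with `baseline`, `followup` (each as from
#'   [generate_phantom()]) and `truth_comparison` (a `serial_comparison`).
#' @export
generate_serial_pair <- function(spec, followup_volume_cc, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spec$lesions) != 1)
    stop("serial pair generation needs a spec with exactly one lesion")
  base_cc <- 4 / 3 * pi * prod(spec$lesions[[1]]$semiaxes_mm) / 1000
  if (base_cc < 1 || followup_volume_cc < 1)
    stop("both volumes must be at least 1 cc")
  f <- (followup_volume_cc / base_cc)^(1 / 3)
  fspec <- spec
  fspec$lesions[[1]]$semiaxes_mm <- spec$lesions[[1]]$semiaxes_mm * f
  fspec$seed <- as.integer(seed)
  list(baseline = generate_phantom(spec),
       followup = generate_phantom(fspec),
       truth_comparison = compare_serial(base_cc, followup_volume_cc))
}

#' Simulate a serial-imaging cohort with known expansion labels
#'
#' Draws `n` baseline volumes log-uniformly in `baseline_range_cc` and
#' assigns exactly `round(n * growth_fraction)` of them true expansion.
#' Growth cases satisfy both HE criteria with margin (relative increase
#' 50-90\% and absolute increase at least 8 cc); non-growth cases change by
#' at most 10\% relative and 2 cc absolute, violating both criteria with
#' margin. Fully reproducible from `seed`.
#'
#' @param n number of baseline/follow-up pairs.
#' @param growth_fraction fraction of pairs with true expansion.
#' @param seed RNG seed.
#' @param baseline_range_cc range of baseline volumes (default 2-60 cc).
#' @param csv optional path; when given the cohort table is also written as
#'   CSV.
#' @return Data frame with `id`, `baseline_cc`, `followup_cc` (analytic
#'   truth volumes), `he_true` and `pair_seed`.
#' @export
simulate_cohort <- function(n, growth_fraction = 0.25, seed = 1L,
                            baseline_range_cc = c(2, 60), csv = NULL) {
  stopifnot(n >= 1, growth_fraction >= 0, growth_fraction <= 1)
  m <- round(n * growth_fraction)
  df <- with_seed(seed, {
    grow <- sample(rep(c(TRUE, FALSE), c(m, n - m)))
    b <- exp(stats::runif(n, log(baseline_range_cc[1]), log(baseline_range_cc[2])))
    f <- numeric(n)
    pct_g <- stats::runif(n, 50, 90)
    pct_s <- stats::runif(n, -10, 10)
    for (i in seq_len(n)) {
      f[i] <- if (grow[i]) b[i] + max(8, b[i] * pct_g[i] / 100)
      else b[i] + max(-2, min(2, b[i] * pct_s[i] / 100))
    }
    data.frame(id = sprintf("case%03d", seq_len(n)),
               baseline_cc = b, followup_cc = f, he_true = grow,
               pair_seed = seed + 7L * seq_len(n))
  })
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE)
  df
}

#' Run the detection pipeline over a simulated cohort
#'
#' For every cohort row a baseline/follow-up phantom pair is generated,
#' [detect_ich()] measures both volumes, [classify_cohort()] applies the
#' conjunction rule to the measured volumes, and the calls are scored
#' against the ground-truth labels.
#'
#' @param cohort a data frame from [simulate_cohort()].
#' @param masking a [masking_params()].
#' @param detection a [detection_params()].
#' @param noise_sigma phantom noise level (default 4 HU).
#' @param distractors add falx and sinus distractors to every phantom
#'   (default TRUE).
#' @return List: `cohort` (with measured volumes and calls appended),
#'   `confusion` (a [confusion_table()]) and `summary` (a
#'   `diagnostic_summary`).
#' @export
evaluate_cohort <- function(cohort, masking = masking_params(),
                            detection = detection_params(),
                            noise_sigma = 4, distractors = TRUE) {
  need <- c("id", "baseline_cc", "followup_cc", "he_true", "pair_seed")
  stopifnot(all(need %in% names(cohort)))
  n <- nrow(cohort)
  meas_b <- meas_f <- numeric(n)
  for (i in seq_len(n)) {
    spec <- phantom_spec(
      lesions = list(phantom_lesion(volume_cc = cohort$baseline_cc[i])),
      noise_sigma = noise_sigma,
      falx_plate = distractors, sinus_blob = distractors,
      seed = cohort$pair_seed[i])
    pair <- generate_serial_pair(spec, cohort$followup_cc[i],
                                 seed = cohort$pair_seed[i] + 1L)
    meas_b[i] <- detect_ich(pair$baseline$volume, masking, detection)$total_volume_cc
    meas_f[i] <- detect_ich(pair$followup$volume, masking, detection)$total_volume_cc
  }
  out <- cohort
  out$measured_baseline_cc <- meas_b
  out$measured_followup_cc <- meas_f
  calls <- classify_cohort(data.frame(id = out$id, baseline_cc = meas_b,
                                      followup_cc = meas_f))
  out$he_detected <- calls$he_positive
  tab <- build_confusion(out$he_true, out$he_detected)
  list(cohort = out, confusion = tab, summary = summarize_diagnostics(tab))
}
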