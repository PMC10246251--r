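# Minimal DICOM Part-10 reader for axial CT series.
#
# Scope: uncompressed Explicit VR Little Endian (transfer syntax
# 1.2.840.10008.1.2.1), single-frame monochrome slices, 16-bit stored pixels
# — the form CT scanners export and the only one this package consumes.
# Only the tags a CT slice needs are interpreted; everything else is skipped
# by length. Compressed or implicit-VR files are rejected with a clear error
# rather than mis-read.

DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# VRs that use the 12-byte header (2 reserved + 4-byte length)
.long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

.u16 <- function(raw) readBin(raw, "integer", size = 2, endian = "little", signed = FALSE)
.u32 <- function(raw) readBin(raw, "integer", size = 4, endian = "little")

# parse one element at offset `pos` (1-based) of raw vector `b`
.read_element <- function(b, pos) {
  group <- .u16(b[pos:(pos + 1)])
  elem  <- .u16(b[(pos + 2):(pos + 3)])
  vr    <- rawToChar(b[(pos + 4):(pos + 5)])
  if (vr %in% .long_vrs) {
    len <- .u32(b[(pos + 8):(pos + 11)])
    data_at <- pos + 12
  } else if (grepl("^[A-Z]{2}$", vr)) {
    len <- .u16(b[(pos + 6):(pos + 7)])
    data_at <- pos + 8
  } else {
    stop("not an Explicit VR Little Endian DICOM element (implicit VR or corrupt file)")
  }
  if (len < 0) stop("undefined-length DICOM element not supported")
  list(group = group, elem = elem, vr = vr, length = len,
       data = if (len > 0) b[data_at:(data_at + len - 1)] else raw(0),
       next_pos = data_at + len)
}

.el_string <- function(el) {
  d <- el$data
  # strip trailing padding (space or nul) before conversion
  while (length(d) && d[length(d)] %in% as.raw(c(0L, 32L))) d <- d[-length(d)]
  rawToChar(d)
}
.el_numeric <- function(el) as.numeric(strsplit(.el_string(el), "\\\\")[[1]])
.el_us <- function(el) .u16(el$data[1:2])

# read one DICOM file, returning the tags of interest
read_dicom_file <- function(path) {
  b <- readBin(path, "raw", n = file.info(path)$size)
  if (length(b) < 132 || rawToChar(b[129:132]) != "DICM")
    stop(sprintf("%s: not a DICOM Part-10 file (missing DICM marker)", path))
  pos <- 133
  tags <- list()
  transfer_syntax <- NULL
  while (pos + 7 <= length(b)) {
    el <- .read_element(b, pos)
    pos <- el$next_pos
    key <- sprintf("%04x,%04x", el$group, el$elem)
    if (key == "0002,0010") transfer_syntax <- .el_string(el)
    tags[[key]] <- el
    if (key == "7fe0,0010") break
  }
  if (!is.null(transfer_syntax) && transfer_syntax != DICOM_EXPLICIT_LE)
    stop(sprintf("%s: unsupported transfer syntax %s (only Explicit VR Little Endian is read)",
                 path, transfer_syntax))
  get_str <- function(key) if (!is.null(tags[[key]])) .el_string(tags[[key]]) else NULL
  get_num <- function(key) if (!is.null(tags[[key]])) .el_numeric(tags[[key]]) else NULL
  get_us  <- function(key) if (!is.null(tags[[key]])) .el_us(tags[[key]]) else NULL

  modality <- get_str("0008,0060")
  rows <- get_us("0028,0010"); cols <- get_us("0028,0011")
  bits <- get_us("0028,0100")
  pixrep <- get_us("0028,0103")
  if (is.null(rows) || is.null(cols) || is.null(tags[["7fe0,0010"]]))
    stop(sprintf("%s: missing Rows/Columns/PixelData", path))
  if (!is.null(bits) && bits != 16L)
    stop(sprintf("%s: only 16-bit stored pixels supported (BitsAllocated=%d)", path, bits))
  px <- readBin(tags[["7fe0,0010"]]$data, "integer", n = as.integer(rows) * cols,
                size = 2, endian = "little",
                signed = !is.null(pixrep) && pixrep == 1L)
  list(
    modality = modality,
    rows = rows, cols = cols,
    pixel_spacing = get_num("0028,0030"),         # (row_mm, col_mm)
    slice_thickness = get_num("0018,0050"),
    position = get_num("0020,0032"),              # ImagePositionPatient (x,y,z)
    orientation = get_num("0020,0037"),           # ImageOrientationPatient
    rescale_intercept = get_num("0028,1052"),
    rescale_slope = get_num("0028,1053"),
    gantry_tilt = get_num("0018,1120"),
    # DICOM PixelData is row-major (fastest index = column)
    pixels = matrix(px, nrow = rows, ncol = cols, byrow = TRUE)
  )
}

# Assemble an axial ct_volume from a directory of DICOM slices.
# Slices are sorted by z position ascending (inferior -> superior), which
# normalises the in-memory slice order regardless of file naming.
read_dicom_series <- function(path, spacing_tolerance = 0.05) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop(sprintf("no files in DICOM directory %s", path))
  slices <- lapply(files, read_dicom_file)

  mod <- unique(vapply(slices, function(s) s$modality %||% "UNKNOWN", ""))
  if (!all(mod == "CT"))
    stop(sprintf("non-HU modality in series: %s (expected CT)",
                 paste(setdiff(mod, "CT"), collapse = ", ")))
  ori <- unique(vapply(slices, function(s)
    paste(signif(s$orientation %||% c(1, 0, 0, 0, 1, 0), 6), collapse = ","), ""))
  if (length(ori) > 1) stop("DICOM series mixes image orientations")

  z <- vapply(slices, function(s) (s$position %||% c(0, 0, NA_real_))[3], 0)
  if (anyNA(z)) stop("DICOM slice without ImagePositionPatient")
  if (anyDuplicated(round(z, 6)))
    stop(sprintf("duplicate slice positions at z = %s mm",
                 paste(unique(round(z[duplicated(round(z, 6))], 3)), collapse = ", ")))
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]

  if (length(z) > 1) {
    dz <- diff(z)
    if (any(dz <= 0)) stop("non-increasing slice positions after sort")
    if ((max(dz) - min(dz)) / stats::median(dz) > spacing_tolerance) {
      gap_at <- which.max(dz)
      stop(sprintf("non-uniform slice spacing beyond %.0f%% tolerance; largest gap %.3f mm between z = %.3f and %.3f",
                   100 * spacing_tolerance, max(dz), z[gap_at], z[gap_at + 1]))
    }
    slice_mm <- stats::median(dz)
  } else {
    slice_mm <- slices[[1]]$slice_thickness %||% 1
  }

  s1 <- slices[[1]]
  ps <- s1$pixel_spacing %||% c(1, 1)
  slope <- s1$rescale_slope %||% 1
  icpt <- s1$rescale_intercept %||% 0
  vox <- array(0, c(s1$rows, s1$cols, length(slices)))
  for (k in seq_along(slices)) {
    sk <- slices[[k]]
    if (sk$rows != s1$rows || sk$cols != s1$cols)
      stop("DICOM slices differ in matrix size")
    vox[, , k] <- (sk$rescale_slope %||% 1) * sk$pixels + (sk$rescale_intercept %||% 0)
  }
  ct_volume(vox, spacing = c(ps[1], ps[2], slice_mm),
            meta = list(source = path, format = "dicom_series",
                        original_thickness_mm = slice_mm,
                        rescale = c(slope = slope, intercept = icpt),
                        gantry_tilt_deg = s1$gantry_tilt %||% 0,
                        n_slices = length(slices)))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
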