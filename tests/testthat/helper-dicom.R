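# Minimal Explicit VR Little Endian DICOM writer for test fixtures.
# Generates standards-shaped CT slices programmatically at test time.

.dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.dcm_element <- function(group, elem, vr, data) {
  if (is.character(data)) {
    data <- charToRaw(data)
    if (length(data) %% 2 == 1)
      data <- c(data, if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  hdr <- c(.dcm_u16(group), .dcm_u16(elem), charToRaw(vr))
  len <- if (vr %in% c("OB", "OW", "SQ", "UN", "UT"))
    c(as.raw(c(0, 0)), .dcm_u32(length(data)))
  else .dcm_u16(length(data))
  c(hdr, len, data)
}

# pixels: integer matrix (rows x cols) of stored values
write_dicom_slice <- function(path, pixels, spacing = c(1, 1), thickness = 5,
                              position = c(0, 0, 0), slope = 1, intercept = -1024,
                              modality = "CT", uid_suffix = "1") {
  storage.mode(pixels) <- "integer"
  px <- writeBin(as.integer(t(pixels)), raw(), size = 2, endian = "little")
  ds <- function(x) paste(format(x, trim = TRUE, scientific = FALSE), collapse = "\\")
  body <- c(
    .dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .dcm_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    .dcm_element(0x0002, 0x0003, "UI", paste0("1.2.826.0.1.999999.", uid_suffix)),
    .dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    .dcm_element(0x0008, 0x0060, "CS", modality),
    .dcm_element(0x0018, 0x0050, "DS", ds(thickness)),
    .dcm_element(0x0020, 0x0032, "DS", ds(position)),
    .dcm_element(0x0020, 0x0037, "DS", ds(c(1, 0, 0, 0, 1, 0))),
    .dcm_element(0x0028, 0x0002, "US", .dcm_u16(1)),
    .dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcm_element(0x0028, 0x0010, "US", .dcm_u16(nrow(pixels))),
    .dcm_element(0x0028, 0x0011, "US", .dcm_u16(ncol(pixels))),
    .dcm_element(0x0028, 0x0030, "DS", ds(spacing)),
    .dcm_element(0x0028, 0x0100, "US", .dcm_u16(16)),
    .dcm_element(0x0028, 0x0101, "US", .dcm_u16(16)),
    .dcm_element(0x0028, 0x0102, "US", .dcm_u16(15)),
    .dcm_element(0x0028, 0x0103, "US", .dcm_u16(1)),
    .dcm_element(0x0028, 0x1052, "DS", ds(intercept)),
    .dcm_element(0x0028, 0x1053, "DS", ds(slope)),
    .dcm_element(0x7fe0, 0x0010, "OW", px)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(body, con)
  invisible(path)
}

# write a small synthetic series: stored[,,k] written one file per slice
write_dicom_series <- function(dir, stored, spacing = c(1, 1), thickness = 5,
                               z0 = 0, slope = 1, intercept = -1024,
                               modality = "CT", names = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- dim(stored)[3]
  if (is.null(names)) names <- sprintf("slice%03d.dcm", seq_len(nz))
  for (k in seq_len(nz))
    write_dicom_slice(file.path(dir, names[k]), stored[, , k],
                      spacing = spacing, thickness = thickness,
                      position = c(0, 0, z0 + (k - 1) * thickness),
                      slope = slope, intercept = intercept,
                      modality = modality, uid_suffix = as.character(k))
  invisible(dir)
}
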