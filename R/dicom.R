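# Minimal DICOM codec for single-frame axial CT series.
#
# Scope is deliberately narrow: explicit-VR little-endian transfer syntax,
# one slice per file, MONOCHROME2, 16-bit stored pixels, axial
# identity-cosine orientation (1\0\0\0\1\0). Anything else is rejected with
# a message. Intensities are stored as int16 with a rescale slope/intercept,
# so integer-HU volumes round-trip bit-exactly.

DICOM_UID_ROOT <- "1.2.826.0.1.3680043.10763."
TRANSFER_SYNTAX_ELE <- "1.2.840.10008.1.2.1" # explicit VR little endian
SOP_CLASS_CT <- "1.2.840.10008.5.1.4.1.1.2"

.uid_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    sprintf("%s%d.%d", DICOM_UID_ROOT, as.integer(Sys.getpid()) %% 100000L, i)
  }
})

.u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32raw <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.pad_even <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

.str_val <- function(s, ui = FALSE) {
  .pad_even(charToRaw(s), pad = if (ui) as.raw(0x00) else as.raw(0x20))
}

.ds_fmt <- function(x) {
  # DS values: up to 16 bytes each; plain formatting without scientific notation
  paste(vapply(x, function(v) {
    s <- formatC(v, format = "fg", digits = 10)
    gsub(" ", "", s)
  }, character(1)), collapse = "\\")
}

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.element <- function(group, elem, vr, value) {
  hdr <- c(.u16raw(group), .u16raw(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(hdr, as.raw(c(0, 0)), .u32raw(length(value)), value)
  } else {
    if (length(value) > 65534L) stop("value too long for short VR")
    c(hdr, .u16raw(length(value)), value)
  }
}

.write_dicom_slice <- function(path, pix_int, rows, cols, spacing_rc, ipp,
                               slope, intercept, instance, series_uid,
                               study_uid) {
  sop_uid <- .uid_counter()
  meta <- c(
    .element(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    .element(0x0002, 0x0002, "UI", .str_val(SOP_CLASS_CT, ui = TRUE)),
    .element(0x0002, 0x0003, "UI", .str_val(sop_uid, ui = TRUE)),
    .element(0x0002, 0x0010, "UI", .str_val(TRANSFER_SYNTAX_ELE, ui = TRUE)),
    .element(0x0002, 0x0012, "UI", .str_val(paste0(DICOM_UID_ROOT, "1"), ui = TRUE))
  )
  pix_raw <- writeBin(as.integer(pix_int), raw(), size = 2, endian = "little")
  body <- c(
    .element(0x0008, 0x0016, "UI", .str_val(SOP_CLASS_CT, ui = TRUE)),
    .element(0x0008, 0x0018, "UI", .str_val(sop_uid, ui = TRUE)),
    .element(0x0008, 0x0060, "CS", .str_val("CT")),
    .element(0x0020, 0x000D, "UI", .str_val(study_uid, ui = TRUE)),
    .element(0x0020, 0x000E, "UI", .str_val(series_uid, ui = TRUE)),
    .element(0x0020, 0x0013, "IS", .str_val(as.character(instance))),
    .element(0x0020, 0x0032, "DS", .str_val(.ds_fmt(ipp))),
    .element(0x0020, 0x0037, "DS", .str_val(.ds_fmt(c(1, 0, 0, 0, 1, 0)))),
    .element(0x0028, 0x0002, "US", .u16raw(1)),
    .element(0x0028, 0x0004, "CS", .str_val("MONOCHROME2")),
    .element(0x0028, 0x0010, "US", .u16raw(rows)),
    .element(0x0028, 0x0011, "US", .u16raw(cols)),
    .element(0x0028, 0x0030, "DS", .str_val(.ds_fmt(spacing_rc))),
    .element(0x0028, 0x0100, "US", .u16raw(16)),
    .element(0x0028, 0x0101, "US", .u16raw(16)),
    .element(0x0028, 0x0102, "US", .u16raw(15)),
    .element(0x0028, 0x0103, "US", .u16raw(1)),
    .element(0x0028, 0x1052, "DS", .str_val(.ds_fmt(intercept))),
    .element(0x0028, 0x1053, "DS", .str_val(.ds_fmt(slope))),
    .element(0x7FE0, 0x0010, "OW", pix_raw)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(.element(0x0002, 0x0000, "UL", .u32raw(length(meta))), con)
  writeBin(meta, con)
  writeBin(body, con)
  invisible(path)
}

#' Write a volume as a DICOM series
#'
#' One explicit-VR little-endian single-frame CT file per axial slice.
#' Stored pixel values are int16 with the given rescale `slope`/`intercept`
#' (HU = slope * stored + intercept); integer-HU volumes round-trip exactly.
#'
#' @param vol a [volume()].
#' @param dir output directory (created if missing).
#' @param slope,intercept rescale mapping from stored values to HU.
#' @return Invisibly, the vector of file paths written.
#' @seealso [read_volume()]
#' @export
write_dicom_series <- function(vol, dir, slope = 1, intercept = -1024) {
  stopifnot(is_volume(vol))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(vol$voxels)
  stored <- round((vol$voxels - intercept) / slope)
  if (min(stored) < -32768 || max(stored) > 32767)
    stop("stored values exceed int16 range; adjust slope/intercept")
  series_uid <- .uid_counter(); study_uid <- .uid_counter()
  paths <- character(d[1])
  for (s in seq_len(d[1])) {
    # pixel data is row-major: all columns of row 1, then row 2, ...
    sl <- stored[s, , ]
    pix <- as.integer(t(sl))
    ipp <- c(vol$origin[1], vol$origin[2],
             vol$origin[3] + (s - 1) * vol$spacing[3])
    paths[s] <- file.path(dir, sprintf("slice_%04d.dcm", s))
    .write_dicom_slice(paths[s], pix, rows = d[2], cols = d[3],
                       spacing_rc = c(vol$spacing[2], vol$spacing[1]),
                       ipp = ipp, slope = slope, intercept = intercept,
                       instance = s, series_uid = series_uid,
                       study_uid = study_uid)
  }
  invisible(paths)
}

.parse_dicom_file <- function(path) {
  r <- readBin(path, raw(), file.info(path)$size)
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop(sprintf("%s: not a DICOM file (missing DICM magic)", basename(path)))
  pos <- 133L
  n <- length(r)
  tags <- list()
  u16 <- function(at) readBin(r[at + 0:1], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(r[at + 0:3], "integer", size = 4,
                              endian = "little")
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(r[pos + 4:5])
    if (!grepl("^[A-Z]{2}$", vr))
      stop(sprintf("%s: implicit VR or unsupported syntax at offset %d",
                   basename(path), pos))
    if (vr %in% LONG_VRS) {
      len <- u32(pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      vstart <- pos + 8L
    }
    if (len < 0)
      stop(sprintf("%s: undefined-length element (%04X,%04X) unsupported",
                   basename(path), group, elem))
    if (vstart + len - 1L > n)
      stop(sprintf("%s: truncated element (%04X,%04X)", basename(path),
                   group, elem))
    key <- sprintf("%04X,%04X", group, elem)
    val <- r[vstart + seq_len(len) - 1L]
    tags[[key]] <- list(vr = vr, raw = val)
    pos <- vstart + len
  }
  tags
}

.tag_str <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  trimws(rawToChar(t$raw[t$raw != as.raw(0)]))
}

.tag_ds <- function(tags, key) {
  s <- .tag_str(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

.tag_us <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  readBin(t$raw, "integer", size = 2, endian = "little", signed = FALSE)
}

#' Read a DICOM series as a volume
#'
#' Reads a directory of single-frame axial CT slices (explicit VR little
#' endian), sorts them by slice position, infers the slice spacing from the
#' inter-slice positions, and rescales stored values to HU via the
#' slope/intercept tags.
#'
#' Mixed series, non-axial orientations, inconsistent in-plane geometry and
#' inconsistent slice spacing (beyond 1% of the median gap) are rejected
#' with a message naming the offending slice.
#'
#' @param path directory containing the `.dcm` files of one series.
#' @return A [volume()].
#' @export
read_volume <- function(path) {
  if (!dir.exists(path)) stop(sprintf("'%s' is not a directory", path))
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) < 2L)
    stop("need at least 2 DICOM slices of one series")
  parsed <- lapply(files, .parse_dicom_file)
  names(parsed) <- basename(files)

  series <- vapply(parsed, .tag_str, character(1), key = "0020,000E")
  if (length(unique(series)) != 1L)
    stop(sprintf("mixed series in directory: %s",
                 paste(unique(series), collapse = ", ")))
  first <- parsed[[1]]
  rows <- .tag_us(first, "0028,0010"); cols <- .tag_us(first, "0028,0011")
  psp <- .tag_ds(first, "0028,0030")
  for (nm in names(parsed)) {
    p <- parsed[[nm]]
    iop <- .tag_ds(p, "0020,0037")
    if (is.null(iop) || max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-6)
      stop(sprintf("%s: only axial identity-cosine orientation is supported", nm))
    if (!identical(.tag_us(p, "0028,0010"), rows) ||
        !identical(.tag_us(p, "0028,0011"), cols))
      stop(sprintf("%s: inconsistent in-plane matrix size", nm))
    if (max(abs(.tag_ds(p, "0028,0030") - psp)) > 1e-6)
      stop(sprintf("%s: inconsistent pixel spacing", nm))
    ba <- .tag_us(p, "0028,0100")
    if (!identical(ba, 16L)) stop(sprintf("%s: only 16-bit pixels supported", nm))
  }
  ipp <- t(vapply(parsed, .tag_ds, numeric(3), key = "0020,0032"))
  ord <- order(ipp[, 3])
  parsed <- parsed[ord]; ipp <- ipp[ord, , drop = FALSE]
  zs <- ipp[, 3]
  dz <- diff(zs)
  if (any(dz <= 0))
    stop("duplicate or non-increasing slice positions in series")
  med <- stats::median(dz)
  bad <- which(abs(dz - med) > 0.01 * med)
  if (length(bad) > 0)
    stop(sprintf(
      "inconsistent slice spacing: gap of %.4g mm after slice '%s' (median %.4g mm)",
      dz[bad[1]], names(parsed)[bad[1]], med))

  vox <- array(0, c(length(parsed), rows, cols))
  for (s in seq_along(parsed)) {
    p <- parsed[[s]]
    slope <- .tag_ds(p, "0028,1053"); intercept <- .tag_ds(p, "0028,1052")
    if (is.null(slope)) slope <- 1
    if (is.null(intercept)) intercept <- 0
    signed <- identical(.tag_us(p, "0028,0103"), 1L)
    pixr <- p[["7FE0,0010"]]
    if (is.null(pixr)) stop(sprintf("slice %d: missing pixel data", s))
    stored <- readBin(pixr$raw, "integer", n = rows * cols, size = 2,
                      endian = "little", signed = signed)
    vox[s, , ] <- t(matrix(slope * stored + intercept, nrow = cols, ncol = rows))
  }
  volume(vox,
         spacing = c(psp[2], psp[1], med),
         origin = c(ipp[1, 1], ipp[1, 2], ipp[1, 3]))
}

#' Write an 8-bit grayscale slice image
#'
#' PNG (lossless, the default for evaluation) or JPG (provided for parity
#' with clinical export pipelines; lossy, so not used for metrics).
#'
#' @param img numeric matrix with values in 0..255.
#' @param path output file path; format chosen by extension (.png or .jpg).
#' @return Invisibly, `path`.
#' @export
write_gray8 <- function(img, path) {
  stopifnot(is.matrix(img))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img / 255, path)
  } else if (ext %in% c("jpg", "jpeg")) {
    grDevices::jpeg(path, width = ncol(img), height = nrow(img),
                    quality = 95)
    op <- graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new()
    graphics::rasterImage(img / 255, 0, 0, 1, 1, interpolate = FALSE)
    graphics::par(op)
    grDevices::dev.off()
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Read an 8-bit grayscale slice image written by [write_gray8()]
#' @param path PNG file path.
#' @return Numeric matrix of integer values in 0..255.
#' @export
read_gray8 <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  round(a * 255)
}
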