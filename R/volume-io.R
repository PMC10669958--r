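# Volume file I/O.
#
# NIfTI goes through RNifti.  NRRD (read/write) and DICOM series (read-only,
# uncompressed explicit/implicit VR little endian) are implemented here because
# no installed R package handles them; both are deliberately minimal and
# validated by round-trip and fixture tests.  NIfTI is the internal
# interchange format; DICOM is never written.

#' Read a 3D volume from disk
#'
#' @param path file (NIfTI/NRRD) or directory (DICOM series)
#' @param format "nifti", "nrrd" or "dicom_series"; default guesses from the
#'   path (directory -> DICOM series, extension otherwise)
#' @return a [VoxelVolume-class] with spacing in mm.  For DICOM series, slices
#'   are sorted along the scan axis and a geometry error is raised when the
#'   slice positions are not uniformly spaced (e.g. a missing slice).
#' @seealso [writeVolume()], [readMask()]
#' @export
readVolume <- function(path, format = c("auto", "nifti", "nrrd", "dicom_series")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_series"
      else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
      else "nifti"
  }
  if (format != "dicom_series" && !file.exists(path))
    stop(sprintf("file not found: %s", path))
  switch(format,
    nifti = .readNiftiVolume(path),
    nrrd = .readNrrd(path),
    dicom_series = .readDicomSeries(path)
  )
}

#' Write a volume or mask to disk
#'
#' Masks are written as integer 0/1 grids.  DICOM output is not supported.
#'
#' @param volume a [VoxelVolume-class] or [BinaryMask-class]
#' @param path output file; extension selects the format (.nii/.nii.gz/.nrrd)
#' @return the path, invisibly
#' @export
writeVolume <- function(volume, path) {
  stopifnot(methods::is(volume, "VoxelVolume"))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    .writeNrrd(volume, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    dat <- volume@data
    if (is.logical(dat)) { dat <- array(as.integer(dat), dim(dat)) }
    img <- RNifti::asNifti(dat)
    RNifti::pixdim(img) <- volume@spacing
    RNifti::writeNifti(img, path)
  } else stop("unsupported output format (use .nii, .nii.gz or .nrrd): ", path)
  invisible(path)
}

#' Read a binary mask
#'
#' Reads a volume and coerces it to a [BinaryMask-class] with \code{!= 0}.
#'
#' @inheritParams readVolume
#' @return a [BinaryMask-class]
#' @export
readMask <- function(path, format = c("auto", "nifti", "nrrd", "dicom_series")) {
  v <- readVolume(path, format)
  BinaryMask(v@data != 0, v@spacing, v@origin)
}

.readNiftiVolume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("cannot read NIfTI '%s': %s",
                                                   path, conditionMessage(e))))
  d <- dim(img)
  if (length(d) > 3L) {
    if (all(d[-(1:3)] == 1L)) d <- d[1:3]
    else stop("expected a 3D NIfTI volume: ", path)
  }
  if (length(d) != 3L) stop("expected a 3D NIfTI volume: ", path)
  dat <- array(as.numeric(img), d)
  sp <- RNifti::pixdim(img)[1:3]
  VoxelVolume(dat, spacing = sp)
}

# ---- NRRD ------------------------------------------------------------------

.writeNrrd <- function(volume, path) {
  d <- dim(volume@data)
  sp <- volume@spacing
  org <- volume@origin
  isMask <- is.logical(volume@data)
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", if (isMask) "uint8" else "double"),
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    "encoding: raw",
    "endian: little",
    "space dimension: 3",
    sprintf("space directions: (%s,0,0) (0,%s,0) (0,0,%s)",
            format(sp[1], digits = 17), format(sp[2], digits = 17),
            format(sp[3], digits = 17)),
    sprintf("space origin: (%s,%s,%s)", format(org[1], digits = 17),
            format(org[2], digits = 17), format(org[3], digits = 17)),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (isMask)
    writeBin(as.integer(volume@data), con, size = 1L, endian = "little")
  else
    writeBin(as.vector(volume@data), con, size = 8L, endian = "little")
  invisible(path)
}

.parseNrrdTuple <- function(s) {
  s <- gsub("[()]", "", s)
  as.numeric(strsplit(trimws(s), "[, ]+")[[1]])
}

.readNrrd <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  # header ends at the first blank line
  nl <- which(raw == as.raw(10L))
  hdrEnd <- NA_integer_
  prev <- 0L
  for (i in nl) {
    lineLen <- i - prev - 1L
    if (lineLen == 0L || (lineLen == 1L && raw[prev + 1L] == as.raw(13L))) {
      hdrEnd <- i; break
    }
    prev <- i
  }
  if (is.na(hdrEnd)) stop(sprintf("corrupt NRRD (no header terminator): %s", path))
  hdrTxt <- rawToChar(raw[seq_len(hdrEnd - 1L)])
  lines <- strsplit(hdrTxt, "\r?\n")[[1]]
  if (!grepl("^NRRD", lines[1])) stop(sprintf("not an NRRD file: %s", path))
  fields <- list()
  for (ln in lines[-1]) {
    if (grepl("^\\s*#", ln) || !grepl(":", ln)) next
    kv <- regmatches(ln, regexpr(":", ln), invert = TRUE)[[1]]
    fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported: ", path)
  type <- tolower(fields[["type"]] %||% "double")
  enc <- tolower(fields[["encoding"]] %||% "raw")
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- vapply(vecs, .parseNrrdTuple, numeric(3))
    spacing <- sqrt(colSums(m^2))
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- .parseNrrdTuple(fields[["space origin"]])
  payload <- raw[(hdrEnd + 1L):length(raw)]
  if (enc == "gzip") payload <- memDecompress(payload, type = "gzip")
  else if (enc != "raw") stop("unsupported NRRD encoding: ", enc)
  n <- prod(sizes)
  typeMap <- list(
    "double" = list(what = "double", size = 8L, signed = TRUE),
    "float"  = list(what = "double", size = 4L, signed = TRUE),
    "uint8"  = list(what = "integer", size = 1L, signed = FALSE),
    "uchar"  = list(what = "integer", size = 1L, signed = FALSE),
    "int16"  = list(what = "integer", size = 2L, signed = TRUE),
    "short"  = list(what = "integer", size = 2L, signed = TRUE),
    "uint16" = list(what = "integer", size = 2L, signed = FALSE),
    "int32"  = list(what = "integer", size = 4L, signed = TRUE),
    "int"    = list(what = "integer", size = 4L, signed = TRUE)
  )
  tm <- typeMap[[type]]
  if (is.null(tm)) stop("unsupported NRRD type: ", type)
  if (length(payload) < n * tm$size)
    stop(sprintf("corrupt NRRD (truncated data): %s", path))
  vals <- readBin(payload, tm$what, n = n, size = tm$size, signed = tm$signed,
                  endian = "little")
  VoxelVolume(array(as.double(vals), sizes), spacing, origin)
}

# ---- DICOM series (read-only, minimal) --------------------------------------

# Parse one DICOM file; returns list(rows, cols, pixelSpacing, ipp, instance,
# pixels).  Supports uncompressed explicit/implicit VR little endian only.
.readDicomFile <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  u16 <- function(off) as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
  u32 <- function(off) as.integer(raw[off + 1L]) + 256 * as.integer(raw[off + 2L]) +
    65536 * as.integer(raw[off + 3L]) + 16777216 * as.integer(raw[off + 4L])
  off <- 0L
  if (length(raw) > 132L && rawToChar(raw[129:132]) == "DICM") off <- 132L
  longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  out <- list()
  explicit <- TRUE            # meta group is always explicit
  metaDone <- FALSE
  transferSyntax <- "1.2.840.10008.1.2.1"
  while (off + 8 <= length(raw)) {
    grp <- u16(off); ele <- u16(off + 2L)
    if (!metaDone && grp != 2L) {
      metaDone <- TRUE
      explicit <- transferSyntax != "1.2.840.10008.1.2"
      if (!transferSyntax %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
        stop(sprintf("unsupported DICOM transfer syntax %s in %s",
                     transferSyntax, path))
    }
    if (explicit || grp == 2L) {
      vr <- rawToChar(raw[(off + 5L):(off + 6L)])
      if (vr %in% longVRs) { len <- u32(off + 8L); hdr <- 12L }
      else { len <- u16(off + 6L); hdr <- 8L }
    } else { vr <- ""; len <- u32(off + 4L); hdr <- 8L }
    if (len == 4294967295) stop(sprintf("unsupported undefined-length element in %s", path))
    valOff <- off + hdr
    if (valOff + len > length(raw)) stop(sprintf("corrupt DICOM file: %s", path))
    val <- raw[seq.int(valOff + 1L, length.out = len)]
    key <- sprintf("%04x,%04x", grp, ele)
    if (key == "0002,0010") transferSyntax <- gsub("\\x00| ", "", rawToChar(val))
    else if (key == "0028,0010") out$rows <- u16(valOff)
    else if (key == "0028,0011") out$cols <- u16(valOff)
    else if (key == "0028,0100") out$bitsAllocated <- u16(valOff)
    else if (key == "0028,0103") out$pixelRepresentation <- u16(valOff)
    else if (key == "0028,0030")
      out$pixelSpacing <- as.numeric(strsplit(rawToChar(val), "\\\\")[[1]])
    else if (key == "0020,0032")
      out$ipp <- as.numeric(strsplit(rawToChar(val), "\\\\")[[1]])
    else if (key == "0020,0013") out$instance <- as.integer(rawToChar(val))
    else if (key == "7fe0,0010") out$pixelRaw <- val
    off <- valOff + len
  }
  for (need in c("rows", "cols", "pixelSpacing", "ipp", "pixelRaw"))
    if (is.null(out[[need]]))
      stop(sprintf("DICOM file %s lacks required element (%s)", path, need))
  bits <- out$bitsAllocated %||% 16L
  if (!bits %in% c(8L, 16L)) stop("unsupported BitsAllocated: ", bits)
  signed <- isTRUE((out$pixelRepresentation %||% 0L) == 1L)
  px <- readBin(out$pixelRaw, "integer", n = out$rows * out$cols,
                size = bits / 8L, signed = if (bits == 8L) FALSE else signed,
                endian = "little")
  # pixel data is row-major (column index fastest); store as (row, col)
  out$pixels <- t(matrix(px, nrow = out$cols, ncol = out$rows))
  out
}

.readDicomSeries <- function(path) {
  if (!dir.exists(path)) stop(sprintf("directory not found: %s", path))
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2L)
    stop(sprintf("DICOM series directory needs at least 2 slices: %s", path))
  slices <- lapply(sort(files), .readDicomFile)
  rows <- unique(vapply(slices, `[[`, 1L, "rows"))
  cols <- unique(vapply(slices, `[[`, 1L, "cols"))
  if (length(rows) != 1L || length(cols) != 1L)
    stop("inconsistent slice dimensions in DICOM series")
  z <- vapply(slices, function(s) s$ipp[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  gaps <- diff(z)
  if (any(gaps <= 0)) stop("geometry error: duplicate slice positions in DICOM series")
  if ((max(gaps) - min(gaps)) > 1e-3 * mean(gaps) + 1e-6)
    stop(sprintf(paste0("geometry error: inconsistent DICOM slice spacing in %s ",
                        "(gaps range %.4f..%.4f mm; missing slice?)"),
                 path, min(gaps), max(gaps)))
  ps <- slices[[1]]$pixelSpacing
  dat <- array(0, c(rows, cols, length(slices)))
  for (i in seq_along(slices)) dat[, , i] <- slices[[i]]$pixels
  VoxelVolume(dat, spacing = c(ps[1], ps[2], mean(gaps)),
              origin = c(slices[[1]]$ipp[1], slices[[1]]$ipp[2], z[1]))
}

# Minimal DICOM slice writer used to build test fixtures (explicit VR little
# endian, uncompressed, 16-bit unsigned).  Internal: fixture plumbing only.
.writeDicomSlice <- function(path, pixels, pixelSpacing = c(1, 1),
                             ipp = c(0, 0, 0), instance = 1L) {
  stopifnot(is.matrix(pixels))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  evenStr <- function(s) { if (nchar(s) %% 2 == 1) paste0(s, " ") else s }
  elem <- function(grp, ele, vr, value) {
    w16(grp); w16(ele)
    if (vr %in% c("OB", "OW")) {
      writeChar(vr, con, eos = NULL); w16(0L); w32(length(value))
      writeBin(value, con)
    } else if (vr %in% c("US",  "SS")) {
      writeChar(vr, con, eos = NULL); w16(2L * length(value)); w16(value)
    } else {
      s <- evenStr(value)
      writeChar(vr, con, eos = NULL); w16(nchar(s)); writeChar(s, con, eos = NULL)
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeChar("DICM", con, eos = NULL)
  # file meta group: group length covers only the transfer-syntax element
  ts <- evenStr("1.2.840.10008.1.2.1")
  metaLen <- 8L + nchar(ts)
  w16(0x0002); w16(0x0000); writeChar("UL", con, eos = NULL); w16(4L); w32(metaLen)
  w16(0x0002); w16(0x0010); writeChar("UI", con, eos = NULL); w16(nchar(ts))
  writeChar(ts, con, eos = NULL)
  # dataset (explicit VR LE)
  elem(0x0020, 0x0013, "IS", as.character(instance))
  elem(0x0020, 0x0032, "DS", paste(format(ipp, digits = 10), collapse = "\\"))
  elem(0x0028, 0x0002, "US", 1L)
  elem(0x0028, 0x0004, "CS", "MONOCHROME2")
  elem(0x0028, 0x0010, "US", nrow(pixels))
  elem(0x0028, 0x0011, "US", ncol(pixels))
  elem(0x0028, 0x0030, "DS", paste(format(pixelSpacing, digits = 10), collapse = "\\"))
  elem(0x0028, 0x0100, "US", 16L)
  elem(0x0028, 0x0101, "US", 16L)
  elem(0x0028, 0x0102, "US", 15L)
  elem(0x0028, 0x0103, "US", 0L)
  px <- as.integer(round(t(pixels)))   # row-major on disk
  w16(0x7fe0); w16(0x0010); writeChar("OW", con, eos = NULL); w16(0L)
  w32(2L * length(px)); w16(px)
  invisible(path)
}
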