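# Minimal DICOM support for axial CT series: explicit- and implicit-VR
# little endian, uncompressed, single-frame 16-bit grayscale slices. This
# covers what the pipeline needs (pixel data, geometry and rescale tags);
# anything else in a file is parsed but ignored.

.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
.SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.padEven <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2L) c(r, pad) else r
}

.strRaw <- function(s, uid = FALSE) {
  .padEven(charToRaw(s), pad = if (uid) as.raw(0x00) else as.raw(0x20))
}

# encode one explicit-VR-LE data element
.dcmElement <- function(group, element, vr, value) {
  body <- switch(vr,
    US = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    UL = .u32(value),
    UI = .strRaw(paste(value, collapse = "\\"), uid = TRUE),
    OW = value,  # already raw
    .strRaw(paste(value, collapse = "\\")))  # DS, IS, CS, LO, SH, PN ...
  hdr <- c(.u16(group), .u16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, as.raw(c(0, 0)), .u32(length(body)), body)
  } else {
    c(hdr, .u16(length(body)), body)
  }
}

.uidCounter <- local({ i <- 0L; function() { i <<- i + 1L; i } })

.makeUID <- function() {
  paste0("2.25.", format(as.numeric(Sys.time()) * 1000, scientific = FALSE,
                          trim = TRUE, digits = 13), ".", .uidCounter(),
         ".", sample.int(.Machine$integer.max, 1))
}

#' Write a CT volume as a DICOM series
#'
#' One explicit-VR little-endian single-frame file per axial slice, with
#' rescale slope 1 and intercept -1024 (stored values are HU + 1024).
#' Intended for phantom export and round-trip testing.
#'
#' @param ct a [CTVolume-class].
#' @param directory output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Invisibly, the vector of file paths written.
#' @export
writeDicomSeries <- function(ct, directory, prefix = "slice") {
  stopifnot(is(ct, "CTVolume"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  v <- voxels(ct)
  d <- dim(v)
  sp <- spacing(ct)
  seriesUID <- .makeUID()
  studyUID <- .makeUID()
  paths <- character(d[3])
  for (z in seq_len(d[3])) {
    sopUID <- .makeUID()
    stored <- as.integer(round(v[, , z])) + 1024L
    stored <- pmin(pmax(stored, -32768L), 32767L)
    # DICOM pixel order is row-major (x varies fastest within a row),
    # which is exactly the column-major order of the [x, y] slice
    pix <- writeBin(stored, raw(), size = 2, endian = "little")
    zpos <- (z - 1) * sp[3]
    meta <- c(
      .dcmElement(0x0002, 0x0002, "UI", .SOP_CT),
      .dcmElement(0x0002, 0x0003, "UI", sopUID),
      .dcmElement(0x0002, 0x0010, "UI", .TS_EXPLICIT_LE))
    meta <- c(.dcmElement(0x0002, 0x0000, "UL", length(meta)), meta)
    ds <- c(
      .dcmElement(0x0008, 0x0016, "UI", .SOP_CT),
      .dcmElement(0x0008, 0x0018, "UI", sopUID),
      .dcmElement(0x0008, 0x0060, "CS", "CT"),
      .dcmElement(0x0020, 0x000D, "UI", studyUID),
      .dcmElement(0x0020, 0x000E, "UI", seriesUID),
      .dcmElement(0x0020, 0x0013, "IS", as.character(z)),
      .dcmElement(0x0020, 0x0032, "DS",
                  c("0", "0", format(zpos, scientific = FALSE))),
      .dcmElement(0x0020, 0x0037, "DS", c("1", "0", "0", "0", "1", "0")),
      .dcmElement(0x0020, 0x1041, "DS", format(zpos, scientific = FALSE)),
      .dcmElement(0x0028, 0x0002, "US", 1L),
      .dcmElement(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dcmElement(0x0028, 0x0010, "US", d[2]),   # Rows = ny
      .dcmElement(0x0028, 0x0011, "US", d[1]),   # Columns = nx
      .dcmElement(0x0028, 0x0030, "DS",
                  c(format(sp[2], scientific = FALSE),
                    format(sp[1], scientific = FALSE))),
      .dcmElement(0x0028, 0x0100, "US", 16L),
      .dcmElement(0x0028, 0x0101, "US", 16L),
      .dcmElement(0x0028, 0x0102, "US", 15L),
      .dcmElement(0x0028, 0x0103, "US", 1L),
      .dcmElement(0x0028, 0x1052, "DS", "-1024"),
      .dcmElement(0x0028, 0x1053, "DS", "1"),
      .dcmElement(0x7FE0, 0x0010, "OW", pix))
    path <- file.path(directory, sprintf("%s_%04d.dcm", prefix, z))
    con <- file(path, "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
    close(con)
    paths[z] <- path
  }
  invisible(paths)
}


.dcmRawToString <- function(r) {
  trimws(rawToChar(r[r != as.raw(0)]), which = "right")
}

# parse one DICOM file into a named list of elements keyed "gggg,eeee"
.parseDicomFile <- function(path) {
  buf <- readBin(path, raw(), n = file.size(path))
  n <- length(buf)
  pos <- 1L
  if (n > 132 && rawToChar(buf[129:132]) == "DICM") pos <- 133L
  rd16 <- function(p) readBin(buf[p:(p + 1L)], "integer", size = 2,
                              endian = "little", signed = FALSE)
  rd32 <- function(p) readBin(buf[p:(p + 3L)], "integer", size = 4,
                              endian = "little")
  elements <- list()
  explicit <- TRUE      # file meta group is always explicit VR
  ts <- .TS_EXPLICIT_LE
  longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n) {
    group <- rd16(pos); element <- rd16(pos + 2L)
    if (group != 0x0002 && !identical(explicit, TRUE) &&
        ts == .TS_IMPLICIT_LE) {
      len <- rd32(pos + 4L)
      vpos <- pos + 8L
      vr <- NA_character_
    } else {
      vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
      if (grepl("^[A-Z]{2}$", vr)) {
        if (vr %in% longVRs) {
          len <- rd32(pos + 8L); vpos <- pos + 12L
        } else {
          len <- rd16(pos + 6L); vpos <- pos + 8L
        }
      } else {          # implicit VR element
        len <- rd32(pos + 4L); vpos <- pos + 8L; vr <- NA_character_
      }
    }
    if (len < 0 || vpos + len - 1L > n)
      stop("corrupt DICOM element in ", path, call. = FALSE)
    key <- sprintf("%04X,%04X", group, element)
    elements[[key]] <- list(vr = vr,
                            raw = if (len > 0) buf[vpos:(vpos + len - 1L)]
                                  else raw(0))
    if (key == "0002,0010") {
      ts <- .dcmRawToString(elements[[key]]$raw)
      if (!ts %in% c(.TS_EXPLICIT_LE, .TS_IMPLICIT_LE))
        stop("unsupported DICOM transfer syntax ", ts, " in ", path,
             call. = FALSE)
      explicit <- ts == .TS_EXPLICIT_LE
    }
    pos <- vpos + len
  }
  elements
}

.dcmString <- function(el, key) {
  e <- el[[key]]
  if (is.null(e)) return(NULL)
  strsplit(.dcmRawToString(e$raw), "\\", fixed = TRUE)[[1]]
}

.dcmNumeric <- function(el, key) {
  s <- .dcmString(el, key)
  if (is.null(s)) NULL else as.numeric(s)
}

.dcmUS <- function(el, key) {
  e <- el[[key]]
  if (is.null(e)) return(NULL)
  readBin(e$raw, "integer", n = length(e$raw) / 2L, size = 2,
          endian = "little", signed = FALSE)
}

#' Read an axial DICOM series into a CT volume
#'
#' Reads every parseable DICOM file in \code{directory}, checks that they
#' belong to a single series, sorts slices by axial position ascending,
#' converts stored values to Hounsfield units via the rescale slope and
#' intercept, and assembles the (x, y, z) voxel grid. Slice spacing is the
#' mean inter-slice distance; non-uniformity beyond 10\% of the mean is a
#' hard error.
#'
#' @param directory directory containing one series (>= 2 axial slices).
#' @return A [CTVolume-class].
#' @export
readDicomSeries <- function(directory) {
  if (!dir.exists(directory))
    stop("no such DICOM directory: ", directory, call. = FALSE)
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  parsed <- list()
  for (f in files) {
    el <- tryCatch(.parseDicomFile(f), error = function(e) NULL)
    if (!is.null(el) && !is.null(el[["7FE0,0010"]])) parsed[[f]] <- el
  }
  if (length(parsed) < 2L)
    stop("directory ", directory,
         " does not contain a DICOM series (need >= 2 image slices)",
         call. = FALSE)
  series <- vapply(parsed, function(el) {
    s <- .dcmString(el, "0020,000E"); if (is.null(s)) "" else s[1]
  }, character(1))
  if (length(unique(series)) > 1L)
    stop("ambiguous DICOM content in ", directory,
         ": multiple series present (", paste(unique(series), collapse = ", "),
         ")", call. = FALSE)
  zpos <- vapply(parsed, function(el) {
    p <- .dcmNumeric(el, "0020,0032")
    if (!is.null(p) && length(p) >= 3) return(p[3])
    p <- .dcmNumeric(el, "0020,1041")
    if (!is.null(p)) return(p[1])
    p <- .dcmNumeric(el, "0020,0013")
    if (!is.null(p)) return(p[1])
    NA_real_
  }, numeric(1))
  if (anyNA(zpos))
    stop("DICOM slices in ", directory, " lack axial position tags",
         call. = FALSE)
  ord <- order(zpos)
  parsed <- parsed[ord]; zpos <- zpos[ord]
  dz <- diff(zpos)
  if (any(dz <= 0))
    stop("duplicate or non-monotone slice positions in ", directory,
         call. = FALSE)
  if (max(abs(dz - mean(dz))) > 0.1 * mean(dz))
    stop("non-uniform slice spacing beyond 10% tolerance in ", directory,
         call. = FALSE)
  first <- parsed[[1]]
  rows <- .dcmUS(first, "0028,0010")
  cols <- .dcmUS(first, "0028,0011")
  ps <- .dcmNumeric(first, "0028,0030")   # (row spacing = dy, col spacing = dx)
  if (is.null(rows) || is.null(cols) || is.null(ps))
    stop("DICOM series in ", directory, " lacks image geometry tags",
         call. = FALSE)
  vol <- array(0, dim = c(cols, rows, length(parsed)))
  for (i in seq_along(parsed)) {
    el <- parsed[[i]]
    bits <- .dcmUS(el, "0028,0100"); if (is.null(bits)) bits <- 16L
    if (bits != 16L)
      stop("unsupported BitsAllocated ", bits, " in ", directory,
           call. = FALSE)
    signed <- identical(.dcmUS(el, "0028,0103"), 1L)
    slope <- .dcmNumeric(el, "0028,1053"); if (is.null(slope)) slope <- 1
    inter <- .dcmNumeric(el, "0028,1052"); if (is.null(inter)) inter <- 0
    pr <- el[["7FE0,0010"]]$raw
    stored <- readBin(pr, "integer", n = length(pr) / 2L, size = 2,
                      endian = "little", signed = signed)
    if (length(stored) != rows * cols)
      stop("pixel data size mismatch in ", directory, call. = FALSE)
    # row-major stored order: the first `cols` values form image row 1
    # (y = 1) varying x, so filling an nx-row matrix gives [x, y]
    vol[, , i] <- matrix(stored * slope + inter, nrow = cols)
  }
  vol <- pmin(pmax(vol, -1024), 3071)
  CTVolume(vol, spacing = c(ps[2], ps[1], mean(dz)))
}
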