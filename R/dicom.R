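# Minimal DICOM PET series support.
#
# No DICOM library exists in the deployment R stack, so a small parser for
# the subset of DICOM part 10 needed here is implemented directly:
# uncompressed little-endian transfer syntaxes (explicit 1.2.840.10008.1.2.1
# and implicit 1.2.840.10008.1.2), single-frame slices, defined- or
# undefined-length sequences. Series whose Units are BQML (activity
# concentration, Bq/ml) are converted to body-weight SUV using
# PatientWeight, RadionuclideTotalDose and the injection-to-series delay.
# A matching writer (used by the test suite to build synthetic series) emits
# conformant explicit-VR little-endian files.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"

dcm_tag <- function(group, elem) sprintf("%04X%04X", group, elem)

DCM_LONG_VR <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse one element stream [pos, end) into a named list tag -> list(vr, bytes)
# or, for SQ, tag -> list of item datasets. Positions are 0-based offsets.
parse_dicom_elements <- function(bytes, pos, end, implicit) {
  out <- list()
  u16 <- function(p) {
    readBin(bytes[(p + 1):(p + 2)], "integer", size = 2L, signed = FALSE,
            endian = "little")
  }
  u32 <- function(p) {
    v <- readBin(bytes[(p + 1):(p + 4)], "integer", size = 4L, endian = "little")
    if (v < 0) v + 4294967296 else v
  }
  while (pos + 8 <= end) {
    group <- u16(pos); elem <- u16(pos + 2)
    tag <- dcm_tag(group, elem)
    if (group == 0xFFFE) {  # item/sequence delimiters at this level: stop
      break
    }
    if (implicit) {
      vr <- if (tag == "7FE00010") "OW" else "UN"
      len <- u32(pos + 4)
      pos <- pos + 8
    } else {
      vr <- rawToChar(bytes[(pos + 5):(pos + 6)])
      if (vr %in% DCM_LONG_VR) {
        len <- u32(pos + 8)
        pos <- pos + 12
      } else {
        len <- u16(pos + 6)
        pos <- pos + 8
      }
    }
    if (vr == "SQ" || (implicit && len == 4294967295)) {
      sq <- parse_dicom_sequence(bytes, pos, len, end, implicit)
      out[[tag]] <- list(vr = "SQ", items = sq$items)
      pos <- sq$pos
    } else {
      if (len == 4294967295) stop("undefined length outside SQ unsupported", call. = FALSE)
      val <- if (len > 0) bytes[(pos + 1):(pos + len)] else raw(0)
      out[[tag]] <- list(vr = vr, bytes = val)
      pos <- pos + len
    }
  }
  list(elements = out, pos = pos)
}

parse_dicom_sequence <- function(bytes, pos, len, end, implicit) {
  u16 <- function(p) readBin(bytes[(p + 1):(p + 2)], "integer", size = 2L,
                             signed = FALSE, endian = "little")
  u32 <- function(p) {
    v <- readBin(bytes[(p + 1):(p + 4)], "integer", size = 4L, endian = "little")
    if (v < 0) v + 4294967296 else v
  }
  sq_end <- if (len == 4294967295) end else pos + len
  items <- list()
  while (pos + 8 <= sq_end) {
    g <- u16(pos); e <- u16(pos + 2); ilen <- u32(pos + 4)
    pos <- pos + 8
    if (g == 0xFFFE && e == 0xE0DD) break          # sequence delimiter
    if (!(g == 0xFFFE && e == 0xE000)) stop("malformed DICOM sequence", call. = FALSE)
    item_end <- if (ilen == 4294967295) sq_end else pos + ilen
    parsed <- parse_dicom_elements(bytes, pos, item_end, implicit)
    items[[length(items) + 1L]] <- parsed$elements
    pos <- parsed$pos
    if (ilen == 4294967295) {                       # item delimiter
      g <- u16(pos); e <- u16(pos + 2)
      if (g == 0xFFFE && e == 0xE00D) pos <- pos + 8
    }
  }
  list(items = items, pos = pos)
}

dcm_string <- function(el) {
  if (is.null(el)) return(NA_character_)
  trimws(rawToChar(el$bytes), whitespace = "[ \\0\t\r\n]")
}
dcm_numeric <- function(el) {
  s <- dcm_string(el)
  if (is.na(s) || !nzchar(s)) return(NA_real_)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dcm_uint16 <- function(el) {
  if (is.null(el)) return(NA_integer_)
  readBin(el$bytes, "integer", size = 2L, signed = FALSE, endian = "little")
}
# DICOM TM "HHMMSS(.frac)" -> seconds after midnight
dcm_time_s <- function(el) {
  s <- dcm_string(el)
  if (is.na(s) || nchar(s) < 6) return(NA_real_)
  as.numeric(substr(s, 1, 2)) * 3600 + as.numeric(substr(s, 3, 4)) * 60 +
    as.numeric(substr(s, 5, nchar(s)))
}

parse_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 132 || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  }
  # file meta group (always explicit VR little endian)
  meta <- parse_dicom_meta(bytes, 132)
  ts <- meta$transfer_syntax
  implicit <- identical(ts, TS_IMPLICIT_LE)
  if (!implicit && !identical(ts, TS_EXPLICIT_LE)) {
    stop("unsupported transfer syntax ", ts, " in ", path, call. = FALSE)
  }
  parse_dicom_elements(bytes, meta$pos, length(bytes), implicit)$elements
}

parse_dicom_meta <- function(bytes, pos) {
  u16 <- function(p) readBin(bytes[(p + 1):(p + 2)], "integer", size = 2L,
                             signed = FALSE, endian = "little")
  ts <- NA_character_
  while (pos + 8 <= length(bytes)) {
    group <- u16(pos)
    if (group != 0x0002) break
    elem <- u16(pos + 2)
    vr <- rawToChar(bytes[(pos + 5):(pos + 6)])
    if (vr %in% DCM_LONG_VR) {
      len <- readBin(bytes[(pos + 9):(pos + 12)], "integer", size = 4L,
                     endian = "little")
      pos <- pos + 12
    } else {
      len <- u16(pos + 6)
      pos <- pos + 8
    }
    if (elem == 0x0010) {
      ts <- trimws(rawToChar(bytes[(pos + 1):(pos + len)]),
                   whitespace = "[ \\0]")
    }
    pos <- pos + len
  }
  list(transfer_syntax = ts, pos = pos)
}

#' Read a DICOM PET series directory as an SUV volume
#'
#' All part-10 files directly inside `path` must belong to one series
#' (identical SeriesInstanceUID). Slices are sorted by the Image Position
#' (Patient) coordinate along the slice axis. If Units is `BQML`, voxels are
#' converted to body-weight SUV using PatientWeight, RadionuclideTotalDose
#' and the delay between RadiopharmaceuticalStartTime and SeriesTime; if
#' Units already denote SUV (`GML`), values are passed through.
#'
#' @param path Directory containing exactly one DICOM PET series.
#' @return An [suv_volume()] in SUV units.
#' @export
read_dicom_series <- function(path) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("ambiguous input: no files in ", path, call. = FALSE)
  slices <- lapply(files, parse_dicom_file)

  uids <- vapply(slices, function(el) dcm_string(el[["0020000E"]]), character(1))
  if (length(unique(uids)) != 1L || any(is.na(uids))) {
    stop("ambiguous input: directory holds more than one series", call. = FALSE)
  }

  first <- slices[[1]]
  nr <- dcm_uint16(first[["00280010"]])
  nc <- dcm_uint16(first[["00280011"]])
  pix_sp <- dcm_numeric(first[["00280030"]])     # row spacing, col spacing (mm)
  units <- dcm_string(first[["00541001"]])

  ipp <- t(vapply(slices, function(el) dcm_numeric(el[["00200032"]]), numeric(3)))
  z <- ipp[, 3]
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  if (length(z) > 1) {
    dz <- diff(z)
    if (any(dz <= 0) || (max(dz) - min(dz)) > 1e-3 * max(abs(dz))) {
      stop("inconsistent geometry: non-uniform or duplicate slice positions",
           call. = FALSE)
    }
    dz <- mean(dz)
  } else {
    dz <- dcm_numeric(first[["00180050"]])
    if (is.na(dz)) dz <- 1
  }

  vox <- array(0, dim = c(nr, nc, length(slices)))
  for (k in seq_along(slices)) {
    el <- slices[[k]]
    bits <- dcm_uint16(el[["00280100"]])
    if (!identical(bits, 16L)) stop("only 16-bit pixel data supported", call. = FALSE)
    signed <- identical(dcm_uint16(el[["00280103"]]), 1L)
    slope <- dcm_numeric(el[["00281053"]]); if (is.na(slope)) slope <- 1
    inter <- dcm_numeric(el[["00281052"]]); if (is.na(inter)) inter <- 0
    pd <- el[["7FE00010"]]
    if (is.null(pd)) stop("missing pixel data in slice ", k, call. = FALSE)
    raw_px <- readBin(pd$bytes, "integer", n = nr * nc, size = 2L,
                      signed = signed, endian = "little")
    # DICOM pixel order is row-major (rows of the image); store as [row, col]
    vox[, , k] <- matrix(raw_px * slope + inter, nrow = nr, ncol = nc, byrow = TRUE)
  }

  meta <- dicom_patient_meta(slices[[1]])
  volume <- suv_volume(vox,
                       spacing = c(pix_sp[1], pix_sp[2], dz),
                       origin = c(ipp[ord[1], 1], ipp[ord[1], 2], z[1]),
                       meta = meta)

  if (identical(units, "BQML")) {
    if (is.na(meta$weight_kg) || is.na(meta$injected_activity_MBq) ||
        is.na(meta$uptake_time_min)) {
      stop("metadata incomplete: BQML series lacks weight/dose/time for SUV",
           call. = FALSE)
    }
    # Bq/ml -> kBq/ml, then body-weight SUV
    volume$voxels <- volume$voxels / 1000
    volume <- apply_suv_conversion(volume)
  }
  volume
}

dicom_patient_meta <- function(el) {
  weight <- dcm_numeric(el[["00101030"]])
  dose_Bq <- NA_real_
  inj_time <- NA_real_
  rps <- el[["00540016"]]
  if (!is.null(rps) && length(rps$items) >= 1) {
    item <- rps$items[[1]]
    dose_Bq <- dcm_numeric(item[["00181074"]])
    inj_time <- dcm_time_s(item[["00181072"]])
  }
  series_time <- dcm_time_s(el[["00080031"]])
  uptake_min <- if (is.na(series_time) || is.na(inj_time)) NA_real_
                else (series_time - inj_time) / 60
  patient_meta(
    weight_kg = weight,
    injected_activity_MBq = dose_Bq / 1e6,
    uptake_time_min = uptake_min
  )
}

# ---- writer (synthetic series; used by tests and phantom export) ----------

# little-endian uint16/uint32 emitters (tag groups like 0xFFFE exceed the
# signed int16 range writeBin would accept)
u16le <- function(x) {
  x <- as.integer(x)
  as.raw(rbind(bitwAnd(x, 255L), bitwShiftR(x, 8L)))
}
u32le <- function(x) {
  x <- as.integer(x)
  as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L),
           bitwAnd(bitwShiftR(x, 16L), 255L), bitwAnd(bitwShiftR(x, 24L), 255L)))
}

dcm_el_str <- function(group, elem, vr, value) {
  bytes <- charToRaw(value)
  if (length(bytes) %% 2 == 1) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    bytes <- c(bytes, pad)
  }
  c(u16le(c(group, elem)), charToRaw(vr), u16le(length(bytes)), bytes)
}

dcm_el_us <- function(group, elem, value) {
  c(u16le(c(group, elem)), charToRaw("US"), u16le(2L), u16le(value))
}

dcm_el_long <- function(group, elem, vr, bytes) {
  c(u16le(c(group, elem)), charToRaw(vr), raw(2L), u32le(length(bytes)), bytes)
}

# Write one synthetic PET slice (explicit VR little endian, int16 pixels).
# Used to build test fixtures and synthetic series; not a general exporter.
write_dicom_slice <- function(path, pixels, slice_z, pixel_spacing,
                              slice_thickness, series_uid, instance,
                              units = "BQML", rescale_slope = 1,
                              rescale_intercept = 0, weight_kg = NA,
                              dose_Bq = NA, injection_time = "100000",
                              series_time = "110000") {
  stopifnot(is.matrix(pixels))
  px <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  if (any(px < -32768 | px > 32767)) stop("pixel values exceed int16", call. = FALSE)

  ds <- c(
    dcm_el_str(0x0008, 0x0031, "TM", series_time),
    dcm_el_str(0x0008, 0x0060, "CS", "PT"),
    if (!is.na(weight_kg)) dcm_el_str(0x0010, 0x1030, "DS", format(weight_kg)),
    dcm_radiopharm_sq(dose_Bq, injection_time),
    dcm_el_str(0x0020, 0x000E, "UI", series_uid),
    dcm_el_str(0x0020, 0x0032, "DS",
               sprintf("0\\0\\%s", format(slice_z))),
    dcm_el_str(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
    dcm_el_str(0x0018, 0x0050, "DS", format(slice_thickness)),
    dcm_el_us(0x0028, 0x0010, nrow(pixels)),
    dcm_el_us(0x0028, 0x0011, ncol(pixels)),
    dcm_el_str(0x0028, 0x0030, "DS",
               sprintf("%s\\%s", format(pixel_spacing[1]), format(pixel_spacing[2]))),
    dcm_el_us(0x0028, 0x0100, 16L),
    dcm_el_us(0x0028, 0x0101, 16L),
    dcm_el_us(0x0028, 0x0102, 15L),
    dcm_el_us(0x0028, 0x0103, 1L),
    dcm_el_str(0x0028, 0x1052, "DS", format(rescale_intercept)),
    dcm_el_str(0x0028, 0x1053, "DS", format(rescale_slope)),
    dcm_el_str(0x0054, 0x1001, "CS", units),
    dcm_el_long(0x7FE0, 0x0010, "OW",
                u16le(bitwAnd(as.integer(t(px)), 65535L)))
  )

  sop_uid <- sprintf("%s.%d", series_uid, instance)
  meta_body <- c(
    dcm_el_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.128"),
    dcm_el_str(0x0002, 0x0003, "UI", sop_uid),
    dcm_el_str(0x0002, 0x0010, "UI", TS_EXPLICIT_LE)
  )
  meta <- c(
    u16le(c(0x0002, 0x0000)), charToRaw("UL"), u16le(4L),
    u32le(length(meta_body)),
    meta_body
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

dcm_radiopharm_sq <- function(dose_Bq, injection_time) {
  if (is.na(dose_Bq)) return(raw(0))
  item_body <- c(
    dcm_el_str(0x0018, 0x1072, "TM", injection_time),
    dcm_el_str(0x0018, 0x1074, "DS", format(dose_Bq, scientific = FALSE))
  )
  item <- c(u16le(c(0xFFFE, 0xE000)), u32le(length(item_body)), item_body)
  dcm_el_long(0x0054, 0x0016, "SQ", item)
}
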