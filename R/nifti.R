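# Minimal NIfTI-1 reader/writer.
#
# The deployment environment ships no R NIfTI package, so the single-file
# NIfTI-1 format is implemented directly: 348-byte header, optional gzip,
# little/big endian detection via sizeof_hdr, scl_slope/scl_inter scaling.
# Geometry handling is deliberately simple: volumes are treated as
# axis-aligned (spacing from pixdim, origin from the sform/qform offsets);
# rotation matrices are not applied. Files are written as float64 with an
# axis-aligned sform so that write -> read round-trips are bit-exact.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path, ignore.case = TRUE)) gzfile(path, mode)
  else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param meta Optional [patient_meta()] to attach.
#' @return An [suv_volume()]. Voxel values are scaled by the header's
#'   `scl_slope`/`scl_inter` when present.
#' @export
read_nifti <- function(path, meta = patient_meta()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))

  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("not a NIfTI-1 file (short header)", call. = FALSE)
  endian <- "little"
  if (readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian) != 348L) {
    endian <- "big"
    if (readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian) != 348L) {
      stop("not a NIfTI-1 file (bad sizeof_hdr)", call. = FALSE)
    }
  }
  rd_i16 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 2 * n)],
                                     "integer", n = n, size = 2L, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                     "double", n = n, size = 4L, endian = endian)

  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic)", call. = FALSE)
  if (magic == "ni1") stop("detached .hdr/.img NIfTI pairs are not supported", call. = FALSE)

  dims <- rd_i16(40L, 8L)
  ndim <- dims[1]
  if (ndim < 3L) stop("expected a 3-D volume, got ", ndim, "-D", call. = FALSE)
  d <- dims[2:4]
  extra <- if (ndim > 3L) prod(pmax(dims[5:(1 + ndim)], 1L)) else 1L
  if (extra != 1L) stop("4-D+ NIfTI volumes are not supported", call. = FALSE)

  datatype <- rd_i16(70L, 1L)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype, call. = FALSE)

  pixdim <- rd_f32(76L, 8L)
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  qform_code <- rd_i16(252L, 1L)
  sform_code <- rd_i16(254L, 1L)
  qoffset <- rd_f32(268L, 3L)
  srow <- rbind(rd_f32(280L, 4L), rd_f32(296L, 4L), rd_f32(312L, 4L))

  spacing <- abs(pixdim[2:4])
  if (any(spacing <= 0)) stop("inconsistent geometry: non-positive pixdim", call. = FALSE)
  origin <- if (sform_code > 0L) srow[, 4] else if (qform_code > 0L) qoffset else c(0, 0, 0)

  # skip from end of header to start of data
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)

  n_vox <- prod(d)
  vox <- readBin(con, dt$what, n = n_vox, size = dt$size,
                 signed = dt$signed, endian = endian)
  if (length(vox) != n_vox) stop("truncated NIfTI data", call. = FALSE)
  vox <- as.double(vox)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vox <- vox * scl_slope + scl_inter
  }
  suv_volume(array(vox, dim = d), spacing = spacing, origin = origin, meta = meta)
}

#' Write a volume as NIfTI-1
#'
#' Writes `.nii` or `.nii.gz` (chosen by extension) as float64 with an
#' axis-aligned sform, so that reading the file back reproduces voxel values
#' and spacing exactly.
#'
#' @param volume An [suv_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "suv_volume"))
  d <- dim(volume$voxels)
  sp <- volume$spacing
  or <- volume$origin

  con <- tryCatch(nifti_connection(path, "wb"),
                  error = function(e) stop("io error: cannot open ", path, call. = FALSE))
  on.exit(close(con))

  wr_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wr_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wr_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wr_raw <- function(n) writeBin(raw(n), con)

  wr_i32(348L)                      # sizeof_hdr
  wr_raw(36L)                       # data_type, db_name, extents, session_error, regular, dim_info
  wr_i16(c(3L, d, 1L, 1L, 1L, 1L))  # dim
  wr_f32(c(0, 0, 0))                # intent_p1..p3
  wr_i16(0L)                        # intent_code
  wr_i16(64L)                       # datatype: float64
  wr_i16(64L)                       # bitpix
  wr_i16(0L)                        # slice_start
  wr_f32(c(1, sp, 1, 1, 1, 1))      # pixdim (qfac = 1)
  wr_f32(352)                       # vox_offset
  wr_f32(1)                         # scl_slope
  wr_f32(0)                         # scl_inter
  wr_i16(0L); wr_raw(1L); wr_raw(1L)  # slice_end, slice_code, xyzt_units
  wr_f32(c(0, 0, 0))                # cal_max, cal_min, slice_duration
  wr_f32(0)                         # toffset
  wr_i32(c(0L, 0L))                 # glmax, glmin
  wr_raw(80L)                       # descrip
  wr_raw(24L)                       # aux_file
  wr_i16(1L)                        # qform_code
  wr_i16(1L)                        # sform_code
  wr_f32(c(0, 0, 0))                # quatern_b, c, d (identity rotation)
  wr_f32(or)                        # qoffset_x, y, z
  wr_f32(c(sp[1], 0, 0, or[1]))     # srow_x
  wr_f32(c(0, sp[2], 0, or[2]))     # srow_y
  wr_f32(c(0, 0, sp[3], or[3]))     # srow_z
  wr_raw(16L)                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  wr_raw(4L)                        # extension flag

  writeBin(as.double(volume$voxels), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a PET volume from disk
#'
#' Dispatches on `format_hint`, or guesses from the path: a directory is
#' read as a DICOM series, a `.nii`/`.nii.gz` file as NIfTI. DICOM series
#' storing activity concentration (Units `BQML`) are converted to
#' body-weight SUV from header metadata.
#'
#' @param path A NIfTI file or a directory holding one DICOM PET series.
#' @param format_hint `"auto"`, `"nifti"`, or `"dicom_series"`.
#' @param meta Optional [patient_meta()] overriding/augmenting file metadata
#'   (NIfTI only; DICOM metadata comes from the headers).
#' @return An [suv_volume()] in SUV units.
#' @export
read_volume <- function(path, format_hint = c("auto", "nifti", "dicom_series"),
                        meta = patient_meta()) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  if (format_hint == "auto") {
    format_hint <- if (dir.exists(path)) "dicom_series" else "nifti"
  }
  switch(format_hint,
    nifti = read_nifti(path, meta = meta),
    dicom_series = read_dicom_series(path)
  )
}

#' Write a volume to disk
#'
#' @param volume An [suv_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) write_nifti(volume, path)
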