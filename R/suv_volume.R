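#' Patient and acquisition metadata
#'
#' Container for the per-study metadata that travels with an [suv_volume()]:
#' what is needed for body-weight SUV conversion plus the acquisition labels
#' (bed time, reconstruction) used to key cohort tables.
#'
#' @param weight_kg Patient body weight in kg (`> 0` when SUV conversion is
#'   requested).
#' @param injected_activity_MBq Injected tracer activity in MBq at injection
#'   time.
#' @param uptake_time_min Delay between injection and acquisition in minutes.
#' @param bed_time_s Acquisition time per bed position in seconds (label).
#' @param recon_label Free-text reconstruction identifier, e.g.
#'   `"Q.Clear 450"`.
#' @return An object of class `patient_meta` (a named list).
#' @export
patient_meta <- function(weight_kg = NA_real_,
                         injected_activity_MBq = NA_real_,
                         uptake_time_min = NA_real_,
                         bed_time_s = NA_real_,
                         recon_label = NA_character_) {
  structure(
    list(
      weight_kg = as.numeric(weight_kg),
      injected_activity_MBq = as.numeric(injected_activity_MBq),
      uptake_time_min = as.numeric(uptake_time_min),
      bed_time_s = as.numeric(bed_time_s),
      recon_label = as.character(recon_label)
    ),
    class = "patient_meta"
  )
}

#' PET SUV volume
#'
#' A 3-D scalar grid in SUV units together with its geometry. The third
#' array index runs over transversal (axial) slices: `voxels[, , k]` is one
#' axial plane. World coordinates are in mm at voxel centers,
#' `x = origin + (index - 1) * spacing` with 1-based voxel indices.
#'
#' @param voxels Numeric 3-D array of SUV values; all values must be finite.
#'   Negative values (possible in reconstructed PET) are allowed and kept.
#' @param spacing Numeric length-3 vector `(dx, dy, dz)` in mm, all `> 0`.
#' @param origin Numeric length-3 vector, world position (mm) of voxel
#'   `[1, 1, 1]`.
#' @param meta A [patient_meta()] object.
#' @return An object of class `suv_volume`.
#' @export
suv_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       meta = patient_meta()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3-D array", call. = FALSE)
  }
  storage.mode(voxels) <- "double"
  if (!all(is.finite(voxels))) {
    stop("all voxel values must be finite", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive values (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  }
  if (!inherits(meta, "patient_meta")) {
    stop("`meta` must be a patient_meta object", call. = FALSE)
  }
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin, meta = meta),
    class = "suv_volume"
  )
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "suv_volume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf(
    "  SUV range [%.4g, %.4g]", min(x$voxels), max(x$voxels)
  ))
  if (!is.na(x$meta$recon_label)) cat(sprintf(", recon %s", x$meta$recon_label))
  if (!is.na(x$meta$bed_time_s)) cat(sprintf(", bed time %g s", x$meta$bed_time_s))
  cat("\n")
  invisible(x)
}

#' @export
dim.suv_volume <- function(x) dim(x$voxels)

#' Number of axial slices of a volume
#' @param volume An [suv_volume()].
#' @return Integer slice count.
#' @export
n_slices <- function(volume) {
  stopifnot(inherits(volume, "suv_volume"))
  dim(volume$voxels)[3]
}

# world coordinate (mm) of 1-based voxel index along one axis
voxel_to_world <- function(index, origin, spacing) origin + (index - 1) * spacing

# 1-based fractional voxel index of a world coordinate (mm)
world_to_voxel <- function(x_mm, origin, spacing) (x_mm - origin) / spacing + 1
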