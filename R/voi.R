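#' Cubic VOI noise measurement
#'
#' The manual reference measurement: mean and pixel-wise sample standard
#' deviation of the SUV values inside a cubic volume of interest of fixed
#' physical edge length (default 2 x 2 x 2 cm) placed at an explicit world
#' coordinate, e.g. in the right liver lobe or lung parenchyma. A voxel
#' belongs to the VOI when its center falls inside the closed cube
#' `center +/- edge/2` on every axis.
#'
#' @param volume An [suv_volume()].
#' @param center_mm Numeric length-3 world coordinate (mm) of the cube
#'   center.
#' @param edge_mm Physical edge length in mm (default 20).
#' @param organ_label Free-text label carried into the result (e.g.
#'   `"liver"`).
#' @return An object of class `voi_measurement`: `center_mm`, `edge_mm`,
#'   `n_voxels`, `mean_suv`, `sd_suv`, `organ_label`.
#' @export
cubic_voi_noise <- function(volume, center_mm, edge_mm = 20,
                            organ_label = NA_character_) {
  stopifnot(inherits(volume, "suv_volume"))
  center_mm <- as.numeric(center_mm)
  if (length(center_mm) != 3L || any(!is.finite(center_mm))) {
    stop("`center_mm` must be 3 finite coordinates (mm)", call. = FALSE)
  }
  if (!is.finite(edge_mm) || edge_mm <= 0) {
    stop("`edge_mm` must be positive", call. = FALSE)
  }
  d <- dim(volume$voxels)
  half <- edge_mm / 2
  lo <- center_mm - half
  hi <- center_mm + half
  # volume extent at voxel centers
  ext_lo <- volume$origin
  ext_hi <- voxel_to_world(d, volume$origin, volume$spacing)
  if (any(lo < ext_lo - 1e-9) || any(hi > ext_hi + 1e-9)) {
    stop("VOI out of bounds", call. = FALSE)
  }

  idx <- lapply(1:3, function(a) {
    i <- seq_len(d[a])
    x <- voxel_to_world(i, volume$origin[a], volume$spacing[a])
    i[x >= lo[a] & x <= hi[a]]
  })
  n <- prod(lengths(idx))
  if (n < 2L) stop("degenerate VOI: fewer than 2 voxels", call. = FALSE)
  vals <- volume$voxels[idx[[1]], idx[[2]], idx[[3]]]
  structure(
    list(
      center_mm = center_mm,
      edge_mm = edge_mm,
      n_voxels = as.integer(n),
      mean_suv = mean(vals),
      sd_suv = block_sd(vals),
      organ_label = organ_label
    ),
    class = "voi_measurement"
  )
}

#' @export
print.voi_measurement <- function(x, ...) {
  cat(sprintf(
    "VOI %s: mean %.4g, SD %.4g SUV (%d voxels, %g mm cube at [%g, %g, %g])\n",
    ifelse(is.na(x$organ_label), "", x$organ_label), x$mean_suv, x$sd_suv,
    x$n_voxels, x$edge_mm, x$center_mm[1], x$center_mm[2], x$center_mm[3]
  ))
  invisible(x)
}

#' Batch VOI measurements from a placement table
#'
#' Runs [cubic_voi_noise()] for every row of a placement table as read from
#' CSV (columns: `study_id`, `organ`, `x_mm`, `y_mm`, `z_mm`, optional
#' `edge_mm`).
#'
#' @param volume An [suv_volume()].
#' @param placements data.frame with the columns above.
#' @param default_edge_mm Edge used when the table has no `edge_mm` column.
#' @return data.frame with `study_id`, `organ`, placement, `n_voxels`,
#'   `mean_suv`, `sd_suv`.
#' @export
voi_batch <- function(volume, placements, default_edge_mm = 20) {
  need <- c("study_id", "organ", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(placements))) {
    stop("schema error: placement table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  edge <- if ("edge_mm" %in% names(placements)) placements$edge_mm
          else rep(default_edge_mm, nrow(placements))
  res <- lapply(seq_len(nrow(placements)), function(i) {
    v <- cubic_voi_noise(
      volume,
      center_mm = c(placements$x_mm[i], placements$y_mm[i], placements$z_mm[i]),
      edge_mm = edge[i],
      organ_label = placements$organ[i]
    )
    data.frame(
      study_id = placements$study_id[i], organ = placements$organ[i],
      x_mm = placements$x_mm[i], y_mm = placements$y_mm[i],
      z_mm = placements$z_mm[i], edge_mm = edge[i],
      n_voxels = v$n_voxels, mean_suv = v$mean_suv, sd_suv = v$sd_suv
    )
  })
  do.call(rbind, res)
}
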