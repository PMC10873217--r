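#' Otsu threshold for tissue/background separation
#'
#' Classic two-class Otsu threshold on a 256-bin histogram of the voxel
#' values, offered as an automatic alternative to the fixed SUV threshold.
#'
#' @param values Numeric vector or array of SUV values.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold value (between-class variance maximizer).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- counts / sum(counts)
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  mt <- cm[n_bins]
  # between-class variance for split after each bin; on the plateau an
  # empty gap between modes produces, take the middle split
  denom <- cw * (1 - cw)
  bcv <- ifelse(denom > 0, (mt * cw - cm)^2 / denom, 0)
  bcv <- bcv[-n_bins]
  at_max <- which(bcv >= max(bcv) - 1e-12 * max(bcv))
  k <- at_max[ceiling(length(at_max) / 2)]
  breaks[k + 1L]
}

#' Segment patient tissue by thresholding
#'
#' Classifies voxels with SUV strictly above `threshold` as patient tissue,
#' slice by slice. Optionally the mask of each axial slice is restricted to
#' its largest 4-connected component (removing detached noise specks and
#' e.g. injection-site artifacts outside the body) and interior holes --
#' low-uptake regions fully enclosed by tissue, such as lung -- are filled.
#' Both refinements are on by default.
#'
#' @param volume An [suv_volume()].
#' @param threshold SUV threshold (`>= 0`), or `"otsu"` for an automatic
#'   threshold computed from the whole volume. Default `0.15`.
#' @param largest_component Keep only the largest connected component per
#'   slice (default `TRUE`).
#' @param fill_holes Fill enclosed background holes per slice (default
#'   `TRUE`).
#' @return An object of class `tissue_mask`: list with `mask` (logical array
#'   congruent with the volume), `threshold_used`, `morphology_applied`, and
#'   `empty` (`TRUE`, with a `"no tissue found"` warning, if no voxel
#'   qualifies anywhere).
#' @export
tissue_mask <- function(volume, threshold = 0.15, largest_component = TRUE,
                        fill_holes = TRUE) {
  stopifnot(inherits(volume, "suv_volume"))
  if (identical(threshold, "otsu")) {
    threshold <- otsu_threshold(volume$voxels)
  }
  threshold <- as.numeric(threshold)
  if (!is.finite(threshold) || threshold < 0) {
    stop("`threshold` must be a non-negative SUV value", call. = FALSE)
  }

  mask <- volume$voxels > threshold
  nz <- dim(mask)[3]
  for (k in seq_len(nz)) {
    sl <- mask[, , k]
    if (!any(sl)) next
    if (largest_component) {
      lab <- .label_cc_2d(sl)
      sizes <- tabulate(lab[lab > 0L])
      sl <- lab == which.max(sizes)
    }
    if (fill_holes) {
      sl <- fill_holes_2d(sl)
    }
    mask[, , k] <- sl
  }

  empty <- !any(mask)
  if (empty) warning("no tissue found", call. = FALSE)
  structure(
    list(
      mask = mask,
      threshold_used = threshold,
      morphology_applied = c(largest_component = largest_component,
                             fill_holes = fill_holes),
      empty = empty
    ),
    class = "tissue_mask"
  )
}

# Fill background components that do not touch the slice border.
fill_holes_2d <- function(slice_mask) {
  bg <- .label_cc_2d(!slice_mask)
  if (max(bg) == 0L) return(slice_mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0L]
  hole <- bg > 0L & !(bg %in% border)
  slice_mask | hole
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf(
    "tissue_mask: %s voxels in mask (threshold %.4g, largest_component=%s, fill_holes=%s)\n",
    format(sum(x$mask), big.mark = ","), x$threshold_used,
    x$morphology_applied[["largest_component"]],
    x$morphology_applied[["fill_holes"]]
  ))
  invisible(x)
}
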