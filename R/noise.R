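#' Sample standard deviation of a block of SUV values
#'
#' The noise of a region is defined as the sample standard deviation
#' (denominator `n - 1`) of its voxel values.
#'
#' @param values Numeric vector with at least 2 values.
#' @return Non-negative scalar SD.
#' @export
block_sd <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("degenerate block: need at least 2 values", call. = FALSE)
  m <- sum(values) / n
  sqrt(sum((values - m)^2) / (n - 1))
}

#' Macro-pixel noise map of one axial slice
#'
#' Reduces a slice to a lower matrix size by tiling it with non-overlapping
#' `block_size` x `block_size` blocks anchored at the top-left corner
#' (trailing partial rows/columns are dropped). Each resulting macro pixel
#' holds the sample SD of the in-mask pixels of its block -- the local image
#' noise. A macro pixel is valid only if at least `min_valid_fraction` of
#' its block lies inside the tissue mask (and at least 2 pixels, so an SD
#' exists); invalid macro pixels are flagged and excluded downstream.
#'
#' @param slice Numeric matrix, one axial SUV plane.
#' @param mask_slice Logical matrix congruent with `slice`.
#' @param block_size Pixels per macro-pixel side (default 8, i.e. 64 pixels
#'   per macro pixel).
#' @param min_valid_fraction Minimum fraction of in-mask pixels per block
#'   (default 0.5).
#' @param slice_index Optional slice position recorded in the result.
#' @return An object of class `noise_map`: `values` (matrix, `NA` where
#'   invalid), `valid` (logical matrix), `block_size`, `slice_index`.
#' @export
slice_noise_map <- function(slice, mask_slice, block_size = 8L,
                            min_valid_fraction = 0.5, slice_index = NA_integer_) {
  if (!is.matrix(slice) || !is.matrix(mask_slice) ||
      !identical(dim(slice), dim(mask_slice))) {
    stop("`slice` and `mask_slice` must be congruent matrices", call. = FALSE)
  }
  block_size <- as.integer(block_size)
  if (block_size < 2L) stop("`block_size` must be >= 2", call. = FALSE)
  if (any(dim(slice) < block_size)) {
    stop("slice too small: smaller than one block", call. = FALSE)
  }
  if (min_valid_fraction <= 0 || min_valid_fraction > 1) {
    stop("`min_valid_fraction` must be in (0, 1]", call. = FALSE)
  }

  nbr <- nrow(slice) %/% block_size
  nbc <- ncol(slice) %/% block_size
  vals <- matrix(NA_real_, nbr, nbc)
  valid <- matrix(FALSE, nbr, nbc)
  need <- min_valid_fraction * block_size^2

  for (bj in seq_len(nbc)) {
    cols <- ((bj - 1L) * block_size + 1L):(bj * block_size)
    for (bi in seq_len(nbr)) {
      rows <- ((bi - 1L) * block_size + 1L):(bi * block_size)
      m <- mask_slice[rows, cols]
      n_in <- sum(m)
      if (n_in >= need && n_in >= 2L) {
        vals[bi, bj] <- block_sd(slice[rows, cols][m])
        valid[bi, bj] <- TRUE
      }
    }
  }
  structure(
    list(values = vals, valid = valid, block_size = block_size,
         slice_index = slice_index),
    class = "noise_map"
  )
}

#' Pool macro-pixel noise values into a whole-volume histogram
#'
#' All valid macro-pixel values from every slice's noise map are pooled into
#' one histogram with uniform left-closed right-open bins
#' `[k*w, (k+1)*w)` starting at 0. On whole-body data the distribution is
#' typically right-skewed: most macro pixels cover homogeneous tissue (low
#' SD) while the few blocks straddling anatomical borders carry very high
#' SDs.
#'
#' @param maps A list of [slice_noise_map()] results (or a single one).
#' @param bin_width Histogram bin width in SUV (default 0.01).
#' @return An object of class `noise_histogram`: `bin_width`, `bin_edges`,
#'   `counts`, `n_total`.
#' @export
noise_histogram <- function(maps, bin_width = 0.01) {
  if (inherits(maps, "noise_map")) maps <- list(maps)
  if (!is.finite(bin_width) || bin_width <= 0) {
    stop("`bin_width` must be positive", call. = FALSE)
  }
  vals <- unlist(lapply(maps, function(nm) nm$values[nm$valid]), use.names = FALSE)
  if (length(vals) == 0L) stop("no noise samples", call. = FALSE)

  idx <- floor(vals / bin_width) + 1L   # left-closed right-open bins from 0
  n_bins <- max(idx)
  counts <- tabulate(idx, nbins = n_bins)
  structure(
    list(
      bin_width = bin_width,
      bin_edges = bin_width * (0:n_bins),
      counts = counts,
      n_total = length(vals)
    ),
    class = "noise_histogram"
  )
}

#' Mode of a noise histogram
#'
#' Returns the center of the bin with the maximal count; on ties the lowest
#' such bin wins. Applied to the whole-volume noise histogram this mode is
#' the Global Noise Index.
#'
#' @param hist A [noise_histogram()].
#' @return Scalar SUV value (bin center).
#' @export
histogram_mode <- function(hist) {
  stopifnot(inherits(hist, "noise_histogram"))
  if (hist$n_total < 1L) stop("no noise samples", call. = FALSE)
  i <- which.max(hist$counts)          # first maximum = lowest tied bin
  (hist$bin_edges[i] + hist$bin_edges[i + 1L]) / 2
}

#' Global Noise Index of a PET SUV volume
#'
#' The full automated noise pipeline: threshold-based tissue mask, per-slice
#' macro-pixel noise maps (sample SD over 8x8 pixel blocks), pooled
#' whole-volume noise histogram, and its mode -- a single global surrogate
#' of image noise across the whole imaging volume.
#'
#' @param volume An [suv_volume()].
#' @param threshold Tissue SUV threshold or `"otsu"` (see [tissue_mask()]).
#' @param block_size Macro-pixel block edge in pixels (default 8).
#' @param bin_width Histogram bin width in SUV (default 0.01).
#' @param min_valid_fraction Minimum in-mask fraction per block (default 0.5).
#' @param largest_component,fill_holes Mask refinement flags, see
#'   [tissue_mask()].
#' @param mask Optional precomputed [tissue_mask()] (skips segmentation).
#' @return An object of class `gni_result`: `gni`, `histogram`, `n_slices`,
#'   `n_macro_pixels`, `params`.
#' @examples
#' spec <- phantom_spec(grid_size = c(64, 64, 24), sigma_ref = 0.2)
#' vol <- make_phantom(spec, bed_time_s = 120, seed = 1)$volume
#' global_noise_index(vol)$gni
#' @export
global_noise_index <- function(volume, threshold = 0.15, block_size = 8L,
                               bin_width = 0.01, min_valid_fraction = 0.5,
                               largest_component = TRUE, fill_holes = TRUE,
                               mask = NULL) {
  stopifnot(inherits(volume, "suv_volume"))
  if (is.null(mask)) {
    mask <- tissue_mask(volume, threshold = threshold,
                        largest_component = largest_component,
                        fill_holes = fill_holes)
  }
  stopifnot(inherits(mask, "tissue_mask"))
  maps <- volume_noise_maps(volume, mask, block_size = block_size,
                            min_valid_fraction = min_valid_fraction)
  hist <- noise_histogram(maps, bin_width = bin_width)
  structure(
    list(
      gni = histogram_mode(hist),
      histogram = hist,
      n_slices = n_slices(volume),
      n_macro_pixels = hist$n_total,
      params = list(
        threshold = mask$threshold_used,
        block_size = as.integer(block_size),
        bin_width = bin_width,
        min_valid_fraction = min_valid_fraction,
        largest_component = unname(mask$morphology_applied["largest_component"]),
        fill_holes = unname(mask$morphology_applied["fill_holes"])
      )
    ),
    class = "gni_result"
  )
}

#' Noise maps for every slice of a volume
#'
#' @param volume An [suv_volume()].
#' @param mask A [tissue_mask()].
#' @inheritParams slice_noise_map
#' @return List of [slice_noise_map()] objects, one per axial slice.
#' @export
volume_noise_maps <- function(volume, mask, block_size = 8L,
                              min_valid_fraction = 0.5) {
  nz <- n_slices(volume)
  lapply(seq_len(nz), function(k) {
    slice_noise_map(volume$voxels[, , k], mask$mask[, , k],
                    block_size = block_size,
                    min_valid_fraction = min_valid_fraction,
                    slice_index = k)
  })
}

#' Slice-wise Global Noise Index
#'
#' Computes the GNI per axial slice (or per slab of consecutive slices),
#' i.e. the mode of the histogram built from that slab's valid macro pixels
#' only. This exposes the axial noise profile and lets specific anatomical
#' regions be analyzed via slice ranges. Slabs without any valid macro pixel
#' are `NA`.
#'
#' @inheritParams global_noise_index
#' @param slab_thickness Number of consecutive slices pooled per value
#'   (default 1).
#' @return An object of class `slice_gni_series`: `gni` (numeric vector,
#'   `NA` where undefined), `slab_start`, `slab_end`, `params`.
#' @export
slicewise_gni <- function(volume, threshold = 0.15, block_size = 8L,
                          bin_width = 0.01, min_valid_fraction = 0.5,
                          largest_component = TRUE, fill_holes = TRUE,
                          slab_thickness = 1L, mask = NULL) {
  stopifnot(inherits(volume, "suv_volume"))
  slab_thickness <- as.integer(slab_thickness)
  if (slab_thickness < 1L) stop("`slab_thickness` must be >= 1", call. = FALSE)
  if (is.null(mask)) {
    mask <- tissue_mask(volume, threshold = threshold,
                        largest_component = largest_component,
                        fill_holes = fill_holes)
  }
  maps <- volume_noise_maps(volume, mask, block_size = block_size,
                            min_valid_fraction = min_valid_fraction)
  nz <- n_slices(volume)
  starts <- seq(1L, nz, by = slab_thickness)
  ends <- pmin(starts + slab_thickness - 1L, nz)
  gni <- vapply(seq_along(starts), function(i) {
    slab <- maps[starts[i]:ends[i]]
    if (sum(vapply(slab, function(nm) sum(nm$valid), integer(1))) == 0L) {
      return(NA_real_)
    }
    histogram_mode(noise_histogram(slab, bin_width = bin_width))
  }, numeric(1))
  structure(
    list(gni = gni, slab_start = starts, slab_end = ends,
         params = list(threshold = mask$threshold_used,
                       block_size = as.integer(block_size),
                       bin_width = bin_width,
                       min_valid_fraction = min_valid_fraction,
                       slab_thickness = slab_thickness)),
    class = "slice_gni_series"
  )
}

#' @export
print.gni_result <- function(x, ...) {
  cat(sprintf(
    "Global Noise Index: %.4g SUV (%d macro pixels over %d slices, bin width %g)\n",
    x$gni, x$n_macro_pixels, x$n_slices, x$params$bin_width
  ))
  invisible(x)
}

#' Stack per-slice noise maps into a reduced-matrix volume
#'
#' The returned volume has in-plane spacing multiplied by the block size and
#' invalid macro pixels set to `fill`; useful for NIfTI export of noise
#' maps.
#'
#' @param maps List of [slice_noise_map()] results.
#' @param volume The source [suv_volume()] (for geometry).
#' @param fill Value written into invalid macro pixels (default 0).
#' @return An [suv_volume()] holding the noise maps.
#' @export
noise_maps_as_volume <- function(maps, volume, fill = 0) {
  stopifnot(length(maps) == n_slices(volume))
  d <- dim(maps[[1]]$values)
  arr <- array(fill, dim = c(d, length(maps)))
  for (k in seq_along(maps)) {
    v <- maps[[k]]$values
    v[!maps[[k]]$valid] <- fill
    arr[, , k] <- v
  }
  b <- maps[[1]]$block_size
  suv_volume(arr,
             spacing = volume$spacing * c(b, b, 1),
             origin = volume$origin,
             meta = volume$meta)
}
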