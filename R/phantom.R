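#' Specification of a synthetic whole-body phantom
#'
#' Describes a piecewise-constant "whole-body" SUV phantom: an elliptic body
#' cylinder (mean SUV 1.0) on exact-zero air, two lung ellipsoids (mean 0.4)
#' in the upper section, and a spherical liver (mean 2.5) below the lungs.
#' Zero-mean Gaussian noise with SD `sigma(t) = sigma_ref * sqrt(120 / t)`
#' is added inside the body, emulating the count-statistics growth of noise
#' as the acquisition time per bed position `t` shrinks. A per-reconstruction
#' Gaussian smoothing FWHM stands in for the strength of a regularized
#' reconstruction: stronger regularization is emulated by more smoothing.
#'
#' @param grid_size Integer length-3 `(nx, ny, nz)`; default
#'   `c(128, 128, 120)`.
#' @param spacing_mm Voxel spacing in mm; default 3 mm isotropic.
#' @param body_semiaxes_mm In-plane semi-axes of the body ellipse (mm);
#'   by default 42% / 30% of the in-plane field of view, so the phantom
#'   scales with the grid.
#' @param organ_means Named SUV means, defaults `body = 1.0`, `liver = 2.5`,
#'   `lung = 0.4` (air is exactly 0).
#' @param sigma_ref Noise SD at the 120 s reference bed time; default 0.15
#'   SUV.
#' @param bed_times_s Available bed times (s); default
#'   `c(15, 30, 60, 90, 120)`.
#' @param smoothing_mm Named per-reconstruction Gaussian FWHM (mm); default
#'   `c("Q.Clear 450" = 0, "Q.Clear 600" = 3)`.
#' @param background_noise_sd Optional Gaussian noise SD in air (default 0,
#'   i.e. air stays exactly zero); useful for mask-robustness tests.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = c(128L, 128L, 120L),
                         spacing_mm = c(3, 3, 3),
                         body_semiaxes_mm = NULL,
                         organ_means = c(body = 1.0, liver = 2.5, lung = 0.4),
                         sigma_ref = 0.15,
                         bed_times_s = c(15L, 30L, 60L, 90L, 120L),
                         smoothing_mm = c("Q.Clear 450" = 0, "Q.Clear 600" = 3),
                         background_noise_sd = 0) {
  grid_size <- as.integer(grid_size)
  if (length(grid_size) != 3L || any(grid_size < 16L)) {
    stop("bad phantom spec: grid_size must be 3 values >= 16", call. = FALSE)
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (is.null(body_semiaxes_mm)) {
    fov <- (grid_size[1:2] - 1) * spacing_mm[1:2]
    body_semiaxes_mm <- c(0.42, 0.30) * fov
  }
  if (!is.finite(sigma_ref) || sigma_ref < 0) {
    stop("bad phantom spec: sigma_ref must be >= 0", call. = FALSE)
  }
  if (any(!is.finite(organ_means)) || any(organ_means < 0) ||
      !all(c("body", "liver", "lung") %in% names(organ_means))) {
    stop("bad phantom spec: organ_means needs non-negative body/liver/lung",
         call. = FALSE)
  }
  if (is.null(names(smoothing_mm)) || any(smoothing_mm < 0)) {
    stop("bad phantom spec: smoothing_mm must be named and >= 0", call. = FALSE)
  }
  structure(
    list(grid_size = grid_size, spacing_mm = as.numeric(spacing_mm),
         body_semiaxes_mm = as.numeric(body_semiaxes_mm),
         organ_means = organ_means, sigma_ref = sigma_ref,
         bed_times_s = as.integer(bed_times_s),
         smoothing_mm = smoothing_mm,
         background_noise_sd = background_noise_sd),
    class = "phantom_spec"
  )
}

# organ label volume and centers for a phantom spec.
# labels: 0 air, 1 body, 2 liver, 3 lung
phantom_labels <- function(spec) {
  d <- spec$grid_size
  sp <- spec$spacing_mm
  x <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp[1]
  y <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp[2]
  z <- (seq_len(d[3]) - (d[3] + 1) / 2) * sp[3]
  a <- spec$body_semiaxes_mm[1]; b <- spec$body_semiaxes_mm[2]

  ell <- outer((x / a)^2, (y / b)^2, `+`) <= 1
  labels <- array(0L, dim = d)
  labels[rep(ell, d[3])] <- 1L

  zmin <- z[1]; zmax <- z[d[3]]
  # lungs: two ellipsoids in the upper 40% of the axial extent
  lung_cz <- zmin + 0.78 * (zmax - zmin)
  lung_r <- c(0.30 * a, 0.42 * b, 0.18 * (zmax - zmin))
  for (s in c(-1, 1)) {
    cx <- s * 0.42 * a
    q <- outer(((x - cx) / lung_r[1])^2, ((y - 0) / lung_r[2])^2, `+`)
    inz <- ((z - lung_cz) / lung_r[3])^2
    for (k in which(inz < 1)) {
      inside <- q <= (1 - inz[k])
      sl <- labels[, , k]
      sl[inside & sl == 1L] <- 3L
      labels[, , k] <- sl
    }
  }
  # liver: sphere under the right lung
  liver_c <- c(0.35 * a, 0.05 * b, zmin + 0.52 * (zmax - zmin))
  liver_r <- 0.45 * min(a, b)
  inz <- ((z - liver_c[3]) / liver_r)^2
  q <- outer(((x - liver_c[1]) / liver_r)^2, ((y - liver_c[2]) / liver_r)^2, `+`)
  for (k in which(inz < 1)) {
    inside <- q <= (1 - inz[k])
    sl <- labels[, , k]
    sl[inside & sl == 1L] <- 2L
    labels[, , k] <- sl
  }

  # world origin so that the grid is centered at 0
  origin <- c(x[1], y[1], z[1])
  # a lung center safely inside the left lung ellipsoid
  lung_center <- c(-0.42 * a, 0, lung_cz)
  list(labels = labels, origin = origin,
       organ_centers_mm = list(liver = liver_c, lung = lung_center,
                               body = c(0, -0.5 * b, zmin + 0.25 * (zmax - zmin))))
}

#' True noise SD of a phantom at a given bed time
#'
#' `sigma(t) = sigma_ref * sqrt(120 / t)` (before any smoothing): noise
#' grows as the inverse square root of the acquisition time, matching count
#' statistics to first order.
#'
#' @param spec A [phantom_spec()].
#' @param bed_time_s Bed time in seconds.
#' @return Noise SD in SUV.
#' @export
phantom_sigma <- function(spec, bed_time_s) {
  spec$sigma_ref * sqrt(120 / bed_time_s)
}

# deterministic per-condition RNG stream; recon does NOT enter: both
# reconstructions smooth the same realization (same emission data)
phantom_seed <- function(seed, subject = 0L, bed_time_s = 120L) {
  as.integer((as.numeric(seed) * 97 + subject * 7919 + bed_time_s * 131) %%
               2147483647)
}

#' Generate one synthetic phantom volume
#'
#' Piecewise-constant organ means plus additive Gaussian noise of SD
#' `phantom_sigma(spec, bed_time_s)` inside the body (air stays exactly 0
#' unless `background_noise_sd > 0`), followed by the reconstruction's
#' Gaussian smoothing. The noise realization depends on `(spec, seed,
#' bed_time_s)` only, so the two reconstruction labels smooth the same
#' realization -- as two reconstructions of the same emission data would.
#'
#' @param spec A [phantom_spec()].
#' @param bed_time_s Bed time in seconds; must be one of
#'   `spec$bed_times_s`.
#' @param recon_label One of `names(spec$smoothing_mm)`.
#' @param seed Integer seed; the output is a pure function of
#'   `(spec, seed, bed_time_s, recon_label)`.
#' @param subject Integer subject id mixed into the RNG stream (default 0).
#' @return List with `volume` (an [suv_volume()]) and `truth` (list:
#'   `labels` array, `sigma_true`, `organ_centers_mm`).
#' @export
make_phantom <- function(spec, bed_time_s, recon_label = names(spec$smoothing_mm)[1],
                         seed = 1L, subject = 0L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!bed_time_s %in% spec$bed_times_s) {
    stop("bad phantom spec: bed_time_s must be one of spec$bed_times_s",
         call. = FALSE)
  }
  if (!recon_label %in% names(spec$smoothing_mm)) {
    stop("bad phantom spec: unknown recon_label ", recon_label, call. = FALSE)
  }
  geo <- phantom_labels(spec)
  lab <- geo$labels
  means <- c(0, spec$organ_means[c("body", "liver", "lung")])
  vox <- array(means[lab + 1L], dim = dim(lab))

  sigma <- phantom_sigma(spec, bed_time_s)
  vox <- with_seed(phantom_seed(seed, subject, bed_time_s), {
    body <- lab > 0L
    if (sigma > 0) {
      vox[body] <- vox[body] + rnorm(sum(body), sd = sigma)
    }
    if (spec$background_noise_sd > 0) {
      vox[!body] <- rnorm(sum(!body), sd = spec$background_noise_sd)
    }
    vox
  })

  fwhm <- spec$smoothing_mm[[recon_label]]
  if (fwhm > 0) {
    vox <- gaussian_smooth_3d(vox, fwhm_mm = fwhm, spacing_mm = spec$spacing_mm)
  }

  meta <- patient_meta(bed_time_s = bed_time_s, recon_label = recon_label)
  list(
    volume = suv_volume(vox, spacing = spec$spacing_mm, origin = geo$origin,
                        meta = meta),
    truth = list(labels = lab, sigma_true = sigma,
                 organ_centers_mm = geo$organ_centers_mm)
  )
}

#' Separable 3-D Gaussian smoothing
#'
#' Convolves the array with a Gaussian kernel (given as FWHM in mm) along
#' each axis, with replicate padding at the edges. FWHM below half a voxel
#' returns the input unchanged.
#'
#' @param arr Numeric 3-D array.
#' @param fwhm_mm Full width at half maximum of the kernel, in mm (scalar or
#'   per-axis).
#' @param spacing_mm Voxel spacing (mm), length 3.
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_smooth_3d <- function(arr, fwhm_mm, spacing_mm = c(1, 1, 1)) {
  stopifnot(length(dim(arr)) == 3L)
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3L)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing_mm
  d <- dim(arr)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s < 0.2) next
    r <- max(1L, ceiling(3 * s))
    k <- dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    dp <- dim(a)
    m <- matrix(a, nrow = dp[1])
    # replicate-pad rows, filter column-wise, trim
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
                m[rep(nrow(m), r), , drop = FALSE])
    f <- stats::filter(mp, k, sides = 2)
    m <- f[(r + 1L):(r + dp[1]), , drop = FALSE]
    arr <- aperm(array(m, dim = dp), order(perm))
  }
  arr
}

#' Generate a synthetic cohort manifest
#'
#' Mirrors a multi-patient acquisition design: per subject, body size and
#' reference noise are randomized, and every combination of bed time and
#' reconstruction label is enumerated. Volumes are not kept in memory;
#' [make_cohort_volume()] re-creates any of them deterministically from the
#' manifest row.
#'
#' @param spec A [phantom_spec()] serving as the cohort template.
#' @param n_subjects Number of subjects (`>= 1`).
#' @param seed Integer cohort seed.
#' @return Object of class `phantom_cohort`: `subject_specs` (list of
#'   per-subject [phantom_spec()]s), `manifest` (data.frame with
#'   `subject_id`, `bed_time_s`, `recon_label`, `sigma_true`, `seed`), and
#'   `seed`.
#' @export
make_cohort <- function(spec, n_subjects, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), n_subjects >= 1)
  subject_specs <- with_seed(phantom_seed(seed, 999983L), {
    lapply(seq_len(n_subjects), function(i) {
      s <- spec
      s$body_semiaxes_mm <- spec$body_semiaxes_mm * stats::runif(2, 0.85, 1.15)
      s$sigma_ref <- spec$sigma_ref * stats::runif(1, 0.8, 1.2)
      s
    })
  })
  grid <- expand.grid(
    subject_id = seq_len(n_subjects),
    bed_time_s = spec$bed_times_s,
    recon_label = names(spec$smoothing_mm),
    stringsAsFactors = FALSE
  )
  grid$sigma_true <- vapply(seq_len(nrow(grid)), function(i) {
    phantom_sigma(subject_specs[[grid$subject_id[i]]], grid$bed_time_s[i])
  }, numeric(1))
  grid$seed <- seed
  structure(
    list(subject_specs = subject_specs, manifest = grid, seed = seed),
    class = "phantom_cohort"
  )
}

#' Materialize one cohort volume
#'
#' @param cohort A [make_cohort()] result.
#' @param row Row index into `cohort$manifest`.
#' @return As [make_phantom()].
#' @export
make_cohort_volume <- function(cohort, row) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  m <- cohort$manifest[row, ]
  make_phantom(cohort$subject_specs[[m$subject_id]],
               bed_time_s = m$bed_time_s, recon_label = m$recon_label,
               seed = cohort$seed, subject = m$subject_id)
}

#' Fill a paired noise table for a synthetic cohort
#'
#' Streams over all cohort conditions: generates each volume, computes the
#' GNI and the liver/lung cubic-VOI SDs at the phantom's known organ
#' centers, and returns one row per (subject, bed time, reconstruction).
#'
#' @param cohort A [make_cohort()] result.
#' @param threshold,block_size,bin_width,min_valid_fraction Noise pipeline
#'   parameters, see [global_noise_index()].
#' @param edge_mm VOI edge length in mm (default 20).
#' @param progress Print one line per condition to stderr.
#' @return data.frame with columns `subject_id`, `bed_time_s`,
#'   `recon_label`, `gni`, `liver_sd`, `lung_sd`, `sigma_true`.
#' @export
cohort_noise_table <- function(cohort, threshold = 0.15, block_size = 8L,
                               bin_width = 0.01, min_valid_fraction = 0.5,
                               edge_mm = 20, progress = FALSE) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  man <- cohort$manifest
  rows <- lapply(seq_len(nrow(man)), function(i) {
    ph <- make_cohort_volume(cohort, i)
    g <- global_noise_index(ph$volume, threshold = threshold,
                            block_size = block_size, bin_width = bin_width,
                            min_valid_fraction = min_valid_fraction)
    liver <- cubic_voi_noise(ph$volume, ph$truth$organ_centers_mm$liver,
                             edge_mm = edge_mm, organ_label = "liver")
    lung <- cubic_voi_noise(ph$volume, ph$truth$organ_centers_mm$lung,
                            edge_mm = edge_mm, organ_label = "lung")
    if (progress) {
      message(sprintf("cohort %d/%d: subject %d, %d s, %s -> GNI %.3f",
                      i, nrow(man), man$subject_id[i], man$bed_time_s[i],
                      man$recon_label[i], g$gni))
    }
    data.frame(
      subject_id = man$subject_id[i], bed_time_s = man$bed_time_s[i],
      recon_label = man$recon_label[i], gni = g$gni,
      liver_sd = liver$sd_suv, lung_sd = lung$sd_suv,
      sigma_true = man$sigma_true[i]
    )
  })
  do.call(rbind, rows)
}

#' Simulate reader quality labels from noise scores
#'
#' Stand-in for consensus reader grading: a study is labeled
#' `"insufficient"` when its noise score plus Gaussian reader noise exceeds
#' a latent cutoff.
#'
#' @param gni_values Numeric noise scores.
#' @param latent_cutoff Latent decision threshold (SUV).
#' @param label_noise_sd SD of the Gaussian reader noise (`>= 0`).
#' @param seed Integer seed.
#' @return Character vector of `"sufficient"` / `"insufficient"` labels.
#' @export
simulate_quality_labels <- function(gni_values, latent_cutoff,
                                    label_noise_sd = 0, seed = 1L) {
  if (label_noise_sd < 0) stop("label_noise_sd must be >= 0", call. = FALSE)
  gni_values <- as.numeric(gni_values)
  noisy <- with_seed(seed, gni_values + rnorm(length(gni_values),
                                              sd = label_noise_sd))
  ifelse(noisy > latent_cutoff, "insufficient", "sufficient")
}
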