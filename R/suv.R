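#' Body-weight standardized uptake value
#'
#' Converts activity concentration to body-weight SUV,
#' \deqn{SUV = \frac{c}{A_0 \, 2^{-t/T_{1/2}} / w},}
#' where `c` is the tissue activity concentration, `A_0` the injected
#' activity, `t` the uptake (injection-to-scan) time, `T_1/2 = 109.77` min
#' the F-18 half-life, and `w` the body weight. Units must be reconciled by
#' the caller so that a concentration numerically equal to decayed activity
#' per gram of body weight yields SUV 1; with concentration in kBq/ml,
#' activity in MBq and weight in kg this holds under the usual 1 g/ml tissue
#' density convention (MBq/kg == kBq/g).
#'
#' @param concentration_kBq_per_ml Activity concentration (kBq/ml); may be a
#'   vector or array.
#' @param weight_kg Body weight in kg, `> 0`.
#' @param injected_activity_MBq Injected activity in MBq at injection time,
#'   `> 0`.
#' @param uptake_time_min Injection-to-scan delay in minutes, `>= 0`.
#' @return SUV value(s), same shape as `concentration_kBq_per_ml`.
#' @examples
#' suv_bw(3, 70, 249.3, 58.7)
#' @export
suv_bw <- function(concentration_kBq_per_ml, weight_kg,
                   injected_activity_MBq, uptake_time_min) {
  if (!is.finite(weight_kg) || weight_kg <= 0 ||
      !is.finite(injected_activity_MBq) || injected_activity_MBq <= 0) {
    stop("invalid metadata: weight and injected activity must be positive",
         call. = FALSE)
  }
  if (!is.finite(uptake_time_min) || uptake_time_min < 0) {
    stop("invalid metadata: uptake time must be non-negative", call. = FALSE)
  }
  decayed_MBq <- injected_activity_MBq * 2^(-uptake_time_min / F18_HALF_LIFE_MIN)
  concentration_kBq_per_ml / (decayed_MBq / weight_kg)
}

#' Convert an activity-concentration volume to SUV
#'
#' Applies [suv_bw()] voxel-wise using the weight, injected activity and
#' uptake time stored in the volume's metadata.
#'
#' @param volume An [suv_volume()] whose voxels hold activity concentration
#'   in kBq/ml.
#' @return An [suv_volume()] in SUV units.
#' @export
apply_suv_conversion <- function(volume) {
  stopifnot(inherits(volume, "suv_volume"))
  m <- volume$meta
  if (is.na(m$weight_kg) || is.na(m$injected_activity_MBq) ||
      is.na(m$uptake_time_min)) {
    stop("metadata incomplete: weight, injected activity and uptake time ",
         "are required for SUV conversion", call. = FALSE)
  }
  volume$voxels[] <- suv_bw(volume$voxels, m$weight_kg,
                            m$injected_activity_MBq, m$uptake_time_min)
  volume
}
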