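#' Body surface area from body weight
#'
#' Meeh allometric formula `BSA = k * W^(2/3)` with the murine coefficient
#' k = 9.8 cm^2 g^(-2/3) by default. Any positive monotone choice of k only
#' rescales the sqrt(BSA) regressor of the normative model.
#'
#' @param body_weight_g Body weight in g (vectorized, >= 0).
#' @param k Meeh coefficient in cm^2 g^(-2/3).
#' @return BSA in cm^2.
#' @examples
#' bsa_from_weight(20) # 72.21 cm^2
#' @export
bsa_from_weight <- function(body_weight_g, k = 9.8) {
  if (any(body_weight_g < 0, na.rm = TRUE)) {
    stop("body_weight_g must be >= 0", call. = FALSE)
  }
  if (k <= 0) stop("Meeh coefficient k must be > 0", call. = FALSE)
  k * body_weight_g^(2 / 3)
}

#' Weight-adjusted vessel dimension
#'
#' The study's body-size adjustment: diameter divided by body weight,
#' multiplied by 100. The result carries pseudo-units mm g^-1 x 100 and
#' must not be mixed with raw mm.
#'
#' @param diameter_mm Dimension in mm (vectorized).
#' @param body_weight_g Body weight in g, > 0.
#' @return Adjusted value (mm g^-1 x 100).
#' @export
weight_adjust <- function(diameter_mm, body_weight_g) {
  if (any(is.na(body_weight_g)) || any(body_weight_g <= 0)) {
    stop("body_weight_g must be > 0", call. = FALSE)
  }
  diameter_mm / body_weight_g * 100
}

#' Mean vessel wall thickness
#'
#' Wall thickness as the arithmetic mean of the upper and lower wall:
#' `(upper + lower) / 2`. Symmetric in its arguments.
#'
#' @param upper_mm,lower_mm Wall thicknesses in mm, >= 0 where present.
#' @return Mean wall thickness in mm.
#' @export
wall_mean <- function(upper_mm, lower_mm) {
  if (any(upper_mm < 0, na.rm = TRUE) || any(lower_mm < 0, na.rm = TRUE)) {
    stop("wall thicknesses must be >= 0", call. = FALSE)
  }
  (upper_mm + lower_mm) / 2
}

#' Caliper-difference wall thickness
#'
#' Wall thickness as outer diameter minus inner diameter. This is a
#' distinct quantity from [wall_mean()] and the two are never silently
#' substituted for one another.
#'
#' @param outer_mm,inner_mm Outer and inner diameter in mm; outer >= inner
#'   wherever both are present.
#' @return `outer_mm - inner_mm` in mm.
#' @export
wall_diff <- function(outer_mm, inner_mm) {
  bad <- which(!is.na(outer_mm) & !is.na(inner_mm) & outer_mm < inner_mm)
  if (length(bad) > 0) {
    stop("inconsistent calipers at position ", bad[1],
         ": outer diameter < inner diameter", call. = FALSE)
  }
  outer_mm - inner_mm
}

#' Append derived measurements to a cohort
#'
#' Adds to each record: `bsa_cm2` and `sqrt_bsa_cm` (Meeh BSA from body
#' weight and its square root, the normative regressor); a weight-adjusted
#' `<measurement>_wadj` column for every mm measurement; the carotid and
#' aortic mean wall thickness (`*_wall_mean_mm`, raw and weight-adjusted);
#' and the carotid caliper-difference wall thickness
#' (`carotid_wall_diff_mm`).
#'
#' @param records Cohort tibble ([cohort_columns()] schema).
#' @param meeh_k Meeh coefficient passed to [bsa_from_weight()].
#' @return The records with derived columns appended.
#' @export
derive_measures <- function(records, meeh_k = 9.8) {
  validate_records(records)
  out <- records
  out$bsa_cm2 <- bsa_from_weight(out$body_weight_g, k = meeh_k)
  out$sqrt_bsa_cm <- sqrt(out$bsa_cm2)
  lengths_mm <- setdiff(echo_measurements(), "ejection_fraction_pct")
  for (m in lengths_mm) {
    out[[paste0(sub("_mm$", "", m), "_wadj")]] <-
      weight_adjust(out[[m]], out$body_weight_g)
  }
  out$carotid_wall_mean_mm <-
    wall_mean(out$carotid_upper_wall_mm, out$carotid_lower_wall_mm)
  out$carotid_wall_mean_wadj <-
    weight_adjust(out$carotid_wall_mean_mm, out$body_weight_g)
  out$carotid_wall_diff_mm <-
    wall_diff(out$carotid_outer_d_mm, out$carotid_inner_d_mm)
  out$aorta_wall_mean_mm <-
    wall_mean(out$aorta_upper_wall_mm, out$aorta_lower_wall_mm)
  out$aorta_wall_mean_wadj <-
    weight_adjust(out$aorta_wall_mean_mm, out$body_weight_g)
  out
}
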