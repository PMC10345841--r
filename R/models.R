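#' Linear HU-to-density conversion rule
#'
#' CT attenuation is close to linear in physical density around water, so
#' tissue density is estimated as `rho = hu * scale + offset`, giving
#' water (0 HU) density 1 and, e.g., fat at -100 HU density 0.9. The unit
#' is documented as kg/cm^3 to match the downstream mass equations, whose
#' fitted slope absorbs the unit scale.
#'
#' @param scale Density change per HU (default 1/1000).
#' @param offset Density at 0 HU (default 1).
#' @return Object of class `density_rule`.
#' @export
density_rule <- function(scale = 1 / 1000, offset = 1) {
  stopifnot(is.numeric(scale), is.numeric(offset), is.finite(scale),
            is.finite(offset))
  structure(list(scale = scale, offset = offset), class = "density_rule")
}

#' Convert Hounsfield units to tissue density
#'
#' @param hu Numeric vector of HU values.
#' @param rule A [density_rule()].
#' @return Densities (`hu * scale + offset`); below 1 for fat, above 1
#'   for muscle.
#' @export
#' @examples
#' hu_to_density(c(0, -100, 40))  # 1.00 0.90 1.04
hu_to_density <- function(hu, rule = density_rule()) {
  stopifnot(inherits(rule, "density_rule"))
  if (anyNA(hu) || any(!is.finite(hu))) {
    stop("hu must be finite", call. = FALSE)
  }
  hu * rule$scale + rule$offset
}

#' Construct a linear mass model
#'
#' An affine map from a CT-derived predictor to a mass in kg:
#' `mass = slope * predictor + intercept`.
#'
#' @param slope kg per predictor unit.
#' @param intercept kg.
#' @param predictor_kind One of `"fat_area_cm2"`, `"muscle_area_cm2"`,
#'   `"density_weighted_fat"`.
#' @param fit Optional fit summary (kept when the model comes from
#'   [fit_linear()]).
#' @return Object of class `linear_mass_model`.
#' @export
linear_mass_model <- function(slope, intercept,
                              predictor_kind = c("fat_area_cm2",
                                                 "muscle_area_cm2",
                                                 "density_weighted_fat"),
                              fit = NULL) {
  predictor_kind <- match.arg(predictor_kind)
  stopifnot(is.numeric(slope), is.finite(slope),
            is.numeric(intercept), is.finite(intercept))
  structure(list(slope = slope, intercept = intercept,
                 predictor_kind = predictor_kind, fit = fit),
            class = "linear_mass_model")
}

#' @export
print.linear_mass_model <- function(x, ...) {
  cat(sprintf("linear_mass_model: mass(kg) = %g * %s + %g\n",
              x$slope, x$predictor_kind, x$intercept))
  invisible(x)
}

#' @export
predict.linear_mass_model <- function(object, newdata, ...) {
  object$slope * newdata + object$intercept
}

#' Published coefficient sets for the three mass models
#'
#' Model 1 is the widely used area-based calibration
#' (FM = 0.042 * fat area + 11.2; FFM = 0.3 * muscle area + 6.06,
#' areas in cm^2 at L3). Model 2 is its least-squares refit on a mixed
#' normal-BMI/obesity cohort (FM = 0.058 * fat area + 7.35;
#' FFM = 0.27 * muscle area + 13.31). The density-weighted ("focusedon")
#' model predicts FM = 0.0069 * (weight / rho_ROI) * FAT% * rho_fat + 4.53
#' and derives FFM as weight - FM.
#'
#' @param which `"m1"`, `"m2"` or `"focusedon"`.
#' @return List with `fm` (and for the area models `ffm`)
#'   [linear_mass_model()] components.
#' @export
model_coefficients <- function(which = c("m1", "m2", "focusedon")) {
  which <- match.arg(which)
  switch(which,
    m1 = list(fm = linear_mass_model(0.042, 11.2, "fat_area_cm2"),
              ffm = linear_mass_model(0.3, 6.06, "muscle_area_cm2")),
    m2 = list(fm = linear_mass_model(0.058, 7.35, "fat_area_cm2"),
              ffm = linear_mass_model(0.27, 13.31, "muscle_area_cm2")),
    focusedon = list(fm = linear_mass_model(0.0069, 4.53,
                                            "density_weighted_fat"))
  )
}

check_area <- function(area) {
  if (anyNA(area) || any(!is.finite(area)) || any(area < 0)) {
    stop("tissue area must be non-negative and finite", call. = FALSE)
  }
  invisible(area)
}

#' Model 1: area-based fat mass
#' @param fat_area Fat (SAT + VAT) area at L3 in cm^2.
#' @param model Coefficients; defaults to the published Model 1 set.
#' @return Fat mass in kg.
#' @export
#' @examples
#' model1_fm(0)    # 11.2
#' model1_fm(100)  # 15.4
model1_fm <- function(fat_area, model = model_coefficients("m1")$fm) {
  check_area(fat_area)
  predict(model, fat_area)
}

#' Model 1: area-based fat-free mass
#' @param muscle_area Skeletal-muscle area at L3 in cm^2.
#' @param model Coefficients; defaults to the published Model 1 set.
#' @return Fat-free mass in kg.
#' @export
model1_ffm <- function(muscle_area, model = model_coefficients("m1")$ffm) {
  check_area(muscle_area)
  predict(model, muscle_area)
}

#' Model 2: refit area-based fat mass
#' @inheritParams model1_fm
#' @export
model2_fm <- function(fat_area, model = model_coefficients("m2")$fm) {
  check_area(fat_area)
  predict(model, fat_area)
}

#' Model 2: refit area-based fat-free mass
#' @inheritParams model1_ffm
#' @export
model2_ffm <- function(muscle_area, model = model_coefficients("m2")$ffm) {
  check_area(muscle_area)
  predict(model, muscle_area)
}

#' Density-weighted fat-mass predictor
#'
#' Derivation: the whole-body volume is extrapolated from scale weight and
#' the whole-slice density, `V_total = weight / rho_ROI`; the fat volume
#' is its share at the measured fat percentage,
#' `V_fat = V_total * FAT% / 100`; the fat mass scale is restored by the
#' fat density, `M_fat ~ V_fat * rho_fat`. The linear model is fitted on
#' the predictor `(weight / rho_ROI) * FAT% * rho_fat` (fat percentage
#' kept on the 0-100 scale; the slope absorbs the factor 100).
#'
#' @param weight kg. @param roi_mean_hu Mean HU of the whole body region.
#' @param fat_pct Fat percentage of the body region, 0-100.
#' @param fat_mean_hu Mean HU of the fat compartment.
#' @param rule A [density_rule()].
#' @return Predictor value (same units the 0.0069 slope expects).
#' @export
density_weighted_predictor <- function(weight, roi_mean_hu, fat_pct,
                                       fat_mean_hu, rule = density_rule()) {
  check_positive(weight, "weight", length(weight))
  if (any(fat_pct < 0) || any(fat_pct > 100) || anyNA(fat_pct)) {
    stop_field("fat_pct", "must lie in [0, 100]")
  }
  rho_roi <- hu_to_density(roi_mean_hu, rule)
  if (any(rho_roi <= 0)) {
    stop("whole-region density is non-positive; roi_mean_hu is nonphysical",
         call. = FALSE)
  }
  rho_fat <- hu_to_density(fat_mean_hu, rule)
  (weight / rho_roi) * fat_pct * rho_fat
}

#' Density-weighted model: fat mass
#'
#' @inheritParams density_weighted_predictor
#' @param model Coefficients; defaults to the published density-weighted
#'   set (slope 0.0069, intercept 4.53).
#' @param details If `TRUE`, also return the intermediate volumes and
#'   masses of the derivation.
#' @return Fat mass in kg, or (with `details = TRUE`) a list with `fm`,
#'   `predictor`, `v_total` (volume extrapolated from weight and
#'   whole-region density), `v_fat` and `m_fat` (pre-calibration fat
#'   volume/mass).
#' @export
#' @examples
#' model3_fm(weight = 100, roi_mean_hu = 0, fat_pct = 50,
#'           fat_mean_hu = -100)  # 0.0069 * 4500 + 4.53 = 35.58
model3_fm <- function(weight, roi_mean_hu, fat_pct, fat_mean_hu,
                      model = model_coefficients("focusedon")$fm,
                      rule = density_rule(), details = FALSE) {
  x <- density_weighted_predictor(weight, roi_mean_hu, fat_pct, fat_mean_hu,
                                  rule)
  fm <- predict(model, x)
  if (!details) return(fm)
  rho_roi <- hu_to_density(roi_mean_hu, rule)
  v_total <- weight / rho_roi
  v_fat <- v_total * fat_pct / 100
  list(fm = fm, predictor = x, v_total = v_total, v_fat = v_fat,
       m_fat = v_fat * hu_to_density(fat_mean_hu, rule))
}

#' Density-weighted model: fat-free mass as the weight complement
#'
#' The density-weighted model estimates fat mass only; fat-free mass is
#' the exact difference, so `fm + ffm == weight` holds to machine
#' precision.
#'
#' @param weight kg. @param fm Fat mass estimate in kg.
#' @return Fat-free mass in kg.
#' @export
model3_ffm <- function(weight, fm) {
  stopifnot(is.numeric(weight), is.numeric(fm))
  weight - fm
}

#' Ordinary least-squares fit of a linear mass model
#'
#' @param predictor Numeric predictor vector (>= 3 points, non-degenerate).
#' @param reference Reference masses in kg (e.g. DXA).
#' @param predictor_kind Recorded on the returned model.
#' @return A [linear_mass_model()] whose `fit` field carries n, sigma,
#'   r.squared and residuals.
#' @export
fit_linear <- function(predictor, reference,
                       predictor_kind = c("fat_area_cm2", "muscle_area_cm2",
                                          "density_weighted_fat")) {
  predictor_kind <- match.arg(predictor_kind)
  if (length(predictor) != length(reference)) {
    stop("predictor and reference lengths differ", call. = FALSE)
  }
  if (length(predictor) < 3L) {
    stop("insufficient data: a linear fit needs at least 3 points",
         call. = FALSE)
  }
  if (anyNA(predictor) || anyNA(reference)) {
    stop("missing values in fit inputs", call. = FALSE)
  }
  if (stats::var(predictor) == 0) {
    stop("degenerate predictor: zero variance", call. = FALSE)
  }
  ft <- stats::lm(reference ~ predictor)
  sm <- summary(ft)
  linear_mass_model(
    slope = unname(stats::coef(ft)[2]),
    intercept = unname(stats::coef(ft)[1]),
    predictor_kind = predictor_kind,
    fit = list(n = length(predictor), sigma = sm$sigma,
               r_squared = sm$r.squared, residuals = stats::residuals(ft))
  )
}

#' Cohen-style sample size for a precision target
#'
#' `N = z^2 * s^2 / d^2`, with `z` the standard-normal critical value,
#' `s` the standard deviation of the estimating variable and `d` the
#' desired precision.
#'
#' @param z Critical value (e.g. 1.96 at the 5% level).
#' @param s Standard deviation of the estimating variable.
#' @param d Desired precision (same units as `s` for the formula to be
#'   dimensionless).
#' @return List with `n` (unrounded) and `n_ceiling`.
#' @export
#' @examples
#' sample_size(1.96, 2, 2)$n  # 3.8416
sample_size <- function(z, s, d) {
  check_positive(z, "z", 1L); check_positive(s, "s", 1L)
  if (!is.numeric(d) || d <= 0) stop_field("d", "must be > 0")
  n <- z^2 * s^2 / d^2
  list(n = n, n_ceiling = ceiling(n))
}

#' Inflate a sample size by a variability margin
#' @param n Base sample size. @param factor Inflation factor.
#' @return `n * factor` (e.g. 51 * 1.35 = 68.85).
#' @export
inflate_sample_size <- function(n, factor = 1.35) {
  check_positive(n, "n", 1L); check_positive(factor, "factor", 1L)
  n * factor
}
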