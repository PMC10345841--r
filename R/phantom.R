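#' Specification of a synthetic L3 cross-section phantom
#'
#' The phantom is a concentric-ellipse idealisation of an axial abdominal
#' slice at L3: a subcutaneous fat ring under the skin, a skeletal-muscle
#' wall, and a visceral cavity lined with visceral fat, containing soft-
#' tissue "organ" filler, random visceral-fat blobs and a vertebral-body
#' bone placeholder. Each tissue's HU values are drawn from a truncated
#' normal (truncation at +/- `hu_trunc` standard deviations), so with the
#' default means every tissue falls strictly inside its segmentation
#' threshold window and the segmenter can be checked pixel-for-pixel
#' against the generated ground truth.
#'
#' @param body_semiaxes Body ellipse semiaxes in mm, (row, column) order.
#' @param sat_thickness Subcutaneous fat ring thickness, mm.
#' @param muscle_thickness Muscle wall thickness, mm.
#' @param visceral_fat_fraction Target fraction of the visceral cavity
#'   occupied by visceral fat (lining plus blobs), in [0, 1].
#' @param vat_lining Thickness in mm of the visceral-fat layer lining the
#'   cavity wall (emulating retroperitoneal fat; also guarantees non-fat
#'   organs never touch the muscle wall).
#' @param hu_means,hu_sds Named per-tissue HU means and standard deviations
#'   (`sat`, `muscle`, `vat`, `other`, `bone`).
#' @param hu_trunc Truncation bound in standard deviations.
#' @param pixel_spacing Pixel spacing in mm, (row, column).
#' @param grid_size Image size in pixels, (rows, columns).
#' @param n_slices Number of slices in the stack.
#' @param invariant_slices If `TRUE` (default) all slices are identical
#'   copies (a translation-invariant stack); if `FALSE` the HU noise is
#'   redrawn per slice over the same geometry.
#' @param background_hu Air value outside the body.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_semiaxes = c(110, 150),
                         sat_thickness = 25,
                         muscle_thickness = 12,
                         visceral_fat_fraction = 0.35,
                         vat_lining = 6,
                         hu_means = c(sat = -100, muscle = 40, vat = -90,
                                      other = 20, bone = 400),
                         hu_sds = c(sat = 5, muscle = 5, vat = 5,
                                    other = 5, bone = 40),
                         hu_trunc = 3,
                         pixel_spacing = c(1.5, 1.5),
                         grid_size = c(256, 256),
                         n_slices = 1,
                         invariant_slices = TRUE,
                         background_hu = -1000,
                         seed = 1L) {
  check_positive(body_semiaxes, "body_semiaxes", 2L)
  if (!is.numeric(sat_thickness) || sat_thickness < 0) {
    stop_field("sat_thickness", "must be a non-negative number")
  }
  check_positive(muscle_thickness, "muscle_thickness", 1L)
  if (!is.numeric(visceral_fat_fraction) || visceral_fat_fraction < 0 ||
      visceral_fat_fraction > 1) {
    stop_field("visceral_fat_fraction", "must lie in [0, 1]")
  }
  check_positive(vat_lining, "vat_lining", 1L)
  tissues <- c("sat", "muscle", "vat", "other", "bone")
  if (!all(tissues %in% names(hu_means))) {
    stop_field("hu_means", paste("must name all of:", paste(tissues, collapse = ", ")))
  }
  if (!all(tissues %in% names(hu_sds)) || any(hu_sds < 0)) {
    stop_field("hu_sds", "must name every tissue with a non-negative sd")
  }
  check_positive(hu_trunc, "hu_trunc", 1L)
  check_positive(pixel_spacing, "pixel_spacing", 2L)
  check_positive(grid_size, "grid_size", 2L)
  check_positive(n_slices, "n_slices", 1L)
  inner <- body_semiaxes - sat_thickness - muscle_thickness - vat_lining
  if (any(inner <= 0)) {
    stop_field("body_semiaxes",
               "too small for the requested sat/muscle/lining thicknesses")
  }
  extent <- grid_size * pixel_spacing
  if (any(2 * body_semiaxes > extent)) {
    warning("body ellipse larger than the field of view; it will be truncated",
            call. = FALSE)
  }
  structure(
    list(body_semiaxes = body_semiaxes, sat_thickness = sat_thickness,
         muscle_thickness = muscle_thickness,
         visceral_fat_fraction = visceral_fat_fraction,
         vat_lining = vat_lining,
         hu_means = hu_means[tissues], hu_sds = hu_sds[tissues],
         hu_trunc = hu_trunc, pixel_spacing = pixel_spacing,
         grid_size = as.integer(grid_size), n_slices = as.integer(n_slices),
         invariant_slices = isTRUE(invariant_slices),
         background_hu = background_hu, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Squared normalised ellipse coordinate for every pixel centre; <= 1 means
# inside the ellipse with semiaxes (ay, ax) mm around the grid centre.
ellipse_field <- function(spec, ay, ax) {
  nr <- spec$grid_size[1]; nc <- spec$grid_size[2]
  y <- (seq_len(nr) - (nr + 1) / 2) * spec$pixel_spacing[1]
  x <- (seq_len(nc) - (nc + 1) / 2) * spec$pixel_spacing[2]
  outer(y^2 / ay^2, rep(1, nc)) + outer(rep(1, nr), x^2 / ax^2)
}

inside_ellipse <- function(spec, semiaxes, offset = c(0, 0)) {
  nr <- spec$grid_size[1]; nc <- spec$grid_size[2]
  y <- (seq_len(nr) - (nr + 1) / 2) * spec$pixel_spacing[1] - offset[1]
  x <- (seq_len(nc) - (nc + 1) / 2) * spec$pixel_spacing[2] - offset[2]
  outer(y^2 / semiaxes[1]^2, rep(1, nc)) +
    outer(rep(1, nr), x^2 / semiaxes[2]^2) <= 1
}

# Ground-truth label matrix for one slice (geometry only; no HU noise).
phantom_labels <- function(spec) {
  lg <- tissue_legend()
  body    <- inside_ellipse(spec, spec$body_semiaxes)
  musc_o  <- inside_ellipse(spec, spec$body_semiaxes - spec$sat_thickness)
  cavity  <- inside_ellipse(spec, spec$body_semiaxes - spec$sat_thickness -
                              spec$muscle_thickness)
  cav_in  <- inside_ellipse(spec, spec$body_semiaxes - spec$sat_thickness -
                              spec$muscle_thickness - spec$vat_lining)
  labels <- matrix(0L, spec$grid_size[1], spec$grid_size[2])
  labels[body]   <- lg[["sat"]]
  labels[musc_o] <- lg[["muscle"]]
  labels[cavity] <- lg[["vat"]]    # lining ring; interior overwritten next
  labels[cav_in] <- lg[["other"]]

  # vertebral-body placeholder, posterior within the inner cavity
  inner <- spec$body_semiaxes - spec$sat_thickness - spec$muscle_thickness -
    spec$vat_lining
  bone_r <- min(17, 0.3 * min(inner))
  bone <- inside_ellipse(spec, c(bone_r, bone_r),
                         offset = c(0.55 * inner[1], 0))
  labels[bone & cav_in] <- lg[["bone"]]

  # visceral-fat blobs until the cavity fat fraction reaches target
  cav_px <- sum(cavity)
  target <- spec$visceral_fat_fraction * cav_px
  tries <- 0L
  while (sum(labels == lg[["vat"]]) < target && tries < 400L) {
    tries <- tries + 1L
    r <- stats::runif(1, 6, 16)
    off <- c(stats::runif(1, -1, 1) * (inner[1] - r),
             stats::runif(1, -1, 1) * (inner[2] - r))
    blob <- inside_ellipse(spec, c(r, r), offset = off)
    sel <- blob & cav_in & labels == lg[["other"]]
    labels[sel] <- lg[["vat"]]
  }
  labels
}

# Fill a label matrix with sampled HU values.
phantom_hu <- function(spec, labels) {
  lg <- tissue_legend()
  hu <- matrix(spec$background_hu, nrow(labels), ncol(labels))
  for (tissue in names(lg)) {
    idx <- which(labels == lg[[tissue]])
    if (length(idx)) {
      hu[idx] <- rtruncnorm3(length(idx), spec$hu_means[[tissue]],
                             spec$hu_sds[[tissue]], spec$hu_trunc)
    }
  }
  hu
}

#' Generate a synthetic L3 phantom stack with ground-truth labels
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom` with elements `slices` (list of
#'   [ct_slice()]), `masks` (list of [label_mask()] ground truth) and
#'   `spec`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_size = c(96, 96),
#'                                     body_semiaxes = c(55, 65),
#'                                     pixel_spacing = c(2, 2)))
#' table(ph$masks[[1]]$labels)
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    labels <- phantom_labels(spec)
    mask <- label_mask(labels)
    if (spec$invariant_slices) {
      hu <- phantom_hu(spec, labels)
      slices <- lapply(seq_len(spec$n_slices), function(k) {
        ct_slice(hu, spec$pixel_spacing, sprintf("phantom%03d", k))
      })
    } else {
      slices <- lapply(seq_len(spec$n_slices), function(k) {
        ct_slice(phantom_hu(spec, labels), spec$pixel_spacing,
                 sprintf("phantom%03d", k))
      })
    }
    masks <- rep(list(mask), spec$n_slices)
    structure(list(slices = slices, masks = masks, spec = spec),
              class = "phantom")
  })
}

#' Analytic area of the phantom's elliptical tissue rings
#'
#' Closed-form areas (cm^2) of the subcutaneous ring, muscle wall and
#' visceral cavity implied by a [phantom_spec()] — the geometric oracle
#' pixel-counted areas are checked against.
#'
#' @param spec A [phantom_spec()].
#' @return Named numeric vector: `sat`, `muscle`, `cavity` areas in cm^2.
#' @export
phantom_analytic_areas <- function(spec) {
  a <- spec$body_semiaxes
  b <- a - spec$sat_thickness
  c_ <- b - spec$muscle_thickness
  ell <- function(s) pi * s[1] * s[2] / 100  # mm^2 -> cm^2
  c(sat = ell(a) - ell(b), muscle = ell(b) - ell(c_), cavity = ell(c_))
}

#' Specification of a synthetic validation cohort
#'
#' Generates subjects with anthropometrics plus paired DXA-style reference
#' masses. The reference fat mass follows the density-weighted linear model
#' (`fm = m * (weight / rho_roi) * fat_pct * rho_fat + n` plus Gaussian
#' noise) by default, so refitting that model on a generated cohort is a
#' parameter-recovery exercise with known truth; `model_form = "area"`
#' instead generates from the classic area-based form
#' (`fm = m * fat_area + n`).
#'
#' @param n_subjects Number of subjects (>= 3; a linear fit needs more
#'   points than parameters).
#' @param weight_range kg pair; @param height_range m pair;
#' @param fat_pct_range fat percentage pair.
#' @param true_m,true_n Generative slope and intercept.
#' @param noise_sd Additive Gaussian noise on reference fat mass, kg.
#' @param model_form `"density"` (default) or `"area"`.
#' @param prop_female Probability a subject is female.
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 70,
                        weight_range = c(55, 160),
                        height_range = c(1.50, 1.90),
                        fat_pct_range = c(18, 55),
                        true_m = 0.0069,
                        true_n = 4.53,
                        noise_sd = 3,
                        model_form = c("density", "area"),
                        prop_female = 0.59,
                        seed = 1L) {
  model_form <- match.arg(model_form)
  if (!is.numeric(n_subjects) || n_subjects < 3) {
    stop_field("n_subjects", "must be >= 3 (fit needs more points than parameters)")
  }
  for (nm in c("weight_range", "height_range", "fat_pct_range")) {
    r <- get(nm)
    check_positive(r, nm, 2L)
    if (r[1] > r[2]) stop_field(nm, "range is inverted")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop_field("noise_sd", "must be >= 0")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), weight_range = weight_range,
         height_range = height_range, fat_pct_range = fat_pct_range,
         true_m = true_m, true_n = true_n, noise_sd = noise_sd,
         model_form = model_form, prop_female = prop_female,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort with paired DXA-style reference masses
#'
#' Per subject: weight, height and fat percentage are drawn uniformly in
#' their ranges; whole-slice and fat-compartment mean HU are drawn from
#' plausible tissue mixtures; densities follow the linear HU-to-density
#' rule; the DXA-style reference fat mass is generated from the configured
#' model form plus noise and fat-free mass as weight minus fat mass.
#' Fat and muscle areas (cm^2) consistent with the fat percentage are also
#' emitted so the area-based models can be exercised on the same table.
#'
#' @param spec A [cohort_spec()].
#' @return List with `subjects` (id, sex, group, anthropometrics, DXA
#'   reference masses) and `metrics` (per-subject CT-derived predictors)
#'   data frames, joinable on `id`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    id <- sprintf("S%03d", seq_len(n))
    sex <- ifelse(stats::runif(n) < spec$prop_female, "F", "M")
    weight <- stats::runif(n, spec$weight_range[1], spec$weight_range[2])
    height <- stats::runif(n, spec$height_range[1], spec$height_range[2])
    fat_pct <- stats::runif(n, spec$fat_pct_range[1], spec$fat_pct_range[2])

    # mean HU of the fat compartment and of the whole body ROI: the ROI is
    # modelled as a fat/lean two-component mixture at the subject's fat
    # fraction, so heavier-fat subjects have lower whole-slice density
    fat_hu <- stats::rnorm(n, -95, 4)
    lean_hu <- stats::rnorm(n, 35, 4)
    roi_hu <- fat_hu * fat_pct / 100 + lean_hu * (1 - fat_pct / 100)
    rho_roi <- hu_to_density(roi_hu)
    rho_fat <- hu_to_density(fat_hu)

    # L3 slice geometry consistent with the fat fraction: body cross-section
    # area grows with weight; fat/muscle areas are shares of it
    body_area <- 280 + 4.2 * weight + stats::rnorm(n, 0, 15)
    fat_area <- body_area * fat_pct / 100
    muscle_pct <- stats::runif(n, 15, 26)
    muscle_area <- body_area * muscle_pct / 100

    predictor <- switch(spec$model_form,
      density = (weight / rho_roi) * fat_pct * rho_fat,
      area = fat_area
    )
    dxa_fm <- spec$true_m * predictor + spec$true_n +
      stats::rnorm(n, 0, spec$noise_sd)
    dxa_fm <- pmin(pmax(dxa_fm, 0), weight)  # physical clamp
    dxa_ffm <- weight - dxa_fm

    bmi <- weight / height^2
    subjects <- data.frame(
      id = id, sex = sex, weight = weight, height = height, bmi = bmi,
      group = ifelse(bmi >= 30, "obesity", "normal-BMI"),
      dxa_fm = dxa_fm, dxa_ffm = dxa_ffm,
      stringsAsFactors = FALSE
    )
    metrics <- data.frame(
      id = id, body_area = body_area, fat_area_cm2 = fat_area,
      muscle_area_cm2 = muscle_area, fat_pct = fat_pct,
      roi_mean_hu = roi_hu, fat_mean_hu = fat_hu,
      stringsAsFactors = FALSE
    )
    list(subjects = subjects, metrics = metrics)
  })
}
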