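test_that("phantom labels partition the body and respect geometry switches", {
  ph <- generate_phantom(small_phantom_spec())
  labels <- ph$masks[[1]]$labels
  lg <- ph$masks[[1]]$spec
  body_px <- sum(labels > 0L)
  per_tissue <- table(labels[labels > 0L])
  expect_equal(sum(per_tissue), body_px)  # mutually exclusive, covering

  # degenerate geometry: no subcutaneous ring requested -> no SAT pixels
  ph0 <- generate_phantom(small_phantom_spec(sat_thickness = 0))
  expect_equal(sum(ph0$masks[[1]]$labels == tissue_legend()[["sat"]]), 0L)
})

test_that("sampled HU values stay strictly inside each tissue's window", {
  ph <- generate_phantom(small_phantom_spec())
  hu <- ph$slices[[1]]$hu
  labels <- ph$masks[[1]]$labels
  lg <- tissue_legend()
  th <- threshold_set()
  expect_true(all(hu[labels == lg[["muscle"]]] >= th$muscle[1] &
                    hu[labels == lg[["muscle"]]] <= th$muscle[2]))
  expect_true(all(hu[labels == lg[["sat"]]] >= th$sat[1] &
                    hu[labels == lg[["sat"]]] <= th$sat[2]))
  expect_true(all(hu[labels == lg[["vat"]]] >= th$vat[1] &
                    hu[labels == lg[["vat"]]] <= th$vat[2]))
  expect_true(all(hu[labels == 0L] == -1000))
})

test_that("pixel-counted ring areas match the analytic ellipse-annulus areas", {
  spec <- small_phantom_spec()
  ph <- generate_phantom(spec)
  labels <- ph$masks[[1]]$labels
  lg <- tissue_legend()
  pxa <- prod(spec$pixel_spacing) / 100
  got <- c(sat = sum(labels == lg[["sat"]]) * pxa,
           muscle = sum(labels == lg[["muscle"]]) * pxa)
  want <- phantom_analytic_areas(spec)
  # discretization tolerance: about one pixel row along the ring perimeter
  perim_cm2 <- 2 * pi * max(spec$body_semiaxes) * max(spec$pixel_spacing) / 100
  expect_lt(abs(got[["sat"]] - want[["sat"]]), perim_cm2)
  expect_lt(abs(got[["muscle"]] - want[["muscle"]]), perim_cm2)
})

test_that("identical seed reproduces phantoms; invariant stacks repeat slices", {
  a <- generate_phantom(small_phantom_spec(n_slices = 3))
  b <- generate_phantom(small_phantom_spec(n_slices = 3))
  expect_identical(a$slices[[2]]$hu, b$slices[[2]]$hu)
  expect_identical(a$masks[[1]]$labels, b$masks[[1]]$labels)
  # translationally invariant option: all slices identical
  expect_identical(a$slices[[1]]$hu, a$slices[[3]]$hu)
  # non-invariant stacks redraw noise over the same geometry
  c <- generate_phantom(small_phantom_spec(n_slices = 2,
                                           invariant_slices = FALSE))
  expect_false(identical(c$slices[[1]]$hu, c$slices[[2]]$hu))
})

test_that("phantom spec validation names the offending field", {
  expect_error(phantom_spec(visceral_fat_fraction = 1.2),
               "visceral_fat_fraction")
  expect_error(phantom_spec(muscle_thickness = -1), "muscle_thickness")
  expect_error(phantom_spec(pixel_spacing = c(1, 0)), "pixel_spacing")
})

test_that("noise-free density-form cohorts refit to the generating parameters", {
  co <- generate_cohort(cohort_spec(n_subjects = 40, noise_sd = 0, seed = 7L))
  x <- density_weighted_predictor(co$subjects$weight, co$metrics$roi_mean_hu,
                                  co$metrics$fat_pct, co$metrics$fat_mean_hu)
  ft <- suppressWarnings(fit_linear(x, co$subjects$dxa_fm,
                                    "density_weighted_fat"))
  expect_equal(ft$slope, 0.0069, tolerance = 1e-9)
  expect_equal(ft$intercept, 4.53, tolerance = 1e-9)
  # the subject table is internally consistent
  expect_equal(co$subjects$dxa_fm + co$subjects$dxa_ffm, co$subjects$weight)
  expect_equal(co$subjects$bmi, co$subjects$weight / co$subjects$height^2)
})

test_that("area-form cohorts refit to their generating parameters too", {
  co <- generate_cohort(cohort_spec(n_subjects = 40, noise_sd = 0,
                                    true_m = 0.042, true_n = 11.2,
                                    model_form = "area", seed = 8L))
  ft <- suppressWarnings(fit_linear(co$metrics$fat_area_cm2,
                                    co$subjects$dxa_fm, "fat_area_cm2"))
  expect_equal(ft$slope, 0.042, tolerance = 1e-9)
  expect_equal(ft$intercept, 11.2, tolerance = 1e-9)
})

test_that("cohort generation is deterministic and validates its spec", {
  a <- generate_cohort(cohort_spec(seed = 3L))
  b <- generate_cohort(cohort_spec(seed = 3L))
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$metrics, b$metrics)
  expect_error(cohort_spec(n_subjects = 1), "n_subjects")
  expect_error(cohort_spec(weight_range = c(90, 50)), "weight_range")
  expect_error(cohort_spec(noise_sd = -1), "noise_sd")
})
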