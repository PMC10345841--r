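make_toy <- function() {
  # 10x10 image: 40 muscle px, 30 SAT px, 20 VAT px, 10 other px
  labels <- matrix(c(rep(2L, 40), rep(1L, 30), rep(3L, 20), rep(5L, 10)),
                   10, 10)
  hu <- matrix(0, 10, 10)
  hu[labels == 2L] <- 40; hu[labels == 1L] <- -100
  hu[labels == 3L] <- -90; hu[labels == 5L] <- 20
  list(slice = ct_slice(hu, c(1, 1)), mask = label_mask(labels))
}

test_that("areas, indices and percentages follow the unit conventions", {
  toy <- make_toy()
  m <- compute_metrics(toy$slice, toy$mask, height = 1.70)
  expect_equal(m$sma, 0.40)          # 40 px at 1x1 mm = 0.40 cm^2
  expect_equal(m$smi, 0.40 / 1.70^2)
  expect_equal(m$sfa, 0.30)
  expect_equal(m$vfa, 0.20)
  expect_equal(m$fat_pct, 50)        # (30 + 20 + 0) / 100 px
  expect_equal(m$pct_muscle + m$pct_sat + m$pct_vat + m$pct_imat +
                 m$pct_other + m$pct_bone, 100, tolerance = 1e-6)
  expect_equal(m$hu_muscle, 40)
  expect_equal(m$roi_mean_hu, (40 * 40 - 100 * 30 - 90 * 20 + 20 * 10) / 100)
  # hand arithmetic on a bigger area: 150 cm^2 at 1.70 m -> 51.90 cm^2/m^2
  expect_equal(150 / 1.70^2, 51.90, tolerance = 0.005)
})

test_that("absent tissues give zero area and a flagged NA mean HU", {
  toy <- make_toy()
  toy$mask$labels[toy$mask$labels == 3L] <- 5L  # remove all VAT
  m <- compute_metrics(toy$slice, toy$mask, height = 1.70)
  expect_equal(m$vfa, 0)
  expect_true(is.na(m$hu_vat))
  expect_true("vat" %in% attr(m, "empty_tissues"))
  expect_false(anyNA(m$fat_pct))
})

test_that("doubling pixel spacing quadruples areas, fixes percentages and HU", {
  toy <- make_toy()
  m1 <- compute_metrics(toy$slice, toy$mask, height = 1.70)
  big <- ct_slice(toy$slice$hu, c(2, 2))
  m2 <- compute_metrics(big, toy$mask, height = 1.70)
  expect_equal(m2$sma, 4 * m1$sma)
  expect_equal(m2$body_area, 4 * m1$body_area)
  expect_equal(m2$fat_pct, m1$fat_pct)
  expect_equal(m2$roi_mean_hu, m1$roi_mean_hu)
})

test_that("tissue areas sum to the body region area", {
  ph <- generate_phantom(small_phantom_spec())
  pred <- segment(ph$slices[[1]], derive_compartments(ph$slices[[1]]))
  m <- compute_metrics(ph$slices[[1]], pred, height = 1.70)
  tissue_sum <- m$sma + m$sfa + m$vfa + m$imat_area +
    (m$npx_other + m$npx_bone) * pixel_area_cm2(ph$slices[[1]])
  expect_equal(tissue_sum, m$body_area)
})

test_that("empty body mask and bad height are rejected", {
  toy <- make_toy()
  empty <- label_mask(matrix(0L, 10, 10))
  expect_error(compute_metrics(toy$slice, empty, 1.70), "empty body")
  expect_error(compute_metrics(toy$slice, toy$mask, -1), "height")
})

test_that("slice aggregation averages areas and pixel-weights mean HU", {
  toy <- make_toy()
  m <- compute_metrics(toy$slice, toy$mask, height = 1.70)
  # identical slices: mean aggregate equals any single slice
  agg <- aggregate_slices(list(m, m, m), mode = "mean")
  for (col in c("sma", "sfa", "vfa", "fat_pct", "roi_mean_hu")) {
    expect_equal(agg[[col]], m[[col]])
  }
  expect_equal(agg$n_slices_aggregated, 3L)

  # two slices with muscle areas 1.0 and 2.0 cm^2 -> mean 1.5
  toy2 <- make_toy()
  extra <- which(toy2$mask$labels == 5L)
  toy2$mask$labels[extra] <- 2L
  toy2$slice$hu[extra] <- 0
  m2 <- compute_metrics(toy2$slice, toy2$mask, height = 1.70)
  agg2 <- aggregate_slices(list(m, m2), mode = "mean")
  expect_equal(agg2$sma, (m$sma + m2$sma) / 2)

  # weighted mean HU oracle: 40 px at 40 HU + 50 px at (40*40+0*10)/50 HU
  w <- c(m$npx_muscle, m2$npx_muscle)
  expect_equal(agg2$hu_muscle,
               sum(c(m$hu_muscle, m2$hu_muscle) * w) / sum(w))

  # single mode picks the designated slice
  expect_equal(aggregate_slices(list(m, m2), mode = "single", index = 2)$sma,
               m2$sma)
  expect_error(aggregate_slices(list(), mode = "mean"), "empty")
})

test_that("mean HU aggregation is pixel-weighted, not slice-weighted", {
  # slice A: 100 muscle px at 40 HU; slice B: 300 muscle px at 0 HU -> 10 HU
  a_lab <- matrix(0L, 20, 20); a_lab[1:100] <- 2L
  b_lab <- matrix(0L, 20, 20); b_lab[1:300] <- 2L
  a_hu <- matrix(-1000, 20, 20); a_hu[1:100] <- 40
  b_hu <- matrix(-1000, 20, 20); b_hu[1:300] <- 0
  suppressWarnings({
    ma <- compute_metrics(ct_slice(a_hu, c(1, 1)), label_mask(a_lab), 1.7)
    mb <- compute_metrics(ct_slice(b_hu, c(1, 1)), label_mask(b_lab), 1.7)
  })
  agg <- aggregate_slices(list(ma, mb), mode = "mean")
  expect_equal(agg$hu_muscle, 10)
})
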