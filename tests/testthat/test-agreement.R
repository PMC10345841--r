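test_that("pearson correlation handles identity, anti-identity and oracle", {
  x <- c(3, 7, 1, 9, 4, 6)
  expect_equal(pearson_with_ci(x, x)$r, 1.0)
  expect_equal(pearson_with_ci(-(x - mean(x)), x)$r, -1.0)

  set.seed(5)
  a <- rnorm(25); b <- 0.6 * a + rnorm(25)
  got <- pearson_with_ci(a, b)
  # brute-force covariance-formula computation
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, r_oracle, tolerance = 1e-12)
  # Fisher-z interval recomputed by hand
  z <- atanh(r_oracle); se <- 1 / sqrt(25 - 3)
  expect_equal(got$ci_low, tanh(z - qnorm(0.975) * se), tolerance = 1e-9)
  expect_equal(got$ci_high, tanh(z + qnorm(0.975) * se), tolerance = 1e-9)
  expect_error(pearson_with_ci(rep(1, 5), 1:5), "zero variance")
})

test_that("pearson r is invariant under positive affine rescaling", {
  set.seed(6)
  a <- rnorm(30); b <- a + rnorm(30)
  r0 <- pearson_with_ci(a, b)$r
  expect_equal(pearson_with_ci(3 * a + 10, b)$r, r0)
  expect_equal(pearson_with_ci(a, 0.2 * b - 4)$r, r0)
})

test_that("Bland-Altman bias and limits match hand computation", {
  ba0 <- bland_altman(c(10, 11, 12), c(10, 11, 12))
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  ba5 <- bland_altman(c(15, 16, 17), c(10, 11, 12))
  expect_equal(ba5$bias, 5)
  expect_equal(c(ba5$loa_low, ba5$loa_high), c(5, 5))

  # differences {-1, 0, 1}: sd = 1 with the n-1 denominator
  ba <- bland_altman(c(9, 11, 13), c(10, 11, 12))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)
  expect_equal(ba$data$mean, c(9.5, 11, 12.5))
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("about 95% of differences fall inside the limits of agreement", {
  set.seed(9)
  ref <- runif(2e4, 40, 90)
  est <- ref + rnorm(2e4, 1, 4)
  ba <- bland_altman(est, ref)
  inside <- mean(ba$data$diff >= ba$loa_low & ba$data$diff <= ba$loa_high)
  expect_gt(inside, 0.93)
  expect_lt(inside, 0.97)
})

test_that("error grid bins relative errors into contiguous bands", {
  eg <- error_grid(c(105, 115, 130), c(100, 100, 100))
  expect_equal(unname(eg$fractions), c(1, 1, 1) / 3)
  expect_equal(sum(eg$fractions), 1)
  expect_equal(names(eg$fractions), c("<10%", "10%-25%", ">=25%"))

  all_small <- error_grid(c(101, 99, 103), c(100, 100, 100))
  expect_equal(unname(all_small$fractions), c(1, 0, 0))
  ident <- error_grid(c(5, 6, 7), c(5, 6, 7))
  expect_equal(unname(ident$fractions[1]), 1)

  # band edges: exactly 10% goes to the middle band, exactly 25% to the top
  edge <- error_grid(c(110, 125), c(100, 100))
  expect_equal(unname(edge$fractions), c(0, 0.5, 0.5))
  expect_error(error_grid(c(1, 2), c(0, 2)), "reference")
})

test_that("QQ pairing recovers slope and intercept of normal samples", {
  n <- 200
  exact <- qnorm((seq_len(n) - 0.5) / n)
  qq <- qq_normality(exact)
  expect_equal(qq$slope, 1, tolerance = 1e-6)
  expect_equal(qq$intercept, 0, tolerance = 1e-6)

  set.seed(13)
  qq2 <- qq_normality(rnorm(1e4))
  expect_gt(qq2$slope, 0.95); expect_lt(qq2$slope, 1.05)

  qq3 <- qq_normality(rep(4, 10))
  expect_true(qq3$degenerate)
  expect_equal(qq3$slope, 0)
})

test_that("agreement grid mirrors FM/FFM rows and keeps the reference schema", {
  co <- generate_cohort(cohort_spec(n_subjects = 30, noise_sd = 0, seed = 2L))
  tab <- summarize_table2(co$subjects, list("1 slice" = co$metrics))
  expect_equal(nrow(tab), 6)  # 3 models x FM/FFM for one slice mode
  expect_setequal(tab$model, c("m1", "m2", "focusedon"))

  # generative identity: density-model FM agrees perfectly on its own cohort
  fo_fm <- tab[tab$model == "focusedon" & tab$component == "FM", ]
  expect_equal(fo_fm$bias, 0, tolerance = 1e-9)
  expect_equal(fo_fm$loa_low, 0, tolerance = 1e-9)
  expect_equal(fo_fm$pearson_r, 1, tolerance = 1e-9)

  # derived FFM: Pearson omitted, bias mirrors FM with opposite sign
  fo_ffm <- tab[tab$model == "focusedon" & tab$component == "FFM", ]
  expect_true(is.na(fo_ffm$pearson_r))
  noisy <- generate_cohort(cohort_spec(n_subjects = 30, noise_sd = 3,
                                       seed = 21L))
  tabn <- summarize_table2(noisy$subjects, list(m = noisy$metrics))
  fm_row <- tabn[tabn$model == "focusedon" & tabn$component == "FM", ]
  ffm_row <- tabn[tabn$model == "focusedon" & tabn$component == "FFM", ]
  expect_equal(ffm_row$bias, -fm_row$bias)
  expect_equal(ffm_row$loa_low, -fm_row$loa_high)

  expect_error(summarize_table2(co$subjects["id"], list(m = co$metrics)),
               "dxa")
})

test_that("the derived-FFM correlation can be displayed on request", {
  co <- generate_cohort(cohort_spec(n_subjects = 20, noise_sd = 2, seed = 4L))
  tab <- summarize_table2(co$subjects, list(m = co$metrics),
                          models = "focusedon", show_derived_ffm_r = TRUE)
  expect_false(anyNA(tab$pearson_r))
})
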