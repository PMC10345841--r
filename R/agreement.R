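check_paired <- function(estimate, reference, min_n = 3L) {
  if (length(estimate) != length(reference)) {
    stop("estimate and reference lengths differ", call. = FALSE)
  }
  if (length(estimate) < min_n) {
    stop("need at least ", min_n, " paired observations", call. = FALSE)
  }
  if (anyNA(c(estimate, reference)) || any(!is.finite(c(estimate, reference)))) {
    stop("paired series must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param estimate,reference Paired numeric vectors (n >= 4 so the CI is
#'   defined).
#' @param level Confidence level (default 0.95).
#' @return List with `r`, `ci_low`, `ci_high`, `level`, `n`, `p_value`.
#' @export
pearson_with_ci <- function(estimate, reference, level = 0.95) {
  check_paired(estimate, reference, min_n = 4L)
  if (stats::var(estimate) == 0 || stats::var(reference) == 0) {
    stop("zero variance in a series; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(estimate, reference, method = "pearson",
                        conf.level = level)
  list(r = unname(ct$estimate), ci_low = ct$conf.int[1],
       ci_high = ct$conf.int[2], level = level,
       n = length(estimate), p_value = ct$p.value)
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are taken as `estimate - reference` (model minus DXA), so a
#' model that underestimates shows a negative bias. Limits of agreement
#' are `bias +/- 1.96 * SD(differences)` with the n-1 SD denominator.
#'
#' @param estimate,reference Paired numeric vectors (n >= 3).
#' @return List of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, `n` and `data` (per-subject pair means vs differences,
#'   i.e. the plot coordinates).
#' @export
#' @examples
#' ba <- bland_altman(c(10, 11, 12), c(11, 11, 11))
#' c(ba$bias, ba$loa_low, ba$loa_high)
bland_altman <- function(estimate, reference) {
  check_paired(estimate, reference, min_n = 3L)
  d <- estimate - reference
  bias <- mean(d)
  sd_d <- stats::sd(d)
  structure(
    list(bias = bias, sd_diff = sd_d,
         loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
         n = length(d),
         data = data.frame(mean = (estimate + reference) / 2, diff = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f, LoA [%.3f, %.3f]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Base-graphics Bland-Altman plot
#' @param x A [bland_altman()] result. @param ... Passed to `plot`.
#' @return `x`, invisibly.
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$data$mean, x$data$diff,
                 xlab = "mean of methods (kg)",
                 ylab = "estimate - reference (kg)", ...)
  graphics::abline(h = c(x$loa_low, x$bias, x$loa_high),
                   lty = c(2, 1, 2), col = c("red", "blue", "red"))
  invisible(x)
}

#' Simplified error grid of relative errors
#'
#' Per-subject relative error `|estimate - reference| / reference`,
#' binned into contiguous severity bands (defaults: below 10%, 10% to
#' below 25%, 25% and above).
#'
#' @param estimate,reference Paired vectors; `reference` must be > 0.
#' @param bands Interior band edges as fractions (default `c(0.10, 0.25)`).
#' @return List: `fractions` (named, summing to 1), `counts`,
#'   `relative_error` per subject, `n`.
#' @export
#' @examples
#' error_grid(c(105, 115, 130), c(100, 100, 100))$fractions
error_grid <- function(estimate, reference, bands = c(0.10, 0.25)) {
  check_paired(estimate, reference, min_n = 1L)
  if (any(reference <= 0)) {
    stop("reference values must be > 0 for relative error", call. = FALSE)
  }
  stopifnot(is.numeric(bands), !is.unsorted(bands), all(bands > 0))
  rel <- abs(estimate - reference) / reference
  edges <- c(0, bands, Inf)
  pct <- function(b) sprintf("%g%%", 100 * b)
  nms <- c(paste0("<", pct(bands[1])),
           if (length(bands) > 1) {
             paste0(pct(bands[-length(bands)]), "-", pct(bands[-1]))
           },
           paste0(">=", pct(bands[length(bands)])))
  counts <- as.vector(table(cut(rel, edges, labels = nms, right = FALSE,
                                include.lowest = TRUE)))
  names(counts) <- nms
  list(fractions = counts / length(rel), counts = counts,
       relative_error = rel, n = length(rel))
}

#' Quantile-quantile pairing against the standard normal
#'
#' Orders the sample and pairs it with standard-normal quantiles at
#' plotting positions `(i - 0.5) / n`, then reports the OLS line through
#' the pairs (slope estimates the SD, intercept the mean, for normal
#' data).
#'
#' @param values Numeric vector, n >= 3.
#' @return List: `theoretical`, `sample` (ordered), `slope`, `intercept`,
#'   `degenerate` (TRUE when the sample is constant, in which case the
#'   slope is 0).
#' @export
qq_normality <- function(values) {
  if (length(values) < 3L || anyNA(values)) {
    stop("need at least 3 finite values", call. = FALSE)
  }
  n <- length(values)
  theo <- stats::qnorm((seq_len(n) - 0.5) / n)
  samp <- sort(values)
  degenerate <- stats::sd(values) == 0
  if (degenerate) {
    slope <- 0; intercept <- samp[1]
  } else {
    ft <- stats::lm(samp ~ theo)
    slope <- unname(stats::coef(ft)[2]); intercept <- unname(stats::coef(ft)[1])
  }
  list(theoretical = theo, sample = samp, slope = slope,
       intercept = intercept, degenerate = degenerate)
}

#' Full agreement summary for one estimate/reference pair
#'
#' One Table-of-agreement cell group: Pearson r with CI, Bland-Altman
#' bias and limits, and error-grid band fractions.
#'
#' @param estimate,reference Paired vectors (kg).
#' @param include_pearson Set `FALSE` for derived quantities whose
#'   correlation would be redundant (reported as `NA`).
#' @param bands Error-grid edges.
#' @return One-row `data.frame`: `n`, `pearson_r`, `r_ci_low`,
#'   `r_ci_high`, `bias`, `loa_low`, `loa_high`, one `band_*` column per
#'   error band.
#' @export
agreement_summary <- function(estimate, reference, include_pearson = TRUE,
                              bands = c(0.10, 0.25)) {
  ba <- bland_altman(estimate, reference)
  eg <- error_grid(estimate, reference, bands)
  if (include_pearson) {
    pr <- pearson_with_ci(estimate, reference)
    r <- pr$r; lo <- pr$ci_low; hi <- pr$ci_high
  } else {
    r <- lo <- hi <- NA_real_
  }
  out <- data.frame(n = ba$n, pearson_r = r, r_ci_low = lo, r_ci_high = hi,
                    bias = ba$bias, loa_low = ba$loa_low,
                    loa_high = ba$loa_high)
  bf <- eg$fractions
  names(bf) <- paste0("band_", gsub("[^0-9a-zA-Z]+", "_", names(bf)))
  cbind(out, as.data.frame(as.list(bf)))
}

#' Estimate FM and FFM for a cohort with one of the three models
#'
#' @param metrics Per-subject CT metric table with columns `id`,
#'   `fat_area_cm2`, `muscle_area_cm2`, `fat_pct`, `roi_mean_hu`,
#'   `fat_mean_hu` (area models use the areas; the density-weighted model
#'   uses the percentage and HU columns plus weight).
#' @param subjects Subject table with `id` and `weight`.
#' @param model `"m1"`, `"m2"` or `"focusedon"`.
#' @param coefficients Optional replacement coefficient set (as returned
#'   by [model_coefficients()] or built from [fit_linear()] results);
#'   refits override the published defaults explicitly, never silently.
#' @return `data.frame` with `id`, `model`, `fm_est`, `ffm_est`.
#' @export
estimate_masses <- function(metrics, subjects,
                            model = c("m1", "m2", "focusedon"),
                            coefficients = NULL) {
  model <- match.arg(model)
  coefs <- if (is.null(coefficients)) model_coefficients(model) else coefficients
  df <- merge(subjects, metrics, by = "id", sort = FALSE)
  if (nrow(df) == 0L) stop("no overlapping ids", call. = FALSE)
  if (model == "focusedon") {
    fm <- model3_fm(df$weight, df$roi_mean_hu, df$fat_pct, df$fat_mean_hu,
                    model = coefs$fm)
    ffm <- model3_ffm(df$weight, fm)
  } else {
    evalf <- switch(model, m1 = list(model1_fm, model1_ffm),
                    m2 = list(model2_fm, model2_ffm))
    fm <- evalf[[1]](df$fat_area_cm2, model = coefs$fm)
    ffm <- evalf[[2]](df$muscle_area_cm2, model = coefs$ffm)
  }
  data.frame(id = df$id, model = model, fm_est = fm, ffm_est = ffm,
             stringsAsFactors = FALSE)
}

#' Agreement grid across models, components and slice modes
#'
#' Produces the standard validation layout: for each slice mode, each
#' model and each of FM/FFM, the Pearson correlation and the Bland-Altman
#' -1.96 SD / mean / +1.96 SD error columns against the DXA reference.
#' The Pearson cell of the density-weighted model's FFM row is omitted by
#' default, since that FFM is derived as weight minus FM rather than
#' estimated directly.
#'
#' @param subjects Subject table with `id`, `weight`, `dxa_fm`, `dxa_ffm`.
#' @param metrics_by_mode Named list of per-subject metric tables, one per
#'   slice mode (e.g. `list("1 slice" = m1s, "16 slices" = m16s)`).
#' @param models Character vector of model names.
#' @param show_derived_ffm_r Report the Pearson r for the derived FFM of
#'   the density-weighted model (default `FALSE`).
#' @return Long `data.frame`, one row per slice mode x model x component,
#'   with agreement columns from [agreement_summary()].
#' @export
summarize_table2 <- function(subjects, metrics_by_mode,
                             models = c("m1", "m2", "focusedon"),
                             show_derived_ffm_r = FALSE) {
  if (!all(c("dxa_fm", "dxa_ffm") %in% names(subjects))) {
    stop("subject table lacks DXA reference columns dxa_fm/dxa_ffm",
         call. = FALSE)
  }
  stopifnot(is.list(metrics_by_mode), length(names(metrics_by_mode)) > 0)
  rows <- list()
  for (mode in names(metrics_by_mode)) {
    for (model in models) {
      est <- estimate_masses(metrics_by_mode[[mode]], subjects, model)
      df <- merge(subjects, est, by = "id", sort = FALSE)
      for (component in c("ffm", "fm")) {
        e <- df[[paste0(component, "_est")]]
        r <- df[[paste0("dxa_", component)]]
        keep_r <- !(model == "focusedon" && component == "ffm" &&
                      !show_derived_ffm_r)
        s <- agreement_summary(e, r, include_pearson = keep_r)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(slice_mode = mode, model = model,
                           component = toupper(component),
                           stringsAsFactors = FALSE), s)
      }
    }
  }
  do.call(rbind, rows)
}
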