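metric_tissues <- c("sat", "muscle", "vat", "imat", "other", "bone")

#' Per-tissue CT body-composition variables for one slice
#'
#' Computes the standard L3 variable set: skeletal muscle area (SMA, cm^2)
#' and index (SMI = SMA / height^2, cm^2/m^2), intramuscular (IMAT),
#' visceral (VFA) and subcutaneous (SFA) fat areas with their indices
#' (IIMAT, VFI, SFI), each tissue's share of the body region (%), mean HU
#' per tissue, the overall fat percentage (SAT + VAT + IMAT share of the
#' body region) and the mean HU of the whole body region (the quantity the
#' density-weighted mass model converts to a whole-body density).
#'
#' Pixel areas convert as `count * row_spacing * col_spacing / 100`
#' (mm^2 to cm^2). Mean HU of an absent tissue is `NA` with the tissue
#' listed in the `empty_tissues` field rather than poisoning aggregates.
#'
#' @param slice A [ct_slice()].
#' @param mask A [label_mask()] aligned with the slice.
#' @param height Subject height in m (> 0).
#' @return A one-row `data.frame` of class `tissue_metrics` with columns
#'   `sma`, `smi`, `imat_area`, `iimat`, `vfa`, `vfi`, `sfa`, `sfi`,
#'   `pct_<tissue>`, `hu_<tissue>`, `npx_<tissue>`, `fat_pct`,
#'   `roi_mean_hu`, `body_area`, `n_slices_aggregated`.
#' @export
#' @examples
#' sl <- ct_slice(matrix(c(rep(40, 50), rep(-100, 14)), 8, 8), c(1, 1))
#' mk <- label_mask(matrix(c(rep(2L, 50), rep(1L, 14)), 8, 8))
#' compute_metrics(sl, mk, height = 1.70)$sma
compute_metrics <- function(slice, mask, height) {
  stopifnot(inherits(slice, "ct_slice"), inherits(mask, "label_mask"))
  check_aligned(slice, mask)
  check_positive(height, "height", 1L)
  lg <- mask$legend
  labels <- mask$labels
  body_px <- sum(labels > 0L)
  if (body_px == 0L) stop("empty body mask; no metrics to compute",
                          call. = FALSE)
  pxa <- pixel_area_cm2(slice)

  npx <- vapply(metric_tissues, function(t) {
    if (t %in% names(lg)) sum(labels == lg[[t]]) else 0L
  }, integer(1))
  area <- npx * pxa
  pct <- npx / body_px * 100
  hu <- vapply(metric_tissues, function(t) {
    if (npx[[t]] > 0) mean(slice$hu[labels == lg[[t]]]) else NA_real_
  }, numeric(1))

  out <- data.frame(
    sma = area[["muscle"]], smi = area[["muscle"]] / height^2,
    imat_area = area[["imat"]], iimat = area[["imat"]] / height^2,
    vfa = area[["vat"]], vfi = area[["vat"]] / height^2,
    sfa = area[["sat"]], sfi = area[["sat"]] / height^2,
    fat_pct = pct[["sat"]] + pct[["vat"]] + pct[["imat"]],
    roi_mean_hu = mean(slice$hu[labels > 0L]),
    body_area = body_px * pxa,
    height = height,
    n_slices_aggregated = 1L
  )
  for (t in metric_tissues) {
    out[[paste0("pct_", t)]] <- pct[[t]]
    out[[paste0("hu_", t)]] <- hu[[t]]
    out[[paste0("npx_", t)]] <- npx[[t]]
  }
  out$npx_body <- body_px
  attr(out, "empty_tissues") <- metric_tissues[npx == 0]
  class(out) <- c("tissue_metrics", "data.frame")
  out
}

#' Aggregate per-slice metrics over a slice stack
#'
#' `mode = "mean"` averages areas, indices and percentages across slices
#' and pixel-count-weights the per-tissue and whole-region mean HU (so the
#' aggregate mean HU equals the mean over all pixels of all slices, not a
#' mean of slice means). `mode = "single"` selects one designated slice.
#'
#' @param metrics_list List of `tissue_metrics` rows from
#'   [compute_metrics()].
#' @param mode `"mean"` or `"single"`.
#' @param index Slice index when `mode = "single"`.
#' @return A one-row `tissue_metrics` with `n_slices_aggregated` recorded.
#' @export
aggregate_slices <- function(metrics_list, mode = c("mean", "single"),
                             index = 1L) {
  mode <- match.arg(mode)
  if (length(metrics_list) == 0L) stop("empty metrics list", call. = FALSE)
  stopifnot(all(vapply(metrics_list, inherits, TRUE, "tissue_metrics")))
  if (mode == "single") {
    if (index < 1L || index > length(metrics_list)) {
      stop("designated slice index out of range", call. = FALSE)
    }
    out <- metrics_list[[index]]
    out$n_slices_aggregated <- 1L
    return(out)
  }
  df <- do.call(rbind, lapply(metrics_list, as.data.frame))
  out <- df[1, , drop = FALSE]
  mean_cols <- c("sma", "smi", "imat_area", "iimat", "vfa", "vfi",
                 "sfa", "sfi", "fat_pct", "body_area",
                 paste0("pct_", metric_tissues))
  for (col in mean_cols) out[[col]] <- mean(df[[col]])
  for (t in metric_tissues) {
    w <- df[[paste0("npx_", t)]]
    h <- df[[paste0("hu_", t)]]
    out[[paste0("hu_", t)]] <-
      if (sum(w) > 0) sum(h[w > 0] * w[w > 0]) / sum(w) else NA_real_
    out[[paste0("npx_", t)]] <- sum(w)
  }
  out$roi_mean_hu <- sum(df$roi_mean_hu * df$npx_body) / sum(df$npx_body)
  out$npx_body <- sum(df$npx_body)
  out$n_slices_aggregated <- nrow(df)
  class(out) <- c("tissue_metrics", "data.frame")
  out
}

#' Segment a slice stack and compute aggregated metrics
#'
#' Convenience wrapper: derives compartments, segments and computes
#' metrics per slice, then aggregates.
#'
#' @param slices List of [ct_slice()].
#' @param height Subject height (m).
#' @param thresholds A [threshold_set()].
#' @param mode,index Passed to [aggregate_slices()].
#' @return List with `per_slice` (list of `tissue_metrics`), `aggregate`
#'   (one `tissue_metrics` row) and `masks` (list of [label_mask()]).
#' @export
analyze_stack <- function(slices, height, thresholds = threshold_set(),
                          mode = c("mean", "single"), index = 1L) {
  mode <- match.arg(mode)
  masks <- lapply(slices, function(s) {
    segment(s, derive_compartments(s, thresholds), thresholds)
  })
  per_slice <- mapply(compute_metrics, slices, masks,
                      MoreArgs = list(height = height), SIMPLIFY = FALSE)
  list(per_slice = per_slice,
       aggregate = aggregate_slices(per_slice, mode = mode, index = index),
       masks = masks)
}
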