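#' Construct a calibrated CT slice
#'
#' A `ct_slice` is the unit of segmentation: a 2-D matrix of Hounsfield
#' units (HU) plus the physical pixel spacing needed to turn pixel counts
#' into areas. Values are expected to be calibrated HU (water = 0,
#' air = -1000); a warning is issued if any pixel falls outside the
#' plausible CT range [-1100, 3100].
#'
#' @param hu Numeric matrix of Hounsfield units (rows = image rows).
#' @param pixel_spacing Numeric pair, (row, column) spacing in mm.
#' @param slice_id Optional label for the slice.
#' @return An object of class `ct_slice`: a list with elements `hu`,
#'   `pixel_spacing`, `slice_id`.
#' @export
#' @examples
#' sl <- ct_slice(matrix(0, 4, 4), c(1, 1))
#' pixel_area_cm2(sl)
ct_slice <- function(hu, pixel_spacing, slice_id = NA_character_) {
  if (!is.matrix(hu) || !is.numeric(hu)) {
    stop_field("hu", "must be a numeric matrix")
  }
  if (anyNA(hu) || any(!is.finite(hu))) {
    stop_field("hu", "must contain only finite values")
  }
  check_positive(pixel_spacing, "pixel_spacing", n = 2L)
  if (any(hu < -1100) || any(hu > 3100)) {
    warning("HU values outside the plausible CT range [-1100, 3100]",
            call. = FALSE)
  }
  structure(
    list(hu = hu, pixel_spacing = as.numeric(pixel_spacing),
         slice_id = as.character(slice_id)),
    class = "ct_slice"
  )
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("ct_slice '%s': %d x %d px, spacing %.3g x %.3g mm, HU [%g, %g]\n",
              x$slice_id, nrow(x$hu), ncol(x$hu),
              x$pixel_spacing[1], x$pixel_spacing[2],
              min(x$hu), max(x$hu)))
  invisible(x)
}

#' Area of one pixel in cm^2
#' @param slice A `ct_slice`.
#' @return Pixel area in cm^2 (mm^2 / 100).
#' @export
pixel_area_cm2 <- function(slice) {
  stopifnot(inherits(slice, "ct_slice"))
  slice$pixel_spacing[1] * slice$pixel_spacing[2] / 100
}

#' Default tissue label legend
#'
#' Integer codes shared by the phantom generator and the segmenter:
#' 0 = background, then subcutaneous fat (sat), skeletal muscle,
#' visceral fat (vat), intramuscular fat (imat), unclassified body
#' tissue (other) and a bone placeholder.
#' @return Named integer vector mapping tissue name to label code.
#' @export
tissue_legend <- function() {
  c(sat = 1L, muscle = 2L, vat = 3L, imat = 4L, other = 5L, bone = 6L)
}

#' Construct a label mask aligned with a CT slice
#'
#' @param labels Integer matrix of tissue codes (0 = background).
#' @param legend Named integer vector mapping tissue names to codes.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, legend = tissue_legend()) {
  if (!is.matrix(labels)) stop_field("labels", "must be an integer matrix")
  storage.mode(labels) <- "integer"
  if (anyNA(labels)) stop_field("labels", "must not contain NA")
  bad <- setdiff(unique(as.vector(labels)), c(0L, unname(legend)))
  if (length(bad)) {
    stop_field("labels", paste("codes outside legend:",
                               paste(bad, collapse = ", ")))
  }
  structure(list(labels = labels, legend = legend), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c(0L, unname(x$legend)),
                      labels = c("background", names(x$legend))))
  cat("label_mask", nrow(x$labels), "x", ncol(x$labels), "px\n")
  print(tab)
  invisible(x)
}

check_aligned <- function(slice, mask) {
  if (!identical(dim(slice$hu), dim(mask$labels))) {
    stop("slice and mask shapes differ", call. = FALSE)
  }
  invisible(TRUE)
}

#' Decode stored CT pixel values to Hounsfield units
#'
#' Applies the linear rescale carried in CT file headers
#' (`HU = stored * slope + intercept`). All readers in this package calibrate
#' at read time; raw stored values never propagate into analysis.
#'
#' @param stored Numeric vector/matrix of stored pixel values.
#' @param slope,intercept Rescale slope and intercept from the image header.
#' @return Values in HU, same shape as `stored`.
#' @export
#' @examples
#' decode_stored_values(1024, slope = 1, intercept = -1024)  # 0 HU
decode_stored_values <- function(stored, slope, intercept) {
  if (!is.numeric(slope) || !is.numeric(intercept) ||
      anyNA(c(slope, intercept))) {
    stop("rescale slope/intercept missing or non-numeric; cannot calibrate HU",
         call. = FALSE)
  }
  stored * slope + intercept
}

#' Write a stack of CT slices as an uncompressed NIfTI-1 volume
#'
#' @param slices List of `ct_slice` objects with identical shape and spacing.
#' @param path Output path ending in `.nii` (or `.nii.gz`).
#' @param slice_thickness Through-plane spacing in mm recorded in the header.
#' @return `path`, invisibly.
#' @export
write_ct_nifti <- function(slices, path, slice_thickness = 5) {
  stopifnot(length(slices) >= 1, all(vapply(slices, inherits, TRUE, "ct_slice")))
  sp <- slices[[1]]$pixel_spacing
  arr <- vapply(slices, function(s) s$hu, slices[[1]]$hu)
  dim(arr) <- c(dim(slices[[1]]$hu), length(slices))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(sp, slice_thickness)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a CT volume into a list of calibrated slices
#'
#' NIfTI values are assumed already calibrated to HU (the usual convention
#' for research NIfTI exports; `scl_slope`/`scl_inter` are applied by the
#' reader). DICOM series are not read directly: convert them to NIfTI first
#' (e.g. with dcm2niix), or calibrate raw pixel data yourself through
#' [decode_stored_values()].
#'
#' @param path Path to a NIfTI file.
#' @param format Only `"nifti"` is supported; `"dicom"` raises an error
#'   explaining the conversion route.
#' @return List of `ct_slice`, ordered by slice index.
#' @export
read_ct <- function(path, format = c("nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "dicom") {
    stop("direct DICOM reading is not supported; convert the series to ",
         "NIfTI (e.g. dcm2niix) or use decode_stored_values() on raw ",
         "pixel data", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 2 || any(!is.finite(pd[1:2])) || any(pd[1:2] <= 0)) {
    stop("pixel spacing (pixdim) missing or non-positive in ", path,
         "; areas would be wrong", call. = FALSE)
  }
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  lapply(seq_len(dim(arr)[3]), function(k) {
    ct_slice(arr[, , k], pd[1:2], slice_id = sprintf("slice%03d", k))
  })
}

#' Write label masks as an integer NIfTI volume with a JSON legend sidecar
#'
#' @param masks List of `label_mask` objects.
#' @param path Output `.nii` path; the legend is written to
#'   `paste0(path, ".legend.json")`.
#' @param pixel_spacing mm pair recorded in the header.
#' @return `path`, invisibly.
#' @export
write_labels_nifti <- function(masks, path, pixel_spacing = c(1, 1)) {
  stopifnot(length(masks) >= 1, all(vapply(masks, inherits, TRUE, "label_mask")))
  arr <- vapply(masks, function(m) m$labels, masks[[1]]$labels)
  dim(arr) <- c(dim(masks[[1]]$labels), length(masks))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(pixel_spacing, 5)
  RNifti::writeNifti(img, path, datatype = "int16")
  jsonlite::write_json(as.list(masks[[1]]$legend),
                       paste0(path, ".legend.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read label masks written by [write_labels_nifti()]
#' @param path `.nii` path; legend read from the `.legend.json` sidecar.
#' @return List of `label_mask`.
#' @export
read_labels_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  legend_path <- paste0(path, ".legend.json")
  legend <- if (file.exists(legend_path)) {
    unlist(jsonlite::read_json(legend_path))
  } else tissue_legend()
  legend <- stats::setNames(as.integer(legend), names(legend))
  lapply(seq_len(dim(arr)[3]), function(k) {
    label_mask(arr[, , k], legend = legend)
  })
}

cohort_required_cols <- c("id", "weight", "height")

#' Read and validate a cohort table
#'
#' Expects a comma-separated UTF-8 file with a header row and at least the
#' columns `id`, `weight` (kg) and `height` (m). `bmi` is recomputed as
#' weight/height^2 when absent. Optional DXA reference columns `dxa_fm` and
#' `dxa_ffm` (kg) are sanity-checked: their sum may not exceed weight by
#' more than 5% (DXA excludes some mass, so it should not exceed scale
#' weight at all in practice).
#'
#' @param path CSV path.
#' @return A validated `data.frame` of subjects.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("cohort file is empty: ", path, call. = FALSE)
    return(df)
  }
  validate_cohort(df)
}

#' Validate an in-memory cohort table
#' @param df Data frame with at least `id`, `weight` (kg), `height` (m).
#' @return The validated (possibly bmi-augmented) data frame.
#' @export
validate_cohort <- function(df) {
  missing_cols <- setdiff(cohort_required_cols, names(df))
  if (length(missing_cols)) {
    stop("cohort table missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) {
    stop("duplicate subject ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  for (col in c("weight", "height")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v <= 0)
    if (length(bad)) {
      stop(sprintf("non-numeric or non-positive %s in row(s): %s",
                   col, paste(bad, collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- v
  }
  bmi <- df$weight / df$height^2
  if (is.null(df$bmi)) {
    df$bmi <- bmi
  } else if (any(abs(df$bmi - bmi) > 0.05, na.rm = TRUE)) {
    stop("bmi column inconsistent with weight/height^2", call. = FALSE)
  }
  if (all(c("dxa_fm", "dxa_ffm") %in% names(df))) {
    over <- which(df$dxa_fm + df$dxa_ffm > df$weight * 1.05)
    if (length(over)) {
      stop("dxa_fm + dxa_ffm exceeds 105% of weight in row(s): ",
           paste(over, collapse = ", "), call. = FALSE)
    }
  }
  df
}

#' Write a cohort table as CSV
#' @param df Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
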