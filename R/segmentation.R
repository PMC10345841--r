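#' HU threshold windows for tissue classification
#'
#' Standard Hounsfield-unit windows: -29 to 150 HU for skeletal muscle,
#' -190 to -30 HU for subcutaneous adipose tissue and -150 to -50 HU for
#' visceral adipose tissue. Bounds are inclusive at both ends. Note the
#' VAT window is contained in the SAT window: HU alone cannot separate the
#' two fat depots, which is why classification is compartment-first (see
#' [derive_compartments()]).
#'
#' @param muscle,sat,vat Length-2 numeric `(low, high)` HU intervals.
#' @return Object of class `threshold_set`.
#' @export
threshold_set <- function(muscle = c(-29, 150),
                          sat = c(-190, -30),
                          vat = c(-150, -50)) {
  for (nm in c("muscle", "sat", "vat")) {
    iv <- get(nm)
    if (!is.numeric(iv) || length(iv) != 2L || anyNA(iv) || iv[1] > iv[2]) {
      stop_field(nm, "must be a (low, high) HU interval with low <= high")
    }
  }
  structure(list(muscle = muscle, sat = sat, vat = vat),
            class = "threshold_set")
}

in_window <- function(hu, window) hu >= window[1] & hu <= window[2]

# labels of connected components (4-connectivity) that contain any TRUE of
# `touch`; returns logical mask of those whole components
components_touching <- function(mask, touch) {
  lab <- EBImage::bwlabel(mask)
  hit <- unique(lab[touch & mask > 0])
  hit <- hit[hit > 0]
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (length(hit)) out[lab %in% hit] <- TRUE
  out
}

#' Derive anatomical compartments from a CT slice
#'
#' Because the SAT and VAT threshold windows overlap in HU, fat depots are
#' separated spatially. The body is the largest connected component above
#' `body_hu_min`, hole-filled. Within it, candidate muscle pixels (muscle
#' HU window) form the abdominal-wall band when their connected components
#' are adjacent to the subcutaneous zone; the subcutaneous zone is the
#' non-muscle-window region connected to the skin surface; everything
#' deeper is the visceral cavity.
#'
#' Small non-muscle pockets fully enclosed by the wall (fat infiltrating
#' the muscle, which the IMAT label later picks up) are absorbed into the
#' wall band when smaller than `hole_max_mm2`; the visceral cavity, which
#' is also enclosed by the wall but orders of magnitude larger, is not.
#'
#' @param slice A [ct_slice()].
#' @param thresholds A [threshold_set()]; the muscle window defines wall
#'   candidates.
#' @param body_hu_min HU threshold separating body from surrounding air.
#' @param hole_max_mm2 Maximum area of an enclosed non-muscle pocket that
#'   still counts as part of the wall band.
#' @return Object of class `compartment_map`: logical matrices `body`,
#'   `wall`, `subcutaneous`, `cavity` (pairwise disjoint;
#'   wall + subcutaneous + cavity = body), plus a `truncated` flag set when
#'   the body touches the image edge.
#' @export
derive_compartments <- function(slice, thresholds = threshold_set(),
                                body_hu_min = -500, hole_max_mm2 = 300) {
  stopifnot(inherits(slice, "ct_slice"))
  hu <- slice$hu
  fg <- hu > body_hu_min
  if (!any(fg)) stop("no body region found above ", body_hu_min, " HU",
                     call. = FALSE)
  lab <- EBImage::bwlabel(fg)
  counts <- tabulate(lab[lab > 0])
  body <- lab == which.max(counts)
  body <- EBImage::fillHull(body) > 0

  nr <- nrow(body); nc <- ncol(body)
  truncated <- any(body[1, ]) || any(body[nr, ]) || any(body[, 1]) ||
    any(body[, nc])
  if (truncated) {
    warning("body region touches the image edge; compartments may be truncated",
            call. = FALSE)
  }

  muscle_cand <- body & in_window(hu, thresholds$muscle)
  non_muscle <- body & !muscle_cand

  # subcutaneous zone: non-muscle-window components reachable from outside
  outside <- !body
  skin_adjacent <- dilate4(outside) & body
  subq <- components_touching(non_muscle, skin_adjacent & non_muscle)
  # degenerate case: body surface is entirely muscle-window (no fat under
  # skin anywhere) -> no subcutaneous zone
  wall <- components_touching(muscle_cand, dilate4(subq) & muscle_cand)
  if (!any(subq)) {
    # without a subcutaneous zone the wall is the muscle-window component
    # touching the skin directly
    wall <- components_touching(muscle_cand, skin_adjacent & muscle_cand)
  }
  # absorb small enclosed non-muscle pockets (intramuscular fat) into the
  # wall band; anything large (the visceral cavity) stays outside it
  rest <- body & !subq & !wall
  if (any(rest) && any(wall)) {
    lab_rest <- EBImage::bwlabel(rest)
    sizes <- tabulate(lab_rest[lab_rest > 0])
    hole_max_px <- hole_max_mm2 / prod(slice$pixel_spacing)
    for (id in which(sizes <= hole_max_px)) {
      comp <- lab_rest == id
      nb <- dilate4(comp) & !comp
      if (all(wall[nb])) wall <- wall | comp
    }
  }
  cavity <- body & !subq & !wall
  structure(list(body = body, wall = wall, subcutaneous = subq,
                 cavity = cavity, truncated = truncated),
            class = "compartment_map")
}

#' Threshold-based tissue segmentation within compartments
#'
#' Classification is compartment-first, HU-window second: skeletal muscle
#' is the muscle window inside the wall band; SAT the fat window inside
#' the subcutaneous zone; VAT the VAT window inside the visceral cavity;
#' intramuscular adipose tissue (IMAT) the fat (SAT) window inside the
#' wall band. All window bounds are inclusive. Remaining body pixels are
#' labelled `other`.
#'
#' @param slice A [ct_slice()].
#' @param compartments A [derive_compartments()] result aligned with the
#'   slice.
#' @param thresholds A [threshold_set()].
#' @return A [label_mask()].
#' @export
segment <- function(slice, compartments = derive_compartments(slice, thresholds),
                    thresholds = threshold_set()) {
  stopifnot(inherits(slice, "ct_slice"),
            inherits(compartments, "compartment_map"),
            inherits(thresholds, "threshold_set"))
  hu <- slice$hu
  if (!identical(dim(hu), dim(compartments$body))) {
    stop("slice and compartment shapes differ", call. = FALSE)
  }
  lg <- tissue_legend()
  labels <- matrix(0L, nrow(hu), ncol(hu))
  labels[compartments$body] <- lg[["other"]]
  labels[compartments$wall & in_window(hu, thresholds$muscle)] <- lg[["muscle"]]
  labels[compartments$wall & in_window(hu, thresholds$sat)] <- lg[["imat"]]
  labels[compartments$subcutaneous & in_window(hu, thresholds$sat)] <- lg[["sat"]]
  labels[compartments$cavity & in_window(hu, thresholds$vat)] <- lg[["vat"]]
  label_mask(labels)
}

#' Per-pixel agreement between a predicted and a reference label mask
#'
#' Compares masks over the union of non-background pixels after collapsing
#' labels through `mapping` (by default the bone placeholder and
#' unclassified tissue both count as `other`, since thresholds alone do
#' not identify bone).
#'
#' @param predicted,reference [label_mask()] objects of identical shape.
#' @param mapping Named character vector collapsing reference tissue names.
#' @return Fraction of pixels in agreement (1 = perfect).
#' @export
label_accuracy <- function(predicted, reference,
                           mapping = c(bone = "other")) {
  stopifnot(inherits(predicted, "label_mask"), inherits(reference, "label_mask"))
  if (!identical(dim(predicted$labels), dim(reference$labels))) {
    stop("mask shapes differ", call. = FALSE)
  }
  to_name <- function(mask) {
    nm <- names(mask$legend)[match(mask$labels, mask$legend)]
    nm[is.na(nm)] <- "background"
    matrix(nm, nrow(mask$labels), ncol(mask$labels))
  }
  p <- to_name(predicted); r <- to_name(reference)
  for (from in names(mapping)) {
    p[p == from] <- mapping[[from]]
    r[r == from] <- mapping[[from]]
  }
  keep <- p != "background" | r != "background"
  mean(p[keep] == r[keep])
}
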