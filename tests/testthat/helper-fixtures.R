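# Small, fast phantom used across tests: 96x96 px at 2 mm, body 55x65 mm.
small_phantom_spec <- function(...) {
  args <- list(...)
  defaults <- list(
    body_semiaxes = c(55, 65), sat_thickness = 12, muscle_thickness = 8,
    vat_lining = 5, visceral_fat_fraction = 0.35,
    pixel_spacing = c(2, 2), grid_size = c(96, 96), seed = 42L
  )
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

# Linear indices of mask pixels whose 4-neighbours are all inside the mask.
interior_indices <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  shrunk <- mask
  shrunk[-1, ]  <- shrunk[-1, ]  & mask[-nr, ]
  shrunk[-nr, ] <- shrunk[-nr, ] & mask[-1, ]
  shrunk[, -1]  <- shrunk[, -1]  & mask[, -nc]
  shrunk[, -nc] <- shrunk[, -nc] & mask[, -1]
  which(shrunk)
}

# Compartment masks implied by the phantom's ground-truth labels.
truth_compartments <- function(mask) {
  lg <- mask$legend
  list(
    subcutaneous = mask$labels == lg[["sat"]],
    wall = mask$labels == lg[["muscle"]],
    cavity = mask$labels == lg[["vat"]] | mask$labels == lg[["other"]] |
      mask$labels == lg[["bone"]]
  )
}
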