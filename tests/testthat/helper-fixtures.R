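# Shared fixtures: small conductor models and physiology settings that keep
# property tests fast while preserving the study geometry.

four_arcs <- function(arc_mm = 8, angles = c(135, 225, 45, 315)) {
  ids <- c("A1", "A2", "B1", "B2")
  lapply(seq_along(ids), function(k) {
    list(id = ids[k], angle_deg = angles[k], arc_mm = arc_mm)
  })
}

small_disk <- function(radius_mm = 20, step_mm = 1, arc_mm = 8) {
  build_disk_phantom(radius_mm, step_mm, four_arcs(arc_mm))
}

# closed-form potential of a +/-I rim dipole on a homogeneous disk
# (method of images: each rim log-source has constant normal flux on the
# circle, cancelling in the source-sink difference)
disk_dipole_potential <- function(coords_mm, src_mm, snk_mm, I_mA = 1,
                                  sigma = 1, thickness_mm = 10) {
  z <- coords_mm / 1000
  a <- src_mm / 1000
  b <- snk_mm / 1000
  da <- sqrt(rowSums(sweep(z, 2, a)^2))
  db <- sqrt(rowSums(sweep(z, 2, b)^2))
  (I_mA / 1000) / (pi * sigma * (thickness_mm / 1000)) * (log(db) - log(da))
}

# rim-projected centre of a registered (single-cell) electrode
rim_point <- function(grid, id, radius_mm) {
  p <- colMeans(beatfield:::cell_coords(grid, grid$electrodes[[id]]$cells))
  p / sqrt(sum(p^2)) * radius_mm
}

quick_params <- function(seed, ...) {
  synth_params(seed = seed, ...)
}
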