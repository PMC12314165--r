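#' Scalar maps over a grid mask
#'
#' A `scalar_map` holds one value per masked cell of a `tissue_grid`, in
#' mask array order, with the grid geometry attached for plotting and I/O.
#' @keywords internal
new_scalar_map <- function(values, grid_dims, grid_spacing, kind = "scalar",
                           normalization = "none") {
  structure(list(values = values, grid_dims = grid_dims,
                 grid_spacing = grid_spacing, kind = kind,
                 normalization = normalization),
            class = "scalar_map")
}

same_geometry <- function(a, b) {
  identical(a$grid_dims, b$grid_dims) &&
    isTRUE(all.equal(a$grid_spacing, b$grid_spacing)) &&
    NROW(a$values) == NROW(b$values)
}

#' Beat frequency of two carriers
#'
#' The interference envelope oscillates at the absolute difference of the
#' two carrier frequencies; equal carriers give a 0-Hz (unmodulated)
#' envelope.
#'
#' @param f1_Hz,f2_Hz carrier frequencies, Hz (> 0).
#' @return Beat frequency, Hz.
#' @examples
#' beat_frequency(2001, 2000)  # 1
#' @export
beat_frequency <- function(f1_Hz, f2_Hz) {
  if (any(c(f1_Hz, f2_Hz) <= 0)) {
    stop("carrier frequencies must be > 0", call. = FALSE)
  }
  abs(f1_Hz - f2_Hz)
}

#' Envelope-modulation amplitude map
#'
#' Cell-wise amplitude of the low-frequency interference envelope produced
#' by two fields oscillating at slightly different carrier frequencies:
#' `2 * min(|E1|, |E2|)`. If both fields carry a known carrier frequency and
#' those frequencies are equal the combination is a coherent single-
#' frequency sum, not an envelope, and the function refuses (use
#' [tacs_magnitude()]).
#'
#' @param E1,E2 `field_map`s on the same grid (typically one per isolated
#'   electrode pair).
#' @param normalization `"none"` or `"peak"` (divide by the maximum so the
#'   map peaks at exactly 1).
#' @return A `scalar_map` of envelope-modulation amplitudes (V/m).
#' @export
envelope_amplitude <- function(E1, E2, normalization = c("none", "peak")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(E1, "field_map"), inherits(E2, "field_map"))
  if (!same_geometry(E1, E2)) stop("fields are on different grids",
                                   call. = FALSE)
  f1 <- E1$pattern$frequency_Hz %||% NA_real_
  f2 <- E2$pattern$frequency_Hz %||% NA_real_
  if (!is.na(f1) && !is.na(f2) && f1 == f2) {
    stop("both fields share one carrier frequency: the result is a ",
         "coherent tACS sum, not an envelope (use tacs_magnitude)",
         call. = FALSE)
  }
  amp <- 2 * pmin(field_magnitude(E1), field_magnitude(E2))
  if (normalization == "peak") {
    m <- max(amp)
    if (m > 0) amp <- amp / m
  }
  new_scalar_map(amp, E1$grid_dims, E1$grid_spacing, kind = "ti_envelope",
                 normalization = normalization)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coherent tACS field magnitude
#'
#' Magnitude of the vector sum of same-frequency fields — the field map of
#' conventional tACS driven through one or several in-phase electrode pairs.
#'
#' @param fields list of `field_map`s on one grid.
#' @return A `scalar_map` of field magnitudes, V/m.
#' @export
tacs_magnitude <- function(fields) {
  if (!length(fields)) stop("empty field list", call. = FALSE)
  for (f in fields) stopifnot(inherits(f, "field_map"))
  if (length(fields) > 1) {
    for (f in fields[-1]) {
      if (!same_geometry(fields[[1]], f)) {
        stop("fields are on different grids", call. = FALSE)
      }
    }
  }
  total <- Reduce(`+`, lapply(fields, `[[`, "values"))
  new_scalar_map(sqrt(rowSums(total^2)), fields[[1]]$grid_dims,
                 fields[[1]]$grid_spacing, kind = "tacs_magnitude")
}

#' Cell-wise difference of two scalar maps
#'
#' @param a,b `scalar_map`s on the same grid.
#' @return A `scalar_map` of `a - b`, e.g. a tTIS-minus-tACS contrast.
#' @export
difference_map <- function(a, b) {
  stopifnot(inherits(a, "scalar_map"), inherits(b, "scalar_map"))
  if (!identical(a$grid_dims, b$grid_dims) ||
      length(a$values) != length(b$values)) {
    stop("maps are on different grids", call. = FALSE)
  }
  new_scalar_map(a$values - b$values, a$grid_dims, a$grid_spacing,
                 kind = "difference")
}

# peak cell of a scalar map restricted to masked cells; smallest-index
# tie-break. Returns list(index into mask order, coordinates mm, value).
map_peak <- function(map, grid) {
  i <- which.max(map$values)          # which.max takes the first maximum
  midx <- mask_index(grid)
  list(mask_index = i, coords_mm = drop(cell_coords(grid, midx[i])),
       value = map$values[i])
}

#' Current-ratio steering sweep
#'
#' Solves both electrode pairs once at unit current and, using linearity,
#' scales the fields to realise each requested current ratio
#' `I1 : I2 = 1 : r`, computing the envelope map and its peak location for
#' every ratio. Increasing the share of one pair steers the envelope peak
#' toward the weaker pair.
#'
#' @param grid a `tissue_grid`.
#' @param pairA,pairB length-2 character vectors of electrode ids; current
#'   enters the first and returns through the second electrode of each pair.
#' @param ratios positive ratios `r` (current of pair B per unit of pair A).
#' @param base_current_mA current of pair A, mA.
#' @param f1_Hz,f2_Hz carrier frequencies of the two pairs.
#' @param tol solver tolerance.
#' @return A list with one element per ratio: `ratio`, `envelope`
#'   (`scalar_map`), `peak_mm`, `peak_value`.
#' @export
ratio_sweep <- function(grid, pairA, pairB, ratios = c(1, 2, 4),
                        base_current_mA = 1, f1_Hz = 2000, f2_Hz = 2001,
                        tol = 1e-8) {
  if (!length(ratios)) stop("empty ratio list", call. = FALSE)
  if (any(ratios <= 0)) stop("ratios must be > 0", call. = FALSE)
  sys <- assemble_system(grid)
  pA <- current_pattern(stats::setNames(c(1, -1) * base_current_mA, pairA),
                        frequency_Hz = f1_Hz, channel_id = "pairA")
  pB <- current_pattern(stats::setNames(c(1, -1) * base_current_mA, pairB),
                        frequency_Hz = f2_Hz, channel_id = "pairB")
  E_A <- solve_field(grid, pA, tol = tol, system = sys)
  E_B <- solve_field(grid, pB, tol = tol, system = sys)
  lapply(ratios, function(r) {
    E_Br <- E_B
    E_Br$values <- E_B$values * r
    env <- envelope_amplitude(E_A, E_Br)
    pk <- map_peak(env, grid)
    list(ratio = r, envelope = env, peak_mm = pk$coords_mm,
         peak_value = pk$value)
  })
}

#' Focality summary of a stimulation map
#'
#' Quantifies how focal a field map is around a stated target: the focal
#' fraction is the fraction of evaluated cells whose value reaches at least
#' half the value at the target cell — smaller means more focal delivery to
#' the target. The peak location uses the smallest-index tie-break on
#' plateaus; its depth is the distance (mm) from the peak cell to the
#' nearest point outside the conductor.
#'
#' @param map a `scalar_map`.
#' @param grid the `tissue_grid` the map lives on.
#' @param target_mm physical coordinates (mm) of the target; snapped to the
#'   nearest masked (or `region`) cell. Must lie inside the mask.
#' @param region optional integer label(s): restrict the evaluation (and
#'   the target snap) to cells with these labels, e.g. the brain
#'   compartment of a head model.
#' @return A list with `peak_mm`, `peak_value`, `focal_fraction`,
#'   `depth_of_peak_mm`, `target_value`, `n_cells`.
#' @export
focality <- function(map, grid, target_mm, region = NULL) {
  stopifnot(inherits(map, "scalar_map"), inherits(grid, "tissue_grid"))
  midx <- mask_index(grid)
  keep <- rep(TRUE, length(midx))
  if (!is.null(region)) keep <- grid$labels[midx] %in% region
  if (!any(keep)) stop("region selects no cells", call. = FALSE)
  vals <- map$values[keep]
  cc <- cell_coords(grid, midx[keep])
  d2 <- rowSums(sweep(cc, 2, target_mm, `-`)^2)
  tgt <- which.min(d2)
  if (sqrt(d2[tgt]) > grid$spacing * sqrt(length(grid$dims))) {
    stop("target lies outside the mask/region", call. = FALSE)
  }
  tv <- vals[tgt]
  pk <- which.max(vals)
  # depth: distance from the peak cell to the nearest non-conductor cell
  bnd <- boundary_cells(grid)
  bc <- cell_coords(grid, bnd)
  depth <- sqrt(min(rowSums(sweep(bc, 2, cc[pk, ], `-`)^2)))
  list(peak_mm = cc[pk, ], peak_value = vals[pk],
       focal_fraction = mean(vals >= 0.5 * tv),
       depth_of_peak_mm = depth, target_value = tv, n_cells = length(vals))
}
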