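#' Labelled conductor grids
#'
#' A `tissue_grid` is a regular Cartesian grid (2-D pixels or 3-D voxels)
#' carrying an integer tissue label per cell, a per-label conductivity in
#' S/m, a logical mask of cells that belong to the conductor, and the set of
#' registered stimulation electrodes. Cell centres live at
#' `origin + (index - 1) * spacing` in mm; grids built by
#' [build_disk_phantom()] and [build_layered_head()] are centred on the
#' physical origin. 2-D grids additionally carry a `thickness_mm` (the
#' conducting sheet depth, e.g. the saline depth in a dish phantom) so that
#' absolute impedances are defined.
#'
#' @param dims integer vector of grid dimensions (length 2 or 3).
#' @param spacing cell edge length, mm (scalar, > 0).
#' @param labels integer array of tissue labels, `dim(labels) == dims`.
#' @param mask logical array, `TRUE` for cells inside the conductor.
#' @param conductivity named numeric vector, S/m, indexed by label value
#'   (name `"k"` maps label `k`); all entries must be > 0.
#' @param origin physical coordinate (mm) of the centre of cell `[1,1(,1)]`.
#' @param thickness_mm conducting-sheet thickness for 2-D grids, mm.
#' @return An object of class `tissue_grid`.
#' @keywords internal
new_tissue_grid <- function(dims, spacing, labels, mask, conductivity,
                            origin, thickness_mm = NA_real_) {
  stopifnot(length(dims) %in% c(2L, 3L), spacing > 0)
  if (any(conductivity <= 0) || anyNA(conductivity)) {
    stop("all conductivities must be > 0 S/m", call. = FALSE)
  }
  lab_in_mask <- unique(labels[mask])
  if (!all(as.character(lab_in_mask) %in% names(conductivity))) {
    stop("every masked cell must have a conductivity for its label",
         call. = FALSE)
  }
  g <- structure(list(
    dims = as.integer(dims),
    spacing = spacing,
    labels = labels,
    mask = mask,
    conductivity = conductivity,
    origin = origin,
    thickness_mm = thickness_mm,
    electrodes = list()
  ), class = "tissue_grid")
  if (!mask_connected(g)) {
    stop("conductor mask is not a single connected component", call. = FALSE)
  }
  g
}

#' @export
print.tissue_grid <- function(x, ...) {
  cat(sprintf("<tissue_grid> %s grid, %.3g mm spacing, %d masked cells, %d electrode(s)\n",
              paste(x$dims, collapse = "x"), x$spacing,
              sum(x$mask), length(x$electrodes)))
  invisible(x)
}

# cell-centre coordinates (mm) for given linear indices of the full array
cell_coords <- function(grid, lin_idx) {
  ai <- arrayInd(lin_idx, grid$dims)
  sweep(sweep(ai - 1, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

# linear indices of all masked cells, in array order
mask_index <- function(grid) which(grid$mask)

# flood fill from the first masked cell; TRUE if every masked cell reached
mask_connected <- function(grid) {
  m <- grid$mask
  n <- sum(m)
  if (n == 0) stop("mask is empty", call. = FALSE)
  id <- array(0L, grid$dims)
  id[m] <- seq_len(n)
  # adjacency via axis shifts
  nbrs <- vector("list", 2L * length(grid$dims))
  k <- 0
  midx <- which(m)
  ai <- arrayInd(midx, grid$dims)
  adj_i <- integer(0); adj_j <- integer(0)
  for (d in seq_along(grid$dims)) {
    for (s in c(-1L, 1L)) {
      bi <- ai
      bi[, d] <- bi[, d] + s
      ok <- bi[, d] >= 1L & bi[, d] <= grid$dims[d]
      lin_b <- lin_index(bi[ok, , drop = FALSE], grid$dims)
      keep <- m[lin_b]
      adj_i <- c(adj_i, id[midx[ok][keep]])
      adj_j <- c(adj_j, id[lin_b[keep]])
    }
  }
  reached <- logical(n)
  frontier <- 1L
  reached[1L] <- TRUE
  adj <- split(adj_j, adj_i)
  while (length(frontier)) {
    nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    nxt <- nxt[!reached[nxt]]
    reached[nxt] <- TRUE
    frontier <- nxt
  }
  all(reached)
}

# row-wise linear index for an arrayInd-style matrix
lin_index <- function(ai, dims) {
  stride <- cumprod(c(1L, dims[-length(dims)]))
  as.integer(1L + (ai - 1L) %*% stride)
}

# masked cells adjacent to a non-mask cell or the array edge
boundary_cells <- function(grid) {
  m <- grid$mask
  midx <- which(m)
  ai <- arrayInd(midx, grid$dims)
  on_bnd <- logical(length(midx))
  for (d in seq_along(grid$dims)) {
    for (s in c(-1L, 1L)) {
      bi <- ai
      bi[, d] <- bi[, d] + s
      outside <- bi[, d] < 1L | bi[, d] > grid$dims[d]
      inside <- !outside
      lin_b <- integer(length(midx))
      lin_b[inside] <- lin_index(bi[inside, , drop = FALSE], grid$dims)
      off_mask <- outside
      off_mask[inside] <- !m[lin_b[inside]]
      on_bnd <- on_bnd | off_mask
    }
  }
  midx[on_bnd]
}

register_electrode <- function(grid, id, cells) {
  if (length(cells) == 0) stop("electrode '", id, "' has no contact cells",
                               call. = FALSE)
  for (e in grid$electrodes) {
    if (length(intersect(e$cells, cells))) {
      stop("electrode '", id, "' overlaps electrode '", e$id, "'",
           call. = FALSE)
    }
  }
  grid$electrodes[[id]] <- list(id = id, cells = cells)
  grid
}

#' Build a homogeneous disk tissue phantom
#'
#' Discretizes a saline-filled circular dish on a regular pixel grid and
#' registers copper electrode arcs on the rim. The default geometry is a
#' 90-mm diameter dish with four symmetric 10-mm arc electrodes, the montage
#' used to map interference fields with a dipole probe.
#'
#' @param radius_mm dish radius, mm (default 45).
#' @param grid_step_mm pixel edge, mm; must be < `radius_mm`.
#' @param electrode_arcs list of arcs, each a list with `id`, `angle_deg`
#'   (arc centre, measured counter-clockwise from +x) and `arc_mm` (arc
#'   length along the rim). May be empty.
#' @param conductivity_S_per_m saline conductivity, S/m (default 1.0).
#' @param thickness_mm saline depth, mm (default 10); sets the conducting
#'   cross-section for absolute impedance.
#' @return A `tissue_grid` with the arcs registered as electrodes.
#' @examples
#' ph <- build_disk_phantom(45, 1.5, list(
#'   list(id = "A1", angle_deg = 120, arc_mm = 10),
#'   list(id = "A2", angle_deg = 240, arc_mm = 10)))
#' @export
build_disk_phantom <- function(radius_mm = 45, grid_step_mm = 1,
                               electrode_arcs = list(),
                               conductivity_S_per_m = 1.0,
                               thickness_mm = 10) {
  if (radius_mm <= 0) stop("radius_mm must be > 0", call. = FALSE)
  if (grid_step_mm >= radius_mm) {
    stop("grid_step_mm must be smaller than radius_mm (resolution error)",
         call. = FALSE)
  }
  h <- grid_step_mm
  n <- 2L * ceiling(radius_mm / h) + 1L
  ax <- (seq_len(n) - (n + 1) / 2) * h
  xx <- matrix(ax, n, n)
  yy <- matrix(ax, n, n, byrow = TRUE)
  mask <- xx^2 + yy^2 <= radius_mm^2
  labels <- array(1L, dim = c(n, n))
  grid <- new_tissue_grid(c(n, n), h, labels, mask,
                          c("1" = conductivity_S_per_m),
                          origin = c(ax[1], ax[1]),
                          thickness_mm = thickness_mm)
  if (length(electrode_arcs)) {
    bnd <- boundary_cells(grid)
    bc <- cell_coords(grid, bnd)
    ang <- atan2(bc[, 2], bc[, 1])
    for (arc in electrode_arcs) {
      half <- (arc$arc_mm / radius_mm) / 2     # half-angle, rad
      d <- angle_diff(ang, arc$angle_deg * pi / 180)
      cells <- bnd[abs(d) <= half + 1e-9]
      if (!length(cells)) {
        stop("electrode arc '", arc$id, "' selects no rim cells",
             call. = FALSE)
      }
      grid <- register_electrode(grid, arc$id, cells)
    }
  }
  grid
}

# wrapped angular difference in (-pi, pi]
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

#' Build a layered ellipsoidal head model
#'
#' Voxelizes nested concentric ellipsoid shells (scalp > skull > CSF >
#' brain) as a stand-in for an image-derived mouse head mesh, with the
#' tissue conductivities used for transcranial stimulation modelling
#' (S/m): grey/white matter 0.126, CSF 1.654, bone 0.01, scalp 0.465.
#' Electrodes are registered as surface patches: skull pins on the outer
#' skull surface and larger cheek patches on the scalp surface.
#'
#' @param shell_semiaxes_mm named list of semi-axis triples (mm), outermost
#'   first; names become tissue labels. Shells must be strictly nested.
#' @param voxel_mm voxel edge, mm.
#' @param conductivity_table named numeric (S/m), one entry per shell name.
#' @param electrode_placements list of placements, each a list with `id`,
#'   `layer` (a shell name), `position_mm` (length-3 target point) and
#'   `diameter_mm` (patch diameter). Contact cells are the cells of that
#'   layer lying on its outer surface within `diameter_mm / 2` of the
#'   nearest surface point to `position_mm`.
#' @return A `tissue_grid` with electrodes registered.
#' @export
build_layered_head <- function(shell_semiaxes_mm = list(
                                 scalp = c(6.0, 5.0, 4.5),
                                 skull = c(5.6, 4.6, 4.1),
                                 csf   = c(5.3, 4.3, 3.8),
                                 brain = c(5.1, 4.1, 3.6)),
                               voxel_mm = 0.25,
                               conductivity_table = c(
                                 scalp = 0.465, skull = 0.01,
                                 csf = 1.654, brain = 0.126),
                               electrode_placements = list()) {
  nm <- names(shell_semiaxes_mm)
  if (is.null(nm) || any(nm == "")) stop("shells must be named", call. = FALSE)
  sx <- do.call(rbind, shell_semiaxes_mm)
  if (any(sx <= 0)) stop("semi-axes must be > 0 (geometry error)", call. = FALSE)
  if (nrow(sx) > 1 && !all(diff(sx[, 1]) < 0 & diff(sx[, 2]) < 0 &
                           diff(sx[, 3]) < 0)) {
    stop("shells must be strictly nested, outermost first (geometry error)",
         call. = FALSE)
  }
  if (!all(nm %in% names(conductivity_table))) {
    stop("conductivity_table must cover every shell name", call. = FALSE)
  }
  h <- voxel_mm
  half <- sx[1, ]
  n <- 2L * ceiling(half / h) + 1L
  ax <- lapply(1:3, function(d) (seq_len(n[d]) - (n[d] + 1) / 2) * h)
  xx <- array(ax[[1]], dim = n)
  yy <- aperm(array(ax[[2]], dim = n[c(2, 1, 3)]), c(2, 1, 3))
  zz <- aperm(array(ax[[3]], dim = n[c(3, 1, 2)]), c(2, 3, 1))
  labels <- array(0L, dim = n)
  for (k in seq_len(nrow(sx))) {     # outermost first; inner shells overwrite
    inside <- (xx / sx[k, 1])^2 + (yy / sx[k, 2])^2 + (zz / sx[k, 3])^2 <= 1
    labels[inside] <- k
  }
  mask <- labels > 0L
  cond <- stats::setNames(conductivity_table[nm], as.character(seq_along(nm)))
  grid <- new_tissue_grid(n, h, labels, mask, cond,
                          origin = c(ax[[1]][1], ax[[2]][1], ax[[3]][1]))
  grid$layer_names <- nm
  for (pl in electrode_placements) {
    grid <- place_surface_electrode(grid, pl)
  }
  grid
}

# cells of a layer adjacent to the next-outer layer (or to outside)
layer_surface_cells <- function(grid, layer_code) {
  m <- grid$labels == layer_code & grid$mask
  idx <- which(m)
  ai <- arrayInd(idx, grid$dims)
  on_surf <- logical(length(idx))
  for (d in seq_along(grid$dims)) {
    for (s in c(-1L, 1L)) {
      bi <- ai
      bi[, d] <- bi[, d] + s
      outside <- bi[, d] < 1L | bi[, d] > grid$dims[d]
      inside <- !outside
      lin_b <- integer(length(idx))
      lin_b[inside] <- lin_index(bi[inside, , drop = FALSE], grid$dims)
      outer <- outside
      outer[inside] <- grid$labels[lin_b[inside]] < layer_code
      on_surf <- on_surf | outer
    }
  }
  idx[on_surf]
}

place_surface_electrode <- function(grid, pl) {
  code <- match(pl$layer, grid$layer_names)
  if (is.na(code)) {
    stop("electrode '", pl$id, "': unknown layer '", pl$layer,
         "' (placement error)", call. = FALSE)
  }
  surf <- layer_surface_cells(grid, code)
  sc <- cell_coords(grid, surf)
  d2 <- rowSums(sweep(sc, 2, pl$position_mm, `-`)^2)
  anchor <- sc[which.min(d2), ]
  r2 <- rowSums(sweep(sc, 2, anchor, `-`)^2)
  cells <- surf[r2 <= (pl$diameter_mm / 2)^2 + 1e-9]
  if (!length(cells)) {
    stop("electrode '", pl$id, "' selects no surface cells (placement error)",
         call. = FALSE)
  }
  register_electrode(grid, pl$id, cells)
}

#' Default head montage
#'
#' Two skull-pin electrodes 4.2 mm apart centre-to-centre on top of the
#' skull, each paired with an ipsilateral cheek patch low on the scalp —
#' the montage used in the awake-mouse experiments (pin diameter 1 mm,
#' cheek patch 8 mm nominal, clipped to the model's scalp).
#'
#' @param pin_sep_mm centre-to-centre pin separation, mm (default 4.2).
#' @param pin_mm pin diameter, mm.
#' @param cheek_mm cheek patch diameter, mm.
#' @return A list of electrode placements for [build_layered_head()].
#' @export
default_head_montage <- function(pin_sep_mm = 4.2, pin_mm = 1,
                                 cheek_mm = 4) {
  half <- pin_sep_mm / 2
  # target points sit just above the default skull dome (z ~ 3.8-4.1 mm)
  # so the nearest-surface-cell anchor lands at the intended (x, y)
  list(
    list(id = "pin_L",   layer = "skull", position_mm = c(-half, 0, 4.2),
         diameter_mm = pin_mm),
    list(id = "pin_R",   layer = "skull", position_mm = c(half, 0, 4.2),
         diameter_mm = pin_mm),
    list(id = "cheek_L", layer = "scalp", position_mm = c(-10, 0, -3),
         diameter_mm = cheek_mm),
    list(id = "cheek_R", layer = "scalp", position_mm = c(10, 0, -3),
         diameter_mm = cheek_mm)
  )
}
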