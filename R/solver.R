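#' Injection current patterns
#'
#' A `current_pattern` records the signed current (mA) injected through each
#' named electrode by one electrically isolated source, together with that
#' source's carrier frequency. Currents must sum to zero: each isolated
#' source conserves charge.
#'
#' @param injections named numeric vector, mA (one entry per electrode id).
#' @param frequency_Hz carrier frequency of this source, Hz.
#' @param channel_id optional identifier of the isolated source.
#' @return An object of class `current_pattern`.
#' @export
current_pattern <- function(injections, frequency_Hz = NA_real_,
                            channel_id = NULL) {
  if (is.null(names(injections)) || any(names(injections) == "")) {
    stop("injections must be a named vector of currents (mA)", call. = FALSE)
  }
  scale <- max(abs(injections), 1e-12)
  if (abs(sum(injections)) > 1e-9 * scale) {
    stop("injections must sum to 0 within one pattern (charge conservation)",
         call. = FALSE)
  }
  structure(list(injections = injections, frequency_Hz = frequency_Hz,
                 channel_id = channel_id), class = "current_pattern")
}

# Finite-volume Laplacian over the masked cells: face conductance
# g = sigma_harmonic * A_face / d with A/d = thickness (2-D sheet) or
# spacing (3-D), both in metres so currents in A give potentials in V.
assemble_system <- function(grid) {
  dims <- grid$dims
  midx <- mask_index(grid)
  nmask <- length(midx)
  id <- array(0L, dims)
  id[midx] <- seq_len(nmask)
  sigma <- grid$conductivity[as.character(grid$labels[midx])]
  h_m <- grid$spacing / 1000
  face_factor <- if (length(dims) == 2L) {
    if (is.na(grid$thickness_mm)) stop("2-D grid needs thickness_mm",
                                       call. = FALSE)
    grid$thickness_mm / 1000
  } else h_m
  ai <- arrayInd(midx, dims)
  ii <- integer(0); jj <- integer(0); gg <- numeric(0)
  for (d in seq_along(dims)) {
    bi <- ai
    bi[, d] <- bi[, d] + 1L
    ok <- bi[, d] <= dims[d]
    lin_b <- lin_index(bi[ok, , drop = FALSE], dims)
    keep <- grid$mask[lin_b]
    a_id <- id[midx[ok][keep]]
    b_id <- id[lin_b[keep]]
    g <- 2 / (1 / sigma[a_id] + 1 / sigma[b_id]) * face_factor
    ii <- c(ii, a_id); jj <- c(jj, b_id); gg <- c(gg, g)
  }
  L <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = -c(gg, gg),
                            dims = c(nmask, nmask))
  Matrix::diag(L) <- -Matrix::rowSums(L)
  list(L = L, id = id, midx = midx, nmask = nmask)
}

# Jacobi-preconditioned conjugate gradients for the (consistent, singular)
# Neumann system; the constant nullspace is handled by mean removal.
pcg_solve <- function(L, b, tol = 1e-8, maxit = 50000L) {
  n <- length(b)
  M <- Matrix::diag(L)
  x <- numeric(n)
  r <- b
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = x, residual = 0, iterations = 0L))
  z <- r / M
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(L %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rn <- sqrt(sum(r^2))
    if (rn <= tol * bnorm) {
      x <- x - mean(x)
      return(list(x = x, residual = rn / bnorm, iterations = it))
    }
    z <- r / M
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop("conjugate-gradient solver did not converge in ", maxit,
       " iterations (relative residual ", signif(rn / bnorm, 3), ")",
       call. = FALSE)
}

#' Solve the quasi-static current-flow problem
#'
#' Solves the discretized conduction equation div(sigma grad V) = 0 on the
#' masked cells of `grid` with the total current of each electrode in
#' `pattern` distributed uniformly over its contact cells and zero-flux
#' (insulating) conditions elsewhere. The potential is gauged to zero mean
#' over the mask; units are volts for currents given in mA.
#'
#' @param grid a `tissue_grid` with the pattern's electrodes registered.
#' @param pattern a [current_pattern()]; injections must sum to zero.
#' @param tol relative residual tolerance for the conjugate-gradient solve.
#' @param system optional pre-assembled system from an earlier solve on the
#'   same grid (reused to avoid re-assembly in sweeps).
#' @return An object of class `potential_solution` with elements
#'   `potential` (V, one value per masked cell in array order), `gauge`,
#'   `residual`, `iterations`, and the generating `pattern`.
#' @export
solve_potential <- function(grid, pattern, tol = 1e-8, system = NULL) {
  stopifnot(inherits(grid, "tissue_grid"), inherits(pattern, "current_pattern"))
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  missing <- setdiff(names(pattern$injections), names(grid$electrodes))
  if (length(missing)) {
    stop("pattern references unregistered electrode(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sys <- if (is.null(system)) assemble_system(grid) else system
  b <- numeric(sys$nmask)
  for (eid in names(pattern$injections)) {
    cells <- grid$electrodes[[eid]]$cells
    b[sys$id[cells]] <- b[sys$id[cells]] +
      (pattern$injections[[eid]] / 1000) / length(cells)
  }
  sol <- pcg_solve(sys$L, b, tol = tol)
  structure(list(potential = sol$x, gauge = "zero-mean over mask",
                 residual = sol$residual, iterations = sol$iterations,
                 pattern = pattern, system = sys,
                 grid_dims = grid$dims, grid_spacing = grid$spacing),
            class = "potential_solution")
}

#' Electrode boundary fluxes of a solution
#'
#' Net current (mA) through each registered electrode, computed as the
#' discrete divergence of the solved potential summed over the electrode's
#' contact cells. For a converged solve each flux equals the injected
#' current and the fluxes sum to zero.
#'
#' @param sol a `potential_solution`.
#' @param grid the `tissue_grid` it was solved on.
#' @return Named numeric vector of currents, mA.
#' @export
electrode_fluxes <- function(sol, grid) {
  sys <- sol$system
  LV <- as.numeric(sys$L %*% sol$potential)
  out <- vapply(grid$electrodes, function(e) sum(LV[sys$id[e$cells]]) * 1000,
                numeric(1))
  stats::setNames(out, names(grid$electrodes))
}

#' Electric field of a solved potential
#'
#' Negative gradient of the potential in V/m: central differences where both
#' axis neighbours are masked, one-sided differences at the conductor
#' boundary.
#'
#' @param sol a `potential_solution`.
#' @param grid the `tissue_grid` the potential was solved on.
#' @return An object of class `field_map`: `values` is an
#'   `n_masked x n_components` matrix (V/m) in mask array order; carries the
#'   generating pattern for envelope bookkeeping.
#' @export
electric_field <- function(sol, grid) {
  stopifnot(inherits(sol, "potential_solution"))
  if (!identical(sol$grid_dims, grid$dims) ||
      !identical(sol$grid_spacing, grid$spacing)) {
    stop("solution and grid do not match", call. = FALSE)
  }
  dims <- grid$dims
  midx <- mask_index(grid)
  V <- array(NA_real_, dims)
  V[midx] <- sol$potential
  h_m <- grid$spacing / 1000
  ai <- arrayInd(midx, dims)
  ncomp <- length(dims)
  E <- matrix(0, length(midx), ncomp)
  for (d in seq_len(ncomp)) {
    up <- ai; up[, d] <- up[, d] + 1L
    dn <- ai; dn[, d] <- dn[, d] - 1L
    up_ok <- up[, d] <= dims[d]
    dn_ok <- dn[, d] >= 1L
    v_up <- rep(NA_real_, length(midx))
    v_dn <- rep(NA_real_, length(midx))
    v_up[up_ok] <- V[lin_index(up[up_ok, , drop = FALSE], dims)]
    v_dn[dn_ok] <- V[lin_index(dn[dn_ok, , drop = FALSE], dims)]
    v0 <- sol$potential
    both <- !is.na(v_up) & !is.na(v_dn)
    only_up <- !is.na(v_up) & is.na(v_dn)
    only_dn <- is.na(v_up) & !is.na(v_dn)
    dV <- numeric(length(midx))
    dV[both] <- (v_up[both] - v_dn[both]) / (2 * h_m)
    dV[only_up] <- (v_up[only_up] - v0[only_up]) / h_m
    dV[only_dn] <- (v0[only_dn] - v_dn[only_dn]) / h_m
    E[, d] <- -dV
  }
  structure(list(values = E, pattern = sol$pattern, grid_dims = grid$dims,
                 grid_spacing = grid$spacing, mask_n = length(midx)),
            class = "field_map")
}

#' Field vector magnitude
#' @param field a `field_map`.
#' @return Numeric vector, V/m, one value per masked cell.
#' @export
field_magnitude <- function(field) {
  sqrt(rowSums(field$values^2))
}

# solve one pattern and return its field in one call
solve_field <- function(grid, pattern, tol = 1e-8, system = NULL) {
  electric_field(solve_potential(grid, pattern, tol = tol, system = system),
                 grid)
}

#' Lead-field basis for a grid and its electrodes
#'
#' Computes a per-channel unit-current field basis from which the field of
#' any balanced injection pattern follows by superposition
#' ([apply_lead_field()]). Two reference policies are supported:
#' `"monopolar"` solves one channel per electrode (+1 mA through it, the
#' return spread equally over the remaining electrodes), giving an
#' `n_electrodes x n_masked x n_components` basis; `"reference"` solves
#' +1 mA through each non-reference electrode against a named reference,
#' giving `n_electrodes - 1` channels.
#'
#' @param grid a `tissue_grid` with at least two electrodes.
#' @param reference_policy `"monopolar"` or `"reference"`.
#' @param reference electrode id (policy `"reference"` only; defaults to
#'   the last registered electrode).
#' @param tol solver tolerance.
#' @return An object of class `lead_field` with `basis` (array
#'   `[channels, locations, components]`, V/m per mA), `channel_order`, and
#'   the policy metadata.
#' @export
lead_field <- function(grid, reference_policy = c("monopolar", "reference"),
                       reference = NULL, tol = 1e-8) {
  reference_policy <- match.arg(reference_policy)
  eids <- names(grid$electrodes)
  n <- length(eids)
  if (n < 2L) stop("lead field needs at least 2 electrodes", call. = FALSE)
  sys <- assemble_system(grid)
  if (reference_policy == "monopolar") {
    channels <- eids
    patterns <- lapply(eids, function(e) {
      inj <- stats::setNames(rep(-1 / (n - 1), n), eids)
      inj[e] <- 1
      current_pattern(inj)
    })
  } else {
    if (is.null(reference)) reference <- eids[n]
    if (!reference %in% eids) stop("unknown reference electrode", call. = FALSE)
    channels <- setdiff(eids, reference)
    patterns <- lapply(channels, function(e) {
      inj <- stats::setNames(c(1, -1), c(e, reference))
      current_pattern(inj)
    })
  }
  fields <- lapply(patterns, function(p) {
    solve_field(grid, p, tol = tol, system = sys)$values
  })
  ncomp <- ncol(fields[[1]])
  basis <- array(0, dim = c(length(channels), nrow(fields[[1]]), ncomp))
  for (k in seq_along(fields)) basis[k, , ] <- fields[[k]]
  structure(list(basis = basis, channel_order = channels,
                 reference_policy = reference_policy, reference = reference,
                 electrode_order = eids, grid_dims = grid$dims,
                 grid_spacing = grid$spacing),
            class = "lead_field")
}

#' Field of an injection pattern by lead-field superposition
#'
#' Reconstructs the field of a balanced pattern as a current-weighted sum of
#' basis rows. Under policy `"monopolar"` the exact weights are
#' `(n-1)/n * I_k` (the n monopolar patterns over-span the balanced
#' subspace by that factor); under `"reference"` the weights are the
#' non-reference currents themselves.
#'
#' @param lf a `lead_field`.
#' @param pattern a [current_pattern()] over the same electrodes.
#' @return A `field_map` carrying `pattern`.
#' @export
apply_lead_field <- function(lf, pattern) {
  stopifnot(inherits(lf, "lead_field"), inherits(pattern, "current_pattern"))
  inj <- stats::setNames(rep(0, length(lf$electrode_order)),
                         lf$electrode_order)
  if (!all(names(pattern$injections) %in% lf$electrode_order)) {
    stop("pattern references electrodes missing from the lead field",
         call. = FALSE)
  }
  inj[names(pattern$injections)] <- pattern$injections
  if (lf$reference_policy == "monopolar") {
    n <- length(lf$electrode_order)
    w <- inj[lf$channel_order] * (n - 1) / n
  } else {
    w <- inj[lf$channel_order]
  }
  ncomp <- dim(lf$basis)[3]
  vals <- matrix(0, dim(lf$basis)[2], ncomp)
  for (k in seq_along(w)) {
    if (w[k] != 0) vals <- vals + w[k] * lf$basis[k, , ]
  }
  structure(list(values = vals, pattern = pattern, grid_dims = lf$grid_dims,
                 grid_spacing = lf$grid_spacing, mask_n = dim(lf$basis)[2]),
            class = "field_map")
}

#' Interelectrode impedance of an electrode pair
#'
#' Solves the DC problem for the pair and reports
#' `(V_a - V_b) / I` in kilo-ohms, with each electrode's potential taken as
#' the mean solved potential over its contact cells.
#'
#' @param grid a `tissue_grid`.
#' @param electrode_a,electrode_b distinct electrode ids.
#' @param current_mA probe current (impedance is current-independent).
#' @param tol solver tolerance.
#' @return Resistance in kOhm (scalar, > 0).
#' @export
pair_impedance <- function(grid, electrode_a, electrode_b, current_mA = 1,
                           tol = 1e-8) {
  if (identical(electrode_a, electrode_b)) {
    stop("impedance needs two distinct electrodes", call. = FALSE)
  }
  pat <- current_pattern(stats::setNames(c(current_mA, -current_mA),
                                         c(electrode_a, electrode_b)))
  sol <- solve_potential(grid, pat, tol = tol)
  id <- sol$system$id
  va <- mean(sol$potential[id[grid$electrodes[[electrode_a]]$cells]])
  vb <- mean(sol$potential[id[grid$electrodes[[electrode_b]]$cells]])
  (va - vb) / current_mA   # V per mA = kOhm
}

#' Calibrate phantom conductivity to a target impedance
#'
#' Bisection on the (monotone decreasing) impedance-vs-conductivity curve of
#' a pair, emulating the adjustment of saline concentration until the
#' interelectrode impedance reaches a target (3 kOhm in the reference
#' phantom).
#'
#' @param grid a disk `tissue_grid` (homogeneous, label 1).
#' @param electrode_a,electrode_b the pair to calibrate on.
#' @param target_kohm target impedance, kOhm.
#' @param bounds_S_per_m search interval for conductivity, S/m.
#' @param tol_kohm convergence tolerance on impedance.
#' @param max_iter bisection iteration cap.
#' @return List with `conductivity_S_per_m`, `impedance_kohm`, and the
#'   per-iteration `trace` (data frame) of the bisection.
#' @export
calibrate_phantom_conductivity <- function(grid, electrode_a, electrode_b,
                                           target_kohm = 3,
                                           bounds_S_per_m = c(0.01, 10),
                                           tol_kohm = 1e-4,
                                           max_iter = 60L) {
  imp_at <- function(sig) {
    g <- grid
    g$conductivity[] <- sig
    pair_impedance(g, electrode_a, electrode_b)
  }
  lo <- bounds_S_per_m[1]; hi <- bounds_S_per_m[2]
  f_lo <- imp_at(lo) - target_kohm   # decreasing in sigma: f_lo > f_hi
  f_hi <- imp_at(hi) - target_kohm
  if (f_lo < 0 || f_hi > 0) {
    stop("target impedance not bracketed by bounds", call. = FALSE)
  }
  trace <- data.frame(iter = integer(0), sigma = numeric(0),
                      impedance_kohm = numeric(0))
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    z <- imp_at(mid)
    trace <- rbind(trace, data.frame(iter = it, sigma = mid,
                                     impedance_kohm = z))
    if (abs(z - target_kohm) < tol_kohm) break
    if (z > target_kohm) lo <- mid else hi <- mid
  }
  list(conductivity_S_per_m = mid, impedance_kohm = z, trace = trace)
}
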