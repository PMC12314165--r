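test_that("disk phantom discretization matches the dish geometry", {
  ph <- build_disk_phantom(45, 1, four_arcs(10))
  # area of the masked disk within 2% of pi r^2
  expect_lt(abs(sum(ph$mask) - pi * 45^2) / (pi * 45^2), 0.02)
  expect_length(ph$electrodes, 4L)
  # all contact cells lie on the conductor boundary
  bnd <- beatfield:::boundary_cells(ph)
  for (e in ph$electrodes) expect_true(all(e$cells %in% bnd))

  # degenerate but valid: no electrodes
  ph0 <- build_disk_phantom(45, 1.5)
  expect_length(ph0$electrodes, 0L)
  expect_s3_class(ph0, "tissue_grid")
})

test_that("invalid disk configurations are refused", {
  # overlapping arcs share rim cells
  expect_error(build_disk_phantom(45, 1, list(
    list(id = "a", angle_deg = 90, arc_mm = 10),
    list(id = "b", angle_deg = 93, arc_mm = 10))), "overlap")
  # grid step at or above the radius cannot resolve the disk
  expect_error(build_disk_phantom(10, 10), "resolution")
  expect_error(build_disk_phantom(-5, 1), "radius")
})

test_that("layered head carries the printed tissue conductivities", {
  hd <- build_layered_head(voxel_mm = 0.5,
                           electrode_placements = default_head_montage())
  codes <- stats::setNames(seq_along(hd$layer_names), hd$layer_names)
  expect_identical(unname(hd$conductivity[as.character(codes["brain"])]),
                   0.126)
  expect_identical(unname(hd$conductivity[as.character(codes["csf"])]),
                   1.654)
  expect_identical(unname(hd$conductivity[as.character(codes["skull"])]),
                   0.01)
  expect_identical(unname(hd$conductivity[as.character(codes["scalp"])]),
                   0.465)
  # every shell present and nested: brain entirely inside csf-or-deeper etc.
  expect_setequal(unique(hd$labels[hd$mask]), 1:4)
  # the montage registers 4 electrodes; pins sit on skull cells
  expect_length(hd$electrodes, 4L)
  expect_true(all(hd$labels[hd$electrodes$pin_L$cells] == codes["skull"]))
  expect_true(all(hd$labels[hd$electrodes$cheek_L$cells] == codes["scalp"]))
  # pins are 4.2 mm apart centre-to-centre (within a voxel)
  pl <- colMeans(beatfield:::cell_coords(hd, hd$electrodes$pin_L$cells))
  pr <- colMeans(beatfield:::cell_coords(hd, hd$electrodes$pin_R$cells))
  expect_lt(abs(sqrt(sum((pl - pr)^2)) - 4.2), 2 * hd$spacing)
})

test_that("non-nested shells are a geometry error", {
  expect_error(build_layered_head(shell_semiaxes_mm = list(
    scalp = c(6, 5, 4.5), skull = c(6, 5, 4.5)),
    conductivity_table = c(scalp = 0.465, skull = 0.01)), "nested")
})

test_that("unbalanced injection patterns are refused", {
  expect_error(current_pattern(c(a = 1, b = -0.5)), "sum to 0")
  expect_silent(current_pattern(c(a = 1, b = -1)))
})

test_that("disk solves are symmetric, linear, and charge-conserving", {
  ph <- build_disk_phantom(20, 1, list(
    list(id = "S", angle_deg = 90, arc_mm = 4),
    list(id = "K", angle_deg = 270, arc_mm = 4)))
  sol <- solve_potential(ph, current_pattern(c(S = 1, K = -1)))
  expect_lt(sol$residual, 1e-8)
  expect_lt(abs(mean(sol$potential)), 1e-12)   # zero-mean gauge

  # antisymmetry about the horizontal bisector (y -> -y negates V)
  cc <- beatfield:::cell_coords(ph, which(ph$mask))
  key <- paste(round(cc[, 1], 6), round(-cc[, 2], 6))
  mirror <- match(key, paste(round(cc[, 1], 6), round(cc[, 2], 6)))
  expect_lt(max(abs(sol$potential + sol$potential[mirror])),
            1e-6 * max(abs(sol$potential)))

  # linearity: doubled current doubles the potential
  sol2 <- solve_potential(ph, current_pattern(c(S = 2, K = -2)))
  expect_lt(max(abs(sol2$potential - 2 * sol$potential)),
            1e-6 * max(abs(sol2$potential)))

  # reciprocity on the symmetric geometry: swapped source/sink negates V
  solr <- solve_potential(ph, current_pattern(c(S = -1, K = 1)))
  expect_lt(max(abs(solr$potential + sol$potential)),
            1e-6 * max(abs(sol$potential)))

  # electrode fluxes reproduce the injections and sum to zero
  fl <- electrode_fluxes(sol, ph)
  expect_lt(abs(fl[["S"]] - 1), 1e-6)
  expect_lt(abs(sum(fl)), 1e-6)
})

test_that("disk solutions converge to the closed-form dipole field", {
  # point-like rim source/sink; max interior error away from the
  # electrodes must shrink with observed order >= 1 under refinement
  err_at <- function(h) {
    R <- 10
    ph <- build_disk_phantom(R, h, list(
      list(id = "S", angle_deg = 90, arc_mm = h),
      list(id = "K", angle_deg = 270, arc_mm = h)))
    sol <- solve_potential(ph, current_pattern(c(S = 1, K = -1)))
    cc <- beatfield:::cell_coords(ph, which(ph$mask))
    pa <- rim_point(ph, "S", R)
    pb <- rim_point(ph, "K", R)
    Va <- disk_dipole_potential(cc, pa, pb)
    far <- sqrt(rowSums(sweep(cc, 2, pa)^2)) > 0.25 * R &
      sqrt(rowSums(sweep(cc, 2, pb)^2)) > 0.25 * R &
      sqrt(rowSums(cc^2)) < 0.85 * R
    Vaf <- Va[far] - mean(Va[far])
    Vnf <- sol$potential[far] - mean(sol$potential[far])
    max(abs(Vnf - Vaf)) / max(abs(Vaf))
  }
  errs <- vapply(c(1, 0.5, 0.25), err_at, numeric(1))
  expect_true(all(diff(errs) < 0))
  order_obs <- log2(errs[1] / errs[3]) / 2
  expect_gte(order_obs, 1)
})

test_that("electric_field differentiates potentials correctly", {
  ph <- build_disk_phantom(10, 1)
  cc <- beatfield:::cell_coords(ph, which(ph$mask))
  # uniform-gradient potential V = a*x -> constant field (-a, 0)
  a <- 3.2
  sol <- structure(list(potential = a * cc[, 1] / 1000,   # V, x in m
                        grid_dims = ph$dims, grid_spacing = ph$spacing,
                        pattern = NULL),
                   class = "potential_solution")
  E <- electric_field(sol, ph)
  interior <- sqrt(rowSums(cc^2)) < 7
  expect_lt(max(abs(E$values[interior, 1] + a)), 1e-9)
  expect_lt(max(abs(E$values[interior, 2])), 1e-9)

  # constant potential -> zero field everywhere
  sol0 <- sol; sol0$potential <- rep(1, sum(ph$mask))
  expect_equal(max(abs(electric_field(sol0, ph)$values)), 0)

  # mismatched grid refused
  ph2 <- build_disk_phantom(12, 1)
  expect_error(electric_field(sol, ph2), "match")
})

test_that("field magnitude peaks next to the driving electrodes", {
  R <- 20
  ph <- build_disk_phantom(R, 1, list(
    list(id = "S", angle_deg = 90, arc_mm = 2),
    list(id = "K", angle_deg = 270, arc_mm = 2)))
  E <- beatfield:::solve_field(ph, current_pattern(c(S = 1, K = -1)))
  cc <- beatfield:::cell_coords(ph, which(ph$mask))
  pk <- cc[which.max(field_magnitude(E)), ]
  d_src <- min(sqrt(sum((pk - rim_point(ph, "S", R))^2)),
               sqrt(sum((pk - rim_point(ph, "K", R))^2)))
  expect_lt(d_src, 3)   # within a few cells of an electrode
})

test_that("lead field reproduces direct solves by superposition", {
  ph <- small_disk()
  lf <- lead_field(ph)
  expect_equal(dim(lf$basis), c(4L, sum(ph$mask), 2L))
  expect_identical(lf$channel_order, names(ph$electrodes))

  pat <- current_pattern(c(A1 = 0.7, A2 = -0.2, B1 = -0.9, B2 = 0.4))
  E_sup <- apply_lead_field(lf, pat)
  E_dir <- beatfield:::solve_field(ph, pat)
  expect_lt(max(abs(E_sup$values - E_dir$values)),
            1e-6 * max(abs(E_dir$values)))

  # under the reference policy a unit pair pattern returns its basis row
  lf2 <- lead_field(ph, "reference", reference = "B2")
  expect_equal(dim(lf2$basis)[1], 3L)
  E_row <- apply_lead_field(lf2, current_pattern(c(A1 = 1, B2 = -1)))
  expect_equal(E_row$values, lf2$basis[1, , ])

  one <- build_disk_phantom(20, 1, four_arcs()[1])
  expect_error(lead_field(one), "at least 2")
})

test_that("pair impedance obeys conductance scaling and calibrates", {
  ph <- small_disk()
  z1 <- pair_impedance(ph, "A1", "A2")
  expect_gt(z1, 0)
  ph2 <- ph
  ph2$conductivity[] <- 2
  expect_equal(pair_impedance(ph2, "A1", "A2"), z1 / 2, tolerance = 1e-8)
  expect_equal(pair_impedance(ph, "A1", "A2", current_mA = 2), z1,
               tolerance = 1e-8)
  expect_error(pair_impedance(ph, "A1", "A1"), "distinct")

  cal <- calibrate_phantom_conductivity(ph, "A1", "A2", target_kohm = 3,
                                        bounds_S_per_m = c(0.05, 5))
  expect_lt(abs(cal$impedance_kohm - 3), 1e-3)
  # bisection interval shrinks monotonically: successive iterates approach
  # the calibrated value
  dev <- abs(cal$trace$impedance_kohm - 3)
  expect_lt(dev[length(dev)], dev[1])
  # analytic check: impedance scales as 1/sigma, so the calibrated sigma
  # equals sigma0 * Z(sigma0) / 3
  expect_equal(cal$conductivity_S_per_m, 1 * z1 / 3, tolerance = 1e-3)
})
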