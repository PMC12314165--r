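test_that("probe waveform synthesis produces the expected two-tone signal", {
  # single pair energised: pure sinusoid at f1 on the x axis
  w <- synth_probe_waveform(c(1, 0), c(0, 0), 2000, 2001, duration_s = 2,
                            fs = 20000)
  expect_equal(w$samples[, 1], sin(2 * pi * 2000 * w$t), tolerance = 1e-12)
  expect_equal(max(abs(w$samples[, 2])), 0)

  # equal in-phase projections at one frequency double the amplitude
  # (checked on the analytic envelope: sample times need not hit the crest)
  w2 <- synth_probe_waveform(c(1, 0), c(1, 0), 2000, 2000,
                             duration_s = 0.05, fs = 20000)
  env2 <- beatfield:::analytic_envelope(w2$samples[, 1])
  expect_equal(stats::median(env2), 2, tolerance = 1e-3)

  # unit tones at 2000/2001 Hz wax and wane with a 1-s period
  w3 <- synth_probe_waveform(c(1, 0), c(1, 0), 2000, 2001, fs = 20000)
  env <- beatfield:::analytic_envelope(w3$samples[, 1])
  core <- seq(1000, length(env) - 1000)
  # envelope maxima recur once per second
  pk1 <- which.max(env[core][1:20000])
  pk2 <- which.max(env[core][20001:40000]) + 20000
  expect_equal((pk2 - pk1) / 20000, 1, tolerance = 0.01)

  expect_error(synth_probe_waveform(c(1, 0), c(1, 0), 2000, 2001,
                                    fs = 3000), "undersampling")
  expect_error(synth_probe_waveform(c(1, 0), c(1, 0), 2000, 2001,
                                    duration_s = 1, fs = 20000),
               "2 beat periods")
})

test_that("time-domain envelope extraction matches the closed forms", {
  w <- synth_probe_waveform(c(1, 0), c(1, 0), 2000, 2001, fs = 20000)
  expect_equal(extract_envelope_modulation(w), 2, tolerance = 1e-6)
  w <- synth_probe_waveform(c(1, 0), c(0.5, 0), 2000, 2001, fs = 20000)
  expect_equal(extract_envelope_modulation(w), 1, tolerance = 1e-6)
  w <- synth_probe_waveform(c(1, 0), c(0, 0), 2000, 2001, fs = 20000)
  expect_lt(extract_envelope_modulation(w), 1e-6)   # single tone: no beat
})

test_that("extraction agrees with 2*min across beats and amplitude ratios", {
  for (beat in c(0.5, 1, 5, 10)) {
    for (ratio in c(1, 2, 10)) {
      E1 <- c(0.8, 0.3)
      E2 <- c(-0.2, 0.5) / ratio
      w <- synth_probe_waveform(E1, E2, 2000, 2000 + beat, fs = 20000)
      truth <- 2 * min(sqrt(sum(E1^2)), sqrt(sum(E2^2)))
      expect_equal(extract_envelope_modulation(w), truth,
                   tolerance = 0.01)
    }
  }
})

test_that("noise-free grid scans reproduce the analytic envelope map", {
  ph <- small_disk(radius_mm = 20, step_mm = 1)
  sys <- beatfield:::assemble_system(ph)
  E1 <- beatfield:::solve_field(ph, current_pattern(c(A1 = 1, A2 = -1), 2000),
                                system = sys)
  E2 <- beatfield:::solve_field(ph, current_pattern(c(B1 = 1, B2 = -1), 2001),
                                system = sys)
  scan <- grid_scan(ph, E1, E2, step_mm = 5, replicates = 1, fs = 20000)
  env <- envelope_amplitude(E1, E2)
  cc <- beatfield:::cell_coords(ph, which(ph$mask))
  truth <- env$values[match(paste(scan$x_mm, scan$y_mm),
                            paste(cc[, 1], cc[, 2]))]
  expect_true(all(abs(scan$value - truth) <= 0.001 * pmax(truth, 1e-9)))

  # replicates are irrelevant without noise
  scan3 <- grid_scan(ph, E1, E2, step_mm = 5, replicates = 3, fs = 20000)
  expect_equal(scan3$value, scan$value)

  expect_error(grid_scan(ph, E1, E2, step_mm = 0.5), "below the grid")
  expect_error(grid_scan(ph, E1, E2, step_mm = 2.5), "multiple")
})

test_that("triplicate averaging shrinks probe-noise error", {
  ph <- small_disk(radius_mm = 15, step_mm = 1)
  sys <- beatfield:::assemble_system(ph)
  E1 <- beatfield:::solve_field(ph, current_pattern(c(A1 = 1, A2 = -1), 2000),
                                system = sys)
  E2 <- beatfield:::solve_field(ph, current_pattern(c(B1 = 1, B2 = -1), 2001),
                                system = sys)
  env <- envelope_amplitude(E1, E2)
  cc <- beatfield:::cell_coords(ph, which(ph$mask))
  truth_at <- function(scan) env$values[match(paste(scan$x_mm, scan$y_mm),
                                              paste(cc[, 1], cc[, 2]))]
  err <- function(reps, seed) {
    s <- grid_scan(ph, E1, E2, step_mm = 5, replicates = reps,
                   noise_sd = 0.5, seed = seed, fs = 10000)
    mean(abs(s$value - truth_at(s)))
  }
  # Monte-Carlo over a few seeds: 9 replicates average out more noise than 1
  e1 <- mean(vapply(1:4, function(s) err(1, s), numeric(1)))
  e9 <- mean(vapply(1:4, function(s) err(9, s), numeric(1)))
  expect_lt(e9, e1)
})

test_that("bilinear interpolation is exact on nodes and affine maps", {
  sc <- expand.grid(x_mm = seq(-10, 10, 5), y_mm = seq(-10, 10, 5))
  sc$value <- 7
  dense <- interpolate_map(sc, 1)
  expect_true(all(abs(dense$value - 7) < 1e-12))       # constant preserved

  sc$value <- 2 * sc$x_mm + 3 * sc$y_mm
  dense <- interpolate_map(sc, 1)
  expect_equal(dense$value, 2 * dense$x_mm + 3 * dense$y_mm,
               tolerance = 1e-12)                      # affine reproduced
  # nodes preserved exactly
  at_nodes <- merge(sc, dense, by = c("x_mm", "y_mm"))
  expect_equal(at_nodes$value.x, at_nodes$value.y, tolerance = 1e-12)

  # interpolant never exceeds the local node range
  set.seed(2)
  sc$value <- runif(nrow(sc))
  dense <- interpolate_map(sc, 1)
  expect_true(all(dense$value >= min(sc$value) - 1e-12 &
                    dense$value <= max(sc$value) + 1e-12))

  expect_error(interpolate_map(sc[1, ], 1), "2x2")
})

test_that("line cuts normalize and reflect montage symmetry", {
  const <- data.frame(x_mm = rep(-5:5, 11), y_mm = rep(-5:5, each = 11),
                      value = 4)
  prof <- line_cut(const, "horizontal", radius_mm = 5)
  expect_true(all(prof$value_norm == 1))
  expect_equal(range(prof$pos_norm), c(-1, 1))

  ph <- small_disk(radius_mm = 20, step_mm = 1)
  sw <- ratio_sweep(ph, c("A1", "A2"), c("B1", "B2"), c(1, 4))
  # 1:1 montage: horizontal profile symmetric about the centre
  p1 <- line_cut(sw[[1]]$envelope, "horizontal", grid = ph, radius_mm = 20)
  rev_match <- rev(p1$value_norm)
  expect_equal(p1$value_norm, rev_match, tolerance = 1e-4)
  # 1:4: profile peak shifted toward the weaker pair (negative x)
  p4 <- line_cut(sw[[2]]$envelope, "horizontal", grid = ph, radius_mm = 20)
  expect_lt(p4$pos_norm[which.max(p4$value_norm)], 0)
})
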