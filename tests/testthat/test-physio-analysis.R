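test_that("isosbestic regression removes exactly shared artifacts", {
  set.seed(21)
  n <- 2000
  drift <- 0.5 * exp(-(1:n) / 800)
  signal <- c(rep(0, 800), rep(0.3, 400), rep(0, 800))
  # least-squares subtraction removes the drift exactly when the signal is
  # orthogonal to it; project out the shared component first
  signal <- signal - drift * sum(signal * (drift - mean(drift))) /
    sum((drift - mean(drift))^2)
  f470 <- 2 + signal + drift
  f405 <- 1 + 0.6 * drift
  corrected <- correct_photometry(list(signal_470 = f470,
                                       control_405 = f405))
  # identical channels cancel completely
  same <- correct_photometry(list(signal_470 = f405, control_405 = f405))
  expect_lt(max(abs(same)), 1e-12)
  # drift carried (scaled) by the control is removed up to a constant
  resid <- corrected - signal
  expect_lt(diff(range(resid)), 0.02 * diff(range(signal)))
  expect_identical(attr(corrected, "method"), "regression")

  # independent white channels: fitted slope near zero, output ~ demeaned 470
  a <- rnorm(n); b <- rnorm(n)
  ind <- correct_photometry(list(signal_470 = a, control_405 = b))
  expect_lt(abs(attr(ind, "coefficients")["a"]), 0.1)
  expect_equal(as.numeric(ind), a - (attr(ind, "coefficients")["a"] * b +
                                       attr(ind, "coefficients")["b"]),
               ignore_attr = TRUE)

  # flat control channel: flagged mean-subtraction fallback
  flat <- correct_photometry(list(signal_470 = a, control_405 = rep(1, n)))
  expect_identical(attr(flat, "method"), "mean")
  expect_equal(as.numeric(flat), a - mean(a), ignore_attr = TRUE)

  expect_error(correct_photometry(list(signal_470 = a, control_405 = b[-1])),
               "equal length")
})

test_that("dF/F applies the baseline-normalized formula", {
  fs <- 100
  f <- c(rep(100, 5 * fs), rep(110, 2 * fs), rep(95, 2 * fs))
  dff <- delta_f_over_f(f, fs, baseline_window = c(0, 5))
  expect_equal(unique(dff[1:(5 * fs)]), 0)
  expect_equal(dff[5 * fs + 1], 0.1)
  expect_equal(dff[7 * fs + 1], -0.05)

  # constant trace: identically zero
  expect_true(all(delta_f_over_f(rep(7, 100), 10, c(0, 5)) == 0))
  # gain invariance: rescaling F leaves dF/F unchanged
  expect_equal(delta_f_over_f(3.7 * f, fs, c(0, 5)), dff)
  # zero baseline mean is an error
  expect_error(delta_f_over_f(c(rep(0, 50), rep(1, 50)), 10, c(0, 5)),
               "zero")
})

test_that("gaussian smoothing preserves mass and handles edge cases", {
  x <- rnorm(500)
  expect_identical(gaussian_smooth(x, 100, 0), x)          # sd = 0: identity
  expect_equal(gaussian_smooth(rep(3, 100), 100, 0.05), rep(3, 100))
  # unit impulse maps to a kernel summing to 1
  imp <- c(rep(0, 250), 1, rep(0, 250))
  sm <- gaussian_smooth(imp, 100, 0.02)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  expect_equal(which.max(sm), 251)
  # long stationary trace keeps its mean
  expect_equal(mean(gaussian_smooth(x, 100, 0.05)), mean(x),
               tolerance = 1e-2 * stats::sd(x))
  expect_error(gaussian_smooth(x, 100, -1), ">= 0")
})

test_that("resampling decimates cleanly from the camera to analysis rate", {
  x <- rnorm(4000)
  y <- resample_trace(x, 200, 100)
  expect_length(y, 2000)                       # N -> N/2
  expect_identical(resample_trace(x, 200, 200), x)
  dc <- resample_trace(rep(2.5, 1000), 200, 100)
  expect_equal(dc, rep(2.5, 500), tolerance = 1e-6)
  expect_error(resample_trace(x, 100, 200), "upsampling")
  expect_error(resample_trace(x, 200, 150), "divide")
})

test_that("pupil displacement converts to rotation angle by arcsin", {
  mk_eye <- function(d) list(pupil_xy = unname(cbind(d, 0)), fs = 100,
                             t = seq_along(d) / 100, epoch_marks = NULL)
  r <- 1.67
  expect_equal(pupil_to_angle(mk_eye(0), r)$angle_xy[1, 1], 0)
  expect_equal(pupil_to_angle(mk_eye(r), r)$angle_xy[1, 1], 90)
  # 0.02915 mm on a 1.67-mm eyeball is almost exactly one degree
  expect_equal(pupil_to_angle(mk_eye(0.02915), r)$angle_xy[1, 1], 1,
               tolerance = 2e-4)
  # odd symmetry
  d <- seq(-0.5, 0.5, length.out = 11)
  th <- pupil_to_angle(mk_eye(d), r)$angle_xy[, 1]
  expect_equal(th, -rev(th))
  # small-angle mode agrees for small displacements
  th_lin <- pupil_to_angle(mk_eye(0.01), r, small_angle = TRUE)$angle_xy[1, 1]
  expect_equal(th_lin, pupil_to_angle(mk_eye(0.01), r)$angle_xy[1, 1],
               tolerance = 1e-4)
  expect_error(pupil_to_angle(mk_eye(2), r), "exceeds")
})

test_that("windowed signed-rank comparison behaves at its boundary cases", {
  fs <- 10
  onsets <- seq(10, by = 20, length.out = 15)
  n <- 320 * fs
  t <- (1:n) / fs
  base <- rep(1, n)
  # identical windows: null-centred statistic, p = 1
  wc <- window_compare(base, fs, onsets)
  expect_identical(wc$p_value, 1)
  expect_equal(wc$statistic, 15 * 16 / 4)

  # large distinct positive shifts during stimulation: the exact p for 15
  # uniformly positive paired differences is 2 * 2^-15 < 0.001 (distinct
  # magnitudes keep the exact signed-rank distribution applicable)
  x <- base
  for (k in seq_along(onsets)) {
    on <- onsets[k]
    x[t >= on & t < on + 3] <- 5 + 0.1 * k
  }
  wc2 <- window_compare(x, fs, onsets)
  expect_lt(wc2$p_value, 0.001)
  expect_equal(wc2$p_value, 2 / 2^15, tolerance = 1e-9)
  expect_identical(wc2$direction, 1)
  expect_identical(wc2$stars, "***")

  # sign flip: same p, opposite direction
  wc3 <- window_compare(-x, fs, onsets)
  expect_equal(wc3$p_value, wc2$p_value)
  expect_identical(wc3$direction, -1)

  expect_error(window_compare(x, fs, onsets[1:3]), "at least 5")
})

test_that("entrainment spectra localise band power correctly", {
  fs <- 100
  t <- (0:1999) / fs
  # a pure 2-Hz tone concentrates nearly all normalized power in its band
  sp <- entrainment_spectrum(sin(2 * pi * 2 * t), fs)
  expect_identical(sp$peak_frequency_Hz, 2)
  expect_gt(sp$normalized_power[sp$band_centers_Hz == 2], 0.99)
  expect_equal(sum(sp$normalized_power), 1, tolerance = 1e-9)

  # white noise: no band dominates (below twice the mean band power)
  set.seed(31)
  spw <- entrainment_spectrum(replicate(10, rnorm(2000), simplify = FALSE),
                              fs)
  expect_lt(max(spw$band_power), 2 * mean(spw$band_power))

  # end-to-end: synthetic entrainment at 1 Hz recovered through the full
  # photometry pipeline
  prot <- stim_protocol(beat_Hz = 1, intensity_mA = 1, n_trials = 5)
  pars <- quick_params(seed = 8)
  ph <- simulate_photometry(simulate_sc_activity(prot, pars))
  dff <- photometry_dff(ph, smoothing_sd_s = 0)
  spe <- entrainment_spectrum(stim_segments(dff, ph$fs, ph$epoch_marks),
                              ph$fs)
  expect_identical(spe$peak_frequency_Hz, 1)

  expect_error(entrainment_spectrum(rnorm(50), fs), "too short")
})
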