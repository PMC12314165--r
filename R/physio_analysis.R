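#' Isosbestic (405-nm) correction of a photometry trace
#'
#' Removes shared motion/bleaching artifacts by subtracting the 405-nm
#' control channel scaled onto the 470-nm channel: the correction is
#' `470 - (a * 405 + b)` with `(a, b)` the least-squares regression of the
#' 470-nm channel on the control. A zero-variance control channel cannot be
#' scaled; the function then falls back to mean subtraction and flags it.
#'
#' @param trace a `photometry_trace`, or a list with numeric `signal_470`
#'   and `control_405` of equal length.
#' @return Numeric corrected signal (mean approximately zero) with
#'   attributes `method` (`"regression"` or `"mean"`), `coefficients`.
#' @export
correct_photometry <- function(trace) {
  f470 <- trace$signal_470
  f405 <- trace$control_405
  if (length(f470) != length(f405)) {
    stop("channels must have equal length", call. = FALSE)
  }
  v <- stats::var(f405)
  if (!is.finite(v) || v < .Machine$double.eps) {
    out <- f470 - mean(f470)
    attr(out, "method") <- "mean"
    attr(out, "coefficients") <- c(a = 0, b = mean(f470))
    return(out)
  }
  a <- stats::cov(f405, f470) / v
  b <- mean(f470) - a * mean(f405)
  out <- f470 - (a * f405 + b)
  attr(out, "method") <- "regression"
  attr(out, "coefficients") <- c(a = a, b = b)
  out
}

#' Baseline-normalized fluorescence change
#'
#' `dF/F = (F - F_baseline) / F_baseline`, with `F_baseline` the mean
#' fluorescence over a pre-stimulus baseline window (5 s before onset in
#' the reference protocol).
#'
#' @param signal numeric fluorescence trace.
#' @param fs sampling rate, Hz.
#' @param baseline_window length-2 numeric, start/end of the baseline
#'   window in seconds from trace start (end exclusive).
#' @param baseline_reference optional second trace whose baseline mean is
#'   used as the denominator (e.g. the raw 470-nm channel when `signal` is
#'   the zero-mean corrected trace); defaults to `signal` itself.
#' @return Numeric dF/F trace.
#' @export
delta_f_over_f <- function(signal, fs, baseline_window,
                           baseline_reference = NULL) {
  t <- (seq_along(signal) - 1) / fs
  sel <- t >= baseline_window[1] & t < baseline_window[2]
  if (!any(sel)) stop("baseline window is empty", call. = FALSE)
  f0_num <- mean(signal[sel])
  f0_den <- if (is.null(baseline_reference)) f0_num else {
    mean(baseline_reference[sel])
  }
  if (abs(f0_den) < .Machine$double.eps^0.5) {
    stop("baseline mean is zero; dF/F undefined", call. = FALSE)
  }
  (signal - f0_num) / f0_den
}

#' Gaussian smoothing of a trace
#'
#' Convolution with a unit-area Gaussian kernel of standard deviation
#' `sd_s` seconds (truncated at four standard deviations, edges handled by
#' reflection); `sd_s = 0` returns the input unchanged.
#'
#' @param x numeric trace.
#' @param fs sampling rate, Hz.
#' @param sd_s kernel standard deviation, s (>= 0).
#' @return Smoothed trace of the same length.
#' @export
gaussian_smooth <- function(x, fs, sd_s) {
  if (sd_s < 0) stop("sd_s must be >= 0", call. = FALSE)
  if (sd_s == 0) return(x)
  n <- length(x)
  if (n < 2L) return(x)
  sd_n <- sd_s * fs
  half <- max(1L, min(ceiling(4 * sd_n), n - 1L))
  k <- stats::dnorm(seq(-half, half), sd = sd_n)
  k <- k / sum(k)
  pad <- half
  xp <- c(x[pad:1], x, x[n:(n - pad + 1)])
  sm <- stats::filter(xp, k, method = "convolution", sides = 2)
  as.numeric(sm[(pad + 1):(pad + n)])
}

#' Down-sample a trace with anti-alias filtering
#'
#' Zero-phase low-pass (forward-backward Butterworth at 40% of the target
#' rate, reflection-padded) followed by decimation. Only integer decimation
#' factors are supported; `to_Hz` equal to the source rate returns the
#' input, and upsampling is refused.
#'
#' @param x numeric trace.
#' @param fs source rate, Hz.
#' @param to_Hz target rate, Hz (must divide `fs`).
#' @return Numeric trace at `to_Hz`.
#' @export
resample_trace <- function(x, fs, to_Hz) {
  if (to_Hz > fs) stop("upsampling is not supported", call. = FALSE)
  if (to_Hz == fs) return(x)
  k <- fs / to_Hz
  if (abs(k - round(k)) > 1e-9) {
    stop("target rate must divide the source rate", call. = FALSE)
  }
  k <- round(k)
  bf <- signal::butter(4, (0.8 * to_Hz / 2) / (fs / 2))
  n <- length(x)
  pad <- min(3L * 2L * 10L, n - 1L)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  xf <- signal::filtfilt(bf, xp)[(pad + 1):(pad + n)]
  xf[seq(1, n, by = k)]
}

#' Convert pupil displacement to eyeball rotation angle
#'
#' After zero-referencing each axis to its mean position in the pre-
#' stimulus baseline windows, the image-plane displacement `d` is converted
#' to a rotation angle `asin(d / r)` in degrees, with `r` the estimated
#' eyeball radius (1.67 mm for the adult mouse). Displacements exceeding
#' the radius are physically impossible and raise an error. A small-angle
#' linear mode (`d / r` in radians, converted to degrees) is available for
#' sensitivity checks.
#'
#' @param eye an `eye_trace`, or a list with `pupil_xy` (n x 2, mm), `t`,
#'   `fs`, `epoch_marks`.
#' @param radius_mm eyeball radius, mm.
#' @param baseline_window_s baseline length before each onset used for
#'   zero-referencing, s.
#' @param small_angle use the linear small-angle conversion.
#' @return The input with `angle_xy` (degrees) added and `radius_mm`
#'   recorded.
#' @export
pupil_to_angle <- function(eye, radius_mm = 1.67, baseline_window_s = 5,
                           small_angle = FALSE) {
  if (radius_mm <= 0) stop("radius must be > 0", call. = FALSE)
  d <- eye$pupil_xy
  if (!is.null(eye$epoch_marks)) {
    base_sel <- rep(FALSE, nrow(d))
    for (k in seq_len(nrow(eye$epoch_marks))) {
      on <- eye$epoch_marks$onset_s[k]
      base_sel <- base_sel | (eye$t >= on - baseline_window_s & eye$t < on)
    }
    if (any(base_sel)) {
      d <- sweep(d, 2, colMeans(d[base_sel, , drop = FALSE]), `-`)
    }
  }
  if (any(abs(d) > radius_mm)) {
    stop("pupil displacement exceeds the eyeball radius", call. = FALSE)
  }
  ang <- if (small_angle) d / radius_mm else asin(d / radius_mm)
  eye$angle_xy <- ang * 180 / pi
  eye$radius_mm <- radius_mm
  eye
}

# exact-ish paired signed-rank with a defined answer for all-zero
# differences (identical windows: null centre, p = 1)
signed_rank_test <- function(pre, during) {
  if (length(pre) != length(during)) {
    stop("unequal trial counts", call. = FALSE)
  }
  d <- during - pre
  if (all(d == 0)) {
    n <- length(d)
    return(list(statistic = n * (n + 1) / 4, p_value = 1))
  }
  ht <- suppressWarnings(stats::wilcox.test(during, pre, paired = TRUE,
                                            exact = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

significance_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Windowed pre/during comparison across trials
#'
#' For each stimulation epoch the trace is averaged over a pre-stimulus
#' window and a window at stimulation onset (3 s each in the reference
#' analysis); the paired per-trial means are compared with a two-sided
#' Wilcoxon signed-rank test, with significance stars at 0.05 / 0.01 /
#' 0.001.
#'
#' @param x numeric trace.
#' @param fs sampling rate, Hz.
#' @param onsets_s stimulation onset times, s (>= 5 trials).
#' @param pre_window_s,during_window_s window lengths, s.
#' @return A list with `statistic`, `p_value`, `direction` (sign of the
#'   median paired difference), `stars`, and the per-trial `means` data
#'   frame.
#' @export
window_compare <- function(x, fs, onsets_s, pre_window_s = 3,
                           during_window_s = 3) {
  if (length(onsets_s) < 5) stop("need at least 5 paired trials",
                                 call. = FALSE)
  t <- (seq_along(x) - 1) / fs
  pre <- vapply(onsets_s, function(on) {
    mean(x[t >= on - pre_window_s & t < on])
  }, numeric(1))
  during <- vapply(onsets_s, function(on) {
    mean(x[t >= on & t < on + during_window_s])
  }, numeric(1))
  ht <- signed_rank_test(pre, during)
  list(statistic = ht$statistic, p_value = ht$p_value,
       direction = sign(stats::median(during - pre)),
       stars = significance_stars(ht$p_value),
       means = data.frame(trial = seq_along(onsets_s), pre = pre,
                          during = during))
}

#' Entrainment spectrum with 1-Hz band aggregation
#'
#' Mean Hann-tapered periodogram over the supplied segments (typically the
#' stimulation windows of all trials), aggregated into bands of width
#' `band_width_Hz` centred on 1, 2, ... up to `fmax_Hz`. The peak frequency
#' is the centre of the maximal band; normalized band powers sum to one
#' over the reported range.
#'
#' @param segments a numeric vector or a list of numeric vectors (one per
#'   stimulation window).
#' @param fs sampling rate, Hz.
#' @param band_width_Hz aggregation band width, Hz.
#' @param fmax_Hz highest band centre, Hz.
#' @return An object of class `spectral_summary` with `frequencies`,
#'   `power` (raw periodogram, averaged), `band_centers_Hz`, `band_power`,
#'   `normalized_power`, `peak_frequency_Hz`.
#' @export
entrainment_spectrum <- function(segments, fs, band_width_Hz = 1,
                                 fmax_Hz = 10) {
  if (band_width_Hz <= 0) stop("band width must be > 0", call. = FALSE)
  if (!is.list(segments)) segments <- list(segments)
  centers <- seq(band_width_Hz, fmax_Hz, by = band_width_Hz)
  fmin <- centers[1] - band_width_Hz / 2
  min_len <- ceiling(2 / max(fmin, 1e-9) * fs)
  nseg <- min(lengths(segments))
  if (nseg < min_len) {
    stop("record too short: need >= 2 cycles of the lowest band",
         call. = FALSE)
  }
  n <- min(lengths(segments))      # common segment length for averaging
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))   # Hann taper
  pows <- lapply(segments, function(s) {
    s <- s[seq_len(n)]
    s <- (s - mean(s)) * w
    p <- Mod(stats::fft(s))^2 / (fs * sum(w^2))
    p[seq_len(floor(n / 2) + 1)]
  })
  power <- Reduce(`+`, pows) / length(pows)
  freq <- (seq_along(power) - 1) * fs / n
  band_power <- vapply(centers, function(c0) {
    sum(power[freq >= c0 - band_width_Hz / 2 &
                freq < c0 + band_width_Hz / 2])
  }, numeric(1))
  total <- sum(band_power)
  norm <- if (total > 0) band_power / total else band_power
  structure(list(frequencies = freq, power = power,
                 band_centers_Hz = centers, band_power = band_power,
                 normalized_power = norm,
                 peak_frequency_Hz = centers[which.max(band_power)]),
            class = "spectral_summary")
}

#' Extract per-trial stimulation-window segments from a trace
#'
#' @param x numeric trace.
#' @param fs sampling rate, Hz.
#' @param epoch_marks data frame with `onset_s` and `offset_s`.
#' @param window_s optional cap on the analysed span after onset, s.
#' @return List of numeric segments, one per epoch.
#' @export
stim_segments <- function(x, fs, epoch_marks, window_s = NULL) {
  t <- (seq_along(x) - 1) / fs
  lapply(seq_len(nrow(epoch_marks)), function(k) {
    on <- epoch_marks$onset_s[k]
    off <- epoch_marks$offset_s[k]
    if (!is.null(window_s)) off <- min(off, on + window_s)
    x[t >= on & t < off]
  })
}

#' Full photometry pipeline: correction, dF/F, smoothing
#'
#' Applies the isosbestic correction, computes dF/F against the 5-s
#' pre-stimulus baseline of the first epoch (denominator from the raw
#' 470-nm baseline so the scale is fluorescence-relative), and smooths
#' with a Gaussian kernel.
#'
#' @param trace a `photometry_trace`.
#' @param smoothing_sd_s Gaussian smoothing sd, s.
#' @param baseline_window_s baseline length before the first onset, s.
#' @return Numeric dF/F trace at `trace$fs`.
#' @export
photometry_dff <- function(trace, smoothing_sd_s = 0.1,
                           baseline_window_s = 5) {
  corrected <- correct_photometry(trace)
  on1 <- trace$epoch_marks$onset_s[1]
  dff <- delta_f_over_f(as.numeric(corrected), trace$fs,
                        baseline_window = c(on1 - baseline_window_s, on1),
                        baseline_reference = trace$signal_470)
  gaussian_smooth(dff, trace$fs, smoothing_sd_s)
}

#' Eye-movement amplitude trace in degrees
#'
#' Converts a pupil trace to rotation angles, reports the radial amplitude
#' `sqrt(theta_x^2 + theta_y^2)` (per-axis angles remain available from
#' [pupil_to_angle()]), smooths it, and down-samples to the analysis rate.
#'
#' @param eye an `eye_trace`.
#' @param radius_mm eyeball radius, mm.
#' @param smoothing_sd_s Gaussian smoothing sd, s.
#' @param resample_to_Hz target rate, Hz (100 in the reference analysis).
#' @return Numeric amplitude trace (degrees) at `resample_to_Hz` with the
#'   rate attached as attribute `fs`.
#' @export
eye_amplitude <- function(eye, radius_mm = 1.67, smoothing_sd_s = 0.05,
                          resample_to_Hz = 100) {
  ang <- pupil_to_angle(eye, radius_mm = radius_mm)$angle_xy
  amp <- sqrt(rowSums(ang^2))
  amp <- gaussian_smooth(amp, eye$fs, smoothing_sd_s)
  out <- resample_trace(amp, eye$fs, resample_to_Hz)
  attr(out, "fs") <- resample_to_Hz
  out
}
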