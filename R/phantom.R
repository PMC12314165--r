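#' Synthesize the dipole-probe waveform at one location
#'
#' The two-frequency field at a probe location projects onto the probe's
#' two orthogonal dipole axes; each axis sees a scalar two-tone signal
#' `E1.u * sin(2*pi*f1*t) + E2.u * sin(2*pi*f2*t)`. Defaults emulate the
#' bench: 2 kHz / 2.001 kHz carriers sampled at 50 kHz for three beat
#' periods.
#'
#' @param E1_at_r,E2_at_r length-2 field vectors at the location, V/m.
#' @param f1,f2 carrier frequencies, Hz.
#' @param duration_s record length, s; default 3 beat periods (3 s at a
#'   1-Hz beat), must cover at least 2 beat periods when `f1 != f2`.
#' @param fs sample rate, Hz; must exceed twice the highest carrier.
#' @param axes 2x2 matrix whose rows are the unit probe axes.
#' @return An object of class `probe_waveform` with `samples` (n x 2
#'   matrix, one column per probe axis), `fs`, `duration_s`, `carriers`.
#' @export
synth_probe_waveform <- function(E1_at_r, E2_at_r, f1 = 2000, f2 = 2001,
                                 duration_s = NULL, fs = 50000,
                                 axes = diag(2)) {
  beat <- abs(f1 - f2)
  if (is.null(duration_s)) {
    duration_s <- if (beat > 0) 3 / beat else 0.05
  }
  if (fs <= 2 * max(f1, f2)) {
    stop("fs must exceed twice the highest carrier (undersampling)",
         call. = FALSE)
  }
  if (beat > 0 && duration_s < 2 / beat) {
    stop("duration must cover at least 2 beat periods", call. = FALSE)
  }
  n <- round(duration_s * fs)        # endpoint excluded: whole periods, and
  t <- (seq_len(n) - 1) / fs         # composite FFT lengths

  p1 <- as.numeric(axes %*% E1_at_r)   # projections on the two axes
  p2 <- as.numeric(axes %*% E2_at_r)
  s1 <- sin(2 * pi * f1 * t)
  s2 <- sin(2 * pi * f2 * t)
  samples <- cbind(p1[1] * s1 + p2[1] * s2,
                   p1[2] * s1 + p2[2] * s2)
  structure(list(samples = samples, fs = fs, duration_s = duration_s,
                 carriers = c(f1, f2), t = t),
            class = "probe_waveform")
}

# analytic-signal envelope |x + i H(x)| via the FFT construction
analytic_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# single-frequency amplitude by quadrature demodulation over whole periods
tone_amplitude <- function(x, fs, f) {
  t <- (seq_along(x) - 1) / fs
  n_per <- floor(t[length(t)] * f)
  keep <- t < n_per / f
  ph <- exp(-2i * pi * f * t[keep])
  2 * Mod(mean(x[keep] * ph))
}

#' Envelope-modulation amplitude of a probe record
#'
#' Time-domain counterpart of the `2*min(|E1|,|E2|)` map: per probe axis
#' the analytic-signal envelope of the two-tone record is evaluated over
#' whole beat periods; its max/min give the two tone amplitudes on that
#' axis (`(max+min)/2` and `(max-min)/2`), the tones are assigned to
#' carriers by their quadrature amplitudes, each carrier's amplitude is
#' combined across the two orthogonal axes as a root-sum-square, and the
#' modulation amplitude is `2 * min(|E1|, |E2|)`. For a scalar two-tone
#' signal with tone amplitudes A1, A2 this equals `2 * min(A1, A2)`.
#'
#' @param w a `probe_waveform`.
#' @param edge_trim_frac fraction of the record dropped at each end before
#'   taking the envelope extrema (analytic-signal edge effects).
#' @return Modulation amplitude, V/m (scalar, >= 0).
#' @export
extract_envelope_modulation <- function(w, edge_trim_frac = 0.05) {
  stopifnot(inherits(w, "probe_waveform"))
  f1 <- w$carriers[1]; f2 <- w$carriers[2]
  beat <- abs(f1 - f2)
  n <- nrow(w$samples)
  trim <- floor(n * edge_trim_frac)
  core <- (trim + 1):(n - trim)
  if (beat == 0) {
    # constant envelope: no modulation by definition
    return(0)
  }
  if (w$duration_s * (1 - 2 * edge_trim_frac) < 2 / beat) {
    stop("record too short: need >= 2 whole beat periods after edge trim",
         call. = FALSE)
  }
  per_axis <- lapply(1:2, function(k) {
    x <- w$samples[, k]
    env <- analytic_envelope(x)[core]
    hi <- max(env); lo <- min(env)
    big <- (hi + lo) / 2
    small <- (hi - lo) / 2
    # assign the larger tone to the carrier with the larger quadrature
    # amplitude on this axis
    a1 <- tone_amplitude(x, w$fs, f1)
    a2 <- tone_amplitude(x, w$fs, f2)
    if (a1 >= a2) c(tone1 = big, tone2 = small) else
      c(tone1 = small, tone2 = big)
  })
  A1 <- sqrt(per_axis[[1]]["tone1"]^2 + per_axis[[2]]["tone1"]^2)
  A2 <- sqrt(per_axis[[1]]["tone2"]^2 + per_axis[[2]]["tone2"]^2)
  unname(2 * min(A1, A2))
}

#' Simulated dipole-probe scan of the phantom
#'
#' Replays the bench protocol in silico: at every grid location spaced
#' `step_mm` apart the two-tone probe waveform is synthesized from the two
#' solved fields, optionally corrupted with additive white Gaussian probe
#' noise, the time-domain envelope-modulation amplitude is extracted, and
#' replicate readings are averaged (the bench averaged thrice).
#'
#' @param grid the disk `tissue_grid`.
#' @param E1,E2 `field_map`s of the two electrode pairs on `grid`.
#' @param step_mm scan pitch, mm; must be a multiple of the grid spacing
#'   and at least the grid spacing.
#' @param replicates readings averaged per location (>= 1).
#' @param noise_sd additive Gaussian noise on waveform samples, V/m.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @param f1,f2 carrier frequencies, Hz.
#' @param fs,duration_s waveform synthesis parameters (see
#'   [synth_probe_waveform()]).
#' @return A `scan_map`: data frame with `x_mm`, `y_mm`, `value` (mean
#'   modulation amplitude, V/m) and `n_rep`, with the scan step attached
#'   as attribute `step_mm`.
#' @export
grid_scan <- function(grid, E1, E2, step_mm = 5, replicates = 3,
                      noise_sd = 0, seed = 1, f1 = 2000, f2 = 2001,
                      fs = 50000, duration_s = NULL) {
  stopifnot(inherits(grid, "tissue_grid"))
  if (step_mm < grid$spacing) {
    stop("scan step is below the grid resolution", call. = FALSE)
  }
  if (abs(step_mm / grid$spacing - round(step_mm / grid$spacing)) > 1e-9) {
    stop("scan step must be a multiple of the grid spacing", call. = FALSE)
  }
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  midx <- mask_index(grid)
  cc <- cell_coords(grid, midx)
  on_scan <- abs(cc[, 1] / step_mm - round(cc[, 1] / step_mm)) < 1e-9 &
    abs(cc[, 2] / step_mm - round(cc[, 2] / step_mm)) < 1e-9
  pts <- which(on_scan)
  set.seed(seed)
  vals <- vapply(pts, function(i) {
    w <- synth_probe_waveform(E1$values[i, ], E2$values[i, ], f1 = f1,
                              f2 = f2, fs = fs, duration_s = duration_s)
    reps <- vapply(seq_len(replicates), function(r) {
      wr <- w
      if (noise_sd > 0) {
        wr$samples <- w$samples + matrix(
          stats::rnorm(length(w$samples), sd = noise_sd), nrow(w$samples))
      }
      extract_envelope_modulation(wr)
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  out <- data.frame(x_mm = cc[pts, 1], y_mm = cc[pts, 2], value = vals,
                    n_rep = replicates)
  attr(out, "step_mm") <- step_mm
  class(out) <- c("scan_map", "data.frame")
  out
}

#' Bilinear interpolation of a scan map
#'
#' Densifies the coarse probe scan onto a finer grid with bilinear
#' interpolation (the bench used MatLab's `interp2`), exact at the scan
#' nodes; locations whose surrounding node square is incomplete (outside
#' the scanned disk) are dropped.
#'
#' @param scan a `scan_map` from [grid_scan()].
#' @param target_step_mm output pitch, mm.
#' @return Data frame `x_mm`, `y_mm`, `value`.
#' @export
interpolate_map <- function(scan, target_step_mm = 1) {
  xs <- sort(unique(scan$x_mm))
  ys <- sort(unique(scan$y_mm))
  if (length(xs) < 2 || length(ys) < 2 || nrow(scan) < 4) {
    stop("interpolation needs at least a 2x2 scan", call. = FALSE)
  }
  Z <- matrix(NA_real_, length(ys), length(xs))   # rows = y (interp2 layout)
  Z[cbind(match(scan$y_mm, ys), match(scan$x_mm, xs))] <- scan$value
  xo <- seq(min(xs), max(xs), by = target_step_mm)
  yo <- seq(min(ys), max(ys), by = target_step_mm)
  gx <- rep(xo, times = length(yo))
  gy <- rep(yo, each = length(xo))
  vi <- pracma::interp2(xs, ys, Z, gx, gy, method = "linear")
  keep <- !is.na(vi)
  data.frame(x_mm = gx[keep], y_mm = gy[keep], value = vi[keep])
}

#' Profile of a map along a horizontal or vertical line
#'
#' Extracts the map values along the horizontal or vertical line closest to
#' the requested offset, optionally normalizing the values to the profile
#' peak and the abscissa to the phantom radius (so a full diameter spans
#' [-1, 1] about the centre).
#'
#' @param map a data frame with `x_mm`, `y_mm`, `value` (a dense map or a
#'   `scan_map`), or a `scalar_map` with 2-D geometry plus `grid`.
#' @param axis `"horizontal"` (vary x at fixed y) or `"vertical"`.
#' @param offset_mm the fixed coordinate of the line (default 0: through
#'   the centre).
#' @param normalize if `TRUE`, scale values to peak 1.
#' @param radius_mm if given, report the abscissa in units of this radius.
#' @param grid required when `map` is a `scalar_map`.
#' @return Data frame with `pos_mm`, `value`, and `pos_norm`/`value_norm`
#'   when requested.
#' @export
line_cut <- function(map, axis = c("horizontal", "vertical"),
                     offset_mm = 0, normalize = TRUE, radius_mm = NULL,
                     grid = NULL) {
  axis <- match.arg(axis)
  if (inherits(map, "scalar_map")) {
    if (is.null(grid)) stop("scalar_map input needs its grid", call. = FALSE)
    midx <- mask_index(grid)
    cc <- cell_coords(grid, midx)
    map <- data.frame(x_mm = cc[, 1], y_mm = cc[, 2], value = map$values)
  }
  fixed <- if (axis == "horizontal") map$y_mm else map$x_mm
  along <- if (axis == "horizontal") map$x_mm else map$y_mm
  lev <- sort(unique(fixed))
  line <- lev[which.min(abs(lev - offset_mm))]
  if (min(abs(lev - offset_mm)) > max(diff(range(along)), 1)) {
    stop("line lies outside the mapped region", call. = FALSE)
  }
  sel <- fixed == line
  if (!any(sel)) stop("line lies outside the mapped region", call. = FALSE)
  ord <- order(along[sel])
  out <- data.frame(pos_mm = along[sel][ord], value = map$value[sel][ord])
  if (normalize) {
    pk <- max(out$value)
    out$value_norm <- if (pk > 0) out$value / pk else out$value
  }
  if (!is.null(radius_mm)) out$pos_norm <- out$pos_mm / radius_mm
  out
}
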