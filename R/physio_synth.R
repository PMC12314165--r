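#' Stimulation protocol
#'
#' Timing and drive parameters of one stimulation session. Defaults mirror
#' the in-vivo protocol: 20-s stimulation epochs repeated five times with
#' 30-s rests, a 5-s pre-stimulus baseline window, and the first 10 s of
#' stimulation as the analysis window.
#'
#' @param carrier_Hz carrier frequency, Hz.
#' @param beat_Hz beat (envelope) frequency, Hz; >= 0, 0 means unmodulated
#'   high-frequency drive (the control condition).
#' @param intensity_mA stimulation current, mA.
#' @param stim_duration_s,rest_duration_s epoch durations, s.
#' @param n_trials number of stimulation epochs.
#' @param baseline_window_s pre-stimulus baseline length, s.
#' @param analysis_window_s analysed span at stimulation onset, s.
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(carrier_Hz = 2000, beat_Hz = 1, intensity_mA = 1,
                          stim_duration_s = 20, rest_duration_s = 30,
                          n_trials = 5, baseline_window_s = 5,
                          analysis_window_s = 10) {
  if (any(c(stim_duration_s, rest_duration_s, baseline_window_s,
            analysis_window_s) <= 0) || n_trials < 1) {
    stop("durations must be > 0 and n_trials >= 1", call. = FALSE)
  }
  if (beat_Hz < 0) stop("beat_Hz must be >= 0", call. = FALSE)
  if (intensity_mA < 0) stop("intensity must be >= 0", call. = FALSE)
  if (rest_duration_s < baseline_window_s) {
    stop("rest must be at least as long as the baseline window",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "stim_protocol")
}

#' Synthetic-generator parameters
#'
#' Effect sizes, kinetics and noise levels of the synthetic physiology
#' generator. The calcium response switches on near `ca_threshold_mA`
#' (0.8 mA) while the eye-movement response switches on at the lower
#' `eye_threshold_mA` (0.4 mA), reproducing the observed threshold
#' dissociation between the two readouts. The sigmoid width and the slow
#' physiological fluctuation are sized so that at 15 trials the windowed
#' signed-rank comparison is decisively significant at threshold (about
#' six trial-level standard deviations) and far sub-significant one
#' intensity step below (about 0.1 sd).
#'
#' @param ca_threshold_mA calcium response threshold, mA.
#' @param eye_threshold_mA eye-movement response threshold, mA.
#' @param threshold_width_mA logistic width of both thresholds, mA.
#' @param response_gain peak firing-rate increase, a.u. (full activation).
#' @param baseline_rate resting rate, a.u.
#' @param entrainment_depth modulation depth of the beat-locked
#'   oscillation, in [0, 1].
#' @param gcamp_tau_s calcium-indicator decay time constant, s.
#' @param noise_sd white measurement noise on fluorescence, a.u.
#' @param slow_sd slow physiological fluctuation sd on fluorescence, a.u.
#' @param slow_tau_s Gaussian smoothing timescale of the slow
#'   fluctuation, s.
#' @param bleach_amp,bleach_tau_s photobleaching drift: amplitude (a.u.)
#'   and decay constant (s) of the shared exponential artifact.
#' @param eye_gain_mm pupil displacement at full drive, mm.
#' @param eye_jitter_sd_mm white jitter of the pupil centre, mm.
#' @param eye_slow_sd_mm slow gaze wander sd, mm.
#' @param eyeball_radius_mm eyeball radius used downstream, mm (1.67 for
#'   the adult mouse).
#' @param photometry_fs_Hz photometry sampling rate, Hz.
#' @param camera_fs_Hz eye-camera frame rate, Hz.
#' @param seed RNG seed (mandatory; all generator noise flows from it).
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(ca_threshold_mA = 0.8, eye_threshold_mA = 0.4,
                         threshold_width_mA = 0.04, response_gain = 0.5,
                         baseline_rate = 1, entrainment_depth = 0.5,
                         gcamp_tau_s = 1.5, noise_sd = 0.02,
                         slow_sd = 0.04, slow_tau_s = 2,
                         bleach_amp = 0.2, bleach_tau_s = 600,
                         eye_gain_mm = 0.06, eye_jitter_sd_mm = 0.01,
                         eye_slow_sd_mm = 0.005, eyeball_radius_mm = 1.67,
                         photometry_fs_Hz = 100, camera_fs_Hz = 200,
                         seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (gcamp_tau_s <= 0) stop("gcamp_tau_s must be > 0", call. = FALSE)
  if (entrainment_depth < 0 || entrainment_depth > 1) {
    stop("entrainment_depth must lie in [0, 1]", call. = FALSE)
  }
  structure(as.list(environment()), class = "synth_params")
}

logistic <- function(z) 1 / (1 + exp(-z))

# per-sample stimulation-epoch bookkeeping for a protocol at rate fs
protocol_timeline <- function(protocol, fs) {
  trial_len <- protocol$rest_duration_s + protocol$stim_duration_s
  total_s <- protocol$n_trials * trial_len
  t <- seq(0, total_s - 1 / fs, by = 1 / fs)
  onsets <- protocol$rest_duration_s + (seq_len(protocol$n_trials) - 1) *
    trial_len
  stim_on <- rep(FALSE, length(t))
  phase_t <- rep(0, length(t))       # time since onset, for the beat phase
  for (on in onsets) {
    sel <- t >= on & t < on + protocol$stim_duration_s
    stim_on[sel] <- TRUE
    phase_t[sel] <- t[sel] - on
  }
  list(t = t, stim_on = stim_on, phase_t = phase_t,
       epoch_marks = data.frame(trial = seq_len(protocol$n_trials),
                                onset_s = onsets,
                                offset_s = onsets + protocol$stim_duration_s))
}

#' Latent collicular rate trace under stimulation
#'
#' Deterministic latent firing-rate trace: during stimulation the rate is
#' `baseline + gain * sigmoid((I - threshold) / width) *
#' (1 + depth * sin(2*pi*beat*t))`, baseline otherwise; a 0-Hz beat leaves
#' the drive unmodulated. The threshold is the calcium threshold; the eye
#' generator applies its own lower threshold to the same protocol.
#'
#' @param protocol a [stim_protocol()].
#' @param params a [synth_params()].
#' @return An object of class `rate_trace` with `t`, `rate`, `fs`,
#'   `epoch_marks`, and the generating `protocol`/`params`.
#' @export
simulate_sc_activity <- function(protocol, params) {
  stopifnot(inherits(protocol, "stim_protocol"),
            inherits(params, "synth_params"))
  fs <- params$photometry_fs_Hz
  tl <- protocol_timeline(protocol, fs)
  drive <- params$response_gain *
    logistic((protocol$intensity_mA - params$ca_threshold_mA) /
               params$threshold_width_mA)
  osc <- if (protocol$beat_Hz > 0) {
    1 + params$entrainment_depth * sin(2 * pi * protocol$beat_Hz * tl$phase_t)
  } else 1
  rate <- params$baseline_rate + ifelse(tl$stim_on, drive * osc, 0)
  structure(list(t = tl$t, rate = rate, fs = fs,
                 epoch_marks = tl$epoch_marks, protocol = protocol,
                 params = params),
            class = "rate_trace")
}

# first-order (exponential-kernel) low-pass with unit DC gain, started at
# steady state for the initial input (recordings begin in equilibrium)
exp_kernel_filter <- function(x, fs, tau_s) {
  a <- exp(-1 / (fs * tau_s))
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive",
                           init = x[1]))
}

# white noise smoothed to a slow fluctuation with the requested sd
slow_fluctuation <- function(n, fs, sd, tau_s) {
  if (sd <= 0) return(numeric(n))
  z <- gaussian_smooth(stats::rnorm(n), fs, tau_s)
  if (stats::sd(z) == 0) return(numeric(n))
  z / stats::sd(z) * sd
}

#' Synthetic two-channel photometry from a rate trace
#'
#' The 470-nm channel is the latent rate convolved with an exponential
#' calcium-indicator kernel plus a shared photobleaching drift, a slow
#' physiological fluctuation, and white measurement noise. The 405-nm
#' isosbestic channel carries the same drift (scaled) and independent
#' noise but no rate signal, so scaled subtraction can remove the
#' artifact without touching the signal.
#'
#' @param rate a `rate_trace` from [simulate_sc_activity()].
#' @param params a [synth_params()]; noise draws are seeded from
#'   `params$seed`.
#' @return An object of class `photometry_trace` with `signal_470`,
#'   `control_405`, `fs`, `t`, `epoch_marks`.
#' @export
simulate_photometry <- function(rate, params = rate$params) {
  stopifnot(inherits(rate, "rate_trace"))
  if (params$gcamp_tau_s <= 0) stop("gcamp_tau_s must be > 0", call. = FALSE)
  n <- length(rate$rate)
  fs <- rate$fs
  set.seed(params$seed)
  conv <- exp_kernel_filter(rate$rate, fs, params$gcamp_tau_s)
  drift <- params$bleach_amp * exp(-rate$t / params$bleach_tau_s)
  slow <- slow_fluctuation(n, fs, params$slow_sd, params$slow_tau_s)
  f470 <- 1 + conv + drift + slow + stats::rnorm(n, sd = params$noise_sd)
  f405 <- 1 + 0.6 * drift + stats::rnorm(n, sd = params$noise_sd)
  structure(list(signal_470 = f470, control_405 = f405, fs = fs,
                 t = rate$t, epoch_marks = rate$epoch_marks,
                 protocol = rate$protocol),
            class = "photometry_trace")
}

#' Synthetic pupil-position trace from a rate trace
#'
#' Pupil-centre displacement at the camera frame rate: the stimulation-
#' locked component is `eye_gain_mm` times a drive with the eye's own
#' (lower) intensity threshold, modulated at the beat frequency, low-pass
#' smoothed, and placed on the horizontal axis; both axes carry slow gaze
#' wander and white jitter. The trace is zero-mean over the pre-stimulus
#' baseline windows.
#'
#' @param rate a `rate_trace` (supplies the protocol and timeline).
#' @param params a [synth_params()].
#' @return An object of class `eye_trace` with `pupil_xy` (n x 2 matrix,
#'   mm), `fs`, `t`, `epoch_marks`.
#' @export
simulate_eye_trace <- function(rate, params = rate$params) {
  stopifnot(inherits(rate, "rate_trace"))
  protocol <- rate$protocol
  fs <- params$camera_fs_Hz
  tl <- protocol_timeline(protocol, fs)
  n <- length(tl$t)
  drive_level <- logistic((protocol$intensity_mA - params$eye_threshold_mA) /
                            params$threshold_width_mA)
  osc <- if (protocol$beat_Hz > 0) {
    1 + params$entrainment_depth * sin(2 * pi * protocol$beat_Hz * tl$phase_t)
  } else 1
  sig <- params$eye_gain_mm * drive_level * ifelse(tl$stim_on, osc, 0)
  sig <- gaussian_smooth(sig, fs, 0.02)   # ocular plant low-pass, 20 ms
  set.seed(params$seed + 1L)
  x <- sig +
    slow_fluctuation(n, fs, params$eye_slow_sd_mm, params$slow_tau_s) +
    stats::rnorm(n, sd = params$eye_jitter_sd_mm)
  y <- slow_fluctuation(n, fs, params$eye_slow_sd_mm, params$slow_tau_s) +
    stats::rnorm(n, sd = params$eye_jitter_sd_mm)
  # reference both axes to the pre-stimulus baseline windows
  base_sel <- rep(FALSE, n)
  for (k in seq_len(nrow(tl$epoch_marks))) {
    on <- tl$epoch_marks$onset_s[k]
    base_sel <- base_sel |
      (tl$t >= on - protocol$baseline_window_s & tl$t < on)
  }
  x <- x - mean(x[base_sel])
  y <- y - mean(y[base_sel])
  structure(list(pupil_xy = cbind(x = x, y = y), fs = fs, t = tl$t,
                 epoch_marks = tl$epoch_marks, protocol = protocol),
            class = "eye_trace")
}
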