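#' Write a 2-D scalar map as CSV
#'
#' Columns `x_mm`, `y_mm`, `value`, one row per masked cell; full double
#' precision.
#'
#' @param map a `scalar_map` on a 2-D grid, or a data frame already in
#'   `x_mm`/`y_mm`/`value` form.
#' @param path output file.
#' @param grid the `tissue_grid` (required for `scalar_map` input).
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path, grid = NULL) {
  if (inherits(map, "scalar_map")) {
    if (is.null(grid)) stop("scalar_map input needs its grid", call. = FALSE)
    cc <- cell_coords(grid, mask_index(grid))
    map <- data.frame(x_mm = cc[, 1], y_mm = cc[, 2], value = map$values)
  }
  stopifnot(all(c("x_mm", "y_mm", "value") %in% names(map)))
  utils::write.csv(format(map, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 2-D scalar map CSV
#'
#' Validates the header and refuses partial or non-numeric content rather
#' than silently truncating.
#'
#' @param path CSV written by [write_map_csv()].
#' @return Data frame with `x_mm`, `y_mm`, `value`.
#' @export
read_map_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("integrity error reading '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE),
                 warning = function(w) stop("integrity error reading '",
                                            path, "': ",
                                            conditionMessage(w),
                                            call. = FALSE))
  need <- c("x_mm", "y_mm", "value")
  if (!all(need %in% names(df))) {
    stop("integrity error: missing columns in '", path, "'", call. = FALSE)
  }
  df <- df[need]
  if (!all(vapply(df, is.numeric, logical(1))) || anyNA(df)) {
    stop("integrity error: non-numeric or missing values in '", path, "'",
         call. = FALSE)
  }
  df
}

#' Write a 3-D scalar map as a NIfTI-1 volume
#'
#' Values are embedded at their voxel positions (zero outside the mask)
#' with the grid spacing in the header, stored as float64.
#'
#' @param map a `scalar_map` on a 3-D grid.
#' @param path output `.nii` file.
#' @param grid the `tissue_grid`.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path, grid) {
  stopifnot(inherits(map, "scalar_map"), length(grid$dims) == 3L)
  vol <- array(0, grid$dims)
  vol[mask_index(grid)] <- map$values
  img <- RNifti::asNifti(
    vol, reference = list(pixdim = c(-1, rep(grid$spacing, 3), 0, 0, 0, 0)),
    datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 map and check its spacing
#'
#' @param path `.nii` file.
#' @param expect_spacing_mm if given, raise an integrity error when the
#'   header spacing differs.
#' @return Numeric array with attribute `spacing_mm`.
#' @export
read_map_nifti <- function(path, expect_spacing_mm = NULL) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  if (!is.null(expect_spacing_mm) &&
      any(abs(sp - expect_spacing_mm) > 1e-6)) {
    stop("integrity error: spacing mismatch on read-back (",
         paste(signif(sp, 6), collapse = "x"), " vs expected ",
         expect_spacing_mm, " mm)", call. = FALSE)
  }
  out <- array(as.numeric(img), dim(img))
  attr(out, "spacing_mm") <- sp
  out
}

# ---- configuration ---------------------------------------------------------

config_error <- function(field, msg) {
  stop("config error at '", field, "': ", msg, call. = FALSE)
}

#' Read and validate a pipeline configuration
#'
#' One structured YAML file per run; see `default_disk_config()` for the
#' shape. Validation errors name the offending field path.
#'
#' @param path YAML file.
#' @return Validated config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg a config list (already parsed).
#' @export
validate_config <- function(cfg) {
  if (is.null(cfg$seed)) config_error("seed", "required")
  if (!is.null(cfg$disk)) {
    d <- cfg$disk
    if (is.null(d$radius_mm) || d$radius_mm <= 0) {
      config_error("disk.radius_mm", "must be > 0")
    }
    if (is.null(d$step_mm) || d$step_mm <= 0 || d$step_mm >= d$radius_mm) {
      config_error("disk.step_mm", "must be in (0, radius_mm)")
    }
    if (is.null(d$conductivity_S_per_m) || d$conductivity_S_per_m <= 0) {
      config_error("disk.conductivity_S_per_m", "must be > 0")
    }
    for (k in seq_along(d$electrodes)) {
      e <- d$electrodes[[k]]
      if (is.null(e$id) || is.null(e$angle_deg) || is.null(e$arc_mm)) {
        config_error(paste0("disk.electrodes[", k, "]"),
                     "needs id, angle_deg, arc_mm")
      }
    }
    for (k in seq_along(d$pairs)) {
      p <- d$pairs[[k]]
      if (is.null(p$electrodes) || length(p$electrodes) != 2) {
        config_error(paste0("disk.pairs[", k, "].electrodes"),
                     "needs exactly two electrode ids")
      }
      if (is.null(p$current_mA) || p$current_mA <= 0) {
        config_error(paste0("disk.pairs[", k, "].current_mA"), "must be > 0")
      }
      if (is.null(p$frequency_Hz) || p$frequency_Hz <= 0) {
        config_error(paste0("disk.pairs[", k, "].frequency_Hz"),
                     "must be > 0")
      }
    }
  }
  if (!is.null(cfg$solver) && !is.null(cfg$solver$tol) &&
      cfg$solver$tol <= 0) {
    config_error("solver.tol", "must be > 0")
  }
  cfg
}

#' Built-in demonstration configuration
#'
#' A small disk phantom with two electrode pairs at 2000/2001 Hz, suitable
#' for an end-to-end pipeline run in seconds.
#'
#' @param seed RNG seed recorded in the config.
#' @return Config list (serialize with `yaml::write_yaml()`).
#' @export
default_disk_config <- function(seed = 1) {
  list(
    seed = seed,
    disk = list(
      radius_mm = 25, step_mm = 1, thickness_mm = 10,
      conductivity_S_per_m = 1.0,
      electrodes = list(
        list(id = "A1", angle_deg = 120, arc_mm = 6),
        list(id = "A2", angle_deg = 240, arc_mm = 6),
        list(id = "B1", angle_deg = 60, arc_mm = 6),
        list(id = "B2", angle_deg = 300, arc_mm = 6)),
      pairs = list(
        list(electrodes = c("A1", "A2"), current_mA = 1,
             frequency_Hz = 2000),
        list(electrodes = c("B1", "B2"), current_mA = 1,
             frequency_Hz = 2001))),
    solver = list(tol = 1e-8),
    scan = list(step_mm = 5, replicates = 3, noise_sd = 0, fs_Hz = 20000),
    physio = list(
      protocol = list(beat_Hz = 1, intensity_mA = 1, n_trials = 5),
      smoothing_sd_s = 0.1)
  )
}

# ---- pipeline --------------------------------------------------------------

known_stages <- c("solve-disk", "envelope", "scan", "simulate-physio",
                  "analyze-physio")

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order (solve-disk ->
#' envelope -> scan; simulate-physio -> analyze-physio), writes every
#' stage's artifacts as CSV under `out_dir`, and always emits exactly one
#' `manifest.json` recording the config snapshot, seed, package version,
#' stage list and output-file hashes. Reruns with an identical config
#' produce bit-identical outputs for the deterministic stages.
#'
#' @param config a config list (see [read_config()]) or a path to a YAML
#'   config file.
#' @param stages character vector of stages (subset of `solve-disk`,
#'   `envelope`, `scan`, `simulate-physio`, `analyze-physio`); empty runs
#'   nothing but still writes a manifest.
#' @param out_dir output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, stages = character(), out_dir) {
  cfg <- if (is.character(config)) read_config(config) else
    validate_config(config)
  bad <- setdiff(stages, known_stages)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known_stages, collapse = ", "), ")",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  log <- list()
  tol <- cfg$solver$tol %||% 1e-8
  state <- list()

  if ("solve-disk" %in% stages || "envelope" %in% stages ||
      "scan" %in% stages) {
    d <- cfg$disk
    grid <- build_disk_phantom(d$radius_mm, d$step_mm, d$electrodes,
                               d$conductivity_S_per_m,
                               thickness_mm = d$thickness_mm %||% 10)
    sys <- assemble_system(grid)
    fields <- lapply(d$pairs, function(p) {
      pat <- current_pattern(stats::setNames(c(1, -1) * p$current_mA,
                                             p$electrodes),
                             frequency_Hz = p$frequency_Hz)
      sol <- solve_potential(grid, pat, tol = tol, system = sys)
      log[[length(log) + 1]] <<- list(stage = "solve-disk",
                                      pair = paste(p$electrodes,
                                                   collapse = "-"),
                                      residual = sol$residual,
                                      iterations = sol$iterations)
      electric_field(sol, grid)
    })
    state$grid <- grid
    state$fields <- fields
    if ("solve-disk" %in% stages) {
      for (k in seq_along(fields)) {
        fmap <- new_scalar_map(field_magnitude(fields[[k]]), grid$dims,
                               grid$spacing, kind = "field_magnitude")
        f <- file.path(out_dir, sprintf("field_pair%d.csv", k))
        write_map_csv(fmap, f, grid)
        outputs <- c(outputs, f)
      }
    }
  }

  if ("envelope" %in% stages) {
    env <- envelope_amplitude(state$fields[[1]], state$fields[[2]])
    f <- file.path(out_dir, "envelope.csv")
    write_map_csv(env, f, state$grid)
    outputs <- c(outputs, f)
    for (ax in c("horizontal", "vertical")) {
      prof <- line_cut(env, axis = ax, grid = state$grid,
                       radius_mm = cfg$disk$radius_mm)
      f <- file.path(out_dir, paste0("profile_", ax, ".csv"))
      utils::write.csv(prof, f, row.names = FALSE)
      outputs <- c(outputs, f)
    }
    foc <- focality(env, state$grid, target_mm = c(0, 0))
    f <- file.path(out_dir, "focality.csv")
    utils::write.csv(data.frame(peak_x_mm = foc$peak_mm[1],
                                peak_y_mm = foc$peak_mm[2],
                                peak_value = foc$peak_value,
                                focal_fraction = foc$focal_fraction,
                                depth_of_peak_mm = foc$depth_of_peak_mm),
                     f, row.names = FALSE)
    outputs <- c(outputs, f)
    state$envelope <- env
  }

  if ("scan" %in% stages) {
    sc <- cfg$scan %||% list()
    scan <- grid_scan(state$grid, state$fields[[1]], state$fields[[2]],
                      step_mm = sc$step_mm %||% 5,
                      replicates = sc$replicates %||% 3,
                      noise_sd = sc$noise_sd %||% 0,
                      seed = cfg$seed,
                      f1 = cfg$disk$pairs[[1]]$frequency_Hz,
                      f2 = cfg$disk$pairs[[2]]$frequency_Hz,
                      fs = sc$fs_Hz %||% 50000)
    f <- file.path(out_dir, "scan.csv")
    utils::write.csv(as.data.frame(scan), f, row.names = FALSE)
    outputs <- c(outputs, f)
    dense <- interpolate_map(scan, target_step_mm = cfg$disk$step_mm)
    f <- file.path(out_dir, "scan_dense.csv")
    utils::write.csv(dense, f, row.names = FALSE)
    outputs <- c(outputs, f)
  }

  if ("simulate-physio" %in% stages || "analyze-physio" %in% stages) {
    ph <- cfg$physio %||% list()
    prot <- do.call(stim_protocol, ph$protocol %||% list())
    par_args <- ph$params %||% list()
    par_args$seed <- par_args$seed %||% cfg$seed
    pars <- do.call(synth_params, par_args)
    rate <- simulate_sc_activity(prot, pars)
    photo <- simulate_photometry(rate, pars)
    eye <- simulate_eye_trace(rate, pars)
    state$photo <- photo; state$eye <- eye; state$prot <- prot
    if ("simulate-physio" %in% stages) {
      f <- file.path(out_dir, "photometry.csv")
      utils::write.csv(data.frame(t_s = photo$t,
                                  signal_470 = photo$signal_470,
                                  control_405 = photo$control_405),
                       f, row.names = FALSE)
      outputs <- c(outputs, f)
      f <- file.path(out_dir, "eye.csv")
      utils::write.csv(data.frame(t_s = eye$t, x_mm = eye$pupil_xy[, 1],
                                  y_mm = eye$pupil_xy[, 2]),
                       f, row.names = FALSE)
      outputs <- c(outputs, f)
      f <- file.path(out_dir, "epochs.csv")
      utils::write.csv(photo$epoch_marks, f, row.names = FALSE)
      outputs <- c(outputs, f)
    }
  }

  if ("analyze-physio" %in% stages) {
    ph <- cfg$physio %||% list()
    dff <- photometry_dff(state$photo,
                          smoothing_sd_s = ph$smoothing_sd_s %||% 0.1)
    wc <- window_compare(dff, state$photo$fs,
                         state$photo$epoch_marks$onset_s)
    amp <- eye_amplitude(state$eye)
    wce <- window_compare(as.numeric(amp), attr(amp, "fs"),
                          state$eye$epoch_marks$onset_s)
    f <- file.path(out_dir, "window_stats.csv")
    utils::write.csv(data.frame(
      readout = c("dff", "eye_amplitude"),
      statistic = c(wc$statistic, wce$statistic),
      p_value = c(wc$p_value, wce$p_value),
      direction = c(wc$direction, wce$direction),
      stars = c(wc$stars, wce$stars)), f, row.names = FALSE)
    outputs <- c(outputs, f)
    spec <- entrainment_spectrum(
      stim_segments(dff, state$photo$fs, state$photo$epoch_marks),
      state$photo$fs)
    f <- file.path(out_dir, "spectrum.csv")
    utils::write.csv(data.frame(band_center_Hz = spec$band_centers_Hz,
                                band_power = spec$band_power,
                                normalized_power = spec$normalized_power),
                     f, row.names = FALSE)
    outputs <- c(outputs, f)
  }

  manifest <- list(
    package = "beatfield",
    version = as.character(utils::packageVersion("beatfield")),
    created = format(Sys.time(), tz = "UTC"),
    seed = cfg$seed,
    stages = as.list(stages),
    config = cfg,
    solver_log = log,
    outputs = lapply(outputs, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
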