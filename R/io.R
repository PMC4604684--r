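#' Write a pressure trace (and optional ECG) to CSV
#'
#' Columns `time_s,pressure_mmHg[,ecg_mv]`, full double precision, so a
#' write/read round trip reproduces the samples.
#'
#' @param trace a `pressure_trace`.
#' @param path output file.
#' @param ecg optional `ecg_trace` sampled at the same rate.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, ecg = NULL) {
  stopifnot(inherits(trace, "pressure_trace"))
  t <- (seq_along(trace$pressure) - 1) / trace$fs
  df <- data.frame(time_s = t, pressure_mmHg = trace$pressure)
  if (!is.null(ecg)) {
    if (length(ecg$ecg) != length(trace$pressure) || ecg$fs != trace$fs)
      stop_param("ecg and trace must share length and sampling rate")
    df$ecg_mv <- ecg$ecg
  }
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pressure trace CSV
#'
#' Expects the header `time_s,pressure_mmHg` with an optional `ecg_mv`
#' column. The time column must be uniformly sampled (relative tolerance
#' 1 ppm); the sampling rate is inferred from it and cross-checked against
#' `fs` when given.
#'
#' @param path CSV file.
#' @param fs optional expected sampling rate; a mismatch beyond 0.1% errors.
#' @return a `pressure_trace`; if an ECG column is present it is attached as
#'   `attr(, "ecg")` (an `ecg_trace`).
#' @export
read_trace <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  need <- c("time_s", "pressure_mmHg")
  if (!all(need %in% names(df)))
    stop_param("expected columns %s, found %s",
               paste(need, collapse = ","), paste(names(df), collapse = ","))
  t <- df$time_s
  if (length(t) < 2) stop_param("trace needs at least 2 samples")
  dt <- diff(t)
  dt_bar <- stats::median(dt)
  if (dt_bar <= 0) stop_param("time column is not increasing")
  bad <- which(abs(dt - dt_bar) / dt_bar > 1e-6)
  if (length(bad))
    stop_param("non-uniform sampling at row %d (dt = %g, expected %g)",
               bad[1] + 1, dt[bad[1]], dt_bar)
  fs_inferred <- 1 / dt_bar
  if (!is.null(fs) && abs(fs_inferred - fs) / fs > 1e-3)
    stop_param("sampling rate %.6g Hz does not match expected %g Hz",
               fs_inferred, fs)
  trace <- structure(list(pressure = df$pressure_mmHg, fs = fs_inferred),
                     class = "pressure_trace")
  if ("ecg_mv" %in% names(df))
    attr(trace, "ecg") <- structure(
      list(ecg = df$ecg_mv, fs = fs_inferred,
           r_peaks = detect_r_peaks(structure(list(ecg = df$ecg_mv,
                                                   fs = fs_inferred),
                                              class = "ecg_trace"))),
      class = "ecg_trace")
  trace
}

#' Read a dose-response table
#'
#' Expects columns `dose_ug_per_kg,response_mmHg` with optional `animal_id`
#' and `agent`.
#'
#' @param path CSV file.
#' @return data frame with columns `dose`, `response` and any of
#'   `animal_id`, `agent` present in the file.
#' @export
read_dose_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("dose_ug_per_kg", "response_mmHg")
  if (!all(need %in% names(df)))
    stop_param("expected columns %s", paste(need, collapse = ","))
  out <- data.frame(dose = df$dose_ug_per_kg, response = df$response_mmHg)
  for (extra in c("animal_id", "agent"))
    if (extra %in% names(df)) out[[extra]] <- df[[extra]]
  out
}

#' Write / read a ring image
#'
#' PNG files are written 8-bit, TIFF files 16-bit grayscale; intensities are
#' clamped to `[0, 1]`.
#'
#' @param image numeric matrix.
#' @param path output path ending in `.png` or `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_ring_image <- function(image, path) {
  img <- image
  img[img < 0] <- 0
  img[img > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 16)
  } else {
    stop_param("unsupported image extension '%s'", ext)
  }
  invisible(path)
}

#' @rdname write_ring_image
#' @export
read_ring_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stop_param("unsupported image extension '%s'", ext)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Pipeline run configuration
#'
#' Bundles the constants of a full run. The defaults encode the analysis
#' conventions: 2,000 samples/s, decay window offsets 30 ms / 20 ms, 20%
#' per-tail trimming, 8 morphometry lines at 22.5 degrees, median +/- 3 MAD
#' gating.
#'
#' @param fs sampling rate (Hz).
#' @param beat a [beat_config()].
#' @param n_lines morphometry line count.
#' @param trim per-tail trim proportion.
#' @param seed integer seed for simulation stages.
#' @param simulate optional list passed to the simulation stage:
#'   `n_beats`, `noise_sd`, and any [beat_shape_params()] overrides.
#' @return list of class `run_config`.
#' @export
run_config <- function(fs = 2000, beat = beat_config(), n_lines = 8,
                       trim = 0.20, seed = 1,
                       simulate = list(n_beats = 20, noise_sd = 0.5)) {
  if (fs <= 0) stop_param("fs must be positive")
  if (n_lines < 1) stop_param("n_lines must be >= 1")
  beat$trim <- trim
  structure(list(fs = fs, beat = beat, n_lines = n_lines, trim = trim,
                 seed = seed, simulate = simulate), class = "run_config")
}

#' Read a YAML run configuration
#'
#' Top-level keys override [run_config()] defaults; keys under `beat:`
#' override [beat_config()] fields and keys under `simulate:` the simulation
#' stage.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  beat_args <- y$beat %||% list()
  cfg <- run_config(
    fs = y$fs %||% 2000,
    beat = do.call(beat_config, beat_args),
    n_lines = y$n_lines %||% 8,
    trim = y$trim %||% 0.20,
    seed = y$seed %||% 1,
    simulate = y$simulate %||% list(n_beats = 20, noise_sd = 0.5))
  cfg
}

#' Run the simulate-and-analyse pipeline
#'
#' Generates a synthetic trace under the configuration, runs the full beat
#' pipeline on it, and returns (optionally writes) a versioned result
#' bundle. Identical configuration and seed give identical output.
#'
#' @param config a [run_config()].
#' @param trace optional existing `pressure_trace`; skips simulation.
#' @param out optional path for the JSON result bundle.
#' @return list with `schema_version`, `params`, `summary` and `beats`.
#' @export
run_pipeline <- function(config = run_config(), trace = NULL, out = NULL) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (is.null(trace)) {
    sim_args <- config$simulate
    shape_args <- sim_args[setdiff(names(sim_args),
                                   c("n_beats", "noise_sd", "artifact"))]
    shape_args$fs <- shape_args$fs %||% config$fs
    params <- do.call(beat_shape_params, shape_args)
    sim <- generate_trace(params, n_beats = sim_args$n_beats %||% 20,
                          noise_sd = sim_args$noise_sd %||% 0.5,
                          artifact = sim_args$artifact,
                          seed = config$seed)
    trace <- sim$trace
    truth <- sim$truth
  }
  res <- analyze_trace(trace, config = config$beat)
  bundle <- list(
    schema_version = 1L,
    params = list(fs = trace$fs, seed = config$seed,
                  sg_window = config$beat$sg_window,
                  sg_order = config$beat$sg_order,
                  gate_k = config$beat$gate_k, trim = config$trim,
                  decay_after_dn_s = config$beat$decay_after_dn_s,
                  decay_before_ed_s = config$beat$decay_before_ed_s),
    summary = if (is.null(res$summary)) NULL else
      c(lapply(res$summary$metrics, as.list),
        list(tau_s = res$summary$tau_s, hr_bpm = res$summary$hr_bpm,
             n_beats_used = res$summary$n_beats_used)),
    beats = res$beats
  )
  if (!is.null(out)) write_results_json(bundle, out)
  bundle
}

#' Write a result bundle as JSON
#'
#' @param x list to serialise.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}
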