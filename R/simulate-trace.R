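#' Generate a multi-beat synthetic arterial pressure trace
#'
#' Concatenates `n_beats` closed-form beats (see [beat_shape_params()]) into a
#' continuous pressure trace with optional additive Gaussian noise, per-beat
#' period jitter, and injected artifact beats, and returns the trace together
#' with analytic ground truth for every per-beat landmark. All randomness is
#' driven by `seed`; the same seed reproduces the trace bit for bit.
#'
#' @param params a [beat_shape_params()] object.
#' @param n_beats number of beats (>= 1).
#' @param noise_sd standard deviation of additive Gaussian noise (mmHg).
#' @param artifact optional artifact specification: a list with elements
#'   `beats` (indices of beats to perturb, or `n` to pick that many spread
#'   through the trace), `sbp_scale` (default 1.3) and `period_scale`
#'   (default 1). Artifact beats emulate respiratory-swing beats and are
#'   flagged in the ground truth.
#' @param period_jitter_sd per-beat standard deviation of the cycle length
#'   (s); periods are redrawn per beat and truncated at 60% of the nominal
#'   period.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return a list with elements `trace` (class `pressure_trace`: `pressure`,
#'   `fs`) and `truth` (class `trace_truth`: per-beat data frame `beats` with
#'   1-based sample indices `start`, `onset`, `an`, `peak`, `dn`,
#'   `end_diastole`, `decay_start`, `decay_end`, the corresponding pressures,
#'   `sbp`, `dbp`, `tau`, `period` and the logical `artifact` flag).
#' @export
generate_trace <- function(params, n_beats, noise_sd = 0, artifact = NULL,
                           period_jitter_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "beat_shape_params"))
  if (n_beats < 1) stop_param("n_beats must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  art_beats <- integer()
  sbp_scale <- 1.3
  period_scale <- 1
  if (!is.null(artifact)) {
    sbp_scale <- artifact$sbp_scale %||% 1.3
    period_scale <- artifact$period_scale %||% 1
    if (!is.null(artifact$beats)) {
      art_beats <- as.integer(artifact$beats)
    } else if (!is.null(artifact$n) && artifact$n > 0) {
      art_beats <- unique(round(seq(min(3, n_beats), max(1, n_beats - 1),
                                    length.out = artifact$n)))
    }
    if (any(art_beats < 1 | art_beats > n_beats))
      stop_param("artifact beat indices out of range")
  }

  periods <- rep(params$period, n_beats)
  if (period_jitter_sd > 0) {
    periods <- params$period + stats::rnorm(n_beats, 0, period_jitter_sd)
    periods <- pmax(periods, 0.6 * params$period)
  }
  periods[art_beats] <- periods[art_beats] * period_scale

  cache <- new.env(parent = emptyenv())
  beat_of <- function(period, is_art) {
    key <- sprintf("%.12g|%d", period, is_art)
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- params
    p$period <- period
    if (is_art) p$sbp <- p$sbp * sbp_scale
    g <- beat_geometry(p)
    o <- beat_oracle(p, g)
    tg <- (0:(g$n - 1)) / p$fs
    cache[[key]] <- list(p = p, g = g, o = o,
                         pressure = beat_pressure(tg, p, g))
    cache[[key]]
  }

  pieces <- vector("list", n_beats)
  rows <- vector("list", n_beats)
  offset <- 0L
  for (b in seq_len(n_beats)) {
    bt <- beat_of(periods[b], b %in% art_beats)
    pieces[[b]] <- bt$pressure
    o <- bt$o
    fs <- params$fs
    rows[[b]] <- data.frame(
      beat = b,
      start = offset + 1L,
      onset = offset + 1L + as.integer(round(o$foot_t * fs)),
      an = if (is.na(o$an_t)) NA_integer_ else
        offset + 1L + as.integer(round(o$an_t * fs)),
      an_time = o$an_t,
      an_pressure = o$an_pressure,
      peak = offset + bt$g$peak_index,
      dn = offset + 1L + as.integer(round(o$dn_t * fs)),
      dn_pressure = o$dn_pressure,
      end_diastole = offset + bt$g$n,
      decay_start = offset + 1L + as.integer(ceiling(o$decay_start_t * fs)),
      decay_end = offset + 1L + as.integer(floor(o$decay_end_t * fs)),
      sbp = bt$p$sbp,
      dbp = bt$p$dbp,
      tau = bt$p$tau,
      period = periods[b],
      artifact = b %in% art_beats
    )
    offset <- offset + bt$g$n
  }
  pressure <- unlist(pieces, use.names = FALSE)
  if (noise_sd > 0)
    pressure <- pressure + stats::rnorm(length(pressure), 0, noise_sd)

  trace <- structure(list(pressure = pressure, fs = params$fs),
                     class = "pressure_trace")
  truth <- structure(list(beats = do.call(rbind, rows), params = params,
                          fs = params$fs, noise_sd = noise_sd),
                     class = "trace_truth")
  list(trace = trace, truth = truth)
}

#' Synthetic ECG surrogate matched to a generated trace
#'
#' Places an impulse-like R wave a fixed offset before each beat's pressure
#' upstroke (default offset 0: the R spike falls on the beat boundary, so
#' consecutive R-R intervals equal the beat periods exactly).
#'
#' @param truth a `trace_truth` object from [generate_trace()].
#' @param fs sampling rate of the ECG (defaults to the trace rate).
#' @param r_offset_s offset of the R peak before the beat boundary (s);
#'   spikes that would fall before the first sample are clamped to it.
#' @param amplitude_mv R-spike amplitude (mV).
#' @return an `ecg_trace` object: `ecg` (mV), `fs`, `r_peaks` (sample
#'   indices).
#' @export
generate_ecg <- function(truth, fs = truth$fs, r_offset_s = 0,
                         amplitude_mv = 1) {
  stopifnot(inherits(truth, "trace_truth"))
  beats <- truth$beats
  if (!nrow(beats)) stop_param("ground truth contains no beats")
  n <- max(beats$end_diastole)
  n_ecg <- as.integer(round(n * fs / truth$fs))
  ecg <- numeric(n_ecg)
  t_start <- (beats$start - 1) / truth$fs
  r_idx <- pmax(1L, 1L + as.integer(round((t_start - r_offset_s) * fs)))
  half <- max(1L, as.integer(round(0.001 * fs)))
  for (r in r_idx) {
    k <- max(1, r - half):min(n_ecg, r + half)
    ecg[k] <- pmax(ecg[k], amplitude_mv * (1 - abs(k - r) / (half + 1)))
  }
  structure(list(ecg = ecg, fs = fs, r_peaks = r_idx), class = "ecg_trace")
}

#' Pure exponential diastolic decay fixture
#'
#' Builds a trace whose "beats" are bare exponential pressure decays
#' `p0 * exp(-t / tau)` with marked dicrotic-notch and end-diastolic samples,
#' for validating the semilog decay-slope estimator under controlled
#' conditions: inside any analysis window the log-pressure is exactly linear
#' with slope `-1 / tau`.
#'
#' @param tau decay time constant (s).
#' @param p0 pressure at the start of each decay (mmHg).
#' @param duration length of each decay segment (s).
#' @param n_beats number of repeated segments.
#' @param noise_sd additive Gaussian noise (mmHg).
#' @param fs sampling rate.
#' @param seed integer seed for the noise.
#' @return a list with `trace` (class `pressure_trace`) and `markers`
#'   (data frame with per-segment `dn` and `end_diastole` sample indices).
#' @export
exp_decay_trace <- function(tau, p0 = 110, duration = 0.12, n_beats = 1,
                            noise_sd = 0, fs = 2000, seed = NULL) {
  if (tau <= 0) stop_param("tau must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  t <- (0:(n - 1)) / fs
  seg <- p0 * exp(-t / tau)
  pressure <- rep(seg, n_beats)
  if (noise_sd > 0)
    pressure <- pressure + stats::rnorm(length(pressure), 0, noise_sd)
  markers <- data.frame(
    beat = seq_len(n_beats),
    dn = (seq_len(n_beats) - 1L) * n + 1L,
    end_diastole = seq_len(n_beats) * n
  )
  list(trace = structure(list(pressure = pressure, fs = fs),
                         class = "pressure_trace"),
       markers = markers)
}

#' Simulate a two-group cohort of pressure traces
#'
#' Draws per-animal beat-shape parameters around group-level means and
#' generates one multi-beat trace per animal, emulating a contrast between a
#' control and a stiffened/hypertensive group (higher reflected-wave
#' amplitude, hence augmentation index, and longer diastolic decay constant).
#' Between-animal variability is log-normal with the given coefficients of
#' variation.
#'
#' @param n_per_group animals per group.
#' @param n_beats beats per animal trace.
#' @param control,case named lists overriding [beat_shape_params()] defaults
#'   for each group (defaults encode the control vs stiffened contrast).
#' @param cv between-animal coefficient of variation applied to
#'   `reflected_amplitude` and `tau` (and, at half strength, `sbp`/`dbp`).
#' @param noise_sd within-trace Gaussian noise (mmHg).
#' @param seed integer seed.
#' @return a data frame of per-animal true parameters with a list-column-free
#'   layout, plus the generated traces in `attr(,"traces")` (list of
#'   `generate_trace()` results, in row order).
#' @export
generate_cohort <- function(n_per_group = 10, n_beats = 20,
                            control = list(reflected_amplitude = 40,
                                           tau = 0.22),
                            case = list(reflected_amplitude = 56,
                                        tau = 0.30),
                            cv = 0.10, noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  draw_animal <- function(group, overrides, id) {
    base <- beat_shape_params()
    for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
    ra <- base$reflected_amplitude * exp(stats::rnorm(1, 0, cv))
    tau <- base$tau * exp(stats::rnorm(1, 0, cv))
    sc <- exp(stats::rnorm(1, 0, cv / 2))
    p <- beat_shape_params(
      sbp = base$sbp * sc,
      dbp = base$dbp * sc,
      period = base$period, reflected_amplitude = ra,
      reflected_delay = base$reflected_delay,
      dn_time_frac = base$dn_time_frac, dn_depth = base$dn_depth,
      dn_width = base$dn_width, tau = tau, fs = base$fs)
    sim <- generate_trace(p, n_beats, noise_sd = noise_sd,
                          seed = sample.int(.Machine$integer.max, 1))
    true_aix <- with(sim$truth$beats[1, ],
                     (sbp - an_pressure) / (sbp - dbp))
    list(row = data.frame(group = group, animal = id, true_ra = ra,
                          true_tau = tau, true_sbp = p$sbp, true_dbp = p$dbp,
                          true_aix = true_aix),
         sim = sim)
  }
  out <- list()
  traces <- list()
  i <- 0
  for (grp in c("control", "case")) {
    ov <- if (grp == "control") control else case
    for (a in seq_len(n_per_group)) {
      i <- i + 1
      res <- draw_animal(grp, ov, a)
      out[[i]] <- res$row
      traces[[i]] <- res$sim
    }
  }
  df <- do.call(rbind, out)
  attr(df, "traces") <- traces
  df
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("<pressure_trace> %d samples at %g Hz (%.2f s), %.1f-%.1f mmHg\n",
              length(x$pressure), x$fs, length(x$pressure) / x$fs,
              min(x$pressure), max(x$pressure)))
  invisible(x)
}

#' @export
plot.pressure_trace <- function(x, ...) {
  t <- (seq_along(x$pressure) - 1) / x$fs
  graphics::plot(t, x$pressure, type = "l", xlab = "time (s)",
                 ylab = "pressure (mmHg)", ...)
  invisible(x)
}
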