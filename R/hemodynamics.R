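#' Derived pressure metrics of one beat
#'
#' Pulse pressure `pp = sbp - dbp`; mean arterial pressure
#' `map = sbp / 3 + 2 dbp / 3`; augmentation pressure `ap = sbp -
#' an_pressure` and augmentation index `aix = ap / pp`, computed only when
#' the anacrotic notch is present. A zero pulse pressure leaves `aix`
#' undefined and sets a flag.
#'
#' @param sbp,dbp systolic and end-diastolic pressure (mmHg).
#' @param an_pressure anacrotic-notch pressure (mmHg) or `NA`.
#' @return list with `pp`, `map`, `ap`, `aix`, `aix_undefined`.
#' @export
compute_beat_metrics <- function(sbp, dbp, an_pressure = NA_real_) {
  pp <- sbp - dbp
  map <- sbp / 3 + 2 * dbp / 3
  ap <- if (is.na(an_pressure)) NA_real_ else sbp - an_pressure
  aix_undef <- pp == 0
  aix <- if (is.na(ap) || aix_undef) NA_real_ else ap / pp
  list(pp = pp, map = map, ap = ap, aix = aix, aix_undefined = aix_undef)
}

#' Semilog slope of the diastolic pressure decay
#'
#' Ordinary least-squares slope of `log(pressure)` against time over the
#' window from `decay_after_dn_s` after the dicrotic notch to
#' `decay_before_ed_s` before end-diastole (avoiding the perturbations around
#' aortic valve closure and the next upstroke). For an exponential decay with
#' time constant tau the slope is exactly `-1 / tau`. Returns `NA` when the
#' window holds fewer than 3 samples or contains non-positive pressures.
#' `semilog = FALSE` fits the raw pressure instead (slope in mmHg/s).
#'
#' @param trace a `pressure_trace`.
#' @param dn,end_diastole sample indices of the dicrotic notch and
#'   end-diastole.
#' @param config a [beat_config()].
#' @param semilog fit `log(pressure)` (default) or raw pressure.
#' @return slope in s^-1 (semilog) or mmHg/s, or `NA_real_`.
#' @export
diastolic_decay_slope <- function(trace, dn, end_diastole,
                                  config = beat_config(), semilog = TRUE) {
  if (is.na(dn) || is.na(end_diastole)) return(NA_real_)
  fs <- trace$fs
  lo <- dn + as.integer(round(config$decay_after_dn_s * fs))
  hi <- end_diastole - as.integer(round(config$decay_before_ed_s * fs))
  if (hi - lo + 1 < 3) return(NA_real_)
  p <- trace$pressure[lo:hi]
  if (any(p <= 0)) return(NA_real_)
  t <- (lo:hi) / fs
  if (semilog) ls_slope(t, log(p)) else ls_slope(t, p)
}

#' Diastolic decay time constant from per-beat slopes
#'
#' tau is the reciprocal of the magnitude of the trimmed mean of the per-beat
#' decay slopes (20% per tail by default). Missing slopes are dropped first.
#'
#' @param slopes per-beat semilog decay slopes (s^-1).
#' @param trim per-tail trim proportion.
#' @return tau in seconds.
#' @export
compute_tau <- function(slopes, trim = 0.20) {
  slopes <- slopes[is.finite(slopes)]
  if (!length(slopes)) stop_param("no finite decay slopes")
  m <- trimmed_mean(slopes, trim)
  if (m == 0) stop_param("trimmed mean slope is zero: tau undefined")
  1 / abs(m)
}

#' Aggregate per-beat metrics into a trace summary
#'
#' Means and trimmed means of the per-beat metrics over non-gated beats, plus
#' the decay time constant and heart rate. Beats lacking the dicrotic or
#' anacrotic notch still contribute to the pressure aggregates but not to
#' `ap`/`aix`/tau.
#'
#' @param beats per-beat data frame from [analyze_trace()] (columns `sbp`,
#'   `dbp`, `pp`, `map`, `ap`, `aix`, `dn_pressure`, `decay_slope`, `onset`,
#'   `gated`).
#' @param fs sampling rate.
#' @param trim per-tail trim proportion.
#' @return list of class `trace_summary`.
#' @export
summarize_trace <- function(beats, fs, trim = 0.20) {
  use <- !beats$gated
  if (!any(use)) stop_param("all beats gated: nothing to summarise")
  b <- beats[use, ]
  agg <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(c(mean = NA_real_, trimmed_mean = NA_real_))
    c(mean = mean(v), trimmed_mean = trimmed_mean(v, trim))
  }
  metrics <- c("sbp", "dbp", "pp", "map", "ap", "aix", "dn_pressure")
  out <- lapply(metrics, function(m) agg(b[[m]]))
  names(out) <- metrics
  slopes <- b$decay_slope[is.finite(b$decay_slope)]
  tau <- if (length(slopes)) compute_tau(slopes, trim) else NA_real_
  hr <- if (sum(use) >= 2)
    compute_heart_rate(beats$onset, fs, gated = beats$gated) else NA_real_
  structure(list(metrics = out, tau_s = tau, hr_bpm = hr,
                 n_beats_used = sum(use), n_beats_total = nrow(beats)),
            class = "trace_summary")
}

#' @export
print.trace_summary <- function(x, ...) {
  cat(sprintf("<trace_summary> %d/%d beats used, HR %.1f bpm, tau %.4f s\n",
              x$n_beats_used, x$n_beats_total, x$hr_bpm, x$tau_s))
  m <- do.call(rbind, x$metrics)
  print(round(m, 4))
  invisible(x)
}

#' Full per-trace waveform analysis
#'
#' Runs the complete beat pipeline on one trace: segmentation (pressure feet
#' or ECG R peaks), per-beat fiducial detection (systolic peak, end-diastole,
#' dicrotic notch, anacrotic notch), artifact gating, per-beat metric
#' computation and trace-level aggregation.
#'
#' @param trace a `pressure_trace`.
#' @param ecg optional `ecg_trace`.
#' @param config a [beat_config()].
#' @return list with `beats` (per-beat data frame) and `summary`
#'   (a `trace_summary`), or `NULL` beats when segmentation found none.
#' @export
analyze_trace <- function(trace, ecg = NULL, config = beat_config()) {
  stopifnot(inherits(trace, "pressure_trace"))
  segs <- segment_beats(trace, ecg = ecg, config = config)
  if (!nrow(segs)) return(list(beats = segs, summary = NULL))
  x <- trace$pressure
  xs <- sg_smooth(x, config)
  d2 <- sg_deriv(xs, trace$fs, config, 2)
  d4 <- an_fourth_derivative(x, trace$fs, config)

  nb <- nrow(segs)
  col <- function(proto) rep(proto, nb)
  beats <- data.frame(
    beat = seq_len(nb), onset = segs$onset, end = segs$end,
    cycle_len = segs$end - segs$onset,
    peak = col(NA_integer_), sbp = col(NA_real_),
    end_diastole = col(NA_integer_), dbp = col(NA_real_),
    dn = col(NA_integer_), dn_pressure = col(NA_real_),
    dn_missing = col(FALSE), dn_fallback = col(FALSE),
    an = col(NA_integer_), an_pressure = col(NA_real_),
    an_missing = col(FALSE), tie = col(FALSE),
    pp = col(NA_real_), map = col(NA_real_), ap = col(NA_real_),
    aix = col(NA_real_), decay_slope = col(NA_real_)
  )
  for (i in seq_len(nb)) {
    on <- segs$onset[i]
    en <- segs$end[i]
    pt <- detect_peak_and_trough(trace, on, en, config, smoothed = xs)
    dn <- detect_dicrotic_notch(trace, on, en, pt$peak, config,
                                smoothed = xs, d2 = d2)
    an <- detect_anacrotic_notch(trace, on, pt$peak, config, d4 = d4)
    met <- compute_beat_metrics(pt$sbp, pt$dbp, an$an_pressure)
    slope <- diastolic_decay_slope(trace, dn$dn, pt$end_diastole, config)
    beats$peak[i] <- pt$peak
    beats$sbp[i] <- pt$sbp
    beats$end_diastole[i] <- pt$end_diastole
    beats$dbp[i] <- pt$dbp
    beats$dn[i] <- dn$dn
    beats$dn_pressure[i] <- dn$dn_pressure
    beats$dn_missing[i] <- dn$missing
    beats$dn_fallback[i] <- dn$fallback
    beats$an[i] <- an$an
    beats$an_pressure[i] <- an$an_pressure
    beats$an_missing[i] <- an$missing
    beats$tie[i] <- pt$tie
    beats$pp[i] <- met$pp
    beats$map[i] <- met$map
    beats$ap[i] <- met$ap
    beats$aix[i] <- met$aix
    beats$decay_slope[i] <- slope
  }
  # a final segment cut short by the end of the trace has an artificially
  # short cycle; exempt it from the cycle-length gate
  beats$cycle_trunc <- beats$end > length(x) &
    beats$cycle_len < 0.98 * stats::median(beats$cycle_len)
  beats$gated <- gate_beats(beats, config)
  summary <- summarize_trace(beats, trace$fs, trim = config$trim)
  list(beats = beats, summary = summary)
}
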