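#' Detection settings for the beat pipeline
#'
#' Collects the tunable constants of segmentation and fiducial detection.
#' The defaults encode the analysis conventions of the pipeline: 2,000
#' samples/s recordings, Savitzky-Golay local-polynomial smoothing and
#' differentiation (order 5; window 21 samples for smoothing and low-order
#' derivatives, window 41 with two pre-smoothing passes for the
#' fourth-derivative filter), a dicrotic-notch search window of 10-60% of
#' the cycle after the systolic peak, a decay-slope window from 30 ms after
#' the dicrotic notch to 20 ms before end-diastole, median +/- 3 MAD artifact
#' gating over a 15-beat rolling window, and 20% per-tail trimmed means.
#'
#' @param sg_window Savitzky-Golay window length (samples, odd) for
#'   smoothing and first/second derivatives.
#' @param sg_order Savitzky-Golay polynomial order.
#' @param an_window wider window used for the fourth-derivative filter: a
#'   fourth derivative at 2 kHz is unusable at the smoothing window length.
#' @param presmooth_passes smoothing passes (at `an_window`) applied before
#'   the fourth-derivative filter in anacrotic-notch detection.
#' @param dn_window dicrotic-notch search window as fractions of the cycle
#'   after the systolic peak.
#' @param dn_fallback use the second-derivative maximum when no local minimum
#'   exists in the search window.
#' @param an_floor relative magnitude below which fourth-derivative samples
#'   are treated as zero when counting sign changes.
#' @param an_lookback_s how far before the detected foot the anacrotic search
#'   may extend when the preceding end-diastole is unknown (s).
#' @param decay_after_dn_s,decay_before_ed_s decay-slope window offsets (s).
#' @param gate_k,gate_window artifact gating threshold (multiples of MAD) and
#'   rolling window (beats).
#' @param gate_floor_sbp,gate_floor_cycle absolute deviation floors (mmHg,
#'   samples) below which a beat is never gated: the MAD of a discretised
#'   near-constant series can vanish, which would otherwise gate beats that
#'   differ from the median by measurement granularity alone.
#' @param trim per-tail trim proportion for trace summaries.
#' @param min_period_s minimum credible beat period for segmentation (s).
#' @param flat_range_mmhg below this peak-to-peak range a trace is treated as
#'   flat and segmentation returns no beats.
#' @param ecg_delay_s offset added to ECG R peaks to obtain beat boundaries
#'   (electromechanical delay).
#' @return a list of class `beat_config`.
#' @export
beat_config <- function(sg_window = 21, sg_order = 5, an_window = 41,
                        presmooth_passes = 2,
                        dn_window = c(0.10, 0.60), dn_fallback = TRUE,
                        an_floor = 1e-3, an_lookback_s = 0.006,
                        decay_after_dn_s = 0.030, decay_before_ed_s = 0.020,
                        gate_k = 3, gate_window = 15,
                        gate_floor_sbp = 2, gate_floor_cycle = 5,
                        trim = 0.20,
                        min_period_s = 0.06, flat_range_mmhg = 1,
                        ecg_delay_s = 0.012) {
  if (sg_window %% 2 != 1 || sg_window < sg_order + 2)
    stop_param("sg_window must be odd and exceed sg_order + 1")
  if (an_window %% 2 != 1 || an_window < sg_order + 2)
    stop_param("an_window must be odd and exceed sg_order + 1")
  if (trim < 0 || trim >= 0.5) stop_param("trim must lie in [0, 0.5)")
  structure(as.list(environment()), class = "beat_config")
}

sg_smooth <- function(x, cfg, passes = 1, window = cfg$sg_window) {
  for (i in seq_len(passes))
    x <- signal::sgolayfilt(x, p = cfg$sg_order, n = window)
  x
}

sg_deriv <- function(x, fs, cfg, m, window = cfg$sg_window) {
  signal::sgolayfilt(x, p = cfg$sg_order, n = window, m = m, ts = 1 / fs)
}

# the two-stage fourth derivative behind anacrotic-notch detection
an_fourth_derivative <- function(x, fs, cfg) {
  xs <- sg_smooth(x, cfg, passes = cfg$presmooth_passes, window = cfg$an_window)
  sg_deriv(xs, fs, cfg, 4, window = cfg$an_window)
}

#' Segment a pressure trace into beats
#'
#' With an ECG, beat boundaries are the R peaks (plus a fixed
#' electromechanical delay). Without one, the pressure foot of each beat is
#' located by the intersecting-tangents rule: the tangent at the point of
#' maximum dP/dt of each upstroke is intersected with the horizontal line
#' through the preceding diastolic minimum. Only complete cycles are
#' returned; partial leading/trailing cycles are discarded. A flat trace
#' yields zero segments with a warning.
#'
#' @param trace a `pressure_trace`.
#' @param ecg optional `ecg_trace` of the same duration.
#' @param config a [beat_config()].
#' @return a data frame with 1-based, half-open segment bounds `onset` and
#'   `end` (exclusive), one row per beat.
#' @export
segment_beats <- function(trace, ecg = NULL, config = beat_config()) {
  stopifnot(inherits(trace, "pressure_trace"))
  x <- trace$pressure
  n <- length(x)
  empty <- data.frame(onset = integer(), end = integer())
  if (!is.null(ecg)) {
    r <- detect_r_peaks(ecg)
    b <- unique(pmin(pmax(r + round(config$ecg_delay_s * trace$fs), 1L), n))
    if (length(b) < 1) return(empty)
    return(close_segments(b, n))
  }
  if (diff(range(x)) < config$flat_range_mmhg) {
    warning("trace is flat: no beats found")
    return(empty)
  }
  xs <- sg_smooth(x, config)
  d1 <- sg_deriv(x, trace$fs, config, 1)
  per <- estimate_period(xs, trace$fs, config$min_period_s)
  min_sep <- max(2L, round(0.55 * per))
  # robust upstroke threshold: a 99th-percentile reference slope is immune to
  # a few outsized (artifact) beats, unlike the global maximum
  thr <- 0.5 * stats::quantile(d1, 0.99, names = FALSE)
  cand <- local_maxima(d1)
  cand <- cand[d1[cand] >= thr]
  if (!length(cand)) {
    warning("no upstrokes found")
    return(empty)
  }
  # enforce minimum separation, keeping the steeper upstroke
  keep <- integer()
  for (i in cand) {
    if (length(keep) && i - keep[length(keep)] < min_sep) {
      if (d1[i] > d1[keep[length(keep)]]) keep[length(keep)] <- i
    } else {
      keep <- c(keep, i)
    }
  }
  ibi <- if (length(keep) > 1) stats::median(diff(keep)) else n
  feet <- integer()
  for (i in keep) {
    lo <- max(1L, i - round(0.4 * ibi))
    pmin_ <- min(xs[lo:i])
    slope <- d1[i] / trace$fs # mmHg per sample
    if (slope <= 0) next
    f <- round(i - (xs[i] - pmin_) / slope)
    feet <- c(feet, min(max(f, lo), i))
  }
  feet <- unique(feet)
  if (length(feet) < 1) return(empty)
  close_segments(feet, n)
}

# dominant cycle length (samples) from the autocorrelation of the smoothed
# pressure: first maximum beyond the minimum credible period
estimate_period <- function(xs, fs, min_period_s) {
  lag_min <- max(2L, round(min_period_s * fs))
  lag_max <- min(length(xs) - 2L, round(2 * fs)) # cap the search at 2 s
  if (lag_max <= lag_min) return(lag_min)
  xc <- xs - mean(xs)
  m <- stats::nextn(2 * length(xc), 2)
  ft <- stats::fft(c(xc, numeric(m - length(xc))))
  ac <- Re(stats::fft(ft * Conj(ft), inverse = TRUE))[1:(lag_max + 1)]
  ac <- ac / ac[1]
  seg <- ac[(lag_min + 1):(lag_max + 1)]
  pk <- local_maxima(seg)
  if (!length(pk)) return(lag_min)
  lag_min + pk[which.max(seg[pk])] - 1L
}

# build half-open segments from boundaries; append the final cycle when the
# remaining tail is long enough to be a complete beat
close_segments <- function(b, n) {
  b <- sort(unique(b))
  if (length(b) == 1) {
    if (n + 1 - b >= 2) return(data.frame(onset = b, end = n + 1L))
    return(data.frame(onset = integer(), end = integer()))
  }
  med <- stats::median(diff(b))
  onsets <- b[-length(b)]
  ends <- b[-1]
  if (n + 1 - b[length(b)] >= 0.85 * med) {
    onsets <- c(onsets, b[length(b)])
    ends <- c(ends, min(n + 1L, b[length(b)] + round(med)))
  }
  data.frame(onset = as.integer(onsets), end = as.integer(ends))
}

detect_r_peaks <- function(ecg) {
  stopifnot(inherits(ecg, "ecg_trace"))
  x <- ecg$ecg
  thr <- 0.5 * max(x)
  above <- x >= thr
  runs <- rle(above)
  stops <- cumsum(runs$lengths)
  starts <- stops - runs$lengths + 1L
  idx <- which(runs$values)
  vapply(idx, function(i) {
    k <- starts[i]:stops[i]
    k[which.max(x[k])]
  }, integer(1))
}

#' Systolic peak and end-diastole of one beat
#'
#' The systolic peak is placed at the maximum of the smoothed pressure within
#' the segment (pressure reported from the raw trace, which avoids the upward
#' bias of a raw argmax under noise); end-diastole at the minimum of the
#' smoothed pressure within the terminal portion of the segment. Ties take
#' the earliest sample and set the `tie` flag.
#'
#' @param trace a `pressure_trace`.
#' @param onset,end 1-based half-open segment bounds.
#' @param config a [beat_config()].
#' @param smoothed optional precomputed smoothed pressure for the whole trace.
#' @param terminal_frac fraction of the segment searched for end-diastole.
#' @return list with `peak`, `sbp`, `end_diastole`, `dbp`, `tie`.
#' @export
detect_peak_and_trough <- function(trace, onset, end, config = beat_config(),
                                   smoothed = NULL, terminal_frac = 0.35) {
  x <- trace$pressure
  xs <- smoothed %||% sg_smooth(x, config)
  seg <- onset:(end - 1L)
  pk_rel <- which.max(xs[seg])
  # ties are judged on the raw samples (an exact plateau)
  tie <- sum(x[seg] == max(x[seg])) > 1
  peak <- seg[pk_rel]
  lo <- max(peak + 1L, end - 1L - as.integer(round(terminal_frac * length(seg))))
  term <- lo:(end - 1L)
  ed <- term[which.min(xs[term])]
  # refine on the raw trace within half a smoothing window: the smoothed
  # minimum of a flat diastolic valley can sit a few samples off the true one
  half <- (config$sg_window - 1L) %/% 2L
  ref <- max(lo, ed - half):min(end - 1L, ed + half)
  ed <- ref[which.min(x[ref])]
  list(peak = peak, sbp = x[peak], end_diastole = ed, dbp = x[ed], tie = tie)
}

#' Dicrotic notch of one beat
#'
#' First local minimum of the smoothed pressure after the systolic peak
#' within a search window expressed as fractions of the cycle length past the
#' peak; if no local minimum exists and `config$dn_fallback` is set, the
#' maximum of the second derivative in the window is used instead. Returns a
#' missing result when neither is available.
#'
#' @inheritParams detect_peak_and_trough
#' @param peak systolic-peak index from [detect_peak_and_trough()].
#' @param d2 optional precomputed second derivative of the whole trace.
#' @return list with `dn`, `dn_pressure`, `missing`, `fallback`.
#' @export
detect_dicrotic_notch <- function(trace, onset, end, peak,
                                  config = beat_config(), smoothed = NULL,
                                  d2 = NULL) {
  x <- trace$pressure
  xs <- smoothed %||% sg_smooth(x, config)
  cyc <- end - onset
  lo <- peak + as.integer(round(config$dn_window[1] * cyc))
  hi <- min(end - 2L, peak + as.integer(round(config$dn_window[2] * cyc)))
  miss <- list(dn = NA_integer_, dn_pressure = NA_real_, missing = TRUE,
               fallback = FALSE)
  if (hi - lo < 2) return(miss)
  win <- lo:hi
  mins <- win[local_maxima(-xs[win])]
  if (length(mins))
    return(list(dn = mins[1], dn_pressure = x[mins[1]], missing = FALSE,
                fallback = FALSE))
  if (!config$dn_fallback) return(miss)
  d2 <- d2 %||% sg_deriv(xs, trace$fs, config, 2)
  dn <- win[which.max(d2[win])]
  # a monotone decay has its d2 maximum pinned at a window edge: treat as none
  if (dn == win[1] || dn == win[length(win)]) return(miss)
  list(dn = dn, dn_pressure = x[dn], missing = FALSE, fallback = TRUE)
}

#' Fourth-derivative sign changes of a pressure signal
#'
#' Smooths the signal (`presmooth_passes` Savitzky-Golay passes), applies the
#' Savitzky-Golay fourth-derivative filter, and returns the sign-change
#' positions (see [sign_changes()] for the tie rules). This is the primitive
#' behind anacrotic-notch detection and can be applied to a whole signal.
#'
#' @param x numeric pressure vector.
#' @param fs sampling rate.
#' @param config a [beat_config()].
#' @return integer vector of crossing indices into `x`.
#' @export
fourth_derivative_crossings <- function(x, fs, config = beat_config()) {
  sign_changes(an_fourth_derivative(x, fs, config),
               floor_frac = config$an_floor)
}

#' Anacrotic notch of one beat
#'
#' The anacrotic notch (reflected-wave shoulder) is the sample at the third
#' sign change of the fourth derivative of the smoothed pressure, counted
#' from the search anchor up to the systolic peak. By default the search
#' starts `config$an_lookback_s` before the detected onset: the
#' intersecting-tangents foot lies on the upstroke, slightly after the first
#' fourth-derivative crossing, while anchoring much earlier would pick up
#' smoothing-filter leakage from the preceding beat.
#'
#' @inheritParams detect_dicrotic_notch
#' @param anchor optional search start (index); default onset minus the
#'   configured lookback.
#' @param d4 optional precomputed fourth derivative of the whole (smoothed)
#'   trace.
#' @return list with `an`, `an_pressure`, `missing`.
#' @export
detect_anacrotic_notch <- function(trace, onset, peak, config = beat_config(),
                                   anchor = NULL, d4 = NULL) {
  x <- trace$pressure
  if (is.null(d4)) d4 <- an_fourth_derivative(x, trace$fs, config)
  a <- anchor %||% max(1L, onset - as.integer(round(config$an_lookback_s *
                                                      trace$fs)))
  miss <- list(an = NA_integer_, an_pressure = NA_real_, missing = TRUE)
  if (peak - a < config$sg_window) return(miss)
  cr <- sign_changes(d4[a:peak], floor_frac = config$an_floor)
  if (length(cr) < 3) return(miss)
  an <- a + cr[3] - 1L
  list(an = an, an_pressure = x[an], missing = FALSE)
}

#' Gate artifact beats
#'
#' Flags beats whose systolic pressure or cycle length deviates from the
#' rolling median by more than `gate_k` times the rolling MAD (normalised,
#' window `gate_window` beats). Deviations are compared strictly, so
#' identical beats are never gated. With fewer than four beats nothing is
#' gated and a warning is raised.
#'
#' @param beats data frame with at least `sbp` and `cycle_len` columns.
#' @param config a [beat_config()].
#' @return logical vector, `TRUE` for gated beats.
#' @export
gate_beats <- function(beats, config = beat_config()) {
  n <- nrow(beats)
  if (n < 4) {
    warning("fewer than 4 beats: gating skipped")
    return(rep(FALSE, n))
  }
  k <- config$gate_k
  half <- config$gate_window %/% 2
  floors <- c(sbp = config$gate_floor_sbp, cycle_len = config$gate_floor_cycle)
  gated <- rep(FALSE, n)
  for (i in seq_len(n)) {
    w <- max(1, i - half):min(n, i + half)
    for (col in c("sbp", "cycle_len")) {
      if (col == "cycle_len" && isTRUE(beats$cycle_trunc[i])) next
      v <- beats[[col]][w]
      med <- stats::median(v)
      s <- stats::mad(v)
      dev <- abs(beats[[col]][i] - med)
      if (is.finite(k) && dev > max(k * s, floors[[col]])) gated[i] <- TRUE
    }
  }
  gated
}

#' Heart rate from beat onsets or an ECG
#'
#' HR (bpm) is 60 divided by the mean inter-beat interval in seconds. Gated
#' beats are excluded: only intervals between adjacent non-gated beats count.
#'
#' @param onsets beat onset sample indices (or R-peak indices).
#' @param fs sampling rate.
#' @param gated optional logical vector marking gated beats.
#' @return heart rate in beats per minute.
#' @export
compute_heart_rate <- function(onsets, fs, gated = NULL) {
  if (length(onsets) < 2) stop_param("heart rate needs at least 2 beats")
  keep_int <- rep(TRUE, length(onsets) - 1)
  if (!is.null(gated))
    keep_int <- !(gated[-length(gated)] | gated[-1])
  ints <- diff(onsets)[keep_int] / fs
  if (!length(ints)) stop_param("no usable inter-beat intervals after gating")
  60 / mean(ints)
}
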