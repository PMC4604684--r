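#' Parameters of the closed-form arterial beat
#'
#' Describes one cardiac cycle of the synthetic arterial pressure waveform.
#' The systolic upstroke is a composite of a forward log-normal lobe and a
#' delayed reflected lobe riding on a cubic baseline ramp; the interference of
#' the two lobes produces the anacrotic shoulder on the upstroke. Systole ends
#' in a dicrotic notch of depth `dn_depth` at `dn_time_frac * period`, after
#' which the pressure decays exponentially with time constant `tau`, reaching
#' `dbp` exactly at the final sample of the cycle. When `tau` is too short for
#' a single exponential to span the whole diastole while staying below `sbp`,
#' the exponential occupies only the terminal part of the diastole and a
#' log-linear bridge connects it to the notch; the ground truth reports the
#' pure-exponential window in either case.
#'
#' @param sbp,dbp systolic / end-diastolic pressure (mmHg). The sampled beat
#'   attains both exactly, at the peak and at the last sample of the cycle.
#' @param period cycle length (s). Default 0.15 s (400 bpm, anaesthetised
#'   mouse range).
#' @param reflected_amplitude nominal amplitude of the reflected lobe (mmHg)
#'   before peak normalisation; larger values give a more augmented waveform
#'   (higher true augmentation index).
#' @param reflected_delay delay of the reflected lobe behind the forward lobe
#'   (s); must place the reflected crest before the dicrotic notch.
#' @param dn_time_frac fraction of the period at which the dicrotic notch
#'   occurs.
#' @param dn_depth depth of the notch below the diastolic envelope (mmHg).
#' @param dn_width full width of the notch dip (s).
#' @param tau diastolic decay time constant (s).
#' @param landing_s duration of the smooth landing at the very end of
#'   diastole (s): a cubic segment that brings the pressure to `dbp` with
#'   zero slope at the last sample, so consecutive beats join without a
#'   slope discontinuity. The ground-truth decay window excludes it.
#' @param fs sampling rate (samples per second).
#' @param forward_frac,sigma_f,sigma_r,decay_cap_frac,sys_end_frac shape
#'   constants of the systolic composite and the diastolic cap; the defaults
#'   produce a late-systolic-augmented waveform with a clear shoulder and are
#'   not normally changed.
#' @return an object of class `beat_shape_params`.
#' @export
beat_shape_params <- function(sbp = 120, dbp = 80, period = 0.15,
                              reflected_amplitude = 48,
                              reflected_delay = 0.035,
                              dn_time_frac = 0.5, dn_depth = 10,
                              dn_width = 0.02, tau = 0.25, landing_s = 0.008,
                              fs = 2000,
                              forward_frac = 0.45, sigma_f = 0.35,
                              sigma_r = 0.35, decay_cap_frac = 0.8,
                              sys_end_frac = 0.85) {
  if (!(sbp > dbp)) stop_param("sbp (%g) must exceed dbp (%g)", sbp, dbp)
  if (dbp <= 0) stop_param("dbp must be positive")
  if (period <= 0 || fs <= 0) stop_param("period and fs must be positive")
  if (tau <= 0) stop_param("tau must be positive")
  if (dn_time_frac <= 0 || dn_time_frac >= 1)
    stop_param("dn_time_frac must lie in (0, 1)")
  if (dn_depth < 0) stop_param("dn_depth must be non-negative")
  if (dn_width <= 0 || dn_time_frac * period - dn_width / 2 <= 0)
    stop_param("dicrotic notch dip must lie inside the cycle")
  if (reflected_delay < 0) stop_param("reflected_delay must be non-negative")
  if (landing_s < 0 || landing_s >= (1 - dn_time_frac) * period)
    stop_param("landing_s must be shorter than the diastole")
  p <- list(sbp = sbp, dbp = dbp, period = period, landing_s = landing_s,
            reflected_amplitude = reflected_amplitude,
            reflected_delay = reflected_delay, dn_time_frac = dn_time_frac,
            dn_depth = dn_depth, dn_width = dn_width, tau = tau, fs = fs,
            forward_frac = forward_frac, sigma_f = sigma_f, sigma_r = sigma_r,
            decay_cap_frac = decay_cap_frac, sys_end_frac = sys_end_frac)
  class(p) <- "beat_shape_params"
  g <- beat_geometry(p)
  if (reflected_delay >= (g$peak_index - 1) / fs + 0.5 / fs &&
      reflected_delay >= g$t_m)
    stop_param("reflected_delay must precede the systolic peak")
  p
}

# derived per-beat constants, including the grid-normalised pulse amplitude A
# chosen so that the sampled maximum equals sbp exactly at one sample
beat_geometry <- function(p) {
  n <- round(p$period * p$fs)
  if (n < 8) stop_param("period * fs too small (%d samples per beat)", n)
  t_end <- (n - 1) / p$fs
  t_dn <- p$dn_time_frac * p$period
  w <- p$dn_width
  t_m <- t_dn - w / 2
  if (t_m <= 0) stop_param("dicrotic notch too early for dn_width")
  p_cap <- p$dbp + p$decay_cap_frac * (p$sbp - p$dbp)
  # the exponential targets dbp at t_end; the landing cubic replaces it over
  # the final landing_s so consecutive beats join with zero slope
  t_land <- t_end - p$landing_s
  t_dec <- max(t_dn + w / 2, t_end - p$tau * log(p_cap / p$dbp))
  if (t_dec >= t_land - 2 / p$fs)
    stop_param("tau too short: no exponential decay window fits the diastole")
  # systolic end level is independent of tau, so the true systolic shape
  # (and hence the true augmentation index) does not vary with it
  B_m <- p$dbp + p$sys_end_frac * (p$sbp - p$dbp)
  tf <- p$forward_frac * t_m
  rho <- p$reflected_amplitude / (p$sbp - p$dbp)
  g <- list(n = n, t_end = t_end, t_land = t_land, t_dn = t_dn, w = w,
            t_m = t_m, t_dec = t_dec, B_m = B_m, tf = tf, rho = rho)
  Rm <- lognormal_lobe(t_m, tf, p$sigma_f) +
    rho * lognormal_lobe(t_m, tf + p$reflected_delay, p$sigma_r)
  g$Rm <- Rm
  tg <- (0:(n - 1)) / p$fs
  sysi <- tg <= t_m
  ts <- tg[sysi]
  R <- lognormal_lobe(ts, tf, p$sigma_f) +
    rho * lognormal_lobe(ts, tf + p$reflected_delay, p$sigma_r)
  Rt <- R - (ts / t_m)^3 * Rm
  c0 <- p$dbp + (B_m - p$dbp) * smoothstep(ts / t_m)
  A <- (p$sbp - p$dbp) / max(Rt)
  for (it in 1:8) {
    k <- which.max(c0 + A * Rt)
    A_new <- (p$sbp - c0[k]) / Rt[k]
    if (abs(A_new - A) < 1e-12) {
      A <- A_new
      break
    }
    A <- A_new
  }
  g$A <- A
  g$peak_index <- which.max(c0 + A * Rt) # 1-based sample within beat
  g
}

# continuous closed-form beat pressure at arbitrary times t in [0, t_end]
beat_pressure <- function(t, p, g = beat_geometry(p)) {
  out <- numeric(length(t))
  sys <- t <= g$t_m
  if (any(sys)) {
    ts <- t[sys]
    R <- lognormal_lobe(ts, g$tf, p$sigma_f) +
      g$rho * lognormal_lobe(ts, g$tf + p$reflected_delay, p$sigma_r)
    Rt <- R - (ts / g$t_m)^3 * g$Rm
    out[sys] <- p$dbp + (g$B_m - p$dbp) * smoothstep(ts / g$t_m) + g$A * Rt
  }
  if (any(!sys)) {
    td <- t[!sys]
    base <- p$dbp * exp((g$t_end - td) / p$tau)
    if (g$t_dec > g$t_m + 1e-12) {
      br <- td < g$t_dec
      if (any(br)) {
        lB <- log(g$B_m)
        lE <- log(p$dbp) + (g$t_end - g$t_dec) / p$tau
        frac <- (td[br] - g$t_m) / (g$t_dec - g$t_m)
        base[br] <- exp(lB + (lE - lB) * frac)
      }
    }
    if (p$landing_s > 0) {
      ld <- td > g$t_land
      if (any(ld)) {
        # cubic Hermite landing: matches the exponential's value and slope
        # at t_land, reaches dbp with zero slope at t_end
        h <- g$t_end - g$t_land
        p1 <- p$dbp * exp((g$t_end - g$t_land) / p$tau)
        m1 <- -p1 / p$tau
        s <- (td[ld] - g$t_land) / h
        h00 <- (1 + 2 * s) * (1 - s)^2
        h10 <- s * (1 - s)^2
        base[ld] <- h00 * p1 + h10 * h * m1 + (1 - h00) * p$dbp
      }
    }
    dip <- ifelse(abs(td - g$t_dn) < g$w / 2,
                  p$dn_depth * 0.5 * (1 + cos(2 * pi * (td - g$t_dn) / g$w)),
                  0)
    out[!sys] <- base - dip
  }
  out
}

# analytic ground-truth landmarks of one beat, from the closed form evaluated
# on an `oversample`-times finer grid (times relative to beat start, seconds)
beat_oracle <- function(p, g = beat_geometry(p), oversample = 10) {
  dt <- 1 / (p$fs * oversample)
  tf <- seq(0, g$t_end, by = dt)
  P <- beat_pressure(tf, p, g)
  pk <- which.max(P)
  # tangent-intersection foot: horizontal through the diastolic minimum
  # crossed with the tangent at maximum dP/dt on the upstroke
  d1 <- c(NA, diff(P)) / dt
  i_star <- which.max(d1[seq_len(pk)])
  t_foot <- tf[i_star] - (P[i_star] - p$dbp) / d1[i_star]
  # anacrotic notch: third sign change of the 4th derivative before the peak
  d4 <- P
  for (i in 1:4) d4 <- c(NA, diff(d4)) / dt
  seg <- d4[5:pk]
  cr <- sign_changes(seg, floor_frac = 1e-3)
  an_t <- if (length(cr) >= 3) tf[4 + cr[3]] else NA_real_
  # dicrotic notch: local minimum of the dip
  win <- which(abs(tf - g$t_dn) <= g$w / 2)
  dn_t <- tf[win[which.min(P[win])]]
  list(foot_t = t_foot, an_t = an_t,
       an_pressure = if (is.na(an_t)) NA_real_ else beat_pressure(an_t, p, g),
       dn_t = dn_t, dn_pressure = min(P[win]),
       peak_t = (g$peak_index - 1) / p$fs,
       decay_start_t = g$t_dec, decay_end_t = g$t_land, end_t = g$t_end)
}
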