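test_that("beat metric formulas: PP, MAP, AP, AIx", {
  m <- compute_beat_metrics(120, 80, 110)
  expect_equal(m$pp, 40)
  expect_equal(m$map, 120 / 3 + 2 * 80 / 3, tolerance = 1e-12)
  expect_equal(m$ap, 10)
  expect_equal(m$aix, 0.25)

  expect_equal(compute_beat_metrics(120, 80, 120)$aix, 0)
  flat <- compute_beat_metrics(100, 100, 100)
  expect_true(flat$aix_undefined)
  expect_true(is.na(flat$aix))
  no_an <- compute_beat_metrics(120, 80)
  expect_true(is.na(no_an$ap) && is.na(no_an$aix))
})

test_that("map lies strictly between dbp and sbp when pp > 0", {
  for (s in 1:5) {
    set.seed(s)
    sbp <- runif(20, 90, 200)
    dbp <- sbp - runif(20, 1, 60)
    m <- mapply(function(a, b) compute_beat_metrics(a, b)$map, sbp, dbp)
    expect_true(all(m > dbp & m < sbp))
  }
})

test_that("decay slope is exact on analytic exponentials", {
  ed <- exp_decay_trace(0.04, p0 = 80, duration = 0.12)
  s <- diastolic_decay_slope(ed$trace, ed$markers$dn[1],
                             ed$markers$end_diastole[1])
  expect_equal(s, -25, tolerance = 1e-9)

  ed2 <- exp_decay_trace(0.08, p0 = 80, duration = 0.12)
  s2 <- diastolic_decay_slope(ed2$trace, ed2$markers$dn[1],
                              ed2$markers$end_diastole[1])
  expect_equal(s2, -12.5, tolerance = 1e-9)

  # window [DN + 30 ms, ED - 20 ms] collapses: missing
  short <- exp_decay_trace(0.04, duration = 0.045)
  expect_true(is.na(diastolic_decay_slope(short$trace, short$markers$dn[1],
                                          short$markers$end_diastole[1])))
})

test_that("raw-pressure slope variant is available", {
  ed <- exp_decay_trace(0.2, p0 = 100, duration = 0.12)
  s_lin <- diastolic_decay_slope(ed$trace, ed$markers$dn[1],
                                 ed$markers$end_diastole[1], semilog = FALSE)
  # mean derivative of 100 exp(-t/0.2) over the window is about -450 mmHg/s
  expect_lt(s_lin, -300)
  expect_gt(s_lin, -600)
})

test_that("tau is the reciprocal trimmed-mean slope magnitude", {
  expect_equal(compute_tau(rep(-25, 10)), 0.040)
  # 20% per-tail trim drops -100 and -24
  slopes <- c(-100, -26, -25, -25, -24)
  expect_equal(trimmed_mean(slopes, 0.2), mean(c(-26, -25, -25)))
  expect_equal(compute_tau(slopes, trim = 0.20), 1 / abs(-76 / 3),
               tolerance = 1e-12)
  expect_equal(compute_tau(c(-20, -30), trim = 0), 0.040)
  expect_error(compute_tau(numeric()), "no finite")
  expect_error(compute_tau(c(2, -2), trim = 0), "zero")
})

test_that("tau recovery on pure exponentials is within 0.5% for any window", {
  for (tau in c(0.02, 0.04, 0.08)) {
    ed <- exp_decay_trace(tau, p0 = 110, duration = 0.12, n_beats = 20)
    slopes <- vapply(seq_len(20), function(i)
      diastolic_decay_slope(ed$trace, ed$markers$dn[i],
                            ed$markers$end_diastole[i]), numeric(1))
    expect_lt(abs(compute_tau(slopes) - tau) / tau, 0.005)
  }
})

test_that("trace summary of identical beats equals the single-beat metrics", {
  res <- quiet_analyze(clean_trace(n_beats = 10)$trace)
  s <- res$summary
  first <- res$beats[2, ]
  expect_equal(s$metrics$sbp[["mean"]], 120)
  expect_equal(s$metrics$dbp[["mean"]], 80)
  expect_equal(s$metrics$pp[["mean"]], 40)
  expect_equal(s$metrics$aix[["trimmed_mean"]], first$aix, tolerance = 0.05)
  expect_equal(s$tau_s, 0.25, tolerance = 1e-6)
  expect_equal(s$hr_bpm, 400, tolerance = 1e-6)
  expect_equal(s$n_beats_used, 10)
})

test_that("gated beats do not influence the summary", {
  sim <- generate_trace(default_beat(), 22, noise_sd = 0.5,
                        artifact = list(beats = c(8, 16)), seed = 42)
  res <- quiet_analyze(sim$trace)
  manual <- res$beats[!res$beats$gated, ]
  expect_equal(res$summary$metrics$sbp[["mean"]], mean(manual$sbp))
  expect_lt(abs(res$summary$metrics$sbp[["mean"]] - 120), 1)
  expect_error(summarize_trace(transform(res$beats, gated = TRUE), 2000),
               "all beats gated")
})

test_that("noisy 60-beat summary recovers the generator pressures", {
  sim <- generate_trace(default_beat(), 60, noise_sd = 0.5, seed = 9)
  res <- quiet_analyze(sim$trace)
  b <- res$beats[!res$beats$gated, ]
  sem <- stats::sd(b$sbp) / sqrt(nrow(b))
  # smoothed-argmax SBP estimator is unbiased to well under half a noise sd
  expect_lt(abs(mean(b$sbp) - 120), max(3 * sem, 0.25))
  expect_lt(abs(res$summary$tau_s - 0.25) / 0.25, 0.05)
  expect_lt(abs(res$summary$hr_bpm - 400), 2)
})
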