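test_that("segmentation finds every complete beat, with and without ECG", {
  sim <- clean_trace(n_beats = 10)
  ecg <- generate_ecg(sim$truth)
  segs_e <- segment_beats(sim$trace, ecg = ecg)
  segs_p <- segment_beats(sim$trace)
  expect_equal(nrow(segs_e), 10)
  expect_equal(nrow(segs_p), 10)
  # intersecting-tangents feet match the oversampled oracle feet
  expect_true(all(abs(segs_p$onset - truth_of(sim)$onset) <= 2))
  # ECG-based and pressure-based onsets agree within 5 ms
  expect_true(all(abs(segs_e$onset - segs_p$onset) <= 0.005 * 2000))
})

test_that("a flat trace yields no beats and a warning", {
  flat <- structure(list(pressure = rep(90, 4000), fs = 2000),
                    class = "pressure_trace")
  expect_warning(segs <- segment_beats(flat), "flat")
  expect_equal(nrow(segs), 0)
})

test_that("peak and trough detection is exact on noise-free beats", {
  sim <- clean_trace(n_beats = 6)
  res <- quiet_analyze(sim$trace)
  tb <- truth_of(sim)
  expect_true(all(abs(res$beats$peak - tb$peak) <= 2))
  expect_true(all(abs(res$beats$end_diastole - tb$end_diastole) <= 2))
  expect_equal(res$beats$sbp, rep(120, 6))
  expect_equal(res$beats$dbp, rep(80, 6))
})

test_that("an exact plateau maximum takes the earliest index and a tie flag", {
  n <- 600
  x <- c(rep(80, 200), seq(80, 120, length.out = 50), rep(120, 100),
         seq(120, 80, length.out = 150), rep(80, 100))
  tr <- structure(list(pressure = x, fs = 2000), class = "pressure_trace")
  pt <- detect_peak_and_trough(tr, 1L, length(x) + 1L)
  expect_true(pt$tie)
  expect_equal(pt$sbp, 120)
  # earliest sample of the (smoothed) plateau maximum
  expect_lte(pt$peak, 260)
})

test_that("noisy SBP stays within 3 sigma of the true peak", {
  sim <- noisy_trace(n_beats = 12, noise_sd = 1, seed = 5)
  res <- quiet_analyze(sim$trace)
  expect_true(all(abs(res$beats$sbp - 120) <= 3))
})

test_that("dicrotic notch is found at the oracle position", {
  sim <- clean_trace(n_beats = 8)
  res <- quiet_analyze(sim$trace)
  expect_true(all(abs(res$beats$dn - truth_of(sim)$dn) <= 2))
  expect_true(all(!res$beats$dn_missing))
})

test_that("monotone decay without a notch reports dn_missing", {
  ed <- exp_decay_trace(0.15, p0 = 120, duration = 0.3)
  cfg <- beat_config(dn_fallback = FALSE)
  out <- detect_dicrotic_notch(ed$trace, 1L, 600L, 1L, config = cfg)
  expect_true(out$missing)
})

test_that("noisy DN and AN detections stay within 5 ms of noise-free ones", {
  clean <- quiet_analyze(clean_trace(n_beats = 12)$trace)$beats
  dn0 <- (clean$dn - clean$onset)[2]
  an0 <- (clean$an - clean$onset)[2]
  dn_err <- c()
  an_err <- c()
  for (s in 1:10) {
    sim <- noisy_trace(n_beats = 12, noise_sd = 0.5, seed = s)
    b <- quiet_analyze(sim$trace)$beats
    mid <- 2:(nrow(b) - 1)
    dn_err <- c(dn_err, abs((b$dn - b$onset)[mid] - dn0))
    an_err <- c(an_err, abs((b$an - b$onset)[mid] - an0))
  }
  expect_gte(mean(dn_err <= 10, na.rm = TRUE), 0.95)
  expect_gte(mean(an_err <= 10, na.rm = TRUE), 0.95)
  expect_lt(mean(is.na(an_err)), 0.02)
})

test_that("fourth-derivative crossings of a pure sine land on the sine zeros", {
  fs <- 2000
  t <- (0:(2 * fs - 1)) / fs
  x <- 100 + 10 * sin(4 * pi * t)
  cr <- fourth_derivative_crossings(x, fs)
  expect_equal((cr[1:3] - 1) / fs, c(0.25, 0.50, 0.75),
               tolerance = 1.1 / fs / 0.25)
})

test_that("anacrotic notch matches the oversampled closed-form oracle", {
  for (ra in c(40, 48, 56)) {
    sim <- clean_trace(n_beats = 6, reflected_amplitude = ra)
    res <- quiet_analyze(sim$trace)
    err_ms <- abs(res$beats$an - truth_of(sim)$an) / 2 # samples -> ms
    expect_true(all(err_ms <= 2))
  }
})

test_that("too-short segments report the anacrotic notch as missing", {
  sim <- clean_trace(n_beats = 2)
  out <- detect_anacrotic_notch(sim$trace, 1L, 15L)
  expect_true(out$missing)
})

test_that("detection indices ignore pressure offset and positive scaling", {
  sim <- clean_trace(n_beats = 8)
  base <- quiet_analyze(sim$trace)$beats
  shifted <- sim$trace
  shifted$pressure <- shifted$pressure + 35
  b1 <- quiet_analyze(shifted)$beats
  scaled <- sim$trace
  scaled$pressure <- scaled$pressure * 1.7
  b2 <- quiet_analyze(scaled)$beats
  for (colm in c("onset", "peak", "dn", "an", "end_diastole")) {
    expect_equal(b1[[colm]], base[[colm]])
    expect_equal(b2[[colm]], base[[colm]])
  }
  # aix is offset-invariant because SBP, DBP and AN pressure shift together
  expect_equal(b1$aix, base$aix)
})

test_that("gating removes exactly the injected artifact beats", {
  sim <- generate_trace(default_beat(), 22, noise_sd = 0.5,
                        artifact = list(beats = c(8, 16)), seed = 42)
  res <- quiet_analyze(sim$trace)
  expect_identical(which(res$beats$gated), c(8L, 16L))
})

test_that("identical beats and an infinite threshold gate nothing", {
  res <- quiet_analyze(clean_trace(n_beats = 10)$trace)
  expect_equal(sum(res$beats$gated), 0)
  sim <- generate_trace(default_beat(), 22, noise_sd = 0.5,
                        artifact = list(beats = c(8, 16)), seed = 42)
  res_inf <- quiet_analyze(sim$trace, config = beat_config(gate_k = Inf))
  expect_equal(sum(res_inf$beats$gated), 0)
})

test_that("fewer than four beats skips gating with a warning", {
  b <- data.frame(sbp = c(120, 150, 120), cycle_len = c(300, 300, 300))
  expect_warning(g <- gate_beats(b), "fewer than 4")
  expect_equal(g, rep(FALSE, 3))
})

test_that("heart rate is 60 over the mean inter-beat interval", {
  expect_equal(compute_heart_rate(seq(1, by = 400, length.out = 10), 2000), 300)
  expect_equal(compute_heart_rate(seq(1, by = 200, length.out = 5), 2000), 600)
  onsets <- cumsum(c(1, rep(c(400, 600), 5)))
  expect_equal(compute_heart_rate(onsets, 2000), 60 / 0.25)
  expect_error(compute_heart_rate(5, 2000), "at least 2")
})

test_that("fiducial ordering invariant holds for all analysed beats", {
  for (s in 1:3) {
    sim <- noisy_trace(n_beats = 10, noise_sd = 0.5, seed = s)
    b <- quiet_analyze(sim$trace)$beats
    ok <- !b$an_missing & !b$dn_missing
    expect_true(all(b$onset[ok] <= b$an[ok]))
    expect_true(all(b$an[ok] < b$peak[ok]))
    expect_true(all(b$peak[ok] < b$dn[ok]))
    expect_true(all(b$dn[ok] < b$end_diastole[ok]))
    expect_true(all(b$sbp > b$dbp))
  }
})
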