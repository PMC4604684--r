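test_that("half-log grids multiply by sqrt(10)", {
  expect_equal(half_log_doses(1, 4), c(1, 10^0.5, 10, 10^1.5),
               tolerance = 1e-12)
})

test_that("noise-free simulation reproduces the closed-form 4PL", {
  tru <- four_pl_truth(bottom = 100, emax = 180, ed50 = 35, hill = 1.5)
  dr <- simulate_dose_response(tru)
  expect_equal(dr$response,
               four_pl(dr$dose, 100, 180, 35, 1.5), tolerance = 1e-12)
  # response at the ed50 is the midpoint
  expect_equal(four_pl(35, 100, 180, 35, 1.5), 140)
})

test_that("zero-noise fits recover all four parameters to 1e-6", {
  tru <- four_pl_truth(bottom = 100, emax = 180, ed50 = 35, hill = 1.5,
                       doses = half_log_doses(1, 8))
  dr <- simulate_dose_response(tru)
  fit <- fit_4pl(dr$dose, dr$response)
  expect_true(fit$converged)
  rel <- abs(fit$coef - c(100, 180, 35, 1.5)) / c(100, 180, 35, 1.5)
  expect_true(all(rel < 1e-6))
})

test_that("degenerate and invalid inputs are rejected", {
  d <- half_log_doses(1, 6)
  expect_error(fit_4pl(d, rep(120, 6)), "constant")
  expect_error(fit_4pl(d, c(1, 2, 3)), "length")
  expect_error(fit_4pl(d[1:3], c(1, 2, 3)), "at least 4")
  expect_error(four_pl_truth(ed50 = -2), "ed50")
  expect_error(four_pl_truth(emax = 90, bottom = 100), "emax")
})

test_that("prediction honours the fitted curve and its asymptotes", {
  tru <- four_pl_truth()
  fit <- fit_4pl(tru$doses, simulate_dose_response(tru)$response)
  expect_equal(predict(fit, fit$coef[["ed50"]]),
               (fit$coef[["bottom"]] + fit$coef[["emax"]]) / 2,
               tolerance = 1e-6)
  expect_equal(predict(fit, 1e6 * fit$coef[["ed50"]]), fit$coef[["emax"]],
               tolerance = 1e-3 * fit$coef[["emax"]])
  expect_equal(predict(fit, 1e-6 * fit$coef[["ed50"]]), fit$coef[["bottom"]],
               tolerance = 1e-3)
  expect_error(predict(fit, -1), "positive")
})

test_that("dose-scale equivariance: ed50 scales, shape stays", {
  tru <- four_pl_truth(noise_sd = 2)
  dr <- simulate_dose_response(tru, seed = 21)
  f1 <- fit_4pl(dr$dose, dr$response)
  f2 <- fit_4pl(dr$dose * 50, dr$response)
  expect_equal(f2$coef[["ed50"]] / f1$coef[["ed50"]], 50, tolerance = 1e-4)
  for (parm in c("bottom", "emax", "hill"))
    expect_equal(f2$coef[[parm]], f1$coef[[parm]], tolerance = 1e-5)
})

test_that("fit residuals do not exceed those of the self-start values", {
  tru <- four_pl_truth(noise_sd = 3)
  for (s in 1:5) {
    dr <- simulate_dose_response(tru, seed = s)
    fit <- fit_4pl(dr$dose, dr$response)
    start_pred <- four_pl(dr$dose, min(dr$response), max(dr$response),
                          dr$dose[which.min(abs(dr$response -
                            (min(dr$response) + max(dr$response)) / 2))], 1)
    expect_lte(fit$rss, sum((dr$response - start_pred)^2) + 1e-9)
  }
})

test_that("median ED50 error shrinks as response noise falls", {
  med_err <- vapply(c(4, 1, 0.25), function(sd) {
    errs <- vapply(1:60, function(s) {
      tru <- four_pl_truth(noise_sd = sd)
      dr <- simulate_dose_response(tru, seed = s)
      fit <- fit_4pl(dr$dose, dr$response)
      abs(fit$coef[["ed50"]] - 35) / 35
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("group comparison separates distinct Emax and respects the null", {
  fit_group <- function(emax, n, seed0) {
    lapply(seq_len(n), function(i) {
      tru <- four_pl_truth(emax = emax, noise_sd = 2)
      dr <- simulate_dose_response(tru, seed = seed0 + i)
      fit_4pl(dr$dose, dr$response)
    })
  }
  a <- fit_group(180, 10, 100)
  b <- fit_group(165, 10, 200)
  cmp <- compare_fits(a, b)
  expect_lt(cmp$emax$test$p, 0.05)
  expect_error(compare_fits(a[1], b), "at least 2")

  # identical groups: rejection rate compatible with the nominal level
  set.seed(4)
  rej <- vapply(1:200, function(i) {
    ea <- 180 + rnorm(6, 0, 2)
    eb <- 180 + rnorm(6, 0, 2)
    group_t_test(ea, eb)$p < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.09)
})
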