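#' Four-parameter logistic curve
#'
#' `R(d) = bottom + (emax - bottom) / (1 + (ed50 / d)^hill)` — the ascending
#' 4PL used for vasopressor dose-response data, where `ed50` is the dose
#' producing the half-maximal response and `emax` the upper asymptote.
#'
#' @param dose dose (same units as `ed50`, > 0).
#' @param bottom,emax lower and upper asymptote (mmHg).
#' @param ed50 half-maximal dose.
#' @param hill Hill slope (dimensionless, > 0 for ascending curves).
#' @return response at `dose`.
#' @export
four_pl <- function(dose, bottom, emax, ed50, hill) {
  bottom + (emax - bottom) / (1 + (ed50 / dose)^hill)
}

#' Half-log dose grid
#'
#' Doses increasing by a factor of sqrt(10) per step, as in half-log serial
#' dilution bolus protocols.
#'
#' @param start first dose.
#' @param n number of doses.
#' @return numeric vector of doses.
#' @export
half_log_doses <- function(start, n) start * 10^((seq_len(n) - 1) / 2)

#' True parameters of a simulated dose-response experiment
#'
#' @param bottom,emax lower/upper asymptote (mmHg); `emax > bottom`.
#' @param ed50 half-maximal dose (ug/kg, > 0).
#' @param hill Hill slope (> 0).
#' @param doses strictly increasing dose grid (ug/kg).
#' @param noise_sd Gaussian response noise (mmHg).
#' @return object of class `four_pl_truth`.
#' @export
four_pl_truth <- function(bottom = 100, emax = 180, ed50 = 35, hill = 1.5,
                          doses = half_log_doses(1, 8), noise_sd = 0) {
  if (ed50 <= 0) stop_param("ed50 must be positive")
  if (emax <= bottom) stop_param("emax must exceed bottom")
  if (hill <= 0) stop_param("hill must be positive")
  if (any(doses <= 0) || is.unsorted(doses, strictly = TRUE))
    stop_param("doses must be positive and strictly increasing")
  structure(list(bottom = bottom, emax = emax, ed50 = ed50, hill = hill,
                 doses = doses, noise_sd = noise_sd),
            class = "four_pl_truth")
}

#' Simulate a dose-response series
#'
#' Evaluates the 4PL at the truth's dose grid and adds Gaussian noise.
#'
#' @param truth a [four_pl_truth()].
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return data frame with `dose` and `response`.
#' @export
simulate_dose_response <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "four_pl_truth"))
  if (!is.null(seed)) set.seed(seed)
  r <- four_pl(truth$doses, truth$bottom, truth$emax, truth$ed50, truth$hill)
  if (truth$noise_sd > 0)
    r <- r + stats::rnorm(length(r), 0, truth$noise_sd)
  data.frame(dose = truth$doses, response = r)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Bounded Levenberg-Marquardt nonlinear least squares on the ascending 4PL,
#' with self-starting values (bottom = min response, emax = max response,
#' ed50 = dose nearest the mid-response, hill = 1) and the Hill slope and
#' ed50 constrained positive. Non-convergence is reported in the result, not
#' raised.
#'
#' @param doses strictly increasing doses (> 0), length >= 4.
#' @param responses responses (mmHg), finite, same length.
#' @return object of class `four_pl_fit`: `coef` (bottom, emax, ed50, hill),
#'   `se`, `rss`, `converged`, `n`, and the data.
#' @export
fit_4pl <- function(doses, responses) {
  if (length(doses) != length(responses))
    stop_param("doses and responses differ in length")
  if (length(doses) < 4)
    stop_param("at least 4 dose-response points are required")
  if (any(!is.finite(responses)) || any(!is.finite(doses)))
    stop_param("doses and responses must be finite")
  if (any(doses <= 0)) stop_param("doses must be positive")
  if (stats::sd(responses) == 0)
    stop_param("responses are constant: 4PL fit is degenerate")
  mid <- (min(responses) + max(responses)) / 2
  start <- list(bottom = min(responses), emax = max(responses),
                ed50 = doses[which.min(abs(responses - mid))], hill = 1)
  df <- data.frame(d = doses, r = responses)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ bottom + (emax - bottom) / (1 + (ed50 / d)^hill),
      data = df, start = start,
      lower = c(bottom = -Inf, emax = -Inf, ed50 = 1e-12, hill = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10,
                                           ptol = 1e-10)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(coef = unlist(start), se = rep(NA_real_, 4),
                          rss = NA_real_, converged = FALSE,
                          n = length(doses), doses = doses,
                          responses = responses,
                          message = conditionMessage(fit)),
                     class = "four_pl_fit"))
  }
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, 4))
  conv <- fit$convInfo$isConv %||% TRUE
  structure(list(coef = co, se = se, rss = sum(stats::resid(fit)^2),
                 converged = isTRUE(conv), n = length(doses),
                 doses = doses, responses = responses),
            class = "four_pl_fit")
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat(sprintf(paste0("<four_pl_fit> bottom %.2f, Emax %.2f, ED50 %.4g, ",
                     "Hill %.3f (n = %d, %s)\n"),
              x$coef["bottom"], x$coef["emax"], x$coef["ed50"],
              x$coef["hill"], x$n,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Predict from a fitted 4PL curve
#'
#' @param object a `four_pl_fit`.
#' @param dose doses (> 0).
#' @param ... unused.
#' @return predicted responses.
#' @export
predict.four_pl_fit <- function(object, dose, ...) {
  if (!object$converged) stop_param("cannot predict from a non-converged fit")
  if (any(dose <= 0)) stop_param("dose must be positive")
  four_pl(dose, object$coef[["bottom"]], object$coef[["emax"]],
          object$coef[["ed50"]], object$coef[["hill"]])
}

#' Compare fitted Emax and ED50 between two groups of animals
#'
#' Unpaired two-tailed Student t-tests on the per-animal fitted `emax` and
#' `ed50` values.
#'
#' @param fits_a,fits_b lists of `four_pl_fit` objects (>= 2 each).
#' @return list with one [group_t_test()] result per parameter, plus the
#'   per-group values.
#' @export
compare_fits <- function(fits_a, fits_b) {
  chk <- function(fits, nm) {
    if (length(fits) < 2)
      stop_param("group %s needs at least 2 fits", nm)
    if (!all(vapply(fits, inherits, logical(1), "four_pl_fit")))
      stop_param("group %s must contain four_pl_fit objects", nm)
  }
  chk(fits_a, "A")
  chk(fits_b, "B")
  pull <- function(fits, what) vapply(fits, function(f) f$coef[[what]],
                                      numeric(1))
  out <- lapply(c(emax = "emax", ed50 = "ed50"), function(par) {
    a <- pull(fits_a, par)
    b <- pull(fits_b, par)
    list(test = group_t_test(a, b), values_a = a, values_b = b)
  })
  out
}
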