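#' Trimmed mean
#'
#' Discards `floor(n * trim)` smallest and largest values and averages the
#' rest (the per-tail robust-statistics convention; for the default
#' `trim = 0.20`, the "20% trimmed mean").
#'
#' @param x numeric values.
#' @param trim per-tail trim proportion in `[0, 0.5)`.
#' @return the trimmed mean.
#' @export
trimmed_mean <- function(x, trim = 0.20) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (!n) stop_param("no values to average")
  if (trim < 0) stop_param("trim must be non-negative")
  k <- floor(n * trim)
  if (2 * k >= n) stop_param("trim %.2f leaves no values for n = %d", trim, n)
  if (k == 0) return(mean(x))
  mean(sort(x)[(k + 1):(n - k)])
}

#' Two-tailed Student t-test between two groups
#'
#' Classical Student t-test, paired or unpaired; the unpaired test pools the
#' variances by default (Welch by `var_equal = FALSE`). Degenerate input
#' (zero variance) yields a flagged result instead of an error.
#'
#' @param a,b numeric samples (paired tests require equal length).
#' @param paired paired test on the differences.
#' @param var_equal pool variances (classical Student); `FALSE` for Welch.
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`, `method`, `error`
#'   (`NULL` unless degenerate).
#' @export
group_t_test <- function(a, b, paired = FALSE, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2)
    stop_param("each group needs at least 2 values")
  if (paired && length(a) != length(b))
    stop_param("paired test requires equal group sizes")
  res <- tryCatch(
    stats::t.test(a, b, paired = paired, var.equal = var_equal,
                  alternative = "two.sided"),
    error = function(e) e)
  if (inherits(res, "error")) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                mean_a = mean(a), mean_b = mean(b),
                method = if (paired) "paired" else "unpaired",
                error = conditionMessage(res)))
  }
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, mean_a = mean(a), mean_b = mean(b),
       method = if (paired) "paired" else
         if (var_equal) "unpaired pooled" else "unpaired Welch",
       error = NULL)
}

#' Ratio t-test for ratiometric expression data
#'
#' One-sample two-tailed t-test of the log-ratios against 0 (i.e. of the
#' ratios against 1, "no change"), reporting the geometric mean ratio and
#' the exponentiated t-based 95% confidence interval of the mean log-ratio.
#' A linear-scale variant (`log_scale = FALSE`) tests the raw ratios
#' against 1.
#'
#' @param ratios positive ratios, length >= 2.
#' @param conf confidence level.
#' @param log_scale analyse log-ratios (default) or raw ratios.
#' @return list of class `ratio_t_test`: `mean_ratio`, `ci` (length 2),
#'   `p`, `t`, `df`, `n`, `flag` (`"no variance"` when degenerate).
#' @export
ratio_t_test <- function(ratios, conf = 0.95, log_scale = TRUE) {
  if (length(ratios) < 2) stop_param("need at least 2 ratios")
  if (any(ratios <= 0)) stop_param("ratios must be positive")
  y <- if (log_scale) log(ratios) else ratios
  mu <- if (log_scale) 0 else 1
  back <- if (log_scale) exp else identity
  centre <- back(mean(y))
  if (stats::sd(y) == 0) {
    return(structure(list(mean_ratio = centre, ci = c(centre, centre),
                          p = NA_real_, t = NA_real_,
                          df = length(y) - 1, n = length(ratios),
                          flag = "no variance"),
                     class = "ratio_t_test"))
  }
  tt <- stats::t.test(y, mu = mu, conf.level = conf)
  structure(list(mean_ratio = centre, ci = back(as.numeric(tt$conf.int)),
                 p = tt$p.value, t = unname(tt$statistic),
                 df = unname(tt$parameter), n = length(ratios), flag = NULL),
            class = "ratio_t_test")
}

#' @export
print.ratio_t_test <- function(x, ...) {
  cat(sprintf("<ratio_t_test> mean ratio %.4f, 95%% CI [%.4f, %.4f], p = %.4g (n = %d)%s\n",
              x$mean_ratio, x$ci[1], x$ci[2], x$p, x$n,
              if (!is.null(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Percent change between two group means
#'
#' @param mean_ref reference mean (non-zero).
#' @param mean_alt comparison mean.
#' @return `100 * (mean_alt - mean_ref) / mean_ref`.
#' @export
percent_change <- function(mean_ref, mean_alt) {
  if (mean_ref == 0) stop_param("reference mean is zero")
  100 * (mean_alt - mean_ref) / mean_ref
}
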