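# internal numeric helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

# log-normal-shaped unit pulse: peak value 1 at t = tp, zero for t <= 0
lognormal_lobe <- function(t, tp, sigma) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- exp(-(log(t[pos] / tp))^2 / (2 * sigma^2))
  out
}

#' Sign changes of a sampled signal
#'
#' Locates zero crossings of `x` using a deterministic tie rule: values with
#' magnitude below `floor_frac * max(abs(x))` are treated as exactly zero,
#' zeros inherit the preceding non-zero sign (leading zeros the following
#' one), and a crossing is reported at the first sample after each sign
#' change. A value passing through an exact zero therefore counts once.
#'
#' @param x numeric vector (typically a derivative of a pressure signal).
#' @param floor_frac relative magnitude below which samples count as zero.
#' @return integer vector of crossing positions (indices into `x`).
#' @export
sign_changes <- function(x, floor_frac = 1e-3) {
  if (!length(x)) return(integer())
  x[!is.finite(x)] <- 0
  mx <- max(abs(x))
  if (mx == 0) return(integer())
  x[abs(x) < floor_frac * mx] <- 0
  s <- sign(x)
  nz <- s != 0
  if (!any(nz)) return(integer())
  # carry last non-zero sign forward; leading zeros take the first real sign
  idx <- cumsum(nz)
  first <- which(nz)[1]
  filled <- s[nz][pmax(idx, 1)]
  filled[seq_len(first - 1)] <- s[nz][1]
  which(diff(filled) != 0) + 1L
}

# local maxima (strict) of a numeric vector; returns indices
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# least-squares slope of y on x without lm() overhead
ls_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc * xc)
}

# bilinear interpolation of matrix img at fractional (row, col) positions
bilinear <- function(img, row, col) {
  nr <- nrow(img)
  nc <- ncol(img)
  r0 <- floor(row)
  c0 <- floor(col)
  fr <- row - r0
  fc <- col - c0
  r0 <- pmin(pmax(r0, 1), nr - 1)
  c0 <- pmin(pmax(c0, 1), nc - 1)
  i00 <- img[cbind(r0, c0)]
  i01 <- img[cbind(r0, c0 + 1)]
  i10 <- img[cbind(r0 + 1, c0)]
  i11 <- img[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * ((1 - fc) * i00 + fc * i01) + fr * ((1 - fc) * i10 + fc * i11)
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)
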