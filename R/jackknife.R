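#' Jackknife inference for a simple linear regression slope
#'
#' Ordinary least-squares fit of \code{y ~ x} with delete-one jackknife
#' inference for the slope, robust to extreme points. Pseudo-values are
#' \code{theta_i* = n * theta - (n - 1) * theta_(-i)} where \code{theta} is
#' the full-data OLS slope and \code{theta_(-i)} the slope with observation
#' i removed; the jackknife estimate is their mean and its standard error
#' \code{sd(pseudo) / sqrt(n)}. Significance uses \code{t = estimate / SE}
#' with \code{n - 1} degrees of freedom, one- or two-tailed per the stated
#' hypothesis direction.
#'
#' @param x,y Numeric vectors of equal length \code{n >= 4}; \code{x} must
#'   not be constant.
#' @param tail \code{"two.sided"}, \code{"positive"} (H1: slope > 0) or
#'   \code{"negative"} (H1: slope < 0).
#' @return Object of class \code{jackknife_regression}: OLS
#'   \code{slope}/\code{intercept}, jackknife \code{estimate} and \code{se},
#'   \code{t}, \code{p}, \code{tail}, \code{n}, plus the quantities needed
#'   for mean-response bands: residual SD \code{s}, \code{x_bar},
#'   \code{sxx}.
#' @seealso [predict_band()], [jackknife_correlation()]
#' @export
jackknife_regression <- function(x, y, tail = c("two.sided", "positive", "negative")) {
  tail <- match.arg(tail)
  check_xy(x, y, min_n = 4L)
  if (stats::sd(x) == 0) stop("predictor x is constant")
  n <- length(x)
  full <- ols_slope(x, y)
  loo <- vapply(seq_len(n), function(i) ols_slope(x[-i], y[-i])["slope"], numeric(1L))
  pseudo <- n * full["slope"] - (n - 1) * loo
  est <- mean(pseudo)
  se <- stats::sd(pseudo) / sqrt(n)
  tp <- t_tail_p(est, se, df = n - 1L, tail = tail)
  res <- y - full["intercept"] - full["slope"] * x
  structure(list(slope = unname(full["slope"]), intercept = unname(full["intercept"]),
                 estimate = unname(est), se = unname(se),
                 t = tp$t, p = tp$p, tail = tail, n = n,
                 s = sqrt(sum(res^2) / (n - 2)),
                 x_bar = mean(x), sxx = sum((x - mean(x))^2)),
            class = "jackknife_regression")
}

ols_slope <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  if (sxx == 0) stop("predictor x is constant in a jackknife subsample")
  b <- sum((x - xb) * (y - yb)) / sxx
  c(slope = b, intercept = yb - b * xb)
}

t_tail_p <- function(est, se, df, tail) {
  if (se == 0) {
    t <- if (est == 0) 0 else sign(est) * Inf
  } else {
    t <- est / se
  }
  p <- switch(tail,
              two.sided = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
              positive  = stats::pt(t, df, lower.tail = FALSE),
              negative  = stats::pt(t, df, lower.tail = TRUE))
  # keep p in (0, 1]: noiseless data gives t = +/-Inf and raw p = 0
  list(t = t, p = max(min(p, 1), .Machine$double.xmin))
}

#' Jackknife inference for a Pearson correlation
#'
#' Pearson correlation with delete-one jackknife pseudo-value estimate and
#' standard error, tested on \code{n - 1} degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length \code{n >= 4} with non-zero
#'   variance.
#' @inheritParams jackknife_regression
#' @return Object of class \code{jackknife_correlation}: \code{r} (full
#'   data), jackknife \code{estimate}, \code{se}, \code{t}, \code{p},
#'   \code{tail}, \code{n}.
#' @export
jackknife_correlation <- function(x, y, tail = c("two.sided", "positive", "negative")) {
  tail <- match.arg(tail)
  check_xy(x, y, min_n = 4L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in x or y")
  n <- length(x)
  r <- stats::cor(x, y)
  loo <- vapply(seq_len(n), function(i) stats::cor(x[-i], y[-i]), numeric(1L))
  if (anyNA(loo)) stop("zero variance in a jackknife subsample")
  pseudo <- n * r - (n - 1) * loo
  est <- mean(pseudo)
  se <- stats::sd(pseudo) / sqrt(n)
  tp <- t_tail_p(est, se, df = n - 1L, tail = tail)
  structure(list(r = r, estimate = unname(est), se = unname(se),
                 t = tp$t, p = tp$p, tail = tail, n = n),
            class = "jackknife_correlation")
}

check_xy <- function(x, y, min_n) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < min_n) stop("need at least ", min_n, " observations")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite with no missing values")
  invisible(TRUE)
}

#' @export
print.jackknife_regression <- function(x, ...) {
  cat(sprintf("Jackknife regression (n = %d): slope = %.4g (OLS), jackknife b = %.4g +/- %.4g, t = %.3g, p = %.4g [%s]\n",
              x$n, x$slope, x$estimate, x$se, x$t, x$p, x$tail))
  invisible(x)
}

#' @export
print.jackknife_correlation <- function(x, ...) {
  cat(sprintf("Jackknife correlation (n = %d): r = %.4g, jackknife r = %.4g +/- %.4g, t = %.3g, p = %.4g [%s]\n",
              x$n, x$r, x$estimate, x$se, x$t, x$p, x$tail))
  invisible(x)
}
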