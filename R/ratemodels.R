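.rateFit <- function(model, coefficients, se, rss, n) {
  methods::new("RateFit", model = model, coefficients = coefficients,
               se = se, rss = rss, n = as.integer(n),
               fStatistic = NA_real_, pValue = NA_real_, selected = NA)
}

.checkXY <- function(x, y, minN = 2L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) {
    keep <- !(is.na(x) | is.na(y))
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < minN) stop("need at least ", minN, " points")
  list(x = x, y = y)
}

#' Zero-intercept linear divergence model
#'
#' Least squares `y = b x` through the origin, the neutral-theory
#' expectation of divergence accumulating linearly with evolutionary
#' distance: `b = sum(xy) / sum(x^2)`.
#'
#' @param x evolutionary distances (substitutions/site).
#' @param y divergences (e.g. percent 16S divergence).
#' @return a [RateFit-class] with coefficient `b`.
#' @examples
#' fitLinearOrigin(c(1, 2), c(1, 3))  # b = 7/5
#' @export
fitLinearOrigin <- function(x, y) {
  d <- .checkXY(x, y, 2L)
  if (all(d$x == 0)) stop("x must not be all zero")
  sxx <- sum(d$x^2)
  b <- sum(d$x * d$y) / sxx
  res <- d$y - b * d$x
  rss <- sum(res^2)
  n <- length(d$x)
  se <- if (n > 1L) sqrt(rss / (n - 1L) / sxx) else NA_real_
  .rateFit("linear_origin", c(b = b), c(b = se), rss, n)
}

#' Zero-intercept quadratic divergence model
#'
#' Least squares `y = b1 x + b2 x^2` (no intercept) by QR. A negative `b2`
#' is the stasis signature: divergence flattens with distance.
#'
#' @inheritParams fitLinearOrigin
#' @return a [RateFit-class] with coefficients `b1`, `b2`.
#' @export
fitQuadraticOrigin <- function(x, y) {
  d <- .checkXY(x, y, 3L)
  X <- cbind(x = d$x, x2 = d$x^2)
  fit <- stats::lm.fit(X, d$y)
  if (fit$rank < 2L) stop("rank-deficient design (x values too degenerate)")
  rss <- sum(fit$residuals^2)
  n <- length(d$x)
  sigma2 <- rss / max(1L, n - 2L)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  co <- fit$coefficients
  names(co) <- names(se) <- c("b1", "b2")
  .rateFit("quadratic_origin", co, se, rss, n)
}

#' Fixed-scale logarithmic divergence model
#'
#' Least squares `y = a log(1 + x/s)` with the scale `s` fixed (default
#' 0.1), which makes the fit linear in `a` and hence closed-form. The
#' logarithmic shape captures substitution saturation: near-linear for
#' `x << s`-scale distances, flattening beyond.
#'
#' @inheritParams fitLinearOrigin
#' @param scale fixed saturation scale `s` (> 0).
#' @return a [RateFit-class] with coefficients `a` and (fixed) `scale`.
#' @export
fitLogarithmic <- function(x, y, scale = 0.1) {
  d <- .checkXY(x, y, 2L)
  if (any(d$x < 0)) stop("x must be >= 0")
  if (scale <= 0) stop("scale must be > 0")
  g <- log1p(d$x / scale)
  sgg <- sum(g^2)
  if (sgg == 0) stop("x must not be all zero")
  a <- sum(d$y * g) / sgg
  rss <- sum((d$y - a * g)^2)
  n <- length(d$x)
  se <- if (n > 1L) sqrt(rss / (n - 1L) / sgg) else NA_real_
  .rateFit("logarithmic", c(a = a, scale = scale), c(a = se, scale = 0),
           rss, n)
}

#' F-test selection between nested origin-constrained models
#'
#' The quadratic model is preferred only where it fits significantly better
#' than the linear one: `F = (rss_lin - rss_quad) / (rss_quad / (n - 2))`
#' with 1 and n-2 degrees of freedom, selected iff `p < alpha`. A perfectly
#' interpolating quadratic (`rss_quad = 0`) is selected only if the linear
#' model does not also interpolate.
#'
#' @param linear a `linear_origin` [RateFit-class].
#' @param quadratic a `quadratic_origin` [RateFit-class] on the same data.
#' @param alpha significance level.
#' @return the selected [RateFit-class], with `fStatistic`, `pValue` and
#'   `selected` filled on both the returned fit.
#' @export
selectModel <- function(linear, quadratic, alpha = 0.05) {
  stopifnot(methods::is(linear, "RateFit"), methods::is(quadratic, "RateFit"))
  if (linear@model != "linear_origin" ||
      quadratic@model != "quadratic_origin")
    stop("selectModel expects a linear_origin and a quadratic_origin fit")
  if (linear@n != quadratic@n) stop("fits are not on the same data (n differs)")
  n <- linear@n
  if (n < 3L) stop("need n >= 3 for the nested comparison")
  rssL <- linear@rss; rssQ <- quadratic@rss
  if (rssQ > rssL + 1e-9 * max(1, rssL))
    stop("quadratic rss exceeds linear rss; fits are not nested on one dataset")
  if (rssQ <= .Machine$double.eps * max(1, rssL)) {
    if (rssL <= .Machine$double.eps) {
      f <- 0; p <- 1  # both interpolate: keep the parsimonious model
    } else {
      f <- Inf; p <- 0
    }
  } else {
    f <- max(0, (rssL - rssQ)) / (rssQ / (n - 2L))
    p <- stats::pf(f, 1L, n - 2L, lower.tail = FALSE)
  }
  pick <- if (p < alpha) quadratic else linear
  pick@fStatistic <- f
  pick@pValue <- p
  pick@selected <- TRUE
  pick
}

#' Ratio of two origin-constrained slopes
#'
#' `b_a / b_b` with a delta-method standard error, used e.g. to recover the
#' mitochondrial/nuclear rate ratio from the vertebrate-mode fits.
#'
#' @param fitA,fitB `linear_origin` [RateFit-class] objects.
#' @return list with `ratio` and `se`.
#' @export
slopeRatio <- function(fitA, fitB) {
  stopifnot(methods::is(fitA, "RateFit"), methods::is(fitB, "RateFit"))
  if (fitA@model != "linear_origin" || fitB@model != "linear_origin")
    stop("slopeRatio expects two linear_origin fits")
  ba <- fitA@coefficients[["b"]]; bb <- fitB@coefficients[["b"]]
  if (bb == 0) stop("denominator slope is zero")
  ratio <- ba / bb
  sa <- fitA@se[["b"]]; sb <- fitB@se[["b"]]
  se <- abs(ratio) * sqrt((sa / ba)^2 + (sb / bb)^2)
  list(ratio = ratio, se = se)
}
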