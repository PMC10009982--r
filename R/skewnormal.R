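#' Skew-normal parameter set
#'
#' Bundles the three parameters of the skew-normal (SN) distribution: the
#' location \eqn{\varphi}, the scale \eqn{\omega > 0} and the shape
#' \eqn{\lambda}. The density is
#' \deqn{f(x) = \frac{2}{\omega}\,\phi\!\left(\frac{x-\varphi}{\omega}\right)
#'   \Phi\!\left(\lambda\frac{x-\varphi}{\omega}\right),}
#' where \eqn{\phi} and \eqn{\Phi} are the standard normal density and
#' distribution function. \code{shape = 0} recovers the normal distribution
#' with mean \code{location} and standard deviation \code{scale};
#' \code{shape > 0} gives right skew.
#'
#' @param location real location parameter (covariate units).
#' @param scale strictly positive scale parameter (covariate units).
#' @param shape real shape (skewness) parameter, dimensionless.
#' @return An object of class \code{"sn_params"}: a named list with
#'   components \code{location}, \code{scale}, \code{shape}.
#' @examples
#' p <- sn_params(0, 1, 5)
#' sn_mean(p)
#' sn_variance(p)
#' @export
sn_params <- function(location = 0, scale = 1, shape = 0) {
  if (!is.numeric(location) || length(location) != 1L || !is.finite(location))
    stop("'location' must be a single finite number", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0)
    stop("'scale' must be a single strictly positive number", call. = FALSE)
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape))
    stop("'shape' must be a single finite number", call. = FALSE)
  structure(list(location = location, scale = scale, shape = shape),
            class = "sn_params")
}

#' @export
print.sn_params <- function(x, ...) {
  cat(sprintf("Skew-normal parameters: location %g, scale %g, shape %g\n",
              x$location, x$scale, x$shape))
  invisible(x)
}

as_sn_params <- function(params) {
  if (inherits(params, "sn_params")) return(params)
  if (is.numeric(params) && length(params) == 3L)
    return(sn_params(params[[1L]], params[[2L]], params[[3L]]))
  stop("'params' must be an sn_params object or a numeric triple ",
       "(location, scale, shape)", call. = FALSE)
}

# delta = lambda / sqrt(1 + lambda^2); E(X) for the standard SN is
# delta * sqrt(2/pi), signed with lambda.
sn_delta <- function(shape) shape / sqrt(1 + shape^2)

#' Owen's T function
#'
#' \eqn{T(h, a) = \frac{1}{2\pi}\int_0^a
#'   \frac{e^{-h^2(1+t^2)/2}}{1+t^2}\,dt}, evaluated by adaptive quadrature
#' of the defining integrand. Used for the skew-normal distribution function
#' through the identity \eqn{F(x;\lambda) = \Phi(x) - 2T(x,\lambda)}.
#'
#' @param h real; vectorized.
#' @param a real; recycled against \code{h}.
#' @return Values of \eqn{T(h,a)}; odd in \code{a}, even in \code{h}.
#' @export
owens_t <- function(h, a) {
  n <- max(length(h), length(a))
  h <- rep_len(h, n)
  a <- rep_len(a, n)
  vapply(seq_len(n), function(i) owens_t1(h[[i]], a[[i]]), numeric(1))
}

owens_t1 <- function(h, a) {
  if (a == 0 || (!is.finite(h) && abs(h) == Inf)) return(0)
  if (!is.finite(a)) {
    # T(h, +/-Inf) = sign(a) * (1 - Phi(|h|)) / 2
    return(sign(a) * pnorm(abs(h), lower.tail = FALSE) / 2)
  }
  if (abs(a) > 1) {
    # reduce to |a| <= 1 where the quadrature is best conditioned:
    # T(h,a) = Phi(h)/2 + Phi(ah)/2 - Phi(h)Phi(ah) - T(ah, 1/a), a > 0
    s <- sign(a); a <- abs(a)
    return(s * (pnorm(h) / 2 + pnorm(a * h) / 2 - pnorm(h) * pnorm(a * h) -
                  owens_t1(a * h, 1 / a)))
  }
  stats::integrate(function(t) exp(-h^2 * (1 + t^2) / 2) / (1 + t^2),
                   0, a, rel.tol = 1e-13, abs.tol = 1e-15,
                   subdivisions = 500L)$value / (2 * pi)
}

#' Skew-normal density
#'
#' @param x numeric vector of evaluation points.
#' @param params an [sn_params] object (or numeric triple).
#' @return Densities, nonnegative; the density integrates to one.
#' @examples
#' sn_pdf(0, sn_params(0, 1, 0))  # 1/sqrt(2*pi)
#' @export
sn_pdf <- function(x, params) {
  params <- as_sn_params(params)
  z <- (x - params$location) / params$scale
  2 / params$scale * dnorm(z) * pnorm(params$shape * z)
}

#' Skew-normal distribution function
#'
#' Computed through Owen's T function:
#' \eqn{F(x;\lambda) = \Phi(x) - 2T(x,\lambda)} in standardized units.
#'
#' @inheritParams sn_pdf
#' @return Probabilities in \eqn{[0,1]}, monotone in \code{x}.
#' @examples
#' sn_cdf(0, sn_params(0, 1, 1))  # 1/2 - atan(1)/pi = 0.25
#' @export
sn_cdf <- function(x, params) {
  params <- as_sn_params(params)
  z <- (x - params$location) / params$scale
  p <- pnorm(z) - 2 * owens_t(z, params$shape)
  pmin(pmax(p, 0), 1)
}

#' Skew-normal quantile function
#'
#' No closed form exists; the monotone distribution function is inverted by
#' bracketed root-finding, with the bracket initialized from the normal
#' quantile shifted by the skew-normal mean.
#'
#' @param p probabilities strictly inside (0, 1); vectorized.
#' @param params an [sn_params] object.
#' @return Quantiles such that \code{sn_cdf(sn_quantile(p)) == p} to within
#'   1e-9 in probability.
#' @export
sn_quantile <- function(p, params) {
  params <- as_sn_params(params)
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  std <- sn_params(0, 1, params$shape)
  mu <- sn_delta(params$shape) * sqrt(2 / pi)
  q <- vapply(p, function(pi) {
    lo <- qnorm(pi) + mu - 1
    hi <- qnorm(pi) + mu + 1
    uniroot(function(q) sn_cdf(q, std) - pi, c(lo, hi),
            extendInt = "upX", tol = 1e-12, maxiter = 200L)$root
  }, numeric(1))
  params$location + params$scale * q
}

#' Skew-normal mean
#'
#' \eqn{E(X) = \varphi + \omega\,\delta\sqrt{2/\pi}} with
#' \eqn{\delta = \lambda/\sqrt{1+\lambda^2}}; carries the sign of the shape.
#'
#' @inheritParams sn_pdf
#' @export
sn_mean <- function(params) {
  params <- as_sn_params(params)
  params$location + params$scale * sn_delta(params$shape) * sqrt(2 / pi)
}

#' Skew-normal variance
#'
#' \eqn{\sigma_x^2 = \omega^2\bigl(1 - 2\lambda^2/(\pi(1+\lambda^2))\bigr)}.
#'
#' @inheritParams sn_pdf
#' @export
sn_variance <- function(params) {
  params <- as_sn_params(params)
  l2 <- params$shape^2
  params$scale^2 * (1 - 2 * l2 / (pi * (1 + l2)))
}

#' Mean of a truncated skew-normal variable
#'
#' Expected value of \eqn{X} conditional on \code{lower < X < upper}. For
#' the standard case the closed form is
#' \deqn{E(X \mid a < X < b) = -\frac{f(b)-f(a)}{F(b)-F(a)} +
#'   \delta\sqrt{2/\pi}\,
#'   \frac{\Phi(b\sqrt{1+\lambda^2})-\Phi(a\sqrt{1+\lambda^2})}{F(b)-F(a)},}
#' with \eqn{f}, \eqn{F} the standard skew-normal density and distribution
#' function and \eqn{\delta = \lambda/\sqrt{1+\lambda^2}}; the general case
#' follows by the location--scale transform. Infinite bounds use
#' \eqn{f(\pm\infty)=0}, \eqn{F(-\infty)=0}, \eqn{F(\infty)=1}.
#'
#' @inheritParams sn_pdf
#' @param lower lower truncation point; \code{-Inf} for no lower bound.
#' @param upper upper truncation point; \code{Inf} for no upper bound.
#' @return The conditional mean, strictly inside \code{(lower, upper)}.
#' @examples
#' sn_truncated_mean(sn_params(0, 1, 0), upper = 0)  # -sqrt(2/pi)
#' @export
sn_truncated_mean <- function(params, lower = -Inf, upper = Inf) {
  params <- as_sn_params(params)
  if (!is.numeric(lower) || !is.numeric(upper) || length(lower) != 1L ||
      length(upper) != 1L || is.na(lower) || is.na(upper))
    stop("'lower' and 'upper' must be single numbers (possibly infinite)",
         call. = FALSE)
  if (lower >= upper)
    stop("'lower' must be strictly less than 'upper'", call. = FALSE)
  a <- (lower - params$location) / params$scale
  b <- (upper - params$location) / params$scale
  std <- sn_params(0, 1, params$shape)
  Fa <- if (is.finite(a)) sn_cdf(a, std) else 0
  Fb <- if (is.finite(b)) sn_cdf(b, std) else 1
  mass <- Fb - Fa
  if (mass <= 1e-14)
    stop("truncation interval carries (numerically) zero probability mass",
         call. = FALSE)
  fa <- if (is.finite(a)) sn_pdf(a, std) else 0
  fb <- if (is.finite(b)) sn_pdf(b, std) else 0
  w <- sqrt(1 + params$shape^2)
  Pa <- if (is.finite(a)) pnorm(a * w) else 0
  Pb <- if (is.finite(b)) pnorm(b * w) else 1
  m <- -(fb - fa) / mass +
    sn_delta(params$shape) * sqrt(2 / pi) * (Pb - Pa) / mass
  params$location + params$scale * m
}

#' Draw skew-normal random samples
#'
#' Uses the conditioning representation: with \eqn{Z_0, Z_1} independent
#' standard normals and \eqn{\delta = \lambda/\sqrt{1+\lambda^2}},
#' \eqn{X = \delta|Z_0| + \sqrt{1-\delta^2}\,Z_1} is standard skew-normal
#' with shape \eqn{\lambda}. A seed is required so that every simulation is
#' reproducible; the caller's RNG state is left untouched.
#'
#' @inheritParams sn_pdf
#' @param n number of draws, at least 1.
#' @param seed integer seed.
#' @return Numeric vector of \code{n} draws.
#' @export
sn_sample <- function(params, n, seed) {
  params <- as_sn_params(params)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a positive count", call. = FALSE)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be supplied as a single integer", call. = FALSE)
  n <- as.integer(n)
  d <- sn_delta(params$shape)
  with_seed(seed, {
    z0 <- rnorm(n)
    z1 <- rnorm(n)
    params$location + params$scale * (d * abs(z0) + sqrt(1 - d^2) * z1)
  })
}

# Evaluate expr under a given seed, then restore the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
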