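#' Trial design for a two-arm randomized study
#'
#' Describes the data-generating model
#' \eqn{y = \alpha + \gamma z + \beta x + \varepsilon},
#' \eqn{\varepsilon \sim N(0, \sigma_\varepsilon)}, with a 1:1 allocation
#' (\code{n_total/2} participants per arm) and a baseline covariate \eqn{x}.
#'
#' @param n_total total sample size; must be even and at least 4.
#' @param gamma treatment effect \eqn{\gamma} (outcome units).
#' @param beta covariate slope \eqn{\beta} (outcome units per covariate unit).
#' @param sigma_eps residual standard deviation \eqn{\sigma_\varepsilon > 0}.
#' @param intercept model intercept \eqn{\alpha} (outcome units).
#' @return An object of class \code{"trial_design"}.
#' @examples
#' trial_design(n_total = 200, gamma = 15, beta = 20, sigma_eps = 30)
#' @export
trial_design <- function(n_total, gamma, beta, sigma_eps, intercept = 0) {
  if (!is.numeric(n_total) || length(n_total) != 1L || is.na(n_total) ||
      n_total < 4 || n_total %% 2 != 0)
    stop("'n_total' must be an even count of at least 4 (1:1 allocation)",
         call. = FALSE)
  if (!is.numeric(sigma_eps) || length(sigma_eps) != 1L ||
      !is.finite(sigma_eps) || sigma_eps <= 0)
    stop("'sigma_eps' must be a single strictly positive number",
         call. = FALSE)
  for (nm in c("gamma", "beta", "intercept")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  structure(list(n_total = as.integer(n_total), gamma = gamma, beta = beta,
                 sigma_eps = sigma_eps, intercept = intercept),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf(
    "Two-arm trial design: n = %d (%d per arm), gamma = %g, beta = %g, sigma_eps = %g\n",
    x$n_total, x$n_total %/% 2L, x$gamma, x$beta, x$sigma_eps))
  invisible(x)
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau))
    stop("'tau' must be a single probability", call. = FALSE)
  if (tau < 1e-6 || tau > 1 - 1e-6)
    stop("'tau' must lie in [1e-6, 1 - 1e-6]: the tau(1-tau) division is ",
         "numerically unstable outside this range", call. = FALSE)
  tau
}

#' Dichotomization specification for a skew-normal covariate
#'
#' Resolves a dichotomization percentile \eqn{\tau} into the threshold value
#' \eqn{u = F^{-1}(\tau)} and the conditional means of the covariate below
#' and above it (\eqn{u_-}, \eqn{u_+}). Replacing the covariate by
#' \eqn{u_-}/\eqn{u_+} (or, equivalently for regression, a 0/1 indicator)
#' is the dichotomized coding whose variance enters the partially restricted
#' model.
#'
#' @param cov covariate distribution, an [sn_params] object.
#' @param tau dichotomization percentile in (0, 1).
#' @return An object of class \code{"dichot_spec"} with fields \code{tau},
#'   \code{u}, \code{u_minus}, \code{u_plus}.
#' @export
dichot_spec <- function(cov, tau) {
  cov <- as_sn_params(cov)
  check_tau(tau)
  u <- sn_quantile(tau, cov)
  structure(list(tau = tau, u = u,
                 u_minus = sn_truncated_mean(cov, upper = u),
                 u_plus = sn_truncated_mean(cov, lower = u)),
            class = "dichot_spec")
}

#' @export
print.dichot_spec <- function(x, ...) {
  cat(sprintf(
    "Dichotomization at tau = %g: threshold %.6g, group means %.6g / %.6g\n",
    x$tau, x$u, x$u_minus, x$u_plus))
  invisible(x)
}

#' Variance of the treatment-effect estimator, full model
#'
#' Under the full model (raw covariate included) and 1:1 allocation,
#' \eqn{V(\hat\gamma; m_f) = 4\sigma_\varepsilon^2 / n}.
#'
#' @param design a [trial_design] object.
#' @export
var_gamma_full <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  4 * design$sigma_eps^2 / design$n_total
}

#' Variance of the treatment-effect estimator, restricted model
#'
#' With the covariate omitted, its variance component \eqn{\beta^2\sigma_x^2}
#' is absorbed into the residual:
#' \eqn{V(\hat\gamma; m_r) = 4(\sigma_\varepsilon^2 + \beta^2\sigma_x^2)/n}.
#'
#' @inheritParams var_gamma_full
#' @param cov covariate distribution, an [sn_params] object.
#' @export
var_gamma_restricted <- function(design, cov) {
  stopifnot(inherits(design, "trial_design"))
  cov <- as_sn_params(cov)
  4 * (design$sigma_eps^2 + design$beta^2 * sn_variance(cov)) / design$n_total
}

#' Variance of the dichotomized covariate
#'
#' Variance of the two-point variable \eqn{x_d} that takes the conditional
#' mean below/above the threshold at percentile \eqn{\tau}:
#' \deqn{V(x_d) = \frac{\omega^2}{\tau(1-\tau)}\Bigl(f(F^{-1}(\tau)) +
#'   \delta\sqrt{2/\pi}\,\bigl(\tau -
#'   \Phi(F^{-1}(\tau)\sqrt{1+\lambda^2})\bigr)\Bigr)^2,}
#' in terms of the standard skew-normal density \eqn{f} and distribution
#' function \eqn{F}, with \eqn{\delta = \lambda/\sqrt{1+\lambda^2}}. Always
#' positive and at most the covariate variance.
#'
#' @inheritParams var_gamma_restricted
#' @param tau dichotomization percentile in (0, 1).
#' @export
var_xd <- function(cov, tau) {
  cov <- as_sn_params(cov)
  check_tau(tau)
  l <- cov$shape
  std <- sn_params(0, 1, l)
  u <- sn_quantile(tau, std)
  term <- sn_pdf(u, std) +
    sn_delta(l) * sqrt(2 / pi) * (tau - pnorm(u * sqrt(1 + l^2)))
  cov$scale^2 * term^2 / (tau * (1 - tau))
}

#' Variance of the treatment-effect estimator, partially restricted model
#'
#' With the covariate dichotomized at percentile \eqn{\tau}, only the
#' residual variance component \eqn{\beta^2(V(x) - V(x_d))} is absorbed:
#' \eqn{V(\hat\gamma; m_p) =
#'   4(\sigma_\varepsilon^2 + \beta^2(V(x) - V(x_d)))/n}.
#'
#' @inheritParams var_gamma_restricted
#' @param tau dichotomization percentile in (0, 1).
#' @export
var_gamma_partial <- function(design, cov, tau) {
  stopifnot(inherits(design, "trial_design"))
  cov <- as_sn_params(cov)
  4 * (design$sigma_eps^2 +
         design$beta^2 * (sn_variance(cov) - var_xd(cov, tau))) /
    design$n_total
}

#' Variance reductions from covariate adjustment
#'
#' The precision gains of the full and the partially restricted model over
#' the unadjusted model:
#' \code{reduction_full} \eqn{= V(\hat\gamma;m_r) - V(\hat\gamma;m_f)
#'   = 4\beta^2\sigma_x^2/n} and
#' \code{reduction_partial} \eqn{= V(\hat\gamma;m_r) - V(\hat\gamma;m_p)
#'   = 4\beta^2 V(x_d)/n}. Their ratio is the dichotomization efficiency.
#'
#' @inheritParams var_gamma_partial
#' @return Named list with \code{reduction_full} and \code{reduction_partial}.
#' @export
variance_reductions <- function(design, cov, tau) {
  stopifnot(inherits(design, "trial_design"))
  cov <- as_sn_params(cov)
  k <- 4 * design$beta^2 / design$n_total
  list(reduction_full = k * sn_variance(cov),
       reduction_partial = k * var_xd(cov, tau))
}

#' Dichotomization efficiency D
#'
#' The fraction of the full-adjustment precision gain that is retained when
#' the skew-normal covariate is dichotomized at percentile \eqn{\tau}:
#' \deqn{D = \frac{V(\hat\gamma;m_r) - V(\hat\gamma;m_p)}
#'                {V(\hat\gamma;m_r) - V(\hat\gamma;m_f)}
#'         = \frac{V(x_d)}{\sigma_x^2}.}
#' D depends only on the shape \eqn{\lambda} and on \eqn{\tau} — location and
#' scale cancel exactly — and lies strictly between 0 and 1 for interior
#' \eqn{\tau}. For a normal covariate (\eqn{\lambda = 0}) at the median,
#' \eqn{D = 2/\pi \approx 0.637}.
#'
#' @param shape skew-normal shape parameter \eqn{\lambda}.
#' @param tau dichotomization percentile in (0, 1); vectorized.
#' @return Efficiencies in (0, 1), one per \code{tau}.
#' @examples
#' dichotomization_efficiency(0, 0.5)   # 2/pi
#' dichotomization_efficiency(5, c(0.5, 2/3))
#' @export
dichotomization_efficiency <- function(shape, tau) {
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape))
    stop("'shape' must be a single finite number", call. = FALSE)
  vapply(tau, function(t) {
    check_tau(t)
    std <- sn_params(0, 1, shape)
    var_xd(std, t) / sn_variance(std)
  }, numeric(1))
}

#' Dichotomization efficiency for a fully specified covariate
#'
#' Convenience wrapper around [dichotomization_efficiency()] that accepts a
#' full parameter set; the location and scale are ignored because D is
#' mathematically invariant to them.
#'
#' @param cov covariate distribution, an [sn_params] object.
#' @param tau dichotomization percentile in (0, 1); vectorized.
#' @export
dichotomization_efficiency_sn <- function(cov, tau) {
  cov <- as_sn_params(cov)
  dichotomization_efficiency(cov$shape, tau)
}

#' Closed-form variance summary for a dichotomized-covariate analysis
#'
#' Assembles the three model variances of \eqn{\hat\gamma}, the two variance
#' reductions, and the dichotomization efficiency for one design, covariate
#' distribution and threshold percentile.
#'
#' @inheritParams var_gamma_partial
#' @return An object of class \code{"efficiency_result"}: list with
#'   \code{var_full}, \code{var_partial}, \code{var_restricted},
#'   \code{reduction_full}, \code{reduction_partial} and \code{D}.
#' @examples
#' d <- trial_design(200, gamma = 15, beta = 20, sigma_eps = 30)
#' efficiency_summary(d, sn_params(0, 1, 2), tau = 0.5)
#' @export
efficiency_summary <- function(design, cov, tau) {
  cov <- as_sn_params(cov)
  red <- variance_reductions(design, cov, tau)
  structure(list(var_full = var_gamma_full(design),
                 var_partial = var_gamma_partial(design, cov, tau),
                 var_restricted = var_gamma_restricted(design, cov),
                 reduction_full = red$reduction_full,
                 reduction_partial = red$reduction_partial,
                 D = dichotomization_efficiency(cov$shape, tau),
                 tau = tau, shape = cov$shape),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("Treatment-effect estimator variances (shape %g, tau %g):\n",
              x$shape, x$tau))
  cat(sprintf("  full %.6g | dichotomized %.6g | unadjusted %.6g\n",
              x$var_full, x$var_partial, x$var_restricted))
  cat(sprintf("  dichotomization efficiency D = %.4f\n", x$D))
  invisible(x)
}

#' Dichotomization efficiency curve over a grid of percentiles
#'
#' @param shape skew-normal shape parameter \eqn{\lambda}.
#' @param tau_grid strictly increasing percentiles in (0, 1); defaults to
#'   0.01, 0.02, ..., 0.99.
#' @return A data frame with columns \code{shape}, \code{tau}, \code{D}.
#' @examples
#' head(efficiency_curve(5, seq(0.1, 0.9, by = 0.1)))
#' @export
efficiency_curve <- function(shape, tau_grid = seq(0.01, 0.99, by = 0.01)) {
  if (length(tau_grid) < 1L || any(diff(tau_grid) <= 0))
    stop("'tau_grid' must be non-empty and strictly increasing",
         call. = FALSE)
  data.frame(shape = shape, tau = tau_grid,
             D = dichotomization_efficiency(shape, tau_grid))
}
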