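# Quadrature oracles, independent of the closed forms under test: every
# quantity is rebuilt from numerical integration of the density formula.

quad_sn_cdf <- function(x, params) {
  integrate(function(t) sn_pdf(t, params), -Inf, x,
            rel.tol = 1e-12, abs.tol = 1e-14)$value
}

quad_sn_mean <- function(params) {
  integrate(function(t) t * sn_pdf(t, params), -Inf, Inf,
            rel.tol = 1e-12, abs.tol = 1e-14)$value
}

quad_sn_variance <- function(params) {
  m <- quad_sn_mean(params)
  integrate(function(t) (t - m)^2 * sn_pdf(t, params), -Inf, Inf,
            rel.tol = 1e-12, abs.tol = 1e-14)$value
}

quad_truncated_mean <- function(params, lower = -Inf, upper = Inf) {
  mass <- integrate(function(t) sn_pdf(t, params), lower, upper,
                    rel.tol = 1e-12, abs.tol = 1e-14)$value
  integrate(function(t) t * sn_pdf(t, params), lower, upper,
            rel.tol = 1e-12, abs.tol = 1e-14)$value / mass
}

# Dichotomization efficiency rebuilt entirely from truncated means and the
# covariate variance (two-point-variable route), bypassing the closed form.
twopoint_efficiency <- function(params, tau) {
  u <- sn_quantile(tau, params)
  mu <- sn_mean(params)
  lo <- sn_truncated_mean(params, upper = u)
  hi <- sn_truncated_mean(params, lower = u)
  (tau * (lo - mu)^2 + (1 - tau) * (hi - mu)^2) / sn_variance(params)
}
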