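#' Simulate one randomized-trial dataset
#'
#' Generates a two-arm trial under the linear model
#' \eqn{y = \alpha + \gamma z + \beta x + \varepsilon} with a skew-normal
#' baseline covariate \eqn{x} and normal residuals. Allocation is exactly
#' balanced: the first \code{n/2} participants receive standard care
#' (\code{arm = 0}), the rest the intervention (\code{arm = 1}), matching
#' the 1:1 design for which \eqn{S_{zz} = n/4}.
#'
#' @param design a [trial_design] object.
#' @param cov covariate distribution, an [sn_params] object.
#' @param seed integer seed; the same seed reproduces the same dataset.
#' @return A data frame with columns \code{arm}, \code{covariate},
#'   \code{outcome}, one row per participant.
#' @examples
#' d <- trial_design(200, gamma = 15, beta = 20, sigma_eps = 30)
#' head(generate_trial(d, sn_params(0, 1, 2), seed = 1))
#' @export
generate_trial <- function(design, cov, seed) {
  stopifnot(inherits(design, "trial_design"))
  cov <- as_sn_params(cov)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be supplied as a single integer", call. = FALSE)
  n <- design$n_total
  arm <- rep(c(0L, 1L), each = n %/% 2L)
  with_seed(seed, {
    d <- sn_delta(cov$shape)
    z0 <- rnorm(n)
    z1 <- rnorm(n)
    x <- cov$location + cov$scale * (d * abs(z0) + sqrt(1 - d^2) * z1)
    eps <- rnorm(n, sd = design$sigma_eps)
    data.frame(arm = arm, covariate = x,
               outcome = design$intercept + design$gamma * arm +
                 design$beta * x + eps)
  })
}

#' Model-based variances of the treatment coefficient under three models
#'
#' Fits by ordinary least squares (i) the full model with the raw covariate,
#' (ii) the restricted model with the covariate omitted, and (iii) the
#' partially restricted model with the covariate dichotomized at the
#' population quantile \eqn{u = F^{-1}(\tau)} of its skew-normal
#' distribution, coded as a 0/1 indicator (affine-equivalent to the
#' conditional-means coding, so the fit and the treatment coefficient's
#' standard error are identical). Each returned value is the squared
#' standard error of the treatment coefficient.
#'
#' @param data a dataset from [generate_trial()] (columns \code{arm},
#'   \code{covariate}, \code{outcome}).
#' @param cov covariate distribution used to locate the threshold.
#' @param tau dichotomization percentile in (0, 1).
#' @return Named numeric vector \code{c(v_full, v_restricted, v_partial)}.
#' @export
fit_three_models <- function(data, cov, tau) {
  if (!is.data.frame(data) ||
      !all(c("arm", "covariate", "outcome") %in% names(data)))
    stop("'data' must have columns arm, covariate, outcome", call. = FALSE)
  cov <- as_sn_params(cov)
  check_tau(tau)
  u <- sn_quantile(tau, cov)
  high <- as.integer(data$covariate > u)
  if (all(high == 0L) || all(high == 1L))
    stop(sprintf(
      "all covariate values fall on one side of the threshold %.4g; ",
      u), "the dichotomized model is not identifiable", call. = FALSE)
  df <- data.frame(arm = data$arm, covariate = data$covariate,
                   outcome = data$outcome, high = high)
  v_of <- function(fit) summary(fit)$coefficients["arm", "Std. Error"]^2
  c(v_full = v_of(lm(outcome ~ arm + covariate, data = df)),
    v_restricted = v_of(lm(outcome ~ arm, data = df)),
    v_partial = v_of(lm(outcome ~ arm + high, data = df)))
}

# Per-replicate seeds are derived from the master seed by a fixed rule so
# any subset of replicates is independently reproducible.
replicate_seed <- function(seed, rep) as.integer(seed) + as.integer(rep)

#' Regression-slope estimate of the dichotomization efficiency
#'
#' Runs \code{n_reps} simulated trials, extracts the model-based variances
#' of the treatment coefficient under the three models, and estimates D as
#' the slope of the regression of the partial-adjustment variance reduction
#' \eqn{V(\hat\gamma;m_r) - V(\hat\gamma;m_p)} on the full-adjustment
#' reduction \eqn{V(\hat\gamma;m_r) - V(\hat\gamma;m_f)} across replicates.
#' The ratio of the two reductions has a random denominator, so replicates
#' with small denominators would inflate the variance of a direct ratio
#' estimate; the regression slope avoids that. The 95\% confidence interval
#' comes from the slope's t-based standard error.
#'
#' @inheritParams generate_trial
#' @param tau dichotomization percentile in (0, 1).
#' @param n_reps number of replicate trials (at least 2; 50+ recommended).
#' @param seed master seed; replicate \code{r} uses \code{seed + r}.
#' @param intercept fit the slope regression with an intercept
#'   (default \code{TRUE}).
#' @return A list of class \code{"sim_estimate"} with \code{tau},
#'   \code{D_hat}, \code{ci_low}, \code{ci_high}, \code{n_reps},
#'   \code{intercept}.
#' @export
empirical_efficiency <- function(design, cov, tau, n_reps = 500L, seed,
                                 intercept = TRUE) {
  stopifnot(inherits(design, "trial_design"))
  cov <- as_sn_params(cov)
  if (!is.numeric(n_reps) || length(n_reps) != 1L || is.na(n_reps) ||
      n_reps < 2)
    stop("'n_reps' must be at least 2", call. = FALSE)
  if (design$beta == 0)
    stop("beta = 0: both variance reductions are pure noise and the slope ",
         "regression is degenerate", call. = FALSE)
  n_reps <- as.integer(n_reps)
  v <- vapply(seq_len(n_reps), function(r) {
    dat <- generate_trial(design, cov, seed = replicate_seed(seed, r))
    fit_three_models(dat, cov, tau)
  }, numeric(3))
  dx <- v["v_restricted", ] - v["v_full", ]
  dy <- v["v_restricted", ] - v["v_partial", ]
  fit <- if (intercept) lm(dy ~ dx) else lm(dy ~ dx + 0)
  est <- summary(fit)$coefficients["dx", , drop = FALSE]
  # with no residual degrees of freedom the CI is undefined, not NaN noise
  halfw <- if (fit$df.residual >= 1)
    qt(0.975, df = fit$df.residual) * est[, "Std. Error"]
  else NA_real_
  structure(list(tau = tau, D_hat = unname(est[, "Estimate"]),
                 ci_low = unname(est[, "Estimate"] - halfw),
                 ci_high = unname(est[, "Estimate"] + halfw),
                 n_reps = n_reps, intercept = intercept),
            class = "sim_estimate")
}

#' @export
print.sim_estimate <- function(x, ...) {
  cat(sprintf(
    "Empirical dichotomization efficiency at tau = %g: %.4f (95%% CI %.4f to %.4f), %d replicates\n",
    x$tau, x$D_hat, x$ci_low, x$ci_high, x$n_reps))
  invisible(x)
}

#' Monte-Carlo corroboration study over shapes and percentiles
#'
#' For every combination of covariate shape and dichotomization percentile,
#' estimates D by the regression-slope method and tabulates it next to the
#' closed-form value, with a coverage summary (fraction of 95\% confidence
#' intervals containing the analytic value). Each cell uses its own block of
#' replicate seeds derived deterministically from the master seed, so the
#' whole table is reproducible bit for bit.
#'
#' @inheritParams empirical_efficiency
#' @param shapes numeric vector of shape parameters.
#' @param tau_grid percentiles in (0, 1).
#' @return A data frame, one row per (shape, tau): columns \code{shape},
#'   \code{tau}, \code{D_analytic}, \code{D_hat}, \code{ci_low},
#'   \code{ci_high}, \code{covered}, \code{n_reps}, \code{seed}; attribute
#'   \code{coverage} holds the overall coverage fraction.
#' @examples
#' \donttest{
#' d <- trial_design(200, gamma = 15, beta = 20, sigma_eps = 30)
#' s <- simulation_study(d, shapes = 2, tau_grid = c(0.3, 0.5, 0.7),
#'                       n_reps = 100, seed = 1)
#' attr(s, "coverage")
#' }
#' @export
simulation_study <- function(design, cov_location = 0, cov_scale = 1,
                             shapes = c(2, 10),
                             tau_grid = seq(0.1, 0.9, by = 0.1),
                             n_reps = 500L, seed, intercept = TRUE) {
  cells <- expand.grid(tau = tau_grid, shape = shapes,
                       KEEP.OUT.ATTRS = FALSE)[, c("shape", "tau")]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    l <- cells$shape[i]; t <- cells$tau[i]
    cell_seed <- as.integer(seed) + (i - 1L) * (as.integer(n_reps) + 1L)
    est <- empirical_efficiency(design, sn_params(cov_location, cov_scale, l),
                                t, n_reps = n_reps, seed = cell_seed,
                                intercept = intercept)
    d_an <- dichotomization_efficiency(l, t)
    data.frame(shape = l, tau = t, D_analytic = d_an, D_hat = est$D_hat,
               ci_low = est$ci_low, ci_high = est$ci_high,
               covered = est$ci_low <= d_an & d_an <= est$ci_high,
               n_reps = est$n_reps, seed = cell_seed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "coverage") <- mean(out$covered)
  attr(out, "intercept") <- intercept
  out
}
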