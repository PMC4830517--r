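# Shared fixtures; expensive fits are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Hand-built 3-subject cohort (2 with records, 1 baseline-only).
toy_cohort <- function() {
  claims_cohort(
    subjects = data.frame(id = c("a", "b", "c"), sex = c(0, 1, 1),
                          age0 = c(70, 80, 90), T_obs = c(5, 3, 0.4),
                          delta = c(0, 1, 0)),
    records = data.frame(id = c("a", "a", "b", "b"), t = c(0, 1, 0, 2),
                         count = c(0, 2, 1, 5)))
}

# Small simulated cohort under default (portfolio-like) conditions.
small_cohort <- function(n = 60, seed = 421, ...) {
  memo(sprintf("cohort_%d_%d", n, seed),
       simulate_cohort(simulation_config(n_subjects = n, ...), seed = seed))
}

# A moderately sized fitted joint model shared by prediction/joint tests.
std_cohort <- function() memo("std_cohort",
  simulate_cohort(simulation_config(n_subjects = 200), seed = 77))

std_fit <- function() memo("std_fit",
  fit_joint(std_cohort(), ghq_nodes = 9, quad_n = 7))

# Build a self-contained fit object from known parameter values (no data),
# sufficient for the prediction functions.  vcov defaults to zero so the
# parameters are treated as known.
synthetic_fit <- function(beta = c(0.32, 0.013), sd_b0 = 0.33, sd_b1 = 0.05,
                          corr_b = 0, sigma = 0.47,
                          gamma = c(sex = -0.5, age0 = 0.05, sex_age0 = 0.01),
                          alpha = 1.5, log_h0 = log(0.03), tau = 8.08,
                          knots = c(2.7, 5.4),
                          weight = weight_function("exponential", p = 0.95),
                          mode = "weighted-cumulative", random_slope = TRUE,
                          vcov_unc = NULL) {
  K <- length(knots) + 4
  fd <- list(knots = knots, boundary = c(0, tau), K = K, mode = mode,
             random_slope = random_slope,
             n_alpha = if (mode == "current-value-plus-slope") 2L else 1L,
             age_center = 75, re_dim = if (random_slope) 2L else 1L,
             ghq_nodes = 9, quad_n = 7, weight = weight)
  gamma_c <- c(gamma[1] + 75 * gamma[3], gamma[2], gamma[3])
  xi_c <- rep(log_h0, K) + 75 * gamma[2]
  theta <- jmclaims:::theta_pack(beta, sd_b0, sd_b1, corr_b, sigma,
                                 gamma_c, alpha, xi_c, fd$re_dim)
  p <- length(theta)
  if (!is.null(vcov_unc) && length(vcov_unc) == 1)
    vcov_unc <- diag(vcov_unc, p)
  structure(list(theta_unc = theta,
                 vcov_unc = vcov_unc %||% matrix(0, p, p),
                 fd = fd,
                 params = jmclaims:::params_from_theta(theta, fd),
                 loglik = NA_real_, aic = NA_real_, df = p),
            class = "jm_joint_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
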