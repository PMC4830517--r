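# Shared toy parameter set over a small simulated cohort.
toy_params <- function(tau, knots) {
  joint_model_params(beta = c(0.32, 0.013), sd_b0 = 0.33, sd_b1 = 0.05,
                     corr_b = 0.2, sigma = 0.47,
                     gamma = c(sex = -1, age0 = 0.05, sex_age0 = 0.01),
                     alpha = 0.8,
                     baseline = baseline_spline(knots, c(0, tau),
                                                rep(-8, length(knots) + 4)))
}

test_that("compiled likelihood equals the reference subject_loglik", {
  ch <- small_cohort(n = 30, seed = 5)
  tau <- max(ch$subjects$T_obs)
  knots <- c(tau / 3, 2 * tau / 3)
  params <- toy_params(tau, knots)
  ll_R <- vapply(ch$subjects$id, function(id)
    subject_loglik(jmclaims:::subject_data(ch, id), params), 0)
  fd <- jmclaims:::joint_fit_data(ch, params$weight, params$mode, knots,
                                  c(0, tau), TRUE, 9, 7)
  th <- jmclaims:::theta_pack(params$beta, params$sd_b0, params$sd_b1,
                              params$corr_b, params$sigma,
                              c(params$gamma[1] + 75 * params$gamma[3],
                                params$gamma[2], params$gamma[3]),
                              params$alpha,
                              params$baseline$coefs + 75 * params$gamma[2], 2)
  ll_C <- jmclaims:::joint_loglik_vec(th, fd)
  # the reference integrates the cumulative hazard piecewise between the
  # spline knots while the fast path uses one fixed rule on [0, T]; they
  # agree to the quadrature error of that rule, far below estimation noise
  expect_equal(unname(ll_R), unname(ll_C), tolerance = 1e-4)
})

test_that("with alpha = 0 the joint likelihood factorizes", {
  ch <- small_cohort(n = 30, seed = 5)
  tau <- max(ch$subjects$T_obs)
  knots <- c(tau / 3, 2 * tau / 3)
  params <- toy_params(tau, knots)
  params$alpha <- 0
  D <- jmclaims:::lmm_D(params)
  for (id in ch$subjects$id[c(1, 7, 19)]) {
    sd_ <- jmclaims:::subject_data(ch, id)
    llj <- subject_loglik(sd_, params)
    Z <- cbind(1, sd_$records$t)
    V <- Z %*% D %*% t(Z) + params$sigma^2 * diag(nrow(Z))
    r <- sd_$records$y - drop(Z %*% params$beta)
    ll_long <- -0.5 * (determinant(V)$modulus + drop(t(r) %*% solve(V, r)) +
                       nrow(Z) * log(2 * pi))
    w <- with(sd_$baseline, c(sex, age0, sex * age0))
    Lam <- cumulative_hazard(params$baseline, params$gamma, w,
                             sd_$baseline$T_obs, quad_n = 7)
    ll_surv <- sd_$baseline$delta *
      (spline_log_hazard(params$baseline, sd_$baseline$T_obs) +
       sum(params$gamma * w)) - Lam
    expect_equal(llj, as.numeric(ll_long + ll_surv), tolerance = 1e-8)
  }
})

test_that("a record-free subject reduces to the prior-integrated survival term", {
  tau <- 8
  params <- toy_params(tau, c(3, 5))
  sd_ <- list(baseline = data.frame(sex = 1, age0 = 80, T_obs = 6, delta = 1),
              records = data.frame(t = numeric(), count = numeric(),
                                   y = numeric()))
  llj <- subject_loglik(sd_, params)
  # independent route: 2-D Riemann integration of the survival term only
  D <- jmclaims:::lmm_D(params)
  g0 <- seq(-4 * params$sd_b0, 4 * params$sd_b0, length.out = 161)
  g1 <- seq(-4 * params$sd_b1, 4 * params$sd_b1, length.out = 161)
  w <- c(1, 80, 80)
  f <- function(b0, b1) {
    off <- jmclaims:::feature_offset_fn(params$beta, c(b0, b1), params$alpha,
                                        params$mode, params$weight)
    Lam <- cumulative_hazard(params$baseline, params$gamma, w, 6, off, 7)
    lh <- spline_log_hazard(params$baseline, 6) + sum(params$gamma * w) +
      off(6)
    dt <- D[1, 1] * D[2, 2] - D[1, 2]^2
    pr <- exp(-0.5 * (D[2, 2] * b0^2 - 2 * D[1, 2] * b0 * b1 +
                      D[1, 1] * b1^2) / dt) / (2 * pi * sqrt(dt))
    exp(lh - Lam) * pr
  }
  vals <- outer(g0, g1, Vectorize(f))
  orac <- log(sum(vals) * diff(g0)[1] * diff(g1)[1])
  expect_equal(llj, orac, tolerance = 1e-4)
})

test_that("joint fit: AIC arithmetic, optimum dominance, quadrature stability", {
  fit <- std_fit()
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$df)
  expect_equal(fit$convergence, 0)
  # optimum dominates the separate-fit initialization under the same rule
  lmm <- fit$lmm_init; surv0 <- fit$surv_init
  th0 <- jmclaims:::theta_pack(lmm$beta, lmm$sd_b0, lmm$sd_b1, lmm$corr_b,
                               lmm$sigma,
                               c(surv0$gamma[1] + 75 * surv0$gamma[3],
                                 surv0$gamma[2], surv0$gamma[3]),
                               0, surv0$baseline$coefs + 75 * surv0$gamma[2],
                               2)
  ll0 <- sum(jmclaims:::joint_loglik_vec(th0, fit$fd))
  expect_gte(fit$loglik, ll0)
  # 9 -> 15 Gauss-Hermite nodes moves the log-likelihood < 1e-4 per subject
  ch <- std_cohort()
  fd15 <- jmclaims:::joint_fit_data(ch, fit$params$weight, fit$params$mode,
                                    fit$fd$knots, fit$fd$boundary, TRUE,
                                    15, fit$fd$quad_n)
  ll15 <- sum(jmclaims:::joint_loglik_vec(fit$theta_unc, fd15))
  expect_lt(abs(ll15 - fit$loglik) / fit$n_subjects, 1e-4)
})

test_that("joint fit recovers a null association", {
  cfg <- simulation_config(n_subjects = 250, alpha = 0,
                           baseline = baseline_constant(9e-6))
  ch <- simulate_cohort(cfg, seed = 17)
  fit <- fit_joint(ch, ghq_nodes = 7)
  expect_lt(abs(fit$estimates[["alpha1"]]) / fit$se[["alpha1"]], 3)
})

test_that("weighting comparison is deterministic and AIC-consistent", {
  ch <- std_cohort()
  cands <- list(exp_fast = weight_function("exponential", p = 0.95),
                exp_fast2 = weight_function("exponential", p = 0.95),
                uniform2 = weight_function("uniform", window = 2))
  tab <- compare_weightings(ch, cands, ghq_nodes = 7, hessian = FALSE)
  expect_equal(nrow(tab), 3)
  expect_true(!is.unsorted(tab$aic))
  expect_equal(tab$aic, -2 * tab$loglik + 2 * tab$df)
  # identical candidates give identical AIC
  expect_equal(tab$aic[tab$weight == "exp_fast"],
               tab$aic[tab$weight == "exp_fast2"])
})

test_that("boundary-mixture LRT behaves at its edge cases", {
  f <- list(loglik = -100)
  out <- lrt_random_slope(f, f)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  out2 <- lrt_random_slope(list(loglik = -105), list(loglik = -100))
  expect_equal(out2$statistic, 10)
  expect_equal(out2$p_value,
               0.5 * pchisq(10, 1, lower.tail = FALSE) +
               0.5 * pchisq(10, 2, lower.tail = FALSE))
  expect_error(lrt_random_slope(list(loglik = -99), list(loglik = -100)),
               class = "jmclaims_lrt_negative")
})
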