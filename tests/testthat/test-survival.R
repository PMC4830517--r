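test_that("spline log-baseline: partition of unity and local support", {
  bl <- baseline_spline(knots = c(2, 4, 6), boundary = c(0, 8),
                        coefs = rep(-2.5, 7))
  tt <- seq(0, 8, by = 0.37)
  expect_equal(spline_log_hazard(bl, tt), rep(-2.5, length(tt)),
               tolerance = 1e-12)
  # perturbing one coefficient only changes the curve on that basis support
  bl2 <- bl; bl2$coefs[5] <- bl2$coefs[5] + 1
  diffv <- spline_log_hazard(bl2, tt) - spline_log_hazard(bl, tt)
  B <- jmclaims:::spline_basis(bl, tt)
  expect_true(all(abs(diffv[B[, 5] == 0]) < 1e-14))
  expect_true(any(abs(diffv) > 0.1))
  expect_error(spline_log_hazard(bl, 9), class = "jmclaims_outside_boundary")
})

test_that("B-spline basis values match an independent de Boor recursion", {
  deboor <- function(knots_all, t, degree) {
    nb <- length(knots_all) - degree - 1
    # order-1 indicator functions, then the Cox-de Boor recursion
    B <- vapply(seq_len(length(knots_all) - 1), function(j)
      as.numeric(t >= knots_all[j] & t < knots_all[j + 1]), 0)
    if (t >= knots_all[length(knots_all)] - 1e-12)
      B[max(which(knots_all < knots_all[length(knots_all)]))] <- 1
    for (d in seq_len(degree)) {
      Bn <- numeric(length(knots_all) - d - 1)
      for (j in seq_along(Bn)) {
        den1 <- knots_all[j + d] - knots_all[j]
        den2 <- knots_all[j + d + 1] - knots_all[j + 1]
        a <- if (den1 > 0) (t - knots_all[j]) / den1 * B[j] else 0
        b <- if (den2 > 0) (knots_all[j + d + 1] - t) / den2 * B[j + 1] else 0
        Bn[j] <- a + b
      }
      B <- Bn
    }
    B[seq_len(nb)]
  }
  bl <- baseline_spline(knots = c(1.5, 3, 5.5), boundary = c(0, 8),
                        coefs = rep(0, 7))
  for (t0 in c(0.01, 1.5, 2.7, 4.9, 7.3)) {
    expect_equal(drop(jmclaims:::spline_basis(bl, t0)),
                 deboor(bl$knots_all, t0, 3), tolerance = 1e-12)
  }
})

test_that("Cox fit maximizes the hand-written partial likelihood", {
  set.seed(21)
  n <- 40
  subj <- data.frame(id = seq_len(n), sex = rbinom(n, 1, 0.5),
                     age0 = runif(n, 65, 90))
  eta <- 0.6 * subj$sex + 0.05 * (subj$age0 - 75)
  subj$T_obs <- rexp(n, 0.1 * exp(eta))
  subj$delta <- as.integer(subj$T_obs < quantile(subj$T_obs, 0.7))
  subj$T_obs <- pmin(subj$T_obs, quantile(subj$T_obs, 0.7))
  ch <- claims_cohort(subj)
  fit <- fit_cox_separate(ch)
  # independent brute force: Breslow partial likelihood (no ties here)
  X <- cbind(subj$sex, subj$age0, subj$sex * subj$age0)
  Xc <- sweep(X, 2, colMeans(X))           # centred for numeric stability
  npl <- function(g) {
    eta <- drop(Xc %*% g)
    ll <- 0
    for (i in which(subj$delta == 1)) {
      rs <- subj$T_obs >= subj$T_obs[i]
      ll <- ll + eta[i] - log(sum(exp(eta[rs])))
    }
    -ll
  }
  o <- optim(c(0, 0, 0), npl, method = "BFGS",
             control = list(reltol = 1e-14))
  o <- optim(o$par, npl, method = "Nelder-Mead",
             control = list(reltol = 1e-15, maxit = 5000))
  expect_equal(unname(fit$gamma), o$par, tolerance = 1e-4)
  expect_equal(fit$loglik, -o$value, tolerance = 1e-8)
})

test_that("null covariates give coefficients within 3 SE of zero", {
  set.seed(5)
  n <- 300
  subj <- data.frame(id = seq_len(n), sex = rbinom(n, 1, 0.5),
                     age0 = runif(n, 65, 90), T_obs = rexp(n, 0.2))
  subj$delta <- as.integer(subj$T_obs < 6)
  subj$T_obs <- pmin(subj$T_obs, 6)
  fit <- fit_cox_separate(claims_cohort(subj))
  expect_true(all(abs(fit$gamma) / fit$se < 3))
})

test_that("two-group exponential simulation recovers the true log hazard ratio", {
  set.seed(77)
  n <- 2000
  sex <- rbinom(n, 1, 0.5)
  T0 <- rexp(n, 0.15 * exp(0.7 * sex))
  subj <- data.frame(id = seq_len(n), sex = sex, age0 = runif(n, 65, 90),
                     T_obs = pmin(T0, 8), delta = as.integer(T0 <= 8))
  fit <- fit_cox_separate(claims_cohort(subj))
  # with the interaction in the model, the sex effect at the age centroid is
  # gamma_sex + gamma_int * mean(age0)
  est <- fit$gamma[["sex"]] + fit$gamma[["sex_age0"]] * mean(subj$age0)
  v <- c(1, mean(subj$age0))
  se <- sqrt(drop(t(v) %*% fit$vcov[c(1, 3), c(1, 3)] %*% v))
  expect_lt(abs(est - 0.7) / se, 3)
})

test_that("hazard ratios reproduce printed worked examples", {
  hr1 <- hazard_ratio(-0.722)
  expect_equal(round(hr1$hr, 3), 0.486)
  expect_equal(round(hr1$pct_lower, 1), 51.4)
  expect_equal(round(hazard_ratio(-4.648)$hr, 3), 0.010)
  expect_equal(hazard_ratio(0)$hr, 1)
  expect_equal(hazard_ratio(0)$pct_change, 0)
})

test_that("cumulative hazard: closed form, monotonicity, survival bounds", {
  bl <- baseline_constant(0.3)
  expect_equal(cumulative_hazard(bl, c(0, 0, 0), c(1, 70, 70), 4), 1.2,
               tolerance = 1e-12)
  lam <- vapply(seq(0, 8, by = 0.5), function(tt)
    cumulative_hazard(bl, c(0.1, 0.01, 0), c(1, 70, 70), tt), 0)
  expect_true(all(diff(lam) > 0))
  S <- exp(-lam)
  expect_equal(S[1], 1)
  expect_true(all(S > 0 & S <= 1))
  expect_true(all(diff(S) < 0))
})

test_that("nested cumulative-hazard integral matches a trapezoid oracle", {
  bl <- baseline_spline(knots = c(3), boundary = c(0, 8),
                        coefs = c(-3, -2.6, -3.2, -2.2, -2.8))
  w <- weight_function("exponential", rate = 3)
  beta <- c(0.32, 0.013); b <- c(0.2, 0.01); alpha <- 1.2
  wcov <- c(1, 78, 78); gam <- c(-0.5, 0.04, 0.005)
  off <- jmclaims:::feature_offset_fn(beta, b, alpha, "weighted-cumulative", w)
  got <- cumulative_hazard(bl, gam, wcov, 7, off, 25)
  s <- seq(0, 7, length.out = 2e5 + 1)
  integrand <- exp(spline_log_hazard(bl, s) + sum(gam * wcov) + off(s))
  orac <- (sum(integrand) - (integrand[1] + integrand[length(s)]) / 2) *
    diff(s)[1]
  expect_equal(got, orac, tolerance = 1e-6)
})

test_that("parametric spline fit recovers a flat baseline", {
  set.seed(10)
  n <- 600
  subj <- data.frame(id = seq_len(n), sex = rbinom(n, 1, 0.5),
                     age0 = runif(n, 65, 90))
  T0 <- rexp(n, 0.1)
  subj$T_obs <- pmin(T0, 8); subj$delta <- as.integer(T0 <= 8)
  fit <- fit_survival_spline(claims_cohort(subj), n_knots = 2)
  tt <- seq(0.5, 7.5, by = 0.5)
  lh <- spline_log_hazard(fit$baseline, tt) +
    fit$gamma[["age0"]] * mean(subj$age0)   # level absorbed between terms
  # recovered log-hazard close to log(0.1) once the age level is restored
  expect_lt(max(abs(lh - log(0.1))), 0.35)
  expect_true(all(abs(fit$gamma[c("sex", "sex_age0")]) < 0.5))
})
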