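test_that("multivariate normal sampler reproduces its covariance", {
  S <- matrix(c(2, 0.7, 0.3, 0.7, 1, -0.2, 0.3, -0.2, 0.5), 3)
  set.seed(2)
  X <- jmclaims:::rmvnorm_eig(1e4, c(1, 2, 3), S)
  expect_lt(norm(cov(X) - S, "F") / norm(S, "F"), 0.05)
  expect_lt(max(abs(colMeans(X) - c(1, 2, 3))), 0.06)
})

test_that("theta draws: zero covariance pins everything at the estimate", {
  fit <- synthetic_fit()
  set.seed(4)
  ths <- sample_theta(fit, 3)
  for (p in ths) {
    expect_equal(p$beta, fit$params$beta)
    expect_equal(p$alpha, fit$params$alpha)
    expect_equal(p$baseline$coefs, fit$params$baseline$coefs)
  }
  # with a real covariance, fixed seeds reproduce draws
  fit2 <- synthetic_fit(vcov_unc = 1e-4)
  set.seed(11); a <- sample_theta(fit2, 2)
  set.seed(11); b <- sample_theta(fit2, 2)
  expect_equal(a, b)
})

test_that("b-posterior with no records and alpha = 0 is the prior", {
  fit <- synthetic_fit(alpha = 0, sd_b0 = 0.3, sd_b1 = 0.04)
  sub <- new_subject(1, 80)
  set.seed(6)
  draws <- t(replicate(600, sample_b_posterior(sub, fit$params, 3,
                                               n_mh = 30)$b))
  expect_lt(abs(sd(draws[, 1]) / 0.3 - 1), 0.2)
  expect_lt(abs(mean(draws[, 1])), 3 * 0.3 / sqrt(600) * 3)
})

test_that("b-posterior concentrates on the exact line as noise vanishes", {
  fit <- synthetic_fit(sigma = 1e-9)
  sub <- new_subject(0, 70,
                     data.frame(t = c(0, 2), count = c(0, 0),
                                y = (0.32 + 0.1) + (0.013 + 0.02) * c(0, 2)))
  set.seed(3)
  for (i in 1:3) {
    b <- sample_b_posterior(sub, fit$params, 2.5)$b
    expect_equal(b, c(0.1, 0.02), tolerance = 1e-3)
  }
})

test_that("one-record posterior draws agree with a grid-evaluated density", {
  fit <- synthetic_fit(alpha = 1.2)
  sub <- new_subject(1, 80, data.frame(t = 1, count = 3))
  t0 <- 1.5
  set.seed(19)
  draws <- t(replicate(800, sample_b_posterior(sub, fit$params, t0,
                                               n_mh = 20)$b))
  # independent marginal of b0 by 2-D grid integration
  g0 <- seq(-1.3, 1.6, length.out = 121)
  g1 <- seq(-0.25, 0.25, length.out = 81)
  dens <- outer(g0, g1, Vectorize(function(b0, b1)
    exp(jmclaims:::b_log_posterior(c(b0, b1), fit$params, sub, t0))))
  marg0 <- rowSums(dens); marg0 <- marg0 / sum(marg0)
  cdf0 <- cumsum(marg0)
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  q_grid <- vapply(qs, function(p) g0[which.min(abs(cdf0 - p))], 0)
  q_mc <- quantile(draws[, 1], qs)
  expect_lt(max(abs(q_grid - q_mc)), 0.12)
})

test_that("conditional survival obeys closed forms", {
  fit <- synthetic_fit(alpha = 0,
                       gamma = c(sex = 0, age0 = 0, sex_age0 = 0),
                       log_h0 = log(0.2))
  sub <- new_subject(0, 70)
  expect_equal(conditional_survival(fit$params, sub, c(0, 0), 2, 2), 1)
  got <- conditional_survival(fit$params, sub, c(0, 0), 2, 5)
  expect_equal(got, exp(-0.2 * 3), tolerance = 1e-6)
  expect_error(conditional_survival(fit$params, sub, c(0, 0), 3, 2),
               class = "jmclaims_invalid_horizon")
})

test_that("prediction curves are proper survival summaries", {
  fit <- synthetic_fit(alpha = 1.5, log_h0 = log(0.05), vcov_unc = 1e-4)
  sub <- new_subject(1, 80, data.frame(t = 0:2, count = c(1, 2, 4)))
  u <- seq(3, 8, by = 0.5)
  pred <- predict_survival(fit, sub, 3, c(3, u), n_draws = 60, seed = 2)
  expect_equal(pred$median[1], 1)            # pi(t | t) = 1
  expect_true(all(diff(pred$median) <= 1e-12))
  expect_true(all(pred$lower95 <= pred$median + 1e-12))
  expect_true(all(pred$median <= pred$upper95 + 1e-12))
  expect_true(all(pred$mean >= 0 & pred$mean <= 1))
  # grid capped at the baseline boundary
  pred2 <- predict_survival(fit, sub, 3, c(5, 9, 20), n_draws = 10, seed = 1)
  expect_true(all(pred2$u_grid <= fit$fd$boundary[2] + 1e-9))
})

test_that("degenerate configuration yields zero-width bands", {
  fit <- synthetic_fit(sigma = 1e-12, alpha = 1)
  sub <- new_subject(0, 70,
                     data.frame(t = c(0, 1), count = c(0, 0),
                                y = 0.32 + 0.013 * c(0, 1)))
  pred <- predict_survival(fit, sub, 1, seq(1, 6, by = 1), n_draws = 30,
                           seed = 5)
  expect_true(all(pred$upper95 - pred$lower95 < 1e-12))
  expect_true(all(abs(pred$mean - pred$median) < 1e-12))
})

test_that("rising claims depress the updated survival curve", {
  fit <- synthetic_fit(alpha = 2.5, log_h0 = log(0.04))
  base_rec <- data.frame(t = 0:2, count = c(1, 1, 1))
  sub <- new_subject(1, 80, base_rec)
  u <- seq(4, 8, by = 1)
  p0 <- predict_survival(fit, sub, 3, u, n_draws = 40, seed = 8)
  upd_flat <- update_prediction(fit, sub, data.frame(t = 3, count = 1), 3.5,
                                c(3.5, u), n_draws = 40, seed = 8)
  upd_jump <- update_prediction(fit, sub, data.frame(t = 3, count = 30), 3.5,
                                c(3.5, u), n_draws = 40, seed = 8)
  i <- length(u)                              # compare at the far horizon
  expect_lt(upd_jump$prediction$median[i + 1],
            upd_flat$prediction$median[i + 1])
  # no-surprise update changes the curve less than the extreme one
  expect_lt(abs(upd_flat$prediction$median[i + 1] - p0$median[i]),
            abs(upd_jump$prediction$median[i + 1] - p0$median[i]))
  # conditioning resets the curve to 1 at t_new
  expect_equal(upd_flat$prediction$median[1], 1)
  expect_true(all(upd_flat$prediction$u_grid >= 3.5))
})

test_that("update rejects records that do not extend the history", {
  fit <- synthetic_fit()
  sub <- new_subject(1, 80, data.frame(t = 0:2, count = c(1, 1, 1)))
  expect_error(update_prediction(fit, sub, data.frame(t = 2, count = 1), 3,
                                 4:6),
               class = "jmclaims_invalid_update")
})

test_that("prediction error: trivial predictors and loss decomposition", {
  subj <- data.frame(id = 1:10, sex = rep(0:1, 5),
                     age0 = seq(66, 89, length.out = 10),
                     T_obs = c(7, 6.5, 2, 3.5, 8, 8, 1.5, 5.2, 8, 4.8),
                     delta = c(0, 1, 1, 0, 0, 0, 1, 1, 0, 0))
  ch <- claims_cohort(subj)
  # perfect 0/1 predictions, no censoring inside the window -> PE = 0
  outcome <- function(i, from, to) as.numeric(subj$T_obs[i] >= to)
  ch_nc <- ch
  ch_nc$subjects$delta[ch_nc$subjects$T_obs < 6] <- 1   # no censored-in-window
  expect_equal(prediction_error(NULL, ch_nc, 1, 6, pi_fun = outcome)$pe, 0)
  # constant 1/2 prediction, no censoring -> PE = 1/2
  expect_equal(prediction_error(NULL, ch_nc, 1, 6,
                                pi_fun = function(i, from, to) 0.5)$pe, 0.5)
  # hand-coded oracle for the censored-in-window decomposition
  pf <- function(i, from, to) exp(-0.08 * (to - from) * (1 + 0.1 * subj$sex[i]))
  got <- prediction_error(NULL, ch, 1, 6, pi_fun = pf)
  risk <- which(subj$T_obs >= 1)
  loss <- 0
  for (i in risk) {
    p <- pf(i, 1, 6)
    loss <- loss + if (subj$T_obs[i] >= 6) abs(1 - p)
    else if (subj$delta[i] == 1) p
    else {
      cont <- pf(i, subj$T_obs[i], 6)
      cont * abs(1 - p) + (1 - cont) * p
    }
  }
  expect_equal(got$pe, loss / length(risk), tolerance = 1e-12)
  expect_equal(got$n_risk, length(risk))
  expect_error(prediction_error(NULL, ch, 10, 11, pi_fun = pf),
               class = "jmclaims_empty_risk_set")
})
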