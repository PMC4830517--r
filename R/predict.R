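#' Describe a new subject for prediction
#'
#' @param sex man 0 / woman 1.
#' @param age0 age at study entry (years).
#' @param records data frame with measurement times \code{t} and either
#'   claim counts \code{count} (transformed via \code{log1p}) or the
#'   log-scale response \code{y}.
#' @return List of class \code{"jm_subject"}.
#' @export
new_subject <- function(sex, age0, records = data.frame(t = numeric(),
                                                        count = numeric())) {
  records <- as.data.frame(records)
  if (nrow(records) && is.null(records$y)) records$y <- log1p(records$count)
  if (nrow(records) && any(records$count < 0, na.rm = TRUE))
    jm_stop("jmclaims_negative_count", "negative claim count in subject records")
  records <- records[order(records$t), , drop = FALSE]
  structure(list(sex = sex, age0 = age0,
                 w_cov = c(sex, age0, sex * age0),
                 records = records),
            class = "jm_subject")
}

# Rebuild a joint_model_params object from an unconstrained theta vector
# and a fit spec (knots, boundary, mode, weight, random_slope, ...).
params_from_theta <- function(theta, fd) {
  p <- theta_unpack(theta, fd)
  a_c <- fd$age_center
  gamma <- c(sex = unname(p$gamma_c[1] - a_c * p$gamma_c[3]),
             age0 = unname(p$gamma_c[2]), sex_age0 = unname(p$gamma_c[3]))
  joint_model_params(beta = p$beta, sd_b0 = p$sd0, sd_b1 = p$sd1,
                     corr_b = p$rho, sigma = p$sigma, gamma = gamma,
                     alpha = p$alpha,
                     baseline = baseline_spline(fd$knots, fd$boundary,
                                                p$xi_c - a_c * p$gamma_c[2]),
                     weight = fd$weight, mode = fd$mode,
                     random_slope = fd$random_slope)
}

#' Draw parameter vectors from the asymptotic posterior
#'
#' Samples \eqn{\theta \sim N(\hat\theta, V(\hat\theta))} on the
#' unconstrained optimization scale (so variance parameters stay valid)
#' and maps each draw back to a full parameter object.  With a zero
#' covariance every draw equals \eqn{\hat\theta}.
#'
#' @param fit a [fit_joint()] result (needs \code{vcov_unc}).
#' @param n number of draws.
#' @return List of \code{n} [joint_model_params()] objects.
#' @export
sample_theta <- function(fit, n = 1) {
  if (is.null(fit$vcov_unc))
    jm_stop("jmclaims_no_vcov", "fit has no covariance matrix; refit with hessian = TRUE")
  Th <- rmvnorm_eig(n, fit$theta_unc, fit$vcov_unc)
  lapply(seq_len(n), function(i) params_from_theta(Th[i, ], fit$fd))
}

# Log posterior density (unnormalized) of b given the subject's records up
# to time t and survival beyond t.
b_log_posterior <- function(b, params, subject, t, quad_n = 7) {
  rec <- subject$records
  rec <- rec[rec$t <= t + 1e-12, , drop = FALSE]
  D <- lmm_D(params)
  re_dim <- if (params$random_slope) 2L else 1L
  lp <- if (re_dim == 2) {
    dt <- D[1, 1] * D[2, 2] - D[1, 2]^2
    if (dt <= 0) return(-Inf)
    -log(2 * pi) - 0.5 * log(dt) -
      0.5 * (D[2, 2] * b[1]^2 - 2 * D[1, 2] * b[1] * b[2] +
             D[1, 1] * b[2]^2) / dt
  } else {
    stats::dnorm(b[1], 0, params$sd_b0, log = TRUE)
  }
  if (nrow(rec)) {
    m <- (params$beta[1] + b[1]) + (params$beta[2] + b[2]) * rec$t
    if (params$sigma <= 0) {
      lp <- lp + if (max(abs(rec$y - m)) < 1e-9) 0 else -Inf
    } else {
      lp <- lp + sum(stats::dnorm(rec$y, m, params$sigma, log = TRUE))
    }
  }
  off <- feature_offset_fn(params$beta, b, params$alpha, params$mode,
                           params$weight)
  t_cap <- if (is.null(params$baseline$boundary)) t
           else min(t, params$baseline$boundary[2])
  lp - cumulative_hazard(params$baseline, params$gamma, subject$w_cov,
                         t_cap, off, quad_n)
}

# Posterior mode and curvature-based covariance of b | data, T* > t.
b_posterior_mode <- function(params, subject, t, quad_n = 7) {
  re_dim <- if (params$random_slope) 2L else 1L
  eb <- empirical_bayes(params, subject$records$t[subject$records$t <= t],
                        subject$records$y[subject$records$t <= t])
  f <- function(b2) {
    b <- if (re_dim == 2) b2 else c(b2, 0)
    -b_log_posterior(b, params, subject, t, quad_n)
  }
  start <- if (re_dim == 2) eb$mode else eb$mode[1]
  if (!is.finite(f(start))) start <- start * 0
  opt <- stats::optim(start, f, method = if (re_dim == 2) "Nelder-Mead"
                      else "Brent",
                      lower = if (re_dim == 1) -10 else -Inf,
                      upper = if (re_dim == 1) 10 else Inf)
  H <- tryCatch(stats::optimHess(opt$par, f), error = function(e) NULL)
  S <- NULL
  if (!is.null(H))
    S <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(S) || any(!is.finite(S)) || any(diag(S) <= 0))
    S <- diag(1e-8, re_dim)
  list(mode = opt$par, cov = (S + t(S)) / 2)
}

#' Metropolis-Hastings draw from the random-effects posterior
#'
#' Samples \eqn{p(b \mid y\text{-history to } t,\ T^* > t,\ \theta)} with a
#' Gaussian random-walk proposal centred at the current state and scaled by
#' the posterior curvature at the mode (factor \eqn{2.4^2/d}).  Returns
#' the state after \code{n_mh} steps.
#'
#' @param subject a [new_subject()].
#' @param params a [joint_model_params()].
#' @param t conditioning time (records after \code{t} are ignored and
#'   survival to \code{t} conditions the posterior).
#' @param n_mh number of Metropolis steps (default 25).
#' @param proposal optional list \code{(mode, cov)} to reuse across calls.
#' @return List with \code{b} (length 2; slope 0 for intercept-only
#'   models), \code{accepted} (steps accepted), \code{n_mh}.
#' @export
sample_b_posterior <- function(subject, params, t, n_mh = 25,
                               proposal = NULL) {
  re_dim <- if (params$random_slope) 2L else 1L
  if (is.null(proposal)) proposal <- b_posterior_mode(params, subject, t)
  S <- proposal$cov * (2.4^2 / re_dim)
  degenerate <- det(as.matrix(S)) < 1e-28 || params$sigma == 0
  cur <- proposal$mode
  full <- function(b2) if (re_dim == 2) b2 else c(b2, 0)
  if (degenerate)
    return(list(b = full(cur), accepted = 0L, n_mh = n_mh))
  L <- t(chol(as.matrix(S)))
  lp_cur <- b_log_posterior(full(cur), params, subject, t)
  acc <- 0L
  for (s in seq_len(n_mh)) {
    prop <- cur + drop(L %*% stats::rnorm(re_dim))
    lp_prop <- b_log_posterior(full(prop), params, subject, t)
    if (is.finite(lp_prop) &&
        log(stats::runif(1)) < lp_prop - lp_cur) {
      cur <- prop; lp_cur <- lp_prop; acc <- acc + 1L
    }
  }
  list(b = full(cur), accepted = acc, n_mh = n_mh)
}

#' Conditional survival probability given random effects
#'
#' \eqn{\Pr(T^* \ge u \mid T^* > t, b, \theta) =
#' \exp\{-(\Lambda(u) - \Lambda(t))\}} with the cumulative hazard from the
#' joint model's hazard (spline baseline, covariates and association
#' feature).
#'
#' @param params a [joint_model_params()].
#' @param subject a [new_subject()] (covariates only are used).
#' @param b random effects \code{c(b0, b1)}.
#' @param t,u conditioning and target times, \eqn{u \ge t}.
#' @param quad_n quadrature size.
#' @return Probability in \eqn{[0, 1]}.
#' @export
conditional_survival <- function(params, subject, b, t, u, quad_n = 7) {
  if (u < t) jm_stop("jmclaims_invalid_horizon", "u must be >= t")
  off <- feature_offset_fn(params$beta, b, params$alpha, params$mode,
                           params$weight)
  Lu <- cumulative_hazard(params$baseline, params$gamma, subject$w_cov, u,
                          off, quad_n)
  Lt <- cumulative_hazard(params$baseline, params$gamma, subject$w_cov, t,
                          off, quad_n)
  exp(-(Lu - Lt))
}

#' Dynamic individualized survival prediction
#'
#' Monte Carlo estimate of \eqn{\pi(u \mid t)}, the probability that a
#' subject alive at \eqn{t} survives to \eqn{u}, propagating both
#' parameter uncertainty (draws from the asymptotic posterior
#' \eqn{N(\hat\theta, V(\hat\theta))}) and random-effect uncertainty
#' (Metropolis-Hastings draws from \eqn{p(b \mid \mathrm{history}, T^* >
#' t)}).  Reports the pointwise mean, median and 2.5/97.5 percent
#' quantiles over draws.
#'
#' @param fit a [fit_joint()] result.
#' @param subject a [new_subject()].
#' @param t conditioning time (years since entry); the subject is assumed
#'   alive at \code{t}.
#' @param u_grid future times \eqn{\ge t}; values beyond the baseline
#'   boundary \eqn{\tau} are dropped (no deaths are observable there, so
#'   no prediction is attempted).
#' @param n_draws Monte Carlo draws (default 200).
#' @param n_mh Metropolis steps per draw (default 25).
#' @param seed optional seed.
#' @return Object of class \code{"jm_survival_prediction"}: \code{t},
#'   \code{u_grid}, \code{mean}, \code{median}, \code{lower95},
#'   \code{upper95}, \code{n_draws}, \code{accept_rate}, \code{draws}
#'   (matrix of curves), \code{seed}.
#' @export
predict_survival <- function(fit, subject, t, u_grid, n_draws = 200,
                             n_mh = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tau <- fit$fd$boundary[2]
  if (t > tau + 1e-9)
    jm_stop("jmclaims_invalid_horizon",
            "conditioning time %.3g beyond the baseline boundary %.3g", t, tau)
  u_grid <- u_grid[u_grid >= t - 1e-12 & u_grid <= tau + 1e-9]
  if (!length(u_grid))
    jm_stop("jmclaims_invalid_horizon", "empty prediction grid within (t, tau]")

  fixed_theta <- is.null(fit$vcov_unc) ||
    all(abs(fit$vcov_unc) < .Machine$double.eps)
  params_hat <- params_from_theta(fit$theta_unc, fit$fd)
  prop <- b_posterior_mode(params_hat, subject, t)

  curves <- matrix(NA_real_, n_draws, length(u_grid))
  acc <- 0L
  for (d in seq_len(n_draws)) {
    pars <- if (fixed_theta) params_hat else sample_theta(fit, 1)[[1]]
    bd <- sample_b_posterior(subject, pars, t, n_mh = n_mh, proposal = prop)
    acc <- acc + bd$accepted
    off <- feature_offset_fn(pars$beta, bd$b, pars$alpha, pars$mode,
                             pars$weight)
    Lt <- cumulative_hazard(pars$baseline, pars$gamma, subject$w_cov, t,
                            off, fit$fd$quad_n)
    curves[d, ] <- vapply(u_grid, function(u) {
      Lu <- cumulative_hazard(pars$baseline, pars$gamma, subject$w_cov, u,
                              off, fit$fd$quad_n)
      exp(-max(Lu - Lt, 0))
    }, 0)
  }
  structure(list(t = t, u_grid = u_grid,
                 mean = colMeans(curves),
                 median = apply(curves, 2, stats::median),
                 lower95 = apply(curves, 2, stats::quantile, 0.025),
                 upper95 = apply(curves, 2, stats::quantile, 0.975),
                 n_draws = n_draws,
                 accept_rate = acc / (n_draws * n_mh),
                 draws = curves, seed = seed),
            class = "jm_survival_prediction")
}

#' @export
print.jm_survival_prediction <- function(x, ...) {
  cat(sprintf("Dynamic survival prediction from t = %.2f (%d draws)\n",
              x$t, x$n_draws))
  print(data.frame(u = x$u_grid, mean = round(x$mean, 3),
                   median = round(x$median, 3),
                   lower95 = round(x$lower95, 3),
                   upper95 = round(x$upper95, 3)))
  invisible(x)
}

#' Update a prediction with a newly observed record
#'
#' Appends the new measurement to the subject's history and recomputes the
#' dynamic prediction conditional on survival to the new measurement time.
#'
#' @param fit a [fit_joint()] result.
#' @param subject a [new_subject()].
#' @param new_record one-row data frame with \code{t} and \code{count} (or
#'   \code{y}); its time must exceed the previous conditioning time.
#' @param t_new new conditioning time, \eqn{\ge} the new record's time.
#' @param u_grid future times; trimmed to \eqn{(t_{new}, \tau]}.
#' @param ... passed to [predict_survival()].
#' @return List with the updated \code{subject} and \code{prediction}.
#' @export
update_prediction <- function(fit, subject, new_record, t_new, u_grid, ...) {
  t_prev <- if (nrow(subject$records)) max(subject$records$t) else 0
  if (new_record$t[1] <= t_prev)
    jm_stop("jmclaims_invalid_update",
            "new record time %.3g not beyond previous history (%.3g)",
            new_record$t[1], t_prev)
  if (t_new < new_record$t[1])
    jm_stop("jmclaims_invalid_update", "t_new must be >= the new record time")
  rec <- as.data.frame(new_record)
  if (is.null(rec$y)) rec$y <- log1p(rec$count)
  if (is.null(rec$count)) rec$count <- pmax(0, round(expm1(rec$y)))
  subject2 <- new_subject(subject$sex, subject$age0,
                          rbind(subject$records[c("t", "count", "y")],
                                rec[c("t", "count", "y")]))
  pred <- predict_survival(fit, subject2, t_new,
                           u_grid[u_grid >= t_new], ...)
  list(subject = subject2, prediction = pred)
}

# Deterministic plug-in estimate of pi(u | t) at theta-hat, integrating the
# random effects over an adaptive Gauss-Hermite grid centred at the
# posterior mode of b | history, T* > t.
survival_prob_plugin <- function(params, subject, t, u, ghq_nodes = 9,
                                 quad_n = 7) {
  re_dim <- if (params$random_slope) 2L else 1L
  pm <- b_posterior_mode(params, subject, t, quad_n)
  gh <- gh_rule(ghq_nodes)
  if (re_dim == 2) {
    L <- t(chol(pm$cov + diag(1e-10, 2)))
    grid <- expand.grid(k1 = seq_len(ghq_nodes), k2 = seq_len(ghq_nodes))
    lw <- log(gh$w[grid$k1]) + log(gh$w[grid$k2]) +
      gh$x[grid$k1]^2 + gh$x[grid$k2]^2
    num <- den <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      z <- c(gh$x[grid$k1[g]], gh$x[grid$k2[g]])
      b <- pm$mode + sqrt(2) * drop(L %*% z)
      lp <- b_log_posterior(b, params, subject, t, quad_n)
      den[g] <- lw[g] + lp
      num[g] <- den[g] +
        log(max(conditional_survival(params, subject, b, t, u, quad_n),
                1e-300))
    }
    exp(logsumexp(num) - logsumexp(den))
  } else {
    s_eb <- sqrt(max(pm$cov[1, 1], 1e-12))
    num <- den <- numeric(ghq_nodes)
    for (g in seq_len(ghq_nodes)) {
      b <- c(pm$mode[1] + sqrt(2) * s_eb * gh$x[g], 0)
      lp <- b_log_posterior(b, params, subject, t, quad_n)
      den[g] <- log(gh$w[g]) + gh$x[g]^2 + lp
      num[g] <- den[g] +
        log(max(conditional_survival(params, subject, b, t, u, quad_n),
                1e-300))
    }
    exp(logsumexp(num) - logsumexp(den))
  }
}

#' Prediction error with absolute loss
#'
#' Estimates the expected absolute loss
#' \eqn{E\,|1\{T^* > u\} - \hat\pi(u \mid t)|} over the subjects of a
#' cohort still at risk at base time \eqn{t}.  Subjects with known status
#' at \eqn{u} contribute their realized loss; a subject censored at
#' \eqn{T_i \in (t, u)} contributes the model-based decomposition
#' \deqn{\hat\pi(u \mid T_i)\,|1 - \hat\pi(u \mid t)| +
#'       (1 - \hat\pi(u \mid T_i))\,|0 - \hat\pi(u \mid t)|,}
#' i.e. their own continuation probability weights the two possible
#' outcomes, rather than dropping the subject.
#'
#' @param fit a [fit_joint()] result, or a [fit_cox_separate()] result
#'   (covariates-only comparator, predictions from the Breslow baseline).
#' @param cohort the evaluation [claims_cohort()].
#' @param t base time; predictions use records up to \code{t}.
#' @param u horizon, \eqn{u > t}.
#' @param ghq_nodes,quad_n numeric-integration sizes for the joint-model
#'   predictor.
#' @param pi_fun optional predictor override: a function
#'   \code{(i, from, to)} returning the continuation probability for
#'   subject row \code{i} from time \code{from} to \code{to}.  Used for
#'   custom predictors and for testing the loss decomposition.
#' @return List with \code{pe}, \code{n_risk}, \code{t}, \code{u}.
#' @export
prediction_error <- function(fit, cohort, t, u, ghq_nodes = 9, quad_n = 7,
                             pi_fun = NULL) {
  stopifnot(u > t)
  s <- cohort$subjects
  risk <- which(s$T_obs >= t)
  if (!length(risk))
    jm_stop("jmclaims_empty_risk_set", "no subjects at risk at t = %.3g", t)

  if (!is.null(pi_fun)) {
    # user-supplied predictor: nothing to prepare
  } else if (inherits(fit, "jm_joint_fit")) {
    params <- params_from_theta(fit$theta_unc, fit$fd)
    tau <- fit$fd$boundary[2]
    pi_fun <- function(i, from, to) {
      sub <- new_subject(s$sex[i], s$age0[i],
                         cohort$records[cohort$records$id == s$id[i] &
                                        cohort$records$t <= from + 1e-12,
                                        c("t", "count", "y")])
      survival_prob_plugin(params, sub, from, min(to, tau), ghq_nodes, quad_n)
    }
  } else if (inherits(fit, "jm_cox_fit")) {
    # centered = FALSE gives the baseline at covariates 0, which is what
    # the explicit exp(gamma'w) rescaling below expects; survfit's note
    # about interaction terms does not apply to that usage
    bh <- suppressWarnings(survival::basehaz(fit$fit, centered = FALSE))
    H0 <- stats::stepfun(bh$time, c(0, bh$hazard))
    pi_fun <- function(i, from, to) {
      eta <- exp(sum(fit$gamma * c(s$sex[i], s$age0[i], s$sex[i] * s$age0[i])))
      exp(-(H0(to) - H0(from)) * eta)
    }
  } else {
    jm_stop("jmclaims_invalid_config", "unsupported fit class for prediction_error")
  }

  loss <- numeric(length(risk))
  for (j in seq_along(risk)) {
    i <- risk[j]
    pi_u <- pi_fun(i, t, u)
    if (s$T_obs[i] >= u) {
      loss[j] <- abs(1 - pi_u)
    } else if (s$delta[i] == 1) {
      loss[j] <- abs(0 - pi_u)
    } else {
      cont <- pi_fun(i, s$T_obs[i], u)
      loss[j] <- cont * abs(1 - pi_u) + (1 - cont) * abs(0 - pi_u)
    }
  }
  list(pe = mean(loss), n_risk = length(risk), t = t, u = u)
}
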