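#' Linear mixed model for log1p-transformed yearly claims
#'
#' Fits by maximum likelihood the longitudinal sub-model
#' \deqn{y_{ij} = m_i(t_{ij}) + \varepsilon_{ij}, \qquad
#'       m_i(t) = (\beta_0 + b_{i0}) + (\beta_1 + b_{i1})\, t,}
#' with \eqn{b_i \sim N(0, D)} (bivariate, or intercept-only when
#' \code{random_slope = FALSE}) and \eqn{\varepsilon_{ij} \sim N(0,
#' \sigma^2)}.  The random effects are integrated analytically, so the
#' marginal likelihood is Gaussian with per-subject covariance
#' \eqn{V_i = Z_i D Z_i^T + \sigma^2 I}; the fixed effects are profiled
#' out by generalized least squares and the variance parameters are
#' maximized on an unconstrained scale (log standard deviations,
#' atanh-correlation).  ML rather than REML is used so log-likelihoods and
#' AIC are comparable across nested and joint fits.
#'
#' Subjects sharing a measurement-time pattern share \eqn{V_i}; the
#' likelihood is evaluated pattern-wise, which makes balanced yearly panels
#' cheap.
#'
#' @param cohort a [claims_cohort()]; at least 2 subjects with records.
#' @param random_slope include the random slope (default) or an
#'   intercept-only random-effects structure.
#' @param control list with \code{maxit} (default 500) and \code{reltol}
#'   (default 1e-10) passed to the optimizer.
#' @return Object of class \code{"jm_lmm_fit"}: \code{beta}, \code{sd_b0},
#'   \code{sd_b1}, \code{corr_b}, \code{sigma}, \code{loglik}, \code{aic},
#'   \code{se} (delta-method standard errors on the natural scale),
#'   \code{vcov_unc} (covariance of the unconstrained parameterization),
#'   \code{random_slope}, \code{convergence}.
#' @export
fit_lmm <- function(cohort, random_slope = TRUE,
                    control = list(maxit = 500, reltol = 1e-10)) {
  pat <- lmm_patterns(cohort)
  if (length(pat$groups) == 0 || nrow(cohort$subjects) < 2)
    jm_stop("jmclaims_insufficient_data",
            "need at least 2 subjects with longitudinal records")

  ## degenerate noiseless data: all observations on one exact line
  allt <- cohort$records$t
  ally <- cohort$records$y
  if (length(unique(round(allt, 12))) >= 2) {
    ols <- stats::lm.fit(cbind(1, allt), ally)
    if (max(abs(ols$residuals)) < 1e-10) {
      beta <- stats::setNames(ols$coefficients, c("beta0", "beta1"))
      return(structure(list(beta = beta, sd_b0 = 0, sd_b1 = 0, corr_b = 0,
                            sigma = 0, loglik = Inf, aic = -Inf,
                            se = NULL, vcov_unc = NULL,
                            random_slope = random_slope,
                            convergence = 0L, degenerate = TRUE),
                       class = "jm_lmm_fit"))
    }
  }

  np <- if (random_slope) 4L else 2L
  unpack <- function(v) {
    if (random_slope) {
      sd0 <- exp(v[1]); sd1 <- exp(v[2]); rho <- tanh(v[3]); sig <- exp(v[4])
      D <- matrix(c(sd0^2, rho * sd0 * sd1, rho * sd0 * sd1, sd1^2), 2)
    } else {
      sd0 <- exp(v[1]); sd1 <- 0; rho <- 0; sig <- exp(v[2])
      D <- matrix(c(sd0^2, 0, 0, 0), 2)
    }
    list(D = D, sigma = sig, sd0 = sd0, sd1 = sd1, rho = rho)
  }
  prof <- function(v) lmm_profile_loglik(unpack(v), pat)
  nll <- function(v) {
    out <- prof(v)
    if (!is.finite(out$loglik)) return(1e10)
    -out$loglik
  }
  ## moment-based starting values
  sig0 <- max(stats::sd(ally) * 0.7, 1e-3)
  init <- if (random_slope) c(log(sig0), log(sig0 / 5), 0, log(sig0))
          else c(log(sig0), log(sig0))
  opt <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = control$maxit %||% 500,
                                     reltol = control$reltol %||% 1e-10))
  th <- unpack(opt$par)
  pr <- prof(opt$par)

  ## observed information on the full unconstrained parameterization
  ## (beta0, beta1, variance parameters)
  full <- function(u) {
    b <- u[1:2]
    th2 <- unpack(u[-(1:2)])
    -lmm_loglik_beta(b, th2, pat)
  }
  u_hat <- c(pr$beta, opt$par)
  H <- tryCatch(stats::optimHess(u_hat, full), error = function(e) NULL)
  se <- vcov_unc <- NULL
  if (!is.null(H)) {
    vcov_unc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vcov_unc)) {
      to_nat <- function(u) {
        t2 <- unpack(u[-(1:2)])
        c(u[1], u[2], t2$sd0, t2$sd1, t2$rho, t2$sigma)
      }
      J <- num_jacobian(to_nat, u_hat)
      v_nat <- J %*% vcov_unc %*% t(J)
      se <- sqrt(pmax(diag(v_nat), 0))
      names(se) <- c("beta0", "beta1", "sd_b0", "sd_b1", "corr_b", "sigma")
      if (!random_slope) se[c("sd_b1", "corr_b")] <- NA_real_
    }
  }
  k <- 2L + np
  structure(list(beta = stats::setNames(pr$beta, c("beta0", "beta1")),
                 sd_b0 = th$sd0, sd_b1 = th$sd1, corr_b = th$rho,
                 sigma = th$sigma,
                 loglik = pr$loglik, aic = -2 * pr$loglik + 2 * k,
                 se = se, vcov_unc = vcov_unc,
                 random_slope = random_slope,
                 convergence = opt$convergence, degenerate = FALSE),
            class = "jm_lmm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.jm_lmm_fit <- function(x, ...) {
  cat("Linear mixed model (ML) on log1p yearly claims\n")
  cat(sprintf("  beta0 = %.4f, beta1 = %.4f\n", x$beta[1], x$beta[2]))
  cat(sprintf("  sd_b0 = %.4f, sd_b1 = %.4f, corr = %.3f, sigma = %.4f\n",
              x$sd_b0, x$sd_b1, x$corr_b, x$sigma))
  cat(sprintf("  logLik = %.3f, AIC = %.3f\n", x$loglik, x$aic))
  invisible(x)
}

# Group subjects by identical measurement-time patterns.  Each group holds
# the shared design (t vector) and a stacked response matrix.
lmm_patterns <- function(cohort) {
  r <- cohort$records
  if (!nrow(r)) return(list(groups = list(), n_obs = 0L))
  sp_t <- split(r$t, r$id)
  sp_y <- split(r$y, r$id)
  key <- vapply(sp_t, function(t) paste(round(t, 9), collapse = ","), "")
  groups <- lapply(split(seq_along(sp_t), key), function(idx) {
    t <- sp_t[[idx[1]]]
    Y <- do.call(rbind, sp_y[idx])
    list(t = t, X = cbind(1, t), Y = Y, n = length(idx), m = length(t))
  })
  list(groups = unname(groups), n_obs = nrow(r))
}

# Profiled marginal log-likelihood: GLS beta-hat given variance parameters.
lmm_profile_loglik <- function(th, pat) {
  A <- matrix(0, 2, 2); cvec <- numeric(2)
  pre <- vector("list", length(pat$groups))
  for (g in seq_along(pat$groups)) {
    G <- pat$groups[[g]]
    Z <- G$X
    V <- Z %*% th$D %*% t(Z) + th$sigma^2 * diag(G$m)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(loglik = -Inf))
    Vinv <- chol2inv(ch)
    A <- A + G$n * crossprod(G$X, Vinv %*% G$X)
    cvec <- cvec + crossprod(G$X, Vinv %*% colSums(G$Y))
    pre[[g]] <- list(Vinv = Vinv, logdet = 2 * sum(log(diag(ch))))
  }
  beta <- tryCatch(drop(solve(A, cvec)), error = function(e) NULL)
  if (is.null(beta)) return(list(loglik = -Inf))
  ll <- 0
  for (g in seq_along(pat$groups)) {
    G <- pat$groups[[g]]
    R <- sweep(G$Y, 2L, drop(G$X %*% beta))
    q <- rowSums((R %*% pre[[g]]$Vinv) * R)
    ll <- ll - 0.5 * sum(q) -
      0.5 * G$n * (pre[[g]]$logdet + G$m * log(2 * pi))
  }
  list(loglik = ll, beta = beta)
}

# Marginal log-likelihood at fixed beta (for the observed information).
lmm_loglik_beta <- function(beta, th, pat) {
  ll <- 0
  for (G in pat$groups) {
    Z <- G$X
    V <- Z %*% th$D %*% t(Z) + th$sigma^2 * diag(G$m)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    Vinv <- chol2inv(ch)
    R <- sweep(G$Y, 2L, drop(G$X %*% beta))
    ll <- ll - 0.5 * sum(rowSums((R %*% Vinv) * R)) -
      0.5 * G$n * (2 * sum(log(diag(ch))) + G$m * log(2 * pi))
  }
  ll
}

# 2x2 random-effects covariance of a fitted model.
lmm_D <- function(fit) {
  od <- fit$corr_b * fit$sd_b0 * fit$sd_b1
  matrix(c(fit$sd_b0^2, od, od, fit$sd_b1^2), 2)
}

#' Empirical-Bayes random effects for one subject
#'
#' Posterior mode (= mean, the posterior being Gaussian) of \eqn{b_i}
#' given the subject's longitudinal responses only:
#' \eqn{\Sigma_i = (Z_i^T Z_i/\sigma^2 + D^{-1})^{-1}}, mode
#' \eqn{\Sigma_i Z_i^T (y_i - X_i\beta)/\sigma^2}.  A subject with no
#' records gets the prior mean \eqn{(0, 0)}.
#'
#' @param fit a [fit_lmm()] result (or any list with \code{beta},
#'   \code{sd_b0}, \code{sd_b1}, \code{corr_b}, \code{sigma}).
#' @param t,y the subject's measurement times and responses.
#' @return List with \code{mode} (length 2) and \code{cov} (2x2 posterior
#'   covariance).
#' @export
empirical_bayes <- function(fit, t, y) {
  D <- lmm_D(fit)
  if (length(t) == 0)
    return(list(mode = c(0, 0), cov = D))
  Z <- cbind(1, t)
  r <- y - drop(Z %*% fit$beta)
  if (fit$sigma <= 1e-12) {
    # noiseless limit: b reproduces the subject's exact least-squares line
    # within the span of the random effects
    if (D[2, 2] <= 1e-14) {
      b0 <- mean(r)
      return(list(mode = c(b0, 0), cov = matrix(0, 2, 2)))
    }
    b <- unname(drop(qr.solve(Z, r)))
    return(list(mode = b, cov = matrix(0, 2, 2)))
  }
  if (D[1, 1] <= 1e-14 && D[2, 2] <= 1e-14)
    return(list(mode = c(0, 0), cov = matrix(0, 2, 2)))
  if (D[2, 2] <= 1e-14) {
    prec <- length(t) / fit$sigma^2 + 1 / D[1, 1]
    v <- 1 / prec
    b0 <- v * sum(r) / fit$sigma^2
    return(list(mode = c(b0, 0), cov = matrix(c(v, 0, 0, 0), 2)))
  }
  P <- crossprod(Z) / fit$sigma^2 + solve(D)
  S <- solve(P)
  list(mode = unname(drop(S %*% crossprod(Z, r)) / fit$sigma^2), cov = S)
}
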