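#' Joint-model parameter set
#'
#' Collects every parameter of the joint model
#' \deqn{y_i(t) = m_i(t) + \varepsilon_i(t), \quad
#'       h_i(t) = h_0(t) \exp\{\gamma^T w_i + \alpha F(m_i(t))\},}
#' with \eqn{m_i(t) = (\beta_0 + b_{i0}) + (\beta_1 + b_{i1}) t},
#' \eqn{b_i \sim N(0, D)}, \eqn{\varepsilon \sim N(0, \sigma^2)}, an
#' exponentiated-spline baseline \eqn{h_0} and a fading-kernel cumulative
#' effect \eqn{F}.
#'
#' @param beta fixed effects \code{c(intercept, slope)}.
#' @param sd_b0,sd_b1,corr_b random-effects covariance via SDs/correlation.
#' @param sigma residual SD.
#' @param gamma survival coefficients \code{(sex, age0, sex_age0)}.
#' @param alpha association coefficient(s); length 2 in the
#'   value-plus-slope mode.
#' @param baseline a baseline-hazard object.
#' @param weight a [weight_function()].
#' @param mode association-feature mode.
#' @param random_slope logical; \code{FALSE} for an intercept-only
#'   random-effects structure (then \code{sd_b1}, \code{corr_b} are 0).
#' @return List of class \code{"jm_joint_params"}.
#' @export
joint_model_params <- function(beta, sd_b0, sd_b1, corr_b, sigma, gamma,
                               alpha, baseline, weight = weight_function(),
                               mode = "weighted-cumulative",
                               random_slope = TRUE) {
  if (!random_slope) { sd_b1 <- 0; corr_b <- 0 }
  stopifnot(sd_b0 >= 0, sd_b1 >= 0, abs(corr_b) <= 1, sigma >= 0,
            all(is.finite(alpha)))
  structure(list(beta = beta, sd_b0 = sd_b0, sd_b1 = sd_b1, corr_b = corr_b,
                 sigma = sigma, gamma = gamma, alpha = alpha,
                 baseline = baseline, weight = weight, mode = mode,
                 random_slope = random_slope),
            class = "jm_joint_params")
}

alpha_len <- function(mode) if (mode == "current-value-plus-slope") 2L else 1L

# Feature basis (phi0, phi1) per mode, for linear trajectories a + c s:
# feature_f(s) = a * phi0_f(s) + c * phi1_f(s).  Returns a list of f
# components, each with vectors phi0, phi1 over the supplied times.
mode_feature_basis <- function(mode, weight, s, quad_n = 15) {
  switch(mode,
    "weighted-cumulative" = list(kernel_feature_basis(weight, s, quad_n)),
    "current-value" = list(list(phi0 = rep(1, length(s)), phi1 = s)),
    "current-value-plus-slope" = list(
      list(phi0 = rep(1, length(s)), phi1 = s),
      list(phi0 = rep(0, length(s)), phi1 = rep(1, length(s)))),
    jm_stop("jmclaims_unknown_mode", "unknown association mode '%s'", mode))
}

#' Subject contribution to the joint log-likelihood
#'
#' Reference implementation of
#' \deqn{\log \int \prod_j N(y_{ij}; m_i(t_{ij}), \sigma^2) \cdot
#'       h_i(T_i)^{\delta_i} e^{-\Lambda_i(T_i)} \cdot N(b; 0, D)\, db}
#' by pseudo-adaptive Gauss-Hermite quadrature, recentred and rescaled at
#' the subject's empirical-Bayes mode and curvature (computed from the
#' longitudinal part of \code{params}).  The cumulative hazard uses nested
#' Gauss-Legendre quadrature.  [fit_joint()] evaluates the same quantity
#' through a compiled fast path; the two agree to quadrature precision.
#'
#' @param subject list with \code{baseline} (one-row data frame: sex, age0,
#'   T_obs, delta) and \code{records} (data frame with t, y), as returned
#'   by internal extractors, or a one-subject [claims_cohort()].
#' @param params a [joint_model_params()].
#' @param ghq_nodes Gauss-Hermite nodes per random-effect dimension.
#' @param quad_n outer Gauss-Legendre size for the cumulative hazard.
#' @return Scalar log-likelihood contribution.
#' @export
subject_loglik <- function(subject, params, ghq_nodes = 9, quad_n = 7) {
  if (inherits(subject, "claims_cohort"))
    subject <- subject_data(subject, subject$subjects$id[1])
  bl <- subject$baseline
  rec <- subject$records
  w_cov <- c(bl$sex, bl$age0, bl$sex * bl$age0)
  re_dim <- if (params$random_slope) 2L else 1L
  D <- matrix(c(params$sd_b0^2,
                rep(params$corr_b * params$sd_b0 * params$sd_b1, 2),
                params$sd_b1^2), 2)

  eb <- empirical_bayes(params, rec$t, rec$y)
  gh <- gh_rule(ghq_nodes)

  cond_loglik <- function(b) {
    ll <- 0
    if (nrow(rec)) {
      m <- (params$beta[1] + b[1]) + (params$beta[2] + b[2]) * rec$t
      ll <- ll + sum(stats::dnorm(rec$y, m, params$sigma, log = TRUE))
    }
    off <- feature_offset_fn(params$beta, b, params$alpha, params$mode,
                             params$weight)
    Lam <- cumulative_hazard(params$baseline, params$gamma, w_cov, bl$T_obs,
                             off, quad_n)
    if (bl$delta == 1) {
      ll <- ll + spline_log_hazard(params$baseline, bl$T_obs) +
        sum(params$gamma * w_cov) + off(bl$T_obs)
    }
    ll - Lam
  }

  if (re_dim == 2) {
    Sig <- eb$cov + diag(1e-10, 2)
    L <- t(chol(Sig))
    grid <- expand.grid(k1 = seq_len(ghq_nodes), k2 = seq_len(ghq_nodes))
    terms <- numeric(nrow(grid))
    dinv <- solve(D + diag(1e-12, 2))
    ldet <- determinant(D + diag(1e-12, 2))$modulus
    for (g in seq_len(nrow(grid))) {
      z <- c(gh$x[grid$k1[g]], gh$x[grid$k2[g]])
      b <- eb$mode + sqrt(2) * drop(L %*% z)
      lprior <- -log(2 * pi) - 0.5 * ldet - 0.5 * drop(t(b) %*% dinv %*% b)
      lw <- log(2) + sum(log(diag(L))) +
        log(gh$w[grid$k1[g]]) + log(gh$w[grid$k2[g]]) + sum(z^2)
      terms[g] <- lw + cond_loglik(b) + lprior
    }
    logsumexp(terms)
  } else {
    s_eb <- sqrt(max(eb$cov[1, 1], 1e-12))
    terms <- numeric(ghq_nodes)
    for (g in seq_len(ghq_nodes)) {
      b0 <- eb$mode[1] + sqrt(2) * s_eb * gh$x[g]
      lprior <- stats::dnorm(b0, 0, params$sd_b0, log = TRUE)
      lw <- 0.5 * log(2) + log(s_eb) + log(gh$w[g]) + gh$x[g]^2
      terms[g] <- lw + cond_loglik(c(b0, 0)) + lprior
    }
    logsumexp(terms)
  }
}

## ---- fast-path precomputation -------------------------------------------

# Everything theta-independent for a cohort: measurement-time pattern
# groups (subjects sharing a time vector share all per-pattern algebra),
# quadrature nodes, spline and feature bases, and the Gauss-Hermite grid.
joint_fit_data <- function(cohort, weight, mode, knots, boundary,
                           random_slope, ghq_nodes, quad_n,
                           age_center = 75) {
  s <- cohort$subjects
  N <- nrow(s)
  K <- length(knots) + 4
  re_dim <- if (random_slope) 2L else 1L

  r <- cohort$records
  groups <- list()
  if (nrow(r)) {
    sp_t <- split(r$t, r$id)
    sp_y <- split(r$y, r$id)
    rows <- match(names(sp_t), s$id)
    key <- vapply(sp_t, function(t) paste(round(t, 9), collapse = ","), "")
    groups <- lapply(split(seq_along(sp_t), key), function(g) {
      list(idx = rows[g], t = sp_t[[g[1]]],
           Y = do.call(rbind, sp_y[g]), m = length(sp_t[[g[1]]]))
    })
    groups <- unname(groups)
  }
  idx_empty <- setdiff(seq_len(N), unlist(lapply(groups, `[[`, "idx")))

  Wc <- cbind(s$sex, s$age0 - age_center, s$sex * (s$age0 - age_center))

  base_r <- gl_rule(quad_n, -1, 1)
  half <- s$T_obs / 2
  Snod <- outer(half, base_r$x + 1)     # N x Q, column-major
  Vw <- outer(half, base_r$w)
  skel <- baseline_spline(knots, boundary, rep(0, K))
  Bq <- spline_basis(skel, as.vector(Snod))
  BT <- spline_basis(skel, s$T_obs)

  fb_q <- mode_feature_basis(mode, weight, as.vector(Snod))
  fb_T <- mode_feature_basis(mode, weight, s$T_obs)
  P0q <- lapply(fb_q, function(f) matrix(f$phi0, N))
  P1q <- lapply(fb_q, function(f) matrix(f$phi1, N))
  P0T <- lapply(fb_T, `[[`, "phi0")
  P1T <- lapply(fb_T, `[[`, "phi1")

  gh <- gh_rule(ghq_nodes)
  if (re_dim == 2) {
    grid <- expand.grid(k1 = seq_len(ghq_nodes), k2 = seq_len(ghq_nodes))
    z1 <- gh$x[grid$k1]; z2 <- gh$x[grid$k2]
    logwt <- log(gh$w[grid$k1]) + log(gh$w[grid$k2]) - log(pi)
  } else {
    z1 <- gh$x; z2 <- rep(0, ghq_nodes)
    logwt <- log(gh$w) - 0.5 * log(pi)
  }

  list(N = N, K = K, re_dim = re_dim, delta = s$delta,
       groups = groups, idx_empty = idx_empty,
       Wc = Wc, age_center = age_center, Bq = Bq, BT = BT, Vw = Vw,
       P0q = P0q, P1q = P1q, P0T = P0T, P1T = P1T,
       z1 = z1, z2 = z2, logwt = logwt,
       knots = knots, boundary = boundary, mode = mode, weight = weight,
       n_alpha = alpha_len(mode), random_slope = random_slope,
       ghq_nodes = ghq_nodes, quad_n = quad_n)
}

# Exact longitudinal-posterior algebra at the current parameters: for every
# subject, the marginal Gaussian log-likelihood Clong of its records, the
# posterior mean mu of b | y, and Gauss-Hermite nodes mapped through the
# posterior covariance (shared within a time pattern).  The stable forms
#   Sigma = D - D Z' (Z D Z' + s^2 I)^{-1} Z D,
#   mu    = D Z' (Z D Z' + s^2 I)^{-1} (y - X beta)
# avoid D^{-1} and remain valid for (near-)singular D.
# Lower Cholesky factor tolerant of semi-definite matrices: roundoff in
# the collapsed-posterior limit can leave tiny negative eigenvalues.
chol_lower_safe <- function(S, d) {
  out <- tryCatch(t(chol(S + diag(1e-12, d))), error = function(e) NULL)
  if (!is.null(out)) return(out)
  e <- eigen(S, symmetric = TRUE)
  t(chol(e$vectors %*% (t(e$vectors) * pmax(e$values, 1e-12)) +
         diag(1e-13, d)))
}

posterior_nodes <- function(beta, D, sigma, fd) {
  N <- fd$N
  d <- fd$re_dim
  Dd <- D[seq_len(d), seq_len(d), drop = FALSE]
  M <- length(fd$z1)
  sqrt2 <- sqrt(2)
  B0 <- B1 <- matrix(0, N, M)
  Clong <- numeric(N)

  fill <- function(idx, mu, L) {
    # mu: n x d matrix; L: d x d lower Cholesky of the posterior covariance
    B0[idx, ] <<- mu[, 1] + sqrt2 * L[1, 1] * rep(fd$z1, each = length(idx))
    if (d == 2)
      B1[idx, ] <<- mu[, 2] + sqrt2 *
        (L[2, 1] * rep(fd$z1, each = length(idx)) +
         L[2, 2] * rep(fd$z2, each = length(idx)))
  }

  if (length(fd$idx_empty)) {
    L0 <- chol_lower_safe(Dd, d)
    fill(fd$idx_empty, matrix(0, length(fd$idx_empty), d), L0)
  }
  for (G in fd$groups) {
    Z <- if (d == 2) cbind(1, G$t) else matrix(1, G$m, 1)
    V <- Z %*% Dd %*% t(Z) + sigma^2 * diag(G$m)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    P <- Dd %*% crossprod(Z, Vinv)          # d x m
    Sig <- Dd - P %*% Z %*% Dd
    Sig <- (Sig + t(Sig)) / 2
    L <- chol_lower_safe(Sig, d)
    R <- sweep(G$Y, 2L, beta[1] + beta[2] * G$t)
    mu <- R %*% t(P)                        # n x d
    Clong[G$idx] <- -0.5 * (G$m * log(2 * pi) + 2 * sum(log(diag(ch))) +
                            rowSums((R %*% Vinv) * R))
    fill(G$idx, mu, L)
  }
  list(B0 = B0, B1 = B1, Clong = Clong)
}

# Unconstrained parameter vector layout (centered-age gamma, spline coefs
# on the centered scale):
#   beta0 beta1 | log sd0 [log sd1 atanh rho] log sigma | gamma_c (3) |
#   alpha (1-2) | xi_c (K)
theta_unpack <- function(theta, fd) {
  i <- 2
  beta <- theta[1:2]
  sd0 <- exp(theta[i + 1])
  if (fd$re_dim == 2) {
    sd1 <- exp(theta[i + 2]); rho <- tanh(theta[i + 3]); i <- i + 3
  } else { sd1 <- 0; rho <- 0; i <- i + 1 }
  sigma <- exp(theta[i + 1]); i <- i + 1
  gamma_c <- theta[i + 1:3]; i <- i + 3
  alpha <- theta[i + seq_len(fd$n_alpha)]; i <- i + fd$n_alpha
  xi_c <- theta[i + seq_len(fd$K)]
  od <- rho * sd0 * sd1
  list(beta = beta, sd0 = sd0, sd1 = sd1, rho = rho, sigma = sigma,
       D = matrix(c(sd0^2, od, od, sd1^2), 2),
       gamma_c = gamma_c, alpha = alpha, xi_c = xi_c)
}

theta_pack <- function(beta, sd0, sd1, rho, sigma, gamma_c, alpha, xi_c,
                       re_dim) {
  vp <- if (re_dim == 2) c(log(sd0), log(sd1), atanh(rho), log(sigma))
        else c(log(sd0), log(sigma))
  unname(c(beta, vp, gamma_c, alpha, xi_c))
}

# Natural-scale parameter vector (for delta-method SEs and reporting).
theta_natural <- function(theta, fd) {
  p <- theta_unpack(theta, fd)
  gamma <- c(p$gamma_c[1] - fd$age_center * p$gamma_c[3], p$gamma_c[2],
             p$gamma_c[3])
  xi <- p$xi_c - fd$age_center * p$gamma_c[2]
  out <- c(p$beta, p$sd0, p$sd1, p$rho, p$sigma, gamma, p$alpha, xi)
  names(out) <- c("beta0", "beta1", "sd_b0", "sd_b1", "corr_b", "sigma",
                  "gamma_sex", "gamma_age0", "gamma_sex_age0",
                  paste0("alpha", seq_len(fd$n_alpha)),
                  paste0("xi", seq_len(fd$K)))
  out
}

# Cohort log-likelihood via the compiled kernel; returns per-subject vector.
joint_loglik_vec <- function(theta, fd) {
  p <- theta_unpack(theta, fd)
  pn <- posterior_nodes(p$beta, p$D, p$sigma, fd)
  if (is.null(pn)) return(rep(-Inf, fd$N))
  loghq <- matrix(fd$Bq %*% p$xi_c, fd$N)
  loghT <- drop(fd$BT %*% p$xi_c)
  gw <- drop(fd$Wc %*% p$gamma_c)
  A0q <- p$alpha[1] * fd$P0q[[1]]; A1q <- p$alpha[1] * fd$P1q[[1]]
  A0T <- p$alpha[1] * fd$P0T[[1]]; A1T <- p$alpha[1] * fd$P1T[[1]]
  if (fd$n_alpha == 2) {
    A0q <- A0q + p$alpha[2] * fd$P0q[[2]]
    A1q <- A1q + p$alpha[2] * fd$P1q[[2]]
    A0T <- A0T + p$alpha[2] * fd$P0T[[2]]
    A1T <- A1T + p$alpha[2] * fd$P1T[[2]]
  }
  joint_subject_loglik_cpp(p$beta[1], p$beta[2], pn$Clong, fd$delta, gw,
                           fd$Vw, loghq, loghT, A0q, A1q, A0T, A1T,
                           pn$B0, pn$B1, fd$logwt)
}

#' Fit the joint model by maximum likelihood
#'
#' Maximizes the sum of [subject_loglik()] contributions over the cohort by
#' quasi-Newton (BFGS) search on an unconstrained parameterization (log
#' SDs, atanh correlation, log residual SD).  The random effects are
#' integrated by adaptive Gauss-Hermite quadrature: the Gaussian
#' longitudinal factor is integrated analytically at the current
#' parameters (exact subject posteriors \eqn{b \mid y}), and the grid —
#' recentred and rescaled through those posteriors at every evaluation —
#' handles only the smooth survival correction.  The baseline log-hazard
#' is a cubic B-spline whose coefficients are estimated jointly.  Standard
#' errors come from the numerically differentiated observed information.
#'
#' Initialization uses the separate longitudinal fit ([fit_lmm()]) and a
#' parametric spline survival fit ([fit_survival_spline()]) with
#' \eqn{\alpha = 0}.
#'
#' @param cohort a [claims_cohort()] with at least one observed death.
#' @param random_slope random intercept + slope (default) or intercept
#'   only.
#' @param mode association-feature mode (see [association_feature()]).
#' @param weight a [weight_function()].
#' @param n_knots interior knots for the baseline spline; default scales
#'   with the number of observed deaths (one knot per ~20 events, capped
#'   at 5).
#' @param ghq_nodes Gauss-Hermite nodes per random-effect dimension
#'   (default 9).
#' @param quad_n outer Gauss-Legendre size for cumulative hazards
#'   (default 7).
#' @param init optional list with components \code{lmm} (a [fit_lmm()]
#'   result) and/or \code{surv} (a [fit_survival_spline()] result) to skip
#'   the separate fits; \code{theta} (full unconstrained vector) overrides
#'   everything.
#' @param hessian compute the observed information (default TRUE; skipping
#'   it saves time in simulation studies that only need point estimates).
#' @param control optimizer control (\code{maxit}, \code{reltol}).
#' @return Object of class \code{"jm_joint_fit"} with \code{params} (a
#'   [joint_model_params()]), \code{estimates} (named natural-scale
#'   vector), \code{se}, \code{vcov} (natural scale), \code{loglik},
#'   \code{aic}, \code{n_subjects}, \code{convergence} and internal
#'   machinery for prediction.
#' @export
fit_joint <- function(cohort, random_slope = TRUE,
                      mode = c("weighted-cumulative", "current-value",
                               "current-value-plus-slope"),
                      weight = weight_function(), n_knots = NULL,
                      ghq_nodes = 9, quad_n = 7, init = NULL,
                      hessian = TRUE,
                      control = list(maxit = 400, reltol = 1e-10)) {
  mode <- match.arg(mode)
  s <- cohort$subjects
  n_events <- sum(s$delta)
  if (n_events < 1)
    jm_stop("jmclaims_no_events", "no observed deaths: cannot fit the joint model")
  if (is.null(n_knots)) n_knots <- max(1, min(5, n_events %/% 20))

  lmm <- init$lmm %||% fit_lmm(cohort, random_slope = random_slope)
  tau <- max(s$T_obs)
  knots <- default_knots(s$T_obs[s$delta == 1], n_knots, c(0, tau))
  surv0 <- init$surv %||% fit_survival_spline(cohort, knots = knots,
                                              quad_n = 15)
  fd <- joint_fit_data(cohort, weight, mode, knots, c(0, tau), random_slope,
                       ghq_nodes, quad_n)
  re_dim <- fd$re_dim
  a_c <- fd$age_center
  gamma_c0 <- c(surv0$gamma[1] + a_c * surv0$gamma[3], surv0$gamma[2],
                surv0$gamma[3])
  xi_c0 <- surv0$baseline$coefs + a_c * surv0$gamma[2]
  theta0 <- init$theta %||% theta_pack(
    lmm$beta, max(lmm$sd_b0, 1e-3),
    max(lmm$sd_b1, 1e-3), lmm$corr_b, max(lmm$sigma, 1e-3),
    gamma_c0, rep(0, fd$n_alpha), xi_c0, re_dim)

  nll <- function(theta) {
    v <- -sum(joint_loglik_vec(theta, fd))
    if (!is.finite(v)) return(1e10)
    v
  }
  opt <- stats::optim(theta0, nll, method = "BFGS",
                      control = list(maxit = control$maxit %||% 400,
                                     reltol = control$reltol %||% 1e-10))
  theta_hat <- opt$par
  loglik <- -opt$value
  k <- length(theta_hat)

  vcov_unc <- vcov_nat <- se <- NULL
  info_ok <- TRUE
  if (hessian) {
    H <- stats::optimHess(theta_hat, nll,
                          control = list(ndeps = rep(1e-4, k)))
    vcov_unc <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(vcov_unc) || any(diag(vcov_unc) < 0)) {
      info_ok <- FALSE
      e <- eigen(H, symmetric = TRUE)
      ev <- ifelse(e$values > 1e-10 * max(abs(e$values)), 1 / e$values, 0)
      vcov_unc <- e$vectors %*% (t(e$vectors) * ev)
    }
    J <- num_jacobian(function(th) theta_natural(th, fd), theta_hat)
    vcov_nat <- J %*% vcov_unc %*% t(J)
    se <- sqrt(pmax(diag(vcov_nat), 0))
    names(se) <- names(theta_natural(theta_hat, fd))
  }

  nat <- theta_natural(theta_hat, fd)
  p <- theta_unpack(theta_hat, fd)
  baseline <- baseline_spline(knots, c(0, tau),
                              p$xi_c - a_c * p$gamma_c[2])
  params <- joint_model_params(
    beta = unname(nat[1:2]),
    sd_b0 = unname(nat["sd_b0"]), sd_b1 = unname(nat["sd_b1"]),
    corr_b = unname(nat["corr_b"]), sigma = unname(nat["sigma"]),
    gamma = stats::setNames(nat[c("gamma_sex", "gamma_age0",
                                  "gamma_sex_age0")],
                            c("sex", "age0", "sex_age0")),
    alpha = unname(nat[paste0("alpha", seq_len(fd$n_alpha))]),
    baseline = baseline, weight = weight, mode = mode,
    random_slope = random_slope)

  structure(list(params = params, estimates = nat, se = se,
                 vcov = vcov_nat, vcov_unc = vcov_unc,
                 theta_unc = theta_hat, fd = fd,
                 loglik = loglik, aic = -2 * loglik + 2 * k, df = k,
                 n_subjects = fd$N, n_events = n_events,
                 convergence = opt$convergence, info_ok = info_ok,
                 counts = opt$counts,
                 lmm_init = lmm, surv_init = surv0),
            class = "jm_joint_fit")
}

#' @export
print.jm_joint_fit <- function(x, ...) {
  cat(sprintf("Joint model fit (%s feature, %s)\n", x$params$mode,
              if (x$params$random_slope) "random intercept + slope"
              else "random intercept"))
  cat(sprintf("  %d subjects, %d deaths; logLik = %.3f, AIC = %.3f\n",
              x$n_subjects, x$n_events, x$loglik, x$aic))
  show <- c("beta0", "beta1", "sd_b0", "sd_b1", "corr_b", "sigma",
            "gamma_sex", "gamma_age0", "gamma_sex_age0",
            paste0("alpha", seq_len(alpha_len(x$params$mode))))
  est <- x$estimates[show]
  se <- if (!is.null(x$se)) x$se[show] else rep(NA_real_, length(show))
  for (i in seq_along(show))
    cat(sprintf("  %-14s %9.4f  (SE %s)\n", show[i], est[i],
                ifelse(is.na(se[i]), "--", sprintf("%.4f", se[i]))))
  if (x$convergence != 0) cat("  WARNING: optimizer did not report convergence\n")
  if (!x$info_ok) cat("  WARNING: information matrix not positive definite; pseudo-inverse SEs\n")
  invisible(x)
}

#' Rank candidate weight functions by AIC
#'
#' Fits one joint model per candidate kernel on the same cohort (shared
#' separate-fit initialization) and returns the candidates sorted by AIC,
#' lowest first.  A failed fit is kept in the table with \code{NA} entries
#' rather than aborting the comparison.
#'
#' @param cohort a [claims_cohort()].
#' @param candidates named list of [weight_function()] objects.
#' @param ... passed to [fit_joint()].
#' @return Data frame with columns \code{weight}, \code{family},
#'   \code{loglik}, \code{df}, \code{aic}, sorted by AIC; the fits are
#'   attached as attribute \code{"fits"}.
#' @export
compare_weightings <- function(cohort, candidates, ...) {
  if (length(candidates) < 2)
    jm_stop("jmclaims_invalid_config", "need at least 2 candidate weightings")
  if (is.null(names(candidates)))
    names(candidates) <- paste0("w", seq_along(candidates))
  lmm <- fit_lmm(cohort, random_slope = TRUE)
  fits <- lapply(candidates, function(w) {
    tryCatch(fit_joint(cohort, weight = w, init = list(lmm = lmm), ...),
             error = function(e) e)
  })
  tab <- data.frame(
    weight = names(candidates),
    family = vapply(candidates, `[[`, "", "family"),
    loglik = vapply(fits, function(f)
      if (inherits(f, "jm_joint_fit")) f$loglik else NA_real_, 0),
    df = vapply(fits, function(f)
      if (inherits(f, "jm_joint_fit")) f$df else NA_real_, 0),
    aic = vapply(fits, function(f)
      if (inherits(f, "jm_joint_fit")) f$aic else NA_real_, 0))
  tab <- tab[order(tab$aic), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Likelihood-ratio test for the random slope
#'
#' Compares nested fits with and without the subject-specific slope.  The
#' null value \eqn{\sigma_{b1} = 0} lies on the boundary of the parameter
#' space, so the statistic \eqn{2\Delta\ell} is referred to a 50:50
#' mixture of \eqn{\chi^2_1} and \eqn{\chi^2_2} (variance component plus
#' the correlation freed with it).
#'
#' @param fit_intercept_only,fit_with_slope nested fits on the same data
#'   (any objects with a \code{loglik} component).
#' @return List with \code{statistic}, \code{p_value}, \code{df_mix}.
#' @export
lrt_random_slope <- function(fit_intercept_only, fit_with_slope) {
  stat <- 2 * (fit_with_slope$loglik - fit_intercept_only$loglik)
  if (stat < -1e-4)
    jm_stop("jmclaims_lrt_negative",
            "alternative log-likelihood below null (%.4g): convergence failure",
            stat)
  stat <- max(stat, 0)
  p <- 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE) +
       0.5 * stats::pchisq(stat, 2, lower.tail = FALSE)
  list(statistic = stat, p_value = p, df_mix = "0.5*chisq(1) + 0.5*chisq(2)")
}
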