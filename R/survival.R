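#' Baseline hazard specifications
#'
#' Two baseline-hazard forms are used: a constant rate (mainly for
#' simulation and closed-form checks) and an exponentiated cubic B-spline,
#' \eqn{\log h_0(t) = \sum_k \xi_k B_k(t)}, which keeps \eqn{h_0(t) > 0}
#' by construction and is the form used inside the joint model and for
#' individualized prediction.
#'
#' @param rate constant hazard rate (1/years), \eqn{> 0}.
#' @param knots strictly increasing interior knot locations in
#'   \eqn{(0, \tau)}.
#' @param boundary boundary knots \code{c(0, tau)}.
#' @param coefs spline coefficients for \eqn{\log h_0}; length
#'   \code{length(knots) + degree + 1}.
#' @param degree spline degree (cubic, 3).
#' @return A baseline-hazard object of class \code{"jm_baseline"}.
#' @export
baseline_constant <- function(rate) {
  stopifnot(rate > 0)
  structure(list(kind = "constant", rate = rate),
            class = c("jm_baseline_constant", "jm_baseline"))
}

#' @rdname baseline_constant
#' @export
baseline_spline <- function(knots, boundary, coefs, degree = 3) {
  if (length(knots) && is.unsorted(knots, strictly = TRUE))
    jm_stop("jmclaims_invalid_baseline_spec", "interior knots must be strictly increasing")
  if (length(knots) && (min(knots) <= boundary[1] || max(knots) >= boundary[2]))
    jm_stop("jmclaims_invalid_baseline_spec", "interior knots must lie inside the boundary")
  k_all <- c(rep(boundary[1], degree + 1), knots, rep(boundary[2], degree + 1))
  K <- length(knots) + degree + 1
  if (length(coefs) != K)
    jm_stop("jmclaims_invalid_baseline_spec",
            "need %d spline coefficients, got %d", K, length(coefs))
  structure(list(kind = "spline", knots = knots, boundary = boundary,
                 coefs = coefs, degree = degree, knots_all = k_all),
            class = c("jm_baseline_spline", "jm_baseline"))
}

# Interior knots at equally spaced quantiles of observed event times.
default_knots <- function(event_times, n_interior = 5, boundary) {
  if (n_interior == 0) return(numeric())
  q <- stats::quantile(event_times,
                       probs = seq_len(n_interior) / (n_interior + 1),
                       names = FALSE, type = 7)
  q <- pmin(pmax(q, boundary[1] + 1e-6), boundary[2] - 1e-6)
  # collapse numerically tied quantiles (heavy ties at yearly granularity)
  unique(sort(q))
}

# B-spline basis matrix at times t (rows), clamped evaluation not allowed.
spline_basis <- function(baseline, t) {
  b <- baseline$boundary
  if (any(t < b[1] - 1e-9 | t > b[2] + 1e-9))
    jm_stop("jmclaims_outside_boundary",
            "time outside the baseline boundary [%g, %g]", b[1], b[2])
  t <- pmin(pmax(t, b[1]), b[2])
  splines::splineDesign(baseline$knots_all, t, ord = baseline$degree + 1)
}

#' Log baseline hazard
#'
#' Evaluates \eqn{\log h_0(t)} for a baseline-hazard object.  Spline
#' baselines are only defined on their boundary interval \eqn{[0, \tau]};
#' evaluation outside it is an error.
#'
#' @param baseline a [baseline_constant()] or [baseline_spline()].
#' @param t vector of times in years.
#' @return Vector of \eqn{\log h_0(t)} values.
#' @export
spline_log_hazard <- function(baseline, t) {
  if (baseline$kind == "constant") return(rep(log(baseline$rate), length(t)))
  drop(spline_basis(baseline, t) %*% baseline$coefs)
}

#' Separate Cox proportional-hazards fit on baseline covariates
#'
#' Fits \eqn{h_i(t \mid w_i) = h_0(t) \exp(\gamma^T w_i)} with
#' \eqn{w_i = (\mathrm{sex}, \mathrm{age0}, \mathrm{sex}\times\mathrm{age0})}
#' by Cox partial likelihood (Efron tie handling), leaving the baseline
#' unspecified, as in a conventional separate survival analysis.
#'
#' @param cohort a [claims_cohort()] with at least one observed death.
#' @return List of class \code{"jm_cox_fit"} with \code{gamma} (named
#'   coefficients), \code{se}, \code{vcov}, \code{loglik} (partial) and the
#'   underlying \code{\link[survival]{coxph}} fit in \code{fit}.
#' @export
fit_cox_separate <- function(cohort) {
  s <- cohort$subjects
  if (sum(s$delta) < 1)
    jm_stop("jmclaims_no_events", "no observed deaths: cannot fit the survival model")
  fit <- survival::coxph(
    survival::Surv(T_obs, delta) ~ sex + age0 + sex:age0,
    data = s, ties = "efron")
  if (any(!is.finite(fit$coefficients)) || any(sqrt(diag(fit$var)) > 1e3))
    warning("possible monotone likelihood (complete separation) in the Cox fit")
  structure(list(gamma = stats::setNames(fit$coefficients,
                                         c("sex", "age0", "sex_age0")),
                 se = sqrt(diag(fit$var)),
                 vcov = fit$var,
                 loglik = fit$loglik[2],
                 fit = fit),
            class = "jm_cox_fit")
}

#' Hazard ratio from a log-hazard coefficient
#'
#' @param coef log-hazard-scale coefficient.
#' @return List with \code{hr} \eqn{= e^{\mathrm{coef}}},
#'   \code{pct_lower} \eqn{= (1 - e^{\mathrm{coef}}) \cdot 100} (risk
#'   reduction when the ratio is below one) and \code{pct_change}
#'   \eqn{= (e^{\mathrm{coef}} - 1) \cdot 100}.
#' @examples
#' hazard_ratio(-0.722)  # hr 0.486, 51.4% lower
#' @export
hazard_ratio <- function(coef) {
  stopifnot(is.finite(coef))
  hr <- exp(coef)
  list(hr = hr, pct_lower = (1 - hr) * 100, pct_change = (hr - 1) * 100)
}

#' Cumulative hazard by quadrature
#'
#' Computes \eqn{\Lambda(t) = \int_0^t h_0(s) \exp(\gamma^T w +
#' g(s))\, ds} by Gauss-Legendre quadrature, where \eqn{g} is an optional
#' time-varying log-hazard offset (typically \eqn{\alpha F(m_i(s))}, the
#' scaled association feature).
#'
#' @param baseline a baseline-hazard object.
#' @param gamma survival coefficients.
#' @param w_cov covariate vector, same length as \code{gamma}.
#' @param t upper limit (scalar, years, \eqn{\ge 0}).
#' @param feature_fn optional vectorized function of time returning the
#'   log-hazard offset \eqn{g(s)}; default none.
#' @param quad_n number of quadrature nodes per smooth segment (default
#'   15).  For spline baselines the integral is evaluated piecewise
#'   between knots, where the integrand is smooth.
#' @return Scalar \eqn{\Lambda(t)}.
#' @export
cumulative_hazard <- function(baseline, gamma, w_cov, t, feature_fn = NULL,
                              quad_n = 15) {
  stopifnot(length(t) == 1L, t >= 0)
  if (t == 0) return(0)
  cuts <- if (baseline$kind == "spline")
    baseline$knots[baseline$knots < t] else numeric()
  edges <- c(0, cuts, t)
  nodes <- wts <- vector("list", length(edges) - 1)
  for (j in seq_len(length(edges) - 1)) {
    r <- gl_rule(quad_n, edges[j], edges[j + 1])
    nodes[[j]] <- r$x; wts[[j]] <- r$w
  }
  x <- unlist(nodes); wq <- unlist(wts)
  lh <- spline_log_hazard(baseline, x) + sum(gamma * w_cov)
  if (!is.null(feature_fn)) lh <- lh + feature_fn(x)
  if (any(!is.finite(lh)))
    jm_stop("jmclaims_quadrature_failure", "non-finite integrand in cumulative hazard")
  sum(wq * exp(lh))
}

#' Parametric survival fit with a spline log-baseline
#'
#' Maximizes the full parametric survival likelihood
#' \eqn{\sum_i \delta_i \log h_i(T_i) - \Lambda_i(T_i)} with
#' \eqn{\log h_i(t) = \log h_0(t) + \gamma^T w_i} and a cubic B-spline
#' \eqn{\log h_0}.  Used to initialize the joint fit and wherever an
#' explicit baseline is needed for a covariates-only model.
#'
#' @param cohort a [claims_cohort()].
#' @param n_knots number of interior knots (quantiles of event times).
#' @param knots explicit interior knot locations, overriding \code{n_knots}.
#' @param quad_n quadrature size for each subject's cumulative hazard.
#' @return List of class \code{"jm_spline_surv_fit"} with \code{gamma},
#'   \code{baseline} (a [baseline_spline()]), \code{loglik} and
#'   \code{convergence}.
#' @export
fit_survival_spline <- function(cohort, n_knots = 2, knots = NULL,
                                quad_n = 15) {
  s <- cohort$subjects
  if (sum(s$delta) < 1)
    jm_stop("jmclaims_no_events", "no observed deaths: cannot fit the survival model")
  tau <- max(s$T_obs)
  if (is.null(knots))
    knots <- default_knots(s$T_obs[s$delta == 1], n_knots, c(0, tau))
  K <- length(knots) + 4
  # optimize with age0 centred at 75 (the baseline level and the age slope
  # are near-collinear otherwise); the shift is undone exactly below using
  # the partition-of-unity property of the B-spline basis
  a_c <- 75
  W <- cbind(s$sex, s$age0 - a_c, s$sex * (s$age0 - a_c))
  base0 <- baseline_spline(knots, c(0, tau), rep(0, K))
  # precompute spline bases at per-subject quadrature nodes and at T_obs
  r <- gl_rule(quad_n, -1, 1)
  half <- s$T_obs / 2
  Snod <- outer(half, r$x + 1)               # n x Q nodes on [0, T_i]
  Vw <- outer(half, r$w)
  Bq <- spline_basis(base0, as.vector(Snod)) # (n*Q) x K
  BT <- spline_basis(base0, s$T_obs)
  n <- nrow(s); Q <- quad_n
  grp <- rep(seq_len(n), times = Q)
  nll <- function(par) {
    xi <- par[seq_len(K)]
    gam <- par[K + 1:3]
    eta <- drop(W %*% gam)
    lh_T <- drop(BT %*% xi) + eta
    lam_nodes <- exp(drop(Bq %*% xi) + eta[grp]) * as.vector(Vw)
    Lam <- rowsum(lam_nodes, grp)
    val <- -(sum(s$delta * lh_T) - sum(Lam))
    if (!is.finite(val)) return(1e10)
    val
  }
  crude <- log(sum(s$delta) / sum(s$T_obs))
  init <- c(rep(crude, K), 0, 0, 0)
  opt <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  gam_c <- opt$par[K + 1:3]
  gamma <- c(sex = gam_c[1] - a_c * gam_c[3], age0 = gam_c[2],
             sex_age0 = gam_c[3])
  xi <- opt$par[seq_len(K)] - a_c * gam_c[2]
  structure(list(gamma = gamma,
                 baseline = baseline_spline(knots, c(0, tau), xi),
                 loglik = -opt$value,
                 convergence = opt$convergence),
            class = "jm_spline_surv_fit")
}
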