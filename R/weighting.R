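#' Fading weight kernels for recency-weighted cumulative effects
#'
#' A weight function \eqn{\bar w(u)} describes how strongly the expected
#' claims trajectory a lag \eqn{u} years in the past contributes to the
#' current death hazard.  The cumulative weighted effect of a trajectory
#' \eqn{m(\cdot)} is
#' \deqn{F(t) = \int_0^t \bar w(t - s)\, m(s)\, ds,}
#' so recent demand for care can weigh more heavily than old demand.
#'
#' Three families are supported:
#' \describe{
#'   \item{exponential}{\eqn{\bar w(u) = \lambda e^{-\lambda u}}, with decay
#'     rate \code{rate}\eqn{= \lambda > 0}.  Instead of \code{rate} the
#'     share \code{p} of total weight carried by the most recent year may be
#'     given, in which case \eqn{\lambda = -\log(1 - p)}.}
#'   \item{uniform}{\eqn{\bar w(u) = 1/L} for \eqn{u < L}, zero beyond the
#'     window length \code{window}\eqn{= L}.}
#'   \item{linear-decay}{\eqn{\bar w(u) = 2(L - u)/L^2} for \eqn{u < L}.}
#' }
#' All families integrate to one over \eqn{[0, \infty)}.  With
#' \code{normalize = "[0,t]"} the kernel is renormalized at every evaluation
#' time so that the weight actually placed on \eqn{[0, t]} integrates to
#' one, which matters early in follow-up when the kernel mass extends
#' beyond the observed history.
#'
#' @param family kernel family, one of \code{"exponential"},
#'   \code{"uniform"}, \code{"linear-decay"}.
#' @param rate exponential decay rate \eqn{\lambda} (1/years).
#' @param window window length \eqn{L} in years (uniform / linear-decay).
#' @param p for the exponential family, the weight share of the most recent
#'   year; used to derive \code{rate} when \code{rate} is missing.
#'   Default 0.95.
#' @param normalize \code{"[0,Inf)"} (default) or \code{"[0,t]"}.
#' @return An object of class \code{"jm_weight"}.
#' @examples
#' w <- weight_function("exponential", p = 0.95)
#' weight_value(w, 0:3)
#' @export
weight_function <- function(family = c("exponential", "uniform", "linear-decay"),
                            rate = NULL, window = NULL, p = NULL,
                            normalize = c("[0,Inf)", "[0,t]")) {
  family <- match.arg(family)
  normalize <- match.arg(normalize)
  if (family == "exponential") {
    if (is.null(rate)) {
      if (is.null(p)) p <- 0.95
      stopifnot(p > 0, p < 1)
      rate <- -log(1 - p)
    }
    if (rate <= 0) jm_stop("jmclaims_invalid_weight", "exponential rate must be > 0")
    window <- NULL
  } else {
    if (is.null(window)) window <- 1
    if (window <= 0) jm_stop("jmclaims_invalid_weight", "window length must be > 0")
    rate <- NULL
  }
  structure(list(family = family, rate = rate, window = window,
                 normalize = normalize),
            class = "jm_weight")
}

#' @export
print.jm_weight <- function(x, ...) {
  par <- if (x$family == "exponential") sprintf("rate = %.4g", x$rate)
         else sprintf("window = %.4g yr", x$window)
  cat(sprintf("<weight kernel: %s, %s, normalized over %s>\n",
              x$family, par, x$normalize))
  invisible(x)
}

#' Evaluate a weight kernel density
#'
#' Returns the kernel density \eqn{\bar w(u)} at elapsed-time lags \code{u}
#' (years), under the over-\eqn{[0,\infty)} normalization.  Per-time
#' renormalization for \code{"[0,t]"} kernels is applied inside
#' [cumulative_weighted_effect()], not here.
#'
#' @param w a [weight_function()] object.
#' @param u vector of nonnegative lags in years.
#' @return Vector of density values.
#' @export
weight_value <- function(w, u) {
  if (any(u < 0)) jm_stop("jmclaims_invalid_weight", "lag u must be nonnegative")
  switch(w$family,
    "exponential"  = w$rate * exp(-w$rate * u),
    "uniform"      = ifelse(u < w$window, 1 / w$window, 0),
    "linear-decay" = ifelse(u < w$window, 2 * (w$window - u) / w$window^2, 0))
}

# Kernel mass \int_0^u w(v) dv, closed form; used for [0,t] renormalization.
weight_mass <- function(w, u) {
  u <- pmax(u, 0)
  switch(w$family,
    "exponential"  = 1 - exp(-w$rate * u),
    "uniform"      = pmin(u / w$window, 1),
    "linear-decay" = {
      v <- pmin(u, w$window)
      (2 * w$window * v - v^2) / w$window^2
    })
}

#' Recency-weighted cumulative effect of a trajectory
#'
#' Computes \eqn{F(t) = \int_0^t \bar w(t-s) m(s) ds} by Gauss-Legendre
#' quadrature on \eqn{[0, t]}.  The result is deterministic given the
#' quadrature size.
#'
#' @param m a function of one argument (time in years) returning the
#'   trajectory value; must be vectorized over its argument.
#' @param w a [weight_function()].
#' @param t evaluation time (scalar, years, \eqn{\ge 0}).
#' @param quad_n number of Gauss-Legendre nodes (default 15).
#' @return Scalar \eqn{F(t)}; 0 when \code{t == 0}.
#' @examples
#' w <- weight_function("exponential", rate = 3)
#' cumulative_weighted_effect(function(s) rep(1, length(s)), w, 5)
#' 1 - exp(-15)  # closed form for a constant trajectory
#' @export
cumulative_weighted_effect <- function(m, w, t, quad_n = 15) {
  stopifnot(length(t) == 1L, t >= 0)
  if (t == 0) return(0)
  # windowed kernels vanish at lags beyond the window: integrate only over
  # the kernel support so the rule never straddles the cut-off
  lo <- if (is.null(w$window)) 0 else max(0, t - w$window)
  r <- gl_rule(quad_n, lo, t)
  ms <- m(r$x)
  if (any(!is.finite(ms)))
    jm_stop("jmclaims_bad_trajectory", "trajectory not evaluable on [0, t]")
  val <- sum(r$w * weight_value(w, t - r$x) * ms)
  if (w$normalize == "[0,t]") {
    mass <- weight_mass(w, t)
    if (mass > 0) val <- val / mass
  }
  val
}

# Feature basis for a *linear* trajectory m(s) = a + c s: returns phi0(s),
# phi1(s) with  F(m)(s) = a * phi0(s) + c * phi1(s).  For the weighted-
# cumulative feature, phi0(s) = int_0^s wbar(s-v) dv and
# phi1(s) = int_0^s wbar(s-v) v dv, both by Gauss-Legendre (vectorized over
# s).  For current-value, (1, s); for the slope component, (0, 1).
kernel_feature_basis <- function(w, s, quad_n = 15) {
  n <- length(s)
  phi0 <- numeric(n); phi1 <- numeric(n)
  pos <- which(s > 0)
  if (length(pos)) {
    base <- gl_rule(quad_n, -1, 1)
    lo <- if (is.null(w$window)) rep(0, length(pos))
          else pmax(0, s[pos] - w$window)
    half <- (s[pos] - lo) / 2
    # nodes v[i, q] on [lo_i, s_i] (the kernel support); lags s_i - v
    V <- lo + outer(half, base$x + 1)
    Wt <- outer(half, base$w)
    lag <- s[pos] - V
    K <- matrix(weight_value(w, as.vector(lag)), nrow = length(pos))
    phi0[pos] <- rowSums(Wt * K)
    phi1[pos] <- rowSums(Wt * K * V)
    if (w$normalize == "[0,t]") {
      mass <- weight_mass(w, s[pos])
      ok <- mass > 0
      phi0[pos][ok] <- phi0[pos][ok] / mass[ok]
      phi1[pos][ok] <- phi1[pos][ok] / mass[ok]
    }
  }
  list(phi0 = phi0, phi1 = phi1)
}

#' Association feature entering the hazard
#'
#' Evaluates the scalar(s) through which the longitudinal process enters
#' the log hazard, for a subject with random effects \code{b_pair} under
#' fixed effects \code{beta}:
#' \itemize{
#'   \item \code{"weighted-cumulative"}: \eqn{F(m_i(t))}, the recency-weighted
#'     cumulative effect of the expected trajectory;
#'   \item \code{"current-value"}: \eqn{m_i(t)} itself;
#'   \item \code{"current-value-plus-slope"}: the pair
#'     \eqn{(m_i(t), dm_i(t)/dt)}, each with its own association
#'     coefficient in the joint model.
#' }
#'
#' @param beta fixed effects \code{c(intercept, slope)}.
#' @param b_pair random effects \code{c(b0, b1)}.
#' @param t time in years.
#' @param mode feature mode (see above).
#' @param w [weight_function()], required for \code{"weighted-cumulative"}.
#' @param quad_n Gauss-Legendre size for the cumulative feature.
#' @return Numeric vector of length 1 (or 2 for the value-plus-slope mode).
#' @export
association_feature <- function(beta, b_pair, t,
                                mode = c("weighted-cumulative", "current-value",
                                         "current-value-plus-slope"),
                                w = weight_function(), quad_n = 15) {
  mode <- match.arg(mode)
  a <- beta[1] + b_pair[1]
  c1 <- beta[2] + b_pair[2]
  m <- function(s) a + c1 * s
  switch(mode,
    "weighted-cumulative" = cumulative_weighted_effect(m, w, t, quad_n),
    "current-value" = m(t),
    "current-value-plus-slope" = c(value = m(t), slope = c1))
}
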