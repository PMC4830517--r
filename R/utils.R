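## Internal numerical helpers shared across modules.

#' @useDynLib jmclaims, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Gauss-Legendre rule on [a, b]; nodes/weights cached per n.
.gl_cache <- new.env(parent = emptyenv())

gl_rule <- function(n, a, b) {
  key <- as.character(n)
  base <- .gl_cache[[key]]
  if (is.null(base)) {
    base <- pracma::gaussLegendre(n, -1, 1)
    .gl_cache[[key]] <- base
  }
  h <- (b - a) / 2
  list(x = a + h * (base$x + 1), w = h * base$w)
}

# Physicists' Gauss-Hermite rule: \int e^{-z^2} f(z) dz ~ sum w f(z).
.gh_cache <- new.env(parent = emptyenv())

gh_rule <- function(n) {
  key <- as.character(n)
  r <- .gh_cache[[key]]
  if (is.null(r)) {
    r <- pracma::gaussHermite(n)
    .gh_cache[[key]] <- r
  }
  r
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix.
row_logsumexp <- function(X) {
  m <- apply(X, 1L, max)
  ok <- is.finite(m)
  out <- m
  if (any(ok)) {
    out[ok] <- m[ok] + log(rowSums(exp(X[ok, , drop = FALSE] - m[ok])))
  }
  out
}

# Half-up rounding for printed-style summary tables (base round() is
# round-half-even, which does not reproduce typewriter tables).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

# Classed validation errors so callers can distinguish failure modes.
jm_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "jmclaims_error", "error")))
}

# Central-difference Jacobian of f: R^p -> R^q (used for delta-method SEs).
num_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  p <- length(x)
  J <- matrix(NA_real_, length(f0), p)
  for (j in seq_len(p)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# Draw n samples from N(mu, Sigma) using an eigendecomposition; tolerates
# semi-definite Sigma (negative eigenvalues are clipped at zero).
rmvnorm_eig <- function(n, mu, Sigma) {
  p <- length(mu)
  e <- eigen(Sigma, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  A <- e$vectors %*% (t(e$vectors) * sqrt(ev))
  Z <- matrix(stats::rnorm(n * p), n, p)
  sweep(Z %*% t(A), 2L, mu, "+")
}
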