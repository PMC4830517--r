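## JSON serialization of fitted models and CSV export of predictions.

#' Write a fitted joint model to JSON
#'
#' Serializes the full parameter set (natural scale), standard errors,
#' log-likelihood, AIC, the unconstrained parameter vector and its
#' covariance, and the structural specification (knots, boundary, feature
#' mode, weight kernel) needed to rebuild the fit for prediction.
#'
#' @param fit a [fit_joint()] result.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
write_joint_fit_json <- function(fit, path) {
  fd <- fit$fd
  obj <- list(
    estimates = as.list(fit$estimates),
    se = if (!is.null(fit$se)) as.list(fit$se) else NULL,
    loglik = fit$loglik, aic = fit$aic, df = fit$df,
    n_subjects = fit$n_subjects, n_events = fit$n_events,
    convergence = fit$convergence, info_ok = fit$info_ok,
    theta_unc = fit$theta_unc,
    vcov_unc = fit$vcov_unc,
    spec = list(knots = fd$knots, boundary = fd$boundary, K = fd$K,
                mode = fd$mode, random_slope = fd$random_slope,
                n_alpha = fd$n_alpha, age_center = fd$age_center,
                re_dim = fd$re_dim, ghq_nodes = fd$ghq_nodes,
                quad_n = fd$quad_n,
                weight = fit$params$weight[c("family", "rate", "window",
                                             "normalize")]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fitted joint model from JSON
#'
#' Rebuilds a lightweight fit object sufficient for [predict_survival()],
#' [prediction_error()] and [sample_theta()] (the raw data are not stored,
#' so the model cannot be refitted from it).
#'
#' @param path JSON file written by [write_joint_fit_json()].
#' @return Object of class \code{"jm_joint_fit"}.
#' @export
read_joint_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- obj$spec
  w <- sp$weight
  weight <- weight_function(w$family,
                            rate = if (w$family == "exponential") w$rate else NULL,
                            window = if (w$family != "exponential") w$window else NULL,
                            normalize = w$normalize)
  fd <- list(knots = as.numeric(sp$knots %||% numeric()),
             boundary = sp$boundary, K = sp$K, mode = sp$mode,
             random_slope = sp$random_slope, n_alpha = sp$n_alpha,
             age_center = sp$age_center, re_dim = sp$re_dim,
             ghq_nodes = sp$ghq_nodes, quad_n = sp$quad_n, weight = weight)
  theta <- as.numeric(obj$theta_unc)
  vcov_unc <- if (!is.null(obj$vcov_unc)) as.matrix(obj$vcov_unc) else NULL
  params <- params_from_theta(theta, fd)
  structure(list(params = params,
                 estimates = unlist(obj$estimates), se = unlist(obj$se),
                 vcov_unc = vcov_unc, theta_unc = theta, fd = fd,
                 loglik = obj$loglik, aic = obj$aic, df = obj$df,
                 n_subjects = obj$n_subjects, n_events = obj$n_events,
                 convergence = obj$convergence, info_ok = obj$info_ok),
            class = "jm_joint_fit")
}

#' Write a dynamic prediction to CSV
#'
#' @param pred a [predict_survival()] result.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_prediction_csv <- function(pred, path) {
  utils::write.csv(data.frame(u = pred$u_grid, mean = pred$mean,
                              median = pred$median, lower95 = pred$lower95,
                              upper95 = pred$upper95),
                   path, row.names = FALSE)
  invisible(path)
}
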