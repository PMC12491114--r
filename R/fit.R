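#' Fit a parametric survival family to (pseudo) individual patient data
#'
#' Maximum-likelihood fit under right censoring, via [flexsurv::flexsurvreg()].
#' Optimization runs on the unconstrained scale (log of positive parameters),
#' and the reported covariance matrix is on that scale, which is also the scale
#' on which the probabilistic sensitivity analysis resamples survival
#' parameters.
#'
#' @param ipd A `pseudo_ipd` (see [pseudo_ipd()]) or data frame with columns
#'   `time` and `event` (1 = event, 0 = censored).
#' @param family One of the families supported by [surv_dist()].
#' @return An object of class `surv_fit`: list with elements `distribution`
#'   (a [surv_dist] at the MLE), `loglik`, `aic`, `bic`, `vcov` (unconstrained
#'   scale), `n`, `n_events`, `converged`, and `diagnostics` (optimizer report
#'   when the fit failed).
#' @examples
#' set.seed(1)
#' ipd <- simulate_ipd(surv_dist("exponential", rate = 0.1), n = 200,
#'                     censor_at = 24)
#' fit_parametric(ipd, "exponential")$distribution
#' @export
fit_parametric <- function(ipd, family) {
  ipd <- as_pseudo_ipd(ipd)
  family <- match.arg(family, names(.dist_families))
  n_events <- sum(ipd$event == 1)
  if (n_events < 2L) {
    stop("fit_parametric: need at least 2 events", call. = FALSE)
  }
  flex_name <- c(exponential = "exp", weibull = "weibull", gamma = "gamma",
                 lognormal = "lnorm", loglogistic = "llogis",
                 gompertz = "gompertz", gengamma = "gengamma")[[family]]
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = ipd,
                          dist = flex_name),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(family = family, converged = FALSE,
                          diagnostics = conditionMessage(fit),
                          n = nrow(ipd), n_events = n_events),
                     class = "surv_fit"))
  }
  est <- fit$res[, "est"]
  # translate flexsurv parameter names to this package's vocabulary
  par_names <- .dist_families[[family]]$params
  names(est) <- par_names[match(rownames(fit$res), .flexsurv_par_names(family))]
  k <- fit$npars
  structure(list(
    distribution = do.call(surv_dist, c(list(family = family), as.list(est))),
    loglik = as.numeric(stats::logLik(fit)),
    aic = 2 * k - 2 * as.numeric(stats::logLik(fit)),
    bic = k * log(nrow(ipd)) - 2 * as.numeric(stats::logLik(fit)),
    vcov = fit$cov,
    coef_unconstrained = fit$res.t[, "est"],
    n = nrow(ipd), n_events = n_events,
    converged = TRUE, diagnostics = NULL,
    flexsurv = fit
  ), class = "surv_fit")
}

.flexsurv_par_names <- function(family) {
  switch(family,
         exponential = "rate",
         weibull = c("shape", "scale"),
         gamma = c("shape", "rate"),
         lognormal = c("meanlog", "sdlog"),
         loglogistic = c("shape", "scale"),
         gompertz = c("shape", "rate"),
         gengamma = c("mu", "sigma", "Q"))
}

#' @export
print.surv_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat(sprintf("<surv_fit> %s: DID NOT CONVERGE (%s)\n", x$family,
                x$diagnostics))
    return(invisible(x))
  }
  cat(sprintf("<surv_fit> n = %d (%d events), loglik = %.3f, AIC = %.3f, BIC = %.3f\n",
              x$n, x$n_events, x$loglik, x$aic, x$bic))
  print(x$distribution)
  invisible(x)
}

#' Fit several families and rank them by information criteria
#'
#' Convenience wrapper used for distribution selection: fits each requested
#' family to the same data and returns a ranking table by AIC (ties by BIC),
#' mirroring how base-case distributions are chosen among candidate families.
#'
#' @inheritParams fit_parametric
#' @param families Character vector of families to try.
#' @return List with `fits` (named list of `surv_fit`) and `ranking`
#'   (data frame with family, loglik, aic, bic, sorted by AIC).
#' @export
fit_families <- function(ipd, families = c("exponential", "weibull", "gamma",
                                           "lognormal", "loglogistic",
                                           "gompertz")) {
  fits <- lapply(families, function(f) fit_parametric(ipd, f))
  names(fits) <- families
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  ranking <- data.frame(
    family = families[ok],
    loglik = vapply(fits[ok], `[[`, numeric(1), "loglik"),
    aic = vapply(fits[ok], `[[`, numeric(1), "aic"),
    bic = vapply(fits[ok], `[[`, numeric(1), "bic"),
    row.names = NULL)
  ranking <- ranking[order(ranking$aic, ranking$bic), ]
  list(fits = fits, ranking = ranking)
}
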