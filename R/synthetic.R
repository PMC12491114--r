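#' Simulate pseudo-IPD from a survival law
#'
#' Inverse-CDF sampling of event times from any [surv_dist] or
#' [surv_piecewise], with administrative right censoring: times beyond
#' `censor_at` are recorded as censored at `censor_at`. This stands in for
#' the published trial curves (and, downstream, the claims data) so the whole
#' reconstruction/fitting chain is testable without external data.
#'
#' @param dist A [surv_dist] or [surv_piecewise] truth law.
#' @param n Number of subjects.
#' @param censor_at Administrative censoring time in months (`Inf` for none).
#' @param seed Optional integer seed for reproducibility.
#' @return A [pseudo_ipd] with attribute `"recipe"` recording the inputs.
#' @examples
#' ipd <- simulate_ipd(surv_dist("exponential", rate = 0.1), 100,
#'                     censor_at = 24, seed = 7)
#' mean(ipd$event)   # share of observed events within 24 months
#' @export
simulate_ipd <- function(dist, n, censor_at = Inf, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  t_event <- quantile_surv(dist, u)
  time <- pmin(t_event, censor_at)
  event <- as.integer(t_event <= censor_at)
  out <- pseudo_ipd(time, event)
  attr(out, "recipe") <- list(dist = dist_to_list(dist), n = n,
                              censor_at = censor_at, seed = seed)
  out
}

#' Build a digitized-KM fixture from pseudo-IPD
#'
#' Emulates the digitization step applied to published survival figures:
#' computes the product-limit curve, samples it on a regular grid, attaches a
#' numbers-at-risk table at the stated interval, and optionally adds small
#' noise (snapped back to monotone) to mimic plot-reading error.
#'
#' @param ipd A [pseudo_ipd].
#' @param grid_step Sampling grid step in months.
#' @param risk_interval Spacing of the numbers-at-risk table in months.
#' @param jitter_sd Standard deviation of additive digitization noise on the
#'   survival scale (0 = exact readings).
#' @param seed Optional seed for the jitter.
#' @return A [digitized_km] with attribute `"recipe"`.
#' @export
make_km_fixture <- function(ipd, grid_step = 1, risk_interval = 3,
                            jitter_sd = 0, seed = NULL) {
  ipd <- as_pseudo_ipd(ipd)
  stopifnot(grid_step > 0, risk_interval > 0)
  if (!is.null(seed)) set.seed(seed)
  km <- km_estimator(ipd)
  t_max <- max(ipd$time)
  grid <- seq(0, t_max, by = grid_step)
  if (grid[length(grid)] < t_max) grid <- c(grid, t_max)
  surv <- km_surv_at(km, grid)
  if (jitter_sd > 0) {
    surv <- pmin(pmax(surv + stats::rnorm(length(surv), 0, jitter_sd), 0), 1)
    surv[1] <- 1
  }
  risk_times <- seq(0, t_max, by = risk_interval)
  n_at_risk <- vapply(risk_times, function(tt) sum(ipd$time >= tt), numeric(1))
  out <- digitized_km(data.frame(time = grid, survival = surv),
                      data.frame(time = risk_times, n_at_risk = n_at_risk),
                      total_events = sum(ipd$event))
  attr(out, "recipe") <- list(grid_step = grid_step,
                              risk_interval = risk_interval,
                              jitter_sd = jitter_sd, seed = seed)
  out
}

#' Simulate right-skewed per-patient cost samples
#'
#' Gamma draws moment-matched to a (mean, SD) pair, emulating the
#' claims-derived per-state monthly cost estimates that feed the value table.
#'
#' @param mean,sd Target mean and standard deviation (EUR).
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of class `cost_samples` with attributes `"summary"`
#'   (sample mean/sd) and `"recipe"`.
#' @export
simulate_cost_samples <- function(mean, sd, n, seed = NULL) {
  g <- gamma_from_mean_sd(mean, sd)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rgamma(n, shape = g$shape, rate = g$rate)
  structure(x, class = c("cost_samples", "numeric"),
            summary = c(mean = base::mean(x), sd = stats::sd(x)),
            recipe = list(mean = mean, sd = sd, n = n, seed = seed))
}

#' Generate the full synthetic fixture suite
#'
#' Writes, for every arm and endpoint of both models, a simulated pseudo-IPD
#' CSV and the corresponding digitized-KM fixture (curve + risk table CSVs),
#' using sample sizes mirroring the source trials. Mainly a convenience for
#' inspecting the reconstruction chain on disk.
#'
#' @param out_dir Output directory (created if needed).
#' @param params A [default_parameters()] list supplying the truth laws.
#' @param n_subjects,censor_at As in [psa_survival_uncertainty()].
#' @param seed Integer seed.
#' @return Invisibly, the vector of files written.
#' @export
make_fixture_suite <- function(out_dir, params = default_parameters(),
                               n_subjects = list(
                                 model_I = c(PRLT_SoC = 551, SoC = 280),
                                 model_II = c(PRLT_SoC = 100, CBZ = 100)),
                               censor_at = c(model_I = 24, model_II = 36),
                               seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (m in names(params$survival)) {
    for (a in names(params$survival[[m]])) {
      for (ep in names(params$survival[[m]][[a]])) {
        seed <- seed + 1L
        ipd <- simulate_ipd(params$survival[[m]][[a]][[ep]],
                            n = n_subjects[[m]][[a]],
                            censor_at = censor_at[[m]], seed = seed)
        km <- make_km_fixture(ipd)
        stem <- file.path(out_dir, paste(m, a, ep, sep = "_"))
        write_pseudo_ipd(ipd, paste0(stem, "_ipd.csv"))
        write_digitized_km(km, paste0(stem, "_km.csv"),
                           paste0(stem, "_risk.csv"))
        files <- c(files, paste0(stem, c("_ipd.csv", "_km.csv", "_risk.csv")))
      }
    }
  }
  invisible(files)
}
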