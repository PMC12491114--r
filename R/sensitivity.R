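#' Moment-matched gamma and beta helpers
#'
#' `gamma_from_mean_sd()` converts the (mean, SD) pairs of the cost table to
#' gamma `shape`/`rate` by moment matching: `shape = mean^2/sd^2`,
#' `rate = mean/sd^2`. `beta_mean()` is the mean `shape1/(shape1+shape2)`
#' implied by a beta utility distribution.
#'
#' @param mean,sd Positive mean and standard deviation in EUR.
#' @return `gamma_from_mean_sd()`: list with `shape` and `rate`.
#' @examples
#' g <- gamma_from_mean_sd(7340, 2942)
#' g$shape / g$rate          # 7340, the mean, recovered analytically
#' @export
gamma_from_mean_sd <- function(mean, sd) {
  if (any(mean <= 0) || any(sd <= 0)) {
    stop("gamma_from_mean_sd: mean and sd must be positive", call. = FALSE)
  }
  list(shape = mean^2 / sd^2, rate = mean / sd^2)
}

#' @rdname gamma_from_mean_sd
#' @param shape1,shape2 Positive beta shape parameters.
#' @export
beta_mean <- function(shape1, shape2) shape1 / (shape1 + shape2)

#' Run both arms of a model and compare them
#'
#' Convenience wrapper: builds and runs the intervention (PRLT plus SoC) and
#' comparator arm of the requested model and returns the incremental
#' comparison with both outcomes attached.
#'
#' @param model `"I"` or `"II"`.
#' @param params A [default_parameters()] list (possibly modified).
#' @param ... Passed to [build_model_I()] / [build_model_II()] (e.g.
#'   `horizon`, `annual_discount`, `third_line_mix`).
#' @return An `incremental_result` (intervention vs comparator).
#' @export
run_model_pair <- function(model = c("I", "II"), params = default_parameters(),
                           ...) {
  model <- match.arg(model)
  if (model == "I") {
    int <- run_strategy(build_model_I("PRLT_SoC", params, ...))
    cmp <- run_strategy(build_model_I("SoC", params, ...))
    labels <- c("PRLT plus SoC", "SoC alone")
  } else {
    int <- run_strategy(build_model_II("PRLT_SoC", params, ...))
    cmp <- run_strategy(build_model_II("CBZ", params, ...))
    labels <- c("PRLT plus SoC", "cabazitaxel")
  }
  compare_strategies(int, cmp, labels = labels)
}

# every cost/utility parameter path relevant for a model (Model II inherits
# the third-line values from the model_I table)
.value_paths <- function(params, model) {
  groups <- if (model == "I") "model_I" else c("model_II", "model_I")
  out <- list()
  for (g in groups) {
    for (a in names(params$values[[g]])) {
      for (s in names(params$values[[g]][[a]])) {
        out[[length(out) + 1L]] <- c("values", g, a, s)
      }
    }
  }
  out
}

.get_path <- function(params, path) params[[path[1]]][[path[2]]][[path[3]]][[path[4]]]
.set_path <- function(params, path, field, value) {
  params[[path[1]]][[path[2]]][[path[3]]][[path[4]]][[field]] <- value
  params
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Perturbs one parameter at a time — each state cost to 50%/150% of base,
#' each state utility to 75%/125% (clamped at 1 with a warning), the discount
#' rate to 0%/5% and the horizon to 84/120 cycles — recomputes the
#' incremental comparison, and returns the tornado table ordered by the
#' absolute ICER spread. The ICER columns carry the signed ratio
#' `delta_cost/delta_effect` so that dominant results remain plottable.
#'
#' @inheritParams run_model_pair
#' @param include_config Also vary discount rate and horizon (default TRUE).
#' @return A data frame of class `dsa_result`: `parameter`, `base`, `low`,
#'   `high`, `icer_base`, `icer_low`, `icer_high`, `spread`, sorted by
#'   decreasing `spread`.
#' @export
run_dsa <- function(model = c("I", "II"), params = default_parameters(),
                    include_config = TRUE) {
  model <- match.arg(model)
  base <- run_model_pair(model, params)
  icer_of <- function(r) r$delta_cost / r$delta_effect
  rows <- list()
  cf <- unlist(params$dsa$cost_factor)
  uf <- unlist(params$dsa$utility_factor)
  for (path in .value_paths(params, model)) {
    entry <- .get_path(params, path)
    label <- paste(path[-1], collapse = ".")
    # cost
    lo <- entry$cost * cf[1]; hi <- entry$cost * cf[2]
    r_lo <- run_model_pair(model, .set_path(params, path, "cost", lo))
    r_hi <- run_model_pair(model, .set_path(params, path, "cost", hi))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = paste0(label, ".cost"), base = entry$cost, low = lo, high = hi,
      icer_low = icer_of(r_lo), icer_high = icer_of(r_hi))
    # utility
    lo <- entry$utility * uf[1]; hi <- entry$utility * uf[2]
    if (hi > 1) {
      warning(sprintf("run_dsa: utility upper bound for %s clamped to 1", label))
      hi <- 1
    }
    r_lo <- run_model_pair(model, .set_path(params, path, "utility", lo))
    r_hi <- run_model_pair(model, .set_path(params, path, "utility", hi))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = paste0(label, ".utility"), base = entry$utility,
      low = lo, high = hi, icer_low = icer_of(r_lo), icer_high = icer_of(r_hi))
  }
  if (include_config) {
    dr <- unlist(params$dsa$discount)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = "config.annual_discount", base = params$model_config$annual_discount,
      low = dr[1], high = dr[2],
      icer_low = icer_of(run_model_pair(model, params, annual_discount = dr[1])),
      icer_high = icer_of(run_model_pair(model, params, annual_discount = dr[2])))
    hz <- unlist(params$dsa$horizon)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = "config.horizon", base = params$model_config$horizon,
      low = hz[1], high = hz[2],
      icer_low = icer_of(run_model_pair(model, params, horizon = hz[1])),
      icer_high = icer_of(run_model_pair(model, params, horizon = hz[2])))
  }
  out <- do.call(rbind, rows)
  out$icer_base <- icer_of(base)
  out$spread <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  class(out) <- c("dsa_result", "data.frame")
  out
}

#' Characterize survival-parameter uncertainty for the PSA
#'
#' The trials' patient-level data are not available, so parameter uncertainty
#' for the survival curves is rebuilt through the same chain the base-case
#' estimates came from: for each arm and endpoint, pseudo-IPD is simulated
#' from the base-case law at the trial's sample size, turned into a digitized
#' Kaplan-Meier fixture with a numbers-at-risk table, reconstructed, and the
#' base-case family refitted, yielding a covariance matrix on the
#' unconstrained (log) scale. For piecewise curves each segment is refitted
#' on its time window (first segment: times censored at the knot; later
#' segments: excess time beyond the knot among subjects still at risk).
#'
#' @param params A [default_parameters()] list.
#' @param n_subjects Named list of sample sizes per model:
#'   `model_I = c(PRLT_SoC, SoC)`, `model_II = c(PRLT_SoC, CBZ)`; defaults
#'   mirror the source trials (551/280 and 100/100).
#' @param censor_at Administrative censoring (months) per model; defaults 24
#'   (Model I trial follow-up) and 36 (Model II).
#' @param seed Integer seed; the chain is deterministic given it.
#' @return Nested list `[[model]][[arm]][[endpoint]]`, each a list of
#'   per-segment `surv_fit` objects plus the knot structure.
#' @export
psa_survival_uncertainty <- function(params = default_parameters(),
                                     n_subjects = list(
                                       model_I = c(PRLT_SoC = 551, SoC = 280),
                                       model_II = c(PRLT_SoC = 100, CBZ = 100)),
                                     censor_at = c(model_I = 24, model_II = 36),
                                     seed = 1L) {
  out <- list()
  for (m in names(params$survival)) {
    out[[m]] <- list()
    for (a in names(params$survival[[m]])) {
      out[[m]][[a]] <- list()
      for (ep in names(params$survival[[m]][[a]])) {
        truth <- params$survival[[m]][[a]][[ep]]
        seed <- seed + 1L
        n <- n_subjects[[m]][[a]]
        ipd <- simulate_ipd(truth, n = n, censor_at = censor_at[[m]],
                            seed = seed)
        km <- make_km_fixture(ipd, grid_step = 1, risk_interval = 3)
        rec <- reconstruct_ipd(km)
        out[[m]][[a]][[ep]] <- .fit_curve_segments(truth, rec)
      }
    }
  }
  structure(out, class = "psa_survival_fits")
}

# refit the family (or each piecewise segment, windowed) of `truth` to ipd
.fit_curve_segments <- function(truth, ipd) {
  if (inherits(truth, "surv_dist")) {
    return(list(knots = numeric(0),
                fits = list(fit_parametric(ipd, truth$family))))
  }
  knots <- truth$knots
  fits <- vector("list", length(truth$segments))
  bounds <- c(0, knots, Inf)
  for (j in seq_along(truth$segments)) {
    lo <- bounds[j]; hi <- bounds[j + 1]
    at_risk <- ipd$time >= lo
    t_rel <- pmin(ipd$time[at_risk], hi) - lo
    ev <- as.integer(ipd$event[at_risk] == 1 & ipd$time[at_risk] < hi)
    # windows that retain too few subjects/events at trial size cannot
    # support a refit; such segments keep their base-case parameters
    # (no sampled uncertainty) rather than an unstable fit
    keep <- t_rel > 0 | ev == 1
    fits[[j]] <- tryCatch(
      fit_parametric(pseudo_ipd(pmax(t_rel[keep], 1e-6), ev[keep]),
                     truth$segments[[j]]$family),
      error = function(e) structure(
        list(converged = FALSE, diagnostics = conditionMessage(e),
             family = truth$segments[[j]]$family),
        class = "surv_fit"))
  }
  list(knots = knots, fits = fits)
}

# draw one distribution from a fitted curve: multivariate normal on the
# unconstrained scale around the refit's own estimate shifted to the
# base-case values (so draws are centred on the published parameters)
.draw_curve <- function(truth, fitinfo) {
  draw_seg <- function(base_dist, fit) {
    if (!isTRUE(fit$converged)) return(base_dist)
    mu <- fit$coef_unconstrained
    L <- tryCatch(chol(fit$vcov), error = function(e) NULL)
    if (is.null(L)) return(base_dist)
    z <- as.numeric(mu + t(L) %*% stats::rnorm(length(mu))) - mu
    # center on the base-case parameters, perturb on the unconstrained scale
    base_u <- .params_to_unconstrained(base_dist)
    .unconstrained_to_dist(base_dist$family, base_u + z)
  }
  if (inherits(truth, "surv_dist")) {
    return(draw_seg(truth, fitinfo$fits[[1]]))
  }
  segs <- lapply(seq_along(truth$segments), function(j)
    draw_seg(truth$segments[[j]], fitinfo$fits[[j]]))
  surv_piecewise(segs, knots = truth$knots)
}

# unconstrained (flexsurv res.t) scale: log for positive parameters,
# identity for real-valued ones
.unconstrained_spec <- function(family) {
  switch(family,
         exponential = c(rate = "log"),
         weibull = c(shape = "log", scale = "log"),
         gamma = c(shape = "log", rate = "log"),
         lognormal = c(meanlog = "id", sdlog = "log"),
         loglogistic = c(shape = "log", scale = "log"),
         gompertz = c(shape = "id", rate = "log"),
         gengamma = c(mu = "id", sigma = "log", Q = "id"))
}

.params_to_unconstrained <- function(dist) {
  spec <- .unconstrained_spec(dist$family)
  vapply(names(spec), function(p) {
    v <- dist$params[[p]]
    if (spec[[p]] == "log") log(v) else v
  }, numeric(1))
}

.unconstrained_to_dist <- function(family, u) {
  spec <- .unconstrained_spec(family)
  vals <- lapply(seq_along(spec), function(i)
    if (spec[[i]] == "log") exp(u[[i]]) else u[[i]])
  names(vals) <- names(spec)
  do.call(surv_dist, c(list(family = family), vals))
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo resampling of all model inputs: state costs from gamma
#' distributions moment-matched to the cost table's mean/SD pairs, utilities
#' from the table's beta distributions, and (optionally) survival parameters
#' from multivariate normal perturbations on the unconstrained scale with
#' covariances from [psa_survival_uncertainty()]. All parameters are drawn
#' independently across arms and states. Each iteration re-runs both arms of
#' the requested model; the probabilistic incremental result is computed on
#' the iteration means.
#'
#' @inheritParams run_model_pair
#' @param n_iter Number of Monte Carlo iterations (the reference analysis
#'   uses 10,000; smaller values are fine for exploration).
#' @param seed Integer seed; results are reproducible given it.
#' @param sample_survival Draw survival parameters as well as costs/utilities.
#' @param survival_fits Optional precomputed [psa_survival_uncertainty()]
#'   result (computed on the fly when sampling survival without one).
#' @return A `psa_result`: `draws` (data frame iter/strategy/cost/qaly),
#'   `means` per strategy, `incremental` (on the means), `quadrant_shares`,
#'   and the share of iterations with positive incremental effect
#'   (`share_de_positive`).
#' @export
run_psa <- function(model = c("I", "II"), params = default_parameters(),
                    n_iter = 10000L, seed = 1L, sample_survival = TRUE,
                    survival_fits = NULL) {
  model <- match.arg(model)
  if (sample_survival && is.null(survival_fits)) {
    survival_fits <- psa_survival_uncertainty(params, seed = seed)
  }
  set.seed(seed)
  arms <- if (model == "I") c("PRLT_SoC", "SoC") else c("PRLT_SoC", "CBZ")
  mkey <- if (model == "I") "model_I" else "model_II"
  paths <- .value_paths(params, model)
  cost <- matrix(NA_real_, n_iter, 2,
                 dimnames = list(NULL, arms))
  qaly <- cost
  for (it in seq_len(n_iter)) {
    p_it <- params
    for (path in paths) {
      entry <- .get_path(params, path)
      g <- gamma_from_mean_sd(entry$cost, entry$cost_sd)
      p_it <- .set_path(p_it, path, "cost",
                        stats::rgamma(1, shape = g$shape, rate = g$rate))
      p_it <- .set_path(p_it, path, "utility",
                        stats::rbeta(1, entry$beta1, entry$beta2))
    }
    if (sample_survival) {
      groups <- if (model == "I") "model_I" else c("model_II", "model_I")
      for (g in groups) {
        for (a in names(p_it$survival[[g]])) {
          for (ep in names(p_it$survival[[g]][[a]])) {
            p_it$survival[[g]][[a]][[ep]] <-
              .draw_curve(params$survival[[g]][[a]][[ep]],
                          survival_fits[[g]][[a]][[ep]])
          }
        }
      }
    }
    for (a in arms) {
      out <- if (model == "I") run_strategy(build_model_I(a, p_it))
             else run_strategy(build_model_II(a, p_it))
      cost[it, a] <- out$total_cost
      qaly[it, a] <- out$total_qaly
    }
  }
  dc <- cost[, 1] - cost[, 2]
  de <- qaly[, 1] - qaly[, 2]
  quad <- paste0(ifelse(dc >= 0, "N", "S"), ifelse(de >= 0, "E", "W"))
  shares <- table(factor(quad, levels = c("NE", "NW", "SE", "SW"))) / n_iter
  mean_out <- function(a) structure(
    list(total_cost = mean(cost[, a]), total_qaly = mean(qaly[, a])),
    class = "econ_outcome")
  incr <- compare_strategies(mean_out(arms[1]), mean_out(arms[2]),
                             labels = arms)
  draws <- data.frame(iter = rep(seq_len(n_iter), 2),
                      strategy = rep(arms, each = n_iter),
                      cost = c(cost[, 1], cost[, 2]),
                      qaly = c(qaly[, 1], qaly[, 2]))
  structure(list(model = model, n_iter = n_iter, seed = seed,
                 draws = draws,
                 means = list(cost = colMeans(cost), qaly = colMeans(qaly)),
                 incremental = incr,
                 quadrant_shares = as.numeric(shares),
                 quadrants = names(shares),
                 share_de_positive = mean(de > 0)),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> Model %s, %d iterations (seed %d)\n",
              x$model, x$n_iter, x$seed))
  print(x$incremental)
  cat(sprintf("  quadrant shares: %s\n",
              paste(sprintf("%s %.1f%%", x$quadrants, 100 * x$quadrant_shares),
                    collapse = ", ")))
  cat(sprintf("  iterations with positive incremental effect: %.1f%%\n",
              100 * x$share_de_positive))
  invisible(x)
}

#' Scenario analyses
#'
#' Applies one of the packaged scenarios — alternative drug price or cost
#' assumptions, or a different third-line treatment mix — to the base-case
#' parameters and recomputes the incremental comparison.
#'
#' Packaged scenarios: `commercial_price` (PRLT under-treatment cost at the
#' commercial price in both models, second and third line),
#' `kreis_cbz_costs` (alternative cabazitaxel cost inputs, Model II),
#' `radium223_soc` (SoC under-treatment cost blended over a 59% Radium-223
#' subgroup, Model I), and the third-line mix variants `mix_25_75`
#' (25% SoC / 75% PRLT), `mix_100_0` (100% SoC), `mix_0_100` (100% PRLT),
#' all Model II.
#'
#' @param name Scenario name (see Details), or `"base"` for no overrides.
#' @param model `"I"` or `"II"`; defaults to the scenario's model where it is
#'   unambiguous.
#' @param params A [default_parameters()] list.
#' @return An `incremental_result` with the scenario name attached as
#'   attribute `"scenario"`.
#' @export
run_scenario <- function(name, model = NULL, params = default_parameters()) {
  if (identical(name, "base")) {
    if (is.null(model)) stop("run_scenario: model needed for 'base'", call. = FALSE)
    res <- run_model_pair(model, params)
    attr(res, "scenario") <- "base"
    return(res)
  }
  sc <- params$scenarios[[name]]
  if (is.null(sc)) {
    stop(sprintf("run_scenario: unknown scenario '%s' (available: %s)", name,
                 paste(names(params$scenarios), collapse = ", ")), call. = FALSE)
  }
  if (is.null(model)) {
    model <- if (!is.null(sc$applies_to)) sc$applies_to[[1]] else "I"
  }
  if (!is.null(sc$applies_to) && !(model %in% sc$applies_to)) {
    stop(sprintf("run_scenario: scenario '%s' applies to model(s) %s", name,
                 paste(sc$applies_to, collapse = ", ")), call. = FALSE)
  }
  p <- params
  mix <- NULL
  if (!is.null(sc$prlt_treatment_cost)) {
    p$values$model_I$PRLT_SoC$treatment$cost <- sc$prlt_treatment_cost
    p$values$model_II$PRLT_SoC$treatment$cost <- sc$prlt_treatment_cost
  }
  if (!is.null(sc$cbz_treatment_cost)) {
    p$values$model_II$CBZ$treatment$cost <- sc$cbz_treatment_cost
  }
  if (!is.null(sc$cbz_stable_cost)) {
    p$values$model_II$CBZ$stable$cost <- sc$cbz_stable_cost
  }
  if (!is.null(sc$soc_treatment_blend)) {
    b <- sc$soc_treatment_blend
    p$values$model_I$SoC$treatment$cost <-
      b$share_radium * b$cost_radium + (1 - b$share_radium) * b$cost_other
  }
  if (!is.null(sc$third_line_mix)) mix <- unlist(sc$third_line_mix)
  res <- if (is.null(mix)) run_model_pair(model, p)
         else run_model_pair(model, p, third_line_mix = mix)
  attr(res, "scenario") <- name
  res
}
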