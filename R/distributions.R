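#' Parametric survival distributions
#'
#' A `surv_dist` is a parametric accelerated-failure-time survival law used to
#' generate per-cycle transition probabilities. Time is measured in months
#' throughout the package; no unit conversion happens internally.
#'
#' Supported families and their parameterizations (matching the conventions of
#' the flexible parametric survival literature and of \pkg{flexsurv}):
#' \describe{
#'   \item{exponential}{`rate > 0`; \eqn{S(t) = e^{-\lambda t}}.}
#'   \item{weibull}{`shape > 0`, `scale > 0`; \eqn{S(t) = e^{-(t/\sigma)^k}}.}
#'   \item{gamma}{`shape > 0`, `rate > 0`; \eqn{S(t) = 1 - P(k, r t)} with
#'     \eqn{P} the regularized lower incomplete gamma function.}
#'   \item{lognormal}{`meanlog` real, `sdlog > 0`;
#'     \eqn{S(t) = 1 - \Phi((\ln t - \mu)/\sigma)}.}
#'   \item{loglogistic}{`shape > 0`, `scale > 0`;
#'     \eqn{S(t) = 1/(1 + (t/\sigma)^k)}.}
#'   \item{gompertz}{`shape` real, `rate > 0`;
#'     \eqn{S(t) = \exp(-(r/a)(e^{a t} - 1))}.}
#'   \item{gengamma}{generalized gamma in the (mu, sigma, Q) form.}
#' }
#'
#' @param family Family name, one of `"exponential"`, `"weibull"`, `"gamma"`,
#'   `"lognormal"`, `"loglogistic"`, `"gompertz"`, `"gengamma"`.
#' @param ... Named parameters for the family (see Details).
#'
#' @return An object of class `surv_dist`.
#' @examples
#' os <- surv_dist("loglogistic", shape = 1.9263, scale = 15.5377)
#' survival_prob(os, c(0, 12, 60))
#' @export
surv_dist <- function(family, ...) {
  family <- match.arg(family, names(.dist_families))
  params <- list(...)
  if (length(params) == 1L && is.null(names(params)) && is.list(params[[1]])) {
    params <- params[[1]]
  }
  spec <- .dist_families[[family]]
  missing <- setdiff(spec$params, names(params))
  if (length(missing)) {
    stop(sprintf("surv_dist('%s'): missing parameter(s) %s", family,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  params <- lapply(params[spec$params], as.numeric)
  for (p in spec$positive) {
    if (!is.finite(params[[p]]) || params[[p]] <= 0) {
      stop(sprintf("surv_dist('%s'): parameter '%s' must be positive, got %s",
                   family, p, format(params[[p]])), call. = FALSE)
    }
  }
  for (p in setdiff(spec$params, spec$positive)) {
    if (!is.finite(params[[p]])) {
      stop(sprintf("surv_dist('%s'): parameter '%s' must be finite", family, p),
           call. = FALSE)
    }
  }
  structure(list(family = family, params = params, time_unit = "months"),
            class = "surv_dist")
}

# family registry: parameter names, positivity constraints, and the p/d/q
# functions backing them (stats for the classical families, flexsurv for
# log-logistic, Gompertz and generalized gamma)
.dist_families <- list(
  exponential = list(
    params = "rate", positive = "rate",
    p = function(q, pr, ...) stats::pexp(q, pr$rate, ...),
    d = function(x, pr) stats::dexp(x, pr$rate),
    q = function(p, pr, ...) stats::qexp(p, pr$rate, ...)),
  weibull = list(
    params = c("shape", "scale"), positive = c("shape", "scale"),
    p = function(q, pr, ...) stats::pweibull(q, pr$shape, pr$scale, ...),
    d = function(x, pr) stats::dweibull(x, pr$shape, pr$scale),
    q = function(p, pr, ...) stats::qweibull(p, pr$shape, pr$scale, ...)),
  gamma = list(
    params = c("shape", "rate"), positive = c("shape", "rate"),
    p = function(q, pr, ...) stats::pgamma(q, pr$shape, rate = pr$rate, ...),
    d = function(x, pr) stats::dgamma(x, pr$shape, rate = pr$rate),
    q = function(p, pr, ...) stats::qgamma(p, pr$shape, rate = pr$rate, ...)),
  lognormal = list(
    params = c("meanlog", "sdlog"), positive = "sdlog",
    p = function(q, pr, ...) stats::plnorm(q, pr$meanlog, pr$sdlog, ...),
    d = function(x, pr) stats::dlnorm(x, pr$meanlog, pr$sdlog),
    q = function(p, pr, ...) stats::qlnorm(p, pr$meanlog, pr$sdlog, ...)),
  loglogistic = list(
    params = c("shape", "scale"), positive = c("shape", "scale"),
    p = function(q, pr, ...) flexsurv::pllogis(q, pr$shape, pr$scale, ...),
    d = function(x, pr) flexsurv::dllogis(x, pr$shape, pr$scale),
    q = function(p, pr, ...) flexsurv::qllogis(p, pr$shape, pr$scale, ...)),
  gompertz = list(
    params = c("shape", "rate"), positive = "rate",
    p = function(q, pr, ...) flexsurv::pgompertz(q, pr$shape, pr$rate, ...),
    d = function(x, pr) flexsurv::dgompertz(x, pr$shape, pr$rate),
    q = function(p, pr, ...) flexsurv::qgompertz(p, pr$shape, pr$rate, ...)),
  gengamma = list(
    params = c("mu", "sigma", "Q"), positive = "sigma",
    p = function(q, pr, ...) flexsurv::pgengamma(q, pr$mu, pr$sigma, pr$Q, ...),
    d = function(x, pr) flexsurv::dgengamma(x, pr$mu, pr$sigma, pr$Q),
    q = function(p, pr, ...) flexsurv::qgengamma(p, pr$mu, pr$sigma, pr$Q, ...))
)

#' @export
print.surv_dist <- function(x, ...) {
  cat(sprintf("<surv_dist> %s(%s)  [time in months]\n", x$family,
              paste(sprintf("%s = %g", names(x$params), unlist(x$params)),
                    collapse = ", ")))
  invisible(x)
}

#' Piecewise survival distribution
#'
#' Stitches parametric segments at the given knot times by conditional
#' survival: \eqn{S(t) = S_1(t)} for \eqn{t < k_1} and
#' \eqn{S(t) = S(k_j) S_{j+1}(t) / S_{j+1}(k_j)} beyond knot \eqn{k_j}, which
#' guarantees a continuous, non-increasing stitched survival function. This is
#' how the knotted progression-free survival curves (knot 3.6 months for the
#' standard-of-care arm, 4.5 months for cabazitaxel) are composed.
#'
#' @param segments List of [surv_dist] objects, one more than `knots`.
#' @param knots Strictly increasing cut times in months.
#' @return An object of class `surv_piecewise`.
#' @examples
#' pfs <- surv_piecewise(
#'   list(surv_dist("loglogistic", shape = 4.7332, scale = 2.3643),
#'        surv_dist("lognormal", meanlog = 2.2763, sdlog = 0.8268)),
#'   knots = 3.6)
#' survival_prob(pfs, c(3.5, 3.6, 3.7))
#' @export
surv_piecewise <- function(segments, knots = numeric(0)) {
  if (inherits(segments, "surv_dist")) segments <- list(segments)
  stopifnot(all(vapply(segments, inherits, logical(1), "surv_dist")))
  knots <- as.numeric(knots)
  if (length(segments) != length(knots) + 1L) {
    stop("surv_piecewise: need exactly one more segment than knots",
         call. = FALSE)
  }
  if (length(knots) && (any(knots <= 0) || is.unsorted(knots, strictly = TRUE))) {
    stop("surv_piecewise: knots must be positive and strictly increasing",
         call. = FALSE)
  }
  # survival at each knot under the stitched law (cumulative product of
  # conditional segment survivals); a segment exhausted at its knot cannot
  # be continued
  S_at_knots <- numeric(length(knots))
  acc <- 1
  for (j in seq_along(knots)) {
    sj <- .segment_surv(segments[[j]], knots[j])
    if (j > 1L) sj <- sj / .segment_surv(segments[[j]], knots[j - 1L])
    acc <- acc * sj
    if (acc <= 0) {
      stop(sprintf("surv_piecewise: stitched survival reaches 0 at knot %g",
                   knots[j]), call. = FALSE)
    }
    S_at_knots[j] <- acc
  }
  structure(list(segments = segments, knots = knots, S_at_knots = S_at_knots),
            class = "surv_piecewise")
}

.segment_surv <- function(dist, t) {
  spec <- .dist_families[[dist$family]]
  spec$p(t, dist$params, lower.tail = FALSE)
}

#' @export
print.surv_piecewise <- function(x, ...) {
  cat(sprintf("<surv_piecewise> %d segments, knots at %s months\n",
              length(x$segments), paste(x$knots, collapse = ", ")))
  for (s in x$segments) print(s)
  invisible(x)
}

#' Survival, density and hazard of a survival distribution
#'
#' `survival_prob()` evaluates \eqn{S(t)}; `hazard_rate()` evaluates
#' \eqn{h(t) = f(t)/S(t)} (per month). Both accept single-family
#' ([surv_dist]) and piecewise ([surv_piecewise]) laws; for piecewise laws the
#' stitched (conditional-continuation) survival is used, so values are
#' continuous across knots.
#'
#' @param dist A [surv_dist] or [surv_piecewise].
#' @param t Time(s) in months; must be non-negative (positive for the hazard).
#' @return Numeric vector of probabilities (survival) or rates per month
#'   (hazard).
#' @examples
#' d <- surv_dist("exponential", rate = 0.1)
#' survival_prob(d, 10)
#' hazard_rate(d, c(1, 5, 10))   # constant 0.1
#' @export
survival_prob <- function(dist, t) {
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("survival_prob: t must be finite and >= 0", call. = FALSE)
  }
  UseMethod("survival_prob")
}

#' @export
survival_prob.surv_dist <- function(dist, t) {
  out <- .segment_surv(dist, t)
  out[t == 0] <- 1
  out
}

#' @export
survival_prob.surv_piecewise <- function(dist, t) {
  out <- numeric(length(t))
  seg_idx <- findInterval(t, dist$knots) + 1L   # which segment governs t
  for (j in unique(seg_idx)) {
    sel <- seg_idx == j
    sj <- .segment_surv(dist$segments[[j]], t[sel])
    if (j > 1L) {
      k <- dist$knots[j - 1L]
      sj <- dist$S_at_knots[j - 1L] * sj / .segment_surv(dist$segments[[j]], k)
    }
    out[sel] <- sj
  }
  out[t == 0] <- 1
  out
}

#' @rdname survival_prob
#' @export
hazard_rate <- function(dist, t) {
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("hazard_rate: t must be finite and > 0", call. = FALSE)
  }
  UseMethod("hazard_rate")
}

#' @export
hazard_rate.surv_dist <- function(dist, t) {
  S <- survival_prob(dist, t)
  if (any(S <= 0)) {
    stop("hazard_rate: survival is 0 at some requested times", call. = FALSE)
  }
  .dist_families[[dist$family]]$d(t, dist$params) / S
}

#' @export
hazard_rate.surv_piecewise <- function(dist, t) {
  # hazard of the stitched law equals the governing segment's hazard
  seg_idx <- findInterval(t, dist$knots) + 1L
  out <- numeric(length(t))
  for (j in unique(seg_idx)) {
    sel <- seg_idx == j
    out[sel] <- hazard_rate(dist$segments[[j]], t[sel])
  }
  out
}

#' Conditional per-cycle event probability
#'
#' Probability of the event occurring in `(t0, t1]` given event-free survival
#' to `t0`: \eqn{1 - S(t_1)/S(t_0)}. This is the discretization that turns the
#' overall-survival and progression-free-survival curves into monthly
#' transition probabilities; for piecewise laws the stitched survival is used,
#' so cycles spanning a knot are handled correctly.
#'
#' @param dist A [surv_dist] or [surv_piecewise].
#' @param t0,t1 Cycle start and end in months, `0 <= t0 <= t1`.
#' @return Probability in `[0, 1]`.
#' @examples
#' conditional_event_prob(surv_dist("exponential", rate = 0.2), 3, 4)
#' 1 - exp(-0.2)   # memoryless: identical
#' @export
conditional_event_prob <- function(dist, t0, t1) {
  t0 <- as.numeric(t0); t1 <- as.numeric(t1)
  if (length(t0) != length(t1)) {
    n <- max(length(t0), length(t1))
    t0 <- rep_len(t0, n); t1 <- rep_len(t1, n)
  }
  if (any(t1 < t0)) stop("conditional_event_prob: t1 must be >= t0", call. = FALSE)
  S0 <- survival_prob(dist, t0)
  if (any(S0 <= 0)) {
    stop("conditional_event_prob: survival is 0 at cycle start", call. = FALSE)
  }
  p <- 1 - survival_prob(dist, t1) / S0
  pmin(pmax(p, 0), 1)
}

#' Quantile function of a survival distribution
#'
#' Returns the time by which a fraction `p` of subjects has had the event,
#' i.e. \eqn{S^{-1}(1-p)}. Closed-form for single families; monotone numeric
#' inversion of the stitched survival for piecewise laws. Used by the
#' synthetic-data generators for inverse-CDF sampling.
#'
#' @param dist A [surv_dist] or [surv_piecewise].
#' @param p Event probabilities in `[0, 1)`.
#' @return Times in months.
#' @export
quantile_surv <- function(dist, p) {
  p <- as.numeric(p)
  if (any(p < 0 | p >= 1)) stop("quantile_surv: p must be in [0, 1)", call. = FALSE)
  UseMethod("quantile_surv")
}

#' @export
quantile_surv.surv_dist <- function(dist, p) {
  .dist_families[[dist$family]]$q(p, dist$params)
}

#' @export
quantile_surv.surv_piecewise <- function(dist, p) {
  vapply(p, function(pi) {
    S_target <- 1 - pi
    if (pi == 0) return(0)
    # locate the governing segment via survival at the knots, then invert it
    j <- 1L
    lower <- 0
    while (j <= length(dist$knots) && dist$S_at_knots[j] > S_target) {
      lower <- dist$knots[j]
      j <- j + 1L
    }
    seg <- dist$segments[[j]]
    if (j == 1L) return(quantile_surv(seg, pi))
    # S(t) = S_at_knots[j-1] * Sj(t)/Sj(k)  =>  Sj(t) = Sj(k) * S_target/S_knot
    Sj_target <- .segment_surv(seg, lower) * S_target / dist$S_at_knots[j - 1L]
    quantile_surv(seg, 1 - Sj_target)
  }, numeric(1))
}

#' Serialize / deserialize distribution specifications
#'
#' Distributions round-trip through plain lists (`family` string plus named
#' parameters, with `knots` + `segments` for piecewise laws), the format used
#' in the packaged parameter file.
#'
#' @param x A [surv_dist] or [surv_piecewise] (for `dist_to_list`), or such a
#'   list (for `dist_from_list`).
#' @return `dist_to_list()` a plain list; `dist_from_list()` a distribution
#'   object.
#' @export
dist_to_list <- function(x) {
  if (inherits(x, "surv_dist")) {
    c(list(family = x$family), x$params)
  } else if (inherits(x, "surv_piecewise")) {
    list(knots = x$knots, segments = lapply(x$segments, dist_to_list))
  } else {
    stop("dist_to_list: not a survival distribution", call. = FALSE)
  }
}

#' @rdname dist_to_list
#' @export
dist_from_list <- function(x) {
  if (inherits(x, c("surv_dist", "surv_piecewise"))) return(x)
  if (!is.null(x$segments)) {
    surv_piecewise(lapply(x$segments, dist_from_list),
                   knots = unlist(x$knots))
  } else {
    family <- x$family
    x$family <- NULL
    do.call(surv_dist, c(list(family = family), x))
  }
}
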