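#' State space with tunnel states
#'
#' Defines the health states of a cohort state-transition model. A tunnel
#' bound of `m` on a state expands it into `m` compartments indexed by time in
#' state (months), which lets a memoryless engine carry duration-dependent
#' costs such as a fixed treatment period.
#'
#' @param states Character vector of unique state names.
#' @param tunnels Named integer vector: tunnel bound (months of residence) per
#'   tunneled state. States not named here are single compartments.
#' @param absorbing Character vector of absorbing states (e.g. `"death"`).
#' @return Object of class `state_space`.
#' @examples
#' sp <- state_space(c("treatment", "stable", "progression", "death"),
#'                   tunnels = c(treatment = 8), absorbing = "death")
#' expand_tunnels(sp)
#' @export
state_space <- function(states, tunnels = NULL, absorbing = character(0)) {
  states <- as.character(states)
  if (anyDuplicated(states)) stop("state_space: duplicate state names", call. = FALSE)
  if (!is.null(tunnels)) {
    if (is.null(names(tunnels)) || !all(names(tunnels) %in% states)) {
      stop("state_space: tunnels must be named by states", call. = FALSE)
    }
    if (any(tunnels < 1)) stop("state_space: tunnel bounds must be >= 1", call. = FALSE)
  }
  if (!all(absorbing %in% states)) {
    stop("state_space: absorbing states must be among states", call. = FALSE)
  }
  structure(list(states = states, tunnels = tunnels, absorbing = absorbing),
            class = "state_space")
}

#' Expand tunnel states into per-month compartments
#'
#' @param space A [state_space].
#' @return Character vector of expanded compartment names (`state.k` for
#'   tunnel month `k`; untouched names for single compartments), with the
#'   originating base state in attribute `"base"`.
#' @export
expand_tunnels <- function(space) {
  stopifnot(inherits(space, "state_space"))
  out <- character(0); base <- character(0)
  for (s in space$states) {
    b <- if (!is.null(space$tunnels) && s %in% names(space$tunnels))
      space$tunnels[[s]] else 1L
    if (b > 1L) {
      out <- c(out, paste(s, seq_len(b), sep = "."))
      base <- c(base, rep(s, b))
    } else {
      out <- c(out, s)
      base <- c(base, s)
    }
  }
  attr(out, "base") <- base
  out
}

#' Run a cohort through a time-inhomogeneous transition rule
#'
#' Multiplies the occupancy row vector through per-cycle transition matrices:
#' `occupancy(c+1) = occupancy(c) %*% matrix(c)`. Each generated matrix is
#' validated (entries in `[0, 1]`, rows summing to 1 within `1e-12` before
#' normalization) and violations raise an error naming the cycle and state.
#'
#' @param rule Function of the cycle index (1-based: cycle `c` spans model
#'   time `c-1` to `c` months) returning the transition matrix for that cycle,
#'   with rows and columns in the order of `init`.
#' @param init Numeric occupancy row at time 0 (sums to the cohort size).
#' @param n_cycles Number of monthly cycles to simulate.
#' @param state_names Optional expanded state names (defaults to the names of
#'   `init`).
#' @return A `cohort_trace`: numeric matrix with `n_cycles + 1` rows (cycle
#'   boundaries `0..n_cycles`) and one column per expanded state; cohort size
#'   kept in attribute `"cohort_size"`.
#' @examples
#' rule <- function(cycle) matrix(c(0.9, 0.1, 0, 1), 2, byrow = TRUE)
#' tr <- run_cohort(rule, c(alive = 1000, dead = 0), 12)
#' tr[13, "alive"] / 1000   # (1 - 0.1)^12
#' @export
run_cohort <- function(rule, init, n_cycles, state_names = NULL) {
  if (is.null(state_names)) state_names <- names(init)
  init <- as.numeric(init)
  S <- length(init)
  if (is.null(state_names)) state_names <- paste0("state", seq_len(S))
  cohort <- sum(init)
  trace <- matrix(0, n_cycles + 1L, S, dimnames = list(0:n_cycles, state_names))
  trace[1L, ] <- init
  occ <- init
  for (cyc in seq_len(n_cycles)) {
    M <- rule(cyc)
    if (!is.matrix(M) || nrow(M) != S || ncol(M) != S) {
      stop(sprintf("run_cohort: rule returned a %s at cycle %d (need %dx%d matrix)",
                   paste(dim(M), collapse = "x"), cyc, S, S), call. = FALSE)
    }
    rs <- rowSums(M)
    bad <- which(abs(rs - 1) > 1e-12 | apply(M < -1e-12 | M > 1 + 1e-12, 1, any))
    if (length(bad)) {
      stop(sprintf("run_cohort: invalid transition row for state '%s' at cycle %d (row sum %.15g)",
                   state_names[bad[1]], cyc, rs[bad[1]]), call. = FALSE)
    }
    occ <- as.numeric(occ %*% M)
    trace[cyc + 1L, ] <- occ
  }
  structure(trace, class = c("cohort_trace", "matrix"),
            cohort_size = cohort)
}

#' Per-state cost and utility values
#'
#' @param cost Named non-negative vector: cost per monthly cycle (EUR) per
#'   expanded state.
#' @param utility Named vector in `[0, 1]`: annual QALY weight per expanded
#'   state (a monthly cycle credits `utility / 12`).
#' @return Object of class `value_map`.
#' @export
value_map <- function(cost, utility) {
  if (!identical(sort(names(cost)), sort(names(utility)))) {
    stop("value_map: cost and utility must cover the same states", call. = FALSE)
  }
  if (any(cost < 0)) stop("value_map: costs must be >= 0", call. = FALSE)
  if (any(utility < 0 | utility > 1)) {
    stop("value_map: utilities must be in [0, 1]", call. = FALSE)
  }
  structure(list(cost = cost, utility = utility[names(cost)]),
            class = "value_map")
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Credits each cycle's occupancy with its state values, applies within-cycle
#' correction and discounting, and reports per-patient totals. Under the
#' life-table correction, the occupancy credited for cycle `c` is the average
#' of the occupancies at its start and end boundaries, the recommended
#' approximation of continuous-time accrual; `"start"` and `"end"` credit the
#' boundary occupancies themselves (bracketing the continuous integral for
#' monotone trajectories), and `"none"` is the uncorrected end-of-cycle
#' convention (alias of `"end"`).
#'
#' Discounting uses the annual rate compounded to monthly cycles: cycle `c`
#' (1-based) carries the factor \eqn{(1+r)^{-c/12}}. Utilities are annual
#' weights, credited at `utility / 12` per monthly cycle.
#'
#' @param trace A [cohort_trace][run_cohort].
#' @param values A [value_map] covering every state of the trace.
#' @param annual_discount Annual discount rate (default 0.03).
#' @param correction Within-cycle correction method.
#' @return An `econ_outcome`: list with `total_cost` and `total_qaly`
#'   (discounted, per patient), `state_months` (discounted credited months per
#'   state, per patient), the `trace`, and the accrual settings.
#' @export
accrue <- function(trace, values, annual_discount = 0.03,
                   correction = c("life_table", "none", "start", "end")) {
  correction <- match.arg(correction)
  stopifnot(inherits(trace, "cohort_trace"), inherits(values, "value_map"))
  sts <- colnames(trace)
  missing <- setdiff(sts, names(values$cost))
  if (length(missing)) {
    stop(sprintf("accrue: no values configured for state(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  n_cycles <- nrow(trace) - 1L
  cohort <- attr(trace, "cohort_size")
  credited <- switch(correction,
    life_table = (trace[-nrow(trace), , drop = FALSE] +
                  trace[-1L, , drop = FALSE]) / 2,
    start = trace[-nrow(trace), , drop = FALSE],
    none = ,
    end = trace[-1L, , drop = FALSE])
  dfac <- (1 + annual_discount)^(-(seq_len(n_cycles)) / 12)
  state_months <- as.numeric(dfac %*% credited) / cohort
  names(state_months) <- sts
  structure(list(
    total_cost = sum(state_months * values$cost[sts]),
    total_qaly = sum(state_months * values$utility[sts] / 12),
    state_months = state_months,
    trace = trace,
    annual_discount = annual_discount,
    correction = correction
  ), class = "econ_outcome")
}

#' @export
print.econ_outcome <- function(x, ...) {
  cat(sprintf("<econ_outcome> per patient: cost EUR %.0f, %.4f QALYs (discount %.1f%%, %s correction)\n",
              x$total_cost, x$total_qaly, 100 * x$annual_discount,
              gsub("_", "-", x$correction)))
  invisible(x)
}

#' Export a cohort trace to CSV
#'
#' @param trace A [cohort_trace][run_cohort].
#' @param file Output path.
#' @export
write_trace_csv <- function(trace, file) {
  df <- data.frame(cycle = as.integer(rownames(trace)),
                   unclass(trace)[, , drop = FALSE], check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(trace)
}
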