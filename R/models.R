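#' Load the packaged base-case parameters
#'
#' Reads the parameter file shipping with the package (or a user-supplied one
#' in the same YAML layout): survival distribution specifications per model
#' and arm, per-state monthly costs and annual utilities with their
#' sensitivity-analysis distributions, treatment durations, the third-line
#' mix, model configuration, one-way ranges, and the scenario catalogue.
#'
#' @param file Optional path to a YAML parameter file; defaults to the
#'   packaged base case.
#' @return A nested list of class `cua_params` with survival specifications
#'   converted to [surv_dist]/[surv_piecewise] objects.
#' @examples
#' p <- default_parameters()
#' p$survival$model_I$PRLT_SoC$os
#' @export
default_parameters <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "parameters.yaml", package = "lupsmacua",
                        mustWork = TRUE)
  }
  raw <- yaml::read_yaml(file)
  for (m in names(raw$survival)) {
    for (a in names(raw$survival[[m]])) {
      raw$survival[[m]][[a]] <- lapply(raw$survival[[m]][[a]], dist_from_list)
    }
  }
  structure(raw, class = "cua_params")
}

#' Per-cycle transition probabilities from OS and PFS curves
#'
#' Discretizes an overall-survival and a progression-free-survival curve into
#' the monthly probabilities of the cohort models. With cycle start
#' `t0 = clock_offset + cycle` and end `t1 = t0 + 1`:
#' \itemize{
#'   \item `p_death = 1 - S_os(t1)/S_os(t0)` — applied from every alive state
#'     (equal mortality from stable and progressed states);
#'   \item `p_progress` depends on `progression_rule`:
#'     `"pfs-direct"` (default) uses the full conditional PFS event
#'     probability `1 - S_pfs(t1)/S_pfs(t0)`, i.e. progression and death are
#'     each read off their own curve and applied jointly;
#'     `"pfs-minus-death"` subtracts the death probability,
#'     `max(0, p_pfs - p_death)`, treating PFS events as the union of
#'     progression and death;
#'   \item `p_stay = 1 - p_progress - p_death`.
#' }
#' When the jointly applied probabilities would exceed 1 (possible only for
#' extreme parameter sets, e.g. resampled sensitivity draws; never for the
#' packaged base case), death keeps priority and progression is capped at the
#' remaining mass.
#' The default is the convention under which the packaged models reproduce
#' their published totals; see the methods vignette for the comparison of the
#' two rules.
#'
#' @param os,pfs [surv_dist] or [surv_piecewise] laws (time in months).
#' @param cycle 0-based cycle index (may be a vector).
#' @param clock_offset Months already elapsed on the survival clock at model
#'   start.
#' @param progression_rule `"pfs-direct"` or `"pfs-minus-death"`.
#' @return A data frame with columns `p_progress`, `p_death`, `p_stay`.
#' @export
transition_probs <- function(os, pfs, cycle, clock_offset = 0,
                             progression_rule = c("pfs-direct",
                                                  "pfs-minus-death")) {
  progression_rule <- match.arg(progression_rule)
  t0 <- clock_offset + cycle
  t1 <- t0 + 1
  p_death <- conditional_event_prob(os, t0, t1)
  p_pfs <- conditional_event_prob(pfs, t0, t1)
  p_progress <- if (progression_rule == "pfs-direct") p_pfs
                else pmax(0, p_pfs - p_death)
  # under joint application the two probabilities can exceed 1 for extreme
  # (e.g. resampled) parameter sets; death keeps priority and progression is
  # capped at the remaining probability mass
  p_progress <- pmin(p_progress, 1 - p_death)
  p_stay <- pmax(1 - p_progress - p_death, 0)
  data.frame(p_progress = p_progress, p_death = p_death, p_stay = p_stay)
}

# resolve config with per-call overrides
.resolve_config <- function(params, ...) {
  cfg <- params$model_config
  dots <- list(...)
  for (nm in names(dots)) if (!is.null(dots[[nm]])) cfg[[nm]] <- dots[[nm]]
  cfg
}

#' Build the third-line strategy model (Model I)
#'
#' Model I compares PRLT plus standard of care against standard of care alone
#' as third-line treatment. Each arm has four health states — treatment
#' (a tunnel of one compartment per month, 8 months in both arms), stable
#' after treatment, progression, and death. Progression-free survival drives
#' transitions out of the treatment/stable states into progression, overall
#' survival drives transitions into death from every alive state, both on the
#' model clock (time since model start).
#'
#' @param arm `"PRLT_SoC"` or `"SoC"`.
#' @param params A [default_parameters()] list (possibly modified).
#' @param horizon,annual_discount,cohort_size,progression_rule Optional
#'   overrides of the packaged model configuration.
#' @return A `strategy_model`; run it with [run_strategy()].
#' @examples
#' m <- build_model_I("PRLT_SoC")
#' out <- run_strategy(m)
#' out$total_cost
#' @export
build_model_I <- function(arm = c("PRLT_SoC", "SoC"),
                          params = default_parameters(),
                          horizon = NULL, annual_discount = NULL,
                          cohort_size = NULL, progression_rule = NULL) {
  arm <- match.arg(arm)
  cfg <- .resolve_config(params, horizon = horizon,
                         annual_discount = annual_discount,
                         cohort_size = cohort_size,
                         progression_rule = progression_rule)
  sv <- params$survival$model_I[[arm]]
  vals <- params$values$model_I[[arm]]
  if (is.null(sv) || is.null(vals)) {
    stop(sprintf("build_model_I: no parameters for arm '%s'", arm), call. = FALSE)
  }
  dur <- params$treatment_duration[[arm]]
  H <- cfg$horizon

  tp <- transition_probs(sv$os, sv$pfs, cycle = 0:(H - 1),
                         progression_rule = cfg$progression_rule)

  space <- state_space(c("treatment", "stable", "progression", "death"),
                       tunnels = c(treatment = dur), absorbing = "death")
  states <- expand_tunnels(space)
  S <- length(states)
  i_treat <- seq_len(dur)
  i_stable <- dur + 1L; i_prog <- dur + 2L; i_death <- dur + 3L

  rule <- function(cyc) {
    M <- matrix(0, S, S)
    pd <- tp$p_death[cyc]; pp <- tp$p_progress[cyc]; ps <- tp$p_stay[cyc]
    for (k in i_treat) {
      M[k, if (k < dur) k + 1L else i_stable] <- ps
      M[k, i_prog] <- pp
      M[k, i_death] <- pd
    }
    M[i_stable, i_stable] <- ps
    M[i_stable, i_prog] <- pp
    M[i_stable, i_death] <- pd
    M[i_prog, i_prog] <- 1 - pd
    M[i_prog, i_death] <- pd
    M[i_death, i_death] <- 1
    M
  }

  cost <- utility <- stats::setNames(numeric(S), states)
  base <- attr(states, "base")
  for (role in c("treatment", "stable", "progression")) {
    cost[base == role] <- vals[[role]]$cost
    utility[base == role] <- vals[[role]]$utility
  }
  init <- stats::setNames(numeric(S), states)
  init[1L] <- cfg$cohort_size

  structure(list(
    model = "I", arm = arm, states = states, init = init,
    rule = rule, values = value_map(cost, utility),
    os = sv$os, pfs = sv$pfs, config = cfg,
    death_state = "death"
  ), class = "strategy_model")
}

#' Build the second-line strategy model (Model II)
#'
#' Model II compares PRLT plus standard of care against cabazitaxel as
#' second-line treatment. Each arm has second-line treatment (tunnel of 8
#' months for PRLT, 7 for cabazitaxel) and stable states driven by the
#' second-line OS/PFS curves; on first progression the cohort splits (75%
#' standard of care, 25% PRLT in the base case) into third-line sub-models
#' that replicate the Model I structures and values, with their own
#' treatment tunnels, stable and next-progression states.
#'
#' The third-line survival clock is configurable: `"model"` (default)
#' evaluates the third-line OS/PFS curves on the model clock, i.e. time since
#' model start; `"reset"` restarts the third-line curves at zero upon entry,
#' which requires expanding third-line states by time since entry. The
#' default is the convention under which the packaged models reproduce their
#' published totals (see the methods vignette).
#'
#' @param arm `"PRLT_SoC"` or `"CBZ"`.
#' @param third_line_mix Named weights over `c("SoC", "PRLT_SoC")` summing
#'   to 1; defaults to the packaged 0.75/0.25.
#' @param third_line_clock `"model"` or `"reset"`.
#' @inheritParams build_model_I
#' @return A `strategy_model`.
#' @export
build_model_II <- function(arm = c("PRLT_SoC", "CBZ"),
                           params = default_parameters(),
                           third_line_mix = NULL,
                           third_line_clock = NULL,
                           horizon = NULL, annual_discount = NULL,
                           cohort_size = NULL, progression_rule = NULL) {
  arm <- match.arg(arm)
  cfg <- .resolve_config(params, horizon = horizon,
                         annual_discount = annual_discount,
                         cohort_size = cohort_size,
                         progression_rule = progression_rule,
                         third_line_clock = third_line_clock)
  mix <- third_line_mix
  if (is.null(mix)) mix <- unlist(params$third_line_mix)
  mix <- mix[c("SoC", "PRLT_SoC")]
  if (abs(sum(mix) - 1) > 1e-9 || any(mix < 0)) {
    stop("build_model_II: third-line mix weights must be >= 0 and sum to 1",
         call. = FALSE)
  }
  sv2 <- params$survival$model_II[[arm]]
  vals2 <- params$values$model_II[[arm]]
  if (is.null(sv2) || is.null(vals2)) {
    stop(sprintf("build_model_II: no parameters for arm '%s'", arm), call. = FALSE)
  }
  dur2 <- params$treatment_duration[[arm]]
  H <- cfg$horizon
  subs <- c("SoC", "PRLT_SoC")

  tp2 <- transition_probs(sv2$os, sv2$pfs, cycle = 0:(H - 1),
                          progression_rule = cfg$progression_rule)
  # third-line probabilities: indexed by model time under the "model" clock,
  # by time since third-line entry under the "reset" clock (same grid 0..H-1)
  tp3 <- lapply(subs, function(s) {
    sv3 <- params$survival$model_I[[s]]
    transition_probs(sv3$os, sv3$pfs, cycle = 0:(H - 1),
                     progression_rule = cfg$progression_rule)
  })
  names(tp3) <- subs
  dur3 <- vapply(subs, function(s) params$treatment_duration[[s]], numeric(1))

  if (cfg$third_line_clock == "model") {
    built <- .model_II_states_modelclock(subs, dur2, dur3, H)
  } else {
    built <- .model_II_states_reset(subs, dur2, dur3, H)
  }
  states <- built$states
  S <- length(states)
  ix <- built$ix

  rule <- function(cyc) {
    M <- matrix(0, S, S)
    pd2 <- tp2$p_death[cyc]; pp2 <- tp2$p_progress[cyc]; ps2 <- tp2$p_stay[cyc]
    # second line: progressors split into the third-line sub-strategies
    for (k in seq_len(dur2)) {
      from <- ix$sl_treat[k]
      M[from, if (k < dur2) ix$sl_treat[k + 1L] else ix$sl_stable] <- ps2
      M[from, ix$death] <- pd2
      for (s in subs) M[from, ix$tl_entry[[s]]] <- pp2 * mix[[s]]
    }
    M[ix$sl_stable, ix$sl_stable] <- ps2
    M[ix$sl_stable, ix$death] <- pd2
    for (s in subs) M[ix$sl_stable, ix$tl_entry[[s]]] <- pp2 * mix[[s]]
    # third line
    for (s in subs) {
      if (cfg$third_line_clock == "model") {
        pd3 <- tp3[[s]]$p_death[cyc]; pp3 <- tp3[[s]]$p_progress[cyc]
        ps3 <- tp3[[s]]$p_stay[cyc]
        tl <- ix$tl[[s]]
        for (k in seq_along(tl$treat)) {
          from <- tl$treat[k]
          M[from, if (k < length(tl$treat)) tl$treat[k + 1L] else tl$stable] <- ps3
          M[from, tl$prog] <- pp3
          M[from, ix$death] <- pd3
        }
        M[tl$stable, tl$stable] <- ps3
        M[tl$stable, tl$prog] <- pp3
        M[tl$stable, ix$death] <- pd3
        M[tl$prog, tl$prog] <- 1 - pd3
        M[tl$prog, ix$death] <- pd3
      } else {
        tl <- ix$tl[[s]]
        n_tau <- length(tl$np)
        for (tau1 in seq_len(n_tau)) {      # tau1 = time since entry + 1
          pd3 <- tp3[[s]]$p_death[tau1]; pp3 <- tp3[[s]]$p_progress[tau1]
          ps3 <- tp3[[s]]$p_stay[tau1]
          from <- tl$np[tau1]
          if (tau1 < n_tau) {
            M[from, tl$np[tau1 + 1L]] <- ps3
            M[from, tl$pg[tau1 + 1L]] <- pp3
          } else {
            M[from, from] <- ps3 + pp3   # horizon edge: no further compartment
          }
          M[from, ix$death] <- pd3
          frompg <- tl$pg[tau1]
          if (tau1 < n_tau) {
            M[frompg, tl$pg[tau1 + 1L]] <- 1 - pd3
          } else {
            M[frompg, frompg] <- 1 - pd3
          }
          M[frompg, ix$death] <- pd3
        }
      }
    }
    M[ix$death, ix$death] <- 1
    M
  }

  cost <- utility <- stats::setNames(numeric(S), states)
  cost[ix$sl_treat] <- vals2$treatment$cost
  utility[ix$sl_treat] <- vals2$treatment$utility
  cost[ix$sl_stable] <- vals2$stable$cost
  utility[ix$sl_stable] <- vals2$stable$utility
  for (s in subs) {
    v3 <- params$values$model_I[[s]]
    tl <- ix$tl[[s]]
    if (cfg$third_line_clock == "model") {
      cost[tl$treat] <- v3$treatment$cost
      utility[tl$treat] <- v3$treatment$utility
      cost[tl$stable] <- v3$stable$cost
      utility[tl$stable] <- v3$stable$utility
      cost[tl$prog] <- v3$progression$cost
      utility[tl$prog] <- v3$progression$utility
    } else {
      in_treat <- seq_along(tl$np) <= dur3[[s]]
      cost[tl$np[in_treat]] <- v3$treatment$cost
      utility[tl$np[in_treat]] <- v3$treatment$utility
      cost[tl$np[!in_treat]] <- v3$stable$cost
      utility[tl$np[!in_treat]] <- v3$stable$utility
      cost[tl$pg] <- v3$progression$cost
      utility[tl$pg] <- v3$progression$utility
    }
  }
  init <- stats::setNames(numeric(S), states)
  init[ix$sl_treat[1L]] <- cfg$cohort_size

  structure(list(
    model = "II", arm = arm, states = states, init = init,
    rule = rule, values = value_map(cost, utility),
    os = sv2$os, pfs = sv2$pfs, third_line_mix = mix, config = cfg,
    death_state = "death"
  ), class = "strategy_model")
}

# expanded state layout for Model II, third line on the model clock
.model_II_states_modelclock <- function(subs, dur2, dur3, H) {
  states <- c(paste("sl_treatment", seq_len(dur2), sep = "."), "sl_stable")
  ix <- list(sl_treat = seq_len(dur2), sl_stable = dur2 + 1L,
             tl = list(), tl_entry = list())
  pos <- dur2 + 1L
  for (s in subs) {
    nm <- tolower(sub("_SoC$", "", s))   # soc / prlt
    treat <- pos + seq_len(dur3[[s]])
    stable <- pos + dur3[[s]] + 1L
    prog <- stable + 1L
    states <- c(states,
                paste(paste0("tl_", nm, "_treatment"), seq_len(dur3[[s]]), sep = "."),
                paste0("tl_", nm, "_stable"), paste0("tl_", nm, "_progression"))
    ix$tl[[s]] <- list(treat = treat, stable = stable, prog = prog)
    ix$tl_entry[[s]] <- treat[1L]
    pos <- prog
  }
  states <- c(states, "death")
  ix$death <- pos + 1L
  list(states = states, ix = ix)
}

# expanded state layout for Model II, third line on a reset clock:
# third-line states carry a time-since-entry index
.model_II_states_reset <- function(subs, dur2, dur3, H) {
  states <- c(paste("sl_treatment", seq_len(dur2), sep = "."), "sl_stable")
  ix <- list(sl_treat = seq_len(dur2), sl_stable = dur2 + 1L,
             tl = list(), tl_entry = list())
  pos <- dur2 + 1L
  for (s in subs) {
    nm <- tolower(sub("_SoC$", "", s))
    np <- pos + seq_len(H)     # time since entry 0 .. H-1
    pg <- pos + H + seq_len(H)
    states <- c(states,
                paste(paste0("tl_", nm, "_np"), seq_len(H) - 1L, sep = "."),
                paste(paste0("tl_", nm, "_pg"), seq_len(H) - 1L, sep = "."))
    ix$tl[[s]] <- list(np = np, pg = pg)
    ix$tl_entry[[s]] <- np[1L]
    pos <- pos + 2L * H
  }
  states <- c(states, "death")
  ix$death <- pos + 1L
  list(states = states, ix = ix)
}

#' Run a strategy model
#'
#' Runs the cohort engine for the strategy and accrues discounted costs and
#' QALYs with the configured within-cycle correction.
#'
#' @param model A `strategy_model` from [build_model_I()] or
#'   [build_model_II()].
#' @return An `econ_outcome` (see [accrue()]) with the strategy attached as
#'   attribute `"model"`.
#' @export
run_strategy <- function(model) {
  stopifnot(inherits(model, "strategy_model"))
  trace <- run_cohort(model$rule, model$init, model$config$horizon,
                      state_names = model$states)
  out <- accrue(trace, model$values,
                annual_discount = model$config$annual_discount,
                correction = model$config$within_cycle_correction)
  attr(out, "model") <- model
  out
}

#' Death-state occupancy fraction at a cycle
#'
#' @param x A `cohort_trace`, `econ_outcome`, or `strategy_model`.
#' @param cycle Cycle boundary (defaults to the last).
#' @return Fraction of the cohort in the death state.
#' @export
death_fraction <- function(x, cycle = NULL) {
  trace <- if (inherits(x, "cohort_trace")) x
           else if (inherits(x, "econ_outcome")) x$trace
           else if (inherits(x, "strategy_model")) run_strategy(x)$trace
           else stop("death_fraction: unsupported input", call. = FALSE)
  if (is.null(cycle)) cycle <- nrow(trace) - 1L
  death_cols <- grep("^death$", colnames(trace))
  sum(trace[cycle + 1L, death_cols]) / attr(trace, "cohort_size")
}

#' @export
print.strategy_model <- function(x, ...) {
  cat(sprintf("<strategy_model> Model %s, arm %s: %d expanded states, %d cycles, discount %.1f%%\n",
              x$model, x$arm, length(x$states), x$config$horizon,
              100 * x$config$annual_discount))
  invisible(x)
}
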