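# shared fixtures: base-case laws and small independent oracles

base_params <- default_parameters()

# base-case distributions, constructed directly (independent of the YAML)
dist_os_prlt_I <- surv_dist("loglogistic", shape = 1.9263, scale = 15.5377)
dist_pfs_prlt_I <- surv_dist("lognormal", meanlog = 2.1048, sdlog = 0.9841)
dist_os_soc_I <- surv_dist("gamma", shape = 1.6065, rate = 0.1140)
dist_pfs_soc_I <- surv_piecewise(
  list(surv_dist("loglogistic", shape = 4.7332, scale = 2.3643),
       surv_dist("lognormal", meanlog = 2.2763, sdlog = 0.8268)),
  knots = 3.6)

# a small panel of valid distributions across every family
family_panel <- list(
  surv_dist("exponential", rate = 0.08),
  surv_dist("weibull", shape = 1.4, scale = 12),
  surv_dist("gamma", shape = 1.6065, rate = 0.1140),
  surv_dist("lognormal", meanlog = 2.1048, sdlog = 0.9841),
  surv_dist("loglogistic", shape = 1.9263, scale = 15.5377),
  surv_dist("gompertz", shape = 0.05, rate = 0.04),
  surv_dist("gompertz", shape = -0.02, rate = 0.08),
  surv_dist("gengamma", mu = 2.3, sigma = 0.8, Q = 0.5)
)

# hand-rolled log-likelihood for an exponential fit under right censoring
exp_loglik_hand <- function(ipd, rate) {
  sum(ipd$event) * log(rate) - rate * sum(ipd$time)
}

# per-patient microsimulation of a 3-state chain (alive -> progressed ->
# dead) under cycle-dependent probabilities; oracle for the cohort engine
microsim_three_state <- function(n, p_prog, p_death, n_cycles) {
  state <- rep(1L, n)   # 1 alive, 2 progressed, 3 dead
  occ <- matrix(0, n_cycles + 1L, 3L)
  occ[1L, ] <- c(n, 0, 0)
  for (cyc in seq_len(n_cycles)) {
    u <- stats::runif(n)
    alive <- state == 1L
    prog <- state == 2L
    state[alive & u < p_death[cyc]] <- 3L
    state[alive & state == 1L &
            u < p_death[cyc] + p_prog[cyc]] <- 2L
    state[prog & u < p_death[cyc]] <- 3L
    occ[cyc + 1L, ] <- tabulate(state, 3L)
  }
  occ / n
}
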