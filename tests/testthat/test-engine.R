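test_that("tunnel expansion produces one compartment per month of residence", {
  sp <- state_space(c("treatment", "stable", "progression", "death"),
                    tunnels = c(treatment = 8), absorbing = "death")
  ex <- expand_tunnels(sp)
  expect_length(ex, 11)
  expect_equal(ex[1:8], paste("treatment", 1:8, sep = "."))
  expect_equal(sum(attr(ex, "base") == "treatment"), 8)

  expect_equal(as.character(expand_tunnels(state_space(c("a", "b")))), c("a", "b"))
  sp1 <- state_space(c("a", "b"), tunnels = c(a = 1))
  expect_equal(as.character(expand_tunnels(sp1)), c("a", "b"))
  expect_error(state_space(c("a", "a")), "duplicate")
  expect_error(state_space("a", tunnels = c(a = 0)), ">= 1")
})

test_that("cohort propagation matches closed forms and a hand iteration", {
  # identity rule: occupancy frozen
  id_rule <- function(cyc) diag(3)
  tr <- run_cohort(id_rule, c(a = 300, b = 600, c = 100), 10)
  expect_true(all(tr == matrix(rep(c(300, 600, 100), each = 11), 11)))

  # constant mortality: geometric survival
  p <- 0.07
  rule <- function(cyc) matrix(c(1 - p, p, 0, 1), 2, byrow = TRUE)
  tr <- run_cohort(rule, c(alive = 1000, dead = 0), 24)
  expect_equal(tr[25, "alive"], 1000 * (1 - p)^24, tolerance = 1e-12)

  # time-varying 3-state chain vs explicit hand iteration over 3 cycles
  pp <- c(0.10, 0.20, 0.15); pd <- c(0.02, 0.05, 0.08)
  rule3 <- function(cyc) matrix(c(1 - pp[cyc] - pd[cyc], pp[cyc], pd[cyc],
                                  0, 1 - pd[cyc], pd[cyc],
                                  0, 0, 1), 3, byrow = TRUE)
  tr3 <- run_cohort(rule3, c(alive = 1, prog = 0, dead = 0), 3)
  occ <- c(1, 0, 0)
  for (cyc in 1:3) {
    occ <- c(occ[1] * (1 - pp[cyc] - pd[cyc]),
             occ[1] * pp[cyc] + occ[2] * (1 - pd[cyc]),
             occ[1] * pd[cyc] + occ[2] * pd[cyc] + occ[3])
    expect_equal(as.numeric(tr3[cyc + 1, ]), occ, tolerance = 1e-14)
  }

  bad <- function(cyc) matrix(c(0.9, 0.2, 0, 1), 2, byrow = TRUE)
  expect_error(run_cohort(bad, c(x = 1, y = 0), 2), "row sum")
})

test_that("random stochastic rules conserve the cohort and keep death monotone", {
  set.seed(99)
  for (rep in 1:20) {
    S <- sample(3:6, 1)
    mats <- lapply(1:15, function(i) {
      M <- matrix(stats::rexp(S * S), S)
      M[S, ] <- c(rep(0, S - 1), 1)     # absorbing death in last column
      M / rowSums(M)
    })
    tr <- run_cohort(function(cyc) mats[[cyc]],
                     stats::setNames(c(rep(100, S - 1), 0), paste0("s", 1:S)), 15)
    expect_true(all(abs(rowSums(tr) - 100 * (S - 1)) < 1e-9))
    expect_true(all(diff(tr[, S]) >= -1e-12))
  }
})

test_that("accrual reproduces closed forms and correction identities", {
  one_state <- function(n) {
    structure(matrix(1000, n + 1, 1, dimnames = list(0:n, "well")),
              class = c("cohort_trace", "matrix"), cohort_size = 1000)
  }
  vm <- value_map(cost = c(well = 500), utility = c(well = 1))
  # a year in full health, undiscounted: exactly 1 QALY
  out <- accrue(one_state(12), vm, annual_discount = 0, correction = "life_table")
  expect_equal(out$total_qaly, 1, tolerance = 1e-12)
  # constant occupancy: correction is irrelevant
  out_n <- accrue(one_state(12), vm, annual_discount = 0, correction = "none")
  expect_equal(out$total_cost, out_n$total_cost, tolerance = 1e-12)
  # discounted cost equals the geometric sum
  r <- 0.03
  out_d <- accrue(one_state(24), vm, annual_discount = r)
  expect_equal(out_d$total_cost, 500 * sum((1 + r)^(-(1:24) / 12)),
               tolerance = 1e-12)
})

test_that("start/end corrections bracket the life-table value for monotone occupancy", {
  n <- 36
  occ <- matrix(c(1000 * 0.9^(0:n), 1000 - 1000 * 0.9^(0:n)), n + 1, 2,
                dimnames = list(0:n, c("alive", "dead")))
  tr <- structure(occ, class = c("cohort_trace", "matrix"), cohort_size = 1000)
  vm <- value_map(cost = c(alive = 100, dead = 0),
                  utility = c(alive = 1, dead = 0))
  costs <- vapply(c("start", "life_table", "end"), function(cr)
    accrue(tr, vm, annual_discount = 0, correction = cr)$total_cost, numeric(1))
  expect_true(costs["start"] > costs["life_table"])
  expect_true(costs["life_table"] > costs["end"])
  # life-table value is their average for a 2-point correction
  expect_equal(costs[["life_table"]], mean(costs[c("start", "end")]),
               tolerance = 1e-12)
})

test_that("undiscounted QALYs at utility 1 equal restricted life expectancy", {
  # alive/dead chain driven by the third-line PRLT OS law
  H <- 60
  pd <- conditional_event_prob(dist_os_prlt_I, 0:(H - 1), 1:H)
  rule <- function(cyc) matrix(c(1 - pd[cyc], pd[cyc], 0, 1), 2, byrow = TRUE)
  tr <- run_cohort(rule, c(alive = 1, dead = 0), H)
  out <- accrue(tr, value_map(cost = c(alive = 0, dead = 0),
                              utility = c(alive = 1, dead = 0)),
                annual_discount = 0, correction = "life_table")
  rmst <- stats::integrate(function(t) survival_prob(dist_os_prlt_I, t),
                           0, H, rel.tol = 1e-10)$value / 12
  expect_equal(out$total_qaly, rmst, tolerance = 5e-4)
})

test_that("the cohort engine agrees with a per-patient microsimulation", {
  set.seed(123)
  n_cycles <- 10
  pp <- stats::runif(n_cycles, 0.05, 0.2)
  pd <- stats::runif(n_cycles, 0.02, 0.1)
  rule <- function(cyc) matrix(c(1 - pp[cyc] - pd[cyc], pp[cyc], pd[cyc],
                                 0, 1 - pd[cyc], pd[cyc],
                                 0, 0, 1), 3, byrow = TRUE)
  tr <- run_cohort(rule, c(alive = 1, prog = 0, dead = 0), n_cycles)
  ms <- microsim_three_state(200000, pp, pd, n_cycles)
  # Monte-Carlo tolerance: 4 * sqrt(0.25 / n) ~ 0.0045
  expect_lt(max(abs(unclass(tr) - ms)), 0.005)
})

test_that("accrual validates its value map", {
  tr <- run_cohort(function(cyc) diag(2), c(a = 1, b = 0), 2)
  expect_error(accrue(tr, value_map(cost = c(a = 1), utility = c(a = 1))),
               "no values configured")
  expect_error(value_map(cost = c(a = -1), utility = c(a = 0.5)), ">= 0")
  expect_error(value_map(cost = c(a = 1), utility = c(a = 1.2)), "\\[0, 1\\]")
})
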