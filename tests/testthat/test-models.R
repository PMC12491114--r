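test_that("per-cycle transition probabilities follow their closed forms", {
  os <- surv_dist("exponential", rate = 0.05)
  pfs <- surv_dist("exponential", rate = 0.20)
  tp <- transition_probs(os, pfs, cycle = 0:5)
  expect_equal(tp$p_death, rep(1 - exp(-0.05), 6), tolerance = 1e-12)
  expect_equal(tp$p_progress, rep(1 - exp(-0.20), 6), tolerance = 1e-12)
  expect_equal(tp$p_stay, 1 - tp$p_progress - tp$p_death, tolerance = 1e-14)

  # subtraction variant: PFS events treated as union of progression and death
  tpm <- transition_probs(os, pfs, cycle = 0:5,
                          progression_rule = "pfs-minus-death")
  expect_equal(tpm$p_progress, rep(exp(-0.05) - exp(-0.20), 6),
               tolerance = 1e-12)
  # identical OS and PFS: all PFS events explained by death under that rule
  tpe <- transition_probs(os, os, cycle = 0:5,
                          progression_rule = "pfs-minus-death")
  expect_equal(tpe$p_progress, rep(0, 6))

  # clock offset shifts the evaluation window
  tp_off <- transition_probs(dist_os_prlt_I, pfs, cycle = 0, clock_offset = 10)
  expect_equal(tp_off$p_death, conditional_event_prob(dist_os_prlt_I, 10, 11),
               tolerance = 1e-14)

  # jointly impossible probabilities: death keeps priority, progression is
  # capped at the remaining mass, rows stay stochastic
  tpc <- transition_probs(surv_dist("exponential", rate = 1.5),
                          surv_dist("lognormal", meanlog = 0.4939, sdlog = 0.5765),
                          cycle = 2)
  expect_equal(tpc$p_death, 1 - exp(-1.5), tolerance = 1e-12)
  expect_equal(tpc$p_progress, 1 - tpc$p_death, tolerance = 1e-12)
  expect_equal(tpc$p_stay, 0)
})

test_that("all packaged strategies generate valid transition rows over the horizon", {
  for (b in list(build_model_I("PRLT_SoC"), build_model_I("SoC"),
                 build_model_II("PRLT_SoC"), build_model_II("CBZ"),
                 build_model_II("CBZ", third_line_clock = "reset"))) {
    S <- length(b$states)
    for (cyc in c(1, 2, 8, 30, 60)) {
      M <- b$rule(cyc)
      expect_true(all(M >= 0 & M <= 1))
      expect_equal(rowSums(M), rep(1, S), tolerance = 1e-12)
    }
    # run_cohort re-validates every cycle; must complete without error
    expect_silent(run_cohort(b$rule, b$init, b$config$horizon,
                             state_names = b$states))
  }
})

test_that("death is governed solely by the OS law (equal-mortality rule)", {
  for (arm in c("PRLT_SoC", "SoC")) {
    m <- build_model_I(arm)
    tr <- run_strategy(m)$trace
    S_os <- survival_prob(m$os, 0:60)
    expect_lt(max(abs(tr[, "death"] / 1000 - (1 - S_os))), 1e-9)
    # and the PFS-state share follows the model's joint-application rule
    alive <- 1 - tr[, "death"] / 1000
    expect_true(all(diff(tr[, "death"]) >= -1e-12))
  }
})

test_that("treatment tunnel empties into the stable state after 8 months", {
  m <- build_model_I("PRLT_SoC")
  tr <- run_strategy(m)$trace
  treat_cols <- grep("^treatment", colnames(tr))
  # boundary 8 (row 9) onward: everyone not progressed/dead sits in "stable"
  expect_true(all(tr[9:61, treat_cols] < 1e-9))
  expect_gt(tr[9, "stable"], 0)
  # boundary 7: the never-progressed sit in tunnel 8 only, not yet in stable
  expect_lt(sum(tr[8, treat_cols[1:7]]) + tr[8, "stable"], 1e-9)
  # tunnel compartments are visited in sequence
  for (k in 1:7) expect_gt(tr[k + 1, treat_cols[k + 1]], 0)
})

test_that("third-line mixture weights split progressors exactly", {
  m <- build_model_II("PRLT_SoC")
  tr <- run_strategy(m)$trace
  soc_entry <- tr[, "tl_soc_treatment.1"]
  prlt_entry <- tr[, "tl_prlt_treatment.1"]
  nz <- soc_entry > 1e-12
  expect_true(all(abs(soc_entry[nz] / prlt_entry[nz] - 0.75 / 0.25) < 1e-9))

  m100 <- build_model_II("PRLT_SoC", third_line_mix = c(SoC = 1, PRLT_SoC = 0))
  tr100 <- run_strategy(m100)$trace
  expect_true(all(tr100[, grep("tl_prlt", colnames(tr100))] == 0))
  expect_error(build_model_II("PRLT_SoC", third_line_mix = c(SoC = 0.6, PRLT_SoC = 0.2)),
               "sum to 1")
})

test_that("a two-phase chain with exponential laws matches a hand iteration", {
  p <- default_parameters()
  p$survival$model_II$PRLT_SoC$os <- surv_dist("exponential", rate = 0.04)
  p$survival$model_II$PRLT_SoC$pfs <- surv_dist("exponential", rate = 0.25)
  p$survival$model_I$SoC$os <- surv_dist("exponential", rate = 0.10)
  p$survival$model_I$SoC$pfs <- surv_dist("exponential", rate = 0.30)
  m <- build_model_II("PRLT_SoC", p, third_line_mix = c(SoC = 1, PRLT_SoC = 0))
  tr <- run_strategy(m)$trace

  pd2 <- 1 - exp(-0.04); pf2 <- 1 - exp(-0.25)
  pd3 <- 1 - exp(-0.10); pf3 <- 1 - exp(-0.30)
  # hand iteration over 3 cycles (second line + third-line entry compartments)
  np2 <- 1; tl_np <- 0; tl_pg <- 0; dead <- 0
  for (cyc in 1:3) {
    enter <- np2 * pf2
    dead <- dead + np2 * pd2 + tl_np * pd3 + tl_pg * pd3
    tl_pg <- tl_pg * (1 - pd3) + tl_np * pf3
    tl_np <- tl_np * (1 - pf3 - pd3) + enter
    np2 <- np2 * (1 - pf2 - pd2)
    sl <- sum(tr[cyc + 1, grep("^sl_", colnames(tr))]) / 1000
    np3 <- sum(tr[cyc + 1, grep("tl_soc_(treatment|stable)", colnames(tr))]) / 1000
    pg3 <- tr[cyc + 1, "tl_soc_progression"] / 1000
    expect_equal(sl, np2, tolerance = 1e-12)
    expect_equal(np3, tl_np, tolerance = 1e-12)
    expect_equal(as.numeric(pg3), tl_pg, tolerance = 1e-12)
    expect_equal(as.numeric(tr[cyc + 1, "death"]) / 1000, dead, tolerance = 1e-12)
  }
})

test_that("overall survival in Model II is a mixture below the second-line OS law", {
  for (clock in c("model", "reset")) {
    m <- build_model_II("PRLT_SoC", third_line_clock = clock)
    tr <- run_strategy(m)$trace
    alive <- 1 - tr[, "death"] / 1000
    S2 <- survival_prob(m$os, 0:60)
    expect_true(all(alive <= S2 + 1e-9), info = clock)
  }
})

test_that("raising a state cost or utility raises the arm total monotonically", {
  p <- default_parameters()
  base <- run_strategy(build_model_I("SoC", p))
  p$values$model_I$SoC$progression$cost <- p$values$model_I$SoC$progression$cost + 1000
  up <- run_strategy(build_model_I("SoC", p))
  expect_gt(up$total_cost, base$total_cost)
  expect_equal(up$total_qaly, base$total_qaly, tolerance = 1e-12)
  p$values$model_I$SoC$progression$utility <- 0.8
  up2 <- run_strategy(build_model_I("SoC", p))
  expect_gt(up2$total_qaly, up$total_qaly)
})
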