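test_that("gamma moment matching satisfies its analytic identities", {
  g <- gamma_from_mean_sd(7340, 2942)
  expect_equal(g$shape / g$rate, 7340, tolerance = 1e-12)         # mean
  expect_equal(sqrt(g$shape) / g$rate, 2942, tolerance = 1e-12)   # sd
  expect_equal(gamma_from_mean_sd(5, 5)$shape, 1)                 # exponential case
  expect_equal(unlist(gamma_from_mean_sd(1, 1)), c(shape = 1, rate = 1))
  expect_error(gamma_from_mean_sd(-1, 2), "positive")

  set.seed(77)
  x <- stats::rgamma(1e6, shape = g$shape, rate = g$rate)
  expect_lt(abs(mean(x) - 7340) / 7340, 0.01)
})

test_that("packaged beta distributions are consistent with the base utilities", {
  expect_equal(beta_mean(2.6590, 0.8901), 0.7492, tolerance = 1e-3)
  expect_equal(nrow(validate_params(default_parameters())), 0)
})

test_that("the tornado reflects cost linearity and the expected ranking", {
  p <- default_parameters()
  base <- run_model_pair("I", p)
  # doubling every cost in both arms doubles the ICER exactly
  p2 <- p
  for (a in names(p2$values$model_I)) {
    for (s in names(p2$values$model_I[[a]])) {
      p2$values$model_I[[a]][[s]]$cost <- 2 * p2$values$model_I[[a]][[s]]$cost
    }
  }
  doubled <- run_model_pair("I", p2)
  expect_equal(doubled$icer, 2 * base$icer, tolerance = 1e-9)
  expect_equal(doubled$delta_effect, base$delta_effect, tolerance = 1e-12)

  dsa <- run_dsa("I", p)
  expect_s3_class(dsa, "dsa_result")
  expect_true(all(diff(dsa$spread) <= 1e-9))
  expect_equal(unique(dsa$icer_base), base$icer, tolerance = 1e-9)
  # cost bars bracket the base-case ICER
  cost_rows <- grep("\\.cost$", dsa$parameter)
  expect_true(all(pmin(dsa$icer_low, dsa$icer_high)[cost_rows] <=
                    dsa$icer_base[cost_rows] + 1e-6))
  expect_true(all(pmax(dsa$icer_low, dsa$icer_high)[cost_rows] >=
                    dsa$icer_base[cost_rows] - 1e-6))
  # progression-state costs of both arms rank above the PRLT treatment cost
  rank_of <- function(par) which(dsa$parameter == par)
  expect_lt(rank_of("model_I.SoC.progression.cost"),
            rank_of("model_I.PRLT_SoC.treatment.cost"))
  expect_lt(rank_of("model_I.PRLT_SoC.progression.cost"),
            rank_of("model_I.PRLT_SoC.treatment.cost"))
})

test_that("near-degenerate sampling distributions reproduce the base case", {
  p <- default_parameters()
  for (a in names(p$values$model_I)) {
    for (s in names(p$values$model_I[[a]])) {
      v <- p$values$model_I[[a]][[s]]
      v$cost_sd <- max(v$cost, 1) * 1e-6
      v$beta1 <- v$beta1 * 1e6; v$beta2 <- v$beta2 * 1e6
      p$values$model_I[[a]][[s]] <- v
    }
  }
  base <- run_model_pair("I", p)
  ps <- run_psa("I", p, n_iter = 20, seed = 5, sample_survival = FALSE)
  for (a in c("PRLT_SoC", "SoC")) {
    expect_lt(abs(ps$means$cost[[a]] - if (a == "PRLT_SoC") base$intervention$total_cost
                  else base$comparator$total_cost) /
                ps$means$cost[[a]], 0.001)
  }
  expect_lt(abs(ps$incremental$delta_effect - base$delta_effect), 0.001)
})

test_that("PSA cost deltas are centred on the base case and reproducible by seed", {
  p <- default_parameters()
  ps1 <- run_psa("I", p, n_iter = 60, seed = 42, sample_survival = FALSE)
  ps2 <- run_psa("I", p, n_iter = 60, seed = 42, sample_survival = FALSE)
  expect_identical(ps1$draws, ps2$draws)     # bitwise reproducible
  base <- run_model_pair("I", p)
  dc <- ps1$draws$cost[ps1$draws$strategy == "PRLT_SoC"] -
    ps1$draws$cost[ps1$draws$strategy == "SoC"]
  se <- stats::sd(dc) / sqrt(length(dc))
  expect_lt(abs(mean(dc) - base$delta_cost), 4 * se)
})

test_that("scenario overrides apply exactly and only what they state", {
  p <- default_parameters()
  base <- run_model_pair("I", p)
  # the no-override path is the base case
  expect_equal(run_scenario("base", model = "I", params = p)$icer, base$icer)
  sc <- run_scenario("commercial_price", model = "I", params = p)
  expect_equal(sc$delta_effect, base$delta_effect, tolerance = 1e-12)
  expect_gt(sc$delta_cost, base$delta_cost)
  expect_error(run_scenario("nope", params = p), "unknown scenario")
  expect_error(run_scenario("kreis_cbz_costs", model = "I", params = p),
               "applies to")
  # the 100%-PRLT mix removes the SoC third line from both arms
  mix <- run_scenario("mix_0_100", params = p)
  expect_equal(attr(mix, "scenario"), "mix_0_100")
})

test_that("scenario results line up with their published values", {
  p <- default_parameters()
  tol <- 0.05
  sc1 <- run_scenario("commercial_price", model = "I", params = p)
  expect_lt(abs(sc1$icer - 264367) / 264367, tol)
  sc2 <- run_scenario("kreis_cbz_costs", params = p)
  expect_lt(abs(sc2$icer - 91095) / 91095, tol)
  sc3 <- run_scenario("radium223_soc", params = p)
  expect_lt(abs(sc3$icer - 77632) / 77632, tol)
  sc4 <- run_scenario("commercial_price", model = "II", params = p)
  expect_lt(abs(sc4$icer - 550686) / 550686, tol)
  # third-line mix variants (incremental effects in QALYs)
  expect_lt(abs(run_scenario("mix_25_75", params = p)$delta_effect - 0.07), 0.015)
  expect_lt(abs(run_scenario("mix_0_100", params = p)$delta_effect - 0.06), 0.015)
  m100 <- run_scenario("mix_100_0", params = p)
  expect_lt(abs(m100$delta_effect - 0.12), 0.015)
  expect_lt(abs(m100$delta_cost - 61), 300)
})
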