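test_that("product-limit estimator matches hand computation", {
  km <- km_estimator(pseudo_ipd(c(1, 2, 3), c(1, 0, 1)))
  expect_equal(km_surv_at(km, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(km_surv_at(km, 3), 0, tolerance = 1e-12)

  # all censored: survival stays at 1
  flat <- km_estimator(pseudo_ipd(c(2, 4, 6), c(0, 0, 0)))
  expect_equal(km_surv_at(flat, c(1, 5, 7)), c(1, 1, 1))

  # single subject with an event
  one <- km_estimator(pseudo_ipd(5, 1))
  expect_equal(km_surv_at(one, 5), 0)
  expect_error(km_estimator(pseudo_ipd(numeric(0), integer(0))), "empty")
})

test_that("a censoring-free interval forces the event count from the drop", {
  km <- digitized_km(points = data.frame(time = c(0, 2), survival = c(1, 0.8)),
                     risk_table = data.frame(time = c(0, 3), n_at_risk = c(10, 8)))
  rec <- reconstruct_ipd(km)
  expect_equal(nrow(rec), 10)
  expect_equal(sum(rec$event == 1 & rec$time == 2), 2)
  expect_equal(sum(rec$event == 0), 8)
})

test_that("a flat digitized curve reconstructs to pure censoring", {
  km <- digitized_km(points = data.frame(time = 0:6, survival = rep(1, 7)),
                     risk_table = data.frame(time = c(0, 3, 6),
                                             n_at_risk = c(12, 8, 4)))
  rec <- reconstruct_ipd(km)
  expect_equal(sum(rec$event), 0)
  expect_equal(nrow(rec), 12)
})

test_that("reconstruction round-trips a synthetic digitized curve", {
  ipd <- simulate_ipd(dist_os_prlt_I, n = 300, censor_at = 24, seed = 21)
  km <- make_km_fixture(ipd, grid_step = 1, risk_interval = 3)
  rec <- reconstruct_ipd(km)
  # subject count conserved
  expect_equal(nrow(rec), 300)
  # implied numbers at risk match the table exactly (events placed exactly at
  # a risk time represent drops just before that reading, so they do not
  # count as at risk there; censorings at that time do)
  for (i in seq_len(nrow(km$risk_table))) {
    tt <- km$risk_table$time[i]
    implied <- sum(rec$time > tt | (rec$time == tt & rec$event == 0))
    expect_equal(implied, km$risk_table$n_at_risk[i],
                 info = sprintf("risk time %g", tt))
  }
  # KM of the reconstruction tracks the digitized survival within 0.02
  grid <- 0:24
  expect_lt(max(abs(km_surv_at(km_estimator(rec), grid) -
                      km_surv_at(km_estimator(ipd), grid))), 0.02)
})

test_that("digitization noise is snapped monotone before reconstruction", {
  ipd <- simulate_ipd(dist_os_prlt_I, n = 150, censor_at = 24, seed = 8)
  km <- make_km_fixture(ipd, grid_step = 1, risk_interval = 6,
                        jitter_sd = 0.005, seed = 9)
  expect_true(all(diff(km$points$survival) <= 0))
  rec <- reconstruct_ipd(km)
  expect_equal(nrow(rec), 150)
})

test_that("truth -> KM -> digitize -> reconstruct -> refit recovers parameters within 10%", {
  ipd <- simulate_ipd(dist_os_prlt_I, n = 800, censor_at = 24, seed = 31)
  rec <- reconstruct_ipd(make_km_fixture(ipd, grid_step = 1, risk_interval = 3))
  fit <- fit_parametric(rec, "loglogistic")
  expect_true(fit$converged)
  expect_lt(abs(fit$distribution$params$shape - 1.9263) / 1.9263, 0.10)
  expect_lt(abs(fit$distribution$params$scale - 15.5377) / 15.5377, 0.10)
})

test_that("inconsistent digitized inputs are rejected", {
  expect_error(
    digitized_km(points = data.frame(time = c(0, 1), survival = c(1, 0.9)),
                 risk_table = data.frame(time = 0, n_at_risk = 10)),
    "two entries")
  expect_error(
    digitized_km(points = data.frame(time = c(0, 1), survival = c(1, 0.9)),
                 risk_table = data.frame(time = c(0, 2), n_at_risk = c(5, 9))),
    "non-increasing")
})

test_that("digitized curves and pseudo-IPD round-trip through CSV", {
  ipd <- simulate_ipd(dist_os_prlt_I, n = 40, censor_at = 24, seed = 13)
  km <- make_km_fixture(ipd)
  d <- withr::local_tempdir()
  write_digitized_km(km, file.path(d, "pts.csv"), file.path(d, "risk.csv"))
  km2 <- read_digitized_km(file.path(d, "pts.csv"), file.path(d, "risk.csv"))
  expect_equal(km2$points$survival, km$points$survival, tolerance = 1e-12)
  expect_equal(km2$risk_table$n_at_risk, km$risk_table$n_at_risk)
  write_pseudo_ipd(ipd, file.path(d, "ipd.csv"))
  back <- read_pseudo_ipd(file.path(d, "ipd.csv"))
  expect_equal(back$time, ipd$time, tolerance = 1e-12)
  expect_equal(back$event, ipd$event)
})
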