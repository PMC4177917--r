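test_that("hourly load conversion follows the unit identity", {
  expect_equal(hourly_load(100, 10), 1) # 100 ng/L x 10 m3/h = 1 mg/h
  expect_equal(hourly_load(0, 500), 0)
  expect_equal(hourly_load(2070, 50), 103.5)
  expect_error(hourly_load(-1, 10), "nonnegative")
})

test_that("daily load aggregates 24 hourly loads under a censor policy", {
  # constant 100 ng/L over a flow totalling 1000 m3/d -> 100 mg/d
  series <- make_series(rep(100, 24))
  flows <- make_flows(1000 / 24)
  res <- daily_load(series, flows)
  expect_equal(res$daily_load_mg_d, 100)
  expect_equal(res$n_above_loq, 24)
  expect_equal(res$n_total, 24)
  expect_equal(res$mean_conc_above_loq_ng_l, 100)

  # all censored under the default zero policy
  res0 <- daily_load(make_series(rep(NA_real_, 24)), flows)
  expect_equal(res0$daily_load_mg_d, 0)
  expect_equal(res0$n_above_loq, 0)

  # the same day under the loq policy is bounded by 24 x LOQ x flow
  resq <- daily_load(make_series(rep(NA_real_, 24), loq = 2), flows, policy = "loq")
  expect_equal(resq$daily_load_mg_d, 2 * 1000 / 1000)
})

test_that("daily load matches a brute-force per-hour sum", {
  set.seed(101)
  for (i in 1:20) {
    conc <- runif(24, 0, 500)
    cens <- runif(24) < 0.3
    conc[cens] <- NA
    flow <- runif(24, 20, 120)
    loq <- 5
    series <- make_series(conc, censored = cens, loq = loq)
    flows <- make_flows(flow)
    for (policy in c("zero", "half_loq", "loq")) {
      sub <- c(zero = 0, half_loq = loq / 2, loq = loq)[[policy]]
      brute <- sum(ifelse(cens, sub, conc) * flow / 1000)
      got <- daily_load(series, flows, policy = policy)$daily_load_mg_d
      expect_equal(got, brute, tolerance = 1e-9)
    }
  }
})

test_that("censor policies order the daily load: zero <= half_loq <= loq", {
  set.seed(202)
  for (i in 1:10) {
    conc <- runif(24, 0, 50)
    cens <- runif(24) < 0.5
    conc[cens] <- NA
    series <- make_series(conc, censored = cens, loq = 8)
    flows <- make_flows(runif(24, 10, 100))
    z <- daily_load(series, flows, policy = "zero")$daily_load_mg_d
    h <- daily_load(series, flows, policy = "half_loq")$daily_load_mg_d
    q <- daily_load(series, flows, policy = "loq")$daily_load_mg_d
    expect_lte(z, h)
    expect_lte(h, q)
  }
})

test_that("incomplete days error unless gaps are allowed and renormalised", {
  series <- make_series(rep(100, 12))
  flows <- make_flows(1000 / 24, n = 12)
  expect_error(daily_load(series, flows), "incomplete day")
  res <- daily_load(series, flows, allow_gaps = TRUE)
  # constant signal: renormalising 12 covered hours reproduces the full day
  expect_equal(res$daily_load_mg_d, 100)
})

test_that("the maximum hourly load is reported with its clock time", {
  conc <- rep(50, 24)
  conc[18] <- 2660 # 18:00 sample, i.e. the 17:00-18:00 hour
  series <- make_series(conc)
  flows <- make_flows(50)
  res <- daily_load(series, flows)
  expect_equal(res$max_hourly_load_mg_h, 2660 * 50 / 1000)
  expect_equal(format(res$max_hour, "%H:%M", tz = "UTC"), "18:00")
})

test_that("percent loss is a signed mass balance with a below-LOQ sentinel", {
  expect_equal(round(percent_loss(410, 206)$percent_loss), 50)
  expect_equal(percent_loss(123, 123)$percent_loss, 0)
  expect_equal(round(percent_loss(3230, 6270)$percent_loss), -94)

  sent <- percent_loss(0, 116)
  expect_true(is.na(sent$percent_loss))
  expect_true(sent$influent_below_loq)

  none <- percent_loss(0, 0)
  expect_equal(none$percent_loss, 0)
  expect_false(none$influent_below_loq)
})

test_that("per-capita loads convert mg/d to ug/cap/d", {
  expect_equal(round(per_capita_load(18600, 208000)), 89)
  expect_equal(round(per_capita_load(410, 6230)), 66)
  expect_equal(per_capita_load(0, 1000), 0)
  expect_error(per_capita_load(10, 0), "positive")
})

test_that("detection frequency is the fraction above the LOQ", {
  expect_equal(detection_frequency(make_series(c(rep(100, 18), rep(NA, 6)))), 0.75)
  expect_equal(detection_frequency(rep(TRUE, 24)), 0)
  expect_equal(detection_frequency(c(rep(FALSE, 21), rep(TRUE, 3))), 0.875)
  expect_error(detection_frequency(logical(0)), "empty")
})

test_that("loads scale with flow while percent loss is flow-invariant", {
  set.seed(303)
  conc_i <- runif(24, 10, 400)
  conc_e <- runif(24, 5, 200)
  flow <- runif(24, 30, 90)
  si <- make_series(conc_i)
  se <- make_series(conc_e, matrix = "effluent")
  li1 <- daily_load(si, make_flows(flow))$daily_load_mg_d
  le1 <- daily_load(se, make_flows(flow))$daily_load_mg_d
  li2 <- daily_load(si, make_flows(2 * flow))$daily_load_mg_d
  le2 <- daily_load(se, make_flows(2 * flow))$daily_load_mg_d
  expect_equal(li2, 2 * li1)
  expect_equal(
    percent_loss(li1, le1)$percent_loss,
    percent_loss(li2, le2)$percent_loss
  )
})

test_that("summarise_loads produces per-analyte rows with per-capita figures", {
  sim <- simulate_study(simulation_config(seed = 9, noise_cv = 0))
  summ <- summarise_loads(sim$samples, sim$flows, population = 6230)
  expect_equal(nrow(summ), 2 * nrow(sim$truth)) # influent + effluent
  infl <- summ[summ$matrix == "influent", ]
  merged <- merge(infl, sim$truth, by = "analyte")
  expect_equal(
    merged$per_capita_ug_cap_d,
    merged$true_mass_mg_d * 1000 / 6230,
    tolerance = 1e-9
  )
  rem <- removal_table(summ)
  expect_equal(nrow(rem), nrow(sim$truth))
})
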