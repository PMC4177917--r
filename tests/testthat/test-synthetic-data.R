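test_that("diurnal flow conserves the daily per-capita volume exactly", {
  cfg <- oc_config(population = 6230)
  fl <- simulate_diurnal_flow(cfg)
  expect_equal(nrow(fl), 24)
  # 6230 people x 230 L/cap/d = 1432.9 m3/d
  expect_equal(sum(fl$flow_m3_h), 1432.9, tolerance = 1e-12)
  expect_true(all(fl$flow_m3_h > 0))

  flat <- simulate_diurnal_flow(
    oc_config(population = 6230, diurnal_amplitude = 0)
  )
  expect_equal(flat$flow_m3_h, rep(1432.9 / 24, 24))

  expect_error(oc_config(diurnal_amplitude = 1), "amplitude")
  expect_error(oc_config(retention_h = -1), "retention")
})

test_that("the simulator is deterministic under a fixed seed", {
  a <- simulate_study(oc_config(seed = 11, noise_cv = 0.3))
  b <- simulate_study(oc_config(seed = 11, noise_cv = 0.3))
  expect_identical(a, b)
  c <- simulate_study(oc_config(seed = 12, noise_cv = 0.3))
  expect_false(identical(a$samples$conc_ng_l, c$samples$conc_ng_l))
})

test_that("influent pulses conserve the excreted mass", {
  # one user, 0.150 g/d, 80% excreted -> 120 mg into the sewer
  cfg <- oc_config(n_users = 1, dose_g_d = 0.150, noise_cv = 0)
  infl <- simulate_influent(cfg)
  expect_equal(sum(infl$hourly_mass_mg$mass_mg), 120)
  expect_equal(infl$truth$true_mass_mg_d, 120)

  # noise-free: recovered daily load equals simulation truth (several seeds,
  # multi-analyte default roster)
  for (seed in 1:5) {
    cfg <- simulation_config(seed = seed, noise_cv = 0)
    infl <- simulate_influent(cfg)
    summ <- summarise_loads(infl$samples, infl$flows, policy = "zero")
    merged <- merge(summ, infl$truth, by = "analyte")
    expect_equal(merged$daily_load_mg_d, merged$true_mass_mg_d,
      tolerance = 1e-9
    )
  }
})

test_that("no users means nothing to detect", {
  infl <- simulate_influent(oc_config(n_users = 0))
  expect_true(all(infl$samples$censored))
  expect_equal(infl$truth$true_mass_mg_d, 0)
})

test_that("small catchments show higher hourly variability than large ones", {
  # Monte-Carlo over replicate days: empirical CV of the hourly arriving
  # mass for a handful of users vs thousands at identical settings
  cv_of <- function(population, n_users, n_rep = 100) {
    cvs <- vapply(seq_len(n_rep), function(s) {
      infl <- simulate_influent(
        oc_config(
          seed = 1000 + s, population = population,
          n_users = n_users, noise_cv = 0
        )
      )
      m <- infl$hourly_mass_mg$mass_mg
      sd(m) / mean(m)
    }, numeric(1))
    mean(cvs)
  }
  small <- cv_of(500, 3)
  large <- cv_of(100000, 600)
  expect_gt(small, large)
})

test_that("effluent applies removal, retention shift and re-censoring", {
  # identity: removal 0, retention 0, no noise
  cfg <- oc_config(removal = 0, retention_h = 0, noise_cv = 0)
  infl <- simulate_influent(cfg)
  effl <- simulate_effluent(infl, cfg)
  expect_equal(effl$conc_ng_l, infl$samples$conc_ng_l)
  expect_equal(effl$censored, infl$samples$censored)

  # scaling: removal 0.5 halves the daily load
  cfg <- oc_config(removal = 0.5, noise_cv = 0, n_users = 10)
  infl <- simulate_influent(cfg)
  effl <- simulate_effluent(infl, cfg)
  both <- summarise_loads(
    dplyr::bind_rows(infl$samples, effl), infl$flows,
    policy = "zero"
  )
  il <- both$daily_load_mg_d[both$matrix == "influent"]
  el <- both$daily_load_mg_d[both$matrix == "effluent"]
  expect_equal(el, il / 2, tolerance = 1e-9)

  # complete removal: everything censored
  cfg <- oc_config(removal = 1, noise_cv = 0)
  infl <- simulate_influent(cfg)
  effl <- simulate_effluent(infl, cfg)
  expect_true(all(effl$censored))

  # the retention shift is circular: mass is conserved across the day
  cfg <- oc_config(removal = 0, retention_h = 8, noise_cv = 0, n_users = 10)
  infl <- simulate_influent(cfg)
  effl <- simulate_effluent(infl, cfg)
  el <- summarise_loads(effl, infl$flows, policy = "zero")$daily_load_mg_d
  expect_equal(el, infl$truth$true_mass_mg_d, tolerance = 1e-9)
})

test_that("river network dilutes the summed upstream load", {
  # one site, known load, known flow: 1000 mg/d into 10,000 m3/d -> 100 ng/L
  cfg <- oc_config(
    noise_cv = 0, population = 1000,
    river_sites = tibble::tibble(
      site_id = "S1", upstream_population = 1000, flow_m3_d = 10000
    )
  )
  truth <- tibble::tibble(
    analyte = "Oseltamivir carboxylate",
    true_mass_mg_d = 1000, true_removal = 0, true_users = 8L
  )
  riv <- simulate_river_network(cfg, truth)
  expect_equal(riv$true_load_mg_d, 1000)
  expect_equal(riv$conc_ng_l, 100)

  # linearity: doubling the upstream population doubles the load
  cfg2 <- oc_config(
    noise_cv = 0,
    river_sites = tibble::tibble(
      site_id = c("S1", "S2"),
      upstream_population = c(1000, 2000), flow_m3_d = c(10000, 10000)
    )
  )
  riv2 <- simulate_river_network(cfg2, truth)
  expect_equal(riv2$true_load_mg_d[2], 2 * riv2$true_load_mg_d[1])

  # misordered sites and dry rivers are rejected
  bad <- oc_config(river_sites = tibble::tibble(
    site_id = c("a", "b"), upstream_population = c(2000, 1000),
    flow_m3_d = c(1, 1)
  ))
  expect_error(simulate_river_network(bad, truth), "nondecreasing")
})

test_that("raising the LOQ never decreases the number of censored samples", {
  sim <- simulate_study(simulation_config(seed = 3, noise_cv = 0.3))
  s <- sim$samples
  for (k in c(1, 2, 5, 10)) {
    n_k <- sum(s$censored | (!is.na(s$conc_ng_l) & s$conc_ng_l < k * s$loq_ng_l))
    expect_gte(n_k, sum(s$censored))
    if (k > 1) {
      n_prev <- sum(s$censored |
        (!is.na(s$conc_ng_l) & s$conc_ng_l < (k - 1) * s$loq_ng_l))
      expect_gte(n_k, n_prev)
    }
  }
})

test_that("written simulations read back through the standard readers", {
  sim <- simulate_study(simulation_config(seed = 5))
  dir <- tempfile()
  write_simulation(sim, dir)
  samples <- read_sample_series(file.path(dir, "samples.csv"))
  expect_equal(nrow(samples), nrow(sim$samples))
  flows <- read_flow_series(file.path(dir, "flows.csv"))
  expect_equal(flows$flow_m3_h, sim$flows$flow_m3_h)
  truth <- readr::read_csv(file.path(dir, "truth.csv"),
    show_col_types = FALSE
  )
  expect_equal(truth$true_mass_mg_d, sim$truth$true_mass_mg_d)
})
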