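test_that("grow_step applies multiplicative growth and ages the cell", {
  c1 <- grow_step(cell_state(10), 0.006)
  expect_equal(c1$size, 10.06)
  expect_equal(c1$age, 1)
  expect_equal(grow_step(cell_state(10), 0)$size, 10)
  # 100 steps vs closed form, and vs an explicit loop oracle
  cl <- cell_state(10)
  loop <- 10
  for (k in 1:100) {
    cl <- grow_step(cl, 0.006)
    loop <- loop * 1.006
  }
  expect_equal(cl$size, 10 * 1.006^100, tolerance = 1e-12)
  expect_equal(cl$size, loop, tolerance = 1e-12)
  expect_equal(cl$size, 18.1885497, tolerance = 1e-7)
  # septated cells do not elongate but still age
  sep <- cell_state(12, phase = "septated", septation_entry_time = 5)
  sep2 <- grow_step(sep, 0.006)
  expect_equal(sep2$size, 12)
  expect_equal(sep2$age, 1)
  expect_error(grow_step(cell_state(10), -0.1), "growth_rate")
})

test_that("size doubles in 116 one-minute steps at growth 0.006", {
  cl <- cell_state(10)
  k <- 0
  while (cl$size < 20) {
    cl <- grow_step(cl, 0.006)
    k <- k + 1
  }
  expect_true(abs(k - 116) <= 1)
})

test_that("division_decision implements each rule's trigger", {
  mk <- function(size, birth = size / 1.9, age = 50, thr = NA, cyc = 0)
    cell_state(size, birth_size = birth, age = age, cyclin = cyc,
               rule_threshold = thr)
  gr <- gaussian_rule(14.5, 1.2)
  expect_false(division_decision(mk(14.4, thr = 14.5), "sizer", gr))
  expect_true(division_decision(mk(14.5, thr = 14.5), "sizer", gr))
  expect_true(division_decision(mk(14, birth = 7, thr = 7), "adder", gr))
  expect_false(division_decision(mk(13.9, birth = 7, thr = 7), "adder", gr))
  expect_true(division_decision(mk(10, age = 100, thr = 100), "timer", gr))
  expect_false(division_decision(mk(10, age = 99, thr = 100), "timer", gr))
  # min_cycle_duration gates every rule
  expect_false(division_decision(mk(20, age = 10, thr = 14.5), "sizer", gr,
                                 min_cycle_duration = 20))
  # pdiv with pmax 0 never fires
  z <- hill_curve(0, 14, 14)
  expect_false(any(vapply(1:100, function(i)
    division_decision(mk(20), "pdiv", z), logical(1))))
  # cdc13 compares amount or concentration with the per-cell threshold
  cp_a <- cdc13_params(threshold_mode = "amount")
  cp_c <- cdc13_params(threshold_mode = "concentration")
  expect_true(division_decision(mk(10, thr = 6, cyc = 6.1), "cdc13", cp_a))
  expect_false(division_decision(mk(10, thr = 6, cyc = 5.9), "cdc13", cp_a))
  expect_true(division_decision(mk(10, thr = 6, cyc = 61), "cdc13", cp_c))
  expect_false(division_decision(mk(10, thr = 6, cyc = 59), "cdc13", cp_c))
})

test_that("pdiv long-run trigger frequency on the plateau equals pmax", {
  set.seed(7)
  cell <- cell_state(1000, age = 50)   # far above the EC50
  hc <- hill_curve(0.1, 14, 14)
  hits <- sum(vapply(1:1e5, function(i)
    division_decision(cell, "pdiv", hc), logical(1)))
  expect_equal(hits / 1e5, 0.1, tolerance = 0.04)  # ~4 SE at n = 1e5
})

test_that("cdc13_update follows the printed accumulation arithmetic", {
  p0 <- cdc13_params(synthesis_noise_sd = 0, synthesis_mode = "absolute")
  c1 <- cdc13_update(cell_state(10, cyclin = 5), p0)
  expect_equal(c1$cyclin, 5.0699)
  pid <- cdc13_params(synthesis_rate = 0, synthesis_noise_sd = 0,
                      degradation_rate = 0)
  expect_equal(cdc13_update(cell_state(10, cyclin = 3), pid)$cyclin, 3)
  # size-proportional synthesis uses the current size
  psz <- cdc13_params(synthesis_noise_sd = 0, degradation_rate = 0,
                      synthesis_mode = "size_proportional")
  expect_equal(cdc13_update(cell_state(10, cyclin = 0), psz)$cyclin, 0.7)
})

test_that("concentration threshold is first crossed near 110 min from birth at size 7", {
  # deterministic single cell: dC/dt ~ 0.07 - g*C from C = 0.7 crosses 6
  # at ~110 min (continuous-time oracle: 110.04)
  p <- cdc13_params(synthesis_noise_sd = 0,
                    synthesis_mode = "size_proportional",
                    threshold_mode = "concentration")
  cl <- cell_state(7, cyclin = 0.7 * 7)
  t <- 0
  while (cl$cyclin / cl$size < 6 && t < 400) {
    cl <- grow_step(cl, 0.006)
    cl <- cdc13_update(cl, p)
    t <- t + 1
  }
  expect_true(t >= 105 && t <= 115)
})

test_that("divide_cell conserves daughter mass and emits exact records", {
  cfg <- sim_config("pdiv", asymmetry_sd = 0, seed = 1)
  cell <- cell_state(14, birth_size = 7.2, birth_time = 100, age = 60)
  out <- divide_cell(cell, cfg, time = 160)
  expect_equal(out$daughters[[1]]$size, 7.35)
  expect_equal(out$daughters[[2]]$size, 7.35)
  expect_equal(out$record$extension, 14 - 7.2)
  expect_equal(out$record$duration, 60)
  expect_equal(out$record$division_time, 160)
  # conservation holds exactly for arbitrary asymmetry draws
  cfg2 <- sim_config("pdiv", seed = 2)
  set.seed(11)
  for (i in 1:50) {
    D <- runif(1, 4, 30)
    dd <- divide_cell(cell_state(D, birth_size = D / 1.9, age = 50),
                      cfg2, time = 10)
    expect_equal(dd$daughters[[1]]$size + dd$daughters[[2]]$size, 1.05 * D)
    expect_true(min(dd$daughters[[1]]$size, dd$daughters[[2]]$size) > 0)
  }
  # founders produce no record
  f <- cell_state(14, record_birth = FALSE)
  expect_null(divide_cell(f, cfg2, time = 50)$record)
  # cdc13 daughters are born with birth_level_factor * birth_size of cyclin
  cfgc <- sim_config("cdc13", asymmetry_sd = 0, seed = 3)
  dc <- divide_cell(cell_state(14, cyclin = 90, age = 100), cfgc, time = 200)
  expect_equal(dc$daughters[[1]]$cyclin, 0.7 * dc$daughters[[1]]$size)
})

test_that("init_population draws the configured Gaussian, truncated positive", {
  set.seed(5)
  pop <- init_population(sim_config("pdiv", n_init = 20, init_sd = 0))
  expect_length(pop, 20)
  expect_true(all(vapply(pop, `[[`, numeric(1), "size") == 14))
  expect_false(any(vapply(pop, `[[`, logical(1), "record_birth")))
  pop2 <- init_population(sim_config("pdiv", n_init = 400))
  m <- mean(vapply(pop2, `[[`, numeric(1), "size"))
  expect_true(abs(m - 14) < 3 * 1.4 / sqrt(400))
  expect_error(sim_config("pdiv", init_sd = -1), "init_sd")
})

test_that("run_simulation is deterministic given the seed", {
  cfg <- sim_config("pdiv", t_max = 400, seed = 99)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$snapshot, s2$snapshot)
})

test_that("a never-firing hazard leaves the population undivided", {
  cfg <- sim_config("pdiv", t_max = 300,
                    rule_params = hill_curve(0, 14, 14), seed = 4)
  sim <- run_simulation(cfg)
  expect_equal(nrow(sim$records), 0)
  expect_equal(nrow(sim$snapshot), 20)
})

test_that("record fields satisfy their defining identities", {
  rec <- run_simulation(sim_config("pdiv", t_max = 500, seed = 12))$records
  expect_true(nrow(rec) > 50)
  expect_equal(rec$extension, rec$division_size - rec$birth_size)
  expect_equal(rec$duration, rec$division_time - rec$birth_time)
  expect_true(all(rec$division_time > rec$birth_time))
  expect_true(all(rec$birth_size > 0))
})

test_that("simulated division sizes match the survival-product hazard oracle", {
  # Cohort of 10^4 cells born at exactly size 10 (no asymmetry noise): the
  # empirical division-size CDF must match the discrete survival product
  # S(s_k) = prod(1 - p(s_j)) along the growth trajectory.
  b <- 10
  cfg <- sim_config("pdiv", n_init = 10000, t_max = 250, init_mean = b,
                    init_sd = 0, asymmetry_sd = 0, seed = 314)
  sim <- run_simulation(cfg, record_initial = TRUE)
  founders <- sim$records[sim$records$birth_time == 0, ]
  expect_gte(nrow(founders), 9990)   # essentially all divided by t = 250
  k_obs <- round(log(founders$division_size / b) / log(1.006))
  kmax <- 250
  s_k <- b * 1.006^(1:kmax)
  p_k <- hill_eval(hill_curve(0.1, 14, 14), s_k)
  S <- cumprod(1 - p_k)
  pmf <- c(p_k[1], S[-kmax] * p_k[-1])
  cdf <- cumsum(pmf) / sum(pmf)
  ecdf_k <- cumsum(tabulate(k_obs, nbins = kmax)) / length(k_obs)
  expect_lt(max(abs(ecdf_k - cdf)), 0.02)
})

test_that("snapshot_series respects septation and the seeding contract", {
  cfg0 <- sim_config("pdiv", t_max = 300, seed = 8)
  snaps <- snapshot_series(cfg0, 50)
  expect_true(all(snaps$phase == "growing"))   # instantaneous division
  expect_identical(snapshot_series(cfg0, 50), snaps)
  expect_error(snapshot_series(cfg0, 0), "sample_interval")
  # septated cells retain their trigger size (never larger than growing max)
  cfg1 <- sim_config("pdiv", t_max = 400, septation_duration = 30, seed = 9)
  sn <- snapshot_series(cfg1, 100)
  expect_true(any(sn$phase == "septated"))
  expect_true(all(sn$size > 0))
})
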