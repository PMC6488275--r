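test_that("fantes_fit recovers the classical algebraic identities", {
  # perfect sizer: constant division size, slope exactly -1
  sizer <- data.frame(birth_size = c(6, 6.5, 7, 7.5, 8), division_size = 14)
  expect_equal(fantes_fit(sizer)$slope, -1)
  # perfect adder: constant extension, slope exactly 0
  adder <- data.frame(birth_size = c(6, 6.5, 7, 7.5, 8),
                      division_size = c(6, 6.5, 7, 7.5, 8) + 6.75)
  expect_equal(fantes_fit(adder)$slope, 0)
  # perfect timer at growth 0.006 for 100 min: slope e^(gT) - 1
  timer <- data.frame(birth_size = c(6, 6.5, 7, 7.5, 8),
                      division_size = c(6, 6.5, 7, 7.5, 8) * 1.006^100)
  expect_equal(fantes_fit(timer)$slope, 1.006^100 - 1, tolerance = 1e-9)
  expect_error(fantes_fit(sizer[1:2, ]), "3 division records")
  expect_error(fantes_fit(data.frame(birth_size = rep(7, 5),
                                     division_size = 14)), "variance")
})

test_that("noiseless simulations are separable by Fantes slope alone", {
  sl <- function(rule, params) {
    rec <- run_simulation(sim_config(rule, t_max = 700, rule_params = params,
                                     seed = 17))$records
    expect_gt(nrow(rec), 500)
    fantes_fit(rec)$slope
  }
  expect_equal(sl("sizer", gaussian_rule(14.5, 1e-9)), -1, tolerance = 0.02)
  expect_equal(sl("adder", gaussian_rule(6.75, 1)), 0, tolerance = 0.1)
  expect_equal(sl("timer", gaussian_rule(100, 1e-9)), 1.006^100 - 1,
               tolerance = 0.02)
})

test_that("division_cov matches the hand oracle and is scale invariant", {
  expect_equal(division_cov(c(14, 14, 14)), 0)
  expect_equal(division_cov(c(10, 10, 14, 14)), sqrt(16 / 3) / 12,
               tolerance = 1e-12)
  set.seed(3)
  x <- runif(200, 8, 20)
  for (c in c(0.1, 3, 250))
    expect_equal(division_cov(c * x), division_cov(x), tolerance = 1e-12)
  expect_error(division_cov(7), "at least 2")
})

test_that("distribution_summary applies the boxplot convention", {
  s <- distribution_summary(1:100)
  expect_equal(s$q25, 25.75)
  expect_equal(s$median, 50.5)
  expect_equal(s$q75, 75.25)
  expect_length(s$outliers, 0)
  konst <- distribution_summary(rep(5, 10))
  expect_true(all(c(konst$q25, konst$median, konst$q75,
                    konst$whisker_low, konst$whisker_high) == 5))
  expect_length(konst$outliers, 0)
  out <- distribution_summary(c(1, 2, 3, 4, 100))
  expect_equal(out$outliers, 100)   # beyond q75 + 1.5 IQR = 7
  expect_equal(out$whisker_high, 4) # furthest point within the fence
  expect_equal(out$whisker_low, 1)
  expect_error(distribution_summary(numeric(0)), "non-empty")
})

test_that("a sweep grid point equals a direct simulation with the derived seed", {
  base <- sim_config("pdiv", t_max = 500, seed = 5)
  sw <- sweep_grid(base, ec50_values = 14, n_values = 14, reps = 1)
  cfg <- base
  cfg$seed <- derive_seed(5, "sweep/14/14/1")
  rec <- run_simulation(cfg)$records
  expect_equal(sw$mean_size[1, 1], mean(rec$division_size))
  expect_equal(sw$cov[1, 1], division_cov(rec))
  expect_equal(sw$fantes_slope[1, 1], fantes_fit(rec)$slope)
})

test_that("sweep results are reproducible and tidy-exportable", {
  base <- sim_config("pdiv", t_max = 400, seed = 23)
  a <- sweep_grid(base, ec50_values = c(12, 16), n_values = c(8, 14), reps = 1)
  b <- sweep_grid(base, ec50_values = c(12, 16), n_values = c(8, 14), reps = 1)
  expect_identical(a$mean_size, b$mean_size)
  expect_identical(a$fantes_slope, b$fantes_slope)
  df <- as.data.frame(a)
  expect_equal(nrow(df), 4)
  expect_named(df, c("ec50", "n", "mean_size", "cov", "fantes_slope", "reps"))
  expect_equal(df$mean_size[df$ec50 == 12 & df$n == 8], a$mean_size["12", "8"])
})
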