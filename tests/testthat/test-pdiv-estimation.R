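test_that("bin_fraction_septated counts and filters per bin", {
  tab <- data.frame(size = c(seq(10.05, 10.95, length.out = 10),
                             seq(12.1, 12.4, length.out = 4)),
                    septated = c(rep(c(TRUE, FALSE, FALSE), length.out = 10),
                                 rep(TRUE, 4)))
  # 10 cells in [10,11): 3 septated (wait: pattern T,F,F x10 -> 4 TRUE)
  b <- bin_fraction_septated(tab, bin_width = 1, min_count = 10)
  expect_equal(nrow(b), 1)                      # the 4-cell bin is dropped
  expect_equal(b$n_total, 10)
  expect_equal(b$fraction, mean(c(rep(c(TRUE, FALSE, FALSE),
                                      length.out = 10))))
  b2 <- bin_fraction_septated(tab, bin_width = 1, min_count = 4)
  expect_equal(nrow(b2), 2)
  expect_equal(b2$fraction[2], 1)               # saturation case
  # exact counting oracle: 3 of 10
  t3 <- data.frame(size = rep(10.5, 10), septated = rep(c(1, 0), c(3, 7)))
  expect_equal(bin_fraction_septated(t3, min_count = 5)$fraction, 0.3)
  expect_error(bin_fraction_septated(t3[0, ]), "empty")
  expect_error(bin_fraction_septated(t3, bin_width = 0), "bin_width")
})

test_that("fit_hill is an exact round trip on noiseless fractions", {
  centers <- 8:20
  truth <- hill_curve(0.1, 14, 14)
  d <- data.frame(center = centers, fraction = hill_eval(truth, centers))
  fit <- fit_hill(d)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(0.1, 14, 14), tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
  # invariant under bin reordering
  fit2 <- fit_hill(d[sample(nrow(d)), ])
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-6)
})

test_that("fit_hill flags degenerate inputs instead of raising", {
  centers <- 8:20
  dec <- data.frame(center = centers,
                    fraction = seq(0.9, 0.1, length.out = 13))
  fit <- fit_hill(dec)
  expect_s3_class(fit, "hill_fit")
  expect_true(!fit$converged || fit$boundary)
  expect_error(fit_hill(data.frame(center = centers, fraction = 0)), "zero")
  expect_error(fit_hill(data.frame(center = 1:3, fraction = c(0, .5, 1))),
               "4 bins")
})

test_that("rate conversions are exact and mutually inverse", {
  expect_equal(rate_from_fraction(0, 30), 0)
  expect_equal(rate_from_fraction(0, 30, "steady_state"), 0)
  expect_equal(rate_from_fraction(0.9, 30), 0.03)
  # steady-state mode inverts the occupancy relation exactly on (0,1)
  h <- c(0.001, 0.01, 0.05, 0.1, 0.5, 2)
  occ <- occupancy_from_rate(h, 30)
  expect_equal(rate_from_fraction(occ, 30, "steady_state"), h)
  expect_error(rate_from_fraction(1, 30, "steady_state"), "infinite")
  expect_error(rate_from_fraction(0.5, 0), "septation_time")
  expect_error(rate_from_fraction(1.2, 30), "fraction")
})

test_that("pdiv_timecourse tracks an EC50 shift and isolates failures", {
  sizes <- runif(20000, 6, 20)
  t1 <- bernoulli_sept_table(hill_curve(0.8, 12, 10), sizes, seed = 21)
  t2 <- bernoulli_sept_table(hill_curve(0.8, 9, 10), sizes, seed = 22)
  fits <- pdiv_timecourse(list(early = t1, late = t2), min_count = 50)
  expect_s3_class(fits[[1]], "hill_fit")
  expect_lt(fits$late$curve$ec50, fits$early$curve$ec50)
  # determinism: identical tables give identical fits
  fits_b <- pdiv_timecourse(list(early = t1, late = t2), min_count = 50)
  expect_equal(coef(fits_b$early), coef(fits$early))
  # an unfittable table is flagged in place, the rest still returned
  bad <- data.frame(size = runif(100, 6, 20), septated = FALSE)
  mixed <- pdiv_timecourse(list(ok = t1, bad = bad), min_count = 5)
  expect_s3_class(mixed$bad, "hill_fit_failure")
  expect_false(mixed$bad$converged)
  expect_s3_class(mixed$ok, "hill_fit")
})
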