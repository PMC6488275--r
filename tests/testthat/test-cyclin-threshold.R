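test_that("assign_bins uses half-open equal-width bins over the stated range", {
  tab <- data.frame(size = c(10.5, 11, 17.99, 18, 9.9, 18.1),
                    septated = FALSE)
  b <- assign_bins(tab, n_bins = 8, size_range = c(10, 18))
  expect_equal(nrow(b), 4)                     # 9.9 and 18.1 excluded
  expect_equal(b$bin[b$size == 10.5], 1)       # width-1 bins from 10
  expect_equal(b$bin[b$size == 11], 2)         # interior edge -> right bin
  expect_equal(b$bin[b$size == 17.99], 8)
  expect_equal(b$bin[b$size == 18], 8)         # last bin closed
  b1 <- assign_bins(tab, n_bins = 1, size_range = c(9, 19))
  expect_true(all(b1$bin == 1))
  expect_error(assign_bins(tab, n_bins = 0, size_range = c(10, 18)), "n_bins")
  expect_error(assign_bins(tab, size_range = c(18, 10)), "size_range")
  # default range comes from septated permissive cells
  tab2 <- data.frame(size = c(5, 12, 14, 16, 20),
                     septated = c(FALSE, TRUE, TRUE, TRUE, FALSE),
                     condition = "permissive")
  b2 <- assign_bins(tab2, n_bins = 4)
  expect_equal(range(attr(b2, "edges")), c(12, 16))
})

test_that("bin_threshold averages the k brightest cells", {
  expect_equal(bin_threshold(1:20, k = 10), 15.5)
  expect_equal(bin_threshold(rep(7, 12)), 7)
  expect_equal(bin_threshold(c(3, 1, 2), k = 3), 2)   # exactly k: plain mean
  expect_warning(thr <- bin_threshold(1:5, k = 10), "flagged")
  expect_true(is.na(thr))
})

test_that("global_threshold is the unweighted mean over valid bins", {
  expect_equal(global_threshold(c(170, 190)), 180)
  expect_equal(global_threshold(c(NA, 120, NA)), 120)
  expect_error(global_threshold(c(NA_real_, NA_real_)), "no valid")
})

test_that("per-bin probabilities follow the counting oracles", {
  tab <- data.frame(size = c(rep(10.5, 10), rep(12.5, 3)),
                    septated = c(rep(TRUE, 3), rep(FALSE, 7), rep(TRUE, 3)),
                    fluor = c(100, 200, 300, rep(50, 7), 240, 150, 90))
  b <- assign_bins(tab, n_bins = 4, size_range = c(10, 14))
  ps <- p_septation_per_bin(b)
  expect_equal(ps[1], 0.3)
  expect_true(is.na(ps[2]))                    # empty bin flagged, not 0
  expect_equal(ps[3], 1)
  psu <- p_suprathreshold_per_bin(b, 180)
  expect_equal(psu[1], 0.2)                    # 200, 300 of ten
  expect_equal(psu[3], 1 / 3)                  # strict >: 240 only
  expect_equal(p_suprathreshold_per_bin(b, 1000)[1], 0)
  # threshold 0 saturates every bin with positive fluorescence
  expect_equal(p_suprathreshold_per_bin(b, 0)[1], 1)
  po <- p_overlap_per_bin(b, c(150, 250))
  expect_equal(po[1], 0.1)                     # of ten, only the 200
  expect_equal(po[3], 2 / 3)                   # 240 and 150, inclusive ends
  expect_equal(p_overlap_per_bin(b, c(0, 1e6))[1], 1)
  expect_equal(p_overlap_per_bin(b, c(149, 149.5))[1], 0)
  expect_error(p_overlap_per_bin(b, c(5, 1)), "lo > hi")
})

test_that("p_suprathreshold is monotone nonincreasing in the threshold", {
  set.seed(8)
  tab <- data.frame(size = runif(400, 10, 18), septated = FALSE,
                    fluor = rlnorm(400, 5, 0.4))
  b <- assign_bins(tab, n_bins = 8, size_range = c(10, 18))
  thr <- sort(runif(10, 50, 400))
  ps <- sapply(thr, function(t) p_suprathreshold_per_bin(b, t))
  for (bin in 1:8) expect_true(all(diff(ps[bin, ]) <= 0))
})

test_that("threshold_correlation handles signs, NAs and degeneracy", {
  x <- c(0.1, 0.4, 0.7, 0.9)
  expect_equal(threshold_correlation(x, x), 1)
  expect_equal(threshold_correlation(x, -x), -1)
  expect_equal(threshold_correlation(c(x, NA), c(-x, 0.5)), -1)
  expect_error(threshold_correlation(x[1:2], x[1:2]), "3 paired")
  expect_error(threshold_correlation(x, rep(1, 4)), "variance")
})

test_that("threshold_analysis is invariant under row shuffling", {
  tab <- make_threshold_tables(2500, cv = 0.1, seed = 61)
  r1 <- threshold_analysis(tab)
  set.seed(99)
  r2 <- threshold_analysis(tab[sample(nrow(tab)), ])
  expect_equal(r2$per_bin, r1$per_bin)
  expect_equal(r2$global_threshold, r1$global_threshold)
  expect_equal(r2$correlation_sept_vs_supra, r1$correlation_sept_vs_supra)
})

test_that("decile_window_cov centers the window at the interpolated decile", {
  tab <- data.frame(size = c(10:19, 11:14), fluor = c(rep(0, 10), rep(80, 4)),
                    septated = rep(c(TRUE, FALSE), c(10, 4)),
                    condition = rep(c("permissive", "restrictive"), c(10, 4)))
  dw <- decile_window_cov(tab, decile = 0.1, half_window = 1.2)
  expect_equal(dw$center, 10.9)
  expect_equal(dw$cov_fluor_in_window, 0)      # constant fluor in window
  expect_equal(dw$n_window, 2)                 # sizes 11 and 12
  expect_true(dw$low_confidence)
  expect_equal(dw$cov_division_size, sd(10:19) / mean(10:19))
  # infinite window equals the plain CoV of restrictive fluorescence
  tab$fluor[tab$condition == "restrictive"] <- c(60, 70, 80, 90)
  dwi <- decile_window_cov(tab, half_window = Inf)
  expect_equal(dwi$cov_fluor_in_window,
               sd(c(60, 70, 80, 90)) / mean(c(60, 70, 80, 90)))
})

test_that("noisier cyclin expression raises both window CoV and size CoV", {
  mk <- function(noise_sd, seed)
    make_threshold_tables(3000, cv = 0.05, seed = seed,
                          pars = threshold_world(synthesis_noise_sd = noise_sd))
  quiet <- decile_window_cov(mk(0.05, 121), half_window = 1)
  noisy <- decile_window_cov(mk(0.8, 131), half_window = 1)
  expect_false(quiet$low_confidence)
  expect_false(noisy$low_confidence)
  expect_gt(noisy$cov_fluor_in_window, quiet$cov_fluor_in_window)
  expect_gt(noisy$cov_division_size, quiet$cov_division_size)
})
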