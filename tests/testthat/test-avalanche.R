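test_that("merged mean ISI matches hand values and the pooled-Poisson rate", {
  expect_equal(merged_mean_isi(c(0, 1)), 1)
  set.seed(1)
  # pooled train at total rate R: mean ISI ~ 1/R
  R <- 8  # spikes per ms
  tt <- cumsum(rexp(20000, R))
  expect_equal(merged_mean_isi(tt), 1 / R, tolerance = 0.03)
  expect_error(merged_mean_isi(1), "at least 2")
})

test_that("avalanche extraction: runs, boundary censoring, conservation, bin monotonicity", {
  av <- extract_avalanches(c(0, 2, 1, 0, 0, 3, 0), dt = 1)
  expect_equal(av$sizes, c(3L, 3L))
  expect_equal(av$durations, c(2L, 1L))
  expect_equal(av$profiles, list(c(2L, 1L), 3L))
  expect_equal(extract_avalanches(rep(0, 10))$sizes, integer(0))
  # runs touching either boundary are censored and discarded
  av2 <- extract_avalanches(c(1, 1, 0, 2))
  expect_length(av2$sizes, 0)
  expect_equal(av2$discarded_spikes, 4)
  # conservation: sizes + discarded = total spikes
  set.seed(2)
  cnt <- rpois(5000, 0.6)
  av3 <- extract_avalanches(cnt)
  expect_equal(sum(av3$sizes) + av3$discarded_spikes, sum(cnt))
  # widening the bin merges avalanches: count nonincreasing in dt
  times <- sort(runif(3000, 0, 1000))
  n_av <- vapply(c(0.2, 0.5, 1, 2, 5), function(dt)
    length(avalanches_from_spikes(times, dt = dt, t_range = c(0, 1000))$sizes),
    numeric(1))
  expect_true(all(diff(n_av) <= 0))
  expect_error(extract_avalanches(c(1, -1)), "nonnegative")
})

test_that("truncated power-law MLE recovers a known exponent and range", {
  x <- sample_discrete_powerlaw(2, 4, 100, 5e4, seed = 21)
  f <- fit_truncated_powerlaw(x, seed = 1)
  expect_true(f$found)
  expect_equal(f$exponent, 2, tolerance = 0.025)
  # recovered range covers at least 80% of the true range in log width
  expect_gt(log10(f$s_max / f$s_min), 0.8 * log10(100 / 4))
  expect_gt(f$p, 0.1)
})

test_that("degenerate and misspecified samples yield no wide power-law range", {
  expect_false(fit_truncated_powerlaw(rep(7L, 500))$found)
  set.seed(3)
  g <- rgeom(5e4, 0.2) + 1L
  fg <- fit_truncated_powerlaw(g, seed = 2)
  if (fg$found) expect_lt(log10(fg$s_max / fg$s_min), 0.5)
  expect_error(fit_truncated_powerlaw(1:50), "at least 100")
})

test_that("size-versus-duration fit is exact on log-linear data, robust to noise", {
  durs <- rep(4:40, times = 5)
  sizes <- durs^1.3
  sv <- fit_size_vs_duration(list(sizes = sizes, durations = durs))
  expect_equal(sv$exponent, 1.3, tolerance = 1e-12)
  # multiplicative lognormal noise at 10^4 avalanches
  set.seed(4)
  durs2 <- sample(4:60, 1e4, replace = TRUE)
  sizes2 <- durs2^1.3 * exp(rnorm(1e4, 0, 0.3))
  sv2 <- fit_size_vs_duration(list(sizes = sizes2, durations = durs2))
  expect_equal(sv2$exponent, 1.3, tolerance = 0.04)
  expect_error(fit_size_vs_duration(list(sizes = c(2, 3), durations = c(1, 2))),
               "distinct durations")
})

test_that("scaling relation error reproduces hand-computed values", {
  expect_equal(scaling_relation_error(2, 2, 1), 0)
  expect_equal(scaling_relation_error(1.5, 2, 2), 0)  # critical branching
  expect_equal(scaling_relation_error(1.95, 2.15, 1.3),
               abs(1.15 / 0.95 - 1.3))
  expect_lt(scaling_relation_error(1.95, 2.15, 1.3), 0.1)
  expect_error(scaling_relation_error(1, 2, 1.3), "tau")
})

test_that("shape collapse finds the constructed exponent and orders alternatives", {
  av <- make_parabolic_avalanches(1.3, durations = c(5, 8, 12, 17, 25, 40),
                                  counts = 30)
  sc <- shape_collapse(av)
  expect_equal(sc$best, 1.3, tolerance = 0.02)
  e <- sc$errors
  expect_lt(e$error[e$exponent == 1.3], 5e-3)
  expect_gt(e$error[e$exponent == 1.0], e$error[e$exponent == 1.3])
  # mean size scales as T^1.3 on these sets
  sv <- fit_size_vs_duration(av)
  expect_equal(sv$exponent, 1.3, tolerance = 0.02)
  # mixed-exponent data: minimum between the two constituents
  mix <- combine_avalanches(
    make_parabolic_avalanches(1.2, c(5, 9, 14, 22, 35), counts = 20, seed = 5),
    make_parabolic_avalanches(1.4, c(6, 10, 16, 24, 38), counts = 20, seed = 6))
  scm <- shape_collapse(mix)
  expect_gt(scm$best, 1.2); expect_lt(scm$best, 1.4)
  one <- make_parabolic_avalanches(1.3, durations = 8, counts = 10)
  expect_error(shape_collapse(one), "distinct durations")
})

test_that("spike counts bin correctly onto the avalanche grid", {
  cnt <- bin_spike_counts(c(0.1, 0.2, 1.4, 3.9), dt = 1, t_range = c(0, 4))
  expect_equal(cnt, c(2L, 1L, 0L, 1L))
  tt <- seq(0.05, 9.95, by = 0.1)
  expect_equal(sum(bin_spike_counts(tt, 0.45, c(0, 10))), length(tt))
  expect_equal(length(bin_spike_counts(tt, 0.45, c(0, 10))), ceiling(10 / 0.45))
})
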