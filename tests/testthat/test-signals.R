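fake_trial <- function(lfp_E, lfp_I, N = 2500) {
  p <- network_params(N)
  structure(list(lfp_E = lfp_E, lfp_I = lfp_I, params = p,
                 duration = length(lfp_E)), class = "ei_trial")
}

test_that("the LFP is the population-mean membrane potential", {
  tr <- fake_trial(rep(-70, 10), rep(-50, 10))
  expect_equal(lfp(tr, "E"), rep(-70, 10))
  expect_equal(lfp(tr, "I"), rep(-50, 10))
  expect_equal(lfp(tr, "all"), rep((-70 * 2000 - 50 * 500) / 2500, 10))
  tr2 <- fake_trial(rep(-60, 5), rep(-60, 5))
  expect_equal(lfp(tr2, "all"), rep(-60, 5))
})

test_that("population autocorrelation separates flat, periodic and Poisson records", {
  expect_equal(population_autocorrelation(rep(4, 500), 10)$ac, rep(0, 11))
  # strictly periodic activity: local maxima at the period and its multiples
  n <- rep(c(5, 0, 0, 0, 0), 400)
  ac <- population_autocorrelation(n, 12)
  peaks <- ac$lag[ac$lag > 0 & ac$ac > 0.9 * max(ac$ac[ac$lag > 0])]
  expect_equal(peaks, c(5, 10))
  # white noise: lags away from 0 stay within 3/sqrt(T)
  set.seed(1)
  np <- rpois(20000, 4)
  acp <- population_autocorrelation(np, 20)
  expect_true(all(abs(acp$ac[acp$lag > 0]) < 3 / sqrt(20000)))
  # AC(0) is the relative variance
  expect_equal(acp$ac[1], var(np) * (1 - 1 / 20000) / mean(np)^2,
               tolerance = 1e-6)
  expect_error(population_autocorrelation(rep(0, 100), 5), "zero")
})

test_that("pairwise correlation behaves for identical, shifted and independent trains", {
  set.seed(2)
  base <- sort(runif(300, 0, 2000))
  two <- data.frame(neuron = rep(1:2, each = 300), time = c(base, base))
  expect_equal(pairwise_correlation(two, duration = 2000), 1, tolerance = 1e-9)
  # a 2.5 ms shift under the 5 ms boxcar: high but below 1
  sh <- data.frame(neuron = rep(1:2, each = 300),
                   time = c(base, pmin(base + 2.5, 1999.9)))
  r <- pairwise_correlation(sh, duration = 2000)
  expect_gt(r, 0.4); expect_lt(r, 0.999)
  # independent Poisson trains: mean correlation near zero
  ens <- make_poisson_ensemble(40, 0.02, 2000, 1, seed = 5)
  pc <- pairwise_correlation(ens$trials[[1]]$spikes, duration = 2000)
  expect_lt(abs(mean(pc)), 0.02)
  expect_true(all(pc >= -1 & pc <= 1))
})

test_that("ISI irregularity: zero for clocklike, unity for Poisson trains", {
  expect_equal(isi_cv(seq(0, 1000, by = 10)), 0)
  expect_true(is.na(isi_cv(c(1, 2, 3))))
  set.seed(3)
  cvs <- replicate(50, isi_cv(cumsum(rexp(200, 0.1))))
  expect_equal(mean(cvs), 1, tolerance = 0.05)
  # invariant to time rescaling
  tt <- cumsum(rexp(100, 1))
  expect_equal(isi_cv(tt), isi_cv(tt * 37.5))
})

test_that("spectral peak detection recovers a known tone, also under noise", {
  t <- (1:2048) / 1000
  x <- sin(2 * pi * 40 * t)
  expect_equal(psd(x)$peak_freq, 40, tolerance = 0.1)  # 3.9 Hz bins
  set.seed(4)
  xn <- x + rnorm(2048, 0, sqrt(0.5))   # SNR ~ 1
  expect_equal(psd(xn)$peak_freq, 40, tolerance = 0.1)
  expect_error(psd(x[1:100]), "shorter")
  # Morlet power concentrates at the tone frequency
  fr <- seq(10, 90, by = 2)
  mp <- morlet_power(x, fr)
  expect_equal(fr[which.max(rowMeans(mp[, 500:1500]))], 40)
  # trial-averaged interface
  sp <- spectra(list(x, xn), wavelet_freqs = fr)
  expect_equal(sp$peak_freq, 40, tolerance = 0.1)
  expect_equal(dim(sp$wavelet), c(length(fr), length(x)))
})

test_that("the state classifier labels constructed and simulated regimes", {
  per <- make_periodic_raster(200, 25, 2000)
  expect_equal(as.character(classify_dynamic_state(per, n_exc = 200,
                                                   duration = 2000)), "P")
  few <- data.frame(neuron = 1, time = c(10, 20))
  expect_equal(as.character(classify_dynamic_state(few, n_exc = 200,
                                                   duration = 100)),
               "indeterminate")
  # network reference points: fast inhibition -> asynchronous,
  # slow inhibition -> periodic all-spike events
  expect_equal(as.character(classify_dynamic_state(reference_trial(4))), "AS")
  expect_equal(as.character(classify_dynamic_state(reference_trial(14))), "P")
  st <- attr(classify_dynamic_state(reference_trial(14)), "stats")
  expect_gt(st$sync_fraction, 0.9)
})

test_that("synchrony rises along the inhibitory-decay ladder", {
  pcc_med <- vapply(c(4, 8, 11, 14), function(td) {
    sp <- exc_spikes(reference_trial(td))
    stats::median(pairwise_correlation(sp, duration = 1500,
                                       max_neurons = 100))
  }, numeric(1))
  expect_true(all(diff(pcc_med) > -0.02))
  expect_gt(pcc_med[4], 0.5)
  # irregular spiking in the asynchronous state: CV near 1
  cv <- isi_cv_distribution(exc_spikes(reference_trial(4)))
  expect_equal(stats::median(cv), 1, tolerance = 0.2)
})
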