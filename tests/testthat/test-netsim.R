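test_that("topology edge counts follow the Bernoulli construction", {
  p0 <- network_params(N = 50, p = 0)
  expect_length(build_topology(p0, 1)$targets, 0)

  p1 <- network_params(N = 10, p = 1)
  topo1 <- build_topology(p1, 1)
  expect_length(topo1$targets, 90)  # complete digraph minus self-loops
  src <- rep(seq_len(10), diff(topo1$offsets))
  expect_false(any(src == topo1$targets + 1))

  # excitatory in-degree ~ Binomial(N_E, p): mean 400, sd ~ 17.9 at N = 2500
  p <- network_params(N = 2500, p = 0.2)
  deg <- unlist(lapply(1:3, function(s)
    in_degrees(build_topology(p, s), source = "E")))
  expect_equal(mean(deg), 0.2 * 2000, tolerance = 0.01)
  expect_gt(stats::sd(deg), 16)
  expect_lt(stats::sd(deg), 20)

  t1 <- build_topology(p, 7)
  t2 <- build_topology(p, 7)
  expect_identical(t1$targets, t2$targets)
  expect_error(network_params(N = 2500, p = 1.5), "p must")
})

test_that("synaptic filter has unit-integral exponential response and superposes", {
  tau_d <- 4; dt <- 0.05
  expect_equal(synapse_filter_update(0, 1, tau_d, 0), 1 / tau_d)
  # iterate the decay: response is (1/tau) exp(-t/tau), integral 1
  g <- 1 / tau_d
  tt <- seq(0, 80, by = dt)
  gs <- numeric(length(tt)); gs[1] <- g
  for (i in 2:length(tt)) gs[i] <- synapse_filter_update(gs[i - 1], 0, tau_d, dt)
  expect_equal(gs, exp(-tt / tau_d) / tau_d, tolerance = 1e-12)
  expect_equal(sum(gs) * dt, 1, tolerance = 2e-2)
  # linearity: two simultaneous spikes double the response everywhere
  g2 <- numeric(length(tt)); g2[1] <- synapse_filter_update(0, 2, tau_d, 0)
  for (i in 2:length(tt)) g2[i] <- synapse_filter_update(g2[i - 1], 0, tau_d, dt)
  expect_equal(g2, 2 * gs, tolerance = 1e-12)
  # decay constant recovered on a log scale to < 1%
  fit <- stats::lm(log(gs) ~ tt)
  expect_equal(-1 / unname(stats::coef(fit)[2]), tau_d, tolerance = 0.01)
  expect_error(synapse_filter_update(0, 1, -1, dt), "tau_d")
})

test_that("isolated neurons settle at the closed-form subthreshold voltage", {
  # no recurrence, constant deterministic drive r: V* = (Vrest/tau)/(1/tau + g_EO r)
  p <- network_params(N = 100, p = 0, tau_dI = 9)
  topo <- build_topology(p, 1)
  r <- 0.05
  tr <- run_trial(p, topo, input_protocol(r, t_onset = 1e9),
                  rep(-70, p$N), seed = 1, duration = 500)
  v_star <- (p$V_restE / p$tau_E) / (1 / p$tau_E + p$g_EO * r)
  expect_lt(abs(tail(tr$lfp_E, 1) - v_star), 0.01)
  # zero drive from rest: leak fixed point, voltage never moves
  tr0 <- run_trial(p, topo, input_protocol(0, t_onset = 1e9),
                   rep(-70, p$N), seed = 1, duration = 100)
  expect_equal(unique(tr0$lfp_E), -70)
  expect_equal(nrow(tr0$spikes), 0L)
})

test_that("threshold crossing resets to V_reset and enforces the refractory period", {
  # strong drive on uncoupled excitatory neurons: periodic firing
  p <- network_params(N = 5, p = 0, tau_dI = 9)
  topo <- build_topology(p, 1)
  tr <- run_trial(p, topo, input_protocol(0.8, t_onset = 1e9),
                  rep(-70, p$N), seed = 1, duration = 200, record = "full")
  st <- tr$spikes$time[tr$spikes$neuron == 1]
  expect_gt(length(st), 5)
  expect_true(all(diff(st) >= p$refrac_E - 1e-9))
  # voltage clamped at V_reset within the refractory window after each spike
  probe <- ceiling(st[1])  # first trace sample at/after the spike
  expect_equal(tr$v[probe, 1], p$V_reset)
})

test_that("trials are bitwise reproducible given seeds, for both drive modes", {
  p <- network_params(N = 500, tau_dI = 9)
  topo <- build_topology(p, 3)
  v0 <- sample_initial_conditions(p$N, 4)
  for (mode in c("deterministic", "poisson")) {
    pr <- input_protocol(0.6, mode = mode, t_onset = 1e9)
    a <- run_trial(p, topo, pr, v0, 9, 300)
    b <- run_trial(p, topo, pr, v0, 9, 300)
    expect_identical(a$spikes, b$spikes)
    expect_identical(a$lfp_E, b$lfp_E)
  }
  expect_error(run_trial(p, topo, input_protocol(0.6, t_onset = 1e9),
                         v0, 9, 300.013), "multiple of dt")
})

test_that("refractory contract holds on a full network record", {
  tr <- reference_trial(4)
  p <- tr$params
  by_n <- spike_times_by_neuron(tr)
  refrac <- ifelse(as.integer(names(by_n)) <= p$N_E, p$refrac_E, p$refrac_I)
  min_isi <- vapply(by_n, function(s) if (length(s) > 1) min(diff(s)) else Inf,
                    numeric(1))
  expect_true(all(min_isi >= refrac - 1e-9))
})

test_that("excitatory and inhibitory currents balance in the asynchronous state", {
  tr <- reference_trial(4)
  cur <- tr$currents
  expect_gt(cur[["E_exc"]], 0)
  expect_lt(cur[["E_inh"]], 0)
  net <- cur[["E_exc"]] + cur[["E_inh"]]
  expect_lt(abs(net), 0.3 * min(cur[["E_exc"]], -cur[["E_inh"]]))
})

test_that("halving the integration step barely changes the population rate", {
  rates <- vapply(c(0.05, 0.025), function(dt) {
    p <- network_params(2500, tau_dI = 4, dt = dt)
    topo <- build_topology(p, seed = 2)
    tr <- run_trial(p, topo, input_protocol(0.8, t_onset = 1e9),
                    sample_initial_conditions(p$N, 4), 6, duration = 2500)
    sum(tr$spikes$time > 500) / 2 / p$N
  }, numeric(1))
  expect_lt(abs(rates[2] - rates[1]) / rates[1], 0.05)
})
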