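fp9 <- field_params(network_params(2500, tau_dI = 9))
fp4 <- field_params(network_params(2500, tau_dI = 4))

test_that("rate sigmoid, its derivative and its inverse are mutually consistent", {
  expect_equal(rate_sigmoid(-50, 3.2), 0.5)
  expect_equal(rate_sigmoid(-1e6, 3.2), 0)
  expect_equal(rate_sigmoid(-55, 3.2),
               1 / (1 + exp(5 * pi / (3.2 * sqrt(3)))))
  expect_equal(rate_sigmoid(-55, 3.2), 0.0556, tolerance = 0.01)
  # derivative against central differences
  num <- (rate_sigmoid(-55 + 1e-6, 3.2) - rate_sigmoid(-55 - 1e-6, 3.2)) / 2e-6
  expect_equal(rate_sigmoid_deriv(-55, 3.2), num, tolerance = 1e-6)
  # inversion identity
  for (v in c(-66, -58, -52)) {
    q <- rate_sigmoid(v, 3.8)
    expect_equal(rate_sigmoid(v, sigma_from_simulation(v, q)), q,
                 tolerance = 1e-12)
  }
  expect_equal(sigma_from_simulation(-55, 0.0556), 3.2, tolerance = 0.01)
  expect_error(sigma_from_simulation(-55, 0.5), "0.5")
  expect_error(sigma_from_simulation(-45, 0.1), "inconsistent")
})

test_that("equilibria satisfy the fixed-point equations and ignore synaptic decay times", {
  # leak-only network: voltages at rest
  p0 <- network_params(2500, tau_dI = 9)
  for (xy in c("EO", "IO", "EE", "IE", "EI", "II"))
    p0[[paste0("g_", xy)]] <- 0
  fp0 <- field_params(p0)
  eq0 <- equilibrium_solve(fp0, 0)
  expect_equal(eq0$V_E, -70, tolerance = 1e-9)
  expect_equal(eq0$V_I, -70, tolerance = 1e-9)
  expect_equal(eq0$Q_E, rate_sigmoid(-70, fp0$sigma_E), tolerance = 1e-12)

  eq <- equilibrium_solve(fp9, 0.55)
  expect_lt(eq$residual, 1e-10)
  # time-derivatives of the full 4-D field equations vanish
  dr <- eicrit:::field_drift(c(eq$V_E, eq$V_I, eq$Phi_E, eq$Phi_I), fp9, 0.55)
  expect_lt(max(abs(dr)), 1e-10)
  # equilibrium is independent of tau_dI across the full range
  eq4 <- equilibrium_solve(field_params(network_params(2500, tau_dI = 4)),
                           0.55)
  eq14 <- equilibrium_solve(field_params(network_params(2500, tau_dI = 14)),
                            0.55)
  expect_equal(eq4$V_E, eq14$V_E, tolerance = 1e-9)
  expect_equal(eq4$Phi_I, eq14$Phi_I, tolerance = 1e-9)
})

test_that("the analytic Jacobian matches finite differences of the drift", {
  for (r_in in c(0.3, 0.55, 0.9)) {
    eq <- equilibrium_solve(fp9, r_in)
    J <- field_jacobian(eq, fp9, r_in)
    x0 <- c(eq$V_E, eq$V_I, eq$Phi_E, eq$Phi_I)
    Jnum <- matrix(0, 4, 4)
    for (j in 1:4) {
      h <- 1e-6 * max(1, abs(x0[j]))
      e <- numeric(4); e[j] <- h
      Jnum[, j] <- (eicrit:::field_drift(x0 + e, fp9, r_in) -
                      eicrit:::field_drift(x0 - e, fp9, r_in)) / (2 * h)
    }
    expect_equal(J, Jnum, tolerance = 1e-6)
  }
  # uncoupled structure: diagonal relaxation rates
  p0 <- network_params(2500, tau_dI = 9)
  for (xy in c("EO", "IO", "EE", "IE", "EI", "II"))
    p0[[paste0("g_", xy)]] <- 0
  fp0 <- field_params(p0)
  eq0 <- equilibrium_solve(fp0, 0)
  J0 <- field_jacobian(eq0, fp0, 0)
  expect_equal(diag(J0), -1 / c(fp0$tau_E, fp0$tau_I, fp0$tau_dE, fp0$tau_dI))
  expect_equal(J0[1, 3], (fp0$V_revE - eq0$V_E) * 0)
  expect_gt(J0[3, 1], 0)  # rate coupling survives in rows 3-4
})

test_that("the Lyapunov solve is exact in 1-D and residual-free in 4-D", {
  a <- 0.7; b <- 0.3
  expect_equal(lna_covariance(matrix(-a), B = matrix(b))[1, 1], b / (2 * a))
  eq <- equilibrium_solve(fp4, 0.55)
  J <- field_jacobian(eq, fp4, 0.55)
  S <- lna_covariance(J, 0.2)
  B <- diag(c(0.2, 0.2, 0, 0))
  expect_lt(max(abs(J %*% S + S %*% t(J) + B)), 1e-10)
  expect_equal(S, t(S), tolerance = 1e-12)
  expect_true(all(eigen(S, only.values = TRUE)$values > -1e-12))
  # non-Hurwitz rejection
  expect_error(lna_covariance(matrix(c(0.1, 0, 0, -1), 2, 2), 0.2),
               "Hurwitz")
})

test_that("LNA variance matches a long stochastic simulation of the linearized system", {
  eq <- equilibrium_solve(fp4, 0.55)
  J <- field_jacobian(eq, fp4, 0.55)
  beta <- 0.2
  S <- lna_covariance(J, beta)
  # Euler-Maruyama on dX = J X dt + sqrt(B) dW across parallel replicas
  set.seed(8)
  M <- 300; dt <- 0.05; n_steps <- 50000; burn <- 5000
  X <- matrix(0, 4, M)
  sq <- sqrt(beta * dt)
  acc2 <- 0; n_acc <- 0
  for (s in seq_len(n_steps)) {
    X <- X + dt * (J %*% X)
    X[1, ] <- X[1, ] + sq * rnorm(M)
    X[2, ] <- X[2, ] + sq * rnorm(M)
    if (s > burn && s %% 20 == 0) {
      acc2 <- acc2 + sum(X[1, ]^2); n_acc <- n_acc + M
    }
  }
  expect_equal(acc2 / n_acc, S[1, 1], tolerance = 0.05)
})

test_that("stability scan shows the Hopf transition structure over (tau_dI, r_in)", {
  scan <- hopf_scan(fp9, tau_dI_grid = seq(3, 14, by = 1),
                    r_in_grid = c(0.4, 0.55, 0.9))
  expect_true(all(scan$converged))
  for (r in unique(scan$r_in)) {
    s <- scan[scan$r_in == r, ]
    expect_true(all(diff(s$lambda_re) > 0))     # destabilizes with slower inhibition
    expect_gt(max(s$lambda_re), 0)              # sign change in the scanned range
    expect_lt(min(s$lambda_re), 0)
  }
  # Hopf frequency in the gamma band near the effective critical line
  near <- scan[scan$near_critical & scan$hurwitz, ]
  expect_true(all(near$hopf_freq_hz > 25 & near$hopf_freq_hz < 80))
  # frequency rises with input strength at fixed near-critical tau_dI
  s9 <- scan[scan$tau_dI == 9, ]
  s9 <- s9[order(s9$r_in), ]
  expect_true(all(diff(s9$hopf_freq_hz) > 0))
})

test_that("LNA fluctuations are larger and more suppressible at the critical state", {
  var_at <- function(fp, r) {
    eq <- equilibrium_solve(fp, r)
    lna_covariance(field_jacobian(eq, fp, r), fp$beta)[1, 1]
  }
  expect_gt(var_at(fp9, 0.55), var_at(fp4, 0.55))
  # variance decreases with input before the bifurcation at the critical point
  vs <- vapply(seq(0.4, 0.9, by = 0.1), function(r) var_at(fp9, r),
               numeric(1))
  expect_true(all(diff(vs) < 0))
  # stimulus-induced suppression, relative to the spontaneous drive 0.55/ms
  expect_equal(delta_var(fp9, 0.55), 0, tolerance = 1e-12)
  expect_lt(delta_var(fp9, 0.75), delta_var(fp4, 0.75))
  expect_lt(delta_var(fp9, 0.75), 0)
  expect_equal(delta_var(fp9, 0.75),
               var_at(fp9, 0.75) - var_at(fp9, 0.55), tolerance = 1e-12)
  # orderings do not depend on the imposed noise strength
  for (beta in c(0.1, 0.4)) {
    f9b <- field_params(network_params(2500, tau_dI = 9), beta = beta)
    f4b <- field_params(network_params(2500, tau_dI = 4), beta = beta)
    expect_gt(var_at(f9b, 0.55), var_at(f4b, 0.55))
    expect_lt(delta_var(f9b, 0.75), delta_var(f4b, 0.75))
  }
})
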