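#' Mean-field parameters
#'
#' Extends the network constants with the effective sigmoid widths of the
#' population rate function (`sigma_E`, `sigma_I`, in mV; they stand for the
#' standard deviation of the membrane-potential distribution within each
#' population and cannot be derived analytically), the phenomenological noise
#' strength `beta` of the noisy field equations, and the mean in-neighbour
#' counts `n_E = p N_E`, `n_I = p N_I`.
#'
#' @param params an [network_params()] object.
#' @param sigma_E,sigma_I effective sigmoid widths (mV).
#' @param beta noise strength of the Gaussian white noise added to the
#'   voltage equations.
#' @return An object of class `ei_field_params`.
#' @export
field_params <- function(params = network_params(), sigma_E = 3.2,
                         sigma_I = 3.8, beta = 0.2) {
  stopifnot(inherits(params, "ei_network_params"),
            sigma_E > 0, sigma_I > 0, beta >= 0)
  obj <- unclass(params)
  obj$sigma_E <- sigma_E
  obj$sigma_I <- sigma_I
  obj$beta <- beta
  obj$n_E <- params$p * params$N_E
  obj$n_I <- params$p * params$N_I
  structure(obj, class = "ei_field_params")
}

#' Population firing-rate sigmoid
#'
#' The fraction of neurons above threshold, under a Gaussian
#' membrane-potential distribution with mean `V` and width `sigma`:
#' `Q(V) = 1 / (1 + exp((V_th - V) pi / (sigma sqrt(3))))`, in spikes per
#' neuron per ms.
#'
#' @param V mean membrane potential (mV), vectorized.
#' @param sigma sigmoid width (mV).
#' @param V_th spike threshold (mV).
#' @return Rate in (0, 1).
#' @export
rate_sigmoid <- function(V, sigma, V_th = -50) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  1 / (1 + exp((V_th - V) * pi / (sigma * sqrt(3))))
}

#' Derivative of the firing-rate sigmoid with respect to V
#' @inheritParams rate_sigmoid
#' @return `dQ/dV` (1/(ms mV)).
#' @export
rate_sigmoid_deriv <- function(V, sigma, V_th = -50) {
  z <- exp((V_th - V) * pi / (sigma * sqrt(3)))
  pi * z / (sqrt(3) * sigma * (1 + z)^2)
}

#' Effective sigmoid width from a simulated steady state
#'
#' Inverts the rate sigmoid: given the steady-state mean voltage `V_ss` and
#' firing rate `Q_ss` of a population (measured from an asynchronous-state
#' network simulation), returns the `sigma` for which
#' `rate_sigmoid(V_ss, sigma) = Q_ss` exactly:
#' `sigma = (V_th - V_ss) pi / (sqrt(3) log(1/Q_ss - 1))`.
#'
#' @param V_ss steady-state mean voltage (mV).
#' @param Q_ss steady-state firing rate per ms, in (0, 1), not equal to 0.5.
#' @param V_th spike threshold (mV).
#' @return Effective width `sigma` (mV).
#' @export
sigma_from_simulation <- function(V_ss, Q_ss, V_th = -50) {
  if (any(Q_ss <= 0) || any(Q_ss >= 1)) stop("Q_ss must lie in (0, 1)")
  if (any(abs(Q_ss - 0.5) < 1e-12))
    stop("Q_ss = 0.5 leaves sigma undefined (log of 1)")
  sigma <- (V_th - V_ss) * pi / (sqrt(3) * log(1 / Q_ss - 1))
  if (any(sigma <= 0))
    stop("inconsistent signs: V_ss and Q_ss must lie on the same side of threshold")
  sigma
}

# drift of the deterministic field equations at state x = (V_E, V_I, Phi_E, Phi_I)
field_drift <- function(x, fp, r_in) {
  V_E <- x[1]; V_I <- x[2]; Phi_E <- x[3]; Phi_I <- x[4]
  Q_E <- rate_sigmoid(V_E, fp$sigma_E, fp$V_th)
  Q_I <- rate_sigmoid(V_I, fp$sigma_I, fp$V_th)
  c((fp$V_restE - V_E) / fp$tau_E +
      (fp$g_EO * r_in + fp$g_EE * Phi_E) * (fp$V_revE - V_E) +
      fp$g_EI * Phi_I * (fp$V_revI - V_E),
    (fp$V_restI - V_I) / fp$tau_I +
      (fp$g_IO * r_in + fp$g_IE * Phi_E) * (fp$V_revE - V_I) +
      fp$g_II * Phi_I * (fp$V_revI - V_I),
    (-Phi_E + fp$n_E * Q_E) / fp$tau_dE,
    (-Phi_I + fp$n_I * Q_I) / fp$tau_dI)
}

# the reduced 2-D equilibrium system in (V_E, V_I), with Phi_a = n_a Q_a(V_a)
equilibrium_residual <- function(v, fp, r_in) {
  Phi_E <- fp$n_E * rate_sigmoid(v[1], fp$sigma_E, fp$V_th)
  Phi_I <- fp$n_I * rate_sigmoid(v[2], fp$sigma_I, fp$V_th)
  c((fp$V_restE - v[1]) / fp$tau_E +
      (fp$g_EO * r_in + fp$g_EE * Phi_E) * (fp$V_revE - v[1]) +
      fp$g_EI * Phi_I * (fp$V_revI - v[1]),
    (fp$V_restI - v[2]) / fp$tau_I +
      (fp$g_IO * r_in + fp$g_IE * Phi_E) * (fp$V_revE - v[2]) +
      fp$g_II * Phi_I * (fp$V_revI - v[2]))
}

#' Equilibrium of the mean-field equations
#'
#' Solves the algebraic fixed-point equations of the deterministic field
#' equations for a constant input rate `r_in` by damped Newton iteration on
#' the reduced system in `(V_E, V_I)` (the conductance states follow as
#' `Phi_a = n_a Q_a(V_a)`), with multistart from a grid of subthreshold
#' voltage pairs.  Because the synaptic filter is normalized, the equilibrium
#' is independent of the synaptic decay times; only its stability depends on
#' them.  All converged roots are reported; the one with the lowest `V_E` is
#' primary.
#'
#' @param fp an [field_params()] object.
#' @param r_in constant input rate (1/ms), >= 0.
#' @param tol residual tolerance.
#' @param starts matrix of starting `(V_E, V_I)` pairs; default grid over
#'   \{-70, -65, -60, -55\} mV.
#' @return An object of class `ei_field_state`: `V_E`, `V_I`, `Phi_E`,
#'   `Phi_I`, `Q_E`, `Q_I`, `r_in`, `residual`, plus `all_roots` (matrix of
#'   distinct converged roots).
#' @export
equilibrium_solve <- function(fp, r_in, tol = 1e-12, starts = NULL) {
  stopifnot(inherits(fp, "ei_field_params"), r_in >= 0)
  if (is.null(starts))
    starts <- as.matrix(expand.grid(V_E = c(-70, -65, -60, -55),
                                    V_I = c(-70, -65, -60, -55)))
  jac2 <- function(v) {
    eps <- 1e-6
    cbind((equilibrium_residual(v + c(eps, 0), fp, r_in) -
             equilibrium_residual(v - c(eps, 0), fp, r_in)) / (2 * eps),
          (equilibrium_residual(v + c(0, eps), fp, r_in) -
             equilibrium_residual(v - c(0, eps), fp, r_in)) / (2 * eps))
  }
  roots <- NULL
  for (k in seq_len(nrow(starts))) {
    v <- as.numeric(starts[k, ])
    ok <- FALSE
    for (it in 1:200) {
      f <- equilibrium_residual(v, fp, r_in)
      if (max(abs(f)) < tol) { ok <- TRUE; break }
      step <- tryCatch(solve(jac2(v), -f), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        v_new <- v + lam * step
        f_new <- equilibrium_residual(v_new, fp, r_in)
        if (all(is.finite(f_new)) &&
            (sum(f_new^2) < sum(f^2) || lam < 1e-6)) break
        lam <- lam / 2
      }
      v <- v_new
    }
    if (ok) roots <- rbind(roots, v)
  }
  if (is.null(roots))
    stop("equilibrium solver failed to converge from all starts; ",
         "last residual ", format(max(abs(equilibrium_residual(
           as.numeric(starts[nrow(starts), ]), fp, r_in)))))
  roots <- roots[!duplicated(round(roots, 6)), , drop = FALSE]
  roots <- roots[order(roots[, 1]), , drop = FALSE]
  v <- roots[1, ]
  Q_E <- rate_sigmoid(v[1], fp$sigma_E, fp$V_th)
  Q_I <- rate_sigmoid(v[2], fp$sigma_I, fp$V_th)
  structure(list(V_E = v[1], V_I = v[2],
                 Phi_E = fp$n_E * Q_E, Phi_I = fp$n_I * Q_I,
                 Q_E = Q_E, Q_I = Q_I, r_in = r_in,
                 residual = max(abs(equilibrium_residual(v, fp, r_in))),
                 all_roots = roots),
            class = "ei_field_state")
}

#' @export
print.ei_field_state <- function(x, ...) {
  cat(sprintf("Field equilibrium at r_in = %g/ms: V_E = %.3f, V_I = %.3f mV; Q_E = %.4g, Q_I = %.4g /ms\n",
              x$r_in, x$V_E, x$V_I, x$Q_E, x$Q_I))
  invisible(x)
}

#' Jacobian of the field equations at an equilibrium
#'
#' The 4x4 Jacobian of the deterministic field equations in the state
#' `(V_E, V_I, Phi_E, Phi_I)`, evaluated at an equilibrium.
#'
#' @param state an [equilibrium_solve()] result (or a list with `V_E`,
#'   `V_I`, `Phi_E`, `Phi_I`).
#' @param fp an [field_params()] object.
#' @param r_in input rate (1/ms).
#' @return 4x4 numeric matrix (units 1/ms on the diagonal blocks).
#' @export
field_jacobian <- function(state, fp, r_in) {
  V_E <- state$V_E; V_I <- state$V_I
  Phi_E <- state$Phi_E; Phi_I <- state$Phi_I
  dQ_E <- rate_sigmoid_deriv(V_E, fp$sigma_E, fp$V_th)
  dQ_I <- rate_sigmoid_deriv(V_I, fp$sigma_I, fp$V_th)
  matrix(c(
    -1 / fp$tau_E - (fp$g_EO * r_in + fp$g_EE * Phi_E + fp$g_EI * Phi_I), 0,
    (fp$V_revE - V_E) * fp$g_EE, (fp$V_revI - V_E) * fp$g_EI,
    0, -1 / fp$tau_I - (fp$g_IO * r_in + fp$g_IE * Phi_E + fp$g_II * Phi_I),
    (fp$V_revE - V_I) * fp$g_IE, (fp$V_revI - V_I) * fp$g_II,
    fp$n_E * dQ_E / fp$tau_dE, 0, -1 / fp$tau_dE, 0,
    0, fp$n_I * dQ_I / fp$tau_dI, 0, -1 / fp$tau_dI),
    nrow = 4, byrow = TRUE)
}

#' Stability of a field equilibrium
#'
#' Eigenvalues of the Jacobian, the leading real part, and the Hopf frequency
#' from the dominant complex pair.  A real part above `-0.05`/ms marks the
#' effectively critical region in which noise sustains oscillatory critical
#' dynamics even before the deterministic Hopf bifurcation.
#'
#' @param J Jacobian from [field_jacobian()].
#' @param critical_threshold real-part threshold (1/ms) for the
#'   near-critical flag.
#' @return An object of class `ei_stability`: `eigenvalues`,
#'   `lambda_re` (leading real part, 1/ms), `hopf_freq_hz` (frequency
#'   `|Im|/2pi` of the leading complex pair, converted to Hz; `NA` if the
#'   leading eigenvalue is real), `hurwitz`, `near_critical`.
#' @export
stability_from_jacobian <- function(J, critical_threshold = -0.05) {
  ev <- eigen(J, only.values = TRUE)$values
  lead <- ev[which.max(Re(ev))]
  freq <- if (abs(Im(lead)) > 1e-12) abs(Im(lead)) / (2 * pi) * 1000
          else NA_real_
  structure(list(eigenvalues = ev, lambda_re = max(Re(ev)),
                 hopf_freq_hz = freq,
                 hurwitz = all(Re(ev) < 0),
                 near_critical = max(Re(ev)) > critical_threshold),
            class = "ei_stability")
}

#' Scan equilibrium stability over the (tau_dI, r_in) plane
#'
#' For each grid point: solve the equilibrium (independent of `tau_dI`),
#' evaluate the Jacobian and its leading eigenvalue pair.  Grid points where
#' the equilibrium solver fails are flagged and skipped.  The deterministic
#' Hopf line is the zero crossing of the leading real part; the effective
#' critical line is its crossing of `critical_threshold`.
#'
#' @param fp an [field_params()] object; its `tau_dI` is overridden by the
#'   grid.
#' @param tau_dI_grid inhibitory decay times (ms).
#' @param r_in_grid input rates (1/ms).
#' @param critical_threshold see [stability_from_jacobian()].
#' @return Data frame with one row per grid point: `tau_dI`, `r_in`,
#'   `lambda_re` (1/ms), `hopf_freq_hz`, `V_E`, `var_VE` (LNA variance where
#'   the equilibrium is stable, else `NA`), `hurwitz`, `near_critical`,
#'   `converged`.
#' @export
hopf_scan <- function(fp, tau_dI_grid = seq(3, 14, by = 0.5),
                      r_in_grid = seq(0.2, 1, by = 0.05),
                      critical_threshold = -0.05) {
  stopifnot(all(tau_dI_grid > 0), all(r_in_grid >= 0))
  rows <- list()
  for (r in r_in_grid) {
    eq <- tryCatch(equilibrium_solve(fp, r), error = function(e) NULL)
    for (td in tau_dI_grid) {
      fpt <- fp
      fpt$tau_dI <- td
      if (is.null(eq)) {
        rows[[length(rows) + 1]] <-
          data.frame(tau_dI = td, r_in = r, lambda_re = NA, hopf_freq_hz = NA,
                     V_E = NA, var_VE = NA, hurwitz = NA, near_critical = NA,
                     converged = FALSE)
        next
      }
      J <- field_jacobian(eq, fpt, r)
      st <- stability_from_jacobian(J, critical_threshold)
      vv <- if (st$hurwitz) lna_covariance(J, fp$beta)[1, 1] else NA_real_
      rows[[length(rows) + 1]] <-
        data.frame(tau_dI = td, r_in = r, lambda_re = st$lambda_re,
                   hopf_freq_hz = st$hopf_freq_hz, V_E = eq$V_E, var_VE = vv,
                   hurwitz = st$hurwitz, near_critical = st$near_critical,
                   converged = TRUE)
    }
  }
  do.call(rbind, rows)
}

#' Stationary covariance from the linear noise approximation
#'
#' Solves the Lyapunov equation `J S + S J' + B = 0` with noise matrix
#' `B = diag(beta, beta, 0, 0)` (noise enters the two voltage equations
#' only), via the Kronecker-product linear system.  Requires a Hurwitz
#' Jacobian.  The `[1, 1]` element is `Var(V_E)`, the LNA prediction of the
#' LFP fluctuation strength.
#'
#' @param J 4x4 (or n x n) Jacobian with all eigenvalue real parts negative.
#' @param beta noise strength; `B = diag(beta, beta, 0, ..., 0)`.
#' @param B optional explicit noise matrix overriding `beta`.
#' @return Symmetric positive semidefinite covariance matrix.
#' @export
lna_covariance <- function(J, beta = 0.2, B = NULL) {
  J <- as.matrix(J)
  n <- nrow(J)
  ev <- eigen(J, only.values = TRUE)$values
  if (any(Re(ev) >= 0)) {
    bad <- ev[which.max(Re(ev))]
    stop("Jacobian is not Hurwitz: eigenvalue ", format(bad),
         " has nonnegative real part")
  }
  if (is.null(B)) {
    B <- matrix(0, n, n)
    B[1, 1] <- beta
    if (n >= 2) B[2, 2] <- beta
  }
  A <- kronecker(diag(n), J) + kronecker(J, diag(n))
  S <- matrix(solve(A, -as.vector(B)), n, n)
  (S + t(S)) / 2
}

#' Stimulus-induced change of the LNA voltage variance
#'
#' `Var(V_E)` at input `r_in` minus its value at the reference input
#' (default 0.55/ms, the spontaneous level of the trial-to-trial-variability
#' protocol).  Negative values mean the stimulus suppresses the LFP
#' fluctuation.
#'
#' @param fp an [field_params()] object (its `tau_dI` is used).
#' @param r_in input rate (1/ms).
#' @param reference reference input rate (1/ms).
#' @return `Var(V_E)(r_in) - Var(V_E)(reference)`.
#' @export
delta_var <- function(fp, r_in, reference = 0.55) {
  var_at <- function(r) {
    eq <- equilibrium_solve(fp, r)
    lna_covariance(field_jacobian(eq, fp, r), fp$beta)[1, 1]
  }
  var_at(r_in) - var_at(reference)
}
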