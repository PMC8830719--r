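#' Network parameters for the conductance-based E-I spiking network
#'
#' Collects all model constants of the excitation-inhibition integrate-and-fire
#' network: population sizes (4:1 excitatory-to-inhibitory ratio), connection
#' probability, dimensionless synaptic strength prefactors, membrane and
#' synaptic time constants, reversal/rest/threshold/reset potentials,
#' refractory periods and the integration step.  Effective synaptic strengths
#' follow the dense balanced-network scaling `g_xy = ghat_xy / sqrt(N)`: with
#' the external rate growing linearly in `N`, external and recurrent currents
#' are then of the same (large) scale and cancel dynamically, which is what
#' produces irregular fluctuation-driven spiking at every network size.
#'
#' @param N total neuron count; must be divisible by 5 so that `N_E = 4 N_I`.
#' @param p connection probability of each directed edge.
#' @param tau_dI inhibitory synaptic decay time (ms).  The biologically
#'   plausible range is 3-14 ms; it is the control parameter that moves the
#'   network between asynchronous, critical, sparsely synchronous and periodic
#'   dynamics.
#' @param tau_dE excitatory synaptic decay time (ms).
#' @param ghat_EO,ghat_IO,ghat_EE,ghat_IE,ghat_EI,ghat_II dimensionless
#'   synaptic strength prefactors (target class first, source second; `O` is
#'   the external drive).
#' @param tau_E,tau_I membrane time constants (ms).
#' @param V_revE,V_revI synaptic reversal potentials (mV).
#' @param V_restE,V_restI resting (leak) potentials (mV).
#' @param V_th,V_reset spike threshold and reset potentials (mV).
#' @param refrac_E,refrac_I refractory periods (ms).
#' @param dt integration step (ms).
#' @return An object of class `ei_network_params`: a named list of the above
#'   plus derived fields `N_E`, `N_I` and the effective strengths
#'   `g_EO, ..., g_II`.
#' @examples
#' p <- network_params(N = 500, tau_dI = 9)
#' p$N_E / p$N_I    # 4
#' p$g_EE * sqrt(p$N)   # ghat_EE
#' @export
network_params <- function(N = 2500, p = 0.2, tau_dI = 10, tau_dE = 4,
                           ghat_EO = 2.5, ghat_IO = 4, ghat_EE = 2,
                           ghat_IE = 4, ghat_EI = 27, ghat_II = 48,
                           tau_E = 20, tau_I = 10,
                           V_revE = 0, V_revI = -70,
                           V_restE = -70, V_restI = -70,
                           V_th = -50, V_reset = -60,
                           refrac_E = 2, refrac_I = 1, dt = 0.05) {
  if (!is.numeric(N) || length(N) != 1 || N < 5 || N %% 5 != 0)
    stop("N must be a positive multiple of 5 (N_E:N_I = 4:1)")
  if (!is.numeric(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  stopifnot(tau_dI > 0, tau_dE > 0, tau_E > 0, tau_I > 0, dt > 0,
            refrac_E >= 0, refrac_I >= 0)
  if (V_reset >= V_th) stop("V_reset must be below V_th")
  obj <- list(N = as.integer(N), N_E = as.integer(N * 4 / 5),
              N_I = as.integer(N / 5), p = p,
              ghat_EO = ghat_EO, ghat_IO = ghat_IO, ghat_EE = ghat_EE,
              ghat_IE = ghat_IE, ghat_EI = ghat_EI, ghat_II = ghat_II,
              tau_E = tau_E, tau_I = tau_I, tau_dE = tau_dE, tau_dI = tau_dI,
              V_revE = V_revE, V_revI = V_revI,
              V_restE = V_restE, V_restI = V_restI,
              V_th = V_th, V_reset = V_reset,
              refrac_E = refrac_E, refrac_I = refrac_I, dt = dt)
  for (xy in c("EO", "IO", "EE", "IE", "EI", "II"))
    obj[[paste0("g_", xy)]] <- obj[[paste0("ghat_", xy)]] / sqrt(obj$N)
  structure(obj, class = "ei_network_params")
}

#' @export
print.ei_network_params <- function(x, ...) {
  cat(sprintf("E-I network parameters: N = %d (N_E = %d, N_I = %d), p = %g\n",
              x$N, x$N_E, x$N_I, x$p))
  cat(sprintf("  tau_E/I = %g/%g ms, tau_dE/dI = %g/%g ms, dt = %g ms\n",
              x$tau_E, x$tau_I, x$tau_dE, x$tau_dI, x$dt))
  cat(sprintf("  V_th = %g, V_reset = %g, V_rest = %g/%g, V_rev = %g/%g mV\n",
              x$V_th, x$V_reset, x$V_restE, x$V_restI, x$V_revE, x$V_revI))
  cat(sprintf("  ghat: EO %g, IO %g, EE %g, IE %g, EI %g, II %g (g = ghat/sqrt(N))\n",
              x$ghat_EO, x$ghat_IO, x$ghat_EE, x$ghat_IE, x$ghat_EI, x$ghat_II))
  invisible(x)
}

#' Build the random directed E-I network topology
#'
#' Every directed edge (excluding self-connections) is present independently
#' with probability `p`.  Neurons `1..N_E` are excitatory, `N_E+1..N` are
#' inhibitory.  The adjacency is stored in compressed sparse row form
#' (per-source target lists).
#'
#' @param params an [network_params()] object.
#' @param seed integer seed; the topology is reproducible given the seed.
#' @return An object of class `ei_topology` with elements `offsets` (0-based,
#'   length `N+1`), `targets` (0-based target ids), `N`, `N_E` and `seed`.
#' @examples
#' topo <- build_topology(network_params(N = 50, p = 0.2), seed = 1)
#' mean(diff(topo$offsets))  # ~ p * (N - 1)
#' @export
build_topology <- function(params, seed) {
  stopifnot(inherits(params, "ei_network_params"))
  seed <- as.integer(seed)
  out <- build_topology_cpp(params$N, params$p, seed)
  structure(list(offsets = out$offsets, targets = out$targets,
                 N = params$N, N_E = params$N_E, seed = seed),
            class = "ei_topology")
}

#' @export
print.ei_topology <- function(x, ...) {
  cat(sprintf("E-I topology: N = %d, %d directed edges (seed %d)\n",
              x$N, length(x$targets), x$seed))
  invisible(x)
}

#' Out-degrees of a topology
#' @param topology an `ei_topology`.
#' @return Integer vector of out-degrees, one per neuron.
#' @export
out_degrees <- function(topology) diff(topology$offsets)

#' In-degrees of a topology, optionally restricted to a source class
#' @param topology an `ei_topology`.
#' @param source `"all"`, `"E"` or `"I"`: which presynaptic class to count.
#' @return Integer vector of in-degrees, one per neuron.
#' @export
in_degrees <- function(topology, source = c("all", "E", "I")) {
  source <- match.arg(source)
  src <- rep.int(seq_len(topology$N), diff(topology$offsets))
  keep <- switch(source, all = TRUE, E = src <= topology$N_E,
                 I = src > topology$N_E)
  tabulate(topology$targets[keep] + 1L, nbins = topology$N)
}

#' One step of the exponential synaptic filter
#'
#' The synaptic filter has impulse response `(1/tau_d) exp(-t/tau_d)` and unit
#' time-integral; responses of multiple spikes superpose linearly.  One update
#' advances the filtered state by `dt` (exact exponential decay) and adds the
#' instantaneous contribution of `n_spikes` presynaptic spikes.
#'
#' @param G current filtered conductance state (1/ms).
#' @param n_spikes number of presynaptic spikes arriving in this step.
#' @param tau_d synaptic decay time (ms).
#' @param dt time step (ms).
#' @return Updated conductance state.
#' @examples
#' synapse_filter_update(0, 1, tau_d = 4, dt = 0) # 1/4, the filter height
#' @export
synapse_filter_update <- function(G, n_spikes, tau_d, dt) {
  if (!is.numeric(tau_d) || tau_d <= 0) stop("tau_d must be positive")
  G * exp(-dt / tau_d) + n_spikes / tau_d
}
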