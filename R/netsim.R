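#' Simulate one trial of the E-I spiking network
#'
#' Integrates the conductance-based integrate-and-fire dynamics with a Heun
#' (second-order predictor-corrector) step at `params$dt`, exact exponential
#' decay of the synaptic conductance states between spikes, end-of-step spike
#' times, reset to `V_reset` and a refractory clamp during which the membrane
#' is not integrated while the conductances keep filtering incoming spikes.
#'
#' External drive: with `protocol$mode == "deterministic"` the external
#' conductance of every neuron is set directly to the instantaneous rate,
#' `GO_i(t) = r_in(t)`; with `"poisson"` each neuron receives an independent
#' Poisson spike train of rate `r_in(t)` filtered by the excitatory synaptic
#' kernel.
#'
#' @param params an [network_params()] object.
#' @param topology an [build_topology()] object (must match `params$N`).
#' @param protocol an [input_protocol()] describing `r_in(t)`.
#' @param v_init initial membrane potentials (mV), length `N`; see
#'   [sample_initial_conditions()].
#' @param seed integer seed for the trial's private random stream (Poisson
#'   drive).  Identical seeds and inputs give bitwise-identical results.
#' @param duration trial length in ms; must be a multiple of `dt`.
#' @param record `"population"` stores the mean membrane potential of the E
#'   and I populations every millisecond (all that is needed for the LFP);
#'   `"full"` additionally stores every neuron's voltage at 1 ms resolution.
#' @return An object of class `ei_trial`: list with `spikes` (data.frame of
#'   `neuron` id and `time` ms, ordered by time), `lfp_E`, `lfp_I` (mV, at
#'   1 ms), optionally `v` (matrix time x neuron), `currents` (time-averaged
#'   per-population synaptic currents, for E-I balance diagnostics), and the
#'   run metadata (`params`, `seed`, `duration`, `onset`).
#' @export
run_trial <- function(params, topology, protocol, v_init, seed,
                      duration, record = c("population", "full")) {
  stopifnot(inherits(params, "ei_network_params"),
            inherits(topology, "ei_topology"),
            inherits(protocol, "ei_input_protocol"))
  record <- match.arg(record)
  if (topology$N != params$N) stop("topology and params disagree on N")
  if (length(v_init) != params$N) stop("v_init must have length N")
  dt <- params$dt
  n_steps <- duration / dt
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("duration must be a multiple of dt")
  n_steps <- as.integer(round(n_steps))
  record_every <- as.integer(round(1 / dt))  # 1 ms trace resolution

  rate <- input_rate(seq(0, duration, by = dt), protocol)
  out <- simulate_trial_cpp(topology$offsets, topology$targets, params$N_E,
                            params, rate, protocol$mode == "poisson",
                            as.numeric(v_init), n_steps, record_every,
                            record == "full", as.integer(seed))
  spikes <- data.frame(neuron = out$spike_id + 1L, time = out$spike_t)
  spikes <- spikes[order(spikes$time, spikes$neuron), , drop = FALSE]
  rownames(spikes) <- NULL
  res <- list(spikes = spikes, lfp_E = out$lfp_E, lfp_I = out$lfp_I,
              currents = out$currents, params = params,
              seed = as.integer(seed), duration = duration,
              onset = protocol$t_onset, protocol = protocol)
  if (record == "full") res$v <- out$v_full
  structure(res, class = "ei_trial")
}

#' @export
print.ei_trial <- function(x, ...) {
  cat(sprintf("E-I network trial: %g ms, %d spikes, N = %d (seed %d)\n",
              x$duration, nrow(x$spikes), x$params$N, x$seed))
  invisible(x)
}

#' Per-neuron spike times from a trial or ensemble
#'
#' @param x an `ei_trial`, or a data.frame with `neuron` and `time` columns.
#' @param neurons which neurons to keep (default all).
#' @return Named list of numeric spike-time vectors, one per requested neuron.
#' @export
spike_times_by_neuron <- function(x, neurons = NULL) {
  sp <- if (inherits(x, "ei_trial")) x$spikes else x
  if (is.null(neurons)) neurons <- sort(unique(sp$neuron))
  out <- split(sp$time, factor(sp$neuron, levels = neurons))
  lapply(out, sort)
}
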