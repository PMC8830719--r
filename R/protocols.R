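#' Stimulus input protocol
#'
#' Describes the external input rate of the network,
#' `r_in(t) = r0 + r_ext(t)`, where `r0` is the constant background rate and
#' `r_ext(t)` is the stimulus: zero before `t_onset`, and within
#' `[t_onset, t_end)` a step `r1` plus (in ERP mode) a transient alpha-function
#' pulse `a (t - t_onset) exp(-(t - t_onset)/tau0)` whose maximum `a tau0 / e`
#' is reached `tau0` ms after onset.  The event-related-potential convention
#' ties the pulse strength to the step, `a = r1` per ms, so stronger steps
#' come with stronger transients.
#'
#' @param r0 background rate (1/ms), constant over the trial.
#' @param r1 stimulus step (1/ms).
#' @param erp if `TRUE`, add the alpha-function pulse with `a = r1` per ms;
#'   if `FALSE`, `a = 0` (pure step, used for trial-to-trial variability).
#' @param tau0 pulse time constant (ms).
#' @param t_onset stimulus onset time (ms).
#' @param t_end stimulus end time (ms); `Inf` keeps the step on for the rest
#'   of the trial.
#' @param mode `"deterministic"` (GO set to the rate directly) or `"poisson"`
#'   (independent filtered Poisson trains per neuron).
#' @return An object of class `ei_input_protocol`.
#' @export
input_protocol <- function(r0, r1 = 0, erp = FALSE, tau0 = 20,
                           t_onset = 1000, t_end = Inf,
                           mode = c("deterministic", "poisson")) {
  mode <- match.arg(mode)
  stopifnot(r0 >= 0, r1 >= 0, tau0 > 0)
  if (t_onset >= t_end) stop("t_onset must be before t_end")
  structure(list(r0 = r0, r1 = r1, a = if (erp) r1 else 0, tau0 = tau0,
                 t_onset = t_onset, t_end = t_end, mode = mode),
            class = "ei_input_protocol")
}

#' Stimulus part of the input rate
#'
#' Evaluates `r_ext(t)`: 0 before `t_onset` and from `t_end` on; in between,
#' `r1 + a (t - t_onset) exp(-(t - t_onset)/tau0)`.
#'
#' @param t time (ms), vectorized.
#' @param protocol an [input_protocol()].
#' @return Stimulus rate (1/ms) at each `t`.
#' @examples
#' pr <- input_protocol(r0 = 0.3, r1 = 0.35, erp = TRUE, t_onset = 0)
#' erp_rate(20, pr)  # r1 + r1 * 20 / e
#' @export
erp_rate <- function(t, protocol) {
  stopifnot(inherits(protocol, "ei_input_protocol"))
  s <- t - protocol$t_onset
  on <- t >= protocol$t_onset & t < protocol$t_end
  out <- numeric(length(t))
  out[on] <- protocol$r1 + protocol$a * s[on] * exp(-s[on] / protocol$tau0)
  out
}

#' Total input rate `r_in(t) = r0 + r_ext(t)`
#' @inheritParams erp_rate
#' @return Input rate (1/ms) at each `t`.
#' @export
input_rate <- function(t, protocol) protocol$r0 + erp_rate(t, protocol)

#' Sample per-neuron initial membrane potentials
#'
#' For each trial a mean `m ~ U[-70, -55]` mV and standard deviation
#' `sigma ~ U[0, 5]` mV are drawn once; each neuron's initial voltage is then
#' `N(m, sigma)`, and any draw above -50 mV (the spike threshold) is replaced
#' by a `U[-70, -50]` draw, so all initial voltages are subthreshold.
#'
#' @param N number of neurons.
#' @param seed integer seed.
#' @return Numeric vector of length `N` of initial voltages (mV), all
#'   `<= -50`.
#' @export
sample_initial_conditions <- function(N, seed) {
  set.seed(as.integer(seed))
  m <- stats::runif(1, -70, -55)
  s <- stats::runif(1, 0, 5)
  v <- stats::rnorm(N, m, s)
  bad <- v > -50
  if (any(bad)) v[bad] <- stats::runif(sum(bad), -70, -50)
  v
}

#' Ensemble configuration
#'
#' A fixed randomly generated topology is shared by all trials; only the
#' initial conditions (and, for Poisson drive, the input spike trains) differ
#' across trials.  Per-trial seeds are derived deterministically from the root
#' seed so any single trial can be reproduced in isolation.
#'
#' @param params an [network_params()] object.
#' @param protocol an [input_protocol()].
#' @param n_trials number of trials.
#' @param duration trial length (ms).
#' @param seed root seed; seeds the topology and the per-trial streams.
#' @param record trace recording mode, see [run_trial()].
#' @return An object of class `ei_ensemble_config`.
#' @export
ensemble_config <- function(params, protocol, n_trials = 100,
                            duration = 2000, seed = 1,
                            record = "population") {
  stopifnot(inherits(params, "ei_network_params"),
            inherits(protocol, "ei_input_protocol"), n_trials >= 1)
  structure(list(params = params, protocol = protocol,
                 n_trials = as.integer(n_trials), duration = duration,
                 seed = as.integer(seed), record = record),
            class = "ei_ensemble_config")
}

#' Derive independent per-trial seeds from a root seed
#' @param seed root integer seed.
#' @param n number of seeds.
#' @return Integer vector of `n` distinct seeds below 2^31.
#' @export
trial_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a fixed-topology multi-trial ensemble
#'
#' Builds one topology from the root seed and simulates `n_trials` trials with
#' per-trial initial conditions and (for Poisson drive) per-trial input
#' streams.  With `n_trials = 1` this reduces to a single [run_trial()].
#'
#' @param config an [ensemble_config()].
#' @param topology optional pre-built topology; by default built from the
#'   root seed.
#' @return An object of class `ei_ensemble`: list with `trials` (list of
#'   `ei_trial`), `topology`, `config` and the seed manifest.
#' @export
run_ensemble <- function(config, topology = NULL) {
  stopifnot(inherits(config, "ei_ensemble_config"))
  if (is.null(topology)) topology <- build_topology(config$params, config$seed)
  seeds <- trial_seeds(config$seed, config$n_trials)
  trials <- vector("list", config$n_trials)
  for (k in seq_len(config$n_trials)) {
    v0 <- sample_initial_conditions(config$params$N, seeds[k])
    trials[[k]] <- run_trial(config$params, topology, config$protocol,
                             v0, seeds[k], config$duration,
                             record = config$record)
  }
  structure(list(trials = trials, topology = topology, config = config,
                 seeds = seeds), class = "ei_ensemble")
}

#' @export
print.ei_ensemble <- function(x, ...) {
  cat(sprintf("E-I ensemble: %d trials of %g ms, N = %d, %s input (seed %d)\n",
              length(x$trials), x$config$duration, x$config$params$N,
              x$config$protocol$mode, x$config$seed))
  invisible(x)
}
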