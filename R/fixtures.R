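#' Sample from a doubly truncated discrete power law
#'
#' Exact inverse-CDF sampling of `P(s) ~ s^-gamma` on the integer support
#' `[s_min, s_max]`.  Used as the ground-truth generator for the power-law
#' estimator recovery tests.
#'
#' @param gamma exponent (> 1 conventionally, any positive value accepted).
#' @param s_min,s_max integer truncation bounds, `s_min <= s_max`.
#' @param n number of samples.
#' @param seed integer seed.
#' @return Integer vector of `n` samples with attribute `ground_truth`
#'   (list of the generating parameters).
#' @export
sample_discrete_powerlaw <- function(gamma, s_min, s_max, n, seed = 1) {
  if (s_min > s_max) stop("s_min must not exceed s_max")
  set.seed(as.integer(seed))
  support <- as.integer(s_min):as.integer(s_max)
  w <- support^(-gamma)
  x <- if (length(support) == 1) rep.int(support, n)
       else sample(support, n, replace = TRUE, prob = w)
  structure(x, ground_truth = list(gamma = gamma, s_min = s_min,
                                   s_max = s_max))
}

#' Mean of the truncated discrete power law
#' @inheritParams sample_discrete_powerlaw
#' @return Analytic mean of `P(s) ~ s^-gamma` on `[s_min, s_max]`.
#' @export
truncated_powerlaw_mean <- function(gamma, s_min, s_max) {
  s <- s_min:s_max
  w <- s^(-gamma)
  sum(s * w) / sum(w)
}

#' Construct exactly collapsing parabolic avalanches
#'
#' Builds an avalanche set whose temporal profiles follow
#' `s(t, T) = scale * T^(e - 1) * 4 x (1 - x)` with `x = (t - 1/2)/T` and
#' `e = inv_svz`, rounded to integers by largest-remainder apportionment so
#' each profile sums exactly to its (rounded) continuous size.  By
#' construction the set collapses exactly (up to integer rounding) at
#' exponent `inv_svz`, and `<S>(T)` scales as `T^inv_svz`.
#'
#' @param inv_svz the `1/(sigma nu z)` exponent to build in.
#' @param durations integer durations (bins), each at least 4.
#' @param counts avalanches per duration (recycled).
#' @param scale amplitude prefactor; larger values reduce the relative
#'   rounding error of the integer profiles.
#' @param jitter multiplicative lognormal noise sd on the profile amplitude
#'   (0 = exact).
#' @param seed seed (used only when `jitter > 0`).
#' @return An `avalanche_set` with attribute `ground_truth`.
#' @export
make_parabolic_avalanches <- function(inv_svz, durations, counts = 1,
                                      scale = 50, jitter = 0, seed = 1) {
  if (any(durations < 4)) stop("durations must be at least 4 bins")
  set.seed(as.integer(seed))
  counts <- rep_len(counts, length(durations))
  profiles <- list()
  for (k in seq_along(durations)) {
    Td <- durations[k]
    x <- (seq_len(Td) - 0.5) / Td
    base <- scale * Td^(inv_svz - 1) * 4 * x * (1 - x)
    for (j in seq_len(counts[k])) {
      prof <- if (jitter > 0) base * exp(stats::rnorm(1, 0, jitter)) else base
      S <- max(Td, round(sum(prof)))
      flo <- floor(prof)
      rem <- S - sum(flo)
      if (rem > 0) {
        add <- order(prof - flo, decreasing = TRUE)[seq_len(min(rem, Td))]
        flo[add] <- flo[add] + 1
        rem <- S - sum(flo)
        if (rem != 0) flo[1] <- flo[1] + rem
      }
      flo[flo < 1] <- 1L
      profiles[[length(profiles) + 1]] <- as.integer(flo)
    }
  }
  structure(list(sizes = vapply(profiles, sum, integer(1)),
                 durations = vapply(profiles, length, integer(1)),
                 profiles = profiles, dt = 1, discarded_spikes = 0L),
            class = "avalanche_set",
            ground_truth = list(inv_svz = inv_svz, scale = scale,
                                jitter = jitter))
}

#' Ensemble of independent homogeneous Poisson spike trains
#'
#' One trial holds `n_neurons` independent Poisson trains of the given rate;
#' `n_trials` trials are wrapped in the same container as a simulated
#' ensemble so every trial-based estimator (Fano factor, CV, pairwise
#' correlation) can be checked against its Poisson identity.
#'
#' @param n_neurons neurons per trial (all counted as excitatory).
#' @param rate firing rate per neuron (spikes/ms).
#' @param duration trial length (ms).
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @param t_onset nominal onset stored in the protocol (for pre/post
#'   bookkeeping).
#' @return An `ei_ensemble`-classed container with `trials` (each an
#'   `ei_trial` with spikes but no voltage traces) and ground-truth metadata.
#' @export
make_poisson_ensemble <- function(n_neurons, rate, duration, n_trials,
                                  seed = 1, t_onset = duration / 2) {
  stopifnot(rate >= 0, duration > 0, n_trials >= 1)
  # params carrier: N_E = n_neurons so analysis code treats all as excitatory
  params <- network_params(N = max(5, ceiling(n_neurons / 4) * 5))
  params$N_E <- as.integer(n_neurons)
  seeds <- trial_seeds(seed, n_trials)
  protocol <- input_protocol(r0 = rate, t_onset = t_onset)
  trials <- lapply(seq_len(n_trials), function(k) {
    set.seed(seeds[k])
    counts <- stats::rpois(n_neurons, rate * duration)
    spikes <- data.frame(
      neuron = rep.int(seq_len(n_neurons), counts),
      time = stats::runif(sum(counts), 0, duration))
    spikes <- spikes[order(spikes$time), , drop = FALSE]
    rownames(spikes) <- NULL
    structure(list(spikes = spikes, lfp_E = NULL, lfp_I = NULL,
                   params = params, seed = seeds[k], duration = duration,
                   onset = t_onset, protocol = protocol),
              class = "ei_trial")
  })
  structure(list(trials = trials, topology = NULL,
                 config = structure(list(params = params,
                                         protocol = protocol,
                                         n_trials = as.integer(n_trials),
                                         duration = duration,
                                         seed = as.integer(seed),
                                         record = "none"),
                                    class = "ei_ensemble_config"),
                 seeds = seeds,
                 ground_truth = list(kind = "poisson", rate = rate)),
            class = "ei_ensemble")
}

#' Strictly periodic raster
#'
#' Every neuron spikes at integer multiples of `period` -- the degenerate,
#' perfectly synchronous construction used to exercise the periodic-state
#' classifier and zero-CV checks.
#'
#' @param n_neurons number of neurons.
#' @param period spike period (ms).
#' @param duration record length (ms).
#' @return Data frame of `neuron`, `time` with attribute `ground_truth`.
#' @export
make_periodic_raster <- function(n_neurons, period, duration) {
  tt <- seq_len(floor((duration - 1e-9) / period)) * period
  structure(data.frame(neuron = rep(seq_len(n_neurons), each = length(tt)),
                       time = rep(tt, n_neurons)),
            ground_truth = list(kind = "periodic", period = period))
}
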