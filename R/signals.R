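#' Local field potential of a trial
#'
#' The LFP is proxied by the arithmetic mean membrane potential of the chosen
#' population at 1 ms resolution.  The excitatory population is the default;
#' inhibitory- or all-neuron averages behave qualitatively the same.
#'
#' @param trial an `ei_trial` from [run_trial()].
#' @param population `"E"`, `"I"` or `"all"`.
#' @return Numeric LFP vector (mV), one sample per millisecond of the trial.
#' @export
lfp <- function(trial, population = c("E", "I", "all")) {
  stopifnot(inherits(trial, "ei_trial"))
  population <- match.arg(population)
  p <- trial$params
  switch(population,
         E = trial$lfp_E,
         I = {
           if (p$N_I == 0) stop("no inhibitory neurons in this network")
           trial$lfp_I
         },
         all = (p$N_E * trial$lfp_E + p$N_I * trial$lfp_I) / p$N)
}

#' Bin spike times into counts on a regular grid
#'
#' @param times spike times (ms).
#' @param dt bin width (ms).
#' @param t_range length-2 numeric; times outside are dropped.  Bin `k` covers
#'   `[t_range[1] + (k-1) dt, t_range[1] + k dt)`.
#' @return Integer vector of counts, length `ceiling(diff(t_range)/dt)`.
#' @export
bin_spike_counts <- function(times, dt, t_range) {
  stopifnot(dt > 0, length(t_range) == 2, t_range[2] > t_range[1])
  n_bins <- ceiling((t_range[2] - t_range[1]) / dt - 1e-9)
  times <- times[times >= t_range[1] & times < t_range[1] + n_bins * dt]
  idx <- floor((times - t_range[1]) / dt) + 1L
  idx[idx > n_bins] <- n_bins  # guard against floating-point edge
  tabulate(idx, nbins = n_bins)
}

#' Autocorrelation of the population activity
#'
#' For the 1 ms population spike-count series `n(t)` with mean `n0`,
#' `AC(tau) = sum_t (n(t+tau) - n0)(n(t) - n0) / (n0^2 T)`.  Note the
#' normalization by the squared mean (not the variance), so `AC(0)` equals the
#' relative variance of the population activity.
#'
#' @param counts population spike counts per 1 ms bin.
#' @param max_lag largest lag (in bins) to evaluate.
#' @return Data frame with `lag` (0..max_lag) and `ac`.
#' @export
population_autocorrelation <- function(counts, max_lag = 100) {
  counts <- as.numeric(counts)
  T_len <- length(counts)
  if (max_lag >= T_len) stop("record must be longer than max_lag")
  n0 <- mean(counts)
  if (n0 == 0) stop("population activity is zero; autocorrelation undefined")
  x <- counts - n0
  ac <- vapply(0:max_lag, function(l) {
    sum(x[seq_len(T_len - l)] * x[seq_len(T_len - l) + l]) / (n0^2 * T_len)
  }, numeric(1))
  data.frame(lag = 0:max_lag, ac = ac)
}

#' Pairwise Pearson correlations of boxcar-filtered spike trains
#'
#' Each neuron's 1 ms spike-count series is filtered by a square (boxcar)
#' kernel of length `kernel` ms; the Pearson correlation is computed for
#' neuron pairs.  Only neurons with at least `min_spikes` spikes enter, and
#' pairs in which either filtered series has zero variance are excluded.
#'
#' @param spikes data.frame with `neuron`, `time` columns (or an `ei_trial`).
#' @param duration record length (ms); taken from the trial if omitted.
#' @param kernel boxcar length (ms).
#' @param min_spikes minimum spike count for a neuron to be included.
#' @param max_neurons cap on the number of (randomly chosen) neurons used, to
#'   bound the O(n^2) pair count; `Inf` uses all eligible neurons.
#' @param seed seed for the neuron subsample.
#' @return Numeric vector of pairwise correlation coefficients in `[-1, 1]`.
#' @export
pairwise_correlation <- function(spikes, duration = NULL, kernel = 5,
                                 min_spikes = 5, max_neurons = 200,
                                 seed = 1) {
  if (inherits(spikes, "ei_trial")) {
    duration <- spikes$duration
    spikes <- spikes$spikes
  }
  if (is.null(duration)) duration <- ceiling(max(spikes$time))
  counts_by <- tapply(spikes$time, spikes$neuron, function(tt) {
    bin_spike_counts(tt, 1, c(0, duration))
  })
  n_spk <- vapply(counts_by, sum, numeric(1))
  counts_by <- counts_by[n_spk >= min_spikes]
  if (length(counts_by) < 2) return(numeric(0))
  if (length(counts_by) > max_neurons) {
    set.seed(as.integer(seed))
    counts_by <- counts_by[sort(sample.int(length(counts_by), max_neurons))]
  }
  k <- rep(1, kernel)
  filt <- vapply(counts_by, function(x) {
    as.numeric(stats::filter(x, k, method = "convolution", sides = 1))
  }, numeric(duration))
  filt <- filt[-seq_len(kernel - 1), , drop = FALSE]  # drop NA edge
  keep <- apply(filt, 2, stats::sd) > 0
  filt <- filt[, keep, drop = FALSE]
  if (ncol(filt) < 2) return(numeric(0))
  cm <- stats::cor(filt)
  cm[upper.tri(cm)]
}

#' Coefficient of variation of inter-spike intervals
#'
#' @param times spike times of one neuron (ms).
#' @param min_spikes minimum number of spikes required.
#' @return `sd(ISI)/mean(ISI)`, or `NA` if the train has fewer than
#'   `min_spikes` spikes.
#' @export
isi_cv <- function(times, min_spikes = 5) {
  if (length(times) < min_spikes) return(NA_real_)
  isi <- diff(sort(times))
  stats::sd(isi) / mean(isi)
}

#' ISI CV distribution across neurons
#' @param spikes data.frame with `neuron`, `time` (or an `ei_trial`).
#' @param min_spikes minimum spikes per neuron.
#' @return Numeric vector of CV values (neurons below the cutoff excluded).
#' @export
isi_cv_distribution <- function(spikes, min_spikes = 5) {
  if (inherits(spikes, "ei_trial")) spikes <- spikes$spikes
  cv <- tapply(spikes$time, spikes$neuron, isi_cv, min_spikes = min_spikes)
  as.numeric(cv[!is.na(cv)])
}

#' Power spectral density by segment-averaged periodogram
#'
#' Mean-removed, 50%-overlapping segments (default 256 ms) with a split-cosine
#' taper, averaged.  The peak frequency is reported within `band`.
#'
#' @param x signal sampled at `fs` Hz (for LFPs, 1000 Hz).
#' @param fs sampling rate (Hz).
#' @param segment segment length in samples.
#' @param overlap fractional segment overlap.
#' @param band length-2 Hz range in which to report the peak frequency.
#' @return List with `freq` (Hz), `power`, and `peak_freq` (Hz).
#' @export
psd <- function(x, fs = 1000, segment = 256, overlap = 0.5,
                band = c(1, 120)) {
  x <- as.numeric(x)
  if (length(x) < segment)
    stop("signal shorter than one segment (", segment, " samples)")
  step <- max(1, floor(segment * (1 - overlap)))
  starts <- seq(1, length(x) - segment + 1, by = step)
  spec <- NULL
  for (s0 in starts) {
    seg <- x[s0:(s0 + segment - 1)]
    sp <- stats::spec.pgram(seg - mean(seg), taper = 0.1, plot = FALSE,
                            detrend = FALSE, fast = FALSE)
    spec <- if (is.null(spec)) sp$spec else spec + sp$spec
  }
  freq <- stats::spec.pgram(x[1:segment], plot = FALSE, fast = FALSE)$freq * fs
  power <- spec / length(starts)
  inb <- freq >= band[1] & freq <= band[2]
  peak <- if (any(inb)) freq[inb][which.max(power[inb])] else NA_real_
  list(freq = freq, power = power, peak_freq = peak)
}

#' Complex Morlet wavelet power of a signal
#'
#' Convolves the signal with complex Morlet wavelets
#' `exp(2 pi i f t) exp(-t^2 / (2 s^2))`, `s = n_cycles / (2 pi f)`, via FFT.
#' The default `n_cycles = 7` gives about 2 Hz frequency resolution in the
#' gamma band at 1 kHz sampling.
#'
#' @param x signal sampled at `fs` Hz.
#' @param freqs frequencies (Hz) at which to evaluate.
#' @param fs sampling rate (Hz).
#' @param n_cycles wavelet width in cycles.
#' @return Matrix `length(freqs) x length(x)` of absolute wavelet
#'   coefficients.
#' @export
morlet_power <- function(x, freqs, fs = 1000, n_cycles = 7) {
  x <- as.numeric(x) - mean(x)
  n <- length(x)
  nfft <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  out <- matrix(0, length(freqs), n)
  tt <- (seq_len(nfft) - 1 - nfft / 2) / fs
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    s <- n_cycles / (2 * pi * f)
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * s^2))
    w <- w / sum(abs(w))
    W <- stats::fft(w)
    conv <- stats::fft(X * Conj(W), inverse = TRUE) / nfft
    # center the kernel: convolution result is circularly shifted by nfft/2
    idx <- ((seq_len(n) - 1 + nfft / 2) %% nfft) + 1
    out[i, ] <- abs(conv[idx])
  }
  out
}

#' Spectral summary of one or more LFP traces
#'
#' @param x numeric LFP vector, or list of per-trial LFP vectors (wavelet
#'   power is then the across-trial mean of absolute Morlet coefficients).
#' @param fs sampling rate (Hz).
#' @param band Hz band for the reported peak frequency.
#' @param wavelet_freqs frequencies for the Morlet analysis; `NULL` skips it.
#' @param ... passed to [psd()].
#' @return List with `psd` (from the concatenated trial-averaged
#'   periodograms), `peak_freq` (Hz), and optionally `wavelet` (frequency x
#'   time matrix of trial-averaged absolute coefficients).
#' @export
spectra <- function(x, fs = 1000, band = c(1, 120), wavelet_freqs = NULL,
                    ...) {
  xs <- if (is.list(x)) x else list(x)
  ps <- lapply(xs, psd, fs = fs, band = band, ...)
  power <- Reduce(`+`, lapply(ps, `[[`, "power")) / length(ps)
  freq <- ps[[1]]$freq
  inb <- freq >= band[1] & freq <= band[2]
  peak <- freq[inb][which.max(power[inb])]
  out <- list(psd = list(freq = freq, power = power), peak_freq = peak)
  if (!is.null(wavelet_freqs)) {
    wl <- lapply(xs, morlet_power, freqs = wavelet_freqs, fs = fs)
    out$wavelet <- Reduce(`+`, wl) / length(wl)
    out$wavelet_freqs <- wavelet_freqs
  }
  out
}

#' Default thresholds for the dynamic-state classifier
#'
#' Heuristic cutoffs on ensemble statistics used by
#' [classify_dynamic_state()].  They are conveniences for labelling
#' simulations, not calibrated quantities.
#'
#' @param sync_fraction fraction of the excitatory population spiking within
#'   one 1 ms bin above which the record counts as having all-spike events.
#' @param disp_as dispersion (variance/mean) of the 1 ms population counts
#'   below which the state is asynchronous.
#' @param disp_ss dispersion above which the state is (at least) sparsely
#'   synchronous.
#' @param pcc_high median pairwise correlation above which the state is
#'   synchronous regardless of dispersion.
#' @return Named list of thresholds.
#' @export
state_thresholds <- function(sync_fraction = 0.4, disp_as = 5,
                             disp_ss = 40, pcc_high = 0.3) {
  list(sync_fraction = sync_fraction, disp_as = disp_as,
       disp_ss = disp_ss, pcc_high = pcc_high)
}

#' Classify the dynamic state of a simulated record
#'
#' Rule-based labelling into asynchronous (`"AS"`), critical (`"Cri"`),
#' sparsely synchronous (`"SS"`) or periodic (`"P"`), from: the largest
#' 1 ms-bin fraction of excitatory neurons spiking together (all-spike events
#' mark the periodic state), the dispersion (variance over mean) of the 1 ms
#' population spike counts (burstiness: near-Poisson in the asynchronous
#' state, strongly super-Poisson once population events appear), and the
#' median pairwise correlation.  The critical label is the in-between
#' dispersion region.  The normalized autocorrelation peak is reported in
#' the attached statistics.  Thresholds come from [state_thresholds()] and
#' are heuristics calibrated at the reference background drive
#' (`r0 = 0.8`/ms, `N = 2500`), not calibrated statistics.
#'
#' @param trial an `ei_trial` (excitatory spikes are used), or a data.frame
#'   of spikes plus `n_exc`/`duration`.
#' @param n_exc number of excitatory neurons.
#' @param duration record length (ms).
#' @param thresholds from [state_thresholds()].
#' @param min_spikes records with fewer spikes are labelled
#'   `"indeterminate"`.
#' @return Character label: `"AS"`, `"Cri"`, `"SS"`, `"P"` or
#'   `"indeterminate"`, with the computed statistics attached as attributes.
#' @export
classify_dynamic_state <- function(trial, n_exc = NULL, duration = NULL,
                                   thresholds = state_thresholds(),
                                   min_spikes = 100) {
  if (inherits(trial, "ei_trial")) {
    n_exc <- trial$params$N_E
    duration <- trial$duration
    spikes <- trial$spikes[trial$spikes$neuron <= n_exc, ]
  } else {
    spikes <- trial
    if (is.null(n_exc) || is.null(duration))
      stop("n_exc and duration are required for raw spike tables")
  }
  if (nrow(spikes) < min_spikes) {
    return(structure("indeterminate", stats = list(n_spikes = nrow(spikes))))
  }
  counts <- bin_spike_counts(spikes$time, 1, c(0, duration))
  sync_frac <- max(counts) / n_exc
  dispersion <- stats::var(counts) / mean(counts)
  ac <- population_autocorrelation(counts,
                                   max_lag = min(100, length(counts) - 1))
  ac_peak <- max(ac$ac[ac$lag >= 3] / ac$ac[1])
  pcc <- pairwise_correlation(spikes, duration = duration, max_neurons = 100)
  pcc_med <- if (length(pcc)) stats::median(pcc) else 0
  st <- list(sync_fraction = sync_frac, dispersion = dispersion,
             ac_peak = ac_peak, pcc_median = pcc_med,
             n_spikes = nrow(spikes))
  label <-
    if (sync_frac >= thresholds$sync_fraction) "P"
    else if (dispersion >= thresholds$disp_ss ||
             pcc_med >= thresholds$pcc_high) "SS"
    else if (dispersion < thresholds$disp_as) "AS"
    else "Cri"
  structure(label, stats = st)
}
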