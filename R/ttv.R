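#' Cross-trial variance of the LFP
#'
#' The trial-to-trial variability of the LFP is the unbiased variance across
#' trials at each 1 ms sample, computed on the raw traces.  A 30 ms
#' square-window smoothed version of the trial-mean LFP is returned alongside
#' for display; the variance itself is never smoothed.
#'
#' @param ensemble an `ei_ensemble`, or a list of equal-length LFP vectors.
#' @param population which population's LFP to use (see [lfp()]).
#' @return List with `time` (ms), `variance` (mV^2), `mean` (raw trial-mean
#'   LFP) and `mean_smoothed` (30 ms boxcar).
#' @export
lfp_cross_trial_variance <- function(ensemble, population = "E") {
  traces <- if (inherits(ensemble, "ei_ensemble")) {
    lapply(ensemble$trials, lfp, population = population)
  } else ensemble
  if (length(traces) < 2) stop("need at least 2 trials")
  len <- vapply(traces, length, integer(1))
  if (length(unique(len)) != 1) stop("trials have different lengths")
  m <- do.call(cbind, traces)            # time x trials
  v <- apply(m, 1, stats::var)
  mu <- rowMeans(m)
  sm <- as.numeric(stats::filter(mu, rep(1 / 30, 30), sides = 2))
  list(time = seq_len(nrow(m)), variance = v, mean = mu, mean_smoothed = sm)
}

# window start times (ms) for the sliding Fano-factor windows: they start at
# trial time 0 and tile in `step` increments
ff_window_starts <- function(duration, window = 100, step = 50) {
  seq(0, duration - window, by = step)
}

#' Cross-trial Fano factor of grouped excitatory spike counts
#'
#' Spiking trial-to-trial variability on the ~100 ms scale: `samples` random
#' groups of `n` excitatory neurons are drawn once; for each group and each
#' 100 ms window (50 ms steps, windows tiling from trial time 0), the group's
#' spike count per trial gives the cross-trial Fano factor
#' `var(count)/mean(count)`.  Group-window combinations with zero mean count
#' are excluded from the group average (rather than counted as zero).  The
#' reported series is additionally smoothed by a square window of 5 steps
#' (250 ms); the unsmoothed series is returned as well.
#'
#' @param ensemble an `ei_ensemble` with at least 2 trials.
#' @param n neurons per group.
#' @param window window length (ms).
#' @param step window step (ms).
#' @param samples number of random neuron groups.
#' @param seed seed for the group sampling.
#' @return List with `time` (window centers, ms), `ff` (group-averaged,
#'   unsmoothed), `ff_smoothed`, `ff_sd` (across-group sd) and the sampling
#'   metadata.
#' @export
fano_factor <- function(ensemble, n = 5, window = 100, step = 50,
                        samples = 200, seed = 1) {
  stopifnot(inherits(ensemble, "ei_ensemble"), n >= 1)
  trials <- ensemble$trials
  if (length(trials) < 2) stop("need at least 2 trials")
  n_exc <- ensemble$config$params$N_E
  duration <- ensemble$config$duration
  starts <- ff_window_starts(duration, window, step)
  n_win <- length(starts)
  stopifnot(window %% step == 0)
  blocks_per_win <- window %/% step
  n_blk <- floor(duration / step)

  set.seed(as.integer(seed))
  groups <- t(vapply(seq_len(samples),
                     function(i) sample.int(n_exc, n), integer(n)))

  # per trial: group x window spike-count matrix, via `step`-ms blocks
  gsum <- array(0, dim = c(samples, n_win, length(trials)))
  ind <- matrix(0, samples, n_exc)
  ind[cbind(rep(seq_len(samples), n), as.vector(groups))] <- 1
  for (tr in seq_along(trials)) {
    sp <- trials[[tr]]$spikes
    sp <- sp[sp$neuron <= n_exc & sp$time < n_blk * step, ]
    blk <- floor(sp$time / step)
    idx <- sp$neuron + n_exc * blk               # (neuron, block) key
    cnt <- matrix(0, n_exc, n_blk)
    tb <- tabulate(idx, nbins = n_exc * n_blk)
    cnt[] <- tb
    gblk <- ind %*% cnt                           # groups x blocks
    for (w in seq_len(n_win)) {
      b0 <- starts[w] / step
      gsum[, w, tr] <- rowSums(gblk[, b0 + seq_len(blocks_per_win),
                                    drop = FALSE])
    }
  }
  mu <- apply(gsum, c(1, 2), mean)
  vv <- apply(gsum, c(1, 2), stats::var)
  ffm <- ifelse(mu > 0, vv / mu, NA_real_)        # exclude zero-mean windows
  ff <- colMeans(ffm, na.rm = TRUE)
  ff_sd <- apply(ffm, 2, stats::sd, na.rm = TRUE)
  sm <- as.numeric(stats::filter(ff, rep(1 / 5, 5), sides = 2))
  list(time = starts + window / 2, ff = ff, ff_smoothed = sm, ff_sd = ff_sd,
       n = n, window = window, step = step, samples = samples, seed = seed)
}

#' Pre/post-stimulus summary of a TTV series
#'
#' Means of an (unsmoothed) time series over the pre-stimulus window
#' `[-550, -50]` ms and the post-stimulus window `[50, 550]` ms relative to
#' stimulus onset.  A window (or sample) containing the onset belongs to
#' neither side.
#'
#' @param time sample times (ms; for Fano series, window centers).
#' @param values series values.
#' @param onset stimulus onset time (ms).
#' @param pre,post windows relative to onset (ms).
#' @param half_width for windowed series, half the window length (ms): a
#'   window is included only if it lies entirely inside the pre or post range.
#' @return List with `pre`, `post` (means) and `ratio = post/pre`.
#' @export
pre_post_summary <- function(time, values, onset, pre = c(-550, -50),
                             post = c(50, 550), half_width = 0) {
  lo <- time - half_width - onset
  hi <- time + half_width - onset
  pre_i <- lo >= pre[1] & hi <= pre[2]
  post_i <- lo >= post[1] & hi <= post[2]
  pm <- mean(values[pre_i], na.rm = TRUE)
  qm <- mean(values[post_i], na.rm = TRUE)
  list(pre = pm, post = qm, ratio = qm / pm)
}

#' Full trial-to-trial variability summary of an ensemble
#'
#' Combines the LFP cross-trial variance series and the grouped Fano-factor
#' series with their pre/post-stimulus means.
#'
#' @param ensemble an `ei_ensemble` whose protocol has a finite onset.
#' @param n,window,step,samples,seed passed to [fano_factor()].
#' @return An object of class `ei_ttv_summary`.
#' @export
ttv_summary <- function(ensemble, n = 5, window = 100, step = 50,
                        samples = 200, seed = 1) {
  onset <- ensemble$config$protocol$t_onset
  lv <- lfp_cross_trial_variance(ensemble)
  ff <- fano_factor(ensemble, n = n, window = window, step = step,
                    samples = samples, seed = seed)
  structure(list(
    lfp_variance = lv, fano = ff, onset = onset,
    lfp_pre_post = pre_post_summary(lv$time, lv$variance, onset),
    ff_pre_post = pre_post_summary(ff$time, ff$ff, onset,
                                   half_width = window / 2)),
    class = "ei_ttv_summary")
}

#' @export
print.ei_ttv_summary <- function(x, ...) {
  cat("Trial-to-trial variability summary\n")
  cat(sprintf("  LFP variance: pre %.4g, post %.4g mV^2 (ratio %.3f)\n",
              x$lfp_pre_post$pre, x$lfp_pre_post$post, x$lfp_pre_post$ratio))
  cat(sprintf("  Fano factor : pre %.4g, post %.4g (ratio %.3f)\n",
              x$ff_pre_post$pre, x$ff_pre_post$post, x$ff_pre_post$ratio))
  invisible(x)
}
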