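#' Mean inter-spike interval of the merged spike train
#'
#' Pools the spike times of the selected population, sorts them, and averages
#' successive differences.  This quantity (often written T_m) is the adaptive
#' avalanche bin width: binning at the merged mean ISI makes the avalanche
#' partition scale with the overall activity level.
#'
#' @param x an `ei_trial`, a data.frame with a `time` column, or a numeric
#'   vector of spike times (ms).
#' @param population `"E"` (default, as avalanches are measured on excitatory
#'   spikes), `"I"` or `"all"`; ignored unless `x` is a trial.
#' @return Mean merged ISI (ms).
#' @export
merged_mean_isi <- function(x, population = c("E", "I", "all")) {
  population <- match.arg(population)
  times <- if (inherits(x, "ei_trial")) {
    n_exc <- x$params$N_E
    keep <- switch(population, E = x$spikes$neuron <= n_exc,
                   I = x$spikes$neuron > n_exc, all = TRUE)
    x$spikes$time[keep]
  } else if (is.data.frame(x)) x$time else as.numeric(x)
  if (length(times) < 2) stop("need at least 2 spikes")
  mean(diff(sort(times)))
}

#' Extract neuronal avalanches from a binned count series
#'
#' An avalanche is a maximal run of consecutive non-empty bins, bounded by
#' empty bins.  Its size `S` is the total spike count of the run, its
#' duration `T` the number of bins, and its profile the per-bin counts.  Runs
#' touching either record boundary are discarded (they are censored: their
#' true extent is unknown), so the sum of all avalanche sizes plus the
#' boundary-discarded spikes equals the total spike count.
#'
#' @param counts integer spike counts per bin (bin width `dt`).
#' @param dt bin width in ms (metadata only).
#' @param keep_profiles store per-avalanche profiles (needed for shape
#'   collapse); disable for very large records to save memory.
#' @return An object of class `avalanche_set`: list with `sizes`,
#'   `durations`, `profiles` (list of integer vectors or `NULL`),
#'   `dt`, and `discarded_spikes` (spikes in boundary-touching runs).  An
#'   all-zero record gives an empty set.
#' @examples
#' extract_avalanches(c(0, 2, 1, 0, 0, 3, 0), dt = 1)
#' @export
extract_avalanches <- function(counts, dt = NA_real_, keep_profiles = TRUE) {
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  r <- rle(counts > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  act <- which(r$values)
  # censored runs: active run touching the first or last bin
  boundary <- act[starts[act] == 1 | ends[act] == length(counts)]
  act <- setdiff(act, boundary)
  discarded <- sum(unlist(lapply(boundary, function(i)
    counts[starts[i]:ends[i]])))
  if (length(act) == 0) {
    return(structure(list(sizes = integer(0), durations = integer(0),
                          profiles = if (keep_profiles) list() else NULL,
                          dt = dt, discarded_spikes = discarded),
                     class = "avalanche_set"))
  }
  profiles <- lapply(act, function(i) counts[starts[i]:ends[i]])
  structure(list(sizes = vapply(profiles, sum, integer(1)),
                 durations = r$lengths[act],
                 profiles = if (keep_profiles) profiles else NULL,
                 dt = dt, discarded_spikes = discarded),
            class = "avalanche_set")
}

#' @export
print.avalanche_set <- function(x, ...) {
  cat(sprintf("Avalanche set: %d avalanches (bin %.4g ms), sizes 1-%s, durations 1-%s\n",
              length(x$sizes), x$dt,
              if (length(x$sizes)) max(x$sizes) else "-",
              if (length(x$sizes)) max(x$durations) else "-"))
  invisible(x)
}

#' Combine avalanche sets
#' @param ... `avalanche_set` objects with the same bin width.
#' @return A single `avalanche_set` pooling all avalanches.
#' @export
combine_avalanches <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "avalanche_set")) sets <- sets[[1]]
  profs <- lapply(sets, `[[`, "profiles")
  structure(list(sizes = unlist(lapply(sets, `[[`, "sizes")),
                 durations = unlist(lapply(sets, `[[`, "durations")),
                 profiles = if (all(!vapply(profs, is.null, logical(1))))
                   do.call(c, profs) else NULL,
                 dt = sets[[1]]$dt,
                 discarded_spikes = sum(vapply(sets, `[[`, numeric(1),
                                               "discarded_spikes"))),
            class = "avalanche_set")
}

# log-likelihood (up to constants) of a discrete power law P(s) ~ s^-gamma
# truncated to [s_min, s_max]; `slog` = sum(log(samples)), n = sample count
trunc_pl_mle <- function(samples, s_min, s_max) {
  support <- s_min:s_max
  n <- length(samples)
  slog <- sum(log(samples))
  nll <- function(g) g * slog + n * log(sum(support^(-g)))
  stats::optimize(nll, c(1.0001, 8))$minimum
}

trunc_pl_cdf <- function(gamma, s_min, s_max) {
  w <- (s_min:s_max)^(-gamma)
  cumsum(w) / sum(w)
}

# KS statistic of in-range integer samples against the fitted truncated CDF
trunc_pl_ks <- function(samples, gamma, s_min, s_max) {
  emp <- cumsum(tabulate(samples - s_min + 1L,
                         nbins = s_max - s_min + 1L)) / length(samples)
  max(abs(emp - trunc_pl_cdf(gamma, s_min, s_max)))
}

# inverse-CDF sampler from the fitted truncated discrete power law
rtrunc_pl <- function(n, gamma, s_min, s_max) {
  cdf <- trunc_pl_cdf(gamma, s_min, s_max)
  s_min + findInterval(stats::runif(n), cdf,
                       left.open = TRUE, rightmost.closed = TRUE)
}

#' Doubly truncated discrete power-law fit with KS model selection
#'
#' Fits `P(s) ~ s^-gamma` on candidate truncation ranges `[s_min, s_max]` by
#' discrete maximum likelihood, assesses each range with a
#' Kolmogorov-Smirnov test whose p-value is the fraction of parametric
#' surrogate datasets (drawn from the fitted truncated model at the matched
#' in-range sample size, with the exponent refitted per surrogate) whose KS
#' statistic exceeds the empirical one, and returns the passing range
#' (`p > p_threshold`) with the largest `log10(s_max/s_min)`, ties broken by
#' the larger in-range sample count.  Candidate lower bounds are the unique
#' sample values up to the 25th percentile, upper bounds the unique values
#' from the 75th percentile up, subject to `s_max/s_min >= min_ratio`.
#' Candidates are examined in order of decreasing log-width, with early
#' rejection (in blocks of 50 surrogates) once the upper confidence bound of
#' the p-value falls below the threshold, so the first acceptance is the
#' widest passing range.
#'
#' @param samples positive integer samples (sizes or durations); at least
#'   100 required.
#' @param p_threshold KS p-value required to accept a range.
#' @param n_surrogates surrogate datasets per candidate range.
#' @param min_ratio minimum `s_max/s_min` of a candidate range.
#' @param seed seed for the surrogate sampling.
#' @param max_candidates cap on the number of candidate ranges examined
#'   (widest first).
#' @param ks_screen skip the surrogate stage whenever
#'   `sqrt(n_in) * KS` exceeds this value; 3 is far beyond any statistic a
#'   passing range can produce (the continuous-case p there is < 1e-7, and
#'   discreteness only lowers the surrogate KS values), so the screen only
#'   removes hopeless candidates.
#' @return An object of class `powerlaw_fit`: `exponent`, `s_min`, `s_max`,
#'   `p`, `n_in` (in-range sample count), `ks`, and `found` (`FALSE` with
#'   `NA` fields when no range passes -- an explicit "no power-law range"
#'   result, not an error).
#' @export
fit_truncated_powerlaw <- function(samples, p_threshold = 0.1,
                                   n_surrogates = 500, min_ratio = 3,
                                   seed = 1, max_candidates = 2000,
                                   ks_screen = 3) {
  samples <- as.integer(samples)
  if (length(samples) < 100) stop("need at least 100 samples")
  if (any(samples < 1)) stop("samples must be positive integers")
  no_fit <- structure(list(exponent = NA_real_, s_min = NA_integer_,
                           s_max = NA_integer_, p = NA_real_,
                           n_in = NA_integer_, ks = NA_real_, found = FALSE),
                      class = "powerlaw_fit")
  u <- sort(unique(samples))
  if (length(u) < 3) return(no_fit)
  q <- stats::quantile(samples, c(0.25, 0.75), type = 1)
  # heavy-tailed data concentrate their lower quartile on the smallest one or
  # two values; always admit at least the 10 smallest unique values so the
  # search can move the lower truncation off the head of the distribution
  lo_cand <- u[u <= max(q[1], u[min(10L, length(u))])]
  hi_cand <- u[u >= q[2]]
  if (!length(hi_cand)) hi_cand <- u[length(u)]
  cand <- expand.grid(s_min = lo_cand, s_max = hi_cand)
  cand <- cand[cand$s_max / cand$s_min >= min_ratio, , drop = FALSE]
  if (!nrow(cand)) return(no_fit)
  cand$width <- log10(cand$s_max / cand$s_min)
  cand$n_in <- vapply(seq_len(nrow(cand)), function(i)
    sum(samples >= cand$s_min[i] & samples <= cand$s_max[i]), numeric(1))
  cand <- cand[cand$n_in >= 100, , drop = FALSE]
  if (!nrow(cand)) return(no_fit)
  cand <- cand[order(-cand$width, -cand$n_in), , drop = FALSE]
  if (nrow(cand) > max_candidates) cand <- cand[seq_len(max_candidates), ]

  set.seed(as.integer(seed))
  block <- 50L
  for (i in seq_len(nrow(cand))) {
    s_min <- cand$s_min[i]; s_max <- cand$s_max[i]
    inr <- samples[samples >= s_min & samples <= s_max]
    g_hat <- trunc_pl_mle(inr, s_min, s_max)
    ks_emp <- trunc_pl_ks(inr, g_hat, s_min, s_max)
    n_in <- length(inr)
    if (sqrt(n_in) * ks_emp > ks_screen) next
    exceed <- 0L; done <- 0L; rejected <- FALSE
    while (done < n_surrogates) {
      m <- min(block, n_surrogates - done)
      for (b in seq_len(m)) {
        surr <- rtrunc_pl(n_in, g_hat, s_min, s_max)
        g_s <- trunc_pl_mle(surr, s_min, s_max)
        if (trunc_pl_ks(surr, g_s, s_min, s_max) > ks_emp)
          exceed <- exceed + 1L
      }
      done <- done + m
      # early rejection: even optimistically, p will not reach the threshold
      if (done >= block &&
          stats::qbeta(0.995, exceed + 1, done - exceed) < p_threshold) {
        rejected <- TRUE
        break
      }
      if (exceed / n_surrogates > p_threshold) break  # already passed
    }
    p_hat <- exceed / done
    if (!rejected && p_hat > p_threshold) {
      return(structure(list(exponent = g_hat, s_min = as.integer(s_min),
                            s_max = as.integer(s_max), p = p_hat,
                            n_in = as.integer(n_in), ks = ks_emp,
                            found = TRUE),
                       class = "powerlaw_fit"))
    }
  }
  no_fit
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  if (x$found) {
    cat(sprintf("Truncated power law: exponent %.3f on [%d, %d] (n = %d, KS p = %.3f)\n",
                x$exponent, x$s_min, x$s_max, x$n_in, x$p))
  } else cat("Truncated power law: no passing range\n")
  invisible(x)
}

#' Mean avalanche size versus duration exponent
#'
#' Regresses `log <S>(T)` on `log T` by weighted least squares, with weights
#' equal to the number of avalanches observed at each duration, restricted to
#' a duration range (usually the truncation range of the duration
#' distribution fit).  The slope estimates `1/(sigma nu z)`.
#'
#' @param av an `avalanche_set` (or a list with `sizes` and `durations`).
#' @param range length-2 duration range; `NULL` uses all durations.
#' @return List with `exponent` (the slope), `intercept`, and the per-duration
#'   table (`duration`, `mean_size`, `n`).
#' @export
fit_size_vs_duration <- function(av, range = NULL) {
  d <- as.numeric(av$durations)
  s <- as.numeric(av$sizes)
  if (!is.null(range)) {
    keep <- d >= range[1] & d <= range[2]
    d <- d[keep]; s <- s[keep]
  }
  tab <- stats::aggregate(s, list(duration = d),
                          function(x) c(mean = mean(x), n = length(x)))
  tab <- data.frame(duration = tab$duration, mean_size = tab$x[, "mean"],
                    n = tab$x[, "n"])
  if (nrow(tab) < 3) stop("need at least 3 distinct durations")
  fit <- stats::lm(log(mean_size) ~ log(duration), data = tab,
                   weights = tab$n)
  list(exponent = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), table = tab)
}

#' Crackling-noise scaling relation error
#'
#' For size exponent `tau`, duration exponent `alpha` and size-duration
#' exponent `inv_svz = 1/(sigma nu z)`, criticality requires
#' `(alpha - 1)/(tau - 1) = 1/(sigma nu z)`; this returns the absolute
#' deviation `|(alpha - 1)/(tau - 1) - inv_svz|`.
#'
#' @param tau size distribution exponent (> 1).
#' @param alpha duration distribution exponent.
#' @param inv_svz mean size versus duration exponent.
#' @return Nonnegative deviation from the scaling relation.
#' @examples
#' scaling_relation_error(1.5, 2, 2)  # critical branching values: 0
#' @export
scaling_relation_error <- function(tau, alpha, inv_svz) {
  if (tau <= 1) stop("tau must exceed 1")
  abs((alpha - 1) / (tau - 1) - inv_svz)
}

#' Avalanche shape collapse
#'
#' Rescales the temporal profiles `s(t, T)` of avalanches with duration
#' `T >= min_duration` as `s(t, T) T^(1 - e)` on normalized time `t/T`
#' (profiles interpolated onto a common grid), for each candidate exponent
#' `e = 1/(sigma nu z)` on a grid.  Profiles of each duration are averaged
#' first.  The collapse error is the mean across-duration variance of the
#' rescaled mean profiles divided by the squared range of the grand mean
#' profile; the best exponent minimizes it.
#'
#' @param av an `avalanche_set` with stored profiles.
#' @param exponents candidate `1/(sigma nu z)` grid.
#' @param min_duration shortest duration (bins) admitted.
#' @param grid_points interpolation grid size on `[0, 1]`.
#' @return List with `best` (argmin exponent), `errors` (data.frame of
#'   `exponent`, `error`) and `n_durations` used.
#' @export
shape_collapse <- function(av, exponents = seq(0.8, 2, by = 0.01),
                           min_duration = 4, grid_points = 100) {
  if (is.null(av$profiles)) stop("avalanche set has no stored profiles")
  keep <- av$durations >= min_duration
  profs <- av$profiles[keep]
  durs <- av$durations[keep]
  ud <- sort(unique(durs))
  if (length(ud) < 2)
    stop("need avalanches of at least 2 distinct durations >= min_duration")
  xg <- seq(0, 1, length.out = grid_points)
  # average profile per duration, interpolated at bin midpoints t/T
  mean_profiles <- lapply(ud, function(Td) {
    pm <- Reduce(`+`, profs[durs == Td]) / sum(durs == Td)
    stats::approx((seq_len(Td) - 0.5) / Td, pm, xout = xg, rule = 2)$y
  })
  M <- do.call(rbind, mean_profiles)      # durations x grid
  errs <- vapply(exponents, function(e) {
    R <- M * ud^(1 - e)
    mu <- colMeans(R)
    rng <- max(mu) - min(mu)
    if (rng == 0) return(Inf)
    mean(apply(R, 2, stats::var)) / rng^2
  }, numeric(1))
  list(best = exponents[which.min(errs)],
       errors = data.frame(exponent = exponents, error = errs),
       n_durations = length(ud))
}

#' Avalanches of a spike record at a given (or adaptive) bin width
#'
#' Convenience wrapper: pools the excitatory spike times of a trial (or a
#' numeric vector of times), bins them at `dt` (default: the merged mean ISI
#' of the record), and extracts avalanches.
#'
#' @param x an `ei_trial` or numeric spike times (ms).
#' @param dt bin width (ms); `NULL` uses the merged mean ISI.
#' @param t_range time range (ms); defaults to the full record.
#' @param keep_profiles see [extract_avalanches()].
#' @return An `avalanche_set`.
#' @export
avalanches_from_spikes <- function(x, dt = NULL, t_range = NULL,
                                   keep_profiles = TRUE) {
  times <- if (inherits(x, "ei_trial")) {
    x$spikes$time[x$spikes$neuron <= x$params$N_E]
  } else as.numeric(x)
  if (is.null(t_range)) {
    t_range <- if (inherits(x, "ei_trial")) c(0, x$duration)
               else range(times) + c(-1e-9, 1e-9)
  }
  times <- times[times >= t_range[1] & times < t_range[2]]
  if (is.null(dt)) dt <- merged_mean_isi(times)
  extract_avalanches(bin_spike_counts(times, dt, t_range), dt = dt,
                     keep_profiles = keep_profiles)
}

#' Full criticality analysis of an avalanche set
#'
#' Fits the size and duration distributions with the doubly truncated
#' power-law machinery (exponents `tau` and `alpha`), the mean size versus
#' duration exponent `1/(sigma nu z)` by weighted least squares within the
#' duration truncation range, and reports the crackling-noise scaling
#' relation error.
#'
#' @param av an `avalanche_set`.
#' @param p_threshold,n_surrogates,seed passed to
#'   [fit_truncated_powerlaw()].
#' @return An object of class `criticality_summary` with `tau`, `alpha`,
#'   `inv_svz`, `relation_error`, the underlying fits, and `n_avalanches`.
#' @export
avalanche_analysis <- function(av, p_threshold = 0.1, n_surrogates = 500,
                               seed = 1) {
  fit_s <- fit_truncated_powerlaw(av$sizes, p_threshold = p_threshold,
                                  n_surrogates = n_surrogates, seed = seed)
  fit_d <- fit_truncated_powerlaw(av$durations, p_threshold = p_threshold,
                                  n_surrogates = n_surrogates,
                                  seed = seed + 1L)
  dur_range <- if (fit_d$found) c(fit_d$s_min, fit_d$s_max) else NULL
  sv <- fit_size_vs_duration(av, range = dur_range)
  rel <- if (fit_s$found && fit_d$found) {
    scaling_relation_error(fit_s$exponent, fit_d$exponent, sv$exponent)
  } else NA_real_
  structure(list(tau = if (fit_s$found) fit_s$exponent else NA_real_,
                 alpha = if (fit_d$found) fit_d$exponent else NA_real_,
                 inv_svz = sv$exponent, relation_error = rel,
                 size_fit = fit_s, duration_fit = fit_d,
                 size_duration_fit = sv,
                 n_avalanches = length(av$sizes), dt = av$dt),
            class = "criticality_summary")
}

#' @export
print.criticality_summary <- function(x, ...) {
  cat(sprintf("Criticality analysis of %d avalanches (bin %.4g ms)\n",
              x$n_avalanches, x$dt))
  cat(sprintf("  tau = %.3f [%s, %s], alpha = %.3f [%s, %s]\n",
              x$tau, x$size_fit$s_min, x$size_fit$s_max,
              x$alpha, x$duration_fit$s_min, x$duration_fit$s_max))
  cat(sprintf("  1/(sigma nu z) = %.3f, scaling relation error = %.4f\n",
              x$inv_svz, x$relation_error))
  invisible(x)
}
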