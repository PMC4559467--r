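#' Per-neuron firing rates
#'
#' Spike count inside a time window divided by the window length; neurons
#' without spikes get rate 0.
#'
#' @param spikes a `spike_record` (data frame with `time` in ms and 0-based
#'   `neuron`).
#' @param window numeric length-2 interval (ms).
#' @param n_neurons population size (defaults to the record's
#'   `n_e + n_i` attribute).
#' @return Numeric vector of rates (Hz) indexed by 0-based neuron id + 1.
#' @export
firing_rates <- function(spikes, window, n_neurons = NULL) {
  if (diff(window) <= 0) stop("window must have positive length")
  if (is.null(n_neurons))
    n_neurons <- attr(spikes, "n_e") + attr(spikes, "n_i")
  sel <- spikes$time > window[1] & spikes$time <= window[2]
  cnt <- tabulate(spikes$neuron[sel] + 1L, n_neurons)
  cnt / (diff(window) / 1000)
}

#' Coefficient of variation of inter-spike intervals
#'
#' `SD(ISI) / mean(ISI)` for a single neuron's spike times; requires at
#' least 3 spikes (2 intervals), otherwise `NA`.
#'
#' @param times spike times of one neuron (ms).
#' @return The CV, or `NA_real_` if fewer than 3 spikes.
#' @export
#' @examples
#' cv_isi(seq(0, 1000, by = 50)) # periodic: 0
cv_isi <- function(times) {
  if (length(times) < 3) return(NA_real_)
  isi <- diff(sort(times))
  sd(isi) / mean(isi)
}

#' Mean outgoing E-E weight of excitatory cells
#'
#' The driver-neuron ranking statistic: the arithmetic mean of a cell's
#' outgoing excitatory-excitatory weights.  Cells without outgoing E-E
#' edges are excluded from ranking and get `NA`.
#'
#' @param topology a [topology] object.
#' @param ids 0-based excitatory ids (default: all).
#' @return Numeric vector of per-cell means (`NA` for zero out-degree).
#' @export
mean_outgoing_weight <- function(topology, ids = seq_len(topology$n_e) - 1L) {
  ee <- topology$edges$ee
  s <- rowsum(ee$w, ee$pre, reorder = FALSE)
  k <- table(ee$pre)
  mean_all <- rep(NA_real_, topology$n_e)
  pre_ids <- as.integer(rownames(s))
  mean_all[pre_ids + 1L] <- s[, 1] / as.integer(k[as.character(pre_ids)])
  mean_all[ids + 1L]
}

new_driver_report <- function(method, threshold, drivers, means) {
  structure(list(method = method, threshold = threshold,
                 drivers = as.integer(drivers), mean_outgoing = means),
            class = "driver_report")
}

#' @export
print.driver_report <- function(x, ...) {
  cat(sprintf("driver report (%s method): %d drivers, threshold %.4g\n",
              x$method, length(x$drivers), x$threshold))
  invisible(x)
}

#' Detect driver neurons by percentile
#'
#' Selects the top fraction (default 0.5%) of the excitatory cells with the
#' largest mean outgoing E-E weight: exactly `round(fraction * n_ranked)`
#' cells, where ranked cells are those with at least one outgoing E-E edge.
#' Ties are broken towards the lower id for determinism.
#'
#' @param topology a [topology] object.
#' @param fraction fraction of ranked cells to select (in (0, 1)).
#' @return A `driver_report` with fields `method`, `threshold`, `drivers`
#'   (0-based ids) and `mean_outgoing` (per-cell means, `NA` when
#'   unranked).
#' @export
detect_drivers_percentile <- function(topology, fraction = 0.005) {
  stopifnot(fraction > 0, fraction < 1)
  mo <- mean_outgoing_weight(topology)
  ranked <- which(!is.na(mo)) # 1-based
  k <- round(fraction * length(ranked))
  ord <- ranked[order(-mo[ranked], ranked)]
  sel <- ord[seq_len(k)]
  thr <- if (k > 0) min(mo[sel]) else NA_real_
  new_driver_report("percentile", thr, sel - 1L, mo)
}

#' Detect driver neurons by standard-deviation threshold
#'
#' Selects all ranked cells whose mean outgoing E-E weight exceeds
#' `mean + k_sd * SD` of the per-cell means (default three standard
#' deviations).  With zero dispersion the driver set is empty.
#'
#' @param topology a [topology] object.
#' @param k_sd number of standard deviations above the mean.
#' @return A `driver_report`.
#' @export
detect_drivers_sd <- function(topology, k_sd = 3) {
  mo <- mean_outgoing_weight(topology)
  ranked <- which(!is.na(mo))
  if (length(ranked) < 2) stop("need at least 2 ranked cells")
  thr <- mean(mo[ranked]) + k_sd * sd(mo[ranked])
  sel <- ranked[mo[ranked] > thr]
  new_driver_report("sd", thr, sel - 1L, mo)
}

#' Shuffle surrogate of the mean-outgoing-weight distribution
#'
#' Permutes the synaptic weights among the existing E-E edges (the edge
#' set and the weight multiset stay fixed), recomputes the per-cell mean
#' outgoing weights, and returns the mean and SD across shuffles of the
#' sorted per-cell means (quantile curves).  Plasticity-induced clustering
#' shows as the original top quantiles exceeding the surrogate band.
#'
#' @param topology a [topology] object.
#' @param n_shuffles number of shuffles.
#' @param seed integer seed.
#' @return A list with `quantile_mean`, `quantile_sd` (surrogate curves
#'   over ranked cells, ascending), and `original` (sorted original
#'   per-cell means).
#' @export
shuffle_weight_surrogate <- function(topology, n_shuffles = 100, seed = NULL) {
  stopifnot(n_shuffles >= 1)
  ee <- topology$edges$ee
  mo <- mean_outgoing_weight(topology)
  orig <- sort(mo[!is.na(mo)])
  with_seed(seed, {
    qs <- matrix(0, n_shuffles, length(orig))
    shuf <- topology
    for (s in seq_len(n_shuffles)) {
      shuf$edges$ee$w <- ee$w[sample.int(nrow(ee))]
      m <- mean_outgoing_weight(shuf)
      qs[s, ] <- sort(m[!is.na(m)])
    }
    list(quantile_mean = colMeans(qs),
         quantile_sd = apply(qs, 2, sd),
         original = orig)
  })
}

#' Count directed E-E connections inside a cell group
#'
#' Number of ordered pairs `(a, b)` of distinct group members joined by an
#' E-E edge.
#'
#' @param topology a [topology] object.
#' @param ids 0-based excitatory ids (distinct).
#' @return Integer count.
#' @export
#' @examples
#' topo <- build_random_topology(100, 0, 0.1, seed = 1)
#' count_subgroup_connections(topo, 0:19)
count_subgroup_connections <- function(topology, ids) {
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop("ids must be distinct")
  ee <- topology$edges$ee
  sum(ee$pre %in% ids & ee$post %in% ids)
}

#' Synchrony-triggered average of the population rate
#'
#' Finds time bins (default 1 ms) in which at least `k` members of a cell
#' group spike, and averages the excitatory population rate in a window of
#' `+/- halfwidth` around these synchrony events.  Events closer than one
#' halfwidth to a previous event are collapsed onto the first; events whose
#' window would leave the recording are dropped.
#'
#' @param spikes a `spike_record`.
#' @param group 0-based ids of the group.
#' @param k minimal number of coincident group spikes.
#' @param bin bin width (ms).
#' @param halfwidth half width of the averaging window (ms).
#' @param n_e excitatory population size (defaults to the record
#'   attribute).
#' @return A list with `lag` (ms), `rate` (Hz), and `n_events`; `n_events`
#'   is 0 with empty `lag`/`rate` when no event qualifies.
#' @export
synchrony_triggered_average <- function(spikes, group, k, bin = 1,
                                        halfwidth = 100, n_e = NULL) {
  stopifnot(k >= 1, bin > 0)
  if (is.null(n_e)) n_e <- attr(spikes, "n_e")
  t0 <- min(spikes$time, 0)
  t1 <- max(spikes$time, 0)
  nb <- max(1L, ceiling((t1 - t0) / bin))
  gb <- spikes$time[spikes$neuron %in% group]
  gcnt <- tabulate(pmin(pmax(ceiling((gb - t0) / bin), 1L), nb), nb)
  ev <- which(gcnt >= k)
  if (length(ev) > 1) { # collapse events within one halfwidth
    keep <- ev[1]
    for (e in ev[-1]) if ((e - keep[length(keep)]) * bin > halfwidth)
      keep <- c(keep, e)
    ev <- keep
  }
  # event time = centre of the triggering bin
  ev_t <- t0 + (ev - 0.5) * bin
  hw_bins <- ceiling(halfwidth / bin)
  ev <- ev[ev - hw_bins >= 1 & ev + hw_bins <= nb]
  ev_t <- t0 + (ev - 0.5) * bin
  if (length(ev) == 0)
    return(list(lag = numeric(0), rate = numeric(0), n_events = 0L))
  eb <- spikes$time[spikes$neuron < n_e]
  ecnt <- tabulate(pmin(pmax(ceiling((eb - t0) / bin), 1L), nb), nb)
  lags <- (-hw_bins):hw_bins
  acc <- numeric(length(lags))
  for (e in ev) acc <- acc + ecnt[e + lags]
  rate <- acc / length(ev) / (bin / 1000) / n_e
  list(lag = lags * bin, rate = rate, n_events = length(ev))
}

#' Peri-stimulus time histogram
#'
#' Spike counts in bins aligned to given times, normalized by bin width
#' and population size and averaged across alignments.
#'
#' @param spikes a `spike_record`.
#' @param bin bin width (ms).
#' @param align_times alignment (stimulus) times (ms).
#' @param window length-2 window around each alignment (ms).
#' @param population 0-based ids over which the rate is computed
#'   (default: excitatory population).
#' @return A data frame with `lag` (bin centre, ms) and `rate` (Hz).
#' @export
psth <- function(spikes, bin = 1, align_times, window = c(-100, 100),
                 population = NULL) {
  stopifnot(bin > 0, length(align_times) >= 1)
  if (is.null(population)) population <- seq_len(attr(spikes, "n_e")) - 1L
  st <- spikes$time[spikes$neuron %in% population]
  edges <- seq(window[1], window[2], by = bin)
  mids <- edges[-length(edges)] + bin / 2
  acc <- numeric(length(mids))
  for (a in align_times) {
    rel <- st - a
    sel <- rel > window[1] & rel <= window[2]
    acc <- acc + tabulate(pmin(ceiling((rel[sel] - window[1]) / bin),
                               length(mids)), length(mids))
  }
  data.frame(lag = mids,
             rate = acc / length(align_times) / (bin / 1000) /
               length(population))
}

new_powerlaw_fit <- function(alpha, x_min, x_max, trim, ks, n_tail) {
  structure(list(alpha = alpha, x_min = x_min, x_max = x_max,
                 upper_trim_fraction = trim, ks_distance = ks,
                 n_tail = as.integer(n_tail)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("power-law fit: alpha = %.3f, x_min = %.4g, x_max = %.4g\n",
              x$alpha, x$x_min, x$x_max))
  cat(sprintf("  KS distance %.4f over %d tail points (top %.0f%% trimmed)\n",
              x$ks_distance, x$n_tail, 100 * x$upper_trim_fraction))
  invisible(x)
}

# truncated continuous power-law: density C x^-a on [x_min, x_max]
plaw_loglik <- function(a, x, x_min, x_max) {
  if (abs(a - 1) < 1e-9) a <- 1 + 1e-9
  logC <- log(a - 1) - log(x_min^(1 - a) - x_max^(1 - a))
  length(x) * logC - a * sum(log(x))
}

plaw_cdf <- function(x, a, x_min, x_max) {
  (x_min^(1 - a) - x^(1 - a)) / (x_min^(1 - a) - x_max^(1 - a))
}

#' Fit a truncated power law by maximum likelihood
#'
#' Continuous maximum-likelihood power-law fit to the middle part of a
#' long-tailed sample: the strongest `upper_trim_fraction` of the sample
#' (default 5%) is discarded, the exponent is estimated by ML for the
#' density `C x^-a` on `[x_min, x_max]` (with `x_max` the trim bound), and
#' `x_min` is selected by minimizing the Kolmogorov-Smirnov distance
#' between the fitted and the empirical tail distribution over a candidate
#' grid.  The returned `alpha` uses the density-exponent sign convention
#' (negative).
#'
#' @param samples positive numeric sample.
#' @param upper_trim_fraction fraction of the largest values to discard
#'   before fitting (in `[0, 1)`).
#' @param n_candidates number of `x_min` candidates (quantile grid).
#' @param min_tail minimal number of points above `x_min`.
#' @return A `powerlaw_fit` object with `alpha`, `x_min`, `x_max`,
#'   `ks_distance` and `n_tail`.
#' @export
fit_powerlaw_mle <- function(samples, upper_trim_fraction = 0.05,
                             n_candidates = 50, min_tail = 50) {
  stopifnot(upper_trim_fraction >= 0, upper_trim_fraction < 1)
  x <- sort(samples[samples > 0])
  if (upper_trim_fraction > 0) {
    n_keep <- floor(length(x) * (1 - upper_trim_fraction))
    x <- x[seq_len(n_keep)]
  }
  if (length(x) < min_tail)
    stop("too few tail points for a power-law fit")
  x_max <- x[length(x)]
  cand <- unique(quantile(x, probs = seq(0, 0.9, length.out = n_candidates),
                          names = FALSE, type = 1))
  cand <- cand[vapply(cand, function(c) sum(x >= c), 0L) >= min_tail]
  best <- NULL
  for (xm in cand) {
    tail_x <- x[x >= xm]
    opt <- optimize(plaw_loglik, c(1.000001, 20), x = tail_x, x_min = xm,
                    x_max = x_max, maximum = TRUE)
    a <- opt$maximum
    ks <- max(abs(plaw_cdf(tail_x, a, xm, x_max) -
                  (seq_along(tail_x) - 0.5) / length(tail_x)))
    if (is.null(best) || ks < best$ks)
      best <- list(a = a, xm = xm, ks = ks, n = length(tail_x))
  }
  new_powerlaw_fit(-best$a, best$xm, x_max, upper_trim_fraction, best$ks,
                   best$n)
}

#' Fit a log-normal distribution by maximum likelihood
#'
#' MLE on the log scale; zero values are excluded (their count is
#' reported).  Goodness of fit is summarized by the Kolmogorov-Smirnov
#' distance to the fitted log-normal.
#'
#' @param samples non-negative sample (all-zero input is an error).
#' @return A list with `mu`, `sigma`, `ks_distance`, `n`, `n_zero`.
#' @export
fit_lognormal <- function(samples) {
  n_zero <- sum(samples <= 0)
  x <- samples[samples > 0]
  if (length(x) == 0) stop("no positive samples for a log-normal fit")
  l <- log(x)
  mu <- mean(l)
  sigma <- sqrt(mean((l - mu)^2))
  ks <- if (sigma > 0) {
    xs <- sort(x)
    max(abs(plnorm(xs, mu, sigma) - (seq_along(xs) - 0.5) / length(xs)))
  } else NA_real_
  list(mu = mu, sigma = sigma, ks_distance = ks, n = length(x),
       n_zero = n_zero)
}
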