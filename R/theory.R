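#' Mean-field results for the plastic two-neuron models
#'
#' Closed-form and semi-analytic predictions for the reduced delta-synapse
#' models: the delay caused by an inhibitory spike, the stationary weight
#' of an inhibitory synapse under Hebbian inhibitory STDP, the resulting
#' postsynaptic rate, and the average STDP drift on an excitatory synapse
#' as a function of its weight.  Weights here are in mV (delta-synapse
#' convention of the derivations), distinct from the network's
#' dimensionless weights; times are in ms and rates in Hz unless noted.
#'
#' @name meanfield
#' @keywords internal
NULL

#' Average delay of the postsynaptic spike caused by one inhibitory spike
#'
#' Under a near-linear rise of the membrane potential, one inhibitory
#' delta PSP of strength `w` delays the next postsynaptic spike by
#' `w / (nu_0 (V_thres - V_rest))`.
#'
#' @param w inhibitory weight (mV).
#' @param nu_0 postsynaptic rate without the inhibitory synapse (Hz).
#' @param delta_v threshold-to-rest distance `V_thres - V_rest` (mV).
#' @return Delay in seconds.
#' @export
#' @examples
#' inhibitory_delay(1, 5, 10) # 0.02 s
inhibitory_delay <- function(w, nu_0, delta_v = 10) {
  stopifnot(all(w >= 0), delta_v > 0)
  if (any(nu_0 <= 0)) stop("nu_0 must be positive")
  w / (nu_0 * delta_v)
}

#' Stationary inhibitory weight under inhibitory STDP
#'
#' The root of the averaged nearest-neighbour update:
#' `w_stat = nu_0 * tau * (V_thres - V_rest) * log(A_plus / A_minus)`.
#' Only the amplitude ratio enters (4 for the reference rule).
#'
#' @param nu_0 postsynaptic base rate (Hz).
#' @param tau STDP time constant (s).
#' @param delta_v `V_thres - V_rest` (mV).
#' @param A_plus,A_minus kernel amplitudes (`A_plus >= A_minus > 0` for a
#'   non-negative weight).
#' @return Stationary weight (mV).
#' @export
#' @examples
#' stationary_inhibitory_weight(5) # 5 * 0.02 * 10 * log(4) = 1.386
stationary_inhibitory_weight <- function(nu_0, tau = 0.02, delta_v = 10,
                                         A_plus = 4e-3, A_minus = 1e-3) {
  if (A_minus <= 0) stop("A_minus must be positive")
  stopifnot(all(nu_0 >= 0), tau > 0, delta_v > 0)
  nu_0 * tau * delta_v * log(A_plus / A_minus)
}

#' Average inhibitory STDP update at weight w
#'
#' The averaged nearest-neighbour weight change per presynaptic spike,
#' `nu_0 tau (1 - e^{-1/(nu_0 tau)}) (A_plus e^{-w/(nu_0 tau delta_v)} - A_minus)`,
#' whose unique root is [stationary_inhibitory_weight()].
#'
#' @inheritParams stationary_inhibitory_weight
#' @param w inhibitory weight (mV).
#' @return Average weight change per presynaptic spike.
#' @export
mean_inhibitory_dw <- function(w, nu_0, tau = 0.02, delta_v = 10,
                               A_plus = 4e-3, A_minus = 1e-3) {
  stopifnot(all(nu_0 > 0))
  nu_0 * tau * (1 - exp(-1 / (nu_0 * tau))) *
    (A_plus * exp(-w / (nu_0 * tau * delta_v)) - A_minus)
}

#' Postsynaptic rate with the stationary inhibitory synapse
#'
#' `nu(nu_0) = nu_0 / (1 + tau nu_inh log(A_plus/A_minus))`: the
#' inhibitory synapse compensates increased drive only partially, so
#' `0 < nu(nu_0 + d) - nu(nu_0) < d`.
#'
#' @inheritParams stationary_inhibitory_weight
#' @param nu_inh rate of the inhibitory presynaptic cell (Hz).
#' @return Postsynaptic rate (Hz).
#' @export
rate_with_inhibition <- function(nu_0, nu_inh, tau = 0.02,
                                 A_plus = 4e-3, A_minus = 1e-3) {
  stopifnot(all(nu_inh >= 0))
  nu_0 / (1 + tau * nu_inh * log(A_plus / A_minus))
}

#' Pair contribution of one presynaptic spike inside a postsynaptic ISI
#'
#' Closed form of the triplet integral: for a presynaptic spike uniform in
#' a postsynaptic inter-spike interval of length `T`, the net STDP change
#' integrates to
#' `A_plus tau_plus (1 - e^{-T/tau_plus}) - A_minus tau_minus (1 - e^{-T/tau_minus})`,
#' approaching the kernel-integral difference as `T -> Inf`.
#' `pair_contribution_shifted` additionally shifts the second postsynaptic
#' spike earlier by `delta` (the rate-increase correction), excluding the
#' final `delta` of the interval where the presynaptic spike would trigger
#' the postsynaptic one.
#'
#' @param T_isi postsynaptic inter-spike interval (ms).
#' @param params list with effective amplitudes `a_plus_eff`,
#'   `a_minus_eff` and time constants `tau_plus`, `tau_minus` (ms), e.g.
#'   an [stdp_params()] record.
#' @return Net weight change contributed by the triplet.
#' @export
pair_contribution <- function(T_isi, params = stdp_params()) {
  stopifnot(all(T_isi >= 0))
  ap <- params$a_plus_eff; am <- params$a_minus_eff
  tp <- params$tau_plus; tm <- params$tau_minus
  ap * tp * (1 - exp(-T_isi / tp)) - am * tm * (1 - exp(-T_isi / tm))
}

#' @rdname pair_contribution
#' @param delta backward time-shift of the second postsynaptic spike (ms).
#' @export
pair_contribution_shifted <- function(T_isi, delta, params = stdp_params()) {
  ap <- params$a_plus_eff; am <- params$a_minus_eff
  tp <- params$tau_plus; tm <- params$tau_minus
  d <- pmin(delta, T_isi / 2)
  i1p <- ap * tp * (1 - exp(-(T_isi - 2 * d) / tp))
  i1m <- am * tm * (exp(-d / tm) - exp(-(T_isi - d) / tm))
  i2p <- ap * tp * (exp(-(T_isi - d) / tp) - exp(-T_isi / tp))
  i2m <- am * tm * (1 - exp(-d / tm))
  i1p - i1m + i2p - i2m
}

#' Average backward shift of the next postsynaptic spike
#'
#' With the postsynaptic rate increasing linearly in the synaptic weight,
#' `delta_r(w) = slope * w`, the average time shift of the next
#' postsynaptic spike is `delta_r / (r (r + delta_r))`.
#'
#' @param w synaptic weight (mV).
#' @param r base postsynaptic rate (Hz).
#' @param delta_r_slope fitted rate increase per unit weight (Hz/mV).
#' @return Shift in seconds.
#' @export
postsynaptic_shift <- function(w, r, delta_r_slope) {
  stopifnot(all(r > 0))
  dr <- delta_r_slope * w
  dr / (r * (r + dr))
}

#' Membrane-potential distribution of a Poisson-driven LIF neuron
#'
#' Either an empirical normalized histogram of subthreshold membrane
#' samples (refractory samples excluded upstream), or the stationary
#' density of the LIF neuron in the diffusion approximation with mean
#' input `mu` and noise strength `sigma` (both mV):
#' `P(V) ~ exp(-(V-mu)^2/sigma^2) * Int_{(V-mu)/sigma}^{(Vthr-mu)/sigma}
#'   H(u - (Vr-mu)/sigma) e^{u^2} du`, normalized on the support grid.
#'
#' @param source `"empirical"` or `"diffusion"`.
#' @param V membrane samples (empirical mode), or `NULL`.
#' @param counts,breaks alternatively, a precomputed histogram.
#' @param mu,sigma diffusion-approximation input mean and noise (mV); for
#'   Poisson delta input of total rate R (Hz) and kick a (mV):
#'   `mu = E_L + R a tau_m`, `sigma^2 = R a^2 tau_m` (tau_m in s).
#' @param neuron a [neuron_params()] record.
#' @param n_bins number of grid bins.
#' @return An object of class `membrane_distribution`: list with bin
#'   `breaks`, `mid` points, and `density` (1/mV) integrating to 1.
#' @export
membrane_distribution <- function(source = c("empirical", "diffusion"),
                                  V = NULL, counts = NULL, breaks = NULL,
                                  mu = NULL, sigma = NULL,
                                  neuron = neuron_params(), n_bins = 200) {
  source <- match.arg(source)
  if (source == "empirical") {
    if (is.null(counts)) {
      if (is.null(V) || length(V) == 0) stop("empty membrane trace")
      breaks <- seq(min(V) - 1e-9, max(V) + 1e-9, length.out = n_bins + 1)
      counts <- tabulate(findInterval(V, breaks, rightmost.closed = TRUE),
                         n_bins)
    }
    widths <- diff(breaks)
    dens <- counts / sum(counts) / widths
  } else {
    stopifnot(!is.null(mu), !is.null(sigma), sigma > 0)
    lo <- min(mu - 6 * sigma, neuron$V_reset)
    breaks <- seq(lo, neuron$V_thres, length.out = n_bins + 1)
    mid <- breaks[-1] - diff(breaks) / 2
    yth <- (neuron$V_thres - mu) / sigma
    yr <- (neuron$V_reset - mu) / sigma
    dens <- vapply(mid, function(v) {
      y <- (v - mu) / sigma
      f <- function(u) exp(pmin(u^2 - y^2, 700)) * (u >= yr)
      integrate(f, max(y, yr - 20), yth, rel.tol = 1e-8,
                stop.on.error = FALSE)$value
    }, 0)
    widths <- diff(breaks)
    dens <- dens / sum(dens * widths)
  }
  mid <- breaks[-1] - diff(breaks) / 2
  structure(list(breaks = breaks, mid = mid, density = dens),
            class = "membrane_distribution")
}

#' Probability that a presynaptic spike triggers a postsynaptic one
#'
#' Mass of the membrane-potential distribution within `w` of threshold:
#' `P_fire(w) = Int_{Vthr - w}^{Vthr} P(V) dV`, evaluated on the
#' distribution's grid with partial-bin interpolation.  Monotone
#' non-decreasing in `w` and bounded by the total mass.
#'
#' @param w excitatory weight (mV).
#' @param dist a `membrane_distribution`.
#' @param V_thres threshold potential (mV).
#' @return Probability.
#' @export
fire_probability <- function(w, dist, V_thres = -50) {
  stopifnot(all(w >= 0))
  vapply(w, function(wi) {
    lo <- V_thres - wi
    b <- dist$breaks
    widths <- diff(b)
    upper <- pmin(b[-1], V_thres)
    lower <- pmax(b[-length(b)], lo)
    ov <- pmax(upper - lower, 0)
    sum(dist$density * ov)
  }, 0)
}

#' Inverse-Gaussian density
#'
#' First-passage-time density used as the ISI model of a Poisson-driven
#' LIF neuron: `IG(mu, lambda)` with mean `mu` and shape `lambda`.
#'
#' @param x quantiles (> 0).
#' @param mu mean.
#' @param lambda shape.
#' @return Density values.
#' @export
dinvgauss <- function(x, mu, lambda) {
  stopifnot(mu > 0, lambda > 0)
  out <- numeric(length(x))
  ok <- x > 0
  out[ok] <- sqrt(lambda / (2 * pi * x[ok]^3)) *
    exp(-lambda * (x[ok] - mu)^2 / (2 * mu^2 * x[ok]))
  out
}

qinvgauss_upper <- function(p_tail, mu, lambda) {
  # small upper-quantile solver by bisection on the integrated density
  f <- function(q) integrate(dinvgauss, 0, q, mu = mu, lambda = lambda,
                             rel.tol = 1e-9)$value - (1 - p_tail)
  hi <- mu
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(mu * 1e-3, hi), tol = mu * 1e-6)$root
}

#' Average STDP drift on an excitatory synapse
#'
#' Semi-analytic estimate of the expected weight change per presynaptic
#' spike as a function of the (frozen) synaptic weight `w`: the shifted
#' triplet contribution averaged over an inverse-Gaussian ISI
#' distribution, plus the direct-trigger term
#' `P_fire(w) * A_plus e^{-tau_syn/tau_plus}`:
#' `E dw(w) = nu Int_0^Inf P(T) dw(T, shift(w)) dT + P_fire(w) STDP+(tau_syn)`.
#' The factor `nu` converts the ISI-averaged triplet integral into a
#' per-presynaptic-spike quantity: a Poisson presynaptic spike falls into a
#' postsynaptic inter-spike interval of length `T` with length-biased
#' probability `T P(T) / mu` and lands uniformly inside it, so the
#' kernel integral over the interval is weighted by `P(T)/mu = nu P(T)`.
#' Depression dominates at `w = 0`; the backward shift of the next
#' postsynaptic spike and the direct triggering make the drift positive
#' above a threshold weight.
#'
#' @param w weight grid (mV).
#' @param rate base postsynaptic rate (Hz).
#' @param delta_r_slope fitted rate-increase slope (Hz/mV).
#' @param dist a `membrane_distribution` of the postsynaptic cell.
#' @param params [stdp_params()] record (effective amplitudes).
#' @param lambda inverse-Gaussian shape (s); default `0.75 / rate`, the
#'   midpoint of the insensitivity range `[0.5/rate, 1/rate]`.
#' @param tau_syn synaptic delay (ms); defaults to the engine step 0.1 ms.
#' @param V_thres threshold potential (mV).
#' @param rel_tol quadrature tolerance.
#' @param trigger_depression also count the depression pairing of the
#'   triggering presynaptic spike with the *previous* postsynaptic spike,
#'   `-P_fire(w) A_minus E_T[exp(-T/tau_minus)]`.  This pairing is real in
#'   any nearest-neighbour accounting but is partially offset by
#'   position-voltage correlations that the uniform-position pair integral
#'   also neglects; it is negligible when the mean ISI is long compared
#'   with the STDP time constant.  Off by default (the plain estimate);
#'   see the methods vignette for when to enable it.
#' @return Expected weight change per presynaptic spike, per grid point.
#' @export
expected_weight_change <- function(w, rate, delta_r_slope, dist,
                                   params = stdp_params(),
                                   lambda = 0.75 / rate, tau_syn = 0.1,
                                   V_thres = -50, rel_tol = 1e-6,
                                   trigger_depression = FALSE) {
  stopifnot(rate > 0, lambda > 0)
  mu_s <- 1 / rate                     # mean ISI in s
  t_max <- qinvgauss_upper(1e-6, mu_s, lambda) * 1000 # ms
  mean_exp_T <- if (trigger_depression) {
    integrate(function(T_ms) dinvgauss(T_ms / 1000, mu_s, lambda) / 1000 *
                exp(-T_ms / params$tau_minus),
              0, t_max, rel.tol = rel_tol)$value
  } else 0
  vapply(w, function(wi) {
    shift_ms <- postsynaptic_shift(wi, rate, delta_r_slope) * 1000
    f <- function(T_ms)
      dinvgauss(T_ms / 1000, mu_s, lambda) / 1000 *
        pair_contribution_shifted(T_ms, shift_ms, params)
    pair_term <- integrate(f, 0, t_max, rel.tol = rel_tol,
                           subdivisions = 500L)$value
    trigger <- fire_probability(wi, dist, V_thres) *
      (params$a_plus_eff * exp(-tau_syn / params$tau_plus) -
         params$a_minus_eff * mean_exp_T)
    rate / 1000 * pair_term + trigger
  }, 0)
}

#' Stationary rate of a LIF neuron in the diffusion approximation
#'
#' First-passage rate
#' `1/nu = tau_ref + tau_m sqrt(pi) Int_{(Vr-mu)/sigma}^{(Vthr-mu)/sigma}
#'   e^{u^2} (1 + erf(u)) du`.
#'
#' @inheritParams membrane_distribution
#' @return Rate in Hz.
#' @export
lif_rate_diffusion <- function(mu, sigma, neuron = neuron_params()) {
  stopifnot(sigma > 0)
  a <- (neuron$V_reset - mu) / sigma
  b <- (neuron$V_thres - mu) / sigma
  # e^{u^2} (1 + erf(u)) = erfcx(-u), numerically stable for u << 0
  i <- integrate(function(u) pracma::erfcx(-u), a, b, rel.tol = 1e-9)$value
  1 / (neuron$tau_ref / 1000 + neuron$tau_m / 1000 * sqrt(pi) * i)
}
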