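#' Neuron, synapse and plasticity parameter sets
#'
#' Constructors for the parameter records used throughout the package.  The
#' defaults are the reference values of the model: a leaky
#' integrate-and-fire neuron with a 20 ms membrane time constant, resting
#' and reset potential -60 mV, threshold -50 mV and a 2 ms refractory
#' period; current-based exponential synapses with time constants 5 ms
#' (excitation) and 10 ms (inhibition) and current normalization factors
#' +1 mV and -9 mV, giving unit-weight EPSP/IPSP peaks of about 0.16 mV and
#' -2.25 mV.
#'
#' @param tau_m membrane time constant (ms).
#' @param E_L leak (resting) potential (mV).
#' @param V_thres spiking threshold (mV).
#' @param V_reset reset potential (mV).
#' @param tau_ref absolute refractory period (ms).
#' @return `neuron_params()`: a named list of class `neuron_params`.
#' @export
#' @examples
#' neuron_params()
neuron_params <- function(tau_m = 20, E_L = -60, V_thres = -50,
                          V_reset = -60, tau_ref = 2) {
  stopifnot(tau_m > 0, tau_ref >= 0, V_reset <= E_L, E_L < V_thres)
  structure(list(tau_m = tau_m, E_L = E_L, V_thres = V_thres,
                 V_reset = V_reset, tau_ref = tau_ref),
            class = "neuron_params")
}

#' @rdname neuron_params
#' @param tau_e,tau_i synaptic time constants (ms).
#' @param c_e_norm,c_i_norm current normalization factors (mV).  The
#'   inhibitory factor is stored with its negative sign; the membrane
#'   equation uses its magnitude with hyperpolarizing effect (calibrated so
#'   that the unit-weight IPSP peaks at -2.25 mV).
#' @param w_e_max,w_i_max maximal dimensionless weights of plastic
#'   excitatory and inhibitory synapses.
#' @return `synapse_params()`: a named list of class `synapse_params`.
#' @export
synapse_params <- function(tau_e = 5, tau_i = 10, c_e_norm = 1,
                           c_i_norm = -9, w_e_max = 20, w_i_max = 5) {
  stopifnot(tau_e > 0, tau_i > 0, c_e_norm > 0, c_i_norm < 0,
            w_e_max > 0, w_i_max > 0)
  structure(list(tau_e = tau_e, tau_i = tau_i, c_e_norm = c_e_norm,
                 c_i_norm = c_i_norm, w_e_max = w_e_max, w_i_max = w_i_max),
            class = "synapse_params")
}

#' STDP rule parameters
#'
#' Parameters of an exponential-kernel STDP rule with all-to-all spike
#' pairing.  A pairing with `t_post - t_pre > 0` potentiates by
#' `A_plus(w) * exp(-dt/tau_plus)`; a pairing with `t_post - t_pre <= 0`
#' depresses by `A_minus(w) * exp(dt/tau_minus)` (zero lag belongs to the
#' depression branch).  For the additive rule both amplitudes are constant
#' and -- when `effective_scaling` is `TRUE`, the convention used for all
#' network simulations -- multiplied by the maximal weight of the
#' connection class to obtain their effective values.  The partly
#' multiplicative variant keeps additive potentiation but scales depression
#' proportionally to the current weight; the fully multiplicative variant
#' additionally scales potentiation by `(1 - w/w_max)`.
#'
#' Defaults are the excitatory-excitatory rule: `A_plus = 1e-3`,
#' `A_minus = 1.05e-3` (depression-dominated kernel), `tau = 20` ms.  The
#' inhibitory-excitatory rule uses `A_minus = 1e-3`, `A_plus = 4e-3`
#' (potentiation-dominated) with `w_max = 5`; see [stdp_params_inhibitory()].
#'
#' @param A_plus,A_minus base LTP/LTD amplitudes (dimensionless).
#' @param tau_plus,tau_minus kernel time constants (ms).
#' @param mode `"additive"`, `"partly_multiplicative"` or
#'   `"fully_multiplicative"`.
#' @param w_max maximal weight of the connection class.
#' @param effective_scaling multiply additive amplitudes by `w_max`.
#' @return A named list of class `stdp_params` with the effective
#'   amplitudes in `a_plus_eff`, `a_minus_eff`.
#' @export
#' @examples
#' stdp_params()                 # E-E rule
#' stdp_params_inhibitory()      # I-E rule
stdp_params <- function(A_plus = 1e-3, A_minus = 1.05e-3,
                        tau_plus = 20, tau_minus = 20,
                        mode = c("additive", "partly_multiplicative",
                                 "fully_multiplicative"),
                        w_max = 20, effective_scaling = TRUE) {
  mode <- match.arg(mode)
  stopifnot(A_plus >= 0, A_minus >= 0, tau_plus > 0, tau_minus > 0, w_max > 0)
  scale <- if (mode == "additive" && !effective_scaling) 1 else w_max
  # in the multiplicative modes the engine divides by w_max again where the
  # rule is weight-proportional, so A_minus_eff * (w/w_max) = A_minus * w
  a_plus_eff <- if (mode == "additive") A_plus * scale else A_plus
  a_minus_eff <- if (mode == "additive") A_minus * scale else A_minus * w_max
  structure(list(A_plus = A_plus, A_minus = A_minus,
                 tau_plus = tau_plus, tau_minus = tau_minus, mode = mode,
                 w_max = w_max, effective_scaling = effective_scaling,
                 a_plus_eff = a_plus_eff, a_minus_eff = a_minus_eff),
            class = "stdp_params")
}

#' @rdname stdp_params
#' @export
stdp_params_inhibitory <- function(A_minus = 1e-3, A_plus = 4 * A_minus,
                                   tau_plus = 20, tau_minus = 20,
                                   w_max = 5, effective_scaling = TRUE) {
  stdp_params(A_plus = A_plus, A_minus = A_minus, tau_plus = tau_plus,
              tau_minus = tau_minus, mode = "additive", w_max = w_max,
              effective_scaling = effective_scaling)
}

#' Plasticity configuration for network simulations
#'
#' Bundles the STDP rules and the homeostatic mechanism used by
#' [run_simulation()].  Homeostasis acts on the incoming
#' excitatory-excitatory weights of each excitatory cell, either as
#' multiplicative weight normalization to a fixed per-synapse mean (applied
#' every `norm_interval` ms) or as slow synaptic scaling
#' `dw/dt = -gamma (nu - nu_0) w^2` with the rate `nu` estimated over a
#' trailing window.
#'
#' @param ee_stdp,ie_stdp enable STDP at E-E / I-E connections.
#' @param ee,ie [stdp_params()] records for the two plastic classes.
#' @param homeostasis `"normalization"`, `"scaling"`, or `"none"`.
#' @param norm_interval normalization cadence (ms).
#' @param norm_target target per-synapse mean weight.
#' @param gamma scaling learning rate (1/(Hz s) in weight units).
#' @param nu_0 scaling target rate (Hz).
#' @param scale_interval scaling-step cadence (ms).
#' @param rate_window sliding window for the rate estimate (s).
#' @return A named list of class `plasticity_config`.
#' @export
plasticity_config <- function(ee_stdp = TRUE, ie_stdp = TRUE,
                              ee = stdp_params(),
                              ie = stdp_params_inhibitory(),
                              homeostasis = c("normalization", "scaling",
                                              "none"),
                              norm_interval = 100, norm_target = 1,
                              gamma = 1e-6, nu_0 = 0,
                              scale_interval = 50, rate_window = 100) {
  homeostasis <- match.arg(homeostasis)
  stopifnot(norm_interval > 0, scale_interval > 0, rate_window > 0,
            gamma >= 0, nu_0 >= 0)
  structure(list(ee_stdp = isTRUE(ee_stdp), ie_stdp = isTRUE(ie_stdp),
                 ee = ee, ie = ie, homeostasis = homeostasis,
                 norm_interval = norm_interval, norm_target = norm_target,
                 gamma = gamma, nu_0 = nu_0,
                 scale_interval = scale_interval, rate_window = rate_window),
            class = "plasticity_config")
}

#' External drive specification
#'
#' Constant mode depolarizes every cell by a fixed amount (the relaxation
#' target becomes `E_L + depolarization`); Poisson mode feeds each cell an
#' independent external Poisson train through a unit-weight excitatory
#' synapse.  The default Poisson rate 2200 Hz matches the mean current of
#' the 11 mV constant drive: rate = depolarization / (c_e * tau_e).
#'
#' @param mode `"constant"`, `"poisson"` or `"none"`.
#' @param depolarization constant depolarization (mV).
#' @param rate external Poisson rate per neuron (Hz).
#' @param weight synaptic weight of the external events.
#' @return A named list of class `drive_spec`.
#' @export
drive_spec <- function(mode = c("constant", "poisson", "none"),
                       depolarization = 11, rate = 2200, weight = 1) {
  mode <- match.arg(mode)
  stopifnot(depolarization >= 0, rate >= 0)
  structure(list(mode = mode, depolarization = depolarization,
                 rate = rate, weight = weight), class = "drive_spec")
}

#' Stimulation protocol specification
#'
#' A burst-stimulation protocol: `n_pulses` brief pulses of a very strong
#' constant current are applied to a set of target cells, separated by a
#' gap that lets the cells leave their refractory period, so that on
#' success every target fires exactly `n_pulses` spikes within
#' `(n_pulses - 1) * (pulse + gap) + epsilon` ms.
#'
#' @param target_ids 0-based ids of the stimulated cells.
#' @param pulse_duration pulse length (ms).
#' @param inter_pulse_gap gap between pulses (ms).
#' @param amplitude drive amplitude (mV-equivalent constant current); the
#'   default 1000 mV guarantees a threshold crossing within one pulse from
#'   any subthreshold potential.
#' @param n_pulses number of pulses.
#' @return A named list of class `stimulus_spec`.
#' @export
stimulus_spec <- function(target_ids, pulse_duration = 0.5,
                          inter_pulse_gap = 2, amplitude = 1000,
                          n_pulses = 2) {
  stopifnot(pulse_duration > 0, inter_pulse_gap >= 0, n_pulses >= 1,
            amplitude > 0)
  structure(list(target_ids = as.integer(target_ids),
                 pulse_duration = pulse_duration,
                 inter_pulse_gap = inter_pulse_gap,
                 amplitude = amplitude, n_pulses = as.integer(n_pulses)),
            class = "stimulus_spec")
}

#' Distance-dependent connectivity profile
#'
#' Gaussian connection-probability profile on the unit torus:
#' `P(d) = epsilon * exp(-d^2 / (2 sigma^2))`.
#'
#' @param epsilon peak connection probability at distance zero.
#' @param sigma length scale (torus units).
#' @return A named list of class `connectivity_profile`.
#' @export
#' @examples
#' connectivity_profile(0.2, 0.1)   # excitatory profile
#' connectivity_profile(0.8, 0.05)  # inhibitory profile
connectivity_profile <- function(epsilon, sigma) {
  stopifnot(epsilon >= 0, epsilon <= 1, sigma > 0)
  structure(list(epsilon = epsilon, sigma = sigma),
            class = "connectivity_profile")
}
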