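#' Closed-form peak of a unit postsynaptic potential
#'
#' Peak membrane deflection of a LIF neuron in response to a single
#' presynaptic spike through a current-based exponential synapse of weight
#' `w`: the response is
#' `dV(t) = w |c| (tau_s / (tau_m - tau_s)) (exp(-t/tau_m) - exp(-t/tau_s))`
#' peaking at `t* = tau_m tau_s / (tau_m - tau_s) * log(tau_m / tau_s)`.
#' With the default parameters the unit-weight EPSP peaks at 0.157 mV and
#' the unit-weight IPSP at -2.25 mV.  In the degenerate limit
#' `tau_s = tau_m` the alpha-function peak `w |c| e^{-1}` is used.
#'
#' @param kind `"excitatory"` or `"inhibitory"`.
#' @param w synaptic weight (>= 0).
#' @param neuron a [neuron_params()] record.
#' @param synapse a [synapse_params()] record.
#' @return Peak deflection in mV (negative for inhibitory).
#' @export
#' @examples
#' psp_peak_amplitude("excitatory", 1) # ~0.157
#' psp_peak_amplitude("inhibitory", 1) # -2.25
psp_peak_amplitude <- function(kind = c("excitatory", "inhibitory"), w = 1,
                               neuron = neuron_params(),
                               synapse = synapse_params()) {
  kind <- match.arg(kind)
  stopifnot(w >= 0)
  tau_m <- neuron$tau_m
  tau_s <- if (kind == "excitatory") synapse$tau_e else synapse$tau_i
  cmag <- abs(if (kind == "excitatory") synapse$c_e_norm else synapse$c_i_norm)
  peak <- if (tau_s == tau_m) {
    w * cmag * exp(-1)
  } else {
    t_star <- tau_m * tau_s / (tau_m - tau_s) * log(tau_m / tau_s)
    w * cmag * (tau_s / (tau_m - tau_s)) *
      (exp(-t_star / tau_m) - exp(-t_star / tau_s))
  }
  if (kind == "inhibitory") -peak else peak
}

new_spike_record <- function(time, neuron, n_e, n_i, duration) {
  structure(data.frame(time = time, neuron = as.integer(neuron)),
            n_e = as.integer(n_e), n_i = as.integer(n_i),
            duration = duration, class = c("spike_record", "data.frame"))
}

new_network_state <- function(V, g_e, g_i, refractory, t, dt) {
  structure(list(V = V, g_e = g_e, g_i = g_i,
                 refractory = refractory, # remaining steps
                 t = t, dt = dt),
            class = "network_state")
}

#' Initial network state
#'
#' Membrane potentials drawn uniformly between the reset and the threshold
#' potential; synaptic traces and refractory timers zero.
#'
#' @param topology a [topology] object.
#' @param neuron a [neuron_params()] record.
#' @param dt integration step (ms).
#' @param seed integer seed.
#' @return A `network_state` object.
#' @export
init_network_state <- function(topology, neuron = neuron_params(), dt = 0.1,
                               seed = NULL) {
  n <- topology$n_e + topology$n_i
  with_seed(seed, {
    V <- runif(n, neuron$V_reset, neuron$V_thres)
    new_network_state(V, numeric(n), numeric(n), integer(n), 0, dt)
  })
}

#' Simulate the network
#'
#' Clock-driven simulation of the LIF network with current-based
#' exponential synapses.  Over each step of length `dt` the linear
#' `(V, g_e, g_i)` subsystem is propagated exactly; threshold crossings are
#' detected after the update, spiking cells are reset and clamped for the
#' refractory period, and emitted spikes increment the postsynaptic traces
#' of their targets by the synaptic weight at the end of the step (one-step
#' transmission delay).  Optional plasticity hooks implement all-to-all
#' STDP at E-E and I-E connections, postsynaptic weight normalization, and
#' slow synaptic scaling.
#'
#' @param topology a [topology] object.
#' @param drive a [drive_spec()].
#' @param duration simulated time (ms).
#' @param dt integration step (ms).
#' @param plasticity a [plasticity_config()] or `NULL` for a static run.
#' @param neuron,synapse parameter records.
#' @param init_state a `network_state` to continue from (`NULL` draws a
#'   fresh uniform initial state).
#' @param stimulus optional [stimulus_spec()]; `stimulus_onset` is its
#'   start time relative to the beginning of this run (ms).
#' @param stimulus_onset onset of the stimulus (ms).
#' @param record list of recording options: `record_from` (absolute time
#'   from which spikes are kept, ms), `monitor_ids` (0-based ids whose
#'   membrane potential is sampled every step), `snapshot_interval` (ms;
#'   cadence of E-E weight snapshots), `summary_interval` (ms; cadence of
#'   the weight/rate trajectory summary), `rate_ceiling` (Hz; abort the run
#'   if the 10-s mean excitatory rate exceeds it).
#' @param seed integer seed.
#' @return A list with elements `spikes` (a `spike_record`), `topology`
#'   (with final weights), `state`, `spike_count` (per neuron), `summary`
#'   (trajectory data frame), `snapshots`, `snapshot_times`, `monitor_V`,
#'   and `aborted`.
#' @export
#' @examples
#' topo <- build_random_topology(80, 20, 0.05, seed = 1)
#' sim <- run_simulation(topo, drive_spec(), duration = 1000, seed = 1)
#' mean(firing_rates(sim$spikes, c(0, 1000))[1:80]) # excitatory rate (Hz)
run_simulation <- function(topology, drive = drive_spec(), duration,
                           dt = 0.1, plasticity = NULL,
                           neuron = neuron_params(),
                           synapse = synapse_params(),
                           init_state = NULL, stimulus = NULL,
                           stimulus_onset = 0,
                           record = list(), seed = NULL) {
  stopifnot(inherits(topology, "topology"), duration >= 0, dt > 0)
  with_seed(seed, {
    if (is.null(init_state))
      init_state <- init_network_state(topology, neuron, dt)
    fl <- flatten_edges(topology)
    plast <- if (is.null(plasticity)) list() else list(
      enabled = TRUE,
      ee = list(on = plasticity$ee_stdp,
                a_plus_eff = plasticity$ee$a_plus_eff,
                a_minus_eff = plasticity$ee$a_minus_eff,
                tau_plus = plasticity$ee$tau_plus,
                tau_minus = plasticity$ee$tau_minus,
                mode = match(plasticity$ee$mode,
                             c("additive", "partly_multiplicative",
                               "fully_multiplicative")) - 1L),
      ie = list(on = plasticity$ie_stdp,
                a_plus_eff = plasticity$ie$a_plus_eff,
                a_minus_eff = plasticity$ie$a_minus_eff,
                tau_plus = plasticity$ie$tau_plus,
                tau_minus = plasticity$ie$tau_minus),
      homeostasis = plasticity$homeostasis,
      norm_interval = plasticity$norm_interval,
      norm_target = plasticity$norm_target,
      gamma = plasticity$gamma, nu_0 = plasticity$nu_0,
      scale_interval = plasticity$scale_interval,
      rate_window = plasticity$rate_window)
    stim <- if (is.null(stimulus)) list() else list(
      target_ids = stimulus$target_ids,
      onset = init_state$t + stimulus_onset,
      pulse_duration = stimulus$pulse_duration,
      inter_pulse_gap = stimulus$inter_pulse_gap,
      amplitude = stimulus$amplitude, n_pulses = stimulus$n_pulses)
    rec <- modifyList(list(record_from = 0, snapshot_interval = 0,
                           summary_interval = 0, rate_ceiling = 0), record)

    out <- cpp_simulate(topology$n_e, topology$n_i,
                        fl$pre, fl$post, fl$w,
                        unclass(neuron), unclass(synapse), unclass(drive),
                        plast, stim,
                        init_state$V, init_state$g_e, init_state$g_i,
                        as.integer(init_state$refractory),
                        init_state$t, duration, dt, rec)

    topology <- unflatten_weights(topology, out$weights)
    summary <- as.data.frame(out$summary)
    if (nrow(summary))
      names(summary) <- c("t", "mean_ee", "var_ee", "mean_ie", "var_ie",
                          "rate_e", "rate_i")
    list(spikes = new_spike_record(out$spike_time, out$spike_id,
                                   topology$n_e, topology$n_i,
                                   out$t_end - init_state$t),
         topology = topology,
         state = new_network_state(out$V, out$g_e, out$g_i, out$refractory,
                                   out$t_end, dt),
         spike_count = out$spike_count,
         summary = summary,
         snapshots = out$snapshots,
         snapshot_times = out$snapshot_times,
         monitor_V = out$monitor_V,
         aborted = out$aborted)
  })
}

#' Apply a burst-stimulation protocol
#'
#' Runs the two-pulse (in general `n_pulses`-pulse) strong-current
#' stimulation of a target group from a given network state.  The protocol
#' only proceeds when none of the targeted cells is refractory at onset;
#' otherwise it returns `success = FALSE` and the state unchanged.
#'
#' @param state a `network_state`.
#' @param topology a [topology] object.
#' @param stimulus a [stimulus_spec()].
#' @param dt integration step (ms).
#' @param drive background drive during the protocol (the network keeps
#'   running).
#' @param neuron,synapse parameter records.
#' @param extra_duration additional time simulated after the last pulse (ms).
#' @return A list with `state`, `spikes` (all spikes during the protocol),
#'   `stimulated_spikes` (spikes of the target cells), and `success`.
#' @export
apply_stimulus_protocol <- function(state, topology, stimulus, dt = 0.1,
                                    drive = drive_spec(),
                                    neuron = neuron_params(),
                                    synapse = synapse_params(),
                                    extra_duration = 0) {
  stopifnot(inherits(state, "network_state"))
  ids <- stimulus$target_ids
  if (length(ids) > 0 && any(state$refractory[ids + 1L] > 0))
    return(list(state = state, spikes = NULL, stimulated_spikes = NULL,
                success = FALSE))
  dur <- stimulus$n_pulses *
    (stimulus$pulse_duration + stimulus$inter_pulse_gap) + extra_duration
  sim <- run_simulation(topology, drive, dur, dt, plasticity = NULL,
                        neuron = neuron, synapse = synapse,
                        init_state = state, stimulus = stimulus,
                        stimulus_onset = 0)
  stim_spk <- sim$spikes[sim$spikes$neuron %in% ids, , drop = FALSE]
  list(state = sim$state, spikes = sim$spikes,
       stimulated_spikes = stim_spk, success = TRUE)
}
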