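#' Experiment specification
#'
#' Bundles everything needed to run a plastic transient: topology recipe,
#' drive, plasticity toggles, duration and recording cadences.  The
#' reduced-scale default (800 excitatory + 200 inhibitory cells,
#' `p = 0.02`, 30 minutes of biological time) keeps the in/out-degree
#' heterogeneity that seeds the symmetry breaking while staying cheap to
#' simulate; the full reference scale (4000 + 1000, around 5 hours) is
#' available by overriding `n_e`, `n_i` and `duration_s`.
#'
#' @param name run label.
#' @param n_e,n_i population sizes.
#' @param p connection probability (ignored when `topology` is supplied).
#' @param topology optional prebuilt [topology]; otherwise an Erdos-Renyi
#'   topology is generated from the spec's seed.
#' @param drive a [drive_spec()].
#' @param plasticity a [plasticity_config()].
#' @param duration_s transient duration (s of biological time).
#' @param dt integration step (ms).
#' @param snapshot_interval_s cadence of E-E weight snapshots (s), also the
#'   spacing used by the convergence check.
#' @param summary_interval_s cadence of the weight/rate trajectory (s).
#' @param tail_s length of the spike-record tail kept for analysis (s).
#' @param ks_tol convergence tolerance on the Kolmogorov-Smirnov distance
#'   between consecutive E-E snapshots.
#' @param rate_ceiling divergence guard (Hz, sustained over 10 s).
#' @param seed master seed; component streams are derived from it.
#' @return A named list of class `experiment_spec`.
#' @export
experiment_spec <- function(name = "reduced", n_e = 800, n_i = 200,
                            p = 0.02, topology = NULL,
                            drive = drive_spec(),
                            plasticity = plasticity_config(),
                            duration_s = 1800, dt = 0.1,
                            snapshot_interval_s = 300,
                            summary_interval_s = 10,
                            tail_s = 100, ks_tol = 0.01,
                            rate_ceiling = 100, seed = 1) {
  stopifnot(duration_s >= 0, snapshot_interval_s > 0)
  structure(list(name = name, n_e = n_e, n_i = n_i, p = p,
                 topology = topology, drive = drive,
                 plasticity = plasticity, duration_s = duration_s,
                 dt = dt, snapshot_interval_s = snapshot_interval_s,
                 summary_interval_s = summary_interval_s,
                 tail_s = tail_s, ks_tol = ks_tol,
                 rate_ceiling = rate_ceiling, seed = seed),
            class = "experiment_spec")
}

ks_distance <- function(a, b) {
  all_v <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(all_v) - ecdf(b)(all_v)))
}

#' Run a plastic transient to weight equilibrium
#'
#' Simulates the plastic network until the E-E weight distribution
#' stabilizes: the run proceeds in chunks of one snapshot interval, and
#' convergence is declared when the Kolmogorov-Smirnov distance between
#' consecutive E-E weight snapshots falls below `spec$ks_tol` (or the
#' configured duration is exhausted).  A divergence guard aborts when the
#' mean excitatory rate exceeds `spec$rate_ceiling` sustained over 10 s.
#'
#' @param spec an [experiment_spec()].
#' @return A list with `topology` (equilibrium weights), `spikes` (tail of
#'   the spike record), `state`, `trajectory` (weight/rate summary),
#'   `snapshots`, `snapshot_times`, `converged`, `converged_at` (ms or
#'   `NA`), and `aborted`.
#' @export
run_transient_to_equilibrium <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  topo <- spec$topology
  if (is.null(topo))
    topo <- build_random_topology(spec$n_e, spec$n_i, spec$p,
                                  seed = derive_seed(spec$seed, "topology"))
  with_seed(derive_seed(spec$seed, "dynamics"), {
    state <- init_network_state(topo, dt = spec$dt)
    chunk_ms <- spec$snapshot_interval_s * 1000
    total_ms <- spec$duration_s * 1000
    n_chunks <- max(1, ceiling(total_ms / chunk_ms))
    snaps <- list(); snap_t <- numeric(0)
    traj <- list()
    prev_snap <- NULL
    converged <- FALSE; converged_at <- NA_real_
    aborted <- FALSE
    spikes <- NULL
    for (ch in seq_len(n_chunks)) {
      this_ms <- min(chunk_ms, total_ms - (ch - 1) * chunk_ms)
      last_chunk <- ch == n_chunks
      rec <- list(summary_interval = spec$summary_interval_s * 1000,
                  snapshot_interval = this_ms,
                  rate_ceiling = spec$rate_ceiling,
                  record_from = if (last_chunk)
                    state$t + this_ms - spec$tail_s * 1000 else
                      state$t + this_ms + 1)
      sim <- run_simulation(topo, spec$drive, this_ms, spec$dt,
                            plasticity = spec$plasticity,
                            init_state = state, record = rec)
      topo <- sim$topology; state <- sim$state
      traj[[ch]] <- sim$summary
      if (length(sim$snapshots)) {
        snaps <- c(snaps, sim$snapshots)
        snap_t <- c(snap_t, sim$snapshot_times)
        cur <- sim$snapshots[[length(sim$snapshots)]]
        if (!is.null(prev_snap) && !converged &&
            ks_distance(prev_snap, cur) < spec$ks_tol) {
          converged <- TRUE
          converged_at <- state$t
        }
        prev_snap <- cur
      }
      if (sim$aborted) {
        aborted <- TRUE
        warning(sprintf(
          "transient aborted: mean excitatory rate exceeded %g Hz",
          spec$rate_ceiling))
        spikes <- sim$spikes
        break
      }
      if (last_chunk) spikes <- sim$spikes
      if (converged && !last_chunk) {
        # finish with one more chunk to collect the spike tail
        rec$record_from <- state$t + this_ms - spec$tail_s * 1000
        sim <- run_simulation(topo, spec$drive, this_ms, spec$dt,
                              plasticity = spec$plasticity,
                              init_state = state, record = rec)
        topo <- sim$topology; state <- sim$state
        spikes <- sim$spikes
        break
      }
    }
    list(topology = topo, spikes = spikes, state = state,
         trajectory = do.call(rbind, traj),
         snapshots = snaps, snapshot_times = snap_t,
         converged = converged, converged_at = converged_at,
         aborted = aborted)
  })
}

#' Stimulate a cell group and measure the network response
#'
#' Repeats the burst-stimulation protocol on a fixed (frozen-weight)
#' equilibrium network across trials.  Before each trial the network runs
#' freely for an exponentially distributed washout (mean `washout_mean_s`),
#' re-drawn until no target cell is refractory at onset; the population
#' rate in the `window_ms` before and after the stimulus gives the
#' post/pre rate ratio, and the trial-averaged excitatory PSTH is
#' returned.
#'
#' @param topology equilibrium [topology] (weights frozen during probing).
#' @param group 0-based target ids.
#' @param protocol a [stimulus_spec()] (its `target_ids` are ignored in
#'   favour of `group`).
#' @param n_trials number of trials.
#' @param drive background drive.
#' @param state optional starting `network_state`.
#' @param washout_mean_s mean washout between trials (s).
#' @param window_ms pre/post window length (ms).
#' @param dt integration step (ms).
#' @param seed integer seed.
#' @return A list with `psth` (data frame lag/rate), `rate_ratio`
#'   (post/pre), `pre_rate`, `post_rate` (Hz), `n_trials`.
#' @export
run_driver_stimulation <- function(topology, group, protocol, n_trials = 20,
                                   drive = drive_spec(), state = NULL,
                                   washout_mean_s = 2, window_ms = 100,
                                   dt = 0.1, seed = NULL) {
  stopifnot(length(group) >= 1)
  protocol$target_ids <- as.integer(group)
  with_seed(seed, {
    if (is.null(state)) state <- init_network_state(topology, dt = dt)
    n_e <- topology$n_e
    pre_counts <- 0; post_counts <- 0
    psth_acc <- NULL
    trials_done <- 0
    while (trials_done < n_trials) {
      wash_ms <- max(200, rexp(1, 1 / (washout_mean_s * 1000)))
      wash <- run_simulation(topology, drive, wash_ms, dt,
                             init_state = state,
                             record = list(record_from =
                                             state$t + wash_ms - window_ms))
      state <- wash$state
      if (any(state$refractory[group + 1L] > 0)) next
      pre_spk <- wash$spikes[wash$spikes$neuron < n_e, , drop = FALSE]
      res <- apply_stimulus_protocol(state, topology, protocol, dt,
                                     drive = drive,
                                     extra_duration = window_ms)
      state <- res$state
      post_spk <- res$spikes[res$spikes$neuron < n_e, , drop = FALSE]
      t_on <- wash$state$t # stimulus onset time
      pre_counts <- pre_counts + nrow(pre_spk)
      post_counts <- post_counts +
        sum(post_spk$time > t_on & post_spk$time <= t_on + window_ms)
      rel <- c(pre_spk$time - t_on, post_spk$time - t_on)
      rel <- rel[rel > -window_ms & rel <= window_ms]
      h <- tabulate(pmin(ceiling(rel + window_ms), 2 * window_ms),
                    2 * window_ms)
      psth_acc <- if (is.null(psth_acc)) h else psth_acc + h
      trials_done <- trials_done + 1
    }
    win_s <- window_ms / 1000
    pre_rate <- pre_counts / n_trials / win_s / n_e
    post_rate <- post_counts / n_trials / win_s / n_e
    list(psth = data.frame(lag = seq(-window_ms + 0.5, window_ms - 0.5, 1),
                           rate = psth_acc / n_trials / 0.001 / n_e),
         rate_ratio = post_rate / max(pre_rate, .Machine$double.eps),
         pre_rate = pre_rate, post_rate = post_rate,
         n_trials = n_trials)
  })
}

#' Driver membership across realizations with fixed topology
#'
#' Repeats the plastic transient on one fixed topology while varying the
#' initial membrane potentials and the Poisson input realization, and
#' returns the relative frequency with which each excitatory cell ends up
#' in the driver group.
#'
#' @param topology fixed [topology].
#' @param n_realizations number of repeats.
#' @param spec an [experiment_spec()] providing drive, plasticity and
#'   durations (its topology/seed fields are overridden).
#' @param driver_fraction percentile used by the driver criterion.
#' @param seed master seed.
#' @return A list with `frequency` (per excitatory cell), `driver_sets`
#'   (list of 0-based id vectors), `n_realizations`.
#' @export
run_realization_ensemble <- function(topology, n_realizations, spec,
                                     driver_fraction = 0.005, seed = 1) {
  stopifnot(n_realizations >= 1)
  freq <- numeric(topology$n_e)
  sets <- vector("list", n_realizations)
  for (r in seq_len(n_realizations)) {
    sp <- spec
    sp$topology <- topology
    sp$seed <- derive_seed(seed, paste0("realization-", r))
    res <- run_transient_to_equilibrium(sp)
    d <- detect_drivers_percentile(res$topology, driver_fraction)
    sets[[r]] <- d$drivers
    freq[d$drivers + 1L] <- freq[d$drivers + 1L] + 1
  }
  list(frequency = freq / n_realizations, driver_sets = sets,
       n_realizations = n_realizations)
}

#' Stationary inhibitory weight in the two-neuron model
#'
#' Simulates the reduced pair -- two integrate-and-fire cells driven by
#' Poisson input, connected by a plastic inhibitory delta synapse with
#' nearest-neighbour Hebbian STDP -- for a grid of postsynaptic base rates
#' and returns the time-averaged late weight together with the closed-form
#' prediction `nu_0 tau delta_v log(A_plus/A_minus)`.
#'
#' @param nu0_grid postsynaptic base rates (Hz).
#' @param duration_s simulated time per trial (s).
#' @param n_trials trials per rate.
#' @param nu_pre presynaptic (inhibitory) rate (Hz).
#' @param kick Poisson input kick size (mV); small kicks approach the
#'   linear-rise regime of the derivation.
#' @param delta_v threshold-to-rest distance (mV).
#' @param A_plus,A_minus effective kernel amplitudes (mV).
#' @param tau_ms STDP time constant (ms).
#' @param w_init initial weight (mV), `w_cap` weight cap (mV).
#' @param w_cap maximal weight (mV).
#' @param tail_frac fraction of the run averaged for the stationary value.
#' @param seed integer seed.
#' @return Data frame with columns `nu0`, `w_mean`, `w_sd`, `analytic`.
#' @export
run_two_neuron_inhibitory <- function(nu0_grid, duration_s = 500,
                                      n_trials = 3, nu_pre = 5,
                                      kick = 0.05, delta_v = 10,
                                      A_plus = 0.02, A_minus = 0.005,
                                      tau_ms = 20, w_init = 1, w_cap = 10,
                                      tail_frac = 0.2, seed = NULL) {
  stopifnot(all(nu0_grid > 0))
  with_seed(seed, {
    rows <- lapply(nu0_grid, function(nu0) {
      ws <- vapply(seq_len(n_trials), function(i)
        cpp_two_neuron_inhibitory(nu0, nu_pre, duration_s, 0.1, kick,
                                  w_init, w_cap, A_plus, A_minus, tau_ms,
                                  delta_v, 0, tail_frac)$w_stationary, 0)
      data.frame(nu0 = nu0, w_mean = mean(ws), w_sd = sd(ws),
                 analytic = stationary_inhibitory_weight(
                   nu0, tau_ms / 1000, delta_v, A_plus, A_minus))
    })
    do.call(rbind, rows)
  })
}

#' Fan-in synaptic competition under STDP with normalization
#'
#' Many Poisson inputs converge onto one LIF cell through plastic
#' excitatory synapses with all-to-all STDP and postsynaptic weight
#' normalization.  A subgroup of "fast" inputs fires at a higher rate and
#' is expected to win the competition over the limited total weight.
#'
#' @param n_syn number of converging synapses.
#' @param fast_ids 0-based indices of the fast inputs.
#' @param fast_rate,slow_rate input rates (Hz).
#' @param duration_s simulated time (s).
#' @param drive constant background depolarization of the postsynaptic
#'   cell (mV).  The default 9 mV keeps the relaxation target 1 mV below
#'   threshold, so spiking is fluctuation-driven as in the balanced
#'   network and causal input-output pairings can express themselves;
#'   with a suprathreshold drive the cell fires regardless of its inputs
#'   and the depression-dominated kernel makes every plastic synapse
#'   decay.
#' @param ee [stdp_params()] of the synapses.
#' @param norm_interval normalization cadence (ms).
#' @param record_every_s weight-trajectory cadence (s).
#' @param seed integer seed.
#' @return A list with `w_final`, `trajectory` (matrix: time + weights),
#'   `post_rate`, `fast_ids`.
#' @export
run_fan_in_competition <- function(n_syn = 80, fast_ids = 0:9,
                                   fast_rate = 25, slow_rate = 5,
                                   duration_s = 500, drive = 9,
                                   ee = stdp_params(),
                                   norm_interval = 100,
                                   record_every_s = 10, seed = NULL) {
  stopifnot(all(fast_ids >= 0), all(fast_ids < n_syn))
  nrn <- neuron_params(); syn <- synapse_params()
  rates <- rep(slow_rate, n_syn)
  rates[fast_ids + 1L] <- fast_rate
  with_seed(seed, {
    out <- cpp_fan_in(rates, duration_s, 0.1, drive,
                      nrn$tau_m, nrn$E_L, nrn$V_thres, nrn$V_reset,
                      nrn$tau_ref, syn$tau_e, syn$c_e_norm,
                      ee$a_plus_eff, ee$a_minus_eff, ee$tau_plus,
                      ee$tau_minus, ee$w_max, 1, norm_interval, 1,
                      record_every_s)
    list(w_final = out$w_final, trajectory = out$trajectory,
         post_rate = out$post_rate, fast_ids = fast_ids)
  })
}

#' Average STDP drift on a frozen excitatory synapse (Monte Carlo)
#'
#' Two LIF cells driven by Poisson delta input (1650 synapses at 1 Hz,
#' 0.5 mV each by default), connected by a frozen delta synapse of
#' strength `w`.  STDP updates (nearest-neighbour pairing, E-E kernel) are
#' accumulated without being applied; the run is repeated and the mean and
#' SD of the accumulated change per presynaptic spike are returned for
#' each `w`.  The baseline (`w = 0`) runs also collect the subthreshold
#' membrane histogram of the postsynaptic cell and the base rate; the
#' linear rate-increase slope is fitted from the measured rates.
#'
#' @param w_grid weight grid (mV).
#' @param duration_s duration per repeat (s).
#' @param n_repeats repeats per grid point.
#' @param n_inputs,in_rate,in_w Poisson input configuration.
#' @param ee [stdp_params()] record of the synapse's STDP rule.
#' @param neuron a [neuron_params()] record.
#' @param seed integer seed.
#' @return A list with `sweep` (data frame: w, dw_mean, dw_sd, rate_post),
#'   `rate0` (base rate, Hz), `delta_r_slope` (Hz/mV), and `dist`
#'   (baseline `membrane_distribution`).
#' @export
run_two_neuron_excitatory_dw <- function(w_grid, duration_s = 500,
                                         n_repeats = 10, n_inputs = 1650,
                                         in_rate = 1, in_w = 0.5,
                                         ee = stdp_params(),
                                         neuron = neuron_params(),
                                         seed = NULL) {
  with_seed(seed, {
    hist_lo <- neuron$E_L - 15
    hist_bins <- 400L
    hist_acc <- numeric(hist_bins)
    isi_mu <- numeric(0); isi_va <- numeric(0)
    run1 <- function(wi) cpp_two_neuron_excitatory(
      wi, duration_s, 0.1, n_inputs, in_rate, in_w,
      neuron$tau_m, neuron$E_L, neuron$V_thres, neuron$V_reset,
      neuron$tau_ref, ee$a_plus_eff, ee$a_minus_eff, ee$tau_plus,
      hist_lo, neuron$V_thres, hist_bins)
    rows <- lapply(w_grid, function(wi) {
      dws <- numeric(n_repeats); rates <- numeric(n_repeats)
      for (r in seq_len(n_repeats)) {
        out <- run1(wi)
        dws[r] <- out$dw_total / max(out$n_pre, 1)
        rates[r] <- out$rate_post
        if (wi == 0) {
          hist_acc <<- hist_acc + out$hist
          isi_mu <<- c(isi_mu, out$isi_mean)
          isi_va <<- c(isi_va, out$isi_var)
        }
      }
      data.frame(w = wi, dw_mean = mean(dws), dw_sd = sd(dws),
                 rate_post = mean(rates))
    })
    sweep <- do.call(rbind, rows)
    if (!any(w_grid == 0)) { # ensure a baseline for rate0 and P(V)
      out <- run1(0)
      hist_acc <- out$hist
      isi_mu <- out$isi_mean; isi_va <- out$isi_var
      rate0 <- out$rate_post
    } else {
      rate0 <- sweep$rate_post[sweep$w == 0]
    }
    breaks <- seq(hist_lo, neuron$V_thres, length.out = hist_bins + 1)
    dist <- membrane_distribution("empirical", counts = hist_acc,
                                  breaks = breaks)
    fit <- lm(I(rate_post - rate0) ~ 0 + w, data = sweep)
    # inverse-Gaussian shape fitted by moments: Var = mu^3 / lambda
    mu_s <- mean(isi_mu) / 1000
    lambda_fit <- mu_s^3 / (mean(isi_va) / 1e6)
    list(sweep = sweep, rate0 = rate0,
         delta_r_slope = unname(coef(fit)[1]),
         isi_mean_s = mu_s, isi_cv = sqrt(mean(isi_va)) / mean(isi_mu),
         lambda_fit = lambda_fit, dist = dist)
  })
}
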