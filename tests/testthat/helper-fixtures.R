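# Shared fixtures and a cross-file cache for expensive simulation runs.
# Heavy equilibrium networks are computed once per test session and reused
# by several test files.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) assign(key, expr, envir = .run_cache)
  get(key, envir = .run_cache)
}

# minimal topology built by hand: explicit edge lists, global 0-based ids
micro_topology <- function(n_e, n_i, ee = NULL, ei = NULL, ie = NULL,
                           ii = NULL) {
  mk <- function(x) {
    if (is.null(x)) return(drivernet:::edge_df(integer(0), integer(0)))
    drivernet:::edge_df(x[[1]], x[[2]], if (length(x) >= 3) x[[3]] else 1)
  }
  drivernet:::new_topology(n_e, n_i,
                           list(ee = mk(ee), ei = mk(ei), ie = mk(ie),
                                ii = mk(ii)))
}

# fresh state with all potentials at a given value (default: rest)
quiet_state <- function(n, V = -60, dt = 0.1) {
  drivernet:::new_network_state(rep(V, n), numeric(n), numeric(n),
                                integer(n), 0, dt)
}

# reduced-scale plastic equilibrium (the reference study condition:
# 800 E + 200 I, p = 0.02, 30 min biological time)
reduced_equilibrium <- function(seed) {
  cached(paste0("eq", seed), run_transient_to_equilibrium(
    experiment_spec(seed = seed)))
}

# brute-force all-to-all pair-sum oracle for STDP (additive, no clipping)
stdp_pair_sum_oracle <- function(pre, post, params) {
  dw <- 0
  for (tp in pre) for (to in post) dw <- dw + pair_delta_w(to - tp, 1, params)
  dw
}

simulate_single_psp <- function(w, kind = "excitatory") {
  # neuron 1 receives one spike from neuron 0 (forced by a strong pulse)
  if (kind == "excitatory") {
    topo <- micro_topology(2, 0, ee = list(0L, 1L, w))
    mon <- 1L
  } else {
    topo <- micro_topology(1, 1, ie = list(1L, 0L, w))
    mon <- 0L
    topo$edges$ie$pre <- 1L
  }
  stim_id <- if (kind == "excitatory") 0L else 1L
  sim <- run_simulation(topo, drive_spec("none"), 150, 0.1,
                        init_state = quiet_state(2),
                        stimulus = stimulus_spec(stim_id, n_pulses = 1),
                        record = list(monitor_ids = mon))
  v <- sim$monitor_V[, 1] + 60
  if (kind == "excitatory") max(v) else min(v)
}
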