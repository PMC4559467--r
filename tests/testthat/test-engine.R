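test_that("numerical trajectory matches the analytic LIF solution", {
  # subthreshold constant drive: V(t) = V_inf + (V0 - V_inf) exp(-t/tau_m)
  topo <- micro_topology(1, 0)
  st <- quiet_state(1, V = -60)
  sim <- run_simulation(topo, drive_spec("constant", 5), 100, 0.1,
                        init_state = st, record = list(monitor_ids = 0L))
  t <- (0:1000) * 0.1
  v_ana <- -55 + (-60 + 55) * exp(-t / 20)
  expect_lt(max(abs(sim$monitor_V[, 1] - v_ana)), 1e-6)
  expect_equal(nrow(sim$spikes), 0)
})

test_that("suprathreshold drive gives the closed-form firing period", {
  topo <- micro_topology(1, 0)
  sim <- run_simulation(topo, drive_spec("constant", 11), 2000, 0.1,
                        init_state = quiet_state(1))
  isi <- diff(sim$spikes$time)
  # T = tau_ref + tau_m log(11/1), discretized to the step
  expect_lt(abs(mean(isi) - (2 + 20 * log(11))), 0.2)
})

test_that("zero drive relaxes to rest with no spikes", {
  topo <- micro_topology(2, 0, ee = list(0L, 1L, 1))
  st <- quiet_state(2, V = -52)
  sim <- run_simulation(topo, drive_spec("none"), 500, 0.1, init_state = st,
                        record = list(monitor_ids = c(0L, 1L)))
  expect_equal(nrow(sim$spikes), 0)
  expect_lt(max(abs(sim$state$V - (-60))), 1e-6)
})

test_that("PSP closed form reproduces the printed calibration", {
  expect_equal(psp_peak_amplitude("excitatory", 1), 0.157, tolerance = 5e-3)
  expect_equal(psp_peak_amplitude("inhibitory", 1), -2.25, tolerance = 1e-3)
  expect_equal(psp_peak_amplitude("excitatory", 0), 0)
  # linearity in w
  expect_equal(psp_peak_amplitude("excitatory", 7),
               7 * psp_peak_amplitude("excitatory", 1))
  # degenerate tau_s = tau_m limit: alpha-function peak
  nrn <- neuron_params()
  syn <- synapse_params(tau_e = 20)
  expect_equal(psp_peak_amplitude("excitatory", 1, nrn, syn), exp(-1))
})


test_that("simulated single PSPs match the closed form within 1%", {
  expect_equal(simulate_single_psp(1), psp_peak_amplitude("excitatory", 1),
               tolerance = 0.01)
  expect_equal(simulate_single_psp(3), psp_peak_amplitude("excitatory", 3),
               tolerance = 0.01)
  expect_equal(simulate_single_psp(1, "inhibitory"),
               psp_peak_amplitude("inhibitory", 1), tolerance = 0.01)
})

test_that("current-based synapses superpose linearly", {
  # response to two presynaptic spikes equals the sum of single responses
  topo2 <- micro_topology(3, 0, ee = list(c(0L, 1L), c(2L, 2L), c(1, 1)))
  both <- run_simulation(topo2, drive_spec("none"), 100, 0.1,
                         init_state = quiet_state(3),
                         stimulus = stimulus_spec(c(0L, 1L), n_pulses = 1),
                         record = list(monitor_ids = 2L))$monitor_V[, 1]
  one <- run_simulation(topo2, drive_spec("none"), 100, 0.1,
                        init_state = quiet_state(3),
                        stimulus = stimulus_spec(0L, n_pulses = 1),
                        record = list(monitor_ids = 2L))$monitor_V[, 1]
  expect_lt(max(abs((both + 60) - 2 * (one + 60))), 1e-9)
})

test_that("no neuron spikes during its refractory period", {
  topo <- build_random_topology(150, 40, 0.05, seed = 2)
  sim <- run_simulation(topo, drive_spec("constant", 11), 3000, 0.1, seed = 3)
  isi <- unlist(lapply(split(sim$spikes$time, sim$spikes$neuron), diff))
  expect_gte(min(isi), 2)
})

test_that("a zero-duration run returns the initial state untouched", {
  topo <- micro_topology(2, 0, ee = list(0L, 1L, 1))
  st <- quiet_state(2, V = -55)
  sim <- run_simulation(topo, drive_spec(), 0, 0.1, init_state = st)
  expect_equal(nrow(sim$spikes), 0)
  expect_equal(sim$state$V, st$V)
  expect_equal(sim$state$t, 0)
})

test_that("burst stimulation fires each target exactly n_pulses times", {
  topo <- build_random_topology(100, 25, 0.02, seed = 4)
  st <- init_network_state(topo, seed = 5)
  stim <- stimulus_spec(0:19, pulse_duration = 0.5, inter_pulse_gap = 2,
                        n_pulses = 2)
  res <- apply_stimulus_protocol(st, topo, stim, drive = drive_spec("none"))
  expect_true(res$success)
  expect_equal(nrow(res$stimulated_spikes), 40)
  spread <- vapply(split(res$stimulated_spikes$time,
                         res$stimulated_spikes$neuron), function(tt)
                           diff(range(tt)), 0)
  expect_true(all(spread <= 2 + 1)) # two spikes within 2 + epsilon ms
  expect_true(all(table(res$stimulated_spikes$neuron) == 2))
})

test_that("stimulation refuses to start on refractory targets", {
  topo <- micro_topology(5, 0)
  st <- quiet_state(5)
  st$refractory[3] <- 10L # cell id 2 mid-refractory
  stim <- stimulus_spec(c(1L, 2L))
  res <- apply_stimulus_protocol(st, topo, stim, drive = drive_spec("none"))
  expect_false(res$success)
  expect_equal(res$state$V, st$V)
  # empty target set trivially succeeds with no spikes
  res0 <- apply_stimulus_protocol(st, topo, stimulus_spec(integer(0)),
                                  drive = drive_spec("none"))
  expect_true(res0$success)
  expect_equal(nrow(res0$stimulated_spikes), 0)
})

test_that("simulation runs are bit-reproducible given a seed", {
  topo <- build_random_topology(80, 20, 0.05, seed = 1)
  a <- run_simulation(topo, drive_spec(), 2000, 0.1, seed = 99)
  b <- run_simulation(topo, drive_spec(), 2000, 0.1, seed = 99)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$state$V, b$state$V)
  p <- run_simulation(topo, drive_spec("poisson"), 1000, 0.1, seed = 7)
  q <- run_simulation(topo, drive_spec("poisson"), 1000, 0.1, seed = 7)
  expect_identical(p$spikes, q$spikes)
})

test_that("the static full-size network stays asynchronous irregular", {
  # fluctuation-driven firing needs the full population: mean rate a few
  # Hz and ISI CV near 1, across seeds
  rates <- cvs <- numeric(5)
  for (s in 1:5) {
    topo <- build_random_topology(4000, 1000, 0.02, seed = s)
    sim <- run_simulation(topo, drive_spec(), 16000, 0.1,
                          record = list(record_from = 1000), seed = s + 10)
    r <- firing_rates(sim$spikes, c(1000, 16000))
    rates[s] <- mean(r[1:4000])
    cv <- vapply(split(sim$spikes$time, sim$spikes$neuron), cv_isi, 0)
    cvs[s] <- mean(cv, na.rm = TRUE)
  }
  expect_true(all(rates > 3 & rates < 8))
  expect_true(all(cvs > 0.8 & cvs < 1.2))
})
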