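test_that("pair_delta_w reproduces the printed kernel values", {
  ee <- stdp_params() # effective amplitudes: 0.02 / 0.021
  expect_equal(pair_delta_w(10, 1, ee), 0.02 * exp(-0.5))
  expect_equal(pair_delta_w(-10, 1, ee), -0.021 * exp(-0.5))
  # zero lag belongs to the depression branch
  expect_equal(pair_delta_w(0, 1, ee), -0.021)
  ie <- stdp_params_inhibitory() # 4:1 ratio, w_max = 5
  expect_equal(pair_delta_w(20, 1, ie), 0.02 * exp(-1))
  expect_equal(pair_delta_w(20, 1, ie), 0.007357589, tolerance = 1e-6)
})

test_that("kernel integrals have the documented signs", {
  expect_lt(stdp_kernel_integral(stdp_params()), 0)      # 1.05 dominance
  expect_gt(stdp_kernel_integral(stdp_params_inhibitory()), 0) # 4:1 ratio
})

test_that("event updates honour traces and clipping", {
  p <- stdp_params()
  r <- stdp_on_pre(1, list(x_pre = 0, x_post = 0), p)
  expect_equal(r$w, 1) # no prior postsynaptic spikes
  expect_equal(r$traces$x_pre, 1)
  # post spiked 10 ms earlier: equals the pair rule at dt = -10
  r <- stdp_on_pre(1, list(x_pre = 0, x_post = exp(-0.5)), p)
  expect_equal(r$w - 1, pair_delta_w(-10, 1, p))
  r <- stdp_on_pre(0, list(x_pre = 0, x_post = 5), p)
  expect_equal(r$w, 0) # clipped at zero
  r <- stdp_on_post(1, list(x_pre = exp(-1), x_post = 0),
                    stdp_params_inhibitory())
  expect_equal(r$w - 1, pair_delta_w(20, 1, stdp_params_inhibitory()))
  r <- stdp_on_post(20, list(x_pre = 3, x_post = 0), p)
  expect_equal(r$w, 20) # clipped at w_max
})

test_that("trace accumulation equals brute-force all-to-all pair summation", {
  p <- stdp_params()
  set.seed(31)
  for (i in 1:8) {
    pre <- sort(runif(60, 0, 1000))
    post <- sort(runif(60, 0, 1000))
    expect_equal(stdp_accumulate_train(pre, post, p, w0 = 0),
                 stdp_pair_sum_oracle(pre, post, p), tolerance = 1e-10)
  }
  # coincident spikes: the zero-lag pairing depresses
  expect_equal(stdp_accumulate_train(5, 5, p, w0 = 0), -p$a_minus_eff)
})

test_that("normalization restores the incoming sum exactly", {
  expect_equal(normalize_incoming(c(3, 1), 2), c(1.5, 0.5))
  expect_equal(normalize_incoming(rep(1, 4), 4), rep(1, 4))
  expect_warning(z <- normalize_incoming(c(0, 0), 2), "all-zero")
  expect_equal(z, c(0, 0))
  w <- runif(17, 0, 3)
  wn <- normalize_incoming(w, 17, target_mean = 1)
  expect_equal(sum(wn), 17)
  expect_equal(wn / w, rep(wn[1] / w[1], 17)) # proportions preserved
})

test_that("synaptic scaling follows dw/dt = -gamma (nu - nu0) w^2", {
  expect_equal(scaling_step(1, nu = 5, gamma = 1e-6, nu_0 = 0,
                            dt_step = 0.05) - 1, -2.5e-7)
  expect_equal(scaling_step(1, nu = 3, nu_0 = 3), 1)
  expect_equal(scaling_step(0, nu = 50), 0)
  expect_equal(scaling_step(1e6, nu = 1e9, dt_step = 1, w_max = 20), 0)
})

test_that("network STDP keeps weights inside [0, w_max]", {
  topo <- build_random_topology(150, 40, 0.05, seed = 6)
  sim <- run_simulation(topo, drive_spec(), 20000, 0.1,
                        plasticity = plasticity_config(), seed = 8)
  expect_true(all(sim$topology$edges$ee$w >= 0 &
                    sim$topology$edges$ee$w <= 20))
  expect_true(all(sim$topology$edges$ie$w >= 0 &
                    sim$topology$edges$ie$w <= 5))
  # static classes untouched
  expect_true(all(sim$topology$edges$ei$w == 1))
  expect_true(all(sim$topology$edges$ii$w == 1))
})

test_that("normalization pins incoming E-E sums at in-degree x target", {
  topo <- build_random_topology(120, 30, 0.06, seed = 12)
  sim <- run_simulation(topo, drive_spec(), 5000, 0.1,
                        plasticity = plasticity_config(), seed = 13,
                        record = list(summary_interval = 500))
  ee <- sim$topology$edges$ee
  sums <- rowsum(ee$w, ee$post)
  deg <- table(ee$post)
  expect_equal(unname(sums[, 1]),
               as.vector(deg[rownames(sums)]) * 1, tolerance = 1e-12)
  # global mean pinned at 1 on every summary row
  expect_true(all(abs(sim$summary$mean_ee - 1) < 1e-9))
})

test_that("slow synaptic scaling shrinks weights of active cells", {
  topo <- build_random_topology(100, 25, 0.06, seed = 14)
  pl <- plasticity_config(ee_stdp = FALSE, ie_stdp = FALSE,
                          homeostasis = "scaling", gamma = 1e-4)
  sim <- run_simulation(topo, drive_spec(), 10000, 0.1, plasticity = pl,
                        seed = 15)
  r <- firing_rates(sim$spikes, c(0, 10000), 125)
  active <- which(r[1:100] > 1) - 1L
  w_in <- sim$topology$edges$ee$w[sim$topology$edges$ee$post %in% active]
  expect_true(all(w_in < 1))
  expect_gt(min(w_in), 0.9) # gamma nu w^2 integrates to a small decrement
})

test_that("multiplicative rule variants shape the amplitudes as documented", {
  pm <- stdp_params(A_plus = 1e-3, A_minus = 1e-3,
                    mode = "partly_multiplicative")
  # depression proportional to the weight, additive potentiation
  expect_equal(pair_delta_w(-10, 10, pm) / pair_delta_w(-10, 5, pm), 2)
  expect_equal(pair_delta_w(10, 10, pm), pair_delta_w(10, 5, pm))
  fm <- stdp_params(A_plus = 1e-3, A_minus = 1e-3,
                    mode = "fully_multiplicative")
  expect_equal(pair_delta_w(10, 20, fm), 0) # potentiation vanishes at w_max
  expect_lt(pair_delta_w(10, 15, fm), pair_delta_w(10, 5, fm))
})
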