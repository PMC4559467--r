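test_that("inhibitory delay is w over nu_0 (V_thres - V_rest)", {
  expect_equal(inhibitory_delay(1, 5, 10), 0.02)
  expect_equal(inhibitory_delay(0, 5, 10), 0)
  expect_equal(inhibitory_delay(1, 10, 10), inhibitory_delay(1, 5, 10) / 2)
  expect_error(inhibitory_delay(1, 0), "positive")
})

test_that("stationary inhibitory weight follows the closed form", {
  expect_equal(stationary_inhibitory_weight(5), 5 * 0.02 * 10 * log(4))
  expect_equal(stationary_inhibitory_weight(5), 1.386294, tolerance = 1e-6)
  expect_equal(stationary_inhibitory_weight(0), 0)
  expect_equal(stationary_inhibitory_weight(5, A_plus = 1e-3,
                                            A_minus = 1e-3), 0)
  expect_error(stationary_inhibitory_weight(5, A_minus = 0), "positive")
})

test_that("the stationary weight is the root of the averaged update", {
  for (nu0 in c(1, 5, 12, 30)) {
    w_stat <- stationary_inhibitory_weight(nu0)
    expect_lt(abs(mean_inhibitory_dw(w_stat, nu0)), 1e-12)
    # and it is the unique crossing: positive below, negative above
    expect_gt(mean_inhibitory_dw(0.9 * w_stat, nu0), 0)
    expect_lt(mean_inhibitory_dw(1.1 * w_stat, nu0), 0)
  }
})

test_that("rate with inhibition compensates increased drive only partially", {
  expect_equal(rate_with_inhibition(5, 0), 5)
  expect_equal(rate_with_inhibition(5, 5), 5 / (1 + 0.1 * log(4)),
               tolerance = 1e-9)
  expect_equal(rate_with_inhibition(5, 5), 4.391, tolerance = 1e-3)
  # contraction: 0 < nu(nu0 + d) - nu(nu0) < d for all d > 0
  for (d in c(0.1, 1, 10)) {
    gain <- rate_with_inhibition(5 + d, 5) - rate_with_inhibition(5, 5)
    expect_gt(gain, 0)
    expect_lt(gain, d)
  }
})

test_that("pair contribution matches quadrature and its limits", {
  p <- stdp_params()
  expect_equal(pair_contribution(0, p), 0)
  expect_equal(pair_contribution(1e6, p),
               p$a_plus_eff * 20 - p$a_minus_eff * 20)
  # numerical quadrature oracle at T = 50 ms
  f <- function(t) p$a_plus_eff * exp(-(50 - t) / 20) -
    p$a_minus_eff * exp(-t / 20)
  expect_equal(pair_contribution(50, p),
               integrate(f, 0, 50, rel.tol = 1e-12)$value,
               tolerance = 1e-9)
  # zero shift reduces the shifted form to the plain one
  expect_equal(pair_contribution_shifted(50, 0, p), pair_contribution(50, p))
  expect_equal(pair_contribution_shifted(37, 0, p), pair_contribution(37, p))
  # shifted closed form equals quadrature of the two shifted integrals
  Tt <- 40; d <- 3
  g1 <- function(t) p$a_plus_eff * exp(-(Tt - t - d) / 20) -
    p$a_minus_eff * exp(-t / 20)
  g2 <- function(t) p$a_plus_eff * exp(-(Tt - t) / 20) -
    p$a_minus_eff * exp(-t / 20)
  expect_equal(pair_contribution_shifted(Tt, d, p),
               integrate(g1, d, Tt - d, rel.tol = 1e-12)$value +
                 integrate(g2, 0, d, rel.tol = 1e-12)$value,
               tolerance = 1e-9)
})

test_that("postsynaptic shift follows delta_r / (r (r + delta_r))", {
  expect_equal(postsynaptic_shift(0, 5, 1), 0)
  expect_equal(postsynaptic_shift(1, 5, 0.5), 0.5 / (5 * 5.5))
  expect_equal(postsynaptic_shift(1, 5, 0.5) * 1000, 18.18, tolerance = 1e-2)
})

test_that("fire probability integrates the near-threshold mass", {
  # uniform membrane density on [-60, -50]
  dist <- membrane_distribution("empirical",
                                counts = rep(1, 100),
                                breaks = seq(-60, -50, length.out = 101))
  expect_equal(fire_probability(0, dist), 0)
  expect_equal(fire_probability(5, dist), 0.5)
  expect_equal(fire_probability(10, dist), 1)
  expect_equal(fire_probability(50, dist), 1) # saturation at total mass
  w <- seq(0, 12, by = 0.5)
  expect_true(all(diff(fire_probability(w, dist)) >= 0))
})

test_that("the inverse-Gaussian density is a proper density", {
  ig <- integrate(dinvgauss, 0, Inf, mu = 0.02, lambda = 0.015)
  expect_equal(ig$value, 1, tolerance = 1e-6)
  m1 <- integrate(function(x) x * dinvgauss(x, 0.02, 0.015), 0, Inf)
  expect_equal(m1$value, 0.02, tolerance = 1e-4)
  expect_equal(dinvgauss(-1, 1, 1), 0)
})

test_that("empirical membrane distributions are normalized", {
  set.seed(50)
  v <- rnorm(20000, -55, 2)
  d <- membrane_distribution("empirical", V = v[v < -50])
  expect_equal(sum(d$density * diff(d$breaks)), 1, tolerance = 1e-9)
  expect_error(membrane_distribution("empirical", V = numeric(0)), "empty")
})

test_that("diffusion-mode distribution cross-validates against simulation", {
  # the reduced two-cell drive: 1650 delta synapses, 1 Hz, 0.5 mV
  mc <- cached("dw_baseline",
               run_two_neuron_excitatory_dw(0, duration_s = 150,
                                            n_repeats = 2, seed = 61))
  mu <- -60 + 1650 * 0.5 * 0.02
  sigma <- sqrt(1650 * 0.5^2 * 0.02)
  dd <- membrane_distribution("diffusion", mu = mu, sigma = sigma,
                              n_bins = 400)
  # compare CDFs on the overlapping support (subthreshold)
  cdf <- function(d) cumsum(d$density * diff(d$breaks))
  emp <- mc$dist
  ks <- max(abs(approx(dd$mid, cdf(dd), xout = emp$mid, yleft = 0,
                       yright = 1)$y - cdf(emp)))
  expect_lt(ks, 0.05)
  # first-passage rate of the same diffusion matches the simulated rate
  expect_equal(lif_rate_diffusion(mu, sigma), mc$rate0, tolerance = 0.1)
})

test_that("the drift estimate is continuous, negative at w = 0, and crosses", {
  mc <- cached("dw_baseline",
               run_two_neuron_excitatory_dw(0, duration_s = 150,
                                            n_repeats = 2, seed = 61))
  w <- seq(0, 2, by = 0.1)
  th <- expected_weight_change(w, mc$rate0, 3.9, mc$dist,
                               lambda = mc$lambda_fit)
  expect_lt(th[1], 0)
  expect_gt(th[length(th)], 0)
  expect_equal(sum(diff(sign(th)) != 0), 1) # single sign change
  expect_lt(max(abs(diff(th))), 3e-4)       # no jumps on a fine grid
})

test_that("the drift estimate is insensitive to lambda in the stated range", {
  mc <- cached("dw_baseline",
               run_two_neuron_excitatory_dw(0, duration_s = 150,
                                            n_repeats = 2, seed = 61))
  w <- seq(0, 2, by = 0.25)
  lo <- expected_weight_change(w, mc$rate0, 3.9, mc$dist,
                               lambda = 0.5 / mc$rate0)
  hi <- expected_weight_change(w, mc$rate0, 3.9, mc$dist,
                               lambda = 1 / mc$rate0)
  scale <- max(abs(lo))
  expect_lt(max(abs(hi - lo)) / scale, 0.05)
})
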