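test_that("Erdos-Renyi constructor matches its edge-count statistics", {
  # degenerate probabilities
  expect_equal(sum(vapply(build_random_topology(10, 10, 0, seed = 1)$edges,
                          nrow, 0L)), 0)
  full <- build_random_topology(2, 0, 1, seed = 1)
  expect_equal(nrow(full$edges$ee), 2) # complete digraph on 2 nodes
  expect_true(all(full$edges$ee$pre != full$edges$ee$post))

  # binomial edge-count expectation, within 4 SD
  topo <- build_random_topology(4000, 1000, 0.02, seed = 7)
  n_pairs <- 4000 * 3999
  expect_lt(abs(nrow(topo$edges$ee) - n_pairs * 0.02),
            4 * sqrt(n_pairs * 0.02 * 0.98))
  expect_true(all(topo$edges$ee$pre != topo$edges$ee$post))
  expect_true(all(topo$edges$ie$pre >= 4000 & topo$edges$ie$post < 4000))
})

test_that("random in-degrees follow Binomial(n-1, p)", {
  counts <- integer(0)
  for (s in 1:20) {
    topo <- build_random_topology(60, 0, 0.1, seed = s)
    counts <- c(counts, in_degrees(topo, "ee"))
  }
  k <- 0:15
  expected <- length(counts) * dbinom(k, 59, 0.1)
  observed <- tabulate(pmin(counts, 15) + 1L, 16)
  keep <- expected > 5
  chi2 <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  expect_lt(chi2, qchisq(0.999, sum(keep) - 1))
})

test_that("homogeneous topology fixes in-degrees exactly", {
  topo <- build_homogeneous_topology(100, 25, 2, 1, seed = 3)
  expect_true(all(in_degrees(topo, "ee") == 2))
  expect_true(all(in_degrees(topo, "ie") == 1))
  expect_true(all(in_degrees(topo, "ei") == 2))
  expect_true(all(in_degrees(topo, "ii") == 1))
  expect_equal(var(in_degrees(topo, "ee")), 0)
  # pigeonhole: 10 distinct excitatory parents are not available
  expect_error(build_homogeneous_topology(10, 5, 10, 1, seed = 1),
               "presynaptic pool")
})

test_that("torus distance wraps around per axis", {
  expect_equal(torus_distance(c(0.9, 0.5), c(0.1, 0.5)), 0.2)
  expect_equal(torus_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(torus_distance(c(0, 0), c(0.5, 0.5)), sqrt(0.5))
  # symmetry
  a <- c(0.12, 0.95); b <- c(0.8, 0.07)
  expect_equal(torus_distance(a, b), torus_distance(b, a))
})

test_that("torus connection probability is a Gaussian bump of height epsilon", {
  pr <- connectivity_profile(0.2, 0.1)
  expect_equal(torus_connection_probability(0, pr), 0.2)
  expect_equal(torus_connection_probability(0.1, pr), 0.2 * exp(-0.5))
  d <- seq(0, 0.7, by = 0.05)
  expect_true(all(diff(torus_connection_probability(d, pr)) <= 0))
  expect_lt(torus_connection_probability(10, pr), 1e-40)
})

test_that("torus topology matches the analytic mean connection probability", {
  # epsilon * 2 pi sigma^2 for sigma << 1
  topo <- build_torus_topology(600, 100, seed = 11)
  p_e <- nrow(topo$edges$ee) / (600 * 599)
  p_ana <- 0.2 * 2 * pi * 0.1^2
  se <- sqrt(p_ana * (1 - p_ana) / (600 * 599))
  expect_lt(abs(p_e - p_ana), 4 * se)
  # zero-amplitude profile produces no edges
  t0 <- build_torus_topology(100, 25, connectivity_profile(0, 0.1),
                             connectivity_profile(0, 0.1), seed = 1)
  expect_equal(nrow(t0$edges$ee) + nrow(t0$edges$ie), 0)
  # grid placement needs a perfect square
  expect_error(build_torus_topology(100, 24, i_placement = "grid", seed = 1),
               "perfect square")
  tg <- build_torus_topology(100, 25, i_placement = "grid", seed = 2)
  expect_equal(sort(unique(tg$positions$u[101:125])),
               (0:4) / 5 + 1 / 10)
})

test_that("weight initialization schemes respect bounds and moments", {
  topo <- build_random_topology(200, 50, 0.05, seed = 5)
  tc <- init_weights(topo, "constant", value = 1)
  expect_true(all(tc$edges$ee$w == 1) && all(tc$edges$ii$w == 1))
  tg <- init_weights(topo, "gaussian", mean = 1, sd = 0, seed = 1)
  expect_equal(tg$edges$ee$w, tc$edges$ee$w)
  tu <- init_weights(topo, "uniform", min = 0, max = 2, seed = 2)
  n <- nrow(tu$edges$ee)
  expect_lt(abs(mean(tu$edges$ee$w) - 1), 4 * sqrt(1 / 3 / n))
  expect_true(all(tu$edges$ee$w >= 0 & tu$edges$ee$w <= 20))
})

test_that("inhibitory pruning removes the rounded fraction per target", {
  topo <- build_homogeneous_topology(100, 30, 5, 20, seed = 9)
  same <- prune_inhibitory_inputs(topo, 0:9, 0, seed = 1)
  expect_identical(same$edges$ie, topo$edges$ie)
  gone <- prune_inhibitory_inputs(topo, 0:9, 1, seed = 1)
  expect_equal(sum(in_degrees(gone, "ie")[1:10]), 0)
  part <- prune_inhibitory_inputs(topo, 0:9, 0.1, seed = 1)
  expect_true(all(in_degrees(part, "ie")[1:10] == 18)) # round(0.1*20) = 2
  expect_true(all(in_degrees(part, "ie")[11:100] == 20))
  # other classes untouched (set equality)
  for (cl in c("ee", "ei", "ii"))
    expect_identical(part$edges[[cl]], topo$edges[[cl]])
  expect_error(prune_inhibitory_inputs(topo, c(0, 5000), 0.1),
               "excitatory")
})

test_that("expected subgroup connectivity is n(n-1)p", {
  expect_equal(expected_subgroup_connections(20, 0.02), 7.6)
  expect_equal(expected_subgroup_connections(20, 0), 0)
  expect_equal(expected_subgroup_connections(40, 0.02), 31.2)
})

test_that("constructors are reproducible given a seed", {
  a <- build_random_topology(150, 40, 0.05, seed = 42)
  b <- build_random_topology(150, 40, 0.05, seed = 42)
  expect_identical(a, b)
  th1 <- build_torus_topology(200, 49, i_placement = "grid", seed = 8)
  th2 <- build_torus_topology(200, 49, i_placement = "grid", seed = 8)
  expect_identical(th1, th2)
  hh1 <- build_homogeneous_topology(80, 20, 4, 2, seed = 13)
  hh2 <- build_homogeneous_topology(80, 20, 4, 2, seed = 13)
  expect_identical(hh1, hh2)
})
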