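test_that("firing rates are counts over the window", {
  spk <- drivernet:::new_spike_record(seq(100, 2000, length.out = 10),
                                      rep(0L, 10), 2, 0, 2000)
  expect_equal(firing_rates(spk, c(0, 2000))[1], 5)
  expect_equal(firing_rates(spk, c(0, 2000))[2], 0)
  expect_error(firing_rates(spk, c(5, 5)), "positive length")
  # Poisson counting statistics
  set.seed(40)
  tt <- sort(runif(2000, 0, 1e5))
  spk <- drivernet:::new_spike_record(tt, rep(0L, 2000), 1, 0, 1e5)
  expect_lt(abs(firing_rates(spk, c(0, 1e5))[1] - 20),
            4 * sqrt(2000) / 100)
})

test_that("ISI coefficient of variation behaves at its limits", {
  expect_equal(cv_isi(seq(0, 1000, by = 50)), 0)
  expect_true(is.na(cv_isi(c(1, 2))))
  set.seed(41)
  pois <- cumsum(rexp(5000, 1 / 50))
  expect_equal(cv_isi(pois), 1, tolerance = 0.06)
})

test_that("mean outgoing weight ranks cells correctly", {
  topo <- micro_topology(4, 0, ee = list(c(0L, 0L, 1L), c(1L, 2L, 2L),
                                         c(2, 4, 1)))
  mo <- mean_outgoing_weight(topo)
  expect_equal(mo[1], 3) # weights (2, 4)
  expect_equal(mo[2], 1)
  expect_true(is.na(mo[3])) # zero out-degree: excluded marker
})

test_that("percentile driver detection equals the brute-force sort", {
  set.seed(42)
  for (i in 1:15) {
    n <- sample(30:80, 1)
    topo <- build_random_topology(n, 0, 0.2, seed = i)
    topo <- init_weights(topo, "uniform", min = 0, max = 2, seed = i + 100)
    rep <- detect_drivers_percentile(topo, 0.1)
    mo <- mean_outgoing_weight(topo)
    ranked <- which(!is.na(mo))
    ord <- ranked[order(-mo[ranked], ranked)] - 1L
    expect_identical(rep$drivers, ord[seq_len(round(0.1 * length(ranked)))])
    expect_true(all(mo[rep$drivers + 1L] >= rep$threshold))
  }
  # deterministic tie-break towards low ids
  tie <- micro_topology(5, 0, ee = list(0:4, c(1:4, 0L), rep(1, 5)))
  expect_identical(detect_drivers_percentile(tie, 0.4)$drivers, c(0L, 1L))
})

test_that("SD-threshold driver detection needs genuine outliers", {
  flat <- micro_topology(5, 0, ee = list(0:4, c(1:4, 0L), rep(1, 5)))
  expect_length(detect_drivers_sd(flat, 3)$drivers, 0)
  out <- micro_topology(21, 0,
                        ee = list(0:20, c(1:20, 0L), c(rep(1, 20), 40)))
  rep <- detect_drivers_sd(out, 3)
  expect_identical(rep$drivers, 20L)
})

test_that("weight shuffling preserves the multiset and flags clustering", {
  topo <- build_random_topology(100, 0, 0.1, seed = 17)
  topo <- init_weights(topo, "uniform", min = 0, max = 2, seed = 18)
  sur <- shuffle_weight_surrogate(topo, n_shuffles = 5, seed = 19)
  expect_equal(length(sur$quantile_mean), length(sur$original))
  # all-equal weights: surrogate identical to the original curve
  tc <- init_weights(topo, "constant", value = 1)
  sur1 <- shuffle_weight_surrogate(tc, n_shuffles = 3, seed = 20)
  expect_true(all(sur1$quantile_sd == 0))
  expect_equal(sur1$quantile_mean, sur1$original)
  # concentrate all strong weights on one cell: original top exceeds band
  tcl <- topo
  strong <- order(-tcl$edges$ee$w)[1:10]
  tcl$edges$ee <- rbind(tcl$edges$ee[-strong, ],
                        data.frame(pre = 0L,
                                   post = seq(50L, 59L),
                                   w = 8))
  sur2 <- shuffle_weight_surrogate(tcl, n_shuffles = 20, seed = 21)
  k <- length(sur2$original)
  expect_gt(sur2$original[k], sur2$quantile_mean[k] + 2 * sur2$quantile_sd[k])
})

test_that("subgroup connection counts match the adjacency submatrix", {
  pre <- rep(0:19, each = 20); post <- rep(0:19, times = 20)
  keep <- pre != post
  full <- micro_topology(20, 0, ee = list(pre[keep], post[keep], 1))
  expect_equal(count_subgroup_connections(full, 0:19), 380)
  empty <- micro_topology(10, 0)
  expect_equal(count_subgroup_connections(empty, 0:9), 0)
  expect_error(count_subgroup_connections(empty, c(1, 1, 2)), "distinct")
  # sparse-matrix oracle, invariance under id permutation
  topo <- build_random_topology(60, 0, 0.1, seed = 22)
  adj <- Matrix::sparseMatrix(i = topo$edges$ee$pre + 1L,
                              j = topo$edges$ee$post + 1L, x = 1,
                              dims = c(60, 60))
  set.seed(23)
  for (i in 1:5) {
    ids <- sample(0:59, 15)
    expect_equal(count_subgroup_connections(topo, ids),
                 sum(adj[ids + 1L, ids + 1L]))
    expect_equal(count_subgroup_connections(topo, rev(ids)),
                 count_subgroup_connections(topo, ids))
  }
})

test_that("synchrony-triggered averages detect causal rate elevations", {
  # constructed record: group of 3 bursts at known times, population rate
  # steps up for 20 ms after each burst
  set.seed(24)
  ev <- seq(500, 9500, by = 1000)
  t_grp <- rep(ev, each = 3) + runif(3 * length(ev), 0, 0.9)
  id_grp <- rep(0:2, times = length(ev))
  t_pop <- sort(c(runif(2000, 0, 10000),
                  unlist(lapply(ev, function(e) runif(150, e + 1, e + 20)))))
  id_pop <- sample(3:49, length(t_pop), replace = TRUE)
  ord <- order(c(t_grp, t_pop))
  spk <- drivernet:::new_spike_record(c(t_grp, t_pop)[ord],
                                      c(id_grp, id_pop)[ord], 50, 0, 10000)
  sta <- synchrony_triggered_average(spk, 0:2, k = 3, bin = 1,
                                     halfwidth = 100)
  expect_equal(sta$n_events, 10)
  post <- mean(sta$rate[sta$lag > 0 & sta$lag <= 25])
  pre <- mean(sta$rate[sta$lag < 0 & sta$lag >= -25])
  expect_gt(post, pre * 2)
  # a group independent of the population rate gives a symmetric STA
  t_ind <- sort(runif(5000, 0, 50000))
  ind <- drivernet:::new_spike_record(t_ind,
                                      sample(0:24, 5000, TRUE), 25, 0, 50000)
  sta0 <- synchrony_triggered_average(ind, 0:2, k = 1, bin = 1,
                                      halfwidth = 50)
  post0 <- mean(sta0$rate[sta0$lag > 0])
  pre0 <- mean(sta0$rate[sta0$lag < 0])
  expect_lt(abs(post0 - pre0), 0.25 * (post0 + pre0))
  # k larger than the group never triggers
  none <- synchrony_triggered_average(spk, 0:2, k = 10)
  expect_equal(none$n_events, 0)
})

test_that("PSTH is flat for stationary activity and zero for empty records", {
  set.seed(25)
  tt <- sort(runif(20000, 0, 20000))
  spk <- drivernet:::new_spike_record(tt, sample(0:19, 20000, TRUE), 20, 0,
                                      20000)
  ps <- psth(spk, bin = 10, align_times = seq(1000, 19000, by = 2000),
             window = c(-500, 500))
  expect_equal(mean(ps$rate), 50, tolerance = 0.05)
  expect_lt(sd(ps$rate) / mean(ps$rate), 0.25)
  empty <- drivernet:::new_spike_record(numeric(0), integer(0), 20, 0, 100)
  expect_true(all(psth(empty, 10, 50, c(-50, 50))$rate == 0))
})

test_that("power-law fitter recovers known exponents", {
  set.seed(26)
  x <- 0.05 * runif(1e5)^(-1 / 0.92) # Pareto, density exponent -1.92
  fit <- fit_powerlaw_mle(x, upper_trim_fraction = 0)
  expect_equal(fit$alpha, -1.92, tolerance = 0.05)
  expect_gte(fit$x_min, 0.05)
  # exponential data: visibly worse tail support
  y <- rexp(1e4, 1)
  fity <- fit_powerlaw_mle(y, upper_trim_fraction = 0)
  expect_gt(fity$ks_distance, 2 * fit$ks_distance)
  expect_error(fit_powerlaw_mle(runif(30)), "too few")
})

test_that("log-normal fitter recovers parameters and reports zeros", {
  set.seed(27)
  x <- rlnorm(1e4, meanlog = 1, sdlog = 0.5)
  fit <- fit_lognormal(x)
  expect_equal(fit$mu, 1, tolerance = 0.05)
  expect_equal(fit$sigma, 0.5, tolerance = 0.05)
  expect_lt(fit$ks_distance, 0.02)
  cst <- fit_lognormal(rep(2, 100))
  expect_equal(cst$sigma, 0)
  mix <- fit_lognormal(c(0, 0, x))
  expect_equal(mix$n_zero, 2)
  expect_equal(mix$n, 1e4)
  expect_error(fit_lognormal(c(0, 0)), "no positive")
})
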