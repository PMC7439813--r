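# Construction and dynamics of the full rate network.

test_that("connectivity has exact indegrees and no self-connections", {
  rp <- rate_net_params()   # defaults: 1024 E + 256 I, c = 100/1024
  net <- build_rate_network(rp, seed = 11)
  expect_equal(dim(net$conn$exc_in_E), c(100, 1024))
  expect_equal(dim(net$conn$inh_in_E), c(25, 1024))
  for (i in c(1, 512, 1024)) {
    col <- net$conn$exc_in_E[, i]
    expect_false(any(col == i))                 # no self-connection
    expect_equal(length(unique(col)), 100)      # sampled without replacement
  }
  for (i in seq_len(256)) {
    expect_false(any(net$conn$inh_in_I[, i] == i))
  }
  expect_error(rate_net_params(N_E = 100, c = 0.13), "integers")
})

test_that("initial weights sit at the fixed-point value with jitter applied", {
  rp <- rate_net_params(init_jitter = 0)
  net <- build_rate_network(rp, seed = 1)
  expect_equal(net$w_star, 1.9 / (0.75 * 100), tolerance = 1e-12)
  expect_equal(unique(as.vector(net$state$W_EE)), net$w_star)
  expect_equal(net$w_max, 10 * net$w_star)

  rpj <- rate_net_params(init_jitter = 0.1)
  netj <- build_rate_network(rpj, seed = 1)
  expect_equal(mean(netj$state$W_EE), net$w_star, tolerance = 2e-3)
  expect_true(all(abs(netj$state$W_EE / net$w_star - 1) <= 0.1 + 1e-12))

  expect_error(build_rate_network(rate_net_params(I_mean = 10.5)), "w\\*")
})

test_that("one BCM step reproduces the rule arithmetic and its fixed point", {
  # unit-indegree network isolates a single synapse per neuron
  rp <- unit_indegree_params(tau_c = 30)
  net <- build_rate_network(rp, seed = 2)
  st <- net$state

  # at the target with matched estimate, weights do not move
  st$r_E <- rep(5, 4); st$r_bar <- rep(5, 4)
  st2 <- bcm_step(st, net$conn, rp, dt = 1e-3, w_max = net$w_max)
  expect_equal(st2$W_EE, st$W_EE)

  # above-threshold potentiation: tau_w dw/dt = (eta w0/kappa^3) r_i r_j
  # (r_i - r_bar^2/kappa) with the indegree normalisation (= 1 here)
  st$r_E <- rep(6, 4); st$r_bar <- rep(5, 4)
  pre <- st$r_E[net$conn$exc_in_E[1, ]]
  st3 <- bcm_step(st, net$conn, rp, dt = 1e-3, w_max = 1e6)
  dw <- (st3$W_EE - st$W_EE) * rp$tau_w / 1e-3
  # tolerance reflects subtractive cancellation: dw ~ 5e-9 against w ~ 0.03
  expect_equal(as.vector(dw), (5 / 125) * 6 * pre * (6 - 25 / 5),
               tolerance = 1e-6)

  # the 0.48 value: r_i = 6, r_bar_i = 5, r_j = 2
  st$r_E <- c(6, 2, 2, 2); st$r_bar <- rep(5, 4)
  st4 <- bcm_step(st, net$conn, rp, dt = 1e-3, w_max = 1e6)
  j <- net$conn$exc_in_E[1, 1]
  if (j != 1) {   # presynaptic partner fires at 2 Hz
    dw1 <- (st4$W_EE[1, 1] - st$W_EE[1, 1]) * rp$tau_w / 1e-3
    expect_equal(dw1, (5 / 125) * 6 * 2 * (6 - 5), tolerance = 1e-6)
    expect_equal(dw1, 0.48, tolerance = 1e-6)
  }

  # below the sliding threshold: depression
  st$r_E <- rep(4, 4); st$r_bar <- rep(5, 4)
  st5 <- bcm_step(st, net$conn, rp, dt = 1e-3, w_max = net$w_max)
  expect_true(all(st5$W_EE < st$W_EE))

  # rate-estimate low-pass
  expect_equal(st5$r_bar, rep(5 + (1e-3 / 30) * (4 - 5), 4))
})

test_that("the compiled simulator matches the R-level BCM step", {
  # network held at its rate fixed point (rates do not move in the step) but
  # with the homeostatic estimate off target, so plasticity acts; the
  # compiled first step must equal one R-level bcm_step
  rp <- small_rate_params(init_jitter = 0, noise_rel_sd = 0,
                          plasticity_warmup = 0, tau_c = 30)
  net <- build_rate_network(rp, seed = 5)
  net$state$r_bar <- rep(4.8, rp$N_E)
  sim <- simulate_rate_network(net, duration = 1e-3, plasticity = TRUE,
                               seed = 5, record_dt = 1e-3)
  st_after <- bcm_step(net$state, net$conn, rp, dt = 1e-3, w_max = net$w_max)
  expect_equal(sim$final$W_EE, st_after$W_EE, tolerance = 1e-9)
  expect_equal(sim$final$r_bar, st_after$r_bar, tolerance = 1e-12)
  expect_equal(sim$final$r_E, net$state$r_E, tolerance = 1e-12)
})

test_that("homogeneous noise-free network replicates the mean-field model", {
  rp <- small_rate_params(init_jitter = 0, noise_rel_sd = 0)
  net <- build_rate_network(rp, seed = 3)
  sim <- simulate_rate_network(net, duration = 5, plasticity = FALSE,
                               seed = 3, record_neurons = TRUE,
                               record_neuron_dt = 1)
  mf <- as_meanfield(rp)
  ss <- steady_state(mf)
  n <- nrow(sim$trace)
  expect_equal(sim$trace$mean_rE[n], ss$r_E, tolerance = 1e-6)
  expect_equal(sim$trace$mean_rI[n], ss$r_I, tolerance = 1e-6)
  expect_equal(sim$trace$p[n], ss$p, tolerance = 1e-6)
  # every neuron equals the population value
  expect_lt(max(abs(sim$final$r_E - ss$r_E)), 1e-6)
  expect_lt(max(abs(sim$final$r_I - ss$r_I)), 1e-6)
})

test_that("release factor follows the scaled total inhibitory activity", {
  # homogeneous r_I = 5 Hz: r_I_tot = 5/c, scaled slope beta*c -> p = 0.75
  rp <- rate_net_params()
  r_I_tot <- rp$N_I * rp$w_EI * 5
  expect_equal(r_I_tot, 5 / rp$c)
  expect_equal(release_factor(rp$transfer_net, r_I_tot)$p, 0.75)
})

test_that("without recurrence rates settle at the input-inhibition balance", {
  rp <- small_rate_params(init_jitter = 0, noise_rel_sd = 0)
  net <- build_rate_network(rp, seed = 4)
  net$state$W_EE[] <- 0
  sim <- simulate_rate_network(net, duration = 5, plasticity = FALSE, seed = 4)
  # r_E = I - w_I r_E with w_I = 1: r_E = I / 2 = 0.25; with zero weights and
  # no recurrence the I population decays to r_I = 1.5 r_E / 1.5
  mf <- as_meanfield(rp, w_tilde_EE = 0)
  expect_equal(tail(sim$trace$mean_rE, 1), steady_state(mf)$r_E,
               tolerance = 1e-4)
})

test_that("rates and release factor respect their bounds under strong drive", {
  rp <- small_rate_params(I_mean = 8, init_jitter = 0.1)
  net <- build_rate_network(rp, seed = 6)
  net$state$W_EE <- net$state$W_EE * 5
  sim <- simulate_rate_network(net, duration = 3, plasticity = FALSE, seed = 6,
                               record_neurons = TRUE, record_neuron_dt = 0.5)
  expect_true(all(sim$rates_E >= 0 & sim$rates_E <= rp$r_max))
  expect_true(all(sim$trace$p >= 0 & sim$trace$p <= 1))
})

test_that("simulation is reproducible from the seed and sensitive to it", {
  rp <- small_rate_params()
  net <- build_rate_network(rp, seed = 9)
  s1 <- simulate_rate_network(net, duration = 2, plasticity = FALSE, seed = 9)
  s2 <- simulate_rate_network(net, duration = 2, plasticity = FALSE, seed = 9)
  s3 <- simulate_rate_network(net, duration = 2, plasticity = FALSE, seed = 10)
  expect_identical(s1$trace, s2$trace)
  expect_false(identical(s1$trace$mean_rE, s3$trace$mean_rE))
})

test_that("recurrence sweep diverges without presynaptic inhibition but stays
           bounded with it", {
  # mean-field equivalent small network, plasticity off
  rp0 <- small_rate_params(transfer = transfer_spec("none"),
                           init_jitter = 0, noise_rel_sd = 0)
  sc0 <- scan_recurrence("rate", rp0, w_grid = c(1, 1.5, 2.5, 3),
                         duration = 8, discard = 4)
  expect_true(all(sc0$points$label[sc0$points$w >= 2.5] == "divergent"))
  expect_true(all(sc0$points$label[sc0$points$w <= 1.5] == "finite"))

  rp1 <- small_rate_params(init_jitter = 0, noise_rel_sd = 0)  # beta = 0.05
  sc1 <- scan_recurrence("rate", rp1, w_grid = c(1, 2.5, 5, 10, 20),
                         duration = 8, discard = 4)
  # the network is never pinned at saturation, at any recurrence
  expect_true(all(sc1$points$label == "finite"))
  # within the dynamically convergent range (beyond w ~ 8 the slow GABA-B
  # feedback produces relaxation oscillations around the bounded fixed
  # point), the curve obeys the steady-state bound and matches mean-field
  conv <- sc1$points$w <= 5
  bound <- 1 / (0.05 * 1)   # 1/(beta w_I)
  expect_true(all(sc1$points$mean_rate[conv] <= bound * 1.05))
  mf_rates <- vapply(sc1$points$w[conv], function(w)
    steady_state(as_meanfield(rp1, w_tilde_EE = w))$r_E, numeric(1))
  expect_equal(sc1$points$mean_rate[conv], mf_rates, tolerance = 0.01)
})
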