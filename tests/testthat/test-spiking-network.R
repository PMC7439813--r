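# LIF network construction, integration accuracy, GABA spillover and the
# triplet plasticity rule.

test_that("connectivity statistics match Bernoulli sampling", {
  sp <- spiking_params(N_E = 1000, N_I = 250)
  net <- build_spiking_network(sp, seed = 21)
  indeg <- tabulate(net$ee$idx + 1L, nbins = sp$N_E)
  # expected indegree c*N_E = 100; empirical mean within 3 SE
  se <- sqrt(sp$N_E * sp$c * (1 - sp$c) / sp$N_E)
  expect_lt(abs(mean(indeg) - sp$c * sp$N_E), 3 * se)
  # no self-connections in E->E
  for (j in c(1, 500, 1000)) {
    targets <- net$ee$idx[(net$ee$ptr[j] + 1):net$ee$ptr[j + 1]] + 1L
    expect_false(any(targets == j))
  }
})

test_that("all-to-all connectivity at c = 1 excludes only the self-loop", {
  sp <- spiking_params(N_E = 5, N_I = 2, N_ext = 4, c = 1)
  net <- build_spiking_network(sp, seed = 1)
  expect_equal(diff(net$ee$ptr), rep(4L, 5))    # N_E - 1 targets each
  expect_equal(diff(net$ie$ptr), rep(5L, 2))    # all E targets
  expect_equal(length(net$ext$idx), 4 * 7)
})

test_that("the inverted E->E index is consistent with the forward one", {
  sp <- spiking_params(N_E = 50, N_I = 10, N_ext = 20)
  net <- build_spiking_network(sp, seed = 33)
  for (i in c(1, 25, 50)) {
    q <- (net$ee_in$ptr[i] + 1):net$ee_in$ptr[i + 1]
    if (net$ee_in$ptr[i] == net$ee_in$ptr[i + 1]) next
    expect_true(all(net$ee$idx[net$ee_in$edge[q] + 1L] == i - 1L))
    for (k in q) {
      j <- net$ee_in$pre[k] + 1L
      expect_true(net$ee_in$edge[k] %in%
                    (net$ee$ptr[j]:(net$ee$ptr[j + 1] - 1L)))
    }
  }
})

test_that("a quiescent network without input never spikes", {
  sp <- spiking_params(N_E = 20, N_I = 5, N_ext = 0, w_EE = 0.5)
  net <- build_spiking_network(sp, seed = 2)
  sim <- simulate_spiking(net, duration = 1)
  expect_equal(nrow(sim$spikes), 0)
  expect_true(all(abs(sim$final$V - sp$V_R) < 1e-12))
})

test_that("constant-drive firing matches the LIF closed form", {
  # rate = 1 / (tau_ref + tau_m ln(I0 / (I0 - (V_T - V_R))))
  for (I0 in c(25, 40)) {
    sp <- spiking_params(N_E = 1, N_I = 1, N_ext = 0, c = 1,
                         w_EE = 0, w_IE = 0, w_EI = 0, w_II = 0,
                         I_const_E = I0, transfer = transfer_spec("none"))
    net <- build_spiking_network(sp, seed = 1)
    sim <- simulate_spiking(net, duration = 20)
    predicted <- 1 / (sp$tau_ref + sp$tau_m * log(I0 / (I0 - 20)))
    expect_equal(sim$mean_rate_E[1], predicted, tolerance = 0.01)
    # refractory bound: no inter-spike interval below tau_ref
    isi <- diff(sim$spikes$time_s)
    expect_true(all(isi >= sp$tau_ref - 1e-9))
  }
})

test_that("GABA accumulation tracks the afferent inhibitory rate", {
  # 100 inhibitory afferents at ~5 Hz with A_GABA = 1/(c N_I) = 0.01:
  # time-averaged C_GABA equals the summed afferent rate x A_GABA = 5
  I5 <- uniroot(function(I) 1 / (0.005 + 0.02 * log(I / (I - 20))) - 5,
                c(20 + 1e-9, 21))$root
  sp <- spiking_params(N_E = 1, N_I = 100, N_ext = 0, c = 1,
                       w_EE = 0, w_IE = 0, w_EI = 0, w_II = 0,
                       A_GABA = 0.01, I_const_I = I5,
                       transfer = transfer_spec("linear", beta = 0.1))
  net <- build_spiking_network(sp, seed = 4)
  sim <- simulate_spiking(net, duration = 60, record_spikes = FALSE)
  expect_equal(mean(sim$mean_rate_I), 5, tolerance = 0.02)
  expect_equal(sim$avg_C[1], 100 * 0.01 * mean(sim$mean_rate_I),
               tolerance = 0.03)
})

test_that("release factors track the GABA level linearly in the
           asynchronous regime", {
  # external-Poisson-driven network: staggered inhibitory firing keeps
  # C_GABA away from the clipping boundary
  sp <- small_spiking_params(w_EE = 0.1,
                             transfer = transfer_spec("linear", beta = 0.02))
  net <- build_spiking_network(sp, seed = 5)
  sim <- simulate_spiking(net, duration = 20, record_spikes = FALSE)
  active <- sim$avg_C > 0.5
  expect_gt(mean(active), 0.5)
  expect_equal(sim$avg_p[active], 1 - 0.02 * sim$avg_C[active],
               tolerance = 0.02)
  expect_true(all(sim$final$p >= 0 & sim$final$p <= 1))
})

test_that("with transfer 'none' every release factor stays at 1", {
  sp <- small_spiking_params(transfer = transfer_spec("none"))
  net <- build_spiking_network(sp, seed = 6)
  sim <- simulate_spiking(net, duration = 5, record_spikes = FALSE)
  expect_true(all(sim$avg_p == 1))
})

test_that("spiking output is reproducible from the seed", {
  sp <- small_spiking_params()
  net <- build_spiking_network(sp, seed = 8)
  s1 <- simulate_spiking(net, duration = 2, seed = 8)
  s2 <- simulate_spiking(net, duration = 2, seed = 8)
  expect_identical(s1$spikes, s2$spikes)
})

test_that("LTD amplitude follows the metaplastic definition", {
  sp <- spiking_params()
  # A- = A+ tau+ tau_slow / (tau- kappa) * r_bar^2 at r_bar = kappa
  expect_equal(ltd_amplitude(sp, 5),
               6.5e-3 * 0.0118 * 0.114 * 5 / 0.0337, tolerance = 1e-12)
  expect_equal(ltd_amplitude(sp, 5), 1.297e-3, tolerance = 1e-3)
  expect_equal(ltd_amplitude(sp, 0), 0)
})

test_that("isolated pre-post pairings potentiate; post-pre pairings at high
           rate-detector values depress", {
  sp <- spiking_params(tau_c = 1e9)   # clamp-like detector
  # causal pairing pre -> post (+10 ms), 20 pairings at 1 Hz
  pre <- seq(0, 19)
  post <- pre + 0.01
  up <- triplet_weight_change(pre, post, sp, r_bar = 5)
  # each pairing: A+ * exp(-10ms/tau+) * z_slow(post before its increment)
  expect_gt(up$dw, 0)
  # anti-causal pairing post -> pre with strong depression at r_bar = 20
  down <- triplet_weight_change(pre + 0.01, pre, sp, r_bar = 20,
                                w_init = 2)
  expect_lt(down$dw, 0)
})

test_that("triplet LTP amplitude matches hand-computed trace values", {
  sp <- spiking_params()
  # single pre at t=0, post at t=0.01 and a second post at t=0.02:
  # first post: z_plus = exp(-0.01/tau+), z_slow = 0 -> no LTP
  # second post: z_plus = exp(-0.02/tau+), z_slow = exp(-0.01/tau_slow)
  res <- triplet_weight_change(0, c(0.01, 0.02), sp, r_bar = 0)
  expected <- sp$A_plus * exp(-0.02 / sp$tau_plus) * exp(-0.01 / sp$tau_slow)
  expect_equal(res$dw, expected, tolerance = 1e-12)
  # LTD on a pre spike after a post spike: w -= A-(r_bar) z_minus
  res2 <- triplet_weight_change(0.01, 0, sp, r_bar = 5, w_init = 1)
  expect_equal(res2$dw, -ltd_amplitude(sp, 5) * exp(-0.01 / sp$tau_minus),
               tolerance = 1e-12)
})

test_that("triplet drift vanishes at the target rate for independent
           Poisson firing", {
  sp <- spiking_params(w_max = Inf)
  set.seed(42)
  drifts <- replicate(20, {
    pre <- poisson_train(5, 100)
    post <- poisson_train(5, 100)
    triplet_weight_change(pre, post, sp, r_bar = 5, w_init = 10)$dw / 100
  })
  se <- stats::sd(drifts) / sqrt(length(drifts))
  expect_lt(abs(mean(drifts)), 3 * se)
  # scale reference: LTP-only flux is much larger than the residual drift
  ltp_flux <- sp$A_plus * sp$tau_plus * sp$tau_slow * 5^3
  expect_lt(abs(mean(drifts)), 0.2 * ltp_flux)
})

test_that("triplet drift is positive above target and negative below", {
  sp <- spiking_params(w_max = Inf)
  set.seed(43)
  hi <- mean(replicate(10, {
    triplet_weight_change(poisson_train(8, 100), poisson_train(8, 100), sp,
                          r_bar = 5, w_init = 10)$dw
  }))
  lo <- mean(replicate(10, {
    triplet_weight_change(poisson_train(2, 100), poisson_train(2, 100), sp,
                          r_bar = 5, w_init = 10)$dw
  }))
  expect_gt(hi, 0)
  expect_lt(lo, 0)
})
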