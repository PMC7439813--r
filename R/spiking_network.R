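#' Parameters of the current-based LIF network with GABA spillover
#'
#' Defaults reproduce the reference spiking network: 4000 excitatory and
#' 1000 inhibitory leaky integrate-and-fire neurons plus 2000 external
#' Poisson units at 5 Hz, all projections Bernoulli with probability 0.1.
#' Membrane: reset/rest -70 mV, threshold -50 mV, `tau_m = 20` ms,
#' `tau_ref = 5` ms; synaptic current filters `tau_E_syn = tau_I_syn = 10`
#' ms. Weights (unitless, current-based): `w_IE = 0.5` (E onto I),
#' `w_EI = w_II = -2.75`, `w_ext = 2.0`; a spike through weight `w`
#' increments the target's filtered current by `w`, so the mean current
#' contributed by a projection is `w x rate x tau`.
#'
#' Presynaptic inhibition: every inhibitory spike deposits a fixed amount of
#' GABA `A_GABA = 1/(c N_I)` at its excitatory targets (filtered with
#' `tau_I_syn`, normalised so the GABA level tracks the afferent inhibitory
#' rate in Hz), and each excitatory neuron's release factor relaxes with
#' `tau_p = 300` ms towards the transfer function of its own GABA level --
#' by default linear with slope `beta = 0.1`, rectified. The release factor
#' gates excitatory input onto excitatory cells at delivery time.
#'
#' Plasticity (triplet STDP with metaplastic LTD): potentiation amplitude
#' `A_plus = 6.5e-3` with traces `tau_plus = 11.8` ms (presynaptic),
#' `tau_slow = 114` ms and `tau_minus = 33.7` ms (postsynaptic); the LTD
#' amplitude of neuron i is `A_plus tau_plus tau_slow / (tau_minus kappa) *
#' r_bar_i^2`, where `r_bar_i` is a moving average of its firing rate with
#' time constant `tau_c` (each own spike adds `1/tau_c`). Plastic E-to-E
#' weights start at `w0` (1 with presynaptic inhibition, 0.5 without) and
#' are clipped to `[0, w_max = 5 w0]`; absent synapses stay absent.
#'
#' @param N_E,N_I,N_ext Neuron/unit counts.
#' @param r_ext External Poisson rate (Hz).
#' @param c Connection probability for all projections.
#' @param V_R,V_T Reset and threshold potentials (mV).
#' @param tau_m,tau_ref,tau_E_syn,tau_I_syn Membrane, refractory and
#'   synaptic time constants (s).
#' @param w_EE Fixed E-to-E weight used when plasticity is off (the free
#'   parameter of the recurrence sweeps); ignored for plastic runs, which
#'   start at `w0`.
#' @param w_IE,w_EI,w_II,w_ext Fixed weights (signs as stated above).
#' @param A_GABA GABA increment per inhibitory spike; default `1/(c N_I)`.
#' @param tau_p Release-factor time constant (s).
#' @param transfer A [transfer_spec()] mapping GABA level to release factor
#'   (no connectivity rescaling needed at this level).
#' @param A_plus,tau_plus,tau_slow,tau_minus Triplet-rule parameters.
#' @param kappa Target rate (Hz).
#' @param tau_c Rate-detector time constant (s).
#' @param w0 Initial plastic weight.
#' @param w_max Plastic-weight cap; default `5 w0`.
#' @param rbar_init Initial value of the LTD rate detector (Hz); default
#'   `kappa` (network initialised close to its operating point).
#' @param I_const_E,I_const_I Constant current added to E / I neurons (mV;
#'   0 by default -- used for controlled single-neuron protocols).
#' @param dt Integration step (s), default 0.1 ms.
#' @param plasticity_warmup Seconds with plasticity off at run start.
#' @return An object of class `spiking_params`.
#' @export
spiking_params <- function(N_E = 4000, N_I = 1000, N_ext = 2000, r_ext = 5,
                           c = 0.1, V_R = -70, V_T = -50,
                           tau_m = 0.02, tau_ref = 0.005,
                           tau_E_syn = 0.01, tau_I_syn = 0.01,
                           w_EE = 0.1, w_IE = 0.5, w_EI = -2.75, w_II = -2.75,
                           w_ext = 2.0, A_GABA = 1 / (c * N_I), tau_p = 0.3,
                           transfer = transfer_spec("linear", beta = 0.1),
                           A_plus = 6.5e-3, tau_plus = 0.0118,
                           tau_slow = 0.114, tau_minus = 0.0337,
                           kappa = 5, tau_c = 10,
                           w0 = 1, w_max = 5 * w0, rbar_init = kappa,
                           I_const_E = 0, I_const_I = 0,
                           dt = 1e-4, plasticity_warmup = 60) {
  stopifnot(inherits(transfer, "transfer_spec"),
            w_EI <= 0, w_II <= 0, w_IE >= 0, w_EE >= 0, w_ext >= 0,
            tau_ref > 0, tau_m > 0, tau_E_syn > 0, tau_I_syn > 0,
            tau_p > 0, tau_c > 0, V_T > V_R, c > 0, c <= 1, dt > 0)
  p <- as.list(environment())
  class(p) <- "spiking_params"
  p
}

#' Build the spiking network
#'
#' Samples Bernoulli(`c`) connectivity for all projection classes (E-to-E,
#' E-to-I, I-to-E, I-to-I, external-to-all) with no self-connections, and
#' initialises the plastic E-to-E weights (to `w0` for plastic use, or to
#' `w_EE` for fixed-weight sweeps -- chosen at simulation time).
#'
#' @param params A [spiking_params()].
#' @param seed Integer seed for the connectivity draw.
#' @return A list of class `spiking_net` holding the CSR adjacency of each
#'   projection, the inverted E-to-E index, and `params`.
#' @export
build_spiking_network <- function(params, seed = 1L) {
  stopifnot(inherits(params, "spiking_params"))
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(substream_seed(seed, "spiking_connectivity"))
  ee <- sample_bernoulli_csr(params$N_E, params$N_E, params$c, TRUE)
  ei <- sample_bernoulli_csr(params$N_E, params$N_I, params$c, FALSE)
  ie <- sample_bernoulli_csr(params$N_I, params$N_E, params$c, FALSE)
  ii <- sample_bernoulli_csr(params$N_I, params$N_I, params$c, TRUE)
  ext <- sample_bernoulli_csr(params$N_ext, params$N_E + params$N_I,
                              params$c, FALSE)
  ee_in <- invert_csr(ee$ptr, ee$idx, params$N_E, params$N_E)
  structure(list(ee = ee, ei = ei, ie = ie, ii = ii, ext = ext,
                 ee_in = ee_in, params = params),
            class = "spiking_net")
}

#' Simulate the spiking network
#'
#' Integrates the LIF network: membrane potentials with a 4th-order
#' Runge-Kutta step (currents held constant within a step), synaptic
#' currents, GABA levels and release factors with forward Euler (default
#' step 0.1 ms). Threshold crossings emit spikes, reset the membrane and
#' start the refractory clock; spikes are delivered to the filtered currents
#' of their targets, with E-to-E increments gated by the target's current
#' release factor; inhibitory spikes additionally deposit GABA at their
#' excitatory targets. With plasticity on (after the warm-up) every E-to-E
#' spike triggers the triplet-rule updates.
#'
#' @param net A `spiking_net` from [build_spiking_network()].
#' @param duration Simulated time (s).
#' @param plasticity Enable the triplet rule.
#' @param w_init Initial plastic weight per existing synapse; default
#'   `params$w0` when plasticity is on, else `params$w_EE`.
#' @param seed Integer seed for the external Poisson stream.
#' @param bin_dt Width of the population-rate bins (s), default 0.1 s.
#' @param record_spikes Keep the event list (time, neuron id)?
#' @param max_spikes Cap on stored events (the population-rate series is
#'   unaffected by the cap).
#' @return An object of class `spike_data`: `spikes` (data.frame `time_s`,
#'   `neuron_id`; excitatory ids `1..N_E`), `rate_E`, `rate_I`, `bin_time`
#'   (binned population rates, Hz), `mean_rate_E` (per-neuron time-averaged
#'   rates), `avg_p`, `avg_C` (per-neuron time averages), `final` state and
#'   `params`.
#' @export
simulate_spiking <- function(net, duration, plasticity = FALSE,
                             w_init = NULL, seed = 1L, bin_dt = 0.1,
                             record_spikes = TRUE, max_spikes = 5e6) {
  stopifnot(inherits(net, "spiking_net"), duration > 0)
  params <- net$params
  if (is.null(w_init)) w_init <- if (plasticity) params$w0 else params$w_EE
  tr <- params$transfer
  kind_code <- match(tr$kind, c("none", "linear", "sigmoid", "exponential")) - 1L
  ee_w0 <- rep(w_init, length(net$ee$idx))

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(substream_seed(seed, "external_poisson"))

  res <- simulate_spiking_cpp(
    ee_ptr = net$ee$ptr, ee_idx = net$ee$idx, ee_w0 = ee_w0,
    ee_in_ptr = net$ee_in$ptr, ee_in_edge = net$ee_in$edge,
    ee_in_pre = net$ee_in$pre,
    ei_ptr = net$ei$ptr, ei_idx = net$ei$idx,
    ie_ptr = net$ie$ptr, ie_idx = net$ie$idx,
    ii_ptr = net$ii$ptr, ii_idx = net$ii$idx,
    ext_ptr = net$ext$ptr, ext_idx = net$ext$idx,
    N_E = params$N_E, N_I = params$N_I, N_ext = params$N_ext,
    r_ext = params$r_ext,
    w_IE = params$w_IE, w_EI = params$w_EI, w_II = params$w_II,
    w_ext = params$w_ext,
    V_R = params$V_R, V_T = params$V_T,
    tau_m = params$tau_m, tau_ref = params$tau_ref,
    tau_E_syn = params$tau_E_syn, tau_I_syn = params$tau_I_syn,
    A_GABA = params$A_GABA, tau_p = params$tau_p,
    kind = kind_code,
    g_par = c(tr$beta, tr$beta_s, tr$r_shift, tr$beta_e),
    A_plus = params$A_plus, tau_plus = params$tau_plus,
    tau_slow = params$tau_slow, tau_minus = params$tau_minus,
    kappa = params$kappa, tau_c = params$tau_c,
    w_max = params$w_max, rbar_init = params$rbar_init,
    I_const_E = params$I_const_E, I_const_I = params$I_const_I,
    duration = duration, dt = params$dt,
    plasticity = plasticity,
    warmup = if (plasticity) params$plasticity_warmup else Inf,
    bin_dt = bin_dt, record_spikes = record_spikes,
    max_spikes = as.integer(max_spikes))

  n_bins <- length(res$rate_E)
  out <- list(
    spikes = data.frame(time_s = res$spike_t, neuron_id = res$spike_id + 1L),
    spikes_truncated = res$spikes_truncated,
    rate_E = res$rate_E, rate_I = res$rate_I,
    bin_time = (seq_len(n_bins) - 0.5) * bin_dt,
    mean_rate_E = res$spike_count[seq_len(params$N_E)] / duration,
    mean_rate_I = res$spike_count[params$N_E + seq_len(params$N_I)] / duration,
    avg_p = res$avg_p, avg_C = res$avg_C,
    final = list(V = res$V, W_EE = res$W_EE, p = res$p,
                 C_GABA = res$C_GABA, r_bar = res$r_bar),
    params = params)
  class(out) <- "spike_data"
  out
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf(paste0("<spike_data> %d events%s; mean E rate %.3g Hz, ",
                     "I rate %.3g Hz; mean p %.3g\n"),
              nrow(x$spikes),
              if (x$spikes_truncated) " (event list truncated)" else "",
              mean(x$mean_rate_E), mean(x$mean_rate_I), mean(x$avg_p)))
  invisible(x)
}

#' Triplet-STDP weight change for given pre/post spike trains
#'
#' Reference (event-driven, R-level) implementation of the minimal triplet
#' rule with metaplastic LTD used in the spiking simulator, for a single
#' synapse. Traces decay exponentially between events; a postsynaptic spike
#' potentiates by `A_plus * z_plus * z_slow` (slow trace read before its own
#' increment); a presynaptic spike depresses by `A_minus(t) * z_minus` with
#' `A_minus = A_plus tau_plus tau_slow / (tau_minus kappa) * r_bar^2`.
#'
#' @param pre_times,post_times Sorted spike times (s).
#' @param params A [spiking_params()] (triplet fields are used).
#' @param r_bar Either a fixed rate (Hz) at which the LTD detector is
#'   clamped, or `NULL` to let it follow the postsynaptic train
#'   (`+1/tau_c` per spike, exponential decay `tau_c`, initial
#'   `params$rbar_init`).
#' @param w_init,w_max Initial weight and cap (defaults from `params`).
#' @return List with final weight `w`, net change `dw` and the LTD
#'   amplitude `A_minus` at the end of the train.
#' @export
triplet_weight_change <- function(pre_times, post_times, params,
                                  r_bar = NULL, w_init = params$w0,
                                  w_max = params$w_max) {
  stopifnot(inherits(params, "spiking_params"))
  ev <- rbind(
    data.frame(t = pre_times, pre = TRUE),
    data.frame(t = post_times, pre = FALSE))
  ev <- ev[order(ev$t, !ev$pre), ]  # post before pre at ties: LTP reads z_plus
  zp <- 0; zm <- 0; zs <- 0
  rb <- if (is.null(r_bar)) params$rbar_init else r_bar
  clamp <- !is.null(r_bar)
  Am_coef <- params$A_plus * params$tau_plus * params$tau_slow /
    (params$tau_minus * params$kappa)
  w <- w_init
  t_last <- 0
  for (k in seq_len(nrow(ev))) {
    dt_ev <- ev$t[k] - t_last
    zp <- zp * exp(-dt_ev / params$tau_plus)
    zm <- zm * exp(-dt_ev / params$tau_minus)
    zs <- zs * exp(-dt_ev / params$tau_slow)
    if (!clamp) rb <- rb * exp(-dt_ev / params$tau_c)
    t_last <- ev$t[k]
    if (ev$pre[k]) {
      w <- max(0, w - Am_coef * rb^2 * zm)
      zp <- zp + 1
    } else {
      w <- min(w_max, w + params$A_plus * zp * zs)
      zm <- zm + 1
      zs <- zs + 1
      if (!clamp) rb <- rb + 1 / params$tau_c
    }
  }
  list(w = w, dw = w - w_init, A_minus = Am_coef * rb^2)
}

#' LTD amplitude of the metaplastic triplet rule
#'
#' `A_minus = A_plus * tau_plus * tau_slow / (tau_minus * kappa) * r_bar^2`;
#' at `r_bar = kappa` this exactly balances LTP against LTD for independent
#' Poisson firing at the target rate.
#'
#' @param params A [spiking_params()].
#' @param r_bar Rate-detector value (Hz).
#' @return LTD amplitude (weight units).
#' @export
ltd_amplitude <- function(params, r_bar) {
  stopifnot(inherits(params, "spiking_params"))
  params$A_plus * params$tau_plus * params$tau_slow /
    (params$tau_minus * params$kappa) * r_bar^2
}
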