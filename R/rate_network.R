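#' Parameters of the full excitatory-inhibitory rate network
#'
#' Defaults reproduce the reference network: 1024 excitatory and 256
#' inhibitory neurons connected with probability `c = 100/1024` and fixed
#' indegree, so every neuron receives exactly `c*N_E = 100` excitatory and
#' `c*N_I = 25` inhibitory inputs. Fixed per-synapse weights carry the
#' `1/(cN)` scaling (`w_EI = 1/(c N_I)`, `w_IE = 1.5/(c N_E)`,
#' `w_II = 0.5/(c N_I)`), so the population weights are 1, 1.5 and 0.5. The
#' plastic E-to-E weights start at the value that makes the target rate
#' `kappa` a fixed point, multiplied by per-synapse jitter. Excitatory
#' neurons receive background input redrawn each Euler step from
#' `Normal(I, (0.1 I)^2)`.
#'
#' The transfer slope is given on the population (mean-field) scale and
#' rescaled internally by the connection probability, because the release
#' factor senses the total weighted activity of all inhibitory neurons (see
#' [scale_transfer()]).
#'
#' @param N_E,N_I Neuron counts.
#' @param c Connection probability; `c*N_E` and `c*N_I` must be integers.
#' @param I_mean Mean background input (Hz).
#' @param noise_rel_sd Background-noise SD relative to `I_mean` (0.1 by
#'   default); `0` disables noise.
#' @param noise_mode `"per_step"` redraws the background input each Euler
#'   step (default); `"static"` draws one value per neuron at start.
#' @param r_max Rate saturation (Hz).
#' @param tau_E,tau_I,tau_p Fast time constants (s).
#' @param transfer A [transfer_spec()] on the population scale.
#' @param kappa,eta,w0,tau_w,tau_c BCM plasticity parameters (target rate,
#'   learning-rate multiplier, initial-weight scale, weight and homeostatic
#'   time constants).
#' @param w_max_factor Plastic-weight cap as a multiple of the initial
#'   fixed-point weight `w*`.
#' @param init_jitter Multiplicative uniform jitter half-width on initial
#'   E-to-E weights (0.1 means +/-10%); `0` gives a homogeneous network.
#' @param plasticity_warmup Simulated seconds with plasticity held off at
#'   the start of plastic runs (default 360 s = 6 min).
#' @return An object of class `rate_net_params`.
#' @export
rate_net_params <- function(N_E = 1024, N_I = 256, c = 100 / 1024,
                            I_mean = 0.5, noise_rel_sd = 0.1,
                            noise_mode = c("per_step", "static"),
                            r_max = 200,
                            tau_E = 0.02, tau_I = 0.01, tau_p = 0.5,
                            transfer = transfer_spec("linear", beta = 0.05),
                            kappa = 5, eta = 5, w0 = 1,
                            tau_w = 300, tau_c = 30,
                            w_max_factor = 10, init_jitter = 0.1,
                            plasticity_warmup = 360) {
  noise_mode <- match.arg(noise_mode)
  kE <- c * N_E
  kI <- c * N_I
  if (abs(kE - round(kE)) > 1e-9 || abs(kI - round(kI)) > 1e-9) {
    stop("rate_net_params: c*N_E and c*N_I must be integers (exact indegrees)")
  }
  stopifnot(inherits(transfer, "transfer_spec"), kappa > 0, r_max > kappa,
            tau_E > 0, tau_I > 0, tau_p > 0, tau_w > 0, tau_c > 0,
            init_jitter >= 0, init_jitter < 1, w_max_factor > 0)
  p <- list(N_E = N_E, N_I = N_I, c = c,
            k_E = as.integer(round(kE)), k_I = as.integer(round(kI)),
            w_EI = 1 / (c * N_I), w_IE = 1.5 / (c * N_E), w_II = 0.5 / (c * N_I),
            I_mean = I_mean, noise_rel_sd = noise_rel_sd,
            noise_mode = noise_mode, r_max = r_max,
            tau_E = tau_E, tau_I = tau_I, tau_p = tau_p,
            transfer = transfer, transfer_net = scale_transfer(transfer, c),
            kappa = kappa, eta = eta, w0 = w0, tau_w = tau_w, tau_c = tau_c,
            w_max_factor = w_max_factor, init_jitter = init_jitter,
            plasticity_warmup = plasticity_warmup)
  class(p) <- "rate_net_params"
  p
}

#' Mean-field counterpart of a rate network
#'
#' Maps a [rate_net_params()] to the equivalent [meanfield_params()]
#' (population weights `c N w`, population-scale transfer), used to attach
#' analytic predictions to simulations.
#'
#' @param params A [rate_net_params()].
#' @param w_tilde_EE Optional mean E-to-E population weight; default `NA`
#'   places the fixed point at `kappa`.
#' @return A [meanfield_params()].
#' @export
as_meanfield <- function(params, w_tilde_EE = NA_real_) {
  stopifnot(inherits(params, "rate_net_params"))
  meanfield_params(
    w_tilde_EE = w_tilde_EE,
    w_tilde_EI = params$c * params$N_I * params$w_EI,
    w_tilde_IE = params$c * params$N_E * params$w_IE,
    w_tilde_II = params$c * params$N_I * params$w_II,
    I = params$I_mean, kappa = params$kappa, eta = params$eta, w0 = params$w0,
    tau_E = params$tau_E, tau_I = params$tau_I, tau_p = params$tau_p,
    tau_w = params$tau_w, tau_c = params$tau_c, r_max = params$r_max,
    transfer = params$transfer)
}

#' Build connectivity and initial state of the rate network
#'
#' Samples, for every neuron, exactly `c*N_E` excitatory and `c*N_I`
#' inhibitory presynaptic partners without replacement (no
#' self-connections). Plastic E-to-E weights start at the per-synapse
#' fixed-point value `w* = (1 + w_I - I/kappa) / (p* c N_E)` with
#' `p* = g(w_I kappa)`, multiplied by per-synapse jitter; rates start at the
#' target, the release factor at `p*`, and the sliding-threshold rate
#' estimates at the target.
#'
#' @param params A [rate_net_params()].
#' @param seed Integer seed for connectivity and jitter.
#' @return A list of class `rate_net` with elements `conn` (index matrices
#'   `exc_in_E`, `inh_in_E`, `exc_in_I`, `inh_in_I`; presynaptic partners in
#'   columns, one column per neuron), `state` (`r_E`, `r_I`, `p`, `W_EE`,
#'   `r_bar`), `w_star`, `w_max` and `params`.
#' @export
build_rate_network <- function(params, seed = 1L) {
  stopifnot(inherits(params, "rate_net_params"))
  wEI_t <- params$c * params$N_I * params$w_EI
  wIE_t <- params$c * params$N_E * params$w_IE
  wII_t <- params$c * params$N_I * params$w_II
  w_I <- wEI_t * wIE_t / (1 + wII_t)
  p_star <- release_factor(params$transfer, w_I * params$kappa)$p
  need <- 1 + w_I - params$I_mean / params$kappa
  if (need <= 0) {
    stop(sprintf(paste0("build_rate_network: background input %.3g Hz alone ",
                        "reaches or exceeds the target drive; w* would be <= 0"),
                 params$I_mean))
  }
  w_star <- need / (p_star * params$c * params$N_E)

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(substream_seed(seed, "connectivity"))
  sample_in <- function(n_targets, pool, k, exclude_self) {
    m <- matrix(0L, k, n_targets)
    for (i in seq_len(n_targets)) {
      cand <- if (exclude_self) pool[pool != i] else pool
      m[, i] <- sample(cand, k)
    }
    m
  }
  conn <- list(
    exc_in_E = sample_in(params$N_E, seq_len(params$N_E), params$k_E, TRUE),
    inh_in_E = sample_in(params$N_E, seq_len(params$N_I), params$k_I, FALSE),
    exc_in_I = sample_in(params$N_I, seq_len(params$N_E), params$k_E, FALSE),
    inh_in_I = sample_in(params$N_I, seq_len(params$N_I), params$k_I, TRUE))

  set.seed(substream_seed(seed, "jitter"))
  jit <- if (params$init_jitter > 0) {
    matrix(stats::runif(params$k_E * params$N_E,
                        1 - params$init_jitter, 1 + params$init_jitter),
           params$k_E, params$N_E)
  } else 1
  state <- list(
    r_E = rep(params$kappa, params$N_E),
    r_I = rep(wIE_t / (1 + wII_t) * params$kappa, params$N_I),
    p = p_star,
    W_EE = w_star * jit * matrix(1, params$k_E, params$N_E),
    r_bar = rep(params$kappa, params$N_E))
  structure(list(conn = conn, state = state, w_star = w_star,
                 w_max = params$w_max_factor * w_star, params = params),
            class = "rate_net")
}

#' One Euler step of the BCM rule with sliding threshold
#'
#' Reference (R-level) implementation of the plasticity update used inside
#' the simulator: for every existing synapse from presynaptic neuron `j`
#' onto postsynaptic neuron `i`,
#' `dw_ij = (dt/tau_w) (eta w0 / kappa^3) r_i r_j (r_i - r_bar_i^2 / kappa)
#' / (c N_E)`, followed by clipping to `[0, w_max]`; the sliding-threshold
#' rate estimates relax towards the current rates with time constant
#' `tau_c`. The `1/(c N_E)` factor is the same indegree normalisation the
#' weights carry: it puts the mean population weight `c N_E <w>` on the
#' population-level plasticity timescale, so the full network reduces
#' exactly to the mean-field model under homogeneous activity.
#'
#' @param state State list with `r_E`, `W_EE`, `r_bar` (as in
#'   [build_rate_network()]).
#' @param conn Connectivity list with `exc_in_E`.
#' @param params A [rate_net_params()].
#' @param dt Time step (s).
#' @param w_max Weight cap.
#' @return The state list with updated `W_EE` and `r_bar`.
#' @export
bcm_step <- function(state, conn, params, dt, w_max) {
  coef <- (dt / params$tau_w) * params$eta * params$w0 /
    (params$c * params$N_E) / params$kappa^3
  post_factor <- coef * state$r_E * (state$r_E - state$r_bar^2 / params$kappa)
  pre_rates <- matrix(state$r_E[conn$exc_in_E], nrow(conn$exc_in_E))
  dW <- sweep(pre_rates, 2, post_factor, `*`)
  state$W_EE <- pmin(pmax(state$W_EE + dW, 0), w_max)
  state$r_bar <- state$r_bar + (dt / params$tau_c) * (state$r_E - state$r_bar)
  state
}

#' Simulate the rate network
#'
#' Forward-Euler integration (default step 1 ms) of the full network: each
#' step the excitatory rates integrate their recurrent excitation (scaled by
#' the global release factor), inhibition and noisy background input;
#' inhibitory rates integrate excitation and recurrent inhibition; rates are
#' rectified and saturated at `r_max`; the release factor relaxes towards
#' the transfer function of the total weighted inhibitory activity
#' `sum_j w_EI r_I_j`; and, when plasticity is on (after the configured
#' warm-up), the BCM rule updates the E-to-E weights and the sliding
#' thresholds.
#'
#' @param net A `rate_net` from [build_rate_network()].
#' @param duration Simulated time (s).
#' @param dt Euler step (s), default 1 ms.
#' @param plasticity Enable the BCM rule (after `params$plasticity_warmup`).
#' @param seed Integer seed for the background-noise stream.
#' @param record_dt Sampling interval for population summaries (s).
#' @param record_neurons If `TRUE`, also record per-neuron excitatory rates
#'   every `record_neuron_dt` seconds.
#' @param record_neuron_dt Per-neuron sampling interval (s).
#' @param stop_on_runaway If `TRUE`, terminate early once the population
#'   mean has sat at `>= 0.95 r_max` for 5 consecutive seconds (the
#'   stability label is already determined); the trace is truncated and
#'   flagged.
#' @return An object of class `rate_trace`: list with `trace` (data.frame:
#'   `time`, `mean_rE`, `sd_rE`, `mean_rI`, `p`, `mean_wEE`), optional
#'   `rates_E` matrix (snapshots x neurons) with `rates_time`, `final`
#'   state, `runaway` flag and `params`.
#' @export
simulate_rate_network <- function(net, duration, dt = 1e-3,
                                  plasticity = FALSE, seed = 1L,
                                  record_dt = 0.1,
                                  record_neurons = FALSE,
                                  record_neuron_dt = 1,
                                  stop_on_runaway = FALSE) {
  stopifnot(inherits(net, "rate_net"), duration > 0, dt > 0)
  params <- net$params
  tr <- params$transfer_net
  kind_code <- match(tr$kind, c("none", "linear", "sigmoid", "exponential")) - 1L

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(substream_seed(seed, "background"))

  res <- simulate_rate_cpp(
    exc_in_E = net$conn$exc_in_E - 1L, inh_in_E = net$conn$inh_in_E - 1L,
    exc_in_I = net$conn$exc_in_I - 1L, inh_in_I = net$conn$inh_in_I - 1L,
    W_EE = net$state$W_EE,
    r_E = net$state$r_E, r_I = net$state$r_I,
    p0 = net$state$p, r_bar = net$state$r_bar,
    w_EI = params$w_EI, w_IE = params$w_IE, w_II = params$w_II,
    I_mean = params$I_mean, noise_sd = params$noise_rel_sd * params$I_mean,
    noise_static = params$noise_mode == "static",
    r_max = params$r_max,
    tau_E = params$tau_E, tau_I = params$tau_I, tau_p = params$tau_p,
    kind = kind_code, g_par = c(tr$beta, tr$beta_s, tr$r_shift, tr$beta_e),
    kappa = params$kappa, eta = params$eta, w0 = params$w0,
    plast_scale = 1 / (params$c * params$N_E),
    tau_w = params$tau_w, tau_c = params$tau_c, w_max = net$w_max,
    duration = duration, dt = dt,
    plasticity = plasticity,
    warmup = if (plasticity) params$plasticity_warmup else Inf,
    record_every = max(1L, as.integer(round(record_dt / dt))),
    neuron_every = if (record_neurons) {
      max(1L, as.integer(round(record_neuron_dt / dt)))
    } else 0L,
    stop_on_runaway = stop_on_runaway)

  trace <- as.data.frame(res$trace)
  names(trace) <- c("time", "mean_rE", "sd_rE", "mean_rI", "p", "mean_wEE")
  out <- list(trace = trace,
              rates_E = res$rates_E, rates_time = res$rates_time,
              final = list(r_E = res$r_E, r_I = res$r_I, p = res$p,
                           W_EE = res$W_EE, r_bar = res$r_bar),
              runaway = res$runaway, params = params)
  class(out) <- "rate_trace"
  out
}

#' @export
print.rate_trace <- function(x, ...) {
  n <- nrow(x$trace)
  tail_w <- x$trace[x$trace$time >= 0.8 * x$trace$time[n], ]
  cat(sprintf(paste0("<rate_trace> %.4g s simulated (%d samples)%s\n",
                     "  final-window mean rate: %.4g Hz; p: %.4g; mean w_EE: %.5g\n"),
              x$trace$time[n], n, if (x$runaway) " [runaway, stopped early]" else "",
              mean(tail_w$mean_rE), mean(tail_w$p), mean(tail_w$mean_wEE)))
  invisible(x)
}
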