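# Experiment drivers: stability classification, recurrence and homeostasis
# scans, and single-neuron rate statistics.

new_scan_outcome <- function(points, parameter, bracket, prediction = NULL) {
  structure(list(points = points, parameter = parameter,
                 bracket = bracket, prediction = prediction),
            class = "scan_outcome")
}

#' @export
print.scan_outcome <- function(x, ...) {
  cat(sprintf("<scan_outcome> %s over %d grid points\n",
              x$parameter, nrow(x$points)))
  print(x$points, row.names = FALSE)
  if (!all(is.na(x$bracket))) {
    cat(sprintf("  bracket: largest stable = %s, smallest unstable = %s\n",
                format(x$bracket[1]), format(x$bracket[2])))
  }
  if (!is.null(x$prediction)) {
    cat(sprintf("  analytic prediction: %.6g\n", x$prediction))
  }
  invisible(x)
}

#' Classify the stability regime of a simulation
#'
#' Operationalises the three dynamical regimes of the plastic network over
#' the final window of a run (default the last 20%):
#' `"target"` if the time-averaged population rate is within `tol_frac` of
#' the target `kappa` and the across-neuron rate SD stays below `kappa`;
#' `"runaway"` if the mean rate exceeds `0.9 r_max` (activity pinned at the
#' saturation/refractory ceiling); otherwise `"fluctuating-low"` (mean rate
#' stays low but single-neuron rates spread widely).
#'
#' @param trace A `rate_trace` from [simulate_rate_network()], or a
#'   data.frame with columns `time`, `mean_rE` and optionally `sd_rE`.
#' @param kappa Target rate (Hz).
#' @param tol_frac Relative tolerance on the mean rate (default 0.1).
#' @param window_frac Fraction of the run used as the final window.
#' @param r_max Saturation rate (Hz).
#' @return `"target"`, `"runaway"` or `"fluctuating-low"`.
#' @export
classify_stability <- function(trace, kappa, tol_frac = 0.1,
                               window_frac = 0.2, r_max = 200) {
  runaway_flag <- FALSE
  if (inherits(trace, "rate_trace")) {
    runaway_flag <- isTRUE(trace$runaway)
    trace <- trace$trace
  }
  stopifnot(all(c("time", "mean_rE") %in% names(trace)))
  if (runaway_flag) return("runaway")
  t_end <- trace$time[nrow(trace)]
  if (window_frac >= 0.5) stop("classify_stability: window longer than half the trace")
  win <- trace[trace$time >= (1 - window_frac) * t_end, , drop = FALSE]
  if (nrow(win) < 2) stop("classify_stability: trace shorter than 2x the window")
  m <- mean(win$mean_rE)
  if (m > 0.9 * r_max) return("runaway")
  sd_ok <- if ("sd_rE" %in% names(win)) mean(win$sd_rE) < kappa else TRUE
  if (abs(m - kappa) <= tol_frac * kappa && sd_ok) "target" else "fluctuating-low"
}

#' Population rate as a function of excitatory recurrence
#'
#' Sweeps the mean E-to-E weight with plasticity off and records the
#' steady-state (mean-field: analytic; networks: time-averaged after a
#' discard period) population rate. Without presynaptic inhibition the rate
#' diverges once the recurrence exceeds `1 + w_I`; with it the curve rises
#' gradually and saturates.
#'
#' @param model `"meanfield"`, `"rate"` or `"spiking"`.
#' @param params A [meanfield_params()], [rate_net_params()] or
#'   [spiking_params()] matching `model`.
#' @param w_grid Mean population E-to-E weights to scan (for the spiking
#'   model: per-synapse `w_EE` values).
#' @param duration,discard Simulated seconds per point and initial seconds
#'   discarded before averaging (network models).
#' @param seed Integer seed.
#' @return A `scan_outcome` whose `points` hold the grid, the measured mean
#'   rate, a stability label (`"finite"`/`"divergent"` by saturation), and
#'   for the mean-field model the analytic rate.
#' @export
scan_recurrence <- function(model = c("meanfield", "rate", "spiking"),
                            params, w_grid,
                            duration = 20, discard = 5, seed = 1L) {
  model <- match.arg(model)
  rows <- lapply(w_grid, function(w) {
    if (model == "meanfield") {
      pp <- params
      pp$w_tilde_EE <- w
      ss <- steady_state(pp)
      data.frame(w = w, mean_rate = ss$r_E,
                 label = if (ss$exists && !ss$saturated) "finite" else "divergent",
                 analytic = ss$r_E)
    } else if (model == "rate") {
      pp <- params
      net <- build_rate_network_at(pp, w, seed)
      sim <- simulate_rate_network(net, duration = duration, plasticity = FALSE,
                                   seed = seed)
      win <- sim$trace[sim$trace$time >= discard, ]
      m <- mean(win$mean_rE)
      data.frame(w = w, mean_rate = m,
                 label = if (m >= 0.95 * pp$r_max) "divergent" else "finite",
                 analytic = NA_real_)
    } else {
      net <- build_spiking_network(params, seed)
      sim <- simulate_spiking(net, duration = duration, plasticity = FALSE,
                              w_init = w, seed = seed, record_spikes = FALSE)
      keep <- sim$bin_time >= discard
      m <- mean(sim$rate_E[keep])
      r_ceiling <- 1 / params$tau_ref
      data.frame(w = w, mean_rate = m,
                 label = if (m >= 0.9 * r_ceiling) "divergent" else "finite",
                 analytic = NA_real_)
    }
  })
  points <- do.call(rbind, rows)
  new_scan_outcome(points, parameter = "w_EE", bracket = c(NA_real_, NA_real_))
}

# Rate network whose mean population recurrence is w_tilde (per-synapse
# weight w_tilde / (c N_E)), bypassing the fixed-point initialisation.
build_rate_network_at <- function(params, w_tilde, seed) {
  net <- build_rate_network(params, seed = seed)
  scale <- (w_tilde / (params$c * params$N_E)) / mean(net$state$W_EE)
  net$state$W_EE <- net$state$W_EE * scale
  net
}

#' Critical-homeostatic-timescale scan
#'
#' Runs the plastic network for each homeostatic time constant in
#' `tau_c_grid`, classifies the outcome with [classify_stability()], and
#' reports the bracket (largest `tau_c` labelled `"target"`, smallest
#' labelled otherwise). For the rate model the mean-field prediction
#' [critical_timescale()] is attached.
#'
#' @param model `"rate"` or `"spiking"`.
#' @param params A [rate_net_params()] or [spiking_params()].
#' @param tau_c_grid Homeostatic time constants to test (s), ascending.
#' @param duration Simulated seconds per grid point (including the
#'   plasticity warm-up).
#' @param seed Integer seed (same connectivity/jitter across grid points).
#' @param stop_on_runaway Allow early termination of saturated runs.
#' @param tol_frac,window_frac Passed to [classify_stability()].
#' @return A `scan_outcome`: per-point final mean rate and label, the
#'   stability bracket, and the analytic prediction where available.
#' @export
scan_homeostasis <- function(model = c("rate", "spiking"), params, tau_c_grid,
                             duration = 1800, seed = 1L,
                             stop_on_runaway = TRUE,
                             tol_frac = 0.1, window_frac = 0.2) {
  model <- match.arg(model)
  stopifnot(!is.unsorted(tau_c_grid))
  rows <- lapply(tau_c_grid, function(tc) {
    pp <- params
    pp$tau_c <- tc
    res <- tryCatch({
      if (model == "rate") {
        net <- build_rate_network(pp, seed = seed)
        sim <- simulate_rate_network(net, duration = duration,
                                     plasticity = TRUE, seed = seed,
                                     stop_on_runaway = stop_on_runaway)
        lab <- classify_stability(sim, kappa = pp$kappa, tol_frac = tol_frac,
                                  window_frac = window_frac, r_max = pp$r_max)
        win <- sim$trace[sim$trace$time >= (1 - window_frac) *
                           max(sim$trace$time), ]
        list(rate = mean(win$mean_rE), label = lab)
      } else {
        net <- build_spiking_network(pp, seed = seed)
        sim <- simulate_spiking(net, duration = duration, plasticity = TRUE,
                                seed = seed, record_spikes = FALSE)
        keep <- sim$bin_time >= (1 - window_frac) * duration
        m <- mean(sim$rate_E[keep])
        r_ceiling <- 1 / pp$tau_ref
        sd_n <- stats::sd(sim$mean_rate_E)
        lab <- if (m > 0.9 * r_ceiling) "runaway"
          else if (abs(m - pp$kappa) <= tol_frac * pp$kappa &&
                   sd_n < pp$kappa) "target" else "fluctuating-low"
        list(rate = m, label = lab)
      }
    }, error = function(e) list(rate = NA_real_, label = "runaway"))
    data.frame(tau_c = tc, mean_rate = res$rate, label = res$label)
  })
  points <- do.call(rbind, rows)
  stable <- points$tau_c[points$label == "target"]
  unstable <- points$tau_c[points$label != "target"]
  bracket <- c(if (length(stable)) max(stable) else NA_real_,
               if (length(unstable)) min(unstable) else NA_real_)
  prediction <- if (model == "rate") {
    tryCatch(critical_timescale(as_meanfield(params)), error = function(e) NULL)
  } else NULL
  new_scan_outcome(points, parameter = "tau_c", bracket = bracket,
                   prediction = prediction)
}

#' Single-neuron rate statistics of a per-neuron trace
#'
#' Summarises the heterogeneity and turnover of single-neuron firing rates:
#' rate histogram and across-neuron SD, the mean per-neuron temporal
#' autocorrelation function, and a turnover index defined as the Spearman
#' rank correlation of per-neuron mean rates between two time windows
#' (1 = the same neurons stay the most active; 0 = complete reshuffling).
#'
#' @param rates Matrix of per-neuron rates, snapshots in rows, neurons in
#'   columns (e.g. `rates_E` from [simulate_rate_network()]).
#' @param times Snapshot times (s).
#' @param window_pair List of two `c(start, end)` windows (s) for the
#'   turnover index; default first and last quarter.
#' @param n_lags Number of autocorrelation lags (in snapshots).
#' @param breaks Histogram breaks (passed to [graphics::hist()] logic via
#'   [base::cut()]); default 30 equal-width bins.
#' @return An object of class `rate_summary`: `mean_rate`, `sd_across`,
#'   `histogram` (data.frame `mid`, `count`), `autocorrelation` (data.frame
#'   `lag_s`, `acf`; `NA` with `constant = TRUE` when every series is
#'   constant), `turnover`.
#' @export
rate_summary <- function(rates, times, window_pair = NULL,
                         n_lags = 20, breaks = 30) {
  stopifnot(is.matrix(rates), nrow(rates) == length(times))
  per_neuron_mean <- colMeans(rates)
  if (is.null(window_pair)) {
    t_end <- times[length(times)]
    window_pair <- list(c(0, t_end / 4), c(3 * t_end / 4, t_end))
  }
  in_win <- function(w) times >= w[1] & times <= w[2]
  m1 <- colMeans(rates[in_win(window_pair[[1]]), , drop = FALSE])
  m2 <- colMeans(rates[in_win(window_pair[[2]]), , drop = FALSE])
  turnover <- if (stats::sd(m1) == 0 && stats::sd(m2) == 0 &&
                  all(m1 == m2)) 1 else
    suppressWarnings(stats::cor(m1, m2, method = "spearman"))

  h <- hist_counts(per_neuron_mean, breaks)

  variable <- apply(rates, 2, function(x) stats::sd(x) > 0)
  n_lags <- min(n_lags, nrow(rates) - 1)
  if (!any(variable) || n_lags < 1) {
    acf_df <- data.frame(lag_s = NA_real_, acf = NA_real_)
    constant <- TRUE
  } else {
    acfs <- vapply(which(variable), function(j) {
      stats::acf(rates[, j], lag.max = n_lags, plot = FALSE,
                 demean = TRUE)$acf[, 1, 1]
    }, numeric(n_lags + 1))
    lag_s <- (0:n_lags) * mean(diff(times))
    acf_df <- data.frame(lag_s = lag_s, acf = rowMeans(acfs))
    constant <- FALSE
  }
  structure(list(mean_rate = mean(per_neuron_mean),
                 sd_across = stats::sd(per_neuron_mean),
                 histogram = h, autocorrelation = acf_df,
                 constant = constant, turnover = turnover),
            class = "rate_summary")
}

hist_counts <- function(x, breaks) {
  if (length(unique(x)) == 1) {
    return(data.frame(mid = x[1], count = length(x)))
  }
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf(paste0("<rate_summary> mean rate %.4g Hz, across-neuron SD ",
                     "%.4g Hz, turnover %.3g%s\n"),
              x$mean_rate, x$sd_across, x$turnover,
              if (x$constant) " (constant series: autocorrelation undefined)"
              else ""))
  invisible(x)
}
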