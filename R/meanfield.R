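#' Mean-field parameters for the two-population rate model
#'
#' Bundles the population-level weights, input, target rate, time constants
#' and the presynaptic-inhibition transfer function of the mean population
#' rate model. Defaults reproduce the reference rate network: population
#' weights `w_tilde_EI = 1`, `w_tilde_IE = 1.5`, `w_tilde_II = 0.5` (so the
#' total recruited inhibition is `w_I = w_tilde_EI * w_tilde_IE /
#' (1 + w_tilde_II) = 1`), background input `I = 0.5` Hz, target rate
#' `kappa = 5` Hz, learning-rate multiplier `eta = 5`, initial-weight scale
#' `w0 = 1`, plasticity time constant `tau_w = 300` s (so the effective
#' plasticity timescale is `tau_plast = tau_w / (eta * w0) = 60` s).
#'
#' @param w_tilde_EE Mean E-to-E population weight (the recurrence `w`). If
#'   `NA` (default), it is set so that the target rate `kappa` is a fixed
#'   point (see [required_recurrence()]).
#' @param w_tilde_EI,w_tilde_IE,w_tilde_II Fixed population weights.
#' @param I Mean background input (Hz).
#' @param kappa Target rate (Hz).
#' @param eta Learning-rate multiplier.
#' @param w0 Initial-weight scale.
#' @param tau_E,tau_I,tau_p Fast time constants (s): excitatory and
#'   inhibitory rate relaxation and the release-factor (GABA-B) filter.
#' @param tau_w Plasticity time constant (s).
#' @param tau_c Homeostatic (sliding-threshold) time constant (s).
#' @param r_max Rate saturation (Hz).
#' @param transfer A [transfer_spec()].
#' @param variant Circuit motif the release factor acts on: `"ee"` scales the
#'   recurrent E-to-E weight only (default); `"inh_onto_exc"` additionally
#'   scales I-to-E; `"exc_onto_inh"` additionally scales E-to-I;
#'   `"all_recurrent"` scales all four recurrent weights; `"input"`
#'   additionally scales the background input.
#' @return An object of class `meanfield_params`.
#' @export
meanfield_params <- function(w_tilde_EE = NA_real_, w_tilde_EI = 1,
                             w_tilde_IE = 1.5, w_tilde_II = 0.5,
                             I = 0.5, kappa = 5, eta = 5, w0 = 1,
                             tau_E = 0.02, tau_I = 0.01, tau_p = 0.5,
                             tau_w = 300, tau_c = 30, r_max = 200,
                             transfer = transfer_spec("linear", beta = 0.05),
                             variant = c("ee", "inh_onto_exc", "exc_onto_inh",
                                         "all_recurrent", "input")) {
  variant <- match.arg(variant)
  stopifnot(inherits(transfer, "transfer_spec"),
            tau_E > 0, tau_I > 0, tau_p > 0, tau_w > 0, tau_c > 0,
            r_max > kappa, kappa > 0, eta > 0, w0 > 0, I >= 0,
            w_tilde_EI >= 0, w_tilde_IE >= 0, w_tilde_II >= 0)
  p <- list(w_tilde_EE = w_tilde_EE, w_tilde_EI = w_tilde_EI,
            w_tilde_IE = w_tilde_IE, w_tilde_II = w_tilde_II,
            I = I, kappa = kappa, eta = eta, w0 = w0,
            tau_E = tau_E, tau_I = tau_I, tau_p = tau_p,
            tau_w = tau_w, tau_c = tau_c, r_max = r_max,
            transfer = transfer, variant = variant)
  class(p) <- "meanfield_params"
  if (is.na(w_tilde_EE)) {
    p$w_tilde_EE <- required_recurrence(p)
  }
  p
}

#' @export
print.meanfield_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<meanfield_params> w = %.4g, w_I = %.4g, I = %g Hz, kappa = %g Hz\n",
    "  tau: E %g, I %g, p %g, w %g, c %g s; tau_plast = %g s; variant = %s\n"),
    x$w_tilde_EE, total_inhibition(x), x$I, x$kappa,
    x$tau_E, x$tau_I, x$tau_p, x$tau_w, x$tau_c, tau_plast(x), x$variant))
  print(x$transfer)
  invisible(x)
}

#' Total inhibition recruited through the inhibitory population
#'
#' `w_I = w_tilde_EI * w_tilde_IE / (1 + w_tilde_II)`: the effective
#' inhibitory weight felt by the excitatory population once the inhibitory
#' rate has settled to its steady state `r_I = w_tilde_IE / (1 + w_tilde_II)
#' * r_E`.
#'
#' @param params A [meanfield_params()].
#' @return Scalar `w_I` (unitless).
#' @export
total_inhibition <- function(params) {
  stopifnot(inherits(params, "meanfield_params"))
  params$w_tilde_EI * params$w_tilde_IE / (1 + params$w_tilde_II)
}

#' Effective plasticity timescale `tau_w / (eta * w0)`
#' @param params A [meanfield_params()].
#' @return Scalar (s).
#' @export
tau_plast <- function(params) {
  stopifnot(inherits(params, "meanfield_params"))
  params$tau_w / (params$eta * params$w0)
}

# Release factor seen by the excitatory population when its own rate is r_E
# (inhibitory steady state folded in: argument is w_I * r_E).
p_at_rate <- function(params, r_E) {
  release_factor(params$transfer, total_inhibition(params) * r_E)
}

#' Steady-state rates of the mean-field model
#'
#' Computes the fixed point of the two-population rate model with the release
#' factor at its own steady state. For the linear transfer and the default
#' `"ee"` motif the positive root of the quadratic self-consistency equation
#' is used (the negative-root branch never yields positive rates); when the
#' input is strong enough that the release factor clips to zero the rate
#' reduces to `I / (1 + w_I)`; with transfer `"none"` the familiar
#' `I / (1 - w + w_I)` applies and the fixed point ceases to exist once
#' `w >= 1 + w_I` (runaway; `exists = FALSE`, rates pinned at `r_max`).
#' Sigmoid/exponential transfers and the alternative circuit motifs are
#' solved numerically.
#'
#' @param params A [meanfield_params()].
#' @return An object of class `steady_state`: list with `r_E`, `r_I` (Hz),
#'   `p` (release factor), `exists` (finite fixed point), `saturated`
#'   (`TRUE` when the solution sits at `r_max`), and `method`.
#' @export
steady_state <- function(params) {
  stopifnot(inherits(params, "meanfield_params"))
  w   <- params$w_tilde_EE
  w_I <- total_inhibition(params)
  I   <- params$I
  tr  <- params$transfer

  if (params$variant != "ee" || !(tr$kind %in% c("none", "linear"))) {
    return(steady_state_numeric(params))
  }

  if (tr$kind == "none") {
    if (w >= 1 + w_I) {
      return(new_steady_state(params$r_max, rI_of_rE(params, params$r_max), 1,
                              exists = FALSE, saturated = TRUE,
                              method = "closed_form"))
    }
    r_E <- I / (1 - w + w_I)
    return(finish_steady_state(params, r_E, method = "closed_form"))
  }

  # linear transfer, "ee" motif
  beta <- tr$beta
  if (beta == 0) {
    params2 <- params
    params2$transfer <- transfer_spec("none")
    return(steady_state(params2))
  }
  if (w_I > 0 && I >= (1 + w_I) / (beta * w_I)) {
    # release factor fully suppressed: p = 0, recurrence decoupled
    r_E <- I / (1 + w_I)
    return(finish_steady_state(params, r_E, method = "closed_form_p0"))
  }
  if (w == 0) {
    r_E <- I / (1 + w_I)
  } else {
    disc <- (w - 1 - w_I)^2 + 4 * beta * w * w_I * I
    r_E <- (w - 1 - w_I + sqrt(disc)) / (2 * beta * w_I * w)
  }
  finish_steady_state(params, r_E, method = "closed_form")
}

new_steady_state <- function(r_E, r_I, p, exists, saturated, method) {
  structure(list(r_E = r_E, r_I = r_I, p = p, exists = exists,
                 saturated = saturated, method = method),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state> r_E = %.6g Hz, r_I = %.6g Hz, p = %.6g%s%s (%s)\n",
              x$r_E, x$r_I, x$p,
              if (!x$exists) " [no finite fixed point]" else "",
              if (x$saturated) " [saturated]" else "", x$method))
  invisible(x)
}

rI_of_rE <- function(params, r_E) {
  pmin(params$r_max,
       params$w_tilde_IE / (1 + params$w_tilde_II) * r_E)
}

finish_steady_state <- function(params, r_E, method) {
  saturated <- r_E >= params$r_max
  r_E <- min(max(r_E, 0), params$r_max)
  p <- p_at_rate(params, r_E)$p
  new_steady_state(r_E, rI_of_rE(params, r_E), p,
                   exists = TRUE, saturated = saturated, method = method)
}

# Numeric fixed point: default motif via a bracketing root solve on the
# self-consistency residual; S1 motifs via adaptively damped iteration on the
# coupled (r_E, r_I) maps (no closed form exists there).
steady_state_numeric <- function(params, tol = 1e-12, max_iter = 1e5) {
  w   <- params$w_tilde_EE
  w_I <- total_inhibition(params)
  I   <- params$I
  r_max <- params$r_max

  if (params$variant == "ee") {
    resid <- function(r) {
      p <- p_at_rate(params, r)$p
      min(max(p * w * r - w_I * r + I, 0), r_max) - r
    }
    lo <- 0
    if (resid(r_max) >= 0) {
      # drive exceeds saturation: pinned at r_max
      return(finish_steady_state(params, r_max, method = "numeric"))
    }
    if (resid(lo) < 0) {
      return(finish_steady_state(params, 0, method = "numeric"))
    }
    sol <- stats::uniroot(resid, c(lo, r_max), tol = tol, maxiter = 1000)
    return(finish_steady_state(params, sol$root, method = "numeric"))
  }

  # circuit-motif variants: release factor multiplies different weight classes
  sc <- variant_scaling(params$variant)
  wEI <- params$w_tilde_EI; wIE <- params$w_tilde_IE; wII <- params$w_tilde_II
  clip <- function(x) min(max(x, 0), r_max)
  map <- function(st) {
    p <- release_factor(params$transfer, wEI * st[2])$p
    s <- function(on) if (on) p else 1
    c(clip(s(sc["ee"]) * w * st[1] - s(sc["ei"]) * wEI * st[2] + s(sc["in"]) * I),
      clip(s(sc["ie"]) * wIE * st[1] - s(sc["ii"]) * wII * st[2]))
  }
  st <- c(params$kappa, wIE / (1 + wII) * params$kappa)
  relax <- 0.5
  prev_delta <- Inf
  for (it in seq_len(max_iter)) {
    st_new <- (1 - relax) * st + relax * map(st)
    delta <- max(abs(st_new - st))
    if (delta > prev_delta * 1.05 && relax > 1e-3) relax <- relax / 2
    prev_delta <- delta
    st <- st_new
    if (delta < 1e-11) break
  }
  if (prev_delta >= 1e-8) {
    stop(sprintf("steady_state: numeric solve did not converge (residual %.3g)",
                 prev_delta))
  }
  p <- release_factor(params$transfer, wEI * st[2])$p
  new_steady_state(st[1], st[2], p, exists = TRUE,
                   saturated = st[1] >= r_max, method = "numeric_variant")
}

variant_scaling <- function(variant) {
  base <- c(ee = TRUE, ei = FALSE, ie = FALSE, ii = FALSE, `in` = FALSE)
  switch(variant,
    ee            = base,
    inh_onto_exc  = replace(base, "ei", TRUE),
    exc_onto_inh  = replace(base, "ie", TRUE),
    all_recurrent = c(ee = TRUE, ei = TRUE, ie = TRUE, ii = TRUE, `in` = FALSE),
    input         = replace(base, "in", TRUE),
    stop("unknown circuit variant: ", variant))
}

#' Asymptotic excitatory rate for unbounded recurrence (linear transfer)
#'
#' With linear presynaptic inhibition the excitatory steady-state rate is
#' bounded in the recurrent weight: as `w` grows without bound the rate
#' approaches `1 / (beta * w_I)` provided the input is moderate
#' (`I < (1 + w_I) / (beta * w_I)`); for stronger inputs the release factor
#' clips to zero and the rate is the recurrence-independent `I / (1 + w_I)`.
#'
#' @param params A [meanfield_params()] with linear transfer.
#' @return Asymptotic rate (Hz).
#' @export
asymptotic_rate <- function(params) {
  stopifnot(inherits(params, "meanfield_params"))
  tr <- params$transfer
  if (tr$kind != "linear") {
    stop("asymptotic_rate: defined for the linear transfer function")
  }
  w_I <- total_inhibition(params)
  if (tr$beta == 0 || w_I == 0) {
    stop("asymptotic_rate: rate grows without bound when beta or w_I is zero")
  }
  bound <- (1 + w_I) / (tr$beta * w_I)
  if (params$I >= bound) params$I / (1 + w_I) else 1 / (tr$beta * w_I)
}

#' Recurrent weight that places the fixed point at the target rate
#'
#' Returns the mean E-to-E population weight `w` for which `r_E = kappa` is a
#' steady state: `w = (1 + w_I - I / kappa) / p*` with `p* = g(w_I * kappa)`
#' (and `p* = 1` for transfer `"none"`). The networks are initialised at this
#' weight.
#'
#' @param params A [meanfield_params()].
#' @return Scalar weight. Returns 0 when the input alone reaches the target
#'   (`I = kappa * (1 + w_I)`); errors when the input exceeds it.
#' @export
required_recurrence <- function(params) {
  stopifnot(inherits(params, "meanfield_params"))
  w_I <- total_inhibition(params)
  need <- 1 + w_I - params$I / params$kappa
  if (need < 0) {
    stop("required_recurrence: background input exceeds the target drive; ",
         "no positive recurrence is needed")
  }
  p_star <- p_at_rate(params, params$kappa)$p
  if (need > 0 && p_star <= 0) {
    stop("required_recurrence: release factor is fully suppressed at the ",
         "target rate; the target cannot be reached through recurrence")
  }
  if (need == 0) 0 else need / p_star
}

#' Sensitivity of the steady-state rate to the recurrent weight
#'
#' Evaluates `dr_E/dw` of the fast-subsystem fixed point, the quantity
#' through which slow weight changes move the rate once the fast variables
#' have equilibrated (timescale separation):
#' `dr_E/dw = g(w_I r_E) r_E^2 / (I - (g'/g)(w_I r_E) * w_I r_E *
#' (r_E + w_I r_E - I))`. For transfer `"none"` this reduces to `r_E^2 / I`.
#'
#' @param params A [meanfield_params()].
#' @param r_E Excitatory rate (Hz) at which to evaluate.
#' @return Sensitivity (Hz per unit weight).
#' @export
rate_sensitivity <- function(params, r_E) {
  stopifnot(inherits(params, "meanfield_params"), r_E >= 0)
  w_I <- total_inhibition(params)
  g <- p_at_rate(params, r_E)
  if (g$p <= 0) stop("rate_sensitivity: release factor is zero at this rate")
  denom <- params$I -
    (g$dp_dr / g$p) * w_I * r_E * (r_E + w_I * r_E - params$I)
  if (abs(denom) < .Machine$double.eps * 100) {
    stop("rate_sensitivity: singular sensitivity (zero denominator)")
  }
  g$p * r_E^2 / denom
}

#' Auxiliary stability constant of the reduced system
#'
#' The constant `Psi = (eta * w0 / kappa^3) * g(w_I kappa) / (I - (g'/g)
#' (w_I kappa) * w_I kappa * (kappa + w_I kappa - I))` collects the local
#' gain of the plasticity-rate feedback loop at the target-rate fixed point;
#' it is strictly positive for moderate input (`I < kappa (1 + w_I)`) and
#' sets the critical homeostatic timescale `tau_w / (Psi kappa^4)`.
#'
#' @param params A [meanfield_params()].
#' @return Scalar `Psi`.
#' @export
psi_constant <- function(params) {
  stopifnot(inherits(params, "meanfield_params"))
  kappa <- params$kappa
  w_I <- total_inhibition(params)
  g <- p_at_rate(params, kappa)
  if (g$p <= 0) stop("psi_constant: release factor is zero at the target rate")
  denom <- params$I -
    (g$dp_dr / g$p) * w_I * kappa * (kappa + w_I * kappa - params$I)
  if (denom <= 0) {
    stop("psi_constant: nonpositive denominator; outside the validity ",
         "regime of the linearised analysis")
  }
  (params$eta * params$w0 / kappa^3) * g$p / denom
}

#' Eigenvalues of the reduced plasticity-homeostasis system
#'
#' Linearises the two-dimensional slow system (excitatory rate and its
#' homeostatic running average) around the target-rate fixed point and
#' returns the two eigenvalues, i.e. the roots of
#' `lambda^2 + (tau_w - Psi kappa^4 tau_c) / (tau_w tau_c) lambda +
#' Psi kappa^4 / (tau_w tau_c) = 0`.
#' The fixed point is stable iff both real parts are negative; a zero real
#' part (the stability boundary) is reported as unstable with `boundary =
#' TRUE`.
#'
#' @param params A [meanfield_params()].
#' @param tau_c Homeostatic time constant (s). Defaults to `params$tau_c`.
#' @return An object of class `stability_report`: `psi`, `eigenvalues`
#'   (complex pair, 1/s), `tau_c_crit` (s), `stable`, `boundary`.
#' @export
linearised_eigenvalues <- function(params, tau_c = params$tau_c) {
  stopifnot(inherits(params, "meanfield_params"))
  if (!is.finite(tau_c) || tau_c <= 0) {
    stop("linearised_eigenvalues: tau_c must be positive")
  }
  psi <- psi_constant(params)
  tw <- params$tau_w
  k4 <- params$kappa^4
  b <- (tw - psi * k4 * tau_c) / (tw * tau_c)
  cc <- psi * k4 / (tw * tau_c)
  disc <- complex(real = b^2 - 4 * cc)
  lam <- (-b + c(1, -1) * sqrt(disc)) / 2
  max_re <- max(Re(lam))
  structure(list(psi = psi, eigenvalues = lam,
                 tau_c_crit = tw / (psi * k4),
                 stable = max_re < 0,
                 boundary = abs(max_re) < 1e-12 * max(abs(b), sqrt(cc))),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(paste0("<stability_report> %s%s; tau_c_crit = %.6g s\n",
                     "  eigenvalues: %.4g%+.4gi, %.4g%+.4gi (1/s); Psi = %.6g\n"),
              if (x$stable) "stable" else "unstable",
              if (x$boundary) " (boundary)" else "",
              x$tau_c_crit,
              Re(x$eigenvalues[1]), Im(x$eigenvalues[1]),
              Re(x$eigenvalues[2]), Im(x$eigenvalues[2]), x$psi))
  invisible(x)
}

#' Critical homeostatic timescale
#'
#' The largest homeostatic time constant for which the target-rate fixed
#' point of the coupled plasticity-rate system is linearly stable:
#' `tau_c_crit = tau_w / (Psi kappa^4)`. Without presynaptic inhibition this
#' reduces to `tau_plast * I / kappa`, showing that for weak input the
#' homeostat must run an order of magnitude faster than plasticity itself;
#' presynaptic inhibition multiplies the admissible timescale.
#'
#' @param params A [meanfield_params()].
#' @return Critical timescale (s).
#' @export
critical_timescale <- function(params) {
  stopifnot(inherits(params, "meanfield_params"))
  params$tau_w / (psi_constant(params) * params$kappa^4)
}

#' Simulate the mean-field model
#'
#' Forward-Euler integration of either the full five-variable system
#' (excitatory rate, inhibitory rate, release factor, mean recurrent weight,
#' homeostatic rate estimate) or the reduced two-variable slow system (rate
#' and rate estimate, with the fast variables assumed equilibrated). Rates
#' are clipped to `[0, r_max]` and the release factor to `[0, 1]` at every
#' step.
#'
#' @param params A [meanfield_params()].
#' @param duration Simulated time (s).
#' @param dt Euler step (s), default 1 ms.
#' @param plasticity If `FALSE` the recurrent weight is frozen (full mode
#'   only; the reduced system is intrinsically plastic).
#' @param mode `"full_5d"` or `"reduced_2d"`.
#' @param initial Optional named list overriding initial values (`r_E`,
#'   `r_I`, `p`, `w`, `r_bar`); defaults to the steady state at
#'   `params$w_tilde_EE`.
#' @param record_dt Sampling interval of the returned trace (s).
#' @return An object of class `meanfield_trace`: data.frame with columns
#'   `time`, `r_E`, `r_I`, `p`, `w`, `r_bar`, plus attributes `mode` and
#'   `params`.
#' @export
simulate_meanfield <- function(params, duration, dt = 1e-3,
                               plasticity = TRUE,
                               mode = c("full_5d", "reduced_2d"),
                               initial = NULL, record_dt = dt) {
  stopifnot(inherits(params, "meanfield_params"), duration > 0, dt > 0)
  mode <- match.arg(mode)
  if (mode == "reduced_2d" && params$variant != "ee") {
    stop("simulate_meanfield: the reduced system is derived for the ",
         "default 'ee' motif only")
  }
  if (dt > 0.5 * min(params$tau_E, params$tau_I, params$tau_p)) {
    stop("simulate_meanfield: dt too large relative to the fast time constants")
  }
  ss <- steady_state(params)
  st <- list(r_E = ss$r_E, r_I = ss$r_I, p = ss$p,
             w = params$w_tilde_EE, r_bar = ss$r_E)
  for (nm in names(initial)) {
    if (!nm %in% names(st)) stop("simulate_meanfield: unknown initial value ", nm)
    st[[nm]] <- initial[[nm]]
  }
  n_steps <- ceiling(duration / dt)
  rec_every <- max(1L, round(record_dt / dt))
  n_rec <- floor(n_steps / rec_every) + 1L
  out <- matrix(NA_real_, n_rec, 6,
                dimnames = list(NULL, c("time", "r_E", "r_I", "p", "w", "r_bar")))
  w_I <- total_inhibition(params)
  wEI <- params$w_tilde_EI; wIE <- params$w_tilde_IE; wII <- params$w_tilde_II
  kappa <- params$kappa
  plast_coef <- params$eta * params$w0 / kappa^3
  clip_r <- function(x) min(max(x, 0), params$r_max)
  sc <- variant_scaling(params$variant)

  rec_i <- 1L
  out[1L, ] <- c(0, st$r_E, st$r_I, st$p, st$w, st$r_bar)
  for (step in seq_len(n_steps)) {
    if (mode == "full_5d") {
      pm <- function(on) if (on) st$p else 1
      d_rE <- (-st$r_E + pm(sc["ee"]) * st$w * st$r_E -
                 pm(sc["ei"]) * wEI * st$r_I + pm(sc["in"]) * params$I) / params$tau_E
      d_rI <- (-st$r_I + pm(sc["ie"]) * wIE * st$r_E -
                 pm(sc["ii"]) * wII * st$r_I) / params$tau_I
      g <- release_factor(params$transfer, wEI * st$r_I)$p
      d_p <- (-st$p + g) / params$tau_p
      d_w <- if (plasticity) {
        plast_coef * st$r_E^2 * (st$r_E - st$r_bar^2 / kappa) / params$tau_w
      } else 0
      d_rb <- (-st$r_bar + st$r_E) / params$tau_c
      st$r_E <- clip_r(st$r_E + dt * d_rE)
      st$r_I <- clip_r(st$r_I + dt * d_rI)
      st$p <- min(max(st$p + dt * d_p, 0), 1)
      st$w <- st$w + dt * d_w
      st$r_bar <- st$r_bar + dt * d_rb
    } else {
      sens_num <- p_at_rate(params, st$r_E)
      if (sens_num$p <= 0) {
        stop(sprintf("simulate_meanfield: release factor hit zero at t = %.3f s",
                     step * dt))
      }
      denom <- params$I - (sens_num$dp_dr / sens_num$p) * w_I * st$r_E *
        (st$r_E + w_I * st$r_E - params$I)
      d_rE <- plast_coef * sens_num$p / denom * st$r_E^4 *
        (st$r_E - st$r_bar^2 / kappa) / params$tau_w
      d_rb <- (-st$r_bar + st$r_E) / params$tau_c
      st$r_E <- clip_r(st$r_E + dt * d_rE)
      st$r_bar <- st$r_bar + dt * d_rb
      st$p <- p_at_rate(params, st$r_E)$p
      st$r_I <- rI_of_rE(params, st$r_E)
    }
    if (!all(is.finite(unlist(st)))) {
      bad <- names(st)[!vapply(st, is.finite, logical(1))][1]
      stop(sprintf("simulate_meanfield: variable %s became non-finite at t = %.3f s",
                   bad, step * dt))
    }
    if (step %% rec_every == 0L) {
      rec_i <- rec_i + 1L
      out[rec_i, ] <- c(step * dt, st$r_E, st$r_I, st$p, st$w, st$r_bar)
    }
  }
  tr <- as.data.frame(out[seq_len(rec_i), , drop = FALSE])
  attr(tr, "mode") <- mode
  attr(tr, "params") <- params
  class(tr) <- c("meanfield_trace", class(tr))
  tr
}
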