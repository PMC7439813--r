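# Mean-field steady states, sensitivity, stability and critical timescale.

test_that("steady state without presynaptic inhibition follows the linear
           fixed point and diverges at w = 1 + w_I", {
  mf <- mf_none(w_tilde_EE = 1, I = 0.5)
  ss <- steady_state(mf)
  expect_equal(ss$r_E, 0.5)          # I / (1 - w + w_I) = 0.5 / 1
  expect_equal(ss$r_I, 0.5)
  expect_true(ss$exists)

  expect_false(steady_state(mf_none(w_tilde_EE = 2))$exists)
  expect_false(steady_state(mf_none(w_tilde_EE = 2.0000001))$exists)
  expect_true(steady_state(mf_none(w_tilde_EE = 1.999999))$exists)
})

test_that("closed-form rate with linear transfer matches the quadratic root", {
  ss <- steady_state(mf_linear(w_tilde_EE = 2))
  expect_equal(ss$r_E, sqrt(0.2) / 0.2, tolerance = 1e-12)  # ~2.2361 Hz
})

test_that("closed form equals the numeric fixed point over the parameter grid", {
  # grid over recurrence, slope and input; relative agreement to 1e-9
  for (beta in seq(0.01, 0.09, by = 0.02)) {
    for (I in c(0.5, 1, 2.5, 5)) {
      for (w in c(0, 0.5, 1, 2, 5, 10, 25, 50, 75, 100)) {
        mf <- meanfield_params(w_tilde_EE = w, I = I,
                               transfer = transfer_spec("linear", beta = beta))
        closed <- steady_state(mf)
        numeric <- presynstab:::steady_state_numeric(mf)
        expect_equal(closed$r_E, numeric$r_E, tolerance = 1e-9,
                     info = sprintf("beta=%g I=%g w=%g", beta, I, w))
      }
    }
  }
})

test_that("steady-state rate is nondecreasing in w and nonincreasing in beta", {
  w_grid <- seq(0, 100, length.out = 60)
  prev_curve <- NULL
  for (beta in seq(0.01, 0.09, by = 0.02)) {
    curve <- vapply(w_grid, function(w) {
      steady_state(meanfield_params(w_tilde_EE = w,
        transfer = transfer_spec("linear", beta = beta)))$r_E
    }, numeric(1))
    expect_true(all(diff(curve) >= -1e-12), info = paste("beta", beta))
    if (!is.null(prev_curve)) {
      expect_true(all(curve <= prev_curve + 1e-12), info = paste("beta", beta))
    }
    prev_curve <- curve
  }
})

test_that("rate saturates at 1/(beta w_I) for large recurrence", {
  for (beta in c(0.05, 0.1)) {
    mf <- meanfield_params(w_tilde_EE = 1e4,
                           transfer = transfer_spec("linear", beta = beta))
    expect_equal(steady_state(mf)$r_E, 1 / beta, tolerance = 0.01)
    expect_equal(asymptotic_rate(mf), 1 / beta)
  }
  # strong input: release factor clips to zero, rate = I / (1 + w_I)
  mf_strong <- meanfield_params(w_tilde_EE = 2, I = 50,
                                transfer = transfer_spec("linear", beta = 0.05))
  expect_equal(asymptotic_rate(mf_strong), 25)
  expect_equal(steady_state(mf_strong)$r_E, 25)
  expect_error(asymptotic_rate(meanfield_params(
    transfer = transfer_spec("linear", beta = 0))), "without bound")
})

test_that("asymptotic rate agrees with the steady state at extreme recurrence", {
  mf <- mf_linear(w_tilde_EE = 1e6)
  expect_equal(steady_state(mf)$r_E, asymptotic_rate(mf), tolerance = 1e-3)
  expect_equal(asymptotic_rate(mf_linear(I = 0.5)), 20)
  expect_equal(asymptotic_rate(meanfield_params(
    transfer = transfer_spec("linear", beta = 0.1))), 10)
})

test_that("required recurrence places the fixed point at the target rate", {
  mf0 <- mf_none()
  expect_equal(required_recurrence(mf0), 1.9)
  mf <- mf_linear()
  expect_equal(required_recurrence(mf), 1.9 / 0.75, tolerance = 1e-12)
  for (m in list(mf0, mf)) {
    m$w_tilde_EE <- required_recurrence(m)
    expect_equal(steady_state(m)$r_E, m$kappa, tolerance = 1e-9)
  }
  # input alone reaching the target needs no recurrence
  expect_equal(required_recurrence(mf_linear(w_tilde_EE = 1, I = 10)), 0)
  expect_error(required_recurrence(mf_linear(w_tilde_EE = 1, I = 11)))
})

test_that("rate sensitivity matches finite differences of the steady state", {
  # transfer "none": closed form r_E^2 / I
  mf0 <- mf_none(w_tilde_EE = 1.9)
  expect_equal(rate_sensitivity(mf0, 5), 50)
  # linear transfer: central finite difference over w
  mf <- mf_linear()
  h <- 1e-6
  fd <- local({
    up <- mf; up$w_tilde_EE <- mf$w_tilde_EE + h
    dn <- mf; dn$w_tilde_EE <- mf$w_tilde_EE - h
    (steady_state(up)$r_E - steady_state(dn)$r_E) / (2 * h)
  })
  expect_equal(rate_sensitivity(mf, 5), fd, tolerance = 1e-5)
  expect_equal(rate_sensitivity(mf, 5), 0.75 * 25 / (0.5 + (0.05 / 0.75) * 5 * 9.5),
               tolerance = 1e-12)
  # vanishes quadratically at zero rate
  expect_lt(rate_sensitivity(mf, 1e-6), 1e-10)
})

test_that("auxiliary stability constant is positive and takes known values", {
  expect_equal(psi_constant(mf_none()), 0.08)           # eta w0 / (kappa^3 I)
  expect_equal(psi_constant(mf_linear()), 0.03 / 3.666666666666667,
               tolerance = 1e-12)
  # positivity up to the validity boundary I < kappa (1 + w_I)
  for (I in c(0.1, 1, 5, 9.9)) {
    expect_gt(psi_constant(mf_linear(I = I)), 0)
  }
})

test_that("eigenvalues change stability exactly at the critical timescale", {
  for (mf in list(mf_none(), mf_linear(),
                  meanfield_params(transfer = transfer_spec("exponential",
                                                            beta_e = 0.1)))) {
    crit <- critical_timescale(mf)
    expect_true(linearised_eigenvalues(mf, 0.5 * crit)$stable)
    at <- linearised_eigenvalues(mf, crit)
    expect_false(at$stable)   # boundary counts as unstable
    expect_true(at$boundary)
    expect_equal(max(Re(at$eigenvalues)), 0, tolerance = 1e-12)
    expect_false(linearised_eigenvalues(mf, 2 * crit)$stable)
  }
  expect_error(linearised_eigenvalues(mf_linear(), -1), "positive")
})

test_that("critical timescale equals the eigenvalue sign-change point for all
           transfer families", {
  for (tr in list(transfer_spec("none"),
                  transfer_spec("linear", beta = 0.05),
                  transfer_spec("sigmoid", beta_s = 0.2, r_shift = 5),
                  transfer_spec("exponential", beta_e = 0.1))) {
    mf <- meanfield_params(transfer = tr)
    crit <- critical_timescale(mf)
    # independent bracketing bisection on the max real part
    max_re <- function(tc) max(Re(linearised_eigenvalues(mf, tc)$eigenvalues))
    lo <- crit / 10; hi <- crit * 10
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (max_re(mid) < 0) lo <- mid else hi <- mid
    }
    expect_equal(crit, (lo + hi) / 2, tolerance = 1e-6, info = tr$kind)
  }
})

test_that("without presynaptic inhibition the critical timescale is
           tau_plast * I / kappa exactly", {
  for (I in c(0.25, 0.5, 1, 2.5)) {
    mf <- mf_none(I = I)
    expect_identical(critical_timescale(mf), tau_plast(mf) * I / mf$kappa)
  }
  expect_equal(critical_timescale(mf_none()), 6)
  expect_equal(critical_timescale(mf_linear()), 58.66666666666667,
               tolerance = 1e-12)
})

test_that("critical timescale increases with input and with transfer slope", {
  crit_I <- vapply(c(0.5, 1, 2.5, 5), function(I)
    critical_timescale(mf_linear(I = I)), numeric(1))
  expect_true(all(diff(crit_I) > 0))
  crit_beta <- vapply(seq(0.01, 0.09, by = 0.02), function(b)
    critical_timescale(meanfield_params(
      transfer = transfer_spec("linear", beta = b))), numeric(1))
  expect_true(all(diff(crit_beta) > 0))
})

test_that("the recurrence-substituted form of the critical timescale matches
           the direct formula to machine precision", {
  # tau_plast / g * (I/kappa - kappa w g' w_I), with w the fixed-point
  # recurrence -- an independent route through the algebra
  for (beta in c(0.01, 0.05, 0.09)) {
    mf <- meanfield_params(transfer = transfer_spec("linear", beta = beta))
    w_I <- total_inhibition(mf)
    g <- release_factor(mf$transfer, w_I * mf$kappa)
    alt <- tau_plast(mf) / g$p *
      (mf$I / mf$kappa - mf$kappa * mf$w_tilde_EE * g$dp_dr * w_I)
    expect_equal(critical_timescale(mf), alt, tolerance = 1e-13)
  }
})

test_that("circuit-motif variants solve to valid steady states and the
           default motif agrees with the closed form", {
  mf_v <- mf_linear(w_tilde_EE = 2)
  mf_v$variant <- "ee"
  expect_equal(presynstab:::steady_state_numeric(mf_v)$r_E, steady_state(mf_v)$r_E,
               tolerance = 1e-8)
  for (v in c("inh_onto_exc", "exc_onto_inh", "all_recurrent", "input")) {
    mf2 <- meanfield_params(w_tilde_EE = 2, variant = v)
    ss <- steady_state(mf2)
    expect_true(ss$r_E >= 0 && ss$r_E <= mf2$r_max, info = v)
    expect_true(ss$p >= 0 && ss$p <= 1, info = v)
    # all motifs still bound the rate below the no-inhibition divergence
    expect_lt(ss$r_E, mf2$r_max, label = v)
  }
  # scaling more synapse classes suppresses the rate at least as strongly
  r_ee <- steady_state(meanfield_params(w_tilde_EE = 4, variant = "ee"))$r_E
  r_all <- steady_state(meanfield_params(w_tilde_EE = 4,
                                         variant = "all_recurrent"))$r_E
  expect_true(is.finite(r_all) && r_all > 0)
})
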