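# Scenario presets and the configuration-driven entry point.
#
# A scenario is a YAML (or R list) configuration: a preset name, parameter
# overrides, grids, durations and a seed. Every override key is validated
# against the target parameter set (typos are rejected with the nearest
# valid key suggested), and the fully resolved configuration is logged next
# to the outputs, so a run is reproducible from its artifacts alone.

scenario_presets <- function() {
  c("fig1_rate_curves", "fig2_homeostasis_scan", "fig3_input_sensitivity",
    "fig4_spiking", "s1_variants", "s4_transfer_functions", "s5_eigenvalues")
}

apply_overrides <- function(params, overrides, where) {
  for (key in names(overrides)) {
    if (!key %in% names(params)) {
      valid <- names(params)
      near <- valid[which.min(utils::adist(key, valid))]
      stop(sprintf("unknown %s parameter '%s'; did you mean '%s'?",
                   where, key, near))
    }
    params[[key]] <- overrides[[key]]
  }
  params
}

resolve_scenario <- function(config) {
  defaults <- list(preset = NULL, seed = 1L, out_dir = "presynstab_out",
                   overrides = list(), duration = NULL, grid = NULL,
                   beta_grid = NULL)
  cfg <- apply_overrides(defaults, config, "scenario")
  if (is.null(cfg$preset) || !cfg$preset %in% scenario_presets()) {
    stop("run_scenario: preset must be one of: ",
         paste(scenario_presets(), collapse = ", "))
  }
  cfg
}

#' Run a preset scenario
#'
#' Dispatches a named experiment preset, writes all artifacts (CSV traces
#' and scan outcomes, JSON summaries, a log with the fully resolved
#' parameters and seed) into the output directory, and returns the manifest
#' of files written. Runs are deterministic given the seed: the same
#' configuration produces byte-identical CSV output.
#'
#' Presets:
#' * `fig1_rate_curves`: mean-field rate-versus-recurrence curves, one per
#'   transfer slope in `{none, 0.01, 0.03, ..., 0.09}`.
#' * `fig2_homeostasis_scan`: rate-network critical-timescale scan with and
#'   without presynaptic inhibition, with the analytic prediction.
#' * `fig3_input_sensitivity`: the same scan across background-input levels.
#' * `fig4_spiking`: spiking-network recurrence sweep with and without
#'   presynaptic inhibition.
#' * `s1_variants`: steady-state curves for the circuit-motif variants.
#' * `s4_transfer_functions`: critical timescale across transfer families
#'   and slopes.
#' * `s5_eigenvalues`: eigenvalues of the reduced system versus `tau_c`.
#'
#' @param config Path to a YAML configuration file, or a named list with
#'   elements `preset`, and optionally `seed`, `out_dir`, `overrides`
#'   (model-parameter overrides), `duration`, `grid`, `beta_grid`.
#' @return Character vector of files written (the manifest), invisibly.
#' @export
run_scenario <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- resolve_scenario(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(cfg$out_dir, 2) != 0) {
    stop("run_scenario: output directory is not writable: ", cfg$out_dir)
  }
  manifest <- character(0)
  emit <- function(path) manifest <<- c(manifest, path)
  out <- function(name) file.path(cfg$out_dir, name)

  log_obj <- list(preset = cfg$preset, seed = cfg$seed,
                  overrides = cfg$overrides,
                  package_version = as.character(utils::packageVersion("presynstab")))

  if (cfg$preset == "fig1_rate_curves") {
    betas <- if (is.null(cfg$beta_grid)) c(NA, seq(0.01, 0.09, by = 0.02))
             else cfg$beta_grid
    w_grid <- if (is.null(cfg$grid)) seq(0, 6, by = 0.1) else cfg$grid
    for (b in betas) {
      tr <- if (is.na(b)) transfer_spec("none") else
        transfer_spec("linear", beta = b)
      mf <- apply_overrides(
        meanfield_params(w_tilde_EE = 1, transfer = tr),
        cfg$overrides, "meanfield")
      sc <- scan_recurrence("meanfield", mf, w_grid)
      f <- out(sprintf("rate_curve_beta_%s.csv",
                       if (is.na(b)) "none" else format(b)))
      write_scan(sc, f)
      emit(f); emit(paste0(f, ".json"))
    }
    log_obj$analytic <- list(
      asymptotic_rate_beta_0.05 = asymptotic_rate(meanfield_params(
        w_tilde_EE = 1, transfer = transfer_spec("linear", beta = 0.05))))
  } else if (cfg$preset %in% c("fig2_homeostasis_scan", "fig3_input_sensitivity")) {
    inputs <- if (cfg$preset == "fig2_homeostasis_scan") 0.5 else c(0.5, 1, 2.5)
    duration <- if (is.null(cfg$duration)) 600 else cfg$duration
    for (I in inputs) {
      for (b in c(NA, 0.05)) {
        tr <- if (is.na(b)) transfer_spec("none") else
          transfer_spec("linear", beta = b)
        rp <- apply_overrides(
          rate_net_params(I_mean = I, transfer = tr, plasticity_warmup = 60),
          cfg$overrides, "rate network")
        mf <- as_meanfield(rp)
        crit <- critical_timescale(mf)
        grid <- if (is.null(cfg$grid)) {
          signif(crit * c(0.4, 0.7, 2, 4), 2)
        } else cfg$grid
        sc <- scan_homeostasis("rate", rp, sort(grid), duration = duration,
                               seed = cfg$seed)
        f <- out(sprintf("homeostasis_I_%s_beta_%s.csv", format(I),
                         if (is.na(b)) "none" else format(b)))
        write_scan(sc, f)
        emit(f); emit(paste0(f, ".json"))
        log_obj$analytic[[sprintf("tau_c_crit_I_%s_beta_%s", format(I),
                                  if (is.na(b)) "none" else format(b))]] <- crit
      }
    }
  } else if (cfg$preset == "fig4_spiking") {
    w_grid <- if (is.null(cfg$grid)) seq(0, 4, by = 0.5) else cfg$grid
    duration <- if (is.null(cfg$duration)) 10 else cfg$duration
    for (b in c(NA, 0.1)) {
      tr <- if (is.na(b)) transfer_spec("none") else
        transfer_spec("linear", beta = b)
      sp <- apply_overrides(
        spiking_params(N_E = 1000, N_I = 250, transfer = tr),
        cfg$overrides, "spiking")
      sc <- scan_recurrence("spiking", sp, w_grid, duration = duration,
                            discard = duration / 4, seed = cfg$seed)
      f <- out(sprintf("spiking_curve_beta_%s.csv",
                       if (is.na(b)) "none" else format(b)))
      write_scan(sc, f)
      emit(f); emit(paste0(f, ".json"))
    }
  } else if (cfg$preset == "s1_variants") {
    w_grid <- if (is.null(cfg$grid)) seq(0, 6, by = 0.2) else cfg$grid
    for (v in c("ee", "inh_onto_exc", "exc_onto_inh", "all_recurrent", "input")) {
      mf <- apply_overrides(
        meanfield_params(w_tilde_EE = 1, variant = v),
        cfg$overrides, "meanfield")
      sc <- scan_recurrence("meanfield", mf, w_grid)
      f <- out(sprintf("variant_%s.csv", v))
      write_scan(sc, f)
      emit(f); emit(paste0(f, ".json"))
    }
  } else if (cfg$preset == "s4_transfer_functions") {
    specs <- list(
      list(name = "linear_0.05", tr = transfer_spec("linear", beta = 0.05)),
      list(name = "exponential_0.1", tr = transfer_spec("exponential", beta_e = 0.1)),
      list(name = "sigmoid_0.2_s5", tr = transfer_spec("sigmoid", beta_s = 0.2,
                                                       r_shift = 5)),
      list(name = "sigmoid_0.2_s4", tr = transfer_spec("sigmoid", beta_s = 0.2,
                                                       r_shift = 4)))
    rows <- lapply(specs, function(s) {
      mf <- apply_overrides(meanfield_params(transfer = s$tr),
                            cfg$overrides, "meanfield")
      data.frame(transfer = s$name,
                 p_at_target = release_factor(s$tr, total_inhibition(mf) *
                                                mf$kappa)$p,
                 tau_c_crit = critical_timescale(mf))
    })
    f <- out("transfer_families.csv")
    write_csv_table(do.call(rbind, rows), f)
    emit(f)
  } else if (cfg$preset == "s5_eigenvalues") {
    grid <- if (is.null(cfg$grid)) seq(1, 150, by = 1) else cfg$grid
    for (b in c(NA, 0.05)) {
      tr <- if (is.na(b)) transfer_spec("none") else
        transfer_spec("linear", beta = b)
      mf <- apply_overrides(meanfield_params(transfer = tr),
                            cfg$overrides, "meanfield")
      rows <- lapply(grid, function(tc) {
        rep <- linearised_eigenvalues(mf, tc)
        data.frame(tau_c = tc,
                   re_1 = Re(rep$eigenvalues[1]), im_1 = Im(rep$eigenvalues[1]),
                   re_2 = Re(rep$eigenvalues[2]), im_2 = Im(rep$eigenvalues[2]),
                   stable = rep$stable)
      })
      f <- out(sprintf("eigenvalues_beta_%s.csv",
                       if (is.na(b)) "none" else format(b)))
      write_csv_table(do.call(rbind, rows), f)
      emit(f)
      log_obj$analytic[[sprintf("tau_c_crit_beta_%s",
                                if (is.na(b)) "none" else format(b))]] <-
        critical_timescale(mf)
    }
  }

  log_file <- out("run_log.json")
  jsonlite::write_json(log_obj, log_file, auto_unbox = TRUE, digits = NA)
  emit(log_file)
  invisible(manifest)
}
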