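# Batch reports and verification utilities tying the modules together:
# benchmark-table replay, full synthetic scenario suites, material model
# verification, and file-based run outputs.

#' Reference hemodynamic components of the benchmark rupture study
#'
#' Per-condition hemodynamic components reported by a published
#' patient-specific fluid-structure interaction study of progressive
#' mitral chordae rupture (a control valve and seven rupture models):
#' aortic regurgitant volume, mitral closing and leakage volumes, forward
#' stroke volume, and the reported regurgitant volume, fraction and
#' severity label. Used as replay inputs and as the default severity
#' settings of the synthetic suite.
#'
#' @return Data frame with one row per condition.
#' @export
reference_hemodynamics <- function() {
  path <- system.file("extdata", "reference_hemodynamics.csv",
                      package = "chordaemr", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Replay hemodynamic summaries from reference component volumes
#'
#' Recomputes, for each condition of a component table (default
#' [reference_hemodynamics()]), the regurgitant volume
#' `RV_MV = closing + leakage`, total stroke volume `LVSV`, regurgitant
#' fraction and severity grade through the package's own arithmetic, so
#' the derived columns of the benchmark table can be checked from its
#' component rows.
#'
#' @param components Data frame with columns `scenario, closing_ml,
#'   leakage_ml, sv_av_ml`.
#' @return Data frame with the recomputed `rv_mv_ml, lvsv_ml, rf_pct,
#'   grade, aha_category` per condition.
#' @export
replay_reference_table <- function(components = reference_hemodynamics()) {
  rows <- lapply(seq_len(nrow(components)), function(i) {
    r <- components[i, ]
    rv <- r$closing_ml + r$leakage_ml
    rf <- regurgitant_fraction(rv, r$sv_av_ml)
    g <- grade_mr(rf)
    data.frame(scenario = r$scenario, closing_ml = r$closing_ml,
               leakage_ml = r$leakage_ml, sv_av_ml = r$sv_av_ml,
               rv_mv_ml = rv, lvsv_ml = r$sv_av_ml + rv, rf_pct = rf,
               grade = g$grade, aha_category = g$aha_category)
  })
  do.call(rbind, rows)
}

#' Synthetic severity suite emulating the benchmark conditions
#'
#' Generates one waveform record per benchmark condition, injecting each
#' condition's closing volume, leakage volume (via the equivalent leak
#' rate) and forward stroke volume into the generator, with a common
#' ejection timing so the control closure time applies to every record.
#'
#' @param components Component table, default [reference_hemodynamics()].
#' @param base Control [waveform_config()].
#' @param dt Sample interval, s.
#' @return As [gen_severity_suite()]; records named by condition. Records
#'   are ordered by leak rate, ascending.
#' @export
gen_reference_suite <- function(components = reference_hemodynamics(),
                                base = waveform_config(), dt = 1e-3) {
  ord <- order(components$leakage_ml)
  components <- components[ord, ]
  leak_rates <- vapply(components$leakage_ml,
                       leak_rate_for_volume, 0, config = base)
  gen_severity_suite(base, leak_rates,
                     closing_volumes = components$closing_ml,
                     sv_av_targets = components$sv_av_ml,
                     names = components$scenario, dt = dt)
}

#' Run the full synthetic scenario suite
#'
#' End-to-end batch analysis: (1) generates the severity suite of waveform
#' records and summarises each with [summarize_hemodynamics()] using the
#' control record's closure time (a benchmark-style hemodynamic table);
#' (2) builds the chordae network, solves every rupture scenario and
#' tabulates group forces and the papillary-muscle force distribution;
#' (3) computes PV-loop energetics per condition from idealized loops and
#' the generated records.
#'
#' @param seed Integer seed controlling the network jitter and noise.
#' @param components Component table driving the generator, default
#'   [reference_hemodynamics()].
#' @param materials Material set with an `ogden` element, default
#'   [example_materials()].
#' @param load A [load_case()] for the chordae solve.
#' @param dt Waveform sample interval, s.
#' @param out_dir Optional directory; when given, writes
#'   `hemodynamics.csv`, `forces.csv`, `pm_distribution.csv`,
#'   `energetics.csv` and a `run_config.json` snapshot (seed + md5 hash).
#' @return List with `hemodynamics`, `forces`, `pm_distribution`,
#'   `energetics` data frames plus the `network`, `suite` and `solutions`.
#' @export
run_scenario_suite <- function(seed = 1L,
                               components = reference_hemodynamics(),
                               materials = example_materials(),
                               load = load_case(), dt = 1e-3,
                               out_dir = NULL) {
  suite <- gen_reference_suite(components, waveform_config(seed = seed), dt = dt)
  ctrl <- suite$records[["control"]]
  t_close <- reference_closure_time(ctrl)
  hemo <- do.call(rbind, lapply(names(suite$records), function(nm) {
    s <- summarize_hemodynamics(suite$records[[nm]], t_close = t_close)
    data.frame(scenario = nm, rv_av_ml = s$rv_av,
               closing_ml = s$closing_volume, leakage_ml = s$leakage_volume,
               rv_mv_ml = s$rv_mv, sv_av_ml = s$sv_av, lvsv_ml = s$lvsv,
               rf_pct = s$rf_mv, grade = s$grade,
               aha_category = s$aha_category)
  }))

  network <- build_network(seed = seed)
  cmp <- compare_scenarios(network, scenario_names(), load, materials$ogden)
  pmdist <- do.call(rbind, lapply(names(cmp$solutions), function(nm) {
    d <- pm_force_distribution(network, cmp$solutions[[nm]])
    d$scenario <- nm
    d[, c("scenario", "pm", "group", "percent")]
  }))

  energ <- do.call(rbind, lapply(names(suite$records), function(nm) {
    rec <- suite$records[[nm]]
    loop <- gen_pv_loop()
    e <- summarize_energetics(loop, rec)
    data.frame(scenario = nm, sw_J = e$sw, fsw_J = e$fsw, pe_J = e$pe,
               pva_J = e$pva, efficiency_pct = e$efficiency)
  }))

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(hemo, file.path(out_dir, "hemodynamics.csv"),
                     row.names = FALSE)
    utils::write.csv(cmp$forces, file.path(out_dir, "forces.csv"),
                     row.names = FALSE)
    utils::write.csv(pmdist, file.path(out_dir, "pm_distribution.csv"),
                     row.names = FALSE)
    utils::write.csv(energ, file.path(out_dir, "energetics.csv"),
                     row.names = FALSE)
    .write_config_snapshot(file.path(out_dir, "run_config.json"),
                           list(seed = seed, dt = dt,
                                scenarios = scenario_names()))
  }
  list(hemodynamics = hemo, forces = cmp$forces, pm_distribution = pmdist,
       energetics = energ, network = network, suite = suite,
       solutions = cmp$solutions, t_close = t_close)
}

# JSON config snapshot embedding its own md5 hash and the seed
.write_config_snapshot <- function(path, config) {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  hash <- unname(tools::md5sum(tmp))
  jsonlite::write_json(c(config, list(config_md5 = hash)), path,
                       auto_unbox = TRUE, digits = NA)
  unlink(tmp)
  invisible(path)
}

#' Generate all study input files
#'
#' Writes the synthetic inputs a full analysis consumes: one waveform CSV
#' per condition, the chordae network JSON, the generator ground-truth
#' table and a config snapshot (seed plus md5 hash). Deterministic for a
#' fixed seed.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param components Component table, default [reference_hemodynamics()].
#' @param dt Sample interval, s.
#' @return Invisibly, the vector of files written.
#' @export
generate_study_inputs <- function(out_dir, seed = 1L,
                                  components = reference_hemodynamics(),
                                  dt = 1e-3) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  suite <- gen_reference_suite(components, waveform_config(seed = seed), dt = dt)
  files <- character(0)
  for (nm in names(suite$records)) {
    f <- file.path(out_dir, sprintf("waveforms_%s.csv", nm))
    write_flow_csv(suite$records[[nm]], f)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(suite$ground_truth, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(out_dir, "chordae_network.json")
  write_network_json(build_network(seed = seed), f)
  files <- c(files, f)
  f <- file.path(out_dir, "run_config.json")
  .write_config_snapshot(f, list(seed = seed, dt = dt,
                                 scenarios = names(suite$records)))
  files <- c(files, f)
  invisible(files)
}

# random admissible deformation gradient: moderate stretch + shear, det > 0
.random_F <- function(rng, amplitude = 0.25) {
  repeat {
    F <- diag(3) + amplitude * matrix(2 * rng(9) - 1, 3, 3)
    if (det(F) > 0.3) return(F)
  }
}

#' Verify the leaflet stress implementation against finite differences
#'
#' Draws random admissible deformation states and compares the analytic
#' first Piola-Kirchhoff stress `P = F S` (with `S` from [stress_mhgo()])
#' against a central finite-difference gradient of [strain_energy_mhgo()]
#' with respect to the deformation gradient.
#'
#' @param params [mhgo_params()], default the example set.
#' @param n Number of random states.
#' @param seed Integer seed.
#' @param step Relative finite-difference step.
#' @param tol Pass threshold on the maximum relative error.
#' @return List with `max_rel_error`, `pass` (error below `tol`) and `tol`.
#' @export
material_verification <- function(params = example_materials()$mhgo,
                                  n = 100, seed = 1L, step = 1e-6,
                                  tol = 1e-5) {
  rng <- .seeded_rng(seed)
  fib <- fiber_directions(params$fiber_angle_deg)
  worst <- 0
  for (k in seq_len(n)) {
    F <- .random_F(rng)
    st <- deformation_state(F, fib)
    S <- stress_mhgo(st, params)$pk2
    P <- F %*% S
    h <- step * max(abs(F))
    Pfd <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      Pfd[i, j] <- (strain_energy_mhgo(deformation_state(Fp, fib), params) -
                      strain_energy_mhgo(deformation_state(Fm, fib), params)) /
        (2 * h)
    }
    err <- max(abs(P - Pfd)) / max(max(abs(P)), 1e-12)
    worst <- max(worst, err)
  }
  list(max_rel_error = worst, pass = worst < tol, tol = tol)
}

#' Uniaxial / equibiaxial stress-stretch response of the leaflet model
#'
#' Tabulates the Cauchy stress of the leaflet material under incompressible
#' uniaxial stretch (`diag(l, 1/sqrt(l), 1/sqrt(l))`) or equibiaxial
#' stretch (`diag(l, l, 1/l^2)`) along the circumferential axis.
#'
#' @param params [mhgo_params()].
#' @param stretches Stretch values.
#' @param mode `"uniaxial"` or `"equibiaxial"`.
#' @return Data frame with stretch, strain energy and the in-plane Cauchy
#'   stress components (MPa).
#' @export
material_response_table <- function(params = example_materials()$mhgo,
                                    stretches = seq(1, 1.3, by = 0.02),
                                    mode = c("uniaxial", "equibiaxial")) {
  mode <- match.arg(mode)
  fib <- fiber_directions(params$fiber_angle_deg)
  rows <- lapply(stretches, function(l) {
    F <- if (mode == "uniaxial") diag(c(l, 1 / sqrt(l), 1 / sqrt(l)))
    else diag(c(l, l, 1 / l^2))
    st <- deformation_state(F, fib)
    res <- stress_mhgo(st, params)
    data.frame(stretch = l, energy_MPa = res$energy,
               sigma_11 = res$cauchy[1, 1], sigma_22 = res$cauchy[2, 2],
               sigma_33 = res$cauchy[3, 3],
               max_principal = max_principal_stress(res$cauchy))
  })
  do.call(rbind, rows)
}
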