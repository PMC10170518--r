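#' Benchmark run configuration
#'
#' Collects every knob of the end-to-end benchmark with toy-scale defaults
#' chosen so a single run finishes in well under ten minutes on one CPU:
#' a few hundred nested-sampler sweeps instead of the tens of thousands a
#' production study would use, and train/test splits of a few hundred
#' structures. All seeds are derived deterministically from `seed`.
#'
#' @param n_heavy,pattern toy molecule, see [make_toy_molecule()].
#' @param perturb_scale,cubic_coeff surrogate-reference perturbations, see
#'   [make_surrogate_reference()].
#' @param sweeps,n_leapfrog,dt,switch_period,T_low,T_target nested-sampler
#'   settings, see [mc_settings()].
#' @param n_train,n_test split sizes for the reparametrization.
#' @param optimize_phases also tune dihedral phases.
#' @param traj_moves hybrid-MC moves per model for population sampling.
#' @param resp_points ESP grid points per conformation.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_heavy = 4, pattern = "mono", perturb_scale = 0.12,
                       cubic_coeff = 30, sweeps = 800, n_leapfrog = 12,
                       dt = 1, switch_period = 2, T_low = 350,
                       T_target = 300, n_train = 120, n_test = 240,
                       optimize_phases = FALSE, traj_moves = 400,
                       resp_points = 400, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the end-to-end force-field benchmark
#'
#' Chains every stage of the pipeline on a synthetic system with known
#' ground truth: build the toy molecule and its base force field; construct
#' the surrogate reference potential; generate a reference ensemble with
#' the nested sampler; split it into train/test sets; retune the bonded
#' parameters on the training set; evaluate relative-energy-difference
#' distributions of the base and tuned force fields on the test set;
#' sample conformer populations with both force fields and score them
#' against the reference-ensemble populations (sum of absolute population
#' errors); refit RESP charges from an exact synthetic ESP; and compute the
#' packaged J-coupling agreement statistics. Writes CSV tables and a JSON
#' manifest (seeds, settings, acceptance diagnostics) into `outdir`.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with elements `molecule`, `sampler`,
#'   `reparam`, `energetics`, `populations`, `resp`, `jcouplings`,
#'   `manifest`.
#' @export
run_benchmark <- function(config = run_config(), outdir = NULL,
                          quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  seed <- config$seed

  say("stage 1/7: toy molecule + base force field")
  mol <- make_toy_molecule(config$n_heavy, config$pattern, seed = seed)
  conf0 <- minimize_conformation(mol$conf, mol$topo, mol$params, tol = 1e-3)

  say("stage 2/7: surrogate reference potential")
  ref <- make_surrogate_reference(mol$params, mol$topo,
                                  perturb_scale = config$perturb_scale,
                                  cubic_coeff = config$cubic_coeff,
                                  seed = seed + 1)

  say("stage 3/7: nested MC-MC reference ensemble")
  low <- ff_potential(mol$topo, mol$params, label = "base-ff")
  settings <- mc_settings(T_low = config$T_low, T_target = config$T_target,
                          dt = config$dt, n_leapfrog = config$n_leapfrog,
                          sweeps = config$sweeps,
                          switch_period = config$switch_period,
                          seed = seed + 2)
  report <- nmcmc_run(low, ref, settings, as.vector(conf0$coords))
  ensemble <- report_to_ensemble(report, mol$topo$n_atoms)
  say(sprintf("  hMC acceptance %.2f, switch acceptance %.2f",
              report$hmc_acceptance, report$switch_acceptance))

  say("stage 4/7: train/test split + reparametrization")
  if (length(ensemble) < config$n_train + config$n_test) {
    stop("ensemble too small for the requested train/test split")
  }
  split <- split_train_test(ensemble, report$energies_high,
                            config$n_train, config$n_test, seed = seed + 3)
  fit <- optimize_parameters(mol$params, mol$topo, split$train,
                             optimize_phases = config$optimize_phases)
  xu_base_test <- energy_term_XU(mol$params, mol$topo, split$test)
  xu_tuned_test <- energy_term_XU(fit$params, mol$topo, split$test)
  say(sprintf("  test X_U: base %.4f -> tuned %.4f",
              xu_base_test, xu_tuned_test))

  say("stage 5/7: relative-energy-difference distributions (test set)")
  e_ref <- split$test$u_ref
  e_base <- vapply(split$test$conformations,
                   function(cf) compute_energy(cf, mol$topo,
                                               mol$params)$total, 0)
  e_tuned <- vapply(split$test$conformations,
                    function(cf) compute_energy(cf, mol$topo,
                                                fit$params)$total, 0)
  dde_base <- delta_delta_E(e_base, e_ref)
  dde_tuned <- delta_delta_E(e_tuned, e_ref)
  energetics <- rbind(
    data.frame(model = "base", t(distribution_summary(dde_base))),
    data.frame(model = "tuned", t(distribution_summary(dde_tuned))))

  say("stage 6/7: population sampling + SAEP")
  p_ref <- trajectory_populations(ensemble, mol$topo, mol$molecule_class)
  sample_pops <- function(params, chain_seed) {
    chain <- hmc_chain(ff_potential(mol$topo, params),
                       T = config$T_target,
                       mc_settings(dt = config$dt,
                                   n_leapfrog = config$n_leapfrog,
                                   sweeps = config$traj_moves,
                                   seed = chain_seed),
                       start = as.vector(conf0$coords))
    traj <- lapply(seq_len(nrow(chain$samples)), function(i) {
      conformation(matrix(chain$samples[i, ], mol$topo$n_atoms, 3))
    })
    trajectory_populations(traj, mol$topo, mol$molecule_class)
  }
  p_base <- sample_pops(mol$params, seed + 4)
  p_tuned <- sample_pops(fit$params, seed + 5)
  populations <- list(reference = p_ref, base = p_base, tuned = p_tuned,
                      saep_base = saep(p_base, p_ref),
                      saep_tuned = saep(p_tuned, p_ref))
  say(sprintf("  SAEP vs reference: base %.3f, tuned %.3f",
              populations$saep_base, populations$saep_tuned))

  say("stage 7/7: RESP round-trip + J-coupling statistics")
  grids <- generate_esp_fixture(mol$topo, mol$params$charges, list(conf0),
                                n_points = config$resp_points,
                                seed = seed + 6)
  q_fit <- two_stage_resp(grids, list(conf0), mol$topo)
  resp <- list(true = mol$params$charges, fitted = as.vector(q_fit),
               max_abs_error = max(abs(as.vector(q_fit) -
                                         mol$params$charges)))
  jstats <- jcoupling_statistics()

  manifest <- list(
    package_version = as.character(utils::packageVersion("fluorff")),
    r_version = R.version.string,
    seed = seed,
    config = unclass(config),
    hmc_acceptance = report$hmc_acceptance,
    switch_acceptance = report$switch_acceptance,
    xu_base_test = xu_base_test,
    xu_tuned_test = xu_tuned_test,
    saep_base = populations$saep_base,
    saep_tuned = populations$saep_tuned,
    resp_max_abs_error = resp$max_abs_error,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_xyz(ensemble, mol$topo$elements,
              file.path(outdir, "reference_ensemble.xyz"))
    write_ff_parameters(mol$params, file.path(outdir, "params_base.txt"))
    write_ff_parameters(fit$params, file.path(outdir, "params_tuned.txt"))
    utils::write.csv(energetics, file.path(outdir, "dde_summary.csv"),
                     row.names = FALSE)
    write_population_csv(p_ref, file.path(outdir, "populations_reference.csv"))
    write_population_csv(p_base, file.path(outdir, "populations_base.csv"))
    write_population_csv(p_tuned, file.path(outdir, "populations_tuned.csv"))
    utils::write.csv(data.frame(atom = seq_along(resp$true),
                                element = mol$topo$elements,
                                q_true = resp$true, q_fit = resp$fitted),
                     file.path(outdir, "resp_charges.csv"),
                     row.names = FALSE)
    utils::write.csv(jstats, file.path(outdir, "jcoupling_statistics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(molecule = mol, sampler = report,
                 reparam = list(fit = fit, xu_base_test = xu_base_test,
                                xu_tuned_test = xu_tuned_test),
                 energetics = energetics, populations = populations,
                 resp = resp, jcouplings = jstats, manifest = manifest))
}
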