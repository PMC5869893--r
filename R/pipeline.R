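#' Run configuration for the planning pipeline
#'
#' Bundles every knob of the end-to-end two-phase workflow: phantom,
#' grid resolution, beam geometry, wishlists, solver settings, output
#' directory and seed.  Defaults reproduce the packaged desk-scale
#' setup: 4 mm grid, 20 beams of 10 mm beamlets, the packaged
#' whole-pelvis wishlists.
#'
#' @param phantom a [phantom_spec()] (or path to a YAML spec).
#' @param grid a [voxel_grid()].
#' @param n_beams number of equi-angular beams.
#' @param beamlet_size beamlet pitch (mm).
#' @param physics a [physics_params()].
#' @param context a [prescription_context()].
#' @param wishlists list with elements `1` and `2`: `wishlist` objects
#'   or YAML paths; `NULL` selects the packaged configs.
#' @param settings a [solver_settings()].
#' @param out_dir output directory for artifacts.
#' @param seed integer seed (phantom jitter and any stochastic step).
#' @return An object of class `run_config`.
#' @export
run_config <- function(phantom = NULL, grid = default_grid(),
                       n_beams = 20L, beamlet_size = 10,
                       physics = physics_params(),
                       context = prescription_context(),
                       wishlists = NULL, settings = solver_settings(),
                       out_dir = "wishplan_run", seed = 42L) {
  if (is.character(phantom)) phantom <- load_phantom_spec(phantom)
  if (is.null(phantom)) phantom <- phantom_spec(seed = seed)
  wl <- list()
  for (ph in 1:2) {
    w <- wishlists[[ph]]
    if (is.null(w)) w <- builtin_wishlist(ph)
    else if (is.character(w)) w <- load_wishlist(w)
    wl[[ph]] <- w
  }
  structure(list(phantom = phantom, grid = grid,
                 n_beams = as.integer(n_beams),
                 beamlet_size = beamlet_size, physics = physics,
                 context = context, wishlists = wl, settings = settings,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

config_fingerprint <- function(config) {
  # config hash for the run manifest: stable digest of the serialized config
  s <- paste(utils::capture.output(utils::str(
    config[c("phantom", "grid", "n_beams", "beamlet_size", "physics",
             "context", "seed")], digits.d = 10)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

log_run <- function(config, step, extra = list()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  entry <- c(list(step = step,
                  version = as.character(utils::packageVersion("wishplan")),
                  config_hash = config_fingerprint(config),
                  seed = config$seed,
                  time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra)
  path <- file.path(config$out_dir, "manifest.json")
  log <- if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = FALSE) else list()
  log[[length(log) + 1L]] <- entry
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(entry)
}

#' Generate phantom structures (pipeline step)
#'
#' Builds the seeded phantom (or a jittered cohort) and writes the
#' structure masks plus manifest under the run directory.
#'
#' @param config a [run_config()].
#' @param cohort number of jittered cases to generate (default 1: the
#'   spec's own seed).
#' @return the generated [structure_set()] (the last one for cohorts),
#'   invisibly; as a side effect writes NIfTI masks when RNifti is
#'   available.
#' @export
cmd_phantom <- function(config, cohort = 1L) {
  ss <- NULL
  for (i in seq_len(cohort)) {
    spec <- config$phantom
    if (cohort > 1L) spec$seed <- config$seed + i - 1L
    ss <- generate_phantom(spec, config$grid)
    sub <- if (cohort > 1L) sprintf("phantom_%03d", i) else "phantom"
    if (rnifti_available())
      save_structure_set(ss, file.path(config$out_dir, sub))
  }
  log_run(config, "phantom", list(cohort = cohort))
  invisible(ss)
}

#' Plan one treatment phase
#'
#' The core auto-planning step: places the isocenter at the centroid of
#' the phase target (`PTV-LN` for phase 1, `PTV-P` for the boost),
#' builds the equi-angular beam set and dose-influence matrix with the
#' fluence aperture shaped to the target, resolves the phase wishlist
#' and runs the prioritized solver.  The two phases are planned
#' independently.
#'
#' @param ss a [structure_set()].
#' @param phase 1 or 2.
#' @param config a [run_config()].
#' @return list with `plan` (a `plan_result`), `dij`, `problem`.
#' @export
plan_phase <- function(ss, phase, config = run_config()) {
  stopifnot(phase %in% c(1, 2))
  target <- if (phase == 1) "PTV-LN" else "PTV-P"
  iso <- mask_centroid(ss$masks[[target]], ss$grid)
  beams <- make_beams(config$n_beams, iso, config$beamlet_size)
  dij <- compute_dij(ss$grid, ss$masks$external, beams, config$physics,
                     field_mask = ss$masks[[target]])
  problem <- resolve_wishlist(config$wishlists[[phase]], config$context, ss)
  plan <- solve_prioritized(dij, problem, config$settings)
  list(plan = plan, dij = dij, problem = problem)
}

#' Plan a phase and write its artifacts (pipeline step)
#'
#' @param config a [run_config()].
#' @param phase 1 or 2.
#' @param ss optional pre-built [structure_set()]; built from the
#'   config's phantom spec when omitted.
#' @return the `plan_phase()` result, invisibly.
#' @export
cmd_plan <- function(config, phase, ss = NULL) {
  if (is.null(ss)) ss <- generate_phantom(config$phantom, config$grid)
  res <- plan_phase(ss, phase, config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  save_plan_trace(res$plan,
                  file.path(config$out_dir,
                            sprintf("phase%d_trace.json", phase)))
  utils::write.csv(res$plan$constraint_slacks,
                   file.path(config$out_dir,
                             sprintf("phase%d_constraints.csv", phase)),
                   row.names = FALSE)
  if (rnifti_available())
    write_nifti_grid(res$plan$dose, config$grid,
                     file.path(config$out_dir,
                               sprintf("phase%d_dose.nii.gz", phase)))
  log_run(config, sprintf("plan_phase%d", phase),
          list(isocenter = as.numeric(mask_centroid(
            ss$masks[[if (phase == 1) "PTV-LN" else "PTV-P"]], ss$grid))))
  invisible(res)
}

#' Evaluate the summed two-phase plan (pipeline step)
#'
#' Sums the phase doses, computes target metrics, the clinical-protocol
#' ledger, rectal V70/V55 on the EQD2-adjusted sum, and per-structure
#' DVHs; writes JSON/CSV reports.
#'
#' @param config a [run_config()].
#' @param ss the [structure_set()].
#' @param dose1,dose2 phase dose arrays.
#' @return list with `metrics`, `protocol`, `rectum_lq`, `dvhs`,
#'   invisibly.
#' @export
cmd_evaluate <- function(config, ss, dose1, dose2) {
  summed <- sum_plans(dose1, dose2)
  metrics <- target_metrics(dose1, dose2, ss, config$context)
  ledger <- check_protocol(summed, ss)
  rlq <- rectum_v70_v55(summed, ss, config$context)
  dvhs <- lapply(required_structures(), function(nm)
    cbind(structure = nm, dvh(summed, ss$masks[[nm]])))
  names(dvhs) <- required_structures()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(metrics, file.path(config$out_dir, "target_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(ledger, file.path(config$out_dir, "protocol_ledger.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, dvhs),
                   file.path(config$out_dir, "dvh_summed.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(metrics = metrics, protocol = ledger, rectum_lq = rlq,
         overall_pass = all(ledger$pass)),
    file.path(config$out_dir, "evaluation.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  log_run(config, "evaluate", list(overall_pass = all(ledger$pass)))
  invisible(list(metrics = metrics, protocol = ledger, rectum_lq = rlq,
                 dvhs = dvhs))
}

#' Gamma-compare two dose grids (pipeline step)
#'
#' @param config a [run_config()].
#' @param ref_dose,eval_dose dose arrays on the config grid.
#' @param dose_pct,dist_mm gamma criteria (default 3%/3 mm).
#' @return the `gamma_result`, invisibly.
#' @export
cmd_gamma <- function(config, ref_dose, eval_dose, dose_pct = 3,
                      dist_mm = 3) {
  gr <- gamma_index(ref_dose, eval_dose, config$grid, dose_pct, dist_mm)
  save_gamma_result(gr, config$grid, file.path(config$out_dir, "gamma"))
  log_run(config, "gamma", list(pass_rate_pct = gr$pass_rate))
  invisible(gr)
}

#' End-to-end two-phase auto-planning
#'
#' phantom -> phase-1 plan -> phase-2 plan -> summed-plan evaluation,
#' all under one seed.  This is the workflow the command-line interface
#' wraps.
#'
#' @param config a [run_config()].
#' @param write write artifacts to `config$out_dir`.
#' @return list with `structures`, `phase1`, `phase2` (each a
#'   [plan_phase()] result) and `evaluation`.
#' @export
run_pipeline <- function(config = run_config(), write = FALSE) {
  ss <- generate_phantom(config$phantom, config$grid)
  p1 <- if (write) cmd_plan(config, 1, ss) else plan_phase(ss, 1, config)
  p2 <- if (write) cmd_plan(config, 2, ss) else plan_phase(ss, 2, config)
  ev <- if (write) {
    cmd_evaluate(config, ss, p1$plan$dose, p2$plan$dose)
  } else {
    summed <- sum_plans(p1$plan$dose, p2$plan$dose)
    list(metrics = target_metrics(p1$plan$dose, p2$plan$dose, ss,
                                  config$context),
         protocol = check_protocol(summed, ss),
         rectum_lq = rectum_v70_v55(summed, ss, config$context))
  }
  list(structures = ss, phase1 = p1, phase2 = p2, evaluation = ev)
}
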