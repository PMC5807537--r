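#' @title End-to-end pipeline
#' @name cli_pipeline
#' @description Orchestration of the full desk-scale analysis: synthetic
#'   generation, spectrum and ensemble analysis, CIU state/transition
#'   detection across all four vinculin variants, and focal-adhesion
#'   morphometry/decay - plus optional structure-based stages when the
#'   user supplies coordinate files. A thin command-line front end is
#'   installed at `system.file("exec", "vinlock", package = "vinlock")`.
NULL

RUN_CONFIG_KEYS <- c("variants", "seed", "out_dir", "n_fas", "fa_frames",
                     "fa_variants", "mean_ions", "with_pdb",
                     "ensemble_ions", "verbose")

#' Build and validate a run configuration
#'
#' @param config named list of settings; unknown keys are rejected.
#'   Known keys: variants (default all four), seed (default 7), out_dir,
#'   n_fas (default 1000), fa_frames (default 60), fa_variants (default
#'   vinculin + T12), mean_ions, ensemble_ions (default 10000), with_pdb
#'   (path to a user-supplied coordinate file for the structure stages,
#'   or NULL), verbose.
#' @return validated `run_config` list with defaults filled.
#' @export
run_config <- function(config = list()) {
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- list(
    variants = config$variants %||% packaged_variants(),
    seed = config$seed %||% 7,
    out_dir = config$out_dir %||% tempfile("vinlock_run_"),
    n_fas = config$n_fas %||% 1000,
    fa_frames = config$fa_frames %||% 60,
    fa_variants = config$fa_variants %||% c("vinculin", "T12"),
    mean_ions = config$mean_ions,
    ensemble_ions = config$ensemble_ions %||% 10000,
    with_pdb = config$with_pdb,
    verbose = isTRUE(config$verbose))
  class(out) <- "run_config"
  out
}

stage_msg <- function(cfg, ...) if (cfg$verbose) message(...)

#' Run the full pipeline
#'
#' Stages run in dependency order (calibration, spectra, CIU, ensemble,
#' focal adhesions, optional structure stages); each stage's tables are
#' written under the output directory and a failing stage stops with its
#' own error without corrupting earlier outputs.
#'
#' @param cfg `run_config` (or plain list passed to `run_config()`).
#' @return report list (also serialised to report.json), invisibly.
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed, variants = cfg$variants)

  stage_msg(cfg, "stage: calibration")
  model <- default_calibration()
  report$calibration <- list(a = model$coeff_a, b = model$exponent_b,
                             max_abs_residual =
                               max(abs(model$fit_residuals)))

  stage_msg(cfg, "stage: spectra")
  report$spectra <- lapply(stats::setNames(nm = cfg$variants),
                           function(nm) {
    v <- variant_params(nm)
    cs <- detect_charge_states(gen_spectrum(
      v, seed = derive_seed(cfg$seed, paste0("spec_", nm))))
    write.csv(cs$entries,
              file.path(cfg$out_dir, paste0("charge_states_", nm,
                                            ".csv")),
              row.names = FALSE)
    list(n_major = cs$n_major, inferred_mass = cs$inferred_mass,
         envelope_center_mz = cs$envelope_center_mz, true_mass = v$mass)
  })

  stage_msg(cfg, "stage: CIU")
  fps <- list()
  report$ciu <- lapply(stats::setNames(nm = cfg$variants), function(nm) {
    v <- variant_params(nm)
    recs <- gen_ciu(v, seed = derive_seed(cfg$seed, paste0("ciu_", nm)),
                    mean_ions = cfg$mean_ions %||%
                      v$mean_ions_per_voltage %||% 2000)
    fp <- build_fingerprint(recs, model, v$mass)
    fps[[nm]] <<- fp
    st <- detect_states(fp, seed = derive_seed(cfg$seed,
                                               paste0("em_", nm)))
    tr <- detect_transitions(st)
    sp <- stability_profile(st)
    write_fingerprint_csv(fp, file.path(cfg$out_dir,
                                        paste0("fingerprint_", nm,
                                               ".csv")))
    write.csv(tr, file.path(cfg$out_dir,
                            paste0("transitions_", nm, ".csv")),
              row.names = FALSE)
    list(states = states_table(st), transitions = tr, stability = sp)
  })
  comp <- compare_variants(fps, seed = derive_seed(cfg$seed, "compare"))
  write.csv(comp$onsets, file.path(cfg$out_dir, "onsets.csv"),
            row.names = FALSE)
  report$onsets <- comp$onsets

  stage_msg(cfg, "stage: ensemble")
  ens_variants <- Filter(function(nm)
    (variant_params(nm)$ensemble$extended_fraction %||% 0) > 0,
    cfg$variants)
  report$ensemble <- lapply(stats::setNames(nm = ens_variants),
                            function(nm) {
    v <- variant_params(nm)
    recs <- gen_ensemble(v, n_ions = cfg$ensemble_ions,
                         seed = derive_seed(cfg$seed,
                                            paste0("ens_", nm)))
    pr <- ensemble_profile(recs, v$mass, model)
    list(extended_fraction = pr$extended_fraction,
         max_ccs = pr$max_ccs,
         true_fraction = v$ensemble$extended_fraction)
  })

  stage_msg(cfg, "stage: focal adhesions")
  report$fa <- lapply(stats::setNames(nm = cfg$fa_variants),
                      function(nm) {
    v <- variant_params(nm)
    ds <- gen_fa_dataset(v, n_fas = cfg$n_fas, frames = cfg$fa_frames,
                         out_dir = file.path(cfg$out_dir,
                                             paste0("fa_", nm)),
                         seed = derive_seed(cfg$seed, paste0("fa_", nm)))
    fi <- fa_intensity_series(ds$labels, ds$frame_paths, ds$times)
    corrected <- bleach_correct(fi$series, ds$reference)
    corrected$intensity <- corrected$intensity / corrected$intensity[1]
    dfit <- fit_decay(corrected, fa_matrix = fi$fa_matrix)
    sfit <- fit_size_distribution(fi$morphometry$area)
    write.csv(fi$morphometry,
              file.path(cfg$out_dir, paste0("fa_measures_", nm, ".csv")),
              row.names = FALSE)
    list(n_fas = nrow(fi$morphometry),
         size_fit = list(mu = sfit$mu, sigma = sfit$sigma),
         decay = list(rate = dfit$rate, plateau = dfit$plateau,
                      initial_slope = dfit$initial_slope))
  })

  if (!is.null(cfg$with_pdb)) {
    stage_msg(cfg, "stage: structure")
    s <- read_structure(cfg$with_pdb)
    p <- default_domain_partition()
    vt_d1 <- interface_area(s, p, "Vt", "D1")
    vt_d4 <- interface_area(s, p, "Vt", "D4")
    ch <- structure_chains(s)[1]
    report$structure <- list(
      source = s$source_id,
      vt_d1_area = vt_d1$mean_area, vt_d4_area = vt_d4$mean_area,
      closed_ccs = pa_ccs(select_chain(s, ch))$value)
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

#' Select a single chain
#' @param s `vl_structure`.
#' @param chain chain identifier.
#' @return `vl_structure` restricted to the chain.
#' @export
select_chain <- function(s, chain) {
  if (!chain %in% s$atoms$chain) stop("unknown chain: ", chain)
  subset_structure(s, s$atoms$chain == chain)
}

#' Reproduce the packaged desk-scale analysis
#'
#' One-call wrapper around `run_pipeline()` on the packaged defaults.
#'
#' @param out_dir output directory.
#' @param seed base seed (default 7).
#' @param with_pdb optional user-supplied coordinate file enabling the
#'   structure stages (no file is downloaded silently).
#' @return report list, invisibly.
#' @export
reproduce <- function(out_dir = tempfile("vinlock_repro_"), seed = 7,
                      with_pdb = NULL) {
  run_pipeline(run_config(list(out_dir = out_dir, seed = seed,
                               with_pdb = with_pdb, verbose = TRUE)))
}
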