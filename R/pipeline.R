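#' Run the phantom-cohort analysis pipeline
#'
#' Drives the stages simulate -> (fit-fwe) -> profile -> analyze -> report
#' on a workspace directory. Each stage writes its outputs to `out_dir`
#' and later stages reuse cached outputs when present (delete the files or
#' pass `overwrite = TRUE` to recompute). All randomness derives from
#' `config$seed`, so two runs with the same config produce identical
#' tables.
#'
#' The default profiling uses the generator's ground-truth metric fields;
#' the optional "fit-fwe" stage instead simulates DWI per subject and fits
#' the free-water model, which is considerably heavier.
#'
#' @param config A [cohort_config()].
#' @param out_dir Workspace directory.
#' @param stages Character vector of stages to run, in order.
#' @param threshold Involvement/eligibility threshold (percent).
#' @param sweep Optional thresholds for the sensitivity sweep.
#' @param bins Distance segments.
#' @param fit_config [fw_fit_config()] for the fit-fwe stage.
#' @param overwrite Recompute even when cached outputs exist.
#' @return Run manifest (list), invisibly; written as run_manifest.json.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "profile", "analyze", "report"),
                         threshold = 5, sweep = NULL,
                         bins = asym_distance_bins(),
                         fit_config = fw_fit_config(), overwrite = FALSE) {
  known <- c("simulate", "fit-fwe", "profile", "analyze", "report")
  if (!all(stages %in% known)) {
    abort(paste0("Unknown stage(s): ",
                 paste(setdiff(stages, known), collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(subjects = file.path(out_dir, "subjects.csv"),
                profiles = file.path(out_dir, "profiles.csv"),
                cohort = file.path(out_dir, "cohort"),
                analysis = file.path(out_dir, "analysis"),
                manifest = file.path(out_dir, "run_manifest.json"))
  log_lines <- character()
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  manifest <- list(tool = "fwtract",
                   version = as.character(utils::packageVersion("fwtract")),
                   config_hash = rlang::hash(unclass(config)),
                   seed = config$seed, threshold = threshold,
                   started = format(Sys.time()), stages = stages,
                   outputs = list())

  if ("simulate" %in% stages) {
    if (overwrite || !file.exists(file.path(paths$cohort, "manifest.json"))) {
      logf("simulate: generating %d subjects", sum(config$n_subjects))
      generate_cohort(config, out_dir = paths$cohort,
                      include_dwi = "fit-fwe" %in% stages,
                      keep_volumes = FALSE)
    } else {
      logf("simulate: cohort already present, skipping")
    }
    manifest$outputs$cohort <- paths$cohort
  }

  if ("fit-fwe" %in% stages) {
    scheme <- make_diffusion_scheme(config$n_directions, config$b_value,
                                    config$n_b0, seed = config$seed)
    cm <- jsonlite::read_json(file.path(paths$cohort, "manifest.json"))
    for (sid in names(cm$subjects)) {
      sp <- cm$subjects[[sid]]$paths
      if (is.null(sp$dwi)) next
      out_fa <- file.path(dirname(sp$dwi), "fwe_fa.nii.gz")
      if (!overwrite && file.exists(out_fa)) next
      logf("fit-fwe: %s", sid)
      dwi <- read_volume(sp$dwi)
      mask <- apply(dwi$data[, , , 1, drop = FALSE], 1:3, function(x) x > 0)
      fit <- fit_free_water(dwi, scheme, mask, fit_config)
      write_volume(fw_volume(fit$fw_fa_map, dwi$affine), out_fa)
      write_volume(fw_volume(fit$fw_md_map, dwi$affine),
                   file.path(dirname(sp$dwi), "fwe_md.nii.gz"))
      write_volume(fw_volume(fit$fwf_map, dwi$affine),
                   file.path(dirname(sp$dwi), "fwe_fwf.nii.gz"))
    }
  }

  if ("profile" %in% stages) {
    if (overwrite || !file.exists(paths$profiles)) {
      logf("profile: building %d-node tract profiles", config$n_nodes)
      cp <- cohort_profiles(config)
      readr::write_csv(cp$subjects, paths$subjects)
      write_profiles(cp$profiles, paths$profiles)
    } else {
      logf("profile: cached profiles found, reusing")
    }
    manifest$outputs$profiles <- paths$profiles
    manifest$outputs$subjects <- paths$subjects
  }

  results <- NULL
  if ("analyze" %in% stages) {
    if (!file.exists(paths$profiles)) {
      abort("analyze: no profiles.csv in workspace (run the profile stage).")
    }
    profiles <- read_profiles(paths$profiles, n_nodes = config$n_nodes)
    subjects <- readr::read_csv(paths$subjects, show_col_types = FALSE)
    logf("analyze: threshold %g%%%s", threshold,
         if (!is.null(sweep)) sprintf(", sweep %s-%s%%", min(sweep),
                                      max(sweep)) else "")
    results <- analyze_cohort(profiles, subjects, threshold = threshold,
                              bins = bins, sweep = sweep)
    dir.create(paths$analysis, showWarnings = FALSE)
    for (nm in names(results)) {
      if (!is.data.frame(results[[nm]])) next
      out <- file.path(paths$analysis, paste0(nm, ".csv"))
      tab <- results[[nm]]
      tab$threshold_pct <- threshold
      tab$config_hash <- manifest$config_hash
      readr::write_csv(tab, out, na = "")
      manifest$outputs[[nm]] <- out
    }
  }

  if ("report" %in% stages) {
    if (is.null(results)) {
      abort("report: the analyze stage must run in the same invocation.")
    }
    fig <- file.path(paths$analysis, "distance_asymmetry.pdf")
    logf("report: writing %s", fig)
    p <- plot_distance_asymmetry(results$distance_asymmetry)
    ggplot2::ggsave(fig, p, width = 9, height = 5)
    manifest$outputs$figure <- fig
  }

  manifest$finished <- format(Sys.time())
  manifest$log <- log_lines
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
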