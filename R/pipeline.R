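# End-to-end pipeline: the four-movement healthy verification (muscle
# calibration + agreement against the radiological statistics) followed by
# the L5-S1 degeneration comparison; all artifacts written as CSV/JSON with a
# checksum manifest.

#' Run the full analysis pipeline
#'
#' Executes, in order: the four healthy-model muscle calibrations, the
#' model-versus-radiology agreement report (using a synthetic cohort), and
#' the degeneration study (severity fitted on flexion). Writes per-movement
#' angle tables, the agreement report, the mobility comparisons and summary,
#' and a manifest of every artifact with MD5 checksums.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed RNG seed for the synthetic cohort.
#' @param geometry_config Optional geometry YAML path.
#' @param n_subjects Cohort size for the verification stage.
#' @param quick If `TRUE`, skip the calibrations and use pure-moment load
#'   cases for the verification stage (used for fast smoke runs).
#' @return Invisibly, the manifest tibble (file, md5).
#' @export
run_pipeline <- function(out_dir, seed = 1L, geometry_config = NULL,
                         n_subjects = 25, quick = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- if (is.null(geometry_config)) default_spine_config() else
    default_spine_config(geometry_config)
  geom <- build_default_spine(cfg)
  card <- material_card("healthy")
  files <- character()
  put_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(tibble::as_tibble(df), path, row.names = FALSE)
    files <<- c(files, path)
    path
  }
  put_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <<- c(files, path)
    path
  }

  # stage 1: healthy verification
  maxima <- list()
  for (mv in c("FLX", "EXT", "LB", "AR")) {
    if (quick) {
      at <- range_of_motion(mv, geometry = geom, cards = card)
      conv <- list(movement = mv, mode = "pure_moment")
    } else {
      cal <- calibrate(mv, geometry = geom, cards = card)
      at <- cal$achieved
      conv <- c(glance(cal), list(mode = "calibrated"))
      put_csv(cal$magnitudes, paste0("muscles_", mv, ".csv"))
    }
    put_csv(at, paste0("angles_healthy_", mv, ".csv"))
    put_json(conv, paste0("convergence_", mv, ".json"))
    maxima[[mv]] <- at
  }

  # stage 2: synthetic cohort + agreement
  spec <- cohort_spec(n_subjects = n_subjects, seed = seed)
  cohort <- generate_cohort(spec)
  put_csv(cohort, "cohort_angles.csv")
  agree <- dplyr::bind_rows(lapply(c("FLX", "EXT", "LB"), function(mv) {
    rep <- agreement_report(maxima[[mv]], cohort_stats(cohort, mv))
    rep$movement <- mv
    rep
  }))
  put_csv(agree, "agreement_report.csv")

  # stage 3: degeneration (quick mode skips the flexion severity fit)
  study <- degeneration_study(geom, card, calibrate = !quick)
  for (cmp in study$comparisons) {
    put_csv(cmp, paste0("mobility_", cmp$movement[1], ".csv"))
  }
  put_json(list(
    severity = study$config$severity,
    height_loss_fraction = study$config$height_loss_fraction,
    slack = as.list(study$config$slack),
    percent_increase = setNames(
      as.list(study$report$percent_increase), study$report$movement)
  ), "degeneration_summary.json")

  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  put_csv(manifest, "manifest.csv")
  invisible(manifest)
}
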