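#' @title End-to-end analysis pipeline
#' @description Runs the full analysis — global/local classification,
#'   switching, pairwise scanpath distances with divergence summaries, and
#'   AOI metrics — on either input files or a freshly generated synthetic
#'   cohort, and writes the result tables plus a run manifest.
#' @name pipeline_cli
NULL

collect_warnings <- function(expr) {
  msgs <- character(0)
  val <- withCallingHandlers(expr, warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = val, warnings = msgs)
}

#' Run the full analysis pipeline
#'
#' @param config list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{fixations, meta, aois}{input file paths (`aois` a named list or
#'       vector, one per sculpture). Omit all three to simulate instead.}
#'     \item{simulate}{logical; when `TRUE` (or when no input paths are
#'       given) a synthetic cohort is generated from `cohort` /`seed`.}
#'     \item{cohort}{optional [cohort_config()] (list form in YAML).}
#'     \item{seed}{seed for simulation (default 1).}
#'     \item{threshold_ms}{global/local threshold, ms, or `"cohort_mean"`
#'       (default 187).}
#'     \item{heights_px}{named numeric: sculpture silhouette heights, px
#'       (used to compute conversion factors).}
#'     \item{factors}{named numeric: configured conversion factors px/ms;
#'       overrides `heights_px` per sculpture.}
#'     \item{inspection}{`"span"` (default) or `"sum"`.}
#'   }
#' @param out_dir output directory (created if needed). Files written:
#'   `globallocal.csv`, `switching.csv`, one `distances_<sculpture>.csv` per
#'   sculpture (full symmetric matrix), `divergence_summary.csv`,
#'   `aoi_metrics.csv`, `manifest.json`. On any stage failure, partial
#'   outputs are removed and the error is re-raised with the stage name.
#' @return invisible list with all result objects (`metrics`, `summaries`,
#'   `distance_matrices`, `divergence`, `aoi`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  all_warnings <- character(0)
  stage <- "configuration"
  emit <- function(name, df, digits = NULL) {
    path <- file.path(out_dir, name)
    write_summary_table(df, path, digits = digits)
    written <<- c(written, path)
    path
  }
  run_stage <- function(name, expr) {
    stage <<- name
    res <- collect_warnings(expr)
    all_warnings <<- c(all_warnings, res$warnings)
    res$value
  }

  result <- tryCatch({
    # ---- inputs --------------------------------------------------------
    simulate <- isTRUE(config$simulate) || is.null(config$fixations)
    if (simulate) {
      cohort_cfg <- if (inherits(config$cohort, "cohort_config"))
        config$cohort else do.call(cohort_config, c(
          config$cohort %||% list(), list(seed = config$seed %||% 1L)))
      cohort <- run_stage("simulate", generate_cohort(cohort_cfg))
      ft <- cohort$fixations; meta <- cohort$meta; aois <- cohort$aois
    } else {
      ft <- run_stage("read_fixations", read_fixation_table(config$fixations))
      meta <- run_stage("read_metadata",
                        read_participant_metadata(config$meta))
      aois <- run_stage("read_aois", {
        a <- lapply(config$aois, read_aoi_set)
        names(a) <- vapply(a, `[[`, "", "sculpture_id")
        a
      })
    }
    profiles <- run_stage("expertise", expertise_profiles(meta))
    sculpt_ids <- sort(unique(ft$sculpture_id))
    threshold <- config$threshold_ms %||% 187
    inspection <- config$inspection %||% "span"

    # ---- global/local --------------------------------------------------
    gl <- run_stage("global_local",
                    global_local_metrics(ft, threshold, inspection))
    gl_sum <- run_stage("group_summary",
      do.call(rbind, lapply(sculpt_ids, function(sid) {
        s <- group_summary(gl[gl$sculpture_id == sid, ], profiles, "gl_ratio")
        cbind(sculpture_id = sid, s)
      })))
    sw_sum <- run_stage("group_summary",
      do.call(rbind, lapply(sculpt_ids, function(sid) {
        s <- group_summary(gl[gl$sculpture_id == sid, ], profiles,
                           "switch_rate_hz")
        cbind(sculpture_id = sid, s)
      })))
    emit("globallocal.csv", gl_sum, digits = c(mean = 2, sd = 2))
    emit("switching.csv", sw_sum, digits = c(mean = 2, sd = 2))

    # ---- eyenalysis distances ------------------------------------------
    dms <- list(); div_rows <- list(); factors_used <- list()
    for (sid in sculpt_ids) {
      fac <- run_stage("conversion_factor", {
        if (!is.null(config$factors[[sid]])) {
          conversion_factor(ft, sid, value = config$factors[[sid]])
        } else {
          h <- config$heights_px[[sid]] %||%
            attr(ft, "heights_px")[[sid]] %||%
            (if (simulate) cohort$config$sculptures[[sid]]$height_px else NULL)
          if (is.null(h)) stop_validation(
            "no conversion factor or height_px configured for sculpture '%s'", sid)
          conversion_factor(ft, sid, height_px = h)
        }
      })
      factors_used[[sid]] <- list(value = fac$value, source = fac$source)
      dm <- run_stage("pairwise_distances",
                      pairwise_distances(ft, profiles, sid, fac))
      dms[[sid]] <- dm
      mat <- as.data.frame(round_half_up(dm$distances))
      mat <- cbind(participant_id = dm$participants, mat)
      emit(sprintf("distances_%s.csv", sid), mat)
      ds <- run_stage("divergence_summary", divergence_summary(dm))
      div_rows[[sid]] <- cbind(sculpture_id = sid, ds)
    }
    divergence <- do.call(rbind, div_rows)
    emit("divergence_summary.csv", divergence,
         digits = c(mean = 0, sd = 0))

    # ---- AOI metrics ---------------------------------------------------
    aoi <- run_stage("aoi_metrics", aoi_metrics(ft, aois, inspection))
    emit("aoi_metrics.csv", aoi,
         digits = c(pct_on_features = 2, revisits_per_min = 2,
                    inspection_time_ms = 0))

    # ---- manifest ------------------------------------------------------
    stage <- "manifest"
    cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "cohort")],
                                 auto_unbox = TRUE, force = TRUE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("scanpath3d")),
      r_version = R.version.string,
      simulated = simulate,
      threshold_ms = if (identical(threshold, "cohort_mean"))
        attr(gl, "threshold_ms") else threshold,
      threshold_mode = if (identical(config$threshold_ms, "cohort_mean"))
        "cohort_mean" else "fixed",
      inspection = inspection,
      config_hash = fnv1a32(as.character(cfg_json)),
      sculptures = as.list(sculpt_ids),
      conversion_factors = factors_used,
      n_participants = length(unique(ft$participant_id)),
      n_fixations = nrow(ft),
      n_undefined_ratios = sum(!gl$gl_defined),
      n_missing_distance_cells = sum(vapply(dms, `[[`, 0, "n_missing")),
      n_images_skipped = sum(vapply(dms, `[[`, 0, "n_images_skipped")),
      n_warnings = length(all_warnings),
      warnings = as.list(all_warnings))
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, manifest_path)

    list(metrics = gl, summaries = list(gl_ratio = gl_sum,
                                        switch_rate = sw_sum),
         distance_matrices = dms, divergence = divergence, aoi = aoi,
         manifest = manifest)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
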