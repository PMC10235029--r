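#' Pipeline run configuration
#'
#' Configures the end-to-end synthetic study: cohort generation, an
#' optional imaging demonstration (ground truth -> block log-ratio
#' spectra -> TV-regularized inversion -> feature extraction), histology
#' quantification, regression/classification and the cohort summary.
#' Every random stage derives its seed deterministically from the global
#' seed and the stage name, so a run is reproducible from the config
#' alone.
#'
#' @param output_dir Directory receiving all stage outputs.
#' @param seed Global integer seed.
#' @param stages Character vector of stages to run, in dependency order,
#'   among `"cohort"`, `"imaging"`, `"histology"`, `"model"`, `"summary"`.
#' @param cohort A [cohort_spec()] (its seed field is overridden by the
#'   derived stage seed).
#' @param imaging List of imaging-demo settings: `shape`, `levels`,
#'   `noise_sd`, `n_frames`, `freq_mhz`, `solver` (a [solver_config()]).
#' @param histology A [histology_spec()] for the histology demo image.
#' @param gpr A [gpr_config()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            seed = 1,
                            stages = c("cohort", "imaging", "histology",
                                       "model", "summary"),
                            cohort = cohort_spec(),
                            imaging = list(
                              shape = c(12, 12),
                              levels = list(delta_b = c(1, 10),
                                            delta_alpha = c(0.1, 0.5)),
                              noise_sd = 0.5,
                              n_frames = 3,
                              freq_mhz = seq(4, 18, length.out = 20),
                              solver = solver_config()),
                            histology = histology_spec(),
                            gpr = gpr_config()) {
  stopifnot(is.character(output_dir), length(output_dir) == 1)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(output_dir = output_dir, seed = seed, stages = stages,
                 cohort = cohort, imaging = imaging,
                 histology = histology, gpr = gpr),
            class = "pipeline_config")
}

# deterministic 32-bit stage seed from the global seed and stage name
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(global_seed) %% 100000L) * 7919L + h
}

config_digest <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(rapply(unclass(config), unclass,
                                     how = "replace"),
                              auto_unbox = TRUE, digits = NA, force = TRUE),
             f)
  unname(tools::md5sum(f))
}

#' Run the synthetic QUS steatosis pipeline
#'
#' Executes the enabled stages in dependency order, writing plain-text
#' artifacts (CSV/JSON) under the configured output directory, and
#' returns a manifest recording, per stage, its outputs, their MD5
#' hashes, the derived seed and the wall time.  A re-run with an
#' unchanged configuration skips stages whose outputs already exist and
#' whose recorded config digest matches.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly also written to
#'   `manifest.json`.
#' @export
run_qus_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  digest <- config_digest(config)
  manifest_path <- file.path(config$output_dir, "manifest.json")
  old <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else NULL

  manifest <- list(config_digest = digest, seed = config$seed,
                   stages = list())
  outputs_of <- function(stage) {
    file.path(config$output_dir, switch(stage,
      cohort = "cohort.csv",
      imaging = c("imaging_features.csv", "imaging_maps.csv"),
      histology = c("histology.csv"),
      model = c("predictions.csv", "metrics.json"),
      summary = c("summary.csv", "feature_p_values.csv")))
  }
  up_to_date <- function(stage) {
    !is.null(old) && identical(old$config_digest, digest) &&
      all(file.exists(outputs_of(stage)))
  }

  artifacts <- list()
  for (stage in config$stages) {
    outs <- outputs_of(stage)
    if (up_to_date(stage)) {
      manifest$stages[[stage]] <- list(status = "skipped", outputs = outs,
                                       md5 = unname(tools::md5sum(outs)))
      next
    }
    t0 <- Sys.time()
    sseed <- stage_seed(config$seed, stage)
    run_stage(stage, config, sseed, artifacts)
    manifest$stages[[stage]] <- list(
      status = "run", outputs = outs,
      md5 = unname(tools::md5sum(outs)),
      seed = sseed,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             manifest_path)
  invisible(manifest)
}

run_stage <- function(stage, config, sseed, artifacts) {
  out <- config$output_dir
  need <- function(f) {
    p <- file.path(out, f)
    if (!file.exists(p))
      stop(sprintf("stage '%s' requires missing upstream artifact %s",
                   stage, f), call. = FALSE)
    p
  }
  switch(stage,
    cohort = {
      spec <- config$cohort
      spec$seed <- sseed
      coh <- make_cohort(spec)
      utils::write.csv(coh, file.path(out, "cohort.csv"),
                       row.names = FALSE)
    },
    imaging = {
      im <- config$imaging
      gt <- make_ground_truth(im$shape, "piecewise", im$levels)
      vol <- simulate_spectra(gt, freq_mhz = im$freq_mhz,
                              noise_sd = im$noise_sd,
                              n_frames = im$n_frames, seed = sseed)
      maps <- fit_rpl_tv(vol, im$solver)
      snr <- array(rayleigh_snr(), dim = dim(maps$delta_b))
      feats <- extract_features(maps, snr)
      utils::write.csv(feats, file.path(out, "imaging_features.csv"),
                       row.names = FALSE)
      flat <- data.frame(
        axial = rep(seq_len(dim(maps$delta_b)[1]), dim(maps$delta_b)[2]),
        lateral = rep(seq_len(dim(maps$delta_b)[2]),
                      each = dim(maps$delta_b)[1]),
        delta_b = as.vector(maps$delta_b[, , 1]),
        delta_n = as.vector(maps$delta_n[, , 1]),
        delta_alpha = as.vector(maps$delta_alpha[, , 1]))
      utils::write.csv(flat, file.path(out, "imaging_maps.csv"),
                       row.names = FALSE)
    },
    histology = {
      spec <- config$histology
      spec$seed <- sseed
      him <- make_histology_image(spec)
      seg <- segment_fat_vacuoles(him$image)
      df <- data.frame(
        target_fat_fraction_pct = spec$target_fat_fraction_pct,
        true_fat_fraction_pct = him$achieved_fat_fraction_pct,
        measured_fat_fraction_pct = seg$fat_fraction_pct,
        grade = brunt_grade(seg$fat_fraction_pct))
      utils::write.csv(df, file.path(out, "histology.csv"),
                       row.names = FALSE)
    },
    model = {
      coh <- utils::read.csv(need("cohort.csv"))
      res <- fit_predict_loo(coh, config = config$gpr,
                             grades = coh$grade_true)
      cls <- classify_from_predictions(res, coh$grade_true)
      utils::write.csv(res$predictions,
                       file.path(out, "predictions.csv"),
                       row.names = FALSE)
      metrics <- list(r_squared = res$r_squared, rmse = res$rmse,
                      accuracy_binary = cls$accuracy_binary,
                      accuracy_multiclass = cls$accuracy_multiclass,
                      feature_p_values = as.list(res$feature_p_values))
      writeLines(jsonlite::toJSON(metrics, auto_unbox = TRUE,
                                  digits = NA, pretty = TRUE),
                 file.path(out, "metrics.json"))
    },
    summary = {
      coh <- utils::read.csv(need("cohort.csv"))
      sm <- summarize_cohort(coh, coh$grade_true)
      utils::write.csv(sm$table, file.path(out, "summary.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(feature = names(sm$p_values),
                                  p_value = unname(sm$p_values)),
                       file.path(out, "feature_p_values.csv"),
                       row.names = FALSE)
    })
  invisible(NULL)
}
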