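# End-to-end orchestration: a single config drives seven stages
# (simulate | indices | qc | calibrate | phenology | propagate | report),
# each writing plain CSV artifacts plus a JSON manifest (input hashes, config
# snapshot, derived seed, row counts) under the output directory. One global
# seed deterministically derives per-stage seeds so stages rerun
# independently yet reproducibly.

#' Default pipeline configuration
#'
#' Every default matches the study design it emulates: a 3-site, 2-year
#' schedule of 1-min recordings every 10 min at 44.1 kHz; 3-10 kHz index
#' band; min-max scaling to \[0.0001, 0.9999\]; squared Mahalanobis threshold
#' 12; delta-AICc 2 averaging; 5-fold x 100 cross-validation; cyclic smooths
#' with 4 basis functions; 1000 propagation iterations.
#'
#' @param output_dir Directory for all stage artifacts.
#' @param seed Global integer seed.
#' @param ... Named overrides for nested entries, e.g.
#'   `simulate = list(duration = 10)` (merged shallowly per section).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir = "phenoacoustics_out", seed = 1L,
                            ...) {
  cfg <- list(
    output_dir = output_dir,
    seed = as.integer(seed),
    band = list(f_min = 3000, f_max = 10000),
    simulate = list(sites = c("T1", "T2", "T3"),
                    start_date = "2018-01-01", end_date = "2019-12-31",
                    cadence_minutes = 10, day_step = 1, missing_fraction = 0,
                    duration = 60, sample_rate = 44100,
                    noise_floor_db = -60, n_sonotypes = 12,
                    rain_rate = 0.08, fault_rate = 0.05),
    indices = list(window_length = 512, aci_chunk = 5, adi_threshold = -50,
                   np_threshold = 0.01),
    qc = list(mahalanobis_threshold = 12, rain_safety = 0.9),
    model = list(delta_max = 2, folds = 5, repeats = 100,
                 candidates = calibration_terms()),
    gam = list(k = 4),
    grid = list(hour_step = 1, doy_step = 1),
    propagation = list(n_iter = 1000)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      for (sub in names(over[[nm]])) cfg[[nm]][[sub]] <- over[[nm]][[sub]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline config as YAML
#'
#' Serialization round-trips: `write_config(read_config(p), p)` leaves the
#' file byte-identical.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `read_config` returns a `pipeline_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  writeLines(yaml::as.yaml(x), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- "pipeline_config"
  cfg
}

stage_path <- function(config, ...) file.path(config$output_dir, ...)

write_manifest <- function(config, stage, files, extra = list()) {
  files <- files[file.exists(files)]
  man <- c(list(stage = stage,
                seed = derive_seed(config$seed, stage),
                created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                files = as.list(stats::setNames(as.character(
                  tools::md5sum(files)), basename(files))),
                row_counts = as.list(stats::setNames(
                  vapply(files, function(f) {
                    if (grepl("\\.csv$", f)) {
                      nrow(utils::read.csv(f))
                    } else NA_integer_
                  }, integer(1)), basename(files))),
                config = unclass(config)),
           extra)
  path <- stage_path(config, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

require_artifact <- function(config, file, producer) {
  p <- stage_path(config, file)
  if (!file.exists(p)) {
    stop("missing artifact '", file, "'; run stage '", producer, "' first")
  }
  p
}

save_calibration_model <- function(model, path) {
  obj <- list(coefficients = as.list(model$coefficients),
              vcov = unname(model$vcov),
              vcov_names = names(model$coefficients),
              phi = model$phi, family = model$family,
              component_terms = model$component_terms,
              weights = model$weights,
              inclusion = as.list(model$inclusion),
              xlevels = model$xlevels,
              n_components = model$n_components)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

load_calibration_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  V <- as.matrix(obj$vcov)
  dimnames(V) <- list(obj$vcov_names, obj$vcov_names)
  structure(list(coefficients = unlist(obj$coefficients), vcov = V,
                 phi = obj$phi, family = obj$family,
                 component_terms = obj$component_terms,
                 weights = obj$weights, inclusion = unlist(obj$inclusion),
                 xlevels = lapply(obj$xlevels, as.character),
                 n_components = obj$n_components),
            class = "averaged_model")
}

stage_simulate <- function(config) {
  sim <- config$simulate
  sch <- recording_schedule(sites = sim$sites, start_date = sim$start_date,
                            end_date = sim$end_date,
                            missing_fraction = sim$missing_fraction,
                            cadence_minutes = sim$cadence_minutes,
                            day_step = sim$day_step)
  audio_dir <- stage_path(config, "audio")
  res <- simulate_corpus(
    sch, library = default_sonotype_library(sim$n_sonotypes),
    activity = default_activity_model(sim$n_sonotypes),
    rain_rate = sim$rain_rate, fault_rate = sim$fault_rate,
    seed = derive_seed(config$seed, "simulate"), output_dir = audio_dir,
    duration = sim$duration, sample_rate = sim$sample_rate,
    noise_floor_db = sim$noise_floor_db)
  truth_path <- stage_path(config, "truth.csv")
  utils::write.csv(res$truth, truth_path, row.names = FALSE)
  write_manifest(config, "simulate", c(truth_path),
                 list(n_clips = nrow(res$truth),
                      planned = planned_clip_count(sch)))
  res$truth
}

stage_indices <- function(config) {
  truth_path <- require_artifact(config, "truth.csv", "simulate")
  truth <- utils::read.csv(truth_path)
  audio_dir <- stage_path(config, "audio")
  ic <- config$indices
  rows <- lapply(truth$clip_id, function(id) {
    clip <- read_wav(file.path(audio_dir, paste0(id, ".wav")))
    sp <- compute_spectrogram(clip, window_length = ic$window_length)
    idx <- compute_indices(clip, f_min = config$band$f_min,
                           f_max = config$band$f_max,
                           window_length = ic$window_length,
                           aci_chunk = ic$aci_chunk,
                           adi_threshold = ic$adi_threshold,
                           np_threshold = ic$np_threshold)
    cbind(idx, rain_metrics(clip, spec = sp))
  })
  idx <- do.call(rbind, rows)
  idx <- merge(idx[, setdiff(names(idx), "site")],
               truth[, c("clip_id", "site", "datetime_iso", "hour", "doy",
                         "year")],
               by = "clip_id", sort = FALSE)
  path <- stage_path(config, "indices.csv")
  utils::write.csv(idx, path, row.names = FALSE)
  write_manifest(config, "indices", path)
  idx
}

stage_qc <- function(config) {
  idx_path <- require_artifact(config, "indices.csv", "indices")
  truth_path <- require_artifact(config, "truth.csv", "simulate")
  idx <- utils::read.csv(idx_path)
  truth <- utils::read.csv(truth_path)
  ok <- !idx$silent
  idx <- idx[ok, , drop = FALSE]
  rain_ids <- truth$clip_id[truth$rain_flag]
  rm_cols <- c("psd_low", "psd_mid", "snr_low", "snr_mid")
  metrics <- idx[, rm_cols]
  thresholds <- NULL
  if (sum(idx$clip_id %in% rain_ids) >= 10L) {
    thresholds <- calibrate_rain_thresholds(
      metrics[idx$clip_id %in% rain_ids, , drop = FALSE],
      safety = config$qc$rain_safety)
  }
  report <- qc_screen(idx, rain_metrics_df = if (!is.null(thresholds))
    metrics else NULL, thresholds = thresholds,
    mahal_threshold = config$qc$mahalanobis_threshold)
  path <- stage_path(config, "qc.csv")
  utils::write.csv(report$records, path, row.names = FALSE)
  message(sprintf("qc: retained %d of %d clips (%.1f%%)",
                  report$summary$n_retained, report$summary$n_total,
                  100 * report$summary$retention))
  write_manifest(config, "qc", path, list(summary = report$summary))
  report
}

stage_calibrate <- function(config) {
  idx <- utils::read.csv(require_artifact(config, "indices.csv", "indices"))
  qc <- utils::read.csv(require_artifact(config, "qc.csv", "qc"))
  truth <- utils::read.csv(require_artifact(config, "truth.csv", "simulate"))
  keep <- qc$clip_id[qc$retained]
  idx <- idx[idx$clip_id %in% keep, , drop = FALSE]
  idx <- scale_indices(idx)
  scaling <- attr(idx, "scaling")
  jsonlite::write_json(scaling, stage_path(config, "index_scaling.json"),
                       digits = NA)
  data <- merge(idx, truth[, c("clip_id", "n_sonotypes_15s", "coverage")],
                by = "clip_id")
  data$coverage_sq <- squeeze_proportion(data$coverage)
  out <- list()
  for (resp in c("coverage", "sonotypes")) {
    family <- if (resp == "coverage") "beta_logit" else "poisson_log"
    ycol <- if (resp == "coverage") "coverage_sq" else "n_sonotypes_15s"
    d <- data
    d[[resp]] <- d[[ycol]]
    ranking <- enumerate_models(d, resp, family,
                                candidates = config$model$candidates)
    avg <- average_models(ranking, delta_max = config$model$delta_max)
    best_terms <- ranking$fits[[1L]]$terms
    cv <- cross_validate(d, best_terms, resp, family,
                         folds = config$model$folds,
                         repeats = config$model$repeats,
                         seed = derive_seed(config$seed, "cv", resp))
    utils::write.csv(ranking$table,
                     stage_path(config, paste0("ranking_", resp, ".csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(coefficient = names(avg$coefficients),
                                estimate = avg$coefficients,
                                se = sqrt(diag(avg$vcov))),
                     stage_path(config, paste0("averaged_", resp, ".csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(term = names(avg$inclusion),
                                inclusions = as.integer(avg$inclusion),
                                n_components = avg$n_components),
                     stage_path(config, paste0("inclusion_", resp, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(list(rmse_mean = cv$rmse_mean, rmse_sd = cv$rmse_sd,
                              mae_mean = cv$mae_mean, mae_sd = cv$mae_sd),
                         stage_path(config, paste0("cv_", resp, ".json")),
                         auto_unbox = TRUE, digits = NA)
    save_calibration_model(avg, stage_path(config,
                                           paste0("model_", resp, ".json")))
    out[[resp]] <- list(ranking = ranking, averaged = avg, cv = cv)
  }
  write_manifest(config, "calibrate",
                 stage_path(config, c("ranking_coverage.csv",
                                      "ranking_sonotypes.csv",
                                      "averaged_coverage.csv",
                                      "averaged_sonotypes.csv")))
  invisible(out)
}

default_grid <- function(config) {
  sim <- config$simulate
  years <- unique(format(seq(as.Date(sim$start_date), as.Date(sim$end_date),
                             by = "day"), "%Y"))
  expand.grid(hour = seq(1, 24, by = config$grid$hour_step),
              doy = seq(1, 365, by = config$grid$doy_step),
              site = sim$sites, year = as.integer(years),
              stringsAsFactors = FALSE)
}

stage_phenology <- function(config) {
  idx <- utils::read.csv(require_artifact(config, "indices.csv", "indices"))
  qc <- utils::read.csv(require_artifact(config, "qc.csv", "qc"))
  scaling <- jsonlite::read_json(require_artifact(config,
                                                  "index_scaling.json",
                                                  "calibrate"),
                                 simplifyVector = TRUE)
  idx <- idx[idx$clip_id %in% qc$clip_id[qc$retained], , drop = FALSE]
  idx <- scale_indices(idx, scaling = scaling)
  fits <- fit_phenology_gams(idx, k = config$gam$k)
  grid <- default_grid(config)
  paths <- character(0)
  for (nm in names(fits)) {
    pr <- predict_gam(fits[[nm]], grid)
    p <- stage_path(config, paste0("gam_pred_", nm, ".csv"))
    utils::write.csv(pr, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  write_manifest(config, "phenology", paths)
  invisible(fits)
}

stage_propagate <- function(config) {
  grid <- default_grid(config)
  gam_preds <- list()
  for (nm in c("aci_s", "adi_s", "bi_s", "h_s", "np_s")) {
    gam_preds[[nm]] <- utils::read.csv(require_artifact(
      config, paste0("gam_pred_", nm, ".csv"), "phenology"))
  }
  paths <- character(0)
  for (resp in c("coverage", "sonotypes")) {
    calib <- load_calibration_model(require_artifact(
      config, paste0("model_", resp, ".json"), "calibrate"))
    dist <- propagate(gam_preds, calib, grid,
                      n_iter = config$propagation$n_iter,
                      seed = derive_seed(config$seed, "propagate", resp),
                      response = resp)
    p <- stage_path(config, paste0("activity_", resp, ".csv"))
    utils::write.csv(dist$summary, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  write_manifest(config, "propagate", paths,
                 list(n_iter = config$propagation$n_iter))
  invisible(paths)
}

stage_report <- function(config) {
  qc <- utils::read.csv(require_artifact(config, "qc.csv", "qc"))
  out <- list(retention = list(n_total = nrow(qc),
                               n_retained = sum(qc$retained),
                               retention = mean(qc$retained)))
  paths <- character(0)
  for (resp in c("coverage", "sonotypes")) {
    act <- utils::read.csv(require_artifact(
      config, paste0("activity_", resp, ".csv"), "propagate"))
    hourly <- stats::aggregate(cbind(median, mean, q2.5, q97.5) ~ hour,
                               data = act, FUN = mean)
    daily <- stats::aggregate(cbind(median, mean, q2.5, q97.5) ~ doy,
                              data = act, FUN = mean)
    ph <- stage_path(config, paste0("report_hourly_", resp, ".csv"))
    pd <- stage_path(config, paste0("report_daily_", resp, ".csv"))
    utils::write.csv(hourly, ph, row.names = FALSE)
    utils::write.csv(daily, pd, row.names = FALSE)
    paths <- c(paths, ph, pd)
    out[[resp]] <- list(hourly = hourly, daily = daily)
    cvp <- stage_path(config, paste0("cv_", resp, ".json"))
    if (file.exists(cvp)) {
      out[[paste0("cv_", resp)]] <- jsonlite::read_json(cvp,
                                                        simplifyVector = TRUE)
    }
  }
  write_manifest(config, "report", paths, list(retention = out$retention))
  out
}

#' Run one pipeline stage
#'
#' Stages form a chain; each reads the artifacts of its predecessors from the
#' output directory and errors (naming the stage to run first) when they are
#' absent. Rerunning a stage with identical inputs and seed reproduces
#' identical artifacts.
#'
#' @param stage One of `"simulate"`, `"indices"`, `"qc"`, `"calibrate"`,
#'   `"phenology"`, `"propagate"`, `"report"`, or `"all"`.
#' @param config A `pipeline_config`.
#' @return The stage's principal in-memory result, invisibly for the heavier
#'   stages.
#' @export
run_stage <- function(stage = c("simulate", "indices", "qc", "calibrate",
                                "phenology", "propagate", "report", "all"),
                      config) {
  stage <- match.arg(stage)
  if (!dir.exists(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE)
  }
  switch(stage,
         simulate = stage_simulate(config),
         indices = stage_indices(config),
         qc = stage_qc(config),
         calibrate = stage_calibrate(config),
         phenology = stage_phenology(config),
         propagate = stage_propagate(config),
         report = stage_report(config),
         all = {
           for (s in c("simulate", "indices", "qc", "calibrate", "phenology",
                       "propagate")) {
             run_stage(s, config)
           }
           run_stage("report", config)
         })
}
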