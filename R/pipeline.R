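# Staged end-to-end driver with on-disk artifacts: each stage reads its
# upstream artifacts, writes its own, and records the resolved
# configuration, seed and input hashes in a structured log.  Stage
# artifacts live on disk (NIfTI/CSV/JSON) so stages are independently
# testable and resumable.

#' Build a pipeline configuration
#'
#' @param out_dir output directory for all artifacts.
#' @param seed master seed.
#' @param n_dev,n_val cohort sizes for the \code{simulate} stage.
#' @param k_range candidate cluster numbers (default 2:32).
#' @param n_reps clustering repetitions per k (default 100).
#' @param n_bins quantization bins (default 256).
#' @param silhouette_n silhouette subsample cap.
#' @param lambda optional Cox-LASSO penalty grid.
#' @param n_boot bootstrap replicates for model comparison.
#' @param survival optional override of the generator's survival settings
#'   (see \code{\link{cohort_spec}}).
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(out_dir, seed = 1, n_dev = 20, n_val = 10,
                            k_range = 2:32, n_reps = 100, n_bins = 256,
                            silhouette_n = 2000, lambda = NULL,
                            n_boot = 100, survival = NULL) {
  structure(list(out_dir = out_dir, seed = seed, n_dev = n_dev,
                 n_val = n_val, k_range = k_range, n_reps = n_reps,
                 n_bins = n_bins, silhouette_n = silhouette_n,
                 lambda = lambda, n_boot = n_boot, survival = survival),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#' @param config a \code{pipeline_config}.
#' @param path JSON path.
#' @return \code{path} (write) or the config (read).
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(pipeline_config, x[intersect(names(x),
    names(formals(pipeline_config)))])
  cfg
}

pipeline_stages <- c("simulate", "preprocess", "perfusion", "habitats",
                     "features", "fit", "evaluate")

stage_log <- function(config, stage, msg) {
  line <- sprintf("[%s] %s: %s (seed=%s, config=%s)",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg,
                  config$seed, substr(object_hash(unclass(config)), 1, 8))
  message(line)
  logf <- file.path(config$out_dir, "pipeline.log")
  cat(line, "\n", file = logf, append = TRUE)
}

require_artifact <- function(path, produced_by) {
  if (!all(file.exists(path)))
    stop(sprintf("missing artifact '%s'; run stage '%s' first",
                 path[!file.exists(path)][1], produced_by), call. = FALSE)
  invisible(path)
}

cohort_dirs <- function(config)
  file.path(config$out_dir, "cohorts", c("development", "validation"))

load_processed_cohort <- function(config, cohort) {
  dir <- file.path(config$out_dir, "preprocessed", cohort)
  require_artifact(file.path(dir, "manifest.json"), "preprocess")
  read_cohort(dir)
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate} (synthetic dual cohort to NIfTI/CSV),
#' \code{preprocess} (1 mm isotropic resampling; histogram matching of the
#' validation cohort to the development reference), \code{perfusion}
#' (wash-in/washout/washout-ratio maps), \code{habitats} (population
#' clustering with k selection; habitat maps for both cohorts),
#' \code{features} (feature tables), \code{fit} (HRS Cox-LASSO model),
#' \code{evaluate} (five risk models report).  Each stage is idempotent
#' given fixed inputs and seed.
#'
#' @param stage stage name.
#' @param config a \code{pipeline_config}.
#' @return invisibly, the paths of the artifacts written.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, pipeline_stages)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pipeline_config(config, file.path(config$out_dir,
                                          "config_resolved.json"))
  out <- switch(stage,
    simulate = stage_simulate(config),
    preprocess = stage_preprocess(config),
    perfusion = stage_perfusion(config),
    habitats = stage_habitats(config),
    features = stage_features(config),
    fit = stage_fit(config),
    evaluate = stage_evaluate(config))
  invisible(out)
}

#' Run all pipeline stages in order
#' @param config a \code{pipeline_config}.
#' @param stages subset of stages to run (default: all, in order).
#' @return invisibly, the evaluation report path if produced.
#' @export
run_pipeline <- function(config, stages = pipeline_stages) {
  for (s in stages) run_stage(s, config)
  invisible(file.path(config$out_dir, "reports", "risk_models.csv"))
}

stage_simulate <- function(config) {
  dirs <- cohort_dirs(config)
  surv_dev <- config$survival
  spec_dev <- cohort_spec(n_patients = config$n_dev, cohort = "development",
                          seed = derive_seed(config$seed, 1))
  spec_val <- cohort_spec(n_patients = config$n_val, cohort = "validation",
                          seed = derive_seed(config$seed, 2))
  if (!is.null(surv_dev)) {
    spec_dev$survival[names(surv_dev)] <- surv_dev
    spec_val$survival[names(surv_dev)] <- surv_dev
  }
  stage_log(config, "simulate",
            sprintf("generating %d + %d patients", config$n_dev,
                    config$n_val))
  write_cohort(simulate_cohort(spec_dev), dirs[1])
  write_cohort(simulate_cohort(spec_val), dirs[2])
  stage_log(config, "simulate", "done")
  dirs
}

stage_preprocess <- function(config) {
  dirs <- cohort_dirs(config)
  require_artifact(file.path(dirs, "manifest.json"), "simulate")
  outd <- file.path(config$out_dir, "preprocessed",
                    c("development", "validation"))
  resampled <- list()
  for (i in 1:2) {
    raw <- read_cohort(dirs[i])
    stage_log(config, "preprocess",
              sprintf("resampling %d studies (%s), input hash %s",
                      length(raw$studies), basename(dirs[i]),
                      substr(object_hash(raw$manifest), 1, 8)))
    studies <- lapply(raw$studies, resample_isotropic)
    resampled[[i]] <- list(raw = raw, studies = studies)
  }
  ref <- build_reference_histogram(resampled[[1]]$studies,
                                   n_quantiles = config$n_bins)
  dir.create(file.path(config$out_dir, "preprocessed"), recursive = TRUE,
             showWarnings = FALSE)
  write_reference_histogram(ref, file.path(config$out_dir, "preprocessed",
                                           "reference_histogram.json"))
  resampled[[2]]$studies <- lapply(resampled[[2]]$studies, histogram_match,
                                   reference = ref)
  for (i in 1:2) {
    dir.create(outd[i], recursive = TRUE, showWarnings = FALSE)
    for (s in resampled[[i]]$studies) write_study(s, outd[i])
    manifest <- resampled[[i]]$raw$manifest
    manifest$spacing <- c(1, 1, 1)
    manifest$files <- lapply(manifest$files, function(f)
      f[!grepl("truehabitat", f)])
    jsonlite::write_json(manifest, file.path(outd[i], "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
    file.copy(file.path(dirs[i], "clinical.csv"),
              file.path(outd[i], "clinical.csv"), overwrite = TRUE)
  }
  stage_log(config, "preprocess", "done")
  outd
}

stage_perfusion <- function(config) {
  outd <- file.path(config$out_dir, "perfusion", c("development",
                                                   "validation"))
  for (i in 1:2) {
    coh <- load_processed_cohort(config, basename(outd[i]))
    dir.create(outd[i], recursive = TRUE, showWarnings = FALSE)
    stage_log(config, "perfusion", sprintf("mapping %d studies (%s)",
                                           length(coh$studies),
                                           basename(outd[i])))
    for (s in coh$studies) {
      m <- compute_perfusion_maps(s, roi_only = FALSE)
      for (part in c("ein", "eout", "rwo"))
        write_volume_nifti(m[[part]], s$spacing,
                           file.path(outd[i],
                                     paste0(s$pid, "_", part, ".nii.gz")))
    }
  }
  stage_log(config, "perfusion", "done")
  outd
}

load_maps <- function(config, cohort) {
  coh <- load_processed_cohort(config, cohort)
  pdir <- file.path(config$out_dir, "perfusion", cohort)
  lapply(coh$studies, function(s) {
    paths <- file.path(pdir, paste0(s$pid, "_", c("ein", "eout", "rwo"),
                                    ".nii.gz"))
    require_artifact(paths, "perfusion")
    v <- lapply(paths, function(p) read_volume_nifti(p)$data)
    structure(list(ein = v[[1]], eout = v[[2]], rwo = v[[3]], roi = s$roi,
                   pid = s$pid, spacing = s$spacing),
              class = "perfusion_maps")
  })
}

stage_habitats <- function(config) {
  maps_dev <- load_maps(config, "development")
  pool <- do.call(rbind, lapply(maps_dev, pfv_table))
  qz <- fit_quantizer(pool[, c("ein", "eout", "rwo")],
                      n_bins = config$n_bins)
  xq <- apply_quantizer(qz, pool)
  stage_log(config, "habitats",
            sprintf("clustering %d pooled voxels over k in [%d, %d]",
                    nrow(xq), min(config$k_range), max(config$k_range)))
  sweep <- habitat_diagnostics(xq, k_range = config$k_range,
                               n_reps = config$n_reps,
                               seed = derive_seed(config$seed, 40),
                               silhouette_n = config$silhouette_n)
  k_star <- select_k(sweep$diagnostics)
  model <- sweep$models[[as.character(k_star)]]
  model$quantizer <- qz
  hdir <- file.path(config$out_dir, "habitats")
  dir.create(hdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sweep$diagnostics,
                   file.path(hdir, "selection_diagnostics.csv"),
                   row.names = FALSE)
  write_habitat_model(model, file.path(hdir, "habitat_model.json"),
                      diagnostics = sweep$diagnostics)
  for (cohort in c("development", "validation")) {
    maps <- if (cohort == "development") maps_dev
            else load_maps(config, cohort)
    for (m in maps) {
      hm <- build_habitat_map(m, model)
      write_volume_nifti(hm$labels, m$spacing,
                         file.path(hdir, paste0(m$pid,
                                                "_habitat.nii.gz")))
    }
  }
  stage_log(config, "habitats", sprintf("selected k = %d", k_star))
  hdir
}

stage_features <- function(config) {
  hdir <- file.path(config$out_dir, "habitats")
  require_artifact(file.path(hdir, "habitat_model.json"), "habitats")
  model <- read_habitat_model(file.path(hdir, "habitat_model.json"))
  fdir <- file.path(config$out_dir, "features")
  dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
  for (cohort in c("development", "validation")) {
    coh <- load_processed_cohort(config, cohort)
    maps <- load_maps(config, cohort)
    hab <- NULL; dce <- NULL; perf <- NULL
    for (pid in names(coh$studies)) {
      s <- coh$studies[[pid]]
      hp <- file.path(hdir, paste0(pid, "_habitat.nii.gz"))
      require_artifact(hp, "habitats")
      labels <- read_volume_nifti(hp)$data
      labels <- array(as.integer(round(labels)), dim(labels))
      hm <- structure(list(labels = labels, k = model$k, pid = pid,
                           spacing = s$spacing,
                           proportions = habitat_proportions(labels,
                                                             model$k)),
                      class = "habitat_map")
      hab <- rbind(hab, habitat_feature_vector(hm, mask = s$roi,
                                               spacing = s$spacing))
      m <- maps[[pid]]
      wt <- function(img, tag) {
        v <- whole_tumor_features(img, s$roi)
        names(v) <- paste0(tag, "_", names(v))
        v
      }
      dce <- rbind(dce, c(wt(s$pre, "pre"), wt(s$early, "early"),
                          wt(s$delayed, "delayed")))
      perf <- rbind(perf, c(wt(m$ein, "ein"),
                            wt(ifelse(is.na(m$eout), 0, m$eout), "eout"),
                            wt(m$rwo, "rwo")))
    }
    rownames(hab) <- rownames(dce) <- rownames(perf) <- names(coh$studies)
    for (nm in c("hab", "dce", "perf")) {
      tab <- get(nm)
      utils::write.csv(data.frame(pid = rownames(tab), tab,
                                  check.names = FALSE),
                       file.path(fdir, sprintf("%s_%s.csv", cohort,
                                               c(hab = "habitat",
                                                 dce = "dce",
                                                 perf = "perfusion")[nm])),
                       row.names = FALSE)
    }
  }
  stage_log(config, "features", "done")
  fdir
}

read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$pid
  m
}

load_eval_inputs <- function(config, cohort) {
  fdir <- file.path(config$out_dir, "features")
  pdir <- file.path(config$out_dir, "preprocessed", cohort)
  require_artifact(file.path(fdir, sprintf("%s_habitat.csv", cohort)),
                   "features")
  clin <- utils::read.csv(file.path(pdir, "clinical.csv"))
  list(habitat = read_feature_csv(file.path(fdir, sprintf("%s_habitat.csv",
                                                          cohort))),
       dce = read_feature_csv(file.path(fdir, sprintf("%s_dce.csv",
                                                      cohort))),
       perfusion = read_feature_csv(file.path(fdir,
                                              sprintf("%s_perfusion.csv",
                                                      cohort))),
       clinical = encode_clinical(clin),
       time = clin$time_months, event = clin$event)
}

stage_fit <- function(config) {
  dev <- load_eval_inputs(config, "development")
  z <- z_score_normalize(dev$habitat)
  model <- fit_cox_lasso(z, dev$time, dev$event, lambda = config$lambda,
                         seed = derive_seed(config$seed, 50))
  mdir <- file.path(config$out_dir, "models")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  write_cox_model(model, file.path(mdir, "hrs_model.json"))
  stage_log(config, "fit",
            sprintf("HRS model: %d features selected, cutoff %.4g",
                    length(model$coefficients), model$cutoff))
  mdir
}

stage_evaluate <- function(config) {
  require_artifact(file.path(config$out_dir, "models", "hrs_model.json"),
                   "fit")
  dev <- load_eval_inputs(config, "development")
  val <- load_eval_inputs(config, "validation")
  res <- build_all_risk_models(dev, val, seed = derive_seed(config$seed, 60),
                               n_boot = config$n_boot)
  rdir <- file.path(config$out_dir, "reports")
  dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$report, file.path(rdir, "risk_models.csv"),
                   row.names = FALSE)
  stage_log(config, "evaluate", "done")
  rdir
}
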