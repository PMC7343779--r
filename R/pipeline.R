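#' Default pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]: phantom geometry and
#' tensor recipe, acquisition scheme, profile parameters, statistics
#' settings and the classification protocol. All tolerances, seeds and the
#' output directory live here so a run is fully described by its config
#' (and reproducible from it).
#'
#' @param seed Master seed used by every stochastic stage.
#' @param out_dir Output directory (created if missing).
#' @param ... Overrides for any top-level config entry (lists are merged).
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("cortexdti_run_"),
                               ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    phantom = list(geometry = "shell", theta_deg = 25, sigma_deg = 5,
                   lambdas = c(1.2, 0.4, 0.3) * 1e-3),
    dwi = list(n_dirs = 64L, bval = 2000, snr = Inf),
    fit = list(method = "ols"),
    profiles = list(step_h = 0.5, solver_tol = 1e-6, angle_unit = "radians"),
    stats = list(fdr_q = 0.05),
    classify = list(n_runs = 50L, k_folds = 10L, knn_k = 5L,
                    loading_threshold = 0.5)
  )
  cfg <- modifyList(cfg, list(...))
  structure(cfg, class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `run_config`.
#' @return `read_run_config` returns a `run_config`; round-trips losslessly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(modifyList(unclass(default_run_config()), cfg), class = "run_config")
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the stages in study order — simulate a phantom and its DWI
#' acquisition, fit the tensor field, build cortical profiles and regional
#' metrics, generate the multi-cohort feature tables, run the group
#' statistics, and run the binary and multiclass classification protocols —
#' writing each stage's outputs plus a manifest (seeds, config hash,
#' per-stage output hashes) to `config$out_dir` so an identical config
#' reproduces identical outputs.
#'
#' @param config A `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @return A `pipeline_result` list: `region_features`, `cohorts`,
#'   `mancova`, `posthoc`, `binary_report`, `selection`,
#'   `multiclass_report`, `manifest`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  manifest <- list(seed = seed, config_hash = rlang::hash(unclass(config)),
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("cortexdti")),
                   stages = list())
  stage_hash <- function(name, obj) {
    manifest$stages[[name]] <<- rlang::hash(obj)
  }

  # 1. phantom + acquisition ------------------------------------------------
  ph <- rlang::exec(make_phantom, !!!config$phantom, seed = seed)
  grad <- gradient_scheme(config$dwi$n_dirs, config$dwi$bval)
  dwi <- simulate_dwi(ph$tensors, grad$bvals, grad$bvecs,
                      snr = config$dwi$snr, seed = seed)
  stage_hash("simulate", list(dim(dwi$signals), sum(dwi$signals)))

  # 2. tensor fit -----------------------------------------------------------
  tf <- fit_tensor(dwi, method = config$fit$method)
  stage_hash("fit_tensor", tf$D)

  # 3. profiles + regional metrics ------------------------------------------
  pot <- solve_ribbon_potential(ph$ribbon, tol = config$profiles$solver_tol)
  prof <- trace_profiles(pot, ph$ribbon, step_h = config$profiles$step_h)
  pm <- sample_profile_metrics(prof, tf)
  feats <- aggregate_regions(pm, subject = "phantom")
  if (identical(config$profiles$angle_unit, "degrees")) {
    feats <- dplyr::mutate(feats, value = ifelse(.data$metric == "angle_r",
                                                 .data$value * 180 / pi,
                                                 .data$value))
  }
  write.csv(feats, file.path(config$out_dir, "region_features.csv"),
            row.names = FALSE)
  stage_hash("profiles", feats)

  # 4. cohorts --------------------------------------------------------------
  cohorts <- make_cohorts(seed = seed)
  write.csv(cohorts, file.path(config$out_dir, "cohorts.csv"), row.names = FALSE)
  stage_hash("cohorts", cohorts)

  # 5. group statistics -----------------------------------------------------
  wb <- c("md_wb", "angle_r_wb", "perp_pd_wb", "parl_pd_wb", "gm_fr")
  sel <- dplyr::filter(cohorts, .data$cohort == "selection")
  fit <- mancova(sel, outcomes = wb, group = "group", covariates = "age")
  affected <- unique(unlist(lapply(cohort_spec()$elevations, names)))
  reg_cols <- paste0("angle_r_", gsub(" ", "_", affected))
  ph_tests <- purrr::map_dfr(reg_cols, function(rc) {
    dplyr::mutate(posthoc_pairwise(sel, rc, "diagnosis"), region = rc)
  })
  ph_tests <- dplyr::bind_cols(ph_tests,
                               fdr_bh(ph_tests$p_value, config$stats$fdr_q)[-1L])
  write.csv(ph_tests, file.path(config$out_dir, "posthoc.csv"), row.names = FALSE)
  stage_hash("group_stats", list(glance(fit), ph_tests))

  # 6. classification -------------------------------------------------------
  train <- dplyr::filter(cohorts, .data$cohort == "training")
  test <- dplyr::filter(cohorts, .data$cohort == "test")
  bin_feats <- c("angle_r_wb", "perp_pd_wb", "parl_pd_wb", "md_wb", "gm_fr", "mmse")
  binary <- train_and_evaluate(train, test, "KNN", bin_feats, label = "group",
                               class_order = c("HS", "FTD"), seed = seed,
                               knn_k = config$classify$knn_k)

  pf <- pca_filter(sel, features = regional_feature_names(),
                   loading_threshold = config$classify$loading_threshold)
  mc_feats <- unique(c("angle_r_wb", pf$selected))
  selres <- select_classifier(sel, mc_feats, label = "diagnosis",
                              n_runs = config$classify$n_runs,
                              k_folds = config$classify$k_folds,
                              master_seed = seed,
                              knn_k = config$classify$knn_k)
  multic <- train_and_evaluate(train, test, selres$winner, mc_feats,
                               label = "diagnosis", seed = seed,
                               knn_k = config$classify$knn_k)
  stage_hash("classification",
             list(binary$counts, selres$wins, multic$counts))

  jsonlite::write_json(
    list(binary_accuracy = binary$metrics$accuracy,
         multiclass_accuracy = multic$metrics$accuracy,
         selected_model = selres$winner,
         n_multiclass_features = length(mc_feats)),
    file.path(config$out_dir, "classification.json"), auto_unbox = TRUE)

  manifest$stages <- manifest$stages
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  structure(
    list(region_features = feats, cohorts = cohorts, mancova = fit,
         posthoc = ph_tests, binary_report = binary, selection = selres,
         multiclass_report = multic, manifest = manifest),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  phantom whole-brain AngleR: %.4f rad\n",
              x$region_features$value[x$region_features$metric == "angle_r" &
                                        x$region_features$region == "whole brain"]))
  cat(sprintf("  binary accuracy: %.1f%%; multiclass (%s): %.1f%%\n",
              x$binary_report$metrics$accuracy, x$selection$winner,
              x$multiclass_report$metrics$accuracy))
  invisible(x)
}
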