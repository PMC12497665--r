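#' Pipeline configuration
#'
#' Bundles every stage's parameters and seeds. The full run is a pure
#' function of this object: simulate (optional) -> IVIM maps -> erosion ->
#' feature extraction -> split -> mRMR + CV feature count -> logistic fit
#' -> bootstrap evaluation. `erosion_enabled = FALSE` reproduces the
#' control analysis on non-eroded regions.
#'
#' @param phantom a [phantom_spec()] (the simulated cohort), or NULL when
#'   supplying `cases` directly to [run_pipeline()].
#' @param erosion an [erosion_spec()].
#' @param settings an [extraction_settings()].
#' @param erosion_enabled apply the erosion stage.
#' @param hyper list of [fit_logistic()] hyperparameters.
#' @param k_max maximum number of mRMR features.
#' @param cv_pool `"pooled"` or `"validation_only"` (see
#'   [select_feature_count_cv()]).
#' @param n_boot bootstrap replicates for evaluation.
#' @param seed seed for split / CV folds / bootstrap (the phantom has its
#'   own seed inside `phantom`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(phantom = phantom_spec(),
                            erosion = erosion_spec(),
                            settings = extraction_settings(),
                            erosion_enabled = TRUE,
                            hyper = list(C = 1, max_iter = 10,
                                         class_weight = "balanced",
                                         fit_intercept = TRUE),
                            k_max = 20,
                            cv_pool = "pooled",
                            n_boot = 1000,
                            seed = 1L) {
  structure(list(phantom = phantom, erosion = erosion, settings = settings,
                 erosion_enabled = erosion_enabled, hyper = hyper,
                 k_max = k_max, cv_pool = cv_pool, n_boot = n_boot,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

process_case <- function(cs, config) {
  # IVIM maps from the DWI stack, restricted to the prostate
  stack <- dwi_stack(cs$dwi, mask = cs$prostate_mask)
  maps <- fit_segmented_ivim(stack)
  regions <- cs$regions
  if (config$erosion_enabled)
    regions <- lapply(regions, erode_region, spec = config$erosion)
  flt <- filter_regions(regions)
  dropped <- flt$dropped
  feats <- NULL
  if (length(flt$kept)) {
    prep <- prepare_extraction_images(maps$adc, maps$fbv, cs$t2w,
                                      config$settings)
    rows <- list()
    for (r in flt$kept) {
      f <- tryCatch(
        extract_region_features_prepared(r, prep, config$settings),
        error = function(e) e)
      if (inherits(f, "error")) {
        # a region can be big enough on the map grid but fall below 2
        # voxels after nearest-neighbour transfer to another grid
        if (grepl("fewer than 2 voxels", conditionMessage(f))) {
          dropped <- rbind(dropped, data.table::data.table(
            region_id = r$region_id, label = r$label,
            reason = "insufficient_voxels_on_grid"))
          next
        }
        stop(f)
      }
      rows[[length(rows) + 1]] <-
        c(list(case_id = r$case_id, region_id = r$region_id,
               label = r$label, volume_cc = r$volume_cc), as.list(f))
    }
    if (length(rows)) feats <- data.table::rbindlist(rows)
  }
  list(features = feats, dropped = dropped)
}

#' Run the full region-classification pipeline
#'
#' Generates (or accepts) a cohort, computes parameter maps, erodes and
#' filters regions, extracts features, splits 60/20/20, ranks features by
#' mRMR on the training rows, selects the feature count by cross-validated
#' balanced accuracy, fits the class-weighted logistic model on the pooled
#' training + validation rows, and evaluates on the held-out test rows
#' with bootstrap confidence intervals. Cases are processed one at a time
#' so memory stays flat in cohort size.
#'
#' @param config a [pipeline_config()].
#' @param cases optional list of phantom-case objects (bypasses
#'   generation).
#' @param out_dir optional run directory; when set, writes features.csv,
#'   dropped_regions.csv, model.json, report.json and run_log.yaml.
#' @return list: `features` (table with split/target), `dropped`,
#'   `ranking`, `k`, `cv_trace`, `model`, `report`, `predictions`.
#' @export
run_pipeline <- function(config, cases = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cases) && is.null(config$phantom))
    stop("either `cases` or a phantom spec is required")
  n_cases <- if (is.null(cases)) config$phantom$n_cases else length(cases)

  feat_rows <- vector("list", n_cases)
  drop_rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    cs <- if (is.null(cases)) generate_phantom_case(config$phantom, i)
          else cases[[i]]
    res <- tryCatch(process_case(cs, config), error = function(e)
      stop(sprintf("stage failure in case %s: %s", cs$case_id,
                   conditionMessage(e)), call. = FALSE))
    feat_rows[[i]] <- res$features
    drop_rows[[i]] <- res$dropped
  }
  features <- data.table::rbindlist(feat_rows)
  dropped <- data.table::rbindlist(drop_rows)
  if (nrow(features) == 0) stop("no regions survived erosion and filtering")

  features$target <- as.integer(features$label == "GP4Crib+")
  features <- split_dataset(features, seed = config$seed)

  meta <- c("case_id", "region_id", "label", "volume_cc", "split", "target")
  candidates <- setdiff(names(features), meta)
  train <- features[features$split == "train", ]
  ranking <- mrmr_rank(as.matrix(train[, candidates, with = FALSE]),
                       train$target, max_features = config$k_max)

  sel <- do.call(select_feature_count_cv,
                 c(list(features, ranking, k_max = config$k_max,
                        seed = config$seed + 1L, cv_pool = config$cv_pool),
                   config$hyper))
  feats_used <- ranking$features[seq_len(sel$k)]

  fit_rows <- features[features$split %in% c("train", "validation"), ]
  model <- do.call(fit_logistic,
                   c(list(as.matrix(fit_rows[, feats_used, with = FALSE]),
                          fit_rows$target), config$hyper))

  test <- features[features$split == "test", ]
  p_test <- predict_probability(model, test[, feats_used, with = FALSE])
  report <- bootstrap_metrics(test$target, p_test,
                              n_boot = config$n_boot,
                              seed = config$seed + 2L,
                              threshold = model$threshold)
  predictions <- data.table::data.table(
    region_id = test$region_id, label = test$label, target = test$target,
    probability = p_test,
    predicted = as.integer(p_test >= model$threshold))

  out <- list(features = features, dropped = dropped, ranking = ranking,
              k = sel$k, cv_trace = sel$trace, model = model,
              report = report, predictions = predictions)
  if (!is.null(out_dir)) write_run_outputs(out, config, out_dir)
  out
}

write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         hyperparameters = model$hyperparameters,
         threshold = model$threshold, converged = model$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_model_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  logistic_model(m$intercept, unlist(m$coefficients),
                 threshold = m$threshold)
}

write_run_outputs <- function(out, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(out$features, file.path(out_dir, "features.csv"))
  data.table::fwrite(out$dropped, file.path(out_dir, "dropped_regions.csv"))
  data.table::fwrite(out$predictions, file.path(out_dir, "predictions.csv"))
  write_model_json(out$model, file.path(out_dir, "model.json"))
  rep <- out$report
  jsonlite::write_json(
    list(point = as.list(rep$point),
         ci = rep$ci, baseline_delta = rep$baseline_delta,
         p_value = rep$p_value, n_boot = rep$n_boot,
         n_redrawn = rep$n_redrawn),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  log <- list(
    package_version = as.character(utils::packageVersion("cribromics")),
    seed = config$seed,
    phantom_seed = if (!is.null(config$phantom)) config$phantom$seed,
    n_cases = if (!is.null(config$phantom)) config$phantom$n_cases,
    erosion_enabled = config$erosion_enabled,
    erosion_radius_voxels = config$erosion$radius_voxels,
    n_regions_kept = nrow(out$features),
    n_regions_dropped = nrow(out$dropped),
    dropped_reasons = as.list(table(out$dropped$reason)),
    k_selected = out$k,
    features_used = out$ranking$features[seq_len(out$k)],
    hyperparameters = config$hyper,
    cv_pool = config$cv_pool,
    n_boot = config$n_boot)
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  invisible(out_dir)
}
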