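#' Run the full classification pipeline on a cohort directory
#'
#' Orchestrates filter -> feature extraction -> per-label training ->
#' cohort-wide prediction -> attribution, writing every artifact under
#' `out_dir`: the 224-column feature matrix, one model directory per target
#' label, a probability table (all samples x all models), metrics JSON and
#' per-model feature-impact rankings. Outputs are a pure function of
#' (inputs, config, seed); the seed and a configuration hash are stamped
#' into `run.json`.
#'
#' @param variant_paths Named character vector of per-sample variant TSVs
#'   (names are sample ids).
#' @param segment_paths Named character vector of per-sample segment TSVs.
#' @param cytoband_path Cytoband file for the genome in use.
#' @param labels Tibble with `sample_id` and `label`.
#' @param out_dir Output directory (created).
#' @param targets Labels to train one-vs-rest models for.
#' @param filter_cfg A [filter_config()].
#' @param schema A [cn_schema()].
#' @param train_cfg A [train_config()]; its `folds` entry may be a named
#'   vector keyed by target label.
#' @param error_model Optional `darc_error_model`.
#' @param seed Integer seed for splits and training.
#' @return Invisibly, a list with `features`, `models`, `probabilities`,
#'   `metrics`.
#' @export
run_pipeline <- function(variant_paths, segment_paths, cytoband_path, labels,
                         out_dir, targets = c("BRCA2d", "CDK12d", "MMRd"),
                         filter_cfg = filter_config(), schema = cn_schema(),
                         train_cfg = train_config(), error_model = NULL,
                         seed = 1L) {
  stopifnot(!is.null(names(variant_paths)), !is.null(names(segment_paths)))
  missing <- c(variant_paths, segment_paths, cytoband_path)
  missing <- missing[!file.exists(missing)]
  if (length(missing) > 0) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  ids <- names(variant_paths)
  if (!setequal(ids, names(segment_paths)) ||
      !all(ids %in% labels$sample_id)) {
    stop("sample ids of variants, segments and labels do not agree")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  arm_map <- read_cytobands(cytoband_path)

  samples <- purrr::map(ids, function(id) {
    sol <- read_segments(segment_paths[[id]])
    if (!accept_solution(sol)) {
      warning("segmentation solution rejected for ", id,
              " (low-cellularity non-diploid); sample excluded")
      return(NULL)
    }
    list(sample_id = id,
         variants = read_variants(variant_paths[[id]]),
         segments = sol$segments)
  })
  samples <- purrr::compact(samples)
  features <- extract_cohort_features(samples, arm_map, error_model,
                                      filter_cfg, schema)
  write_feature_matrix(features, file.path(out_dir, "features.tsv"))

  lab <- labels$label[match(features$sample_id, labels$sample_id)]
  folds_by_target <- train_cfg$folds
  models <- list()
  metrics <- list()
  probs <- tibble::tibble(sample_id = features$sample_id, label = lab)
  for (target in targets) {
    y <- binarize_labels(lab, target)
    cfg <- train_cfg
    cfg$folds <- if (!is.null(names(folds_by_target)) &&
                     target %in% names(folds_by_target)) {
      as.integer(folds_by_target[[target]])
    } else {
      as.integer(folds_by_target[1])
    }
    cfg$seed <- seed
    split <- stratified_split(y, cfg$test_fraction, seed)
    model <- grid_search_train(features[split$train, ], y[split$train],
                               cfg, target = target)
    p_all <- predict_proba(model, features)
    ev <- evaluate_classification(y[split$test], p_all[split$test])
    model$threshold <- ev$threshold
    save_model(model, file.path(out_dir, paste0("model_", target)))
    imp <- feature_impact(model, features)
    readr::write_tsv(imp$impact,
                     file.path(out_dir, paste0("impact_", target, ".tsv")),
                     progress = FALSE)
    probs[[paste0("p_", target)]] <- p_all
    models[[target]] <- model
    metrics[[target]] <- list(auc_test = ev$auc, threshold = ev$threshold,
                              f1_test = ev$f1,
                              n_train = length(split$train),
                              n_test = length(split$test))
  }
  readr::write_tsv(probs, file.path(out_dir, "probabilities.tsv"),
                   progress = FALSE)
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(seed = seed,
         config_hash = rlang::hash(list(filter_cfg, schema,
                                        train_cfg, targets)),
         n_samples = nrow(features)),
    file.path(out_dir, "run.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(list(features = features, models = models,
                 probabilities = probs, metrics = metrics))
}
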