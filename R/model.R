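#' Training configuration for the one-vs-rest boosted-tree models
#'
#' Encodes the training protocol: a 40:60 test:train split stratified on the
#' binary label, an exhaustive grid search over the four subsampling
#' fractions (`subsample`, `colsample_bytree`, `colsample_bylevel`,
#' `colsample_bynode`) in `[0.5, 1]`, scored by stratified K-fold
#' cross-validation on the ordered criteria AUC (descending), classification
#' error (ascending) and log loss (ascending), followed by a refit of the
#' winning candidate on the full training split. Trees have maximum depth 3
#' and learning rate 0.001 with a binary logistic objective. Boosting runs to
#' `nrounds` with patience-based early stopping on validation AUC; the
#' production protocol caps rounds at one million, and the default here is a
#' desk-scale cap.
#'
#' @param test_fraction Held-out fraction of the cohort, default 0.4.
#' @param folds Cross-validation folds (10 for the BRCA2d model, 6 for
#'   CDK12d and MMRd in the reference protocol).
#' @param grid Fractions searched for each of the four subsampling
#'   hyperparameters, within `[0.5, 1]`.
#' @param max_depth Tree depth, default 3.
#' @param eta Learning rate, default 0.001.
#' @param nrounds Boosting-round cap, default 400 (set 1e6 for the full
#'   protocol).
#' @param patience Early-stopping patience in rounds on the first scoring
#'   criterion, default 50.
#' @param seed Integer seed controlling the split, fold assignment and
#'   boosting.
#' @return A `darc_train_config` list.
#' @export
train_config <- function(test_fraction = 0.4, folds = 10L,
                         grid = c(0.5, 0.75, 1.0), max_depth = 3L,
                         eta = 0.001, nrounds = 400L, patience = 50L,
                         seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            all(grid >= 0.5 & grid <= 1), folds >= 2)
  structure(as.list(environment()), class = "darc_train_config")
}

#' Binarize cohort labels against one target phenotype
#'
#' Positives are the samples carrying the target label; every other sample —
#' wild-type and other defect labels alike — is a negative.
#'
#' @param labels Character vector of phenotype labels.
#' @param target Target label, e.g. `"BRCA2d"`.
#' @return Integer vector of 0/1.
#' @export
binarize_labels <- function(labels, target) {
  as.integer(labels == target)
}

#' Stratified train/test split
#'
#' Assigns `test_fraction` of each class to the test set (rounded per class),
#' reproducibly for a given seed; the index sets are disjoint and exhaustive.
#'
#' @param labels Binary (or categorical) label vector.
#' @param test_fraction Fraction assigned to the test set.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, test_fraction = 0.4, seed = 1L) {
  idx <- seq_along(labels)
  test <- integer(0)
  rng <- rng_local(seed)
  for (cl in sort(unique(labels))) {
    members <- idx[labels == cl]
    n_test <- round(length(members) * test_fraction)
    test <- c(test, rng$sample(members, n_test))
  }
  test <- sort(test)
  list(train = setdiff(idx, test), test = test)
}

# Local RNG sandbox so package functions never disturb the caller's RNG.
rng_local <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
    s
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, envir = globalenv())
    })
    f()
  }
  list(
    sample = function(x, n) with_state(function() {
      if (length(x) == 1) x[seq_len(n)] else sample(x, n)
    }),
    runif = function(n) with_state(function() stats::runif(n)),
    shuffle = function(x) with_state(function() sample(x))
  )
}

# Stratified K-fold assignment: class members shuffled then dealt round-robin.
stratified_folds <- function(labels, k, seed = 1L) {
  rng <- rng_local(seed + 1L)
  fold <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    members <- which(labels == cl)
    members <- if (length(members) > 1) rng$shuffle(members) else members
    fold[members] <- rep_len(seq_len(k), length(members))
  }
  fold
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic: the probability that a random
#' positive scores above a random negative, ties counted half.
#'
#' @param labels Binary 0/1 labels.
#' @param scores Numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("AUC needs both positive and negative labels")
  }
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

log_loss <- function(labels, p, eps = 1e-15) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

xgb_params <- function(config, cand, seed) {
  list(objective = "binary:logistic", max_depth = config$max_depth,
       eta = config$eta, eval_metric = "auc", nthread = 1,
       subsample = cand$subsample, colsample_bytree = cand$colsample_bytree,
       colsample_bylevel = cand$colsample_bylevel,
       colsample_bynode = cand$colsample_bynode, seed = seed)
}

#' Grid-search cross-validated training of one binary model
#'
#' Runs the full protocol on a training matrix: exhaustive grid over the four
#' subsampling fractions, stratified K-fold cross-validation per candidate,
#' lexicographic scoring (mean validation AUC desc, then classification
#' error at probability 0.5 asc, then log loss asc), and a final refit of the
#' winner on all training samples using the largest early-stopped round count
#' observed across its folds.
#'
#' @param features Numeric matrix or tibble, samples x named features.
#' @param labels Binary 0/1 vector (needs at least `folds` positives).
#' @param config A [train_config()].
#' @param target Label name stored on the model (metadata only).
#' @return A `darc_model`: list with the fitted `booster`, `feature_names`,
#'   `target`, `params` (winning candidate), `cv` (per-candidate mean
#'   scores), `threshold` (`NA` until [derive_threshold()]), `config`.
#' @export
grid_search_train <- function(features, labels, config = train_config(),
                              target = "positive") {
  x <- as_feature_matrix(features)
  labels <- as.integer(labels)
  if (sum(labels == 1) < config$folds) {
    stop(sprintf(
      "only %d positive samples for %d folds; reduce the fold count",
      sum(labels == 1), config$folds))
  }
  cand <- tidyr::expand_grid(
    subsample = config$grid, colsample_bytree = config$grid,
    colsample_bylevel = config$grid, colsample_bynode = config$grid)
  fold <- stratified_folds(labels, config$folds, config$seed)
  scores <- purrr::map_dfr(seq_len(nrow(cand)), function(ci) {
    params <- xgb_params(config, cand[ci, ], config$seed)
    per_fold <- purrr::map_dfr(seq_len(config$folds), function(k) {
      tr <- fold != k; va <- fold == k
      if (!any(va) || length(unique(labels[va])) < 2 ||
          length(unique(labels[tr])) < 2) {
        return(tibble::tibble(auc = NA_real_, error = NA_real_,
                              logloss = NA_real_, best_iter = NA_real_))
      }
      dtr <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = labels[tr])
      dva <- xgboost::xgb.DMatrix(x[va, , drop = FALSE], label = labels[va])
      fit <- xgboost::xgb.train(
        params = params, data = dtr, nrounds = config$nrounds,
        evals = list(val = dva), early_stopping_rounds = config$patience,
        verbose = 0)
      p <- stats::predict(fit, dva)
      tibble::tibble(
        auc = roc_auc(labels[va], p),
        error = mean((p >= 0.5) != labels[va]),
        logloss = log_loss(labels[va], p),
        best_iter = best_iteration(fit, config$nrounds))
    })
    dplyr::summarise(per_fold,
                     auc = mean(.data$auc, na.rm = TRUE),
                     error = mean(.data$error, na.rm = TRUE),
                     logloss = mean(.data$logloss, na.rm = TRUE),
                     max_best_iter = max(.data$best_iter, na.rm = TRUE))
  })
  cv <- dplyr::bind_cols(cand, scores)
  # lexicographic: AUC desc, error asc, log loss asc; candidate order breaks ties
  ord <- order(-cv$auc, cv$error, cv$logloss)
  best <- ord[1]
  final_rounds <- max(1, cv$max_best_iter[best])
  dall <- xgboost::xgb.DMatrix(x, label = labels)
  booster <- xgboost::xgb.train(
    params = xgb_params(config, cand[best, ], config$seed),
    data = dall, nrounds = final_rounds, verbose = 0)
  structure(
    list(booster = booster, feature_names = colnames(x), target = target,
         params = as.list(cand[best, ]), cv = cv, threshold = NA_real_,
         config = config),
    class = "darc_model"
  )
}

best_iteration <- function(fit, cap) {
  bi <- tryCatch(xgboost::xgb.attr(fit, "best_iteration"),
                 error = function(e) NULL)
  if (is.null(bi) || is.na(suppressWarnings(as.numeric(bi)))) return(cap)
  as.numeric(bi) + 1  # stored 0-based
}

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    features <- features[setdiff(names(features), "sample_id")]
    features <- as.matrix(features)
  }
  if (is.null(colnames(features))) stop("feature matrix must have named columns")
  storage.mode(features) <- "double"
  features
}

#' Predict class-membership probabilities
#'
#' Column names and order are enforced against the feature order stored at
#' training time; a mismatch is an error, never a silent reordering.
#'
#' @param model A `darc_model`.
#' @param features Samples x features matrix or tibble.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, features) {
  x <- as_feature_matrix(features)
  if (!identical(colnames(x), model$feature_names)) {
    stop("feature columns do not match the model's training order")
  }
  stats::predict(model$booster, xgboost::xgb.DMatrix(x))
}

#' Derive the F1-optimal decision threshold
#'
#' Scans all thresholds from 0 to 1 at 0.001 intervals; a sample is called
#' positive when its probability is greater than or equal to the threshold.
#' Returns the minimum threshold achieving the maximum F1.
#'
#' @param labels Binary 0/1 labels.
#' @param probabilities Predicted probabilities.
#' @return Threshold on the 0.001 grid.
#' @export
derive_threshold <- function(labels, probabilities) {
  if (sum(labels == 1) == 0) stop("F1 undefined without positive labels")
  grid <- seq.int(0L, 1000L) / 1000
  f1 <- vapply(grid, function(t) f1_score(labels, probabilities >= t),
               numeric(1))
  grid[which.max(f1)]  # which.max returns the first (minimum) maximizer
}

f1_score <- function(labels, called) {
  tp <- sum(called & labels == 1)
  fp <- sum(called & labels == 0)
  fn <- sum(!called & labels == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Evaluate a probability vector against binary labels
#'
#' @param labels Binary 0/1 labels.
#' @param probabilities Predicted probabilities.
#' @return A `darc_eval`: list with `auc`, the derived `threshold`, `f1` at
#'   that threshold, and a `curve` tibble (threshold grid with precision,
#'   recall, F1).
#' @export
evaluate_classification <- function(labels, probabilities) {
  grid <- seq.int(0L, 1000L) / 1000
  curve <- purrr::map_dfr(grid, function(t) {
    called <- probabilities >= t
    tp <- sum(called & labels == 1)
    fp <- sum(called & labels == 0)
    fn <- sum(!called & labels == 1)
    tibble::tibble(
      threshold = t,
      precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
      recall = tp / (tp + fn),
      f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
  })
  thr <- derive_threshold(labels, probabilities)
  structure(
    list(auc = roc_auc(labels, probabilities), threshold = thr,
         f1 = f1_score(labels, probabilities >= thr), curve = curve,
         labels = labels, probabilities = probabilities),
    class = "darc_eval"
  )
}

#' @export
print.darc_eval <- function(x, ...) {
  cat("<darc_eval> AUC", round(x$auc, 4), "| threshold", x$threshold,
      "| F1", round(x$f1, 4), "\n")
  invisible(x)
}

#' @method glance darc_eval
#' @export
glance.darc_eval <- function(x, ...) {
  tibble::tibble(auc = x$auc, threshold = x$threshold, f1 = x$f1,
                 n = length(x$labels), n_pos = sum(x$labels == 1))
}

#' Precision/recall and ROC plots for an evaluation
#'
#' @param object A `darc_eval`.
#' @param ... Unused.
#' @return A ggplot: precision and recall as functions of the decision
#'   threshold, with the derived threshold marked.
#' @method autoplot darc_eval
#' @export
autoplot.darc_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(object$curve, c("precision", "recall"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$threshold, .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dotted") +
    ggplot2::theme_minimal() +
    ggplot2::labs(y = NULL, title = paste0("AUC = ", round(object$auc, 3)))
}

#' Additive (Shapley) feature attributions and impact ranking
#'
#' Per-sample attributions from the tree-path-dependent Shapley procedure;
#' the attributions plus the base value reproduce each sample's model margin
#' (local accuracy), checked to `tol` and raised as an internal error when
#' violated. Feature impact is the sum over samples of the absolute
#' attribution.
#'
#' @param model A `darc_model`.
#' @param features Samples x features matrix or tibble.
#' @param tol Local-accuracy tolerance on the margin, default 1e-4.
#' @return A `darc_impact`: list with `impact` (tibble: feature, impact,
#'   sorted descending) and `attributions` (samples x features matrix plus
#'   `.base` column).
#' @export
feature_impact <- function(model, features, tol = 1e-4) {
  x <- as_feature_matrix(features)
  if (!identical(colnames(x), model$feature_names)) {
    stop("feature columns do not match the model's training order")
  }
  d <- xgboost::xgb.DMatrix(x)
  contrib <- stats::predict(model$booster, d, predcontrib = TRUE)
  margin <- stats::predict(model$booster, d, outputmargin = TRUE)
  err <- max(abs(rowSums(contrib) - margin))
  if (err > tol) {
    stop("attribution/model mismatch: local accuracy violated (", err, ")")
  }
  bias <- which(colnames(contrib) %in% c("BIAS", "(Intercept)"))
  if (length(bias) == 0) bias <- ncol(contrib)
  imp <- colSums(abs(contrib[, -bias, drop = FALSE]))
  structure(
    list(impact = tibble::tibble(feature = names(imp),
                                 impact = as.numeric(imp)) |>
           dplyr::arrange(dplyr::desc(.data$impact)),
         attributions = contrib,
         local_accuracy_error = err),
    class = "darc_impact"
  )
}

#' @method tidy darc_impact
#' @export
tidy.darc_impact <- function(x, ...) x$impact

#' Bar plot of the most impactful features
#'
#' @param object A `darc_impact`.
#' @param top_n Number of features shown, default 15.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot darc_impact
#' @export
autoplot.darc_impact <- function(object, top_n = 15, ...) {
  df <- utils::head(object$impact, top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(.data$impact, .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "sum |attribution|", y = NULL)
}

#' Tidy and summarize a trained model
#'
#' `tidy()` returns the cross-validation grid with per-candidate mean scores;
#' `glance()` a one-row summary (target, winning hyperparameters, threshold).
#'
#' @param x A `darc_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy darc_model
#' @export
tidy.darc_model <- function(x, ...) x$cv

#' @rdname tidy.darc_model
#' @method glance darc_model
#' @export
glance.darc_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(target = x$target, threshold = x$threshold,
                   cv_auc = max(x$cv$auc)),
    tibble::as_tibble(x$params))
}

#' @export
print.darc_model <- function(x, ...) {
  cat("<darc_model>", x$target, "| CV AUC", round(max(x$cv$auc), 4),
      "| threshold", x$threshold, "\n")
  invisible(x)
}

#' Save / load a trained model
#'
#' The model artifact is a directory holding the serialized tree ensemble
#' (`ensemble.ubj`) and a `metadata.json` with the feature order, target
#' label, derived threshold, winning hyperparameters, CV table and seed.
#' Round-trips preserve predictions bit-exactly.
#'
#' @param model A `darc_model`.
#' @param path Artifact directory.
#' @return `save_model()`: `path`, invisibly. `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$booster, file.path(path, "ensemble.ubj"))
  meta <- list(
    target = model$target,
    feature_names = model$feature_names,
    threshold = model$threshold,
    params = model$params,
    cv = model$cv,
    config = model$config[setdiff(names(model$config), "grid")],
    grid = model$config$grid
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path)) stop("model metadata not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  booster <- xgboost::xgb.load(file.path(path, "ensemble.ubj"))
  cfg <- meta$config
  cfg$grid <- meta$grid
  structure(
    list(booster = booster,
         feature_names = meta$feature_names,
         target = meta$target,
         params = as.list(meta$params),
         cv = tibble::as_tibble(meta$cv),
         threshold = if (is.null(meta$threshold)) NA_real_ else meta$threshold,
         config = cfg),
    class = "darc_model"
  )
}
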