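#' Stratified k-fold assignment
#'
#' Partitions samples into `k` folds so that each fold's class composition
#' matches the global one to within one sample per class: within every
#' class, indices are shuffled (seeded) and dealt round-robin, with the
#' starting fold rotated per class so no fold systematically collects the
#' remainders.
#'
#' @param labels Vector of class labels (any type with equality).
#' @param k Number of folds (default 5, i.e. 20% validation splits).
#' @param seed Integer seed for the within-class shuffles.
#' @return Integer vector of fold ids (1..k), same length as `labels`.
#' @export
stratified_folds <- function(labels, k = 5, seed = 1) {
  n <- length(labels)
  if (k < 2) stop("k must be at least 2")
  counts <- table(labels)
  rare <- names(counts)[counts < k]
  if (length(rare) > 0) {
    stop("class(es) with fewer than k = ", k, " members: ",
         paste(rare, collapse = ", "),
         "; merge classes or use more data")
  }
  set.seed(seed)
  fold <- integer(n)
  classes <- sort(unique(as.character(labels)))
  for (ci in seq_along(classes)) {
    idx <- which(as.character(labels) == classes[ci])
    idx <- sample(idx)
    start <- (ci - 1L) %% k
    fold[idx] <- ((seq_along(idx) - 1L + start) %% k) + 1L
  }
  fold
}

## internal: features -> numeric matrix in the contracted column order,
## erroring rather than reordering silently when columns are absent
feature_matrix <- function(table, feature_names = FEATURE_NAMES) {
  missing <- setdiff(feature_names, colnames(table))
  if (length(missing) > 0) {
    stop("feature table missing required column(s): ",
         paste(missing, collapse = ", "),
         " (features are matched by name, never by position)")
  }
  as.matrix(as.data.frame(table)[, feature_names, drop = FALSE])
}

## internal: normalize softprob predictions to an n x k matrix (xgboost
## returns a matrix since 3.x, a flat row-major vector before)
prob_matrix <- function(p, n_class) {
  if (is.matrix(p)) p else matrix(p, ncol = n_class, byrow = TRUE)
}

## internal: default training hyperparameters (grid midpoint)
default_params <- function() list(depth = 6, eta = 0.1, lambda = 3)

## internal: one xgboost fit with the multinomial cross-entropy objective
## and L2 leaf regularization; single-threaded for bit reproducibility
fit_boost <- function(x, y_int, n_class, params, nrounds, seed,
                      watch = NULL, early_stopping = NULL) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y_int)
  xp <- list(objective = "multi:softprob", num_class = n_class,
             eval_metric = "mlogloss",
             max_depth = params$depth, eta = params$eta,
             lambda = params$lambda,
             subsample = 1, colsample_bytree = 1, nthread = 1,
             seed = seed)
  evals <- list(train = dtrain)
  if (!is.null(watch)) evals <- c(evals, list(val = watch))
  xgboost::xgb.train(params = xp, data = dtrain, nrounds = nrounds,
                     evals = evals, verbose = 0,
                     early_stopping_rounds = early_stopping)
}

#' Fix the boosting iteration count by early stopping
#'
#' Trains a model with the given (by default, untuned "vanilla")
#' hyperparameters against one stratified hold-out fold and stops when the
#' validation multinomial loss has not improved for `patience` rounds; the
#' best iteration is returned and then held fixed during the grid scan.
#'
#' @param table Feature table (complete rows).
#' @param labels Class labels aligned with `table`.
#' @param params Hyperparameter list (`depth`, `eta`, `lambda`).
#' @param k Fold count used to size the hold-out (1/k of the data).
#' @param seed Integer seed.
#' @param max_rounds,patience Early-stopping budget (defaults 2000 / 50).
#' @return Integer: the selected number of boosting iterations.
#' @export
choose_nrounds <- function(table, labels, params = default_params(),
                           k = 5, seed = 1, max_rounds = 2000,
                           patience = 50) {
  x <- feature_matrix(table)
  classes <- sort(unique(labels))
  y <- match(labels, classes) - 1L
  fold <- stratified_folds(labels, k = k, seed = seed)
  val <- fold == 1L
  dval <- xgboost::xgb.DMatrix(x[val, , drop = FALSE], label = y[val])
  fit <- fit_boost(x[!val, , drop = FALSE], y[!val], length(classes),
                   params, max_rounds, seed, watch = dval,
                   early_stopping = patience)
  best <- xgboost::xgb.attributes(fit)$best_iteration
  if (is.null(best)) {
    xgboost::xgb.get.num.boosted.rounds(fit)
  } else {
    as.integer(best) + 1L  # stored 0-based
  }
}

#' Train the four-class gradient-boosting model
#'
#' Fits boosted trees with a multinomial (multiclass cross-entropy)
#' objective and L2 leaf regularization on the eight-feature variant
#' table. The feature ordering contract, class labels, hyperparameters
#' and seed are recorded in the returned bundle; retraining with the same
#' inputs and seed reproduces the model exactly (single-threaded, no
#' subsampling).
#'
#' @param table Feature table containing the eight model features
#'   (incomplete rows must be removed by the caller; see
#'   [assemble_features()]).
#' @param labels Class labels (subset of [VARIANT_CLASSES] or any factor).
#' @param params Hyperparameters: list with `depth`, `eta` (learning
#'   rate), `lambda` (L2 strength).
#' @param nrounds Number of boosting iterations (see [choose_nrounds()]).
#' @param seed Integer seed.
#' @return An object of class `classifier_bundle`.
#' @export
train_classifier <- function(table, labels, params = default_params(),
                             nrounds = 300, seed = 1) {
  x <- feature_matrix(table)
  if (any(!is.finite(x))) stop("feature table contains incomplete rows; ",
                               "filter on the 'complete' flag first")
  classes <- sort(unique(as.character(labels)))
  y <- match(as.character(labels), classes) - 1L
  model <- fit_boost(x, y, length(classes), params, nrounds, seed)
  structure(list(model_raw = xgboost::xgb.save.raw(model),
                 feature_names = FEATURE_NAMES,
                 classes = classes, params = params,
                 nrounds = nrounds, seed = seed,
                 n_train = nrow(x)),
            class = "classifier_bundle")
}

#' @export
print.classifier_bundle <- function(x, ...) {
  cat("classifier_bundle:", length(x$classes), "classes,",
      x$nrounds, "rounds, depth", x$params$depth,
      ", eta", x$params$eta, ", lambda", x$params$lambda,
      "; trained on", x$n_train, "variants\n")
  if (!is.null(x$cv)) {
    cat("  mean CV accuracy ", signif(x$cv$mean_accuracy, 3),
        ", mean CV MCC ", signif(x$cv$mean_mcc, 3), "\n", sep = "")
  }
  invisible(x)
}

#' Predict variant classes
#'
#' Applies a trained bundle to a feature table. Only rows with all eight
#' features present are predicted; incomplete rows are returned in the
#' `unpredicted` attribute so coverage can be reported. Features are
#' matched to the bundle's contract by name.
#'
#' @param object A `classifier_bundle`.
#' @param table Feature table (e.g. from [assemble_features()]).
#' @param ... Unused.
#' @return data.frame with identifier columns (`position`, `wt`, `mut`
#'   when present in `table`), the predicted `class`, and one probability
#'   column per class (`prob_<CLASS>`, rows summing to 1).
#' @export
predict.classifier_bundle <- function(object, table, ...) {
  x <- feature_matrix(table, object$feature_names)
  complete <- rowSums(!is.finite(x)) == 0
  model <- xgboost::xgb.load.raw(object$model_raw)
  probs <- matrix(numeric(0), 0, length(object$classes))
  if (any(complete)) {
    p <- predict(model, xgboost::xgb.DMatrix(x[complete, , drop = FALSE]))
    probs <- prob_matrix(p, length(object$classes))
  }
  colnames(probs) <- paste0("prob_", object$classes)
  ids <- intersect(c("position", "wt", "mut"), colnames(table))
  out <- cbind(
    as.data.frame(table)[complete, ids, drop = FALSE],
    class = object$classes[max.col(probs, ties.method = "first")],
    as.data.frame(probs)
  )
  rownames(out) <- NULL
  attr(out, "unpredicted") <-
    as.data.frame(table)[!complete, ids, drop = FALSE]
  out
}

#' Multiclass performance metrics
#'
#' Accuracy, per-class precision and recall, the generalized (Gorodkin)
#' multiclass Matthews correlation coefficient, and the full confusion
#' matrix. The MCC is computed from the confusion matrix as
#' `(c*s - sum(t*p)) / sqrt((s^2 - sum(p^2)) * (s^2 - sum(t^2)))` with
#' `c` the trace, `s` the sample count, and `t`, `p` the per-class truth
#' and prediction counts; a zero denominator (e.g. a constant predictor)
#' yields 0 by convention.
#'
#' @param predicted,truth Aligned class-label vectors.
#' @return List with `accuracy`, `mcc`, `precision`, `recall` (named per
#'   class), `confusion` (truth in rows, predictions in columns), `n`.
#' @export
evaluate <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth have different lengths (",
         length(predicted), " vs ", length(truth), ")")
  }
  classes <- sort(union(unique(as.character(predicted)),
                        unique(as.character(truth))))
  cm <- table(truth = factor(truth, levels = classes),
              predicted = factor(predicted, levels = classes))
  s <- sum(cm)
  c_ <- sum(diag(cm))
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  denom <- sqrt((s^2 - sum(p_k^2))) * sqrt((s^2 - sum(t_k^2)))
  mcc <- if (denom == 0) 0 else (c_ * s - sum(t_k * p_k)) / denom
  precision <- diag(cm) / p_k
  recall <- diag(cm) / t_k
  list(accuracy = c_ / s, mcc = mcc,
       precision = precision, recall = recall,
       confusion = cm, n = s)
}

#' Stratified k-fold cross-validation
#'
#' Fits and scores the model on `k` stratified folds (each validation set
#' holding 1/k of the data). `backend = "ranger"` runs a random-forest
#' comparator on the exact same folds, producing a metrics report of
#' identical shape for side-by-side comparison with the boosted model.
#'
#' @param table Feature table (complete rows).
#' @param labels Aligned class labels.
#' @param k Fold count (default 5).
#' @param seed Integer seed (folds and model fits).
#' @param params Hyperparameters for the boosted model (ignored by the
#'   random forest except `num.trees` via `rf_trees`).
#' @param nrounds Boosting iterations per fold.
#' @param backend `"xgboost"` (default) or `"ranger"`.
#' @param rf_trees Trees for the random-forest comparator (default 500).
#' @return List with `folds` (per-fold metric lists from [evaluate()]),
#'   `mean_accuracy`, `mean_mcc`, `fold_id`, `backend`.
#' @export
cross_validate <- function(table, labels, k = 5, seed = 1,
                           params = default_params(), nrounds = 300,
                           backend = c("xgboost", "ranger"),
                           rf_trees = 500) {
  backend <- match.arg(backend)
  x <- feature_matrix(table)
  labels <- as.character(labels)
  fold <- stratified_folds(labels, k = k, seed = seed)
  classes <- sort(unique(labels))
  y <- match(labels, classes) - 1L

  per_fold <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    if (backend == "xgboost") {
      fit <- fit_boost(x[tr, , drop = FALSE], y[tr], length(classes),
                       params, nrounds, seed)
      p <- predict(fit, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE]))
      pm <- prob_matrix(p, length(classes))
      pred <- classes[max.col(pm, ties.method = "first")]
    } else {
      fit <- ranger::ranger(x = x[tr, , drop = FALSE],
                            y = factor(labels[tr], levels = classes),
                            num.trees = rf_trees, seed = seed,
                            num.threads = 1)
      pred <- as.character(predict(fit, data = x[!tr, , drop = FALSE],
                                   num.threads = 1)$predictions)
    }
    evaluate(pred, labels[!tr])
  })
  list(folds = per_fold,
       mean_accuracy = mean(vapply(per_fold, `[[`, 0, "accuracy")),
       mean_mcc = mean(vapply(per_fold, `[[`, 0, "mcc")),
       fold_id = fold, backend = backend)
}

#' Grid scan for boosting hyperparameters
#'
#' The iteration count is fixed first by early stopping on the untuned
#' model ([choose_nrounds()]); tree depth, learning rate and L2 strength
#' are then scanned over `grid`, scoring each combination by mean
#' stratified-CV accuracy. The winning setting is refitted on the full
#' data and returned as a bundle with the complete grid results attached.
#'
#' @param table Feature table (complete rows).
#' @param labels Aligned class labels.
#' @param grid data.frame with columns `depth`, `eta`, `lambda`; the
#'   default spans depth 4/6/8, learning rate 0.03/0.1/0.3 and L2
#'   strength 1/3/10.
#' @param k,seed Cross-validation folds and seed.
#' @param nrounds Iterations; `NULL` (default) selects them by early
#'   stopping first.
#' @param max_rounds,patience Early-stopping budget passed through.
#' @return A `classifier_bundle` with `cv` (CV report of the winning
#'   setting) and `grid_results` (one row per setting with its mean CV
#'   accuracy and MCC) attached.
#' @export
grid_search <- function(table, labels,
                        grid = expand.grid(depth = c(4, 6, 8),
                                           eta = c(0.03, 0.1, 0.3),
                                           lambda = c(1, 3, 10)),
                        k = 5, seed = 1, nrounds = NULL,
                        max_rounds = 2000, patience = 50) {
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  stopifnot(all(c("depth", "eta", "lambda") %in% names(grid)))

  if (is.null(nrounds)) {
    nrounds <- choose_nrounds(table, labels, k = k, seed = seed,
                              max_rounds = max_rounds, patience = patience)
  }
  results <- grid
  results$mean_accuracy <- NA_real_
  results$mean_mcc <- NA_real_
  cvs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- list(depth = grid$depth[i], eta = grid$eta[i],
              lambda = grid$lambda[i])
    cvs[[i]] <- cross_validate(table, labels, k = k, seed = seed,
                               params = p, nrounds = nrounds)
    results$mean_accuracy[i] <- cvs[[i]]$mean_accuracy
    results$mean_mcc[i] <- cvs[[i]]$mean_mcc
  }
  best <- which.max(results$mean_accuracy)
  params <- list(depth = grid$depth[best], eta = grid$eta[best],
                 lambda = grid$lambda[best])
  bundle <- train_classifier(table, labels, params = params,
                             nrounds = nrounds, seed = seed)
  bundle$cv <- cvs[[best]]
  bundle$grid_results <- results
  bundle
}

#' Most-frequent-class null model
#'
#' Baseline classifier that always predicts the modal training class
#' (ties broken lexicographically, a fixed documented rule). Its accuracy
#' on data with the training class distribution equals the modal class
#' frequency, the floor any informative model must beat.
#'
#' @param labels Training class labels.
#' @return Object of class `null_classifier`.
#' @export
null_model <- function(labels) {
  if (length(labels) == 0) stop("need at least one label")
  counts <- table(as.character(labels))
  modal <- sort(names(counts)[counts == max(counts)])[1]
  structure(list(class = modal, counts = counts),
            class = "null_classifier")
}

#' @rdname null_model
#' @param object A `null_classifier`.
#' @param table New data (only its row count is used).
#' @param ... Unused.
#' @export
predict.null_classifier <- function(object, table, ...) {
  rep(object$class, nrow(as.data.frame(table)))
}

#' Save or load a trained bundle
#'
#' Single-file persistence: a JSON manifest holding the hyperparameters,
#' class labels, feature-order contract, seed, a digest of the training
#' data size, and the serialized boosted model (base64-encoded).
#'
#' @param bundle A `classifier_bundle`.
#' @param path File path.
#' @return `path` invisibly (save); a `classifier_bundle` (load).
#' @export
save_bundle <- function(bundle, path) {
  obj <- list(
    format = "funsites_bundle_v1",
    feature_names = bundle$feature_names,
    classes = bundle$classes,
    params = bundle$params,
    nrounds = bundle$nrounds,
    seed = bundle$seed,
    n_train = bundle$n_train,
    model_b64 = jsonlite::base64_enc(as.raw(bundle$model_raw))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "funsites_bundle_v1")) {
    stop("not a funsites model bundle: ", path)
  }
  structure(list(model_raw = jsonlite::base64_dec(obj$model_b64),
                 feature_names = obj$feature_names,
                 classes = obj$classes,
                 params = lapply(as.list(obj$params), as.numeric),
                 nrounds = as.integer(obj$nrounds), seed = obj$seed,
                 n_train = obj$n_train),
            class = "classifier_bundle")
}
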