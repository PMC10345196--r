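test_that("stratified folds balance classes to within one sample", {
  lab <- rep(VARIANT_CLASSES, each = 25)
  f <- stratified_folds(lab, k = 5, seed = 1)
  expect_setequal(unique(f), 1:5)
  expect_true(all(table(f) == 20))
  expect_true(all(table(lab, f) == 5))

  ## imbalanced 70/10/10/10: each fold within +-1 of 14/2/2/2
  lab2 <- rep(VARIANT_CLASSES, c(70, 10, 10, 10))
  f2 <- stratified_folds(lab2, k = 5, seed = 2)
  tab <- table(lab2, f2)
  expect_true(all(abs(tab[VARIANT_CLASSES[1], ] - 14) <= 1))
  expect_true(all(abs(tab[VARIANT_CLASSES[2], ] - 2) <= 1))

  ## folds partition the index set
  expect_equal(length(f2), 100)
  expect_true(all(f2 %in% 1:5))

  expect_error(stratified_folds(c(rep("A", 50), rep("B", 3)), k = 5),
               "fewer than k")
})

test_that("metrics match a hand-computed confusion matrix", {
  ## 12-sample toy, worked out by hand:
  ## truth:  a a a a b b b b c c c c
  ## pred:   a a b c b b a c c c c b
  truth <- rep(c("a", "b", "c"), each = 4)
  pred <- c("a", "a", "b", "c", "b", "b", "a", "c", "c", "c", "c", "b")
  m <- evaluate(pred, truth)
  expect_equal(m$accuracy, 7 / 12)
  expect_equal(unname(m$recall), c(2, 2, 3) / 4)
  expect_equal(unname(m$precision), c(2 / 3, 2 / 4, 3 / 5))
  ## Gorodkin MCC from the counts: c=7, s=12, t=(4,4,4), p=(3,4,5)
  num <- 7 * 12 - sum(c(4, 4, 4) * c(3, 4, 5))
  den <- sqrt(12^2 - sum(c(3, 4, 5)^2)) * sqrt(12^2 - sum(c(4, 4, 4)^2))
  expect_equal(m$mcc, num / den)

  perfect <- evaluate(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)

  ## constant prediction on balanced truth: accuracy 1/k, MCC 0
  const <- evaluate(rep("a", 12), truth)
  expect_equal(const$accuracy, 1 / 3)
  expect_equal(const$mcc, 0)

  expect_error(evaluate(pred[1:5], truth), "different lengths")
})

test_that("null model predicts the modal class with lexicographic ties", {
  lab <- rep(c("WT_LIKE", "SBI"), c(60, 40))
  nm <- null_model(lab)
  expect_equal(predict(nm, data.frame(x = 1:5)),
               rep("WT_LIKE", 5))
  expect_equal(evaluate(predict(nm, data.frame(x = seq_along(lab))),
                        lab)$accuracy, 0.6)
  ## tie: lexicographically first of the tied classes
  expect_equal(null_model(c("b", "b", "a", "a"))$class, "a")
  expect_error(null_model(character(0)), "at least one")
})

test_that("training is deterministic and prediction is stateless", {
  pl <- planted_variants(n_residues = 60, seed = 12)
  b1 <- train_classifier(pl$features, pl$labels, nrounds = 60, seed = 5)
  b2 <- train_classifier(pl$features, pl$labels, nrounds = 60, seed = 5)
  expect_identical(b1$model_raw, b2$model_raw)

  p <- predict(b1, pl$features)
  expect_equal(nrow(p), nrow(pl$features))
  probs <- as.matrix(p[, paste0("prob_", b1$classes)])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(p)), tolerance = 1e-6)
  expect_equal(p$class,
               b1$classes[max.col(probs, ties.method = "first")])

  ## permuting rows permutes outputs identically
  set.seed(3)
  perm <- sample(nrow(pl$features))
  p2 <- predict(b1, pl$features[perm, ])
  expect_equal(p2$class, p$class[perm])

  ## missing feature column is an error, never positional matching
  broken <- pl$features
  names(broken)[names(broken) == "wcn"] <- "contact"
  expect_error(predict(b1, broken), "matched by name")
})

test_that("incomplete rows are excluded from prediction and reported", {
  pl <- planted_variants(n_residues = 40, seed = 13)
  b <- train_classifier(pl$features, pl$labels, nrounds = 40, seed = 1)
  holey <- pl$features
  holey$ddE_variant[holey$position == 2] <- NA
  p <- predict(b, holey)
  expect_equal(nrow(p), nrow(holey) - 19)
  expect_equal(nrow(attr(p, "unpredicted")), 19)
  expect_true(all(attr(p, "unpredicted")$position == 2))
})

test_that("the tuned model recovers planted classes that no single feature separates", {
  pl <- planted_variants(n_residues = 120, seed = 14)
  cv <- cross_validate(pl$features, pl$labels, k = 5, seed = 1,
                       nrounds = 150)
  expect_gt(cv$mean_accuracy, 0.9)
  ## SBI recall per fold
  sbi_recall <- vapply(cv$folds, function(f) unname(f$recall["SBI"]),
                       numeric(1))
  expect_gt(mean(sbi_recall), 0.85)
  ## the null model cannot do this
  nm_acc <- max(table(pl$labels)) / length(pl$labels)
  expect_gt(cv$mean_accuracy, nm_acc + 0.2)
})

test_that("permuting an informative feature hurts; permuting noise does not", {
  ## train on one fixture, score on a freshly generated one so that
  ## position-level memorization cannot mask a destroyed feature
  tr <- planted_variants(n_residues = 100, seed = 15)
  te <- planted_variants(n_residues = 60, seed = 16)
  acc_on_fresh <- function(features) {
    b <- train_classifier(features, tr$labels, nrounds = 120, seed = 1)
    evaluate(predict(b, te$features)$class, te$labels)$accuracy
  }
  base <- acc_on_fresh(tr$features)

  set.seed(99)
  perm <- sample(nrow(tr$features))
  ## conservation carries the SBI/total-loss split: permute all ddE columns
  broken <- tr$features
  for (cl in c("ddE_variant", "ddE_residue_avg", "ddE_neighbour_avg")) {
    broken[[cl]] <- broken[[cl]][perm]
  }
  hurt <- acc_on_fresh(broken)

  ## contact number is uninformative for the planted classes
  noisy <- tr$features
  noisy$wcn <- noisy$wcn[perm]
  same <- acc_on_fresh(noisy)

  expect_gt(same, base - 0.05)
  expect_lt(hurt, base - 0.15)
})

test_that("a single-setting grid reduces to plain cross-validated training", {
  pl <- planted_variants(n_residues = 50, seed = 16)
  g <- grid_search(pl$features, pl$labels,
                   grid = data.frame(depth = 4, eta = 0.1, lambda = 3),
                   k = 3, seed = 2, nrounds = 80)
  cv <- cross_validate(pl$features, pl$labels, k = 3, seed = 2,
                       params = list(depth = 4, eta = 0.1, lambda = 3),
                       nrounds = 80)
  expect_equal(g$cv$mean_accuracy, cv$mean_accuracy)
  expect_equal(nrow(g$grid_results), 1)
  expect_error(grid_search(pl$features, pl$labels,
                           grid = data.frame()), "empty")
})

test_that("grid search is reproducible and picks by mean CV accuracy", {
  pl <- planted_variants(n_residues = 50, seed = 17)
  grid <- data.frame(depth = c(3, 5), eta = c(0.1, 0.1),
                     lambda = c(1, 3))
  g1 <- grid_search(pl$features, pl$labels, grid = grid, k = 3,
                    seed = 3, nrounds = 60)
  g2 <- grid_search(pl$features, pl$labels, grid = grid, k = 3,
                    seed = 3, nrounds = 60)
  expect_identical(g1$params, g2$params)
  expect_equal(g1$grid_results$mean_accuracy, g2$grid_results$mean_accuracy)
  expect_equal(max(g1$grid_results$mean_accuracy), g1$cv$mean_accuracy)
})

test_that("the random-forest comparator reports the same metric schema", {
  pl <- planted_variants(n_residues = 60, seed = 18)
  gb <- cross_validate(pl$features, pl$labels, k = 3, seed = 4,
                       nrounds = 80)
  rf <- cross_validate(pl$features, pl$labels, k = 3, seed = 4,
                       backend = "ranger", rf_trees = 200)
  expect_identical(names(gb), names(rf))
  expect_identical(names(gb$folds[[1]]), names(rf$folds[[1]]))
  expect_identical(gb$fold_id, rf$fold_id)  # same folds
  expect_gt(rf$mean_accuracy, 0.8)
})

test_that("bundles persist to a single file and reload identically", {
  pl <- planted_variants(n_residues = 40, seed = 19)
  b <- train_classifier(pl$features, pl$labels, nrounds = 40, seed = 1)
  f <- tempfile(fileext = ".json")
  save_bundle(b, f)
  b2 <- load_bundle(f)
  expect_identical(b2$feature_names, b$feature_names)
  expect_identical(b2$params, b$params)
  expect_equal(predict(b2, pl$features)$class,
               predict(b, pl$features)$class)
  bogus <- tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "something_else"), bogus,
                       auto_unbox = TRUE)
  expect_error(load_bundle(bogus), "not a funsites")
})
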