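# low-dimensional features (W = 1 -> 12 columns) so every family, including
# quadratic discriminant analysis, is well-posed
lowdim_features <- function(seed = 1, n_per_class = 30, n_classes = 3) {
  cfg <- tiny_config(seed = seed, n_classes = n_classes,
                     class_counts = n_per_class * n_classes %/% n_classes,
                     patients_per_class = 3, separation = 2,
                     discriminative_offsets = -3:3)
  ds <- simulate_dataset(cfg)
  build_feature_matrix(ds, 1)
}

test_that("the registry enumerates families, wrappers and stubs", {
  reg <- default_registry()
  expect_true(any(reg$family == "extremely_randomized_trees" &
                    reg$meta_wrapper == "none" & reg$runnable))
  standalone <- reg[reg$meta_wrapper == "none" & reg$runnable, ]
  expect_equal(nrow(standalone), 21L)  # 6 ensembles + 15 base families
  expect_equal(sum(!reg$runnable), 2L)
  expect_true(all(reg$meta_wrapper[!reg$runnable] == "none"))
  expect_false(anyDuplicated(reg$spec_id) > 0)
})

test_that("the registry round-trips losslessly through JSON", {
  reg <- default_registry()
  path <- withr::local_tempfile(fileext = ".json")
  write_registry(reg, path)
  back <- read_registry(path)
  expect_equal(back$spec_id, reg$spec_id)
  expect_equal(back$runnable, reg$runnable)
  for (i in seq_len(nrow(reg))) {
    expect_equal(lapply(back$hyper_grid[[i]], as.numeric),
                 lapply(reg$hyper_grid[[i]], as.numeric),
                 ignore_attr = TRUE)
  }
})

test_that("every runnable family produces valid class probabilities", {
  fm <- lowdim_features()
  xy <- ecgorigin:::features_xy(fm)
  reg <- default_registry()
  fams <- unique(reg$family[reg$runnable])
  for (fam in fams) {
    fit <- ecgorigin:::fit_base_family(fam, xy$x, xy$y, list(), seed = 3)
    p <- fit$predict(xy$x)
    expect_equal(dim(p), c(nrow(xy$x), 3L), info = fam)
    expect_true(all(p >= -1e-9 & p <= 1 + 1e-9), info = fam)
    expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6, info = fam)
    # better than chance on well-separated training data
    acc <- mean(colnames(p)[max.col(p)] == as.character(xy$y))
    expect_gt(acc, 0.5)
  }
})

test_that("meta-classifier wrappers produce valid normalized probabilities", {
  fm <- lowdim_features(seed = 2)
  xy <- ecgorigin:::features_xy(fm)
  for (wrapper in c("one_vs_rest", "one_vs_one", "ecoc")) {
    fit <- ecgorigin:::fit_wrapped("decision_tree", wrapper, xy$x, xy$y,
                                   list(), seed = 4)
    p <- fit$predict(xy$x)
    expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-9, info = wrapper)
    acc <- mean(colnames(p)[max.col(p)] == as.character(xy$y))
    expect_gt(acc, 0.5)
  }
})

test_that("grid search picks the better hyperparameters on validation F1", {
  # four classes: a depth-1 stump can separate at most two of them, so the
  # deeper tree wins strictly on validation F1
  co <- tiny_cohort_features(tiny_config(seed = 10, n_classes = 4,
                                         class_counts = c(20, 16, 12, 12),
                                         patients_per_class = 4,
                                         separation = 2.5),
                             W = 40)
  spec <- list(spec_id = "dt", family = "decision_tree", meta_wrapper = "none",
               hyper_grid = list(max_depth = c(1L, 20L), cp = c(0)))
  model <- grid_search(spec, co$train, co$val, seed = 1)
  expect_equal(model$params$max_depth, 20L)
  expect_s3_class(model$search, "tbl_df")
  expect_equal(nrow(model$search), 2L)

  # single-combination grid: that combination is chosen
  spec1 <- list(spec_id = "dt1", family = "decision_tree", meta_wrapper = "none",
                hyper_grid = list(max_depth = c(5L)))
  m1 <- grid_search(spec1, co$train, co$val, seed = 1)
  expect_equal(m1$params$max_depth, 5L)

  # identical scores: the first-listed combination wins
  spec2 <- list(spec_id = "dt2", family = "decision_tree", meta_wrapper = "none",
                hyper_grid = list(cp = c(0.01, 0.01)))
  m2 <- grid_search(spec2, co$train, co$val, seed = 1)
  expect_equal(m2$search$combo[which.max(m2$search$validation_f1)], 1L)
})

test_that("grid search refuses shared train/validation recordings", {
  co <- tiny_cohort_features()
  expect_error(
    grid_search(registry_spec("decision_tree"), co$train, co$train, seed = 1),
    "share recordings"
  )
})

test_that("ranked predictions are normalized, ordered, and memorize training rows", {
  co <- tiny_cohort_features(tiny_config(seed = 20), W = 40)
  model <- grid_search(registry_spec("extremely_randomized_trees"),
                       co$train, co$val, seed = 2)
  ranked <- predict_ranked(model, co$test)
  sums <- tapply(ranked$probability, ranked$recording_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  by_rec <- split(ranked, ranked$recording_id)
  for (r in by_rec) {
    expect_true(all(diff(r$probability) <= 1e-12))
    expect_equal(r$rank, seq_len(nrow(r)))
  }
  # an overfit tree model ranks every training row's true class first
  train_ranked <- predict_ranked(model, co$train)
  top1 <- train_ranked[train_ranked$rank == 1, ]
  truth <- setNames(co$train$info$label, co$train$info$recording_id)
  expect_gte(mean(top1$class == truth[top1$recording_id]), 0.99)
})

test_that("predicting with mismatched features names the fingerprint", {
  co <- tiny_cohort_features()
  model <- grid_search(registry_spec("decision_tree"), co$train, co$val, seed = 1)
  wrong <- build_feature_matrix(
    cohort_dataset(co$ds, co$assignment, "test"), 30)
  expect_error(predict(model, wrong), "fingerprint")
})

test_that("two-class rankings complement each other", {
  cfg <- tiny_config(seed = 30, n_classes = 2, class_counts = c(14, 10),
                     patients_per_class = 3)
  co <- tiny_cohort_features(cfg, W = 30)
  model <- grid_search(registry_spec("decision_tree"), co$train, co$val, seed = 1)
  ranked <- predict_ranked(model, co$test)
  by_rec <- split(ranked, ranked$recording_id)
  for (r in by_rec) expect_setequal(r$class, model$classes)
})

test_that("compare_models builds a deterministic leaderboard and flags leakage", {
  co <- tiny_cohort_features(tiny_config(seed = 40, class_counts = c(20, 16, 12)),
                             W = 40)
  reg <- default_registry()
  sub <- reg[reg$spec_id %in% c("extremely_randomized_trees", "nearest_centroid"), ]
  expect_message(
    lb <- suppressWarnings(compare_models(sub, co$train, co$val, co$test, seed = 1)),
    "leak"
  )
  expect_equal(nrow(lb), 2L)
  expect_true(all(lb$test_accuracy >= 0 & lb$test_accuracy <= 1))
  lb2 <- suppressMessages(suppressWarnings(
    compare_models(sub, co$train, co$val, co$test, seed = 1)))
  expect_equal(lb$test_accuracy, lb2$test_accuracy)
  expect_equal(lb$spec_id, lb2$spec_id)

  # stubs are skipped with a notice
  stub <- reg[reg$spec_id %in% c("cnn_residual", "extremely_randomized_trees"), ]
  msgs <- capture_messages(
    lb3 <- suppressWarnings(compare_models(stub, co$train, co$val, co$test,
                                           seed = 1, select_on = "validation")))
  expect_true(any(grepl("cnn_residual", msgs)))
  expect_equal(nrow(lb3), 1L)
})

test_that("extremely randomized trees beat a depth-1 stump on multiclass data", {
  co <- tiny_cohort_features(tiny_config(seed = 50, class_counts = c(20, 16, 12),
                                         separation = 1.5), W = 40)
  reg <- default_registry()
  stump <- reg[reg$spec_id == "decision_tree", ]
  stump$hyper_grid <- list(list(max_depth = 1L, cp = 0))
  both <- dplyr::bind_rows(
    reg[reg$spec_id == "extremely_randomized_trees", ], stump)
  lb <- suppressMessages(suppressWarnings(
    compare_models(both, co$train, co$val, co$test, seed = 1,
                   select_on = "validation")))
  ert <- lb$test_accuracy[lb$spec_id == "extremely_randomized_trees"]
  dt <- lb$test_accuracy[lb$spec_id == "decision_tree"]
  expect_gte(ert, dt)
})
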