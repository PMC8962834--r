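#' Feature-importance map of a fitted tree model
#'
#' Reshapes the model's impurity-based per-feature importances into a
#' 12 x W matrix (leads x window offsets) and normalizes it to sum to 1.
#' Only tree families expose impurity importances; other families raise an
#' error (permutation importance is out of scope).
#'
#' @param model An `ecg_model` from a tree family fitted without a meta
#'   wrapper.
#' @param train Optional `ecg_features`; required only for families whose
#'   backend needs a refit with importance recording (the ranger-backed
#'   families record importance at predict-independent refit).
#' @param seed Seed for the importance refit.
#' @return An `importance_map`: 12 x W matrix, lead rownames, offset
#'   colnames, entries nonnegative and summing to 1.
#' @export
importance_map <- function(model, train = NULL, seed = model$seed) {
  tree_fams <- c("bagging_average", "random_forest", "extremely_randomized_trees",
                 "gradient_boost_tree", "extreme_gradient_boost", "decision_tree")
  if (!model$family %in% tree_fams || model$meta_wrapper != "none") {
    abort(paste0(
      "Impurity importances are available for unwrapped tree families only ",
      "(got ", model$family,
      if (model$meta_wrapper != "none") paste0(" under ", model$meta_wrapper),
      "). Consider permutation importance outside this package."
    ))
  }
  imp <- model$importance %||% {
    if (is.null(train)) {
      abort("This model did not record importances; pass the training features to refit.")
    }
    compute_importance(model, train, seed)
  }
  imp <- imp[model$feature_names]
  imp[is.na(imp)] <- 0
  W <- model$window_W
  m <- matrix(imp, nrow = 12L, ncol = W, byrow = TRUE,
              dimnames = list(ECG_LEADS, window_offsets(window_config(W))))
  m <- pmax(m, 0)
  total <- sum(m)
  if (total == 0) abort("All importances are zero; map undefined.")
  structure(m / total, class = c("importance_map", class(m)))
}

compute_importance <- function(model, train, seed) {
  xy <- features_xy(train)
  fam <- model$family
  p <- model$params
  if (fam %in% c("bagging_average", "random_forest", "extremely_randomized_trees")) {
    args <- list(x = xy$x, y = xy$y, probability = TRUE, seed = seed,
                 num.threads = 1, importance = "impurity",
                 num.trees = p$num_trees %||% 300L)
    if (fam == "bagging_average") args$mtry <- ncol(xy$x)
    if (fam == "extremely_randomized_trees") {
      args <- c(args, list(splitrule = "extratrees",
                           num.random.splits = p$num_random_splits %||% 1L,
                           replace = FALSE, sample.fraction = 1))
    }
    fit <- do.call(ranger::ranger, args)
    imp <- fit$variable.importance
  } else if (fam %in% c("gradient_boost_tree", "extreme_gradient_boost")) {
    dtrain <- xgboost::xgb.DMatrix(xy$x, label = as.integer(xy$y) - 1L)
    fit <- withr::with_seed(seed, xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = nlevels(xy$y),
                    eta = p$eta %||% 0.1, max_depth = p$max_depth %||% 3L,
                    nthread = 1, verbosity = 0),
      data = dtrain, nrounds = p$nrounds %||% 100L
    ))
    tab <- xgboost::xgb.importance(model = fit)
    imp <- setNames(tab$Gain, tab$Feature)
  } else {
    df <- as.data.frame(xy$x)
    df$.y <- xy$y
    fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(cp = p$cp %||% 0.01, xval = 0))
    imp <- fit$variable.importance
  }
  full <- setNames(numeric(length(model$feature_names)), model$feature_names)
  imp <- imp[names(imp) %in% names(full)]
  full[names(imp)] <- imp
  full
}

#' @export
print.importance_map <- function(x, ...) {
  cat(sprintf("<importance_map> 12 x %d, mass sums to %.6f\n", ncol(x), sum(x)))
  invisible(x)
}

#' Tidy an importance map into long form
#'
#' @param x An `importance_map`.
#' @param ... Unused.
#' @return A tibble `lead`, `offset`, `importance`.
#' @export
tidy.importance_map <- function(x, ...) {
  as_tibble(as.data.frame.table(unclass(x), responseName = "importance")) |>
    transmute(lead = as.character(.data$Var1),
              offset = as.integer(as.character(.data$Var2)),
              importance = .data$importance)
}

#' Top-k most important (lead, offset) features
#'
#' Descending by importance, ties by lead order then offset; offsets are
#' reported in the "nth point after/before the reference line" convention
#' (the reference sample is point 1 after).
#'
#' @param map An [importance_map()].
#' @param k Number of features (truncated at 12*W).
#' @return A tibble `lead`, `offset`, `description`, `importance`.
#' @export
top_features <- function(map, k = 3) {
  if (k < 1) abort("`k` must be >= 1.")
  df <- tidy.importance_map(map) |>
    mutate(lead_order = match(.data$lead, ECG_LEADS)) |>
    arrange(desc(.data$importance), .data$lead_order, .data$offset) |>
    head(k) |>
    mutate(description = paste0("lead ", .data$lead, ", ",
                                offset_label(.data$offset))) |>
    select("lead", "offset", "description", "importance")
  df
}

#' Plot an importance map as a heat map
#'
#' Leads on the x-axis, window sampling offset on the y-axis, brightness
#' increasing with importance.
#'
#' @param object An `importance_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.importance_map <- function(object, ...) {
  df <- tidy.importance_map(object)
  ggplot(df, aes(x = factor(.data$lead, levels = ECG_LEADS),
                 y = .data$offset, fill = .data$importance)) +
    geom_tile() +
    scale_fill_viridis_c(option = "magma") +
    labs(x = "Lead", y = "Offset from reference line (samples)",
         fill = "Importance") +
    theme_minimal()
}

#' Smoothed average beat morphology of one class
#'
#' Pointwise mean across beats followed by Gaussian kernel regression over
#' the sample index. As the bandwidth shrinks toward zero the curve tends to
#' the raw pointwise mean; scaling every input beat scales the curve by the
#' same factor.
#'
#' @param beats Numeric matrix, one row per windowed beat (single lead), all
#'   the same width W; or a vector for a single beat.
#' @param bandwidth Gaussian kernel bandwidth in samples (> 0; default 5).
#' @return Numeric vector of length W.
#' @export
average_morphology <- function(beats, bandwidth = 5) {
  if (is.vector(beats)) beats <- matrix(beats, nrow = 1)
  if (nrow(beats) < 1) abort("At least one beat is required.")
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    abort("`bandwidth` must be positive.")
  }
  m <- colMeans(beats)
  W <- length(m)
  idx <- seq_len(W)
  kw <- outer(idx, idx, function(i, j) dnorm((i - j) / bandwidth))
  drop((kw %*% m) / rowSums(kw))
}

#' Average morphology curves for every class of a feature lead
#'
#' @param fm An `ecg_features` object.
#' @param lead Lead name (default "V1", the most discriminative lead).
#' @param bandwidth Smoother bandwidth in samples.
#' @return A tibble `label`, `offset`, `voltage`.
#' @export
class_morphologies <- function(fm, lead = "V1", bandwidth = 5) {
  offs <- window_offsets(fm$window)
  cols <- paste0(lead, "_", offs)
  labs <- sort(unique(fm$info$label))
  map(labs, function(cl) {
    beats <- fm$values[fm$info$label == cl, cols, drop = FALSE]
    tibble(label = cl, offset = offs,
           voltage = average_morphology(beats, bandwidth))
  }) |> list_rbind()
}

#' Plot per-class average morphologies
#'
#' @param fm An `ecg_features` object.
#' @inheritParams class_morphologies
#' @return A ggplot faceted by class.
#' @export
plot_morphologies <- function(fm, lead = "V1", bandwidth = 5) {
  df <- class_morphologies(fm, lead, bandwidth)
  ggplot(df, aes(x = .data$offset, y = .data$voltage)) +
    geom_line(color = "firebrick") +
    facet_wrap(~label, scales = "free_y") +
    labs(x = "Offset from reference line (samples)",
         y = sprintf("Smoothed mean voltage (lead %s)", lead)) +
    theme_minimal()
}
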