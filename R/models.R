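# ---- classifier family registry ---------------------------------------------
#
# Every runnable family is a function (x, y, params, seed) -> list(predict =
# function(newx) probability matrix). Families backed by an installed package
# call it directly; the small closed-form or classic online algorithms with no
# installed backend (nearest centroid, the three discrete naive Bayes
# variants, k-NN probabilities, AdaBoost/SAMME, linear SGD, passive-
# aggressive) are implemented here.

ENSEMBLE_FAMILIES <- c(
  "bagging_average", "random_forest", "adaboost", "gradient_boost_tree",
  "extreme_gradient_boost", "extremely_randomized_trees"
)

BASE_FAMILIES <- c(
  "decision_tree", "k_nearest_neighbors", "nearest_centroid", "gaussian_nb",
  "multinomial_nb", "complement_nb", "bernoulli_nb", "linear_discriminant",
  "quadratic_discriminant", "multinomial_logistic", "mlp", "ridge",
  "sgd_linear", "passive_aggressive", "linear_svm"
)

STUB_FAMILIES <- c("cnn_residual", "lstm_attention")

default_hyper_grid <- function(family) {
  switch(family,
    bagging_average = list(num_trees = c(100L)),
    random_forest = list(num_trees = c(100L, 300L)),
    adaboost = list(n_rounds = c(30L), max_depth = c(2L)),
    gradient_boost_tree = list(nrounds = c(100L), eta = c(0.1), max_depth = c(3L)),
    extreme_gradient_boost = list(nrounds = c(100L), eta = c(0.3), max_depth = c(6L)),
    extremely_randomized_trees = list(num_trees = c(300L), num_random_splits = c(1L)),
    decision_tree = list(cp = c(0.01), max_depth = c(30L)),
    k_nearest_neighbors = list(k = c(5L)),
    gaussian_nb = list(),
    multinomial_nb = list(alpha = c(1)),
    complement_nb = list(alpha = c(1)),
    bernoulli_nb = list(alpha = c(1)),
    nearest_centroid = list(),
    linear_discriminant = list(),
    quadratic_discriminant = list(),
    multinomial_logistic = list(lambda = c(1e-4)),
    mlp = list(size = c(8L), decay = c(1e-3)),
    ridge = list(lambda = c(1)),
    sgd_linear = list(epochs = c(20L), learning_rate = c(0.05)),
    passive_aggressive = list(epochs = c(10L), aggressiveness = c(1)),
    linear_svm = list(cost = c(1)),
    list()
  )
}

#' Default classifier registry
#'
#' Enumerates the six tree ensembles and fifteen base classifier families,
#' each standalone and under each of the three meta-classifier wrappers
#' (one-vs-rest, one-vs-one, error-correcting output codes), plus two inert
#' deep-learning stub entries (a residual CNN and an LSTM-with-attention)
#' flagged not runnable. The registry is plain data: edit it, or round-trip
#' it through JSON with [write_registry()] / [read_registry()], to reproduce
#' any enumeration of model combinations.
#'
#' @return A tibble with columns `spec_id`, `family`, `meta_wrapper`
#'   (`"none"`, `"one_vs_rest"`, `"one_vs_one"`, `"ecoc"`), `runnable`, and a
#'   `hyper_grid` list-column of parameter candidate lists.
#' @export
default_registry <- function() {
  fams <- c(ENSEMBLE_FAMILIES, BASE_FAMILIES)
  wrappers <- c("none", "one_vs_rest", "one_vs_one", "ecoc")
  combos <- expand_grid(family = fams, meta_wrapper = wrappers)
  runnable <- tibble(
    spec_id = ifelse(combos$meta_wrapper == "none", combos$family,
                     paste(combos$family, combos$meta_wrapper, sep = ".")),
    family = combos$family,
    meta_wrapper = combos$meta_wrapper,
    runnable = TRUE,
    hyper_grid = map(combos$family, default_hyper_grid)
  )
  stubs <- tibble(
    spec_id = STUB_FAMILIES, family = STUB_FAMILIES, meta_wrapper = "none",
    runnable = FALSE, hyper_grid = list(list(), list())
  )
  bind_rows(runnable, stubs)
}

#' Write / read a registry as JSON
#'
#' @param registry A registry tibble as from [default_registry()].
#' @param path JSON path.
#' @return `path` invisibly; `read_registry` returns the registry tibble.
#' @export
write_registry <- function(registry, path) {
  doc <- pmap(registry, function(spec_id, family, meta_wrapper, runnable, hyper_grid) {
    list(spec_id = spec_id, family = family, meta_wrapper = meta_wrapper,
         runnable = runnable, hyper_grid = hyper_grid)
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  tibble(
    spec_id = map_chr(doc, "spec_id"),
    family = map_chr(doc, "family"),
    meta_wrapper = map_chr(doc, "meta_wrapper"),
    runnable = map_lgl(doc, "runnable"),
    hyper_grid = map(doc, function(d) map(d$hyper_grid, ~ unlist(.x, use.names = FALSE)))
  )
}

# ---- base fitters ------------------------------------------------------------

softmax_rows <- function(s) {
  s <- s - apply(s, 1, max)
  e <- exp(s)
  e / rowSums(e)
}

prob_matrix <- function(p, classes) {
  # ensure an n x k matrix with all class columns in order
  out <- matrix(0, nrow = nrow(p), ncol = length(classes),
                dimnames = list(NULL, classes))
  out[, colnames(p)] <- p
  out
}

fit_base_family <- function(family, x, y, params = list(), seed = 1) {
  y <- droplevels(as.factor(y))
  classes <- levels(y)
  p <- modifyList(default_params(family), params)
  fitter <- switch(family,
    bagging_average = fit_ranger_family(x, y, seed, num.trees = p$num_trees %||% 100L,
                                        mtry = ncol(x), replace = TRUE),
    random_forest = fit_ranger_family(x, y, seed, num.trees = p$num_trees %||% 100L),
    extremely_randomized_trees = fit_ranger_family(
      x, y, seed, num.trees = p$num_trees %||% 300L, splitrule = "extratrees",
      num.random.splits = p$num_random_splits %||% 1L, replace = FALSE,
      sample.fraction = 1
    ),
    adaboost = fit_adaboost(x, y, seed, n_rounds = p$n_rounds %||% 30L,
                            max_depth = p$max_depth %||% 2L),
    gradient_boost_tree = fit_xgb(x, y, seed, nrounds = p$nrounds %||% 100L,
                                  eta = p$eta %||% 0.1, max_depth = p$max_depth %||% 3L,
                                  lambda = 0, colsample = 1),
    extreme_gradient_boost = fit_xgb(x, y, seed, nrounds = p$nrounds %||% 100L,
                                     eta = p$eta %||% 0.3, max_depth = p$max_depth %||% 6L,
                                     lambda = 1, colsample = 0.8),
    decision_tree = fit_rpart(x, y, cp = p$cp %||% 0.01, max_depth = p$max_depth %||% 30L),
    k_nearest_neighbors = fit_knn(x, y, k = p$k %||% 5L),
    nearest_centroid = fit_nearest_centroid(x, y),
    gaussian_nb = fit_gaussian_nb(x, y),
    multinomial_nb = fit_multinomial_nb(x, y, alpha = p$alpha %||% 1, complement = FALSE),
    complement_nb = fit_multinomial_nb(x, y, alpha = p$alpha %||% 1, complement = TRUE),
    bernoulli_nb = fit_bernoulli_nb(x, y, alpha = p$alpha %||% 1,
                                    binarize = p$binarize %||% 0),
    linear_discriminant = fit_lda(x, y, quadratic = FALSE),
    quadratic_discriminant = fit_lda(x, y, quadratic = TRUE),
    multinomial_logistic = fit_glmnet(x, y, alpha = 0, lambda = p$lambda %||% 1e-4),
    ridge = fit_glmnet(x, y, alpha = 0, lambda = p$lambda %||% 1),
    mlp = fit_mlp(x, y, seed, size = p$size %||% 8L, decay = p$decay %||% 1e-3,
                  maxit = p$maxit %||% 150L),
    sgd_linear = fit_sgd(x, y, seed, epochs = p$epochs %||% 20L,
                         lr = p$learning_rate %||% 0.05),
    passive_aggressive = fit_pa(x, y, seed, epochs = p$epochs %||% 10L,
                                C = p$aggressiveness %||% 1),
    linear_svm = fit_svm(x, y, seed, cost = p$cost %||% 1),
    abort(sprintf("Family '%s' is not runnable.", family))
  )
  list(classes = classes,
       importance = attr(fitter, "importance"),
       predict = function(newx) {
         prob_matrix(fitter(newx), classes)
       })
}

default_params <- function(family) {
  map(default_hyper_grid(family), ~ .x[[1]])
}

fit_ranger_family <- function(x, y, seed, ...) {
  fit <- ranger::ranger(x = x, y = y, probability = TRUE, seed = seed,
                        num.threads = 1, importance = "impurity", ...)
  out <- function(newx) predict(fit, data = newx, num.threads = 1)$predictions
  attr(out, "importance") <- fit$variable.importance
  out
}

fit_xgb <- function(x, y, seed, nrounds, eta, max_depth, lambda, colsample) {
  k <- nlevels(y)
  dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
  fit <- withr::with_seed(seed, xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = k, eta = eta,
                  max_depth = max_depth, lambda = lambda,
                  colsample_bytree = colsample, nthread = 1,
                  verbosity = 0),
    data = dtrain, nrounds = nrounds
  ))
  classes <- levels(y)
  out <- function(newx) {
    p <- predict(fit, xgboost::xgb.DMatrix(newx))
    if (!is.matrix(p)) p <- matrix(p, ncol = k, byrow = TRUE)
    colnames(p) <- classes
    p
  }
  imp_tab <- tryCatch(xgboost::xgb.importance(model = fit), error = function(e) NULL)
  if (!is.null(imp_tab)) {
    attr(out, "importance") <- setNames(imp_tab$Gain, imp_tab$Feature)
  }
  out
}

fit_rpart <- function(x, y, cp, max_depth) {
  df <- as.data.frame(x)
  df$.y <- y
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(cp = cp, maxdepth = min(max_depth, 30L),
                                                     xval = 0))
  out <- function(newx) predict(fit, newdata = as.data.frame(newx), type = "prob")
  attr(out, "importance") <- fit$variable.importance
  out
}

# SAMME multiclass AdaBoost over depth-limited CART stumps
fit_adaboost <- function(x, y, seed, n_rounds, max_depth) {
  k <- nlevels(y)
  classes <- levels(y)
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- as.data.frame(x)
  df$.y <- y
  stumps <- list()
  alphas <- numeric(0)
  withr::with_seed(seed, {
    for (m in seq_len(n_rounds)) {
      fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                          control = rpart::rpart.control(maxdepth = max_depth,
                                                         cp = 0, xval = 0))
      pred <- predict(fit, type = "class")
      err <- sum(w * (pred != y)) / sum(w)
      if (err >= 1 - 1 / k) break
      err <- max(err, 1e-10)
      alpha <- log((1 - err) / err) + log(k - 1)
      w <- w * exp(alpha * (pred != y))
      w <- w / sum(w)
      stumps[[length(stumps) + 1L]] <- fit
      alphas <- c(alphas, alpha)
      if (err < 1e-10) break
    }
  })
  function(newx) {
    ndf <- as.data.frame(newx)
    scores <- matrix(0, nrow(ndf), k, dimnames = list(NULL, classes))
    for (m in seq_along(stumps)) {
      pred <- predict(stumps[[m]], newdata = ndf, type = "class")
      scores[cbind(seq_len(nrow(ndf)), as.integer(pred))] <-
        scores[cbind(seq_len(nrow(ndf)), as.integer(pred))] + alphas[m]
    }
    softmax_rows(scores / max(sum(alphas), 1e-10))
  }
}

fit_knn <- function(x, y, k) {
  k <- min(k, nrow(x))
  classes <- levels(y)
  xsq <- rowSums(x^2)
  function(newx) {
    d2 <- outer(rowSums(newx^2), xsq, "+") - 2 * newx %*% t(x)
    p <- t(apply(d2, 1, function(d) {
      nn <- order(d)[seq_len(k)]
      tabulate(as.integer(y[nn]), nbins = length(classes)) / k
    }))
    colnames(p) <- classes
    p
  }
}

fit_nearest_centroid <- function(x, y) {
  classes <- levels(y)
  cent <- t(vapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]),
                   numeric(ncol(x))))
  function(newx) {
    d2 <- outer(rowSums(newx^2), rowSums(cent^2), "+") - 2 * newx %*% t(cent)
    colnames(d2) <- classes
    softmax_rows(-d2 / max(median(d2), 1e-10))
  }
}

fit_gaussian_nb <- function(x, y) {
  fit <- e1071::naiveBayes(x = as.data.frame(x), y = y)
  function(newx) predict(fit, newdata = as.data.frame(newx), type = "raw")
}

fit_multinomial_nb <- function(x, y, alpha, complement) {
  shift <- pmin(apply(x, 2, min), 0)
  xs <- sweep(x, 2, shift)
  classes <- levels(y)
  p_feat <- ncol(x)
  logw <- matrix(0, length(classes), p_feat, dimnames = list(classes, NULL))
  logprior <- log(as.vector(table(y)) / length(y))
  for (i in seq_along(classes)) {
    rows <- if (complement) y != classes[i] else y == classes[i]
    s <- colSums(xs[rows, , drop = FALSE]) + alpha
    logw[i, ] <- log(s / sum(s))
  }
  function(newx) {
    xn <- pmax(sweep(newx, 2, shift), 0)
    scores <- xn %*% t(logw)
    if (complement) scores <- -scores else scores <- sweep(scores, 2, -logprior)
    colnames(scores) <- classes
    softmax_rows(scores)
  }
}

fit_bernoulli_nb <- function(x, y, alpha, binarize) {
  b <- x > binarize
  classes <- levels(y)
  theta <- t(vapply(classes, function(cl) {
    (colSums(b[y == cl, , drop = FALSE]) + alpha) / (sum(y == cl) + 2 * alpha)
  }, numeric(ncol(x))))
  logprior <- log(as.vector(table(y)) / length(y))
  function(newx) {
    bn <- newx > binarize
    scores <- bn %*% t(log(theta)) + (1 - bn) %*% t(log(1 - theta))
    scores <- sweep(scores, 2, -logprior)
    colnames(scores) <- classes
    softmax_rows(scores)
  }
}

fit_lda <- function(x, y, quadratic) {
  fit <- if (quadratic) MASS::qda(x, grouping = y) else
    suppressWarnings(MASS::lda(x, grouping = y))
  function(newx) predict(fit, newdata = newx)$posterior
}

fit_glmnet <- function(x, y, alpha, lambda) {
  fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = alpha,
                        lambda = lambda)
  classes <- levels(y)
  function(newx) {
    p <- predict(fit, newx = newx, type = "response")[, , 1]
    if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
    p[, classes, drop = FALSE]
  }
}

fit_mlp <- function(x, y, seed, size, decay, maxit) {
  ycls <- nnet::class.ind(y)
  fit <- withr::with_seed(seed, nnet::nnet(
    x = x, y = ycls, size = size, decay = decay, maxit = maxit,
    softmax = TRUE, trace = FALSE, MaxNWts = 1e7
  ))
  function(newx) predict(fit, newdata = newx, type = "raw")
}

# multinomial logistic regression fitted by stochastic gradient descent
fit_sgd <- function(x, y, seed, epochs, lr) {
  n <- nrow(x); p <- ncol(x); k <- nlevels(y)
  classes <- levels(y)
  W <- matrix(0, p + 1, k)
  yi <- as.integer(y)
  xb <- cbind(1, x)
  withr::with_seed(seed, {
    t_step <- 0
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        t_step <- t_step + 1
        eta <- lr / (1 + 1e-4 * t_step)
        s <- drop(xb[i, ] %*% W)
        pr <- exp(s - max(s)); pr <- pr / sum(pr)
        pr[yi[i]] <- pr[yi[i]] - 1
        W <- W - eta * tcrossprod(xb[i, ], pr)
      }
    }
  })
  function(newx) {
    s <- cbind(1, newx) %*% W
    colnames(s) <- classes
    softmax_rows(s)
  }
}

# multiclass passive-aggressive (PA-II) with hinge loss
fit_pa <- function(x, y, seed, epochs, C) {
  n <- nrow(x); p <- ncol(x); k <- nlevels(y)
  classes <- levels(y)
  W <- matrix(0, p + 1, k)
  yi <- as.integer(y)
  xb <- cbind(1, x)
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        s <- drop(xb[i, ] %*% W)
        r <- order(-s)
        rival <- if (r[1] == yi[i]) r[2] else r[1]
        loss <- max(0, 1 - s[yi[i]] + s[rival])
        if (loss > 0) {
          tau <- loss / (2 * sum(xb[i, ]^2) + 1 / (2 * C))
          W[, yi[i]] <- W[, yi[i]] + tau * xb[i, ]
          W[, rival] <- W[, rival] - tau * xb[i, ]
        }
      }
    }
  })
  function(newx) {
    s <- cbind(1, newx) %*% W
    colnames(s) <- classes
    softmax_rows(s)
  }
}

fit_svm <- function(x, y, seed, cost) {
  fit <- withr::with_seed(seed, e1071::svm(
    x = x, y = y, kernel = "linear", cost = cost, probability = TRUE
  ))
  classes <- levels(y)
  function(newx) {
    pred <- predict(fit, newdata = newx, probability = TRUE)
    attr(pred, "probabilities")[, classes, drop = FALSE]
  }
}

# ---- meta-classifier wrappers ------------------------------------------------

fit_wrapped <- function(family, meta_wrapper, x, y, params, seed) {
  y <- droplevels(as.factor(y))
  classes <- levels(y)
  if (meta_wrapper == "none" || length(classes) <= 2) {
    return(fit_base_family(family, x, y, params, seed))
  }
  switch(meta_wrapper,
    one_vs_rest = fit_ovr(family, x, y, params, seed),
    one_vs_one = fit_ovo(family, x, y, params, seed),
    ecoc = fit_ecoc(family, x, y, params, seed),
    abort(sprintf("Unknown meta wrapper '%s'.", meta_wrapper))
  )
}

fit_ovr <- function(family, x, y, params, seed) {
  classes <- levels(y)
  fits <- imap(setNames(classes, classes), function(cl, nm) {
    yb <- factor(ifelse(y == cl, "pos", "rest"), levels = c("pos", "rest"))
    fit_base_family(family, x, yb, params, seed)
  })
  list(classes = classes, predict = function(newx) {
    p <- vapply(classes, function(cl) fits[[cl]]$predict(newx)[, "pos"],
                numeric(nrow(newx)))
    p <- matrix(p, nrow = nrow(newx), dimnames = list(NULL, classes))
    rs <- rowSums(p)
    rs[rs == 0] <- 1
    p / rs
  })
}

fit_ovo <- function(family, x, y, params, seed) {
  classes <- levels(y)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  fits <- map(pairs, function(pr) {
    keep <- y %in% pr
    yb <- factor(as.character(y[keep]), levels = pr)
    fit_base_family(family, x[keep, , drop = FALSE], yb, params, seed)
  })
  list(classes = classes, predict = function(newx) {
    votes <- matrix(0, nrow(newx), length(classes),
                    dimnames = list(NULL, classes))
    for (j in seq_along(pairs)) {
      pr <- pairs[[j]]
      p <- fits[[j]]$predict(newx)
      votes[, pr[1]] <- votes[, pr[1]] + p[, pr[1]]
      votes[, pr[2]] <- votes[, pr[2]] + p[, pr[2]]
    }
    votes / rowSums(votes)
  })
}

fit_ecoc <- function(family, x, y, params, seed) {
  classes <- levels(y)
  k <- length(classes)
  L <- max(4L, ceiling(1.5 * k))
  code <- withr::with_seed(seed, {
    repeat {
      cm <- matrix(sample(c(-1, 1), k * L, replace = TRUE), k, L)
      ok_cols <- apply(cm, 2, function(col) length(unique(col)) == 2)
      ok_rows <- !anyDuplicated(cm)
      if (all(ok_cols) && ok_rows) break
    }
    cm
  })
  rownames(code) <- classes
  fits <- map(seq_len(L), function(l) {
    yb <- factor(ifelse(code[as.character(y), l] > 0, "pos", "neg"),
                 levels = c("pos", "neg"))
    fit_base_family(family, x, yb, params, seed)
  })
  list(classes = classes, predict = function(newx) {
    pl <- vapply(seq_len(L), function(l) fits[[l]]$predict(newx)[, "pos"],
                 numeric(nrow(newx)))
    pl <- matrix(pl, nrow = nrow(newx))
    target <- (code + 1) / 2
    d <- vapply(classes, function(cl) {
      rowSums(abs(sweep(pl, 2, target[cl, ], "-")))
    }, numeric(nrow(newx)))
    d <- matrix(d, nrow = nrow(newx), dimnames = list(NULL, classes))
    softmax_rows(-d)
  })
}

# ---- model fitting and selection --------------------------------------------

features_xy <- function(fm) {
  list(x = fm$values, y = factor(fm$info$label, levels = sort(unique(fm$info$label))))
}

base_ids <- function(ids) sub("_dup[0-9]+$", "", ids)

#' Fit one model spec with validation-driven hyperparameter search
#'
#' Exhaustively evaluates the spec's hyperparameter grid, selecting the
#' combination with the highest weighted-average F1 score on the validation
#' cohort (ties: the first-listed combination), then refits it on the
#' training features.
#'
#' @param spec One registry row (as a list or one-row tibble) with `spec_id`,
#'   `family`, `meta_wrapper`, `hyper_grid`.
#' @param train,val `ecg_features` for the (oversampled) training cohort and
#'   the untouched validation cohort. Their recording ids must be disjoint.
#' @param seed Integer seed for all stochastic fitters.
#' @return An `ecg_model`: the fitted predictor with its chosen
#'   hyperparameters, class list, training fingerprint (window, feature
#'   names, training recording ids, seed) and the search trace.
#' @export
grid_search <- function(spec, train, val, seed = 1) {
  if (is.data.frame(spec)) spec <- as.list(spec[1, ])
  if (is.list(spec$hyper_grid) && length(spec$hyper_grid) == 1 &&
      is.list(spec$hyper_grid[[1]]) && is.null(names(spec$hyper_grid))) {
    spec$hyper_grid <- spec$hyper_grid[[1]]
  }
  leak <- intersect(base_ids(train$info$recording_id), base_ids(val$info$recording_id))
  if (length(leak)) {
    abort(paste0("Training and validation share recordings: ",
                 paste(head(leak, 5), collapse = ", ")))
  }
  grid <- spec$hyper_grid %||% list()
  combos <- if (length(grid) == 0) list(list()) else {
    gg <- do.call(expand_grid, grid)
    pmap(gg, function(...) list(...))
  }
  tv <- features_xy(train)
  vv <- features_xy(val)
  absent <- setdiff(levels(tv$y), as.character(vv$y))
  if (length(absent)) {
    warn(paste0("Training classes absent from validation (F1 weight 0): ",
                paste(absent, collapse = ", ")))
  }
  scores <- map_dbl(combos, function(par) {
    fit <- fit_wrapped(spec$family, spec$meta_wrapper, tv$x, tv$y, par, seed)
    pred <- predicted_class(fit$predict(vv$x))
    panel <- suppressMessages(
      one_vs_rest_metrics(confusion(as.character(vv$y), pred,
                                    classes = fit$classes))
    )
    # selection score: support-weighted F1 with undefined per-class F1
    # counting as 0 (a class never predicted correctly must not drop out of
    # the average, or degenerate models that ignore classes rank too high)
    f1 <- ifelse(is.na(panel$F1), 0, panel$F1)
    if (sum(panel$support) == 0) return(NA_real_)
    sum(f1 * panel$support) / sum(panel$support)
  })
  scores[is.na(scores)] <- -Inf
  best <- which.max(scores)
  chosen <- combos[[best]]
  fit <- fit_wrapped(spec$family, spec$meta_wrapper, tv$x, tv$y, chosen, seed)
  structure(
    list(
      spec_id = spec$spec_id, family = spec$family,
      meta_wrapper = spec$meta_wrapper, params = chosen,
      classes = fit$classes, feature_names = colnames(train$values),
      window_W = train$window$W, seed = seed,
      train_ids = unique(base_ids(train$info$recording_id)),
      importance = fit$importance,
      search = tibble(combo = seq_along(combos),
                      params = combos, validation_f1 = scores),
      fit = fit
    ),
    class = "ecg_model"
  )
}

#' @export
print.ecg_model <- function(x, ...) {
  cat(sprintf("<ecg_model %s> %s%s, %d classes, W=%d\n",
              x$spec_id, x$family,
              if (x$meta_wrapper != "none") paste0(" [", x$meta_wrapper, "]") else "",
              length(x$classes), x$window_W))
  invisible(x)
}

#' @export
glance.ecg_model <- function(x, ...) {
  tibble(spec_id = x$spec_id, family = x$family, meta_wrapper = x$meta_wrapper,
         n_classes = length(x$classes), window = x$window_W,
         validation_f1 = max(x$search$validation_f1), seed = x$seed)
}

check_feature_match <- function(model, fm) {
  if (!identical(colnames(fm$values), model$feature_names)) {
    abort(sprintf(
      "Feature columns do not match the model fingerprint (expected W=%d with the standard naming).",
      model$window_W
    ))
  }
}

#' Class-probability predictions
#'
#' @param object An `ecg_model`.
#' @param newdata An `ecg_features` object or bare feature matrix with the
#'   model's feature columns.
#' @param ... Unused.
#' @return An n x k probability matrix (rows sum to 1).
#' @export
predict.ecg_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "ecg_features")) {
    check_feature_match(object, newdata)
    newdata$values
  } else newdata
  p <- object$fit$predict(x)
  p / rowSums(p)
}

predicted_class <- function(prob) {
  classes <- colnames(prob)
  classes[max.col(prob, ties.method = "first")]
}

#' Ranked per-recording site predictions
#'
#' Orders each recording's predicted classes by descending probability (ties
#' by class-code order), the form used for top-k failure analysis.
#'
#' @inheritParams predict.ecg_model
#' @param model An `ecg_model`.
#' @param features An `ecg_features` object.
#' @return A tibble with `recording_id`, `rank`, `class`, `probability`.
#' @export
predict_ranked <- function(model, features) {
  p <- predict(model, features)
  classes <- colnames(p)
  ids <- features$info$recording_id
  map(seq_len(nrow(p)), function(i) {
    ord <- order(-p[i, ], classes)
    tibble(recording_id = ids[[i]], rank = seq_along(classes),
           class = classes[ord], probability = unname(p[i, ord]))
  }) |> list_rbind()
}

#' Compare every runnable registry spec across the three cohorts
#'
#' For each runnable spec: hyperparameters are tuned on (train, validation)
#' via [grid_search()], then the cohort named by `select_on` scores the spec.
#' The study design this reproduces selects on the testing cohort, which
#' leaks test information into model choice; a prominent message flags this,
#' and `select_on = "validation"` gives the leak-free variant.
#'
#' @param registry Registry tibble ([default_registry()] or a subset).
#' @param train,val,test `ecg_features` for the three cohorts.
#' @param seed Integer seed.
#' @param select_on `"test"` (faithful, flagged) or `"validation"`.
#' @return A leaderboard tibble sorted by the selection accuracy, of class
#'   `ecg_leaderboard`, with the fitted models in a `model` list-column.
#' @export
compare_models <- function(registry, train, val, test, seed = 1,
                           select_on = c("test", "validation")) {
  select_on <- match.arg(select_on)
  if (select_on == "test") {
    inform(paste0(
      "Model selection is scored on the TEST cohort (faithful to the original ",
      "study design); this leaks test information into model choice. ",
      "Use select_on = \"validation\" for a leak-free comparison."
    ))
  }
  skipped <- registry$spec_id[!registry$runnable]
  if (length(skipped)) {
    inform(paste0("Skipping non-runnable specs: ", paste(skipped, collapse = ", ")))
  }
  runnable <- registry[registry$runnable, , drop = FALSE]
  rows <- map(seq_len(nrow(runnable)), function(i) {
    spec <- as.list(runnable[i, ])
    spec$hyper_grid <- runnable$hyper_grid[[i]]
    model <- grid_search(spec, train, val, seed)
    acc_of <- function(fm) {
      truth <- fm$info$label
      mean(predicted_class(predict(model, fm)) == truth)
    }
    tibble(spec_id = spec$spec_id, family = spec$family,
           meta_wrapper = spec$meta_wrapper,
           validation_f1 = max(model$search$validation_f1),
           test_accuracy = acc_of(test),
           validation_accuracy = acc_of(val),
           model = list(model))
  })
  lb <- list_rbind(rows)
  key <- if (select_on == "test") lb$test_accuracy else lb$validation_accuracy
  lb <- lb[order(-key), ]
  structure(lb, class = c("ecg_leaderboard", class(lb)),
            select_on = select_on)
}

#' Persist a model's metadata sidecar
#'
#' The predictor itself is an in-memory closure; what is serialized is the
#' reproducibility fingerprint (spec, chosen hyperparameters, scheme classes,
#' window, seed, training recording ids) from which the fit can be re-run.
#'
#' @param model An `ecg_model`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  doc <- list(spec_id = model$spec_id, family = model$family,
              meta_wrapper = model$meta_wrapper, params = model$params,
              classes = model$classes, window_W = model$window_W,
              seed = model$seed, train_ids = model$train_ids)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
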