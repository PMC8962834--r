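#' Candidate beat-window sizes
#'
#' The study's grid ran from 200 samples (100 ms at 2,000 Hz) to 1,000 samples
#' (500 ms) in steps of 10 samples (5 ms); the sequence truncates at the last
#' value not exceeding `max_w` when the step does not divide the range.
#'
#' @param min_w,max_w Window bounds in samples.
#' @param step Step in samples (>= 1).
#' @return Integer vector of window sizes.
#' @export
candidate_windows <- function(min_w = 200, max_w = 1000, step = 10) {
  if (min_w > max_w || min_w < 1 || step < 1) {
    abort("Require 1 <= min_w <= max_w and step >= 1.")
  }
  seq.int(as.integer(min_w), as.integer(max_w), by = as.integer(step))
}

#' Validation accuracy of one window size
#'
#' Builds `W`-windowed features for the training and validation cohorts, fits
#' a seeded random forest with fixed default hyperparameters (100 trees), and
#' returns the validation accuracy.
#'
#' @param W Window size in samples.
#' @param train,val Labeled [ecg_dataset()]s (patient-disjoint).
#' @param seed Integer seed for the forest.
#' @param denoise Denoise before windowing?
#' @param num_trees Evaluator forest size (fixed default 100).
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_window <- function(W, train, val, seed = 1, denoise = FALSE,
                            num_trees = 100) {
  if (nrow(val) == 0) abort("Validation cohort is empty.")
  fm_tr <- build_feature_matrix(train, W, denoise = denoise)
  fm_va <- build_feature_matrix(val, W, denoise = denoise)
  y_tr <- factor(fm_tr$info$label)
  fit <- ranger::ranger(x = fm_tr$values, y = y_tr, num.trees = num_trees,
                        seed = seed, num.threads = 1)
  pred <- predict(fit, data = fm_va$values, num.threads = 1)$predictions
  mean(as.character(pred) == fm_va$info$label)
}

#' Exhaustive search for the best window size
#'
#' Evaluates every candidate with [evaluate_window()] and returns the argmax;
#' ties resolve to the smallest window (cheaper features). The full accuracy
#' curve is retained for plotting. The study's own optima per scheme
#' (250/550/360/320 samples for schemes 1-4) are real-data outcomes shipped
#' as defaults in [scheme_default_windows()], not asserted anywhere.
#'
#' @param candidates Window sizes (non-empty), e.g. [candidate_windows()].
#' @param train,val Labeled [ecg_dataset()]s.
#' @param seed Integer seed.
#' @param denoise Denoise before windowing?
#' @param repeats Number of evaluator seeds averaged per candidate (default 1).
#' @return A `window_search` object: tibble `window`, `accuracy` plus
#'   attributes `best_window` and `evaluator`.
#' @export
search_best_window <- function(candidates, train, val, seed = 1,
                               denoise = FALSE, repeats = 1) {
  if (length(candidates) == 0) abort("`candidates` must be non-empty.")
  scores <- map_dbl(candidates, function(W) {
    mean(map_dbl(seq_len(repeats), function(r) {
      evaluate_window(W, train, val, seed = seed + r - 1, denoise = denoise)
    }))
  })
  best <- candidates[which.max(scores)]  # first max = smallest window on ties
  structure(
    tibble(window = as.integer(candidates), accuracy = scores),
    best_window = as.integer(best),
    evaluator = list(num_trees = 100, seed = seed, repeats = repeats),
    class = c("window_search", class(tibble()))
  )
}

#' @rdname search_best_window
#' @param x A `window_search` result.
#' @export
best_window <- function(x) attr(x, "best_window")

#' Study-reported optimal windows per scheme
#'
#' The window sizes (samples at 2,000 Hz) that maximized validation accuracy
#' on the clinical data for schemes 1-4. Shipped as ready defaults; deriving
#' them requires the clinical recordings.
#'
#' @return Named integer vector over schemes "1".."4".
#' @export
scheme_default_windows <- function() {
  c(`1` = 250L, `2` = 550L, `3` = 360L, `4` = 320L)
}

#' Plot a window-search accuracy curve
#'
#' @param object A `window_search` result.
#' @param ... Unused.
#' @return A ggplot of accuracy against window size.
#' @export
autoplot.window_search <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$window, y = .data$accuracy)) +
    geom_line(color = "steelblue") +
    geom_point(size = 0.8) +
    geom_vline(xintercept = best_window(object), linetype = "dashed") +
    labs(x = "Window size (samples)", y = "Validation accuracy") +
    theme_minimal()
}
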