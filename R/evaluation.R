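#' Confusion matrix of true versus predicted site labels
#'
#' @param true_labels,predicted_labels Equal-length character vectors.
#' @param classes Ordered class codes; defaults to the sorted union of the
#'   observed labels. All labels must belong to `classes`.
#' @return A square integer matrix (rows = true, columns = predicted) of class
#'   `confusion_matrix`.
#' @export
confusion <- function(true_labels, predicted_labels, classes = NULL) {
  if (length(true_labels) != length(predicted_labels)) {
    abort("Label vectors must have equal length.")
  }
  if (is.null(classes)) {
    classes <- sort(unique(c(true_labels, predicted_labels)))
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), classes)
  if (length(bad)) {
    abort(paste0("Labels outside `classes`: ", paste(bad, collapse = ", ")))
  }
  counts <- table(factor(true_labels, levels = classes),
                  factor(predicted_labels, levels = classes))
  m <- matrix(as.integer(counts), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d classes, %d recordings\n", nrow(x), sum(x)))
  print(unclass(x))
  invisible(x)
}

#' Tidy a confusion matrix into long counts
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return A tibble with `true`, `predicted`, `n`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(unclass(x), responseName = "n")) |>
    mutate(true = as.character(.data$true),
           predicted = as.character(.data$predicted),
           n = as.integer(.data$n))
}

#' Per-class one-vs-rest metric panel
#'
#' For each class the multiclass problem is reduced to class-vs-others and
#' sensitivity (SE), specificity (SP), positive and negative predictive value
#' (PPV, NPV), F1 and balanced accuracy are computed from the binary
#' contingency counts. Any 0/0 ratio is reported as `NA` (undefined) rather
#' than 0, with an informative message; downstream weighted averages
#' renormalize over defined classes.
#'
#' @param cm A [confusion()] matrix.
#' @return A tibble with one row per class: `class`, `support`, `TP`, `FP`,
#'   `FN`, `TN`, `SE`, `SP`, `PPV`, `NPV`, `F1`, `balanced_accuracy`.
#' @export
one_vs_rest_metrics <- function(cm) {
  classes <- rownames(cm)
  total <- sum(cm)
  ratio <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  rows <- map(classes, function(cl) {
    TP <- cm[cl, cl]
    FN <- sum(cm[cl, ]) - TP
    FP <- sum(cm[, cl]) - TP
    TN <- total - TP - FN - FP
    SE <- ratio(TP, TP + FN)
    SP <- ratio(TN, TN + FP)
    PPV <- ratio(TP, TP + FP)
    NPV <- ratio(TN, TN + FN)
    F1 <- if (is.na(SE) || is.na(PPV) || (PPV + SE) == 0) NA_real_ else
      2 * PPV * SE / (PPV + SE)
    BA <- if (is.na(SE) || is.na(SP)) NA_real_ else (SE + SP) / 2
    tibble(class = cl, support = TP + FN, TP = TP, FP = FP, FN = FN, TN = TN,
           SE = SE, SP = SP, PPV = PPV, NPV = NPV, F1 = F1,
           balanced_accuracy = BA)
  })
  panel <- list_rbind(rows)
  undef <- panel$class[!stats::complete.cases(panel[, c("SE", "SP", "PPV", "NPV", "F1")])]
  if (length(undef)) {
    inform(paste0("Undefined (0/0) metrics reported as NA for: ",
                  paste(undef, collapse = ", ")))
  }
  panel
}

#' Support-weighted average of a metric panel
#'
#' Weighted mean over classes with defined (non-`NA`) values; the weights are
#' renormalized over the defined classes per metric. A metric undefined for
#' every class averages to `NA`.
#'
#' @param panel Output of [one_vs_rest_metrics()].
#' @param supports Per-class weights; defaults to the panel's true-class
#'   supports.
#' @return A one-row tibble with columns `SE`, `SP`, `PPV`, `NPV`, `F1`,
#'   `balanced_accuracy`.
#' @export
weighted_average <- function(panel, supports = panel$support) {
  wmean <- function(v) {
    ok <- !is.na(v) & supports > 0
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * supports[ok]) / sum(supports[ok])
  }
  tibble(
    SE = wmean(panel$SE), SP = wmean(panel$SP), PPV = wmean(panel$PPV),
    NPV = wmean(panel$NPV), F1 = wmean(panel$F1),
    balanced_accuracy = wmean(panel$balanced_accuracy)
  )
}

#' Accuracy and partial-credit adjusted accuracy
#'
#' Accuracy is the diagonal fraction of the confusion matrix. Adjusted
#' accuracy replaces each count's contribution with its partial-credit weight:
#' `sum_ij counts[i,j] * weights[i,j] / total`. With the identity credit
#' matrix the two coincide; with any nonnegative unit-diagonal credit matrix
#' adjusted accuracy dominates plain accuracy.
#'
#' @param cm A [confusion()] matrix.
#' @param credit A [partial_credit_matrix()] (or compatible square matrix with
#'   matching class dimnames), or `NULL` to skip the adjusted value.
#' @return A one-row tibble with `accuracy` and `adjusted_accuracy`
#'   (`NA` when `credit` is `NULL`).
#' @export
accuracy_and_adjusted <- function(cm, credit = NULL) {
  total <- sum(cm)
  if (total == 0) abort("Empty confusion matrix: accuracy undefined.")
  acc <- sum(diag(cm)) / total
  adj <- NA_real_
  if (!is.null(credit)) {
    if (!identical(rownames(credit), rownames(cm)) ||
        !identical(colnames(credit), colnames(cm))) {
      credit_classes <- rownames(credit)
      if (!setequal(credit_classes, rownames(cm))) {
        abort("Credit matrix classes do not match the confusion matrix.")
      }
      credit <- credit[rownames(cm), colnames(cm)]
    }
    adj <- sum(unclass(cm) * unclass(credit)) / total
  }
  tibble(accuracy = acc, adjusted_accuracy = adj)
}

#' Percentile bootstrap confidence interval for a classification metric
#'
#' Resamples the evaluated recordings with replacement `B` times and reports
#' the metric's 2.5/97.5 percentile bounds (two-sided 95% interval). When the
#' metric is undefined (`NA`) on more than 10% of replicates the interval is
#' reported as undefined with a diagnostic attribute.
#'
#' @param metric_fn `function(true_labels, predictions) -> scalar`.
#' @param true_labels,predictions Equal-length vectors; `predictions` may be
#'   any per-recording structure indexable by `[`.
#' @param B Bootstrap replications (the study used 2,000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @param clusters Optional vector (same length) of cluster ids, e.g.
#'   patient ids: whole clusters are then resampled with replacement
#'   (cluster bootstrap), which is more conservative when recordings within
#'   a patient are correlated. Default: resampling unit = recording.
#' @return A one-row tibble `point`, `lower`, `upper`, `B`, `prop_undefined`.
#' @export
bootstrap_ci <- function(metric_fn, true_labels, predictions, B = 2000,
                         seed = 1, conf = 0.95, clusters = NULL) {
  n <- length(true_labels)
  if (n == 0) abort("Empty label vector.")
  if (B < 1) abort("`B` must be >= 1.")
  if (!is.null(clusters) && length(clusters) != n) {
    abort("`clusters` must align with the labels.")
  }
  point <- metric_fn(true_labels, predictions)
  draw <- if (is.null(clusters)) {
    function() sample.int(n, n, replace = TRUE)
  } else {
    members <- split(seq_len(n), clusters)
    function() {
      unlist(members[sample.int(length(members), length(members),
                                replace = TRUE)], use.names = FALSE)
    }
  }
  stats <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- draw()
      metric_fn(true_labels[idx], predictions[idx])
    }, numeric(1))
  })
  prop_na <- mean(is.na(stats))
  if (prop_na > 0.1) {
    out <- tibble(point = point, lower = NA_real_, upper = NA_real_,
                  B = as.integer(B), prop_undefined = prop_na)
    attr(out, "diagnostic") <- sprintf(
      "Metric undefined on %.1f%% of bootstrap replicates; CI not reported.",
      100 * prop_na)
    return(out)
  }
  alpha <- 1 - conf
  q <- quantile(stats, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE, names = FALSE)
  tibble(point = point, lower = q[1], upper = q[2], B = as.integer(B),
         prop_undefined = prop_na)
}

#' Rank-of-true-site histogram (top-k failure analysis)
#'
#' Tabulates, over evaluated recordings, the rank at which the true site
#' appears in the model's probability-ordered prediction list: rank 1 is a
#' correct top prediction, rank 2 means the second-ranked site was correct,
#' and ranks beyond `k_max` pool into `">k"`.
#'
#' @param ranked Output of [predict_ranked()] (columns `recording_id`,
#'   `rank`, `class`).
#' @param true_labels Named character vector (names = recording ids) or a
#'   vector aligned with the unique recording order of `ranked`.
#' @param k_max Last individually reported rank (default 3).
#' @return A tibble with `rank` (`"1"`.. `"k_max"`, `">k_max"`), `n`, and
#'   `cumulative` hit counts.
#' @export
topk_analysis <- function(ranked, true_labels, k_max = 3) {
  ids <- unique(ranked$recording_id)
  if (is.null(names(true_labels))) {
    true_labels <- setNames(true_labels, ids)
  }
  rank_of_true <- map_int(ids, function(id) {
    sub <- ranked[ranked$recording_id == id, ]
    r <- sub$rank[sub$class == true_labels[[id]]]
    if (length(r) == 0) {
      warn(sprintf("True class of %s missing from its ranking; counted beyond k.", id))
      return(as.integer(k_max + 1L))
    }
    as.integer(min(r))
  })
  bins <- c(as.character(seq_len(k_max)), paste0(">", k_max))
  counts <- c(tabulate(pmin(rank_of_true, k_max + 1L), nbins = k_max + 1L))
  tibble(rank = bins, n = counts, cumulative = cumsum(counts))
}

#' Full metric report for one evaluated cohort
#'
#' Bundles the confusion matrix, per-class one-vs-rest panel, weighted
#' averages, overall and adjusted accuracy, bootstrap confidence intervals
#' for the headline metrics, and the top-k rank histogram.
#'
#' @param true_labels Character vector of true site codes.
#' @param ranked [predict_ranked()] output for the same recordings (its rank-1
#'   rows are the point predictions).
#' @param classes Ordered class codes.
#' @param credit Optional [partial_credit_matrix()].
#' @param B Bootstrap replications (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @param k_max Top-k depth (default 3).
#' @return A `metric_report` list with elements `confusion`, `panel`,
#'   `weighted`, `accuracy`, `ci`, `topk`, `config`.
#' @export
metric_report <- function(true_labels, ranked, classes = NULL, credit = NULL,
                          B = 2000, seed = 1, k_max = 3) {
  top1 <- ranked |> filter(.data$rank == 1)
  ids <- unique(ranked$recording_id)
  pred <- setNames(top1$class, top1$recording_id)[ids]
  names(true_labels) <- ids
  cm <- confusion(unname(true_labels), unname(pred), classes)
  panel <- one_vs_rest_metrics(cm)
  acc <- accuracy_and_adjusted(cm, credit)
  ci_acc <- bootstrap_ci(function(tr, pr) mean(tr == pr), unname(true_labels),
                         unname(pred), B = B, seed = seed)
  ci_f1 <- bootstrap_ci(function(tr, pr) {
    suppressMessages(
      weighted_average(one_vs_rest_metrics(confusion(tr, pr, rownames(cm))))$F1
    )
  }, unname(true_labels), unname(pred), B = B, seed = seed + 1)
  structure(
    list(confusion = cm, panel = panel, weighted = weighted_average(panel),
         accuracy = acc,
         ci = tibble(metric = c("accuracy", "weighted_F1"),
                     bind_rows(ci_acc, ci_f1)),
         topk = topk_analysis(ranked, true_labels, k_max),
         config = list(B = B, seed = seed, k_max = k_max)),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> %d recordings, %d classes | accuracy %.4f, weighted F1 %.4f%s\n",
    sum(x$confusion), nrow(x$confusion), x$accuracy$accuracy, x$weighted$F1,
    if (!is.na(x$accuracy$adjusted_accuracy))
      sprintf(", adjusted %.4f", x$accuracy$adjusted_accuracy) else ""
  ))
  invisible(x)
}

#' Tidy / summarize a metric report
#'
#' `tidy()` returns the per-class panel (percent scale matching the reporting
#' convention is left to the caller); `glance()` returns the one-row summary.
#'
#' @param x A `metric_report`.
#' @param ... Unused.
#' @export
tidy.metric_report <- function(x, ...) x$panel

#' @rdname tidy.metric_report
#' @export
glance.metric_report <- function(x, ...) {
  bind_cols(
    x$accuracy,
    x$weighted,
    tibble(accuracy_ci_lower = x$ci$lower[1], accuracy_ci_upper = x$ci$upper[1],
           n = sum(x$confusion))
  )
}

#' Plot a confusion matrix as a tile heat map
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy.confusion_matrix(object)
  ggplot(df, aes(x = .data$predicted, y = .data$true, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = ifelse(.data$n > 0, .data$n, "")), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    scale_y_discrete(limits = rev(rownames(object))) +
    labs(x = "Predicted site", y = "True site", fill = "Recordings") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Export a metric report
#'
#' Writes the report as JSON plus a per-class CSV (one row per class and an
#' `Average` row, metrics on the percent scale).
#'
#' @param report A `metric_report`.
#' @param path_json,path_csv Destinations (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_metric_report <- function(report, path_json = NULL, path_csv = NULL) {
  if (!is.null(path_json)) {
    doc <- list(
      accuracy = report$accuracy, weighted = report$weighted,
      ci = report$ci, panel = report$panel,
      confusion = list(classes = rownames(report$confusion),
                       counts = unclass(report$confusion)),
      topk = report$topk, config = report$config
    )
    jsonlite::write_json(doc, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(path_csv)) {
    pct <- function(v) round(100 * v, 2)
    per_class <- report$panel |>
      transmute(class = .data$class, support = .data$support,
                SE = pct(.data$SE), SP = pct(.data$SP), PPV = pct(.data$PPV),
                NPV = pct(.data$NPV), F1 = pct(.data$F1),
                balanced_accuracy = pct(.data$balanced_accuracy))
    avg <- report$weighted |>
      transmute(class = "Average", support = sum(report$panel$support),
                SE = pct(.data$SE), SP = pct(.data$SP), PPV = pct(.data$PPV),
                NPV = pct(.data$NPV), F1 = pct(.data$F1),
                balanced_accuracy = pct(.data$balanced_accuracy))
    readr::write_csv(bind_rows(per_class, avg), path_csv, progress = FALSE)
  }
  invisible(c(path_json, path_csv))
}
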