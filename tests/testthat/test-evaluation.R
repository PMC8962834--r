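# independent brute-force metric oracle working from raw label pairs
oracle_metrics <- function(truth, pred, cl) {
  TP <- sum(truth == cl & pred == cl)
  FN <- sum(truth == cl & pred != cl)
  FP <- sum(truth != cl & pred == cl)
  TN <- sum(truth != cl & pred != cl)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  SE <- div(TP, TP + FN); SP <- div(TN, TN + FP)
  PPV <- div(TP, TP + FP); NPV <- div(TN, TN + FN)
  F1 <- if (is.na(SE) || is.na(PPV) || SE + PPV == 0) NA_real_ else
    2 * PPV * SE / (PPV + SE)
  c(SE = SE, SP = SP, PPV = PPV, NPV = NPV, F1 = F1)
}

test_that("confusion counts match hand tallies and handle edge cases", {
  cm <- confusion(c("A", "A", "B"), c("A", "B", "B"), classes = c("A", "B"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2,
                                   dimnames = list(true = c("A", "B"),
                                                   predicted = c("A", "B"))),
               ignore_attr = TRUE)
  perfect <- confusion(c("A", "B", "C"), c("A", "B", "C"))
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  empty <- confusion(character(), character(), classes = c("A", "B"))
  expect_true(all(empty == 0))
  expect_error(confusion("A", "Z", classes = "A"), "Z")
  expect_error(confusion(c("A", "B"), "A"), "equal length")
})

test_that("one-vs-rest metrics agree with hand arithmetic", {
  cm <- confusion(rep(c("1", "2"), c(10, 10)),
                  c(rep("1", 8), rep("2", 2), "1", rep("2", 9)),
                  classes = c("1", "2"))
  panel <- one_vs_rest_metrics(cm)
  r1 <- panel[panel$class == "1", ]
  expect_equal(r1$SE, 0.8)
  expect_equal(r1$SP, 0.9)
  expect_equal(r1$PPV, 8 / 9)
  expect_equal(r1$F1, 2 * (8 / 9) * 0.8 / ((8 / 9) + 0.8))
  expect_equal(r1$balanced_accuracy, (0.8 + 0.9) / 2)

  diag_cm <- confusion(c("A", "B"), c("A", "B"))
  pd <- one_vs_rest_metrics(diag_cm)
  expect_true(all(pd[, c("SE", "SP", "PPV", "NPV", "F1")] == 1))

  # zero predicted positives: PPV and F1 undefined, SE = 0
  cm0 <- confusion(c("A", "A", "B"), c("B", "B", "B"), classes = c("A", "B"))
  expect_message(p0 <- one_vs_rest_metrics(cm0), "Undefined")
  rA <- p0[p0$class == "A", ]
  expect_equal(rA$SE, 0)
  expect_true(is.na(rA$PPV) && is.na(rA$F1))
})

test_that("the metric panel equals a brute-force oracle on random instances", {
  withr::with_seed(314, {
    for (i in 1:50) {
      k <- sample(2:6, 1)
      n <- sample(10:200, 1)
      classes <- LETTERS[1:k]
      truth <- sample(classes, n, replace = TRUE)
      pred <- sample(classes, n, replace = TRUE)
      panel <- suppressMessages(
        one_vs_rest_metrics(confusion(truth, pred, classes)))
      for (cl in classes) {
        got <- unlist(panel[panel$class == cl, c("SE", "SP", "PPV", "NPV", "F1")])
        expect_equal(got, oracle_metrics(truth, pred, cl), ignore_attr = TRUE)
      }
      # micro identity: accuracy equals support-weighted SE
      acc <- mean(truth == pred)
      expect_equal(suppressMessages(weighted_average(panel))$SE, acc)
    }
  })
})

test_that("weighted averages renormalize over defined classes", {
  panel <- tibble::tibble(class = c("A", "B"), support = c(1, 1),
                          SE = c(0.8, 1), SP = c(1, 1), PPV = c(NA, 0.5),
                          NPV = c(1, 1), F1 = c(NA, 0.5),
                          balanced_accuracy = c(0.9, 1))
  avg <- weighted_average(panel)
  expect_equal(avg$SE, 0.9)
  expect_equal(avg$PPV, 0.5)  # only the defined class counts
  avg2 <- weighted_average(panel, supports = c(3, 1))
  expect_equal(avg2$SE, (3 * 0.8 + 1) / 4)
})

test_that("adjusted accuracy reduces, dominates, and matches hand computation", {
  cm <- confusion(c("1", "1", "2", "2"), c("1", "2", "2", "2"),
                  classes = c("1", "2"))
  w <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("1", "2"), c("1", "2")))
  out <- accuracy_and_adjusted(cm, w)
  expect_equal(out$accuracy, 0.75)
  expect_equal(out$adjusted_accuracy, 0.875)

  ident <- diag(2); dimnames(ident) <- dimnames(w)
  expect_equal(accuracy_and_adjusted(cm, ident)$adjusted_accuracy, 0.75)

  withr::with_seed(8, {
    for (i in 1:20) {
      k <- sample(2:5, 1)
      classes <- LETTERS[1:k]
      truth <- sample(classes, 50, replace = TRUE)
      pred <- sample(classes, 50, replace = TRUE)
      cmr <- confusion(truth, pred, classes)
      wr <- matrix(runif(k * k), k, dimnames = list(classes, classes))
      diag(wr) <- 1
      res <- accuracy_and_adjusted(cmr, wr)
      expect_gte(res$adjusted_accuracy, res$accuracy)
    }
  })
  expect_error(accuracy_and_adjusted(confusion(character(), character(), "A")),
               "undefined")
})

test_that("bootstrap CIs behave like the binomial closed form", {
  # degenerate: all correct
  ci <- bootstrap_ci(function(tr, pr) mean(tr == pr),
                     rep("A", 50), rep("A", 50), B = 200, seed = 1)
  expect_equal(c(ci$point, ci$lower, ci$upper), c(1, 1, 1))

  # width against the binomial closed form at n = 1000, 90% correct
  truth <- rep("A", 1000)
  pred <- c(rep("A", 900), rep("B", 100))
  ci2 <- bootstrap_ci(function(tr, pr) mean(tr == pr), truth, pred,
                      B = 2000, seed = 42)
  width <- ci2$upper - ci2$lower
  closed <- 2 * 1.96 * sqrt(0.9 * 0.1 / 1000)
  expect_gt(width, closed * 0.7)
  expect_lt(width, closed * 1.3)
  expect_equal(ci2$point, 0.9)
})

test_that("bootstrap interval brackets the point across random instances", {
  withr::with_seed(77, {
    for (i in 1:100) {
      n <- sample(20:60, 1)
      truth <- sample(c("A", "B"), n, replace = TRUE)
      pred <- sample(c("A", "B"), n, replace = TRUE)
      ci <- bootstrap_ci(function(tr, pr) mean(tr == pr), truth, pred,
                         B = 100, seed = i)
      expect_lte(ci$lower, ci$point + 1e-12)
      expect_gte(ci$upper, ci$point - 1e-12)
    }
  })
})

test_that("bootstrap CI width shrinks roughly like 1/sqrt(n)", {
  widths <- vapply(c(100, 400, 1600), function(n) {
    truth <- rep("A", n)
    pred <- c(rep("A", round(0.9 * n)), rep("B", n - round(0.9 * n)))
    ci <- bootstrap_ci(function(tr, pr) mean(tr == pr), truth, pred,
                       B = 1000, seed = 5)
    ci$upper - ci$lower
  }, numeric(1))
  expect_gt(widths[1] / widths[2], 1.5)
  expect_lt(widths[1] / widths[2], 2.7)
  expect_gt(widths[2] / widths[3], 1.5)
  expect_lt(widths[2] / widths[3], 2.7)
})

test_that("the cluster bootstrap widens intervals under within-patient correlation", {
  # 40 patients x 5 identical recordings: per-recording resampling pretends
  # n = 200 independent observations, the patient bootstrap does not
  withr::with_seed(15, {
    pat <- rep(sprintf("P%02d", 1:40), each = 5)
    correct <- rep(rbinom(40, 1, 0.8) == 1, each = 5)
    truth <- rep("A", 200)
    pred <- ifelse(correct, "A", "B")
    acc <- function(tr, pr) mean(tr == pr)
    ci_rec <- bootstrap_ci(acc, truth, pred, B = 500, seed = 1)
    ci_pat <- bootstrap_ci(acc, truth, pred, B = 500, seed = 1, clusters = pat)
    expect_gt(ci_pat$upper - ci_pat$lower, ci_rec$upper - ci_rec$lower)
    expect_lte(ci_pat$lower, ci_pat$point)
    expect_gte(ci_pat$upper, ci_pat$point)
  })
})

test_that("a mostly-undefined bootstrap metric reports an undefined CI", {
  metric <- function(tr, pr) if (runif(1) < 0.5) NA_real_ else 1
  ci <- bootstrap_ci(metric, rep("A", 10), rep("A", 10), B = 200, seed = 3)
  expect_true(is.na(ci$lower) && is.na(ci$upper))
  expect_match(attr(ci, "diagnostic"), "undefined")
})

test_that("top-k analysis ranks the true site correctly", {
  ranked <- tibble::tibble(
    recording_id = rep(c("r1", "r2"), each = 2),
    rank = rep(1:2, 2),
    class = c("A", "B", "A", "B"),
    probability = c(0.6, 0.4, 0.9, 0.1)
  )
  hist <- topk_analysis(ranked, c(r1 = "B", r2 = "A"), k_max = 3)
  expect_equal(hist$n, c(1L, 1L, 0L, 0L))
  expect_equal(hist$cumulative, c(1L, 2L, 2L, 2L))

  perfect <- topk_analysis(ranked, c(r1 = "A", r2 = "A"), k_max = 3)
  expect_equal(perfect$n[1], 2L)
  expect_true(all(diff(perfect$cumulative) >= 0))
  expect_equal(sum(hist$n), 2L)

  # true class missing from the ranking pools beyond k
  expect_warning(
    miss <- topk_analysis(ranked, c(r1 = "Z", r2 = "A"), k_max = 2),
    "missing"
  )
  expect_equal(miss$n[[3]], 1L)
})

test_that("metric_report bundles a consistent panel and exports cleanly", {
  truth <- c("A", "A", "B", "B", "C")
  ranked <- purrr::list_rbind(purrr::map(1:5, function(i) {
    pred <- c("A", "A", "B", "C", "C")[i]
    others <- setdiff(c("A", "B", "C"), pred)
    tibble::tibble(recording_id = paste0("r", i), rank = 1:3,
                   class = c(pred, others), probability = c(0.8, 0.15, 0.05))
  }))
  rep <- suppressMessages(metric_report(truth, ranked, classes = c("A", "B", "C"),
                                        B = 100, seed = 2))
  expect_equal(rep$accuracy$accuracy, 0.8)
  expect_equal(sum(rep$topk$n), 5)
  expect_equal(sum(rep$confusion), 5)
  g <- glance(rep)
  expect_equal(g$accuracy, 0.8)
  paths <- withr::local_tempfile(fileext = c(".json", ".csv"))
  write_metric_report(rep, paths[1], paths[2])
  csv <- readr::read_csv(paths[2], show_col_types = FALSE)
  expect_equal(nrow(csv), 4L)  # 3 classes + Average
  expect_equal(csv$class[4], "Average")
})
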