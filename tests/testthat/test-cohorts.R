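test_that("the exclusion-flow arithmetic reproduces the final cohort", {
  flow <- patient_flow()
  expect_equal(flow$remaining[1], 747)
  expect_equal(tail(flow$remaining, 1), 545)
  expect_equal(sum(flow$removed), 202)
})

test_that("545 single-stratum patients split 436/55/54", {
  ds <- flat_dataset(545)
  for (seed in c(1, 7, 99)) {
    pm <- split_patients(ds, seed = seed)
    counts <- table(pm$cohort)
    expect_equal(unname(counts[c("train", "validation", "test")]),
                 c(436L, 55L, 54L), ignore_attr = TRUE)
  }
})

test_that("a five-patient class splits 3/1/1 and one patient warns into training", {
  ds5 <- flat_dataset(5, label = "Summit")
  pm <- split_patients(ds5, seed = 2)
  expect_equal(unname(table(pm$cohort)[c("train", "validation", "test")]),
               c(3L, 1L, 1L), ignore_attr = TRUE)

  ds1 <- flat_dataset(1)
  expect_warning(pm1 <- split_patients(ds1, seed = 2), "single patient")
  expect_equal(pm1$cohort, "train")
})

test_that("splitting is deterministic given (dataset, fractions, seed)", {
  ds <- simulate_dataset(tiny_config())
  a <- split_patients(ds, seed = 5)
  b <- split_patients(ds, seed = 5)
  expect_identical(a, b)
  c <- split_patients(ds, seed = 6)
  expect_false(identical(a$cohort, c$cohort))
})

test_that("recordings inherit their patient's cohort, never split", {
  ds <- simulate_dataset(tiny_config())
  pm <- split_patients(ds, seed = 3)
  a <- suppressWarnings(allocate_recordings(ds, pm, seed = 3))
  joined <- merge(a$recordings, pm, by = "patient_id")
  expect_true(all(joined$cohort.x == joined$cohort.y))
  # cohorts are patient-disjoint
  tab <- table(a$recordings$patient_id, a$recordings$cohort)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("oversampling equalizes every training class to the majority count", {
  ds <- simulate_dataset(tiny_config(class_counts = c(30, 12, 6)))
  pm <- split_patients(ds, seed = 4)
  a <- suppressWarnings(allocate_recordings(ds, pm, seed = 4))
  a <- oversample_training(a, seed = 9)
  train <- a$recordings[a$recordings$cohort == "train", ]
  lab <- setNames(train$label, train$recording_id)
  tally <- table(lab[a$oversampled_train])
  expect_true(all(tally == max(tally)))
  # the multiset contains the training set
  expect_true(all(train$recording_id %in% a$oversampled_train))
  # validation / test multiplicities all equal 1
  tidy_a <- tidy(a)
  expect_true(all(tidy_a$multiplicity[tidy_a$cohort != "train"] == 1))
})

test_that("an already balanced training set is a fixed point", {
  ds <- simulate_dataset(tiny_config(n_classes = 2, class_counts = c(12, 12),
                                     patients_per_class = 3))
  pm <- split_patients(ds, seed = 1)
  a <- suppressWarnings(allocate_recordings(ds, pm, seed = 1))
  train_n <- sum(a$recordings$cohort == "train")
  a2 <- oversample_training(a, seed = 2)
  tally <- table(a2$oversampled_train)
  if (length(unique(table(a$recordings$label[a$recordings$cohort == "train"]))) == 1) {
    expect_equal(length(a2$oversampled_train), train_n)
    expect_true(all(tally == 1))
  }
})

test_that("printed training counts oversample the 25-recording minority to 1,694", {
  dist <- site_distribution()
  recs <- tibble::tibble(
    recording_id = sprintf("T%05d", seq_len(sum(dist$training))),
    patient_id = "bulk",
    label = rep(dist$site, dist$training),
    cohort = "train"
  )
  a <- structure(list(patients = NULL, recordings = recs,
                      oversampled_train = recs$recording_id, seed = 1),
                 class = "cohort_assignment")
  a <- oversample_training(a, seed = 1)
  lab <- setNames(recs$label, recs$recording_id)
  tally <- table(lab[a$oversampled_train])
  expect_equal(max(dist$training), 1694)
  expect_true(all(tally == 1694))
  expect_equal(unname(tally["Summit"]), 1694, ignore_attr = TRUE)
})

test_that("patient-disjointness and balance hold across seeds", {
  ds <- simulate_dataset(tiny_config(class_counts = c(20, 10, 5)))
  for (seed in 1:20) {
    pm <- split_patients(ds, seed = seed)
    a <- suppressWarnings(allocate_recordings(ds, pm, seed = seed))
    a <- oversample_training(a, seed = seed)
    tab <- table(a$recordings$patient_id, a$recordings$cohort)
    expect_true(all(rowSums(tab > 0) == 1))
    train <- a$recordings[a$recordings$cohort == "train", ]
    tally <- table(setNames(train$label, train$recording_id)[a$oversampled_train])
    expect_true(all(tally == max(tally)))
  }
})
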