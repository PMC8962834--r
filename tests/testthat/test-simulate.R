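test_that("patient and recording counts follow the configuration", {
  cfg <- simulation_config(n_classes = 3, class_counts = 50,
                           patients_per_class = 10, record_length = 600,
                           discriminative_offsets = -30:30, seed = 1)
  ds <- simulate_dataset(cfg)
  expect_equal(nrow(ds), 150L)
  expect_equal(length(unique(ds$patient_id)), 30L)
  expect_equal(unname(table(ds$label)), rep(50L, 3), ignore_attr = TRUE)
  # each patient's recordings all carry one label
  expect_true(all(tapply(ds$label, ds$patient_id, function(x) length(unique(x))) == 1))
})

test_that("the noiseless limit reproduces the class template exactly", {
  cfg <- simulation_config(n_classes = 2, class_counts = 4,
                           patients_per_class = 2, noise_sd = 0,
                           patient_jitter_sd = 0, record_length = 600,
                           discriminative_offsets = -30:30, seed = 3)
  ds <- simulate_dataset(cfg)
  templates <- make_templates(cfg)
  names(templates) <- vapply(templates, function(t) t$class_code, character(1))
  for (i in seq_len(nrow(ds))) {
    expect_equal(unname(ds$signal[[i]]),
                 unname(templates[[ds$label[[i]]]]$signal), tolerance = 1e-12)
  }
})

test_that("separation scales template distances linearly from a common origin", {
  base_cfg <- function(sep) {
    simulation_config(n_classes = 4, class_counts = 4, patients_per_class = 2,
                      separation = sep, record_length = 600,
                      discriminative_offsets = -30:30, seed = 5)
  }
  t0 <- make_templates(base_cfg(0))
  sigs <- lapply(t0, function(t) t$signal)
  for (i in 2:4) expect_equal(sigs[[i]], sigs[[1]])  # separation 0: identical

  t1 <- make_templates(base_cfg(1))
  t2 <- make_templates(base_cfg(2))
  dist <- function(a, b) sqrt(sum((a$signal - b$signal)^2))
  for (pair in list(c(1, 2), c(1, 3), c(2, 4))) {
    d1 <- dist(t1[[pair[1]]], t1[[pair[2]]])
    d2 <- dist(t2[[pair[1]]], t2[[pair[2]]])
    expect_equal(d2, 2 * d1, tolerance = 1e-9)
  }
})

test_that("lead II carries the dominant R lobe at the planted peak", {
  cfg <- tiny_config(seed = 8)
  templates <- make_templates(cfg)
  for (t in templates) {
    ii <- t$signal["II", ]
    expect_equal(which.max(ii), cfg$r_peak_at)
    expect_gt(max(ii), max(abs(ii[-cfg$r_peak_at])))
  }
  # fallback detector finds the planted peak without the annotation
  ds <- simulate_dataset(cfg)
  rec <- ecgorigin:::dataset_recording(ds, 1)
  rec$r_peak_index <- NULL
  expect_lt(abs(locate_reference(rec) - cfg$r_peak_at), 3)
})

test_that("identical seeds generate bit-identical datasets", {
  cfg <- tiny_config(seed = 12)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$signal, d2$signal)
  expect_identical(d1$patient_id, d2$patient_id)
  d3 <- simulate_dataset(tiny_config(seed = 13))
  expect_false(identical(d1$signal[[1]], d3$signal[[1]]))
})

test_that("a 21-class roster uses the anatomical site codes", {
  cfg <- simulation_config(n_classes = 21, class_counts = 3,
                           patients_per_class = 1, record_length = 600,
                           discriminative_offsets = -30:30, seed = 2)
  expect_identical(cfg$class_codes, anatomy_sites())
  templates <- make_templates(cfg)
  expect_length(templates, 21L)
  sigs <- lapply(templates, function(t) t$signal)
  for (i in 2:21) expect_false(identical(sigs[[1]], sigs[[i]]))
})

test_that("the frozen benchmark is constant and triggers oversampling", {
  b1 <- default_benchmark()
  b2 <- default_benchmark()
  expect_identical(b1, b2)
  expect_equal(b1$sampling_rate, 2000)
  expect_equal(b1$record_length, 2400L)
  expect_equal(max(b1$class_counts) / min(b1$class_counts), 50)
  expect_lt(min(b1$class_counts), max(b1$class_counts))  # minority < majority
})

test_that("patient jitter correlates recordings within a patient", {
  cfg <- simulation_config(n_classes = 2, class_counts = 10,
                           patients_per_class = 2, noise_sd = 0.01,
                           patient_jitter_sd = 0.2, record_length = 600,
                           discriminative_offsets = -30:30, seed = 21)
  ds <- simulate_dataset(cfg)
  # residuals from the class template
  templates <- make_templates(cfg)
  names(templates) <- vapply(templates, function(t) t$class_code, character(1))
  resid <- lapply(seq_len(nrow(ds)), function(i) {
    as.vector(ds$signal[[i]] - templates[[ds$label[[i]]]]$signal)
  })
  same_patient <- cor(resid[[1]], resid[[2]])
  expect_gt(same_patient, 0.5)
})
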