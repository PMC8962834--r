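#' Patient-selection flow arithmetic
#'
#' Applies the study's exclusion filters to an initial enrolment count:
#' incomplete or mismatched procedure logs, arrhythmia recurrence during the
#' first six months of follow-up, structural/ischemic comorbidity, and
#' multiple ablation sites. Defaults are the study's printed counts.
#'
#' @param n_initial Patients screened (default 747).
#' @param n_incomplete Removed for incomplete/mismatched records (109).
#' @param n_recurrence Removed for six-month recurrence (76).
#' @param n_comorbidity Removed for structural disease (5).
#' @param n_multisite Removed for multiple ablation sites (12).
#' @return A tibble with one row per stage (`stage`, `removed`, `remaining`);
#'   the last `remaining` is the final cohort size.
#' @export
patient_flow <- function(n_initial = 747, n_incomplete = 109, n_recurrence = 76,
                         n_comorbidity = 5, n_multisite = 12) {
  removed <- c(0, n_incomplete, n_recurrence, n_comorbidity, n_multisite)
  tibble(
    stage = c("screened", "incomplete records", "six-month recurrence",
              "structural comorbidity", "multiple ablation sites"),
    removed = removed,
    remaining = n_initial - cumsum(removed)
  )
}

#' Printed per-site sample distribution (finest scheme)
#'
#' The study's per-site patient and recording counts with the 80/10/10
#' recording allocation, usable as input to bookkeeping functions (e.g. to
#' reconstruct the oversampling arithmetic without clinical data).
#'
#' @return A tibble with columns `site`, `patients`, `recordings`,
#'   `training`, `validation`, `testing`.
#' @export
site_distribution <- function() {
  tribble(
    ~site,                     ~patients, ~recordings, ~training, ~validation, ~testing,
    "LC",                      67,  2118, 1694, 212, 212,
    "RVOT posterior septal",   43,  1848, 1478, 185, 185,
    "LCC",                     41,   588,  470,  59,  59,
    "AC",                      38,  1079,  863, 108, 108,
    "RVOT free wall",          32,  1287, 1029, 129, 129,
    "RVOT anterior septal",    32,  1014,  812, 101, 101,
    "Right His bundle",        31,   705,  563,  71,  71,
    "RC",                      24,   353,  283,  35,  35,
    "AMC",                     23,  1434, 1146, 144, 144,
    "LPF",                     18,   913,  731,  91,  91,
    "TV",                      18,   563,  451,  56,  56,
    "LAF",                     13,   885,  707,  89,  89,
    "LCC-RCC commissure",      11,   172,  138,  17,  17,
    "Epicardium of LV summit", 10,   351,  281,  35,  35,
    "LPPM",                     9,   677,  541,  68,  68,
    "MV",                       8,   330,  264,  33,  33,
    "LAPM",                     8,   192,  154,  19,  19,
    "RCC",                      7,    51,   41,   5,   5,
    "Summit",                   5,    31,   25,   3,   3,
    "Left His bundle",          3,   149,  119,  15,  15,
    "RAPM",                     2,    14,   12,   1,   1
  )
}

# Per-class cohort quota: floor quotas, extras by largest fractional
# remainder (ties: training, then validation, then test), then a coverage
# step guaranteeing >= 1 validation and >= 1 test patient whenever the class
# has at least 3 patients. Reproduces 545 -> 436/55/54 and 5 -> 3/1/1.
cohort_quota <- function(n, fractions) {
  base <- floor(n * fractions)
  frac <- n * fractions - base
  extras <- n - sum(base)
  if (extras > 0) {
    ord <- order(-frac, seq_along(fractions))
    for (i in head(ord, extras)) base[i] <- base[i] + 1
  }
  if (n >= 3) {
    for (i in c(2L, 3L)) {
      if (base[i] == 0 && base[1] > 0) {
        base[1] <- base[1] - 1
        base[i] <- base[i] + 1
      }
    }
  }
  setNames(base, c("train", "validation", "test"))
}

#' Patient-level stratified 80/10/10 split
#'
#' Patients are stratified by their (leaf-level) class so one assignment can
#' serve all collapse schemes; within each class, patients are shuffled with
#' the seed and assigned to training, validation and test by largest-remainder
#' quotas. Classes with at least three patients are guaranteed one validation
#' and one test patient; a single-patient class goes entirely to training with
#' a warning. A patient with recordings under several labels is stratified by
#' its most frequent label (ties: first in vocabulary order).
#'
#' @param ds An [ecg_dataset()].
#' @param fractions Cohort fractions, summing to 1 (default `c(0.8, 0.1, 0.1)`).
#' @param seed Integer seed controlling the shuffle.
#' @return A tibble with columns `patient_id`, `class`, `cohort`.
#' @export
split_patients <- function(ds, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-9 || length(fractions) != 3) {
    abort("`fractions` must be three values summing to 1.")
  }
  pat <- ds |>
    as_tibble() |>
    count(.data$patient_id, .data$label) |>
    group_by(.data$patient_id) |>
    slice_max(.data$n, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("patient_id", class = "label")
  out <- withr::with_seed(seed, {
    pat |>
      group_by(.data$class) |>
      group_modify(function(g, key) {
        g <- g[sample.int(nrow(g)), , drop = FALSE]
        quota <- cohort_quota(nrow(g), fractions)
        if (nrow(g) == 1) {
          warn(sprintf(
            "Class '%s' has a single patient; assigned to training (no validation/test coverage).",
            key$class
          ))
        }
        g$cohort <- rep(c("train", "validation", "test"), times = quota)
        g
      }) |>
      ungroup()
  })
  out |> select("patient_id", "class", "cohort") |> arrange(.data$patient_id)
}

#' Allocate recordings to their patients' cohorts
#'
#' Every recording inherits its patient's cohort (recordings of one patient
#' are never split). Within each class, a deviation of the realized recording
#' shares from the target fractions by more than 2 percentage points emits a
#' warning: patient-level assignment constrains how exact the recording-level
#' split can be.
#'
#' @param ds An [ecg_dataset()].
#' @param patient_map Output of [split_patients()].
#' @param fractions Target cohort fractions.
#' @param seed Seed recorded on the assignment (allocation itself is
#'   deterministic given the patient map).
#' @return A `cohort_assignment`: list with `patients`, `recordings` (tibble:
#'   recording_id, patient_id, label, cohort), `oversampled_train`
#'   (recording-id multiset, initially the training set itself) and `seed`.
#' @export
allocate_recordings <- function(ds, patient_map, fractions = c(0.8, 0.1, 0.1),
                                seed = 1) {
  missing <- setdiff(unique(ds$patient_id), patient_map$patient_id)
  if (length(missing)) {
    abort(paste0("Patients missing from the map: ", paste(missing, collapse = ", ")))
  }
  recs <- ds |>
    as_tibble() |>
    select("recording_id", "patient_id", "label") |>
    left_join(patient_map |> select("patient_id", "cohort"), by = "patient_id")
  shares <- recs |>
    count(.data$label, .data$cohort) |>
    group_by(.data$label) |>
    mutate(share = .data$n / sum(.data$n)) |>
    ungroup()
  target <- setNames(fractions, c("train", "validation", "test"))
  dev <- shares |>
    mutate(deviation = abs(.data$share - target[.data$cohort])) |>
    filter(.data$deviation > 0.02)
  if (nrow(dev)) {
    warn(sprintf(
      "Recording shares deviate from target fractions by > 2 points for %d class/cohort cells (max %.1f points).",
      nrow(dev), 100 * max(dev$deviation)
    ))
  }
  structure(
    list(patients = patient_map, recordings = recs,
         oversampled_train = recs$recording_id[recs$cohort == "train"],
         seed = seed),
    class = "cohort_assignment"
  )
}

#' @export
print.cohort_assignment <- function(x, ...) {
  tab <- table(x$recordings$cohort)
  cat(sprintf(
    "<cohort_assignment> %d patients; recordings train=%d validation=%d test=%d; oversampled train=%d\n",
    nrow(x$patients), tab["train"] %||% 0, tab["validation"] %||% 0,
    tab["test"] %||% 0, length(x$oversampled_train)
  ))
  invisible(x)
}

#' Majority-matching oversampling of the training cohort
#'
#' For each class, training recordings are duplicated by seeded sampling with
#' replacement until the class count equals the majority class's training
#' count. Validation and test cohorts are never touched.
#'
#' @param assignment A `cohort_assignment`.
#' @param seed Integer seed for the resampling.
#' @param labels Optional named character vector (recording_id -> label)
#'   overriding the stored labels, e.g. labels collapsed to a coarser scheme
#'   before balancing.
#' @return The assignment with `oversampled_train` replaced by the balanced
#'   multiset of recording ids.
#' @export
oversample_training <- function(assignment, seed = 1, labels = NULL) {
  train <- assignment$recordings |> filter(.data$cohort == "train")
  if (nrow(train) == 0) abort("Training cohort is empty.")
  lab <- if (is.null(labels)) setNames(train$label, train$recording_id) else
    labels[train$recording_id]
  counts <- table(lab)
  target <- max(counts)
  ids <- withr::with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      pool <- train$recording_id[lab == cl]
      need <- target - length(pool)
      c(pool, if (need > 0) sample(pool, need, replace = TRUE))
    }), use.names = FALSE)
  })
  absent <- setdiff(unique(assignment$recordings$label), names(counts))
  if (length(absent) && is.null(labels)) {
    warn(paste0("Classes absent from training were skipped: ",
                paste(absent, collapse = ", ")))
  }
  assignment$oversampled_train <- ids
  assignment
}

#' Tidy a cohort assignment
#'
#' @param x A `cohort_assignment`.
#' @param ... Unused.
#' @return Tibble with recording_id, patient_id, label, cohort, multiplicity
#'   (multiplicity > 1 only for oversampled training recordings).
#' @export
tidy.cohort_assignment <- function(x, ...) {
  mult <- table(x$oversampled_train)
  x$recordings |>
    mutate(multiplicity = ifelse(
      .data$cohort == "train",
      as.integer(mult[.data$recording_id]),
      1L
    ))
}

#' Subset a dataset to one cohort
#'
#' @param ds The [ecg_dataset()] the assignment was built from.
#' @param assignment A `cohort_assignment`.
#' @param cohort One of "train", "validation", "test".
#' @param oversampled Use the oversampled training multiset (training only)?
#' @return An [ecg_dataset()] (rows repeated per multiplicity when
#'   `oversampled`).
#' @export
cohort_dataset <- function(ds, assignment, cohort, oversampled = FALSE) {
  ids <- if (cohort == "train" && oversampled) {
    assignment$oversampled_train
  } else {
    assignment$recordings$recording_id[assignment$recordings$cohort == cohort]
  }
  idx <- match(ids, ds$recording_id)
  out <- ds[idx, ]
  if (oversampled && cohort == "train") {
    # duplicated rows need unique recording ids downstream
    dup <- duplicated(out$recording_id)
    out$recording_id[dup] <- paste0(out$recording_id[dup], "_dup",
                                    seq_len(sum(dup)))
  }
  new_ecg_dataset(out, label_vocabulary(ds), attr(ds, "provenance") %||% "")
}
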