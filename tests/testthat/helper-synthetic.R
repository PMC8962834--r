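# Shared fixture builders. Everything is generated in code at test time.

# small, fast, well-separated 3-class simulation for pipeline mechanics
tiny_config <- function(seed = 42, separation = 1.5, noise_sd = 0.05,
                        patient_jitter_sd = 0.03, n_classes = 3,
                        class_counts = c(15, 12, 9), patients_per_class = 3,
                        record_length = 600,
                        discriminative_offsets = -40:40) {
  simulation_config(
    n_classes = n_classes, class_counts = class_counts,
    patients_per_class = patients_per_class, separation = separation,
    noise_sd = noise_sd, patient_jitter_sd = patient_jitter_sd,
    record_length = record_length,
    discriminative_offsets = discriminative_offsets, seed = seed
  )
}

# a raw recording with a controllable lead-II bump
bump_recording <- function(T_len = 400, peak = 200, amp = 1, noise = 0,
                           id = "R1", patient = "P1", label = NULL,
                           r_peak_index = NULL, seed = 7) {
  withr::with_seed(seed, {
    sig <- matrix(rnorm(12 * T_len, 0, noise), 12, T_len)
    rownames(sig) <- ecg_leads()
    t_idx <- seq_len(T_len)
    sig["II", ] <- sig["II", ] + amp * exp(-((t_idx - peak)^2) / (2 * 9))
    ecg_recording(sig, patient_id = patient, recording_id = id,
                  r_peak_index = r_peak_index, label = label)
  })
}

# dataset of n single-recording patients sharing one class label
flat_dataset <- function(n_patients, label = "LC", T_len = 8) {
  recs <- lapply(seq_len(n_patients), function(i) {
    sig <- matrix(0, 12, T_len)
    rownames(sig) <- ecg_leads()
    ecg_recording(sig, patient_id = sprintf("P%04d", i),
                  recording_id = sprintf("R%04d", i), label = label)
  })
  ecg_dataset(recs)
}

# feature set whose only class signal sits in lead V1, window offsets 1..10
planted_v1_dataset <- function(n_per_class = 40, n_classes = 3, T_len = 80,
                               r_peak = 40, amp = 2, seed = 99) {
  withr::with_seed(seed, {
    recs <- list()
    n <- 0L
    for (ci in seq_len(n_classes)) {
      shift <- amp * (ci - (n_classes + 1) / 2)
      for (i in seq_len(n_per_class)) {
        n <- n + 1L
        sig <- matrix(rnorm(12 * T_len, 0, 0.25), 12, T_len)
        rownames(sig) <- ecg_leads()
        sig["V1", r_peak:(r_peak + 9)] <- sig["V1", r_peak:(r_peak + 9)] + shift
        recs[[n]] <- ecg_recording(
          sig, patient_id = sprintf("P%03d", n), recording_id = sprintf("R%03d", n),
          r_peak_index = r_peak, label = sprintf("C%02d", ci)
        )
      }
    }
    ecg_dataset(recs)
  })
}

# three patient-disjoint cohorts of features from one simulated dataset
tiny_cohort_features <- function(cfg = tiny_config(), W = 60, seed = 1) {
  ds <- simulate_dataset(cfg)
  pm <- split_patients(ds, seed = seed)
  a <- suppressWarnings(allocate_recordings(ds, pm, seed = seed))
  a <- oversample_training(a, seed = seed + 1)
  list(
    ds = ds, assignment = a,
    train = build_feature_matrix(cohort_dataset(ds, a, "train", oversampled = TRUE), W),
    val = build_feature_matrix(cohort_dataset(ds, a, "validation"), W),
    test = build_feature_matrix(cohort_dataset(ds, a, "test"), W)
  )
}

registry_spec <- function(id) {
  reg <- default_registry()
  reg[reg$spec_id == id, ]
}
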