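#' Beat-window configuration
#'
#' A window of `W` samples straddling the lead-II R-peak reference line:
#' `pre = floor(W/2)` samples strictly before the reference sample and
#' `post = W - pre` samples at-and-after it. The reference sample is the first
#' sample of the "post" side, so feature offsets run `-pre..-1, 1..post` with
#' offset 1 denoting the reference sample itself (offset 0 does not exist).
#'
#' @param W Window length in samples (>= 1).
#' @return A list with `W`, `pre`, `post`, of class `window_config`.
#' @export
window_config <- function(W) {
  W <- as.integer(W)
  if (is.na(W) || W < 1L) abort("`W` must be a positive integer.")
  pre <- W %/% 2L
  structure(list(W = W, pre = pre, post = W - pre), class = "window_config")
}

#' @export
print.window_config <- function(x, ...) {
  cat(sprintf("<window_config> W=%d (pre=%d, post=%d)\n", x$W, x$pre, x$post))
  invisible(x)
}

#' Locate the beat's reference sample
#'
#' Returns the annotated lead-II R-peak index when the recording carries one;
#' otherwise falls back to the index of maximum absolute voltage on lead II
#' (each recording contains a single QRS complex, so the global extremum is
#' the R peak). Ties resolve to the first maximizer.
#'
#' @param rec An [ecg_recording()].
#' @return Integer sample index (first sample = 1).
#' @export
locate_reference <- function(rec) {
  stopifnot(inherits(rec, "ecg_recording"))
  if (!is.null(rec$r_peak_index)) return(rec$r_peak_index)
  which.max(abs(rec$signal["II", ]))
}

#' Extract the R-peak-aligned window of a recording
#'
#' Takes samples `[r - pre, r + post)` of every lead, where `r` is the
#' reference index. Portions overrunning either end of the recording are
#' filled by edge-value padding, so the output is always exactly 12 x W.
#'
#' @param rec An [ecg_recording()].
#' @param cfg A [window_config()] or a window length `W`.
#' @return A 12 x W numeric matrix with lead rownames.
#' @export
extract_window <- function(rec, cfg) {
  stopifnot(inherits(rec, "ecg_recording"))
  if (!inherits(cfg, "window_config")) cfg <- window_config(cfg)
  r <- locate_reference(rec)
  T_len <- ncol(rec$signal)
  idx <- (r - cfg$pre):(r + cfg$post - 1L)
  idx <- pmin(pmax(idx, 1L), T_len)
  out <- rec$signal[, idx, drop = FALSE]
  colnames(out) <- NULL
  out
}

#' Feature names for a beat window
#'
#' Names follow `LEAD_OFFSET` with offsets `-pre..-1, 1..post`; offset 1 is
#' the reference-line sample ("counted as the first point"). Leads vary
#' slowest, so a row of windowed voltages is the concatenation of the 12 lead
#' windows in standard lead order.
#'
#' @param cfg A [window_config()] or window length.
#' @return Character vector of length `12 * W`.
#' @export
feature_names <- function(cfg) {
  if (!inherits(cfg, "window_config")) cfg <- window_config(cfg)
  offsets <- window_offsets(cfg)
  as.vector(vapply(ECG_LEADS, function(l) paste0(l, "_", offsets),
                   character(cfg$W)))
}

window_offsets <- function(cfg) {
  c(if (cfg$pre > 0) seq.int(-cfg$pre, -1L), seq_len(cfg$post))
}

#' Offset label of a feature, in reference-line terms
#'
#' Converts a signed offset to the reporting convention "nth point after/
#' before the reference line", where the reference sample is point 1 after.
#'
#' @param offset Signed integer offset (no zero).
#' @return Character description.
#' @export
offset_label <- function(offset) {
  ifelse(offset > 0,
         paste0(ordinal(offset), " point after the reference line"),
         paste0(ordinal(-offset), " point before the reference line"))
}

ordinal <- function(n) {
  suffix <- ifelse(n %% 100 %in% 11:13, "th",
                   c("st", "nd", "rd", rep("th", 7))[pmin(n %% 10 + (n %% 10 == 0) * 10, 10)])
  paste0(n, suffix)
}

#' Build the windowed feature matrix of a dataset
#'
#' Row i is the concatenation of the 12 windowed leads of recording i in
#' standard lead order; columns are named per [feature_names()].
#'
#' @param ds A labeled [ecg_dataset()].
#' @param cfg A [window_config()] or window length.
#' @param denoise Apply [denoise_recording()] before windowing? Default FALSE
#'   (denoising is a front-of-pipeline step; see the methods vignette).
#' @return An object of class `ecg_features`: list with `values`
#'   (n x 12W matrix), `info` (tibble: recording_id, patient_id, label) and
#'   `window` (the `window_config`).
#' @export
build_feature_matrix <- function(ds, cfg, denoise = FALSE) {
  if (!inherits(cfg, "window_config")) cfg <- window_config(cfg)
  unlabeled <- ds$recording_id[is.na(ds$label)]
  if (length(unlabeled)) {
    abort(paste0("Unlabeled recordings: ", paste(unlabeled, collapse = ", ")))
  }
  n <- nrow(ds)
  values <- matrix(NA_real_, nrow = n, ncol = 12L * cfg$W)
  for (i in seq_len(n)) {
    rec <- dataset_recording(ds, i)
    if (denoise) rec <- denoise_recording(rec)
    values[i, ] <- as.vector(t(extract_window(rec, cfg)))
  }
  colnames(values) <- feature_names(cfg)
  new_ecg_features(values,
                   tibble(recording_id = ds$recording_id,
                          patient_id = ds$patient_id,
                          label = ds$label),
                   cfg)
}

new_ecg_features <- function(values, info, cfg) {
  structure(list(values = values, info = info, window = cfg),
            class = "ecg_features")
}

#' @export
print.ecg_features <- function(x, ...) {
  cat(sprintf("<ecg_features> %d recordings x %d features (W=%d)\n",
              nrow(x$values), ncol(x$values), x$window$W))
  invisible(x)
}

#' @export
dim.ecg_features <- function(x) dim(x$values)

#' Tidy a feature matrix into long form
#'
#' @param x An `ecg_features` object.
#' @param ... Unused.
#' @return A tibble with recording_id, patient_id, label, lead, offset, value.
#' @export
tidy.ecg_features <- function(x, ...) {
  offs <- window_offsets(x$window)
  long <- as_tibble(x$values) |>
    mutate(recording_id = x$info$recording_id,
           patient_id = x$info$patient_id,
           label = x$info$label) |>
    pivot_longer(cols = -c("recording_id", "patient_id", "label"),
                 names_to = "feature", values_to = "value")
  long |>
    mutate(lead = sub("_[-0-9]+$", "", .data$feature),
           offset = as.integer(sub("^.*_", "", .data$feature))) |>
    select("recording_id", "patient_id", "label", "lead", "offset", "value")
}

#' Write / read a feature matrix as wide CSV
#'
#' @param fm An `ecg_features` object.
#' @param path CSV destination.
#' @return `path` invisibly; `read_feature_csv` returns an `ecg_features`.
#' @export
write_feature_csv <- function(fm, path) {
  df <- bind_cols(fm$info, as_tibble(fm$values))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  info <- df |> select("recording_id", "patient_id", "label") |>
    mutate(across(everything(), as.character))
  values <- as.matrix(df |> select(-c("recording_id", "patient_id", "label")))
  W <- ncol(values) / 12L
  new_ecg_features(values, info, window_config(W))
}
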