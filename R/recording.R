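#' Construct a single-beat 12-lead ECG recording
#'
#' An `ecg_recording` holds one 12 x T voltage matrix for a single PVC/VT beat
#' context, together with its patient and recording identifiers, sampling rate,
#' an optional lead-II R-peak sample index, and an optional anatomical origin
#' label. Voltages are treated as arbitrary-but-consistent units; the
#' tree-based classifiers downstream are insensitive to per-feature monotone
#' rescaling, so no unit conversion is ever attempted.
#'
#' @param signal Numeric 12 x T matrix, rows in the order of [ecg_leads()].
#'   A matrix with permuted (but complete) rownames is re-ordered, not rejected.
#' @param patient_id,recording_id Identifier strings.
#' @param sampling_rate Samples per second (the study hardware used 2,000 Hz).
#' @param r_peak_index Optional integer sample index (first sample = 1) of the
#'   lead-II R-wave peak.
#' @param label Optional site code; one of the 21 leaf codes of
#'   [anatomy_sites()] for clinical data, or any code for synthetic data.
#' @return An object of class `ecg_recording`.
#' @export
ecg_recording <- function(signal, patient_id = "P0", recording_id = "R0",
                          sampling_rate = 2000, r_peak_index = NULL,
                          label = NULL) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    abort("`signal` must be a numeric matrix.")
  }
  if (!is.null(rownames(signal))) {
    missing <- setdiff(ECG_LEADS, rownames(signal))
    extra <- setdiff(rownames(signal), ECG_LEADS)
    if (length(missing) || length(extra)) {
      abort(paste0(
        "`signal` rownames must be the 12 standard leads; ",
        if (length(missing)) paste0("missing: ", paste(missing, collapse = ", "), ". "),
        if (length(extra)) paste0("unexpected: ", paste(extra, collapse = ", "), ".")
      ))
    }
    signal <- signal[ECG_LEADS, , drop = FALSE]
  }
  if (nrow(signal) != 12L) {
    abort(sprintf("`signal` must have exactly 12 rows (got %d).", nrow(signal)))
  }
  if (ncol(signal) < 1L) abort("`signal` must have at least one sample.")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be positive.")
  }
  if (!is.null(r_peak_index)) {
    r_peak_index <- as.integer(r_peak_index)
    if (is.na(r_peak_index) || r_peak_index < 1L || r_peak_index > ncol(signal)) {
      abort(sprintf(
        "`r_peak_index` must lie in [1, %d] (got %s).", ncol(signal),
        as.character(r_peak_index)
      ))
    }
  }
  rownames(signal) <- ECG_LEADS
  structure(
    list(
      patient_id = as.character(patient_id),
      recording_id = as.character(recording_id),
      sampling_rate = as.numeric(sampling_rate),
      lead_names = ECG_LEADS,
      signal = signal,
      r_peak_index = r_peak_index,
      label = if (is.null(label) || is.na(label)) NULL else as.character(label)
    ),
    class = "ecg_recording"
  )
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf(
    "<ecg_recording %s> patient %s, %d samples @ %g Hz, label %s, R peak %s\n",
    x$recording_id, x$patient_id, ncol(x$signal), x$sampling_rate,
    x$label %||% "<none>",
    if (is.null(x$r_peak_index)) "<none>" else x$r_peak_index
  ))
  invisible(x)
}

#' @export
dim.ecg_recording <- function(x) dim(x$signal)

parse_metadata_lines <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  out <- list()
  for (ln in meta_lines) {
    ln <- sub("^#\\s*", "", ln)
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    out[[key]] <- val
  }
  out
}

#' Read a single-beat recording from its CSV file
#'
#' The dialect is comma-separated with `.` decimals: optional `#`-prefixed
#' `key=value` metadata lines (patient_id, recording_id, sampling_rate,
#' r_peak_index, label), then a header row naming the 12 leads, then one row
#' per sample. Files with permuted lead columns are re-ordered on read.
#'
#' @param path Path to a recording CSV written by [write_recording_csv()].
#' @return An [ecg_recording()].
#' @export
read_recording_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File does not exist: %s", path))
  lines <- readLines(path, warn = FALSE)
  meta <- parse_metadata_lines(lines)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) abort(sprintf("No signal rows in %s", path))
  header <- strsplit(body[[1]], ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  missing <- setdiff(ECG_LEADS, header)
  extra <- setdiff(header, ECG_LEADS)
  if (length(missing) || length(extra)) {
    abort(paste0(
      "Lead columns do not match the 12 standard leads in ", path, ". ",
      if (length(missing)) paste0("Missing: ", paste(missing, collapse = ", "), ". "),
      if (length(extra)) paste0("Unexpected: ", paste(extra, collapse = ", "), ".")
    ))
  }
  cells <- strsplit(body[-1], ",", fixed = TRUE)
  n_col <- length(header)
  bad_len <- which(lengths(cells) != n_col)
  if (length(bad_len)) {
    abort(sprintf("Row %d of %s has %d fields; expected %d.",
                  bad_len[[1]], path, lengths(cells)[bad_len[[1]]], n_col))
  }
  vals <- suppressWarnings(as.numeric(unlist(cells, use.names = FALSE)))
  if (anyNA(vals)) {
    bad_row <- ceiling(which(is.na(vals))[[1]] / n_col)
    abort(sprintf("Non-numeric value in signal row %d of %s.", bad_row, path))
  }
  m <- matrix(vals, ncol = n_col, byrow = TRUE)
  colnames(m) <- header
  signal <- t(m[, ECG_LEADS, drop = FALSE])
  ecg_recording(
    signal,
    patient_id = meta$patient_id %||% "P0",
    recording_id = meta$recording_id %||% basename(path),
    sampling_rate = as.numeric(meta$sampling_rate %||% 2000),
    r_peak_index = if (!is.null(meta$r_peak_index)) as.integer(meta$r_peak_index),
    label = meta$label
  )
}

#' Write a recording to the package CSV dialect
#'
#' @param rec An [ecg_recording()].
#' @param path Destination file path.
#' @param digits Significant digits retained for voltages; the default (15)
#'   round-trips doubles through [read_recording_csv()] exactly.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path, digits = 15) {
  stopifnot(inherits(rec, "ecg_recording"))
  meta <- c(
    sprintf("# patient_id=%s", rec$patient_id),
    sprintf("# recording_id=%s", rec$recording_id),
    sprintf("# sampling_rate=%s", format(rec$sampling_rate, digits = 15)),
    if (!is.null(rec$r_peak_index)) sprintf("# r_peak_index=%d", rec$r_peak_index),
    if (!is.null(rec$label)) sprintf("# label=%s", rec$label)
  )
  m <- t(rec$signal)
  rows <- apply(format(m, digits = digits, trim = TRUE, scientific = TRUE), 1,
                paste, collapse = ",")
  out <- c(meta, paste(ECG_LEADS, collapse = ","), rows)
  tryCatch(
    writeLines(out, path),
    error = function(e) abort(sprintf("Cannot write %s: %s", path, conditionMessage(e)))
  )
  invisible(path)
}

#' Assemble recordings into a dataset tibble
#'
#' An `ecg_dataset` is a tibble with one row per recording and columns
#' `recording_id`, `patient_id`, `label`, `sampling_rate`, `r_peak_index` and a
#' `signal` list-column of 12 x T matrices, plus a `label_vocabulary`
#' attribute.
#'
#' @param recordings List of [ecg_recording()] objects.
#' @param label_vocabulary Permitted site codes; defaults to the 21 anatomical
#'   leaf codes when every label is one of them, otherwise to the sorted set of
#'   observed labels.
#' @param provenance Free-text metadata recorded on the dataset.
#' @return A tibble of class `ecg_dataset`.
#' @export
ecg_dataset <- function(recordings, label_vocabulary = NULL, provenance = "") {
  ids <- map_chr(recordings, "recording_id")
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate recording_id: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  labels <- map_chr(recordings, function(r) r$label %||% NA_character_)
  if (is.null(label_vocabulary)) {
    seen <- sort(unique(labels[!is.na(labels)]))
    label_vocabulary <- if (all(seen %in% anatomy_sites())) anatomy_sites() else seen
  }
  bad <- setdiff(labels[!is.na(labels)], label_vocabulary)
  if (length(bad)) {
    abort(paste0("Labels outside the vocabulary: ", paste(bad, collapse = ", ")))
  }
  ds <- tibble(
    recording_id = ids,
    patient_id = map_chr(recordings, "patient_id"),
    label = labels,
    sampling_rate = map_dbl(recordings, "sampling_rate"),
    r_peak_index = map_int(recordings, function(r) r$r_peak_index %||% NA_integer_),
    signal = map(recordings, "signal")
  )
  new_ecg_dataset(ds, label_vocabulary, provenance)
}

new_ecg_dataset <- function(tbl, label_vocabulary, provenance = "") {
  structure(tbl,
            label_vocabulary = label_vocabulary,
            provenance = provenance,
            class = c("ecg_dataset", class(tibble())))
}

#' @rdname ecg_dataset
#' @param ds An `ecg_dataset`.
#' @export
label_vocabulary <- function(ds) {
  attr(ds, "label_vocabulary") %||% sort(unique(na.omit(ds$label)))
}

dataset_recording <- function(ds, i) {
  ecg_recording(
    ds$signal[[i]],
    patient_id = ds$patient_id[[i]],
    recording_id = ds$recording_id[[i]],
    sampling_rate = ds$sampling_rate[[i]],
    r_peak_index = if (!is.na(ds$r_peak_index[[i]])) ds$r_peak_index[[i]],
    label = if (!is.na(ds$label[[i]])) ds$label[[i]]
  )
}

#' Load a dataset from a manifest of recording files
#'
#' The manifest is a CSV with columns `path` (relative paths resolve against
#' the manifest's directory), `patient_id`, `label`, and optionally
#' `r_peak_index`; non-path columns, when present, override the metadata
#' stored in each recording file.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param label_vocabulary Permitted site codes. Default `NULL`: the 21
#'   anatomical leaf codes when every manifest label is one of them; a fully
#'   non-clinical roster (synthetic class codes) is accepted as its own
#'   vocabulary; mixing clinical and unknown codes is an error naming the
#'   stray labels.
#' @return An [ecg_dataset()].
#' @export
load_dataset <- function(manifest_path, label_vocabulary = NULL) {
  man <- readr::read_csv(manifest_path, show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(man) == 0) {
    return(new_ecg_dataset(
      tibble(recording_id = character(), patient_id = character(),
             label = character(), sampling_rate = numeric(),
             r_peak_index = integer(), signal = list()),
      label_vocabulary %||% anatomy_sites(), provenance = manifest_path
    ))
  }
  if (!"path" %in% names(man)) abort("Manifest must have a `path` column.")
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                  file.path(dirname(manifest_path), man$path))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("Missing recording files:\n  ", paste(missing, collapse = "\n  ")))
  }
  if (is.null(label_vocabulary) && "label" %in% names(man)) {
    seen <- unique(na.omit(as.character(man$label)))
    clinical <- seen %in% anatomy_sites()
    if (any(clinical) && !all(clinical)) {
      # a mixed roster is a labeling mistake, not a synthetic vocabulary
      abort(paste0("Labels outside the site vocabulary: ",
                   paste(seen[!clinical], collapse = ", ")))
    }
    label_vocabulary <- if (all(clinical)) anatomy_sites() else sort(seen)
  }
  recs <- map(seq_along(paths), function(i) {
    r <- read_recording_csv(paths[[i]])
    if ("patient_id" %in% names(man) && !is.na(man$patient_id[[i]])) {
      r$patient_id <- as.character(man$patient_id[[i]])
    }
    if ("label" %in% names(man) && !is.na(man$label[[i]])) {
      r$label <- as.character(man$label[[i]])
    }
    if ("r_peak_index" %in% names(man) && !is.na(man$r_peak_index[[i]])) {
      r$r_peak_index <- as.integer(man$r_peak_index[[i]])
      if (r$r_peak_index < 1L || r$r_peak_index > ncol(r$signal)) {
        abort(sprintf("r_peak_index override out of range for %s", r$recording_id))
      }
    }
    r
  })
  ecg_dataset(recs, label_vocabulary = label_vocabulary,
              provenance = manifest_path)
}

#' Write every recording of a dataset plus a manifest
#'
#' @param ds An [ecg_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(ds))
  for (i in seq_len(nrow(ds))) {
    paths[[i]] <- paste0(ds$recording_id[[i]], ".csv")
    write_recording_csv(dataset_recording(ds, i), file.path(dir, paths[[i]]))
  }
  man <- tibble(path = paths, patient_id = ds$patient_id, label = ds$label,
                r_peak_index = ds$r_peak_index)
  manifest <- file.path(dir, "manifest.csv")
  readr::write_csv(man, manifest, progress = FALSE)
  invisible(manifest)
}
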