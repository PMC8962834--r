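# Four-level anatomical taxonomy of idiopathic ventricular arrhythmia origin
# sites. Levels: region (3) -> tract (5) -> group (18) -> leaf (21). A site
# that does not subdivide is carried through the lower levels unchanged, so
# intermediate "group" nodes exist only where a scheme-3 class splits into
# several scheme-4 sites (Left Septal, Papillary Muscle, RVOT septal). The
# epicardium of the LV summit stands alone at every level.
anatomy_table <- function() {
  tribble(
    ~leaf,                      ~group,                ~tract,                   ~region,
    "LCC",                      "LCC",                 "LV Outflow tract",       "LV endocardium",
    "RCC",                      "RCC",                 "LV Outflow tract",       "LV endocardium",
    "AMC",                      "AMC",                 "LV Outflow tract",       "LV endocardium",
    "Summit",                   "Summit",              "LV Outflow tract",       "LV endocardium",
    "LCC-RCC commissure",       "LCC-RCC commissure",  "LV Outflow tract",       "LV endocardium",
    "Left His bundle",          "Left His bundle",     "LV Non-Outflow tract",   "LV endocardium",
    "MV",                       "MV",                  "LV Non-Outflow tract",   "LV endocardium",
    "LAF",                      "Left Septal",         "LV Non-Outflow tract",   "LV endocardium",
    "LPF",                      "Left Septal",         "LV Non-Outflow tract",   "LV endocardium",
    "LAPM",                     "Papillary Muscle",    "LV Non-Outflow tract",   "LV endocardium",
    "LPPM",                     "Papillary Muscle",    "LV Non-Outflow tract",   "LV endocardium",
    "AC",                       "AC",                  "RV Outflow tract",       "RV endocardium",
    "LC",                       "LC",                  "RV Outflow tract",       "RV endocardium",
    "RC",                       "RC",                  "RV Outflow tract",       "RV endocardium",
    "RVOT posterior septal",    "RVOT septal",         "RV Outflow tract",       "RV endocardium",
    "RVOT anterior septal",     "RVOT septal",         "RV Outflow tract",       "RV endocardium",
    "RVOT free wall",           "RVOT free wall",      "RV Outflow tract",       "RV endocardium",
    "Right His bundle",         "Right His bundle",    "RV Non-Outflow tract",   "RV endocardium",
    "TV",                       "TV",                  "RV Non-Outflow tract",   "RV endocardium",
    "RAPM",                     "RAPM",                "RV Non-Outflow tract",   "RV endocardium",
    "Epicardium of LV summit",  "Epicardium of LV summit", "Epicardium of LV summit", "Epicardium of LV summit"
  )
}

#' The 21 anatomical leaf site codes
#'
#' Ordered as in the taxonomy: left ventricular outflow tract sites, left
#' non-outflow sites, right outflow sites, right non-outflow sites, and the
#' epicardial LV summit.
#'
#' @return Character vector of length 21.
#' @export
anatomy_sites <- function() anatomy_table()$leaf

#' Build the anatomical hierarchy as a node table
#'
#' Returns one row per node with columns `code`, `level` (`region`, `tract`,
#' `group`, or `leaf`) and `parent` (`NA` for the three roots). A node whose
#' code repeats at a deeper level (a site that never subdivides) appears once,
#' at its shallowest level; nodes with no children are exactly the 21 leaf
#' sites.
#'
#' @return A tibble of nodes.
#' @export
build_hierarchy <- function() {
  tab <- anatomy_table()
  regions <- tibble(code = unique(tab$region), level = "region", parent = NA_character_)
  tracts <- tab |>
    filter(.data$tract != .data$region) |>
    distinct(code = .data$tract, parent = .data$region) |>
    mutate(level = "tract", .after = "code")
  groups <- tab |>
    filter(.data$group != .data$tract) |>
    distinct(code = .data$group, parent = .data$tract) |>
    mutate(level = "group", .after = "code")
  leaves <- tab |>
    filter(.data$leaf != .data$group) |>
    distinct(code = .data$leaf, parent = .data$group) |>
    mutate(level = "leaf", .after = "code")
  bind_rows(regions, tracts, groups, leaves)
}

#' Parent code of a hierarchy node
#'
#' @param code A node code present in [build_hierarchy()].
#' @param hierarchy Node table; defaults to [build_hierarchy()].
#' @return The parent code, or `NA` for a root.
#' @export
anatomy_parent <- function(code, hierarchy = build_hierarchy()) {
  i <- match(code, hierarchy$code)
  if (anyNA(i)) abort(paste0("Unknown node code: ",
                             paste(code[is.na(i)], collapse = ", ")))
  hierarchy$parent[i]
}

#' A label-collapse map for one classification scheme
#'
#' Scheme 1 collapses the 21 leaf sites to the 3 general regions, scheme 2 to
#' the 5 outflow/non-outflow tracts, scheme 3 to 18 anatomical groups, and
#' scheme 4 is the identity on the 21 sites.
#'
#' @param scheme_id Integer 1-4.
#' @return A list with `scheme_id`, `classes` (ordered class codes) and
#'   `collapse` (named character vector, leaf code -> class code), of class
#'   `scheme_map`.
#' @export
scheme_map <- function(scheme_id) {
  if (!scheme_id %in% 1:4) abort("`scheme_id` must be 1, 2, 3 or 4.")
  tab <- anatomy_table()
  col <- c("region", "tract", "group", "leaf")[[scheme_id]]
  collapse <- setNames(tab[[col]], tab$leaf)
  structure(
    list(scheme_id = as.integer(scheme_id),
         classes = unique(unname(collapse)),
         collapse = collapse),
    class = "scheme_map"
  )
}

#' @export
print.scheme_map <- function(x, ...) {
  cat(sprintf("<scheme_map %d> %d classes\n", x$scheme_id, length(x$classes)))
  invisible(x)
}

#' Collapse leaf labels to a scheme's classes
#'
#' @param labels Character vector of leaf site codes.
#' @param scheme A [scheme_map()] or a scheme id 1-4.
#' @return Character vector of class codes, same length as `labels`.
#' @export
collapse_labels <- function(labels, scheme) {
  if (!inherits(scheme, "scheme_map")) scheme <- scheme_map(scheme)
  out <- scheme$collapse[labels]
  if (anyNA(out)) {
    abort(paste0("Unknown leaf codes: ",
                 paste(unique(labels[is.na(out)]), collapse = ", ")))
  }
  unname(out)
}

#' Partial-credit weight matrix for adjusted accuracy
#'
#' Misclassifications between sites sharing the same immediate parent in the
#' anatomical hierarchy (e.g. the two RVOT septal sub-sites) often lead to the
#' same ablation approach, so they earn partial credit. The published scoring
#' matrix is not available; this sibling-based construction is the package's
#' documented stand-in, and any externally supplied square matrix (e.g. read
#' from CSV with [read_credit_matrix()]) can be used in its place.
#'
#' @param scheme A [scheme_map()] or scheme id; adjusted accuracy is defined
#'   for schemes 3 and 4.
#' @param sibling_weight Credit in `[0, 1]` for predicting a sibling of the
#'   true site (default 0.5).
#' @return A square numeric matrix with unit diagonal, class codes as
#'   dimnames, of class `credit_matrix`.
#' @export
partial_credit_matrix <- function(scheme, sibling_weight = 0.5) {
  if (!inherits(scheme, "scheme_map")) scheme <- scheme_map(scheme)
  if (!scheme$scheme_id %in% c(3L, 4L)) {
    abort("Partial credit is defined for schemes 3 and 4 only.")
  }
  if (!is.numeric(sibling_weight) || sibling_weight < 0 || sibling_weight > 1) {
    abort("`sibling_weight` must lie in [0, 1].")
  }
  hier <- build_hierarchy()
  classes <- scheme$classes
  parent <- vapply(classes, function(cl) {
    p <- hier$parent[match(cl, hier$code)]
    if (is.na(p)) cl else p  # a root (the epicardial summit) is its own block
  }, character(1))
  w <- outer(parent, parent, "==") * sibling_weight
  diag(w) <- 1
  dimnames(w) <- list(true = classes, predicted = classes)
  structure(w, class = c("credit_matrix", class(w)))
}

#' Read / write a partial-credit matrix as CSV
#'
#' The CSV has class codes as both the first column and the header, so a
#' published scoring matrix can be dropped in verbatim.
#'
#' @param path CSV path.
#' @return For `read_credit_matrix`, a `credit_matrix`; for
#'   `write_credit_matrix`, `path` invisibly.
#' @export
read_credit_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  classes <- df[[1]]
  w <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(w), as.character(classes))) {
    abort("Credit matrix CSV must have identical row and column class codes.")
  }
  dimnames(w) <- list(true = classes, predicted = classes)
  if (any(abs(diag(w) - 1) > 1e-12)) abort("Credit matrix diagonal must be 1.")
  structure(w, class = c("credit_matrix", class(w)))
}

#' @rdname read_credit_matrix
#' @param credit A `credit_matrix`.
#' @export
write_credit_matrix <- function(credit, path) {
  df <- as.data.frame(unclass(credit))
  df <- cbind(class = rownames(credit), df)
  readr::write_csv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Serialize the hierarchy and scheme maps to JSON
#'
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
write_anatomy_json <- function(path) {
  doc <- list(
    nodes = build_hierarchy(),
    schemes = map(1:4, function(s) {
      m <- scheme_map(s)
      list(scheme_id = m$scheme_id, classes = m$classes,
           collapse = as.list(m$collapse))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
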