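#' Pool marker sets into a nonredundant catalog
#'
#' Accessions are normalized (case-folded, trailing version suffixes such as
#' `.1` stripped) and merged through an optional alias map (e.g. arCOG to
#' TIGRFAM cross-references). Each catalog entry records every source set
#' that contributed it and every raw accession string that mapped to it, so
#' the "nonredundant" merge stays auditable.
#'
#' @param source_sets Named list, one character vector of accessions per
#'   published marker set.
#' @param alias_map Optional named character vector mapping accession ->
#'   canonical accession (applied after normalization; chains are followed).
#' @param max_alias_depth Alias chains longer than this raise an error
#'   (cycle suspicion); default 10.
#' @return An object of class `marker_catalog`: list with `entries` (data
#'   frame `marker_id`, list-columns `sources` and `aliases`) and the input
#'   `source_sets`.
#' @examples
#' cat <- dereplicate(list(S1 = c("a", "b"), S2 = c("b", "c")))
#' nrow(cat$entries)  # 3
#' @export
dereplicate <- function(source_sets, alias_map = NULL, max_alias_depth = 10L) {
  stopifnot(is.list(source_sets), length(source_sets) >= 1L,
            !is.null(names(source_sets)), all(nzchar(names(source_sets))))
  if (any(vapply(source_sets, length, integer(1L)) == 0L))
    stop("empty source set")
  amap <- NULL
  if (!is.null(alias_map)) {
    amap <- stats::setNames(normalize_accession(unname(alias_map)),
                            normalize_accession(names(alias_map)))
  }
  canon <- function(acc) {
    x <- normalize_accession(acc)
    depth <- 0L
    while (!is.null(amap) && x %in% names(amap)) {
      x <- amap[[x]]
      depth <- depth + 1L
      if (depth > max_alias_depth)
        stop("alias chain longer than ", max_alias_depth,
             " starting from '", acc, "' (cycle?)")
    }
    x
  }
  entries <- list()
  for (set_name in names(source_sets)) {
    for (acc in source_sets[[set_name]]) {
      id <- canon(acc)
      if (is.null(entries[[id]]))
        entries[[id]] <- list(sources = character(), aliases = character())
      entries[[id]]$sources <- union(entries[[id]]$sources, set_name)
      entries[[id]]$aliases <- union(entries[[id]]$aliases, acc)
    }
  }
  ids <- names(entries)
  df <- data.frame(marker_id = ids, stringsAsFactors = FALSE)
  df$sources <- lapply(entries, `[[`, "sources")
  df$aliases <- lapply(entries, `[[`, "aliases")
  rownames(df) <- NULL
  structure(list(entries = df, source_sets = source_sets),
            class = "marker_catalog")
}

#' Normalize a marker accession
#'
#' Case-folds, trims whitespace and strips a trailing numeric version suffix
#' (`A1.2` -> `a1`).
#'
#' @param x Character vector of accessions.
#' @return Normalized character vector.
#' @export
normalize_accession <- function(x) {
  sub("\\.\\d+$", "", tolower(trimws(x)))
}

#' @export
print.marker_catalog <- function(x, ...) {
  cat("Marker catalog:", nrow(x$entries), "nonredundant markers from",
      length(x$source_sets), "source sets\n")
  invisible(x)
}

#' Subset a catalog to a list of marker ids
#'
#' Order-preserving; provenance retained. Unknown ids are an error.
#'
#' @param cat A `marker_catalog`.
#' @param ids Marker ids (normalized accessions) to keep.
#' @return A `marker_catalog` restricted to `ids`.
#' @export
subset_catalog <- function(cat, ids) {
  stopifnot(inherits(cat, "marker_catalog"))
  ids <- normalize_accession(ids)
  missing <- setdiff(ids, cat$entries$marker_id)
  if (length(missing))
    stop("unknown marker ids: ", paste(missing, collapse = ", "))
  keep <- cat$entries[match(ids, cat$entries$marker_id), , drop = FALSE]
  rownames(keep) <- NULL
  structure(list(entries = keep, source_sets = cat$source_sets),
            class = "marker_catalog")
}

#' Count catalog entries contributed by one source set
#'
#' @param cat A `marker_catalog`.
#' @param source Source set name.
#' @return Number of entries whose provenance includes `source`.
#' @export
count_by_source <- function(cat, source) {
  stopifnot(inherits(cat, "marker_catalog"))
  if (!source %in% names(cat$source_sets))
    stop("unknown source set: ", source)
  sum(vapply(cat$entries$sources, function(s) source %in% s, logical(1L)))
}

#' Keep only single-copy (genome, marker) hits
#'
#' Genomes with more than one copy of a marker are excluded from that
#' marker's alignment under single-copy orthodoxy.
#'
#' @param hits Hit-table data frame (`genome_id`, `family_id`, `n_copies`).
#' @return The rows with `n_copies == 1`.
#' @export
filter_single_copy <- function(hits) {
  hits[hits$n_copies == 1L, , drop = FALSE]
}

#' Read named marker sets from a TSV
#'
#' Expects a `set_name` column plus either `accession` (raw source sets) or
#' `marker_id` (canonical subset lists).
#'
#' @param file Path to the TSV.
#' @return Named list of accession vectors.
#' @export
read_marker_sets <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  acc_col <- intersect(c("accession", "marker_id"), names(df))
  if (!"set_name" %in% names(df) || length(acc_col) == 0L)
    stop("marker set table must have columns set_name and accession/marker_id")
  split(df[[acc_col[1L]]], df$set_name)
}

#' Read an alias map from a TSV
#'
#' Expects columns `accession` and `canonical`.
#'
#' @param file Path to the TSV.
#' @return Named character vector accession -> canonical.
#' @export
read_alias_map <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("accession", "canonical") %in% names(df)))
    stop("alias table must have columns accession, canonical")
  stats::setNames(df$canonical, df$accession)
}

#' Write a marker catalog as TSV
#'
#' List-columns are `;`-joined.
#'
#' @param cat A `marker_catalog`.
#' @param file Output path.
#' @export
write_catalog <- function(cat, file) {
  stopifnot(inherits(cat, "marker_catalog"))
  df <- data.frame(
    marker_id = cat$entries$marker_id,
    sources = vapply(cat$entries$sources, paste, character(1L), collapse = ";"),
    aliases = vapply(cat$entries$aliases, paste, character(1L), collapse = ";"))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
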