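#' Classify a marker tree's placement tendency for the focal clade
#'
#' The tree is rooted on its outgroup leaves when they are present and form
#' a clade in the unrooted tree, and by midpoint otherwise. If fewer than
#' two focal genomes are present, or the focal clade is not monophyletic on
#' the rooted tree, the marker is `UNRESOLVED` (conservative: a broken focal
#' clade has no single placement). Otherwise the focal clade's sister
#' subtree is located and its leaves tallied by group membership: clades
#' named in `groups_a` versus `groups_b`, with outgroup leaves ignored.
#' The label is `WITH_A` if the A fraction exceeds `majority`, `WITH_B` if
#' the B fraction does, else `UNRESOLVED` (so an exactly 50/50 sister is
#' `UNRESOLVED` at the default strict majority of 0.5).
#'
#' @param tree A `phylo` gene tree.
#' @param taxonomy Taxonomy data frame assigning every leaf to a clade/role.
#' @param groups_a Clade names of the A (TACK-like) series.
#' @param groups_b Clade names of the B (Asgard-like) series.
#' @param majority Strict majority threshold in \[0.5, 1), default 0.5.
#' @return One-row data frame: `marker_id`, `label`, `focal_monophyletic`,
#'   `n_sister_A`, `n_sister_B`.
#' @export
classify_tendency <- function(tree, taxonomy, groups_a, groups_b,
                              majority = 0.5) {
  taxonomy <- validate_taxonomy(taxonomy)
  marker_id <- attr(tree, "marker_id")
  if (is.null(marker_id)) marker_id <- NA_character_
  unknown <- setdiff(tree$tip.label, taxonomy$genome_id)
  if (length(unknown))
    stop("leaves missing from taxonomy: ", paste(unknown, collapse = ", "))
  clade_of <- stats::setNames(taxonomy$clade, taxonomy$genome_id)
  role_of <- stats::setNames(taxonomy$role, taxonomy$genome_id)
  focal_all <- taxonomy$genome_id[taxonomy$role == "focal"]
  if (length(focal_all) == 0L) stop("taxonomy defines no focal genomes")
  row <- function(label, mono, nA = NA_integer_, nB = NA_integer_)
    data.frame(marker_id = marker_id, label = label,
               focal_monophyletic = mono, n_sister_A = nA, n_sister_B = nB,
               stringsAsFactors = FALSE)

  focal <- intersect(tree$tip.label, focal_all)
  if (length(focal) < 2L) return(row("UNRESOLVED", NA))
  rooted <- .root_tree(tree, tree$tip.label[role_of[tree$tip.label] == "outgroup"])
  mrca <- ape::getMRCA(rooted, focal)
  desc <- phangorn::Descendants(rooted, mrca, type = "tips")[[1L]]
  if (!setequal(rooted$tip.label[desc], focal)) return(row("UNRESOLVED", FALSE))
  parent <- rooted$edge[rooted$edge[, 2L] == mrca, 1L]
  if (length(parent) == 0L) return(row("UNRESOLVED", TRUE, 0L, 0L))
  sibs <- setdiff(rooted$edge[rooted$edge[, 1L] == parent, 2L], mrca)
  sister <- unlist(lapply(phangorn::Descendants(rooted, sibs, type = "tips"),
                          function(i) rooted$tip.label[i]))
  nA <- sum(clade_of[sister] %in% groups_a)
  nB <- sum(clade_of[sister] %in% groups_b)
  if (nA + nB == 0L) return(row("UNRESOLVED", TRUE, nA, nB))
  fracA <- nA / (nA + nB)
  label <- if (fracA > majority) "WITH_A"
           else if (1 - fracA > majority) "WITH_B"
           else "UNRESOLVED"
  row(label, TRUE, nA, nB)
}

# outgroup rooting when the outgroup forms a clade of the unrooted tree,
# midpoint otherwise
.root_tree <- function(tree, outgroup_tips) {
  og <- intersect(outgroup_tips, tree$tip.label)
  if (length(og) > 0L && length(og) < ape::Ntip(tree)) {
    ok <- length(og) == 1L ||
      is_monophyletic(tree, clade_definition("og", og)) == "monophyletic"
    if (ok)
      return(ape::root(tree, outgroup = og, resolve.root = TRUE))
  }
  phangorn::midpoint(tree)
}

#' Classify a list of marker trees
#'
#' @inheritParams classify_tendency
#' @param trees Named list of `phylo` gene trees.
#' @return A `tendency_table` data frame, one row per marker.
#' @export
classify_tendencies <- function(trees, taxonomy, groups_a, groups_b,
                                majority = 0.5) {
  stopifnot(!is.null(names(trees)))
  rows <- lapply(names(trees), function(id) {
    tr <- trees[[id]]
    attr(tr, "marker_id") <- id
    classify_tendency(tr, taxonomy, groups_a, groups_b, majority)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tendency_table", class(out))
  out
}

# half-up decimal rounding; matches the reporting precision of percentages
round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Venn-partition marker sets with per-region tendency percentages
#'
#' Every marker in the union is assigned to exactly one region of the k-set
#' Venn partition, keyed by its exact membership signature. For each
#' nonempty region the percentage of markers labelled `WITH_B` is reported
#' to one decimal place (half-up).
#'
#' @param sets Named list (2-4 sets) of marker-id vectors.
#' @param tendencies A `tendency_table` covering every marker in the union.
#' @return An object of class `venn_report`: data frame with `region`
#'   (signature such as `"setA&setB"`), `n`, `n_with_B`, `pct_with_B` and a
#'   list-column `marker_ids`.
#' @export
venn_overlap <- function(sets, tendencies) {
  stopifnot(is.list(sets), length(sets) >= 2L, length(sets) <= 4L,
            !is.null(names(sets)))
  sets <- lapply(sets, unique)
  all_ids <- sort(unique(unlist(sets)))
  missing <- setdiff(all_ids, tendencies$marker_id)
  if (length(missing))
    stop("markers missing from tendency table: ",
         paste(missing, collapse = ", "))
  label_of <- stats::setNames(tendencies$label, tendencies$marker_id)
  sig <- vapply(all_ids, function(id) {
    inset <- vapply(sets, function(s) id %in% s, logical(1L))
    paste(names(sets)[inset], collapse = "&")
  }, character(1L))
  regions <- split(all_ids, sig)
  df <- data.frame(region = names(regions),
                   n = vapply(regions, length, integer(1L)),
                   n_with_B = vapply(regions, function(ids)
                     sum(label_of[ids] == "WITH_B"), integer(1L)),
                   stringsAsFactors = FALSE)
  df$pct_with_B <- round_half_up(100 * df$n_with_B / df$n, 1L)
  df$marker_ids <- regions
  rownames(df) <- NULL
  class(df) <- c("venn_report", class(df))
  df
}

#' Write a tendency table as TSV
#' @param tendencies A `tendency_table`.
#' @param file Output path.
#' @export
write_tendency_table <- function(tendencies, file) {
  utils::write.table(as.data.frame(tendencies), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a Venn report as TSV (marker ids `;`-joined)
#' @param report A `venn_report`.
#' @param file Output path.
#' @export
write_venn_report <- function(report, file) {
  df <- as.data.frame(report[c("region", "n", "n_with_B", "pct_with_B")])
  df$marker_ids <- vapply(report$marker_ids, paste, character(1L), collapse = ";")
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
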