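#' Leaf-set bipartitions of a tree
#'
#' Returns, for every edge, the set of tip labels on the child side. Read
#' unrooted, each set (together with its complement) is the split induced by
#' removing that edge.
#'
#' @param tree A `phylo` object.
#' @return A list of character vectors, one per edge of `tree`.
#' @export
tree_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  tips_below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tips_below[[i]] <- tree$tip.label[i]
  # postorder: children are filled before their parent is visited
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(ord))) {
    par <- ord[k, 1L]; child <- ord[k, 2L]
    tips_below[[par]] <- c(tips_below[[par]], tips_below[[child]])
  }
  lapply(tree$edge[, 2L], function(ch) tips_below[[ch]])
}

#' Define a named lineage for monophyly testing
#'
#' @param name Clade name.
#' @param members Character vector of genome ids.
#' @param min_present Minimum number of members that must be present in a tree
#'   for the clade to be evaluable (default 2: a singleton is vacuously
#'   monophyletic and would inflate scores of sparse markers).
#' @return An object of class `clade_definition`.
#' @export
clade_definition <- function(name, members, min_present = 2L) {
  stopifnot(length(members) >= 1L, min_present >= 2L)
  structure(list(name = name, members = unique(as.character(members)),
                 min_present = as.integer(min_present)),
            class = "clade_definition")
}

#' Derive clade definitions from a taxonomy map
#'
#' One definition per clade name among genomes with the given roles.
#'
#' @param taxonomy Taxonomy data frame (`genome_id`, `clade`, `role`).
#' @param roles Roles to include, default all three.
#' @param min_present Passed to [clade_definition()].
#' @return Named list of `clade_definition` objects.
#' @export
clades_from_taxonomy <- function(taxonomy,
                                 roles = c("ingroup", "outgroup", "focal"),
                                 min_present = 2L) {
  taxonomy <- validate_taxonomy(taxonomy)
  taxonomy <- taxonomy[taxonomy$role %in% roles, , drop = FALSE]
  out <- lapply(split(taxonomy$genome_id, taxonomy$clade),
                function(m) NULL)
  for (cl in names(out))
    out[[cl]] <- clade_definition(cl, taxonomy$genome_id[taxonomy$clade == cl],
                                  min_present = min_present)
  out
}

#' Test whether a clade is monophyletic on an unrooted tree
#'
#' The clade is restricted to its members present as leaves. Fewer than
#' `min_present` present members make the clade `not_evaluable`. Otherwise it
#' is `monophyletic` iff some edge of the unrooted tree induces a bipartition
#' one side of which is exactly the present members, and `violated` otherwise.
#' The verdict does not depend on where the tree is rooted or on leaf order.
#'
#' @param tree A `phylo` object (treated as unrooted).
#' @param clade A [clade_definition()].
#' @return One of `"monophyletic"`, `"violated"`, `"not_evaluable"`.
#' @export
is_monophyletic <- function(tree, clade) {
  stopifnot(inherits(clade, "clade_definition"))
  present <- intersect(clade$members, tree$tip.label)
  if (length(present) < clade$min_present) return("not_evaluable")
  if (length(present) == ape::Ntip(tree)) return("monophyletic")
  target <- sort(present)
  all_tips <- tree$tip.label
  for (side in tree_bipartitions(tree)) {
    if (length(side) == length(target) && identical(sort(side), target))
      return("monophyletic")
    other <- setdiff(all_tips, side)
    if (length(other) == length(target) && identical(sort(other), target))
      return("monophyletic")
  }
  "violated"
}

#' Score one marker tree against a set of lineage definitions
#'
#' The congruence score is the fraction of evaluable clades found
#' monophyletic. Markers with no evaluable clade have an undefined score
#' (`NA`) and are excluded from ranking.
#'
#' @param tree A `phylo` gene tree.
#' @param clades List of [clade_definition()] objects (at least one).
#' @param marker_id Marker identifier; defaults to the tree's `marker_id`
#'   attribute.
#' @return An object of class `congruence_score`: a list with `marker_id`,
#'   `n_evaluable`, `n_monophyletic`, `score` and the per-clade verdicts.
#' @export
score_marker <- function(tree, clades, marker_id = attr(tree, "marker_id")) {
  stopifnot(length(clades) >= 1L)
  if (is.null(marker_id)) marker_id <- NA_character_
  verdicts <- vapply(clades, function(cl) is_monophyletic(tree, cl), character(1L))
  names(verdicts) <- vapply(clades, `[[`, character(1L), "name")
  n_eval <- sum(verdicts != "not_evaluable")
  n_mono <- sum(verdicts == "monophyletic")
  structure(list(marker_id = marker_id,
                 n_evaluable = n_eval,
                 n_monophyletic = n_mono,
                 score = if (n_eval > 0L) n_mono / n_eval else NA_real_,
                 per_clade = verdicts),
            class = "congruence_score")
}

#' Score a list of marker trees
#'
#' @param trees Named list of `phylo` gene trees (names = marker ids).
#' @param clades List of [clade_definition()] objects.
#' @return Data frame with columns `marker_id`, `n_evaluable`,
#'   `n_monophyletic`, `score`, plus one verdict column per clade.
#' @export
score_markers <- function(trees, clades) {
  stopifnot(length(trees) >= 1L, !is.null(names(trees)))
  rows <- lapply(names(trees), function(id) {
    s <- score_marker(trees[[id]], clades, marker_id = id)
    cbind(data.frame(marker_id = id, n_evaluable = s$n_evaluable,
                     n_monophyletic = s$n_monophyletic, score = s$score,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(s$per_clade), stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Rank markers by congruence score and select a top fraction
#'
#' Markers are ordered by score (descending), then number of evaluable
#' clades (descending), then marker id (ascending), so the output is
#' deterministic regardless of input order. Markers with undefined scores
#' are dropped before ranking. `k = round(top_fraction * n)` (half away
#' from zero) unless `k_override` is given; the override exists because
#' published set sizes need not equal the exact fraction.
#'
#' @param scores Data frame as from [score_markers()] (needs `marker_id`,
#'   `n_evaluable`, `score`).
#' @param top_fraction Fraction in (0, 1].
#' @param k_override Optional explicit selection size.
#' @return Object of class `ranked_selection`: list with `ranking` (all
#'   ranked ids, best first), `top_fraction`, `k` and `selected`.
#' @export
rank_and_select <- function(scores, top_fraction, k_override = NULL) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1L,
            top_fraction > 0, top_fraction <= 1)
  sc <- scores[!is.na(scores$score), , drop = FALSE]
  if (nrow(sc) == 0L) stop("no marker has an evaluable score")
  ord <- order(-sc$score, -sc$n_evaluable, sc$marker_id)
  ranking <- sc$marker_id[ord]
  n <- length(ranking)
  k <- if (!is.null(k_override)) as.integer(k_override)
       else as.integer(floor(top_fraction * n + 0.5))
  if (k > n) stop("k_override (", k, ") exceeds number of ranked markers (", n, ")")
  k <- max(k, 0L)
  structure(list(ranking = ranking, top_fraction = top_fraction, k = k,
                 selected = ranking[seq_len(k)]),
            class = "ranked_selection")
}

#' @export
print.ranked_selection <- function(x, ...) {
  cat("Ranked selection: top", format(x$top_fraction), "of", length(x$ranking),
      "markers ->", x$k, "selected\n")
  utils::head(x$selected, 10L) |> paste(collapse = ", ") |> cat("\n")
  invisible(x)
}

#' Write a congruence score table as TSV
#' @param scores Data frame from [score_markers()].
#' @param file Output path.
#' @export
write_score_table <- function(scores, file) {
  utils::write.table(scores, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
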