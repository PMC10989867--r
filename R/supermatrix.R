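#' Concatenate per-marker alignments with a column-occupancy filter
#'
#' Genomes lacking a marker receive all-gap rows before filtering (standard
#' supermatrix practice). A column is "present" in a taxon iff the residue
#' is neither `-` nor `?` (`X` counts as present: it is a residue of unknown
#' identity). A column is kept iff it is present in at least
#' `ceiling(threshold * n_taxa)` taxa. Partitions record the post-filter
#' interval of each marker in 0-based half-open coordinates (possibly
#' empty); [write_partitions()] emits the 1-based inclusive form.
#'
#' @param alignments Named list of character matrices (names = marker ids),
#'   as from [read_fasta_alignment()] or [evolve_alignment()].
#' @param taxa Ordered genome ids forming the supermatrix rows.
#' @param threshold Occupancy threshold in (0, 1], default 0.6.
#' @return An object of class `supermatrix`: list with `matrix` (taxa x
#'   kept columns), `partitions` (data frame `marker_id`, `start`, `end`,
#'   `width`, `n_dropped`), `taxa`, `occupancy_threshold`,
#'   `n_columns_kept`, `n_columns_dropped`.
#' @export
concatenate <- function(alignments, taxa, threshold = 0.6) {
  stopifnot(is.list(alignments), length(alignments) >= 1L,
            !is.null(names(alignments)), length(taxa) >= 1L,
            threshold > 0, threshold <= 1)
  need <- as.integer(ceiling(threshold * length(taxa)))
  blocks <- vector("list", length(alignments))
  parts <- data.frame(marker_id = names(alignments), start = NA_integer_,
                      end = NA_integer_, width = NA_integer_,
                      n_dropped = NA_integer_, stringsAsFactors = FALSE)
  offset <- 0L
  for (i in seq_along(alignments)) {
    aln <- alignments[[i]]
    stopifnot(is.matrix(aln), !is.null(rownames(aln)))
    if (anyDuplicated(rownames(aln)))
      stop("duplicate genome in alignment ", names(alignments)[i])
    full <- matrix("-", nrow = length(taxa), ncol = ncol(aln),
                   dimnames = list(taxa, NULL))
    shared <- intersect(taxa, rownames(aln))
    full[shared, ] <- aln[shared, , drop = FALSE]
    present <- full != "-" & full != "?"
    keep <- colSums(present) >= need
    blocks[[i]] <- full[, keep, drop = FALSE]
    parts$start[i] <- offset
    parts$end[i] <- offset + sum(keep)
    parts$width[i] <- sum(keep)
    parts$n_dropped[i] <- sum(!keep)
    offset <- offset + sum(keep)
  }
  structure(list(matrix = do.call(cbind, blocks), taxa = taxa,
                 partitions = parts, occupancy_threshold = threshold,
                 n_columns_kept = offset,
                 n_columns_dropped = sum(parts$n_dropped)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Supermatrix:", length(x$taxa), "taxa x", x$n_columns_kept,
      "columns (", x$n_columns_dropped, "dropped at occupancy >=",
      x$occupancy_threshold, ") over", nrow(x$partitions), "markers\n")
  invisible(x)
}

#' Down-sample over-represented clades on a guide tree
#'
#' Selects, per clade, up to `quota` genomes. Method `diversity_greedy`
#' greedily maximizes the summed pairwise path distance on the guide tree
#' (farthest pair first, then the genome adding the most summed distance;
#' ties broken alphabetically, so the plan is deterministic). Method
#' `first_k` keeps the first `quota` genomes in taxonomy order. Focal and
#' outgroup genomes bypass quotas and are always retained. Clades named in
#' `quotas` but absent from the taxonomy produce a warning, not an error.
#'
#' @param tree Guide `phylo` tree containing the ingroup genomes.
#' @param taxonomy Taxonomy data frame.
#' @param quotas Named integer vector, clade -> quota (>= 1).
#' @param method `"diversity_greedy"` (default) or `"first_k"`.
#' @param seed Unused by the deterministic tie-breaks but accepted so call
#'   sites can treat the planner like the other generators.
#' @return An object of class `downsample_plan`: list with `selected`
#'   (genome ids), `per_clade` (list of kept ids per clade), `method`.
#' @export
downsample <- function(tree, taxonomy, quotas,
                       method = c("diversity_greedy", "first_k"),
                       seed = NULL) {
  method <- match.arg(method)
  taxonomy <- validate_taxonomy(taxonomy)
  stopifnot(all(quotas >= 1L))
  absent <- setdiff(names(quotas), taxonomy$clade)
  if (length(absent))
    warning("quota clades absent from taxonomy: ", paste(absent, collapse = ", "))
  dmat <- ape::cophenetic.phylo(tree)
  keep_bypass <- taxonomy$genome_id[taxonomy$role %in% c("focal", "outgroup")]
  per_clade <- list()
  for (cl in unique(taxonomy$clade)) {
    members <- taxonomy$genome_id[taxonomy$clade == cl]
    if (any(members %in% keep_bypass) || !(cl %in% names(quotas)) ||
        quotas[[cl]] >= length(members)) {
      per_clade[[cl]] <- members
      next
    }
    q <- as.integer(quotas[[cl]])
    per_clade[[cl]] <- switch(method,
      first_k = members[seq_len(q)],
      diversity_greedy = .greedy_diverse(members, dmat, q))
  }
  structure(list(selected = unlist(per_clade, use.names = FALSE),
                 per_clade = per_clade, method = method),
            class = "downsample_plan")
}

# greedy max-sum-of-pairwise-distances subset; alphabetical tie-break
.greedy_diverse <- function(members, dmat, q) {
  members <- sort(members)
  if (q == 1L) {
    tot <- rowSums(dmat[members, members, drop = FALSE])
    return(members[which.max(tot)])
  }
  sub <- dmat[members, members, drop = FALSE]
  far <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
  sel <- sort(members[far])
  while (length(sel) < q) {
    rest <- setdiff(members, sel)
    gain <- colSums(dmat[sel, rest, drop = FALSE])
    sel <- c(sel, rest[which.max(gain)])
  }
  sort(sel)
}

#' Write a supermatrix (FASTA + per-marker occupancy summary)
#'
#' @param sm A `supermatrix`.
#' @param fasta Output FASTA path.
#' @param partitions Optional partition-file path.
#' @param occupancy Optional per-marker occupancy TSV path.
#' @export
write_supermatrix <- function(sm, fasta, partitions = NULL, occupancy = NULL) {
  stopifnot(inherits(sm, "supermatrix"))
  write_fasta_alignment(sm$matrix, fasta)
  if (!is.null(partitions)) write_partitions(sm, partitions)
  if (!is.null(occupancy))
    utils::write.table(sm$partitions, occupancy, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(fasta)
}
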