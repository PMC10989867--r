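#' Read a newick tree with optional dual support labels
#'
#' Parses a newick string (or file) into an [ape::phylo] object. Internal node
#' labels of the form `"97/98"` are interpreted as a pair of branch supports,
#' ultrafast bootstrap (UFBoot) first and SH-aLRT second; a bare number is
#' stored as UFBoot only. Labels are kept verbatim on the tree; use
#' [tree_support()] to obtain them as numbers. An absent component is missing
#' (`NA`), never 0: zero is a meaningful support value.
#'
#' @param text A newick string. Exactly one of `text` and `file` must be given.
#' @param file Path to a newick file (first tree is read).
#' @param marker_id Optional marker identifier stored as an attribute.
#' @return A `phylo` object, possibly with a `marker_id` attribute.
#' @examples
#' tr <- read_newick("((a:1,b:1)97/98:1,c:1,d:1);")
#' tree_support(tr)
#' @export
read_newick <- function(text = NULL, file = NULL, marker_id = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  .check_parentheses(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("newick parse failure")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf ids: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch length")
  if (!is.null(marker_id)) attr(tree, "marker_id") <- marker_id
  tree
}

# report the character offset of the first unbalanced parenthesis
.check_parentheses <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed newick: unmatched ')' at character ", i)
    }
  }
  if (depth > 0L)
    stop("malformed newick: ", depth, " unclosed '(' at end of string (length ",
         nchar(text), ")")
  invisible(TRUE)
}

#' Write a tree as a newick string
#'
#' @param tree A `phylo` object.
#' @param file Optional output path; when `NULL` the string is returned.
#' @return The newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Parse dual support labels from internal nodes
#'
#' Splits each internal node label on `"/"`; the first field is UFBoot, the
#' second SH-aLRT, both on a 0-100 scale. Empty labels give `NA` for both; a
#' single number fills UFBoot only.
#'
#' @param tree A `phylo` object as returned by [read_newick()].
#' @return A data frame with columns `node`, `ufboot`, `shalrt`, one row per
#'   internal node.
#' @export
tree_support <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n_int <- tree$Nnode
  nodes <- ape::Ntip(tree) + seq_len(n_int)
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", n_int)
  parse1 <- function(s) {
    if (is.na(s) || !nzchar(s)) return(c(NA_real_, NA_real_))
    parts <- strsplit(s, "/", fixed = TRUE)[[1L]]
    uf <- suppressWarnings(as.numeric(parts[1L]))
    sh <- if (length(parts) >= 2L) suppressWarnings(as.numeric(parts[2L])) else NA_real_
    c(uf, sh)
  }
  m <- t(vapply(lab, parse1, numeric(2L)))
  ok <- function(x) is.na(x) | (x >= 0 & x <= 100)
  if (!all(ok(m)))
    stop("support values outside [0, 100]")
  data.frame(node = nodes, ufboot = m[, 1L], shalrt = m[, 2L], row.names = NULL)
}

#' Read an aligned protein FASTA file
#'
#' All sequences must have equal length (ragged input is an error). Residues
#' are upper-cased; the alphabet is restricted to the IUPAC amino-acid codes
#' plus `-` (gap), `?` and `X` (ambiguity).
#'
#' @param file Path to an aligned FASTA file.
#' @return A character matrix (taxa x columns) with genome ids as row names.
#' @export
read_fasta_alignment <- function(file) {
  ss <- Biostrings::readBStringSet(file)
  if (length(ss) == 0L) stop("empty FASTA: ", file)
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1L)
    stop("ragged alignment in ", file, ": sequence lengths ",
         paste(unique(w), collapse = ", "))
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", file)
  mat <- do.call(rbind, strsplit(toupper(as.character(ss)), "", fixed = TRUE))
  rownames(mat) <- ids
  bad <- setdiff(unique(as.vector(mat)), c(strsplit("ACDEFGHIKLMNPQRSTVWYBZJUO*", "")[[1L]], "-", "?", "X"))
  if (length(bad))
    stop("illegal alignment characters: ", paste(bad, collapse = " "))
  mat
}

#' Write an alignment matrix as wrapped FASTA
#'
#' @param aln Character matrix (taxa x columns), row names are ids.
#' @param file Output path.
#' @param width Line-wrap width, default 60.
#' @export
write_fasta_alignment <- function(aln, file, width = 60L) {
  stopifnot(is.matrix(aln), !is.null(rownames(aln)))
  con <- base::file(file, "w")
  on.exit(close(con))
  for (id in rownames(aln)) {
    seq <- paste(aln[id, ], collapse = "")
    writeLines(paste0(">", id), con)
    starts <- seq(1L, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1L, nchar(seq))), con)
  }
  invisible(file)
}

#' Read a genome-to-clade taxonomy map
#'
#' Tab-separated with columns `genome_id`, `clade`, `role`; role is one of
#' `ingroup`, `outgroup`, `focal`.
#'
#' @param file Path to the TSV.
#' @return A data frame with the three columns, one row per genome.
#' @export
read_taxonomy <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  validate_taxonomy(df)
}

#' Validate a taxonomy map
#'
#' @param df Data frame with columns `genome_id`, `clade`, `role`.
#' @return The validated data frame.
#' @export
validate_taxonomy <- function(df) {
  need <- c("genome_id", "clade", "role")
  if (!all(need %in% names(df)))
    stop("taxonomy must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$genome_id))
    stop("genomes assigned more than one clade: ",
         paste(unique(df$genome_id[duplicated(df$genome_id)]), collapse = ", "))
  bad <- setdiff(unique(df$role), c("ingroup", "outgroup", "focal"))
  if (length(bad)) stop("unknown roles: ", paste(bad, collapse = ", "))
  df[need]
}

#' Write a taxonomy map as TSV
#' @param df Taxonomy data frame.
#' @param file Output path.
#' @export
write_taxonomy <- function(df, file) {
  utils::write.table(validate_taxonomy(df), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a partition file for a supermatrix
#'
#' One line per marker with a non-empty post-filter interval, in
#' concatenation order: `marker_id = start-end`, 1-based inclusive
#' coordinates (internal coordinates are 0-based half-open).
#'
#' @param sm A [supermatrix] object (see [concatenate()]).
#' @param file Optional output path; when `NULL` lines are returned.
#' @return Character vector of lines, invisibly when writing to a file.
#' @export
write_partitions <- function(sm, file = NULL) {
  stopifnot(inherits(sm, "supermatrix"))
  p <- sm$partitions
  p <- p[p$width > 0L, , drop = FALSE]
  if (nrow(p) == 0L) stop("supermatrix has no non-empty partitions")
  lines <- sprintf("%s = %d-%d", p$marker_id, p$start + 1L, p$end)
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Read a hit table (genome, family/marker, copy number)
#'
#' Tab-separated with columns `genome_id`, `family_id` and optionally
#' `n_copies` (missing column means one copy per row). Duplicate
#' (genome, family) rows are summed.
#'
#' @param file Path to the TSV.
#' @return Data frame with columns `genome_id`, `family_id`, `n_copies`.
#' @export
read_hit_table <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("genome_id", "family_id") %in% names(df)))
    stop("hit table must have columns genome_id, family_id")
  if (is.null(df$n_copies)) df$n_copies <- 1L
  if (any(df$n_copies < 0)) stop("negative copy numbers")
  agg <- stats::aggregate(n_copies ~ genome_id + family_id, df, sum)
  agg[order(agg$genome_id, agg$family_id), ]
}
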