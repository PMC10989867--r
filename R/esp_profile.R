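#' Build a presence-absence matrix from a hit table
#'
#' A cell is 1 iff the genome has at least one hit to the family. Genomes or
#' families with no rows in the table appear as all-zero; duplicate
#' (genome, family) rows are merged.
#'
#' @param hits Hit-table data frame (`genome_id`, `family_id`, optional
#'   `n_copies`).
#' @param families Ordered family ids (columns). Defaults to those in `hits`.
#' @param genomes Ordered genome ids (rows). Defaults to those in `hits`.
#' @return Binary integer matrix (genomes x families).
#' @export
build_matrix <- function(hits, families = NULL, genomes = NULL) {
  if (is.null(families)) families <- sort(unique(hits$family_id))
  if (is.null(genomes)) genomes <- sort(unique(hits$genome_id))
  m <- matrix(0L, nrow = length(genomes), ncol = length(families),
              dimnames = list(genomes, families))
  keep <- hits$genome_id %in% genomes & hits$family_id %in% families
  h <- hits[keep, , drop = FALSE]
  n <- if (is.null(h$n_copies)) rep(1L, nrow(h)) else h$n_copies
  pos <- n > 0
  m[cbind(h$genome_id[pos], h$family_id[pos])] <- 1L
  m
}

#' Pairwise profile distances
#'
#' `jaccard`: 1 - |intersection| / |union| of the two genomes' family sets,
#' defined as 0 when both profiles are all-zero (two genomes with no
#' signature families are not evidence of divergence). `hamming`: fraction
#' of families on which the profiles differ.
#'
#' @param m Binary matrix from [build_matrix()] (>= 2 genomes).
#' @param metric `"jaccard"` (default) or `"hamming"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
profile_distance <- function(m, metric = c("jaccard", "hamming")) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- m[i, ] != 0L; b <- m[j, ] != 0L
      d[i, j] <- d[j, i] <- switch(metric,
        jaccard = {
          u <- sum(a | b)
          if (u == 0L) 0 else 1 - sum(a & b) / u
        },
        hamming = mean(a != b))
    }
  }
  d
}

#' UPGMA clustering of genome profiles
#'
#' Iteratively merges the closest pair of clusters under average linkage
#' weighted by cluster sizes (the unweighted pair group method). The merge
#' height is half the merge distance, so the cophenetic distance between two
#' leaves reproduces the linkage value at which they first joined. Distance
#' ties are broken by the smallest (row, col) index pair in the current
#' cluster order, making the dendrogram deterministic.
#'
#' @param d Symmetric distance matrix with zero diagonal (>= 2 genomes),
#'   e.g. from [profile_distance()].
#' @return An object of class `upgma_dendrogram`: list with `tree` (rooted
#'   ultrametric `phylo`) and `heights` (nondecreasing merge heights).
#' @export
upgma <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2L)
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("g", seq_len(nrow(d)))
  n <- nrow(d)
  active <- as.list(seq_len(n))            # member leaf indices per cluster
  newick <- as.list(labels)                # newick fragment per cluster
  height <- rep(0, n)                      # current height per cluster
  size <- rep(1L, n)
  dm <- d
  merge_heights <- numeric(0)
  while (length(active) > 1L) {
    k <- length(active)
    best <- c(Inf, NA_integer_, NA_integer_)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      if (dm[i, j] < best[1L]) best <- c(dm[i, j], i, j)
    i <- best[2L]; j <- best[3L]
    h <- best[1L] / 2
    merge_heights <- c(merge_heights, h)
    frag <- sprintf("(%s:%.10g,%s:%.10g)",
                    newick[[i]], h - height[i], newick[[j]], h - height[j])
    # average-linkage update weighted by cluster sizes = mean over all
    # leaf pairs, i.e. the unweighted (UPGMA) update
    newrow <- (size[i] * dm[i, ] + size[j] * dm[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(k), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], newrow[keep]),
                c(newrow[keep], 0))
    active <- c(active[keep], list(c(active[[i]], active[[j]])))
    newick <- c(newick[keep], list(frag))
    height <- c(height[keep], h)
    size <- c(size[keep], size[i] + size[j])
  }
  tree <- read_newick(paste0(newick[[1L]], ";"))
  structure(list(tree = tree, heights = merge_heights),
            class = "upgma_dendrogram")
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat("UPGMA dendrogram over", ape::Ntip(x$tree), "genomes; root height",
      format(max(x$heights)), "\n")
  invisible(x)
}

#' Cophenetic distances of a UPGMA dendrogram
#'
#' Leaf-to-leaf path lengths; equals the linkage distance at which the two
#' genomes' clusters merged.
#'
#' @param dend An `upgma_dendrogram`.
#' @return Symmetric numeric matrix.
#' @export
cophenetic_distances <- function(dend) {
  stopifnot(inherits(dend, "upgma_dendrogram"))
  ape::cophenetic.phylo(dend$tree)
}
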