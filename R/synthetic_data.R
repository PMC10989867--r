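#' Configuration for the synthetic marker-gene study generator
#'
#' The generator emulates the study design this package targets: a rooted
#' species tree with an outgroup, a series of "TACK-like" clades (group A), a
#' series of "Asgard-like" clades (group B) and a focal clade sister to the
#' B series; per-marker gene trees that deviate from the species tree through
#' horizontal-transfer grafts of the focal clade and through contaminant
#' leaves; and protein alignments evolved on those trees.
#'
#' @param n_clades_A Number of group-A clades (default 4).
#' @param n_clades_B Number of group-B clades (default 4).
#' @param taxa_per_clade Genomes per A/B clade (default 4).
#' @param n_outgroup Outgroup genomes (default 4).
#' @param focal_size Genomes in the focal clade (default 4).
#' @param n_markers Number of marker gene trees (default 50).
#' @param hgt_rate Per-marker probability of a focal-clade graft event, in
#'   \[0, 1\].
#' @param contaminant_rate Per-marker probability of one contaminant leaf.
#' @param graft_target Where grafts land: `"A"`, `"B"` or `"random"`.
#' @param subst_model Amino-acid exchangeability used by [evolve_alignment()];
#'   default `"WAG"`. Equal site rates: the simulation only needs enough
#'   signal for recovery tests, not the site-heterogeneous mixtures used on
#'   real data.
#' @param jitter_sigma Sigma of the multiplicative lognormal branch-length
#'   jitter applied per gene tree (default 0.2).
#' @param aln_length Alignment columns per marker (default 200).
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_clades_A = 4L, n_clades_B = 4L, taxa_per_clade = 4L,
                       n_outgroup = 4L, focal_size = 4L, n_markers = 50L,
                       hgt_rate = 0.2, contaminant_rate = 0.05,
                       graft_target = c("B", "A", "random"),
                       subst_model = "WAG", jitter_sigma = 0.2,
                       aln_length = 200L, seed = 1L) {
  graft_target <- match.arg(graft_target)
  counts <- c(n_clades_A, n_clades_B, taxa_per_clade, n_outgroup,
              focal_size, n_markers, aln_length)
  if (any(counts < 1L)) stop("all counts must be >= 1")
  if (hgt_rate < 0 || hgt_rate > 1 || contaminant_rate < 0 || contaminant_rate > 1)
    stop("rates must lie in [0, 1]")
  structure(list(n_clades_A = as.integer(n_clades_A),
                 n_clades_B = as.integer(n_clades_B),
                 taxa_per_clade = as.integer(taxa_per_clade),
                 n_outgroup = as.integer(n_outgroup),
                 focal_size = as.integer(focal_size),
                 n_markers = as.integer(n_markers),
                 hgt_rate = hgt_rate, contaminant_rate = contaminant_rate,
                 graft_target = graft_target, subst_model = subst_model,
                 jitter_sigma = jitter_sigma, aln_length = as.integer(aln_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# pectinate (ladder) newick fragment over tip labels, all branch lengths bl
.ladder <- function(tips, bl = 0.1) {
  if (length(tips) == 1L) return(sprintf("%s:%g", tips, bl))
  acc <- sprintf("%s:%g", tips[1L], bl)
  for (t in tips[-1L])
    acc <- sprintf("(%s,%s:%g):%g", acc, t, bl, bl)
  acc
}

#' Simulate the species tree and its taxonomy map
#'
#' Topology: `(outgroup, (A-series, (focal, B-series)))`, rooted between the
#' outgroup and the ingroup; every named clade is monophyletic by
#' construction. Branch lengths are drawn uniformly on \[0.05, 0.3\] under
#' the config seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `tree` (rooted `phylo`) and `taxonomy` (data frame with
#'   `genome_id`, `clade`, `role`).
#' @export
simulate_species_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  lab <- function(prefix, n) sprintf("%s_t%02d", prefix, seq_len(n))
  out_tips <- lab("OUT", cfg$n_outgroup)
  foc_tips <- lab("FOC", cfg$focal_size)
  a_clades <- lapply(seq_len(cfg$n_clades_A),
                     function(i) lab(sprintf("A%02d", i), cfg$taxa_per_clade))
  b_clades <- lapply(seq_len(cfg$n_clades_B),
                     function(i) lab(sprintf("B%02d", i), cfg$taxa_per_clade))
  series <- function(clades) {
    parts <- vapply(clades, function(t) sprintf("(%s):0.1", .ladder(t)), character(1L))
    if (length(parts) == 1L) return(parts)
    acc <- parts[1L]
    for (p in parts[-1L]) acc <- sprintf("(%s,%s):0.1", acc, p)
    acc
  }
  out_part <- if (cfg$n_outgroup == 1L) sprintf("%s:0.1", out_tips)
              else sprintf("(%s):0.1", .ladder(out_tips))
  foc_part <- if (cfg$focal_size == 1L) sprintf("%s:0.1", foc_tips)
              else sprintf("(%s):0.1", .ladder(foc_tips))
  nwk <- sprintf("(%s,(%s,(%s,%s):0.1):0.1);",
                 out_part, series(a_clades), foc_part, series(b_clades))
  tree <- ape::collapse.singles(read_newick(nwk))
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.05, 0.3)
  taxonomy <- rbind(
    data.frame(genome_id = out_tips, clade = "Out", role = "outgroup"),
    do.call(rbind, lapply(seq_along(a_clades), function(i)
      data.frame(genome_id = a_clades[[i]], clade = sprintf("A%02d", i),
                 role = "ingroup"))),
    data.frame(genome_id = foc_tips, clade = "Focal", role = "focal"),
    do.call(rbind, lapply(seq_along(b_clades), function(i)
      data.frame(genome_id = b_clades[[i]], clade = sprintf("B%02d", i),
                 role = "ingroup"))))
  rownames(taxonomy) <- NULL
  list(tree = tree, taxonomy = taxonomy)
}

# series membership ("OUT", "A", "B", "FOCAL") per genome, from the taxonomy
.series_of <- function(taxonomy) {
  s <- ifelse(taxonomy$role == "outgroup", "OUT",
       ifelse(taxonomy$role == "focal", "FOCAL",
       ifelse(grepl("^A", taxonomy$clade), "A", "B")))
  stats::setNames(s, taxonomy$genome_id)
}

# child nodes of edges whose descendant tip set lies entirely inside `tips`
.edges_within <- function(tree, tips) {
  bip <- tree_bipartitions(tree)
  which(vapply(bip, function(s) all(s %in% tips), logical(1L)))
}

# detach the focal subtree and re-attach it at the midpoint of a random edge
# lying wholly inside the target series
.graft_focal <- function(tree, focal_tips, target_tips) {
  sub <- ape::keep.tip(tree, focal_tips)
  sub$root.edge <- 0.05
  pruned <- ape::drop.tip(tree, focal_tips)
  cand <- .edges_within(pruned, target_tips)
  if (length(cand) == 0L) stop("graft impossible: target series has no edges")
  e <- cand[sample.int(length(cand), 1L)]
  child <- pruned$edge[e, 2L]
  pos <- pruned$edge.length[e] / 2
  ape::bind.tree(pruned, sub, where = child, position = pos)
}

# move one leaf onto the midpoint of a random edge inside a different series
.move_leaf <- function(tree, leaf, target_tips) {
  pruned <- ape::drop.tip(tree, leaf)
  cand <- .edges_within(pruned, target_tips)
  if (length(cand) == 0L) return(NULL)
  e <- cand[sample.int(length(cand), 1L)]
  child <- pruned$edge[e, 2L]
  pos <- pruned$edge.length[e] / 2
  phytools::bind.tip(pruned, leaf, edge.length = 0.1,
                     where = child, position = pos)
}

#' Simulate discordant gene trees with ground truth
#'
#' Each marker starts as a copy of the species tree with multiplicative
#' lognormal branch-length jitter. With probability `hgt_rate` the focal
#' clade is pruned and regrafted onto a random edge inside the target series
#' (a horizontal-transfer analogue); with probability `contaminant_rate` one
#' random non-focal leaf is moved onto a random edge in a different series
#' (a contaminant analogue). Leaf counts are preserved so taxon sets stay
#' comparable across markers. Every event is recorded in the truth table.
#'
#' @param species Species `phylo` tree from [simulate_species_tree()].
#' @param taxonomy Matching taxonomy data frame.
#' @param cfg A [sim_config()].
#' @return List with `trees` (named list of `phylo`) and `truth` (data frame
#'   `marker_id`, `clean`, `graft_group`, `contaminant_leaf`).
#' @export
simulate_gene_trees <- function(species, taxonomy, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(species, "phylo"))
  set.seed(cfg$seed + 1L)
  series <- .series_of(taxonomy)
  focal_tips <- names(series)[series == "FOCAL"]
  a_tips <- names(series)[series == "A"]
  b_tips <- names(series)[series == "B"]
  ids <- sprintf("m%03d", seq_len(cfg$n_markers))
  trees <- vector("list", cfg$n_markers)
  truth <- data.frame(marker_id = ids, clean = TRUE,
                      graft_group = "none",
                      contaminant_leaf = NA_character_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(cfg$n_markers)) {
    gt <- species
    gt$edge.length <- gt$edge.length *
      stats::rlnorm(length(gt$edge.length), 0, cfg$jitter_sigma)
    if (stats::runif(1L) < cfg$hgt_rate) {
      grp <- if (cfg$graft_target == "random") sample(c("A", "B"), 1L)
             else cfg$graft_target
      target <- if (grp == "A") a_tips else b_tips
      if (length(target) == 0L) stop("graft impossible: series ", grp, " is empty")
      gt <- .graft_focal(gt, focal_tips, target)
      truth$graft_group[i] <- grp
    }
    if (stats::runif(1L) < cfg$contaminant_rate) {
      leaf <- sample(setdiff(gt$tip.label, focal_tips), 1L)
      own <- series[[leaf]]
      pools <- list(OUT = names(series)[series == "OUT"], A = a_tips, B = b_tips)
      choices <- setdiff(names(pools), own)
      moved <- NULL
      for (tgt in sample(choices)) {
        moved <- .move_leaf(gt, leaf, setdiff(pools[[tgt]], leaf))
        if (!is.null(moved)) break
      }
      if (!is.null(moved)) {
        gt <- moved
        truth$contaminant_leaf[i] <- leaf
      }
    }
    truth$clean[i] <- truth$graft_group[i] == "none" &&
      is.na(truth$contaminant_leaf[i])
    attr(gt, "marker_id") <- ids[i]
    trees[[i]] <- gt
  }
  names(trees) <- ids
  list(trees = trees, truth = truth)
}

#' Evolve a protein alignment along a tree
#'
#' The root sequence is drawn from the stationary frequencies of the chosen
#' exchangeability matrix and substitutions are placed along branches under a
#' homogeneous continuous-time process with equal site rates
#' (via [phangorn::simSeq()]).
#'
#' @param tree A `phylo` tree with branch lengths (zero lengths allowed).
#' @param length Number of alignment columns (>= 1).
#' @param seed Integer seed.
#' @param model Amino-acid model name, default `"WAG"`.
#' @param missing_taxa Optional tip labels whose rows are replaced by gaps,
#'   emulating genomes lacking the marker.
#' @return Character matrix (taxa x columns) of amino-acid residues.
#' @export
evolve_alignment <- function(tree, length, seed, model = "WAG",
                             missing_taxa = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length < 1L) stop("alignment length must be >= 1")
  set.seed(seed)
  dat <- phangorn::simSeq(tree, l = length, type = "AA", model = model)
  m <- toupper(as.character(dat))
  if (!is.null(missing_taxa))
    m[intersect(missing_taxa, rownames(m)), ] <- "-"
  m
}

#' Simulate a presence-absence hit table for signature-protein profiling
#'
#' Group-B and focal genomes share an enriched family repertoire while
#' group-A and outgroup genomes carry a smaller, partially overlapping one,
#' mimicking the asymmetric accumulation of eukaryotic signature proteins
#' between archaeal superphyla. Presence is Bernoulli per (genome, family)
#' within each group's repertoire.
#'
#' @param taxonomy Taxonomy data frame.
#' @param n_families Number of protein families (default 30).
#' @param seed Integer seed.
#' @param p_present Probability a repertoire family is present in a genome
#'   (default 0.9).
#' @return Hit-table data frame (`genome_id`, `family_id`, `n_copies`).
#' @export
simulate_esp_hits <- function(taxonomy, n_families = 30L, seed = 1L,
                              p_present = 0.9) {
  set.seed(seed)
  fams <- sprintf("ESP%03d", seq_len(n_families))
  series <- .series_of(taxonomy)
  third <- max(1L, n_families %/% 3L)
  repertoire <- list(
    OUT = fams[seq_len(third)],
    A = fams[seq_len(2L * third)],
    B = fams[(third + 1L):n_families],
    FOCAL = fams[(third + 1L):n_families])
  rows <- lapply(taxonomy$genome_id, function(g) {
    rep_f <- repertoire[[series[[g]]]]
    keep <- rep_f[stats::runif(length(rep_f)) < p_present]
    if (length(keep) == 0L) return(NULL)
    data.frame(genome_id = g, family_id = keep, n_copies = 1L)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic study data set
#'
#' Runs the species-tree, gene-tree, alignment and signature-protein
#' generators and optionally writes them to a directory in the pipeline's
#' on-disk layout (`species.nwk`, `markers/*.nwk`, `alignments/*.fasta`,
#' `taxonomy.tsv`, `truth.tsv`, `esp_hits.tsv`, `config.yaml`).
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory.
#' @param alignments Whether to evolve per-marker alignments (default TRUE).
#' @return List with `species`, `taxonomy`, `trees`, `truth`, `alignments`
#'   (or NULL) and `esp_hits`.
#' @export
simulate_dataset <- function(cfg, dir = NULL, alignments = TRUE) {
  sp <- simulate_species_tree(cfg)
  gt <- simulate_gene_trees(sp$tree, sp$taxonomy, cfg)
  alns <- NULL
  if (alignments) {
    alns <- lapply(seq_along(gt$trees), function(i)
      evolve_alignment(gt$trees[[i]], cfg$aln_length, seed = cfg$seed + 1000L + i,
                       model = cfg$subst_model))
    names(alns) <- names(gt$trees)
  }
  esp <- simulate_esp_hits(sp$taxonomy, seed = cfg$seed + 2L)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "markers"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
    write_newick(sp$tree, file.path(dir, "species.nwk"))
    for (id in names(gt$trees))
      write_newick(gt$trees[[id]], file.path(dir, "markers", paste0(id, ".nwk")))
    if (!is.null(alns))
      for (id in names(alns))
        write_fasta_alignment(alns[[id]],
                              file.path(dir, "alignments", paste0(id, ".fasta")))
    write_taxonomy(sp$taxonomy, file.path(dir, "taxonomy.tsv"))
    utils::write.table(gt$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(esp, file.path(dir, "esp_hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  }
  list(species = sp$tree, taxonomy = sp$taxonomy, trees = gt$trees,
       truth = gt$truth, alignments = alns, esp_hits = esp)
}
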