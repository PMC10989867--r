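# Generates the synthetic marker-catalog fixture under inst/extdata/.
# The fixture is a stand-in for the published supplementary marker table:
# seven source sets that dereplicate to 248 nonredundant markers (12 of them
# with asCOG provenance) and four ranked subsets undin28/undin56/tacka60/
# tacka120 (28/56/60/120 markers) whose four-way intersection holds 19
# markers, with 3 asCOGs in tacka60 and 6 in tacka120. Deterministic; no RNG.

pool <- c(sprintf("cog%04d", 1:118), sprintf("arcog%05d", 1:118)) # 236
ascog <- sprintf("ascog%03d", 1:12)

idx <- list(
  dombrowski = 1:120,
  williams   = 60:140,
  rinke      = 130:200,   # written as upper-case versioned variants
  phylosift  = 1:38,
  gtdb       = 180:236,
  spang      = 20:90      # written through TIGR-style alias accessions
)
spang_alias <- sprintf("tigr%05d", seq_along(idx$spang))

sources <- rbind(
  data.frame(set_name = "dombrowski", accession = pool[idx$dombrowski]),
  data.frame(set_name = "williams",   accession = pool[idx$williams]),
  data.frame(set_name = "rinke",
             accession = paste0(toupper(pool[idx$rinke]), ".1")),
  data.frame(set_name = "phylosift",  accession = pool[idx$phylosift]),
  data.frame(set_name = "gtdb",       accession = pool[idx$gtdb]),
  data.frame(set_name = "spang",      accession = spang_alias),
  data.frame(set_name = "liu_ascog",  accession = ascog))

aliases <- data.frame(accession = spang_alias, canonical = pool[idx$spang])

core19 <- pool[1:19]
undin28  <- c(core19, pool[20:28])
undin56  <- c(undin28, pool[29:56])
tacka60  <- c(core19, pool[57:94], ascog[1:3])
tacka120 <- c(tacka60, pool[95:151], ascog[4:6])
subsets <- rbind(
  data.frame(set_name = "undin28",  marker_id = undin28),
  data.frame(set_name = "undin56",  marker_id = undin56),
  data.frame(set_name = "tacka60",  marker_id = tacka60),
  data.frame(set_name = "tacka120", marker_id = tacka120))

stopifnot(length(unique(c(pool, ascog))) == 248,
          table(subsets$set_name)[c("undin28", "undin56", "tacka60", "tacka120")] ==
            c(28, 56, 60, 120),
          length(Reduce(intersect, split(subsets$marker_id, subsets$set_name))) == 19)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.table(sources, "inst/extdata/synthetic_marker_sources.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(aliases, "inst/extdata/synthetic_marker_aliases.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(subsets, "inst/extdata/synthetic_marker_subsets.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
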