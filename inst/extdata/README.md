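# Synthetic marker-catalog fixture

These tables are **synthetic** stand-ins for a published supplementary marker
catalog, generated deterministically by `data-raw/make_marker_fixture.R`.
They reproduce the catalog's published *structure* — seven source sets that
dereplicate to 248 nonredundant markers, 12 of them with asCOG provenance,
and four ranked subsets (undin28/undin56/tacka60/tacka120 with 28/56/60/120
members, a 19-marker four-way intersection, and 3/6 asCOGs in
tacka60/tacka120) — not its real accessions.

- `synthetic_marker_sources.tsv` — `set_name`, `accession` (raw, including
  case/version variants that dereplication must normalize)
- `synthetic_marker_aliases.tsv` — `accession`, `canonical` cross-references
- `synthetic_marker_subsets.tsv` — `set_name`, `marker_id` for the four
  ranked subsets
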