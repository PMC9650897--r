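# File formats

All tables are tab-separated with a header row. Sequences use the RNA
alphabet (A/C/G/U); DNA (T) is transliterated on read with a notice.

## miRNA catalog (`read_mirna_catalog`)

Columns: `mirna_id`, `mature_seq` (5'→3', ≥ 8 nt), `family_id`,
`conservation_group` (2 = broadly conserved, 1 = conserved, 0 = poorly
conserved, −1 = possibly misannotated), `mirbase_accession` (rows with an
empty accession are excluded by default — isomiR filter), `cluster_id`
(empty = not in a cluster), `n_loci` (≥ 1). The layout mirrors the
TargetScan miRNA family information table but is its own dialect; the
reader derives `seed` (nucleotides 2–8) and `in_cluster`.

## Site table (`read_site_table`, `write_site_table`)

Columns: `gene_id`, `utr_id`, `start`, `end`, `family_id`, `site_type`
(`8mer`, `7mer-m8`, `7mer-A1`, `6mer`), `conserved` (0/1), optionally
`bls`, `n_species`, `site_id` (generated when absent). Two coordinate
dialects: `native` is 0-based half-open `[start, end)`; `targetscan` is
1-based inclusive and is converted on read/write. Interval length must
equal the site-type length.

## Species presence (`read_species_presence`)

`site_id` followed by one 0/1 column per panel species, reference
species (human) first, in divergence order. Column names are the tip
labels of the Newick species tree (read with `ape::read.tree`).

## Expression table (`read_expression_table`, `write_expression_table`)

Wide on disk: `gene_id`, `mean_cpm`, then `log2fc_<condition>` /
`fdr_<condition>` pairs, one per transfection condition. Pivoted to the
long form (`gene_id`, `condition`, `log2fc`, `fdr`, `mean_cpm`) on read.
Genes with `mean_cpm` below 1 are dropped on read by default.

## Haploinsufficiency table (`read_hi_table`)

`gene_id`, `p_hi` with probabilities in [0, 1].

## Gene sets (`read_gmt`, `write_gmt`)

Standard GMT: per line, set name, description, then member genes,
tab-separated. Duplicates are removed; empty sets dropped with a warning.

## BED export (`write_sites_bed`)

Four columns (`utr_id`, `start`, `end`, `name`), 0-based half-open —
identical to the internal convention. With `merge_overlaps = TRUE`,
overlapping site intervals are merged and the name lists the member
site ids.
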