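---
title: "Methods: seed-overlap cotargeting, conservation classes, and response statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-overlap cotargeting, conservation classes, and response statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotargetr)
```

cotargetr quantifies two modes of combinatorial miRNA regulation in
3′ UTRs: *seed overlap* cotargeting, where the seed-match sequences of two
miRNAs are similar enough that their sites occupy overlapping coordinates
and cannot be bound simultaneously, and *neighborhood* cotargeting, where
two sites spaced 15–100 nt apart (between seed starts) can act
cooperatively. This vignette documents the statistical model behind each
stage, the parameters that matter, the numerical conventions, and what
the synthetic-data generator does and does not emulate.

## The seed model

A miRNA seed is nucleotides 2–8 (1-based) of the mature sequence. The
four canonical site types on the mRNA (written 5′→3′) are derived from
the seed's reverse complement: `7mer-m8` is the full 7-nt reverse
complement; `8mer` appends an A opposite miRNA position 1; `6mer` is the
reverse complement of miRNA positions 2–7; `7mer-A1` is the 6mer plus the
A1. These identities (`8mer = 7mer-m8 + "A"`, `7mer-A1 = 6mer + "A"`) are
asserted as properties in the test suite. The internal alphabet is RNA;
DNA input is transliterated (T→U) at the I/O boundary with a notice,
because catalogs in the wild mix genomic and mature-miRNA conventions.

## Pairwise seed overlap and the randomization null

For two same-type site-match sequences of length $L$, `max_overlap()`
returns the largest $k$ such that the last $k$ characters of one sequence
equal the first $k$ of the other, trying both relative orders; ties
between orders are broken by placing the first argument leftmost, and the
reported `offset` is the start of the second sequence relative to the
first. A pair overlaps *extensively* when $k \in \{L-1, L-2\}$ — 7/6 nt
for 8mer sites and 6/5 nt for the 7mer types. Overlap is only computed
within one site type; sites of different types interact only through
coordinates (below). Identical-seed pairs are excluded from pair
enumeration: seed families already collapse identical seeds, so such
pairs would count within-family redundancy as overlap.

`randomization_test()` compares the observed frequency of extensive pairs
among a group's families against $B$ replicates (default 1000) in which
every seed is replaced by a GC-matched random seed: the G/C positions are
drawn uniformly among all position subsets of the seed's G+C count, and
each position is then filled G/C or A/U with probability ½. Matching the
per-seed G+C count holds sequence composition fixed while destroying the
arrangement that produces overlap. Random seeds are not forced to differ
from real seeds — rejection sampling would complicate the null for a
collision probability of order $4^{-7}$ per seed. The empirical p-value
uses the add-one estimator $p = (1 + \#\{\text{null} \ge
\text{obs}\})/(B+1)$, one-tailed for enrichment, which is never zero and
bounded below by $1/(B+1)$. Because the null statistic is a discrete
frequency, ties between null and observed values make the estimator
conservative when the expected number of extensive pairs is small; the
calibration test therefore uses a group large enough (60 families, 1770
pairs) and the 6mer site type (whose shorter extensive blocks occur most
often by chance) so that the discrete null is fine-grained, and checks a
5% ± 2% rejection rate at $\alpha = 0.05$ over 200 repeats with $B = 200$.

`mirna_gene_association()` tests whether extensive-overlap miRNAs are
enriched for cluster membership and multi-locus distribution with
one-tailed Fisher tests; the reported odds ratio is the sample odds ratio
of the 2×2 table, with an `NA`/p = 1 fallback (and a warning) on empty
margins.

## Conservation: BLS, species counts, and the two-class split

The branch length score (BLS) of a site is the total branch length of the
minimal subtree of the species phylogeny connecting the species in which
the site is present; one or zero species score 0. `branch_length_score()`
prunes the tree (`ape::keep.tip`) and sums the remaining edges;
`branch_length_scores()` vectorises the same quantity over a whole
presence table through an edge-incidence matrix (an edge contributes iff
present species lie on both of its sides). The two routes are checked
against each other and against a path-union oracle in the tests.

Sites are called conserved at the TargetScan BLS cutoffs — 1.8 (8mer),
2.8 (7mer-m8), 3.6 (7mer-A1); 6mer sites carry no cutoff and are never
called conserved. Conserved sites are split at a species-count threshold
of 62 of the 84-species panel (the boundary separating Platypus and
birds) into a *shallow* class (< 62 species, typically eutherian mammals)
and a *deep* class (≥ 62, human to *Coelacanth*). The reference species
counts toward `n_species`, so the minimum is 1. The panel excludes fish,
whose UTR alignments are unreliable. BLS is computed on the full species
tree supplied; per-UTR tree re-estimation (as TargetScan performs
internally) is out of scope, and when a site table already carries BLS
values those are used as-is — recomputation is a fallback, not a
replacement.

## Cotarget geometry

Coordinates are 0-based half-open internally; the TargetScan dialect
(1-based inclusive) is converted at I/O. *Conserved overlap* requires two
conserved sites on one UTR whose intervals intersect in at least one
nucleotide — no minimum overlap, because the stringent $L-1/L-2$
thresholds belong to the seed-string statistic, not the coordinate class.
*Neighborhood* requires seed starts $15 \le |d| \le 100$ nt apart
(inclusive bounds; the "approximately 15–100" range in the literature is
resolved to exact inclusive bounds to be testable), and an overlapping
pair is never also a neighborhood pair. The seed start equals the site
start in this representation, since the A1 of an 8mer lies at the 3′ end
of the match. Both annotations distinguish same-miRNA from
distinct-miRNA partners, and a site may carry both annotations via
different partners.

`gene_groups()` assigns each gene, per miRNA family, to its strongest
category: conserved-overlap target (a conserved site with a
distinct-miRNA overlap partner) > 8mer > 7mer > 6mer > non-conserved-only
> background (no sites). When a gene carries several site categories this
strongest-site rule decides the group — the alternative (counting a gene
once per category) double-counts genes in the odds-ratio denominators.
The strict subset "exactly one conserved site and zero non-conserved
sites" is flagged separately so single-site effects can be isolated.

## Response statistics

Downregulated genes have log2 FC < 0 and FDR < 0.05 (0.1 selectable,
matching the two thresholds in common use). Odds ratios compare each
group against the pooled 8mer+7mer reference with a Haldane–Anscombe 0.5
correction when a cell is zero. Rank tests use the exact Wilcoxon
distribution when the smaller sample has ≤ 10 observations and no ties,
otherwise the normal approximation with continuity and tie corrections —
small-sample p-values are checked against exhaustive enumeration. The
log-additivity test forms the expected double-transfection response as
the sum of the single-miRNA log2 FCs and applies a paired signed-rank
test to observed − expected (two-sided by default; one-tailed variants
for directed cooperativity/competition hypotheses). Gene-set enrichment
is the upper-tail hypergeometric probability of the query/set overlap
within a user-supplied universe (default: all genes in the expression
table, since no universe is canonical), BH-corrected across sets.

## What the generator emulates — and what it does not

`sim_config()` fixes the study conditions; the notable defaults are an
84-species panel split at 62, a 0.65/0.35 shallow/deep mixture among
conserved sites, 50 planted extensive pairs among 120 miRNAs, a 10%
planted conserved-overlap fraction and 10% neighborhood fraction,
site-type effects β = (−0.6, −0.4, −0.35, −0.15) log2 units for
8mer/7mer-m8/7mer-A1/6mer with noise σ = 0.15, additive doubles
(δ = 0), and a +0.2 haploinsufficiency-probability shift for the deep
class. Effect sizes are of the magnitude seen in single-site
transfection responses (a few tenths of a log2 unit) and enforce the
8mer > 7mer > 6mer hierarchy; they are fixed once here and not tuned per
analysis.

Planted structure is exact by construction: partner seeds are shifted
copies of a base seed (guaranteeing $k \in \{L-1, L-2\}$), and all other
seeds are rejection-sampled so no unplanted pair overlaps extensively —
the planted pairs are the complete ground truth for `extensive_pairs()`.
Background sites are spaced ≥ 140 nt apart so no accidental coordinate
overlap or neighborhood spacing arises; planted cotarget pairs live in a
reserved coordinate window. The species tree is a ladder (pectinate)
ultrametric tree with jittered join heights ordered by divergence;
presence vectors are nested prefixes of the panel, which makes
conservation profiles monotone and — because the height increments are
bounded — guarantees that sites present in ≥ 20 species exceed the
largest BLS cutoff while sites in ≤ 19 never reach the smallest, so the
conserved flag, the BLS cutoffs and the species counts are mutually
consistent.

What the generator does *not* emulate: real UTR sequence evolution
(presence is planted, not derived from alignments), per-UTR phylogenies,
read-count noise (FDR flags come from two-sided z-tests against the known
σ with BH correction, not from a count model), correlated expression
across genes, and non-canonical site types. Passing tests therefore
demonstrate that each stage recovers the structure it is designed to
detect under its own assumptions — not that those assumptions hold in any
particular real data set.

## Numerical choices and degenerate inputs

Empirical p-values are never 0 by construction. `max_overlap()` rejects
empty sequences; ties between the two arrangement orders report the
first argument leftmost. Conservation calls require finite inputs and
reject unknown site types. `two_class_summary()` errors when no site is
conserved, `conservation_profile()` when a class is empty.
`find_neighborhood()` validates `d_min <= d_max`; site tables are
validated for 0 ≤ start < end and type-consistent lengths. Association
tables with an empty margin return an undefined odds ratio with p = 1
and a warning rather than failing. All randomized stages accept an
integer seed, and the pipeline derives per-stage seeds from one master
seed, so a single integer fixes every simulated table and every test
statistic; seeds are restored on exit so callers' RNG streams are not
disturbed.

## Problem sizes

The test suite runs the mixture-recovery checks at ~10,000 sites
(tolerance ± 0.02), the randomization-test calibration at 200 repeats
with B = 200 over 60 families, the additivity calibration at 500
simulations (size 0.05 ± 0.02) and power at n = 20 pairs with
δ = −0.5, σ = 0.1 (power ≥ 0.9), and exhaustive-enumeration cross-checks
for every small-sample p-value. The default pipeline configuration
(120 miRNAs, 2000 genes, B = 1000) is the one `scripts/acceptance.R`
reports on; these sizes were chosen so each statistic's sampling error is
comfortably inside its stated tolerance.

## Known limitations

Mixed-site-type seed-string overlap is intentionally not computed (the
coordinate classes cover it); thermodynamic affinity, 3′-supplementary
pairing, site accessibility and AU context are out of scope; the
enrichment universe defaults to the expression table, which understates
enrichment if the true assay universe was larger; and whether cotarget
denominators should count sites or pairs is ambiguous in the field —
the package reports site-level fractions and exposes partner lists so
pair-level counts can be derived.
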