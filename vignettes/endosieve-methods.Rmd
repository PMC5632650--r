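---
title: "Methods: evidence-based endosymbiont deconvolution and downstream statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evidence-based endosymbiont deconvolution and downstream statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endosieve)
```

This vignette explains the models and procedures the package implements, the
parameters that matter and their defaults, what the synthetic-data generators
do and do not emulate, and the numerical choices made where the design was
genuinely open. Coordinates are 0-based half-open everywhere inside the
package; conversion to and from the 1-based inclusive conventions of GFF3 and
tabular hit files happens only in the readers and writers.

## Contig binning

A bulk assembly of an endosymbiont-bearing eukaryote mixes two genomes that
differ in three measurable ways — homology, base composition, and copy
number — and, when a symbiont-cured (aposymbiotic) culture has also been
assembled, in presence. The published analyses of such data apply these four
evidences narratively and by hand; `classify_contigs()` formalizes them as
votes with a quorum so the procedure is reproducible and tunable.

* **Homology-coverage ratio.** `query_coverage()` is the length of the union
  of query-side hit intervals over the contig length (overlaps counted
  once; whether published "query coverage" merged overlapping hits is rarely
  stated — we merge, and the tests pin this to a per-base counter).
  `homology_ratio()` divides symbiont-side by host-side coverage; ratio > 1
  votes symbiont. Conventions: positive coverage over zero host coverage is
  `Inf` (counts as > 1); zero over zero is undefined and casts no vote.
* **GC.** The default cutoff `gc_symbiont_max = 0.56` is the midpoint between
  the upper end of the symbiont range (0.49) and the host value (0.65) in the
  motivating data. GC denominators exclude `N` everywhere.
* **Depth.** Absolute depths are dataset-specific, so the vote is relative:
  symbiont requires `mean_depth >= depth_fold_min` (default 5) times the
  median depth of the *host candidates*, seeded as the contigs whose ratio
  vote is "against". With an ~874× vs ~25× separation this is a wide margin.
* **Aposymbiotic absence.** A contig whose best-match query coverage against
  the aposymbiotic assembly is below `apo_cov_max = 0.5` counts as absent.
  This approximates the published criterion (which inspected the *read*
  coverage of the matched contigs, ~1×, to dismiss them as cross-sample
  contamination) by match coverage, which is what hit tables expose.

A contig is `symbiont` when the ratio vote is "for" (required by default;
`ratio_required = FALSE` relaxes it to "not against") and at least
`min_votes = 2` votes are "for"; `host` when the ratio vote is "against" and
the quorum fails; `ambiguous` otherwise. Unavailable evidence never counts
for either side, and a contig with all four evidences unavailable is an
error rather than a silent guess. The vote columns are kept in the output so
every call is auditable.

**Duplicated fragments.** Genuinely duplicated segments assemble once but
attract twice the reads. Among symbiont-labelled contigs,
`flag_duplicates()` flags depth folds inside `dup_window = c(1.6, 2.4)`
around the median symbiont depth — a window wide enough to bracket the
~1.78× and ~2.13× folds seen in practice while excluding ordinary depth
scatter. The median is recomputed after setting aside the duplicate
candidates themselves so that, in small genomes where duplicates are a large
share of contigs, they do not drag the reference depth upward.

## Composition and codon-usage statistics

`codon_counts()` counts codons over the concatenated CDS of a genome
(ambiguous-base CDS excluded with a warning; a length not divisible by 3 is
an error naming the sequence). Terminal stop codons, when annotated CDS
include them, are tallied separately and excluded from sense counts; internal
stops are reported and never reach RSCU. The genetic code defaults to NCBI
table 11 (bacterial), under which exactly Met and Trp are single-codon amino
acids — matching the standard exclusion list for the bias measure.

RSCU is `n_i * x_c / T_i` per family; `rscu_sd()` is the sample standard
deviation (divisor N−1; the population divisor is available via `divisor =
"n"` since published descriptions rarely state which was used) over defined
multi-codon families. Families with zero observed counts are excluded rather
than imputed as zero — imputation would manufacture bias in small genomes.
Useful identities that the tests assert: RSCU sums to the family size within
every defined family, and the unweighted mean of the three codon-position GC
fractions equals the GC of the coding set.

Intergenic lengths are gaps between consecutive spans of the *merged*
gene-span union per contig; overlapping genes therefore never create
negative or zero gaps. Contig-terminal flanks are excluded in linear mode
and joined across the origin in circular mode (annotations rarely say which
convention their source used; linear is the conservative default).
Pseudogene features are excluded from the length statistics.
`group_compare()` wraps `aov()` + `TukeyHSD()` at `alpha = 0.05`; degenerate
inputs with zero between-group variance short-circuit to F = 0, p = 1.

## Dollo gain/loss mapping

Under Dollo parsimony a gene family is gained exactly once and can only be
lost afterwards. Given a presence/absence matrix and a rooted species tree,
the loss-minimizing single-gain history is: gain on the edge above the MRCA
of the possessing taxa, one loss per maximal possessing-free subtree inside
the gain clade. Moving the gain above the MRCA strictly adds losses, so the
minimum is unique in gain placement; the test suite verifies both claims by
exhaustive enumeration of every gain node over all 2^6 presence patterns on
random 6-leaf trees. Multifurcating trees need no special handling — a
"maximal absent subtree" generalizes as-is. OGs present in all taxa gain at
the root node and are flagged `gain_at_root`, so users who prefer to read
universal families as ancestral presence rather than a root-edge gain can
re-tally without re-running. OGs absent everywhere are reported as skipped,
not errors (they arise naturally when a matrix is subset to a tree's taxa).

`exclusive_shared()` and `paralog_census()` are set operations on the same
matrix: OGs present in a focal taxon and a group and nowhere else, and the
per-taxon histogram of OG copy numbers.

## Phylogenomic filtering and the supermatrix

`mean_support()` averages the numeric internal-node labels of a gene tree
(the common Newick dialect for bootstrap values); nodes without a value —
typically the root — are excluded rather than imputed. `filter_genes()`
compares inclusively (`>= 70` by default): the usual phrasing "setting 70% as
a threshold" does not state strictness, so the boundary is documented and
configurable. Concatenation appends genes in input order, gap-fills taxa
missing from a gene, and emits a 1-based inclusive partition table of the
form partition files expect.

## Synteny blocks

Anchors (pairwise local alignments) are chained per contig pair into blocks
of at least `min_anchors = 7` anchors whose second-genome starts are strictly
monotone — increasing for `same` orientation, decreasing for `inverted` —
with consecutive members within `max_gap = 100000` bp on both genomes.
Rather than growing runs greedily left to right, the implementation
repeatedly extracts the highest-scoring monotone chain (quadratic dynamic
programming over anchors sorted by first-genome start) until no chain
reaches the minimum size: a single stray anchor inside an otherwise
collinear run is then skipped instead of splitting the run, which matters as
soon as the anchor set contains any noise. The procedure is deterministic
and invariant to input order, and strict monotonicity means two anchors
tying on a second-genome start can never share a block.

`merge_blocks()` applies the two decision rules stated with the reference
tool settings: same-orientation blocks on the same contig pair whose spans
lie within `merge_distance = 50000` bp on both genomes are merged to a fixed
point; where two blocks still overlap on a contig afterwards, only the
larger is kept (more anchors, then longer first-genome span, then lower
start). The gap and merge distances of the original tool runs are not
published; the defaults here are stated conventions, not reproductions, and
both are exposed.

## Pseudogene calling

`mask_genes()` replaces the union of annotated gene spans with `N` and keeps
a ledger of the masked intervals. `call_pseudogenes()` keeps
translated-homology hits with `evalue <= 1` (the permissive ceiling
appropriate for decayed sequences) whose query intervals are entirely
disjoint from gene spans — a hit partially overlapping a gene is discarded,
not trimmed, which is the conservative reading — and merges kept hits within
`max_merge_gap = 100` bp into single calls. The published workflows insert a
manual-inspection step here; the deterministic merge rule replaces it and
the gap parameter exposes the judgment that step embodied. Frame and strand
of translated hits are ignored: annotation is by coordinates only. The tests
assert that no call ever intersects a gene span, that merging is idempotent
and order-independent, and that planted decayed fragments yield exactly one
containing call each.

## Synthetic data: what it emulates, and what it does not

All generators take a mandatory seed, restore the caller's RNG state, and
are byte-deterministic given identical arguments. Each emits a truth object
sufficient to score the corresponding stage without re-deriving anything.

* `simulate_mixed_assembly()` — defaults are the study conditions: host
  contigs at 65% GC and 25× depth, symbiont contigs at 44% GC and 874×
  depth, 150 + 50 contigs of 1–5 kb, 5% of symbiont contigs planted at
  doubled depth. Depth is negative binomial around the class mean with
  `size = 200`: the relevant noise is that of a *per-contig mean* over at
  least a thousand positions, so its coefficient of variation (~7%) sits
  well inside the 1.6–2.4× duplicate window. Homology hits cover 60–95% of
  each contig on its own side; `noise_rate` adds low-coverage (2–15%)
  wrong-side hits; aposymbiotic matches cover 80–98% of host contigs and
  2–30% of symbiont contigs. GC jitter (`gc_sd`) makes the GC evidence
  overlap between classes.
* `simulate_coding_genome()` — genes are sampled codon-wise with synonymous
  weights `exp(beta)` on one preferred codon per family (the
  alphabetically first) against weight 1 for the rest, optionally tilted by
  `exp(gc_weight * GC-count)` to shift coding GC, which acts mostly at the
  synonymous third position. `beta = 0` is *exactly* uniform usage — a
  random-probability scheme (e.g. Dirichlet-distributed family
  probabilities) would make even the zero-bias setting biased in
  realization, defeating the uniform-limit check — and `beta -> Inf`
  collapses each family to one codon, the maximal-bias limit where every
  defined RSCU is 0 or the family size. Mean RSCU-SD is monotone in `beta`.
* `simulate_dollo()` — one gain on a uniformly chosen node's parent edge,
  then independent losses (probability `p`) on edges inside the gain clade,
  pruned top-down so nested events are never recorded; OGs erased entirely
  are excluded from the matrix and listed. Simulated histories are not
  always the most parsimonious explanation of the pattern they leave (two
  sibling losses mimic one deeper loss), which is exactly the gap the
  recovery tests quantify: reconstruction is exact precisely on the
  oracle-verified minimal histories.
* `simulate_support_trees()` draws integer supports so recomputed means
  equal the drawn means without floating-point round-trip concerns;
  `simulate_anchors()` plants monotone runs separated by 300 kb (beyond the
  default gap cap) with a stated inverted fraction plus uniformly placed
  noise anchors; `simulate_pseudogene_scan()` plants decayed fragments in
  intergenic spacers with abutting hits that must merge, plus decoy hits
  over genes that the mask must reject.

Sequence content is i.i.d. per base or codon: there is no k-mer structure,
no repeats, no sequencing-error model, and no rearrangement history behind
the anchor sets. Passing tests therefore demonstrate the correctness of the
decision rules and statistics under the stated signal separations, not
robustness to the full messiness of real assemblies (chimeric contigs,
horizontally transferred segments, coverage dips at GC extremes — the last
being a caveat the depth evidence inherits in real data).

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to run on a
single CPU in a few minutes while keeping the statistics meaningful: 50
random 6-leaf trees × all 63 non-empty presence patterns for the Dollo
oracle; 1,000 simulated OGs at `p = 0.05`; 200-contig assemblies; 1,000
random hit sets for the coverage oracle; ~60,000 codons for the
uniform-usage RSCU-SD floor (multinomial noise alone contributes ~0.03 at
that depth, so the 0.05 check needs that scale); 20 bias levels × 50
replicates of ~2,000-codon genomes for the monotonicity rank correlation;
10 planted synteny blocks of 20 anchors with 5% noise. Tolerances: RSCU
family sums are asserted to 1e-9 and the positional-GC identity to 1e-12;
everything else is exact or a counting recovery.

Known limitations, beyond the generator realism above: binning treats
contigs independently (no assembly-graph information); the depth evidence
needs at least one host candidate seeded by the ratio evidence, otherwise it
abstains; Dollo parsimony cannot, by construction, recover a true history
that is not minimal; and the synteny chainer does not stitch blocks across
contig pairs (no translocation handling).
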