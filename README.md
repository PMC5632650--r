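# endosieve

Deconvolution and comparative genomics of bacterial endosymbiont genomes in
mixed host–symbiont assemblies.

When a eukaryotic host carrying an intracellular bacterium is sequenced in
bulk, the assembly mixes host and symbiont contigs. `endosieve` separates
them with the four lines of evidence such studies rely on, and implements the
downstream comparative statistics that characterize reduced endosymbiont
genomes: codon-usage bias, composition by codon position, gene-family
gain/loss histories, phylogenomic gene filtering, synteny blocks, and
pseudogene calling. Every stage has a seeded synthetic-data generator with
machine-readable ground truth, so the whole pipeline is testable offline.

## What it computes

**Contig binning.** Each contig of the mixed assembly receives four evidence
votes:

1. *homology-coverage ratio* — the fraction of the contig covered by hits
   against a symbiont-side reference set divided by the fraction covered by
   host-side hits; values above 1 favour symbiont origin
   (`cov_host = 0, cov_symbiont > 0` counts as above 1);
2. *GC content* — endosymbiont genomes are typically AT-shifted relative to
   a GC-rich host (defaults calibrated to a ~65% GC host vs a 43–49% GC
   symbiont);
3. *read depth* — intracellular bacteria are present in many copies per host
   cell, so symbiont contigs carry a fold higher coverage (~874× vs ~25× in
   the motivating setting); the vote compares depth against the median of
   the host candidates;
4. *absence from an aposymbiotic assembly* — a contig missing from the
   assembly of a symbiont-cured host culture is symbiont-derived.

A configurable quorum (`binning_config()`) turns the votes into
`symbiont` / `host` / `ambiguous` labels, and symbiont contigs whose depth is
≈2× the symbiont median are flagged as putative duplicated fragments.

**Codon-usage bias.** For codon *c* in a synonymous family of size *n_i* with
counts *x*, the relative synonymous codon usage is

    RSCU_c = n_i * x_c / sum_{c' in family} x_{c'}

so RSCU = 1 means unbiased usage. The scalar bias measure is the sample
standard deviation of RSCU over all sense codons, excluding stop codons and
the single-codon amino acids Met and Trp (`rscu_sd()`). Also provided: GC by
codon position, amino-acid frequencies, gene/intergenic length
distributions, and one-way ANOVA + Tukey HSD group comparisons
(`group_compare()`).

**Dollo parsimony.** Gene families (ortholog groups) are assumed gained once
and only lost thereafter. `dollo_map()` places each OG's gain on the edge
above the MRCA of the possessing taxa and charges one loss to each maximal
subtree inside the gain clade with no possessing taxon — the loss-minimizing
single-gain history, verified in the tests against exhaustive enumeration.

**Phylogenomics, synteny, pseudogenes.** `filter_genes()` keeps genes whose
gene trees have mean bootstrap support ≥ 70 (inclusive, configurable) and
`concatenate_alignments()` builds the partitioned supermatrix.
`chain_anchors()` + `merge_blocks()` build synteny blocks of ≥ 7 collinear
anchors, strictly monotone on the second genome (decreasing = inverted),
merging nearby same-orientation blocks and keeping the larger of two
overlapping ones. `mask_genes()` + `call_pseudogenes()` scan gene-masked
genomes for translated-homology hits in intergenic space (E ≤ 1) and merge
nearby hits into pseudogene calls.

## Worked example

```r
library(endosieve)

# RSCU from its definition: Glu observed as GAA x3, GAG x1
rscu(codon_counts("GAAGAAGAAGAG")) |> dplyr::filter(amino_acid == "E")
#> # A tibble: 2 x 5
#>   codon amino_acid family_size count  rscu
#>   <chr> <chr>            <int> <int> <dbl>
#> 1 GAA   E                    2     3   1.5
#> 2 GAG   E                    2     1   0.5

# simulate a mixed assembly at the study separations and bin it
asm <- simulate_mixed_assembly(seed = 42, n_host = 30, n_symbiont = 10)
bins <- bin_contigs(asm$contigs, asm$hits_symbiont, asm$hits_host,
                    asm$depth, hits_apo = asm$hits_apo)
table(as.character(bins$label), asm$truth$class)
#>            host symbiont
#>   host       30        0
#>   symbiont    0       10

autoplot(bins)   # the GC-vs-depth blob plot, coloured by label
```

The first tibble reads: glutamate is encoded 3:1 in favour of GAA, so GAA is
used 1.5× its uniform expectation and GAG 0.5×. The confusion matrix shows
every simulated contig recovered its true class.

The one-command demonstration pipeline simulates all three main input kinds,
runs binning, composition and Dollo mapping, and scores them against the
generator truth:

```r
run_demo(seed = 11, out_dir = "demo_out")$scores
#> # A tibble: 1 x 4
#>   binning_accuracy duplicate_recall dollo_event_accuracy rscu_sd
#>              <dbl>            <dbl>                <dbl>   <dbl>
#> 1                1                1                0.955   0.509
```

Binning and duplicate flagging are perfect; 95.5% of simulated gain/loss
histories are recovered exactly (the remainder are histories whose random
losses admit a strictly more parsimonious explanation, which Dollo parsimony
by construction prefers); the simulated genome's codon-usage bias at
`beta = 1` yields RSCU-SD 0.509. A thin command-line wrapper around the same
functions ships in `inst/cli/endosieve.R`.

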