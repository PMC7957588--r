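# heatmiR

Identification of heat-responsive microRNAs from unreplicated plant small RNA
sequencing — for studies that compare a heat-tolerant and a heat-sensitive
genotype under normal (NT) and high temperature (HT), one sRNA library per
genotype × condition (four libraries in all), and ask which miRNAs respond to
heat and which genes they repress.

## What it computes

**Preprocessing.** Raw FASTQ reads are quality-filtered, adapter-trimmed,
restricted to 18–30 nt, cleaned of poly-A artifacts, and collapsed into unique
sequence tags with per-library counts. Tags are annotated hierarchically
(rRNA → scRNA → snoRNA → snRNA → tRNA → repeat → mRNA fragment →
candidate sRNA); only candidate sRNAs enter miRNA discovery, and known-miRNA
matching runs before gene-model removal so catalogued miRNAs overlapping exons
are not lost.

**miRNA identification.** Tags are classified as *known* (match to the focal
species catalog, allowing ≤ 2 nt terminal shifts), *new members* of known
families (≤ 2 mismatches to another species' mature miRNA plus a validated
hairpin), or *novel*. Novel calls require excising candidate precursors around
genomic hits, folding (ViennaRNA), trimming to the enclosing stem-loop, and
passing five structural criteria:

1. the miR-5p/miR-3p duplex has **> 16 matched pairs** and arm lengths differ
   by **≤ 4 nt**;
2. both duplex ends show the Dicer-characteristic **2-nt 3′ overhang**;
3. **≤ 1 asymmetric bulge**, none larger than **2 nt**, within the duplex;
4. the most abundant arm read reaches **≥ 10 reads** in at least one library;
5. **MFE < −0.2 kcal/mol/nt** and **MFEI > 0.85**, with
   MFEI = |MFE/length × 100| / GC%.

**Targets.** Transcripts are scanned for ungapped complementary sites under
six rules: total mismatch score ≤ 4 with G·U wobble = 0.5; no more than 2
adjacent non-matches; no adjacent non-matches in positions 2–12 (5′ of the
miRNA); positions 10–11 matched; score over positions 1–12 ≤ 2.5; and duplex
MFE ≥ 75 % of the perfect-complement duplex MFE.

**Differential expression.** Counts are normalized to tags per million
(TPM = count / total clean tags × 10⁶). With one library per condition,
significance uses an Audic–Claverie exact test on counts (two-sided); a miRNA
is a DEM when fold change ≥ 2 and *p* < 0.05. Each miRNA's (tolerant,
sensitive) heat response places it in a 3×3 grid of pattern types I–IX
(induced in both = I, repressed in both = IV, no response = IX). A
2^−ΔΔCt utility supports qPCR validation arithmetic.

**Network.** Significant DEMs are joined with predicted targets and a
gene-level DEG table: an edge requires opposite directions in the same
contrast and gene |fold change| > 1.5.

A synthetic-data module generates a complete input bundle — genome with
planted compliant hairpins and single-violation decoys, four FASTQ libraries
realizing all nine pattern types, transcripts with rule-graded target sites,
and a DEG table — together with machine-readable ground truth, so the whole
pipeline is testable end-to-end offline.

## Worked example

```r
library(heatmiR)
fx  <- make_fixture("tiny", dir = "fixture", seed = 7)   # synthetic bundle
res <- run_pipeline(fx$config, "run1")

table(res$records$class)
#>      known new_member      novel
#>          9          2          4

head(res$dems$tolerant[res$dems$tolerant$significant,
                       c("mirna_id", "fold_change", "p_value", "direction")])
#>     mirna_id  fold_change      p_value direction
#> 1 gma-miR001  12.24311995 2.767572e-82        up
#> 2 gma-miR002 290.01648008 1.994321e-87        up
#> 3 gma-miR003   9.90300176 1.254171e-76        up
#> 4 gma-miR004   0.09948209 1.359187e-72      down

table(res$types$pattern_type)
#>    I   II  III   IV   IX    V   VI  VII VIII
#>    2    2    2    1    4    1    1    1    1

head(res$network$edges[, c("mirna_id", "gene_id", "contrast",
                           "mirna_direction", "gene_direction")])
#>     mirna_id  gene_id contrast mirna_direction gene_direction
#> 1 gma-miR001 Gene0001 tolerant              up           down
#> 2 gma-miR001 Gene0005 tolerant              up           down
#> 3 gma-miR002 Gene0002 tolerant              up           down
```

`run_pipeline()` writes every stage's tables (library statistics, tag FASTA,
expression matrix with counts and TPM, DEM tables per contrast, pattern
types, hairpin report with per-criterion verdicts, target sites, network
edges) plus the serialized config and a JSON manifest into the run directory.
The fold-change column is HT over NT: `gma-miR001` is induced ~12-fold by
heat in the tolerant genotype, and the network rows read "miRNA up, target
gene down" — candidate negative regulation under heat stress.

A thin command-line wrapper is installed at `inst/scripts/heatmir.R`
(`fixture` and `run` subcommands).

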