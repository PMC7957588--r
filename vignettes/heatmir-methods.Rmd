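---
title: "Methods: miRNA discovery, scoring and differential expression in heatmiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA discovery, scoring and differential expression in heatmiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

heatmiR implements a complete analysis path for unreplicated plant small RNA
sequencing studies of heat stress: two genotypes (heat-tolerant and
heat-sensitive) × two conditions (normal temperature NT, high temperature
HT), one library each. This vignette documents the methods, every tunable
that matters, the numerical and design choices made where the method leaves
room, and what the synthetic tests do and do not establish.

## Read cleaning and tag annotation

Reads are discarded for exactly one reason each, in a fixed order, so raw
counts reconcile exactly: (1) *low quality* — any base below Phred 20 within
the first 25 cycles; (2) *adapter-only* — the 3' adapter starts at position
1; (3) length outside 18–30 nt after adapter trimming; (4) *poly-A* — ≥ 80 %
adenosine in the trimmed insert. Adapter trimming cuts at the first exact
occurrence of the adapter's leading 8-mer. The quality rule, the poly-A
fraction and the adapter are configuration values (`min_quality`,
`quality_cycles`, `polya_frac`, `adapter`): sRNA protocols differ, and the
defaults are ordinary practice for this library type rather than anything
data-derived. Because the insert is everything before the *first* adapter
seed hit, cleaned reads can never contain the seed, which makes cleaning
idempotent — a property the tests assert.

Tags (unique cleaned sequences with per-library counts) are annotated by
exact substring match on either strand against user-supplied reference sets,
with one class per tag in a fixed priority: rRNA → scRNA → snoRNA → snRNA →
tRNA → repeat → mRNA fragment → candidate sRNA. The priority is a
convention (the removal steps themselves don't order ties); placing
structural RNAs first reflects that a tag inside an rRNA is almost surely an
rRNA fragment whatever else it overlaps. Known-miRNA matching is performed
*before* exon/intron-based removal: gene-model overlap flags likely mRNA
degradation fragments, and a catalogued mature miRNA is positive evidence
against that interpretation. Genome mapping is exact (both strands, all hits
recorded) through a per-width k-mer index; at the scale this package targets
a heuristic aligner would add dependencies without adding sensitivity, and
mismatch-tolerant genomic mapping is deliberately out of scope.

## miRNA classes

* **Known**: identical to a focal-species catalog mature, or identical after
  trimming/extending up to 2 nt at each terminus (isomiR tolerance). The
  shift bound is a package decision — common isomiR variation is 1–2 nt of
  terminal heterogeneity — and internal mismatches are never tolerated.
  Extension variants are accepted only when the catalog mature is contained
  in the tag, since extensions cannot be validated without the catalog
  precursor. Tags matching several entries equally are counted for each and
  flagged ambiguous.
* **New members of known families**: the tag aligns ungapped, with ≤ 2
  substitutions and ≤ 2 nt length difference, to another species' mature
  miRNA, *and* one of its genomic loci folds into a hairpin passing all
  structural criteria with the tag as a mature arm read. The family label is
  inherited from the matched foreign entry.
* **Novel**: everything else that passes the hairpin criteria below.

## Precursor excision, trimming and the five hairpin criteria

Around each locus anchor (the most abundant mapped candidate tag), three
windows are excised — 5'-heavy (250 nt up, 20 down), 3'-heavy (20 up, 250
down) and centered (135/135), clipped to the contig and to 60–400 nt, the
plausible plant pre-miRNA range. Each window is folded (ViennaRNA RNAfold;
the engine identity and version are recorded in the run manifest because MFE
values are engine-dependent) and then *trimmed to the enclosing stem-loop*:
starting from the hairpin loop the tag's pairing partners lead to, the
precursor is the outermost base pair that still encloses exactly that one
loop. Trimming is essential for the energy criteria to be meaningful —
without it, MFE and MFEI would be computed over arbitrary flanking sequence
and would depend on the window layout rather than on the locus. Trimmed
candidates are deduplicated, refolded, and evaluated; among passing windows
of a locus the lowest-MFE one is kept, and overlapping accepted loci are
merged (lowest MFE wins). Multi-mapping tags are counted once per miRNA
record, not once per locus, so expression is never double-counted.

The criteria, with the arm reads defined as the most abundant read wholly on
each side of the loop (loop-spanning reads disqualify an arm):

1. **Duplex size**: strictly more than 16 matched pairs between the arms and
   an arm-length difference of at most 4 nt. The boundary is strict: a
   duplex with exactly 16 pairs fails, and a dedicated test pins this.
2. **2-nt 3' overhangs** at both duplex ends, the signature of Dicer
   processing. Overhangs are read off the pairing map by projecting each
   arm's first paired position onto the partner arm's end, which tolerates
   terminal mismatches without changing the measured overhang.
3. **Asymmetric bulges**: at most one within the duplex, none larger than
   2 nt. Symmetric internal loops (equal unpaired counts on both strands)
   are mismatches, not bulges, and are constrained only through criterion 1.
4. **Abundance**: the most abundant arm read must reach ≥ 10 reads in at
   least one library. The source convention for this criterion is worded as
   "no more than 10 reads", which read literally would reject every
   well-expressed miRNA and keep only noise; heatmiR implements the
   evidently intended minimum-evidence reading. The threshold is exposed as
   `min_reads` so users who want the literal behavior can study it.
5. **Energetics**: MFE per nucleotide < −0.2 kcal/mol/nt and MFEI > 0.85,
   where MFEI = |MFE/length × 100| / GC%. The MFEI formula is the standard
   one (it is algebraically |MFE per nt| / GC fraction) and is reported as a
   positive magnitude so thresholds and typical published ranges (roughly
   0.9–3) are directly comparable. MFE and MFEI are reported separately in
   the verdict vector, besides the combined criterion, because they fail for
   different biological reasons (weak folding vs GC-rich non-miRNA hairpins
   such as repeats).

Degenerate inputs are handled explicitly: windows whose structure has zero
or several hairpin loops, loci with reads on only one arm, or tags that are
entirely unpaired are reported as unevaluable with a reason rather than
scored.

## Target rules

Sites are ungapped windows of the miRNA's length, compared antiparallel
(miRNA position 1 against the window's 3'-most base), slid 1 nt at a time.
Gapped (bulged) target sites are out of scope: the position-indexed rules
below are ill-defined under gaps, which is also why the scan is a pattern
match rather than an alignment.

* r1 — total score ≤ 4, where a G·U wobble counts 0.5 and a mismatch 1;
* r2 — no more than 2 adjacent non-matches anywhere;
* r3 — no adjacent non-matches in positions 2–12 (5' of the miRNA);
* r4 — positions 10–11 (the cleavage site) perfectly matched;
* r5 — score over positions 1–12 at most 2.5;
* r6 — |duplex MFE| ≥ 75 % of |MFE against the perfect complement|,
  inclusive at the boundary.

G·U handling is the one genuinely open choice: the 0.5 weighting is defined
for the counting rules (r1, r5) only. heatmiR defaults to *strict* wobble
handling — G·U is a non-match for the adjacency and position rules r2–r4 —
because a wobble at the cleavage site is known to impair slicing; the
lenient alternative is available as `gu_strict = FALSE`. All accepted
overlapping windows are reported (no non-maximum suppression), with the
best-scoring site per miRNA/transcript pair flagged. r6 is evaluated only on
r1–r5 survivors, with RNAduplex batched over candidate sites.

A note on orientation: the scan examines the given transcript strand only.
Mirror-image invariance under reverse complementation does not hold for this
scoring (G·U pairs have no mirror), so no such property is claimed or
tested; strand contracts are instead tested where they are exact, on genomic
mapping and precursor excision.

## Expression, significance and pattern types

TPM = count / total clean tags × 10⁶; summed over all clean tags of a
library this is exactly 10⁶, a normalization identity the tests verify to
1 part in 10⁶. Fold change is the TPM ratio (HT over NT); when either raw
count is zero, one pseudocount is added to both sides first so on/off miRNAs
have a finite, directional fold change (they are additionally flagged
`on_off`).

With one library per condition there are no replicates, so significance uses
an Audic–Claverie-style exact test conditional on library totals — the
standard choice for unreplicated SAGE/sRNA tag comparisons. It is
implemented through the negative-binomial identity for the posterior
predictive of the second count given the first, two-sided by doubling the
smaller tail. The pair is oriented canonically (conditioning on the library
with the smaller observed proportion, with a deterministic tie-break on
totals) so that swapping the contrast changes the fold change to its
reciprocal but leaves the p-value bit-identical. Under a simulated null
(equal proportions, 2 000 tags, 10⁶-tag libraries) the rejection rate at
α = 0.05 sits within three binomial standard errors of 0.05; the test is
mildly conservative at low counts, as all exact tag-count tests are. A miRNA
is a DEM when max(FC, 1/FC) ≥ 2 (inclusive) *and* p < 0.05 (strict). No
multiple-testing correction is applied to the calls, matching the stated
thresholds of the analysis this package systematizes; a Benjamini–Hochberg
column is emitted for information.

Pattern types place each miRNA's per-genotype response (induced / repressed
/ unchanged, reusing the DEM verdicts) in a 3×3 grid. Three cells are fixed
by convention anchors — induced in both genotypes is type I, repressed in
both is type IV, unchanged in both is type IX. The remaining six assignments
(II = induced only in the tolerant genotype, III = induced-tolerant /
repressed-sensitive, V = repressed-tolerant only, VI = repressed-tolerant /
induced-sensitive, VII = induced-sensitive only, VIII = repressed-sensitive
only) are this package's documented convention; on/off expression is a
sub-flag, not a separate type. Users comparing against other tabulations
should check the grid, not assume it.

The 2^−ΔΔCt utility computes relative expression against an internal control
and calibrator sample, averaging replicate Ct values per well class and
propagating their standard errors to the ΔΔCt scale.

## Network integration

An edge joins a significant DEM and a gene when the miRNA has ≥ 1 passing
site in the gene's transcript, the gene's |fold change| exceeds 1.5
(strictly; the DEG table is taken as provided and never re-called), and the
two move in opposite directions *within the same contrast* — negative
regulation is contrast-specific, and each edge records which contrast
satisfied it. The 1.5-fold cutoff applies to the gene side only; the miRNA
side already carries its own ≥ 2-fold threshold. Edges are also rolled up
per miRNA family.

## The synthetic data generator

The generator is first-class, tested code, and defines the study conditions
for all end-to-end checks. It emulates: a background genome (default 50 kb,
GC 0.45) carrying planted stem-loops — compliant hairpins built by explicit
reverse-complement arm design (a 19-pair duplex with engineered 2-nt 3'
overhangs inside a paired flank stem) and decoys violating exactly one
criterion each (three same-base stem mismatches for criterion 1; a 1-nt
shifted mature for criterion 2; two engineered 1-nt bulges for criterion 3;
sub-threshold read counts for criterion 4; AT-rich stems with long loops
whose C content steers GC for the MFE/MFEI classes) — plus embedded known
matures, a foreign catalog two substitutions away from the new-member
matures, non-coding RNA references, repeat and gene segments. Nothing about
a designed structure is assumed: every planted locus is verified *in
genomic context* with the same excision, trimming, folding and criterion
code the caller uses, and redrawn on disagreement (bounded retries, then an
explicit error naming the locus). This guards the planted truth against
folding-engine idiosyncrasies without ever tuning thresholds.

The four libraries sample miRNA reads multinomially from a designed
expression table in which the nine known miRNAs realize the nine pattern
types (induced = 40 NT / 400 HT counts, repressed mirrored, unchanged =
200/200, the type II representative expressed only under HT), star arms sit
at a constant 60 reads, and the criterion-4 decoy at 3/2 reads. Effect
sizes are deliberately large relative to multinomial noise so that designed
significance is stable across seeds; this is a property of the designed
study, not a tuned quantity. Filler classes exercise every cleaning rule
(poly-A, sub-18-nt, low-quality, adapter-only reads) alongside ncRNA
fragments, repeat/gene-body fragments and unmappable background. Transcripts
carry perfect-complement target sites for selected DEMs, one decoy site per
target rule (the rule-6 decoy is verified against the duplex engine at
generation time), a gene shared by two DEMs, a direction-concordant control
and a below-cutoff control; the DEG table holds the designed log2 fold
changes plus null genes.

What the generator does **not** emulate: sequencing error models, quality
score distributions, isomiR clouds around planted matures, multi-locus miRNA
families sharing one mature sequence, bulged target sites, and
genome-scale repeat structure. Passing the end-to-end tests therefore
demonstrates that the pipeline's logic is correct and self-consistent under
idealized signal — it does not calibrate sensitivity or specificity on real
sequencing data, where adapter chemistry, expression skew and structural
ambiguity are all harsher.

## Problem sizes and numerical conventions

The shipped test suite uses two presets chosen as the package's own working
scale: *tiny* (20-kb genome, 2 compliant + 2 decoy loci, 4 × 20 000 reads,
15 transcripts) for fast checks, and *demo* (50-kb genome, 5 compliant + 7
decoy + 2 new-member loci, 9 known miRNAs, 4 × 100 000 reads, 50
transcripts) for the full end-to-end recovery checks. Coordinates are
1-based inclusive externally (GFF3, reported tables) and converted at module
boundaries; minus-strand hits are reverse-complemented into transcription
orientation before folding. Ties are broken deterministically everywhere (a
locus anchor is the most abundant tag, then leftmost; the best window is the
lowest MFE; the best site is the lowest score, first window on ties), and
all generators are seed-deterministic down to output bytes, which the tests
assert. Undefined statistics (e.g. the 24/21-nt ratio with no 21-nt tags)
are reported as `NA`, never as an error or a sentinel number.

## Known limitations

* Exact-match mapping means sequencing errors in real data would lose tags;
  a mismatch-tolerant mapper can be slotted in upstream by providing already
  cleaned reads.
* MFE/MFEI values — and hence criterion 5 near its boundary — are folding
  engine- and version-dependent; the manifest records the engine so runs are
  comparable.
* The exact test is conservative for very low counts; with designed fold
  changes of ≥ 2 at ≥ 10 reads this does not affect calls, but users probing
  singleton tags should expect reduced power.
* Family assignment (single-linkage at ≤ 2 mismatches) can chain distinct
  families through intermediates in dense sequence neighborhoods; at typical
  plant miRNA divergence this is rare.
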