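---
title: "Methods: satellite discovery, k-mer feature libraries and CENP-A annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellite discovery, k-mer feature libraries and CENP-A annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(censatr)
```

## The problem

Centromeres of most complex genomes are built from megabase-scale tandem
arrays of satellite DNA monomers. Because the arrays are too repetitive to
assemble, linear genome assemblies carry "centromere gaps" and the
centromeric sequence itself survives only as unassembled shotgun reads and
unplaced (chrUn) contigs. `censatr` reconstructs a centromeric satellite
sequence database from such reads and annotates it functionally with
CENP-A chromatin state, in three phases:

1. **Sequence characterization** — detect tandem repeats, build a
   non-redundant monomer family library, annotate and classify reads, and
   anchor families to centromeres by (a) enrichment in assembly windows
   adjacent to centromere gaps and (b) mate-pair linkage networks seeded
   from gap-enriched families. Reads classified to anchored families, plus
   their mates (which capture adjacent non-satellite sequence), form the
   centromeric read database.
2. **Sequence feature library** — reformat the database into canonical
   50-mers (50 bp window, 1 bp slide), remove every k-mer that occurs
   verbatim in the assembly, and classify the remainder single- versus
   multi-copy against a calibrated single-copy depth model. Junction
   k-mers straddling satellite/non-satellite boundaries provide landmarks.
3. **Functional annotation** — score each library k-mer for CENP-A
   ChIP-seq enrichment against genomic background replicates sampled from
   the WGS reads, call k-mers enriched when they pass the threshold in
   two independent comparisons, classify reads CENP-A[+]/[−], and resolve
   monomer subtypes by consensus-anchored window clustering, distance
   phylogenies, and mate-pair subtype networks.

A synthetic genome module generates all inputs with complete planted
truth, so every stage is testable end to end.

## Models and key parameters

### Tandem repeat detection (`detect_tandem_repeats()`)

Candidate periods are the spacings at which exact 12-mers recur; each
candidate span is validated by folding it at the period and comparing to
the column-majority wraparound consensus. A hit requires `min_copies`
(default 3) copies and `min_frac_identity` (default 0.8) identity, with a
period ceiling of 2000 bp. This is a deliberately simple detector: the
contract is recovery of planted periods and spans, not score parity with
alignment-matrix engines, and the tests hold it to exactly that contract
(planted arrays with up to 5% substitution noise; zero hits on i.i.d.
random sequence).

### Family construction (`cluster_consensi()`)

Tandem consensi are clustered by single linkage over pairwise local
alignments, linking two consensi when they align at more than 95% identity
over at least 100 bp. Both strands are tried, and the shorter sequence is
aligned against the doubled longer one so every circular rotation is
reachable (monomer phase is arbitrary). Single linkage is the most
permissive deterministic reading of "grouping by pairwise alignment"; the
family consensus is the medoid. Note the consequence, which the tests
assert in both directions: subfamilies whose pairwise divergence is below
~5% merge into one family, while more divergent subfamilies split.

### Annotation (`annotate_sequences()`)

Seed-and-extend masking: exact 12-mer seeds of each library element locate
candidate regions; banded local alignment (match 1, mismatch −2, gap open
4, extend 1) validates them. Satellite elements are matched as tandem
concatemers. Spans require `min_identity` 0.8 over `min_span` 50 bp, and
overlaps are resolved highest-identity-first with trimming. A `"seed"`
mode skips the alignment and reports merged exact-seed runs — near-exact
matching used where millions of short ChIP reads only need family-level
classification. Reads are classified to the family covering ≥ 50% of
their length, `"mixed"` when two families each cover ≥ 25%, else
`"nonsatellite"`; the 50%/25% thresholds are package choices (no published
rule exists) and are exposed as arguments.

### Pericentric enrichment and the mate-pair network

Assembly chromosomes are tiled with `pericentric_window`-sized windows
anchored at the gap side (2 Mb at study scale; the synthetic scenario
scales this to 20 kb). Per family, fold = (mean masked bp per gap-adjacent
window + 1) / (mean per remaining window + 1); the 1 bp pseudocount keeps
folds finite for background-absent families. Significance is by permuting
the gap-adjacent flag (default 1000 permutations,
`p = (1 + #{fold* >= fold}) / (1 + N)`). With few chromosomes this
permutation test has a hard floor — a family whose signal sits in a single
window can never reach p < 0.05 with 2 gap windows among 14 — which is why
the synthetic scenario plants each family at both centromeres, as real
centromeric families recur across chromosomes.

Mate-pair networks count pairs between read class labels. Seed families
(gap-enriched, p < 0.05 and fold ≥ 2) are expanded by breadth-first
closure over edges carrying at least `min_pair_edge = 10` pairs,
traversing family nodes only. The centromeric read database is every read
classified to an anchored family plus every mate of such a read; the two
sources are kept disjoint so the accounting is exact.

### The 50-mer feature library

K-mers are canonical (lexicographic minimum of the k-mer and its reverse
complement): ChIP reads are strand-agnostic, collapsing halves the table,
and matching becomes symmetric. K-mers containing N are skipped. Assembly
subtraction removes k-mers with an exact canonical occurrence in the
assembly; unplaced (chrUn) contigs are excluded from the subtraction by
default since they are themselves gap sequence.

Single-copy calibration: the count of a k-mer from single-copy sequence
under coverage `c` and read length `L` has mean `c (L - k + 1) / L` (only
read windows fully containing the k-mer count). Three modes: `simulated`
(Poisson draws from the closed form, binomially thinned by the error-free
window probability), `observed` (counts of the k-mers of a known
single-copy locus — the simulator designates one; in the real system a
locus like *XIST* plays this role), and `pooled` (the average of both).
The pipeline uses pooled mode when a locus is supplied: a single locus of
a few kb carries regional coverage noise, and averaging with the closed
form halves that bias — which is also why both calibration sources exist
in the first place. Multi-copy is called strictly
above `mu + 2 sd`.

### CENP-A enrichment

Backgrounds are ten independent uniform draws without replacement from
the WGS read set, **depth-matched** to the ChIP library: each replicate
is drawn so its k-mer total sits slightly (10%) under the ChIP
table's total.
Without depth matching, the total-normalization term `T_bg / T_chip`
alone pushes scores toward enrichment (a k-mer absent from both tables
would score `log2(T_bg / T_chip)`), and at desk-scale ChIP depth that
lets isolated sampling coincidences on single-copy k-mers clear the
2-fold bar. Depth matching is the standard input-normalization practice
in ChIP-seq and removes the artifact at its source. Per k-mer and
replicate `r`,

```
s_r = log2( ((c_chip + 1) / T_chip) / ((c_bg,r + 1) / T_bg,r) )
```

with `T` the total k-mer count of each table. Log base 2 makes the
published ">2-fold" rule a threshold of 1.0. The background depth (0.9 of
the ChIP total) and the pipeline pseudocount (2) are calibrated jointly to
the method's specified operating point: a fold-1 (uniform) ChIP simulation
must call fewer than 1% of library k-mers enriched. Singleton k-mers are
covered by only ~2-3 ChIP reads at desk scale, and without smoothing their
shot noise clears a hard 2-fold cutoff far too often; the pseudocount
shrinks exactly those ratios while leaving multi-copy satellite k-mers
(counts in the tens to hundreds) untouched. A k-mer is *enriched* when `s_r >= 1`
in each of the first two background comparisons; the remaining replicates
estimate variance for family-level enrichment.

A read is CENP-A[+] when the union of positions covered by enriched
k-mers contains a continuous run of at least
`min_continuous_enriched_bp`, CENP-A[−] when it contains no enriched
k-mer, and CENP-A[−] with a logged `partial` flag in between. The package
default for the run threshold is **100 bp (two full k-mer lengths)**: one
isolated enriched 50-mer is the weakest possible evidence, and at desk
scale (where a single-copy k-mer is covered by only ~3 ChIP reads)
Poisson sampling noise makes isolated single-copy calls common, while
genuine domain reads carry runs of hundreds of bp. The
`classify_reads_cenpa()` function itself defaults to 50 bp (one k-mer),
the minimal reading.

### Monomer subtypes

Reads classified to a family group (discovered families are
subfamily-resolution, so families linked at 75% identity are pooled —
they are rotations/variants of one monomer) are anchored onto the group
consensus by local alignment against the doubled consensus, absorbing the
circular register; anchors require identity ≥ 0.7 over ≥ 100 bp. Each
read is projected into consensus coordinates (insertions dropped,
deletions gapped) and contributes a row to every full 200 bp window
(slide 100) it covers by ≥ 90%. Positions a read does not reach — up to
10% at window edges — are imputed with the column consensus; without
imputation the edge-gap runs of partially covering reads form tight
artificial k-means clusters.

Rows are one-hot encoded (A, C, G, T, gap), so squared Euclidean distance
is twice the Hamming distance. For each k in `k_range`, `stats::kmeans`
(Hartigan–Wong, 10 restarts, seed derived from the master seed and k) is
scored by mean silhouette on squared Euclidean dissimilarities, and the
best k wins (ties to the smaller k). Hartigan–Wong with multiple restarts
replaces a k-means++ single-shot initialization: it is the standard R
implementation, and best-of-restarts by within-cluster sum of squares is
at least as robust; determinism comes from the derived seed. Cluster ids
are renumbered by decreasing size, and a read's subtype is the ordered
concatenation of its cluster ids across windows.

Distances between rows use the F84 model with base frequencies pooled
over the pair and pairwise deletion of gap sites; saturated pairs return
`Inf`. Under uniform composition F84 reduces exactly to Kimura's
two-parameter distance, which the tests exploit as a closed-form oracle
(and `ape::dist.dna(model = "F84")` serves as an independent
cross-check). Trees are UPGMA (`phangorn::upgma`) and neighbor joining
(`ape::nj`, negative branches clamped to 0), with column-resampling
bootstrap supports (`ape::boot.phylo`, 100 replicates by default).

Subtype mate-pair networks weight nodes by read depth and keep edges with
at least `min_pair_edge` pairs; transitional reads are CENP-A[+] reads
mate-paired to CENP-A[−] reads, and in the synthetic scenario they
concentrate on the planted block boundaries.

## The synthetic scenario

`simulate_scenario()` is the package's reference study condition:

* 2 chromosomes of 200 kb; each ends (acrocentrically) in two satellite
  arrays — family `CenSatB` proximal to the flank, `CenSatA` distal —
  with templates shared across chromosomes, since centromeric families
  recur genome-wide.
* Each array is (S2 × 25, S1 × 8, S2 × 25) monomers of 738 bp (the
  CarSat1 unit length). Subfamily templates diverge 5% from a common
  ancestor (~10% pairwise); monomers carry 0.5% within-subfamily noise
  (homogenized arrays).
* The S1 blocks of both families are the CENP-A domains — the minority of
  each array, mirroring the finding that CENP-A occupies a subset of
  monomer types. One 400 bp TE is inserted in the chr1 `CenSatA` array
  outside the domain.
* The assembly keeps the flanks plus two monomers of the proximal array
  edge at each gap (real assemblies capture some satellite adjacent to
  gaps — the signal pericentric enrichment measures) and re-emits 25% of
  array bp as 1–5 kb unplaced contigs.
* WGS: 7.5× coverage of 500 bp paired reads with 2 kb ± 200 bp inserts
  and 0.5% substitution error (Sanger-era WGS, like the 7.5× study
  data). The insert length balances two constraints: long enough that
  array-junction mate pairs reliably exceed the 10-pair network edge
  threshold, short enough that block-boundary pairs stay a small
  minority of within-array pairs. ChIP: 50,000 single-end 72 bp reads
  with 10-fold higher start density inside CENP-A domains.

What the simulation does *not* emulate: indels and platform-specific
error profiles (substitution-only by default, keeping exact 50-mer logic
interpretable), higher-order repeat periodicity (the block model is an
assumption; real homogenization structure is not quantified), chromatin
recovery bias in ChIP (uniform recovery is assumed), and assembler
behavior (chrUn contigs are random array sub-spans). Passing tests
therefore demonstrate the pipeline's correctness under its own model
assumptions, not robustness to every artifact of real sequencing data.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere, including BED/BEDGraph
  output; converters to 1-based closed reports are provided and
  round-trip tested.
* Canonical k-mers collapse strands; a literal stranded reading can be
  recovered by counting on the raw k-mers, but all pipeline logic uses
  canonical form.
* Pseudocounts: 1 bp per window in pericentric folds, 1 count in k-mer
  score ratios — both keep ratios finite for absent features and are
  configurable.
* Tie-breaks: silhouette ties choose the smaller k; UPGMA merge ties
  follow `hclust`'s deterministic index order; cluster renumbering is by
  size, then first occurrence.
* Degenerate inputs: empty FASTA warns and returns an empty table;
  windows longer than a chromosome fall back to one whole-chromosome
  window with a warning; zero-margin TE co-occurrence tables report `NA`
  fold (with a Haldane-style continuity ratio when only the outside count
  is zero); reads shorter than k classify CENP-A[−] with a warning;
  saturated F84 distances are `Inf`.
* Problem sizes: the scenario runs ~6,000 WGS reads and 50,000 ChIP
  reads; subtype clustering caps at 1,200 anchored reads per family group
  and 400 rows per window (deterministic subsamples), and the pipeline's
  k-means search uses k = 2..8 — sizes chosen so a complete end-to-end
  run finishes in minutes on one core while every recovery statistic
  retains comfortable statistical power. Study-scale constants (2 Mb
  windows, k = 2..20) remain expressible through `censat_config()`.

## Known limitations

* The tandem detector reports the modal 12-mer spacing as the period; at
  very high divergence (>15%) seeds vanish and arrays are missed.
* `cluster_consensi()` is O(n²) in the number of consensi.
* Exact integer k-mer counting holds tables in memory; study-scale
  (~20M+ k-mers) would need a disk-backed store.
* The permutation test for pericentric enrichment is only as granular as
  the window count; genomes with few chromosomes have a coarse p-value
  floor.
* Family-level ChIP enrichment classifies reads by near-exact seed
  matching; its sensitivity differs slightly between 72 bp ChIP reads and
  500 bp WGS reads, so family folds are mildly conservative.
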