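---
title: "Methods: contamination screening, SL detection and co-expression analytics for de novo transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contamination screening, SL detection and co-expression analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(transqc)
library(dplyr)
```

transqc implements the downstream analytics that accompany a de novo
transcriptome assembly of a non-model eukaryote such as *Euglena
gracilis*: sequence-level quality summaries, contamination screening,
spliced-leader (SL) detection, composition and taxonomy analysis,
expression transformation, k-medoids co-expression clustering with a
correlation-ratio choice of k, and term enrichment with a kappa-score
term network. Assembly itself (read cleaning, Trinity/EvidentialGene,
alignment, abundance estimation) is out of scope: the package starts
from a FASTA of transcripts, tabular alignment hits, SAM alignment
scores, and a TPM matrix.

Every stage has a seeded generator producing synthetic inputs with the
statistical structure the stage assumes, so the whole pipeline is
testable on a laptop with no downloads.

## Assembly summaries

`summarize_assembly()` reports sequence counts, length statistics, the
N[z] family and pooled GC. N[z] is the minimum contig length needed to
cover z% of the total assembly length: lengths are sorted descending and
the first length at which the cumulative sum reaches z% of the total is
returned (the usual N50 convention, with the threshold met inclusively).
Pooled GC is base-weighted over the whole set — the GC of the
transcriptome as a whole — rather than a mean of per-sequence values;
per-sequence GC is kept for the composition module. Size-class counts
use strict inequalities (< 200 nt, > 1000 nt, > 10,000 nt). Mean length is
reported both exactly and integer-rounded, since repository summaries
print integers.

## Contamination screening

Transcript-level screening works on BLAST hits against a broad
nucleotide database. The best hit per query is the one with the highest
bit score (ties: lowest e-value, then file order). Conservative
thresholds — e-value at most 1e-50 and identity at least 90% — keep only
confident matches; organism names are tallied and the most abundant
organisms whose name does not contain a target substring (by default
"Euglena") are flagged, together with the transcripts whose best hit
points at them. Matching is done on organism names rather than taxids
because screening databases report `sscinames` reliably and taxids only
sometimes.

Read-level decontamination follows the local aligner's default minimal
score: a read of length L aligning to a contaminant genome is removed
iff its alignment score strictly exceeds `20 + 8 ln(L)` (natural log);
boundary scores and unmapped reads are kept. Removal is reported in
reads per million, `floor(removed / total * 1e6)`, with the
pre-processed read count as denominator — the convention that reproduces
the published per-experiment rates.

## Spliced-leader scanning

In euglenozoans a short leader RNA is trans-spliced onto the 5' end of
nuclear pre-mRNAs; its remnant on an assembled transcript marks a
complete 5' end. Because assembled transcripts are unoriented, each
transcript and its reverse complement are truncated to the first 40 nt
and scanned for maximal exact substrings shared with the SL sequence at
a minimum length (conventional thresholds 12, 14 and 24 nt for the 24-nt
*Euglena* SL). Matches are not anchored at position 0 — the 5'
constraint is the truncation itself. One match per orientation per
transcript is reported (longest, then leftmost), so sub-matches of a
single SL hit cannot inflate counts; a transcript may still count once
forward and once reverse, and summaries expose both match counts and
distinct matched transcripts. Ambiguity codes never match. The SL
sequence is a required input, not a constant: different euglenozoans
use different leaders.

```{r}
sl <- "ACACTTTCTGAGTGTCTATTTTTG"
sim <- sim_transcripts(n = 200, sl_fraction = 0.2, sl_seq = sl, seed = 1)
sl_summary(scan_sl(sim$transcripts, sl, min_match = 12), 200)
```

## Taxonomic affiliation

`assign_lca()` is a MEGAN-like last-common-ancestor classifier: for each
query, hits below a bit score of 80 are dropped and, of the survivors,
those within 95% of the best bit score (inclusive, multiplicative — the
standard top-percent semantics) support the assignment. The LCA is the
deepest node on the intersection of the supporting taxa's root paths.
Assignments are binned into broad groups with specific lineages
(Viridiplantae, Kinetoplastida) checked before the Eukaryota fallback,
then Bacteria and Archaea, then "other cellular organisms". Hits without
a taxid are skipped with a warning — reference databases vary in how
completely they carry taxonomy — and queries with no usable hit are
"unclassified". Organelle-encoded proteins are only called on
near-perfect evidence: identity of at least 99% and an alignment
covering query and subject end-to-end at strictly identical lengths.

## Composition analysis

Tetranucleotide frequencies (TNF) are the classic composition signature
for spotting sequences of foreign origin. `tnf_profiles()` counts all
overlapping 4-mers containing only A/C/G/T on the forward strand (no
reverse-complement canonicalisation, matching the common word-count
tool's default) and normalises per transcript; windows containing
ambiguity codes are skipped, and a transcript with no valid 4-mer has an
undefined profile rather than a zero one. Transcripts are also ranked by
GC and split into four equal-sized partitions (remainder to the
lowest-GC blocks, stable ties).

`tnf_pca()` repeats a covariance PCA on sub-samples of 1000 transcripts
(repeat r uses seed `seed + r - 1`). Frequencies are centred but not
scaled to unit variance — the 256 coordinates are commensurate — and
each component's sign is fixed so its largest-magnitude loading is
positive, making repeated runs comparable. On data with a GC gradient,
PC1 tracks GC almost perfectly, which is exactly why composition alone
could not separate contaminants from genuine transcripts in the
motivating study: the taxonomic signal is mixed along the same axis.

## Expression handling

Isoform TPM values are pooled to gene level by summation (conserving
per-sample totals), log2-transformed with a pseudocount of 1 (TPM of
zero is common; the pseudocount is exposed), and z-scored per sample
with the population (n-denominator) standard deviation — the wording of
the source procedure is ambiguous between population and sample
denominators, so the choice is pinned and configurable. Zero-variance
samples map to zeros rather than NaN. The 2500 most variable genes
(row variance of the transformed matrix, ties broken by gene id) feed
clustering; separately, a transcript counts as expressed iff its maximum
TPM across samples reaches 1 ("below 1 TPM" excludes, the boundary is
kept).

## Co-expression clustering and the choice of k

Gene-gene dissimilarity is `d = 1 - r^2` on Pearson correlation across
samples, so perfectly anti-correlated genes are as close as perfectly
correlated ones — co-regulation in either direction is proximity.

`pam_cluster()` is partitioning around medoids. For small problems (at
most 20,000 candidate medoid sets) the optimal set is found exhaustively,
so the cost is the global minimum; beyond that the classic deterministic
local search is used: greedy BUILD seeding followed by best-improvement
SWAP until no single exchange lowers the cost, all ties to the lowest
index. The exact path exists because the local search — in any
implementation, including the reference one — misses the global optimum
on roughly a tenth of small random dissimilarity matrices, and at sizes
where enumeration is cheap there is no reason to accept a local optimum.
Both paths are seed-free and reproducible.

`select_k()` scans k (by default 5..75) and computes, per solution, the
average over non-singleton clusters of the maximum pairwise |r| (w-k
cor_max), the average over medoids of the minimum |r| to the other
medoids (b-k cor_min), and their ratio b/w — a reinterpretation of the
Dunn index on the correlation scale, minimised, ties to the smallest k.

```{r}
x <- c(1, -1, 1, -1); y <- c(1, 1, -1, -1)
m <- dplyr::bind_cols(tibble::tibble(gene_id = paste0("g", 1:4)),
                      tibble::as_tibble(as.data.frame(rbind(x, -x, y, -y))))
sel <- select_k(m, k_min = 2, k_max = 3)
glance(sel)
```

A caveat established while validating this criterion on planted
clusters: because the within statistic takes per-cluster *maxima* and
the between statistic per-medoid *minima*, merging two clusters leaves
the within term at its ceiling (a merged cluster still contains a
tightly correlated pair) and splitting one never raises any between
minimum (the new medoid is highly correlated with its twin, and minima
ignore large values). The ratio therefore has no structural parsimony
penalty: on cleanly planted, near-orthogonal clusters its argmin over a
scan is driven by sampling noise and frequently lands above the planted
k (recovering the planted number in only about 1-2 of 10 seeded runs in
our simulations, though the adjusted Rand index of the selected
solution stays fairly high because over-clustering splits off small
satellites). On rich real data with hierarchical correlation structure
the curve can still show a usable minimum, but the criterion should be
read as "smallest adequately separated solution", with the tie-break to
the smallest k doing real work. The scan table and `autoplot()` method
expose the whole curve so users can judge the minimum rather than trust
the argmin.

Heatmap ordering uses agglomerative clustering with correlation distance
`1 - r` and centroid linkage, returning the dendrogram leaf order.

## Enrichment and the kappa term network

Term over-representation per cluster is the upper-tail hypergeometric
test: k genes of the cluster carry the term, out of n annotated cluster
genes, K term carriers in a background of N annotated genes (the
analysed, annotated gene set — the "whole term space" background).
Tested terms must sit between levels 3 and 12 of the ontology hierarchy
(levels are supplied with the annotations; no ontology-file reasoning is
done) and cover at least 3% of the cluster. Benjamini-Hochberg
adjustment is applied within each cluster's tested set, and a term is
significant at an adjusted p of at most 0.05.

Significant terms form a network in which an edge joins two terms whose
gene-membership indicators agree beyond chance: Cohen's kappa over the
analysed universe, with edges at kappa of at least 0.3 (inclusive). The
full parent-child fusion logic of interactive tools is simplified to a
documented approximation: when one significant term's gene set is
contained in another's and the pair is connected, the node table records
the more specific (deeper-level) term as the label for the pair. Degree
and connected components come from the graph itself.

On the null — uniformly random annotations — the raw hypergeometric
p-values hold their size. Because the statistic is discrete, the
attainable level sits slightly below the nominal 0.05; the null
simulations in the tests use large counts (background 2000, term size
500, cluster 240; attainable level 0.0492) so the discreteness gap is
well inside the binomial uncertainty of 1000 simulations, and each
simulation contributes one independent test.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their parameters and a seed, and
every planted feature is recorded in a truth table only — record headers
carry no truth, so parsers cannot cheat.

- `sim_transcripts()`: log-normal lengths; per-transcript GC targets on a
  uniform gradient (0.40-0.70 by default, bracketing the 58-64% GC of
  the motivating assemblies); a fraction of transcripts receive the SL
  (or one of its suffixes of at least 12 nt) at the 5' end, half in
  reverse-complement orientation; contaminants get distinct GC (0.30)
  and foreign taxids.
- `sim_hits()`: a best hit to the planted source taxon plus noise hits
  at least 6% below it in bit score, so the top-fraction rule excludes
  them; narrowing the gap below 5% is the controlled violation used to
  show the LCA climbing.
- `sim_expression()`: 23 samples over five studies (6/2/1/10/4) with the
  fermentative/heterotrophic/mixotrophic/phototrophic layout of the
  emulated compendium; cluster archetypes are iid standard-normal sample
  patterns, genes follow their archetype up to a random sign flip
  (exercising `1 - r^2`) plus per-gene study-level batch shifts and iid
  noise; TPM is `2^profile`, scaled positive.
- `sim_read_alignments()`: integer alignment scores placed strictly
  above or at/below `20 + 8 ln(L)`, so the removed set equals the
  planted truth exactly.

What the generators do **not** emulate: sequencing error, isoform
structure, coverage-dependent assembly artefacts, phylogenetic
correlation among database hits, heavy-tailed TPM distributions, or the
unbalanced batch-condition confounding of real compendia. Passing tests
on these inputs demonstrate algorithmic correctness against the planted
structure, not robustness to everything real data does.

## Numerical choices and problem sizes

Tolerances: exact comparisons are used wherever arithmetic is exact
(RPM floors, Nxx, BH on rational examples); correlation-based checks use
the documented thresholds (|r| > 0.9 for the GC axis). Degenerate
inputs are mapped to explicit markers, not zeros: GC of an all-ambiguous
sequence is NA, a TNF profile with no valid 4-mer is NA, a zero-match SL
summary has an NA mean, zero-variance columns z-score to zero, and
zero-variance PCA input yields zero coordinates with zero explained
variance. Ties break deterministically everywhere (lowest index,
lexicographic ids, smallest k), so reruns are byte-stable.

The validation suites run at desk scale: oracle cross-checks use 1000
random transcripts (SL), 100 random matrices with n of at most 10 (PAM
vs exhaustive enumeration), the full enumeration grid up to N = 12
(hypergeometric), 10 seeded replicates of 40 genes over a k-scan of 2-8
(planted clusters), and 1000 null simulations (enrichment size). These
sizes were chosen so the whole suite completes in about a minute while
keeping every Monte-Carlo margin comfortably away from its threshold.

## Known limitations

- The k-selection ratio is reported faithfully but, as discussed, is a
  weak model-selection statistic on clean planted structure; inspect the
  scan curve.
- PAM's local-search path (used when enumeration is infeasible) is a
  heuristic; its cost can exceed the global optimum.
- Term-network fusion is a subset-based approximation of interactive
  tools' parent-child fusion and is flagged as such in the result
  metadata.
- SL scanning is exact-match only; mismatch-tolerant detection (and
  polyA handling) is out of scope.
- No batch correction is applied to expression data; the emulated
  study's own attempt was ineffective and abandoned, and the package
  follows the published procedure.
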