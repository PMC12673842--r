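---
title: "Methods: transcript-level DE interpretation in isoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript-level DE interpretation in isoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and assumptions

`isoscope` interprets transcript-level differential-expression results; it
does not produce them. The upstream quantifier and tester (short-read
pseudo-alignment with resampling-aware testing, or long-read pipelines
aligned to a reference transcriptome) are assumed to emit, per feature, a
log2 fold-change, a p-value and a multiplicity-adjusted q-value. Two such
tables — one keyed by transcript accession, one by gene accession — plus a
GENCODE-style reference are the inputs. The toolkit assumes a genome with
high-quality transcript-class annotation (human and mouse in practice);
everything downstream leans on the annotated transcript biotype.

Accession versions (`ENST…​.2`) are preserved in storage, but every join
runs through a version-stripped index, because DE tools variably strip
versions. Coordinates are stored exactly as GTF gives them — 1-based,
inclusive at both ends — and GFF3 input is normalized to the same
convention at import, so there is a single coordinate convention in the
package.

# Biotype categories and significance thresholds

Transcript biotypes are normalized through an editable mapping table
(`inst/extdata/biotype_categories.tsv`) into the categories
`protein_coding`, `lncRNA`, `retained_intron`, `nonsense_mediated_decay`
and `CDS_undefined`; unmapped biotypes fall to `other`. The mapping table
exists because the CDS-undefined class is spelled differently across
GENCODE releases (`processed_transcript` historically,
`protein_coding_CDS_not_defined` in recent releases); shipping the table
as config defers release-specific vocabulary to the user.

Significance is a pure function of (category, |log2FC|, q):

* coding-locus categories (`protein_coding`, `retained_intron`,
  `nonsense_mediated_decay`, `CDS_undefined`, and the `other` fallback):
  |log2FC| ≥ 1 and q < 0.05;
* `lncRNA`: |log2FC| ≥ 0.5 and q < 0.05.

The relaxed lncRNA bound reflects their systematically lower expression;
requiring a full doubling would discard biologically relevant lncRNA
isoforms. Three decisions here were genuinely open and are fixed as
follows. First, the retained-intron, NMD and CDS-undefined classes take
the mRNA thresholds because they arise at coding loci; the
`ThresholdPolicy` class makes this overridable. Second, the relaxed lncRNA
rule is applied to the *absolute* fold-change — treating down-regulation
asymmetrically would be indefensible. Third, boundary semantics are fixed
as inclusive on the fold-change (≥) and strict on the q-value (<); the
test suite pins all six boundary combinations on a hand-written table.

Rows with missing q-values are flagged not significant (and counted in a
warning) rather than dropped, so table shapes are preserved.

# Isoform-switch candidates (DET without DEG)

`detWithoutDeg()` returns the significant transcripts whose parent gene is
not significant in the gene-level table. Gene-level significance uses the
coding-locus thresholds for all genes: the gene-level log2FC is dominated
by the locus's aggregate behaviour, and applying per-biotype rules to a
gene summary would mix levels of description. A gene absent from the
gene-level table is treated as not differentially expressed but the row is
flagged `untested` instead of `no`, so users can exclude those candidates;
silently dropping them would hide exactly the genes most often missed by
gene-level pipelines. When a `contrast` column is present, all operations
group by it.

Transcripts that an upstream collapser grouped into equivalence clusters
(near-identical isoforms whose read assignment is unstable) can be removed
before interpretation with `removeCollapsedClusters()`; membership ids
absent from the table are ignored with a warning rather than an error,
since cluster files routinely cover transcripts filtered earlier.

# Stratified preranked enrichment

No curated pathway database exists at transcript level, so gene-level GMT
sets are projected onto transcripts: each set's genes are replaced by all
their transcripts whose category matches the stratum under test. Strata
are the four coding-locus categories, `lncRNA`, and `non_coding_group`,
which pools retained-intron, NMD and CDS-undefined — the three main
products of alternative mRNA processing — to contrast their collective
behaviour with the protein-coding stratum. The projection inherits the
limits of gene-level annotation: it assumes protein-coding transcripts
mirror their gene's function and says nothing transcript-specific.

The ranking statistic is the log2 fold-change, descending, over **all**
tested transcripts of the stratum (a preranked walk needs the full
background, not only the significant rows); ties break by ascending
q-value and then lexicographic transcript id, making the ranking fully
deterministic. The statistic is the classic weighted running sum: walking
the ranked list, a set member at rank *i* adds
$|s_i|^p / \sum_{hits} |s|^p$ and a non-member subtracts $1/(N - N_h)$;
the enrichment score is the value of maximal absolute deviation (signed).
The weight exponent defaults to $p = 1$, the conventional preranked
choice; $p = 0$ gives the unweighted Kolmogorov–Smirnov-like statistic.

The null distribution draws `nPerm` random member sets of the observed
size without replacement from the ranked list. The p-value is one-sided on
the observed sign with +1 smoothing,
$p = (1 + b)/(1 + B_s)$, where $B_s$ counts matching-sign null scores and
$b$ those at least as extreme — the smoothing avoids zero p-values at
finite `nPerm`. NES divides the observed score by the mean magnitude of
the matching-sign null; when that null is empty NES is reported missing
rather than inventing a scale. Benjamini–Hochberg adjustment is applied
within each stratum, not globally, because strata answer different
questions and their p-value ensembles should not compete.

## Numerical choices

The walk is implemented in compiled code with plain double accumulation.
This matters twice. First, base `cumsum()`/`sum()` accumulate in extended
precision, so a vectorized walk is not reproducible step by step by an
independent scalar re-implementation; with double accumulation the profile
is exactly re-derivable. Second, the permutation null must use arithmetic
bit-identical to the observed score's: on small, discrete nulls, a
last-ulp difference flips `≥` comparisons and shifts p-values by whole
grid steps (1/15 for a 6-choose-2 null). The null path and observed path
therefore share one kernel; the test suite asserts bit-identity between
them and exact agreement with a brute-force oracle, and checks the
statistic against an independent library implementation.

Degenerate inputs error loudly: a set covering the whole ranked list (the
miss decrement is undefined), an empty intersection, or all-zero hit
weights at $p \ge 1$. An empty stratum yields zero result rows plus a
warning. One RNG stream, seeded once per `runEnrichment()` call, drives
all permutations, so identical calls give identical tables.

# Plot models

The three displays are built as declarative `PlotModel` objects — ordered
mark tables (bars, rectangles, segments, whiskers, labels) with geometry
in data units — and rendering is a thin, statistics-free pass over the
marks. This makes the figures testable as data (mark counts, coordinates,
opacities) instead of pixels. Choices the display conventions left open:
the "standard deviation arrows" of the expression profile are modeled as
symmetric whiskers at mean ± 1 sample SD (n−1 denominator; a one-sample
group gets a degenerate whisker at SD 0); intron segments span exactly the
gap between consecutive exons with no chevrons, strand being conveyed by
the row label and the ordering rule (rows sorted by genomic start, so
plus-strand models read left→right and minus-strand models start at the
right); and a gene present among transcripts but absent from the
gene-level table is drawn as a zero-height bar with a distinct
`gene_untested` colour key rather than omitted.

# The synthetic-data generator

The simulator emulates the *structure* of a transcript-level study of a
well-annotated organism: 150 genes on two synthetic chromosomes with 2–5
isoforms each (first isoform always protein-coding, the canonical form),
up to 8 non-overlapping exons per transcript drawn from a shared
per-gene skeleton, and biotype proportions (45% protein-coding, 20%
lncRNA, 15% retained-intron, 10% NMD, 10% CDS-undefined) chosen once as a
plausible composition of a transcript-level DE table at coding loci.
Twenty genes carry a planted isoform switch — the canonical isoform gets
log2FC ≥ 3 with q < 0.01 while the gene row stays null — and one GMT set
consists exactly of the switch genes. Null rows draw log2FC from
Normal(0, 0.2) and q-values uniform on (0.05, 1]: keeping null q-values
above the significance boundary makes chance candidates impossible *by
construction*, which is deliberate — the fixtures test recovery, and
boundary behaviour is tested separately with hand-written rows. TPMs are
log-normal with multiplicative noise; case-group means of switch isoforms
are scaled by $2^{\mathrm{effect}}$.

What the simulator does **not** emulate: expression covariance between
isoforms of a gene, realistic q-value distributions under partial signal,
overlapping genes, multi-mapping ambiguity, or read-level artifacts.
Passing tests therefore demonstrate correctness of the interpretation
logic under its stated contracts, not robustness of upstream DE calling on
real data.

All outputs are byte-deterministic given the seed; truth tables are
first-class outputs so checks never re-derive the planted signal.

# Problem sizes and verification scale

The test suite verifies the enrichment statistic against a brute-force
oracle on 220+ random instances (N ≤ 50), checks Monte-Carlo p-values
against the exhaustive 15-combination null at N = 6 with 50 000
permutations, and measures the permutation null's type-I error on ≥ 2 000
random sets over null-simulated tables (expected within [0.03, 0.07] at
α = 0.05). Switch recovery and planted-set enrichment run at the
simulator's default scale (≈ 500 transcripts, 25 sets, 1 000
permutations). These sizes were chosen so the full statistical story —
exactness, calibration, recovery — is demonstrated at desk scale.

# Known limitations

* Reference fetching (`fetchReference()`) is best-effort plumbing; nothing
  else depends on the network and no test exercises a download.
* Non-GENCODE FASTA header dialects (Ensembl, RefSeq) are out of scope, as
  are sequence-level operations (ORF finding, indexing).
* The enrichment projection is gene-level annotation in transcript
  clothing; it cannot discover transcript-specific function.
* `writeGtf()` serializes the package's canonical layout; arbitrary
  third-party GTFs are parsed faithfully but not round-tripped
  byte-exactly (comments and attribute order are not preserved).
* Uncertainty from upstream resampling (inferential replicates) is not
  propagated; the q-values are taken at face value.
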