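---
title: "Validating and mapping flanking sequence tags: methods and design"
author: "flanktag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and mapping flanking sequence tags: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flanktag)
```

# The problem

Insertional mutagenesis with T-DNA or transposons produces thousands of
transgenic lines, each carrying the element at an unknown genomic location.
A flanking sequence tag (FST) is a read spanning the junction between the
inserted element and the host genome, typically obtained by adaptor-ligation
or tail-PCR and Sanger sequencing. Each raw FST is a composite molecule: a
stub of the element's border sequence at one end, the unknown genomic
flank in the middle, and the PCR adaptor at the other end — or, for failed
events, binary-vector backbone in place of genome. Before any biology can
be read off, every FST must be cleaned, classified, placed on the genome,
and interpreted against the gene annotation. `flanktag` automates that
pipeline for batches from a few dozen to tens of thousands of reads.

# Quality trimming

Reads arriving with per-base Phred qualities (FASTQ, PHD) are trimmed by
the modified-Mott algorithm: with error probability
$p_i = 10^{-q_i/10}$ at base $i$ and threshold $p_0$, the retained read is
the contiguous segment maximizing $\sum_i (p_0 - p_i)$. Bases better than
the threshold contribute positively, worse bases negatively, so the
maximal-scoring segment is the longest stretch that is good *on balance*.
The threshold defaults to $p_0 = 0.03$ (Phred ≈ 15.2). A read whose every
base is worse than $p_0$ trims to length zero. Tie-breaking between
equal-scoring segments is leftmost start, then longest — an arbitrary but
fixed rule that makes trimming deterministic. The implementation is a
linear prefix-sum scan; tests compare it against an exhaustive $O(n^2)$
segment search.

# The validating stage

Three optional construct sequences may accompany a batch: the **border**
(terminal element sequence expected at one read end), the **adaptor**
(ligated oligo at the other end), and the **vector** backbone. Each is
locally aligned against each trimmed read and all alignments at or below
the role's e-value cutoff become mask intervals. The defaults — 10.0 for
border and adaptor, 1e-10 for vector — are deliberately asymmetric: border
and adaptor stubs can be very short (a dozen bases at a read end), so their
threshold is permissive, while a vector call discards the read and
therefore demands essentially certain identity. Border and adaptor masks
reaching within 3 bp of a read end are extended to that end, since the
unaligned terminal residue belongs to the synthetic construct, not to the
genome.

Classification applies a fixed priority:

* **LOW** — the post-trim read is shorter than the MSL. This interprets
  "low quality" as failure before masking even begins, which keeps quality
  failures distinct from short inserts in the batch report.
* **VECTOR** — vector masks cover more than half of the read outside the
  border/adaptor masks. The one-half rule is this package's own threshold;
  it tolerates short chimeric genomic fragments while catching backbone
  reads, whose coverage in practice is near-total.
* **A** / **NA** — the genomic segment (the longest unmasked run; ties go
  to the leftmost) is at least / shorter than the MSL (default 30 bp,
  the shortest segment that still maps essentially uniquely in a
  several-hundred-Mb genome at the default mapping cutoff).

Per-read results report the 1-based border end, adaptor start, and insert
length; masked FASTA output writes construct sequence in lower case so that
upper-casing reproduces the input exactly.

# The alignment core

The pipeline carries its own nucleotide local aligner so that nothing
outside the package is required; an adapter to NCBI BLASTN (tabular output)
is provided for users who prefer it. The internal aligner is seed-and-
verify: an index of all k-mers (word size 11, BLASTN-like) over the
subjects; query seeds grouped by subject and diagonal band (±50, split on
subject gaps beyond the query length plus 200 bp); and each cluster
resolved by *exact* affine-gap Smith–Waterman over a subject window
spanning the cluster plus a query-length margin. Resolving clusters by full
DP rather than X-drop extension trades a little speed for an exactness
guarantee: whenever an alignment contains at least one exact word-size
seed, its score equals the global Smith–Waterman optimum, which the test
suite verifies against the standalone `smith_waterman()` oracle (itself
cross-checked against `Biostrings::pairwiseAlignment`). Overlapping hits on
the same subject and strand (>50% of the shorter interval) are
deduplicated keeping the higher score. The minus strand is searched by
reverse-complementing the query, keeping the index single-stranded.

Scoring defaults are match +2, mismatch −3, gap open 5, gap extend 2.
Significance uses the Karlin–Altschul form $E = K m n e^{-\lambda S}$ with
$m$ the query length and $n$ the total subject length; $\lambda$ is solved
at package default from $\tfrac14 e^{\lambda\,\mathrm{match}} +
\tfrac34 e^{\lambda\,\mathrm{mismatch}} = 1$ (uniform base composition) and
$K = 0.71$ is treated as configuration. These e-values are compared only
against the pipeline's permissive thresholds (10, 1e-10, 1e-5), where the
exact value of $K$ is immaterial; `N` bases never count as matches and
never seed.

# The mapping stage

Only the genomic segment of each acceptable FST is aligned to the genome,
with e-value cutoff 1e-5. The highest raw score selects the integration
site; if a second hit ties the top score at a distinct locus (subject
overlap ≤ 50% with the top hit) the FST is a **repeat** and receives no
coordinate — raw integer scores make this tie test exact and reproducible.
No hits at the cutoff leaves the read **unmapped**, reported separately
from the six insertional types.

The reported coordinate is the genome base aligned to the query base
adjacent to the border mask — the junction base, which is the biologically
meaningful breakpoint; without a border the query-5'-most aligned base is
used. On a minus-strand hit the junction maps to the high-coordinate end of
the subject interval.

Categorization against the gene models applies a fixed precedence. A
position inside a transcript is **exon** (with CDS/5'UTR/3'UTR detail from
the CDS bounds) or **intron**; overlapping transcripts resolve to the gene
with the nearer ATG. Otherwise the strand-aware flanks are tested:
**upstream5** within 1,000 bp 5' of an ATG, **downstream3** within 300 bp
3' of a stop codon, competing flanks resolved by smaller distance with ties
to upstream5 (the promoter-side call is the more consequential
interpretation). Everything else is **intergenic**, reported with the
nearest gene and a signed distance (negative when the gene lies 5' of the
site on the forward strand). Annotation is ingested from GFF3 (longest
transcript per gene, matching the one-structure-per-gene convention of FST
databases) or BED12 (thickStart/thickEnd as CDS); genes lacking a CDS keep
transcript bounds and are flagged. Coordinates are 0-based half-open
internally and 1-based inclusive in every report.

# Statistics and figures

The type summary groups exon, intron, upstream5, and downstream3 as
*genic*; percentages are computed on genic + intergenic + repeat and
rounded half-up to one decimal (so recomputing published-style tables
reproduces their printed values). The chromosome summary reports insertions
per Mb at one decimal; note that densities are *always* insertions per Mb.
The frequency profile counts insertions in 500-kb windows advanced by
100 kb from position 0 of each chromosome; trailing windows are truncated,
not dropped, and an interior insertion therefore appears in exactly five
windows. Window anchoring at 0 is a convention choice; the figures are
insensitive to it at these scales. Both figures (chromosome distribution
map with one tick per insertion; per-chromosome frequency line graph) are
rendered with base graphics to PNG and are byte-deterministic for fixed
input.

# The synthetic-data generator

`sim_design()` fixes the verification conditions: a 2-Mb genome in two
chromosomes (1.2 + 0.8 Mb) carrying 60 multi-exon genes on both strands —
desk-scale but large enough that a 30-bp segment is not trivially unique —
plus one 2-kb block duplicated between the chromosomes. The default read
batch is 300 FSTs: 36 per placed insertional type (180), 20 repeat-locus
reads sampling the duplicated block, 40 short-insert reads (segments at
least 10 bp below the MSL), 40 vector reads, and 20 reads at Q8 throughout
(error probability 0.16, uniformly worse than the 0.03 trim threshold).
Acceptable reads carry segments of 60–120 bp — at least 10 bp above the
MSL, and long enough for guaranteed-unique placement — sampled so that the
junction coordinate has the intended insertional type and the segment
occurs exactly once in the genome (twice for repeat reads), checked by
exact pattern counting on both strands. Genes carry real ATG and stop
codons at their CDS anchors. Everything is a pure function of the seed.

What the generator does *not* emulate: realistic base composition,
sequencing error inside retained reads (qualities are two-level), chimeric
reads, tandem or truncated element copies, and genomes with repeat content
beyond the one designed duplication. Passing the end-to-end tests therefore
demonstrates that the pipeline's logic is correct under clean conditions
with designed margins, not that its thresholds are optimal for noisy
production data — those thresholds are taken from the pipeline's standard
operating point, not fitted.

# Numerical and degenerate-input choices

* Equal-scoring trim segments: leftmost, then longest. Equal-scoring
  alignment hits: ordered by descending score, ascending e-value, subject
  id, subject start, strand. Repeat ties use exact integer score equality.
* Nearest-gene ties resolve to the lower start coordinate.
* An empty batch errors; an empty FASTA yields an empty list with a
  warning; a read trimmed to nothing classifies LOW; a chromosome with no
  genes yields intergenic calls with no gene.
* Genomes above the configured 200-Mb cap are refused up front.
* Verification problem sizes (2-Mb genome, 300 reads, 500 aligner-oracle
  pairs, 200-case property sweeps) were chosen so the whole suite completes
  in a couple of minutes on one CPU while every margin in the design is
  still exercised.

# Known limitations

The aligner is desk-scale: the k-mer index lives in memory and cluster
windows are re-aligned per query, which is comfortable for genomes up to a
few hundred Mb and thousands of FSTs but is not a short-read mapper.
Protein-space mapping (TBLASTX) is out of scope, as are junction-spanning
split-read logic and reconstruction of multi-copy insertions. One gene
model per gene is kept; alternative transcripts beyond the longest are
ignored.
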