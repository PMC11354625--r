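---
title: "Methods: virus discovery and vsiRNA profiling with vsikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virus discovery and vsiRNA profiling with vsikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsikit)
```

`vsikit` implements the computational half of an insect-virus
characterization study: a homology screen that finds candidate viral
contigs in an assembled metatranscriptome, annotation of the resulting
genomes (including circular ones), zero-mismatch small-RNA mapping, and
profiling of virus-derived siRNAs (vsiRNAs) whose signature — a 21-nt
size peak, balanced strand polarity, 5′-A/U bias — is the accepted
evidence of active replication in the insect host. This vignette
explains the models and conventions behind each stage, the parameters
that matter, what the synthetic-data generator does and does not
emulate, and the design decisions taken where conventions vary.

## The discovery screen

Assembled contigs are translated in all six frames. Each frame
translation is split at stop codons and the resulting peptides, if at
least 20 aa long (shorter fragments are alignment noise), are aligned
locally against every protein in the user's viral panel with an
affine-gap Smith–Waterman under BLOSUM62. Gap costs follow the BLAST
11/1 convention: a gap of length $n$ costs $11 + 1\cdot(n-1)$.
Significance uses Karlin–Altschul statistics,

$$\mathrm{bit} = \frac{\lambda S - \ln K}{\ln 2}, \qquad
  E = m\,n\,2^{-\mathrm{bit}},$$

with the standard gapped BLOSUM62 11/1 calibration
$\lambda = 0.267$, $K = 0.041$ shipped as the default. We do not
re-derive the calibration the way BLAST does for each database, so
E-values differ in detail from NCBI's; both the scoring scheme and the
cutoff are configurable. Two filters are applied in order: contig length
**strictly greater than** 1000 bp (the boundary case of exactly 1000 bp
fails, and is pinned by a test), then $E \le 10^{-20}$. Every rejection
is counted by reason (`short_contig`, `weak_evalue`, `no_alignment`) so
a screen is auditable. Per (contig, panel protein) only the best hit is
kept: lowest $E$, ties to higher identity, then lexicographic panel id —
fully deterministic. The traceback itself breaks ties diagonal > up >
left, so aligned strings are reproducible across platforms.

Identity is reported as $100 \cdot \text{matches}/\text{columns}$ over
**all** alignment columns, gaps included. Conventions differ between
tools here; ours is stated in the output metadata, and matters when
comparing against identities computed by other aligners.

## Genome annotation on linear and circular topologies

An ORF is *maximal*: it runs from the first in-frame ATG after the
previous in-frame stop through the next stop, and the reported span
includes the stop codon (so a 6639-nt ORF encodes 2212 residues). ATG is
the only start codon considered (configurable); the minimum span
defaults to 300 nt, below the smallest ORF annotated in the viruses this
package was built around (450 nt) but high enough to suppress spurious
short ORFs. Overlapping ORFs in different frames are all reported; no
culling rule is imposed. Coordinates are 1-based and fully closed
everywhere, including the GFF3 and TSV outputs.

Circular genomes need two extra rules. First, scanning happens on the
doubled sequence so origin-spanning ORFs are seen; duplicates are
removed by reducing starts modulo the genome length $L$, and spans are
capped at $L$ so no ORF is counted around more than one lap. Second —
the subtle one — an open region whose upstream boundary is the start of
the doubled-sequence scan (rather than a real stop codon) is skipped,
because the same region reappears later in the scan with its true
upstream context. Without this rule the choice of sequence origin leaks
into which ATG counts as "first", and rotating a circular genome would
change its annotation; with it, rotation invariance holds exactly and is
enforced by a property test against a brute-force positional scanner.
An ORF crossing the origin is reported with `end < start` and
`wraps_origin = TRUE`, and is emitted in GFF3 as two CDS parts sharing
one `ID`.

Terminal UTRs are defined only for linear genomes: the leading UTR is
`first_orf$start − 1`, the trailing UTR `L − last_orf$end`. Both termini
are always reported without guessing which the depositor meant by "5′"
versus "3′" — for a negative-sense virus the labeling depends on whether
coordinates follow the genome or the antigenome, and the package works
on the deposited orientation throughout, treating negative-sense biology
as a labeling concern rather than a computational one.

Gene order is typed against templates: an ordered list of labels where a
parenthesized token such as `(x)` optionally matches one unlabeled ORF.
A template matches when its non-wildcard labels appear in order among
the labeled ORFs; on circular genomes all rotations are tried, since
gene order on a circle is defined only up to rotation. The built-ins are
the chuvirus `L-G-N-(x)` order and the mononegavirus-style `N...G...L`
order with unassigned ORFs permitted between the core genes. Functional
labels (N/G/L/x) are *inputs* — domain identification is out of scope.

## The zero-mismatch mapper

Small-RNA studies of RNAi use exact mapping deliberately: a single
mismatch distinguishes a genuine Dicer product from sequencing error or
a paralogous locus. The mapper indexes every plus-strand k-mer start
($k = 18$ by default, the lower edge of the small-RNA window; reads
shorter than $k$ are rejected with a distinct error), including k-mers
across the origin on circular genomes, and verifies candidate placements
by full-length comparison — reverse-strand hits are found by looking up
the read's reverse complement. `N` matches nothing, so a read containing
`N` never maps; that is the strict reading of "zero mismatches".
Placement positions are always the 5′-most plus-strand coordinate of the
matched interval; a minus-strand read's own 5′ end therefore sits at
`position + length − 1`. This convention is recorded because the
positional vsiRNA profile depends on it.

Multimapping policies: `all` (every placement, weight 1), `unique`
(drop multi-placed reads, count them), and the default `fractional`
(weight $1/n$ per placement). Popular aligners assign a multi-mapped
read to one best location at random, which is not reproducible run to
run; fractional weighting is deterministic with the same expectation,
and the policy in force is stamped into every report. Coverage adds each
placement's weight to every covered position (modulo $L$ when
wrapping), so under `fractional` the total depth mass equals the summed
length of mapped reads — a conservation law the tests assert.

## vsiRNA profiling conventions

Reads are first restricted to the 18–30 nt window (inclusive bounds).
The size distribution is tabulated by (length, strand) in the mapper's
weights; the modal length breaks ties toward the smaller length. The
5′-nucleotide preference is computed at a focal length (default 21 nt,
the dominant Dicer-2 product) using the read's **own first base as
sequenced** — for a minus-strand placement that is the complement of the
genome base at `position + length − 1`. This is the convention under
which Dicer/Argonaute 5′ bias is defined; computing it on the plus
strand would scramble the signal for the antisense half of the
population. T is reported as U, these being RNA.

The positional profile deposits each read's weight at its 5′-end
coordinate, strand-resolved. "Hotspots" — regions preferentially
targeted — are operationalized as non-overlapping windows (default
50 nt) whose weight exceeds the per-strand mean by $z$ standard
deviations (default $z = 3$). With roughly 200 windows per strand the
$z = 3$ threshold admits an occasional upper-tail window even under a
perfectly uniform read distribution (measured: ~30% of uniform runs show
1–2 such windows; at $z = 4$, under 2%). Hotspot calls at $z = 3$ should
therefore be read as candidates for inspection, not detections; the
window size and threshold are stamped into the report and the null
behaviour is characterized by a calibration test.

## The synthetic-data generator

The generator exists so that every stage can be validated against known
truth. `gen_viral_genome` plants ATG-initiated, stop-terminated ORFs at
chosen coordinates with labels following a family template, and fills
the spacers with a construction that makes "the planted set is exactly
the annotated set" a guarantee rather than a likelihood: each 24-nt
spacer unit is an 11-nt stop cassette (`TAATTAATTAA` — stops at offsets
0, 4, 8 cover all three frames) followed by 13 random bases over
{C,G,T}. The cassette has no G and the filler no A, so spacers contain
no ATG anywhere and terminate any reading frame within one unit, while
staying non-repetitive so spacer-derived reads do not multimap. ORF
interiors are random non-stop codons at the requested GC (resampled in
the rare case a shifted-frame ORF above threshold appears by chance).
Inter-ORF spacers must be at least 12 nt so each holds a full cassette.
The two stand-ins used for regression — a 9873-nt linear genome with
N/G/L ORFs at 91–1077, 2674–4101, 4185–4955 (hence a 90-nt leading UTR)
and an 11590-nt circular genome with L/G/N/x ORFs at 70–6708, 7242–9272,
9631–10971, 11079–11528 — reproduce published coordinate architectures
on synthetic sequence and are labelled synthetic in name and
documentation.

`gen_vsirna_reads` draws read lengths from a categorical distribution
(default peaked at 21 nt), strands as Bernoulli(`sense_fraction`), and
origins uniformly (optionally up-weighted at hotspot positions). Two
design points matter. First, the 5′-A/U bias is imposed by **origin
resampling** — when the bias event fires (probability `au5_fraction`)
the origin is redrawn until the read's first base as sequenced is A or
T (up to 50 attempts, then flagged) — never by editing the read, so
viral reads remain exact substrings and the zero-mismatch contract is
testable. A consequence worth stating: the expected A/U fraction is not
`au5_fraction` itself but
$\mathrm{au5} + (1-\mathrm{au5})\cdot b$, where $b$ is the genome's A/T
frequency at sampled 5′ sites, because non-bias reads still start with
A/T at the baseline rate. Recovery tests compare against this
expectation and against the per-read truth table. Second, background
reads are rejection-sampled against both genome strands, making "no
background read maps" a hard invariant the mapper tests rely on.

`gen_rnaseq_reads` draws `round(coverage · L / read_len)` uniform
origins (wrapping on circles, clamped on linear genomes), so the
realized mean coverage equals the target up to rounding.
`mutate_protein` substitutes exactly `round((1−identity)·len)` positions
without replacement and without indels, so planted pairwise identities
are exact under ungapped alignment.

What the generator does **not** emulate: sequencing error and quality
scores, adapter remnants, chimeric reads, host transcripts with partial
viral homology, uneven library composition, or the Dicer phasing
patterns of real vsiRNA populations. Passing tests therefore demonstrate
correctness of the computation under clean inputs, not robustness to
the full messiness of real libraries — which is the appropriate division
of labour, since the upstream trimming and assembly stages are expressly
out of scope.

## Identity matrices and trees

Pairwise identities are computed from global (Needleman–Wunsch,
affine-gap, terminal gaps penalized) alignments, identity over all
columns as above, and converted to distances $d = 1 - \mathrm{id}/100$.
Trees are built by neighbor joining, which reconstructs additive
distance matrices exactly — the tests verify 4- and 5-taxon recovery by
exhaustively enumerating all unrooted topologies and least-squares
fitting each. **NJ on identity distances is a deliberate substitution
for maximum-likelihood inference**: it is deterministic, dependency-light
and sufficient for the topology-level claims this package makes
(sister-pair grouping, genus monophyly on simulated families). It does
not provide substitution-model-based branch lengths, rate heterogeneity
or bootstrap support, and published ML trees should not be expected to
match its branch lengths. Negative NJ branch estimates are clamped to
zero and the count of clamped edges attached to the tree. Newick output
round-trips through the reader to six decimals.

## Problem sizes and numerical choices

The simulation scales used throughout tests and the acceptance script —
a ~10-kb genome, 20,000 viral plus 5,000 background small reads, 50×
RNA-seq coverage, protein families of ~300–2200 aa — were chosen to
match the scale of the motivating study while keeping any single stage
under a few seconds; statistical recovery tests size their tolerances as
3 binomial/multinomial standard errors at $n = 20{,}000$. Other fixed
choices: sub-seeds for independent stages derive deterministically from
one user seed; JSON/TSV outputs are byte-deterministic for identical
inputs; alignment tracebacks and best-hit selection are tie-broken as
stated above; `U` is accepted on input and normalized to `T`, lowercase
to uppercase, and anything else outside the alphabet is an error rather
than silently masked.

## Known limitations

The screen re-implements alignment and significance, not BLAST's seeding
heuristics, so it is quadratic per (peptide, panel protein) pair and
meant for focused panels, not all-of-RefSeq searches. E-values use a
fixed calibration (above). ORF finding considers ATG starts only, and
the "first ATG" rule means a truncated 5′ context (e.g. a contig that
starts inside a gene) shifts the reported start to the next in-frame
ATG. Hotspot calling is a descriptive operationalization, not a
significance test. The mapper is exact-match only — by design — and so
says nothing about reads one mismatch away; interoperability outputs
(SAM, GFF3, Newick, outfmt-6-like tables) are provided for downstream
tools that handle the relaxed questions.
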