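---
title: "Triage of strand-specific de novo transcriptome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of strand-specific de novo transcriptome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssfilter)
```

## The problem

De novo assemblers such as Trinity emit many *putative transcripts* per
gene-like *component*: genuine splice isoforms, truncated fragments,
misassemblies, and two classes of artifact specific to this setting:

* **Leakage antisense duplicates.** In a dUTP strand-specific library
  the second cDNA strand is degraded before amplification, so read
  orientation encodes transcript strand. Degradation is imperfect; a
  fraction of fragments is sequenced in flipped orientation and, at
  sufficient depth, assembles into a reverse-complement twin of a real
  transcript.
* **Genomic contamination.** Residual genomic DNA (host or microbial)
  yields short, weakly supported contigs with no strand preference.

`ssfilter` reduces such an assembly to one well-supported representative
transcript per component, then layers on the descriptive analyses that
typically follow: two-pool expression ratios, a substitution-site scan,
and taxonomic attribution of homology hits.

## The statistics and rules

### SSLR

For each transcript, over the *proper* read pairs aligned to it,

$$\mathrm{SSLR} = \log_2 \frac{n_{\text{read1 on plus}} + 0.5}
                             {n_{\text{read2 on plus}} + 0.5}.$$

Under the dUTP chemistry the second-in-pair read of a sense transcript
maps on the plus strand, so sense transcripts have negative SSLR,
antisense artifacts positive, and unstranded (genomic) contigs sit near
zero. With leakage probability $p$, the expected SSLR of a deeply
covered sense transcript converges to $\log_2\!\big(p/(1-p)\big)$; the
test suite recovers this at $p \in \{0.2, 0.5\}$. The symmetric 0.5
pseudocount is a package choice: it keeps SSLR finite at zero counts and
exactly antisymmetric under count exchange. All alignment lines are
counted (multi-mapped reads included) because identical sequence in two
orientations *must* multi-map for the statistic to separate a
transcript from its twin.

### Leakage removal

Candidate twins are transcript pairs matching in alternate orientation
over more than 80% of the shorter member (merged HSP intervals), from an
all-vs-all nucleotide search (BLASTN outfmt 6 input, e-value $\le$
1e-5), or from a built-in exact-k-mer/ungapped-extension fallback that
keeps the test suite hermetic. The positive-SSLR member is discarded iff

* the other member's SSLR is below $-2.5$,
* its own SSLR is above $+1.5$, and
* it is at most 10% longer than the negative-SSLR member.

A permissive mode (discard on positive SSLR alone) is available; the
strict rule is the default.

### Support and coverage dips

Transcripts with fewer than 20 proper pairs are discarded (inclusive
threshold: 20 is kept). Coverage evenness is summarized by partitioning
the transcript into fixed 100-bp windows — assembler graph nodes are not
available post-assembly, so windows stand in for them — and counting a
*dip* whenever adjacent window means differ by more than 5-fold (strict,
with a small epsilon guarding zero-coverage windows). The trailing
remainder window participates when it spans at least half a window.

### ORF reconciliation

Six-frame ORFs of at least 300 bp (stop codon included; edge-truncated
ORFs are reported and flagged partial) are found by a built-in
ATG-to-stop scanner; a stop-to-stop mode mirrors the convention of
classical ORF finders. Built-in calls are first restricted to the strand
of the longest ORF (ties prefer the SSLR-predicted sense strand, else
plus). Externally predicted ORFs (GFF3) take priority: plus-strand
priority calls are admitted first, then non-overlapping minus-strand
priority calls, then non-overlapping built-in calls, where two ORFs
"overlap" when they share more than 50% of the shorter ORF's length.
Within an admission group, candidates enter longest-first, so of two
mutually overlapping ORFs only the longer survives. The ">50% of the
shorter" rule is read as the shorter *ORF* (the alternative reading,
shorter transcript, is meaningless within a single transcript).

### Weighted evidence score

Every surviving transcript gets 19 bounded metrics, each multiplied by a
configurable weight (defaults 10, 8, 7, 5, 4, 9, 7, 6, 4, 3, 7, 7 for
the sequence/homology block; 10, 10, 8, 3, 8, 8 for the ORF block; 10
for dips). The sequence block rewards: fraction of the database protein
covered by the first (lowest e-value) hit in a curated and a general
protein database, fraction of the transcript covered, covered lengths
relative to the longest such hit in the component, match strand agreeing
with the SSLR, normalized $-\mathrm{SSLR}$ itself, and relative
transcript length. The ORF block penalizes multiple ORFs, ORFs with
different best subjects, and ORFs on both strands (graded by whether
both, one, or neither strand has a protein hit — implemented as
minority/majority ORF-count ratio so the penalty is maximal for balanced
strands, a package interpretation of an underdefined rule). The dip
metric penalizes dips relative to the component maximum. Every
normalizer is per-component, including the $\max|\mathrm{SSLR}|$ used by
the strand metrics (a `global` alternative exists); every $0/0$ is
defined as 0 so absent evidence is neutral. Under the default weights
the aggregate is bounded by 85, attained exactly by a transcript with
perfect hits, one sense ORF, maximal length and no dips.

Per component, the highest-scoring transcript is kept — ties broken by
longer transcript, then lexicographic id — and only if its aggregate
strictly exceeds 14, which is exactly the score of a hit-less, ORF-less
transcript that is merely longest and most strand-specific in its
component; the threshold therefore encodes "has a protein hit or an
ORF".

### Expression ratios, variant scan, LCA

The two-pool expression module is deliberately descriptive (the design
it serves had one DSN-normalized library per pool, no replicates): per
transcript, $\log_2(a/b)$ with zero counts replaced by 0.5, restricted
to pooled counts strictly above 50, then normalized by subtracting the
center of the most populated 0.1-wide histogram bin. Modal ties break
toward the bin nearest zero, then the lower bin; note that with tied
modal bins this tie rule is deliberately not shift-invariant, so the
exact shift-invariance property holds whenever the mode is unique (the
operative regime: a dominant null spike). Binning uses
`floor(round(x/w, 6))` so floating-point noise at bin edges cannot break
invariance for shifts that are exact multiples of the bin width.

The substitution scan treats the assembly itself as the reference:
per-position base counts from the alignments (duplicate-flagged reads
dropped; deletion-spanning reads counted as skips in depth but excluded
from allele fractions), consensus = majority base with ties broken in
A<C<G<T order, and every non-consensus base whose fraction strictly
exceeds 5% of the called bases emitted, flagged *strict* above 20%.
Only columns with more than 20 reads are evaluated. Indels are not
called.

LCA assignment aggregates, per query, all hits tied at the minimal
e-value and returns the deepest taxonomy node ancestral to all of their
subject taxa, walking a user-supplied parent map; hits with unknown taxa
are dropped with a warning.

## The simulator: what it emulates, what it does not

`sim_config()` defaults state the emulated world: 100-bp paired reads, a
fixed 250-bp fragment with uniform start, 5% orientation leakage,
one-in-ten sense transcripts acquiring an exact reverse-complement twin,
contamination contigs that are short (80–400 bp, short-biased) and
supported by 2–15 pairs (below the 20-pair cutoff by construction),
coding anchors whose planted ORF occupies ~60% of the transcript, and
0.5% uniform sequencing error.

Design points worth knowing:

* **Twins receive every pair of their sense partner**, mirrored and
  strand-flipped, emulating a multi-match aligner on two
  reverse-complement contigs. This is what makes twin SSLR ≈
  −(sense SSLR); assigning only the leaked pairs would give twins
  sense-like orientation and the leakage rule could never fire.
* **Fragment isoforms are end-truncations** (random prefix/suffix,
  30–70% of the anchor), so their homology hits cover the planted
  protein proportionally. An interior fragment can contain the entire
  ORF, in which case selecting it over the anchor is legitimate under
  the scoring logic — exactly the ambiguity the truncation model avoids
  when representative selection is being tested.
* **Planted substitution sites sit in the fully covered interior span**
  (at least one fragment length from each end). Edge positions are
  depth-starved by the uniform-fragment construction; planting there
  tests coverage geometry, not the caller.
* Not emulated: realistic error/quality profiles, GC or positional
  bias, fragment-length variation, splice structure, expression dynamic
  range. A green test therefore establishes the *logic* of the filters
  on data obeying the stated statistical structure, not performance on
  real libraries.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere (SAM/GFF3/BLAST
  convention); a minus-strand translated match is encoded by
  `q_start > q_end`.
* Thresholds quoted as "more than" are strict (`>`); the support cutoff
  "20 pairs" is inclusive (`>= 20`).
* All 0/0 ratios in scoring are 0; a component with no dips anywhere
  gives every member a dip metric of 0.
* Empty inputs are data, not errors: an empty hit file is an empty
  stream; a transcript shorter than the minimum ORF length yields no
  ORFs; an empty ORF set writes a header-only GFF3.
* The strand-restriction tie (equal longest ORFs on both strands)
  prefers the SSLR-predicted sense strand when an SSLR is supplied,
  else plus.
* Simulator seeding derives per-stage seeds from the master seed with a
  small affine map kept below $2^{31}$; identical configuration and
  seed reproduce byte-identical artifacts.

## Known limitations

* The built-in alternate-orientation detector is an exact-match seeder
  with ungapped extension: adequate for the exact twins the simulator
  plants and for near-identical duplicates, not a replacement for BLASTN
  on diverged sequence.
* Coverage dips over fixed windows approximate the original graph-node
  formulation; window width changes dip counts and is exposed as a
  parameter rather than estimated.
* The expression module offers no inference — no dispersion, no
  replicates, no FDR — by design.
* Variant sensitivity at the strict 20% tier is depth-limited: at a true
  allele fraction of 0.30 the per-site miss probability is
  `pbinom(floor(0.2 n), n, 0.3)`, about 1.7% at 100x and 0.5% at 133x,
  so sub-99% recovery at moderate depth is a property of the thresholds,
  not a defect of the caller.
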