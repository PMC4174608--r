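# ssfilter

Post-assembly triage of strand-specific de novo transcriptome
assemblies.

## Who this is for

De novo assemblers (Trinity and kin) emit many *putative transcripts*
per gene-like *component*: real isoforms, fragments, misassemblies —
and, in dUTP strand-specific libraries, reverse-complement "leakage"
twins of genuine transcripts plus short, weakly supported contigs from
contaminating genomic DNA. Anyone who needs one clean representative
transcript per gene for annotation or comparative work has to triage
that redundancy first. `ssfilter` implements that triage as a tested,
scriptable pipeline, together with the descriptive analyses that
typically follow (two-pool expression ratios, substitution-site scan,
LCA taxonomy), and a seeded simulator that generates assemblies,
alignments, homology tables and truth labels so every step is testable
without external data.

## The statistics at the core

**SSLR (strand-specific log ratio).** Per transcript, over proper read
pairs,

    SSLR = log2( (n_read1_plus + 0.5) / (n_read2_plus + 0.5) )

Under dUTP chemistry the second-in-pair read of a sense transcript maps
on the plus strand: sense transcripts go negative, antisense artifacts
positive, unstranded contamination sits near zero. With leakage
probability *p*, deeply covered sense transcripts converge to
`log2(p/(1-p))`.

**Leakage rule.** A transcript pair matching in alternate orientation
over >80% of the shorter member loses its positive-SSLR member iff the
other member's SSLR < −2.5, its own SSLR > +1.5, and it is at most 10%
longer than its partner.

**Support and dips.** Transcripts with fewer than 20 proper pairs are
discarded; a >5-fold change in mean depth between adjacent 100-bp
windows counts as a coverage dip.

**Weighted evidence score.** Each surviving transcript gets 19 bounded
metrics — protein-hit coverage of subject and query in two databases,
component-relative hit and transcript lengths, SSLR agreement of match
and ORF strands, ORF multiplicity/consistency penalties, dip penalty —
weighted (defaults 10, 8, 7, 5, 4, 9, 7, 6, 4, 3, 7, 7; 10, 10, 8, 3, 8, 8;
10) and summed; the maximum is 85. The best-scoring transcript per
component is kept when its score strictly exceeds 14 (the exact score of
a hit-less, ORF-less transcript — i.e. "has a BLAST match or an ORF").

**Downstream.** Expression: `log2(a/b)` with a 0.5 substitute for zero
counts, pooled count > 50, normalized by centering the mode of a
0.1-wide histogram. Variants: majority-consensus pileup, alleles > 5%
(relaxed) / > 20% (strict) of called bases at > 20 reads. Taxonomy:
lowest common ancestor of all hits tied at the best e-value.

## Worked example

```r
library(ssfilter)

d <- tempfile()
cfg <- sim_config(seed = 42, n_components = 12,
                  isoforms_per_component = c(1, 3),
                  transcript_len = c(600, 1200),
                  pairs_per_transcript = c(40, 120),
                  twin_fraction = 0.25, contamination_fraction = 0.25)
res <- simulate_run(cfg, d)                       # FASTA + SAM + hit tables
man <- run_pipeline(list(fasta = res$fasta, sam = res$sam,
                         uniref = res$hits[["uniref"]],
                         nr = res$hits[["nr"]],
                         self_hits = res$hits[["self"]],
                         out_dir = file.path(d, "out")))
```

The manifest reports the funnel, each discard with a reason:

    stage leakage   in=30 kept=27 discarded=leakage_antisense=3
    stage support   in=27 kept=24 discarded=low_support=3, contaminant=0
    stage selection in=24 kept=11 discarded=not_selected=12, low_score=1

30 contigs enter (12 components' isoforms + 3 planted twins + 3
contamination contigs); the 3 twins fall to the leakage rule, the 3
weakly supported contamination contigs to the 20-pair cutoff, and
scoring then reduces 24 survivors to 11 representatives (one component's
best never beats 14 — it is the non-coding anchor with no hits). The
SSLR table (`out/sslr.tsv`) joined to the truth labels shows the
separation the filters exploit:

                   label mean_sslr     n
                   sense     -4.28    24
       leakage_antisense      4.27     3
           contamination     -0.10     3

and `out/representatives.tsv` carries the per-transcript score
breakdown, e.g.

       component_id  transcript_id aggregate_score length_bp
          comp11_c0 comp11_c0_seq1            76.8      1188
          comp12_c0 comp12_c0_seq1            78.8      1022
           comp1_c0  comp1_c0_seq1            78.8       721

Every stage is also a standalone subcommand (`inst/exec/ssfilter`):

```sh
ssfilter simulate --seed 3 --out simdir/
ssfilter sslr simdir/pairs.sam --out sslr.tsv
ssfilter de a_counts.tsv b_counts.tsv --out de.tsv
```

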