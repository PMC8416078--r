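---
title: "Shotgun metabarcoding of herbal products: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shotgun metabarcoding of herbal products: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A traditional herbal patent medicine is a powdered, processed mixture of
several plant species at very unequal dosages, possibly carrying
adulterant congeners, field weeds, and fungal contaminants. Amplicon
metabarcoding of such products suffers from PCR bias and primer
mismatch; shotgun sequencing avoids amplification entirely, but barcode
loci then make up only a tiny fraction of the reads. `herbshot`
implements the computational half of this *shotgun metabarcoding*
strategy: pull the reads of three barcode regions -- the nuclear
ribosomal ITS2 spacer and the chloroplast *matK* and *rbcL* genes --
out of an untargeted shotgun library, reconstruct the barcode
haplotypes present, verify them, and assign them to taxa.

The bundled example formulation is a six-herb gynecological remedy
whose prescribed mass proportions span 59.26% down to 3.70% -- a 16:1
range that makes the low-dosage ingredients easy to lose. The pipeline
must recover all six.

## Pipeline model, stage by stage

**Quality trimming** (`filter_pairs`). Adapters are clipped at a 10 nt
exact seed extended with at most 10% mismatches; a sliding window
(default 4 nt) is scanned 5'→3' and the read is cut at the first base of
the first window whose mean Phred quality drops below the threshold
(default Q15). A pair survives only if both mates retain `min_len`
(default 36 nt): downstream enrichment and mapping are pair-oriented,
so no orphan stream is kept. The defaults are the published defaults of
the standard trimmer for this protocol.

**Enrichment** (`build_kmer_index`, `enrich_pairs`). Each reference
sequence is decomposed into canonical k-mers (lexicographic minimum of
the k-mer and its reverse complement; k = 21, odd, 15--31) labelled
with its marker. A pair is assigned to the marker with the most k-mer
hits across both mates if that count reaches `min_hits` (default 3);
one informative mate suffices (mate rescue), and a tie at the top
leaves the pair unassigned so that per-marker counts stay additive.
An alignment-free screen is deterministic and dependency-free; the
high-identity re-check happens later at assignment time.

**Assembly** (`assemble_bin`). Each marker bin is assembled with a de
Bruijn graph at every k in a ladder (default 31, 55, 77, 99, 127,
capped below the read length), pooling unitigs across k. Edges below
`min_edge_cov` (default 2) are dropped. Two further cleanups matter at
realistic depths:

* *Relative junction cleanup* (`junction_alpha`, default 0.05). At the
  depths produced by a dominant ingredient (hundreds to thousands
  fold), a specific substitution error recurs several times and
  survives any absolute coverage cutoff. At each branching node, edges
  carrying less than `junction_alpha` times the strongest competing
  edge are removed. Genuine haplotype bubbles of comparable depth --
  e.g. ITS2 paralog variants differing by one or two substitutions --
  survive by construction, and the suite tests that property
  explicitly. Setting `junction_alpha = 0` recovers a purely absolute
  cutoff.
* *Tip/debris removal*: paths shorter than 2k are removed when they are
  isolated, or dead-ended with a competing continuation at their
  junction. A dead-ended path that is the sole continuation (the
  natural end of a locus) is never removed.

Unitigs of at least 100 nt are reported; `dereplicate` then removes
contigs identical to, or exact substrings of, a retained contig on
either strand, keeping the longest (ties: lexicographically smallest),
which makes the retained set independent of input order.

**Barcode extraction** (`extract_barcodes`). *matK*/*rbcL* contigs are
cut at semi-global primer matches (standard plant barcoding primers by
default; up to ⌈0.1 × primer length⌉ errors); contigs lacking primers
pass through flagged `none`, because verification later removes
unsupported sequence. ITS2 is delimited by two position-weight-matrix
profiles modelling the conserved 5.8S-end and 28S-start flank motifs;
both placements must clear a bit-score threshold (default 25 bits,
roughly two substitutions deep) and delimit 100--500 nt. A dual-PWM
flank scorer uses the same discriminative content as a profile-HMM
annotator and is a drop-in upgrade path.

**Chimera removal** (`detect_chimera`). A candidate is chimeric iff
some crossover splits it into a left segment ≥ 99% identical to one
eligible parent and a right segment ≥ 99% identical to another (both
segments ≥ 30 nt) while its full-length identity to every pool member
stays ≤ 97%. Parents must be at least twice as abundant as the query
(the de novo convention; abundance is proxied by assembly coverage at
this stage). Segments are scored against per-position match profiles of
the query to each parent under start-anchored and end-anchored
alignments, both ungapped and gapped, in both orientations -- a short
true segment therefore cannot be masked by the unrelated half of the
query dragging a single global alignment. One inherent limitation is
shared with all tools of this family: a splice of two near-identical
congeners (> 97% similar) is indistinguishable from a real sequence by
the full-length ceiling and is deliberately not called.

**OTU clustering** (`cluster_otus`). Surviving candidates are grouped
by exact sequence identity after strand normalization -- OTUs here are
exact haplotypes, which is what keeps 1--2-substitution paralog
variants distinct.

**Verification** (`verify_otus`, `filter_reliable`). Every mate of the
marker bin is mapped back to every OTU representative by 15 nt exact
seed anchoring and banded (± 8) extension; a mate is accepted at ≥ 95%
identity over ≥ 80% of its length, with soft-clipping only at
representative boundaries. Mates map independently, and a read counts
toward every representative it maps to, so shared haplotypes do not
silently lose support. From the accepted intervals a per-base depth
array gives mean depth and coverage (% of positions with depth ≥ 1).
An OTU is removed iff mean depth ≤ 3 **or** coverage ≤ 95% -- the "or"
reading is the stricter one and matches the large OTU reduction this
filter is meant to achieve. The scalar depth statistic is the mean;
the threshold's original description does not say mean, minimum, or
read count, so the summary is configurable in code.

**Taxonomy** (`assign_otus`, `build_report`). Each reliable OTU is
aligned locally (match +1, mismatch −2, gap open −5, extend −2, both
strands) against every reference of its marker; hits ≥ 90% identity
over ≥ 60% of the query are ranked by score. Hits within 10% of the
best score are retained: a single retained taxon at ≥ 97% identity
yields a direct species call, otherwise the OTU is placed at the
lowest common ancestor of the retained taxa. These defaults mirror
common practice for short-read LCA classifiers and are configurable.
The report aggregates mapped reads of reliable OTUs per taxon and
marker (relative abundances per marker sum to 100), categorizes each
taxon (prescribed; ancestor of a prescribed species = prescribed at
lower resolution; non-prescribed congener = adulterant candidate;
other green plant = weed/other; fungus), and emits the species ×
marker detection matrix plus per-marker summaries (OTU count, mean
length, GC%).

## The simulator: what it emulates, and what it does not

`simulate_shotgun` is the package's study condition generator. Given a
formulation table it draws pair counts per taxon multinomially in
proportion to mass, samples fragment positions uniformly over each
locus, draws insert sizes from a truncated normal (default 350 ± 50 nt,
minimum one read length of 150 nt), reverse-complements the second
mate, applies i.i.d. substitution errors (default 1%), and emits
constant Phred qualities encoding that error rate. A configurable
fraction of on-target fragments (default 2%) is replaced by two-parent
splices with a single crossover uniform in the middle 60% of the
fragment; a ground-truth table records the origin, chimera parents and
coordinates of every pair. The off-target background (default 50% of
pairs) is sampled from a single seeded random decoy sequence at GC 40%,
which guarantees -- testably -- zero k-mer overlap with the references.
Identical design and seed give byte-identical FASTQ output.

The synthetic loci embed each barcode region in realistic context:
ITS2 between the conserved 5.8S/28S motifs, *matK*/*rbcL* between
their primer sites, with 300 nt of random flank on each side. Region
lengths and base composition follow the markers' typical values
(ITS2 ≈ 210 nt at 59% GC; *matK* ≈ 840 nt at 33% GC; *rbcL* ≈ 700 nt
at 43% GC). Congeneric species pairs (an adulterant congener of one
prescribed herb; a second congener of another) are derived by point
mutation at marker-dependent divergence -- 8% for ITS2, 1.2% for the
chloroplast markers -- reflecting the fast-evolving nuclear spacer
versus the conserved coding genes; with the default LCA band this
reproduces the characteristic behaviour of the markers: ITS2 resolves
congeners at species rank while *matK*/*rbcL* stop at the genus. The
fungal contaminant carries only ITS2.

What the simulator does **not** model: indels and instrument-specific
quality profiles (a separate low-quality-tail switch exercises the
trimmer instead), PCR amplification bias (irrelevant to shotgun data),
multi-copy ITS2 paralog families within one genome, real genomic
backgrounds, and GC-dependent coverage bias. Passing the end-to-end
tests therefore demonstrates the pipeline's logic under controlled
conditions, not its performance on real NovaSeq libraries.

## Problem sizes and numerical choices

The end-to-end validation uses 50,000 pairs (≈ 15 Mb), three markers,
the bundled six-herb formulation, 1% error and a fixed seed; module
tests use smaller instances. These sizes exercise every stage --
including error-branch cleanup at four-digit depths -- while keeping a
complete run on one CPU in a few minutes.

Tolerances and tie-breaks worth knowing: dereplication and OTU
ordering break ties lexicographically, so outputs are deterministic;
enrichment ties go to "unassigned"; the insert-size distribution is
truncated, never resampled; alignment scoring conventions follow the
affine convention in which a gap of length L costs open + L · extend;
depth profiling uses half-open intervals; proportions must sum to 100
within 0.1; relative abundances are checked to sum to 100 within 0.01.
All randomness flows from a single seed, and the pipeline stages
themselves are fully deterministic.

## Known limitations

* Congener-crossing chimeras (parents > 97% identical) are
  undetectable under the full-length identity ceiling, as in the
  reference family of chimera detectors.
* The k-mer screen requires roughly k + min_hits − 1 consecutive
  error-free bases shared with a reference; reads confined to unindexed
  flanking sequence are not enriched.
* Mapping anchors on a 15 nt exact seed; a mate with no error-free
  15-mer in common with a representative cannot be mapped even if its
  identity is above the acceptance threshold.
* Equal-proportion ingredients are not distinguishable by read share;
  the read-share ranking test therefore only constrains strictly
  ordered dosage levels.
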