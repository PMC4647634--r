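---
title: "Profiling transcription, small RNAs and RNA editing in multichromosomal plant mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling transcription, small RNAs and RNA editing in multichromosomal plant mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plant mitochondrial genomes are mostly non-coding, and in the most
extreme cases (several *Silene* species) they span megabases fragmented
into dozens of circular-mapping chromosomes, some carrying no annotated
gene at all. Strand-specific RNA-seq of mitochondrial-enriched and
total-cellular samples can ask whether that sequence is transcriptionally
active and post-transcriptionally processed: intergenic transcription
appears as localized read depth, candidate novel proteins as expressed
open reading frames, candidate functional small RNAs as discrete read
stacks, and editing activity as C-to-U mismatches between cDNA and the
genomic reference. This package implements that entire screen, plus a
synthetic-data generator that plants each structure at known parameters
so every stage can be validated against exact truth.

This vignette documents the models and conventions behind each stage,
the tunable parameters and their defaults, what the generator does and
does not emulate, and the numerical choices made where the procedure was
genuinely open.

## Conventions

All coordinates are 1-based and fully inclusive (the GFF convention);
the only conversion, to 0-based half-open intervals, happens at the BED
export boundary (`write_bed()`). Strand always means the transcript
strand. Minus-strand read sequences are kept in reference orientation
(as SAM stores them), so pileups count reference-space bases and the
canonical C-to-U change reads as genomic C→T on plus-strand transcripts
and G→A on minus-strand transcripts.

Alignments are treated as ungapped blocks: the generator emits only
ungapped records, and records with indel CIGARs contribute only their
leading aligned run to pileups, with a warning. The analyses here are
substitution- and coverage-based, so this loses nothing on the intended
inputs.

## Coverage, windows and thresholds

`compute_depth()` increments depth by one at every position a read
covers, per strand. `window_profile()` tiles each chromosome with
windows starting at 1, 1+step, …; the final window is truncated at the
chromosome end and its mean uses the truncated length (truncation avoids
discarding chromosome ends; the alternative—dropping partial
windows—biases against short chromosomes, which are exactly the
interesting ones here). Window CPM is the window's mean depth scaled by
millions of *mapped* reads in that library: a mapped-read denominator
keeps libraries comparable when enrichment efficiency differs, which is
the entire point of the mitochondrial-enriched versus total-cellular
contrast. When replicates are averaged (`average_profiles()`), CPM is
computed per library first and then averaged, rather than averaging raw
depths — the replicate with more reads should not dominate.

`tail_threshold()` returns a nearest-rank upper-tail quantile of window
means. A 5 % tail on typical organellar data lands near 100×, which is
the default expressed-region floor (`region_depth_floor = 100`). Region
calling keeps windows with mean depth *strictly* above the threshold
(matching the ">100×" convention), merges kept windows that overlap or
abut (`merge_gap = 0`, configurable), and — rather than discarding
regions near genes — flags any region within 2 kb of an annotated gene,
tRNA, rRNA or pseudogene, so genic transcription and intergenic
candidates stay distinguishable downstream.

Enrichment classification requires both replicate concordance (every
mitochondrial-enriched CPM above every total-cellular CPM) and a pooled
fold change of at least 2 (`enrichment_fold`). The fold threshold is a
design choice — "overrepresented" needs an operational definition — and
2× with replicate concordance is conservative enough that plastid- and
nuclear-derived insert regions, whose transcripts reach the
mitochondrial alignments only by cross-mapping, classify cleanly as
`tc_enriched`. The rule is antisymmetric by construction: swapping the
two profile sets swaps the labels.

`cds_coverage_dropoff()` compares mean depth over the last 100 nt of a
CDS with the 100 nt after the stop codon, in transcription direction. A
ratio below 0.1 is called a sharp 3' drop-off — the phenomenon it
detects (efficient 3' processing) produces ratios near
zero, and unprocessed run-on transcription produces ratios near one, so
any cutoff well inside (0, 1) separates them; 0.1 is configurable. The
same 0.1 applies to the interior scan for mid-CDS coverage collapses
(transcripts that die out before the in-frame stop).

`flag_cross_mapping()` marks a region when it shares an exact k-mer
(default k = 50, either orientation) with an annotated gene elsewhere in
the genome. Fifty is comfortably above chance matching for genomes at
this scale and below typical read length, which is the regime in which
cross-mapping actually occurs.

## The ORF screen

`find_orfs()` scans all six frames for ATG-to-stop spans under the
standard genetic code — plant mitochondria use the standard nuclear code
— with ATG as the only start and TAA/TAG/TGA as stops. ORF length
*includes* the stop codon, so the 201-nt default minimum means 66 codons
plus a stop; this matches common ORF-finder conventions, and the
201/198 boundary is pinned by tests. By default only maximal ORFs are
reported (the first ATG after the previous in-frame stop); because
published counts can depend on whether internal ATGs spawn nested ORFs,
an `all_atg` mode is provided as well.

`filter_remote_orfs()` keeps ORFs whose edge-to-edge gap to the nearest
annotated gene, tRNA, rRNA or pseudogene is strictly greater than 2 kb
(0 for overlap), removing ORFs explainable by run-on or readthrough
transcription of known genes. `rank_orfs_by_depth()` attaches mean
coding-strand depth, selects the top `ceiling(n × 0.05)`, and flags
those above 100× mean depth; ties break by (depth desc, chromosome,
start) so repeated runs agree exactly.

## The small-RNA screen

Candidate functional small RNAs must survive three filters: length
17-25 nt, perfect match to the reference (edit distance 0; reads with a
missing edit-distance tag are treated as unverifiable and dropped), and
no overlap with the *coding* strand of an annotated protein, tRNA or
rRNA gene — sense-strand overlap is the signature of a degradation
fragment, while antisense reads are kept. `stack_candidates()` then
groups reads by exact (chromosome, start, length, strand); a group is a
candidate when its pooled count across the two mitochondrial-enriched
libraries is at least 50 and at most one other filtered read (pooled
across all four libraries, either strand) overlaps its footprint. The
pooled-replicate reading of the 50× minimum is a choice — requiring 50
in each replicate would be stricter — and is configurable; neighbor
reads are counted as reads, not positions. Discrete stacks versus
scattered overlapping smears is exactly the contrast the generator
plants, and the end-to-end test demands exact separation.

`smallrna_mrna_correlation()` computes Pearson correlation between
small-RNA and mRNA CPM on a shared window grid; fewer than three windows
or zero variance is signalled as an explicit NA with a warning rather
than propagated silently.

## The editing caller

`build_pileup()` counts A/C/G/T calls per position per transcript
strand, tagging every call that lies within `trim_margin` (default 5) nt
of its read's 3' end — for a minus-strand read, its 3' end is the
reference-leftmost position. The 3'-end margin (rather than both ends)
reflects where residual adapter bases and clustered end-of-read errors
accumulate in single-end data.

`call_edit_sites()` emits sites where, on one strand, depth ≥ 100 and
the most frequent non-reference base reaches ≥ 20 % of all calls at the
position on that strand. Both thresholds are inclusive ("a minimum of"
reads naturally as ≥) and both boundaries are pinned by tests. The
frequency denominator is all calls on the assigned strand, not just
reference-plus-variant — the simpler and monotone choice. Only the
single most frequent non-reference base is considered per site. Where
both strands pass at a position, the deeper strand wins (transcript
strand by read majority); an exact tie keeps the plus strand and sets an
ambiguity flag.

`classify_edit_sites()` assigns categories with precedence coding >
pseudogene > intron > UTR > IGS. Coding sites are typed
synonymous/nonsynonymous by translating the codon with and without the
edit (spliced across CDS segments in transcription order; stop-gain is
nonsynonymous; a CDS whose concatenated length is not divisible by 3 is
a fatal, named error). Intronic sites within 20 nt of an exon boundary
are dropped entirely — read mapping across splice boundaries is
unreliable there — and returned separately in an attribute rather than
silently discarded. UTR versus IGS is an arbitrary 2-kb distance cutoff
from annotated coding sequence.

`end_trim_recheck()` recomputes each site's depth and frequency ignoring
calls within 5 nt of read 3' ends and flags sites that no longer meet
the calling thresholds. This is an in-pileup equivalent of remapping
after trimming 5 bp from every read — exact for ungapped alignments and
much cheaper; it is a deliberate departure from a literal re-run of an
aligner. Genuine editing is uniform along reads and survives; calls
driven by end-clustered mismatches collapse.

`dedupe_edit_sites()` collapses sites at homologous offsets of
identical repeat pairs with the same base change, keeping one
representative per group. Deduplication is driven by an explicit repeat
table rather than by suppressing calls inside repeats: variant callers
that silently misbehave in repeats were a documented failure mode of the
workflow this package systematizes, so calling stays per-column on
whatever alignments are provided and duplicates are resolved openly.
`summarize_editing()` then reports per-category counts, unique
(deduplicated) counts and mean frequencies over unique, non-artifact
canonical sites, with protein-coding and total roll-ups. Reference
assembly errors masquerading as editing (identical-looking repeats that
actually differ at the DNA level) are out of detection scope; they
surface as non-canonical calls and are the analyst's cue to inspect the
assembly.

## The synthetic study

`generate_study()` builds, by default, 8 chromosomes of 20-60 kb (grown
when planted content needs room), 10 protein-coding genes, and 2
chromosomes with no annotation — a desk-scale stand-in for a 7-Mb,
63-chromosome genome that keeps generation under two minutes on one
CPU. The planted structures mirror the phenomena the pipeline screens
for:

- genes at 250-800× in mitochondrial-enriched libraries, attenuated
  20-fold (`tc_attenuation = 0.05`) in total-cellular libraries,
  consistent with enrichment-driven mapping-rate differences; one gene
  carries an intron, one a mid-CDS coverage collapse at 60 % of its
  transcript, two lack 3' processing (run-on past the stop), the rest
  end sharply at the stop codon;
- a pseudogene, and plastid/nuclear insert regions expressed at full
  depth in total-cellular libraries with a 0.4× cross-mapped signal in
  mitochondrial ones, so they are detectable yet classify `tc_enriched`;
- five intergenic regions at 300-900×, two of them on an annotation-free
  chromosome; one contains a planted 729-bp ORF (its region is redrawn
  until no competing ORF ≥ 201 nt exists inside it, so the ORF screen
  has an unambiguous winner), another a verbatim 390-nt copy of a gene's
  3' end as cross-mapping bait;
- an identical 2-kb repeat pair, both copies expressed, with an editing
  site planted at the same offset in each;
- canonical C-to-U editing sites at frequencies 0.1 through 0.9 across
  coding (codon-templated so synonymous/nonsynonymous truth is forced by
  the genetic code), intron (one interior, one 10 nt from an exon
  boundary to exercise the exclusion), UTR, pseudogene and IGS contexts
  — realized by flipping the base on each covering read independently
  with the planted frequency, i.e. exactly the binomial model the
  caller assumes;
- three non-canonical artifact sites supported only by reads whose 3'
  ends pile within 5 nt of the site (the generator's abstraction of
  1-bp adapter remnants), at ~0.9× the local depth so they pass the
  caller and must be caught by the end-trim recheck;
- four small-RNA stacks (pooled mitochondrial counts 190, 155, 75 and
  45 — the last deliberately below the 50 threshold) at quiet loci, and
  degradation smears over every expressed unit in proportion to its
  mRNA depth, which also induces the positive small-RNA/mRNA coverage
  correlation;
- uniform background "spurious transcription" at 2× per strand
  genome-wide.

Reads are emitted pre-mapped as coordinate-sorted SAM (a deliberate
departure from a FASTQ-plus-aligner round trip: mapping is out of scope
and emitting alignments keeps the truth table exact). A single seeded
RNG drives every draw, so a spec and seed reproduce the study
byte-for-byte.

What the generator does **not** emulate — and hence what green tests do
not establish about real data: base-call errors and quality scores,
indels, spliced alignments across the planted intron, multi-mapping
ambiguity beyond the one repeat pair, fragment-length biases, and real
adapter chemistry (end-biased mismatches are planted abstractly). The
recovery tests show the implementation is correct under its stated
model, not that the thresholds are optimal for any particular tissue or
platform.

## Numerical choices and degenerate inputs

Nearest-rank quantiles (no interpolation) keep thresholds equal to an
observed window value. Strict inequality for region calling versus
inclusive thresholds for editing depth/frequency follow the published
conventions they pin (">100×" versus "a minimum of"). Ranking and
candidate tables order deterministically, so reruns are byte-identical.
Empty inputs return typed empty tibbles rather than errors wherever an
empty result is meaningful (no alignments → zero coverage; no windows
above threshold → no regions); undefined statistics (zero-variance
correlation) return NA with a warning; contract violations (features off
the genome, unequal repeat-pair lengths, unresolvable codon phase) are
fatal with the offending feature named.

## Problem sizes

The test suite and the acceptance script run the full synthetic study —
about 350 kb of genome and roughly 300,000 mRNA alignments across four
libraries plus four small-RNA libraries — in a few minutes on one CPU;
oracle-equivalence tests run on ≤ 10-kb instances where brute force is
exact. These sizes were chosen as the smallest at which every planted
phenomenon (window-scale regions, 100×-depth editing calls, stack
versus smear separation) is realized with comfortable statistical
margins.

## Limitations

Beyond the generator's idealizations listed above: the pipeline accepts
whatever multi-mapping behavior the upstream aligner produced and does
not re-resolve it (cross-mapping is flagged, not corrected); t-element
(tRNA-like 3'-processing element) identification is out of scope;
similarity searches of candidate ORFs and small RNAs against external
databases are left to the exported FASTA plus external tools; and the
optional genomic-DNA evidence hook for distinguishing editing from
reference error is off by default because it needs inputs this package
does not generate.
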