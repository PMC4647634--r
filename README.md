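# mitotranscriptr

Characterization of transcription across multichromosomal plant
mitochondrial genomes from strand-specific RNA-seq alignments.

Plant mitochondrial genomes — most dramatically in *Silene* species,
where they reach several megabases split into dozens of circular-mapping
chromosomes — consist overwhelmingly of intergenic sequence, and some
chromosomes carry no annotated gene at all. Whether those regions harbor
unannotated functional elements is an open question that RNA-seq can
address: intergenic transcription shows up as localized coverage, novel
protein-coding candidates as expressed ORFs, functional small RNAs as
discrete read stacks, and active post-transcriptional processing as
C-to-U RNA editing. `mitotranscriptr` implements that screen as a set of
composable, tibble-returning functions for R users working with
organellar transcriptomes:

- **Coverage profiling** — strand-specific per-base depth
  (`compute_depth()`), sliding-window profiles in CPM
  (`window_profile()`, e.g. 500/250-nt windows), empirical tail
  thresholds (`tail_threshold()`), and per-gene RPKM
  (`gene_expression_rpkm()`), where
  `RPKM = reads / (kb of feature x millions of mapped reads)`.
- **Expressed-region screen** — windows above a depth threshold merge
  into regions (`detect_expressed_regions()`); regions are classified
  `mito_enriched` / `tc_enriched` / `ambiguous` by comparing CPM between
  mitochondrial-enriched and total-cellular libraries
  (`classify_enrichment()`), and flagged when exact k-mer sharing with a
  gene elsewhere suggests cross-mapping (`flag_cross_mapping()`).
- **3' processing diagnostics** — `cds_coverage_dropoff()` measures the
  depth ratio across the stop codon (sharp drop-offs indicate efficient
  3' transcript processing) and scans for mid-CDS coverage collapses.
- **ORF screen** — six-frame discovery under the standard genetic code
  (`find_orfs()`, minimum 201 nt including the stop codon), distance
  filtering against annotation (`filter_remote_orfs()`, > 2 kb), and
  expression ranking (`rank_orfs_by_depth()`, top 5 % with a 100x
  high-depth flag).
- **Small-RNA stack caller** — `filter_smallrna_reads()` keeps perfect
  17-25-nt matches off the coding strand of annotated genes;
  `stack_candidates()` calls groups of reads sharing an exact start and
  length with at most one overlapping neighbor and >= 50 pooled reads in
  mitochondrial-enriched libraries; `smallrna_mrna_correlation()`
  quantifies how much small-RNA signal tracks long-transcript coverage.
- **RNA-editing caller** — strand-aware pileup (`build_pileup()`),
  calling at >= 100x depth and >= 20 % variant frequency
  (`call_edit_sites()`), canonical C-to-U typing (genomic C->T on plus-,
  G->A on minus-strand transcripts), codon-aware category assignment
  (`classify_edit_sites()`), read-end artifact rechecking
  (`end_trim_recheck()`), repeat-aware deduplication
  (`dedupe_edit_sites()`) and per-category summaries
  (`summarize_editing()`).
- **Synthetic studies** — `generate_study()` plants all of the above
  structures into a toy multichromosomal genome with a machine-readable
  truth table, so the whole pipeline is testable without any download.

`run_pipeline()` orchestrates every stage from FASTA + GFF3 + SAM/BAM
inputs to TSV/BED/VCF outputs with a run manifest.

## Worked example

```r
library(mitotranscriptr)
library(dplyr)

# a synthetic study: 8 chromosomes (2 with no annotated gene), 10 genes,
# planted intergenic transcripts, editing sites, small-RNA stacks
sim <- generate_study(simulation_spec(seed = 1), dir = tempfile())

res <- run_pipeline(
  pipeline_config(),
  genome_path = sim$paths$genome,
  annotation_path = sim$paths$annotation,
  sam_paths = sim$paths$sam,
  libraries = mutate(sim$libraries, total_mapped_reads = NA),
  repeat_pairs = sim$truth$repeat_pairs,
  out_dir = tempfile())

nrow(res$regions)                  # 20 expressed regions
table(res$regions$enrichment)      # mito_enriched: 18, tc_enriched: 2
sum(res$regions$cross_map)         # 1 (a verbatim gene-3'-end duplication)
res$orfs[1, c("length", "mean_depth", "high_depth")]
#   length mean_depth high_depth
#      729    1903.55       TRUE
glance(res$edit_sites)[, 1:4]
#   n_sites n_canonical n_noncanonical canonical_pct
#        15          12              3            80
sum(res$edit_sites$artifact)       # 3: all flagged by the 5-nt end recheck
res$smallrna_mrna_r                # 0.8872804
summarize_editing(res$edit_sites)
```

The editing summary is a per-category table (protein-coding split into
synonymous/nonsynonymous, pseudogene, intron, UTR, IGS, totals) of site
counts, repeat-deduplicated unique counts, and mean editing frequencies
over unique sites.

Plotting: `autoplot()` methods exist for window profiles (genome-wide
coverage panels), expressed-region tables and editing summaries;
`tidy()`/`glance()` methods summarize coverage tracks, profiles and
edit-site tables.

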