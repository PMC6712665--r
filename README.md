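# emgekit

Discovery, classification, host assignment and quantification of
**extrachromosomal mobile genetic elements** (eMGEs — plasmids and
bacteriophages) from long-read metagenome assemblies.

Most gut plasmids and many phages replicate as circular molecules, so a
complete eMGE shows up in an assembly as a **circular contig (CC)**.
Assembly graphs of complex communities, however, leave many potential
circles tangled at shared junctions. `emgekit` implements a post-assembly
pipeline that recovers, characterizes and quantifies these elements:

1. **Bin-guided circularization** — external genome-bin labels untangle
   the unitig graph: a junction with exactly one in-edge and one out-edge
   carrying the *same* bin ID is merged, iterated to a fixed point; the
   surviving self-loops of at least 2.2 kb are reported as circular
   contigs. Unbinned unitigs get fresh unique bin IDs so repeats never
   self-merge.
2. **Phage/plasmid classification** — fraction of genes with phage
   orthologous group (POG) hits at > 90 % length coverage, a fixed list of
   13 plasmid-enriched COGs (replication, toxin–antitoxin, type IV
   secretion), reference similarity (≥ 90 % identity, ≥ 70 % coverage),
   and optional external classifier verdicts; plasmid is the default
   class and reference plasmid hits override POG evidence with a conflict
   flag.
3. **Terminal direct repeat (TDR) detection and linearization** — a
   linear phage genome whose ends carry an identical ~kb repeat
   misassembles as a circle one repeat copy short. The collapsed repeat
   betrays itself by about twofold read coverage, an excess of read
   termini at its boundaries, and the absence of reads spanning it.
   `detect_tdr()` finds it, `linearize()` re-expands the genome with the
   repeat verbatim at both ends, and `gc_skew()`/`skew_transition()`
   profile the replication structure of the corrected genome.
4. **Host prediction** — three independent lines of evidence:
   Spearman co-occurrence of length-normalized abundances across samples
   (SCC ≥ 0.7); CRISPR spacer–protospacer matches (spacers ≥ 20 bp, at
   most 1 mismatch, > 95 % coverage, both strands); and shared DNA
   methylation motifs with equal binarized IPD (inter-pulse duration)
   states, using motifs filtered at methylated fraction ≥ 0.6 and mean
   coverage ≥ 25 with the ubiquitous motif GATC (m6A) excluded and IPD
   ratios binarized at 2.5. `consolidate_hosts()` reports per-method
   calls with rank-by-rank agreement flags.
5. **Quantification and enrichment** — elements with read coverage
   breadth < 60 % are excluded; the rest cluster at ≥ 90 % identity,
   ≥ 70 % coverage of the shorter sequence and ≥ 0.7 length ratio
   (connected components); reads at ≥ 95 % identity are counted once per
   cluster and normalized by the longest representative. The
   plasmid-per-chromosome ratio is estimated as
   `(reads_emge / mean_emge_size) / (reads_chrom / mean_chrom_size)`.
   Per-COG and per-category Fisher's exact tests with q-values compare
   plasmid against chromosome gene content; a Wilcoxon rank-sum test
   compares abundances of ARG-positive and ARG-negative plasmids.

A **synthetic community generator** (`sim_config()`,
`generate_community()`, `simulate_reads()`, `simulate_motif_profiles()`,
`simulate_abundance_matrix()`) builds ground-truth communities — host
chromosomes carrying circular plasmids and linear TDR phages, long/short
reads, IPD kinetics, CRISPR arrays holding protospacers of resident
phages, and abundance matrices in which eMGEs covary with their hosts —
so every stage is testable against known truth.

## Worked example

```r
library(emgekit)

cfg <- sim_config(seed = 42)            # 5 hosts, 10 plasmids, 3 phages
truth <- generate_community(cfg)
#> community_truth: 5 hosts, 10 plasmids, 3 phages

## recover circles from the bin-annotated unitig graph
graph <- community_unitig_graph(truth, pieces = 3)
res <- circularize(graph)
length(res$circles)
#> [1] 13                                # all 10 plasmids + 3 phage circles

## detect and correct a misassembled linear phage
cfg0 <- sim_config(seed = 42, long_error_rate = 0, short_error_rate = 0)
truth0 <- generate_community(cfg0)
ph <- truth0$phages[[1]]                # true TDR length: 1614 bp
cc <- misassemble_tdr_as_circle(ph)
long_reads  <- simulate_reads(truth0, cfg0, "long",  elements = ph$id)
short_reads <- simulate_reads(truth0, cfg0, "short", elements = ph$id)
aln_l <- project_reads_onto_circle(long_reads$alignments,  ph$length, ph$tdr_length)
aln_s <- project_reads_onto_circle(short_reads$alignments, ph$length, ph$tdr_length)
tdr <- detect_tdr(cc, aln_l, aln_s)
tdr$tdr_interval
#> [1] 46889 48503                       # detected length 1614 bp: exact
tdr$evidence$coverage_ratio
#> [1] 1.94                              # ~twofold over the collapsed repeat
tdr$evidence$spanning_reads
#> [1] 0                                 # no read spans the repeat
lin <- linearize(cc, tdr$tdr_interval, evidence = tdr$evidence)
identical(lin$sequence, ph$sequence)
#> [1] TRUE                              # misassembly fully corrected

## link eMGEs to hosts by shared methylation motifs
profs <- simulate_motif_profiles(truth, cfg)
baits <- filter_motifs(profs[profs$sequence_type == "chromosome", ])
links <- link_by_motifs(profs[profs$sequence_type != "chromosome", ],
                        profs[profs$sequence_type == "chromosome", ], baits)
head(links[, c("emge_id", "host_id", "method", "score")], 4)
#>      emge_id host_id      method score
#> 1 plasmid_01 host_01 methylation    10
#> 2 plasmid_02 host_02 methylation    10
#> 3 plasmid_03 host_03 methylation    10
#> 4 plasmid_04 host_04 methylation    10
```

The detected interval's length equals the true repeat exactly because
read termini pile up at the collapsed repeat's boundaries (the linear
template's molecule ends), and `detect_tdr()` snaps the coverage-based
candidate to those pileups. The methylation score counts the baited
motifs shared, with equal binarized IPD state, between element and bin.

## Scope

The pipeline consumes assemblies, bin labels, alignments, gene/motif
tables and spacer lists; it does not run assemblers, binners, aligners,
gene callers or HMM searches. See the methods vignette
(`vignettes/emge-discovery.Rmd`) for the model, parameter and design
discussion.
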