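---
title: "Discovering and quantifying extrachromosomal mobile genetic elements"
author: "emgekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and quantifying extrachromosomal mobile genetic elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgekit)
```

## The problem

Plasmids and many gut bacteriophages replicate apart from the host
chromosome. Because most are circular molecules, a completely assembled
element appears as a circular contig (CC), and a long-read metagenome
assembly can in principle deliver entire plasmidomes and phageomes as
closed sequences. Two obstacles stand in the way. First, assembly
graphs of complex communities leave circles entangled: a junction shared
with another genome breaks the circle into unitigs. Second, some phages
that *look* circular are not: a linear genome carrying an identical
terminal direct repeat (TDR) at both ends collapses during assembly into
a circle one repeat copy short. `emgekit` addresses both, then carries
the recovered elements through classification, host assignment,
quantification and functional comparison.

## Bin-guided circularization

The model of the assembly graph is deliberately minimal: unitigs are
edges, junctions are nodes, and each unitig runs from its head junction
to its tail junction. External binning assigns each unitig a bin ID —
a proxy for "same genome". The single merging rule is:

> if a junction has exactly one in-edge and exactly one out-edge and
> both carry the same bin ID, concatenate them.

Unbinned unitigs receive fresh unique bin IDs, so an unbinned repeat can
never merge with itself and spurious self-loops are avoided. Merging is
iterated to a fixed point (a single-sweep mode is exposed via
`fixed_point = FALSE` for comparison). The rule is *confluent*: each
merge is local to one junction and removes it, so no merge can enable or
disable a merge elsewhere, and the fixed point is independent of visit
order. The test suite verifies this by exhaustive enumeration of all
merge orders on random graphs.

Three design points were genuinely open:

* **Orientation.** The merge is applied only head-to-tail; a junction
  where two unitigs meet head-to-head or tail-to-tail cannot satisfy
  the one-in-one-out rule and is reported as an orientation conflict
  rather than resolved by reverse complementation. This is the
  conservative reading; flipping sequences would silently commit to one
  of two possible layouts.
* **Merged depth** is the length-weighted mean of the members, the
  unbiased estimate under uniform coverage.
* **Canonical rotation.** A circle's sequence is emitted as the
  lexicographically minimal rotation of whichever strand has the
  smaller minimal rotation. Comparing *unrotated* strands would make
  the strand choice depend on where the assembler happened to open the
  circle; comparing minimal rotations makes the output a true canonical
  form, identical across runs.

Circles shorter than 2.2 kb are suppressed: the assembly overlap cutoff
(2 200 bp between error-corrected subreads) means smaller circles cannot
be assembled faithfully in the first place, so calls below it would be
artifacts.

## Classification

Evidence is gene-level. The fraction of a CC's genes with phage
orthologous group hits covering **strictly more than 90 %** of the gene
calls phages; the presence of any of 13 plasmid-enriched COGs
(replication, toxin–antitoxin, type IV secretion: COG1475, COG2026,
COG2126, COG2336, COG2948, COG3077, COG3451, COG3505, COG3704, COG3736,
COG3843, COG5527, COG5655) supports plasmid origin; reference similarity
(identity ≥ 90 %, CC coverage ≥ 70 %, interval-union coverage on the CC)
assigns known elements. External classifier verdicts may be supplied as
columns — virome-classifier categories 1, 2, 4 and 5 count as phage
evidence while 3 and 6 are ignored as false-positive-prone — but no
external tool is ever invoked.

The POG-fraction cutoff that turns "phage-like gene content" into a
phage call is not a published constant; the default is 0.5 and it is an
exposed parameter (`phage_call_fraction`). Plasmid is the default class:
a CC with no phage evidence is a plasmid. When a reference assignment
says plasmid but the POG fraction clears the phage bar, the reference
wins and the call is flagged `conflict` — gene content occasionally
looks phage-like on genuine plasmids, and the flag preserves the
disagreement instead of hiding it.

## Terminal direct repeats

On a misassembled circle, the collapsed repeat region shows three
signals, each computed by its own function so they can be inspected
separately:

* about **twofold coverage** (`coverage_profile`) — both repeat copies'
  reads map onto one collapsed copy;
* **read-terminus pileups** at the repeat boundaries
  (`read_start_profile`) — reads of a linear molecule are clipped at
  its physical ends, and those ends project exactly onto the collapsed
  repeat's boundaries;
* **no spanning reads** (`spanning_count`) — the junction between the
  two repeat copies does not exist in the molecule, so no read can
  cross the collapsed repeat with flanks on both sides (100-bp flanks
  by default).

`detect_tdr()` combines them: the depth profile is smoothed with a
circular running mean (default 500 bp) and thresholded at `ratio_low`
(default 1.6, an operationalization of "about twofold" — the evidence
reports the observed ratio) times the median; the longest circular run
is the candidate; its boundaries are snapped to the strongest read
terminus pileups within the smoothing window; the candidate is accepted
only with at most `max_spanning` spanning reads (default 0, i.e.
absence) and a terminus excess of at least 3x background at both ends.

Evidence is split by read type. Long reads, which are longer than the
repeat itself, are the only way to establish *absence of spanning* and
give clean terminus pileups — but they are hopeless at measuring the
coverage of a 1–3 kb plateau precisely (a 2-kb region holds only a
handful of independent 8-kb reads, so region means fluctuate by
±15–20 % at 30x). Short reads resolve the plateau to a few percent.
`detect_tdr()` therefore uses short-read coverage for the candidate and
the reported ratio whenever short alignments are supplied, and falls
back to long-read coverage otherwise; spanning and terminus evidence
always come from long reads. The per-position mean-depth gate
(`min_depth = 10`) returns an explicit `"insufficient-coverage"`
no-call rather than a silent negative.

`linearize()` re-expands the genome: repeat + rotated circle, so the
repeat appears verbatim at both ends (no consensus polishing between
copies — the copies are near-identical in practice, and inventing a
consensus would erase the observable differences). On error-free
fixtures `linearize()` inverts `misassemble_tdr_as_circle()` exactly,
which the suite asserts.

GC skew is computed in 100-bp windows at a 50-bp step,
`(G − C)/(G + C)` with empty windows missing; the replication transition
is located at the largest extremum of the cumulative skew.

## Host prediction

Three methods, deliberately independent, never overriding one another:

* **Co-occurrence**: Spearman correlation (average ranks under ties) of
  length-normalized abundances across samples, threshold 0.7
  *inclusive* ("SCCs of ≥ 0.7"). At least 3 samples are required;
  constant vectors are skipped rather than given an undefined rank
  correlation.
* **CRISPR spacers**: ungapped Hamming matching of spacers ≥ 20 bp over
  both strands, at most one mismatch, coverage > 95 % (full-length
  matches, so coverage is automatically complete). Gapped alignment
  adds nothing at these lengths and word sizes; an exhaustive
  sliding-window oracle in the tests confirms exact agreement.
* **Methylation motifs**: chromosome-bin motifs passing methylated
  fraction ≥ 0.6 and mean coverage ≥ 25 (both inclusive; the wording
  names thresholds, not open bounds) become baits; GATC (m6A) is always
  removed because it is ubiquitous among bacteria and carries no
  host-specific signal. Mean IPD ratios binarize at strictly > 2.5
  ("higher than the threshold"). An eMGE links to a bin when at least
  one baited motif occurs in both and *every* baited motif present in
  both agrees in binarized state, missing values acting as wildcards.
  The all-shared-must-agree reading is the stricter of the two
  possible interpretations and is what gives the method its precision.

`consolidate_hosts()` reports each method's hosts side by side with
`agree@rank` / `conflict@rank` flags computed rank-by-rank on the
provided taxon strings; no taxonomy database is consulted.

## Quantification

Breadth of coverage (union of aligned intervals over element length) at
≥ 60 % gates elements into clustering. Pairs are similar at identity
≥ 90 %, alignment coverage ≥ 70 % measured on the **shorter** sequence
(the source is silent on which; together with the 0.7 length-ratio
condition this is the self-consistent permissive reading), and
shorter-to-longer length ratio ≥ 0.7; clusters are connected components
(single linkage, the simplest rule consistent with the description —
clusters whose internal pairs violate the thresholds are flagged
`nontransitive`). Reads at ≥ 95 % identity count once per cluster (best
hit: identity, then fewest mismatches, then lexicographic cluster id)
and are normalized by the longest representative's length.

The ratio estimator
`(reads_emge / mean_emge_size) / (reads_chrom / mean_chrom_size)`
converts read counts into molecules per chromosome. Gene-based
composition scores a taxon by the sum over its genes of contig depth
divided by gene length, normalized across taxa — exact when taxa carry
comparable gene panels, which is how the concordance check constructs
its fixtures. Fisher's exact tests (two-sided, minimum-likelihood
definition) with Benjamini–Hochberg q-values (a Storey-style `pi0`
rescaling is available via `q_method = "storey"`) compare COG content;
the Wilcoxon rank-sum test compares ARG-positive and ARG-negative
plasmid abundances, exact for small samples.

## The synthetic community

The generator emulates exactly the statistical structure each stage
assumes, with ground truth for recovery testing. Defaults are the study
conditions of the validation suite:

| parameter | default | why |
|---|---|---|
| hosts / plasmids / phages | 5 / 10 / 3 | small community with multiple elements per host |
| chromosome length | 50–100 kb | desk-scale stand-ins for Mb-scale genomes; long enough to carry motif and CRISPR structure |
| plasmid length | 5–20 kb | typical small-plasmid range |
| phage length, TDR | 30–60 kb, 1–3 kb | phage-genome scale with a kb-scale terminal repeat |
| plasmid copy ratio | 3.0 per chromosome | the community-level design point for the ratio estimator |
| long reads | lognormal, 8 kb median, 10 % error | long-read length/error regime |
| short reads | 150 bp, 0.2 % error | short-read regime |
| depth | 30x per copy | enough for TDR and motif evidence without waste |
| IPD model | methylated N(4.0, 0.5), unmethylated N(1.0, 0.2) | Normal on the ratio scale, separated by the 2.5 cutoff; no generative model is published, so separation is the design criterion |
| methylated fraction | Beta(18, 2) vs Beta(1, 19) | concentrated near 0.9 / 0.05 |
| abundance | lognormal hosts (sdlog 1), coupling noise sdlog 0.3, multinomial reads | eMGEs covary with their hosts across samples |

Choices worth calling out:

* **One root seed, labelled child streams.** Every sub-generator derives
  its own seed from `child_seed(seed, label)`, so adding a stage never
  perturbs the draws of another and any stage is reproducible in
  isolation.
* **Disjoint motif sets per host.** Restriction–modification systems
  are host-specific; each host methylates GATC (ubiquitous, excluded by
  the filter — its presence exercises that rule) plus 1–3 motifs drawn
  without replacement across the community. Shared motifs between hosts
  would make methylation host assignment ill-posed, which is a fact
  about the method, not the generator.
* **Linear templates are sheared molecules.** Read start positions may
  fall before the template start and reads are clipped at the ends.
  This yields flat coverage *and* the terminus pileups at the genome
  ends that real linear molecules produce — the very signal the TDR
  detector uses — and guarantees by construction that no read crosses
  the non-existent junction between the two repeat copies.
* **Constant plasmid copy number** (`3.0 * n_hosts / n_plasmids` each)
  keeps the community-level copies-per-chromosome exactly at the design
  point, so estimator error is attributable to sampling, not to
  configuration drift.

What the generator does **not** emulate: strain microdiversity,
chimeric reads, homopolymer-biased errors, real SMRT kinetics, gene
content (gene tables for the classifier are constructed directly), or
Mb-scale chromosomes. Passing tests therefore demonstrate correctness
of the *decision rules and estimators* under their stated assumptions,
not robustness to every artifact of real sequencing.

## Validation design and problem sizes

The suite validates each stage against an independent oracle computed
from first principles: exhaustive merge-order enumeration for the
circularizer (100 random graphs of up to 15 unitigs), average-rank
Spearman, hypergeometric Fisher enumeration, permutation Wilcoxon,
sliding-window Hamming spacer search, position-marking coverage, and
transitive-closure clustering (50 elements including near-duplicate
pairs). Simulation-based checks use 20 seeds each: TDR recovery on 20
collapsed linear genomes (detected length within ±10 %, observed
coverage ratio within [1.8, 2.2], zero spanning reads) with 20 circular
negative controls, host-prediction precision/recall on the default
community, and ratio-estimator recovery within ±10 % of 3.0 from 1e5
reads per seed. These sizes keep the full suite at about two minutes
while leaving each check statistically meaningful.

## Known limitations

* The circularizer resolves only the stated one-in-one-out rule; longer
  repeat structures stay unresolved, by design.
* TDR boundary refinement relies on terminus pileups; with very low
  depth the smoothed-coverage boundaries (±smoothing window) are used.
* Methylation linking assumes motif profiles are comparable between
  elements and bins; mosaic methylation within a bin would confound it.
* Single-linkage clustering can chain through intermediate elements;
  such clusters are flagged rather than re-cut.
* The ratio estimator assumes read sampling proportional to molecule
  length; strong GC or length biases in library preparation would bias
  it.
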