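---
title: "Homology-based pseudogene prediction with pseudoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-based pseudogene prediction with pseudoscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoscan)
```

## The problem

Pseudogenes are defective paralogous copies of functional "parent" genes.
They arise mainly by two mechanisms, each leaving a diagnostic signature:

* **Processed pseudogenes (PPGs)** are reverse-transcribed copies of mature
  mRNA. They lack introns and a promoter, typically end in a 3' poly-A
  tail, are flanked by short identical target-site duplications (TSDs)
  left by the insertion machinery, and are often 5'-truncated because
  reverse transcription aborts early.
* **Duplicated (unprocessed) pseudogenes (DPGs)** arise from genomic
  duplication. They retain the parent's exon-intron structure but carry
  disabling mutations: premature stop codons, frameshifts, disruptive
  indels.
* **Unitary pseudogenes (UPGs)** are single-copy genes disabled in place.
  Because no functional counterpart survives, homology-based prediction
  cannot find them; they matter only for evaluation accounting.

Because pseudogenes retain sequence similarity to their parents, the
standard prediction strategy is: search parent proteins against the
intergenic portion of a genome, assemble the local hits into candidate
loci, re-align each candidate to its parent so that the disablements
become visible, and classify by structural evidence. `pseudoscan`
implements that strategy end to end, together with the overlap-based
protocol used to benchmark such pipelines against a known pseudogene
annotation, and a simulator that generates fully annotated synthetic
genomes so every stage is testable without external data.

## Pipeline stages and their models

### 1. Search space

The genome is hard-masked: every base inside a repeat interval or an
annotated parent gene span is replaced by `N` (`build_intergenic()`).
Masking is idempotent and length-preserving; translated codons containing
`N` become `X`, which scores 0 against every residue, so masked regions
are invisible to the search. Soft-masked input is hardened on load.

### 2. Translated homology search

`search_hits()` aligns each parent protein against all six translated
frames of every sequence. The implementation is seed-and-extend: exact
amino-acid words (`seed_word_size`, default 4) are clustered by diagonal,
clusters with at least `min_seeds` (2) words define windows, and each
window is aligned by exact affine-gap Smith-Waterman. Within a window the
alignment is iterated with masking so multiple copies are all found. On
instances small enough to check, the windowed search attains the full
Smith-Waterman optimum (this is a tested invariant).

Significance uses the Karlin-Altschul formula `E = K m n exp(-lambda S)`
with `m` the query length and `n` the unmasked translated search-space
size; `lambda = 0.267`, `K = 0.041` are the published gapped-BLOSUM62
constants, so E-values approximate rather than replicate NCBI tBLASTn.
Hits with `E < 1e-5` (the conventional threshold, configurable) are kept.
The filter is applied per hit, before chaining. A stop codon in a
translated frame scores -4 against everything at this stage: stops must
not be rewarded during search; counting them is the realignment's job.

### 3. Chaining

Hits of one parent on one sequence are made pairwise-disjoint by an exact
maximum-weight interval-scheduling selection (`partition_disjoint()`);
the surviving "disjoint hits" play the role of pseudo-exons. Colinear
neighbours (genomic gap at most `max_merge_gap`, protein order consistent
with the strand, protein overlap at most `max_protein_overlap`) merge
into candidate loci (`merge_adjacent()`). Where loci of different parents
overlap, only the top-scoring locus survives, with ties broken by
identity and then parent id, so each locus has exactly one parent and the
output is invariant under permutation of its input
(`assign_best_parent()`).

`max_merge_gap` defaults to 5000 nt: large enough to bridge retained
introns and small insertions, small enough not to fuse unrelated loci. No
published value exists for this distance; it is configuration, and all
downstream results reported by the package are robust to it in the range
of a few kilobases.

### 4. Disablement-aware realignment

Each locus (plus `flank` = 300 nt of context per side) is re-aligned to
its parent protein by a dynamic program whose moves are: codon
match/substitution; codon gaps in either sequence (affine, 11/1 in codon
units); frameshift "codons" of 1, 2, 4 or 5 nt (penalty -15); and intron
skips of at least `min_intron` = 40 nt (penalty -8, free extension, +4
split between GT donor and AG acceptor). Premature stops score -10 and
are counted, not forbidden. Intron skips are distinguished from ordinary
deletions purely by length, with the splice bonus as soft evidence.

The alignment is local at both ends. A strictly protein-global polarity
would force fragments and 5'-truncated copies to stretch across unrelated
sequence; instead, unaligned parent ends are reported as 5'/3' truncation
(`detect_truncations()`), and on clean full-length inputs the optimum
coincides with protein-level global alignment (a tested limit case).
Because an intron skip is cheap, a lucky two-codon match in flanking DNA
could otherwise telescope the reported span; terminal segments scoring
below `min_exon_score` (20) are therefore trimmed after traceback. The
reported score is the DP optimum and is checked against an exhaustive
path-enumeration oracle on small instances.

### 5. Classification

`classify_call()` applies the structural rules in fixed order:

1. coverage below `fragment_max_coverage` (0.70) -> **fragment**. No
   published threshold exists; 0.70 follows common pipeline convention.
2. intron loss at the parent's junctions -> **processed**. A junction is
   "lost" when the alignment is contiguous there (no intron gap within
   `junction_tol` = 10 aa).
3. parent intronless and a poly-A tail present -> **processed** (poly-A
   verification exists precisely because some parents have no introns).
4. otherwise -> **duplicated**; candidates with no disablement at all are
   still emitted, flagged `no_disablement`.

Poly-A detection scans `polyA_window` (50) nt downstream of the
strand-aware 3' end for a `polyA_min_run_window` (20) nt window with A
fraction at least `polyA_min_fraction` (0.8), then extends the reported
interval over the maximal A run. TSD detection searches for an identical
k-mer (5-20 nt) ending at the insertion's left boundary and recurring at
its right boundary. Two positional regimes are used: a tight one (2 nt of
slack, any k) and a slack one (18 nt, k >= 8 only) that tolerates
alignment end-clipping and a diverged poly-A tail between the element and
its downstream TSD; the k >= 8 restriction keeps the measured
false-positive rate on random flanks around 1-2%, well under 5%.
Truncation is recorded on both ends for all classes; the textbook claim
that duplicated pseudogenes truncate only at 3' is known to be unreliable
and is not enforced.

Unitary pseudogenes are deliberately **not** a predictable class: with the
parent absent from the query set there is nothing to align. They exist in
the simulator truth and in evaluation accounting only.

### 6. Ka/Ks validation channel

For every call, clean aligned codon columns (in-frame, gap-, frameshift-
and stop-free) yield parent/pseudogene codon pairs, from which `ng86()`
computes Nei-Gojobori (1986) Ka and Ks: synonymous site fractions
averaged over both sequences (mutations to stop codons excluded from site
counting, so each sense codon contributes exactly 3 sites),
equal-weight pathway averaging for multi-nucleotide codon differences,
and the Jukes-Cantor correction `d = -(3/4) ln(1 - 4p/3)`. No
transition/transversion weighting is used: the simplest published
estimator is preferred because it is hand-checkable, and Ka/Ks here is a
set-level validation channel (pseudogenes, free of constraint, should sit
near 1; functional genes well below), never a per-call gate. Results with
fewer than 10 codon pairs are flagged unreliable; `p >= 3/4` is flagged
saturated and left undefined.

### 7. Evaluation protocol

A predicted and a known pseudogene are "the same" when the predicted
interval covers strictly more than 60% of the known element
(`overlap_params()`; the denominator is the known length by default, with
predicted-length and reciprocal modes available, and the report names the
mode). "Uniquely" is enforced as one-to-one matching, assigned greedily
by descending overlap with deterministic tie-breaks; strand is ignored
because known annotations often lack reliable strand. Reports carry exact
counts; percentages are displayed at one decimal, rounded half up.
`compare_toolsets()` adds pairwise common counts and Dice similarity
`2|common| / (|A| + |B|)`, union and per-tool unique counts.

## The simulator and what passing tests mean

`simulate_genome()` generates i.i.d. background DNA at a configured GC
content (0.40), places multi-exon parent genes (valid ORFs, GT..AG
introns at codon boundaries) and implants on random strands with
randomized spacers, and emits the genome, the parent annotation and a
truth table. Class recipes follow the formation mechanisms: processed =
spliced CDS, optional 5' truncation (probability 0.3, at most 25% of the
length), neutral mutation, poly-A tail (20-40 nt), identical TSDs (8-16
nt); duplicated = full genomic copy with one forced premature stop or
1-nt exonic deletion; unitary = duplicated-style implant whose parent is
withheld from the emitted annotation; fragment = a CDS sub-segment below
the fragment threshold. The truth interval is the element core; poly-A
and TSDs are recorded as context so overlap-based evaluation is not
inflated.

The default configuration is the package's reference study condition:
divergence 0.05 substitutions/site, indel rate 0.002/site, 20 processed
plus 20 duplicated implants drawn from 20 parents of at least 200 codons
on a 200 kb genome. Under these conditions the pipeline's tested
properties are recall >= 0.90 at the >60%-overlap criterion and class
accuracy >= 0.80 over seeds 1-5 (both are met with margin).

What the simulator does **not** emulate: repeat families (background is
i.i.d., so repeat masking is a no-op on simulated data), paralogous gene
families (parents are mutually unrelated, so the unique-parent rule is
never stressed by true paralogy), transcription-level evidence, GC
heterogeneity and mutation-rate variation along real chromosomes.
Passing the end-to-end tests therefore demonstrates correctness of the
machinery under the stated generative model, not expected accuracy on a
real plant genome, where repeat contamination and paralogy are the
dominant failure modes.

## Numerical and design choices

* **Coordinates** are 1-based inclusive on the forward strand throughout
  (the Bioconductor convention), converted only at the BED boundary.
* **Determinism**: prediction uses no randomness; every stage sorts its
  outputs, and all tie-breaks (score, identity, lexicographic id, start
  coordinate) are total, so re-running is bit-identical and input order
  never matters. The simulator is byte-identical under a fixed seed.
* **Degenerate inputs**: empty FASTA, empty parent sets, all-`N`
  sequences and zero-call runs return empty, typed results with warnings
  rather than errors; parents with internal stops or CDS length not
  divisible by 3 are rejected loudly (parents must be functional).
* **Problem sizes in the shipped tests** were chosen so the whole suite
  runs in about a minute: oracle equivalence on 1000 random local
  alignments (<= 20 aa x 40 aa) and 200 realignment instances
  (<= 15 aa x 60 nt), 100 disablement-counting constructions, 50-call
  Ka/Ks simulations, and five seeded end-to-end genomes at the reference
  condition.
* The terminal stop codon of the parent is excluded from the query: the
  protein alone is searched, and the stop sits just past the aligned
  region. This is noted for comparability with tools that include it.

## Known limitations

* E-values are calibrated, not empirical; absolute values can deviate
  from NCBI BLAST by an order of magnitude near the threshold.
* Intron boundaries are placed by score, not by a splice-site model;
  GeneWise-class HMMs would localise junctions more precisely.
* Very short pseudo-exons (under ~8 aa of conserved sequence) fall below
  seeding sensitivity and are recovered only via realignment across the
  locus.
* Heavily decayed pseudogenes whose best local alignment falls below the
  E-value threshold are invisible, as in any homology-based approach.
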