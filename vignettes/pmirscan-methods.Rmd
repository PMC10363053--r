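---
title: "Detecting plant microRNAs in human plasma small RNA data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting plant microRNAs in human plasma small RNA data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmirscan)
```

## The detection problem

A mature plant microRNA is a 21–24 nt RNA. In a plasma small-RNA library it
is indistinguishable, by length or abundance, from fragments of degraded
human RNA. Claims of dietary ("cross-kingdom") miRNA uptake therefore stand
or fall on the specificity of the detection protocol: the best-known
counter-argument is that putative plant miRNAs in human data were perfect
matches to portions of human ribosomal RNA. `pmirscan` encodes a
deliberately stringent protocol in which a read must simultaneously (a)
fail to match the host, (b) match a plant genome perfectly inside an
annotated miRNA locus, and (c) win a competitive scoring contest against
human and other-species references before it is called a pmiRNA.

This vignette documents the model behind each stage, the tunable parameters
and their defaults, the synthetic data the package tests itself on, the
numerical choices, and the known limitations.

## Pipeline model, stage by stage

### Ingestion and collapsing

Reads are uppercased, U is mapped to T, and reads outside 16–35 nt or
containing N are dropped. The window brackets the mature-miRNA size range
with margin for adapter-trimming variation; both bounds are arguments of
`read_fastq()`. Adapter and quality trimming are assumed done upstream — the
reader is a pass-through in that respect. N-containing reads are removed
because the downstream stages require unambiguous 100%-identity decisions.

All downstream work operates on *collapsed* reads (`collapse_reads()`):
unique sequences with per-experiment counts, ordered lexicographically so
every run of the pipeline is deterministic. Library size — the RPM
denominator — is fixed here, *before* host subtraction, so that RPM reflects
abundance relative to everything that was sequenced, not relative to the
non-host remainder. `build_matrix()` takes the denominator as an explicit
argument, so the post-host-filter convention is one line away if preferred.

### Host subtraction

A read is attributed to the host if it matches the host genome,
transcriptome or extra-chromosomal DNA *end-to-end, without gaps*, on either
strand, with at most `max_mismatches` (default 1) substitutions. End-to-end
rather than local matching is deliberate: local matching would discard
miRNA-sized reads that share short cores with the 3-Gb host by chance, and
the decisive human-identity test happens again, more strictly, at
classification. Matching uses a pigeonhole seed search (8-mer index,
`max_mismatches + 1` blocks) that is *complete* — it finds a qualifying
match whenever one exists — so the monotonicity properties tested in the
suite (raising the tolerance never retains more reads) hold exactly rather
than approximately. Attribution order is genome → transcriptome →
extra-chromosomal, first match wins.

### Plant mapping and annotation intersection

Mature miRNAs are encoded verbatim in their genome, so the defaults require
the full read at 100% identity (`min_identity = 1`, `min_coverage = 1`);
both are configurable for mutation-tolerant studies, in which case the
genome word size (default 16) should be lowered so seeds fit between
mismatches. A read may count in several species but counts once per species
(presence semantics). Counts are also reported per megabase of genome
(`normalize_by_genome_size()`): if alignments were chance hits, counts would
scale with genome size, and the reads/Mb column makes that visible.

Alignments then must overlap an annotated `miRNA`,
`miRNA_primary_transcript` or `pre-miRNA` feature by at least 90% of the
aligned span. Overlap is strand-agnostic because a mature miRNA may derive
from either arm of its precursor and annotation strand conventions vary.
Intervals are handled 0-based half-open internally; GFF3 I/O converts at the
file boundary.

### The aligner

The package carries its own local aligner so the whole protocol is
self-contained and oracle-testable: `smith_waterman()` is an exact
affine-gap dynamic program with a deterministic traceback (ties prefer
diagonal, then up, then left), and `seeded_search()` is a seed-and-extend
search over a k-mer index that runs the same dynamic program over candidate
windows on both strands. Whenever an exact word-size seed lies on the
optimal alignment, the seeded score equals the exact score; the test suite
verifies this on hundreds of constructed pairs, and independently checks the
dynamic program against `Biostrings::pairwiseAlignment()`.

Scoring defaults are the common nucleotide-BLAST parameterization — match
+2, mismatch −3, gap open 5, gap extend 2 — with Karlin–Altschul constants
λ = 0.625, K = 0.41, giving the bit score S′ = (λS − ln K)/ln 2 and
E = m·n·2^(−S′). Effective-length (edge) corrections to E are omitted: all
pipeline decisions are made on bit scores, never on E-value cut-offs, so the
correction would be cosmetic. Word sizes default to 11 for database search
and 16 for genome mapping (sensitivity vs speed).

### Competitive classification

Each surviving sequence is searched against exactly four databases: plant
miRNAs, human miRNAs, other-species miRNAs, human mRNA. Per database the
best hit is kept (bit score, then identity, then accession). The verdict
rule, in order:

1. any full-length 100%-identity hit to a *human* database →
   `discarded_human_identity`;
2. no hit anywhere → `no_hit`;
3. plant hit absent, or any competing database's best bit score ≥ the plant
   bit score → `discarded_not_top_plant` (the maximum must be strict; ties
   discard — the conservative reading of "highest bit score must be plant");
4. otherwise `validated_pmiRNA`.

"100% identity with human sequences" is interpreted at *full read length*:
requiring merely a local 100%-identity micro-match would discard nearly
every read, since short perfect cores are ubiquitous. A local mode remains
available by lowering the coverage component of the rule. The other-species
database participates in the strict-maximum rule exactly like the human
ones.

The KDE diagnostic (`kde()`, `overlap_coefficient()`) quantifies the
filter's effect: Gaussian kernel densities of the plant-miRNA and human-mRNA
bit scores on a common grid, and the integral of their pointwise minimum
(1 = indistinguishable score distributions, 0 = disjoint). On the synthetic
corpus the overlap drops from ≈ 0.46 over all classified sequences to
≈ 0.19 over validated ones — numbers the acceptance script recomputes on
every run.

### Quantification

RPM = 10⁶ · count / library size. The per-sequence summary is the mean over
*all* experiments, zeros included — a sequence absent from an experiment
counts as 0 there — and the overall mean/median/min/max are taken over those
per-sequence means. Both conventions (denominator stage, zero inclusion) are
explicit arguments or documented defaults, and the summary JSON records the
numbers actually computed.

### Target scoring and enrichment

Plant miRNAs recognize targets by near-full complementarity anywhere on the
transcript (not mainly the 3′ UTR as in animals), so `predict_targets()`
slides the miRNA over every transcript position. The expectation score per
site sums 0 for a Watson–Crick pair, 0.5 for a G:U wobble, and 1 for any
other mismatch, with penalties doubled at miRNA positions 2–13 (the
functionally critical pairing region in plant miRNA:target interactions) and
sites reported at expectation ≤ 5. These constants follow the published
plant-target-scoring family (miRU / psRNATarget lineage); they are a design
choice of this package, fully configurable via `target_schema()` and echoed
in the output metadata. Gapless sliding windows are the default; gapped
sites can be scored through the aligner module.

Enrichment is the upper-tail hypergeometric test P(X ≥ k) per term with
Benjamini–Hochberg adjustment across the tested terms, reported with
−log₁₀(adjusted p). BH is a deliberate, documented divergence from web-based
enrichment services with proprietary multiple-testing schemes; published
term-level values from such services are not a reproduction target.

### Clustering, project distribution, consensus

The validated-sequence × experiment matrix is clustered on both axes with
Euclidean distance on log(1 + RPM) and average linkage — unspecified
upstream, so chosen as the standard abundance-matrix defaults; a
presence/absence mode (binarized matrix, Jaccard distance) matches
clustering on detection alone. The numbers of experiment groups (EG) and
sequence groups (SG) are user inputs, defaulting to 5 and 4 (clipped to the
axis size), never auto-detected. Per experiment group, the project
composition is reported as percentages rounded half-up to two decimals; each
row sums to 100 within rounding.

`consensus_search()` tallies every k-mer (k in a configurable range,
default 10–12 in the pipeline) over the *unique* validated sequences and
reports those present in at least 90% of them, longest first; an empty
result is the "no conserved core" outcome.

## The synthetic corpus

The generator (`sim_config()`, `simulate_references()`, `simulate_reads()`)
defines the conditions under which the package validates itself:

- **Scale** (defaults): 200 kb host genome, 20 host transcripts,
  16 kb extra-chromosomal sequence; 3 plant genomes of 50 kb with 20
  annotated 21-nt miRNAs each; 5 experiments over 3 projects, 20 000 reads
  per experiment. Desk scale, chosen so the full corpus runs in well under a
  minute per pipeline pass while every stage still sees thousands of
  sequences.
- **Read classes**: 70% host (exact substrings of the host references,
  either strand), 10% spiked plant miRNAs, 10% rRNA-like decoys, 10%
  uniform-random background. Plasma small-RNA libraries are dominated by
  host material; exogenous content, when reported, is orders of magnitude
  rarer than 10% — the spike is set high so recovery statistics have tight
  denominators, not to mimic plasma stoichiometry.
- **IsomiR-like trimming**: spiked reads lose 0/1/2 nt from the 3′ end with
  probabilities 0.60/0.25/0.15, emulating the 3′-length heterogeneity of
  real mature-miRNA reads; 15% of spiked reads are "degraded" copies with
  per-base substitution probability 0.02 (these fail the 100%-identity
  mapping, as degraded copies should).
- **Decoys**: a fixed 400-nt GC-rich rRNA-like sequence — synthetic, built
  once from its own frozen seed, not taken from any real genome — is present
  verbatim in a human mRNA record *and* inside an annotated region of every
  plant genome, and decoy reads are exact substrings of it. Decoys therefore
  travel the entire pipeline and reach the classifier, which must reject
  every one of them by the human-identity rule: this is the engineered
  version of the rRNA ambiguity that motivates the protocol.
- **Paralogs**: one third of the plant miRNAs get a single-substitution
  (≥95% identical) human paralog placed in the human miRNA and human mRNA
  databases, exercising the strict-maximum rule with competition that loses
  by a small, known margin. The substitution sits near the 5′ end
  (position 6 for 21-nt miRNAs) so that 3′-trimmed read variants still share
  a seed-length word with the paralog — placing it mid-read would make the
  competing hit invisible to an 11-mer seed for trimmed reads and leave the
  post-filter score distribution degenerate.
- **Block structure**: each project spikes the miRNAs of its own plant
  species (the default block plan), giving project-pure experiment groups;
  `simulate_block_matrix()` additionally provides planted-block abundance
  matrices with tunable contamination noise for clustering-recovery checks
  with known labels.
- **Positive controls**: the first miRNA of each species has its exact
  reverse complement planted in a target transcript at a recorded offset,
  and a gene-set term containing the targeted genes is planted in the GMT
  file. The target transcript set is a *separate* input from the human mRNA
  classification database: a perfect reverse-complement site inside the
  classification database would, by construction, trigger the
  100%-identity discard for that miRNA's reads.

A single integer seed drives everything through per-stage substreams, so
equal seeds give byte-identical corpora.

**What passing on this corpus does and does not show.** The generator uses
uniform-random references (no repeats, no homopolymer structure, no real
genome homology), error-free reads with flat qualities, and exact decoys.
Recovery of 100% of exact spiked reads and rejection of 100% of decoys
demonstrates that the machinery implements its rules correctly, not that
those operating points are optimal for real plasma data, where host
similarity, sequencing error and incomplete annotation make both numbers
worse. Published study-level quantities (counts of validated sequences,
their RPM summaries, group structures) depend on real archives and database
states and are deliberately not reproduction targets of the test suite.

## Numerical choices and degenerate inputs

- KDE bandwidth: Scott's rule (`stats::bw.nrd`). Bit-score sets are heavily
  tied; when the interquartile range is zero but the spread is positive, the
  bandwidth falls back to the Gaussian-reference form 1.06·sd·n^(−1/5).
  Fewer than two finite scores, or zero spread, is an error — the overlap
  diagnostic reports NA in that case rather than fabricating a density.
- Overlap integrals use the trapezoidal rule on a shared 512-point grid
  padded 10% beyond the combined score range; with the default 3-bandwidth
  tail cut the self-overlap of a density is 1 within 1%.
- Traceback ties in the aligner prefer diagonal, then up, then left; the
  best cell is the first maximum in row-major order — alignments are fully
  deterministic.
- Database hit ties break by identity, then lexicographic accession;
  classification ties between plant and non-plant bit scores *discard*.
- Percentages in project-distribution tables round half-up (not banker's)
  to match fixed-precision table formatting; rows sum to 100 ± 0.02.
- `hclust` group labels are renumbered by first appearance along the leaf
  order, so EG1 is always the leftmost group in the dendrogram.
- Empty inputs are legal throughout: empty FASTQs give a zero report;
  an empty validated set gives an empty (but valid) expression matrix and
  skips clustering; single-row/column matrices cluster trivially with a
  warning.
- Stage timings are printed to the console but never written into output
  files, so reruns with identical configuration are byte-identical.

## Limitations

- The aligner is a full dynamic program over seeded windows: exact and fast
  at read-vs-database scale, but not a replacement for a production mapper
  on gigabase genomes.
- Host subtraction is substitution-only (no indels) by design; a read with
  a 1-nt indel relative to the host will reach the classifier, where the
  human-identity rule no longer catches it unless it also matches
  full-length elsewhere.
- RPM is the only normalization offered; no between-sample scaling factors
  (TMM/median-of-ratios) are computed, as presence and within-study
  comparison, not differential expression, are the goals.
- Enrichment treats terms as flat sets: no ontology propagation, no
  hierarchy-aware correction.
- The synthetic corpus does not model sequencing error profiles, adapter
  read-through, or real cross-species homology; see the corpus section for
  what that implies about test evidence.
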