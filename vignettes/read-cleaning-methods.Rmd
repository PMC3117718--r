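---
title: "Cleaning 454 pyrosequencing reads: models, thresholds and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning 454 pyrosequencing reads: models, thresholds and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyroclean)
```

## The problem

Long-read pyrosequencing (454) exhibits a replicate bias: one DNA
fragment can yield several reads within a run. Such *artificial
duplicates* start at the same template position on the same strand and
are near-identical, differing only through the platform's error modes —
homopolymer over/under-calls (±1 indels in runs of identical bases),
occasional substitutions, and different stop positions. Because they
masquerade as independent observations of a fragment, they corrupt
abundance estimates and mislead assemblers. `pyroclean` removes them,
validates paired-end reads, and applies standard per-read filters.

Everything in the package operates on a `ReadSet`: an ordered
collection of reads with id, sequence over `{A,C,G,T,N}` and optional
Phred qualities, loaded from FASTQ, FASTA (± `.qual` sidecar) or SFF v1.
Intervals are 0-based and half-open throughout; SFF's 1-based clip
points are converted on ingest, and when both quality and adapter clips
are present their intersection (max of left clips, min of positive
right clips) is used.

## Duplicate detection

### Model

Two reads are duplicate candidates if an alignment *anchored at the
first base of both reads* — a co-start alignment — supports it. The
score uses unit match reward so it is commensurate with "number of
matching bases": match +1, mismatch −2, gap −3 per gapped base. The
alignment extends to the end of the shorter read and leaves the longer
read's tail free, since duplicates stop at different positions. An edge
joins two reads when

* score > 100 (strict), and
* unless `aggressive = TRUE`, their length difference < 70 bases
  (strict).

Connected components of the edge graph are duplication clusters; the
longest member of each is kept (ties broken by smallest id for
determinism). A direct consequence of the unit-match scoring: reads
shorter than 101 bases can never be flagged as duplicates at the
default threshold.

### Search strategy

All-vs-all alignment is avoided by observing that a co-start alignment
with an error-free opening can only exist between reads sharing their
prefix. Candidate pairs are therefore reads with identical first
`seed_k = 16` bases (forward strand only, which enforces the same-strand
requirement structurally); candidates are then scored with a banded
dynamic program (band half-width 8 — duplicates carry few indels; a
path leaving the band is truncated at the last in-band cell).

Two limitations follow and are deliberate:

* an error within the first 16 bases hides a pair from seeding. The
  synthetic duplicate generator consequently perturbs copies only
  outside this protected prefix — co-start duplicates share their
  start by definition, and the tests quantify recovery under that
  model, not under arbitrary early errors;
* overlapping shotgun fragments whose starts differ by a few bases can
  reach score > 100 through a leading gap, yet are invisible to prefix
  seeding. They are not co-start duplicates in the sense above, and
  the equivalence tests against brute-force all-pairs DP use
  independent templates so that every true edge is an injected one.

The unbanded full-matrix co-start DP is kept in the package as an
oracle; tests check the banded path against it across random
perturbations, and against an independent global aligner
(`Biostrings::pairwiseAlignment`) on equal-length pairs.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `score_threshold` | 100 | strict lower bound on the co-start score |
| `length_diff_max` | 70 bases | strict upper bound on length difference |
| `aggressive` | `FALSE` | ignore the length gate |
| `seed_k` | 16 bases | shared-prefix length for candidacy |
| `band` | 8 | DP band half-width |

The score and length defaults are the method's published operating
point; the weights (+1/−2/−3) keep "score > 100" meaning roughly "more
than 100 matching bases". `seed_k` trades sensitivity against candidate
volume; 16 makes chance prefix collisions (4^−16 per pair) negligible
while remaining robust given the protected-prefix duplicate model.

## Paired-end cleaning

A 454 paired-end read is end-A + linker + end-B of a circularised
fragment. Linkers (chemistry-specific, user-supplied as FASTA; an
example file ships in `inst/extdata/`, to be verified against the
chemistry actually used) are located by Smith–Waterman local alignment
(+1/−2/−3) on both strands; hits covering less than half the linker are
ignored as noise, and multiple hits are reported non-overlapping,
greedily by score. The decision tree over the hit list:

| case | situation | action |
|---|---|---|
| a | no linker | keep whole as single |
| b | ≥ 2 linker hits | discard |
| c | one partial hit, within 5 bases of a read end | clip linker, keep longest remainder |
| d | one partial hit, internal | discard |
| e | one full hit, both flanks ≥ 50 bases | split into mates `<id>/1`, `<id>/2` |
| f | one full hit, neither flank ≥ 50 bases | discard |
| g | one full hit, one flank ≥ 50 bases | keep that flank as single |

A hit is *full* when it spans the whole linker with at most 2
mismatches + gapped bases. The numeric choices — flank minimum 50 bases
(a usable mate for contig bridging), end margin 5, partial-hit floor
0.5, mismatch cap 2 — are not dictated by the method; they are exposed
in `pairend_config()` and were fixed once as sensible values for
Titanium-era read lengths. When two flanks qualify in the single-read
cases the longer one is kept (tie: left), i.e. the longest linker-free
subsequence survives.

## Basic filters

Each filter is a pure per-read predicate (the standard-deviation length
filter is the one collective exception: its mean and population σ are
computed once from the pristine input, before any removal):

* **length window**: keep iff `length_min ≤ len ≤ length_max`
  (inclusive; defaults 50–1000);
* **length by σ**: keep iff within mean ± 2σ (population σ, divisor N);
* **complexity**: 100 × (zlib-compressed length − empty-stream
  baseline) / read length. The baseline subtraction removes the fixed
  codec overhead so short reads are not penalised; R's zlib default
  level is used, fixed and deterministic. Uniform-random DNA scores
  ≈ 35–40, homopolymers < 2, so the default threshold 25 separates
  low-information reads from random sequence with margin on both
  sides. Keep iff score > threshold, either on the whole read or — in
  windowed mode — in at least one 100-base window every 50 bases (a
  trailing window ≥ 50 bases is scored too);
* **quality**: keep iff at least one base is strictly above Phred 20.
  This is deliberately literal and permissive — one good base saves the
  read; a mean-quality criterion would be stricter and is intentionally
  not what this filter does;
* **N rate**: keep iff the fraction of `N` bases ≤ 0.02.

## Pipeline semantics

Stage order is fixed: paired-end splitting first (it rewrites the read
set), then length, Ns, complexity, quality, duplicates. A read is
attributed to the *first* stage that removes it, so the per-reason
counters sum to the input count. When a later filter removes one mate
of a validated pair, the surviving mate is demoted to the singles
output; the pairs and singles files are disjoint and together account
for every non-discarded read. With identical input and flags, outputs
and log are byte-identical (the log timestamp is off by default).

## The simulator and the duplication null

`random_genome()` + `simulate_shotgun_reads()` implement the
random-fragmentation null: reads of length L drawn with uniform start
and strand from a genome of length G. With M = 2(G−L+1) equally likely
(start, strand) cells, the count in a cell is ≈ Poisson(λ),
λ = (n−1)/M, and the expected replication rate — the fraction of reads
in clusters of size ≥ 2 — is 1 − e^(−λ). At the full study scale
(n = 671,856 reads of 500 bp, G = 4.6 Mb) λ ≈ 0.073 and the expected
rate is ≈ 7%.

Design choices here:

* the genome is uniform random at E. coli K12 scale (4.6 Mb). The null
  depends only on length; a real genome's repeat families (rRNA
  operons) would add co-start pairs that are *not* duplication
  artifacts, muddying the null;
* "replication rate" admits two readings and both are computed: the
  **membership rate** (reads in clusters of size ≥ 2)/N — the headline,
  matching the closed form above — and the **removal rate**
  (N − #clusters)/N;
* error-free reads sharing (start, strand) are exact copies, so
  full-scale clustering uses exact grouping on the (start, strand) key.
  This fast path is *verified at every run* against the alignment-based
  path on a 10,000-read subsample (`verified` in the result);
* `inject_duplicates()` emulates the artifact itself for testing:
  copies with homopolymer ±1 indels outside the 16-base protected
  prefix, substitutions, and 3′ truncations.

What the simulator does **not** emulate: flow-space signal, position-
dependent quality decay, real genome repeat structure, chimeras, and
early-read errors. Tests passing on simulated data therefore establish
the correctness of the clustering machinery and its calibration under
the stated duplicate model — not the field error profile of any
particular instrument run.

## Numerical and degenerate-input choices

* Strict inequalities at both published gates (score > 100, length
  difference < 70) — boundary tests pin these.
* Tie-breaks: cluster representative by (max length, then smallest id);
  linker hits by (max score, then leftmost).
* Reads shorter than `seed_k` never enter duplicate seeding (logged).
* Empty read sets flow through every stage and produce empty outputs
  and zero counters; a single-read set makes the σ-length filter a
  warning no-op.
* Characters outside `{A,C,G,T,N}` are mapped to `N` on ingest with a
  warning; `N` never counts as a match in any aligner.
* FASTQ is Sanger Phred+33 only; a malformed record is a hard error
  naming the record.

## Problem sizes in the test suite

The suite exercises the full-scale replication experiment (671,856
reads, via the hash fast path) once; alignment-heavy checks run at
reduced but honest sizes chosen for tightness per unit time: the
brute-force clustering oracle on 200 reads of 150 bp (19,900 full DP
alignments), duplicate recovery over 100 seeded replicates of 23 reads
of 500 bp, and property checks (monotonicity, idempotence, determinism,
round trips) on sets of tens of reads.

## Known limitations

* Duplicates with an error in their first 16 bases escape detection;
  lowering `seed_k` raises sensitivity at a candidate-volume cost.
* Reads ≤ 100 bases cannot be flagged duplicates at the default score
  threshold.
* Reverse-complement duplicates are out of scope by design (the
  artifact is same-strand).
* SFF files are read, never written; cleaned output is FASTQ or FASTA.
* The quality filter is a whole-read keep/discard decision; no
  trimming is performed.
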