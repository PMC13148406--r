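---
title: "Methods behind markerphylo: profile search, marker filtering, and species-tree inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind markerphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, algorithms, numerical conventions and
design choices inside `markerphylo`, in the order the pipeline applies
them. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. Profile HMM search

### Architecture

Each marker is a profile hidden Markov model with match (`M_k`), insert
(`I_k`) and delete (`D_k`) states for positions `k = 1..M`, read and
written in the HMMER3 text format (negative natural-log probabilities,
`*` for probability zero; `GA` gathering cutoffs and `COMPO` background
frequencies are honoured, `STATS` calibration lines are parsed and
ignored). Scoring uses a *glocal* architecture: the model must be
traversed in full (through `M`/`D` states), while sequence residues
outside the aligned core are absorbed by free flanking states that emit at
the null frequency — so flanks cost nothing in log-odds and the score does
not depend on how much unrelated sequence surrounds the domain. This is
the natural contract for single-copy, single-domain markers; multihit
local alignment (as in full HMMER) is deliberately out of scope. The
node-0 insert state `I_0` of the HMMER3 format is supported and emits at
the null frequency, so files produced by `hmmbuild` parse and score
without special-casing.

All arithmetic is in natural-log space with `-Inf` as the zero-probability
sentinel; scores are converted to bits (`/ ln 2`) at the interface. The
Viterbi and forward recursions are implemented in C++ (Rcpp) because the
search stage evaluates every (sequence, marker) pair; both are verified
against a brute-force enumeration over *all* state paths for every model
with `M <= 3` and sequences of length `<= 4` (tolerance 1e-9 in log
space), and the inequality `forward >= viterbi` is property-tested on
random models.

### Reporting threshold and prefilter

A hit is reported when its **forward** bit score passes the marker's
gathering cutoff, or a flat floor of 10 bits when the profile carries no
`GA` line; the floor is a user-visible option (`threshold`). E-value
calibration is intentionally omitted — thresholds operate on bit scores.
Because `forward >= viterbi` always, the search first computes the cheap
Viterbi bound and only evaluates the exact forward score when that bound
comes within 30 bits of the threshold; sequences short-circuited this way
are at least 30 bits below the floor on their *best* path, so in practice
no passing sequence is lost (the margin would have to be exceeded by the
log-number of near-optimal paths for a miss to occur). This mirrors the
filter-pipeline idea HMMER itself uses.

### Worker allocation

`plan_search_workers()` implements the pipeline's CPU rule: below eight
CPUs a single search instance uses all cores; at eight or more, the pool
splits into `floor(nCPUs/4)` instances of four cores each, because one
large instance scales poorly past a few cores. The planner is pure
bookkeeping (this package executes searches serially inside one R
process); it is exported so schedulers can honour the same contract.

## 2. Single-copy orthology and checkpointing

Any sample with two or more passing hits to one marker is excluded *for
that marker only* — with single-copy markers, multiple hits indicate
duplication or contamination and the true ortholog cannot be identified.
The rule is idempotent and only removes (marker, sample) cells. A sequence
hitting two different markers may serve both: markers are treated as
independent families. Markers kept for tree building must be present in at
least `min_taxa` samples (default 4); the run itself requires at least
four samples.

Search results are keyed by the SHA-256 digest of each sample file's raw
bytes, never by path or name: byte-identical files are one sample wherever
they live, which makes checkpoints portable and shareable. Compressed
inputs are hashed as stored. The checkpoint file is a one-line JSON header
(format version + a fingerprint of marker-set digest, threshold and
sequence type) followed by one JSON line per sample; doubles are written
at full precision so a load/save cycle is byte-identical. A fingerprint
mismatch refuses the checkpoint unless `force` is set. Checkpoint reuse
covers only the search step — downstream outputs are cheap to recompute
and depend on the whole sample set. The test suite proves incremental
equivalence: processing eight fixture samples as one batch, as 5 + 3, or
as 8 − 2 + 2 yields identical hit tables and alignments.

## 3. Alignment and trimming

Hit sequences are threaded through their Viterbi paths: output column `k`
holds the residue emitted at match state `k`, or `-` when the path used
`D_k`; insert-state residues are discarded. Every marker alignment
therefore has width exactly `M`, in profile match-state coordinates,
regardless of input lengths (the profile-alignment behaviour of
`hmmalign`'s match columns).

Trimming keeps exactly the parsimony-informative columns: at least two
distinct non-gap, non-ambiguous states, each in at least two rows.
Ambiguity codes (`X`, `B`, `Z`, ... for protein; IUPAC codes for
nucleotide) count as missing — a conservative reading of the parsimony
definition. Internally columns are 0-based; everything user-facing
(reports, `kept` indices) is 1-based inclusive. Trimming is idempotent and
is tested against an independent column-classifier oracle on random
alignments.

For coding-sequence input, samples are translated (standard code),
searched and aligned as peptides, and the codons are then threaded back:
each peptide column becomes a codon triple, peptide gaps become `---`, and
the peptide-space trim mask carries over by column triple. A trailing stop
codon is tolerated and dropped; internal stops are an error by default.
Translating a back-threaded row reproduces the gapped peptide row exactly,
which is a tested invariant.

## 4. Marker informativeness (treeness / RCV)

For each trimmed marker alignment the package computes:

* **treeness** — internal branch length over total branch length of the
  marker's gene tree, in [0, 1]; a zero-length tree is defined as 0, with
  a warning.
* **RCV** — `sum_j sum_i |c_ij - mean_j| / (n t)` over residue states `j`
  and taxa `i` (`n` taxa, `t` sites), gaps and ambiguity excluded from the
  counts. Zero iff all taxa have identical residue counts.
* **score** — `treeness / max(rcv, 1e-9)`. The epsilon makes perfectly
  homogeneous composition rank *above* every positive-RCV marker of equal
  treeness instead of producing a division by zero: compositional
  homogeneity is maximally desirable.

Ranking is by descending score with lexicographic marker-id tie-breaks. By
default **all** markers are kept — aggressive top-*n* filtering can
discard genuine signal, so filtering is opt-in. Scores are computed from
the *trimmed* alignments, matching the stage order of the pipeline
(trimmed output feeds the filter).

### The internal gene-tree builder

Gene trees (and the internal concatenation tree) are built by neighbor
joining on corrected distances — `p`, Poisson `-ln(1-p)` for peptides, or
JC69 for nucleotides, computed over columns where both rows are unambiguous;
saturated pairs are capped at 10 with a warning — followed by
nearest-neighbor-interchange **maximum-parsimony refinement** and NNLS
branch-length re-fitting (negative estimates clamped to zero). The
parsimony step exists for a measured reason: the pipeline hands the tree
stage *parsimony-informative columns only*, and distances computed on such
censored columns are systematically non-additive, which can mislead pure
NJ even when the alignments are perfect (in development, fixtures whose
untrimmed data gave the true topology in every run lost up to two internal
branches after trimming under pure NJ). The parsimony criterion is
invariant to removing parsimony-uninformative sites, so the refinement
restores exactly the information the trim preserves. `nj_tree()` itself is
exported unchanged and recovers additive matrices exactly (a tested
invariant for up to eight taxa).

An adapter remains: externally computed gene trees (e.g. from FastTree)
can be passed to the scorer and to the consensus step directly.

## 5. Species-tree inference

**Consensus (coalescent-style) mode.** The species tree is the maximizer
of the quartet score — the number of induced four-taxon topologies shared
with the gene trees, counting only quartets resolved in both trees
(multifurcating gene trees are accepted; their unresolved quartets simply
contribute nothing). For eight or fewer taxa the search is exhaustive over
all unrooted topologies (10,395 at n = 8), with the candidate quartet
profiles cached per session; beyond eight, a greedy start (NJ on mean
topological distances across gene trees) is hill-climbed through NNI moves
to a local optimum — an honest desk-scale stand-in for large-sample
quartet methods, and an adapter accepts an externally computed species
tree for comparison. Optimality is tested against exhaustive search on
random six-taxon instances.

**Concatenation mode.** Marker alignments are concatenated in sorted
marker-id order over the union of taxa, missing taxa gap-filled per
partition; partitions are 1-based inclusive and tile the matrix exactly
(tested). The supermatrix FASTA and a RAxML-style partition file
(`PROT, marker = start-end`) are always exported so external partitioned
ML tools can be used; the internal tree uses the builder of §4. Branch
support is standard nonparametric bootstrap (default B = 100): resample
columns with replacement, rebuild, report the percentage of replicates
containing each split. (Ultrafast bootstrap is an optimization internal to
specific ML engines; the contract — % of replicates containing a split —
is preserved.) Site concordance factors sample, per internal branch,
quartets with one tip from each of the four surrounding subtrees (default
100) and average, over decisive sites (exactly two states, two rows each),
the percentage supporting the branch's own pairing; branches with no
decisive site in any sampled quartet are reported missing (`NA`). Both are
deterministic given the run seed.

**Benchmark utilities.** Robinson–Foulds distance is the symmetric
difference of non-trivial bipartition sets, normalized by `2(n-3)`
(cross-checked against an independent implementation in tests, and
spot-checked as a metric). Monophyly of a tip group holds iff the group is
one side of some bipartition of the unrooted tree; singletons are
monophyletic by convention.

Everything downstream of inference treats trees as unrooted; rooting is
for display only.

## 6. The synthetic-data generator

Fixtures emulate the pipeline's real inputs: a known species tree,
per-marker homologous families evolved along it, decoy sequences, optional
injected paralogs, and HMMER3 marker files built from the true alignments.

* **Species tree** — Yule growth (a uniformly chosen extant lineage splits
  until `n_taxa` tips); branch lengths `0.01 + Exp(mean 0.09)` (mean 0.1).
  The 0.01 floor keeps every internal branch minimally identifiable at
  fixture scale — without it a fixture can pose an arbitrarily hard
  problem that says nothing about code correctness.
* **Sequence evolution** — the 20-state equal-rate analogue of
  Jukes–Cantor: along a branch of length `b` each site substitutes with
  probability `p(b) = (19/20)(1 − e^{−20 r b / 19})` to a uniformly chosen
  different residue. The closed form makes the simulator itself testable
  (a Monte-Carlo mismatch fraction over 10,000 sites is checked against it
  within three standard errors). The default rate 0.5 places the default
  eight-taxon fixture (mean root-to-tip depth ≈ 0.57) at ≈ 0.28 expected
  substitutions per site root-to-tip — the low-divergence regime
  single-copy marker pipelines target.
* **Proteomes** — each sample file holds its ungapped marker genes under
  opaque shuffled ids plus `n_decoys` background sequences drawn from the
  *same* uniform residue frequencies as the markers, so search specificity
  is genuinely exercised; injected paralogs are near-identical duplicates
  (1% point mutations). CDS fixtures back-translate with uniformly random
  synonymous codons.
* **Marker files** — one profile per family from the seed-alignment
  builder: match columns are columns with ≤ 50% gaps; emissions are
  pseudocount estimates `(count + α)/(n + 20α)` (α default 1); transitions
  are fixed, documented defaults (M→M 0.9, M→I 0.05, M→D 0.05; I→M 0.8,
  I→I 0.2; D→M 0.8, D→D 0.2; final-node M→D mass reassigned to the end
  state). A JSON manifest records file digests.

Every artifact is a pure function of the `simulation_spec` seed.

What the generator does *not* emulate: indels (alignments are gap-free and
columnar-homologous by construction), rate heterogeneity across sites,
compositional bias, incomplete lineage sorting, horizontal transfer, or
annotation noise. Passing the end-to-end suite therefore demonstrates that
the machinery is correct and internally consistent under a clean
generating process — not that the pipeline is robust to the pathologies of
real genomes.

## 7. Problem sizes and numerical conventions

The shipped test suite runs the full pipeline at 8 taxa x 50 markers x 200
sites x 10 decoys per sample over 20 seeds in both inference modes (these
sizes keep a complete run comfortably within a coffee break on one CPU
while still exercising every stage at realistic marker counts); oracle
tests enumerate all paths for tiny models; consensus optimality is checked
exhaustively at six taxa. `scripts/acceptance.R` repeats the recovery
study over ten seeds per invocation.

Conventions collected in one place: log-space scoring with `-Inf` as the
zero sentinel; bit scores = natural-log odds / `ln 2`; probability zero
written `*` in HMMER3 files; emissions renormalized on read (files carry
rounded encodings); distances capped at 10 on saturation; negative NJ/NNLS
branch lengths clamped to 0; ranking ties broken lexicographically;
quartet ties (no unique minimum pairing) treated as unresolved; internal
0-based column indices, 1-based user-facing coordinates; all stochastic
steps (bootstrap, sCF sampling, simulation) flow from a single integer
seed.

## 8. Known limitations

* The consensus search beyond eight taxa is a local NNI optimum, not a
  provably optimal tree.
* Bit-score thresholds only; no E-values, bias composition filters, or
  translated-search mode.
* The internal tree builder is distance + parsimony; for publication-grade
  trees export the supermatrix and partition file to a dedicated ML
  program.
* Site concordance uses the supermatrix only (no gene-concordance
  factors).
* Checkpoints do not migrate across format versions.
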