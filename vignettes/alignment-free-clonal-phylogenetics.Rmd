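---
title: "Alignment-free clonal phylogenetics from k-mer frequency profiles"
author: "KmerPhylo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free clonal phylogenetics from k-mer frequency profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(KmerPhylo)
```

## The problem and the model

Longitudinal and multi-region sequencing of tumors produces sets of FASTQ
files -- multiple regions of a tumor, recurrences, metastases, a matched
normal -- whose evolutionary relationships are usually reconstructed by
aligning reads to a reference, calling somatic variants, and building a
tree from the calls. Every step of that chain discards signal: reads that
do not align uniquely, larger insertions and deletions, rearranged
regions. Alignment-free comparison sidesteps the chain entirely by
summarizing each sample as its *feature frequency profile*: the vector of
relative frequencies of all length-$k$ subwords (k-mers) of its reads.

For two samples with frequency profiles $P = (p_1, \dots, p_m)$ and
$Q = (q_1, \dots, q_m)$ over the shared (union) k-mer axis, the package
computes two divergences:

* **Jensen–Shannon divergence**, built from Kullback–Leibler divergences
  to the mixture $M = \tfrac12 (P + Q)$:
  $$\mathrm{JS}(P, Q) = \tfrac12 \mathrm{KL}(P, M) + \tfrac12 \mathrm{KL}(Q, M),
    \qquad \mathrm{KL}(P, M) = \sum_i p_i \log_2 \frac{p_i}{m_i}.$$
  With base-2 logarithms $\mathrm{JS} \in [0, 1]$, reaching 1 exactly on
  disjoint supports, and $\sqrt{\mathrm{JS}}$ is a metric.

* **Hellinger distance**
  $$H(P, Q) = \sqrt{\tfrac12 \sum_i \left(\sqrt{p_i} - \sqrt{q_i}\right)^2}
    \in [0, 1],$$
  a metric that is 1 iff the supports are disjoint.

The pairwise divergence matrix over all samples of a patient (or cohort)
is then summarized two ways: an unrooted **neighbor-joining** tree, and a
classical (Torgerson) **MDS** embedding for a model-free picture of the
same distances. Agreement between trees -- across divergences, across
k-mer lengths, or against an external tree -- is quantified by the
Robinson–Foulds **symmetric distance** (topology only) and the
Kuhner–Felsenstein **branch-score distance** (topology and branch
lengths).

## Pipeline steps and the choices behind them

`runPipeline()` executes: count k-mers per sample, normalize counts to
frequencies, merge profiles on the sorted k-mer union, compute pairwise
divergences, and infer the tree (plus the MDS embedding).

**Canonical counting (default on).** Shotgun reads sample both strands,
so each window is folded with its reverse complement (the
lexicographically smaller of the two represents the pair). This is the
only orientation-invariant choice; stranded counting remains available
(`canonical = FALSE`) for data with a defined strand.

**Normalization.** Counts are divided by the per-sample total, making
each profile a probability vector -- the form the divergences require.
No abundance filtering is applied by default; a `minCount` threshold is
exposed for error-rich data, since k-mers seen once are dominated by
sequencing errors at typical error rates.

**Word length.** `k` is capped at 31 so a word packs into a 64-bit
integer (2-bit encoding); the counter is written in C++ and runs a
rolling hash over each read, skipping windows that contain non-ACGT
characters entirely. The default `k = 21` sits in the band (roughly
17–25) where words are long enough to be effectively unique in
genome-scale data but short enough that a single substitution does not
dominate; `sweepK()` exists precisely to check the stability of the
resulting topology over that band, and the pipeline warns below
`k = 13`.

**Determinism.** The merged k-mer axis is sorted in byte order, ties in
the neighbor-joining criterion are broken by the smallest index pair
(replacing the input-order randomization of classical implementations),
newick children are ordered by their smallest descendant label, MDS axis
signs are fixed by making each column's largest-magnitude entry
positive, and all numeric artifacts are written at fixed precision. Two
runs on identical inputs are therefore byte-identical -- a property the
test suite asserts.

**Negative branch lengths.** Neighbor joining can estimate negative
lengths on non-additive input. They are kept by default (matching the
classical programs); `clampNegative = TRUE` sets them to zero and
transfers the deficit to the adjacent branch created at the same join.

**Hellinger form.** Some renderings of the Hellinger definition drop the
inner square roots. The standard square-root form above is the default
(it is the Hellinger distance of the statistics literature, bounded by 1
and a metric); `form = "literal"` exposes the no-radical scaled
Euclidean reading for comparison.

**Branch-score convention.** The branch score is computed over the union
of all splits, pendant edges included (they carry length signal), with
length 0 for a split absent from a tree. `takeSqrt = TRUE` (default)
returns the square root of the sum of squared differences -- the metric
form; the raw sum is available because published implementations have
been read both ways. The symmetric distance uses non-trivial splits
only, the standard Robinson–Foulds convention.

## The built-in clonal simulator

`simulateLineage()` and `simulateCohort()` generate validation data with
a known answer. The lineage plan is fixed and mirrors a minimal model of
tumor clonal evolution: a normal genome **N** acquires a mutational step
to become the cancer founder **C**; C is mutated three separate times
into subclone founders **C1a, C2a, C3a** (intratumoral heterogeneity);
each founder is mutated twice more in succession (**b**, **c**),
representing ongoing subclone evolution. The sequenced cohort is N plus
the nine subclone samples; C itself is the internal branching point and
is retained for ledger replay.

Per step, the simulator applies (defaults in parentheses): SNVs at
distinct positions forced to a different base (50), short indels with
geometric lengths of mean 3 (5), and optionally structural variants --
deletion, tandem duplication, reverse-complement inversion -- of 50–500
bases (0; set `nSv > 0` for the whole-genome-style scenario). Every
event is recorded in a ledger whose root-to-leaf replay reproduces each
genome byte-for-byte, and truth-tree branch lengths equal the event
counts per step. Reads are drawn uniformly (100 bp, 30x coverage, 0.1%
substitution error, constant placeholder qualities) from either strand.

The defaults were chosen once so that per-step profile shifts are well
above coverage noise at desk scale: a 100 kb reference keeps the full
ten-sample pipeline in seconds-to-minutes territory while leaving each
55-event step clearly detectable (a step touches roughly
$55 \times 21 \approx 1{,}100$ of $\sim 10^5$ k-mers, about 1% of
profile mass). What the simulator does **not** model: quality-dependent
or indel sequencing errors, capture bias, contamination, tumor purity
mixtures. Passing the end-to-end tests therefore demonstrates the
pipeline's correctness and sensitivity under clean clonal structure, not
robustness to every artifact of real tumor data.

## What end-to-end recovery can and cannot show

One structural point deserves emphasis. The generating lineage contains
a true polytomy: the founder C connects the normal sample and the three
subclone chains, a degree-4 internal vertex, so the truth tree has
exactly 6 non-trivial splits over the 10 samples. Neighbor joining, like
any agglomerative method, always returns a fully resolved (binary)
tree -- 7 non-trivial splits on 10 leaves. An inferred tree therefore
*always* contains exactly one split absent from the truth, however good
the data: the arbitrary resolution of the polytomy, empirically carried
by a near-zero branch. The meaningful recovery statements, which the
test suite asserts, are that all 6 true splits are recovered and that
root-to-tip distances from N order a < b < c within every subclone
branch. A raw symmetric distance of 0 between a binary inferred
tree and the multifurcating truth is unattainable by counting (6 vs 7
splits), so the suite's strict SD = 0 recovery check documents this
floor of SD = 1. For the same reason, the JSD- and Hellinger-derived
trees agree on all six real splits but may disagree on which near-zero
edge resolves the polytomy, so their mutual symmetric distance
fluctuates between 0 and 2 across seeds. The same caveat applies to
k-mer length sweeps on simulated cohorts: the six real splits are stable
across the 17–25 band, while the polytomy-resolving edge -- always the
shortest internal edge by an order of magnitude -- can flip between k
values.

## Worked example

```{r example, eval = FALSE}
library(KmerPhylo)

# simulate a ten-sample clonal cohort with a known truth tree
cohort <- simulateCohort(LineageSpec(seed = 1), ReadSimSpec(seed = 1),
                         dir = tempfile("cohort"))

# run the full pipeline at the default operating point
run <- runPipeline(cohort$fastq, outDir = tempfile("run"),
                   k = 21, metric = "jsd")
writeNewick(run$tree)

# compare against the generating lineage
symmetricDistance(run$tree, truthTree(cohort$truth))

# topology stability across the informative k band
sw <- sweepK(cohort$fastq, c(17, 19, 21, 23, 25),
             outDir = tempfile("sweep"))
sw$pairs
```

The chunk is not evaluated at build time (it simulates and counts ~30
Mb of reads); the same computation runs in the package's test suite and
in `scripts/acceptance.R`, which print the quantities discussed above.

## Numerical notes and limitations

* Frequencies are doubles; profile rows sum to 1 within 1e-12 and the
  merged matrix is validated to 1e-9.
* `0 log 0 = 0` is applied by summing only over positive entries; the
  JSD mixture is positive wherever either profile is, so no division by
  zero can occur. Divergences are clamped to [0, 1] against
  representation error at the bounds.
* MDS eigenvalues can be negative because the divergences are not
  Euclidean; negative eigenvalues are clamped to zero in coordinates but
  reported unmodified for diagnostics.
* In-memory counting targets desk-scale data (up to a few hundred Mb of
  reads per sample); there is no disk-spill or probabilistic counting.
* Quality trimming and adapter removal are preconditions, not package
  features: profiles are built from the sequences as given.
* The k-mer profile discards positional information; two samples with
  identical k-mer content are indistinguishable regardless of
  arrangement, and distances saturate once profiles become disjoint.
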