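# KmerPhylo

Alignment-free phylogenetics for longitudinal and multi-region sequencing
cohorts, built on k-mer frequency profiles.

## The problem

Reconstructing the evolutionary relationships among tumor samples from a
single patient -- multiple regions, recurrences, metastases, a matched
normal -- usually goes through alignment and somatic variant calling,
which discards reads that do not align uniquely and is blind to larger
insertions, deletions, and rearrangements. KmerPhylo instead summarizes
each sample's raw FASTQ reads as a *feature frequency profile* (the
relative frequencies of all length-k nucleotide words), compares profiles
with information-theoretic divergences, and builds trees directly from
those distances. No reference genome, aligner, or variant caller is
involved.

## The method

For samples with frequency profiles *P*, *Q* over the shared k-mer axis:

* **Jensen–Shannon divergence** (log base 2, in [0, 1]):
  JS(P, Q) = ½ KL(P, M) + ½ KL(Q, M), with M = ½(P + Q) and
  KL(P, M) = Σᵢ pᵢ log₂(pᵢ/mᵢ).
* **Hellinger distance** (in [0, 1]):
  H(P, Q) = √(½ Σᵢ (√pᵢ − √qᵢ)²).

The pairwise divergence matrix feeds an unrooted **neighbor-joining**
tree (Saitou–Nei with the Studier–Keppler criterion, deterministic
tie-breaking) and a classical **MDS** embedding. Trees are compared by
the Robinson–Foulds **symmetric distance** (SD, topology only) and the
Kuhner–Felsenstein **branch-score distance** (BSD, topology and branch
lengths). A built-in clonal-evolution simulator generates validation
cohorts with a known truth tree and a replayable mutation ledger.

## Worked example

Simulate a ten-sample clonal cohort -- normal N, cancer founder C, three
subclones each sampled at three successive timepoints (a, b, c) -- and
run the pipeline at the default operating point (k = 21, JSD, canonical
k-mers):

```r
library(KmerPhylo)

cohort <- simulateCohort(LineageSpec(seed = 1), ReadSimSpec(seed = 1),
                         dir = "cohort")
run <- runPipeline(cohort$fastq, outDir = "run", k = 21, metric = "jsd")

round(as.matrix(run$distance)[c("N", "C1a", "C1b", "C1c"),
                              c("N", "C1a", "C1b", "C1c")], 4)
#>          N    C1a    C1b    C1c
#> N   0.0000 0.0581 0.0667 0.0790
#> C1a 0.0581 0.0000 0.0468 0.0584
#> C1b 0.0667 0.0468 0.0000 0.0464
#> C1c 0.0790 0.0584 0.0464 0.0000

writeNewick(run$tree)
#> [1] "(((C1a:0.0187294691134,(C1b:0.0173759652264,C1c:0.0289831142537):0.0106855758828):0.0107169175511,N:0.0284561653738):0.000263264112383,(C2a:0.0179151892103,(C2b:0.0177064299107,C2c:0.0289926264238):0.010946274057):0.0108017898152,(C3a:0.0182266660012,(C3b:0.0185670464903,C3c:0.0289011231882):0.010973864819):0.0110340191247);"

symmetricDistance(run$tree, truthTree(cohort$truth))
#> [1] 1
```

The distances grow monotonically with mutational load (N → C1a → C1b →
C1c), and the tree shows the three subclone branches with the *c*
samples most distal. The symmetric distance of 1 to the generating
lineage is the structural floor, not an error: the true lineage has a
polytomy at the cancer founder (six non-trivial splits), while a
neighbor-joining tree is always fully resolved (seven), so exactly one
near-zero edge -- here 0.0003, two orders of magnitude below the real
edges -- is an arbitrary resolution. All six true splits are recovered.

Topology stability across the informative k band, and the CLI:

```r
sweepK(cohort$fastq, c(17, 19, 21, 23, 25), outDir = "sweep")$pairs
```

```sh
Rscript inst/scripts/kmerphylo.R treedist --tree1 a.nwk --tree2 b.nwk
```

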