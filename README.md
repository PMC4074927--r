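# entroclust

Alignment-free clustering of DNA genomes from the variability of their
local Shannon entropy.

Two genomes can be compared without any alignment by asking how their
*local* nucleotide composition varies along the sequence. `entroclust`
implements that idea for whole genomes — originally motivated by large
double-stranded DNA algal viruses (*Phycodnaviridae*) and their plant
hosts, where the distribution of local entropy separates viruses by host
and viruses from hosts — but the machinery applies to any set of DNA
sequences.

## The method

1. **Block entropies.** A cleaned genome (A/C/G/T only) is subdivided
   into `N` consecutive, non-overlapping blocks of `B` nucleotides. Each
   block `X_i` gets the plug-in Shannon entropy of its base frequencies,

   `H(X_i) = − Σ_{x ∈ {A,C,G,T}} p(x) log₂ p(x)` ∈ [0, 2] bits.

   Under Chargaff's second parity rule (A ≈ T, C ≈ G within a strand)
   this collapses to `H ≈ 1 + h(gc)` with `h` the binary entropy of the
   block's GC fraction, so the per-block GC fraction is reported as a
   diagnostic alongside.

2. **Entropy distribution and superinformation.** The `N` block
   entropies are collected into `M` equally spaced bins on the fixed
   range [0, 2] bits and normalized to a probability vector
   `p_j = H_j / N`. Its own entropy,

   `H_s = − Σ_j p_j log₂ p_j` ∈ [0, log₂ M],

   is the *superinformation* — the "entropy of entropy" — measuring how
   variable local composition is along the genome. Genomes of higher
   organisms tend to larger `H_s` than compositionally homogeneous viral
   genomes.

3. **Jensen–Shannon metric.** Two genomes' entropy distributions `p`,
   `q` (on one shared binning) are compared by

   `D_JS(p, q) = ½ D_KL(p‖m) + ½ D_KL(q‖m)`, `m = (p + q)/2`,

   bounded by 1 bit, and its square root `d = √D_JS` — a true metric —
   fills the pairwise distance matrix.

4. **Clustering.** The distance matrix is clustered by UPGMA (default;
   complete, single and neighbor-joining are selectable) and exported as
   a Newick tree with branch lengths.

A synthetic-genome generator with controlled along-sequence GC
composition (fixed, beta-distributed, or two-point mosaic GC per
segment) makes the whole pipeline testable without downloading genomes.

## Worked example

Simulate two planted "host groups" of genomes with different GC-mosaic
regimes and recover them from entropy distributions alone:

```r
library(entroclust)

regA <- composition_regime("two_point", gc1 = 0.35, gc2 = 0.65)  # broad GC mosaic
regB <- composition_regime("two_point", gc1 = 0.45, gc2 = 0.55)  # narrow GC mosaic
cohort <- generate_cohort(list(
  list(name = "hostA", regime = regA, n = 2, length = 500000),
  list(name = "hostB", regime = regB, n = 2, length = 500000)), seed = 7)

scheme <- make_binning(M = 64, lower = 0, upper = 2)
dists <- lapply(cohort$genomes, function(g)
  histogram_entropies(entropy_profile(g, B = 100), scheme))

sapply(dists, superinformation)
#> [1] 2.556724 2.543431 1.298218 1.305971

dm <- distance_matrix(dists)
print(dm)
#> <js_distmat> 4 genomes (B = 100, M = 64, sqrt_js)
#>          hostA_01 hostA_02 hostB_01 hostB_02
#> hostA_01   0.0000   0.0305   0.6210   0.6189
#> hostA_02   0.0305   0.0000   0.6143   0.6122
#> hostB_01   0.6210   0.6143   0.0000   0.0143
#> hostB_02   0.6189   0.6122   0.0143   0.0000

tree <- hierarchical_cluster(dm, method = "average")
cat(to_newick(tree))
#> ((hostB_01:0.007137786459,hostB_02:0.007137786459):0.3011575024,
#>  (hostA_01:0.01526519298,hostA_02:0.01526519298):0.2930300959);

bipartition_check(tree, list(c("hostA_01", "hostA_02"),
                             c("hostB_01", "hostB_02")))
#> [1] TRUE
```

The broad-mosaic group carries about twice the superinformation of the
narrow one (~2.55 vs ~1.30 bits at B = 100, M = 64), within-group
distances (~0.01–0.03) sit far below between-group distances (~0.61),
and UPGMA recovers both planted groups as clades.

The same workflow is available file-in/file-out through `cmd_profile()`,
`cmd_superinfo()`, `cmd_sweep()`, `cmd_distmat()`, `cmd_cluster()` and
`cmd_simulate()`, or from a shell via the wrapper installed at
`system.file("cli", "entroclust.R", package = "entroclust")` with
subcommands `simulate | profile | superinfo | sweep | distmat | cluster`.

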