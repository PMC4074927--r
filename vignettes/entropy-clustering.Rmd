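---
title: "Clustering genomes by local entropy variability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering genomes by local entropy variability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entroclust)
```

## The model

`entroclust` compares genomes by the *distribution* of their local
Shannon entropy rather than by sequence similarity. The chain of
statistics is:

* Each cleaned genome is subdivided into $N = \lfloor L/B \rfloor$
  consecutive, non-overlapping blocks of $B$ nucleotides. Block $X_i$
  receives the plug-in entropy
  $H(X_i) = -\sum_{x \in \{A,C,G,T\}} p(x)\log_2 p(x)$ of its base
  frequencies, a value in $[0, 2]$ bits.
* The $N$ block entropies are histogrammed into $M$ equally spaced bins
  over $[0, 2]$ bits and normalized, $p_j = H_j / N$. The entropy of
  this distribution, $H_s = -\sum_j p_j \log_2 p_j$, is the
  **superinformation**: it is large when local composition varies
  widely along the genome and zero when every block looks alike.
* Pairs of genomes are compared by the Jensen-Shannon divergence
  between their entropy distributions,
  $D_{JS}(p,q) = \tfrac12 D_{KL}(p\|m) + \tfrac12 D_{KL}(q\|m)$ with
  $m = (p+q)/2$, and clustered on the metric $d = \sqrt{D_{JS}}$.

The implicit assumptions: composition is the signal (the method is
blind to base *order* within a block); single-nucleotide frequencies
suffice (no k-mer structure); and genomes are long enough that
$N \gg M$, so the histogram is a stable estimate of the underlying
block-entropy distribution.

Under Chargaff's second parity rule (within-strand $A \approx T$,
$C \approx G$) a block's four frequencies collapse to one degree of
freedom, its GC fraction $g$, and the block entropy becomes exactly
$H = 1 + h(g)$ with $h$ the binary entropy. This closed form is both a
useful intuition (the entropy profile is essentially a transformed
windowed-GC profile) and a sharp test: it is asserted to $10^{-12}$ on
randomly generated parity blocks in the test suite.

## Parameters that matter

* **Block size `B`** (nucleotides; default 100). `B` sets the
  resolution of "local". Small `B` gives noisy per-block estimates
  (the plug-in entropy of a length-$B$ block is biased low by
  $\approx 3/(2B\ln 2)$ bits near balanced composition, and its
  sampling spread grows as $B$ shrinks); large `B` averages away local
  structure. `B = 100` sits in the stable regime for genomes from a
  few hundred kb upward while staying far below the megabase isochore
  scale. `sensitivity_sweep()` reports $|H_s(B_k) - H_s(B_{k+1})|$
  across a grid (default 50, 100, 150, 200) so the stability of a
  chosen `B` can be verified per dataset.
* **Bin count `M`** (default 64). $H_s$ is bounded by $\log_2 M$ and
  depends on `M`, so every report carries its $(B, M)$ context. With
  $N \approx 3\cdot10^3$–$10^4$ blocks, 64 bins balance resolution
  against per-bin sampling noise. No automatic bin-width selection is
  attempted; `M` is a visible, reported parameter.
* **Bin range** (default $[0, 2]$ bits, global). Jensen-Shannon
  comparison requires a shared support; fixing the full theoretical
  range makes binnings identical across genomes by construction.
  Distributions built on different schemes are *refused* by the
  distance code rather than silently rebinned.
* **Metric mode** (default `sqrt_js`). Only $\sqrt{D_{JS}}$ satisfies
  the triangle inequality; raw $D_{JS}$ is available for comparison.
* **Linkage** (default `average`, i.e. UPGMA). The distance-matrix
  clustering behind the method's published trees does not pin a
  linkage; UPGMA is the explicit default (its ultrametric dendrogram
  matches branch-length-proportional plots), with complete, single and
  neighbor-joining selectable. Neighbor-joining trees are emitted
  unrooted.

## Numerical choices

* $0 \log 0 := 0$ everywhere; in $D_{JS}$, bins empty in both
  distributions are skipped (the mixture is zero there). $D_{KL}$
  refuses support violations ($p_j > 0$ where $m_j = 0$) instead of
  returning infinity — inside the JS construction this cannot occur.
* Bins are left-closed right-open, with the last bin closed so the
  maximal entropy 2.0 is counted.
* The trailing $L \bmod B$ bases are discarded (and recorded), never
  padded: a short block's entropy is not on the same scale.
* Block coordinates are 0-based half-open; block $i$ covers
  $[iB, (i+1)B)$ on the cleaned sequence.
* Cleaning removes (and counts) every non-ACGT character after
  case-folding, so every block holds exactly $B$ valid bases. Deleting
  rather than masking keeps $N$ maximal and preserves order.
* Clustering sorts genomes lexicographically by label before linkage,
  making ties (e.g. an all-zero matrix) and tree output deterministic
  and independent of input order. Negative neighbor-joining branch
  lengths are clamped to zero.
* Entropies are clamped into $[0, 2]$ and divergences into their
  theoretical ranges to absorb last-ulp floating-point excursions.
* All file output uses fixed 6-decimal formatting and records the full
  effective configuration (tool version, $B$, $M$, range, metric,
  linkage, input digests) in comment headers, so repeated runs are
  byte-identical and self-describing.

## Design decisions

* **Multi-record FASTA files are concatenated by default** into one
  genome per file (flag to keep records separate): the unit of
  comparison is the organism, one distribution per genome. Whether to
  concatenate chromosomes and how to treat assembly gaps are genuinely
  open choices; both are exposed as flags rather than hard-coded.
* **No strand canonicalization**: sequences are used as given. By
  Chargaff parity the entropy distribution is approximately
  strand-symmetric, so reverse-complementing would change essentially
  nothing.
* **Non-overlapping blocks, no sliding windows**, matching
  $N = \lfloor L/B \rfloor$ bookkeeping; overlap would correlate
  adjacent blocks and distort the histogram's effective sample size.
* **Plug-in entropy, no bias correction** (no Miller-Madow) in the
  method path: the bias is common to all genomes at fixed $B$ and
  cancels in comparisons; the known first-order term is instead used
  as an external check on the generator (below).

## The synthetic-data generator

`generate_genome()` draws a GC value per `segment_length` (default
1000 nt) from a composition regime — fixed GC, $\mathrm{Beta}(\alpha,
\beta)$, or a two-point mosaic — and then draws bases i.i.d. within the
segment, with optional A/T and C/G skews. It emulates exactly the
feature the method measures: blockwise composition that varies along
the sequence. A fixed-GC regime yields a narrow, unimodal block-entropy
distribution (virus-like); a wide beta regime yields a broad one
(plant-like); an *asymmetric* two-point mosaic yields a bimodal one.
(A GC pair symmetric about 0.5, such as {0.35, 0.65}, is deliberately
*not* a bimodality fixture: $H = 1 + h(g)$ is symmetric about
$g = 0.5$, so both branches land on the same entropy mode — the
bimodality tests use {0.1, 0.5}.)

Segment granularity is decoupled from `B` so tests can probe
misaligned segment/block boundaries. Seeds are mandatory; cohort
members get per-genome seeds via the documented polynomial hash
`derive_seed(master, group, index)` so any single genome is
regenerable in isolation.

What the generator does **not** emulate: genes, codon structure,
introns, repeats, megabase-scale isochores, dinucleotide correlations.
Passing planted-recovery tests therefore shows the pipeline correctly
separates genomes that differ in along-sequence GC variability — the
quantity the method is built on — not that real viral and host genomes
must separate; that claim rests on the method's application to real
assemblies.

Verification anchors for the generator itself: empirical GC converges
to the regime mean within binomial error, and the mean block entropy
of a balanced genome at $B = 100$ matches the first-order plug-in bias
prediction $2 - 3/(2B\ln 2) \approx 1.9784$ bits within three standard
errors.

## Problem sizes

The test suite and the acceptance script run on synthetic cohorts of
500 kb genomes (a realistic *Phycodnaviridae* scale; PBCV-1 is
~330 kb), 2–3 groups of two genomes each at $B = 100$, $M = 64$;
oracle comparisons use $10^3$ random length-100 blocks and $10^3$
random 64-bin probability vectors. These sizes give stable histograms
($N = 5000$ blocks per genome) while keeping the full suite fast.

## Known limitations

* $H_s$ values are only comparable at identical $(B, M)$; the package
  enforces shared binning for distances but the user must keep $(B, M)$
  fixed when comparing superinformation across studies.
* Genomes much shorter than $\sim M \cdot B$ give sparse histograms and
  noisy distances; the method is designed for $\ge$ 100 kb sequences.
* Composition is the only signal: genomes with identical windowed-GC
  distributions but different sequence order are indistinguishable by
  construction.
* Heatmap/dendrogram rendering is left to standard tools (`ape::plot.phylo`,
  `pheatmap`) on the exported Newick/TSV files.
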