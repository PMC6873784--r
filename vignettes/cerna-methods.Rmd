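---
title: "Inferring competing endogenous RNA triplets from case/control expression profiles"
author: "ceRNAnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring competing endogenous RNA triplets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAnet)
```

## The model

Competing endogenous RNA (ceRNA) regulation is the hypothesis that
transcripts sharing miRNA binding sites compete for a limited miRNA pool: a
long non-coding RNA (lncRNA) that sponges a miRNA relieves repression of
that miRNA's mRNA targets. The observable signature in expression data is a
*co-expression competing triplet*: a lncRNA and an mRNA that are strongly
positively correlated with each other, are both predicted targets of the
same miRNA, and are both negatively correlated with that miRNA.

ceRNAnet turns that signature into a pipeline:

1. **Differential expression.** Per feature, the linear-scale fold change
   (folded to be $\ge 1$ and labelled up/down by the case/control direction)
   and a classic pooled-variance Student t-test. Defaults follow the usual
   small-sample array conventions: fold change $> 2$ for miRNAs, $> 1.5$ for
   lncRNAs/mRNAs, $p < 0.05$, no multiple-testing correction for filtering
   (a BH-FDR column is reported for information). The t-test runs on log2
   intensities, where array noise is closest to homoscedastic normal; fold
   changes are computed on the linear scale, where they are interpretable as
   ratios. With three to six samples per group these screens are
   deliberately permissive; the raw-p convention mirrors how such arrays
   are usually filtered, not a recommendation for confirmatory analysis.
2. **Candidate interactions.** miRNA→target pairs either imported from
   external prediction tools as tab-delimited tables, or produced by the
   built-in canonical seed-match scanner: every occurrence on the target of
   the reverse complement of miRNA positions 2–7, classified into the
   standard 6mer / 7mer-A1 / 7mer-m8 / 8mer taxonomy by the match at miRNA
   position 8 and the adenosine opposite position 1. The scanner is a
   transparent, testable stand-in for thermodynamic predictors (duplex
   free-energy computation is out of scope by design); the default minimum
   reported class is 7mer.
3. **Pair selection.** All differentially expressed lncRNA × mRNA
   combinations are tested with the Pearson correlation across all samples
   (case and control pooled, log2 scale by default); pairs with
   $r > 0.99$ and $p < 0.05$ (from $t = r\sqrt{(n-2)/(1-r^2)}$, $df = n-2$)
   are kept. The 0.99 threshold is extremely stringent — at $n \ge 6$ it is
   vanishingly rare under independence, which is what makes the triplet
   count specific.
4. **Triplet assembly.** For each retained pair, each miRNA that targets
   *both* members in the interaction table and is negatively co-expressed
   with both ($r < 0$, $p < 0.05$ on each side) yields one triplet.
   Interaction support is required even when the correlations would pass.
   The "ceRNA score" attached to each triplet is the shared-miRNA
   hypergeometric score: the overlap of the two members' miRNA target sets
   and the upper-tail probability of an overlap at least that large given
   the miRNA universe. No consensus definition of a ceRNA score exists; the
   hypergeometric overlap is this package's explicit, documented choice and
   is labelled as such in outputs.
5. **Network topology.** Triplets assemble into a tripartite undirected
   network (typed nodes, typed edges `lnc_mir`/`mir_mrna`/`lnc_mrna`).
   The hub panel per node: degree; unnormalized Brandes betweenness (each
   unordered pair once); *harmonic* closeness divided by $n-1$; PageRank
   with damping 0.85. Harmonic closeness was chosen because ceRNA networks
   are frequently disconnected and the classical closeness is undefined
   across components; published absolute closeness values from GUI network
   tools are generally not recomputable without the exact edge list and
   implementation, so closeness is used for ranking, not for value-matching.
6. **Random walk with restart.** Deterministic power iteration
   $p \leftarrow (1-r)\,W p + r\,p_0$ with the column-normalized adjacency,
   uniform restart vector over the seed nodes, and dangling-node mass
   redistributed to $p_0$. Default restart probability 0.7 (the common
   network-medicine choice); tolerance $10^{-10}$ in L1. PageRank is the
   same fixed point with all nodes as seeds and restart $0.15$, which keeps
   one well-tested iteration engine behind both statistics.
7. **Modules and enrichment.** Bidirectional hierarchical clustering
   (independent row and column dendrograms) with 1 − Pearson distance and
   average linkage, cut at $k = 2$ by default; Euclidean/complete are
   available by flag. Correlation distance matches the goal of grouping by
   co-expression pattern; the published analyses this emulates do not state
   their metric/linkage, so module membership is treated as qualitative.
   Enrichment is a generic hypergeometric test over user-supplied GMT
   annotation sets with BH adjustment — no ontology database is bundled or
   downloaded.

## The synthetic-data generator

`SyntheticSpec()`/`simulateDataset()` emulate the structure of a small
two-group, three-class microarray study: 3–12 samples per group, log2
intensities around a common baseline, a minority of features with large
fold changes, and planted triplets with the exact ceRNA correlation
signature. For each planted triplet one latent value $z_j$ per sample is
drawn, and

$$\text{lncRNA}_j = \mu + z_j + \delta\,[j \in \text{case}] + \varepsilon_j,
\qquad \text{mRNA}_j \text{ likewise}, \qquad
\text{miRNA}_j = \mu - z_j - \delta\,[j \in \text{case}] + \varepsilon_j,$$

the minimal construction that simultaneously forces the positive
lncRNA–mRNA correlation, both negative miRNA correlations, and differential
expression of all three members. Background features are independent noise
around the baseline.

Defaults, with reasoning:

* `baselineMean = 8`, `backgroundNoiseSd = 0.25` (log2): placeholder values
  in the range typical of normalized two-colour/oligo array intensities;
  no raw-intensity estimates were available to fit them.
* `latentSd = 0.5`: a shared signal clearly above measurement noise but
  small against the baseline, giving planted pair correlations near 1 at
  realistic noise (`backgroundNoiseSd = 0.05` in the benchmark) without
  making recovery trivial at high noise.
* `effect = 2` log2 units (4-fold): comfortably inside the fold-change
  range such screens report (roughly 2- to 200-fold).
* `decoyRatio = 3`: three expression-unsupported interaction pairs per
  planted pair, so the anticorrelation filter has something to reject.
  Decoys are drawn only from pairs with at least one background endpoint.
  Pairs connecting members of *different* planted triplets are excluded on
  purpose: all planted features share the case/control shift, so such pairs
  would carry correlated expression and would not be "no expression
  support" decoys but cross-triplet leakage, which the generator does not
  model.

What the generator does **not** emulate: probe-level artifacts, batch
effects, heteroscedastic intensity-dependent noise, correlated background
co-expression structure, or sequence evolution. Passing the recovery
benchmark therefore shows the pipeline implements its selection rules
correctly and is calibrated under clean null structure — it does not show
that real tissue data meet those assumptions.

## Numerical choices and degenerate inputs

* Zero pooled variance in the t-test: $p = 1$ when the group means are
  equal, $p = 0$ when they differ (the difference is then exact).
* A zero group mean against a positive one gives fold change `Inf` with the
  correct direction; both means zero is an error.
* Constant expression profiles are dropped with a warning before any
  correlation, rather than producing undefined $r$.
* $r = \pm 1$ maps to $p = 0$ exactly.
* Ranking ties (equal centrality) break lexicographically by node id; edge
  endpoints are stored in canonical class order, so networks compare and
  deduplicate deterministically.
* All randomness flows from the single spec/config seed; the RWR engine is
  deterministic power iteration, not sampling. Identical inputs reproduce
  identical outputs byte for byte.

## Problem sizes used in the shipped benchmarks

The test-suite and acceptance-script benchmarks use 30 lncRNA / 20 miRNA /
40 mRNA features: recovery uses 10 planted triplets, noise sd 0.05 and 12
samples per group over 50 simulation seeds; null calibration uses 100
seeds of the default 3 + 3 design with no planted structure; the
brute-force topology cross-checks use 200 random networks of at most 12
nodes, where exact path enumeration and dense linear solves are cheap.
These sizes make every property check exact or tightly Monte-Carlo-bounded
while keeping a full run of the suite fast on a laptop.

## Known limitations

* The Pearson-based screen detects linear co-expression only, and the
  stringent $r > 0.99$ cut-off is sensible only for the very small sample
  sizes it was designed around; at larger $n$ it becomes needlessly harsh.
* The seed-match scanner ignores binding energetics, conservation and
  context; imported predictions are taken at face value (no score filter
  unless requested).
* Correlations pool case and control samples; a group-restricted mode
  exists (`useLog2`/group flags) but group-specific ceRNA rewiring is not
  modelled.
* The hypergeometric ceRNA score treats target sets as exchangeable draws
  from the miRNA universe, ignoring target-set size biases.
* Partial-correlation or conditional ceRNA scores (sensitivity
  correlation) are out of scope.
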