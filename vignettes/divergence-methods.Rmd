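---
title: "Divergence-based N-terminal sorting signal prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence-based N-terminal sorting signal prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divsig)
```

## The model

N-terminal sorting signals — mitochondrial matrix targeting signals (MTS),
secretory signal peptides (SP) and chloroplast transit peptides (CTP) — are
constrained by physico-chemical properties rather than by sequence, and
consequently diverge rapidly between orthologs while the protein body stays
conserved. `divsig` turns that divergence into a predictive feature.

The core quantity is the gap-aware column entropy of an ortholog multiple
sequence alignment (orthoMSA). For column $i$,

$$H(i) = -\sum_{j \in A} F(i,j)\, \log_2 F(i,j),$$

where $A$ contains the amino-acid characters **and gaps, each gap
occurrence counted as a unique character**. Amino acids pool by identity
(frequency $c/n$ for $c$ occurrences among $n$ rows); every gap contributes
a frequency of exactly $1/n$. Columns riddled with gaps therefore score as
highly divergent — an alignment region that cannot even be aligned is the
strongest form of divergence. $H(i)$ ranges from $0$ to $\log_2 n$; an
all-gap column attains the maximum exactly. A pooled-gap ("plain entropy")
variant was considered and rejected: treating all gaps as one character
understates divergence in gap-rich signal regions.

`entropy_profile()` reports $H$ in **reference-residue coordinates**:
columns where the reference protein has a gap are dropped, and position $k$
means the $k$-th residue of the reference protein. This convention is a
documented design choice — the interval features below describe the
reference protein's N-terminus (its first 20 or 40 residues), so the
profile must be indexed by residues of that protein, not by MSA columns,
which shift with indels in other species.

### Divergence features

All interval features derive from the smoothed entropy
$\bar H_{i,j}$ = mean of $H$ over the inclusive interval $[i, j]$:

| feature | definition |
|---|---|
| `LD_i` | $\bar H_{i-10,\,i+10}$ (local divergence, 21-residue window) |
| `Nraw20`, `Nraw40` | $\bar H_{1,20}$, $\bar H_{1,40}$ |
| `Nraw80_99` | $\bar H_{80,99}$ |
| `mu20`/`sigma20`, `mu40`/`sigma40` | mean / population SD of all length-20 (40) window means |
| `NCdiff` | `Nraw20 − Nraw80_99` |
| `N20`, `N40` | z-scores of `Nraw20`, `Nraw40` against (`mu20`,`sigma20`), (`mu40`,`sigma40`) |
| `N80_99` | z-score of `Nraw80_99` against (`mu20`, `sigma20`) |

`NCdiff` subtracts the divergence of residues 80–99 as a per-protein
normalizer, so proteins with globally fast evolution are not mistaken for
signal-bearing ones. `N80_99` is deliberately normalized with the
length-20 window statistics (its own window is length 20).

Numerical choices, all unit-tested:

* **Boundary clipping.** `LD` windows and feature intervals clip at the
  profile ends rather than erroring, so `LD(1)` (mean over positions 1–11)
  exists and N-terminal divergence curves can be drawn from position 1.
* **Window statistics** `mu_w`/`sigma_w` are computed over *all* length-$w$
  windows of the full profile (not only the N-terminal region), with the
  population (not sample) SD. Both readings of "all windows" are
  defensible; the alignment-wide choice uses the protein body as the
  reference distribution, which is what the z-scores are meant to capture.
* **Short proteins.** For $80 \le L < 99$ the tail window clips to
  $[80, L]$. For $L < 80$ there is no C-terminal normalization window at
  all; rather than fabricate one, `divergence_features()` raises a typed
  condition and `compute_features()` excludes the protein (with a message).
* **Degenerate profiles.** If `sigma_w` is zero (constant profile, up to
  floating-point dust from the rolling-mean `cumsum`), z-scores are set to
  0 with a warning.
* Default `LD` positions are every fourth residue in 1–49 plus position
  13; position 13 is the single most informative local-divergence position
  in this problem, and the grid covers the region where MTS/SP/CTP signals
  live without inflating the feature count.

### Classical features

Charged-residue counts use positive = {R, K}, negative = {D, E}.
Histidine is excluded: at physiological pH it is mostly neutral, and MTS
positive charge is carried by arginine/lysine. Hydrophobicity is the
original Kyte-Doolittle scale (A 1.8 … R −4.5), embedded as a constant and
unit-tested against its published extremes; `X` residues are skipped from
both numerator and denominator. Composition is the frequency of the 20
standard amino acids over the N-terminal 20, N-terminal 40, or full
sequence (`pos20 … comp20_A … compf_Y` naming).

### Ortholog sets

Orthologs are defined operationally as reciprocal best hits (RBH) under
**global** alignment similarity: local alignment would let a strong shared
domain mask exactly the N/C-terminal differences that signal a different
localization. Scoring uses BLOSUM62 with affine penalties (open 10,
extend 1) and penalized end gaps; the dynamic-programming engine is
`Biostrings::pairwiseAlignment`, cross-checked in the test suite against
exhaustive enumeration of all global alignments for short sequences. Ties
for best hit are resolved conservatively: "more similar than any other
protein" is read as strict superiority, so a tie yields no RBH pair. Sets
keep the reference protein plus all its RBHs and are discarded below 4
sequences, the point at which the divergence score distribution
stabilizes. Set assembly is reference-vs-each-species independently; no
transitive clustering.

### Feature importance

Single-feature importance is the information gain
$I(C;F) = H(C) - H(C\mid F)$ in bits, computed after Fayyad-Irani MDL
discretization: recursive binary splitting at the entropy-minimizing
boundary midpoint, a split being accepted only when its gain exceeds
$[\log_2(N-1) + \log_2(3^k-2) - (k\,\mathrm{Ent}(S) - k_1\mathrm{Ent}(S_1)
- k_2\mathrm{Ent}(S_2))]/N$. Candidate cuts are restricted to midpoints
between adjacent distinct values whose value-groups are not both pure with
the same class (boundary points), which provably preserves the optimum;
identical feature values are never split apart. Ranking ties break by
feature name for determinism.

### Classifiers and evaluation

* **Majority baseline** predicts the modal training label (ties broken by
  the fixed order MTS < SP < CTP < none). By the stated conventions its
  MCC is identically 0 (zero-denominator rule) and its AUC 0.5 (constant
  scores under midrank tie handling) — both fall out of the metric
  implementations rather than being special-cased.
* **Decision tree**: an information-gain tree (rpart) with cp-based
  pruning serves as the interpretable baseline; exact equivalence with any
  particular C4.5 implementation is a non-goal.
* **SVM**: Gaussian RBF kernel with $\gamma = 1/d$ and cost $C = 50$
  (the default cost of 1 is too soft for RBF on these features), trained
  by libsvm via e1071. Multiclass uses one-vs-one machines with majority
  voting; voting ties break by the smallest decoded loss (below). Features
  are z-scored on training-fold statistics (default on for the SVM only):
  $\gamma = 1/d$ presumes comparable feature scales, and counts, entropies
  and compositions live on different scales.
* **Evaluation** is stratified k-fold cross-validation (default 5×5,
  seeded, bit-reproducible). Accuracy and per-class one-vs-rest AUC/MCC
  are computed per fold and reported as mean ± SD over folds × repeats.
  The per-class AUC score in multiclass settings is the decoded
  pseudo-posterior of that class — a documented assumption, since per-class
  AUC otherwise has no canonical score in a voting ensemble. AUC is the
  rank-based Mann-Whitney form (ties count ½); MCC comes from the
  one-vs-rest confusion counts with the zero-denominator → 0 convention.
  The pooled confusion matrix sums to dataset size × repeats. A
  label-shuffled control (`shuffle_labels = TRUE`) permutes labels per
  repeat and should return AUC ≈ 0.5, MCC ≈ 0.
* **Balancing**: `balance_classes()` subsamples every class to the
  minimum class size, the standard antidote to the heavy class skew of
  real localization datasets.

### Influence of divergence features

To find proteins whose prediction hinges on divergence, the SVM is trained
with and without the divergence columns and each example's one-vs-one
decision scores are compared. Raw SVM scores are not probabilities and
each machine addresses a different class pair, so the comparison goes
through **exponential loss-based decoding**: with the one-vs-one coding
matrix $M$, $\mathrm{loss}(c) = \sum_{\text{machines}} e^{-M[c,\cdot]\,s}$,
and pseudo-posteriors $p(c) \propto 1/\mathrm{loss}(c)$. The influence of
the divergence features on one example is the total-variation distance
between the two decoded posterior vectors, reported together with both
argmin-loss labels. This combination rule is a stated stand-in — no
canonical formula exists for comparing score sets across ensembles — but
any measure that is zero iff the decodings coincide and grows with the
posterior shift would order drastic changes similarly. Scores are taken
from stratified cross-validation held-out folds, not from models scoring
their own training data.

## The synthetic family generator

`simulate_family()` produces labeled orthoMSAs with the one statistical
property the method exploits: **signal regions evolve faster than the
protein body, with class-typical composition**. An ancestral sequence is
drawn from class-conditional position-specific frequencies; each of
`n_species − 1` orthologs then evolves independently down a star phylogeny
(per-site substitution probability = background rate × ρ inside the signal
region, capped at 1), with signal-region sites of non-reference rows gapped
at the indel rate. The reference row stays ungapped, so reference-gap
coordinate mapping is exercised separately by hand-built fixtures.

Defaults, chosen once as field-realistic study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_species` | 11 | typical size of a curated per-division species panel |
| length | U(150, 500) | common range of globular proteins |
| signal length | MTS/SP 20, CTP 50 | typical presequence/SP lengths; CTPs are markedly longer |
| `background_rate` | 0.15/site/branch | body identity ~85% between orthologs of moderately diverged species |
| `rho` | 4 | signal regions visibly but not saturatingly faster (0.6/site) |
| `indel_rate` | 0.05 | signals also gain/lose residues, inflating gap divergence |
| MTS bias | R,K ×3; D,E ×0.2 | arginine/lysine-rich, acid-depleted presequences |
| SP bias | I,L,V,F ×4 at positions 6–15 | the hydrophobic h-region |
| CTP bias | S ×3; D,E ×0.5 | serine-enriched transit peptides |
| none | background everywhere | uniform rate, no composition shift |

A star phylogeny suffices because the entropy score itself ignores
phylogenetic relationships; substitutions are redraws from the position
frequencies rather than a rate-matrix CTMC because only column
heterogeneity matters downstream.

**What the simulator does not emulate** — and hence what passing tests do
*not* demonstrate about real data: correlated evolution along a real tree
(star branches are independent, so column entropies are more regular than
in nature), alignment error from real MSA programs, cleavage-site motifs,
the mammal-vs-yeast divergence-scale difference, paralog contamination of
RBH sets, and annotation noise. Synthetic recovery results certify the
pipeline's correctness, not its field accuracy.

## Problem sizes

The test suite and behavioral checks run at deliberately modest scale:
oracle equivalences at 1,000 random instances (MCC, AUC) and 20–30 tiny
pairs (aligner enumeration, lengths ≤ 4); generator properties at 40–100
families per condition; the shuffled control at 500 families and the
balanced 3-class recovery at 100 families per class, both under 5×5
cross-validation. These sizes give stable statistics for every claim
tested while keeping a full run in the low minutes on one core.

## Known limitations

* The divergence score ignores phylogeny; closely related species inflate
  apparent conservation. Phylogeny-aware conservation scores are out of
  scope.
* Reference-residue indexing of `LD` positions and alignment-wide window
  statistics are documented assumptions where the method description
  admits two readings.
* The RBH scoring parameters (BLOSUM62, 10/1) are an explicit stand-in for
  an unrecoverable heuristic-tool default; RBH itself is paralog-blind.
* The decision tree is a baseline, not a Weka J48 clone.
* Proteins shorter than 80 residues are excluded rather than renormalized.
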