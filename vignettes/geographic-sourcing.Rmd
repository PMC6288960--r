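---
title: "Alignment-free geographic sourcing: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free geographic sourcing: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmergeo)
```

## The problem

Where did a DNA sample come from? For traded biological materials — timber
is the motivating case — the question often has to be answered from low-
coverage shotgun sequence of a degraded sample, with no reference genome
and no hope of reliable alignment. kmergeo answers it alignment-free: a
sample is summarized by its k-mer occurrence profile, compared against a
panel of georeferenced reference samples with background-adjusted
dissimilarity statistics, and assigned a continent of origin by a
K-nearest-neighbor vote. Everything downstream — significance of the
continental structure, ordination, confidence in individual calls — works
off the same pairwise dissimilarity matrix.

## Dissimilarity statistics

Let $X_w$ be the number of occurrences of word $w \in \{A,C,G,T\}^k$ in a
sample's reads (windows are confined to single reads, windows containing N
are skipped, and by default each read and its reverse complement are both
counted, so strand sampling is symmetrized away), $N = \sum_w X_w$, and
$f_w = X_w/N$. The six statistics:

* **Manhattan** $\sum_w |f_{X,w} - f_{Y,w}|$ and **Euclidean**
  $\sqrt{\sum_w (f_{X,w} - f_{Y,w})^2}$ on raw frequencies.
* **d2** $\tfrac12\!\left(1 - \frac{\sum_w X_w Y_w}{\|X\|_2\|Y\|_2}\right)$,
  the cosine form, so that like the background-adjusted statistics it lives
  in $[0,1]$ with 0 for identical and 1 for anti-correlated profiles.
* **d2\*** and **d2s** first remove what base composition alone would
  predict. An $m$-th order Markov chain is fitted to each sample's own
  reads: transition probabilities $P(a \mid u) = C(ua) / \sum_b C(ub)$ from
  $(m{+}1)$-mer counts, initial context probabilities from $m$-mer counts,
  and word probabilities by the chain rule
  $p_w = q(w_{1..m}) \prod_i P(w_i \mid w_{i-m..i-1})$. With centered
  counts $\tilde X_w = X_w - N p_w$,
  $$D_2^* = \sum_w \frac{\tilde X_w \tilde Y_w}
      {\sqrt{N_X p_{X,w}\, N_Y p_{Y,w}}}, \qquad
    d_2^* = \frac12\left(1 - \frac{D_2^*}
      {\sqrt{\sum_w \frac{\tilde X_w^2}{N_X p_{X,w}}}
       \sqrt{\sum_w \frac{\tilde Y_w^2}{N_Y p_{Y,w}}}}\right),$$
  and $d_2^s$ replaces the variance normalizer by
  $\sqrt{\tilde X_w^2 + \tilde Y_w^2}$ per word (with the matching
  self-normalizers). Words with zero background probability in either
  sample are excluded from the $d_2^*$ sums *and* from both
  self-normalizers; this keeps the two normalizers consistent with the
  cross term, which is what pins the statistic inside $[0,1]$ and makes
  the self-dissimilarity exactly 0. No pseudocounts are added by default —
  at the intended depths every word of a fully covered model has positive
  probability anyway, and pseudocounts would blur the centering.
* **CVTree** uses a plug-in expectation instead of a fitted chain:
  $E_w = X(w_{1..k-1}) X(w_{2..k}) / X(w_{2..k-1})$ (zero when the
  denominator is), composition-vector entries $a_w = (X_w - E_w)/E_w$, and
  the same $\tfrac12(1-\cos)$ form. Structurally this is the order-$(k-2)$
  background.

For the normalization of $d_2^s$ more than one convention circulates; the
one implemented is fixed by three requirements checked in the test suite:
self-dissimilarity 0, anti-correlated centered profiles at exactly 1, and
agreement with a brute-force evaluation that loops over all $4^k$ words.

### k and m

The word length `k` and Markov order `m` are paired as `k = m + 2` when
only one is supplied — the pairing under which the background-adjusted
statistics discriminate best. At real data scale (hundreds of Mbp per
sample) `k = 12, m = 10` is the working point; profiles are stored densely
over the $4^k$ alphabet, so k much beyond 12 needs a different data
structure and is out of scope. All synthetic-scale analyses here use
`k = 8, m = 2`, which the 200 kb desk genome can actually populate.

## Classification and confidence

`knn_predict` votes among the K references nearest to the query in the
precomputed matrix. Tie handling is fully deterministic and documented
rather than left to chance: candidate neighbors are ordered by (distance,
sample id); tied votes go to the label owning the single nearest neighbor,
then to the smallest summed distance, then alphabetically. `evaluate_splits`
reports mean test accuracy over random unstratified train/test splits
(stratification is deliberately not imposed; a split that loses a continent
from the training set simply cannot predict it, which is informative
rather than an error).

Two bootstrap-style scores qualify an individual call:

* **RC (reference confidence)** — resample the reference panel with
  replacement B times (a sample drawn twice genuinely occupies two of the
  K slots); RC is the fraction of resamples whose prediction matches the
  full-panel prediction.
* **NC (NGS confidence)** — split the query's reads into disjoint subsets
  of a fixed base total, rerun profile → dissimilarity → KNN per subset;
  NC is the fraction predicting the modal label (modal ties broken by the
  subset with the smallest 1NN distance).

## Statistics on the matrix

The intra- versus inter-continental contrast uses the Wilcoxon–Mann–
Whitney count $U = \#\{(a,b): b > a\} + \tfrac12\#\{b = a\}$ over
(within-continent, between-continent) pair values, with a permutation
null: sample labels are permuted jointly and the pair partition is rebuilt
each time, which preserves the strong dependence among pairs sharing a
sample. The p-value is the add-one estimator $(1 + \#\{U_{perm} \ge
U_{obs}\})/(B+1)$ — it can never return 0, and counting ties with $\ge$ is
conservative. For the pooled test (`group = "ALL"`) the three per-continent
pair partitions are concatenated, so a between-continent pair contributes
to both continents it touches; this doubling rescales $U$ identically under
permutation and leaves the p-value's meaning intact. Default B is $10^4$;
at that B the smallest attainable p is $10^{-4}$.

PCoA is classical Gower double-centering with eigendecomposition (via
`ape::pcoa`); negative eigenvalues — expected, since d2* is not Euclidean —
are reported and dropped, with no Cailliez/Lingoes correction, and variance
fractions are taken over the positive eigenvalues only. Great-circle
distances use the haversine formula on the IUGG mean sphere
(R = 6371.0088 km); the correlation of pairwise dissimilarity with pairwise
great-circle distance (`geo_correlation`) is reported as Pearson R, R², and
Spearman rho over all sample pairs.

## The synthetic design

The simulator exists so that every stage of the pipeline can be exercised
and falsified without multi-GB downloads. It emulates the *structure* of a
three-continent reference panel, not the biology of any real species:

* a root genome of i.i.d. bases at a configurable GC content;
* a star phylogeny — root → continent ancestors at substitution
  probability δc per site, ancestor → individuals at δi per site,
  substitutions independent and uniform over the three alternative bases
  (no indels, no transition/transversion bias, no recombination — this is
  deliberately not a coalescent model);
* shotgun reads with uniform start positions, random strand, and per-base
  substitution error ε; `inject_errors` composes additional error on top
  by sequential application;
* sampling coordinates scattered (Gaussian, in km) around three fixed
  continent centers (40N 95W, 48N 10E, 45N 125E).

The desk preset is L = 200 kb, 12 individuals × 3 continents, δc = 0.02,
δi = 0.002, 100 bp reads, 200 kb per sample, ε = 0.001, analyzed at
k = 8, m = 2 — a scaled stand-in for a ~0.8 Gb genome panel of ~92 samples
at 50–300 Mbp per sample and k = 12, m = 10. Problem sizes in the test
suite (5 seeds per property, B = 999 permutations, B = 200 bootstraps,
5 × 100 kb read subsets) were chosen as the smallest at which the checked
properties are statistically stable.

With `ibd = TRUE` the three continental branch lengths are set by the
three-point split of the pairwise great-circle distances between the
continent centers, scaled so the largest pairwise divergence is 2δc. Then
expected sequence divergence is proportional to geographic distance —
an isolation-by-distance world in which the dissimilarity–distance
correlation has a known positive sign, and more sequenced bases per sample
mean less profile noise and a higher correlation.

What passing on this design does *not* show: robustness to repetitive DNA,
uneven coverage, contamination, library-preparation bias, indel error
(PacBio-style), or population structure more complex than a star tree.
Real-data behavior on those axes has to be established on real data.

## Numerical and degenerate-input choices

* Sums over the $4^k$ alphabet are accumulated in double precision with
  R's long-double `sum`; agreement with the brute-force oracle is asserted
  to 1e-9.
* Empty profiles (N = 0), zero normalizers, and constant dissimilarity
  vectors raise explicit "undefined measure"/degenerate errors or
  NA-with-warning rather than silently returning 0.
* Down-sampling and read partitioning accumulate whole reads until a
  target is first reached — no read trimming, so read-internal k-mer
  structure is preserved; the overshoot is bounded by one read length.
* Continent labeling applies the country rule (US/Canada → NA) before the
  60°E longitude rule, so North American samples are recognized at any
  longitude.
* All stochastic stages draw from sub-seeds derived from a master seed via
  a fixed 32-bit hash of a stage tag (`stage_seed`), so any single stage
  can be rerun in isolation, bit-reproducibly.

## Known limitations

Dense $4^k$ profiles cap the practical word length near 12; paired-end
mates are treated as independent reads; FASTQ qualities are read and
discarded (no quality trimming); the Markov order m is a configuration
parameter — no order-estimation procedure is bundled; and the permutation
test permutes all labels jointly even for per-continent contrasts, which
is one of several defensible nulls.
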