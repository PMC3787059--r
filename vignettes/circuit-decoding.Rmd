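---
title: "Decoding behavior from neuronal functional networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding behavior from neuronal functional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeCircuits)
```

## The question and the model

Given simultaneously recorded spike trains segmented into behavioral trials
of two types, does the pattern of pairwise functional coupling among the
neurons differ between the types — and strongly enough to classify a single
held-out trial? `spikeCircuits` answers this with a network pipeline rather
than a firing-rate one: every trial is summarized as a weighted graph over
the fixed neuron roster, trials are compared in graph space, and both an
unsupervised (spectral clustering) and a supervised (leave-one-out
classification) read-out are computed.

### Stage 1: per-trial weighted functional networks

Spike trains are restricted to the half-open trial window [start, end) and
counted in consecutive non-overlapping bins of width 1 s (a trailing
partial bin is discarded; at least two full bins are required). The edge
weight between neurons $x$ and $y$ is the Pearson correlation of their
bin-count vectors when positive, and 0 otherwise:

$$R_{xy} = \max\!\left(0,\;
  \frac{\sum_k (x_k - \bar x)(y_k - \bar y)}
       {\sqrt{\sum_k (x_k - \bar x)^2}\sqrt{\sum_k (y_k - \bar y)^2}}\right).$$

Negative coupling is deliberately discarded — the method models functional
*co-activation* — and the weighted matrix is analyzed directly: no
threshold-and-binarize step, whose threshold would be arbitrary, is
applied. A neuron silent (or constant) within a trial has an undefined
correlation; it receives weight 0 to every partner and is retained, so the
matrices of all trials stay conformable. This matters in stage 3, where
matrices are subtracted entrywise.

### Stage 2: circuit groups by modularity maximization

Each network is partitioned into communities ("local neuronal circuit
groups") by maximizing Newman's weighted modularity

$$Q = \frac{1}{2l} \sum_{ij} \left[ w_{ij} -
  \frac{k_i k_j}{2l} \right] \delta(c_i, c_j),$$

with $l$ the total connection weight and $k_i$ the weighted node strength.
The search follows the classical two-step recipe: build a hierarchical
clustering of the connected nodes on the distance $d = 1 - R$ (absent edges
have $d = 1$), then evaluate $Q$ at every dendrogram cut
$c = 1, \dots, n$ and keep the cut with maximal $Q$. Average linkage is the
default (the conventional choice for similarity-derived distances; single
and complete linkage are available). Exact ties in $Q$ — and values within
$10^{-12}$ of the maximum, to absorb floating-point noise — resolve toward
fewer communities. Nodes without any positive-weight edge cannot contribute
to $Q$; they are set aside first as outlier singletons, and the reported
$Q$ refers to the connected subnetwork. The dendrogram restricts the
partitions examined, so global optimality is not guaranteed on adversarial
graphs; the test suite verifies agreement with exhaustive enumeration on
clearly modular planted graphs (where the restriction is harmless) and the
known resolution limit of modularity is accepted as-is.

The circuit-group ("LNCG") representation of a trial keeps the weighted
matrix on intra-community edges and zeroes the rest. How community
structure should re-enter the trial-comparison stage is genuinely open; the
masked weighted matrix is the primary choice because it preserves edge
magnitudes (the quantity stage 3 measures), and a binary co-membership
matrix (`mode = "comembership"`) is provided as the alternative reading.

### Stage 3: trial similarity and two-way spectral clustering

Trials $i, j$ are compared with a Gaussian kernel on the Frobenius distance
between their matrices, taken over the upper triangle so each neuron pair
counts once:

$$S_{ij} = \exp\!\left( -\frac{\| R^{(i)} - R^{(j)} \|_F^2}{2\sigma^2} \right),
\qquad \sigma = 4 \text{ by default.}$$

(Summing over the full matrix would only rescale distances by $\sqrt 2$,
which $\sigma$ absorbs.) Two standard two-way partitioners run on $S$:

* **NJW**: eigendecompose $D^{-1/2} S D^{-1/2}$, take the two leading
  eigenvectors, normalize the rows to unit length, k-means with $k = 2$.
  k-means uses a fixed internal seed with 10 restarts, so results are
  deterministic and the caller's RNG stream is untouched; a pathological
  all-equal similarity matrix yields a seed-determined, arbitrary split.
* **Normalized cut**: the Fiedler vector of the generalized problem
  $(D - S) v = \lambda D v$, followed by a sweep of all $k - 1$ thresholds
  over its sorted entries, returning the bipartition with minimal
  $\mathrm{Ncut}(A, \bar A) = \mathrm{cut}/\mathrm{vol}(A) +
  \mathrm{cut}/\mathrm{vol}(\bar A)$.

The unit self-similarity $S_{ii} = 1$ (the kernel at distance 0) is kept on
the diagonal in both methods and in their brute-force test oracles; with
all entries of $S$ positive the similarity graph is connected, so the
generalized eigenproblem is well posed. Cluster ids are arbitrary, so
accuracy against the true behavioral labels is reported after the better of
the two label permutations ("aligned accuracy").

### Stage 4: single-trial decoding

Under leave-one-out cross-validation each trial is predicted from the other
$N - 1$, trained with their true labels. Two classifiers operate on rows of
$S$ (the held-out trial's self-similarity never participates):

* **Pattern matching**: mean similarity to each group's trials; the larger
  mean wins. An exact tie goes to the larger training group, then to the
  first label in sorted order.
* **KNN**: majority label among the $\min(k, N-1)$ most similar training
  trials ($k = 7$ by default; similarity ties resolve toward the lower
  trial index, keeping the rule deterministic). An even neighbor split —
  impossible for odd $k$ with a full neighborhood — falls back to the
  pattern-matching rule.

Performance is the two-class coefficient $s = p_1 + p_2$, where $p_j$ is
the number of correctly classified label-$j$ trials divided by the total
trial count $N$. Note $p_1 + p_2$ is algebraically the overall fraction
correct; the package keeps the two-term form because the per-label terms
are useful diagnostics, and the name `jaccardCoefficient` follows the
field's usage for this two-way score — it is *not* the set-theoretic
Jaccard index. One consequence of the deterministic tie rules is worth
knowing: on perfectly uninformative data (all trial matrices identical,
balanced labels) the held-out trial's own group is always one trainer
short, so the tie rule predicts the opposite class every time and the score
is 0, not 0.5. Real noisy data do not produce exact ties; null simulations
decode at ~0.5 as expected.

## The synthetic-data generator

No public recordings accompany this problem setting, so the package ships
a generator whose output has exactly the statistical structure the pipeline
measures: trial-type-dependent block correlation of 1-s bin counts.

Each trial is discretized into 10-ms sub-bins. Every module (block of
neurons under the current trial type's module map) has a shared binary
event process: the event indicator is drawn once per 0.2-s block with
probability `commonEventRate * eventDuration` and held for the block.
Neuron $i$ spikes in a sub-bin with probability

$$p = \mathrm{clip}\big(\texttt{baseRate} \cdot dt \cdot
   (1 + \texttt{commonGain} \cdot E_{m(i)}), \, 0, 1\big),$$

with the spike time uniform within the sub-bin. Neurons sharing a module
receive common input and correlate; neurons in different modules are
independent, and all induced correlations are non-negative — matching the
pipeline's retention of positive coefficients only. The common-input
Bernoulli construction was chosen over a dichotomized-Gaussian approach
because it is simpler, exactly seedable, and cannot produce negative
coupling.

Event *persistence* is the load-bearing choice. If the shared events were
redrawn independently every 10-ms sub-bin, the induced correlation of 1-s
counts would be tiny at any plausible gain (about 0.015 at the default
rates and gain 4: with sparse firing, the independent Bernoulli noise of
~100 sub-bins swamps the shared-rate variance). Holding each event for
0.2 s makes the shared rate fluctuation slow relative to the analysis bin,
giving a within-module correlation of about 0.65 at the defaults — the
closed form implemented in `expectedCorrelationContrast()`, which the test
suite checks against Monte-Carlo estimates. Biologically this models slow
common drive (up-states, shared afferent volleys) rather than precise
synchrony.

Defaults: 12 neurons, 80 trials of 10 s (labels alternating, as maze
behaviors do), 1-s inter-trial gap, 5 spikes/s baseline, events at 2/s x
0.2 s, gain 4. The default module maps make the two types maximally
different in topology while identical in rates: type A groups neurons
1–6 vs 7–12, type B groups 1–3+7–9 vs 4–6+10–12. `makeNullSession()`
applies the first label's map to both types, so the label carries no
connectivity information and decoders should score ~50%.

What the generator does **not** emulate: refractoriness, bursting, place
fields or any within-trial nonstationarity, negative correlations, firing
rates calibrated to a specific preparation (defaults are chosen for
desk-scale testability). Passing tests therefore demonstrate that the
pipeline recovers block-correlation structure from realistic spike-count
noise — not that any particular cortical dataset will decode well.

## Numerical choices and degenerate inputs

* Trial windows are half-open [start, end): a spike exactly at the end
  belongs to the next epoch, never to two trials.
* Binning floors the trial duration; fewer than two full bins is an error.
* Zero-variance neurons yield the undefined-correlation sentinel (`NA`
  from `pearsonWeight()`), mapped to weight 0 by `buildNetwork()`.
* A network with no positive edge cannot be partitioned (degenerate-network
  error); a network where *some* nodes have no edges partitions the rest
  and flags those nodes as outliers.
* `modularityQ()` of the single-community partition is 0 by construction;
  `bestPartition()` snaps |Q| < 1e-12 to 0 so exact cancellation does not
  leak floating-point dust.
* Spike and trial files are written with 17 significant digits, so
  write-then-read round-trips values exactly.

## Problem sizes

The test suite and the acceptance script run entirely on simulated data at
desk scale, chosen so the full suite completes in well under a minute of
compute per stage: null sessions of 100 trials x 10 neurons (20 seeds),
structured sessions of 80 trials x 12 neurons (10 seeds), an effect-size
sweep over gains {0, 1, 2, 4} (5 seeds each), exhaustive-oracle checks on
graphs of at most 8 nodes (all 4140 partitions) and similarity matrices of
at most 12 trials (all 2047 bipartitions). Larger problems only change the
runtime: every algorithm is polynomial in neurons and trials, with the
k x k eigendecompositions (k = number of trials) dominating.

## Known limitations

* Pearson correlation on 1-s bins is a linear, timescale-committed
  connectivity measure; binless or nonlinear couplings are out of scope.
* Modularity maximization inherits the resolution limit; very small
  circuit groups in large networks may be merged.
* The dendrogram-cut search can miss the global Q-optimum on graphs whose
  best partition is not nested in any linkage hierarchy.
* Only two-way clustering and two-class decoding are implemented; the
  behavioral designs targeted here have exactly two trial types.
* With 10 bins per trial the per-pair correlation estimates are noisy;
  the pipeline compensates by pooling over all neuron pairs, but very
  short trials (few bins) will degrade every downstream stage.
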