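---
title: "Graph convolutional beat classification for annotated single-lead ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph convolutional beat classification for annotated single-lead ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgraphnet)
```

## The problem

A 10-second single-lead ECG strip contains a variable number of heartbeats,
and each beat must be classified as normal (N), supraventricular ectopic (S)
or ventricular ectopic (V). Fixed-input models (CNNs, LSTMs) struggle with
the variable length; whole-graph pooling discards the beat-level resolution
that arrhythmia detection needs. `ecgraphnet` represents each annotated
P/QRS/T segment as a graph node and classifies *every* beat in one forward
pass, for any beat count, with a graph convolutional network (GCN).

The package assumes beats are already delineated: each beat carries a class
label and 0-based half-open sample-index ranges for its P, QRS and T
segments (a V beat may lack a P annotation). Segment *detection* is out of
scope.

## Graph representation

**Segment-level graph.** The graph over one record has one node per
annotated segment, ordered chronologically. Node features (d = 22 under the
defaults) are

* one-hot segment type (3),
* segment width in seconds (1),
* a 16-dimensional autoencoder embedding of the segment waveform,
* the time gaps to the previous and to the next node in seconds (2; a
  boundary node uses 0 for its missing side).

Edges are: self-loops with weight 1; chronologically adjacent pairs; and
QRS-QRS pairs within a window of 5 (each QRS connects to up to 2 preceding
and 2 following QRS complexes). Alternative same-type edge schemes (P-P,
both, none) are available behind `graph_config(edges = ...)` to reproduce
the representation ablation axis. Every non-self edge is weighted by a
logistic function of the time gap,

$$w(\Delta t) = \frac{1}{1 + e^{\alpha (\Delta t - \delta_0)}},$$

so segments closer in time get weights nearer 1. Defaults are
$\alpha = 10\,\mathrm{s}^{-1}$, $\delta_0 = 0.3$ s, chosen so that typical
intra-beat gaps (tens of milliseconds) map near 1 and gaps beyond a beat
map near 0; the monotone-decreasing contract is enforced. Adjacent-pair
gaps are measured offset-to-next-onset, QRS-QRS gaps onset-to-onset
(matching the definition of the distance features).

**Beat-level graph.** A second graph has one node per QRS complex and edges
only between consecutive beats, weighted from the RR interval. RR intervals
live on a different time scale (roughly 0.4-1.5 s) than inter-segment gaps,
so the beat-level logistic uses its own parameters
($\alpha_\mathrm{qrs} = 4\,\mathrm{s}^{-1}$,
$\delta_{0,\mathrm{qrs}} = 1.0$ s, the midpoint at a typical resting RR);
reusing the segment-scale midpoint would push every RR edge weight to
nearly zero and the beat-level graph would carry no rhythm information.
A raw-RR mode (`qrs_edge_mode = "raw"`) is available.

## QRS-centered weighted average pooling

Beat-level features are obtained from node features by a weighted average
centered on each QRS node $n$:

$$\mathrm{pool}(f_n) = \frac{1}{1+k+j} \sum_{i=-k}^{j} (1 - c\,|i|)\, f_{n+i},$$

where $k$ and $j$ are the node-position offsets to the nearest preceding
and following QRS nodes (truncated at the graph boundary to the available
nodes). The window therefore reaches exactly to the neighbouring QRS nodes
— the printed limits include them — and a `pool_exclusive` switch restricts
it to the strictly interior P/T nodes instead. Weights decay linearly with
distance from the central QRS node; with $c \ge 0$ they are floored at 0
when $1 - c|i| < 0$, while the normaliser $1/(1+k+j)$ is kept as written
(this is a weighted average with a fixed normaliser, not a renormalised
mean). The default is $c = 0.1$.

A worked example: $c = 0.1$, $k = j = 2$, scalar features $(1,2,3,4,5)$
centered on the 3: $(0.8 \cdot 1 + 0.9 \cdot 2 + 1 \cdot 3 + 0.9 \cdot 4 +
0.8 \cdot 5)/5 = 2.64$.

## Segment embeddings

Each segment type gets its own autoencoder (`AE_P`, `AE_QRS`, `AE_T`): a
fully connected 64-32-16-32-64 stack trained by Adam on the mean squared
reconstruction error. Inputs are linearly resampled to 64 points and
min-max normalised per segment (a constant segment maps to all 0.5); the
16-dimensional latent code passes through a logistic squashing so every
coordinate lies strictly in (0, 1). The sizes follow from the feature
budget: one-hot(3) + width(1) + embedding(16) + distances(2) = 22. In every
cross-validation fold the autoencoders are fit on training-fold segments
only and then frozen; held-out segments are embedded with the frozen
parameters (asserted in the pipeline).

## Architectures

The graph convolution layer is the standard symmetrically normalised form
$H' = \mathrm{ReLU}(\mathrm{BN}(\hat A H W))$ with
$\hat A = D^{-1/2} A D^{-1/2}$ and $D$ the weighted degree (self-loops keep
every degree positive). Batch normalisation uses batch-of-graphs statistics
during training and running averages at inference — per-graph normalisation
would break single-graph prediction. Three nested architectures share this
vocabulary:

* **PQRST-Net** — GC blocks on the segment graph, QRS-centered pooling,
  then a fully connected prediction block (FC-BN-ReLU-FC-softmax).
* **PQRST-QRS-Net** — additionally routes the pooled beat features through
  GC blocks on the beat-level RR graph.
* **ECG-GraphNet** — additionally concatenates a skip path carrying the
  pooled segment-level features with the beat-level output ahead of the
  prediction block (additive fusion is available behind
  `graphnet_config(skip = "add")`).

Default widths are 2 GC blocks of 64 channels per block group and a hidden
FC width of 32; all sizes are configurable and grid-searchable
(`grid_search()`). Setting `ch_qrs = integer(0)` with `skip = "none"`
collapses ECG-GraphNet structurally onto PQRST-Net, which the test suite
uses as a regression check. The output layer is a 3-way softmax per beat;
argmax ties are broken by the fixed class order N < S < V.

Training minimises per-beat cross-entropy with Adam and early stopping on
validation loss. Non-improving epochs are not counted against the patience
before `min_epochs` (default 15): without this warmup floor an occasional
fold stops inside the initial majority-class plateau, before the minority
classes have been learned at all. Batches of whole graphs are fused into
one block-diagonal sparse system, so training cost scales with total node
count, not graph count.

## Synthetic data generator

The clinical dataset this method was designed for is private, so the
package ships a generator whose defaults emulate its statistical structure:
10-second records at 250 Hz (the device rate is unpublished; configurable),
a 75.0/15.2/10.4 N/S/V beat mixture, per-patient child seeds derived
splitmix-style from one master seed, and class-dependent morphology —
V beats carry a QRS widened by a factor 1.8, a 1.2-fold amplitude scale and
(with probability `p_noP = 1`, configurable) no P annotation; S beats
shorten their preceding RR interval by 35%. Waveforms are sums of Gaussian
bumps (P, T) and a biphasic difference-of-Gaussians (QRS) plus Gaussian
noise; annotations mark exactly where templates were placed. Records end at
the last complete beat inside 10 s; partial beats are never annotated.

What the generator does *not* emulate: real delineation error, baseline
wander, electrode artefacts, morphology drift within a patient, or the
within-class morphological diversity of real ectopy. Passing the end-to-end
tests therefore demonstrates that the pipeline learns the encoded
class-conditional contrasts under interpatient validation — not clinical
performance.

Two named regimes are used by the tests and the acceptance script:

* the **default regime** above, and
* an **easy regime** with strengthened contrasts
  (`v_qrs_widen = 2.2`, `s_prematurity = 0.45`, `noise_sd = 0.01`) under
  which the classes are cleanly separable, used for learning checks that
  must converge quickly on one CPU.

Problem sizes were likewise fixed once: 40 patients × 7 records
(≈2800 beats) for cross-validation checks, 20 training + 8 test patients
for the scalability protocol, channels halved to 32 and autoencoder
training shortened to 60 epochs. These sizes are the package's desk-scale
study conditions; headline numbers from the private 328-patient dataset are
not reproducible and are not targeted.

## Augmentation

Minority-class rebalancing operates purely on graphs ("without signal
distortion"): new graphs are beat-window subgraphs extracted around
randomly chosen minority beats, re-indexed, with adjacency and distance
features rebuilt by the construction rules, then duplicated with
multiplicative Gaussian jitter (sd 5%) on the width and distance features
only — one-hot and embedding coordinates encode segment identity and
morphology and are left untouched. Because the reference algorithm is
unpublished, the package makes one further design choice: an extracted
window is clipped to the run of consecutive minority beats containing the
chosen centre (at most `w = 8` beats), so augmented graphs contain only S/V
beats and the N beat count never increases; a single isolated minority beat
yields a single-beat graph. Generation repeats until realised proportions
are within `tol` (default 2 pp) of the targets or a cap is reached, and is
applied to training folds only.

## Evaluation protocols

Metrics are confusion-matrix based: per-class Sn, PPV, F1; overall
accuracy; Macro F1 (unweighted mean of class F1s, with classes absent from
the labels dropped from the mean by default — a documented, switchable
convention); exact-match accuracy over graphs; and the cross-validation
error range reported as (max − min)/2 across folds. An `exclude_ends`
switch drops the first and last beat of every graph before counting,
because end nodes have systematically lower connectivity.

Cross-validation is always interpatient: folds partition patients, and
patient disjointness between any training and validation/test side is
asserted at run time.

The scalability protocol re-splits the data by rule: patients owning at
least one 8-beat record with ≥ 1 N beat and ≥ 4 consecutive S or V beats
become test patients; the remaining patients supply an 8-beat training set.
Five fold models are trained within the training set, and the Pattern
(qualifying 8-beat), Size (≥ 9 beats) and Control (8-beat, non-qualifying)
test sets are evaluated by averaging the five members' softmax outputs
(soft voting) — with no architectural reconfiguration, since every
component is size-agnostic.

## Numerical and design notes

* Degenerate inputs: a record with no beats, a graph with no QRS node, and
  an empty training set are errors; a single-beat graph is legal everywhere
  (its beat-level graph is one self-loop).
* Determinism: every stochastic step takes a seed; child seeds are derived
  with integer arithmetic kept exact in doubles. Identical (config, seed)
  pairs give identical datasets, embeddings, parameters and predictions.
* Features are expressed in seconds, never samples, so graphs are invariant
  to the sampling rate and to time translation of the record.
* Where a beat straddles a 10-second window boundary, it is assigned to the
  window containing its QRS onset (the reference handling is unstated; this
  is the package's convention).
* Grid-search ties are broken by smaller parameter count, then grid order.
* The fitted model object is a plain R list; `saveRDS()`/`readRDS()` are
  the supported checkpoint mechanism, and autoencoders additionally
  round-trip through portable JSON (`write_ae_model()`).

## Known limitations

* The autoencoder depth, latent size, the exact edge-weight
  parameterisation, the reference augmentation algorithm and the original
  grid-search space are unpublished; the package's choices are declared
  here and in the function documentation, and the ablation axes are exposed
  as configuration switches rather than fixed.
* At desk scale, with cleanly separable synthetic contrasts, the three
  architectures perform within noise of each other; the architecture
  ordering reported on the private clinical data reflects ambiguity real
  data has and this generator largely lacks.
* No bundle-branch-block morphologies, no multi-lead support, no segment
  delineation.

## A minimal session

```{r example, eval = FALSE}
ds <- generate_dataset(n_patients = 12, records_per_patient = 3, seed = 1)
aes <- fit_segment_embeddings(ds, seed = 2)
graphs <- build_graphs(ds, aes)

cv <- cross_validate(ds, k = 3, cfg = graphnet_config(), seed = 3)
print(cv)

fit <- graphnet_fit(graphs[1:30], val = graphs[31:36], seed = 4)
predict(fit, graphs[[36]], type = "class")
```
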