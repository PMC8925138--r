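---
title: "Predicting binned inter-residue geometries from MSA embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting binned inter-residue geometries from MSA embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msageom)
```

## The problem and the model

A protein's multiple sequence alignment (MSA) carries coevolutionary
signal: residue pairs that are close in the folded structure tend to
mutate in a correlated way across homologs. Modern protein language
models trained on alignments expose this signal in two forms that this
package consumes: per-token feature vectors (an $r \times c \times 768$
tensor over $r$ aligned sequences and $c$ columns) and *row-attention
maps* — one $c \times c$ attention matrix per head per layer (12 layers
$\times$ 12 heads = 144 maps). `msageom` turns these into per-pair
predictions of four inter-residue geometries in the trRosetta
parameterization:

* $d$ — the C$\beta$–C$\beta$ distance (symmetric),
* $\omega$ — the C$\alpha_i$–C$\beta_i$–C$\beta_j$–C$\alpha_j$ dihedral
  (symmetric),
* $\theta$ — the N$_i$–C$\alpha_i$–C$\beta_i$–C$\beta_j$ dihedral
  (directional), and
* $\varphi$ — the C$\alpha_i$–C$\beta_i$–C$\beta_j$ planar angle
  (directional).

Each geometry is discretized and predicted as a classification target:
37 bins for $d$ (bin 0 is the no-contact class for pairs at
$d \ge 20$ Å, bins 1–36 tile $[2, 20)$ Å in 0.5 Å steps), 25 bins for
$\theta$ and $\omega$ (15° steps over $(-180°, 180°]$), and 13 bins for
$\varphi$ (15° steps over $[0°, 180°]$). Whenever the distance label is
the no-contact class, all four labels are the no-contact class: angular
geometry between far-apart residues is neither learnable nor useful
downstream.

The network is deliberately small. Query-row features are reduced from
768 to 128 dimensions by a position-wise MLP (768→384→192→128, ReLU
between layers, none after the last), outer-concatenated into a
$c \times c \times 256$ block, and joined with the 144 symmetrized
attention maps ($M + M^\top$, layer-major order) to form the
$c \times c \times 400$ network input. Three 1×1 convolutions (256, 128,
64 kernels, each followed by instance normalization and ReLU) reduce the
depth; a trunk of 28 pre-activation residual blocks (two 3×3
convolutions of 64 kernels each, dilation cycling 1, 2, 4 per block)
propagates pairwise context; four independent 1×1 heads emit the logits
(25/13/25/37 channels).

## Embedders are plugins; the stub defines the contract

The pretrained language model itself is external and frozen: the
package defines only its I/O contract (feature and attention shapes,
row-stochastic attention, finiteness) and validates every embedder
against it. The shipped `"stub"` embedder honours the contract with
hash-derived pseudo-random values: features are a fixed seeded
projection of one-hot tokens, attentions a per-row softmax of
hash-derived scores. All stub randomness comes from integer
multiplicative hashing in double precision, not from the platform RNG,
so outputs are bitwise identical everywhere. The stub is
content-sensitive but carries *no* coevolutionary information — passing
tests with it demonstrates mechanical correctness of the pipeline,
never predictive accuracy on real proteins. A site holding the real
model can register an adapter under `"msa-transformer"`; the adapter
must strip any model-side begin-of-sequence column and remap the
vocabulary, and is validated by the same contract checks.

## MSA subsampling

Three subsamplers are provided. Training uses uniform random selection
of $\min(r, \max(16, \lfloor 2^{14}/c \rfloor))$ rows (query always
kept first): the token budget caps memory for long proteins and acts as
data augmentation across epochs. Inference uses greedy *diversity
minimization*: starting from the query, repeatedly add the row with the
lowest mean hamming fraction to the rows already selected, up to 256
rows; diversity *maximization* (greedy max–min) is included for
ablation. Two readings of "lowest average hamming distance" are
possible — distance to the query only, or to the growing selected set.
We implement the accretive reading (distance to the selected set) since
selection proceeds by adding one sequence at a time; ties break on the
lowest original row index, making all subsamplers deterministic. The
hamming fraction treats the gap character as an ordinary symbol.
Likewise, the training-time row count could be read as itself random
between 16 and $2^{14}/c$; we read the bounds as a deterministic clamp
and leave randomness to row choice only.

## Training

The loss is an equal-weight sum of categorical cross-entropies over the
four objectives, each averaged over off-diagonal pairs; no-contact
pairs are ordinary class-0 targets, not masked. Optimization uses
Rectified Adam (lr $10^{-3}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$; the
rectified adaptive step is used once the variance estimate becomes
tractable, with the unadapted momentum update before that, following
the reference implementation's threshold $\rho_t > 5$). Because
proteins have different lengths, a "batch" of 16 is assembled by
gradient accumulation over 16 single-example micro-steps; with
instance (not batch) normalization this is mathematically identical to
a padded batch, up to floating-point summation order. Proteins longer
than 1023 residues are skipped. Since no deep-learning framework is
involved, all forward/backward passes are explicit matrix algebra:
3×3 dilated convolutions are im2col gathers followed by one BLAS
multiplication, and every layer has a hand-derived backward pass that
the test suite verifies against central finite differences.

Initialization is seeded He-style for all weights; instance-norm
scales start at 1, shifts and biases at 0. No learning-rate schedule,
weight decay or gradient clipping is applied by default. Network
outputs for $d$ and $\omega$ — symmetric pair functions — are averaged
with their position-transpose when converting logits to posteriors;
$\theta$ and $\varphi$ are directional and left asymmetric.

## Ground-truth featurization

Backbone coordinates are read from single-chain PDB files (first model;
alternate locations resolved by highest occupancy, then altloc id;
residues missing N/CA/C dropped with a warning). Glycine — or any
residue without a deposited C$\beta$ — receives a virtual C$\beta$
built from N, C$\alpha$, C with the fixed trRosetta coefficients on the
unnormalized frame vectors. Dihedrals follow the IUPAC sign convention
(trans = 180°); the 180° value wraps into the topmost bin so that the
label set is exactly 24 angular classes. Distances below 2 Å (steric
clashes in deposited coordinates) clamp into bin 1 with a warning
rather than failing. Degenerate geometry (coincident atoms) flags the
pair invalid, which discretization maps to the no-contact class.

## Evaluation

Contact probability is the summed posterior mass of distance bins lying
fully below 8 Å (bins covering $[2, 8)$), symmetrized and
diagonal-zeroed; truth is C$\beta$–C$\beta$ $< 8$ Å (strict), the CASP
convention. Top $L/k$ precision ranks eligible pairs
($j - i \ge$ 24 for the long-range class) by probability with
deterministic lexicographic tie-breaks and reports the true fraction of
the top $\max(1, \lfloor L/k \rfloor)$. When no pair satisfies the
separation constraint the metric is reported as undefined (`NA` with a
reason), never as 0. The per-objective Pearson correlation between
maximum-probability bin indices and ground-truth indices excludes
no-contact pairs, whose class-0 index is categorical rather than
ordinal — including them would reward a constant "far" prediction.

## Synthetic data: what it does and does not emulate

The MSA generator mutates a random query uniformly over the 19
alternative residues per column (rate `mutation_rate`) and adds gaps
independently (rate `gap_rate`), giving an expected hamming fraction of
`gap_rate + (1 - gap_rate) * mutation_rate` to the query — controlled
divergence for subsampler tests, with *no* covariation between columns.
The backbone generator builds ideal-geometry chains from torsion
profiles (NeRF chain extension with textbook bond lengths and angles):
`ideal_helix` uses $\varphi/\psi = -57°/-47°$ (the standard
$\alpha$-helix, ~1.5 Å rise per residue); `helix_turn_helix` joins two
helices through a fixed four-residue turn, calibrated once so that the
two arms pack with C$\beta$ contacts near 5 Å at sequence separations
beyond 24 for lengths 36–64, giving every metric a non-empty long-range
truth set; `random_chain` draws uniform torsions for oracle tests.
Because synthetic MSAs carry no structural signal, end-to-end tests
demonstrate plumbing, determinism and overfitting capacity — not
biological prediction accuracy. Restraint files store the four
posterior arrays as float32 in a small gzip container under the
downstream key names (`dist`, `omega`, `theta`, `phi`).

## Problem sizes used by the test and acceptance runs

The shipped checks run at desk scale, chosen to exercise every code
path: contract checks on 8×32 MSAs; geometry oracles on 100 random
8-residue chains (tolerance $10^{-6}$ Å / $10^{-4}$°); binning oracles
on a 100×100 grid of random values per objective; ranking oracles on
1000 random 30-residue instances; and a training-sanity run of 200
accumulated micro-steps on two 32-residue synthetic proteins
(accumulation boundary 2, i.e. one optimizer update per pass over the
pair), which must reduce the training loss below 25% of its initial
value. A full-scale reproduction of the published training — a 100M
parameter embedder, ~16k structures, days of GPU time — is out of scope
by design.

## Worked example

```{r example, eval = FALSE}
# synthetic two-protein dataset
ds <- lapply(c(11L, 12L), function(s) {
  bb <- synthetic_backbone(32L, "helix_turn_helix", seed = s)
  labels <- discretize_geometries(pair_geometries(bb))
  msa <- synthetic_msa(32L, 16L, mutation_rate = 0.2, seed = s,
                       query = bb$sequence)
  list(msa = msa, labels = labels)
})
model <- train_geometry_model(
  ds, net_config(seed = 1L),
  train_config(effective_batch = 2L, steps = 40L, seed = 1L))
print(model)
post <- predict_geometry(ds[[1L]]$msa, model)
cm <- contact_probability(post)
```

## Known limitations

* The stub embedder cannot support accuracy claims; only a registered
  pretrained adapter can.
* Training is CPU-bound R: practical for fixtures and small corpora,
  not for thousands of structures.
* Only single-chain, single-model PDB inputs are supported; mmCIF is
  not parsed.
* The downstream structure-realization stage (restraint-guided
  folding) is external; this package stops at the restraint hand-off.
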