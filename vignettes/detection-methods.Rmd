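---
title: "Voxel-based detection of ligand-binding sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based detection of ligand-binding sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(voxsite)
```

## The problem

Druggable binding sites are concave regions on a protein surface where a
small molecule can bind. `voxsite` treats their detection as a 3D object
detection problem: the protein structure becomes a multi-channel density
image, a convolutional network scores coarse spatial cells for the
presence of a site center, and standard detection machinery (greedy
non-maximum suppression, precision-recall scoring) turns raw cell outputs
into ranked site predictions. Applied frame by frame to a conformational
ensemble, the same machinery yields a spatiotemporal map of transient
pockets.

## From structure to image

Each protein heavy atom contributes a truncated Gaussian density
$\rho(r) = e^{-r^2/2}$ for $r \le r_\mathrm{cutoff}$ (4 Å by default, and
exactly zero beyond; atoms at the cutoff still count) to every voxel
center within the cutoff. Hydrogens, waters, and monoatomic ions are
stripped first; alternate locations keep the highest-occupancy copy (ties
broken by altloc letter). Voxel centers sit at
$\mathrm{origin} + (i + 0.5)\,v_\mathrm{size}$ with 0-based indices.

Channels are pluggable. The 11-channel default comprises four element
channels (C, N, O, S), six property channels assigned from a
residue/atom-name table for the 20 standard amino acids (hydrophobic,
aromatic, H-bond donor, H-bond acceptor, formally positive, formally
negative), and a total-occupancy channel; this channel inventory is one
defensible reading of common protein-image featurizations, and the table
is deliberately replaceable because the literature does not pin a unique
definition. Atoms with unrecognized elements land in the occupancy
channel only, with a warning. A 4-channel `minimal` scheme (C, N, O,
occupancy) serves desk-scale experiments.

Structures wider than one 64-voxel tile are covered by overlapping tiles
advancing by `stride` voxels (48 by default). Per axis, tiles start at
the bounding-box minimum of the protein atoms and advance until the box
maximum falls inside the last tile; no padding is applied, because atoms
outside a tile still contribute density within the cutoff of its
boundary, which also keeps the tile count equal to the smallest $k$ with
$\mathrm{cube} + \mathrm{stride}\,(k-1) \ge \mathrm{extent}$. Tiles with
mean density below $10^{-4}$ are treated as empty and skipped.

## The detection network

The full-profile network maps a $64^3 \times 11$ tile to an
$8\times8\times8\times4$ tensor through ten 3D convolutional layers (32,
32, 32, 32, 32, 64, 64, 64, 128, 4 filters; $3^3$ kernels), with
stride-2 max pooling after layers 2, 5, and 8, batch-norm + ReLU on all
layers but the last, and a sigmoid on the four outputs. Each output cell
covers $8^3$ voxels and carries a probability score $\hat s$ plus the
fractional in-cell coordinates $(\hat x, \hat y, \hat z)$ of the
predicted center, decoded to Cartesian space as
$\hat X = c_\mathrm{size} v_\mathrm{size} (i_\mathrm{cell} + \hat x) + O_x$.
Target encoding is the exact inverse; a center on a cell boundary belongs
to the lower-index cell, and when two centers share a cell (which four
scalars cannot express) the larger ligand wins, ties to the lower residue
number.

Training minimizes, per tile,
$$\mathcal{L} = \sum_i (s_i - \hat s_i)^2
  + \lambda \sum_i s_i \left[ (x_i-\hat x_i)^2 + (y_i-\hat y_i)^2 + (z_i-\hat z_i)^2 \right]
  + \gamma L_2,$$
with $\lambda = 5$ and $\gamma = 10^{-5}$ by default. The coordinate term
is gated by the binary target score, so only true-site cells constrain
the coordinate head; the $L_2$ term covers convolution weights only (not
batch-norm parameters), and no class weighting is applied to the heavily
negative score term. $\lambda = 5$ follows the loss definition; a
tuning-table reading supports $\lambda = 10$, so the coefficient is
configurable and both values are legitimate. Optimization is Adam
(default moments), minibatches of 16 tiles, and a learning rate decaying
exponentially from $10^{-3}$ to $10^{-5}$ across the epoch budget (400
epochs at full scale). Because the architecture is not rotationally
invariant, training supports per-epoch random-orientation augmentation in
two forms: full re-imaging of every structure under a fresh random SO(3)
rotation, and a grid-space variant that applies one of the 24 proper
rotations of the cube directly to each stored tile and its target tensor
-- exact on the voxel lattice, no re-voxelization, and therefore cheap
enough to leave on by default in the desk-scale experiment.

The network and its gradients are implemented directly in R: the $3^3$
same-padded convolution is 27 shifted gathers feeding one BLAS matrix
multiply per layer, with the backward pass scattering through the same
index sets. A finite-difference check in the test suite pins the
analytic gradients. Weights are He-initialized; biases start at zero.
The `toy_model_config()` profile (16-voxel tiles of 2 Å voxels, minimal
channels, filters 8/16/16/4, one pooling) is the desk-scale study
condition: coarser voxels are the documented speed-for-accuracy trade,
and a 32 Å tile holds one synthetic globule.

## Post-processing

Raw predictions from all tiles are pooled in one Cartesian frame and
pruned by greedy non-maximum suppression: drop scores below
$s_\mathrm{threshold}$, repeatedly seed on the best remaining score and
absorb everything within $d_\mathrm{threshold} = 8$ Å, keep the top
$N_\mathrm{top}$ seeds. Score ties break on lower x, then y, then z, so
the result is order-independent. Overlapping-tile duplicates are handled
by this same global pass. The conventions mirror their published use:
$s_\mathrm{threshold} = 0.1$ with $N_\mathrm{top} = 5$ during training,
$s_\mathrm{threshold} = 0.01$ for benchmarking (so average precision sees
every prediction), and a 4 Å suppression radius when nearby orthosteric
and allosteric sites must stay distinct. Each kept center is annotated
with all residues having a heavy atom within 6 Å (inclusive).

Rotation-replica averaging damps the rotational variance of the network:
the structure is rotated about its centroid around the 10 axes through
opposite facet-centroid pairs of a regular icosahedron, by $\pi/3,
2\pi/3, \pi, 4\pi/3, 5\pi/3$ — 50 replicas. Predictions are mapped back
by the inverse rotations, pooled, grouped by the same greedy rule, and
each group is replaced by its mean center and the sum of member scores
divided by the replica count. Whether pooling should precede or follow
per-replica suppression is not settled by the published description;
grouping the pooled raw predictions once is the single consistent
reading implemented here, and dividing by all replicas (not just
contributors) makes a site seen in 1 of 50 orientations fifty-fold
weaker — exactly the artifact-damping the protocol is for.

## Ensembles and cluster scores

For a pre-aligned ensemble (frames are assumed superposed upstream, as
MD pipelines export them), per-frame post-NMS predictions form a cloud
that is clustered by one of three algorithms: mean shift (flat kernel,
bandwidth defaulting to $d_\mathrm{threshold}$), DBSCAN (eps
$d_\mathrm{threshold}/2$, min 5 points; noise points are kept as flagged
singletons rather than discarded, since the published protocol does not
say which was done), or average-linkage agglomerative clustering, on
Cartesian centers or — agglomerative only — on residue sets under
$1 - \mathrm{Jaccard}$ with a 0.5 cut. DBSCAN and mean shift are small
textbook algorithms implemented in the package and verified against
planted well-separated fixtures.

Each cluster gets two scores. Score 1 sums the cluster's maximal member
score in each frame (0 where absent) and divides by the total frame
count, so a pocket open in a fraction $w$ of frames at score $s$ scores
$\approx ws$. Score 2 is the wordier one: in each frame where the
cluster has members scoring above 0.1, sum those member scores; average
the sums over the frames that contributed. "Mean sum over the
corresponding frames" is read here as averaging only over contributing
frames — the alternative (dividing by all frames) would duplicate
score 1's normalization and make the two scores near-redundant.

## Evaluation protocol

A prediction is correct for a site if its center lies within 4 Å of the
site center (training definition) or within 4 Å of the nearest ligand
heavy atom (cross-method definition). The top-scored correct prediction
of each site is its single true positive; matching is one-to-one (a
prediction cannot claim two sites; greedy by score, then distance —
one-to-one is a choice made here to preserve the counting identities
$|TP|+|FN| = $ sites and $|TP|+|FP| = $ predictions). Everything else is
a false positive, unmatched sites are false negatives, precision and
recall are the exact ratios with $0/0 \equiv 0$, and average precision
is the interpolation-free step sum over the ranked list — equal to the
integral of precision over recall, verified in the tests against an
exhaustive threshold-sweep oracle. Top-N evaluation truncates each
structure's ranked predictions to its own site count before pooling.
Per-family breakdowns take a user-supplied family mapping and report AP
for families with at least 20 structures.

## Training-corpus curation and splitting

Complexes enter a training corpus if the resolution is better than
3.0 Å, there are fewer than four chains, and after dropping chains
shorter than 50 residues something remains; "long" structures whose
extent along any principal component of the heavy-atom coordinates
exceeds 250 Å are rejected. Ligands are non-excluded hetero groups with
more than 14 heavy atoms (the bundled exclusion list names common
cryoprotectants, detergents, and buffers and is user-extensible, the
published supplement not being reproducible from the main text); a site
is kept when at least 20 protein heavy atoms lie within 4 Å of the
ligand, and its center is the center of mass of the site residues. A
generic coordinate-displacement counter supports the discard-if-refinement-
moved-3-site-atoms rule for users who refine structures externally.

Train/validation splitting consumes an externally computed
structural-similarity matrix (e.g. TM-scores). Chains are grouped so no
two chains in different groups have similarity $\ge 0.5$; only
single-linkage agglomeration (connected components of the
similarity-$\ge$-threshold graph) guarantees that property, so that is
the linkage used, and the soundness is asserted exhaustively in the
tests. Whole groups then go to validation greedily until its target
fraction is reached; a group too large to leave the training side stays
there with a warning.

## Synthetic fixtures

The generator builds what the pipeline needs and nothing more: a compact
globule of pseudo-residues (4 heavy atoms each: N, CA, CB, O, with
realistic local offsets and jitter), one or more pockets carved as
empty spheres at about half the globule radius, a 16-residue lining
shell ringing each pocket so the planted 16-atom ligand always makes
20+ protein contacts, and ground truth computed by the same curation
rules users run. Trajectories perturb the base structure with bounded
per-atom displacements and can open the pocket only inside a frame
window (outside it the cavity is plugged), giving clustering a known
time-varying signal. Defaults (60 residues, 22 Å globule, 4.5 Å pocket,
16-atom ligand, 0.3 Å jitter) were chosen once as a plausible miniature
of a small single-domain protein and are not tuned per experiment; all
randomness flows from a single explicit seed, so fixtures are
bit-reproducible.

What passing on fixtures does and does not show: the geometry, encoding,
suppression, scoring, and learning machinery demonstrably work
end-to-end, and a detector trained on fixtures finds planted pockets it
has never seen. Fixtures have no real side-chain chemistry, no
crystallographic noise, and far less shape diversity than the PDB, so
fixture performance says nothing quantitative about performance on real
proteins — reproducing published benchmark numbers would require the
external datasets and published weights, which are out of scope.

## Numerical choices and limitations

* Distance comparisons at thresholds are inclusive (`<=`) everywhere a
  boundary example is specified: density cutoff, residue assignment,
  matching distance.
* Degenerate inputs fail fast with messages: empty structures after
  stripping, empty ensembles, empty training sets, pocket geometry that
  cannot fit its globule.
* The desk-scale experiment exercised by the acceptance script trains
  the toy profile on 400 generated structures (30 epochs, minibatches of
  8, learning rate 1e-3 decaying to 5e-4, cube-rotation augmentation)
  and evaluates on 50 held-out ones; problem sizes were fixed once
  alongside the toy profile as the package's study condition for a
  single-CPU workstation. Smaller corpora overfit the toy network's
  score head, which is expected behavior for a detector with this
  capacity, not a defect of the loss.
* The full 10-layer profile is constructed and shape-verified in the
  tests; training it to published accuracy needs GPU-scale resources
  and the curated PDB corpus, neither of which this package ships.
* Batch-norm uses running statistics at inference, so predictions are
  deterministic; training is deterministic given a seed and a BLAS.
* The final-layer biases are initialized at zero: with one positive cell
  in 512, a pessimistic (negative) score-bias initialization saturates
  the sigmoid and starves the positive cell of gradient, so the neutral
  start is the stable choice under this class imbalance.
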