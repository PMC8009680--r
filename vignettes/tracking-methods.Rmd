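---
title: "Tracking nuclei in deforming 3D tissue: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking nuclei in deforming 3D tissue: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(voltrackr)
```

voltrackr follows individual cell nuclei through volumetric (3D + time)
fluorescence recordings of deforming tissue — a crawling nematode's brain, a
beating heart, a growing tumour spheroid. The pipeline has two halves:
**detection** (find every nucleus in every volume) and **identity
propagation** (decide which detection at time $t$ is which cell from time
$t-1$). This vignette explains the models behind each stage, the parameters
that matter, what the synthetic-scene generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## Detection

### Local contrast normalization

Nuclear marker intensity varies strongly across cells (expression levels,
depth attenuation). `local_contrast_normalize()` equalizes them with a
windowed subtractive–divisive transform,

$$\tilde I(v) \;=\; \frac{I(v) - \mu_w(v)}{\max\{\sigma_w(v),\ \eta\}},$$

where $\mu_w$ and $\sigma_w$ are the mean and standard deviation over a
sliding window centred on voxel $v$ (default $27 \times 27 \times 3$ voxels
in $x, y, z$ — wide in the fine-resolution plane, narrow along the coarse
axis), with symmetric border padding. The floor $\eta$ (`noise_level`, in
raw counts) is the step's single dataset-dependent knob: below it, flat
background is divided by a constant rather than amplified. Choosing $\eta$
*above* the typical within-cell windowed deviation matters: then bright
structure is divided by roughly a constant too, and the cell-to-background
contrast survives normalization (with $\eta$ at the background noise level
the division compresses exactly the structures one wants to keep). Values
of tens to hundreds of counts are typical; the package default is 50.
The transform is invariant to global intensity offsets by construction.
Activity extraction never sees normalized data — it always reads the raw
channels.

### Voxel classification

Detection is phrased as per-voxel classification (cell-like vs background)
behind a common contract: any backend maps a volume to probabilities in
$[0,1]$ of the same shape, is trained on a *single* annotated volume, and
larger volumes are tiled into patches (25% overlap, each voxel taken from
the tile whose centre is nearest; undersized borders reflect-padded).

* `classical_threshold` calibrates an intensity threshold on the annotated
  volume by maximizing the voxelwise F1 score, floored at the midpoint of
  the two class medians — the F1 optimum alone tends to hug the
  background class, and a recording noisier than the training volume
  would then flood the mask; the midpoint keeps a margin. A logistic soft
  transition around the threshold yields the probabilities. On
  well-normalized data this is a strong baseline and is entirely
  CPU-trivial.
* `unet3d_small` is a compact 3D encoder–decoder: two pooling levels
  (pooling restricted to $x$–$y$, because axial resolution is usually a
  factor 3–4 coarser), $3^3$ convolutions with ReLU, skip connections, a
  sigmoid head, binary cross-entropy loss, Adam, and random affine
  augmentation restricted to the $x$–$y$ plane (rotation $\pm 20^\circ$,
  scale 0.9–1.1, shear $\pm 0.1$). Convolutions run as im2col + GEMM
  through BLAS; backpropagation is implemented in the package. It is
  deliberately small enough to train on a CPU in tens of seconds; larger
  encoder–decoder layouts are configuration, not architecture, changes.

### Two-stage seeded watershed

Voxels with probability strictly above 0.5 form the cell-like mask. The
anisotropy-aware Euclidean distance to background (exact separable
transform with physical voxel spacing) is Gaussian-blurred
(`blur_sigma` = 1 voxel by default) and its local maxima become seeds:
plateaus of equal value are merged to the voxel nearest the plateau
centroid, and a greedy pass in descending value enforces a minimum
separation. The separation is keyed to the only size scale available,
`min_cell_size`: the edge of a cube of that many voxels, taken as a
*physical* length and converted to voxels per axis (an isotropic voxel
count would span three times more micrometres axially than laterally on
typical confocal anisotropy and suppress genuinely distinct axial
neighbours).

Watershed then runs twice, reflecting the anisotropy: first within each
$x$–$y$ plane (4-connected priority flood descending the blurred distance
map), then in full 3D (6-connected). Each in-plane region is assigned the
3D label that dominates it, with seed-bearing regions pinned to their own
seed, so the final instances are 3D-consistent but in-plane boundaries come
from the fine-resolution pass. Labels smaller than `min_cell_size` are
removed and the rest renumbered consecutively. The labels partition the
mask; every surviving label contains exactly one seed.

## Identity propagation

### The neighborhood descriptor (61 components)

Each cell centre is described by its 20 nearest neighbours in physical
coordinates: the offset vectors are divided by the mean neighbour distance
$\bar d$, sorted by ascending magnitude (ties broken lexicographically by
$z, y, x$), flattened, and $\bar d$ appended — 61 numbers. Components 1–60
are invariant to translation and to uniform scaling; $\bar d$ retains the
absolute scale. The descriptor survives the bulk motion that defeats
nearest-point assignment, which is the entire point: a whole-tissue
translation changes no offsets.

### The pair-similarity network

A three-layer network scores whether two descriptors (one per volume) name
the same cell: a shared 61→512 encoder per point, a 1024→512 comparison
layer on the concatenated encodings, and a sigmoid unit; batch
normalization precedes each ReLU (the order is a convention choice —
linear → BN → ReLU — the alternative is not meaningfully different at this
depth), and BN statistics are frozen into running averages for inference.
Training minimizes binary cross-entropy with Adam on mini-batches of 128.

Because annotated correspondences across volumes are scarce, training
pairs are *simulated* from one segmented volume: a random near-identity
affine map plus noise,

$$x' = (I + U)\,x + \varepsilon_1 + \varepsilon_2,$$

applied to mean-removed coordinates, with $U_{ij} \sim \mathrm{unif}(\pm
0.05)$, $\varepsilon_1 \sim \mathrm{unif}(\pm 2)$ per point, and
$\varepsilon_2 \sim \mathrm{unif}(\pm 5)$ on a random subset (20 points of
a 175-cell set) imitating gross segmentation errors. Noise half-widths are
in the point set's own coordinate units (micrometres here). Positive pairs
couple a transformed point with its own original; negative pairs couple an
original point with the transformed image of one of its **adjacent**
cells. "Adjacent" is implemented as the `n_adjacent` = 3 nearest
neighbours, sampled uniformly: restricting negatives to the single nearest
neighbour leaves the score of every *other* pairing unconstrained by
training, and we measured the resulting matcher losing to plain
nearest-point assignment; three-neighbour sampling fixes this while
staying within the meaning of "adjacent". Exactly
`positive_fraction` $\times$ `n_pairs` positives are emitted, by
construction. The default composition is 360 pairs per deformed set.

For scoring all $n \times m$ cross-volume pairs the comparison layer's
additive structure is exploited: $W_2 [h_A; h_B] = W_{2a} h_A + W_{2b}
h_B$, so two per-set projections and an outer sum replace materializing
$nm$ concatenated inputs. A test asserts bit-level agreement with the
naive forward pass.

### Greedy initial matching

Scores become a one-to-one matching by repeatedly taking the globally
highest remaining entry and deleting its row and column, stopping below
`min_score` = 0.5; ties resolve to the lowest row then column index. The
result is intentionally partial — unmatched cells are the registration
stage's problem.

### EM refinement with a motion-coherence prior

The matching is refined into a smooth transformation $T(x) = x + \sum_k
c_k \exp(-\|x - a_k\|^2 / 2\beta^2)$ anchored at the moving points, by EM
over a Gaussian mixture: each target point is explained by a component
centred at a transformed moving point (with the initial matching injected
as prior weights, `match_prior_weight` = 0.7 on the matched entry) or by a
uniform outlier component (`outlier_weight` = 0.1). Where the full score
matrix is available, the residual prior mass follows the scores rather
than a uniform distribution, so a greedy mistake's runner-up retains its
standing. The M step solves the $\lambda$-regularized kernel least-squares
system $(\mathrm{diag}(P\mathbf 1) G + \lambda \sigma^2 I)\,C = P B -
\mathrm{diag}(P\mathbf 1) A$; the mixture variance re-estimates from the
weighted residuals each iteration (no annealing schedule — none of the
exposed parameters suggests one). $\beta$ (micrometres) sets the coherence
length over which neighbouring cells must move alike; $\lambda$ trades
data fit against field roughness. Defaults $\beta = 20\,\mu m$, $\lambda =
0.01$, 20 iterations, convergence when the mean displacement update falls
below $10^{-4}$ of the set diameter. With a hard one-to-one prior, zero
outlier mass and a fixed variance, one iteration reduces exactly to kernel
ridge regression of the matched displacements — a test checks this against
a direct solve. For very large movements the initial matching can be
recomputed from the moved points every `rematch_every` iterations.

### Accurate correction and collision handling

Registration predicts; detection corrects. Each cell's first-volume
template region is placed at its predicted centre, and the centre moves to
the probability-weighted centroid of the cell-like voxels (probability
> 0.5) the placed region overlaps, iterating up to `correction_max_iter`
times or until the largest shift drops below `correction_tol` (0.1 µm).
The pull is restricted to the cell's own territory: voxels closer to
another tracked centre than to this one contribute nothing, so two cells
sharing one merged blob keep to their own sides instead of collapsing onto
a common centroid.
The full step to the weighted centroid is taken each iteration — with the
iteration cap this reproduces "correct until convergence" behaviour with
no extra step-size parameter. An alternative target, the overlap-weighted
centres of the detected instance regions (`correction_target =
"region_centers"`), is provided; on the reference synthetic scene it
measured consistently worse than the probability centroid (it snaps
wholesale onto the neighbour when the prediction strays), so the centroid
remains the default. Cells whose placed regions collide are re-separated
by a seeded watershed on the blurred distance map of the union, seeded at
the corrected centres. A cell whose placed region overlaps no cell-like
voxel keeps its predicted position and is flagged (`corrected = FALSE`);
one that leaves the volume is flagged `exited` and frozen.

With `interpolate_z`, correction centroids are evaluated on a z-refined
grid by trilinear interpolation (useful when axial spacing is several
times the lateral spacing).

### Single and ensemble modes; skipped volumes

Single mode predicts volume $t$ from $t-1$. Ensemble mode averages up to
20 predictions from references $[t-d, t-2d, \ldots, t-20d]$, $d = (t-1)
\operatorname{div} 20$ (all predecessors when $t \le 21$), trading compute
for robustness to large per-step movements; exited cells are excluded from
the average. Volumes listed in `skip_volumes` (dropouts, lost frames) are
carried forward unchanged: cells are assumed not to have moved.

### The difficulty metric

Relative movement, $RM = \|\text{step}\| / \text{(distance to the nearest
neighbouring cell at } t)$, measures per-movement difficulty. In the
canonical two-cell, one-dimensional construction, assigning each cell at
the new time to the nearest old cell first fails exactly at $m/D = 0.5$
(`rm_failure_boundary()` sweeps this); movements with $RM \ge 0.5$ are
precisely the ones a nearest-cell tracker cannot survive. `rm_stats()`
tabulates counts beyond 0.5 and 1.0 per cell and in total.

## The synthetic scene generator

`render_scene()` produces the ground-truth world the package validates
against: `n_cells` nuclei (default 150) in a `(16, 192, 192)`-voxel volume
at `(2, 0.5, 0.5)` µm spacing — 96 × 96 × 32 µm, worm-brain-like density
and confocal-like anisotropy. Nuclei are flat-topped blobs
($\exp(-2 (d/r)^4)$, radius $\sim N(2, 0.3^2)$ µm): a marker-filled
nucleus is near-uniform inside with a sharp boundary, unlike a Gaussian
whose dim tails make any fixed annotation boundary unlearnable. Peak
amplitude 500 counts over a 100-count background, with Poisson shot noise
on everything and optional per-volume photobleaching. The activity channel
shares the nuclear geometry with an independent sinusoidal per-cell time
course (period 10–30 volumes), recorded as ground truth.

Per time step, cells ride a smooth random displacement field: white vector
noise on a coarse grid, Gaussian-filtered at
`deformation_coherence_length` (20 µm), sampled at the cell centres,
mean-removed, and rescaled so the median step magnitude equals
`deformation_amplitude`. An elastic pull (`reversion_rate` = 0.15 per
step) draws every cell back toward its reference position, so the tissue
deforms *about* a stable configuration — as a bending worm or a beating
heart does — rather than diffusing apart; this also is the regime in
which averaging predictions from older reference volumes (ensemble mode)
is meaningful. Each displacement component tapers smoothly
(smoothstep over min(8 µm, a third of the usable extent)) to zero at the
walls it points toward — without this, cells clamp against the volume
boundary and acquire incoherent jumps no deforming tissue exhibits.
Residual overlaps after a step are resolved by small pairwise push-aparts.
The default amplitude (2.6 µm) was calibrated once so the default scene's
median truth RM is ≈ 0.3, the regime the tracker is designed for; roughly
16% of movements exceed RM 0.5. `degrade()` supplies the stress variants:
zero-mean-adjusted Poisson noise of specified standard deviation, temporal
subsampling (keep every $k$-th volume), and z sum-binning (photon
conserving, spacing rescaled).

What the generator does **not** emulate — and hence what passing tests do
not establish about real recordings: optical blur and depth-dependent
attenuation; autofluorescence and non-cellular structure; cell division,
death, or entry; whole-body posture changes of a freely moving animal;
inter-plane acquisition jitter (a rigid-alignment preprocessing concern);
and annotation error in the first volume, which here is exact by
construction. The generator provides clean, controllable difficulty — it
is a validation instrument, not a realism benchmark.

## Numerical choices and problem sizes

* All distances, kernels and positions are in micrometres; voxel indices
  convert as $(\text{index} - 1) \times \text{spacing}$ (0-based voxel
  convention in files, 1-based inside R). On-disk track tables use a
  0-based time index (volume #1 is $t = 0$).
* Box and Gaussian filters are separable with symmetric padding; the box
  filter runs in $O(n)$ per line via column-wise cumulative sums.
* The M-step solve falls back to a ridge-jittered system (with a warning)
  if singular. The mixture variance is floored to keep E-step weights
  finite; the kernel Gram matrix is never explicitly inverted.
* Watershed flooding breaks priority ties first-in-first-out, making
  labels deterministic; greedy matching resolves ties toward the lowest
  indices.
* The test suite's end-to-end checks run on a 150-cell, 50-volume default
  scene (the reference recording) plus a 40-cell, 4-volume scene for unit
  tests and a 12-cell volume for the U-Net; the matcher used in the
  acceptance checks trains on 100,000 simulated pairs for 4 epochs. The
  tracking-accuracy statistic is the fraction of correct (cell, volume)
  assignments — a cell counts correct at a volume if it lies inside its
  true region or within half its true nearest-neighbour distance; a
  misassigned cell counts wrong until it re-enters its true region.
  Ordering comparisons between degraded runs allow 0.5% slack, the
  binomial resolution of 7,500 cell-steps.

## Known limitations

* Identities are fixed at volume 1: division, fusion, and cells entering
  the field of view are out of scope by design.
* Single-mode errors persist: once a cell snaps onto a wrong region it
  rarely recovers (ensemble mode mitigates, at 10–20× matching cost).
* The matcher is trained per point-set geometry; it transfers across
  recordings with similar cell densities but not across radically
  different spatial statistics without retraining (cheap: the training
  data are simulated).
* Dense packings where nuclei actually touch stress the seed-separation
  heuristic; `min_cell_size` is the only knob, and very heterogeneous
  cell sizes may need per-dataset adjustment.
* The classifier contract assumes one annotated volume suffices; heavily
  drifting imaging conditions (strong photobleaching, or added noise far
  beyond the training volume's) degrade the threshold backend first and
  steeply — its robustness window under added noise is narrow, and once
  detection thins out, tracking follows. The U-Net backend, seeing
  context, is more robust but not immune.
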