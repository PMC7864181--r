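---
title: "IFCM-MS: model, design choices and numerical details"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IFCM-MS: model, design choices and numerical details}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifcmms)
```

## The problem

Fuzzy C-means (FCM) segments a grayscale image by alternating two
updates: soft memberships $u_{ik}$ of each pixel $k$ to each cluster
$i$ from the distances to the gray centers, and centers $v_i$ as
membership-weighted intensity means. Because each pixel is treated in
isolation, impulse (salt-and-pepper) noise moves individual pixels
across cluster boundaries, which matters in medical applications such
as tumor delineation in FLAIR MRI, where tumors are small, bright
structures.

IFCM-MS augments FCM with three ingredients:

1. **Intuitionistic fuzzy memberships.** Each membership $\mu$ is
   paired with a nonmembership $\nu$ and a hesitation
   $\pi = 1 - \mu - \nu$ produced by a fuzzy-complement generator.
   The working membership becomes $u' \propto u + \pi(u)$,
   re-normalized per pixel, which inflates uncertain assignments near
   tissue boundaries. The intuitionistic fuzzy entropy
   $\sum_i \pi'_i e^{1-\pi'_i}$ (with $\pi'_i$ the mean hesitation of
   cluster $i$) is added to the monitored objective; it does not enter
   the update equations, whose derivation it drops out of.

2. **Membership information transfer.** After each iteration, each
   cluster's membership map is filtered by a guided filter whose
   guidance is the *median-filtered membership map of the previous
   iteration*. The median prefilter suppresses impulse outliers in the
   guidance; the guided filter then smooths the current map within
   regions while preserving membership edges, and couples consecutive
   iterations. The filtered stack is clipped to $[0,1]$ and
   renormalized per pixel.

3. **Similarity measurement.** Distances in the membership update are
   replaced by a similarity $Sim(x_k, c_i) = w_d \cdot w_g \in (0,1]$,
   the product of a distance kernel and a gray kernel with *adaptive*
   per-pixel scales $D$ and $G$ (mean absolute deviations of the
   pixel's dissimilarities across the clusters). Memberships follow
   from constrained minimization of
   $\sum_{i,k} (u'_{ik})^m / S_{ik}^2$:
   $u'_{ik} \propto S_{ik}^{2/(m-1)}$, normalized per pixel.

The loop per iteration is: similarity field → aggregate statistic
$S_{ik}$ → membership update → center update → intuitionistic
correction (`use_ifs`) → membership transfer (`use_transfer`) →
convergence test. The three switches `use_ifs`, `use_transfer`,
`use_similarity` remove one ingredient each, which makes the ablation
chain (baseline kernel, +IFS, +transfer, +similarity) reproducible.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `clusters` | — | number of clusters $c \ge 2$ |
| `m` | 2 | fuzzifier; 2 throughout the study conditions |
| `eta` | `1e-5` | convergence threshold on the max-abs change of consecutive post-transfer membership stacks |
| `max_iter` | 100 | iteration cap; non-convergence is reported, not thrown |
| `generator` | Sugeno, $\lambda = 2$ | fuzzy-complement generator for $\nu$; Yager with $\alpha \in (0,1)$ available |
| `transfer$radius` | 3 | guided-filter box half-width (pixels) |
| `transfer$eps` | 0.01 | guided-filter regularizer on the $[0,1]$ membership scale |
| `transfer$subsample` | 1 | fast-guided-filter ratio; 1 disables subsampling |
| `transfer$median_radius` | 1 | median prefilter half-width (3×3) |
| `similarity$mode` | `"direct"` | `S_ik = Sim` directly, or `"neighborhood"`: membership-weighted 3×3 average of `Sim` |
| `similarity$scale_mode` | `"printed"` | see below |
| `similarity$distance` | `"gray"` | see below |
| `center_power_m` | `TRUE` | weights $u'^m$ (vs $u'$) in the center update |
| `init` | `"centers"` | k-means++-style seeded center initialization |

The guided-filter defaults (`radius` 3, `eps` 0.01) sit at the scale
usual for edge-preserving filtering of probability maps; membership
maps live on $[0,1]$, so `eps` of order $10^{-2}$ smooths within-region
fluctuations while leaving region edges (membership jumps of order 1)
intact. `subsample = 1` because the intended inputs are modest 2-D
slices; the fast path (`subsample` > 1) trades accuracy for speed and
agrees with the exact path to within a few percent on smooth maps.

## Design choices where the formulation is open

Several parts of the method admit more than one reading; the package
fixes defaults and keeps the alternatives as options.

**How the hesitation is generated.** The IFS layer needs a concrete
map $\mu \mapsto \nu$. The default is the Sugeno complement
$\nu = (1-\mu)/(1+\lambda\mu)$ with $\lambda = 2$, which guarantees
$\pi \ge 0$ for every $\mu \in [0,1]$. The Yager complement
$(1-\mu^\alpha)^{1/\alpha}$ is accepted only for $\alpha \in (0,1)$;
$\alpha \ge 1$ gives $\pi \le 0$ and is rejected at construction.
Because $u' = u + \pi$ cannot itself satisfy $\sum_i u'_{ik} = 1$
unless all hesitations vanish, $u + \pi$ is renormalized per pixel;
the map $u \mapsto (u + \pi)/(1 + \sum \pi)$ is strictly increasing in
$u$, so it never reorders a pixel's cluster preferences. The
hesitation is recomputed from the current memberships each iteration
rather than carried across iterations.

**What "distance" means in the similarity.** The distance kernel
$w_d = \exp(-dis^2/D)$ can read $dis(x_k, c_i)$ two ways. The default
(`distance = "gray"`) is the pixel-to-center distance in gray space,
$|g(x_k) - v_i|$ — the same quantity classical FCM uses. The
alternative (`distance = "spatial"`) measures the Euclidean distance
from the pixel's coordinates to the cluster's membership-weighted
spatial centroid. The spatial reading is attractive in principle
(impulse noise is gray-similar but location-dissimilar to the tumor),
but it assumes every cluster is a compact blob. For classes that are
spatially extended or non-convex — the background surrounding the
brain, a ring of cortex — the centroid is far from most of the class's
own pixels, the multiplicative spatial kernel dominates the gray
kernel by orders of magnitude, and the partition degenerates toward a
centroidal Voronoi tessellation of the image plane, independent of
intensity. On the package's phantoms this is exactly what happens, so
the spatial reading is provided for experimentation but not as the
default.

**Adaptive scale conventions.** With $q_i$ a squared dissimilarity to
cluster $i$, the default `"printed"` convention uses
$w_d = \exp(-dis^2/D)$ with $D$ the mean absolute deviation (across
clusters) of the *linear* distances, and
$w_g = \exp(-(\Delta g/G)^2)$ with $G$ the deviation of the *squared*
gray gaps. These mixed powers are dimensionally uneven — on an 8-bit
intensity scale the gray factor is nearly inert — but they preserve
the published structure of the kernels. The `"balanced"` convention
instead divides each squared dissimilarity by the deviation of the
squared dissimilarities, making both exponents scale-free and
commensurate. Both are implemented; under the package defaults the two
behave equivalently on the bundled phantoms.

**Center update weighting.** The center update is
$v_i = \sum_k w_{ik} x_k / \sum_k w_{ik}$. With plain $w = u'$
(`center_power_m = FALSE`) the update is a weak contraction toward
distinct intensity modes under the similarity-softmax membership rule:
in experiments, centers initialized exactly at the class means drift
into pairwise-merged duplicates, because fuzzy weights tie every
center to the global mean. The classical $w = u'^m$ weighting sharpens
the weights enough to keep distinct modes separated and is the
default.

**Initialization.** Any membership-random initialization places every
initial center at the global image mean (weighted means of random
weights), which leaves the similarity-softmax update at a symmetric,
meta-stable configuration; runs then depend on rounding noise to break
ties and often converge with merged centers. The default `"centers"`
initialization draws seeded random pixels k-means++-style (first
uniformly, then proportionally to squared gray distance from the
chosen set), which spreads initial centers across the intensity modes.
The same policy is used for the FCM baseline, so method-versus-baseline
comparisons are initialization-fair; `init = "memberships"` restores
per-pixel normalized-uniform random memberships.

**Convergence.** The stopping rule is the max-abs entrywise difference
between consecutive post-transfer membership stacks against
`eta = 1e-5`. With the transfer filter enabled the iteration is a
fixed-point map whose convergence is linear with a rate close to one,
so runs frequently stop at `max_iter` with label maps that stabilized
long before; `converged = FALSE` therefore accompanies a perfectly
usable result, and the per-iteration `membership_deltas` and
`objective_trace` are returned for inspection.

## Numerical details

* **Membership update without underflow.** $u' \propto S^{2/(m-1)}$ is
  invariant to per-pixel rescaling of $S$, so the driver exponentiates
  log-similarities after subtracting each pixel's maximum; a pixel far
  from all clusters can no longer underflow to an all-zero row. The
  objective monitor floors $S$ at `1e-154` before squaring.
* **Degenerate scales.** A pixel equidistant (in the relevant sense)
  from all clusters has zero deviation; scales are floored at
  `similarity$scale_floor` (`1e-12`).
* **Filters.** Both the median filter and the guided filter's box
  means use replicate padding. Window means are computed with
  cumulative-sum (integral-image) windows; the 3×3 median uses a
  vectorized 19-comparison selection network, larger radii an explicit
  per-window sort. Guided-filter windows with
  $\mathrm{var}(I) + \varepsilon = 0$ get $a_k = 0$ (constant-guide
  window).
* **Ties and degenerates.** The final label map breaks membership ties
  toward the lowest cluster index. Constant images are rejected (no
  partition exists). A cluster whose total membership weight vanishes
  is re-seeded to a random pixel, with a message. Pixels whose
  clipped post-filter memberships sum to zero are set to the uniform
  $1/c$ assignment, with a message.
* **Seeding.** Every stochastic element of a run (initialization,
  re-seeding) draws from a single seed recorded in the configuration
  and the JSON report; the caller's RNG state is restored afterwards.

## The synthetic phantom

`make_phantom()` builds a piecewise-constant "brain": dark background
(mean 10), a large elliptical brain (90), one to three interior tissue
blobs (140), and one small bright tumor blob (220, about 150 pixels at
the default 128×128 size, always ≥ 9 pixels), each with within-class
Gaussian noise (sd 4 by default) and clipped to the 8-bit range. The
returned mask is the exact generating partition, so ground truth is
free. `salt_and_pepper()` corrupts an *exact* count
$\mathrm{round}(p\,n)$ of seeded, distinct pixels to 0 or 255 with
equal probability — exact-count rather than Bernoulli corruption keeps
noise-grid experiments reproducible pixel for pixel. The study grid is
$p \in \{0, 0.005, 0.01, 0.02\}$.

What the phantom does **not** emulate: intensity inhomogeneity (bias
fields), partial-volume voxels, Rician noise, textured tissue, or
anatomically shaped classes. Its class means are well separated
relative to the within-class noise, so intensity clustering alone
nearly solves the clean image. Passing the phantom benchmarks
therefore demonstrates noise robustness and the mechanics of the
method — not performance on real MRI, where class overlap is the
dominant difficulty and baseline FCM degrades far more.

A consequence worth stating explicitly: at impulse intensity $p$, a
baseline that clusters the clean structure correctly misclassifies
only (part of) the corrupted pixels, so its tumor-accuracy deficit is
bounded by about $p/2$ plus edge effects. On this phantom the
achievable accuracy gap between IFCM-MS and a *stable* FCM baseline at
$p = 0.02$ is therefore about 0.01, whatever the method does — gaps
larger than that require a baseline that also fails on clean
structure, as happens on real, overlapping-intensity data.

## Problem sizes used by the tests

The test-suite benchmarks run the default 128×128 phantom over 20
seeds per condition (noise levels 0 and 0.02; the four ablation
configurations), with the oracle-equivalence checks on 16×16 images
(clustering) and 8×8 maps (guided filter) against brute-force
reference implementations, and loop invariants on 40–48 pixel-wide
phantoms. `scripts/acceptance.R` recomputes the benchmark quantities
from scratch at the same sizes.

## Known limitations

* 2-D single-channel images only; no volumes, no multispectral data.
* `clusters` is user-chosen; there is no model selection.
* The transfer fixed-point's slow tail means `eta = 1e-5` is rarely
  reached within 100 iterations with filtering enabled (see
  *Convergence* above).
* The similarity's spatial-distance reading is unsuitable for
  non-compact classes (see above) and is off by default.
* Evaluation is binary (tumor versus rest) by design; use the
  brightest-center rule or an explicit `tumor_cluster`.
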