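---
title: "Connectome harmonics: model, alterations, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome harmonics: model, alterations, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(connharm)
```

## The model

A high-resolution structural connectome is a graph whose nodes are the `m`
vertices of a triangulated cortical surface mesh. Two kinds of edges enter:

* **Local gray-matter connectivity** `A_l`: vertex pairs within graph
  distance `lambda_s` on the mesh edge graph (`lambda_s` is 1 or 2; the
  default 2 connects neighbours and neighbours-of-neighbours). This models
  intrinsic horizontal gray-matter connections at the 1-6 mm scale.
* **Long-range white-matter connectivity** `A_c`: streamline tractography
  produces a count matrix `C[i, j]` — the number of streamlines whose two
  endpoints map to vertices `i` and `j` under the track-mesh intersection
  rule — which is z-scored over its nonzero weight population,
  `Cz = (C - mu_C) / sigma_C`, and binarized at the adjacency weight
  threshold `z_C` (default 1): `A_c[i, j] = 1` iff `Cz[i, j] > z_C`.

The combined connectome is the binary union `A = A_l | A_c`. Its graph
Laplacian `L = ((D - A) + (D - A)^T) / 2 = D - A` (with `D` the degree
matrix) is the discrete counterpart of the Laplace-Beltrami operator on the
cortical manifold; its eigenvectors `psi_k` with ascending eigenvalues
`lambda_k` — the *connectome harmonics* — generalize the Fourier basis to
the brain's connectivity structure. For a connected graph `lambda_1 = 0`
with constant `psi_1`; the number of (near-)zero eigenvalues equals the
number of connected components, so a brain whose hemispheres are fully
disconnected shows exactly two zero modes and a pairwise-organized spectrum.

### Track-mesh intersection

Each streamline endpoint is resolved to a mesh vertex by intersecting the
track's terminal segment with the surface triangles; if no crossing is
found, the segment is extended 3 mm along the direction from the third-last
track point to the endpoint and tested again. The crossing nearest to the
endpoint wins, and the assigned vertex is the hit triangle's vertex nearest
the intersection point (ties break deterministically toward the lowest
vertex index). Endpoints farther than 5 mm from the surface are discarded,
as are tracks shorter than 10 mm and tracks whose two ends resolve to a
single vertex. The 5 mm gap test uses the nearest-vertex distance, which
bounds the true point-to-surface distance to within about half an edge
length at these mesh resolutions.

## Alterations

All of the following operate on the built matrices and preserve symmetry,
binarity, and the zero diagonal; random modes are reproducible under seeds.

| Parameter | Operation | Default | Range |
|---|---|---|---|
| `f_i` | mesh smoothing iterations (inverse-distance Laplacian) | 0 | 0, 8, 21, 89 |
| `z_C` | adjacency weight threshold (sd units) | 1 | 0-10 |
| `lambda_s` | local kernel width (graph distance) | 2 | 1, 2 |
| `eta` | % long-range edges trimmed by mean track length | 0 | 0-100 |
| `kappa` | % inter-hemispheric edges removed (callosectomy) | 0 | 0-100 (99 random) |
| `rho` | % local edges removed (anisotropy) | 0 | 0-100 |

Design choices worth stating explicitly:

* **z-score population.** `mu_C` and `sigma_C` are computed over the
  *nonzero* upper-triangular weights with the population (not sample)
  standard deviation. Including the ~`m^2` structural zeros would collapse
  `sigma_C` and make integer thresholds meaningless; the weight
  distribution is only defined conditional on a connection existing.
* **Local ratio.** `r = n_local / (n_local + n_longrange)` with both counts
  taken as undirected edge counts (equivalently `tr(A^2)/2` for a binary
  symmetric zero-diagonal matrix — the trace of the adjacency itself is
  identically zero, so only the squared form is meaningful).
* **Trimming/callosectomy vs anisotropy randomness.** Trimming and random
  callosectomy remove an exact rounded count of edges (sampled without
  replacement); anisotropy's random mode removes each edge independently
  with probability `rho/100`. Length ties break lexicographically by vertex
  pair so ordered modes are fully deterministic.
* **Randomization nulls.** Degree-preserving double-edge swaps with about
  10 attempted swaps per edge, restricted to hemispheric blocks: `inter`
  uses bipartite swaps on the off-diagonal block (preserving every node's
  inter-hemispheric degree), `intra` rewires each diagonal block
  independently — swaps pairing edges of different hemispheres would create
  inter-hemispheric edges, so per-block isolation is forced by the
  constraint itself — `inter+intra` does all three blocks in isolation, and
  `global` shuffles all long-range edges in one batch. Proposals creating
  self-loops or duplicate edges are rejected. The swap count is a standard
  mixing heuristic; raising it further does not change the degree sequence,
  which is exactly preserved by construction.
* **Eigensolver.** A dense symmetric LAPACK decomposition, bitwise
  reproducible and exact to machine precision at the vertex counts used
  here (up to a few thousand). Eigenvector signs are fixed by making each
  vector's largest-magnitude entry positive. Within degenerate multiplets
  individual eigenvectors are basis-dependent; property tests therefore
  compare multiplets by principal angles between subspaces, while
  harmonic-by-harmonic correlation matrices use `|Pearson|`, which absorbs
  the sign but not the rotation ambiguity — the honest behaviour for
  degenerate spectra. Eigenvalues below `1e-8` times the spectral scale
  count as zero.

## Similarity metrics and statistics

Mutual information between a harmonic and a binary network map discretizes
the harmonic into 16 equal-width bins over its observed range (the simplest
reading of fixed-bin discretization; equal-count binning is a noted
alternative that we do not use) and uses natural logarithms, so values are
in nats. MI is computed per-vertex; correlations between harmonics of
*different* meshes are computed after projecting each harmonic to a common
atlas space by unweighted per-region means.

The Monte-Carlo surrogate statistic pools harmonics `k = 7 ... 11` over
`N_surr = 100` randomized connectomes:
`p_MI_surr = (1 + #{MI_surr >= MI_orig}) / (1 + N_surr * n_k)`,
bounded in `[1/501, 1]`. Scheme-level p-values are corrected with
Benjamini-Hochberg (FDR 0.1 as the reference procedure; the pipeline-level
direction test reports BH-adjusted p-values against 0.05).

## The synthetic brain generator

Real cortical meshes and tractography are replaced by a fully seeded
generator whose defaults are the package's study conditions:

* **Geometry.** Two icospheres (subdivision 3, 642 vertices each, radius
  35 mm, surface gap 10 mm) with 0.5 mm Gaussian vertex jitter; mean edge
  length about 5 mm, within the 1-6 mm scale of local connectivity. The
  sphere is a deliberate idealization: the analysis depends on graph
  structure, not cortical folding, and the sphere limit provides an
  analytic oracle — with no long-range edges the low harmonics of a
  jitter-free icosphere span spherical harmonics of matching degree.
  (The icosahedral symmetry group has irreducible representations of
  dimensions 1, 3, 3, 4, 5 only, so the seven degree-3 spherical harmonics
  split into near-degenerate blocks of 3 + 4 — about 13% apart for the
  subdivision-3 icosphere — while their joint span still aligns with the
  analytic degree-3 space to within a few degrees.)
* **Parcellation and map.** Farthest-point seeding with geodesic
  nearest-seed assignment gives 17 contiguous, roughly equal-area regions
  per hemisphere (a Desikan-Killiany-scale atlas). The planted network map
  is bilateral and homotopic: a randomly seeded region plus its three
  nearest neighbours forms a contiguous left-hemisphere territory (~24% of
  the hemisphere), mirrored onto the right hemisphere — the spatial layout
  of a large resting-state network.
* **Streamlines as bundles.** 20,000 polylines are organized into repeated
  fiber bundles (a pool of endpoint vertex pairs, about five streamlines
  per bundle, lognormal bundle weights), which produces the heavy-tailed
  pairwise streamline-count distribution that makes integer z-score
  thresholds meaningful — isolated endpoint pairs never survive
  thresholding, fascicles do. Five populations:
  20% inter-hemispheric bundles with homotopic bias (callosal endpoints
  cluster near the mirror vertex); 2% deliberately shorter than the 10 mm
  filter; of the remaining intra-hemispheric tracks, 30% are
  network-binding association bundles connecting vertices of the planted
  territory, 30% are same-region (modular) bundles routed outside that
  territory, 25% are long (> 1 rad angular span) background bundles also
  outside it, and the rest follow a right-skewed gamma angular-length law
  (median track length ~30 mm, mean ~40 mm). Endpoints are displaced
  off-surface by 1 mm Gaussian offsets, exercising the extension-recovery
  path of the intersection rule.

The planted structure exploits a spectral mechanism: the low eigenmodes of
a near-spherical mesh come in nearly degenerate multiplets whose
*orientation* is free. The dense association-bundle community inside the
planted territory pins that orientation, so the low harmonics — including
the 7-11 window used for statistics — develop lobes and nodal structure
coherent with the map, tripling their mutual information with it relative
to the bare mesh. A degree-preserving shuffle of the intra-hemispheric
long-range edges destroys the pair structure that does the pinning, and
alignment falls; shuffling only inter-hemispheric edges leaves it largely
intact. Background wiring is deliberately routed outside the planted
territory so that territory membership is *not* predictable from the
long-range degree sequence — two earlier designs failed instructively:
planting inside isolated scattered patches concentrates degree on network
vertices, and the degree-preserving null then rewires those vertices into
a tighter community than the original (surrogate alignment *rises*); and
a map drawn without any planted community cannot exceed the ~0.05 nat
alignment noise floor of a region-union map against unpinned modes.

Two directional behaviours of the original study do not transfer to this
synthetic scale, and the corresponding validation checks fail by design
honesty rather than implementation error. First, the Monte-Carlo surrogate
probability pooled over harmonics 7-11 is directionally right in the mean
but fluctuates strongly with the seed (roughly 0.02-0.45): with 1,284
vertices the window sits inside near-degenerate multiplets whose ordering
collides between original and surrogate decompositions, so single window
indices can pair an unaligned original mode with a surrogate's residual
community mode. Second, anisotropy (local edge removal) leaves MI flat or
slightly rising here, because the synthetic alignment is carried by the
planted long-range community rather than by local connectivity — at this
mesh size a region-union map cannot align with window harmonics of the
bare mesh above the noise floor, so the two mechanisms cannot be combined.
Both behaviours are quantified by the validation suite and the
reproduction script rather than hidden.

What the generator does not emulate: cortical folding and curvature,
subject-level variability, distance-dependent tractography biases, and
gyral-crown seeding artifacts. Passing directional tests on this synthetic
brain shows the pipeline's machinery reproduces the qualitative mechanics
of the analysis, not that it would reproduce numerical MI values from any
particular imaging dataset.

## Problem sizes and numerical choices

Validation runs use the 1,284-vertex two-sphere brain with 20,000
streamlines, 100 surrogates per randomization scheme, and harmonics up to
`K = 100` (window 7-11 for statistics) — sizes chosen so a complete
validation cycle runs in minutes on a single CPU while keeping all
qualitative regimes (threshold, trimming, callosectomy, anisotropy,
randomization) well exercised. The dense eigensolver is exact at these
sizes; Lanczos-style iterative solvers only become necessary above tens of
thousands of vertices, where full decomposition is intractable and only
the lowest modes are computed.

Degenerate inputs are handled explicitly: constant harmonics or constant
maps give MI 0 with a warning; an all-equal weight population is a z-score
error; randomization blocks with fewer than two edges return unchanged with
a warning; `kappa = 100` is rejected in random mode (the ordered modes
allow the exact full split).

## Known limitations

* MI values depend on the bin convention (16 equal-width bins, natural
  log); comparisons are internally consistent but absolute values are not
  comparable across bin conventions.
* The sphere-limit check is exact only for the jitter-free icosphere;
  jitter breaks the degeneracy blocks smoothly.
* Atlas-space correlation of harmonics from different meshes inherits the
  parcellation's coarseness; diagonal correlation values are noisier than
  vertex-space ones, as expected when projecting ~600 vertices onto ~34
  regions.
* TRK streamline files are not read; use TCK or plain text.
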