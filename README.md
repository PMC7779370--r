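# connharm

Connectome harmonics are the eigenvectors of the graph Laplacian of a
high-resolution structural brain connectome. They generalize the Fourier
basis to the brain's wiring: low-frequency harmonics form smooth,
widespread cortical patterns that have been linked to resting-state
networks such as the default mode network (DMN). `connharm` implements the
full analysis needed to study how *robust* those patterns are to changes in
the underlying connectivity — for computational neuroscientists and
methods researchers who want a tested, fully reproducible implementation
that runs on synthetic data out of the box.

## The model

Given a cortical surface mesh with `m` vertices and a set of tractography
streamlines:

* **Local connectivity** `A_l`: vertices within mesh graph distance
  `Λ_s ∈ {1, 2}` are connected (gray-matter wiring at the 1–6 mm scale).
* **Long-range connectivity**: each streamline endpoint is assigned to a
  mesh vertex by intersecting the track's terminal segment (plus a 3 mm
  linear extension if needed) with the surface; every surviving track
  increments the count matrix `C[i,j]`. Counts are z-scored over the
  nonzero weight population, `Cᶻ = (C − μ_C)/σ_C`, and binarized at the
  threshold `z_C`: `A_c[i,j] = 1` iff `Cᶻ[i,j] > z_C`.
* **Combined connectome** `A = A_l ∪ A_c`, graph Laplacian `L = D − A`,
  harmonics `L ψ_k = λ_k ψ_k` with `λ_1 ≤ λ_2 ≤ …`.

Alterations probe the structure: thresholding (`z_C`), distance-based
trimming of long-range edges (`η`, longest/shortest/random first),
*callosectomy* (removal of inter-hemispheric edges, `κ`), *anisotropy*
(removal of local mesh edges, `ρ`), mesh smoothing (`f_i`), and four
degree-preserving randomization null models (`inter`, `intra`,
`inter+intra`, `global`). Effects are quantified by the mutual information
(16-bin histogram, nats) between each harmonic and a binary network map,
with a Monte-Carlo surrogate statistic
`p_MI_surr = (1 + #{MI_surr ≥ MI_orig}) / (1 + N_surr·n_k)`
pooled over harmonics 7–11 and 100 surrogates, and by |Pearson| correlation
matrices between harmonic sets (per-vertex, or per-region after atlas
projection).

A seeded synthetic-brain generator (`synth_brain_config()`,
`synthesize_brain()`) replaces MRI-derived inputs: two jittered icospheres,
a geodesic parcellation, a planted binary network map, and fiber-bundle
streamlines with a heavy-tailed pair-count distribution. Analytic spherical
harmonics provide the sphere-limit oracle for the eigensolver.

## Worked example

```r
library(connharm)

brain <- synthesize_brain(synth_brain_config(seed = 1))
wc    <- zscore_weights(build_long_range(brain$streamlines, brain$mesh))
local <- build_local_adjacency(brain$mesh, lambda_s = 2)
lr    <- threshold_long_range(wc, z_C = 1)

local_ratio(local, lr)          # proportion of local connections r
basis <- eigendecompose(graph_laplacian(combine_connectome(local, lr)), K = 11)
mi_profile(basis, brain$rsn$map, ks = 7:11)   # MI of harmonics 7-11, nats

ens <- surrogate_mi_test(local, lr, brain$mesh$hemisphere, brain$rsn$map,
                         scheme = "intra", n_surr = 100, seed = 2000)
ens$p_mi_surr
```

On this synthetic brain the run prints (seed 1): `r = 0.912`, MI values of
`0.099 0.191 0.092 0.100 0.124` nats for harmonics 7-11 (mean 0.121,
versus about 0.05 for the bare mesh: the planted network community pins
the low harmonics onto the map territory), and a mean surrogate MI of
0.091 under `scheme = "intra"` — shuffling intra-hemispheric connections
while preserving degrees destroys the planted network-binding structure
and lowers the alignment, whereas `scheme = "inter"` changes it least. The
pooled Monte-Carlo probability (`ens$p_mi_surr`, 0.367 at this seed) is
noisier than the mean effect at this mesh size; the methods vignette
discusses why. A 100% `callosectomy()` yields exactly two zero eigenvalues
(one per disconnected hemisphere), and `eigenvalue_blocks()` on a single
jitter-free icosphere recovers the spherical-harmonic shell structure.

See `vignettes/connectome-harmonics.Rmd` for the full account of the model,
the alteration semantics, the generator's design, and known limitations.

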