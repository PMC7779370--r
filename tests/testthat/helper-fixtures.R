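# Shared fixtures, memoized so expensive objects are built once per test run.
fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = fixture_env)) assign(name, force(expr), envir = fixture_env)
  get(name, envir = fixture_env)
}

# Single triangle mesh in the z = 0 plane.
triangle_mesh <- function() {
  cortical_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                rbind(c(1, 2, 3)))
}

icosahedron_mesh <- function(radius = 50) {
  make_hemisphere_mesh(0, radius)
}

icosphere3 <- function() memo("icosphere3", make_hemisphere_mesh(3, 50))

# Small two-hemisphere brain for cheap module tests.
small_config <- function(...) {
  defaults <- list(subdivisions = 2, n_streamlines = 2000,
                   n_regions_per_hemisphere = 8, n_rsn_patches = 3, seed = 42L)
  do.call(synth_brain_config, utils::modifyList(defaults, list(...)))
}

small_brain <- function() memo("small_brain", synthesize_brain(small_config()))

small_build <- function() memo("small_build", {
  brain <- small_brain()
  wc <- zscore_weights(build_long_range(brain$streamlines, brain$mesh))
  local <- build_local_adjacency(brain$mesh, 2)
  lr <- threshold_long_range(wc, 1)
  list(brain = brain, wc = wc, local = local, lr = lr)
})

# Study-conditions brain (default generator configuration) and its connectome
# build, shared by the pipeline-level tests.
study_brain <- function() memo("study_brain", synthesize_brain(synth_brain_config(seed = 1L)))

study_build <- function() memo("study_build", {
  brain <- study_brain()
  wc <- zscore_weights(build_long_range(brain$streamlines, brain$mesh))
  local <- build_local_adjacency(brain$mesh, 2)
  lr <- threshold_long_range(wc, 1)
  list(brain = brain, wc = wc, local = local, lr = lr)
})

study_mi <- function(local, lr, map, ks = 7:11) {
  basis <- eigendecompose(graph_laplacian(combine_connectome(local, lr)),
                          K = max(ks))
  mi_profile(basis, map, ks)
}

# Independent brute-force segment/triangle oracle: scalar loop over all
# triangles, barycentric solve via a 3x3 linear system (distinct algorithm
# from the package's vectorized Moller-Trumbore).
oracle_segment_hits <- function(mesh, p0, p1) {
  hits <- list()
  for (tt in seq_len(nrow(mesh$triangles))) {
    tri <- mesh$triangles[tt, ]
    a <- mesh$vertices[tri[1], ]; b <- mesh$vertices[tri[2], ]; cc <- mesh$vertices[tri[3], ]
    M <- cbind(b - a, cc - a, -(p1 - p0))
    if (abs(det(M)) < 1e-12) next
    sol <- solve(M, p0 - a)
    u <- sol[1]; v <- sol[2]; t <- sol[3]
    if (u >= 0 && v >= 0 && u + v <= 1 && t >= 0 && t <= 1)
      hits[[length(hits) + 1]] <- list(tri = tt, t = t, point = p0 + t * (p1 - p0))
  }
  hits
}

# Full oracle re-implementation of the end-assignment rule.
oracle_assign_end <- function(mesh, track, which_end, extension_mm = 3, max_gap_mm = 5) {
  n <- nrow(track)
  if (which_end == "start") {
    ep <- track[1, ]; inner <- track[2, ]; third <- track[3, ]
  } else {
    ep <- track[n, ]; inner <- track[n - 1, ]; third <- track[n - 2, ]
  }
  if (min(sqrt(rowSums(sweep(mesh$vertices, 2, ep)^2))) > max_gap_mm) return(NA_integer_)
  pick <- function(hits) {
    if (length(hits) == 0) return(NULL)
    d <- vapply(hits, function(h) sum((h$point - ep)^2), numeric(1))
    h <- hits[[which.min(d)]]
    verts <- sort(mesh$triangles[h$tri, ])
    vd <- round(sqrt(rowSums(sweep(mesh$vertices[verts, , drop = FALSE], 2, h$point)^2)), 9)
    verts[which.min(vd)]
  }
  res <- pick(oracle_segment_hits(mesh, inner, ep))
  if (!is.null(res)) return(res)
  dirv <- ep - third
  nd <- sqrt(sum(dirv^2))
  if (nd < 1e-12 || extension_mm <= 0) return(NA_integer_)
  res <- pick(oracle_segment_hits(mesh, ep, ep + dirv / nd * extension_mm))
  if (is.null(res)) NA_integer_ else res
}

# Independent double-loop joint-histogram MI oracle.
oracle_mi <- function(psi, v, n_bins = 16) {
  rng <- range(psi)
  joint <- matrix(0, n_bins, 2)
  for (i in seq_along(psi)) {
    b <- floor((psi[i] - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1
    if (b > n_bins) b <- n_bins
    joint[b, v[i] + 1] <- joint[b, v[i] + 1] + 1
  }
  joint <- joint / length(psi)
  mi <- 0
  for (n in 1:n_bins) for (m in 1:2) {
    p <- joint[n, m]
    if (p > 0) mi <- mi + p * log(p / (sum(joint[n, ]) * sum(joint[, m])))
  }
  mi
}
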