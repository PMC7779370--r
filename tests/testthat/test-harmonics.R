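path3 <- function() {
  A <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 3), x = 1, dims = c(3, 3),
                            symmetric = TRUE)
  as(A, "CsparseMatrix")
}

test_that("the graph Laplacian is D - A with zero row sums", {
  lap <- graph_laplacian(path3())
  expect_equal(as.matrix(lap$L),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)),
               ignore_attr = TRUE)
  expect_equal(max(abs(Matrix::rowSums(lap$L))), 0)
  # random graph: sparse result equals the dense loop construction
  set.seed(11)
  m <- 50
  A <- matrix(0, m, m)
  picks <- which(upper.tri(A))[sample(m * (m - 1) / 2, 120)]
  A[picks] <- 1
  A <- A + t(A)
  dense <- diag(rowSums(A)) - A
  lap2 <- graph_laplacian(methods::as(Matrix::Matrix(A, sparse = TRUE), "CsparseMatrix"))
  expect_equal(as.matrix(lap2$L), dense, ignore_attr = TRUE)
  # asymmetry beyond tolerance is an error
  bad <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(3, 3))
  expect_error(graph_laplacian(bad), "asymmetry")
})

test_that("eigendecomposition returns ascending orthonormal harmonics", {
  lap <- graph_laplacian(path3())
  basis <- eigendecompose(lap, K = 3)
  expect_equal(basis$values, c(0, 1, 3), tolerance = 1e-12)
  expect_error(eigendecompose(lap, K = 4), "<=")
  # constant first mode on a connected graph
  expect_lt(diff(range(basis$vectors[, 1])), 1e-10)
  b <- small_build()
  lap2 <- graph_laplacian(combine_connectome(b$local, b$lr))
  basis2 <- eigendecompose(lap2, K = 12)
  expect_true(all(diff(basis2$values) >= -1e-10))
  # residual and orthogonality
  R <- as.matrix(lap2$L %*% basis2$vectors) -
    basis2$vectors %*% diag(basis2$values)
  expect_lt(max(abs(R)), 1e-8 * max(basis2$values))
  G <- crossprod(basis2$vectors)
  expect_lt(max(abs(G - diag(12))), 1e-10)
  # Rayleigh bound and sign convention
  expect_lte(max(basis2$values), 2 * max(lap2$degrees))
  peaks <- apply(basis2$vectors, 2, function(x) x[which.max(abs(x))])
  expect_true(all(peaks > 0))
  # bitwise reproducibility
  basis3 <- eigendecompose(lap2, K = 12)
  expect_identical(basis2$vectors, basis3$vectors)
})

test_that("zero modes count connected components", {
  lap <- graph_laplacian(path3())
  expect_equal(count_zero_modes(eigendecompose(lap, 3)), 1L)
  # three disjoint triangles
  tri3 <- Matrix::bdiag(lapply(1:3, function(i) {
    Matrix::sparseMatrix(i = c(1, 1, 2), j = c(2, 3, 3), x = 1, dims = c(3, 3),
                         symmetric = TRUE)
  }))
  expect_equal(count_zero_modes(eigendecompose(graph_laplacian(tri3), 9)), 3L)
  # random graphs vs the union-find (igraph components) oracle
  set.seed(99)
  for (rep in 1:20) {
    m <- 40
    n_e <- sample(10:50, 1)
    ij <- cbind(sample(m, n_e, TRUE), sample(m, n_e, TRUE))
    ij <- ij[ij[, 1] != ij[, 2], , drop = FALSE]
    A <- Matrix::sparseMatrix(i = pmin(ij[, 1], ij[, 2]), j = pmax(ij[, 1], ij[, 2]),
                              x = 1, dims = c(m, m), symmetric = TRUE)
    A <- methods::as(A, "CsparseMatrix"); A@x[] <- 1
    basis <- eigendecompose(graph_laplacian(A), K = m)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(count_zero_modes(basis), igraph::components(g)$no)
  }
})

test_that("split-hemisphere bases merge into paired spectra", {
  # identical mirrored hemispheres: eigenvalues come in exact pairs
  mesh <- make_hemisphere_mesh(2, 30)
  Al <- build_local_adjacency(mesh, 1)$A
  basis_h <- eigendecompose(graph_laplacian(Al), K = 8)
  m <- 2 * nrow(Al)
  merged <- merge_hemisphere_bases(basis_h, basis_h, m,
                                   idx_left = seq_len(nrow(Al)),
                                   idx_right = nrow(Al) + seq_len(nrow(Al)))
  expect_length(merged$values, 16)
  expect_equal(merged$values[seq(1, 15, 2)], merged$values[seq(2, 16, 2)])
  expect_equal(merged$side[1:2], c("left", "right"))
  # embedded vectors vanish on the other hemisphere
  expect_true(all(merged$vectors[nrow(Al) + seq_len(nrow(Al)), merged$side == "left"] == 0))
  expect_error(merge_hemisphere_bases(basis_h, basis_h, m, 1:162, 100:261),
               "overlap")
  # near-mirror (jittered) hemispheres: within-pair gaps far below between-pair gaps
  b <- small_brain()
  hemi <- b$mesh$hemisphere
  Ab <- build_local_adjacency(b$mesh, 1)$A
  il <- which(hemi == "left"); ir <- which(hemi == "right")
  bl <- eigendecompose(graph_laplacian(Ab[il, il]), K = 6)
  br <- eigendecompose(graph_laplacian(Ab[ir, ir]), K = 6)
  mg <- merge_hemisphere_bases(bl, br, b$mesh$m, il, ir)
  v <- mg$values[1:10]
  within <- v[seq(2, 10, 2)] - v[seq(1, 9, 2)]
  between <- v[seq(3, 9, 2)] - v[seq(2, 8, 2)]
  expect_lt(max(within[-1]), 0.2 * min(between[-1]))
})

test_that("icosphere harmonics recover spherical-harmonic shell structure", {
  mesh <- icosphere3()
  basis <- eigendecompose(graph_laplacian(build_local_adjacency(mesh, 1)$A), K = 30)
  # the icosahedral symmetry group splits the 7-fold l=3 shell into 3 + 4
  blocks <- eigenvalue_blocks(basis$values[1:16], rel_tol = 0.05)
  expect_equal(blocks, c(1, 3, 5, 3, 4))
  # block subspaces align with analytic spherical harmonics
  sh <- function(l) sapply(-l:l, function(m) spherical_harmonic_reference(l, m, mesh))
  expect_lt(subspace_angle(basis$vectors[, 2:4, drop = FALSE], sh(1)), 10)
  expect_lt(subspace_angle(basis$vectors[, 5:9, drop = FALSE], sh(2)), 10)
  # jointly, the split l=3 blocks still span the degree-3 harmonics
  expect_lt(subspace_angle(basis$vectors[, 10:16, drop = FALSE], sh(3)), 10)
})
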