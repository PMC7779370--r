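# A toy long-range adjacency with known per-edge mean lengths.
toy_longrange <- function() {
  m <- 8L
  edges <- cbind(c(1, 2, 3, 4), c(5, 6, 7, 8))
  lens <- c(5, 10, 15, 20)
  Ac <- Matrix::sparseMatrix(i = edges[, 1], j = edges[, 2], x = 1,
                             dims = c(m, m), symmetric = TRUE)
  Lbar <- Matrix::sparseMatrix(i = edges[, 1], j = edges[, 2], x = lens,
                               dims = c(m, m), symmetric = TRUE)
  list(lr = structure(list(A_c = methods::as(Ac, "CsparseMatrix"), z_C = 1),
                      class = "long_range_adjacency"),
       Lbar = methods::as(Lbar, "CsparseMatrix"),
       hemi = rep(c("left", "right"), each = 4))
}

test_that("trimming removes edges by mean track length", {
  toy <- toy_longrange()
  expect_error(trim_long_range(toy$lr, toy$Lbar, 150), "eta")
  t0 <- trim_long_range(toy$lr, toy$Lbar, 0)
  expect_equal(Matrix::nnzero(t0$A_c - toy$lr$A_c), 0)
  t100 <- trim_long_range(toy$lr, toy$Lbar, 100)
  expect_equal(Matrix::nnzero(t100$A_c), 0)
  # 50% descending removes the 20 mm and 15 mm edges
  td <- trim_long_range(toy$lr, toy$Lbar, 50, "descending")
  expect_equal(td$A_c[1, 5], 1); expect_equal(td$A_c[2, 6], 1)
  expect_equal(td$A_c[3, 7], 0); expect_equal(td$A_c[4, 8], 0)
  ta <- trim_long_range(toy$lr, toy$Lbar, 50, "ascending")
  expect_equal(ta$A_c[1, 5], 0); expect_equal(ta$A_c[4, 8], 1)
  # random mode removes the exact rounded count, reproducibly
  trr <- trim_long_range(toy$lr, toy$Lbar, 50, "random", seed = 3)
  expect_equal(Matrix::nnzero(trr$A_c) / 2, 2)
  expect_equal(Matrix::nnzero(
    trim_long_range(toy$lr, toy$Lbar, 50, "random", seed = 3)$A_c - trr$A_c), 0)
})

test_that("callosectomy touches only inter-hemispheric edges", {
  b <- small_build()
  hemi <- b$brain$mesh$hemisphere
  lr <- b$lr
  edges <- connharm:::adjacency_edges(lr$A_c)
  inter <- hemi[edges[, 1]] != hemi[edges[, 2]]
  n_inter <- sum(inter)
  expect_gt(n_inter, 3)
  expect_error(callosectomy(lr, hemi, 100, "random"), "kappa")
  c0 <- callosectomy(lr, hemi, 0, "random", seed = 1)
  expect_equal(Matrix::nnzero(c0$A_c - lr$A_c), 0)
  c50 <- callosectomy(lr, hemi, 50, "random", Lbar = b$wc$Lbar, seed = 1)
  e50 <- connharm:::adjacency_edges(c50$A_c)
  i50 <- hemi[e50[, 1]] != hemi[e50[, 2]]
  expect_equal(sum(i50), n_inter - round(0.5 * n_inter))
  # intra-hemispheric edges bit-identical
  intra_in <- edges[!inter, , drop = FALSE]
  intra_out <- e50[!i50, , drop = FALSE]
  expect_identical(intra_in[order(intra_in[, 1], intra_in[, 2]), ],
                   intra_out[order(intra_out[, 1], intra_out[, 2]), ])
  # a fixture with 40 inter edges at 25% loses exactly 10
  m <- 100L
  fe <- cbind(1:40, 51:90)
  Ac <- methods::as(Matrix::sparseMatrix(i = fe[, 1], j = fe[, 2], x = 1,
                                         dims = c(m, m), symmetric = TRUE),
                    "CsparseMatrix")
  flr <- structure(list(A_c = Ac, z_C = 1), class = "long_range_adjacency")
  fh <- rep(c("left", "right"), each = 50)
  out <- callosectomy(flr, fh, 25, "random", seed = 9)
  expect_equal(Matrix::nnzero(out$A_c) / 2, 30)
})

test_that("full ordered callosectomy splits the brain into two components", {
  b <- small_build()
  hemi <- b$brain$mesh$hemisphere
  cut <- callosectomy(b$lr, hemi, 100, "descending", Lbar = b$wc$Lbar)
  basis <- eigendecompose(graph_laplacian(combine_connectome(b$local, cut)), K = 5)
  expect_equal(count_zero_modes(basis), 2L)
})

test_that("anisotropy removes local edges per its two removal laws", {
  b <- small_build()
  loc <- b$local
  expect_error(anisotropy(loc, -5), "rho")
  a0 <- anisotropy(loc, 0)
  expect_equal(Matrix::nnzero(a0$A - loc$A), 0)
  # Bernoulli mode: removed count within the binomial 99% interval
  n_e <- nrow(loc$edges)
  a30 <- anisotropy(loc, 30, "random", seed = 4)
  removed <- n_e - nrow(a30$edges)
  band <- 2.58 * sqrt(n_e * 0.3 * 0.7)
  expect_gt(removed, 0.3 * n_e - band)
  expect_lt(removed, 0.3 * n_e + band)
  # descending mode removes the single longest edge first
  one <- anisotropy(loc, 100 / n_e * 0.999 + 1e-9, "descending")
  gone <- loc$edges[!paste(loc$edges[, 1], loc$edges[, 2]) %in%
                      paste(one$edges[, 1], one$edges[, 2]), , drop = FALSE]
  if (nrow(gone) == 1)
    expect_equal(edge_lengths(b$brain$mesh, gone), max(loc$edge_lengths))
  expect_true(Matrix::isSymmetric(a30$A))
})

test_that("randomization preserves degrees and untouched blocks", {
  b <- small_build()
  hemi <- b$brain$mesh$hemisphere
  lr <- b$lr
  is_left <- hemi == "left"
  block_degrees <- function(A) {
    Al <- A[is_left, is_left]; Ar <- A[!is_left, !is_left]
    Ax <- A[is_left, !is_left]
    list(left = Matrix::rowSums(Al), right = Matrix::rowSums(Ar),
         inter_l = Matrix::rowSums(Ax), inter_r = Matrix::colSums(Ax))
  }
  d0 <- block_degrees(lr$A_c)
  for (sch in c("inter", "intra", "inter+intra", "global")) {
    out <- randomize_long_range(lr, hemi, scheme = sch, seed = 17)
    expect_true(Matrix::isSymmetric(out$A_c))
    expect_true(all(Matrix::diag(out$A_c) == 0))
    expect_equal(Matrix::nnzero(out$A_c), Matrix::nnzero(lr$A_c))
    d1 <- block_degrees(out$A_c)
    # total degree always preserved
    expect_equal(Matrix::rowSums(out$A_c), Matrix::rowSums(lr$A_c))
    if (sch != "global") {
      # block-restricted schemes preserve within-block degrees too
      expect_equal(d1$inter_l, d0$inter_l)
      expect_equal(d1$inter_r, d0$inter_r)
      expect_equal(d1$left, d0$left)
      expect_equal(d1$right, d0$right)
    }
    if (sch == "inter") {
      expect_equal(Matrix::nnzero(out$A_c[is_left, is_left] - lr$A_c[is_left, is_left]), 0)
      expect_equal(Matrix::nnzero(out$A_c[!is_left, !is_left] - lr$A_c[!is_left, !is_left]), 0)
    }
    if (sch == "intra") {
      expect_equal(Matrix::nnzero(out$A_c[is_left, !is_left] - lr$A_c[is_left, !is_left]), 0)
    }
    # reproducibility, and actual shuffling happened
    again <- randomize_long_range(lr, hemi, scheme = sch, seed = 17)
    expect_equal(Matrix::nnzero(out$A_c - again$A_c), 0)
    expect_gt(Matrix::nnzero(abs(out$A_c - lr$A_c)), 0)
  }
  # surrogate ensembles conserve the edge count exactly
  counts <- vapply(1:25, function(s)
    Matrix::nnzero(randomize_long_range(lr, hemi, "global", seed = s)$A_c) / 2,
    numeric(1))
  expect_true(all(counts == Matrix::nnzero(lr$A_c) / 2))
  # blocks with < 2 edges are returned unchanged with a warning
  tiny <- structure(list(A_c = methods::as(
    Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(4, 4), symmetric = TRUE),
    "CsparseMatrix"), z_C = 1), class = "long_range_adjacency")
  warns <- capture_warnings(out <- randomize_long_range(tiny, rep("left", 4), "intra", seed = 1))
  expect_match(warns, "unchanged", all = TRUE)
  expect_equal(Matrix::nnzero(out$A_c - tiny$A_c), 0)
})

test_that("mesh smoothing shrinks jitter and preserves topology", {
  mesh <- make_hemisphere_mesh(2, 30, vertex_jitter_mm = 1.5, seed = 8)
  s0 <- smooth_mesh(mesh, 0)
  expect_identical(s0$vertices, mesh$vertices)
  s21 <- smooth_mesh(mesh, 21)
  expect_identical(s21$triangles, mesh$triangles)
  radius_var <- function(m) stats::var(sqrt(rowSums(m$vertices^2)))
  expect_lt(radius_var(s21), radius_var(mesh))
  expect_error(smooth_mesh(mesh, -1), "f_i")
})

test_that("null alterations leave the pipeline bit-identical", {
  b <- small_build()
  hemi <- b$brain$mesh$hemisphere
  lr <- trim_long_range(b$lr, b$wc$Lbar, 0)
  lr <- callosectomy(lr, hemi, 0, "random", seed = 1)
  loc <- anisotropy(b$local, 0)
  expect_equal(Matrix::nnzero(lr$A_c - b$lr$A_c), 0)
  expect_equal(Matrix::nnzero(loc$A - b$local$A), 0)
  # downstream harmonics correlate with |P| = 1 on the diagonal
  K <- 10
  b0 <- eigendecompose(graph_laplacian(combine_connectome(b$local, b$lr)), K)
  b1 <- eigendecompose(graph_laplacian(combine_connectome(loc, lr)), K)
  P <- suppressWarnings(correlation_matrix(b0, b1, K))
  expect_equal(unname(diag(P)), rep(1, K), tolerance = 1e-10)
  # trimming everything reduces the combined connectome to the local one
  gone <- trim_long_range(b$lr, b$wc$Lbar, 100)
  expect_equal(Matrix::nnzero(combine_connectome(b$local, gone)$A - b$local$A), 0)
})
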