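test_that("endpoint assignment follows the tie-break and gap rules", {
  tri <- triangle_mesh()
  centroid <- c(1 / 3, 1 / 3, 0)
  # segment through the centroid, perpendicular: all vertices equidistant
  track <- rbind(centroid + c(0, 0, 3), centroid + c(0, 0, 1.5), centroid + c(0, 0, -1))
  expect_equal(intersect_track_end(track, tri, "end"), 1L)
  # endpoint 20 mm off-surface: rejected by the gap rule
  far <- rbind(c(0, 0, 25), c(0, 0, 22), c(0, 0, 20))
  expect_true(is.na(intersect_track_end(far, tri, "end", max_gap_mm = 5)))
  expect_error(intersect_track_end(rbind(c(0, 0, 1), c(0, 0, 0)), tri, "end"),
               "3 points")
})

test_that("the extension recovers short tracks along the third-last direction", {
  tri <- triangle_mesh()
  centroid <- c(1 / 3, 1 / 3, 0)
  # terminal segment stops 1 mm above the plane; 3 mm extension crosses it
  track <- rbind(centroid + c(0, 0, 9), centroid + c(0, 0, 5), centroid + c(0, 0, 1))
  expect_equal(intersect_track_end(track, tri, "end", extension_mm = 3), 1L)
  expect_true(is.na(intersect_track_end(track, tri, "end", extension_mm = 0.5)))
})

test_that("endpoint assignment matches the brute-force all-triangle oracle", {
  mesh <- memo("ico2_oracle", make_hemisphere_mesh(2, 20))
  set.seed(31)
  n_agree <- 0L
  for (i in 1:200) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    # random radial track ending near the surface (inside or outside)
    r_end <- 20 + runif(1, -4, 4)
    track <- rbind(u * (r_end - 8), u * (r_end - 4), u * r_end)
    got <- intersect_track_end(track, mesh, "end")
    want <- oracle_assign_end(mesh, track, "end")
    expect_identical(got, want)
    n_agree <- n_agree + identical(got, want)
  }
  expect_equal(n_agree, 200L)
})

test_that("long-range build counts, filters, and accumulates lengths", {
  mesh <- icosahedron_mesh(50)
  v1 <- mesh$vertices[1, ]; v2 <- mesh$vertices[7, ]
  mk_track <- function(a, b, lift = 0.9) {
    mid <- (a + b) / 2 * lift
    rbind(a * 1.01, mid, b * 1.01)
  }
  tr <- mk_track(v1, v2)
  ss <- streamline_set(list(tr, tr))
  wc <- build_long_range(ss, mesh)
  expect_equal(wc$C[1, 7], 2)
  expect_equal(wc$C[7, 1], 2)
  expect_equal(wc$Lbar[1, 7], polyline_len <- streamline_lengths(ss)[1])
  expect_equal(wc$counts$kept, 2L)
  expect_true(Matrix::isSymmetric(wc$C))
  expect_true(all(Matrix::diag(wc$C) == 0))
  # tracks shorter than 10 mm are discarded even with perfect intersections
  short_mesh <- make_hemisphere_mesh(2, 20)
  a <- short_mesh$vertices[1, ]
  nb <- mesh_edges(short_mesh)
  b <- short_mesh$vertices[nb[nb[, 1] == 1, 2][1], ]
  short_tr <- rbind(a * 1.001, (a + b) / 2 * 0.9, b * 1.001)
  ss2 <- streamline_set(list(short_tr))
  expect_lt(streamline_lengths(ss2), 10)
  wc2 <- build_long_range(ss2, short_mesh)
  expect_equal(wc2$counts$discarded_short, 1L)
  expect_equal(Matrix::nnzero(wc2$C), 0)
  # empty input, and kept + discarded == total
  wc3 <- build_long_range(streamline_set(list()), mesh)
  expect_equal(Matrix::nnzero(wc3$C), 0)
  b <- small_build()
  with(b$wc$counts,
       expect_equal(kept + discarded_short + discarded_unresolved + discarded_self,
                    total))
})

test_that("local adjacency matches kernel width definitions and a BFS oracle", {
  expect_error(build_local_adjacency(triangle_mesh(), 3), "lambda_s")
  l1 <- build_local_adjacency(triangle_mesh(), 1)
  expect_equal(Matrix::nnzero(l1$A) / 2, 3)
  ico <- icosahedron_mesh()
  d1 <- Matrix::rowSums(build_local_adjacency(ico, 1)$A)
  expect_true(all(d1 == 5))
  # lambda_s = 2 equals the BFS distance <= 2 neighbourhood
  sph <- make_hemisphere_mesh(2, 30)
  l2 <- build_local_adjacency(sph, 2)
  g <- igraph::graph_from_edgelist(mesh_edges(sph), directed = FALSE)
  bfs_deg <- vapply(seq_len(sph$m), function(v)
    sum(igraph::distances(g, v = v, weights = NA) <= 2) - 1L, numeric(1))
  expect_equal(unname(Matrix::rowSums(l2$A)), bfs_deg)
  expect_true(all(Matrix::diag(l2$A) == 0))
})

test_that("z-scoring uses the nonzero weight population", {
  m <- 4L
  C <- Matrix::sparseMatrix(i = c(1, 1, 2), j = c(2, 3, 4), x = c(1, 2, 3),
                            dims = c(m, m), symmetric = TRUE)
  wc <- structure(list(C = as(C, "CsparseMatrix"), Lbar = C, m = m),
                  class = "weighted_connectome")
  wc <- zscore_weights(wc)
  expect_equal(wc$mu_C, 2)
  z <- sort(wc$Cz[cbind(c(1, 1, 2), c(2, 3, 4))])
  expect_equal(z, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  # z-scores of the support have mean 0 and population sd 1
  expect_equal(mean(z), 0)
  expect_equal(sqrt(mean(z^2)), 1)
  # constant weights are degenerate
  Cc <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 3), x = c(5, 5),
                             dims = c(m, m), symmetric = TRUE)
  wcc <- structure(list(C = as(Cc, "CsparseMatrix"), Lbar = Cc, m = m),
                   class = "weighted_connectome")
  expect_error(zscore_weights(wcc), "degenerate")
})

test_that("thresholding is nested and keeps only strong weights", {
  m <- 6L
  ij <- cbind(c(1, 1, 2, 3, 4), c(2, 3, 4, 5, 6))
  C <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = c(1, 1, 1, 1, 10),
                            dims = c(m, m), symmetric = TRUE)
  wc <- structure(list(C = as(C, "CsparseMatrix"), Lbar = C, m = m),
                  class = "weighted_connectome")
  wc <- zscore_weights(wc)
  # only the weight-10 pair exceeds one sd
  a1 <- threshold_long_range(wc, 1)
  expect_equal(Matrix::nnzero(a1$A_c) / 2, 1)
  expect_equal(a1$A_c[4, 6], 1)
  # below the minimum z-score the support is the full C support
  alow <- threshold_long_range(wc, min(wc$Cz@x) - 1)
  expect_equal(Matrix::nnzero(alow$A_c), Matrix::nnzero(wc$C))
  # above the maximum: empty
  ahigh <- threshold_long_range(wc, max(wc$Cz@x) + 1)
  expect_equal(Matrix::nnzero(ahigh$A_c), 0)
  # nestedness on a real build
  b <- small_build()
  prev <- NULL
  for (zc in c(0, 0.5, 1, 2)) {
    cur <- threshold_long_range(b$wc, zc)$A_c
    if (!is.null(prev)) expect_equal(Matrix::nnzero(cur - prev > 0), 0)
    prev <- cur
  }
})

test_that("combining is a binary union with correct edge arithmetic", {
  m <- 10L
  e_l <- cbind(1:5, 2:6)
  e_c <- cbind(c(3, 4, 7, 8), c(4, 5, 8, 9))   # overlaps (3,4) and (4,5)
  Al <- Matrix::sparseMatrix(i = e_l[, 1], j = e_l[, 2], x = 1, dims = c(m, m),
                             symmetric = TRUE)
  Ac <- Matrix::sparseMatrix(i = e_c[, 1], j = e_c[, 2], x = 1, dims = c(m, m),
                             symmetric = TRUE)
  comb <- combine_connectome(as(Al, "CsparseMatrix"), as(Ac, "CsparseMatrix"))
  expect_equal(Matrix::nnzero(comb$A) / 2, 5 + 4 - 2)
  expect_true(all(comb$A@x == 1))
  # A_c empty returns the local adjacency
  empty <- Matrix::sparseMatrix(i = integer(0), j = integer(0), dims = c(m, m))
  expect_equal(Matrix::nnzero(combine_connectome(Al, empty)$A - Al), 0)
  expect_error(combine_connectome(Al, Matrix::Diagonal(4)), "differ")
})

test_that("the local ratio follows its definition and grows with z_C", {
  m <- 30L
  mk <- function(n_edges, offset = 0) {
    i <- seq_len(n_edges) %% (m - 1) + 1
    Matrix::sparseMatrix(i = i, j = pmin(i + 1 + offset, m), x = 1,
                         dims = c(m, m), symmetric = TRUE)
  }
  b <- small_build()
  expect_equal(local_ratio(mk(10), mk(5, 3)), 10 / 15)
  empty <- Matrix::sparseMatrix(i = integer(0), j = integer(0), dims = dim(b$local$A))
  expect_equal(local_ratio(b$local$A, empty), 1)
  expect_error(local_ratio(empty, empty), "undefined")
  # monotone non-decreasing in z_C
  rs <- vapply(c(0, 0.5, 1, 2, 4),
               function(zc) local_ratio(b$local, threshold_long_range(b$wc, zc)),
               numeric(1))
  expect_true(all(diff(rs) >= 0))
})
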