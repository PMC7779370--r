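#' Cortical mesh objects
#'
#' A `cortical_mesh` is a triangulated surface: an `m x 3` matrix of vertex
#' coordinates in millimetres, a `t x 3` integer matrix of triangle vertex
#' indices (1-based), and a per-vertex hemisphere label (`"left"` / `"right"`).
#' Meshes stand in for FreeSurfer cortical surfaces; the synthetic generator
#' produces sphere-like hemispheres whose edge lengths match the 1-6 mm scale
#' of local gray-matter connectivity.
#'
#' @param vertices numeric matrix, m x 3, coordinates in mm.
#' @param triangles integer matrix, t x 3, 1-based vertex indices.
#' @param hemisphere character vector of length m, `"left"` or `"right"`.
#' @return An object of class `cortical_mesh`.
#' @export
cortical_mesh <- function(vertices, triangles, hemisphere = rep("left", nrow(vertices))) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  m <- nrow(vertices)
  if (ncol(vertices) != 3L) stop_invalid("vertices must be an m x 3 matrix")
  if (ncol(triangles) != 3L) stop_invalid("triangles must be a t x 3 matrix")
  if (nrow(triangles) > 0L && (min(triangles) < 1L || max(triangles) > m))
    stop_invalid("triangle indices out of range [1, m]")
  if (length(hemisphere) != m)
    stop_invalid("hemisphere labels must cover all vertices")
  if (!all(hemisphere %in% c("left", "right")))
    stop_invalid("hemisphere labels must be 'left' or 'right'")
  structure(list(vertices = vertices, triangles = triangles,
                 hemisphere = as.character(hemisphere), m = m),
            class = "cortical_mesh")
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat(sprintf("cortical_mesh: %d vertices, %d triangles (%d left / %d right)\n",
              x$m, nrow(x$triangles),
              sum(x$hemisphere == "left"), sum(x$hemisphere == "right")))
  invisible(x)
}

# Base icosahedron with unit circumradius.
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, triangles = f)
}

# One 4-to-1 triangle subdivision pass with midpoint de-duplication; vertices
# are re-projected onto the unit sphere.
subdivide_sphere <- function(v, f) {
  nv <- nrow(v)
  key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  e1 <- key(f[, 1], f[, 2]); e2 <- key(f[, 2], f[, 3]); e3 <- key(f[, 3], f[, 1])
  ekeys <- unique(c(e1, e2, e3))
  eidx <- seq_along(ekeys) + nv
  names(eidx) <- ekeys
  pairs <- do.call(rbind, strsplit(ekeys, "_"))
  a <- as.integer(pairs[, 1]); b <- as.integer(pairs[, 2])
  mid <- (v[a, , drop = FALSE] + v[b, , drop = FALSE]) / 2
  mid <- mid / row_norms(mid)
  m1 <- eidx[e1]; m2 <- eidx[e2]; m3 <- eidx[e3]
  newf <- rbind(cbind(f[, 1], m1, m3),
                cbind(f[, 2], m2, m1),
                cbind(f[, 3], m3, m2),
                cbind(m1, m2, m3))
  list(vertices = rbind(v, mid), triangles = unname(newf))
}

#' Generate one sphere-like hemisphere mesh
#'
#' Builds an icosphere (recursively subdivided icosahedron projected onto a
#' sphere), scales it to `radius_mm`, optionally perturbs every vertex with
#' isotropic Gaussian jitter, and translates it to `center`. An icosphere at
#' subdivision level `s` has `10 * 4^s + 2` vertices and `20 * 4^s` triangles.
#'
#' @param subdivisions integer >= 0, icosphere refinement level.
#' @param radius_mm positive sphere radius in mm.
#' @param center numeric length-3 center in mm.
#' @param vertex_jitter_mm nonnegative sd of isotropic Gaussian vertex jitter.
#' @param seed optional integer seed for the jitter.
#' @param hemisphere label assigned to every vertex.
#' @return A [cortical_mesh()].
#' @export
make_hemisphere_mesh <- function(subdivisions, radius_mm, center = c(0, 0, 0),
                                 vertex_jitter_mm = 0, seed = NULL,
                                 hemisphere = "left") {
  if (subdivisions < 0) stop_invalid("'subdivisions' must be >= 0")
  if (!is.numeric(radius_mm) || radius_mm <= 0) stop_invalid("'radius_mm' must be positive")
  if (vertex_jitter_mm < 0) stop_invalid("'vertex_jitter_mm' must be nonnegative")
  ico <- icosahedron()
  v <- ico$vertices; f <- ico$triangles
  for (i in seq_len(subdivisions)) {
    sub <- subdivide_sphere(v, f)
    v <- sub$vertices; f <- sub$triangles
  }
  v <- v * radius_mm
  if (vertex_jitter_mm > 0) {
    v <- v + with_local_seed(seed, matrix(rnorm(length(v), sd = vertex_jitter_mm),
                                          ncol = 3))
  }
  v <- sweep(v, 2, center, "+")
  cortical_mesh(v, f, rep(hemisphere, nrow(v)))
}

#' Unique undirected edges of a mesh
#'
#' @param mesh a [cortical_mesh()].
#' @return Integer matrix with columns `i`, `j` (`i < j`), one row per edge.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$triangles
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  colnames(e) <- c("i", "j")
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' Euclidean lengths of a set of vertex-pair edges
#'
#' @param mesh a [cortical_mesh()].
#' @param edges integer matrix with columns `i`, `j`; defaults to the mesh edges.
#' @return Numeric vector of lengths in mm.
#' @export
edge_lengths <- function(mesh, edges = mesh_edges(mesh)) {
  d <- mesh$vertices[edges[, 1], , drop = FALSE] -
       mesh$vertices[edges[, 2], , drop = FALSE]
  row_norms(d)
}

#' Merge two hemisphere meshes into one brain mesh
#'
#' Concatenates vertices and triangles of a left and a right hemisphere mesh
#' (offsetting the right triangle indices); no triangle spans hemispheres.
#'
#' @param left,right [cortical_mesh()] objects.
#' @return A [cortical_mesh()] with hemisphere labels `"left"` then `"right"`.
#' @export
merge_hemisphere_meshes <- function(left, right) {
  cortical_mesh(rbind(left$vertices, right$vertices),
                rbind(left$triangles, right$triangles + left$m),
                c(rep("left", left$m), rep("right", right$m)))
}

#' Laplacian mesh smoothing with inverse-distance weights
#'
#' Each iteration moves every vertex to the inverse-distance-weighted mean of
#' its mesh neighbours, with the weights `1 / dist(i, j)` recomputed from the
#' current iterate's coordinates. The triangle list (topology) is unchanged.
#'
#' @param mesh a [cortical_mesh()].
#' @param f_i number of smoothing iterations (0 returns the mesh unchanged).
#'   The study grid uses Fibonacci values 0, 8, 21, 89.
#' @return The smoothed [cortical_mesh()].
#' @export
smooth_mesh <- function(mesh, f_i) {
  if (f_i < 0) stop_invalid("'f_i' must be nonnegative")
  f_i <- as.integer(f_i)
  if (f_i == 0L) return(mesh)
  edges <- mesh_edges(mesh)
  ii <- c(edges[, 1], edges[, 2])
  jj <- c(edges[, 2], edges[, 1])
  v <- mesh$vertices
  m <- mesh$m
  for (it in seq_len(f_i)) {
    d <- row_norms(v[ii, , drop = FALSE] - v[jj, , drop = FALSE])
    w <- 1 / pmax(d, 1e-12)
    W <- Matrix::sparseMatrix(i = ii, j = jj, x = w, dims = c(m, m))
    v <- as.matrix(W %*% v) / Matrix::rowSums(W)
  }
  cortical_mesh(v, mesh$triangles, mesh$hemisphere)
}
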