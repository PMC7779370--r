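# Precomputed triangle geometry + vertex->triangle incidence for fast
# segment-mesh intersection queries.
mesh_triangle_cache <- function(mesh) {
  f <- mesh$triangles
  v <- mesh$vertices
  v0 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - v0
  e2 <- v[f[, 3], , drop = FALSE] - v0
  vert_tri <- split(rep(seq_len(nrow(f)), 3), as.vector(f))
  list(mesh = mesh, v0 = v0, e1 = e1, e2 = e2, f = f, vert_tri = vert_tri)
}

# Moller-Trumbore segment/triangle intersection of segment p0 -> p1 against the
# triangle subset `tris`. Returns hits as (triangle, t in [0,1], point).
segment_triangle_hits <- function(cache, p0, p1, tris) {
  if (length(tris) == 0) return(NULL)
  d <- p1 - p0
  v0 <- cache$v0[tris, , drop = FALSE]
  e1 <- cache$e1[tris, , drop = FALSE]
  e2 <- cache$e2[tris, , drop = FALSE]
  h <- cross3_vec_mat(d, e2)
  a <- rowSums(e1 * h)
  ok <- abs(a) > 1e-12
  if (!any(ok)) return(NULL)
  s <- sweep(-v0, 2, p0, "+")       # p0 - v0
  u <- rowSums(s * h) / a
  q <- cross3_mat_mat(s, e1)
  vv <- as.numeric(q %*% d) / a
  t <- rowSums(e2 * q) / a
  hit <- ok & u >= 0 & vv >= 0 & (u + vv) <= 1 & t >= 0 & t <= 1
  if (!any(hit)) return(NULL)
  idx <- which(hit)
  pts <- matrix(rep(p0, length(idx)), ncol = 3, byrow = TRUE) +
    outer(t[idx], d)
  list(tri = tris[idx], t = t[idx], points = pts)
}

# Candidate triangles: all triangles touching a vertex within `radius` of `p`.
candidate_triangles <- function(cache, p, radius) {
  d2 <- rowSums(sweep(cache$mesh$vertices, 2, p)^2)
  near <- which(d2 <= radius * radius)
  if (length(near) == 0) return(integer(0))
  unique(unlist(cache$vert_tri[as.character(near)], use.names = FALSE))
}

# Resolve one intersection search against a triangle subset: the hit nearest to
# `ref` wins; the assigned vertex is the hit triangle's vertex nearest to the
# intersection point, ties broken by lowest vertex index.
resolve_hit <- function(cache, hits, ref) {
  if (is.null(hits)) return(NULL)
  d2 <- rowSums(sweep(hits$points, 2, ref)^2)
  k <- which.min(d2)
  tri <- hits$tri[k]
  pt <- hits$points[k, ]
  verts <- sort(cache$f[tri, ])
  vd <- row_norms(sweep(cache$mesh$vertices[verts, , drop = FALSE], 2, pt))
  # rounding makes exact ties (e.g. centroid hits) resolve by lowest index
  verts[which.min(round(vd, 9))]
}

intersect_end_cached <- function(cache, track, which_end, extension_mm, max_gap_mm) {
  n <- nrow(track)
  if (which_end == "start") {
    endpoint <- track[1, ]; inner <- track[2, ]; third <- track[3, ]
  } else {
    endpoint <- track[n, ]; inner <- track[n - 1, ]; third <- track[n - 2, ]
  }
  # gap filter: endpoint farther than max_gap from the surface (nearest vertex)
  d2 <- rowSums(sweep(cache$mesh$vertices, 2, endpoint)^2)
  if (min(d2) > max_gap_mm^2) return(NA_integer_)
  seg_len <- sqrt(sum((endpoint - inner)^2))
  radius <- seg_len + extension_mm + max_gap_mm + 10
  tris <- candidate_triangles(cache, endpoint, radius)
  hit <- resolve_hit(cache,
                     segment_triangle_hits(cache, inner, endpoint, tris),
                     ref = endpoint)
  if (!is.null(hit)) return(hit)
  # linear extension along the third-last -> endpoint direction
  dirv <- endpoint - third
  nd <- sqrt(sum(dirv^2))
  if (nd < 1e-12 || extension_mm <= 0) return(NA_integer_)
  ext <- endpoint + dirv / nd * extension_mm
  hit <- resolve_hit(cache,
                     segment_triangle_hits(cache, endpoint, ext, tris),
                     ref = endpoint)
  if (is.null(hit)) NA_integer_ else hit
}

#' Assign a streamline endpoint to a cortical mesh vertex
#'
#' Tests the track's terminal segment against the mesh triangles; if it does
#' not cross the surface, the segment is extended by `extension_mm` along the
#' direction from the third-last track point to the endpoint and tested again.
#' On intersection the assigned vertex is the hit triangle's vertex nearest to
#' the intersection point (ties broken by lowest vertex index); if a segment
#' crosses several triangles the crossing nearest to the track endpoint wins.
#' Endpoints farther than `max_gap_mm` from the surface are rejected outright.
#'
#' @param track matrix of >= 3 polyline points (mm).
#' @param mesh a [cortical_mesh()].
#' @param which_end `"start"` or `"end"`.
#' @param extension_mm linear extension length, mm (default 3).
#' @param max_gap_mm maximum endpoint-to-surface distance, mm (default 5).
#' @return The 1-based vertex index, or `NA` if the end is unresolved.
#' @export
intersect_track_end <- function(track, mesh, which_end = c("end", "start"),
                                extension_mm = 3, max_gap_mm = 5) {
  which_end <- match.arg(which_end)
  track <- as.matrix(track)
  if (nrow(track) < 3L) stop_invalid("track must have >= 3 points")
  if (extension_mm < 0) stop_invalid("'extension_mm' must be >= 0")
  cache <- mesh_triangle_cache(mesh)
  intersect_end_cached(cache, track, which_end, extension_mm, max_gap_mm)
}

#' Weighted long-range connectome from streamlines
#'
#' Builds the sparse symmetric streamline-count matrix `C` (and companion mean
#' track length matrix `Lbar`) by intersecting both ends of every streamline
#' with the cortical surface mesh. Tracks shorter than `min_track_length_mm`
#' are discarded; tracks with either end unresolved (no intersection within
#' the extension, or endpoint beyond `max_gap_mm` of the surface) are
#' discarded; tracks whose two ends map to the same vertex are discarded.
#' Each surviving track increments `C[i, j]` and `C[j, i]` by 1 and
#' accumulates its length into the pair's mean.
#'
#' @param streamlines a [streamline_set()].
#' @param mesh a [cortical_mesh()].
#' @param min_track_length_mm minimum track length kept, mm (default 10).
#' @param extension_mm see [intersect_track_end()].
#' @param max_gap_mm see [intersect_track_end()].
#' @return Object of class `weighted_connectome`: `C` (sparse integer counts),
#'   `Lbar` (sparse mean lengths on the support of `C`), `m`, and a `counts`
#'   list (`kept`, `discarded_short`, `discarded_unresolved`,
#'   `discarded_self`).
#' @export
build_long_range <- function(streamlines, mesh, min_track_length_mm = 10,
                             extension_mm = 3, max_gap_mm = 5) {
  if (mesh$m == 0L) stop_invalid("mesh is empty")
  cache <- mesh_triangle_cache(mesh)
  ntr <- length(streamlines$tracks)
  vi <- integer(ntr); vj <- integer(ntr); len <- numeric(ntr)
  kept <- 0L; d_short <- 0L; d_unres <- 0L; d_self <- 0L
  for (k in seq_len(ntr)) {
    trk <- streamlines$tracks[[k]]
    L <- streamlines$lengths[k]
    if (L < min_track_length_mm) { d_short <- d_short + 1L; next }
    a <- intersect_end_cached(cache, trk, "start", extension_mm, max_gap_mm)
    if (is.na(a)) { d_unres <- d_unres + 1L; next }
    b <- intersect_end_cached(cache, trk, "end", extension_mm, max_gap_mm)
    if (is.na(b)) { d_unres <- d_unres + 1L; next }
    if (a == b) { d_self <- d_self + 1L; next }
    kept <- kept + 1L
    vi[kept] <- min(a, b); vj[kept] <- max(a, b); len[kept] <- L
  }
  m <- mesh$m
  if (kept > 0L) {
    vi <- vi[seq_len(kept)]; vj <- vj[seq_len(kept)]; len <- len[seq_len(kept)]
    Cu <- Matrix::sparseMatrix(i = vi, j = vj, x = 1, dims = c(m, m))
    Su <- Matrix::sparseMatrix(i = vi, j = vj, x = len, dims = c(m, m))
    Lu <- Su
    Lu@x <- Su@x / Cu@x
    C <- Cu + Matrix::t(Cu)
    Lbar <- Lu + Matrix::t(Lu)
  } else {
    C <- Matrix::sparseMatrix(i = integer(0), j = integer(0), dims = c(m, m))
    Lbar <- C
  }
  structure(list(C = C, Lbar = Lbar, m = m,
                 mu_C = NULL, sigma_C = NULL, Cz = NULL,
                 counts = list(kept = kept, discarded_short = d_short,
                               discarded_unresolved = d_unres,
                               discarded_self = d_self,
                               total = ntr)),
            class = "weighted_connectome")
}

#' @export
print.weighted_connectome <- function(x, ...) {
  cat(sprintf("weighted_connectome: %d vertices, %d connected pairs, %d tracks kept of %d\n",
              x$m, edge_count(as_binary_pattern(x$C)), x$counts$kept, x$counts$total))
  invisible(x)
}
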