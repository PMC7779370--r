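#' Contiguous geodesic parcellation of a brain mesh
#'
#' Partitions the vertices of each hemisphere into contiguous, roughly
#' equal-area regions: region seeds are chosen by farthest-point sampling on
#' the mesh edge graph (geodesic distances, edge-length weighted) and every
#' vertex is assigned to its nearest seed. This is the synthetic stand-in for
#' an anatomical atlas such as Desikan-Killiany.
#'
#' @param mesh a [cortical_mesh()] (one or two hemispheres).
#' @param n_regions_per_hemisphere number of regions per hemisphere.
#' @return An object of class `atlas_parcellation`: list with `region`
#'   (integer per vertex, contiguous ids from 1), `n_regions`, and
#'   `hemisphere_of_region`.
#' @export
make_parcellation <- function(mesh, n_regions_per_hemisphere) {
  if (n_regions_per_hemisphere < 1)
    stop_invalid("'n_regions_per_hemisphere' must be >= 1")
  edges <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = edge_lengths(mesh, edges))
  if (igraph::vcount(g) < mesh$m)
    g <- igraph::add_vertices(g, mesh$m - igraph::vcount(g))
  region <- integer(mesh$m)
  hemis <- unique(mesh$hemisphere)
  offset <- 0L
  hemi_of_region <- character(0)
  for (h in hemis) {
    idx <- which(mesh$hemisphere == h)
    k <- min(n_regions_per_hemisphere, length(idx))
    seeds <- idx[1]
    if (k > 1) {
      dmin <- igraph::distances(g, v = seeds, to = idx)[1, ]
      for (s in 2:k) {
        nxt <- idx[which.max(dmin)]
        seeds <- c(seeds, nxt)
        dmin <- pmin(dmin, igraph::distances(g, v = nxt, to = idx)[1, ])
      }
    }
    dmat <- igraph::distances(g, v = seeds, to = idx)
    region[idx] <- offset + apply(dmat, 2, which.min)
    hemi_of_region <- c(hemi_of_region, rep(h, k))
    offset <- offset + k
  }
  centroids <- t(vapply(seq_len(offset), function(r)
    colMeans(mesh$vertices[region == r, , drop = FALSE]), numeric(3)))
  structure(list(region = region, n_regions = offset,
                 hemisphere_of_region = hemi_of_region,
                 centroids = centroids),
            class = "atlas_parcellation")
}

#' @export
print.atlas_parcellation <- function(x, ...) {
  cat(sprintf("atlas_parcellation: %d regions over %d vertices\n",
              x$n_regions, length(x$region)))
  invisible(x)
}

#' Plant a binary resting-state-network map from parcellation regions
#'
#' Selects a spatially clustered, homotopic set of patches: a randomly
#' seeded region of the left hemisphere plus its `n_rsn_patches - 1`
#' nearest neighbours by centroid distance, and the mirror-image cluster of
#' the right hemisphere (regions nearest to the reflected left-cap
#' centroid). All their vertices are marked as network members. The result
#' emulates a bilateral resting-state-network map: a union of whole
#' cortical patches occupying mirrored territories, as resting-state
#' networks do.
#'
#' @param parcellation an [make_parcellation()] result.
#' @param n_rsn_patches regions per hemisphere to include (0 gives an all-zero
#'   map, the per-hemisphere region count gives an all-one map).
#' @param seed integer seed for the seed-patch choice.
#' @return List of class `rsn_map`: `map` (0/1 integer per vertex) and
#'   `regions` (selected region ids).
#' @export
make_rsn <- function(parcellation, n_rsn_patches, seed = NULL) {
  hemis <- unique(parcellation$hemisphere_of_region)
  counts <- table(factor(parcellation$hemisphere_of_region, levels = hemis))
  if (any(n_rsn_patches > counts))
    stop_invalid("'n_rsn_patches' exceeds the number of regions in a hemisphere")
  if (n_rsn_patches < 0) stop_invalid("'n_rsn_patches' must be >= 0")
  picked <- with_local_seed(seed, {
    if (n_rsn_patches == 0) {
      integer(0)
    } else {
      first <- which(parcellation$hemisphere_of_region == hemis[1])
      seed_reg <- if (length(first) == 1) first else sample(first, 1)
      near_cluster <- function(ids, target) {
        d <- rowSums(sweep(parcellation$centroids[ids, , drop = FALSE], 2, target)^2)
        sort(ids[order(d)][seq_len(n_rsn_patches)])
      }
      left_cap <- near_cluster(first, parcellation$centroids[seed_reg, ])
      out <- left_cap
      if (length(hemis) > 1) {
        # homotopic counterpart: mirror the left-cap centroid across x = 0
        mirror <- colMeans(parcellation$centroids[left_cap, , drop = FALSE]) *
          c(-1, 1, 1)
        others <- which(parcellation$hemisphere_of_region == hemis[2])
        out <- c(left_cap, near_cluster(others, mirror))
      }
      out
    }
  })
  map <- as.integer(parcellation$region %in% picked)
  structure(list(map = map, regions = picked), class = "rsn_map")
}

#' Project a per-vertex vector to atlas space
#'
#' Region value = unweighted mean of the vertex values inside the region.
#' Used to compare harmonics across meshes whose vertex orderings differ.
#'
#' @param x numeric per-vertex vector.
#' @param parcellation an `atlas_parcellation` covering all vertices.
#' @return Numeric vector of length `n_regions`, ordered by region id.
#' @export
project_to_atlas <- function(x, parcellation) {
  if (length(x) != length(parcellation$region))
    stop_invalid("vector length does not match the parcellation")
  if (any(parcellation$region < 1L | parcellation$region > parcellation$n_regions))
    stop_invalid("parcellation leaves vertices unmapped")
  as.numeric(tapply(x, factor(parcellation$region,
                              levels = seq_len(parcellation$n_regions)), mean))
}

#' Real spherical harmonic evaluated on a sphere-like mesh
#'
#' Evaluates the real orthonormal spherical harmonic `Y_lm` at the direction of
#' each mesh vertex relative to `center`. These analytic references anchor the
#' sphere-limit validation: without long-range edges, the low graph-Laplacian
#' eigenmodes of a jitter-free icosphere span the spherical harmonics of
#' matching degree.
#'
#' @param degree_l integer degree `l >= 0`.
#' @param order_m integer order, `|m| <= l`.
#' @param mesh a single sphere-like [cortical_mesh()].
#' @param center sphere center (defaults to the vertex centroid).
#' @return Numeric vector of length `m` (one value per vertex).
#' @export
spherical_harmonic_reference <- function(degree_l, order_m, mesh,
                                         center = colMeans(mesh$vertices)) {
  l <- as.integer(degree_l); mm <- as.integer(order_m)
  if (l < 0) stop_invalid("'degree_l' must be >= 0")
  if (abs(mm) > l) stop_invalid("|order_m| must be <= degree_l")
  v <- sweep(mesh$vertices, 2, center)
  v <- v / row_norms(v)
  ct <- pmin(pmax(v[, 3], -1), 1)
  phi <- atan2(v[, 2], v[, 1])
  am <- abs(mm)
  # pracma::legendre returns rows m = 0..l of the associated Legendre P_l^m
  # (MATLAB convention, Condon-Shortley phase included).
  P <- pracma::legendre(l, ct)
  Plm <- if (l == 0) rep(1, length(ct)) else P[am + 1L, ]
  norm <- sqrt((2 * l + 1) / (4 * pi) *
               exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
  if (mm == 0) {
    norm * Plm
  } else if (mm > 0) {
    sqrt(2) * norm * Plm * cos(am * phi)
  } else {
    sqrt(2) * norm * Plm * sin(am * phi)
  }
}
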