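#' Configuration for the synthetic brain generator
#'
#' Bundles every parameter of the synthetic two-hemisphere brain: mesh
#' geometry, streamline counts and length law, planted network structure, and
#' the master seed. Identical configurations with identical seeds reproduce
#' bit-identical meshes, streamlines, parcellations, and maps.
#'
#' Defaults describe the study conditions used throughout the package's
#' validation: two subdivision-3 icospheres of radius 35 mm (mean edge length
#' about 5 mm, within the 1-6 mm local-connectivity scale) with 0.5 mm vertex
#' jitter; 20,000 streamlines organized as repeated fiber bundles (about 5
#' streamlines per bundle), of which 20% are inter-hemispheric with homotopic
#' bias and 2% deliberately short (< 10 mm) to exercise the length filter;
#' 17 contiguous regions per hemisphere; and a bilateral, homotopic planted
#' network of 4 adjacent patches per hemisphere whose territory receives 30%
#' of the intra-hemispheric tracks as network-binding association bundles,
#' with a further 30% same-region (modular) and 25% long (> 1 rad) background
#' bundles, the rest following the right-skewed gamma angular length law.
#'
#' @param subdivisions icosphere refinement level per hemisphere.
#' @param radius_mm hemisphere sphere radius, mm.
#' @param hemisphere_gap_mm surface-to-surface gap between hemispheres
#'   (center separation minus the two radii); must be positive.
#' @param vertex_jitter_mm sd of isotropic Gaussian vertex jitter, mm.
#' @param n_streamlines number of streamlines to generate.
#' @param inter_fraction fraction of streamlines that are inter-hemispheric.
#' @param length_shape length-2 vector `(shape, scale)` of the gamma law for
#'   the angular distance (radians) between intra-hemispheric endpoints.
#' @param endpoint_offset_sd_mm sd of the Gaussian endpoint displacement off
#'   the surface, mm.
#' @param short_track_fraction fraction of tracks planted below 10 mm.
#' @param n_regions_per_hemisphere parcellation regions per hemisphere.
#' @param n_rsn_patches planted network patches per hemisphere.
#' @param rsn_coupling fraction of intra-hemispheric tracks whose endpoints are
#'   both drawn from a single planted network patch.
#' @param region_bias fraction of the remaining intra-hemispheric tracks whose
#'   endpoints are both drawn from one (any) parcellation region — the
#'   modular, spatially local white-matter structure that intra-hemispheric
#'   randomization destroys.
#' @param long_bundle_fraction fraction of the then-remaining
#'   intra-hemispheric tracks forming long (> ~1 rad angular span) bundles
#'   between unrelated locations — the strongly weighted long fibers whose
#'   removal by descending-length trimming is felt first.
#' @param weight_sdlog sdlog of the lognormal per-vertex sampling weights
#'   (heavy-tailed pairwise streamline counts).
#' @param seed master integer seed.
#' @return A list of class `synth_brain_config`.
#' @export
synth_brain_config <- function(subdivisions = 3,
                               radius_mm = 35,
                               hemisphere_gap_mm = 10,
                               vertex_jitter_mm = 0.5,
                               n_streamlines = 20000,
                               inter_fraction = 0.2,
                               length_shape = c(2, 0.35),
                               endpoint_offset_sd_mm = 1,
                               short_track_fraction = 0.02,
                               n_regions_per_hemisphere = 17,
                               n_rsn_patches = 4,
                               rsn_coupling = 0.3,
                               region_bias = 0.3,
                               long_bundle_fraction = 0.25,
                               weight_sdlog = 0.5,
                               bundle_mean_count = 5,
                               seed = 1L) {
  if (subdivisions < 0) stop_invalid("'subdivisions' must be >= 0")
  if (radius_mm <= 0) stop_invalid("'radius_mm' must be positive")
  if (hemisphere_gap_mm <= 0)
    stop_invalid("'hemisphere_gap_mm' must be positive (hemispheres may not overlap)")
  if (vertex_jitter_mm < 0) stop_invalid("'vertex_jitter_mm' must be nonnegative")
  if (n_streamlines < 0) stop_invalid("'n_streamlines' must be >= 0")
  check_fraction(inter_fraction, "inter_fraction")
  check_fraction(short_track_fraction, "short_track_fraction")
  check_fraction(rsn_coupling, "rsn_coupling")
  check_fraction(region_bias, "region_bias")
  check_fraction(long_bundle_fraction, "long_bundle_fraction")
  if (bundle_mean_count < 1) stop_invalid("'bundle_mean_count' must be >= 1")
  if (inter_fraction + short_track_fraction > 1)
    stop_invalid("inter_fraction + short_track_fraction must be <= 1")
  if (endpoint_offset_sd_mm < 0) stop_invalid("'endpoint_offset_sd_mm' must be nonnegative")
  structure(as.list(environment()), class = "synth_brain_config")
}

#' Build a synthetic two-hemisphere brain mesh and parcellation
#'
#' Two jittered icospheres separated along the x axis (no triangle spans
#' hemispheres), plus a contiguous geodesic parcellation of each hemisphere.
#'
#' @param config a [synth_brain_config()].
#' @return List with `mesh` (a [cortical_mesh()], hemisphere labels inside),
#'   and `parcellation` (an `atlas_parcellation`).
#' @export
make_brain <- function(config) {
  stopifnot(inherits(config, "synth_brain_config"))
  half <- config$radius_mm + config$hemisphere_gap_mm / 2
  left <- make_hemisphere_mesh(config$subdivisions, config$radius_mm,
                               center = c(-half, 0, 0),
                               vertex_jitter_mm = config$vertex_jitter_mm,
                               seed = config$seed, hemisphere = "left")
  right <- make_hemisphere_mesh(config$subdivisions, config$radius_mm,
                                center = c(half, 0, 0),
                                vertex_jitter_mm = config$vertex_jitter_mm,
                                seed = config$seed + 1L, hemisphere = "right")
  mesh <- merge_hemisphere_meshes(left, right)
  parcellation <- make_parcellation(mesh, config$n_regions_per_hemisphere)
  list(mesh = mesh, parcellation = parcellation)
}

#' Streamline set container
#'
#' @param tracks list of polylines (matrices with 3 columns, ordered points in
#'   mm); every track must have at least 3 points.
#' @return Object of class `streamline_set` with per-track `lengths` (mm).
#' @export
streamline_set <- function(tracks) {
  if (length(tracks) > 0) {
    npts <- vapply(tracks, nrow, integer(1))
    if (any(npts < 3L)) stop_invalid("every track must have >= 3 points")
  }
  lengths <- vapply(tracks, polyline_length, numeric(1))
  structure(list(tracks = tracks, lengths = lengths), class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("streamline_set: %d tracks", length(x$tracks)))
  if (length(x$tracks))
    cat(sprintf(", length %.1f-%.1f mm (median %.1f)",
                min(x$lengths), max(x$lengths), stats::median(x$lengths)))
  cat("\n")
  invisible(x)
}

polyline_length <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(row_norms(p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]))
}

#' Per-track lengths of a streamline set
#' @param streamlines a [streamline_set()].
#' @return Numeric vector of lengths in mm.
#' @export
streamline_lengths <- function(streamlines) streamlines$lengths

# Polyline between two surface points: interior waypoints are bowed toward the
# hemisphere center(s) -- with a depth proportional to the chord, so short
# tracks stay short -- and terminal segments cross the surface outward;
# endpoints carry the Gaussian off-surface displacement.
build_polyline <- function(p1, p2, c1, c2, offset_sd) {
  chord <- sqrt(sum((p1 - p2)^2))
  depth <- min(0.15 * chord, 12)
  n <- max(3L, as.integer(ceiling(chord / 5)) + 1L)
  t <- seq(0, 1, length.out = n)
  base <- outer(1 - t, p1) + outer(t, p2)
  cmid <- outer(1 - t, c1) + outer(t, c2)
  off <- cmid - base
  nrm <- pmax(row_norms(off), 1e-9)
  pts <- base + off / nrm * (depth * sin(pi * t))
  pts[1, ] <- p1 + rnorm(3, sd = offset_sd)
  pts[n, ] <- p2 + rnorm(3, sd = offset_sd)
  pts
}

#' Generate synthetic tractography streamlines
#'
#' Samples streamline endpoint pairs on the mesh surface and connects them by
#' polylines with at least 3 points bowed through the interior. Streamlines
#' are organized as fiber *bundles*: a limited pool of endpoint vertex pairs
#' is drawn per track population and each streamline samples a bundle with
#' heavy-tailed (lognormal) bundle weights, so vertex pairs repeat the way
#' fascicles do and the pairwise streamline-count distribution has a heavy
#' tail. Five track populations are generated:
#'
#' * inter-hemispheric bundles (probability `inter_fraction`) with homotopic
#'   bias: the callosal endpoint clusters near the mirror image of its seed;
#' * deliberately short tracks below the 10 mm filter
#'   (`short_track_fraction`), connecting mesh neighbours;
#' * network bundles (`rsn_coupling` of the remaining intra-hemispheric
#'   tracks, when `rsn` is given): short association-fiber bundles densely
#'   wiring the contiguous planted network territory of each hemisphere;
#' * modular bundles (`region_bias` of the remainder): both endpoints inside
#'   one (any) parcellation region -- spatially local background wiring;
#' * diffuse background: endpoint pairs whose angular span follows the
#'   right-skewed gamma length law, essentially unrepeated (below the
#'   adjacency threshold).
#'
#' @param mesh a two-hemisphere [cortical_mesh()].
#' @param hemisphere per-vertex hemisphere labels (defaults to the mesh's).
#' @param config a [synth_brain_config()].
#' @param parcellation optional `atlas_parcellation` (needed for planting).
#' @param rsn optional `rsn_map` whose patches receive planted bundles.
#' @return A [streamline_set()].
#' @export
make_streamlines <- function(mesh, hemisphere = mesh$hemisphere, config,
                             parcellation = NULL, rsn = NULL) {
  stopifnot(inherits(config, "synth_brain_config"))
  if (mesh$m == 0L) stop_invalid("mesh is empty")
  n <- config$n_streamlines
  if (n == 0L) return(streamline_set(list()))
  with_local_seed(config$seed + 2L, {
    hemis <- c("left", "right")
    idx <- lapply(hemis, function(h) which(hemisphere == h))
    names(idx) <- hemis
    centers <- lapply(idx, function(i) colMeans(mesh$vertices[i, , drop = FALSE]))
    unit <- mesh$vertices
    for (h in hemis)
      unit[idx[[h]], ] <- sweep(mesh$vertices[idx[[h]], , drop = FALSE], 2, centers[[h]])
    unit <- unit / row_norms(unit)
    w <- rlnorm(mesh$m, meanlog = 0, sdlog = config$weight_sdlog)
    edges <- mesh_edges(mesh)
    nbr <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
    wsample <- function(pool, k = 1) {
      if (length(pool) == 1) rep(pool, k) else sample(pool, k, prob = w[pool])
    }

    # --- track population assignment ---
    p_inter <- config$inter_fraction
    p_short <- config$short_track_fraction
    u <- runif(n)
    type <- rep("bg", n)
    type[u < p_inter] <- "inter"
    type[u >= p_inter & u < p_inter + p_short] <- "short"
    plantable <- !is.null(parcellation)
    if (plantable && !is.null(rsn) && length(rsn$regions)) {
      bg_idx <- which(type == "bg")
      type[bg_idx[runif(length(bg_idx)) < config$rsn_coupling]] <- "rsn"
    }
    if (plantable) {
      bg_idx <- which(type == "bg")
      type[bg_idx[runif(length(bg_idx)) < config$region_bias]] <- "region"
    }
    bg_idx <- which(type == "bg")
    type[bg_idx[runif(length(bg_idx)) < config$long_bundle_fraction]] <- "long"
    home <- sample(hemis, n, replace = TRUE)

    # --- bundle pools: repeated endpoint pairs per population ---
    draw_inter_pair <- function() {
      v1 <- wsample(idx$left)
      mir <- unit[v1, ] * c(-1, 1, 1)
      ang <- acos(pmin(pmax(unit[idx$right, , drop = FALSE] %*% mir, -1), 1))
      wr <- w[idx$right] * exp(-(ang / 0.25)^2 / 2)
      if (sum(wr) <= 0) wr <- w[idx$right]
      c(v1, sample(idx$right, 1, prob = wr))
    }
    draw_rsn_pair <- function(h) {
      regs <- intersect(rsn$regions, which(parcellation$hemisphere_of_region == h))
      if (length(regs) == 0) regs <- rsn$regions
      verts <- which(parcellation$region %in% regs)
      pair <- wsample(verts, 2)
      if (pair[2] == pair[1]) pair[2] <- nbr[[as.character(pair[1])]][1]
      pair
    }
    draw_region_pair <- function(h) {
      regs <- which(parcellation$hemisphere_of_region == h)
      if (!is.null(rsn)) regs <- setdiff(regs, rsn$regions)
      if (length(regs) == 0) regs <- which(parcellation$hemisphere_of_region == h)
      reg <- if (length(regs) == 1) regs else sample(regs, 1)
      wsample(which(parcellation$region == reg), 2)
    }
    draw_long_pair <- function(h) {
      ih <- idx[[h]]
      if (!is.null(rsn) && !is.null(parcellation))
        ih <- ih[!parcellation$region[ih] %in% rsn$regions]
      if (length(ih) < 2) ih <- idx[[h]]
      v1 <- wsample(ih)
      ang <- acos(pmin(pmax(unit[ih, , drop = FALSE] %*% unit[v1, ], -1), 1))
      far <- ih[ang > 1.0]
      if (length(far) == 0) far <- ih[ih != v1]
      c(v1, wsample(far))
    }
    theta_all <- pmin(pi - 1e-6,
                      pmax(0.05, rgamma(n, shape = config$length_shape[1],
                                        scale = config$length_shape[2])))
    draw_bg_pair <- function(h, theta) {
      ih <- idx[[h]]
      v1 <- wsample(ih)
      cand <- sample(ih, 40L, replace = TRUE, prob = w[ih])
      ang <- acos(pmin(pmax(unit[cand, , drop = FALSE] %*% unit[v1, ], -1), 1))
      keep <- cand != v1
      cand <- cand[keep]; ang <- ang[keep]
      v2 <- if (length(cand)) cand[which.min(abs(ang - theta))] else nbr[[as.character(v1)]][1]
      c(v1, v2)
    }

    make_pool <- function(n_tracks, drawfun) {
      if (n_tracks == 0L) return(NULL)
      size <- max(1L, ceiling(n_tracks / config$bundle_mean_count))
      pairs <- t(vapply(seq_len(size), function(i) as.integer(drawfun(i)), integer(2)))
      list(pairs = pairs, weights = rlnorm(size, 0, 0.5))
    }
    n_of <- table(factor(type,
      levels = c("inter", "short", "rsn", "region", "long", "bg")))
    hs_rsn <- sample(hemis, max(1, ceiling(n_of[["rsn"]] / config$bundle_mean_count)),
                     replace = TRUE)
    hs_reg <- sample(hemis, max(1, ceiling(n_of[["region"]] / config$bundle_mean_count)),
                     replace = TRUE)
    hs_long <- sample(hemis, max(1, ceiling(n_of[["long"]] / config$bundle_mean_count)),
                      replace = TRUE)
    pools <- list(
      inter = if (n_of[["inter"]] > 0)
        make_pool(n_of[["inter"]], function(i) draw_inter_pair()) else NULL,
      rsn = if (n_of[["rsn"]] > 0)
        make_pool(n_of[["rsn"]], function(i) draw_rsn_pair(hs_rsn[i])) else NULL,
      region = if (n_of[["region"]] > 0)
        make_pool(n_of[["region"]], function(i) draw_region_pair(hs_reg[i])) else NULL,
      long = if (n_of[["long"]] > 0)
        make_pool(n_of[["long"]], function(i) draw_long_pair(hs_long[i])) else NULL
    )
    pick_bundle <- function(pool) {
      k <- nrow(pool$pairs)
      i <- if (k == 1) 1L else sample.int(k, 1, prob = pool$weights)
      pool$pairs[i, ]
    }

    # --- per-track polylines ---
    tracks <- vector("list", n)
    for (tr in seq_len(n)) {
      h <- home[tr]
      pair <- switch(type[tr],
        inter = pick_bundle(pools$inter),
        short = { v1 <- wsample(idx[[h]]); c(v1, nbr[[as.character(v1)]][1]) },
        rsn = pick_bundle(pools$rsn),
        region = pick_bundle(pools$region),
        long = pick_bundle(pools$long),
        bg = draw_bg_pair(h, theta_all[tr]))
      v1 <- pair[1]; v2 <- pair[2]
      tracks[[tr]] <- build_polyline(mesh$vertices[v1, ], mesh$vertices[v2, ],
                                     centers[[hemisphere[v1]]],
                                     centers[[hemisphere[v2]]],
                                     offset_sd = config$endpoint_offset_sd_mm)
    }
    out <- streamline_set(tracks)
    out$type <- type
    out
  })
}

#' Generate a complete synthetic brain
#'
#' Convenience wrapper chaining [make_brain()], [make_rsn()] and
#' [make_streamlines()] under one configuration and seed.
#'
#' @param config a [synth_brain_config()].
#' @return List with `mesh`, `parcellation`, `rsn`, `streamlines`, `config`.
#' @export
synthesize_brain <- function(config = synth_brain_config()) {
  brain <- make_brain(config)
  rsn <- make_rsn(brain$parcellation, config$n_rsn_patches,
                  seed = config$seed + 1L)
  streamlines <- make_streamlines(brain$mesh, brain$mesh$hemisphere, config,
                                  parcellation = brain$parcellation, rsn = rsn)
  list(mesh = brain$mesh, parcellation = brain$parcellation, rsn = rsn,
       streamlines = streamlines, config = config)
}
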