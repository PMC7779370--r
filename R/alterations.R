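# Shared machinery: rank edges by a length value with deterministic
# lexicographic (i, j) tie-break, and drop a rounded count.
select_removal <- function(edges, lens, percent, order, seed, exact_n = TRUE) {
  n <- nrow(edges)
  if (n == 0L) return(integer(0))
  n_remove <- round(percent / 100 * n)
  if (order == "random") {
    if (n_remove == 0L) return(integer(0))
    return(with_local_seed(seed, sample.int(n, n_remove)))
  }
  if (n_remove == 0L) return(integer(0))
  ord <- if (order == "descending")
    order(-lens, edges[, 1], edges[, 2])
  else
    order(lens, edges[, 1], edges[, 2])
  ord[seq_len(n_remove)]
}

lbar_of_edges <- function(Lbar, edges) {
  if (nrow(edges) == 0L) return(numeric(0))
  Lbar[cbind(edges[, 1], edges[, 2])]
}

#' Trim long-range connections by mean track length
#'
#' Removes `round(eta / 100 * n_edges)` long-range edges ranked by their mean
#' streamline length: `"descending"` removes the longest tracks first,
#' `"ascending"` the shortest first, `"random"` a uniform sample without
#' replacement. Ties in length break by lexicographic vertex pair. Trimming is
#' applied to the thresholded adjacency (study baseline `z_C = 1`).
#'
#' @param longrange a `long_range_adjacency`.
#' @param Lbar sparse mean-track-length matrix (from the `weighted_connectome`).
#' @param eta percentage trimmed, in `[0, 100]`.
#' @param order `"descending"`, `"ascending"`, or `"random"`.
#' @param seed seed for the random order.
#' @return The trimmed `long_range_adjacency`.
#' @export
trim_long_range <- function(longrange, Lbar, eta,
                            order = c("descending", "ascending", "random"),
                            seed = NULL) {
  order <- match.arg(order)
  check_percent(eta, "eta")
  A <- longrange$A_c
  edges <- adjacency_edges(A)
  drop <- select_removal(edges, lbar_of_edges(Lbar, edges), eta, order, seed)
  keep <- if (length(drop)) edges[-drop, , drop = FALSE] else edges
  out <- longrange
  out$A_c <- edges_to_adjacency(keep, nrow(A))
  out$alteration <- list(op = "trim", eta = eta, order = order, seed = seed)
  out
}

#' Callosectomy: remove inter-hemispheric long-range connections
#'
#' Removes `round(kappa / 100 * n_inter)` inter-hemispheric edges, ranked by
#' mean track length (descending or ascending) or drawn uniformly at random;
#' intra-hemispheric edges are untouched. The random mode caps `kappa` at 99%
#' so the hemispheres are never fully disconnected by chance; the ordered
#' modes allow the full 100% split.
#'
#' @param longrange a `long_range_adjacency`.
#' @param hemisphere per-vertex hemisphere labels.
#' @param kappa percentage of inter-hemispheric edges removed.
#' @param order `"descending"`, `"ascending"`, or `"random"`.
#' @param Lbar sparse mean-track-length matrix (required for ordered modes).
#' @param seed seed for the random order.
#' @return The altered `long_range_adjacency`.
#' @export
callosectomy <- function(longrange, hemisphere, kappa,
                         order = c("descending", "ascending", "random"),
                         Lbar = NULL, seed = NULL) {
  order <- match.arg(order)
  if (order == "random") check_percent(kappa, "kappa", upper = 99)
  else check_percent(kappa, "kappa")
  if (order != "random" && is.null(Lbar) && kappa > 0)
    stop_invalid("ordered callosectomy needs the mean-track-length matrix 'Lbar'")
  A <- longrange$A_c
  edges <- adjacency_edges(A)
  inter <- hemisphere[edges[, 1]] != hemisphere[edges[, 2]]
  ie <- edges[inter, , drop = FALSE]
  lens <- if (is.null(Lbar)) numeric(nrow(ie)) else lbar_of_edges(Lbar, ie)
  drop_local <- select_removal(ie, lens, kappa, order, seed)
  keep <- rbind(edges[!inter, , drop = FALSE],
                if (length(drop_local)) ie[-drop_local, , drop = FALSE] else ie)
  out <- longrange
  out$A_c <- edges_to_adjacency(keep, nrow(A))
  out$alteration <- list(op = "callosectomy", kappa = kappa, order = order,
                         seed = seed, n_inter = nrow(ie),
                         n_removed = length(drop_local))
  out
}

#' Anisotropy: remove local gray-matter edges
#'
#' In random mode every local edge is removed independently with probability
#' `rho / 100` (per-edge Bernoulli); the ordered modes remove
#' `round(rho / 100 * n_edges)` edges by descending or ascending Euclidean
#' edge length.
#'
#' @param local a `local_adjacency`.
#' @param rho percentage in `[0, 100]`.
#' @param order `"random"`, `"descending"`, or `"ascending"`.
#' @param seed seed for the random mode.
#' @return The altered `local_adjacency`.
#' @export
anisotropy <- function(local, rho,
                       order = c("random", "descending", "ascending"),
                       seed = NULL) {
  order <- match.arg(order)
  check_percent(rho, "rho")
  edges <- local$edges
  lens <- local$edge_lengths
  if (order == "random") {
    drop <- with_local_seed(seed, which(runif(nrow(edges)) < rho / 100))
  } else {
    drop <- select_removal(edges, lens, rho, order, seed)
  }
  keep <- if (length(drop)) seq_len(nrow(edges))[-drop] else seq_len(nrow(edges))
  out <- local
  out$A <- edges_to_adjacency(edges[keep, , drop = FALSE], nrow(local$A))
  out$edges <- edges[keep, , drop = FALSE]
  out$edge_lengths <- lens[keep]
  out$alteration <- list(op = "anisotropy", rho = rho, order = order, seed = seed)
  out
}

# Degree-preserving double-edge swaps within one vertex block.
# edges: k x 2 matrix. If bipartite, column 1 stays on side A and column 2 on
# side B (each node's block degree is preserved on its own side); otherwise
# edges are undirected i<j pairs within one block. `B` is the dense logical
# adjacency of the full long-range graph, used to veto duplicate edges.
rewire_edges <- function(edges, B, bipartite, attempts) {
  k <- nrow(edges)
  if (k < 2L) return(list(edges = edges, B = B, swaps = 0L, warned = TRUE))
  swaps <- 0L
  e1s <- sample.int(k, attempts, replace = TRUE)
  e2s <- sample.int(k, attempts, replace = TRUE)
  flips <- runif(attempts) < 0.5
  for (s in seq_len(attempts)) {
    i1 <- e1s[s]; i2 <- e2s[s]
    if (i1 == i2) next
    a <- edges[i1, 1]; b <- edges[i1, 2]
    p <- edges[i2, 1]; q <- edges[i2, 2]
    if (!bipartite && flips[s]) { tmp <- p; p <- q; q <- tmp }
    # proposed rewiring: (a-q), (p-b)
    if (a == q || p == b) next
    if (B[a, q] || B[p, b]) next
    B[a, b] <- FALSE; B[b, a] <- FALSE
    B[p, q] <- FALSE; B[q, p] <- FALSE
    B[a, q] <- TRUE;  B[q, a] <- TRUE
    B[p, b] <- TRUE;  B[b, p] <- TRUE
    edges[i1, ] <- c(a, q)
    edges[i2, ] <- c(p, b)
    swaps <- swaps + 1L
  }
  list(edges = edges, B = B, swaps = swaps, warned = FALSE)
}

#' Degree-preserving randomization of the long-range connectome
#'
#' Shuffles long-range edges by repeated double-edge swaps while keeping every
#' node's degree unchanged, restricted to hemispheric blocks:
#' \describe{
#'   \item{`inter`}{only inter-hemispheric edges, using bipartite swaps that
#'     preserve each node's inter-hemispheric degree; intra blocks are
#'     bit-identical to the input.}
#'   \item{`intra`}{each within-hemisphere block rewired independently;
#'     inter edges untouched.}
#'   \item{`inter+intra`}{all three blocks rewired, each in isolation.}
#'   \item{`global`}{one batch over all long-range edges (edges may migrate
#'     between blocks; total degree per node is still preserved).}
#' }
#' Roughly `swaps_per_edge * n_edges` swaps are attempted per block; proposals
#' creating self-loops or duplicate edges are rejected. Blocks with fewer than
#' 2 edges are returned unchanged with a warning.
#'
#' @param longrange a `long_range_adjacency`.
#' @param hemisphere per-vertex hemisphere labels.
#' @param scheme one of `"inter"`, `"intra"`, `"inter+intra"`, `"global"`.
#' @param seed integer seed.
#' @param swaps_per_edge attempted swaps per edge (default 10).
#' @return The randomized `long_range_adjacency`.
#' @export
randomize_long_range <- function(longrange, hemisphere,
                                 scheme = c("inter", "intra", "inter+intra", "global"),
                                 seed = NULL, swaps_per_edge = 10) {
  scheme <- match.arg(scheme)
  A <- longrange$A_c
  m <- nrow(A)
  edges <- adjacency_edges(A)
  with_local_seed(seed, {
    B <- matrix(FALSE, m, m)
    if (nrow(edges)) {
      B[edges] <- TRUE
      B[edges[, c(2, 1), drop = FALSE]] <- TRUE
    }
    is_left <- hemisphere == "left"
    inter <- is_left[edges[, 1]] != is_left[edges[, 2]]
    blocks <- list()
    if (scheme == "global") {
      blocks$all <- list(edges = edges, bipartite = FALSE)
    } else {
      if (scheme %in% c("inter", "inter+intra")) {
        ie <- edges[inter, , drop = FALSE]
        # orient: left vertex in column 1
        flip <- !is_left[ie[, 1]]
        ie[flip, ] <- ie[flip, c(2, 1)]
        blocks$inter <- list(edges = ie, bipartite = TRUE)
      }
      if (scheme %in% c("intra", "inter+intra")) {
        intra_e <- edges[!inter, , drop = FALSE]
        ll <- is_left[intra_e[, 1]]
        blocks$left <- list(edges = intra_e[ll, , drop = FALSE], bipartite = FALSE)
        blocks$right <- list(edges = intra_e[!ll, , drop = FALSE], bipartite = FALSE)
      }
    }
    new_edges <- list()
    for (nm in names(blocks)) {
      blk <- blocks[[nm]]
      res <- rewire_edges(blk$edges, B, blk$bipartite,
                          attempts = as.integer(swaps_per_edge * max(1, nrow(blk$edges))))
      if (res$warned)
        warning(sprintf("block '%s' has < 2 edges; left unchanged", nm))
      B <- res$B
      new_edges[[nm]] <- res$edges
    }
    shuffled <- do.call(rbind, new_edges)
    untouched <- switch(scheme,
                        inter = edges[!inter, , drop = FALSE],
                        intra = edges[inter, , drop = FALSE],
                        "inter+intra" = edges[0, , drop = FALSE],
                        global = edges[0, , drop = FALSE])
    all_e <- rbind(untouched, shuffled)
    all_e <- cbind(pmin(all_e[, 1], all_e[, 2]), pmax(all_e[, 1], all_e[, 2]))
    out <- longrange
    out$A_c <- edges_to_adjacency(all_e, m)
    out$alteration <- list(op = "randomize", scheme = scheme, seed = seed,
                           swaps_per_edge = swaps_per_edge)
    out
  })
}
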