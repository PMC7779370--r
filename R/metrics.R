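#' Mutual information between a harmonic and a binary network map
#'
#' The harmonic values are discretized into `n_bins` equal-width bins spanning
#' their observed range; the binary map contributes two states. Mutual
#' information (natural-log units) is computed from the joint vertex-count
#' histogram, with empty cells contributing zero. A constant harmonic or a
#' constant map carries no information: MI = 0 is returned with a warning.
#'
#' @param psi numeric per-vertex harmonic vector.
#' @param v binary (0/1) per-vertex map of the same length.
#' @param n_bins number of harmonic bins (study value 16).
#' @return List of class `mi_result`: `mi` (nats), `joint` (n_bins x 2
#'   probability matrix), `p_psi`, `p_map`, `n_bins`.
#' @export
mutual_information <- function(psi, v, n_bins = 16) {
  if (length(psi) != length(v))
    stop_invalid("harmonic and map vectors differ in length")
  if (!all(v %in% c(0, 1))) stop_invalid("map must be binary 0/1")
  rng <- range(psi)
  empty <- matrix(0, n_bins, 2)
  if (length(unique(v)) < 2L) {
    warning("constant map: MI = 0")
    return(structure(list(mi = 0, joint = empty, p_psi = rep(0, n_bins),
                          p_map = c(mean(v == 0), mean(v == 1)),
                          n_bins = n_bins), class = "mi_result"))
  }
  if (rng[1] == rng[2]) {
    warning("constant harmonic: MI = 0")
    return(structure(list(mi = 0, joint = empty, p_psi = rep(0, n_bins),
                          p_map = c(mean(v == 0), mean(v == 1)),
                          n_bins = n_bins), class = "mi_result"))
  }
  bin <- pmin(floor((psi - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L, n_bins)
  joint <- table(factor(bin, levels = seq_len(n_bins)),
                 factor(v, levels = c(0, 1)))
  joint <- unclass(joint) / length(psi)
  p_psi <- rowSums(joint)
  p_map <- colSums(joint)
  pos <- joint > 0
  outer_p <- outer(p_psi, p_map)
  mi <- sum(joint[pos] * log(joint[pos] / outer_p[pos]))
  structure(list(mi = mi, joint = joint, p_psi = p_psi, p_map = p_map,
                 n_bins = n_bins), class = "mi_result")
}

#' MI of a window of harmonics against a map
#'
#' @param basis a `harmonic_basis`.
#' @param v binary per-vertex map.
#' @param ks harmonic indices (1-based; study window 7 to 11).
#' @param n_bins harmonic bins for [mutual_information()].
#' @return Named numeric vector of MI values (nats), one per harmonic.
#' @export
mi_profile <- function(basis, v, ks = 7:11, n_bins = 16) {
  if (max(ks) > ncol(basis$vectors))
    stop_invalid("basis has fewer modes than requested")
  out <- vapply(ks, function(k)
    suppressWarnings(mutual_information(basis$vectors[, k], v, n_bins)$mi),
    numeric(1))
  names(out) <- as.character(ks)
  out
}

#' Absolute-Pearson correlation matrix between two harmonic sets
#'
#' `P[i, j] = |Pearson(psi_i^A, psi_j^B)|`, computed per-vertex or after
#' projection to atlas space (mandatory when the two bases live on different
#' meshes, whose vertex orderings do not pair). The absolute value absorbs
#' the arbitrary eigenvector sign. Comparing a basis with itself in vertex
#' space gives the identity up to eigenvector orthogonality.
#'
#' @param basis_a,basis_b `harmonic_basis` objects.
#' @param K number of harmonics compared.
#' @param space `"vertex"` or `"atlas"`.
#' @param parcellation_a,parcellation_b parcellations for atlas space.
#' @return K x K matrix with entries in `[0, 1]`.
#' @export
correlation_matrix <- function(basis_a, basis_b, K,
                               space = c("vertex", "atlas"),
                               parcellation_a = NULL, parcellation_b = parcellation_a) {
  space <- match.arg(space)
  if (K > ncol(basis_a$vectors) || K > ncol(basis_b$vectors))
    stop_invalid("'K' exceeds the number of available harmonics")
  Ua <- basis_a$vectors[, seq_len(K), drop = FALSE]
  Ub <- basis_b$vectors[, seq_len(K), drop = FALSE]
  if (space == "atlas") {
    if (is.null(parcellation_a) || is.null(parcellation_b))
      stop_invalid("atlas space requires a parcellation")
    Ua <- apply(Ua, 2, project_to_atlas, parcellation = parcellation_a)
    Ub <- apply(Ub, 2, project_to_atlas, parcellation = parcellation_b)
  }
  near_const <- function(U) apply(U, 2, function(x)
    stats::sd(x) <= 1e-10 * max(abs(x), .Machine$double.eps))
  const_a <- near_const(Ua)
  const_b <- near_const(Ub)
  if (any(const_a) || any(const_b))
    warning("constant vector(s): correlations defined by convention (1 if both constant, else 0)")
  Ua[, const_a] <- NA; Ub[, const_b] <- NA
  P <- suppressWarnings(abs(stats::cor(Ua, Ub)))
  P[is.na(P)] <- 0
  # two constant patterns are identical up to scale
  P[const_a, const_b] <- 1
  P
}

#' Monte-Carlo surrogate p-value for MI degradation
#'
#' `p = (1 + #\{surrogate MI >= its original MI\}) / (1 + N_surr * n_k)`,
#' counting over all surrogates and all harmonics of the window. Bounds:
#' `1 / (1 + N_surr * n_k) <= p <= 1`.
#'
#' @param mi_orig numeric vector of original MI values (length `n_k`).
#' @param mi_surr `N_surr x n_k` matrix of surrogate MI values, columns
#'   aligned with `mi_orig`.
#' @return The Monte-Carlo probability.
#' @export
surrogate_pvalue <- function(mi_orig, mi_surr) {
  mi_surr <- as.matrix(mi_surr)
  if (ncol(mi_surr) != length(mi_orig))
    stop_invalid("surrogate matrix columns must match the original MI vector")
  exceed <- sum(sweep(mi_surr, 2, mi_orig, ">=") )
  (1 + exceed) / (1 + length(mi_surr))
}

#' Benjamini-Hochberg step-up rejections
#'
#' Standard step-up procedure at false-discovery rate `q`, via adjusted
#' p-values; rejecting a p-value implies rejecting all smaller ones.
#'
#' @param p_values p-values in `(0, 1]`.
#' @param q false-discovery rate (study value 0.1).
#' @return Logical rejection flags (empty input gives an empty vector).
#' @export
benjamini_hochberg <- function(p_values, q = 0.1) {
  if (length(p_values) == 0) return(logical(0))
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Bonferroni rejections
#'
#' @param p_values p-values in `(0, 1]`.
#' @param alpha family-wise error rate.
#' @return Logical flags: `p <= alpha / n_tests`.
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) return(logical(0))
  p_values <= alpha / length(p_values)
}

#' Monte-Carlo surrogate test of harmonic-map MI under randomization
#'
#' Generates `n_surr` degree-preserving surrogates of the long-range
#' connectome under the chosen randomization scheme, recomputes the combined
#' connectome, its harmonics, and the MI of harmonics `k0 ... k0 + n_k - 1`
#' with the map for each surrogate, and summarizes the ensemble with the
#' Monte-Carlo probability that surrogate MI reaches the original MI.
#'
#' @param local a `local_adjacency`.
#' @param longrange a `long_range_adjacency`.
#' @param hemisphere per-vertex hemisphere labels.
#' @param v binary per-vertex map.
#' @param scheme randomization scheme (see [randomize_long_range()]).
#' @param n_surr number of surrogates (study value 100).
#' @param k0 first harmonic of the window (study value 7).
#' @param n_k window width (study value 5).
#' @param n_bins MI bins.
#' @param seed integer seed; surrogate `s` uses `seed + s`.
#' @param swaps_per_edge see [randomize_long_range()].
#' @param zero_tol eigenvalue zero tolerance.
#' @return Object of class `surrogate_ensemble`: `mi_orig`, `mi_surr`
#'   (`n_surr x n_k`), `p_mi_surr`, and the window parameters.
#' @export
surrogate_mi_test <- function(local, longrange, hemisphere, v,
                              scheme = "global", n_surr = 100,
                              k0 = 7, n_k = 5, n_bins = 16, seed = 1L,
                              swaps_per_edge = 10, zero_tol = 1e-8) {
  ks <- seq(k0, k0 + n_k - 1)
  K <- max(ks)
  basis0 <- eigendecompose(graph_laplacian(combine_connectome(local, longrange)),
                           K = K, zero_tol = zero_tol)
  mi_orig <- mi_profile(basis0, v, ks, n_bins)
  mi_surr <- matrix(NA_real_, n_surr, n_k,
                    dimnames = list(NULL, as.character(ks)))
  for (s in seq_len(n_surr)) {
    surr <- randomize_long_range(longrange, hemisphere, scheme = scheme,
                                 seed = seed + s, swaps_per_edge = swaps_per_edge)
    basis_s <- eigendecompose(graph_laplacian(combine_connectome(local, surr)),
                              K = K, zero_tol = zero_tol)
    mi_surr[s, ] <- mi_profile(basis_s, v, ks, n_bins)
  }
  structure(list(mi_orig = mi_orig, mi_surr = mi_surr,
                 p_mi_surr = surrogate_pvalue(mi_orig, mi_surr),
                 scheme = scheme, k0 = k0, n_k = n_k, n_surr = n_surr,
                 seed = seed),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("surrogate_ensemble: scheme=%s, harmonics %d-%d, %d surrogates\n",
              x$scheme, x$k0, x$k0 + x$n_k - 1, x$n_surr))
  cat(sprintf("  mean MI original %.4f, surrogate %.4f, p_MI_surr = %.4g\n",
              mean(x$mi_orig), mean(x$mi_surr), x$p_mi_surr))
  invisible(x)
}
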