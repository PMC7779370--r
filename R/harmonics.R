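#' Graph Laplacian of a combined connectome
#'
#' `L = ((D - A) + (D - A)^T) / 2`, which equals `D - A` for a symmetric
#' adjacency; the symmetrization tolerates round-trip asymmetry up to 1e-12,
#' anything larger is an error. `D` is the diagonal degree matrix.
#'
#' @param A a `combined_connectome` or sparse symmetric binary matrix with
#'   zero diagonal.
#' @return Object of class `laplacian_matrix`: `L` (sparse symmetric), and
#'   `degrees`.
#' @export
graph_laplacian <- function(A) {
  if (inherits(A, "combined_connectome")) A <- A$A
  A <- methods::as(A, "CsparseMatrix")
  asym <- max(abs(A - Matrix::t(A)))
  if (asym > 1e-12)
    stop_invalid(sprintf("adjacency asymmetry %.3g exceeds tolerance 1e-12", asym))
  A <- (A + Matrix::t(A)) / 2
  deg <- Matrix::rowSums(A)
  L <- Matrix::Diagonal(x = deg) - A
  structure(list(L = L, degrees = deg), class = "laplacian_matrix")
}

# Deterministic sign convention: the largest-magnitude entry of each
# eigenvector is positive (first occurrence on exact magnitude ties).
fix_signs <- function(U) {
  for (k in seq_len(ncol(U))) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) U[, k] <- -U[, k]
  }
  U
}

#' Connectome harmonics: low eigenpairs of the graph Laplacian
#'
#' Computes the `K` smallest eigenvalues and unit-norm eigenvectors of the
#' graph Laplacian, in ascending order, with a deterministic sign convention
#' (largest-magnitude entry positive). Harmonics are indexed from `k = 1`,
#' the constant mode of a connected graph. A dense symmetric LAPACK solver is
#' used: it is bitwise reproducible and exact to machine precision at the
#' vertex counts this package targets.
#'
#' @param laplacian a `laplacian_matrix` (or bare symmetric matrix).
#' @param K number of harmonics, `K <= m`.
#' @param zero_tol relative tolerance (times the largest computed eigenvalue)
#'   below which an eigenvalue counts as zero.
#' @return Object of class `harmonic_basis`: `values` (length K, ascending),
#'   `vectors` (m x K), `zero_tol`.
#' @export
eigendecompose <- function(laplacian, K, zero_tol = 1e-8) {
  L <- if (inherits(laplacian, "laplacian_matrix")) laplacian$L else laplacian
  m <- nrow(L)
  if (K > m) stop_invalid("'K' must be <= the number of vertices")
  if (K < 1) stop_invalid("'K' must be >= 1")
  e <- eigen(as.matrix(L), symmetric = TRUE)
  ord <- seq(m, m - K + 1L)
  values <- e$values[ord]
  vectors <- fix_signs(e$vectors[, ord, drop = FALSE])
  structure(list(values = values, vectors = vectors, zero_tol = zero_tol,
                 lambda_max = e$values[1]),
            class = "harmonic_basis")
}

#' @export
print.harmonic_basis <- function(x, ...) {
  cat(sprintf("harmonic_basis: %d modes on %d vertices, lambda in [%.3g, %.3g]\n",
              length(x$values), nrow(x$vectors), x$values[1], max(x$values)))
  invisible(x)
}

#' Number of (near-)zero Laplacian eigenvalues
#'
#' Counts eigenvalues below `zero_tol` times the largest computed eigenvalue;
#' for a basis computed with enough modes this equals the number of connected
#' components of the graph (two isolated hemispheres give exactly two).
#'
#' @param basis a `harmonic_basis`.
#' @return Integer count.
#' @export
count_zero_modes <- function(basis) {
  stopifnot(inherits(basis, "harmonic_basis"))
  scale <- max(abs(basis$values), basis$lambda_max, na.rm = TRUE)
  if (scale == 0) return(length(basis$values))
  sum(basis$values < basis$zero_tol * scale)
}

#' Merge per-hemisphere harmonic bases into a whole-brain basis
#'
#' Embeds each hemisphere eigenvector into a whole-brain vector (zeros on the
#' other hemisphere) and interleaves the two spectra in ascending eigenvalue
#' order, with exact ties resolved left-before-right. This reconstructs
#' whole-brain harmonics for the fully split (100% callosectomy) brain, whose
#' eigenvalues then come organized in near-equal pairs.
#'
#' @param basis_left,basis_right per-hemisphere `harmonic_basis` objects.
#' @param m total vertex count of the merged mesh.
#' @param idx_left,idx_right vertex indices of each hemisphere in the merged
#'   mesh; they must partition `1:m` without overlap.
#' @return A `harmonic_basis` of `K_left + K_right` modes, with a `side`
#'   field recording each mode's hemisphere.
#' @export
merge_hemisphere_bases <- function(basis_left, basis_right, m, idx_left, idx_right) {
  if (length(intersect(idx_left, idx_right)) > 0)
    stop_invalid("hemisphere vertex maps overlap")
  if (length(idx_left) != nrow(basis_left$vectors) ||
      length(idx_right) != nrow(basis_right$vectors))
    stop_invalid("vertex maps do not match the basis dimensions")
  kl <- length(basis_left$values); kr <- length(basis_right$values)
  values <- c(basis_left$values, basis_right$values)
  side <- c(rep("left", kl), rep("right", kr))
  ord <- order(values, match(side, c("left", "right")))
  vectors <- matrix(0, nrow = m, ncol = kl + kr)
  vectors[idx_left, seq_len(kl)] <- basis_left$vectors
  vectors[idx_right, kl + seq_len(kr)] <- basis_right$vectors
  structure(list(values = values[ord], vectors = vectors[, ord, drop = FALSE],
                 zero_tol = basis_left$zero_tol,
                 lambda_max = max(basis_left$lambda_max, basis_right$lambda_max),
                 side = side[ord]),
            class = "harmonic_basis")
}

#' Partition an ascending eigenvalue sequence into near-degenerate blocks
#'
#' Starts a new block whenever the gap to the previous eigenvalue exceeds
#' `rel_tol` times the current eigenvalue. Used for the sphere-limit
#' validation, where the icosphere Laplacian spectrum forms shells.
#'
#' @param values ascending eigenvalues.
#' @param rel_tol relative gap tolerance.
#' @return Integer vector of block sizes.
#' @export
eigenvalue_blocks <- function(values, rel_tol = 0.05) {
  if (length(values) == 0) return(integer(0))
  sizes <- integer(0); cur <- 1L
  for (i in seq_along(values)[-1]) {
    gap <- values[i] - values[i - 1]
    ref <- max(abs(values[i]), .Machine$double.eps)
    if (gap / ref > rel_tol) { sizes <- c(sizes, cur); cur <- 1L }
    else cur <- cur + 1L
  }
  c(sizes, cur)
}

#' Largest principal angle between two subspaces
#'
#' Orthonormalizes both column spans and returns the largest principal angle
#' in degrees; small angles mean the subspaces align. Used to compare
#' degenerate eigenvector multiplets against analytic spherical harmonics.
#'
#' @param U,V matrices whose columns span the two subspaces (same row count).
#' @return Angle in degrees.
#' @export
subspace_angle <- function(U, V) {
  Qu <- qr.Q(qr(U)); Qv <- qr.Q(qr(V))
  s <- svd(crossprod(Qu, Qv))$d
  acos(max(-1, min(1, min(s)))) * 180 / pi
}
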