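#' Local gray-matter adjacency from mesh connectivity
#'
#' Connects vertex pairs within graph distance `lambda_s` on the mesh edge
#' graph (the local diffusion kernel width): `lambda_s = 1` is the mesh edge
#' set itself, `lambda_s = 2` additionally connects neighbours-of-neighbours.
#'
#' @param mesh a [cortical_mesh()].
#' @param lambda_s kernel width, 1 or 2.
#' @return Object of class `local_adjacency`: `A` (sparse symmetric binary),
#'   `lambda_s`, `edges` (i<j pairs) and `edge_lengths` (Euclidean, mm).
#' @export
build_local_adjacency <- function(mesh, lambda_s = 2) {
  if (!lambda_s %in% c(1, 2)) stop_invalid("'lambda_s' must be 1 or 2")
  e <- mesh_edges(mesh)
  A1 <- edges_to_adjacency(e, mesh$m)
  A <- if (lambda_s == 1) A1 else {
    A2 <- as_binary_pattern(A1 + A1 %*% A1)
    Matrix::diag(A2) <- 0
    Matrix::drop0(A2)
  }
  edges <- adjacency_edges(A)
  structure(list(A = A, lambda_s = lambda_s, edges = edges,
                 edge_lengths = edge_lengths(mesh, edges)),
            class = "local_adjacency")
}

#' Z-score the long-range connection weights
#'
#' Computes the mean and population standard deviation of the nonzero
#' upper-triangular streamline counts and stores the z-scored weights on the
#' same support, so that integer adjacency thresholds `z_C` relate to standard
#' deviations of the weight population.
#'
#' @param wc a `weighted_connectome` from [build_long_range()].
#' @return The connectome with `mu_C`, `sigma_C`, and sparse `Cz` filled.
#' @export
zscore_weights <- function(wc) {
  stopifnot(inherits(wc, "weighted_connectome"))
  tri <- as(Matrix::triu(wc$C, k = 1L), "TsparseMatrix")
  wts <- tri@x
  if (length(wts) < 2L)
    stop_invalid("need at least two nonzero weights to z-score")
  mu <- mean(wts)
  sigma <- sqrt(mean((wts - mu)^2))
  if (sigma == 0)
    stop_invalid("degenerate weight distribution: all nonzero weights equal (sigma = 0)")
  z <- (wts - mu) / sigma
  Cz <- Matrix::sparseMatrix(i = c(tri@i + 1L, tri@j + 1L),
                             j = c(tri@j + 1L, tri@i + 1L),
                             x = c(z, z), dims = dim(wc$C))
  wc$mu_C <- mu; wc$sigma_C <- sigma; wc$Cz <- Cz
  wc
}

#' Threshold the z-scored long-range connectome into a binary adjacency
#'
#' `A_c[i, j] = 1` iff `Cz[i, j] > z_C`. Thresholds are nested: a larger `z_C`
#' produces a subset of the edges of a smaller one.
#'
#' @param wc a z-scored `weighted_connectome` (see [zscore_weights()]).
#' @param z_C adjacency weight threshold, in standard deviations of the
#'   weight population (study default 1).
#' @return Object of class `long_range_adjacency`: `A_c` (sparse symmetric
#'   binary), `z_C`.
#' @export
threshold_long_range <- function(wc, z_C = 1) {
  stopifnot(inherits(wc, "weighted_connectome"))
  if (is.null(wc$Cz)) stop_invalid("z-scored weights missing; run zscore_weights() first")
  tri <- as(Matrix::triu(wc$Cz, k = 1L), "TsparseMatrix")
  keep <- tri@x > z_C
  edges <- cbind(i = tri@i[keep] + 1L, j = tri@j[keep] + 1L)
  structure(list(A_c = edges_to_adjacency(edges, wc$m), z_C = z_C),
            class = "long_range_adjacency")
}

long_range_adjacency <- function(A_c, z_C = NA_real_) {
  structure(list(A_c = as_binary_pattern(A_c), z_C = z_C),
            class = "long_range_adjacency")
}

#' Combine local and long-range adjacencies
#'
#' Binary union of the local gray-matter adjacency and the thresholded
#' long-range adjacency (an edge present in both contributes once).
#'
#' @param local a `local_adjacency` (or bare sparse matrix).
#' @param longrange a `long_range_adjacency` (or bare sparse matrix).
#' @return Object of class `combined_connectome` with the binary symmetric
#'   union `A`.
#' @export
combine_connectome <- function(local, longrange) {
  Al <- if (inherits(local, "local_adjacency")) local$A else local
  Ac <- if (inherits(longrange, "long_range_adjacency")) longrange$A_c else longrange
  if (!all(dim(Al) == dim(Ac)))
    stop_invalid("local and long-range adjacency dimensions differ")
  A <- as_binary_pattern(Al + Ac)
  Matrix::diag(A) <- 0
  structure(list(A = Matrix::drop0(A)), class = "combined_connectome")
}

#' Proportion of local connections in the combined connectome
#'
#' `r = n_local / (n_local + n_longrange)`, both counted as undirected edges
#' of their own adjacency matrix.
#'
#' @param local a `local_adjacency` (or bare sparse matrix).
#' @param longrange a `long_range_adjacency` (or bare sparse matrix).
#' @return `r` in `[0, 1]`.
#' @export
local_ratio <- function(local, longrange) {
  Al <- if (inherits(local, "local_adjacency")) local$A else local
  Ac <- if (inherits(longrange, "long_range_adjacency")) longrange$A_c else longrange
  if (!all(dim(Al) == dim(Ac)))
    stop_invalid("local and long-range adjacency dimensions differ")
  nl <- edge_count(Al); nc <- edge_count(Ac)
  if (nl + nc == 0) stop_invalid("both adjacencies are empty: ratio undefined")
  nl / (nl + nc)
}
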