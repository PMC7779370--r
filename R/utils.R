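#' @importFrom methods as is
#' @importFrom stats cor rbinom rgamma rlnorm rnorm runif sd p.adjust
#' @importFrom utils head tail
NULL

# Evaluate expr with a locally-set RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_invalid(sprintf("'%s' must be a single value in [0, 1]", name))
  invisible(x)
}

check_percent <- function(x, name, upper = 100) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > upper)
    stop_invalid(sprintf("'%s' must be a single percentage in [0, %g]", name, upper))
  invisible(x)
}

row_norms <- function(x) sqrt(rowSums(x * x))

# Cross products of a single 3-vector with the rows of a matrix (and vice versa).
cross3_vec_mat <- function(v, m) {
  cbind(v[2] * m[, 3] - v[3] * m[, 2],
        v[3] * m[, 1] - v[1] * m[, 3],
        v[1] * m[, 2] - v[2] * m[, 1])
}

cross3_mat_mat <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Undirected edge count of a binary symmetric sparse matrix.
edge_count <- function(A) {
  Matrix::nnzero(A) / 2
}

# Upper-triangular edge list (i < j) of a binary symmetric sparse matrix.
adjacency_edges <- function(A) {
  tri <- as(Matrix::triu(A, k = 1L), "TsparseMatrix")
  cbind(i = tri@i + 1L, j = tri@j + 1L)
}

# Symmetric binary sparse matrix from an i<j edge list.
edges_to_adjacency <- function(edges, m) {
  if (is.null(edges) || nrow(edges) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), dims = c(m, m)))
  Matrix::sparseMatrix(i = c(edges[, 1L], edges[, 2L]),
                       j = c(edges[, 2L], edges[, 1L]),
                       x = 1, dims = c(m, m))
}

as_binary_pattern <- function(A) {
  A <- methods::as(A, "CsparseMatrix")
  A@x[] <- 1
  Matrix::drop0(A)
}
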