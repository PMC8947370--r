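# Vertex enumeration for polytopes of the form {x : A x = b, x >= 0}.
#
# The equality system is reduced first: a particular solution x0 and an
# orthonormal null-space basis N of A are computed by SVD, so the polytope
# becomes {t : N t >= -x0} in the null-space coordinates. Vertices are then
# basic feasible points: every choice of k = dim(null) linearly independent
# active nonnegativity constraints determines a candidate, which is kept if
# it satisfies all remaining constraints. Duplicate constraint rows (after
# projection) and duplicate vertices are deduplicated. Convex objectives
# attain their maximum at one of the returned vertices.

#' Enumerate the vertices of \{x : A x = b, x >= 0\}
#'
#' @param A Equality constraint matrix.
#' @param b Right-hand side.
#' @param tol Numerical tolerance for rank decisions and feasibility.
#' @param max_bases Guard on the number of active-set combinations to try;
#'   exceeding it raises a `pid_vertex_overflow` condition.
#' @return A list with `vertices` (matrix, one column per vertex),
#'   `dim_null` (polytope dimension after equality reduction),
#'   `n_bases` (combinations examined) and `n_ineq` (distinct
#'   nonnegativity constraints after projection).
#' @export
polytope_vertices <- function(A, b, tol = 1e-9, max_bases = 2e6) {
  d <- ncol(A)
  sv <- svd(A, nu = min(dim(A)), nv = d)
  smax <- if (length(sv$d)) max(sv$d) else 0
  r <- sum(sv$d > smax * 1e-10)
  if (r == 0) pid_stop("pid_io_error", "degenerate constraint system")
  x0 <- sv$v[, seq_len(r), drop = FALSE] %*%
    ((t(sv$u[, seq_len(r), drop = FALSE]) %*% b) / sv$d[seq_len(r)])
  x0 <- as.vector(x0)
  if (max(abs(A %*% x0 - b)) > 1e-7 * (1 + max(abs(b))))
    pid_stop("pid_infeasible", "equality system is inconsistent")
  k <- d - r
  if (k == 0) {
    if (min(x0) < -1e-8) pid_stop("pid_infeasible", "unique solution violates nonnegativity")
    x0[x0 < 0] <- 0
    return(list(vertices = matrix(x0, ncol = 1), dim_null = 0L,
                n_bases = 0L, n_ineq = 0L))
  }
  N <- sv$v[, (r + 1):d, drop = FALSE]
  G <- N                    # rows: constraints N[j, ] t >= -x0[j]
  h <- -x0
  # deduplicate projected constraint rows (up to positive scaling)
  M <- cbind(G, h)
  nrm <- sqrt(rowSums(M^2))
  active <- nrm > tol
  keys <- rep("null", nrow(M))
  keys[active] <- apply(round(M[active, , drop = FALSE] / nrm[active], 8), 1,
                        paste, collapse = ",")
  # rows with a zero normal are vacuous (h <= 0 there since x0 satisfies
  # nothing to enforce); rows violated by no t never bind
  distinct <- which(active & !duplicated(keys))
  m <- length(distinct)
  if (m < k)
    pid_stop("pid_vertex_overflow",
             "feasible set appears unbounded after reduction; cannot enumerate vertices")
  n_bases <- choose(m, k)
  if (n_bases > max_bases)
    pid_stop("pid_vertex_overflow",
             sprintf(paste("vertex enumeration would examine %.3g active-set",
                           "combinations (dimension %d, %d constraints);",
                           "consider a q-cap"), n_bases, k, m))
  Gd <- G[distinct, , drop = FALSE]
  hd <- h[distinct]
  combs <- utils::combn(m, k)
  ts <- matrix(NA_real_, k, ncol(combs))
  nsol <- 0L
  for (j in seq_len(ncol(combs))) {
    S <- combs[, j]
    B <- Gd[S, , drop = FALSE]
    t_j <- tryCatch(solve(B, hd[S]), error = function(e) NULL)
    if (is.null(t_j) || any(!is.finite(t_j))) next
    nsol <- nsol + 1L
    ts[, nsol] <- t_j
  }
  if (nsol == 0)
    pid_stop("pid_infeasible", "no basic solutions found")
  ts <- ts[, seq_len(nsol), drop = FALSE]
  # feasibility against the full original system, then map back
  slack <- G %*% ts - h      # >= 0 required (componentwise = x itself)
  feas <- which(apply(slack, 2, min) >= -1e-8)
  if (!length(feas))
    pid_stop("pid_infeasible", "polytope has no vertices satisfying nonnegativity")
  X <- x0 + N %*% ts[, feas, drop = FALSE]
  X[X < 0] <- 0
  keysX <- apply(round(X, 8), 2, paste, collapse = ",")
  X <- X[, !duplicated(keysX), drop = FALSE]
  list(vertices = X, dim_null = k, n_bases = ncol(combs), n_ineq = m)
}
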