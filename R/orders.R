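# "More informative" ordering relations between sources, relative to a
# target Y: Blackwell (channel degradation), conditional independence, and
# deterministic-function. All three are monotone for mutual information and
# form a strength chain: deterministic => conditional independence =>
# Blackwell => I(B;Y) <= I(C;Y).

# Core Blackwell feasibility test on conditionals. MB, MC are matrices
# P(b|y), P(c|y) with columns indexed by y. B is Blackwell-dominated by C
# iff there is a column-stochastic kappa[b, c] with kappa %*% MC = MB.
# Solved as nonnegative least squares on the stacked equality system
# (a finite active-set method): the residual vanishes iff the linear
# program is feasible.
blackwell_feasible <- function(MB, MC, tol = 1e-8) {
  nb <- nrow(MB); nc <- nrow(MC); ny <- ncol(MB)
  stopifnot(ncol(MC) == ny)
  nv <- nb * nc                      # vec(kappa), b fastest
  rows <- nb * ny + nc
  A <- matrix(0, rows, nv)
  d <- numeric(rows)
  # degradation equations: sum_c kappa[b,c] MC[c,y] = MB[b,y]
  r <- 0L
  for (y in seq_len(ny)) {
    for (b in seq_len(nb)) {
      r <- r + 1L
      A[r, b + nb * (seq_len(nc) - 1L)] <- MC[, y]
      d[r] <- MB[b, y]
    }
  }
  # column-stochasticity: sum_b kappa[b,c] = 1
  for (cc in seq_len(nc)) {
    r <- r + 1L
    A[r, nb * (cc - 1L) + seq_len(nb)] <- 1
    d[r] <- 1
  }
  fit <- tryCatch(pracma::lsqnonneg(A, d), error = function(e) NULL)
  if (is.null(fit)) return(list(feasible = FALSE, witness = NULL, residual = Inf))
  resid <- sqrt(max(fit$resid.norm, 0))
  if (resid > tol) return(list(feasible = FALSE, witness = NULL, residual = resid))
  kappa <- matrix(fit$x, nb, nc)
  kappa[kappa < 0] <- 0
  kappa <- sweep(kappa, 2, pmax(colSums(kappa), .Machine$double.eps), "/")
  list(feasible = TRUE, witness = kappa, residual = resid)
}

#' Test the Blackwell order between two sources
#'
#' Decides whether source `b_label` is Blackwell-dominated by source
#' `c_label` relative to the target: whether the conditional `P(b|y)` can
#' be produced by post-processing (garbling) `P(c|y)` through some
#' stochastic channel. The test depends only on the pairwise marginals of
#' each source with the target. Feasibility is decided by nonnegative
#' least squares on the defining linear system, with equality tolerance
#' `tol`.
#'
#' @param dist A `pid_dist`.
#' @param b_label,c_label Source variable names (must differ from the
#'   target).
#' @param target Target variable name; defaults to the last variable.
#' @param tol Residual tolerance on the defining equalities.
#' @return A list with `verdict` (logical), `witness` (a `pid_channel`
#'   mapping the alphabet of `c_label` to that of `b_label` when the
#'   verdict is `TRUE`, otherwise `NULL`), and `residual`.
#' @export
is_blackwell_leq <- function(dist, b_label, c_label,
                             target = default_target(dist), tol = 1e-8) {
  check_vars(dist, c(b_label, c_label, target))
  if (b_label == target || c_label == target)
    pid_stop("pid_target_as_source", "the target cannot appear as a source in an order test")
  MB <- conditional(dist, b_label, target)$matrix
  MC <- conditional(dist, c_label, target)$matrix
  res <- blackwell_feasible(MB, MC, tol)
  wit <- NULL
  if (res$feasible)
    wit <- channel(res$witness, input = dist$alphabets[[c_label]],
                   output = dist$alphabets[[b_label]])
  list(verdict = res$feasible, witness = wit, residual = res$residual)
}

#' Test conditional independence B - C - Y
#'
#' True iff `b_label` is conditionally independent of the target given
#' `c_label` under the joint: P(b, y | c) = P(b|c) P(y|c) for every c of
#' positive mass, within `tol`. This relation is stronger than the
#' Blackwell order.
#'
#' @inheritParams is_blackwell_leq
#' @param tol Absolute tolerance on the factorization.
#' @return Logical.
#' @export
is_ci_leq <- function(dist, b_label, c_label,
                      target = default_target(dist), tol = 1e-9) {
  check_vars(dist, c(b_label, c_label, target))
  if (b_label == target || c_label == target)
    pid_stop("pid_target_as_source", "the target cannot appear as a source in an order test")
  if (b_label == c_label) return(TRUE)
  j <- marginal(dist, c(b_label, c_label, target))
  # reorder prob array to (b, c, y)
  perm <- match(c(b_label, c_label, target), j$vars)
  p <- aperm(j$prob, perm)
  for (ci in seq_len(dim(p)[2])) {
    slab <- p[, ci, , drop = FALSE]
    pc <- sum(slab)
    if (pc <= 0) next
    slab <- matrix(slab, dim(p)[1], dim(p)[3]) / pc
    fact <- outer(rowSums(slab), colSums(slab))
    if (max(abs(slab - fact)) > tol) return(FALSE)
  }
  TRUE
}

#' Test the deterministic-function order B = f(C)
#'
#' True iff every outcome of `c_label` with positive mass co-occurs with
#' exactly one outcome of `b_label`, i.e. B is a deterministic function of
#' C on the support.
#'
#' @param dist A `pid_dist`.
#' @param b_label,c_label Variable names.
#' @return Logical.
#' @export
is_deterministic_leq <- function(dist, b_label, c_label) {
  check_vars(dist, c(b_label, c_label))
  if (b_label == c_label) return(TRUE)
  j <- marginal(dist, c(b_label, c_label))
  p <- j$prob
  if (j$vars[1] != b_label) p <- t(p)
  all(colSums(p > 0) <= 1)
}

#' Define a finite utility game
#'
#' A decision problem: an agent observes a signal, picks one of `actions`,
#' and receives utility `u[a, y]` depending on the action and the realized
#' target outcome.
#'
#' @param utility Numeric matrix `u[a, y]` (rows = actions, columns =
#'   target outcomes); must be finite.
#' @param actions Optional action labels.
#' @return A `pid_game`.
#' @export
utility_game <- function(utility, actions = rownames(utility)) {
  utility <- as.matrix(utility)
  if (!all(is.finite(utility)))
    pid_stop("pid_io_error", "utilities must be finite")
  if (is.null(actions)) actions <- as.character(seq_len(nrow(utility)))
  rownames(utility) <- actions
  structure(list(actions = actions, utility = utility), class = "pid_game")
}

#' Maximum expected utility from observing a source
#'
#' The value of information: the best expected utility achievable by any
#' decision rule that maps outcomes of `b_label` to actions. The optimum
#' is attained by the deterministic rule that picks, for each signal
#' outcome, the action maximizing the conditional expected utility, so no
#' optimization over stochastic rules is needed. Ties are broken by the
#' first action in the declared order (the value is unaffected).
#'
#' @param dist A `pid_dist`.
#' @param b_label Observed variable.
#' @param game A `pid_game`; `ncol(utility)` must equal the target
#'   alphabet size.
#' @param target Target variable name.
#' @return The maximal expected utility (at least the no-information value
#'   `max_a sum_y P(y) u(a, y)`).
#' @export
value_of_information <- function(dist, b_label, game,
                                 target = default_target(dist)) {
  check_vars(dist, c(b_label, target))
  ny <- length(dist$alphabets[[target]])
  if (ncol(game$utility) != ny)
    pid_stop("pid_shape_mismatch", "utility matrix columns must match the target alphabet")
  j <- marginal(dist, c(b_label, target))
  p <- j$prob                       # P(b, y)
  if (j$vars[1] != b_label) p <- t(p)
  eu <- game$utility %*% t(p)       # eu[a, b] = sum_y u(a,y) P(y,b)
  sum(apply(eu, 2, max))
}

#' Search for a utility game separating two sources
#'
#' Samples random utility games and checks whether any of them gives a
#' strictly higher value of information to `b_label` than to `c_label`.
#' Such a game certifies (by Blackwell's theorem) that `b_label` is not
#' Blackwell-dominated by `c_label`; the search can only falsify the
#' relation, never certify it.
#'
#' @inheritParams is_blackwell_leq
#' @param n_games Number of random games (entries i.i.d. uniform on
#'   \[-1, 1\], action count equal to the target alphabet size).
#' @param seed Integer seed for reproducible sampling.
#' @return A list with `refuted` (logical) and `counterexample_game` (a
#'   `pid_game`, or `NULL`).
#' @export
blackwell_falsifier <- function(dist, b_label, c_label, n_games = 200,
                                seed = 1, target = default_target(dist)) {
  stopifnot(n_games >= 1)
  ny <- length(dist$alphabets[[target]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  for (g in seq_len(n_games)) {
    u <- matrix(stats::runif(ny * ny, -1, 1), ny, ny)
    game <- utility_game(u)
    vb <- value_of_information(dist, b_label, game, target)
    vc <- value_of_information(dist, c_label, game, target)
    if (vb > vc + 1e-9)
      return(list(refuted = TRUE, counterexample_game = game))
  }
  list(refuted = FALSE, counterexample_game = NULL)
}
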