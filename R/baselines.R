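# Baseline optimization-form redundancy measures: minimum mutual
# information, the deterministic-function order measure (via the maximal
# common function of the sources), Gacs-Korner common information, and the
# conditional-independence (Markov constraint) measure.

#' Minimum-mutual-information redundancy
#'
#' The weakest order compatible with monotone mutual information gives
#' redundancy `min_i I(X_i; Y)`.
#'
#' @param dist A `pid_dist`.
#' @param target Target variable name.
#' @return Redundancy in bits.
#' @export
redundancy_mmi <- function(dist, target = default_target(dist)) {
  src <- source_vars(dist, target)
  min(vapply(src, function(s) mutual_information(dist, s, target), 1.0))
}

#' Maximal common function of the sources (common part)
#'
#' Computes the maximal random variable that is a deterministic function
#' of every source separately. Outcomes of the joint source support are
#' linked whenever they share a coordinate value; the connected components
#' of this graph are the blocks of the common part. Blocks are numbered by
#' their lexicographically smallest member tuple.
#'
#' @param dist A `pid_dist`; the common part is computed on the marginal
#'   over `sources`.
#' @param sources Character vector of source names (default: all but the
#'   last variable). At least two.
#' @return A list of class `pid_common_part`: `labeling` (per source, a
#'   named integer vector mapping each outcome to its block),
#'   `block_count`, `block_of_tuple` (block index per supported joint
#'   outcome), `tuples` (the supported outcomes), `block_prob` (block
#'   probability distribution).
#' @export
common_part <- function(dist, sources = dist$vars[-length(dist$vars)]) {
  stopifnot(length(sources) >= 2)
  check_vars(dist, sources)
  sm <- marginal(dist, sources)
  tab <- as.data.frame(sm)                 # supported tuples + p
  n <- length(sources)
  # nodes: tuples; edges: tuples sharing coordinate (i, value)
  nt <- nrow(tab)
  edges <- integer(0)
  for (i in seq_len(n)) {
    groups <- split(seq_len(nt), tab[[sources[i]]])
    for (g in groups) {
      if (length(g) > 1)
        edges <- c(edges, rbind(g[-length(g)], g[-1]))
    }
  }
  gr <- igraph::make_graph(edges = edges, n = nt, directed = FALSE)
  comp <- igraph::components(gr)$membership
  # canonical block numbering by smallest lexicographic member tuple
  key <- do.call(paste, c(tab[sources], sep = "\r"))
  first_key <- tapply(key, comp, min)      # ordered by component id 1..K
  newid <- as.integer(rank(first_key, ties.method = "first")[comp])
  labeling <- lapply(seq_len(n), function(i) {
    blk <- tapply(newid, tab[[sources[i]]], function(z) {
      stopifnot(length(unique(z)) == 1)    # well-definedness invariant
      z[1]
    })
    stats::setNames(as.integer(blk), names(blk))
  })
  names(labeling) <- sources
  bp <- as.vector(tapply(tab$p, newid, sum))
  structure(list(labeling = labeling,
                 block_count = max(newid),
                 block_of_tuple = as.integer(newid),
                 tuples = tab[sources],
                 block_prob = bp / sum(bp)),
            class = "pid_common_part")
}

#' @export
print.pid_common_part <- function(x, ...) {
  cat(sprintf("Common part with %d block(s); block probabilities: %s\n",
              x$block_count, paste(round(x$block_prob, 6), collapse = ", ")))
  invisible(x)
}

#' Gacs-Korner common information
#'
#' Entropy of the maximal random variable that is a deterministic function
#' of both variables: `C(X ^ Y) = max H(Q) s.t. Q = f(X) = g(Y)`. Always
#' between 0 and `I(X; Y)`.
#'
#' @param dist A `pid_dist` over exactly two variables.
#' @param base Logarithm base (2 for bits).
#' @return Common information.
#' @export
gacs_korner <- function(dist, base = 2) {
  if (length(dist$vars) != 2)
    pid_stop("pid_wrong_arity", "gacs_korner needs a distribution over exactly two variables")
  cp <- common_part(dist, dist$vars)
  entropy_vec(cp$block_prob, base = base)
}

#' Deterministic-order redundancy
#'
#' Maximizes `I(Q; Y)` over variables Q that are deterministic functions
#' of every source. The maximal common function dominates every feasible Q
#' under coarsening, and mutual information is monotone under refinement,
#' so the optimum is attained combinatorially at the common part — no
#' search needed. Vanishes whenever the joint source distribution has full
#' support.
#'
#' @param dist A `pid_dist`.
#' @param target Target variable name.
#' @return A `pid_result` whose optimizer joint is the distribution of
#'   (common part, target). For a single source the common part is the
#'   source itself.
#' @export
redundancy_det <- function(dist, target = default_target(dist)) {
  src <- source_vars(dist, target)
  if (length(src) == 1) {
    val <- mutual_information(dist, src, target)
    return(pid_result(val, optimizer_joint = marginal(dist, c(src, target)),
                      diagnostics = list(solver = "single_source")))
  }
  cp <- common_part(dist, src)
  # joint of (block, y): map each supported source tuple to its block
  tab <- as.data.frame(dist)
  key <- do.call(paste, c(tab[src], sep = "\r"))
  ckey <- do.call(paste, c(cp$tuples, sep = "\r"))
  blk <- cp$block_of_tuple[match(key, ckey)]
  jt <- data.frame(Q = as.character(blk), y = tab[[target]], p = tab$p,
                   stringsAsFactors = FALSE)
  names(jt)[2] <- target
  opt <- joint_dist(jt)
  val <- mutual_information(opt, "Q", target)
  pid_result(val, optimizer_joint = opt,
             diagnostics = list(solver = "common_part",
                                block_count = cp$block_count))
}

#' Conditional-independence redundancy
#'
#' Maximizes `I(Q; Y)` over conditional distributions
#' `kappa(q | x_1..x_n, y)` subject to the Markov constraints
#' `Q - X_i - Y` for every source (the conditional of Q given `(x_i, y)`
#' must not depend on y). The constraints are linear in `kappa` and the
#' objective is convex, so the optimum is found by vertex enumeration, as
#' for the Blackwell redundancy. Always at most the Blackwell redundancy.
#'
#' @param dist A `pid_dist`.
#' @param target Target variable name.
#' @param q_cardinality Outcomes allowed for Q. No sufficient cardinality
#'   bound is known for this program; the default reuses the Blackwell
#'   bound `(sum_i |X_i|) - n + 1` and results are reported as certified
#'   at the chosen cardinality (see `diagnostics$certified`).
#' @param max_bases Guard on enumeration size.
#' @return A `pid_result`.
#' @export
redundancy_gh <- function(dist, target = default_target(dist),
                          q_cardinality = NULL, max_bases = 2e6) {
  src <- source_vars(dist, target)
  ny <- length(dist$alphabets[[target]])
  if (ny == 1) return(pid_result(0, diagnostics = list(solver = "degenerate_target")))
  nq <- if (is.null(q_cardinality)) q_cardinality_bound(dist, target)
        else as.integer(q_cardinality)
  stopifnot(nq >= 1)
  tab <- as.data.frame(dist)               # support cells (x, y)
  ncell <- nrow(tab)
  d <- nq * ncell                          # kappa[q, cell], q fastest
  rows <- list(); bvec <- numeric(0)
  for (cc in seq_len(ncell)) {             # normalization per cell
    z <- numeric(d); z[(cc - 1L) * nq + seq_len(nq)] <- 1
    rows[[length(rows) + 1L]] <- z; bvec <- c(bvec, 1)
  }
  # Markov constraints: P(q | x_i, y) equal across y for each (i, x_i, q)
  for (s in src) {
    for (x in dist$alphabets[[s]]) {
      sel <- which(tab[[s]] == x)
      ys <- unique(tab[[target]][sel])
      if (length(ys) < 2) next
      wy <- lapply(ys, function(y) {
        cs <- sel[tab[[target]][sel] == y]
        w <- tab$p[cs] / sum(tab$p[cs])    # P(cell | x_i, y)
        list(cells = cs, w = w)
      })
      for (q in seq_len(nq)) {
        for (j in 2:length(ys)) {
          z <- numeric(d)
          z[(wy[[1]]$cells - 1L) * nq + q] <- wy[[1]]$w
          z[(wy[[j]]$cells - 1L) * nq + q] <-
            z[(wy[[j]]$cells - 1L) * nq + q] - wy[[j]]$w
          rows[[length(rows) + 1L]] <- z; bvec <- c(bvec, 0)
        }
      }
    }
  }
  A <- do.call(rbind, rows)
  vv <- polytope_vertices(A, bvec, max_bases = max_bases)
  yi <- match(tab[[target]], dist$alphabets[[target]])
  best <- -Inf; best_pqy <- NULL
  for (j in seq_len(ncol(vv$vertices))) {
    kap <- matrix(vv$vertices[, j], nq, ncell)
    pqy <- matrix(0, nq, ny)
    for (cc in seq_len(ncell)) pqy[, yi[cc]] <- pqy[, yi[cc]] + kap[, cc] * tab$p[cc]
    val <- mi_from_matrix(pqy)
    if (val > best + 1e-12) { best <- val; best_pqy <- pqy }
  }
  dimnames(best_pqy) <- list(as.character(seq_len(nq)), dist$alphabets[[target]])
  opt <- validate_dist(new_pid_dist(best_pqy, c("Q", target)))
  pid_result(best, optimizer_joint = opt,
             diagnostics = list(n_vertices = ncol(vv$vertices),
                                q_cardinality = nq,
                                certified = "at_cardinality",
                                dim_null = vv$dim_null,
                                solver = "vertex_enumeration"))
}
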