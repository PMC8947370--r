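# Benchmark gate distributions and seeded random joints. Gate
# probabilities are dyadic rationals, hence exactly representable in
# double precision.

#' Generate a benchmark logic-gate distribution
#'
#' Builds the standard test distributions for information decomposition:
#' \describe{
#'   \item{and, sum, unq, copy}{Two binary sources, uniform marginals;
#'     target is `X1 AND X2`, `X1 + X2`, `X1`, or the pair `(X1, X2)`.}
#'   \item{and3, sum3}{Three i.i.d. uniform binary sources with
#'     `Y = X1 AND X2 AND X3` or `Y = X1 + X2 + X3`.}
#'   \item{overlap}{Four i.i.d. uniform bits A, B, C, D grouped into
#'     sources `X1 = (A,B)`, `X2 = (A,C)`, `X3 = (A,D)`; the target is
#'     the joint outcome of all three sources. The sources overlap on A
#'     only.}
#' }
#' For the two-source gates, `correlation` couples the sources while
#' keeping their uniform marginals: `P(X1 = X2) = (1 + correlation) / 2`.
#'
#' @param gate One of `"and"`, `"sum"`, `"unq"`, `"copy"`, `"and3"`,
#'   `"sum3"`, `"overlap"`.
#' @param correlation Coupling parameter in `[-1, 1]` for the two-source
#'   gates (default 0, independent sources).
#' @return A `pid_dist` whose last variable `y` is the target.
#' @examples
#' make_gate("and")
#' make_gate("copy", correlation = 0.5)
#' @export
make_gate <- function(gate = c("and", "sum", "unq", "copy", "and3", "sum3",
                               "overlap"), correlation = 0) {
  gate <- tryCatch(match.arg(gate),
                   error = function(e) pid_stop("pid_bad_spec", conditionMessage(e)))
  if (gate %in% c("and3", "sum3", "overlap") && correlation != 0)
    pid_stop("pid_bad_spec", "correlation is only supported for two-source gates")
  if (abs(correlation) > 1) pid_stop("pid_bad_spec", "correlation must be in [-1, 1]")
  if (gate %in% c("and", "sum", "unq", "copy")) {
    rho <- correlation
    g <- expand.grid(x1 = 0:1, x2 = 0:1)
    g$p <- ifelse(g$x1 == g$x2, (1 + rho) / 4, (1 - rho) / 4)
    g$y <- switch(gate,
                  and = g$x1 * g$x2,
                  sum = g$x1 + g$x2,
                  unq = g$x1,
                  copy = paste0(g$x1, g$x2))
    return(joint_dist(g[c("x1", "x2", "y", "p")]))
  }
  if (gate %in% c("and3", "sum3")) {
    g <- expand.grid(x1 = 0:1, x2 = 0:1, x3 = 0:1)
    g$p <- 1 / 8
    g$y <- if (gate == "and3") g$x1 * g$x2 * g$x3 else g$x1 + g$x2 + g$x3
    return(joint_dist(g[c("x1", "x2", "x3", "y", "p")]))
  }
  # overlap gate
  g <- expand.grid(a = 0:1, b = 0:1, c = 0:1, d = 0:1)
  g$p <- 1 / 16
  g$x1 <- paste0(g$a, g$b)
  g$x2 <- paste0(g$a, g$c)
  g$x3 <- paste0(g$a, g$d)
  g$y <- paste(g$x1, g$x2, g$x3, sep = "|")
  joint_dist(g[c("x1", "x2", "x3", "y", "p")])
}

#' Seeded random joint distribution
#'
#' Draws a Dirichlet(1) random probability table over the given alphabet
#' sizes (sources first, target last), optionally zeroing a fraction of
#' cells before renormalizing. The same seed always yields the same
#' table; the caller's RNG state is untouched.
#'
#' @param alphabet_sizes Integer vector of alphabet sizes for all
#'   variables, sources first and the target last.
#' @param seed Integer seed.
#' @param sparsity Probability with which each cell is zeroed (default 0,
#'   full support).
#' @param n_sources Number of leading variables that are sources
#'   (default: all but the last). Only variable naming depends on it.
#' @return A `pid_dist` with variables `x1, ..., xk, y`.
#' @export
random_joint <- function(alphabet_sizes, seed, sparsity = 0,
                         n_sources = length(alphabet_sizes) - 1) {
  stopifnot(all(alphabet_sizes >= 1), n_sources >= 1,
            n_sources < length(alphabet_sizes))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  ncell <- prod(alphabet_sizes)
  repeat {
    p <- stats::rgamma(ncell, 1)
    if (sparsity > 0) p[stats::runif(ncell) < sparsity] <- 0
    if (sum(p) > 0) break
  }
  p <- p / sum(p)
  vars <- c(paste0("x", seq_len(n_sources)),
            if (length(alphabet_sizes) - n_sources == 1) "y"
            else paste0("y", seq_len(length(alphabet_sizes) - n_sources)))
  alpha <- stats::setNames(lapply(alphabet_sizes, function(k) as.character(seq_len(k) - 1)),
                           vars)
  prob <- array(p, dim = alphabet_sizes, dimnames = alpha)
  validate_dist(new_pid_dist(prob, vars))
}
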