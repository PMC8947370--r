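# Error helper: all package errors are classed conditions so callers can
# dispatch on the failure kind (e.g. "pid_not_normalized").
pid_stop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "pid_error", "error")))
}

#' Construct a joint distribution over discrete variables
#'
#' A `pid_dist` holds a finite joint probability distribution over a set of
#' named discrete variables. By convention the last variable is the target
#' and the preceding ones are the sources, although every function that
#' needs a target accepts an explicit `target` argument.
#'
#' Construction runs [validate_dist()]: probabilities must be nonnegative
#' and sum to one within `1e-6` (the table is then renormalized exactly),
#' and outcomes with zero marginal probability are dropped from each
#' variable's alphabet so that all single-variable marginals have full
#' support.
#'
#' @param table A data.frame whose first columns are outcome labels (one
#'   column per variable, coerced to character) and whose last column,
#'   named `p`, holds probabilities. Duplicated outcome rows are summed.
#' @param vars Optional character vector of variable names; defaults to the
#'   outcome column names of `table`.
#' @return An object of class `pid_dist` with fields `vars` (variable
#'   names), `alphabets` (named list of outcome sets) and `prob` (a dense
#'   array of probabilities with one dimension per variable).
#' @examples
#' and <- joint_dist(data.frame(
#'   x1 = c(0, 0, 1, 1), x2 = c(0, 1, 0, 1), y = c(0, 0, 0, 1),
#'   p = rep(1 / 4, 4)))
#' ent(and, "y")
#' @export
joint_dist <- function(table, vars = NULL) {
  if (!is.data.frame(table) || ncol(table) < 2)
    pid_stop("pid_io_error", "`table` must be a data.frame with outcome columns and a `p` column")
  pcol <- ncol(table)
  if (!is.null(table$p)) pcol <- which(names(table) == "p")[1]
  p <- as.numeric(table[[pcol]])
  out <- table[-pcol]
  out[] <- lapply(out, as.character)
  if (is.null(vars)) vars <- names(out)
  if (length(vars) != ncol(out)) pid_stop("pid_io_error", "length(vars) must match the number of outcome columns")
  names(out) <- vars
  alphabets <- lapply(out, function(col) sort(unique(col)))
  prob <- array(0, dim = vapply(alphabets, length, 1L), dimnames = alphabets)
  idx <- as.matrix(as.data.frame(mapply(function(col, alpha) match(col, alpha),
                                        out, alphabets, SIMPLIFY = FALSE)))
  for (r in seq_along(p)) {
    prob[matrix(idx[r, ], 1)] <- prob[matrix(idx[r, ], 1)] + p[r]
  }
  validate_dist(new_pid_dist(prob, vars))
}

new_pid_dist <- function(prob, vars) {
  if (is.null(dim(prob))) {
    prob <- array(prob, dim = length(prob),
                  dimnames = stats::setNames(list(names(prob)), vars))
  }
  structure(list(vars = vars,
                 alphabets = stats::setNames(dimnames(prob), vars),
                 prob = prob),
            class = "pid_dist")
}

#' Validate and normalize a joint distribution
#'
#' Checks nonnegativity and normalization, renormalizes exactly, and drops
#' zero-probability outcomes from each variable's alphabet (so that every
#' single-variable marginal has full support, the standing convention for
#' all measures in this package).
#'
#' @param dist A `pid_dist` (possibly freshly constructed).
#' @return The validated `pid_dist`.
#' @export
validate_dist <- function(dist) {
  p <- dist$prob
  if (any(p < -1e-12))
    pid_stop("pid_negative_probability",
             sprintf("negative probability mass (min %.3g)", min(p)))
  p[p < 0] <- 0
  s <- sum(p)
  if (abs(s - 1) > 1e-6)
    pid_stop("pid_not_normalized",
             sprintf("probabilities sum to %.8f, not 1 (tolerance 1e-6)", s))
  p <- p / s
  # drop outcomes with zero marginal mass, per-variable
  keep <- lapply(seq_along(dim(p)), function(d) {
    m <- apply(p, d, sum)
    which(m > 0)
  })
  p <- do.call(`[`, c(list(p), keep, list(drop = FALSE)))
  stopifnot(abs(sum(p) - 1) < 1e-9)
  new_pid_dist(p, dist$vars)
}

#' @export
print.pid_dist <- function(x, ...) {
  cat("Joint distribution over", paste(x$vars, collapse = ", "), "\n")
  cat("Alphabet sizes:",
      paste(sprintf("|%s|=%d", x$vars, vapply(x$alphabets, length, 1L)),
            collapse = ", "), "\n")
  cat("Support size:", sum(x$prob > 0), "\n")
  invisible(x)
}

#' Convert a joint distribution to its support table
#'
#' @param x A `pid_dist`.
#' @param ... Unused.
#' @param zero.drop Drop zero-probability cells (default `TRUE`).
#' @return A data.frame with one outcome column per variable and a final
#'   `p` column.
#' @export
as.data.frame.pid_dist <- function(x, ..., zero.drop = TRUE) {
  grid <- expand.grid(x$alphabets, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$p <- as.vector(x$prob)
  if (zero.drop) grid <- grid[grid$p > 0, , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

check_vars <- function(dist, subset) {
  bad <- setdiff(subset, dist$vars)
  if (length(bad))
    pid_stop("pid_unknown_variable",
             paste("unknown variable(s):", paste(bad, collapse = ", ")))
}

#' Marginal distribution over a subset of variables
#'
#' Sums out the complementary variables.
#'
#' @param dist A `pid_dist`.
#' @param subset Character vector of variable names to retain (order taken
#'   from `dist`).
#' @return A `pid_dist` over `subset`.
#' @export
marginal <- function(dist, subset) {
  if (!length(subset)) pid_stop("pid_unknown_variable", "subset must be nonempty")
  check_vars(dist, subset)
  keep <- which(dist$vars %in% subset)
  m <- apply(dist$prob, keep, sum)
  if (length(keep) == 1) {
    m <- array(m, dim = length(m), dimnames = dist$alphabets[keep])
  }
  new_pid_dist(m, dist$vars[keep])
}

#' Stochastic channel (conditional distribution matrix)
#'
#' A `pid_channel` is a column-stochastic matrix `matrix[out, in]` of
#' conditional probabilities of an output alphabet given an input alphabet.
#'
#' @param matrix Numeric matrix; columns must sum to 1 within `1e-9` and
#'   entries must be nonnegative.
#' @param input,output Optional alphabets (default from dimnames).
#' @return A `pid_channel`.
#' @export
channel <- function(matrix, input = colnames(matrix), output = rownames(matrix)) {
  if (any(matrix < -1e-12))
    pid_stop("pid_negative_probability", "channel entries must be nonnegative")
  matrix[matrix < 0] <- 0
  cs <- colSums(matrix)
  if (any(abs(cs - 1) > 1e-9))
    pid_stop("pid_not_normalized", "channel columns must sum to 1")
  if (is.null(input)) input <- as.character(seq_len(ncol(matrix)))
  if (is.null(output)) output <- as.character(seq_len(nrow(matrix)))
  dimnames(matrix) <- list(output, input)
  structure(list(input = input, output = output, matrix = matrix),
            class = "pid_channel")
}

#' @export
print.pid_channel <- function(x, ...) {
  cat(sprintf("Channel: %d inputs -> %d outputs\n",
              length(x$input), length(x$output)))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Conditional distribution P(of | given) as a channel
#'
#' @param dist A `pid_dist`.
#' @param of,given Variable names. `given` has full support by
#'   construction of `pid_dist`, so every column is well defined.
#' @return A `pid_channel` mapping the alphabet of `given` to the alphabet
#'   of `of`.
#' @export
conditional <- function(dist, of, given) {
  check_vars(dist, c(of, given))
  if (identical(of, given)) {
    k <- length(dist$alphabets[[of]])
    m <- diag(k)
    dimnames(m) <- list(dist$alphabets[[of]], dist$alphabets[[of]])
    return(channel(m))
  }
  joint <- marginal(dist, c(of, given))
  m <- joint$prob
  if (joint$vars[1] != of) m <- t(m)
  m <- sweep(m, 2, colSums(m), "/")
  channel(m, input = dist$alphabets[[given]], output = dist$alphabets[[of]])
}

# entropy of a bare probability vector/array, in bits by default;
# 0 log 0 = 0 by explicit masking.
entropy_vec <- function(p, base = 2) {
  p <- as.vector(p)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Shannon entropy of a subset of variables
#'
#' @param dist A `pid_dist`.
#' @param subset Variables whose joint entropy is computed (default: all).
#' @param base Logarithm base; 2 (bits) by default.
#' @return Entropy, a nonnegative scalar.
#' @export
ent <- function(dist, subset = dist$vars, base = 2) {
  check_vars(dist, subset)
  entropy_vec(marginal(dist, subset)$prob, base = base)
}

#' Mutual information between two groups of variables
#'
#' `I(left; right) = H(left) + H(right) - H(left, right)`, clamped at zero
#' within numerical tolerance.
#'
#' @param dist A `pid_dist`.
#' @param left,right Disjoint character vectors of variable names.
#' @param base Logarithm base; 2 (bits) by default.
#' @return Mutual information, nonnegative.
#' @export
mutual_information <- function(dist, left, right, base = 2) {
  check_vars(dist, c(left, right))
  if (length(intersect(left, right)))
    pid_stop("pid_overlapping_subsets", "left and right subsets must be disjoint")
  v <- ent(dist, left, base) + ent(dist, right, base) -
    ent(dist, c(left, right), base)
  if (v < 0 && v > -1e-9) v <- 0
  v
}

# mutual information of a 2-d joint probability matrix (rows = one
# variable, cols = the other), in bits
mi_from_matrix <- function(m, base = 2) {
  v <- entropy_vec(rowSums(m), base) + entropy_vec(colSums(m), base) -
    entropy_vec(m, base)
  max(v, 0)
}

# source labels for a distribution given the target
source_vars <- function(dist, target) {
  check_vars(dist, target)
  setdiff(dist$vars, target)
}

# default target: last variable
default_target <- function(dist) dist$vars[length(dist$vars)]
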