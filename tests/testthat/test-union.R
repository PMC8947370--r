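test_that("union information reproduces the closed-form gate values", {
  # COPY of independent bits: union is the joint source entropy, 2 bits
  u <- union_blackwell(make_gate("copy"))
  expect_equal(u$value, 2.0, tolerance = 1e-6)
  # AND: mutual Blackwell dominance forces union = I(X_i; Y)
  expect_equal(union_blackwell(make_gate("and"))$value, AND_MI1,
               tolerance = 1e-6)
  # Y = X1 with independent noise source: union = I(X1;Y) = 1
  expect_equal(union_blackwell(make_gate("unq"))$value, 1.0, tolerance = 1e-6)
})

test_that("self-union: a single source yields its mutual information", {
  for (s in 1:6) {
    d <- random_joint(c(3, 3), seed = 1000 + s)
    expect_equal(union_blackwell(d)$value,
                 mutual_information(d, "x1", "y"), tolerance = 1e-6)
  }
})

test_that("the union optimizer is feasible and certifies a small gap", {
  for (d in list(make_gate("and"), make_gate("sum"),
                 random_joint(c(2, 2, 3), seed = 31))) {
    u <- union_blackwell(d)
    expect_true(union_feasibility_check(d, u$optimizer_joint, tol = 1e-7))
    expect_lte(u$diagnostics$gap, 1e-8)
    # the coupled joint source dominates every individual source
    src <- setdiff(d$vars, "y")
    tab <- as.data.frame(u$optimizer_joint)
    tab$xx <- do.call(paste, c(tab[src], sep = "|"))
    dj <- joint_dist(tab[c(src, "xx", "y", "p")])
    for (s in src)
      expect_true(is_blackwell_leq(dj, s, "xx")$verdict)
  }
})

test_that("infeasible candidates are rejected", {
  d <- make_gate("and")
  expect_true(union_feasibility_check(d, d))
  # product coupling of the wrong pairwise marginal
  g <- expand.grid(x1 = c("0", "1"), x2 = c("0", "1"), y = c("0", "1"),
                   stringsAsFactors = FALSE)
  g$p <- 1 / 8
  expect_false(union_feasibility_check(d, joint_dist(g)))
  wrong <- joint_dist(data.frame(a = c(0, 1), y = c(0, 1), p = c(0.5, 0.5)))
  expect_error(union_feasibility_check(d, wrong), class = "pid_shape_mismatch")
})

test_that("synergy and excluded information derive from the union value", {
  and <- make_gate("and")
  u <- union_blackwell(and)
  expect_equal(synergy(and, union = u), 0.5, tolerance = 1e-6)
  expect_equal(excluded_information(and, 1, union = u), 0, tolerance = 1e-6)
  expect_equal(excluded_information(and, 2, union = u), 0, tolerance = 1e-6)

  cp <- make_gate("copy")
  expect_equal(synergy(cp), 0, tolerance = 1e-6)

  unq <- make_gate("unq")
  uu <- union_blackwell(unq)
  expect_equal(excluded_information(unq, "x1", union = uu), 0, tolerance = 1e-6)
  expect_equal(excluded_information(unq, "x2", union = uu), 1, tolerance = 1e-6)

  d1 <- random_joint(c(3, 2), seed = 37)
  expect_equal(synergy(d1), 0, tolerance = 1e-6)
  expect_equal(excluded_information(d1, 1), 0, tolerance = 1e-6)
})

test_that("no sampled feasible coupling beats the union optimum", {
  # random feasible points: convex paths from the conditional-independence
  # coupling toward re-normalized random perturbations in the constraint
  # null space
  for (s in 1:5) {
    d <- random_joint(c(2, 2, 2), seed = 1100 + s)
    u <- union_blackwell(d)
    cells <- blackwellpid:::union_cells(d, "y")
    cons <- blackwellpid:::union_constraints(cells, d, "y")
    A <- cons$A
    sv <- svd(A, nu = min(dim(A)), nv = ncol(A))
    r <- sum(sv$d > max(sv$d) * 1e-10)
    if (r == ncol(A)) next
    N <- sv$v[, (r + 1):ncol(A), drop = FALSE]
    grid <- cells$grid
    xg <- do.call(paste, c(grid[setdiff(d$vars, "y")], sep = "|"))
    p0 <- u$optimizer_joint   # reconstruct CI start instead
    py <- marginal(d, "y")$prob
    start <- as.vector(py)[match(grid$y, d$alphabets$y)]
    for (sv2 in setdiff(d$vars, "y")) {
      cm <- conditional(d, sv2, "y")$matrix
      start <- start * cm[cbind(grid[[sv2]], grid$y)]
    }
    set.seed(s)
    for (j in 1:40) {
      dir <- as.vector(N %*% rnorm(ncol(N)))
      neg <- dir < 0
      amax <- if (any(neg)) min(-start[neg] / dir[neg]) else 0
      p <- start + runif(1) * amax * dir
      p[p < 0] <- 0
      mjoint <- tapply(p, list(xg, grid$y), sum, default = 0)
      val <- Hvec(rowSums(mjoint)) + Hvec(colSums(mjoint)) - Hvec(mjoint)
      expect_gte(val, u$value - 1e-6)
    }
  }
})
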