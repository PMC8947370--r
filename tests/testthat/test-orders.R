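test_that("Blackwell order: reflexivity, constants, and the unique-source gate", {
  unq <- make_gate("unq")
  # reflexivity via a duplicate of the same conditional: X1 vs X1 is not a
  # legal pair of labels, so duplicate the source in the table
  tab <- as.data.frame(unq)
  tab$x3 <- tab$x1
  d <- joint_dist(tab[c("x1", "x2", "x3", "y", "p")])
  r <- is_blackwell_leq(d, "x1", "x3")
  expect_true(r$verdict)
  expect_equal(unname(r$witness$matrix), diag(2), tolerance = 1e-7)

  # a constant variable is dominated by anything (garbling to a point)
  tabc <- as.data.frame(unq)
  tabc$x3 <- "c"
  dc <- joint_dist(tabc[c("x1", "x2", "x3", "y", "p")])
  expect_true(is_blackwell_leq(dc, "x3", "x1")$verdict)
  expect_true(is_blackwell_leq(dc, "x3", "x2")$verdict)

  # Y = X1, X2 independent noise: X2 is dominated by X1 but not conversely
  expect_true(is_blackwell_leq(unq, "x2", "x1")$verdict)
  expect_false(is_blackwell_leq(unq, "x1", "x2")$verdict)

  expect_error(is_blackwell_leq(unq, "x1", "y"),
               class = "pid_target_as_source")
})

test_that("Blackwell witness reproduces the dominated conditional", {
  and <- make_gate("and")
  r <- is_blackwell_leq(and, "x1", "x2")   # symmetric conditionals: true
  expect_true(r$verdict)
  MB <- conditional(and, "x1", "y")$matrix
  MC <- conditional(and, "x2", "y")$matrix
  expect_lt(max(abs(r$witness$matrix %*% MC - MB)), 1e-7)
})

test_that("Blackwell order depends only on the pairwise marginals", {
  for (s in 1:8) {
    d <- random_joint(c(2, 2, 2), seed = 400 + s)
    # re-couple the two sources through conditional independence given y,
    # preserving both pairwise marginals with the target
    py <- marginal(d, "y")$prob
    c1 <- conditional(d, "x1", "y")$matrix
    c2 <- conditional(d, "x2", "y")$matrix
    g <- expand.grid(x1 = d$alphabets$x1, x2 = d$alphabets$x2,
                     y = d$alphabets$y, stringsAsFactors = FALSE)
    g$p <- as.vector(py)[match(g$y, d$alphabets$y)] *
      c1[cbind(g$x1, g$y)] * c2[cbind(g$x2, g$y)]
    d2 <- joint_dist(g)
    for (pair in list(c("x1", "x2"), c("x2", "x1"))) {
      expect_equal(is_blackwell_leq(d, pair[1], pair[2])$verdict,
                   is_blackwell_leq(d2, pair[1], pair[2])$verdict)
    }
  }
})

test_that("conditional-independence order detects Markov structure", {
  # a deterministic function of the conditioning variable is conditionally
  # independent of anything given it
  cp <- make_gate("copy", correlation = 0.5)
  tab <- as.data.frame(cp)
  tab$x3 <- ifelse(tab$x1 == "0", "f0", "f1")   # X3 = f(X1)
  d <- joint_dist(tab[c("x1", "x2", "x3", "y", "p")])
  expect_true(is_ci_leq(d, "x3", "x1", target = "y"))

  and <- make_gate("and")
  expect_false(is_ci_leq(and, "x1", "x2"))
  # B = Y itself, not a function of C: dependence survives conditioning
  sum2 <- make_gate("sum")
  tab2 <- as.data.frame(sum2)
  tab2$x3 <- tab2$y
  d2 <- joint_dist(tab2[c("x1", "x2", "x3", "y", "p")])
  expect_false(is_ci_leq(d2, "x3", "x1", target = "y"))
})

test_that("deterministic-function order", {
  cp <- make_gate("copy")
  expect_true(is_deterministic_leq(cp, "x1", "y"))   # X1 is a coordinate of Y
  expect_false(is_deterministic_leq(cp, "y", "x1"))
  expect_true(is_deterministic_leq(cp, "x1", "x1"))
  unq <- make_gate("unq")
  expect_false(is_deterministic_leq(unq, "x1", "x2"))
})

test_that("value of information: closed-form decision problems", {
  and <- make_gate("and")
  match_game <- utility_game(diag(2))
  # observing X1: best guess per signal outcome
  expect_equal(value_of_information(and, "x1", match_game), 3 / 4)
  # observing the target itself: perfect prediction
  tab <- as.data.frame(and)
  tab$b <- tab$y
  d <- joint_dist(tab[c("x1", "x2", "b", "y", "p")])
  expect_equal(value_of_information(d, "b", match_game), 1.0)
  # independent observer: no-information value max_y P(y)
  unq <- make_gate("unq")
  expect_equal(value_of_information(unq, "x2", match_game), 1 / 2)
  # never below the no-information value
  for (s in 1:5) {
    dr <- random_joint(c(2, 3, 2), seed = 500 + s)
    g <- utility_game(matrix(runif(4, -1, 1), 2, 2))
    v0 <- max(g$utility %*% marginal(dr, "y")$prob)
    expect_gte(value_of_information(dr, "x1", g), v0 - 1e-12)
  }
})

test_that("utility-game falsifier refutes only genuine non-dominance", {
  unq <- make_gate("unq")
  expect_true(blackwell_falsifier(unq, "x1", "x2", n_games = 200, seed = 3)$refuted)
  expect_false(blackwell_falsifier(unq, "x2", "x1", n_games = 200, seed = 3)$refuted)
  # same variable duplicated: never refuted
  tab <- as.data.frame(unq)
  tab$x3 <- tab$x1
  d <- joint_dist(tab[c("x1", "x2", "x3", "y", "p")])
  expect_false(blackwell_falsifier(d, "x1", "x3", n_games = 100, seed = 5)$refuted)
  # falsifier is deterministic given the seed
  a <- blackwell_falsifier(unq, "x1", "x2", n_games = 50, seed = 11)
  b <- blackwell_falsifier(unq, "x1", "x2", n_games = 50, seed = 11)
  expect_identical(a$refuted, b$refuted)
})

test_that("order strength chain: deterministic => conditional independence
           => Blackwell => monotone information", {
  for (s in 1:12) {
    d <- random_joint(c(2, 2, 2), seed = 600 + s, sparsity = 0.2)
    if (length(d$alphabets$x1) < 2 || length(d$alphabets$x2) < 2 ||
        length(d$alphabets$y) < 2) next
    for (pair in list(c("x1", "x2"), c("x2", "x1"))) {
      det <- is_deterministic_leq(d, pair[1], pair[2])
      ci <- is_ci_leq(d, pair[1], pair[2])
      bw <- is_blackwell_leq(d, pair[1], pair[2])$verdict
      if (det) expect_true(ci)
      if (ci) expect_true(bw)
      if (bw) expect_lte(mutual_information(d, pair[1], "y"),
                         mutual_information(d, pair[2], "y") + 1e-9)
    }
  }
})
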