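test_that("minimum-mutual-information redundancy", {
  expect_equal(redundancy_mmi(make_gate("and")), AND_MI1, tolerance = 1e-9)
  expect_equal(redundancy_mmi(make_gate("overlap")), 2.0, tolerance = 1e-9)
  d <- random_joint(c(3, 2), seed = 41)
  expect_equal(redundancy_mmi(d), mutual_information(d, "x1", "y"),
               tolerance = 1e-12)
})

test_that("common part: block structure of the joint source support", {
  # perfectly correlated bits: two singleton blocks
  cp1 <- common_part(make_gate("copy", correlation = 1), c("x1", "x2"))
  expect_equal(cp1$block_count, 2L)
  # independent full-support pair: a single constant block
  cp0 <- common_part(make_gate("copy"), c("x1", "x2"))
  expect_equal(cp0$block_count, 1L)
  # overlap gate: blocks indexed by the shared bit A
  ov <- make_gate("overlap")
  cpo <- common_part(ov, c("x1", "x2", "x3"))
  expect_equal(cpo$block_count, 2L)
  expect_equal(cpo$block_prob, c(0.5, 0.5))
  # the labeling is a function of each source separately
  for (s in c("x1", "x2", "x3")) {
    lab <- cpo$labeling[[s]]
    expect_equal(unname(lab[c("00", "01")]), c(1L, 1L))
    expect_equal(unname(lab[c("10", "11")]), c(2L, 2L))
  }
})

test_that("common part is maximal: no coarser common labeling has more entropy", {
  # exhaustive oracle on two small sources: any assignment of X1 outcomes
  # to labels that extends to a well-defined common function is a
  # coarsening of the common part
  for (s in 1:8) {
    d <- random_joint(c(3, 3, 2), seed = 1200 + s, sparsity = 0.45)
    if (length(d$alphabets$x1) < 2 || length(d$alphabets$x2) < 2) next
    sm <- marginal(d, c("x1", "x2"))
    tab <- as.data.frame(sm)
    cp <- common_part(d, c("x1", "x2"))
    hcp <- Hvec(cp$block_prob)
    a1 <- d$alphabets$x1
    n1 <- length(a1)
    grids <- expand.grid(rep(list(seq_len(n1)), n1))
    best <- 0
    for (g in seq_len(nrow(grids))) {
      f1 <- unlist(grids[g, ])
      names(f1) <- a1
      # induced labels on x2 must be consistent
      lab2 <- tapply(f1[tab$x1], tab$x2, function(z) {
        if (length(unique(z)) == 1) z[1] else NA
      })
      if (anyNA(lab2)) next
      bp <- tapply(tab$p, f1[tab$x1], sum)
      best <- max(best, Hvec(as.vector(bp)))
    }
    expect_equal(hcp, best, tolerance = 1e-9)
  }
})

test_that("Gacs-Korner common information: identity, independence, full support", {
  ident <- joint_dist(data.frame(x = c(0, 1), y = c(0, 1), p = c(0.5, 0.5)))
  expect_equal(gacs_korner(ident), 1.0)
  indep <- joint_dist(expand.grid(x = 0:1, y = 0:1) |>
                        transform(p = 0.25))
  expect_equal(gacs_korner(indep), 0.0)
  # correlated but full support: common information collapses to zero
  corr <- joint_dist(data.frame(x = c(0, 0, 1, 1), y = c(0, 1, 0, 1),
                                p = c(0.45, 0.05, 0.05, 0.45)))
  expect_equal(gacs_korner(corr), 0.0)
  expect_lte(gacs_korner(corr), mutual_information(corr, "x", "y"))
  expect_error(gacs_korner(make_gate("and")), class = "pid_wrong_arity")
})

test_that("deterministic-order redundancy via the maximal common function", {
  expect_equal(redundancy_det(make_gate("and"))$value, 0, tolerance = 1e-12)
  expect_equal(redundancy_det(make_gate("sum"))$value, 0, tolerance = 1e-12)
  expect_equal(redundancy_det(make_gate("overlap"))$value, 1.0,
               tolerance = 1e-9)
  # X1 = X2 = Y: the common part is the shared bit
  d <- joint_dist(data.frame(x1 = c(0, 1), x2 = c(0, 1), y = c(0, 1),
                             p = c(0.5, 0.5)))
  expect_equal(redundancy_det(d)$value, 1.0)
  # full joint source support forces zero
  for (s in 1:4) {
    dr <- random_joint(c(2, 2, 3), seed = 1300 + s)
    expect_equal(redundancy_det(dr)$value, 0, tolerance = 1e-12)
  }
})

test_that("conditional-independence redundancy reproduces the gate values", {
  expect_equal(redundancy_gh(make_gate("and"))$value, GH_AND, tolerance = 1e-9)
  expect_equal(redundancy_gh(make_gate("sum"))$value, 0, tolerance = 1e-9)
  # Y = X1 with correlated noise source: redundancy is the source coupling
  # information I(X1; X2)
  for (rho in c(0.5, 0.25)) {
    unq <- make_gate("unq", correlation = rho)
    expect_equal(redundancy_gh(unq)$value,
                 1 - Hb((1 + rho) / 2), tolerance = 1e-7)
  }
})

test_that("measure ordering: det <= gh <= blackwell <= mmi", {
  for (s in 1:10) {
    d <- random_joint(c(2, 2, 2), seed = 1400 + s)
    rdet <- redundancy_det(d)$value
    rgh <- redundancy_gh(d, q_cardinality = 2)$value  # certified lower bound
    rbw <- redundancy_blackwell(d)$value
    rmmi <- redundancy_mmi(d)
    expect_lte(rdet, rgh + 1e-7)
    expect_lte(rgh, rbw + 1e-7)
    expect_lte(rbw, rmmi + 1e-7)
  }
})
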