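test_that("parameter validation enforces the open unit interval", {
  expect_s3_class(valence_model(0.5, 0.1, 0.3, 0.2, 0.4), "valence_model")
  # the grid extremes are valid
  expect_s3_class(valence_model(0.99, 0.01, 0.01, 0.99, 0.99),
                  "valence_model")
  expect_error(valence_model(1.0, 0.1, 0.3, 0.2, 0.4), "r must lie strictly")
  expect_error(valence_model(0.5, 0, 0.3, 0.2, 0.4), "s must lie strictly")
  expect_error(valence_model(0.5, 0.1, -0.1, 0.2, 0.4),
               "alpha must lie strictly")
  expect_error(valence_model(0.5, 0.1, 0.3, NA, 0.4), "finite")
  expect_named(coef(valence_model(0.5, 0.1, 0.3, 0.2, 0.4)),
               c("r", "s", "alpha", "beta", "omega"))
})

test_that("state indexing packs (V, M, E) as 4V + 2M + E + 1", {
  st <- state_space()
  expect_equal(st$index, 4 * st$V + 2 * st$M + st$E + 1)
  expect_equal(unlist(st[1, 2:4]), c(V = 0, M = 0, E = 0))
  expect_equal(unlist(st[8, 2:4]), c(V = 1, M = 1, E = 1))
  expect_equal(st$syntonic, st$V == st$M)
  expect_equal(which(st$syntonic), c(1L, 2L, 7L, 8L))
})

test_that("component chains are symmetric and doubly stochastic", {
  expect_equal(mood_matrix(0.9),
               matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE,
                      dimnames = list(c("M0", "M1"), c("M0", "M1"))))
  expect_equal(unname(event_matrix(0.1)),
               matrix(c(0.1, 0.9, 0.9, 0.1), 2, 2, byrow = TRUE))
  for (x in runif(20)) {
    PM <- mood_matrix(x)
    expect_equal(PM, t(PM))
    expect_equal(colSums(PM), rowSums(PM))
    expect_equal(unname(rowSums(PM)), c(1, 1))
  }
})

test_that("valence retention terms follow the egosyntonicity switch", {
  m <- valence_model(r = 0.7, s = 0.1, alpha = 0.3, beta = 0.2, omega = 0.4)
  # egodystonic with a negative event: a negative valence is certainly kept
  expect_equal(valence_terms(m, V = 0, M = 1, E = 0)$p00, 1)
  # egosyntonic with a positive event: a positive valence is certainly kept
  expect_equal(valence_terms(m, V = 1, M = 1, E = 1)$p11, 1)
  # egosyntonic, positive event: p00 = (1-omega)(1-alpha)
  expect_equal(valence_terms(m, V = 0, M = 0, E = 1)$p00, 0.42)
  vt <- valence_terms(m, V = 0, M = 0, E = 0)
  expect_equal(vt$eta0, 0.7)
  expect_equal(vt$eta1, 1)
  vt <- valence_terms(m, V = 1, M = 0, E = 0)
  expect_equal(vt$eta0, 1)
  expect_equal(vt$eta1, 0.8)
})

test_that("joint matrix entries match hand-evaluated products", {
  m <- valence_model(r = 0.7, s = 0.1, alpha = 0.3, beta = 0.2, omega = 0.4)
  P <- transition_matrix(m, method = "composed")
  Pp <- transition_matrix(m, method = "printed")
  # state 1 -> state 1: (omega + (1-alpha)(1-omega)) * r * s
  expect_equal(P[1, 1], 0.82 * 0.7 * 0.1)
  # state 4 -> state 1: (1-omega)(1-r)(1-s)
  expect_equal(Pp[4, 1], 0.6 * 0.3 * 0.9)
  # certain valence retention zeroes half of rows 3 and 8
  expect_equal(unname(P[3, 5:8]), rep(0, 4))
  expect_equal(unname(P[8, 1:4]), rep(0, 4))
  expect_equal(unname(rowSums(P)), rep(1, 8), tolerance = 1e-12)
  expect_equal(unname(rowSums(Pp)), rep(1, 8), tolerance = 1e-12)
})

test_that("the two joint-matrix constructions agree across random draws", {
  set.seed(101)
  p <- random_params(300)
  for (i in seq_len(nrow(p))) {
    m <- model_from_row(p, i)
    d <- max(abs(transition_matrix(m, "composed") -
                   transition_matrix(m, "printed")))
    expect_lt(d, 1e-12)
  }
})

test_that("marginalizing the joint chain recovers the component chains", {
  set.seed(17)
  p <- random_params(25)
  st <- state_space()
  for (i in seq_len(nrow(p))) {
    m <- model_from_row(p, i)
    P <- transition_matrix(m)
    PM <- mood_matrix(m)
    PE <- event_matrix(m)
    for (row in 1:8) {
      expect_equal(sum(P[row, st$M == 0]), PM[st$M[row] + 1, 1],
                   tolerance = 1e-12)
      expect_equal(sum(P[row, st$E == 1]), PE[st$E[row] + 1, 2],
                   tolerance = 1e-12)
    }
  }
})

test_that("the joint chain is irreducible and aperiodic on the open cube", {
  set.seed(23)
  p <- random_params(20)
  for (i in seq_len(nrow(p))) {
    P <- transition_matrix(model_from_row(p, i))
    # some power entrywise positive => irreducible + aperiodic
    P2 <- P %*% P
    expect_true(all(P2 %*% P2 > 0))
  }
})
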