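test_that("propagate applies the chain update and respects stationarity", {
  m <- valence_model(0.7, 0.1, 0.3, 0.2, 0.4)
  P <- transition_matrix(m)
  u <- rep(1 / 8, 8)
  expect_equal(propagate(u, P, 0), u)
  expect_equal(propagate(u, P, 1), as.numeric(u %*% P))
  pi_bar <- stationary_distribution(P)
  expect_equal(propagate(pi_bar, P, 7), unname(pi_bar), tolerance = 1e-12)
  expect_error(propagate(rep(0.5, 2), P, 1), "length")
})

test_that("direct stationary solve matches the power-iteration oracle", {
  set.seed(31)
  p <- random_params(10)
  for (i in seq_len(nrow(p))) {
    P <- transition_matrix(model_from_row(p, i))
    pi_direct <- stationary_distribution(P)
    pi_power <- propagate(rep(1 / 8, 8), P, 10000)
    expect_equal(unname(pi_direct), pi_power, tolerance = 1e-10)
    expect_equal(sum(pi_direct), 1, tolerance = 1e-12)
    expect_true(all(pi_direct >= 0))
  }
})

test_that("two-state chains have the uniform stationary distribution", {
  for (x in runif(25)) {
    expect_equal(unname(stationary_distribution(mood_matrix(x))),
                 c(0.5, 0.5), tolerance = 1e-12)
  }
  expect_error(stationary_distribution(matrix(c(0.5, 0.6, 0.6, 0.4), 2)),
               "sum to 1")
})

test_that("closed-form pi_v1 matches hand evaluation and the reduced form", {
  # alpha = beta forces 0.5: numerator -0.2348, denominator -0.4696
  expect_equal(pi_v1_closed_form(0.3, 0.3, 0.4, 0.7), 0.5,
               tolerance = 1e-14)
  expect_equal(pi_v1_simplified(0.9, 0.1, 0.5), 0.95 / 1.5,
               tolerance = 1e-14)
  # the reduced form applies at r = 0.5
  set.seed(43)
  p <- random_params(100)
  expect_equal(pi_v1_closed_form(p$alpha, p$beta, p$omega, rep(0.5, 100)),
               pi_v1_simplified(p$alpha, p$beta, p$omega),
               tolerance = 1e-12)
  # swap symmetry: shared denominator
  expect_equal(pi_v1_simplified(p$alpha, p$beta, p$omega) +
                 pi_v1_simplified(p$beta, p$alpha, p$omega),
               rep(1, 100), tolerance = 1e-12)
})

test_that("closed-form pi_v1 equals the stationary mass on V = 1 states", {
  set.seed(59)
  p <- random_params(60)
  for (i in seq_len(nrow(p))) {
    m <- model_from_row(p, i)
    pv_num <- sum(stationary_distribution(transition_matrix(m))[5:8])
    pv_cf <- pi_v1_closed_form(p$alpha[i], p$beta[i], p$omega[i], p$r[i])
    expect_equal(pv_num, pv_cf, tolerance = 1e-10)
  }
})

test_that("steady summary is internally consistent and s-independent", {
  s <- summary(valence_model(0.8, 0.1, 0.7, 0.2, 0.6))
  expect_s3_class(s, "summary.valence_model")
  expect_equal(s$pi_v1 + s$pi_v0, 1, tolerance = 1e-12)
  expect_equal(s$delta_ego, 2 * sum(s$pi_bar[c(1, 2, 7, 8)]) - 1)
  expect_equal(unname(s$mood_marginal), c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(unname(s$event_marginal), c(0.5, 0.5), tolerance = 1e-10)
  s9 <- summary(valence_model(0.8, 0.9, 0.7, 0.2, 0.6))
  expect_equal(s$pi_v1, s9$pi_v1, tolerance = 1e-10)
  expect_output(print(s), "pi_v1")
})

test_that("swapping alpha and beta reflects pi_v1 and negates delta_ego", {
  # the chain has a point symmetry: exchanging the two sensitivities maps
  # (pi_v1, delta_ego) to (1 - pi_v1, -delta_ego)
  set.seed(67)
  p <- random_params(100)
  for (i in seq_len(nrow(p))) {
    s1 <- summary(valence_model(p$r[i], p$s[i], p$alpha[i], p$beta[i],
                                p$omega[i]))
    s2 <- summary(valence_model(p$r[i], p$s[i], p$beta[i], p$alpha[i],
                                p$omega[i]))
    expect_equal(s1$pi_v1, 1 - s2$pi_v1, tolerance = 1e-10)
    expect_equal(s1$delta_ego, -s2$delta_ego, tolerance = 1e-10)
  }
})

test_that("pi_v1 grows with the egosyntonicity sensitivity alpha", {
  grid_vals <- phenotype_grid()$alpha
  set.seed(71)
  for (k in 1:20) {
    beta <- sample(grid_vals, 1); r <- sample(grid_vals, 1)
    omega <- sample(grid_vals, 1)
    pv <- pi_v1_closed_form(grid_vals, beta, omega, r)
    expect_true(all(diff(pv) >= -1e-12))
    # sign of pi_v1 - 0.5 follows the sign of alpha - beta
    expect_true(all(sign(round(pv - 0.5, 12)) == sign(grid_vals - beta)))
  }
})
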