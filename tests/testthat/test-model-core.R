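test_that("category probabilities form a proper distribution and match closed forms", {
  # flat item: all exponents zero
  p <- category_probabilities(0, rep(0, 10), 1)
  expect_equal(p, rep(1 / 11, 11), tolerance = 1e-14)
  expect_lt(abs(sum(p) - 1), 1e-12)
  # dichotomous reduction to the logistic
  p <- category_probabilities(2, 0, 1)
  expect_equal(p[2], exp(2) / (1 + exp(2)), tolerance = 1e-12)
  # direct-formula oracle on random parameter draws
  set.seed(42)
  for (k in 1:20) {
    m <- sample(2:10, 1)
    tau <- stats::runif(m, -3, 3)
    delta <- stats::runif(1, 0.3, 3)
    theta <- stats::runif(1, -4, 4)
    expect_equal(category_probabilities(theta, tau, delta),
                 slow_gpcm_prob(theta, tau, delta), tolerance = 1e-12)
  }
  # first category falls, last rises in theta
  th <- seq(-4, 4, by = 0.5)
  P <- category_probabilities(th, fig1_tau, 1.5)
  expect_true(all(diff(P[, 1]) < 0))
  expect_true(all(diff(P[, 11]) > 0))
  expect_error(category_probabilities(0, fig1_tau, -1), "positive")
  expect_error(category_probabilities(0, numeric(0), 1), "degenerate")
})

test_that("adjacent CCCs intersect exactly at the thresholds", {
  for (delta in c(1.5, 3)) {
    for (s in seq_along(fig1_tau)) {
      p <- category_probabilities(fig1_tau[s], fig1_tau, delta)
      expect_lt(abs(p[s] - p[s + 1]), 1e-10)
    }
  }
  # higher discrimination sharpens every interior peak
  th <- seq(-6, 6, by = 0.01)
  P1 <- category_probabilities(th, fig1_tau, 1.5)
  P2 <- category_probabilities(th, fig1_tau, 3)
  for (x in 2:10) expect_gt(max(P2[, x]), max(P1[, x]))
})

test_that("pattern probabilities multiply over items and normalize", {
  ps <- tiny_params()
  # single-item pattern equals the category probability
  expect_equal(class_conditional_pattern_probability(c(1, NA), 1, ps, 0.7),
               category_probabilities(0.7, ps$tau[[1]][[1]], 1.2)[2])
  # empty product convention
  expect_equal(class_conditional_pattern_probability(c(NA, NA), 1, ps, 0), 1)
  expect_error(class_conditional_pattern_probability(c(5, 0), 1, ps, 0),
               "out of range")
  # class-conditional probabilities over the full outcome space sum to 1
  for (theta in c(-1.3, 0, 2)) {
    tot <- sum(vapply(0:2, function(a) vapply(0:2, function(b) {
      class_conditional_pattern_probability(c(a, b), 1, ps, theta)
    }, numeric(1)), numeric(3)))
    expect_lt(abs(tot - 1), 1e-12)
  }
  # marginal probabilities normalize within quadrature tolerance
  grid <- quadrature_grid(41)
  tot <- sum(vapply(0:2, function(a) vapply(0:2, function(b) {
    marginal_pattern_probability(c(a, b), ps, grid)
  }, numeric(1)), numeric(3)))
  expect_lt(abs(tot - 1), 1e-8)
  # a two-class mixture with identical components collapses
  ps2 <- parameter_set(list(ps$tau[[1]], ps$tau[[1]]),
                       matrix(1.2, 2, 2), c(0.35, 0.65), c(1, 1),
                       variant = "rmGPCM")
  expect_equal(marginal_pattern_probability(c(1, 2), ps2, grid),
               marginal_pattern_probability(c(1, 2), ps, grid),
               tolerance = 1e-14)
  expect_error(marginal_pattern_probability(c(1, 1), ps, list(nodes = NULL)),
               "empty quadrature")
})

test_that("quadrature is converged under node doubling at the documented setting", {
  # high-discrimination 11-category items need more than the 21-node
  # default; at the 61 nodes recommended for such items, doubling the grid
  # no longer moves pattern probabilities, and both agree with a dense
  # Riemann oracle
  ps <- parameter_set(list(list(c(-2, -1, 0.5, 2), c(-3, 0, 3))),
                      discriminations = c(3, 1.1), mixing = 1, variances = 1,
                      variant = "GPCM")
  g61 <- quadrature_grid(61); g122 <- quadrature_grid(122)
  for (pat in list(c(0, 0), c(2, 1), c(4, 3))) {
    p61 <- marginal_pattern_probability(pat, ps, g61)
    p122 <- marginal_pattern_probability(pat, ps, g122)
    expect_lt(abs(p122 - p61), 1e-6)
    expect_lt(abs(p122 - slow_marginal(pat, ps)), 1e-6)
  }
})

test_that("log-likelihood is additive and matches a dense-grid oracle", {
  ps <- tiny_params()
  pat <- matrix(c(1, 2), 1, 2)
  one <- response_matrix(pat, n_categories = 3)
  five <- response_matrix(pat[rep(1, 5), ], n_categories = 3)
  g <- quadrature_grid(41)
  expect_equal(log_likelihood(five, ps, g), 5 * log_likelihood(one, ps, g),
               tolerance = 1e-12)
  expect_equal(log_likelihood(NULL, ps, g), 0)
  tiny <- response_matrix(rbind(c(0, 2), c(1, 1), c(2, 0)), n_categories = 3)
  oracle <- sum(log(vapply(1:3, function(v) {
    slow_marginal(tiny$values[v, ], ps)
  }, numeric(1))))
  expect_equal(log_likelihood(tiny, ps, g), oracle, tolerance = 1e-6)
})

test_that("model variants coincide under their defining constraints", {
  set.seed(9)
  dat <- generate_responses(scenario_preset("ordered_11"), 40, seed = 3)$data
  tau3 <- lapply(1:2, function(g) lapply(1:5, function(i) fig1_tau + 0.1 * g))
  g <- quadrature_grid(21)
  # mGPCM with tied class parameters equals the shared-slope mixture
  p_rm <- parameter_set(tau3, c(1, 1.3, 0.8, 1.1, 0.9), c(0.5, 0.5),
                        c(1, 1.2), variant = "rmGPCM")
  p_mg <- parameter_set(tau3, matrix(c(1, 1.3, 0.8, 1.1, 0.9), 2, 5,
                                     byrow = TRUE),
                        c(0.5, 0.5), c(1, 1.2), variant = "mGPCM")
  expect_equal(log_likelihood(dat, p_rm, g), log_likelihood(dat, p_mg, g),
               tolerance = 1e-10)
  # shared slopes all equal reduces to the partial credit mixture
  p_rm1 <- parameter_set(tau3, rep(1, 5), c(0.5, 0.5), c(1, 1.2),
                         variant = "rmGPCM")
  p_mp <- parameter_set(tau3, 1, c(0.5, 0.5), c(1, 1.2), variant = "mPCM")
  expect_equal(log_likelihood(dat, p_rm1, g), log_likelihood(dat, p_mp, g),
               tolerance = 1e-10)
})

test_that("free-parameter counts follow the identification scheme", {
  # 11-category, 5-item family across class counts
  for (G in 1:5) {
    spec <- model_spec(if (G == 1) "GPCM" else "rmGPCM", G, 11, 5)
    expect_identical(count_free_parameters(spec),
                     as.integer(G * 50 + 4 + G + (G - 1)))
  }
  expect_identical(count_free_parameters(model_spec("PCM", 1, 3, 2)), 5L)
  expect_identical(count_free_parameters(model_spec("mGPCM", 2, 4, 3)),
                   as.integer(2 * 9 + (6 - 1) + 2 + 1))
})

test_that("parameter sets validate their invariants and round-trip JSON", {
  expect_error(parameter_set(list(list(c(0, 1))), discriminations = -1),
               "positive")
  expect_error(parameter_set(list(list(c(0, 1)), list(c(0, 1))),
                             mixing = c(0.4, 0.7)), "sum to 1")
  expect_error(parameter_set(list(list(c(0, 1)), list(c(0, 1))),
                             discriminations = matrix(c(1, 2), 2, 1),
                             mixing = c(0.5, 0.5), variant = "rmGPCM"),
               "shared across classes")
  ps <- scenario_preset("hilda_like")
  tmp <- tempfile(fileext = ".json")
  params_to_json(ps, tmp)
  back <- params_from_json(tmp)
  expect_equal(back$tau, ps$tau, tolerance = 1e-12)
  expect_equal(back$delta, ps$delta)
  expect_equal(back$pi, ps$pi)
  expect_identical(back$variant, "rmGPCM")
})
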