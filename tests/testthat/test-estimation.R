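test_that("posterior class probabilities follow Bayes' rule", {
  ps <- tiny_params()
  dat <- generate_responses(ps, 30, seed = 2)$data
  # G = 1: posterior identically one
  post1 <- posterior_class_probabilities(ps, dat)
  expect_true(all(post1 == 1))
  # identical class parameters: class marginals equal the mixing weights
  ps2 <- parameter_set(list(ps$tau[[1]], ps$tau[[1]]), matrix(1.2, 2, 2),
                       c(0.3, 0.7), c(1, 1), variant = "rmGPCM")
  post2 <- posterior_class_probabilities(ps2, dat)
  expect_equal(post2, matrix(c(0.3, 0.7), 30, 2, byrow = TRUE),
               tolerance = 1e-10, ignore_attr = TRUE)
  # hand-computable two-node case, one dichotomous item
  grid <- structure(list(nodes = c(-1, 1), weights = c(0.5, 0.5)),
                    class = "mixpcm_grid")
  psd <- parameter_set(list(list(0), list(1)), matrix(1, 2, 1),
                       c(0.4, 0.6), c(1, 1), variant = "mPCM")
  d1 <- response_matrix(matrix(1, 1, 1), n_categories = 2)
  eng <- mixpcm:::estep_engine(d1, psd, grid, want_counts = FALSE)
  # joint: pi_g * w_q * P(x=1 | theta_gq), theta_gq = sigma_g * z_q
  p_gq <- function(pi, tau, th) pi * 0.5 * exp(th - tau) / (1 + exp(th - tau))
  joint <- c(p_gq(0.4, 0, -1), p_gq(0.4, 0, 1), p_gq(0.6, 1, -1), p_gq(0.6, 1, 1))
  expect_equal(as.numeric(eng$r), joint / sum(joint), tolerance = 1e-12)
  expect_equal(exp(eng$ll), sum(joint), tolerance = 1e-12)
  # permutation invariance: relabeling classes permutes posterior columns
  psd_swapped <- mixpcm:::relabel_by_size(psd, c(2L, 1L))
  post_a <- posterior_class_probabilities(psd, d1)
  post_b <- posterior_class_probabilities(psd_swapped, d1)
  expect_equal(post_a[, c(2, 1), drop = FALSE], post_b, tolerance = 1e-12)
})

test_that("EM updates match their closed forms and respect constraints", {
  ps2 <- parameter_set(list(list(c(-1, 0.2), c(-0.4, 0.8)),
                            list(c(0.5, 1.2), c(-1.5, 0))),
                       1, c(0.55, 0.45), c(1, 1), variant = "mPCM")
  dat <- generate_responses(ps2, 300, seed = 8)$data
  grid <- quadrature_grid(21)
  eng <- mixpcm:::estep_engine(dat, ps2, grid)
  # responsibilities per person sum to one over (class, node)
  expect_equal(rowSums(eng$r), rep(1, 300), tolerance = 1e-10)
  # one EM iteration: pi update equals class-marginal responsibility means
  em1 <- mixpcm:::run_em(dat, ps2, grid, 2, 1e-15)
  Ng <- colSums(matrix(eng$Ngq, length(grid$nodes), 2))
  expect_equal(em1$params$pi, Ng / 300, tolerance = 1e-12)
  # partial-credit mixture updates never touch the slopes
  expect_true(all(em1$params$delta == 1))
})

test_that("EM is monotone and deterministic; fits agree with an independent oracle", {
  ps <- tiny_params()
  dat <- generate_responses(ps, 200, seed = 5)$data
  f1 <- quiet_fit(dat, "PCM", 1, options = fast_opts(11))
  f2 <- quiet_fit(dat, "PCM", 1, options = fast_opts(11))
  expect_identical(f1$log_likelihood, f2$log_likelihood)
  tr <- f1$convergence$em_trace
  expect_true(all(diff(tr) >= -1e-8 * abs(tr[-length(tr)])))
  # independent oracle: dense-grid marginal likelihood maximized by nlminb
  # over (tau11, tau12, tau21, tau22, log sigma2) from several starts
  theta <- seq(-6, 6, by = 0.01)
  x1 <- dat$values[, 1] + 1L; x2 <- dat$values[, 2] + 1L
  obj <- function(v) {
    dens <- stats::dnorm(theta, 0, sqrt(exp(v[5]))) * 0.01
    P1 <- t(vapply(theta, function(t) slow_gpcm_prob(t, v[1:2], 1), numeric(3)))
    P2 <- t(vapply(theta, function(t) slow_gpcm_prob(t, v[3:4], 1), numeric(3)))
    lik <- crossprod(P1[, x1] * P2[, x2], dens)   # per-person marginals
    -sum(log(lik))
  }
  best <- Inf
  for (s in list(c(-0.5, 0.5, -1, 0.3, 0), c(0, 0, 0, 0, 0.2))) {
    o <- stats::nlminb(s, obj)
    best <- min(best, o$objective)
  }
  expect_lt(abs(-best - f1$log_likelihood), 1e-3 * abs(best))
})

test_that("widely separated classes yield near-certain posteriors", {
  # thresholds shifted +-5 put the two classes' response ranges apart;
  # the Bayes posterior then assigns nearly all mass to one class
  base <- c(-1, 0, 1)
  ps <- parameter_set(list(lapply(1:3, function(i) base - 5),
                           lapply(1:3, function(i) base + 5)),
                      1, c(0.6, 0.4), c(1, 1), variant = "mPCM")
  dat <- generate_responses(ps, 250, seed = 4)$data
  post <- posterior_class_probabilities(ps, dat)
  expect_equal(rowSums(post), rep(1, 250), tolerance = 1e-10)
  expect_gt(mean(apply(post, 1, max)), 0.99)
})

test_that("modal assignment uses the documented tie-break and reports class means", {
  post <- rbind(c(0.9, 0.1), c(0.6, 0.4))
  expect_warning(res <- assign_modal_classes(post), "empty class")
  expect_identical(res$labels, c(1L, 1L))
  expect_equal(res$mean_probability[1], 0.75)
  expect_true(is.nan(res$mean_probability[2]) ||
                is.na(res$mean_probability[2]))
  tie <- suppressWarnings(assign_modal_classes(rbind(c(0.5, 0.5))))
  expect_identical(tie$labels, 1L)
  expect_identical(tie$n_ties, 1L)
  ident <- assign_modal_classes(diag(3))
  expect_equal(ident$mean_probability, rep(1, 3))
})

test_that("nested variants are ordered in likelihood when seeded from each other", {
  ps <- parameter_set(list(list(c(-1, 0, 1), c(-0.5, 0.3, 1.2)),
                           list(c(0.5, 1, 1.5), c(-1.2, -0.4, 0.6))),
                      c(1, 1.6), c(0.5, 0.5), c(1, 1), variant = "rmGPCM")
  dat <- generate_responses(ps, 400, seed = 14)$data
  o <- fast_opts(7, n_starts = 4)
  f_mp <- quiet_fit(dat, "mPCM", 2, options = o)
  f_rm <- quiet_fit(dat, "rmGPCM", 2, options = o,
                    start = mixpcm:::embed_in_variant(f_mp$params, "rmGPCM"))
  f_mg <- quiet_fit(dat, "mGPCM", 2, options = o,
                    start = mixpcm:::embed_in_variant(f_rm$params, "mGPCM"))
  expect_gte(f_rm$log_likelihood, f_mp$log_likelihood - 1e-6)
  expect_gte(f_mg$log_likelihood, f_rm$log_likelihood - 1e-6)
  # label-switching control: classes come back ordered by size
  expect_true(all(diff(f_mp$params$pi) <= 0))
  expect_true(all(diff(f_rm$params$pi) <= 0))
})

test_that("standard errors shrink at the root-n rate and skip fixed parameters", {
  ps <- tiny_params()
  ns <- c(400, 1600, 6400)
  ses <- vapply(ns, function(n) {
    dat <- generate_responses(ps, n, seed = 100 + n)$data
    fit <- quiet_fit(dat, "PCM", 1, options = fast_opts(2, n_starts = 2))
    fit <- standard_errors(fit, dat)
    fit$se$se[fit$se$parameter == "tau[g1,item1,s1]"]
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(ses) ~ log(ns)))[2]
  expect_lt(abs(slope + 0.5), 0.1)
  # GPCM: the first item's slope is fixed and carries no SE row
  dat <- generate_responses(parameter_set(list(list(c(-1, 1), c(0, 0.8))),
                                          c(1, 1.4), 1, 1, variant = "GPCM"),
                            300, seed = 9)$data
  fit <- standard_errors(quiet_fit(dat, "GPCM", 1,
                                   options = fast_opts(2, n_starts = 2)), dat)
  expect_false(any(grepl("delta\\[item1\\]", fit$se$parameter)))
  expect_true(any(grepl("delta\\[item2\\]", fit$se$parameter)))
  expect_true(all(fit$se$se > 0))
})

test_that("observed-information SEs agree with a parametric-bootstrap SD", {
  # four dichotomous items, single class
  ps <- parameter_set(list(list(-0.8, -0.2, 0.4, 1)), 1, 1, 1,
                      variant = "PCM")
  dat <- generate_responses(ps, 600, seed = 31)$data
  fit <- quiet_fit(dat, "PCM", 1, options = fast_opts(5, n_starts = 2))
  fit <- standard_errors(fit, dat)
  se_tau1 <- fit$se$se[fit$se$parameter == "tau[g1,item1,s1]"]
  boot <- vapply(1:60, function(b) {
    sim <- generate_responses(fit$params, 600, seed = 7000 + b)$data
    bf <- quiet_fit(sim, "PCM", 1,
                    options = fit_options(n_starts = 1, n_start_iterations = 5,
                                          max_em_iterations = 200,
                                          max_newton_iterations = 40,
                                          em_tolerance = 1e-7, seed = b))
    bf$params$tau[[1]][[1]][1]
  }, numeric(1))
  expect_lt(abs(se_tau1 - stats::sd(boot)) / stats::sd(boot), 0.25)
})
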