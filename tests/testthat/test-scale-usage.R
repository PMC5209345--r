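fig_params <- function(tau, delta = 1.5) {
  parameter_set(list(list(tau)), delta, 1, 1)
}

test_that("threshold ordering distinguishes ordinary and disordered items", {
  rep1 <- threshold_order_report(fig_params(fig1_tau))
  expect_identical(rep1$n_ordered, 9L)
  expect_length(rep1$inversions[[1]], 0)
  rep2 <- threshold_order_report(fig_params(fig2_tau))
  expect_identical(rep2$inversions[[1]], 7L)
  expect_identical(rep2$n_ordered, 8L)
  # ties count as ordered under the documented non-strict convention
  rep3 <- threshold_order_report(fig_params(rep(0.3, 4)))
  expect_identical(rep3$n_ordered, 3L)
  expect_length(rep3$inversions[[1]], 0)
})

test_that("avoided-category detection flags the covered category only", {
  for (delta in c(1.5, 3)) {
    ms <- modal_category_set(fig2_tau, delta)
    expect_identical(ms$avoided, 7L)
    expect_setequal(ms$modal, setdiff(0:10, 7))
  }
  ms1 <- modal_category_set(fig1_tau, 1.5)
  expect_length(ms1$avoided, 0)
  # dichotomous item: both categories modal
  msd <- modal_category_set(0.2, 1)
  expect_setequal(msd$modal, 0:1)
  expect_error(modal_category_set(fig1_tau, 1.5, theta_range = c(2, 2)),
               "degenerate")
})

test_that("modal regions of an ordered equidistant item are bounded by its thresholds", {
  theta <- seq(-6, 6, by = 0.001)
  P <- category_probabilities(theta, fig1_tau, 1.5)
  arg <- max.col(P, ties.method = "first") - 1L
  expect_true(all(diff(arg) >= 0))
  # transition points sit within one grid step of the thresholds
  trans <- theta[which(diff(arg) == 1L)]
  expect_equal(trans, fig1_tau, tolerance = 2e-3)
})

test_that("CCC curve data normalizes and orders argmax sequences", {
  cc <- ccc_curve_data(fig1_tau, 1.5, theta = seq(-5, 5, by = 0.05))
  expect_equal(rowSums(cc[, -1]), rep(1, nrow(cc)), tolerance = 1e-12)
  arg <- max.col(as.matrix(cc[, -1]), ties.method = "first") - 1L
  expect_true(all(diff(arg) >= 0))
  cc2 <- ccc_curve_data(fig2_tau, 3, theta = seq(-6, 6, by = 0.01))
  arg2 <- unique(max.col(as.matrix(cc2[, -1]), ties.method = "first") - 1L)
  expect_false(7 %in% arg2)
})

test_that("latent category widths are adjacent threshold differences", {
  w1 <- latent_category_widths(fig_params(fig1_tau))
  expect_equal(w1$widths$width, rep(0.5, 9))
  expect_equal(w1$class_summary$min_ordered_width, 0.5)
  wd <- latent_category_widths(fig_params(0.4))
  expect_identical(nrow(wd$widths), 0L)
  # three-class preset: class-1 total-pay widths match direct subtraction
  ps <- scenario_preset("hilda_like")
  w <- latent_category_widths(ps)
  tp <- w$widths[w$widths$class == 1 & w$widths$item == "total_pay", ]
  expect_equal(tp$width, diff(ps$tau[[1]][[1]]), tolerance = 1e-12)
})

test_that("expected category frequencies normalize and vary smoothly", {
  # a flat item (all tau = 0) is symmetric in the categories; integrating
  # over the latent distribution keeps the symmetry (and collapses to the
  # uniform 1/11 vector only as the latent variance vanishes)
  flat <- parameter_set(list(list(rep(0, 10), rep(0, 10))), 1, 1, 1)
  ef <- expected_category_frequencies(flat)
  expect_equal(ef$by_class[1, ], rev(ef$by_class[1, ]), tolerance = 1e-12,
               ignore_attr = TRUE)
  flat0 <- parameter_set(list(list(rep(0, 10), rep(0, 10))), 1, 1, 1e-10)
  ef0 <- expected_category_frequencies(flat0)
  expect_equal(as.numeric(ef0$by_class[1, ]), rep(1 / 11, 11),
               tolerance = 1e-6)
  ps <- scenario_preset("hilda_like")
  ef2 <- expected_category_frequencies(ps)
  expect_equal(rowSums(ef2$by_class), rep(1, 3), tolerance = 1e-9)
  expect_equal(sum(ef2$overall), 1, tolerance = 1e-9)
  # continuity in the thresholds
  ps_pert <- ps
  ps_pert$tau[[1]][[1]][3] <- ps_pert$tau[[1]][[1]][3] + 1e-6
  ef3 <- expected_category_frequencies(ps_pert)
  expect_lt(max(abs(ef3$by_class - ef2$by_class)), 1e-4)
})

test_that("marginal reliability behaves like an information measure", {
  ps4 <- parameter_set(list(rep(list(c(-1, 0, 1)), 4)), 1.5, 1, 1,
                       variant = "PCM")
  sim <- generate_responses(ps4, 800, seed = 12)
  rel4 <- marginal_reliability(ps4, sim$data)
  expect_gte(rel4, 0); expect_lte(rel4, 1)
  # dropping half the items lowers reliability on the same persons
  ps2 <- parameter_set(list(rep(list(c(-1, 0, 1)), 2)), 1.5, 1, 1,
                       variant = "PCM")
  d2 <- response_matrix(sim$data$values[, 1:2], n_categories = 4)
  expect_gt(rel4, marginal_reliability(ps2, d2))
  # near-zero discrimination carries almost no information
  ps0 <- parameter_set(list(rep(list(c(-1, 0, 1)), 4)), 0.01, 1, 1,
                       variant = "PCM")
  expect_lt(marginal_reliability(ps0, sim$data), 0.05)
  # invariant to class relabeling
  psm <- parameter_set(list(rep(list(c(-1, 0, 1)), 2),
                            rep(list(c(0, 1, 2)), 2)),
                       1, c(0.6, 0.4), c(1, 1), variant = "mPCM")
  simm <- generate_responses(psm, 400, seed = 3)
  expect_equal(marginal_reliability(psm, simm$data),
               marginal_reliability(mixpcm:::relabel_by_size(psm, c(2L, 1L)),
                                    simm$data), tolerance = 1e-12)
})

test_that("Cronbach's alpha matches hand computation and null behaviour", {
  x <- cbind(a = c(0, 1, 2, 1, 0, 2), b = c(0, 1, 2, 1, 0, 2))
  expect_equal(cronbach_alpha(x), 1, tolerance = 1e-12)
  m3 <- rbind(c(0, 1, 2), c(1, 2, 0), c(2, 2, 1))
  items <- apply(m3, 2, stats::var)
  tot <- stats::var(rowSums(m3))
  expect_equal(cronbach_alpha(m3), 1.5 * (1 - sum(items) / tot),
               tolerance = 1e-12)
  set.seed(44)
  u <- matrix(sample(0:10, 5 * 10000, replace = TRUE), ncol = 5)
  expect_lt(abs(cronbach_alpha(u)), 0.05)
  expect_warning(expect_true(is.nan(cronbach_alpha(matrix(1, 5, 3)))),
                 "zero")
})

test_that("the scale-usage report assembles all diagnostics", {
  rep <- scale_usage_report(scenario_preset("avoided_mid"))
  expect_s3_class(rep, "mixpcm_usage")
  expect_true(all(rep$avoided$n_avoided >= 1))
  expect_true(all(vapply(rep$avoided$avoided, function(a) 7 %in% a, logical(1))))
  expect_identical(rep$thresholds$inversions[[1]], 7L)
})
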