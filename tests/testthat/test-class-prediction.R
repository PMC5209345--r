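test_that("the classification error matrix follows its defining formula", {
  post <- diag(3)[c(1, 2, 3, 1, 2), ]
  D <- classification_error_matrix(post)
  expect_equal(D, diag(3), ignore_attr = TRUE)
  post2 <- matrix(0.5, 4, 2)
  D2 <- classification_error_matrix(post2, modal_labels = rep(1L, 4))
  expect_equal(unname(D2), rbind(c(1, 1), c(0, 0)))
  set.seed(5)
  r <- matrix(stats::rexp(60), 20, 3)
  r <- r / rowSums(r)
  D3 <- classification_error_matrix(r)
  expect_equal(colSums(D3), rep(1, 3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(classification_error_matrix(r * 2), "sum to 1")
})

test_that("dummy encoding respects declared references and round-trips", {
  df <- data.frame(size = c("s", "m", "l", "m"), age = c(30, 40, 50, 60),
                   stringsAsFactors = FALSE)
  X <- dummy_encode(df, references = list(size = "s"))
  expect_identical(colnames(X), c("(Intercept)", "size=l", "size=m", "age"))
  expect_equal(X[1, c("size=l", "size=m")], c(`size=l` = 0, `size=m` = 0))
  # decode from the indicator columns recovers the original levels
  dec <- ifelse(X[, "size=l"] == 1, "l", ifelse(X[, "size=m"] == 1, "m", "s"))
  expect_identical(unname(dec), df$size)
  expect_error(dummy_encode(df, references = list(size = "xl")), "not a level")
  df$age[2] <- NA
  expect_error(dummy_encode(df), "missing covariate")
})

test_that("with an identity error matrix the three-step fit is a plain multinomial logit", {
  skip_if_not_installed("nnet")
  set.seed(71)
  n <- 1500
  x <- stats::rnorm(n)
  f <- factor(sample(c("a", "b"), n, replace = TRUE))
  eta2 <- -0.4 + 0.8 * x + 0.5 * (f == "b")
  eta3 <- 0.2 - 0.6 * x
  pr <- cbind(1, exp(eta2), exp(eta3))
  pr <- pr / rowSums(pr)
  lab <- vapply(seq_len(n), function(i) sample(3, 1, prob = pr[i, ]), 1L)
  X <- dummy_encode(data.frame(x = x, f = f))
  res <- three_step_multinomial(lab, diag(3), X)
  oracle <- nnet::multinom(factor(lab) ~ x + f, trace = FALSE, reltol = 1e-12)
  expect_equal(as.numeric(res$B), as.numeric(coef(oracle)), tolerance = 5e-4)
  expect_true(all(res$coefficients[[1]]$ci_lower <
                    res$coefficients[[1]]$ci_upper))
  expect_gt(res$pseudo_r2, 0)
  # intercept-only model reproduces the label proportions
  res0 <- three_step_multinomial(lab, diag(3), X[, 1, drop = FALSE])
  b0 <- res0$B[, 1]
  p_hat <- exp(c(0, b0)) / sum(exp(c(0, b0)))
  expect_equal(p_hat, as.numeric(table(lab) / n), tolerance = 1e-6)
})

test_that("covariate generation and adjusted regression recover a known logit truth", {
  set.seed(123)
  n <- 8000
  labels <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.33, 0.27))
  spec <- list(
    z = list(type = "normal", mean = 0, sd = 1, beta = c(0, 0.6, -0.4)),
    grp = list(type = "categorical", levels = c("ref", "alt"),
               base = c(0.5, 0.5),
               beta = rbind(c(0, 0, 0), c(0, 0.7, 0.3))))
  cov <- generate_covariates(labels, spec, seed = 2)
  X <- dummy_encode(cov)
  res <- three_step_multinomial(labels, diag(3), X)
  # slopes recover the generating coefficients
  expect_lt(abs(res$B[1, colnames(X) == "z"] - 0.6), 0.1)
  expect_lt(abs(res$B[2, colnames(X) == "z"] + 0.4), 0.1)
  expect_lt(abs(res$B[1, colnames(X) == "grp=alt"] - 0.7), 0.1)
  expect_lt(abs(res$B[2, colnames(X) == "grp=alt"] - 0.3), 0.1)
})

test_that("pairwise contrasts are consistent across reference choices", {
  set.seed(31)
  n <- 2000
  x <- stats::rnorm(n)
  pr <- cbind(1, exp(0.5 * x), exp(-0.5 + 0.3 * x))
  pr <- pr / rowSums(pr)
  lab <- vapply(seq_len(n), function(i) sample(3, 1, prob = pr[i, ]), 1L)
  X <- dummy_encode(data.frame(x = x))
  r1 <- three_step_multinomial(lab, diag(3), X, reference = 1)
  r3 <- three_step_multinomial(lab, diag(3), X, reference = 3)
  derived <- threestep_contrast(r1, 2, 3)    # class 2 vs class 3
  direct <- r3$coefficients[["class2_vs_class3"]]
  expect_equal(derived$B, direct$B, tolerance = 1e-5)
  # the derived contrast is exactly the coefficient difference
  expect_equal(derived$B, r1$B[1, ] - r1$B[2, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("as classification error vanishes, adjusted estimates approach unadjusted ones", {
  set.seed(99)
  n <- 3000
  x <- stats::rnorm(n)
  pr <- cbind(1, exp(0.3 + 0.8 * x))
  pr <- pr / rowSums(pr)
  true_lab <- vapply(seq_len(n), function(i) sample(2, 1, prob = pr[i, ]), 1L)
  X <- dummy_encode(data.frame(x = x))
  unadj <- three_step_multinomial(true_lab, diag(2), X)$B[1, 2]
  flip_labels <- function(p_keep) {
    keep <- stats::runif(n) < p_keep
    ifelse(keep, true_lab, 3L - true_lab)
  }
  # near-perfect assignment: adjusted and unadjusted coincide
  lab_hi <- flip_labels(0.999)
  D_hi <- matrix(c(0.999, 0.001, 0.001, 0.999), 2, 2)
  adj_hi <- three_step_multinomial(lab_hi, D_hi, X)$B[1, 2]
  expect_lt(abs(adj_hi - unadj), 0.05)
  # substantial misclassification: the correction de-attenuates the slope
  lab_lo <- flip_labels(0.8)
  D_lo <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2)
  adj <- three_step_multinomial(lab_lo, D_lo, X)$B[1, 2]
  naive <- three_step_multinomial(lab_lo, diag(2), X)$B[1, 2]
  expect_lt(abs(adj - 0.8), abs(naive - 0.8))
  expect_lt(naive, adj)   # naive estimate is attenuated toward zero
})
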