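# Bias-adjusted three-step regression of latent class membership on
# covariates: classify (modal assignment), quantify the classification
# error, then fit a multinomial logit in which the observed label's
# likelihood contribution is corrected by the misclassification matrix
# (the ML-based adjustment).

#' Classification error matrix
#'
#' \eqn{D[s, t] = P(assigned = s | true = t)} estimated from the posterior:
#' column t averages the indicator of assignment s weighted by the
#' posterior probability of class t.  Columns are probability vectors.
#'
#' @param posterior n x G posterior class probabilities.
#' @param modal_labels integer assignments (defaults to the modal rule).
#' @export
classification_error_matrix <- function(posterior, modal_labels = NULL) {
  posterior <- as.matrix(posterior)
  G <- ncol(posterior)
  if (max(abs(rowSums(posterior) - 1)) > 1e-6) {
    stop("posterior rows must sum to 1")
  }
  if (is.null(modal_labels)) {
    modal_labels <- assign_modal_classes(posterior)$labels
  }
  D <- matrix(0, G, G)
  for (t in seq_len(G)) {
    denom <- sum(posterior[, t])
    if (denom <= 0) stop("class ", t, " has no posterior support")
    for (s in seq_len(G)) {
      D[s, t] <- sum(posterior[modal_labels == s, t]) / denom
    }
  }
  dimnames(D) <- list(assigned = paste0("g", seq_len(G)),
                      true = paste0("g", seq_len(G)))
  D
}

#' Dummy-encode a covariate table
#'
#' Numeric columns pass through; each k-level factor becomes k - 1
#' indicator columns against its declared reference level.  An intercept
#' column is prepended.
#'
#' @param table data frame of covariates.
#' @param references named list/character vector: reference level per
#'   factor column (defaults to the first level).
#' @return design matrix with attribute \code{"assign_levels"} recording
#'   the factor levels for round-tripping and prediction-time checks.
#' @export
dummy_encode <- function(table, references = NULL) {
  stopifnot(is.data.frame(table))
  cols <- list(`(Intercept)` = rep(1, nrow(table)))
  levels_used <- list()
  for (nm in names(table)) {
    v <- table[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- as.numeric(v)
    } else {
      f <- as.factor(v)
      ref <- if (!is.null(references) && nm %in% names(references)) {
        as.character(references[[nm]])
      } else levels(f)[1]
      if (!ref %in% levels(f)) stop("declared reference '", ref,
                                    "' is not a level of ", nm)
      f <- stats::relevel(f, ref = ref)
      levels_used[[nm]] <- levels(f)
      for (lv in levels(f)[-1]) {
        cols[[paste0(nm, "=", lv)]] <- as.numeric(f == lv)
      }
    }
  }
  X <- do.call(cbind, cols)
  if (anyNA(X)) {
    stop("missing covariate values are not accepted; supply complete data")
  }
  attr(X, "assign_levels") <- levels_used
  X
}

# Negative log-likelihood and gradient of the corrected multinomial logit.
# B is (G-1) x p (classes 2..G vs reference class 1); d_v = D[s_v, ].
threestep_nll <- function(bvec, X, Drows, G) {
  p <- ncol(X); n <- nrow(X)
  B <- matrix(bvec, G - 1L, p)
  eta <- cbind(0, X %*% t(B))            # n x G
  mx <- do.call(pmax, as.data.frame(eta))
  U <- exp(eta - mx)
  U <- U / rowSums(U)                     # P(true = t | x)
  L <- rowSums(U * Drows)
  L <- pmax(L, 1e-300)
  val <- -sum(log(L))
  # dlogL/deta_k = U_k (d_k / L - 1); reference class column dropped
  W <- U * (Drows / L - 1)
  grad <- -t(W[, -1L, drop = FALSE]) %*% X   # (G-1) x p
  list(value = val, grad = as.numeric(grad))
}

#' Bias-adjusted three-step multinomial regression
#'
#' Maximum-likelihood multinomial logit of the (unobserved) true class on
#' covariates where each person's contribution is \eqn{\sum_t P(true = t |
#' x_v; B) D[s_v, t]}, \eqn{s_v} the modal assignment.  With D the
#' identity this reduces to an ordinary multinomial logit on the labels.
#' Coefficients are reported per non-reference class with standard errors
#' from the observed information, odds ratios \eqn{e^B} and 95\% Wald CIs
#' \eqn{\exp(B \pm 1.96 SE)}, plus McFadden's pseudo-R2 (in percent) on the
#' corrected likelihood.  Any pairwise contrast between classes r and q is
#' the coefficient difference \eqn{B_r - B_q}.
#'
#' @param modal_labels integer class assignments (1..G).
#' @param D G x G classification error matrix ([classification_error_matrix()]).
#' @param X design matrix from [dummy_encode()] (includes intercept).
#' @param reference reference class index (default 1).
#' @param max_iterations optimizer cap.
#' @return object of class \code{mixpcm_threestep}: coefficient tables per
#'   contrast, \code{pseudo_r2} (percent), the misclassification matrix and
#'   the log-likelihood.
#' @export
three_step_multinomial <- function(modal_labels, D, X, reference = 1,
                                   max_iterations = 500) {
  X <- as.matrix(X)
  G <- nrow(D)
  if (!all(modal_labels %in% seq_len(G))) stop("labels outside 1..G")
  if (nrow(X) != length(modal_labels)) stop("design matrix and labels disagree")
  kappa_D <- tryCatch(kappa(D), error = function(e) Inf)
  if (kappa_D > 1e8) {
    stop("classification error matrix is numerically singular (condition ",
         "number ", format(kappa_D, digits = 3), ")")
  }
  # reorder classes so the reference is class 1 internally
  perm <- c(reference, setdiff(seq_len(G), reference))
  Dp <- D[perm, perm]
  lab <- match(modal_labels, perm)
  Drows <- Dp[lab, , drop = FALSE]
  p <- ncol(X)
  cache <- new.env(parent = emptyenv())
  eval_at <- function(b) {
    if (!identical(cache$b, b)) {
      cache$res <- threestep_nll(b, X, Drows, G)
      cache$b <- b
    }
    cache$res
  }
  opt <- stats::optim(rep(0, (G - 1L) * p),
                      fn = function(b) eval_at(b)$value,
                      gr = function(b) eval_at(b)$grad,
                      method = "BFGS",
                      control = list(maxit = max_iterations, reltol = 1e-12))
  if (opt$convergence != 0 && opt$convergence != 1) {
    stop("three-step optimizer failed: code ", opt$convergence)
  }
  if (opt$convergence == 1) warning("three-step optimizer hit the iteration cap")
  B <- matrix(opt$par, G - 1L, p)
  if (any(abs(B) > 15)) warning("large coefficients suggest separation")
  # observed information by central differences of the analytic gradient
  nb <- length(opt$par)
  H <- matrix(0, nb, nb)
  for (j in seq_len(nb)) {
    h <- 1e-5 * (1 + abs(opt$par[j]))
    up <- opt$par; up[j] <- up[j] + h
    dn <- opt$par; dn[j] <- dn[j] - h
    H[, j] <- (eval_at2(up, X, Drows, G) - eval_at2(dn, X, Drows, G)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  cov <- tryCatch(solve(H), error = function(e) pracma::pinv(H))
  SE <- matrix(sqrt(pmax(diag(cov), 0)), G - 1L, p)
  # null model: intercept-only corrected likelihood for McFadden's R2
  X0 <- X[, 1, drop = FALSE]
  opt0 <- stats::optim(rep(0, G - 1L),
                       fn = function(b) threestep_nll(b, X0, Drows, G)$value,
                       gr = function(b) threestep_nll(b, X0, Drows, G)$grad,
                       method = "BFGS", control = list(maxit = max_iterations))
  pseudo_r2 <- 100 * (1 - opt$value / opt0$value)
  classes <- perm[-1L]
  coef_tables <- lapply(seq_len(G - 1L), function(k) {
    b <- B[k, ]; se <- SE[k, ]
    data.frame(term = colnames(X), B = b, SE = se,
               odds_ratio = exp(b),
               ci_lower = exp(b - 1.96 * se), ci_upper = exp(b + 1.96 * se),
               z = b / se, p_value = 2 * stats::pnorm(-abs(b / se)),
               row.names = NULL)
  })
  names(coef_tables) <- sprintf("class%d_vs_class%d", classes, reference)
  structure(list(coefficients = coef_tables, B = B, SE = SE,
                 reference = reference, classes = classes,
                 D = D, pseudo_r2 = pseudo_r2,
                 log_likelihood = -opt$value,
                 null_log_likelihood = -opt0$value),
            class = "mixpcm_threestep")
}

eval_at2 <- function(b, X, Drows, G) threestep_nll(b, X, Drows, G)$grad

#' Pairwise contrast between two non-reference classes
#'
#' The log-odds of class a versus class b is the coefficient difference
#' \eqn{B_a - B_b}.  Only the point contrast is reported; for standard
#' errors refit with \code{reference = class_b}.
#'
#' @param result a [three_step_multinomial()] result.
#' @param class_a,class_b non-reference class indices.
#' @export
threestep_contrast <- function(result, class_a, class_b) {
  ka <- match(class_a, result$classes)
  kb <- match(class_b, result$classes)
  if (is.na(ka) || is.na(kb)) stop("classes must be non-reference classes")
  data.frame(term = result$coefficients[[1]]$term,
             B = result$B[ka, ] - result$B[kb, ], row.names = NULL)
}

#' @export
print.mixpcm_threestep <- function(x, ...) {
  cat(sprintf("<mixpcm_threestep> reference class %d; pseudo-R2 = %.1f%%\n",
              x$reference, x$pseudo_r2))
  for (nm in names(x$coefficients)) {
    cat(" ", nm, "\n")
    tab <- x$coefficients[[nm]]
    print(data.frame(term = tab$term,
                     round(tab[, c("B", "SE", "odds_ratio")], 3)),
          row.names = FALSE)
  }
  invisible(x)
}
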