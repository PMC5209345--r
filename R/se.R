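# Standard errors from the observed information of the marginal likelihood.
# The Hessian is obtained by central differences of the analytic score; the
# sandwich variant combines it with per-person score outer products.

numeric_hessian <- function(vec, template, data, grid, h = 1e-5) {
  p <- length(vec)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    hj <- h * (1 + abs(vec[j]))
    up <- vec; up[j] <- up[j] + hj
    dn <- vec; dn[j] <- dn[j] - hj
    gu <- ll_grad_packed(up, template, data, grid)$grad
    gd <- ll_grad_packed(dn, template, data, grid)$grad
    H[, j] <- (gu - gd) / (2 * hj)
  }
  (H + t(H)) / 2
}

# n x p matrix of per-person score contributions at the packed estimate.
person_scores <- function(params, data, grid) {
  Q <- length(grid$nodes); G <- params$G; I <- params$I
  n <- nrow(data$values)
  eng <- estep_engine(data, params, grid, want_counts = FALSE)
  vals <- data$values
  Sc <- NULL
  # tau blocks, ordered (g, i, s)
  for (g in seq_len(G)) {
    cols <- (g - 1L) * Q + seq_len(Q)
    rg <- eng$r[, cols, drop = FALSE]
    for (i in seq_len(I)) {
      m <- params$m[i]
      lP <- eng$LP[[g]][[i]]; P <- exp(lP)
      Pge <- P %*% geq_matrix(m)
      x <- vals[, i]; ok <- !is.na(x)
      blk <- matrix(0, n, m)
      for (s in seq_len(m)) {
        kern <- -params$delta[g, i] *
          (matrix(as.numeric(x[ok] >= s), sum(ok), Q) -
             matrix(Pge[, s], sum(ok), Q, byrow = TRUE))
        blk[ok, s] <- rowSums(rg[ok, , drop = FALSE] * kern)
      }
      Sc <- cbind(Sc, blk)
    }
  }
  # log-delta entries
  msk <- free_delta_mask(params$variant, G, I)
  Dsc <- array(0, c(n, G, I))
  for (g in seq_len(G)) {
    cols <- (g - 1L) * Q + seq_len(Q)
    rg <- eng$r[, cols, drop = FALSE]
    for (i in seq_len(I)) {
      m <- params$m[i]
      P <- exp(eng$LP[[g]][[i]])
      A <- outer(eng$theta[g, ], 0:m) -
        matrix(c(0, cumsum(params$tau[[g]][[i]])), Q, m + 1L, byrow = TRUE)
      Abar <- rowSums(P * A)
      x <- vals[, i]; ok <- !is.na(x)
      Aobs <- t(A)[x[ok] + 1L, , drop = FALSE]  # persons x Q
      kern <- Aobs - matrix(Abar, sum(ok), Q, byrow = TRUE)
      Dsc[ok, g, i] <- rowSums(rg[ok, , drop = FALSE] * kern) * params$delta[g, i]
    }
  }
  if (nrow(msk) == 1L) {
    shared <- apply(Dsc, c(1, 3), sum)           # n x I
    Sc <- cbind(Sc, shared[, msk[1L, ], drop = FALSE])
  } else {
    flat <- matrix(Dsc, n, G * I)                # column-major over (g, i)
    Sc <- cbind(Sc, flat[, as.vector(msk), drop = FALSE])
  }
  # log sigma2
  for (g in seq_len(G)) {
    cols <- (g - 1L) * Q + seq_len(Q)
    rg <- eng$r[, cols, drop = FALSE]
    tot <- matrix(0, n, Q)
    for (i in seq_len(I)) {
      m <- params$m[i]
      P <- exp(eng$LP[[g]][[i]])
      Ex <- rowSums(P * matrix(0:m, Q, m + 1L, byrow = TRUE))
      x <- vals[, i]; ok <- !is.na(x)
      tot[ok, ] <- tot[ok, ] + params$delta[g, i] *
        (matrix(x[ok], sum(ok), Q) - matrix(Ex, sum(ok), Q, byrow = TRUE))
    }
    Sc <- cbind(Sc, rowSums(rg * tot * matrix(eng$theta[g, ] / 2, n, Q, byrow = TRUE)))
  }
  if (G > 1L) {
    post <- posterior_from_engine(eng)
    Sc <- cbind(Sc, post[, seq_len(G - 1L), drop = FALSE] -
                  matrix(params$pi[seq_len(G - 1L)], n, G - 1L, byrow = TRUE))
  }
  Sc
}

#' Standard errors for the free parameters of a fitted model
#'
#' Default: square roots of the diagonal of the inverse observed
#' information (numerical Hessian of the marginal log-likelihood at the
#' estimate).  The \code{"sandwich"} (robust) variant uses per-person score
#' outer products between two information inverses.  A singular information
#' matrix triggers a Moore-Penrose pseudo-inverse and a flag; non-finite or
#' non-positive variances are flagged as extreme.  Parameters fixed by the
#' identification scheme carry no standard error.
#'
#' Thresholds are reported on their natural scale; discrimination and
#' variance SEs are delta-method transforms of the log-scale SEs.
#'
#' @param fitted a [fit_mixgpcm()] result.
#' @param data the [response_matrix()] the model was fitted to.
#' @param type \code{"hessian"} (default) or \code{"sandwich"}.
#' @return the fit with \code{$se} filled in: a data frame of parameter
#'   names, estimates and standard errors, plus attributes \code{singular}
#'   and \code{n_extreme_se}.
#' @export
standard_errors <- function(fitted, data, type = c("hessian", "sandwich")) {
  type <- match.arg(type)
  stopifnot(inherits(fitted, "mixpcm_fit"))
  params <- fitted$params
  grid <- fitted$grid
  vec <- pack_params(params)
  H <- numeric_hessian(vec, params, data, grid)
  info <- -H
  singular <- FALSE
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov) || !all(is.finite(cov)) || any(diag(cov) <= 0)) {
    cov <- pracma::pinv(info)
    singular <- TRUE
  }
  if (type == "sandwich") {
    Sc <- person_scores(params, data, grid)
    meat <- crossprod(Sc)
    cov <- cov %*% meat %*% cov
  }
  se <- sqrt(pmax(diag(cov), 0))
  nm <- free_parameter_names(params)
  # delta-method back-transform for log-scale entries
  est <- vec
  natural <- est
  idx_logd <- grep("^log_delta", nm)
  idx_logs <- grep("^log_sigma2", nm)
  natural[idx_logd] <- exp(est[idx_logd])
  natural[idx_logs] <- exp(est[idx_logs])
  se_nat <- se
  se_nat[idx_logd] <- se[idx_logd] * exp(est[idx_logd])
  se_nat[idx_logs] <- se[idx_logs] * exp(est[idx_logs])
  tab <- data.frame(parameter = sub("^log_", "", nm), estimate = natural,
                    se = se_nat, stringsAsFactors = FALSE)
  extreme <- !is.finite(tab$se) | tab$se <= 0 | tab$se > 100
  attr(tab, "singular") <- singular
  attr(tab, "n_extreme_se") <- sum(extreme)
  attr(tab, "type") <- type
  fitted$se <- tab
  fitted
}
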