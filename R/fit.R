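#' Fitting options
#'
#' Controls for [fit_mixgpcm()].  Defaults mirror common practice for
#' mixture IRT estimation: many random starts, a generous EM iteration cap
#' (8000) with a Newton refinement cap (600), and a relative log-likelihood
#' convergence tolerance.
#'
#' @param n_starts number of random starting-value sets (default 100).
#' @param n_start_iterations short-EM iterations run per start before the
#'   best start is pursued to convergence (default 20).
#' @param max_em_iterations EM iteration cap (default 8000).
#' @param max_newton_iterations cap for the quasi-Newton refinement on the
#'   unconstrained parameters (default 600).
#' @param em_tolerance relative log-likelihood change declaring EM
#'   convergence (default 1e-8).
#' @param seed integer seed governing all starts via a splitting scheme:
#'   the seed generates one sub-seed per start, so results are reproducible
#'   and invariant to adding later starts.
#' @param strict if TRUE, refuse data with missing responses.
#' @param verbose print progress.
#' @export
fit_options <- function(n_starts = 100, n_start_iterations = 20,
                        max_em_iterations = 8000, max_newton_iterations = 600,
                        em_tolerance = 1e-8, seed = 1, strict = FALSE,
                        verbose = FALSE) {
  stopifnot(n_starts >= 1, n_start_iterations >= 1, max_em_iterations >= 1,
            max_newton_iterations >= 0, em_tolerance > 0)
  structure(list(n_starts = as.integer(n_starts),
                 n_start_iterations = as.integer(n_start_iterations),
                 max_em_iterations = as.integer(max_em_iterations),
                 max_newton_iterations = as.integer(max_newton_iterations),
                 em_tolerance = em_tolerance, seed = as.integer(seed),
                 strict = isTRUE(strict), verbose = isTRUE(verbose)),
            class = "mixpcm_options")
}

# Random starting values: thresholds uniform(-2, 2) sorted per item with
# jitter, delta log-uniform(0.5, 2) on free entries, pi from a flat random
# simplex, sigma2 = 1.
random_start <- function(spec) {
  G <- spec$G; I <- spec$I; m <- spec$m
  tau <- lapply(seq_len(G), function(g) {
    lapply(seq_len(I), function(i) {
      sort(stats::runif(m[i], -2, 2)) + stats::rnorm(m[i], 0, 0.1)
    })
  })
  delta <- matrix(1, G, I)
  if (spec$variant %in% c("GPCM", "rmGPCM")) {
    d <- exp(stats::runif(I, log(0.5), log(2))); d[1] <- 1
    delta <- matrix(d, G, I, byrow = TRUE)
  } else if (spec$variant == "mGPCM") {
    delta <- matrix(exp(stats::runif(G * I, log(0.5), log(2))), G, I)
    delta[1, 1] <- 1
  }
  pi <- if (G > 1) { e <- stats::rexp(G); e / sum(e) } else 1
  # keep starts off the simplex boundary
  if (G > 1) pi <- (pi + 0.05) / sum(pi + 0.05)
  parameter_set(tau, delta, pi, rep(1, G), variant = spec$variant)
}

# ---- M-step: per-item weighted GPCM maximization --------------------------

# Objective and gradient of the expected complete-data log-likelihood for
# one item, given counts C [category, node, class] and node locations
# theta [class, node].  Parameters: all class thresholds, plus log-delta
# entries according to `dfree` ("none", "shared", or a logical mask per
# class for class-specific slopes).
item_objgrad <- function(par, C, theta, m, delta0, dfree) {
  G <- nrow(theta)
  tau <- matrix(par[seq_len(G * m)], m, G)
  delta <- delta0
  nd <- 0L
  if (identical(dfree, "shared")) {
    delta <- rep(exp(par[G * m + 1L]), G); nd <- 1L
  } else if (is.logical(dfree)) {
    nd <- sum(dfree)
    if (nd > 0L) delta[dfree] <- exp(par[G * m + seq_len(nd)])
  }
  res <- .cpp_item_objgrad(as.numeric(C), theta, tau, delta)
  grad <- as.numeric(res$gtau)
  if (identical(dfree, "shared")) {
    grad <- c(grad, sum(res$gdelta) * delta[1])
  } else if (is.logical(dfree) && nd > 0L) {
    grad <- c(grad, (res$gdelta * delta)[dfree])
  }
  list(value = res$value, grad = grad)
}

item_delta_structure <- function(variant, i, G) {
  switch(variant,
    PCM = , mPCM = "none",
    GPCM = , rmGPCM = if (i == 1L) "none" else "shared",
    mGPCM = { msk <- rep(TRUE, G); if (i == 1L) msk[1L] <- FALSE; msk })
}

mstep_item <- function(C, theta, m, tau_cur, delta_cur, dfree, maxit = 15) {
  G <- nrow(theta)
  par0 <- c(as.numeric(tau_cur))
  if (identical(dfree, "shared")) par0 <- c(par0, log(delta_cur[1]))
  else if (is.logical(dfree) && any(dfree)) par0 <- c(par0, log(delta_cur[dfree]))
  cache <- new.env(parent = emptyenv())
  eval_at <- function(p) {
    if (!identical(cache$p, p)) {
      cache$res <- item_objgrad(p, C, theta, m, delta_cur, dfree)
      cache$p <- p
    }
    cache$res
  }
  nd <- length(par0) - G * m
  opt <- stats::optim(par0, fn = function(p) eval_at(p)$value,
                      gr = function(p) eval_at(p)$grad, method = "L-BFGS-B",
                      lower = c(rep(-30, G * m), rep(log(1e-3), nd)),
                      upper = c(rep(30, G * m), rep(log(1e3), nd)),
                      control = list(fnscale = -1, maxit = maxit))
  v0 <- item_objgrad(par0, C, theta, m, delta_cur, dfree)$value
  par <- opt$par; val <- opt$value
  k <- 0L
  while (val < v0 && k < 50L) {      # halving line search back toward par0
    par <- (par + par0) / 2
    val <- item_objgrad(par, C, theta, m, delta_cur, dfree)$value
    k <- k + 1L
  }
  if (val < v0) { par <- par0; val <- v0; warning("item M-step kept previous values") }
  tau <- matrix(par[seq_len(G * m)], m, G)
  delta <- delta_cur
  if (identical(dfree, "shared")) delta <- rep(exp(par[G * m + 1L]), G)
  else if (is.logical(dfree) && any(dfree)) delta[dfree] <- exp(par[G * m + seq_len(sum(dfree))])
  list(tau = tau, delta = delta, value = val)
}

# One-dimensional update of a class variance given expected counts.
mstep_sigma <- function(params, counts, nodes, Q, g) {
  taus <- params$tau[[g]]
  deltas <- params$delta[g, ]
  fn <- function(ls2) {
    .cpp_sigma_obj(counts, taus, deltas, nodes, exp(ls2 / 2), g - 1L,
                   params$G)
  }
  cur <- log(params$sigma2[g])
  opt <- stats::optimize(fn, interval = c(log(1e-3), log(25)), maximum = TRUE,
                         tol = 1e-6)
  if (opt$objective >= fn(cur)) opt$maximum else cur
}

run_em <- function(data, params, grid, max_iter, tol,
                   verbose = FALSE) {
  Q <- length(grid$nodes)
  trace <- numeric(0)
  ll_prev <- -Inf
  iter <- 0L
  eng <- NULL
  repeat {
    eng <- estep_engine(data, params, grid, want_counts = TRUE)
    ll <- sum(eng$ll)
    trace <- c(trace, ll)
    iter <- iter + 1L
    if (verbose && iter %% 50L == 0L) {
      message(sprintf("  EM iter %d: ll = %.4f", iter, ll))
    }
    done <- is.finite(ll_prev) &&
      abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-3)
    if (done || iter >= max_iter) break
    ll_prev <- ll
    # pi update
    if (params$G > 1L) {
      Ng <- colSums(matrix(eng$Ngq, Q, params$G))
      pi <- pmax(Ng / sum(Ng), 1e-12)
      params$pi <- pi / sum(pi)
    }
    # item updates at current node locations
    for (i in seq_len(params$I)) {
      C <- item_count_array(eng$counts[[i]], params$G, Q)
      tau_cur <- vapply(seq_len(params$G),
                        function(g) params$tau[[g]][[i]],
                        numeric(params$m[i]))
      tau_cur <- matrix(tau_cur, params$m[i], params$G)
      upd <- mstep_item(C, eng$theta, params$m[i], tau_cur,
                        params$delta[, i], item_delta_structure(params$variant, i, params$G))
      for (g in seq_len(params$G)) params$tau[[g]][[i]] <- upd$tau[, g]
      params$delta[, i] <- upd$delta
    }
    # variance updates
    for (g in seq_len(params$G)) {
      params$sigma2[g] <- exp(mstep_sigma(params, eng$counts, grid$nodes, Q, g))
    }
  }
  list(params = params, ll = trace[length(trace)], trace = trace,
       iterations = iter, engine = eng)
}

# ---- full-likelihood value/gradient on the unconstrained scale ------------

ll_grad_packed <- function(vec, template, data, grid) {
  params <- unpack_params(vec, template)
  Q <- length(grid$nodes)
  G <- params$G; I <- params$I
  eng <- estep_engine(data, params, grid, want_counts = TRUE)
  gtau <- vector("list", G)
  gdelta <- matrix(0, G, I)
  gsig <- numeric(G)
  for (g in seq_len(G)) {
    gtau[[g]] <- vector("list", I)
    cols <- (g - 1L) * Q + seq_len(Q)
    for (i in seq_len(I)) {
      m <- params$m[i]
      L <- geq_matrix(m)
      C <- eng$counts[[i]][, cols, drop = FALSE]     # (m+1) x Q
      lP <- eng$LP[[g]][[i]]                          # Q x (m+1)
      P <- exp(lP)
      Ntot <- colSums(C)
      Cge <- crossprod(L, C)
      Pge <- P %*% L
      gtau[[g]][[i]] <- -params$delta[g, i] * rowSums(Cge - t(Pge * Ntot))
      A <- outer(eng$theta[g, ], 0:m) -
        matrix(c(0, cumsum(params$tau[[g]][[i]])), Q, m + 1L, byrow = TRUE)
      Abar <- rowSums(P * A)
      gdelta[g, i] <- sum(C * t(A)) - sum(Ntot * Abar)
      Ex <- rowSums(P * matrix(0:m, Q, m + 1L, byrow = TRUE))
      Cx <- colSums(C * (0:m))
      gsig[g] <- gsig[g] +
        sum((eng$theta[g, ] / 2) * params$delta[g, i] * (Cx - Ntot * Ex))
    }
  }
  grad <- unlist(gtau, use.names = FALSE)
  msk <- free_delta_mask(params$variant, G, I)
  if (nrow(msk) == 1L) {
    gshared <- colSums(gdelta) * params$delta[1L, ]
    grad <- c(grad, gshared[msk[1L, ]])
  } else {
    gfull <- gdelta * params$delta
    grad <- c(grad, gfull[msk])
  }
  grad <- c(grad, gsig)
  if (G > 1L) {
    Ng <- colSums(matrix(eng$Ngq, Q, G))
    grad <- c(grad, (Ng - sum(Ng) * params$pi)[seq_len(G - 1L)])
  }
  list(value = sum(eng$ll), grad = grad)
}

newton_refine <- function(params, data, grid, maxit) {
  if (maxit < 1L) return(list(params = params, ll = NA_real_, counts = c(0L, 0L)))
  vec0 <- pack_params(params)
  cache <- new.env(parent = emptyenv())
  eval_at <- function(p) {
    if (!identical(cache$p, p)) {
      cache$res <- ll_grad_packed(p, params, data, grid)
      cache$p <- p
    }
    cache$res
  }
  b <- packed_bounds(params)
  opt <- tryCatch(
    stats::optim(vec0, fn = function(p) eval_at(p)$value,
                 gr = function(p) eval_at(p)$grad, method = "L-BFGS-B",
                 lower = b$lower, upper = b$upper,
                 control = list(fnscale = -1, maxit = maxit, factr = 1e4)),
    error = function(e) NULL)
  if (is.null(opt)) return(list(params = params, ll = NA_real_, counts = c(0L, 0L)))
  list(params = unpack_params(opt$par, params), ll = opt$value,
       counts = opt$counts)
}

#' Fit a (mixture) partial credit model by marginal maximum likelihood
#'
#' Estimation proceeds in three stages: short EM runs from \code{n_starts}
#' random starting-value sets; full EM from the best start until the
#' relative log-likelihood change falls below \code{em_tolerance} (or the
#' iteration cap); and a quasi-Newton (BFGS) refinement of the marginal
#' log-likelihood on unconstrained transformed parameters (thresholds free,
#' log discriminations, log variances, mixing logits).  Classes are
#' relabeled by descending mixing proportion before the fit is returned.
#'
#' @param data a [response_matrix()].
#' @param variant model variant (see [model_spec()]).
#' @param n_classes number of latent classes.
#' @param options a [fit_options()] list.
#' @param quadrature_nodes Gauss-Hermite nodes for the latent trait.
#' @param spec optionally a ready-made [model_spec()] (overrides
#'   \code{variant}/\code{n_classes}).
#' @param start optional [parameter_set()] used as an additional starting
#'   value alongside the random starts (e.g. a nested model's solution).
#' @return object of class \code{mixpcm_fit}: the parameter estimates,
#'   log-likelihood, free-parameter count, posterior class probabilities,
#'   convergence trace, and boundary/extreme-parameter flags.  Standard
#'   errors are added by [standard_errors()].
#' @export
fit_mixgpcm <- function(data, variant = "rmGPCM", n_classes = 1,
                        options = fit_options(), quadrature_nodes = 21,
                        spec = NULL, start = NULL) {
  stopifnot(inherits(data, "mixpcm_responses"))
  if (options$strict && anyNA(data$values)) {
    stop("missing responses present under strict fitting")
  }
  if (is.null(spec)) {
    spec <- model_spec(variant, n_classes, data$m + 1L, ncol(data$values),
                       quadrature_nodes)
  }
  if (spec$I != ncol(data$values) || any(spec$m != data$m)) {
    stop("model specification does not match the data dimensions")
  }
  grid <- quadrature_grid(spec$quadrature_nodes)
  set.seed(options$seed)
  subseeds <- sample.int(.Machine$integer.max, options$n_starts)
  starts <- vector("list", options$n_starts)
  start_ll <- rep(-Inf, options$n_starts)
  for (s in seq_len(options$n_starts)) {
    set.seed(subseeds[s])
    p0 <- random_start(spec)
    res <- tryCatch(
      run_em(data, p0, grid, options$n_start_iterations,
             options$em_tolerance),
      error = function(e) NULL)
    if (!is.null(res)) { starts[[s]] <- res$params; start_ll[s] <- res$ll }
    if (options$verbose) message(sprintf("start %d: ll = %.3f", s, start_ll[s]))
  }
  if (!is.null(start)) {
    res <- tryCatch(
      run_em(data, start, grid, options$n_start_iterations,
             options$em_tolerance),
      error = function(e) NULL)
    if (!is.null(res)) {
      starts <- c(starts, list(res$params))
      start_ll <- c(start_ll, res$ll)
    }
  }
  if (all(!is.finite(start_ll))) {
    stop("all starting values failed; per-start log-likelihoods: ",
         paste(round(start_ll, 2), collapse = ", "))
  }
  best <- which.max(start_ll)
  em <- run_em(data, starts[[best]], grid, options$max_em_iterations,
               options$em_tolerance, verbose = options$verbose)
  nr <- newton_refine(em$params, data, grid,
                      options$max_newton_iterations)
  if (is.finite(nr$ll) && nr$ll >= em$ll - 1e-8) {
    params <- nr$params; ll <- max(nr$ll, em$ll)
  } else {
    params <- em$params; ll <- em$ll
  }
  ord <- order(params$pi, decreasing = TRUE)
  params <- relabel_by_size(params, ord)
  params$item_labels <- data$item_labels
  eng <- estep_engine(data, params, grid, want_counts = FALSE)
  post <- posterior_from_engine(eng)
  flags <- extreme_flags(params)
  fit <- structure(list(
    spec = spec, params = params, log_likelihood = ll,
    n_free_parameters = count_free_parameters(spec),
    n_persons = nrow(data$values),
    posterior = post,
    convergence = list(em_trace = em$trace, em_iterations = em$iterations,
                       newton_evals = nr$counts,
                       start_log_likelihoods = start_ll,
                       best_start = best, seed = options$seed),
    flags = flags, se = NULL, grid = grid), class = "mixpcm_fit")
  fit
}

posterior_from_engine <- function(eng) {
  Q <- eng$Q; G <- eng$G
  post <- vapply(seq_len(G), function(g) {
    rowSums(eng$r[, (g - 1L) * Q + seq_len(Q), drop = FALSE])
  }, numeric(eng$n))
  post <- matrix(post, eng$n, G)
  post / rowSums(post)
}

extreme_flags <- function(params) {
  list(boundary_pi = sum(params$pi < 1e-4),
       boundary_sigma2 = sum(params$sigma2 < 1e-4),
       extreme_delta = sum(params$delta > 50),
       extreme_tau = sum(abs(unlist(params$tau)) > 10))
}

#' @export
print.mixpcm_fit <- function(x, ...) {
  cat(sprintf("<mixpcm_fit> %s with G = %d classes, %d items\n",
              x$spec$variant, x$spec$G, x$spec$I))
  cat(sprintf("  log-likelihood %.2f on %d free parameters (n = %d)\n",
              x$log_likelihood, x$n_free_parameters, x$n_persons))
  cat("  class sizes:", paste(sprintf("%.3f", x$params$pi), collapse = ", "), "\n")
  cat(sprintf("  EM iterations: %d; flags: %s\n",
              x$convergence$em_iterations,
              paste(names(x$flags), unlist(x$flags), sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
logLik.mixpcm_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_free_parameters,
            nobs = object$n_persons, class = "logLik")
}

#' Posterior class-membership probabilities
#'
#' Bayes posterior \eqn{P(g | x_v)} proportional to \eqn{\pi_g} times the
#' class-conditional marginal likelihood; rows sum to one.
#'
#' @param fitted a [fit_mixgpcm()] result (or a [parameter_set()]).
#' @param data a [response_matrix()]; defaults to reusing the stored
#'   posterior when omitted and \code{fitted} is a fit.
#' @export
posterior_class_probabilities <- function(fitted, data = NULL) {
  if (inherits(fitted, "mixpcm_fit") && is.null(data)) return(fitted$posterior)
  params <- if (inherits(fitted, "mixpcm_fit")) fitted$params else fitted
  grid <- if (inherits(fitted, "mixpcm_fit")) fitted$grid else quadrature_grid(21)
  eng <- estep_engine(data, params, grid, want_counts = FALSE)
  posterior_from_engine(eng)
}

#' Modal class assignment
#'
#' Assigns each person to the class with the largest posterior probability
#' (ties broken toward the lowest class index, which is logged as an
#' attribute) and reports the mean winning probability per class, a common
#' summary of classification accuracy.
#'
#' @param posterior n x G matrix of posterior probabilities.
#' @return list with \code{labels} (integer vector), \code{mean_probability}
#'   (per class; NaN with a warning for empty classes) and \code{n_ties}.
#' @export
assign_modal_classes <- function(posterior) {
  posterior <- as.matrix(posterior)
  G <- ncol(posterior)
  labels <- apply(posterior, 1, which.max)  # which.max takes the first max
  ties <- apply(posterior, 1, function(row) sum(row == max(row)) > 1L)
  winners <- posterior[cbind(seq_len(nrow(posterior)), labels)]
  meanp <- vapply(seq_len(G), function(g) {
    sel <- labels == g
    if (!any(sel)) NaN else mean(winners[sel])
  }, numeric(1))
  if (anyNA(meanp) || any(is.nan(meanp))) {
    warning("empty class after modal assignment; mean probability is NaN")
  }
  list(labels = as.integer(labels), mean_probability = meanp,
       n_ties = sum(ties))
}
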