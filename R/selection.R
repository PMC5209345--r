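#' Information criteria for model comparison
#'
#' AIC = -2 LL + 2 p; BIC = -2 LL + p ln n; CAIC = -2 LL + p (ln n + 1)
#' (Bozdogan's consistent AIC).  Lower values indicate the preferable model.
#'
#' @param log_likelihood maximized marginal log-likelihood.
#' @param n_free_parameters free-parameter count p.
#' @param n_persons sample size n.
#' @return named list with AIC, BIC and CAIC.
#' @export
information_criteria <- function(log_likelihood, n_free_parameters, n_persons) {
  stopifnot(n_persons >= 1)
  ll <- log_likelihood; p <- n_free_parameters; n <- n_persons
  list(AIC = -2 * ll + 2 * p,
       BIC = -2 * ll + p * log(n),
       CAIC = -2 * ll + p * (log(n) + 1))
}

#' Pearson chi-square statistic over a cell set
#'
#' @param observed,expected non-negative vectors over the same cells, with
#'   equal totals (tolerance 1e-6 relative) and strictly positive expected
#'   counts.
#' @export
pearson_statistic <- function(observed, expected) {
  check_cells(observed, expected)
  sum((observed - expected)^2 / expected)
}

#' Cressie-Read power-divergence statistic
#'
#' \eqn{2 / (\lambda (\lambda + 1)) \sum O [(O/E)^\lambda - 1]} with the
#' conventional \eqn{\lambda = 2/3}.  At \eqn{\lambda = 1} it equals the
#' Pearson statistic.  The limit cases \eqn{\lambda \in \{0, -1\}} (G2 and
#' modified statistics) are not taken; request them explicitly elsewhere.
#'
#' @inheritParams pearson_statistic
#' @param lambda power-divergence index (default 2/3).
#' @export
cressie_read_statistic <- function(observed, expected, lambda = 2 / 3) {
  if (lambda %in% c(0, -1)) {
    stop("lambda 0 / -1 are limiting cases (likelihood-ratio and modified ",
         "statistics); this function requires lambda outside {0, -1}")
  }
  check_cells(observed, expected)
  ratio <- ifelse(observed > 0, (observed / expected)^lambda, 0)
  (2 / (lambda * (lambda + 1))) * sum(observed * (ratio - 1))
}

check_cells <- function(observed, expected) {
  if (length(observed) != length(expected)) stop("cell vectors differ in length")
  if (any(expected <= 0)) stop("zero or negative expected count on an included cell")
  if (abs(sum(observed) - sum(expected)) > 1e-6 * max(1, sum(expected))) {
    stop("observed and expected totals differ beyond tolerance")
  }
  invisible(TRUE)
}

# Observed-pattern cell set: one cell per distinct complete response
# pattern present in the data, plus a pooled remainder cell absorbing the
# probability of all unseen patterns.  The full outcome space is far too
# sparse to use directly for long rating scales (11^5 cells here).
gof_cells <- function(params, data, grid) {
  vals <- data$values
  complete <- stats::complete.cases(vals)
  if (!all(complete)) {
    warning(sum(!complete), " rows with missing responses excluded from the ",
            "goodness-of-fit cell set")
  }
  vals <- vals[complete, , drop = FALSE]
  n <- nrow(vals)
  key <- apply(vals, 1, paste, collapse = ",")
  tab <- table(key)
  upat <- do.call(rbind, lapply(strsplit(names(tab), ","), as.integer))
  udata <- response_matrix(upat, n_categories = data$m + 1L,
                           item_labels = data$item_labels)
  eng <- estep_engine(udata, params, grid, want_counts = FALSE)
  p <- exp(eng$ll)
  observed <- c(as.numeric(tab), 0)
  expected <- c(n * p, n * max(1 - sum(p), 1e-12))
  # renormalize the tiny numerical defect so totals agree exactly
  expected <- expected * (n / sum(expected))
  list(observed = observed, expected = expected, n = n)
}

#' Parametric-bootstrap goodness-of-fit test
#'
#' Computes the observed Pearson or Cressie-Read statistic over the
#' observed-pattern cells (plus a pooled remainder cell), then simulates
#' \code{B} datasets from the fitted parameters, refits the same model on
#' each (with a reduced number of starts for tractability) and compares.
#' The p-value uses the add-one convention \eqn{(1 + \#\{T_b \ge
#' T_{obs}\})/(B + 1)}, so it is bounded below by \eqn{1/(B+1)}.
#'
#' @param fitted a [fit_mixgpcm()] result.
#' @param data the data the model was fitted to.
#' @param statistic \code{"pearson"} or \code{"cressie_read"}.
#' @param B number of bootstrap samples (default 500).
#' @param seed RNG seed; the result is reproducible and invariant to
#'   replicate order.
#' @param refit_options [fit_options()] for the bootstrap refits; the
#'   default uses 10 starts and a looser EM tolerance.
#' @param lambda Cressie-Read index.
#' @return list with the observed statistic, the bootstrap statistics,
#'   the p-value, the number of dropped (non-convergent) replicates and the
#'   seed.
#' @export
parametric_bootstrap_gof <- function(fitted, data,
                                     statistic = c("pearson", "cressie_read"),
                                     B = 500, seed = 1,
                                     refit_options = NULL, lambda = 2 / 3) {
  statistic <- match.arg(statistic)
  stat_fun <- if (statistic == "pearson") {
    function(o, e) pearson_statistic(o, e)
  } else {
    function(o, e) cressie_read_statistic(o, e, lambda)
  }
  cells <- gof_cells(fitted$params, data, fitted$grid)
  observed_stat <- stat_fun(cells$observed, cells$expected)
  if (is.null(refit_options)) {
    refit_options <- fit_options(n_starts = 10, n_start_iterations = 10,
                                 max_em_iterations = 500,
                                 max_newton_iterations = 50,
                                 em_tolerance = 1e-6, seed = seed)
  }
  set.seed(seed)
  repseeds <- sample.int(.Machine$integer.max, B)
  boot <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    sim <- generate_responses(fitted$params, cells$n, seed = repseeds[b])
    ro <- refit_options; ro$seed <- repseeds[b]
    refit <- tryCatch(
      suppressWarnings(fit_mixgpcm(sim$data, spec = fitted$spec, options = ro)),
      error = function(e) NULL)
    if (is.null(refit)) next
    bc <- gof_cells(refit$params, sim$data, refit$grid)
    boot[b] <- stat_fun(bc$observed, bc$expected)
  }
  dropped <- sum(is.na(boot))
  if (dropped > 0.1 * B) {
    warning(sprintf("%d of %d bootstrap replicates failed to converge", dropped, B))
  }
  ok <- boot[!is.na(boot)]
  p <- (1 + sum(ok >= observed_stat)) / (length(ok) + 1)
  structure(list(statistic = statistic, observed = observed_stat,
                 bootstrap = boot, p_value = p, B = B, dropped = dropped,
                 seed = seed), class = "mixpcm_gof")
}

#' @export
print.mixpcm_gof <- function(x, ...) {
  cat(sprintf("Parametric bootstrap %s test: T = %.2f, p = %.4f (B = %d, %d dropped)\n",
              x$statistic, x$observed, x$p_value, x$B, x$dropped))
  invisible(x)
}

# Promote a restricted solution into a more general variant's parameter
# space (used to seed the general fit so the LR difference cannot go
# negative).  Returns NULL when no embedding exists.
embed_in_variant <- function(params, variant) {
  hierarchy <- c(PCM = 1, mPCM = 1, GPCM = 2, rmGPCM = 2, mGPCM = 3)
  if (hierarchy[[variant]] < hierarchy[[params$variant]]) return(NULL)
  tryCatch(parameter_set(params$tau, params$delta, params$pi, params$sigma2,
                         variant = variant, item_labels = params$item_labels),
           error = function(e) NULL)
}

#' Degrees of freedom of a nested model comparison
#'
#' Difference in free-parameter counts between a restricted model and a
#' more general one, after verifying the nesting (equal class counts and
#' dimensions; variant hierarchy PCM/mPCM within GPCM/rmGPCM within
#' mGPCM).
#'
#' @param restricted,general [model_spec()] objects (or fitted models).
#' @return integer df.
#' @export
nesting_df <- function(restricted, general) {
  as_spec <- function(x) if (inherits(x, "mixpcm_fit")) x$spec else x
  r <- as_spec(restricted); g <- as_spec(general)
  stopifnot(inherits(r, "mixpcm_spec"), inherits(g, "mixpcm_spec"))
  if (r$G != g$G || r$I != g$I || any(r$m != g$m)) {
    stop("nesting requires equal class counts and item dimensions")
  }
  hierarchy <- c(PCM = 1, mPCM = 1, GPCM = 2, rmGPCM = 2, mGPCM = 3)
  if (hierarchy[[r$variant]] >= hierarchy[[g$variant]]) {
    stop(r$variant, " is not nested in ", g$variant)
  }
  count_free_parameters(g) - count_free_parameters(r)
}

#' Bootstrapped likelihood-ratio difference test for nested models
#'
#' \eqn{\Delta = 2 (LL_{general} - LL_{restricted})} with df the difference
#' in free-parameter counts.  The null distribution is obtained by
#' simulating from the restricted fit and fitting both models on each
#' replicate; the general refit is additionally seeded from the restricted
#' replicate solution so each replicate's difference is non-negative.
#'
#' @param restricted_fit,general_fit fits of the nested and the more
#'   general model on the same data.
#' @param data the common dataset.
#' @param B bootstrap replicates.
#' @param seed RNG seed.
#' @param refit_options [fit_options()] for replicate fits (reduced starts
#'   by default).
#' @return list with \code{delta}, \code{df}, \code{p}, and the replicate
#'   differences.
#' @export
bootstrap_lr_test <- function(restricted_fit, general_fit, data, B = 500,
                              seed = 1, refit_options = NULL) {
  df <- general_fit$n_free_parameters - restricted_fit$n_free_parameters
  if (df <= 0) stop("general model must have more free parameters")
  delta <- 2 * (general_fit$log_likelihood - restricted_fit$log_likelihood)
  if (delta < -1e-6) {
    stop("general fit has lower likelihood than the restricted fit; ",
         "re-fit the general model seeded from the restricted solution")
  }
  delta <- max(delta, 0)
  if (is.null(refit_options)) {
    refit_options <- fit_options(n_starts = 5, n_start_iterations = 10,
                                 max_em_iterations = 500,
                                 max_newton_iterations = 50,
                                 em_tolerance = 1e-6, seed = seed)
  }
  n <- restricted_fit$n_persons
  set.seed(seed)
  repseeds <- sample.int(.Machine$integer.max, B)
  deltas <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    sim <- generate_responses(restricted_fit$params, n, seed = repseeds[b])
    ro <- refit_options; ro$seed <- repseeds[b]
    rfit <- tryCatch(
      suppressWarnings(fit_mixgpcm(sim$data, spec = restricted_fit$spec,
                                   options = ro)),
      error = function(e) NULL)
    if (is.null(rfit)) next
    seedp <- embed_in_variant(rfit$params, general_fit$spec$variant)
    gfit <- tryCatch(
      suppressWarnings(fit_mixgpcm(sim$data, spec = general_fit$spec,
                                   options = ro, start = seedp)),
      error = function(e) NULL)
    if (is.null(gfit)) next
    deltas[b] <- max(2 * (gfit$log_likelihood - rfit$log_likelihood), 0)
  }
  ok <- deltas[!is.na(deltas)]
  if (length(ok) < 0.9 * B) {
    warning(sprintf("%d of %d LR bootstrap replicates dropped", B - length(ok), B))
  }
  p <- (1 + sum(ok >= delta)) / (length(ok) + 1)
  list(delta = delta, df = df, p = p, bootstrap = deltas, seed = seed)
}

# Promote a (G-1)-class solution to a G-class starting value by splitting
# the largest class: duplicate its thresholds with jitter and halve its
# weight.  Incremental starts of this kind find the G-class basin far more
# reliably than random starts alone.
split_largest_class <- function(params, variant, jitter_seed) {
  set.seed(jitter_seed)
  tau <- params$tau
  newcl <- lapply(tau[[1]], function(v) v + stats::rnorm(length(v), 0, 0.3))
  tau <- c(tau, list(newcl))
  delta <- rbind(params$delta, params$delta[1, ])
  pi <- c(params$pi, params$pi[1] / 2)
  pi[1] <- pi[1] / 2
  sigma2 <- c(params$sigma2, params$sigma2[1])
  tryCatch(parameter_set(tau, delta, pi / sum(pi), sigma2, variant = variant,
                         item_labels = params$item_labels),
           error = function(e) NULL)
}

#' Class enumeration by information criteria
#'
#' Fits the chosen variant for each number of classes in \code{G_range},
#' tabulates log-likelihood, free parameters and AIC/BIC/CAIC, and selects
#' the class count with the lowest CAIC (ties resolved toward the smaller,
#' more parsimonious G).  When consecutive class counts are fitted, each
#' G-class fit receives — in addition to its random starts — an incremental
#' starting value built from the (G-1)-class solution by splitting its
#' largest class, which guards against the G-class fit landing in a poorer
#' basin than the model it is compared with.
#'
#' @param data a [response_matrix()].
#' @param variant model variant (mixture variants for G > 1; the G = 1 row
#'   uses the corresponding single-class model automatically).
#' @param G_range integer vector of class counts to fit.
#' @param options [fit_options()] shared by all fits.
#' @param quadrature_nodes latent-trait nodes.
#' @return list with \code{table} (one row per fitted G), \code{fits},
#'   \code{selected_G} and \code{selected} (the chosen fit).
#' @export
enumerate_classes <- function(data, variant = "rmGPCM", G_range = 1:5,
                              options = fit_options(),
                              quadrature_nodes = 21) {
  stopifnot(length(G_range) >= 1)
  G_range <- sort(unique(as.integer(G_range)))
  fits <- list(); rows <- list()
  prev <- NULL
  for (G in G_range) {
    v <- variant
    if (G == 1L) {
      v <- switch(variant, mPCM = "PCM", rmGPCM = "GPCM", mGPCM = "GPCM",
                  variant)
    }
    start <- NULL
    if (!is.null(prev) && prev$spec$G == G - 1L && G > 1L) {
      prev_params <- prev$params
      if (prev_params$variant != v) {
        prev_params <- embed_in_variant(prev_params, v)
      }
      if (!is.null(prev_params)) {
        start <- split_largest_class(prev_params, v, options$seed + G)
      }
    }
    f <- tryCatch(
      fit_mixgpcm(data, variant = v, n_classes = G, options = options,
                  quadrature_nodes = quadrature_nodes, start = start),
      error = function(e) { warning("fit failed for G = ", G, ": ",
                                    conditionMessage(e)); NULL })
    fits[[as.character(G)]] <- f
    if (is.null(f)) next
    prev <- f
    ic <- information_criteria(f$log_likelihood, f$n_free_parameters,
                               f$n_persons)
    rows[[as.character(G)]] <- data.frame(
      model = v, G = G, n_par = f$n_free_parameters,
      LL = f$log_likelihood, AIC = ic$AIC, BIC = ic$BIC, CAIC = ic$CAIC)
  }
  if (!length(rows)) stop("no model could be fitted over G_range")
  tab <- do.call(rbind, rows)
  best <- tab$G[which.min(tab$CAIC)]  # which.min takes the first (smallest G)
  list(table = tab, fits = fits, selected_G = best,
       selected = fits[[as.character(best)]])
}
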