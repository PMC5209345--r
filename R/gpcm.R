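# Core probability machinery of the (generalized) partial credit family.
# Category probabilities follow the adjacent-category logit form
#   P(x | theta) = exp(sum_{s<=x} delta (theta - tau_s)) / normalizer,
# with the s = 0 term identically zero, so category 0 is the reference.

.mixpcm_state <- new.env(parent = emptyenv())
.mixpcm_state$floor_count <- 0L

#' Number of probability-floor events since the last reset
#'
#' Pattern probabilities are floored at 1e-300 before logging; each floored
#' evaluation increments this counter.
#' @param reset if TRUE, zero the counter after reading.
#' @export
floor_events <- function(reset = FALSE) {
  n <- .mixpcm_state$floor_count
  if (reset) .mixpcm_state$floor_count <- 0L
  n
}

# log P(x | theta) for a vector of theta values; rows = theta, cols = 0..m.
gpcm_logprob <- function(theta, tau, delta) {
  m <- length(tau)
  cum <- c(0, cumsum(tau))
  S <- delta * (outer(theta, 0:m) - matrix(cum, length(theta), m + 1L, byrow = TRUE))
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  S - (mx + log(rowSums(exp(S - mx))))
}

# upper-triangular indicator used for P(X >= s) sums: (m+1) x m with
# entry [x + 1, s] = 1{x >= s}
geq_matrix <- function(m) {
  outer(seq_len(m + 1L), seq_len(m), ">") * 1
}

#' Category response probabilities of the generalized partial credit model
#'
#' @param theta latent-trait value(s).
#' @param thresholds numeric vector of m thresholds (need not be ordered).
#' @param discrimination positive slope parameter.
#' @return for scalar \code{theta} a probability vector of length m + 1
#'   (categories 0..m); for a vector, a matrix with one row per theta value.
#'   Probabilities are non-negative and sum to one.
#' @examples
#' category_probabilities(0, rep(0, 10), 1)  # uniform over 11 categories
#' @export
category_probabilities <- function(theta, thresholds, discrimination) {
  if (!is.numeric(discrimination) || length(discrimination) != 1L ||
      !is.finite(discrimination) || discrimination <= 0) {
    stop("discrimination must be a single positive number")
  }
  m <- length(thresholds)
  if (m < 1L) stop("degenerate item: need at least one threshold (2 categories)")
  P <- exp(gpcm_logprob(as.numeric(theta), as.numeric(thresholds),
                        discrimination))
  if (length(theta) == 1L) drop(P) else P
}

#' Probability of one response pattern given class and latent trait
#'
#' Product over non-missing items of the category probabilities; missing
#' items contribute a factor of one (the all-missing pattern has
#' probability one by the empty-product convention).
#'
#' @param pattern integer vector of categories (NA = missing), one per item.
#' @param class_index latent class g.
#' @param params a [parameter_set()].
#' @param theta latent-trait value.
#' @export
class_conditional_pattern_probability <- function(pattern, class_index, params,
                                                  theta) {
  stopifnot(inherits(params, "mixpcm_params"))
  g <- as.integer(class_index)
  if (g < 1L || g > params$G) stop("class_index out of range")
  if (length(pattern) != params$I) stop("pattern length must equal item count")
  p <- 1
  for (i in seq_len(params$I)) {
    x <- pattern[i]
    if (is.na(x)) next
    if (x < 0 || x > params$m[i]) {
      stop(sprintf("category %d out of range 0..%d for item %d", x, params$m[i], i))
    }
    pi_x <- category_probabilities(theta, params$tau[[g]][[i]],
                                   params$delta[g, i])[x + 1L]
    p <- p * pi_x
  }
  p
}

#' Marginal probability of a response pattern under the mixture
#'
#' Integrates the class-conditional pattern probability over the latent
#' trait \eqn{N(0, \sigma_g^2)} (quadrature grid rescaled by \eqn{\sigma_g})
#' and mixes over classes with weights \eqn{\pi_g}.
#'
#' @inheritParams class_conditional_pattern_probability
#' @param grid a [quadrature_grid()].
#' @export
marginal_pattern_probability <- function(pattern, params, grid) {
  stopifnot(inherits(params, "mixpcm_params"))
  if (is.null(grid$nodes) || length(grid$nodes) == 0L) {
    stop("empty quadrature grid")
  }
  total <- 0
  for (g in seq_len(params$G)) {
    theta_g <- sqrt(params$sigma2[g]) * grid$nodes
    lp <- numeric(length(theta_g))
    for (i in seq_len(params$I)) {
      x <- pattern[i]
      if (is.na(x)) next
      lp <- lp + gpcm_logprob(theta_g, params$tau[[g]][[i]],
                              params$delta[g, i])[, x + 1L]
    }
    total <- total + params$pi[g] * sum(grid$weights * exp(lp))
  }
  total
}

#' Marginal log-likelihood of a response matrix
#'
#' Sum over persons of the log marginal pattern probability.  Patterns with
#' probability numerically zero are floored at 1e-300 (with a warning and an
#' increment of [floor_events()]), so the result can be -Inf only before
#' flooring.
#'
#' @param data a [response_matrix()].
#' @param params a [parameter_set()].
#' @param grid a [quadrature_grid()]; defaults to 21 nodes.
#' @export
log_likelihood <- function(data, params, grid = quadrature_grid(21)) {
  if (is.null(data) || nrow(data$values) == 0L) return(0)
  eng <- estep_engine(data, params, grid, want_counts = FALSE)
  sum(eng$ll)
}
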