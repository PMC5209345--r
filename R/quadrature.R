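#' Gauss-Hermite quadrature grid on the standard-normal scale
#'
#' Nodes and weights for approximating \eqn{\int f(\theta) \phi(\theta)
#' d\theta} by \eqn{\sum_q w_q f(z_q)} with \eqn{\phi} the standard normal
#' density.  Class-specific latent distributions \eqn{N(0, \sigma_g^2)} are
#' handled by rescaling the nodes by \eqn{\sigma_g}; the weights are
#' unchanged.
#'
#' @param n number of nodes (>= 5; default 21).
#' @return list with \code{nodes} (strictly increasing) and \code{weights}
#'   (non-negative, summing to one).
#' @export
quadrature_grid <- function(n = 21) {
  n <- as.integer(n)
  if (is.na(n) || n < 5L) stop("quadrature grid needs at least 5 nodes")
  gh <- pracma::gaussHermite(n)
  nodes <- gh$x * sqrt(2)
  weights <- gh$w / sqrt(pi)
  weights <- weights / sum(weights)
  structure(list(nodes = as.numeric(nodes), weights = as.numeric(weights)),
            class = "mixpcm_grid")
}
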