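# Internal vectorized engine shared by the likelihood, the EM steps, the
# analytic score and the information matrix.  For n persons, G classes and a
# Q-node grid it forms the n x (G*Q) matrix of log joint terms
#   log pi_g + log w_q + sum_i log P_i(x_vi | sigma_g z_q),
# from which the log-likelihood (row log-sum-exp), the responsibilities
# (row softmax) and the expected item-category counts follow.

# Log-probability tables: LP[[g]][[i]] is Q x (m_i + 1).
logprob_tables <- function(params, theta) {
  lapply(seq_len(params$G), function(g) {
    lapply(seq_len(params$I), function(i) {
      gpcm_logprob(theta[g, ], params$tau[[g]][[i]], params$delta[g, i])
    })
  })
}

class_thetas <- function(params, grid) {
  outer(sqrt(params$sigma2), grid$nodes)
}

estep_engine <- function(data, params, grid, want_counts = TRUE) {
  vals <- data$values
  n <- nrow(vals); G <- params$G; Q <- length(grid$nodes)
  theta <- class_thetas(params, grid)
  LP <- logprob_tables(params, theta)
  iv <- vals
  iv[is.na(iv)] <- -1L
  res <- .cpp_estep(iv, unlist(LP, recursive = FALSE), log(params$pi),
                    log(grid$weights), isTRUE(want_counts))
  ll <- res$ll
  floored <- ll < log(1e-300)
  if (any(floored)) {
    .mixpcm_state$floor_count <- .mixpcm_state$floor_count + sum(floored)
    warning(sum(floored), " pattern probabilities floored at 1e-300")
    ll[floored] <- log(1e-300)
  }
  r <- t(res$rt)
  out <- list(ll = ll, r = r, theta = theta, LP = LP, n = n, G = G, Q = Q)
  if (want_counts) {
    out$counts <- res$counts
    out$Ngq <- colSums(r)
  }
  out
}

# Reshape one item's count matrix into a [category, node, class] array.
item_count_array <- function(cnt, G, Q) {
  array(cnt, dim = c(nrow(cnt), Q, G))
}
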