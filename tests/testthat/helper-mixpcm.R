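# Shared fixtures and independent oracles.  Oracles deliberately avoid the
# package's vectorized engine: plain-R probability formulas and dense-grid
# integration, so engine bugs cannot cancel.

# direct evaluation of the adjacent-category logit model, scalar theta
slow_gpcm_prob <- function(theta, tau, delta) {
  m <- length(tau)
  S <- vapply(0:m, function(x) {
    if (x == 0) 0 else sum(delta * (theta - tau[seq_len(x)]))
  }, numeric(1))
  e <- exp(S - max(S))
  e / sum(e)
}

# dense-grid marginal pattern probability (Riemann sum over N(0, sigma2_g))
slow_marginal <- function(pattern, params, step = 0.002, span = 8) {
  theta <- seq(-span, span, by = step)
  total <- 0
  for (g in seq_len(params$G)) {
    dens <- stats::dnorm(theta, 0, sqrt(params$sigma2[g]))
    lik <- rep(1, length(theta))
    for (i in seq_len(params$I)) {
      x <- pattern[i]
      if (is.na(x)) next
      lik <- lik * vapply(theta, function(t) {
        slow_gpcm_prob(t, params$tau[[g]][[i]], params$delta[g, i])[x + 1L]
      }, numeric(1))
    }
    total <- total + params$pi[g] * sum(dens * lik) * step
  }
  total
}

tiny_params <- function() {
  parameter_set(list(list(c(-0.5, 0.5), c(-1, 0.3))),
                discriminations = 1.2, mixing = 1, variances = 1)
}

fig1_tau <- seq(-2.25, 2.25, by = 0.5)
fig2_tau <- c(-2.25, -1.75, -1.25, -0.75, -0.25, 0.25, 1.25, 0.75, 1.75, 2.25)

# permutation of estimated classes minimizing total squared threshold error
best_alignment <- function(truth, est) {
  G <- truth$G
  perms <- combinat_perms(G)
  score <- vapply(perms, function(p) {
    sum(unlist(Map(function(a, b) unlist(Map(`-`, a, b))^2,
                   truth$tau, est$tau[p])))
  }, numeric(1))
  as.integer(perms[[which.min(score)]])
}

combinat_perms <- function(G) {
  if (G == 1) return(list(1L))
  out <- list()
  rec <- function(prefix, rest) {
    if (!length(rest)) { out[[length(out) + 1L]] <<- prefix; return() }
    for (k in seq_along(rest)) rec(c(prefix, rest[k]), rest[-k])
  }
  rec(integer(0), seq_len(G))
  out
}

aligned_tau_errors <- function(truth, est) {
  p <- best_alignment(truth, est)
  unlist(Map(function(a, b) unlist(Map(`-`, a, b)), truth$tau, est$tau[p]))
}

quiet_fit <- function(...) suppressWarnings(fit_mixgpcm(...))

fast_opts <- function(seed, n_starts = 3, ...) {
  fit_options(n_starts = n_starts, n_start_iterations = 8,
              max_em_iterations = 400, max_newton_iterations = 60,
              em_tolerance = 1e-7, seed = seed, ...)
}
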