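# Diagnostics translating fitted class-specific item parameters into
# scale-usage findings: threshold ordering, avoided categories, latent
# category widths, category characteristic curves and expected category
# frequencies.

#' Threshold ordering report
#'
#' For every class and item, lists the adjacent threshold pairs (s, s + 1)
#' with \eqn{\tau_s > \tau_{s+1}} (strict inversions; ties count as ordered
#' under the documented non-strict convention) and the number of correctly
#' ordered adjacent pairs.  Ordered thresholds mean every category occupies
#' a segment of the latent continuum; inversions typically signal avoided
#' categories.
#'
#' @param params a [parameter_set()] (or a fit, whose parameters are used).
#' @return data frame with one row per class/item: \code{class},
#'   \code{item}, \code{n_pairs}, \code{n_ordered}, \code{inversions}
#'   (list-column of inverted pair start indices).
#' @export
threshold_order_report <- function(params) {
  params <- as_params(params)
  rows <- list()
  for (g in seq_len(params$G)) for (i in seq_len(params$I)) {
    tau <- params$tau[[g]][[i]]
    d <- diff(tau)
    inv <- which(d < 0)
    rows[[length(rows) + 1L]] <- data.frame(
      class = g, item = params$item_labels[i],
      n_pairs = length(d), n_ordered = sum(d >= 0),
      inversions = I(list(as.integer(inv))))
  }
  do.call(rbind, rows)
}

#' Modal and avoided categories of one item
#'
#' Evaluates the category characteristic curves on a grid over
#' \code{theta_range} and records which categories attain the (strict)
#' maximum somewhere.  A category never attaining the maximum is "avoided":
#' its curve is completely covered by neighbouring categories.  Near-ties
#' within \code{tie_tolerance} are treated as attained (and logged via the
#' \code{n_near_ties} field).  With a sufficiently wide range the extreme
#' categories always register as modal at the endpoints.
#'
#' @param thresholds item threshold vector.
#' @param discrimination item slope.
#' @param theta_range evaluation range (default \code{c(-6, 6)}, covering
#'   more than 99.99\% of the latent mass for sigma <= 2).
#' @param grid_step evaluation step (default 0.01).
#' @param tie_tolerance probability difference treated as a tie (1e-9).
#' @return list with \code{modal} (sorted category set), \code{avoided}
#'   (complement in 0..m) and \code{n_near_ties}.
#' @export
modal_category_set <- function(thresholds, discrimination,
                               theta_range = c(-6, 6), grid_step = 0.01,
                               tie_tolerance = 1e-9) {
  if (!all(is.finite(theta_range)) || diff(theta_range) <= 0 || grid_step <= 0) {
    stop("degenerate theta range or step")
  }
  theta <- seq(theta_range[1], theta_range[2], by = grid_step)
  P <- category_probabilities(theta, thresholds, discrimination)
  mx <- P[cbind(seq_len(nrow(P)), max.col(P, ties.method = "first"))]
  hit <- P >= mx - tie_tolerance
  near <- rowSums(hit) > 1L
  modal <- which(colSums(hit) > 0L) - 1L
  m <- length(thresholds)
  list(modal = modal, avoided = setdiff(0:m, modal),
       n_near_ties = sum(near))
}

#' Category characteristic curve data for plotting
#'
#' @param thresholds item threshold vector.
#' @param discrimination item slope.
#' @param theta evaluation grid (vector).
#' @return data frame: \code{theta} followed by one probability column per
#'   category (\code{cat0..catm}); each row sums to one.
#' @export
ccc_curve_data <- function(thresholds, discrimination,
                           theta = seq(-6, 6, by = 0.05)) {
  P <- category_probabilities(theta, thresholds, discrimination)
  out <- data.frame(theta = theta, P)
  names(out) <- c("theta", paste0("cat", 0:length(thresholds)))
  out
}

#' Latent category widths
#'
#' Signed distances between adjacent thresholds, \eqn{\tau_{s+1} - \tau_s},
#' per class and item: the width of the latent segment represented by each
#' interior category.  The class-level summary reports the minimum and
#' maximum over all ordered (positive-width) adjacent pairs across items.
#'
#' @param params a [parameter_set()] or fit.
#' @return list with \code{widths} (data frame class/item/pair/width) and
#'   \code{class_summary} (min/max ordered width per class).
#' @export
latent_category_widths <- function(params) {
  params <- as_params(params)
  rows <- list()
  for (g in seq_len(params$G)) for (i in seq_len(params$I)) {
    tau <- params$tau[[g]][[i]]
    d <- diff(tau)
    if (!length(d)) next
    rows[[length(rows) + 1L]] <- data.frame(
      class = g, item = params$item_labels[i], pair = seq_along(d),
      width = d)
  }
  widths <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = integer(0), item = character(0), pair = integer(0),
               width = numeric(0))
  summ <- NULL
  if (nrow(widths)) {
    summ <- do.call(rbind, lapply(split(widths, widths$class), function(w) {
      pos <- w$width[w$width > 0]
      data.frame(class = w$class[1],
                 min_ordered_width = if (length(pos)) min(pos) else NA_real_,
                 max_ordered_width = if (length(pos)) max(pos) else NA_real_)
    }))
    rownames(summ) <- NULL
  }
  list(widths = widths, class_summary = summ)
}

#' Expected category frequencies per class
#'
#' For each class, the model-implied distribution over categories: the
#' average over the class's latent distribution (by quadrature) of the
#' category probabilities, averaged over items.  The overall vector is the
#' mixture of the class vectors with weights \eqn{\pi_g}.  These
#' frequencies reflect both the class-specific item parameters and the
#' latent distribution, and are the data behind expected-frequency plots.
#'
#' @param fitted a fit or [parameter_set()].
#' @param grid [quadrature_grid()]; defaults to the fit's grid or 21 nodes.
#' @return list with \code{by_class} (G x (m+1) matrix, rows sum to 1) and
#'   \code{overall} (length m+1).  Requires all items to share m.
#' @export
expected_category_frequencies <- function(fitted, grid = NULL) {
  params <- as_params(fitted)
  if (is.null(grid)) {
    grid <- if (inherits(fitted, "mixpcm_fit")) fitted$grid else quadrature_grid(21)
  }
  if (length(unique(params$m)) != 1L) {
    stop("expected category frequencies need a common category count across items")
  }
  m <- params$m[1]
  by_class <- matrix(0, params$G, m + 1L)
  for (g in seq_len(params$G)) {
    theta <- sqrt(params$sigma2[g]) * grid$nodes
    acc <- matrix(0, length(theta), m + 1L)
    for (i in seq_len(params$I)) {
      acc <- acc + exp(gpcm_logprob(theta, params$tau[[g]][[i]],
                                    params$delta[g, i]))
    }
    acc <- acc / params$I
    by_class[g, ] <- colSums(grid$weights * acc)
  }
  colnames(by_class) <- paste0("cat", 0:m)
  list(by_class = by_class,
       overall = as.numeric(params$pi %*% by_class))
}

#' Marginal (EAP) reliability under the mixture
#'
#' Person-level expected a posteriori trait scores are computed within the
#' mixture (class-weighted over classes and nodes); reliability is
#' var(EAP) / (var(EAP) + mean posterior variance), bounded in [0, 1].
#' Controlling class-specific scale usage this way typically yields a lower
#' -- less inflated -- coefficient than raw-score internal consistency.
#'
#' @param fitted a [fit_mixgpcm()] result.
#' @param data the fitted [response_matrix()].
#' @return reliability in [0, 1]; NaN with a warning when the EAP variance
#'   is numerically zero.
#' @export
marginal_reliability <- function(fitted, data) {
  params <- as_params(fitted)
  grid <- if (inherits(fitted, "mixpcm_fit")) fitted$grid else quadrature_grid(21)
  eng <- estep_engine(data, params, grid, want_counts = FALSE)
  thetas <- as.numeric(t(eng$theta))          # order (g, q) matching columns
  eap <- as.numeric(eng$r %*% thetas)
  second <- as.numeric(eng$r %*% (thetas^2))
  postvar <- pmax(second - eap^2, 0)
  v <- stats::var(eap)
  tot <- v + mean(postvar)
  if (!is.finite(tot) || tot <= 1e-12) {
    warning("zero total variance; reliability undefined")
    return(NaN)
  }
  v / tot
}

#' Cronbach's alpha
#'
#' Raw-score internal consistency \eqn{(I/(I-1)) (1 - \sum_i s_i^2 /
#' s_{total}^2)} computed on complete rows (incomplete rows are dropped
#' with a message).
#'
#' @param data a [response_matrix()] or numeric matrix.
#' @export
cronbach_alpha <- function(data) {
  vals <- if (inherits(data, "mixpcm_responses")) data$values else as.matrix(data)
  if (ncol(vals) < 2L) stop("alpha needs at least two items")
  cc <- stats::complete.cases(vals)
  if (!all(cc)) message(sum(!cc), " incomplete rows dropped for alpha")
  vals <- vals[cc, , drop = FALSE]
  total <- rowSums(vals)
  vt <- stats::var(total)
  if (!is.finite(vt) || vt <= 1e-12) {
    warning("zero total-score variance; alpha undefined")
    return(NaN)
  }
  (ncol(vals) / (ncol(vals) - 1)) * (1 - sum(apply(vals, 2, stats::var)) / vt)
}

#' Full scale-usage report for a fitted mixture
#'
#' Combines the threshold-order report, avoided-category detection, latent
#' category widths and expected category frequencies into one object.
#'
#' @param fitted a [fit_mixgpcm()] result or [parameter_set()].
#' @param theta_range,grid_step modal-set detection grid (see
#'   [modal_category_set()]).
#' @return object of class \code{mixpcm_usage}: a list with
#'   \code{thresholds} (order report), \code{avoided} (data frame
#'   class/item/avoided categories), \code{widths},
#'   \code{expected_frequencies}.
#' @export
scale_usage_report <- function(fitted, theta_range = c(-6, 6),
                               grid_step = 0.01) {
  params <- as_params(fitted)
  ord <- threshold_order_report(params)
  av <- list()
  for (g in seq_len(params$G)) for (i in seq_len(params$I)) {
    ms <- modal_category_set(params$tau[[g]][[i]], params$delta[g, i],
                             theta_range, grid_step)
    av[[length(av) + 1L]] <- data.frame(
      class = g, item = params$item_labels[i],
      n_avoided = length(ms$avoided),
      avoided = I(list(ms$avoided)))
  }
  structure(list(thresholds = ord, avoided = do.call(rbind, av),
                 widths = latent_category_widths(params),
                 expected_frequencies = tryCatch(
                   expected_category_frequencies(fitted),
                   error = function(e) NULL)),
            class = "mixpcm_usage")
}

#' @export
print.mixpcm_usage <- function(x, ...) {
  cat("<mixpcm_usage> scale-usage report\n")
  cat("  inversions per class/item:\n")
  print(x$thresholds[, c("class", "item", "n_pairs", "n_ordered")])
  cat("  avoided categories:\n")
  av <- x$avoided
  for (k in seq_len(nrow(av))) {
    cats <- av$avoided[[k]]
    if (length(cats)) {
      cat(sprintf("   class %d, %s: %s\n", av$class[k], av$item[k],
                  paste(cats, collapse = ", ")))
    }
  }
  invisible(x)
}

as_params <- function(x) {
  if (inherits(x, "mixpcm_fit")) x$params
  else if (inherits(x, "mixpcm_params")) x
  else stop("expected a parameter set or fitted model")
}
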