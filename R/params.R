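MODEL_VARIANTS <- c("PCM", "mPCM", "GPCM", "rmGPCM", "mGPCM")

#' Model specification
#'
#' Describes which member of the partial-credit family is fitted and its
#' dimensions.  \code{PCM} and \code{GPCM} are the single-class models;
#' \code{mPCM}, \code{rmGPCM} and \code{mGPCM} are their latent-class
#' mixtures.  The "restricted" \code{rmGPCM} shares item discriminations
#' across classes; the full \code{mGPCM} frees them per class.
#'
#' @param variant one of \code{"PCM"}, \code{"mPCM"}, \code{"GPCM"},
#'   \code{"rmGPCM"}, \code{"mGPCM"}.
#' @param n_classes number of latent classes G (1 for PCM/GPCM).
#' @param n_categories integer vector (length I, or scalar recycled) of
#'   categories per item, i.e. \code{m_i + 1}.
#' @param n_items number of items I (inferred from \code{n_categories} when
#'   that has length > 1).
#' @param quadrature_nodes nodes for latent-trait integration (default 21).
#' @return object of class \code{mixpcm_spec}.
#' @export
model_spec <- function(variant, n_classes = 1, n_categories, n_items = NULL,
                       quadrature_nodes = 21) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  G <- as.integer(n_classes)
  if (G < 1L) stop("n_classes must be >= 1")
  if (variant %in% c("PCM", "GPCM") && G != 1L) {
    stop(variant, " implies a single class; use the mixture variant for G > 1")
  }
  if (is.null(n_items)) {
    n_items <- if (length(n_categories) > 1L) length(n_categories) else 1L
  }
  I <- as.integer(n_items)
  if (I < 1L) stop("need at least one item")
  if (length(n_categories) == 1L) n_categories <- rep(n_categories, I)
  m <- as.integer(n_categories) - 1L
  if (length(m) != I || any(m < 1L)) stop("invalid per-item category counts")
  structure(list(variant = variant, G = G, I = I, m = m,
                 quadrature_nodes = as.integer(quadrature_nodes)),
            class = "mixpcm_spec")
}

#' @export
print.mixpcm_spec <- function(x, ...) {
  cat(sprintf("<mixpcm_spec> %s, G = %d, I = %d, categories %s, %d quadrature nodes\n",
              x$variant, x$G, x$I, paste(x$m + 1L, collapse = "/"),
              x$quadrature_nodes))
  invisible(x)
}

#' Parameter set for a (mixture) partial credit model
#'
#' Holds every quantity of the measurement model: class-specific thresholds
#' \eqn{\tau_{isg}} (s = 1..m_i, in latent-trait units), discriminations
#' \eqn{\delta} (structure depends on the variant), mixing proportions
#' \eqn{\pi_g} and latent variances \eqn{\sigma_g^2}.  Class means are fixed
#' at zero.  Identification follows the convention: first item's
#' discrimination fixed at 1 for GPCM/rmGPCM; a single overall reference
#' (item 1, class 1) fixed at 1 for the mGPCM; all discriminations identically
#' 1 for PCM/mPCM.
#'
#' @param thresholds list of length G; element g is a list of length I of
#'   numeric threshold vectors (length \code{m_i}).  A G x I x m array or a
#'   single I x m matrix (G = 1) is also accepted when all items share m.
#' @param discriminations G x I matrix of positive slopes (a vector of
#'   length I is recycled across classes; scalar recycled over both).
#' @param mixing numeric vector of class proportions (sums to 1).
#' @param variances positive latent variances per class (default all 1).
#' @param variant model variant; consistency with the discrimination
#'   structure is checked.
#' @param item_labels optional item names.
#' @return object of class \code{mixpcm_params}.
#' @export
parameter_set <- function(thresholds, discriminations = 1, mixing = 1,
                          variances = NULL, variant = NULL,
                          item_labels = NULL) {
  thresholds <- canonical_thresholds(thresholds)
  G <- length(thresholds)
  I <- length(thresholds[[1]])
  m <- vapply(thresholds[[1]], length, 1L)
  for (g in seq_len(G)) {
    mg <- vapply(thresholds[[g]], length, 1L)
    if (length(mg) != I || any(mg != m)) {
      stop("threshold structure must agree across classes")
    }
    if (any(!is.finite(unlist(thresholds[[g]])))) stop("non-finite threshold")
  }
  delta <- discriminations
  if (is.null(dim(delta))) {
    if (length(delta) == 1L) delta <- matrix(delta, G, I)
    else if (length(delta) == I) delta <- matrix(delta, G, I, byrow = TRUE)
    else stop("discriminations must be scalar, length I, or a G x I matrix")
  }
  delta <- matrix(as.numeric(delta), G, I)
  if (any(delta <= 0)) stop("discriminations must be strictly positive")
  mixing <- as.numeric(mixing)
  if (length(mixing) != G) stop("mixing must have one entry per class")
  if (abs(sum(mixing) - 1) > 1e-8) stop("mixing proportions must sum to 1")
  if (G > 1L && any(mixing <= 0 | mixing >= 1)) {
    stop("mixing proportions must lie strictly in (0, 1) for G > 1")
  }
  if (is.null(variances)) variances <- rep(1, G)
  variances <- as.numeric(variances)
  if (length(variances) == 1L) variances <- rep(variances, G)
  if (length(variances) != G || any(variances <= 0)) {
    stop("variances must be positive, one per class")
  }
  if (is.null(variant)) {
    variant <- if (G == 1L) {
      if (all(delta == delta[1])) "PCM" else "GPCM"
    } else {
      if (all(delta == delta[1])) "mPCM"
      else if (all(apply(delta, 2, function(col) all(col == col[1])))) "rmGPCM"
      else "mGPCM"
    }
  }
  variant <- match.arg(variant, MODEL_VARIANTS)
  check_variant_delta(variant, delta)
  if (is.null(item_labels)) item_labels <- paste0("item", seq_len(I))
  structure(list(variant = variant, G = G, I = I, m = as.integer(m),
                 tau = thresholds, delta = delta, pi = mixing,
                 sigma2 = variances, item_labels = item_labels),
            class = "mixpcm_params")
}

canonical_thresholds <- function(thresholds) {
  if (is.matrix(thresholds)) {
    thresholds <- list(lapply(seq_len(nrow(thresholds)),
                              function(i) as.numeric(thresholds[i, ])))
  } else if (is.array(thresholds) && length(dim(thresholds)) == 3L) {
    d <- dim(thresholds)
    thresholds <- lapply(seq_len(d[1]), function(g) {
      lapply(seq_len(d[2]), function(i) as.numeric(thresholds[g, i, ]))
    })
  } else if (is.list(thresholds) && !is.list(thresholds[[1]])) {
    thresholds <- list(lapply(thresholds, as.numeric))
  } else if (is.list(thresholds)) {
    thresholds <- lapply(thresholds, function(cl) lapply(cl, as.numeric))
  } else if (is.numeric(thresholds)) {
    thresholds <- list(list(as.numeric(thresholds)))
  } else stop("unsupported threshold structure")
  thresholds
}

check_variant_delta <- function(variant, delta, tol = 1e-8) {
  G <- nrow(delta); I <- ncol(delta)
  switch(variant,
    PCM = , mPCM = {
      if (any(abs(delta - delta[1]) > tol)) {
        stop(variant, " requires all discriminations equal")
      }
    },
    GPCM = , rmGPCM = {
      if (any(apply(delta, 2, function(col) diff(range(col))) > tol)) {
        stop(variant, " requires discriminations shared across classes")
      }
    },
    mGPCM = invisible(NULL))
  invisible(NULL)
}

#' @export
print.mixpcm_params <- function(x, ...) {
  cat(sprintf("<mixpcm_params> %s: G = %d, I = %d\n", x$variant, x$G, x$I))
  cat("  pi     =", paste(sprintf("%.3f", x$pi), collapse = ", "), "\n")
  cat("  sigma2 =", paste(sprintf("%.3f", x$sigma2), collapse = ", "), "\n")
  cat("  delta  =\n")
  print(round(x$delta, 3))
  invisible(x)
}

spec_of <- function(params, quadrature_nodes = 21) {
  model_spec(params$variant, params$G, params$m + 1L, params$I,
             quadrature_nodes)
}

#' Number of free parameters of a model specification
#'
#' Under the identification scheme used throughout the package: per class,
#' all \eqn{m_i} thresholds of every item are free; one latent variance per
#' class; G - 1 mixing proportions; discriminations contribute 0 free
#' parameters for PCM/mPCM, I - 1 for GPCM/rmGPCM (first item fixed at 1) and
#' I * G - 1 for the mGPCM (single overall reference fixed at 1).
#'
#' @param spec a [model_spec()] object.
#' @return integer count.
#' @export
count_free_parameters <- function(spec) {
  stopifnot(inherits(spec, "mixpcm_spec"))
  n_tau <- spec$G * sum(spec$m)
  n_delta <- switch(spec$variant,
    PCM = 0L, mPCM = 0L,
    GPCM = spec$I - 1L, rmGPCM = spec$I - 1L,
    mGPCM = spec$I * spec$G - 1L)
  as.integer(n_tau + n_delta + spec$G + (spec$G - 1L))
}

# --- free-parameter packing (unconstrained scale) -------------------------
# Order: tau (g, then item, then step); log delta (free entries only);
# log sigma2 per class; softmax logits alpha_1..alpha_{G-1} (class G ref).

free_delta_mask <- function(variant, G, I) {
  # TRUE marks a free entry in the packing; for shared-delta variants only
  # the first row is packed (one value per item).
  switch(variant,
    PCM = , mPCM = matrix(FALSE, 1L, I),
    GPCM = , rmGPCM = matrix(c(FALSE, rep(TRUE, I - 1L)), 1L, I, byrow = TRUE),
    mGPCM = {
      msk <- matrix(TRUE, G, I)
      msk[1L, 1L] <- FALSE
      msk
    })
}

pack_params <- function(params) {
  G <- params$G
  tau <- unlist(params$tau, use.names = FALSE)
  msk <- free_delta_mask(params$variant, G, params$I)
  drow <- if (nrow(msk) == 1L) params$delta[1L, , drop = FALSE] else params$delta
  ld <- log(drow[msk])
  c(tau, ld, log(params$sigma2),
    if (G > 1L) log(params$pi[-G] / params$pi[G]) else numeric(0))
}

unpack_params <- function(vec, template) {
  G <- template$G; I <- template$I; m <- template$m
  pos <- 0L
  tau <- template$tau
  for (g in seq_len(G)) for (i in seq_len(I)) {
    tau[[g]][[i]] <- vec[pos + seq_len(m[i])]
    pos <- pos + m[i]
  }
  msk <- free_delta_mask(template$variant, G, I)
  nfree <- sum(msk)
  drow <- if (nrow(msk) == 1L) template$delta[1L, , drop = FALSE] else template$delta
  if (nfree > 0L) {
    drow[msk] <- exp(vec[pos + seq_len(nfree)])
    pos <- pos + nfree
  }
  delta <- if (nrow(msk) == 1L) matrix(drow, G, I, byrow = TRUE) else drow
  sigma2 <- exp(vec[pos + seq_len(G)]); pos <- pos + G
  if (G > 1L) {
    alpha <- c(vec[pos + seq_len(G - 1L)], 0)
    pos <- pos + G - 1L
    pi <- exp(alpha - max(alpha)); pi <- pi / sum(pi)
  } else pi <- 1
  out <- template
  out$tau <- tau; out$delta <- delta; out$sigma2 <- sigma2; out$pi <- pi
  out
}

# Box constraints on the packed scale, aligned with pack_params: thresholds
# and mixing logits in [-30, 30], log-discriminations in [log 1e-3, log 1e3],
# log-variances in [log 1e-3, log 25] (the same interval the EM variance
# update searches).
packed_bounds <- function(params) {
  G <- params$G
  n_tau <- sum(vapply(params$tau, function(cl) sum(lengths(cl)), 1L))
  msk <- free_delta_mask(params$variant, G, params$I)
  nd <- sum(msk)
  lower <- c(rep(-30, n_tau), rep(log(1e-3), nd), rep(log(1e-3), G),
             rep(-30, max(G - 1L, 0L)))
  upper <- c(rep(30, n_tau), rep(log(1e3), nd), rep(log(25), G),
             rep(30, max(G - 1L, 0L)))
  list(lower = lower, upper = upper)
}

free_parameter_names <- function(params) {
  G <- params$G; I <- params$I; m <- params$m
  nm <- character(0)
  for (g in seq_len(G)) for (i in seq_len(I)) {
    nm <- c(nm, sprintf("tau[g%d,%s,s%d]", g, params$item_labels[i], seq_len(m[i])))
  }
  msk <- free_delta_mask(params$variant, G, I)
  for (g in seq_len(nrow(msk))) for (i in seq_len(I)) {
    if (msk[g, i]) {
      lab <- if (nrow(msk) == 1L) sprintf("log_delta[%s]", params$item_labels[i])
             else sprintf("log_delta[g%d,%s]", g, params$item_labels[i])
      nm <- c(nm, lab)
    }
  }
  nm <- c(nm, sprintf("log_sigma2[g%d]", seq_len(G)))
  if (G > 1L) nm <- c(nm, sprintf("alpha[g%d]", seq_len(G - 1L)))
  nm
}

# Reorder classes by descending mixing proportion (label-switching control).
relabel_by_size <- function(params, order = NULL) {
  if (is.null(order)) order <- order(params$pi, decreasing = TRUE)
  params$tau <- params$tau[order]
  params$delta <- params$delta[order, , drop = FALSE]
  params$pi <- params$pi[order]
  params$sigma2 <- params$sigma2[order]
  attr(params, "class_order") <- order
  params
}

#' Serialize a parameter set to JSON
#'
#' @param params a [parameter_set()] object.
#' @param path optional file path; when \code{NULL} the JSON string is
#'   returned.
#' @export
params_to_json <- function(params, path = NULL) {
  obj <- list(variant = params$variant, G = params$G, I = params$I,
              m = params$m, item_labels = params$item_labels,
              thresholds = params$tau, discriminations = params$delta,
              mixing = params$pi, variances = params$sigma2,
              conventions = list(threshold_index = "s = 1..m, category 0 reference",
                                 class_means = "fixed at 0",
                                 class_order = "descending mixing proportion"))
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a parameter set from JSON written by [params_to_json()]
#' @param path file path or JSON string.
#' @export
params_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tau <- lapply(obj$thresholds, function(cl) {
    lapply(cl, function(v) as.numeric(unlist(v)))
  })
  G <- as.integer(obj$G); I <- as.integer(obj$I)
  # toJSON writes matrices row-wise
  delta <- matrix(as.numeric(unlist(obj$discriminations)), G, I, byrow = TRUE)
  parameter_set(tau, discriminations = delta,
                mixing = as.numeric(unlist(obj$mixing)),
                variances = as.numeric(unlist(obj$variances)),
                variant = obj$variant,
                item_labels = as.character(unlist(obj$item_labels)))
}
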