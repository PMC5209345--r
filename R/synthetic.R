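# Synthetic-data generator: draws ordinal response data from any parameter
# set in the family (class -> latent trait -> categories) plus covariates
# with a class-conditional structure whose implied class-membership model
# is an exact multinomial logit.  Named presets bundle the study conditions
# the package is designed around: five 11-category satisfaction items and a
# three-class mixture with published class-specific thresholds.

#' Named scenario presets
#'
#' \describe{
#'   \item{\code{"hilda_like"}}{Five 11-category job-satisfaction items,
#'     G = 3 classes with proportions 0.40/0.33/0.27, item discriminations
#'     (1, 0.71, 1.27, 2.58, 1.76) shared across classes (rmGPCM) and the
#'     published class-specific threshold estimates transcribed verbatim.
#'     Latent variances are set to 1 (the application does not report
#'     them).}
#'   \item{\code{"hilda_like_stable"}}{Same, with thresholds clipped to
#'     |tau| <= 4.  A few published thresholds are extreme with huge
#'     standard errors (an artifact of near-empty categories); the clipped
#'     variant is the appropriate truth for parameter-recovery
#'     experiments.}
#'   \item{\code{"ordered_11"}}{One class, five items with ordered
#'     equidistant thresholds -2.25, -1.75, ..., 2.25 and slope 1.5:
#'     ordinary scale usage over 11 categories.}
#'   \item{\code{"avoided_mid"}}{As \code{"ordered_11"} but with thresholds
#'     7 and 8 swapped (1.25 before 0.75), so category 7's curve is
#'     completely covered -- the canonical avoided-category pattern.}
#'   \item{\code{"ers_dichotomous"}}{One class with fully reversed
#'     thresholds: only the two extreme categories are ever modal, an
#'     extreme-response-style archetype.}
#' }
#'
#' @param name preset name.
#' @return a [parameter_set()].
#' @export
scenario_preset <- function(name = c("hilda_like", "hilda_like_stable",
                                     "ordered_11", "avoided_mid",
                                     "ers_dichotomous")) {
  name <- match.arg(name)
  items <- c("total_pay", "job_security", "work_itself", "working_hours",
             "flexibility")
  if (name %in% c("hilda_like", "hilda_like_stable")) {
    tau <- jobsat_class_thresholds()
    if (name == "hilda_like_stable") {
      tau <- lapply(tau, function(cl) lapply(cl, function(v) pmin(pmax(v, -4), 4)))
    }
    return(parameter_set(tau,
                         discriminations = c(1, 0.71, 1.27, 2.58, 1.76),
                         mixing = c(0.40, 0.33, 0.27),
                         variances = c(1, 1, 1),
                         variant = "rmGPCM", item_labels = items))
  }
  base <- switch(name,
    ordered_11 = seq(-2.25, 2.25, by = 0.5),
    avoided_mid = c(-2.25, -1.75, -1.25, -0.75, -0.25, 0.25, 1.25, 0.75,
                    1.75, 2.25),
    ers_dichotomous = seq(1.8, -1.8, length.out = 10))
  delta <- if (name == "ers_dichotomous") 1 else 1.5
  parameter_set(lapply(seq_len(5), function(i) base),
                discriminations = delta, mixing = 1, variances = 1,
                variant = "PCM", item_labels = items)
}

# Class-specific threshold estimates of the published three-class solution
# (items x steps per class), transcribed to two decimals.
jobsat_class_thresholds <- function() {
  c1 <- rbind(
    c(-2.27, -1.52, -0.86, -0.41, -0.64, -0.25, -0.46, -0.10,  1.92,  1.16),
    c(-2.43, -1.72, -1.18,  0.04, -1.16, -0.06, -0.84, -0.99,  0.95,  0.29),
    c( 2.44, -5.71, -1.42, -0.45, -0.83, -0.30, -0.53, -0.36,  1.08,  0.95),
    c(-3.47, -1.28, -0.66, -0.41, -0.41, -0.11, -0.23, -0.03,  0.86,  0.67),
    c(-1.08, -1.06, -0.56, -0.22, -0.48, -0.17, -0.33, -0.16,  0.56,  0.53))
  c2 <- rbind(
    c( 0.98, -0.77, -0.52, -0.08, -1.22,  0.61, -0.78, -0.24,  1.24, -1.89),
    c( 1.11, -1.00,  0.10, -0.05, -1.79,  1.47, -0.80, -1.35,  0.98, -3.51),
    c( 0.22, -0.84, -0.44, -0.06, -1.39,  0.25, -0.64, -0.49,  0.74, -1.61),
    c( 0.12, -0.77, -0.26, -0.15, -0.77,  0.21, -0.34, -0.29,  0.56, -0.88),
    c( 0.30, -0.57, -0.18, -0.16, -0.93,  0.63, -0.69, -0.38,  0.54, -1.38))
  c3 <- rbind(
    c(-1.61, -0.60, -0.35,  0.22, -0.83, -0.01, -0.85, -0.03, -0.11,  1.93),
    c(-0.38, -0.28,  0.61, -0.68, -1.43,  1.33, -2.24, -0.33, -1.35,  0.93),
    c(-1.79, -0.47, -0.27,  0.01, -0.84, -0.26, -0.68, -0.16, -0.76,  1.15),
    c(-2.15, -0.25, -0.31, -0.09, -0.59, -0.08, -0.24, -0.05, -0.30,  0.79),
    c(-0.66, -0.39, -0.15, -0.18, -0.59,  0.18, -0.36, -0.31, -0.45,  0.40))
  lapply(list(c1, c2, c3), function(M) {
    lapply(seq_len(nrow(M)), function(i) as.numeric(M[i, ]))
  })
}

#' Simulate ordinal responses from a parameter set
#'
#' Persons are assigned a class from \eqn{Categorical(\pi)}, a latent trait
#' from \eqn{N(0, \sigma_g^2)}, and item responses from the class's
#' category probabilities.  Deterministic given the seed.
#'
#' @param params a [parameter_set()] (e.g. from [scenario_preset()]).
#' @param n number of persons.
#' @param seed RNG seed.
#' @return list with \code{data} (a [response_matrix()]) and \code{truth}
#'   (class labels, latent traits, the generating parameters and the seed).
#' @export
generate_responses <- function(params, n, seed = 1) {
  stopifnot(inherits(params, "mixpcm_params"), n >= 1)
  set.seed(seed)
  G <- params$G
  labels <- if (G == 1L) rep(1L, n) else
    sample.int(G, n, replace = TRUE, prob = params$pi)
  theta <- stats::rnorm(n, 0, sqrt(params$sigma2[labels]))
  vals <- matrix(NA_integer_, n, params$I)
  for (g in seq_len(G)) {
    idx <- which(labels == g)
    if (!length(idx)) next
    for (i in seq_len(params$I)) {
      P <- category_probabilities(theta[idx], params$tau[[g]][[i]],
                                  params$delta[g, i])
      P <- matrix(P, length(idx), params$m[i] + 1L)
      cp <- t(apply(P, 1, cumsum))
      u <- stats::runif(length(idx))
      vals[idx, i] <- rowSums(u > cp[, -ncol(cp), drop = FALSE])
    }
  }
  colnames(vals) <- params$item_labels
  data <- response_matrix(vals, n_categories = params$m + 1L,
                          item_labels = params$item_labels)
  list(data = data,
       truth = list(labels = labels, theta = theta, params = params,
                    seed = seed))
}

#' Default covariate-generating specification
#'
#' A schematic covariate battery mirroring a typical employment-survey
#' predictor set: age, gender, education, income, tenure, job position,
#' part-time status, organization size, four job-characteristics subscale
#' scores and job importance.  Class effects (log-odds against class 1)
#' loosely follow the signs and magnitudes reported in applied work;
#' distributional families are schematic, since only the class-covariate
#' association structure matters for testing the three-step machinery.
#'
#' @param G number of classes (2 or 3 supported by the default effects).
#' @return list of per-covariate entries understood by
#'   [generate_covariates()].
#' @export
default_covariate_spec <- function(G = 3) {
  b <- function(...) { v <- c(0, ...); length(v) <- G; v[is.na(v)] <- 0; v }
  list(
    age        = list(type = "normal", mean = 39.2, sd = 11.5, beta = b(0.02, 0.01)),
    gender     = list(type = "categorical", levels = c("male", "female"),
                      base = c(0.53, 0.47),
                      beta = rbind(b(), b(0.42, 0.36))),
    education  = list(type = "categorical", levels = c("basic", "degree"),
                      base = c(0.42, 0.58),
                      beta = rbind(b(), b(-0.30, 0.02))),
    income     = list(type = "normal", mean = 43, sd = 25, beta = b(0, 0)),
    tenure     = list(type = "normal", mean = 8, sd = 7, beta = b(0, 0)),
    job_position = list(type = "categorical",
                        levels = c("level3", "level2", "level1"),
                        base = c(0.35, 0.33, 0.32),
                        beta = rbind(b(), b(-0.20, -0.07), b(-0.43, -0.27))),
    part_time  = list(type = "categorical", levels = c("no", "yes"),
                      base = c(0.74, 0.26),
                      beta = rbind(b(), b(0.91, 0.57))),
    org_size   = list(type = "categorical",
                      levels = c("large", "small", "medium"),
                      base = c(0.34, 0.33, 0.33),
                      beta = rbind(b(), b(0.55, 0.02), b(0.15, 0.09))),
    autonomy   = list(type = "normal", mean = 4.5, sd = 1.2, beta = b(0.16, 0.03)),
    skills     = list(type = "normal", mean = 4.8, sd = 1.2, beta = b(0.14, 0.14)),
    security   = list(type = "normal", mean = 5.0, sd = 1.2, beta = b(0.28, 0.11)),
    stress     = list(type = "normal", mean = 4.0, sd = 1.3, beta = b(-0.25, -0.08)),
    importance = list(type = "normal", mean = 7.5, sd = 2.0, beta = b(0.39, 0.14)))
}

#' Simulate covariates with a multinomial-logit link to class
#'
#' Covariates are drawn class-conditionally so that the implied model of
#' class membership given covariates is an exact multinomial logit with the
#' requested coefficients: a normal covariate with variance \eqn{\sigma^2}
#' and class-g mean shift \eqn{\beta_g \sigma^2} contributes log-odds
#' coefficient \eqn{\beta_g}; a categorical covariate with class-g level
#' log-odds shifts \eqn{\beta_{g,l}} (reference level 0) contributes dummy
#' coefficients \eqn{\beta_{g,l}} exactly.  Covariates are complete (no
#' missing values).
#'
#' @param labels integer class labels (1..G).
#' @param spec per-covariate entries as in [default_covariate_spec()]:
#'   \code{type} ("normal"/"categorical") plus \code{mean}, \code{sd},
#'   \code{beta} (length G, reference class 1) for normals, or
#'   \code{levels}, \code{base} (reference-class level probabilities) and
#'   \code{beta} (levels x G matrix, first row/column zero) for factors.
#' @param seed RNG seed.
#' @return data frame of covariates with attribute \code{"truth"} holding
#'   the implied multinomial-logit coefficients per covariate.
#' @export
generate_covariates <- function(labels, spec = default_covariate_spec(max(labels)),
                                seed = 1) {
  set.seed(seed)
  n <- length(labels)
  G <- max(labels)
  out <- list()
  truth <- list()
  for (nm in names(spec)) {
    e <- spec[[nm]]
    if (e$type == "normal") {
      beta <- e$beta
      if (length(beta) != G) stop("beta length mismatch for ", nm)
      shift <- beta * e$sd^2
      out[[nm]] <- stats::rnorm(n, e$mean + shift[labels], e$sd)
      truth[[nm]] <- beta
    } else if (e$type == "categorical") {
      beta <- e$beta            # levels x G (first column = reference class)
      if (is.null(dim(beta))) beta <- matrix(beta, ncol = G)
      if (nrow(beta) != length(e$levels) || ncol(beta) != G) {
        stop("beta dimensions mismatch for ", nm)
      }
      probs <- vapply(seq_len(G), function(g) {
        p <- e$base * exp(beta[, g])
        p / sum(p)
      }, numeric(length(e$levels)))
      draws <- character(n)
      for (g in seq_len(G)) {
        idx <- which(labels == g)
        if (length(idx)) {
          draws[idx] <- sample(e$levels, length(idx), replace = TRUE,
                               prob = probs[, g])
        }
      }
      out[[nm]] <- factor(draws, levels = e$levels)
      truth[[nm]] <- beta
    } else stop("unknown covariate type for ", nm)
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  attr(df, "truth") <- truth
  df
}

#' Per-item category frequencies, mean and SD
#'
#' Descriptive check for the characteristic left-skew of satisfaction
#' ratings: relative category frequencies plus the mean and standard
#' deviation (sample convention, n - 1) of the 0..m scores per item.
#'
#' @param data a [response_matrix()].
#' @return list with \code{frequencies} (items x categories, rows sum to
#'   1), \code{mean} and \code{sd} per item.
#' @export
left_skew_check <- function(data) {
  stopifnot(inherits(data, "mixpcm_responses"))
  m_all <- max(data$m)
  freq <- matrix(0, ncol(data$values), m_all + 1L,
                 dimnames = list(data$item_labels, paste0("cat", 0:m_all)))
  mu <- sdv <- numeric(ncol(data$values))
  for (i in seq_len(ncol(data$values))) {
    x <- data$values[, i]; x <- x[!is.na(x)]
    tab <- tabulate(x + 1L, nbins = m_all + 1L)
    freq[i, ] <- tab / length(x)
    mu[i] <- mean(x)
    sdv[i] <- stats::sd(x)
  }
  list(frequencies = freq, mean = stats::setNames(mu, data$item_labels),
       sd = stats::setNames(sdv, data$item_labels))
}
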