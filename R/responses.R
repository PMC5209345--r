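#' Ordinal response matrix
#'
#' Container for a persons-by-items matrix of ordinal responses with
#' categories coded \code{0..m_i} per item.  Missing entries are stored as
#' \code{NA} and are treated as ignorably missing by the likelihood (each
#' missing item contributes a factor of one).
#'
#' @param values integer matrix (or data frame), one row per person, one
#'   column per item; entries in \code{0..m_i} or \code{NA}.
#' @param n_categories optional integer vector giving the number of
#'   categories \code{m_i + 1} per item.  When \code{NULL} the count is
#'   inferred as \code{max(column) + 1}.
#' @param item_labels optional character vector of item names; defaults to
#'   column names or \code{item1, item2, ...}.
#' @param strict if \code{TRUE}, any missing entry is an error (complete-case
#'   analyses); the default allows missing responses.
#'
#' @return An object of class \code{mixpcm_responses}: a list with
#'   \code{values} (integer matrix), \code{m} (per-item maximum category) and
#'   \code{item_labels}.
#' @export
response_matrix <- function(values, n_categories = NULL, item_labels = NULL,
                            strict = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("response values must be numeric integer codes")
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("need at least one person and one item")
  }
  nonmiss <- values[!is.na(values)]
  if (any(nonmiss != round(nonmiss))) {
    stop("response categories must be integers")
  }
  storage.mode(values) <- "integer"
  I <- ncol(values)
  if (is.null(item_labels)) {
    item_labels <- colnames(values)
    if (is.null(item_labels)) item_labels <- paste0("item", seq_len(I))
  }
  if (is.null(n_categories)) {
    m <- apply(values, 2, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) stop("an item has no observed responses")
      max(v)
    })
  } else {
    if (length(n_categories) == 1L) n_categories <- rep(n_categories, I)
    m <- as.integer(n_categories) - 1L
  }
  if (any(m < 1L)) stop("every item needs at least 2 categories")
  for (i in seq_len(I)) {
    v <- values[, i]
    bad <- which(!is.na(v) & (v < 0L | v > m[i]))
    if (length(bad)) {
      stop(sprintf("item '%s': category %d at row %d outside 0..%d",
                   item_labels[i], v[bad[1]], bad[1], m[i]))
    }
  }
  if (strict && anyNA(values)) stop("missing responses present under strict = TRUE")
  if (any(rowSums(!is.na(values)) == 0L)) {
    stop("every person must have at least one non-missing response")
  }
  structure(list(values = values, m = as.integer(m),
                 item_labels = as.character(item_labels)),
            class = "mixpcm_responses")
}

#' @export
print.mixpcm_responses <- function(x, ...) {
  cat(sprintf("<mixpcm_responses> %d persons x %d items; categories: %s; %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              paste(x$m + 1L, collapse = "/"),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.mixpcm_responses <- function(x) dim(x$values)

#' Read a response matrix from delimited text
#'
#' Expects a header row, one row per person and one integer column per item.
#' The separator is taken from the file extension (\code{.csv} comma,
#' otherwise tab) unless given explicitly.
#'
#' @param path file path.
#' @param missing_token string standing for a missing response (default
#'   \code{"NA"}); empty cells are always treated as missing.
#' @param sep field separator; \code{NULL} to infer from the extension.
#' @param n_categories as in [response_matrix()].
#' @return A [response_matrix()] object.
#' @export
read_responses <- function(path, missing_token = "NA", sep = NULL,
                           n_categories = NULL) {
  if (!file.exists(path)) stop("response file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c(missing_token, ""),
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 1L) stop("no item columns found in ", path)
  vals <- matrix(NA_integer_, nrow(df), ncol(df))
  for (j in seq_len(ncol(df))) {
    raw <- df[[j]]
    ok <- is.na(raw) | grepl("^\\s*-?[0-9]+\\s*$", raw)
    if (!all(ok)) {
      stop(sprintf("non-integer cell at row %d, column '%s': '%s'",
                   which(!ok)[1], names(df)[j], raw[which(!ok)[1]]))
    }
    vals[, j] <- suppressWarnings(as.integer(raw))
  }
  colnames(vals) <- names(df)
  response_matrix(vals, n_categories = n_categories)
}

#' Write responses to CSV (inverse of [read_responses()])
#' @param data a [response_matrix()] object.
#' @param path output path.
#' @param missing_token token used for missing entries.
#' @export
write_responses <- function(data, path, missing_token = "NA") {
  df <- as.data.frame(data$values)
  names(df) <- data$item_labels
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = missing_token)
  invisible(path)
}
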