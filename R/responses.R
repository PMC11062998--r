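#' Construct a binary item response matrix
#'
#' Validates and wraps an N x J table of binary item responses. Rows are
#' respondents, columns are items. Missing responses (`NA`) are allowed and
#' are skipped in all likelihood computations (ignorable missingness); every
#' respondent must have at least one observed response.
#'
#' @param x A data frame or matrix with entries in `{0, 1, NA}`. Column names
#'   are taken as item identifiers (defaults `item1..itemJ`).
#' @return An object of class `latdif_responses`: a list with `values`
#'   (integer matrix, `NA` where unobserved) and `observed` (logical matrix).
#' @examples
#' y <- data.frame(i1 = c(1, 0), i2 = c(0, NA))
#' r <- as_response_matrix(y)
#' dim(r)
#' @export
as_response_matrix <- function(x) {
  if (inherits(x, "latdif_responses")) return(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("responses must be a matrix or data frame", call. = FALSE)
  storage.mode(x) <- "double"
  bad <- which(!is.na(x) & x != 0 & x != 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-binary response value %s at row %d, column %d (%s)",
      format(x[bad[1, , drop = FALSE]]), bad[1, 1], bad[1, 2],
      if (!is.null(colnames(x))) colnames(x)[bad[1, 2]] else "unnamed"
    ), call. = FALSE)
  }
  if (nrow(x) < 1 || ncol(x) < 2) {
    stop("need at least 1 respondent and 2 items", call. = FALSE)
  }
  observed <- !is.na(x)
  if (any(rowSums(observed) == 0)) {
    stop("every respondent must have at least one observed response", call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("item", seq_len(ncol(x)))
  storage.mode(x) <- "integer"
  structure(list(values = x, observed = observed), class = "latdif_responses")
}

#' @export
dim.latdif_responses <- function(x) dim(x$values)

#' @export
print.latdif_responses <- function(x, ...) {
  n_miss <- sum(!x$observed)
  cat(sprintf(
    "<latdif_responses> %d respondents x %d items (%d missing entries)\n",
    nrow(x$values), ncol(x$values), n_miss
  ))
  invisible(x)
}

# Dense numeric views used throughout the likelihood code: Y has NA -> 0 so
# that Y * O picks out observed ones only.
prep_responses <- function(data) {
  data <- as_response_matrix(data)
  O <- matrix(as.numeric(data$observed), nrow(data$values), ncol(data$values))
  Y <- data$values
  Y[!data$observed] <- 0L
  Y <- matrix(as.numeric(Y), nrow(Y), ncol(Y))
  list(
    Y = Y, O = O, YO = Y * O,
    N = nrow(Y), J = ncol(Y),
    items = colnames(data$values),
    complete = all(data$observed)
  )
}

#' Read a response matrix from CSV
#'
#' Expects a header row of item identifiers and one row per respondent with
#' cells in `{0, 1, NA}` (empty cells also count as missing). Malformed cells
#' are rejected with their row/column location.
#'
#' @param path Path to a CSV file.
#' @return A [as_response_matrix()] object.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop("response file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = NA, na.strings = c("NA", ""))
  if (nrow(df) == 0) stop("empty response file: ", path, call. = FALSE)
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col) && !is.logical(col)) {
      bad <- which(!is.na(col))[1]
      stop(sprintf("non-binary value '%s' at row %d, column %d (%s) of %s",
                   col[bad], bad, j, names(df)[j], path), call. = FALSE)
    }
  }
  m <- as.matrix(df)
  bad <- which(!is.na(m) & m != 0 & m != 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-binary value '%s' at row %d, column %d (%s) of %s",
                 format(m[bad[1, , drop = FALSE]]), bad[1, 1], bad[1, 2],
                 colnames(m)[bad[1, 2]], path), call. = FALSE)
  }
  as_response_matrix(m)
}

#' Write a response matrix to CSV
#'
#' Inverse of [read_responses()]: round-trips exactly, including the
#' missingness pattern (written as `NA`).
#'
#' @param data Responses coercible via [as_response_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(data, path) {
  data <- as_response_matrix(data)
  utils::write.csv(as.data.frame(data$values), path, row.names = FALSE, na = "NA")
  invisible(path)
}
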