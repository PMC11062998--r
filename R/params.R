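#' Parameter set for the latent-DIF mixture 2-PL model
#'
#' Bundles all free parameters of the model: item discriminations `a` and
#' easiness intercepts `d`, the J x K matrix of class-specific DIF offsets
#' `delta` (class 0, the reference class, has all offsets fixed at zero and
#' is not stored), class proportions `nu` over classes `0..K`, and the
#' class-conditional ability means `mu` and variances `sigma2`. The reference
#' class is pinned at `mu[0] = 0`, `sigma2[0] = 1`, which identifies the
#' location and scale of the latent trait.
#'
#' Indexing convention: vectors over classes have length `K + 1` with element
#' 1 holding the reference class (class 0); `delta` columns `1..K` hold
#' classes `1..K`.
#'
#' @param a,d Numeric vectors of length J.
#' @param delta Numeric J x K matrix (or `NULL` for `K = 0`).
#' @param nu Probability vector of length `K + 1` summing to 1.
#' @param mu Class means, length `K + 1`, first element 0.
#' @param sigma2 Class variances, length `K + 1`, first element 1, all > 0.
#' @return An object of class `latdif_params`.
#' @export
latdif_params <- function(a, d, delta = NULL, nu = 1, mu = 0, sigma2 = 1) {
  J <- length(a)
  K <- length(nu) - 1L
  if (is.null(delta)) delta <- matrix(0, J, K)
  delta <- as.matrix(delta)
  p <- structure(
    list(a = as.numeric(a), d = as.numeric(d), delta = delta,
         nu = as.numeric(nu), mu = as.numeric(mu), sigma2 = as.numeric(sigma2)),
    class = "latdif_params"
  )
  validate_params(p)
}

validate_params <- function(p) {
  J <- length(p$a); K <- length(p$nu) - 1L
  stopifnot(length(p$d) == J)
  if (!all(dim(p$delta) == c(J, K))) {
    stop("delta must be a ", J, " x ", K, " matrix", call. = FALSE)
  }
  if (length(p$mu) != K + 1 || length(p$sigma2) != K + 1) {
    stop("mu and sigma2 must have length K + 1", call. = FALSE)
  }
  if (any(!is.finite(unlist(p[c("a", "d", "delta", "nu", "mu", "sigma2")])))) {
    stop("non-finite parameter value", call. = FALSE)
  }
  if (abs(sum(p$nu) - 1) > 1e-8 || any(p$nu < -1e-12)) {
    stop("nu must be a probability vector", call. = FALSE)
  }
  if (p$mu[1] != 0 || p$sigma2[1] != 1) {
    stop("reference class must have mu = 0, sigma2 = 1", call. = FALSE)
  }
  if (any(p$sigma2 <= 0)) stop("sigma2 must be positive", call. = FALSE)
  p
}

n_classes <- function(params) length(params$nu)

#' @export
print.latdif_params <- function(x, ...) {
  J <- length(x$a); K <- length(x$nu) - 1L
  cat(sprintf("<latdif_params> J = %d items, K = %d focal class(es)\n", J, K))
  cat("  nu:    ", paste(formatC(x$nu, digits = 3, format = "f"), collapse = " "), "\n")
  cat("  mu:    ", paste(formatC(x$mu, digits = 3, format = "f"), collapse = " "), "\n")
  cat("  sigma2:", paste(formatC(x$sigma2, digits = 3, format = "f"), collapse = " "), "\n")
  if (K > 0) cat("  nonzero DIF offsets:", sum(x$delta != 0), "of", J * K, "\n")
  invisible(x)
}

#' Shift-and-absorb identifiability transform
#'
#' The latent trait scale is not identified without anchor items: shifting a
#' focal class mean by `c[k]` while absorbing `a_j * c[k]` into that class's
#' DIF offsets leaves the marginal likelihood unchanged. This transform is
#' exposed for invariance testing; the sparsity penalty is what breaks the
#' indeterminacy during estimation.
#'
#' @param params A [latdif_params()] object.
#' @param c_shift Numeric vector of length K (one shift per focal class).
#' @return Transformed `latdif_params` with identical marginal likelihood.
#' @export
apply_identifiability_transform <- function(params, c_shift) {
  K <- n_classes(params) - 1L
  if (length(c_shift) != K) stop("c_shift must have length K = ", K, call. = FALSE)
  if (K == 0) return(params)
  out <- params
  out$mu[-1] <- out$mu[-1] + c_shift
  out$delta <- out$delta - outer(params$a, c_shift)
  validate_params(out)
}

#' Permute the focal-class labels of a parameter set
#'
#' Focal classes are exchangeable (label switching); this relabels them so
#' that new class `k` is old class `perm[k]`. The reference class is never
#' permuted, and the marginal likelihood is unchanged.
#'
#' @param params A [latdif_params()] object.
#' @param perm A permutation of `1..K`.
#' @return Relabelled `latdif_params`.
#' @export
permute_classes <- function(params, perm) {
  K <- n_classes(params) - 1L
  if (!setequal(perm, seq_len(K))) stop("perm must permute 1..K", call. = FALSE)
  out <- params
  out$nu[-1] <- params$nu[1 + perm]
  out$mu[-1] <- params$mu[1 + perm]
  out$sigma2[-1] <- params$sigma2[1 + perm]
  out$delta <- params$delta[, perm, drop = FALSE]
  out
}

params_to_list <- function(p) {
  list(a = p$a, d = p$d, delta = unclass(p$delta),
       nu = p$nu, mu = p$mu, sigma2 = p$sigma2)
}

params_from_list <- function(x) {
  a <- as.numeric(unlist(x$a))
  nu <- as.numeric(unlist(x$nu))
  K <- length(nu) - 1L
  delta <- x$delta
  if (K == 0 || is.null(delta) || length(delta) == 0) {
    delta <- matrix(0, length(a), K)
  } else {
    delta <- matrix(as.numeric(as.matrix(delta)), length(a), K)
  }
  latdif_params(a = a, d = as.numeric(unlist(x$d)), delta = delta,
                nu = nu, mu = as.numeric(unlist(x$mu)),
                sigma2 = as.numeric(unlist(x$sigma2)))
}

#' Serialise / deserialise a parameter set as JSON
#'
#' `delta` is stored dense, with explicit zeros, so the DIF support is
#' recoverable from the file alone.
#'
#' @param params A [latdif_params()] object.
#' @param path File path.
#' @return `read_params` returns a `latdif_params`; `write_params` returns
#'   `path` invisibly.
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(params_to_list(params), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  params_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}
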