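#' Item response function of the mixture 2-PL
#'
#' Probability of a correct/positive response given ability `theta` for an
#' item with discrimination `a_j`, easiness `d_j`, and class-specific DIF
#' offset `delta_jk` (zero for the reference class):
#' `P(Y = 1) = logistic(a_j * theta + d_j + delta_jk)`. The offset is the
#' log-odds ratio between a focal-class and a reference-class respondent at
#' equal ability.
#'
#' @param theta Ability value(s).
#' @param a_j,d_j Item discrimination and easiness.
#' @param delta_jk DIF offset (default 0).
#' @return Response probabilities in (0, 1).
#' @examples
#' irf_prob(0, 1, 0)           # 0.5
#' irf_prob(2, 1.5, -1, 0.5)   # logistic(2.5)
#' @export
irf_prob <- function(theta, a_j, d_j, delta_jk = 0) {
  eta <- a_j * theta + d_j + delta_jk
  if (any(!is.finite(eta))) stop("non-finite item response logit", call. = FALSE)
  stats::plogis(eta)
}

# log(1 + exp(x)), stably, vectorised
log1pexp <- function(x) -stats::plogis(x, lower.tail = FALSE, log.p = TRUE)

# Standard-normal Gauss-Hermite rule on the z scale: integrates
# E[f(Z)], Z ~ N(0,1), as sum w * f(z). Cached per Q.
gh_standard <- local({
  cache <- list()
  function(Q) {
    key <- as.character(Q)
    if (is.null(cache[[key]])) {
      gh <- pracma::gaussHermite(Q)
      cache[[key]] <<- list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
    }
    cache[[key]]
  }
})

#' Per-class quadrature rule for the ability distribution
#'
#' Gauss-Hermite nodes and weights transformed to each class's normal ability
#' distribution: node = `mu_k + sqrt(2 * sigma2_k) * x`, weight = `w / sqrt(pi)`,
#' so the weights sum to 1 and weighted node moments match `N(mu_k, sigma2_k)`.
#'
#' @param mu Class means (length number of classes).
#' @param sigma2 Class variances, all positive.
#' @param Q Number of quadrature points, at least 2.
#' @return List with `nodes` (Q x n_classes matrix) and `weights` (length Q,
#'   shared across classes).
#' @export
make_quadrature <- function(mu, sigma2, Q = 31) {
  if (Q < 2) stop("Q must be at least 2", call. = FALSE)
  if (any(sigma2 <= 0) || any(!is.finite(sigma2)) || any(!is.finite(mu))) {
    stop("mu must be finite and sigma2 positive", call. = FALSE)
  }
  gh <- gh_standard(Q)
  nodes <- outer(gh$z, sqrt(sigma2)) + rep(mu, each = Q)
  list(nodes = nodes, weights = gh$w)
}

quad_for_params <- function(params, Q) make_quadrature(params$mu, params$sigma2, Q)

# Conditional response log-likelihood per respondent and node, one N x Q
# matrix per class: L_c[i, q] = sum_{j observed} log Bern(Y_ij; p(node_cq)).
# Uses log p - log(1 - p) = eta so only one stable log1pexp evaluation.
cond_loglik_by_class <- function(params, pd, quad) {
  C <- n_classes(params)
  Q <- length(quad$weights)
  lapply(seq_len(C), function(c) {
    dd <- params$d + if (c > 1) params$delta[, c - 1L] else 0
    eta <- outer(params$a, quad$nodes[, c]) + dd       # J x Q
    lq <- -log1pexp(eta)                               # log(1 - p)
    pd$YO %*% eta + pd$O %*% lq                        # N x Q
  })
}

# Joint per-(class, node) log weights: N x (C * Q) matrix with blocks per
# class; block c column q holds log nu_c + log w_q + L_c[i, q].
joint_log_weights <- function(params, pd, quad) {
  Ls <- cond_loglik_by_class(params, pd, quad)
  C <- n_classes(params)
  lw <- log(quad$weights)
  lnu <- ifelse(params$nu > 0, log(params$nu), -Inf)
  do.call(cbind, lapply(seq_len(C), function(c) {
    sweep(Ls[[c]], 2, lw + lnu[c], "+")
  }))
}

row_logsumexp <- function(m) {
  mx <- do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
  mx + log(rowSums(exp(m - mx)))
}

#' Marginal log-likelihood of the mixture 2-PL
#'
#' The observed-data log-likelihood with both the latent class and the latent
#' ability integrated out; the ability integral is evaluated by the per-class
#' quadrature rule and all sums are in log space, so the value is finite for
#' any finite parameters.
#'
#' @param params A [latdif_params()] object.
#' @param data Responses coercible via [as_response_matrix()].
#' @param quad Quadrature rule from [make_quadrature()] built at
#'   `params$mu`, `params$sigma2`; defaults to a fresh rule with `Q` points.
#' @param Q Quadrature size used when `quad` is `NULL`.
#' @return The scalar log-likelihood.
#' @export
log_marginal_likelihood <- function(params, data, quad = NULL, Q = 31) {
  pd <- prep_responses(data)
  if (length(params$a) != pd$J) stop("parameter/item dimension mismatch", call. = FALSE)
  if (pd$N < 1) stop("empty data", call. = FALSE)
  if (is.null(quad)) quad <- quad_for_params(params, Q)
  sum(row_logsumexp(joint_log_weights(params, pd, quad)))
}

#' L1-penalised negative log-likelihood
#'
#' The objective minimised by the regularised estimator:
#' `-log L + lambda * sum(|delta|)`. The penalty covers only the DIF offsets;
#' item, structural, and mixing parameters are unpenalised.
#'
#' @inheritParams log_marginal_likelihood
#' @param lambda Nonnegative penalty weight.
#' @return The scalar penalised objective.
#' @export
penalized_objective <- function(params, data, lambda, quad = NULL, Q = 31) {
  if (lambda < 0) stop("lambda must be nonnegative", call. = FALSE)
  -log_marginal_likelihood(params, data, quad = quad, Q = Q) +
    lambda * sum(abs(params$delta))
}
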