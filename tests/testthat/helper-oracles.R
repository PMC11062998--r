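# Independent oracles used across the suite. These re-derive quantities by
# brute force (dense grids, enumeration, pairwise counting) and must stay
# free of the package's own computational path.

# Marginal log-likelihood by trapezoid integration on a dense theta grid.
brute_log_marginal <- function(params, Y, grid_n = 10001, lim = 10) {
  K <- length(params$nu) - 1L
  th <- seq(-lim, lim, length.out = grid_n)
  dth <- th[2] - th[1]
  sum(vapply(seq_len(nrow(Y)), function(i) {
    per_class <- vapply(0:K, function(k) {
      dlt <- if (k > 0) params$delta[, k] else rep(0, length(params$a))
      lik <- vapply(th, function(t) {
        pr <- stats::plogis(params$a * t + params$d + dlt)
        prod(ifelse(is.na(Y[i, ]), 1, pr^Y[i, ] * (1 - pr)^(1 - Y[i, ])))
      }, numeric(1))
      sum(lik * stats::dnorm(th, params$mu[k + 1], sqrt(params$sigma2[k + 1]))) * dth
    }, numeric(1))
    log(sum(params$nu * per_class))
  }, numeric(1)))
}

# Joint posterior over (class, node) by direct term-by-term enumeration.
brute_posterior <- function(params, Y, quad) {
  K <- length(params$nu) - 1L
  Q <- length(quad$weights)
  N <- nrow(Y)
  joint <- array(0, dim = c(N, K + 1, Q))
  for (i in seq_len(N)) {
    for (k in 0:K) {
      dlt <- if (k > 0) params$delta[, k] else rep(0, length(params$a))
      for (q in seq_len(Q)) {
        pr <- stats::plogis(params$a * quad$nodes[q, k + 1] + params$d + dlt)
        lik <- prod(ifelse(is.na(Y[i, ]), 1, pr^Y[i, ] * (1 - pr)^(1 - Y[i, ])))
        joint[i, k + 1, q] <- params$nu[k + 1] * quad$weights[q] * lik
      }
    }
    joint[i, , ] <- joint[i, , ] / sum(joint[i, , ])
  }
  joint
}

# Pairwise-counting AUC with half-credit for ties.
brute_auc <- function(scores, truth) {
  pos <- which(truth == 1); neg <- which(truth == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

random_params <- function(J, K, seed) {
  set.seed(seed)
  delta <- matrix(0, J, K)
  if (K > 0) delta[sample(J * K, ceiling(J * K / 3))] <- runif(ceiling(J * K / 3), -1, 1)
  nu <- runif(K + 1, 0.2, 1); nu <- nu / sum(nu)
  latdif_params(a = runif(J, 0.5, 1.5), d = runif(J, -1.5, 1.5), delta = delta,
                nu = nu, mu = c(0, if (K > 0) runif(K, -0.7, 0.7)),
                sigma2 = c(1, if (K > 0) runif(K, 0.6, 1.6)))
}

random_data <- function(params, N, seed) {
  set.seed(seed)
  K <- length(params$nu) - 1L
  xi <- sample(0:K, N, TRUE, prob = params$nu)
  th <- rnorm(N, params$mu[1 + xi], sqrt(params$sigma2[1 + xi]))
  dlt <- cbind(0, params$delta)
  eta <- outer(th, params$a) + rep(params$d, each = N) + t(dlt[, 1 + xi, drop = FALSE])
  y <- matrix(as.integer(runif(length(eta)) < plogis(eta)), N, length(params$a))
  colnames(y) <- paste0("item", seq_len(ncol(y)))
  y
}
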