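#' EM algorithm controls
#'
#' Tuning knobs for the regularised EM fit. Defaults follow standard practice
#' for proximal-gradient schemes: one E-step per iteration, then `n_inner`
#' line-searched proximal-gradient steps on the smooth-plus-L1 surrogate.
#'
#' @param max_iter Maximum EM iterations.
#' @param tol Relative penalised-objective change declaring convergence.
#' @param step_init Initial proximal step size (warm-started across
#'   iterations: twice the previously accepted step).
#' @param backtrack_factor Step shrink factor in (0, 1) for the backtracking
#'   line search.
#' @param armijo_const Sufficient-decrease constant in (0, 1).
#' @param n_starts Number of jittered multistarts.
#' @param seed Seed for the multistart jitter.
#' @param Q Quadrature points per latent class.
#' @param n_inner Maximum proximal-gradient steps per M-step (the inner loop
#'   exits early once per-step progress is negligible).
#' @param precondition Take the proximal step in the diagonal Gauss-Newton
#'   metric of the surrogate (default) rather than the identity metric; the
#'   plain update needs far more iterations on these likelihoods.
#' @return A list of class `latdif_controls`.
#' @export
em_controls <- function(max_iter = 1000, tol = 1e-6, step_init = 1,
                        backtrack_factor = 0.5, armijo_const = 0.1,
                        n_starts = 5, seed = 1, Q = 31, n_inner = 10,
                        precondition = TRUE) {
  stopifnot(
    max_iter >= 1, tol > 0, step_init > 0,
    backtrack_factor > 0, backtrack_factor < 1,
    armijo_const > 0, armijo_const < 1,
    n_starts >= 1, Q >= 2, n_inner >= 1
  )
  structure(
    list(max_iter = as.integer(max_iter), tol = tol, step_init = step_init,
         backtrack_factor = backtrack_factor, armijo_const = armijo_const,
         n_starts = as.integer(n_starts), seed = as.integer(seed),
         Q = as.integer(Q), n_inner = as.integer(n_inner),
         precondition = isTRUE(precondition)),
    class = "latdif_controls"
  )
}

# Internal E-step: blocks[[c]] is the N x Q posterior mass over nodes for
# class c; loglik is the marginal log-likelihood at `params` (for
# `fixed_class`, the known-groups likelihood, with no mixing-probability
# factor). Returned masses sum to 1 per respondent.
.e_step <- function(params, pd, quad, fixed_class = NULL) {
  C <- n_classes(params)
  Q <- length(quad$weights)
  Ls <- cond_loglik_by_class(params, pd, quad)
  lw <- log(quad$weights)
  if (is.null(fixed_class)) {
    lnu <- ifelse(params$nu > 0, log(params$nu), -Inf)
    M <- do.call(cbind, lapply(seq_len(C), function(c) {
      sweep(Ls[[c]], 2, lw + lnu[c], "+")
    }))
    lse <- row_logsumexp(M)
    P <- exp(M - lse)
    blocks <- lapply(seq_len(C), function(c) P[, (c - 1L) * Q + seq_len(Q), drop = FALSE])
  } else {
    lse <- numeric(pd$N)
    blocks <- lapply(seq_len(C), function(c) matrix(0, pd$N, Q))
    for (c in seq_len(C)) {
      idx <- which(fixed_class == c - 1L)
      if (length(idx) == 0) next
      Mc <- sweep(Ls[[c]][idx, , drop = FALSE], 2, lw, "+")
      lse_c <- row_logsumexp(Mc)
      blocks[[c]][idx, ] <- exp(Mc - lse_c)
      lse[idx] <- lse_c
    }
  }
  cm <- vapply(blocks, rowSums, numeric(pd$N))
  if (pd$N == 1) cm <- matrix(cm, 1)
  list(blocks = blocks, class_marginal = cm, loglik = sum(lse))
}

#' E-step posterior over latent class and quadrature node
#'
#' Joint responsibilities `joint[i, k, q]` proportional to
#' `nu_k * w_q * prod_j Bern(Y_ij; p(node_kq))`, normalised per respondent
#' and computed in log space. `class_marginal` sums out the nodes.
#'
#' @param params A [latdif_params()] object.
#' @param data Responses coercible via [as_response_matrix()].
#' @param quad Quadrature rule (defaults to one built at `params`).
#' @param Q Quadrature size when `quad` is `NULL`.
#' @return List of class `latdif_posterior` with `joint`
#'   (N x n_classes x Q array), `class_marginal` (N x n_classes), `loglik`.
#' @export
e_step <- function(params, data, quad = NULL, Q = 31) {
  pd <- prep_responses(data)
  if (is.null(quad)) quad <- quad_for_params(params, Q)
  es <- .e_step(params, pd, quad)
  C <- n_classes(params)
  nq <- length(quad$weights)
  joint <- array(0, dim = c(pd$N, C, nq))
  for (c in seq_len(C)) joint[, c, ] <- es$blocks[[c]]
  structure(list(joint = joint, class_marginal = es$class_marginal,
                 loglik = es$loglik),
            class = "latdif_posterior")
}

posterior_blocks <- function(post, params = NULL) {
  if (!is.null(post$blocks)) return(post)
  C <- dim(post$joint)[2]
  blocks <- lapply(seq_len(C), function(c) post$joint[, c, , drop = TRUE])
  blocks <- lapply(blocks, function(b) if (is.matrix(b)) b else matrix(b, nrow = dim(post$joint)[1]))
  list(blocks = blocks, class_marginal = post$class_marginal, loglik = post$loglik)
}

#' Closed-form update of the class proportions
#'
#' The minimiser of the mixing-probability part of the EM surrogate under the
#' simplex constraint: the average posterior class membership.
#'
#' @param post Posterior from [e_step()].
#' @return Probability vector over classes `0..K`, summing to 1.
#' @export
update_class_probs <- function(post) {
  cm <- post$class_marginal
  colSums(cm) / nrow(cm)
}

# Sufficient statistics of the smooth surrogate F_t: per class,
# S[j, q] = sum_i r_icq * Y_ij (observed only), Ocnt[j, q] = sum_i r_icq * obs_ij.
surrogate_stats <- function(post, pd) {
  es <- posterior_blocks(post)
  lapply(es$blocks, function(b) {
    list(S = crossprod(pd$YO, b), Ocnt = crossprod(pd$O, b))
  })
}

# F_t evaluated at arbitrary trial parameters (quadrature nodes re-derived
# from the trial mu/sigma2, so the structural parameters enter smoothly).
surrogate_F <- function(params, stats, gh) {
  C <- n_classes(params)
  val <- 0
  for (c in seq_len(C)) {
    theta <- params$mu[c] + sqrt(params$sigma2[c]) * gh$z
    dd <- params$d + if (c > 1) params$delta[, c - 1L] else 0
    eta <- outer(params$a, theta) + dd
    val <- val - sum(stats[[c]]$S * eta) + sum(stats[[c]]$Ocnt * log1pexp(eta))
  }
  val
}

# Exact gradient of F_t w.r.t. (a, d, delta, mu_k, log sigma_k).
surrogate_grad <- function(params, stats, gh) {
  C <- n_classes(params)
  J <- length(params$a)
  K <- C - 1L
  ga <- numeric(J); gd <- numeric(J)
  gdelta <- matrix(0, J, K); gmu <- numeric(K); gls <- numeric(K)
  for (c in seq_len(C)) {
    sig <- sqrt(params$sigma2[c])
    theta <- params$mu[c] + sig * gh$z
    dd <- params$d + if (c > 1) params$delta[, c - 1L] else 0
    eta <- outer(params$a, theta) + dd
    W <- stats[[c]]$S - stats[[c]]$Ocnt * stats::plogis(eta)   # J x Q
    rw <- rowSums(W)
    gd <- gd - rw
    ga <- ga - as.numeric(W %*% theta)
    if (c > 1) {
      k <- c - 1L
      gdelta[, k] <- -rw
      cw <- as.numeric(crossprod(params$a, W))                 # length Q
      gmu[k] <- -sum(cw)
      gls[k] <- -sum(cw * sig * gh$z)
    }
  }
  list(a = ga, d = gd, delta = gdelta, mu = gmu, log_sigma = gls)
}

#' Gradient of the smooth surrogate
#'
#' Exact gradient of the smooth part of the EM surrogate (the expected
#' complete-data negative log-likelihood, excluding the L1 term and the
#' mixing probabilities) with respect to `a`, `d`, `delta`, the focal-class
#' means, and the focal-class log standard deviations.
#'
#' @param params Expansion-point parameters (must match those used for the
#'   E-step).
#' @param post Posterior from [e_step()].
#' @param data Responses.
#' @param quad Quadrature rule at `params` (defaults to a fresh one).
#' @return List with components `a`, `d`, `delta`, `mu`, `log_sigma`.
#' @export
grad_F <- function(params, post, data, quad = NULL) {
  pd <- prep_responses(data)
  if (is.null(quad)) quad <- quad_for_params(params, length(post$joint[1, 1, ]))
  gh <- gh_standard(length(quad$weights))
  stats <- surrogate_stats(post, pd)
  surrogate_grad(params, stats, gh)
}

#' Soft-thresholding operator
#'
#' The proximal operator of the absolute value: shrinks `z` towards zero by
#' `t` and snaps to exact zero when `|z| <= t`. This is what produces exact
#' zeros (and hence DIF-item selection) in the regularised fit.
#'
#' @param z Numeric input (vectorised).
#' @param t Nonnegative threshold.
#' @return Shrunk value(s).
#' @examples
#' soft_threshold(1, 0.3)    # 0.7
#' soft_threshold(-0.2, 0.3) # exactly 0
#' @export
soft_threshold <- function(z, t) {
  if (any(t < 0)) stop("threshold must be nonnegative", call. = FALSE)
  sign(z) * pmax(abs(z) - t, 0)
}

# Gauss-Newton diagonal curvature of F_t, used to precondition the proximal
# step (per-coordinate information: sum of posterior-weighted p(1-p) times
# the squared linear predictor derivative). Floored away from zero so steps
# stay bounded for empty classes.
surrogate_curv <- function(params, stats, gh) {
  C <- n_classes(params)
  J <- length(params$a)
  K <- C - 1L
  ha <- numeric(J); hd <- numeric(J)
  hdelta <- matrix(0, J, K); hmu <- numeric(K); hls <- numeric(K)
  for (c in seq_len(C)) {
    sig <- sqrt(params$sigma2[c])
    theta <- params$mu[c] + sig * gh$z
    dd <- params$d + if (c > 1) params$delta[, c - 1L] else 0
    eta <- outer(params$a, theta) + dd
    P <- stats::plogis(eta)
    W2 <- stats[[c]]$Ocnt * P * (1 - P)
    hd <- hd + rowSums(W2)
    ha <- ha + as.numeric(W2 %*% theta^2)
    if (c > 1) {
      k <- c - 1L
      hdelta[, k] <- rowSums(W2)
      caw <- as.numeric(crossprod(params$a^2, W2))
      hmu[k] <- sum(caw)
      hls[k] <- sum(caw * (sig * gh$z)^2)
    }
  }
  floor_h <- function(h) pmax(h, 1e-2)
  list(a = floor_h(ha), d = floor_h(hd), delta = floor_h(hdelta),
       mu = floor_h(hmu), log_sigma = floor_h(hls))
}

# Identity metric: the plain (vanilla) proximal-gradient update.
unit_metric <- function(params) {
  J <- length(params$a)
  K <- n_classes(params) - 1L
  list(a = rep(1, J), d = rep(1, J), delta = matrix(1, J, K),
       mu = rep(1, K), log_sigma = rep(1, K))
}

# One proximal step on Delta_2 in the diagonal metric `hess` at global step
# size `step`: coordinate moves step * g / h, DIF offsets soft-thresholded
# at step * lambda / h (the prox of the L1 term in that metric).
prox_step <- function(params, grad, hess, step, lambda, fixed_support = NULL) {
  out <- params
  out$a <- params$a - step * grad$a / hess$a
  out$d <- params$d - step * grad$d / hess$d
  K <- n_classes(params) - 1L
  if (K > 0) {
    out$delta <- soft_threshold(params$delta - step * grad$delta / hess$delta,
                                step * lambda / hess$delta)
    if (!is.null(fixed_support)) out$delta[!fixed_support] <- 0
    out$mu[-1] <- params$mu[-1] - step * grad$mu / hess$mu
    ls <- 0.5 * log(params$sigma2[-1]) - step * grad$log_sigma / hess$log_sigma
    out$sigma2[-1] <- exp(2 * pmin(pmax(ls, -5), 5))
  }
  out
}

# Squared step length in the preconditioning metric.
delta2_sqnorm <- function(p_new, p_old, hess) {
  K <- n_classes(p_old) - 1L
  v <- sum(hess$a * (p_new$a - p_old$a)^2) +
    sum(hess$d * (p_new$d - p_old$d)^2) +
    sum(hess$delta * (p_new$delta - p_old$delta)^2)
  if (K > 0) {
    v <- v + sum(hess$mu * (p_new$mu[-1] - p_old$mu[-1])^2) +
      sum(hess$log_sigma *
            (0.5 * log(p_new$sigma2[-1]) - 0.5 * log(p_old$sigma2[-1]))^2)
  }
  v
}

#' One proximal-gradient update of all parameters
#'
#' Takes a gradient step on the smooth surrogate for `a`, `d`, the
#' focal-class means and log standard deviations, soft-thresholds the DIF
#' offsets at `step * lambda`, and refreshes the class proportions by their
#' closed-form update. With `lambda = 0` this is a plain gradient step.
#'
#' @inheritParams grad_F
#' @param lambda Nonnegative L1 penalty weight.
#' @param step Positive step size.
#' @param fixed_support Optional logical J x K matrix; offsets outside the
#'   support are held at zero.
#' @return Updated [latdif_params()].
#' @export
proximal_update <- function(params, post, data, quad = NULL, lambda = 0,
                            step = 1, fixed_support = NULL) {
  stopifnot(step > 0, lambda >= 0)
  pd <- prep_responses(data)
  if (is.null(quad)) quad <- quad_for_params(params, dim(post$joint)[3])
  gh <- gh_standard(length(quad$weights))
  stats <- surrogate_stats(post, pd)
  grad <- surrogate_grad(params, stats, gh)
  out <- prox_step(params, grad, unit_metric(params), step, lambda,
                   fixed_support)
  out$nu <- update_class_probs(post)
  validate_params(out)
}

# Backtracking line search for the proximal-gradient step on the surrogate
# h = F_t + lambda * ||delta||_1. Accepts the largest step (halving from
# step_init) giving sufficient decrease; flags stationarity if the step
# underflows without decrease.
.line_search <- function(params, stats, gh, lambda, step_init, controls,
                         fixed_support = NULL) {
  F_old <- surrogate_F(params, stats, gh)
  h_old <- F_old + lambda * sum(abs(params$delta))
  grad <- surrogate_grad(params, stats, gh)
  hess <- if (controls$precondition) surrogate_curv(params, stats, gh) else
    unit_metric(params)
  step <- step_init
  repeat {
    cand <- prox_step(params, grad, hess, step, lambda, fixed_support)
    sq <- delta2_sqnorm(cand, params, hess)
    if (sq == 0) {
      return(list(step = step, params = params, stationary = TRUE, h = h_old))
    }
    h_new <- surrogate_F(cand, stats, gh) + lambda * sum(abs(cand$delta))
    if (is.finite(h_new) &&
        h_new <= h_old - controls$armijo_const * sq / (2 * step)) {
      return(list(step = step, params = cand, stationary = FALSE, h = h_new))
    }
    step <- step * controls$backtrack_factor
    if (step < 1e-12) {
      return(list(step = step, params = params, stationary = TRUE, h = h_old))
    }
  }
}

#' Line-searched proximal-gradient step
#'
#' Backtracking line search guaranteeing sufficient decrease of the
#' surrogate-plus-penalty; returns the old parameters flagged stationary if
#' no step down to 1e-12 decreases it.
#'
#' @inheritParams proximal_update
#' @param step_init Initial trial step.
#' @param controls [em_controls()].
#' @return List with `step`, `params` (class proportions untouched), and
#'   `stationary`.
#' @export
line_search <- function(params, post, data, quad = NULL, lambda = 0,
                        step_init = 1, controls = em_controls(),
                        fixed_support = NULL) {
  pd <- prep_responses(data)
  if (is.null(quad)) quad <- quad_for_params(params, controls$Q)
  gh <- gh_standard(length(quad$weights))
  stats <- surrogate_stats(post, pd)
  ls <- .line_search(params, stats, gh, lambda, step_init, controls, fixed_support)
  ls[c("step", "params", "stationary")]
}

# Classification-based start: cluster respondents on their residuals from a
# single-class 2-PL fit and seed the focal classes from the smaller clusters,
# with initial DIF offsets at (shrunk) between-cluster item logit contrasts.
# Standard practice for mixture IRT, where zero-DIF starts tend to separate
# classes on ability rather than on the DIF pattern.
kmeans_init <- function(pd, K, base_params, seed = 1) {
  quad <- quad_for_params(base_params, 21)
  theta_hat <- {
    es <- .e_step(base_params, pd, quad)
    as.numeric(es$blocks[[1]] %*% quad$nodes[, 1])
  }
  phat <- stats::plogis(outer(theta_hat, base_params$a) +
                          rep(base_params$d, each = pd$N))
  resid <- (pd$Y - phat) * pd$O
  set.seed(seed)
  km <- tryCatch(stats::kmeans(resid, centers = K + 1L, nstart = 5),
                 error = function(e) NULL)
  if (is.null(km)) return(init_params(pd, K))
  ord <- order(tabulate(km$cluster, K + 1L), decreasing = TRUE)
  cluster <- match(km$cluster, ord)    # 1 = largest cluster = reference
  item_logit <- function(idx) {
    pbar <- (colSums(pd$YO[idx, , drop = FALSE]) + 0.5) /
      (colSums(pd$O[idx, , drop = FALSE]) + 1)
    stats::qlogis(pmin(pmax(pbar, 0.02), 0.98))
  }
  ref_logit <- item_logit(cluster == 1)
  delta <- matrix(0, pd$J, K)
  for (k in seq_len(K)) {
    delta[, k] <- pmin(pmax(0.5 * (item_logit(cluster == k + 1) - ref_logit),
                            -2), 2)
  }
  nu <- pmax(tabulate(cluster, K + 1L) / pd$N, 0.02)
  latdif_params(a = base_params$a, d = base_params$d, delta = delta,
                nu = nu / sum(nu), mu = c(0, rep(0.1, K)),
                sigma2 = rep(1, K + 1))
}

# Default starting values: unit slopes, intercepts at the observed item
# logits, zero DIF, uniform mixing, focal means spread over [0.25, 1].
# Multistarts jitter a/d/mu to break the label symmetry of the zero-DIF start.
init_params <- function(pd, K, jitter_sd = 0) {
  pbar <- colSums(pd$YO) / pmax(colSums(pd$O), 1)
  d0 <- pmin(pmax(stats::qlogis(pmin(pmax(pbar, 0.05), 0.95)), -3), 3)
  a0 <- rep(1, pd$J)
  mu <- c(0, if (K > 0) seq(0.25, 1, length.out = K))
  if (jitter_sd > 0) {
    a0 <- pmax(a0 + stats::rnorm(pd$J, 0, jitter_sd), 0.2)
    d0 <- d0 + stats::rnorm(pd$J, 0, jitter_sd)
    if (K > 0) mu[-1] <- mu[-1] + stats::rnorm(K, 0, jitter_sd)
  }
  latdif_params(a = a0, d = d0, delta = matrix(0, pd$J, K),
                nu = rep(1 / (K + 1), K + 1), mu = mu,
                sigma2 = rep(1, K + 1))
}

#' Fit the L1-regularised mixture 2-PL by proximal-gradient EM
#'
#' Minimises `-log L + lambda * sum(|delta|)` by a generalized EM algorithm:
#' each iteration runs an E-step, the closed-form class-proportion update,
#' and `n_inner` line-searched proximal-gradient steps on the remaining
#' parameters (soft-thresholding the DIF offsets, plain gradient steps for
#' the rest). The penalised objective is non-increasing across iterations.
#' With `fixed_support` and `lambda = 0` this computes the constrained
#' maximum likelihood refit of a selected model; with `fixed_class` it
#' maximises the known-groups (oracle) likelihood, in which the class
#' memberships are data and the mixing proportions drop out.
#'
#' @param data Responses coercible via [as_response_matrix()].
#' @param K Number of focal latent classes (`K = 0` gives a plain 2-PL).
#' @param lambda Nonnegative L1 penalty weight.
#' @param controls [em_controls()].
#' @param init Optional [latdif_params()] starting value (suppresses
#'   multistarts).
#' @param fixed_support Optional logical J x K matrix; DIF offsets outside it
#'   are constrained to zero.
#' @param fixed_class Optional integer vector of known class memberships in
#'   `0..K` (oracle fitting).
#' @return A `latdif_fit`: `params`, `objective_trace`, `loglik`
#'   (unpenalised, at convergence), `support`, `converged`, `n_iter`,
#'   `lambda`.
#' @export
fit_regularized <- function(data, K, lambda = 0, controls = em_controls(),
                            init = NULL, fixed_support = NULL,
                            fixed_class = NULL) {
  stopifnot(K >= 0, lambda >= 0)
  pd <- prep_responses(data)
  gh <- gh_standard(controls$Q)
  if (!is.null(fixed_support)) {
    fixed_support <- matrix(as.logical(fixed_support), pd$J, K)
  }
  if (!is.null(fixed_class)) {
    stopifnot(length(fixed_class) == pd$N, all(fixed_class %in% 0:K))
  }

  starts <- if (!is.null(init)) {
    list(validate_params(init))
  } else {
    st <- lapply(seq_len(controls$n_starts), function(s) {
      if (s > 1) set.seed(controls$seed + s)
      p0 <- init_params(pd, K, jitter_sd = if (s > 1) 0.2 else 0)
      if (!is.null(fixed_class)) {
        p0$nu <- as.numeric(table(factor(fixed_class, levels = 0:K))) / pd$N
      }
      p0
    })
    if (K > 0 && is.null(fixed_class) && is.null(fixed_support) &&
        controls$n_starts > 1) {
      base <- .em_run(init_params(pd, 0L), pd, 0L, 0,
                      utils::modifyList(controls, list(max_iter = 200L)),
                      gh, NULL, NULL)$params
      st[[2]] <- kmeans_init(pd, K, base, seed = controls$seed)
    }
    st
  }

  best <- NULL
  for (p0 in starts) {
    fit <- .em_run(p0, pd, K, lambda, controls, gh, fixed_support, fixed_class)
    if (is.null(best) || utils::tail(fit$objective_trace, 1) <
        utils::tail(best$objective_trace, 1)) {
      best <- fit
    }
  }
  best$lambda <- lambda
  best$controls <- controls
  best$support <- best$params$delta != 0
  class(best) <- "latdif_fit"
  best
}

.em_run <- function(params, pd, K, lambda, controls, gh, fixed_support,
                    fixed_class) {
  if (!is.null(fixed_support)) params$delta[!fixed_support] <- 0
  trace <- numeric(0)
  obj_prev <- Inf
  step_ws <- controls$step_init
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    quad <- make_quadrature(params$mu, params$sigma2, controls$Q)
    es <- .e_step(params, pd, quad, fixed_class)
    obj <- -es$loglik + lambda * sum(abs(params$delta))
    trace <- c(trace, obj)
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) / (abs(obj_prev) + 1e-10) < controls$tol) {
      converged <- TRUE
      break
    }
    if (iter >= controls$max_iter) break
    obj_prev <- obj
    if (is.null(fixed_class)) params$nu <- update_class_probs(es)
    stats <- surrogate_stats(es, pd)
    stationary <- FALSE
    for (m in seq_len(controls$n_inner)) {
      ls <- .line_search(params, stats, gh, lambda, step_ws, controls,
                         fixed_support)
      decrease <- if (m == 1) Inf else h_prev - ls$h
      h_prev <- ls$h
      params <- ls$params
      step_ws <- min(ls$step * 2, 4)
      if (ls$stationary) { stationary <- TRUE; break }
      # stop polishing the surrogate once per-step progress is negligible
      if (is.finite(decrease) && decrease < 0.01 * controls$tol * abs(ls$h)) break
    }
    if (stationary && iter > 1) {
      # surrogate stationary: one more E-step records the final objective
      quad <- make_quadrature(params$mu, params$sigma2, controls$Q)
      es <- .e_step(params, pd, quad, fixed_class)
      obj <- -es$loglik + lambda * sum(abs(params$delta))
      trace <- c(trace, obj)
      converged <- TRUE
      break
    }
  }
  list(params = params, objective_trace = trace, loglik = es$loglik,
       converged = converged, n_iter = iter)
}

#' @export
print.latdif_fit <- function(x, ...) {
  K <- n_classes(x$params) - 1L
  cat(sprintf(
    "<latdif_fit> K = %d, lambda = %.4g, loglik = %.2f, %s in %d iterations\n",
    K, x$lambda, x$loglik, if (x$converged) "converged" else "NOT converged",
    x$n_iter
  ))
  if (K > 0) {
    cat("  DIF items:", sum(rowSums(x$params$delta != 0) > 0), "of",
        length(x$params$a), "\n")
  }
  invisible(x)
}

#' Serialise / deserialise a fitted model as JSON
#'
#' Stores the parameters, objective trace, support pattern, convergence
#' diagnostics, and a controls echo for exact reloading.
#'
#' @param fit A `latdif_fit`.
#' @param path File path.
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(
    list(params = params_to_list(fit$params),
         objective_trace = fit$objective_trace,
         loglik = fit$loglik,
         support = unclass(fit$support) * 1L,
         converged = fit$converged, n_iter = fit$n_iter,
         lambda = fit$lambda, controls = unclass(fit$controls)),
    path, digits = NA, auto_unbox = FALSE
  )
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- params_from_list(x$params)
  structure(
    list(params = params,
         objective_trace = as.numeric(x$objective_trace),
         loglik = as.numeric(x$loglik),
         support = params$delta != 0,
         converged = as.logical(x$converged), n_iter = as.integer(x$n_iter),
         lambda = as.numeric(x$lambda),
         controls = do.call(em_controls, as.list(x$controls))),
    class = "latdif_fit"
  )
}

# --- direct maximum-likelihood polishing -----------------------------------
#
# EM converges linearly and crawls along the weakly identified directions of
# these mixtures (mean-shift/offset tradeoffs). Constrained refits feed BIC
# comparisons with margins of a few nats, so after EM we polish them by
# quasi-Newton (BFGS) on the marginal log-likelihood itself, using the exact
# score obtained from the E-step responsibilities (Fisher identity).

pack_params <- function(params, support, with_nu) {
  K <- n_classes(params) - 1L
  v <- c(params$a, params$d)
  if (K > 0) {
    v <- c(v, params$delta[support],
           params$mu[-1], 0.5 * log(params$sigma2[-1]))
    if (with_nu) v <- c(v, log(pmax(params$nu[-1], 1e-12) / pmax(params$nu[1], 1e-12)))
  }
  v
}

unpack_params <- function(v, template, support, with_nu) {
  J <- length(template$a)
  K <- n_classes(template) - 1L
  p <- template
  p$a <- v[seq_len(J)]
  p$d <- v[J + seq_len(J)]
  pos <- 2L * J
  if (K > 0) {
    ns <- sum(support)
    p$delta <- matrix(0, J, K)
    p$delta[support] <- v[pos + seq_len(ns)]; pos <- pos + ns
    p$mu[-1] <- v[pos + seq_len(K)]; pos <- pos + K
    p$sigma2[-1] <- exp(2 * pmin(pmax(v[pos + seq_len(K)], -5), 5)); pos <- pos + K
    if (with_nu) {
      lg <- v[pos + seq_len(K)]
      e <- exp(c(0, lg) - max(0, lg))
      p$nu <- e / sum(e)
    }
  }
  p
}

ml_polish <- function(params, pd, controls, fixed_support = NULL,
                      fixed_class = NULL, maxit = 200) {
  K <- n_classes(params) - 1L
  support <- if (is.null(fixed_support)) matrix(TRUE, pd$J, K) else fixed_support
  with_nu <- is.null(fixed_class) && K > 0
  gh <- gh_standard(controls$Q)

  cache <- new.env(parent = emptyenv())
  evaluate <- function(v) {
    key <- paste(v, collapse = ",")
    if (identical(cache$key, key)) return(cache$val)
    p <- unpack_params(v, params, support, with_nu)
    quad <- make_quadrature(p$mu, p$sigma2, controls$Q)
    es <- .e_step(p, pd, quad, fixed_class)
    g <- surrogate_grad(p, surrogate_stats(es, pd), gh)
    gv <- c(g$a, g$d)
    if (K > 0) {
      gv <- c(gv, g$delta[support], g$mu, g$log_sigma)
      if (with_nu) {
        cm <- colSums(es$class_marginal)
        # d(-ll)/d(logit nu_k): softmax chain through the simplex
        gv <- c(gv, -(cm[-1] - sum(cm) * p$nu[-1]))
      }
    }
    cache$key <- key
    cache$val <- list(value = -es$loglik, grad = gv)
    cache$val
  }
  v0 <- pack_params(params, support, with_nu)
  opt <- tryCatch(
    stats::optim(v0, fn = function(v) evaluate(v)$value,
                 gr = function(v) evaluate(v)$grad,
                 method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value)) {
    return(list(params = params, loglik = NA_real_, converged = FALSE))
  }
  p <- unpack_params(opt$par, params, support, with_nu)
  # declare convergence on optimiser success or a small relative score norm
  score_ok <- max(abs(evaluate(opt$par)$grad)) < 1e-3 * (1 + abs(opt$value))
  list(params = validate_params(p), loglik = -opt$value,
       converged = opt$convergence == 0 || score_ok)
}
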