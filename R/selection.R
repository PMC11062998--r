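#' Number of free parameters of a (constrained) model
#'
#' Counts `2J` item parameters, `K` free mixing proportions, `2K` focal-class
#' means and variances, plus the DIF offsets left free by the support
#' pattern. Used by the BIC.
#'
#' @param params A [latdif_params()] object.
#' @param support Logical J x K matrix of free DIF offsets (defaults to the
#'   nonzero pattern of `params$delta`).
#' @return Integer count.
#' @export
count_free_parameters <- function(params, support = NULL) {
  J <- length(params$a)
  K <- n_classes(params) - 1L
  if (is.null(support)) support <- params$delta != 0
  if (!all(dim(as.matrix(support)) == c(J, K))) {
    stop("support dimensions must match delta", call. = FALSE)
  }
  2L * J + K + 2L * K + sum(support)
}

#' Bayesian Information Criterion
#'
#' `-2 * loglik + log(N) * n_free`, computed on the constrained maximum
#' likelihood refit (never on the penalised objective).
#'
#' @param loglik Maximised log-likelihood.
#' @param n_free Number of free parameters.
#' @param N Number of respondents.
#' @return The BIC value.
#' @export
bic <- function(loglik, n_free, N) {
  stopifnot(N >= 1)
  -2 * loglik + log(N) * n_free
}

# Smallest lambda (up to a factor of 2) at which the regularised fit has an
# all-zero DIF matrix, found by a doubling search. The search starts from
# the marginal score bound at the no-DIF MLE (by the Fisher identity the
# marginal score equals the surrogate gradient at the expansion point);
# doubling then accounts for other likelihood basins in which nonzero
# offsets survive larger penalties.
lambda_max_search <- function(null_fit, data, controls, fixed_class = NULL,
                              max_doublings = 12) {
  params <- null_fit$params
  pd <- prep_responses(data)
  quad <- quad_for_params(params, controls$Q)
  es <- .e_step(params, pd, quad, fixed_class)
  g <- surrogate_grad(params, surrogate_stats(es, pd), gh_standard(controls$Q))
  lam <- 1.1 * max(abs(g$delta), 1e-8)
  sctl <- controls
  sctl$max_iter <- min(controls$max_iter, 150L)
  fit <- fit_regularized(data, K = ncol(params$delta), lambda = lam,
                         controls = sctl, fixed_class = fixed_class)
  # continue warm from the previous solution so the search tracks the basin
  # in which offsets survive the longest, not just the no-DIF basin
  for (i in seq_len(max_doublings)) {
    if (all(fit$params$delta == 0)) break
    lam <- 2 * lam
    fit <- fit_regularized(data, K = ncol(params$delta), lambda = lam,
                           controls = sctl, init = fit$params,
                           fixed_class = fixed_class)
  }
  lam
}

#' Default tuning-parameter grid
#'
#' `M` log-spaced values descending from the smallest `lambda` at which the
#' regularised fit has all DIF offsets zero down to 1/100 of it, ordered for
#' warm-started path fitting.
#'
#' @param data Responses.
#' @param K Number of focal classes.
#' @param M Grid size (at least 2).
#' @param controls [em_controls()].
#' @return Strictly decreasing numeric vector of length `M`.
#' @export
default_lambda_grid <- function(data, K, M = 10, controls = em_controls()) {
  stopifnot(M >= 2)
  null_fit <- fit_regularized(data, K, lambda = 0, controls = controls,
                              fixed_support = matrix(FALSE, ncol(as_response_matrix(data)$values), K))
  lmax <- lambda_max_search(null_fit, data, controls)
  exp(seq(log(lmax), log(lmax / 100), length.out = M))
}

#' Regularised estimation with BIC tuning-parameter selection
#'
#' The full selection pipeline: fit the no-DIF model, build (or take) a
#' descending `lambda` grid, solve the L1-penalised problem along the grid
#' with warm starts, refit each selected support by constrained maximum
#' likelihood with `lambda = 0`, score the refits by BIC, and return the
#' refit minimising it (ties broken towards the smallest `lambda`, i.e. the
#' model found last on the descending path). An item is flagged as a DIF
#' item when any of its refitted class offsets is nonzero.
#'
#' @param data Responses coercible via [as_response_matrix()].
#' @param K Number of focal classes (`K = 0` reduces to a plain 2-PL fit).
#' @param grid Optional decreasing `lambda` grid; built automatically when
#'   `NULL`.
#' @param controls [em_controls()].
#' @param M Grid size when `grid` is `NULL`.
#' @param fixed_class Optional known class memberships (oracle variant: the
#'   mixing proportions drop out of the likelihood and the parameter count).
#' @return A `latdif_selection`: `lambda_grid`, `bic_per_lambda`,
#'   `best_lambda`, `final_fit` (the refit), `dif_items`, and a `path`
#'   tibble (lambda, BIC, nonzero offsets, convergence).
#' @export
select_lambda <- function(data, K, grid = NULL, controls = em_controls(),
                          M = 10, fixed_class = NULL) {
  data <- as_response_matrix(data)
  pd <- prep_responses(data)
  oracle <- !is.null(fixed_class)

  if (K == 0) {
    fit <- fit_regularized(data, 0, lambda = 0, controls = controls,
                           fixed_class = fixed_class)
    b <- bic(fit$loglik, 2L * pd$J, pd$N)
    return(structure(
      list(lambda_grid = 0, bic_per_lambda = b, best_lambda = 0,
           final_fit = fit, dif_items = rep(FALSE, pd$J),
           path = tibble::tibble(lambda = 0, bic = b, n_nonzero = 0L,
                                 converged = fit$converged),
           K = 0L, oracle = oracle),
      class = "latdif_selection"))
  }

  null_fit <- fit_regularized(data, K, lambda = 0, controls = controls,
                              fixed_support = matrix(FALSE, pd$J, K),
                              fixed_class = fixed_class)
  if (is.null(grid)) {
    lmax <- lambda_max_search(null_fit, data, controls, fixed_class)
    grid <- exp(seq(log(lmax), log(lmax / 100), length.out = M))
  }
  grid <- sort(grid, decreasing = TRUE)

  nfree_adj <- if (oracle) -K else 0L   # no mixing proportions in the oracle
  M_len <- length(grid)

  # Path fits only provide candidate supports and warm starts, so they get a
  # hard iteration cap; the BIC-bearing refits below run to full precision.
  pctl <- controls
  pctl$max_iter <- min(controls$max_iter, 150L)

  # Two warm-started passes over the grid. The descending pass starts at the
  # all-zero (no-DIF) fit; the ascending pass starts at the smallest lambda
  # from a fresh multistart (including the residual-clustering start), which
  # seeds the latent classes from the DIF pattern rather than from ability.
  # Per lambda the pass with the better penalised objective wins; this
  # guards the path against local optima in which the classes separate on
  # ability alone and absorb the DIF signal.
  desc <- vector("list", M_len)
  warm <- null_fit$params
  for (m in seq_len(M_len)) {
    desc[[m]] <- fit_regularized(data, K, lambda = grid[m],
                                 controls = pctl, init = warm,
                                 fixed_class = fixed_class)
    warm <- desc[[m]]$params
  }
  asc <- vector("list", M_len)
  asc[[M_len]] <- fit_regularized(data, K, lambda = grid[M_len],
                                  controls = pctl,
                                  fixed_class = fixed_class)
  if (M_len > 1) {
    for (m in rev(seq_len(M_len - 1))) {
      asc[[m]] <- fit_regularized(data, K, lambda = grid[m],
                                  controls = pctl,
                                  init = asc[[m + 1]]$params,
                                  fixed_class = fixed_class)
    }
  }
  # Refits are compared at BIC margins of a few nats, so after a capped EM
  # warm-up each refit is polished by BFGS on the marginal log-likelihood
  # (see ml_polish); EM alone crawls along the weakly identified directions.
  rctl <- controls
  rctl$max_iter <- min(controls$max_iter, 60L)
  refit_constrained <- function(init_params, supp) {
    fit_regularized(data, K, lambda = 0, controls = rctl,
                    init = init_params, fixed_support = supp,
                    fixed_class = fixed_class)
  }

  # Candidate supports come from both passes at every lambda; each is
  # refitted by constrained ML and scored by BIC, so basin disagreements
  # between the passes are settled by the refit likelihood itself.
  cand_fits <- c(desc, asc)
  cand_lambda <- c(grid, grid)
  supp_list <- lapply(cand_fits, function(f) f$params$delta != 0)
  keys <- vapply(supp_list, function(s) paste0("s", paste(which(s), collapse = ",")),
                 character(1))

  # Constrained refits, largest support first, each warm-started both from
  # its own penalised fit and from the next-denser refit projected onto the
  # support (out-of-support offsets zeroed). The projection keeps the refit
  # sequence in one likelihood basin as the support shrinks, so BIC
  # differences reflect the support and not basin jumps.
  refit_cache <- new.env(parent = emptyenv())
  prev_refit <- NULL
  for (m in order(vapply(supp_list, sum, integer(1)), decreasing = TRUE)) {
    key <- keys[m]
    if (is.null(refit_cache[[key]])) {
      supp <- supp_list[[m]]
      cand <- refit_constrained(cand_fits[[m]]$params, supp)
      if (!is.null(prev_refit)) {
        proj <- prev_refit$params
        proj$delta[!supp] <- 0
        cand2 <- refit_constrained(proj, supp)
        if (cand2$loglik > cand$loglik) cand <- cand2
      }
      refit_cache[[key]] <- cand
    }
    prev_refit <- refit_cache[[key]]
  }
  # second pass, smallest support first: a refit warm-started from the best
  # refit of a nested (subset) support can only improve; this enforces
  # likelihood coherence across nested supports
  uniq <- !duplicated(keys)
  ord_asc <- order(vapply(supp_list, sum, integer(1)))
  ord_asc <- ord_asc[uniq[ord_asc]]
  for (m in ord_asc) {
    supp <- supp_list[[m]]
    cur <- refit_cache[[keys[m]]]
    best_sub <- NULL
    for (m2 in ord_asc) {
      if (identical(keys[m2], keys[m])) break
      if (all(supp_list[[m2]] <= supp)) {
        r2 <- refit_cache[[keys[m2]]]
        if (is.null(best_sub) || r2$loglik > best_sub$loglik) best_sub <- r2
      }
    }
    if (!is.null(best_sub) && best_sub$loglik > cur$loglik) {
      cand <- refit_constrained(best_sub$params, supp)
      if (cand$loglik > cur$loglik) refit_cache[[keys[m]]] <- cand
    }
  }
  # final pass, largest support first again: project each denser refit onto
  # the sparser supports so that late improvements of shared parameters also
  # reach the sparse refits (otherwise extra offsets get credited with
  # optimisation progress that is really due to a, d, mu, sigma)
  ord_desc <- rev(ord_asc)
  for (m in ord_desc) {
    supp <- supp_list[[m]]
    cur <- refit_cache[[keys[m]]]
    best_sup <- NULL
    for (m2 in ord_desc) {
      if (identical(keys[m2], keys[m])) break
      if (all(supp_list[[m2]] >= supp)) {
        r2 <- refit_cache[[keys[m2]]]
        if (is.null(best_sup) || r2$loglik > best_sup$loglik) best_sup <- r2
      }
    }
    if (!is.null(best_sup)) {
      proj <- best_sup$params
      proj$delta[!supp] <- 0
      cand <- refit_constrained(proj, supp)
      if (cand$loglik > cur$loglik) refit_cache[[keys[m]]] <- cand
    }
  }
  # one BFGS polish per unique support near the BIC frontier (candidates far
  # above the running minimum cannot win, so EM precision suffices there)
  uniq_idx <- which(!duplicated(keys))
  pre_bic <- vapply(uniq_idx, function(m) {
    f <- refit_cache[[keys[m]]]
    bic(f$loglik, count_free_parameters(f$params, supp_list[[m]]) + nfree_adj,
        pd$N)
  }, numeric(1))
  for (m in uniq_idx[pre_bic <= min(pre_bic) + 60]) {
    key <- keys[m]
    f <- refit_cache[[key]]
    pol <- ml_polish(f$params, pd, controls,
                     fixed_support = supp_list[[m]],
                     fixed_class = fixed_class)
    if (is.finite(pol$loglik)) {
      f$converged <- f$converged || isTRUE(pol$converged)
      if (pol$loglik > f$loglik) {
        f$params <- pol$params
        f$loglik <- pol$loglik
        f$objective_trace <- c(f$objective_trace, -pol$loglik)
        f$support <- f$params$delta != 0
      }
      refit_cache[[key]] <- f
    }
  }
  refits <- lapply(keys, function(k) refit_cache[[k]])
  nnz_cand <- vapply(supp_list, sum, integer(1))
  conv_cand <- vapply(refits, function(f) f$converged, logical(1))
  bic_cand <- vapply(seq_along(cand_fits), function(m) {
    bic(refits[[m]]$loglik,
        count_free_parameters(refits[[m]]$params, supp_list[[m]]) + nfree_adj,
        pd$N)
  }, numeric(1))

  # collapse to one row per lambda (minimum BIC over the two passes)
  pick <- vapply(seq_len(M_len), function(m) {
    idx <- c(m, m + M_len)
    idx[which.min(bic_cand[idx])]
  }, integer(1))
  bics <- bic_cand[pick]
  nnz <- nnz_cand[pick]
  conv <- conv_cand[pick]
  refits <- refits[pick]
  if (!any(conv)) {
    stop("no lambda produced a converged fit; BIC path: ",
         paste(sprintf("lambda=%.3g bic=%.1f", grid, bics), collapse = "; "),
         call. = FALSE)
  }
  cand <- which(bics == min(bics))
  best_m <- cand[which.min(grid[cand])]
  final <- refits[[best_m]]
  structure(
    list(lambda_grid = grid, bic_per_lambda = bics,
         best_lambda = grid[best_m], final_fit = final,
         dif_items = rowSums(final$params$delta != 0) > 0,
         path = tibble::tibble(lambda = grid, bic = bics, n_nonzero = nnz,
                               converged = conv),
         K = as.integer(K), oracle = oracle),
    class = "latdif_selection")
}

#' @export
print.latdif_selection <- function(x, ...) {
  cat(sprintf(
    "<latdif_selection> K = %d%s: best lambda = %.4g (BIC = %.1f), %d DIF item(s)\n",
    x$K, if (isTRUE(x$oracle)) " (oracle)" else "", x$best_lambda,
    min(x$bic_per_lambda), sum(x$dif_items)
  ))
  print(x$path)
  invisible(x)
}

#' Select the number of latent classes by BIC
#'
#' Runs the full tuning-parameter selection pipeline for each candidate `K`
#' and returns the one whose selected-and-refitted model minimises the BIC
#' (ties broken towards the smaller, more parsimonious `K`).
#'
#' @param data Responses.
#' @param K_candidates Distinct nonnegative integers.
#' @param controls [em_controls()].
#' @param M Grid size per K.
#' @return List with `K_star`, `bic_per_K` tibble, and the per-K
#'   `latdif_selection` objects in `selections`.
#' @export
select_K <- function(data, K_candidates = 0:2, controls = em_controls(),
                     M = 10) {
  stopifnot(all(K_candidates >= 0), !anyDuplicated(K_candidates))
  K_candidates <- sort(K_candidates)
  sels <- lapply(K_candidates, function(K) {
    tryCatch(select_lambda(data, K, controls = controls, M = M),
             error = function(e) {
               stop("selection failed for K = ", K, ": ", conditionMessage(e),
                    call. = FALSE)
             })
  })
  bics <- vapply(sels, function(s) min(s$bic_per_lambda), numeric(1))
  K_star <- K_candidates[which.min(bics)]   # which.min takes first = smaller K
  list(K_star = as.integer(K_star),
       bic_per_K = tibble::tibble(K = as.integer(K_candidates), bic = bics),
       selections = stats::setNames(sels, paste0("K", K_candidates)))
}
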