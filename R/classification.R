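#' Posterior latent-class probabilities for each respondent
#'
#' Empirical-Bayes posterior `P(class = k | responses)` under the supplied
#' parameter estimates, with the ability integrated out by quadrature.
#'
#' @inheritParams log_marginal_likelihood
#' @return N x (K + 1) matrix of posterior probabilities (rows sum to 1).
#' @export
posterior_class_probs <- function(params, data, quad = NULL, Q = 31) {
  pd <- prep_responses(data)
  if (is.null(quad)) quad <- quad_for_params(params, Q)
  .e_step(params, pd, quad)$class_marginal
}

#' MAP class assignment
#'
#' Row-wise most probable class (0-based); ties go to the smallest class
#' index.
#'
#' @param posterior N x (K + 1) matrix of class probabilities.
#' @return Integer vector of classes in `0..K`.
#' @export
map_classify <- function(posterior) {
  posterior <- as.matrix(posterior)
  max.col(posterior, ties.method = "first") - 1L
}

#' Classify respondents under a fitted model
#'
#' Convenience wrapper returning a tibble with posterior class probabilities
#' and the MAP class per respondent.
#'
#' @param fit A `latdif_fit` (or a [latdif_params()] object).
#' @param data Responses.
#' @param Q Quadrature size.
#' @return Tibble with `respondent`, one `p_class*` column per class, and
#'   `map_class`.
#' @export
classify_respondents <- function(fit, data, Q = 31) {
  params <- if (inherits(fit, "latdif_fit")) fit$params else fit
  post <- posterior_class_probs(params, data, Q = Q)
  colnames(post) <- paste0("p_class", seq_len(ncol(post)) - 1L)
  tibble::as_tibble(post) |>
    dplyr::mutate(respondent = dplyr::row_number(), .before = 1) |>
    dplyr::mutate(map_class = map_classify(post))
}

#' Resolve focal-class labels
#'
#' Focal classes are exchangeable, so fitted labels are arbitrary. With a
#' truth vector available (simulation), returns the permutation of `1..K`
#' minimising the MAP classification error over all `K!` relabelings;
#' otherwise orders classes by the stated convention (ascending mixing
#' proportion by default, mirroring the "larger class gets the higher label"
#' convention, or ascending mean).
#'
#' @param fit A `latdif_fit`, or a [latdif_params()] object.
#' @param rule `"nu"` (ascending proportion) or `"mu"` (ascending mean).
#' @param data,truth Optional responses and true class memberships; when both
#'   are given the minimum-error matching is used instead of the ordering rule.
#' @return Permutation `perm` of `1..K`: relabelled class `k` is fitted class
#'   `perm[k]` (apply with [permute_classes()]).
#' @export
resolve_labels <- function(fit, rule = c("nu", "mu"), data = NULL,
                           truth = NULL) {
  params <- if (inherits(fit, "latdif_fit")) fit$params else fit
  K <- n_classes(params) - 1L
  stopifnot(K >= 1)
  if (K == 1) return(1L)
  if (!is.null(truth) && !is.null(data)) {
    post <- posterior_class_probs(params, data)
    perms <- all_perms(K)
    map <- map_classify(post)
    errs <- vapply(perms, function(p) {
      mean(relabel_assignments(map, p) != truth)
    }, numeric(1))
    return(perms[[which.min(errs)]])
  }
  rule <- match.arg(rule)
  key <- if (rule == "nu") params$nu[-1] else params$mu[-1]
  order(key)
}

all_perms <- function(K) {
  if (K == 1) return(list(1L))
  sub <- all_perms(K - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(K - 1L)) {
      out[[length(out) + 1L]] <- append(p, K, after = pos)
    }
  }
  out
}

# Map fitted MAP labels to resolved labels: fitted class perm[k] becomes k.
relabel_assignments <- function(map_class, perm) {
  K <- length(perm)
  new_label <- integer(K + 1)
  new_label[1 + perm] <- seq_len(K)
  new_label[1] <- 0L
  new_label[1 + map_class]
}

#' MAP classification error
#'
#' Fraction of respondents whose (label-resolved) MAP class disagrees with
#' the truth.
#'
#' @param map_class,truth Integer class vectors of equal length.
#' @return Error rate in `[0, 1]`.
#' @export
classification_error <- function(map_class, truth) {
  if (length(map_class) != length(truth)) {
    stop("map_class and truth must have equal length", call. = FALSE)
  }
  mean(map_class != truth)
}

#' One-vs-rest AUC from posterior class probabilities
#'
#' Mann-Whitney estimate of the probability that a random true member of the
#' class receives a higher posterior probability than a random non-member;
#' ties count one half.
#'
#' @param scores Posterior probabilities for the class.
#' @param truth_indicator Binary membership indicator.
#' @return AUC in `[0, 1]`.
#' @export
auc_one_vs_rest <- function(scores, truth_indicator) {
  stopifnot(length(scores) == length(truth_indicator))
  truth_indicator <- as.integer(truth_indicator != 0)
  n1 <- sum(truth_indicator)
  n0 <- length(truth_indicator) - n1
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: need at least one member and one non-member",
         call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[truth_indicator == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
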