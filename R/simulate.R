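#' Simulation scenario configuration
#'
#' Describes one data-generating condition: sample size, test length, latent
#' class structure, and the DIF layout. True item parameters are drawn once
#' per scenario (from `seed`) and held fixed across replicates; responses are
#' redrawn per replicate.
#'
#' @param N Respondents.
#' @param J Items.
#' @param class_proportions Probability vector over classes `0..K`
#'   (reference first); its length determines `K`.
#' @param class_means,class_variances Ability means/variances per class
#'   (reference fixed at 0 and 1).
#' @param dif_items_per_class List of item index vectors, one per focal
#'   class, carrying nonzero DIF offsets.
#' @param dif_ranges List of `c(low, high)` uniform ranges for the nonzero
#'   offsets, one per focal class.
#' @param a_range,d_range Uniform ranges for discriminations and intercepts.
#' @param B Default replication count.
#' @param seed Scenario seed: fixes the true parameters; replicate `b` uses
#'   stream seed `seed + b`.
#' @param name Optional label.
#' @return A list of class `latdif_scenario`.
#' @export
scenario_config <- function(N, J, class_proportions,
                            class_means, class_variances,
                            dif_items_per_class, dif_ranges,
                            a_range = c(0.5, 1.5), d_range = c(-2, 2),
                            B = 100, seed = 1, name = NULL) {
  K <- length(class_proportions) - 1L
  stopifnot(
    abs(sum(class_proportions) - 1) < 1e-8,
    length(class_means) == K + 1, length(class_variances) == K + 1,
    length(dif_items_per_class) == K, length(dif_ranges) == K,
    all(unlist(dif_items_per_class) %in% seq_len(J))
  )
  structure(
    list(N = as.integer(N), J = as.integer(J), K = K,
         class_proportions = class_proportions,
         class_means = class_means, class_variances = class_variances,
         dif_items_per_class = dif_items_per_class, dif_ranges = dif_ranges,
         a_range = a_range, d_range = d_range,
         B = as.integer(B), seed = as.integer(seed),
         name = name %||% sprintf("N%d_J%d_K%d", N, J, K)),
    class = "latdif_scenario"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

two_group_scenario <- function(J, pi_focal, N, B = 100, seed = 1) {
  scenario_config(
    N = N, J = J,
    class_proportions = c(1 - pi_focal, pi_focal),
    class_means = c(0, 0.5), class_variances = c(1, 1.5),
    dif_items_per_class = list(seq_len(if (J == 25) 10 else 20)),
    dif_ranges = list(c(0.5, 1.5)),
    B = B, seed = seed,
    name = sprintf("two_group_J%d_pi%s_N%d", J, format(pi_focal), N)
  )
}

three_group_scenario <- function(J, N, B = 100, seed = 1) {
  dif_items <- if (J == 25) 16:25 else 31:50
  scenario_config(
    N = N, J = J,
    class_proportions = c(0.5, 0.3, 0.2),
    class_means = c(0, 0.5, 1), class_variances = c(1, 1.5, 1.2),
    dif_items_per_class = list(dif_items, dif_items),
    dif_ranges = list(c(0.5, 1), c(1, 1.5)),
    B = B, seed = seed,
    name = sprintf("three_group_J%d_N%d", J, N)
  )
}

#' Built-in simulation scenario grid
#'
#' Two-group conditions crossing test length (25, 50 items), focal-group
#' proportion (0.1, 0.2, 0.5), and sample size (1000, 5000), with DIF on the
#' first 40% of items and offsets Uniform(0.5, 1.5); three-group conditions
#' with proportions (0.5, 0.3, 0.2), DIF on the last 40% of items, and
#' offsets Uniform(0.5, 1) / Uniform(1, 1.5) for the two focal classes.
#'
#' @param seed Base scenario seed.
#' @return Named list of [scenario_config()] objects.
#' @export
builtin_scenarios <- function(seed = 1) {
  out <- list()
  for (J in c(25, 50)) for (pi_f in c(0.1, 0.2, 0.5)) for (N in c(1000, 5000)) {
    s <- two_group_scenario(J, pi_f, N, seed = seed)
    out[[s$name]] <- s
  }
  for (J in c(25, 50)) for (N in c(1000, 5000)) {
    s <- three_group_scenario(J, N, seed = seed)
    out[[s$name]] <- s
  }
  out
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

# True parameters are a pure function of (config, config$seed).
draw_true_params <- function(config) {
  set.seed(config$seed)
  a <- runif_range(config$J, config$a_range)
  d <- runif_range(config$J, config$d_range)
  delta <- matrix(0, config$J, config$K)
  for (k in seq_len(config$K)) {
    items <- config$dif_items_per_class[[k]]
    delta[items, k] <- runif_range(length(items), config$dif_ranges[[k]])
  }
  latdif_params(a = a, d = d, delta = delta,
                nu = config$class_proportions,
                mu = config$class_means, sigma2 = config$class_variances)
}

#' Generate one simulated dataset
#'
#' Draws class memberships, class-conditional normal abilities, and Bernoulli
#' responses under the scenario's (frozen) true parameters. Fully
#' reproducible: the same `(config, replicate_seed)` yields a bit-identical
#' dataset.
#'
#' @param config A [scenario_config()].
#' @param replicate_seed Seed for the response stream (defaults to
#'   `config$seed + 1`).
#' @return List of class `latdif_simdata`: `responses`, `true_params`,
#'   `true_class` (0-based), `seed`.
#' @export
generate_dataset <- function(config, replicate_seed = config$seed + 1L) {
  truth <- draw_true_params(config)
  set.seed(replicate_seed)
  xi <- sample(0:config$K, config$N, replace = TRUE,
               prob = config$class_proportions)
  theta <- stats::rnorm(config$N, mean = truth$mu[1 + xi],
                        sd = sqrt(truth$sigma2[1 + xi]))
  delta_full <- cbind(0, truth$delta)          # J x (K+1), class 0 first
  eta <- tcrossprod(theta, truth$a) +
    matrix(truth$d, config$N, config$J, byrow = TRUE) +
    t(delta_full[, 1 + xi, drop = FALSE])
  y <- matrix(as.integer(stats::runif(length(eta)) < stats::plogis(eta)),
              config$N, config$J)
  colnames(y) <- paste0("item", seq_len(config$J))
  structure(
    list(responses = as_response_matrix(y), true_params = truth,
         true_class = xi, seed = as.integer(replicate_seed)),
    class = "latdif_simdata"
  )
}

as_delta_list <- function(x) {
  if (is.list(x) && !is.matrix(x)) x else list(x)
}

#' True positive rate of DIF detection
#'
#' Fraction of truly nonzero DIF offsets whose estimate is nonzero, averaged
#' over replicates.
#'
#' @param estimated_delta A J x K matrix or list of such (one per replicate).
#' @param true_delta The true J x K DIF matrix.
#' @return Rate in `[0, 1]`.
#' @export
tpr <- function(estimated_delta, true_delta) {
  pos <- true_delta != 0
  if (!any(pos)) stop("no true nonzero DIF offsets", call. = FALSE)
  mean(vapply(as_delta_list(estimated_delta),
              function(est) sum(est != 0 & pos) / sum(pos), numeric(1)))
}

#' False positive rate of DIF detection
#'
#' Fraction of truly zero DIF offsets whose estimate is nonzero, averaged
#' over replicates.
#'
#' @inheritParams tpr
#' @return Rate in `[0, 1]`.
#' @export
fpr <- function(estimated_delta, true_delta) {
  neg <- true_delta == 0
  if (!any(neg)) stop("no true zero DIF offsets", call. = FALSE)
  mean(vapply(as_delta_list(estimated_delta),
              function(est) sum(est != 0 & neg) / sum(neg), numeric(1)))
}

#' Known-groups (oracle) regularised fit
#'
#' The oracle benchmark: class memberships are treated as observed, the
#' mixing proportions drop out of the likelihood, and the same L1 path /
#' BIC-refit machinery selects the DIF support. Quantifies how much is lost
#' by having to infer the groups.
#'
#' @param simdata A `latdif_simdata` from [generate_dataset()].
#' @param controls [em_controls()].
#' @param grid Optional lambda grid.
#' @param M Grid size when `grid` is `NULL`.
#' @return A `latdif_selection` (see [select_lambda()]).
#' @export
oracle_fit <- function(simdata, controls = em_controls(), grid = NULL,
                       M = 10) {
  select_lambda(simdata$responses, K = n_classes(simdata$true_params) - 1L,
                grid = grid, controls = controls, M = M,
                fixed_class = simdata$true_class)
}

#' Parameter-recovery accuracy table
#'
#' Per scalar parameter, the absolute bias `|mean(est - true)|` and RMSE over
#' replicates, averaged within parameter type (intercepts, slopes, DIF
#' offsets per focal class, class means, class standard deviations, focal
#' proportions). Fitted parameter sets must be label-resolved first.
#'
#' @param fitted_params List of [latdif_params()], one per replicate.
#' @param true_params The true [latdif_params()].
#' @return Tibble with `parameter`, `class`, `abs_bias`, `rmse`.
#' @export
accuracy_metrics <- function(fitted_params, true_params) {
  if (inherits(fitted_params, "latdif_params")) {
    fitted_params <- list(fitted_params)
  }
  K <- n_classes(true_params) - 1L
  scalars <- function(p) {
    out <- list(d = p$d, a = p$a)
    for (k in seq_len(K)) {
      out[[paste0("delta.", k)]] <- p$delta[, k]
      out[[paste0("mu.", k)]] <- p$mu[1 + k]
      out[[paste0("sigma.", k)]] <- sqrt(p$sigma2[1 + k])
      out[[paste0("pi.", k)]] <- p$nu[1 + k]
    }
    out
  }
  truth <- scalars(true_params)
  ests <- lapply(fitted_params, scalars)
  rows <- lapply(names(truth), function(nm) {
    errs <- do.call(rbind, lapply(ests, function(e) e[[nm]] - truth[[nm]]))
    per_scalar_bias <- abs(colMeans(errs))
    per_scalar_rmse <- sqrt(colMeans(errs^2))
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    tibble::tibble(
      parameter = parts[1],
      class = if (length(parts) > 1) as.integer(parts[2]) else NA_integer_,
      abs_bias = mean(per_scalar_bias),
      rmse = mean(per_scalar_rmse)
    )
  })
  dplyr::bind_rows(rows)
}

replicate_seed <- function(master_seed, b) as.integer(master_seed + b)

#' Run a full simulation scenario
#'
#' For each replicate: generate data, run the selection pipeline, resolve
#' focal-class labels against the truth, and record DIF-detection rates,
#' MAP classification error and per-class AUC (under both the estimated and
#' the true parameters), and parameter-recovery errors. Optionally also runs
#' the known-groups oracle benchmark.
#'
#' @param config A [scenario_config()].
#' @param B Replications (defaults to `config$B`).
#' @param controls [em_controls()] used for every fit; the multistart seed is
#'   re-derived per replicate.
#' @param include_oracle Also run [oracle_fit()] per replicate.
#' @param M Lambda grid size.
#' @param verbose Print per-replicate progress.
#' @return List of class `latdif_scenario_run` with `metrics` (tidy tibble of
#'   scenario-level averages), `accuracy` (from [accuracy_metrics()]),
#'   `replicates` (per-replicate tibble), `n_failed`, and echoes of `config`,
#'   `B`.
#' @export
run_scenario <- function(config, B = config$B, controls = em_controls(),
                         include_oracle = FALSE, M = 10, verbose = FALSE) {
  stopifnot(B >= 1)
  truth <- draw_true_params(config)
  K <- config$K
  reps <- list()
  resolved_params <- list()
  n_failed <- 0L
  for (b in seq_len(B)) {
    res <- tryCatch(
      run_one_replicate(config, b, controls, include_oracle, M, truth),
      error = function(e) {
        warning("replicate ", b, " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    reps[[length(reps) + 1L]] <- res$row
    resolved_params[[length(resolved_params) + 1L]] <- res$params
    if (verbose) {
      message(sprintf("[%s] replicate %d/%d: tpr=%.3f fpr=%.3f err=%.3f",
                      config$name, b, B, res$row$tpr, res$row$fpr,
                      res$row$classification_error))
    }
  }
  if (length(reps) == 0) stop("all replicates failed", call. = FALSE)
  rep_tbl <- dplyr::bind_rows(reps)
  mean_cols <- setdiff(names(rep_tbl), "replicate")
  metrics <- tidyr::pivot_longer(
    dplyr::summarise(rep_tbl, dplyr::across(dplyr::all_of(mean_cols),
                                            ~ mean(.x, na.rm = TRUE))),
    dplyr::everything(), names_to = "metric", values_to = "value")
  structure(
    list(metrics = metrics,
         accuracy = accuracy_metrics(resolved_params, truth),
         replicates = rep_tbl, n_failed = n_failed,
         config = config, B = B),
    class = "latdif_scenario_run")
}

run_one_replicate <- function(config, b, controls, include_oracle, M, truth) {
  K <- config$K
  sim <- generate_dataset(config, replicate_seed(config$seed, b))
  ctl <- controls
  ctl$seed <- replicate_seed(config$seed, b)
  sel <- select_lambda(sim$responses, K, controls = ctl, M = M)
  perm <- resolve_labels(sel$final_fit, data = sim$responses,
                         truth = sim$true_class)
  est <- permute_classes(sel$final_fit$params, perm)

  post <- posterior_class_probs(est, sim$responses, Q = ctl$Q)
  map_est <- map_classify(post)
  post_true <- posterior_class_probs(truth, sim$responses, Q = ctl$Q)
  map_true <- map_classify(post_true)

  row <- tibble::tibble(
    replicate = b,
    tpr = tpr(est$delta, truth$delta),
    fpr = fpr(est$delta, truth$delta),
    classification_error = classification_error(map_est, sim$true_class),
    classification_error_true = classification_error(map_true, sim$true_class),
    best_lambda = sel$best_lambda
  )
  for (k in seq_len(K)) {
    pos_k <- truth$delta[, k] != 0
    row[[paste0("tpr_class", k)]] <-
      if (any(pos_k)) sum(est$delta[pos_k, k] != 0) / sum(pos_k) else NA_real_
    row[[paste0("fpr_class", k)]] <-
      if (any(!pos_k)) sum(est$delta[!pos_k, k] != 0) / sum(!pos_k) else NA_real_
    row[[paste0("auc_class", k)]] <-
      auc_one_vs_rest(post[, 1 + k], sim$true_class == k)
    row[[paste0("auc_class", k, "_true")]] <-
      auc_one_vs_rest(post_true[, 1 + k], sim$true_class == k)
  }
  if (include_oracle) {
    osel <- oracle_fit(sim, controls = ctl, M = M)
    row$tpr_oracle <- tpr(osel$final_fit$params$delta, truth$delta)
    row$fpr_oracle <- fpr(osel$final_fit$params$delta, truth$delta)
    for (k in seq_len(K)) {
      pos_k <- truth$delta[, k] != 0
      row[[paste0("tpr_oracle_class", k)]] <-
        if (any(pos_k)) sum(osel$final_fit$params$delta[pos_k, k] != 0) / sum(pos_k) else NA_real_
      row[[paste0("fpr_oracle_class", k)]] <-
        if (any(!pos_k)) sum(osel$final_fit$params$delta[!pos_k, k] != 0) / sum(!pos_k) else NA_real_
    }
  }
  list(row = row, params = est)
}

#' @export
print.latdif_scenario_run <- function(x, ...) {
  cat(sprintf("<latdif_scenario_run> %s: B = %d (%d failed)\n",
              x$config$name, x$B, x$n_failed))
  print(x$metrics, n = Inf)
  invisible(x)
}
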