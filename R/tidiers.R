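#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted latent-DIF model
#'
#' One row per estimated scalar: item parameters (`a`, `d`), DIF offsets per
#' focal class (`delta`), and structural parameters (`nu`, `mu`, `sigma2`).
#'
#' @param x A `latdif_fit`.
#' @param ... Unused.
#' @return Tibble with `parameter`, `item`, `class`, `estimate`.
#' @export
tidy.latdif_fit <- function(x, ...) {
  p <- x$params
  J <- length(p$a)
  K <- n_classes(p) - 1L
  items <- seq_len(J)
  out <- list(
    tibble::tibble(parameter = "a", item = items, class = NA_integer_,
                   estimate = p$a),
    tibble::tibble(parameter = "d", item = items, class = NA_integer_,
                   estimate = p$d)
  )
  for (k in seq_len(K)) {
    out[[length(out) + 1L]] <- tibble::tibble(
      parameter = "delta", item = items, class = k, estimate = p$delta[, k])
  }
  out[[length(out) + 1L]] <- tibble::tibble(
    parameter = rep(c("nu", "mu", "sigma2"), each = K + 1),
    item = NA_integer_,
    class = rep(0:K, 3),
    estimate = c(p$nu, p$mu, p$sigma2))
  dplyr::bind_rows(out)
}

#' Glance at a fitted latent-DIF model
#'
#' @param x A `latdif_fit`.
#' @param ... Unused.
#' @return One-row tibble with fit-level summaries.
#' @export
glance.latdif_fit <- function(x, ...) {
  tibble::tibble(
    K = n_classes(x$params) - 1L,
    lambda = x$lambda,
    loglik = x$loglik,
    n_nonzero = sum(x$params$delta != 0),
    n_dif_items = sum(rowSums(x$params$delta != 0) > 0),
    n_iter = x$n_iter,
    converged = x$converged
  )
}

#' Tidy a tuning-parameter selection
#'
#' @param x A `latdif_selection`.
#' @param ... Unused.
#' @return The per-lambda path tibble (`lambda`, `bic`, `n_nonzero`,
#'   `converged`).
#' @export
tidy.latdif_selection <- function(x, ...) x$path

#' @rdname tidy.latdif_selection
#' @export
glance.latdif_selection <- function(x, ...) {
  tibble::tibble(
    K = x$K,
    best_lambda = x$best_lambda,
    bic = min(x$bic_per_lambda),
    n_dif_items = sum(x$dif_items),
    oracle = isTRUE(x$oracle)
  )
}

#' Tidy a scenario run
#'
#' @param x A `latdif_scenario_run`.
#' @param ... Unused.
#' @return The scenario-level metric tibble.
#' @export
tidy.latdif_scenario_run <- function(x, ...) x$metrics

#' Plot estimated DIF offsets by item
#'
#' @param object A `latdif_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.latdif_fit <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$parameter == "delta") |>
    dplyr::mutate(class = factor(.data$class))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item, y = .data$estimate,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "item", y = "estimated DIF offset",
                  fill = "focal class") +
    ggplot2::theme_minimal()
}

#' Plot the BIC path over the tuning-parameter grid
#'
#' @param object A `latdif_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.latdif_selection <- function(object, ...) {
  ggplot2::ggplot(object$path, ggplot2::aes(x = .data$lambda, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$n_nonzero))) +
    ggplot2::geom_vline(xintercept = object$best_lambda, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "BIC",
                  colour = "nonzero offsets") +
    ggplot2::theme_minimal()
}

#' Plot scenario-level simulation metrics
#'
#' @param object A `latdif_scenario_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.latdif_scenario_run <- function(object, ...) {
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean over replicates",
                  title = object$config$name) +
    ggplot2::theme_minimal()
}
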