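test_that("E-step responsibilities match brute-force enumeration", {
  p <- random_params(J = 3, K = 2, seed = 21)
  Y <- random_data(p, 3, seed = 22)
  Y[2, 1] <- NA
  quad <- make_quadrature(p$mu, p$sigma2, Q = 11)
  post <- e_step(p, Y, quad)
  expect_equal(post$joint, brute_posterior(p, Y, quad), tolerance = 1e-10)
  # total mass one per respondent; class marginal consistent with the joint
  expect_equal(apply(post$joint, 1, sum), rep(1, 3), tolerance = 1e-10)
  expect_equal(apply(post$joint, c(1, 2), sum), unname(post$class_marginal),
               tolerance = 1e-12)
})

test_that("E-step degenerates correctly for K = 0 and symmetric classes", {
  p0 <- latdif_params(a = c(1, 0.8), d = c(0, 0.3), nu = 1, mu = 0, sigma2 = 1)
  post0 <- e_step(p0, matrix(c(1L, 0L, 1L, 1L), 2, 2), Q = 15)
  expect_equal(unname(post0$class_marginal[, 1]), c(1, 1))

  # exchangeable focal classes get identical responsibilities
  ps <- latdif_params(a = c(1, 1, 1), d = c(0, 0.5, -0.5),
                      delta = matrix(0.4, 3, 2),
                      nu = c(0.4, 0.3, 0.3), mu = c(0, 0.2, 0.2),
                      sigma2 = c(1, 1.3, 1.3))
  posts <- e_step(ps, random_data(ps, 10, seed = 23), Q = 15)
  expect_equal(posts$class_marginal[, 2], posts$class_marginal[, 3],
               tolerance = 1e-12)
})

test_that("class-probability update solves the simplex-constrained subproblem", {
  p <- random_params(J = 4, K = 2, seed = 25)
  Y <- random_data(p, 7, seed = 26)
  post <- e_step(p, Y, Q = 11)
  nu_new <- update_class_probs(post)
  expect_equal(sum(nu_new), 1, tolerance = 1e-12)
  expect_equal(nu_new, colMeans(post$class_marginal), tolerance = 1e-12)

  # numerical-optimiser oracle for the minimiser of the mixing part of the
  # surrogate, -sum_i sum_k cm[i,k] log nu_k, over the simplex
  cm <- post$class_marginal
  obj <- function(lg) {
    nu <- exp(c(0, lg)); nu <- nu / sum(nu)
    -sum(cm %*% log(nu))
  }
  opt <- optim(c(0, 0), obj, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 500))
  nu_opt <- exp(c(0, opt$par)); nu_opt <- nu_opt / sum(nu_opt)
  expect_equal(nu_new, nu_opt, tolerance = 1e-6)

  # a class with zero responsibility keeps probability zero
  cm0 <- cbind(cm[, 1] + cm[, 3], cm[, 2], 0)
  expect_equal(update_class_probs(list(class_marginal = cm0))[3], 0)
})

test_that("soft thresholding shrinks to exact zero", {
  expect_equal(soft_threshold(1.0, 0.3), 0.7)
  expect_identical(soft_threshold(-0.2, 0.3), 0)
  expect_identical(soft_threshold(0, 5), 0)
  expect_equal(soft_threshold(c(-2, 2), 0.5), c(-1.5, 1.5))
  expect_error(soft_threshold(1, -0.1), "nonnegative")
})

test_that("surrogate gradient matches central finite differences", {
  p <- random_params(J = 4, K = 1, seed = 27)
  Y <- random_data(p, 40, seed = 28)
  pd <- latdif:::prep_responses(as_response_matrix(Y))
  quad <- make_quadrature(p$mu, p$sigma2, Q = 15)
  post <- e_step(p, Y, quad)
  gh <- latdif:::gh_standard(15)
  stats <- latdif:::surrogate_stats(post, pd)
  g <- grad_F(p, post, Y, quad)

  h <- 1e-5
  fd <- function(mutate) {
    (latdif:::surrogate_F(mutate(p, h), stats, gh) -
       latdif:::surrogate_F(mutate(p, -h), stats, gh)) / (2 * h)
  }
  for (j in 1:4) {
    expect_equal(g$d[j],
                 fd(function(q, e) { q$d[j] <- q$d[j] + e; q }),
                 tolerance = 1e-4)
    expect_equal(g$a[j],
                 fd(function(q, e) { q$a[j] <- q$a[j] + e; q }),
                 tolerance = 1e-4)
    expect_equal(g$delta[j, 1],
                 fd(function(q, e) { q$delta[j, 1] <- q$delta[j, 1] + e; q }),
                 tolerance = 1e-4)
  }
  expect_equal(g$mu[1],
               fd(function(q, e) { q$mu[2] <- q$mu[2] + e; q }),
               tolerance = 1e-4)
  expect_equal(g$log_sigma[1],
               fd(function(q, e) { q$sigma2[2] <- exp(2 * (0.5 * log(q$sigma2[2]) + e)); q }),
               tolerance = 1e-4)
})

test_that("gradient is zero for a class with no responsibility", {
  p <- random_params(J = 3, K = 1, seed = 29)
  p$nu <- c(1, 0)
  Y <- random_data(random_params(J = 3, K = 0, seed = 29), 10, seed = 30)
  post <- e_step(p, Y, Q = 11)
  g <- grad_F(p, post, Y)
  expect_equal(g$delta[, 1], rep(0, 3))
})

test_that("proximal update soft-thresholds offsets and steps the rest", {
  p <- random_params(J = 4, K = 1, seed = 31)
  Y <- random_data(p, 30, seed = 32)
  quad <- make_quadrature(p$mu, p$sigma2, Q = 15)
  post <- e_step(p, Y, quad)
  g <- grad_F(p, post, Y, quad)
  step <- 0.01

  up0 <- proximal_update(p, post, Y, quad, lambda = 0, step = step)
  expect_equal(up0$d, p$d - step * g$d, tolerance = 1e-10)
  expect_equal(up0$a, p$a - step * g$a, tolerance = 1e-10)
  expect_equal(up0$delta, soft_threshold(p$delta - step * g$delta, 0),
               tolerance = 1e-10)
  expect_equal(up0$nu, update_class_probs(post), tolerance = 1e-12)
  expect_equal(up0$mu[1], 0)
  expect_equal(up0$sigma2[1], 1)

  # a huge penalty zeroes every offset in one update, exactly
  up_inf <- proximal_update(p, post, Y, quad,
                            lambda = (max(abs(g$delta)) + max(abs(p$delta)) / step) * 2,
                            step = step)
  expect_true(all(up_inf$delta == 0))

  # one-coordinate prox against a numeric minimiser of the local surrogate
  z <- p$delta[2, 1] - step * g$delta[2, 1]
  lam <- 3
  oracle <- optimize(function(x) 0.5 * (x - z)^2 + step * lam * abs(x),
                     interval = c(-5, 5), tol = 1e-12)$minimum
  up <- proximal_update(p, post, Y, quad, lambda = lam, step = step)
  expect_equal(up$delta[2, 1], oracle, tolerance = 1e-8)
  expect_equal(up$delta[2, 1], soft_threshold(z, step * lam), tolerance = 1e-12)
})

test_that("line search decreases the surrogate or flags stationarity", {
  p <- random_params(J = 4, K = 1, seed = 33)
  Y <- random_data(p, 40, seed = 34)
  quad <- make_quadrature(p$mu, p$sigma2, Q = 15)
  post <- e_step(p, Y, quad)
  pd <- latdif:::prep_responses(as_response_matrix(Y))
  gh <- latdif:::gh_standard(15)
  stats <- latdif:::surrogate_stats(post, pd)
  lam <- 0.5
  surro <- function(q) latdif:::surrogate_F(q, stats, gh) + lam * sum(abs(q$delta))

  ls <- line_search(p, post, Y, quad, lambda = lam, step_init = 1,
                    controls = em_controls(Q = 15))
  expect_false(ls$stationary)
  expect_lt(surro(ls$params), surro(p))

  # at (numerical) stationarity of the surrogate the old point is returned
  ctl <- em_controls(Q = 15, n_starts = 1, tol = 1e-10, max_iter = 2000,
                     n_inner = 25)
  fit <- fit_regularized(Y, K = 1, lambda = lam, controls = ctl, init = p)
  post2 <- e_step(fit$params, Y, Q = 15)
  ls2 <- line_search(fit$params, post2, Y, NULL, lambda = lam,
                     step_init = 1e-6, controls = em_controls(Q = 15))
  d2 <- latdif:::delta2_sqnorm(ls2$params, fit$params,
                               latdif:::unit_metric(fit$params))
  expect_lt(d2, 1e-6)
})

test_that("EM trace is monotone and constraints are preserved", {
  for (seed in c(41, 42)) {
    p <- random_params(J = 6, K = 1, seed = seed)
    Y <- random_data(p, 120, seed = seed + 100)
    fit <- fit_regularized(Y, K = 1, lambda = 1,
                           controls = em_controls(Q = 15, n_starts = 1,
                                                  seed = seed, max_iter = 60))
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
    expect_equal(sum(fit$params$nu), 1, tolerance = 1e-10)
    expect_true(all(fit$params$sigma2 > 0))
    expect_identical(fit$params$mu[1], 0)
    expect_identical(fit$params$sigma2[1], 1)
    expect_identical(fit$support, fit$params$delta != 0)
  }
})

test_that("a plain 2-PL fit recovers its generating parameters", {
  truth <- latdif_params(a = c(0.8, 1.2, 1, 1.4, 0.6),
                         d = c(-1, 0.5, 0, 1.2, -0.4),
                         nu = 1, mu = 0, sigma2 = 1)
  Y <- random_data(truth, 500, seed = 51)
  fit <- fit_regularized(Y, K = 0,
                         controls = em_controls(Q = 21, n_starts = 1, seed = 1))
  expect_true(fit$converged)
  expect_lt(sqrt(mean((fit$params$a - truth$a)^2)), 0.25)
  expect_lt(sqrt(mean((fit$params$d - truth$d)^2)), 0.25)
})

test_that("an overwhelming penalty reproduces the no-DIF fit", {
  p <- random_params(J = 5, K = 1, seed = 61)
  Y <- random_data(p, 150, seed = 62)
  ctl <- em_controls(Q = 15, n_starts = 1, seed = 2, max_iter = 300)
  fit_big <- fit_regularized(Y, K = 1, lambda = 1e4, controls = ctl)
  expect_true(all(fit_big$params$delta == 0))
  fit_null <- fit_regularized(Y, K = 1, lambda = 0, controls = ctl,
                              fixed_support = matrix(FALSE, 5, 1))
  expect_equal(fit_big$loglik, fit_null$loglik, tolerance = 1e-3)
})

test_that("a fixed support excludes offsets from the fit", {
  p <- random_params(J = 5, K = 1, seed = 63)
  Y <- random_data(p, 100, seed = 64)
  supp <- matrix(c(TRUE, FALSE, TRUE, FALSE, FALSE), 5, 1)
  fit <- fit_regularized(Y, K = 1, lambda = 0, controls =
                           em_controls(Q = 15, n_starts = 1, max_iter = 200),
                         fixed_support = supp)
  expect_true(all(fit$params$delta[!supp] == 0))
})

test_that("fit artifacts serialise and reload exactly", {
  p <- random_params(J = 4, K = 1, seed = 71)
  Y <- random_data(p, 60, seed = 72)
  fit <- fit_regularized(Y, K = 1, lambda = 0.8,
                         controls = em_controls(Q = 15, n_starts = 1,
                                                max_iter = 50))
  f <- tempfile(fileext = ".json")
  write_fit(fit, f)
  fit2 <- read_fit(f)
  expect_equal(fit2$params$delta, fit$params$delta, tolerance = 1e-12)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-12)
  expect_identical(fit2$support, fit$support)
  expect_identical(fit2$converged, fit$converged)
  expect_equal(fit2$lambda, fit$lambda)
})
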