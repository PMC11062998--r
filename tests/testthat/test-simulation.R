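test_that("dataset generation is exactly reproducible and well calibrated", {
  sc <- scenario_config(N = 400, J = 10, class_proportions = c(0.8, 0.2),
                        class_means = c(0, 0.5), class_variances = c(1, 1.5),
                        dif_items_per_class = list(1:4),
                        dif_ranges = list(c(0.5, 1.5)), seed = 5)
  d1 <- generate_dataset(sc, 99)
  d2 <- generate_dataset(sc, 99)
  expect_identical(d1$responses$values, d2$responses$values)
  expect_identical(d1$true_class, d2$true_class)
  expect_identical(d1$true_params$delta, d2$true_params$delta)
  # truths are frozen per scenario, independent of the replicate stream
  d3 <- generate_dataset(sc, 100)
  expect_identical(d3$true_params$a, d1$true_params$a)
  expect_false(identical(d3$responses$values, d1$responses$values))
  # nonzero offsets exactly on the configured items
  expect_identical(which(d1$true_params$delta[, 1] != 0), 1:4)

  # focal-class count within 4 binomial standard deviations
  scN <- scenario_config(N = 10000, J = 4, class_proportions = c(0.9, 0.1),
                         class_means = c(0, 0.5), class_variances = c(1, 1.5),
                         dif_items_per_class = list(1:2),
                         dif_ranges = list(c(0.5, 1.5)), seed = 6)
  dN <- generate_dataset(scN, 7)
  expect_lt(abs(sum(dN$true_class == 1) - 1000), 4 * sqrt(10000 * 0.1 * 0.9))

  # per-item response rates match the quadrature-computed marginal
  truth <- dN$true_params
  q <- make_quadrature(truth$mu, truth$sigma2, 41)
  dlt <- cbind(0, truth$delta)
  for (j in 1:4) {
    marg <- sum(vapply(1:2, function(c) {
      truth$nu[c] * sum(q$weights * plogis(truth$a[j] * q$nodes[, c] +
                                             truth$d[j] + dlt[j, c]))
    }, numeric(1)))
    emp <- mean(dN$responses$values[, j])
    expect_lt(abs(emp - marg), 4 * sqrt(marg * (1 - marg) / 10000))
  }
})

test_that("builtin scenarios reproduce the study grid", {
  scs <- builtin_scenarios()
  expect_length(scs, 16)
  two25 <- scs[["two_group_J25_pi0.1_N1000"]]
  expect_identical(two25$dif_items_per_class[[1]], 1:10)
  expect_equal(two25$class_proportions, c(0.9, 0.1))
  expect_equal(two25$class_variances, c(1, 1.5))
  three <- scs[["three_group_J25_N1000"]]
  expect_equal(three$class_proportions, c(0.5, 0.3, 0.2))
  expect_identical(three$dif_items_per_class[[1]], 16:25)
  expect_equal(three$dif_ranges[[2]], c(1, 1.5))
  # DIF on 40% of items everywhere
  for (sc in scs) {
    expect_equal(length(unique(unlist(sc$dif_items_per_class))) / sc$J, 0.4)
  }
})

test_that("detection rates count support agreement", {
  true_d <- matrix(c(1, 0.8, 0, 0, 0), 5, 1)
  expect_equal(tpr(true_d, true_d), 1)
  expect_equal(tpr(matrix(0, 5, 1), true_d), 0)
  expect_equal(tpr(matrix(c(1, 0, 0, 0, 0), 5, 1), true_d), 0.5)
  expect_equal(fpr(matrix(c(1, 0, 0, 0, 0), 5, 1), true_d), 0)
  expect_equal(fpr(matrix(1, 5, 1), true_d), 1)
  expect_equal(fpr(matrix(c(0, 0, 1, 0, 0), 5, 1), true_d), 1 / 3)
  # averaging over replicates
  expect_equal(tpr(list(true_d, matrix(0, 5, 1)), true_d), 0.5)
  expect_error(tpr(true_d, matrix(0, 5, 1)), "nonzero")
  expect_error(fpr(true_d, matrix(1, 5, 1)), "zero")
})

test_that("accuracy metrics aggregate bias and RMSE by parameter type", {
  truth <- random_params(J = 3, K = 1, seed = 141)
  exact <- accuracy_metrics(list(truth, truth), truth)
  expect_true(all(exact$abs_bias == 0))
  expect_true(all(exact$rmse == 0))

  shift <- truth
  shift$d <- truth$d + 0.1
  tab <- accuracy_metrics(list(shift, shift), truth)
  expect_equal(tab$abs_bias[tab$parameter == "d"], 0.1, tolerance = 1e-12)
  expect_equal(tab$rmse[tab$parameter == "d"], 0.1, tolerance = 1e-12)

  up <- truth; up$d <- truth$d + 0.1
  dn <- truth; dn$d <- truth$d - 0.1
  alt <- accuracy_metrics(list(up, dn), truth)
  expect_equal(alt$abs_bias[alt$parameter == "d"], 0, tolerance = 1e-12)
  expect_equal(alt$rmse[alt$parameter == "d"], 0.1, tolerance = 1e-12)
  # RMSE never below absolute bias
  expect_true(all(alt$rmse >= alt$abs_bias - 1e-12))
})

test_that("oracle fitting conditions on the known classes", {
  sc <- scenario_config(N = 400, J = 8, class_proportions = c(0.7, 0.3),
                        class_means = c(0, 0), class_variances = c(1, 1),
                        dif_items_per_class = list(7:8),
                        dif_ranges = list(c(-3.5, -2.5)), seed = 21)
  sim <- generate_dataset(sc, 22)
  # with known classes the E-step puts all class mass on the truth
  p <- sim$true_params
  pd <- latdif:::prep_responses(sim$responses)
  quad <- make_quadrature(p$mu, p$sigma2, 15)
  es <- latdif:::.e_step(p, pd, quad, fixed_class = sim$true_class)
  picked <- max.col(es$class_marginal) - 1L
  expect_identical(picked, sim$true_class)
  expect_equal(rowSums(es$class_marginal), rep(1, 400), tolerance = 1e-10)

  ctl <- em_controls(Q = 15, n_starts = 1, seed = 1, max_iter = 150)
  osel <- oracle_fit(sim, controls = ctl, M = 6)
  expect_true(osel$oracle)
  # strong negative DIF on the configured items is recovered
  expect_equal(tpr(osel$final_fit$params$delta, sim$true_params$delta), 1)
  expect_lte(fpr(osel$final_fit$params$delta, sim$true_params$delta), 1 / 6)
})

test_that("a single-replicate scenario run emits one tidy record", {
  sc <- scenario_config(N = 300, J = 8, class_proportions = c(0.75, 0.25),
                        class_means = c(0, 0), class_variances = c(1, 1),
                        dif_items_per_class = list(7:8),
                        dif_ranges = list(c(-3.5, -2.5)), seed = 31)
  run <- run_scenario(sc, B = 1,
                      controls = em_controls(Q = 15, n_starts = 2, seed = 1,
                                             max_iter = 150))
  expect_s3_class(run, "latdif_scenario_run")
  expect_identical(nrow(run$replicates), 1L)
  vals <- run$metrics$value[run$metrics$metric %in%
                              c("tpr", "fpr", "classification_error",
                                "auc_class1")]
  expect_true(all(vals >= 0 & vals <= 1))
  expect_identical(run$n_failed, 0L)
  expect_s3_class(tidy(run), "tbl_df")
  expect_s3_class(autoplot(run), "ggplot")
})
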