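# Scenario runs shared by several acceptance tests (computed once per
# session). Replications are reduced relative to a full study; the
# quadrature size and start counts used here are the package's standard
# simulation-harness settings.
scenario_cache <- new.env(parent = emptyenv())

acceptance_controls <- function(seed = 1) {
  em_controls(Q = 21, n_starts = 2, seed = seed)
}

table1_run <- function() {
  if (is.null(scenario_cache$table1)) {
    sc <- scenario_config(
      N = 1000, J = 25, class_proportions = c(0.9, 0.1),
      class_means = c(0, 0.5), class_variances = c(1, 1.5),
      dif_items_per_class = list(1:10), dif_ranges = list(c(0.5, 1.5)),
      seed = 1, name = "two_group_J25_pi0.1_N1000")
    scenario_cache$table1 <- run_scenario(sc, B = 20,
                                          controls = acceptance_controls(),
                                          include_oracle = TRUE)
  }
  scenario_cache$table1
}

table2_run <- function() {
  if (is.null(scenario_cache$table2)) {
    sc <- scenario_config(
      N = 1000, J = 25, class_proportions = c(0.5, 0.3, 0.2),
      class_means = c(0, 0.5, 1), class_variances = c(1, 1.5, 1.2),
      dif_items_per_class = list(16:25, 16:25),
      dif_ranges = list(c(0.5, 1), c(1, 1.5)),
      seed = 1, name = "three_group_J25_N1000")
    scenario_cache$table2 <- run_scenario(sc, B = 10,
                                          controls = acceptance_controls())
  }
  scenario_cache$table2
}

metric_value <- function(run, name) {
  v <- run$metrics$value[run$metrics$metric == name]
  stopifnot(length(v) == 1)
  v
}
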