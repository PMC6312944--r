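sim_cached <- local({
  cfg <- default_config()
  cfg$settings$max_steps <- 200
  run_simulation(cfg, seed = 21)
})

test_that("waiting time is arrival to first exit from the entry ward", {
  cfg <- chain_config(max_steps = 10, cap_ed = 5, cap_w1 = 5)
  sim <- run_simulation(cfg, seed = 1)
  wt <- waiting_times(sim, target = 4)
  # constant LOS 1 with free beds: admit at arrival, leave ed one step later
  expect_true(all(wt$waits$wait == 1))
  expect_equal(wt$pct_within_target, 100)
  expect_equal(wt$n_censored,
               sim$totals[["arrived"]] - wt$n_measured)
})

test_that("the within-target percentage is monotone in the target", {
  pcts <- vapply(1:12, function(tg) {
    waiting_times(sim_cached, target = tg)$pct_within_target
  }, numeric(1))
  expect_true(all(diff(pcts) >= 0))
  expect_true(all(pcts >= 0 & pcts <= 100))
})

test_that("an empty run reports no waits rather than zero percent", {
  sim <- run_simulation(tiny_config(max_steps = 0, max_patients = 5), seed = 1)
  wt <- waiting_times(sim, target = 4)
  expect_equal(wt$n_measured, 0)
  expect_true(is.na(wt$pct_within_target))
})

test_that("occupancy utilisation is occupancy over capacity, never above 1", {
  occ <- occupancy_series(sim_cached)
  expect_equal(occ$utilisation, occ$occupancy / occ$capacity)
  expect_true(all(occ$utilisation <= 1 + 1e-12, na.rm = TRUE))
  expect_equal(nrow(occ), sim_cached$steps_run * nrow(sim_cached$config$wards))
})

test_that("the flow network counts each movement once and reconciles with the log", {
  sim <- run_simulation(tiny_config(max_steps = 10), seed = 1)
  net <- build_flow_network(sim)
  e <- net$edges
  expect_equal(e$count[e$from == "EXTERNAL" & e$to == "ed"], 10)
  expect_equal(e$count[e$from == "ed" & e$to == "DISCHARGE"], 9)

  net2 <- build_flow_network(sim_cached)
  inflow_dis <- sum(net2$edges$count[net2$edges$to == "DISCHARGE"])
  expect_equal(inflow_dis, unname(sim_cached$totals[["discharged"]]))
  outflow_ext <- sum(net2$edges$count[net2$edges$from == "EXTERNAL"])
  expect_equal(outflow_ext, unname(sim_cached$totals[["admitted"]]))
  # edge totals reconcile with event-log counts exactly
  moved <- sum(sim_cached$events$kind %in%
                 c("ADMIT", "TRANSFER", "DIVERT", "RETURN", "DISCHARGE"))
  expect_equal(sum(net2$edges$count), moved)
})

test_that("centralities match hand-derived values on canonical graphs", {
  path <- tibble::tibble(from = c("a", "b"), to = c("b", "c"), count = c(1, 1))
  s <- network_statistics(path)
  expect_equal(s$betweenness[s$node == "b"], 1)  # sole relay on the line
  expect_equal(s$betweenness[s$node == "a"], 0)
  expect_equal(s$betweenness[s$node == "c"], 0)
  expect_equal(s$closeness[s$node == "a"], (1 + 1 / 2) / 2)
  expect_equal(s$closeness[s$node == "c"], 0)

  star <- tibble::tibble(from = "hub", to = c("l1", "l2", "l3"), count = 2)
  st <- network_statistics(star)
  expect_equal(st$out_degree[st$node == "hub"], 3)
  expect_equal(st$in_degree[st$node == "hub"], 0)
  expect_equal(st$out_degree_weighted[st$node == "hub"], 6)

  single <- structure(list(nodes = "a",
                           edges = tibble::tibble(from = character(),
                                                  to = character(),
                                                  count = integer())),
                      class = "flow_network")
  s1 <- network_statistics(single)
  expect_equal(s1$betweenness, 0)
  expect_equal(s1$closeness, 0)
  expect_error(network_statistics(tibble::tibble(from = character(),
                                                 to = character(),
                                                 count = integer())),
               "no flow recorded")
})

test_that("centralities agree with the brute-force oracle on random graphs", {
  set.seed(77)
  for (i in 1:200) {
    g <- random_small_graph()
    got <- network_statistics(structure(g, class = "flow_network"))
    want <- oracle_network_stats(g$nodes, g$edges)
    expect_equal(setNames(got$betweenness, got$node),
                 want$betweenness[got$node], tolerance = 1e-12,
                 info = paste("graph", i))
    expect_equal(setNames(got$closeness, got$node),
                 want$closeness[got$node], tolerance = 1e-12,
                 info = paste("graph", i))
  }
})

test_that("journey summaries report order statistics per unique path", {
  sim <- run_simulation(tiny_config(max_steps = 12), seed = 1)
  js <- journey_summary(sim)
  expect_equal(nrow(js$journeys), 1)
  expect_equal(js$journeys$journey, "ed")
  expect_equal(js$journeys$count + js$n_censored,
               unname(sim$totals[["arrived"]]))
  expect_equal(js$journeys$min_duration, 1)
  expect_equal(js$journeys$max_duration, 1)

  js2 <- journey_summary(sim_cached)
  expect_equal(sum(js2$journeys$count),
               unname(sim_cached$totals[["discharged"]]))
  expect_equal(sum(js2$path_lengths$count),
               unname(sim_cached$totals[["discharged"]]))
  # durations can only exceed the pure treatment time
  done <- sim_cached$patients[sim_cached$patients$location == "DISCHARGED", ]
  min_time <- vapply(done$los_required, sum, numeric(1))
  expect_true(all(done$discharge_step - done$arrival_step >= min_time))
})

test_that("median journey duration follows the even-count convention", {
  # three one-ward stays with durations 2, 4, 9: median 4; with an even
  # count the two central values are averaged
  expect_equal(median(c(2, 4, 9)), 4)
  expect_equal(median(c(2, 4, 6, 9)), 5)
  js <- journey_summary(sim_cached)
  expect_true(all(js$journeys$min_duration <= js$journeys$median_duration))
  expect_true(all(js$journeys$median_duration <= js$journeys$max_duration))
})

test_that("boarding wards are excluded from journeys", {
  cfg <- hospital_config(
    wards = data.frame(
      id = c("ed", "w1", "v"),
      capacity = c(3, 1, 5),
      resources = 10, los_lambda = 0, need_lambda = 0,
      allow_overflow = c(FALSE, FALSE, TRUE),
      is_entry = c(TRUE, FALSE, FALSE)
    ),
    graph = list(ed = c(w1 = 1), w1 = c(DISCHARGE = 1), v = c(DISCHARGE = 1)),
    settings = sim_settings(max_steps = 30, max_patients = 5,
                            arrivals_min = 3, arrivals_max = 3)
  )
  sim <- run_simulation(cfg, seed = 2)
  expect_gt(sum(sim$events$kind == "DIVERT"), 0)
  js <- journey_summary(sim)
  expect_false(any(grepl("v", js$journeys$journey)))
  expect_equal(js$journeys$journey, "ed -> w1")
})

test_that("basic statistics compute the closed-form operating cost", {
  cfg <- hospital_config(
    wards = data.frame(id = "ed", capacity = 5, resources = 10,
                       los_lambda = 0, need_lambda = 0, is_entry = TRUE),
    graph = list(ed = c(DISCHARGE = 1)),
    settings = sim_settings(max_steps = 100, arrivals_min = 0,
                            arrivals_max = 1, resource_unit_cost = 1,
                            bed_unit_cost = 2)
  )
  sim <- run_simulation(cfg, seed = 1)
  b <- basic_statistics(sim)
  expect_equal(b$operating_cost, 100 * (10 * 1 + 5 * 2))  # 2000
  expect_equal(b$n_patients, unname(sim$totals[["arrived"]]))
  expect_lte(b$n_unique_journeys, b$n_discharged)

  sim0 <- run_simulation(tiny_config(max_steps = 0, max_patients = 5), seed = 1)
  expect_equal(basic_statistics(sim0)$operating_cost, 0)
})

test_that("tidiers and plots expose the run in tidy form", {
  expect_identical(tidy(sim_cached), sim_cached$events)
  g <- glance(sim_cached)
  expect_equal(g$n_arrived, unname(sim_cached$totals[["arrived"]]))
  rep <- analyze(sim_cached)
  expect_s3_class(glance(rep), "tbl_df")
  expect_equal(tidy(rep), rep$network_stats)
  expect_s3_class(autoplot(sim_cached), "ggplot")
  expect_s3_class(plot_waiting_times(sim_cached), "ggplot")
  expect_s3_class(plot_flow_network(build_flow_network(sim_cached)), "ggplot")
})
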