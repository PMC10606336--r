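test_that("the bundled perinatology scenario file loads with the known capacities", {
  path <- system.file("extdata", "perinatology.yaml", package = "carenet")
  expect_true(nzchar(path))
  sc <- load_scenario(path)
  expect_equal(sc$network$units$id, c("O3", "N1", "N2", "N3", "O1"))
  expect_equal(sc$network$units$beds, c(6, 14, 4, 11, 7))
  expect_length(sc$pooling_models, 4)
  # and it is the same scenario the package builds in code
  expect_equal(sc$network$units, perinatology_network()$units)
  expect_equal(sc$network$routing, perinatology_network()$routing)
})

test_that("scenario round-trip is the identity on canonical form", {
  set.seed(61)
  for (k in 1:5) {
    net <- random_ff_network(n = sample(2:5, 1))
    ids <- net$units$id
    plan <- pooling_plan(stats::setNames(as.list(ids), ids))
    sc <- scenario_config(net, list(plain = plan),
                          simulation_config(100, seed = k))
    path <- withr::local_tempfile(fileext = ".yaml")
    save_scenario(sc, path)
    back <- load_scenario(path)
    expect_equal(back$network$units, sc$network$units)
    expect_equal(back$network$routing, sc$network$routing)
    expect_equal(lapply(back$pooling_models, `[[`, "groups"),
                 lapply(sc$pooling_models, `[[`, "groups"))
    expect_equal(back$simulation$horizon_days, sc$simulation$horizon_days)
    expect_equal(back$simulation$seed, sc$simulation$seed)
  }
})

test_that("schema violations are reported with field paths", {
  p1 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("units: []", p1)
  expect_error(load_scenario(p1), "units")
  p2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("units:", "  - id: A", "    service_rate: 0.5"), p2)
  expect_error(load_scenario(p2), "units\\[1\\]\\.beds")
  p3 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("units:", "  - {id: A, beds: 2, service_rate: 0.5}",
               "routing:", "  - {from: A, to: ZZ, p: 0.3}"), p3)
  expect_error(load_scenario(p3), "routing\\[1\\]\\.to")
})

test_that("an identity plan is always present in a scenario", {
  net <- perinatology_network()
  sc <- scenario_config(net, list(pool = perinatology_plans()[["Model 3"]]))
  identities <- vapply(sc$pooling_models, function(p)
    all(lengths(p$groups) == 1L), logical(1))
  expect_true(any(identities))
})

test_that("synthetic generation hits the target demand correlation", {
  # independence
  syn0 <- generate_synthetic(synthetic_spec(2, target_correlation = 0,
                                            horizon_days = 10000, seed = 4))
  expect_lt(abs(cor(syn0$demand)[1, 2]), 0.1)
  # calibrated negative common mode
  syn <- generate_synthetic(synthetic_spec(2, target_correlation = -0.5,
                                           horizon_days = 10000, seed = 4))
  r <- cor(syn$demand)[1, 2]
  expect_gt(r, -0.6); expect_lt(r, -0.4)
  # positive target
  synp <- generate_synthetic(synthetic_spec(3, target_correlation = 0.6,
                                            horizon_days = 10000, seed = 4))
  cp <- cor(synp$demand)
  expect_lt(max(abs(cp[upper.tri(cp)] - 0.6)), 0.1)
  # determinism and attainability
  again <- generate_synthetic(synthetic_spec(2, target_correlation = -0.5,
                                             horizon_days = 10000, seed = 4))
  expect_identical(syn$demand, again$demand)
  expect_error(synthetic_spec(2, target_correlation = 1), "unattainable")
})

test_that("anti-correlated synthetic units pool below the sum of variances", {
  syn <- generate_synthetic(synthetic_spec(2, target_correlation = -0.5,
                                           horizon_days = 5000, seed = 9))
  v <- var(rowSums(syn$demand))
  expect_lt(v, sum(apply(syn$demand, 2, var)))
})

test_that("the full comparison reproduces the aggregated decision columns", {
  cmp <- run_full_comparison(perinatology_scenario(seed = 1))
  rep <- cmp$report
  hub <- rep[rep$strategy == "hub" & rep$aggregated, ]
  expect_true(all(hub$decision_bits == 0))
  hier <- rep[rep$strategy == "hierarchy" & rep$aggregated, ]
  expect_equal(round(hier$decision_bits[match(paste("Model", 1:4), hier$model)], 1),
               c(3.6, 2.6, 3, 2.6))
  # flagged optimum is the argmin of the reported totals
  expect_equal(cmp$optimal$total_bits, min(rep$total_bits))
  # hub <= hierarchy <= network within every model and aggregation level
  by_grp <- split(rep, list(rep$model, rep$aggregated))
  for (g in by_grp) {
    expect_lte(g$total_bits[g$strategy == "hub"],
               g$total_bits[g$strategy == "hierarchy"])
    expect_lte(g$total_bits[g$strategy == "hierarchy"],
               g$total_bits[g$strategy == "network"])
  }
})

test_that("a single-model single-strategy scenario gives a one-row report", {
  net <- perinatology_network()
  sc <- scenario_config(net, list("Model 1" = identity_plan(net)),
                        simulation_config(30, seed = 2),
                        strategies = "hub", aggregated = TRUE)
  cmp <- run_full_comparison(sc)
  expect_equal(nrow(cmp$report), 1)
  expect_equal(cmp$report$decision_bits, 0)
})
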