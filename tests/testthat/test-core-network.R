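test_that("traffic equations reproduce the fixture's NICU inflow", {
  net <- perinatology_network()
  eff <- effective_arrival_rates(net)
  # 15.8% of 4 births/day plus 0.6/day external admissions
  expect_equal(unname(eff["N1"]), 4.0 * 0.158 + 0.6)
  expect_equal(round(unname(eff["N1"]), 1), 1.2)
  expect_equal(unname(eff["N2"]), 0.2)
})

test_that("zero routing leaves external rates unchanged; a chain splits them", {
  units <- list(care_unit("A", 5, 0.5, external_rate = 2),
                care_unit("B", 5, 0.5, external_rate = 0))
  net <- care_network(units)
  expect_equal(effective_arrival_rates(net), c(A = 2, B = 0))
  R <- matrix(c(0, 0.5, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  chain <- care_network(units, R)
  expect_equal(effective_arrival_rates(chain), c(A = 2, B = 1))
})

test_that("traffic solution matches path-sum enumeration on random feed-forward networks", {
  set.seed(42)
  for (k in 1:25) {
    net <- random_ff_network()
    expect_equal(effective_arrival_rates(net), path_sum_rates(net),
                 tolerance = 1e-10)
  }
})

test_that("cyclic routing is solved linearly and unstable cycles are named", {
  ids <- c("A", "B")
  units <- list(care_unit("A", 5, 0.5, external_rate = 1),
                care_unit("B", 5, 0.5, external_rate = 0))
  R <- matrix(c(0, 0.5, 0.5, 0), 2, 2, byrow = TRUE, dimnames = list(ids, ids))
  net <- care_network(units, R)
  # A gets 1 + eff_B/2, B gets eff_A/2 -> eff_A = 4/3, eff_B = 2/3
  expect_equal(effective_arrival_rates(net), c(A = 4 / 3, B = 2 / 3))
  Rbad <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE, dimnames = list(ids, ids))
  bad <- care_network(units, Rbad)
  expect_error(effective_arrival_rates(bad), "unstable network.*A.*B")
})

test_that("utilization matches the published per-unit figures and edge cases", {
  expect_equal(round(utilization(4.0, 6, 1.00), 3), 0.667)
  expect_equal(round(utilization(0.9, 11, 0.19), 3), 0.431)
  expect_equal(utilization(0, 17, 0.3), 0)
  expect_false(is_stable(1.5, 2, 0.5))   # rho > 1 is overload, not an error
  expect_gt(utilization(3, 2, 0.5), 1)
  expect_error(utilization(1, 0, 0.5), "invalid unit")
  expect_error(utilization(1, 4, -1), "invalid unit")
})

test_that("utilization is linear in arrivals and inversely linear in c and mu", {
  set.seed(7)
  for (k in 1:20) {
    lam <- runif(1, 0, 10); c0 <- sample(1:30, 1); mu <- runif(1, 0.05, 2)
    a <- runif(1, 0.1, 5)
    expect_equal(utilization(a * lam, c0, mu), a * utilization(lam, c0, mu))
    expect_equal(utilization(lam, c0, a * mu), utilization(lam, c0, mu) / a)
  }
})

test_that("pooling combines beds, demand and staff, and conserves occupancy", {
  net <- perinatology_network()
  plans <- perinatology_plans()
  m3 <- apply_pooling(net, plans[["Model 3"]])
  expect_equal(n_distinct_units <- nrow(m3$units), 4)
  expect_equal(m3$units$beds[m3$units$id == "N2+N3"], 4 + 11)
  # expected occupancy sum(eff/mu) conserved by the pooled service rate
  eff0 <- effective_arrival_rates(net)
  occ0 <- sum(eff0 / net$units$service_rate)
  eff3 <- effective_arrival_rates(m3)
  occ3 <- sum(eff3 / m3$units$service_rate)
  expect_equal(occ3, occ0)
  # member occupancies 3.33 and 5.41 end up summed in the pooled unit
  pooled_occ <- eff3["N2+N3"] / m3$units$service_rate[m3$units$id == "N2+N3"]
  expect_equal(unname(pooled_occ),
               sum(eff0[c("N2", "N3")] / net$units$service_rate[3:4]))
})

test_that("the identity plan returns an equivalent network", {
  net <- perinatology_network()
  same <- apply_pooling(net, identity_plan(net))
  expect_equal(same$units$beds, net$units$beds)
  expect_equal(same$units$service_rate, net$units$service_rate)
  expect_equal(same$routing, net$routing)
  expect_equal(effective_arrival_rates(same), effective_arrival_rates(net))
})

test_that("pooling conserves total external inflow and sums member effective rates", {
  set.seed(11)
  for (k in 1:10) {
    net <- random_ff_network(n = sample(3:6, 1))
    ids <- net$units$id
    # pool two downstream leaves (no outgoing arcs) when available, else last two
    leaves <- ids[rowSums(net$routing) == 0]
    pair <- if (length(leaves) >= 2) utils::tail(leaves, 2) else utils::tail(ids, 2)
    singles <- setdiff(ids, pair)
    plan <- pooling_plan(c(stats::setNames(as.list(singles), singles),
                           list(G = pair)))
    pooled <- apply_pooling(net, plan)
    expect_equal(sum(pooled$units$external_rate), sum(net$units$external_rate))
    eff0 <- effective_arrival_rates(net)
    eff1 <- effective_arrival_rates(pooled)
    if (all(pair %in% leaves))
      expect_equal(unname(eff1["G"]), sum(eff0[pair]), tolerance = 1e-10)
  }
})

test_that("pooling rejects bad plans", {
  net <- perinatology_network()
  expect_error(pooling_plan(list(A = character(0))), "non-empty")
  expect_error(pooling_plan(list(A = "N1", B = c("N1", "N2"))), "exactly one group")
  expect_error(apply_pooling(net, pooling_plan(list(G = c("N1", "ZZ")))),
               "partition")
})

test_that("care_network validates units and routing", {
  expect_error(care_network(care_unit("A", beds = 0, service_rate = 1)),
               "positive integers")
  expect_error(care_network(care_unit("A", beds = 2, service_rate = 0)),
               "service rates")
  u2 <- dplyr::bind_rows(care_unit("A", 2, 1), care_unit("A", 3, 1))
  expect_error(care_network(u2), "unique")
  u <- dplyr::bind_rows(care_unit("A", 2, 1), care_unit("B", 3, 1))
  Rbad <- matrix(c(0, 0.6, 0.7, 0), 2, 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("A", "B")))
  diag(Rbad) <- c(0.1, 0)
  expect_error(care_network(u, Rbad), "diagonal")
  Rbig <- matrix(c(0, 1.2, 0, 0), 2, 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(care_network(u, Rbig), "\\[0, 1\\]")
})
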