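test_that("shannon_entropy on hand-checked distributions", {
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon_entropy(c(0.7, -0.1, 0.4)), "negative")
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
})

test_that("entropy is bounded by log2(n) with equality only for uniform", {
  set.seed(19)
  for (k in 1:50) {
    p <- random_distribution()
    n <- length(p)
    h <- shannon_entropy(p)
    expect_lte(h, log2(n) + 1e-12)
    expect_gte(h, 0)
    if (max(abs(p - 1 / n)) > 1e-3) expect_lt(h, log2(n) - 1e-9)
    expect_equal(shannon_entropy(rep(1 / n, n)), log2(n))
    # permutation invariance
    expect_equal(shannon_entropy(sample(p)), h)
  }
})

test_that("merging two outcomes loses exactly the within-group entropy", {
  set.seed(29)
  h2 <- function(q) shannon_entropy(c(q, 1 - q))
  for (k in 1:25) {
    p <- random_distribution(n = sample(3:8, 1))
    merged <- c(p[1] + p[2], p[-(1:2)])
    loss <- (p[1] + p[2]) * h2(p[1] / (p[1] + p[2]))
    expect_equal(shannon_entropy(p), shannon_entropy(merged) + loss)
  }
})

test_that("arrival entropy of the current configuration matches the published value", {
  ae <- arrival_entropy(c(4.0, 1.2, 0.2, 0.9, 2.7))
  expect_equal(round(ae$entropy_bits, 1), 1.9)
  expect_equal(round(ae$max_entropy_bits, 2), 2.32)
  expect_equal(sum(ae$relative_demand), 1)
  # network input route: fixture with printed rates and no routing
  ae2 <- arrival_entropy(perinatology_network("printed"))
  expect_equal(ae2$entropy_bits, ae$entropy_bits)
})

test_that("arrival entropy degenerate cases", {
  expect_equal(arrival_entropy(5)$entropy_bits, 0)
  expect_equal(arrival_entropy(5)$max_entropy_bits, 0)
  expect_error(arrival_entropy(c(0, 0, 0)), "all arrival rates are zero")
})

test_that("pooling any two units lowers the maximum arrival entropy", {
  set.seed(37)
  for (k in 1:10) {
    net <- random_ff_network(n = sample(3:6, 1))
    ids <- net$units$id
    pair <- sample(ids, 2)
    singles <- setdiff(ids, pair)
    plan <- pooling_plan(c(stats::setNames(as.list(singles), singles),
                           list(G = pair)))
    pooled <- apply_pooling(net, plan)
    expect_lt(arrival_entropy(pooled)$max_entropy_bits,
              arrival_entropy(net)$max_entropy_bits)
  }
})

test_that("positional entropy: one-hot, uniform, and the observed birth split", {
  expect_equal(positional_entropy(position_matrix(rbind(c(1, 0, 0))))$entropy_bits, 0)
  expect_equal(positional_entropy(position_matrix(rbind(rep(0.25, 4))))$entropy_bits, 2)
  birth <- position_matrix(rbind(birth = c(0.685, 0.158, 0.157)))
  expect_equal(round(positional_entropy(birth)$entropy_bits, 3), 1.214)
  # K uniform classes over N units: H = K log2 N, additive over classes
  K <- 3; N <- 5
  P <- position_matrix(matrix(1 / N, K, N))
  pe <- positional_entropy(P)
  expect_equal(pe$entropy_bits, K * log2(N))
  expect_equal(pe$entropy_bits, sum(pe$per_class))
  expect_error(position_matrix(rbind(c(0.5, 0.4))), "sum to 1")
})

test_that("the derived position matrix carries the fixture's birth routing", {
  pm <- derive_position_matrix(perinatology_network())
  expect_equal(unname(pm["entry_O3", c("O1", "N1", "N3")]),
               c(0.685, 0.158, 0.157))
  expect_equal(unname(rowSums(pm)), rep(1, nrow(pm)))
  # single entry stream fully routed to one unit -> one-hot row
  u <- list(care_unit("A", 2, 1, external_rate = 1), care_unit("B", 2, 1))
  R <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  pm2 <- derive_position_matrix(care_network(u, R))
  expect_equal(positional_entropy(pm2)$entropy_bits, 0)
  # cyclic networks have no canonical one-step derivation
  Rc <- matrix(c(0, 0.5, 0.5, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(derive_position_matrix(care_network(u, Rc)), "cyclic")
})

test_that("decision entropy sums per-maker entropies; uniform rows give log2 counts", {
  ds <- decision_structure(list(
    manager = c("TM_neo", "TM_obs"),
    TM_neo = c("s1", "s2", "s3"),
    TM_obs = c("s4", "s5")
  ))
  de <- decision_entropy(ds)
  expect_equal(de$entropy_bits, 1 + log2(3) + 1)
  expect_equal(round(de$entropy_bits, 1), 3.6)
  expect_equal(de$entropy_bits, sum(de$per_maker))
  empty <- decision_structure(list(solo = character(0)))
  expect_equal(decision_entropy(empty)$entropy_bits, 0)
  expect_error(decision_structure(list(a = c(a = 1))), "own source")
})

test_that("total entropy is the exact order-invariant sum of its components", {
  expect_equal(total_entropy(2.32, 4.16, 8), 14.48)
  expect_equal(total_entropy(0, 0, 0), 0)
  set.seed(41)
  for (k in 1:10) {
    x <- runif(3, 0, 10)
    expect_identical(total_entropy(x[1], x[2], x[3]), x[1] + x[2] + x[3])
    expect_equal(total_entropy(x[2], x[3], x[1]), sum(x))
  }
  # report objects: use_max picks the maximum-entropy variants
  ae <- arrival_entropy(c(4, 1.2, 0.2, 0.9, 2.7))
  pe <- positional_entropy(position_matrix(rbind(rep(0.25, 4))))
  de <- decision_entropy(decision_structure(list(a = c("x", "y"))))
  expect_equal(total_entropy(ae, pe, de),
               ae$entropy_bits + pe$entropy_bits + 1)
  expect_equal(total_entropy(ae, pe, de, use_max = TRUE),
               log2(5) + 2 + 1)
})
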