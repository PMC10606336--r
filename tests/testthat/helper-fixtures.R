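# Shared test fixtures and independent oracles.

# Random feed-forward network on <= 6 units: routing only from lower to
# higher index, row sums strictly below 1 so every patient can discharge.
random_ff_network <- function(n = sample(2:6, 1)) {
  ids <- paste0("U", seq_len(n))
  units <- dplyr::bind_rows(lapply(seq_len(n), function(i)
    care_unit(ids[i], beds = sample(2:20, 1),
              service_rate = runif(1, 0.05, 1),
              external_rate = runif(1, 0, 5),
              team = if (i %% 2) "neonatology" else "obstetrics",
              nurses = c(day = sample(1:12, 1), evening = sample(1:6, 1),
                         night = sample(1:6, 1)))))
  R <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    raw <- runif(n - i)
    R[i, (i + 1):n] <- raw / sum(raw) * runif(1, 0, 0.9)
  }
  care_network(units, R)
}

# Independent oracle for the traffic equations on acyclic networks:
# enumerate every routing path from each external entry until discharge,
# accumulating external rate times the path's probability at each unit.
path_sum_rates <- function(network) {
  R <- network$routing
  ids <- rownames(R)
  eff <- setNames(numeric(length(ids)), ids)
  walk <- function(u, w) {
    eff[u] <<- eff[u] + w
    for (v in ids) if (R[u, v] > 0) walk(v, w * R[u, v])
  }
  lam0 <- setNames(network$units$external_rate, ids)
  for (u in ids) if (lam0[u] > 0) walk(u, lam0[u])
  eff
}

# Random probability vector.
random_distribution <- function(n = sample(2:8, 1)) {
  x <- rexp(n)
  x / sum(x)
}

# Random two-team scenario for coordination-structure property tests;
# every staffed unit has at least one nurse on every shift.
random_team_network <- function(n = sample(2:7, 1)) {
  ids <- paste0("W", seq_len(n))
  teams <- sample(c("neonatology", "obstetrics"), n, replace = TRUE)
  teams[1] <- "neonatology"
  dplyr::bind_rows(lapply(seq_len(n), function(i)
    care_unit(ids[i], beds = sample(2:15, 1), service_rate = runif(1, 0.1, 1),
              external_rate = runif(1, 0.5, 4), team = teams[i],
              nurses = c(day = sample(1:12, 1), evening = sample(1:8, 1),
                         night = sample(1:8, 1))))) |>
    care_network()
}
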