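#' Simulation configuration
#'
#' @param horizon_days Number of simulated days (>= 1); the standard run
#'   uses a year (365).
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param arrival_model Daily arrival model; currently `"poisson_daily"`:
#'   each unit's external arrivals on each day are an independent Poisson
#'   draw at its external rate (pooled units draw each member component
#'   separately and sum, which is distributionally identical and keeps the
#'   demand stream comparable across pooling plans under a common seed).
#' @param routing How sampled daily arrivals propagate through the routing
#'   matrix: `"sampled"` (default) draws each day's transfers as
#'   binomial/multinomial counts, so each transferred patient is a discrete
#'   event; `"expected"` propagates the day's counts deterministically at
#'   the routing fractions (the traffic equations applied to the day's
#'   draws). Sampled routing requires a feed-forward (acyclic) network.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(horizon_days = 365L, seed = NULL,
                              arrival_model = "poisson_daily",
                              routing = c("sampled", "expected")) {
  routing <- match.arg(routing)
  arrival_model <- match.arg(arrival_model, "poisson_daily")
  horizon_days <- as.integer(horizon_days)
  if (is.na(horizon_days) || horizon_days < 1L)
    stop("horizon_days must be a positive integer", call. = FALSE)
  structure(list(horizon_days = horizon_days, seed = seed,
                 arrival_model = arrival_model, routing = routing),
            class = "simulation_config")
}

#' Daily Monte-Carlo occupancy simulation
#'
#' Simulates `horizon_days` days of varying demand. Each day, external
#' arrivals are drawn per unit, propagated through the routing matrix to
#' give that day's effective arrivals, and converted to an expected
#' occupancy \eqn{U_{iS} = \rho_{iS} c_i = \lambda_{iS}/\mu_i}. A unit with
#' \eqn{U_{iS} > c_i} is overutilized by \eqn{U_{iS} - c_i} beds that day;
#' otherwise it is underutilized by the complement. System-level
#' over/underutilization sums the positive parts across units, and the
#' number of days with any overutilization is the number of days on which
#' nurses must be reallocated.
#'
#' @param network A [care_network()].
#' @param config A [simulation_config()].
#' @return An object of class `care_sim` with elements
#'   \describe{
#'     \item{days}{tibble: one row per day per unit with sampled external
#'       arrivals, effective arrivals, utilization, occupancy, over and
#'       under beds;}
#'     \item{system}{tibble: per-day system over/under beds;}
#'     \item{summary}{tibble: mean and SD of daily system over- and
#'       underutilized beds, and `days_overutilized`;}
#'     \item{occupancy, arrivals, eff_arrivals}{day-by-unit matrices;}
#'     \item{network, config}{the inputs.}
#'   }
#' @examples
#' sim <- simulate_days(perinatology_network(),
#'                      simulation_config(horizon_days = 365, seed = 1))
#' sim$summary
#' @export
simulate_days <- function(network, config = simulation_config()) {
  stopifnot(inherits(network, "care_network"),
            inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  u <- network$units
  n <- nrow(u)
  d <- config$horizon_days
  ids <- u$id

  # external arrivals: one Poisson stream per demand component, summed by unit
  A <- matrix(0L, d, n, dimnames = list(NULL, ids))
  for (i in seq_len(n)) {
    for (rate in u$components[[i]]) {
      if (rate > 0) A[, i] <- A[, i] + stats::rpois(d, rate)
    }
  }

  R <- network$routing
  if (config$routing == "sampled") {
    ord <- topological_order(R)
    if (is.null(ord))
      stop("sampled routing requires a feed-forward network; ",
           "use routing = \"expected\" for cyclic routing", call. = FALSE)
    E <- A
    for (i in ord) {
      dest <- which(R[i, ] > 0)
      if (!length(dest)) next
      rem <- E[, i]
      pleft <- 1
      for (j in dest) {          # sequential binomial thinning == multinomial
        x <- stats::rbinom(d, rem, min(1, R[i, j] / pleft))
        E[, j] <- E[, j] + x
        rem <- rem - x
        pleft <- pleft - R[i, j]
      }
    }
  } else {
    if (any(R > 0)) {
      M <- solve(diag(n) - t(R))    # errors like effective_arrival_rates
      rho_spec <- max(Mod(eigen(R, only.values = TRUE)$values))
      if (rho_spec >= 1 - 1e-12)
        stop("unstable network: routing spectral radius >= 1 (cycle among ",
             paste(cycle_members(R), collapse = ", "), ")", call. = FALSE)
      E <- A %*% t(M)
    } else E <- A * 1.0
  }

  rho <- sweep(E, 2, u$beds * u$service_rate, "/")
  U <- sweep(E, 2, u$service_rate, "/")
  over <- pmax(sweep(U, 2, u$beds, "-"), 0)
  under <- pmax(-sweep(U, 2, u$beds, "-"), 0)
  sys_over <- rowSums(over)
  sys_under <- rowSums(under)

  days_tbl <- tibble::tibble(
    day = rep(seq_len(d), times = n),
    id = rep(ids, each = d),
    arrivals = as.vector(A),
    eff_arrivals = as.vector(E),
    utilization = as.vector(rho),
    occupancy = as.vector(U),
    over = as.vector(over),
    under = as.vector(under)
  )
  structure(list(
    days = days_tbl,
    system = tibble::tibble(day = seq_len(d), over = sys_over, under = sys_under),
    summary = tibble::tibble(
      mean_over = mean(sys_over), sd_over = stats::sd(sys_over),
      mean_under = mean(sys_under), sd_under = stats::sd(sys_under),
      days_overutilized = sum(sys_over > 0),
      horizon_days = d
    ),
    occupancy = U, arrivals = A, eff_arrivals = E,
    network = network, config = config
  ), class = "care_sim")
}

#' @export
print.care_sim <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<care_sim> %d day(s), %d unit(s)\n  overutilized beds/day  %.2f (+/- %.2f)\n  underutilized beds/day %.2f (+/- %.2f)\n  days with overutilization (nurse reallocation): %d\n",
    s$horizon_days, ncol(x$occupancy), s$mean_over, s$sd_over,
    s$mean_under, s$sd_under, s$days_overutilized))
  invisible(x)
}

#' Single-day bed mismatch
#'
#' The per-day arithmetic of the occupancy simulation for one unit: a day's
#' effective arrival rate is converted to utilization, expected occupancy,
#' and over/under beds.
#'
#' @inheritParams utilization
#' @return A tibble with `utilization`, `occupancy`, `over`, `under`;
#'   vectorized over the inputs.
#' @examples
#' bed_mismatch(0.3, beds = 4, service_rate = 0.06)  # 1 bed over
#' @export
bed_mismatch <- function(eff_arrival, beds, service_rate) {
  rho <- utilization(eff_arrival, beds, service_rate)
  U <- rho * beds
  tibble::tibble(utilization = rho, occupancy = U,
                 over = pmax(U - beds, 0), under = pmax(beds - U, 0))
}

#' Pearson correlation of daily unit censuses
#'
#' Pairwise Pearson correlation of the units' simulated daily occupancy
#' series — the portfolio view of which units' demands move together.
#' Pairs involving a constant (zero-variance) series have no defined
#' correlation; they are returned as `NA` and flagged in the `"undefined"`
#' attribute rather than propagating `NaN`.
#'
#' @param x A `care_sim` result (occupancy series are used) or a numeric
#'   day-by-unit matrix.
#' @param pairs Optional list of length-2 character vectors of unit ids;
#'   when supplied, a tibble of the requested pairs is returned instead of
#'   the full matrix.
#' @return A correlation matrix (diagonal 1) with an `"undefined"` logical
#'   matrix attribute, or a tibble `(a, b, correlation)` when `pairs` is
#'   given.
#' @export
census_correlation <- function(x, pairs = NULL) {
  M <- if (inherits(x, "care_sim")) x$occupancy else as.matrix(x)
  if (nrow(M) < 3L) stop("need at least 3 days to correlate censuses", call. = FALSE)
  v <- apply(M, 2, stats::var)
  C <- suppressWarnings(stats::cor(M))
  zero <- v <= 0
  undefined <- outer(zero, zero, `|`)
  diag(undefined) <- FALSE
  C[undefined] <- NA_real_
  diag(C) <- 1
  attr(C, "undefined") <- undefined
  if (any(undefined))
    warning("correlation undefined for zero-variance series: ",
            paste(colnames(M)[zero], collapse = ", "), call. = FALSE)
  if (is.null(pairs)) return(C)
  dplyr::bind_rows(lapply(pairs, function(p)
    tibble::tibble(a = p[1], b = p[2], correlation = C[p[1], p[2]])))
}

#' Variance effect of pooling correlated censuses
#'
#' For each group of a pooling plan, compares the variance of the pooled
#' daily occupancy with the sum of the members' variances. By the identity
#' \eqn{\mathrm{Var}(\sum X_i) = \sum \mathrm{Var}(X_i) + 2\sum_{i<j}
#' \mathrm{Cov}(X_i, X_j)}, negatively correlated members make the pooled
#' variance fall below the sum — the portfolio argument for pooling.
#'
#' @param result A `care_sim` result simulated on the *unpooled* network.
#' @param plan A [pooling_plan()] over that network's unit ids.
#' @return A tibble with one row per group: `pooled_var`, `sum_member_var`,
#'   `cov_term` (twice the summed pairwise covariances) and `reduction`
#'   (`sum_member_var - pooled_var`, positive when pooling dampens
#'   variance).
#' @export
pooling_variance_gain <- function(result, plan) {
  stopifnot(inherits(result, "care_sim"), inherits(plan, "pooling_plan"))
  M <- result$occupancy
  if (nrow(M) < 3L) stop("need at least 3 days", call. = FALSE)
  rows <- lapply(names(plan$groups), function(g) {
    members <- plan$groups[[g]]
    if (!all(members %in% colnames(M)))
      stop("plan group '", g, "' references unknown unit ids", call. = FALSE)
    sub <- M[, members, drop = FALSE]
    V <- stats::cov(sub)
    pooled <- stats::var(rowSums(sub))
    sum_var <- sum(diag(V))
    cov_term <- sum(V) - sum_var
    tibble::tibble(group = g, n_members = length(members),
                   pooled_var = pooled, sum_member_var = sum_var,
                   cov_term = cov_term, reduction = sum_var - pooled)
  })
  dplyr::bind_rows(rows)
}
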