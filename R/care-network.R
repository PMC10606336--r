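#' Define a single care unit
#'
#' A care unit is one ward of the care system, modelled as an M/M/c station:
#' patients arrive from outside the system at `external_rate` per day
#' (Poisson), stay for an exponentially distributed time with mean
#' `1/service_rate` days, and occupy one of `beds` staffed beds.
#'
#' @param id Short unique label, e.g. `"N1"`.
#' @param beds Number of staffed beds (positive integer).
#' @param service_rate Service rate in 1/day (> 0); the reciprocal of the
#'   mean length of stay.
#' @param external_rate External arrival rate in patients/day (>= 0).
#'   Arrivals routed from other units are added on top via the traffic
#'   equations; see [effective_arrival_rates()].
#' @param name Free-text unit name; defaults to `id`.
#' @param team Team-manager label the unit reports to (e.g. `"neonatology"`,
#'   `"obstetrics"`); used by the coordination-structure builders.
#' @param nurses Named numeric vector of nurses per shift with names among
#'   `day`, `evening`, `night`; missing shifts count as 0.
#'
#' @return A one-row tibble suitable for binding into the `units` argument
#'   of [care_network()].
#' @examples
#' care_unit("N1", beds = 14, service_rate = 0.10, external_rate = 0.6,
#'           team = "neonatology", nurses = c(day = 12, evening = 7, night = 8))
#' @export
care_unit <- function(id, beds, service_rate, external_rate = 0,
                      name = id, team = NA_character_,
                      nurses = c(day = 0, evening = 0, night = 0)) {
  stopifnot(is.character(id), length(id) == 1L)
  shifts <- c("day", "evening", "night")
  if (length(nurses) && (is.null(names(nurses)) || !all(names(nurses) %in% shifts)))
    stop("`nurses` must be named with shifts among day/evening/night", call. = FALSE)
  full <- stats::setNames(numeric(3), shifts)
  full[names(nurses)] <- nurses
  tibble::tibble(
    id = id, name = name, beds = beds,
    external_rate = external_rate, service_rate = service_rate,
    team = team,
    nurses_day = unname(full["day"]),
    nurses_evening = unname(full["evening"]),
    nurses_night = unname(full["night"])
  )
}

#' Assemble a care network from units and a routing matrix
#'
#' The care network is a (Jackson-type) queueing network: a set of M/M/c
#' units plus a routing matrix whose entry \eqn{r_{ij}} is the probability
#' that a patient leaving unit *i* is transferred to unit *j*. Row sums may
#' be below 1; the shortfall is the probability of leaving the system
#' (discharge home).
#'
#' @param units Data frame of units as produced by [care_unit()] (one row
#'   per unit), or a list of such rows.
#' @param routing Square numeric matrix with dimnames equal to the unit ids,
#'   zero diagonal, entries in \[0, 1\] and row sums <= 1. `NULL` means no
#'   inter-unit transfers.
#'
#' @return An object of class `care_network`: a list with elements `units`
#'   (tibble) and `routing` (matrix).
#' @seealso [effective_arrival_rates()], [apply_pooling()],
#'   [perinatology_network()]
#' @export
care_network <- function(units, routing = NULL) {
  if (is.list(units) && !is.data.frame(units)) units <- dplyr::bind_rows(units)
  units <- tibble::as_tibble(units)
  required <- c("id", "beds", "external_rate", "service_rate")
  missing_cols <- setdiff(required, names(units))
  if (length(missing_cols))
    stop("units is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!"name" %in% names(units)) units$name <- units$id
  if (!"team" %in% names(units)) units$team <- NA_character_
  for (sh in c("nurses_day", "nurses_evening", "nurses_night"))
    if (!sh %in% names(units)) units[[sh]] <- 0
  if (!"components" %in% names(units))
    units$components <- lapply(seq_len(nrow(units)), function(i)
      stats::setNames(units$external_rate[i], units$id[i]))
  n <- nrow(units)
  if (n < 1L) stop("a care network needs at least one unit", call. = FALSE)
  if (anyDuplicated(units$id)) stop("unit ids must be unique", call. = FALSE)
  if (any(units$beds < 1) || any(units$beds != round(units$beds)))
    stop("staffed beds must be positive integers", call. = FALSE)
  if (any(units$service_rate <= 0)) stop("service rates must be > 0", call. = FALSE)
  if (any(units$external_rate < 0)) stop("external arrival rates must be >= 0", call. = FALSE)
  if (is.null(routing)) {
    routing <- matrix(0, n, n, dimnames = list(units$id, units$id))
  } else {
    routing <- as.matrix(routing)
    if (!all(dim(routing) == c(n, n)))
      stop("routing dimensions must match the number of units", call. = FALSE)
    if (is.null(dimnames(routing))) dimnames(routing) <- list(units$id, units$id)
    if (!identical(rownames(routing), units$id))
      routing <- routing[units$id, units$id, drop = FALSE]
    if (any(routing < 0) || any(routing > 1))
      stop("routing probabilities must lie in [0, 1]", call. = FALSE)
    if (any(diag(routing) != 0))
      stop("routing diagonal must be zero (no self-transfers)", call. = FALSE)
    if (any(rowSums(routing) > 1 + 1e-9))
      stop("routing row sums must be <= 1 (shortfall = discharge probability)",
           call. = FALSE)
  }
  structure(list(units = units, routing = routing), class = "care_network")
}

#' @export
print.care_network <- function(x, ...) {
  cat(sprintf("<care_network> %d unit(s), %d routed transfer arc(s)\n",
              nrow(x$units), sum(x$routing > 0)))
  show <- x$units[, c("id", "name", "beds", "external_rate", "service_rate", "team")]
  print(show, n = Inf)
  invisible(x)
}

n_units <- function(network) nrow(network$units)
unit_ids <- function(network) network$units$id

# Kahn topological order of the routing graph; NULL if cyclic.
topological_order <- function(routing) {
  n <- nrow(routing)
  adj <- routing > 0
  indeg <- colSums(adj)
  order <- integer(0)
  avail <- which(indeg == 0)
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    order <- c(order, v)
    out <- which(adj[v, ])
    adj[v, ] <- FALSE
    indeg[out] <- indeg[out] - 1L
    avail <- c(avail, out[indeg[out] == 0])
  }
  if (length(order) < n) NULL else order
}

# Units involved in a cycle (for error messages): those not removable by Kahn.
cycle_members <- function(routing) {
  n <- nrow(routing)
  adj <- routing > 0
  repeat {
    drop <- which(rowSums(adj) == 0 | colSums(adj) == 0)
    drop <- drop[rowSums(adj)[drop] == 0 | colSums(adj)[drop] == 0]
    keep <- setdiff(seq_len(nrow(adj)), drop)
    if (length(keep) == nrow(adj)) break
    adj <- adj[keep, keep, drop = FALSE]
    if (!nrow(adj)) break
  }
  rownames(adj)
}

#' Solve the traffic equations for effective arrival rates
#'
#' The effective arrival rate of unit *i* is its external arrival rate plus
#' the inflow routed from the other units:
#' \deqn{\mathrm{Eff}\,\lambda_i = \lambda_{0i} + \sum_j \mathrm{Eff}\,\lambda_j\, r_{ji}.}
#' For feed-forward networks this equals single-pass propagation in
#' topological order; in general it is the unique solution of the linear
#' system \eqn{(I - R^\top)\,\lambda = \lambda_0}, which exists when the
#' spectral radius of the routing matrix is below 1 (every patient
#' eventually leaves the system).
#'
#' @param network A [care_network()].
#' @param external Optional replacement vector of external arrival rates
#'   (same order as the units); used by the day-by-day simulation to
#'   propagate one day's sampled arrivals. Defaults to the units' rates.
#' @return Named numeric vector of effective arrival rates (patients/day).
#' @examples
#' net <- perinatology_network()
#' effective_arrival_rates(net)
#' @export
effective_arrival_rates <- function(network, external = NULL) {
  stopifnot(inherits(network, "care_network"))
  R <- network$routing
  lam0 <- if (is.null(external)) network$units$external_rate else external
  stopifnot(length(lam0) == nrow(R))
  n <- nrow(R)
  if (any(R > 0)) {
    rho_spec <- max(Mod(eigen(R, only.values = TRUE)$values))
    if (rho_spec >= 1 - 1e-12) {
      cyc <- cycle_members(R)
      stop("unstable network: routing spectral radius >= 1 (cycle among ",
           paste(cyc, collapse = ", "), ")", call. = FALSE)
    }
  }
  eff <- solve(diag(n) - t(R), lam0)
  stats::setNames(as.numeric(eff), rownames(R))
}

#' Unit utilization under the traffic formula
#'
#' Utilization is \eqn{\rho = \lambda / (c \mu)}: the offered load relative
#' to capacity. Values above 1 signal overload (a meaningful output, not an
#' error); a unit is stable only when \eqn{\lambda < c\mu}.
#'
#' @param eff_arrival Effective arrival rate(s), patients/day (>= 0).
#' @param beds Staffed beds `c` (> 0).
#' @param service_rate Service rate `mu` in 1/day (> 0).
#' @return Numeric utilization fraction(s); vectorized over the inputs.
#' @examples
#' utilization(4.0, beds = 6, service_rate = 1.00)   # 0.667
#' utilization(0.9, beds = 11, service_rate = 0.19)  # 0.431
#' @export
utilization <- function(eff_arrival, beds, service_rate) {
  if (any(beds <= 0) || any(service_rate <= 0))
    stop("invalid unit: beds and service_rate must be > 0", call. = FALSE)
  if (any(eff_arrival < 0)) stop("eff_arrival must be >= 0", call. = FALSE)
  eff_arrival / (beds * service_rate)
}

#' @rdname utilization
#' @return `is_stable()` returns `TRUE` where \eqn{\lambda < c\mu}.
#' @export
is_stable <- function(eff_arrival, beds, service_rate) {
  eff_arrival < beds * service_rate
}

#' Per-unit utilization table
#'
#' Assembles the standard per-unit performance table: external arrival rate,
#' effective arrival rate from the traffic equations, staffed beds, service
#' rate and utilization.
#'
#' @param network A [care_network()].
#' @param rounded If `TRUE`, round rates to one decimal and utilization to a
#'   whole percent (the usual reporting convention); internal computation is
#'   always at full precision.
#' @return A tibble with one row per unit.
#' @export
utilization_table <- function(network, rounded = FALSE) {
  eff <- effective_arrival_rates(network)
  u <- network$units
  rho <- utilization(eff, u$beds, u$service_rate)
  out <- tibble::tibble(
    id = u$id, name = u$name,
    external_rate = u$external_rate,
    eff_arrival = as.numeric(eff),
    beds = u$beds, service_rate = u$service_rate,
    utilization = unname(rho),
    stable = unname(is_stable(eff, u$beds, u$service_rate))
  )
  if (rounded) {
    out$external_rate <- round(out$external_rate, 1)
    out$eff_arrival <- round(out$eff_arrival, 1)
    out$utilization_pct <- round(100 * out$utilization)
  }
  out
}
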