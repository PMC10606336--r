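#' Define a pooling plan
#'
#' A pooling plan partitions the unit ids into named groups; each group
#' becomes a single pooled unit (combined beds, demand and staff). The
#' optional team assignment says which team manager a pooled group reports
#' to in the hierarchy coordination structure.
#'
#' @param groups Named list of character vectors partitioning the unit ids.
#'   A single id may be given as a bare string.
#' @param team_assignment Optional named character vector mapping group
#'   names to team labels (e.g. `c("N2+N3" = "neonatology")`). Groups whose
#'   members share a team inherit it; mixed groups default to
#'   `"neonatology"` unless assigned here.
#' @return An object of class `pooling_plan`.
#' @examples
#' pooling_plan(list(O3 = "O3", N1 = "N1", "N2+N3" = c("N2", "N3"), O1 = "O1"))
#' @export
pooling_plan <- function(groups, team_assignment = NULL) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  groups <- lapply(groups, as.character)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- vapply(groups, paste, "", collapse = "+")
  if (any(lengths(groups) == 0L)) stop("every group must be non-empty", call. = FALSE)
  all_ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("every unit id must appear in exactly one group", call. = FALSE)
  structure(list(groups = groups, team_assignment = team_assignment),
            class = "pooling_plan")
}

#' @export
print.pooling_plan <- function(x, ...) {
  cat("<pooling_plan>\n")
  for (g in names(x$groups))
    cat(sprintf("  %s: {%s}\n", g, paste(x$groups[[g]], collapse = ", ")))
  invisible(x)
}

#' The identity plan: every unit its own group
#' @param network A [care_network()].
#' @return A [pooling_plan()] leaving the network unchanged.
#' @export
identity_plan <- function(network) {
  ids <- unit_ids(network)
  pooling_plan(stats::setNames(as.list(ids), ids))
}

#' Pool units of a care network
#'
#' Returns the redesigned network with one unit per group of the plan.
#' Combining units combines the demand and the capacity associated with
#' them:
#' * pooled staffed beds, external arrival rates and nurses per shift are
#'   the sums over members;
#' * pooled routing uses an arrival-weighted merge,
#'   \eqn{r_{GH} = \sum_{i \in G} w_i \sum_{j \in H} r_{ij}} with weights
#'   \eqn{w_i = \mathrm{Eff}\lambda_i / \sum_{G} \mathrm{Eff}\lambda_i};
#'   transfers inside a pooled group are dropped (no longer transfers);
#' * the pooled service rate is the arrival-weighted harmonic mean of the
#'   members' service rates, so that the pooled expected occupancy
#'   \eqn{\sum_g \lambda_g/\mu_g} is conserved.
#'
#' The pooled network keeps each member's external demand stream as a
#' separate component (summed at simulation time), so that simulations of
#' different pooling plans under the same seed see the same realized demand.
#'
#' @param network A [care_network()].
#' @param plan A [pooling_plan()] partitioning the network's unit ids.
#' @param routing Optional full replacement routing matrix for the pooled
#'   network (e.g. re-measured transfer fractions), overriding the
#'   arrival-weighted merge.
#' @return A new [care_network()] with one unit per group, ordered by each
#'   group's first member's position in the input network.
#' @examples
#' net <- perinatology_network()
#' apply_pooling(net, perinatology_plans()[["Model 3"]])
#' @export
apply_pooling <- function(network, plan, routing = NULL) {
  stopifnot(inherits(network, "care_network"), inherits(plan, "pooling_plan"))
  ids <- unit_ids(network)
  member_ids <- unlist(plan$groups, use.names = FALSE)
  if (!setequal(member_ids, ids))
    stop("plan must partition exactly the network's unit ids; unknown or missing: ",
         paste(union(setdiff(member_ids, ids), setdiff(ids, member_ids)),
               collapse = ", "), call. = FALSE)
  u <- network$units
  eff <- effective_arrival_rates(network)
  # keep original unit order: group position = first member's position
  first_pos <- vapply(plan$groups, function(g) min(match(g, ids)), 0)
  gnames <- names(plan$groups)[order(first_pos)]
  groups <- plan$groups[gnames]

  rows <- lapply(gnames, function(g) {
    m <- match(groups[[g]], ids)
    occ <- sum(eff[m] / u$service_rate[m])
    mu_pooled <- if (occ > 0) sum(eff[m]) / occ else
      sum(u$service_rate[m] * u$beds[m]) / sum(u$beds[m])
    team <- unique(u$team[m])
    team <- if (!is.null(plan$team_assignment) && g %in% names(plan$team_assignment))
      unname(plan$team_assignment[[g]])
    else if (length(team) == 1L) team
    else "neonatology"
    tibble::tibble(
      id = g,
      name = if (length(m) == 1L) u$name[m] else paste(u$name[m], collapse = " + "),
      beds = sum(u$beds[m]),
      external_rate = sum(u$external_rate[m]),
      service_rate = mu_pooled,
      team = team,
      nurses_day = sum(u$nurses_day[m]),
      nurses_evening = sum(u$nurses_evening[m]),
      nurses_night = sum(u$nurses_night[m]),
      components = list(do.call(c, unname(u$components[m])))
    )
  })
  units_new <- dplyr::bind_rows(rows)

  if (is.null(routing)) {
    G <- length(gnames)
    Rp <- matrix(0, G, G, dimnames = list(gnames, gnames))
    R <- network$routing
    for (a in seq_len(G)) {
      ma <- match(groups[[a]], ids)
      w <- eff[ma]
      w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(ma), length(ma))
      for (b in seq_len(G)) {
        if (a == b) next
        mb <- match(groups[[b]], ids)
        Rp[a, b] <- sum(w * rowSums(R[ma, mb, drop = FALSE]))
      }
    }
    routing <- Rp
  }
  care_network(units_new, routing)
}
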