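#' Decision structure of a coordination strategy
#'
#' A bipartite description of who processes information from which sources:
#' for each decision maker, a probability distribution over its information
#' sources. Under the maximum-entropy principle the package's builders use
#' uniform distributions — no source is assumed more likely than another
#' unless data say so.
#'
#' @param sources Named list: one element per decision maker, each a named
#'   numeric probability vector over its sources (possibly empty). A
#'   character vector may be given instead and is expanded to the uniform
#'   distribution over those sources.
#' @param roles Optional named character vector of maker roles
#'   (`"manager"`, `"team_manager"`, `"planner"`).
#' @return An object of class `decision_structure`.
#' @examples
#' ds <- decision_structure(list(
#'   manager = c("TM neonatology", "TM obstetrics"),
#'   "TM neonatology" = c("N1", "N2", "N3")
#' ))
#' decision_entropy(ds)
#' @export
decision_structure <- function(sources, roles = NULL) {
  stopifnot(is.list(sources))
  if (is.null(names(sources)) || any(!nzchar(names(sources))))
    stop("every decision maker needs a name", call. = FALSE)
  sources <- lapply(sources, function(p) {
    if (is.character(p)) p <- stats::setNames(rep(1 / length(p), length(p)), p)
    if (length(p) && abs(sum(p) - 1) > 1e-6)
      stop("each maker's source distribution must sum to 1", call. = FALSE)
    if (any(p < 0)) stop("source probabilities must be >= 0", call. = FALSE)
    p
  })
  for (a in names(sources))
    if (a %in% names(sources[[a]]))
      stop("decision maker '", a, "' cannot be its own source", call. = FALSE)
  structure(list(sources = sources, roles = roles), class = "decision_structure")
}

#' @export
print.decision_structure <- function(x, ...) {
  cat(sprintf("<decision_structure> %d decision maker(s)\n", length(x$sources)))
  for (a in names(x$sources)) {
    p <- x$sources[[a]]
    cat(sprintf("  %s <- %d source(s)%s\n", a, length(p),
                if (length(p)) paste0(" [", paste(names(p), collapse = ", "), "]")
                else ""))
  }
  invisible(x)
}

nurse_count <- function(units, shift) {
  col <- paste0("nurses_", shift)
  stopifnot(col %in% names(units))
  stats::setNames(units[[col]], units$id)
}

nurse_sources <- function(unit_id, count) {
  if (count < 1) character(0) else paste0("nurse_", unit_id, "_", seq_len(count))
}

resolve_network_plan <- function(network, plan) {
  if (is.null(plan)) network else apply_pooling(network, plan)
}

uniform_or_empty <- function(src) {
  if (length(src) == 0L) stats::setNames(numeric(0), character(0)) else src
}

#' Build the hierarchy coordination structure
#'
#' Decision power sits at the top of the pyramid: nurses report to unit
#' planners, planners to one team manager per team, team managers to a
#' single manager. With aggregated information the nurse-level detail
#' collapses to one workload signal per unit: team managers read their
#' units' aggregate signals directly (planners then contribute 0 bits) and
#' the manager reads the team managers. Without aggregation, each planner
#' reads its unit's individual nurses of the chosen shift, each team
#' manager its planners, and the manager the team managers. All
#' distributions are uniform.
#'
#' @param network A [care_network()]; pooled units carry summed nurse
#'   counts and the team assigned by the plan.
#' @param plan Optional [pooling_plan()] applied to `network` first.
#' @param aggregated Use unit-level aggregate workload signals instead of
#'   nurse-level detail.
#' @param shift Which shift's nurse counts feed the nurse-level sources.
#' @return A [decision_structure()].
#' @examples
#' ds <- build_hierarchy(perinatology_network(), aggregated = TRUE)
#' decision_entropy(ds)$entropy_bits  # log2(2) + log2(3) + log2(2) = 3.585
#' @export
build_hierarchy <- function(network, plan = NULL, aggregated = TRUE,
                            shift = c("day", "evening", "night")) {
  shift <- match.arg(shift)
  net <- resolve_network_plan(network, plan)
  u <- net$units
  if (any(is.na(u$team)))
    stop("every unit needs a team for the hierarchy structure", call. = FALSE)
  teams <- unique(u$team)
  tm <- function(t) paste0("TM_", t)
  sources <- list()
  roles <- c()
  if (aggregated) {
    for (t in teams) {
      sources[[tm(t)]] <- paste0("signal_", u$id[u$team == t])
      roles[tm(t)] <- "team_manager"
    }
  } else {
    counts <- nurse_count(u, shift)
    for (i in seq_len(nrow(u))) {
      pl <- paste0("planner_", u$id[i])
      src <- nurse_sources(u$id[i], counts[[u$id[i]]])
      if (!length(src)) {
        warning("unit ", u$id[i], " has no ", shift,
                "-shift nurses; its planner contributes 0 bits", call. = FALSE)
        src <- paste0("empty_", u$id[i])
      }
      sources[[pl]] <- src
      roles[pl] <- "planner"
    }
    for (t in teams) {
      sources[[tm(t)]] <- paste0("planner_", u$id[u$team == t])
      roles[tm(t)] <- "team_manager"
    }
  }
  sources[["manager"]] <- vapply(teams, tm, "")
  roles["manager"] <- "manager"
  decision_structure(sources, roles = roles)
}

#' Build the network (peer-to-peer) coordination structure
#'
#' Decision power sits with the unit planners, who contact each other
#' directly. With aggregated information each planner reads the other
#' units' aggregate workload signals — with `A` units the structure's
#' entropy is `A * log2(A - 1)`. Without aggregation each planner reads the
#' other units' individual nurses of the chosen shift. A single-unit
#' network has no counterpart to contact and yields an empty structure.
#'
#' @inheritParams build_hierarchy
#' @return A [decision_structure()].
#' @export
build_network <- function(network, plan = NULL, aggregated = TRUE,
                          shift = c("day", "evening", "night")) {
  shift <- match.arg(shift)
  net <- resolve_network_plan(network, plan)
  u <- net$units
  sources <- list()
  roles <- c()
  counts <- if (!aggregated) nurse_count(u, shift)
  for (i in seq_len(nrow(u))) {
    pl <- paste0("planner_", u$id[i])
    others <- u$id[-i]
    src <- if (aggregated) {
      if (length(others)) paste0("signal_", others) else character(0)
    } else {
      unlist(lapply(others, function(j) nurse_sources(j, counts[[j]])),
             use.names = FALSE)
    }
    sources[[pl]] <- uniform_or_empty(src)
    roles[pl] <- "planner"
  }
  decision_structure(sources, roles = roles)
}

#' Build the hub coordination structure
#'
#' Decision power sits with the unit planners, supported by a centralized
#' information system. With aggregated information each planner's sole
#' source is the central aggregate record — a degenerate distribution, so
#' the structure carries 0 bits. Without aggregation each planner still
#' decides which detailed records matter and reads its own unit's
#' nurse-level records feeding the central system.
#'
#' @inheritParams build_hierarchy
#' @return A [decision_structure()].
#' @export
build_hub <- function(network, plan = NULL, aggregated = TRUE,
                      shift = c("day", "evening", "night")) {
  shift <- match.arg(shift)
  net <- resolve_network_plan(network, plan)
  u <- net$units
  sources <- list()
  roles <- c()
  counts <- if (!aggregated) nurse_count(u, shift)
  for (i in seq_len(nrow(u))) {
    pl <- paste0("planner_", u$id[i])
    src <- if (aggregated) "central_aggregate"
           else uniform_or_empty(nurse_sources(u$id[i], counts[[u$id[i]]]))
    sources[[pl]] <- src
    roles[pl] <- "planner"
  }
  decision_structure(sources, roles = roles)
}

#' Decision entropies of all coordination strategies
#'
#' Convenience wrapper: builds the hierarchy, network and hub structures
#' for a (possibly pooled) network and returns their entropies.
#'
#' @inheritParams build_hierarchy
#' @param strategies Subset of `c("hierarchy", "network", "hub")`.
#' @param aggregated Logical vector; both `TRUE` and `FALSE` may be given.
#' @return Tibble with columns `strategy`, `aggregated`, `entropy_bits`.
#' @export
coordination_entropies <- function(network, plan = NULL,
                                   strategies = c("hierarchy", "network", "hub"),
                                   aggregated = c(TRUE, FALSE),
                                   shift = "day") {
  strategies <- match.arg(strategies, several.ok = TRUE)
  builders <- list(hierarchy = build_hierarchy, network = build_network,
                   hub = build_hub)
  grid <- expand.grid(strategy = strategies, aggregated = aggregated,
                      stringsAsFactors = FALSE)
  bits <- mapply(function(s, a) {
    decision_entropy(builders[[s]](network, plan, aggregated = a,
                                   shift = shift))$entropy_bits
  }, grid$strategy, grid$aggregated)
  tibble::tibble(strategy = grid$strategy, aggregated = grid$aggregated,
                 entropy_bits = as.numeric(bits))
}

#' Export a decision structure as a DOT graph
#'
#' @param structure A [decision_structure()].
#' @param name Graph name.
#' @return A character scalar with DOT source (render with Graphviz).
#' @export
structure_to_dot <- function(structure, name = "decision_structure") {
  stopifnot(inherits(structure, "decision_structure"))
  q <- function(x) paste0('"', gsub('"', "'", x), '"')
  lines <- c(sprintf("digraph %s {", q(name)), "  rankdir=BT;")
  for (a in names(structure$sources)) {
    p <- structure$sources[[a]]
    for (b in names(p))
      lines <- c(lines, sprintf("  %s -> %s [label=\"%.3g\"];", q(b), q(a), p[[b]]))
  }
  paste(c(lines, "}"), collapse = "\n")
}
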