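#' Scenario configuration
#'
#' Bundles everything needed for a full design comparison: the care
#' network, the named candidate pooling plans, the simulation settings,
#' an optional explicit position matrix for the unpooled configuration,
#' and the coordination strategies to evaluate. An identity plan (every
#' unit its own group) is always present; if none of the supplied plans is
#' one, it is added under the name `"Model 1"`.
#'
#' @param network A [care_network()].
#' @param pooling_models Named list of [pooling_plan()] objects.
#' @param simulation A [simulation_config()].
#' @param position_matrix Optional [position_matrix()] used for the
#'   identity configuration instead of [derive_position_matrix()].
#' @param strategies Coordination strategies to evaluate.
#' @param aggregated Information-aggregation levels to evaluate.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(network,
                            pooling_models = list(),
                            simulation = simulation_config(),
                            position_matrix = NULL,
                            strategies = c("hierarchy", "network", "hub"),
                            aggregated = c(TRUE, FALSE)) {
  stopifnot(inherits(network, "care_network"),
            inherits(simulation, "simulation_config"))
  strategies <- match.arg(strategies, several.ok = TRUE)
  ids <- unit_ids(network)
  if (length(pooling_models) &&
      (is.null(names(pooling_models)) || any(!nzchar(names(pooling_models)))))
    stop("pooling_models must be a named list", call. = FALSE)
  for (nm in names(pooling_models)) {
    plan <- pooling_models[[nm]]
    if (!inherits(plan, "pooling_plan"))
      stop("pooling_models[['", nm, "']] is not a pooling_plan", call. = FALSE)
    members <- unlist(plan$groups, use.names = FALSE)
    if (!setequal(members, ids))
      stop("pooling_models[['", nm, "']] does not partition the network's unit ids",
           call. = FALSE)
  }
  is_identity <- vapply(pooling_models, function(p)
    all(lengths(p$groups) == 1L), logical(1))
  if (!any(is_identity)) {
    nm <- if ("Model 1" %in% names(pooling_models)) "unpooled" else "Model 1"
    pooling_models <- c(stats::setNames(list(identity_plan(network)), nm),
                        pooling_models)
  }
  structure(list(network = network, pooling_models = pooling_models,
                 simulation = simulation, position_matrix = position_matrix,
                 strategies = strategies, aggregated = aggregated),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %d unit(s), %d pooling model(s), horizon %d day(s)\n",
              n_units(x$network), length(x$pooling_models),
              x$simulation$horizon_days))
  invisible(x)
}

scenario_field_error <- function(path, msg) {
  stop("scenario config error at ", path, ": ", msg, call. = FALSE)
}

#' Read / write a scenario configuration as YAML
#'
#' The on-disk format is a plain YAML document with blocks `units:` (list
#' of `{id, name, beds, external_rate, service_rate, team, nurses: {day,
#' evening, night}}`), `routing:` (sparse list of `{from, to, p}`),
#' `pooling_models:` (named plans with `groups:` and optional `team:`) and
#' `simulation:`. `save_scenario()` followed by `load_scenario()` restores
#' the scenario exactly (canonical form).
#'
#' @param path File path.
#' @return `load_scenario()` returns a [scenario_config()].
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' save_scenario(perinatology_scenario(), path)
#' load_scenario(path)
#' @export
load_scenario <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$units) || !length(doc$units))
    scenario_field_error("units", "at least one unit is required")
  units <- lapply(seq_along(doc$units), function(i) {
    u <- doc$units[[i]]
    where <- sprintf("units[%d]", i)
    for (f in c("id", "beds", "service_rate"))
      if (is.null(u[[f]])) scenario_field_error(paste0(where, ".", f), "missing")
    nurses <- unlist(u$nurses %||% list())
    tryCatch(
      care_unit(id = u$id, beds = u$beds, service_rate = u$service_rate,
                external_rate = u$external_rate %||% 0,
                name = u$name %||% u$id, team = u$team %||% NA_character_,
                nurses = if (length(nurses)) nurses else c(day = 0)),
      error = function(e) scenario_field_error(where, conditionMessage(e)))
  })
  units <- dplyr::bind_rows(units)
  ids <- units$id
  R <- matrix(0, nrow(units), nrow(units), dimnames = list(ids, ids))
  for (i in seq_along(doc$routing)) {
    arc <- doc$routing[[i]]
    where <- sprintf("routing[%d]", i)
    for (f in c("from", "to", "p"))
      if (is.null(arc[[f]])) scenario_field_error(paste0(where, ".", f), "missing")
    if (!arc$from %in% ids) scenario_field_error(paste0(where, ".from"),
                                                 paste("unknown unit", arc$from))
    if (!arc$to %in% ids) scenario_field_error(paste0(where, ".to"),
                                               paste("unknown unit", arc$to))
    R[arc$from, arc$to] <- arc$p
  }
  network <- tryCatch(care_network(units, R),
                      error = function(e) scenario_field_error("routing",
                                                               conditionMessage(e)))
  plans <- list()
  for (nm in names(doc$pooling_models)) {
    pm <- doc$pooling_models[[nm]]
    where <- sprintf("pooling_models['%s']", nm)
    if (is.null(pm$groups)) scenario_field_error(paste0(where, ".groups"), "missing")
    team <- if (!is.null(pm$team)) unlist(pm$team)
    plans[[nm]] <- tryCatch(pooling_plan(pm$groups, team_assignment = team),
                            error = function(e)
                              scenario_field_error(where, conditionMessage(e)))
  }
  sim <- doc$simulation %||% list()
  simulation <- tryCatch(
    simulation_config(horizon_days = sim$horizon_days %||% 365L,
                      seed = sim$seed,
                      routing = sim$routing %||% "sampled"),
    error = function(e) scenario_field_error("simulation", conditionMessage(e)))
  pm <- NULL
  if (!is.null(doc$position_matrix)) {
    p <- doc$position_matrix
    if (is.null(p$probabilities) || is.null(p$positions))
      scenario_field_error("position_matrix", "needs positions and probabilities")
    mat <- do.call(rbind, p$probabilities)
    colnames(mat) <- unlist(p$positions)
    pm <- tryCatch(position_matrix(mat, classes = unlist(p$classes)),
                   error = function(e)
                     scenario_field_error("position_matrix", conditionMessage(e)))
  }
  scenario_config(network, plans, simulation, position_matrix = pm,
                  strategies = unlist(doc$strategies) %||%
                    c("hierarchy", "network", "hub"),
                  aggregated = unlist(doc$aggregated) %||% c(TRUE, FALSE))
}

#' @rdname load_scenario
#' @param config A [scenario_config()].
#' @export
save_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  u <- config$network$units
  units <- lapply(seq_len(nrow(u)), function(i) {
    out <- list(id = u$id[i], name = u$name[i], beds = u$beds[i],
                external_rate = u$external_rate[i],
                service_rate = u$service_rate[i],
                nurses = list(day = u$nurses_day[i],
                              evening = u$nurses_evening[i],
                              night = u$nurses_night[i]))
    if (!is.na(u$team[i])) out$team <- u$team[i]
    out
  })
  R <- config$network$routing
  arcs <- which(R > 0, arr.ind = TRUE)
  routing <- lapply(seq_len(nrow(arcs)), function(k)
    list(from = rownames(R)[arcs[k, 1]], to = colnames(R)[arcs[k, 2]],
         p = R[arcs[k, 1], arcs[k, 2]]))
  plans <- lapply(config$pooling_models, function(p) {
    out <- list(groups = p$groups)
    if (!is.null(p$team_assignment)) out$team <- as.list(p$team_assignment)
    out
  })
  doc <- list(units = units, routing = routing, pooling_models = plans,
              simulation = list(horizon_days = config$simulation$horizon_days,
                                seed = config$simulation$seed,
                                routing = config$simulation$routing),
              strategies = config$strategies,
              aggregated = config$aggregated)
  if (!is.null(config$position_matrix)) {
    P <- unclass(config$position_matrix)
    doc$position_matrix <- list(
      classes = rownames(P), positions = colnames(P),
      probabilities = lapply(seq_len(nrow(P)), function(i) unname(P[i, ])))
  }
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specification for a synthetic scenario
#'
#' @param n_units Number of units (>= 2).
#' @param external_range,service_range Ranges the unit rates are drawn
#'   from (uniform), patients/day and 1/day.
#' @param beds_range Range of staffed beds (integer).
#' @param target_correlation Target pairwise correlation of the daily
#'   demand series, in (-1, 1). Achieved by adding a signed common-mode
#'   component on top of independent Poisson noise; with more than two
#'   units and a negative target, units alternate the sign of their
#'   common-mode loading, so only opposite-sign pairs are negatively
#'   correlated.
#' @param horizon_days Length of the generated daily demand series.
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_units = 2L, external_range = c(2, 8),
                           service_range = c(0.1, 1), beds_range = c(4, 20),
                           target_correlation = 0, horizon_days = 10000L,
                           seed = 1L) {
  if (n_units < 2L) stop("n_units must be >= 2", call. = FALSE)
  if (abs(target_correlation) >= 1)
    stop("unattainable correlation target: |target| must be < 1", call. = FALSE)
  structure(list(n_units = as.integer(n_units),
                 external_range = external_range,
                 service_range = service_range, beds_range = beds_range,
                 target_correlation = target_correlation,
                 horizon_days = as.integer(horizon_days),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic scenario with controlled demand correlation
#'
#' Draws unit parameters uniformly from the spec's ranges and builds a
#' daily demand series per unit as independent Poisson noise plus a signed,
#' mean-centred common-mode component whose intensity is calibrated so the
#' pairwise demand correlation matches the target (exactly in expectation;
#' empirically within sampling error of the horizon). Useful for studying
#' pooling's portfolio effect without historical census data. Units get
#' alternating team labels and a simple nurse roster (about one day nurse
#' per three beds, at least one per shift) so coordination structures can
#' be built on them.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `config` (a [scenario_config()]) and `demand`
#'   (day-by-unit matrix of the generated series; mean-centred common-mode
#'   swings can make strongly anti-correlated series dip below zero).
#' @examples
#' syn <- generate_synthetic(synthetic_spec(2, target_correlation = -0.5,
#'                                          horizon_days = 2000))
#' cor(syn$demand)[1, 2]
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_units
  lam <- stats::runif(n, spec$external_range[1], spec$external_range[2])
  mu <- stats::runif(n, spec$service_range[1], spec$service_range[2])
  beds <- sample(seq(spec$beds_range[1], spec$beds_range[2]), n, replace = TRUE)
  ids <- sprintf("U%02d", seq_len(n))
  r <- spec$target_correlation
  s <- if (r >= 0) rep(1, n) else rep_len(c(1, -1), n)
  nu <- 0
  if (abs(r) > 0) {
    # mean pairwise |corr| = mean over i<j of nu / sqrt((lam_i+nu)(lam_j+nu))
    pair_mean <- function(nu) {
      cs <- utils::combn(n, 2)
      mean(nu / sqrt((lam[cs[1, ]] + nu) * (lam[cs[2, ]] + nu)))
    }
    nu <- stats::uniroot(function(x) pair_mean(x) - abs(r),
                         lower = 1e-9, upper = 1e6 * max(lam))$root
  }
  d <- spec$horizon_days
  base <- matrix(stats::rpois(d * n, rep(lam, each = d)), d, n,
                 dimnames = list(NULL, ids))
  demand <- base
  if (nu > 0) {
    common <- stats::rpois(d, nu) - nu
    demand <- base + outer(common, s)
  }
  teams <- rep_len(c("neonatology", "obstetrics"), n)
  units <- dplyr::bind_rows(lapply(seq_len(n), function(i)
    care_unit(ids[i], beds = beds[i], service_rate = mu[i],
              external_rate = lam[i], team = teams[i],
              nurses = c(day = max(1, round(beds[i] / 3)),
                         evening = max(1, round(beds[i] / 4)),
                         night = max(1, round(beds[i] / 4))))))
  config <- scenario_config(
    care_network(units),
    simulation = simulation_config(horizon_days = spec$horizon_days,
                                   seed = spec$seed))
  list(config = config, demand = demand)
}

#' Run the full design comparison
#'
#' For every pooling model of the scenario: simulates the pooled network
#' (same seed for every model, so all models face the same realized demand
#' stream), computes the arrival entropy and its maximum, derives the
#' positional entropy and its maximum, builds the requested coordination
#' structures at both aggregation levels and computes their decision
#' entropies, and forms the total entropy per the summary convention
#' (maximum arrival + maximum positional + decision). The design with the
#' minimal total entropy is flagged.
#'
#' @param config A [scenario_config()].
#' @param shift Shift whose nurse counts feed non-aggregated structures.
#' @return An object of class `care_comparison`: list with `report` (one
#'   row per model x strategy x aggregation), `simulations` (per-model
#'   `care_sim` summaries), and `optimal` (the minimal-total-entropy row).
#' @examples
#' \donttest{
#' cmp <- run_full_comparison(perinatology_scenario(seed = 1))
#' cmp$optimal
#' }
#' @export
run_full_comparison <- function(config, shift = "day") {
  stopifnot(inherits(config, "scenario_config"))
  models <- names(config$pooling_models)
  sims <- list()
  rows <- list()
  for (m in models) {
    plan <- config$pooling_models[[m]]
    pooled <- apply_pooling(config$network, plan)
    sim <- simulate_days(pooled, config$simulation)
    sims[[m]] <- sim
    ae <- arrival_entropy(pooled)
    is_identity <- all(lengths(plan$groups) == 1L)
    pe <- tryCatch({
      pm <- if (is_identity && !is.null(config$position_matrix))
        config$position_matrix else derive_position_matrix(pooled)
      positional_entropy(pm)
    }, error = function(e) NULL)
    ce <- coordination_entropies(pooled, strategies = config$strategies,
                                 aggregated = config$aggregated, shift = shift)
    s <- sim$summary
    rows[[m]] <- tibble::tibble(
      model = m,
      strategy = ce$strategy,
      aggregated = ce$aggregated,
      n_units = n_units(pooled),
      days_overutilized = s$days_overutilized,
      mean_over = s$mean_over, sd_over = s$sd_over,
      mean_under = s$mean_under, sd_under = s$sd_under,
      arrival_bits = ae$entropy_bits,
      arrival_max_bits = ae$max_entropy_bits,
      positional_bits = if (is.null(pe)) NA_real_ else pe$entropy_bits,
      positional_max_bits = if (is.null(pe)) NA_real_ else pe$max_entropy_bits,
      decision_bits = ce$entropy_bits,
      total_bits = ae$max_entropy_bits +
        (if (is.null(pe)) 0 else pe$max_entropy_bits) + ce$entropy_bits
    )
  }
  report <- dplyr::bind_rows(rows)
  optimal <- report[which.min(report$total_bits), ]
  structure(list(report = report, simulations = sims, optimal = optimal,
                 scenario = config),
            class = "care_comparison")
}

#' @export
print.care_comparison <- function(x, ...) {
  cat("<care_comparison>\n")
  print(x$report, n = Inf)
  cat(sprintf("\noptimal design: %s, %s strategy, %s information (%.2f bits)\n",
              x$optimal$model, x$optimal$strategy,
              if (x$optimal$aggregated) "aggregated" else "detailed",
              x$optimal$total_bits))
  invisible(x)
}

#' Write a comparison report to CSV
#'
#' @param comparison A `care_comparison` from [run_full_comparison()].
#' @param file Output path.
#' @export
write_comparison_csv <- function(comparison, file) {
  stopifnot(inherits(comparison, "care_comparison"))
  utils::write.csv(comparison$report, file, row.names = FALSE)
  invisible(file)
}
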