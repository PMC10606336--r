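#' Built-in perinatology care-system fixture
#'
#' A five-unit newborn-flow network: delivery room (O3), neonatal intensive
#' care (N1), neonatal post-intensive care (N2), neonatal high/medium care
#' (N3) and the obstetric nursery ward (O1). Two rate variants are
#' provided:
#'
#' * `"derived"` (default): external arrival rates are the observed entry
#'   streams (4.0 births/day at the delivery room, 0.6/day external NICU
#'   admissions, 0.4/day external HC/MC admissions) and the routing matrix
#'   carries the observed transfer fractions (68.5% of births to the
#'   nursery ward, 15.8% to the NICU, 15.7% to HC/MC, and the NICU-to-post-IC
#'   fraction implied by the post-IC inflow of 0.2/day). Effective arrival
#'   rates follow from the traffic equations. This is the variant to use
#'   for simulation and for positional analysis.
#' * `"printed"`: each unit's reported (rounded) effective arrival rate
#'   (4.0, 1.2, 0.2, 0.9, 2.7 patients/day) is stored directly as its
#'   arrival rate with no routing. This is the variant behind the published
#'   per-unit utilization and arrival-entropy figures.
#'
#' The two variants disagree slightly for the HC/MC unit: the printed
#' effective rate (0.9/day) is below what the entry streams alone imply
#' (0.4 + 0.157 x 4.0 = 1.028/day), presumably because the published table
#' was computed from unrounded source data. Both variants are kept as-is;
#' reports state which variant was used.
#'
#' @param rates `"derived"` or `"printed"` (see Details).
#' @return A [care_network()] of five units.
#' @examples
#' utilization_table(perinatology_network("printed"), rounded = TRUE)
#' @export
perinatology_network <- function(rates = c("derived", "printed")) {
  rates <- match.arg(rates)
  nurses <- list(
    O3 = c(day = 3, evening = 3, night = 3),
    N1 = c(day = 12, evening = 7, night = 8),
    N2 = c(day = 2, evening = 2, night = 2),
    N3 = c(day = 4, evening = 2, night = 2),
    O1 = c(day = 1, evening = 1, night = 1)
  )
  base <- list(
    care_unit("O3", beds = 6, service_rate = 1.00, name = "Delivery room",
              team = "obstetrics", nurses = nurses$O3),
    care_unit("N1", beds = 14, service_rate = 0.10, name = "Neonatal IC unit",
              team = "neonatology", nurses = nurses$N1),
    care_unit("N2", beds = 4, service_rate = 0.06, name = "Neonatal post-IC unit",
              team = "neonatology", nurses = nurses$N2),
    care_unit("N3", beds = 11, service_rate = 0.19, name = "Neonatal HC/MC unit",
              team = "neonatology", nurses = nurses$N3),
    care_unit("O1", beds = 7, service_rate = 0.91, name = "Nursery wards",
              team = "obstetrics", nurses = nurses$O1)
  )
  units <- dplyr::bind_rows(base)
  if (rates == "printed") {
    units$external_rate <- c(4.0, 1.2, 0.2, 0.9, 2.7)
    units$components <- lapply(seq_len(nrow(units)), function(i)
      stats::setNames(units$external_rate[i], units$id[i]))
    return(care_network(units))
  }
  units$external_rate <- c(4.0, 0.6, 0, 0.4, 0)
  units$components <- lapply(seq_len(nrow(units)), function(i)
    stats::setNames(units$external_rate[i], units$id[i]))
  ids <- units$id
  R <- matrix(0, 5, 5, dimnames = list(ids, ids))
  R["O3", "N1"] <- 0.158
  R["O3", "N3"] <- 0.157
  R["O3", "O1"] <- 0.685
  # NICU outflow to post-IC implied by the post-IC effective inflow of 0.2/day
  R["N1", "N2"] <- 0.2 / (4.0 * 0.158 + 0.6)
  care_network(units, R)
}

#' Pooling plans of the four candidate care configurations
#'
#' Model 1 is the current configuration (identity plan). Model 2 pools the
#' neonatal HC/MC unit with the nursery ward, Model 3 pools the neonatal
#' post-IC unit with HC/MC, and Model 4 pools the post-IC unit with the
#' nursery ward. Pooled groups report to the neonatology team manager.
#'
#' @return Named list of [pooling_plan()] objects (`"Model 1"` ...
#'   `"Model 4"`).
#' @export
perinatology_plans <- function() {
  neo <- "neonatology"
  list(
    "Model 1" = pooling_plan(list(O3 = "O3", N1 = "N1", N2 = "N2",
                                  N3 = "N3", O1 = "O1")),
    "Model 2" = pooling_plan(list(O3 = "O3", N1 = "N1", N2 = "N2",
                                  "N3+O1" = c("N3", "O1")),
                             team_assignment = c("N3+O1" = neo)),
    "Model 3" = pooling_plan(list(O3 = "O3", N1 = "N1",
                                  "N2+N3" = c("N2", "N3"), O1 = "O1"),
                             team_assignment = c("N2+N3" = neo)),
    "Model 4" = pooling_plan(list(O3 = "O3", N1 = "N1",
                                  "N2+O1" = c("N2", "O1"), N3 = "N3"),
                             team_assignment = c("N2+O1" = neo))
  )
}

#' Complete perinatology scenario
#'
#' Bundles the fixture network, the four pooling plans and a default
#' 365-day simulation configuration into a [scenario_config()].
#'
#' @inheritParams perinatology_network
#' @param seed Simulation seed stored in the scenario.
#' @return A [scenario_config()].
#' @export
perinatology_scenario <- function(rates = c("derived", "printed"), seed = 1L) {
  rates <- match.arg(rates)
  scenario_config(
    network = perinatology_network(rates),
    pooling_models = perinatology_plans(),
    simulation = simulation_config(horizon_days = 365L, seed = seed)
  )
}
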