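# The annual simulation loop wiring all stages, and the built-in LEGAL /
# ILLEGAL scenario configurations.

#' Scenario configuration
#'
#' A scenario maps every zoning category to a harvest mode and carries the
#' global simulation parameters. Two configurations are built in:
#' \describe{
#'   \item{LEGAL}{RIL everywhere harvest is allowed — National Forests, other
#'     sustainable-use land, private and undesignated public land all follow
#'     the legal management rules.}
#'   \item{ILLEGAL}{RIL inside National Forests and other sustainable-use
#'     land, conventional logging (CL) on private and undesignated land —
#'     the business-as-usual counterfactual.}
#' }
#' Strictly protected, indigenous and military land is never harvested.
#'
#' @param name `"LEGAL"`, `"ILLEGAL"`, or any name when `category_mode` is
#'   supplied explicitly.
#' @param params a [sim_params()].
#' @param category_mode optional named character vector (zoning category ->
#'   `"RIL"`/`"CL"`/`"NONE"`) overriding the built-ins.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(name, params = sim_params(), category_mode = NULL) {
  if (is.null(category_mode)) {
    category_mode <- switch(
      name,
      LEGAL = c(private_nonprotected = "RIL", sustainable_use_other = "RIL",
                national_forest = "RIL", undesignated_federal = "RIL",
                undesignated_state = "RIL", strictly_protected = "NONE",
                indigenous = "NONE", military = "NONE"),
      ILLEGAL = c(private_nonprotected = "CL", sustainable_use_other = "RIL",
                  national_forest = "RIL", undesignated_federal = "CL",
                  undesignated_state = "CL", strictly_protected = "NONE",
                  indigenous = "NONE", military = "NONE"),
      stop("unknown built-in scenario '", name,
           "'; supply category_mode for custom scenarios", call. = FALSE)
    )
  }
  bad <- setdiff(category_mode, c("RIL", "CL", "NONE"))
  if (length(bad)) stop("unknown harvest mode(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  protected <- c("strictly_protected", "indigenous", "military")
  if (any(category_mode[intersect(protected, names(category_mode))] != "NONE"))
    stop("strictly protected, indigenous and military land cannot be harvested",
         call. = FALSE)
  structure(list(name = name, category_mode = category_mode, params = params),
            class = "scenario_config")
}

baseline_table <- function(grid) {
  znc <- zoning_codes()
  lcf <- land_cover_codes()[["forest"]]
  data.frame(
    category = names(znc),
    stock_m3 = vapply(znc, function(z)
      sum(grid$volume[grid$zoning == z]) * grid$cell_area, 0),
    forest_area_ha = vapply(znc, function(z)
      sum(grid$zoning == z & grid$land_cover == lcf) * grid$cell_area, 0),
    area_ha = vapply(znc, function(z) sum(grid$zoning == z) * grid$cell_area, 0),
    row.names = NULL)
}

# harvestable volume (m3 per cell) still available to the industry: mode caps
# applied, single-entry RIL cells excluded
available_volume <- function(grid, mode_map, partition, params) {
  hv <- harvestable_per_ha(grid, mode_map, params) * grid$cell_area
  hv[partition$harvested_flag] <- 0
  hv
}

#' Run a harvest-cycle scenario
#'
#' The annual loop: rebuild the friction surface (roads may have grown),
#' accumulate transport costs and areas of influence, assign center prices
#' and harvest costs to the map, compute net rent, determine eligibility
#' (APU-of-the-year for RIL, any remaining volume for CL), allocate each
#' center's capacity over its area of influence in decreasing rent order,
#' apply removals, build unpaved roads to the newly harvested cells, then
#' update center capacities and spawn replacements for shutdowns.
#' Deterministic for a fixed `params$rng_seed`.
#'
#' @param grid a [landscape_grid()].
#' @param centers a [logging_centers()] table.
#' @param scenario a [scenario_config()].
#' @param years number of years to simulate (default: the full cycle).
#' @param verbose print a one-line annual log to stderr.
#' @return An [annual_ledger()] with attributes `final_grid`, `centers`,
#'   `partition`, `logged_mask` and `center_log`.
#' @export
run_scenario <- function(grid, centers, scenario, years = NULL, verbose = FALSE) {
  params <- scenario$params
  if (is.null(years)) years <- params$cycle_years
  stopifnot(years >= 0, years <= params$cycle_years)
  withr::local_seed(params$rng_seed)

  baseline <- baseline_table(grid)
  mode_map <- assign_modes(grid$zoning, scenario)
  partition <- partition_fmus(mode_map == HARVEST_MODES[["RIL"]],
                              params$fmu_area, params$cycle_years,
                              grid$cell_area, seed = params$rng_seed)
  logged_mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
  edge <- cell_edge_km(grid)
  znc <- zoning_codes()

  records <- list()
  center_log <- list()
  all_events <- list()
  year <- 0L
  while (year < years) {
    year <- year + 1L
    if (!any(centers$active)) break
    cap_start <- stats::setNames(centers$capacity_m3yr, centers$id)
    friction <- build_friction_surface(grid)
    cs <- cost_distance(friction, centers, edge)
    grid <- assign_center_layers(grid, cs, centers)
    rent <- net_rent_map(grid, cs, params, mode_map)
    elig <- eligible_cells(grid, partition, mode_map, year)
    hv <- harvestable_per_ha(grid, mode_map, params) * grid$cell_area

    events <- list()
    for (k in which(centers$active)) {
      cid <- centers$id[k]
      cells <- which(elig & cs$allocation == cid)
      ev <- allocate_harvest(cells, rent$rent, hv, centers$capacity_m3yr[k],
                             mode_map, grid$n_rows)
      if (nrow(ev)) {
        ev$center_id <- cid
        upd <- apply_harvest(grid, ev, partition)
        grid <- upd$grid; partition <- upd$partition
        events[[length(events) + 1L]] <- ev
      }
    }
    events <- if (length(events)) do.call(rbind, events) else
      data.frame(cell = integer(), row = integer(), col = integer(),
                 mode = integer(), volume_m3 = numeric(), rent_brl = numeric(),
                 center_id = integer())

    if (nrow(events)) {
      # road construction in rent-descending order of the harvested cells
      ord <- order(-rent$rent[events$cell], events$row, events$col)
      rd <- extend_roads(grid, friction, events[ord, , drop = FALSE], centers)
      grid <- rd$grid

      all_events[[length(all_events) + 1L]] <- cbind(year = year, events)
      new_cell <- !logged_mask[events$cell]
      logged_mask[events$cell] <- TRUE
      records[[length(records) + 1L]] <- data.frame(
        year = year,
        center_id = events$center_id,
        category = code_name(znc, grid$zoning[events$cell]),
        volume_m3 = events$volume_m3,
        new_area_ha = ifelse(new_cell, grid$cell_area, 0),
        rent_brl = events$rent_brl)
    }

    # capacity reacts to the post-harvest profitable volume in each area of
    # influence, computed on the current year's cost surface
    avail <- available_volume(grid, mode_map, partition, params)
    tot_cost <- unit_total_cost(grid$harvest_cost, cs$tc, params$interest_rate)
    prof_vol <- avail * ((grid$price - tot_cost) > 0)
    was_active <- centers$active
    prof_by_center <- vapply(seq_len(nrow(centers)), function(k) {
      if (!centers$active[k]) return(0)
      sum(prof_vol[cs$allocation == centers$id[k]])
    }, 0)
    centers$capacity_m3yr[was_active] <-
      update_capacity(centers$capacity_m3yr[was_active],
                      prof_by_center[was_active], params$max_capacity_growth)
    centers$active <- centers$active & centers$capacity_m3yr > 0
    shutdowns <- sum(was_active & !centers$active)
    for (s in seq_len(shutdowns)) {
      nb <- spawn_center(grid, prof_vol, centers, params)
      if (!is.null(nb)) centers <- rbind(centers, nb)
    }

    center_log[[length(center_log) + 1L]] <- data.frame(
      year = year, id = centers$id,
      capacity_start_m3yr = unname(cap_start[as.character(centers$id)]),
      capacity_m3yr = centers$capacity_m3yr,
      profitable_volume_m3 = c(prof_by_center,
                               rep(NA, nrow(centers) - length(prof_by_center))),
      active = centers$active)
    if (verbose)
      message(sprintf("year %2d: %8.0f m3 harvested, %d active center(s)",
                      year, if (nrow(events)) sum(events$volume_m3) else 0,
                      sum(centers$active)))
  }

  records <- if (length(records)) do.call(rbind, records) else
    data.frame(year = integer(), center_id = integer(), category = character(),
               volume_m3 = numeric(), new_area_ha = numeric(), rent_brl = numeric())
  rownames(records) <- NULL
  led <- annual_ledger(records, baseline, scenario = scenario$name)
  attr(led, "final_grid") <- grid
  attr(led, "centers") <- centers
  attr(led, "partition") <- partition
  attr(led, "logged_mask") <- logged_mask
  attr(led, "center_log") <- if (length(center_log)) do.call(rbind, center_log) else NULL
  attr(led, "events") <- if (length(all_events)) do.call(rbind, all_events) else
    data.frame(year = integer(), cell = integer(), row = integer(),
               col = integer(), mode = integer(), volume_m3 = numeric(),
               rent_brl = numeric(), center_id = integer())
  led
}

#' Run the LEGAL and ILLEGAL scenarios from identical initial conditions
#'
#' Both runs start from the same landscape, centers, parameters and RNG seed,
#' so any difference between the two ledgers is attributable to the harvest
#' mode rules alone.
#'
#' @param grid a [landscape_grid()].
#' @param centers a [logging_centers()] table.
#' @param params a [sim_params()].
#' @param years number of years (default: full cycle).
#' @return `list(LEGAL = annual_ledger, ILLEGAL = annual_ledger)`.
#' @export
run_pair <- function(grid, centers, params = sim_params(), years = NULL) {
  list(
    LEGAL = run_scenario(grid, centers, scenario_config("LEGAL", params), years),
    ILLEGAL = run_scenario(grid, centers, scenario_config("ILLEGAL", params), years)
  )
}
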