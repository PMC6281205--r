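# Friction surfaces, accumulated transport cost, areas of influence,
# total unit cost and per-cell net rent (stumpage).

#' Friction values (R$/m3/km) by category
#'
#' Traversal cost of each terrain/network class. Strictly protected,
#' indigenous and military zones are barriers carrying the prohibitive (but
#' finite) sentinel 5,000.
#' @return A list with components `land_cover`, `road`, `zoning_soft`,
#'   `barrier`.
#' @export
friction_table <- function() {
  list(
    land_cover = c(forest = 0.8, deforested = 0.7, grassland = 0.7,
                   non_navigable_water = 2.0),
    road = c(paved = 0.3, unpaved = 0.5, duplicated = 0.2,
             navigable_river = 0.1, seasonally_navigable_river = 1.0),
    zoning_soft = 0.8,   # sustainable-use and undesignated public forest
    barrier = 5000
  )
}

#' Build the friction surface of a landscape
#'
#' Per-cell traversal cost with precedence: (1) barrier zoning
#' (strictly protected / indigenous / military) overrides everything at
#' 5,000 R$/m3/km; (2) otherwise a road or waterway class sets its own
#' value; (3) otherwise the land-cover value applies, capped at 0.8 inside
#' sustainable-use and undesignated public forest (so e.g. non-navigable
#' water inside those zones costs 0.8, not 2.0).
#'
#' @param grid a [landscape_grid()].
#' @return A `friction_surface`: list with `friction` (numeric matrix) and
#'   `provenance` (character matrix: which rule set each cell —
#'   `"zoning_barrier"`, `"road"`, `"land_cover"` or `"zoning"`).
#' @export
build_friction_surface <- function(grid) {
  ft <- friction_table()
  lc <- grid$land_cover; zn <- grid$zoning; rd <- grid$roads
  lcc <- land_cover_codes(); znc <- zoning_codes(); rdc <- road_codes()

  f <- matrix(ft$land_cover[code_name(lcc, lc)], grid$n_rows)
  prov <- matrix("land_cover", grid$n_rows, grid$n_cols)

  soft <- zn %in% znc[c("sustainable_use_other", "national_forest",
                        "undesignated_federal", "undesignated_state")]
  softer <- soft & f > ft$zoning_soft
  f[softer] <- ft$zoning_soft
  prov[softer] <- "zoning"

  on_road <- rd != rdc[["none"]]
  f[on_road] <- ft$road[code_name(rdc, rd[on_road])]
  prov[on_road] <- "road"

  barrier <- zn %in% barrier_zones()
  f[barrier] <- ft$barrier
  prov[barrier] <- "zoning_barrier"

  structure(list(friction = f, provenance = prov), class = "friction_surface")
}

#' Accumulated transport cost and areas of influence
#'
#' Least-cost accumulation from every cell to its cheapest active logging
#' center on the 8-connected lattice: a step between adjacent cells costs
#' the mean of their frictions times the step length (edge length, scaled by
#' sqrt(2) on diagonals). The arg-min center defines the areas of influence.
#'
#' @param friction a `friction_surface` from [build_friction_surface()], or a
#'   bare friction matrix.
#' @param centers a [logging_centers()] table; only active centers are used.
#' @param cell_edge_km cell edge length in km.
#' @return A `cost_surface`: list with `tc` (R$/m3 matrix, 0 at centers) and
#'   `allocation` (integer matrix of center ids).
#' @export
cost_distance <- function(friction, centers, cell_edge_km = 1) {
  f <- if (inherits(friction, "friction_surface")) friction$friction else friction
  act <- centers[centers$active & centers$capacity_m3yr > 0, , drop = FALSE]
  if (nrow(act) == 0) stop("state error: no active logging centers", call. = FALSE)
  res <- cpp_cost_distance(f, as.integer(act$row), as.integer(act$col),
                           as.integer(act$id), cell_edge_km)
  structure(list(tc = res$tc, allocation = res$allocation),
            class = "cost_surface")
}

#' Total unit cost of delivered round wood
#'
#' `(harvest cost + transport cost) * (1 + interest rate)`, all in R$/m3.
#' The interest multiplier represents the opportunity cost of capital.
#'
#' @param hc harvest cost at the center, R$/m3.
#' @param tc accumulated transport cost, R$/m3. Vectorised.
#' @param interest_rate fraction/yr.
#' @export
unit_total_cost <- function(hc, tc, interest_rate) {
  if (any(hc < 0) || any(tc < 0) || interest_rate < 0)
    stop("domain error: costs and interest rate must be >= 0", call. = FALSE)
  (hc + tc) * (1 + interest_rate)
}

# price / harvest-cost rasters implied by the areas of influence
assign_center_layers <- function(grid, cost_surface, centers) {
  idx <- match(as.vector(cost_surface$allocation), centers$id)
  grid$price <- matrix(centers$price_brl_m3[idx], grid$n_rows)
  grid$harvest_cost <- matrix(centers$harvest_cost_brl_m3[idx], grid$n_rows)
  grid
}

# per-cell harvestable volume (m3/ha) under the mode rules
harvestable_per_ha <- function(grid, mode_map, params) {
  cap <- max_ril_removal(params$max_intensity, params$cycle_years)
  v <- grid$volume
  v[mode_map == HARVEST_MODES[["RIL"]]] <-
    pmin(v[mode_map == HARVEST_MODES[["RIL"]]], cap)
  v[mode_map == HARVEST_MODES[["NONE"]]] <- 0
  v
}

#' Per-cell net rent (stumpage) map
#'
#' Net rent = harvestable volume x cell area x (price - total unit cost),
#' in R$ per cell. Harvestable volume is the remaining volume capped at the
#' RIL cycle limit on RIL cells, the full remaining volume on CL cells and
#' zero on no-harvest cells. Cells with rent <= 0 are unprofitable.
#'
#' @param grid a [landscape_grid()] with `price`/`harvest_cost` assigned.
#' @param cost_surface a `cost_surface` from [cost_distance()].
#' @param params a [sim_params()].
#' @param mode_map integer matrix of harvest modes (see [assign_modes()]).
#' @return List with `rent` (R$ per cell matrix) and `profitable` (logical).
#' @export
net_rent_map <- function(grid, cost_surface, params, mode_map) {
  if (!identical(dim(mode_map), dim(grid$volume)))
    stop("registration error: mode_map shape mismatch", call. = FALSE)
  if (is.null(grid$price) || is.null(grid$harvest_cost))
    stop("price and harvest_cost layers must be assigned", call. = FALSE)
  v <- harvestable_per_ha(grid, mode_map, params)
  tot_cost <- unit_total_cost(grid$harvest_cost, cost_surface$tc, params$interest_rate)
  rent <- v * grid$cell_area * (grid$price - tot_cost)
  list(rent = rent, profitable = rent > 0)
}
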