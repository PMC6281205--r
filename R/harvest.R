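# FMU/APU management partition, RIL and CL harvest rules, and the annual
# profitability-driven harvest allocation per logging center.

HARVEST_MODES <- c(NONE = 0L, RIL = 1L, CL = 2L)

#' Harvest-mode codes
#'
#' `RIL` (reduced-impact logging) cells follow the legal management rules:
#' intensity cap, annual production units, single entry per cycle. `CL`
#' (conventional logging) cells can be fully harvested and re-entered.
#' `NONE` cells are never harvested.
#' @return Named integer vector.
#' @export
harvest_modes <- function() HARVEST_MODES

#' Maximum RIL removal per cycle
#'
#' The legal logging-intensity cap: `max_intensity` m3/ha/yr times the cycle
#' length, applied as a per-cell, per-cycle removal ceiling in RIL mode
#' (0.86 x 30 = 25.8 m3/ha under the defaults).
#'
#' @param max_intensity m3/ha/yr.
#' @param cycle_years years per harvest cycle.
#' @return m3/ha.
#' @export
max_ril_removal <- function(max_intensity, cycle_years) {
  stopifnot(max_intensity >= 0, cycle_years >= 0)
  max_intensity * cycle_years
}

#' Partition RIL land into forest management units and annual production units
#'
#' Tiles the grid into rectangular FMU blocks of `fmu_area` and splits each
#' into `cycle_years` APUs. Where an FMU block is complete (every cell RIL),
#' APUs are contiguous square sub-blocks; truncated edge FMUs fall back to a
#' round-robin assignment giving proportionally smaller APUs. Deterministic.
#'
#' @param ril_mask logical matrix: cells under RIL management.
#' @param fmu_area FMU size, ha.
#' @param cycle_years APUs per FMU (one per cycle year).
#' @param cell_area ha per cell.
#' @param seed unused placeholder for future stochastic layouts.
#' @return A `management_partition`: list with integer matrices `fmu_id` and
#'   `apu_index` (NA off RIL land) and logical `harvested_flag`.
#' @export
partition_fmus <- function(ril_mask, fmu_area, cycle_years, cell_area, seed = 1L) {
  nr <- nrow(ril_mask); nc <- ncol(ril_mask)
  fmu_cells <- round(fmu_area / cell_area)
  if (fmu_cells / cycle_years < 1)
    stop("configuration error: APU smaller than one cell", call. = FALSE)
  apu_cells <- fmu_cells / cycle_years

  # block geometry: square APUs arranged in the most square APU lattice when
  # the arithmetic is exact, else a near-square FMU block with round-robin APUs
  s <- sqrt(apu_cells)
  exact <- apu_cells == round(apu_cells) && s == round(s)
  if (exact) {
    s <- as.integer(round(s))
    b <- max(which(cycle_years %% seq_len(floor(sqrt(cycle_years))) == 0))
    a <- cycle_years %/% b                   # a x b APU lattice, a >= b
    block_r <- a * s; block_c <- b * s
  } else {
    block_r <- as.integer(ceiling(sqrt(fmu_cells)))
    block_c <- as.integer(ceiling(fmu_cells / block_r))
  }

  fmu_id <- matrix(NA_integer_, nr, nc)
  apu_index <- matrix(NA_integer_, nr, nc)
  next_id <- 0L
  for (br in seq_len(ceiling(nr / block_r))) {
    for (bc in seq_len(ceiling(nc / block_c))) {
      rows <- ((br - 1L) * block_r + 1L):min(br * block_r, nr)
      cols <- ((bc - 1L) * block_c + 1L):min(bc * block_c, nc)
      sub <- ril_mask[rows, cols, drop = FALSE]
      n_in <- sum(sub)
      if (n_in == 0L) next
      next_id <- next_id + 1L
      fmu_id[rows, cols][sub] <- next_id
      complete <- exact && n_in == fmu_cells &&
        length(rows) == block_r && length(cols) == block_c
      if (complete) {
        rel_r <- matrix(seq_along(rows), length(rows), length(cols))
        rel_c <- matrix(seq_along(cols), length(rows), length(cols), byrow = TRUE)
        apu <- (ceiling(rel_r / s) - 1L) * b + ceiling(rel_c / s)
        apu_index[rows, cols][sub] <- as.integer(apu[sub])
      } else {
        # row-major round-robin over the block's RIL cells
        apu_m_t <- matrix(NA_integer_, length(cols), length(rows))
        apu_m_t[t(sub)] <- rep_len(seq_len(cycle_years), n_in)
        apu_index[rows, cols][sub] <- t(apu_m_t)[sub]
        if (n_in < cycle_years)
          warning(sprintf("FMU %d truncated to %d cell(s): APUs smaller than one cell",
                          next_id, n_in), call. = FALSE)
      }
    }
  }
  structure(list(fmu_id = fmu_id, apu_index = apu_index,
                 harvested_flag = matrix(FALSE, nr, nc),
                 cycle_years = as.integer(cycle_years)),
            class = "management_partition")
}

#' Assign harvest modes from zoning and a scenario
#'
#' Maps every zoning category to RIL, CL or NONE according to the scenario's
#' category-mode table. Strictly protected, indigenous and military land is
#' NONE in every built-in scenario.
#'
#' @param zoning integer matrix with [zoning_codes()].
#' @param scenario a [scenario_config()].
#' @return Integer matrix of [harvest_modes()] codes.
#' @export
assign_modes <- function(zoning, scenario) {
  znc <- zoning_codes()
  present <- code_name(znc, sort(unique(as.vector(zoning))))
  miss <- setdiff(present, names(scenario$category_mode))
  if (length(miss))
    stop("configuration error: scenario lacks a mode for: ",
         paste(miss, collapse = ", "), call. = FALSE)
  lut <- HARVEST_MODES[scenario$category_mode]
  names(lut) <- names(scenario$category_mode)
  matrix(unname(lut[code_name(znc, zoning)]), nrow(zoning))
}

#' Cells eligible for harvest in a given cycle year
#'
#' RIL cells are eligible only in the year matching their APU index and only
#' if not yet harvested this cycle (single entry). CL cells are eligible
#' whenever volume remains (re-entry allowed). NONE cells never.
#'
#' @param grid a [landscape_grid()].
#' @param partition a `management_partition` from [partition_fmus()].
#' @param mode_map from [assign_modes()].
#' @param year cycle year, 1..cycle_years.
#' @return Logical matrix.
#' @export
eligible_cells <- function(grid, partition, mode_map, year) {
  if (year < 1 || year > partition$cycle_years)
    stop("domain error: year outside 1..cycle_years", call. = FALSE)
  ril <- mode_map == HARVEST_MODES[["RIL"]] &
    !is.na(partition$apu_index) & partition$apu_index == year &
    !partition$harvested_flag
  cl <- mode_map == HARVEST_MODES[["CL"]] & grid$volume > 0
  ril | cl
}

#' Allocate a center's annual harvest over its eligible cells
#'
#' Greedy by net rent: cells are taken in strictly decreasing rent order
#' (ties broken by row, then column) while cumulative removed volume fits the
#' center's capacity; the last cell may be taken partially. Only cells with
#' positive rent are harvested.
#'
#' @param cells integer vector of eligible cell indices (column-major) inside
#'   the center's area of influence.
#' @param rent numeric matrix of per-cell net rent, R$.
#' @param harvestable numeric matrix of per-cell harvestable volume, m3
#'   (already mode-capped, per cell not per ha).
#' @param capacity the center's annual capacity, m3.
#' @param mode_map from [assign_modes()].
#' @param n_rows grid row count (to recover row/col from indices).
#' @return data.frame of harvest events: `cell`, `row`, `col`, `mode`,
#'   `volume_m3`, `rent_brl`.
#' @export
allocate_harvest <- function(cells, rent, harvestable, capacity, mode_map, n_rows) {
  if (capacity < 0) stop("domain error: capacity < 0", call. = FALSE)
  empty <- data.frame(cell = integer(), row = integer(), col = integer(),
                      mode = integer(), volume_m3 = numeric(), rent_brl = numeric())
  if (capacity == 0 || length(cells) == 0) return(empty)
  r <- rent[cells]; v <- harvestable[cells]
  keep <- r > 0 & v > 0
  cells <- cells[keep]; r <- r[keep]; v <- v[keep]
  if (length(cells) == 0) return(empty)
  row <- (cells - 1L) %% n_rows + 1L
  col <- (cells - 1L) %/% n_rows + 1L
  ord <- order(-r, row, col)
  cells <- cells[ord]; r <- r[ord]; v <- v[ord]; row <- row[ord]; col <- col[ord]
  cum <- cumsum(v)
  n_full <- sum(cum <= capacity)
  take <- numeric(length(cells))
  take[seq_len(n_full)] <- v[seq_len(n_full)]
  left <- capacity - if (n_full) cum[n_full] else 0
  if (n_full < length(cells) && left > 0) take[n_full + 1L] <- min(v[n_full + 1L], left)
  sel <- take > 0
  data.frame(cell = cells[sel], row = row[sel], col = col[sel],
             mode = mode_map[cells[sel]], volume_m3 = take[sel],
             rent_brl = r[sel] * take[sel] / v[sel])
}

#' Apply harvest events to the landscape
#'
#' Decrements remaining volume and sets the single-entry flag on RIL cells.
#' Volume never goes negative; events on no-harvest cells or exceeding the
#' remaining stock are consistency errors.
#'
#' @param grid a [landscape_grid()].
#' @param events data.frame from [allocate_harvest()].
#' @param partition a `management_partition`.
#' @return `list(grid = , partition = )` with updated state.
#' @export
apply_harvest <- function(grid, events, partition) {
  if (nrow(events)) {
    if (any(events$mode == HARVEST_MODES[["NONE"]]))
      stop("consistency error: harvest event on a no-harvest cell", call. = FALSE)
    remaining <- grid$volume[events$cell] * grid$cell_area
    if (any(events$volume_m3 > remaining + 1e-6))
      stop("consistency error: removal exceeds remaining volume", call. = FALSE)
    grid$volume[events$cell] <- pmax(0, grid$volume[events$cell] -
                                       events$volume_m3 / grid$cell_area)
    ril <- events$cell[events$mode == HARVEST_MODES[["RIL"]]]
    partition$harvested_flag[ril] <- TRUE
  }
  list(grid = grid, partition = partition)
}
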