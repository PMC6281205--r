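# Domain types and I/O for the raster landscape, logging centers and ledgers.
#
# All rasters are base R matrices indexed [row, col], row 1 at the top,
# co-registered on a projected metric grid with a configurable cell size
# (default 100 ha = 1 km x 1 km). Categories are small integer codes with
# the legends below.

#' Category legends
#'
#' Integer codes used in the category rasters of a [landscape_grid()].
#'
#' @return A named integer vector mapping category names to raster codes.
#' @export
land_cover_codes <- function() {
  c(forest = 1L, deforested = 2L, grassland = 3L, non_navigable_water = 4L)
}

#' @rdname land_cover_codes
#' @export
zoning_codes <- function() {
  c(private_nonprotected = 1L, sustainable_use_other = 2L, national_forest = 3L,
    undesignated_federal = 4L, undesignated_state = 5L, strictly_protected = 6L,
    indigenous = 7L, military = 8L)
}

#' @rdname land_cover_codes
#' @export
road_codes <- function() {
  c(none = 0L, paved = 1L, unpaved = 2L, duplicated = 3L,
    navigable_river = 4L, seasonally_navigable_river = 5L)
}

# zoning categories that act as transport barriers and are never harvested
barrier_zones <- function() zoning_codes()[c("strictly_protected", "indigenous", "military")]

code_name <- function(codes, x) names(codes)[match(x, codes)]

#' Construct a landscape grid
#'
#' Bundles the co-registered raster layers of the study area: commercial wood
#' volume (m3/ha), land cover, protection zoning and the transport network.
#' Commercial volume is masked to zero on non-forest cells (baseline
#' deforestation masking). Optional `price` and `harvest_cost` layers
#' (R$/m3) are normally derived per area of influence during a run.
#'
#' @param volume numeric matrix, commercial wood volume in m3/ha, >= 0.
#' @param land_cover integer matrix with codes from [land_cover_codes()].
#' @param zoning integer matrix with codes from [zoning_codes()].
#' @param roads integer matrix with codes from [road_codes()].
#' @param cell_area hectares per cell (default 100 ha, i.e. 1 km2 cells).
#' @param price,harvest_cost optional numeric matrices, R$/m3.
#' @return An object of class `landscape_grid`.
#' @export
landscape_grid <- function(volume, land_cover, zoning, roads,
                           cell_area = 100, price = NULL, harvest_cost = NULL) {
  layers <- list(volume = volume, land_cover = land_cover, zoning = zoning,
                 roads = roads)
  if (!is.null(price)) layers$price <- price
  if (!is.null(harvest_cost)) layers$harvest_cost <- harvest_cost
  dims <- vapply(layers, function(m) {
    if (!is.matrix(m)) stop("registration error: all layers must be matrices", call. = FALSE)
    dim(m)
  }, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("registration error: layers have mismatched shapes", call. = FALSE)
  if (!is.numeric(cell_area) || length(cell_area) != 1L || cell_area <= 0)
    stop("cell_area must be a positive scalar (hectares)", call. = FALSE)

  check_codes <- function(m, codes, what) {
    bad <- setdiff(unique(as.vector(m)), codes)
    if (length(bad))
      stop(sprintf("schema error: unknown %s code(s): %s", what,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  check_codes(land_cover, land_cover_codes(), "land_cover")
  check_codes(zoning, zoning_codes(), "zoning")
  check_codes(roads, road_codes(), "roads")
  if (any(volume < 0) || any(!is.finite(volume)))
    stop("volume must be finite and >= 0", call. = FALSE)

  volume[land_cover != land_cover_codes()[["forest"]]] <- 0
  volume <- matrix(as.numeric(volume), nrow(volume))  # drop stray attributes

  structure(list(
    n_rows = nrow(volume), n_cols = ncol(volume), cell_area = cell_area,
    volume = volume,
    land_cover = matrix(as.integer(land_cover), nrow(volume)),
    zoning = matrix(as.integer(zoning), nrow(volume)),
    roads = matrix(as.integer(roads), nrow(volume)),
    price = price, harvest_cost = harvest_cost
  ), class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("<landscape_grid> %d x %d cells (%.0f ha each)\n",
              x$n_rows, x$n_cols, x$cell_area))
  fa <- sum(x$land_cover == land_cover_codes()[["forest"]]) * x$cell_area
  cat(sprintf("  forest area: %.0f ha; commercial stock: %.0f m3\n",
              fa, sum(x$volume) * x$cell_area))
  invisible(x)
}

# edge length of a cell in km (cell_area in ha; 100 ha <-> 1 km)
cell_edge_km <- function(grid) sqrt(grid$cell_area / 100)

#' Total commercial stock on the grid, in m3
#' @param grid a [landscape_grid()].
#' @export
total_stock <- function(grid) sum(grid$volume) * grid$cell_area

#' Construct a logging-center table
#'
#' Centers are demand nodes (mills) with an annual processing capacity, a
#' round-wood price and a harvest cost that apply throughout their area of
#' influence.
#'
#' @param df data.frame with columns `id`, `row`, `col`, `capacity_m3yr`,
#'   `price_brl_m3`, `harvest_cost_brl_m3` and optionally `active`.
#' @param grid optional [landscape_grid()] used to check placement.
#' @return A `logging_centers` data.frame.
#' @export
logging_centers <- function(df, grid = NULL) {
  req <- c("id", "row", "col", "capacity_m3yr", "price_brl_m3", "harvest_cost_brl_m3")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("schema error: center table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"active" %in% names(df)) df$active <- df$capacity_m3yr > 0
  df <- df[, c(req, "active")]
  if (anyDuplicated(df$id)) stop("center ids must be unique", call. = FALSE)
  if (any(df$capacity_m3yr < 0)) stop("capacity must be >= 0", call. = FALSE)
  if (any(df$price_brl_m3 <= 0)) stop("price must be > 0", call. = FALSE)
  if (any(df$harvest_cost_brl_m3 < 0)) stop("harvest cost must be >= 0", call. = FALSE)
  df$active <- df$active & df$capacity_m3yr > 0
  if (!is.null(grid)) {
    if (any(df$row < 1 | df$row > grid$n_rows | df$col < 1 | df$col > grid$n_cols))
      stop("placement error: center outside grid", call. = FALSE)
  }
  class(df) <- c("logging_centers", "data.frame")
  df
}

#' Simulation parameters
#'
#' Global constants of the harvest-cycle simulation. Defaults reproduce the
#' published Amazon configuration: a 30-year cycle, the legal RIL intensity
#' cap of 0.86 m3/ha/yr, 27,000-ha management units split into 900-ha annual
#' production units, 20 %/yr maximum center growth, a 200-500 km emergence
#' band for new centers, 5 %/yr opportunity cost of capital and the 2009
#' exchange rate of R$1.995 per USD.
#'
#' @param cycle_years length of the harvest cycle in years.
#' @param max_intensity RIL logging-intensity cap, m3/ha/yr.
#' @param fmu_area forest-management-unit size, ha.
#' @param apu_area annual-production-unit size, ha.
#' @param newborn_capacity initial capacity of spawned centers, m3/yr.
#' @param max_capacity_growth maximum relative capacity increase per year.
#' @param min_spawn_distance,max_spawn_distance emergence band for new
#'   centers, km (straight-line distance to the nearest active center).
#' @param interest_rate opportunity cost of capital, fraction/yr.
#' @param price_drift temporal variation of the round-wood price, fraction/yr.
#' @param exchange_rate BRL per USD.
#' @param spawn_window_km radius of the neighbourhood over which profitable
#'   volume is summed when siting an emerging center.
#' @param rng_seed integer seed for the simulation RNG.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(cycle_years = 30, max_intensity = 0.86,
                       fmu_area = 27000, apu_area = 900,
                       newborn_capacity = 50000, max_capacity_growth = 0.20,
                       min_spawn_distance = 200, max_spawn_distance = 500,
                       interest_rate = 0.05, price_drift = 0,
                       exchange_rate = 1.995, spawn_window_km = 50,
                       rng_seed = 1L) {
  p <- list(cycle_years = as.integer(cycle_years), max_intensity = max_intensity,
            fmu_area = fmu_area, apu_area = apu_area,
            newborn_capacity = newborn_capacity,
            max_capacity_growth = max_capacity_growth,
            min_spawn_distance = min_spawn_distance,
            max_spawn_distance = max_spawn_distance,
            interest_rate = interest_rate, price_drift = price_drift,
            exchange_rate = exchange_rate, spawn_window_km = spawn_window_km,
            rng_seed = as.integer(rng_seed))
  rates <- c(p$max_intensity, p$max_capacity_growth, p$interest_rate, p$price_drift)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  if (p$cycle_years < 1) stop("cycle_years must be >= 1", call. = FALSE)
  if (p$min_spawn_distance >= p$max_spawn_distance)
    stop("min_spawn_distance must be < max_spawn_distance", call. = FALSE)
  if (p$exchange_rate <= 0) stop("exchange_rate must be > 0", call. = FALSE)
  class(p) <- "sim_params"
  p
}

# ---------------------------------------------------------------------------
# raster I/O: ESRI ASCII grid (plain text, one layer per file)

#' Write / read a raster layer as an ESRI ASCII grid
#'
#' Plain-text raster exchange format (`ncols`/`nrows`/`cellsize` header
#' followed by row-major values, row 1 at the top). Integer layers
#' round-trip bit-exactly.
#'
#' @param m a matrix.
#' @param path file path (conventionally `.asc`).
#' @param cellsize cell edge length in the map unit (km here).
#' @export
write_asc <- function(m, path, cellsize = 1) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
    "xllcorner 0", "yllcorner 0", sprintf("cellsize %.10g", cellsize),
    "NODATA_value -9999"), con)
  fmt <- if (is.integer(m) || all(m == round(m))) "%d" else "%.10g"
  if (fmt == "%d") m <- matrix(as.integer(m), nrow(m))
  for (i in seq_len(nrow(m)))
    writeLines(paste(sprintf(fmt, m[i, ]), collapse = " "), con)
  invisible(path)
}

#' @rdname write_asc
#' @return `read_asc()` returns a matrix with attribute `cellsize`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7) stop("parse error: truncated ASCII grid: ", path, call. = FALSE)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  for (k in c("ncols", "nrows", "cellsize"))
    if (!k %in% keys || is.na(vals[[k]]))
      stop("parse error: missing header field '", k, "' in ", path, call. = FALSE)
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nr * nc)
    stop("parse error: expected ", nr * nc, " values, got ", length(body), call. = FALSE)
  m <- matrix(body, nrow = nr, byrow = TRUE)
  if (all(m == round(m))) m <- matrix(as.integer(m), nr)
  attr(m, "cellsize") <- vals[["cellsize"]]
  m
}

#' Save / load a landscape bundle
#'
#' Writes one `.asc` per layer plus `centers.csv` and a small
#' `landscape.yaml` with the cell size and the category legends, so a saved
#' landscape is self-describing.
#'
#' @param grid a [landscape_grid()].
#' @param centers a [logging_centers()] table.
#' @param dir output directory (created if needed).
#' @export
save_landscape <- function(grid, centers, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ek <- cell_edge_km(grid)
  for (ly in c("volume", "land_cover", "zoning", "roads"))
    write_asc(grid[[ly]], file.path(dir, paste0(ly, ".asc")), cellsize = ek)
  utils::write.csv(as.data.frame(centers), file.path(dir, "centers.csv"),
                   row.names = FALSE)
  meta <- list(cell_area_ha = grid$cell_area,
               legends = list(land_cover = as.list(land_cover_codes()),
                              zoning = as.list(zoning_codes()),
                              roads = as.list(road_codes())))
  yaml::write_yaml(meta, file.path(dir, "landscape.yaml"))
  invisible(dir)
}

#' Load a landscape from raster files and a center table
#'
#' Validates co-registration, category codes and center placement, and masks
#' commercial volume to zero on non-forest cells.
#'
#' @param raster_paths named character vector/list with entries `volume`,
#'   `land_cover`, `zoning`, `roads` (paths to `.asc` files).
#' @param center_table_path path to a CSV with the [logging_centers()] columns.
#' @param cell_area hectares per cell.
#' @return `list(grid = landscape_grid, centers = logging_centers)`.
#' @export
load_landscape <- function(raster_paths, center_table_path, cell_area = 100) {
  need <- c("volume", "land_cover", "zoning", "roads")
  miss <- setdiff(need, names(raster_paths))
  if (length(miss))
    stop("missing raster layer path(s): ", paste(miss, collapse = ", "), call. = FALSE)
  layers <- lapply(raster_paths[need], read_asc)
  grid <- landscape_grid(volume = layers$volume * 1.0,
                         land_cover = layers$land_cover,
                         zoning = layers$zoning, roads = layers$roads,
                         cell_area = cell_area)
  centers <- logging_centers(utils::read.csv(center_table_path), grid)
  list(grid = grid, centers = centers)
}

#' @rdname load_landscape
#' @param dir a directory written by [save_landscape()].
#' @export
load_landscape_dir <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "landscape.yaml"))
  paths <- stats::setNames(
    file.path(dir, paste0(c("volume", "land_cover", "zoning", "roads"), ".asc")),
    c("volume", "land_cover", "zoning", "roads"))
  load_landscape(paths, file.path(dir, "centers.csv"),
                 cell_area = meta$cell_area_ha)
}

# ---------------------------------------------------------------------------
# annual ledger

#' Construct an annual ledger
#'
#' Per (year, center, land category) accounting of a scenario run: volume
#' harvested (m3), newly logged area (ha; a cell counts the first year it is
#' entered) and net rent (R$), plus the baseline stock and area per category
#' needed for fraction-of-baseline reporting.
#'
#' @param records data.frame with columns `year`, `center_id`, `category`,
#'   `volume_m3`, `new_area_ha`, `rent_brl`.
#' @param baseline data.frame with columns `category`, `stock_m3`,
#'   `forest_area_ha`, `area_ha`.
#' @param scenario scenario name.
#' @return An object of class `annual_ledger`.
#' @export
annual_ledger <- function(records, baseline, scenario = NA_character_) {
  rec_cols <- c("year", "center_id", "category", "volume_m3", "new_area_ha", "rent_brl")
  base_cols <- c("category", "stock_m3", "forest_area_ha", "area_ha")
  if (!all(rec_cols %in% names(records)))
    stop("parse error: ledger records missing column(s): ",
         paste(setdiff(rec_cols, names(records)), collapse = ", "), call. = FALSE)
  if (!all(base_cols %in% names(baseline)))
    stop("parse error: ledger baseline missing column(s): ",
         paste(setdiff(base_cols, names(baseline)), collapse = ", "), call. = FALSE)
  records <- records[rec_cols]
  num <- c("volume_m3", "new_area_ha")
  if (nrow(records) && any(records[num] < 0))
    stop("ledger entries must be >= 0", call. = FALSE)
  structure(list(records = records, baseline = baseline[base_cols],
                 scenario = scenario),
            class = "annual_ledger")
}

#' @export
print.annual_ledger <- function(x, ...) {
  cat(sprintf("<annual_ledger> scenario %s: %d records over %s year(s)\n",
              x$scenario, nrow(x$records),
              if (nrow(x$records)) max(x$records$year) else 0))
  cat(sprintf("  harvested %.0f m3 on %.0f ha, net rent %.0f R$\n",
              sum(x$records$volume_m3), sum(x$records$new_area_ha),
              sum(x$records$rent_brl)))
  invisible(x)
}

#' Save / load an annual ledger as CSV
#'
#' One delimited file with a `section` column separating the per-year
#' records from the per-category baseline; lossless round-trip.
#'
#' @param ledger an [annual_ledger()].
#' @param path CSV file path.
#' @export
save_ledger <- function(ledger, path) {
  rec <- ledger$records
  base <- ledger$baseline
  out <- data.frame(
    section = c(rep("record", nrow(rec)), rep("baseline", nrow(base))),
    scenario = ledger$scenario,
    year = c(rec$year, rep(NA, nrow(base))),
    center_id = c(rec$center_id, rep(NA, nrow(base))),
    category = c(rec$category, base$category),
    volume_m3 = c(rec$volume_m3, rep(NA, nrow(base))),
    new_area_ha = c(rec$new_area_ha, rep(NA, nrow(base))),
    rent_brl = c(rec$rent_brl, rep(NA, nrow(base))),
    stock_m3 = c(rep(NA, nrow(rec)), base$stock_m3),
    forest_area_ha = c(rep(NA, nrow(rec)), base$forest_area_ha),
    area_ha = c(rep(NA, nrow(rec)), base$area_ha),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname save_ledger
#' @export
load_ledger <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("section", "scenario", "year", "center_id", "category",
            "volume_m3", "new_area_ha", "rent_brl", "stock_m3",
            "forest_area_ha", "area_ha")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parse error: ledger file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  rec <- df[df$section == "record",
            c("year", "center_id", "category", "volume_m3", "new_area_ha", "rent_brl")]
  base <- df[df$section == "baseline",
             c("category", "stock_m3", "forest_area_ha", "area_ha")]
  rownames(rec) <- rownames(base) <- NULL
  annual_ledger(rec, base,
                scenario = if (nrow(df)) df$scenario[1] else NA_character_)
}
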