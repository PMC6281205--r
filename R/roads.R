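# Annual construction of unpaved roads connecting newly harvested cells to
# the existing transport network along least-cost paths.

#' Extend the road network to newly harvested cells
#'
#' Each harvested cell not already on the network is connected to its nearest
#' network cell (existing road/waterway or logging center) by the least-cost
#' path on the current friction surface; the path cells become unpaved road
#' (friction 0.5 thereafter). Paths are built in decreasing net-rent order of
#' their target cells, so roads built for the best cells cheapen access for
#' the rest within the same year. Cells inside barrier zoning are never
#' converted to road even when a path is forced across them.
#'
#' @param grid a [landscape_grid()].
#' @param friction a `friction_surface` (updated in place as roads appear).
#' @param events harvest-event data.frame from [allocate_harvest()]; the
#'   row order (rent-descending) sets the build order.
#' @param centers [logging_centers()] table; center cells anchor the network.
#' @return `list(grid, friction, build_log)` where `build_log` is a
#'   data.frame of newly built road cells (`target_cell`, `row`, `col`).
#' @export
extend_roads <- function(grid, friction, events, centers) {
  rdc <- road_codes()
  unpaved <- friction_table()$road[["unpaved"]]
  edge <- cell_edge_km(grid)
  network <- grid$roads != rdc[["none"]]
  act <- centers[centers$active, , drop = FALSE]
  network[cbind(act$row, act$col)] <- TRUE
  barrier <- matrix(grid$zoning %in% barrier_zones(), grid$n_rows)

  f <- friction$friction
  log_rows <- list()
  for (i in seq_len(nrow(events))) {
    r <- events$row[i]; c <- events$col[i]
    if (network[r, c]) next
    path <- cpp_path_to_network(f, network, r, c, edge)
    if (nrow(path) == 0) {
      warning(sprintf("cell (%d,%d) unreachable; no road built", r, c), call. = FALSE)
      next
    }
    pc <- cbind(path[, 1], path[, 2])
    if (any(barrier[pc]))
      warning(sprintf("road to cell (%d,%d) crosses prohibitive terrain; barrier cells not converted",
                      r, c), call. = FALSE)
    new_cells <- !network[pc] & !barrier[pc]
    conv <- pc[new_cells, , drop = FALSE]
    grid$roads[conv] <- rdc[["unpaved"]]
    f[conv] <- pmin(f[conv], unpaved)
    network[pc[!barrier[pc], , drop = FALSE]] <- TRUE
    if (nrow(conv))
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(target_cell = (c - 1L) * grid$n_rows + r,
                   row = conv[, 1], col = conv[, 2])
  }
  friction$friction <- f
  build_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(target_cell = integer(), row = integer(), col = integer())
  list(grid = grid, friction = friction, build_log = build_log)
}
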