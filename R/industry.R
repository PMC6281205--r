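# Logging-center capacity evolution, shutdown and emergence of new centers.

#' Annual capacity update of a logging center
#'
#' If the profitable volume available in the center's area of influence
#' exceeds the current capacity, capacity grows by at most `max_growth`
#' (never past the available volume). Otherwise capacity declines to track
#' the available volume exactly; a center whose capacity reaches zero shuts
#' down.
#'
#' @param capacity current capacity, m3/yr.
#' @param profitable_volume positive-rent harvestable volume in the area of
#'   influence, m3. Vectorised.
#' @param max_growth maximum relative growth per year (default 0.20).
#' @return New capacity, m3/yr.
#' @export
update_capacity <- function(capacity, profitable_volume, max_growth = 0.20) {
  stopifnot(all(capacity >= 0), all(profitable_volume >= 0), max_growth >= 0)
  ifelse(profitable_volume > capacity,
         pmin(capacity * (1 + max_growth), profitable_volume),
         profitable_volume)
}

# windowed sum via an integral image; square (Chebyshev) window of the given
# half-width in cells
window_sum <- function(m, half_width) {
  nr <- nrow(m); nc <- ncol(m)
  ii <- apply(apply(m, 2, cumsum), 1, cumsum)   # transposed integral image
  ii <- t(ii)
  pad <- function(i, n) pmin(pmax(i, 0L), n)
  out <- matrix(0, nr, nc)
  r <- seq_len(nr); c <- seq_len(nc)
  r1 <- pad(r - half_width - 1L, nr); r2 <- pad(r + half_width, nr)
  c1 <- pad(c - half_width - 1L, nc); c2 <- pad(c + half_width, nc)
  at <- function(ri, ci) {
    v <- matrix(0, nr, nc)
    ok_r <- ri > 0L; ok_c <- ci > 0L
    v[ok_r, ok_c] <- ii[ri[ok_r], ci[ok_c], drop = FALSE]
    v
  }
  at(r2, c2) - at(r1, c2) - at(r2, c1) + at(r1, c1)
}

#' Site an emerging logging center after a shutdown
#'
#' When a center shuts down, the industry searches for a nearby area of high
#' profitable volume to found a new one. Candidate cells must lie within the
#' 200-500 km straight-line band from the nearest active center; among them
#' the cell maximising the profitable harvestable volume within a local
#' window (default 50 km radius) wins, ties broken by the simulation RNG.
#' The newborn inherits price and harvest cost from the nearest existing
#' center and starts at `newborn_capacity` (50,000 m3/yr by default).
#'
#' @param grid a [landscape_grid()].
#' @param profitable_volume matrix of positive-rent harvestable volume per
#'   cell, m3 (zero where unprofitable or not harvestable).
#' @param centers current [logging_centers()] table (all, active and not).
#' @param params a [sim_params()].
#' @return A one-row center data.frame, or `NULL` when no cell falls in the
#'   emergence band.
#' @export
spawn_center <- function(grid, profitable_volume, centers, params) {
  act <- centers[centers$active, , drop = FALSE]
  edge <- cell_edge_km(grid)
  nr <- grid$n_rows; nc <- grid$n_cols
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d_near <- matrix(Inf, nr, nc)
  if (nrow(act)) {
    for (k in seq_len(nrow(act)))
      d_near <- pmin(d_near, sqrt((rows - act$row[k])^2 + (cols - act$col[k])^2) * edge)
  }
  band <- d_near >= params$min_spawn_distance & d_near <= params$max_spawn_distance
  band <- band & profitable_volume > 0
  if (!any(band)) return(NULL)

  half <- max(1L, as.integer(round(params$spawn_window_km / edge)))
  score <- window_sum(profitable_volume, half)
  best <- max(score[band])
  cand <- which(band & score >= best)
  pick <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
  pr <- (pick - 1L) %% nr + 1L
  pc <- (pick - 1L) %/% nr + 1L

  src <- centers[which.min(sqrt((centers$row - pr)^2 + (centers$col - pc)^2)), ]
  data.frame(id = max(centers$id) + 1L, row = pr, col = pc,
             capacity_m3yr = params$newborn_capacity,
             price_brl_m3 = src$price_brl_m3,
             harvest_cost_brl_m3 = src$harvest_cost_brl_m3,
             active = TRUE)
}
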