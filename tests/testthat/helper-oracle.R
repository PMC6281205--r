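# Independent brute-force oracles, deliberately naive and separate from the
# package's own algorithms.

# O(V^2) multi-source Dijkstra on the same step-cost graph as cost_distance():
# 8-connectivity, mean-of-endpoints friction, sqrt(2) diagonal scaling.
oracle_cost_distance <- function(friction, centers, edge_km = 1) {
  nr <- nrow(friction); nc <- ncol(friction); n <- nr * nc
  dist <- rep(Inf, n); alloc <- rep(NA_integer_, n); done <- rep(FALSE, n)
  for (k in seq_len(nrow(centers))) {
    i <- (centers$col[k] - 1L) * nr + centers$row[k]
    if (dist[i] > 0) { dist[i] <- 0; alloc[i] <- centers$id[k] }
  }
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    r <- (u - 1L) %% nr + 1L; c <- (u - 1L) %/% nr + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      v <- (cc - 1L) * nr + rr
      len <- edge_km * if (dr != 0 && dc != 0) sqrt(2) else 1
      nd <- dist[u] + 0.5 * (friction[u] + friction[v]) * len
      if (nd < dist[v]) { dist[v] <- nd; alloc[v] <- alloc[u] }
    }
  }
  list(tc = matrix(dist, nr), allocation = matrix(alloc, nr))
}

# exhaustive greedy harvest allocation: full sort, then sweep
oracle_allocate <- function(cells, rent, harvestable, capacity, n_rows) {
  df <- data.frame(cell = cells, rent = rent[cells], vol = harvestable[cells])
  df$row <- (df$cell - 1L) %% n_rows + 1L
  df$col <- (df$cell - 1L) %/% n_rows + 1L
  df <- df[df$rent > 0 & df$vol > 0, ]
  df <- df[order(-df$rent, df$row, df$col), ]
  taken <- numeric(0); cell <- integer(0)
  left <- capacity
  for (i in seq_len(nrow(df))) {
    if (left <= 0) break
    v <- min(df$vol[i], left)
    taken <- c(taken, v); cell <- c(cell, df$cell[i])
    left <- left - v
  }
  data.frame(cell = cell, volume_m3 = taken)
}

# naive windowed (square) sum
oracle_window_sum <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rs <- max(1, r - half):min(nr, r + half)
    cs <- max(1, c - half):min(nc, c + half)
    out[r, c] <- sum(m[rs, cs])
  }
  out
}

# random landscape for property tests: valid small grid with assorted terrain
random_small_grid <- function(nr, nc, seed, n_centers = 1) {
  withr::with_seed(seed, {
    lcc <- land_cover_codes(); znc <- zoning_codes(); rdc <- road_codes()
    land_cover <- matrix(sample(lcc, nr * nc, replace = TRUE,
                                prob = c(0.7, 0.15, 0.1, 0.05)), nr)
    zoning <- matrix(sample(znc, nr * nc, replace = TRUE,
                            prob = c(0.4, 0.1, 0.05, 0.1, 0.1, 0.1, 0.1, 0.05)), nr)
    roads <- matrix(sample(rdc, nr * nc, replace = TRUE,
                           prob = c(0.8, 0.05, 0.08, 0.02, 0.03, 0.02)), nr)
    volume <- matrix(stats::runif(nr * nc, 0, 50), nr)
    grid <- landscape_grid(volume, land_cover, zoning, roads)
    pos <- sample(nr * nc, n_centers)
    centers <- logging_centers(data.frame(
      id = seq_len(n_centers),
      row = (pos - 1L) %% nr + 1L, col = (pos - 1L) %/% nr + 1L,
      capacity_m3yr = stats::runif(n_centers, 5e4, 2e5),
      price_brl_m3 = stats::runif(n_centers, 100, 180),
      harvest_cost_brl_m3 = stats::runif(n_centers, 30, 60)), grid)
    list(grid = grid, centers = centers)
  })
}
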