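# Seeded generator of synthetic landscapes: spatially autocorrelated volume
# fields, contiguous zoning mosaics, sparse road networks and center tables
# with the statistical structure the analysis assumes.

#' Specification of a synthetic landscape
#'
#' Defaults emulate the Amazon-scale inputs: forest-cell volume averaging
#' 16 m3/ha (the published baseline stock/area ratio, 4,835 Mm3 over 302 Mha
#' of forest), a contiguous zoning mosaic with the category area fractions of
#' the public-forest registry, ~60 % forest cover, and per-center prices,
#' harvest costs and capacities in the reported 2009 ranges.
#'
#' @param n_rows,n_cols grid shape.
#' @param cell_area ha per cell (default 100 = 1 km cells).
#' @param mean_forest_volume mean commercial volume on forest cells, m3/ha.
#' @param volume_sill variance of the volume field, (m3/ha)^2.
#' @param correlation_range autocorrelation range of the volume field, cells.
#' @param category_fractions named vector of target zoning area fractions
#'   (must cover [zoning_codes()] and sum to 1).
#' @param land_cover_fractions named vector of land-cover area fractions.
#' @param n_centers number of logging centers.
#' @param capacity_range,price_range,harvest_cost_range uniform draw ranges
#'   for the center table (m3/yr, R$/m3, R$/m3).
#' @param road_density expected extra road spurs per cell (the center-
#'   connecting trunk network is always built).
#' @param price_floor optional R$/m3 threshold: price draws below it are
#'   treated as unreliable outliers and replaced by the mean of all draws.
#' @param seed integer RNG seed.
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(n_rows = 100, n_cols = 100, cell_area = 100,
                           mean_forest_volume = 16, volume_sill = 64,
                           correlation_range = 10,
                           category_fractions = c(
                             private_nonprotected = 0.42,
                             sustainable_use_other = 0.11,
                             national_forest = 0.03,
                             undesignated_federal = 0.08,
                             undesignated_state = 0.07,
                             strictly_protected = 0.13,
                             indigenous = 0.15,
                             military = 0.01),
                           land_cover_fractions = c(
                             forest = 0.60, deforested = 0.25,
                             grassland = 0.13, non_navigable_water = 0.02),
                           n_centers = 4,
                           capacity_range = c(5e4, 5e5),
                           price_range = c(100, 200),
                           harvest_cost_range = c(30, 60),
                           road_density = 0.003, price_floor = NULL,
                           seed = 1L) {
  spec <- as.list(environment())
  if (abs(sum(category_fractions) - 1) > 1e-8)
    stop("spec error: category fractions must sum to 1", call. = FALSE)
  if (any(category_fractions < 0) || any(land_cover_fractions < 0))
    stop("spec error: fractions must be >= 0", call. = FALSE)
  if (abs(sum(land_cover_fractions) - 1) > 1e-8)
    stop("spec error: land-cover fractions must sum to 1", call. = FALSE)
  if (!setequal(names(category_fractions), names(zoning_codes())))
    stop("spec error: category_fractions must cover all zoning categories",
         call. = FALSE)
  if (mean_forest_volume <= 0)
    stop("spec error: mean_forest_volume must be > 0", call. = FALSE)
  for (rg in list(capacity_range, price_range, harvest_cost_range))
    if (length(rg) != 2 || rg[1] > rg[2])
      stop("spec error: ranges must be c(lo, hi) with lo <= hi", call. = FALSE)
  if (n_rows * n_cols < 9 * n_centers)
    stop("spec error: grid too small for n_centers", call. = FALSE)
  class(spec) <- "landscape_spec"
  spec
}

# ---------------------------------------------------------------------------
# building blocks

# unassigned 4-neighbours of a region mask
region_frontier <- function(mask, unassigned) {
  nr <- nrow(mask); nc <- ncol(mask)
  nb <- matrix(FALSE, nr, nc)
  nb[-1, ] <- nb[-1, ] | mask[-nr, ]
  nb[-nr, ] <- nb[-nr, ] | mask[-1, ]
  nb[, -1] <- nb[, -1] | mask[, -nc]
  nb[, -nc] <- nb[, -nc] | mask[, -1]
  nb & unassigned
}

# contiguous mosaic by quota-bounded multi-seed region growing
grow_mosaic <- function(n_rows, n_cols, fractions, mean_patch_cells = 600) {
  n <- n_rows * n_cols
  k <- length(fractions)
  quota <- floor(fractions * n)
  quota[which.max(quota)] <- quota[which.max(quota)] + (n - sum(quota))
  zone <- matrix(0L, n_rows, n_cols)
  counts <- integer(k)
  # seeds: roughly one per mean_patch_cells of quota
  for (i in seq_len(k)) {
    if (quota[i] == 0) next
    ns <- max(1L, round(quota[i] / mean_patch_cells))
    free <- which(zone == 0L)
    s <- sample(free, min(ns, length(free)))
    zone[s] <- i
    counts[i] <- counts[i] + length(s)
  }
  repeat {
    un <- zone == 0L
    if (!any(un)) break
    progress <- FALSE
    for (i in sample.int(k)) {
      rem <- quota[i] - counts[i]
      if (rem <= 0) next
      fr <- which(region_frontier(zone == i, un))
      if (!length(fr)) {                       # trapped: re-seed
        free <- which(un)
        fr <- sample(free, 1L)
      }
      take <- if (length(fr) > rem) sample(fr, rem) else fr
      zone[take] <- i
      counts[i] <- counts[i] + length(take)
      un[take] <- FALSE
      progress <- TRUE
    }
    if (!progress) {                           # quotas met; flood the rest
      for (i in seq_len(k)) {
        fr <- which(region_frontier(zone == i, un))
        if (length(fr)) { zone[fr] <- i; un[fr] <- FALSE }
      }
      if (any(un) && all(!vapply(seq_len(k), function(i)
        any(region_frontier(zone == i, un)), TRUE))) {
        zone[un] <- sample.int(k, sum(un), replace = TRUE)
        un[] <- FALSE
      }
    }
  }
  zone
}

# stationary Gaussian random field, mean 0 sd 1, via circular convolution of
# white noise with a Gaussian kernel
gaussian_field <- function(n_rows, n_cols, range_cells) {
  wrap_dist <- function(n) {
    d <- 0:(n - 1)
    pmin(d, n - d)
  }
  kern <- outer(exp(-wrap_dist(n_rows)^2 / (2 * range_cells^2)),
                exp(-wrap_dist(n_cols)^2 / (2 * range_cells^2)))
  w <- matrix(stats::rnorm(n_rows * n_cols), n_rows)
  z <- Re(stats::fft(stats::fft(w) * stats::fft(kern), inverse = TRUE)) /
    (n_rows * n_cols)
  (z - mean(z)) / stats::sd(z)
}

# 8-connected raster line
line_cells <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0), 1L)
  t <- 0:n
  cbind(round(r0 + (r1 - r0) * t / n), round(c0 + (c1 - c0) * t / n))
}

#' Generate a synthetic landscape
#'
#' Deterministic for a fixed `spec$seed`: a contiguous zoning mosaic matching
#' the target category fractions, a land-cover mosaic, a positive spatially
#' autocorrelated (log-Gaussian) volume field on forest cells, a road
#' skeleton connecting all centers, and a center table drawn from the
#' configured ranges.
#'
#' @param spec a [landscape_spec()].
#' @return `list(grid = landscape_grid, centers = logging_centers)`.
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  withr::with_seed(spec$seed, {
    nr <- spec$n_rows; nc <- spec$n_cols
    znc <- zoning_codes(); lcc <- land_cover_codes(); rdc <- road_codes()

    zoning <- grow_mosaic(nr, nc, spec$category_fractions[names(znc)])
    land_cover <- grow_mosaic(nr, nc, spec$land_cover_fractions[names(lcc)],
                              mean_patch_cells = 300)

    # log-Gaussian volume on forest cells: exact target mean in expectation
    z <- gaussian_field(nr, nc, spec$correlation_range)
    mu <- spec$mean_forest_volume
    sigma <- sqrt(log(1 + spec$volume_sill / mu^2))
    volume <- mu * exp(sigma * z - sigma^2 / 2)
    volume[land_cover != lcc[["forest"]]] <- 0

    # centers on non-water land, pairwise separated
    land <- which(land_cover != lcc[["non_navigable_water"]])
    min_sep <- max(3, round(min(nr, nc) / (spec$n_centers + 1)))
    rows <- (land - 1L) %% nr + 1L
    cols <- (land - 1L) %/% nr + 1L
    chosen <- integer(0)
    for (tries in seq_len(200 * spec$n_centers)) {
      if (length(chosen) == spec$n_centers) break
      cand <- sample(seq_along(land), 1L)
      if (!length(chosen) ||
          min(sqrt((rows[cand] - rows[chosen])^2 +
                   (cols[cand] - cols[chosen])^2)) >= min_sep)
        chosen <- c(chosen, cand)
    }
    if (length(chosen) < spec$n_centers) {
      extra <- sample(setdiff(seq_along(land), chosen),
                      spec$n_centers - length(chosen))
      chosen <- c(chosen, extra)
    }
    crow <- rows[chosen]; ccol <- cols[chosen]

    prices <- stats::runif(spec$n_centers, spec$price_range[1], spec$price_range[2])
    if (!is.null(spec$price_floor)) {
      low <- prices < spec$price_floor
      if (any(low)) prices[low] <- mean(prices)
    }
    centers <- data.frame(
      id = seq_len(spec$n_centers), row = crow, col = ccol,
      capacity_m3yr = stats::runif(spec$n_centers, spec$capacity_range[1],
                                   spec$capacity_range[2]),
      price_brl_m3 = prices,
      harvest_cost_brl_m3 = stats::runif(spec$n_centers,
                                         spec$harvest_cost_range[1],
                                         spec$harvest_cost_range[2]))

    # road skeleton: minimum spanning tree over the centers, plus spurs
    roads <- matrix(rdc[["none"]], nr, nc)
    if (spec$n_centers > 1) {
      d <- as.matrix(stats::dist(cbind(crow, ccol)))
      in_tree <- 1L
      while (length(in_tree) < spec$n_centers) {
        dd <- d[in_tree, -in_tree, drop = FALSE]
        j <- which(dd == min(dd), arr.ind = TRUE)[1, ]
        from <- in_tree[j[1]]
        to <- setdiff(seq_len(spec$n_centers), in_tree)[j[2]]
        cls <- if (stats::runif(1) < 0.35) rdc[["paved"]] else rdc[["unpaved"]]
        roads[line_cells(crow[from], ccol[from], crow[to], ccol[to])] <- cls
        in_tree <- c(in_tree, to)
      }
    }
    n_spurs <- round(spec$road_density * nr * nc)
    road_cells <- which(roads != rdc[["none"]])
    for (s in seq_len(n_spurs)) {
      anchors <- if (length(road_cells)) road_cells else
        (ccol - 1L) * nr + crow
      a <- anchors[sample.int(length(anchors), 1L)]
      ar <- (a - 1L) %% nr + 1L; ac <- (a - 1L) %/% nr + 1L
      tr <- max(1L, min(nr, ar + sample(-15:15, 1L)))
      tc <- max(1L, min(nc, ac + sample(-15:15, 1L)))
      roads[line_cells(ar, ac, tr, tc)] <- rdc[["unpaved"]]
      road_cells <- which(roads != rdc[["none"]])
    }

    grid <- landscape_grid(volume = volume, land_cover = land_cover,
                           zoning = zoning, roads = roads,
                           cell_area = spec$cell_area)
    list(grid = grid, centers = logging_centers(centers, grid))
  })
}

#' Pinned test fixtures
#'
#' Small, deterministic landscape bundles used throughout the test suite:
#' \describe{
#'   \item{tiny_oracle}{15 x 15, one center, mixed friction (roads, river,
#'     a strictly protected block) — the cost-distance oracle fixture.}
#'   \item{leakage_demo}{30 x 30, one capacity-limited center, a National
#'     Forest block ringed by private and undesignated land of equal volume,
#'     so conventional logging outside draws harvest away from the National
#'     Forest under the ILLEGAL scenario.}
#'   \item{two_centers}{20 x 20, two well-separated centers.}
#' }
#'
#' @param name one of `"tiny_oracle"`, `"leakage_demo"`, `"two_centers"`.
#' @return `list(grid, centers, params)`.
#' @export
generate_fixture <- function(name) {
  lcc <- land_cover_codes(); znc <- zoning_codes(); rdc <- road_codes()
  if (name == "tiny_oracle") {
    nr <- 15L; nc <- 15L
    land_cover <- matrix(lcc[["forest"]], nr, nc)
    land_cover[6, ] <- lcc[["non_navigable_water"]]   # a river barrier strip
    land_cover[6, 8] <- lcc[["forest"]]               # with one ford
    land_cover[12:13, 2:5] <- lcc[["deforested"]]
    zoning <- matrix(znc[["private_nonprotected"]], nr, nc)
    zoning[1:3, 12:15] <- znc[["strictly_protected"]]
    zoning[9:11, 1:3] <- znc[["national_forest"]]
    roads <- matrix(rdc[["none"]], nr, nc)
    roads[10, ] <- rdc[["paved"]]
    roads[, 8] <- rdc[["unpaved"]]
    volume <- matrix(20, nr, nc)
    grid <- landscape_grid(volume, land_cover, zoning, roads, cell_area = 100)
    centers <- logging_centers(data.frame(
      id = 1L, row = 10L, col = 8L, capacity_m3yr = 1e5,
      price_brl_m3 = 120, harvest_cost_brl_m3 = 40), grid)
    list(grid = grid, centers = centers,
         params = sim_params(rng_seed = 42L))
  } else if (name == "leakage_demo") {
    nr <- 30L; nc <- 30L
    land_cover <- matrix(lcc[["forest"]], nr, nc)
    zoning <- matrix(znc[["private_nonprotected"]], nr, nc)
    zoning[11:20, 3:12] <- znc[["national_forest"]]
    zoning[11:20, 19:28] <- znc[["undesignated_federal"]]
    roads <- matrix(rdc[["none"]], nr, nc)
    volume <- matrix(40, nr, nc)
    grid <- landscape_grid(volume, land_cover, zoning, roads, cell_area = 100)
    centers <- logging_centers(data.frame(
      id = 1L, row = 15L, col = 15L, capacity_m3yr = 6e4,
      price_brl_m3 = 150, harvest_cost_brl_m3 = 40), grid)
    list(grid = grid, centers = centers,
         params = sim_params(rng_seed = 42L))
  } else if (name == "two_centers") {
    nr <- 20L; nc <- 20L
    land_cover <- matrix(lcc[["forest"]], nr, nc)
    zoning <- matrix(znc[["private_nonprotected"]], nr, nc)
    zoning[1:6, 1:6] <- znc[["undesignated_state"]]
    roads <- matrix(rdc[["none"]], nr, nc)
    roads[10, ] <- rdc[["unpaved"]]
    volume <- matrix(25, nr, nc)
    grid <- landscape_grid(volume, land_cover, zoning, roads, cell_area = 100)
    centers <- logging_centers(data.frame(
      id = 1:2, row = c(5L, 16L), col = c(5L, 16L),
      capacity_m3yr = c(8e4, 8e4), price_brl_m3 = c(130, 110),
      harvest_cost_brl_m3 = c(35, 45)), grid)
    list(grid = grid, centers = centers,
         params = sim_params(rng_seed = 42L))
  } else {
    stop("catalogue error: unknown fixture '", name, "'", call. = FALSE)
  }
}
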