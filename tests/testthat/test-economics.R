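# friction surface, cost distance, unit cost, net rent

test_that("friction assignment follows the precedence rules", {
  lcc <- land_cover_codes(); znc <- zoning_codes(); rdc <- road_codes()
  lc <- matrix(lcc[["forest"]], 5, 5)
  lc[1, 2] <- lcc[["non_navigable_water"]]
  lc[2, 1] <- lcc[["deforested"]]
  zn <- matrix(znc[["private_nonprotected"]], 5, 5)
  zn[3, 3] <- znc[["sustainable_use_other"]]
  zn[4, 4] <- znc[["strictly_protected"]]
  zn[1, 2] <- znc[["undesignated_federal"]]
  rd <- matrix(rdc[["none"]], 5, 5)
  rd[1, 1] <- rdc[["paved"]]
  rd[4, 4] <- rdc[["paved"]]
  rd[5, 5] <- rdc[["navigable_river"]]
  g <- landscape_grid(matrix(10, 5, 5), lc, zn, rd)
  fs <- build_friction_surface(g)

  expect_equal(fs$friction[1, 1], 0.3)    # paved road on private land
  expect_equal(fs$friction[3, 3], 0.8)    # forest, no road, sustainable use
  expect_equal(fs$friction[2, 2], 0.8)    # plain forest
  expect_equal(fs$friction[2, 1], 0.7)    # deforested
  expect_equal(fs$friction[5, 5], 0.1)    # navigable river
  # barrier dominates even a paved road; provenance flags the zoning rule
  expect_equal(fs$friction[4, 4], 5000)
  expect_identical(fs$provenance[4, 4], "zoning_barrier")
  # soft zoning caps expensive land cover (water inside undesignated land)
  expect_equal(fs$friction[1, 2], 0.8)
  expect_identical(fs$provenance[1, 2], "zoning")
})

test_that("uniform-friction cost distance matches the closed form", {
  f <- matrix(0.8, 9, 9)
  ctr <- data.frame(id = 1L, row = 5L, col = 5L)
  cs <- cost_distance(structure(list(friction = f), class = "friction_surface"),
                      data.frame(ctr, capacity_m3yr = 1, price_brl_m3 = 1,
                                 harvest_cost_brl_m3 = 0, active = TRUE),
                      cell_edge_km = 1)
  expect_equal(cs$tc[5, 5], 0)                   # center cell
  expect_identical(cs$allocation[5, 5], 1L)
  expect_equal(cs$tc[5, 9], 0.8 * 4)             # straight axis path, d = 4
  expect_equal(cs$tc[1, 5], 0.8 * 4)
  expect_equal(cs$tc[1, 1], 0.8 * 4 * sqrt(2))   # pure diagonal
})

test_that("cost_distance equals the brute-force Dijkstra oracle", {
  # pinned fixture
  fx <- generate_fixture("tiny_oracle")
  fs <- build_friction_surface(fx$grid)
  cs <- cost_distance(fs, fx$centers, cell_edge_km = 1)
  or <- oracle_cost_distance(fs$friction, fx$centers, edge_km = 1)
  expect_equal(cs$tc, or$tc, tolerance = 1e-9)

  # random grids up to 20x20, multiple centers
  withr::local_seed(99)
  for (seed in 1:6) {
    nr <- sample(5:20, 1); nc <- sample(5:20, 1)
    rs <- random_small_grid(nr, nc, seed, n_centers = sample(1:3, 1))
    fs <- build_friction_surface(rs$grid)
    cs <- cost_distance(fs, rs$centers, cell_edge_km = 1)
    or <- oracle_cost_distance(fs$friction, rs$centers, edge_km = 1)
    expect_equal(cs$tc, or$tc, tolerance = 1e-9)
    # allocation is an arg-min: the allocated center's single-source cost
    # equals the multi-source cost everywhere
    for (k in seq_len(nrow(rs$centers))) {
      single <- oracle_cost_distance(fs$friction, rs$centers[k, ], edge_km = 1)
      mine <- cs$allocation == rs$centers$id[k]
      expect_true(all(abs(single$tc[mine] - cs$tc[mine]) < 1e-9))
    }
  }
})

test_that("cheaper roads never increase accumulated cost (monotonicity)", {
  fx <- generate_fixture("two_centers")
  fs0 <- build_friction_surface(fx$grid)
  cs0 <- cost_distance(fs0, fx$centers)
  g2 <- fx$grid
  g2$roads[15, ] <- road_codes()[["paved"]]      # add a paved corridor
  fs1 <- build_friction_surface(g2)
  cs1 <- cost_distance(fs1, fx$centers)
  expect_true(all(cs1$tc <= cs0$tc + 1e-9))
})

test_that("barriers are prohibitive, not absolute", {
  znc <- zoning_codes()
  zn <- matrix(znc[["private_nonprotected"]], 9, 9)
  zn[4:6, 4] <- znc[["strictly_protected"]]      # ring around the center
  zn[4:6, 6] <- znc[["strictly_protected"]]
  zn[4, 5] <- znc[["strictly_protected"]]
  zn[6, 5] <- znc[["strictly_protected"]]
  g <- landscape_grid(matrix(10, 9, 9), matrix(1L, 9, 9), zn, matrix(0L, 9, 9))
  ctr <- logging_centers(data.frame(id = 1L, row = 5L, col = 5L,
                                    capacity_m3yr = 1, price_brl_m3 = 1,
                                    harvest_cost_brl_m3 = 0), g)
  cs <- cost_distance(build_friction_surface(g), ctr)
  outside <- cs$tc[1, 1]
  expect_true(is.finite(outside))
  expect_gt(outside, 2500)   # at least one barrier half-step at 5000/2
})

test_that("areas of influence partition the grid", {
  fx <- generate_fixture("two_centers")
  cs <- cost_distance(build_friction_surface(fx$grid), fx$centers)
  expect_true(all(is.finite(cs$tc)))
  expect_true(all(cs$allocation %in% fx$centers$id))
  expect_setequal(unique(as.vector(cs$allocation)), fx$centers$id)
})

test_that("no active centers is a state error", {
  fx <- generate_fixture("tiny_oracle")
  ctr <- fx$centers
  ctr$active <- FALSE
  expect_error(cost_distance(build_friction_surface(fx$grid), ctr),
               "state error")
})

test_that("unit_total_cost implements the capital-cost markup", {
  expect_equal(unit_total_cost(10, 20, 0.05), 31.5)
  expect_equal(unit_total_cost(10, 20, 0), 30)
  expect_equal(unit_total_cost(0, 0, 0.05), 0)
  expect_error(unit_total_cost(-1, 0, 0.05), "domain error")
})

test_that("net rent applies the mode-specific harvestable volume", {
  lcc <- land_cover_codes()
  g <- landscape_grid(matrix(c(25.8, 40, 40, 40), 2, 2),
                      matrix(lcc[["forest"]], 2, 2),
                      matrix(zoning_codes()[["private_nonprotected"]], 2, 2),
                      matrix(road_codes()[["none"]], 2, 2))
  g$price <- matrix(100, 2, 2)
  g$harvest_cost <- matrix(10, 2, 2)
  cs <- list(tc = matrix(20, 2, 2), allocation = matrix(1L, 2, 2))
  params <- sim_params()
  modes <- harvest_modes()
  mm <- matrix(modes[["RIL"]], 2, 2)
  mm[1, 2] <- modes[["CL"]]
  mm[2, 2] <- modes[["NONE"]]

  rm_ <- net_rent_map(g, cs, params, mm)
  # v = 25.8, 100 ha, margin 100 - 31.5 = 68.5 -> 2580 * 68.5
  expect_equal(rm_$rent[1, 1], 2580 * 68.5)
  # RIL cap: 40 m3/ha capped at 25.8; CL uses the full 40
  expect_equal(rm_$rent[2, 1], 2580 * 68.5)
  expect_equal(rm_$rent[1, 2], 4000 * 68.5)
  expect_equal(rm_$rent[1, 2] / rm_$rent[2, 1], 40 / 25.8)
  expect_equal(rm_$rent[2, 2], 0)               # NONE cell
  expect_false(rm_$profitable[2, 2])

  # price equal to unit cost -> zero rent, unprofitable
  g$price <- matrix(31.5, 2, 2)
  rm0 <- net_rent_map(g, cs, params, mm)
  expect_true(all(rm0$rent <= 0))
  expect_false(any(rm0$profitable))

  expect_error(net_rent_map(g, cs, params, matrix(0L, 3, 3)),
               "registration error")
})
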