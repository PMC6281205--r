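# the annual loop, scenario configurations and run-level invariants

test_that("zero years leaves the world untouched", {
  fx <- generate_fixture("two_centers")
  led <- run_scenario(fx$grid, fx$centers, scenario_config("LEGAL", fx$params),
                      years = 0)
  expect_identical(nrow(led$records), 0L)
  expect_identical(attr(led, "final_grid")$volume, fx$grid$volume)
})

test_that("runs are deterministic for identical inputs and seed", {
  fx <- generate_fixture("two_centers")
  a <- suppressWarnings(run_scenario(fx$grid, fx$centers,
                                     scenario_config("ILLEGAL", fx$params),
                                     years = 8))
  b <- suppressWarnings(run_scenario(fx$grid, fx$centers,
                                     scenario_config("ILLEGAL", fx$params),
                                     years = 8))
  expect_identical(a$records, b$records)
  expect_identical(attr(a, "final_grid")$volume, attr(b, "final_grid")$volume)
  expect_identical(attr(a, "center_log"), attr(b, "center_log"))
})

test_that("run-level invariants hold on a synthetic landscape", {
  ls1 <- generate_landscape(landscape_spec(n_rows = 50, n_cols = 50, seed = 31L,
                                           n_centers = 2))
  params <- sim_params(rng_seed = 31L)
  for (name in c("LEGAL", "ILLEGAL")) {
    led <- suppressWarnings(
      run_scenario(ls1$grid, ls1$centers, scenario_config(name, params),
                   years = 12))
    g_end <- attr(led, "final_grid")
    # conservation: baseline stock = remaining + harvested
    expect_equal(total_stock(ls1$grid),
                 total_stock(g_end) + sum(led$records$volume_m3),
                 tolerance = 1e-6)
    # zoning safety: no volume from protected categories
    expect_false(any(led$records$category %in%
                       c("strictly_protected", "indigenous", "military")))
    # ledger consistency: entries non-negative, yearly harvest <= capacity
    expect_true(all(led$records$volume_m3 >= 0))
    expect_true(all(led$records$new_area_ha >= 0))
    harv <- aggregate(volume_m3 ~ year + center_id, led$records, sum)
    cl <- attr(led, "center_log")
    key <- paste(harv$year, harv$center_id)
    cap <- cl$capacity_start_m3yr[match(key, paste(cl$year, cl$id))]
    expect_true(all(harv$volume_m3 <= cap + 1e-6))
  }
})

test_that("RIL cap and single entry hold through a LEGAL run", {
  fx <- generate_fixture("leakage_demo")
  led <- suppressWarnings(
    run_scenario(fx$grid, fx$centers, scenario_config("LEGAL", fx$params)))
  ev <- attr(led, "events")
  # per-cell removals never exceed 25.8 m3/ha x 100 ha
  by_cell <- tapply(ev$volume_m3, ev$cell, sum)
  expect_true(all(by_cell <= 25.8 * 100 + 1e-6))
  # single entry: no RIL cell harvested twice
  ril <- ev[ev$mode == harvest_modes()[["RIL"]], ]
  expect_false(anyDuplicated(ril$cell) > 0)
})

test_that("CL cells may be re-entered but NONE cells never harvested", {
  fx <- generate_fixture("two_centers")
  fx$grid$zoning[1:4, 10:14] <- zoning_codes()[["indigenous"]]
  led <- suppressWarnings(
    run_scenario(fx$grid, fx$centers, scenario_config("ILLEGAL", fx$params),
                 years = 15))
  ev <- attr(led, "events")
  expect_true(all(ev$mode != harvest_modes()[["NONE"]]))
  protected_cells <- which(matrix(fx$grid$zoning %in%
                                    c(zoning_codes()[["indigenous"]]),
                                  fx$grid$n_rows))
  expect_false(any(ev$cell %in% protected_cells))
})

test_that("paired runs share the baseline and reproduce the leakage direction", {
  fx <- generate_fixture("leakage_demo")
  pair <- suppressWarnings(run_pair(fx$grid, fx$centers, fx$params))
  expect_equal(pair$LEGAL$baseline, pair$ILLEGAL$baseline)

  tl <- summarize_ledger(pair$LEGAL)
  ti <- summarize_ledger(pair$ILLEGAL)
  nf <- function(tb, col) tb[tb$category == "national_forest", col]
  outside <- function(tb, col)
    sum(tb[tb$category %in% c("private_nonprotected", "undesignated_federal",
                              "undesignated_state"), col])
  # harvest leaks out of the National Forest under ILLEGAL
  expect_lt(nf(ti, "area_Mha"), nf(tl, "area_Mha"))
  expect_lt(nf(ti, "volume_Mm3"), nf(tl, "volume_Mm3"))
  expect_gt(outside(ti, "volume_Mm3"), outside(tl, "volume_Mm3"))
  # CL is unconstrained by the intensity cap: total volume at least as large
  expect_gte(sum(ti$volume_Mm3[ti$category == "total"]),
             sum(tl$volume_Mm3[tl$category == "total"]))
  # LEGAL removals all respect the cap
  evl <- attr(pair$LEGAL, "events")
  expect_true(all(evl$volume_m3 <= 25.8 * fx$grid$cell_area + 1e-6))
})
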