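# FMU/APU partition, mode assignment, eligibility, allocation, application

test_that("max_ril_removal is intensity times cycle length", {
  expect_equal(max_ril_removal(0.86, 30), 25.8)
  expect_equal(max_ril_removal(0, 30), 0)
  expect_equal(max_ril_removal(1.0, 10), 10)
})

test_that("an exact 270-cell block partitions into 30 APUs of 9 cells", {
  mask <- matrix(TRUE, 18, 15)   # 270 cells = 27,000 ha at 100 ha/cell
  p <- partition_fmus(mask, fmu_area = 27000, cycle_years = 30, cell_area = 100)
  expect_identical(length(unique(na.omit(as.vector(p$fmu_id)))), 1L)
  counts <- table(p$apu_index)
  expect_identical(length(counts), 30L)          # 27,000 / 900 = 30 APUs
  expect_true(all(counts == 9))                  # 900 ha = 9 cells each
  # each APU is a contiguous 3x3 sub-block
  for (k in c(1, 17, 30)) {
    cells <- which(p$apu_index == k, arr.ind = TRUE)
    expect_equal(diff(range(cells[, 1])), 2)
    expect_equal(diff(range(cells[, 2])), 2)
  }
})

test_that("every RIL cell gets exactly one (fmu, apu) and flags start clear", {
  mask <- matrix(FALSE, 40, 40)
  mask[3:35, 5:38] <- TRUE
  p <- suppressWarnings(
    partition_fmus(mask, 27000, 30, 100))
  expect_true(all(!is.na(p$fmu_id[mask])))
  expect_true(all(!is.na(p$apu_index[mask])))
  expect_true(all(is.na(p$fmu_id[!mask])))
  expect_true(all(p$apu_index[mask] >= 1 & p$apu_index[mask] <= 30))
  expect_false(any(p$harvested_flag))
  # truncated FMUs: APU sizes within each FMU differ by at most one cell
  for (f in unique(na.omit(as.vector(p$fmu_id)))) {
    sizes <- table(p$apu_index[p$fmu_id == f & !is.na(p$fmu_id)])
    expect_lte(diff(range(sizes)), 1)
  }
})

test_that("degenerate 5-cell region yields one truncated FMU with a warning", {
  mask <- matrix(FALSE, 10, 10)
  mask[1, 1:5] <- TRUE
  expect_warning(p <- partition_fmus(mask, 27000, 30, 100), "truncated")
  expect_identical(length(unique(na.omit(as.vector(p$fmu_id)))), 1L)
  expect_true(all(table(p$apu_index) <= 1))
  expect_error(partition_fmus(mask, 900, 30, 100), "configuration error")
})

test_that("assign_modes follows the scenario table", {
  znc <- zoning_codes()
  zn <- matrix(znc, 2, 4)   # all eight categories
  legal <- scenario_config("LEGAL")
  illegal <- scenario_config("ILLEGAL")
  modes <- harvest_modes()

  m_l <- assign_modes(zn, legal)
  m_i <- assign_modes(zn, illegal)
  at <- function(m, cat) m[which(zn == znc[[cat]])[1]]

  expect_identical(at(m_i, "undesignated_federal"), modes[["CL"]])
  expect_identical(at(m_i, "private_nonprotected"), modes[["CL"]])
  expect_identical(at(m_i, "national_forest"), modes[["RIL"]])
  expect_identical(at(m_i, "sustainable_use_other"), modes[["RIL"]])
  expect_identical(at(m_l, "undesignated_federal"), modes[["RIL"]])
  expect_identical(at(m_l, "private_nonprotected"), modes[["RIL"]])
  for (cat in c("indigenous", "strictly_protected", "military")) {
    expect_identical(at(m_l, cat), modes[["NONE"]])
    expect_identical(at(m_i, cat), modes[["NONE"]])
  }

  partial <- scenario_config("X", category_mode = c(private_nonprotected = "CL"))
  expect_error(assign_modes(zn, partial), "configuration error")
  expect_error(scenario_config("X", category_mode = c(indigenous = "RIL")),
               "cannot be harvested")
})

test_that("eligibility: APU-of-the-year for RIL, remaining volume for CL", {
  lcc <- land_cover_codes()
  g <- landscape_grid(matrix(c(30, 30, 5, 0), 2, 2),
                      matrix(lcc[["forest"]], 2, 2),
                      matrix(zoning_codes()[["private_nonprotected"]], 2, 2),
                      matrix(road_codes()[["none"]], 2, 2))
  modes <- harvest_modes()
  mm <- matrix(c(modes[["RIL"]], modes[["RIL"]], modes[["CL"]], modes[["CL"]]), 2, 2)
  p <- list(apu_index = matrix(c(3L, 7L, NA, NA), 2, 2),
            harvested_flag = matrix(FALSE, 2, 2), cycle_years = 30L)
  class(p) <- "management_partition"

  e3 <- eligible_cells(g, p, mm, year = 3)
  expect_true(e3[1, 1])          # RIL cell, apu 3, year 3, unharvested
  expect_false(e3[2, 1])         # RIL cell, apu 7
  expect_true(e3[1, 2])          # CL with 5 m3/ha left: re-entry allowed
  expect_false(e3[2, 2])         # CL exhausted

  # single entry: once flagged, never eligible again
  p$harvested_flag[1, 1] <- TRUE
  expect_false(eligible_cells(g, p, mm, year = 3)[1, 1])
  expect_error(eligible_cells(g, p, mm, year = 31), "domain error")
})

test_that("allocation matches the exhaustive greedy oracle", {
  withr::local_seed(4)
  for (rep in 1:5) {
    nr <- 4
    rent <- matrix(runif(24, -50, 5000), nr)
    hv <- matrix(runif(24, 500, 3000), nr)
    cells <- sample(24, 6)
    capacity <- sum(hv[cells][1:2]) + 0.5 * hv[cells][3]   # ~2.5 cells' worth
    mm <- matrix(harvest_modes()[["CL"]], nr, 6)
    ev <- allocate_harvest(cells, rent, hv, capacity, mm, nr)
    or <- oracle_allocate(cells, rent, hv, capacity, nr)
    expect_equal(ev$cell, or$cell)
    expect_equal(ev$volume_m3, or$volume_m3, tolerance = 1e-9)
    expect_lte(sum(ev$volume_m3), capacity + 1e-9)
  }
})

test_that("allocation saturates and respects zero capacity", {
  nr <- 3
  rent <- matrix(100, nr, 3); hv <- matrix(10, nr, 3)
  mm <- matrix(harvest_modes()[["CL"]], nr, 3)
  ev <- allocate_harvest(1:9, rent, hv, capacity = 1e6, mm, nr)
  expect_identical(nrow(ev), 9L)                    # all positive-rent cells
  expect_identical(nrow(allocate_harvest(1:9, rent, hv, 0, mm, nr)), 0L)
  rent[1, 1] <- -5
  ev2 <- allocate_harvest(1:9, rent, hv, 1e6, mm, nr)
  expect_false(1L %in% ev2$cell)                    # non-positive rent skipped
  expect_error(allocate_harvest(1:9, rent, hv, -1, mm, nr), "domain error")
})

test_that("apply_harvest enforces the RIL cap arithmetic and conservation", {
  lcc <- land_cover_codes()
  g <- landscape_grid(matrix(40, 1, 2), matrix(lcc[["forest"]], 1, 2),
                      matrix(zoning_codes()[["private_nonprotected"]], 1, 2),
                      matrix(road_codes()[["none"]], 1, 2))
  modes <- harvest_modes()
  p <- list(apu_index = matrix(c(1L, NA), 1), harvested_flag = matrix(FALSE, 1, 2),
            cycle_years = 30L)
  class(p) <- "management_partition"

  # RIL cell: cap 25.8 m3/ha on 100 ha -> 2,580 m3 removed, 14.2 m3/ha left
  ev_ril <- data.frame(cell = 1L, row = 1L, col = 1L, mode = modes[["RIL"]],
                       volume_m3 = 2580, rent_brl = 1)
  up <- apply_harvest(g, ev_ril, p)
  expect_equal(up$grid$volume[1, 1], 14.2)
  expect_true(up$partition$harvested_flag[1, 1])

  # CL cell fully harvested: 4,000 m3 off, nothing left
  ev_cl <- data.frame(cell = 2L, row = 1L, col = 2L, mode = modes[["CL"]],
                      volume_m3 = 4000, rent_brl = 1)
  up2 <- apply_harvest(up$grid, ev_cl, up$partition)
  expect_equal(up2$grid$volume[1, 2], 0)
  expect_false(up2$partition$harvested_flag[1, 2])

  # conservation: initial = remaining + harvested
  init <- 40 * 100 * 2
  expect_equal(sum(up2$grid$volume) * 100 + 2580 + 4000, init)

  ev_bad <- data.frame(cell = 2L, row = 1L, col = 2L, mode = modes[["NONE"]],
                       volume_m3 = 1, rent_brl = 0)
  expect_error(apply_harvest(up2$grid, ev_bad, up2$partition), "consistency error")
  ev_over <- data.frame(cell = 2L, row = 1L, col = 2L, mode = modes[["CL"]],
                        volume_m3 = 10, rent_brl = 0)
  expect_error(apply_harvest(up2$grid, ev_over, up2$partition), "consistency error")
})
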