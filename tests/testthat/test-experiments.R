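test_that("sweep specs validate grids and curve overrides", {
  expect_s3_class(sweep_spec(resist_params(), grid = c(0, 0.5, 1),
                             grid_param = "phi", curve_param = "r",
                             curve_values = c(0, 1)), "sweep_spec")
  expect_error(sweep_spec(resist_params(), grid = c(0, 1.5),
                          grid_param = "phi"), "\\[0, 1\\]")
  expect_error(sweep_spec(resist_params(), grid = 0.5, grid_param = "phi",
                          curve_param = "nope", curve_values = 1),
               "unknown curve parameter")
  expect_error(sweep_spec(resist_params(), grid = 0.5, grid_param = "phi",
                          curve_param = "r", curve_values = 2))
  expect_error(sweep_spec(resist_params(), grid = 0.5, grid_param = "phi",
                          curve_param = "r"), "together")
})

test_that("fixation boundary: repellency and human-feeding structure", {
  sp <- sweep_spec(resist_params(), grid = c(0, 0.5, 1),
                   grid_param = "phi", curve_param = "r",
                   curve_values = c(0, 1))
  tab <- fixation_boundary_experiment(sp, grid_points = 51)
  expect_named(tab, c("curve_param", "curve_value", "phi", "psi_threshold"))
  expect_equal(nrow(tab), 6)

  # fully repellent nets select nothing: boundary independent of phi
  r1 <- tab$psi_threshold[tab$curve_value == 1]
  expect_lt(max(r1) - min(r1), 2e-4)
  # without repellency, nets add selection: boundary falls with phi and
  # vanishes once nets alone fix resistance
  r0 <- tab$psi_threshold[tab$curve_value == 0]
  expect_true(all(diff(r0) <= 0))
  expect_gt(r0[1], 0)
  expect_equal(r0[3], 0)
  # larvicide-only fixation boundary sits near 10% coverage (the root of
  # lambda_S = 1; invasion alone starts at ~9.7%)
  expect_lt(abs(tab$psi_threshold[tab$curve_value == 1 & tab$phi == 0] -
                  0.075 / 0.6984375), 1e-3)

  # no human feeding removes net exposure entirely: same as full repellency
  spQ <- sweep_spec(resist_params(), grid = c(0, 0.5, 1),
                    grid_param = "phi", curve_param = "Q",
                    curve_values = 0)
  tabQ <- fixation_boundary_experiment(spQ, grid_points = 51)
  expect_equal(tabQ$psi_threshold, r1, tolerance = 1e-6)
})

test_that("boundary table agrees with outcome classification nearby", {
  # phi values below the net-only fixation point, so the psi boundary is
  # interior and both sides of it can be probed
  sp <- sweep_spec(resist_params(), grid = c(0, 0.3), grid_param = "phi",
                   curve_param = "r", curve_values = 0.7)
  tab <- fixation_boundary_experiment(sp)
  eps <- 5e-3
  for (i in seq_len(nrow(tab))) {
    p <- update_params(resist_params(r = tab$curve_value[i]),
                       phi = tab$phi[i])
    thr_fix <- tab$psi_threshold[i]
    thr_inv <- find_coverage_threshold(p, vary = "psi",
                                       criterion = "invasion")
    expect_gt(thr_inv, eps)
    # above the fixation boundary resistance fixes; below the invasion
    # boundary it is eliminated; in between sits the polymorphism band
    expect_identical(
      classify_outcome(update_params(p, psi = thr_fix + eps)), "fixation")
    expect_identical(
      classify_outcome(update_params(p, psi = thr_inv - eps)),
      "elimination")
  }
})

test_that("time-to-resistance tables reflect larvicide and repellency", {
  # larvicide speeds evolution up at fixed high net coverage
  sp_psi <- sweep_spec(resist_params(), grid = c(0.8, 1),
                       grid_param = "phi", curve_param = "psi",
                       curve_values = c(0, 0.25))
  tab <- time_to_resistance_experiment(sp_psi)
  expect_named(tab, c("curve_param", "curve_value", "phi", "generations"))
  for (phi in c(0.8, 1)) {
    t0 <- tab$generations[tab$curve_value == 0 & tab$phi == phi]
    t25 <- tab$generations[tab$curve_value == 0.25 & tab$phi == phi]
    expect_lt(t25, t0)
  }

  # stronger repellency slows evolution pointwise
  sp_r <- sweep_spec(resist_params(), grid = 1, grid_param = "phi",
                     curve_param = "r", curve_values = c(0, 0.8))
  tr <- time_to_resistance_experiment(sp_r)
  expect_gt(tr$generations[tr$curve_value == 0.8],
            tr$generations[tr$curve_value == 0])

  # neutral override: never rows, explicitly present
  sp_n <- sweep_spec(resist_params(rho = 0, Z = 0), grid = c(0.5, 1),
                     grid_param = "phi", curve_param = "psi",
                     curve_values = 0.2)
  tn <- time_to_resistance_experiment(sp_n, max_generations = 300)
  expect_equal(nrow(tn), 2)
  expect_true(all(is.infinite(tn$generations)))
})

test_that("ratio tables separate finite, infinite and undefined points", {
  sp <- sweep_spec(resist_params(r = 0), grid = c(0, 0.25, 0.5, 0.8),
                   grid_param = "coverage", curve_param = "r",
                   curve_values = c(0, 0.7))
  tab <- larvicide_itn_ratio_experiment(sp)
  expect_named(tab, c("curve_param", "curve_value", "coverage", "ratio",
                      "status"))
  # zero coverage: no selection in either arm
  expect_true(all(tab$status[tab$coverage == 0] == "undefined"))
  # nets at typical repellency never invade at coverage 0.25
  expect_identical(tab$status[tab$curve_value == 0.7 &
                                tab$coverage == 0.25], "inf")
  # larvicides at least 8x faster at equal coverage 0.5, no repellency
  r0 <- tab$ratio[tab$curve_value == 0 & tab$coverage == 0.5]
  expect_identical(tab$status[tab$curve_value == 0 & tab$coverage == 0.5],
                   "finite")
  expect_gte(r0, 8)
  # higher repellency gives a pointwise larger ratio where both finite
  r0_8 <- tab$ratio[tab$curve_value == 0 & tab$coverage == 0.8]
  r7_8 <- tab$ratio[tab$curve_value == 0.7 & tab$coverage == 0.8]
  expect_identical(tab$status[tab$curve_value == 0.7 & tab$coverage == 0.8],
                   "finite")
  expect_gt(r7_8, r0_8)

  # neutral override: undefined everywhere (grid below psi = 1, where a
  # neutral population would go extinct outright)
  spn <- sweep_spec(resist_params(rho = 0, Z = 0), grid = c(0.25, 0.5),
                    grid_param = "coverage")
  tn <- larvicide_itn_ratio_experiment(spn, max_generations = 300)
  expect_true(all(tn$status == "undefined"))
})

test_that("tables serialize deterministically with literal markers", {
  sp <- sweep_spec(resist_params(r = 0), grid = c(0, 0.25, 0.5),
                   grid_param = "coverage", curve_param = "r",
                   curve_values = c(0, 0.7))
  tab <- larvicide_itn_ratio_experiment(sp)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_table_csv(tab, f1)
  write_table_csv(larvicide_itn_ratio_experiment(sp), f2)
  expect_identical(readLines(f1), readLines(f2))
  txt <- readLines(f1)
  expect_true(any(grepl("undefined", txt)))
  expect_true(any(grepl(",inf,", txt)))
  expect_false(any(grepl("Inf", txt)))

  spn <- sweep_spec(resist_params(rho = 0, Z = 0), grid = 1,
                    grid_param = "phi", curve_param = "psi",
                    curve_values = 0)
  tn <- time_to_resistance_experiment(spn, max_generations = 100)
  f3 <- tempfile(fileext = ".csv")
  write_table_csv(tn, f3)
  expect_true(any(grepl("never", readLines(f3))))
})
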