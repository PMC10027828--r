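test_that("percent change truncates toward zero at two decimals", {
  # published grid-study arithmetic
  expect_equal(percent_change(12.73, 14.97), 17.59, tolerance = 1e-12)
  expect_equal(percent_change(14.97, 15.84), 5.81, tolerance = 1e-12)
  expect_equal(percent_change(15.84, 15.88), 0.25, tolerance = 1e-12)
  # truncation, not rounding: 17.596 % must not become 17.60
  expect_equal(percent_change(100, 117.596), 17.59, tolerance = 1e-12)
  expect_identical(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "positive")
  expect_error(percent_change(-2, 1), "positive")
})

test_that("grid-study reporting reproduces a supplied WSS column", {
  gs <- run_grid_study(NULL, c(0.28e-3, 0.23e-3, 0.18e-3, 0.15e-3),
                       values = c(12.73, 14.97, 15.84, 15.88))
  expect_equal(gs$change_pct, c(NA, 17.59, 5.81, 0.25))
  expect_identical(attr(gs, "selected"), 4L)
  # identical rows: zero change, first eligible grid selected
  gs0 <- run_grid_study(NULL, c(2e-4, 1e-4), values = c(3, 3))
  expect_equal(gs0$change_pct, c(NA, 0))
  expect_identical(attr(gs0, "selected"), 2L)
  expect_error(run_grid_study(NULL, c(1e-4, 2e-4), values = c(1, 2)))
})

test_that("coil table consistency report agrees on all rows", {
  tb <- table1_consistency()
  expect_identical(nrow(tb), 3L)
  expect_true(all(tb$agree))
  expect_equal(tb$computed, c(2.70e7, 1.85e7, 0.85))
})

test_that("a single-cell sweep is bitwise the same as a direct run", {
  base <- fixture_case(cycles = 1L)
  base$mesh <- fixture_mesh()
  sw <- run_sweep(sweep_spec(hematocrits = 0.40, porosities = 1,
                             base_case = base))
  expect_identical(nrow(sw), 1L)
  direct <- base
  direct$rheology <- params_from_hematocrit(0.40)
  direct$porous <- porous_props(1)
  rep_ <- indices_report(run_transient(direct))
  sac <- rep_$regions[rep_$regions$region == "WALL_SAC", ]
  expect_identical(sw$avg_osi_sac, sac$avg_osi)
  expect_identical(sw$avg_tawss_sac, sac$avg_tawss)
  expect_identical(sw$max_tawss_sac, sac$max_tawss)
})

test_that("sac WSS refinement changes shrink across the convergent range", {
  # mirrors the grid-study protocol on the fixture: within the
  # asymptotic range of this discretization the percent change between
  # successive refinements decreases
  case <- fixture_case()
  gs <- run_grid_study(case, c(5.5e-4, 4.2e-4, 3.2e-4))
  expect_true(all(diff(gs$n_elements) > 0))
  expect_true(all(gs$avg_wss_sac > 0))
  ch <- gs$change_pct[-1]
  expect_true(all(diff(ch) < 0))
})

test_that("trend report grades directional expectations pass/warn", {
  fake <- data.frame(hct = rep(0.4, 2), porosity = c(0.75, 1),
                     max_osi_sac = c(0.2, 0.1), avg_osi_sac = c(0.05, 0.01),
                     avg_tawss_sac = c(0.5, 1.5), max_tawss_sac = c(1, 2),
                     max_pressure_sac_systole = c(100, 120),
                     error = NA_character_)
  class(fake) <- c("aneu_sweep", "data.frame")
  tr <- trend_report(fake)
  expect_true(all(tr$status == "pass"))
  # reversed direction downgrades to warn, never errors
  fake$avg_osi_sac <- rev(fake$avg_osi_sac)
  tr2 <- trend_report(fake)
  expect_identical(tr2$status[1], "warn")
  # a sweep without an uncoiled cell cannot be graded
  only_coiled <- fake[fake$porosity < 1, ]
  class(only_coiled) <- c("aneu_sweep", "data.frame")
  expect_error(trend_report(only_coiled), "uncoiled")
})
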