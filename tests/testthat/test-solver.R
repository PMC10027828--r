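test_that("zero inflow from rest stays exactly at rest", {
  ch <- tiny_channel()
  n <- nrow(ch$nodes)
  st0 <- flow_state(0, numeric(n), numeric(n), numeric(n))
  st1 <- advance_state(st0, 0.002, ch, newtonian_params(0.0035),
                       porous_props(1), bc_spec(), solver_config(),
                       inlet_velocity = 0)
  expect_identical(st1$u, numeric(n))
  expect_identical(st1$v, numeric(n))
  expect_identical(st1$p, numeric(n))
  expect_identical(attr(st1, "iterations"), 0L)
})

test_that("steady channel flow develops Poiseuille structure and conserves mass", {
  ch <- tiny_channel()
  st <- cached("tiny_poiseuille", {
    solve_steady(ch, newtonian_params(0.0035), bc = bc_spec(),
                 inlet_velocity = 0.01)
  })
  # global mass conservation is discrete-exact
  fin <- boundary_flux(st, ch, "INLET")
  fout <- boundary_flux(st, ch, "OUTLET")
  expect_lt(abs(fin + fout) / abs(fin), 1e-10)
  # no-slip holds exactly on wall nodes
  wall <- unique(unlist(ch$boundary[grepl("WALL", ch$boundary$tag),
                                    c("n1", "n2")]))
  expect_identical(st$u[wall], numeric(length(wall)))
  # centerline approaches 1.5x the mean on this coarse grid
  xs <- sort(unique(ch$nodes[, 1]))
  sel <- ch$nodes[, 1] == xs[which.min(abs(xs - 0.004))]
  expect_equal(max(st$u[sel]), 0.015, tolerance = 0.05)
})

test_that("transient bookkeeping: steps, snapshot phases, mass balance", {
  fl <- cached("tiny_transient", {
    case <- case_config(mesh = tiny_channel(),
                        geometry = NULL,
                        solver = solver_config(cycles = 1L))
    run_transient(case)
  })
  # 1 cycle, period 0.8 s, dt 0.002 s -> 400 steps, final time 0.8 s
  expect_identical(nrow(fl$residual_log), 400L)
  expect_equal(fl$residual_log$time[400], 0.8)
  expect_equal(max(fl$snap_times), 0.8)
  # phase snapshots recorded exactly at the waveform's phase times
  ph <- fl$phase_index
  expect_setequal(ph$phase, c("systole", "diastole"))
  expect_equal(sort(ph$time), c(0.24, 0.54))
  # inflow and outflow agree at every saved snapshot
  expect_lt(max(mass_balance_error(fl)), solver_config()$continuity_tolerance)
  # residual tolerances were met at every accepted step
  expect_true(all(fl$residual_log$momentum <
                    solver_config()$momentum_tolerance))
})

test_that("three cycles at dt 0.002 make 1200 steps ending at 2.4 s", {
  # arithmetic contract of the integrator setup, checked on the
  # default fixture run shared across the suite
  fl <- fixture_flow()
  expect_identical(nrow(fl$residual_log), 1200L)
  expect_equal(fl$residual_log$time[1200], 2.4)
  expect_identical(fl$n_per_cycle, 400)
})

test_that("a strangled outer loop fails loudly with residuals attached", {
  ch <- tiny_channel()
  err <- tryCatch(
    solve_steady(ch, newtonian_params(0.0035),
                 bc = bc_spec(), inlet_velocity = 0.3,
                 config = solver_config(outer_iterations_max = 1L,
                                        momentum_tolerance = 1e-12,
                                        continuity_tolerance = 1e-12)),
    aneuflow_divergence = function(e) e)
  expect_s3_class(err, "aneuflow_divergence")
  expect_true(all(is.finite(err$residuals)))
  expect_match(conditionMessage(err), "outer iterations exceeded")
})

test_that("checkpoint round trip is exact and restart matches straight-through", {
  case <- case_config(mesh = tiny_channel(), geometry = NULL,
                      solver = solver_config(cycles = 1L))
  full <- cached("tiny_transient", run_transient(case))
  half <- run_transient(case, halt_at_step = 200L)
  expect_false(half$complete)
  path <- withr::local_tempfile(fileext = ".rds")
  checkpoint_write(half, path)
  back <- checkpoint_read(path)
  expect_identical(back$progress$step, 200L)
  resumed <- resume_transient(back)
  expect_true(resumed$complete)
  n_s <- length(full$snapshots)
  expect_identical(length(resumed$snapshots), n_s)
  for (i in seq_len(n_s))
    expect_states_equal(resumed$snapshots[[i]], full$snapshots[[i]],
                        tol = 1e-10)
  expect_identical(resumed$wall$tau_x, full$wall$tau_x)
})

test_that("corrupt or foreign checkpoints are refused", {
  path <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a checkpoint", path)
  expect_error(checkpoint_read(path), "unreadable|not an aneuflow")
  saveRDS(list(format = "aneuflow-checkpoint", version = 99L), path)
  expect_error(checkpoint_read(path), "version mismatch")
})

test_that("BDF2 time stepping runs and conserves mass", {
  case <- case_config(mesh = tiny_channel(), geometry = NULL,
                      solver = solver_config(cycles = 1L,
                                             time_scheme = "bdf2"))
  fl <- run_transient(case, halt_at_step = 30L)
  st <- fl$progress$state
  expect_true(all(is.finite(st$u)))
  fin <- boundary_flux(st, fl$mesh, "INLET")
  fout <- boundary_flux(st, fl$mesh, "OUTLET")
  expect_lt(abs(fin + fout) / abs(fin), 1e-8)
})

test_that("dt must divide the period and land on the phase times", {
  expect_error(
    run_transient(case_config(mesh = tiny_channel(), geometry = NULL,
                              solver = solver_config(dt = 0.003))),
    "dt must")
})
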