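# Shared fixtures and a cache for expensive transient runs, so several
# test files can reuse the same simulations within one test session.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache))
    assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}

# Coarse desk-scale aneurysm fixture: 16 mm vessel, sac at mid-length,
# ~0.7 mm elements (about 350 triangles).  Resolution chosen so a full
# three-cycle run stays under a minute.
fixture_geometry <- function(mesh_size = 7e-4) {
  geometry_params(mesh_size = mesh_size, vessel_length = 16e-3,
                  sac_stand_off = 8e-3)
}

fixture_case <- function(porosity = 1, hct = 0.40, cycles = 3L,
                         mesh_size = 7e-4, ...) {
  case_config(geometry = fixture_geometry(mesh_size),
              rheology = params_from_hematocrit(hct),
              porous = if (is.null(porosity)) NULL else porous_props(porosity),
              solver = solver_config(cycles = cycles, ...))
}

fixture_mesh <- function() cached("fixture_mesh", {
  build_idealized_geometry(fixture_geometry())
})

# Default three-cycle uncoiled run at normal hematocrit.
fixture_flow <- function() cached("fixture_flow", {
  case <- fixture_case()
  case$mesh <- fixture_mesh()
  run_transient(case)
})

# The full 3 HCT x 3 porosity sweep on the coarse fixture.
fixture_sweep <- function() cached("fixture_sweep", {
  run_sweep(sweep_spec(base_case = fixture_case()), keep_reports = TRUE)
})

# Tiny channel for fast solver unit tests.
tiny_channel <- function() cached("tiny_channel", {
  build_channel_mesh(0.008, 0.002, 4e-4, boundary_layer_layers = 2)
})

expect_states_equal <- function(a, b, tol = 0) {
  if (tol == 0) {
    expect_identical(a$u, b$u)
    expect_identical(a$v, b$v)
    expect_identical(a$p, b$p)
  } else {
    expect_lt(max(abs(a$u - b$u), abs(a$v - b$v), abs(a$p - b$p)), tol)
  }
}
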