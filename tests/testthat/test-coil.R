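ref_coil <- coil_spec(wire_diameter = 0.254e-3, length = 0.30,
                      sac_volume = 103.87e-9)

test_that("coil porosity follows the volume-fraction closed form", {
  # independent arithmetic oracle
  v_coil <- pi * (0.254e-3)^2 * 0.30 / 4
  expect_equal(porosity_from_coil(ref_coil), 1 - v_coil / 103.87e-9,
               tolerance = 1e-15)
  expect_equal(round(porosity_from_coil(ref_coil), 2), 0.85)
  # empty-sac limit
  eps <- porosity_from_coil(coil_spec(0.254e-3, 1e-9, 103.87e-9))
  expect_lt(abs(eps - 1), 1e-6)
  # overpacked coil errors
  expect_error(porosity_from_coil(coil_spec(0.254e-3, 3, 103.87e-9)),
               "overpacked")
})

test_that("back-solving coil length for a target porosity", {
  # porosity 0.75 requires roughly a 51.3 cm coil in the reference sac
  f <- function(L) porosity_from_coil(coil_spec(0.254e-3, L, 103.87e-9)) - 0.75
  L75 <- uniroot(f, c(0.01, 2))$root
  expect_equal(L75, 0.513, tolerance = 0.005)
})

test_that("permeability anchors, interpolation and the uncoiled sentinel", {
  expect_identical(permeability_for_porosity(0.75), 3.7e-8)
  expect_identical(permeability_for_porosity(0.85), 5.4e-8)
  expect_identical(permeability_for_porosity(1), Inf)
  # linear interpolation between the anchors
  expect_equal(permeability_for_porosity(0.80), (3.7e-8 + 5.4e-8) / 2,
               tolerance = 1e-12)
  expect_error(permeability_for_porosity(0), "positive")
  expect_error(permeability_for_porosity(-0.1), "positive")
  expect_error(permeability_for_porosity(1.1), "exceed")
  # reciprocals round (3 s.f.) to the tabulated resistances
  expect_identical(signif(1 / 3.7e-8, 3), 2.70e7)
  expect_identical(signif(1 / 5.4e-8, 3), 1.85e7)
})

test_that("Darcy sink formula and the disabled limit", {
  props <- porous_props(0.75, permeability = 3.7e-8)
  expect_identical(darcy_sink(c(0, 0), 0.00345, props), c(0, 0))
  s <- darcy_sink(c(0.1, 0), 0.00345, props)
  expect_equal(s[1], -9324.324, tolerance = 1e-4)  # -mu u / k
  expect_identical(s[2], 0)
  # porosity 1: permeability Inf, sink identically zero
  off <- porous_props(1)
  expect_identical(darcy_sink(c(0.3, -0.2), 0.004, off), c(0, 0))
})

test_that("1D porous slab pressure drop matches mu U L / k", {
  # steady plug flow through a fully porous channel with slip walls
  mu <- 0.00345; k <- 3.7e-8; U <- 0.1; L <- 0.01
  slab <- build_channel_mesh(L, 0.002, 4e-4, region = "SAC")
  st <- solve_steady(slab, newtonian_params(mu),
                     porous = porous_props(0.75, permeability = k),
                     bc = bc_spec(inlet = "velocity",
                                  inlet_profile = "uniform", walls = "slip"),
                     inlet_velocity = U)
  bnd <- slab$boundary
  p_in <- mean(st$p[unique(c(bnd$n1[bnd$tag == "INLET"],
                             bnd$n2[bnd$tag == "INLET"]))])
  p_out <- mean(st$p[unique(c(bnd$n1[bnd$tag == "OUTLET"],
                              bnd$n2[bnd$tag == "OUTLET"]))])
  expect_equal(p_in - p_out, mu * U * L / k, tolerance = 0.02)
})
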