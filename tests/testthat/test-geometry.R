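test_that("default geometry meshes with all tags and a populated sac", {
  mesh <- cached("default_geom_mesh",
                 build_idealized_geometry(geometry_params()))
  expect_s3_class(mesh, "aneu_mesh")
  expect_gt(sum(mesh$region == "SAC"), 0)
  expect_setequal(unique(mesh$boundary$tag),
                  c("INLET", "OUTLET", "WALL_VESSEL", "WALL_SAC"))
  expect_silent(validate_mesh(mesh))
})

test_that("degenerate geometry parameters are rejected by name", {
  expect_error(geometry_params(neck_width = 6e-3, dome_diameter = 5e-3),
               "neck_width")
  expect_error(geometry_params(vessel_diameter = -1), "positive")
  expect_error(geometry_params(boundary_layer_growth = 0.9),
               "boundary_layer_growth")
  expect_error(geometry_params(sac_stand_off = 1e-3, neck_width = 2.5e-3),
               "neck chord")
})

test_that("halving the element size roughly quadruples the element count", {
  coarse <- build_idealized_geometry(fixture_geometry(8e-4))
  fine <- build_idealized_geometry(fixture_geometry(4e-4))
  ratio <- nrow(fine$tri) / nrow(coarse$tri)
  expect_gte(ratio, 3)
  expect_lte(ratio, 5)
})

test_that("mesh validity suite holds across a parameter grid", {
  grid <- list(
    fixture_geometry(),
    geometry_params(dome_diameter = 6e-3, neck_width = 2e-3,
                    mesh_size = 5e-4),
    geometry_params(vessel_diameter = 4e-3, neck_width = 3.5e-3,
                    mesh_size = 5e-4, boundary_layer_layers = 2L),
    geometry_params(mesh_size = 4e-4, boundary_layer_layers = 0L)
  )
  for (g in grid) {
    mesh <- build_idealized_geometry(g)
    expect_silent(validate_mesh(mesh))
    # every boundary edge belongs to exactly one triangle, and its
    # directed form is an edge of that triangle (outward orientation)
    tri <- mesh$tri[mesh$boundary$tri, , drop = FALSE]
    ok <- mapply(function(n1, n2, a, b, c) {
      any((c(a, b, c) == n1) & (c(b, c, a) == n2))
    }, mesh$boundary$n1, mesh$boundary$n2, tri[, 1], tri[, 2], tri[, 3])
    expect_true(all(ok))
  }
})

test_that("meshed sac area converges to the analytic bulge segment", {
  coarse <- build_idealized_geometry(fixture_geometry(8e-4))
  fine <- build_idealized_geometry(fixture_geometry(4e-4))
  exact <- attr(fine, "sac_area_analytic")
  # independent oracle: area of the major circular segment
  R <- 2.5e-3; w <- 1.25e-3; d0 <- sqrt(R^2 - w^2)
  expect_equal(exact, pi * R^2 - (R^2 * acos(d0 / R) - d0 * w),
               tolerance = 1e-12)
  err_c <- abs(region_area(coarse, "SAC") - exact) / exact
  err_f <- abs(region_area(fine, "SAC") - exact) / exact
  expect_lt(err_f, 0.01)
  expect_lt(err_f, err_c)
})

test_that("plain channel meshes are valid and tagged", {
  ch <- tiny_channel()
  expect_silent(validate_mesh(ch, require_sac = FALSE))
  expect_setequal(unique(ch$boundary$tag),
                  c("INLET", "OUTLET", "WALL_VESSEL"))
  expect_error(validate_mesh(ch), "WALL_SAC")
  slab <- build_channel_mesh(0.004, 0.002, 5e-4, region = "SAC")
  expect_true(all(slab$region == "SAC"))
})
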