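test_that("MSH round trip preserves coordinates, connectivity and tags", {
  mesh <- fixture_mesh()
  path <- withr::local_tempfile(fileext = ".msh")
  write_mesh(mesh, path)
  back <- read_mesh(path)
  expect_equal(back$nodes, mesh$nodes, tolerance = 1e-12)
  expect_identical(back$tri, mesh$tri)
  expect_identical(back$region, mesh$region)
  # boundary edges are rebuilt from the triangulation: same tagged set
  key <- function(m) paste(pmin(m$boundary$n1, m$boundary$n2),
                           pmax(m$boundary$n1, m$boundary$n2), m$boundary$tag)
  expect_setequal(key(back), key(mesh))
  expect_silent(validate_mesh(back))
})

test_that("a mesh file without a SAC region is rejected when one is required", {
  ch <- tiny_channel()
  path <- withr::local_tempfile(fileext = ".msh")
  write_mesh(ch, path)
  expect_error(read_mesh(path), "no SAC region")
  expect_silent(validate_mesh(read_mesh_msh(path, require_sac = FALSE),
                              require_sac = FALSE))
})

test_that("an externally authored MSH with the standard groups is accepted", {
  mesh <- read_mesh_msh(test_path("fixtures", "external-synthetic.msh"))
  expect_identical(nrow(mesh$nodes), 6L)
  expect_identical(nrow(mesh$tri), 4L)
  expect_identical(sum(mesh$region == "SAC"), 2L)
  expect_setequal(unique(mesh$boundary$tag),
                  c("INLET", "OUTLET", "WALL_VESSEL", "WALL_SAC"))
  expect_silent(validate_mesh(mesh))
})

test_that("unknown physical groups are reported by name", {
  expect_error(read_mesh_msh(test_path("fixtures", "bad-group.msh")),
               "FREE_SURFACE")
})

test_that("VTK export writes a well-formed unstructured grid", {
  mesh <- tiny_channel()
  path <- withr::local_tempfile(fileext = ".vtk")
  write_mesh(mesh, path, point_data = list(p = seq_len(nrow(mesh$nodes)) * 1.0))
  txt <- readLines(path)
  expect_true(any(grepl("DATASET UNSTRUCTURED_GRID", txt)))
  expect_true(any(grepl(sprintf("POINTS %d double", nrow(mesh$nodes)), txt)))
  expect_true(any(grepl(sprintf("CELL_TYPES %d", nrow(mesh$tri)), txt)))
  expect_true(any(grepl("SCALARS p double", txt)))
})

test_that("unsupported extensions error", {
  expect_error(read_mesh("mesh.stl"), "unsupported")
  expect_error(write_mesh(tiny_channel(), "mesh.obj"), "unsupported")
})
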