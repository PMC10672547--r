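test_that("cube volume and surface area match closed forms", {
  cube <- unit_cube_mesh()
  expect_true(is_watertight(cube))
  expect_equal(mesh_volume(cube), 1)
  expect_equal(mesh_surface_area(cube), 6)
  big <- unit_cube_mesh(side = 2.5)
  expect_equal(mesh_volume(big), 2.5^3)
  expect_equal(mesh_surface_area(big), 6 * 2.5^2)
})

test_that("orientation flip yields the same absolute volume, with a warning", {
  cube <- unit_cube_mesh()
  flipped <- triangle_mesh(cube$vertices, cube$faces[, c(1, 3, 2)],
                           clean = FALSE)
  expect_warning(v <- mesh_volume(flipped), "orientation")
  expect_equal(v, 1)
})

test_that("non-watertight meshes are rejected for volume with open-edge count", {
  cube <- unit_cube_mesh()
  open <- triangle_mesh(cube$vertices, cube$faces[-1, , drop = FALSE],
                        clean = FALSE)
  expect_false(is_watertight(open))
  expect_error(mesh_volume(open), "not watertight")
  expect_error(mesh_volume(open), "3 edge")
})

test_that("a single equilateral triangle has area sqrt(3) for side 2", {
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0)),
                       rbind(c(1, 2, 3)), clean = FALSE)
  expect_equal(mesh_surface_area(tri), sqrt(3))
})

test_that("icosphere volume and area converge to the analytic sphere", {
  s <- icosphere(radius = 10, subdivisions = 4)
  expect_true(is_watertight(s))
  expect_lt(abs(mesh_volume(s) / (4 / 3 * pi * 1000) - 1), 0.01)
  expect_lt(abs(mesh_surface_area(s) / (400 * pi) - 1), 0.01)
})

test_that("volume and area are invariant under rigid motion and scale as k^3 / k^2", {
  set.seed(31)
  m <- generate_tumor_mesh(target_volume_cm3 = 5, amplitude = 0.35,
                           seed = 3, subdivisions = 3)
  v0 <- mesh_volume(m)
  a0 <- mesh_surface_area(m)
  for (i in 1:3) {
    rot <- random_rotation()
    moved <- morphosurv:::transform_mesh(m, rotation = rot,
                                         translation = stats::rnorm(3, sd = 40))
    expect_equal(mesh_volume(moved), v0, tolerance = 1e-9)
    expect_equal(mesh_surface_area(moved), a0, tolerance = 1e-9)
  }
  k <- 1.7
  scaled <- morphosurv:::transform_mesh(m, scale = k)
  expect_equal(mesh_volume(scaled), k^3 * v0, tolerance = 1e-12)
  expect_equal(mesh_surface_area(scaled), k^2 * a0, tolerance = 1e-12)
  expect_equal(sphericity(mesh_volume(scaled), mesh_surface_area(scaled)),
               sphericity(v0, a0), tolerance = 1e-12)
})

test_that("cleaning merges duplicate vertices and drops degenerate faces", {
  # cube with every face listing its own vertex copies plus one zero-area face
  cube <- unit_cube_mesh()
  v_dup <- cube$vertices[as.vector(t(cube$faces)), ]
  f_dup <- matrix(seq_len(nrow(v_dup)), ncol = 3, byrow = TRUE)
  v_dup <- rbind(v_dup, c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))
  f_dup <- rbind(f_dup, nrow(v_dup) - c(2, 1, 0))
  expect_warning(m <- triangle_mesh(v_dup, f_dup), "degenerate")
  expect_equal(nrow(m$vertices), 8)
  expect_equal(nrow(m$faces), 12)
  expect_true(is_watertight(m))
  expect_equal(mesh_volume(m), 1)
})

test_that("degenerate construction inputs are rejected", {
  expect_error(triangle_mesh(matrix(0, 0, 3), matrix(1L, 0, 3)), "empty")
  expect_error(triangle_mesh(rbind(c(0, 0, 0)), rbind(c(1, 1, 2))),
               "out of range")
})
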