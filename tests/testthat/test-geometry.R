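test_that("icosphere produces closed outward-oriented spheres of the expected size", {
  ico <- icosphere(1, 0)
  expect_equal(nrow(ico$vertices), 12L)
  expect_equal(nrow(ico$faces), 20L)
  expect_equal(sqrt(rowSums(ico$vertices^2)), rep(1, 12), tolerance = 1e-12)

  s2 <- icosphere(1, 2)
  expect_equal(nrow(s2$faces), 320L)
  # total face area within 5% of the sphere area 4*pi
  expect_lt(abs(sum(face_areas(s2)) - 4 * pi) / (4 * pi), 0.05)
  expect_gt(signed_volume(s2), 0)
  expect_silent(validate_mesh(s2))

  g10 <- geodesic_sphere(50, 10)
  expect_equal(nrow(g10$vertices), 10L * 100L + 2L)
  expect_silent(validate_mesh(g10))
})

test_that("phantom surfaces are closed, nested and non-intersecting", {
  ph <- torso_ventricle_phantom(heart_frequency = 4, torso_frequency = 6)
  expect_s3_class(ph$heart, "ecgi_mesh")
  expect_identical(ph$heart$role, "heart")
  expect_identical(ph$torso$role, "torso")
  expect_silent(validate_mesh(ph$heart))
  expect_silent(validate_mesh(ph$torso))
  expect_gt(ph$min_distance, 0)

  # concentric spheres: min distance equals the radius difference
  sp <- torso_ventricle_phantom(torso_semiaxes = c(200, 200, 200),
                                heart_semiaxes = c(50, 50, 50),
                                heart_offset = c(0, 0, 0),
                                heart_frequency = 4, torso_frequency = 4)
  expect_equal(sp$min_distance, 150, tolerance = 0.02)

  # heart pushed through the torso wall
  expect_error(torso_ventricle_phantom(heart_offset = c(160, 0, 0),
                                       heart_frequency = 3,
                                       torso_frequency = 4),
               "geometry error")
})

test_that("electrode grids are deterministic, unique and near-uniform", {
  ph <- torso_ventricle_phantom(heart_frequency = 4, torso_frequency = 8)
  for (n in c(32, 64)) {
    lay <- electrode_grid(ph$torso, n)
    expect_length(unique(as.integer(lay)), n)
  }
  expect_identical(electrode_grid(ph$torso, 128), electrode_grid(ph$torso, 128))
  expect_error(electrode_grid(ph$torso, nrow(ph$torso$vertices) + 1))

  # spacing dispersion within 3x of the farthest-point-sampling oracle
  lay <- electrode_grid(ph$torso, 64)
  disp_grid <- nn_dispersion(ph$torso$vertices[as.integer(lay), ])
  disp_fps <- nn_dispersion(ph$torso$vertices[fps_layout(ph$torso, 64), ])
  expect_lt(disp_grid, 3 * disp_fps)
})

test_that("lesion zones follow the two-zone linear ramp", {
  # synthetic geometry with nodes at controlled distances from the origin
  # (spread over a fan so triangles are non-degenerate)
  d <- c(0, 10, 21.6, 24.3, 26.9, 27.0, 30)
  # zone-edge points (d = 21.6 and 27 exactly) sit on coordinate axes so
  # their distances from the origin are exact in floating point
  ang <- c(0.1, 0.2, pi / 2, 0.4, 0.5, 0, 0.6)
  verts <- cbind(d * cos(ang), d * sin(ang), 0)
  mesh <- ecgi_mesh(verts, rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5),
                                 c(4, 5, 6), c(5, 6, 7)), closed = FALSE)
  z <- lesion_zones(mesh, lesion_spec(c(0, 0, 0), 27))
  expect_equal(as.character(z$zone),
               c("central", "central", "central", "boundary", "boundary",
                 "boundary", "healthy"))
  expect_equal(z$weight[1], 1)                    # centre
  expect_equal(z$weight[3], 1)                    # boundary onset at 0.8 r
  expect_equal(z$weight[4], 0.5)                  # midpoint of the band
  expect_equal(z$weight[7], 0)

  # ramp continuity on a fine distance grid (points on a fan, exact radii)
  dd <- seq(21, 28, by = 1e-3)
  aa <- seq(0, 1, length.out = length(dd))
  m2 <- ecgi_mesh(cbind(dd * cos(aa), dd * sin(aa), 0),
                  rbind(c(1L, 2L, length(dd))), closed = FALSE)
  w <- lesion_zones(m2, lesion_spec(c(0, 0, 0), 27))$weight
  expect_lt(max(abs(diff(w))), 1e-3 / (27 * 0.2) + 1e-12)
})

test_that("mesh and layout serialisation round-trips", {
  m <- icosphere(10, 1)
  for (ext in c("ply", "obj")) {
    p <- file.path(tempdir(), paste0("mesh.", ext))
    write_mesh(m, p)
    m2 <- read_mesh(p)
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(m2$faces, m$faces, ignore_attr = TRUE)
  }
  ph <- torso_ventricle_phantom(heart_frequency = 3, torso_frequency = 5)
  lay <- electrode_grid(ph$torso, 32)
  p <- file.path(tempdir(), "layout.txt")
  write_layout(lay, p)
  expect_identical(as.integer(read_layout(p)), as.integer(lay))
})
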