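test_that("action potential waveform honours its template parameters", {
  tm <- ap_template()
  expect_identical(ap_waveform(tm, -5), -85)
  expect_identical(ap_waveform(tm, -1e-9), -85)

  t <- seq(0, 400, by = 0.5)
  v <- ap_waveform(tm, t)
  # monotone upstroke reaching (nearly) the peak at upstroke_duration
  up <- t <= tm$upstroke_duration
  expect_true(all(diff(v[up]) >= 0))
  expect_gt(v[t == tm$upstroke_duration], 0.99 * (tm$peak_potential + 85) - 85)
  # back within 10% of the resting-to-peak range by t = apd
  expect_lt(v[t == tm$apd], -85 + 0.1 * 105 + 1e-6)
  expect_equal(measure_apd90(v, t, 0, -85, 20), 274, tolerance = 0.5)
})

test_that("ischemic remodelling interpolates linearly with lesion weight", {
  ctr <- ischemic_parameters(weight = 1)
  expect_equal(ctr$resting, -85 + 18)     # fully depolarised centre
  expect_equal(ctr$apd, 150)
  bord <- ischemic_parameters(weight = 0.5)
  expect_equal(bord$resting, -76)         # ~ -85 + 10 at the border
  expect_equal(bord$apd, 212, tolerance = 1e-12)  # near the border's 228 ms
  expect_equal(ischemic_parameters(weight = 0)$apd, 274)

  # APD90 measured from generated traces recovers the template value
  for (w in c(0, 0.5, 1)) {
    p <- ischemic_parameters(weight = w)
    tm <- ap_template(p$resting, p$peak, p$apd, p$upstroke)
    t <- seq(0, 400, by = 1)
    v <- ap_waveform(tm, t)
    expect_equal(measure_apd90(v, t, 0, p$resting, p$peak), p$apd,
                 tolerance = 1)
  }
})

test_that("activation times are geodesic distances over velocity", {
  m <- icosphere(1, 0)    # icosahedron: hand-checkable geodesics
  e <- mesh_edges(m)
  elen <- sqrt(sum((m$vertices[e[1, 1], ] - m$vertices[e[1, 2], ])^2))
  act <- activation_map(m, pacing_nodes = 1L, conduction_velocity = 0.5)
  expect_equal(act[1], 0)
  # neighbours one edge away, the antipode three, everything else two
  g <- mesh_graph(m)
  hops <- as.integer(igraph::distances(g, v = 1, weights = NA))
  expect_equal(as.numeric(act), hops * elen / 0.5, tolerance = 1e-10)
  expect_equal(sort(unique(hops)), 0:3)
  expect_error(activation_map(m, integer(0)), "empty")
})

test_that("epicardial fields reduce to shifted copies without a lesion", {
  ph <- torso_ventricle_phantom(heart_frequency = 4, torso_frequency = 6)
  act <- activation_map(ph$heart, default_pacing_sites(ph$heart), 0.8)
  # snap activation to the time grid so shifts are whole timesteps
  act <- structure(round(as.numeric(act)), class = "ecgi_activation")
  fld <- epicardial_field(ph$heart, NULL, act)
  i <- which.min(act); j <- which.max(act)
  shift <- as.integer(act[j] - act[i])
  nt <- ncol(fld$values)
  expect_equal(fld$values[i, 1:(nt - shift)],
               fld$values[j, (shift + 1):nt], tolerance = 1e-9)

  # lesion radius -> 0 converges to the lesion-free field
  les <- lesion_spec(lesion_sites()$RV_LAT + 0.123, 1e-6)
  fld2 <- epicardial_field(ph$heart, les, act)
  expect_lt(max(abs(fld2$values - fld$values)), 1e-8)

  # central-lesion nodes sit below healthy tissue during the plateau
  les27 <- lesion_spec(lesion_sites()$RV_LAT, 27)
  fld3 <- epicardial_field(ph$heart, les27, act)
  z <- lesion_zones(ph$heart, les27)
  plateau <- which(field_times(fld3) >= max(act) + 10 &
                     field_times(fld3) <= 250)
  cz <- z$zone == "central"
  expect_true(all(colMeans(fld3$values[cz, plateau, drop = FALSE]) <
                    colMeans(fld3$values[z$zone == "healthy", plateau])))
})

test_that("gaussian noise is seeded, calibrated and zero-mean", {
  # calibration on a field at the full study scale
  set.seed(99)
  base <- matrix(sin(seq_len(7000) / 50), 7000, 400) +
    matrix(stats::rnorm(7000 * 400), 7000, 400)
  fld <- potential_field(base)
  for (snr in c(10, 20, 30, 40)) {
    noisy <- add_gaussian_noise(fld, snr, seed = 1234)
    emp <- 10 * log10(mean(base^2) / mean((noisy$values - base)^2))
    expect_lt(abs(emp - snr), 0.2)
  }
  n1 <- add_gaussian_noise(fld, 20, seed = 7)
  n2 <- add_gaussian_noise(fld, 20, seed = 7)
  expect_identical(n1$values, n2$values)

  # noise std scales by 10^1.5 between 10 and 40 dB
  small <- potential_field(matrix(stats::rnorm(500 * 300), 500, 300))
  s10 <- stats::sd(add_gaussian_noise(small, 10, 3)$values - small$values)
  s40 <- stats::sd(add_gaussian_noise(small, 40, 3)$values - small$values)
  expect_equal(s10 / s40, 10^1.5, tolerance = 0.02)

  # zero-mean: sample mean within 3 standard errors
  nz <- add_gaussian_noise(small, 20, 11)$values - small$values
  se <- stats::sd(nz) / sqrt(length(nz))
  expect_lt(abs(mean(nz)), 3 * se + 1e-12)

  expect_error(add_gaussian_noise(potential_field(matrix(0, 4, 4)), 20, 1),
               "all-zero")
  expect_identical(add_gaussian_noise(fld, Inf, 1)$values, fld$values)
})

test_that("potential fields serialise and read back", {
  fld <- potential_field(matrix(stats::rnorm(30), 5, 6), dt = 2, t0 = 10,
                         role = "heart")
  p <- file.path(tempdir(), "field.tsv")
  write_field(fld, p)
  fld2 <- read_field(p)
  expect_equal(fld2$values, fld$values, tolerance = 1e-10)
  expect_equal(fld2$dt, 2)
  expect_equal(fld2$t0, 10)
  expect_identical(fld2$role, "heart")
})
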