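test_that("RDMS closed forms are exact", {
  x <- c(3, -1, 2, 5)
  expect_equal(rdms(x, x), 0, tolerance = 1e-12)
  expect_equal(rdms(x, 7.3 * x), 0, tolerance = 1e-12)
  expect_equal(rdms(x, -x), 2, tolerance = 1e-12)
  expect_equal(rdms(c(1, 0), c(0, 1)), sqrt(2), tolerance = 1e-12)
  expect_error(rdms(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(rdms(1:3, 1:4), "length")
  # literal squared variant differs by exactly the square
  expect_equal(rdms(c(1, 0), c(0, 1), take_root = FALSE), 2, tolerance = 1e-12)
})

test_that("RDMS stays within [0, 2] and vanishes only for positive scalings", {
  set.seed(21)
  for (i in 1:25) {
    a <- stats::rnorm(10); b <- stats::rnorm(10)
    r <- rdms(a, b)
    expect_gte(r, 0); expect_lte(r, 2)
    expect_gt(rdms(a, a + 0.5), 0)
  }
})

test_that("RDMS summaries agree with a naive per-slice loop", {
  set.seed(8)
  x <- matrix(stats::rnorm(60), 6, 10)
  h <- x + 0.3 * matrix(stats::rnorm(60), 6, 10)
  s <- rdms_summary(x, h, "spatial")
  expect_length(s$per_value, 10)
  loop <- vapply(1:10, function(j) rdms(x[, j], h[, j]), numeric(1))
  expect_equal(s$per_value, loop, tolerance = 1e-12)
  expect_equal(s$mean, mean(loop), tolerance = 1e-12)

  tmode <- rdms_summary(x, h, "temporal")
  expect_length(tmode$per_value, 6)
  expect_equal(tmode$per_value[2], rdms(x[2, ], h[2, ]), tolerance = 1e-12)

  ident <- rdms_summary(x, x, "spatial")
  expect_equal(ident$mean, 0); expect_equal(ident$sd, 0)

  # zero column flagged and excluded
  x0 <- x; x0[, 4] <- 0
  expect_warning(s0 <- rdms_summary(x0, h, "spatial"), "excluded")
  expect_equal(s0$n_excluded, 1)
  expect_true(is.na(s0$per_value[4]))
})

test_that("detection threshold arithmetic matches the defining formula", {
  w <- c(0, 20, 10)                  # mean 10, min 0
  expect_equal(detection_threshold(w, 0.4), 6)
  expect_equal(detection_threshold(w, 0.5), 5)
  expect_equal(detection_threshold(rep(3.3, 5), 0.4), 3.3)
})

test_that("threshold detection behaves at the limits and in Q", {
  m <- icosphere(20, 2)
  n <- nrow(m$vertices)
  uniform <- potential_field(matrix(-20, n, 3))
  expect_false(any(detect_ischemia(uniform, m, 0.4, 1)))

  set.seed(5)
  fld <- potential_field(matrix(stats::rnorm(n, sd = 10) - 40, n, 1))
  # q = 0: threshold at the mean
  det0 <- detect_ischemia(fld, m, 0, 0)
  w <- fld$values[, 1]
  fmean <- (w[m$faces[, 1]] + w[m$faces[, 2]] + w[m$faces[, 3]]) / 3
  expect_identical(det0, fmean < mean(w))
  # detected area non-increasing in q
  areas <- vapply(c(0.3, 0.4, 0.5, 1), function(q)
    sum(face_areas(m)[detect_ischemia(fld, m, q, 0)]), numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
  expect_error(detect_ischemia(fld, m, 0.4, 99), "timeline")
})

test_that("traffic-light scores match hand computation on the toy mesh", {
  m <- toy_area_mesh()
  expect_equal(face_areas(m), c(1, 1, 2, 2), tolerance = 1e-12)
  real <- c(TRUE, FALSE, TRUE, FALSE)       # areas 1 + 2 = 3
  det <- c(FALSE, FALSE, TRUE, TRUE)        # areas 2 + 2
  tl <- traffic_light(real, det, m)
  expect_equal(tl[["ci_pct"]], 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(tl[["ih_pct"]], 100 * 1 / 3, tolerance = 1e-12)
  expect_equal(tl[["ii_pct"]], 100 * 2 / 3, tolerance = 1e-12)

  expect_equal(traffic_light(real, real, m),
               c(ci_pct = 100, ih_pct = 0, ii_pct = 0))
  expect_equal(traffic_light(real, rep(FALSE, 4), m),
               c(ci_pct = 0, ih_pct = 100, ii_pct = 0))
  # over-detection can push II past 100%
  tiny <- c(FALSE, FALSE, FALSE, TRUE)
  all4 <- rep(TRUE, 4)
  expect_gt(traffic_light(tiny, all4, m)[["ii_pct"]], 100)
  expect_error(traffic_light(rep(FALSE, 4), det, m), "empty real lesion")

  labs <- traffic_light_labels(real, det)
  expect_identical(labs, c(2L, 0L, 1L, 3L))
})

test_that("CI and IH always partition the real lesion area", {
  m <- icosphere(15, 2)
  nf <- nrow(m$faces)
  set.seed(13)
  for (i in 1:20) {
    real <- stats::runif(nf) < 0.3
    if (!any(real)) real[1] <- TRUE
    det <- stats::runif(nf) < 0.4
    tl <- traffic_light(real, det, m)
    expect_equal(tl[["ci_pct"]] + tl[["ih_pct"]], 100, tolerance = 1e-9)
    expect_true(all(tl >= 0))
  }
})

test_that("peak contrast time finds the depressed-plateau window", {
  # two-population field: ischemic nodes depressed between t = 10 and 20
  vals <- matrix(0, 10, 30)
  vals[1:3, 11:20] <- -30
  vals[, 1:5] <- 5
  fld <- potential_field(vals)
  expect_true(peak_contrast_time(fld) %in% 10:19)
  expect_error(peak_contrast_time(fld, t_min = 100), "empty")
})
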