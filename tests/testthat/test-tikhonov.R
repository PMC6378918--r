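test_that("regularizers take the specified forms", {
  heart <- icosphere(30, 1)
  n <- nrow(heart$vertices)
  x <- stats::rnorm(n)
  expect_equal(as.numeric(regularizer(0, heart) %*% x), x)
  expect_equal(max(abs(regularizer(1, heart) %*% rep(1, n))), 0)
  expect_equal(max(abs(regularizer(2, heart) %*% rep(1, n))), 0,
               tolerance = 1e-10)
  expect_error(regularizer(3, heart), "unsupported")
})

test_that("tikhonov solutions match SVD and GSVD filter-factor oracles", {
  set.seed(42)
  for (rep in seq_len(50)) {
    m <- sample(6:30, 1)
    n <- sample(4:min(m, 20), 1)
    A <- matrix(stats::rnorm(m * n), m, n)
    B <- matrix(stats::rnorm(m * 2), m, 2)
    lam <- 10^stats::runif(1, -3, 1)

    # SVD filter-factor oracle, L = I
    sv <- svd(A)
    x_svd <- sv$v %*% ((sv$d / (sv$d^2 + lam^2)) * crossprod(sv$u, B))
    expect_equal(tikhonov_solve(A, B, diag(n), lam), x_svd,
                 tolerance = 1e-8, ignore_attr = TRUE)
    op <- tikhonov_operator(A, diag(n))
    expect_equal(as.matrix(tikhonov_solve(A, B, diag(n), lam, operator = op)),
                 x_svd, tolerance = 1e-8, ignore_attr = TRUE)

    # generalised (first-difference L) oracle via the regularised
    # normal equations, an independent solution route
    L <- diff(diag(n))
    x_gsvd <- solve(crossprod(A) + lam^2 * crossprod(L), crossprod(A, B))
    expect_equal(tikhonov_solve(A, B, L, lam), x_gsvd,
                 tolerance = 1e-6, ignore_attr = TRUE)
    opL <- tikhonov_operator(A, L)
    expect_equal(as.matrix(tikhonov_solve(A, B, L, lam, operator = opL)),
                 x_gsvd, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("unregularised and over-smoothed limits behave", {
  set.seed(7)
  A <- matrix(stats::rnorm(36), 6, 6)
  K <- matrix(stats::rnorm(12), 6, 2)
  expect_equal(tikhonov_solve(A, K, diag(6), 0), solve(A, K),
               tolerance = 1e-10, ignore_attr = TRUE)
  # rank-deficient system at lambda = 0 errors with advice
  Ad <- cbind(A[, 1:5], A[, 5])
  expect_error(tikhonov_solve(Ad, K, diag(6), 0), "lambda > 0")
  # enormous lambda crushes the solution norm
  smax <- max(svd(A)$d)
  x0 <- tikhonov_solve(A, K, diag(6), 1e-8)
  xb <- tikhonov_solve(A, K, diag(6), 1e6 * smax)
  expect_lt(sqrt(sum(xb^2)), 1e-4 * sqrt(sum(x0^2)))
})

test_that("the L-curve is monotone in lambda", {
  set.seed(3)
  A <- matrix(stats::rnorm(200), 20, 10)
  K <- matrix(stats::rnorm(40), 20, 2)
  lams <- 10^seq(-4, 2, length.out = 25)
  pts <- t(vapply(lams, function(l) lcurve_point(A, K, diag(10), l),
                  numeric(2)))
  expect_true(all(diff(pts[, 1]) >= -1e-10))   # residual nondecreasing
  expect_true(all(diff(pts[, 2]) <= 1e-10))    # seminorm nonincreasing
  # residual -> 0 for a consistent square system as lambda -> 0+
  As <- matrix(stats::rnorm(64), 8, 8)
  ks <- As %*% stats::rnorm(8)
  expect_lt(lcurve_point(As, ks, diag(8), 1e-10)[1], 1e-6)
})

test_that("a gradient-descent oracle confirms the minimised objective", {
  set.seed(11)
  A <- matrix(stats::rnorm(60), 10, 6)
  k <- stats::rnorm(10)
  lam <- 0.5
  obj <- function(x) sum((A %*% x - k)^2) + lam^2 * sum(x^2)
  x_opt <- stats::optim(rep(0, 6), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))$par
  x_tik <- as.numeric(tikhonov_solve(A, k, diag(6), lam))
  expect_equal(x_tik, x_opt, tolerance = 1e-4)
  pt <- lcurve_point(A, k, diag(6), lam)
  expect_equal(pt[["residual"]], sqrt(sum((A %*% x_opt - k)^2)),
               tolerance = 1e-4)
})


test_that("the iterative corner matches a dense-grid curvature oracle", {
  prob <- gaussian_kernel_problem()
  op <- tikhonov_operator(prob$A, diag(64))
  found <- find_corner_lambda(prob$A, prob$b, diag(64), reg_config(order = 0),
                              operator = op)

  # dense-grid oracle: maximum Menger curvature over 200 log-spaced points
  g <- op$gamma[op$mu < 1 - 1e-9]
  lams <- 10^seq(log10(max(min(g[g > 0]), 1e-12 * max(g))), log10(max(g)),
                 length.out = 200)
  pts <- t(vapply(lams, function(l)
    log10(pmax(lcurve_point(prob$A, prob$b, diag(64), l, operator = op),
               1e-300)), numeric(2)))
  curv <- vapply(2:199, function(i)
    ecgi:::menger_curvature(pts[i - 1, ], pts[i, ], pts[i + 1, ]),
    numeric(1))
  lam_grid <- lams[which.max(curv) + 1]
  expect_lt(abs(log(found$lambda / lam_grid)), log(3))

  # reconstruction error within 1.5x of the grid-minimum error
  err <- function(l) sqrt(sum((as.numeric(
    tikhonov_solve(prob$A, prob$b, diag(64), l, operator = op)) -
      prob$x_true)^2))
  best_err <- min(vapply(lams, err, numeric(1)))
  expect_lt(err(found$lambda), 1.5 * best_err)
})

test_that("corner location is robust to bracket shifts", {
  prob <- gaussian_kernel_problem()
  op <- tikhonov_operator(prob$A, diag(64))
  base <- find_corner_lambda(prob$A, prob$b, diag(64), reg_config(order = 0),
                             operator = op)
  shifted <- find_corner_lambda(
    prob$A, prob$b, diag(64),
    reg_config(order = 0, lambda_min = 0.5 * min(base$trace$lambda),
               lambda_max = 2 * max(base$trace$lambda)),
    operator = op)
  expect_lt(abs(log(shifted$lambda / base$lambda)), log(2.5))
})
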