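#' Regularisation operator for a Tikhonov order
#'
#' Order 0 is the identity (penalising solution amplitude), order 1 the
#' first-difference gradient operator (favouring flat solutions), order
#' 2 the cotangent Laplacian (penalising roughness in a second
#' derivative sense). Orders 1 and 2 annihilate constants.
#'
#' @param order 0, 1 or 2.
#' @param heart heart [ecgi_mesh] (its operators are used for orders
#'   1 and 2).
#' @return a (possibly sparse) operator matrix with `n_heart` columns.
#' @export
regularizer <- function(order, heart) {
  n <- nrow(heart$vertices)
  if (order == 0) return(Matrix::Diagonal(n))
  ops <- surface_operators(heart)
  if (order == 1) return(ops$gradient)
  if (order == 2) return(ops$laplacian)
  stop("unsupported Tikhonov order: ", order)
}

#' Regularisation configuration
#'
#' @param order Tikhonov order, 0/1/2.
#' @param lambda_mode `"global"` (one lambda for the stacked time
#'   instants) or `"per_timestep"` (a lambda per column).
#' @param lambda_min,lambda_max L-curve search bracket; `NULL` derives
#'   it from the (generalised) singular spectrum of the transfer matrix,
#'   clipped below at `1e-12` of the largest value.
#' @param iterations maximum corner-search iterations (>= 4).
#' @param tolerance relative lambda tolerance of the corner search.
#' @return list of class `ecgi_reg_config`.
#' @export
reg_config <- function(order = 2, lambda_mode = c("global", "per_timestep"),
                       lambda_min = NULL, lambda_max = NULL,
                       iterations = 50L, tolerance = 1e-3) {
  lambda_mode <- match.arg(lambda_mode)
  if (!order %in% c(0, 1, 2)) stop("order must be 0, 1 or 2")
  if (iterations < 4) stop("need at least 4 iterations")
  if (!is.null(lambda_min) && !is.null(lambda_max)) {
    if (lambda_min <= 0 || lambda_min >= lambda_max)
      stop("need 0 < lambda_min < lambda_max")
  }
  structure(list(order = order, lambda_mode = lambda_mode,
                 lambda_min = lambda_min, lambda_max = lambda_max,
                 iterations = as.integer(iterations), tolerance = tolerance),
            class = "ecgi_reg_config")
}

#' Tikhonov solution for a fixed regularisation parameter
#'
#' Returns the minimiser of `||A R - K||^2 + lambda^2 ||L R||^2`
#' column-wise. Solved through a stable decomposition: the augmented
#' least-squares system `[A; lambda L] R = [K; 0]` by QR, or, when a
#' prebuilt [tikhonov_operator()] is supplied, through its generalised
#' eigenbasis (the two routes agree to solver precision).
#'
#' @param A transfer matrix (`ecgi_transfer` or plain matrix).
#' @param K right-hand side matrix (torso potentials, one column per
#'   timestep) or torso `ecgi_field`.
#' @param L regularisation operator.
#' @param lambda regularisation parameter, >= 0.
#' @param operator optional [tikhonov_operator()] for `(A, L)`.
#' @return heart-node x time matrix.
#' @export
tikhonov_solve <- function(A, K, L, lambda, operator = NULL) {
  Am <- if (inherits(A, "ecgi_transfer")) A$matrix else as.matrix(A)
  Km <- if (inherits(K, "ecgi_field")) K$values else as.matrix(K)
  if (nrow(Km) != nrow(Am)) stop("A and K dimensions are incompatible")
  if (lambda < 0) stop("lambda must be non-negative")
  if (!is.null(operator)) return(operator_solve(operator, Km, lambda)$x)
  if (lambda == 0) {
    qrA <- qr(Am)
    if (qrA$rank < ncol(Am))
      stop("system is singular at lambda = 0; use lambda > 0")
    return(qr.coef(qrA, Km))
  }
  Lm <- as.matrix(L)
  if (ncol(Lm) != ncol(Am)) stop("L and A column counts differ")
  aug <- rbind(Am, lambda * Lm)
  rhs <- rbind(Km, matrix(0, nrow(Lm), ncol(Km)))
  qr.coef(qr(aug), rhs)
}

#' Precomputed Tikhonov operator for repeated solves
#'
#' Factorises the pair `(A, L)` once so that solutions, residual norms
#' and seminorms for any lambda (and any right-hand side) cost a vector
#' scaling: the symmetric pencil `A'A v = mu (A'A + L'L) v` is
#' diagonalised, giving a generalised-SVD-like basis in which the
#' Tikhonov filter is diagonal. Requires `null(A)` and `null(L)` to
#' intersect trivially.
#'
#' @param A transfer matrix (`ecgi_transfer` or matrix).
#' @param L regularisation operator.
#' @return object of class `ecgi_tik_op` with the eigenbasis `V`, the
#'   pencil eigenvalues `mu` in `[0,1]`, the mapped basis `AV` and the
#'   generalised singular values `gamma = sqrt(mu/(1-mu))`.
#' @export
tikhonov_operator <- function(A, L) {
  Am <- if (inherits(A, "ecgi_transfer")) A$matrix else as.matrix(A)
  Cm <- crossprod(Am)
  Dm <- as.matrix(Matrix::crossprod(L))
  S <- Cm + Dm
  R <- tryCatch(chol(S),
                error = function(e)
                  stop("A and L have a common null vector: ", conditionMessage(e)))
  ## B = R^-T C R^-1, symmetric; eigen in the S-metric
  Z <- backsolve(R, Cm, transpose = TRUE)     # R^-T C
  B <- backsolve(R, t(Z), transpose = TRUE)   # R^-T C^T R^-1 (C symmetric)
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  mu <- pmin(pmax(eg$values, 0), 1)
  V <- backsolve(R, eg$vectors)
  gamma <- sqrt(mu / pmax(1 - mu, .Machine$double.eps))
  structure(list(V = V, mu = mu, AV = Am %*% V, gamma = gamma,
                 n = ncol(Am), m = nrow(Am)),
            class = "ecgi_tik_op")
}

## project K once, then per-lambda filtering is O(n * n_t)
operator_project <- function(op, Km) {
  list(b = crossprod(op$AV, Km), k2 = sum(Km^2), nt = ncol(Km))
}

operator_filter <- function(op, proj, lambda) {
  denom <- op$mu + lambda^2 * (1 - op$mu)
  z <- proj$b / denom
  res2 <- max(proj$k2 - 2 * sum(z * proj$b) + sum(op$mu * z^2), 0)
  semi2 <- max(sum((1 - op$mu) * z^2), 0)
  list(z = z, residual = sqrt(res2), seminorm = sqrt(semi2))
}

operator_solve <- function(op, Km, lambda) {
  proj <- operator_project(op, Km)
  flt <- operator_filter(op, proj, lambda)
  list(x = op$V %*% flt$z, residual = flt$residual, seminorm = flt$seminorm)
}

#' One point of the L-curve
#'
#' Residual norm `||A R - K||` and seminorm `||L R||` of the Tikhonov
#' solution at `lambda` (Frobenius norms over all columns of `K`).
#'
#' @inheritParams tikhonov_solve
#' @return named numeric vector `c(residual, seminorm)`.
#' @export
lcurve_point <- function(A, K, L, lambda, operator = NULL) {
  Km <- if (inherits(K, "ecgi_field")) K$values else as.matrix(K)
  if (is.null(operator)) {
    Am <- if (inherits(A, "ecgi_transfer")) A$matrix else as.matrix(A)
    X <- tikhonov_solve(Am, Km, L, lambda)
    c(residual = sqrt(sum((Am %*% X - Km)^2)),
      seminorm = sqrt(sum(as.matrix(L %*% X)^2)))
  } else {
    flt <- operator_filter(operator, operator_project(operator, Km), lambda)
    c(residual = flt$residual, seminorm = flt$seminorm)
  }
}

## Menger curvature of three points on the log-log L-curve
menger_curvature <- function(p1, p2, p3) {
  cross <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
  d12 <- sqrt(sum((p2 - p1)^2)); d23 <- sqrt(sum((p3 - p2)^2))
  d13 <- sqrt(sum((p3 - p1)^2))
  if (d12 * d23 * d13 == 0) return(0)
  2 * cross / (d12 * d23 * d13)
}

#' Locate the L-curve corner lambda
#'
#' Iterative corner location on the log-log L-curve by a golden-section
#' scheme over log(lambda) driven by the 4-point Menger curvature: the
#' interior point on the flatter side is discarded each iteration until
#' the bracket collapses to the relative tolerance. Deterministic; on a
#' flat curvature plateau the smallest lambda attaining the maximum
#' curvature is returned (preferring fidelity over smoothing).
#'
#' @inheritParams tikhonov_solve
#' @param config an [reg_config()]; its bracket, iteration cap and
#'   tolerance are used.
#' @return list with `lambda`, `converged`, and `trace` (a data frame of
#'   evaluated `(lambda, residual, seminorm)` points).
#' @export
find_corner_lambda <- function(A, K, L, config = reg_config(), operator = NULL) {
  Km <- if (inherits(K, "ecgi_field")) K$values else as.matrix(K)
  if (is.null(operator)) operator <- tikhonov_operator(A, L)
  proj <- operator_project(operator, Km)
  ## bracket from the generalised singular spectrum, excluding the
  ## directions in null(L) (mu ~ 1, infinite generalised singular value)
  g <- operator$gamma[operator$mu < 1 - 1e-9]
  gpos <- g[g > 0 & is.finite(g)]
  if (!length(gpos)) stop("empty generalised singular spectrum")
  lam_max <- config$lambda_max %||% max(gpos)
  lam_min <- config$lambda_min %||% max(min(gpos), 1e-12 * lam_max)
  trace <- list()
  pt <- function(lam) {
    flt <- operator_filter(operator, proj, lam)
    trace[[length(trace) + 1L]] <<- c(lam, flt$residual, flt$seminorm)
    log10(c(max(flt$residual, 1e-300), max(flt$seminorm, 1e-300)))
  }
  phi <- (1 + sqrt(5)) / 2
  x1 <- log10(lam_min); x4 <- log10(lam_max)
  x2 <- x4 - (x4 - x1) / phi
  x3 <- x1 + (x4 - x1) / phi
  lam <- 10^c(x1, x2, x3, x4)
  P <- lapply(lam, pt)
  it <- 0L
  converged <- FALSE
  while (it < config$iterations) {
    it <- it + 1L
    c2 <- menger_curvature(P[[1]], P[[2]], P[[3]])
    c3 <- menger_curvature(P[[2]], P[[3]], P[[4]])
    if ((lam[4] - lam[1]) / lam[4] < config$tolerance) { converged <- TRUE; break }
    if (c2 >= c3) {   # corner on the left; ties keep the smaller lambda
      lam <- c(lam[1], NA, lam[2], lam[3]); P <- list(P[[1]], NULL, P[[2]], P[[3]])
      x <- log10(lam[4]) - (log10(lam[4]) - log10(lam[1])) / phi
      lam[2] <- 10^x; P[[2]] <- pt(lam[2])
    } else {
      lam <- c(lam[2], lam[3], NA, lam[4]); P <- list(P[[2]], P[[3]], NULL, P[[4]])
      x <- log10(lam[1]) + (log10(lam[4]) - log10(lam[1])) / phi
      lam[3] <- 10^x; P[[3]] <- pt(lam[3])
    }
  }
  if (!converged)
    warning("L-curve corner search did not converge within iteration budget")
  tr <- do.call(rbind, trace)
  tr <- as.data.frame(tr)
  names(tr) <- c("lambda", "residual", "seminorm")
  tr <- tr[order(tr$lambda), ]
  ## the corner is the evaluated point of maximal Menger curvature over
  ## the whole trace (near-duplicate lambdas merged); the golden-section
  ## refinement above concentrates evaluations around it
  keep <- c(TRUE, diff(log10(tr$lambda)) > log10(1 + config$tolerance / 10))
  tu <- tr[keep, , drop = FALSE]
  lp <- cbind(log10(pmax(tu$residual, 1e-300)),
              log10(pmax(tu$seminorm, 1e-300)))
  best <- lam[2]
  if (nrow(tu) >= 3) {
    curv <- vapply(2:(nrow(tu) - 1), function(i)
      menger_curvature(lp[i - 1, ], lp[i, ], lp[i + 1, ]), numeric(1))
    cmax <- max(curv)
    best <- tu$lambda[min(which(curv >= cmax - 1e-12 * abs(cmax))) + 1L]
  }
  list(lambda = best, converged = converged, trace = tr)
}
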