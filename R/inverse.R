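#' Reconstruct epicardial potentials from body-surface potentials
#'
#' The package's core estimator: solves the ill-posed ECGI inverse
#' problem `K = A R` for the epicardial potential matrix `R` by Tikhonov
#' regularisation, with the regularisation parameter selected at the
#' corner of the L-curve. In `"global"` mode all time instants are
#' stacked into a single matrix system and one lambda is used throughout
#' (the default, trading a marginal accuracy loss for a single corner
#' search); in `"per_timestep"` mode a corner is located independently
#' for every column.
#'
#' @param A transfer matrix (`ecgi_transfer` or plain matrix).
#' @param K interpolated body-surface potentials: torso `ecgi_field` or
#'   matrix (torso nodes x time).
#' @param config an [reg_config()] (order, lambda mode, corner-search
#'   controls).
#' @param heart heart [ecgi_mesh]; required for orders 1 and 2 when `L`
#'   is not given explicitly.
#' @param L optional explicit regularisation operator (overrides
#'   `config$order`).
#' @param lambda optional fixed lambda; skips the corner search.
#' @param operator optional prebuilt [tikhonov_operator()] to reuse
#'   across calls with the same `(A, L)`.
#' @return an object of class `ecgi_inverse` with components
#'   `reconstructed` (heart `ecgi_field`), `lambda_used` (scalar or
#'   per-timestep vector), `residual_norm`, `seminorm`, `lcurve_trace`,
#'   `converged`, `config`, and the problem dimensions.
#' @seealso [tikhonov_solve()], [find_corner_lambda()]
#' @export
ecgi_reconstruct <- function(A, K, config = reg_config(), heart = NULL,
                             L = NULL, lambda = NULL, operator = NULL) {
  Km <- if (inherits(K, "ecgi_field")) K$values else as.matrix(K)
  dt <- if (inherits(K, "ecgi_field")) K$dt else 1
  t0 <- if (inherits(K, "ecgi_field")) K$t0 else 0
  if (is.null(L)) {
    if (config$order == 0) {
      n <- if (inherits(A, "ecgi_transfer")) A$n_heart else ncol(A)
      L <- Matrix::Diagonal(n)
    } else {
      if (is.null(heart))
        stop("heart mesh required for order ", config$order, " regularisation")
      L <- regularizer(config$order, heart)
    }
  }
  if (is.null(operator)) operator <- tikhonov_operator(A, L)

  if (config$lambda_mode == "global" || ncol(Km) == 1L || !is.null(lambda)) {
    if (is.null(lambda)) {
      corner <- find_corner_lambda(A, Km, L, config, operator = operator)
      lambda <- corner$lambda
      trace <- corner$trace
      converged <- corner$converged
    } else {
      trace <- NULL
      converged <- NA
    }
    proj <- operator_project(operator, Km)
    flt <- operator_filter(operator, proj, lambda)
    out <- list(reconstructed = potential_field(operator$V %*% flt$z, dt, t0, "heart"),
                lambda_used = lambda, residual_norm = flt$residual,
                seminorm = flt$seminorm, lcurve_trace = trace,
                converged = converged, Z = flt$z)
  } else {
    nt <- ncol(Km)
    lambdas <- numeric(nt); res <- numeric(nt); sem <- numeric(nt)
    conv <- logical(nt)
    Z <- matrix(0, operator$n, nt)
    for (j in seq_len(nt)) {
      kj <- Km[, j, drop = FALSE]
      corner <- suppressWarnings(
        find_corner_lambda(A, kj, L, config, operator = operator))
      lambdas[j] <- corner$lambda
      conv[j] <- corner$converged
      flt <- operator_filter(operator, operator_project(operator, kj),
                             corner$lambda)
      Z[, j] <- flt$z
      res[j] <- flt$residual; sem[j] <- flt$seminorm
    }
    out <- list(reconstructed = potential_field(operator$V %*% Z, dt, t0, "heart"),
                lambda_used = lambdas, residual_norm = res, seminorm = sem,
                lcurve_trace = NULL, converged = all(conv), Z = Z)
  }
  out$config <- config
  out$n_torso <- nrow(Km); out$n_heart <- operator$n; out$n_time <- ncol(Km)
  out$K <- Km
  out$operator <- operator
  class(out) <- "ecgi_inverse"
  out
}

#' @export
print.ecgi_inverse <- function(x, ...) {
  cat(sprintf("ECGI Tikhonov reconstruction (order %d, %s lambda)\n",
              x$config$order, x$config$lambda_mode))
  cat(sprintf("  %d torso nodes -> %d heart nodes, %d timesteps\n",
              x$n_torso, x$n_heart, x$n_time))
  if (length(x$lambda_used) == 1L)
    cat(sprintf("  lambda = %.4g, residual = %.4g, seminorm = %.4g\n",
                x$lambda_used, x$residual_norm, x$seminorm))
  else
    cat(sprintf("  per-timestep lambda in [%.4g, %.4g]\n",
                min(x$lambda_used), max(x$lambda_used)))
  invisible(x)
}

#' @export
summary.ecgi_inverse <- function(object, ...) {
  cat(sprintf("ECGI inverse solution: order-%d Tikhonov, %s lambda mode\n",
              object$config$order, object$config$lambda_mode))
  cat(sprintf("  problem size: %d x %d, %d timesteps\n",
              object$n_torso, object$n_heart, object$n_time))
  lam <- object$lambda_used
  cat("  lambda:", if (length(lam) == 1) format(lam, digits = 4) else
    paste0("median ", format(stats::median(lam), digits = 4),
           " [", format(min(lam), digits = 3), ", ",
           format(max(lam), digits = 3), "]"), "\n")
  cat(sprintf("  residual |AR-K|_F = %.4g, seminorm |LR|_F = %.4g\n",
              sum(object$residual_norm), sum(object$seminorm)))
  rng <- range(object$reconstructed$values)
  cat(sprintf("  reconstructed potentials in [%.2f, %.2f] mV\n", rng[1], rng[2]))
  if (isFALSE(object$converged))
    cat("  note: corner search hit the iteration budget\n")
  invisible(object)
}

#' @export
coef.ecgi_inverse <- function(object, ...) object$reconstructed$values

#' @export
fitted.ecgi_inverse <- function(object, ...) {
  ## torso potentials implied by the reconstruction, A R-hat = (A V) Z
  object$operator$AV %*% object$Z
}

#' @export
residuals.ecgi_inverse <- function(object, ...) {
  object$K - fitted(object)
}

#' Plot an L-curve
#'
#' Log-log plot of the solution seminorm against the residual norm over
#' the evaluated lambdas, with the selected corner highlighted.
#' @param x an `ecgi_inverse` (global mode, with a recorded trace).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ecgi_inverse <- function(x, ...) {
  tr <- x$lcurve_trace
  if (is.null(tr)) stop("no L-curve trace recorded (fixed-lambda or per-timestep fit)")
  graphics::plot(tr$residual, tr$seminorm, log = "xy", type = "b",
                 xlab = "residual norm ||AR - K||",
                 ylab = "seminorm ||LR||",
                 main = sprintf("L-curve, order-%d Tikhonov", x$config$order), ...)
  sel <- which.min(abs(tr$lambda - x$lambda_used[1]))
  graphics::points(tr$residual[sel], tr$seminorm[sel], pch = 19, col = "red")
  graphics::legend("topright", legend = sprintf("corner lambda = %.3g",
                                                x$lambda_used[1]),
                   pch = 19, col = "red", bty = "n")
  invisible(x)
}
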