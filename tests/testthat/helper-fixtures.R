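# Shared fixtures and independent oracles, built in code at test time.

# flat triangulated unit square with (k+1)^2 vertices (open patch)
flat_patch <- function(k = 8) {
  g <- expand.grid(x = 0:k / k, y = 0:k / k)
  verts <- cbind(g$x, g$y, 0)
  id <- function(i, j) i + 1L + j * (k + 1L)
  tris <- list()
  for (j in 0:(k - 1L)) for (i in 0:(k - 1L)) {
    tris[[length(tris) + 1L]] <- c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L))
    tris[[length(tris) + 1L]] <- c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
  }
  ecgi_mesh(verts, do.call(rbind, tris), closed = FALSE)
}

patch_interior <- function(k = 8) {
  g <- expand.grid(x = 0:k / k, y = 0:k / k)
  which(g$x > 0 & g$x < 1 & g$y > 0 & g$y < 1)
}

# planar 4-face toy mesh with face areas 1, 1, 2, 2 (open patch)
toy_area_mesh <- function() {
  verts <- rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0),
                 c(0, 1, 0), c(2, 1, 0), c(4, 2, 0))
  faces <- rbind(c(1, 2, 4),   # area 1
                 c(2, 5, 4),   # area 1
                 c(2, 3, 6),   # area 2
                 c(3, 6, 5))   # area 2
  ecgi_mesh(verts, faces, closed = FALSE)
}

# farthest-point-sampling oracle: greedy max-min layout on mesh vertices
fps_layout <- function(mesh, n) {
  v <- mesh$vertices
  chosen <- 1L
  d <- sqrt(rowSums(sweep(v, 2, v[1L, ])^2))
  while (length(chosen) < n) {
    nxt <- which.max(d)
    chosen <- c(chosen, nxt)
    d <- pmin(d, sqrt(rowSums(sweep(v, 2, v[nxt, ])^2)))
  }
  chosen
}

# nearest-neighbour distance dispersion (max/min) within a point set
nn_dispersion <- function(points) {
  d <- as.matrix(stats::dist(points))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  max(nn) / min(nn)
}

# first APD90 crossing time of a trace sampled at dt, given activation time
measure_apd90 <- function(trace, times, t_act, resting, peak) {
  thr <- resting + 0.1 * (peak - resting)
  after <- times > t_act + 5
  j <- which(after & trace < thr)[1]
  times[j] - t_act
}

# memoised phantom-scale context shared by the acceptance tests
phantom_cache <- new.env(parent = emptyenv())
acceptance_context <- function() {
  if (is.null(phantom_cache$ctx))
    phantom_cache$ctx <- study_context(study_config())
  phantom_cache$ctx
}

# analytic central-dipole potential in a bounded (insulated) sphere of
# radius R: V(r, theta) = cos(theta) * (1/r^2 + 2 r / R^3), unit moment
dipole_potential <- function(points, R) {
  r <- sqrt(rowSums(points^2))
  costh <- points[, 3] / r
  costh * (1 / r^2 + 2 * r / R^3)
}

gaussian_kernel_problem <- function(n = 64, noise = 0.01, seed = 5) {
  ## discrete smoothing-kernel inverse problem: a Gaussian blur applied
  ## to a frozen correlated (integrated-noise) source profile, which has
  ## spectral content across all modes so that the L-curve corner is an
  ## error-competitive parameter choice; 1% relative noise by default
  s <- seq(0, 1, length.out = n)
  A <- exp(-outer(s, s, function(a, b) (a - b)^2) / (2 * 0.05^2))
  A <- A / rowSums(A)
  set.seed(8)
  x_true <- cumsum(stats::rnorm(n)) / sqrt(n)
  x_true <- x_true - mean(x_true)
  b0 <- A %*% x_true
  set.seed(seed)
  b <- b0 + stats::rnorm(n, sd = noise * sqrt(mean(b0^2)))
  list(A = A, b = b, x_true = x_true)
}
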