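#' Signed solid angle of a triangle
#'
#' Closed-form (van Oosterom-Strackee) signed solid angle subtended by a
#' triangle at an observation point; the sign follows the triangle
#' winding (positive when the outward normal faces away from the
#' observer, i.e. the observer is on the inner side).
#'
#' @param triangle 3 x 3 matrix, one vertex per row (mm).
#' @param observation length-3 observation point (mm).
#' @return solid angle in steradians.
#' @export
solid_angle <- function(triangle, observation) {
  v1 <- triangle[1, ] - observation
  v2 <- triangle[2, ] - observation
  v3 <- triangle[3, ] - observation
  l1 <- sqrt(sum(v1^2)); l2 <- sqrt(sum(v2^2)); l3 <- sqrt(sum(v3^2))
  num <- v1[1] * (v2[2] * v3[3] - v2[3] * v3[2]) -
         v1[2] * (v2[1] * v3[3] - v2[3] * v3[1]) +
         v1[3] * (v2[1] * v3[2] - v2[2] * v3[1])
  den <- l1 * l2 * l3 + sum(v1 * v2) * l3 + sum(v1 * v3) * l2 + sum(v2 * v3) * l1
  2 * atan2(num, den)
}

## Double-layer collocation block: obs_points x mesh-vertex matrix of
## solid-angle weights. The linearly varying vertex density over each
## triangle is integrated with a one-point (barycentric-average) rule:
## the face's analytic solid angle is split equally over its 3 vertices.
double_layer_block <- function(obs, mesh) {
  n_obs <- nrow(obs)
  v <- mesh$vertices; f <- mesh$faces
  P <- matrix(0, n_obs, nrow(v))
  ox <- obs[, 1]; oy <- obs[, 2]; oz <- obs[, 3]
  for (k in seq_len(nrow(f))) {
    p1 <- v[f[k, 1], ]; p2 <- v[f[k, 2], ]; p3 <- v[f[k, 3], ]
    a1 <- p1[1] - ox; a2 <- p1[2] - oy; a3 <- p1[3] - oz
    b1 <- p2[1] - ox; b2 <- p2[2] - oy; b3 <- p2[3] - oz
    c1 <- p3[1] - ox; c2 <- p3[2] - oy; c3 <- p3[3] - oz
    la <- sqrt(a1^2 + a2^2 + a3^2)
    lb <- sqrt(b1^2 + b2^2 + b3^2)
    lc <- sqrt(c1^2 + c2^2 + c3^2)
    num <- a1 * (b2 * c3 - b3 * c2) - a2 * (b1 * c3 - b3 * c1) +
           a3 * (b1 * c2 - b2 * c1)
    den <- la * lb * lc + (a1 * b1 + a2 * b2 + a3 * b3) * lc +
           (a1 * c1 + a2 * c2 + a3 * c3) * lb +
           (b1 * c1 + b2 * c2 + b3 * c3) * la
    om <- 2 * atan2(num, den) / 3
    P[, f[k, 1]] <- P[, f[k, 1]] + om
    P[, f[k, 2]] <- P[, f[k, 2]] + om
    P[, f[k, 3]] <- P[, f[k, 3]] + om
  }
  P
}

## analytic integral of 1/R over a triangle observed from its own vertex P
vertex_single_layer <- function(P, Q, R) {
  u <- R - Q
  lu <- sqrt(sum(u^2))
  u <- u / lu
  Fp <- Q + sum((P - Q) * u) * u       # foot of perpendicular from P
  d <- sqrt(sum((P - Fp)^2))
  if (d < 1e-12) return(0)
  sQ <- sum((Q - Fp) * u)
  sR <- sum((R - Fp) * u)
  abs(d * (asinh(sR / d) - asinh(sQ / d)))
}

## Single-layer collocation block: obs x mesh-vertex matrix of integrals
## of the linear shape functions against 1/R. A 3-point interior rule
## (points shifted towards each vertex) integrates each shape function
## with distinct weights per vertex column — an equal per-vertex split
## would acquire an exact null vector on 3-colorable triangulations
## (geodesic frequency divisible by 3). When `self`, the singular
## own-vertex triangles use the analytic vertex integral, of which the
## observation vertex's shape function takes exactly half.
single_layer_block <- function(obs, mesh, self = FALSE) {
  n_obs <- nrow(obs)
  v <- mesh$vertices; f <- mesh$faces
  areas <- face_areas(mesh)
  G <- matrix(0, n_obs, nrow(v))
  ox <- obs[, 1]; oy <- obs[, 2]; oz <- obs[, 3]
  for (k in seq_len(nrow(f))) {
    p1 <- v[f[k, 1], ]; p2 <- v[f[k, 2], ]; p3 <- v[f[k, 3], ]
    q1 <- (4 * p1 + p2 + p3) / 6
    q2 <- (p1 + 4 * p2 + p3) / 6
    q3 <- (p1 + p2 + 4 * p3) / 6
    r1 <- 1 / sqrt((q1[1] - ox)^2 + (q1[2] - oy)^2 + (q1[3] - oz)^2)
    r2 <- 1 / sqrt((q2[1] - ox)^2 + (q2[2] - oy)^2 + (q2[3] - oz)^2)
    r3 <- 1 / sqrt((q3[1] - ox)^2 + (q3[2] - oy)^2 + (q3[3] - oz)^2)
    w <- areas[k] / 3
    c1 <- w * (4 * r1 + r2 + r3) / 6
    c2 <- w * (r1 + 4 * r2 + r3) / 6
    c3 <- w * (r1 + r2 + 4 * r3) / 6
    if (self) {
      for (vi in f[k, ]) {
        others <- setdiff(f[k, ], vi)
        total <- vertex_single_layer(v[vi, ], v[others[1], ], v[others[2], ])
        c1[vi] <- total * (if (f[k, 1] == vi) 0.5 else 0.25)
        c2[vi] <- total * (if (f[k, 2] == vi) 0.5 else 0.25)
        c3[vi] <- total * (if (f[k, 3] == vi) 0.5 else 0.25)
      }
    }
    G[, f[k, 1]] <- G[, f[k, 1]] + c1
    G[, f[k, 2]] <- G[, f[k, 2]] + c2
    G[, f[k, 3]] <- G[, f[k, 3]] + c3
  }
  G
}

#' Assemble the epicardial-to-torso transfer matrix
#'
#' Boundary element assembly of the linear map `y = A x` from epicardial
#' node potentials to torso node potentials for a homogeneous volume
#' conductor with an insulating torso boundary. Vertex collocation of
#' Green's representation on both surfaces yields two coupled equations;
#' the heart-surface normal-gradient unknowns are eliminated through the
#' heart single-layer block, and the self-surface solid-angle diagonals
#' are closed by constant-potential consistency (each self block's rows
#' sum to the on-surface solid angle 2*pi), which makes a constant
#' epicardial potential map exactly to the same constant on the torso.
#'
#' @param torso,heart closed outward-oriented [ecgi_mesh] surfaces; the
#'   heart must lie strictly inside the torso.
#' @return object of class `ecgi_transfer` with elements `matrix`
#'   (n_torso x n_heart), `n_torso`, `n_heart`, `torso_label`,
#'   `heart_label`.
#' @export
assemble_transfer <- function(torso, heart) {
  validate_mesh(torso); validate_mesh(heart)
  if (min_cross_distance(heart$vertices, torso$vertices) <= 0)
    stop("geometry error: surfaces touch or intersect")
  vb <- torso$vertices; vh <- heart$vertices
  nb <- nrow(vb); nh <- nrow(vh)

  P_BB <- double_layer_block(vb, torso)
  P_BH <- double_layer_block(vb, heart)
  P_HB <- double_layer_block(vh, torso)
  P_HH <- double_layer_block(vh, heart)

  ## containment check: closed torso seen from an interior point subtends 4*pi
  if (any(abs(rowSums(P_HB) - 4 * pi) > 0.2))
    stop("geometry error: heart surface is not strictly inside the torso")

  ## auto-solid-angle closure of the self blocks (principal value = 2*pi)
  diag(P_BB) <- 0
  diag(P_BB) <- 2 * pi - rowSums(P_BB)
  diag(P_HH) <- 0
  diag(P_HH) <- 2 * pi - rowSums(P_HH)

  G_BH <- single_layer_block(vb, heart, self = FALSE)
  G_HH <- single_layer_block(vh, heart, self = TRUE)

  X <- tryCatch(solve(G_HH, cbind(P_HB, P_HH + diag(2 * pi, nh))),
                error = function(e)
                  stop("singular heart single-layer block (rcond = ",
                       format(rcond(G_HH)), "): ", conditionMessage(e)))
  X1 <- X[, seq_len(nb), drop = FALSE]
  X2 <- X[, nb + seq_len(nh), drop = FALSE]

  M_BB <- diag(2 * pi, nb) - P_BB + G_BH %*% X1
  M_BH <- -P_BH + G_BH %*% X2
  A <- tryCatch(solve(M_BB, M_BH),
                error = function(e)
                  stop("singular reduced torso system (rcond = ",
                       format(rcond(M_BB)), "): ", conditionMessage(e)))
  structure(list(matrix = A, n_torso = nb, n_heart = nh,
                 torso_label = torso$role, heart_label = heart$role),
            class = "ecgi_transfer")
}

#' @export
print.ecgi_transfer <- function(x, ...) {
  cat(sprintf("ecgi_transfer: %d torso nodes x %d heart nodes\n",
              x$n_torso, x$n_heart))
  rs <- rowSums(x$matrix)
  cat(sprintf("  row sums in [%.4f, %.4f] (constant-consistency ~ 1)\n",
              min(rs), max(rs)))
  invisible(x)
}

#' @export
as.matrix.ecgi_transfer <- function(x, ...) x$matrix

#' Forward body-surface potentials
#'
#' Applies the transfer matrix column-wise: `y_t = A x_t` for every
#' timestep, preserving the timeline metadata.
#'
#' @param A an `ecgi_transfer`.
#' @param x epicardial `ecgi_field` (heart-node rows).
#' @return torso `ecgi_field`.
#' @export
forward_bsp <- function(A, x) {
  if (nrow(x$values) != A$n_heart)
    stop("dimension mismatch: field has ", nrow(x$values),
         " nodes, transfer expects ", A$n_heart)
  potential_field(A$matrix %*% x$values, x$dt, x$t0, role = "torso")
}

#' Write / read a transfer matrix as delimited text
#'
#' Tab-separated dense matrix preceded by a `#`-comment header naming
#' the two surfaces and their node counts.
#' @param A an `ecgi_transfer`.
#' @param path file path.
#' @return `path` / an `ecgi_transfer`.
#' @export
write_transfer <- function(A, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ecgi_transfer torso=%s n_torso=%d heart=%s n_heart=%d",
                     A$torso_label, A$n_torso, A$heart_label, A$n_heart), con)
  utils::write.table(A$matrix, con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_transfer
#' @export
read_transfer <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  kv <- stats::setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   comment.char = "#"))
  dimnames(m) <- NULL
  structure(list(matrix = m, n_torso = nrow(m), n_heart = ncol(m),
                 torso_label = kv[["torso"]], heart_label = kv[["heart"]]),
            class = "ecgi_transfer")
}
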