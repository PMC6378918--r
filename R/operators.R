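#' Discrete surface operators
#'
#' Builds the sparse first- and second-order roughness operators used by
#' the regularisers and by the harmonic body-surface interpolation:
#'
#' * `gradient`: edge-by-node incidence matrix with rows
#'   `(x_j - x_i) / |e_ij|` — a first-difference operator whose squared
#'   norm penalises potential differences across mesh edges, scaled by
#'   inverse edge length. It annihilates constants.
#' * `laplacian`: symmetric cotangent-weighted Laplacian `L = D - W`
#'   with `w_ij = (cot a_ij + cot b_ij)/2` over the two angles opposite
#'   edge `ij`. Rows sum to zero, so constants are in its null space;
#'   on a connected closed surface the null space is exactly the
#'   constants.
#'
#' @param mesh an [ecgi_mesh].
#' @return list of class `ecgi_operators` with sparse matrices
#'   `gradient` (n_edges x n_nodes) and `laplacian` (n_nodes x n_nodes).
#' @export
surface_operators <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)

  cot3 <- function(i, j, k) {
    # cotangent of the angle at vertex i in triangles (i, j, k)
    u <- v[j, , drop = FALSE] - v[i, , drop = FALSE]
    w <- v[k, , drop = FALSE] - v[i, , drop = FALSE]
    dot <- rowSums(u * w)
    cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    dot / pmax(sqrt(cx^2 + cy^2 + cz^2), 1e-300)
  }
  # angle at vertex 1 weights edge (2,3), etc.
  ii <- c(f[, 2], f[, 3], f[, 1])
  jj <- c(f[, 3], f[, 1], f[, 2])
  ww <- c(cot3(f[, 1], f[, 2], f[, 3]),
          cot3(f[, 2], f[, 3], f[, 1]),
          cot3(f[, 3], f[, 1], f[, 2])) / 2
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(n, n))
  L <- Matrix::Diagonal(n, Matrix::rowSums(W)) - W

  e <- mesh_edges(mesh)
  elen <- sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
  G <- Matrix::sparseMatrix(i = rep(seq_len(nrow(e)), 2L),
                            j = c(e[, 1], e[, 2]),
                            x = c(-1 / elen, 1 / elen),
                            dims = c(nrow(e), n))
  structure(list(gradient = G, laplacian = L, n_nodes = n),
            class = "ecgi_operators")
}

#' Mesh edge-graph as an igraph object
#'
#' Undirected graph over mesh vertices with Euclidean edge lengths as
#' weights; used for geodesic activation times and connectivity checks.
#' @param mesh an [ecgi_mesh].
#' @return an [igraph::graph] with a `weight` edge attribute in mm.
#' @export
mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  v <- mesh$vertices
  len <- sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- len
  g
}
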