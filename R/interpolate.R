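#' Sample multi-lead ECGs at electrode nodes
#'
#' Extracts the body-surface potential rows at the electrode nodes, in
#' layout order: the multi-lead "ECG matrix" (electrodes x time, mV).
#'
#' @param bsp torso `ecgi_field`.
#' @param layout an `ecgi_layout` of torso node indices.
#' @return numeric matrix with attribute `layout` (the node indices) and
#'   timeline attributes `dt`, `t0`.
#' @export
sample_leads <- function(bsp, layout) {
  idx <- as.integer(layout)
  if (any(idx < 1L | idx > nrow(bsp$values)))
    stop("electrode index out of range for this torso field")
  leads <- bsp$values[idx, , drop = FALSE]
  attr(leads, "layout") <- idx
  attr(leads, "dt") <- bsp$dt
  attr(leads, "t0") <- bsp$t0
  leads
}

#' Harmonic interpolation operator for a torso layout
#'
#' Prefactorises the constrained cotangent-Laplacian system used by
#' [interpolate_full_bsp()]: free (non-electrode) nodes are solved as
#' the discrete harmonic extension of the electrode values, one sparse
#' triangular solve per timestep against a single shared factorisation.
#'
#' @param torso torso [ecgi_mesh].
#' @param layout an `ecgi_layout`.
#' @return internal operator object (class `ecgi_interp_op`).
#' @export
interpolation_operator <- function(torso, layout) {
  idx <- sort(unique(as.integer(layout)))
  n <- nrow(torso$vertices)
  if (length(idx) < 4) stop("need at least 4 electrodes")
  L <- surface_operators(torso)$laplacian
  free <- setdiff(seq_len(n), idx)
  ## every free connected component must touch a constrained node
  if (length(free)) {
    g <- mesh_graph(torso)
    sub <- igraph::induced_subgraph(g, free)
    comp <- igraph::components(sub)$membership
    adj <- igraph::as_adjacency_matrix(g)
    touch_any <- tapply(Matrix::rowSums(adj[free, idx, drop = FALSE]) > 0, comp, any)
    if (!all(touch_any))
      stop("free node component with no constrained neighbour")
  }
  Lff <- L[free, free, drop = FALSE]
  Lfc <- L[free, idx, drop = FALSE]
  fac <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Lff)),
                  error = function(e) Matrix::lu(Lff))
  structure(list(free = free, constrained = idx, Lfc = Lfc, factor = fac,
                 n = n), class = "ecgi_interp_op")
}

#' Interpolate the full body-surface potential map
#'
#' Reconstructs potentials at every torso node from the limited
#' electrode recordings: electrode nodes keep their measured values
#' exactly; all other nodes take the discrete harmonic extension, i.e.
#' the minimiser of the cotangent-Laplacian Dirichlet energy subject to
#' the electrode constraints (the surface analogue of linear
#' interpolation between scattered samples).
#'
#' @param leads electrode x time matrix from [sample_leads()] (or any
#'   matrix whose rows follow `layout` order).
#' @param layout the `ecgi_layout` the rows correspond to.
#' @param torso torso [ecgi_mesh].
#' @param op optional prebuilt [interpolation_operator()] (rebuilt when
#'   omitted).
#' @param dt,t0 timeline metadata when `leads` carries none.
#' @return torso `ecgi_field` with all nodes filled.
#' @export
interpolate_full_bsp <- function(leads, layout, torso, op = NULL,
                                 dt = NULL, t0 = NULL) {
  idx <- as.integer(layout)
  leads <- as.matrix(leads)
  if (nrow(leads) != length(idx))
    stop("lead matrix rows must match layout length")
  if (is.null(op)) op <- interpolation_operator(torso, layout)
  full <- matrix(0, op$n, ncol(leads))
  ## operator stores constraints sorted; reorder incoming rows to match
  ord <- match(op$constrained, idx)
  vals_c <- leads[ord, , drop = FALSE]
  full[op$constrained, ] <- vals_c
  if (length(op$free)) {
    rhs <- -op$Lfc %*% vals_c
    full[op$free, ] <- as.matrix(Matrix::solve(op$factor, rhs))
  }
  potential_field(full,
                  dt = dt %||% attr(leads, "dt") %||% 1,
                  t0 = t0 %||% attr(leads, "t0") %||% 0,
                  role = "torso")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read multi-lead ECG matrices
#'
#' Tab-separated matrix (electrodes x time) with a header row of 0-based
#' electrode node indices.
#' @param leads lead matrix from [sample_leads()].
#' @param path file path.
#' @return `path` / a lead matrix with `layout` attribute.
#' @export
write_leads <- function(leads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(attr(leads, "layout") - 1L, collapse = "\t"), con)
  utils::write.table(unclass(leads), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_leads
#' @export
read_leads <- function(path) {
  hdr <- as.integer(strsplit(readLines(path, n = 1), "\t")[[1]]) + 1L
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE, skip = 1))
  dimnames(m) <- NULL
  attr(m, "layout") <- hdr
  m
}
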