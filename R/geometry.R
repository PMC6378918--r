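#' Icosphere mesh
#'
#' Geodesic sphere obtained by recursive subdivision of an icosahedron,
#' giving `20 * 4^subdivisions` faces with near-uniform triangles; the
#' workhorse for spherical validation geometries and, after anisotropic
#' scaling, for the ellipsoidal phantom surfaces.
#'
#' @param radius sphere radius in mm.
#' @param subdivisions non-negative integer; each level quadruples the
#'   face count.
#' @return an [ecgi_mesh] with all vertices at distance `radius` from the
#'   origin and outward-oriented faces.
#' @export
icosphere <- function(radius, subdivisions = 0L) {
  stopifnot(radius > 0, subdivisions >= 0)
  geodesic_sphere(radius, 2L^as.integer(subdivisions))
}

#' Geodesic sphere of arbitrary frequency
#'
#' Class-I geodesic subdivision of the icosahedron: each face is split
#' into `frequency^2` triangles before projection to the sphere, giving
#' `10 * frequency^2 + 2` vertices. Frequencies that are not powers of
#' two allow intermediate mesh resolutions (e.g. frequency 10 gives a
#' 1002-node surface).
#'
#' @param radius sphere radius (mm).
#' @param frequency positive integer subdivision frequency.
#' @return an [ecgi_mesh].
#' @export
geodesic_sphere <- function(radius, frequency = 1L) {
  stopifnot(radius > 0, frequency >= 1)
  nu <- as.integer(frequency)
  ico <- icosahedron()
  key_env <- new.env(hash = TRUE, size = 12L * nu^2)
  verts <- matrix(0, 0, 3)
  vcount <- 0L
  get_vertex <- function(p) {
    p <- p / sqrt(sum(p^2))
    key <- paste(sprintf("%.9f", p), collapse = ",")
    id <- key_env[[key]]
    if (is.null(id)) {
      vcount <<- vcount + 1L
      verts <<- rbind(verts, p)
      key_env[[key]] <- vcount
      id <- vcount
    }
    id
  }
  faces <- vector("list", nrow(ico$faces))
  for (fi in seq_len(nrow(ico$faces))) {
    A <- ico$vertices[ico$faces[fi, 1], ]
    B <- ico$vertices[ico$faces[fi, 2], ]
    C <- ico$vertices[ico$faces[fi, 3], ]
    # vertex grid in barycentric lattice coordinates (i towards B, j towards C)
    ids <- matrix(NA_integer_, nu + 1L, nu + 1L)
    for (i in 0:nu) for (j in 0:(nu - i))
      ids[i + 1L, j + 1L] <- get_vertex((A * (nu - i - j) + B * i + C * j) / nu)
    tri <- list()
    for (i in 0:(nu - 1L)) for (j in 0:(nu - 1L - i)) {
      tri[[length(tri) + 1L]] <- c(ids[i + 1L, j + 1L], ids[i + 2L, j + 1L], ids[i + 1L, j + 2L])
      if (j < nu - 1L - i)
        tri[[length(tri) + 1L]] <- c(ids[i + 2L, j + 1L], ids[i + 2L, j + 2L], ids[i + 1L, j + 2L])
    }
    faces[[fi]] <- do.call(rbind, tri)
  }
  faces <- do.call(rbind, faces)
  verts <- verts * radius
  rownames(verts) <- NULL
  m <- structure(list(vertices = verts, faces = faces, role = "generic",
                      closed = TRUE), class = "ecgi_mesh")
  if (signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  validate_mesh(m)
  m
}

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

#' Ellipsoid mesh
#'
#' Geodesic sphere scaled anisotropically to the given semi-axes and
#' translated to `centre`. The scaling preserves outward orientation.
#'
#' @param semiaxes length-3 positive vector (mm).
#' @param centre length-3 vector (mm).
#' @param frequency geodesic frequency (see [geodesic_sphere()]).
#' @param role surface role tag.
#' @return an [ecgi_mesh].
#' @export
ellipsoid_mesh <- function(semiaxes, centre = c(0, 0, 0), frequency = 8L,
                           role = "generic") {
  stopifnot(length(semiaxes) == 3, all(semiaxes > 0))
  m <- geodesic_sphere(1, frequency)
  m$vertices <- sweep(sweep(m$vertices, 2, semiaxes, `*`), 2, centre, `+`)
  m$role <- role
  validate_mesh(m)
  m
}

#' Synthetic heart-torso phantom
#'
#' A pair of closed surfaces standing in for anatomical ventricle and
#' torso geometries: an ellipsoidal torso containing an ellipsoidal
#' "ventricle" offset towards the left-anterior chest wall. Default
#' dimensions mimic adult anatomy scale (torso semi-axes 170/120/300 mm,
#' ventricle 45/40/70 mm), with mesh resolutions near 1,000 heart nodes
#' and 2,500 torso nodes at the default frequencies.
#'
#' @param torso_semiaxes,heart_semiaxes length-3 semi-axes (mm).
#' @param heart_offset translation of the heart centre from the torso
#'   centre (mm); default shifts left (+x) and anterior (-y).
#' @param heart_frequency,torso_frequency geodesic frequencies of the two
#'   meshes (vertex count `10*f^2+2`).
#' @return list with elements `heart` and `torso` ([ecgi_mesh] objects,
#'   role-tagged), plus `min_distance`, the minimum heart-vertex to
#'   torso-surface vertex distance (mm).
#' @export
torso_ventricle_phantom <- function(torso_semiaxes = c(170, 120, 300),
                                    heart_semiaxes = c(45, 40, 70),
                                    heart_offset = c(40, -35, 60),
                                    heart_frequency = 10L,
                                    torso_frequency = 16L) {
  torso <- ellipsoid_mesh(torso_semiaxes, c(0, 0, 0), torso_frequency, "torso")
  heart <- ellipsoid_mesh(heart_semiaxes, heart_offset, heart_frequency, "heart")
  # containment: every heart vertex strictly inside the torso ellipsoid
  q <- sweep(heart$vertices, 2, torso_semiaxes, `/`)
  if (any(rowSums(q^2) >= 1))
    stop("geometry error: heart surface intersects or leaves the torso")
  dmin <- min_cross_distance(heart$vertices, torso$vertices)
  list(heart = heart, torso = torso, min_distance = dmin)
}

min_cross_distance <- function(a, b) {
  ## min over pairs of euclidean distance, computed blockwise
  best <- Inf
  step <- 512L
  for (s in seq(1L, nrow(a), by = step)) {
    blk <- a[s:min(s + step - 1L, nrow(a)), , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(b^2), `+`) - 2 * blk %*% t(b)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

#' Electrode grid layout on the torso
#'
#' Constructs an approximately uniform grid of recording electrodes: a
#' regular lattice in (azimuth, height) over the torso surface — heights
#' restricted to the central 80% of the torso's vertical extent to avoid
#' the degenerate polar caps — snapped to the nearest torso-mesh nodes.
#' Snapping conflicts are resolved deterministically by taking the
#' nearest unused node, so the layout has exactly `n` unique indices and
#' is reproducible for a fixed mesh and `n`.
#'
#' @param torso torso [ecgi_mesh].
#' @param n number of electrodes, `4 <= n <=` node count; the study
#'   defaults use 32, 64, 128, 256, 512 and 1024.
#' @return an object of class `ecgi_layout`: integer vector of 1-based
#'   torso node indices with attribute `n`.
#' @export
electrode_grid <- function(torso, n) {
  nv <- nrow(torso$vertices)
  if (n < 4 || n > nv) stop("electrode count must be in [4, node count]")
  v <- torso$vertices
  ctr <- colMeans(v)
  theta <- atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])
  z <- v[, 3]
  rbar <- mean(sqrt((v[, 1] - ctr[1])^2 + (v[, 2] - ctr[2])^2))
  zr <- range(z)
  margin <- 0.10 * diff(zr)
  n_rows <- max(2L, round(sqrt(n / 2)))
  n_cols <- ceiling(n / n_rows)
  z_levels <- seq(zr[1] + margin, zr[2] - margin, length.out = n_rows)
  th_levels <- seq(-pi, pi, length.out = n_cols + 1L)[seq_len(n_cols)]
  grid <- expand.grid(theta = th_levels, z = z_levels)[seq_len(n), ]
  used <- logical(nv)
  idx <- integer(n)
  for (k in seq_len(n)) {
    dth <- abs(theta - grid$theta[k])
    dth <- pmin(dth, 2 * pi - dth)
    d2 <- (rbar * dth)^2 + (z - grid$z[k])^2
    d2[used] <- Inf
    j <- which.min(d2)
    idx[k] <- j
    used[j] <- TRUE
  }
  structure(as.integer(idx), n = n, class = "ecgi_layout")
}

#' Ischemic lesion specification
#'
#' Circular transmural lesion: a ball of given radius about a centre
#' point on/near the heart surface, with a fully remodelled central zone
#' covering `central_fraction` of the radius and a boundary zone with a
#' linear central-to-healthy taper over the remainder.
#'
#' @param centre length-3 point (mm).
#' @param radius lesion radius (mm), > 0; study defaults 27, 20, 14, 8.
#' @param central_fraction fraction of the radius occupied by the central
#'   zone (default 0.8, i.e. the boundary zone is the outer 20%).
#' @return an object of class `ecgi_lesion`.
#' @export
lesion_spec <- function(centre, radius, central_fraction = 0.8) {
  stopifnot(length(centre) == 3, radius > 0,
            central_fraction > 0, central_fraction < 1)
  structure(list(centre = as.numeric(centre), radius = radius,
                 central_fraction = central_fraction),
            class = "ecgi_lesion")
}

#' Lesion zone membership and remodelling weight
#'
#' Labels each heart node healthy / boundary / central by Euclidean
#' distance from the lesion centre and returns the remodelling ramp
#' weight: 1 inside the central zone, falling linearly to 0 across the
#' boundary zone, 0 outside the lesion.
#'
#' @param heart heart [ecgi_mesh].
#' @param lesion an [lesion_spec()] object, or `NULL` for no lesion.
#' @return list with `zone` (factor healthy/boundary/central per node),
#'   `weight` (numeric in `[0,1]` per node) and `distance` (mm).
#' @export
lesion_zones <- function(heart, lesion) {
  nv <- nrow(heart$vertices)
  if (is.null(lesion)) {
    return(list(zone = factor(rep("healthy", nv),
                              levels = c("healthy", "boundary", "central")),
                weight = rep(0, nv), distance = rep(Inf, nv)))
  }
  d <- sqrt(rowSums(sweep(heart$vertices, 2, lesion$centre)^2))
  rc <- lesion$central_fraction * lesion$radius
  w <- ifelse(d <= rc, 1,
              ifelse(d <= lesion$radius,
                     (lesion$radius - d) / (lesion$radius - rc), 0))
  zone <- factor(ifelse(d <= rc, "central",
                        ifelse(d <= lesion$radius, "boundary", "healthy")),
                 levels = c("healthy", "boundary", "central"))
  list(zone = zone, weight = w, distance = d)
}

#' Write / read electrode layouts as plain text
#'
#' Serialised as 0-based node indices, one per line.
#' @param layout an `ecgi_layout`.
#' @param path file path.
#' @return `path` / an `ecgi_layout`.
#' @export
write_layout <- function(layout, path) {
  writeLines(as.character(as.integer(layout) - 1L), path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  idx <- as.integer(readLines(path)) + 1L
  structure(idx, n = length(idx), class = "ecgi_layout")
}
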