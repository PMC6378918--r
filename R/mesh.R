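#' Triangulated surface mesh
#'
#' Container for a closed, outward-oriented triangulated surface in
#' millimetre coordinates, used for both the epicardial (heart) and torso
#' surfaces.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices with
#'   consistent outward winding.
#' @param role surface role, `"heart"`, `"torso"` or `"generic"`.
#' @param closed logical; if `TRUE` (default) the mesh is validated as a
#'   closed orientable surface (every edge shared by exactly two faces,
#'   positive signed volume). Open patches (used e.g. for planar test
#'   fixtures) pass `closed = FALSE`.
#'
#' @return An object of class `ecgi_mesh`: a list with elements
#'   `vertices`, `faces`, `role`, `closed`.
#' @export
ecgi_mesh <- function(vertices, faces, role = c("generic", "heart", "torso"),
                      closed = TRUE) {
  role <- match.arg(role)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  mesh <- structure(
    list(vertices = vertices, faces = faces, role = role, closed = closed),
    class = "ecgi_mesh"
  )
  validate_mesh(mesh)
  mesh
}

#' Validate mesh invariants
#'
#' Checks index ranges, absence of degenerate (zero-area) faces and, for
#' closed meshes, the two-faces-per-edge property and outward orientation
#' (positive signed volume).
#'
#' @param mesh an [ecgi_mesh].
#' @return `mesh`, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (anyNA(v) || any(!is.finite(v))) stop("non-finite vertex coordinates")
  if (min(f) < 1L || max(f) > nrow(v)) stop("face vertex index out of range")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("face with repeated vertex index")
  a <- face_areas(mesh)
  if (any(a <= 1e-12 * max(a))) stop("zero-area face present")
  if (isTRUE(mesh$closed)) {
    ek <- edge_keys(f)
    tab <- table(ek)
    if (any(tab != 2L))
      stop("mesh is not closed: ", sum(tab != 2L),
           " edge(s) not shared by exactly 2 faces")
    if (signed_volume(mesh) <= 0)
      stop("mesh not outward oriented (signed volume <= 0)")
  }
  invisible(mesh)
}

edge_keys <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Unique undirected edges of a mesh
#' @param mesh an [ecgi_mesh].
#' @return two-column integer matrix of vertex index pairs (i < j).
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Signed volume enclosed by a closed mesh
#'
#' Positive for outward-oriented surfaces (divergence theorem on x/3).
#' @param mesh an [ecgi_mesh].
#' @return scalar volume in mm^3.
#' @export
signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' Triangle areas of a mesh
#' @param mesh an [ecgi_mesh].
#' @return numeric vector of face areas (mm^2).
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Face centroids
#' @param mesh an [ecgi_mesh].
#' @return m x 3 matrix of triangle centroids (mm).
#' @export
face_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' @export
print.ecgi_mesh <- function(x, ...) {
  cat(sprintf("ecgi_mesh (%s): %d vertices, %d faces%s\n",
              x$role, nrow(x$vertices), nrow(x$faces),
              if (isTRUE(x$closed)) ", closed" else ", open patch"))
  if (isTRUE(x$closed))
    cat(sprintf("  enclosed volume: %.1f cm^3\n", signed_volume(x) / 1000))
  invisible(x)
}

#' Read a triangle mesh from ASCII PLY or OBJ
#'
#' Minimal readers for the two plain-text dialects used by the package:
#' ASCII PLY with vertex x/y/z properties and triangular faces, and
#' Wavefront OBJ with `v`/`f` records (1-based indices per the OBJ
#' standard; texture/normal slashes in face records are tolerated).
#'
#' @param path file path; format chosen by extension (`.ply` / `.obj`).
#' @param role surface role tag for the resulting mesh.
#' @param closed whether to validate the mesh as closed.
#' @return an [ecgi_mesh].
#' @export
read_mesh <- function(path, role = "generic", closed = TRUE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") read_ply(path, role, closed)
  else if (ext == "obj") read_obj(path, role, closed)
  else stop("unsupported mesh format: ", ext)
}

read_ply <- function(path, role, closed) {
  lines <- readLines(path)
  if (!grepl("^ply", lines[1])) stop("not a PLY file")
  if (!any(grepl("format ascii", lines))) stop("only ASCII PLY supported")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
  hdr_end <- which(lines == "end_header")[1]
  vl <- lines[(hdr_end + 1):(hdr_end + nv)]
  fl <- lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]
  verts <- matrix(scan(text = vl, quiet = TRUE), ncol = length(strsplit(trimws(vl[1]), "\\s+")[[1]]), byrow = TRUE)[, 1:3, drop = FALSE]
  fm <- matrix(scan(text = fl, quiet = TRUE), ncol = 4, byrow = TRUE)
  if (any(fm[, 1] != 3)) stop("non-triangular face in PLY")
  ecgi_mesh(verts, fm[, 2:4] + 1L, role, closed)
}

read_obj <- function(path, role, closed) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  verts <- matrix(scan(text = sub("^v ", "", vl), quiet = TRUE), ncol = 3, byrow = TRUE)
  idx <- lapply(strsplit(sub("^f ", "", fl), "\\s+"), function(tok)
    as.integer(vapply(strsplit(tok, "/"), `[[`, "", 1)))
  if (any(lengths(idx) != 3)) stop("non-triangular face in OBJ")
  ecgi_mesh(verts, do.call(rbind, idx), role, closed)
}

#' Write a triangle mesh to ASCII PLY or OBJ
#'
#' @param mesh an [ecgi_mesh].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(v)),
             "property float x", "property float y", "property float z",
             paste("element face", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    body <- c(apply(v, 1, function(r) paste(format(r, digits = 10), collapse = " ")),
              apply(f - 1L, 1, function(r) paste(c(3L, r), collapse = " ")))
    writeLines(c(hdr, body), path)
  } else if (ext == "obj") {
    writeLines(c(apply(v, 1, function(r) paste("v", paste(format(r, digits = 10), collapse = " "))),
                 apply(f, 1, function(r) paste("f", paste(r, collapse = " ")))), path)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}
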