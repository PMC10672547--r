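#' Closed triangle meshes of segmented tumors
#'
#' A `triangle_mesh` stores an oriented triangulated surface: an `n x 3`
#' numeric matrix of vertex coordinates in millimetres and an `m x 3` integer
#' matrix of 1-based vertex indices per face. It is the container for every
#' surface handled by the package, from STL exports of clinical segmentations
#' to synthetic perturbed spheres.
#'
#' Construction cleans the mesh: vertices closer than `merge_tol` (mm) are
#' merged and faces with (near-)zero area or repeated vertices are dropped,
#' with a warning naming how many were removed. Watertightness (every edge
#' shared by exactly two faces) is assessed once and cached in the
#' `watertight` attribute; enclosed-volume computations refuse meshes that
#' are not watertight.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param clean logical; merge duplicate vertices and drop degenerate faces.
#' @param merge_tol vertices closer than this distance (mm) are merged.
#' @return An object of class `triangle_mesh` with elements `vertices` and
#'   `faces` and attribute `watertight`.
#' @examples
#' cube <- triangle_mesh(
#'   vertices = as.matrix(expand.grid(0:1, 0:1, 0:1)),
#'   faces = rbind(
#'     c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
#'     c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
#'     c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6)
#'   )
#' )
#' mesh_volume(cube) # 1 mm^3
#' @export
triangle_mesh <- function(vertices, faces, clean = TRUE, merge_tol = 1e-6) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns (x, y, z in mm)")
  if (ncol(faces) != 3L) stop("faces must have 3 columns of vertex indices")
  if (nrow(vertices) == 0L || nrow(faces) == 0L) {
    stop("empty mesh: no vertices or no faces")
  }
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of range")
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh")
  if (clean) mesh <- clean_mesh(mesh, merge_tol = merge_tol)
  attr(mesh, "watertight") <- is_watertight(mesh)
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, %s\n",
              nrow(x$vertices), nrow(x$faces),
              if (isTRUE(attr(x, "watertight"))) "watertight"
              else "NOT watertight"))
  invisible(x)
}

# Merge coincident vertices and drop degenerate faces. Merging is by rounding
# coordinates to the merge tolerance, which is exact for STL files where the
# same corner is re-listed per facet.
clean_mesh <- function(mesh, merge_tol = 1e-6) {
  v <- mesh$vertices
  f <- mesh$faces
  key <- paste(round(v[, 1] / merge_tol), round(v[, 2] / merge_tol),
               round(v[, 3] / merge_tol))
  idx <- match(key, key[!duplicated(key)])
  keep <- !duplicated(key)
  v2 <- v[keep, , drop = FALSE]
  f2 <- matrix(idx[f], ncol = 3L)
  degen <- f2[, 1] == f2[, 2] | f2[, 2] == f2[, 3] | f2[, 1] == f2[, 3]
  areas <- triangle_areas(v2, f2)
  degen <- degen | areas <= merge_tol^2
  if (any(degen)) {
    warning(sprintf("dropped %d degenerate (zero-area) face(s)", sum(degen)))
    f2 <- f2[!degen, , drop = FALSE]
  }
  if (nrow(f2) == 0L) stop("mesh has no non-degenerate faces after cleaning")
  used <- sort(unique(as.vector(f2)))
  remap <- integer(nrow(v2))
  remap[used] <- seq_along(used)
  structure(list(vertices = v2[used, , drop = FALSE],
                 faces = matrix(remap[f2], ncol = 3L)),
            class = "triangle_mesh")
}

# Per-face areas (mm^2) via half cross-product magnitude.
triangle_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a
  w <- c - a
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Undirected edge table: for each face edge, a key identifying the vertex pair.
mesh_edge_keys <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2])
  hi <- pmax(e[, 1], e[, 2])
  lo + (hi - 1) * as.double(nrow(mesh$vertices))
}

#' Test whether a mesh is watertight
#'
#' A mesh is watertight (closed) when every undirected edge is shared by
#' exactly two faces. Only watertight meshes have a well-defined enclosed
#' volume.
#'
#' @param mesh a [triangle_mesh()].
#' @return `TRUE` or `FALSE`.
#' @export
is_watertight <- function(mesh) {
  counts <- table(mesh_edge_keys(mesh))
  all(counts == 2L)
}

# Keys of edges not shared by exactly two faces (for error messages).
open_edge_count <- function(mesh) {
  counts <- table(mesh_edge_keys(mesh))
  sum(counts != 2L)
}

#' Enclosed volume of a watertight mesh
#'
#' Sums signed tetrahedron volumes `det(a, b, c) / 6` over all faces
#' (divergence theorem). The absolute value is returned so that a mesh with
#' globally flipped orientation still yields a positive volume; a warning is
#' emitted when the signed sum is negative, since that indicates an
#' inward-facing orientation convention.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @return Enclosed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  if (!isTRUE(attr(mesh, "watertight")) && !is_watertight(mesh)) {
    stop(sprintf("mesh is not watertight (%d edge(s) not shared by exactly 2 faces); volume is undefined",
                 open_edge_count(mesh)))
  }
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  signed <- sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
                a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
                a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
  if (signed < 0) {
    warning("signed volume is negative: mesh orientation appears inward-facing; returning absolute value")
  }
  abs(signed)
}

#' Surface area of a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @return Total surface area in mm^2.
#' @export
mesh_surface_area <- function(mesh) {
  sum(triangle_areas(mesh$vertices, mesh$faces))
}

#' Icosphere: a geodesic approximation to a sphere
#'
#' Starts from a regular icosahedron and repeatedly splits each triangle into
#' four, projecting new vertices back onto the sphere. Used as the reference
#' near-unit-sphericity surface and as the substrate for synthetic tumor
#' shapes.
#'
#' @param radius sphere radius in mm.
#' @param subdivisions number of 4-way subdivision passes (0 gives the raw
#'   icosahedron, 20 faces; each pass multiplies the face count by 4).
#' @param center length-3 numeric, sphere centre in mm.
#' @return A watertight [triangle_mesh()] with outward orientation.
#' @examples
#' s <- icosphere(radius = 10, subdivisions = 3)
#' mesh_volume(s) / (4 / 3 * pi * 10^3) # just under 1
#' @export
icosphere <- function(radius = 1, subdivisions = 4, center = c(0, 0, 0)) {
  stopifnot(radius > 0, subdivisions >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- pmin(e[, 1], e[, 2]) + (pmax(e[, 1], e[, 2]) - 1) * as.double(nv)
    uk <- unique(key)
    mid_id <- nv + match(key, uk)
    first <- match(uk, key)
    mids <- (v[e[first, 1], , drop = FALSE] + v[e[first, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m12 <- mid_id[seq_len(nrow(f))]
    m23 <- mid_id[nrow(f) + seq_len(nrow(f))]
    m31 <- mid_id[2 * nrow(f) + seq_len(nrow(f))]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  v <- v * radius
  v <- sweep(v, 2, center, "+")
  triangle_mesh(v, f, clean = FALSE)
}

# Rigid-transform helpers used by tests and the synthetic-shape generator.
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1) {
  v <- mesh$vertices %*% t(rotation) * scale
  v <- sweep(v, 2, translation, "+")
  triangle_mesh(v, mesh$faces, clean = FALSE)
}
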