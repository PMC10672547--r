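#' Read a mesh from an STL file
#'
#' Reads binary or ASCII STL (the export format of most segmentation
#' software), auto-detecting the variant. STL lists every triangle with its
#' own copies of the corner coordinates, so shared corners are merged on
#' read (tolerance `merge_tol` mm) and degenerate facets dropped; the result
#' carries a cached watertightness flag.
#'
#' @param path path to an `.stl` file.
#' @param merge_tol vertex-merge tolerance in mm.
#' @return A [triangle_mesh()].
#' @export
read_stl <- function(path, merge_tol = 1e-6) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  size <- file.info(path)$size
  if (is.na(size) || size < 15) stop("file too small to be an STL: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", n = min(80, size))
  binary <- FALSE
  if (size >= 84) {
    nfac <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    # a well-formed binary STL has size 84 + 50 * nfacets; files beginning
    # with "solid" can still be binary, so trust the size check
    if (!is.na(nfac) && nfac >= 0 && size == 84 + 50 * as.double(nfac)) {
      binary <- TRUE
    }
  }
  if (binary) {
    tri <- read_stl_binary(con, nfac)
  } else {
    tri <- read_stl_ascii(path)
  }
  if (nrow(tri) == 0L) stop("STL file contains no facets: ", path)
  n <- nrow(tri) / 3L
  faces <- matrix(seq_len(3L * n), ncol = 3L, byrow = TRUE)
  triangle_mesh(tri, faces, clean = TRUE, merge_tol = merge_tol)
}

read_stl_binary <- function(con, nfac) {
  # each facet: 12 float32 (normal + 3 vertices) + uint16 attribute
  rec <- readBin(con, "raw", n = 50 * nfac)
  idx <- rep(seq(0L, length.out = nfac, by = 50L), each = 48L) +
    rep(1:48, times = nfac)
  vals <- readBin(rec[idx], "double", n = 12L * nfac, size = 4,
                  endian = "little")
  m <- matrix(vals, ncol = 12L, byrow = TRUE)
  rbind_vertices <- matrix(t(m[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
  rbind_vertices
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L) {
    stop("malformed ASCII STL (vertex count not a multiple of 3): ", path)
  }
  parts <- strsplit(trimws(vl), "\\s+")
  coords <- vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))
  matrix(t(coords), ncol = 3L)
}

#' Write a mesh to an STL file
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param binary write binary STL (default) or ASCII.
#' @param solid_name name recorded in the ASCII header.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE, solid_name = "mesh") {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  u <- b - a
  w <- c - a
  nx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  ny <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  nz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  len <- sqrt(nx^2 + ny^2 + nz^2)
  len[len == 0] <- 1
  nrm <- cbind(nx, ny, nz) / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    block <- cbind(nrm, a, b, c) # nfac x 12
    nfac <- nrow(f)
    floats <- writeBin(as.numeric(t(block)), raw(), size = 4,
                       endian = "little")
    rec <- raw(50L * nfac)
    pos <- rep(seq(0L, length.out = nfac, by = 50L), each = 48L) +
      rep(1:48, times = nfac)
    rec[pos] <- floats
    writeBin(rec, con)
  } else {
    fmt <- function(x) sprintf("%.9g", x)
    lines <- paste0("solid ", solid_name)
    body <- vapply(seq_len(nrow(f)), function(i) {
      paste0("  facet normal ", paste(fmt(nrm[i, ]), collapse = " "), "\n",
             "    outer loop\n",
             "      vertex ", paste(fmt(a[i, ]), collapse = " "), "\n",
             "      vertex ", paste(fmt(b[i, ]), collapse = " "), "\n",
             "      vertex ", paste(fmt(c[i, ]), collapse = " "), "\n",
             "    endloop\n",
             "  endfacet")
    }, character(1))
    lines <- c(lines, body, paste0("endsolid ", solid_name))
    writeLines(lines, path)
  }
  invisible(path)
}
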