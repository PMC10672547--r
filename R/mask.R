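#' Binary voxel masks of segmented tumors
#'
#' A `voxel_mask` holds a binary segmentation on an axial grid: a 3D array
#' of 0/1 labels, the voxel spacing `(dx, dy, dz)` in mm per axis, and the
#' world position of the centre of voxel `(0, 0, 0)` (0-based indices, axis
#' order x, y, z).
#'
#' @param grid 3D array; values above `level` in [mesh_from_mask()] count as
#'   foreground (logical or 0/1 arrays are typical).
#' @param spacing length-3 positive numeric, mm per voxel along x, y, z.
#' @param origin length-3 numeric, world coordinates (mm) of the first voxel
#'   centre.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(grid)) != 3L) stop("grid must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive values (mm)")
  }
  storage.mode(grid) <- "double"
  structure(list(grid = grid, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("voxel_mask: %s grid, spacing %s mm, %d foreground voxel(s)\n",
              paste(dim(x$grid), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              sum(x$grid > 0.5)))
  invisible(x)
}

#' Read a binary mask from a NIfTI file
#'
#' Voxel spacing is taken from the NIfTI header (`pixdim`); values above
#' `threshold` become foreground.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param threshold binarization threshold applied to the stored intensities.
#' @return A [voxel_mask()].
#' @export
read_nifti_mask <- function(path, threshold = 0.5) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)
  if (length(spacing) < 3L) stop("NIfTI header lacks 3D pixel dimensions")
  arr <- as.array(img)
  if (length(dim(arr)) > 3L) arr <- arr[, , , 1]
  voxel_mask((arr > threshold) * 1, spacing = spacing[1:3])
}

#' Foreground volume by voxel counting
#'
#' The simple volume estimate: number of foreground voxels times the voxel
#' volume. Serves as an independent check on the mesh-based volume.
#'
#' @param mask a [voxel_mask()].
#' @param level foreground threshold.
#' @return Volume in mm^3.
#' @export
mask_voxel_volume <- function(mask, level = 0.5) {
  sum(mask$grid > level) * prod(mask$spacing)
}

#' Extract a surface mesh from a binary mask
#'
#' Builds the `level` iso-surface of the zero-padded binary field by
#' marching tetrahedra: each grid cell is split into six tetrahedra (a
#' consistent Kuhn triangulation of space, so the result is watertight by
#' construction), and the iso-surface is interpolated along tetrahedron
#' edges. Iso-surfacing the raw 0/1 field produces a faceted staircase
#' whose surface area substantially overestimates the true tumor surface,
#' so by default the binary field is first smoothed with an isotropic
#' Gaussian of `presmooth_sigma` voxels; the 0.5 level set of the smoothed
#' occupancy field tracks the true boundary closely in both volume and
#' area. Vertex coordinates are scaled by the voxel spacing into mm.
#'
#' When the foreground is so small that smoothing leaves no value above the
#' iso-level (e.g. an isolated voxel), the raw binary field is used instead
#' and a message is emitted. Under that fallback a single foreground voxel
#' with unit spacing yields a small watertight solid of volume 0.5 mm^3
#' (the Kuhn-tetrahedra mid-edge iso-surface convention); this convention
#' is pinned by a regression test.
#'
#' @param mask a [voxel_mask()].
#' @param level iso-level in the (smoothed) occupancy field, default 0.5.
#' @param presmooth_sigma Gaussian sigma in voxels applied to the binary
#'   field before extraction; `0` disables smoothing.
#' @return A watertight [triangle_mesh()] in mm coordinates.
#' @examples
#' g <- array(0, c(16, 16, 16))
#' cc <- 8.5
#' idx <- which(outer(outer((1:16 - cc)^2, (1:16 - cc)^2, "+"),
#'                    (1:16 - cc)^2, "+") <= 5^2)
#' g[idx] <- 1
#' m <- mesh_from_mask(voxel_mask(g))
#' mesh_volume(m) / (4 / 3 * pi * 5^3)
#' @export
mesh_from_mask <- function(mask, level = 0.5, presmooth_sigma = 1) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!any(mask$grid > level)) {
    stop("mask has no foreground voxels above the iso-level")
  }
  d <- dim(mask$grid)
  pad <- max(1L, as.integer(ceiling(3 * presmooth_sigma)) + 1L)
  vol <- array(0, d + 2L * pad)
  vol[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    mask$grid
  field <- vol
  if (presmooth_sigma > 0) {
    field <- gaussian_smooth_3d(vol, presmooth_sigma)
    if (!any(field > level)) {
      message("foreground too small for Gaussian pre-smoothing; extracting from the raw binary field")
      field <- vol
    }
  }
  surf <- marching_tetrahedra(field, level)
  # padded voxel (pad, pad, pad) in 0-based coords is the original (0,0,0)
  v <- sweep(sweep(surf$vertices - pad, 2, mask$spacing, "*"), 2,
             mask$origin, "+")
  mesh <- triangle_mesh(v, surf$faces, clean = FALSE)
  attr(mesh, "watertight") <- is_watertight(mesh)
  mesh
}

# Separable Gaussian smoothing of a 3D array (zero boundary), sigma in
# voxels; kernel truncated at 3 sigma and renormalised.
gaussian_smooth_3d <- function(a, sigma) {
  r <- as.integer(ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv1 <- function(x) { # along dim 1
    d <- dim(x)
    m <- matrix(x, d[1], d[2] * d[3])
    mp <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    out <- stats::filter(mp, k, sides = 2)
    array(out[(r + 1):(r + d[1]), , drop = FALSE], d)
  }
  a <- conv1(a)
  a <- aperm(conv1(aperm(a, c(2, 3, 1))), c(3, 1, 2))
  aperm(conv1(aperm(a, c(3, 1, 2))), c(2, 3, 1))
}

# Iso-surface of a 3D scalar field by marching tetrahedra on the Kuhn
# 6-tetrahedron cell decomposition. Returns vertices in 0-based voxel
# coordinates and consistently outward-oriented faces.
marching_tetrahedra <- function(vol, level) {
  d <- dim(vol)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  nxny <- as.double(nx) * ny
  inside <- as.vector(vol > level)
  # cell base corner = voxel (i,j,k), cells span i<nx, j<ny, k<nz
  base <- as.vector(outer(outer(seq_len(nx - 1),
                                (seq_len(ny - 1) - 1) * nx, "+"),
                          (seq_len(nz - 1) - 1) * nxny, "+"))
  # corner order: (0,0,0) (1,0,0) (1,1,0) (0,1,0) (0,0,1) (1,0,1) (1,1,1) (0,1,1)
  coff <- c(0, 1, 1 + nx, nx, nxny, 1 + nxny, 1 + nx + nxny, nx + nxny)
  s <- integer(length(base))
  for (o in coff) s <- s + inside[base + o]
  base <- base[s > 0L & s < 8L]
  if (length(base) == 0L) stop("iso-surface is empty at this level")
  # Kuhn tetrahedra around the cell diagonal (0,0,0)-(1,1,1)
  tets <- rbind(c(0, 1, 2, 6), c(0, 2, 3, 6), c(0, 3, 7, 6),
                c(0, 7, 4, 6), c(0, 4, 5, 6), c(0, 5, 1, 6)) + 1L
  ti <- do.call(rbind, lapply(seq_len(6), function(t) {
    cbind(base + coff[tets[t, 1]], base + coff[tets[t, 2]],
          base + coff[tets[t, 3]], base + coff[tets[t, 4]])
  }))
  ins <- matrix(inside[ti], ncol = 4L)
  nin <- rowSums(ins)
  mixed <- nin > 0L & nin < 4L
  ti <- ti[mixed, , drop = FALSE]
  ins <- ins[mixed, , drop = FALSE]
  nin <- nin[mixed]
  # reorder each tetrahedron's corners: inside corners first (stable)
  ord <- t(apply(!ins, 1, order))
  ti <- matrix(ti[cbind(rep(seq_len(nrow(ti)), 4L), as.vector(ord))],
               ncol = 4L)

  vals <- matrix(vol[ti], ncol = 4L)
  pos <- function(li) { # linear index -> 0-based (x, y, z)
    i0 <- li - 1
    cbind(i0 %% nx, (i0 %/% nx) %% ny, i0 %/% nxny)
  }
  interp <- function(p, q) { # edge keys + interpolated points
    vp <- vol[p]; vq <- vol[q]
    t <- (level - vp) / (vq - vp)
    list(key = pmin(p, q) + (pmax(p, q) - 1) * (nxny * nz),
         pt = pos(p) + t * (pos(q) - pos(p)))
  }
  tri_key <- list(); tri_pt <- list(); refs <- list(); k <- 0L
  add_tris <- function(e1, e2, e3, ref) {
    k <<- k + 1L
    tri_key[[k]] <<- cbind(e1$key, e2$key, e3$key)
    tri_pt[[k]] <<- cbind(e1$pt, e2$pt, e3$pt)
    refs[[k]] <<- ref
  }
  g1 <- nin == 1L
  if (any(g1)) {
    a <- ti[g1, 1]; b <- ti[g1, 2]; cc <- ti[g1, 3]; dd <- ti[g1, 4]
    add_tris(interp(a, b), interp(a, cc), interp(a, dd),
             (pos(b) + pos(cc) + pos(dd)) / 3 - pos(a))
  }
  g3 <- nin == 3L
  if (any(g3)) {
    a <- ti[g3, 1]; b <- ti[g3, 2]; cc <- ti[g3, 3]; dd <- ti[g3, 4]
    add_tris(interp(dd, a), interp(dd, b), interp(dd, cc),
             pos(dd) - (pos(a) + pos(b) + pos(cc)) / 3)
  }
  g2 <- nin == 2L
  if (any(g2)) {
    a <- ti[g2, 1]; b <- ti[g2, 2]; cc <- ti[g2, 3]; dd <- ti[g2, 4]
    ref <- (pos(cc) + pos(dd)) / 2 - (pos(a) + pos(b)) / 2
    eac <- interp(a, cc); ead <- interp(a, dd)
    ebd <- interp(b, dd); ebc <- interp(b, cc)
    add_tris(eac, ead, ebd, ref)
    add_tris(eac, ebd, ebc, ref)
  }
  keys <- do.call(rbind, tri_key)
  pts <- do.call(rbind, tri_pt) # columns: p1(xyz) p2(xyz) p3(xyz)
  ref <- do.call(rbind, refs)
  # orient so the normal points from inside to outside
  u <- pts[, 4:6, drop = FALSE] - pts[, 1:3, drop = FALSE]
  w <- pts[, 7:9, drop = FALSE] - pts[, 1:3, drop = FALSE]
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  flip <- rowSums(nrm * ref) < 0
  tmp <- keys[flip, 2]
  keys[flip, 2] <- keys[flip, 3]
  keys[flip, 3] <- tmp
  tmpp <- pts[flip, 4:6, drop = FALSE]
  pts[flip, 4:6] <- pts[flip, 7:9, drop = FALSE]
  pts[flip, 7:9] <- tmpp
  # weld vertices shared between tetrahedra via their edge keys
  allk <- as.vector(t(keys))
  uk <- unique(allk)
  fidx <- matrix(match(allk, uk), ncol = 3L, byrow = TRUE)
  allp <- matrix(NA_real_, nrow(keys) * 3L, 3L)
  allp[seq(1, by = 3, length.out = nrow(keys)), ] <- pts[, 1:3]
  allp[seq(2, by = 3, length.out = nrow(keys)), ] <- pts[, 4:6]
  allp[seq(3, by = 3, length.out = nrow(keys)), ] <- pts[, 7:9]
  verts <- allp[match(uk, allk), , drop = FALSE]
  list(vertices = verts, faces = fidx)
}

#' Taubin mesh smoothing
#'
#' Alternating shrink/inflate Laplacian passes (`lambda` then `mu` per
#' iteration) with uniform weights. Unlike plain Laplacian smoothing this
#' does not systematically shrink the surface, so enclosed volume is
#' approximately preserved while high-frequency faceting (e.g. the voxel
#' staircase of an iso-surface extracted from binary data) is removed.
#'
#' @param mesh a [triangle_mesh()].
#' @param iterations number of lambda/mu pass pairs.
#' @param lambda positive smoothing step.
#' @param mu negative inflation step, `|mu| > lambda`.
#' @return The smoothed [triangle_mesh()] (same topology).
#' @export
taubin_smooth <- function(mesh, iterations = 10, lambda = 0.5, mu = -0.53) {
  v <- mesh$vertices
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  deg <- tabulate(e[, 1], nbins = nrow(v))
  has <- deg > 0
  for (it in seq_len(iterations)) {
    for (fac in c(lambda, mu)) {
      s <- rowsum(v[e[, 2], , drop = FALSE], e[, 1], reorder = TRUE)
      ids <- as.integer(rownames(s))
      avg <- v
      avg[ids, ] <- s / deg[ids]
      v[has, ] <- v[has, ] + fac * (avg[has, ] - v[has, ])
    }
  }
  out <- triangle_mesh(v, f, clean = FALSE)
  attr(out, "watertight") <- attr(mesh, "watertight")
  out
}
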