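#' Wadell sphericity
#'
#' Sphericity of a solid with volume `V_p` and surface area `A_p`:
#'
#' \deqn{S = \frac{\pi^{1/3} (6 V_p)^{2/3}}{A_p}}
#'
#' i.e. the surface area of the sphere having the same volume as the
#' particle, divided by the particle's own surface area. A perfect sphere
#' has `S = 1`; by the isoperimetric inequality every other closed surface
#' has `S < 1`, so lower values indicate a more irregular (less sphere-like)
#' tumor surface. `S` is dimensionless and invariant under uniform scaling,
#' i.e. `sphericity(k^3 * V, k^2 * A) == sphericity(V, A)`.
#'
#' @param volume particle volume `V_p` (any unit, e.g. mm^3), must be > 0.
#' @param area particle surface area `A_p` in the matching squared unit,
#'   must be > 0.
#' @return Sphericity in (0, 1] (up to floating point; tessellated spheres
#'   approach 1 from below).
#' @examples
#' sphericity(4 / 3 * pi * 5^3, 4 * pi * 5^2) # sphere: exactly 1
#' sphericity(1, 6)                           # unit cube: ~0.806
#' @export
sphericity <- function(volume, area) {
  if (any(!is.finite(volume)) || any(!is.finite(area))) {
    stop("volume and area must be finite")
  }
  if (any(volume <= 0)) stop("volume must be positive")
  if (any(area <= 0)) stop("area must be positive")
  pi^(1 / 3) * (6 * volume)^(2 / 3) / area
}

#' Tumor morphometrics from a mesh
#'
#' Computes the three shape descriptors used throughout the prognosis
#' analysis: tumor volume `Vt` (reported in cm^3 as in clinical tables),
#' surface area (cm^2), and tumor sphericity `St`. Mesh coordinates are
#' assumed to be in mm; the conversion to cm^3 divides the mm^3 volume by
#' 1000.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @return A list of class `morphometrics` with elements `Vt_cm3`,
#'   `area_cm2`, `St`, plus the raw `volume_mm3` and `area_mm2`.
#' @examples
#' mesh_morphometrics(icosphere(radius = 10, subdivisions = 3))
#' @export
mesh_morphometrics <- function(mesh) {
  vol_mm3 <- mesh_volume(mesh)
  area_mm2 <- mesh_surface_area(mesh)
  structure(list(
    Vt_cm3 = vol_mm3 / 1000,
    area_cm2 = area_mm2 / 100,
    St = sphericity(vol_mm3, area_mm2),
    volume_mm3 = vol_mm3,
    area_mm2 = area_mm2
  ), class = "morphometrics")
}

#' @export
print.morphometrics <- function(x, ...) {
  cat(sprintf("tumor morphometrics: Vt = %.3f cm^3, area = %.3f cm^2, St = %.4f\n",
              x$Vt_cm3, x$area_cm2, x$St))
  invisible(x)
}

#' Morphometrics for a directory of STL meshes
#'
#' Applies [mesh_morphometrics()] to every `.stl` file in a directory, one
#' tumor per file, file name (without extension) taken as the patient id.
#' Per-file failures (unreadable files, non-watertight surfaces) are
#' collected rather than aborting the batch.
#'
#' @param dir directory containing `.stl` files.
#' @return A data frame with columns `id`, `Vt_cm3`, `area_cm2`, `St`, and
#'   attribute `failures`, a data frame of `id` and `reason` for meshes that
#'   could not be measured.
#' @export
morphometrics_from_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.stl$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) stop("no .stl files found in ", dir)
  ids <- sub("\\.stl$", "", basename(files), ignore.case = TRUE)
  rows <- vector("list", length(files))
  fail <- character(0)
  fail_ids <- character(0)
  for (i in seq_along(files)) {
    res <- tryCatch({
      m <- suppressWarnings(read_stl(files[i]))
      mm <- mesh_morphometrics(m)
      data.frame(id = ids[i], Vt_cm3 = mm$Vt_cm3, area_cm2 = mm$area_cm2,
                 St = mm$St)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      fail <- c(fail, res)
      fail_ids <- c(fail_ids, ids[i])
    } else {
      rows[[i]] <- res
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(id = character(0), Vt_cm3 = numeric(0),
                      area_cm2 = numeric(0), St = numeric(0))
  }
  attr(out, "failures") <- data.frame(id = fail_ids, reason = fail)
  out
}
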