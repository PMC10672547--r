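# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a tumor-like synthetic mesh with controllable irregularity
#'
#' Produces a watertight closed surface by radially perturbing a unit
#' icosphere with band-limited angular noise, then rescaling isotropically
#' so the enclosed volume matches `target_volume_cm3` exactly. The noise
#' field is a sum of `harmonic_order` cosine lobes around random directions
#' with angular wavenumbers 1..`harmonic_order`, normalised to unit peak
#' amplitude, so `amplitude` is the maximum relative radial excursion:
#' `amplitude = 0` yields an unperturbed sphere (sphericity near 1), larger
#' amplitudes give increasingly irregular, lower-sphericity surfaces.
#' The same seed always reproduces the same mesh.
#'
#' @param target_volume_cm3 enclosed volume of the result, in cm^3.
#' @param amplitude relative radial perturbation amplitude, in `[0, 1)`
#'   (at 1 the radius would touch zero).
#' @param harmonic_order number of angular noise lobes (wavenumbers
#'   1..order); 0 disables perturbation.
#' @param seed RNG seed for the noise field.
#' @param subdivisions icosphere subdivision level (resolution).
#' @return A watertight [triangle_mesh()] in mm coordinates, centred at the
#'   origin.
#' @examples
#' m <- generate_tumor_mesh(target_volume_cm3 = 13.6, amplitude = 0.3,
#'                          seed = 7)
#' mesh_morphometrics(m)
#' @export
generate_tumor_mesh <- function(target_volume_cm3 = 13.6, amplitude = 0.3,
                                harmonic_order = 4, seed = 1,
                                subdivisions = 4) {
  stopifnot(target_volume_cm3 > 0, harmonic_order >= 0, subdivisions >= 0)
  if (amplitude < 0 || amplitude >= 1) {
    stop("amplitude must be in [0, 1): at 1 the perturbed radius reaches 0")
  }
  base <- icosphere(radius = 1, subdivisions = subdivisions)
  u <- base$vertices / sqrt(rowSums(base$vertices^2))
  if (amplitude > 0 && harmonic_order > 0) {
    f <- with_seed(seed, {
      acc <- numeric(nrow(u))
      for (l in seq_len(harmonic_order)) {
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        a <- stats::rnorm(1)
        phase <- stats::runif(1, 0, 2 * pi)
        ang <- acos(pmin(1, pmax(-1, u %*% dir)))
        acc <- acc + a * cos(l * ang + phase)
      }
      acc
    })
    f <- f / max(abs(f))
    radius <- 1 + amplitude * as.vector(f)
  } else {
    radius <- rep(1, nrow(u))
  }
  v <- u * radius
  mesh <- triangle_mesh(v, base$faces, clean = FALSE)
  vol <- mesh_volume(mesh)
  scale <- (target_volume_cm3 * 1000 / vol)^(1 / 3)
  out <- transform_mesh(mesh, scale = scale)
  attr(out, "watertight") <- TRUE
  out
}
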