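# Analog Monte Carlo photon transport with fluorescence conversion.
#
# Physics assumptions (matched to the analytic model's regime): isotropic
# elastic scattering, unit fluorescence quantum yield, delta-function
# absorption/emission spectra (two discrete wavelengths), no reabsorption of
# the emitted light by the fluorophore, index-matched boundaries (no
# refraction or internal reflection).  Transport is analog (unweighted):
# every interaction either absorbs, scatters, or converts the photon.

#' Propagate photons through a phantom
#'
#' Tracks `N` photons from a collimated source on the sample surface.  Free
#' paths are sampled exactly against the piecewise-constant voxel grids; at
#' each interaction the channel is chosen proportionally to the local
#' coefficients (intrinsic absorption, elastic scattering, and - at the
#' excitation wavelength - absorption by the fluorophore followed by
#' isotropic re-emission at the fluorescence wavelength).  Photons exiting
#' the cuboid are recorded as surface hits.
#'
#' @param phantom a [build_phantom()] result.
#' @param position length-3 source position (x, y, z) in mm, on a face.
#' @param direction length-3 illumination direction (normalized internally).
#' @param N number of photons (positive integer).
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   that each source can carry an independent, reproducible stream.
#' @param record_excitation also record photons exiting at the excitation
#'   wavelength (default records fluorescence hits only).
#' @param record_axes optional 3 x m matrix of unit axes: fluorescence hits
#'   are recorded only if their exit direction lies within `record_beta` of
#'   some axis (a memory filter for large runs; tallies are unaffected).
#' @param record_beta half-angle (radians) for `record_axes`.
#' @param max_hits cap on stored hits (excess hits set an `overflow` flag).
#' @return A list of class `"brt_hits"`: `hits` matrix with columns
#'   x, y, z, dx, dy, dz, tag (0 excitation / 1 fluorescence), tallies
#'   `absorbed`, `exited_excitation`, `exited_fluorescence`, `converted`,
#'   and the photon count `N`.  Photon conservation holds exactly:
#'   `absorbed + exited_excitation + exited_fluorescence == N`.
#' @export
mc_propagate <- function(phantom, position, direction, N, seed = NULL,
                         record_excitation = FALSE,
                         record_axes = NULL, record_beta = NULL,
                         max_hits = 5e6) {
  if (!is.numeric(N) || length(N) != 1 || N < 1) stop("N must be a positive count")
  if (!is.null(seed)) set.seed(seed)
  d <- as.numeric(direction); d <- d / sqrt(sum(d^2))
  if (is.null(record_axes)) {
    axes <- matrix(numeric(), nrow = 3, ncol = 0)
    cmin <- -1
  } else {
    axes <- apply(record_axes, 2, function(v) v / sqrt(sum(v^2)))
    axes <- matrix(axes, nrow = 3)
    cmin <- cos(if (is.null(record_beta)) pi else record_beta)
  }
  sp <- phantom$spec
  res <- cpp_mc_propagate(phantom$mu_a_e, phantom$mu_s_e,
                          phantom$n * sp$sigma_e,
                          phantom$mu_a_f, phantom$mu_s_f,
                          as.integer(phantom$dims), phantom$pitch,
                          as.numeric(position), d,
                          as.numeric(N), isTRUE(record_excitation),
                          axes, cmin, max_hits)
  res$N <- N
  res$position <- as.numeric(position)
  res$direction <- d
  class(res) <- "brt_hits"
  res
}

#' @export
print.brt_hits <- function(x, ...) {
  cat(sprintf("Monte Carlo run: N = %g photons\n", x$N))
  cat(sprintf("  absorbed %g | exited (excitation) %g | exited (fluorescence) %g | conversions %g\n",
              x$absorbed, x$exited_excitation, x$exited_fluorescence, x$converted))
  cat(sprintf("  recorded hits: %d%s\n", nrow(x$hits),
              if (isTRUE(x$overflow)) " (storage cap reached)" else ""))
  invisible(x)
}

#' Score surface hits with an angularly selective detector
#'
#' Sums `eta0 * (s_k . s_j) * E_f` over fluorescence hits that fall in the
#' scoring region (the projection of the detector onto the sample surface)
#' and whose exit direction lies within the acceptance cone of half-angle
#' beta about the collimation direction.
#'
#' @param hits a [mc_propagate()] result.
#' @param detector a [detector_spec()].
#' @param r_d detector centre in slice coordinates (y, z); z selects the
#'   face (0 or Lz).
#' @param s_k outward collimation direction in the slice plane (y, z).
#' @param x_center centre of the scoring region along x (mm).
#' @param constants a [beam_constants()].
#' @return Scalar `deltaW` (0 when no hit is accepted), with attributes
#'   `count` (accepted hits) and `region` (scoring extents).
#' @export
mc_score <- function(hits, detector, r_d, s_k, x_center,
                     constants = beam_constants()) {
  H <- hits$hits
  s_k <- unit2(s_k)
  cos_alpha <- abs(s_k[2])
  w_in <- if (detector$scoring_mode == "same-detector") {
    if (cos_alpha < 1e-6) stop("collimation direction parallel to the surface")
    detector$delta_d / cos_alpha
  } else detector$delta_d
  if (nrow(H) == 0)
    return(structure(0, count = 0L, region = c(w_in = w_in)))
  face_z <- r_d[2]
  tol <- 1e-9 # scoring-region edge tolerance in mm
  sel <- H[, "tag"] == 1 &
    abs(H[, "z"] - face_z) < 1e-6 &
    abs(H[, "x"] - x_center) <= detector$delta_d / 2 + tol &
    abs(H[, "y"] - r_d[1]) <= w_in / 2 + tol
  if (!any(sel))
    return(structure(0, count = 0L, region = c(w_in = w_in)))
  D <- H[sel, , drop = FALSE]
  # full 3D angle to the collimation axis (axis has no x-component)
  cosang <- D[, "dy"] * s_k[1] + D[, "dz"] * s_k[2]
  acc <- cosang >= cos(detector$beta)
  dW <- detector$eta0 * constants$E_f * sum(cosang[acc])
  structure(dW, count = sum(acc), region = c(w_in = w_in))
}
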