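# Noise-free single-scattering forward model.
#
# The detected signal for a source at r_s illuminating along s_l and a
# finite detector at r_d collimated along s_k is, at vertex-ray fidelity,
#   deltaW = eta0 W/(2 pi sigma) * f_bar * n_tilde(R) *
#            exp(-int_leg1 mu_e - int_leg2 mu_f),
# with R the broken-ray vertex and f_bar the finite-detector geometric
# factor.  Absolute constants never matter downstream: the attenuation
# reconstruction differentiates the log-signal and the concentration is
# max-normalized, so the defaults are all 1.

#' Physical constants of the forward model
#'
#' @param W source power per unit area.
#' @param eta0 detector sensitivity constant.
#' @param sigma fluorophore absorption cross-section (same sigma that enters
#'   the phantom's total attenuation).
#' @param E_f energy of a fluorescence photon (Monte Carlo scoring unit).
#' @return List of class `"brt_constants"`.
#' @export
beam_constants <- function(W = 1, eta0 = 1, sigma = 1, E_f = 1) {
  stopifnot(W > 0, eta0 > 0, sigma > 0, E_f > 0)
  structure(list(W = W, eta0 = eta0, sigma = sigma, E_f = E_f),
            class = "brt_constants")
}

#' Line integral of a slice map along a ray
#'
#' Exact voxel-walk traversal (chord length times voxel value, accumulated to
#' the exit point or to `length`).
#'
#' @param map matrix (rows z, cols y) of a per-mm coefficient.
#' @param pitch voxel pitch in mm.
#' @param start length-2 point (y, z) inside or on the grid boundary.
#' @param direction length-2 direction (normalized internally).
#' @param length optional truncation length in mm (default: to the boundary).
#' @return The integral (dimensionless optical depth).
#' @export
ray_integral <- function(map, pitch, start, direction, length = Inf) {
  d <- unit2(direction)
  cpp_ray_integral(map, pitch, start[1], start[2], d[1], d[2], length)
}

# vectorized internal version; starts (n x 2), all rays share direction u
ray_integrals_dir <- function(map, pitch, starts, u, tmax) {
  n <- nrow(starts)
  dirs <- matrix(rep(u, each = n), ncol = 2)
  cpp_ray_integrals(map, pitch, starts, dirs, rep_len(tmax, n))
}

# n_tilde value at a point (nearest-voxel lookup)
slice_lookup <- function(map, pitch, y, z) {
  iy <- clamp_idx(as.integer(floor(y / pitch)) + 1L, ncol(map))
  iz <- clamp_idx(as.integer(floor(z / pitch)) + 1L, nrow(map))
  map[cbind(iz, iy)]
}

#' Single-scattering detector signal (vertex-ray fidelity)
#'
#' The default data generator: the broken ray through the detector centre
#' defines the vertex; attenuation is integrated along its two legs.
#'
#' @param slice a `"brt_slice"` (see [extract_slice()]).
#' @param r_s,s_l source position (on a face, slice coordinates) and
#'   illumination direction.
#' @param r_d,s_k detector centre and outward collimation direction.
#' @param detector a [detector_spec()].
#' @param constants a [beam_constants()].
#' @param fbar the finite-detector geometric factor; `NULL` computes it by
#'   quadrature ([geom_factor_bar()]).  Pass 1 when only the data function
#'   (in which f_bar cancels) is needed.
#' @param x_mode out-of-plane treatment for the computed geometric factor,
#'   see [geom_factor_bar()]; `"cone"` is the right choice when comparing
#'   against 3D Monte Carlo scoring.
#' @return List of class `"brt_signal"`: `deltaW`, `fbar`, the broken `ray`
#'   and a `valid` flag (FALSE when the vertex falls outside the sample).
#' @export
signal_single_scatter <- function(slice, r_s, s_l, r_d, s_k, detector,
                                  constants = beam_constants(), fbar = NULL,
                                  x_mode = c("collapsed", "cone")) {
  x_mode <- match.arg(x_mode)
  br <- broken_ray(r_s, s_l, r_d, s_k, c(slice$Ly, slice$Lz))
  if (!br$valid)
    return(structure(list(deltaW = NA_real_, fbar = NA_real_, ray = br,
                          valid = FALSE), class = "brt_signal"))
  if (is.null(fbar))
    fbar <- geom_factor_bar(detector, r_d, s_k, r_s, s_l,
                            x_mode = x_mode, rho = br$L2)
  nt <- slice_lookup(slice$n_tilde, slice$pitch, br$R[1], br$R[2])
  Ie <- ray_integral(slice$mu_e, slice$pitch, r_s, s_l, br$L1)
  If <- ray_integral(slice$mu_f, slice$pitch, br$R, s_k, br$L2)
  C0 <- constants$eta0 * constants$W / (2 * pi * constants$sigma)
  structure(list(deltaW = C0 * fbar * nt * exp(-(Ie + If)),
                 fbar = fbar, ray = br, valid = TRUE,
                 leg_integrals = c(mu_e = Ie, mu_f = If)),
            class = "brt_signal")
}

#' Area- and angle-integrated detector signal
#'
#' Higher-fidelity validation signal: integrates the single-scattered
#' intensity over the scoring region and over the angular acceptance window
#' at each scoring point, with the vertex recomputed per observation
#' direction.  Converges to [signal_single_scatter()] for small detectors and
#' acceptance angles; the discrepancy grows near the detector face, where the
#' vertex-ray approximation degrades.
#'
#' @inheritParams signal_single_scatter
#' @param nq in-plane quadrature nodes over the scoring region.
#' @param ntheta quadrature nodes over the angular window.
#' @return Scalar signal `deltaW`.
#' @export
signal_area_integrated <- function(slice, r_s, s_l, r_d, s_k, detector,
                                   constants = beam_constants(),
                                   nq = 31, ntheta = 101) {
  s_l <- unit2(s_l); s_k <- unit2(s_k)
  cos_alpha <- abs(s_k[2])
  w_in <- if (detector$scoring_mode == "same-detector")
    detector$delta_d / cos_alpha else detector$delta_d
  ys <- r_d[1] + w_in * ((seq_len(nq) - 0.5) / nq - 0.5)
  C0 <- constants$eta0 * constants$W / (2 * pi * constants$sigma)
  box <- c(slice$Ly, slice$Lz)
  total <- 0
  for (y in ys) {
    r <- c(y, r_d[2])
    wp <- window_pieces(r, r_s, s_l, s_k, detector$beta)
    if (!nrow(wp$pieces)) next
    st <- sin(wp$theta_l)
    if (st < 1e-9) next
    for (p in seq_len(nrow(wp$pieces))) {
      lo <- wp$pieces[p, 1]; hi <- wp$pieces[p, 2]
      dth <- (hi - lo) / ntheta
      deltas <- lo + (seq_len(ntheta) - 0.5) * dth
      for (dd in deltas) {
        psi <- wp$A + dd
        s <- c(cos(psi), sin(psi))             # photon travel direction at r
        vr <- tryCatch(ray_vertex(r_s, s_l, r, s), error = function(e) NULL)
        if (is.null(vr) || vr$t < 0 || vr$u < 0) next
        Rp <- vr$point
        if (Rp[1] < 0 || Rp[1] > box[1] || Rp[2] < 0 || Rp[2] > box[2]) next
        nt <- slice_lookup(slice$n_tilde, slice$pitch, Rp[1], Rp[2])
        if (nt <= 0) next
        Ie <- ray_integral(slice$mu_e, slice$pitch, r_s, s_l, vr$t)
        If <- ray_integral(slice$mu_f, slice$pitch, Rp, s, vr$u)
        total <- total + nt * exp(-(Ie + If)) * dth / (wp$dist * st)
      }
    }
  }
  C0 * detector$delta_d * (w_in / nq) * total
}
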