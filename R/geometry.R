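# Broken-ray geometry in the slice plane (y, z).
#
# Conventions: z increases into the sample from the illuminated face z = 0;
# the opposite face is z = Lz.  The three fixed scan directions are stored as
# unit vectors pointing FROM the vertex TOWARD the source/detector positions
# (the u_l of the inversion formulas).  Direction 1 is normal to the
# illuminated surface, so u_1 = (0, -1).  Low-level functions take angles in
# radians; user-facing detector specifications use degrees.

#' The three fixed scan directions
#'
#' For the transmission scan the two oblique directions make +/-45 degrees
#' with the surface normal and point toward the far face (sources and
#' detectors face each other across the slab); for the backscattering scan
#' they make 45 and -70 degrees and point back toward the illuminated face.
#'
#' @param scan_type `"transmission"` or `"backscattering"`.
#' @return A list of class `"brt_directions"`: `u` is a 2 x 3 matrix of
#'   from-vertex unit vectors (rows y, z), `angles_deg` the line angles to
#'   the surface normal.
#' @export
scan_directions <- function(scan_type = c("transmission", "backscattering")) {
  scan_type <- match.arg(scan_type)
  if (scan_type == "transmission") {
    ang <- c(0, 45, -45)
    u <- cbind(c(0, -1),
               c(sin(deg2rad(45)),  cos(deg2rad(45))),
               c(sin(deg2rad(-45)), cos(deg2rad(-45))))
  } else {
    ang <- c(0, 45, -70)
    u <- cbind(c(0, -1),
               c(sin(deg2rad(45)),  -cos(deg2rad(45))),
               c(sin(deg2rad(-70)), -cos(deg2rad(-70))))
  }
  structure(list(u = u, angles_deg = ang, scan_type = scan_type),
            class = "brt_directions")
}

#' @export
print.brt_directions <- function(x, ...) {
  cat(sprintf("%s scan directions (from-vertex unit vectors):\n", x$scan_type))
  m <- round(x$u, 4); dimnames(m) <- list(c("y", "z"), paste0("u", 1:3))
  print(m)
  invisible(x)
}

#' Angularly selective detector specification
#'
#' @param delta_d detector side (mm) of the square detector area.
#' @param beta_deg acceptance half-angle in degrees (0 < beta < 90).
#' @param eta0 detector sensitivity constant.
#' @param scoring_mode `"same-detector"`: photons are scored on the
#'   projection of the tilted detector onto the sample surface (a rectangle
#'   `delta_d` by `delta_d / cos(alpha)`); `"per-direction-square"`: scored on
#'   a fixed square of side `delta_d` for every direction.
#' @return A list of class `"brt_detector"`.
#' @export
detector_spec <- function(delta_d, beta_deg, eta0 = 1,
                          scoring_mode = c("same-detector", "per-direction-square")) {
  scoring_mode <- match.arg(scoring_mode)
  stopifnot_scalar(delta_d, "delta_d", positive = TRUE)
  stopifnot_scalar(beta_deg, "beta_deg")
  if (beta_deg <= 0 || beta_deg >= 90) stop("beta must lie in (0, 90) degrees")
  structure(list(delta_d = delta_d, beta_deg = beta_deg,
                 beta = deg2rad(beta_deg), eta0 = eta0,
                 scoring_mode = scoring_mode),
            class = "brt_detector")
}

#' Vertex of a broken ray
#'
#' Intersection of the source ray `r_s + t s_l` (t >= 0) with the detector
#' line of sight `r_d - u s_k` (u >= 0), where `s_l` is the illumination
#' direction and `s_k` the outward collimation direction.
#'
#' @param r_s,s_l source position and direction (length-2, slice plane).
#' @param r_d,s_k detector position and collimation direction.
#' @return List with `point` (the vertex), `t` (distance from the source) and
#'   `u` (distance to the detector).  Errors if the lines are parallel.
#' @export
ray_vertex <- function(r_s, s_l, r_d, s_k) {
  s_l <- unit2(s_l); s_k <- unit2(s_k)
  b <- r_d - r_s
  det <- s_l[1] * s_k[2] - s_l[2] * s_k[1]
  if (abs(det) < 1e-12) stop("degenerate geometry: source ray and detector line of sight are parallel")
  tt <- (b[1] * s_k[2] - b[2] * s_k[1]) / det
  uu <- (s_l[1] * b[2] - s_l[2] * b[1]) / det
  list(point = r_s + tt * s_l, t = tt, u = uu)
}

#' Construct a broken ray from a source-detector pair
#'
#' @inheritParams ray_vertex
#' @param sample_box extents `c(Ly, Lz)` of the slice (mm); the vertex must
#'   lie inside for the measurement to be valid.
#' @return A list of class `"brt_ray"`: vertex `R`, from-vertex unit vectors
#'   `u_l`, `u_k`, leg lengths `L1`, `L2`, and a `valid` flag.
#' @export
broken_ray <- function(r_s, s_l, r_d, s_k, sample_box) {
  v <- ray_vertex(r_s, s_l, r_d, s_k)
  R <- v$point
  valid <- v$t >= 0 && v$u >= 0 &&
    R[1] >= 0 && R[1] <= sample_box[1] && R[2] >= 0 && R[2] <= sample_box[2]
  structure(list(R = R,
                 u_l = unit2(r_s - R), u_k = unit2(r_d - R),
                 L1 = sqrt(sum((R - r_s)^2)), L2 = sqrt(sum((r_d - R)^2)),
                 valid = valid),
            class = "brt_ray")
}

#' Angular acceptance window of a detector point
#'
#' For an observation point `r` and a source ray `(r_s, s_l)`, the window of
#' polar angles theta (measured from the line of sight `r - r_s`) for which a
#' direction s in the slice plane both back-projects onto the source ray and
#' lies within the acceptance cone of half-angle `beta` about `s_k`.
#'
#' @param r observation point (on the detector/scoring surface).
#' @param r_s,s_l source position and direction.
#' @param s_k collimation direction (photon arrival direction at `r`).
#' @param beta acceptance half-angle in radians.
#' @return A list of class `"brt_window"` with `theta_min`, `theta_max`,
#'   `width` (the angular measure `Delta theta`, 0 when the cone misses the
#'   source ray) and `theta_l` (polar angle of the source direction).
#' @export
theta_window <- function(r, r_s, s_l, s_k, beta) {
  wp <- window_pieces(r, r_s, s_l, s_k, beta)
  width <- 0; th <- numeric()
  if (nrow(wp$pieces)) {
    d <- wp$pieces # relative angles delta about the line of sight
    width <- sum(d[, 2] - d[, 1])
    th <- c(abs(d[, 1]), abs(d[, 2]), if (any(d[, 1] < 0 & d[, 2] > 0)) 0)
  }
  structure(list(theta_min = if (length(th)) min(th) else NA_real_,
                 theta_max = if (length(th)) max(th) else NA_real_,
                 width = width, theta_l = wp$theta_l),
            class = "brt_window")
}

# Internal: admissible angular intervals, in the *relative* angle delta
# (signed angle about the line of sight r - r_s), for which a direction s in
# the slice plane back-projects onto the source ray and lies within the
# acceptance cone about s_k.  Returns the interval pieces, the polar angle
# theta_l of the source direction, the line-of-sight angle A and |r - r_s|.
window_pieces <- function(r, r_s, s_l, s_k, beta) {
  a <- r - r_s
  dist <- sqrt(sum(a^2))
  if (dist < 1e-12) stop("observation point coincides with the source")
  A <- atan2(a[2], a[1])
  psi_l <- wrap_angle(atan2(s_l[2], s_l[1]) - A)
  theta_l <- abs(psi_l)
  delta_k <- wrap_angle(atan2(s_k[2], s_k[1]) - A)

  if (theta_l < 1e-12) {
    adm <- c(-pi, pi)          # r on the source ray: every direction admissible
  } else if (psi_l > 0) {
    adm <- c(-(pi - theta_l), 0)
  } else {
    adm <- c(0, pi - theta_l)
  }

  pieces <- matrix(numeric(), ncol = 2)
  for (shift in c(-2 * pi, 0, 2 * pi)) {
    lo <- max(adm[1], delta_k - beta + shift)
    hi <- min(adm[2], delta_k + beta + shift)
    if (hi > lo) pieces <- rbind(pieces, c(lo, hi))
  }
  list(pieces = pieces, theta_l = theta_l, A = A, dist = dist)
}

#' Pointwise geometric factor f_lk(r)
#'
#' `f_lk(r) = Delta theta_lk(r) / (|r - r_s| sin(theta_l))`: the weight
#' describing the distribution of single-scattered photons over the detector
#' surface.
#'
#' @inheritParams theta_window
#' @return Nonnegative scalar; zero where the angular window is empty.
#'   Errors when the detector line of sight is parallel to the source ray
#'   (`sin(theta_l) = 0`).
#' @export
geom_factor <- function(r, r_s, s_l, s_k, beta) {
  w <- theta_window(r, r_s, s_l, s_k, beta)
  st <- sin(w$theta_l)
  if (st < 1e-9) stop("degenerate geometry: observation point on the source ray")
  dist <- sqrt(sum((r - r_s)^2))
  w$width / (dist * st)
}

#' Finite-detector geometric factor
#'
#' Quadrature of [geom_factor()] over the projection of the detector onto
#' the sample surface.  The out-of-plane (x) extent of the scoring region
#' enters as a multiplicative length `delta_d`; the in-plane extent is
#' `delta_d / |cos(alpha)|` in same-detector mode (alpha the collimation
#' angle to the face normal) or `delta_d` in per-direction-square mode.
#'
#' @param detector a [detector_spec()].
#' @param r_d detector centre on a sample face (length-2, slice plane).
#' @param s_k outward collimation direction.
#' @param r_s,s_l source position and direction.
#' @param nq number of midpoint quadrature nodes along the in-plane extent.
#' @param x_mode out-of-plane treatment of the scoring region.
#'   `"collapsed"` (default) multiplies by the full x-extent `delta_d`;
#'   `"cone"` accounts for the circular acceptance cone in 3D, under which a
#'   scoring point at out-of-plane offset x only accepts photons when the
#'   out-of-plane arrival angle `x / rho` stays within the cone - the
#'   x-extent saturates at `2 beta rho` (the partial x-illumination regime
#'   of small vertex-detector distances).
#' @param rho vertex-to-detector distance (mm); required for
#'   `x_mode = "cone"`.
#' @return Scalar `f_bar >= 0` (units mm, from the x-extent of the scoring
#'   region).
#' @export
geom_factor_bar <- function(detector, r_d, s_k, r_s, s_l, nq = 21,
                            x_mode = c("collapsed", "cone"), rho = NULL) {
  x_mode <- match.arg(x_mode)
  cos_alpha <- abs(unit2(s_k)[2])  # faces are z = const; normal (0, +/-1)
  w_in <- if (detector$scoring_mode == "same-detector") {
    if (cos_alpha < 1e-6) stop("collimation direction parallel to the surface")
    detector$delta_d / cos_alpha
  } else detector$delta_d
  ys <- r_d[1] + w_in * ((seq_len(nq) - 0.5) / nq - 0.5)
  vals <- vapply(ys, function(y) {
    f <- tryCatch(geom_factor(c(y, r_d[2]), r_s, s_l, s_k, detector$beta),
                  error = function(e) NA_real_)
    if (is.na(f)) 0 else f
  }, numeric(1))
  x_len <- if (x_mode == "collapsed") detector$delta_d
  else cone_x_extent(detector$delta_d, detector$beta, rho)
  x_len * (w_in / nq) * sum(vals)
}

# Effective x-extent of the scoring region under a circular 3D acceptance
# cone: integral over x of sqrt(1 - (x / (rho beta))^2)_+ across the
# detector width.  Equals delta_d when 2 beta rho >> delta_d (fully
# illuminated) and pi beta rho / 2 when the cone footprint is narrower.
cone_x_extent <- function(delta_d, beta, rho) {
  if (is.null(rho) || !is.finite(rho) || rho < 0)
    stop("x_mode = 'cone' needs the vertex-detector distance rho")
  a <- rho * beta
  if (a <= 0) return(0)
  b <- min(delta_d / 2, a)
  2 * (b / 2 * sqrt(max(0, 1 - (b / a)^2)) + a / 2 * asin(min(1, b / a)))
}
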