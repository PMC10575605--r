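# Local inversion of the non-reciprocal broken-ray transform.
#
# For noiseless single-scattering data the data functions decompose as
#   phi_lk = -ln n_tilde + I_e,l + I_f,k,
# with I_.,l the attenuation integrals from the vertex to the surface along
# the fixed direction u_l.  Writing I_l(+) = int mu(+) and I_l(-) = int mu(-)
# (mu(+) = (mu_e + mu_f)/2, mu(-) = mu_e - mu_f), the symmetrized functions
# are phi_lk(+) = -ln n_tilde + I_l(+) + I_k(+) and
# phi_lk(-) = I_l(-) - I_k(-).
#
# With weights sigma_l solving sigma1 u1 + sigma2 u2 + sigma3 u3 = 0, the
# vector fields
#   Phi(+) = -(sigma3 u3) phi12(+) - (sigma2 u2) phi13(+) - (sigma1 u1) phi23(+)
#   Phi(-) = -(sigma2 u2) phi12(-) - (sigma3 u3) phi13(-)
# give each integral family I_l a total coefficient sigma_l u_l (and cancel
# the -ln n_tilde terms of Phi(+) pixelwise, because the three coefficients
# sum to zero).  Since the directional derivative of I_l along u_l is -mu at
# the vertex,  div Phi(+/-) = -(sigma1+sigma2+sigma3) mu(+/-):  the
# reconstruction is local and independent of all constant bundles.

#' Direction weights for the divergence formula
#'
#' The unique (up to scale) solution of
#' `sigma1 u1 + sigma2 u2 + sigma3 u3 = 0`, normalized to `sigma1 = 1`.
#'
#' @param geometry a [scan_directions()] object (three pairwise non-parallel
#'   coplanar unit vectors).
#' @return Numeric length-3 weights.
#' @export
direction_weights <- function(geometry) {
  u <- geometry$u
  M <- u[, 2:3]
  if (abs(det(M)) < 1e-10) stop("degenerate directions: two of them are parallel")
  s23 <- solve(M, -u[, 1])
  c(1, s23)
}

#' Inversion configuration
#'
#' @param lambda total-variation regularization weight; `0` selects plain
#'   second-order centred differences (the noise-free limit).
#' @param median_kernel odd median-filter window applied to the Phi fields
#'   (and, in the concentration step, to the data functions); `1` disables.
#' @param pad_pixels edge rows/columns duplicated outside the region of
#'   interest before differentiation (reduces boundary artefacts).
#' @param tv_iterations,tv_tolerance,tv_eps lagged-diffusivity iteration
#'   controls for the TV solver.
#' @return List of class `"brt_inv_config"`.
#' @export
inversion_config <- function(lambda = 0, median_kernel = 1, pad_pixels = 10,
                             tv_iterations = 100, tv_tolerance = 1e-6,
                             tv_eps = 1e-8) {
  stopifnot(lambda >= 0, median_kernel >= 1, median_kernel %% 2 == 1,
            pad_pixels >= 0, tv_iterations >= 1)
  structure(list(lambda = lambda, median_kernel = as.integer(median_kernel),
                 pad_pixels = as.integer(pad_pixels),
                 tv_iterations = as.integer(tv_iterations),
                 tv_tolerance = tv_tolerance, tv_eps = tv_eps),
            class = "brt_inv_config")
}

#' 2D median filter
#'
#' Mask-aware k x k median filter; windows are clipped at the image edges.
#' With `fill_only = TRUE` only invalid pixels are replaced (by the median
#' of their valid neighbours), leaving valid pixels untouched.
#'
#' @param m matrix.
#' @param k odd window size (1 returns `m` unchanged unless filling).
#' @param mask logical matrix, `TRUE` = valid; `NULL` means all valid.
#' @param fill_only replace only invalid pixels.
#' @return Filtered matrix.
#' @export
median_filter2 <- function(m, k = 3, mask = NULL, fill_only = FALSE) {
  if (k == 1 && !fill_only) return(m)
  if (k == 1) k <- 3
  nr <- nrow(m); nc <- ncol(m)
  half <- (k - 1) / 2
  mm <- m
  if (!is.null(mask)) mm[!mask] <- NA_real_
  shifts <- expand.grid(dr = -half:half, dc = -half:half)
  stack <- array(NA_real_, c(nr, nc, nrow(shifts)))
  for (s in seq_len(nrow(shifts))) {
    dr <- shifts$dr[s]; dc <- shifts$dc[s]
    r_src <- clamp_idx(seq_len(nr) + dr, nr)
    c_src <- clamp_idx(seq_len(nc) + dc, nc)
    stack[, , s] <- mm[r_src, c_src]
  }
  med <- apply(stack, c(1, 2), median, na.rm = TRUE)
  med[is.nan(med)] <- NA_real_
  if (fill_only) {
    out <- mm
    bad <- if (is.null(mask)) is.na(mm) else !mask
    out[bad] <- med[bad]
    out
  } else med
}

# replicate p edge rows/columns (the pad-then-crop boundary treatment)
pad_replicate <- function(m, p) {
  if (p == 0) return(m)
  m <- m[c(rep(1, p), seq_len(nrow(m)), rep(nrow(m), p)), , drop = FALSE]
  m[, c(rep(1, p), seq_len(ncol(m)), rep(ncol(m), p)), drop = FALSE]
}

# plain second-order derivative along axis (1 = down rows/z, 2 = across
# columns/y), centred in the interior, one-sided at the ends
centered_diff <- function(m, axis, h) {
  if (axis == 2) return(t(centered_diff(t(m), 1, h)))
  n <- nrow(m)
  if (n < 3) stop("field too small to differentiate")
  d <- (m[c(2:n, n), , drop = FALSE] - m[c(1, 1:(n - 1)), , drop = FALSE]) /
    (2 * h)
  d[1, ] <- (m[2, ] - m[1, ]) / h
  d[n, ] <- (m[n, ] - m[n - 1, ]) / h
  d
}

# TV-regularized derivative of a single line sampled at spacing h:
# minimize (1/2)||A u - (f - f_1)||^2 + lambda * sum |u_{i+1} - u_i|,
# where A is the running-sum antiderivative in the forward or backward
# base scheme.  Lagged-diffusivity fixed point; dense solves (short lines).
tv_deriv_line <- function(f, h, lambda, scheme, iterations, tol, eps) {
  n <- length(f)
  f0 <- f - f[1]
  A <- matrix(0, n, n)
  if (scheme == "forward") {
    for (i in 2:n) A[i, 1:(i - 1)] <- h
  } else {
    for (i in 2:n) A[i, 2:i] <- h
  }
  D <- diff(diag(n)) # (n-1) x n first-difference operator
  AtA <- crossprod(A)
  Atf <- crossprod(A, f0)
  u <- c(f[2] - f[1], (f[3:n] - f[1:(n - 2)]) / 2, f[n] - f[n - 1]) / h
  for (it in seq_len(iterations)) {
    w <- 1 / sqrt((D %*% u)^2 + eps^2)
    H <- AtA + lambda * crossprod(D, as.vector(w) * D)
    unew <- tryCatch(solve(H, Atf), error = function(e) u)
    rel <- sqrt(sum((unew - u)^2)) / max(sqrt(sum(u^2)), 1e-12)
    u <- as.vector(unew)
    if (rel < tol) return(list(u = u, converged = TRUE, iter = it))
  }
  list(u = u, converged = FALSE, iter = iterations)
}

#' Total-variation regularized derivative of a 2D field
#'
#' Differentiates a (possibly noisy, discontinuous) field along one axis.
#' With `lambda > 0` each line is differentiated by minimizing a
#' data-fidelity term on the antiderivative plus a total-variation penalty
#' on the derivative, using both the forward- and backward-difference base
#' schemes and averaging the two (a second-order combination); with
#' `lambda = 0` plain second-order centred differences are used.
#'
#' @param field matrix (rows z, cols y).
#' @param axis 1 = derivative along z (down rows), 2 = along y.
#' @param h sample spacing (mm).
#' @param config an [inversion_config()].
#' @return Matrix of the derivative (per mm).  A warning is raised when the
#'   TV iteration fails to converge on some line (the last iterate is used).
#' @export
tv_derivative <- function(field, axis = 1, h, config = inversion_config()) {
  if (config$lambda <= 0) return(centered_diff(field, axis, h))
  if (axis == 2) return(t(tv_derivative(t(field), 1, h, config)))
  out <- matrix(0, nrow(field), ncol(field))
  nonconv <- 0L
  for (j in seq_len(ncol(field))) {
    rf <- tv_deriv_line(field[, j], h, config$lambda, "forward",
                        config$tv_iterations, config$tv_tolerance, config$tv_eps)
    rb <- tv_deriv_line(field[, j], h, config$lambda, "backward",
                        config$tv_iterations, config$tv_tolerance, config$tv_eps)
    if (!rf$converged || !rb$converged) nonconv <- nonconv + 1L
    out[, j] <- (rf$u + rb$u) / 2
  }
  if (nonconv > 0)
    warning(sprintf("TV derivative: %d line(s) did not converge in %d iterations",
                    nonconv, config$tv_iterations))
  out
}

#' Assemble the Phi(+) and Phi(-) vector fields
#'
#' @param scan a [assemble_scan()] result (complete: all six ordered pairs).
#' @param weights direction weights; default [direction_weights()].
#' @return List with `plus` and `minus`, each a list of `y` and `z`
#'   component matrices, plus the combined `mask` and the `weights`.
#' @export
build_phi_fields <- function(scan, weights = NULL) {
  if (is.null(weights)) weights <- direction_weights(scan$geometry)
  sym <- scan_symmetrize(scan)
  u <- scan$geometry$u
  cp <- list("12" = -weights[3] * u[, 3],
             "13" = -weights[2] * u[, 2],
             "23" = -weights[1] * u[, 1])
  cm <- list("12" = -weights[2] * u[, 2],
             "13" = -weights[3] * u[, 3])
  zero <- matrix(0, nrow(sym$plus[["12"]]), ncol(sym$plus[["12"]]))
  plus <- list(y = zero, z = zero)
  minus <- list(y = zero, z = zero)
  for (key in names(cp)) {
    plus$y <- plus$y + cp[[key]][1] * sym$plus[[key]]
    plus$z <- plus$z + cp[[key]][2] * sym$plus[[key]]
  }
  for (key in names(cm)) {
    minus$y <- minus$y + cm[[key]][1] * sym$minus[[key]]
    minus$z <- minus$z + cm[[key]][2] * sym$minus[[key]]
  }
  list(plus = plus, minus = minus, mask = sym$mask, weights = weights)
}

#' Reconstruct the attenuation maps
#'
#' Applies the local divergence formula: median-filters the Phi fields,
#' duplicates edge pixels outside the region of interest, differentiates
#' (TV-regularized or centred), crops, and scales by the direction weights.
#' `mu_e = mu(+) + mu(-)/2`, `mu_f = mu(+) - mu(-)/2`.
#'
#' @param scan a [assemble_scan()] result.
#' @param config an [inversion_config()].
#' @return List of class `"brt_mu"` with matrices `mu_plus`, `mu_minus`,
#'   `mu_e`, `mu_f`, the validity `mask`, `weights` and `config`.
#' @export
reconstruct_mu <- function(scan, config = inversion_config()) {
  fields <- build_phi_fields(scan)
  sw <- sum(fields$weights)
  p <- config$pad_pixels
  h <- scan$h
  deriv_one <- function(comp, axis) {
    m <- comp
    if (!all(fields$mask)) m <- median_filter2(m, 3, fields$mask, fill_only = TRUE)
    m <- median_filter2(m, config$median_kernel)
    m <- pad_replicate(m, p)
    d <- tv_derivative(m, axis, h, config)
    d[p + seq_len(nrow(comp)), p + seq_len(ncol(comp)), drop = FALSE]
  }
  div_plus <- deriv_one(fields$plus$y, 2) + deriv_one(fields$plus$z, 1)
  div_minus <- deriv_one(fields$minus$y, 2) + deriv_one(fields$minus$z, 1)
  mu_plus <- -div_plus / sw
  mu_minus <- -div_minus / sw
  structure(list(mu_plus = mu_plus, mu_minus = mu_minus,
                 mu_e = mu_plus + mu_minus / 2,
                 mu_f = mu_plus - mu_minus / 2,
                 mask = fields$mask, weights = fields$weights,
                 config = config),
            class = "brt_mu")
}

#' Line integral of a reconstructed map from vertices to the ROI boundary
#'
#' Integrates a reconstructed (region-of-interest) map from every vertex
#' along a from-vertex direction until the ray leaves the region.  Rays that
#' exit through the lateral ROI boundary (where the map is unknown) are
#' flagged invalid; the surface-normal direction 1 always stays inside.
#'
#' @param map ROI matrix (rows z, cols y).
#' @param h pixel pitch (mm).
#' @param u from-vertex unit direction (y, z).
#' @return List with matrix `I` and logical matrix `valid`.
#' @export
line_integral_roi <- function(map, h, u) {
  nzr <- nrow(map); nyr <- ncol(map)
  ys <- (seq_len(nyr) - 0.5) * h
  zs <- (seq_len(nzr) - 0.5) * h
  Y <- matrix(rep(ys, each = nzr), nzr, nyr)
  Z <- matrix(rep(zs, times = nyr), nzr, nyr)
  Lyr <- nyr * h; Lzr <- nzr * h
  t_face <- if (u[2] < 0) as.vector(Z) / (-u[2]) else (Lzr - as.vector(Z)) / u[2]
  ry <- as.vector(Y) + t_face * u[1]
  valid <- ry >= -1e-9 & ry <= Lyr + 1e-9
  starts <- cbind(as.vector(Y), as.vector(Z))
  I <- ray_integrals_dir(map, h, starts, u, rep(Inf, length(ry)))
  list(I = matrix(I, nzr, nyr), valid = matrix(valid, nzr, nyr))
}

#' Reconstruct the normalized fluorophore concentration
#'
#' Three modes:
#' \describe{
#'   \item{`"eq11"`}{(default) uses the three symmetric data functions and a
#'     single line integral `I1(+)` of the reconstructed `mu(+)` along the
#'     surface normal, which never leaves the region of interest:
#'     `n_tilde = exp(2 I1(+) - phi12(+) + phi32(+) - phi13(+))`.}
#'   \item{`"eq9"`}{`n_tilde = exp(I_l(+) + I_k(+) - phi_lk(+))` for one
#'     pair; vertices whose oblique integrals leave the region are masked.}
#'   \item{`"eq12"`}{conventional fluorescence tomography: the true
#'     attenuation maps are supplied and a single (unsymmetrized) data
#'     function is used: `n_tilde = exp(I_e,l + I_f,k - phi_lk)`.}
#' }
#' A median filter (the `median_kernel` of `config`) is applied to the data
#' functions and to `mu_plus` before the integrals.  The output is
#' normalized to its maximum over valid pixels, so it lies in [0, 1].
#'
#' @param scan a [assemble_scan()] result.
#' @param mu_plus reconstructed `mu(+)` ROI map (modes eq11/eq9).
#' @param mode `"eq11"`, `"eq9"` or `"eq12"`.
#' @param pair direction pair `c(l, k)` for modes eq9/eq12.
#' @param truth a `"brt_slice"` with the true maps (mode eq12); defaults to
#'   the scan's stored truth.
#' @param config an [inversion_config()] (median kernel and padding reuse).
#' @return List of class `"brt_n"` with the normalized map `n_norm`, its
#'   `mask` and the `mode`.
#' @export
reconstruct_n <- function(scan, mu_plus = NULL,
                          mode = c("eq11", "eq9", "eq12"),
                          pair = c(1, 2), truth = NULL,
                          config = inversion_config()) {
  mode <- match.arg(mode)
  h <- scan$h
  mf <- function(m) median_filter2(m, config$median_kernel)
  if (mode %in% c("eq11", "eq9")) {
    if (is.null(mu_plus)) stop("modes eq11/eq9 need the reconstructed mu(+)")
    sym <- scan_symmetrize(scan)
    mup <- mf(mu_plus)
    if (mode == "eq11") {
      u1 <- scan$geometry$u[, 1]
      li <- line_integral_roi(mup, h, u1)
      lg <- 2 * li$I - mf(sym$plus[["12"]]) + mf(sym$plus[["23"]]) -
        mf(sym$plus[["13"]])
      valid <- li$valid & sym$mask
    } else {
      l <- pair[1]; k <- pair[2]
      key <- paste0(min(l, k), max(l, k))
      Il <- line_integral_roi(mup, h, scan$geometry$u[, l])
      Ik <- line_integral_roi(mup, h, scan$geometry$u[, k])
      lg <- Il$I + Ik$I - mf(sym$plus[[key]])
      valid <- Il$valid & Ik$valid & sym$mask
    }
  } else {
    if (is.null(truth)) truth <- scan$truth
    if (is.null(truth)) stop("mode eq12 needs the true attenuation maps")
    l <- pair[1]; k <- pair[2]
    key <- paste0(l, k)
    roi <- scan$roi
    Y <- matrix(rep(scan$ys, each = length(scan$zs)),
                length(scan$zs), length(scan$ys))
    Z <- matrix(rep(scan$zs, times = length(scan$ys)),
                length(scan$zs), length(scan$ys))
    starts <- cbind(as.vector(Y), as.vector(Z))
    Ie <- ray_integrals_dir(truth$mu_e, h, starts, scan$geometry$u[, l], Inf)
    If <- ray_integrals_dir(truth$mu_f, h, starts, scan$geometry$u[, k], Inf)
    lg <- matrix(Ie + If, nrow(Y), ncol(Y)) - mf(scan$phi[[key]])
    valid <- scan$mask[[key]]
  }
  nt <- exp(lg)
  nt[!valid] <- NA_real_
  mx <- suppressWarnings(max(nt, na.rm = TRUE))
  if (!is.finite(mx) || mx <= 0) stop("concentration reconstruction failed: no valid pixels")
  structure(list(n_norm = nt / mx, mask = valid & is.finite(nt), mode = mode),
            class = "brt_n")
}
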