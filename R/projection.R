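# Broken-ray-transform data functions on the vertex grid.
#
# For every ordered direction pair (l, k), l != k, the data function
#   phi_lk(R) = -ln[ deltaW_lk / (eta0 W f_bar /(2 pi sigma)) ]
#             = -ln n_tilde(R) + int_leg_l mu_e + int_leg_k mu_f
# is tabulated on the slice's vertex grid (one vertex per voxel centre in
# the region of interest).  A complete scan holds all six ordered pairs:
# the source-detector interchange (k, l) reverses which leg carries mu_e,
# which is the non-reciprocity the inversion exploits.

#' Projection data function
#'
#' @param deltaW measured or simulated detector signal (> 0).
#' @param fbar finite-detector geometric factor used for normalization.
#' @param constants a [beam_constants()].
#' @return `phi = -log(deltaW / (eta0 W fbar / (2 pi sigma)))`; `NA` (a
#'   masked, missing measurement - never -Inf) when `deltaW <= 0`.
#' @export
data_function <- function(deltaW, fbar, constants = beam_constants()) {
  C0 <- constants$eta0 * constants$W / (2 * pi * constants$sigma)
  out <- rep(NA_real_, length(deltaW))
  ok <- is.finite(deltaW) & deltaW > 0 & is.finite(fbar) & fbar > 0
  out[ok] <- -log(deltaW[ok] / (C0 * fbar[ok]))
  if (length(deltaW) == 1) out[1] else out
}

#' Widest fully scannable region of interest
#'
#' Returns the y-index window (full depth) such that, for every vertex in
#' the window, the rays along all three directions meet the source/detector
#' faces within the sample's lateral extent.
#'
#' @param slice a `"brt_slice"`.
#' @param geometry a [scan_directions()] object.
#' @return List with integer vectors `iy`, `iz` (1-based voxel indices).
#' @export
default_roi <- function(slice, geometry) {
  h <- slice$pitch
  ny <- ncol(slice$mu_e); nz <- nrow(slice$mu_e)
  lo <- 0; hi <- slice$Ly
  for (l in 1:3) {
    u <- geometry$u[, l]
    if (abs(u[1]) < 1e-12) next
    # surface offset |t u_y| is largest at the depth farthest from the face
    tmax <- slice$Lz / abs(u[2])
    off <- tmax * u[1]
    if (off > 0) hi <- min(hi, slice$Ly - off) else lo <- max(lo, -off)
  }
  iy_lo <- max(1L, as.integer(ceiling(lo / h + 0.5)))
  iy_hi <- min(ny, as.integer(floor(hi / h + 0.5)))
  if (iy_hi < iy_lo) stop("sample too narrow: no fully scannable region of interest")
  list(iy = iy_lo:iy_hi, iz = seq_len(nz))
}

# surface endpoint parameters for vertices (ys, zs) along from-vertex unit u
surface_reach <- function(ys, zs, u, Ly, Lz) {
  t <- if (u[2] < 0) zs / (-u[2]) else (Lz - zs) / u[2]
  ry <- ys + t * u[1]
  face <- if (u[2] < 0) 0 else Lz
  list(t = t, ry = ry, face = face,
       valid = ry >= -1e-9 & ry <= Ly + 1e-9)
}

#' Assemble a complete broken-ray scan
#'
#' Tabulates the data functions phi_lk for all six ordered direction pairs
#' on the vertex grid of the region of interest, using either the analytic
#' single-scattering forward model or the Monte Carlo engine.
#'
#' For the analytic engine, source and detector positions are computed
#' exactly for each vertex (an idealized continuous scan) and the geometric
#' factor cancels in the data function unless `fbar_mode = "full"`.  For the
#' Monte Carlo engine, sources are simulated at stations snapped to the
#' 0.1 mm grid on the faces (exact for the 0/+-45 degree directions), one
#' independent seeded run per station, and signals are scored per Eq.-style
#' acceptance-cone counting; vertices with zero accepted counts are masked.
#'
#' @param slice a `"brt_slice"` with the optical-parameter maps.
#' @param geometry a [scan_directions()] object.
#' @param detector a [detector_spec()].
#' @param roi list with `iy`, `iz` index vectors (default: [default_roi()],
#'   full depth).
#' @param engine `"analytic"` or `"mc"`.
#' @param constants a [beam_constants()].
#' @param fbar_mode `"cancel"` (analytic only: use the algebraic
#'   cancellation of f_bar in phi) or `"full"` (quadrature per vertex).
#' @param phantom the full [build_phantom()] object (required for `"mc"`).
#' @param N photons per source station (`"mc"`).
#' @param seed base seed; station s uses `seed + s` (`"mc"`).
#' @param partial if `TRUE`, vertices without a valid measurement are masked
#'   instead of failing the coverage check.
#' @param keep_truth attach the slice as ground truth for later evaluation.
#' @return A list of class `"brt_scan"`: `phi` and `mask` keyed by `"12"`,
#'   `"21"`, ..., vertex coordinates `ys`, `zs`, geometry/detector metadata.
#' @export
assemble_scan <- function(slice, geometry, detector, roi = NULL,
                          engine = c("analytic", "mc"),
                          constants = beam_constants(),
                          fbar_mode = c("cancel", "full"),
                          phantom = NULL, N = 1e5, seed = 1,
                          partial = FALSE, keep_truth = TRUE) {
  engine <- match.arg(engine)
  fbar_mode <- match.arg(fbar_mode)
  if (is.null(roi)) roi <- default_roi(slice, geometry)
  h <- slice$pitch
  ys <- (roi$iy - 0.5) * h
  zs <- (roi$iz - 0.5) * h
  nyr <- length(ys); nzr <- length(zs)
  Y <- matrix(rep(ys, each = nzr), nzr, nyr)
  Z <- matrix(rep(zs, times = nyr), nzr, nyr)
  pairs <- list(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
  phi <- list(); mask <- list()
  coverage <- character()
  starts <- cbind(as.vector(Y), as.vector(Z))
  reach <- lapply(1:3, function(l)
    surface_reach(as.vector(Y), as.vector(Z), geometry$u[, l],
                  slice$Ly, slice$Lz))

  for (p in pairs) {
    l <- p[1]; k <- p[2]
    key <- paste0(l, k)
    src <- reach[[l]]; det <- reach[[k]]
    ok <- src$valid & det$valid
    if (!all(ok)) {
      coverage <- c(coverage, sprintf(
        "pair %s: %d of %d vertices unreachable", key, sum(!ok), length(ok)))
      if (!partial) next # defer the error until all pairs are reported
    }
    ph <- rep(NA_real_, length(ok))

    if (engine == "analytic") {
      u_l <- geometry$u[, l]; u_k <- geometry$u[, k]
      Ie <- ray_integrals_dir(slice$mu_e, h, starts, u_l, src$t)
      If <- ray_integrals_dir(slice$mu_f, h, starts, u_k, det$t)
      nt <- as.vector(slice$n_tilde[roi$iz, roi$iy, drop = FALSE])
      C0 <- constants$eta0 * constants$W / (2 * pi * constants$sigma)
      fb <- rep(1, length(ok))
      if (fbar_mode == "full") {
        s_l <- -u_l; s_k <- u_k
        for (i in which(ok)) {
          fb[i] <- geom_factor_bar(detector,
                                   r_d = c(det$ry[i], det$face), s_k = s_k,
                                   r_s = c(src$ry[i], src$face), s_l = s_l)
        }
      }
      dW <- C0 * fb * nt * exp(-(Ie + If))
      ph[ok] <- data_function(dW[ok], fb[ok], constants)
    }
    phi[[key]] <- matrix(ph, nzr, nyr)
    mask[[key]] <- if (engine == "analytic")
      matrix(ok & is.finite(ph), nzr, nyr) else matrix(ok, nzr, nyr)
  }

  if (length(coverage) && !partial)
    stop("region of interest not fully covered:\n  ",
         paste(coverage, collapse = "\n  "))

  if (engine == "mc") {
    # one seeded run per unique (source direction, snapped station),
    # scoring the detectors of both pairs that share the source
    if (is.null(phantom)) stop("the Monte Carlo engine needs the full phantom")
    x_center <- (slice$x_index - 0.5) * phantom$pitch
    for (l in 1:3) {
      src <- reach[[l]]
      s_l <- -geometry$u[, l]
      ks <- setdiff(1:3, l)
      valid_any <- src$valid &
        (reach[[ks[1]]]$valid | reach[[ks[2]]]$valid)
      sy <- round(src$ry / h) * h
      stations <- sort(unique(sy[valid_any]))
      axes <- cbind(c(0, geometry$u[, ks[1]]), c(0, geometry$u[, ks[2]]))
      for (si in seq_along(stations)) {
        st <- stations[si]
        idx <- which(valid_any & sy == st)
        if (!length(idx)) next
        run <- mc_propagate(phantom,
                            position = c(x_center, st, src$face),
                            direction = c(0, s_l),
                            N = N, seed = seed + 7919L * l + si,
                            record_axes = axes,
                            record_beta = detector$beta + 0.02)
        for (k in ks) {
          key <- paste0(l, k)
          det <- reach[[k]]
          s_k <- geometry$u[, k]
          for (i in idx) {
            if (!det$valid[i]) next
            dy_i <- round(det$ry[i] / h) * h
            fb <- geom_factor_bar(detector,
                                  r_d = c(dy_i, det$face), s_k = s_k,
                                  r_s = c(st, src$face), s_l = s_l,
                                  x_mode = "cone", rho = det$t[i])
            dW <- mc_score(run, detector, r_d = c(dy_i, det$face),
                           s_k = s_k, x_center = x_center,
                           constants = constants) / N * constants$W
            phi[[key]][[i]] <- data_function(dW, fb, constants)
          }
        }
      }
    }
    for (key in names(phi))
      mask[[key]] <- mask[[key]] & is.finite(phi[[key]])
  }

  structure(list(phi = phi, mask = mask, ys = ys, zs = zs, h = h,
                 roi = roi, geometry = geometry, detector = detector,
                 constants = constants, engine = engine,
                 Ly = slice$Ly, Lz = slice$Lz,
                 N = if (engine == "mc") N else NA_real_,
                 seed = if (engine == "mc") seed else NA_integer_,
                 truth = if (keep_truth) slice else NULL,
                 coverage = coverage),
            class = "brt_scan")
}

#' @export
print.brt_scan <- function(x, ...) {
  cat(sprintf("Broken-ray scan (%s, %s engine): %d x %d vertex grid, %d direction pairs\n",
              x$geometry$scan_type, x$engine, length(x$zs), length(x$ys),
              length(x$phi)))
  nmask <- sum(!vapply(x$mask, sum, numeric(1)) == length(x$ys) * length(x$zs))
  if (nmask) cat(" ", nmask, "pair(s) carry masked vertices\n")
  invisible(x)
}

#' Symmetric and antisymmetric data functions
#'
#' `phi_lk(+) = (phi_lk + phi_kl)/2` and `phi_lk(-) = phi_lk - phi_kl`,
#' the average and difference under source-detector interchange.
#'
#' @param scan a [assemble_scan()] result.
#' @return List with `plus` and `minus` (each keyed `"12"`, `"13"`, `"23"`)
#'   and the combined validity `mask`.
#' @export
scan_symmetrize <- function(scan) {
  plus <- list(); minus <- list(); mask <- NULL
  for (key in c("12", "13", "23")) {
    rev <- paste0(substr(key, 2, 2), substr(key, 1, 1))
    a <- scan$phi[[key]]; b <- scan$phi[[rev]]
    if (is.null(a) || is.null(b)) stop("incomplete scan: missing pair ", key)
    plus[[key]] <- (a + b) / 2
    minus[[key]] <- a - b
    m <- scan$mask[[key]] & scan$mask[[rev]]
    mask <- if (is.null(mask)) m else mask & m
  }
  list(plus = plus, minus = minus, mask = mask)
}

#' Noise diagnostics against a reference signal
#'
#' Percentage relative difference between simulated and model signals per
#' source-detector separation, after a least-squares global scaling of the
#' simulated values onto the model (the absolute Monte Carlo scale is a
#' constant bundle that cancels in reconstruction).
#'
#' @param deltaW_sim simulated signals.
#' @param deltaW_model model (analytic) signals, same length.
#' @param separation source-detector separations (mm) for the table.
#' @return data frame with `separation`, `deltaW_model`, `deltaW_sim_scaled`
#'   and `eps_percent`; the fitted scale is attached as attribute `"scale"`.
#' @export
noise_diagnostics <- function(deltaW_sim, deltaW_model, separation) {
  stopifnot(length(deltaW_sim) == length(deltaW_model),
            length(separation) == length(deltaW_model))
  ok <- is.finite(deltaW_sim) & is.finite(deltaW_model) & deltaW_model > 0
  # Poisson-weighted least squares: minimize sum (s*x - m)^2 / m
  s <- sum(deltaW_sim[ok]) / sum(deltaW_sim[ok]^2 / deltaW_model[ok])
  if (!is.finite(s) || s <= 0) s <- 1
  eps <- 100 * (s * deltaW_sim - deltaW_model) / deltaW_model
  structure(data.frame(separation = separation,
                       deltaW_model = deltaW_model,
                       deltaW_sim_scaled = s * deltaW_sim,
                       eps_percent = eps),
            scale = s)
}
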