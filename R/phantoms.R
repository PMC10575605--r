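# Voxelized numerical samples: cuboid background plus spherical inclusions.
#
# A sample is parameterized the way the simulation studies in this field
# tabulate them: by dimensionless products (optical depth Lz*mu_s of the
# background, ratios mu_a/mu_s and sigma*n/mu_a, inclusion products D*mu_s and
# contrasts of the total attenuation and of the fluorophore concentration).
# Absolute scales (the fluorophore cross-section sigma, source power, detector
# sensitivity) do not affect the attenuation reconstruction and enter the
# concentration only through a global constant, so sigma defaults to 1.

#' Describe a spherical inclusion of a sample
#'
#' @param center_mm numeric length-3 centre (x, y, z) in mm.
#' @param diameter_mm sphere diameter D in mm.
#' @param mu_s_e,mu_s_f intrinsic scattering coefficients of the inclusion at
#'   the excitation / fluorescence wavelength (per mm).
#' @param mu_e_contrast,mu_f_contrast ratio of the inclusion's total
#'   attenuation to the background total attenuation at each wavelength.
#' @param n_contrast ratio of the inclusion fluorophore concentration to the
#'   background concentration, or `NA` when the background holds no agent.
#' @param n_value absolute inclusion fluorophore concentration; used when
#'   `n_contrast` is `NA`.
#' @return A list of class `"brt_inclusion"`.
#' @export
inclusion <- function(center_mm, diameter_mm, mu_s_e, mu_s_f,
                      mu_e_contrast, mu_f_contrast,
                      n_contrast = NA_real_, n_value = NA_real_) {
  stopifnot(length(center_mm) == 3, diameter_mm > 0,
            mu_s_e >= 0, mu_s_f >= 0, mu_e_contrast > 0, mu_f_contrast > 0)
  structure(list(center_mm = as.numeric(center_mm),
                 diameter_mm = diameter_mm,
                 mu_s_e = mu_s_e, mu_s_f = mu_s_f,
                 mu_e_contrast = mu_e_contrast,
                 mu_f_contrast = mu_f_contrast,
                 n_contrast = n_contrast, n_value = n_value),
            class = "brt_inclusion")
}

#' Specify a cuboid sample
#'
#' @param dims_mm numeric length-3 sample lengths (Lx, Ly, Lz) in mm.  The
#'   illuminated face is z = 0; z increases into the sample.
#' @param voxel_pitch voxel edge length in mm (default 0.1).
#' @param bg_mu_s_e,bg_mu_s_f intrinsic background scattering (per mm).
#' @param bg_mu_a_e,bg_mu_a_f intrinsic background absorption (per mm).
#' @param bg_n background fluorophore concentration (arbitrary units).
#' @param sigma_e fluorophore absorption cross-section at the excitation
#'   wavelength; the fluorophore contributes `n * sigma_e` to the total
#'   attenuation at the excitation wavelength only (reabsorption of the
#'   emitted light is neglected).
#' @param inclusions list of [inclusion()] objects (possibly empty).
#' @param scan_type suggested scan type, `"transmission"` or
#'   `"backscattering"` (metadata used by the pipeline presets).
#' @param lambda_preset suggested regularization weight for noisy data.
#' @param scoring_mode detector scoring convention, see [detector_spec()].
#' @return A list of class `"brt_sample_spec"`.
#' @export
sample_spec <- function(dims_mm, voxel_pitch = 0.1,
                        bg_mu_s_e, bg_mu_s_f, bg_mu_a_e, bg_mu_a_f,
                        bg_n = 0, sigma_e = 1, inclusions = list(),
                        scan_type = "transmission",
                        lambda_preset = 50,
                        scoring_mode = "same-detector") {
  stopifnot(length(dims_mm) == 3, all(dims_mm > 0), voxel_pitch > 0,
            bg_mu_s_e >= 0, bg_mu_s_f >= 0, bg_mu_a_e >= 0, bg_mu_a_f >= 0,
            bg_n >= 0, sigma_e > 0)
  # pitch must divide each dimension to within one voxel
  for (L in dims_mm) {
    k <- round(L / voxel_pitch)
    if (abs(L - k * voxel_pitch) > voxel_pitch)
      stop("voxel_pitch does not divide the sample dimensions")
  }
  spec <- structure(list(dims_mm = as.numeric(dims_mm),
                         voxel_pitch = voxel_pitch,
                         bg_mu_s_e = bg_mu_s_e, bg_mu_s_f = bg_mu_s_f,
                         bg_mu_a_e = bg_mu_a_e, bg_mu_a_f = bg_mu_a_f,
                         bg_n = bg_n, sigma_e = sigma_e,
                         inclusions = inclusions,
                         scan_type = scan_type,
                         lambda_preset = lambda_preset,
                         scoring_mode = scoring_mode),
                    class = "brt_sample_spec")
  validate_sample_spec(spec)
  spec
}

validate_sample_spec <- function(spec) {
  d <- spec$dims_mm
  for (inc in spec$inclusions) {
    r <- inc$diameter_mm / 2
    if (any(inc$center_mm - r < -1e-9) || any(inc$center_mm + r > d + 1e-9))
      stop("inclusion sphere extends outside the cuboid")
  }
  ni <- length(spec$inclusions)
  if (ni > 1) {
    for (i in seq_len(ni - 1)) for (j in (i + 1):ni) {
      a <- spec$inclusions[[i]]; b <- spec$inclusions[[j]]
      if (sqrt(sum((a$center_mm - b$center_mm)^2)) <
          (a$diameter_mm + b$diameter_mm) / 2)
        stop("overlapping inclusions are not supported")
    }
  }
  invisible(spec)
}

# absolute background / inclusion coefficients implied by a spec
spec_background <- function(spec) {
  mu_e <- spec$bg_mu_a_e + spec$bg_mu_s_e + spec$bg_n * spec$sigma_e
  mu_f <- spec$bg_mu_a_f + spec$bg_mu_s_f
  list(mu_e = mu_e, mu_f = mu_f)
}

inclusion_values <- function(spec, inc) {
  bg <- spec_background(spec)
  n <- if (is.finite(inc$n_contrast)) inc$n_contrast * spec$bg_n else inc$n_value
  if (!is.finite(n)) stop("inclusion concentration undefined: give n_contrast or n_value")
  mu_e <- inc$mu_e_contrast * bg$mu_e
  mu_f <- inc$mu_f_contrast * bg$mu_f
  mu_a_e <- mu_e - inc$mu_s_e - n * spec$sigma_e
  mu_a_f <- mu_f - inc$mu_s_f
  if (mu_a_e < -1e-12 || mu_a_f < -1e-12)
    stop("inclusion contrasts imply a negative intrinsic absorption")
  list(mu_s_e = inc$mu_s_e, mu_s_f = inc$mu_s_f,
       mu_a_e = max(mu_a_e, 0), mu_a_f = max(mu_a_f, 0),
       n = n, mu_e = mu_e, mu_f = mu_f)
}

#' Build a sample specification from dimensionless products
#'
#' Constructs a [sample_spec()] from the dimensionless characterization used
#' for the simulation samples: background optical depths `Lz*mu_s` at both
#' wavelengths, the ratios `mu_a/mu_s` and `sigma*n/mu_a`, and per-inclusion
#' products `D*mu_s` and contrast ratios.  The ratio `mu_a;f/mu_s;f` is taken
#' equal to `mu_a;e/mu_s;e`.
#'
#' @param dims_mm,voxel_pitch,sigma_e,scan_type,lambda_preset,scoring_mode
#'   passed to [sample_spec()].
#' @param Lz_mu_s_e,Lz_mu_s_f background optical depths at the two wavelengths.
#' @param mu_a_over_mu_s background ratio of intrinsic absorption to scattering.
#' @param sigma_n_over_mu_a background ratio `sigma*n / mu_a;e` (0 when the
#'   agent is confined to the inclusions).
#' @param D inclusion diameters (mm), one per inclusion.
#' @param D_mu_s_e,D_mu_s_f inclusion products `D * mu_s` at each wavelength.
#' @param mu_e_contrast,mu_f_contrast,n_contrast inclusion contrast ratios.
#' @param incl_sigma_n_over_mu_a inclusion `sigma*n / mu_a;e` (used instead of
#'   `n_contrast` when the background concentration is zero).
#' @param centers matrix (one row per inclusion) of centres in mm, or `NULL`
#'   to place inclusions at the slice centre, spread along y.
#' @return A [sample_spec()].
#' @export
spec_from_products <- function(dims_mm, Lz_mu_s_e, Lz_mu_s_f,
                               mu_a_over_mu_s, sigma_n_over_mu_a,
                               D = numeric(), D_mu_s_e = numeric(),
                               D_mu_s_f = numeric(),
                               mu_e_contrast = numeric(),
                               mu_f_contrast = numeric(),
                               n_contrast = NULL,
                               incl_sigma_n_over_mu_a = NULL,
                               centers = NULL, voxel_pitch = 0.1,
                               sigma_e = 1, scan_type = "transmission",
                               lambda_preset = 50,
                               scoring_mode = "same-detector") {
  Lz <- dims_mm[3]
  mu_s_e <- Lz_mu_s_e / Lz
  mu_s_f <- Lz_mu_s_f / Lz
  mu_a_e <- mu_a_over_mu_s * mu_s_e
  mu_a_f <- mu_a_over_mu_s * mu_s_f
  bg_n <- sigma_n_over_mu_a * mu_a_e / sigma_e
  ninc <- length(D)
  if (is.null(centers) && ninc > 0) {
    # spread along y about the sample centre, all in the central slice
    gap <- if (ninc > 1) (D[-ninc] + D[-1]) / 2 + 0.4 else numeric()
    off <- c(0, cumsum(gap)); off <- off - mean(off)
    centers <- cbind(dims_mm[1] / 2, dims_mm[2] / 2 + off, Lz / 2)
  }
  incs <- vector("list", ninc)
  for (i in seq_len(ninc)) {
    nc <- if (!is.null(n_contrast)) n_contrast[i] else NA_real_
    nv <- if (!is.null(incl_sigma_n_over_mu_a))
      incl_sigma_n_over_mu_a[i] * mu_a_e / sigma_e else NA_real_
    incs[[i]] <- inclusion(centers[i, ], D[i],
                           mu_s_e = D_mu_s_e[i] / D[i],
                           mu_s_f = D_mu_s_f[i] / D[i],
                           mu_e_contrast = mu_e_contrast[i],
                           mu_f_contrast = mu_f_contrast[i],
                           n_contrast = nc, n_value = nv)
  }
  sample_spec(dims_mm, voxel_pitch = voxel_pitch,
              bg_mu_s_e = mu_s_e, bg_mu_s_f = mu_s_f,
              bg_mu_a_e = mu_a_e, bg_mu_a_f = mu_a_f,
              bg_n = bg_n, sigma_e = sigma_e, inclusions = incs,
              scan_type = scan_type, lambda_preset = lambda_preset,
              scoring_mode = scoring_mode)
}

#' Recompute the dimensionless products of a sample specification
#'
#' @param spec a [sample_spec()].
#' @return A list with the background products (`Lz_mu_s_e`, `Lz_mu_s_f`,
#'   `mu_a_over_mu_s`, `sigma_n_over_mu_a`) and a data frame of per-inclusion
#'   products (`D_mu_s_e`, `D_mu_s_f`, contrasts).
#' @export
dimensionless_products <- function(spec) {
  Lz <- spec$dims_mm[3]
  bg <- spec_background(spec)
  incl <- NULL
  if (length(spec$inclusions)) {
    rows <- lapply(spec$inclusions, function(inc) {
      v <- inclusion_values(spec, inc)
      data.frame(D = inc$diameter_mm,
                 D_mu_s_e = inc$diameter_mm * v$mu_s_e,
                 D_mu_s_f = inc$diameter_mm * v$mu_s_f,
                 mu_e_contrast = v$mu_e / bg$mu_e,
                 mu_f_contrast = v$mu_f / bg$mu_f,
                 n_contrast = if (spec$bg_n > 0) v$n / spec$bg_n else NA_real_)
    })
    incl <- do.call(rbind, rows)
  }
  list(Lz_mu_s_e = Lz * spec$bg_mu_s_e,
       Lz_mu_s_f = Lz * spec$bg_mu_s_f,
       mu_a_over_mu_s = spec$bg_mu_a_e / spec$bg_mu_s_e,
       sigma_n_over_mu_a = spec$bg_n * spec$sigma_e / spec$bg_mu_a_e,
       inclusions = incl)
}

#' Build a voxelized phantom from a sample specification
#'
#' Voxel membership uses a voxel-centre-in-sphere test (sharp, step-like
#' inclusion boundaries at the 0.1 mm discretization).  The derived total
#' attenuations are `mu_e = mu_a_e + mu_s_e + n * sigma_e` and
#' `mu_f = mu_a_f + mu_s_f` (no fluorophore reabsorption at the emission
#' wavelength).
#'
#' @param spec a [sample_spec()].
#' @return A list of class `"brt_phantom"` holding 3D arrays (`dim =
#'   c(nx, ny, nz)`) `mu_s_e`, `mu_s_f`, `mu_a_e`, `mu_a_f`, `n`, `mu_e`,
#'   `mu_f`, the pitch and the spec.
#' @export
build_phantom <- function(spec) {
  validate_sample_spec(spec)
  h <- spec$voxel_pitch
  nd <- pmax(1L, as.integer(round(spec$dims_mm / h)))
  nx <- nd[1]; ny <- nd[2]; nz <- nd[3]
  mk <- function(v) array(v, dim = c(nx, ny, nz))
  ph <- list(mu_s_e = mk(spec$bg_mu_s_e), mu_s_f = mk(spec$bg_mu_s_f),
             mu_a_e = mk(spec$bg_mu_a_e), mu_a_f = mk(spec$bg_mu_a_f),
             n = mk(spec$bg_n))
  cx <- (seq_len(nx) - 0.5) * h
  cy <- (seq_len(ny) - 0.5) * h
  cz <- (seq_len(nz) - 0.5) * h
  for (inc in spec$inclusions) {
    v <- inclusion_values(spec, inc)
    r2 <- (inc$diameter_mm / 2)^2
    ix <- which((cx - inc$center_mm[1])^2 <= r2)
    iy <- which((cy - inc$center_mm[2])^2 <= r2)
    iz <- which((cz - inc$center_mm[3])^2 <= r2)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (cx[ix] - inc$center_mm[1])^2
    dy2 <- (cy[iy] - inc$center_mm[2])^2
    dz2 <- (cz[iz] - inc$center_mm[3])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r2
    sub <- function(a, val) { b <- a[ix, iy, iz, drop = FALSE]; b[inside] <- val; b }
    ph$mu_s_e[ix, iy, iz] <- sub(ph$mu_s_e, v$mu_s_e)
    ph$mu_s_f[ix, iy, iz] <- sub(ph$mu_s_f, v$mu_s_f)
    ph$mu_a_e[ix, iy, iz] <- sub(ph$mu_a_e, v$mu_a_e)
    ph$mu_a_f[ix, iy, iz] <- sub(ph$mu_a_f, v$mu_a_f)
    ph$n[ix, iy, iz]      <- sub(ph$n, v$n)
  }
  ph$mu_e <- ph$mu_a_e + ph$mu_s_e + ph$n * spec$sigma_e
  ph$mu_f <- ph$mu_a_f + ph$mu_s_f
  ph$pitch <- h
  ph$dims <- nd
  ph$spec <- spec
  class(ph) <- "brt_phantom"
  ph
}

#' @export
print.brt_phantom <- function(x, ...) {
  cat("Voxelized phantom:", paste(x$dims, collapse = " x "),
      sprintf("voxels at %.3g mm pitch\n", x$pitch))
  cat(sprintf("  background mu_e = %.4g, mu_f = %.4g per mm; %d inclusion(s)\n",
              x$mu_e[1, 1, 1], x$mu_f[1, 1, 1], length(x$spec$inclusions)))
  invisible(x)
}

#' Extract a (y, z) slice of optical-parameter maps
#'
#' Maps are matrices with rows indexing depth z (row 1 at the illuminated
#' face) and columns indexing the lateral coordinate y.
#'
#' @param phantom a [build_phantom()] result.
#' @param x_index slice index along x (1-based).
#' @return A list of class `"brt_slice"` with matrices `mu_e`, `mu_f`, `n`,
#'   `n_tilde` (`= sigma_e^{3/2} n`), the intrinsic coefficient maps, the
#'   pitch and extents.
#' @export
extract_slice <- function(phantom, x_index) {
  if (x_index < 1 || x_index > phantom$dims[1]) stop("x_index out of range")
  pick <- function(a) t(a[x_index, , ]) # -> [nz, ny]
  sl <- list(mu_e = pick(phantom$mu_e), mu_f = pick(phantom$mu_f),
             n = pick(phantom$n),
             mu_s_e = pick(phantom$mu_s_e), mu_s_f = pick(phantom$mu_s_f),
             mu_a_e = pick(phantom$mu_a_e), mu_a_f = pick(phantom$mu_a_f))
  sl$n_tilde <- phantom$spec$sigma_e^1.5 * sl$n
  sl$pitch <- phantom$pitch
  sl$Ly <- phantom$dims[2] * phantom$pitch
  sl$Lz <- phantom$dims[3] * phantom$pitch
  sl$sigma_e <- phantom$spec$sigma_e
  sl$x_index <- x_index
  class(sl) <- "brt_slice"
  sl
}

#' Central slice of a phantom
#'
#' Convenience wrapper: the slice through (or nearest to) the centre of the
#' first inclusion, or the middle slice for homogeneous samples.
#' @param phantom a [build_phantom()] result.
#' @return A `"brt_slice"`.
#' @export
central_slice <- function(phantom) {
  ix <- if (length(phantom$spec$inclusions)) {
    clamp_idx(as.integer(ceiling(phantom$spec$inclusions[[1]]$center_mm[1] /
                                   phantom$pitch)), phantom$dims[1])
  } else as.integer(ceiling(phantom$dims[1] / 2))
  extract_slice(phantom, ix)
}

#' Catalog of the thirteen study samples
#'
#' Returns the specifications of the simulation samples as characterized by
#' their dimensionless products: background optical depths from 0.7 to 4,
#' absorption-to-scattering ratios around 0.1, and spherical inclusions with
#' attenuation contrasts between 2.2 and 3.8.  Samples 11-13 carry the
#' contrast agent exclusively in the inclusion.  The absolute cuboid
#' dimensions are package choices (the physics depends only on the products);
#' every field can be overridden by rebuilding the spec.
#'
#' @return Named list `sample_1` ... `sample_13` of [sample_spec()] objects.
#' @export
sample_library <- function() {
  P <- spec_from_products
  list(
    sample_1 = P(c(6, 14, 4.1), 0.7, 0.63, 0.43, 4.3,
                 D = c(1.8, 1.3), D_mu_s_e = c(0.8, 0.6),
                 D_mu_s_f = c(0.7, 0.5),
                 mu_e_contrast = c(2, 4), mu_f_contrast = c(2, 4),
                 n_contrast = c(2, 4),
                 scan_type = "transmission", lambda_preset = 50),
    sample_2 = P(c(6, 13, 2), 0.7, 0.6, 0.14, 5,
                 D = 1, D_mu_s_e = 0.6, D_mu_s_f = 0.5,
                 mu_e_contrast = 2.6, mu_f_contrast = 2, n_contrast = 3.5,
                 scan_type = "backscattering", lambda_preset = 30,
                 scoring_mode = "per-direction-square"),
    sample_3 = P(c(4, 32, 5.1), 0.7, 0.6, 0.14, 5,
                 D = 1.5, D_mu_s_e = 0.4, D_mu_s_f = 0.4,
                 mu_e_contrast = 3.2, mu_f_contrast = 2, n_contrast = 5.1,
                 scan_type = "backscattering", lambda_preset = 100,
                 scoring_mode = "per-direction-square"),
    sample_4 = P(c(6, 24, 3.7), 0.7, 0.6, 0.1, 10,
                 D = 2.3, D_mu_s_e = 1.1, D_mu_s_f = 0.9,
                 mu_e_contrast = 2.3, mu_f_contrast = 2.5, n_contrast = 2,
                 scan_type = "backscattering", lambda_preset = 200,
                 scoring_mode = "per-direction-square"),
    sample_5 = P(c(6, 16, 5.1), 1.5, 1.0, 0.1, 5,
                 D = 2, D_mu_s_e = 1.8, D_mu_s_f = 1.2,
                 mu_e_contrast = 3, mu_f_contrast = 3, n_contrast = 3,
                 scan_type = "transmission", lambda_preset = 250),
    sample_6 = P(c(6, 14, 4.1), 1.5, 1.0, 0.1, 3.3,
                 D = 3, D_mu_s_e = 1.3, D_mu_s_f = 0.9,
                 mu_e_contrast = 2.3, mu_f_contrast = 2, n_contrast = 3.5,
                 scan_type = "transmission", lambda_preset = 50),
    sample_7 = P(c(6, 16, 5.1), 1.5, 1.0, 0.1, 0.5,
                 D = 2, D_mu_s_e = 1.8, D_mu_s_f = 1.2,
                 mu_e_contrast = 3.7, mu_f_contrast = 3, n_contrast = 18,
                 scan_type = "transmission", lambda_preset = 100),
    sample_8 = P(c(6, 16, 5.1), 1.5, 1.0, 0.1, 0.25,
                 D = 2, D_mu_s_e = 1.8, D_mu_s_f = 1.2,
                 mu_e_contrast = 3.7, mu_f_contrast = 3, n_contrast = 36,
                 scan_type = "transmission", lambda_preset = 50),
    sample_9 = P(c(6, 16, 5.1), 3.0, 2.0, 0.1, 2.5,
                 D = 2, D_mu_s_e = 3.5, D_mu_s_f = 2.4,
                 mu_e_contrast = 3, mu_f_contrast = 3, n_contrast = 3,
                 scan_type = "transmission", lambda_preset = 50),
    sample_10 = P(c(6, 14, 4.1), 3.0, 2.5, 0.1, 1.6,
                  D = 3, D_mu_s_e = 2.6, D_mu_s_f = 2.1,
                  mu_e_contrast = 2.2, mu_f_contrast = 2, n_contrast = 3.5,
                  scan_type = "transmission", lambda_preset = 25),
    sample_11 = P(c(6, 16, 5.1), 3.0, 2.0, 0.1, 0,
                  D = 2, D_mu_s_e = 3.5, D_mu_s_f = 2.4,
                  mu_e_contrast = 3.7, mu_f_contrast = 3,
                  incl_sigma_n_over_mu_a = 7.5,
                  scan_type = "transmission", lambda_preset = 50),
    sample_12 = P(c(4, 20, 3.1), 3.0, 2.0, 0.1, 0,
                  D = 1.5, D_mu_s_e = 4.4, D_mu_s_f = 2.9,
                  mu_e_contrast = 3.7, mu_f_contrast = 3,
                  incl_sigma_n_over_mu_a = 7.5,
                  scan_type = "backscattering", lambda_preset = 100,
                  scoring_mode = "per-direction-square"),
    sample_13 = P(c(6, 16, 5.1), 4.0, 3.6, 0.1, 0,
                  D = 2, D_mu_s_e = 4.7, D_mu_s_f = 4.2,
                  mu_e_contrast = 3.8, mu_f_contrast = 3,
                  incl_sigma_n_over_mu_a = 9,
                  scan_type = "transmission", lambda_preset = 50)
  )
}

#' Desk-scale variant of the weakly scattering study sample
#'
#' A reduced cuboid with the same dimensionless characterization as the
#' weakly scattering sample (background optical depth 0.7 at excitation,
#' 0.63 at emission, `mu_a/mu_s = 0.43`, `sigma*n/mu_a = 4.3`) and a single
#' inclusion of contrast 2.  Intended for fast Monte Carlo validation runs.
#'
#' @param Lz sample depth in mm (default 3).
#' @param Ly,Lx lateral extents in mm.
#' @param D inclusion diameter in mm.
#' @return A [sample_spec()].
#' @export
mini_sample <- function(Lz = 3, Ly = 12, Lx = 4, D = 1) {
  spec_from_products(c(Lx, Ly, Lz), 0.7, 0.63, 0.43, 4.3,
                     D = D, D_mu_s_e = 0.8 * D / 1.8, D_mu_s_f = 0.7 * D / 1.8,
                     mu_e_contrast = 2, mu_f_contrast = 2, n_contrast = 2,
                     scan_type = "transmission", lambda_preset = 5)
}
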