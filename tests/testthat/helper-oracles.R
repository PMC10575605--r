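# Independent oracles and shared fixtures for the test suite.

# --- ray-integral oracles ---------------------------------------------------

# Exact integral of a voxelized slice map along a ray, by sorting all
# voxel-plane crossings and accumulating chord * value.  Independent of the
# package's incremental voxel walk.
oracle_ray_integral_crossings <- function(map, h, start, dir, tmax = Inf) {
  d <- dir / sqrt(sum(dir^2))
  ny <- ncol(map); nz <- nrow(map)
  Ly <- ny * h; Lz <- nz * h
  tend <- tmax
  if (d[1] > 0) tend <- min(tend, (Ly - start[1]) / d[1])
  if (d[1] < 0) tend <- min(tend, -start[1] / d[1])
  if (d[2] > 0) tend <- min(tend, (Lz - start[2]) / d[2])
  if (d[2] < 0) tend <- min(tend, -start[2] / d[2])
  if (tend <= 0) return(0)
  ts <- c(0, tend)
  if (abs(d[1]) > 1e-14) ts <- c(ts, ((0:ny) * h - start[1]) / d[1])
  if (abs(d[2]) > 1e-14) ts <- c(ts, ((0:nz) * h - start[2]) / d[2])
  ts <- sort(unique(pmin(pmax(ts, 0), tend)))
  acc <- 0
  for (i in seq_len(length(ts) - 1)) {
    t0 <- ts[i]; t1 <- ts[i + 1]
    if (t1 - t0 < 1e-14) next
    mid <- start + 0.5 * (t0 + t1) * d
    iy <- min(max(floor(mid[1] / h) + 1, 1), ny)
    iz <- min(max(floor(mid[2] / h) + 1, 1), nz)
    acc <- acc + map[iz, iy] * (t1 - t0)
  }
  acc
}

# Dense midpoint sampling (step in mm); approximate but implementation-free.
oracle_ray_integral_midpoint <- function(map, h, start, dir, tmax = Inf,
                                         step = 1e-4) {
  d <- dir / sqrt(sum(dir^2))
  ny <- ncol(map); nz <- nrow(map)
  Ly <- ny * h; Lz <- nz * h
  tend <- tmax
  if (d[1] > 0) tend <- min(tend, (Ly - start[1]) / d[1])
  if (d[1] < 0) tend <- min(tend, -start[1] / d[1])
  if (d[2] > 0) tend <- min(tend, (Lz - start[2]) / d[2])
  if (d[2] < 0) tend <- min(tend, -start[2] / d[2])
  if (tend <= 0) return(0)
  tt <- seq(step / 2, tend, by = step)
  yy <- start[1] + tt * d[1]; zz <- start[2] + tt * d[2]
  iy <- pmin(pmax(floor(yy / h) + 1, 1), ny)
  iz <- pmin(pmax(floor(zz / h) + 1, 1), nz)
  sum(map[cbind(iz, iy)]) * step
}

# --- angular-window oracle --------------------------------------------------

# Brute-force scan of the acceptance-cone directions: a direction is
# admissible if its back-ray from r meets the source ray in front of both
# (t >= 0 toward the vertex, xi >= 0 from the source).  Returns the angular
# measure and the extreme polar angles about the line of sight.
oracle_theta_scan <- function(r, r_s, s_l, s_k, beta, n = 1e5) {
  A <- atan2(r[2] - r_s[2], r[1] - r_s[1])
  psik <- atan2(s_k[2], s_k[1])
  psi <- psik + beta * (2 * (seq_len(n) - 0.5) / n - 1)
  sy <- cos(psi); sz <- sin(psi)
  by <- r[1] - r_s[1]; bz <- r[2] - r_s[2]
  dt <- sy * s_l[2] - sz * s_l[1]
  tt <- (by * s_l[2] - bz * s_l[1]) / dt
  xi <- (sy * bz - sz * by) / dt
  ok <- abs(dt) > 1e-14 & tt >= 0 & xi >= 0
  if (!any(ok)) return(list(width = 0, theta_min = NA, theta_max = NA))
  th <- abs(atan2(sin(psi - A), cos(psi - A)))
  list(width = 2 * beta * mean(ok),
       theta_min = min(th[ok]), theta_max = max(th[ok]),
       resolution = 2 * beta / n)
}

# --- SSIM oracle ------------------------------------------------------------

# Naive per-pixel SSIM with an explicit double loop over window offsets,
# symmetric padding, Gaussian weights.  Same mathematical definition as the
# package routine, independent code path.
oracle_ssim <- function(x, y, window = 7, sigma = 1.5, data_range = NULL,
                        K1 = 0.01, K2 = 0.03) {
  if (is.null(data_range)) data_range <- max(y)
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  half <- (window - 1) / 2
  g1 <- exp(-((-half):half)^2 / (2 * sigma^2)); g1 <- g1 / sum(g1)
  W <- outer(g1, g1)
  nr <- nrow(x); nc <- ncol(x)
  reflect <- function(i, n) {
    i[i < 1] <- 1 - i[i < 1]
    i[i > n] <- 2 * n + 1 - i[i > n]
    i
  }
  s <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- reflect(i + (-half):half, nr)
    cj <- reflect(j + (-half):half, nc)
    px <- x[ri, cj]; py <- y[ri, cj]
    mx <- sum(W * px); my <- sum(W * py)
    vx <- sum(W * px^2) - mx^2; vy <- sum(W * py^2) - my^2
    cv <- sum(W * px * py) - mx * my
    s[i, j] <- ((2 * mx * my + C1) * (2 * cv + C2)) /
      ((mx^2 + my^2 + C1) * (vx + vy + C2))
  }
  mean(s)
}

# --- shared fixtures --------------------------------------------------------

# A slice with independent mu_e, mu_f, n_tilde maps (not tied to a physical
# phantom); used for forward/projection algebra tests.
make_raw_slice <- function(mu_e, mu_f, n_tilde, pitch = 0.1) {
  structure(list(mu_e = mu_e, mu_f = mu_f, n_tilde = n_tilde,
                 n = n_tilde, pitch = pitch,
                 Ly = ncol(mu_e) * pitch, Lz = nrow(mu_e) * pitch,
                 sigma_e = 1, x_index = 1L),
            class = "brt_slice")
}

homog_slice <- function(nz, ny, mu_e, mu_f, n_tilde = 1, pitch = 0.1) {
  make_raw_slice(matrix(mu_e, nz, ny), matrix(mu_f, nz, ny),
                 matrix(n_tilde, nz, ny), pitch)
}

# cache expensive fixtures across test files
.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

mini_fit_fixture <- function() {
  fixture("mini_fit", function() {
    spec <- mini_sample()
    ph <- build_phantom(spec)
    sl <- central_slice(ph)
    geom <- scan_directions("transmission")
    det <- detector_spec(0.07, 0.5)
    scan <- assemble_scan(sl, geom, det)
    list(spec = spec, phantom = ph, slice = sl, geom = geom, det = det,
         scan = scan, fit = nrbrt(scan))
  })
}

# interior mask: at least `margin` pixels from the ROI edges and from the
# boundary circle of every inclusion
interior_mask <- function(fit, spec, margin = 5) {
  nz <- nrow(fit$mu_plus); ny <- ncol(fit$mu_plus)
  Y <- matrix(rep(fit$ys, each = nz), nz, ny)
  Z <- matrix(rep(fit$zs, times = ny), nz, ny)
  keep <- matrix(TRUE, nz, ny)
  keep[seq_len(margin), ] <- FALSE; keep[nz - seq_len(margin) + 1, ] <- FALSE
  keep[, seq_len(margin)] <- FALSE; keep[, ny - seq_len(margin) + 1] <- FALSE
  for (inc in spec$inclusions) {
    dcirc <- abs(sqrt((Y - inc$center_mm[2])^2 + (Z - inc$center_mm[3])^2) -
                   inc$diameter_mm / 2)
    keep <- keep & dcirc > margin * fit$h
  }
  keep
}
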