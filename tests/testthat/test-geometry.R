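# Scan directions, vertices, acceptance windows, geometric factors.

test_that("scan directions have the stated angles and unit norms", {
  tr <- scan_directions("transmission")
  bs <- scan_directions("backscattering")
  expect_equal(tr$angles_deg, c(0, 45, -45))
  expect_equal(bs$angles_deg, c(0, 45, -70))
  for (g in list(tr, bs)) {
    expect_equal(colSums(g$u^2), rep(1, 3))
    expect_equal(g$u[, 1], c(0, -1)) # direction 1 normal to the surface
  }
  # transmission: oblique directions at 135 degrees to direction 1,
  # mutually orthogonal
  expect_equal(sum(tr$u[, 1] * tr$u[, 2]), cos(135 * pi / 180))
  expect_equal(sum(tr$u[, 2] * tr$u[, 3]), 0)
  # line angles to the surface normal
  expect_equal(abs(asin(bs$u[1, 2])) * 180 / pi, 45)
  expect_equal(abs(asin(bs$u[1, 3])) * 180 / pi, 70, tolerance = 1e-9)
})

test_that("ray vertex solves elementary and random intersections", {
  Lz <- 5
  # source at (y=0, z=0) along +z; detector line through (2, Lz) along
  # outward (1, 1)/sqrt(2): line of sight descends toward (0, Lz - 2)
  v <- ray_vertex(c(0, 0), c(0, 1), c(2, Lz), c(1, 1) / sqrt(2))
  expect_equal(v$point, c(0, Lz - 2), tolerance = 1e-12)
  # random configurations: residual distance to each line below 1e-12 mm
  set.seed(7)
  for (i in 1:200) {
    r_s <- runif(2, 0, 10); r_d <- runif(2, 0, 10)
    a1 <- runif(1, 0, 2 * pi); a2 <- a1 + runif(1, 0.1, pi - 0.1)
    s_l <- c(cos(a1), sin(a1)); s_k <- c(cos(a2), sin(a2))
    v <- ray_vertex(r_s, s_l, r_d, s_k)
    d1 <- v$point - (r_s + v$t * s_l)
    d2 <- v$point - (r_d - v$u * s_k)
    expect_lt(sqrt(sum(d1^2)) + sqrt(sum(d2^2)), 1e-12)
  }
  expect_error(ray_vertex(c(0, 0), c(0, 1), c(1, 0), c(0, 1)), "parallel")
})

test_that("broken rays have consistent legs and flags", {
  Lz <- 5; box <- c(10, Lz)
  br <- broken_ray(c(0, 0), c(0, 1), c(2, Lz), c(1, 1) / sqrt(2), box)
  expect_true(br$valid)
  expect_equal(br$L1, Lz - 2, tolerance = 1e-12)
  expect_equal(br$L2, 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(sum(br$u_l * -c(0, 1)), 1, tolerance = 1e-12) # antiparallel
  set.seed(11)
  for (i in 1:100) {
    r_s <- c(runif(1, 0, 10), 0); r_d <- c(runif(1, 0, 10), Lz)
    s_l <- c(runif(1, -0.5, 0.5), 1); s_l <- s_l / sqrt(sum(s_l^2))
    s_k <- c(runif(1, -0.5, 0.5), 1); s_k <- s_k / sqrt(sum(s_k^2))
    br <- tryCatch(broken_ray(r_s, s_l, r_d, s_k, box),
                   error = function(e) NULL)
    if (is.null(br)) next
    expect_gte(br$L1 + br$L2, sqrt(sum((r_d - r_s)^2)) - 1e-12)
  }
})

test_that("angular window matches the brute-force scan on random configurations", {
  set.seed(101)
  worst <- 0
  for (i in 1:300) {
    r_s <- runif(2, 0, 10)
    r <- r_s + runif(2, -5, 5)
    if (sum((r - r_s)^2) < 0.1) next
    a1 <- runif(1, 0, 2 * pi); a2 <- runif(1, 0, 2 * pi)
    s_l <- c(cos(a1), sin(a1)); s_k <- c(cos(a2), sin(a2))
    beta <- runif(1, 0.002, 0.4)
    w <- theta_window(r, r_s, s_l, s_k, beta)
    o <- oracle_theta_scan(r, r_s, s_l, s_k, beta, n = 2e4)
    res <- 2 * beta / 2e4
    expect_lt(abs(w$width - o$width), 2 * res + 1e-12)
    if (o$width > 0 && w$width > 0) {
      worst <- max(worst, abs(w$theta_min - o$theta_min) / res,
                   abs(w$theta_max - o$theta_max) / res)
    }
  }
  expect_lt(worst, 1 + 1e-9) # endpoints within one scan-resolution step
})

test_that("window limits: zero at beta -> 0, full cone on the source ray", {
  r_s <- c(1, 0); s_l <- c(0, 1)
  r <- c(4, 3); s_k <- c(1, 1) / sqrt(2)
  w1 <- theta_window(r, r_s, s_l, s_k, 1e-4)
  w2 <- theta_window(r, r_s, s_l, s_k, 1e-6)
  expect_lte(w1$width, 2e-4 + 1e-12)
  expect_lte(w2$width, 2e-6 + 1e-12)
  # r on the source ray, collimation pointing back at the source: the
  # symmetric cone is fully admissible
  r_on <- c(1, 4)
  w <- theta_window(r_on, r_s, s_l, -c(0, 1), pi / 180)
  expect_equal(w$width, 2 * pi / 180, tolerance = 1e-9)
  o <- oracle_theta_scan(r_on, r_s, s_l, -c(0, 1), pi / 180, n = 1e4)
  expect_equal(w$width, o$width, tolerance = 4 * 2 * (pi / 180) / 1e4)
  # delta theta never exceeds 2 beta
  set.seed(5)
  for (i in 1:100) {
    r <- runif(2, 0, 6); rs <- runif(2, 0, 6)
    if (sum((r - rs)^2) < 0.1) next
    b <- runif(1, 0.01, 1)
    a1 <- runif(1, 0, 2 * pi); a2 <- runif(1, 0, 2 * pi)
    w <- theta_window(r, rs, c(cos(a1), sin(a1)), c(cos(a2), sin(a2)), b)
    expect_lte(w$width, 2 * b + 1e-12)
  }
})

test_that("pointwise geometric factor scales as the formula dictates", {
  r_s <- c(1, 0); s_l <- c(0, 1); beta <- pi / 180
  # on the source ray the window is always the full cone, so doubling the
  # distance exactly halves f... but sin(theta_l)=0 there is degenerate;
  # use a mirror-symmetric configuration with theta_l = 90 deg instead
  r1 <- c(3, 2); r2 <- r_s + 2 * (r1 - r_s)
  s_k1 <- (r1 - c(1, 2)) / sqrt(sum((r1 - c(1, 2))^2)) # aims r back at the ray
  w1 <- theta_window(r1, r_s, s_l, s_k1, beta)
  f1 <- geom_factor(r1, r_s, s_l, s_k1, beta)
  expect_equal(f1, w1$width / (sqrt(sum((r1 - r_s)^2)) * sin(w1$theta_l)))
  # empty window -> zero factor (back-ray meets the source-ray extension
  # behind the source, xi < 0, for the whole narrow cone)
  f0 <- geom_factor(c(3, -2), r_s, s_l, c(1, 1) / sqrt(2), 0.01)
  expect_equal(f0, 0)
  # degenerate: observation point on the source ray
  expect_error(geom_factor(c(1, 3), r_s, s_l, c(0, 1), 0.1), "degenerate")
})

test_that("finite-detector factor converges, scales with area, and is translation invariant", {
  det <- detector_spec(0.07, 0.5)
  Lz <- 5
  r_s <- c(5, 0); s_l <- c(0, 1)
  s_k <- c(1, 1) / sqrt(2)
  r_d <- c(8.5, Lz) # far regime: separation >> delta_d
  fb21 <- geom_factor_bar(det, r_d, s_k, r_s, s_l, nq = 21)
  fb201 <- geom_factor_bar(det, r_d, s_k, r_s, s_l, nq = 201)
  expect_gt(fb21, 0)
  expect_equal(fb21, fb201, tolerance = 1e-3) # quadrature refinement
  # midpoint approximation: area x f(centre)
  f_mid <- geom_factor(r_d, r_s, s_l, s_k, det$beta)
  area <- det$delta_d * det$delta_d / abs(s_k[2])
  expect_equal(fb201, area * f_mid, tolerance = 0.01)
  # halving delta_d reduces f_bar about 4-fold in the far regime
  det_half <- detector_spec(0.035, 0.5)
  fb_half <- geom_factor_bar(det_half, r_d, s_k, r_s, s_l, nq = 201)
  expect_equal(fb201 / fb_half, 4, tolerance = 0.02)
  # translation of the whole configuration parallel to the surface
  shift <- c(1.3, 0)
  fb_shift <- geom_factor_bar(det, r_d + shift, s_k, r_s + shift, s_l, nq = 21)
  expect_equal(fb_shift, fb21, tolerance = 1e-12)
})

test_that("the 3D-cone x-extent saturates to the collapsed form in the far regime", {
  det <- detector_spec(0.07, 0.5)
  r_s <- c(5, 0); s_l <- c(0, 1); s_k <- c(1, 1) / sqrt(2); r_d <- c(8.5, 5)
  # far regime: cone footprint much wider than the detector
  fb_flat <- geom_factor_bar(det, r_d, s_k, r_s, s_l)
  fb_cone <- geom_factor_bar(det, r_d, s_k, r_s, s_l,
                             x_mode = "cone", rho = 50)
  expect_equal(fb_cone, fb_flat, tolerance = 0.005)
  # near the face the cone footprint truncates the x-extent to pi*beta*rho/2
  rho_near <- 0.2
  fb_near <- geom_factor_bar(det, r_d, s_k, r_s, s_l,
                             x_mode = "cone", rho = rho_near)
  expect_equal(fb_near / fb_flat,
               (pi * det$beta * rho_near / 2) / det$delta_d, tolerance = 1e-6)
  expect_error(geom_factor_bar(det, r_d, s_k, r_s, s_l, x_mode = "cone"),
               "rho")
})
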