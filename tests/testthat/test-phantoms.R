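# Voxelized sample construction and the study-sample catalog.

test_that("homogeneous spec fills every voxel with background values", {
  spec <- sample_spec(c(2, 3, 5.1), bg_mu_s_e = 0.2, bg_mu_s_f = 0.15,
                      bg_mu_a_e = 0.02, bg_mu_a_f = 0.015, bg_n = 0.1)
  ph <- build_phantom(spec)
  expect_equal(dim(ph$mu_e), c(20L, 30L, 51L))
  expect_equal(dim(ph$mu_e)[3], round(5.1 / 0.1)) # 51 voxels along z
  expect_true(all(ph$mu_s_e == 0.2))
  expect_true(all(ph$n == 0.1))
  expect_equal(unique(as.vector(ph$mu_e)), 0.02 + 0.2 + 0.1 * 1)
  expect_equal(unique(as.vector(ph$mu_f)), 0.015 + 0.15)
})

test_that("an optical depth of 0.7 over 14.1 mm gives the implied background scattering", {
  spec <- spec_from_products(c(2, 4, 14.1), 0.7, 0.63, 0.1, 5)
  expect_equal(spec$bg_mu_s_e, 0.7 / 14.1, tolerance = 1e-12)
  expect_equal(spec$bg_mu_s_e, 0.0496, tolerance = 1e-3)
  # re-multiplying recovers the printed optical depth
  expect_equal(spec$dims_mm[3] * spec$bg_mu_s_e, 0.7, tolerance = 1e-12)
})

test_that("total attenuation exceeds the intrinsic part wherever fluorophore is present", {
  spec <- mini_sample()
  ph <- build_phantom(spec)
  expect_true(all(ph$mu_e >= ph$mu_a_e + ph$mu_s_e - 1e-15))
  # mu_f carries no fluorophore term
  expect_equal(ph$mu_f, ph$mu_a_f + ph$mu_s_f)
})

test_that("slice extraction returns disks of the expected size and ordering", {
  spec <- sample_spec(c(4, 6, 4), bg_mu_s_e = 0.1, bg_mu_s_f = 0.1,
                      bg_mu_a_e = 0.01, bg_mu_a_f = 0.01, bg_n = 0.05,
                      inclusions = list(inclusion(c(2, 3, 2), 2, 0.15, 0.15,
                                                  2, 2, n_contrast = 2)))
  ph <- build_phantom(spec)
  sl_mid <- extract_slice(ph, 20)   # through the centre
  sl_off <- extract_slice(ph, 26)   # 0.55 mm off-centre
  disk_mid <- sum(sl_mid$n > 0.05)
  disk_off <- sum(sl_off$n > 0.05)
  expect_gt(disk_mid, disk_off)     # central slice has the larger disk
  # disk diameter ~ D at the central slice
  cols <- which(apply(sl_mid$n > 0.05, 2, any))
  expect_equal(length(cols) * 0.1, 2, tolerance = 0.1)
  # homogeneous phantom: any slice constant
  ph0 <- build_phantom(mini_sample(D = 0.4)) # small inclusion
  sl0 <- extract_slice(ph0, 2)               # far from the inclusion
  expect_equal(length(unique(as.vector(sl0$mu_e))), 1L)
  expect_error(extract_slice(ph, 1000), "out of range")
})

test_that("overlapping inclusions are rejected", {
  expect_error(
    sample_spec(c(6, 6, 6), bg_mu_s_e = 0.1, bg_mu_s_f = 0.1,
                bg_mu_a_e = 0.01, bg_mu_a_f = 0.01, bg_n = 0.1,
                inclusions = list(
                  inclusion(c(3, 2.5, 3), 2, 0.4, 0.4, 2, 2, 2),
                  inclusion(c(3, 3.5, 3), 2, 0.4, 0.4, 2, 2, 2))),
    "overlap")
})

test_that("catalog reproduces the tabulated dimensionless products", {
  lib <- sample_library()
  expect_length(lib, 13)
  p5 <- dimensionless_products(lib$sample_5)
  expect_equal(p5$Lz_mu_s_e, 1.5, tolerance = 1e-12)
  expect_equal(p5$mu_a_over_mu_s, 0.1, tolerance = 1e-12)
  expect_equal(p5$sigma_n_over_mu_a, 5, tolerance = 1e-12)
  p1 <- dimensionless_products(lib$sample_1)
  expect_equal(p1$Lz_mu_s_e, 0.7, tolerance = 1e-12)
  expect_equal(p1$Lz_mu_s_f, 0.63, tolerance = 1e-12)
  expect_equal(p1$inclusions$n_contrast, c(2, 4), tolerance = 1e-12)
  # round-trip: every spec builds, and the products recomputed from the
  # built phantom match the catalog values
  for (id in names(lib)) {
    spec <- lib[[id]]
    ph <- build_phantom(spec)
    expect_equal(ph$dims[3] * ph$pitch * ph$mu_s_e[1, 1, 1],
                 dimensionless_products(spec)$Lz_mu_s_e, tolerance = 1e-9,
                 label = id)
    expect_true(all(ph$mu_a_e >= 0) && all(ph$mu_a_f >= 0), label = id)
  }
})

test_that("raising the fluorophore concentration changes mu_e and n but never mu_f", {
  base <- function(bgn, nc = 2) {
    sample_spec(c(3, 4, 3), bg_mu_s_e = 0.2, bg_mu_s_f = 0.2,
                bg_mu_a_e = 0.02, bg_mu_a_f = 0.02, bg_n = bgn,
                inclusions = list(inclusion(c(1.5, 2, 1.5), 1, 0.5, 0.3,
                                            3, 2, n_contrast = nc)))
  }
  # more agent in the background: mu_e = mu_a + mu_s + n*sigma grows with n,
  # mu_f is blind to the agent (no reabsorption at the emission wavelength)
  a <- build_phantom(base(0.05)); b <- build_phantom(base(0.1))
  expect_false(identical(a$n, b$n))
  expect_false(identical(a$mu_e, b$mu_e))
  expect_identical(a$mu_f, b$mu_f)
  expect_identical(a$mu_s_f, b$mu_s_f)
  # a higher inclusion contrast redistributes n inside the sphere; mu_f of
  # the inclusion is pinned by its own contrast and stays unchanged
  c2 <- build_phantom(base(0.05, nc = 3))
  expect_false(identical(a$n, c2$n))
  expect_identical(a$mu_f, c2$mu_f)
})

test_that("voxelized inclusion volume approximates the sphere volume", {
  D <- 1.2 # 12 voxel pitches
  spec <- sample_spec(c(3, 3, 3), bg_mu_s_e = 0.1, bg_mu_s_f = 0.1,
                      bg_mu_a_e = 0.01, bg_mu_a_f = 0.01, bg_n = 0.1,
                      inclusions = list(inclusion(c(1.5, 1.5, 1.5), D,
                                                  0.1, 0.1, 2, 2, 2)))
  ph <- build_phantom(spec)
  nvox <- sum(ph$n > 0.1)
  expect_equal(nvox, (pi / 6) * D^3 / 0.1^3, tolerance = 0.05)
})

test_that("sample specs survive YAML and JSON round trips", {
  spec <- mini_sample()
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_sample_spec(spec, f)
    back <- read_sample_spec(f)
    expect_equal(back$bg_mu_s_e, spec$bg_mu_s_e)
    expect_equal(back$inclusions[[1]]$center_mm, spec$inclusions[[1]]$center_mm)
    expect_equal(dimensionless_products(back), dimensionless_products(spec))
    unlink(f)
  }
})

test_that("phantom TIFF export writes one page per slice and parameter", {
  ph <- build_phantom(mini_sample(Lz = 1, Ly = 2, Lx = 0.5, D = 0.4))
  f <- tempfile(fileext = ".tif")
  out <- write_phantom_tiff(ph, f, what = c("mu_e", "n"))
  pages <- tiff::readTIFF(f, all = TRUE)
  expect_length(pages, 2 * dim(ph$mu_e)[1])
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$scale, attr(out, "scale"))
  expect_equal(pages[[1]] * side$scale, t(ph$mu_e[1, , ]), tolerance = 1e-6)
  unlink(c(f, paste0(f, ".json")))
})
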