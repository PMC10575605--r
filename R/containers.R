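# On-disk interchange: sample specs as YAML/JSON, phantoms as multi-page
# TIFF, and scans/reconstructions as structured directory containers
# (named CSV datasets plus a JSON metadata sidecar).

#' Write / read a sample specification
#'
#' Format chosen by extension: `.yaml`/`.yml` or `.json`.
#' @param spec a [sample_spec()].
#' @param path file path.
#' @return `read_sample_spec` returns a [sample_spec()].
#' @export
write_sample_spec <- function(spec, path) {
  x <- unclass(spec)
  x$inclusions <- lapply(spec$inclusions, unclass)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 15L)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_sample_spec
#' @export
read_sample_spec <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = FALSE)
  num1 <- function(v, default = NA_real_) {
    v <- suppressWarnings(as.numeric(unlist(v)))
    if (!length(v) || all(is.na(v))) default else v[1]
  }
  incs <- lapply(x$inclusions, function(i) {
    inclusion(as.numeric(unlist(i$center_mm)), num1(i$diameter_mm),
              num1(i$mu_s_e), num1(i$mu_s_f),
              num1(i$mu_e_contrast), num1(i$mu_f_contrast),
              n_contrast = num1(i$n_contrast),
              n_value = num1(i$n_value))
  })
  sample_spec(as.numeric(unlist(x$dims_mm)), voxel_pitch = num1(x$voxel_pitch, 0.1),
              bg_mu_s_e = num1(x$bg_mu_s_e), bg_mu_s_f = num1(x$bg_mu_s_f),
              bg_mu_a_e = num1(x$bg_mu_a_e), bg_mu_a_f = num1(x$bg_mu_a_f),
              bg_n = num1(x$bg_n, 0), sigma_e = num1(x$sigma_e, 1),
              inclusions = incs,
              scan_type = unlist(x$scan_type)[1],
              lambda_preset = num1(x$lambda_preset, 50),
              scoring_mode = unlist(x$scoring_mode)[1])
}

#' Export phantom parameter maps as multi-page TIFF
#'
#' One 32-bit page per slice (x index) and parameter.  TIFF stores values in
#' [0, 1], so all pages are divided by a common scale (the global maximum),
#' which is recorded in a JSON sidecar `<path>.json` for exact restoration.
#'
#' @param phantom a [build_phantom()] result.
#' @param path output `.tif` path.
#' @param what parameter grids to export.
#' @return The path, invisibly, with attribute `"scale"`.
#' @export
write_phantom_tiff <- function(phantom, path, what = c("mu_e", "mu_f", "n")) {
  pages <- list()
  for (q in what) {
    a <- phantom[[q]]
    for (ix in seq_len(dim(a)[1]))
      pages[[length(pages) + 1]] <- t(a[ix, , ]) # rows z, cols y
  }
  scale <- max(1e-300, max(vapply(pages, max, numeric(1))))
  tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                  bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(scale = scale, what = what,
                            pages_per_parameter = dim(phantom$mu_e)[1],
                            pitch = phantom$pitch),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(structure(path, scale = scale))
}

#' Write / read a scan container
#'
#' A directory holding one CSV per data-function map (`phi_12.csv`, ...),
#' matching mask CSVs, and `meta.json` with the geometry, detector,
#' constants and provenance.
#'
#' @param scan a [assemble_scan()] result.
#' @param dir container directory (created if needed).
#' @return `read_scan_container` returns a `"brt_scan"` (without the truth
#'   slice, which is not serialized).
#' @export
write_scan_container <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(scan$phi)) {
    write.csv(scan$phi[[key]], file.path(dir, paste0("phi_", key, ".csv")),
              row.names = FALSE)
    write.csv(scan$mask[[key]] * 1L,
              file.path(dir, paste0("mask_", key, ".csv")), row.names = FALSE)
  }
  meta <- list(ys = scan$ys, zs = scan$zs, h = scan$h, roi = scan$roi,
               scan_type = scan$geometry$scan_type,
               detector = unclass(scan$detector)[c("delta_d", "beta_deg",
                                                   "eta0", "scoring_mode")],
               constants = unclass(scan$constants),
               engine = scan$engine, N = scan$N, seed = scan$seed,
               Ly = scan$Ly, Lz = scan$Lz, pairs = names(scan$phi))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_scan_container
#' @export
read_scan_container <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  phi <- list(); mask <- list()
  for (key in meta$pairs) {
    phi[[key]] <- as.matrix(read.csv(file.path(dir, paste0("phi_", key, ".csv"))))
    mask[[key]] <- as.matrix(read.csv(file.path(dir, paste0("mask_", key, ".csv")))) == 1
    dimnames(phi[[key]]) <- NULL; dimnames(mask[[key]]) <- NULL
  }
  structure(list(phi = phi, mask = mask, ys = meta$ys, zs = meta$zs,
                 h = meta$h, roi = meta$roi,
                 geometry = scan_directions(meta$scan_type),
                 detector = detector_spec(meta$detector$delta_d,
                                          meta$detector$beta_deg,
                                          meta$detector$eta0,
                                          meta$detector$scoring_mode),
                 constants = do.call(beam_constants, meta$constants),
                 engine = meta$engine, N = meta$N, seed = meta$seed,
                 Ly = meta$Ly, Lz = meta$Lz, truth = NULL,
                 coverage = character()),
            class = "brt_scan")
}
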