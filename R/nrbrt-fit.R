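# The model-fitting front end: estimate attenuation and concentration maps
# from a broken-ray scan, in the style of a classed fit object.

#' Fit the non-reciprocal broken-ray tomography model to a scan
#'
#' Reconstructs the spectrally averaged attenuation `mu(+)`, the spectral
#' difference `mu(-)`, the per-wavelength attenuations `mu_e`, `mu_f`, and
#' the max-normalized fluorophore concentration from a complete scan of
#' data functions.  When the scan carries ground truth (synthetic data),
#' RMSE/SSIM metrics are attached.
#'
#' @param scan a [assemble_scan()] result.
#' @param lambda TV regularization weight; default 0 (plain centred
#'   differences) for noise-free analytic scans and the sample's preset for
#'   Monte Carlo scans is a sensible starting point.
#' @param median_kernel median prefilter window; default 1 for analytic
#'   scans, 3 for Monte Carlo scans.
#' @param pad_pixels duplicated edge pixels before differentiation.
#' @param n_mode concentration mode, see [reconstruct_n()]; `"none"` skips it.
#' @param pair direction pair for modes `"eq9"` / `"eq12"`.
#' @param evaluate compute metrics against the scan's stored truth.
#' @return Object of class `"nrbrt"` with components `mu_plus`, `mu_minus`,
#'   `mu_e`, `mu_f`, `n_norm`, `mask`, `weights`, `config`, `scan` metadata,
#'   `truth` maps (cropped to the region of interest) and `metrics`.
#' @seealso [reconstruct_mu()], [reconstruct_n()], [metrics_report()]
#' @examples
#' spec <- mini_sample()
#' ph <- build_phantom(spec)
#' sl <- central_slice(ph)
#' geom <- scan_directions("transmission")
#' det <- detector_spec(delta_d = 0.07, beta_deg = 0.5)
#' scan <- assemble_scan(sl, geom, det)
#' fit <- nrbrt(scan)
#' summary(fit)
#' @export
nrbrt <- function(scan, lambda = NULL, median_kernel = NULL, pad_pixels = 10,
                  n_mode = c("eq11", "eq9", "eq12", "none"),
                  pair = c(1, 2), evaluate = TRUE) {
  n_mode <- match.arg(n_mode)
  if (is.null(lambda)) lambda <- if (scan$engine == "analytic") 0 else 5
  if (is.null(median_kernel))
    median_kernel <- if (scan$engine == "analytic") 1L else 3L
  config <- inversion_config(lambda = lambda, median_kernel = median_kernel,
                             pad_pixels = pad_pixels)
  mu <- reconstruct_mu(scan, config)
  nrec <- NULL
  if (n_mode != "none") {
    nrec <- tryCatch(
      reconstruct_n(scan, mu$mu_plus, mode = n_mode, pair = pair,
                    config = config),
      error = function(e) {
        warning("concentration not reconstructed: ", conditionMessage(e))
        NULL
      })
  }

  truth <- NULL; metrics <- NULL
  if (!is.null(scan$truth)) {
    roi <- scan$roi
    tr <- scan$truth
    t_mu_e <- tr$mu_e[roi$iz, roi$iy, drop = FALSE]
    t_mu_f <- tr$mu_f[roi$iz, roi$iy, drop = FALSE]
    t_nt <- tr$n_tilde[roi$iz, roi$iy, drop = FALSE]
    truth <- list(mu_plus = (t_mu_e + t_mu_f) / 2,
                  mu_minus = t_mu_e - t_mu_f,
                  mu_e = t_mu_e, mu_f = t_mu_f,
                  n_norm = if (max(t_nt) > 0) t_nt / max(t_nt) else t_nt)
    if (evaluate) {
      maps <- list(mu_plus = mu$mu_plus, mu_minus = mu$mu_minus,
                   mu_e = mu$mu_e, mu_f = mu$mu_f)
      if (!is.null(nrec)) maps$n_norm <- nrec$n_norm
      metrics <- metrics_report(
        maps, truth,
        provenance = list(lambda = lambda, median_kernel = median_kernel,
                          beta_deg = scan$detector$beta_deg,
                          delta_d = scan$detector$delta_d,
                          engine = scan$engine, N = scan$N))
    }
  }

  structure(list(mu_plus = mu$mu_plus, mu_minus = mu$mu_minus,
                 mu_e = mu$mu_e, mu_f = mu$mu_f,
                 n_norm = if (is.null(nrec)) NULL else nrec$n_norm,
                 n_mask = if (is.null(nrec)) NULL else nrec$mask,
                 n_mode = if (is.null(nrec)) NA_character_ else nrec$mode,
                 mask = mu$mask, weights = mu$weights, config = mu$config,
                 h = scan$h, ys = scan$ys, zs = scan$zs,
                 geometry = scan$geometry, detector = scan$detector,
                 engine = scan$engine, truth = truth, metrics = metrics,
                 call = match.call()),
            class = "nrbrt")
}

#' @export
print.nrbrt <- function(x, ...) {
  cat("Non-reciprocal broken-ray tomography fit\n")
  cat(sprintf("  %s scan (%s data), %d x %d vertex grid at %.3g mm\n",
              x$geometry$scan_type, x$engine,
              nrow(x$mu_plus), ncol(x$mu_plus), x$h))
  cat(sprintf("  lambda = %g, median kernel = %d, weights = (%s)\n",
              x$config$lambda, x$config$median_kernel,
              paste(round(x$weights, 4), collapse = ", ")))
  cat(sprintf("  mu(+) range: [%.4g, %.4g] per mm; mu(-) range: [%.4g, %.4g]\n",
              min(x$mu_plus), max(x$mu_plus), min(x$mu_minus), max(x$mu_minus)))
  if (!is.null(x$metrics)) {
    cat("  metrics vs model: ")
    t <- x$metrics$table
    cat(paste(sprintf("%s RMSE=%.3g", t$quantity, t$rmse), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.nrbrt <- function(object, ...) {
  structure(list(fit = object), class = "summary.nrbrt")
}

#' @export
print.summary.nrbrt <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  qs <- list(mu_plus = f$mu_plus, mu_minus = f$mu_minus,
             mu_e = f$mu_e, mu_f = f$mu_f)
  if (!is.null(f$n_norm)) qs$n_norm <- f$n_norm
  cat("\nPer-map summaries:\n")
  for (q in names(qs)) {
    v <- qs[[q]]
    cat(sprintf("  %-8s min %9.4g  median %9.4g  max %9.4g\n",
                q, min(v, na.rm = TRUE), median(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
  }
  if (!is.null(f$metrics)) { cat("\n"); print(f$metrics) }
  invisible(x)
}

#' @export
coef.nrbrt <- function(object, ...) {
  out <- list(mu_plus = object$mu_plus, mu_minus = object$mu_minus,
              mu_e = object$mu_e, mu_f = object$mu_f)
  if (!is.null(object$n_norm)) out$n_norm <- object$n_norm
  out
}

#' @export
residuals.nrbrt <- function(object, ...) {
  if (is.null(object$truth)) return(NULL)
  qs <- intersect(names(coef(object)), names(object$truth))
  out <- lapply(qs, function(q) coef(object)[[q]] - object$truth[[q]])
  names(out) <- qs
  out
}

#' Predicted data functions from a fitted model
#'
#' Recomputes the projection data functions implied by the fitted maps
#' (attenuation integrals within the region of interest minus the log of
#' the normalized concentration).  Because the fitted concentration is
#' max-normalized, the prediction carries an unknown global additive
#' constant; it is useful for shape diagnostics against the measured
#' `scan$phi`.
#'
#' @param object an [nrbrt()] fit.
#' @param pairs character keys of ordered pairs (default all six).
#' @param ... unused.
#' @return Named list of matrices (NA where a leg leaves the region of
#'   interest or the concentration is unavailable).
#' @export
predict.nrbrt <- function(object, pairs = c("12", "21", "13", "31", "23", "32"),
                          ...) {
  if (is.null(object$n_norm)) stop("prediction needs a reconstructed concentration")
  h <- object$h
  lnn <- log(object$n_norm)
  out <- list()
  for (key in pairs) {
    l <- as.integer(substr(key, 1, 1)); k <- as.integer(substr(key, 2, 2))
    Ie <- line_integral_roi(object$mu_e, h, object$geometry$u[, l])
    If <- line_integral_roi(object$mu_f, h, object$geometry$u[, k])
    m <- -lnn + Ie$I + If$I
    m[!(Ie$valid & If$valid)] <- NA_real_
    out[[key]] <- m
  }
  out
}

#' Display reconstructed maps next to their models
#'
#' @param x an [nrbrt()] fit.
#' @param what quantities to draw.
#' @param clip apply the standard display clipping (0 to 1.5 x model max)
#'   when truth is available.
#' @param ... passed to [graphics::image()].
#' @importFrom graphics image par title
#' @importFrom grDevices hcl.colors
#' @export
plot.nrbrt <- function(x, what = c("mu_plus", "mu_minus", "mu_e", "mu_f",
                                   "n_norm"),
                       clip = TRUE, ...) {
  what <- intersect(what, names(coef(x)))
  has_truth <- !is.null(x$truth)
  op <- par(mfrow = c(length(what), if (has_truth) 2 else 1),
            mar = c(2, 2, 2, 1))
  on.exit(par(op))
  pal <- hcl.colors(64, "viridis")
  for (q in what) {
    m <- coef(x)[[q]]
    if (has_truth) {
      mod <- x$truth[[q]]
      if (clip && startsWith(q, "mu")) m <- clip_for_display(m, mod)
      zl <- range(c(m, mod), na.rm = TRUE)
      image(x$ys, x$zs, t(mod), col = pal, zlim = zl, ylim = rev(range(x$zs)),
            xlab = "", ylab = "", ...)
      title(paste(q, "(model)"))
      image(x$ys, x$zs, t(m), col = pal, zlim = zl, ylim = rev(range(x$zs)),
            xlab = "", ylab = "", ...)
      title(paste(q, "(reconstruction)"))
    } else {
      image(x$ys, x$zs, t(m), col = pal, ylim = rev(range(x$zs)),
            xlab = "", ylab = "", ...)
      title(q)
    }
  }
  invisible(x)
}
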