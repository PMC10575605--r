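# Image-quality metrics for reconstructed maps.

#' Root-mean-square error between an image and its model
#'
#' @param image,model numeric matrices of the same shape.
#' @param na.rm drop pixels that are NA in either input.
#' @return Scalar RMSE (same units as the inputs).
#' @export
rmse <- function(image, model, na.rm = TRUE) {
  if (!all(dim(image) == dim(model))) stop("shape mismatch")
  d <- (image - model)^2
  sqrt(mean(d, na.rm = na.rm))
}

# 1D Gaussian kernel, sd in pixels
gauss_kernel <- function(size, sd) {
  half <- (size - 1) / 2
  k <- exp(-(seq(-half, half))^2 / (2 * sd^2))
  k / sum(k)
}

# separable convolution with symmetric (reflected) padding
conv2_sym <- function(m, k) {
  half <- (length(k) - 1) / 2
  nr <- nrow(m); nc <- ncol(m)
  padidx <- function(n) c(rev(seq_len(half)), seq_len(n), n - seq_len(half) + 1)
  mp <- m[padidx(nr), padidx(nc)]
  # rows
  out <- matrix(0, nr, nc + 2 * half)
  for (j in seq_along(k))
    out <- out + k[j] * mp[(j - 1) + seq_len(nr), ]
  # cols
  res <- matrix(0, nr, nc)
  for (j in seq_along(k))
    res <- res + k[j] * out[, (j - 1) + seq_len(nc)]
  res
}

#' Structural similarity index (SSIM)
#'
#' Mean SSIM with a Gaussian sliding window and the standard stabilization
#' constants `C1 = (K1 L)^2`, `C2 = (K2 L)^2`.  The dynamic range `L`
#' defaults to the maximum of the model image, which is also the convention
#' used when clipping reconstructions for display.
#'
#' @param image,model numeric matrices of the same shape.
#' @param window odd Gaussian window size in pixels.
#' @param sigma Gaussian window standard deviation in pixels.
#' @param data_range dynamic range `L` (default `max(model)`).
#' @param K1,K2 stabilization constants.
#' @return Scalar in [-1, 1].
#' @export
ssim <- function(image, model, window = 7, sigma = 1.5,
                 data_range = NULL, K1 = 0.01, K2 = 0.03) {
  if (!all(dim(image) == dim(model))) stop("shape mismatch")
  x <- image; y <- model
  nas <- is.na(x) | is.na(y)
  if (any(nas)) { x[nas] <- 0; y[nas] <- 0 }
  if (is.null(data_range)) data_range <- max(y)
  if (!is.finite(data_range) || data_range <= 0)
    stop("degenerate model: data range must be positive")
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  # shrink the window for images smaller than it (keeps reflection padding valid)
  window <- min(window, min(dim(image)))
  if (window %% 2 == 0) window <- window - 1
  window <- max(window, 1)
  k <- gauss_kernel(window, sigma)
  mu_x <- conv2_sym(x, k); mu_y <- conv2_sym(y, k)
  xx <- conv2_sym(x * x, k); yy <- conv2_sym(y * y, k); xy <- conv2_sym(x * y, k)
  var_x <- xx - mu_x^2; var_y <- yy - mu_y^2; cov <- xy - mu_x * mu_y
  s <- ((2 * mu_x * mu_y + C1) * (2 * cov + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (var_x + var_y + C2))
  mean(s[!nas])
}

#' Clip an image to the display range used for figures
#'
#' Reconstructions are displayed clipped to [0, 1.5 * max(model)]; metrics
#' are always computed on the unclipped values.
#'
#' @param image matrix to clip.
#' @param model reference model image (must have a positive maximum).
#' @return Clipped copy of `image`.
#' @export
clip_for_display <- function(image, model) {
  mx <- max(model, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) stop("degenerate model: maximum must be positive")
  pmin(pmax(image, 0), 1.5 * mx)
}

#' Metrics report for a set of reconstructed maps
#'
#' @param maps named list of reconstructed matrices.
#' @param models named list of matching ground-truth matrices.
#' @param provenance named list recorded verbatim (lambda, beta, delta_d, N...).
#' @param window,sigma SSIM window parameters (recorded in the report).
#' @return A list of class `"brt_metrics"`: data frame `table` with columns
#'   `quantity`, `rmse`, `ssim`, plus the provenance and SSIM settings.
#' @export
metrics_report <- function(maps, models, provenance = list(),
                           window = 7, sigma = 1.5) {
  qs <- intersect(names(maps), names(models))
  rows <- lapply(qs, function(q) {
    mx <- suppressWarnings(max(models[[q]], na.rm = TRUE))
    data.frame(quantity = q,
               rmse = rmse(maps[[q]], models[[q]]),
               # SSIM is undefined against an all-zero model (e.g. the
               # spectral difference of a wavelength-flat medium)
               ssim = if (is.finite(mx) && mx > 0)
                 ssim(maps[[q]], models[[q]], window = window, sigma = sigma)
               else NA_real_)
  })
  structure(list(table = do.call(rbind, rows),
                 provenance = provenance,
                 ssim_window = window, ssim_sigma = sigma),
            class = "brt_metrics")
}

#' @export
print.brt_metrics <- function(x, ...) {
  cat("Reconstruction quality vs model:\n")
  print(x$table, row.names = FALSE, digits = 3)
  if (length(x$provenance)) {
    pv <- vapply(x$provenance, function(v) paste(format(v), collapse = ","),
                 character(1))
    cat("  settings:", paste(names(pv), pv, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
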