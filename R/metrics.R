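#' Reconstruction and quantification metrics
#'
#' Computes, between an estimate and a reference of identical shape:
#' * NMSE `||est - ref||^2 / ||ref||^2` (single global ratio over the
#'   whole tensor);
#' * relative L1 `||est - ref||_1 / ||ref||_1`;
#' * PSNR on magnitudes with dynamic range `max(|ref|)` (identical inputs
#'   yield the sentinel `Inf`);
#' * SSIM on magnitude images: standard Gaussian window (11 points, sigma
#'   1.5), stabilisation constants `(K1 L)^2, (K2 L)^2` with
#'   `K1 = 0.01, K2 = 0.03, L = max(|ref|)`, computed per 2-D slice on the
#'   window-valid region and averaged over slices (and over any leading
#'   frame axis). Inputs with fewer than 2 spatial dims get `ssim = NA`.
#'
#' @param estimate,reference numeric or complex arrays of the same shape.
#'   For SSIM, arrays are interpreted with the last two or three
#'   dimensions as `M x M (x P)` slices; a leading time axis is averaged.
#' @return object of class `metric_report`: list with `nmse`,
#'   `relative_l1`, `psnr_db`, `ssim`.
#' @export
compute_metrics <- function(estimate, reference) {
  check_that(length(estimate) == length(reference) &&
               all(dim(estimate) %||% length(estimate) ==
                     dim(reference) %||% length(reference)),
             "estimate and reference must have the same shape")
  ref2 <- sum(Mod(reference)^2)
  check_that(ref2 > 0, "reference must not be identically zero")
  diff <- estimate - reference
  nmse <- sum(Mod(diff)^2) / ref2
  rl1 <- sum(Mod(diff)) / sum(Mod(reference))
  L <- max(Mod(reference))
  mse_mag <- mean((Mod(estimate) - Mod(reference))^2)
  psnr <- if (mse_mag == 0) Inf else 10 * log10(L^2 / mse_mag)
  structure(list(nmse = nmse, relative_l1 = rl1, psnr_db = psnr,
                 ssim = ssim_stack(Mod(estimate), Mod(reference), L)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("NMSE %.4g | Relative-L1 %.4g | PSNR %.2f dB | SSIM %s\n",
              x$nmse, x$relative_l1, x$psnr_db,
              ifelse(is.na(x$ssim), "NA", sprintf("%.4f", x$ssim))))
  invisible(x)
}

gaussian_window <- function(n = 11L, sigma = 1.5) {
  x <- seq_len(n) - (n + 1) / 2
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

## separable valid-region Gaussian filtering via banded matrices
valid_filter_mat <- function(m, w) {
  n <- length(w)
  out <- matrix(0, m - n + 1L, m)
  for (i in seq_len(m - n + 1L)) out[i, i:(i + n - 1L)] <- w
  out
}

ssim_slice <- function(a, b, L, w = gaussian_window()) {
  n <- length(w)
  if (nrow(a) < n || ncol(a) < n) return(NA_real_)
  Gx <- valid_filter_mat(nrow(a), w)
  Gy <- valid_filter_mat(ncol(a), w)
  f <- function(x) Gx %*% x %*% t(Gy)
  mu_a <- f(a); mu_b <- f(b)
  va <- f(a * a) - mu_a^2
  vb <- f(b * b) - mu_b^2
  cab <- f(a * b) - mu_a * mu_b
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  mean(((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
         ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2)))
}

ssim_stack <- function(a, b, L) {
  d <- dim(a)
  if (is.null(d) || length(d) < 2) return(NA_real_)
  if (length(d) == 2) return(ssim_slice(a, b, L))
  ## treat the last axis (and any leading axes) as the slice stack:
  ## reshape to M x M x n_slices with the two spatial dims assumed to be
  ## the two penultimate... convention: dims (..., M, M, P) -> per-P slice
  ## for 3-D; (T, M, M, P) -> all (T, P) slices.
  if (length(d) == 3) {
    vals <- vapply(seq_len(d[3]), function(p)
      ssim_slice(a[, , p], b[, , p], L), numeric(1))
    return(mean(vals, na.rm = TRUE))
  }
  if (length(d) == 4) {
    vals <- c()
    for (t in seq_len(d[1])) for (p in seq_len(d[4]))
      vals <- c(vals, ssim_slice(matrix(a[t, , , p], d[2], d[3]),
                                 matrix(b[t, , , p], d[2], d[3]), L))
    return(mean(vals, na.rm = TRUE))
  }
  NA_real_
}

#' NMSE between two tensors
#' @param estimate,reference same-shape arrays.
#' @return `||est - ref||^2 / ||ref||^2`.
#' @export
nmse <- function(estimate, reference) {
  sum(Mod(estimate - reference)^2) / sum(Mod(reference)^2)
}
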