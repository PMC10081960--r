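#' @importFrom stats rnorm runif fft setNames
#' @importFrom methods as
NULL

stop_invalid <- function(...) {
  stop(structure(class = c("mrfkz_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_that <- function(cond, ...) if (!isTRUE(cond)) stop_invalid(...)

#' Round half away from zero
#'
#' Rounding used when comparing computed acceleration factors with values
#' printed to a fixed number of decimals (base R `round()` rounds half to
#' even, which is not the convention used for such tables).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## fftshift for even-length axes (the only case the NUFFT supports);
## for even n, fftshift and ifftshift coincide, so the permutation is
## self-inverse and the FFT-with-shifts operator has an exact adjoint.
fftshift_idx <- function(n) {
  h <- n %/% 2
  c((h + 1L):n, 1L:h)
}

fftshift2 <- function(x) {
  d <- dim(x)
  x[fftshift_idx(d[1]), fftshift_idx(d[2]), drop = FALSE]
}

## centered 2-D FFT: X[u] = sum_n x[n] exp(-2*pi*1i*<u,n>/G), n,u centered
cfft2 <- function(x, inverse = FALSE) {
  fftshift2(fft(fftshift2(x), inverse = inverse))
}

## centered DFT matrix along one axis: F[p, z] = exp(-2i*pi*(p-h)(z-h)/n)
centered_dft_matrix <- function(n, inverse = FALSE) {
  h <- n %/% 2
  f <- (seq_len(n) - 1L) - h
  s <- if (inverse) 2i else -2i
  m <- exp(s * pi * outer(f, f) / n)
  if (inverse) m / n else m
}

complex_mat <- function(sp, x) {
  ## real sparse matrix times complex dense matrix
  as.matrix(sp %*% Re(x)) + 1i * as.matrix(sp %*% Im(x))
}

rel_err <- function(a, b) {
  sqrt(sum(Mod(a - b)^2) / max(sum(Mod(b)^2), .Machine$double.xmin))
}
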