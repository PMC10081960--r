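## Kaiser-Bessel gridding NUFFT (type 2 forward: image -> non-uniform
## samples; exact algebraic adjoint). Oversampling factor 2, kernel width
## J = 7, Beatty shape parameter. Conventions: image of size N x N (N
## even), voxel index n centered (-N/2 .. N/2-1); k-space coordinates
## kappa in cycles/FOV in [-0.5, 0.5); forward computes
##   F(kappa) = sum_n x[n] exp(-2i*pi*<kappa, n>).

kb_beta <- function(J, osf = 2) {
  pi * sqrt((J / osf)^2 * (osf - 0.5)^2 - 0.8)
}

kb_kernel <- function(t, J, beta) {
  a <- 1 - (2 * t / J)^2
  w <- numeric(length(t))
  ok <- a > 0
  w[ok] <- besselI(beta * sqrt(a[ok]), 0) / besselI(beta, 0)
  w
}

## Fourier transform of the KB kernel, evaluated at f = n/G: the
## apodization (roll-off) correction. sinh form for |pi*J*f| < beta,
## sinc form beyond.
kb_apod <- function(f, J, beta) {
  arg <- beta^2 - (pi * J * f)^2
  out <- numeric(length(f))
  pos <- arg > 0
  out[pos] <- sinh(sqrt(arg[pos])) / sqrt(arg[pos])
  out[!pos] <- sinc_safe(sqrt(-arg[!pos]))
  out * J / besselI(beta, 0)
}

sinc_safe <- function(x) ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)

#' Plan a 2-D gridding NUFFT for fixed sample coordinates
#'
#' Precomputes the sparse interpolation matrix and apodization correction
#' for a type-2 NUFFT from an `N x N` image (N even) to arbitrary k-space
#' coordinates in cycles/FOV.
#'
#' @param coords Q x 2 coordinates in `[-0.5, 0.5)` (cycles/FOV).
#' @param N image matrix size (even).
#' @param J interpolation kernel width in oversampled grid cells.
#' @param osf grid oversampling factor (the implementation assumes 2).
#' @return a `nufft_plan` object.
#' @export
nufft_plan <- function(coords, N, J = 7L, osf = 2L) {
  coords <- as.matrix(coords)
  check_that(N %% 2 == 0, "N must be even")
  check_that(all(abs(coords) <= 0.5 + 1e-12), "coords must lie in [-0.5, 0.5]")
  Q <- nrow(coords)
  G <- as.integer(osf * N)
  beta <- kb_beta(J, osf)
  half <- (J - 1L) %/% 2L
  offs <- (-half):(J - 1L - half)          # J taps around the nearest cell
  sx <- coords[, 1] * G                    # target position on oversampled grid
  sy <- coords[, 2] * G
  u0x <- round(sx); u0y <- round(sy)
  ## per-dimension weights: Q x J
  wx <- sapply(offs, function(o) kb_kernel(sx - (u0x + o), J, beta))
  wy <- sapply(offs, function(o) kb_kernel(sy - (u0y + o), J, beta))
  ## grid columns, wrapped periodically, centered layout index u + G/2 + 1
  colx <- sapply(offs, function(o) ((u0x + o + G %/% 2) %% G) + 1L)
  coly <- sapply(offs, function(o) ((u0y + o + G %/% 2) %% G) + 1L)
  nnz_per <- J * J
  ii <- rep(seq_len(Q), each = nnz_per)
  jx <- matrix(0L, Q, nnz_per); vv <- matrix(0, Q, nnz_per)
  k <- 0L
  for (a in seq_len(J)) for (b in seq_len(J)) {
    k <- k + 1L
    jx[, k] <- colx[, a] + (coly[, b] - 1L) * G
    vv[, k] <- wx[, a] * wy[, b]
  }
  S <- Matrix::sparseMatrix(i = ii, j = as.vector(t(jx)), x = as.vector(t(vv)),
                            dims = c(Q, G * G))
  nidx <- (seq_len(N) - 1L) - N %/% 2L
  a1 <- kb_apod(nidx / G, J, beta)
  structure(list(S = S, N = as.integer(N), G = G, Q = Q, J = J, beta = beta,
                 apod2 = outer(a1, a1), coords = coords),
            class = "nufft_plan")
}

#' Forward NUFFT: image(s) to non-uniform samples
#'
#' @param plan a [nufft_plan()].
#' @param img complex `N x N` matrix or `N^2 x L` matrix of vectorised
#'   images (centered layout).
#' @return `Q x L` complex matrix of samples.
#' @export
nufft_forward <- function(plan, img) {
  N <- plan$N; G <- plan$G
  x <- if (is.matrix(img) && nrow(img) == N && ncol(img) == N)
    matrix(as.vector(img), ncol = 1) else as.matrix(img)
  check_that(nrow(x) == N * N, "image size does not match plan")
  L <- ncol(x)
  out <- matrix(0i, plan$Q, L)
  lo <- G %/% 2L - N %/% 2L + 1L; hi <- lo + N - 1L
  Y <- matrix(0i, G * G, L)
  for (l in seq_len(L)) {
    xm <- matrix(x[, l], N, N) / plan$apod2
    pad <- matrix(0i, G, G)
    pad[lo:hi, lo:hi] <- xm
    Y[, l] <- as.vector(cfft2(pad))
  }
  complex_mat(plan$S, Y)
}

#' Adjoint NUFFT: non-uniform samples to image(s)
#'
#' The exact algebraic adjoint of [nufft_forward()] (conjugate-transpose
#' of every step); to approximate an inverse, pre-multiply samples by
#' density-compensation weights (see [dcf_weights()]).
#'
#' @param plan a [nufft_plan()].
#' @param samples `Q x L` complex matrix (or length-Q vector).
#' @return `N^2 x L` complex matrix of vectorised images.
#' @export
nufft_adjoint <- function(plan, samples) {
  y <- as.matrix(samples)
  check_that(nrow(y) == plan$Q, "sample count does not match plan")
  N <- plan$N; G <- plan$G; L <- ncol(y)
  St <- Matrix::t(plan$S)
  Yv <- complex_mat(St, y)
  lo <- G %/% 2L - N %/% 2L + 1L; hi <- lo + N - 1L
  out <- matrix(0i, N * N, L)
  for (l in seq_len(L)) {
    W <- cfft2(matrix(Yv[, l], G, G), inverse = TRUE)
    out[, l] <- as.vector(W[lo:hi, lo:hi] / plan$apod2)
  }
  out
}

#' Density-compensation weights for a spiral interleaf set
#'
#' Weights approximating the k-space area element per sample, used to turn
#' the adjoint NUFFT into an approximate inverse. Mode `"jacobian"`
#' (default) uses the exact area element of the (parameter, arm) to
#' k-space mapping for the uniform-density Archimedean family
#' `k(tau) = k_max * tau * e^{i 2 pi turns tau}`: the inter-arm offset at
#' radius `r` is azimuthal with magnitude `2 pi r / n_interleaves`, and
#' only the radial component `k_max dtau` of the arm velocity crosses it,
#' giving `dA = (2 pi r / n_interleaves) * k_max * dtau` — proportional to
#' the radius and to the uniform parameter step, independent of `turns`
#' (the apex sample covers the disk of radius half the radial step). Mode
#' `"radial"` is the generic heuristic `w = |k| * ds` with `ds` the
#' along-arc spacing. Both are normalised so the weights of the full
#' interleaf set sum to the sampled disk area `pi k_max^2`.
#'
#' @param traj a [make_spiral()] trajectory.
#' @param n_interleaves number of interleaves contributing to the frame.
#' @param mode `"jacobian"` or `"radial"`.
#' @return length-Q weight vector (for one interleaf; identical for every
#'   rotated copy).
#' @export
dcf_weights <- function(traj, n_interleaves = 1L,
                        mode = c("jacobian", "radial")) {
  mode <- match.arg(mode)
  co <- traj$coords
  r <- sqrt(rowSums(co^2))
  Q <- nrow(co)
  w <- if (mode == "jacobian") {
    dr <- traj$k_max / (Q - 1)
    wj <- 2 * pi * r * dr / n_interleaves
    wj[r < dr / 2] <- pi * (dr / 2)^2 / n_interleaves
    wj
  } else {
    seg <- sqrt(rowSums(diff(co)^2))
    ds <- c(seg[1], (seg[-length(seg)] + seg[-1]) / 2, seg[length(seg)])
    r * ds[seq_len(Q)]
  }
  w * (pi * traj$k_max^2) / (sum(w) * n_interleaves)
}
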