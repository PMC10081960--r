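## Spiral GRAPPA along the partition-encoding direction: each readout
## location i has its own kernel (spiral points are not equally spaced, so
## kernels vary with location). For target offset m in 1..R-1 and coil c,
## the skipped sample is a linear combination of the two flanking acquired
## partitions (offsets 0 and R), readout window i-v..i+v, all coils:
## source-vector length 2*(2v+1)*C.

src_len <- function(v, C) 2L * (2L * v + 1L) * C

## Build, for one readout index i, the calibration source matrix
## (n_instances x 2*(2v+1)*C) from ACS data acs[T, P_acs, Q, C].
## starts: 0-based partition offsets p of the lower acquired partition.
grappa_sources <- function(acs, i, v, R, starts) {
  d <- dim(acs); Tn <- d[1]; Q <- d[3]; C <- d[4]
  nin <- Tn * length(starts)
  out <- matrix(0i, nin, src_len(v, C))
  col <- 0L
  for (dp in c(0L, R)) for (di in (-v):v) {
    ii <- i + di
    for (cc in seq_len(C)) {
      col <- col + 1L
      if (ii >= 1L && ii <= Q)   # readout edges: zero padding
        out[, col] <- as.vector(acs[, starts + dp + 1L, ii, cc])
    }
  }
  out
}

#' Calibrate spiral GRAPPA kernels on ACS partitions
#'
#' For every readout location `i`, offset `m` in `1..R-1` and target coil
#' `c`, fits by (optionally ridge-regularised) least squares the complex
#' weights predicting the skipped sample from a `2 x (2v+1) x C` source
#' neighbourhood: the two flanking acquired partitions (offsets 0 and R),
#' `2v+1` readout points and all coils. Calibration instances are pooled
#' across all time frames and all stride-1 ACS start positions (maximising
#' equations, since calibration data per kernel is far scarcer than in
#' Cartesian MRI); `per_frame = TRUE` calibrates one kernel set per frame
#' instead.
#'
#' @param acs complex `T x P_acs x Q x C` array of ACS partitions.
#' @param R partition-direction acceleration factor.
#' @param v readout half-width of the kernel (default 1: a 2 x 3 kernel).
#' @param ridge relative Tikhonov factor; the actual penalty is
#'   `ridge * mean(diag(A^H A))`. 0 reproduces plain least squares
#'   (minimum-norm via pseudo-inverse, with a warning, if
#'   under-determined).
#' @param per_frame calibrate separately per time frame.
#' @return object of class `grappa_kernels`: `weights` — complex array
#'   `(2*(2v+1)*C) x ((R-1)*C) x Q` (per-frame mode: a list of such
#'   arrays), plus `v`, `R`, `Q`, `C`, `ridge`.
#' @export
calibrate_grappa <- function(acs, R, v = 1L, ridge = 1e-6,
                             per_frame = FALSE) {
  d <- dim(acs)
  check_that(length(d) == 4, "acs must be a T x P_acs x Q x C array")
  Tn <- d[1]; Pa <- d[2]; Q <- d[3]; C <- d[4]
  check_that(Pa >= R + 1, "need at least R+1 ACS partitions")
  check_that(Q >= 2 * v + 1, "Q must be >= 2v+1")
  starts <- 0:(Pa - R - 1L)
  fit_all <- function(sub) {
    W <- array(0i, dim = c(src_len(v, C), (R - 1L) * C, Q))
    for (i in seq_len(Q)) {
      A <- grappa_sources(sub, i, v, R, starts)
      Y <- matrix(0i, nrow(A), (R - 1L) * C)
      col <- 0L
      for (m in seq_len(R - 1L)) for (cc in seq_len(C)) {
        col <- col + 1L
        Y[, col] <- as.vector(sub[, starts + m + 1L, i, cc])
      }
      W[, , i] <- grappa_solve(A, Y, ridge)
    }
    W
  }
  weights <- if (per_frame) {
    lapply(seq_len(Tn), function(t) fit_all(acs[t, , , , drop = FALSE]))
  } else fit_all(acs)
  structure(list(weights = weights, v = as.integer(v), R = as.integer(R),
                 Q = Q, C = C, ridge = ridge, per_frame = per_frame),
            class = "grappa_kernels")
}

grappa_solve <- function(A, Y, ridge) {
  n <- ncol(A)
  AhA <- Conj(t(A)) %*% A
  AhY <- Conj(t(A)) %*% Y
  if (ridge > 0) {
    lam <- ridge * mean(Re(diag(AhA)))
    sol <- tryCatch(solve(AhA + lam * diag(n), AhY),
                    error = function(e) NULL)
    if (!is.null(sol)) return(sol)
  }
  if (nrow(A) < n && ridge == 0)
    warning("under-determined GRAPPA calibration; returning minimum-norm solution")
  ## orthogonal-decomposition fallback / minimum-norm pseudo-inverse
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(sv$d)
  pos <- sv$d > tol
  di <- ifelse(pos, 1 / sv$d, 0)
  sv$v %*% (di * (Conj(t(sv$u)) %*% Y))
}

grappa_predict_pair <- function(kernels, W, frame_data, p_lo, p_hi) {
  ## frame_data: P x Q x C for one frame; returns Q x ((R-1)*C)
  v <- kernels$v; Q <- kernels$Q; C <- kernels$C; R <- kernels$R
  S <- matrix(0i, Q, src_len(v, C))
  col <- 0L
  for (p in c(p_lo, p_hi)) for (di in (-v):v) {
    sl <- frame_data[p + 1L, , ]                       # Q x C
    sh <- matrix(0i, Q, C)
    idx <- seq_len(Q) + di
    ok <- idx >= 1L & idx <= Q
    sh[ok, ] <- sl[idx[ok], ]
    for (cc in seq_len(C)) {
      col <- col + 1L
      S[, col] <- sh[, cc]
    }
  }
  out <- matrix(0i, Q, (R - 1L) * C)
  for (j in seq_len(ncol(S)))
    out <- out + S[, j] * t(W[j, , ])
  out
}

#' Apply GRAPPA kernels to reconstruct skipped partitions
#'
#' Predicts every skipped partition from its two flanking acquired
#' partitions using the calibrated location-specific kernels. Acquired
#' partitions are passed through unchanged (data consistency). Trailing
#' skipped partitions with only one flanking acquired neighbour are
#' predicted from a degenerate pair that reuses the nearest acquired
#' partition for the missing flank.
#'
#' @param kernels a [calibrate_grappa()] kernel set.
#' @param ks an undersampled `mrf_kspace` with the same `R`, `Q`, `C`.
#' @return completed `mrf_kspace` with `acquired_mask` all `TRUE`.
#' @export
apply_grappa <- function(kernels, ks) {
  check_that(inherits(kernels, "grappa_kernels"), "kernels type mismatch")
  check_that(inherits(ks, "mrf_kspace"), "ks must be an mrf_kspace")
  d <- dim(ks$data)
  check_that(d[3] == kernels$Q && d[4] == kernels$C,
             "kernel geometry does not match data")
  check_that(ks$schedule$R == kernels$R, "acceleration factor mismatch")
  R <- kernels$R; C <- kernels$C
  acq <- which(ks$acquired_mask) - 1L                  # 0-based
  missing <- setdiff(0:(d[2] - 1L), acq)
  out <- ks
  for (t in seq_len(d[1])) {
    W <- if (kernels$per_frame) kernels$weights[[t]] else kernels$weights
    fd <- ks$data[t, , , , drop = TRUE]
    dim(fd) <- d[2:4]
    for (q in missing) {
      lo <- suppressWarnings(max(acq[acq < q]))
      hi <- suppressWarnings(min(acq[acq > q]))
      if (is.finite(lo) && is.finite(hi) && hi - lo == R) {
        m <- q - lo
        pred <- grappa_predict_pair(kernels, W, fd, lo, hi)
      } else if (is.finite(lo)) {                      # trailing fallback
        m <- min(q - lo, R - 1L)
        pred <- grappa_predict_pair(kernels, W, fd, lo, lo)
      } else {
        m <- min(hi - q, R - 1L)
        pred <- grappa_predict_pair(kernels, W, fd, hi, hi)
      }
      cols <- (m - 1L) * C + seq_len(C)
      out$data[t, q + 1L, , ] <- pred[, cols]
    }
  }
  out$acquired_mask <- rep(TRUE, d[2])
  out
}
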