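#' Reconstruct image frames from completed k-space
#'
#' Inverse centered DFT along the partition (kz) direction, then a
#' density-compensated adjoint NUFFT per slice with the frame's rotated
#' trajectory, then coil combination: `"rss"` root-sum-of-squares
#' (magnitude only), `"sens"` sensitivity-weighted complex combine
#' `sum(conj(S_c) x_c) / sum(|S_c|^2)` using supplied coil maps (the
#' phase-preserving option; in the synthetic pipeline the generator's own
#' maps are available), or `"none"` to keep per-coil complex images.
#'
#' @param ks a completed `mrf_kspace` (all partitions present).
#' @param dcf_mode density-compensation mode, see [dcf_weights()].
#' @param combine coil combination: `"sens"`, `"rss"`, or `"none"`.
#' @param coils `coil_sensitivities` (required for `combine = "sens"`).
#' @param frames optional 1-based subset of frames to reconstruct.
#' @return complex array `T x M x M x P` (combined) or `T x M x M x P x C`.
#' @export
reconstruct_frames <- function(ks, dcf_mode = c("jacobian", "radial"),
                               combine = c("sens", "rss", "none"),
                               coils = NULL, frames = NULL) {
  dcf_mode <- match.arg(dcf_mode)
  combine <- match.arg(combine)
  check_that(inherits(ks, "mrf_kspace"), "ks must be an mrf_kspace")
  check_that(all(ks$acquired_mask),
             "k-space has missing partitions; interpolate them first")
  d <- dim(ks$data)
  Tn <- d[1]; P <- d[2]; Qt <- d[3]; C <- d[4]
  traj <- ks$trajectory
  n_il <- ks$n_interleaves %||% 1L
  if (combine == "sens") {
    check_that(inherits(coils, "coil_sensitivities"),
               "combine = 'sens' requires coil maps")
    M <- dim(coils$maps)[1]
  } else {
    M <- if (!is.null(M_arg <- attr(ks, "matrix"))) M_arg
         else if (!is.null(coils)) dim(coils$maps)[1]
         else infer_matrix(traj)
  }
  if (is.null(frames)) frames <- seq_len(Tn)
  w <- rep(dcf_weights(traj, n_il, dcf_mode), n_il)
  Fki <- centered_dft_matrix(P, inverse = TRUE)
  out <- if (combine == "none") array(0i, c(length(frames), M, M, P, C))
         else array(0i, c(length(frames), M, M, P))
  if (combine == "sens") {
    sens <- matrix(coils$maps, ncol = C)           # (M*M*P) x C
    ssq <- rowSums(Mod(sens)^2)
    ssq[ssq == 0] <- 1
  }
  angles <- ks$schedule$frame_angles
  for (oi in seq_along(frames)) {
    t <- frames[oi]
    plan <- nufft_plan(frame_coords(traj, angles[t], n_il), M)
    fd <- ks$data[t, , , , drop = TRUE]
    dim(fd) <- d[2:4]
    ## kz -> z: P x Qt x C, inverse DFT along partitions
    fz <- array(0i, dim = c(P, Qt, C))
    for (cc in seq_len(C)) fz[, , cc] <- Fki %*% fd[, , cc]
    ## samples matrix Qt x (P*C), partition fastest within coil
    smp <- matrix(aperm(fz, c(2, 1, 3)), Qt, P * C) * w
    img <- nufft_adjoint(plan, smp)                # (M*M) x (P*C)
    if (combine == "none") {
      out[oi, , , , ] <- array(img, c(M, M, P, C))
    } else if (combine == "rss") {
      vol <- array(img, c(M * M, P, C))
      out[oi, , , ] <- array(sqrt(apply(Mod(vol)^2, 1:2, sum)), c(M, M, P))
    } else {
      ## img columns are (partition fastest, then coil); the flat memory
      ## order (voxel, partition, coil) is already voxel-major
      vol <- matrix(img, ncol = C)
      comb <- rowSums(Conj(sens) * vol) / ssq
      out[oi, , , ] <- array(comb, c(M, M, P))
    }
  }
  out
}

infer_matrix <- function(traj) {
  ## Nyquist-consistent matrix for the trajectory family
  as.integer(round(traj$turns * traj$n_interleaves_full / traj$k_max))
}

#' Fingerprint dictionary over a T1/T2 grid
#'
#' One unit-norm entry per feasible `(T1, T2)` pair (pairs with
#' `T2 >= T1` are excluded), simulated with [simulate_fingerprint()].
#'
#' @param t1_grid,t2_grid strictly increasing grids in ms.
#' @param acq an [make_acq()] schedule.
#' @return object of class `mrf_dictionary`: `entries` (`T x N` complex,
#'   unit-norm columns), `t1_ms`, `t2_ms` (length N), `acq`.
#' @export
build_dictionary <- function(t1_grid, t2_grid, acq) {
  check_that(length(t1_grid) > 0 && length(t2_grid) > 0, "empty grid")
  check_that(!is.unsorted(t1_grid, strictly = TRUE) &&
               !is.unsorted(t2_grid, strictly = TRUE),
             "grids must be strictly increasing")
  gr <- expand.grid(t1 = t1_grid, t2 = t2_grid)
  gr <- gr[gr$t1 > gr$t2, , drop = FALSE]
  check_that(nrow(gr) > 0, "no feasible (T1 > T2) grid pairs")
  entries <- sapply(seq_len(nrow(gr)), function(k)
    simulate_fingerprint(gr$t1[k], gr$t2[k], acq))
  nrm <- sqrt(colSums(Mod(entries)^2))
  entries <- sweep(entries, 2, nrm, `/`)
  structure(list(entries = entries, t1_ms = gr$t1, t2_ms = gr$t2, acq = acq),
            class = "mrf_dictionary")
}

#' Dictionary template matching
#'
#' Per voxel, selects the dictionary entry maximising the magnitude of the
#' normalised inner product with the measured time course; assigns that
#' entry's (T1, T2) and `PD = |<signal, entry>|`. Voxels whose time-course
#' norm falls below `mask_frac` of the image maximum are masked out.
#'
#' @param series complex `T x M x M x P` array (or `T x n_voxels` matrix).
#' @param dict an [build_dictionary()] dictionary.
#' @param mask_frac background threshold as a fraction of the maximum
#'   time-course norm.
#' @return object of class `tissue_maps`: `t1_ms`, `t2_ms`, `pd` volumes
#'   and logical `mask` (same spatial shape as the input).
#' @export
template_match <- function(series, dict, mask_frac = 0.1) {
  check_that(inherits(dict, "mrf_dictionary"), "dict type mismatch")
  d <- dim(series)
  check_that(d[1] == nrow(dict$entries),
             "series length does not match dictionary entries")
  spatial <- if (length(d) > 2) d[-1] else d[2]
  S <- matrix(series, nrow = d[1])
  nrm <- sqrt(colSums(Mod(S)^2))
  mask <- nrm > mask_frac * max(nrm)
  ip <- Mod(Conj(t(dict$entries)) %*% S[, mask, drop = FALSE])
  best <- max.col(t(ip), ties.method = "first")
  t1 <- t2 <- pd <- numeric(ncol(S))
  t1[mask] <- dict$t1_ms[best]
  t2[mask] <- dict$t2_ms[best]
  pd[mask] <- ip[cbind(best, seq_along(best))]
  shape <- function(x) if (length(spatial) > 1) array(x, spatial) else x
  structure(list(t1_ms = shape(t1), t2_ms = shape(t2), pd = shape(pd),
                 mask = shape(mask)),
            class = "tissue_maps")
}
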