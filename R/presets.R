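#' Named simulation presets
#'
#' Parameter sets for the synthetic pipeline. `"desk"` is the default
#' working size for experiments and tests (T=48, P=24, Q=512, C=8, M=64);
#' `"tiny"` is a seconds-scale smoke size; `"full-1mm"` and
#' `"full-0.8mm"` mirror the full acquisition geometries of the
#' corresponding high-resolution brain protocols (matrix 256/320,
#' 144/176 partitions, 768 frames, 32 coils, 12/16 ACS partitions) and
#' are intended as configuration presets, not test sizes.
#'
#' @param name preset name.
#' @return named list of simulation parameters.
#' @export
mrf_preset <- function(name = c("desk", "tiny", "full-1mm", "full-0.8mm")) {
  name <- match.arg(name)
  switch(name,
    tiny = list(M = 16L, P = 8L, Q = 128L, C = 2L, T = 12L, n_segments = 4L,
                R = 2L, n_acs = 4L, n_interleaves_full = 8L, k_max = 0.5,
                turns = 0.5 * 16 / 8, noise_frac = 0),
    desk = list(M = 64L, P = 24L, Q = 512L, C = 8L, T = 48L, n_segments = 4L,
                R = 4L, n_acs = 12L, n_interleaves_full = 48L, k_max = 0.5,
                turns = 0.5 * 64 / 48, noise_frac = 2.5e-4),
    `full-1mm` = list(M = 256L, P = 144L, Q = 2452L, C = 32L, T = 768L,
                       n_segments = 16L, R = 4L, n_acs = 12L,
                       n_interleaves_full = 48L, k_max = 0.5,
                       turns = 0.5 * 256 / 48, noise_frac = 2.5e-4),
    `full-0.8mm` = list(M = 320L, P = 176L, Q = 3300L, C = 32L, T = 768L,
                         n_segments = 16L, R = 4L, n_acs = 16L,
                         n_interleaves_full = 48L, k_max = 0.5,
                         turns = 0.5 * 320 / 48, noise_frac = 2.5e-4))
}

#' Simulate a complete synthetic MRF acquisition
#'
#' Convenience wrapper: builds phantom, coils, trajectory, schedules,
#' forward-samples the k-space (fully sampled along partitions, one
#' in-plane interleaf per frame) and adds complex noise calibrated as a
#' fraction of the ACS peak magnitude.
#'
#' @param params parameter list as returned by [mrf_preset()] (individual
#'   entries can be overridden via `...`).
#' @param seed master seed (phantom/coils and noise streams derive from it).
#' @param ... overrides for entries of `params`.
#' @return list with `ks` (`mrf_kspace`), `phantom`, `coils`, `traj`,
#'   `sched`, `acq`, `params`.
#' @export
simulate_mrf <- function(params = mrf_preset("desk"), seed = 0L, ...) {
  ov <- list(...)
  params[names(ov)] <- ov
  p <- params
  ph <- make_phantom(p$M, p$P, p$C, seed = seed)
  traj <- make_spiral(p$Q, p$n_interleaves_full, p$k_max, p$turns)
  sched <- make_schedule(p$P, p$R, p$n_acs, T = p$T)
  acq <- make_acq(T = p$T, n_segments = p$n_segments)
  ks <- forward_sample(ph$phantom, ph$coils, traj, sched, acq,
                       noise_sigma = 0, seed = seed)
  if (p$noise_frac > 0) {
    sigma <- noise_sigma_from_acs(ks, p$noise_frac)
    set.seed(as.integer(seed) + 1L)
    n <- length(ks$data)
    ks$data <- ks$data + sigma * complex(real = rnorm(n), imaginary = rnorm(n))
  }
  list(ks = ks, phantom = ph$phantom, coils = ph$coils, traj = traj,
       sched = sched, acq = acq, params = p)
}

#' Extract the ACS block of an undersampled acquisition
#'
#' @param ks an `mrf_kspace` whose schedule has an ACS block.
#' @return complex `T x P_acs x Q x C` array.
#' @export
acs_block <- function(ks) {
  idx <- ks$schedule$acs_indices
  check_that(length(idx) > 0, "schedule has no ACS partitions")
  ks$data[, idx + 1L, , , drop = FALSE]
}

#' Fully sampled reference image series (streaming)
#'
#' Per frame, forward-samples the phantom with the full in-plane
#' interleaf set and all partitions, then reconstructs with the
#' density-compensated adjoint NUFFT and sensitivity-weighted coil
#' combination. Frames are processed one at a time so the fully sampled
#' k-space is never materialised.
#'
#' @param phantom,coils from [make_phantom()].
#' @param traj a [make_spiral()] trajectory.
#' @param sched schedule providing the frame angles.
#' @param acq acquisition schedule.
#' @param frames 1-based frames to compute (default all).
#' @param dcf_mode see [dcf_weights()].
#' @return complex `length(frames) x M x M x P` array.
#' @export
reference_series <- function(phantom, coils, traj, sched, acq,
                             frames = seq_len(acq$T), dcf_mode = "jacobian") {
  M <- phantom$M; P <- phantom$P
  C <- dim(coils$maps)[4]
  n_il <- traj$n_interleaves_full
  f <- class_fingerprints(phantom, acq)
  spectra <- class_kz_spectra(phantom, coils)
  w <- rep(dcf_weights(traj, n_il, dcf_mode), n_il)
  Fki <- centered_dft_matrix(P, inverse = TRUE)
  sens <- matrix(coils$maps, ncol = C)
  ssq <- rowSums(Mod(sens)^2); ssq[ssq == 0] <- 1
  out <- array(0i, c(length(frames), M, M, P))
  for (oi in seq_along(frames)) {
    t <- frames[oi]
    G <- f[t, 1] * spectra[[1]]
    for (l in seq_along(spectra)[-1]) G <- G + f[t, l] * spectra[[l]]
    plan <- nufft_plan(frame_coords(traj, sched$frame_angles[t], n_il), M)
    smp <- nufft_forward(plan, G)                      # (Q*n_il) x (P*C)
    img <- nufft_adjoint(plan, smp * w)                # (M*M) x (P*C)
    ## columns are (p fastest, c): kz -> z per coil, then combine
    vol <- array(img, c(M * M, P, C))
    for (cc in seq_len(C)) vol[, , cc] <- vol[, , cc] %*% t(Fki)
    comb <- rowSums(Conj(sens) * matrix(vol, ncol = C)) / ssq
    out[oi, , , ] <- array(comb, c(M, M, P))
  }
  out
}

#' Ground-truth tissue maps of a phantom
#'
#' @param phantom a `digital_phantom`.
#' @return a `tissue_maps` object with the per-label T1/T2/PD values.
#' @export
phantom_maps <- function(phantom) {
  cm <- phantom$class_map
  pick <- function(vals) {
    out <- array(0, dim(cm))
    nz <- cm > 0L
    out[nz] <- vals[cm[nz]]
    out
  }
  structure(list(t1_ms = pick(phantom$classes$t1_ms),
                 t2_ms = pick(phantom$classes$t2_ms),
                 pd = pick(phantom$classes$pd),
                 mask = phantom$label_map > 0),
            class = "tissue_maps")
}

#' Default T1/T2 dictionary grids
#'
#' Conventional brain ranges, including the phantom's tissue values as
#' on-grid entries.
#'
#' @return list with `t1_grid`, `t2_grid` (ms).
#' @export
default_dictionary_grids <- function() {
  list(t1_grid = sort(unique(c(seq(200, 2000, by = 100), 2500, 3000, 4000))),
       t2_grid = sort(unique(c(seq(20, 120, by = 10),
                               150, 200, 300, 500, 1000, 1800))))
}

#' Zero-filling baseline
#'
#' Returns the undersampled k-space unchanged but with the mask marked
#' complete, so skipped partitions contribute zeros: the no-interpolation
#' reference every interpolator must beat.
#'
#' @param ks an undersampled `mrf_kspace`.
#' @return `mrf_kspace` with `acquired_mask` all TRUE.
#' @export
zero_fill <- function(ks) {
  ks$acquired_mask <- rep(TRUE, dim(ks$data)[2])
  ks
}

#' k-space NMSE restricted to originally skipped partitions
#'
#' @param completed completed `mrf_kspace` (after interpolation).
#' @param truth fully sampled `mrf_kspace` of the same acquisition.
#' @param sched the undersampling schedule that defined the skipped set.
#' @return NMSE over the skipped partitions only.
#' @export
skipped_partition_nmse <- function(completed, truth, sched) {
  sk <- setdiff(0:(sched$n_partitions - 1L), sched$acquired_indices)
  nmse(completed$data[, sk + 1L, , , drop = FALSE],
       truth$data[, sk + 1L, , , drop = FALSE])
}
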