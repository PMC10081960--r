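#' MRF acquisition schedule (flip-angle train and preparation modules)
#'
#' Describes the fingerprinting pulse train: `T = n_segments *
#' trs_per_segment` TRs with variable flip angles, an optional inversion
#' at the start, a T2-preparation module (with the given effective echo
#' time) at selected segment boundaries, and an optional longitudinal
#' recovery delay at each segment boundary.
#'
#' @param T number of time frames (TRs).
#' @param n_segments number of segments; `T` must be divisible by it.
#' @param tr_ms repetition time (ms).
#' @param te_ms echo time (ms).
#' @param flip_deg flip-angle train in degrees (length `T`); default is a
#'   smooth per-segment half-sine ramp within 5-12 degrees.
#' @param t2prep_te_ms length-`n_segments` vector of T2-prep effective
#'   echo times (ms); 0 means no preparation before that segment; entry 1
#'   is ignored (the train starts with the inversion instead). Default
#'   cycles 0/50/0/90.
#' @param inversion start from inverted magnetisation (Mz = -1).
#' @param seg_wait_ms longitudinal recovery delay (ms) applied at each
#'   segment boundary before the next preparation.
#' @return object of class `acq_schedule`.
#' @export
make_acq <- function(T = 48L, n_segments = 4L, tr_ms = 9.2, te_ms = 1.3,
                     flip_deg = NULL, t2prep_te_ms = NULL,
                     inversion = TRUE, seg_wait_ms = 300) {
  check_that(T >= 1 && n_segments >= 1 && T %% n_segments == 0,
             "T must be a positive multiple of n_segments")
  check_that(tr_ms > 0 && te_ms >= 0, "tr_ms must be positive, te_ms >= 0")
  T <- as.integer(T); n_segments <- as.integer(n_segments)
  trs <- T %/% n_segments
  if (is.null(flip_deg)) {
    amp <- rep(c(12, 9, 11, 8), length.out = n_segments)
    flip_deg <- as.vector(sapply(seq_len(n_segments), function(s)
      5 + (amp[s] - 5) * sin(pi * seq_len(trs) / (trs + 1))))
  }
  check_that(length(flip_deg) == T, "flip_deg must have length T")
  if (is.null(t2prep_te_ms)) t2prep_te_ms <- rep(c(0, 50, 0, 90),
                                                 length.out = n_segments)
  check_that(length(t2prep_te_ms) == n_segments,
             "t2prep_te_ms must have length n_segments")
  structure(list(T = T, n_segments = n_segments, trs_per_segment = trs,
                 tr_ms = tr_ms, te_ms = te_ms, flip_deg = flip_deg,
                 t2prep_te_ms = t2prep_te_ms, inversion = inversion,
                 seg_wait_ms = seg_wait_ms),
            class = "acq_schedule")
}

#' Simulate a fingerprint time course (gradient-spoiled stand-in)
#'
#' A deliberately simple longitudinal-recursion signal model, not a Bloch
#' or extended-phase-graph simulation: starting from `Mz = -1` (inversion)
#' or `+1`, each TR emits `s_t = Mz * sin(alpha_t) * exp(-TE/T2)`, then
#' applies `Mz <- Mz * cos(alpha_t)` and T1 recovery
#' `Mz <- 1 + (Mz - 1) * exp(-TR/T1)`. At each segment boundary the
#' recovery delay acts on Mz, followed by the next segment's T2-prep
#' attenuation `Mz <- Mz * exp(-TE_prep/T2)`. The model preserves the
#' qualitative T1/T2 encoding of the sequence (which is all the k-space
#' interpolators depend on) without claiming quantitative fidelity to any
#' scanner implementation.
#'
#' @param t1_ms,t2_ms relaxation times in ms (positive).
#' @param acq an [make_acq()] schedule.
#' @return complex vector of length `acq$T`.
#' @export
simulate_fingerprint <- function(t1_ms, t2_ms, acq) {
  check_that(is.numeric(t1_ms) && t1_ms > 0, "t1_ms must be positive")
  check_that(is.numeric(t2_ms) && t2_ms > 0, "t2_ms must be positive")
  check_that(inherits(acq, "acq_schedule"), "acq must be an acq_schedule")
  mz <- if (acq$inversion) -1 else 1
  e1_tr <- exp(-acq$tr_ms / t1_ms)
  e2_te <- exp(-acq$te_ms / t2_ms)
  s <- numeric(acq$T)
  a <- acq$flip_deg * pi / 180
  t <- 0L
  for (seg in seq_len(acq$n_segments)) {
    if (seg > 1L) {
      if (acq$seg_wait_ms > 0)
        mz <- 1 + (mz - 1) * exp(-acq$seg_wait_ms / t1_ms)
      tep <- acq$t2prep_te_ms[seg]
      if (tep > 0) mz <- mz * exp(-tep / t2_ms)
    }
    for (j in seq_len(acq$trs_per_segment)) {
      t <- t + 1L
      s[t] <- mz * sin(a[t]) * e2_te
      mz <- mz * cos(a[t])
      mz <- 1 + (mz - 1) * e1_tr
    }
  }
  as.complex(s)
}

#' Digital brain phantom and coil sensitivities
#'
#' Concentric-ellipsoid anatomy (labels 0 background, 1 white matter,
#' 2 grey matter, 3 CSF) with conventional 3T relaxation values
#' (WM 800/70 ms, GM 1300/90 ms, CSF 4000/1800 ms; PD 0.7/0.8/1.0). The
#' ellipsoids are tilted (a head never lies exactly on the scanner axes)
#' and the ventricle sits off-centre, so genuine structure is present
#' along the partition direction rather than a degenerate constant-in-z
#' column profile.
#'
#' Coil model `"array"` (default) emulates a receive array of localised
#' elements arranged in rings around the object (two rings along z when
#' `C >= 4`): Gaussian magnitude profiles centred just outside the object
#' with seed-controlled jitter and smooth linear phase. Localised elements
#' carry usable spatial encoding along the partition direction, which is
#' what makes partition-direction GRAPPA and network interpolation
#' well-posed. Model `"poly"` gives global second-order complex
#' polynomial fields; these are so smooth along z that partition
#' interpolation beyond R = 2 becomes ill-posed, so they are kept only as
#' a degenerate-geometry option. Both are normalised so the
#' root-sum-of-squares magnitude is 1 at every voxel.
#'
#' Within-tissue relaxation heterogeneity: real tissue T1/T2 vary by a few
#' percent around the tissue mean, which also makes the acquisition's
#' temporal structure full-rank — with perfectly homogeneous labels every
#' voxel time course is one of only three fingerprints, and ACS-based
#' kernel calibration becomes rank-deficient in a way real scans never
#' are. `heterogeneity = h` modulates each tissue's (T1, T2) by factors
#' `1 - h, 1, 1 + h` assigned from smooth seeded spatial fields (3 x 3
#' sub-classes per tissue). Set `h = 0` for exactly on-dictionary values
#' (the regime for parameter-recovery checks).
#'
#' @param M in-plane matrix size.
#' @param P number of partitions (slices).
#' @param C number of coils.
#' @param seed integer seed; the output is bit-reproducible given the seed.
#' @param t1_ms,t2_ms,pd per-label tissue values (WM, GM, CSF).
#' @param coil_model `"array"` or `"poly"`.
#' @param heterogeneity fractional within-tissue (T1, T2) spread.
#' @return list with elements `phantom` (class `digital_phantom`: fields
#'   `label_map`, `class_map`, `classes` (one row per tissue sub-class:
#'   `label`, `t1_ms`, `t2_ms`, `pd`), per-label `t1_ms`/`t2_ms`/`pd`)
#'   and `coils` (class `coil_sensitivities`: field `maps`, an
#'   `M x M x P x C` complex array).
#' @export
make_phantom <- function(M, P, C, seed = 0L,
                         t1_ms = c(WM = 800, GM = 1300, CSF = 4000),
                         t2_ms = c(WM = 70, GM = 90, CSF = 1800),
                         pd = c(WM = 0.7, GM = 0.8, CSF = 1.0),
                         coil_model = c("array", "poly"),
                         heterogeneity = 0.04) {
  check_that(M >= 1 && P >= 1 && C >= 1, "M, P, C must be >= 1")
  check_that(all(t1_ms > t2_ms) && all(t2_ms > 0), "need T1 > T2 > 0 per label")
  check_that(heterogeneity >= 0 && heterogeneity < 0.5,
             "heterogeneity must be in [0, 0.5)")
  coil_model <- match.arg(coil_model)
  M <- as.integer(M); P <- as.integer(P); C <- as.integer(C)
  x <- (seq_len(M) - (M + 1) / 2) / (M / 2)
  z <- if (P > 1) (seq_len(P) - (P + 1) / 2) / (P / 2) else 0
  ## tilted coordinates: rotate by fixed angles about x then y
  g <- expand.grid(x = x, y = x, z = z)
  a1 <- 0.28; a2 <- 0.18                       # ~16 and ~10 degrees
  yr <- cos(a1) * g$y - sin(a1) * g$z
  zr <- sin(a1) * g$y + cos(a1) * g$z
  xr <- cos(a2) * g$x - sin(a2) * zr
  zr <- sin(a2) * g$x + cos(a2) * zr
  lab <- array(0L, dim = c(M, M, P))
  ell <- function(ax, ay, az, cx = 0, cy = 0, cz = 0) {
    array(((xr - cx) / ax)^2 + ((yr - cy) / ay)^2 + ((zr - cz) / az)^2 <= 1,
          dim = c(M, M, P))
  }
  lab[ell(0.82, 0.68, 0.88)] <- 2L                 # grey-matter shell
  lab[ell(0.64, 0.52, 0.70)] <- 1L                 # white matter
  lab[ell(0.20, 0.14, 0.33, cx = 0.05, cz = 0.12)] <- 3L  # CSF (ventricle)
  set.seed(as.integer(seed))
  ## tissue sub-classes: 3 T1 levels x 3 T2 levels per label, assigned
  ## from two smooth low-frequency random fields (tertile split)
  smooth_field <- function() {
    co <- rnorm(6)
    array(co[1] * sin(pi * xr + co[4]) + co[2] * sin(pi * yr + co[5]) +
            co[3] * sin(pi * zr + co[6]), dim = c(M, M, P))
  }
  if (heterogeneity > 0) {
    lev <- function(f) {
      q <- stats::quantile(f, c(1 / 3, 2 / 3))
      1L + (f > q[1]) + (f > q[2])
    }
    l1 <- lev(smooth_field()); l2 <- lev(smooth_field())
  } else {
    l1 <- l2 <- array(2L, dim = c(M, M, P))
  }
  classes <- expand.grid(i1 = 1:3, i2 = 1:3, label = 1:3)
  classes$t1_ms <- t1_ms[classes$label] * (1 + heterogeneity * (classes$i1 - 2))
  classes$t2_ms <- t2_ms[classes$label] * (1 + heterogeneity * (classes$i2 - 2))
  classes$pd <- pd[classes$label]
  class_map <- array(0L, dim = c(M, M, P))
  obj <- lab > 0L
  class_map[obj] <- (lab[obj] - 1L) * 9L + (l2[obj] - 1L) * 3L + l1[obj]
  keep <- sort(unique(class_map[obj]))
  remap <- integer(27L); remap[keep] <- seq_along(keep)
  class_map[obj] <- remap[class_map[obj]]
  classes <- classes[keep, c("label", "t1_ms", "t2_ms", "pd")]
  rownames(classes) <- NULL
  phantom <- structure(list(label_map = lab, class_map = class_map,
                            classes = classes, t1_ms = t1_ms, t2_ms = t2_ms,
                            pd = pd, M = M, P = P,
                            heterogeneity = heterogeneity),
                       class = "digital_phantom")
  maps <- array(0i, dim = c(M, M, P, C))
  if (coil_model == "array") {
    n_rings <- if (C >= 4 && P > 1) 2L else 1L
    per_ring <- C %/% n_rings
    for (cc in seq_len(C)) {
      ring <- (cc - 1L) %/% per_ring
      within <- (cc - 1L) %% per_ring
      ang <- 2 * pi * within / per_ring + ring * pi / per_ring
      cz <- if (n_rings > 1) c(-0.45, 0.45)[ring + 1L] else 0
      cx <- 1.15 * cos(ang) + rnorm(1, sd = 0.05)
      cy <- 1.15 * sin(ang) + rnorm(1, sd = 0.05)
      cz <- cz + rnorm(1, sd = 0.05)
      ph_co <- rnorm(3, sd = 0.5)
      ## loop elements: in-plane extent ~ object radius, tighter along z so
      ## adjacent partitions see distinct coil weightings (kz encoding)
      r2 <- outer(outer((x - cx)^2 / (2 * 0.75^2),
                        (x - cy)^2 / (2 * 0.75^2), `+`),
                  (z - cz)^2 / (2 * 0.35^2), `+`)
      phase <- outer(outer(ph_co[1] * x, ph_co[2] * x, `+`),
                     ph_co[3] * z, `+`) + ang
      maps[, , , cc] <- exp(-r2) * exp(1i * phase)
    }
  } else {
    basis <- cbind(1, g$x, g$y, g$z, g$x^2, g$y^2, g$z^2,
                   g$x * g$y, g$x * g$z, g$y * g$z)
    for (cc in seq_len(C)) {
      co <- complex(real = rnorm(10, sd = 0.4), imaginary = rnorm(10, sd = 0.4))
      co[1] <- co[1] + exp(2i * pi * (cc - 1) / C)
      maps[, , , cc] <- array(basis %*% co, dim = c(M, M, P))
    }
  }
  rss <- sqrt(apply(Mod(maps)^2, 1:3, sum))
  rss[rss < 1e-12] <- 1
  maps <- maps / as.vector(rss)                    # recycles over coil axis
  list(phantom = phantom,
       coils = structure(list(maps = maps), class = "coil_sensitivities"))
}

## one fingerprint per tissue sub-class: T x n_classes complex matrix
class_fingerprints <- function(phantom, acq) {
  matrix(vapply(seq_len(nrow(phantom$classes)), function(k)
    simulate_fingerprint(phantom$classes$t1_ms[k], phantom$classes$t2_ms[k],
                         acq), complex(acq$T)),
    nrow = acq$T)
}

## kz-DFT'd coil-weighted sub-class volumes: list over classes of
## M^2 x (P*C) complex matrices, columns ordered partition-fastest.
class_kz_spectra <- function(phantom, coils) {
  M <- phantom$M; P <- phantom$P
  C <- dim(coils$maps)[4]
  Fk <- centered_dft_matrix(P)
  lapply(seq_len(nrow(phantom$classes)), function(k) {
    vol <- (phantom$class_map == k) * phantom$classes$pd[k]
    out <- matrix(0i, M * M, P * C)
    for (cc in seq_len(C)) {
      b <- matrix(vol * coils$maps[, , , cc], M * M, P)
      out[, (cc - 1L) * P + seq_len(P)] <- b %*% t(Fk)
    }
    out
  })
}

frame_coords <- function(traj, angle, n_interleaves = 1L) {
  do.call(rbind, lapply(seq_len(n_interleaves), function(j)
    rotate_coords(traj$coords,
                  angle + 2 * pi * (j - 1) / max(n_interleaves, 1L))))
}

#' Forward-sample multi-coil stack-of-spirals k-space
#'
#' Simulates the acquisition: per frame, the per-voxel image is
#' `PD * fingerprint_t * coil map`; a centered discrete Fourier transform
#' along the partition (kz) direction is followed by the in-plane NUFFT
#' evaluated at the trajectory rotated by the frame's golden angle.
#' Complex white Gaussian noise of standard deviation `noise_sigma` is
#' added i.i.d. All partitions are sampled; apply [undersample()]
#' separately for retrospective acceleration.
#'
#' @param phantom,coils from [make_phantom()].
#' @param traj a [make_spiral()] trajectory.
#' @param sched a [make_schedule()] (its `frame_angles` set the frames).
#' @param acq an [make_acq()] schedule with `acq$T == length(frame_angles)`.
#' @param noise_sigma complex-noise standard deviation (absolute units).
#' @param seed seed for the noise stream.
#' @param n_interleaves in-plane interleaves per frame (1 = accelerated
#'   MRF regime; `traj$n_interleaves_full` = fully sampled in-plane).
#' @param frames optional integer subset of frames (1-based) to simulate.
#' @return object of class `mrf_kspace`: `data` (complex
#'   `T x P x Q_total x C`), `trajectory`, `schedule`, `acq`,
#'   `n_interleaves`, `acquired_mask` (length P, all TRUE), `scale` (1).
#' @export
forward_sample <- function(phantom, coils, traj, sched, acq,
                           noise_sigma = 0, seed = 0L, n_interleaves = 1L,
                           frames = NULL) {
  check_that(inherits(phantom, "digital_phantom"), "phantom type mismatch")
  check_that(inherits(coils, "coil_sensitivities"), "coils type mismatch")
  check_that(noise_sigma >= 0, "noise_sigma must be >= 0")
  dm <- dim(coils$maps)
  check_that(all(dm[1:3] == c(phantom$M, phantom$M, phantom$P)),
             "coil maps do not match phantom dimensions")
  check_that(acq$T == length(sched$frame_angles),
             "acq$T must equal the schedule's frame count")
  check_that(sched$n_partitions == phantom$P,
             "schedule partition count must match phantom")
  M <- phantom$M; P <- phantom$P; C <- dm[4]
  if (is.null(frames)) frames <- seq_len(acq$T)
  Tn <- length(frames)
  Qt <- nrow(traj$coords) * n_interleaves
  f <- class_fingerprints(phantom, acq)
  spectra <- class_kz_spectra(phantom, coils)
  set.seed(as.integer(seed))
  data <- array(0i, dim = c(Tn, P, Qt, C))
  for (ti in seq_len(Tn)) {
    t <- frames[ti]
    G <- f[t, 1] * spectra[[1]]
    for (l in seq_along(spectra)[-1]) G <- G + f[t, l] * spectra[[l]]
    plan <- nufft_plan(frame_coords(traj, sched$frame_angles[t],
                                    n_interleaves), M)
    smp <- nufft_forward(plan, G)                     # Qt x (P*C), p fastest
    if (noise_sigma > 0)
      smp <- smp + noise_sigma *
        complex(real = rnorm(length(smp)), imaginary = rnorm(length(smp)))
    data[ti, , , ] <- aperm(array(smp, dim = c(Qt, P, C)), c(2, 1, 3))
  }
  structure(list(data = data, trajectory = traj, schedule = sched, acq = acq,
                 n_interleaves = as.integer(n_interleaves),
                 frames = frames,
                 acquired_mask = rep(TRUE, P), scale = 1),
            class = "mrf_kspace")
}

#' Retrospective partition-direction undersampling
#'
#' Zeroes every partition outside the schedule's acquired set and records
#' the acquisition mask; acquired partitions are passed through
#' bit-identical.
#'
#' @param ks an `mrf_kspace` object.
#' @param sched a [make_schedule()] with matching partition count.
#' @return the undersampled `mrf_kspace`.
#' @export
undersample <- function(ks, sched) {
  check_that(inherits(ks, "mrf_kspace"), "ks must be an mrf_kspace")
  check_that(sched$n_partitions == dim(ks$data)[2],
             "schedule partition count does not match data")
  mask <- rep(FALSE, sched$n_partitions)
  mask[sched$acquired_indices + 1L] <- TRUE
  ks$data[, !mask, , ] <- 0i
  ks$acquired_mask <- mask
  ks$schedule <- sched
  ks
}

#' Calibrated complex-noise level
#'
#' Noise standard deviation expressed as a fraction of the maximum
#' magnitude over the ACS partitions (or over all partitions when the
#' schedule has no ACS block).
#'
#' @param ks an `mrf_kspace` object (noiseless).
#' @param frac fraction of the ACS peak magnitude.
#' @return absolute `noise_sigma`.
#' @export
noise_sigma_from_acs <- function(ks, frac) {
  idx <- ks$schedule$acs_indices
  if (length(idx) == 0) idx <- ks$schedule$acquired_indices
  frac * max(Mod(ks$data[, idx + 1L, , , drop = FALSE]))
}
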