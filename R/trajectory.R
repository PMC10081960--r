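#' Archimedean spiral readout trajectory
#'
#' Generates a single uniform-density spiral interleaf
#' `k(tau) = k_max * tau * exp(1i * 2 * pi * turns * tau)` sampled at `Q`
#' uniformly spaced parameter values `tau` in `[0, 1]`. Coordinates are in
#' cycles/FOV, normalised to `[-0.5, 0.5)`. Full in-plane sampling is
#' obtained by rotating the arm by multiples of `2*pi/n_interleaves_full`;
#' `turns` should be chosen so that the rotated set tiles the plane at the
#' Nyquist spacing of the target matrix (`turns = k_max * matrix /
#' n_interleaves_full`).
#'
#' @param Q number of readout points on the interleaf (>= 2).
#' @param n_interleaves_full interleaves needed for full in-plane sampling.
#' @param k_max maximum k-space radius in cycles/FOV (<= 0.5).
#' @param turns number of revolutions of the arm; default corresponds to a
#'   256 matrix sampled with 48 interleaves at `k_max = 0.5`.
#' @return an object of class `spiral_trajectory` with fields `coords`
#'   (Q x 2), `n_interleaves_full`, `k_max`, `turns`.
#' @export
#' @examples
#' traj <- make_spiral(256, 48, 0.5)
#' max(sqrt(rowSums(traj$coords^2)))  # = k_max
make_spiral <- function(Q, n_interleaves_full = 48L, k_max = 0.5,
                        turns = k_max * 256 / n_interleaves_full) {
  check_that(is.numeric(Q) && length(Q) == 1 && Q >= 2,
             "Q must be a single integer >= 2")
  check_that(n_interleaves_full >= 1, "n_interleaves_full must be >= 1")
  check_that(is.numeric(k_max) && k_max > 0, "k_max must be positive")
  check_that(k_max <= 0.5 + 1e-12, "k_max must be <= 0.5 cycles/FOV")
  Q <- as.integer(Q)
  tau <- seq(0, 1, length.out = Q)
  ang <- 2 * pi * turns * tau
  coords <- cbind(kx = k_max * tau * cos(ang), ky = k_max * tau * sin(ang))
  structure(list(coords = coords,
                 n_interleaves_full = as.integer(n_interleaves_full),
                 k_max = k_max, turns = turns),
            class = "spiral_trajectory")
}

#' Rotate trajectory coordinates
#'
#' @param coords Q x 2 coordinate matrix.
#' @param theta rotation angle in radians.
#' @return rotated Q x 2 matrix.
#' @export
rotate_coords <- function(coords, theta) {
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  coords %*% rot
}

#' Partition-direction sampling schedule
#'
#' Builds the kz sampling pattern for one acquisition: every `R`-th
#' partition starting at index 0, plus a contiguous auto-calibration (ACS)
#' block centered on the partition-direction k-space center, plus the
#' golden-angle rotation angle of the spiral arm for each time frame.
#' Partition indices are 0-based throughout.
#'
#' ACS centering follows `floor(P/2) - floor(n_acs/2) ... floor(P/2) +
#' ceiling(n_acs/2) - 1`.
#'
#' @param n_partitions number of partitions P.
#' @param R integer acceleration factor along the partition direction.
#' @param n_acs number of central ACS partitions (0 for none).
#' @param T number of time frames (for the golden-angle schedule).
#' @param angle_increment frame-to-frame rotation increment in radians;
#'   defaults to the golden angle `pi * (3 - sqrt(5))` (137.5077...deg).
#' @return an object of class `sampling_schedule` with fields
#'   `n_partitions`, `R`, `n_acs`, `acs_indices`, `acquired_indices`
#'   (sorted, 0-based), `frame_angles` (length `T`, starting at 0), and
#'   `angle_increment`.
#' @export
#' @examples
#' s <- make_schedule(144, 4, 12, T = 8)
#' length(s$acquired_indices)
make_schedule <- function(n_partitions, R, n_acs = 0L, T = 1L,
                          angle_increment = pi * (3 - sqrt(5))) {
  check_that(n_partitions >= 1, "n_partitions must be >= 1")
  check_that(R >= 1 && R <= n_partitions, "R must satisfy 1 <= R <= n_partitions")
  check_that(n_acs >= 0 && n_acs <= n_partitions,
             "n_acs must satisfy 0 <= n_acs <= n_partitions")
  check_that(T >= 1, "T must be >= 1")
  n_partitions <- as.integer(n_partitions); R <- as.integer(R)
  n_acs <- as.integer(n_acs); T <- as.integer(T)
  regular <- seq.int(0L, n_partitions - 1L, by = R)
  acs <- if (n_acs > 0) {
    lo <- n_partitions %/% 2L - n_acs %/% 2L
    seq.int(lo, lo + n_acs - 1L)
  } else integer(0)
  structure(list(n_partitions = n_partitions, R = R, n_acs = n_acs,
                 acs_indices = acs,
                 acquired_indices = sort(union(regular, acs)),
                 frame_angles = (seq_len(T) - 1) * angle_increment,
                 angle_increment = angle_increment),
            class = "sampling_schedule")
}

#' Effective acceleration factor accounting for ACS partitions
#'
#' Closed form `n_partitions * R / (n_partitions + n_acs * (R - 1))`: the
#' nominal factor R discounted by the extra centrally acquired ACS
#' partitions. For a 144-partition acquisition with 12 ACS partitions this
#' reproduces, after rounding to one decimal (half away from zero), the
#' factors 1.8, 2.6, 3.2, 3.8 and 4.2 for R = 2..6. The exact acquired-set
#' count can differ by +/-1 partition when R does not divide
#' `n_partitions`; use `length(make_schedule(...)$acquired_indices)` for
#' the literal count.
#'
#' @inheritParams make_schedule
#' @return effective acceleration (fold), unrounded.
#' @export
#' @examples
#' round_half_away(effective_acceleration(144, 4, 12), 1)  # 3.2
effective_acceleration <- function(n_partitions, R, n_acs = 0L) {
  check_that(n_partitions >= 1, "n_partitions must be >= 1")
  check_that(R >= 1, "R must be >= 1")
  check_that(n_acs >= 0 && n_acs <= n_partitions,
             "n_acs must satisfy 0 <= n_acs <= n_partitions")
  n_partitions * R / (n_partitions + n_acs * (R - 1))
}

#' Temporal and combined acceleration bookkeeping
#'
#' MRF scans are additionally shortened by truncating the fingerprint time
#' series: using the first `n_frames_used` of `n_frames_full` frames gives
#' a temporal factor `n_frames_full / n_frames_used`, which multiplies the
#' partition-direction factor.
#'
#' @param n_frames_full full number of time frames acquired.
#' @param n_frames_used frames retained for reconstruction.
#' @param R_kz nominal partition-direction acceleration factor.
#' @return list with `temporal` and `combined` factors.
#' @export
acceleration_summary <- function(n_frames_full, n_frames_used, R_kz = 1) {
  check_that(n_frames_used >= 1 && n_frames_used <= n_frames_full,
             "need 1 <= n_frames_used <= n_frames_full")
  temporal <- n_frames_full / n_frames_used
  list(temporal = temporal, combined = temporal * R_kz)
}
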