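test_that("fingerprint recursion matches a hand-unrolled oracle", {
  ## 3 TRs, one segment, inversion on: unroll the recursion by hand
  acq <- make_acq(T = 3, n_segments = 1, tr_ms = 9.2, te_ms = 1.3,
                  flip_deg = rep(10, 3), t2prep_te_ms = 0, seg_wait_ms = 0)
  s <- simulate_fingerprint(800, 70, acq)
  a <- 10 * pi / 180
  e1 <- exp(-9.2 / 800); e2 <- exp(-1.3 / 70)
  mz <- -1
  expected <- numeric(3)
  for (t in 1:3) {
    expected[t] <- mz * sin(a) * e2
    mz <- mz * cos(a)
    mz <- 1 + (mz - 1) * e1
  }
  expect_equal(Re(s), expected, tolerance = 1e-12)
})

test_that("zero flip angles give pure inversion recovery", {
  n <- 8
  acq <- make_acq(T = n, n_segments = 1, tr_ms = 12, flip_deg = rep(0, n),
                  t2prep_te_ms = 0, seg_wait_ms = 0)
  s <- simulate_fingerprint(1000, 80, acq)
  expect_true(all(Mod(s) == 0))
  ## track Mz through an extra TR-less probe: emit with a 90-degree pulse
  acq2 <- make_acq(T = n + 1, n_segments = 1, tr_ms = 12,
                   flip_deg = c(rep(0, n), 90), t2prep_te_ms = 0,
                   seg_wait_ms = 0)
  s2 <- simulate_fingerprint(1000, 80, acq2)
  mz_after_n <- 1 - 2 * exp(-n * 12 / 1000)
  expect_equal(Re(s2[n + 1]), mz_after_n * exp(-acq2$te_ms / 80),
               tolerance = 1e-12)
})

test_that("a T2-prep module attenuates Mz by exp(-TE/T2)", {
  ## two segments of one TR each; the boundary carries a 50 ms prep
  base <- make_acq(T = 2, n_segments = 2, tr_ms = 10, flip_deg = c(90, 90),
                   t2prep_te_ms = c(0, 0), inversion = FALSE, seg_wait_ms = 0)
  prep <- make_acq(T = 2, n_segments = 2, tr_ms = 10, flip_deg = c(90, 90),
                   t2prep_te_ms = c(0, 50), inversion = FALSE, seg_wait_ms = 0)
  s0 <- simulate_fingerprint(800, 100, base)
  s1 <- simulate_fingerprint(800, 100, prep)
  ## after a 90-degree pulse Mz = 0, so the second emission comes purely
  ## from T1 recovery; the prep multiplies it by exp(-50/100)
  expect_equal(Re(s1[2]) / Re(s0[2]), exp(-0.5), tolerance = 1e-12)
  expect_error(simulate_fingerprint(-5, 70, base), "t1_ms")
  expect_error(simulate_fingerprint(800, 0, base), "t2_ms")
})

test_that("default fingerprints of distinct tissues are distinguishable", {
  acq <- make_acq()
  f1 <- simulate_fingerprint(800, 70, acq)
  f2 <- simulate_fingerprint(1300, 90, acq)
  ip <- Mod(sum(Conj(f1) * f2)) /
    sqrt(sum(Mod(f1)^2) * sum(Mod(f2)^2))
  expect_lt(ip, 1 - 1e-4)
})

test_that("phantom generation is deterministic and well formed", {
  a <- make_phantom(32, 12, 4, seed = 3)
  b <- make_phantom(32, 12, 4, seed = 3)
  expect_identical(a$phantom, b$phantom)
  expect_identical(a$coils$maps, b$coils$maps)
  expect_setequal(unique(as.vector(a$phantom$label_map)), 0:3)
  rss <- apply(Mod(a$coils$maps)^2, 1:3, sum)
  obj <- a$phantom$label_map > 0
  expect_true(all(rss[obj] >= 1e-6))
  ## per-voxel truth maps respect T1 > T2 inside the mask
  gt <- phantom_maps(a$phantom)
  expect_true(all(gt$t1_ms[gt$mask] > gt$t2_ms[gt$mask]))
  expect_true(all(gt$t2_ms[gt$mask] > 0))
})

test_that("forward sampling satisfies the DC identity and linearity", {
  sim <- tiny_sim()
  p <- sim$params
  fps <- mrfkz:::class_fingerprints(sim$phantom, sim$acq)
  cm <- sim$phantom$class_map
  img1 <- array(0i, dim(cm))
  for (k in seq_len(nrow(sim$phantom$classes))) {
    img1 <- img1 + (cm == k) * sim$phantom$classes$pd[k] * fps[1, k]
  }
  cc <- 1
  dc_true <- sum(img1 * sim$coils$maps[, , , cc])
  dc_ks <- sim$ks$data[1, p$P / 2 + 1, 1, cc]   # k=(0,0), central kz
  expect_lt(Mod(dc_ks - dc_true) / Mod(dc_true), 1e-6)

  ## doubling PD doubles every sample (noiseless linearity)
  ph2 <- make_phantom(p$M, p$P, p$C, seed = 1,
                      pd = 2 * c(WM = 0.7, GM = 0.8, CSF = 1.0))
  ks2 <- forward_sample(ph2$phantom, ph2$coils, sim$traj, sim$sched, sim$acq,
                        seed = 1)
  expect_lt(max(Mod(ks2$data - 2 * sim$ks$data)) / max(Mod(sim$ks$data)),
            1e-12)
})

test_that("fast forward sampling matches a direct discrete-sum oracle", {
  M <- 16L; P <- 8L; C <- 2L
  ph <- make_phantom(M, P, C, seed = 2)
  traj <- make_spiral(200, 8, 0.5, turns = 1)
  sched <- make_schedule(P, 1, 0, T = 1)
  acq <- make_acq(T = 1, n_segments = 1)
  ks <- forward_sample(ph$phantom, ph$coils, traj, sched, acq, seed = 0)
  ## oracle: exact DFT along kz then exact direct sum in-plane
  fps <- mrfkz:::class_fingerprints(ph$phantom, acq)
  cm <- ph$phantom$class_map
  img <- array(0i, dim(cm))
  for (k in seq_len(nrow(ph$phantom$classes)))
    img <- img + (cm == k) * ph$phantom$classes$pd[k] * fps[1, k]
  Fk <- mrfkz:::centered_dft_matrix(P)
  worst <- 0
  for (cc in seq_len(C)) {
    vol <- matrix(img * ph$coils$maps[, , , cc], M * M, P) %*% t(Fk)
    smp <- oracle_nufft(traj$coords, vol, M)       # Q x P
    worst <- max(worst, max(Mod(t(smp) - ks$data[1, , , cc])) /
                   max(Mod(smp)))
  }
  expect_lt(worst, 1e-5)
})

test_that("undersampling zeroes exactly the skipped partitions", {
  sim <- tiny_sim()
  s1 <- make_schedule(sim$params$P, 1, 0, T = sim$params$T)
  expect_identical(undersample(sim$ks, s1)$data, sim$ks$data)

  sched <- make_schedule(16, 4, 4, T = sim$params$T)
  expect_error(undersample(sim$ks, sched), "partition count")

  s2 <- make_schedule(sim$params$P, 2, 2, T = sim$params$T)
  us <- undersample(sim$ks, s2)
  nz <- apply(Mod(us$data), 2, sum) > 0
  expect_identical(which(nz) - 1L, s2$acquired_indices)
  expect_identical(us$data[, s2$acquired_indices + 1L, , ],
                   sim$ks$data[, s2$acquired_indices + 1L, , ])
})

test_that("noiseless k-space energy is rotation invariant for a radially
           symmetric object", {
  M <- 64L; P <- 2L; C <- 1L
  ph <- make_phantom(M, P, C, seed = 5)
  ## overwrite anatomy with an axis-aligned disk (radially symmetric
  ## in-plane), constant along z
  x <- (seq_len(M) - (M + 1) / 2) / (M / 2)
  disk <- outer(x^2, x^2, `+`) <= 0.5^2
  lab <- array(1L * rep(disk, P), dim = c(M, M, P))
  ph$phantom$label_map <- lab
  ph$phantom$class_map <- lab
  ph$phantom$classes <- data.frame(label = 1L, t1_ms = 800, t2_ms = 70,
                                   pd = 1)
  ph$coils$maps <- array(1 + 0i, dim = c(M, M, P, C))
  traj <- make_spiral(256, 48, 0.5, turns = 0.5 * 64 / 48)
  acq <- make_acq(T = 1, n_segments = 1)
  energies <- sapply(c(0, 0.9, 2.3), function(theta) {
    sched <- make_schedule(P, 1, 0, T = 1, angle_increment = 0)
    sched$frame_angles <- theta
    ks <- forward_sample(ph$phantom, ph$coils, traj, sched, acq, seed = 0)
    sum(Mod(ks$data)^2)
  })
  expect_lt(max(abs(energies - energies[1])) / energies[1], 1e-3)
})
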