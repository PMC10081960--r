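test_that("dictionary entries are unit norm, feasible and distinct", {
  acq <- make_acq(T = 12, n_segments = 4)
  t1g <- seq(100, 2000, by = 100)                       # 20 values
  t2g <- c(seq(5, 95, by = 10), 99, 105, 205, 305, 605) # 15 values
  infeasible <- sum(outer(t1g, t2g, `<=`))
  expect_identical(infeasible, 12L)
  d <- build_dictionary(t1g, t2g, acq)
  expect_identical(ncol(d$entries), 20L * 15L - 12L)    # 288
  expect_equal(sqrt(colSums(Mod(d$entries)^2)), rep(1, 288),
               tolerance = 1e-12)
  expect_true(all(d$t1_ms > d$t2_ms))
  ## exhaustive distinctness on a small grid
  d5 <- build_dictionary(seq(400, 1200, length.out = 5),
                         seq(40, 120, length.out = 5), acq)
  E <- d5$entries
  n <- ncol(E)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    expect_gt(sum(Mod(E[, i] - E[, j])^2), 0)
  }
  expect_error(build_dictionary(c(50), c(100), acq), "feasible")
})

test_that("template matching is exact, scale invariant and oracle-equal", {
  acq <- make_acq(T = 24, n_segments = 4)
  d <- build_dictionary(c(400, 800, 1300, 2000), c(40, 70, 90, 120), acq)
  ## a voxel that is exactly a dictionary entry scaled by 3.7
  k0 <- 5L
  series <- matrix(d$entries[, k0] * 3.7, ncol = 1)
  m <- template_match(series, d, mask_frac = 0)
  expect_identical(m$t1_ms[1], d$t1_ms[k0])
  expect_identical(m$t2_ms[1], d$t2_ms[k0])
  expect_equal(m$pd[1], 3.7, tolerance = 1e-10)
  ## invariance to a global nonzero complex constant
  m2 <- template_match(series * (0.3 - 1.2i), d, mask_frac = 0)
  expect_identical(m2$t1_ms[1], m$t1_ms[1])
  expect_identical(m2$t2_ms[1], m$t2_ms[1])

  ## 10 x 10 toy image against a per-voxel brute-force argmax oracle
  set.seed(8)
  idx <- sample(ncol(d$entries), 100, replace = TRUE)
  amp <- runif(100, 0.5, 2)
  S <- d$entries[, idx] * rep(amp, each = acq$T) +
    0.01 * matrix(complex(real = rnorm(acq$T * 100),
                          imaginary = rnorm(acq$T * 100)), acq$T)
  series <- array(S, c(acq$T, 10, 10, 1))
  m3 <- template_match(series, d, mask_frac = 0)
  for (v in seq_len(100)) {
    ip <- abs(Conj(t(d$entries)) %*% S[, v])
    best <- which.max(ip)
    expect_identical(as.vector(m3$t1_ms)[v], d$t1_ms[best])
    expect_identical(as.vector(m3$t2_ms)[v], d$t2_ms[best])
  }
  expect_error(template_match(matrix(0i, acq$T + 1, 4), d), "length")
})

test_that("metrics reproduce hand-computed values and identities", {
  r <- compute_metrics(c(1, 2), c(1, 1))
  expect_equal(r$nmse, 0.5)
  expect_equal(r$relative_l1, 0.5)

  x <- array(runif(24 * 24 * 3), c(24, 24, 3))
  id <- compute_metrics(x, x)
  expect_identical(id$nmse, 0)
  expect_identical(id$relative_l1, 0)
  expect_identical(id$psnr_db, Inf)
  expect_equal(id$ssim, 1, tolerance = 1e-12)

  ## closed-form PSNR under uniform scaling est = ref * (1 + delta)
  set.seed(10)
  ref <- array(runif(500, 0.1, 1), c(500))
  delta <- 10^(-3 / 2)
  est <- ref * (1 + delta)
  r2 <- compute_metrics(est, ref)
  expect_equal(r2$psnr_db,
               20 * log10(max(ref) * sqrt(500) / (delta * sqrt(sum(ref^2)))),
               tolerance = 1e-10)

  ## nmse and relative L1 of (alpha * ref vs ref) depend only on alpha
  alpha <- 0.8
  a <- compute_metrics(alpha * ref, ref)
  ref2 <- array(runif(300, 0.5, 3), c(300))
  b <- compute_metrics(alpha * ref2, ref2)
  expect_equal(a$nmse, b$nmse, tolerance = 1e-12)
  expect_equal(a$relative_l1, b$relative_l1, tolerance = 1e-12)

  expect_error(compute_metrics(c(1, 2), c(0, 0)), "zero")
  expect_error(compute_metrics(c(1, 2), c(1, 2, 3)), "shape")
})

test_that("reconstruction demands complete k-space and preserves zeros", {
  sim <- tiny_sim()
  us <- undersample(sim$ks, make_schedule(sim$params$P, 2, 2,
                                          T = sim$params$T))
  expect_error(reconstruct_frames(us, coils = sim$coils), "missing")
  z <- sim$ks
  z$data[] <- 0i
  img <- reconstruct_frames(z, combine = "sens", coils = sim$coils,
                            frames = 1)
  expect_true(all(Mod(img) == 0))
})

test_that("frame reconstruction approximates the simulated image", {
  sim <- tiny_sim()
  fps <- mrfkz:::class_fingerprints(sim$phantom, sim$acq)
  cm <- sim$phantom$class_map
  truth <- array(0i, dim(cm))
  for (k in seq_len(nrow(sim$phantom$classes)))
    truth <- truth + (cm == k) * sim$phantom$classes$pd[k] * fps[1, k]
  ref <- reference_series(sim$phantom, sim$coils, sim$traj, sim$sched,
                          sim$acq, frames = 1)
  err <- sqrt(sum(Mod(ref[1, , , ] - truth)^2) / sum(Mod(truth)^2))
  expect_lt(err, 0.2)   # tiny 16-voxel matrix: Gibbs-limited
})
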