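test_that("training-pair construction counts and layouts", {
  Tn <- 2L; Pa <- 12L; Q <- 6L; C <- 3L
  acs <- array(complex(real = rnorm(Tn * Pa * Q * C),
                       imaginary = rnorm(Tn * Pa * Q * C)),
               c(Tn, Pa, Q, C))
  p2 <- make_training_pairs(acs, R = 2)
  expect_length(p2, 10L * Tn)
  p4 <- make_training_pairs(acs, R = 4)
  expect_length(p4, 8L * Tn)
  expect_identical(dim(p4[[1]]$target), c(Q, 3L * 2L * C))
  expect_identical(dim(p4[[1]]$input), c(Q, 2L * 2L * C))
  expect_error(make_training_pairs(acs[, 1:3, , , drop = FALSE], R = 4),
               "P_acs")
  ## real/imag stacking across 32 coils gives 128 input features
  acs32 <- array(0i, c(1, 5, 2, 32))
  expect_identical(ncol(make_training_pairs(acs32, R = 2)[[1]]$input), 128L)
})

test_that("default block channels follow the full-size reference architecture", {
  cfg <- interpolator_config("gcn", R = 2, n_coils = 8)
  expect_identical(cfg$block_channels, c(512L, 1024L, 1024L))
  expect_identical(cfg$in_channels, 32L)
  expect_identical(cfg$out_channels, 16L)
})

test_that("learning-rate schedule is the closed-form decay", {
  tc <- training_config()
  expect_identical(lr_at_epoch(tc, 0), 5e-4)
  expect_equal(lr_at_epoch(tc, 10), 5e-4 * 0.99^10, tolerance = 1e-15)
})

test_that("gcn with K = 1 equals a pointwise CNN with shared weights", {
  Q <- 16L
  graph <- build_adjacency(make_spiral(Q, 8, 0.5)$coords, K = 1)
  cfg_g <- interpolator_config("gcn", R = 2, n_coils = 2, n_blocks = 2,
                               block_channels = c(6L, 8L, 8L), K = 1L)
  cfg_c <- interpolator_config("cartesian_cnn", R = 2, n_coils = 2,
                               n_blocks = 2, block_channels = c(6L, 8L, 8L),
                               cnn_kernel = 1L)
  set.seed(1); g <- build_interpolator(cfg_g, graph)
  set.seed(2); c <- build_interpolator(cfg_c)
  c <- mrfkz:::net_set_params(c, mrfkz:::net_params(g))
  x <- matrix(rnorm(Q * cfg_g$in_channels), Q)
  expect_lt(max(abs(predict(g, x) - predict(c, x))), 1e-6)
})

test_that("a single graph convolution equals the dense matrix oracle", {
  Q <- 8L
  co <- cbind(c(0, .1, .3, .32, .5, .7, .75, 1), c(0, .2, .1, .4, .5, .45, .8, 1))
  graph <- build_adjacency(co, K = 3)
  set.seed(6)
  ly <- mrfkz:::layer_new("graph", 4L, 5L)
  H <- matrix(rnorm(Q * 4), Q)
  fast <- pmax(mrfkz:::layer_forward(ly, H, graph$propagation)$Z, 0)
  dense <- pmax(as.matrix(graph$propagation) %*% H %*% ly$W +
                  matrix(ly$b, Q, 5L, byrow = TRUE), 0)
  expect_lt(max(abs(fast - dense)), 1e-6)
})

test_that("gcn has fewer parameters than the Cartesian CNN", {
  graph <- build_adjacency(make_spiral(32, 8, 0.5)$coords, K = 5)
  for (nb in c(1L, 3L)) {
    cfg_g <- interpolator_config("gcn", R = 4, n_coils = 8, n_blocks = nb,
                                 block_channels = c(64L, 128L, 128L))
    cfg_c <- interpolator_config("cartesian_cnn", R = 4, n_coils = 8,
                                 n_blocks = nb,
                                 block_channels = c(64L, 128L, 128L))
    expect_lt(count_parameters(build_interpolator(cfg_g, graph)),
              count_parameters(build_interpolator(cfg_c)))
  }
})

test_that("training is deterministic and reduces the loss", {
  us <- mid_undersampled()
  pairs <- make_training_pairs(acs_block(us), R = 2)[1:4]
  graph <- build_adjacency(mid_sim()$traj$coords, K = 5)
  cfg <- interpolator_config("gcn", R = 2, n_coils = 8, n_blocks = 1,
                             block_channels = c(8L, 16L, 16L), K = 5L)
  run <- function() {
    m <- train_interpolator(build_interpolator(cfg, graph), pairs,
                            training_config(epochs = 30, seed = 42))
    m$loss_history
  }
  h1 <- run(); h2 <- run()
  expect_lt(abs(tail(h1, 1) - tail(h2, 1)), 1e-10)
  expect_lt(tail(h1, 1), h1[1])
  ## smoothed loss history is non-increasing
  sm <- stats::filter(h1, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 1e-6))
})

test_that("network outputs stay finite on random inputs", {
  graph <- build_adjacency(make_spiral(12, 8, 0.5)$coords, K = 3)
  cfg <- interpolator_config("gcn", R = 2, n_coils = 1, n_blocks = 1,
                             block_channels = c(4L, 6L, 6L), K = 3L)
  set.seed(0)
  m <- build_interpolator(cfg, graph)
  for (i in 1:100) {
    x <- matrix(rnorm(12 * cfg$in_channels, sd = 10), 12)
    expect_true(all(is.finite(predict(m, x))))
  }
})

test_that("interpolation honours data consistency and completeness", {
  sim <- mid_sim()
  us <- mid_undersampled()
  mdl <- fixture("mid_gcn", function() {
    graph <- build_adjacency(sim$traj$coords, K = 5)
    cfg <- interpolator_config("gcn", R = 2, n_coils = 8, n_blocks = 1,
                               block_channels = c(32L, 64L, 64L), K = 5L)
    train_interpolator(build_interpolator(cfg, graph),
                       make_training_pairs(acs_block(us), R = 2),
                       training_config(epochs = 15, seed = 0))
  })
  out <- interpolate_partitions(mdl, us)
  aidx <- sim$sched$acquired_indices + 1L
  expect_identical(out$data[, aidx, , ], us$data[, aidx, , ])
  expect_true(all(out$acquired_mask))
  expect_true(all(apply(Mod(out$data), 2, sum) > 0))
})

test_that("trained GCN beats nearest-neighbour partition copy", {
  sim <- mid_sim()
  us <- mid_undersampled()
  mdl <- fixture_env$mid_gcn
  comp <- interpolate_partitions(mdl, us)
  nn <- us
  aidx <- sim$sched$acquired_indices
  for (t in seq_len(dim(us$data)[1])) {
    for (q in setdiff(0:(sim$sched$n_partitions - 1L), aidx)) {
      src <- aidx[which.min(abs(aidx - q))]
      nn$data[t, q + 1L, , ] <- us$data[t, src + 1L, , ]
    }
  }
  nm_gcn <- skipped_partition_nmse(comp, sim$ks, sim$sched)
  nm_nn <- skipped_partition_nmse(zero_fill(nn), sim$ks, sim$sched)
  expect_lt(nm_gcn, nm_nn)
  expect_lt(nm_gcn, 1)
})

test_that("mismatched configurations are rejected", {
  expect_error(interpolator_config("gcn", R = 1, n_coils = 2), "R")
  graph <- build_adjacency(make_spiral(8, 8, 0.5)$coords, K = 2)
  cfg <- interpolator_config("gcn", R = 2, n_coils = 2)
  expect_error(build_interpolator(cfg, graph = NULL), "kspace_graph")
  expect_error(train_interpolator(build_interpolator(cfg, graph), list()),
               "pairs")
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(3)
  Q <- 10L
  graph <- build_adjacency(make_spiral(Q, 8, 0.5)$coords, K = 3)
  cfg <- interpolator_config("gcn", R = 2, n_coils = 2, n_blocks = 2,
                             block_channels = c(5L, 7L, 6L), K = 3L)
  m <- build_interpolator(cfg, graph)
  x <- matrix(rnorm(Q * cfg$in_channels), Q)
  y <- matrix(rnorm(Q * cfg$out_channels), Q)
  loss_of <- function(mm) mean((mrfkz:::net_forward(mm, x) - y)^2)
  fw <- mrfkz:::net_forward(m, x, want_cache = TRUE)
  flat <- mrfkz:::flatten_grads(
    mrfkz:::net_backward(m, fw, 2 * (fw$out - y) / length(y)), m)
  params <- mrfkz:::net_params(m)
  eps <- 1e-6
  for (nm in names(params)) {
    p <- params[[nm]]
    for (j in sample(length(p), min(3, length(p)))) {
      p2 <- params
      p2[[nm]][j] <- p2[[nm]][j] + eps
      num <- (loss_of(mrfkz:::net_set_params(m, p2)) - loss_of(m)) / eps
      expect_equal(flat[[nm]][j], num, tolerance = 1e-3)
    }
  }
})
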