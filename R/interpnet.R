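#' Interpolator network configuration
#'
#' Architecture shared by the Cartesian CNN and the GCN: `n_blocks`
#' residual blocks, each with one aggregation layer (width-3 1-D
#' convolution for the CNN; propagation-matrix graph convolution for the
#' GCN) followed by two pointwise (width-1) layers, all ReLU-activated
#' except the pre-residual layer; a learned pointwise projection bridges
#' channel mismatches on the shortcut; a final linear pointwise map
#' produces the `(R-1) * 2 * n_coils` output channels. Default block
#' channels are 512, 1024, 1024.
#'
#' @param kind `"cartesian_cnn"` or `"gcn"`.
#' @param R partition-direction acceleration factor.
#' @param n_coils number of receive coils C.
#' @param n_blocks number of residual blocks (GCN-1B/GCN-3B presets: 1/3).
#' @param block_channels integer triple of filters per block layer.
#' @param K graph kernel size (neighbours retained per row; GCN only).
#' @param cnn_kernel width of the CNN aggregation convolution (3, or 1 for
#'   a purely pointwise first layer).
#' @return an `interp_config` object; `in_channels = 2*2*n_coils`,
#'   `out_channels = (R-1)*2*n_coils`.
#' @export
interpolator_config <- function(kind = c("gcn", "cartesian_cnn"), R, n_coils,
                                n_blocks = 3L,
                                block_channels = c(512L, 1024L, 1024L),
                                K = 5L, cnn_kernel = 3L) {
  kind <- match.arg(kind)
  check_that(R >= 2, "R must be >= 2 for interpolation")
  check_that(n_blocks >= 1, "n_blocks must be >= 1")
  check_that(length(block_channels) == 3 && all(block_channels >= 1),
             "block_channels must be a positive integer triple")
  check_that(cnn_kernel %in% c(1L, 3L), "cnn_kernel must be 1 or 3")
  structure(list(kind = kind, R = as.integer(R), n_coils = as.integer(n_coils),
                 n_blocks = as.integer(n_blocks),
                 block_channels = as.integer(block_channels),
                 K = as.integer(K), cnn_kernel = as.integer(cnn_kernel),
                 in_channels = 4L * as.integer(n_coils),
                 out_channels = (as.integer(R) - 1L) * 2L * as.integer(n_coils)),
            class = "interp_config")
}

#' Training configuration
#'
#' @param lr0 initial learning rate.
#' @param lr_decay_per_epoch multiplicative decay applied at the end of
#'   each epoch (0.99 = "decayed by a factor of 99%").
#' @param batch_size samples per optimisation step.
#' @param epochs number of passes over the training pairs.
#' @param seed seed controlling initialisation and sample order.
#' @return a `training_config` object.
#' @export
training_config <- function(lr0 = 5e-4, lr_decay_per_epoch = 0.99,
                            batch_size = 1L, epochs = 100L, seed = 0L) {
  check_that(lr_decay_per_epoch > 0 && lr_decay_per_epoch <= 1,
             "lr_decay_per_epoch must be in (0, 1]")
  structure(list(lr0 = lr0, lr_decay_per_epoch = lr_decay_per_epoch,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 loss = "mse"),
            class = "training_config")
}

#' Learning rate after a number of completed epochs
#' @param tcfg a [training_config()].
#' @param epochs_completed number of finished epochs.
#' @return `lr0 * decay^epochs_completed`.
#' @export
lr_at_epoch <- function(tcfg, epochs_completed) {
  tcfg$lr0 * tcfg$lr_decay_per_epoch^epochs_completed
}

## --- real/imag channel stacking --------------------------------------

pair_features <- function(A, B) cbind(Re(A), Im(A), Re(B), Im(B))

target_features <- function(parts) {
  ## parts: list of Q x C complex matrices (offsets m = 1..R-1)
  do.call(cbind, lapply(parts, function(p) cbind(Re(p), Im(p))))
}

target_complex <- function(feat, m, C) {
  off <- (m - 1L) * 2L * C
  feat[, off + seq_len(C), drop = FALSE] +
    1i * feat[, off + C + seq_len(C), drop = FALSE]
}

#' Build self-calibration training pairs from ACS partitions
#'
#' One pair per (frame, start position): input is the real/imaginary
#' coil-stacked data of two acquired partitions `p` and `p + R`
#' (`Q x 2*2*C` reals, ordered: partition A real coils 1..C, A imaginary,
#' B real, B imaginary), target the `R - 1` partitions in between
#' (`Q x (R-1)*2*C`, ordered by offset, real before imaginary). All
#' features are divided by the global ACS scale `max(|acs|)`; with
#' `normalize = "pair"` (default) each pair (input and target jointly) is
#' additionally divided by the RMS of its own input, so the network sees
#' amplitude-equivariant examples — k-space magnitudes span orders of
#' magnitude between central and outer kz partitions, and a net trained
#' on raw scales does not extrapolate from the central ACS amplitudes to
#' the outer partitions it must predict. The matching inference
#' ([interpolate_partitions()]) rescales by the input pair's own RMS, so
#' no per-pair statistics need to be stored.
#'
#' @param acs complex `T x P_acs x Q x C` array.
#' @param R acceleration factor.
#' @param stride step between start positions (ACS stride, default 1).
#' @param normalize `"pair"` (input-RMS equivariant) or `"global"`
#'   (global ACS scale only).
#' @return list of pairs (each with `input`, `target`, `frame`,
#'   `position`), with attributes `scale` and `normalize`.
#' @export
make_training_pairs <- function(acs, R, stride = 1L,
                                normalize = c("pair", "global")) {
  normalize <- match.arg(normalize)
  d <- dim(acs)
  check_that(length(d) == 4, "acs must be a T x P_acs x Q x C array")
  check_that(d[2] > R, "too few ACS partitions: need P_acs >= R + 1")
  scale <- max(Mod(acs))
  if (scale == 0) scale <- 1
  starts <- seq.int(0L, d[2] - 1L - R, by = stride)
  pairs <- list()
  for (t in seq_len(d[1])) for (p in starts) {
    A <- matrix(acs[t, p + 1L, , ], d[3], d[4])
    B <- matrix(acs[t, p + R + 1L, , ], d[3], d[4])
    tg <- lapply(seq_len(R - 1L), function(m)
      matrix(acs[t, p + m + 1L, , ], d[3], d[4]))
    input <- pair_features(A, B) / scale
    target <- target_features(tg) / scale
    if (normalize == "pair") {
      s <- sqrt(mean(input^2))
      if (s > 0) { input <- input / s; target <- target / s }
    }
    pairs[[length(pairs) + 1L]] <-
      list(input = input, target = target, frame = t, position = p)
  }
  attr(pairs, "scale") <- scale
  attr(pairs, "normalize") <- normalize
  pairs
}

## --- layers -----------------------------------------------------------

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

unfold3 <- function(H) {
  Q <- nrow(H)
  zero <- matrix(0, 1, ncol(H))
  cbind(rbind(zero, H[-Q, , drop = FALSE]),       # neighbour i-1
        H,
        rbind(H[-1, , drop = FALSE], zero))       # neighbour i+1
}

fold3 <- function(dHcat, nc) {
  Q <- nrow(dHcat)
  d1 <- dHcat[, seq_len(nc), drop = FALSE]
  d2 <- dHcat[, nc + seq_len(nc), drop = FALSE]
  d3 <- dHcat[, 2 * nc + seq_len(nc), drop = FALSE]
  zero <- matrix(0, 1, nc)
  rbind(d1[-1, , drop = FALSE], zero) + d2 + rbind(zero, d3[-Q, , drop = FALSE])
}

layer_new <- function(kind, n_in, n_out) {
  fan_in <- if (kind == "conv3") 3L * n_in else n_in
  list(kind = kind, n_in = n_in, n_out = n_out,
       W = glorot(fan_in, n_out), b = numeric(n_out))
}

layer_forward <- function(layer, H, prop) {
  A <- switch(layer$kind,
              conv3 = unfold3(H),
              graph = as.matrix(prop %*% H),
              pw = H)
  list(A = A, Z = sweep(A %*% layer$W, 2, layer$b, `+`))
}

layer_backward <- function(layer, cache, dZ, prop) {
  g <- list(W = crossprod(cache$A, dZ), b = colSums(dZ))
  dA <- dZ %*% t(layer$W)
  dH <- switch(layer$kind,
               conv3 = fold3(dA, layer$n_in),
               graph = as.matrix(Matrix::t(prop) %*% dA),
               pw = dA)
  list(grads = g, dH = dH)
}

#' Build a k-space interpolator network
#'
#' @param cfg an [interpolator_config()].
#' @param graph a [build_adjacency()] `kspace_graph` (required for
#'   `kind = "gcn"`; its `Q` must match the data).
#' @return an object of class `kz_interpolator` with untrained,
#'   seed-controlled variance-scaled uniform weights (set the seed with
#'   `set.seed()` or via [train_interpolator()]'s config before building
#'   for reproducible initialisation).
#' @export
build_interpolator <- function(cfg, graph = NULL) {
  check_that(inherits(cfg, "interp_config"), "cfg must be an interp_config")
  if (cfg$kind == "gcn") {
    check_that(inherits(graph, "kspace_graph"), "gcn requires a kspace_graph")
  }
  agg_kind <- if (cfg$kind == "gcn") "graph" else
    if (cfg$cnn_kernel == 3L) "conv3" else "pw"
  bc <- cfg$block_channels
  blocks <- list()
  prev <- cfg$in_channels
  for (b in seq_len(cfg$n_blocks)) {
    blk <- list(l1 = layer_new(agg_kind, prev, bc[1]),
                l2 = layer_new("pw", bc[1], bc[2]),
                l3 = layer_new("pw", bc[2], bc[3]),
                proj = if (prev != bc[3]) layer_new("pw", prev, bc[3]))
    blocks[[b]] <- blk
    prev <- bc[3]
  }
  structure(list(cfg = cfg,
                 prop = if (cfg$kind == "gcn") graph$propagation,
                 blocks = blocks,
                 final = layer_new("pw", prev, cfg$out_channels),
                 scale = 1),
            class = "kz_interpolator")
}

net_forward <- function(model, H, want_cache = FALSE) {
  prop <- model$prop
  caches <- list()
  for (b in seq_along(model$blocks)) {
    blk <- model$blocks[[b]]
    Hin <- H
    f1 <- layer_forward(blk$l1, Hin, prop); H1 <- pmax(f1$Z, 0)
    f2 <- layer_forward(blk$l2, H1, prop); H2 <- pmax(f2$Z, 0)
    f3 <- layer_forward(blk$l3, H2, prop)
    if (is.null(blk$proj)) { sc <- Hin; fs <- NULL }
    else { fs <- layer_forward(blk$proj, Hin, prop); sc <- fs$Z }
    Z4 <- f3$Z + sc
    H <- pmax(Z4, 0)
    if (want_cache)
      caches[[b]] <- list(Hin = Hin, f1 = f1, H1 = H1, f2 = f2, H2 = H2,
                          f3 = f3, fs = fs, Z4 = Z4)
  }
  ff <- layer_forward(model$final, H, prop)
  if (want_cache) list(out = ff$Z, caches = caches, Hfin = H, ffin = ff)
  else ff$Z
}

net_backward <- function(model, fw, dOut) {
  prop <- model$prop
  grads <- list()
  bf <- layer_backward(model$final, fw$ffin, dOut, prop)
  grads$final <- bf$grads
  dH <- bf$dH
  for (b in rev(seq_along(model$blocks))) {
    blk <- model$blocks[[b]]; ca <- fw$caches[[b]]
    dZ4 <- dH * (ca$Z4 > 0)
    g <- list()
    b3 <- layer_backward(blk$l3, ca$f3, dZ4, prop); g$l3 <- b3$grads
    dH2 <- b3$dH * (ca$f2$Z > 0)
    b2 <- layer_backward(blk$l2, ca$f2, dH2, prop); g$l2 <- b2$grads
    dH1 <- b2$dH * (ca$f1$Z > 0)
    b1 <- layer_backward(blk$l1, ca$f1, dH1, prop); g$l1 <- b1$grads
    dH <- b1$dH
    if (is.null(blk$proj)) dH <- dH + dZ4
    else {
      bp <- layer_backward(blk$proj, ca$fs, dZ4, prop); g$proj <- bp$grads
      dH <- dH + bp$dH
    }
    grads[[paste0("block", b)]] <- g
  }
  grads
}

## flatten parameters to a named list of matrices/vectors for the
## optimiser and for weight sharing across equivalent architectures
net_params <- function(model) {
  out <- list()
  for (b in seq_along(model$blocks)) for (nm in c("l1", "l2", "l3", "proj")) {
    ly <- model$blocks[[b]][[nm]]
    if (is.null(ly)) next
    out[[paste0("block", b, ".", nm, ".W")]] <- ly$W
    out[[paste0("block", b, ".", nm, ".b")]] <- ly$b
  }
  out$final.W <- model$final$W
  out$final.b <- model$final$b
  out
}

net_set_params <- function(model, params) {
  for (b in seq_along(model$blocks)) for (nm in c("l1", "l2", "l3", "proj")) {
    if (is.null(model$blocks[[b]][[nm]])) next
    model$blocks[[b]][[nm]]$W <- params[[paste0("block", b, ".", nm, ".W")]]
    model$blocks[[b]][[nm]]$b <- params[[paste0("block", b, ".", nm, ".b")]]
  }
  model$final$W <- params$final.W
  model$final$b <- params$final.b
  model
}

#' Number of learnable parameters
#' @param model a `kz_interpolator`.
#' @return integer count of weights and biases.
#' @export
count_parameters <- function(model) {
  sum(vapply(net_params(model), length, integer(1)))
}

#' Predict with an interpolator network
#'
#' @param object a `kz_interpolator`.
#' @param input `Q x in_channels` real feature matrix.
#' @param ... unused.
#' @return `Q x out_channels` real prediction.
#' @export
predict.kz_interpolator <- function(object, input, ...) {
  net_forward(object, input)
}

#' Train an interpolator on ACS pairs (self-calibration)
#'
#' Minimises the mean squared error between the network output and the
#' skipped ACS partitions using ADAM (batch size 1 by default), with the
#' learning rate multiplied by `lr_decay_per_epoch` at the end of each
#' epoch. Fully deterministic given `tcfg$seed` (which also re-initialises
#' the weights).
#'
#' @param model a [build_interpolator()] network.
#' @param pairs training pairs from [make_training_pairs()].
#' @param tcfg a [training_config()].
#' @return the trained model, with `$loss_history` (per-epoch mean MSE)
#'   and `$scale` (the ACS normalisation factor carried from the pairs).
#' @export
train_interpolator <- function(model, pairs, tcfg = training_config()) {
  check_that(length(pairs) > 0, "no training pairs supplied")
  set.seed(tcfg$seed)
  ## re-initialise under the training seed for reproducibility
  model <- build_interpolator(model$cfg,
                              graph = if (!is.null(model$prop))
                                structure(list(propagation = model$prop),
                                          class = "kspace_graph"))
  params <- net_params(model)
  m1 <- lapply(params, function(p) p * 0)
  m2 <- m1
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  lr <- tcfg$lr0
  history <- numeric(tcfg$epochs)
  for (epoch in seq_len(tcfg$epochs)) {
    ord <- sample.int(length(pairs))
    total <- 0
    for (idx in ord) {
      pr <- pairs[[idx]]
      fw <- net_forward(model, pr$input, want_cache = TRUE)
      err <- fw$out - pr$target
      loss <- mean(err^2)
      if (!is.finite(loss)) stop("training diverged: loss is not finite")
      total <- total + loss
      grads <- net_backward(model, fw, 2 * err / length(err))
      flat <- flatten_grads(grads, model)
      step <- step + 1L
      for (nm in names(params)) {
        g <- flat[[nm]]
        m1[[nm]] <- beta1 * m1[[nm]] + (1 - beta1) * g
        m2[[nm]] <- beta2 * m2[[nm]] + (1 - beta2) * g^2
        mh <- m1[[nm]] / (1 - beta1^step)
        vh <- m2[[nm]] / (1 - beta2^step)
        params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
      }
      model <- net_set_params(model, params)
    }
    history[epoch] <- total / length(pairs)
    lr <- lr * tcfg$lr_decay_per_epoch
  }
  model$loss_history <- history
  model$scale <- attr(pairs, "scale") %||% 1
  model$normalize <- attr(pairs, "normalize") %||% "global"
  model$tcfg <- tcfg
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

flatten_grads <- function(grads, model) {
  out <- list()
  for (b in seq_along(model$blocks)) {
    g <- grads[[paste0("block", b)]]
    for (nm in names(g)) {
      out[[paste0("block", b, ".", nm, ".W")]] <- g[[nm]]$W
      out[[paste0("block", b, ".", nm, ".b")]] <- g[[nm]]$b
    }
  }
  out$final.W <- grads$final$W
  out$final.b <- grads$final$b
  out
}

#' Interpolate all skipped partitions with a trained network
#'
#' Each group of `R - 1` skipped partitions is predicted from its two
#' flanking acquired partitions; acquired partitions pass through
#' unchanged; features are normalised by the training ACS scale and the
#' prediction de-normalised. Trailing skipped partitions with a single
#' flanking neighbour reuse that neighbour for the missing flank.
#'
#' @param model a trained `kz_interpolator`.
#' @param ks an undersampled `mrf_kspace` with matching `R`, `Q`, `C`.
#' @return completed `mrf_kspace`, `acquired_mask` all `TRUE`.
#' @export
interpolate_partitions <- function(model, ks) {
  check_that(inherits(model, "kz_interpolator"), "model type mismatch")
  check_that(inherits(ks, "mrf_kspace"), "ks must be an mrf_kspace")
  d <- dim(ks$data)
  C <- model$cfg$n_coils; R <- model$cfg$R
  check_that(d[4] == C, "coil count does not match model")
  check_that(ks$schedule$R == R, "acceleration factor does not match model")
  scale <- model$scale %||% 1
  acq <- which(ks$acquired_mask) - 1L
  missing <- setdiff(0:(d[2] - 1L), acq)
  out <- ks
  for (t in seq_len(d[1])) {
    done <- logical(d[2])
    for (q in missing) {
      if (done[q + 1L]) next
      lo <- suppressWarnings(max(acq[acq < q]))
      hi <- suppressWarnings(min(acq[acq > q]))
      if (!(is.finite(lo) && is.finite(hi) && hi - lo == R)) {
        if (is.finite(lo)) hi <- lo else { lo <- hi }
      }
      A <- matrix(ks$data[t, lo + 1L, , ], d[3], d[4]) / scale
      B <- matrix(ks$data[t, hi + 1L, , ], d[3], d[4]) / scale
      input <- pair_features(A, B)
      ps <- 1
      if (identical(model$normalize %||% "global", "pair")) {
        ps <- sqrt(mean(input^2))
        if (ps == 0) ps <- 1
      }
      pred <- net_forward(model, input / ps) * ps
      for (m in seq_len(R - 1L)) {
        q2 <- lo + m
        if (hi == lo) q2 <- min(lo + m, d[2] - 1L)
        if (q2 > d[2] - 1L || ks$acquired_mask[q2 + 1L] || done[q2 + 1L]) next
        out$data[t, q2 + 1L, , ] <- target_complex(pred, m, C) * scale
        done[q2 + 1L] <- TRUE
      }
    }
  }
  out$acquired_mask <- rep(TRUE, d[2])
  out
}
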