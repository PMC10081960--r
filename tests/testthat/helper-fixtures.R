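## Fixtures are generated in code and cached for the session.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

tiny_sim <- function() fixture("tiny_sim", function()
  simulate_mrf(mrf_preset("tiny"), seed = 1))

## mid-size acquisition with enough coil/kz encoding for interpolation
## quality properties (R = 2), still seconds-scale
mid_sim <- function() fixture("mid_sim", function()
  simulate_mrf(mrf_preset("desk"), seed = 1, M = 48L, P = 16L, Q = 384L,
               T = 24L, n_acs = 8L, R = 2L, noise_frac = 0))

mid_undersampled <- function() fixture("mid_us", function()
  undersample(mid_sim()$ks, mid_sim()$sched))

## brute-force O(Q^2) adjacency oracle, independent of build_adjacency
oracle_adjacency <- function(coords, K) {
  Q <- nrow(coords)
  D <- matrix(0, Q, Q)
  for (i in 1:Q) for (j in 1:Q)
    D[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
  dbar <- mean(D[upper.tri(D)])
  A <- exp(-(D / dbar)^2)
  out <- matrix(0, Q, Q)
  for (i in 1:Q) {
    ord <- order(-A[i, ], seq_len(Q))[seq_len(K)]
    out[i, ord] <- A[i, ord]
  }
  out
}

## direct discrete-sum transform oracle (exact DFT, no gridding):
## image stack (M^2 x L) sampled at coords, centered conventions
oracle_nufft <- function(coords, img, M) {
  n <- (seq_len(M) - 1) - M %/% 2
  out <- matrix(0i, nrow(coords), ncol(img))
  for (q in seq_len(nrow(coords))) {
    px <- exp(-2i * pi * coords[q, 1] * n)
    py <- exp(-2i * pi * coords[q, 2] * n)
    ph <- outer(px, py)
    out[q, ] <- crossprod(matrix(as.vector(ph), ncol = 1), img)
  }
  out
}
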