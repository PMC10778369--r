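# Shared fixtures. Expensive artifacts (trained networks, tile sets) are
# built lazily once per session and cached here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small labeled tile sets for unit tests (96 px keeps them cheap)
small_tiles <- function(n = 8, seed = 101, size = 96L) {
  cached(sprintf("tiles_%d_%d_%d", n, seed, size), function() {
    synth_dataset(n, seed = seed, size_px = size)
  })
}

# a tiny untrained network
fresh_net <- function(seed = 1L) build_network(network_config("tiny"), seed)

# stub "network": per-channel 8x8 block mean of the input (commutes with
# aligned tiling, so corner-mosaic and center-crop routes agree exactly)
stub_block_mean <- function(img) {
  h <- dim(img)[1] %/% 8L; w <- dim(img)[2] %/% 8L
  out <- array(0, c(h, w, dim(img)[3]))
  for (c in seq_len(dim(img)[3])) {
    m <- img[, , c]
    dim(m) <- c(8L, h, 8L * w)
    m <- colMeans(m)                 # h x (8w)
    m <- matrix(m, h, 8L * w)
    m2 <- array(t(m), c(8L, w, h))   # transpose trick for column blocks
    out[, , c] <- t(colMeans(m2))
  }
  out
}

# brute-force per-pixel loss oracles, independent of the package
# implementations (explicit loops, no shared helpers)
oracle_weighted_ce <- function(probs, gt, wts) {
  tot <- 0
  for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt))) {
    c <- gt[i, j] + 1L
    tot <- tot + wts[c] * (-log(max(probs[i, j, c], 1e-12)))
  }
  tot / length(gt)
}

oracle_bce <- function(p, g, pw) {
  tot <- 0
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
    pij <- min(max(p[i, j], 1e-12), 1 - 1e-12)
    tot <- tot - (pw * g[i, j] * log(pij) + (1 - g[i, j]) * log(1 - pij))
  }
  tot / length(g)
}

oracle_bas <- function(probs, gt, b, t) {
  tot <- 0
  for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt))) {
    if (b[i, j] > t) {
      c <- gt[i, j] + 1L
      tot <- tot - log(max(probs[i, j, c], 1e-12))
    }
  }
  tot / length(gt)
}

oracle_unimatch <- function(pw, pfp, ps1, ps2, tau, lam, mu) {
  C <- dim(pw)[3]
  tot <- 0
  for (i in seq_len(dim(pw)[1])) for (j in seq_len(dim(pw)[2])) {
    conf <- max(pw[i, j, ]); hard <- which.max(pw[i, j, ])
    if (conf >= tau) {
      h <- function(p) -log(max(p[i, j, hard], 1e-12))
      tot <- tot + lam * h(pfp) + (mu / 2) * (h(ps1) + h(ps2))
    }
  }
  tot / (dim(pw)[1] * dim(pw)[2])
}

random_prob_map <- function(h, w, C) {
  x <- array(runif(h * w * C, 0.05, 1), c(h, w, C))
  s <- x[, , 1]
  for (c in seq_len(C)[-1]) s <- s + x[, , c]
  x / as.vector(s)
}

# brute-force set-counting IoU oracle
oracle_iou <- function(pred, gt, cls) {
  inter <- 0; uni <- 0
  for (i in seq_along(pred)) {
    a <- pred[i] == cls; b <- gt[i] == cls
    if (a && b) inter <- inter + 1
    if (a || b) uni <- uni + 1
  }
  if (uni == 0) NA_real_ else 100 * inter / uni
}
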