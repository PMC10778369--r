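#' Multi-scale context geometry
#'
#' A context window of side `S` is processed three ways, each yielding a
#' score map for the central `S/2` crop at output stride 8 (side `S/16`):
#' four corner crops of side `S/2` (reassembled, center-cropped), the center
#' crop itself, and the whole window downscaled to `S/2` (center-cropped,
#' upsampled 2x). The published geometry uses S = 4096 (crop 2048, output
#' 256); the desk-scale default is S = 512.
#'
#' @param S context side; must be divisible by 16
#' @return object of class `ms_geometry` with fields `context_side`,
#'   `crop_side`, `out_stride`, `out_side`, `corner_offsets` (4 x 2, 0-based
#'   row/col), `center_offset`
#' @export
plan_geometry <- function(S = 512L) {
  S <- as.integer(S)
  if (S %% 16L != 0L) stop("context side must be divisible by 16")
  crop <- S %/% 2L
  structure(list(
    context_side = S, crop_side = crop, out_stride = 8L,
    out_side = crop %/% 8L,
    corner_offsets = rbind(c(0L, 0L), c(0L, crop), c(crop, 0L), c(crop, crop)),
    center_offset = c(S %/% 4L, S %/% 4L)
  ), class = "ms_geometry")
}

crop_arr <- function(x, r0, c0, side) {
  if (length(dim(x)) == 3) x[r0 + seq_len(side), c0 + seq_len(side), , drop = FALSE]
  else x[r0 + seq_len(side), c0 + seq_len(side), drop = FALSE]
}

#' Corner / center / downscale branch score maps for one context window
#'
#' The backbone is applied with frozen weights to the six sub-images; no
#' parameters are touched. `net` may be a `seg_network` (its main-head
#' logits are used, after the network's stored color normalization) or any
#' function mapping an H x W x 3 image to an H/8 x W/8 x C score map (used
#' with stub networks in tests).
#'
#' @param net a `seg_network` or a function
#' @param context_image S x S x 3 array, values 0..1
#' @param geom a [plan_geometry()]
#' @return list of class `branch_triplet` with `p1`, `p2`, `p3`
#'   (out_side x out_side x C)
#' @export
branch_outputs <- function(net, context_image, geom = plan_geometry()) {
  S <- geom$context_side; crop <- geom$crop_side; os <- geom$out_side
  if (!all(dim(context_image)[1:2] == S)) stop("context image must be S x S")
  fwd <- if (is.function(net)) net else {
    function(img) net_forward(net, normalize_img(img, net$norm))$pl
  }
  # corner mosaic
  mosaic <- NULL
  for (k in 1:4) {
    off <- geom$corner_offsets[k, ]
    out <- fwd(crop_arr(context_image, off[1], off[2], crop))
    if (is.null(mosaic)) mosaic <- array(0, c(2L * os, 2L * os, dim(out)[3]))
    mosaic[off[1] / 8 + seq_len(os), off[2] / 8 + seq_len(os), ] <- out
  }
  p1 <- crop_arr(mosaic, os %/% 2L, os %/% 2L, os)
  # center branch
  p2 <- fwd(crop_arr(context_image, geom$center_offset[1],
                     geom$center_offset[2], crop))
  # downscale branch: whole context at half scale; central os/2 window, x2 up
  small <- bilinear_resize_cpp(context_image, crop, crop)
  out3 <- fwd(small)
  ctr <- crop_arr(out3, os %/% 4L, os %/% 4L, os %/% 2L)
  p3 <- bilinear_resize_cpp(ctr, os, os)
  structure(list(p1 = p1, p2 = p2, p3 = p3), class = "branch_triplet")
}

# ---- attentional feature fusion --------------------------------------------

#' Initialise one attentional-feature-fusion (AFF) module
#'
#' Channel attention over the sum of the two inputs: a per-pixel (local,
#' 1x1-conv) bottleneck MLP plus a globally pooled bottleneck MLP produce a
#' sigmoid gate g in (0,1), and the output is the convex blend
#' `g * a + (1 - g) * b`. With `b2 = 0` the initial gate sits at 0.5.
#'
#' @param channels number of channels of the fused maps
#' @param reduction bottleneck reduction ratio
#' @param seed integer seed
#' @export
aff_init <- function(channels = 3L, reduction = 4L, seed = 1L) {
  cr <- max(1L, channels %/% reduction)
  with_seed(seed, {
    rnd <- function(r, c) matrix(rnorm(r * c, 0, 0.2), r, c)
    structure(list(
      C = channels, Cr = cr,
      W1 = rnd(cr, channels), b1 = rep(0, cr),
      W2 = rnd(channels, cr), b2 = rep(0, channels),
      G1 = rnd(cr, channels), g1 = rep(0, cr),
      G2 = rnd(channels, cr), g2 = rep(0, channels)
    ), class = "aff_params")
  })
}

aff_forward_full <- function(a, b, p, gate = NULL) {
  d <- dim(a); hw <- d[1] * d[2]; C <- d[3]
  X <- matrix(a + b, hw, C)
  if (is.null(gate)) {
    Lh <- pmax(X %*% t(p$W1) + matrix(p$b1, hw, p$Cr, byrow = TRUE), 0)
    L <- Lh %*% t(p$W2) + matrix(p$b2, hw, C, byrow = TRUE)
    gv <- colMeans(X)
    Gh <- pmax(as.vector(p$G1 %*% gv + p$g1), 0)
    Gv <- as.vector(p$G2 %*% Gh + p$g2)
    Z <- L + matrix(Gv, hw, C, byrow = TRUE)
    g <- 1 / (1 + exp(-Z))
  } else {
    g <- matrix(gate, hw, C)
    Lh <- NULL; Gh <- NULL; Z <- NULL
  }
  am <- matrix(a, hw, C); bm <- matrix(b, hw, C)
  fused <- array(g * am + (1 - g) * bm, d)
  list(fused = fused, g = g, X = X, Lh = Lh, Gh = Gh, am = am, bm = bm, d = d)
}

#' Fuse two score maps with an AFF module
#'
#' @param a,b arrays H x W x C (same shape)
#' @param params an [aff_init()] parameter set
#' @param gate optional scalar or matrix overriding the computed gate (used
#'   in tests to force the convex-blend endpoints)
#' @return fused H x W x C array
#' @export
aff_fuse <- function(a, b, params, gate = NULL) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  aff_forward_full(a, b, params, gate)$fused
}

# backward through one AFF; returns grads w.r.t. a, b and parameter grads
aff_backward <- function(cache, p, dF) {
  d <- cache$d; hw <- d[1] * d[2]; C <- d[3]
  dFm <- matrix(dF, hw, C)
  g <- cache$g
  da <- g * dFm
  db <- (1 - g) * dFm
  dg <- (cache$am - cache$bm) * dFm
  dZ <- dg * g * (1 - g)
  # local path
  dW2 <- t(dZ) %*% cache$Lh
  db2 <- colSums(dZ)
  dLh <- dZ %*% p$W2
  dLh[cache$Lh <= 0] <- 0
  dW1 <- t(dLh) %*% cache$X
  db1 <- colSums(dLh)
  dX <- dLh %*% p$W1
  # global path
  dGv <- colSums(dZ)
  dG2 <- outer(dGv, cache$Gh)
  dg2 <- dGv
  dGh <- as.vector(t(p$G2) %*% dGv)
  dGh[cache$Gh <= 0] <- 0
  gv <- colMeans(cache$X)
  dG1 <- outer(dGh, gv)
  dg1 <- dGh
  dgv <- as.vector(t(p$G1) %*% dGh)
  dX <- dX + matrix(dgv / hw, hw, C, byrow = TRUE)
  da <- da + dX; db <- db + dX
  list(da = array(da, d), db = array(db, d),
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    G1 = dG1, g1 = dg1, G2 = dG2, g2 = dg2))
}

#' Cascade the two AFF modules over a branch triplet
#'
#' `p = AFF(AFF(p1, p2), p3)`: fine detail first, broader context last.
#'
#' @param triplet a `branch_triplet`
#' @param params list with elements `aff1`, `aff2` from [aff_init()]
#' @return fused score map
#' @export
fuse_triplet <- function(triplet, params) {
  q <- aff_fuse(triplet$p1, triplet$p2, params$aff1)
  aff_fuse(q, triplet$p3, params$aff2)
}

#' Stage-2 training: fit the AFF cascade with the backbone frozen
#'
#' Branch triplets are precomputed with the frozen backbone; only the AFF
#' parameters receive SGD updates, against cross-entropy between the fused
#' map and the ground truth nearest-downsampled to the output side.
#'
#' @param net a frozen `seg_network` (never modified) or stub function
#' @param dataset list of lists with `context` (S x S x 3 image, 0..1) and
#'   `gt` (class matrix at context or crop resolution; its central crop is
#'   used)
#' @param geom a [plan_geometry()]
#' @param epochs,lr,momentum SGD schedule
#' @param seed seed for AFF initialisation
#' @param params optional initial AFF parameter list (e.g. for zero-epoch
#'   checks)
#' @return list with `params` (trained AFF modules), `history` of per-epoch
#'   CE, and `backbone_hash` before/after (identical by construction)
#' @export
train_stage2 <- function(net, dataset, geom = plan_geometry(), epochs = 40L,
                         lr = 0.001, momentum = 0.9, seed = 1L,
                         params = NULL) {
  hash_before <- if (inherits(net, "seg_network")) param_hash(net) else NA
  C <- NULL
  triplets <- lapply(dataset, function(it) {
    tr <- branch_outputs(net, it$context, geom)
    gt_full <- it$gt
    if (nrow(gt_full) == geom$context_side) {
      gt_full <- crop_arr(gt_full, geom$center_offset[1],
                          geom$center_offset[2], geom$crop_side)
    }
    list(tr = tr, gt8 = resize_nearest(gt_full, geom$out_side, geom$out_side))
  })
  C <- dim(triplets[[1]]$tr$p1)[3]
  if (is.null(params))
    params <- list(aff1 = aff_init(C, seed = derive_seed(seed, "aff1")),
                   aff2 = aff_init(C, seed = derive_seed(seed, "aff2")))
  pn <- c("W1", "b1", "W2", "b2", "G1", "g1", "G2", "g2")
  vel <- lapply(params, function(p) lapply(p[pn], function(x) x * 0))
  history <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, "s2order", ep),
                     sample(length(triplets)))
    ep_loss <- 0
    for (i in ord) {
      tr <- triplets[[i]]$tr; gt8 <- triplets[[i]]$gt8
      c1 <- aff_forward_full(tr$p1, tr$p2, params$aff1)
      c2 <- aff_forward_full(c1$fused, tr$p3, params$aff2)
      probs <- softmax_map(c2$fused)
      ce <- weighted_ce(probs, gt8, NULL, grad = TRUE)
      ep_loss <- ep_loss + ce$loss / length(triplets)
      bw2 <- aff_backward(c2, params$aff2, ce$grad)
      bw1 <- aff_backward(c1, params$aff1, bw2$da)
      for (nm in pn) {
        vel$aff2[[nm]] <- momentum * vel$aff2[[nm]] - lr * bw2$grads[[nm]]
        params$aff2[[nm]] <- params$aff2[[nm]] + vel$aff2[[nm]]
        vel$aff1[[nm]] <- momentum * vel$aff1[[nm]] - lr * bw1$grads[[nm]]
        params$aff1[[nm]] <- params$aff1[[nm]] + vel$aff1[[nm]]
      }
    }
    if (!is.finite(ep_loss)) stop("non-finite stage-2 loss")
    history <- c(history, ep_loss)
  }
  hash_after <- if (inherits(net, "seg_network")) param_hash(net) else NA
  list(params = params, history = history,
       backbone_hash = c(before = hash_before, after = hash_after))
}
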