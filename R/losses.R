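#' Loss weights and thresholds for supervised and semi-supervised training
#'
#' The supervised objective is the weighted combination
#' \deqn{L_s = \lambda_0 l_0 + \lambda_1 l_1 + \lambda_2 l_2 + \lambda_3 l_3}
#' of (l0) weighted cross-entropy on the auxiliary head, (l1) weighted binary
#' cross-entropy on the boundary head, (l2) weighted cross-entropy on the
#' main head, and (l3) the boundary-aware cross-entropy restricted to pixels
#' where the boundary head fires above threshold `t`. The unsupervised
#' consistency objective gates per-pixel terms by pseudo-label confidence
#' `tau` and weighs the feature-perturbation stream by `lambda_fp` and the
#' two image-perturbation streams by `mu/2` each.
#'
#' Defaults for the lambda coefficients follow the convention of the cited
#' three-branch network (the source work leaves them as empirical); `t = 0.8`
#' and `tau = 0.95` are the cited-method conventions.
#'
#' @param lambda0,lambda1,lambda2,lambda3 nonnegative combination weights
#' @param t boundary-firing threshold in (0,1)
#' @param tau pseudo-label confidence threshold in (0,1]
#' @param lambda_fp,mu nonnegative stream weights of the consistency loss
#' @param class_weights per-class nonnegative weights for the weighted CE
#'   terms (recycled to the number of classes)
#' @param unlabeled_weight scale of the unsupervised loss against the
#'   supervised one
#' @return object of class `loss_weights`
#' @export
loss_weights <- function(lambda0 = 0.4, lambda1 = 20, lambda2 = 1,
                         lambda3 = 1, t = 0.8, tau = 0.95,
                         lambda_fp = 0.5, mu = 0.5,
                         class_weights = c(1, 1, 1),
                         unlabeled_weight = 1.0) {
  vals <- c(lambda0, lambda1, lambda2, lambda3, lambda_fp, mu,
            unlabeled_weight, class_weights)
  if (any(vals < 0)) stop("loss weights must be nonnegative")
  if (t <= 0 || t >= 1) stop("t must be in (0,1)")
  if (tau <= 0 || tau > 1) stop("tau must be in (0,1]")
  structure(list(lambda0 = lambda0, lambda1 = lambda1, lambda2 = lambda2,
                 lambda3 = lambda3, t = t, tau = tau, lambda_fp = lambda_fp,
                 mu = mu, class_weights = class_weights,
                 unlabeled_weight = unlabeled_weight),
            class = "loss_weights")
}

CLIP <- 1e-12

#' Weighted multi-class cross-entropy
#'
#' Mean over pixels of `w[gt] * (-log p[gt])`, probabilities clipped at
#' 1e-12. Gradients (w.r.t. logits) are returned on request for the training
#' loop.
#'
#' @param pred_probs array H x W x C of per-pixel class probabilities
#' @param gt integer matrix of true classes in 0..C-1
#' @param class_weights per-class weights (recycled to C)
#' @param grad if TRUE also return the gradient w.r.t. the pre-softmax scores
#' @return scalar loss, or list(loss, grad) when `grad = TRUE`
#' @export
weighted_ce <- function(pred_probs, gt, class_weights = NULL, grad = FALSE) {
  C <- dim(pred_probs)[3]
  if (any(gt < 0 | gt >= C)) stop("gt class out of range")
  w <- rep(class_weights %||% 1, length.out = C)
  n <- length(gt)
  idx <- cbind(as.vector(row(gt)), as.vector(col(gt)), as.vector(gt) + 1L)
  p_gt <- pmax(pred_probs[idx], CLIP)
  wpix <- w[as.vector(gt) + 1L]
  loss <- sum(wpix * (-log(p_gt))) / n
  if (!grad) return(loss)
  g <- pred_probs  # softmax - onehot, scaled by class weight / n
  oh <- onehot_mask(gt, C)
  for (c in seq_len(C)) g[, , c] <- matrix(wpix / n, nrow(gt), ncol(gt)) *
      (pred_probs[, , c] - oh[, , c])
  list(loss = loss, grad = g)
}

#' Weighted binary cross-entropy for the boundary head
#'
#' Mean over pixels of `-[pos_weight * g * log p + (1 - g) * log(1 - p)]`.
#'
#' @param plB_probs matrix (or H x W x 1 array) of boundary probabilities
#' @param gB binary ground-truth matrix
#' @param pos_weight weight on the (rare) positive class
#' @param grad if TRUE also return the gradient w.r.t. the boundary logit
#' @export
boundary_bce <- function(plB_probs, gB, pos_weight = 1, grad = FALSE) {
  p <- if (length(dim(plB_probs)) == 3) plB_probs[, , 1] else plB_probs
  if (!all(dim(p) == dim(gB))) stop("shape mismatch")
  pc <- clamp(p, CLIP, 1 - CLIP)
  n <- length(gB)
  loss <- -sum(pos_weight * gB * log(pc) + (1 - gB) * log(1 - pc)) / n
  if (!grad) return(loss)
  gz <- (-pos_weight * gB * (1 - pc) + (1 - gB) * pc) / n
  list(loss = loss, grad = gz)
}

#' Boundary-aware cross-entropy (BAS loss)
#'
#' Cross-entropy restricted to the pixels where the boundary head fires:
#' \deqn{l_3 = -\sum_{i,c} 1[b_i > t]\, s_{i,c} \log \hat s_{i,c}}
#' normalised by the total pixel count (so the value is resolution-invariant
#' and monotonically non-increasing in `t`). No gradient flows through the
#' boundary scores `b`; the indicator only selects pixels.
#'
#' @param pred_probs array H x W x C of predicted probabilities
#' @param gt_onehot array H x W x C of one-hot ground truth (or an integer
#'   matrix of classes, which is one-hot encoded)
#' @param boundary_probs matrix (or H x W x 1 array) of boundary-head
#'   probabilities in 0..1
#' @param t firing threshold
#' @param grad if TRUE also return gradient w.r.t. the class scores
#' @export
bas_loss <- function(pred_probs, gt_onehot, boundary_probs, t = 0.8,
                     grad = FALSE) {
  C <- dim(pred_probs)[3]
  if (is.matrix(gt_onehot)) gt_onehot <- onehot_mask(gt_onehot, C)
  b <- if (length(dim(boundary_probs)) == 3) boundary_probs[, , 1] else boundary_probs
  fire <- b > t
  n <- length(b)
  loss <- 0
  for (c in seq_len(C))
    loss <- loss - sum(fire * gt_onehot[, , c] *
                         log(pmax(pred_probs[, , c], CLIP)))
  loss <- loss / n
  if (!grad) return(loss)
  g <- pred_probs
  sel <- matrix(as.numeric(fire), nrow(b), ncol(b))
  for (c in seq_len(C))
    g[, , c] <- sel * (pred_probs[, , c] - gt_onehot[, , c]) / n
  list(loss = loss, grad = g)
}

#' Supervised loss: weighted combination of the four head losses
#'
#' @param outputs list with full-resolution probability maps `plS_probs`
#'   (H x W x C), `pl_probs` (H x W x C) and `plB_probs` (H x W)
#' @param gs integer ground-truth class matrix
#' @param gB binary boundary ground-truth matrix
#' @param w a [loss_weights()]
#' @param pos_weight positive-class weight of the boundary BCE
#' @return list with `Ls` and the components `l0`..`l3`
#' @export
supervised_loss <- function(outputs, gs, gB, w = loss_weights(),
                            pos_weight = 1) {
  l0 <- weighted_ce(outputs$plS_probs, gs, w$class_weights)
  l1 <- boundary_bce(outputs$plB_probs, gB, pos_weight)
  l2 <- weighted_ce(outputs$pl_probs, gs, w$class_weights)
  l3 <- bas_loss(outputs$pl_probs, gs, outputs$plB_probs, w$t)
  Ls <- w$lambda0 * l0 + w$lambda1 * l1 + w$lambda2 * l2 + w$lambda3 * l3
  list(Ls = Ls, l0 = l0, l1 = l1, l2 = l2, l3 = l3)
}

#' Consistency loss over dual-stream perturbations of one unlabeled view
#'
#' Implements the confidence-gated consistency objective
#' \deqn{L_u = \frac{1}{B_u}\sum 1[\max p^w \ge \tau]\big(\lambda H(p^w, p^{fp})
#'   + \tfrac{\mu}{2}(H(p^w, p^{s1}) + H(p^w, p^{s2}))\big)}
#' with `H` realised as hard-pseudo-label cross-entropy: the argmax of the
#' (gradient-detached) weak prediction `pw` is the target for the three
#' perturbed streams. Per-pixel terms are averaged over pixels; the batch
#' average over `Bu` items is taken by the caller.
#'
#' @param pw,pfp,ps1,ps2 arrays H x W x C of probabilities (same shape)
#' @param w a [loss_weights()] supplying `tau`, `lambda_fp`, `mu`
#' @param grad if TRUE also return gradients w.r.t. the scores of
#'   `pfp`, `ps1`, `ps2` (never `pw`)
#' @export
unimatch_loss <- function(pw, pfp, ps1, ps2, w = loss_weights(), grad = FALSE) {
  stopifnot(all(dim(pw) == dim(pfp)), all(dim(pw) == dim(ps1)),
            all(dim(pw) == dim(ps2)))
  C <- dim(pw)[3]
  conf <- apply(pw, c(1, 2), max)
  hard <- argmax_map(pw)
  gate <- conf >= w$tau
  n <- length(gate)
  ce_sel <- function(p) {  # gated CE against the hard pseudo-label, mean/pixel
    idx <- cbind(as.vector(row(hard)), as.vector(col(hard)),
                 as.vector(hard) + 1L)
    sum(as.vector(gate) * (-log(pmax(p[idx], CLIP)))) / n
  }
  loss <- w$lambda_fp * ce_sel(pfp) +
    (w$mu / 2) * (ce_sel(ps1) + ce_sel(ps2))
  if (!grad) return(loss)
  oh <- onehot_mask(hard, C)
  sel <- matrix(as.numeric(gate), nrow(gate), ncol(gate))
  gfun <- function(p, coeff) {
    g <- p
    for (c in seq_len(C)) g[, , c] <- coeff * sel * (p[, , c] - oh[, , c]) / n
    g
  }
  list(loss = loss,
       grad_pfp = gfun(pfp, w$lambda_fp),
       grad_ps1 = gfun(ps1, w$mu / 2),
       grad_ps2 = gfun(ps2, w$mu / 2))
}

#' Pixel-frequency-based class weights from a labeled set
#'
#' Weights proportional to `(1/frequency)^power`, normalised to mean 1. The
#' default `power = 0.5` (square-root inverse frequency) tempers the raw
#' inverse-frequency weighting, which on nest-sparse tiles makes background
#' errors so cheap that the model over-predicts tumor.
#'
#' @param tiles list of `labeled_tile`s
#' @param n_classes number of classes
#' @param power exponent on the inverse frequency (1 = plain inverse)
#' @param cap upper bound on any weight relative to the smallest
#' @export
class_weights_from <- function(tiles, n_classes = 3L, power = 0.5, cap = 10) {
  counts <- rep(0, n_classes)
  for (tl in tiles) {
    tb <- tabulate(as.vector(tl$mask) + 1L, n_classes)
    counts <- counts + tb
  }
  counts <- pmax(counts, 1)
  w <- (sum(counts) / (n_classes * counts))^power
  w <- pmin(w, cap * min(w))
  w / mean(w)
}
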