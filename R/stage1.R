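#' Stage-1 training configuration
#'
#' Optimiser defaults (SGD, learning rate 0.001, momentum 0.9, weight decay
#' 0.0005) follow the source training protocol; the `desk` profile scales the
#' schedule to CPU (crop 256, 20 epochs, tiny preset) while the `paper`
#' profile keeps the published scale (crop 1024, 300 epochs).
#'
#' @param lr,momentum,weight_decay SGD hyperparameters
#' @param epochs number of epochs (>= 1)
#' @param batch_labeled,batch_unlabeled per-step batch sizes
#' @param crop training crop side (divisible by 8)
#' @param scale_range random-rescale interval applied before cropping
#' @param jitter_strength color-jitter strength of the strong augmentation
#' @param fp_drop channel-dropout rate of the feature-perturbation flow
#' @param lr_power polynomial learning-rate decay exponent
#' @param seed base seed: every random draw in training is derived from it
#' @param checkpoint_every epochs between checkpoints (0 = only final)
#' @param out_dir checkpoint/log directory or NULL
#' @export
stage1_config <- function(lr = 0.001, momentum = 0.9, weight_decay = 5e-4,
                          epochs = 20L, batch_labeled = 2L,
                          batch_unlabeled = 2L, crop = 256L,
                          scale_range = c(0.5, 1.5), jitter_strength = 0.3,
                          fp_drop = 0.5, lr_power = 0.9, seed = 1L,
                          checkpoint_every = 0L, out_dir = NULL) {
  stopifnot(lr > 0, epochs >= 1, crop %% 8 == 0, batch_labeled >= 1)
  structure(as.list(environment()), class = "stage1_config")
}

# ---- augmentation -----------------------------------------------------------

reflect_pad_mat <- function(m, top, bottom, left, right) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(rev(seq_len(min(top, h))), seq_len(h),
          h - seq_len(min(bottom, h)) + 1L)
  ci <- c(rev(seq_len(min(left, w))), seq_len(w),
          w - seq_len(min(right, w)) + 1L)
  m[ri, ci, drop = FALSE]
}

reflect_pad_img <- function(img, top, bottom, left, right) {
  out <- array(0, c(dim(img)[1] + top + bottom, dim(img)[2] + left + right,
                    dim(img)[3]))
  for (c in seq_len(dim(img)[3]))
    out[, , c] <- reflect_pad_mat(img[, , c], top, bottom, left, right)
  out
}

# draw the shared geometric transform for one sample
draw_geom <- function(h, w, crop, scale_range) {
  s <- runif(1, scale_range[1], scale_range[2])
  nh <- max(16L, round(h * s)); nw <- max(16L, round(w * s))
  pad_h <- max(0L, crop - nh); pad_w <- max(0L, crop - nw)
  oy <- if (nh + pad_h > crop) sample.int(nh + pad_h - crop + 1L, 1) - 1L else 0L
  ox <- if (nw + pad_w > crop) sample.int(nw + pad_w - crop + 1L, 1) - 1L else 0L
  list(nh = nh, nw = nw, pad_h = pad_h, pad_w = pad_w, oy = oy, ox = ox,
       hflip = runif(1) < 0.5, vflip = runif(1) < 0.5)
}

apply_geom_img <- function(img, g, crop) {
  x <- bilinear_resize_cpp(img, g$nh, g$nw)
  if (g$pad_h > 0 || g$pad_w > 0)
    x <- reflect_pad_img(x, 0L, g$pad_h, 0L, g$pad_w)
  x <- x[g$oy + seq_len(crop), g$ox + seq_len(crop), , drop = FALSE]
  if (g$hflip) x <- x[, rev(seq_len(crop)), , drop = FALSE]
  if (g$vflip) x <- x[rev(seq_len(crop)), , , drop = FALSE]
  x
}

apply_geom_mask <- function(mask, g, crop) {
  m <- resize_nearest(mask, g$nh, g$nw)
  if (g$pad_h > 0 || g$pad_w > 0)
    m <- reflect_pad_mat(m, 0L, g$pad_h, 0L, g$pad_w)
  m <- m[g$oy + seq_len(crop), g$ox + seq_len(crop), drop = FALSE]
  if (g$hflip) m <- m[, rev(seq_len(crop)), drop = FALSE]
  if (g$vflip) m <- m[rev(seq_len(crop)), , drop = FALSE]
  m
}

# photometric perturbation; strength 0 is the identity
color_jitter <- function(img, strength) {
  if (strength <= 0) return(img)
  bright <- runif(1, 1 - strength, 1 + strength)
  contrast <- runif(1, 1 - strength, 1 + strength)
  gains <- runif(3, 1 - strength / 2, 1 + strength / 2)
  x <- img
  for (c in 1:3) x[, , c] <- x[, , c] * gains[c]
  mu <- mean(x)
  x <- (x - mu) * contrast + mu * bright
  if (runif(1) < 0.2) {  # occasional grayscale mix
    g <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
    a <- runif(1, 0.3, 1)
    for (c in 1:3) x[, , c] <- (1 - a) * x[, , c] + a * g
  }
  if (runif(1) < 0.3) {  # occasional blur
    sg <- runif(1, 0.3, 1.0)
    for (c in 1:3) x[, , c] <- gaussian_blur_cpp(x[, , c], sg)
  }
  clamp(x, 0, 1)
}

normalize_img <- function(img, stats) {
  if (is.null(stats)) return(img)
  for (c in 1:3) img[, , c] <- (img[, , c] - stats$mean[c]) / stats$sd[c]
  img
}

#' Per-channel intensity statistics of a tile set (for color normalization)
#' @param tiles list of `labeled_tile`s
#' @export
dataset_stats <- function(tiles) {
  px <- vapply(tiles, function(t) {
    c(apply(t$image / 255, 3, mean), apply(t$image / 255, 3, sd))
  }, numeric(6))
  list(mean = rowMeans(px)[1:3], sd = pmax(rowMeans(px)[4:6], 1e-3))
}

#' Augment one labeled tile (geometry + photometric + normalization)
#'
#' @param tile a `labeled_tile`
#' @param crop output side
#' @param seed seed controlling every random draw
#' @param jitter_strength photometric jitter strength (0 = none)
#' @param norm_stats optional list(mean, sd) per channel
#' @param scale_range random-rescale interval
#' @return list(image, mask, boundary) at crop resolution; the boundary band
#'   is re-derived from the transformed mask
#' @export
augment_labeled <- function(tile, crop, seed, jitter_strength = 0.3,
                            norm_stats = NULL, scale_range = c(0.5, 1.5)) {
  with_seed(seed, {
    g <- draw_geom(nrow(tile$mask), ncol(tile$mask), crop, scale_range)
    img <- apply_geom_img(tile$image / 255, g, crop)
    msk <- apply_geom_mask(tile$mask, g, crop)
    img <- color_jitter(img, jitter_strength)
    list(image = normalize_img(img, norm_stats), mask = msk,
         boundary = derive_boundary_gt(msk, 2L))
  })
}

#' Build the weak and two strong views of one unlabeled image
#'
#' The three views share one geometric transform (so their outputs are
#' pixelwise comparable) and differ photometrically: the weak view `xw` gets
#' no color perturbation while `xs1`, `xs2` receive independent color
#' jitters.
#'
#' @param image H x W x 3 array in 0..1 (or a `labeled_tile`)
#' @param crop output side
#' @param seed seed; sub-streams for the two strong jitters are derived
#' @param jitter_strength strength of the strong color jitter
#' @param norm_stats optional normalization statistics applied to all views
#' @param scale_range shared geometric rescale interval
#' @return list(xw, xs1, xs2)
#' @export
make_views <- function(image, crop, seed, jitter_strength = 0.3,
                       norm_stats = NULL, scale_range = c(0.5, 1.5)) {
  if (inherits(image, "labeled_tile")) image <- image$image / 255
  if (nrow(image) < 16 || ncol(image) < 16) stop("image too small")
  g <- with_seed(derive_seed(seed, "geom"),
                 draw_geom(dim(image)[1], dim(image)[2], crop, scale_range))
  base <- apply_geom_img(image, g, crop)
  xw <- base
  xs1 <- with_seed(derive_seed(seed, "jit1"), color_jitter(base, jitter_strength))
  xs2 <- with_seed(derive_seed(seed, "jit2"), color_jitter(base, jitter_strength))
  list(xw = normalize_img(xw, norm_stats),
       xs1 = normalize_img(xs1, norm_stats),
       xs2 = normalize_img(xs2, norm_stats))
}

#' Channel dropout on a feature map (feature perturbation)
#'
#' Whole channels are zeroed with probability `drop_rate`; survivors are
#' rescaled by 1/(1-drop_rate) so the perturbation is expectation-preserving.
#'
#' @param features H x W x C array
#' @param drop_rate in [0, 1)
#' @param seed integer seed
#' @export
feature_perturb <- function(features, drop_rate, seed = 1L) {
  stopifnot(drop_rate >= 0, drop_rate < 1)
  if (drop_rate == 0) return(features)
  C <- dim(features)[3]
  keep <- with_seed(seed, runif(C) >= drop_rate)
  scale <- ifelse(keep, 1 / (1 - drop_rate), 0)
  for (c in seq_len(C)) features[, , c] <- features[, , c] * scale[c]
  features
}

# ---- training ---------------------------------------------------------------

# supervised gradients for one labeled sample; returns loss components and
# pushes gradients into the network (scaled by `scale`)
backprop_supervised <- function(net, img, msk, gB, w, pos_weight, scale) {
  out <- net_forward(net, img)
  cw <- rep(w$class_weights %||% 1, length.out = dim(out$pl)[3])
  r <- sup_loss_grad_cpp(out$plS, out$pl, out$plB,
                         matrix(as.integer(msk), nrow(msk), ncol(msk)),
                         gB * 1.0, cw, w$lambda0, w$lambda1, w$lambda2,
                         w$lambda3, w$t, pos_weight, scale)
  net_backward_cpp(net$ptr, r$gS8, r$gM8, r$gB8, FALSE)
  list(Ls = w$lambda0 * r$l0 + w$lambda1 * r$l1 +
         w$lambda2 * r$l2 + w$lambda3 * r$l3,
       l0 = r$l0, l1 = r$l1, l2 = r$l2, l3 = r$l3)
}

# consistency gradients for one unlabeled sample (views precomputed).
# pw and pfp share one backbone forward; ps1/ps2 are separate forwards.
backprop_unlabeled <- function(net, views, w, fp_drop, seed, scale) {
  out_w <- net_forward(net, views$xw)
  pw <- softmax_map(out_w$pl)  # detached pseudo-label source
  pfp_logits <- net_forward_fp(net, fp_drop, derive_seed(seed, "fpdrop"))
  pfp <- softmax_map(pfp_logits)
  zero3 <- array(0, dim(out_w$plS)); zero1 <- array(0, dim(out_w$plB))
  # gradient pass for the fp stream must run before the next forward
  lu_fp <- unimatch_loss(pw, pfp, pfp, pfp, w, grad = TRUE)
  if (any(lu_fp$grad_pfp != 0))
    net_backward_cpp(net$ptr, zero3, lu_fp$grad_pfp * scale, zero1, TRUE)
  out_s1 <- net_forward(net, views$xs1)
  ps1 <- softmax_map(out_s1$pl)
  lu_s1 <- unimatch_loss(pw, ps1, ps1, ps1, w, grad = TRUE)
  if (any(lu_s1$grad_ps1 != 0))
    net_backward_cpp(net$ptr, zero3, lu_s1$grad_ps1 * scale, zero1, FALSE)
  out_s2 <- net_forward(net, views$xs2)
  ps2 <- softmax_map(out_s2$pl)
  lu_s2 <- unimatch_loss(pw, ps2, ps2, ps2, w, grad = TRUE)
  if (any(lu_s2$grad_ps2 != 0))
    net_backward_cpp(net$ptr, zero3, lu_s2$grad_ps2 * scale, zero1, FALSE)
  Lu <- unimatch_loss(pw, pfp, ps1, ps2, w)
  Lu
}

#' One optimisation step over a labeled and an (optional) unlabeled batch
#'
#' Total objective: mean supervised loss over the labeled batch plus
#' `unlabeled_weight` times the mean consistency loss over the unlabeled
#' batch, followed by one SGD-with-momentum update.
#'
#' @param net a `seg_network` (modified in place)
#' @param labeled_batch list of lists with `image`, `mask`, `boundary`
#'   (already augmented, normalized, crop-sized)
#' @param unlabeled_batch list of view triples from [make_views()], or NULL
#' @param weights a [loss_weights()]
#' @param cfg a [stage1_config()]
#' @param lr learning rate for this step (scheduler-resolved)
#' @param step_seed seed for the feature-perturbation dropout
#' @param pos_weight boundary BCE positive-class weight
#' @return list of loss components (`Ls`, `l0`..`l3`, `Lu`, `total`)
#' @export
stage1_step <- function(net, labeled_batch, unlabeled_batch = NULL,
                        weights = loss_weights(), cfg = stage1_config(),
                        lr = cfg$lr, step_seed = 1L, pos_weight = 1) {
  if (length(labeled_batch) == 0) stop("labeled batch must be non-empty")
  net_zero_grad_cpp(net$ptr)
  nl <- length(labeled_batch)
  comps <- list(Ls = 0, l0 = 0, l1 = 0, l2 = 0, l3 = 0)
  for (it in labeled_batch) {
    r <- backprop_supervised(net, it$image, it$mask, it$boundary, weights,
                             pos_weight, scale = 1 / nl)
    for (k in names(comps)) comps[[k]] <- comps[[k]] + r[[k]] / nl
  }
  Lu <- 0
  if (!is.null(unlabeled_batch) && length(unlabeled_batch) > 0 &&
      weights$unlabeled_weight > 0) {
    bu <- length(unlabeled_batch)
    for (i in seq_along(unlabeled_batch)) {
      Lu <- Lu + backprop_unlabeled(
        net, unlabeled_batch[[i]], weights, cfg$fp_drop,
        derive_seed(step_seed, "unl", i),
        scale = weights$unlabeled_weight / bu
      ) / bu
    }
  }
  net_sgd_step_cpp(net$ptr, lr, cfg$momentum, cfg$weight_decay, 1.0)
  c(comps, list(Lu = Lu, total = comps$Ls + weights$unlabeled_weight * Lu))
}

#' Train the segmentation network (Stage 1)
#'
#' Joint supervised + semi-supervised optimisation. All randomness (shuffle
#' order, augmentation, dropout) is derived from `cfg$seed`, per epoch and
#' step, so an interrupted run resumed from a checkpoint reproduces the
#' uninterrupted trajectory bitwise.
#'
#' @param net a `seg_network` (modified in place)
#' @param labeled list of `labeled_tile`s
#' @param unlabeled optional list of `labeled_tile`s or raw images treated as
#'   unlabeled
#' @param val optional list of `labeled_tile`s for per-epoch mIoU
#' @param cfg a [stage1_config()]
#' @param weights a [loss_weights()]; if `class_weights` is NULL they are
#'   computed as inverse pixel frequencies of the labeled set
#' @param resume_from optional checkpoint stem to resume from
#' @return list with the trained `net`, per-epoch `history` data.frame,
#'   `norm_stats`, and `checkpoint` stem (if `out_dir` is set)
#' @export
train_stage1 <- function(net, labeled, unlabeled = NULL, val = NULL,
                         cfg = stage1_config(), weights = NULL,
                         resume_from = NULL) {
  if (length(labeled) == 0) stop("labeled set must be non-empty")
  norm_stats <- dataset_stats(labeled)
  if (is.null(weights))
    weights <- loss_weights(class_weights = class_weights_from(labeled))
  else if (is.null(weights$class_weights))
    weights$class_weights <- class_weights_from(labeled)
  start_epoch <- 1L
  if (!is.null(resume_from)) {
    sidecar <- jsonlite::read_json(paste0(resume_from, ".json"),
                                   simplifyVector = TRUE)
    state <- readRDS(paste0(resume_from, ".rds"))
    net_set_state_cpp(net$ptr, state, isTRUE(sidecar$with_velocity))
    start_epoch <- as.integer(sidecar$epoch) + 1L
  }
  n_steps_total <- cfg$epochs * ceiling(length(labeled) / cfg$batch_labeled)
  history <- list()
  step_global <- (start_epoch - 1L) * ceiling(length(labeled) / cfg$batch_labeled)
  for (epoch in start_epoch:cfg$epochs) {
    ord <- with_seed(derive_seed(cfg$seed, "order", epoch),
                     sample(length(labeled)))
    uord <- if (!is.null(unlabeled) && length(unlabeled) > 0)
      with_seed(derive_seed(cfg$seed, "uorder", epoch),
                sample(length(unlabeled))) else integer(0)
    nb <- ceiling(length(ord) / cfg$batch_labeled)
    ep <- list(Ls = 0, Lu = 0)
    for (s in seq_len(nb)) {
      idx <- ord[((s - 1) * cfg$batch_labeled + 1):min(s * cfg$batch_labeled,
                                                       length(ord))]
      lb <- lapply(seq_along(idx), function(j) {
        augment_labeled(labeled[[idx[j]]], cfg$crop,
                        derive_seed(cfg$seed, "aug", epoch, s, j),
                        cfg$jitter_strength, norm_stats, cfg$scale_range)
      })
      ub <- NULL
      if (length(uord) > 0) {
        ui <- uord[(((s - 1) * cfg$batch_unlabeled) %% length(uord)) +
                     seq_len(min(cfg$batch_unlabeled, length(uord)))]
        ui <- ui[!is.na(ui)]
        ub <- lapply(seq_along(ui), function(j) {
          src <- unlabeled[[ui[j]]]
          make_views(src, cfg$crop,
                     derive_seed(cfg$seed, "views", epoch, s, j),
                     cfg$jitter_strength, norm_stats, cfg$scale_range)
        })
      }
      lr_t <- cfg$lr * (1 - step_global / n_steps_total)^cfg$lr_power
      rep_ <- stage1_step(net, lb, ub, weights, cfg, lr = lr_t,
                          step_seed = derive_seed(cfg$seed, "step", epoch, s))
      if (!is.finite(rep_$total))
        stop(sprintf("non-finite loss at epoch %d step %d (Ls=%g Lu=%g)",
                     epoch, s, rep_$Ls, rep_$Lu))
      ep$Ls <- ep$Ls + rep_$Ls / nb
      ep$Lu <- ep$Lu + rep_$Lu / nb
      step_global <- step_global + 1L
    }
    miou <- NA_real_
    if (!is.null(val) && length(val) > 0)
      miou <- eval_miou(net, val, norm_stats)
    history[[length(history) + 1]] <-
      data.frame(epoch = epoch, Ls = ep$Ls, Lu = ep$Lu, val_miou = miou)
    if (!is.null(cfg$out_dir)) {
      message(sprintf("[stage1] epoch %d/%d Ls=%.4f Lu=%.4f mIoU=%.3f",
                      epoch, cfg$epochs, ep$Ls, ep$Lu, miou))
      if (cfg$checkpoint_every > 0 && epoch %% cfg$checkpoint_every == 0)
        save_checkpoint(net, file.path(cfg$out_dir, sprintf("ck_ep%03d", epoch)),
                        epoch = epoch, with_velocity = TRUE,
                        extra = list(norm_stats = norm_stats))
    }
  }
  net$norm <- norm_stats
  ck <- NULL
  if (!is.null(cfg$out_dir)) {
    ck <- file.path(cfg$out_dir, "stage1_final")
    save_checkpoint(net, ck, epoch = cfg$epochs, with_velocity = TRUE,
                    extra = list(norm_stats = norm_stats))
  }
  list(net = net, history = do.call(rbind, history), norm_stats = norm_stats,
       checkpoint = ck)
}

# pooled (dataset-level) mean IoU over DCIS+IC at stride 8
eval_miou <- function(net, tiles, norm_stats = NULL) {
  inter <- rep(0, 2); uni <- rep(0, 2)
  for (tl in tiles) {
    img <- normalize_img(tl$image / 255, norm_stats)
    pred <- predict_mask(net, img, stride8 = TRUE)
    gt <- resize_nearest(tl$mask, nrow(pred), ncol(pred))
    for (c in 1:2) {
      inter[c] <- inter[c] + sum(pred == c & gt == c)
      uni[c] <- uni[c] + sum(pred == c | gt == c)
    }
  }
  present <- uni > 0
  if (!any(present)) return(NA_real_)
  mean(inter[present] / uni[present])
}
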