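#' Tissue mask from a low-resolution overview
#'
#' A pixel is tissue iff its HSV saturation exceeds `sat_threshold` after
#' 5x5 median smoothing; empty glass is nearly white (saturation ~ 0).
#'
#' @param lowres_rgb H x W x 3 array, values 0..1 or 0..255
#' @param sat_threshold saturation cutoff in 0..1
#' @return logical matrix
#' @export
tissue_mask <- function(lowres_rgb, sat_threshold = 0.05) {
  img <- if (max(lowres_rgb) > 1.5) lowres_rgb / 255 else lowres_rgb
  mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
  mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  median_filter_cpp(sat, 2L) > sat_threshold
}

reflect_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  # fold into [1, n] by mirroring (period 2n - 2)
  j <- (i - 1) %% (2 * n - 2)
  ifelse(j < n, j + 1, 2 * n - j - 1)
}

extract_window <- function(image, r0, c0, side) {
  h <- dim(image)[1]; w <- dim(image)[2]
  ri <- reflect_index(r0 + seq_len(side), h)
  ci <- reflect_index(c0 + seq_len(side), w)
  image[ri, ci, , drop = FALSE]
}

#' Plan context windows covering a whole-slide-like image
#'
#' Cores (the kept central regions, side S/2) are laid on a stride-S/2 grid
#' and partition the image exactly as half-open rectangles; each core's
#' context extends S/4 beyond it on every side (reflect-padded at image
#' borders).
#'
#' @param image_dims integer c(height, width)
#' @param geom a [plan_geometry()]
#' @return list of windows, each with 0-based half-open `core` = c(r0, r1,
#'   c0, c1) and `context` = c(r0, c0) (top-left, may be negative)
#' @export
tile_plan <- function(image_dims, geom = plan_geometry()) {
  h <- image_dims[1]; w <- image_dims[2]
  crop <- geom$crop_side; m <- geom$context_side %/% 4L
  nr <- ceiling(h / crop); nc <- ceiling(w / crop)
  plan <- list()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      r0 <- (i - 1L) * crop; c0 <- (j - 1L) * crop
      plan[[length(plan) + 1L]] <- list(
        core = c(r0, min(r0 + crop, h), c0, min(c0 + crop, w)),
        context = c(r0 - m, c0 - m),
        padded = r0 - m < 0 || c0 - m < 0 ||
          r0 - m + geom$context_side > h || c0 - m + geom$context_side > w
      )
    }
  }
  plan
}

#' Context-aware tiled inference over a whole-slide-like image
#'
#' Each context window is passed through the frozen backbone's three branches
#' and the trained AFF cascade; the argmax of the fused scores is written into
#' the core region of a stride-8 label mask. Windows whose core contains no
#' tissue are skipped (background). Deterministic, and independent of window
#' visit order since cores are disjoint.
#'
#' @param net a `seg_network` (or stub function)
#' @param aff AFF parameter list (`aff1`, `aff2`) from [train_stage2()], or
#'   NULL to average the three branches
#' @param image H x W x 3 array in 0..1; H, W divisible by 8
#' @param geom a [plan_geometry()]
#' @param tissue_opts list(enabled, sat_threshold) controlling tissue gating
#' @return object of class `label_mask`: list with `mask` (stride-8 integer
#'   class matrix), `stride`, `geometry` and `provenance`
#' @export
infer_wsi <- function(net, aff, image, geom = plan_geometry(),
                      tissue_opts = list(enabled = TRUE, sat_threshold = 0.05)) {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h %% 8 != 0 || w %% 8 != 0) stop("image dims must be divisible by 8")
  plan <- tile_plan(c(h, w), geom)
  mask8 <- matrix(0L, h %/% 8L, w %/% 8L)
  tmask <- NULL
  if (isTRUE(tissue_opts$enabled)) {
    low <- bilinear_resize_cpp(image, h %/% 8L, w %/% 8L)
    tmask <- tissue_mask(low, tissue_opts$sat_threshold %||% 0.05)
  }
  for (win in plan) {
    cr <- win$core
    rr8 <- (cr[1] %/% 8L + 1L):(cr[2] %/% 8L)
    cc8 <- (cr[3] %/% 8L + 1L):(cr[4] %/% 8L)
    if (!is.null(tmask) && !any(tmask[rr8, cc8])) next
    ctx <- extract_window(image, win$context[1], win$context[2],
                          geom$context_side)
    tr <- branch_outputs(net, ctx, geom)
    fused <- if (is.null(aff)) (tr$p1 + tr$p2 + tr$p3) / 3
    else fuse_triplet(tr, aff)
    pred <- argmax_map(fused)
    core_h8 <- length(rr8); core_w8 <- length(cc8)
    mask8[rr8, cc8] <- pred[seq_len(core_h8), seq_len(core_w8)]
  }
  structure(list(mask = mask8, stride = 8L, geometry = geom,
                 provenance = list(aff = !is.null(aff),
                                   tissue = isTRUE(tissue_opts$enabled))),
            class = "label_mask")
}

#' Naive no-context tiled inference (comparison baseline)
#'
#' The image is cut into non-overlapping crop-sized tiles, each predicted
#' independently; used to quantify the context benefit of [infer_wsi()].
#'
#' @param net a `seg_network` or stub function
#' @param image H x W x 3 array, dims divisible by tile side
#' @param tile_side side of the independent tiles
#' @return stride-8 integer class matrix
#' @export
infer_tiles_nocontext <- function(net, image, tile_side = 256L) {
  h <- dim(image)[1]; w <- dim(image)[2]
  fwd <- if (is.function(net)) net else {
    function(img) net_forward(net, normalize_img(img, net$norm))$pl
  }
  mask8 <- matrix(0L, h %/% 8L, w %/% 8L)
  for (r0 in seq(0L, h - tile_side, by = tile_side)) {
    for (c0 in seq(0L, w - tile_side, by = tile_side)) {
      out <- fwd(crop_arr(image, r0, c0, tile_side))
      pred <- argmax_map(out)
      mask8[r0 / 8 + seq_len(tile_side / 8), c0 / 8 + seq_len(tile_side / 8)] <-
        pred
    }
  }
  mask8
}

#' Cross-border seam disagreement rate
#'
#' Fraction of adjacent pixel pairs straddling core borders whose predicted
#' labels differ, restricted to pairs whose ground-truth labels agree
#' (generator-uniform regions), so genuine class boundaries on a seam do not
#' count as artifacts.
#'
#' @param pred stride-8 predicted class matrix
#' @param gt ground-truth class matrix at the same resolution
#' @param core_side8 core side in stride-8 pixels (borders every core_side8)
#' @return disagreement rate in 0..1 (NaN when no eligible pairs)
#' @export
seam_disagreement <- function(pred, gt, core_side8) {
  stopifnot(all(dim(pred) == dim(gt)))
  num <- 0; den <- 0
  rows <- seq(core_side8, nrow(pred) - 1, by = core_side8)
  for (r in rows) {
    ok <- gt[r, ] == gt[r + 1, ]
    num <- num + sum(pred[r, ok] != pred[r + 1, ok])
    den <- den + sum(ok)
  }
  cols <- seq(core_side8, ncol(pred) - 1, by = core_side8)
  for (cc in cols) {
    ok <- gt[, cc] == gt[, cc + 1]
    num <- num + sum(pred[ok, cc] != pred[ok, cc + 1])
    den <- den + sum(ok)
  }
  num / den
}
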