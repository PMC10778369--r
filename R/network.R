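#' Configuration of the three-branch segmentation network
#'
#' The network has a detail-preserving branch (P, medium depth, stride 8), a
#' context branch (I, deep, stride 16 with a global-context unit, projected
#' and upsampled back to stride 8), and a shallow boundary branch (D) whose
#' sigmoid output gates the fusion of detail and context features
#' (boundary-attention-guided fusion). Three heads are emitted at output
#' stride 8: `plS` (auxiliary, on P), `pl` (main, on the fused features) and
#' `plB` (boundary logits).
#'
#' @param preset one of "tiny", "S", "M", "L"; `tiny` is sized for CPU
#'   training in tests, the others scale width
#' @param num_classes number of semantic classes (background, DCIS, IC)
#' @param width optional channel multiplier overriding the preset
#' @param depths named integer vector with entries P, I, D; must satisfy
#'   depth(I) >= depth(P) >= depth(D)
#' @return object of class `network_config`
#' @export
network_config <- function(preset = c("tiny", "S", "M", "L"),
                           num_classes = 3L, width = NULL,
                           depths = c(P = 2L, I = 3L, D = 1L)) {
  preset <- match.arg(preset)
  base <- switch(preset, tiny = c(12L, 24L, 48L), S = c(24L, 48L, 96L),
                 M = c(32L, 64L, 128L), L = c(48L, 96L, 192L))
  if (!is.null(width)) base <- as.integer(round(base * width))
  if (num_classes < 2) stop("num_classes must be >= 2")
  if (!(depths["I"] >= depths["P"] && depths["P"] >= depths["D"]))
    stop("depths must satisfy depth(I) >= depth(P) >= depth(D)")
  structure(list(preset = preset, num_classes = as.integer(num_classes),
                 c1 = base[1], c2 = base[2], c3 = base[3],
                 depths = depths), class = "network_config")
}

#' Build a segmentation network
#'
#' @param config a [network_config()]
#' @param seed integer seed for parameter initialisation
#' @return object of class `seg_network` wrapping the native model
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  ptr <- net_create_cpp(config$c1, config$c2, config$c3, config$num_classes,
                        as.integer(config$depths["P"]),
                        as.integer(config$depths["I"]),
                        as.integer(config$depths["D"]), as.integer(seed))
  structure(list(ptr = ptr, config = config, seed = as.integer(seed)),
            class = "seg_network")
}

#' @export
print.seg_network <- function(x, ...) {
  cat(sprintf("<seg_network> preset=%s classes=%d params=%d\n",
              x$config$preset, x$config$num_classes, n_params(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param net a `seg_network`
#' @export
n_params <- function(net) as.integer(net_n_params_cpp(net$ptr))

#' Hash of the current parameter values (freeze-contract checks)
#' @param net a `seg_network`
#' @export
param_hash <- function(net) digest::digest(net_get_state_cpp(net$ptr, FALSE))

#' Forward pass
#'
#' @param net a `seg_network`
#' @param image numeric array H x W x 3 with values in 0..1 (H, W divisible
#'   by 8)
#' @param fp_drop channel-dropout rate applied to the fused features before
#'   the main head (feature-perturbation flow); 0 disables
#' @param fp_seed integer seed for the dropout mask
#' @return list of stride-8 score maps `plS`, `pl` (H/8 x W/8 x C) and `plB`
#'   (H/8 x W/8 x 1), class `network_outputs`
#' @export
net_forward <- function(net, image, fp_drop = 0, fp_seed = 0L) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  out <- net_forward_cpp(net$ptr, image, fp_drop, as.integer(fp_seed))
  class(out) <- "network_outputs"
  out
}

# feature-perturbation flow reusing the last forward's cached backbone
net_forward_fp <- function(net, fp_drop, fp_seed) {
  net_forward_fp_cpp(net$ptr, fp_drop, as.integer(fp_seed))
}

#' Upsample stride-8 head scores to full resolution
#'
#' Bilinear upsampling of each head; the argmax over classes of the
#' upsampled main head defines the predicted class map.
#'
#' @param outputs a `network_outputs` list from [net_forward()]
#' @param target_hw integer length-2 vector; must equal 8x the score-map
#'   dimensions
#' @return list with probability maps `plS_probs`, `pl_probs` (H x W x C),
#'   `plB_probs` (H x W), raw upsampled scores, and `class_map` (integer
#'   matrix, 0-based classes)
#' @export
upsample_scores <- function(outputs, target_hw) {
  hw <- dim(outputs$pl)[1:2]
  if (!all(target_hw == hw * 8L))
    stop("target_hw must be 8x the score-map dimensions")
  plS <- bilinear_resize_cpp(outputs$plS, target_hw[1], target_hw[2])
  pl <- bilinear_resize_cpp(outputs$pl, target_hw[1], target_hw[2])
  plB <- bilinear_resize_cpp(outputs$plB, target_hw[1], target_hw[2])
  pl_probs <- softmax_map(pl)
  list(plS = plS, pl = pl, plB = plB[, , 1],
       plS_probs = softmax_map(plS), pl_probs = pl_probs,
       plB_probs = 1 / (1 + exp(-plB[, , 1])),
       class_map = argmax_map(pl_probs))
}

#' Predict a class mask for one image
#'
#' @param net a `seg_network`
#' @param image H x W x 3 array in 0..1
#' @param stride8 if TRUE return the stride-8 mask, else upsample (nearest)
#'   to the input resolution
#' @return integer class matrix (0 = background, 1 = DCIS, 2 = IC)
#' @export
predict_mask <- function(net, image, stride8 = TRUE) {
  out <- net_forward(net, image)
  probs <- softmax_map(out$pl)
  m <- argmax_map(probs)
  if (!stride8) m <- resize_nearest(m, dim(image)[1], dim(image)[2])
  m
}

# ---- checkpointing ----------------------------------------------------------

#' Save a network (and optionally optimiser) state to disk
#'
#' Writes `<path>.rds` (flat numeric state vector) and a JSON sidecar
#' `<path>.json` with the architecture, seed, epoch and a content hash; no
#' arbitrary serialised objects beyond the numeric state.
#'
#' @param net a `seg_network`
#' @param path file stem
#' @param epoch training epoch recorded in the sidecar
#' @param with_velocity include SGD momentum buffers (for exact resume)
#' @param extra named list merged into the sidecar
#' @export
save_checkpoint <- function(net, path, epoch = NA_integer_,
                            with_velocity = FALSE, extra = list()) {
  state <- net_get_state_cpp(net$ptr, with_velocity)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(state, paste0(path, ".rds"))
  cfg_out <- unclass(net$config)
  cfg_out$depths <- as.list(cfg_out$depths)  # keep names through JSON
  sidecar <- c(list(
    package = "ihcseg", kind = "seg_network",
    config = cfg_out, seed = net$seed, epoch = epoch,
    with_velocity = with_velocity, n_params = n_params(net),
    state_hash = digest::digest(state)
  ), extra)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a network checkpoint saved by [save_checkpoint()]
#' @param path file stem used at save time
#' @return a `seg_network` with restored parameters; sidecar attached as
#'   attribute `sidecar`
#' @export
load_checkpoint <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- network_config(preset = sidecar$config$preset,
                        num_classes = sidecar$config$num_classes,
                        depths = unlist(sidecar$config$depths))
  cfg$c1 <- sidecar$config$c1; cfg$c2 <- sidecar$config$c2
  cfg$c3 <- sidecar$config$c3
  net <- build_network(cfg, seed = sidecar$seed)
  state <- readRDS(paste0(path, ".rds"))
  if (!identical(digest::digest(state), sidecar$state_hash))
    stop("checkpoint state hash mismatch")
  net_set_state_cpp(net$ptr, state, isTRUE(sidecar$with_velocity))
  attr(net, "sidecar") <- sidecar
  net
}
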