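#' @useDynLib ihcseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd cor setNames
#' @importFrom utils write.csv read.csv modifyList head
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible sub-seed from a base seed and a stream label
#'
#' Independent RNG streams (data order, augmentation, dropout, ...) are keyed
#' by label so that adding one consumer does not shift the draws of another.
#' Result is a non-negative integer below 2^31.
#' @param seed base integer seed
#' @param ... labels (coerced to character) identifying the stream
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- digest::digest(key, algo = "xxhash32", serialize = FALSE)
  as.integer(strtoi(substr(h, 1, 7), 16L))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Channelwise softmax of a score array
#' @param x array H x W x C of scores (logits)
#' @return array of probabilities summing to 1 over the third dimension
#' @export
softmax_map <- function(x) {
  d <- dim(x)
  m <- x[, , 1]
  for (c in seq_len(d[3])[-1]) m <- pmax(m, x[, , c])
  e <- exp(x - as.vector(m))
  s <- e[, , 1]
  for (c in seq_len(d[3])[-1]) s <- s + e[, , c]
  e / as.vector(s)
}

#' Per-pixel argmax class of a score array (0-based classes)
#' @param x array H x W x C
#' @export
argmax_map <- function(x) {
  d <- dim(x)
  cls <- matrix(1L, d[1], d[2])
  best <- x[, , 1]
  for (c in seq_len(d[3])[-1]) {
    better <- x[, , c] > best
    cls[better] <- c
    best[better] <- x[, , c][better]
  }
  cls - 1L
}

#' One-hot encode a class-index matrix
#' @param mask integer matrix with values in 0..(n_classes-1)
#' @param n_classes number of classes
#' @return array H x W x n_classes of 0/1
#' @export
onehot_mask <- function(mask, n_classes) {
  out <- array(0, c(nrow(mask), ncol(mask), n_classes))
  for (c in seq_len(n_classes)) out[, , c] <- (mask == c - 1L) * 1
  out
}

#' Bilinear resize of an image or score array
#'
#' Top-left-aligned sampling (source coordinate = target * in/out), so that
#' upsampling by a factor f leaves the values at positions 0, f, 2f, ...
#' exactly equal to the source pixels.
#' @param x matrix or 3-d array
#' @param out_h,out_w output dimensions
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  was_mat <- is.matrix(x)
  if (was_mat) dim(x) <- c(dim(x), 1L)
  y <- bilinear_resize_cpp(x, as.integer(out_h), as.integer(out_w))
  if (was_mat) dim(y) <- dim(y)[1:2]
  y
}

#' Nearest-neighbour resize of a class-index matrix
#' @param mask integer matrix
#' @param out_h,out_w output dimensions
#' @export
resize_nearest <- function(mask, out_h, out_w) {
  h <- nrow(mask); w <- ncol(mask)
  ri <- pmin(floor((seq_len(out_h) - 1) * h / out_h) + 1, h)
  ci <- pmin(floor((seq_len(out_w) - 1) * w / out_w) + 1, w)
  mask[ri, ci, drop = FALSE]
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}
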