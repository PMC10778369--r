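#' Per-class intersection over union for one tile
#'
#' IoU_c = |pred = c AND gt = c| / |pred = c OR gt = c| * 100. A class absent
#' from both prediction and ground truth is excluded from this tile's
#' average (reported as NA).
#'
#' @param pred,gt integer class matrices of identical shape
#' @param classes classes to score (default DCIS = 1 and IC = 2; background
#'   is excluded from the reported average)
#' @return list with `iou` (named vector, %, NA when absent), `mean` (over
#'   present classes), and the raw intersection/union counts
#' @export
iou_per_class <- function(pred, gt, classes = c(1L, 2L)) {
  if (!all(dim(pred) == dim(gt))) stop("shape mismatch")
  inter <- uni <- setNames(numeric(length(classes)), classes)
  for (k in seq_along(classes)) {
    c <- classes[k]
    inter[k] <- sum(pred == c & gt == c)
    uni[k] <- sum(pred == c | gt == c)
  }
  iou <- ifelse(uni > 0, 100 * inter / uni, NA_real_)
  names(iou) <- paste0("class", classes)
  list(iou = iou, mean = if (all(is.na(iou))) NA_real_ else mean(iou, na.rm = TRUE),
       intersection = inter, union = uni)
}

#' Dataset-level IoU report over prediction / ground-truth pairs
#'
#' Emits both the dataset-level IoU (pooled confusion counts over all tiles,
#' the headline number) and the per-tile table (tile-averaged IoU also
#' reported).
#'
#' @param preds,gts lists of class matrices
#' @param metadata optional data.frame with one row per tile (e.g. `stain`,
#'   `tumor_type`) carried into the per-tile table
#' @param classes classes to score
#' @return object of class `iou_report`: list(dataset (named %), mean,
#'   per_tile data.frame)
#' @export
eval_dataset <- function(preds, gts, metadata = NULL, classes = c(1L, 2L)) {
  stopifnot(length(preds) == length(gts))
  inter <- uni <- setNames(numeric(length(classes)), classes)
  rows <- list()
  for (i in seq_along(preds)) {
    r <- iou_per_class(preds[[i]], gts[[i]], classes)
    inter <- inter + r$intersection
    uni <- uni + r$union
    rows[[i]] <- data.frame(tile = i, t(r$iou), mean = r$mean)
  }
  per_tile <- do.call(rbind, rows)
  if (!is.null(metadata)) per_tile <- cbind(per_tile, metadata)
  dataset <- ifelse(uni > 0, 100 * inter / uni, NA_real_)
  names(dataset) <- paste0("class", classes)
  structure(list(dataset = dataset,
                 mean = mean(dataset, na.rm = TRUE),
                 per_tile = per_tile), class = "iou_report")
}

#' @export
print.iou_report <- function(x, ...) {
  cat("dataset-level IoU (%):",
      paste(sprintf("%s=%.2f", names(x$dataset), x$dataset), collapse = " "),
      sprintf("mean=%.2f\n", x$mean))
  invisible(x)
}

#' Stratified mean IoU by stain and tumor type
#'
#' @param report an `iou_report` whose per-tile table carries the strata
#'   columns
#' @param by character vector of stratum columns (default stain and
#'   tumor_type)
#' @return data.frame with one row per non-empty stratum: mean per-class IoU
#'   and tile count. Empty strata are absent, not zero.
#' @export
stratified_eval <- function(report, by = c("stain", "tumor_type")) {
  pt <- report$per_tile
  if (!all(by %in% names(pt))) stop("missing stratum metadata: ",
                                    paste(setdiff(by, names(pt)), collapse = ", "))
  key <- interaction(pt[by], drop = TRUE, sep = "/")
  iou_cols <- grep("^class", names(pt), value = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    sub <- pt[key == k, , drop = FALSE]
    cbind(sub[1, by, drop = FALSE],
          as.data.frame(t(colMeans(sub[iou_cols], na.rm = TRUE))),
          mean = mean(sub$mean, na.rm = TRUE), n = nrow(sub))
  }))
  rownames(out) <- NULL
  out
}

#' Case-grouped k-fold cross-validation split
#'
#' Items sharing a case id always land in the same fold (no case leakage);
#' cases are shuffled with the given seed and dealt round-robin.
#'
#' @param items vector or list of items
#' @param case_ids case identifier per item
#' @param k number of folds
#' @param seed shuffle seed
#' @return integer vector of fold assignments (1..k) per item
#' @export
crossval_split <- function(items, case_ids, k, seed = 1L) {
  stopifnot(length(case_ids) == length(items))
  cases <- unique(case_ids)
  if (k > length(cases)) stop("k exceeds the number of cases")
  ord <- with_seed(seed, sample(length(cases)))
  fold_of_case <- setNames(rep(seq_len(k), length.out = length(cases)),
                           cases[ord])
  as.integer(fold_of_case[as.character(case_ids)])
}
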