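#' Detect nuclei in stain optical-density maps
#'
#' Total nuclear OD (hematoxylin + DAB) is Gaussian-smoothed and thresholded;
#' the resulting components are optionally split by a marker-based watershed
#' and filtered by area. Markers are intensity-dome peaks found *per stain
#' channel* (a faint hematoxylin nucleus pressed against a bright DAB
#' nucleus still forms a clear dome in its own channel), and the flood runs
#' on the total smoothed OD. A detection is called chromogen-positive when
#' its mean DAB OD exceeds `dab_threshold`.
#'
#' @param od_maps list with `hema` and `dab` matrices from [od_deconvolve()]
#' @param params list: `sigma` (smoothing, px), `threshold` (total OD),
#'   `min_area`,`max_area` (px^2), `watershed` (logical), `dab_threshold`
#'   (mean OD for a positive call), `peak_min_dist` (px)
#' @return data.frame with columns x, y (centroid, 1-based px), area,
#'   mean_dab, mean_hema, call ("positive"/"negative"); zero rows when
#'   nothing is found
#' @export
detect_nuclei <- function(od_maps, params = list()) {
  # defaults matched to ~5-6 px nucleus spacing: sigma ~ radius/3, threshold
  # between intra-nest background OD (~0.15) and dim negative nuclei (>0.4),
  # peak window just under the minimum center-to-center distance
  p <- modifyList(list(sigma = 1.0, threshold = 0.22, min_area = 5,
                       max_area = 400, watershed = TRUE, dab_threshold = 0.2,
                       peak_min_dist = 2L), params)
  smh <- gaussian_blur_cpp(od_maps$hema, p$sigma)
  smd <- gaussian_blur_cpp(od_maps$dab, p$sigma)
  sm <- smh + smd
  bin <- sm > p$threshold
  empty <- data.frame(x = numeric(0), y = numeric(0), area = numeric(0),
                      mean_dab = numeric(0), mean_hema = numeric(0),
                      call = character(0), stringsAsFactors = FALSE)
  if (!any(bin)) return(empty)
  if (isTRUE(p$watershed)) {
    r <- as.integer(p$peak_min_dist)
    pk <- function(m) (m >= max_filter_cpp(m, r) - 1e-9) &
      (m > 0.8 * p$threshold) & bin
    markers <- label_components_cpp(pk(smh) | pk(smd), 8L)
    lab <- watershed_cpp(sm, markers, bin)
  } else {
    lab <- label_components_cpp(bin, 4L)
  }
  v <- as.vector(lab)
  keep <- v > 0
  if (!any(keep)) return(empty)
  f <- factor(v[keep])
  rows <- as.vector(row(lab))[keep]; cols <- as.vector(col(lab))[keep]
  dab <- as.vector(od_maps$dab)[keep]; hem <- as.vector(od_maps$hema)[keep]
  area <- tabulate(f)
  cy <- tapply(rows, f, mean); cx <- tapply(cols, f, mean)
  mdab <- tapply(dab, f, mean); mhem <- tapply(hem, f, mean)
  det <- data.frame(x = as.numeric(cx), y = as.numeric(cy),
                    area = as.numeric(area), mean_dab = as.numeric(mdab),
                    mean_hema = as.numeric(mhem), stringsAsFactors = FALSE)
  det <- det[det$area >= p$min_area & det$area <= p$max_area, , drop = FALSE]
  det$call <- ifelse(det$mean_dab > p$dab_threshold, "positive", "negative")
  rownames(det) <- NULL
  det
}

#' Ki-67 index of a set of detections under a mask condition
#'
#' The condition fixes the scored region: `no_mask` counts every detection,
#' `tumor_mask` only detections whose centroid falls on tumor (classes 1 or
#' 2 of the label mask), `ic_mask` only on invasive carcinoma (class 2).
#' Membership is tested at the centroid with the (stride-8) mask upsampled by
#' nearest neighbour.
#'
#' @param detections data.frame from [detect_nuclei()]
#' @param mask a `label_mask`, a class matrix, or NULL (required unless
#'   condition is "no_mask")
#' @param condition one of "no_mask", "tumor_mask", "ic_mask"
#' @param stride mask stride relative to detection coordinates (taken from a
#'   `label_mask` automatically)
#' @return object of class `ki67_result`: list(condition, n_positive,
#'   n_negative, index) with index in percent
#' @export
ki67_index <- function(detections, mask = NULL,
                       condition = c("no_mask", "tumor_mask", "ic_mask"),
                       stride = 1L) {
  condition <- match.arg(condition)
  if (condition == "no_mask") {
    inc <- rep(TRUE, nrow(detections))
  } else {
    if (is.null(mask)) stop("a mask is required for condition ", condition)
    if (inherits(mask, "label_mask")) { stride <- mask$stride; mask <- mask$mask }
    ri <- pmin(pmax(floor((detections$y - 1) / stride) + 1, 1), nrow(mask))
    ci <- pmin(pmax(floor((detections$x - 1) / stride) + 1, 1), ncol(mask))
    cls <- mask[cbind(ri, ci)]
    inc <- if (condition == "tumor_mask") cls %in% c(1L, 2L) else cls == 2L
  }
  n_pos <- sum(detections$call[inc] == "positive")
  n_neg <- sum(detections$call[inc] == "negative")
  if (n_pos + n_neg == 0)
    stop("Ki-67 index undefined: no detections inside the scored region")
  structure(list(condition = condition, n_positive = n_pos,
                 n_negative = n_neg,
                 index = 100 * n_pos / (n_pos + n_neg)),
            class = "ki67_result")
}

#' @export
print.ki67_result <- function(x, ...) {
  cat(sprintf("Ki-67 [%s]: %d+ / %d- -> %.2f%%\n", x$condition,
              x$n_positive, x$n_negative, x$index))
  invisible(x)
}

#' Full Ki-67 quantification of one image under the three mask conditions
#'
#' @param image H x W x 3 RGB array (0..255 scale)
#' @param mask segmentation mask (`label_mask` or matrix), or NULL to only
#'   compute the no-mask condition
#' @param detect_params passed to [detect_nuclei()]
#' @return list with `detections` and a named list `results` of
#'   `ki67_result`s
#' @export
ki67_quantify <- function(image, mask = NULL, detect_params = list()) {
  od <- od_deconvolve(image)
  det <- detect_nuclei(od, detect_params)
  conds <- if (is.null(mask)) "no_mask" else c("no_mask", "tumor_mask", "ic_mask")
  results <- lapply(conds, function(cn)
    tryCatch(ki67_index(det, mask, cn), error = function(e) NULL))
  names(results) <- conds
  list(detections = det, results = results)
}

#' Agreement statistics between estimated and reference Ki-67 indices
#'
#' Errors are reported as estimate minus reference, in percentage points
#' (negative mean = systematic underestimation).
#'
#' @param estimates,references paired numeric vectors (n >= 3)
#' @return object of class `agreement_stats`: list(pearson_r, mean_error,
#'   sd_error, n, table)
#' @export
summarize_agreement <- function(estimates, references) {
  if (length(estimates) != length(references)) stop("length mismatch")
  if (length(estimates) < 3) stop("need at least 3 paired cases")
  if (sd(estimates) == 0 || sd(references) == 0)
    stop("zero variance: correlation undefined")
  err <- estimates - references
  structure(list(
    pearson_r = cor(estimates, references),
    mean_error = mean(err), sd_error = sd(err), n = length(err),
    table = data.frame(reference = references, estimate = estimates,
                       error = err)
  ), class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("agreement over %d cases: r=%.4f, mean error=%.2f, sd=%.2f\n",
              x$n, x$pearson_r, x$mean_error, x$sd_error))
  invisible(x)
}
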