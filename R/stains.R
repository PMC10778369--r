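#' Standard H-DAB stain vectors
#'
#' Unit optical-density RGB absorption vectors for hematoxylin (nuclear
#' counterstain, blue) and 3,3'-diaminobenzidine (DAB, the brown chromogen),
#' after Ruifrok & Johnston; the residual vector completes an orthogonal-ish
#' basis so the 3x3 system is invertible.
#'
#' @return list with unit vectors `hema`, `dab`, `res` and the 3x3 matrix `M`
#'   whose rows are the vectors.
#' @export
stain_vectors <- function() {
  hema <- c(0.650, 0.704, 0.286)
  dab <- c(0.268, 0.570, 0.776)
  res <- c(
    hema[2] * dab[3] - hema[3] * dab[2],
    hema[3] * dab[1] - hema[1] * dab[3],
    hema[1] * dab[2] - hema[2] * dab[1]
  )
  hema <- hema / sqrt(sum(hema^2))
  dab <- dab / sqrt(sum(dab^2))
  res <- res / sqrt(sum(res^2))
  M <- rbind(hema = hema, dab = dab, res = res)
  list(hema = hema, dab = dab, res = res, M = M)
}

#' Render per-stain optical-density maps to an 8-bit RGB image
#'
#' Beer-Lambert forward model: transmitted intensity
#' I_c = 256 * 10^(-OD_c) - 1 per channel, quantised to 8 bits. This is the
#' exact inverse of the deconvolution convention OD = -log10((I+1)/256).
#'
#' @param od_h,od_d,od_r matrices of hematoxylin / DAB / residual OD
#' @param vectors stain basis from [stain_vectors()]
#' @return numeric array H x W x 3 with values in 0..255 (whole numbers)
#' @export
od_to_rgb <- function(od_h, od_d, od_r = NULL, vectors = stain_vectors()) {
  h <- nrow(od_h); w <- ncol(od_h)
  if (is.null(od_r)) od_r <- matrix(0, h, w)
  img <- array(0, c(h, w, 3))
  for (c in 1:3) {
    od_c <- od_h * vectors$hema[c] + od_d * vectors$dab[c] + od_r * vectors$res[c]
    img[, , c] <- clamp(round(256 * 10^(-od_c) - 1), 0, 255)
  }
  img
}

#' Ruifrok-Johnston color deconvolution
#'
#' Projects per-pixel optical density OD = -log10((I+1)/256) onto the stain
#' basis and clips the resulting stain concentrations at zero. Accepts
#' non-integer intensities so that synthetic round trips can be tested below
#' quantisation noise.
#'
#' @param rgb numeric array H x W x 3, intensities on the 0..255 scale
#' @param vectors stain basis from [stain_vectors()]
#' @return list of matrices `hema`, `dab`, `res` (stain OD maps, >= 0)
#' @export
od_deconvolve <- function(rgb, vectors = stain_vectors()) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  M <- vectors$M
  if (abs(det(M)) < 1e-8) stop("singular stain basis")
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  od <- -log10((matrix(rgb, h * w, 3) + 1) / 256)
  conc <- od %*% solve(M)  # rows: pixels; cols: stains
  conc[conc < 0] <- 0
  list(
    hema = matrix(conc[, 1], h, w),
    dab = matrix(conc[, 2], h, w),
    res = matrix(conc[, 3], h, w)
  )
}
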