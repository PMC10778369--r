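test_that("stain basis is unit-norm and invertible; deconvolution round-trips", {
  v <- stain_vectors()
  for (u in list(v$hema, v$dab, v$res))
    expect_equal(sum(u^2), 1, tolerance = 1e-12)
  expect_gt(abs(det(v$M)), 0.1)
  # pure white: OD ~ 0 everywhere
  white <- array(255, c(2, 2, 3))
  od <- od_deconvolve(white)
  expect_lt(max(abs(od$hema)), 1e-2)
  expect_lt(max(abs(od$dab)), 1e-2)
  # a pixel synthesised from the hematoxylin vector at unit OD (unquantised)
  px <- array(256 * 10^(-v$hema) - 1, c(1, 1, 3))
  od1 <- od_deconvolve(px)
  expect_equal(od1$hema[1, 1], 1, tolerance = 1e-3)
  expect_lt(abs(od1$dab[1, 1]), 1e-3)
  # DAB round trip likewise
  pd <- array(256 * 10^(-0.7 * v$dab) - 1, c(1, 1, 3))
  od2 <- od_deconvolve(pd)
  expect_equal(od2$dab[1, 1], 0.7, tolerance = 1e-3)
  # singular basis rejected
  bad <- v; bad$M <- rbind(v$hema, v$hema, v$res)
  expect_error(od_deconvolve(white, bad), "singular")
})

test_that("deconvolution separates positive from negative generator nuclei", {
  tl <- generate_tile(tile_spec(scenario = "invasive", stain = "Ki67",
                                positivity = 0.5, seed = 31))
  od <- od_deconvolve(tl$image)
  nuc <- tl$nuclei[tl$nuclei$class == "tumor_ic", ]
  dab_at <- od$dab[cbind(round(nuc$y), round(nuc$x))]
  expect_gt(min(dab_at[nuc$marker_positive]),
            max(dab_at[!nuc$marker_positive]))
})

# draw synthetic nuclei directly in OD space at known positions
draw_nuclei_tile <- function(centers, positive, size = 128L, radius = 3) {
  H <- matrix(0.03, size, size); D <- matrix(0, size, size)
  for (k in seq_len(nrow(centers))) {
    cx <- centers[k, 1]; cy <- centers[k, 2]
    ii <- pmax(1, cy - 5):pmin(size, cy + 5)
    jj <- pmax(1, cx - 5):pmin(size, cx + 5)
    d2 <- outer((ii - cy)^2, (jj - cx)^2, "+")
    w <- pmax(0, 1 - sqrt(d2) / radius)
    w <- matrix(pmin(1, 2 * w), length(ii), length(jj))
    if (positive[k]) D[ii, jj] <- D[ii, jj] + 0.9 * w
    else H[ii, jj] <- H[ii, jj] + 0.7 * w
  }
  od_to_rgb(H, D)
}

test_that("nucleus detection: blank tiles, counts, calls, watershed split", {
  blank <- od_deconvolve(array(255, c(64, 64, 3)))
  expect_equal(nrow(detect_nuclei(blank)), 0L)
  # 50 well-separated nuclei on a jittered grid
  withr::with_seed(17, {
    grid <- expand.grid(x = seq(10, 120, by = 15), y = seq(10, 120, by = 15))
    grid <- grid[sample(nrow(grid), 50), ]
    pos <- runif(50) < 0.4
    img <- draw_nuclei_tile(as.matrix(grid), pos)
  })
  det <- detect_nuclei(od_deconvolve(img))
  expect_gte(nrow(det), 48)
  expect_lte(nrow(det), 52)
  # match detections to truth by nearest centre; calls >= 95% correct
  truth_call <- ifelse(pos, "positive", "negative")
  matched <- vapply(seq_len(nrow(det)), function(i) {
    d2 <- (grid$x - det$x[i])^2 + (grid$y - det$y[i])^2
    truth_call[which.min(d2)]
  }, "")
  expect_gte(mean(matched == det$call), 0.95)
  # two touching blobs: watershed separates them, plain labelling does not
  touch <- draw_nuclei_tile(rbind(c(60, 60), c(66, 60)), c(TRUE, FALSE),
                            size = 96L)
  od_t <- od_deconvolve(touch)
  expect_equal(nrow(detect_nuclei(od_t, list(watershed = TRUE))), 2L)
  expect_equal(nrow(detect_nuclei(od_t, list(watershed = FALSE))), 1L)
})

test_that("ki67_index: definition, region logic, undefined case", {
  det <- data.frame(x = c(rep(10, 80), rep(10, 20)), y = rep(10, 100),
                    call = c(rep("positive", 80), rep("negative", 20)))
  r <- ki67_index(det, condition = "no_mask")
  expect_equal(r$index, 80)
  expect_equal(r$n_positive, 80L)
  # lymphocyte-like negatives outside the tumor mask lower only no_mask
  mask <- matrix(0L, 4, 4)
  mask[1, 1] <- 2L; mask[2, 2] <- 1L
  det2 <- data.frame(
    x = c(rep(4, 10), rep(12, 6), rep(28, 30)),   # IC, DCIS, outside
    y = c(rep(4, 10), rep(12, 6), rep(28, 30)),
    call = c(rep(c("positive", "negative"), 5),   # IC: 5+/5-
             rep("positive", 6),                  # DCIS: 6+/0-
             rep("negative", 30)))                # lymphocytes: all negative
  lm <- structure(list(mask = mask, stride = 8L), class = "label_mask")
  no <- ki67_index(det2, lm, "no_mask")
  tu <- ki67_index(det2, lm, "tumor_mask")
  ic <- ki67_index(det2, lm, "ic_mask")
  expect_equal(ic$index, 50)
  expect_equal(tu$index, 100 * 11 / 16)
  expect_equal(no$index, 100 * 11 / 46)
  expect_lt(no$index, tu$index)
  # dropping the outside negatives changes no_mask only
  det3 <- det2[1:16, ]
  expect_equal(ki67_index(det3, lm, "tumor_mask")$index, tu$index)
  expect_equal(ki67_index(det3, lm, "ic_mask")$index, ic$index)
  expect_gt(ki67_index(det3, lm, "no_mask")$index, no$index)
  # no detections inside the region: explicit error
  far <- data.frame(x = 28, y = 28, call = "negative")
  expect_error(ki67_index(far, lm, "ic_mask"), "undefined")
})

test_that("agreement statistics match the textbook formulas", {
  expect_error(summarize_agreement(1:2, 1:2), "at least 3")
  expect_error(summarize_agreement(c(1, 1, 1), c(1, 2, 3)), "variance")
  s <- summarize_agreement(c(10, 20, 30), c(10, 20, 30))
  expect_equal(s$pearson_r, 1)
  expect_equal(s$mean_error, 0)
  expect_equal(s$sd_error, 0)
  s2 <- summarize_agreement(c(12, 22, 32), c(10, 20, 30))
  expect_equal(s2$pearson_r, 1)
  expect_equal(s2$mean_error, 2)
  expect_equal(s2$sd_error, 0)
  withr::with_seed(23, {
    for (rep in 1:5) {
      a <- runif(10, 0, 100); b <- a + rnorm(10, 2, 5)
      s3 <- summarize_agreement(b, a)
      n <- 10
      r_oracle <- (sum(a * b) - n * mean(a) * mean(b)) /
        sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
      expect_equal(s3$pearson_r, r_oracle, tolerance = 1e-10)
      expect_equal(s3$mean_error, mean(b - a), tolerance = 1e-12)
      expect_equal(s3$sd_error, sqrt(sum((b - a - mean(b - a))^2) / (n - 1)),
                   tolerance = 1e-12)
    }
  })
})

test_that("index is invariant to detection ordering", {
  withr::with_seed(29, {
    det <- data.frame(x = runif(60, 1, 60), y = runif(60, 1, 60),
                      call = sample(c("positive", "negative"), 60, TRUE))
    mask <- matrix(sample(0:2, 64, TRUE), 8, 8)
    lm <- structure(list(mask = mask, stride = 8L), class = "label_mask")
    a <- ki67_index(det, lm, "tumor_mask")
    b <- ki67_index(det[sample(60), ], lm, "tumor_mask")
    expect_equal(a$index, b$index)
  })
})
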