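test_that("tile_spec validates its invariants", {
  expect_error(tile_spec(size_px = 60), "64")
  expect_error(tile_spec(size_px = 100), "divisible by 8")
  expect_error(tile_spec(positivity = 1.2), "positivity")
  expect_error(tile_spec(nest_size_range = c(0, 10)), "positive lower")
  expect_error(tile_spec(confounders = "stroma"), "subset")
  expect_s3_class(tile_spec(), "tile_spec")
})

test_that("normal scenario yields an all-background mask", {
  tl <- generate_tile(tile_spec(scenario = "normal", size_px = 128L, seed = 3))
  expect_true(all(tl$mask == 0L))
  expect_true(all(tl$boundary == 0L))
  # the lobule is rendered (image is not blank) yet labeled background
  expect_gt(sd(tl$image), 1)
})

test_that("generation is bit-reproducible for a fixed spec", {
  sp <- tile_spec(scenario = "dcis", seed = 7, size_px = 128L)
  a <- generate_tile(sp)
  b <- generate_tile(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$nuclei, b$nuclei)
  c <- generate_tile(tile_spec(scenario = "dcis", seed = 8, size_px = 128L))
  expect_false(identical(a$image, c$image))
})

test_that("mixed tiles contain both classes and match the placement log", {
  for (seed in c(2, 5, 9)) {
    tl <- generate_tile(tile_spec(scenario = "mixed", seed = seed))
    expect_setequal(intersect(unique(as.vector(tl$mask)), 1:2), 1:2)
    log_px <- tapply(tl$placements$n_pixels, tl$placements$class, sum)
    expect_identical(sum(tl$mask == 1L), as.integer(log_px[["1"]]))
    expect_identical(sum(tl$mask == 2L), as.integer(log_px[["2"]]))
  }
})

test_that("scenario purity: dcis tiles have no IC and vice versa", {
  d <- generate_tile(tile_spec(scenario = "dcis", seed = 1))
  i <- generate_tile(tile_spec(scenario = "invasive", seed = 1))
  expect_false(any(d$mask == 2L))
  expect_false(any(i$mask == 1L))
})

test_that("boundary ground truth matches a brute-force neighborhood scan", {
  # uniform mask: no transitions anywhere
  expect_true(all(derive_boundary_gt(matrix(1L, 10, 10), 2L) == 0L))
  # 8x8 left half class 1 / right half class 2, width 1: exactly the two
  # transition columns (16 pixels)
  m <- cbind(matrix(1L, 8, 4), matrix(2L, 8, 4))
  b1 <- derive_boundary_gt(m, 1L)
  expect_equal(sum(b1), 16L)
  expect_true(all(b1[, 4:5] == 1L))
  # brute force over random masks, width 1 and 2
  withr::with_seed(42, {
    for (rep in 1:5) {
      mk <- matrix(sample(0:2, 64, TRUE), 8, 8)
      for (wd in 1:2) {
        got <- derive_boundary_gt(mk, wd)
        want <- matrix(0L, 8, 8)
        for (i in 1:8) for (j in 1:8) {
          trans <- FALSE
          for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
            ii <- i + d[1]; jj <- j + d[2]
            if (ii >= 1 && ii <= 8 && jj >= 1 && jj <= 8 &&
                mk[ii, jj] != mk[i, j]) trans <- TRUE
          }
          if (trans) {
            for (ii in max(1, i - wd + 1):min(8, i + wd - 1))
              for (jj in max(1, j - wd + 1):min(8, j + wd - 1))
                want[ii, jj] <- 1L
          }
        }
        expect_identical(got, want)
      }
      # dilation monotonicity
      expect_true(all(derive_boundary_gt(mk, 2L) >= derive_boundary_gt(mk, 1L)))
    }
  })
})

test_that("chromogen appearance is coupled to the positivity labels", {
  tl <- generate_tile(tile_spec(scenario = "mixed", stain = "Ki67",
                                positivity = 0.5, seed = 21))
  od <- od_deconvolve(tl$image)
  nuc <- tl$nuclei[tl$nuclei$class %in% c("tumor_dcis", "tumor_ic"), ]
  at <- function(df) od$dab[cbind(pmin(pmax(round(df$y), 1), nrow(od$dab)),
                                  pmin(pmax(round(df$x), 1), ncol(od$dab)))]
  m_pos <- mean(at(nuc[nuc$marker_positive, ]))
  m_neg <- mean(at(nuc[!nuc$marker_positive, ]))
  expect_gt(m_pos, m_neg + 0.3)
})

test_that("HER2 tiles localise the chromogen on membranes, not nuclei", {
  tl <- generate_tile(tile_spec(scenario = "dcis", stain = "HER2",
                                positivity = 0.8, seed = 5))
  od <- od_deconvolve(tl$image)
  pos <- tl$nuclei[tl$nuclei$marker_positive, ]
  pos <- pos[pos$x > 8 & pos$x < 248 & pos$y > 8 & pos$y < 248, ]
  centre <- mean(od$dab[cbind(round(pos$y), round(pos$x))])
  ring <- mean(od$dab[cbind(round(pos$y), round(pos$x + 4))])
  expect_gt(ring, centre)
  # nuclear stains put the chromogen at the nucleus centre instead
  tk <- generate_tile(tile_spec(scenario = "dcis", stain = "Ki67",
                                positivity = 0.8, seed = 5))
  odk <- od_deconvolve(tk$image)
  posk <- tk$nuclei[tk$nuclei$marker_positive, ]
  posk <- posk[posk$x > 8 & posk$x < 248 & posk$y > 8 & posk$y < 248, ]
  expect_gt(mean(odk$dab[cbind(round(posk$y), round(posk$x))]),
            mean(odk$dab[cbind(round(posk$y), round(posk$x + 4))]))
})

test_that("pseudo-WSI ledger is exact and deterministic", {
  w <- generate_pseudo_wsi(side_px = 1024L, context_side = 512L, seed = 4)
  w2 <- generate_pseudo_wsi(side_px = 1024L, context_side = 512L, seed = 4)
  expect_identical(w$nuclei, w2$nuclei)
  expect_identical(w$image, w2$image)
  # nucleus classes partition the ledger
  expect_identical(
    sum(table(w$nuclei$class)), nrow(w$nuclei)
  )
  # all centers inside the canvas
  expect_true(all(w$nuclei$x >= 1 & w$nuclei$x <= 1024 &
                    w$nuclei$y >= 1 & w$nuclei$y <= 1024))
  # recorded truth indices agree with direct recomputation from the ledger
  ic <- w$nuclei[w$nuclei$class == "tumor_ic", ]
  expect_equal(w$truth$index_ic, 100 * sum(ic$marker_positive) / nrow(ic))
  tum <- w$nuclei[w$nuclei$class %in% c("tumor_ic", "tumor_dcis"), ]
  expect_equal(w$truth$index_tumor,
               100 * sum(tum$marker_positive) / nrow(tum))
  expect_equal(w$truth$index_image,
               100 * sum(tum$marker_positive) / nrow(w$nuclei))
  # lymphocytes are always marker-negative
  expect_false(any(w$nuclei$marker_positive[w$nuclei$class == "lymphocyte"]))
  # undersized canvases are rejected
  expect_error(generate_pseudo_wsi(side_px = 768L, context_side = 512L),
               ">= 2x")
})

test_that("synth_dataset groups tiles into cases and varies strata", {
  tiles <- small_tiles()
  expect_length(tiles, 8)
  expect_length(unique(vapply(tiles, `[[`, "", "case_id")), 2L)
  expect_true(all(vapply(tiles, `[[`, "", "stain") %in%
                    c("ER", "PR", "HER2", "Ki67")))
})
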