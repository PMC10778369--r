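test_that("geometry: published sizes and scaled-down sizes", {
  g <- plan_geometry(4096L)
  expect_equal(g$crop_side, 2048L)
  expect_equal(g$out_side, 256L)
  expect_equal(g$corner_offsets,
               rbind(c(0L, 0L), c(0L, 2048L), c(2048L, 0L), c(2048L, 2048L)))
  expect_equal(g$center_offset, c(1024L, 1024L))
  gs <- plan_geometry(512L)
  expect_equal(gs$corner_offsets[4, ], c(256L, 256L))
  expect_equal(gs$center_offset, c(128L, 128L))
  expect_equal(gs$out_side, 32L)
  expect_error(plan_geometry(520L), "divisible by 16")
})

test_that("corner crops tile the context exactly (bit-exact reassembly)", {
  withr::with_seed(2, {
    img <- array(runif(128 * 128 * 3), c(128, 128, 3))
    g <- plan_geometry(128L)
    rec <- array(NA_real_, dim(img))
    for (k in 1:4) {
      off <- g$corner_offsets[k, ]
      rec[off[1] + seq_len(64), off[2] + seq_len(64), ] <-
        img[off[1] + seq_len(64), off[2] + seq_len(64), ]
    }
    expect_identical(rec, img)
  })
})

test_that("with a block-mean stub network p1 == p2 exactly and p3 is close", {
  withr::with_seed(4, {
    # smooth field (feature scale ~64 px: unit-amplitude 4x4 noise upsampled)
    base <- array(runif(4 * 4 * 3), c(4, 4, 3))
    img <- ihcseg:::bilinear_resize_cpp(base, 256L, 256L)
    g <- plan_geometry(256L)
    tr <- branch_outputs(stub_block_mean, img, g)
    expect_equal(dim(tr$p1), c(16, 16, 3))
    expect_identical(tr$p1, tr$p2)  # same region, same scale, aligned blocks
    # p3 loses half the sampling rate: allow twice the measured interpolation
    # error of this field class, far below its O(0.3) signal variation
    expect_lt(max(abs(tr$p3 - tr$p2)), 0.15)
    expect_lt(mean(abs(tr$p3 - tr$p2)), 0.05)
  })
})

test_that("constant context gives constant branch maps", {
  img <- array(0.4, c(128, 128, 3))
  tr <- branch_outputs(stub_block_mean, img, plan_geometry(128L))
  for (p in tr) expect_true(all(abs(p - 0.4) < 1e-12))
})

test_that("AFF convex-blend endpoints and symmetry", {
  withr::with_seed(8, {
    a <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
    b <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
    p <- aff_init(3L, seed = 1)
    expect_identical(aff_fuse(a, b, p, gate = 1), a)
    expect_identical(aff_fuse(a, b, p, gate = 0), b)
    expect_equal(aff_fuse(a, b, p, gate = 0.5), (a + b) / 2, tolerance = 1e-12)
    # equal inputs are a fixed point for any learned gate
    expect_equal(aff_fuse(a, a, p), a, tolerance = 1e-12)
    # learned gate lies strictly in (0,1): fused within elementwise hull
    f <- aff_fuse(a, b, p)
    expect_true(all(f <= pmax(a, b) + 1e-12 & f >= pmin(a, b) - 1e-12))
    expect_error(aff_fuse(a, array(0, c(2, 2, 3)), p), "mismatch")
  })
})

test_that("the cascade applies the two AFF modules in the stated order", {
  withr::with_seed(9, {
    tr <- structure(list(p1 = array(rnorm(48), c(4, 4, 3)),
                         p2 = array(rnorm(48), c(4, 4, 3)),
                         p3 = array(rnorm(48), c(4, 4, 3))),
                    class = "branch_triplet")
    params <- list(aff1 = aff_init(3L, seed = 2), aff2 = aff_init(3L, seed = 3))
    # identical inputs pass through unchanged (convexity at every stage)
    same <- structure(list(p1 = tr$p1, p2 = tr$p1, p3 = tr$p1),
                      class = "branch_triplet")
    expect_equal(fuse_triplet(same, params), tr$p1, tolerance = 1e-12)
    # order matters for generic inputs
    swapped <- structure(list(p1 = tr$p3, p2 = tr$p2, p3 = tr$p1),
                         class = "branch_triplet")
    expect_gt(max(abs(fuse_triplet(tr, params) -
                        fuse_triplet(swapped, params))), 1e-6)
    # forced 0.5 gates: p = ((p1 + p2)/2 + p3)/2
    q <- aff_fuse(tr$p1, tr$p2, params$aff1, gate = 0.5)
    p <- aff_fuse(q, tr$p3, params$aff2, gate = 0.5)
    expect_equal(p, ((tr$p1 + tr$p2) / 2 + tr$p3) / 2, tolerance = 1e-12)
  })
})

test_that("AFF backward matches finite differences", {
  withr::with_seed(12, {
    a <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
    b <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
    p <- aff_init(3L, seed = 4)
    dF <- array(rnorm(12), c(2, 2, 3))
    cache <- ihcseg:::aff_forward_full(a, b, p)
    bw <- ihcseg:::aff_backward(cache, p, dF)
    loss <- function(pp, aa = a, bb = b) sum(aff_fuse(aa, bb, pp) * dF)
    eps <- 1e-6
    for (nm in c("W1", "b2", "G1", "g2")) {
      k <- sample(length(p[[nm]]), 1)
      p1 <- p; p1[[nm]][k] <- p1[[nm]][k] + eps
      p2 <- p; p2[[nm]][k] <- p2[[nm]][k] - eps
      expect_equal(bw$grads[[nm]][k], (loss(p1) - loss(p2)) / (2 * eps),
                   tolerance = 1e-4)
    }
    k <- 5
    a1 <- a; a1[k] <- a1[k] + eps; a2 <- a; a2[k] <- a2[k] - eps
    expect_equal(bw$da[k], (loss(p, aa = a1) - loss(p, aa = a2)) / (2 * eps),
                 tolerance = 1e-4)
  })
})

test_that("stage-2 training touches only the AFF parameters", {
  net <- fresh_net(3)
  hash0 <- param_hash(net)
  wsis <- lapply(1:2, function(i) {
    w <- generate_pseudo_wsi(side_px = 256L, context_side = 128L,
                             seed = 40 + i)
    list(context = ihcseg:::crop_arr(w$image / 255, 64L, 64L, 128L),
         gt = ihcseg:::crop_arr(w$mask, 64L, 64L, 128L))
  })
  g <- plan_geometry(128L)
  # zero epochs: AFF parameters unchanged
  p0 <- list(aff1 = aff_init(3L, seed = 1), aff2 = aff_init(3L, seed = 2))
  r0 <- train_stage2(net, wsis, g, epochs = 0L, params = p0)
  expect_identical(r0$params, p0)
  # a few epochs: AFF parameters move, backbone does not
  r <- train_stage2(net, wsis, g, epochs = 3L, lr = 0.01, seed = 5)
  expect_identical(param_hash(net), hash0)
  expect_identical(r$backbone_hash[["before"]], r$backbone_hash[["after"]])
  expect_false(identical(r$params$aff1$W1,
                         aff_init(3L, seed = derive_seed(5, "aff1"))$W1))
  expect_length(r$history, 3L)
})
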