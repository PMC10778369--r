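test_that("loss_weights validates ranges", {
  expect_error(loss_weights(lambda1 = -1), "nonnegative")
  expect_error(loss_weights(t = 1.2), "t must")
  expect_error(loss_weights(tau = 0), "tau")
})

test_that("weighted CE: worked examples", {
  # perfect one-hot prediction -> 0 (up to clipping)
  p <- array(0, c(2, 2, 3)); gt <- matrix(0:1, 2, 2)
  for (i in 1:2) for (j in 1:2) p[i, j, gt[i, j] + 1] <- 1
  expect_lt(weighted_ce(p, gt), 1e-10)
  # uniform binary prediction -> ln 2
  expect_equal(weighted_ce(array(0.5, c(1, 1, 2)), matrix(0L, 1, 1)),
               log(2), tolerance = 1e-12)
  # 2x2 with probs 0.7/0.9/0.6/0.8 on true classes, weights (1,2,1)
  gt <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  probs <- array(1 / 3, c(2, 2, 3))
  ptrue <- matrix(c(0.7, 0.9, 0.6, 0.8), 2, 2)
  for (i in 1:2) for (j in 1:2) {
    others <- setdiff(1:3, gt[i, j] + 1)
    probs[i, j, gt[i, j] + 1] <- ptrue[i, j]
    probs[i, j, others] <- (1 - ptrue[i, j]) / 2
  }
  wts <- c(1, 2, 1)
  expect_equal(weighted_ce(probs, gt, wts), oracle_weighted_ce(probs, gt, wts),
               tolerance = 1e-12)
  expect_error(weighted_ce(probs, matrix(3L, 2, 2), wts), "out of range")
})

test_that("boundary BCE: worked examples", {
  g <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_lt(boundary_bce(g, g), 1e-10)
  expect_equal(boundary_bce(matrix(0.5, 1, 1), matrix(1, 1, 1)), log(2),
               tolerance = 1e-12)
  p <- matrix(c(0.9, 0.2, 0.6, 0.4), 2, 2)
  expect_equal(boundary_bce(p, g, pos_weight = 10), oracle_bce(p, g, 10),
               tolerance = 1e-12)
})

test_that("BAS loss: gating exactness and worked example", {
  probs <- random_prob_map(3, 3, 3)
  gt <- matrix(sample(0:2, 9, TRUE), 3, 3)
  # all boundary scores <= t: exactly zero, whatever the predictions
  expect_identical(bas_loss(probs, gt, matrix(0.8, 3, 3), t = 0.8), 0)
  # perfect predictions with all pixels firing: zero
  perfect <- array(0, c(3, 3, 3))
  for (i in 1:3) for (j in 1:3) perfect[i, j, gt[i, j] + 1] <- 1
  expect_lt(bas_loss(perfect, gt, matrix(0.9, 3, 3), t = 0.8), 1e-10)
  # single pixel, b = 0.9 > t = 0.8, true-class prob 0.25
  expect_equal(
    bas_loss(array(c(0.25, 0.75), c(1, 1, 2)), matrix(0L, 1, 1),
             matrix(0.9, 1, 1), t = 0.8),
    -log(0.25), tolerance = 1e-12)
})

test_that("BAS loss is monotonically non-increasing in t", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      probs <- random_prob_map(4, 4, 3)
      gt <- matrix(sample(0:2, 16, TRUE), 4, 4)
      b <- matrix(runif(16), 4, 4)
      ts <- seq(0.05, 0.95, by = 0.1)
      vals <- vapply(ts, function(t) bas_loss(probs, gt, b, t), 0)
      expect_true(all(diff(vals) <= 1e-12))
    }
  })
})

test_that("supervised loss is the stated linear combination", {
  # all components zero -> zero; fixed components scale linearly
  outs <- list(plS_probs = random_prob_map(2, 2, 3),
               pl_probs = random_prob_map(2, 2, 3),
               plB_probs = matrix(0.5, 2, 2))
  gs <- matrix(0L, 2, 2); gB <- matrix(0, 2, 2)
  w1 <- loss_weights(lambda0 = 1, lambda1 = 1, lambda2 = 1, lambda3 = 1)
  w2 <- loss_weights(lambda0 = 2, lambda1 = 2, lambda2 = 2, lambda3 = 2)
  r1 <- supervised_loss(outs, gs, gB, w1)
  r2 <- supervised_loss(outs, gs, gB, w2)
  expect_equal(r1$Ls, r1$l0 + r1$l1 + r1$l2 + r1$l3, tolerance = 1e-12)
  expect_equal(r2$Ls, 2 * r1$Ls, tolerance = 1e-12)
  perfect <- array(0, c(2, 2, 3)); perfect[, , 1] <- 1
  rp <- supervised_loss(list(plS_probs = perfect, pl_probs = perfect,
                             plB_probs = matrix(0, 2, 2)), gs, gB, w1)
  expect_lt(rp$Ls, 1e-9)
})

test_that("consistency loss: worked single-pixel case and gating", {
  w <- loss_weights(tau = 0.95, lambda_fp = 0.5, mu = 0.5)
  pw <- array(c(0.97, 0.03), c(1, 1, 2))
  pfp <- array(c(0.8, 0.2), c(1, 1, 2))
  ps1 <- array(c(0.6, 0.4), c(1, 1, 2))
  ps2 <- array(c(0.97, 0.03), c(1, 1, 2))
  got <- unimatch_loss(pw, pfp, ps1, ps2, w)
  want <- 0.5 * (-log(0.8)) + 0.25 * (-log(0.6) - log(0.97))
  expect_equal(got, want, tolerance = 1e-12)
  expect_lt(abs(got - 0.246901), 1e-5)  # quoted constant, printed precision
  # every pixel below tau: exactly zero
  soft <- array(c(0.6, 0.4), c(1, 1, 2))
  expect_identical(unimatch_loss(soft, pfp, ps1, ps2, w), 0)
  # agreeing one-hot maps: ~0
  hard <- array(c(1, 0), c(1, 1, 2))
  expect_lt(unimatch_loss(hard, hard, hard, hard, w), 1e-10)
  # tau = 0 gates nothing: equals the plain consistency loss
  w0 <- loss_weights(tau = 1e-9, lambda_fp = 0.5, mu = 0.5)
  expect_equal(unimatch_loss(soft, pfp, ps1, ps2, w0),
               0.5 * (-log(0.8)) + 0.25 * (-log(0.6) - log(0.97)),
               tolerance = 1e-12)
})

test_that("all losses match independent per-pixel oracles on random maps", {
  withr::with_seed(11, {
    for (rep in 1:8) {
      h <- sample(2:4, 1); wd <- sample(2:4, 1); C <- sample(2:4, 1)
      probs <- random_prob_map(h, wd, C)
      gt <- matrix(sample(0:(C - 1), h * wd, TRUE), h, wd)
      wts <- runif(C, 0.5, 2)
      expect_equal(weighted_ce(probs, gt, wts),
                   oracle_weighted_ce(probs, gt, wts), tolerance = 1e-6)
      pb <- matrix(runif(h * wd), h, wd)
      gb <- matrix(sample(0:1, h * wd, TRUE), h, wd)
      pwt <- runif(1, 1, 10)
      expect_equal(boundary_bce(pb, gb, pwt), oracle_bce(pb, gb, pwt),
                   tolerance = 1e-6)
      t <- runif(1, 0.2, 0.9)
      expect_equal(bas_loss(probs, gt, pb, t), oracle_bas(probs, gt, pb, t),
                   tolerance = 1e-6)
      pw <- random_prob_map(h, wd, C); pfp <- random_prob_map(h, wd, C)
      ps1 <- random_prob_map(h, wd, C); ps2 <- random_prob_map(h, wd, C)
      tau <- runif(1, 0.3, 0.9); lam <- runif(1); mu <- runif(1)
      lw <- loss_weights(tau = tau, lambda_fp = lam, mu = mu)
      expect_equal(unimatch_loss(pw, pfp, ps1, ps2, lw),
                   oracle_unimatch(pw, pfp, ps1, ps2, tau, lam, mu),
                   tolerance = 1e-6)
    }
  })
})

test_that("loss gradients agree with finite differences", {
  withr::with_seed(5, {
    gt <- matrix(sample(0:2, 9, TRUE), 3, 3)
    z <- array(rnorm(27), c(3, 3, 3))
    wts <- c(0.5, 1, 1.5)
    num_grad <- function(f, z, eps = 1e-6) {
      g <- array(0, dim(z))
      for (k in seq_along(z)) {
        z1 <- z; z1[k] <- z1[k] + eps
        z2 <- z; z2[k] <- z2[k] - eps
        g[k] <- (f(z1) - f(z2)) / (2 * eps)
      }
      g
    }
    ana <- weighted_ce(softmax_map(z), gt, wts, grad = TRUE)$grad
    num <- num_grad(function(zz) weighted_ce(softmax_map(zz), gt, wts), z)
    expect_equal(ana, num, tolerance = 1e-5)
    b <- matrix(runif(9), 3, 3)
    ana3 <- bas_loss(softmax_map(z), gt, b, 0.5, grad = TRUE)$grad
    num3 <- num_grad(function(zz) bas_loss(softmax_map(zz), gt, b, 0.5), z)
    expect_equal(ana3, num3, tolerance = 1e-5)
  })
})

test_that("the fused C++ supervised-loss path matches the R reference", {
  withr::with_seed(13, {
    for (rep in 1:4) {
      h8 <- sample(2:4, 1); H <- 8L * h8
      plS <- array(rnorm(h8 * h8 * 3), c(h8, h8, 3))
      pl <- array(rnorm(h8 * h8 * 3), c(h8, h8, 3))
      plB <- array(rnorm(h8 * h8), c(h8, h8, 1))
      gs <- matrix(sample(0:2, H * H, TRUE), H, H)
      gB <- matrix(sample(0:1, H * H, TRUE), H, H)
      cw <- runif(3, 0.3, 2)
      r <- ihcseg:::sup_loss_grad_cpp(plS, pl, plB, gs, gB * 1.0, cw,
                                      0.4, 20, 1, 1, 0.8, 2.0, 1.0)
      up <- function(x) ihcseg:::bilinear_resize_cpp(x, H, H)
      expect_equal(r$l0, weighted_ce(softmax_map(up(plS)), gs, cw),
                   tolerance = 1e-9)
      expect_equal(r$l1, boundary_bce(1 / (1 + exp(-up(plB)[, , 1])), gB, 2.0),
                   tolerance = 1e-9)
      expect_equal(r$l2, weighted_ce(softmax_map(up(pl)), gs, cw),
                   tolerance = 1e-9)
      expect_equal(r$l3, bas_loss(softmax_map(up(pl)), gs,
                                  1 / (1 + exp(-up(plB)[, , 1])), 0.8),
                   tolerance = 1e-9)
    }
  })
})

test_that("class weights temper inverse frequency and normalise to mean 1", {
  tiles <- small_tiles()
  w1 <- class_weights_from(tiles, power = 1)
  w5 <- class_weights_from(tiles)
  expect_equal(mean(w5), 1, tolerance = 1e-9)
  expect_gt(w1[2] / w1[1], w5[2] / w5[1])  # sqrt weights are softer
  expect_true(all(w5 > 0))
})
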