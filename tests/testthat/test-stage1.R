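test_that("make_views shares geometry and varies photometry", {
  img <- small_tiles()[[1]]$image / 255
  v <- make_views(img, crop = 64L, seed = 5, jitter_strength = 0.4)
  # zero jitter: strong views collapse onto the weak view
  v0 <- make_views(img, crop = 64L, seed = 5, jitter_strength = 0)
  expect_identical(v0$xw, v0$xs1)
  expect_identical(v0$xw, v0$xs2)
  # same geometry across views: weak view identical with and without jitter
  expect_identical(v$xw, v0$xw)
  # nonzero jitter with different sub-seeds: the strong views differ
  expect_false(identical(v$xs1, v$xs2))
  expect_false(identical(v$xs1, v$xw))
  # fixed seed: reproducible triple
  v2 <- make_views(img, crop = 64L, seed = 5, jitter_strength = 0.4)
  expect_identical(v, v2)
  expect_error(make_views(array(0.5, c(8, 8, 3)), 64L, 1), "small")
})

test_that("augment_labeled keeps image and mask aligned", {
  tl <- small_tiles()[[2]]
  a <- augment_labeled(tl, crop = 64L, seed = 9, jitter_strength = 0)
  expect_equal(dim(a$image), c(64, 64, 3))
  expect_equal(dim(a$mask), c(64, 64))
  expect_identical(a$boundary, derive_boundary_gt(a$mask, 2L))
  # determinism
  b <- augment_labeled(tl, crop = 64L, seed = 9, jitter_strength = 0)
  expect_identical(a, b)
})

test_that("feature perturbation is channelwise and expectation-preserving", {
  f <- array(runif(4 * 4 * 8, 0.5, 1), c(4, 4, 8))
  expect_identical(feature_perturb(f, 0), f)
  fp <- feature_perturb(f, 0.5, seed = 3)
  per_ch <- vapply(1:8, function(c) {
    r <- fp[, , c] / f[, , c]
    unique(round(r, 10))[1]
  }, 0)
  expect_true(all(per_ch %in% c(0, 2)))  # zeroed or rescaled by 1/(1-p)
  # Monte-Carlo expectation over seeds approximates the identity
  acc <- array(0, dim(f))
  for (s in 1:1000) acc <- acc + feature_perturb(f, 0.5, seed = s)
  expect_lt(max(abs(acc / 1000 - f) / f), 0.15)
  expect_lt(mean(abs(acc / 1000 - f) / f), 0.05)
})

test_that("stage1_step: empty unlabeled batch reduces to the supervised loss", {
  tl <- small_tiles()[[1]]
  lb <- list(list(image = tl$image / 255, mask = tl$mask,
                  boundary = tl$boundary))
  net <- fresh_net(2)
  r <- stage1_step(net, lb, NULL, loss_weights(), stage1_config())
  expect_equal(r$Lu, 0)
  expect_equal(r$total, r$Ls, tolerance = 1e-12)
  expect_true(all(vapply(r[c("l0", "l1", "l2", "l3")], `>=`, TRUE, 0)))
  expect_error(stage1_step(net, list(), NULL), "non-empty")
})

test_that("tau = 1 on soft predictions: consistency term vanishes and the
           update equals the supervised-only update (pseudo-label hygiene)", {
  tiles <- small_tiles()
  lb <- list(list(image = tiles[[1]]$image / 255, mask = tiles[[1]]$mask,
                  boundary = tiles[[1]]$boundary))
  ub <- list(make_views(tiles[[3]]$image / 255, 96L, seed = 7))
  w_gated <- loss_weights(tau = 1)  # untrained nets are nowhere that confident
  net_a <- fresh_net(5); net_b <- fresh_net(5)
  expect_identical(param_hash(net_a), param_hash(net_b))
  ra <- stage1_step(net_a, lb, ub, w_gated, stage1_config(), step_seed = 3)
  rb <- stage1_step(net_b, lb, NULL, w_gated, stage1_config(), step_seed = 3)
  expect_equal(ra$Lu, 0)
  expect_identical(param_hash(net_a), param_hash(net_b))
  expect_equal(ra$Ls, rb$Ls, tolerance = 1e-12)
})

test_that("the loss decreases over 50 steps on a small synthetic set", {
  tiles <- cached("train20", function() synth_dataset(20, seed = 33,
                                                      size_px = 96L))
  net <- fresh_net(1)
  w <- loss_weights(class_weights = class_weights_from(tiles))
  cfg <- stage1_config(crop = 96L, batch_labeled = 1L)
  losses <- numeric(50)
  for (s in 1:50) {
    tl <- tiles[[(s - 1) %% 20 + 1]]
    a <- augment_labeled(tl, 96L, seed = s, jitter_strength = 0.2)
    losses[s] <- stage1_step(net, list(a), NULL, w, cfg,
                             step_seed = s)$total
  }
  expect_lt(mean(losses[41:50]), mean(losses[1:10]))
})

test_that("train_stage1 is resumable bitwise and labeled-only equals
           unlabeled_weight = 0", {
  tiles <- small_tiles()
  dirA <- withr::local_tempdir()
  cfg <- function(out = NULL, ck = 0L)
    stage1_config(epochs = 4L, crop = 96L, batch_labeled = 2L, seed = 11,
                  out_dir = out, checkpoint_every = ck)
  netA <- fresh_net(6)
  resA <- suppressMessages(
    train_stage1(netA, tiles[1:6], cfg = cfg(dirA, 2L)))
  # resume from the epoch-2 checkpoint reproduces the uninterrupted run
  netB <- fresh_net(6)
  resB <- suppressMessages(
    train_stage1(netB, tiles[1:6], cfg = cfg(),
                 resume_from = file.path(dirA, "ck_ep002")))
  expect_identical(param_hash(netA), param_hash(netB))
  expect_equal(resA$history$Ls[3:4], resB$history$Ls, tolerance = 1e-12)
  # unlabeled_weight = 0 run equals the labeled-only run
  netC <- fresh_net(6); netD <- fresh_net(6)
  suppressMessages(train_stage1(netC, tiles[1:6], cfg = cfg()))
  suppressMessages(train_stage1(
    netD, tiles[1:6], unlabeled = tiles[7:8], cfg = cfg(),
    weights = loss_weights(unlabeled_weight = 0,
                           class_weights = class_weights_from(tiles[1:6]))))
  expect_identical(param_hash(netC), param_hash(netD))
  expect_error(train_stage1(fresh_net(1), list()), "non-empty")
})
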