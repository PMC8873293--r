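test_that("network outputs match the input spatial shape", {
  mc <- model_config(base_channels = 2L, depth = 3L)
  h <- build_network(mc, seed = 1L)
  set.seed(2)
  x <- array(rnorm(32^3), c(32, 32, 32))
  fw <- net_forward(h, x)
  expect_equal(dim(fw$seg_probs), c(32, 32, 32, 9))
  expect_equal(dim(fw$boundary_prob), c(32, 32, 32))
  sums <- rowSums(matrix(fw$seg_probs, ncol = 9))
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-6)
  expect_error(net_forward(h, array(0, c(30, 32, 32))), "divisible")
})

test_that("builds are seed-deterministic", {
  mc <- model_config(base_channels = 4L, depth = 2L)
  a <- build_network(mc, seed = 7L)
  b <- build_network(mc, seed = 7L)
  expect_identical(a$params, b$params)
  c2 <- build_network(mc, seed = 8L)
  expect_false(identical(a$params, c2$params))
})

test_that("boundary target is the 6-connected one-voxel shell", {
  m <- array(0, c(9, 9, 9))
  m[3:7, 3:7, 3:7] <- 1
  bt <- boundary_target(m)
  expect_equal(sum(bt), 5^3 - 3^3)     # 98 for a solid 5^3 cube
  expect_true(all(m[bt > 0] == 1))     # shell within the mask
  expect_equal(sum(boundary_target(array(0, c(5, 5, 5)))), 0)
})

test_that("dice loss spans perfect, worst and uniform predictions", {
  t1 <- array(0, c(4, 4, 4, 3))
  t1[, , , 2] <- 1
  expect_lt(dice_loss(t1, t1), 1e-4)
  # binary problem: prediction = 1 - target
  tb <- array(rep(c(1, 0), each = 32), c(4, 4, 4))
  expect_gt(dice_loss(1 - tb, tb), 0.999)
  # uniform 1/9 prediction on a balanced 9-class target: each foreground
  # term is (2*n/9 + e) / (n/9 + n + e) -> dice = 1 - 2/10
  n <- 3 * 3 * 9
  tgt <- array(0, c(3, 3, 9, 9))
  for (c4 in 1:9) tgt[, , c4, c4] <- 1   # 9 voxels per class
  unif <- array(1 / 9, dim(tgt))
  expected <- 1 - (2 * n / 9) / (n / 9 + n / 9 * 1 + 0)  # hand-evaluated
  got <- dice_loss(unif, tgt)
  # hand formula: per class sum p = n/9 = 9, sum t = 9, sum pt = 1
  expect_equal(got, 1 - (2 * 1 + 1e-5) / (9 + 9 + 1e-5), tolerance = 1e-9)
  expect_gte(got, 0)
  expect_lte(got, 1)
  expect_error(dice_loss(unif, tgt[, , , 1:3]), "mismatch")
})

test_that("learning-rate schedule decays by 0.1 every 50 epochs", {
  tc <- train_config()
  expect_equal(lr_at_epoch(tc, 0), 1e-3)
  expect_equal(lr_at_epoch(tc, 49), 1e-3)
  expect_equal(lr_at_epoch(tc, 50), 1e-4)
  expect_equal(lr_at_epoch(tc, 100), 1e-5)
  expect_equal(lr_at_epoch(tc, 149), 1e-5)
  expect_error(lr_at_epoch(tc, 150), "range")
  expect_error(lr_at_epoch(tc, -1), "range")
})

tiny_setup <- function() {
  cfg <- phantom_config(grid_shape = c(24L, 24L, 16L),
                        spacing_mm = c(8, 8, 12),
                        liver_radius_mm = c(60, 48, 50),
                        seed = 5)
  case <- generate_case(cfg)
  list(cases = list(case),
       mc = model_config(base_channels = 2L, depth = 2L),
       pc = preprocess_config(target_spacing_mm = c(8, 8, 12),
                              patch_shape = c(16L, 16L, 16L)))
}

test_that("training is reproducible and handles oversized batches", {
  ts <- tiny_setup()
  tc <- train_config(lr_initial = 0.1, epochs = 2L, batch_size = 8L,
                     patches_per_case = 1L, momentum = 0.9, seed = 2L)
  r1 <- train_segmenter(ts$cases, ts$mc, tc, ts$pc)
  r2 <- train_segmenter(ts$cases, ts$mc, tc, ts$pc)
  expect_identical(r1$history, r2$history)   # bit-identical loss history
  expect_identical(r1$handle$params, r2$handle$params)
  expect_equal(nrow(r1$history), 2)
  expect_true(all(is.finite(r1$history$loss)))
})

test_that("prediction returns native-shape labels consistent with probs", {
  ts <- tiny_setup()
  tc <- train_config(lr_initial = 0.1, epochs = 1L, batch_size = 1L,
                     patches_per_case = 1L, seed = 2L)
  r <- train_segmenter(ts$cases, ts$mc, tc, ts$pc)
  case <- ts$cases[[1]]
  pred <- predict_segments(case$image, r$handle, ts$pc,
                           keep_largest = FALSE)
  expect_equal(dim(pred$labels$data), dim(case$image$data))
  expect_true(all(pred$labels$data %in% 0:8))
  # argmax of fused probabilities matches the labels voxelwise (no
  # padding/resampling in this configuration)
  am <- array(max.col(matrix(pred$probs, ncol = 9), ties.method = "first")
              - 1L, dim(pred$labels$data))
  expect_equal(array(pred$labels$data, dim(am)), am)
})

test_that("the norm-free network is exactly translation-equivariant", {
  # without normalization layers every interior logit depends only on its
  # receptive field, so two crops offset by a pooling-aligned shift must
  # agree exactly (to float precision) away from the borders
  mc <- model_config(base_channels = 2L, depth = 2L, norm = FALSE)
  h <- build_network(mc, seed = 3L)
  set.seed(8)
  big <- array(rnorm(56 * 48 * 48), c(56, 48, 48))
  sh <- 8L
  f1 <- net_forward(h, big[1:48, , ])
  f2 <- net_forward(h, big[(1 + sh):(48 + sh), , ])
  m <- 14L   # margin wider than half the receptive field
  in1 <- f1$seg_logits[(m + sh + 1):(48 - m), (m + 1):(48 - m),
                       (m + 1):(48 - m), ]
  in2 <- f2$seg_logits[(m + 1):(48 - m - sh), (m + 1):(48 - m),
                       (m + 1):(48 - m), ]
  expect_lt(max(abs(in1 - in2)), 1e-4)
})
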