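test_that("U-Net maps batches to per-pixel 5-class probability maps", {
  m <- build_unet(unet_config(seed = 3))
  imgs <- lapply(1:2, function(i) matrix(runif(64 * 128), 64, 128))
  probs <- octez:::cpp_unet_forward(m$ptr, imgs, FALSE)
  expect_length(probs, 2)
  expect_equal(dim(probs[[1]]), c(64, 128, 5))
  sums <- apply(probs[[1]], c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_true(all(probs[[1]] >= 0 & probs[[1]] <= 1))
})

test_that("parameter count is of the expected order (about 1.2 million)", {
  m <- build_unet(unet_config(seed = 1))
  expect_gte(m$n_params, 0.6e6)
  expect_lte(m$n_params, 2.4e6)
})

test_that("invalid configurations are rejected", {
  expect_error(unet_config(loss_lambda = 0), "lambda")
  expect_error(unet_config(loss_lambda = 1.2), "lambda")
  expect_error(unet_config(n_classes = 3), "5 classes")
  expect_error(unet_config(class_weights = c(1, 1)), "class_weights")
  expect_error(octez:::cpp_unet_forward(build_unet(unet_config())$ptr,
                                        list(matrix(0, 30, 64)), FALSE),
               "divisible by 8")
})

test_that("combined loss matches a brute-force per-pixel oracle", {
  # perfect one-hot prediction: both terms vanish
  mask <- matrix(c(0L, 1L, 2L, 3L), 2, 2)
  perfect <- array(0, dim = c(2, 2, 5))
  for (i in 1:2) for (j in 1:2) perfect[i, j, mask[i, j] + 1] <- 1
  expect_equal(combined_loss(mask, perfect, lambda = 1), 0)
  expect_equal(combined_loss(mask, perfect, lambda = 0), 0)

  # hand-computed 2-pixel case, lambda = 0.6, uniform weights
  mask2 <- matrix(c(0L, 1L), 1, 2)
  p <- array(0, dim = c(1, 2, 5))
  p[1, 1, ] <- c(0.7, 0.1, 0.1, 0.05, 0.05)
  p[1, 2, ] <- c(0.2, 0.6, 0.1, 0.05, 0.05)
  ce <- mean(c(-log(0.7), -log(0.6)))
  dice <- ((2 * 0.7 + 1) / (0.9 + 1 + 1) + (2 * 0.6 + 1) / (0.7 + 1 + 1) +
             (0 + 1) / (0.2 + 0 + 1) + (0 + 1) / (0.1 + 0 + 1) +
             (0 + 1) / (0.1 + 0 + 1)) / 5
  expect_equal(combined_loss(mask2, p, lambda = 0.6),
               0.6 * ce + 0.4 * (1 - dice))

  # random 4x4 tensors against the naive loop oracle, several draws
  for (s in 1:5) {
    set.seed(s)
    mask4 <- matrix(sample(0:4, 16, TRUE), 4, 4)
    probs4 <- random_probs(4, 4, 5, seed = s + 10)
    w <- runif(5, 0.2, 2)
    lam <- runif(1, 0.1, 0.9)
    expect_equal(combined_loss(mask4, probs4, lam, w),
                 naive_combined_loss(mask4, probs4, lam, w))
  }
  expect_error(combined_loss(mask2, p * 2, 0.5), "probabilities")
})

test_that("internal training loss agrees with combined_loss on one-hot masks", {
  # forward a tiny net, then compare the C++ loss with the R implementation
  set.seed(9)
  img <- matrix(runif(16 * 16), 16, 16)
  msk <- matrix(sample(0:4, 256, TRUE), 16, 16)
  m <- build_unet(unet_config(base_filters = 2, seed = 4))
  w <- c(1, 2, 0.5, 1, 1.5)
  probs <- octez:::cpp_unet_forward(m$ptr, list(img), TRUE)[[1]]
  expect_equal(octez:::cpp_unet_loss(m$ptr, list(img), list(msk), 0.35, w),
               combined_loss(msk, probs, 0.35, w), tolerance = 1e-4)
})

test_that("analytic gradients match finite differences on a tiny network", {
  set.seed(1)
  img <- matrix(runif(16 * 16), 16, 16)
  msk <- matrix(sample(0:4, 256, TRUE), 16, 16)
  m <- build_unet(unet_config(base_filters = 2, seed = 5))
  w <- c(1, 2, 0.5, 1, 1)
  gr <- octez:::cpp_unet_backward(m$ptr, list(img), list(msk), 0.3, w)
  wt <- unet_weights(m)
  eps <- 1e-3
  for (li in c(1, 7, 12, 15)) {
    g <- gr$conv[[li]]$dW
    idx <- which.max(abs(g))
    w2 <- wt
    w2$conv[[li]]$W[idx] <- w2$conv[[li]]$W[idx] + eps
    set_unet_weights(m, w2)
    lp <- octez:::cpp_unet_loss(m$ptr, list(img), list(msk), 0.3, w)
    w2$conv[[li]]$W[idx] <- w2$conv[[li]]$W[idx] - 2 * eps
    set_unet_weights(m, w2)
    lm <- octez:::cpp_unet_loss(m$ptr, list(img), list(msk), 0.3, w)
    set_unet_weights(m, wt)
    numeric <- (lp - lm) / (2 * eps)
    expect_lt(abs(numeric - g[idx]), 2e-3 + 0.02 * abs(g[idx]))
  }
})

test_that("participant split is stratified, leak-free and seed-stable in counts", {
  roster <- data.frame(
    participant_id = sprintf("p%03d", 1:116),
    cohort = rep(c("control", "patient"), c(94, 22)))
  sp <- split_by_participant(roster, 0.8, seed = 1)
  expect_equal(nrow(sp$train), 93)
  expect_equal(sum(sp$train$cohort == "control"), 75)
  expect_equal(sum(sp$train$cohort == "patient"), 18)
  expect_equal(nrow(sp$validation), 23)
  expect_length(intersect(sp$train$participant_id,
                          sp$validation$participant_id), 0)
  # per-stratum counts identical across seeds; partitions exhaustive
  for (s in 2:6) {
    sps <- split_by_participant(roster, 0.8, seed = s)
    expect_equal(table(sps$train$cohort), table(sp$train$cohort))
    expect_setequal(c(sps$train$participant_id, sps$validation$participant_id),
                    roster$participant_id)
  }
  # round-half-away-from-zero per stratum: 5 controls + 5 patients -> 4 + 4
  r10 <- data.frame(participant_id = paste0("q", 1:10),
                    cohort = rep(c("a", "b"), each = 5))
  sp10 <- split_by_participant(r10, 0.8, seed = 3)
  expect_equal(unname(c(table(sp10$train$cohort))), c(4, 4))
  expect_error(split_by_participant(roster, 1.2), "train_fraction")
})

test_that("augmentation transforms image and mask consistently", {
  out <- generate_bscan(small_spec(), seed = 2)
  img <- out$image$pixels; msk <- out$mask
  # find a seed that flips (flip decision is the first random draw)
  flip_seed <- Filter(function(s) octez:::with_seed(s, runif(1) < 0.5), 1:20)[1]
  aug <- augment_pair(img, msk, seed = flip_seed, max_shift = 0)
  expect_identical(aug$mask, msk[, rev(seq_len(ncol(msk)))])
  noflip_seed <- Filter(function(s) !octez:::with_seed(s, runif(1) < 0.5), 1:20)[1]
  aug2 <- augment_pair(img, msk, seed = noflip_seed, max_shift = 0)
  expect_identical(aug2$mask, msk)  # intensity-only: mask untouched
  expect_false(identical(aug2$image, img))
  # determinism
  expect_identical(augment_pair(img, msk, seed = 11),
                   augment_pair(img, msk, seed = 11))
})

test_that("an untrained network refuses to predict", {
  m <- build_unet(unet_config(base_filters = 2, seed = 1))
  expect_error(predict_classmap(m, matrix(0.5, 16, 16)), "not been trained")
})

test_that("argmax prediction breaks probability ties toward the lower class", {
  probs <- array(0, dim = c(1, 1, 5))
  probs[1, 1, ] <- c(0.5, 0.5, 0, 0, 0)
  oracle <- function(img) probs
  pred <- predict_classmap(oracle, matrix(0.5, 1, 1))
  expect_identical(pred$mask[1, 1], 0L)
})

test_that("an oracle predictor reproduces the ground truth mask exactly", {
  out <- generate_bscan(small_spec(), seed = 3)
  oracle <- function(img) {
    a <- array(0, dim = c(nrow(img), ncol(img), 5))
    for (k in 0:4) a[, , k + 1] <- (out$mask == k) * 1
    a
  }
  pred <- predict_classmap(oracle, out$image)
  expect_identical(pred$mask, out$mask)
  expect_identical(dim(pred$mask), dim(out$image$pixels))
})

test_that("segmentation metrics: Dice/sensitivity per class, NA when absent", {
  a <- matrix(0L, 10, 10); b <- matrix(0L, 10, 10)
  a[1:5, 1:4] <- 1L          # 20 px
  b[1:5, 3:6] <- 1L          # 20 px, 10 shared
  m <- segmentation_metrics(a, b)
  expect_equal(m$dice[m$class == 1], 0.5)
  expect_equal(m$sensitivity[m$class == 1], 0.5)
  expect_equal(m$dice[m$class == 0], 2 * 70 / (80 + 80))
  expect_true(is.na(m$dice[m$class == 3]))     # absent from both
  ident <- segmentation_metrics(b, b)
  expect_true(all(ident$dice[ident$n_truth > 0] == 1))
  a[1, 1] <- 7L
  expect_error(segmentation_metrics(a, b), "invalid label")
})

test_that("training on a phantom batch strictly reduces the combined loss", {
  out <- generate_bscan(small_spec(speckle = 0.15), seed = 5)
  pair <- list(list(image = out$image$pixels, mask = out$mask))
  cfg <- unet_config(epochs = 15, batch_size = 1, seed = 7)
  fit <- train_segmenter(pair, config = cfg)
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  expect_true(all(is.finite(fit$history$loss)))
  expect_error(train_segmenter(list(), config = cfg), "empty")
})
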