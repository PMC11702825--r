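# Shared fixtures: compact phantoms built in code at test time.

# 64x64 noise-free phantom with well-separated bands; odd EZ thickness so
# the raised-cosine peak sits exactly on the band-centre row.
small_spec <- function(width = 64L, height = 64L, speckle = 0,
                       pit_depth = 3L, pit_width = 16L, ...) {
  phantom_spec(image_height = height, image_width = width,
               opl_depth = 26L, opl_thickness = 5L, opl_reflectance = 0.55,
               elm_depth = 36L, elm_thickness = 3L, elm_reflectance = 0.50,
               ez_depth = 41L, ez_thickness = 3L, ez_reflectance = 0.85,
               rpe_depth = 47L, rpe_thickness = 5L, rpe_reflectance = 0.90,
               pit_depth = pit_depth, pit_width = pit_width,
               speckle_level = speckle, ...)
}

# flat-band variant: no pit, so band rows are identical in every column
flat_spec <- function(width = 64L, height = 64L, ...) {
  small_spec(width = width, height = height, pit_depth = 0L, pit_width = 0L, ...)
}

# brute-force EZ local/total variation oracle (naive triple loop)
naive_granularity <- function(px, bands, beta) {
  W <- ncol(px)
  lv <- rep(NA_real_, W)
  for (x in seq_len(W)) {
    u <- bands$upper[1L, x]
    if (is.na(u)) next
    rows <- u:bands$lower[1L, x]
    acc <- 0
    for (k in -beta:beta) {
      xk <- x + k
      if (xk < 1 || xk > W) next
      for (y in rows) acc <- acc + abs(px[y, xk] - px[y, x])
    }
    lv[x] <- acc
  }
  n <- sum(!is.na(lv))
  list(lv = lv, tv_percent = 100 * sum(lv, na.rm = TRUE) / (2 * beta * n))
}

# brute-force per-pixel combined-loss oracle
naive_combined_loss <- function(mask, probs, lambda, w = rep(1, dim(probs)[3])) {
  K <- dim(probs)[3]
  eps <- 1
  dice_sum <- 0
  for (k in seq_len(K)) {
    inter <- 0; psum <- 0; tsum <- 0
    for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
      p <- probs[i, j, k]
      y <- as.numeric(mask[i, j] == k - 1)
      inter <- inter + p * y; psum <- psum + p; tsum <- tsum + y
    }
    dice_sum <- dice_sum + (2 * inter + eps) / (psum + tsum + eps)
  }
  ce_num <- 0; ce_den <- 0
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    y <- mask[i, j] + 1
    ce_num <- ce_num + w[y] * -log(probs[i, j, y])
    ce_den <- ce_den + w[y]
  }
  (1 - lambda) * (1 - dice_sum / K) + lambda * ce_num / ce_den
}

# random probability array normalized over classes
random_probs <- function(H, W, K, seed = 1) {
  set.seed(seed)
  a <- array(runif(H * W * K, 0.01, 1), dim = c(H, W, K))
  tot <- apply(a, c(1, 2), sum)
  for (k in seq_len(K)) a[, , k] <- a[, , k] / tot
  a
}
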