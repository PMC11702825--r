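#' Configuration for the five-class outer-retina U-Net
#'
#' The segmentation model is a modified four-level U-Net: double 5x5
#' convolutional blocks with batch normalization and leaky-ReLU, 16 filters
#' at the first level doubling per level in the encoder, max-pool
#' downsampling, transposed-convolution upsampling mirroring the encoder,
#' skip concatenations, and a final 1x1 convolution onto five classes
#' (approximately 1.2 million parameters at the defaults).
#'
#' The training loss is `(1 - lambda) * Dice + lambda * weighted
#' cross-entropy` (see [combined_loss()]). Class weights default to inverse
#' class frequency computed on the training set, which counteracts the
#' extreme imbalance between the thin EZ/ELM bands and the background.
#'
#' @param base_filters Filters at the first encoder level (default 16).
#' @param n_classes Number of classes (fixed at 5 for this pipeline).
#' @param loss_lambda Mixing weight `lambda` of the combined loss, in (0, 1).
#' @param class_weights Optional numeric vector of `n_classes` nonnegative
#'   weights; `NULL` means inverse class frequency at training time.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Patches per gradient step.
#' @param patch_width,overlap Patch geometry used at inference by
#'   [predict_classmap()] (defaults 128/64).
#' @param seed Seed for weight initialization and shuffling.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(base_filters = 16L, n_classes = 5L,
                        loss_lambda = 0.5, class_weights = NULL,
                        learning_rate = 1e-3, epochs = 20L, batch_size = 8L,
                        patch_width = 128L, overlap = 64L, seed = 1L) {
  if (loss_lambda <= 0 || loss_lambda >= 1)
    stop("loss_lambda must lie strictly in (0, 1)")
  if (n_classes != 5L)
    stop("this pipeline segments exactly 5 classes")
  if (!is.null(class_weights)) {
    if (length(class_weights) != n_classes || any(class_weights < 0))
      stop("class_weights must be ", n_classes, " nonnegative values")
  }
  if (base_filters < 1L) stop("base_filters must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(base_filters = as.integer(base_filters),
                 n_classes = as.integer(n_classes),
                 levels = 4L, kernel_size = 5L,
                 loss_lambda = loss_lambda,
                 class_weights = class_weights,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patch_width = as.integer(patch_width),
                 overlap = as.integer(overlap),
                 seed = as.integer(seed)),
            class = "unet_config")
}

#' Build the U-Net model
#'
#' Instantiates the network with He-initialized weights. The model is an
#' opaque handle plus its configuration; use [train_segmenter()] to fit it
#' and [predict_classmap()] for inference. Input rasters must have height
#' and width divisible by 8 (three pooling stages).
#'
#' @param config A [unet_config()].
#' @return An object of class `unet` with elements `ptr` (native handle),
#'   `config`, `n_params`, `trained`.
#' @export
build_unet <- function(config = unet_config()) {
  if (!inherits(config, "unet_config")) stop("config must be a unet_config")
  ptr <- cpp_unet_create(config$base_filters, config$n_classes, config$seed)
  structure(list(ptr = ptr, config = config,
                 n_params = cpp_unet_nparams(ptr), trained = FALSE),
            class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  cat(sprintf("<unet> 4 levels, %d base filters, %d classes, %s parameters%s\n",
              x$config$base_filters, x$config$n_classes,
              format(x$n_params, big.mark = ","),
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

#' Extract or restore network weights
#'
#' `unet_weights()` returns all parameters (including batch-norm running
#' statistics) as a plain R list that can be serialized with `saveRDS()`;
#' `set_unet_weights()` loads such a list into a model of identical
#' topology. Together they provide checkpointing.
#'
#' @param model A `unet` model.
#' @param weights A list previously returned by `unet_weights()`.
#' @return `unet_weights()`: a list; `set_unet_weights()`: the model,
#'   invisibly.
#' @export
unet_weights <- function(model) {
  stopifnot(inherits(model, "unet"))
  cpp_unet_get_weights(model$ptr)
}

#' @rdname unet_weights
#' @export
set_unet_weights <- function(model, weights) {
  stopifnot(inherits(model, "unet"))
  cpp_unet_set_weights(model$ptr, weights)
  model$trained <- TRUE
  invisible(model)
}

#' Combined Dice / weighted cross-entropy segmentation loss
#'
#' Computes `(1 - lambda) * L_Dice + lambda * L_wCE` between a ground-truth
#' class map and predicted per-pixel class probabilities. The Dice term is
#' the soft (probabilistic) Dice loss averaged over classes, smoothed with
#' `epsilon = 1` in numerator and denominator so classes absent from both
#' prediction and truth contribute no loss. The cross-entropy term is the
#' class-weighted mean of per-pixel negative log-likelihoods (weights
#' normalized by their realized sum).
#'
#' `lambda` may be 0 or 1 here to isolate either term for testing, even
#' though training configurations require `lambda` strictly inside (0, 1).
#'
#' @param mask Integer matrix of true labels in `0:(n_classes - 1)`.
#' @param probs `H x W x n_classes` array of predicted probabilities.
#' @param lambda Mixing weight in `[0, 1]`.
#' @param class_weights Nonnegative weights, one per class (default: equal).
#' @return Nonnegative scalar loss.
#' @export
combined_loss <- function(mask, probs, lambda = 0.5, class_weights = NULL) {
  d <- dim(probs)
  if (length(d) != 3L) stop("probs must be an H x W x n_classes array")
  K <- d[3]
  mask <- as.matrix(mask)
  if (!all(dim(mask) == d[1:2])) stop("mask and probs shapes differ")
  if (anyNA(probs) || min(probs) < -1e-8 || max(probs) > 1 + 1e-8)
    stop("probabilities must lie in [0, 1]")
  if (any(!(mask %in% 0:(K - 1L)))) stop("mask labels outside 0..", K - 1L)
  if (is.null(class_weights)) class_weights <- rep(1, K)
  if (length(class_weights) != K || any(class_weights < 0))
    stop("class_weights must be ", K, " nonnegative values")
  eps <- 1
  dice <- 0
  ce_num <- 0; ce_den <- 0
  for (k in seq_len(K)) {
    y <- (mask == k - 1L)
    p <- probs[, , k]
    dice <- dice + (2 * sum(p[y]) + eps) / (sum(p) + sum(y) + eps)
    if (any(y)) {
      ce_num <- ce_num + class_weights[k] * sum(-log(pmax(p[y], 1e-12)))
      ce_den <- ce_den + class_weights[k] * sum(y)
    }
  }
  dice_loss <- 1 - dice / K
  ce_loss <- if (ce_den > 0) ce_num / ce_den else 0
  (1 - lambda) * dice_loss + lambda * ce_loss
}

#' Stratified participant-level train/validation split
#'
#' Splits a roster of participants into training and validation partitions
#' at the participant level so that all scans of one participant land in
#' exactly one partition (no data leakage). The split is stratified by
#' cohort: each cohort contributes `round(n * train_fraction)` participants
#' (half away from zero) to the training set, so the per-cohort counts are
#' independent of the seed. A roster of 94 controls and 22 patients at 0.8
#' therefore yields 93 training participants (75 + 18) and 23 validation.
#'
#' @param roster Data frame with columns `participant_id` and `cohort`.
#' @param train_fraction Fraction of each cohort assigned to training.
#' @param seed Integer seed deciding which participants land where.
#' @return List with data frames `train` and `validation`.
#' @export
split_by_participant <- function(roster, train_fraction = 0.8, seed = 1L) {
  if (!is.data.frame(roster) || nrow(roster) == 0L)
    stop("roster must be a nonempty data frame")
  if (!all(c("participant_id", "cohort") %in% names(roster)))
    stop("roster needs columns participant_id and cohort")
  if (anyDuplicated(roster$participant_id))
    stop("roster has duplicated participant ids")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly in (0, 1)")
  idx_train <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(roster)), roster$cohort), function(ix) {
      n_tr <- round_half_up(length(ix) * train_fraction)
      sample(ix, n_tr)
    }), use.names = FALSE)
  })
  list(train = roster[sort(idx_train), , drop = FALSE],
       validation = roster[setdiff(seq_len(nrow(roster)), idx_train), , drop = FALSE])
}

#' Paired augmentation of a B-scan and its mask
#'
#' Applies seeded random geometric transforms (horizontal flip, small
#' integer shifts) identically to image and mask — integer shifts make
#' nearest-neighbour label resampling exact — and intensity transforms
#' (gamma, brightness/contrast jitter, additive Gaussian noise) to the
#' image only. Intensities are clipped back to `[0, 1]`.
#'
#' @param image Numeric matrix (or [bscan()]) of intensities.
#' @param mask Integer matrix of labels, same shape.
#' @param seed Integer seed; the same seed reproduces the same transforms.
#' @param max_shift Maximum absolute shift in pixels along each axis.
#' @return List with transformed `image` (matrix) and `mask`.
#' @export
augment_pair <- function(image, mask, seed = 1L, max_shift = 4L) {
  px <- as_pixels(image)
  mask <- assert_classmap(mask)
  if (!all(dim(px) == dim(mask))) stop("image and mask shapes differ")
  with_seed(seed, {
    if (stats::runif(1) < 0.5) {             # horizontal flip
      px <- px[, rev(seq_len(ncol(px))), drop = FALSE]
      mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
    }
    shift_int <- function(m, dr, dc, fill) {
      H <- nrow(m); W <- ncol(m)
      out <- matrix(fill, H, W)
      rs <- intersect(seq_len(H), seq_len(H) + dr)
      cs <- intersect(seq_len(W), seq_len(W) + dc)
      out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
      out
    }
    dr <- sample(-max_shift:max_shift, 1)
    dc <- sample(-max_shift:max_shift, 1)
    px <- shift_int(px, dr, dc, fill = 0)
    mask <- shift_int(mask, dr, dc, fill = 0L)
    gamma <- stats::runif(1, 0.7, 1.4)
    gain <- stats::runif(1, 0.85, 1.15)
    offset <- stats::runif(1, -0.08, 0.08)
    px <- gain * px^gamma + offset
    px <- px + matrix(stats::rnorm(length(px), sd = 0.02), nrow(px), ncol(px))
    px <- pmin(pmax(px, 0), 1)
    list(image = px, mask = mask)
  })
}

# inverse-class-frequency weights over a list of masks, normalized to mean 1
inverse_frequency_weights <- function(masks, n_classes = 5L) {
  counts <- numeric(n_classes)
  for (m in masks) {
    tab <- tabulate(as.vector(m) + 1L, nbins = n_classes)
    counts <- counts + tab
  }
  w <- ifelse(counts > 0, 1 / counts, 0)
  w / mean(w[w > 0])
}

#' Train the U-Net on image/mask pairs
#'
#' Minimizes the combined Dice / weighted cross-entropy loss with Adam over
#' shuffled mini-batches. If the configuration has no explicit class
#' weights, inverse class frequencies are computed on the training masks.
#' Per-epoch mean training loss — and, if a validation set is given, the
#' validation EZ-class Dice — are logged in the returned history.
#'
#' @param train List of training pairs, each `list(image =, mask =)` with
#'   matrix image (values in `[0, 1]`, dimensions divisible by 8) and
#'   integer mask.
#' @param val Optional list of validation pairs in the same format.
#' @param config A [unet_config()].
#' @param model Optionally, an existing [build_unet()] model to continue
#'   training; by default a fresh model is built from `config`.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (trained `unet`) and `history` (data frame
#'   with columns `epoch`, `loss`, `val_dice_ez`).
#' @export
train_segmenter <- function(train, val = NULL, config = unet_config(),
                            model = NULL, verbose = FALSE) {
  if (length(train) == 0L) stop("training set is empty")
  imgs <- lapply(train, function(p) as_pixels(p$image))
  masks <- lapply(train, function(p) assert_classmap(p$mask))
  if (is.null(model)) model <- build_unet(config)
  model$trained <- TRUE   # training starts now; enables in-loop validation
  wts <- config$class_weights
  if (is.null(wts)) wts <- inverse_frequency_weights(masks, config$n_classes)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_dice_ez = numeric())
  n <- length(imgs)
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(config$seed + epoch, sample.int(n))
    losses <- c()
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      loss <- cpp_unet_train_batch(model$ptr, imgs[idx], masks[idx],
                                   config$loss_lambda, wts,
                                   config$learning_rate)
      losses <- c(losses, loss)
    }
    vd <- NA_real_
    if (!is.null(val) && length(val) > 0L) {
      dices <- vapply(val, function(p) {
        pred <- predict_classmap(model, p$image)
        m <- segmentation_metrics(pred$mask, p$mask)
        m$dice[m$class == 1L]
      }, numeric(1))
      vd <- mean(dices, na.rm = TRUE)
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         loss = mean(losses),
                                         val_dice_ez = vd))
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f  val EZ dice %s",
                      epoch, config$epochs, mean(losses),
                      ifelse(is.na(vd), "-", sprintf("%.3f", vd))))
  }
  model$trained <- TRUE
  model$class_weights <- wts
  list(model = model, history = history)
}

#' Segment a B-scan into a class map
#'
#' Runs the patch-wise inference pipeline: [partition_bscan()] with the
#' configuration's patch geometry (narrow images are processed as a single
#' patch), a forward pass per patch, [stitch_probabilities()], and a
#' per-pixel argmax with ties broken toward the lower class index.
#'
#' `model` may also be a function `image_matrix -> H x W x 5 probability
#' array`, which supports oracle predictors in tests.
#'
#' @param model A trained `unet`, or a predictor function.
#' @param image A [bscan()] or numeric matrix.
#' @return List with `mask` (integer class map) and `probs`
#'   (`H x W x n_classes` array).
#' @export
predict_classmap <- function(model, image) {
  px <- as_pixels(image)
  if (is.function(model)) {
    probs <- model(px)
  } else {
    if (!inherits(model, "unet")) stop("model must be a unet or a function")
    if (!isTRUE(model$trained))
      stop("model has not been trained; run train_segmenter() or load weights")
    pw <- min(model$config$patch_width, ncol(px))
    ov <- if (pw == ncol(px)) 0L else model$config$overlap
    ps <- partition_bscan(px, patch_width = pw, overlap = ov)
    patch_probs <- cpp_unet_forward(model$ptr, ps$patches, FALSE)
    probs <- stitch_probabilities(patch_probs, ps)
  }
  mask <- apply(probs, c(1, 2), which.max) - 1L  # which.max ties -> lowest index
  storage.mode(mask) <- "integer"
  list(mask = mask, probs = probs)
}

#' Per-class Dice and sensitivity between two class maps
#'
#' Dice = `2|A n B| / (|A| + |B|)` and sensitivity = `|A n B| / |B|` with
#' `B` the truth, per class. Classes absent from both maps are reported as
#' `NA` (undefined), not 1.
#'
#' @param pred,truth Integer class maps of identical shape with labels 0-4.
#' @return Data frame with columns `class`, `dice`, `sensitivity`,
#'   `n_pred`, `n_truth`.
#' @export
segmentation_metrics <- function(pred, truth) {
  pred <- assert_classmap(pred)
  truth <- assert_classmap(truth)
  if (!all(dim(pred) == dim(truth))) stop("class maps differ in shape")
  out <- lapply(0:4, function(k) {
    a <- pred == k; b <- truth == k
    na <- sum(a); nb <- sum(b); ni <- sum(a & b)
    data.frame(class = k,
               dice = if (na + nb == 0) NA_real_ else 2 * ni / (na + nb),
               sensitivity = if (nb == 0) NA_real_ else ni / nb,
               n_pred = na, n_truth = nb)
  })
  do.call(rbind, out)
}
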