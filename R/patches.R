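#' Partition a B-scan into overlapping full-height patches
#'
#' Splits a B-scan along its width into patches of `patch_width` columns
#' with `overlap` columns shared between neighbours (stride
#' `patch_width - overlap`), the tiling used to feed fixed-width inputs to
#' the segmentation network. Patches span the full image height (for
#' Spectralis-like scans that is the canonical 496 rows). When the width is
#' not an exact multiple of the stride the final patch is filled by
#' reflecting the image about its right edge, so every source column is
#' covered by at least one patch.
#'
#' @param image A [bscan()] or numeric matrix.
#' @param patch_width Patch width in columns (default 128).
#' @param overlap Columns shared between adjacent patches (default 64).
#' @return An object of class `patch_set`: list with `patches` (list of
#'   matrices), `origins` (1-based first source column of each patch),
#'   `source_width`, `patch_width`, `overlap`.
#' @export
partition_bscan <- function(image, patch_width = 128L, overlap = 64L) {
  px <- as_pixels(image)
  W <- ncol(px)
  patch_width <- as.integer(patch_width)
  overlap <- as.integer(overlap)
  if (overlap < 0L || overlap >= patch_width)
    stop("overlap must satisfy 0 <= overlap < patch_width")
  if (W < patch_width)
    stop(sprintf("image width %d is narrower than patch_width %d", W, patch_width))
  stride <- patch_width - overlap
  n <- as.integer(ceiling((W - patch_width) / stride)) + 1L
  origins <- (seq_len(n) - 1L) * stride + 1L
  padded_width <- origins[n] + patch_width - 1L
  if (padded_width > W) {
    n_pad <- padded_width - W
    # reflect about the right edge (do not repeat the edge column)
    pad_cols <- px[, W - seq_len(n_pad), drop = FALSE]
    px <- cbind(px, pad_cols)
  }
  patches <- lapply(origins, function(o) px[, o:(o + patch_width - 1L), drop = FALSE])
  structure(list(patches = patches, origins = origins,
                 source_width = W, patch_width = patch_width,
                 overlap = overlap),
            class = "patch_set")
}

#' Stitch per-patch class probabilities back to scan geometry
#'
#' Inverse of [partition_bscan()] for network outputs: overlapping columns
#' are combined by the arithmetic mean of the class probabilities and then
#' renormalized to sum to one per pixel; columns produced only by reflect
#' padding are dropped. Averaging probabilities is order-independent and
#' idempotent where patches agree.
#'
#' @param patch_probs List of `H x patch_width x n_classes` arrays, one per
#'   patch, in [partition_bscan()] order.
#' @param patchset The `patch_set` the patches came from.
#' @return `H x source_width x n_classes` array of probabilities.
#' @export
stitch_probabilities <- function(patch_probs, patchset) {
  if (!inherits(patchset, "patch_set")) stop("patchset must be a patch_set")
  if (length(patch_probs) != length(patchset$patches))
    stop("expected one probability block per patch")
  d <- dim(patch_probs[[1]])
  if (length(d) != 3L || d[2] != patchset$patch_width)
    stop("probability blocks must be H x patch_width x n_classes arrays")
  H <- d[1]; K <- d[3]
  padded_width <- patchset$origins[length(patchset$origins)] +
    patchset$patch_width - 1L
  acc <- array(0, dim = c(H, padded_width, K))
  cnt <- matrix(0, H, padded_width)
  for (i in seq_along(patch_probs)) {
    p <- patch_probs[[i]]
    if (!all(dim(p) == d)) stop("probability block ", i, " has mismatched shape")
    cols <- patchset$origins[i]:(patchset$origins[i] + patchset$patch_width - 1L)
    acc[, cols, ] <- acc[, cols, ] + p
    cnt[, cols] <- cnt[, cols] + 1
  }
  for (k in seq_len(K)) acc[, , k] <- acc[, , k] / cnt
  out <- acc[, seq_len(patchset$source_width), , drop = FALSE]
  tot <- apply(out, c(1, 2), sum)
  for (k in seq_len(K)) out[, , k] <- out[, , k] / tot
  out
}
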