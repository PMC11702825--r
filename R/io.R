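#' Read and write B-scan rasters with JSON metadata sidecars
#'
#' B-scans travel as grayscale PNG or TIFF rasters with intensities
#' rescaled to `[0, 1]` from the source bit depth, plus a JSON sidecar
#' (`<image>.json`) carrying the acquisition metadata
#' (`axial_um_per_px`, `lateral_um_per_px`, `fovea_column`, `laterality`,
#' `bscan_index`, `bscan_spacing_um`). A missing sidecar is tolerated:
#' Spectralis-like defaults (3.5 um axial, 11 um lateral, central fovea)
#' are applied with a warning. Multi-channel rasters are rejected.
#'
#' @param path Raster path (`.png`, `.tif`, `.tiff`).
#' @param image A [bscan()] to write.
#' @param bits Bit depth for TIFF output (8 or 16; PNG is written 8-bit).
#' @return `read_bscan()`: a [bscan()]. `write_bscan()`: `path`, invisibly.
#' @export
read_bscan <- function(path) {
  px <- read_gray_raster(path)
  meta_path <- sidecar_path(path)
  meta <- list()
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    warning("no metadata sidecar at ", meta_path,
            "; applying Spectralis-like defaults (3.5/11 um per px)")
  }
  bscan(px,
        axial_um_per_px = meta$axial_um_per_px %||% 3.5,
        lateral_um_per_px = meta$lateral_um_per_px %||% 11,
        fovea_column = meta$fovea_column %||% as.integer(round(ncol(px) / 2)),
        laterality = meta$laterality %||% "right",
        bscan_index = meta$bscan_index %||% NA_integer_,
        bscan_spacing_um = meta$bscan_spacing_um %||% NA_real_)
}

#' @rdname read_bscan
#' @export
write_bscan <- function(image, path, bits = 16L) {
  stopifnot(inherits(image, "bscan"))
  write_gray_raster(image$pixels, path, bits = bits)
  meta <- list(axial_um_per_px = image$axial_um_per_px,
               lateral_um_per_px = image$lateral_um_per_px,
               fovea_column = image$fovea_column,
               laterality = image$laterality,
               bscan_index = image$bscan_index,
               bscan_spacing_um = image$bscan_spacing_um)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read and write class-map label rasters
#'
#' Class maps are stored as 8-bit grayscale rasters whose pixel values are
#' the labels 0-4 directly; the round trip is lossless. Any other value in
#' the raster is an error naming the offending label.
#'
#' @param path Raster path (`.png`, `.tif`, `.tiff`).
#' @param mask Integer class map to write.
#' @return `read_classmap()`: integer matrix. `write_classmap()`: `path`,
#'   invisibly.
#' @export
read_classmap <- function(path) {
  px <- read_gray_raster(path)
  labels <- round(px * 255)
  if (max(abs(px * 255 - labels)) > 1e-6)
    stop("raster does not hold integer labels")
  assert_classmap(labels)
}

#' @rdname read_classmap
#' @export
write_classmap <- function(mask, path) {
  mask <- assert_classmap(mask)
  write_gray_raster(mask / 255, path, bits = 8L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

read_gray_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               png = png::readPNG(path),
               tif = ,
               tiff = tiff::readTIFF(path),
               stop("unsupported raster format: .", ext))
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 1L) px <- px[, , 1]
    else stop("multi-channel raster; grayscale expected: ", path)
  }
  px
}

write_gray_raster <- function(px, path, bits = 8L) {
  px <- pmin(pmax(as.matrix(px), 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(px, path),
         tif = ,
         tiff = tiff::writeTIFF(px, path, bits.per.sample = as.integer(bits)),
         stop("unsupported raster format: .", ext))
  invisible(path)
}
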