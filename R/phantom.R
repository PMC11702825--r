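#' Specification of a synthetic layered-retina B-scan phantom
#'
#' Describes the geometry, reflectance and degradation of a synthetic
#' Spectralis-like B-scan with four hyperreflective outer-retinal bands
#' (OPL zone, ELM zone, EZ, IZ+RPE+BM) over a dark background. The phantom
#' is the ground-truth substrate for every downstream stage: its class map
#' is exact by construction, so segmentation, biomarker and en-face code can
#' be tested without any acquired data.
#'
#' Depths are 1-based row indices of the top of each band (row 1 is the
#' innermost, vitreous-side row); thicknesses are in pixels. Reflectances
#' are the peak in-band intensities in `[0, 1]`; within a band the intensity
#' follows a raised-cosine profile whose sampled maximum equals the stated
#' reflectance, so intensity peaks are well defined and interior.
#'
#' The foveal pit is a smooth Gaussian depression: every band is shifted
#' posteriorly (larger row index) near `fovea_column` by up to `pit_depth`
#' pixels with FWHM `pit_width`; top and bottom of each band shift together,
#' so per-column band thickness is preserved exactly.
#'
#' Disease-style EZ loss is controlled by two knobs: `ez_extent_mm` (lateral
#' half-width of surviving EZ around the fovea; `Inf` keeps the full scan)
#' and `ez_attenuation` (multiplies the EZ reflectance).
#'
#' @param image_height,image_width Raster size in pixels.
#' @param axial_um_per_px Axial sampling, micrometres per pixel (Spectralis
#'   manual value is approximately 3.5).
#' @param lateral_um_per_px Lateral sampling, micrometres per pixel; the
#'   default 11 makes one en-face pixel approximately 121 square micrometres.
#' @param opl_depth,opl_thickness,opl_reflectance OPL-zone band (class 2).
#' @param elm_depth,elm_thickness,elm_reflectance ELM-zone band (class 3).
#' @param ez_depth,ez_thickness,ez_reflectance EZ band (class 1).
#' @param rpe_depth,rpe_thickness,rpe_reflectance IZ+RPE+BM band (class 4).
#' @param background_reflectance Intensity outside all bands.
#' @param fovea_column Column index of the foveal centre (default: centre).
#' @param pit_depth,pit_width Foveal pit depth (pixels) and FWHM (pixels).
#' @param ez_extent_mm Lateral half-width of surviving EZ in millimetres.
#' @param ez_attenuation Multiplicative factor in `[0, 1]` on EZ reflectance.
#' @param speckle_level Multiplicative speckle scale (0 = noise free).
#' @param laterality `"left"` or `"right"` eye.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_bscan()], [generate_volume()], [apply_speckle()]
#' @export
phantom_spec <- function(image_height = 496L, image_width = 768L,
                         axial_um_per_px = 3.5, lateral_um_per_px = 11,
                         opl_depth = 300L, opl_thickness = 11L, opl_reflectance = 0.55,
                         elm_depth = 352L, elm_thickness = 3L, elm_reflectance = 0.50,
                         ez_depth = 362L, ez_thickness = 5L, ez_reflectance = 0.85,
                         rpe_depth = 374L, rpe_thickness = 9L, rpe_reflectance = 0.90,
                         background_reflectance = 0.05,
                         fovea_column = NULL,
                         pit_depth = 12L, pit_width = 80L,
                         ez_extent_mm = Inf, ez_attenuation = 1,
                         speckle_level = 0,
                         laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  if (is.null(fovea_column)) fovea_column <- as.integer(round(image_width / 2))
  spec <- list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    axial_um_per_px = axial_um_per_px,
    lateral_um_per_px = lateral_um_per_px,
    bands = data.frame(
      name = c("opl", "elm", "ez", "rpe"),
      class = c(2L, 3L, 1L, 4L),
      depth = as.integer(c(opl_depth, elm_depth, ez_depth, rpe_depth)),
      thickness = as.integer(c(opl_thickness, elm_thickness,
                               ez_thickness, rpe_thickness)),
      reflectance = c(opl_reflectance, elm_reflectance,
                      ez_reflectance, rpe_reflectance),
      stringsAsFactors = FALSE
    ),
    background_reflectance = background_reflectance,
    fovea_column = as.integer(fovea_column),
    pit_depth = as.integer(pit_depth),
    pit_width = as.integer(pit_width),
    ez_extent_mm = ez_extent_mm,
    ez_attenuation = ez_attenuation,
    speckle_level = speckle_level,
    laterality = laterality
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  b <- spec$bands
  if (spec$image_height < 1L || spec$image_width < 1L)
    stop("phantom dimensions must be positive")
  if (any(b$thickness < 1L))
    stop("band thicknesses must be >= 1 pixel")
  if (any(b$reflectance < 0 | b$reflectance > 1) ||
      spec$background_reflectance < 0 || spec$background_reflectance > 1)
    stop("reflectances must lie in [0, 1]")
  if (spec$ez_attenuation < 0 || spec$ez_attenuation > 1)
    stop("ez_attenuation must lie in [0, 1]")
  if (spec$speckle_level < 0) stop("speckle_level must be >= 0")
  if (spec$fovea_column < 1L || spec$fovea_column > spec$image_width)
    stop("fovea_column must lie within the image width")
  ord <- order(b$depth)
  tops <- b$depth[ord]
  bottoms <- b$depth[ord] + b$thickness[ord] - 1L
  if (!identical(b$name[ord], c("opl", "elm", "ez", "rpe")))
    stop("bands must be ordered OPL, ELM, EZ, RPE in depth")
  if (any(tops[-1] <= bottoms[-length(bottoms)]))
    stop("phantom bands overlap; adjust depths/thicknesses")
  if (tops[1] < 1L ||
      bottoms[length(bottoms)] + spec$pit_depth > spec$image_height)
    stop("phantom bands (including the foveal pit shift) exceed the image height")
  invisible(spec)
}

#' Construct a B-scan container
#'
#' Bundles a `[0, 1]` intensity raster (row 1 = innermost/vitreous side,
#' columns = A-scans) with its acquisition metadata.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`.
#' @param axial_um_per_px,lateral_um_per_px Sampling in micrometres per pixel.
#' @param fovea_column Column index of the foveal centre.
#' @param laterality `"left"` or `"right"`.
#' @param bscan_index,bscan_spacing_um Position within a volume (optional).
#' @return An object of class `bscan`.
#' @export
bscan <- function(pixels, axial_um_per_px = 3.5, lateral_um_per_px = 11,
                  fovea_column = as.integer(round(ncol(pixels) / 2)),
                  laterality = c("right", "left"),
                  bscan_index = NA_integer_, bscan_spacing_um = NA_real_) {
  laterality <- match.arg(laterality)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("empty B-scan raster")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("B-scan intensities must lie in [0, 1]")
  if (fovea_column < 1L || fovea_column > ncol(pixels))
    stop("fovea_column outside the scan width")
  structure(list(pixels = pixels,
                 axial_um_per_px = axial_um_per_px,
                 lateral_um_per_px = lateral_um_per_px,
                 fovea_column = as.integer(fovea_column),
                 laterality = laterality,
                 bscan_index = bscan_index,
                 bscan_spacing_um = bscan_spacing_um),
            class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan> %d x %d px, %.2f um/px axial, %.2f um/px lateral, fovea col %d (%s eye)\n",
              nrow(x$pixels), ncol(x$pixels), x$axial_um_per_px,
              x$lateral_um_per_px, x$fovea_column, x$laterality))
  invisible(x)
}

# extract the pixel matrix whether given a bscan or a plain matrix
as_pixels <- function(image) {
  if (inherits(image, "bscan")) image$pixels else as.matrix(image)
}

# per-column posterior shift of all bands from the Gaussian foveal pit
pit_shift <- function(spec) {
  x <- seq_len(spec$image_width)
  if (spec$pit_depth == 0L || spec$pit_width == 0L)
    return(integer(spec$image_width))
  sigma <- spec$pit_width / (2 * sqrt(2 * log(2)))   # FWHM -> sigma
  as.integer(round(spec$pit_depth *
                     exp(-((x - spec$fovea_column)^2) / (2 * sigma^2))))
}

# raised-cosine band profile, renormalized so the sampled maximum is 1
band_profile <- function(n) {
  w <- sin(pi * (seq_len(n) - 0.5) / n)^2
  w / max(w)
}

#' Generate a synthetic B-scan and its ground-truth class map
#'
#' Renders the phantom described by a [phantom_spec()]: four raised-cosine
#' reflectance bands over a dark background, a Gaussian foveal pit, optional
#' disease-style EZ truncation/attenuation, and optional multiplicative
#' speckle. The returned class map uses the fixed label semantics
#' 0 background, 1 EZ, 2 OPL zone, 3 ELM zone, 4 IZ+RPE+BM.
#'
#' Identical `(spec, seed)` pairs yield bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for the speckle noise.
#' @return A list with elements `image` (a [bscan()]) and `mask`
#'   (integer matrix of class labels, same shape).
#' @export
generate_bscan <- function(spec, seed = 1L) {
  validate_phantom_spec(spec)
  H <- spec$image_height; W <- spec$image_width
  img <- matrix(spec$background_reflectance, H, W)
  mask <- matrix(0L, H, W)
  shift <- pit_shift(spec)
  ez_half_px <- if (is.finite(spec$ez_extent_mm))
    spec$ez_extent_mm * 1000 / spec$lateral_um_per_px else Inf
  for (k in seq_len(nrow(spec$bands))) {
    bnd <- spec$bands[k, ]
    refl <- bnd$reflectance
    is_ez <- bnd$name == "ez"
    if (is_ez) refl <- refl * spec$ez_attenuation
    prof <- band_profile(bnd$thickness) * refl
    for (x in seq_len(W)) {
      if (is_ez && (spec$ez_extent_mm <= 0 ||
                    abs(x - spec$fovea_column) > ez_half_px)) next
      rows <- (bnd$depth + shift[x]):(bnd$depth + shift[x] + bnd$thickness - 1L)
      img[rows, x] <- prof
      mask[rows, x] <- bnd$class
    }
  }
  img <- pmin(pmax(img, 0), 1)
  scan <- bscan(img,
                axial_um_per_px = spec$axial_um_per_px,
                lateral_um_per_px = spec$lateral_um_per_px,
                fovea_column = spec$fovea_column,
                laterality = spec$laterality)
  if (spec$speckle_level > 0)
    scan <- apply_speckle(scan, spec$speckle_level, seed = seed)
  list(image = scan, mask = mask)
}

#' Generate a volume of B-scans with an elliptical EZ footprint
#'
#' Stacks `n_bscans` phantoms across the slow-scan axis. The surviving EZ
#' footprint is an ellipse with semi-axes `footprint_mm` (lateral, slow-scan)
#' centred on the fovea: each B-scan's EZ extent is the ellipse
#' cross-section at that scan's position. B-scans are spaced evenly over
#' `span_mm` and carry `bscan_index`/`bscan_spacing_um` metadata.
#'
#' @param spec A [phantom_spec()]; its `ez_extent_mm` is overridden per scan.
#' @param n_bscans Number of B-scans (>= 2).
#' @param footprint_mm Length-2 numeric: ellipse semi-axes in millimetres
#'   (lateral, slow-scan). Use `c(0, 0)` for an EZ-free volume.
#' @param span_mm Slow-scan extent covered by the volume, in millimetres.
#' @param seed Integer seed (per-scan speckle is derived from it).
#' @return A list with `images` (list of [bscan()]), `masks` (list of
#'   integer matrices), and `positions_mm` (slow-scan coordinates,
#'   fovea at 0).
#' @export
generate_volume <- function(spec, n_bscans, footprint_mm, span_mm = 6,
                            seed = 1L) {
  if (n_bscans < 2L) stop("a volume needs at least 2 B-scans")
  if (length(footprint_mm) == 1L) footprint_mm <- rep(footprint_mm, 2)
  if (any(footprint_mm < 0)) stop("footprint semi-axes must be non-negative")
  if (span_mm <= 0) stop("span_mm must be positive")
  pos <- seq(-span_mm / 2, span_mm / 2, length.out = n_bscans)
  spacing_um <- (span_mm / (n_bscans - 1)) * 1000
  rx <- footprint_mm[1]; ry <- footprint_mm[2]
  images <- vector("list", n_bscans)
  masks <- vector("list", n_bscans)
  for (j in seq_len(n_bscans)) {
    half <- if (ry > 0 && abs(pos[j]) <= ry)
      rx * sqrt(max(0, 1 - (pos[j] / ry)^2)) else 0
    sj <- spec
    sj$ez_extent_mm <- half
    out <- generate_bscan(sj, seed = seed + j)
    out$image$bscan_index <- j
    out$image$bscan_spacing_um <- spacing_um
    images[[j]] <- out$image
    masks[[j]] <- out$mask
  }
  list(images = images, masks = masks, positions_mm = pos)
}

#' Sample a population of randomized phantom specifications
#'
#' Draws phantom specs with anatomy-like variability — jittered band
#' depths, foveal position and pit size, and (optionally) disease-style EZ
#' attenuation and shortening — for building training/validation
#' populations for the segmentation network. The geometry is the default
#' 496-row anatomy scaled to the requested raster height.
#'
#' @param n Number of specs.
#' @param seed Integer seed.
#' @param image_height,image_width Raster size (divisible by 8 for the
#'   network).
#' @param speckle_level Speckle scale applied to every phantom.
#' @param diseased Fraction of specs given EZ attenuation/shortening.
#' @return List of [phantom_spec()] objects.
#' @export
sample_phantom_specs <- function(n, seed = 1L,
                                 image_height = 64L, image_width = 64L,
                                 speckle_level = 0.2, diseased = 0.3) {
  # compact anatomy anchored at a 64-row raster, scaled to the request
  t <- image_height / 64
  d <- function(v) as.integer(round(v * t))
  with_seed(seed, lapply(seq_len(n), function(i) {
    shift <- sample(-3:3, 1)
    dis <- stats::runif(1) < diseased
    scan_half_mm <- image_width / 2 * 11 / 1000
    phantom_spec(
      image_height = image_height, image_width = image_width,
      opl_depth = d(26) + shift, opl_thickness = max(3L, d(5)),
      elm_depth = d(36) + shift, elm_thickness = max(1L, d(2)),
      ez_depth = d(41) + shift, ez_thickness = max(2L, d(3)),
      rpe_depth = d(47) + shift, rpe_thickness = max(2L, d(5)),
      pit_depth = sample(2:4, 1),
      pit_width = max(8L, as.integer(round(stats::runif(1, 10, 16) * t))),
      fovea_column = as.integer(round(image_width * stats::runif(1, 0.35, 0.65))),
      ez_extent_mm = if (dis) stats::runif(1, 0.1, 0.8 * scan_half_mm) else Inf,
      ez_attenuation = if (dis) stats::runif(1, 0.5, 0.9) else 1,
      speckle_level = speckle_level,
      laterality = sample(c("left", "right"), 1)
    )
  }))
}

#' Apply unit-mean multiplicative speckle noise
#'
#' Multiplies the raster by i.i.d. gamma noise with unit mean and standard
#' deviation `level` (shape `1/level^2`, scale `level^2`), the standard
#' surrogate for OCT speckle; unit mean preserves band reflectances on
#' average. The result is clipped to `[0, 1]`. `level = 0` returns the
#' input unchanged.
#'
#' @param image A [bscan()] or numeric matrix.
#' @param level Noise scale (standard deviation of the multiplier), >= 0.
#' @param seed Integer seed.
#' @return Same type as `image`.
#' @export
apply_speckle <- function(image, level, seed = 1L) {
  if (level < 0) stop("speckle level must be >= 0")
  if (level == 0) return(image)
  px <- as_pixels(image)
  noise <- with_seed(seed, {
    shape <- 1 / level^2
    matrix(stats::rgamma(length(px), shape = shape, scale = level^2),
           nrow(px), ncol(px))
  })
  out <- pmin(pmax(px * noise, 0), 1)
  if (inherits(image, "bscan")) {
    image$pixels <- out
    image
  } else {
    out
  }
}
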