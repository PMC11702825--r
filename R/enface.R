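#' Per-B-scan EZ lateral limits
#'
#' Finds the leftmost and rightmost column carrying the EZ label (class 1)
#' in each B-scan mask of a volume. The per-scan EZ extent is the outer
#' envelope between those two limits, so interior EZ gaps within one
#' B-scan are bridged by convention. Scans without EZ are flagged absent
#' and excluded from interpolation anchoring.
#'
#' @param masks List of integer class maps, ordered along the slow axis.
#' @param positions_mm Slow-axis coordinate of each B-scan in millimetres.
#' @return Data frame of class `ez_limits`: `bscan`, `y_mm`, `left`,
#'   `right` (`NA` where absent).
#' @export
ez_limits <- function(masks, positions_mm) {
  if (length(masks) != length(positions_mm))
    stop("one position per mask is required")
  rows <- lapply(seq_along(masks), function(j) {
    m <- assert_classmap(masks[[j]])
    cols <- which(colSums(m == 1L) > 0)
    if (length(cols) == 0L)
      data.frame(bscan = j, y_mm = positions_mm[j],
                 left = NA_real_, right = NA_real_)
    else
      data.frame(bscan = j, y_mm = positions_mm[j],
                 left = min(cols), right = max(cols))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ez_limits", "data.frame")
  out
}

#' Interpolate EZ limits into an en-face presence map
#'
#' Builds a binary en-face footprint of the EZ from per-B-scan limits.
#' The left and right limits are linearly interpolated (in column units
#' against slow-axis position) across runs of EZ-absent B-scans bounded on
#' both sides by EZ-bearing scans, filling gaps between B-scans; absent
#' runs at the volume edge are not extrapolated. The map is resampled on a
#' regular slow-axis grid of pitch `row_pitch_um` (defaulting to the
#' lateral pixel pitch, giving square en-face pixels of about
#' `lateral_um_per_px^2` square micrometres — 121 at the Spectralis
#' default).
#'
#' @param limits An [ez_limits()] data frame.
#' @param n_columns Width of the en-face grid (B-scan width in columns).
#' @param lateral_um_per_px Lateral (fast-axis) pixel pitch in micrometres.
#' @param row_pitch_um Slow-axis pitch of the en-face grid (default:
#'   `lateral_um_per_px`).
#' @return Object of class `enface_map`: list with `presence` (logical
#'   matrix, rows = slow-axis samples), `y_mm` (row coordinates),
#'   `lateral_um_per_px`, `row_pitch_um`, `pixel_area_um2`.
#' @export
interpolate_limits <- function(limits, n_columns, lateral_um_per_px = 11,
                               row_pitch_um = lateral_um_per_px) {
  if (!inherits(limits, "ez_limits")) stop("limits must be an ez_limits")
  present <- !is.na(limits$left)
  y <- seq(min(limits$y_mm), max(limits$y_mm), by = row_pitch_um / 1000)
  grid <- matrix(FALSE, length(y), n_columns)
  if (sum(present) == 0L) {
    # nothing to anchor on
  } else if (sum(present) == 1L) {
    warning("only one EZ-bearing B-scan: no interpolation possible, ",
            "footprint restricted to that scan")
    j <- which(present)
    i <- which.min(abs(y - limits$y_mm[j]))
    grid[i, limits$left[j]:limits$right[j]] <- TRUE
  } else {
    ya <- limits$y_mm[present]
    la <- limits$left[present]
    ra <- limits$right[present]
    li <- stats::approx(ya, la, xout = y, rule = 1)$y
    ri <- stats::approx(ya, ra, xout = y, rule = 1)$y
    for (i in seq_along(y)) {
      if (is.na(li[i])) next
      c0 <- max(1L, as.integer(round(li[i])))
      c1 <- min(n_columns, as.integer(round(ri[i])))
      if (c1 >= c0) grid[i, c0:c1] <- TRUE
    }
  }
  structure(list(presence = grid, y_mm = y,
                 lateral_um_per_px = lateral_um_per_px,
                 row_pitch_um = row_pitch_um,
                 pixel_area_um2 = lateral_um_per_px * row_pitch_um),
            class = "enface_map")
}

#' ETDRS region of interest on the en-face grid
#'
#' Builds the 6-mm region-of-interest mask centred on the fovea, either as
#' the 6 x 6-mm square bounding the ETDRS circle (default) or as the 6-mm
#' disc, plus the standard grid sectors (central 1-mm disc, inner 1-3-mm
#' ring, outer 3-6-mm ring, four quadrants with nasal/temporal resolved by
#' laterality).
#'
#' @param map An [interpolate_limits()] map (supplies the grid geometry).
#' @param fovea_column Fast-axis pixel of the foveal centre.
#' @param fovea_y_mm Slow-axis coordinate of the foveal centre (default 0).
#' @param diameter_mm ROI diameter (default 6).
#' @param shape `"square"` (default) or `"disc"`.
#' @param laterality `"left"` or `"right"` (orients nasal quadrants).
#' @return List with `roi` (logical matrix), `sector` (character matrix:
#'   `"center"`, `"inner_<quad>"`, `"outer_<quad>"`, or `NA` outside),
#'   and the geometry parameters.
#' @export
etdrs_roi <- function(map, fovea_column, fovea_y_mm = 0,
                      diameter_mm = 6, shape = c("square", "disc"),
                      laterality = c("right", "left")) {
  shape <- match.arg(shape)
  laterality <- match.arg(laterality)
  if (diameter_mm < 0) stop("diameter_mm must be >= 0")
  ny <- nrow(map$presence); nx <- ncol(map$presence)
  x_mm <- (seq_len(nx) - fovea_column) * map$lateral_um_per_px / 1000
  y_mm <- map$y_mm - fovea_y_mm
  X <- matrix(x_mm, ny, nx, byrow = TRUE)
  Y <- matrix(y_mm, ny, nx)
  r <- diameter_mm / 2
  roi <- if (shape == "disc") (X^2 + Y^2) <= r^2
  else (abs(X) <= r & abs(Y) <= r)
  if (!any(abs(x_mm) <= r) || !any(abs(y_mm) <= r))
    warning("ETDRS ROI extends outside the en-face grid; mask clipped")
  R <- sqrt(X^2 + Y^2)
  quad <- ifelse(abs(X) >= abs(Y),
                 ifelse(X >= 0, "right", "left"),
                 ifelse(Y <= 0, "superior", "inferior"))
  horiz <- c(right = if (laterality == "left") "nasal" else "temporal",
             left = if (laterality == "left") "temporal" else "nasal")
  quad[quad == "right"] <- horiz["right"]
  quad[quad == "left"] <- horiz["left"]
  sector <- matrix(NA_character_, ny, nx)
  sector[R <= 0.5] <- "center"
  sel <- R > 0.5 & R <= 1.5
  sector[sel] <- paste0("inner_", quad[sel])
  sel <- R > 1.5 & R <= 3
  sector[sel] <- paste0("outer_", quad[sel])
  list(roi = roi, sector = sector, shape = shape,
       diameter_mm = diameter_mm, fovea_column = fovea_column,
       fovea_y_mm = fovea_y_mm, laterality = laterality)
}

#' EZ area in square millimetres
#'
#' Tallies EZ-present en-face pixels (optionally restricted to a region of
#' interest) and scales by the pixel area — approximately 121 square
#' micrometres per pixel at the Spectralis default pitch.
#'
#' @param map An [interpolate_limits()] map.
#' @param roi Optional logical matrix from [etdrs_roi()] (or any mask of
#'   the same shape); `NULL` counts the whole grid.
#' @return Area in square millimetres.
#' @export
ez_area <- function(map, roi = NULL) {
  presence <- map$presence
  if (!is.null(roi)) {
    if (is.list(roi)) roi <- roi$roi
    if (!all(dim(roi) == dim(presence))) stop("ROI and map shapes differ")
    presence <- presence & roi
  }
  sum(presence) * map$pixel_area_um2 * 1e-6
}

#' EZ width as a percentage of the region of interest
#'
#' For one B-scan, the EZ extent between its lateral limits is intersected
#' with the ROI span centred on the fovea and expressed as a percentage of
#' the ROI diameter (6 mm by default), clipped to `[0, 100]`. Scans
#' without EZ yield 0.
#'
#' @param left,right EZ limit columns (from [ez_limits()]); `NA` = absent.
#' @param fovea_column Foveal centre column.
#' @param lateral_um_per_px Lateral pixel pitch in micrometres.
#' @param roi_diameter_mm ROI diameter (default 6).
#' @return Percentage in `[0, 100]`.
#' @export
ez_width_percent <- function(left, right, fovea_column,
                             lateral_um_per_px = 11, roi_diameter_mm = 6) {
  if (is.na(left) || is.na(right)) return(0)
  half <- roi_diameter_mm / 2
  lo_mm <- max((left - fovea_column) * lateral_um_per_px / 1000, -half)
  hi_mm <- min((right - fovea_column) * lateral_um_per_px / 1000, half)
  width_mm <- max(hi_mm - lo_mm, 0)
  min(100, max(0, 100 * width_mm / roi_diameter_mm))
}

#' Full en-face EZ report for a volume of masks
#'
#' Convenience wrapper: extracts per-B-scan limits, interpolates the
#' en-face footprint, applies the ETDRS ROI, and reports EZ area (mm^2)
#' plus per-B-scan EZ width (%).
#'
#' @param masks List of class maps (slow-axis order).
#' @param positions_mm Slow-axis positions of the B-scans.
#' @param fovea_column Foveal centre column.
#' @param lateral_um_per_px Lateral pixel pitch.
#' @param roi_shape `"square"` or `"disc"`.
#' @param laterality Eye laterality.
#' @return List with `area_mm2`, `width_percent` (per B-scan), `map`,
#'   `roi`, `limits`.
#' @export
enface_report <- function(masks, positions_mm, fovea_column,
                          lateral_um_per_px = 11,
                          roi_shape = c("square", "disc"),
                          laterality = c("right", "left")) {
  roi_shape <- match.arg(roi_shape)
  laterality <- match.arg(laterality)
  lim <- ez_limits(masks, positions_mm)
  map <- interpolate_limits(lim, n_columns = ncol(masks[[1]]),
                            lateral_um_per_px = lateral_um_per_px)
  roi <- etdrs_roi(map, fovea_column, fovea_y_mm = 0, shape = roi_shape,
                   laterality = laterality)
  wp <- mapply(ez_width_percent, lim$left, lim$right,
               MoreArgs = list(fovea_column = fovea_column,
                               lateral_um_per_px = lateral_um_per_px))
  list(area_mm2 = ez_area(map, roi), width_percent = wp,
       map = map, roi = roi, limits = lim)
}
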