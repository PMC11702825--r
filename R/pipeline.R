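#' Default end-to-end pipeline configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]: phantom cohort
#' sizes and disease knobs, the segmentation source, biomarker parameters
#' and the ROI shape. The demo scale (small phantoms, ground-truth
#' segmentation) finishes in seconds; switch `segmentation$mode` to
#' `"model"` and supply a weights file to exercise the trained network.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Master seed; every stochastic stage derives from it.
#' @param n_control,n_patient Eyes per simulated cohort.
#' @param image_height,image_width Phantom raster size.
#' @param speckle_level Phantom speckle scale.
#' @param segmentation List: `mode` (`"truth"` or `"model"`),
#'   `weights` (RDS path of [unet_weights()], model mode only),
#'   `config` (a [unet_config()], model mode only).
#' @param alpha,beta,sy Biomarker parameters.
#' @param roi_shape `"square"` or `"disc"`.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            n_control = 6L, n_patient = 6L,
                            image_height = 96L, image_width = 192L,
                            speckle_level = 0.15,
                            segmentation = list(mode = "truth"),
                            alpha = 0.05, beta = 3L, sy = 3.5,
                            roi_shape = c("square", "disc")) {
  roi_shape <- match.arg(roi_shape)
  if (!segmentation$mode %in% c("truth", "model"))
    stop("segmentation$mode must be 'truth' or 'model'")
  if (segmentation$mode == "model") {
    if (is.null(segmentation$weights))
      stop("segment-only/model mode needs segmentation$weights")
    if (!file.exists(segmentation$weights))
      stop("model weights not found: ", segmentation$weights)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_control = as.integer(n_control),
                 n_patient = as.integer(n_patient),
                 image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 speckle_level = speckle_level,
                 segmentation = segmentation,
                 alpha = alpha, beta = as.integer(beta), sy = sy,
                 roi_shape = roi_shape),
            class = "run_config")
}

# phantom geometry scaled to the configured raster (keeps band order and
# relative placement of the default 496-row phantom)
scaled_spec <- function(H, W, sy, disease = FALSE, seed_jitter = 0) {
  s <- H / 496
  jit <- function(v) as.integer(round(v * s)) + seed_jitter
  phantom_spec(
    image_height = H, image_width = W, axial_um_per_px = sy,
    opl_depth = jit(300), opl_thickness = max(3L, as.integer(round(11 * s))),
    elm_depth = jit(352), elm_thickness = max(1L, as.integer(round(3 * s))),
    ez_depth = jit(362), ez_thickness = max(2L, as.integer(round(5 * s))),
    rpe_depth = jit(374), rpe_thickness = max(2L, as.integer(round(9 * s))),
    pit_depth = max(2L, as.integer(round(12 * s))),
    pit_width = max(8L, as.integer(round(80 * s))),
    ez_extent_mm = if (disease) 0.7 else Inf,
    ez_attenuation = if (disease) 0.55 else 1
  )
}

#' Run the end-to-end analysis pipeline on simulated cohorts
#'
#' Executes simulate -> segment -> biomarkers -> stats, writing every
#' intermediate artifact (rasters + sidecars, biomarker CSV, comparison
#' CSV) and a machine-readable provenance log under `config$out_dir`.
#' Rerunning with an identical configuration reproduces all deterministic
#' outputs bit for bit.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return List with `biomarkers` (data frame), `comparisons` (data
#'   frame), `paths` (written artifacts), invisibly also written to disk.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (!inherits(config, "run_config")) stop("config must be a pipeline_config")
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  scans_dir <- file.path(config$out_dir, "scans")
  dir.create(scans_dir, showWarnings = FALSE)
  stage <- function(name, expr) {
    if (verbose) message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  # -- simulate ------------------------------------------------------------
  cohort <- data.frame(
    eye = sprintf("eye%02d", seq_len(config$n_control + config$n_patient)),
    cohort = rep(c("control", "patient"),
                 c(config$n_control, config$n_patient)))
  scans <- stage("simulate", {
    lapply(seq_len(nrow(cohort)), function(i) {
      spec <- scaled_spec(config$image_height, config$image_width, config$sy,
                          disease = cohort$cohort[i] == "patient",
                          seed_jitter = (i %% 3L) - 1L)
      spec$speckle_level <- config$speckle_level
      out <- generate_bscan(spec, seed = config$seed * 1000L + i)
      img_path <- file.path(scans_dir, paste0(cohort$eye[i], ".tif"))
      write_bscan(out$image, img_path)
      write_classmap(out$mask, file.path(scans_dir,
                                         paste0(cohort$eye[i], "_truth.png")))
      list(image = out$image, truth = out$mask, path = img_path)
    })
  })

  # -- segment -------------------------------------------------------------
  masks <- stage("segment", {
    if (config$segmentation$mode == "truth") {
      lapply(scans, `[[`, "truth")
    } else {
      model <- build_unet(config$segmentation$config %||% unet_config())
      model <- set_unet_weights(model, readRDS(config$segmentation$weights))
      lapply(scans, function(s) predict_classmap(model, s$image)$mask)
    }
  })
  for (i in seq_along(masks))
    write_classmap(masks[[i]], file.path(scans_dir,
                                         paste0(cohort$eye[i], "_seg.png")))

  # -- biomarkers ----------------------------------------------------------
  biom <- stage("biomarkers", {
    rows <- lapply(seq_along(scans), function(i) {
      rec <- biomarker_record(scans[[i]]$image, masks[[i]],
                              alpha = config$alpha, beta = config$beta)
      rec$eye <- cohort$eye[i]
      rec$cohort <- cohort$cohort[i]
      rec
    })
    do.call(rbind, rows)
  })
  biom_path <- file.path(config$out_dir, "biomarkers.csv")
  utils::write.csv(biom, biom_path, row.names = FALSE)

  # -- stats ---------------------------------------------------------------
  comparisons <- stage("stats", {
    wide <- stats::reshape(
      biom[biom$region != "full-scan",
           c("eye", "cohort", "region", "measure", "mean")],
      direction = "wide", idvar = c("eye", "cohort", "region"),
      timevar = "measure")
    names(wide) <- sub("^mean\\.", "", names(wide))
    vcols <- setdiff(names(wide), c("eye", "cohort", "region"))
    compare_biomarker_table(wide, group_col = "cohort",
                            value_cols = vcols, region_col = "region")
  })
  stats_path <- file.path(config$out_dir, "comparisons.csv")
  utils::write.csv(comparisons, stats_path, row.names = FALSE)

  # -- provenance ----------------------------------------------------------
  prov <- list(
    package = "octez",
    version = as.character(utils::packageVersion("octez")),
    r_version = R.version.string,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    n_scans = nrow(cohort))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(list(biomarkers = biom, comparisons = comparisons,
                 paths = list(biomarkers = biom_path, comparisons = stats_path,
                              scans = scans_dir)))
}
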