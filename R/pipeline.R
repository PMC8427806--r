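## End-to-end orchestration: config -> features + calibration + yield model
## artifacts on disk, with a machine-readable run manifest.

#' Run the full canopy-fPAR pipeline from a configuration
#'
#' Reads the DSM and layout, runs the terrain pipeline, extracts per-tree
#' features, aggregates them, and — when lightbar and/or yield CSVs are
#' supplied — computes the calibration statistics, adjusted ratio, and yield
#' regression. All outputs are written under `out_dir` together with a JSON
#' manifest (inputs, parameter values, package version, MD5 checksums), so a
#' rerun with identical inputs reproduces identical files. Missing optional
#' inputs skip their stage with a warning rather than failing.
#'
#' Configuration (R list or YAML file) schema:
#' \describe{
#'   \item{dsm}{path to the DSM (ESRI ASCII grid, `.asc`).}
#'   \item{layout}{path to the layout YAML (see [read_layout()]).}
#'   \item{lightbar}{optional CSV: `row` (or `block`), and either
#'     `fpar_pct` or `par_below`+`par_above`.}
#'   \item{yield}{optional CSV: `row`/`block`/`tree` id columns and
#'     `yield_lb_acre`.}
#'   \item{out_dir}{output directory (created).}
#'   \item{params}{optional: `slope_threshold_deg` (20),
#'     `closing_diameter_px` (50), `min_canopy_height_m` (0.5), `level`
#'     (`"row"`), `base_ratio` (57.9).}
#'   \item{save_intermediate}{write slope/DEM/AGL rasters (default FALSE).}
#' }
#'
#' @param config list or path to a YAML file.
#' @return (invisibly) list with `features_tree`, `features_agg`,
#'   `calibration`, `adjusted_ratio`, `yield_model`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("dsm", "layout", "out_dir"))
    if (is.null(config[[key]])) stop("pipeline config missing `", key, "`")
  p <- config$params %||% list()
  slope_thr <- p$slope_threshold_deg %||% 20
  closing_px <- p$closing_diameter_px %||% 50
  min_h <- p$min_canopy_height_m %||% 0.5
  level <- p$level %||% "row"
  base_ratio <- p$base_ratio %||% 57.9
  defaults <- c(slope_threshold_deg = 20, closing_diameter_px = 50,
                min_canopy_height_m = 0.5)
  used <- c(slope_threshold_deg = slope_thr,
            closing_diameter_px = closing_px, min_canopy_height_m = min_h)
  for (nm in names(defaults))
    if (used[[nm]] != defaults[[nm]])
      message(sprintf("parameter override: %s = %g (default %g)",
                      nm, used[[nm]], defaults[[nm]]))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dsm <- read_asc(config$dsm)
  layout <- read_layout(config$layout)

  terr <- terrain_pipeline(dsm, slope_threshold_deg = slope_thr,
                           closing_diameter_px = closing_px)
  feats <- per_tree_features(terr$agl, layout, min_height_m = min_h)
  agg <- aggregate_features(feats, level = level)

  paths <- list(
    features_tree = file.path(config$out_dir, "features_tree.csv"),
    features_agg = file.path(config$out_dir,
                             sprintf("features_%s.csv", level))
  )
  write_features_csv(feats, paths$features_tree)
  write_features_csv(agg, paths$features_agg)
  if (isTRUE(config$save_intermediate)) {
    write_asc(terr$dem, file.path(config$out_dir, "dem.asc"))
    write_asc(terr$agl, file.path(config$out_dir, "agl.asc"))
  }

  calib <- NULL
  adj <- NULL
  if (!is.null(config$lightbar) && file.exists(config$lightbar %||% "")) {
    lb <- read.csv(config$lightbar)
    if (is.null(lb$fpar_pct)) {
      if (is.null(lb$par_below) || is.null(lb$par_above))
        stop("lightbar CSV needs fpar_pct or par_below + par_above columns")
      lb$fpar_pct <- 100 * lightbar_fpar(lb$par_below, lb$par_above)
    }
    idcol <- if (level %in% names(lb)) level else "row"
    m <- merge(agg, lb, by.x = level, by.y = idcol)
    if (nrow(m) >= 4) {
      calib <- tryCatch(calibration_stats(m$fpar_pct, m$canopy_cover_pct),
                        error = function(e) {
                          warning("calibration skipped: ", conditionMessage(e))
                          NULL
                        })
    } else {
      warning("fewer than 4 matched lightbar records; calibration skipped")
    }
    if (!is.null(calib)) {
      adj <- list(base_ratio = base_ratio, slope = calib$slope0,
                  adjusted_ratio = adjusted_ratio(base_ratio, calib$slope0),
                  adjusted_ratio_2dp = round_half_up(
                    adjusted_ratio(base_ratio, calib$slope0), 2))
      paths$calibration <- file.path(config$out_dir, "calibration.json")
      jsonlite::write_json(c(unclass(calib), adj), paths$calibration,
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  } else if (!is.null(config$lightbar)) {
    warning("lightbar CSV not found; calibration stage skipped")
  }

  ymod <- NULL
  if (!is.null(config$yield) && file.exists(config$yield %||% "")) {
    yl <- read.csv(config$yield)
    ylevel <- if (level %in% names(yl)) level else
      intersect(c("tree", "block", "row"), names(yl))[1]
    ftab <- if (identical(ylevel, "tree")) feats else
      if (identical(ylevel, attr(agg, "level"))) agg else
        aggregate_features(feats, level = ylevel)
    by_f <- if (identical(ylevel, "tree")) c("row", "tree") else ylevel
    m <- merge(ftab, yl, by = by_f)
    if (nrow(m) >= 4) {
      ymod <- tryCatch(yield_regression(m$canopy_cover_pct, m$yield_lb_acre,
                                        ratio = base_ratio),
                       error = function(e) {
                         warning("yield stage skipped: ", conditionMessage(e))
                         NULL
                       })
    } else {
      warning("fewer than 4 matched yield records; yield stage skipped")
    }
    if (!is.null(ymod)) {
      paths$yield_model <- file.path(config$out_dir, "yield_model.json")
      jsonlite::write_json(
        unclass(ymod)[setdiff(names(unclass(ymod)), "fit")],
        paths$yield_model, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  } else if (!is.null(config$yield)) {
    warning("yield CSV not found; yield stage skipped")
  }

  out_files <- unlist(paths)
  manifest <- list(
    package = "canopyfpar",
    version = as.character(utils::packageVersion("canopyfpar")),
    inputs = list(dsm = config$dsm, layout = config$layout,
                  lightbar = config$lightbar, yield = config$yield),
    parameters = list(slope_threshold_deg = slope_thr,
                      closing_diameter_px = closing_px,
                      min_canopy_height_m = min_h,
                      level = level, base_ratio = base_ratio),
    input_md5 = as.list(tools::md5sum(
      unlist(config[c("dsm", "layout")], use.names = FALSE))),
    output_md5 = as.list(tools::md5sum(out_files))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(features_tree = feats, features_agg = agg,
                 calibration = calib, adjusted_ratio = adj,
                 yield_model = ymod, manifest = manifest))
}
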