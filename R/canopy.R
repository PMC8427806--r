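## Per-tree canopy features: footprint, cover, volume index, heights.

#' Segment canopy pixels from normalized heights
#'
#' Canopy pixels have above-ground height greater than or equal to
#' `min_height_m` (inclusive threshold).
#'
#' @param agl an [elev_raster()] of kind `"HEIGHT_AGL"`.
#' @param min_height_m minimum canopy elevation (m; default 0.5).
#' @return logical matrix (`TRUE` = canopy).
#' @export
canopy_mask <- function(agl, min_height_m = 0.5) {
  stopifnot(is_elev_raster(agl))
  if (agl$kind != "HEIGHT_AGL")
    stop("canopy_mask expects a HEIGHT_AGL raster (see normalize_heights)")
  m <- agl$values >= min_height_m
  m[is.na(m)] <- FALSE
  m
}

# Assign points to grid sites via the orientation frame. Membership is by
# pixel center in the half-open allocated cell: along-row and cross-row
# offsets in [-spacing/2, +spacing/2) around the site center, so shared cell
# edges never double-count (lower edge inclusive in frame coordinates).
# Returns 0-based row/tree indices, NA outside the grid.
assign_sites <- function(x, y, layout) {
  fr <- layout$frame
  dx <- x - fr$origin[1]
  dy <- y - fr$origin[2]
  u <- dx * fr$u1[1] + dy * fr$u1[2]
  v <- dx * fr$u2[1] + dy * fr$u2[2]
  r <- floor(v / layout$row_spacing + 0.5)
  shift <- row_shift(layout, r)
  t <- floor((u - shift) / layout$tree_spacing + 0.5)
  bad <- r < 0 | r >= layout$n_rows | t < 0 | t >= layout$trees_per_row
  r[bad] <- NA_integer_
  t[bad] <- NA_integer_
  list(row = as.integer(r), tree = as.integer(t))
}

#' Per-tree canopy profile features
#'
#' Segments canopy pixels from the AGL raster, clips them to each site's
#' allocated cell (pixel centers, half-open edges), and computes for every
#' non-excluded tree: footprint area (`n_canopy_px * pixel_size^2`, the
#' raster count is the area authority), allocated area, canopy cover
#' (`100 * footprint / allocated`, the aerial fPAR estimate), canopy volume
#' index (`sum(pixel_area * height)` over footprint pixels), and mean and
#' maximum canopy height. Trees with no canopy pixels report zeros. Sites
#' whose allocated cell lies entirely outside the raster are flagged
#' (`cell_in_raster = FALSE`) with `NA` features and the pipeline continues.
#'
#' @param agl an [elev_raster()] of kind `"HEIGHT_AGL"`.
#' @param layout an [orchard_layout()].
#' @param min_height_m canopy height threshold (m; default 0.5).
#' @param sites site table (defaults to the layout's grid; excluded sites
#'   are dropped from the output).
#' @return data.frame of class `canopy_features` with columns `orchard`,
#'   `row`, `tree`, `block`, `footprint_m2`, `allocated_m2`,
#'   `canopy_cover_pct`, `volume_index_m3`, `mean_h_m`, `max_h_m`,
#'   `n_canopy_px`, `cell_in_raster`; attribute `level = "tree"`.
#' @export
per_tree_features <- function(agl, layout, min_height_m = 0.5,
                              sites = layout_tree_centers(layout)) {
  stopifnot(is_elev_raster(agl), inherits(layout, "orchard_layout"))
  mask <- canopy_mask(agl, min_height_m)
  px <- agl$pixel_size
  px_area <- px^2
  alloc <- layout$tree_spacing * layout$row_spacing

  xy <- raster_xy(agl)
  idx <- which(mask)
  hh <- agl$values[idx]
  ii <- (idx - 1) %% nrow(mask) + 1
  jj <- (idx - 1) %/% nrow(mask) + 1
  asn <- assign_sites(xy$x[jj], xy$y[ii], layout)
  keep <- !is.na(asn$row)
  key <- asn$row[keep] * layout$trees_per_row + asn$tree[keep]
  hh <- hh[keep]

  n_sites_all <- layout$n_rows * layout$trees_per_row
  counts <- numeric(n_sites_all)
  vol <- numeric(n_sites_all)
  hmax <- numeric(n_sites_all)
  hsum <- numeric(n_sites_all)
  if (length(key)) {
    tb <- tapply(hh, key, length)
    counts[as.integer(names(tb)) + 1] <- as.numeric(tb)
    sb <- tapply(hh, key, sum)
    hsum[as.integer(names(sb)) + 1] <- as.numeric(sb)
    mb <- tapply(hh, key, max)
    hmax[as.integer(names(mb)) + 1] <- as.numeric(mb)
    vol <- hsum * px_area
  }

  active <- sites[!sites$excluded, , drop = FALSE]
  skey <- active$row * layout$trees_per_row + active$tree + 1
  npx <- counts[skey]
  foot <- pmin(npx * px_area, alloc)
  out <- data.frame(
    orchard = active$orchard, row = active$row, tree = active$tree,
    block = active$block,
    footprint_m2 = foot,
    allocated_m2 = alloc,
    canopy_cover_pct = 100 * foot / alloc,
    volume_index_m3 = vol[skey],
    mean_h_m = ifelse(npx > 0, hsum[skey] / npx, 0),
    max_h_m = hmax[skey],
    n_canopy_px = as.integer(npx)
  )

  # flag sites whose cell misses the raster entirely
  ext <- c(agl$xll, agl$xll + ncol(mask) * px,
           agl$yll, agl$yll + nrow(mask) * px)
  out$cell_in_raster <- vapply(seq_len(nrow(active)), function(i) {
    poly <- allocated_cell(active[i, ], layout)
    any(poly[, 1] >= ext[1] & poly[, 1] <= ext[2] &
        poly[, 2] >= ext[3] & poly[, 2] <= ext[4])
  }, logical(1))
  bad <- !out$cell_in_raster
  if (any(bad)) {
    warning(sum(bad), " allocated cell(s) fall outside the raster; features set to NA")
    feat_cols <- c("footprint_m2", "canopy_cover_pct", "volume_index_m3",
                   "mean_h_m", "max_h_m")
    out[bad, feat_cols] <- NA_real_
  }
  rownames(out) <- NULL
  attr(out, "level") <- "tree"
  class(out) <- c("canopy_features", "data.frame")
  out
}

#' Aggregate per-tree features to block or row level
#'
#' Canopy cover at an aggregation level is `100 * sum(footprint) /
#' sum(allocated)` over member trees (equal to the mean of tree covers when
#' cells are equal, as they are within one orchard); footprint and volume
#' index are sums; mean height is the footprint-area-weighted mean; max
#' height is the max of member maxima. Levels with zero member trees are
#' dropped with a warning.
#'
#' @param features a per-tree table from [per_tree_features()].
#' @param level `"block"` or `"row"`.
#' @return a `canopy_features` data.frame at the requested level.
#' @export
aggregate_features <- function(features, level = c("block", "row")) {
  level <- match.arg(level)
  if (!identical(attr(features, "level"), "tree"))
    stop("aggregate_features expects a per-tree feature table")
  f <- features[!is.na(features$footprint_m2), , drop = FALSE]
  dropped <- nrow(features) - nrow(f)
  if (dropped > 0)
    warning(dropped, " tree(s) with NA features dropped before aggregation")
  g <- interaction(f$orchard, f[[level]], drop = TRUE)
  agg <- function(x, fun) as.numeric(tapply(x, g, fun))
  foot <- agg(f$footprint_m2, sum)
  alloc <- agg(f$allocated_m2, sum)
  wsum <- agg(f$mean_h_m * f$footprint_m2, sum)
  out <- data.frame(
    orchard = as.character(tapply(as.character(f$orchard), g,
                                  function(x) x[1])),
    footprint_m2 = foot,
    allocated_m2 = alloc,
    canopy_cover_pct = 100 * foot / alloc,
    volume_index_m3 = agg(f$volume_index_m3, sum),
    mean_h_m = ifelse(foot > 0, wsum / foot, 0),
    max_h_m = agg(f$max_h_m, max),
    n_trees = agg(rep(1, nrow(f)), sum)
  )
  out[[level]] <- as.integer(agg(f[[level]], function(x) x[1]))
  out <- out[, c("orchard", level, setdiff(names(out), c("orchard", level)))]
  rownames(out) <- NULL
  attr(out, "level") <- level
  class(out) <- c("canopy_features", "data.frame")
  out
}

#' Export per-tree footprint outlines as GeoJSON
#'
#' Writes one MultiPolygon-ish feature per tree built from the exterior
#' outlines of its clipped canopy pixels (pixel squares dissolved into a
#' pixel-boundary contour). The raster pixel count, not these polygons, is
#' the area authority; the polygons are export artifacts for GIS inspection.
#'
#' @param agl an [elev_raster()] of kind `"HEIGHT_AGL"`.
#' @param layout an [orchard_layout()].
#' @param path output file; `NULL` returns the GeoJSON string.
#' @param min_height_m canopy height threshold (m).
#' @return path (invisibly) or GeoJSON string.
#' @export
footprints_to_geojson <- function(agl, layout, path = NULL,
                                  min_height_m = 0.5) {
  mask <- canopy_mask(agl, min_height_m)
  xy <- raster_xy(agl)
  px <- agl$pixel_size
  idx <- which(mask)
  ii <- (idx - 1) %% nrow(mask) + 1
  jj <- (idx - 1) %/% nrow(mask) + 1
  asn <- assign_sites(xy$x[jj], xy$y[ii], layout)
  keep <- !is.na(asn$row)
  df <- data.frame(i = ii[keep], j = jj[keep],
                   row = asn$row[keep], tree = asn$tree[keep])
  feats <- lapply(split(df, paste(df$row, df$tree)), function(d) {
    squares <- lapply(seq_len(nrow(d)), function(k) {
      x0 <- xy$x[d$j[k]] - px / 2
      y0 <- xy$y[d$i[k]] - px / 2
      list(list(c(x0, y0), c(x0 + px, y0), c(x0 + px, y0 + px),
                c(x0, y0 + px), c(x0, y0)))
    })
    list(type = "Feature",
         properties = list(orchard = layout$orchard_id,
                           row = d$row[1], tree = d$tree[1],
                           n_px = nrow(d)),
         geometry = list(type = "MultiPolygon", coordinates = squares))
  })
  gj <- jsonlite::toJSON(
    list(type = "FeatureCollection", features = unname(feats)),
    auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(gj))
  writeLines(as.character(gj), path)
  invisible(path)
}

#' Write a feature table to CSV
#'
#' Column schema (tree level): `orchard,row,tree,block,footprint_m2,
#' allocated_m2,canopy_cover_pct,volume_index_m3,mean_h_m,max_h_m,
#' n_canopy_px,cell_in_raster`.
#'
#' @param features a `canopy_features` table.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_features_csv <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}
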