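## Terrain pipeline: DSM -> tree mask -> bare-earth DEM -> AGL heights.

# 3x3 neighborhood of a matrix with edge replication; returns list of the 9
# shifted matrices indexed [dr+2, dc+2]
shift9 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- rbind(m[1, , drop = FALSE], m, m[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  out <- vector("list", 9)
  k <- 1
  for (dc in -1:1) for (dr in -1:1) {
    out[[k]] <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    k <- k + 1
  }
  out
}

#' Surface slope of a DSM (Horn's method)
#'
#' Per-pixel slope in degrees from Horn's 8-neighbor finite differences on
#' the 3×3 window, the common default of terrain libraries. Border pixels use
#' edge replication. Any nodata pixel in the window makes the output pixel
#' nodata.
#'
#' @param dsm an [elev_raster()] of kind `"DSM_ASL"`.
#' @return an [elev_raster()] carrying slope in degrees in `[0, 90)` (kind
#'   tag left as the input's; values are degrees, not meters).
#' @export
#' @examples
#' z <- outer(rep(1, 8), (0:7) * 0.1 * tan(pi / 6))
#' s <- compute_slope(elev_raster(z, pixel_size = 0.1))
#' s$values[4, 4]  # 30 degrees
compute_slope <- function(dsm) {
  stopifnot(is_elev_raster(dsm))
  if (dsm$kind != "DSM_ASL")
    stop("compute_slope expects a DSM_ASL raster")
  m <- dsm$values
  if (nrow(m) < 3 || ncol(m) < 3)
    stop("raster must be at least 3x3 to compute slope")
  s <- shift9(m)
  # index helper: s[[dr+2 + (dc+1)*3]] holds shift by (dr, dc)
  g <- function(dr, dc) s[[dr + 2 + (dc + 1) * 3]]
  px <- dsm$pixel_size
  # matrix rows run north->south: +x is +col, +y is -row
  dzdx <- ((g(-1, 1) + 2 * g(0, 1) + g(1, 1)) -
           (g(-1, -1) + 2 * g(0, -1) + g(1, -1))) / (8 * px)
  dzdy <- ((g(-1, -1) + 2 * g(-1, 0) + g(-1, 1)) -
           (g(1, -1) + 2 * g(1, 0) + g(1, 1))) / (8 * px)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  anyna <- Reduce(`|`, lapply(s, is.na))
  slope[anyna] <- NA_real_
  out <- dsm
  out$values <- slope
  out
}

#' Threshold a slope raster into a tree mask
#'
#' Pixels with slope strictly greater than the threshold are classified as
#' trees; nodata pixels are non-tree.
#'
#' @param slope slope raster in degrees (from [compute_slope()]).
#' @param threshold_deg slope threshold (default 20).
#' @return logical matrix aligned to the raster.
#' @export
tree_mask <- function(slope, threshold_deg = 20) {
  v <- if (is_elev_raster(slope)) slope$values else slope
  m <- v > threshold_deg
  m[is.na(m)] <- FALSE
  m
}

#' Morphological closing with a discrete disk
#'
#' Dilation then erosion with a circular structural element: pixel offset
#' `(di, dj)` belongs to the element iff `sqrt(di^2 + dj^2) <= diameter/2`
#' (integer offsets, so `diameter = 1` is the identity). Pixels outside the
#' raster are background for both operations (zero padding), which makes the
#' closing extensive (a superset of the input) and idempotent. Implemented
#' via an exact Euclidean distance transform, so results are bit-stable. A
#' warning is issued when the input mask touches the raster edge, where the
#' zero padding biases the closing.
#'
#' @param mask logical matrix (`TRUE` = tree).
#' @param diameter_px element diameter in pixels (>= 1; default 50).
#' @return closed logical matrix.
#' @export
close_mask <- function(mask, diameter_px = 50) {
  stopifnot(is.logical(mask), is.matrix(mask), diameter_px >= 1)
  if (any(mask[1, ]) || any(mask[nrow(mask), ]) ||
      any(mask[, 1]) || any(mask[, ncol(mask)]))
    warning("tree mask touches the raster edge; closing is biased there")
  if (!any(mask)) return(mask)
  d2 <- diameter_px^2
  # operate on a zero-padded domain wide enough to hold the dilation, so the
  # result equals true set-morphology closing on the integer plane
  pad <- ceiling(diameter_px / 2) + 1
  nr <- nrow(mask); nc <- ncol(mask)
  ri <- pad + seq_len(nr); ci <- pad + seq_len(nc)
  big <- matrix(FALSE, nr + 2 * pad, nc + 2 * pad)
  big[ri, ci] <- mask
  # dilation: pixels within diameter/2 of a mask pixel (4*sq <= d^2 exact)
  dil <- 4 * cpp_sqdist_transform(big) <= d2
  # erosion: distance to nearest background pixel must exceed diameter/2
  er <- 4 * cpp_sqdist_transform(!dil) > d2
  er[ri, ci, drop = FALSE]
}

#' Extract ground pixels by inverting the closed tree mask
#'
#' @param dsm an [elev_raster()] of kind `"DSM_ASL"`.
#' @param closed_tree_mask logical matrix from [close_mask()].
#' @return an [elev_raster()] with DSM values on ground pixels and nodata
#'   under the mask.
#' @export
extract_ground <- function(dsm, closed_tree_mask) {
  stopifnot(is_elev_raster(dsm),
            identical(dim(dsm$values), dim(closed_tree_mask)))
  v <- dsm$values
  v[closed_tree_mask] <- NA_real_
  if (all(is.na(v)))
    stop("tree mask covers the whole raster: no ground pixels remain")
  out <- dsm
  out$values <- v
  out
}

#' Infill missing ground by nearest-neighbor interpolation
#'
#' Every nodata pixel takes the value of the Euclidean-nearest (pixel
#' centers) defined pixel; defined pixels are unchanged. Equidistant seeds
#' are broken deterministically by the lowest column-major linear pixel
#' index.
#'
#' @param ground an [elev_raster()] with gaps (from [extract_ground()]).
#' @return a gap-free [elev_raster()] of kind `"DEM_ASL"`.
#' @export
interpolate_ground <- function(ground) {
  stopifnot(is_elev_raster(ground))
  if (all(is.na(ground$values)))
    stop("cannot interpolate: raster is entirely nodata")
  out <- ground
  out$values <- cpp_nn_fill(ground$values)
  out$kind <- "DEM_ASL"
  out
}

#' Normalize a DSM to above-ground heights
#'
#' `height = max(DSM - DEM, 0)`; negative differences (photogrammetric noise
#' where the DEM sits above the DSM) are clamped to zero, so ground pixels
#' whose value fed the DEM are exactly 0.
#'
#' @param dsm an [elev_raster()] of kind `"DSM_ASL"`.
#' @param dem aligned [elev_raster()] of kind `"DEM_ASL"`.
#' @return an [elev_raster()] of kind `"HEIGHT_AGL"`.
#' @export
normalize_heights <- function(dsm, dem) {
  stopifnot(is_elev_raster(dsm), is_elev_raster(dem))
  if (!same_grid(dsm, dem))
    stop("DSM and DEM grids do not match (shape, pixel size, or origin)")
  out <- dsm
  out$values <- pmax(dsm$values - dem$values, 0)
  out$kind <- "HEIGHT_AGL"
  out
}

#' Run the full terrain pipeline on a DSM
#'
#' Slope → tree mask → closing → ground extraction → nearest-neighbor DEM →
#' AGL normalization, with the published default parameters.
#'
#' @param dsm an [elev_raster()] of kind `"DSM_ASL"`.
#' @param slope_threshold_deg tree/ground slope threshold (default 20).
#' @param closing_diameter_px disk diameter of the closing element
#'   (default 50).
#' @return list with `slope`, `mask` (raw), `closed` (closed mask), `dem`,
#'   `agl`.
#' @export
terrain_pipeline <- function(dsm, slope_threshold_deg = 20,
                             closing_diameter_px = 50) {
  slope <- compute_slope(dsm)
  mask <- tree_mask(slope, slope_threshold_deg)
  closed <- close_mask(mask, closing_diameter_px)
  if (all(closed)) stop("closed tree mask covers the whole raster")
  ground <- extract_ground(dsm, closed)
  dem <- interpolate_ground(ground)
  agl <- normalize_heights(dsm, dem)
  list(slope = slope, mask = mask, closed = closed, dem = dem, agl = agl)
}
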