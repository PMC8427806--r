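#' Define a parametric orchard planting layout
#'
#' The planting grid is anchored by three tree-center points at orchard
#' corners: `p1` and `p2` span the along-row direction, `p1` and `p3` the
#' cross-row direction. Only the directions matter — row and tree counts and
#' spacings, not the corner distances, determine the grid. The two directions
#' must be perpendicular within `angle_tol_deg`; if the along-row corner
#' distance disagrees with `(trees_per_row - 1) * tree_spacing` a warning
#' (not an error) is raised.
#'
#' @param p1,p2,p3 numeric length-2 planar map coordinates (m) of tree
#'   centers at three orchard corners; `p2` anchors the along-row direction,
#'   `p3` the cross-row direction.
#' @param n_rows,trees_per_row positive integers.
#' @param row_spacing,tree_spacing center-to-center spacings (m).
#' @param pattern `"square"` (adjacent rows aligned) or `"offset"` (adjacent
#'   rows shifted by half the tree spacing).
#' @param blocks_per_row positive integer; must divide `trees_per_row`.
#' @param offset_parity which rows carry the half-spacing shift under the
#'   offset pattern: `"odd"` (default) or `"even"` (0-based row index).
#' @param exclusions optional 2-column matrix/data.frame of 0-based
#'   `(row, tree)` indices of missing or inter-planted trees; excluded sites
#'   keep their allocated cell but are dropped from feature tables.
#' @param angle_tol_deg tolerance (degrees) on the perpendicularity of the
#'   two corner-point directions.
#' @param orchard_id label carried into exports.
#' @return an object of class `orchard_layout`.
#' @export
#' @examples
#' lay <- orchard_layout(c(0, 0), c(30, 0), c(0, 40),
#'                       n_rows = 3, trees_per_row = 4,
#'                       row_spacing = 6, tree_spacing = 3)
orchard_layout <- function(p1, p2, p3, n_rows, trees_per_row,
                           row_spacing, tree_spacing,
                           pattern = c("square", "offset"),
                           blocks_per_row = 1L,
                           offset_parity = c("odd", "even"),
                           exclusions = NULL,
                           angle_tol_deg = 5,
                           orchard_id = "orchard") {
  pattern <- match.arg(pattern)
  offset_parity <- match.arg(offset_parity)
  stopifnot(n_rows >= 1, trees_per_row >= 1,
            row_spacing > 0, tree_spacing > 0, blocks_per_row >= 1)
  if (trees_per_row %% blocks_per_row != 0)
    stop(sprintf("blocks_per_row (%d) must divide trees_per_row (%d)",
                 blocks_per_row, trees_per_row))
  frame <- build_orientation(p1, p2, p3, angle_tol_deg = angle_tol_deg)
  span <- sqrt(sum((p2 - p1)^2))
  expect_span <- (trees_per_row - 1) * tree_spacing
  if (trees_per_row > 1 &&
      abs(span - expect_span) > 0.25 * tree_spacing + 1e-9)
    warning(sprintf(
      "along-row corner distance %.2f m differs from (trees_per_row-1)*tree_spacing = %.2f m",
      span, expect_span))
  if (!is.null(exclusions)) {
    exclusions <- as.matrix(exclusions)
    storage.mode(exclusions) <- "integer"
    stopifnot(ncol(exclusions) == 2)
  }
  structure(
    list(p1 = as.numeric(p1), p2 = as.numeric(p2), p3 = as.numeric(p3),
         n_rows = as.integer(n_rows), trees_per_row = as.integer(trees_per_row),
         row_spacing = row_spacing, tree_spacing = tree_spacing,
         pattern = pattern, blocks_per_row = as.integer(blocks_per_row),
         offset_parity = offset_parity, exclusions = exclusions,
         frame = frame, orchard_id = orchard_id),
    class = "orchard_layout"
  )
}

#' @export
print.orchard_layout <- function(x, ...) {
  cat(sprintf("<orchard_layout '%s': %d rows x %d trees (%s), %g x %g m, %d blocks/row>\n",
              x$orchard_id, x$n_rows, x$trees_per_row, x$pattern,
              x$tree_spacing, x$row_spacing, x$blocks_per_row))
  invisible(x)
}

#' Build the orchard orientation frame from three corner points
#'
#' Returns an orthonormal planar frame: origin at `p1`, unit along-row axis
#' `u1` toward `p2`, unit cross-row axis `u2` obtained by orthogonalizing
#' `p3 - p1` against `u1` (so `p3` always lies on the positive `u2` side).
#' The raw directions must be perpendicular within `angle_tol_deg`.
#'
#' @inheritParams orchard_layout
#' @return list with `origin`, `u1`, `u2` (numeric length-2 each).
#' @export
#' @examples
#' build_orientation(c(0, 0), c(10, 0), c(0, 5))
build_orientation <- function(p1, p2, p3, angle_tol_deg = 5) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  stopifnot(length(p1) == 2, length(p2) == 2, length(p3) == 2)
  v1 <- p2 - p1
  v2 <- p3 - p1
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12)
    stop("degenerate frame: corner points must be distinct")
  u1 <- v1 / n1
  cross <- u1[1] * v2[2] - u1[2] * v2[1]
  if (abs(cross) < 1e-9 * n2)
    stop("degenerate frame: the three corner points are collinear")
  ang <- acos(pmin(1, pmax(-1, sum(u1 * v2) / n2))) * 180 / pi
  if (abs(ang - 90) > angle_tol_deg)
    stop(sprintf(
      "corner-point directions meet at %.2f deg; must be within %g deg of 90",
      ang, angle_tol_deg))
  w <- v2 - sum(v2 * u1) * u1
  u2 <- w / sqrt(sum(w^2))
  list(origin = p1, u1 = u1, u2 = u2)
}

row_shift <- function(layout, row_index) {
  if (layout$pattern != "offset") return(rep(0, length(row_index)))
  odd <- row_index %% 2 == 1
  shifted <- if (layout$offset_parity == "odd") odd else !odd
  ifelse(shifted, layout$tree_spacing / 2, 0)
}

#' Lay out every tree center of a planting grid
#'
#' Tree center `(r, t)` (0-based row and within-row indices) sits at
#' `origin + u2 * r * row_spacing + u1 * (t * tree_spacing + shift(r))`,
#' where `shift(r)` is 0 for the square pattern and half the tree spacing on
#' shifted rows of the offset pattern. Block index is
#' `row * blocks_per_row + floor(tree / (trees_per_row / blocks_per_row))`.
#'
#' @param layout an [orchard_layout()].
#' @param drop_excluded drop sites listed in the layout's exclusion list
#'   (default `FALSE`: they are returned flagged).
#' @return data.frame with one site per row: `orchard`, `row`, `tree`,
#'   `block` (all 0-based indices except `orchard`), map coordinates `x`,
#'   `y`, and logical `excluded`.
#' @export
#' @examples
#' lay <- orchard_layout(c(0, 0), c(9, 0), c(0, 12), n_rows = 3,
#'                       trees_per_row = 4, row_spacing = 6, tree_spacing = 3)
#' layout_tree_centers(lay)
layout_tree_centers <- function(layout, drop_excluded = FALSE) {
  stopifnot(inherits(layout, "orchard_layout"))
  fr <- layout$frame
  grid <- expand.grid(tree = seq_len(layout$trees_per_row) - 1L,
                      row = seq_len(layout$n_rows) - 1L)
  shift <- row_shift(layout, grid$row)
  along <- grid$tree * layout$tree_spacing + shift
  across <- grid$row * layout$row_spacing
  x <- fr$origin[1] + fr$u1[1] * along + fr$u2[1] * across
  y <- fr$origin[2] + fr$u1[2] * along + fr$u2[2] * across
  trees_per_block <- layout$trees_per_row %/% layout$blocks_per_row
  block <- grid$row * layout$blocks_per_row + grid$tree %/% trees_per_block
  excluded <- rep(FALSE, nrow(grid))
  if (!is.null(layout$exclusions) && nrow(layout$exclusions) > 0) {
    key <- paste(grid$row, grid$tree)
    exkey <- paste(layout$exclusions[, 1], layout$exclusions[, 2])
    excluded <- key %in% exkey
  }
  sites <- data.frame(orchard = layout$orchard_id,
                      row = as.integer(grid$row), tree = as.integer(grid$tree),
                      block = as.integer(block), x = x, y = y,
                      excluded = excluded)
  if (drop_excluded) sites <- sites[!sites$excluded, , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Allocated-cell polygon of one tree site
#'
#' The rectangle of area `tree_spacing * row_spacing` centered on the site,
#' aligned to the orientation frame (extent `tree_spacing` along `u1`,
#' `row_spacing` along `u2`).
#'
#' @param site one row of [layout_tree_centers()] output (or any list with
#'   `x`, `y`).
#' @param layout the [orchard_layout()] the site came from.
#' @return a 4×2 matrix of polygon vertices (counter-clockwise, not closed).
#' @export
allocated_cell <- function(site, layout) {
  stopifnot(inherits(layout, "orchard_layout"))
  fr <- layout$frame
  ht <- layout$tree_spacing / 2
  hr <- layout$row_spacing / 2
  ctr <- c(site$x, site$y)
  corners <- rbind(c(-ht, -hr), c(ht, -hr), c(ht, hr), c(-ht, hr))
  t(apply(corners, 1, function(cc) ctr + fr$u1 * cc[1] + fr$u2 * cc[2]))
}

#' Build an orchard registry
#'
#' A registry binds a site table to an orchard id and optional per-site
#' variety labels, and carries the counts used in sampling summaries. The
#' tree count can be overridden when the true planted count is known to
#' differ from the parametric grid (e.g. irregular guard rows).
#'
#' @param sites site table from [layout_tree_centers()], or `NULL` when only
#'   counts are known.
#' @param orchard_id label.
#' @param variety optional character vector: one label per (non-excluded)
#'   site, or a single label for the whole orchard.
#' @param n_trees optional explicit tree-count override.
#' @param n_blocks,n_rows optional explicit count overrides.
#' @return an object of class `orchard_registry`.
#' @export
orchard_registry <- function(sites = NULL, orchard_id = "orchard",
                             variety = NULL, n_trees = NULL,
                             n_blocks = NULL, n_rows = NULL) {
  if (is.null(sites) && is.null(n_trees))
    stop("either `sites` or an explicit `n_trees` must be given")
  active <- if (!is.null(sites)) sites[!sites$excluded, , drop = FALSE] else NULL
  n_trees <- n_trees %||% nrow(active)
  n_blocks <- n_blocks %||% (if (!is.null(active)) length(unique(active$block)) else NA_integer_)
  n_rows <- n_rows %||% (if (!is.null(active)) length(unique(active$row)) else NA_integer_)
  if (!is.null(variety) && !is.null(active) && length(variety) == 1)
    variety <- rep(variety, nrow(active))
  structure(
    list(orchard_id = orchard_id, sites = active, variety = variety,
         n_trees = as.integer(n_trees), n_blocks = as.integer(n_blocks),
         n_rows = as.integer(n_rows)),
    class = "orchard_registry"
  )
}

#' Summarize registries: counts and sample proportions
#'
#' Proportions are percentages of the pooled tree count across all supplied
#' registries, rounded half-up to 2 decimals; totals are sums.
#'
#' @param registries a single [orchard_registry()] or a list of them.
#' @param by `"orchard"` or `"variety"` (varieties require labels).
#' @return data.frame with `unit`, `n_trees`, `proportion_pct` plus a
#'   `TOTAL` row.
#' @export
#' @examples
#' r1 <- orchard_registry(orchard_id = "O1", n_trees = 722)
#' r2 <- orchard_registry(orchard_id = "O2", n_trees = 449)
#' r3 <- orchard_registry(orchard_id = "O3", n_trees = 269)
#' registry_summary(list(r1, r2, r3))
registry_summary <- function(registries, by = c("orchard", "variety")) {
  by <- match.arg(by)
  if (inherits(registries, "orchard_registry")) registries <- list(registries)
  if (length(registries) == 0) stop("empty registry list")
  counts <- if (by == "orchard") {
    stats::setNames(vapply(registries, function(r) r$n_trees, integer(1)),
                    vapply(registries, function(r) r$orchard_id, character(1)))
  } else {
    tabs <- lapply(registries, function(r) {
      if (is.null(r$variety)) stop("variety summary requires variety labels")
      table(r$variety)
    })
    tot <- Reduce(`+`, lapply(tabs, function(t) {
      all_lv <- unique(unlist(lapply(tabs, names)))
      out <- stats::setNames(integer(length(all_lv)), all_lv)
      out[names(t)] <- as.integer(t)
      out
    }))
    tot
  }
  if (sum(counts) == 0) stop("registry has no trees")
  total <- sum(counts)
  out <- data.frame(unit = names(counts), n_trees = as.integer(counts),
                    proportion_pct = round_half_up(100 * counts / total, 2))
  out <- rbind(out, data.frame(unit = "TOTAL", n_trees = total,
                               proportion_pct = 100))
  rownames(out) <- NULL
  out
}

#' Export allocated cells as GeoJSON
#'
#' One polygon feature per site with `orchard`, `row`, `tree`, `block`
#' properties, in the layout's planar map coordinates.
#'
#' @param layout an [orchard_layout()].
#' @param path output file; `NULL` returns the GeoJSON string.
#' @param sites optional site table (defaults to the full grid).
#' @return path (invisibly) or the GeoJSON string.
#' @export
cells_to_geojson <- function(layout, path = NULL,
                             sites = layout_tree_centers(layout)) {
  feats <- lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    poly <- allocated_cell(s, layout)
    ring <- rbind(poly, poly[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(orchard = s$orchard, row = s$row, tree = s$tree,
                        block = s$block, excluded = s$excluded),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(k) ring[k, ])))
    )
  })
  gj <- jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(gj))
  writeLines(as.character(gj), path)
  invisible(path)
}

#' Read an orchard layout from a YAML config file
#'
#' Schema (keys): `orchard_id`, `p1`, `p2`, `p3` (each `[x, y]` in planar
#' meters), `n_rows`, `trees_per_row`, `row_spacing`, `tree_spacing`,
#' `pattern` (`square`/`offset`), `blocks_per_row`, `offset_parity`,
#' `exclusions` (list of `[row, tree]`, 0-based), `angle_tol_deg`.
#'
#' @param path YAML file path.
#' @return an [orchard_layout()].
#' @export
read_layout <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("p1", "p2", "p3", "n_rows", "trees_per_row",
            "row_spacing", "tree_spacing")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("layout config missing keys: ", paste(missing, collapse = ", "))
  excl <- cfg$exclusions
  if (!is.null(excl)) excl <- do.call(rbind, lapply(excl, as.integer))
  orchard_layout(
    p1 = unlist(cfg$p1), p2 = unlist(cfg$p2), p3 = unlist(cfg$p3),
    n_rows = cfg$n_rows, trees_per_row = cfg$trees_per_row,
    row_spacing = cfg$row_spacing, tree_spacing = cfg$tree_spacing,
    pattern = cfg$pattern %||% "square",
    blocks_per_row = cfg$blocks_per_row %||% 1L,
    offset_parity = cfg$offset_parity %||% "odd",
    exclusions = excl,
    angle_tol_deg = cfg$angle_tol_deg %||% 5,
    orchard_id = cfg$orchard_id %||% "orchard"
  )
}
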