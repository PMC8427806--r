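test_that("orientation frame handles axis-aligned, rotated, and degenerate corners", {
  f <- build_orientation(c(0, 0), c(10, 0), c(0, 5))
  expect_equal(f$u1, c(1, 0))
  expect_equal(f$u2, c(0, 1))
  expect_equal(f$origin, c(0, 0))

  f <- build_orientation(c(0, 0), c(0, 10), c(-4, 0))
  expect_equal(f$u1, c(0, 1))
  expect_equal(f$u2, c(-1, 0))

  expect_error(build_orientation(c(0, 0), c(10, 0), c(20, 0)), "collinear")
  expect_error(build_orientation(c(0, 0), c(0, 0), c(1, 1)), "distinct")
  # 80 degrees is outside the default 5-degree tolerance; message names angle
  expect_error(build_orientation(c(0, 0), c(10, 0), c(1, 5.67)), "deg")
})

test_that("near-perpendicular corners are orthogonalized onto the positive side", {
  f <- build_orientation(c(0, 0), c(10, 0), c(0.3, 7))
  expect_equal(sum(f$u1 * f$u2), 0, tolerance = 1e-12)
  expect_equal(sqrt(sum(f$u2^2)), 1, tolerance = 1e-12)
  expect_gt(sum((c(0.3, 7)) * f$u2), 0)
})

test_that("tree centers follow square and offset patterns with block indexing", {
  lay <- demo_layout(n_rows = 2, trees_per_row = 3, pattern = "offset",
                     tree_spacing = 4, row_spacing = 6)
  s <- layout_tree_centers(lay)
  r0 <- s[s$row == 0, ]
  r1 <- s[s$row == 1, ]
  expect_equal(r1$x, r0$x + 2)  # odd rows shift by half the tree spacing
  expect_equal(unique(r1$y), 6)

  sq <- layout_tree_centers(demo_layout(pattern = "square", tree_spacing = 4))
  expect_equal(sq$x[sq$row == 1], sq$x[sq$row == 0])

  one <- layout_tree_centers(orchard_layout(c(0, 0), c(1, 0), c(0, 1),
                                            n_rows = 1, trees_per_row = 1,
                                            row_spacing = 1, tree_spacing = 1))
  expect_equal(nrow(one), 1)
  expect_equal(c(one$x, one$y), c(0, 0))

  # 21 rows x 12 trees, 4 blocks/row: 84 blocks of 3 trees
  big <- suppressWarnings(orchard_layout(
    c(0, 0), c(11 * 5.5, 0), c(0, 20 * 6), n_rows = 21, trees_per_row = 12,
    row_spacing = 6, tree_spacing = 5.5, blocks_per_row = 4))
  sb <- layout_tree_centers(big)
  expect_equal(length(unique(sb$block)), 84)
  expect_true(all(table(sb$block) == 3))
  expect_error(orchard_layout(c(0, 0), c(10, 0), c(0, 10), n_rows = 2,
                              trees_per_row = 12, row_spacing = 6,
                              tree_spacing = 1, blocks_per_row = 5),
               "divide")
})

test_that("allocated cells have exact area and tile without overlap", {
  for (sp in list(c(6, 3), c(6.5, 4), c(1, 1))) {
    lay <- demo_layout(n_rows = 2, trees_per_row = 3,
                       row_spacing = sp[1], tree_spacing = sp[2])
    s <- layout_tree_centers(lay)
    areas <- vapply(seq_len(nrow(s)), function(i) {
      p <- allocated_cell(s[i, ], lay)
      abs(sum(p[, 1] * c(p[-1, 2], p[1, 2]) - p[, 2] * c(p[-1, 1], p[1, 1]))) / 2
    }, numeric(1))
    expect_equal(areas, rep(sp[1] * sp[2], nrow(s)), tolerance = 1e-9)
  }
  # interiors disjoint: cell centers of distinct sites are farther apart than
  # zero in frame coordinates and the assignment map is single-valued
  lay <- demo_layout(n_rows = 3, trees_per_row = 4, pattern = "offset")
  s <- layout_tree_centers(lay)
  asn <- canopyfpar:::assign_sites(s$x, s$y, lay)
  expect_equal(asn$row, s$row)
  expect_equal(asn$tree, s$tree)
})

test_that("grid is equivariant under rigid motion of the corner points", {
  lay <- demo_layout(n_rows = 3, trees_per_row = 4, pattern = "offset")
  s0 <- layout_tree_centers(lay)
  th <- 0.7; Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tr <- c(120, -40)
  move <- function(p) as.numeric(Rm %*% p + tr)
  lay2 <- orchard_layout(move(lay$p1), move(lay$p2), move(lay$p3),
                         n_rows = 3, trees_per_row = 4, row_spacing = 6,
                         tree_spacing = 5, pattern = "offset")
  s1 <- layout_tree_centers(lay2)
  moved <- t(apply(as.matrix(s0[, c("x", "y")]), 1, move))
  expect_equal(unname(as.matrix(s1[, c("x", "y")])), unname(moved),
               tolerance = 1e-9)
})

test_that("square pattern equals offset pattern on unshifted rows", {
  sq <- layout_tree_centers(demo_layout(n_rows = 4, pattern = "square"))
  of <- layout_tree_centers(demo_layout(n_rows = 4, pattern = "offset"))
  even <- sq$row %% 2 == 0
  expect_equal(sq$x[even], of$x[even])
  expect_equal(sq$y, of$y)
})

test_that("exclusion list drops sites from tables but keeps the grid", {
  lay <- demo_layout(exclusions = rbind(c(0, 1), c(1, 2)))
  all_sites <- layout_tree_centers(lay)
  expect_equal(sum(all_sites$excluded), 2)
  kept <- layout_tree_centers(lay, drop_excluded = TRUE)
  expect_equal(nrow(kept), 4)
})

test_that("registry summaries reproduce count/proportion arithmetic", {
  regs <- list(orchard_registry(orchard_id = "O1", n_trees = 722),
               orchard_registry(orchard_id = "O2", n_trees = 449),
               orchard_registry(orchard_id = "O3", n_trees = 269))
  s <- registry_summary(regs)
  expect_equal(s$proportion_pct[s$unit == "O1"], 50.14)
  expect_equal(s$proportion_pct[s$unit == "O2"], 31.18)
  expect_equal(s$proportion_pct[s$unit == "O3"], 18.68)
  expect_equal(s$n_trees[s$unit == "TOTAL"], 1440)

  one <- registry_summary(orchard_registry(orchard_id = "only", n_trees = 7))
  expect_equal(one$proportion_pct[one$unit == "only"], 100)
  expect_error(registry_summary(list()), "empty")
})

test_that("layout round-trips through the YAML config schema", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("orchard_id: O2", "p1: [0, 0]", "p2: [16, 0]", "p3: [0, 12]",
               "n_rows: 3", "trees_per_row: 5", "row_spacing: 6.5",
               "tree_spacing: 4", "pattern: offset", "blocks_per_row: 5",
               "exclusions:", "  - [0, 2]"), f)
  lay <- suppressWarnings(read_layout(f))
  expect_s3_class(lay, "orchard_layout")
  expect_equal(lay$pattern, "offset")
  expect_equal(nrow(layout_tree_centers(lay, drop_excluded = TRUE)), 14)
  expect_error(read_layout({
    g <- tempfile(); writeLines("p1: [0, 0]", g); g
  }), "missing keys")
})

test_that("allocated cells export as valid GeoJSON polygons", {
  lay <- demo_layout()
  gj <- jsonlite::fromJSON(cells_to_geojson(lay), simplifyVector = FALSE)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), 6)
  ring <- gj$features[[1]]$geometry$coordinates[[1]]
  expect_equal(length(ring), 5)  # closed ring
  expect_equal(ring[[1]], ring[[5]])
})
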