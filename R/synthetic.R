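## Synthetic orchard scenes with closed-form per-tree truth. The generator
## exists so the terrain and canopy modules can be validated end-to-end
## against analytic footprints, volumes and heights, and so the statistical
## layer can be exercised on tables with known slopes and ratios.

#' Specify a synthetic orchard scene
#'
#' Describes a DSM to synthesize: a planting layout, a ground surface (plane
#' plus optional sinusoidal relief), per-site crown solids, pixel size,
#' additive elevation noise, and a seed. Crowns are `"hemiellipsoid"`
#' (height field `h * sqrt(1 - (d/r)^2)`; closed-form solid volume
#' `(2/3) * pi * r^2 * h`, footprint at cut height `c` equal to
#' `pi * r^2 * (1 - (c/h)^2)`) or `"spherical_cap"` (sphere radius
#' `R = (r^2 + h^2) / (2h)`), or `"none"`.
#'
#' @param layout an [orchard_layout()].
#' @param ground numeric `c(z0, gx, gy)`: plane `z = z0 + gx*x + gy*y` (m;
#'   gradients as rise per meter).
#' @param crowns data.frame with one row per crown: `row`, `tree` (0-based
#'   site indices), `shape`, `r` (crown radius, m), `h` (apex height above
#'   ground, m). Use `default_crowns()` for a uniform canopy.
#' @param pixel_size raster resolution (m/px); must resolve the smallest
#'   crown (`pixel_size < r/3`).
#' @param noise_sd i.i.d. Gaussian elevation noise sd (m; default 0).
#' @param sine optional `c(amplitude, wavelength)` ground sinusoid added
#'   along x (m).
#' @param margin ground margin beyond the outermost allocated cells (m).
#' @param seed RNG seed; fixed seed gives identical rasters.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(layout, ground = c(100, 0, 0),
                       crowns = default_crowns(layout),
                       pixel_size = 0.05, noise_sd = 0,
                       sine = NULL, margin = 5, seed = 1L) {
  stopifnot(inherits(layout, "orchard_layout"), length(ground) == 3,
            pixel_size > 0, noise_sd >= 0, margin >= 0)
  crowns$shape <- as.character(crowns$shape)
  stopifnot(all(crowns$shape %in% c("none", "hemiellipsoid", "spherical_cap")))
  live <- crowns$shape != "none"
  if (any(live)) {
    rmin <- min(crowns$r[live])
    if (pixel_size >= rmin / 3)
      stop(sprintf(
        "pixel_size %.3g cannot resolve crowns of radius %.3g (need < r/3)",
        pixel_size, rmin))
    if (any(crowns$h[live] <= 0)) stop("crown apex heights must be positive")
  }
  structure(list(layout = layout, ground = as.numeric(ground),
                 crowns = crowns, pixel_size = pixel_size,
                 noise_sd = noise_sd, sine = sine, margin = margin,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Uniform crown table for a layout
#'
#' One crown per non-excluded site, same shape everywhere.
#'
#' @param layout an [orchard_layout()].
#' @param shape crown solid (default `"hemiellipsoid"`).
#' @param r crown radius (m; default 2).
#' @param h apex height above ground (m; default 3.5, a mature orchard
#'   canopy).
#' @return data.frame with `row`, `tree`, `shape`, `r`, `h`.
#' @export
default_crowns <- function(layout, shape = "hemiellipsoid", r = 2, h = 3.5) {
  sites <- layout_tree_centers(layout, drop_excluded = TRUE)
  data.frame(row = sites$row, tree = sites$tree, shape = shape, r = r, h = h)
}

crown_height_field <- function(shape, d, r, h) {
  inside <- d < r
  z <- numeric(length(d))
  if (shape == "hemiellipsoid") {
    z[inside] <- h * sqrt(1 - (d[inside] / r)^2)
  } else if (shape == "spherical_cap") {
    R <- (r^2 + h^2) / (2 * h)
    z[inside] <- sqrt(R^2 - d[inside]^2) - (R - h)
  }
  z
}

crown_truth <- function(shape, r, h, cut) {
  if (shape == "none" || h <= cut)
    return(list(footprint = 0, volume = 0, apex = if (shape == "none") 0 else h))
  if (shape == "hemiellipsoid") {
    list(footprint = pi * r^2 * (1 - (cut / h)^2),
         volume = (2 / 3) * pi * r^2 * h,
         apex = h)
  } else {  # spherical cap of sphere radius R, cap height h, base radius r
    R <- (r^2 + h^2) / (2 * h)
    rc2 <- R^2 - (R - h + cut)^2
    list(footprint = pi * max(rc2, 0),
         volume = pi * h^2 * (R - h / 3),
         apex = h)
  }
}

#' Generate a synthetic DSM with analytic per-tree truth
#'
#' Synthesizes `DSM = ground + crown height field + noise` on a grid
#' covering every allocated cell plus the margin, crowns combined by max (a
#' surface model sees the top surface), and returns the closed-form truth
#' table: per site, the analytic footprint area at the canopy cut height,
#' the analytic crown solid volume, the apex height, and the expected canopy
#' cover (footprint clipped to the allocated-cell area). Deterministic under
#' the scene seed.
#'
#' @param spec a [scene_spec()].
#' @param cut_height_m canopy segmentation height used for the analytic
#'   footprint truth (m; default 0.5, matching [canopy_mask()]).
#' @return list with `dsm` (an [elev_raster()]), `truth` (data.frame: `row`,
#'   `tree`, `block`, `x`, `y`, `shape`, `r`, `h`, `apex_m`,
#'   `footprint_m2`, `volume_m3`, `allocated_m2`, `expected_cover_pct`),
#'   `ground_fn` (function of `(x, y)` returning the true bare-earth
#'   elevation).
#' @export
#' @examples
#' lay <- orchard_layout(c(0, 0), c(6, 0), c(0, 6), n_rows = 1,
#'                       trees_per_row = 2, row_spacing = 6, tree_spacing = 6)
#' sc <- generate_dsm(scene_spec(lay, pixel_size = 0.2))
#' sc$truth$expected_cover_pct
generate_dsm <- function(spec, cut_height_m = 0.5) {
  stopifnot(inherits(spec, "scene_spec"))
  layout <- spec$layout
  sites <- layout_tree_centers(layout)
  cells <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i)
    allocated_cell(sites[i, ], layout)))
  px <- spec$pixel_size
  xmin <- min(cells[, 1]) - spec$margin
  xmax <- max(cells[, 1]) + spec$margin
  ymin <- min(cells[, 2]) - spec$margin
  ymax <- max(cells[, 2]) + spec$margin
  nc <- ceiling((xmax - xmin) / px)
  nr <- ceiling((ymax - ymin) / px)

  g <- spec$ground
  sine <- spec$sine
  ground_fn <- function(x, y) {
    z <- g[1] + g[2] * x + g[3] * y
    if (!is.null(sine)) z <- z + sine[1] * sin(2 * pi * x / sine[2])
    z
  }

  xs <- xmin + (seq_len(nc) - 0.5) * px
  ys <- ymin + (nr - seq_len(nr) + 0.5) * px
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  z <- ground_fn(X, Y)

  crowns <- merge(spec$crowns, sites[, c("row", "tree", "x", "y", "block")],
                  by = c("row", "tree"), sort = TRUE)
  canopy <- matrix(0, nr, nc)
  for (i in seq_len(nrow(crowns))) {
    cr <- crowns[i, ]
    if (cr$shape == "none") next
    jr <- which(abs(xs - cr$x) <= cr$r)
    ir <- which(abs(ys - cr$y) <= cr$r)
    if (!length(jr) || !length(ir)) next
    d <- sqrt(outer((ys[ir] - cr$y)^2, (xs[jr] - cr$x)^2, `+`))
    hz <- crown_height_field(cr$shape, d, cr$r, cr$h)
    canopy[ir, jr] <- pmax(canopy[ir, jr], hz)
  }
  z <- z + canopy
  if (spec$noise_sd > 0)
    z <- z + with_seed(spec$seed, matrix(rnorm(nr * nc, 0, spec$noise_sd),
                                         nr, nc))

  alloc <- layout$tree_spacing * layout$row_spacing
  truth <- do.call(rbind, lapply(seq_len(nrow(crowns)), function(i) {
    cr <- crowns[i, ]
    tt <- crown_truth(cr$shape, cr$r, cr$h, cut_height_m)
    data.frame(row = cr$row, tree = cr$tree, block = cr$block,
               x = cr$x, y = cr$y, shape = cr$shape, r = cr$r, h = cr$h,
               apex_m = tt$apex, footprint_m2 = tt$footprint,
               volume_m3 = tt$volume, allocated_m2 = alloc,
               expected_cover_pct = 100 * min(tt$footprint, alloc) / alloc)
  }))
  truth <- truth[order(truth$row, truth$tree), ]
  rownames(truth) <- NULL

  list(dsm = elev_raster(z, pixel_size = px, xll = xmin, yll = ymin,
                         kind = "DSM_ASL"),
       truth = truth, ground_fn = ground_fn)
}

#' Generate synthetic lightbar records from scene truth
#'
#' Emulates per-row mobile lightbar fPAR: the row's true mean canopy cover
#' (%) scaled by a bias factor plus Gaussian noise, clamped to `[0, 100]`,
#' with raw PAR readings back-computed from a nominal above-canopy PPFD.
#' With `bias = b` and no noise, the zero-intercept slope of cover on
#' lightbar fPAR is `1/b`.
#'
#' @param truth truth table from [generate_dsm()].
#' @param bias multiplicative bias of the lightbar relative to truth
#'   (default 1).
#' @param noise_sd additive noise sd in fPAR percentage points (default 0).
#' @param seed RNG seed.
#' @param par_above nominal above-canopy PPFD (μmol·m⁻²·s⁻¹, default 2000).
#' @param date record date label.
#' @return data.frame with `row`, `par_below`, `par_above`, `fpar_pct`,
#'   `date`.
#' @export
generate_lightbar <- function(truth, bias = 1, noise_sd = 0, seed = 1L,
                              par_above = 2000, date = "sim") {
  mu <- tapply(truth$expected_cover_pct, truth$row, mean)
  f <- as.numeric(mu) * bias
  if (noise_sd > 0)
    f <- f + with_seed(seed, rnorm(length(f), 0, noise_sd))
  f <- pmin(pmax(f, 0), 100)
  data.frame(row = as.integer(names(mu)),
             par_below = par_above * (1 - f / 100),
             par_above = par_above,
             fpar_pct = f, date = date)
}

#' Generate synthetic per-tree yield records from scene truth
#'
#' Emulates actual dry-kernel yield sitting below the potential line:
#' `yield = attainment_fraction * ratio * cover% + noise`, floored at 0.
#' With no noise the zero-intercept slope of yield against potential yield
#' equals `attainment_fraction`.
#'
#' @param truth truth table from [generate_dsm()].
#' @param ratio potential-yield ratio, lb·acre⁻¹ per % fPAR (default 57.9).
#' @param attainment_fraction fraction of potential realized, in (0, 1]
#'   (default 0.6, reflecting orchards running well below potential).
#' @param noise_sd additive yield noise sd, lb·acre⁻¹ (default 0).
#' @param seed RNG seed.
#' @return data.frame with `row`, `tree`, `block`, `cover_pct`,
#'   `yield_lb_acre`.
#' @export
generate_yield <- function(truth, ratio = 57.9, attainment_fraction = 0.6,
                           noise_sd = 0, seed = 1L) {
  stopifnot(attainment_fraction > 0, attainment_fraction <= 1)
  y <- attainment_fraction * ratio * truth$expected_cover_pct
  if (noise_sd > 0)
    y <- y + with_seed(seed, rnorm(length(y), 0, noise_sd))
  data.frame(row = truth$row, tree = truth$tree, block = truth$block,
             cover_pct = truth$expected_cover_pct,
             yield_lb_acre = pmax(y, 0))
}
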