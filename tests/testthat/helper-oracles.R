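# Independent brute-force oracles and small shared fixtures. Every oracle
# here is written directly from the operation's definition, not by calling
# the package's implementation path.

# Horn slope by explicit per-pixel loop over the 3x3 window (edge replication)
oracle_horn_slope <- function(z, px) {
  nr <- nrow(z); nc <- ncol(z)
  at <- function(i, j) z[min(max(i, 1), nr), min(max(j, 1), nc)]
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    # +x east (+col), +y north (-row)
    dzdx <- ((at(i - 1, j + 1) + 2 * at(i, j + 1) + at(i + 1, j + 1)) -
             (at(i - 1, j - 1) + 2 * at(i, j - 1) + at(i + 1, j - 1))) / (8 * px)
    dzdy <- ((at(i - 1, j - 1) + 2 * at(i - 1, j) + at(i - 1, j + 1)) -
             (at(i + 1, j - 1) + 2 * at(i + 1, j) + at(i + 1, j + 1))) / (8 * px)
    out[i, j] <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  }
  out
}

# Set-arithmetic closing on the integer plane: embed the mask in a padded
# array, take the union of element translates (dilation), then the pixels
# whose whole element fits inside the dilation (erosion), and crop.
oracle_close <- function(mask, d) {
  offs <- expand.grid(di = -d:d, dj = -d:d)
  offs <- offs[offs$di^2 + offs$dj^2 <= d^2 / 4, ]
  pad <- d + 2
  nr <- nrow(mask); nc <- ncol(mask)
  big <- matrix(FALSE, nr + 2 * pad, nc + 2 * pad)
  big[pad + seq_len(nr), pad + seq_len(nc)] <- mask
  NR <- nrow(big); NC <- ncol(big)
  dil <- matrix(FALSE, NR, NC)
  for (k in seq_len(nrow(offs))) {
    di <- offs$di[k]; dj <- offs$dj[k]
    sr <- max(1, 1 - di):min(NR, NR - di)
    sc <- max(1, 1 - dj):min(NC, NC - dj)
    dil[sr + di, sc + dj] <- dil[sr + di, sc + dj] | big[sr, sc]
  }
  er <- matrix(TRUE, NR, NC)
  for (k in seq_len(nrow(offs))) {
    di <- offs$di[k]; dj <- offs$dj[k]
    shifted <- matrix(FALSE, NR, NC)
    sr <- max(1, 1 - di):min(NR, NR - di)
    sc <- max(1, 1 - dj):min(NC, NC - dj)
    shifted[sr, sc] <- dil[sr + di, sc + dj]
    er <- er & shifted
  }
  er[pad + seq_len(nr), pad + seq_len(nc)]
}

# Exhaustive nearest-seed scan: for each gap pixel compare against every
# seed; ties by lowest column-major 0-based linear index.
oracle_nn_fill <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  seeds <- which(!is.na(m))
  si <- (seeds - 1) %% nr
  sj <- (seeds - 1) %/% nr
  out <- m
  for (idx in which(is.na(m))) {
    i <- (idx - 1) %% nr
    j <- (idx - 1) %/% nr
    sq <- (si - i)^2 + (sj - j)^2
    best <- which(sq == min(sq))
    pick <- best[which.min(seeds[best])]
    out[idx] <- m[seeds[pick]]
  }
  out
}

# small standard layout used across tests
demo_layout <- function(n_rows = 2, trees_per_row = 3, pattern = "square",
                        blocks_per_row = 1, row_spacing = 6,
                        tree_spacing = 5, ...) {
  orchard_layout(
    c(0, 0), c((trees_per_row - 1) * tree_spacing, 0),
    c(0, (n_rows - 1) * row_spacing + if (n_rows == 1) row_spacing else 0),
    n_rows = n_rows, trees_per_row = trees_per_row,
    row_spacing = row_spacing, tree_spacing = tree_spacing,
    pattern = pattern, blocks_per_row = blocks_per_row, ...
  )
}

# closing element diameter equivalent to a 0.8 m disk at this resolution
closing_px_for <- function(pixel_size) max(1, round(0.8 / pixel_size))
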