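#' Nearest-neighbour resampling onto a target grid
#'
#' Each target cell takes the value of the source cell containing the target
#' cell's center (the nearest source cell center; boundary points resolve to
#' the cell to the right/below under the half-open cell convention). Target
#' cells whose centers fall outside the source extent become nodata (`FALSE`
#' for masks). Used to harmonise input layers of differing resolution before
#' stacking.
#'
#' @param layer a categorical, continuous or mask layer.
#' @param target a `grid_spec` overlapping the source extent.
#' @return A layer of the same type on `target`.
#' @export
resample_nearest <- function(layer, target) {
  stopifnot(inherits(layer, "hm_layer"), inherits(target, "grid_spec"))
  src <- layer$grid
  if (grids_aligned(src, target)) {
    out <- layer
    out$grid <- target
    return(out)
  }
  xs <- target$origin_x + (seq_len(target$n_cols) - 0.5) * target$cell_size
  ys <- target$origin_y - (seq_len(target$n_rows) - 0.5) * target$cell_size
  cols <- floor((xs - src$origin_x) / src$cell_size) + 1
  rows <- floor((src$origin_y - ys) / src$cell_size) + 1
  cols[cols < 1 | cols > src$n_cols] <- NA_integer_
  rows[rows < 1 | rows > src$n_rows] <- NA_integer_
  if (all(is.na(rows)) || all(is.na(cols)))
    stop("source and target extents do not overlap")
  # index matrix: out[i, j] = src[rows[i], cols[j]]
  m <- layer$data[rows, cols, drop = FALSE]
  m[is.na(rows), ] <- NA
  m[, is.na(cols)] <- NA
  dimnames(m) <- NULL
  if (inherits(layer, "categorical_layer"))
    categorical_layer(target, m, layer$legend_id)
  else if (inherits(layer, "continuous_layer"))
    continuous_layer(target, m, layer$units)
  else
    binary_mask(target, m)
}

# Truncated box sum: S[i,j] = sum of m over the window of half-width r
# centred at (i,j), clipped at the grid edge. Summed-area-table based.
box_sum <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 1, nc + 1)
  cm <- matrix(apply(m, 2, cumsum), nr, nc)          # column cumsums
  p[-1, -1] <- matrix(t(apply(cm, 1, cumsum)), nr, nc)  # then row cumsums
  r1 <- pmax(seq_len(nr) - r, 1); r2 <- pmin(seq_len(nr) + r, nr)
  c1 <- pmax(seq_len(nc) - r, 1); c2 <- pmin(seq_len(nc) + r, nc)
  p[r2 + 1, c2 + 1, drop = FALSE] - p[r1, c2 + 1, drop = FALSE] -
    p[r2 + 1, c1, drop = FALSE] + p[r1, c1, drop = FALSE]
}

#' Focal modal (majority) filter
#'
#' Replaces each cell by the most frequent non-nodata code within the square
#' window of half-width `radius_cells` (edge windows are truncated at the
#' grid boundary). Ties break to the smallest code; windows containing only
#' nodata yield nodata. This is the operation used to expand coarse wetland
#' mapping outwards.
#'
#' @param layer a `categorical_layer`.
#' @param radius_cells window half-width in cells (>= 1); the window is
#'   `(2 * radius_cells + 1)` cells on a side.
#' @return A `categorical_layer` on the same grid and legend.
#' @export
modal_filter <- function(layer, radius_cells) {
  stopifnot(inherits(layer, "categorical_layer"))
  if (length(radius_cells) != 1 || is.na(radius_cells) || radius_cells < 1)
    stop("radius_cells must be a positive integer")
  r <- as.integer(radius_cells)
  codes <- sort(unique(as.vector(layer$data)))
  codes <- codes[!is.na(codes)]
  out <- matrix(NA_integer_, nrow(layer$data), ncol(layer$data))
  if (length(codes) > 0) {
    best <- matrix(0, nrow(layer$data), ncol(layer$data))
    for (cd in codes) {  # ascending: strict > keeps the smallest code on ties
      cnt <- box_sum((!is.na(layer$data)) & layer$data == cd, r)
      upd <- cnt > best
      out[upd] <- cd
      best[upd] <- cnt[upd]
    }
  }
  categorical_layer(layer$grid, out, layer$legend_id)
}

# Integer window offsets within Euclidean distance radius_m of the origin,
# distances measured center-to-center in map units.
disk_offsets <- function(radius_m, cell_size) {
  r <- floor(radius_m / cell_size + 1e-9)
  dr <- rep(-r:r, each = 2 * r + 1)
  dc <- rep(-r:r, times = 2 * r + 1)
  keep <- (dr^2 + dc^2) * cell_size^2 <= radius_m^2 + 1e-6
  cbind(dr = dr[keep], dc = dc[keep])
}

#' Euclidean binary dilation
#'
#' Sets every cell whose center lies within `radius_m` (map units,
#' center-to-center) of a set cell of the input; input cells remain set.
#' This is the buffering primitive behind the 500 m urban boundary used for
#' rural gardens and the 300 m positional-error buffer used in validation.
#'
#' @param mask a `binary_mask`.
#' @param radius_m positive buffer radius in map units.
#' @return A `binary_mask`.
#' @export
binary_dilate <- function(mask, radius_m) {
  stopifnot(inherits(mask, "binary_mask"))
  if (length(radius_m) != 1 || is.na(radius_m) || radius_m <= 0)
    stop("radius_m must be positive")
  f <- mask$data
  off <- disk_offsets(radius_m, mask$grid$cell_size)
  nr <- nrow(f); nc <- ncol(f)
  out <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(off))) {
    dr <- off[k, 1]; dc <- off[k, 2]
    sr <- max(1, 1 - dr):min(nr, nr - dr)   # dest rows receiving src rows sr + dr
    sc <- max(1, 1 - dc):min(nc, nc - dc)
    out[sr, sc] <- out[sr, sc] | f[sr + dr, sc + dc]
  }
  binary_mask(mask$grid, out)
}

#' Cells within a Euclidean radius of a cell center
#'
#' Enumerates all in-grid cells whose centers lie within `radius_m` of the
#' center of (`center_row`, `center_col`), clipping at grid edges. Shared
#' helper for buffered validation lookups.
#'
#' @param grid a `grid_spec` (a layer is also accepted).
#' @param center_row,center_col 1-based cell indices; must be inside the grid.
#' @param radius_m radius in map units; below `cell_size` only the center
#'   cell is returned.
#' @return Two-column integer matrix (`row`, `col`).
#' @export
disk_cells <- function(grid, center_row, center_col, radius_m) {
  if (inherits(grid, "hm_layer")) grid <- grid$grid
  stopifnot(inherits(grid, "grid_spec"))
  if (center_row < 1 || center_row > grid$n_rows ||
      center_col < 1 || center_col > grid$n_cols)
    stop("center cell is outside the grid")
  off <- disk_offsets(max(radius_m, 0), grid$cell_size)
  rr <- center_row + off[, 1]
  cc <- center_col + off[, 2]
  keep <- rr >= 1 & rr <= grid$n_rows & cc >= 1 & cc <= grid$n_cols
  cbind(row = as.integer(rr[keep]), col = as.integer(cc[keep]))
}
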