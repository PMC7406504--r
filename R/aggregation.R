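#' Fractional aggregation of a habitat map to a coarser grid
#'
#' Coarsens a fine categorical map by an integer `factor`, reporting for each
#' coarse cell the fraction of its *non-nodata* fine cells carrying each
#' code, plus `valid_fraction`, the share of fine cells that are non-nodata.
#' Class fractions therefore sum to 1 on every coarse cell with
#' `valid_fraction > 0`; on all-nodata blocks fractions are nodata. When the
#' fine dimensions are not divisible by `factor`, edge blocks are computed
#' over the truncated block and the result is flagged
#' (`edge_truncated = TRUE`).
#'
#' @param map a `categorical_layer` (e.g. a Level-2 habitat map).
#' @param factor integer block size >= 2.
#' @return An object of class `fractional_stack`: list with `grid` (coarse
#'   `grid_spec`), `codes`, `fractions` (3-d array coarse_rows x coarse_cols
#'   x code), `valid_fraction` matrix, `counts` array of fine-cell counts,
#'   `block_size` matrix of fine cells per block, and `edge_truncated`.
#' @export
fractional_aggregate <- function(map, factor) {
  stopifnot(inherits(map, "categorical_layer"))
  if (length(factor) != 1 || is.na(factor) || factor < 2)
    stop("aggregation factor must be an integer >= 2")
  factor <- as.integer(factor)
  g <- map$grid
  nr2 <- ceiling(g$n_rows / factor)
  nc2 <- ceiling(g$n_cols / factor)
  truncated <- (g$n_rows %% factor != 0) || (g$n_cols %% factor != 0)
  coarse <- grid_spec(nr2, nc2, cell_size = g$cell_size * factor,
                      origin_x = g$origin_x, origin_y = g$origin_y,
                      nodata = g$nodata)
  bi <- (seq_len(g$n_rows) - 1L) %/% factor + 1L
  bj <- (seq_len(g$n_cols) - 1L) %/% factor + 1L
  block <- matrix(bi, g$n_rows, g$n_cols) +
    (matrix(bj, g$n_rows, g$n_cols, byrow = TRUE) - 1L) * nr2
  codes <- sort(unique(as.vector(map$data)))
  codes <- codes[!is.na(codes)]
  nblocks <- nr2 * nc2
  block_size <- matrix(tabulate(block, nblocks), nr2, nc2)
  valid <- matrix(tabulate(block[!is.na(map$data)], nblocks), nr2, nc2)
  counts <- array(0L, dim = c(nr2, nc2, length(codes)),
                  dimnames = list(NULL, NULL, codes))
  for (k in seq_along(codes)) {
    sel <- !is.na(map$data) & map$data == codes[k]
    counts[, , k] <- matrix(tabulate(block[sel], nblocks), nr2, nc2)
  }
  fractions <- array(NA_real_, dim = dim(counts), dimnames = dimnames(counts))
  vf <- valid
  vf[vf == 0] <- NA_integer_
  for (k in seq_along(codes)) fractions[, , k] <- counts[, , k] / vf
  structure(list(grid = coarse, codes = codes, fractions = fractions,
                 counts = counts, valid_fraction = valid / block_size,
                 block_size = block_size, factor = factor,
                 edge_truncated = truncated),
            class = "fractional_stack")
}

#' @export
print.fractional_stack <- function(x, ...) {
  cat(sprintf("<fractional_stack> %d x %d coarse cells, %d classes, factor %d%s\n",
              x$grid$n_rows, x$grid$n_cols, length(x$codes), x$factor,
              if (x$edge_truncated) " (edge blocks truncated)" else ""))
  invisible(x)
}

#' Extract one class's fraction layer from a fractional stack
#' @param fs a `fractional_stack`.
#' @param code habitat code.
#' @return `continuous_layer` of fractions in `[0, 1]`.
#' @export
fraction_layer <- function(fs, code) {
  k <- match(code, fs$codes)
  if (is.na(k)) stop("code ", code, " not present in the fractional stack")
  continuous_layer(fs$grid, fs$fractions[, , k, drop = TRUE], units = "fraction")
}

#' Majority-class coarsening
#'
#' Per coarse block, the code with the largest fine-cell count; ties break
#' to the smallest code; all-nodata blocks are nodata. Consistent by
#' construction with the argmax of [fractional_aggregate()] under the same
#' tie rule.
#'
#' @inheritParams fractional_aggregate
#' @return A `categorical_layer` on the coarse grid.
#' @export
majority_coarsen <- function(map, factor) {
  fs <- fractional_aggregate(map, factor)
  out <- matrix(NA_integer_, fs$grid$n_rows, fs$grid$n_cols)
  best <- matrix(0L, fs$grid$n_rows, fs$grid$n_cols)
  for (k in seq_along(fs$codes)) {       # ascending codes: ties keep smallest
    cnt <- fs$counts[, , k]
    upd <- cnt > best
    out[upd] <- fs$codes[k]
    best[upd] <- cnt[upd]
  }
  categorical_layer(fs$grid, out, map$legend_id)
}
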