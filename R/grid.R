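#' Grid geometry for a single-band planar raster
#'
#' A `grid_spec` describes a regular grid of square cells in a planar map
#' coordinate system: `n_rows` by `n_cols` cells of side `cell_size` (map
#' units, metres by convention), anchored at the top-left corner
#' (`origin_x`, `origin_y`). Rows increase downwards (decreasing y), columns
#' increase rightwards (increasing x); indexing is 1-based as usual in R.
#' `nodata` is the integer sentinel used on disk; in memory missing cells are
#' always `NA`.
#'
#' Two grids are *aligned* when every field except the nodata sentinel is
#' identical; all layers in a [layer_stack()] must be aligned.
#'
#' @param n_rows,n_cols positive integers, grid dimensions.
#' @param cell_size positive cell side length in map units.
#' @param origin_x,origin_y map coordinates of the top-left grid corner.
#' @param nodata integer sentinel written to / read from files.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(4, 5, cell_size = 100)
#' cell_center(g, 1, 1)  # (50, -50) relative to the default origin
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 100,
                      origin_x = 0, origin_y = n_rows * cell_size,
                      nodata = -9999L) {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1,
            n_rows >= 1, n_cols >= 1, cell_size > 0,
            is.finite(origin_x), is.finite(origin_y))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = as.numeric(cell_size),
                 origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 nodata = as.integer(nodata)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %g m/cell, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

#' Are two grids aligned?
#'
#' Aligned means identical geometry (dimensions, cell size, origin); the
#' nodata sentinel may differ.
#' @param a,b `grid_spec` objects.
#' @return logical scalar.
#' @export
grids_aligned <- function(a, b) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y))
}

#' Map coordinates of a cell center
#' @param grid a `grid_spec`.
#' @param row,col 1-based cell indices (vectorised).
#' @return list with numeric vectors `x` and `y`.
#' @export
cell_center <- function(grid, row, col) {
  list(x = grid$origin_x + (col - 0.5) * grid$cell_size,
       y = grid$origin_y - (row - 0.5) * grid$cell_size)
}

#' Cell containing a map coordinate
#'
#' Cells are half-open: a point exactly on a shared edge belongs to the cell
#' to its right / below. Points outside the grid extent yield `NA`.
#' @param grid a `grid_spec`.
#' @param x,y map coordinates (vectorised).
#' @return list with integer vectors `row` and `col` (`NA` when off-grid).
#' @export
cell_of <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1
  bad <- row < 1 | row > grid$n_rows | col < 1 | col > grid$n_cols
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

new_layer <- function(grid, data, class, extra = list()) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(data),
            nrow(data) == grid$n_rows, ncol(data) == grid$n_cols)
  structure(c(list(grid = grid), extra, list(data = data)),
            class = c(class, "hm_layer"))
}

#' Raster layer containers
#'
#' Three thin S3 containers hold the pipeline's layers on a shared
#' [grid_spec()]:
#' * `categorical_layer()` — integer codes referencing a registered legend
#'   (`legend_id`), `NA` for nodata;
#' * `continuous_layer()` — finite numeric values with free-text `units`,
#'   `NA` for nodata;
#' * `binary_mask()` — logical flags (no nodata state; `NA` inputs are
#'   coerced to `FALSE`).
#'
#' @param grid a `grid_spec`.
#' @param codes integer matrix of legend codes (`NA` = nodata).
#' @param legend_id name of the legend the codes refer to.
#' @param values numeric matrix (`NA` = nodata).
#' @param units free-text unit string, e.g. `"heads/km2"`.
#' @param flags logical matrix.
#' @return A layer object inheriting from `hm_layer`.
#' @name layers
NULL

#' @rdname layers
#' @export
categorical_layer <- function(grid, codes, legend_id) {
  storage.mode(codes) <- "integer"
  new_layer(grid, codes, "categorical_layer", list(legend_id = legend_id))
}

#' @rdname layers
#' @export
continuous_layer <- function(grid, values, units = "") {
  storage.mode(values) <- "double"
  if (any(is.infinite(values))) stop("continuous layer values must be finite or NA")
  new_layer(grid, values, "continuous_layer", list(units = units))
}

#' @rdname layers
#' @export
binary_mask <- function(grid, flags) {
  flags[is.na(flags)] <- FALSE
  storage.mode(flags) <- "logical"
  new_layer(grid, flags, "binary_mask")
}

#' @export
print.hm_layer <- function(x, ...) {
  kind <- class(x)[1]
  n_valid <- sum(!is.na(x$data))
  cat(sprintf("<%s> %d x %d (%d valid cells)", kind,
              x$grid$n_rows, x$grid$n_cols, n_valid))
  if (kind == "categorical_layer") cat(sprintf(", legend '%s'", x$legend_id))
  if (kind == "continuous_layer" && nzchar(x$units)) cat(sprintf(" [%s]", x$units))
  cat("\n")
  invisible(x)
}

#' Named stack of aligned layers
#'
#' The classifier's sole input: a named collection of layers sharing one
#' grid. Names must be unique and non-empty.
#'
#' @param ... named layers, or a single named list of layers.
#' @return An object of class `layer_stack` (a named list).
#' @export
layer_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) && !inherits(layers[[1]], "hm_layer"))
    layers <- layers[[1]]
  if (length(layers) == 0) stop("layer_stack needs at least one layer")
  nm <- names(layers)
  if (is.null(nm) || any(!nzchar(nm))) stop("all stack layers must be named")
  if (anyDuplicated(nm)) stop("duplicate layer names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  for (l in layers) stopifnot(inherits(l, "hm_layer"))
  g <- layers[[1]]$grid
  for (i in seq_along(layers))
    if (!grids_aligned(g, layers[[i]]$grid))
      stop("layer '", nm[i], "' is not aligned with the stack grid")
  structure(layers, class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  g <- x[[1]]$grid
  cat(sprintf("<layer_stack> %d layers on %d x %d grid: %s\n",
              length(x), g$n_rows, g$n_cols,
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Fetch a layer from a stack by name
#' @param stack a `layer_stack`.
#' @param name layer name.
#' @param context optional string used in the error message (e.g. rule id).
#' @return the layer.
#' @export
stack_layer <- function(stack, name, context = NULL) {
  if (!name %in% names(stack)) {
    msg <- sprintf("layer '%s' not found in stack", name)
    if (!is.null(msg) && !is.null(context)) msg <- paste0(msg, " (", context, ")")
    stop(msg, call. = FALSE)
  }
  stack[[name]]
}
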