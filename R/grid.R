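# Minimal single-frame raster container. All layers in an analysis share one
# grid; there is no CRS handling -- inputs must already be co-registered in a
# common projected frame (coordinates in map units, typically metres).

#' Create a raster grid
#'
#' A `pheno_grid` is a numeric or integer matrix with a georeferencing
#' contract: row 1 is the northernmost row, `xll`/`yll` locate the lower-left
#' corner of the grid, and every cell is square with side `cellsize` map
#' units. `NA` cells are nodata.
#'
#' @param values numeric or integer matrix (row 1 = top/north).
#' @param xll,yll coordinates of the lower-left corner, map units.
#' @param cellsize cell side length, map units (> 0).
#' @return An object of class `pheno_grid`.
#' @export
pheno_grid <- function(values, xll = 0, yll = 0, cellsize = 1) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a single positive number")
  structure(values,
            xll = as.numeric(xll), yll = as.numeric(yll),
            cellsize = as.numeric(cellsize),
            class = c("pheno_grid", class(values)))
}

#' @export
print.pheno_grid <- function(x, ...) {
  cat(sprintf("<pheno_grid> %d x %d cells, cellsize %g, origin (%g, %g)\n",
              nrow(x), ncol(x), attr(x, "cellsize"),
              attr(x, "xll"), attr(x, "yll")))
  cat(sprintf("  values: [%s], %d nodata cell(s)\n",
              paste(signif(range(x, na.rm = TRUE), 4), collapse = ", "),
              sum(is.na(x))))
  invisible(x)
}

grid_template <- function(g) {
  list(xll = attr(g, "xll"), yll = attr(g, "yll"),
       cellsize = attr(g, "cellsize"), nrow = nrow(g), ncol = ncol(g))
}

same_grid <- function(a, b) {
  ta <- grid_template(a); tb <- grid_template(b)
  isTRUE(all.equal(ta, tb, tolerance = 1e-9))
}

#' Map point coordinates to grid cells
#'
#' Uses half-open pixel intervals: a point belongs to the cell whose x
#' interval is `[x0, x0 + cellsize)` and y interval `[y0, y0 + cellsize)`
#' counted from the lower-left corner, so points on a shared edge are
#' assigned deterministically to exactly one cell. Points outside the grid
#' extent get `NA` row/col.
#'
#' @param grid a [pheno_grid()].
#' @param x,y numeric vectors of map coordinates.
#' @return data.frame with columns `row`, `col` (`NA` outside the extent).
#' @export
cell_from_xy <- function(grid, x, y) {
  cs <- attr(grid, "cellsize")
  ix <- floor((x - attr(grid, "xll")) / cs)   # 0-based col
  iy <- floor((y - attr(grid, "yll")) / cs)   # 0-based row from bottom
  col <- ix + 1L
  row <- nrow(grid) - iy                      # convert to top-origin row
  bad <- col < 1L | col > ncol(grid) | row < 1L | row > nrow(grid) |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Cell-center coordinates of every grid cell
#'
#' @param grid a [pheno_grid()].
#' @return data.frame `x`, `y` in column-major cell order.
#' @export
xy_from_cell <- function(grid) {
  cs <- attr(grid, "cellsize")
  col <- rep(seq_len(ncol(grid)), each = nrow(grid))
  row <- rep(seq_len(nrow(grid)), ncol(grid))
  data.frame(x = attr(grid, "xll") + (col - 0.5) * cs,
             y = attr(grid, "yll") + (nrow(grid) - row + 0.5) * cs)
}

#' Cell area in square kilometres
#' @param grid a [pheno_grid()].
#' @return scalar, km^2 per cell (cellsize is assumed to be in metres).
#' @export
cell_area_km2 <- function(grid) attr(grid, "cellsize")^2 / 1e6
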