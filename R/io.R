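# Plain-text I/O: ESRI ASCII grid for rasters, CSV for ignition points,
# YAML for pipeline configuration. ASCII grid is the interchange format
# because it is plain text and read by standard GIS tooling; all layers of
# an analysis are assumed to sit in one projected coordinate frame.

#' Write a grid as ESRI ASCII raster (.asc)
#'
#' @param grid a [pheno_grid()].
#' @param path output file path.
#' @param nodata numeric value written for `NA` cells (default -9999).
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "pheno_grid"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(grid)),
    sprintf("nrows %d", nrow(grid)),
    sprintf("xllcorner %.10g", attr(grid, "xll")),
    sprintf("yllcorner %.10g", attr(grid, "yll")),
    sprintf("cellsize %.10g", attr(grid, "cellsize")),
    sprintf("NODATA_value %.10g", nodata)), con)
  m <- unclass(grid)
  m[is.na(m)] <- nodata
  write.table(format(m, scientific = FALSE, trim = TRUE, digits = 15),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII raster (.asc)
#'
#' @param path file path.
#' @param integer logical; coerce cell values to integer.
#' @return a [pheno_grid()]; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path, integer = FALSE) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "[[:space:]]+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys))
    stop("malformed ASCII grid header in ", path)
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  body <- scan(path, skip = sum(keys %in% c(need, "nodata_value")),
               quiet = TRUE)
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  if (length(body) != nr * nc)
    stop("ASCII grid body has ", length(body), " values, expected ", nr * nc)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  if (integer) storage.mode(m) <- "integer"
  pheno_grid(m, xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
             cellsize = vals[["cellsize"]])
}

#' Read fire-ignition points from CSV
#'
#' Expects a header `x,y` (a `date` column is optional and carried along).
#'
#' @param path CSV file path.
#' @return an `ignition_set`: data.frame with columns `x`, `y` and
#'   optionally `date`.
#' @export
read_ignitions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df)))
    stop("ignition CSV must have columns `x` and `y`: ", path)
  if (nrow(df) == 0L)
    warning("ignition file ", path, " contains a header but no points")
  ignition_set(df$x, df$y, date = if ("date" %in% names(df)) df$date else NULL)
}

#' @rdname read_ignitions
#' @param fires an `ignition_set`.
#' @export
write_ignitions <- function(fires, path) {
  df <- as.data.frame(unclass(fires), stringsAsFactors = FALSE)
  if (is.null(df$date)) df$date <- NA
  utils::write.csv(df[, c("x", "y", "date")], path, row.names = FALSE)
  invisible(path)
}

#' Construct a set of ignition points
#'
#' @param x,y numeric map coordinates (finite).
#' @param date optional vector of dates (carried, not interpreted).
#' @return data.frame of class `ignition_set`.
#' @export
ignition_set <- function(x, y, date = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) && (any(!is.finite(x)) || any(!is.finite(y))))
    stop("ignition coordinates must be finite")
  df <- data.frame(x = x, y = y)
  if (!is.null(date)) df$date <- date
  class(df) <- c("ignition_set", "data.frame")
  df
}

#' @export
print.ignition_set <- function(x, ...) {
  cat(sprintf("<ignition_set> %d point(s)\n", nrow(x)))
  if (nrow(x)) {
    cat(sprintf("  x: [%g, %g]  y: [%g, %g]\n",
                min(x$x), max(x$x), min(x$y), max(x$y)))
  }
  invisible(x)
}
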