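#' Lightweight georeferenced grid
#'
#' A minimal raster container: a numeric matrix plus an affine geometry
#' (lower-left origin and square cell size). Row 1 of the matrix is the
#' southernmost row; `NA` marks nodata. All layers of a study region share
#' one geometry, so grids can be stacked by name in a plain list.
#'
#' @param values numeric matrix (rows = south-to-north, cols = west-to-east).
#' @param origin numeric length-2, (x, y) of the lower-left corner, in the
#'   projected unit (km by default throughout the package).
#' @param cell_size cell edge length in the same unit.
#' @return an object of class `env_grid`.
#' @export
env_grid <- function(values, origin = c(0, 0), cell_size = 1) {
  stopifnot(is.matrix(values), length(origin) == 2, cell_size > 0)
  structure(list(values = values, origin = as.numeric(origin),
                 cell_size = as.numeric(cell_size)),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<env_grid> %d x %d cells, cell size %g, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  values: [%g, %g], %d nodata\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.env_grid <- function(x) dim(x$values)

#' @export
as.matrix.env_grid <- function(x, ...) x$values

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    all(abs(a$origin - b$origin) < tol) &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Map point coordinates to grid cells
#'
#' Cells are half-open squares `[x0 + j*cs, x0 + (j+1)*cs)`; indices are
#' 0-based `(row, col)` counted from the lower-left corner, with a linear
#' cell id `row * ncol + col`. Points outside the grid extent are an error.
#'
#' @param x,y point coordinates.
#' @param grid an `env_grid` (or anything with `origin`, `cell_size`,
#'   and `values`) providing the geometry.
#' @return data.frame with columns `row`, `col` (0-based) and `cell` (id).
#' @export
cell_of <- function(x, y, grid) {
  cs <- grid$cell_size
  col <- floor((x - grid$origin[1]) / cs)
  row <- floor((y - grid$origin[2]) / cs)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  bad <- which(col < 0 | col >= nc | row < 0 | row >= nr)
  if (length(bad))
    stop("points outside grid extent: ", paste(bad, collapse = ", "))
  data.frame(row = row, col = col, cell = row * nc + col)
}

#' Coordinates of cell centres
#'
#' @param row,col 0-based cell indices.
#' @param grid geometry provider as in [cell_of()].
#' @return data.frame with `x`, `y` of the cell centres.
#' @export
cell_center <- function(row, col, grid) {
  cs <- grid$cell_size
  data.frame(x = grid$origin[1] + (col + 0.5) * cs,
             y = grid$origin[2] + (row + 0.5) * cs)
}

#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text `.asc` with the standard 6-line header; rows are written
#' north-to-south as the format requires. `NA` becomes `NODATA_value`.
#'
#' @param grid an `env_grid`.
#' @param path output file path.
#' @param nodata sentinel written for `NA` cells.
#' @param digits significant digits for cell values.
#' @export
write_asc <- function(grid, path, nodata = -9999, digits = 10) {
  v <- grid$values
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", grid$origin[1]),
           sprintf("yllcorner %.10g", grid$origin[2]),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %g", nodata))
  v[is.na(v)] <- nodata
  rows <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path `.asc` file written by [write_asc()] or compatible tools.
#' @return an `env_grid`; nodata cells are `NA`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- tolower(vapply(hdr, `[`, "", 1L))
  val <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(val) <- key
  nc <- as.integer(val[["ncols"]]); nr <- as.integer(val[["nrows"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  stopifnot(length(body) == nc * nr)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == val[["nodata_value"]]] <- NA
  env_grid(m[rev(seq_len(nr)), , drop = FALSE],
           origin = c(val[["xllcorner"]], val[["yllcorner"]]),
           cell_size = val[["cellsize"]])
}

# Separable Gaussian blur with reflecting edges; used to make spatially
# autocorrelated noise fields without any raster dependency.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  pad_filter <- function(v) {
    n <- length(v)
    padded <- c(v[pmin(half:1, n)], v, v[pmax(n - (1:half) + 1, 1)])
    as.numeric(stats::filter(padded, k, sides = 2))[(half + 1):(half + n)]
  }
  m2 <- apply(m, 2L, pad_filter)
  t(apply(m2, 1L, pad_filter))
}

# Smooth standard-normal random field over an nr x nc grid.
random_field <- function(nr, nc, sigma) {
  f <- gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
  (f - mean(f)) / stats::sd(f)
}
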