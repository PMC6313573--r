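#' Raster field on the reference grid
#'
#' A `raster_field` holds values on the regular analysis grid (default
#' 3 x 3 km cells) together with two logical masks: `mask_missing` for cells
#' with no usable input data (e.g. municipalities without water measurements)
#' and `mask_invalid` for cells where the estimate is flagged as not relevant
#' (e.g. high-altitude, sparsely populated areas for air). Coordinates are
#' planar, in km, with cell-center georeferencing: cell (i, j) is centered at
#' ((j - 0.5) * cell, (i - 0.5) * cell).
#'
#' @param values numeric matrix, `ny` rows (y) by `nx` columns (x).
#' @param cell_size_km cell edge length in km (> 0).
#' @param mask_missing,mask_invalid logical matrices of the same shape;
#'   default all `FALSE`.
#' @return object of class `raster_field`.
#' @export
raster_field <- function(values, cell_size_km = 3,
                         mask_missing = NULL, mask_invalid = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric")
  if (cell_size_km <= 0) stop("cell_size_km must be > 0")
  dm <- dim(values)
  if (is.null(mask_missing)) mask_missing <- matrix(FALSE, dm[1], dm[2])
  if (is.null(mask_invalid)) mask_invalid <- matrix(FALSE, dm[1], dm[2])
  stopifnot(identical(dim(mask_missing), dm), identical(dim(mask_invalid), dm))
  ok <- !(mask_missing | mask_invalid)
  if (any(!is.finite(values[ok]))) {
    stop("non-finite values in unmasked cells")
  }
  structure(
    list(values = values, cell_size_km = cell_size_km,
         mask_missing = mask_missing, mask_invalid = mask_invalid),
    class = "raster_field"
  )
}

#' @export
print.raster_field <- function(x, ...) {
  dm <- dim(x$values)
  cat(sprintf("<raster_field %d x %d cells, %.3g km cells, %d missing, %d invalid>\n",
              dm[1], dm[2], x$cell_size_km,
              sum(x$mask_missing), sum(x$mask_invalid)))
  invisible(x)
}

#' @export
dim.raster_field <- function(x) dim(x$values)

#' Cell-center coordinates of a raster field
#'
#' @param x a `raster_field`, or a list with `grid_nx`, `grid_ny`,
#'   `cell_size_km` (a scenario config).
#' @return data.frame with `x_km`, `y_km`, `row`, `col`, one row per cell in
#'   column-major order (matching `as.vector` of the value matrix).
#' @export
raster_coords <- function(x) {
  if (inherits(x, "raster_field")) {
    ny <- nrow(x$values); nx <- ncol(x$values); h <- x$cell_size_km
  } else {
    ny <- x$grid_ny; nx <- x$grid_nx; h <- x$cell_size_km
  }
  row <- rep(seq_len(ny), times = nx)
  col <- rep(seq_len(nx), each = ny)
  data.frame(x_km = (col - 0.5) * h, y_km = (row - 0.5) * h,
             row = row, col = col)
}

#' Serialize a raster field to CSV (long format)
#'
#' One row per cell: row, col, x_km, y_km, value, mask_missing, mask_invalid.
#' Plain-text stand-in for a georeferenced raster format.
#'
#' @param x a `raster_field`
#' @param path output file
#' @export
write_raster_csv <- function(x, path) {
  co <- raster_coords(x)
  co$value <- as.vector(x$values)
  co$mask_missing <- as.vector(x$mask_missing)
  co$mask_invalid <- as.vector(x$mask_invalid)
  utils::write.csv(co, path, row.names = FALSE)
  invisible(path)
}

#' Read a raster field written by [write_raster_csv()]
#'
#' @param path CSV file
#' @param cell_size_km cell size; if `NULL`, inferred from coordinates.
#' @return a `raster_field`
#' @export
read_raster_csv <- function(path, cell_size_km = NULL) {
  d <- utils::read.csv(path)
  ny <- max(d$row); nx <- max(d$col)
  if (is.null(cell_size_km)) cell_size_km <- 2 * min(d$x_km)
  v <- matrix(NA_real_, ny, nx); mm <- mi <- matrix(FALSE, ny, nx)
  idx <- cbind(d$row, d$col)
  v[idx] <- d$value
  mm[idx] <- as.logical(d$mask_missing)
  mi[idx] <- as.logical(d$mask_invalid)
  v[mm | mi] <- ifelse(is.finite(v[mm | mi]), v[mm | mi], 0)
  raster_field(v, cell_size_km, mm, mi)
}
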