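#' Lightweight in-memory raster
#'
#' A minimal north-up raster container used throughout the package: a numeric
#' (or integer) matrix with a cell size in metres and the projected coordinates
#' of the upper-left corner. Row 1 is the northernmost row; missing cells are
#' `NA`. All package operations (aggregation, terrain analysis, scene
#' simulation) work on this container; ESRI ASCII grid I/O is provided by
#' [write_asc()] / [read_asc()].
#'
#' @param values numeric matrix, row 1 = north.
#' @param cell_size cell edge length in metres (> 0).
#' @param origin length-2 numeric, projected (x, y) of the upper-left corner.
#' @param label free-text band semantics (e.g. "lst_k", "elevation_m").
#' @return An object of class `cc_raster`.
#' @export
cc_raster <- function(values, cell_size, origin = c(0, 0), label = "") {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("`origin` must be two finite coordinates")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), label = as.character(label)[1]),
    class = "cc_raster"
  )
}

#' @export
print.cc_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<cc_raster> %d x %d @ %g m%s\n", nrow(v), ncol(v), x$cell_size,
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  cat(sprintf("  origin (UL): %g, %g   NA cells: %d/%d\n",
              x$origin[1], x$origin[2], sum(is.na(v)), length(v)))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  if (all(is.finite(rng))) cat(sprintf("  range: %g .. %g\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.cc_raster <- function(x) dim(x$values)

is_cc_raster <- function(x) inherits(x, "cc_raster")

#' Projected coordinates of every cell center
#'
#' @param r a [cc_raster()].
#' @return data.frame with columns `x`, `y` (metres), in matrix element order
#'   (column-major, matching `as.vector(r$values)`).
#' @export
cell_centers <- function(r) {
  stopifnot(is_cc_raster(r))
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cell_size
  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), times = nc)
  data.frame(x = r$origin[1] + (col - 0.5) * cs,
             y = r$origin[2] - (row - 0.5) * cs)
}

# shared grid check (same dims, cell size, origin)
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

# integer block factor between a fine raster and a coarser target cell size
block_factor <- function(fine_cell_size, target_cell_size, what = "grids") {
  f <- target_cell_size / fine_cell_size
  if (abs(f - round(f)) > 1e-9 || round(f) < 1)
    stop(sprintf("%s do not nest: %g m is not an integer multiple of %g m",
                 what, target_cell_size, fine_cell_size))
  as.integer(round(f))
}

# Apply `fun` over f x f blocks of a matrix; trailing partial blocks are kept
# and simply contain fewer subcells. Returns a ceiling(nr/f) x ceiling(nc/f)
# matrix.
block_apply <- function(m, f, fun) {
  nr <- nrow(m); nc <- ncol(m)
  br <- ceiling(nr / f); bc <- ceiling(nc / f)
  out <- matrix(NA_real_, br, bc)
  for (i in seq_len(br)) {
    ri <- ((i - 1L) * f + 1L):min(i * f, nr)
    for (j in seq_len(bc)) {
      ci <- ((j - 1L) * f + 1L):min(j * f, nc)
      out[i, j] <- fun(m[ri, ci])
    }
  }
  out
}

#' Block-mean resampling to a coarser, nesting grid
#'
#' Aggregates a fine raster to a coarser cell size by averaging the non-missing
#' subcells of each block (the convention used to bring 30 m thermal data onto
#' a 90 m analysis grid). Blocks whose subcells are all missing become `NA`.
#' Trailing partial blocks at the south/east edge are averaged over the
#' subcells they do contain.
#'
#' @param r fine-resolution [cc_raster()].
#' @param target_cell_size coarser cell size; must be an integer multiple of
#'   `r$cell_size`.
#' @return a `cc_raster` at the target resolution, same origin.
#' @export
resample_mean <- function(r, target_cell_size) {
  stopifnot(is_cc_raster(r))
  f <- block_factor(r$cell_size, target_cell_size)
  vals <- block_apply(r$values, f, function(b) {
    b <- b[!is.na(b)]
    if (length(b) == 0L) NA_real_ else mean(b)
  })
  cc_raster(vals, target_cell_size, r$origin, r$label)
}

#' Write / read ESRI ASCII grids
#'
#' Plain-text raster exchange format (readable by GDAL, QGIS, ArcGIS). Rows are
#' written north to south; `NA` maps to the declared `NODATA_value`.
#'
#' @param r a [cc_raster()].
#' @param path file path (conventionally `.asc`).
#' @param nodata sentinel written for missing cells.
#' @param digits significant digits written.
#' @return `write_asc` returns `path` invisibly; `read_asc` returns a
#'   `cc_raster`.
#' @export
write_asc <- function(r, path, nodata = -9999, digits = 10) {
  stopifnot(is_cc_raster(r))
  v <- r$values
  nr <- nrow(v); nc <- ncol(v); cs <- r$cell_size
  hdr <- c(
    sprintf("NCOLS %d", nc),
    sprintf("NROWS %d", nr),
    sprintf("XLLCORNER %.10g", r$origin[1]),
    sprintf("YLLCORNER %.10g", r$origin[2] - nr * cs),
    sprintf("CELLSIZE %.10g", cs),
    sprintf("NODATA_VALUE %.10g", nodata)
  )
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(row) paste(signif(row, digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_asc
#' @param label band semantics attached to the raster read back.
#' @export
read_asc <- function(path, label = "") {
  ln <- readLines(path)
  hdr <- ln[1:6]
  key <- toupper(sub("\\s.*$", "", hdr))
  val <- as.numeric(sub("^\\S+\\s+", "", hdr))
  names(val) <- key
  need <- c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "CELLSIZE", "NODATA_VALUE")
  if (!all(need %in% key)) stop("not an ESRI ASCII grid: ", path)
  nc <- as.integer(val["NCOLS"]); nr <- as.integer(val["NROWS"])
  body <- scan(text = paste(ln[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nr * nc) stop("ASCII grid body has wrong length: ", path)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == val["NODATA_VALUE"]] <- NA_real_
  origin <- c(val[["XLLCORNER"]], val[["YLLCORNER"]] + nr * val[["CELLSIZE"]])
  cc_raster(m, val[["CELLSIZE"]], origin, label)
}
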