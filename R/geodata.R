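#' Rasterize classed polygons onto a fine grid
#'
#' Burns land-use/land-cover polygons onto a grid by the cell-center rule: a
#' cell takes the class of the polygon containing its center; cells covered by
#' no polygon are `NA`. When several polygons cover a center, the last one in
#' the input wins (documented tie-break). This mirrors how 10 m class maps are
#' produced from urban-atlas style vector data before fraction aggregation.
#'
#' @param polygons list of polygons, each `list(class = <chr>, coords = <n x 2
#'   matrix>)` with vertices in projected metres (closed implicitly); see
#'   [read_polygons_geojson()].
#' @param grid_spec list with `nrow`, `ncol`, `cell_size`, `origin` (UL corner)
#'   describing the target grid.
#' @param classes class vocabulary (character); polygon classes outside it are
#'   rejected. Defaults to the classes present.
#' @return integer `cc_raster` of class codes with a `classes` attribute
#'   (code `k` = `classes[k]`).
#' @export
rasterize_polygons <- function(polygons, grid_spec, classes = NULL) {
  if (!length(polygons)) stop("no polygons supplied")
  cls <- vapply(polygons, function(p) p$class, character(1))
  if (is.null(classes)) classes <- unique(cls)
  if (!all(cls %in% classes))
    stop("polygon class outside vocabulary: ",
         paste(setdiff(cls, classes), collapse = ", "))
  nr <- grid_spec$nrow; nc <- grid_spec$ncol
  cs <- grid_spec$cell_size; org <- grid_spec$origin
  out <- matrix(NA_integer_, nr, nc)
  xs <- org[1] + (seq_len(nc) - 0.5) * cs
  ys <- org[2] - (seq_len(nr) - 0.5) * cs
  for (p in polygons) {
    co <- p$coords
    if (!is.matrix(co) || nrow(co) < 3L || ncol(co) != 2L ||
        any(!is.finite(co)))
      stop("invalid polygon geometry (need >= 3 finite vertices)")
    if (max(co[, 1]) < min(xs) - cs / 2 || min(co[, 1]) > max(xs) + cs / 2 ||
        max(co[, 2]) < min(ys) - cs / 2 || min(co[, 2]) > max(ys) + cs / 2) {
      warning("polygon of class '", p$class, "' lies outside the grid; ignored")
      next
    }
    ji <- which(xs >= min(co[, 1]) & xs <= max(co[, 1]))
    ii <- which(ys >= min(co[, 2]) & ys <= max(co[, 2]))
    if (!length(ji) || !length(ii)) next
    code <- match(p$class, classes)
    px <- rep(xs[ji], each = length(ii))
    py <- rep(ys[ii], times = length(ji))
    inside <- point_in_polygon(px, py, co)
    if (any(inside)) {
      sub <- out[ii, ji, drop = FALSE]
      sub[matrix(inside, nrow = length(ii))] <- code
      out[ii, ji] <- sub
    }
  }
  r <- cc_raster(out, cs, org, "lulc_class")
  attr(r, "classes") <- classes
  r
}

# even-odd ray casting; vectorized over points
point_in_polygon <- function(px, py, coords) {
  n <- nrow(coords)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- coords[i, 1]; yi <- coords[i, 2]
    xj <- coords[j, 1]; yj <- coords[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read classed polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon features carrying a `class` property.
#' Only the outer ring of each polygon is used (no holes).
#'
#' @param path GeoJSON file.
#' @return polygon list suitable for [rasterize_polygons()].
#' @export
read_polygons_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  if (is.null(g$features)) stop("not a GeoJSON FeatureCollection: ", path)
  lapply(g$features, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("only Polygon features are supported")
    ring <- f$geometry$coordinates[[1]]
    co <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    list(class = f$properties$class, coords = co)
  })
}

#' Aggregate a 10 m class map (plus tree overlay) to per-cell fractions
#'
#' For each analysis cell, the fraction of each land-cover class is the count
#' of fine subcells of that class divided by the count of non-missing subcells
#' — the integer-arithmetic definition of cover fractions. The urban-tree
#' layer is an overlay on top of the mutually exclusive classes: its fraction
#' is computed the same way but does not enter the exclusive per-cell sum
#' (trees may stand over fabric or green space).
#'
#' @param class_map integer `cc_raster` from [rasterize_polygons()] or
#'   [generate_landcover()] (must carry a `classes` attribute).
#' @param target_cell_size analysis resolution in metres, an integer multiple
#'   of the fine cell size (30 and 90 are the conventional choices).
#' @param tree_map optional 0/1 `cc_raster` on the same fine grid marking the
#'   urban-tree overlay.
#' @param tree_name name under which the overlay fraction is stored.
#' @return a `fraction_stack`: named list of fraction `cc_raster`s (one per
#'   class, plus the overlay), with attributes `classes` and `tree_name`.
#' @export
aggregate_fractions <- function(class_map, target_cell_size, tree_map = NULL,
                                tree_name = "urban_trees") {
  stopifnot(is_cc_raster(class_map))
  classes <- attr(class_map, "classes")
  if (is.null(classes)) stop("`class_map` lacks a `classes` attribute")
  f <- block_factor(class_map$cell_size, target_cell_size,
                    "class map and target grid")
  m <- class_map$values
  valid <- block_apply(m, f, function(b) sum(!is.na(b)))
  stack <- list()
  for (k in seq_along(classes)) {
    cnt <- block_apply(m, f, function(b) sum(b == k, na.rm = TRUE))
    fr <- ifelse(valid > 0, cnt / valid, NA_real_)
    stack[[classes[k]]] <- cc_raster(fr, target_cell_size, class_map$origin,
                                     paste0("frac_", classes[k]))
  }
  if (!is.null(tree_map)) {
    if (!same_grid(class_map, tree_map))
      stop("tree overlay must share the fine grid of the class map")
    tv <- tree_map$values
    tvalid <- block_apply(tv, f, function(b) sum(!is.na(b)))
    tcnt <- block_apply(tv, f, function(b) sum(b > 0, na.rm = TRUE))
    fr <- ifelse(tvalid > 0, tcnt / tvalid, NA_real_)
    stack[[tree_name]] <- cc_raster(fr, target_cell_size, class_map$origin,
                                    paste0("frac_", tree_name))
  }
  structure(stack, class = "fraction_stack", classes = classes,
            tree_name = if (is.null(tree_map)) NULL else tree_name)
}

#' Terrain aspect by Horn's method
#'
#' Aspect (downslope compass direction, 0 deg = north, clockwise) from the 8
#' neighbour Horn gradient. Border cells, cells with missing neighbours and
#' flat cells (zero gradient) are `NA`; flat cells are thereby excluded from
#' any later north-facing denominator.
#'
#' @param dem elevation `cc_raster` in metres, at least 3 x 3.
#' @return aspect `cc_raster` in degrees `[0, 360)`.
#' @export
compute_aspect <- function(dem) {
  stopifnot(is_cc_raster(dem))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3L || nc < 3L) stop("DEM must be at least 3 x 3")
  cs <- dem$cell_size
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  # Horn 1981 weights; rows run north -> south
  zx <- ((z[i - 1, j + 1] + 2 * z[i, j + 1] + z[i + 1, j + 1]) -
         (z[i - 1, j - 1] + 2 * z[i, j - 1] + z[i + 1, j - 1])) / (8 * cs)
  zs <- ((z[i + 1, j - 1] + 2 * z[i + 1, j] + z[i + 1, j + 1]) -
         (z[i - 1, j - 1] + 2 * z[i - 1, j] + z[i - 1, j + 1])) / (8 * cs)
  # downslope unit direction: east component -zx, north component +zs
  asp <- atan2(-zx, zs) * 180 / pi
  asp <- (asp + 360) %% 360
  asp[zx == 0 & zs == 0] <- NA_real_
  out <- matrix(NA_real_, nr, nc)
  out[i, j] <- asp
  cc_raster(out, cs, dem$origin, "aspect_deg")
}

#' Fraction of north-facing slopes per analysis cell
#'
#' Fine-grid aspect is reclassified into north-facing (`[270, 360) U [0, 90)`)
#' and south-facing (`[90, 270)`) slopes; the intervals are half-open, so the
#' boundary direction 90 deg falls in the south class and 270 deg in the
#' north class — ties must break one way, and this one is tested. Per
#' analysis cell the
#' fraction is north-facing count over count of cells with defined aspect;
#' cells whose subcells are all flat/undefined are `NA`.
#'
#' @param aspect fine aspect `cc_raster` from [compute_aspect()].
#' @param target_cell_size analysis cell size (integer multiple of fine size).
#' @return `cc_raster` of fractions in `[0, 1]`.
#' @export
north_facing_fraction <- function(aspect, target_cell_size) {
  stopifnot(is_cc_raster(aspect))
  f <- block_factor(aspect$cell_size, target_cell_size,
                    "aspect and analysis grids")
  a <- aspect$values
  north <- ifelse(is.na(a), NA_real_,
                  as.numeric(a >= 270 | a < 90))
  defined <- block_apply(north, f, function(b) sum(!is.na(b)))
  ncount <- block_apply(north, f, function(b) sum(b, na.rm = TRUE))
  fr <- ifelse(defined > 0, ncount / defined, NA_real_)
  cc_raster(fr, target_cell_size, aspect$origin, "north_facing_fraction")
}

#' NDVI to fraction of vegetation cover
#'
#' Squared scaled-NDVI relationship: NDVI is rescaled between a bare-soil and
#' a full-vegetation reference value, clipped to `[0, 1]` and squared. The two
#' reference NDVIs are configuration, not constants.
#'
#' @param ndvi numeric vector/matrix or `cc_raster`.
#' @param ndvi_soil NDVI of bare soil (default 0.2).
#' @param ndvi_veg NDVI of full vegetation (default 0.5); must exceed
#'   `ndvi_soil`.
#' @return FVC in `[0, 1]`, same shape as the input.
#' @export
ndvi_to_fvc <- function(ndvi, ndvi_soil = 0.2, ndvi_veg = 0.5) {
  if (!(ndvi_veg > ndvi_soil))
    stop("`ndvi_veg` must be greater than `ndvi_soil`")
  fv <- function(x) pmin(pmax((x - ndvi_soil) / (ndvi_veg - ndvi_soil), 0), 1)^2
  if (is_cc_raster(ndvi)) {
    out <- ndvi; out$values <- fv(ndvi$values); out$label <- "fvc"; out
  } else fv(ndvi)
}

#' Fraction of vegetation cover to broadband emissivity
#'
#' Linear mixing between the bare-surface emissivity 0.97 and the vegetated
#' emissivity 0.99: `e = 0.97 (1 - fvc) + 0.99 fvc`.
#'
#' @param fvc FVC in `[0, 1]` (vector/matrix or `cc_raster`).
#' @return emissivity in `[0.97, 0.99]`, same shape.
#' @export
fvc_to_emissivity <- function(fvc) {
  em <- function(x) {
    if (any(x < 0 | x > 1, na.rm = TRUE)) stop("`fvc` must lie in [0, 1]")
    0.97 * (1 - x) + 0.99 * x
  }
  if (is_cc_raster(fvc)) {
    out <- fvc; out$values <- em(fvc$values); out$label <- "emissivity"; out
  } else em(fvc)
}
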