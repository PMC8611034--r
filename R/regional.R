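#' Smooth spatial trend surface over city results
#'
#' Penalized 2-D thin-plate smooth of a per-city field (e.g. the hot-extreme
#' contrast) over projected city coordinates, evaluated on a regular grid
#' clipped to the cities' bounding box — an interpolation of the per-city
#' values that reveals continental-scale gradients. The effective basis
#' dimension is capped below the number of cities.
#'
#' @param city_results data.frame with `x`, `y` (projected metres) and the
#'   field column.
#' @param field column name to smooth.
#' @param basis_dim nominal per-axis basis dimension; the 2-D basis uses
#'   `basis_dim^2` functions (capped at `n - 1`).
#' @param grid_n evaluation grid resolution per axis.
#' @return a `regional_surface`: list with `x`, `y` (axes), `z` (matrix,
#'   rows = y), `model`, `field`.
#' @export
smooth_spatial_trend <- function(city_results, field, basis_dim = 5,
                                 grid_n = 40) {
  n <- nrow(city_results)
  if (n < ceiling(basis_dim^2 / 2))
    stop("too few cities for the requested smoothness: ", n, " < ",
         ceiling(basis_dim^2 / 2))
  df <- data.frame(x = city_results$x, y = city_results$y,
                   value = city_results[[field]])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  gx <- seq(min(df$x), max(df$x), length.out = grid_n)
  gy <- seq(min(df$y), max(df$y), length.out = grid_n)
  if (stats::var(df$value) < 1e-12) {
    # degenerate uniform field: the interpolant is the constant itself
    z <- matrix(mean(df$value), grid_n, grid_n)
    return(structure(list(x = gx, y = gy, z = z,
                          model = stats::lm(value ~ 1, data = df),
                          field = field),
                     class = "regional_surface"))
  }
  k <- min(basis_dim^2, nrow(df) - 1L)
  if (k < 4L)
    stop("too few cities for a 2-D smooth (need a basis of at least 4)")
  fit <- mgcv::gam(value ~ s(x, y, k = k), data = df, method = "REML")
  nd <- expand.grid(x = gx, y = gy)
  z <- matrix(mgcv::predict.gam(fit, newdata = nd), nrow = grid_n,
              byrow = TRUE)  # rows indexed by y
  structure(list(x = gx, y = gy, z = z, model = fit, field = field),
            class = "regional_surface")
}

#' Per-group mean and standard error of the mean
#'
#' Country- or region-level synthesis of per-city values: arithmetic mean,
#' `sd / sqrt(n)`, and the city count per group. Singleton groups report a
#' missing standard error.
#'
#' @param city_results data.frame of per-city values.
#' @param group column name holding the grouping label (country or region).
#' @param field column name of the value to summarise.
#' @return data.frame `group`, `mean`, `se`, `n`.
#' @export
group_summary <- function(city_results, group, field) {
  v <- city_results[[field]]
  g <- as.character(city_results[[group]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  if (!length(v)) stop("no complete (group, value) pairs")
  out <- do.call(rbind, lapply(split(v, g), function(z) {
    data.frame(mean = mean(z),
               se = if (length(z) > 1L) stats::sd(z) / sqrt(length(z))
                    else NA_real_,
               n = length(z))
  }))
  out <- data.frame(group = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$group), , drop = FALSE]
}

#' Inter-city association between cooling and a driver
#'
#' Ordinary least-squares line of a per-city response (e.g. the urban-tree
#' cooling contrast) on a per-city driver (e.g. rural-forest ET), with the
#' coefficient of determination — the diagnostic used to ask how much of the
#' continental variation in cooling a driver explains.
#'
#' @param city_results data.frame of per-city values.
#' @param x_field,y_field driver and response column names.
#' @return list `slope`, `intercept`, `r_squared`, `n`.
#' @export
association <- function(city_results, x_field, y_field) {
  df <- data.frame(x = city_results[[x_field]], y = city_results[[y_field]])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 3L) stop("need at least 3 cities with both fields")
  if (stats::var(df$x) <= 0) stop("driver `", x_field, "` has zero variance")
  fit <- stats::lm(y ~ x, data = df)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n = nrow(df))
}
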