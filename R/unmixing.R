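#' Blue-sky albedo approximation
#'
#' Cellwise average of white-sky (diffuse) and black-sky (direct) albedo; a
#' simplified stand-in for actual-illumination albedo. Missing cells in
#' either input propagate.
#'
#' @param white,black aligned albedo `cc_raster`s with values in `[0, 1]`.
#' @return blue-sky albedo `cc_raster`.
#' @export
blue_sky_albedo <- function(white, black) {
  stopifnot(is_cc_raster(white), is_cc_raster(black))
  if (!same_grid(white, black))
    stop("white- and black-sky rasters are not on the same grid")
  rng <- range(c(white$values, black$values), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("albedo values must lie in [0, 1]")
  cc_raster((white$values + black$values) / 2, white$cell_size,
            white$origin, "albedo_blue")
}

#' Monthly climatology of dated rasters
#'
#' Per calendar month, the multi-year cellwise mean ignoring missing cells.
#' Months with no rasters are absent from the result.
#'
#' @param rasters list of aligned `cc_raster`s.
#' @param dates Date vector parallel to `rasters`.
#' @param variable label stored with the product.
#' @return a `coarse_product`: list with `variable` and `months` (named list
#'   of `cc_raster`s, names "01".."12").
#' @export
monthly_climatology <- function(rasters, dates, variable = "et") {
  stopifnot(length(rasters) == length(dates), length(rasters) > 0)
  for (r in rasters[-1])
    if (!same_grid(rasters[[1]], r)) stop("rasters are not aligned")
  mo <- format(as.Date(dates), "%m")
  months <- sort(unique(mo))
  out <- lapply(months, function(m) {
    sel <- rasters[mo == m]
    arr <- vapply(sel, function(r) r$values,
                  matrix(0, nrow(rasters[[1]]$values),
                         ncol(rasters[[1]]$values)))
    dim(arr) <- c(dim(rasters[[1]]$values), length(sel))
    v <- apply(arr, c(1, 2), function(z) {
      z <- z[!is.na(z)]
      if (!length(z)) NA_real_ else mean(z)
    })
    cc_raster(v, rasters[[1]]$cell_size, rasters[[1]]$origin,
              paste0(variable, "_", m))
  })
  names(out) <- months
  structure(list(variable = variable, months = out), class = "coarse_product")
}

#' Attribute coarse-pixel values to land-cover classes by unmixing
#'
#' Least-squares regression of the coarse-pixel values on the sub-pixel class
#' fractions, with no intercept so each coefficient is directly the per-class
#' value (signature). Aliased classes (rank deficiency, e.g. a class absent
#' from every unmasked pixel) are dropped with a warning; cities with fewer
#' than `3 x n_classes` unmasked pixels are rejected. Negative estimates are
#' flagged — physically impossible for ET — so downstream analyses can
#' exclude them while keeping the audit trail.
#'
#' @param product `cc_raster` of coarse observations (ET or albedo).
#' @param fractions `fraction_stack` on the same coarse grid.
#' @param classes which stack layers act as predictors (default: the
#'   exclusive classes of the stack).
#' @param variable label recorded in the output.
#' @return data.frame `class`, `value`, `se`, `flag_negative`, `n_pixels`,
#'   `variable`; dropped classes appear with `NA` value.
#' @export
unmix <- function(product, fractions, classes = attr(fractions, "classes"),
                  variable = "et") {
  stopifnot(is_cc_raster(product))
  if (!same_grid(product, fractions[[1]]))
    stop("product and fraction stack are not on the same grid")
  X <- vapply(classes, function(k) as.vector(fractions[[k]]$values),
              numeric(length(product$values)))
  y <- as.vector(product$values)
  keep <- !is.na(y) & stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- length(y)
  if (n < 3L * length(classes))
    stop("insufficient pixels for unmixing: ", n, " unmasked, need ",
         3L * length(classes))
  qrX <- qr(X)
  use <- classes
  if (qrX$rank < ncol(X)) {
    aliased <- classes[-qrX$pivot[seq_len(qrX$rank)]]
    warning("dropping aliased class(es) from unmixing: ",
            paste(aliased, collapse = ", "), call. = FALSE)
    use <- classes[qrX$pivot[seq_len(qrX$rank)]]
    X <- X[, use, drop = FALSE]
  }
  fit <- stats::lm.fit(X, y)
  co <- fit$coefficients
  dfres <- n - length(use)
  sigma2 <- if (dfres > 0) sum(fit$residuals^2) / dfres else 0
  XtXinv <- chol2inv(chol(crossprod(X)))
  ses <- sqrt(pmax(0, sigma2 * diag(XtXinv)))
  out <- data.frame(class = classes,
                    value = NA_real_, se = NA_real_,
                    flag_negative = NA, n_pixels = n, variable = variable,
                    stringsAsFactors = FALSE)
  idx <- match(use, classes)
  out$value[idx] <- co
  out$se[idx] <- ses
  out$flag_negative[idx] <- co < 0
  out
}
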