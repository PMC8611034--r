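#' Season label from acquisition date
#'
#' Standard climatological seasons from the calendar month: DJF, MAM, JJA,
#' SON.
#'
#' @param date Date vector (or coercible).
#' @return character vector of season labels.
#' @export
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA", "JJA", "JJA",
    "SON", "SON", "SON", "DJF")[m]
}

#' Background temperature for one scene
#'
#' Uses a gridded air-temperature table (date-keyed, e.g. station-based
#' reanalysis sampled at the city) when one is supplied and it covers the
#' scene's date; otherwise falls back to the spatial mean of the scene's
#' usable LST values as the background-temperature indicator.
#'
#' @param scene a `scene_record` (needs `date` and `lst`).
#' @param gridded optional data.frame with columns `date`, `tb`.
#' @return background temperature in deg C.
#' @export
assign_background_temp <- function(scene, gridded = NULL) {
  if (!is.null(gridded)) {
    hit <- which(as.Date(gridded$date) == as.Date(scene$date))
    if (length(hit)) return(gridded$tb[hit[1]])
  }
  v <- scene$lst$values
  v <- v[!is.na(v)]
  if (!length(v))
    stop("no background-temperature source: no gridded record for ",
         scene$date, " and the scene has no usable cells")
  mean(v)
}

#' Build the per-scene contrast series against background temperature
#'
#' Joins a contrast table (one class pair) with background temperatures and
#' season labels and sorts by background temperature, ready for curve
#' fitting.
#'
#' @param contrasts data.frame from [contrast_all_scenes()], already filtered
#'   to one class pair (or carrying a single pair).
#' @param tb numeric vector of background temperatures, parallel to
#'   `contrasts` rows, or a data.frame `scene_id`, `tb` to join on.
#' @return data.frame `scene_id`, `date`, `tb`, `delta_t`, `se`, `season`,
#'   sorted by `tb`.
#' @export
delta_t_series <- function(contrasts, tb) {
  if (is.data.frame(tb)) {
    idx <- match(contrasts$scene_id, tb$scene_id)
    if (anyNA(idx)) stop("missing background temperature for some scenes")
    tbv <- tb$tb[idx]
  } else {
    if (length(tb) != nrow(contrasts))
      stop("`tb` must match the contrast rows")
    tbv <- tb
  }
  out <- data.frame(scene_id = contrasts$scene_id, date = contrasts$date,
                    tb = tbv, delta_t = contrasts$delta_t, se = contrasts$se,
                    season = season_of(contrasts$date),
                    stringsAsFactors = FALSE)
  out[order(out$tb), , drop = FALSE]
}

# tricube local-linear fit at points x0; returns fitted values and the
# variance factor sum(l^2) of each local estimate. rob are robustness
# weights on the data points; wts optional user weights.
local_linear <- function(x, y, x0, span, rob = NULL, wts = NULL) {
  n <- length(x)
  q <- max(2L, floor(span * n))
  if (is.null(rob)) rob <- rep(1, n)
  if (is.null(wts)) wts <- rep(1, n)
  fit <- numeric(length(x0)); l2 <- numeric(length(x0))
  for (i in seq_along(x0)) {
    d <- abs(x - x0[i])
    h <- sort(d, partial = q)[q]
    if (h <= 0) h <- max(d)
    w <- (pmax(1 - pmin(d / h, 1)^3, 0))^3 * rob * wts
    sw <- sum(w)
    if (sw <= 0 || sum(w > 0) < 2L) { # degenerate window: weighted mean
      w <- rob * wts
      sw <- sum(w)
    }
    xc <- x - x0[i]
    sx <- sum(w * xc); sxx <- sum(w * xc * xc)
    denom <- sw * sxx - sx * sx
    if (abs(denom) < 1e-12 * max(sxx, 1)) {
      l <- w / sw                      # fall back to local constant
    } else {
      l <- w * (sxx - sx * xc) / denom # intercept row of the 2x2 WLS solve
    }
    fit[i] <- sum(l * y)
    l2[i] <- sum(l * l)
  }
  list(fit = fit, l2 = l2)
}

#' Robust cooling curve of contrast versus background temperature
#'
#' Local linear regression with tricube distance weights (loess-style
#' nearest-neighbour bandwidth, `q = floor(span * n)`), followed by
#' `robust_iters` reweighting passes with Tukey-bisquare weights on residuals
#' scaled by six times their median absolute value — a re-descending
#' M-estimator that discounts gross outliers entirely. Pointwise standard
#' errors come from the final weighted local fits; the curve is evaluated on
#' a grid covering exactly the observed background-temperature range (no
#' extrapolation), always including the maximum.
#'
#' @param series data.frame from [delta_t_series()] (needs `tb`, `delta_t`),
#'   or any data.frame with those columns.
#' @param span fraction of points in each local neighbourhood, in (0, 1].
#' @param robust_iters number of bisquare reweighting passes (0 = plain
#'   tricube loess).
#' @param eval_n number of grid points.
#' @param weights optional prior weights (e.g. inverse-variance from the
#'   per-scene contrast standard errors); default unweighted.
#' @return a `cooling_curve`: list with `tb_grid`, `fit`, `se`, `endpoint`
#'   (list `tb`, `delta_t`, `se`), `robustness_weights`, `span`,
#'   `robust_iters`, `n`.
#' @export
fit_cooling_curve <- function(series, span = 0.75, robust_iters = 4,
                              eval_n = 100, weights = NULL) {
  x <- series$tb; y <- series$delta_t
  if (!(span > 0 && span <= 1)) stop("span must lie in (0, 1]")
  n <- length(x)
  if (n < max(10, ceiling(2 / span)))
    stop("too few points for a loess curve: n = ", n)
  if (diff(range(x)) <= 0)
    stop("background temperatures have zero spread")
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  if (!is.null(weights)) weights <- weights[ord]
  rob <- rep(1, n)
  for (it in seq_len(robust_iters)) {
    f <- local_linear(x, y, x, span, rob = rob, wts = weights)
    r <- y - f$fit
    s <- 6 * stats::median(abs(r))
    if (s <= 1e-10 * max(abs(r), 1)) {
      # residual scale collapsed (fit exact on the clean majority):
      # keep the exactly fitted points, discount the rest entirely
      rob <- as.numeric(abs(r) <= max(abs(r)) * 1e-8)
      if (!any(rob > 0)) rob <- rep(1, n)
      break
    }
    u <- pmin(abs(r) / s, 1)
    rob <- (1 - u^2)^2
    if (sum(rob > 0) < max(3, ceiling(2 / span)))
      stop("robust reweighting removed almost all points")
  }
  grid <- seq(min(x), max(x), length.out = eval_n)
  grid[eval_n] <- max(x)   # endpoint exactly at the hottest observation
  gfit <- local_linear(x, y, grid, span, rob = rob, wts = weights)
  dfit <- local_linear(x, y, x, span, rob = rob, wts = weights)
  r <- y - dfit$fit
  wr <- rob * if (is.null(weights)) 1 else weights
  n_eff <- sum(wr > 0)
  # Gaussian consistency of the bisquare-weighted residual variance: with
  # weights (1 - (r/k)^2)^2 at k = 6 * median|r| (= 6 * 0.67449 sigma for
  # normal errors), E[w r^2]/E[w] = 0.77558 sigma^2; divide it back out so
  # the scale estimate is unbiased under clean Gaussian scatter.
  bisq_consistency <- if (robust_iters > 0 && any(rob < 1)) 0.77558 else 1
  sigma2 <- sum(wr * r^2) / max(1, sum(wr) - 2) / bisq_consistency
  se <- sqrt(sigma2 * gfit$l2)
  structure(list(tb_grid = grid, fit = gfit$fit, se = se,
                 endpoint = list(tb = max(x), delta_t = gfit$fit[eval_n],
                                 se = se[eval_n]),
                 robustness_weights = rob, span = span,
                 robust_iters = robust_iters, n = n, n_eff = n_eff),
            class = "cooling_curve")
}

#' Hot-extreme cooling: the curve endpoint
#'
#' The curve value and pointwise standard error at the maximum observed
#' background temperature — the estimate of the vegetation-fabric contrast
#' for the hottest, most extreme conditions on record for the city.
#'
#' @param curve a [fit_cooling_curve()] result.
#' @return named list `delta_t`, `se`, `tb`.
#' @export
extreme_cooling <- function(curve) {
  stopifnot(inherits(curve, "cooling_curve"))
  curve$endpoint
}

#' Seasonal order statistics of the contrast series
#'
#' Median, first and third quartile (linear interpolation between order
#' statistics, the type-7 rule) and count per season. Seasons with no scenes
#' appear with `n = 0` and missing statistics.
#'
#' @param series data.frame with `season` and `delta_t` (see
#'   [delta_t_series()]).
#' @return data.frame `season`, `n`, `q1`, `median`, `q3`, `min`, `max`.
#' @export
seasonal_summary <- function(series) {
  seasons <- c("DJF", "MAM", "JJA", "SON")
  out <- lapply(seasons, function(s) {
    v <- series$delta_t[series$season == s]
    if (!length(v))
      return(data.frame(season = s, n = 0L, q1 = NA_real_,
                        median = NA_real_, q3 = NA_real_,
                        min = NA_real_, max = NA_real_))
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(season = s, n = length(v), q1 = qs[1], median = qs[2],
               q3 = qs[3], min = min(v), max = max(v))
  })
  do.call(rbind, out)
}
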