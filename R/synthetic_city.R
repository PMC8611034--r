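#' Ground-truth configuration for a synthetic city
#'
#' Bundles everything the generator needs to plant a fully known signal:
#' per-class surface-temperature offsets as functions of background
#' temperature, an elevation lapse rate, a smooth spatial confounder
#' amplitude, observation noise, cloud-like missingness, and per-class ET and
#' albedo signatures for the coarse products. The baseline class (continuous
#' urban fabric) must have the zero offset function so planted contrasts
#' against it read directly off the other classes' offsets.
#'
#' @param class_names ordered LULC labels; must include
#'   `"continuous_urban_fabric"`, `"urban_trees"` and `"green_spaces"`.
#' @param offsets named list mapping each class to a function
#'   `f(tb)` returning the K offset from background temperature `tb` (deg C);
#'   see [offset_constant()], [offset_linear()], [offset_breakpoint()].
#' @param baseline_class class acting as the zero-offset reference.
#' @param lapse_rate K per metre of elevation (negative = cooling with height).
#' @param trend_amplitude K, amplitude of the smooth 2-D spatial confounder.
#' @param noise_sd K, i.i.d. observation noise per cell.
#' @param missing_frac proportion of cells masked per scene, in `[0, 1)`.
#' @param et_signature,albedo_signature named per-class values (mm/8day;
#'   dimensionless in `[0, 1]`).
#' @param seed integer; fully determines every generated artifact.
#' @return a `truth_config` list.
#' @export
truth_config <- function(class_names = c("continuous_urban_fabric",
                                         "urban_trees", "green_spaces",
                                         "other_impervious"),
                         offsets = default_offsets(class_names),
                         baseline_class = "continuous_urban_fabric",
                         lapse_rate = -0.006,
                         trend_amplitude = 2,
                         noise_sd = 0.5,
                         missing_frac = 0.1,
                         et_signature = default_et(class_names),
                         albedo_signature = default_albedo(class_names),
                         seed = 1L) {
  need <- c("continuous_urban_fabric", "urban_trees", "green_spaces")
  if (!all(need %in% class_names))
    stop("class_names must include: ", paste(need, collapse = ", "))
  if (!baseline_class %in% class_names) stop("unknown baseline class")
  if (!all(class_names %in% names(offsets)))
    stop("every class needs an offset function")
  probe <- c(0, 15, 30)
  if (any(abs(offsets[[baseline_class]](probe)) > 1e-12))
    stop("the baseline class must carry the zero offset function")
  if (!(missing_frac >= 0 && missing_frac < 1))
    stop("missing_frac must lie in [0, 1)")
  if (!all(class_names %in% names(et_signature)) ||
      !all(class_names %in% names(albedo_signature)))
    stop("ET and albedo signatures must cover every class")
  if (any(albedo_signature < 0 | albedo_signature > 1))
    stop("albedo signatures must lie in [0, 1]")
  structure(list(class_names = class_names, offsets = offsets,
                 baseline_class = baseline_class,
                 lapse_rate = lapse_rate, trend_amplitude = trend_amplitude,
                 noise_sd = noise_sd, missing_frac = missing_frac,
                 et_signature = et_signature[class_names],
                 albedo_signature = albedo_signature[class_names],
                 seed = as.integer(seed)),
            class = "truth_config")
}

#' Planted offset-function constructors
#'
#' Convenience constructors for the per-class offset functions of
#' [truth_config()]. `offset_linear` plants a cooling that changes linearly
#' with background temperature (the energy-limited regime when the slope is
#' negative); `offset_breakpoint` plants a piecewise-linear offset whose slope
#' changes above a breakpoint, emulating the soil-moisture-limited regime in
#' which cooling weakens during the hottest conditions.
#'
#' @param value offset in K (`offset_constant`), or offset at `ref_tb`
#'   (`offset_linear`, `offset_breakpoint`).
#' @param slope,ref_tb K per deg C and reference background temperature.
#' @param slope_above,break_tb slope above the breakpoint and its location.
#' @return a function `f(tb)`.
#' @export
offset_constant <- function(value) {
  force(value); function(tb) rep(value, length(tb))
}

#' @rdname offset_constant
#' @export
offset_zero <- function() offset_constant(0)

#' @rdname offset_constant
#' @export
offset_linear <- function(value, slope, ref_tb = 10) {
  force(value); force(slope); force(ref_tb)
  function(tb) value + slope * (tb - ref_tb)
}

#' @rdname offset_constant
#' @export
offset_breakpoint <- function(value, slope, slope_above, break_tb,
                              ref_tb = 10) {
  force(value); force(slope); force(slope_above); force(break_tb)
  force(ref_tb)
  at_break <- value + slope * (break_tb - ref_tb)
  function(tb) ifelse(tb <= break_tb,
                      value + slope * (tb - ref_tb),
                      at_break + slope_above * (tb - break_tb))
}

default_offsets <- function(class_names) {
  base <- list(
    continuous_urban_fabric = offset_zero(),
    urban_trees  = offset_linear(-4, -0.2, ref_tb = 10),
    green_spaces = offset_linear(-1.5, -0.075, ref_tb = 10),
    other_impervious = offset_constant(-0.5)
  )
  miss <- setdiff(class_names, names(base))
  for (m in miss) base[[m]] <- offset_zero()
  base[class_names]
}

default_et <- function(class_names) {
  base <- c(continuous_urban_fabric = 2, urban_trees = 25, green_spaces = 16,
            other_impervious = 5, forest = 28, pasture = 14)
  out <- base[class_names]
  out[is.na(out)] <- 10
  names(out) <- class_names
  out
}

default_albedo <- function(class_names) {
  base <- c(continuous_urban_fabric = 0.13, urban_trees = 0.10,
            green_spaces = 0.18, other_impervious = 0.15, forest = 0.11,
            pasture = 0.20)
  out <- base[class_names]
  out[is.na(out)] <- 0.15
  names(out) <- class_names
  out
}

#' Generate a contiguous-patch land-cover map
#'
#' Nearest-seed (Voronoi) tessellation: seed points are scattered uniformly,
#' with per-class point counts proportional to target area shares, and every
#' cell takes the class of its nearest seed. This yields contiguous patches
#' resembling urban-atlas geometry while leaving coarse analysis cells with
#' mixed fractions at patch borders. Regenerates with a shifted point set (up
#' to 20 attempts) if any class ends up below 1% area; identical arguments
#' give bit-identical maps.
#'
#' @param nrow,ncol grid dimensions (at least 50 x 50 for multi-class maps).
#' @param truth a [truth_config()].
#' @param seed integer RNG seed.
#' @param cell_size fine cell size in metres.
#' @param origin upper-left corner coordinates.
#' @param shares named target area shares per class (renormalised); default
#'   favours urban fabric with sizeable tree and green-space shares.
#' @param n_patches total number of Voronoi seed points.
#' @return integer `cc_raster` with a `classes` attribute.
#' @export
generate_landcover <- function(nrow, ncol, truth, seed = truth$seed,
                               cell_size = 10, origin = c(0, nrow * cell_size),
                               shares = NULL, n_patches = 60) {
  classes <- truth$class_names
  if (length(classes) >= 2L && (nrow < 50L || ncol < 50L))
    stop("grid too small to place all classes (need at least 50 x 50)")
  if (is.null(shares)) {
    shares <- c(continuous_urban_fabric = 0.40, urban_trees = 0.22,
                green_spaces = 0.20, other_impervious = 0.18)[classes]
    shares[is.na(shares)] <- 0.15
    names(shares) <- classes
  }
  shares <- shares[classes] / sum(shares[classes])
  if (length(classes) == 1L) {
    m <- matrix(1L, nrow, ncol)
    r <- cc_raster(m, cell_size, origin, "lulc_class")
    attr(r, "classes") <- classes
    return(r)
  }
  npts <- pmax(1L, round(shares * n_patches))
  cx <- (rep(seq_len(ncol), each = nrow) - 0.5)
  cy <- (rep(seq_len(nrow), times = ncol) - 0.5)
  for (attempt in 0:19) {
    set.seed(seed + 100003L * attempt)
    px <- runif(sum(npts), 0, ncol)
    py <- runif(sum(npts), 0, nrow)
    pcls <- rep(seq_along(classes), times = npts)
    # nearest seed per cell
    d2 <- outer(cx, px, "-")^2 + outer(cy, py, "-")^2
    nearest <- max.col(-d2, ties.method = "first")
    m <- matrix(pcls[nearest], nrow, ncol)
    areas <- tabulate(m, nbins = length(classes)) / length(m)
    if (all(areas >= 0.01)) {
      r <- cc_raster(m, cell_size, origin, "lulc_class")
      attr(r, "classes") <- classes
      return(r)
    }
  }
  stop("could not place all classes with >= 1% area; grid too small ",
       "or shares too skewed")
}

# sum of a few seeded low-frequency sinusoids, normalised to max |.| = 1
smooth_field <- function(nrow, ncol, seed, n_waves = 3) {
  set.seed(seed)
  x <- (rep(seq_len(ncol), each = nrow) - 0.5) / ncol
  y <- (rep(seq_len(nrow), times = ncol) - 0.5) / nrow
  z <- numeric(nrow * ncol)
  for (w in seq_len(n_waves)) {
    # band-limited below ~0.8 cycles per domain so a modest 2-D smooth can
    # absorb the field (the structural assumption the analysis relies on)
    fx <- runif(1, 0.2, 0.8); fy <- runif(1, 0.2, 0.8)
    ph <- runif(1, 0, 2 * pi); amp <- runif(1, 0.5, 1)
    z <- z + amp * sin(2 * pi * (fx * x + fy * y) + ph)
  }
  z <- z / max(abs(z))
  matrix(z, nrow, ncol)
}

#' Generate a smooth synthetic DEM
#'
#' Elevation as a seeded sum of low-frequency sinusoids: smooth, band-limited
#' relief that a 2-D spatial smooth can absorb, with no sharp breaks.
#'
#' @param nrow,ncol grid dimensions.
#' @param seed RNG seed.
#' @param cell_size metres.
#' @param origin upper-left corner.
#' @param base_elev,relief mean elevation and half-range in metres.
#' @return elevation `cc_raster`.
#' @export
generate_dem <- function(nrow, ncol, seed, cell_size = 10,
                         origin = c(0, nrow * cell_size),
                         base_elev = 300, relief = 60) {
  z <- base_elev + relief * smooth_field(nrow, ncol, seed + 7L)
  cc_raster(z, cell_size, origin, "elevation_m")
}

#' Draw scene acquisition dates and background temperatures
#'
#' Dates are sampled uniformly over the requested years; the background
#' temperature follows a sinusoidal seasonal cycle (coldest mid-January,
#' warmest mid-July) plus Gaussian scatter, so summer (JJA) and hot-extreme
#' logic downstream is exercised.
#'
#' @param n_scenes number of scenes.
#' @param seed RNG seed.
#' @param years calendar years to sample from.
#' @param tb_mean,tb_amplitude,tb_sd deg C: annual mean, seasonal
#'   half-amplitude, and day-to-day scatter.
#' @return data.frame with `date` (Date) and `tb` (deg C), sorted by date.
#' @export
draw_scene_conditions <- function(n_scenes, seed, years = 2006:2018,
                                  tb_mean = 13, tb_amplitude = 11,
                                  tb_sd = 2.5) {
  set.seed(seed)
  yr <- sample(years, n_scenes, replace = TRUE)
  doy <- sample.int(365, n_scenes, replace = TRUE)
  date <- as.Date(sprintf("%d-01-01", yr)) + (doy - 1L)
  tb <- tb_mean - tb_amplitude * cos(2 * pi * (doy - 15) / 365.25) +
    rnorm(n_scenes, 0, tb_sd)
  out <- data.frame(date = date, tb = tb)
  out[order(out$date), , drop = FALSE]
}

#' Simulate one LST scene on the analysis grid
#'
#' Inverts the additive model the analysis assumes: per analysis cell,
#' `LST = tb + sum_k frac_k * offset_k(tb) + lapse * (elev - mean elev) +
#' trend + noise`, with a seeded Bernoulli mask emulating cloud cover.
#'
#' @param city a [synth_city()] object (supplies fractions, elevation, trend).
#' @param date acquisition date (Date or ISO string).
#' @param tb background temperature, deg C (finite).
#' @param truth the city's [truth_config()].
#' @param seed RNG seed for noise and missingness.
#' @return a `scene_record`: list with `id`, `date`, `tb`, `lst`
#'   (`cc_raster`, deg C).
#' @export
simulate_scene <- function(city, date, tb, truth = city$truth,
                           seed = truth$seed) {
  if (!is.finite(tb)) stop("`tb` must be finite")
  fr <- city$fractions
  elev <- city$elev_analysis$values
  lst <- matrix(tb, nrow(elev), ncol(elev))
  for (k in truth$class_names)
    lst <- lst + fr[[k]]$values * truth$offsets[[k]](tb)
  lst <- lst + truth$lapse_rate * (elev - mean(elev, na.rm = TRUE))
  lst <- lst + city$trend$values
  set.seed(seed)
  if (truth$noise_sd > 0)
    lst <- lst + matrix(rnorm(length(lst), 0, truth$noise_sd),
                        nrow(lst), ncol(lst))
  if (truth$missing_frac > 0) {
    drop <- matrix(runif(length(lst)) < truth$missing_frac,
                   nrow(lst), ncol(lst))
    lst[drop] <- NA_real_
  }
  structure(list(id = format(as.Date(date), "scene_%Y%m%d"),
                 date = as.Date(date), tb = tb,
                 lst = cc_raster(lst, fr[[1]]$cell_size, fr[[1]]$origin,
                                 "lst_c")),
            class = "scene_record")
}

#' Simulate coarse ET and albedo products as linear mixtures
#'
#' Coarse-pixel values are fraction-weighted mixtures of the per-class
#' signatures plus optional noise. ET is masked where the summed urban-class
#' fraction exceeds 0.5, emulating the absence of satellite ET retrievals over
#' built-up areas; white- and black-sky albedo are produced as the blue-sky
#' mixture plus/minus a fixed diffuse-direct split so their average recovers
#' the planted blue-sky value exactly.
#'
#' @param class_map fine class map (with `classes` attribute).
#' @param truth a [truth_config()].
#' @param coarse_cell_size coarse resolution in metres (integer multiple of
#'   the fine cell size).
#' @param noise_sd per-pixel noise (ET units; albedo noise is scaled by
#'   1/100 of this to stay in `[0,1]`).
#' @param seed RNG seed.
#' @param urban_classes classes counted as urban for the ET mask.
#' @return list with `et`, `albedo_white`, `albedo_black` (`cc_raster`s) and
#'   `fractions` (the coarse `fraction_stack` used).
#' @export
simulate_coarse_products <- function(class_map, truth,
                                     coarse_cell_size = 450,
                                     noise_sd = 0, seed = truth$seed,
                                     urban_classes =
                                       c("continuous_urban_fabric",
                                         "other_impervious")) {
  fr <- aggregate_fractions(class_map, coarse_cell_size)
  classes <- truth$class_names
  dims <- dim(fr[[1]]$values)
  mix <- function(sig) {
    m <- matrix(0, dims[1], dims[2])
    for (k in classes) m <- m + fr[[k]]$values * sig[[k]]
    m
  }
  set.seed(seed + 31L)
  et <- mix(truth$et_signature)
  if (noise_sd > 0)
    et <- et + matrix(rnorm(length(et), 0, noise_sd), dims[1], dims[2])
  urb <- matrix(0, dims[1], dims[2])
  for (k in intersect(urban_classes, classes)) urb <- urb + fr[[k]]$values
  et[urb > 0.5] <- NA_real_
  blue <- mix(truth$albedo_signature)
  if (noise_sd > 0)
    blue <- blue + matrix(rnorm(length(blue), 0, noise_sd / 100),
                          dims[1], dims[2])
  split <- 0.02
  white <- pmin(blue + split, 1)
  black <- pmax(blue - split, 0)
  g <- fr[[1]]
  list(et = cc_raster(et, g$cell_size, g$origin, "et_mm8day"),
       albedo_white = cc_raster(white, g$cell_size, g$origin, "albedo_white"),
       albedo_black = cc_raster(black, g$cell_size, g$origin, "albedo_black"),
       fractions = fr)
}

#' Build a complete synthetic city
#'
#' Orchestrates the generator: land-cover map (10 m), urban-tree overlay, DEM,
#' fraction stack and terrain covariates on the analysis grid, a smooth
#' spatial confounder, a set of dated LST scenes spanning the seasonal cycle,
#' and coarse ET/albedo products. Everything is a deterministic function of
#' `truth$seed`.
#'
#' @param truth a [truth_config()].
#' @param nrow,ncol fine-grid dimensions at `cell_size` m.
#' @param cell_size fine resolution (m).
#' @param analysis_cell_size analysis resolution (m), multiple of `cell_size`.
#' @param n_scenes number of LST scenes.
#' @param coarse_cell_size resolution of the ET/albedo products (m).
#' @param coarse_noise_sd noise on the coarse products.
#' @param shares,n_patches passed to [generate_landcover()].
#' @param years,tb_mean,tb_amplitude,tb_sd passed to
#'   [draw_scene_conditions()].
#' @param origin upper-left corner of all grids.
#' @return a `synth_city` list: `class_map`, `tree_map`, `dem`, `fractions`,
#'   `elev_analysis`, `north_fraction`, `trend`, `scenes`, `scene_table`,
#'   `coarse`, `truth`.
#' @export
synth_city <- function(truth, nrow = 300, ncol = 300, cell_size = 10,
                       analysis_cell_size = 90, n_scenes = 60,
                       coarse_cell_size = 450, coarse_noise_sd = 0,
                       shares = NULL, n_patches = 60, years = 2006:2018,
                       tb_mean = 13, tb_amplitude = 11, tb_sd = 2.5,
                       origin = c(0, nrow * cell_size)) {
  seed <- truth$seed
  class_map <- generate_landcover(nrow, ncol, truth, seed = seed,
                                  cell_size = cell_size, origin = origin,
                                  shares = shares, n_patches = n_patches)
  tree_vals <- (class_map$values ==
                  match("urban_trees", truth$class_names)) * 1
  tree_map <- cc_raster(tree_vals, cell_size, origin, "urban_tree_overlay")
  dem <- generate_dem(nrow, ncol, seed, cell_size = cell_size, origin = origin)
  fractions <- aggregate_fractions(class_map, analysis_cell_size,
                                   tree_map = tree_map)
  elev_analysis <- resample_mean(dem, analysis_cell_size)
  aspect <- compute_aspect(dem)
  north <- north_facing_fraction(aspect, analysis_cell_size)
  dims <- dim(elev_analysis$values)
  trend_m <- truth$trend_amplitude *
    smooth_field(dims[1], dims[2], seed + 13L)
  trend <- cc_raster(trend_m, analysis_cell_size, origin, "spatial_trend_k")
  cond <- draw_scene_conditions(n_scenes, seed + 29L, years = years,
                                tb_mean = tb_mean, tb_amplitude = tb_amplitude,
                                tb_sd = tb_sd)
  city <- structure(list(class_map = class_map, tree_map = tree_map,
                         dem = dem, fractions = fractions,
                         elev_analysis = elev_analysis,
                         north_fraction = north, trend = trend,
                         truth = truth),
                    class = "synth_city")
  scenes <- vector("list", nrow(cond))
  for (i in seq_len(nrow(cond)))
    scenes[[i]] <- simulate_scene(city, cond$date[i], cond$tb[i], truth,
                                  seed = seed + 1000L + i)
  city$scenes <- scenes
  city$scene_table <- data.frame(
    scene_id = vapply(scenes, `[[`, character(1), "id"),
    date = cond$date, tb = cond$tb)
  city$coarse <- simulate_coarse_products(class_map, truth,
                                          coarse_cell_size = coarse_cell_size,
                                          noise_sd = coarse_noise_sd,
                                          seed = seed + 53L)
  city
}

#' Planted temperature contrast between two classes
#'
#' The generator's ground truth: by construction the pure-class LST
#' difference A minus B at background temperature `tb` is
#' `offset_A(tb) - offset_B(tb)`. Downstream recovery tests compare fitted
#' contrasts against this.
#'
#' @param truth a [truth_config()].
#' @param class_a,class_b class labels.
#' @param tb background temperature(s), deg C.
#' @return numeric vector of planted contrasts (K).
#' @export
planted_contrast <- function(truth, class_a,
                             class_b = "continuous_urban_fabric", tb) {
  truth$offsets[[class_a]](tb) - truth$offsets[[class_b]](tb)
}

#' Write a synthetic city to disk as plain-text artifacts
#'
#' Class map, tree overlay and DEM as ESRI ASCII grids, scenes as one ASCII
#' grid each plus a metadata CSV (ISO-8601 dates), the truth configuration as
#' JSON (offset functions summarised by deparsed body).
#'
#' @param city a [synth_city()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_city <- function(city, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_asc(city$class_map, file.path(dir, "class_map.asc"))
  write_asc(city$tree_map, file.path(dir, "tree_overlay.asc"))
  write_asc(city$dem, file.path(dir, "dem.asc"))
  sdir <- file.path(dir, "scenes")
  dir.create(sdir, showWarnings = FALSE)
  for (s in city$scenes)
    write_asc(s$lst, file.path(sdir, paste0(s$id, ".asc")))
  meta <- city$scene_table
  meta$date <- format(meta$date, "%Y-%m-%d")
  utils::write.csv(meta, file.path(dir, "scene_metadata.csv"),
                   row.names = FALSE)
  tr <- city$truth
  truth_json <- list(
    class_names = tr$class_names, baseline_class = tr$baseline_class,
    lapse_rate = tr$lapse_rate, trend_amplitude = tr$trend_amplitude,
    noise_sd = tr$noise_sd, missing_frac = tr$missing_frac,
    et_signature = as.list(tr$et_signature),
    albedo_signature = as.list(tr$albedo_signature), seed = tr$seed,
    offsets = lapply(tr$offsets, function(f) deparse(body(f))))
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
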