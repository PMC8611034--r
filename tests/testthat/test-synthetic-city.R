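test_that("truth configuration enforces its invariants", {
  expect_error(truth_config(missing_frac = 1), "missing_frac")
  expect_error(truth_config(offsets = list(
    continuous_urban_fabric = offset_constant(1),
    urban_trees = offset_zero(), green_spaces = offset_zero(),
    other_impervious = offset_zero())), "zero offset")
  expect_error(truth_config(albedo_signature = c(
    continuous_urban_fabric = 1.2, urban_trees = 0.1, green_spaces = 0.2,
    other_impervious = 0.1)), "\\[0, 1\\]")
  expect_error(truth_config(class_names = c("a", "b")), "must include")
})

test_that("land-cover generation is deterministic and covers every class", {
  truth <- linear_truth(seed = 7)
  a <- generate_landcover(300, 300, truth, seed = 7)
  b <- generate_landcover(300, 300, truth, seed = 7)
  expect_identical(a$values, b$values)
  areas <- tabulate(a$values, 4) / length(a$values)
  expect_true(all(areas >= 0.01))
  # different seed, different map
  c2 <- generate_landcover(300, 300, truth, seed = 8)
  expect_false(identical(a$values, c2$values))
})

test_that("a single-class request yields a uniform map with unit fractions", {
  tr1 <- truth_config(
    class_names = c("continuous_urban_fabric", "urban_trees", "green_spaces"),
    offsets = list(continuous_urban_fabric = offset_zero(),
                   urban_trees = offset_zero(),
                   green_spaces = offset_zero()),
    et_signature = c(continuous_urban_fabric = 2, urban_trees = 25,
                     green_spaces = 16),
    albedo_signature = c(continuous_urban_fabric = 0.1, urban_trees = 0.1,
                         green_spaces = 0.2))
  one <- tr1
  one$class_names <- "continuous_urban_fabric"
  m <- generate_landcover(60, 60, one)
  expect_true(all(m$values == 1L))
  fs <- aggregate_fractions(m, 60)
  expect_true(all(fs$continuous_urban_fabric$values == 1))
})

test_that("small grids cannot host a multi-class city", {
  expect_error(generate_landcover(20, 20, linear_truth()), "too small")
})

test_that("scene simulation follows the planted additive formula exactly", {
  # noiseless, flat DEM, no trend: pure-class cells read back the offset
  truth <- constant_truth(tree_offset = -8)
  city <- synth_city(truth, nrow = 90, ncol = 90, analysis_cell_size = 30,
                     n_scenes = 1, n_patches = 12)
  city$dem$values[] <- 200
  city$elev_analysis$values[] <- 200
  city$trend$values[] <- 0
  sc <- simulate_scene(city, "2012-07-01", 20, truth, seed = 1)
  fr <- city$fractions
  pure_tree <- fr$urban_trees$values == 1
  pure_fab <- fr$continuous_urban_fabric$values == 1
  expect_true(any(pure_tree) && any(pure_fab))
  expect_true(all(abs(sc$lst$values[pure_tree] - (20 - 8)) < 1e-10))
  expect_true(all(abs(sc$lst$values[pure_fab] - 20) < 1e-10))
  # a half/half cell mixes offsets linearly: 0 and -8 -> -4
  half <- abs(fr$urban_trees$values - 0.5) < 1e-9 &
    abs(fr$continuous_urban_fabric$values - 0.5) < 1e-9
  if (any(half))
    expect_true(all(abs(sc$lst$values[half] - (20 - 4)) < 1e-10))
  # constructed check of the linear-mixture rule at one cell
  manual <- 20 + fr$urban_trees$values * (-8)
  other <- fr$green_spaces$values > 0 | fr$other_impervious$values > 0
  expect_equal(sc$lst$values[!other], manual[!other], tolerance = 1e-10)
})

test_that("scene noise has the planted standard deviation", {
  truth <- linear_truth(noise_sd = 1, missing_frac = 0, trend_amplitude = 0)
  city <- synth_city(truth, nrow = 200, ncol = 50, cell_size = 10,
                     analysis_cell_size = 10, n_scenes = 0, n_patches = 40)
  sc <- simulate_scene(city, "2012-07-01", 20, truth, seed = 11)
  fr <- city$fractions
  noiseless <- 20 +
    fr$urban_trees$values * truth$offsets$urban_trees(20) +
    fr$green_spaces$values * truth$offsets$green_spaces(20) +
    fr$other_impervious$values * truth$offsets$other_impervious(20) +
    truth$lapse_rate * (city$elev_analysis$values -
                          mean(city$elev_analysis$values))
  res <- sc$lst$values - noiseless
  n <- length(res)
  expect_gte(n, 10000)
  expect_lt(abs(mean(res)), 4 / sqrt(n))
  expect_lt(abs(sd(res) - 1), 0.05)
})

test_that("missingness masks the planted proportion of cells", {
  truth <- linear_truth(missing_frac = 0.3, seed = 2)
  city <- synth_city(truth, nrow = 300, ncol = 300, n_scenes = 2)
  fr_na <- mean(is.na(city$scenes[[1]]$lst$values))
  expect_lt(abs(fr_na - 0.3), 0.05)
})

test_that("whole-city generation is seed-deterministic", {
  truth <- linear_truth(seed = 4)
  a <- synth_city(truth, nrow = 120, ncol = 120, analysis_cell_size = 40,
                  n_scenes = 2, n_patches = 24)
  b <- synth_city(truth, nrow = 120, ncol = 120, analysis_cell_size = 40,
                  n_scenes = 2, n_patches = 24)
  expect_identical(a$class_map$values, b$class_map$values)
  expect_identical(a$dem$values, b$dem$values)
  expect_identical(a$scenes[[1]]$lst$values, b$scenes[[1]]$lst$values)
  expect_identical(a$scene_table$tb, b$scene_table$tb)
  expect_identical(a$coarse$et$values, b$coarse$et$values)
})

test_that("fractions aggregated from the class map sum to one everywhere", {
  truth <- linear_truth(seed = 6)
  city <- synth_city(truth, nrow = 150, ncol = 150, analysis_cell_size = 50,
                     n_scenes = 0, n_patches = 30)
  tot <- Reduce(`+`, lapply(truth$class_names,
                            function(k) city$fractions[[k]]$values))
  expect_equal(tot, matrix(1, nrow(tot), ncol(tot)), tolerance = 1e-12)
})

test_that("coarse products are exact mixtures that unmixing inverts", {
  truth <- linear_truth(seed = 9)
  city <- synth_city(truth, nrow = 300, ncol = 300, n_scenes = 0,
                     coarse_cell_size = 300, coarse_noise_sd = 0)
  co <- city$coarse
  # pure coarse pixels carry the class signature exactly
  for (k in truth$class_names) {
    pure <- which(co$fractions[[k]]$values == 1 & !is.na(co$et$values))
    if (length(pure))
      expect_true(all(abs(co$et$values[pure] - truth$et_signature[[k]])
                      < 1e-10))
  }
  # ET is masked over urban-dominated pixels
  urb <- co$fractions$continuous_urban_fabric$values +
    co$fractions$other_impervious$values
  expect_true(all(is.na(co$et$values[urb > 0.5])))
  expect_true(all(!is.na(co$et$values[urb <= 0.5])))
  # unmixing the noiseless ET mixture recovers all signatures
  sig <- unmix(co$et, co$fractions, variable = "et")
  rel <- abs(sig$value - truth$et_signature[sig$class]) /
    abs(truth$et_signature[sig$class])
  expect_true(all(rel <= 1e-8))
  # blue-sky albedo of the generated white/black pair is the planted mixture
  blue <- blue_sky_albedo(co$albedo_white, co$albedo_black)
  siga <- unmix(blue, co$fractions, variable = "albedo_blue")
  expect_equal(unname(siga$value[match(truth$class_names, siga$class)]),
               unname(truth$albedo_signature[truth$class_names]),
               tolerance = 1e-6)
})

test_that("city artifacts round-trip through plain-text files", {
  truth <- constant_truth(seed = 11)
  city <- synth_city(truth, nrow = 60, ncol = 60, analysis_cell_size = 30,
                     n_scenes = 2, n_patches = 12)
  dir <- withr::local_tempdir()
  write_city(city, dir)
  expect_true(file.exists(file.path(dir, "class_map.asc")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- coolcity:::read_city(dir, truth$class_names,
                               analysis_cell_size = 30)
  expect_equal(back$class_map$values, city$class_map$values)
  expect_equal(back$scenes[[1]]$lst$values, city$scenes[[1]]$lst$values,
               tolerance = 1e-6)
  expect_equal(back$scene_table$tb, city$scene_table$tb, tolerance = 1e-6)
})

test_that("background temperatures follow the seasonal cycle", {
  cond <- draw_scene_conditions(400, seed = 5)
  mo <- as.integer(format(cond$date, "%m"))
  expect_gt(mean(cond$tb[mo %in% 6:8]), mean(cond$tb[mo %in% c(12, 1, 2)]) + 10)
  expect_true(all(range(cond$tb) > -15 & range(cond$tb) < 40))
})
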