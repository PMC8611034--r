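classes3 <- c("urban_trees", "green_spaces", "continuous_urban_fabric")

test_that("an exactly linear response is reproduced and contrasted exactly", {
  df <- fixture_covariates()
  df$lst <- 20 + 3 - 8 * df$frac_urban_trees   # a + b * frac_trees only
  des <- design_from_df(df, classes3)
  fit <- suppressWarnings(fit_scene_model(des, small_model_config()))
  expect_lt(sqrt(mean(stats::residuals(fit$model)^2)), 1e-3)
  ct <- lulc_contrast(fit, "urban_trees")
  expect_equal(ct$delta_t, -8, tolerance = 1e-3)
})

test_that("planted constant offsets are recovered on noiseless data", {
  truth <- constant_truth()
  df <- fixture_covariates()
  df$lst <- fixture_response(df, tb = 20, truth = truth)
  fit <- suppressWarnings(
    fit_scene_model(design_from_df(df, classes3), small_model_config()))
  ct <- lulc_contrast(fit, "urban_trees")
  expect_lt(abs(ct$delta_t - (-8)), 0.05)
  cg <- lulc_contrast(fit, "green_spaces")
  expect_lt(abs(cg$delta_t - (-3)), 0.05)
})

test_that("a constant response is rejected as degenerate", {
  df <- fixture_covariates()
  df$lst <- 12
  expect_error(fit_scene_model(design_from_df(df, classes3),
                               small_model_config()),
               "zero variance")
})

test_that("contrast of a class with itself is exactly zero", {
  df <- fixture_covariates()
  df$lst <- fixture_response(df, tb = 20, truth = constant_truth())
  fit <- suppressWarnings(
    fit_scene_model(design_from_df(df, classes3), small_model_config()))
  ct <- lulc_contrast(fit, "urban_trees", "urban_trees")
  expect_identical(ct$delta_t, 0)
  expect_identical(ct$se, 0)
})

test_that("contrasts are invariant to response and covariate shifts", {
  truth <- linear_truth(noise_sd = 0.3)
  df <- fixture_covariates()
  df$lst <- fixture_response(df, tb = 22, truth = truth, noise_sd = 0.3)
  cfg <- small_model_config()
  base <- lulc_contrast(fit_scene_model(design_from_df(df, classes3), cfg),
                        "urban_trees")
  shifted <- df; shifted$lst <- shifted$lst + 7.5
  s1 <- lulc_contrast(fit_scene_model(design_from_df(shifted, classes3), cfg),
                      "urban_trees")
  expect_equal(s1$delta_t, base$delta_t, tolerance = 1e-8)
  lifted <- df; lifted$elev <- lifted$elev + 250
  s2 <- lulc_contrast(fit_scene_model(design_from_df(lifted, classes3), cfg),
                      "urban_trees")
  expect_equal(s2$delta_t, base$delta_t, tolerance = 1e-6)
})

test_that("linear-terms contrast equals the OLS coefficient difference", {
  truth <- linear_truth(noise_sd = 0.4)
  df <- fixture_covariates()
  df$lst <- fixture_response(df, tb = 25, truth = truth, noise_sd = 0.4)
  cfg <- model_config(linear = TRUE, min_cells = 50)
  fit <- fit_scene_model(design_from_df(df, classes3), cfg)
  ct <- lulc_contrast(fit, "urban_trees")
  ols <- stats::lm(lst ~ x + y + elev + north + frac_urban_trees +
                     frac_green_spaces + frac_continuous_urban_fabric,
                   data = df)
  oracle <- unname(coef(ols)["frac_urban_trees"] -
                     coef(ols)["frac_continuous_urban_fabric"])
  expect_lt(abs(ct$delta_t - oracle) / abs(oracle), 1e-6)
  # delta-method se matches the OLS contrast se as well
  V <- vcov(ols)
  d <- as.numeric(names(coef(ols)) == "frac_urban_trees") -
    as.numeric(names(coef(ols)) == "frac_continuous_urban_fabric")
  expect_lt(abs(ct$se - sqrt(drop(t(d) %*% V %*% d))) / ct$se, 1e-6)
})

test_that("pure-noise responses are penalized toward near-linear smooths", {
  set.seed(17)
  df <- fixture_covariates()
  df$lst <- rnorm(nrow(df))
  fit <- fit_scene_model(design_from_df(df, classes3), small_model_config())
  edf <- summary(fit$model)$edf     # per-smooth effective dfs
  expect_true(all(edf[-1] < 2.5))   # 1-D smooths shrink toward ~1 df
})

test_that("constant terms are dropped with a warning; missing classes error", {
  df <- fixture_covariates()
  df$north <- 0.5
  df$lst <- fixture_response(df, tb = 20, truth = constant_truth(),
                             noise_sd = 0.05)
  expect_warning(
    fit <- fit_scene_model(design_from_df(df, classes3),
                           small_model_config()),
    "north")
  expect_false("north" %in% all.vars(formula(fit$model)))
  expect_error(lulc_contrast(fit, "forest"), "forest")
})

test_that("scenes below the cell floor are rejected with a clear reason", {
  df <- fixture_covariates(n_side = 6)
  df$lst <- fixture_response(df, tb = 20, truth = constant_truth())
  expect_error(fit_scene_model(design_from_df(df, classes3),
                               small_model_config()),
               "insufficient cells")
})

test_that("contrast_all_scenes records failures instead of dropping scenes", {
  truth <- constant_truth(seed = 3)
  city <- synth_city(truth, nrow = 150, ncol = 150, analysis_cell_size = 50,
                     n_scenes = 3, n_patches = 30)
  # sabotage one scene: too few usable cells
  city$scenes[[2]]$lst$values[-(1:20)] <- NA
  ct <- suppressWarnings(
    contrast_all_scenes(city, config = small_model_config()))
  fails <- attr(ct, "failures")
  expect_equal(nrow(fails), 1L)
  expect_match(fails$reason, "insufficient cells")
  expect_setequal(unique(ct$scene_id),
                  setdiff(vapply(city$scenes, `[[`, character(1), "id"),
                          fails$scene_id))
})

test_that("identical noiseless scenes give identical contrasts", {
  truth <- constant_truth(seed = 5)
  city <- synth_city(truth, nrow = 150, ncol = 150, analysis_cell_size = 50,
                     n_scenes = 3, n_patches = 30, tb_sd = 0)
  # force a common background temperature so scenes are bit-identical
  for (i in 1:3)
    city$scenes[[i]] <- simulate_scene(city, city$scenes[[i]]$date, 20,
                                       truth, seed = 1)
  ct <- suppressWarnings(
    contrast_all_scenes(city, config = small_model_config()))
  tr <- ct[ct$class_a == "urban_trees", "delta_t"]
  expect_equal(tr[2], tr[1], tolerance = 1e-10)
  expect_equal(tr[3], tr[1], tolerance = 1e-10)
  expect_lt(abs(tr[1] - (-8)), 0.1)
})
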