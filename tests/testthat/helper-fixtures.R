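# Shared fixtures: small, fast synthetic objects built in code.

# truth with linear tree cooling -4 - 0.2*(tb - 10), the reference planting
linear_truth <- function(seed = 1, noise_sd = 0.5, missing_frac = 0.1,
                         trend_amplitude = 2) {
  truth_config(
    offsets = list(
      continuous_urban_fabric = offset_zero(),
      urban_trees = offset_linear(-4, -0.2, ref_tb = 10),
      green_spaces = offset_linear(-1.5, -0.075, ref_tb = 10),
      other_impervious = offset_constant(-0.5)),
    noise_sd = noise_sd, missing_frac = missing_frac,
    trend_amplitude = trend_amplitude, seed = seed)
}

# noiseless, confounder-free truth with constant offsets (exact recovery)
constant_truth <- function(seed = 1, tree_offset = -8, green_offset = -3) {
  truth_config(
    offsets = list(
      continuous_urban_fabric = offset_zero(),
      urban_trees = offset_constant(tree_offset),
      green_spaces = offset_constant(green_offset),
      other_impervious = offset_zero()),
    lapse_rate = 0, trend_amplitude = 0, noise_sd = 0, missing_frac = 0,
    seed = seed)
}

# hand-built scene design from a data.frame (bypasses the raster plumbing)
design_from_df <- function(df, classes) {
  structure(list(data = df, classes = classes, scene_id = "fixture",
                 date = as.Date("2012-07-15"), n_cells = nrow(df)),
            class = "scene_design")
}

# covariate table with mixed fractions on a small grid; fractions are
# beta-distributed and renormalised to sum below 1 (implicit complement)
fixture_covariates <- function(n_side = 22, seed = 42) {
  set.seed(seed)
  n <- n_side^2
  xy <- expand.grid(x = (1:n_side) * 90, y = (1:n_side) * 90)
  raw <- cbind(trees = rbeta(n, 0.4, 0.8), green = rbeta(n, 0.4, 0.8),
               fabric = rbeta(n, 0.8, 0.4))
  tot <- pmax(rowSums(raw), 1)
  raw <- raw / ifelse(tot > 1, tot, 1)
  # guarantee observed pure cells so counterfactuals are interpolations
  raw[1, ] <- c(1, 0, 0); raw[2, ] <- c(0, 1, 0); raw[3, ] <- c(0, 0, 1)
  data.frame(x = xy$x, y = xy$y,
             elev = 300 + 50 * sin(xy$x / 900) * cos(xy$y / 1100),
             north = runif(n),
             frac_urban_trees = raw[, "trees"],
             frac_green_spaces = raw[, "green"],
             frac_continuous_urban_fabric = raw[, "fabric"])
}

# response following the planted additive truth on fixture covariates
fixture_response <- function(df, tb = 20, truth = linear_truth(),
                             noise_sd = 0, seed = 99) {
  set.seed(seed)
  tb +
    df$frac_urban_trees * truth$offsets$urban_trees(tb) +
    df$frac_green_spaces * truth$offsets$green_spaces(tb) +
    df$frac_continuous_urban_fabric *
      truth$offsets$continuous_urban_fabric(tb) +
    truth$lapse_rate * (df$elev - mean(df$elev)) +
    rnorm(nrow(df), 0, noise_sd)
}

small_model_config <- function(...) {
  model_config(basis_2d = c(4, 4), basis_1d = 4, min_cells = 50, ...)
}

# tiny raster helpers
mat_raster <- function(m, cell_size = 10, origin = c(0, nrow(m) * cell_size),
                       label = "") {
  cc_raster(m, cell_size, origin, label)
}
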