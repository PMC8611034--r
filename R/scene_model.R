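#' Configuration of the per-scene additive model
#'
#' @param basis_2d basis dimensions of the 2-D tensor-product smooth over
#'   (x, y), default `c(5, 5)`.
#' @param basis_1d basis dimension of each 1-D thin-plate smooth (elevation,
#'   north-facing fraction, each land-cover fraction), default 5.
#' @param method smoothing-parameter selection criterion: `"REML"` (default)
#'   or `"GCV.Cp"`.
#' @param engine `"gam"` (default) or `"bam"`; `bam` uses fast REML with
#'   discretised covariates and is preferred for bulk replication.
#' @param linear if `TRUE` all terms enter as plain linear effects (no
#'   smooths) — the OLS-equivalent configuration used for oracle checks.
#' @param min_cells hard floor on usable cells per scene; a scene must also
#'   have at least 10x the total basis dimension. Default 100.
#' @param extrapolation_threshold contrasts get `extrapolation_flag = TRUE`
#'   when the maximum observed fraction of either contrasted class falls
#'   below this value (default 0.9).
#' @return a `model_config` list.
#' @export
model_config <- function(basis_2d = c(5, 5), basis_1d = 5, method = "REML",
                         engine = c("gam", "bam"), linear = FALSE,
                         min_cells = 100, extrapolation_threshold = 0.9) {
  engine <- match.arg(engine)
  if (!method %in% c("REML", "GCV.Cp"))
    stop("method must be \"REML\" or \"GCV.Cp\"")
  structure(list(basis_2d = basis_2d, basis_1d = basis_1d, method = method,
                 engine = engine, linear = isTRUE(linear),
                 min_cells = min_cells,
                 extrapolation_threshold = extrapolation_threshold),
            class = "model_config")
}

#' Assemble the per-scene design table
#'
#' Joins one LST scene with the city's analysis-grid covariates (coordinates,
#' elevation, north-facing fraction, one fraction column per declared
#' land-cover predictor) and drops cells that are missing in any layer.
#'
#' @param scene a `scene_record` (or any `cc_raster` of LST on the analysis
#'   grid).
#' @param fractions a `fraction_stack` on the analysis grid.
#' @param elev,north `cc_raster`s of elevation and north-facing fraction.
#' @param class_predictors character; which stack layers enter the model.
#'   Classes left out act as the implicit complement/baseline. Must include
#'   every class you later want to contrast.
#' @return a `scene_design`: list with `data` (data.frame), `classes`,
#'   `scene_id`, `date`, `n_cells`.
#' @export
scene_design <- function(scene, fractions, elev, north,
                         class_predictors = c("urban_trees", "green_spaces",
                                              "continuous_urban_fabric")) {
  lst <- if (is_cc_raster(scene)) scene else scene$lst
  missing_cls <- setdiff(class_predictors, names(fractions))
  if (length(missing_cls))
    stop("fraction stack lacks predictor class(es): ",
         paste(missing_cls, collapse = ", "))
  cc <- cell_centers(lst)
  df <- data.frame(lst = as.vector(lst$values), x = cc$x, y = cc$y,
                   elev = as.vector(elev$values),
                   north = as.vector(north$values))
  for (k in class_predictors)
    df[[paste0("frac_", k)]] <- as.vector(fractions[[k]]$values)
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  structure(list(data = df, classes = class_predictors,
                 scene_id = if (is_cc_raster(scene)) NA_character_
                            else scene$id,
                 date = if (is_cc_raster(scene)) as.Date(NA) else scene$date,
                 n_cells = nrow(df)),
            class = "scene_design")
}

# total number of model coefficients implied by a config
total_basis_dim <- function(config, n_smooth_1d) {
  if (config$linear) 1L + 2L + n_smooth_1d
  else 1L + prod(config$basis_2d) - 1L + n_smooth_1d * (config$basis_1d - 1L)
}

#' Fit the per-scene penalized additive model
#'
#' One additive model per LST scene: a 2-D tensor-product smooth over the
#' spatial coordinates absorbs smooth confounding, thin-plate regression
#' splines carry elevation, north-facing fraction and each land-cover
#' fraction, and smoothing parameters are selected by REML (or GCV). Terms
#' that are constant over the usable cells are dropped with a warning; scenes
#' with too few usable cells or a constant response are rejected.
#'
#' @param design a [scene_design()].
#' @param config a [model_config()].
#' @return a `scene_fit`: list with the fitted mgcv model, the surviving
#'   class terms, dropped terms, reference covariate means, per-class maximum
#'   observed fractions, `r2` and `n_cells`.
#' @export
fit_scene_model <- function(design, config = model_config()) {
  df <- design$data
  vars <- c("elev", "north", paste0("frac_", design$classes))
  keep <- vapply(vars, function(v) {
    rg <- range(df[[v]])
    (rg[2] - rg[1]) > 1e-10
  }, logical(1))
  dropped <- vars[!keep]
  for (d in dropped)
    warning("dropping constant term `", d, "` from scene ",
            design$scene_id, call. = FALSE)
  vars <- vars[keep]
  classes <- sub("^frac_", "", grep("^frac_", vars, value = TRUE))
  floor_n <- max(10L * total_basis_dim(config, length(vars)),
                 config$min_cells)
  if (nrow(df) < floor_n)
    stop("insufficient cells: scene has ", nrow(df),
         " usable cells, needs ", floor_n)
  if (stats::var(df$lst) <= 0)
    stop("response has zero variance in scene ", design$scene_id)
  if (config$linear) {
    terms <- c("x", "y", vars)
  } else {
    k1 <- config$basis_1d
    terms <- c(sprintf("te(x, y, k = c(%d, %d))",
                       config$basis_2d[1], config$basis_2d[2]),
               sprintf("s(%s, k = %d)", vars, k1))
  }
  fml <- stats::as.formula(paste("lst ~", paste(terms, collapse = " + ")))
  fit <- if (config$engine == "bam" && !config$linear) {
    mgcv::bam(fml, data = df,
              method = if (config$method == "REML") "fREML" else "GCV.Cp",
              discrete = (config$method == "REML"))
  } else {
    mgcv::gam(fml, data = df, method = config$method)
  }
  ref <- vapply(df[, c("x", "y", "elev", "north")], mean, numeric(1))
  max_frac <- vapply(classes,
                     function(k) max(df[[paste0("frac_", k)]]), numeric(1))
  structure(list(model = fit, classes = classes, dropped = dropped,
                 reference = ref, max_frac = max_frac, config = config,
                 r2 = summary(fit)$r.sq, n_cells = nrow(df),
                 scene_id = design$scene_id, date = design$date),
            class = "scene_fit")
}

#' Counterfactual pure-class temperature contrast
#'
#' Evaluates the fitted model at two counterfactual states sharing the same
#' reference covariates (city means): 100% cover of `class_a` and 100% cover
#' of `class_b`, all other modelled fractions zero. The contrast is the
#' difference of these predictions — a linear functional of the coefficients
#' — and its standard error follows by the delta method from the coefficient
#' covariance. Negative values mean `class_a` is cooler than `class_b`.
#'
#' @param fit a [fit_scene_model()] result.
#' @param class_a vegetated (or any) class predicted at fraction 1.
#' @param class_b reference class, default continuous urban fabric.
#' @return one-row data.frame: `scene_id`, `date`, `class_a`, `class_b`,
#'   `delta_t` (K), `se` (K), `n_cells`, `extrapolation_flag`, `r2`.
#' @export
lulc_contrast <- function(fit, class_a,
                          class_b = "continuous_urban_fabric") {
  for (cl in c(class_a, class_b))
    if (!cl %in% fit$classes)
      stop("class `", cl, "` is not a term of this scene model")
  res <- data.frame(scene_id = fit$scene_id, date = fit$date,
                    class_a = class_a, class_b = class_b,
                    delta_t = 0, se = 0, n_cells = fit$n_cells,
                    extrapolation_flag = FALSE, r2 = fit$r2,
                    stringsAsFactors = FALSE)
  if (identical(class_a, class_b)) return(res)
  nd <- as.data.frame(as.list(fit$reference))
  for (k in fit$classes) nd[[paste0("frac_", k)]] <- 0
  nd <- nd[c(1, 1), , drop = FALSE]
  nd[1, paste0("frac_", class_a)] <- 1
  nd[2, paste0("frac_", class_b)] <- 1
  Xp <- mgcv::predict.gam(fit$model, newdata = nd, type = "lpmatrix")
  d <- Xp[1, ] - Xp[2, ]
  beta <- stats::coef(fit$model)
  V <- stats::vcov(fit$model)
  res$delta_t <- sum(d * beta)
  res$se <- sqrt(max(0, drop(t(d) %*% V %*% d)))
  thr <- fit$config$extrapolation_threshold
  res$extrapolation_flag <- (fit$max_frac[class_a] < thr) ||
    (fit$max_frac[class_b] < thr)
  res
}

#' Contrast every scene of a city
#'
#' Fits one additive model per scene and computes the requested pure-class
#' contrasts. Scenes whose fit is rejected (too few usable cells, degenerate
#' response) are recorded in the `failures` attribute with their reason —
#' never silently dropped.
#'
#' @param city a [synth_city()] (or any list with `scenes`, `fractions`,
#'   `elev_analysis`, `north_fraction`).
#' @param class_pairs list of `c(class_a, class_b)` pairs; default contrasts
#'   urban trees and green spaces against continuous urban fabric.
#' @param config a [model_config()].
#' @param class_predictors layers entering each model. The default mirrors
#'   the practice of modelling the full land-cover vocabulary: every class of
#'   the city's fraction stack enters except one class not named in any
#'   contrast, which is left out as the implicit complement/baseline (the
#'   fractions would otherwise sum to one and alias the intercept).
#'   Omitting a class with a land-cover signal of its own from the predictor
#'   list biases the remaining terms, so only the complement is dropped.
#' @return data.frame of contrasts (one row per scene x pair) with a
#'   `failures` attribute (data.frame `scene_id`, `reason`).
#' @export
contrast_all_scenes <- function(city,
                                class_pairs = list(
                                  c("urban_trees", "continuous_urban_fabric"),
                                  c("green_spaces", "continuous_urban_fabric")),
                                config = model_config(),
                                class_predictors = NULL) {
  if (!length(city$scenes)) stop("city has no scenes")
  if (is.null(class_predictors)) {
    vocab <- attr(city$fractions, "classes")
    in_pairs <- unique(unlist(class_pairs))
    spare <- setdiff(vocab, in_pairs)
    complement <- if (length(spare)) spare[length(spare)] else character()
    class_predictors <- setdiff(vocab, complement)
  }
  rows <- list(); fails <- list()
  for (s in city$scenes) {
    res <- tryCatch({
      des <- scene_design(s, city$fractions, city$elev_analysis,
                          city$north_fraction,
                          class_predictors = class_predictors)
      fit <- fit_scene_model(des, config)
      do.call(rbind, lapply(class_pairs, function(p)
        lulc_contrast(fit, p[1], p[2])))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(scene_id = s$id, reason = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows))
    stop("all scenes failed; first reason: ", fails[[1]]$reason)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails)
    else data.frame(scene_id = character(), reason = character())
  out
}
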