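grid10 <- function(n = 20) list(nrow = n, ncol = n, cell_size = 10,
                                origin = c(0, n * 10))

rect_poly <- function(x0, y0, x1, y1, class) {
  list(class = class,
       coords = rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)))
}

test_that("rasterization follows the cell-center rule", {
  g <- grid10(10)
  # one rectangle covering everything
  r <- rasterize_polygons(list(rect_poly(-1, -1, 101, 101, "a")), g)
  expect_true(all(r$values == 1L))

  # two half-plane rectangles: left A, right B, no nodata
  r2 <- rasterize_polygons(list(rect_poly(-1, -1, 50, 101, "a"),
                                rect_poly(50, -1, 101, 101, "b")), g)
  expect_false(anyNA(r2$values))
  expect_true(all(r2$values[, 1:5] == 1L))
  expect_true(all(r2$values[, 6:10] == 2L))

  # uncovered cells are nodata
  r3 <- rasterize_polygons(list(rect_poly(-1, -1, 45, 101, "a")), g)
  expect_true(all(is.na(r3$values[, 6:10])))
})

test_that("rasterized circle area is close to pi r^2", {
  g <- list(nrow = 30, ncol = 30, cell_size = 10, origin = c(0, 300))
  theta <- seq(0, 2 * pi, length.out = 200)[-200]
  circ <- list(class = "c",
               coords = cbind(150 + 55 * cos(theta), 150 + 55 * sin(theta)))
  r <- rasterize_polygons(list(circ), g)
  area <- sum(!is.na(r$values)) * 100
  expect_lt(abs(area - pi * 55^2) / (pi * 55^2), 0.1)
})

test_that("polygons outside the grid warn and are ignored; bad geometry rejects", {
  g <- grid10(10)
  expect_warning(
    r <- rasterize_polygons(list(rect_poly(-1, -1, 101, 101, "a"),
                                 rect_poly(500, 500, 600, 600, "b")), g),
    "outside")
  expect_true(all(r$values == 1L))
  bad <- list(list(class = "a", coords = rbind(c(0, 0), c(1, 1))))
  expect_error(rasterize_polygons(bad, g), "geometry")
})

test_that("fraction aggregation equals subcell counts exactly", {
  # build a 9x9 fine map: 40 cells of class 2 in the single 90 m block
  m <- matrix(1L, 9, 9)
  m[seq_len(40) + 9] <- 2L   # deterministic placement of 40 subcells
  cm <- mat_raster(m, cell_size = 10)
  attr(cm, "classes") <- c("continuous_urban_fabric", "urban_trees")
  fs <- aggregate_fractions(cm, 90)
  expect_equal(fs$urban_trees$values[1, 1], 40 / 81)
  expect_equal(fs$continuous_urban_fabric$values[1, 1], 41 / 81)

  # uniform map: fraction 1 for that class, 0 for the others
  u <- mat_raster(matrix(1L, 18, 18), cell_size = 10)
  attr(u, "classes") <- c("a", "b")
  fu <- aggregate_fractions(u, 90)
  expect_true(all(fu$a$values == 1))
  expect_true(all(fu$b$values == 0))
})

test_that("exclusive fractions sum to one on fully covered cells", {
  set.seed(5)
  m <- matrix(sample(1:3, 27 * 27, replace = TRUE), 27, 27)
  cm <- mat_raster(m, cell_size = 10)
  attr(cm, "classes") <- c("a", "b", "c")
  fs <- aggregate_fractions(cm, 90)
  tot <- fs$a$values + fs$b$values + fs$c$values
  expect_equal(tot, matrix(1, 3, 3), tolerance = 1e-12)
})

test_that("nodata subcells shrink the denominator, and the tree overlay is independent", {
  m <- matrix(1L, 9, 9); m[1:3] <- NA
  cm <- mat_raster(m, cell_size = 10)
  attr(cm, "classes") <- c("a")
  tree <- mat_raster(matrix(c(rep(1, 20), rep(0, 61)), 9, 9), cell_size = 10)
  fs <- aggregate_fractions(cm, 90, tree_map = tree)
  expect_equal(fs$a$values[1, 1], 1)           # 78/78 of valid subcells
  expect_equal(fs$urban_trees$values[1, 1], 20 / 81)
})

test_that("aspect of tilted planes matches the analytic dip direction", {
  n <- 9
  xy <- expand.grid(row = 1:n, col = 1:n)
  mk <- function(f) mat_raster(matrix(f(xy$row, xy$col), n, n), cell_size = 10)
  # z decreasing southward (row increasing) -> downslope due south
  south <- compute_aspect(mk(function(r, co) 1000 - 5 * r))
  expect_true(all(abs(south$values[2:(n - 1), 2:(n - 1)] - 180) < 0.5))
  # z decreasing eastward -> due east
  east <- compute_aspect(mk(function(r, co) 1000 - 5 * co))
  expect_true(all(abs(east$values[2:(n - 1), 2:(n - 1)] - 90) < 0.5))
  # all 8 cardinal/diagonal dips: plane decreasing along compass angle theta
  for (theta in seq(0, 315, by = 45)) {
    th <- theta * pi / 180
    a <- compute_aspect(mk(function(r, co)
      1000 - 5 * (sin(th) * co - cos(th) * r)))
    interior <- a$values[2:(n - 1), 2:(n - 1)]
    diffs <- (interior - theta + 180) %% 360 - 180
    expect_true(all(abs(diffs) < 0.5), label = paste("dip", theta))
  }
  # constant DEM: all nodata
  flat <- compute_aspect(mk(function(r, co) 500))
  expect_true(all(is.na(flat$values)))
})

test_that("north-facing classification uses the quoted half-open intervals", {
  n <- 9
  mk_aspect <- function(deg) {
    a <- mat_raster(matrix(deg, n, n), cell_size = 10)
    a$values[c(1, n), ] <- NA; a$values[, c(1, n)] <- NA
    a
  }
  expect_equal(north_facing_fraction(mk_aspect(0), 90)$values[1, 1], 1)
  expect_equal(north_facing_fraction(mk_aspect(180), 90)$values[1, 1], 0)
  # boundary directions 90 and 270 are south-facing
  expect_equal(north_facing_fraction(mk_aspect(90), 90)$values[1, 1], 0)
  expect_equal(north_facing_fraction(mk_aspect(270), 90)$values[1, 1], 1)
  expect_equal(north_facing_fraction(mk_aspect(269.99), 90)$values[1, 1], 0)
  # uniform aspects: fraction approaches one half
  set.seed(8)
  u <- mat_raster(matrix(runif(90 * 90, 0, 360), 90, 90), cell_size = 10)
  fr <- north_facing_fraction(u, 900)
  expect_lt(abs(fr$values[1, 1] - 0.5), 0.02)
})

test_that("FVC follows the squared scaled-NDVI relationship with clipping", {
  expect_equal(ndvi_to_fvc(0.1), 0)       # below soil reference
  expect_equal(ndvi_to_fvc(0.2), 0)
  expect_equal(ndvi_to_fvc(0.5), 1)       # at/above vegetation reference
  expect_equal(ndvi_to_fvc(0.9), 1)
  expect_equal(ndvi_to_fvc(0.35), 0.25)   # midpoint: (1/2)^2
  expect_error(ndvi_to_fvc(0.3, ndvi_soil = 0.6, ndvi_veg = 0.2), "greater")
})

test_that("emissivity interpolates linearly between 0.97 and 0.99", {
  expect_identical(fvc_to_emissivity(0), 0.97)
  expect_identical(fvc_to_emissivity(1), 0.99)
  expect_equal(fvc_to_emissivity(0.5), 0.98)
  expect_error(fvc_to_emissivity(1.2), "\\[0, 1\\]")
  # monotone and bounded along an NDVI sweep
  nd <- seq(-0.2, 0.9, by = 0.01)
  em <- fvc_to_emissivity(ndvi_to_fvc(nd))
  expect_true(all(diff(em) >= 0))
  expect_true(all(em >= 0.97 & em <= 0.99))
})
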