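# Geometry layer: plot composition, reference plots, super hedges,
# infrastructure proximity.

test_that("plot composition resolves pure and split plots exactly", {
  m <- uniform_map("arable", n = 30, cell_size = 10)
  p <- plot_composition(m, circular_plot(c(150, 150), radius = 60))
  expect_equal(unname(p[["arable"]]), 1)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  hp <- halfplane_map("arable", "meadow", n = 200, cell_size = 1)
  # plot centred on the boundary: cell centres are symmetric about it
  p2 <- plot_composition(hp, circular_plot(c(100, 100), radius = 40))
  expect_equal(unname(p2[["arable"]]), 0.5, tolerance = 1e-12)
  expect_equal(unname(p2[["meadow"]]), 0.5, tolerance = 1e-12)
})

test_that("plot composition rejects empty intersections and unlabelled area", {
  m <- uniform_map("arable", n = 10, cell_size = 10)
  expect_error(plot_composition(m, circular_plot(c(1e4, 1e4), radius = 50)),
               "does not intersect")
  g <- matrix("arable", 10, 10)
  holey <- make_grid_map(g, cell_size = 10)
  holey$grid[3:8, 3:8] <- NA
  expect_error(plot_composition(holey, circular_plot(c(50, 50), radius = 40)),
               "unlabelled")
})

test_that("composition proportions are invariant to patch layout relabelling", {
  # two maps with identical per-code cell multisets but different arrangement
  set.seed(1)
  g1 <- matrix(c("arable", "meadow"), 20, 20)
  g2 <- matrix(sample(g1), 20, 20)
  m1 <- make_grid_map(g1, cell_size = 5)
  m2 <- make_grid_map(g2, cell_size = 5)
  big <- circular_plot(c(50, 50), radius = 1000)  # covers everything, clipped
  expect_equal(plot_composition(m1, big)[["arable"]],
               plot_composition(m2, big)[["arable"]], tolerance = 1e-12)
})

test_that("grid rasterisation of polygons converges to exact areas", {
  # 120 m square: left 70 m arable, right 50 m split into meadow / road
  sq <- survey_square("g1", cx = 60, cy = 60, side = 120)
  ring <- function(x0, y0, x1, y1) {
    cbind(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0))
  }
  feats <- list(
    list(square_id = "g1", year = 2017, scale = "rough", habitat = "arable",
         ring = ring(0, 0, 70, 120)),
    list(square_id = "g1", year = 2017, scale = "rough", habitat = "meadow",
         ring = ring(70, 0, 120, 60)),
    list(square_id = "g1", year = 2017, scale = "rough", habitat = "road",
         ring = ring(70, 60, 120, 120))
  )
  path <- write_toy_geojson(tempfile(fileext = ".geojson"), feats)
  exact <- c(arable = 70 * 120, meadow = 50 * 60, road = 50 * 60) / (120 * 120)
  errs <- vapply(c(4, 2, 1), function(cs) {
    m <- read_patch_geojson(path, sq, cell_size = cs)
    max(abs(map_composition(m)[names(exact)] - exact))
  }, numeric(1))
  expect_lt(errs[3], 0.01)
  expect_true(errs[3] <= errs[1])
  # plot-level agreement across resolutions
  m1 <- read_patch_geojson(path, sq, cell_size = 1)
  m025 <- read_patch_geojson(path, sq, cell_size = 0.25)
  plt <- circular_plot(c(65, 60), radius = 30)
  p1 <- plot_composition(m1, plt)
  p2 <- plot_composition(m025, plt)
  expect_lt(max(abs(p1[c("arable", "meadow", "road")] - p2[c("arable", "meadow", "road")])), 0.01)
})

test_that("reference plots sit at square centres with the right area", {
  sqs <- survey_square(c("a", "b"), cx = c(0, 1000), cy = c(0, 0), side = 618)
  pa <- reference_plot(sqs[1, ], radius = 100)
  pb <- reference_plot(sqs[2, ], radius = 100)
  expect_equal(pa$center, c(0, 0))
  expect_equal(pb$center, c(1000, 0))
  expect_equal(pa$area_ha, pi, tolerance = 1e-6)  # 3.14 ha at 100 m
  expect_equal(pa$kind, "availability")
  expect_error(reference_plot(sqs[1, ], radius = 0), "radius")
})

test_that("super hedges require all three thresholds strictly exceeded", {
  expect_true(classify_super_hedge(5, 3, 0.80))
  expect_false(classify_super_hedge(4, 3, 0.80))   # height at the boundary
  expect_false(classify_super_hedge(5, 3, 0.70))   # cover at the boundary
  expect_false(classify_super_hedge(5, 2, 0.80))   # width at the boundary
  expect_equal(classify_super_hedge(c(5, 4.5), c(3, 1), c(0.8, 0.9)), c(TRUE, FALSE))
  expect_error(classify_super_hedge(-1, 3, 0.5), "non-negative")
  expect_error(classify_super_hedge(5, 3, 1.2), "<= 1")
})

test_that("infrastructure distance is zero inside, exact to plane geometry outside", {
  # 100 x 100 m arable map with a vertical road strip x in [40, 50]
  g <- matrix("arable", 20, 20)
  g[, 9:10] <- "road"
  m <- make_grid_map(g, cell_size = 5)
  expect_equal(distance_to_nearest_infrastructure(c(45, 50), m), 0)
  expect_equal(distance_to_nearest_infrastructure(c(100, 50), m), 50)
  # undefined when no infrastructure exists
  expect_true(is.na(distance_to_nearest_infrastructure(c(5, 5), uniform_map("arable"))))
})

test_that("infrastructure distance matches a brute-force raster oracle and is 1-Lipschitz", {
  for (s in 1:5) {
    set.seed(s)
    g <- matrix(sample(c("arable", "meadow", "road"), 144, replace = TRUE,
                       prob = c(0.6, 0.3, 0.1)), 12, 12)
    m <- make_grid_map(g, cell_size = 5)
    cc_x <- (seq_len(12) - 0.5) * 5
    infra <- which(g == "road", arr.ind = TRUE)
    pts <- matrix(runif(20, 0, 60), ncol = 2)
    prev <- NULL
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, ]
      d <- distance_to_nearest_infrastructure(p, m)
      oracle <- min(sqrt((cc_x[infra[, 2]] - p[1])^2 + (cc_x[infra[, 1]] - p[2])^2))
      expect_lt(abs(d - oracle), 5 * sqrt(2) / 2 + 1e-9)
      expect_lte(d, oracle + 1e-9)
    }
    # Lipschitz along a random segment
    p0 <- c(10, 10); p1 <- c(55, 50)
    dvals <- sapply(seq(0, 1, length.out = 25), function(t)
      distance_to_nearest_infrastructure(p0 + t * (p1 - p0), m))
    step <- sqrt(sum((p1 - p0)^2)) / 24
    expect_true(all(abs(diff(dvals)) <= step + 1e-9))
  }
})

test_that("ASCII-grid round trip preserves maps bit-identically", {
  scn <- scenario_fixture()
  m <- generate_landscape(scn, 2017L)[[2]]
  asc <- tempfile(fileext = ".asc"); leg <- tempfile(fileext = ".csv")
  write_patch_asc(m, asc, leg)
  m2 <- read_patch_asc(asc, leg)
  expect_identical(m2$grid, m$grid)
  expect_identical(m2$levels, m$levels)
  expect_identical(m2$square_id, m$square_id)
  expect_equal(m2$origin, m$origin)
  expect_equal(m2$cell_size, m$cell_size)
})

test_that("unknown habitat codes are rejected, not pooled", {
  vocab <- habitat_vocabulary("rough")
  expect_error(
    patch_map(matrix("lunar_regolith", 2, 2), square_id = "x", year = 2017,
              scale = "rough", cell_size = 10),
    "unknown habitat code"
  )
  expect_true("road" %in% infrastructure_codes(vocab))
  expect_false("meadow" %in% infrastructure_codes(vocab))
})
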