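# Landscape metrics: patches, change tables, diversity, distances, trends.

test_that("patchify labels connected same-type regions", {
  m <- uniform_map("arable", n = 10, cell_size = 10)
  p <- patchify(m)
  expect_equal(nrow(p), 1L)
  expect_equal(p$area_ha, 1)  # 100 x 100 m

  checker <- make_grid_map(matrix(c("arable", "meadow", "meadow", "arable"), 2, 2),
                           cell_size = 10)
  expect_equal(nrow(patchify(checker, connectivity = 4)), 4L)
  expect_equal(nrow(patchify(checker, connectivity = 8)), 2L)
})

test_that("patchify agrees with a brute-force labelling oracle on random maps", {
  # oracle: naive label propagation, iterated to a fixed point
  oracle_components <- function(g, connectivity) {
    nr <- nrow(g); nc <- ncol(g)
    lab <- matrix(seq_along(g), nr, nc)
    offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    if (connectivity == 8) {
      offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
    }
    repeat {
      changed <- FALSE
      for (i in seq_len(nr)) for (j in seq_len(nc)) for (o in offs) {
        i2 <- i + o[1]; j2 <- j + o[2]
        if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc &&
            g[i, j] == g[i2, j2] && lab[i2, j2] < lab[i, j]) {
          lab[i, j] <- lab[i2, j2]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    sort(as.numeric(table(lab)))
  }
  for (s in 1:4) for (conn in c(4, 8)) {
    set.seed(s)
    g <- matrix(sample(c("arable", "meadow", "road"), 64, replace = TRUE), 8, 8)
    m <- make_grid_map(g, cell_size = 10)
    p <- patchify(m, connectivity = conn)
    expect_equal(sort(p$n_cells), oracle_components(g, conn))
    expect_equal(sum(p$area_ha), map_total_area(m), tolerance = 1e-12)
  }
})

test_that("change summary reports plot-sampled patch statistics per scope", {
  m <- uniform_map("arable", n = 20, cell_size = 10, square_id = "s1", year = 2017L)
  cs <- change_summary(list(m), scopes = "availability", radius = 50)
  expect_equal(cs$avg_patches, 1)
  expect_equal(cs$avg_patch_area_ha, 4)  # full square: 200 x 200 m
  expect_equal(cs$total_infra_ha, 0)

  # infrastructure columns count only infrastructure codes
  g <- matrix("arable", 20, 20); g[, 10] <- "road"
  m2 <- make_grid_map(g, cell_size = 10, square_id = "s1", year = 2017L)
  cs2 <- change_summary(list(m2), scopes = "availability", radius = 50)
  expect_equal(cs2$avg_infra_patches, 1)
  expect_equal(cs2$total_infra_ha, 20 * 100 / 1e4)

  # presence scopes flag empty years instead of reporting zeros
  obs <- data.frame(obs_id = "o1", unit_id = "o1", square_id = "s1", x = 100, y = 100,
                    year = 2016L, season = "spring", unit_kind = "territory",
                    group_size = 2L)
  cs3 <- change_summary(list(m2), obs, scopes = "per_partridge", radius = 50)
  expect_true(cs3$empty)  # observation year does not match the map year
  expect_true(is.na(cs3$avg_patches))
})

test_that("change summary is invariant to square ordering", {
  scn <- scenario_fixture()
  maps <- generate_landscape(scn, 2017L)
  a <- change_summary(maps, scopes = "availability", radius = 60)
  b <- change_summary(rev(maps), scopes = "availability", radius = 60)
  expect_equal(a, b)
})

test_that("the generator's fragmentation trend shows up in patch counts", {
  counts <- sapply(1:6, function(s) {
    scn <- partridge_scenario(
      n_squares = 5, years = c(2001L, 2009L), patches_per_square = c(8L, 24L),
      composition = NULL, seed = 900 + s
    )
    sapply(scn$years, function(yr) {
      mean(vapply(generate_landscape(scn, yr), function(m) nrow(patchify(m)), numeric(1)))
    })
  })
  ratio <- mean(counts[2, ] / counts[1, ])
  expect_gte(ratio, 2.4)
  expect_lte(ratio, 3.6)
})

test_that("Shannon index matches closed forms and vegan", {
  expect_equal(shannon_index(c(1)), 0)
  expect_equal(shannon_index(c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_equal(shannon_index(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_index(c(0.5, 0.5, 0)), log(2), tolerance = 1e-12)  # 0 ln 0 = 0
  expect_error(shannon_index(c(-0.1, 1.1)), "non-negative")
  # never exceeds ln(m); equality only at uniformity
  set.seed(3)
  for (i in 1:10) {
    p <- runif(5); p <- p / sum(p)
    expect_lte(shannon_index(p), log(5) + 1e-12)
  }
})

test_that("diversity table separates used and available records", {
  dv <- diversity_table(
    used = list(u1 = c(0.9, 0.1), u2 = c(0.5, 0.5)),
    available = list(s1 = c(0.25, 0.75))
  )
  expect_equal(nrow(dv), 3L)
  expect_equal(dv$H[dv$unit == "u2"], log(2), tolerance = 1e-12)
  expect_setequal(unique(dv$type), c("used", "available"))
})

test_that("seasonal distance summary orders groups by construction", {
  # winter points on the road, spring points far from it
  g <- matrix("arable", 30, 30); g[, 15] <- "road"
  m <- make_grid_map(g, cell_size = 10, square_id = "s1", year = 2017L)
  obs <- data.frame(
    obs_id = paste0("o", 1:6), unit_id = paste0("o", 1:6), square_id = "s1",
    x = c(145, 146, 144, 20, 25, 290), y = c(50, 100, 150, 50, 100, 150),
    year = 2017L, season = rep(c("winter", "spring"), each = 3),
    unit_kind = rep(c("covey", "territory"), each = 3), group_size = 5L
  )
  ds <- seasonal_distance_summary(obs, list(m), seed = 5)
  med <- setNames(ds$median_m, ds$group)
  expect_equal(unname(med["winter_used"]), 0)
  expect_gt(med["spring_used"], med["winter_used"])
  expect_equal(ds$n_undefined, c(0L, 0L, 0L))
  # single point: median defined, SE flagged NA
  one <- seasonal_distance_summary(obs[1, ], list(m), seed = 5)
  expect_true(is.na(one$se_median[one$group == "winter_used"]))
})

test_that("trend correlation matches the closed-form definition", {
  x <- 1:10
  expect_equal(trend_correlation(x, 2 * x + 1), 1)
  expect_equal(trend_correlation(x, -2 * x + 31), -1)
  set.seed(8)
  y <- rnorm(10)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(trend_correlation(x, y), manual, tolerance = 1e-12)
  expect_error(trend_correlation(1:2, 2:3), "3 pairs")
  expect_error(trend_correlation(c(1, 1, 1), 1:3), "zero variance")
})
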