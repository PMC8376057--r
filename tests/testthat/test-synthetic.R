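# Synthetic scenario generator: determinism, composition targets, placement
# model, ground truth.

test_that("landscape generation is deterministic and hits composition targets", {
  # the composition contract applies at the scenario's full 20-square extent
  scn <- partridge_scenario(seed = 31L)
  m1 <- generate_landscape(scn, 2001L)
  m2 <- generate_landscape(scn, 2001L)
  expect_identical(lapply(m1, `[[`, "grid"), lapply(m2, `[[`, "grid"))

  for (yi in seq_along(scn$years)) {
    maps <- if (yi == 1) m1 else generate_landscape(scn, scn$years[yi])
    comp <- Reduce(`+`, lapply(maps, map_composition)) / length(maps)
    target <- scn$composition[yi, ]
    expect_lt(max(abs(comp[names(target)] - target)), 0.05)
  }

  # different seed, different landscape
  m3 <- generate_landscape(partridge_scenario(seed = 32L), 2001L)
  expect_false(identical(m1[[1]]$grid, m3[[1]]$grid))
})

test_that("single-type targets produce one patch per square", {
  scn <- partridge_scenario(
    n_squares = 2, years = 2017L, habitats = "arable",
    composition = matrix(1, 1, 1, dimnames = list(NULL, "arable")),
    patches_per_square = 5L,
    weights = list(winter = c(arable = 1), spring = c(arable = 1)),
    seed = 4L
  )
  maps <- generate_landscape(scn, 2017L)
  expect_true(all(vapply(maps, function(m) nrow(patchify(m)) == 1L, logical(1))))
})

test_that("rejected scenarios fail loudly", {
  badshare <- matrix(c(0.6, 0.6), 1, 2, dimnames = list(NULL, c("arable", "meadow")))
  expect_error(
    partridge_scenario(years = 2017L, habitats = c("arable", "meadow"),
                       composition = badshare, patches_per_square = 4L),
    "sum to 1"
  )
  expect_error(partridge_scenario(covey_size_range = c(2L, 10L)), "exceed 2")
  expect_error(
    partridge_scenario(weights = list(
      winter = c(arable = -1, meadow = 1, vineyard = 1, hedgerow = 1, road = 1, field_path = 1),
      spring = c(arable = 1, meadow = 1, vineyard = 1, hedgerow = 1, road = 1, field_path = 1))),
    "> 0"
  )
  expect_error(generate_landscape(partridge_scenario(), 1999L), "not part")
})

test_that("placed units respect covey structure and square membership", {
  scn <- scenario_fixture()
  maps <- generate_landscape(scn, 2017L)
  winter <- place_units(scn, maps, "winter", 2017L)
  expect_true(all(winter$group_size >= 3 & winter$group_size <= 15))
  expect_true(all(winter$unit_kind == "covey"))
  expect_equal(length(unique(winter$unit_id)), scn$units_per_season[["winter"]])
  spring <- place_units(scn, maps, "spring", 2017L)
  expect_equal(nrow(spring), scn$units_per_season[["spring"]])  # 1 location each
  expect_true(all(spring$unit_kind == "territory"))
  # locations inside their square
  expect_equal(nrow(validate_inputs(rbind(winter, spring), maps)), 0L)
  # determinism
  expect_identical(winter, place_units(scn, maps, "winter", 2017L))
})

test_that("uniform weights make use converge to availability", {
  scn <- partridge_scenario(
    n_squares = 2,
    weights = list(
      winter = stats::setNames(rep(1, 6), c("arable", "meadow", "vineyard", "hedgerow", "road", "field_path")),
      spring = stats::setNames(rep(1, 6), c("arable", "meadow", "vineyard", "hedgerow", "road", "field_path"))
    ),
    units_per_season = c(winter = 1, spring = 1),
    locations_per_unit = c(winter = 5000, spring = 1),
    seed = 91L
  )
  maps <- generate_landscape(scn, 2001L)
  obs <- place_units(scn, maps, "winter", 2001L)
  sq <- obs$square_id[1]
  avail <- map_composition(maps[[sq]])[scn$habitats]
  cc <- cell_centres(maps[[sq]])
  # classify each location by its containing cell's habitat
  j <- findInterval(obs$x, c(cc$x - scn$cell_size / 2, Inf))
  i <- findInterval(obs$y, c(cc$y - scn$cell_size / 2, Inf))
  codes <- maps[[sq]]$levels[maps[[sq]]$grid[cbind(i, j)]]
  use <- table(factor(codes, levels = scn$habitats)) / nrow(obs)
  expect_lt(max(abs(as.numeric(use) - avail)), 0.03)
})

test_that("weights on absent types are renormalised with a warning", {
  scn <- partridge_scenario(
    n_squares = 2, years = 2017L,
    habitats = c("arable", "meadow", "road"),
    composition = matrix(c(0.7, 0.3, 0), 1, 3,
                         dimnames = list(NULL, c("arable", "meadow", "road"))),
    patches_per_square = 6L,
    weights = list(winter = c(arable = 1, meadow = 1, road = 5),
                   spring = c(arable = 1, meadow = 1, road = 5)),
    units_per_season = c(winter = 3, spring = 3),
    locations_per_unit = c(winter = 10, spring = 1),
    seed = 6L
  )
  maps <- generate_landscape(scn, 2017L)  # road never realised (share 0)
  expect_warning(obs <- place_units(scn, maps, "winter", 2017L), "renormalised")
  expect_true(all(obs$square_id %in% names(maps)))
})

test_that("analytic ground truth follows the alpha/epsilon algebra", {
  gt <- scenario_ground_truth(partridge_scenario())
  expect_equal(gt$m, 6L)
  for (season in c("winter", "spring")) {
    df <- gt[[season]]
    expect_equal(sum(df$true_alpha), 1, tolerance = 1e-12)
    # monotone weights give monotone electivities
    expect_equal(order(df$true_alpha), order(df$true_epsilon))
    expect_true(all(abs(df$true_epsilon) <= 1))
  }
  # m = 2 reduction: eps = 2 alpha - 1
  scn2 <- partridge_scenario(
    n_squares = 2, years = 2017L, habitats = c("arable", "meadow"),
    composition = matrix(c(0.5, 0.5), 1, 2, dimnames = list(NULL, c("arable", "meadow"))),
    patches_per_square = 4L,
    weights = list(winter = c(arable = 9, meadow = 1), spring = c(arable = 9, meadow = 1)),
    seed = 2L
  )
  gt2 <- scenario_ground_truth(scn2)$winter
  expect_equal(gt2$true_alpha, c(0.9, 0.1))
  expect_equal(gt2$true_epsilon, c(0.8, -0.8), tolerance = 1e-12)
  # neutral weights give zero electivity
  eqw <- stats::setNames(rep(1, 6), partridge_scenario()$habitats)
  gt0 <- scenario_ground_truth(partridge_scenario(weights = list(winter = eqw, spring = eqw)))
  expect_equal(gt0$winter$true_epsilon, rep(0, 6), tolerance = 1e-12)
})

test_that("a simulated study bundles maps and observations coherently", {
  scn <- partridge_scenario(
    n_squares = 3, units_per_season = c(winter = 4, spring = 4),
    locations_per_unit = c(winter = 5, spring = 1), seed = 77L
  )
  sim <- simulate_scenario(scn)
  expect_equal(nrow(sim$squares), 3L)
  expect_equal(length(sim$maps), 3L * 3L)  # squares x years
  expect_setequal(unique(sim$observations$year[sim$observations$season == "winter"]), 2017L)
  expect_setequal(unique(sim$observations$year[sim$observations$season == "spring"]),
                  c(2001L, 2009L, 2017L))
})
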