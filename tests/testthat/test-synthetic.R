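test_that("generation is fully determined by the seed", {
  a1 <- generate_county(synth_config(seed = 5, n_towns = 24))
  a2 <- generate_county(synth_config(seed = 5, n_towns = 24))
  expect_identical(a1$units, a2$units)
  expect_identical(igraph::as_edgelist(area_graph(a1)),
                   igraph::as_edgelist(area_graph(a2)))
  a3 <- generate_county(synth_config(seed = 6, n_towns = 24))
  expect_false(identical(a1$units$mos, a3$units$mos))
})

test_that("the town lattice is connected and simple", {
  for (s in 1:5) {
    a <- generate_county(synth_config(seed = s, n_towns = 10 + 7 * s))
    g <- area_graph(a)
    expect_true(igraph::is_connected(g))
    expect_true(igraph::is_simple(g))
    expect_equal(igraph::vcount(g), 10 + 7 * s)
  }
})

test_that("block-group populations match the configured dispersion", {
  cfg <- synth_config(seed = 3, n_towns = 2000, bg_per_town = c(1, 1),
                      city_fraction = 0)
  bg <- block_group_units(generate_county(cfg))
  expect_equal(nrow(bg), 2000)
  expect_lt(abs(mean(bg$population) - cfg$pop_mean) / cfg$pop_mean, 0.05)
  expect_lt(abs(sd(bg$population) - cfg$pop_sd) / cfg$pop_sd, 0.05)
})

test_that("hazard and capacity indices are inversely correlated as configured", {
  cfg <- synth_config(seed = 17, n_towns = 200, city_fraction = 0,
                      h_a_correlation = -0.6)
  area <- compute_indices(generate_county(cfg))
  tu <- top_units(area)
  r <- cor(tu$h_s, tu$a_s)
  expect_lt(r, 0)
  expect_lt(abs(r - (-0.6)), 0.15)
})

test_that("a configured city exceeds the MOS bound and triggers splitting", {
  cfg <- synth_config(seed = 9, n_towns = 60) # one city by default
  area <- generate_county(cfg)
  tu <- top_units(area)
  n_strata <- 14
  b <- mos_bounds(sum(tu$mos) / n_strata)
  expect_true(any(tu$mos > b[["hi"]]))
  expect_gte(split_count(max(tu$mos), sum(tu$mos) / n_strata), 2L)
})

test_that("nesting is intact: town totals equal their block-group sums", {
  area <- generate_county(synth_config(seed = 12, n_towns = 20))
  tu <- top_units(area)
  bg <- block_group_units(area)
  pops <- tapply(bg$population, bg$parent_id, sum)
  expect_equal(as.numeric(pops[tu$unit_id]), tu$population)
  mos <- tapply(bg$mos, bg$parent_id, sum)
  expect_equal(as.numeric(mos[tu$unit_id]), tu$mos)
})

test_that("index-space extremes map to the extreme ratings", {
  # plant two synthetic towns at the opposite corners of indicator space:
  # all-hazard/no-capacity and the mirror image
  area <- generate_county(synth_config(seed = 21, n_towns = 40,
                                       city_fraction = 0))
  u <- area$units
  bad <- u$scale == "block_group" & u$parent_id == "T001"
  good <- u$scale == "block_group" & u$parent_id == "T040"
  for (col in c("pop_density", "traffic_density", "pollution_density",
                "education_hs_pct", "poverty_pct",
                "linguistic_isolation_pct", "minority_pct")) {
    u[[col]][bad] <- max(u[[col]], na.rm = TRUE) * 2
    u[[col]][good] <- 0
  }
  u$median_income[bad] <- 0
  u$median_income[good] <- max(u$median_income, na.rm = TRUE) * 2
  area$units <- u
  area <- compute_indices(area)
  tu <- top_units(area)
  expect_equal(tu$rating[tu$unit_id == "T001"], "5,1")
  expect_equal(tu$rating[tu$unit_id == "T040"], "1,5")
})
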