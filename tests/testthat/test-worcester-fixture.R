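fx <- load_worcester_fixture()

test_that("the fixture reconciles with the published county frame", {
  expect_equal(nrow(fx$table), 64)
  expect_equal(length(unique(fx$table$stratum)), 18)
  # county-wide block-group census
  expect_equal(sum(fx$table$n_block_groups), 595)
  expect_equal(min(fx$table$min_bg_pop), 104)
  expect_equal(max(fx$table$max_bg_pop), 4332)
  # the five city sub-strata carry the city's expected births
  city <- fx$table[fx$table$scale == "city_subdivision", ]
  expect_equal(nrow(city), 5)
  expect_equal(sum(city$mos), 10385)
  # printed stratum MOS totals average to the published mean target
  smos <- fx$table$stratum_mos[!is.na(fx$table$stratum_mos)]
  expect_equal(length(smos), 18)
  expect_equal(round(mean(smos)), 2113)
  # every town sits in exactly one stratum
  expect_false(anyDuplicated(fx$table$unit_id) > 0)
})

test_that("fixture extremes carry the full rating spectrum", {
  pet <- fx$table[fx$table$name == "Petersham", ]
  expect_equal(pet$h_class, 1)
  expect_equal(pet$a_class, 5)
  web <- fx$table[fx$table$name == "Webster", ]
  expect_equal(web$h_class, 5)
  expect_equal(web$a_class, 1)
})

test_that("natural-breaks classification puts the minimum H_s town in class 1", {
  towns <- fx$table[fx$table$scale == "town", ]
  breaks <- jenks_breaks(towns$h_s, 5)
  cls <- classify_values(towns$h_s, breaks)
  expect_equal(cls[which.min(towns$h_s)], 1L)
  expect_equal(towns$name[which.min(towns$h_s)], "Petersham")
  expect_equal(sort(unique(cls)), 1:5)
})

test_that("the published partition passes every sampling rule", {
  cfg <- strat_config(n_strata = 18)
  rep <- validate_partition(fx$area, fx$partition, cfg)
  expect_true(rep$overall)
  expect_true(rep$rules$coverage$pass)
  expect_true(rep$rules$no_overlap$pass)
  expect_true(rep$rules$contiguity$pass)
  expect_true(rep$rules$strata_count$pass)
  expect_true(rep$rules$mos_bounds$pass)
  expect_equal(sum(rep$mos_table$within_bounds), 18)
  # printed stratum totals also sit inside the published 1,902-2,324 range
  smos <- fx$table$stratum_mos[!is.na(fx$table$stratum_mos)]
  expect_true(all(smos >= 1902 & smos <= 2324))
})

test_that("outside the city, strata average about four and a half towns", {
  towns <- fx$table[fx$table$scale == "town", ]
  n_town_strata <- length(unique(towns$stratum))
  expect_equal(n_town_strata, 13)
  expect_equal(round(nrow(towns) / n_town_strata, 1), 4.5)
})

test_that("the solver finds a compliant 18-stratum plan on the fixture", {
  cfg <- strat_config(n_strata = 18, seed = 11)
  p <- build_strata(fx$area, cfg)
  expect_true(attr(p, "feasible"))
  expect_true(validate_partition(fx$area, p, cfg)$overall)
})
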