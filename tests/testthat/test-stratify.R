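test_that("MOS bounds use half-up integer rounding", {
  expect_equal(mos_bounds(2113, 0.10), c(lo = 1902, hi = 2324))
  expect_equal(mos_bounds(1000, 0.10), c(lo = 900, hi = 1100))
  expect_equal(mos_bounds(500, 0), c(lo = 500, hi = 500))
  expect_error(mos_bounds(1000, 1), "< 1")
})

test_that("split counts round the MOS ratio half-up with floor one", {
  expect_equal(split_count(10385, 2113), 5L) # ratio 4.91
  expect_equal(split_count(2113, 2113), 1L)
  expect_equal(split_count(5282.5, 2113), 3L) # ratio 2.5 rounds up
  expect_equal(split_count(100, 2113), 1L)
  expect_error(split_count(0, 10), "unit_mos")
})

test_that("recruitment arithmetic follows the fixed rounding sequence", {
  plan <- recruitment_plan(1000, 18, 4, 0.30)
  expect_equal(plan$per_stratum, 55)
  expect_equal(plan$per_year, 14)
  expect_equal(plan$per_year_inflated, 18)
  expect_equal(recruitment_plan(1000, 18, 4, 0)$per_year_inflated, 14)
  expect_equal(recruitment_plan(100, 100, 1, 0)$per_year_inflated, 1)
  expect_error(recruitment_plan(100, 0, 1), "n_strata")
})

test_that("a uniform 6-path splits into two equal contiguous strata", {
  area <- path_area(6)
  p <- build_strata(area, strat_config(2, seed = 3))
  expect_true(attr(p, "feasible"))
  expect_equal(sort(p$strata$mos), c(300, 300))
  expect_equal(sort(p$strata$n_units), c(3, 3))
  # oracle: among all contiguous 2-partitions, only the 3+3 split balances MOS
  cfg <- strat_config(2)
  parts <- enum_connected_partitions(igraph_adj_list(area), 2)
  feas <- Filter(function(bl) blocks_feasible(area, bl, cfg), parts)
  expect_equal(length(feas), 1)
  expect_equal(sort(lengths(feas[[1]])), c(3, 3))
})

test_that("a single unit forms its own trivially compliant stratum", {
  units <- toy_units(1)
  area <- study_area(units, NULL)
  p <- build_strata(area, strat_config(1, seed = 1))
  expect_true(attr(p, "feasible"))
  expect_true(validate_partition(area, p)$overall)
})

test_that("solver preconditions are enforced", {
  area <- path_area(4)
  expect_error(build_strata(area, strat_config(5, seed = 1)), "exceeds")
  # disconnected graph
  units <- toy_units(4)
  edges <- data.frame(from = c("u1", "u3"), to = c("u2", "u4"))
  disc <- study_area(units, edges)
  expect_error(build_strata(disc, strat_config(2, seed = 1)), "disconnected")
  # oversized unit must be pre-split
  big <- path_area(4, mos = c(1000, 100, 100, 100))
  expect_error(build_strata(big, strat_config(3, seed = 1)), "pre-split")
})

test_that("solver matches the exhaustive optimum on small graphs", {
  cases <- list(
    list(area = path_area(8, mos = c(90, 110, 100, 95, 105, 100, 98, 102),
                          h = c(1, 1.5, 2, 5, 5.5, 8, 8.2, 8.4),
                          a = c(9, 8.5, 8, 5, 4.5, 2, 1.8, 1.6)),
         k = 2),
    list(area = grid_area(3, 3,
                          mos = c(100, 120, 95, 105, 100, 98, 110, 90, 102),
                          h = c(1, 1, 2, 4, 5, 5, 8, 9, 9),
                          a = c(9, 9, 8, 5, 5, 4, 2, 1, 1)),
         k = 3),
    list(area = path_area(12, mos = rep(100, 12),
                          h = c(rep(1, 4), rep(5, 4), rep(9, 4)),
                          a = c(rep(9, 4), rep(5, 4), rep(1, 4))),
         k = 3)
  )
  for (cs in cases) {
    cfg <- strat_config(cs$k, seed = 5, restarts = 8)
    p <- build_strata(cs$area, cfg)
    expect_true(attr(p, "feasible"))
    parts <- enum_connected_partitions(igraph_adj_list(cs$area), cs$k)
    feas <- Filter(function(bl) blocks_feasible(cs$area, bl, cfg), parts)
    expect_gt(length(feas), 0)
    best <- min(vapply(feas, function(bl) blocks_objective(cs$area, bl, cfg),
                       numeric(1)))
    expect_equal(attr(p, "objective"), best, tolerance = 1e-8)
  }
})

test_that("solver output is reproducible for a fixed seed", {
  set.seed(4)
  area <- grid_area(4, 3, mos = rep(c(90, 100, 110), 4),
                    h = runif(12, 0, 10), a = runif(12, 0, 10))
  cfg <- strat_config(3, seed = 99)
  p1 <- build_strata(area, cfg)
  p2 <- build_strata(area, cfg)
  expect_identical(p1$assignment, p2$assignment)
  expect_identical(attr(p1, "objective"), attr(p2, "objective"))
})

test_that("tightening the MOS tolerance only shrinks the feasible set", {
  area <- path_area(8, mos = c(90, 110, 100, 95, 105, 100, 98, 102))
  parts <- enum_connected_partitions(igraph_adj_list(area), 2)
  for (tols in list(c(0.02, 0.05), c(0.05, 0.10), c(0.10, 0.20))) {
    tight <- Filter(function(bl)
      blocks_feasible(area, bl, strat_config(2, mos_tolerance = tols[1])), parts)
    loose <- Filter(function(bl)
      blocks_feasible(area, bl, strat_config(2, mos_tolerance = tols[2])), parts)
    expect_lte(length(tight), length(loose))
    # every tightly-feasible partition remains feasible under the looser rule
    key <- function(bl) paste(sort(vapply(bl, function(b)
      paste(sort(b), collapse = "-"), character(1))), collapse = "|")
    expect_true(all(vapply(tight, key, character(1)) %in%
                      vapply(loose, key, character(1))))
  }
})

test_that("validation flags overlap, gaps, and broken contiguity", {
  area <- path_area(4)
  # a unit claimed by two strata
  dup <- data.frame(unit_id = c("u1", "u1", "u2", "u3", "u4"),
                    stratum_id = c("A", "B", "A", "B", "B"))
  rep <- validate_partition(area, dup, strat_config(2))
  expect_false(rep$rules$no_overlap$pass)
  expect_false(rep$overall)
  # an unassigned unit
  gap <- data.frame(unit_id = c("u1", "u2"), stratum_id = c("A", "A"))
  expect_false(validate_partition(area, gap, strat_config(1))$rules$coverage$pass)
  # two non-adjacent units in one stratum
  split <- c(u1 = "A", u2 = "B", u3 = "B", u4 = "A")
  expect_false(validate_partition(area, split,
                                  strat_config(2))$rules$contiguity$pass)
  # unknown unit is a reference error, not a rule failure
  expect_error(validate_partition(area, c(zz = "A"), strat_config(1)),
               "unknown unit")
})

test_that("homogeneity report uses population SDs and variance shares", {
  area <- path_area(4, h = c(1, 3, 6, 8), a = c(2, 2, 7, 7))
  p <- new_partition(c(u1 = "A", u2 = "A", u3 = "B", u4 = "B"), area)
  rep <- homogeneity_report(area, p)
  expect_equal(rep$mean_h_s, c(2, 7))
  expect_equal(rep$sd_h_s, c(1, 1)) # population convention, divisor n
  expect_equal(rep$sd_a_s, c(0, 0))
  expect_equal(attr(rep, "between_share_a"), 1)
  expect_gt(attr(rep, "between_share_h"), 0.8)

  # single-member strata have SD exactly 0
  p1 <- new_partition(setNames(LETTERS[1:4], paste0("u", 1:4)), area)
  expect_equal(homogeneity_report(area, p1)$sd_h_s, rep(0, 4))

  # identical strata explain no variance
  flat <- path_area(4, h = rep(5, 4), a = rep(5, 4))
  rep0 <- homogeneity_report(flat, p)
  expect_equal(attr(rep0, "between_share"), 0)
})

test_that("optimized strata beat size-matched random contiguous strata", {
  syn <- compute_indices(generate_county(
    synth_config(seed = 23, n_towns = 48, city_fraction = 0)))
  cfg <- strat_config(8, seed = 23)
  p <- build_strata(syn, cfg)
  expect_true(attr(p, "feasible"))
  opt_share <- attr(homogeneity_report(syn, p), "between_share")
  sizes <- as.integer(table(p$assignment$stratum_id))
  shares <- vapply(1:5, function(s) {
    rnd <- random_contiguous_partition(syn, sizes, seed = s)
    attr(homogeneity_report(syn, rnd), "between_share")
  }, numeric(1))
  expect_gt(opt_share, mean(shares))
})
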