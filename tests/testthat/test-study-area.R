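test_that("unit tables round-trip through CSV with schema mapping", {
  df <- data.frame(
    unit_id = c("a", "b", "c"), name = c("A", "B", "C"), scale = "town",
    population = c(100, 200, 300), mos = c(5, 10, 15)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  units <- read_unit_table(path)
  expect_equal(nrow(units), 3)
  expect_equal(units$unit_id, df$unit_id)
  expect_equal(units$mos, df$mos)

  # schema maps non-standard column names
  df2 <- df
  names(df2)[names(df2) == "unit_id"] <- "GEOID"
  write.csv(df2, path, row.names = FALSE)
  units2 <- read_unit_table(path, schema = c(unit_id = "GEOID"))
  expect_equal(units2$unit_id, df$unit_id)
  expect_error(read_unit_table(path), "missing required column 'unit_id'")
})

test_that("unit table validation names the offending row and column", {
  df <- data.frame(unit_id = c("a", "b"), scale = "town",
                   population = c(10, 20), mos = c(4, -1))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(read_unit_table(path), "negative mos.*'b'")
  df$mos <- c(4, 4)
  df$population[1] <- -5
  write.csv(df, path, row.names = FALSE)
  expect_error(read_unit_table(path), "negative population.*'a'")
})

test_that("edge lists become symmetric simple graphs", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("from,to", "A,B", "B,C"), path)
  g <- read_adjacency(path)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)

  writeLines(c("from,to", "A,B", "B,A", "A,B"), path)
  g2 <- read_adjacency(path)
  expect_equal(igraph::ecount(g2), 1)

  writeLines(c("from,to", "A,A"), path)
  expect_error(read_adjacency(path), "self-loop")
  writeLines(c("from,to", "A,Z"), path)
  expect_error(read_adjacency(path, unit_ids = c("A", "B")), "unknown unit")
})

test_that("rook adjacency links squares sharing an edge, not a corner", {
  # 2x2 grid of unit squares: 4 rook edges, no diagonals
  polys <- list(
    p11 = square_poly(0, 0), p12 = square_poly(1, 0),
    p21 = square_poly(0, 1), p22 = square_poly(1, 1)
  )
  g <- derive_adjacency_from_polygons(polys)
  expect_equal(igraph::ecount(g), 4)
  expect_false(igraph::are_adjacent(g, "p11", "p22"))
  # queen adds the two diagonal point-contacts
  gq <- derive_adjacency_from_polygons(polys, contiguity = "queen")
  expect_equal(igraph::ecount(gq), 6)
  expect_true(igraph::are_adjacent(gq, "p11", "p22"))

  # disjoint squares share nothing
  g0 <- derive_adjacency_from_polygons(
    list(a = square_poly(0, 0), b = square_poly(5, 5))
  )
  expect_equal(igraph::ecount(g0), 0)

  # 3x3 grid: 12 interior shared edges
  polys9 <- list()
  for (r in 0:2) for (c in 0:2) {
    polys9[[sprintf("s%d%d", r, c)]] <- square_poly(c, r)
  }
  g9 <- derive_adjacency_from_polygons(polys9)
  expect_equal(igraph::ecount(g9), 12)

  expect_error(
    derive_adjacency_from_polygons(list(bad = matrix(1, 2, 2))),
    "invalid geometry for unit 'bad'"
  )
})

test_that("GeoJSON polygons feed the contiguity derivation", {
  ring <- function(x, y) {
    m <- rbind(square_poly(x, y), square_poly(x, y)[1, ])
    lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
  }
  gj <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature", properties = list(unit_id = "a"),
           geometry = list(type = "Polygon", coordinates = list(ring(0, 0)))),
      list(type = "Feature", properties = list(unit_id = "b"),
           geometry = list(type = "Polygon", coordinates = list(ring(1, 0))))
    )
  )
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  polys <- read_geojson_polygons(path)
  expect_named(polys, c("a", "b"))
  g <- derive_adjacency_from_polygons(polys)
  expect_true(igraph::are_adjacent(g, "a", "b"))
})

test_that("study areas enforce structural invariants", {
  units <- toy_units(3)
  edges <- data.frame(from = c("u1", "u2"), to = c("u2", "u3"))
  area <- study_area(units, edges)
  expect_equal(nrow(top_units(area)), 3)

  # block-group parent must exist
  bad <- rbind(units,
               data.frame(unit_id = "bg1", scale = "block_group",
                          population = 10, mos = 1, h_s = 1, a_s = 1))
  expect_error(study_area(bad, edges), "no top-scale parent")
  bad$parent_id <- c(NA, NA, NA, "u1")
  expect_no_error(study_area(bad, edges))

  # adjacency naming an unknown unit is a reference error
  expect_error(
    study_area(units, data.frame(from = "u1", to = "zz")),
    "unknown unit"
  )
  # index values outside [0, 10] are rejected
  units$h_s <- c(3, 11, 2)
  expect_error(study_area(units, edges), "outside \\[0, 10\\]")
})

test_that("partition assignments round-trip through CSV", {
  area <- path_area(4)
  p <- new_partition(c(u1 = "S1", u2 = "S1", u3 = "S2", u4 = "S2"), area)
  path <- withr::local_tempfile(fileext = ".csv")
  write_partition(p, path)
  back <- read_partition(path)
  expect_equal(back, p$assignment)
  expect_identical(new_partition(back, area)$assignment, p$assignment)
})
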