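TOP_SCALES <- c("town", "city_subdivision")
ALL_SCALES <- c("block_group", "town", "city_subdivision")

#' Assemble a study area from a unit table and an adjacency graph
#'
#' A study area holds the full collection of spatial units at up to two
#' nested scales — block groups nested in top-scale units (towns, or
#' city subdivisions created by splitting an oversized city) — together with
#' an undirected contiguity graph over the top-scale units.
#'
#' @param units data.frame with at least `unit_id`, `scale` (one of
#'   `"block_group"`, `"town"`, `"city_subdivision"`), `population`, `mos`;
#'   optionally `name`, `parent_id`, raw indicator columns and computed
#'   columns `h_s`, `a_s`, `h_class`, `a_class`.
#' @param adjacency an igraph, a two-column edge data.frame over top-scale
#'   unit ids, or `NULL` for an edgeless graph.
#' @param name,source descriptive metadata.
#' @param allow_isolated permit top-scale units with no neighbours (default
#'   `FALSE`; single-unit areas are always allowed).
#' @return object of class `study_area` with elements `units` (data.frame),
#'   `graph` (igraph over top-scale ids) and `meta`.
#' @seealso [read_unit_table()], [read_adjacency()], [top_units()]
#' @export
study_area <- function(units, adjacency = NULL, name = "study area",
                       source = NA_character_, allow_isolated = FALSE) {
  units <- validate_units(units)
  top_ids <- units$unit_id[units$scale %in% TOP_SCALES]
  if (length(top_ids) == 0L) abort("study area has no top-scale units")

  if (is.null(adjacency)) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(top_ids), name = top_ids)
  } else if (igraph::is_igraph(adjacency)) {
    g <- igraph::as_undirected(adjacency, mode = "collapse")
  } else {
    g <- graph_from_edges(as.data.frame(adjacency), top_ids)
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)

  missing <- setdiff(top_ids, igraph::V(g)$name)
  if (length(missing) > 0L) {
    g <- igraph::add_vertices(g, length(missing), name = missing)
    if (!allow_isolated && length(top_ids) > 1L) {
      abort("top-scale unit(s) missing from adjacency: %s",
            paste(head(missing, 5L), collapse = ", "))
    }
  }
  unknown <- setdiff(igraph::V(g)$name, top_ids)
  if (length(unknown) > 0L) {
    abort("adjacency references unknown unit(s): %s",
          paste(head(unknown, 5L), collapse = ", "))
  }
  if (!allow_isolated && length(top_ids) > 1L &&
      any(igraph::degree(g) == 0)) {
    iso <- igraph::V(g)$name[igraph::degree(g) == 0]
    abort("isolated top-scale unit(s): %s (set allow_isolated = TRUE to keep)",
          paste(head(iso, 5L), collapse = ", "))
  }

  structure(
    list(units = units, graph = g,
         meta = list(name = name, source = source)),
    class = "study_area"
  )
}

validate_units <- function(units) {
  if (!is.data.frame(units)) abort("units must be a data.frame")
  need <- c("unit_id", "scale", "population", "mos")
  miss <- setdiff(need, names(units))
  if (length(miss) > 0L) {
    abort("unit table lacks required column(s): %s", paste(miss, collapse = ", "))
  }
  units$unit_id <- as.character(units$unit_id)
  if (anyDuplicated(units$unit_id)) {
    abort("duplicate unit_id: %s",
          units$unit_id[anyDuplicated(units$unit_id)])
  }
  if (!all(units$scale %in% ALL_SCALES)) {
    abort("scale must be one of %s", paste(ALL_SCALES, collapse = ", "))
  }
  if (!"name" %in% names(units)) units$name <- units$unit_id
  if (!"parent_id" %in% names(units)) units$parent_id <- NA_character_
  units$parent_id <- as.character(units$parent_id)

  for (col in c("population", "mos")) {
    v <- units[[col]]
    if (!is.numeric(v)) abort("column '%s' must be numeric", col)
    bad <- which(!is.na(v) & v < 0)
    if (length(bad) > 0L) {
      abort("negative %s for unit '%s'", col, units$unit_id[bad[1L]])
    }
  }
  for (col in c("h_s", "a_s")) {
    if (col %in% names(units)) {
      v <- units[[col]]
      bad <- which(!is.na(v) & (v < 0 | v > 10))
      if (length(bad) > 0L) {
        abort("%s outside [0, 10] for unit '%s'", col, units$unit_id[bad[1L]])
      }
    }
  }
  for (col in c("h_class", "a_class")) {
    if (col %in% names(units)) {
      v <- units[[col]]
      bad <- which(!is.na(v) & !v %in% 1:5)
      if (length(bad) > 0L) {
        abort("%s outside 1..5 for unit '%s'", col, units$unit_id[bad[1L]])
      }
    }
  }
  bg <- units[units$scale == "block_group", , drop = FALSE]
  if (nrow(bg) > 0L) {
    parents <- units$unit_id[units$scale %in% TOP_SCALES]
    bad <- which(is.na(bg$parent_id) | !bg$parent_id %in% parents)
    if (length(bad) > 0L) {
      abort("block-group '%s' has no top-scale parent in the study area",
            bg$unit_id[bad[1L]])
    }
  }
  units
}

graph_from_edges <- function(edges, ids) {
  if (ncol(edges) < 2L) abort("adjacency edge list needs two columns")
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  if (any(a == b)) {
    abort("self-loop adjacency for unit '%s'", a[which(a == b)[1L]])
  }
  unknown <- setdiff(c(a, b), ids)
  if (length(unknown) > 0L) {
    abort("adjacency references unknown unit(s): %s",
          paste(head(unknown, 5L), collapse = ", "))
  }
  igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
}

#' @export
print.study_area <- function(x, ...) {
  nt <- sum(x$units$scale %in% TOP_SCALES)
  nb <- sum(x$units$scale == "block_group")
  cat(sprintf("study_area '%s': %d top-scale units, %d block-groups, %d adjacency edges\n",
              x$meta$name, nt, nb, igraph::ecount(x$graph)))
  cat(sprintf("  total MOS (top scale): %s\n",
              format(round(sum(top_units(x)$mos), 1), big.mark = ",")))
  invisible(x)
}

#' Top-scale units of a study area
#'
#' @param area a `study_area`.
#' @return data.frame of units at the town / city-subdivision scale, ordered
#'   as in the unit table.
#' @export
top_units <- function(area) {
  stopifnot(inherits(area, "study_area"))
  area$units[area$units$scale %in% TOP_SCALES, , drop = FALSE]
}

#' Block-group units of a study area
#'
#' @param area a `study_area`.
#' @return data.frame of block-group-scale units (possibly empty).
#' @export
block_group_units <- function(area) {
  stopifnot(inherits(area, "study_area"))
  area$units[area$units$scale == "block_group", , drop = FALSE]
}

#' Contiguity graph of a study area
#'
#' @param area a `study_area`.
#' @return the igraph over top-scale unit ids.
#' @export
area_graph <- function(area) {
  stopifnot(inherits(area, "study_area"))
  area$graph
}

#' Read a unit attribute table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row. The `schema`
#' argument maps the standard field names to the file's column names, so
#' tables exported under other conventions can be ingested without editing.
#' Any column not claimed by the schema is carried along unchanged (raw
#' indicator fields in particular).
#'
#' @param path CSV file.
#' @param schema named character vector, standard name -> file column, for any
#'   of `unit_id`, `name`, `scale`, `parent_id`, `population`, `mos`. Omitted
#'   entries default to the standard name itself.
#' @return data.frame of units, validated as for [study_area()].
#' @export
read_unit_table <- function(path, schema = NULL) {
  if (!file.exists(path)) abort("unit table not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  std <- c(unit_id = "unit_id", name = "name", scale = "scale",
           parent_id = "parent_id", population = "population", mos = "mos")
  if (!is.null(schema)) std[names(schema)] <- schema
  for (field in names(std)) {
    col <- std[[field]]
    required <- field %in% c("unit_id", "scale", "population", "mos")
    if (!col %in% names(raw)) {
      if (required) abort("unit table is missing required column '%s'", col)
      next
    }
    if (col != field) {
      names(raw)[names(raw) == col] <- field
    }
  }
  validate_units(raw)
}

#' Read an adjacency edge list from CSV
#'
#' Two columns of unit ids per row, one undirected edge each; duplicate and
#' reversed edges collapse to a single edge. Self-loops are rejected, and any
#' edge naming a unit outside `unit_ids` (when supplied) is a reference error.
#'
#' @param path CSV file with two columns.
#' @param unit_ids optional character vector of known top-scale ids; the graph
#'   then contains exactly these vertices.
#' @return an undirected simple igraph.
#' @export
read_adjacency <- function(path, unit_ids = NULL) {
  if (!file.exists(path)) abort("adjacency file not found: %s", path)
  edges <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) abort("adjacency edge list needs two columns")
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  if (any(a == b)) abort("self-loop adjacency for unit '%s'", a[which(a == b)[1L]])
  ids <- unit_ids %||% sort(unique(c(a, b)))
  unknown <- setdiff(c(a, b), ids)
  if (length(unknown) > 0L) {
    abort("adjacency references unknown unit(s): %s",
          paste(head(unknown, 5L), collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  igraph::simplify(g)
}

#' Derive rook or queen contiguity from unit polygons
#'
#' Two units are rook-contiguous iff their boundaries share a segment of
#' positive length; queen contiguity additionally links polygons that touch
#' only at a point. Rook is the default: it is the stricter, map-coherent
#' notion (a shared corner is not a shared border).
#'
#' @param polygons named list of polygons, one per unit: a two-column
#'   coordinate matrix (a single ring, closed or open), or a list of such
#'   rings for multi-part units.
#' @param contiguity `"rook"` (default) or `"queen"`.
#' @param tol coordinate tolerance for coincidence tests.
#' @return an undirected simple igraph over the polygon names.
#' @seealso [read_geojson_polygons()]
#' @export
derive_adjacency_from_polygons <- function(polygons,
                                           contiguity = c("rook", "queen"),
                                           tol = 1e-9) {
  contiguity <- match.arg(contiguity)
  if (is.null(names(polygons)) || any(names(polygons) == "")) {
    abort("polygons must be a named list keyed by unit id")
  }
  rings <- lapply(names(polygons), function(id) {
    p <- polygons[[id]]
    if (is.matrix(p) || is.data.frame(p)) p <- list(as.matrix(p))
    p <- lapply(p, as.matrix)
    for (ring in p) {
      if (ncol(ring) < 2L || nrow(ring) < 3L || anyNA(ring)) {
        abort("invalid geometry for unit '%s'", id)
      }
    }
    lapply(p, close_ring)
  })
  names(rings) <- names(polygons)
  ids <- names(polygons)
  n <- length(ids)
  edges <- list()
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in (i + 1L):n) {
      if (polygons_touch(rings[[i]], rings[[j]], contiguity, tol)) {
        edges[[length(edges) + 1L]] <- c(ids[i], ids[j])
      }
    }
  }
  edf <- if (length(edges) > 0L) {
    as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0))
  }
  igraph::simplify(igraph::graph_from_data_frame(
    edf, directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  ))
}

close_ring <- function(ring) {
  first <- ring[1L, 1:2]
  last <- ring[nrow(ring), 1:2]
  if (any(first != last)) ring <- rbind(ring, ring[1L, , drop = FALSE])
  ring[, 1:2, drop = FALSE]
}

ring_segments <- function(ring) {
  n <- nrow(ring) - 1L
  cbind(ring[seq_len(n), , drop = FALSE], ring[seq_len(n) + 1L, , drop = FALSE])
}

# length of the collinear overlap of segments (a1,a2) and (b1,b2); 0 if none
segment_overlap_length <- function(a1, a2, b1, b2, tol) {
  d <- a2 - a1
  len <- sqrt(sum(d^2))
  if (len < tol) return(0)
  u <- d / len
  # both b endpoints must lie on the a line
  perp <- function(p) abs((p[1] - a1[1]) * u[2] - (p[2] - a1[2]) * u[1])
  if (perp(b1) > tol || perp(b2) > tol) return(0)
  proj <- function(p) (p[1] - a1[1]) * u[1] + (p[2] - a1[2]) * u[2]
  lo <- max(0, min(proj(b1), proj(b2)))
  hi <- min(len, max(proj(b1), proj(b2)))
  max(0, hi - lo)
}

polygons_touch <- function(rings_a, rings_b, contiguity, tol) {
  segs_a <- do.call(rbind, lapply(rings_a, ring_segments))
  segs_b <- do.call(rbind, lapply(rings_b, ring_segments))
  shared <- 0
  for (i in seq_len(nrow(segs_a))) {
    a1 <- segs_a[i, 1:2]; a2 <- segs_a[i, 3:4]
    for (j in seq_len(nrow(segs_b))) {
      shared <- shared +
        segment_overlap_length(a1, a2, segs_b[j, 1:2], segs_b[j, 3:4], tol)
      if (shared > tol) return(TRUE)
    }
  }
  if (contiguity == "queen") {
    va <- unique(do.call(rbind, rings_a))
    vb <- unique(do.call(rbind, rings_b))
    for (i in seq_len(nrow(va))) {
      if (any(abs(vb[, 1] - va[i, 1]) <= tol & abs(vb[, 2] - va[i, 2]) <= tol)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Read unit polygons from a GeoJSON file
#'
#' Supports FeatureCollections of Polygon and MultiPolygon features. The unit
#' id is taken from the feature `id`, or from the property named by
#' `id_property`. Only outer rings are used (holes do not create contiguity).
#'
#' @param path GeoJSON file.
#' @param id_property property holding the unit id (default `"unit_id"`).
#' @return named list of rings suitable for [derive_adjacency_from_polygons()].
#' @export
read_geojson_polygons <- function(path, id_property = "unit_id") {
  if (!file.exists(path)) abort("GeoJSON file not found: %s", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features %||% abort("expected a GeoJSON FeatureCollection")
  out <- list()
  for (f in feats) {
    id <- as.character(f$id %||% f$properties[[id_property]] %||%
                         abort("feature lacks an id and property '%s'", id_property))
    geom <- f$geometry
    ring_mat <- function(ring) {
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    }
    rings <- switch(
      geom$type %||% "",
      Polygon = list(ring_mat(geom$coordinates[[1]])),
      MultiPolygon = lapply(geom$coordinates, function(poly) ring_mat(poly[[1]])),
      abort("unsupported geometry type '%s' for unit '%s'", geom$type, id)
    )
    out[[id]] <- rings
  }
  out
}
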