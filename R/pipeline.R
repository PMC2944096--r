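#' Compute composite H and A indices and classes for a study area
#'
#' Runs the index-construction chain over the area's raw indicator columns:
#' population-weighted aggregation of block-group values to their parent
#' top-scale units, range standardization to `[0, range_width]`, polarity
#' orientation, weighted linear combination into `h_s` and `a_s`, Jenks
#' natural-breaks classification of the top-scale values into `k` classes
#' (class 1 = very low .. class `k` = very high), and the ordered \[H,A\]
#' rating.
#'
#' Two orders of aggregation and standardization are supported.
#' `"aggregate_first"` (default) aggregates raw block-group values to
#' population-weighted town means and then standardizes across towns;
#' `"standardize_first"` standardizes across block groups, composites at the
#' block-group level, and aggregates the composite to towns. Both leave
#' block-group-level `h_s`/`a_s` on the block-group rows (always computed
#' across block groups) for homogeneity diagnostics and city splitting.
#'
#' When the indicator set excludes the minority-share indicator (see
#' [default_indicators()]) but a `minority_pct` column exists, an
#' environmental-justice flag `ej_flag` is added instead: `TRUE` for units in
#' the top minority class combined with very low adaptive capacity
#' (`a_class <= 2`).
#'
#' @param area a `study_area` whose units carry the raw indicator columns
#'   (on block-group rows when present, else on top-scale rows).
#' @param indicators indicator specs, as from [default_indicators()].
#' @param range_width standardization scale width (default 10).
#' @param k number of classes (default 5).
#' @param order `"aggregate_first"` or `"standardize_first"`.
#' @return the area with `h_s`, `a_s`, `h_class`, `a_class` (and `rating`
#'   label) filled on top-scale units, `h_s`/`a_s` on block-group units, and
#'   the class cut points stored as attributes `h_breaks` / `a_breaks`.
#' @export
compute_indices <- function(area, indicators = default_indicators(),
                            range_width = 10, k = 5,
                            order = c("aggregate_first", "standardize_first")) {
  stopifnot(inherits(area, "study_area"))
  order <- match.arg(order)
  check_indicator_specs(indicators)
  units <- area$units
  is_top <- units$scale %in% TOP_SCALES
  is_bg <- units$scale == "block_group"
  have_bg <- any(is_bg)
  source_rows <- if (have_bg) is_bg else is_top

  miss <- setdiff(indicators$name, names(units))
  if (length(miss) > 0L) {
    abort("unit table lacks indicator column(s): %s", paste(miss, collapse = ", "))
  }
  for (col in indicators$name) {
    if (anyNA(units[[col]][source_rows])) {
      bad <- units$unit_id[source_rows & is.na(units[[col]])][1L]
      abort("missing value for indicator '%s' at unit '%s'", col, bad)
    }
  }

  top_ids <- units$unit_id[is_top]
  # population-weighted aggregation of a block-group column to the top scale;
  # a top unit without children keeps its own value
  aggregate_col <- function(col) {
    vapply(top_ids, function(id) {
      ch <- which(is_bg & units$parent_id == id)
      if (length(ch) > 0L) {
        population_weighted_mean(units[[col]][ch], units$population[ch])
      } else {
        v <- units[[col]][units$unit_id == id]
        if (is.na(v)) abort("unit '%s' has no children and no value for '%s'", id, col)
        v
      }
    }, numeric(1))
  }

  oriented <- function(raw_mat, specs) {
    out <- raw_mat
    for (j in seq_len(nrow(specs))) {
      out[, j] <- orient_indicator(
        standardize(raw_mat[, j], range_width = range_width),
        specs$polarity[j], range_width = range_width
      )
    }
    out
  }

  index_values <- function(specs) {
    # block-group composite (when block groups exist): standardized across bgs
    bg_comp <- NULL
    if (have_bg) {
      raw_bg <- as.matrix(units[is_bg, specs$name, drop = FALSE])
      bg_comp <- composite_index(oriented(raw_bg, specs), specs$weight)
    }
    top_comp <- if (order == "aggregate_first" || !have_bg) {
      raw_top <- vapply(specs$name, aggregate_col, numeric(length(top_ids)))
      raw_top <- matrix(raw_top, nrow = length(top_ids),
                        dimnames = list(top_ids, specs$name))
      composite_index(oriented(raw_top, specs), specs$weight)
    } else {
      vapply(top_ids, function(id) {
        ch <- which(units$parent_id[is_bg] == id)
        population_weighted_mean(bg_comp[ch], units$population[is_bg][ch])
      }, numeric(1))
    }
    list(top = top_comp, bg = bg_comp)
  }

  h_specs <- indicators[indicators$index == "H", , drop = FALSE]
  a_specs <- indicators[indicators$index == "A", , drop = FALSE]
  if (nrow(h_specs) == 0L || nrow(a_specs) == 0L) {
    abort("indicator set must cover both the H and the A index")
  }
  hv <- index_values(h_specs)
  av <- index_values(a_specs)

  units$h_s[is_top] <- hv$top
  units$a_s[is_top] <- av$top
  if (have_bg) {
    units$h_s[is_bg] <- hv$bg
    units$a_s[is_bg] <- av$bg
  }

  h_breaks <- jenks_breaks(hv$top, k)
  a_breaks <- jenks_breaks(av$top, k)
  units$h_class[is_top] <- classify_values(hv$top, h_breaks)
  units$a_class[is_top] <- classify_values(av$top, a_breaks)
  units$rating <- NA_character_
  units$rating[is_top] <- vulnerability_rating(
    units$h_class[is_top], units$a_class[is_top], k = k
  )$label

  if (!"minority_pct" %in% indicators$name && "minority_pct" %in% names(units)) {
    minority_top <- aggregate_col("minority_pct")
    m_class <- classify_values(minority_top, jenks_breaks(minority_top, k))
    units$ej_flag <- NA
    units$ej_flag[is_top] <- m_class == k & units$a_class[is_top] <= 2L
  }

  area$units <- units
  attr(area, "h_breaks") <- h_breaks
  attr(area, "a_breaks") <- a_breaks
  area
}

#' Pre-split units whose MOS exceeds the stratum bound
#'
#' A top-scale unit with MOS above the upper acceptable bound (e.g. a large
#' city) cannot fit in any stratum and is divided into [split_count()] pieces
#' at the block-group scale: its block groups are ordered by their
#' block-group-level `h_s` (exploiting contiguous relative homogeneity in
#' index space) and packed greedily into groups of comparable MOS. Each piece
#' becomes a `city_subdivision` unit; the pieces are chained to each other in
#' the adjacency graph and inherit all of the city's former neighbours.
#'
#' @param area a `study_area` with indices computed (block-group `h_s`
#'   required for any unit that needs splitting).
#' @param n_strata the planned number of strata (sets the mean MOS target).
#' @param mos_tolerance MOS tolerance (default 0.10).
#' @return the area with each oversized unit replaced by its subdivisions.
#' @export
split_oversized_units <- function(area, n_strata, mos_tolerance = 0.10) {
  stopifnot(inherits(area, "study_area"))
  tu <- top_units(area)
  mean_target <- sum(tu$mos) / n_strata
  b <- mos_bounds(mean_target, mos_tolerance)
  oversized <- tu$unit_id[tu$mos > b[["hi"]]]
  for (id in oversized) {
    unit <- area$units[area$units$unit_id == id, ]
    kk <- max(2L, split_count(unit$mos, mean_target))
    ch <- which(area$units$scale == "block_group" & area$units$parent_id == id)
    if (length(ch) < kk) {
      abort("unit '%s' (MOS %s) needs %d-way splitting but has %d block groups",
            id, round(unit$mos), kk, length(ch))
    }
    bg <- area$units[ch, ]
    if (is.null(bg$h_s) || anyNA(bg$h_s) || is.null(bg$a_s) || anyNA(bg$a_s)) {
      abort("block-group h_s required to split unit '%s'; run compute_indices first", id)
    }
    ord <- order(bg$h_s, bg$unit_id)
    bg <- bg[ord, ]
    # greedy fill: walk block groups in index order, closing a piece when its
    # MOS is nearest the piece target; the last piece takes the remainder
    pack <- function(kk, target) {
      piece <- integer(nrow(bg))
      p <- 1L
      acc <- 0
      for (i in seq_len(nrow(bg))) {
        piece[i] <- p
        acc <- acc + bg$mos[i]
        remaining <- nrow(bg) - i
        if (p < kk &&
            (acc >= target - (if (i < nrow(bg)) bg$mos[i + 1L] / 2 else 0) ||
             remaining == (kk - p))) {
          p <- p + 1L
          acc <- 0
        }
      }
      piece
    }
    # prefer a piece count whose equal shares sit inside the MOS bounds, so
    # each piece can stand as a stratum on its own (the split-ratio count when
    # it qualifies). If no count yields standalone-viable pieces — the shares
    # straddle a bound, or block-group discreteness overflows it — cut full
    # pieces just under the upper bound plus one remainder piece that merges
    # with neighbouring units during stratification.
    k_min <- max(2L, as.integer(ceiling(unit$mos / b[["hi"]])))
    k_max <- as.integer(floor(unit$mos / max(1, b[["lo"]])))
    piece <- NULL
    if (k_max >= k_min) {
      for (k_try in seq(k_min, k_max)[order(abs(seq(k_min, k_max) - kk))]) {
        p_try <- pack(k_try, unit$mos / k_try)
        sums <- rowsum(bg$mos, p_try)
        if (max(sums) <= b[["hi"]] && min(sums) >= b[["lo"]]) {
          piece <- p_try
          kk <- k_try
          break
        }
      }
    }
    if (is.null(piece)) {
      full <- b[["hi"]] * 0.98
      repeat {
        kk <- max(2L, as.integer(ceiling(unit$mos / full)))
        piece <- pack(kk, full)
        if (max(rowsum(bg$mos, piece)) <= b[["hi"]] || full < b[["hi"]] * 0.8) break
        full <- full * 0.97
      }
    }
    sub_ids <- sprintf("%s_S%d", id, seq_len(kk))
    subs <- do.call(rbind, lapply(seq_len(kk), function(j) {
      m <- piece == j
      data.frame(
        unit_id = sub_ids[j],
        name = sprintf("%s subdivision %d", unit$name, j),
        scale = "city_subdivision",
        parent_id = NA_character_,
        population = sum(bg$population[m]),
        mos = sum(bg$mos[m]),
        stringsAsFactors = FALSE
      )
    }))
    for (col in setdiff(names(area$units), names(subs))) subs[[col]] <- NA
    subs$h_s <- vapply(seq_len(kk), function(j) {
      m <- piece == j
      population_weighted_mean(bg$h_s[m], bg$population[m])
    }, numeric(1))
    subs$a_s <- vapply(seq_len(kk), function(j) {
      m <- piece == j
      population_weighted_mean(bg$a_s[m], bg$population[m])
    }, numeric(1))
    if (!is.null(attr(area, "h_breaks"))) {
      subs$h_class <- classify_values(subs$h_s, attr(area, "h_breaks"))
      subs$a_class <- classify_values(subs$a_s, attr(area, "a_breaks"))
    }
    # reparent block groups, replace the unit row, rewire the graph
    area$units$parent_id[ch] <- sub_ids[piece[match(seq_along(ch), ord)]]
    area$units <- rbind(area$units[area$units$unit_id != id, ], subs)
    g <- area$graph
    nbrs <- igraph::V(g)$name[igraph::neighbors(g, id)]
    g <- igraph::delete_vertices(g, id)
    g <- igraph::add_vertices(g, kk, name = sub_ids)
    new_edges <- c(rbind(sub_ids[-kk], sub_ids[-1L]))
    for (nb in nbrs) new_edges <- c(new_edges, c(rbind(sub_ids, rep(nb, kk))))
    area$graph <- igraph::simplify(g + igraph::edges(new_edges))
  }
  area
}

#' Run the full stratification pipeline
#'
#' Executes the six-step flow end to end: ingest the unit table and
#' adjacency, standardize/orient the raw indicators and aggregate them to the
#' top scale, form the composite H and A indices, classify and rate,
#' pre-split oversized units, build contiguous size-balanced strata, validate
#' them against the sampling rules, and emit reports. Any stage failure is
#' re-raised with the stage name; no partial outputs are written.
#'
#' @param units a `study_area`, or the path to a unit-table CSV.
#' @param adjacency adjacency for a CSV ingest: an edge-list CSV path, an
#'   igraph, or an edge data.frame. Ignored when `units` is a `study_area`
#'   that already has a graph.
#' @param config a [strat_config()].
#' @param indicators indicator specs (default [default_indicators()]); set to
#'   `NULL` to skip index computation when `h_s`/`a_s` are already present.
#' @param k classification scale (default 5).
#' @param order standardization/aggregation order, see [compute_indices()].
#' @param partition validate-only mode: check this partition instead of
#'   building one.
#' @param out_dir if non-`NULL`, write `units.csv` and `adjacency.csv` (the
#'   final post-split area, re-ingestible by [read_unit_table()] /
#'   [read_adjacency()]), `partition.csv`, `compliance.json`,
#'   `homogeneity.csv` and `manifest.json` there (created if needed).
#' @return list with `area` (indices and ratings filled, oversized units
#'   split), `partition`, `report` (a `compliance_report`), `homogeneity`,
#'   and `manifest`.
#' @export
run_pipeline <- function(units, adjacency = NULL, config,
                         indicators = default_indicators(), k = 5,
                         order = "aggregate_first", partition = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "strat_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  input_files <- character(0)

  area <- stage("ingest", {
    if (inherits(units, "study_area")) {
      units
    } else {
      input_files <- c(input_files, units)
      utab <- read_unit_table(units)
      g <- if (is.character(adjacency)) {
        input_files <- c(input_files, adjacency)
        read_adjacency(adjacency,
                       unit_ids = utab$unit_id[utab$scale %in% TOP_SCALES])
      } else {
        adjacency
      }
      study_area(utab, g, name = "ingested study area", source = units)
    }
  })

  needs_indices <- is.null(top_units(area)$h_s) || anyNA(top_units(area)$h_s)
  if (!is.null(indicators) && needs_indices) {
    area <- stage("indices", {
      compute_indices(area, indicators, k = k, order = order)
    })
  }

  area <- stage("split_oversized", {
    split_oversized_units(area, config$n_strata, config$mos_tolerance)
  })

  part <- stage("stratify", {
    if (is.null(partition)) build_strata(area, config)
    else new_partition(assignment_frame(partition), area)
  })

  report <- stage("validate", validate_partition(area, part, config))
  homog <- stage("report", homogeneity_report(area, part))

  manifest <- list(
    package_version = as.character(utils::packageVersion("vulnstrat")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    input_files = if (length(input_files) > 0L) {
      as.list(tools::md5sum(input_files))
    } else list(),
    n_top_units = nrow(top_units(area)),
    n_strata = nrow(part$strata),
    feasible = attr(part, "feasible") %||% NA,
    overall_compliance = report$overall
  )

  if (!is.null(out_dir)) {
    stage("outputs", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      # checkpoint the final (post-split) area so every artifact re-ingests
      write.csv(area$units, file.path(out_dir, "units.csv"), row.names = FALSE)
      e <- igraph::as_edgelist(area_graph(area))
      write.csv(data.frame(from = e[, 1], to = e[, 2]),
                file.path(out_dir, "adjacency.csv"), row.names = FALSE)
      write_partition(part, file.path(out_dir, "partition.csv"))
      jsonlite::write_json(
        list(rules = report$rules, overall = report$overall,
             mos_bounds = as.list(report$mos_bounds),
             mos_table = report$mos_table),
        file.path(out_dir, "compliance.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      write.csv(homog, file.path(out_dir, "homogeneity.csv"), row.names = FALSE)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }

  list(area = area, partition = part, report = report,
       homogeneity = homog, manifest = manifest)
}
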