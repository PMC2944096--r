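#' Configuration for stratum construction
#'
#' Collects the sampling-rule parameters and solver controls. The rule set:
#' strata must fully cover the study area, be contiguous, be limited to a
#' reasonably small number (preferably 12-15, never more than 20), and have
#' comparable measures of size — each stratum's MOS within `mos_tolerance`
#' (default 10%) of the mean target `sum(MOS) / n_strata`.
#'
#' @param n_strata number of strata (1-20).
#' @param mos_tolerance allowed relative deviation of a stratum's MOS from the
#'   mean target (default 0.10).
#' @param homogeneity_weight,mos_penalty_weight weights of the two objective
#'   terms: the sum over strata of within-stratum variances of `h_s` and
#'   `a_s`, and the squared excess relative MOS deviation beyond the
#'   tolerance.
#' @param max_iterations annealing proposals per restart.
#' @param restarts independent solver restarts; the best feasible solution
#'   across restarts is returned.
#' @param seed integer seed fixing all solver randomness.
#' @return a list of class `strat_config`.
#' @export
strat_config <- function(n_strata, mos_tolerance = 0.10,
                         homogeneity_weight = 1, mos_penalty_weight = 100,
                         max_iterations = 4000, restarts = 5, seed = 1) {
  check_number(n_strata, "n_strata", lower = 1, upper = 20)
  check_number(mos_tolerance, "mos_tolerance", lower = 0)
  if (mos_tolerance >= 1) abort("mos_tolerance must be < 1")
  check_number(homogeneity_weight, "homogeneity_weight", lower = 0)
  check_number(mos_penalty_weight, "mos_penalty_weight", lower = 0)
  structure(
    list(n_strata = as.integer(n_strata), mos_tolerance = mos_tolerance,
         homogeneity_weight = homogeneity_weight,
         mos_penalty_weight = mos_penalty_weight,
         max_iterations = as.integer(max_iterations),
         restarts = as.integer(restarts), seed = as.integer(seed)),
    class = "strat_config"
  )
}

#' Acceptable MOS range for a stratum
#'
#' Integer bounds `round(mean * (1 - tol))` .. `round(mean * (1 + tol))` with
#' half-up rounding, e.g. a mean target of 2,113 births/year at 10% tolerance
#' gives the range 1,902-2,324.
#'
#' @param mean_target_mos mean stratum MOS (total MOS / number of strata).
#' @param tolerance relative tolerance in `[0, 1)`.
#' @return named numeric vector `c(lo, hi)`.
#' @examples
#' mos_bounds(2113, 0.10) # 1902 2324
#' @export
mos_bounds <- function(mean_target_mos, tolerance = 0.10) {
  check_number(mean_target_mos, "mean_target_mos", lower = .Machine$double.eps)
  check_number(tolerance, "tolerance", lower = 0)
  if (tolerance >= 1) abort("tolerance must be < 1")
  c(lo = round_half_up(mean_target_mos * (1 - tolerance)),
    hi = round_half_up(mean_target_mos * (1 + tolerance)))
}

#' Number of strata an oversized unit must be split into
#'
#' A unit whose MOS exceeds the upper MOS bound cannot sit inside any single
#' stratum and must be pre-split into `round(unit_mos / mean_target_mos)`
#' pieces (half-up, floor 1): a city with MOS 10,385 against a mean target of
#' 2,113 has ratio 4.91 and is split five ways.
#'
#' @param unit_mos the unit's MOS.
#' @param mean_target_mos mean stratum MOS.
#' @return integer `k >= 1`.
#' @examples
#' split_count(10385, 2113) # 5
#' @export
split_count <- function(unit_mos, mean_target_mos) {
  check_number(unit_mos, "unit_mos", lower = .Machine$double.eps)
  check_number(mean_target_mos, "mean_target_mos", lower = .Machine$double.eps)
  max(1L, as.integer(round_half_up(unit_mos / mean_target_mos)))
}

#' Annual recruitment arithmetic per selected segment
#'
#' Fixed rounding sequence: per-stratum target is `floor(total / n_strata)`;
#' the annual target is that divided by the recruitment years, rounded half
#' up; the inflated target adds the loss/dropout allowance and rounds half up
#' again. E.g. 1,000 children across 18 strata over 4 years with a 30%
#' allowance: 1,000/18 = 55; 55/4 = 14; 14 + 30% = 18.
#'
#' @param total_sample total target sample size.
#' @param n_strata number of strata (= selected segments, one per stratum).
#' @param years recruitment years.
#' @param inflation loss/dropout allowance as a fraction (>= 0).
#' @return list with `per_stratum`, `per_year`, `per_year_inflated`.
#' @export
recruitment_plan <- function(total_sample, n_strata, years, inflation = 0.30) {
  check_number(total_sample, "total_sample", lower = 1)
  check_number(n_strata, "n_strata", lower = 1)
  check_number(years, "years", lower = 1)
  check_number(inflation, "inflation", lower = 0)
  per_stratum <- floor(total_sample / n_strata)
  per_year <- round_half_up(per_stratum / years)
  list(
    per_stratum = per_stratum,
    per_year = per_year,
    per_year_inflated = round_half_up(per_year * (1 + inflation))
  )
}

# ---- partition object ------------------------------------------------------

#' Create a partition of a study area's top-scale units into strata
#'
#' @param assignment named character vector (`unit_id -> stratum_id`) or a
#'   data.frame with columns `unit_id`, `stratum_id`.
#' @param area the `study_area` the assignment refers to.
#' @return object of class `partition`: the assignment plus per-stratum
#'   aggregates (member count, MOS sum, mean/SD of members' `h_s` and `a_s`,
#'   modal \[H,A\] rating where classes are present).
#' @seealso [build_strata()], [validate_partition()]
#' @export
new_partition <- function(assignment, area) {
  df <- assignment_frame(assignment)
  if (anyDuplicated(df$unit_id)) {
    abort("unit '%s' assigned to more than one stratum",
          df$unit_id[anyDuplicated(df$unit_id)])
  }
  tu <- top_units(area)
  unknown <- setdiff(df$unit_id, tu$unit_id)
  if (length(unknown) > 0L) {
    abort("assignment references unknown unit(s): %s",
          paste(head(unknown, 5L), collapse = ", "))
  }
  structure(
    list(assignment = df, strata = stratum_summary(df, tu)),
    class = "partition"
  )
}

assignment_frame <- function(assignment) {
  if (inherits(assignment, "partition")) return(assignment$assignment)
  if (is.data.frame(assignment)) {
    need <- c("unit_id", "stratum_id")
    if (!all(need %in% names(assignment))) {
      abort("assignment data.frame needs columns unit_id, stratum_id")
    }
    df <- assignment[, need]
  } else {
    if (is.null(names(assignment))) abort("assignment vector must be named by unit_id")
    df <- data.frame(unit_id = names(assignment),
                     stratum_id = as.character(assignment),
                     stringsAsFactors = FALSE)
  }
  df$unit_id <- as.character(df$unit_id)
  df$stratum_id <- as.character(df$stratum_id)
  df
}

pop_sd <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

stratum_summary <- function(df, tu) {
  tu <- tu[match(df$unit_id, tu$unit_id), , drop = FALSE]
  ids <- sort(unique(df$stratum_id))
  has_idx <- all(c("h_s", "a_s") %in% names(tu)) && !anyNA(tu$h_s) && !anyNA(tu$a_s)
  has_cls <- all(c("h_class", "a_class") %in% names(tu)) &&
    !anyNA(tu$h_class) && !anyNA(tu$a_class)
  rows <- lapply(ids, function(s) {
    m <- df$stratum_id == s
    out <- data.frame(
      stratum_id = s, n_units = sum(m), mos = sum(tu$mos[m]),
      members = paste(df$unit_id[m], collapse = ";"),
      stringsAsFactors = FALSE
    )
    out$mean_h_s <- if (has_idx) mean(tu$h_s[m]) else NA_real_
    out$sd_h_s <- if (has_idx) pop_sd(tu$h_s[m]) else NA_real_
    out$mean_a_s <- if (has_idx) mean(tu$a_s[m]) else NA_real_
    out$sd_a_s <- if (has_idx) pop_sd(tu$a_s[m]) else NA_real_
    out$modal_rating <- if (has_cls) {
      lab <- paste(tu$h_class[m], tu$a_class[m], sep = ",")
      names(sort(table(lab), decreasing = TRUE))[1L]
    } else NA_character_
    out
  })
  do.call(rbind, rows)
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d units in %d strata\n",
              nrow(x$assignment), nrow(x$strata)))
  if (!is.null(attr(x, "feasible"))) {
    cat(sprintf("  feasible: %s", attr(x, "feasible")))
    if (!isTRUE(attr(x, "feasible"))) {
      cat(sprintf(" (violated: %s)", paste(attr(x, "violated"), collapse = ", ")))
    }
    cat("\n")
  }
  cat(sprintf("  stratum MOS: %s - %s\n",
              format(min(x$strata$mos), big.mark = ","),
              format(max(x$strata$mos), big.mark = ",")))
  invisible(x)
}

#' Write / read a partition assignment as CSV
#'
#' The on-disk form is the two-column table `unit_id, stratum_id`.
#'
#' @param partition a `partition` (or anything [new_partition()] accepts).
#' @param path CSV file path.
#' @return `write_partition` returns `path` invisibly; `read_partition`
#'   returns the assignment data.frame (pass it with an area to
#'   [new_partition()] to restore a full object).
#' @export
write_partition <- function(partition, path) {
  df <- assignment_frame(partition)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) abort("partition file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  assignment_frame(df)
}

# ---- objective -------------------------------------------------------------

#' Stratification objective value of a partition
#'
#' The quantity [build_strata()] minimizes:
#' `homogeneity_weight * sum_s (var(h_s) + var(a_s)) +
#'  mos_penalty_weight * sum_s max(0, |MOS_s - mean| / mean - tol)^2`,
#' with population variances (divisor n) and `mean = sum(MOS) / n_strata`.
#' For any partition meeting the MOS rule the second term is zero, so the
#' objective reduces to the within-stratum heterogeneity of the two indices.
#'
#' @param area a `study_area` with `h_s`, `a_s` on its top-scale units.
#' @param partition a `partition` or assignment table covering the top scale.
#' @param config a [strat_config()].
#' @return single numeric objective value.
#' @export
partition_objective <- function(area, partition, config) {
  tu <- top_units(area)
  df <- assignment_frame(partition)
  tu <- tu[match(df$unit_id, tu$unit_id), , drop = FALSE]
  if (anyNA(tu$h_s) || anyNA(tu$a_s)) {
    abort("index values h_s/a_s must be computed for all top-scale units")
  }
  mean_target <- sum(top_units(area)$mos) / config$n_strata
  obj <- 0
  for (s in unique(df$stratum_id)) {
    m <- df$stratum_id == s
    vh <- mean((tu$h_s[m] - mean(tu$h_s[m]))^2)
    va <- mean((tu$a_s[m] - mean(tu$a_s[m]))^2)
    dev <- max(0, abs(sum(tu$mos[m]) - mean_target) / mean_target -
                 config$mos_tolerance)
    obj <- obj + config$homogeneity_weight * (vh + va) +
      config$mos_penalty_weight * dev^2
  }
  obj
}

# ---- solver ----------------------------------------------------------------

#' Build contiguous, size-balanced, homogeneous strata
#'
#' Partitions the top-scale units of a study area into `n_strata` connected
#' strata that fully cover the area, each with MOS inside the acceptable
#' range, minimizing within-stratum heterogeneity of the `(h_s, a_s)` index
#' values (see [partition_objective()]). Contiguity-constrained
#' regionalization under size balance is NP-hard, so the solver is a seeded
#' heuristic: region growing from the units most dispersed in index space,
#' then boundary-unit moves under simulated annealing, an MOS repair pass,
#' and a strict-descent polish; several restarts are run and the best
#' feasible solution returned. Coverage and contiguity are never violated;
#' if no partition within the MOS bounds is found, the best attempt is
#' returned flagged infeasible with the violated rules named.
#'
#' All randomness comes from `config$seed`: the same area and config
#' reproduce the same partition.
#'
#' @param area a `study_area`; top-scale units need `mos`, `h_s`, `a_s`, and
#'   the adjacency graph must be connected. Units with MOS above the upper
#'   bound must be pre-split (see [split_count()], [split_oversized_units()]).
#' @param config a [strat_config()].
#' @return a [new_partition()] with attributes `feasible` (logical),
#'   `violated` (character), `objective`, and `mos_bounds`.
#' @export
build_strata <- function(area, config) {
  stopifnot(inherits(area, "study_area"), inherits(config, "strat_config"))
  tu <- top_units(area)
  n <- nrow(tu)
  K <- config$n_strata
  if (K > n) abort("n_strata (%d) exceeds number of units (%d)", K, n)
  g <- area_graph(area)
  if (!igraph::is_connected(g)) {
    abort("adjacency graph is disconnected; strata cannot straddle components")
  }
  # align unit order with graph vertex order
  vids <- igraph::V(g)$name
  tu <- tu[match(vids, tu$unit_id), , drop = FALSE]
  if (anyNA(tu$h_s) || anyNA(tu$a_s)) {
    abort("index values h_s/a_s must be computed before stratification")
  }
  mos <- tu$mos
  h <- tu$h_s
  a <- tu$a_s
  mean_target <- sum(mos) / K
  b <- mos_bounds(mean_target, config$mos_tolerance)
  if (any(mos > b[["hi"]])) {
    abort("unit '%s' has MOS %s above the upper bound %s; pre-split it (split_count)",
          tu$unit_id[which.max(mos)], round(max(mos)), b[["hi"]])
  }
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  edges <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(edges) <- "integer"

  hw <- config$homogeneity_weight
  mw <- config$mos_penalty_weight
  tol <- config$mos_tolerance

  st_cost <- function(cnt, sh, sh2, sa, sa2, sm) {
    if (cnt == 0L) return(0)
    vh <- sh2 / cnt - (sh / cnt)^2
    va <- sa2 / cnt - (sa / cnt)^2
    dev <- max(0, abs(sm - mean_target) / mean_target - tol)
    hw * (max(0, vh) + max(0, va)) + mw * dev^2
  }

  total_cost <- function(st) {
    sum(vapply(seq_len(K), function(k) {
      st_cost(st$cnt[k], st$sh[k], st$sh2[k], st$sa[k], st$sa2[k], st$sm[k])
    }, numeric(1)))
  }

  connected_after_removal <- function(assign, s, u) {
    members <- which(assign == s)
    members <- members[members != u]
    if (length(members) <= 1L) return(length(members) == 1L)
    inset <- logical(n)
    inset[members] <- TRUE
    seen <- logical(n)
    stack <- members[1L]
    seen[stack] <- TRUE
    found <- 1L
    while (length(stack) > 0L) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      for (w in adj[[v]]) {
        if (inset[w] && !seen[w]) {
          seen[w] <- TRUE
          found <- found + 1L
          stack <- c(stack, w)
        }
      }
    }
    found == length(members)
  }

  apply_move <- function(st, u, from, to) {
    st$cnt[from] <- st$cnt[from] - 1L; st$cnt[to] <- st$cnt[to] + 1L
    st$sh[from] <- st$sh[from] - h[u]; st$sh[to] <- st$sh[to] + h[u]
    st$sh2[from] <- st$sh2[from] - h[u]^2; st$sh2[to] <- st$sh2[to] + h[u]^2
    st$sa[from] <- st$sa[from] - a[u]; st$sa[to] <- st$sa[to] + a[u]
    st$sa2[from] <- st$sa2[from] - a[u]^2; st$sa2[to] <- st$sa2[to] + a[u]^2
    st$sm[from] <- st$sm[from] - mos[u]; st$sm[to] <- st$sm[to] + mos[u]
    st
  }

  move_delta <- function(st, u, from, to) {
    before <- st_cost(st$cnt[from], st$sh[from], st$sh2[from], st$sa[from],
                      st$sa2[from], st$sm[from]) +
      st_cost(st$cnt[to], st$sh[to], st$sh2[to], st$sa[to], st$sa2[to], st$sm[to])
    st2 <- apply_move(st, u, from, to)
    after <- st_cost(st2$cnt[from], st2$sh[from], st2$sh2[from], st2$sa[from],
                     st2$sa2[from], st2$sm[from]) +
      st_cost(st2$cnt[to], st2$sh[to], st2$sh2[to], st2$sa[to], st2$sa2[to],
              st2$sm[to])
    after - before
  }

  feasible_mos <- function(st) {
    all(st$sm >= b[["lo"]] & st$sm <= b[["hi"]])
  }

  stviol <- function(sm) max(0, b[["lo"]] - sm) + max(0, sm - b[["hi"]])

  # u (in s) and v (in t) exchange strata
  apply_swap <- function(st, u, v, s, t) {
    apply_move(apply_move(st, u, s, t), v, t, s)
  }

  pair_cost <- function(st, s, t) {
    st_cost(st$cnt[s], st$sh[s], st$sh2[s], st$sa[s], st$sa2[s], st$sm[s]) +
      st_cost(st$cnt[t], st$sh[t], st$sh2[t], st$sa[t], st$sa2[t], st$sm[t])
  }

  swap_delta <- function(st, u, v, s, t) {
    st2 <- apply_swap(st, u, v, s, t)
    pair_cost(st2, s, t) - pair_cost(st, s, t)
  }

  connected_set <- function(members) {
    if (length(members) <= 1L) return(length(members) == 1L)
    inset <- logical(n)
    inset[members] <- TRUE
    seen <- logical(n)
    stack <- members[1L]
    seen[stack] <- TRUE
    found <- 1L
    while (length(stack) > 0L) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      for (w in adj[[v]]) {
        if (inset[w] && !seen[w]) {
          seen[w] <- TRUE
          found <- found + 1L
          stack <- c(stack, w)
        }
      }
    }
    found == length(members)
  }

  swap_ok <- function(assign, u, v) {
    s <- assign[u]; t <- assign[v]
    ms <- which(assign == s)
    mt <- which(assign == t)
    connected_set(c(ms[ms != u], v)) && connected_set(c(mt[mt != v], u))
  }

  # candidate boundary moves (u, from, to), one row per directed boundary edge
  boundary_moves <- function(assign) {
    e1 <- edges[, 1L]; e2 <- edges[, 2L]
    cross <- assign[e1] != assign[e2]
    rbind(
      cbind(u = e1[cross], from = assign[e1[cross]], to = assign[e2[cross]]),
      cbind(u = e2[cross], from = assign[e2[cross]], to = assign[e1[cross]])
    )
  }

  cross_edges <- function(assign) {
    e1 <- edges[, 1L]; e2 <- edges[, 2L]
    cross <- assign[e1] != assign[e2]
    cbind(u = e1[cross], v = e2[cross])
  }

  # steepest descent over boundary moves and boundary swaps.
  # mode "viol": potential = total MOS-bound violation.
  # mode "obj":  potential = objective; with guard = TRUE candidates that
  #              break the MOS bounds of an affected stratum are rejected
  #              (used to polish a feasible solution without losing it).
  descend <- function(assign, st, mode, guard = FALSE, max_steps = 400L) {
    move_gain <- function(u, from, to) {
      sm_f <- st$sm[from] - mos[u]
      sm_t <- st$sm[to] + mos[u]
      if (mode == "viol") {
        (stviol(sm_f) + stviol(sm_t)) -
          (stviol(st$sm[from]) + stviol(st$sm[to]))
      } else {
        if (guard && (stviol(sm_f) > 0 || stviol(sm_t) > 0)) return(Inf)
        move_delta(st, u, from, to)
      }
    }
    swap_gain <- function(u, v, s, t) {
      sm_s <- st$sm[s] - mos[u] + mos[v]
      sm_t <- st$sm[t] - mos[v] + mos[u]
      if (mode == "viol") {
        (stviol(sm_s) + stviol(sm_t)) -
          (stviol(st$sm[s]) + stviol(st$sm[t]))
      } else {
        if (guard && (stviol(sm_s) > 0 || stviol(sm_t) > 0)) return(Inf)
        swap_delta(st, u, v, s, t)
      }
    }
    for (step in seq_len(max_steps)) {
      mv <- boundary_moves(assign)
      if (nrow(mv) == 0L) break
      best_gain <- -1e-10
      best <- NULL
      for (i in seq_len(nrow(mv))) {
        u <- mv[i, 1L]; from <- mv[i, 2L]; to <- mv[i, 3L]
        if (st$cnt[from] <= 1L) next
        gain <- move_gain(u, from, to)
        if (gain < best_gain && connected_after_removal(assign, from, u)) {
          best_gain <- gain
          best <- list(type = "move", u = u, from = from, to = to)
        }
      }
      ce <- cross_edges(assign)
      for (i in seq_len(nrow(ce))) {
        u <- ce[i, 1L]; v <- ce[i, 2L]
        s <- assign[u]; t <- assign[v]
        gain <- swap_gain(u, v, s, t)
        if (gain < best_gain && swap_ok(assign, u, v)) {
          best_gain <- gain
          best <- list(type = "swap", u = u, v = v, s = s, t = t)
        }
      }
      if (is.null(best)) break
      if (best$type == "move") {
        st <- apply_move(st, best$u, best$from, best$to)
        assign[best$u] <- best$to
      } else {
        st <- apply_swap(st, best$u, best$v, best$s, best$t)
        assign[best$u] <- best$t
        assign[best$v] <- best$s
      }
    }
    list(assign = assign, st = st)
  }

  grow_regions <- function(seeds) {
    assign <- rep(NA_integer_, n)
    assign[seeds] <- seq_len(K)
    st <- list(cnt = integer(K), sh = numeric(K), sh2 = numeric(K),
               sa = numeric(K), sa2 = numeric(K), sm = numeric(K))
    for (k in seq_len(K)) st <- apply_move_init(st, seeds[k], k)
    while (anyNA(assign)) {
      ord <- order(st$sm)
      grew <- FALSE
      for (k in ord) {
        members <- which(assign == k)
        cand <- unique(unlist(adj[members]))
        cand <- cand[is.na(assign[cand])]
        if (length(cand) == 0L) next
        mh <- st$sh[k] / st$cnt[k]
        ma <- st$sa[k] / st$cnt[k]
        cost <- (h[cand] - mh)^2 + (a[cand] - ma)^2 +
          100 * (pmax(0, st$sm[k] + mos[cand] - b[["hi"]]) / mean_target)^2
        u <- cand[which.min(cost)]
        assign[u] <- k
        st <- apply_move_init(st, u, k)
        grew <- TRUE
        break
      }
      if (!grew) {
        # safety: attach any unassigned unit touching an assigned one
        left <- which(is.na(assign))
        for (u in left) {
          nb <- adj[[u]]
          nb <- nb[!is.na(assign[nb])]
          if (length(nb) > 0L) {
            k <- assign[nb[1L]]
            assign[u] <- k
            st <- apply_move_init(st, u, k)
            grew <- TRUE
            break
          }
        }
        if (!grew) abort("region growing stalled on a connected graph (internal error)")
      }
    }
    list(assign = assign, st = st)
  }

  apply_move_init <- function(st, u, k) {
    st$cnt[k] <- st$cnt[k] + 1L
    st$sh[k] <- st$sh[k] + h[u]; st$sh2[k] <- st$sh2[k] + h[u]^2
    st$sa[k] <- st$sa[k] + a[u]; st$sa2[k] <- st$sa2[k] + a[u]^2
    st$sm[k] <- st$sm[k] + mos[u]
    st
  }

  farthest_seeds <- function() {
    sc <- cbind(h, a)
    centroid <- colMeans(sc)
    d0 <- (sc[, 1] - centroid[1])^2 + (sc[, 2] - centroid[2])^2
    seeds <- which.max(d0)
    while (length(seeds) < K) {
      dmin <- rep(Inf, n)
      for (s in seeds) {
        ds <- (sc[, 1] - sc[s, 1])^2 + (sc[, 2] - sc[s, 2])^2
        dmin <- pmin(dmin, ds)
      }
      dmin[seeds] <- -Inf
      seeds <- c(seeds, which.max(dmin))
    }
    seeds
  }

  mos_violation <- function(st) {
    sum(pmax(0, b[["lo"]] - st$sm) + pmax(0, st$sm - b[["hi"]]))
  }

  run_restart <- function(r) {
    seeds <- if (r == 1L) farthest_seeds() else sample.int(n, K)
    gr <- grow_regions(seeds)
    assign <- gr$assign
    st <- gr$st
    if (K > 1L) {
      # simulated annealing on the full objective, biased toward MOS repair;
      # the best feasible state visited is remembered
      obj <- total_cost(st)
      t0 <- max(obj * 0.1, 1e-3)
      alpha <- (1e-4 / t0)^(1 / max(1L, config$max_iterations))
      temp <- t0
      cur_obj <- obj
      snap <- NULL
      snap_obj <- Inf
      note_state <- function() {
        if (feasible_mos(st) && cur_obj < snap_obj) {
          snap <<- list(assign = assign, st = st)
          snap_obj <<- cur_obj
        }
      }
      note_state()
      for (iter in seq_len(config$max_iterations)) {
        temp <- temp * alpha
        viol <- which(st$sm < b[["lo"]] | st$sm > b[["hi"]])
        mv <- NULL
        if (length(viol) > 0L && runif(1) < 0.7) {
          s <- if (length(viol) == 1L) viol else sample(viol, 1L)
          if (st$sm[s] > b[["hi"]]) {
            # move a boundary member out of the overfull stratum
            members <- which(assign == s)
            cand <- members[vapply(members, function(u)
              any(assign[adj[[u]]] != s), logical(1))]
            if (length(cand) > 0L) {
              u <- if (length(cand) == 1L) cand else sample(cand, 1L)
              tos <- unique(assign[adj[[u]]])
              tos <- tos[tos != s]
              mv <- c(u, s, if (length(tos) == 1L) tos else sample(tos, 1L))
            }
          } else {
            # pull a neighbouring unit into the underfull stratum
            members <- which(assign == s)
            cand <- unique(unlist(adj[members]))
            cand <- cand[assign[cand] != s]
            if (length(cand) > 0L) {
              u <- if (length(cand) == 1L) cand else sample(cand, 1L)
              mv <- c(u, assign[u], s)
            }
          }
        }
        if (is.null(mv) && runif(1) < 0.3) {
          # swap proposal across a random boundary edge
          i <- sample.int(nrow(edges), 1L)
          u <- edges[i, 1L]; v <- edges[i, 2L]
          if (assign[u] == assign[v]) next
          delta <- swap_delta(st, u, v, assign[u], assign[v])
          if (delta > 0 && runif(1) >= exp(-delta / temp)) next
          if (!swap_ok(assign, u, v)) next
          s <- assign[u]; t <- assign[v]
          st <- apply_swap(st, u, v, s, t)
          assign[u] <- t
          assign[v] <- s
          cur_obj <- cur_obj + delta
          note_state()
          next
        }
        if (is.null(mv)) {
          i <- sample.int(nrow(edges), 1L)
          u <- edges[i, 1L]; v <- edges[i, 2L]
          if (assign[u] == assign[v]) next
          if (runif(1) < 0.5) mv <- c(u, assign[u], assign[v])
          else mv <- c(v, assign[v], assign[u])
        }
        u <- mv[1L]; from <- mv[2L]; to <- mv[3L]
        if (st$cnt[from] <= 1L) next
        delta <- move_delta(st, u, from, to)
        if (delta > 0 && runif(1) >= exp(-delta / temp)) next
        if (!connected_after_removal(assign, from, u)) next
        st <- apply_move(st, u, from, to)
        assign[u] <- to
        cur_obj <- cur_obj + delta
        note_state()
      }
      # repair: strict descent on total MOS violation, with random kicks
      # between rounds when the descent stalls short of feasibility
      for (round in 1:6) {
        d <- descend(assign, st, mode = "viol")
        assign <- d$assign; st <- d$st
        if (feasible_mos(st)) break
        kick_temp <- t0 * 0.05
        for (kick in 1:40) {
          i <- sample.int(nrow(edges), 1L)
          u <- edges[i, 1L]; v <- edges[i, 2L]
          if (assign[u] == assign[v]) next
          if (runif(1) < 0.5) { tmp <- u; u <- v; v <- tmp }
          from <- assign[u]; to <- assign[v]
          if (st$cnt[from] <= 1L) next
          delta <- move_delta(st, u, from, to)
          if (delta > 0 && runif(1) >= exp(-delta / kick_temp)) next
          if (!connected_after_removal(assign, from, u)) next
          st <- apply_move(st, u, from, to)
          assign[u] <- to
        }
      }
      # polish the objective without leaving feasibility (if reached)
      d <- descend(assign, st, mode = "obj", guard = feasible_mos(st))
      assign <- d$assign; st <- d$st
      # fall back to the best feasible state seen during annealing if the
      # final state is worse (or infeasible)
      if (!is.null(snap)) {
        final_obj <- total_cost(st)
        if (!feasible_mos(st) || snap_obj < final_obj) {
          d <- descend(snap$assign, snap$st, mode = "obj", guard = TRUE)
          if (total_cost(d$st) < final_obj || !feasible_mos(st)) {
            assign <- d$assign; st <- d$st
          }
        }
      }
    }
    list(assign = assign, st = st, obj = total_cost(st),
         feasible = feasible_mos(st), violation = mos_violation(st))
  }

  res <- with_seed(config$seed, {
    best_feas <- NULL
    best_any <- NULL
    for (r in seq_len(max(1L, config$restarts))) {
      cand <- run_restart(r)
      if (is.null(best_any) || cand$violation < best_any$violation ||
          (cand$violation == best_any$violation && cand$obj < best_any$obj)) {
        best_any <- cand
      }
      if (cand$feasible && (is.null(best_feas) || cand$obj < best_feas$obj)) {
        best_feas <- cand
      }
    }
    best_feas %||% best_any
  })

  labels <- sprintf("S%02d", seq_len(K))
  assignment <- setNames(labels[res$assign], vids)
  part <- new_partition(assignment, area)
  attr(part, "feasible") <- res$feasible
  attr(part, "violated") <- if (res$feasible) character(0) else "mos_bounds"
  attr(part, "objective") <- res$obj
  attr(part, "mos_bounds") <- b
  part
}

# ---- validation ------------------------------------------------------------

#' Check a partition against the probability-sampling rules
#'
#' Evaluates each rule independently: full coverage of the top-scale units,
#' no unit in more than one stratum, contiguity of every stratum under the
#' area's adjacency graph, the stratum-count bound (at most 20; equal to the
#' configured `n_strata` when a config is given), and every stratum's MOS
#' within the acceptable range derived from `sum(MOS) / n_strata` and the
#' tolerance.
#'
#' @param area a `study_area`.
#' @param partition a `partition`, a named assignment vector, or a raw
#'   `unit_id`/`stratum_id` data.frame (which may contain duplicates —
#'   caught by the no-overlap rule).
#' @param config a [strat_config()]; when `NULL`, `n_strata` is taken as the
#'   number of strata present and the tolerance defaults to 0.10.
#' @return object of class `compliance_report`: per-rule pass/fail with
#'   detail, a per-stratum MOS table, homogeneity statistics (when index
#'   values are available), and `overall` — `TRUE` iff all hard rules pass.
#' @export
validate_partition <- function(area, partition, config = NULL) {
  stopifnot(inherits(area, "study_area"))
  df <- assignment_frame(partition)
  tu <- top_units(area)
  unknown <- setdiff(df$unit_id, tu$unit_id)
  if (length(unknown) > 0L) {
    abort("partition references unknown unit(s): %s",
          paste(head(unknown, 5L), collapse = ", "))
  }
  strata_ids <- unique(df$stratum_id)
  if (is.null(config)) {
    config <- strat_config(n_strata = min(20L, length(strata_ids)))
  }

  rules <- list()
  dup <- unique(df$unit_id[duplicated(df$unit_id)])
  rules$no_overlap <- list(
    pass = length(dup) == 0L,
    detail = if (length(dup) > 0L)
      sprintf("unit(s) in more than one stratum: %s",
              paste(head(dup, 5L), collapse = ", "))
    else "each unit in exactly one stratum"
  )
  missing <- setdiff(tu$unit_id, df$unit_id)
  rules$coverage <- list(
    pass = length(missing) == 0L,
    detail = if (length(missing) > 0L)
      sprintf("unassigned unit(s): %s", paste(head(missing, 5L), collapse = ", "))
    else "all top-scale units assigned"
  )
  g <- area_graph(area)
  bad_contig <- character(0)
  for (s in strata_ids) {
    members <- unique(df$unit_id[df$stratum_id == s])
    sub <- igraph::induced_subgraph(g, members)
    if (!igraph::is_connected(sub)) bad_contig <- c(bad_contig, s)
  }
  rules$contiguity <- list(
    pass = length(bad_contig) == 0L,
    detail = if (length(bad_contig) > 0L)
      sprintf("non-contiguous strata: %s", paste(bad_contig, collapse = ", "))
    else "every stratum induces a connected subgraph"
  )
  n_found <- length(strata_ids)
  count_ok <- n_found <= 20L && n_found == config$n_strata
  rules$strata_count <- list(
    pass = count_ok,
    detail = sprintf("%d strata (configured %d, hard maximum 20)",
                     n_found, config$n_strata)
  )

  mean_target <- sum(tu$mos) / config$n_strata
  b <- mos_bounds(mean_target, config$mos_tolerance)
  mos_tab <- aggregate(
    mos ~ stratum_id,
    data = merge(df, tu[, c("unit_id", "mos")], by = "unit_id"),
    FUN = sum
  )
  mos_tab$within_bounds <- mos_tab$mos >= b[["lo"]] & mos_tab$mos <= b[["hi"]]
  rules$mos_bounds <- list(
    pass = all(mos_tab$within_bounds),
    detail = sprintf("%d/%d strata within [%d, %d]",
                     sum(mos_tab$within_bounds), nrow(mos_tab),
                     b[["lo"]], b[["hi"]])
  )

  homog <- NULL
  if (all(c("h_s", "a_s") %in% names(tu)) && !anyNA(tu$h_s) && !anyNA(tu$a_s) &&
      rules$no_overlap$pass && rules$coverage$pass) {
    homog <- homogeneity_report(area, df)
  }

  structure(
    list(rules = rules,
         overall = all(vapply(rules, `[[`, logical(1), "pass")),
         mos_table = mos_tab, mos_bounds = b, homogeneity = homog,
         config = config),
    class = "compliance_report"
  )
}

#' @export
print.compliance_report <- function(x, ...) {
  cat("compliance report\n")
  for (nm in names(x$rules)) {
    r <- x$rules[[nm]]
    cat(sprintf("  [%s] %-13s %s\n", if (r$pass) "ok" else "FAIL", nm, r$detail))
  }
  cat(sprintf("  overall: %s\n", if (x$overall) "PASS" else "FAIL"))
  invisible(x)
}

# ---- diagnostics -----------------------------------------------------------

#' Within-stratum homogeneity diagnostics
#'
#' Per-stratum mean and standard deviation of the standardized index values,
#' plus the between-strata variance share — the fraction of total variance in
#' the index values explained by the stratum grouping (0 when all strata are
#' identical, approaching 1 for perfectly homogeneous strata). SDs use the
#' population convention (divisor n), so a single-member stratum has SD 0.
#'
#' @param area a `study_area` with index values computed.
#' @param partition a `partition` or assignment table.
#' @param scale `"top"` (default) to summarize over the member units
#'   themselves, or `"block_group"` to summarize over constituent block
#'   groups (requires block-group-level `h_s`/`a_s`).
#' @return data.frame with one row per stratum (`stratum_id`, `n`, `mean_h_s`,
#'   `sd_h_s`, `mean_a_s`, `sd_a_s`) and attributes `between_share_h`,
#'   `between_share_a`, `between_share` (their mean).
#' @export
homogeneity_report <- function(area, partition, scale = c("top", "block_group")) {
  scale <- match.arg(scale)
  df <- assignment_frame(partition)
  if (scale == "top") {
    vals <- top_units(area)
  } else {
    bg <- block_group_units(area)
    if (nrow(bg) == 0L) abort("no block-group units in this study area")
    bg$stratum_id <- df$stratum_id[match(bg$parent_id, df$unit_id)]
    vals <- bg
  }
  if (scale == "top") {
    vals$stratum_id <- df$stratum_id[match(vals$unit_id, df$unit_id)]
  }
  if (anyNA(vals$stratum_id)) {
    abort("unit '%s' has no stratum assignment",
          vals$unit_id[which(is.na(vals$stratum_id))[1L]])
  }
  if (!all(c("h_s", "a_s") %in% names(vals)) || anyNA(vals$h_s) || anyNA(vals$a_s)) {
    abort("index values h_s/a_s must be computed for all units at this scale")
  }
  ids <- sort(unique(df$stratum_id))
  empty <- setdiff(ids, vals$stratum_id)
  if (length(empty) > 0L) {
    abort("stratum '%s' has no member units at the %s scale", empty[1L], scale)
  }
  out <- do.call(rbind, lapply(ids, function(s) {
    m <- vals$stratum_id == s
    data.frame(stratum_id = s, n = sum(m),
               mean_h_s = mean(vals$h_s[m]), sd_h_s = pop_sd(vals$h_s[m]),
               mean_a_s = mean(vals$a_s[m]), sd_a_s = pop_sd(vals$a_s[m]),
               stringsAsFactors = FALSE)
  }))
  share <- function(v) {
    ss_tot <- sum((v - mean(v))^2)
    if (ss_tot == 0) return(0)
    ss_within <- sum(vapply(ids, function(s) {
      sum((v[vals$stratum_id == s] - mean(v[vals$stratum_id == s]))^2)
    }, numeric(1)))
    (ss_tot - ss_within) / ss_tot
  }
  attr(out, "between_share_h") <- share(vals$h_s)
  attr(out, "between_share_a") <- share(vals$a_s)
  attr(out, "between_share") <- mean(c(share(vals$h_s), share(vals$a_s)))
  out
}

#' Random contiguous partition with prescribed stratum sizes
#'
#' Null-model generator: grows `length(sizes)` regions from random seeds,
#' respecting contiguity and the target member counts. Used to benchmark the
#' homogeneity of an optimized partition against chance.
#'
#' @param area a `study_area` with a connected adjacency graph.
#' @param sizes integer member counts, summing to the number of top-scale
#'   units.
#' @param seed integer seed.
#' @param max_tries restart attempts before giving up.
#' @return a [new_partition()].
#' @export
random_contiguous_partition <- function(area, sizes, seed = 1, max_tries = 200) {
  tu <- top_units(area)
  g <- area_graph(area)
  vids <- igraph::V(g)$name
  n <- length(vids)
  if (sum(sizes) != n) abort("sizes must sum to the number of top-scale units (%d)", n)
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  K <- length(sizes)
  connected_without <- function(assign, s, u) {
    members <- which(assign == s)
    members <- members[members != u]
    if (length(members) <= 1L) return(length(members) == 1L)
    seen <- members[1L]
    repeat {
      grow <- setdiff(intersect(unlist(adj[seen]), members), seen)
      if (length(grow) == 0L) break
      seen <- c(seen, grow)
    }
    length(seen) == length(members)
  }
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      # unconstrained random contiguous growth (always completes), then
      # rebalance member counts toward the targets by boundary moves
      assign <- rep(NA_integer_, n)
      seeds <- sample.int(n, K)
      assign[seeds] <- seq_len(K)
      while (anyNA(assign)) {
        frontier <- which(!is.na(assign))
        frontier <- frontier[vapply(frontier, function(u)
          any(is.na(assign[adj[[u]]])), logical(1))]
        u <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
        cand <- adj[[u]][is.na(assign[adj[[u]]])]
        v <- if (length(cand) == 1L) cand else sample(cand, 1L)
        assign[v] <- assign[u]
      }
      # pair region ranks with size ranks so little movement is needed
      cnt <- tabulate(assign, K)
      target <- integer(K)
      target[order(cnt)] <- sort(sizes)
      ok <- FALSE
      for (move in seq_len(20L * n)) {
        if (all(cnt == target)) { ok <- TRUE; break }
        over <- which(cnt > target)
        moved <- FALSE
        for (s in sample(over)) {
          members <- which(assign == s)
          members <- members[vapply(members, function(u)
            any(assign[adj[[u]]] != s), logical(1))]
          for (u in sample(members)) {
            tos <- unique(assign[adj[[u]]])
            tos <- tos[tos != s & cnt[tos] < target[tos]]
            if (length(tos) == 0L) next
            if (!connected_without(assign, s, u)) next
            t <- if (length(tos) == 1L) tos else sample(tos, 1L)
            assign[u] <- t
            cnt[s] <- cnt[s] - 1L
            cnt[t] <- cnt[t] + 1L
            moved <- TRUE
            break
          }
          if (moved) break
        }
        if (!moved) break
      }
      if (ok) {
        return(new_partition(
          setNames(sprintf("R%02d", assign), vids), area
        ))
      }
    }
    abort("could not realize the requested stratum sizes in %d tries", max_tries)
  })
}
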