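# independent brute-force oracles, deliberately naive

# minimum total within-class SSE over all contiguous partitions of sorted x
# into k classes, by exhaustive enumeration of break positions
brute_jenks_sse <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  sse <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(sse(xs))
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, j], n)
    tot <- 0
    for (i in seq_len(k)) {
      tot <- tot + sse(xs[(bounds[i] + 1):bounds[i + 1]])
    }
    best <- min(best, tot)
  }
  best
}

# total within-class SSE implied by a set of cut points
breaks_sse <- function(x, breaks) {
  cls <- vapply(x, function(v) 1L + sum(v > breaks), integer(1))
  sum(vapply(unique(cls), function(cl) {
    v <- x[cls == cl]
    sum((v - mean(v))^2)
  }, numeric(1)))
}

# all partitions of the vertices of an undirected graph (adjacency list of
# integer vectors) into exactly k connected blocks
enum_connected_partitions <- function(adj, k) {
  n <- length(adj)
  is_conn <- function(members) {
    if (length(members) <= 1) return(TRUE)
    seen <- members[1]
    repeat {
      grow <- setdiff(intersect(unlist(adj[seen]), members), seen)
      if (length(grow) == 0) break
      seen <- c(seen, grow)
    }
    length(seen) == length(members)
  }
  # all connected subsets of `allowed` containing its smallest element
  conn_subsets <- function(allowed) {
    v <- min(allowed)
    out <- list()
    grow <- function(S, cand) {
      out[[length(out) + 1]] <<- S
      while (length(cand) > 0) {
        u <- cand[1]
        cand <- cand[-1]
        newS <- c(S, u)
        newcand <- union(cand, setdiff(intersect(adj[[u]], allowed), newS))
        newcand <- setdiff(newcand, newS)
        grow(newS, newcand)
      }
    }
    grow(v, setdiff(intersect(adj[[v]], allowed), v))
    out
  }
  recurse <- function(allowed, k) {
    if (k == 1) {
      if (is_conn(allowed)) return(list(list(allowed)))
      return(list())
    }
    res <- list()
    for (S in conn_subsets(allowed)) {
      rest <- setdiff(allowed, S)
      if (length(rest) < k - 1) next
      for (sub in recurse(rest, k - 1)) {
        res[[length(res) + 1]] <- c(list(S), sub)
      }
    }
    res
  }
  recurse(seq_len(n), k)
}

igraph_adj_list <- function(area) {
  lapply(igraph::as_adj_list(area_graph(area)), as.integer)
}

# objective of a block list (list of integer vectors) matching
# partition_objective's definition
blocks_objective <- function(area, blocks, config) {
  tu <- top_units(area)
  vids <- igraph::V(area_graph(area))$name
  tu <- tu[match(vids, tu$unit_id), ]
  mean_target <- sum(tu$mos) / config$n_strata
  obj <- 0
  for (bl in blocks) {
    vh <- mean((tu$h_s[bl] - mean(tu$h_s[bl]))^2)
    va <- mean((tu$a_s[bl] - mean(tu$a_s[bl]))^2)
    dev <- max(0, abs(sum(tu$mos[bl]) - mean_target) / mean_target -
                 config$mos_tolerance)
    obj <- obj + config$homogeneity_weight * (vh + va) +
      config$mos_penalty_weight * dev^2
  }
  obj
}

blocks_feasible <- function(area, blocks, config) {
  tu <- top_units(area)
  vids <- igraph::V(area_graph(area))$name
  tu <- tu[match(vids, tu$unit_id), ]
  b <- mos_bounds(sum(tu$mos) / config$n_strata, config$mos_tolerance)
  all(vapply(blocks, function(bl) {
    s <- sum(tu$mos[bl])
    s >= b[["lo"]] && s <= b[["hi"]]
  }, logical(1)))
}
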