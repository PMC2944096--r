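# toy study-area builders used across tests

toy_units <- function(n, mos = rep(100, n), h = rep(5, n), a = rep(5, n),
                      prefix = "u") {
  data.frame(
    unit_id = paste0(prefix, seq_len(n)),
    scale = "town",
    population = 1000,
    mos = mos, h_s = h, a_s = a,
    stringsAsFactors = FALSE
  )
}

path_area <- function(n, mos = rep(100, n), h = rep(5, n), a = rep(5, n)) {
  units <- toy_units(n, mos, h, a)
  edges <- data.frame(from = units$unit_id[-n], to = units$unit_id[-1])
  study_area(units, edges, name = sprintf("path-%d", n))
}

grid_area <- function(nr, nc, mos = NULL, h = NULL, a = NULL) {
  n <- nr * nc
  units <- toy_units(n, mos %||% rep(100, n), h %||% rep(5, n),
                     a %||% rep(5, n))
  idx <- function(r, c) (r - 1L) * nc + c
  edges <- list()
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (c < nc) edges[[length(edges) + 1L]] <- c(idx(r, c), idx(r, c + 1L))
      if (r < nr) edges[[length(edges) + 1L]] <- c(idx(r, c), idx(r + 1L, c))
    }
  }
  e <- do.call(rbind, edges)
  study_area(units, data.frame(from = units$unit_id[e[, 1]],
                               to = units$unit_id[e[, 2]]),
             name = sprintf("grid-%dx%d", nr, nc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# unit square polygon at offset (x, y)
square_poly <- function(x, y, side = 1) {
  rbind(c(x, y), c(x + side, y), c(x + side, y + side), c(x, y + side))
}
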