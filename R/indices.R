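#' Range-standardize raw indicator values to a common scale
#'
#' Linear rescaling of raw values to `[0, range_width]`:
#' `range_width * (raw - min) / (max - min)`. The minimum and maximum are by
#' default taken over the supplied values, i.e. over the entire dataset for
#' that indicator; no external reference ranges are used. The default range
#' width of 10 puts every indicator on a 0-10 scale before combination.
#'
#' @param x numeric vector of raw values.
#' @param min_value,max_value range anchors; default the observed extremes of
#'   `x`. `max_value` must exceed `min_value`; a constant indicator is a
#'   degenerate input and raises an error rather than silently mapping to 0.
#' @param range_width width of the output scale (default 10).
#' @param clamp if `TRUE`, values outside `[min_value, max_value]` are clamped
#'   to the endpoints instead of raising an error (useful when anchors come
#'   from a different dataset).
#' @return numeric vector in `[0, range_width]`.
#' @examples
#' standardize(c(2, 4, 10)) # 0, 2.5, 10
#' @export
standardize <- function(x, min_value = min(x), max_value = max(x),
                        range_width = 10, clamp = FALSE) {
  if (!is.numeric(x) || anyNA(x)) abort("raw values must be numeric and non-missing")
  check_number(range_width, "range_width", lower = .Machine$double.eps)
  if (max_value <= min_value) {
    abort("degenerate indicator: max_value (%s) must exceed min_value (%s)",
          max_value, min_value)
  }
  if (clamp) {
    x <- pmin(pmax(x, min_value), max_value)
  } else if (any(x < min_value | x > max_value)) {
    abort("raw values outside [min_value, max_value]; set clamp = TRUE to clip")
  }
  out <- range_width * (x - min_value) / (max_value - min_value)
  # guard against floating-point spill just past the endpoints
  pmin(pmax(out, 0), range_width)
}

#' Population-weighted mean of child-unit values
#'
#' Aggregates block-group-level values to their parent unit as
#' `sum(value_i * pop_i) / sum(pop_i)`, so populous block groups dominate the
#' parent's value.
#'
#' @param values numeric vector of child values.
#' @param populations non-negative weights (person counts), same length.
#' @return single numeric value.
#' @examples
#' population_weighted_mean(c(0, 10), c(1000, 3000)) # 7.5
#' @export
population_weighted_mean <- function(values, populations) {
  if (length(values) != length(populations)) {
    abort("values (%d) and populations (%d) differ in length",
          length(values), length(populations))
  }
  if (length(values) < 1L) abort("need at least one child value")
  if (any(populations < 0)) abort("populations must be non-negative")
  tot <- sum(populations)
  if (tot <= 0) abort("population sum is zero; cannot aggregate")
  sum(values * populations) / tot
}

#' Orient a standardized indicator so larger always means more of the index
#'
#' Indicators whose raw direction opposes their index (e.g. poverty rate for
#' adaptive capacity) are reflected: `range_width - value`. Positive-polarity
#' indicators pass through unchanged. Applied after [standardize()] and before
#' [composite_index()], so every column entering the composite raises the
#' index in its named direction.
#'
#' @param x standardized values in `[0, range_width]`.
#' @param polarity `+1` (identity) or `-1` (reflect).
#' @param range_width scale width (default 10).
#' @return oriented values in `[0, range_width]`.
#' @examples
#' orient_indicator(2.5, -1) # 7.5
#' @export
orient_indicator <- function(x, polarity, range_width = 10) {
  if (!polarity %in% c(1, -1)) abort("polarity must be +1 or -1")
  if (any(x < 0 | x > range_width)) {
    abort("values outside [0, %s]; standardize before orienting", range_width)
  }
  if (polarity == 1) x else range_width - x
}

#' Weighted linear composite of oriented indicators
#'
#' Combines a units-by-indicators matrix of standardized, oriented values into
#' one composite score per unit: `sum_j w_j * SV_j` with weights normalized to
#' sum to one. Because the combination is convex, the composite stays on the
#' same `[0, range_width]` scale as its inputs.
#'
#' @param values numeric matrix (rows = units, columns = indicators); no
#'   missing cells.
#' @param weights non-negative weights, one per column; any positive rescaling
#'   of the weights yields the same composite.
#' @return numeric vector, one composite value per row.
#' @examples
#' composite_index(cbind(4, 8), c(0.25, 0.75)) # 7
#' @export
composite_index <- function(values, weights) {
  values <- as.matrix(values)
  if (ncol(values) != length(weights)) {
    abort("got %d weights for %d indicator columns", length(weights), ncol(values))
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    abort("missing indicator value at unit row %d, indicator column %d",
          bad[[1L]], bad[[2L]])
  }
  if (any(weights < 0)) abort("weights must be non-negative")
  tot <- sum(weights)
  if (tot <= 0) abort("weights must not all be zero")
  drop(values %*% (weights / tot))
}

#' Fisher-Jenks natural-breaks cut points
#'
#' Optimal univariate classification: partitions the sorted values into `k`
#' contiguous classes minimizing the total within-class sum of squared
#' deviations, by the exact O(k n^2) dynamic program. The result is
#' deterministic; ties between equal-cost partitions are broken toward the
#' earliest feasible boundary.
#'
#' @param x numeric vector; must contain at least `k` distinct values.
#' @param k number of classes (>= 1).
#' @return ascending numeric vector of `k - 1` cut points, the maximum value
#'   of each class but the last. Use with [classify_values()].
#' @examples
#' jenks_breaks(c(1, 2, 10, 11), 2) # 2: {1,2} | {10,11}
#' @export
jenks_breaks <- function(x, k) {
  if (!is.numeric(x) || anyNA(x)) abort("values must be numeric and non-missing")
  check_number(k, "k", lower = 1)
  k <- as.integer(k)
  n_distinct <- length(unique(x))
  if (n_distinct < k) {
    abort("cannot form %d classes from %d distinct values", k, n_distinct)
  }
  if (k == 1L) return(numeric(0))
  xs <- sort(x)
  n <- length(xs)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  # within-class SSE of xs[i..j]
  sse <- function(i, j) {
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  # cost[m, j]: best total SSE splitting xs[1..j] into m classes
  cost <- matrix(Inf, nrow = k, ncol = n)
  from <- matrix(NA_integer_, nrow = k, ncol = n)
  for (j in seq_len(n)) cost[1L, j] <- sse(1L, j)
  for (m in 2:k) {
    for (j in m:n) {
      best <- Inf
      arg <- NA_integer_
      for (i in m:j) {
        cand <- cost[m - 1L, i - 1L] + sse(i, j)
        if (cand < best - 1e-12) {
          best <- cand
          arg <- i
        }
      }
      cost[m, j] <- best
      from[m, j] <- arg
    }
  }
  # backtrack class boundaries (last index of each class except the final one)
  bounds <- integer(k - 1L)
  j <- n
  for (m in k:2) {
    i <- from[m, j]
    bounds[m - 1L] <- i - 1L
    j <- i - 1L
  }
  xs[bounds]
}

#' Assign values to classes given ascending cut points
#'
#' Class 1 is the lowest interval. A value exactly equal to a cut point is
#' assigned to the lower class (deterministic tie rule): value `v` falls in
#' class `1 + #(breaks < v)`.
#'
#' @param x numeric vector.
#' @param breaks ascending cut points (length `k - 1`); `numeric(0)` puts
#'   everything in class 1.
#' @return integer classes in `1..k`.
#' @examples
#' classify_values(c(1, 2, 10, 11), jenks_breaks(c(1, 2, 10, 11), 2))
#' @export
classify_values <- function(x, breaks) {
  if (is.unsorted(breaks, strictly = FALSE)) abort("breaks must be ascending")
  vapply(x, function(v) 1L + sum(v > breaks), integer(1))
}

#' Ordered [H,A] vulnerability rating
#'
#' The rating keeps the two class labels as an ordered pair rather than
#' collapsing them to a ratio (one unit of hazard is not one unit of
#' capacity): with five classes per index there are 25 distinct ratings, from
#' `[5,1]` (very high hazard, very low capacity: worst) to `[1,5]` (best).
#'
#' @param h_class,a_class integer class vectors in `1..k` (recycled to a
#'   common length).
#' @param k classification scale (default 5).
#' @return data.frame with columns `h_class`, `a_class`, `label` (e.g.
#'   `"5,1"`) and `designation` (`"worst"`, `"best"` or `NA`).
#' @examples
#' vulnerability_rating(5, 1)$designation # "worst"
#' @export
vulnerability_rating <- function(h_class, a_class, k = 5) {
  n <- max(length(h_class), length(a_class))
  h_class <- rep_len(as.integer(h_class), n)
  a_class <- rep_len(as.integer(a_class), n)
  if (anyNA(h_class) || anyNA(a_class) ||
      any(h_class < 1L | h_class > k) || any(a_class < 1L | a_class > k)) {
    abort("classes must be integers in 1..%d", k)
  }
  designation <- rep(NA_character_, n)
  designation[h_class == k & a_class == 1L] <- "worst"
  designation[h_class == 1L & a_class == k] <- "best"
  data.frame(
    h_class = h_class, a_class = a_class,
    label = paste(h_class, a_class, sep = ","),
    designation = designation, stringsAsFactors = FALSE
  )
}

#' Enumerate all possible vulnerability ratings
#'
#' @param k classification scale (default 5, giving 25 ratings).
#' @return data.frame of all `k^2` ratings, as in [vulnerability_rating()].
#' @export
all_ratings <- function(k = 5) {
  grid <- expand.grid(h_class = seq_len(k), a_class = seq_len(k))
  vulnerability_rating(grid$h_class, grid$a_class, k = k)
}
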