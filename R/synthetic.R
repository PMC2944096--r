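#' Configuration for the synthetic-county generator
#'
#' The generator emulates the statistical structure the stratification method
#' assumes: block groups nested in towns; widely dispersed block-group
#' populations (lognormal, targeting a mean of 1,262 people with SD 650, the
#' dispersion observed in the motivating county frame); MOS roughly
#' proportional to population; spatially smooth hazard and capacity indicator
#' fields that are inversely correlated across units (an industrial urban
#' core is high-hazard and low-capacity, a rural periphery the opposite);
#' and optionally an oversized "city" unit whose MOS forces a pre-split.
#'
#' @param seed integer; fixes all randomness.
#' @param n_towns number of towns (default 60).
#' @param bg_per_town integer range `c(min, max)` of block groups per town.
#' @param pop_mean,pop_sd target mean and SD of block-group populations.
#' @param births_per_capita expected births/year per person converting
#'   population to MOS (default 0.05, the MOS-to-population ratio of the
#'   packaged county fixture).
#' @param mos_noise_sd lognormal SD of the multiplicative MOS noise.
#' @param h_a_correlation target correlation between the latent hazard and
#'   capacity fields, in `[-1, 0]` (default -0.6).
#' @param smoothness spatial smoothing strength in `[0, 1]` for the latent
#'   fields (0 = white noise).
#' @param indicator_noise_sd SD of block-group-level indicator noise around
#'   the town latent value.
#' @param city_fraction fraction of towns promoted to an oversized city
#'   (default `1 / n_towns`, i.e. one city; 0 disables).
#' @param city_scale MOS of a city relative to the mean ordinary town
#'   (default 20, matching a dominant central city).
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(seed = 1, n_towns = 60, bg_per_town = c(1, 13),
                         pop_mean = 1262, pop_sd = 650,
                         births_per_capita = 0.05, mos_noise_sd = 0.05,
                         h_a_correlation = -0.6, smoothness = 0.6,
                         indicator_noise_sd = 0.3,
                         city_fraction = 1 / n_towns, city_scale = 20) {
  check_number(n_towns, "n_towns", lower = 1)
  check_number(h_a_correlation, "h_a_correlation", lower = -1, upper = 0)
  check_number(smoothness, "smoothness", lower = 0, upper = 1)
  check_number(city_fraction, "city_fraction", lower = 0, upper = 1)
  check_number(pop_mean, "pop_mean", lower = 1)
  check_number(pop_sd, "pop_sd", lower = 0)
  if (length(bg_per_town) != 2L || bg_per_town[1] < 1 ||
      bg_per_town[2] < bg_per_town[1]) {
    abort("bg_per_town must be an increasing range c(min, max), min >= 1")
  }
  structure(
    list(seed = as.integer(seed), n_towns = as.integer(n_towns),
         bg_per_town = as.integer(bg_per_town), pop_mean = pop_mean,
         pop_sd = pop_sd, births_per_capita = births_per_capita,
         mos_noise_sd = mos_noise_sd, h_a_correlation = h_a_correlation,
         smoothness = smoothness, indicator_noise_sd = indicator_noise_sd,
         city_fraction = city_fraction, city_scale = city_scale),
    class = "synth_config"
  )
}

# neighbour-averaging smoother on the town lattice
smooth_field <- function(z, adj, s, passes = 2L) {
  for (p in seq_len(passes)) {
    nb_mean <- vapply(seq_along(z), function(i) {
      if (length(adj[[i]]) == 0L) z[i] else mean(z[adj[[i]]])
    }, numeric(1))
    z <- (1 - s) * z + s * nb_mean
  }
  as.numeric(scale(z))
}

#' Generate a synthetic study area
#'
#' Lays the towns out on a jittered rectangular lattice (geometry is
#' abstract: the method consumes contiguity, not shape) with rook adjacency,
#' draws a smooth latent "urbanicity" field and a correlated latent capacity
#' field over it, and emits block groups nested in towns with raw indicator
#' columns matching [default_indicators()]: the three hazard densities load
#' positively on urbanicity; the five social indicators load on the capacity
#' field with their natural polarities (income up, poverty/education-only/
#' linguistic-isolation/minority down). Block-group populations are lognormal
#' and MOS is population times the birth rate with multiplicative noise.
#'
#' With `city_fraction > 0`, the most urban town(s) are inflated into cities
#' whose MOS is `city_scale` times the mean ordinary town, guaranteeing at
#' least one unit above any reasonable stratum MOS bound.
#'
#' @param config a [synth_config()].
#' @return a [study_area()] with town and block-group units, raw indicators,
#'   MOS, and a connected rook-lattice adjacency.
#' @examples
#' area <- generate_county(synth_config(seed = 7, n_towns = 20))
#' area
#' @export
generate_county <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_towns
  with_seed(config$seed, {
    # jittered lattice and rook adjacency
    nr <- max(1L, floor(sqrt(n)))
    nc <- ceiling(n / nr)
    row <- (seq_len(n) - 1L) %/% nc
    col <- (seq_len(n) - 1L) %% nc
    town_ids <- sprintf("T%03d", seq_len(n))
    edges <- list()
    for (i in seq_len(n)) {
      if (col[i] + 1L < nc && i + 1L <= n && row[i + 1L] == row[i]) {
        edges[[length(edges) + 1L]] <- c(i, i + 1L)
      }
      if (i + nc <= n) edges[[length(edges) + 1L]] <- c(i, i + nc)
    }
    edf <- do.call(rbind, edges)
    adj <- vector("list", n)
    for (k in seq_len(nrow(edf))) {
      adj[[edf[k, 1L]]] <- c(adj[[edf[k, 1L]]], edf[k, 2L])
      adj[[edf[k, 2L]]] <- c(adj[[edf[k, 2L]]], edf[k, 1L])
    }

    # latent fields: urbanicity u drives hazards; capacity c is negatively
    # coupled to u with the configured correlation
    u <- smooth_field(rnorm(n), adj, config$smoothness)
    w <- smooth_field(rnorm(n), adj, config$smoothness)
    w <- as.numeric(scale(stats::residuals(stats::lm(w ~ u))))
    rho <- -config$h_a_correlation
    cap <- -(rho * u) + sqrt(max(0, 1 - rho^2)) * w

    # block groups per town; cities get many more
    n_city <- if (config$city_fraction > 0) {
      max(1L, as.integer(round_half_up(config$city_fraction * n)))
    } else 0L
    city_idx <- if (n_city > 0L) order(u, decreasing = TRUE)[seq_len(n_city)] else integer(0)
    nbg <- sample(seq(config$bg_per_town[1], config$bg_per_town[2]),
                  n, replace = TRUE)
    mean_bg <- mean(seq(config$bg_per_town[1], config$bg_per_town[2]))
    nbg[city_idx] <- as.integer(round_half_up(config$city_scale * mean_bg))

    # lognormal block-group populations hitting the target mean/SD
    cv2 <- (config$pop_sd / config$pop_mean)^2
    sdlog <- sqrt(log(1 + cv2))
    meanlog <- log(config$pop_mean) - sdlog^2 / 2

    town_rows <- list()
    bg_rows <- list()
    noise_sd <- config$indicator_noise_sd
    for (i in seq_len(n)) {
      pops <- round_half_up(rlnorm(nbg[i], meanlog, sdlog))
      pops <- pmax(pops, 1)
      mos_bg <- pops * config$births_per_capita *
        rlnorm(nbg[i], 0, config$mos_noise_sd)
      bg_u <- u[i] + rnorm(nbg[i], 0, noise_sd)
      bg_c <- cap[i] + rnorm(nbg[i], 0, noise_sd)
      bg <- data.frame(
        unit_id = sprintf("%s_BG%03d", town_ids[i], seq_len(nbg[i])),
        name = sprintf("%s block group %d", town_ids[i], seq_len(nbg[i])),
        scale = "block_group",
        parent_id = town_ids[i],
        population = pops,
        mos = mos_bg,
        # hazard densities: positive loadings on urbanicity, plausible scales
        pop_density = 1500 * exp(0.9 * (bg_u + rnorm(nbg[i], 0, noise_sd))),
        traffic_density = 4000 * exp(0.8 * (bg_u + rnorm(nbg[i], 0, noise_sd))),
        pollution_density = pmax(0, 2 + 1.5 * (bg_u + rnorm(nbg[i], 0, noise_sd))),
        # capacity indicators with their natural polarities
        education_hs_pct = pmin(80, pmax(5, 35 - 8 * (bg_c + rnorm(nbg[i], 0, noise_sd)))),
        median_income = pmax(15000, 55000 + 15000 * (bg_c + rnorm(nbg[i], 0, noise_sd))),
        poverty_pct = pmin(60, pmax(0.5, 9 - 4 * (bg_c + rnorm(nbg[i], 0, noise_sd)))),
        linguistic_isolation_pct = pmin(50, pmax(0.1, 5 - 2.5 * (bg_c + rnorm(nbg[i], 0, noise_sd)))),
        minority_pct = pmin(95, pmax(0.5, 15 - 8 * (bg_c + rnorm(nbg[i], 0, noise_sd)))),
        stringsAsFactors = FALSE
      )
      bg_rows[[i]] <- bg
      town_rows[[i]] <- data.frame(
        unit_id = town_ids[i],
        name = if (i %in% city_idx) sprintf("City %s", town_ids[i]) else
          sprintf("Town %s", town_ids[i]),
        scale = "town",
        parent_id = NA_character_,
        population = sum(pops),
        mos = sum(mos_bg),
        stringsAsFactors = FALSE
      )
    }
    towns <- do.call(rbind, town_rows)
    bgs <- do.call(rbind, bg_rows)
    # pad the bg-only indicator columns on the town table with NA; town-level
    # values are derived by population-weighted aggregation downstream
    for (col in setdiff(names(bgs), names(towns))) towns[[col]] <- NA_real_
    units <- rbind(towns, bgs[, names(towns)])

    edge_df <- data.frame(from = town_ids[edf[, 1L]], to = town_ids[edf[, 2L]],
                          stringsAsFactors = FALSE)
    study_area(units, edge_df,
               name = sprintf("synthetic county (seed %d)", config$seed),
               source = "generate_county")
  })
}
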