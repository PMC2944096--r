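#' Load the packaged Worcester County, MA stratification fixture
#'
#' A transcription of the published data summary for the Worcester County
#' study frame: 59 towns plus the city of Worcester represented by its five
#' pre-split sub-strata (the source prints no block-group-level data for the
#' city), with town population (2000 census), MOS (expected births/year,
#' 2001-2008 data), standardized index values H_s and A_s, the 1-5 H and A
#' classes, block-group summary columns, and the published 18-stratum
#' assignment.
#'
#' Notes on the transcription:
#' * City sub-strata print no town population or town-scale H_s/A_s; the
#'   fixture units take `population` from the printed stratum population and
#'   `h_s`/`a_s` from the printed mean block-group index values.
#' * Printed stratum MOS totals differ by up to 1 birth/year from the sum of
#'   their towns' printed MOS (rounding in the source); the `stratum_mos`
#'   column carries the printed totals.
#' * The source does not publish a town contiguity matrix. The bundled
#'   adjacency (`worcester_town_adjacency_synthetic.csv`) is a synthetic,
#'   plausible reconstruction: every published stratum is connected under it
#'   and neighbouring strata share edges, but individual town borders are not
#'   authoritative.
#'
#' @return a list with elements
#'   \describe{
#'     \item{area}{a [study_area()] of the 64 top-scale units and the
#'       synthetic adjacency,}
#'     \item{partition}{the published 18-stratum assignment as a
#'       [partition] object,}
#'     \item{table}{the full transcribed table (one row per printed row),
#'       including stratum-level columns.}
#'   }
#' @examples
#' fx <- load_worcester_fixture()
#' sum(fx$table$n_block_groups) # 595 block-groups county-wide
#' @export
load_worcester_fixture <- function() {
  tab_path <- system.file("extdata", "worcester_strata_summary.csv",
                          package = "vulnstrat", mustWork = TRUE)
  adj_path <- system.file("extdata", "worcester_town_adjacency_synthetic.csv",
                          package = "vulnstrat", mustWork = TRUE)
  tab <- read.csv(tab_path, stringsAsFactors = FALSE)

  units <- data.frame(
    unit_id = tab$unit_id,
    name = tab$name,
    scale = tab$scale,
    parent_id = NA_character_,
    population = ifelse(is.na(tab$population), tab$stratum_pop, tab$population),
    mos = tab$mos,
    h_s = ifelse(is.na(tab$h_s), tab$mean_bg_hs, tab$h_s),
    a_s = ifelse(is.na(tab$a_s), tab$mean_bg_as, tab$a_s),
    h_class = tab$h_class,
    a_class = tab$a_class,
    stringsAsFactors = FALSE
  )
  graph <- read_adjacency(adj_path, unit_ids = units$unit_id)
  area <- study_area(units, graph,
                     name = "Worcester County, MA",
                     source = "published stratification table; synthetic adjacency")
  part <- new_partition(
    setNames(as.character(tab$stratum), tab$unit_id), area
  )
  list(area = area, partition = part, table = tab)
}
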