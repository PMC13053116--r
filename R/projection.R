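#' Project expected affected individuals in a population
#'
#' Scales a genetic prevalence (or single-genotype frequency) to an
#' expected count of affected individuals in a named population. The raw
#' product is kept alongside a rounded figure with an explicit rounding
#' grain, since headline numbers for large populations are conventionally
#' reported to the nearest 50 or 100 while small counts are reported
#' exactly.
#'
#' @param population_size Number of individuals (non-negative).
#' @param rate Probability (prevalence or genotype frequency) in `[0, 1]`.
#' @param grain Rounding grain (positive integer); the rounded count is the
#'   nearest multiple of `grain`, halves away from zero. Default: 1 when
#'   the raw expectation is below 1000, otherwise 100.
#' @param population_name Optional label recorded in the output.
#' @return One-row tibble with `population_name`, `population_size`,
#'   `rate`, `expected_count_raw`, `expected_count_rounded`, `grain`.
#' @export
#' @examples
#' project_affected(8.2e9, 1 / 235776, grain = 100)
project_affected <- function(population_size, rate, grain = NULL,
                             population_name = NA_character_) {
  stopifnot(population_size >= 0, rate >= 0, rate <= 1)
  raw <- population_size * rate
  if (is.null(grain)) grain <- if (raw < 1000) 1L else 100L
  if (grain <= 0) stop("rounding grain must be a positive integer", call. = FALSE)
  tibble::tibble(
    population_name = population_name,
    population_size = population_size,
    rate = rate,
    expected_count_raw = raw,
    expected_count_rounded = grain * round_half_away(raw / grain),
    grain = as.integer(grain)
  )
}

#' Project across a population table
#'
#' @param populations Tibble from [read_population_table()].
#' @param rate Probability applied to every population.
#' @param grain Optional common rounding grain (default: per-row automatic,
#'   see [project_affected()]).
#' @return Tibble with one projection row per population.
#' @export
project_populations <- function(populations, rate, grain = NULL) {
  dplyr::bind_rows(lapply(seq_len(nrow(populations)), function(i) {
    project_affected(populations$population_size[i], rate, grain,
                     population_name = populations$population_name[i])
  }))
}
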