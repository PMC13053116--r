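#' Per-variant allele frequency in one ancestry group
#'
#' @param variants Tibble with per-group `AC_*`/`AN_*` columns (candidates
#'   or inclusion sets).
#' @param group Ancestry-group label, or `"all"` for the pooled frequency
#'   `sum(AC_g) / sum(AN_g)` across groups (matching how a global AF column
#'   is constructed from stratified counts).
#' @return Numeric vector of allele frequencies; variants with no allele
#'   number in the group contribute zero (with a warning), mirroring the
#'   convention that variants absent from the reference cohort have AF 0.
#' @export
group_allele_frequency <- function(variants, group) {
  groups <- ancestry_groups()
  if (identical(group, "all")) {
    ac <- rowSums(as.matrix(variants[paste0("AC_", groups)]))
    an <- rowSums(as.matrix(variants[paste0("AN_", groups)]))
  } else {
    if (!group %in% groups) stop("unknown ancestry group: ", group, call. = FALSE)
    ac <- variants[[paste0("AC_", group)]]
    an <- variants[[paste0("AN_", group)]]
  }
  af <- numeric(length(ac))
  has_an <- !is.na(an) & an > 0
  if (any(!has_an)) {
    warning(sum(!has_an), " variant(s) with no allele number in group '",
            group, "' contribute AF = 0", call. = FALSE)
  }
  af[has_an] <- ac[has_an] / an[has_an]
  af
}

#' Aggregate allele frequency of an inclusion set
#'
#' The aggregate allele frequency of a group is the sum over included
#' variants of that group's per-variant allele frequency. An aggregate
#' above 1 is not a probability and signals malformed input, so it raises
#' an error rather than being clamped.
#'
#' @inheritParams group_allele_frequency
#' @param included Inclusion set from [inclusion_set()] (or any variant
#'   table with frequency columns).
#' @return The aggregate allele frequency (a probability).
#' @export
aggregate_allele_frequency <- function(included, group) {
  if (nrow(included) == 0L) return(0)
  s <- sum(group_allele_frequency(included, group))
  if (s > 1) {
    stop("aggregate frequency exceeds 1 in group '", group,
         "': malformed input", call. = FALSE)
  }
  s
}

#' Carrier frequency from an aggregate allele frequency
#'
#' Uses the Hardy-Weinberg approximation `2 * sum_q` for the fraction of
#' heterozygous carriers (the exact binomial form `2q(1-q)` differs by
#' under 1% at the frequencies seen for rare recessive disease; the linear
#' form is the stated convention of this estimator).
#'
#' @param sum_q Aggregate allele frequency, at most 0.5.
#' @return Carrier frequency `2 * sum_q`.
#' @export
carrier_frequency <- function(sum_q) {
  stopifnot(all(sum_q >= 0))
  if (any(sum_q > 0.5)) {
    stop("aggregate allele frequency above 0.5: carrier frequency would exceed 1",
         call. = FALSE)
  }
  2 * sum_q
}

#' Genetic prevalence from an aggregate allele frequency
#'
#' Under Hardy-Weinberg equilibrium the expected fraction of individuals
#' carrying two included alleles (homozygous or compound heterozygous) is
#' `sum_q^2`, since `(sum q_i)^2 = sum_i sum_j q_i q_j` enumerates every
#' ordered pair of disease alleles.
#'
#' @param sum_q Aggregate allele frequency in `[0, 1]`.
#' @return Genetic prevalence `sum_q^2`.
#' @export
genetic_prevalence <- function(sum_q) {
  stopifnot(all(sum_q >= 0), all(sum_q <= 1))
  sum_q^2
}

#' Homozygote frequency of a single variant
#'
#' Expected frequency of individuals homozygous for one specific variant in
#' one ancestry group: the squared group allele frequency.
#'
#' @param variant One-row variant tibble with frequency columns.
#' @param group Ancestry-group label.
#' @return `q^2` for that variant and group.
#' @export
homozygote_frequency <- function(variant, group) {
  stopifnot(nrow(variant) == 1L)
  an <- variant[[paste0("AN_", group)]]
  if (is.null(an) || is.na(an) || an == 0) {
    stop("no frequency data for group '", group, "'", call. = FALSE)
  }
  (variant[[paste0("AC_", group)]] / an)^2
}

#' Format a frequency as "1 in N"
#'
#' @param freq Frequency in `(0, 1]`.
#' @return `"1 in N"` with `N = 1/freq` rounded to the nearest integer,
#'   halves away from zero.
#' @export
#' @examples
#' format_one_in(0.015625)
format_one_in <- function(freq) {
  if (any(freq <= 0)) stop("frequency must be positive", call. = FALSE)
  paste("1 in", format(round_half_away(1 / freq), scientific = FALSE))
}

#' Reciprocal denominator of a frequency
#'
#' The numeric `N` of [format_one_in()], convenient for comparisons.
#'
#' @inheritParams format_one_in
#' @return `round(1/freq)` (halves away from zero).
#' @export
one_in_denominator <- function(freq) {
  if (any(freq <= 0)) stop("frequency must be positive", call. = FALSE)
  round_half_away(1 / freq)
}

#' Format a frequency as a percentage
#'
#' @inheritParams format_one_in
#' @param digits Decimal places (default 2, the convention used for
#'   carrier-frequency bar charts).
#' @return Character, e.g. `"0.41%"`.
#' @export
format_percent <- function(freq, digits = 2) {
  pct <- round_half_away(freq * 100 * 10^digits) / 10^digits
  paste0(formatC(pct, format = "f", digits = digits), "%")
}

#' Per-group prevalence estimates
#'
#' Computes, for the pooled cohort and each ancestry group, the aggregate
#' allele frequency, carrier frequency (`2*sum_q`), genetic prevalence
#' (`sum_q^2`), the number of included variants observed in the group
#' (allele frequency above zero), and formatted display strings.
#'
#' @param included Inclusion set from [inclusion_set()].
#' @param mode Label recorded in the output (`"conservative"` or
#'   `"relaxed"`).
#' @return Tibble with one row per group in display order (`all` first)
#'   and columns `group`, `mode`, `sum_q`, `carrier_freq`, `prevalence`,
#'   `n_variants`, `carrier_one_in`, `prevalence_one_in`, `carrier_percent`.
#' @export
estimate_all_groups <- function(included, mode = "conservative") {
  rows <- lapply(ancestry_groups(display = TRUE), function(g) {
    af <- if (nrow(included)) group_allele_frequency(included, g) else numeric()
    sum_q <- sum(af)
    if (sum_q > 1) {
      stop("aggregate frequency exceeds 1 in group '", g, "'", call. = FALSE)
    }
    cf <- carrier_frequency(sum_q)
    gp <- genetic_prevalence(sum_q)
    tibble::tibble(
      group = g, mode = mode, sum_q = sum_q, carrier_freq = cf,
      prevalence = gp, n_variants = sum(af > 0),
      carrier_one_in = if (cf > 0) format_one_in(cf) else NA_character_,
      prevalence_one_in = if (gp > 0) format_one_in(gp) else NA_character_,
      carrier_percent = format_percent(cf)
    )
  })
  dplyr::bind_rows(rows)
}
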