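#' Merge source records into deduplicated candidate variants
#'
#' Collapses source records (from one or more [read_source_table()] calls)
#' onto distinct normalized variant keys. Each candidate carries the union
#' of its source provenance, a pLoF flag (true when any provenance record is
#' a high-confidence pLoF call), and, when a frequency table is supplied,
#' its per-group allele counts. Candidates absent from the frequency table
#' are retained (they still belong in curation queues) but contribute an
#' allele frequency of zero to every estimate.
#'
#' @param records Tibble of source records; multiple sources may be bound
#'   together with `dplyr::bind_rows()`.
#' @param freqs Optional frequency table from [read_frequency_table()].
#' @return Tibble with one row per distinct `(contig, pos, ref, alt)`,
#'   ordered by key, with columns `n_sources`, `sources` (list column of
#'   per-source records), `asserted_classes` (list column), `is_plof`,
#'   `hgvs_c`, `ac_total`, `in_gnomad` and the per-group `AC_*`, `AN_*`,
#'   `nhomalt_*` columns (zero when absent from `freqs`).
#' @export
dedupe_candidates <- function(records, freqs = NULL) {
  if (nrow(records) == 0L) {
    records <- tibble::tibble(
      contig = character(), pos = integer(), ref = character(),
      alt = character(), source = character(), asserted_class = character(),
      hgvs_c = character(), hgvs_p = character(), source_id = character()
    )
  }
  stopifnot(all(c("contig", "pos", "ref", "alt", "source",
                  "asserted_class") %in% names(records)))
  dup <- duplicated(records[c("contig", "pos", "ref", "alt", "source")])
  if (any(dup)) {
    # one record per source per key: keep first occurrence
    records <- records[!dup, ]
  }
  grp <- dplyr::group_by(records, .data$contig, .data$pos, .data$ref, .data$alt)
  out <- dplyr::summarise(
    grp,
    n_sources = dplyr::n(),
    sources = list(tibble::tibble(source = source,
                                  asserted_class = asserted_class,
                                  source_id = source_id)),
    asserted_classes = list(unique(.data$asserted_class)),
    is_plof = any(.data$asserted_class == "PLOF_HC"),
    hgvs_c = first_non_na(.data$hgvs_c),
    hgvs_p = first_non_na(.data$hgvs_p),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$contig, .data$pos, .data$ref, .data$alt)

  groups <- ancestry_groups()
  triples <- as.vector(t(outer(c("AC_", "AN_", "nhomalt_"), groups, paste0)))
  if (!is.null(freqs)) {
    out <- dplyr::left_join(
      out, freqs[c("contig", "pos", "ref", "alt", triples)],
      by = c("contig", "pos", "ref", "alt")
    )
    out$in_gnomad <- !is.na(out[[paste0("AC_", groups[1])]])
  } else {
    for (cc in triples) out[[cc]] <- NA_integer_
    out$in_gnomad <- FALSE
  }
  for (cc in triples) out[[cc]][is.na(out[[cc]])] <- 0L
  out$ac_total <- as.integer(rowSums(as.matrix(
    out[paste0("AC_", groups)]
  )))
  out
}

first_non_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x)) x[1] else NA_character_
}
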